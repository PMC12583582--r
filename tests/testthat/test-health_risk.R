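reg <- default_registry()
p_adult <- registry_lookup(reg, "exposure_profiles", "pte_adult")
p_child <- registry_lookup(reg, "exposure_profiles", "pte_child")

test_that("ingestion dose matches the hand-multiplied oracle", {
  # C*IngR*CF*EF*ED/(BW*AT) with the adult profile at the mean Pb level
  oracle <- 27.04 * 100 * 1e-6 * 350 * 30 / (70 * 365 * 30)
  expect_equal(compute_add(27.04, "ingestion", p_adult), oracle)
  expect_equal(round(oracle, 9), 3.7041e-05, tolerance = 1e-6)
})

test_that("doses are linear in concentration and vanish at zero", {
  for (pw in c("ingestion", "inhalation", "dermal")) {
    expect_identical(compute_add(0, pw, p_adult), 0)
    expect_equal(compute_add(2 * 13.7, pw, p_child),
                 2 * compute_add(13.7, pw, p_child))
  }
})

test_that("dose scales inversely with body weight", {
  p2 <- p_adult
  p2$BW <- 2 * p_adult$BW
  for (pw in c("ingestion", "inhalation", "dermal")) {
    expect_equal(compute_add(50, pw, p2), compute_add(50, pw, p_adult) / 2)
  }
})

test_that("with AT = 365*ED the exposure duration cancels in HQ", {
  p1 <- p_adult
  p2 <- p_adult
  p2$ED <- 7
  p2$AT_nc <- 365 * 7
  for (pw in c("ingestion", "inhalation", "dermal")) {
    expect_equal(compute_add(80, pw, p1), compute_add(80, pw, p2))
  }
})

test_that("strict-paper inhalation mode uses the literal printed formula", {
  default <- compute_add(50, "inhalation", p_adult)
  strict <- compute_add(50, "inhalation", p_adult, strict_paper = TRUE)
  expect_equal(default,
               50 * p_adult$InhR * p_adult$EF * p_adult$ED /
                 (p_adult$PEF * p_adult$BW * p_adult$AT_nc))
  expect_equal(strict,
               50 * p_adult$IngR * p_adult$CF * p_adult$EF * p_adult$ED /
                 (p_adult$PEF * p_adult$BW * p_adult$AT_nc))
  expect_true(abs(default - strict) > 0)
})

test_that("hazard quotients and index follow HQ = ADD/RfD, HI = sum", {
  expect_equal(compute_hq(0.003, 0.003), 1)
  expect_equal(compute_hi(c(1e-4, 2e-5, 3e-6)), 1.23e-4)
  set.seed(5)
  hqs <- runif(6)
  expect_identical(compute_hi(hqs), compute_hi(sample(hqs)))
  expect_error(compute_hq(1, 0), "> 0")
})

test_that("child ingestion hazard exceeds the adult's at equal concentration", {
  for (c0 in c(0.5, 27.04, 300)) {
    hq_child <- compute_hq(compute_add(c0, "ingestion", p_child), 0.0035)
    hq_adult <- compute_hq(compute_add(c0, "ingestion", p_adult), 0.0035)
    expect_gt(hq_child, hq_adult)
  }
})

test_that("carcinogenic risk requires all three pathways and bands correctly", {
  zero <- c(ingestion = 0, inhalation = 0, dermal = 0)
  r0 <- compute_cr(zero, sf = 1.5)
  expect_equal(r0$cr, 0)
  expect_equal(as.character(r0$band), "negligible")
  r1 <- compute_cr(c(ingestion = 5e-6, inhalation = 1e-6, dermal = 4e-6),
                   sf = 1.5)
  expect_equal(r1$cr, 1.5e-5)
  expect_equal(as.character(r1$band), "acceptable_range")
  r2 <- compute_cr(c(ingestion = 1e-3, inhalation = 0, dermal = 0), sf = 1.5)
  expect_equal(as.character(r2$band), "unacceptable")
  expect_error(compute_cr(c(ingestion = 1e-6, dermal = 1e-6), 1.5),
               "inhalation")
  # strictly increasing in each pathway dose
  base <- c(ingestion = 1e-6, inhalation = 1e-8, dermal = 1e-7)
  for (pw in names(base)) {
    up <- base
    up[pw] <- up[pw] * 2
    expect_gt(compute_cr(up, 1.5)$cr, compute_cr(base, 1.5)$cr)
  }
})

test_that("survey-level health risk has HI = sum of pathway HQs", {
  sv <- soil_survey(c("S1", "S2"),
                    data.frame(Pb = c(27.04, 5), Cr = c(111, 72)),
                    ph = 8.5, ec = 400)
  hr <- health_risk(sv)
  for (rec in c("child", "adult")) {
    tab <- hr[[rec]]
    expect_equal(tab$HI,
                 tab$HQ_ingestion + tab$HQ_inhalation + tab$HQ_dermal)
    expect_true(all(tab$CR >= 0, na.rm = TRUE))
  }
  # published qualitative finding: children carry higher hazard than adults
  expect_true(all(hr$child$HI > hr$adult$HI))
})
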