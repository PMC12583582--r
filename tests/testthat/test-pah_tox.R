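reg <- default_registry()

test_that("toxicity equivalents are the exact TEF-weighted sum", {
  r <- compute_teq(c(DBA = 31.65, Ant = 141.02), c(DBA = 1, Ant = 0.01))
  expect_equal(unname(r$bapeq), c(31.65, 1.4102))
  expect_equal(round(r$teq, 2), 33.06)
  # single compound with TEF 1 passes through; all-zero TEFs vanish
  expect_equal(compute_teq(c(BaP = 12.5), c(BaP = 1))$teq, 12.5)
  expect_equal(compute_teq(c(Ant = 9, Flu = 4), c(Ant = 0, Flu = 0))$teq, 0)
  expect_error(compute_teq(c(Ant = 1, Xyz = 2), c(Ant = 0.01)), "Xyz")
})

test_that("TEQ is additive over disjoint compound sets", {
  tefs <- setNames(reg$pah$tef_paper, reg$pah$compound)
  set.seed(23)
  conc <- setNames(rlnorm(15, 2, 1), pah_compounds())
  split <- sample(15, 7)
  expect_equal(compute_teq(conc, tefs)$teq,
               compute_teq(conc[split], tefs)$teq +
                 compute_teq(conc[-split], tefs)$teq)
})

test_that("ND handling: excluded by default, half-LOD on request", {
  conc <- c(BaP = NA, Ant = 100)
  tefs <- c(BaP = 1, Ant = 0.01)
  expect_equal(compute_teq(conc, tefs)$teq, 1)
  expect_equal(compute_teq(conc, tefs, nd = "half_lod",
                           lod = c(BaP = 2, Ant = 2))$teq, 1 + 1)
  expect_error(compute_teq(conc, tefs, nd = "half_lod"), "lod")
})

test_that("child ingestion ILCR matches the hand-evaluated oracle", {
  # cs * CSF_ing * (BW/70)^(1/3) * IR * EF * ED / (BW * AT * 1e6)
  oracle <- 73.55 * (3.7 * (15 / 70)^(1 / 3)) * 200 * 180 * 6 /
    (15 * 25550 * 1e6)
  r <- compute_ilcr(73.55, "child")
  expect_equal(r$ingestion, oracle)
  expect_equal(r$ingestion, 9.18e-5, tolerance = 2e-3)
  expect_equal(r$total, r$ingestion + r$dermal + r$inhalation)
})

test_that("ILCR vanishes at zero and is monotone in cs", {
  z <- compute_ilcr(0, "adult")
  expect_equal(c(z$ingestion, z$dermal, z$inhalation, z$total), rep(0, 4))
  lo <- compute_ilcr(10, "adult")
  hi <- compute_ilcr(20, "adult")
  for (f in c("ingestion", "dermal", "inhalation", "total")) {
    expect_gt(hi[[f]], lo[[f]])
  }
})

test_that("receptor orderings match the published qualitative pattern", {
  child <- compute_ilcr(73.55, "child")
  adult <- compute_ilcr(73.55, "adult")
  expect_gt(child$ingestion, adult$ingestion)  # hand-to-mouth intake
  expect_gt(adult$dermal, child$dermal)        # larger skin area, longer ED
})

test_that("ERL/ERM screening classifies against both thresholds", {
  scr <- screen_erl_erm(c(Ant = 141.02, Nap = 4.46, Flu = 27.53, BaP = NA))
  cls <- setNames(scr$class, scr$compound)
  expect_equal(cls[["Ant"]], "possible")   # above ERL 85.3, below ERM 1100
  expect_equal(cls[["Nap"]], "minimal")    # below ERL 160
  expect_equal(cls[["Flu"]], "possible")   # above ERL 19
  expect_equal(cls[["BaP"]], "not_detected")
  # boundary: exactly ERL screens possible, exactly ERM screens probable
  b <- screen_erl_erm(c(Ant = 85.3, Nap = 2100))
  expect_equal(setNames(b$class, b$compound),
               c(Ant = "possible", Nap = "probable"))
})

test_that("composition fractions agree with a ring-class summation oracle", {
  meta <- pah_metadata()
  set.seed(31)
  conc <- setNames(rlnorm(15, 3, 1), pah_compounds())
  cs <- composition_summary(conc)
  lmw_direct <- sum(conc[meta$compound[meta$rings <= 3]]) / sum(conc)
  carc_direct <- sum(conc[meta$compound[meta$carcinogenic]]) / sum(conc)
  expect_equal(cs$lmw_fraction, lmw_direct)
  expect_equal(cs$carcinogenic_fraction, carc_direct)
  expect_equal(cs$lmw_fraction + cs$hmw_fraction, 1)
  # degenerate profiles
  expect_equal(composition_summary(c(Ant = 5, Phe = 3))$lmw_fraction, 1)
  expect_equal(composition_summary(c(Ant = 5, BbF = 5))$lmw_fraction, 0.5)
  expect_error(composition_summary(c(BaP = NA)), "empty profile")
})
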