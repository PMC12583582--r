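ems <- end_members()

test_that("forward model handles pure end-members and hand-computed mixtures", {
  pure <- forward_mix(c(1, 0, 0), ems)
  expect_equal(pure$r_soil, 1.2252)
  expect_equal(pure$c_soil, 6681)
  mix <- forward_mix(c(0.3, 0.5, 0.2), ems)
  expect_equal(mix$r_soil, 0.3 * 1.2252 + 0.5 * 1.1497 + 0.2 * 1.097)
  expect_equal(mix$r_soil, 1.16181, tolerance = 1e-10)
  expect_equal(mix$c_soil, 1 / (0.3 / 6681 + 0.5 / 2397 + 0.2 / 2397))
  expect_equal(mix$c_soil, 2967.9, tolerance = 1e-4)
  sym <- forward_mix(rep(1 / 3, 3), ems)
  expect_equal(sym$r_soil, mean(ems$R))
  expect_error(forward_mix(c(0.5, 0.5, 0.5), ems), "sum to 1")
  expect_error(forward_mix(c(1.2, -0.1, -0.1), ems), "\\[0, 1\\]")
})

test_that("inversion recovers forward-generated fractions to 1e-9", {
  f <- c(0.3, 0.5, 0.2)
  obs <- forward_mix(f, ems)
  sol <- solve_mix(obs$r_soil, obs$c_soil, ems)
  expect_equal(unname(sol$f), f, tolerance = 1e-9)
  expect_true(sol$feasible)
  expect_lt(sol$residual, 1e-12)
  # pure end-member observation
  sol1 <- solve_mix(1.2252, 6681, ems)
  expect_equal(unname(sol1$f), c(1, 0, 0), tolerance = 1e-9)
})

test_that("round-trip identity holds over Dirichlet-sampled fractions", {
  set.seed(101)
  n <- 200
  g <- matrix(rgamma(3 * n, shape = c(2, 3, 2)), ncol = 3, byrow = TRUE)
  fr <- g / rowSums(g)
  worst <- 0
  for (i in seq_len(n)) {
    obs <- forward_mix(fr[i, ], ems)
    sol <- solve_mix(obs$r_soil, obs$c_soil, ems)
    worst <- max(worst, max(abs(sol$f - fr[i, ])))
    expect_equal(sum(sol$f), 1, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-9)
})

test_that("round trip also holds for random valid end-member sets", {
  set.seed(55)
  for (i in 1:25) {
    e <- end_members(r = sort(runif(3, 1.05, 1.30), decreasing = TRUE),
                     c = runif(3, 100, 9000))
    f <- as.numeric(rgamma(3, 2))
    f <- f / sum(f)
    obs <- forward_mix(f, e)
    sol <- solve_mix(obs$r_soil, obs$c_soil, e)
    expect_equal(unname(sol$f), f, tolerance = 1e-8)
  }
})

test_that("feasible mixtures stay inside the mixing envelope", {
  set.seed(77)
  for (i in 1:50) {
    f <- as.numeric(rgamma(3, 1))
    f <- f / sum(f)
    obs <- forward_mix(f, ems)
    expect_gte(obs$r_soil, min(ems$R) - 1e-12)
    expect_lte(obs$r_soil, max(ems$R) + 1e-12)
    expect_gte(obs$c_soil, min(ems$C) - 1e-9)
    expect_lte(obs$c_soil, max(ems$C) + 1e-9)
  }
})

test_that("observations outside the envelope are flagged, never clipped", {
  sol <- solve_mix(1.30, 3000, ems)  # ratio above every end-member
  expect_false(sol$feasible)
  expect_false(all(sol$f >= 0))
  expect_equal(sum(sol$f), 1, tolerance = 1e-12)
  proj <- solve_mix(1.30, 3000, ems, project = TRUE)
  expect_equal(sum(proj$f_projected), 1, tolerance = 1e-12)
  expect_true(all(proj$f_projected >= 0))
})

test_that("degenerate end-members raise a singularity error", {
  expect_error(end_members(r = c(1.2, 1.2, 1.1)), "distinct")
  e <- end_members()
  # equal ratio AND equal concentration on two sources: truly singular
  e$R <- c(1.2252, 1.097, 1.097)
  expect_error(solve_mix(1.15, 2000, e), "singular")
})

test_that("overdetermined solver agrees on consistent data and keeps the constraint", {
  f <- c(0.25, 0.45, 0.30)
  obs <- forward_mix(f, ems)
  sol <- solve_mix_overdetermined(obs$r_soil, obs$c_soil, obs$r_prime_soil,
                                  ems)
  expect_equal(unname(sol$f), f, tolerance = 1e-8)
  expect_lt(sol$residual, 1e-10)
  # perturbed second ratio: residual grows, constraint survives
  noisy <- solve_mix_overdetermined(obs$r_soil, obs$c_soil,
                                    obs$r_prime_soil * 1.01, ems)
  expect_gt(noisy$residual, 0)
  expect_equal(sum(noisy$f), 1, tolerance = 1e-12)
  # observation outside the mixing envelope on every coordinate: the
  # constrained least-squares solution leaves the simplex and is flagged
  conflict <- solve_mix_overdetermined(1.30, 8000, 2.55, ems)
  expect_false(conflict$feasible)
  expect_equal(sum(conflict$f), 1, tolerance = 1e-12)
})

test_that("contribution summaries average the published per-sample table", {
  tbl11 <- data.frame(
    F1 = c(0.3, 0.25, 0.1, 0.35, 0.2, 0.4, 0.45, 0.15, 0.35, 0.1, 0.25, 0.2),
    F2 = c(0.5, 0.5, 0.6, 0.45, 0.6, 0.4, 0.4, 0.55, 0.45, 0.7, 0.5, 0.5),
    F3 = c(0.2, 0.25, 0.3, 0.2, 0.2, 0.2, 0.15, 0.3, 0.2, 0.2, 0.25, 0.3)
  )
  # every published row is a valid fraction triple
  expect_equal(rowSums(tbl11), rep(1, 12), ignore_attr = TRUE)
  s <- summarize_contributions(tbl11)
  expect_equal(s$mean, c(0.2583, 0.5125, 0.2292), tolerance = 1e-3)
  one <- summarize_contributions(tbl11[3, ])
  expect_equal(one$mean, unname(unlist(tbl11[3, ])), ignore_attr = TRUE)
  perm <- summarize_contributions(tbl11[sample(12), ])
  expect_equal(perm$mean, s$mean)
})

test_that("industrial-ratio sensitivity sweep spans the published range", {
  obs <- forward_mix(c(0.3, 0.5, 0.2), ems)
  sw <- sensitivity_r2(obs$r_soil, obs$c_soil)
  expect_equal(nrow(sw), 8)
  expect_equal(range(sw$r2), c(1.1427, 1.1567))
  # fractions respond smoothly (no sign flips of the trend)
  expect_true(all(diff(sw$F2) < 0) || all(diff(sw$F2) > 0))
})
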