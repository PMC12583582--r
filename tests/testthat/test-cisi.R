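test_that("chemical index is min-max scaling with clamped extremes", {
  expect_equal(chemical_index(10, 0, 10), 1)
  expect_equal(chemical_index(0, 0, 10), 0)
  expect_equal(chemical_index(5, 0, 10), 0.5)
  expect_warning(out <- chemical_index(12, 0, 10), "clamped")
  expect_equal(out, 1)
  expect_error(chemical_index(1, 3, 3), "degenerate")
  # shift invariance
  set.seed(9)
  x <- runif(20, 10, 50)
  expect_equal(chemical_index(x, min(x), max(x)),
               chemical_index(x + 7, min(x) + 7, max(x) + 7))
})

test_that("isotopic index is one minus the relative deviation", {
  expect_equal(isotopic_index(1.2, 1.2), 1)
  expect_equal(isotopic_index(2.5, 2.5), 1)
  expect_equal(isotopic_index(0.6, 1.2), 0.5)
  expect_equal(isotopic_index(3.0, 1.2), 1 - 1.8 / 1.2)  # negative, unclamped
  expect_equal(isotopic_index(3.0, 1.2, clamp = TRUE), 0)
  expect_error(isotopic_index(1, 0), "> 0")
})

test_that("combined index reproduces the published low-contamination sample", {
  r <- compute_cisi(0.0778, c(0.1675, 0.5316))
  expect_equal(round(r$cisi, 4), 0.1865)
  expect_equal(r$ii_mean, mean(c(0.1675, 0.5316)))
  # degenerate all-zero / all-one cases
  expect_equal(compute_cisi(0, c(0, 0))$cisi, 0)
  expect_equal(compute_cisi(c(1, 1), c(1, 1))$cisi, 1)
  expect_error(compute_cisi(numeric(0), 1), "CI")
})

test_that("published high-contamination sample back-solves consistently", {
  # CISI 0.6468 with II pair (0.7880, 0.8340) implies a mean chemical index
  # near 0.5373 under weights (0.6, 0.4)
  ci_implied <- (0.6468 - 0.4 * mean(c(0.7880, 0.8340))) / 0.6
  expect_lt(abs(ci_implied - 0.5373), 2e-4)
  expect_equal(round(compute_cisi(ci_implied, c(0.7880, 0.8340))$cisi, 4),
               0.6468)
})

test_that("index is bounded and monotone under valid weights", {
  set.seed(21)
  for (i in 1:20) {
    ci <- runif(5)
    ii <- runif(2)
    r <- compute_cisi(ci, ii)
    expect_gte(r$cisi, 0)
    expect_lte(r$cisi, 1)
    # raising any component raises the index
    ci2 <- ci
    ci2[1] <- min(ci2[1] + 0.1, 1)
    expect_gte(compute_cisi(ci2, ii)$cisi, r$cisi)
  }
  expect_error(cisi_config(w1 = 0.7, w2 = 0.4), "sum to 1")
})

test_that("table-level assessment ranks samples and is shift-invariant", {
  chem <- data.frame(sample_id = paste0("S", 1:6), pH = c(7, 8, 7.5, 8.2, 7.1, 7.9),
                     Fe = c(1, 5, 3, 2, 4, 6) * 1e4, Mn = seq(300, 800, 100),
                     Pb = c(10, 120, 50, 30, 80, 60), Ca = c(1, 3, 2, 5, 4, 6) * 1e3)
  iso <- data.frame(sample_id = paste0("S", 1:6),
                    r206_207 = seq(1.10, 1.22, length.out = 6),
                    r208_207 = seq(2.40, 2.49, length.out = 6))
  tab <- cisi_assess(chem, iso)
  expect_equal(tab$CISI, 0.6 * tab$CI_mean + 0.4 * tab$II_mean)
  expect_true(all(tab$CI_mean >= 0 & tab$CI_mean <= 1))
  expect_equal(sort(tab$rank), 1:6)
  # adding a constant to every chemical value leaves CISI unchanged
  chem2 <- chem
  for (p in c("Fe", "Mn", "Pb", "Ca")) chem2[[p]] <- chem2[[p]] + 1000
  expect_equal(cisi_assess(chem2, iso)$CISI, tab$CISI)
})

test_that("PCA validation yields orthonormal loadings and full variance", {
  set.seed(42)
  x <- matrix(rnorm(200 * 5), 200, 5)
  p <- validate_pca(x)
  expect_equal(sum(p$explained), 1)
  expect_equal(unname(t(p$loadings) %*% p$loadings), diag(5),
               tolerance = 1e-9)
  # deterministic sign: largest-magnitude loading element positive
  for (j in 1:5) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # two perfectly correlated features: PC1 explains everything
  y <- cbind(a = x[, 1], b = 2 * x[, 1])
  suppressWarnings(p2 <- validate_pca(y))
  expect_equal(p2$explained[1], 1, tolerance = 1e-12)
  # identity covariance at large n: near-equal variance shares
  expect_true(all(abs(p$explained - 0.2) < 0.05))
  expect_error(validate_pca(x[1:2, ]), "3 samples")
  expect_warning(validate_pca(cbind(x, const = 1)), "zero-variance")
})

test_that("weight sweep finds the variance-maximising weighting", {
  ci <- c(0.1, 0.9)
  ii <- c(0.5, 0.5)  # no isotopic contrast: all weight on CI maximises spread
  sw <- sensitivity_weights(ci, ii, w1_grid = seq(0, 1, 0.25))
  # brute-force oracle over the same grid
  best <- seq(0, 1, 0.25)[which.max(vapply(seq(0, 1, 0.25), function(w)
    var(w * ci + (1 - w) * ii), numeric(1)))]
  expect_equal(attr(sw, "best_w1"), best)
  expect_equal(attr(sw, "best_w1"), 1)
  # single sample: flat sweep
  flat <- sensitivity_weights(0.4, 0.7)
  expect_true(all(flat$cisi_var == 0))
  # w1 = 1 reduces CISI to the mean chemical index
  expect_equal(compute_cisi(0.3, 0.9, cisi_config(w1 = 1, w2 = 0))$cisi, 0.3)
})
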