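# Shared fixtures built in code.

# published descriptive statistics used as calibration targets
tbl_pte <- default_pte_targets()

# published mean Er values (for the aggregate-index oracle)
mean_er_published <- c(Zn = 4.05, Cu = 9.8, Ni = 14.05, Pb = 9.01,
                       Cr = 6.37, Cd = 91.32, As = 9.62)

# brute-force central-moment oracle, independent of compute_descriptive_stats
brute_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^(3 / 2)
  g2 <- (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2 - 3
  list(mean = m, sd = s,
       skew = g1 * sqrt(n * (n - 1)) / (n - 2),
       kurt = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)))
}

# small three-sample PTE survey written to a temp CSV
write_pte_fixture <- function(path = tempfile(fileext = ".csv")) {
  sv <- soil_survey(c("A1", "A2", "A3"),
                    data.frame(Zn = c(74, 125.55, 270),
                               Cd = c(0.19, 0.24, 1.6)),
                    ph = c(8.1, 8.5, 8.8), ec = c(223, 674, 3160),
                    land_use = c("industrial", "residential", "traffic"))
  write_survey(sv, path)
  path
}
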