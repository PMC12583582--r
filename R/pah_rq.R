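# Risk quotients of individual PAHs against negligible-concentration (NC)
# and maximum-permissible-concentration (MPC) benchmarks, cumulative
# sum-of-quotients over compounds at or above 1, and the classification grid.

#' Risk quotient
#'
#' `RQ = C / benchmark`; linear in the concentration.
#'
#' @param c Concentration, ug/kg (non-negative; vectorised).
#' @param benchmark NC or MPC benchmark, ug/kg (> 0).
#' @return RQ, dimensionless.
#' @export
#' @examples
#' compute_rq(141.02, 1.2)   # ~117.5
#' compute_rq(141.02, 120)   # ~1.175
compute_rq <- function(c, benchmark) {
  if (any(benchmark <= 0)) stop("benchmark must be > 0", call. = FALSE)
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  c / benchmark
}

#' Classify an individual PAH by its two risk quotients
#'
#' Both RQ < 1: negligible (risk-free); RQ_nc >= 1 and RQ_mpc < 1:
#' low_to_moderate; RQ_mpc >= 1: high. Boundaries are >=-inclusive.
#'
#' @param rq_nc,rq_mpc Risk quotients against NC and MPC (vectorised).
#' @return Character vector of classes.
#' @export
classify_individual_rq <- function(rq_nc, rq_mpc) {
  if (any(rq_nc < 0 | rq_mpc < 0, na.rm = TRUE)) {
    stop("risk quotients must be >= 0", call. = FALSE)
  }
  ifelse(rq_mpc >= 1, "high",
         ifelse(rq_nc >= 1, "low_to_moderate", "negligible"))
}

#' Cumulative risk quotient over a compound set
#'
#' Sums only the per-compound quotients that are at least 1 (compounds below
#' their benchmark do not contribute). The combined class uses the published
#' grid on the pair (sum of RQ_nc terms >= 1, sum of RQ_mpc terms >= 1):
#' both sums < 1: risk_free; NC sum in \[1, 800) and MPC sum < 1: low;
#' NC sum >= 800 and MPC sum < 1: moderate_1; NC sum < 800 and MPC sum >= 1:
#' moderate_2; both >= their bound: high. The grid's overlap at an NC sum of
#' exactly 800 with an MPC sum >= 1 is resolved to the higher class (high).
#'
#' @param rq_nc,rq_mpc Named numeric vectors of per-compound quotients.
#' @return List of class `"rq_cumulative"`: `sum_nc`, `sum_mpc`, `class`.
#' @export
cumulative_rq <- function(rq_nc, rq_mpc) {
  if (!length(rq_nc)) stop("empty risk-quotient map", call. = FALSE)
  s_nc <- sum(rq_nc[!is.na(rq_nc) & rq_nc >= 1])
  s_mpc <- sum(rq_mpc[!is.na(rq_mpc) & rq_mpc >= 1])
  cls <- if (s_nc < 1 && s_mpc < 1) "risk_free"
  else if (s_mpc < 1 && s_nc < 800) "low"
  else if (s_mpc < 1) "moderate_1"
  else if (s_nc < 800) "moderate_2"
  else "high"
  out <- list(sum_nc = s_nc, sum_mpc = s_mpc, class = cls)
  class(out) <- "rq_cumulative"
  out
}

#' @export
print.rq_cumulative <- function(x, ...) {
  cat(sprintf("cumulative RQ: NC %.4g, MPC %.4g -> %s\n",
              x$sum_nc, x$sum_mpc, x$class))
  invisible(x)
}

#' Full risk-quotient assessment of a PAH profile
#'
#' Per-compound RQ against NC and MPC benchmarks with classification, plus
#' the cumulative quotients and combined class. `RQ_mpc = RQ_nc * NC / MPC`
#' holds exactly by construction.
#'
#' @param conc Named numeric vector of concentrations (ug/kg); `NA` = ND,
#'   excluded.
#' @param registry A [default_registry()] object supplying NC/MPC.
#' @return List of class `"rq_result"`: `table` (per-compound data.frame) and
#'   `cumulative` ([cumulative_rq()] output).
#' @export
#' @examples
#' r <- pah_rq(c(Ant = 141.02, Nap = 4.46))
#' r$table
pah_rq <- function(conc, registry = default_registry()) {
  conc <- conc[!is.na(conc)]
  pah <- registry$pah
  unknown <- setdiff(names(conc), rownames(pah))
  if (length(unknown)) {
    stop("no NC/MPC benchmarks for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nc <- pah[names(conc), "NC"]
  mpc <- pah[names(conc), "MPC"]
  rq_nc <- compute_rq(conc, nc)
  rq_mpc <- compute_rq(conc, mpc)
  tab <- data.frame(compound = names(conc), conc = unname(conc),
                    NC = nc, MPC = mpc,
                    RQ_nc = unname(rq_nc), RQ_mpc = unname(rq_mpc),
                    class = classify_individual_rq(rq_nc, rq_mpc),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, cumulative = cumulative_rq(rq_nc, rq_mpc))
  class(out) <- "rq_result"
  out
}

#' @export
print.rq_result <- function(x, ...) {
  cat("<rq_result>", nrow(x$table), "compounds\n")
  print(x$cumulative)
  invisible(x)
}
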