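# Hakanson potential ecological risk: single-element risk factor
# Er = Tr * C / Cn and their sum, the risk index RI, with the standard
# classification thresholds.

#' Single-element potential ecological risk factor
#'
#' `Er = Tr * C / Cn`: the element's toxic-response factor times the ratio of
#' its measured concentration to a reference (background/UCC) concentration.
#' Linear in `c`.
#'
#' @param c Concentration, mg/kg (non-negative; vectorised).
#' @param tr Toxic-response factor (> 0).
#' @param cn Reference concentration, mg/kg (> 0).
#' @return Er, dimensionless.
#' @export
#' @examples
#' compute_er(125.55, tr = 1, cn = 31)  # ~4.05
compute_er <- function(c, tr, cn) {
  if (any(cn <= 0)) stop("reference concentration cn must be > 0", call. = FALSE)
  if (any(tr <= 0)) stop("toxic-response factor tr must be > 0", call. = FALSE)
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  tr * c / cn
}

#' Aggregate risk index
#'
#' `RI = sum(Er)` over the assessed elements (exact sum, order-invariant).
#'
#' @param er_values Named numeric vector of per-element Er values.
#' @return RI, dimensionless.
#' @export
compute_ri <- function(er_values) {
  if (length(er_values) == 0) stop("at least one Er value required", call. = FALSE)
  sum(er_values)
}

#' Classify ecological risk
#'
#' Standard Hakanson grades. Intervals are lower-inclusive: a boundary value
#' is assigned to the higher class (Er = 40 is "moderate").
#' Er: <40 low, \[40,80) moderate, \[80,160) considerable, \[160,320) high,
#' >=320 very_high. RI: <150 low, \[150,300) moderate, \[300,600)
#' considerable, >=600 high.
#'
#' @param er,ri Non-negative values (vectorised).
#' @return Factor of grades.
#' @export
grade_er <- function(er) {
  if (any(er < 0, na.rm = TRUE)) stop("Er must be >= 0", call. = FALSE)
  cut(er, breaks = c(-Inf, 40, 80, 160, 320, Inf), right = FALSE,
      labels = c("low", "moderate", "considerable", "high", "very_high"))
}

#' @rdname grade_er
#' @export
grade_ri <- function(ri) {
  if (any(ri < 0, na.rm = TRUE)) stop("RI must be >= 0", call. = FALSE)
  cut(ri, breaks = c(-Inf, 150, 300, 600, Inf), right = FALSE,
      labels = c("low", "moderate", "considerable", "high"))
}

#' Ecological risk assessment of a soil survey
#'
#' Computes per-sample, per-element Er, the per-sample RI and categorical
#' grades for every element present in both the survey and the registry's
#' toxicity table.
#'
#' @param survey A [soil_survey()] data.frame.
#' @param registry A [default_registry()] object (or one with edited
#'   `toxicity` values).
#' @return List of class `"eco_risk"` with elements `er` (data.frame of
#'   per-sample Er), `er_grade`, `ri`, `ri_grade`.
#' @export
#' @examples
#' sv <- soil_survey("S1", data.frame(Zn = 125.55, Cd = 0.24), ph = 8.5, ec = 600)
#' eco_risk(sv)$ri
eco_risk <- function(survey, registry = default_registry()) {
  elems <- intersect(pte_elements(), names(survey))
  if (!length(elems)) stop("no PTE columns found in survey", call. = FALSE)
  er <- vapply(elems, function(el) {
    tox <- registry_lookup(registry, "toxicity", el)
    compute_er(survey[[el]], tox$Tr, tox$Cn)
  }, numeric(nrow(survey)))
  er <- as.data.frame(matrix(er, nrow = nrow(survey),
                             dimnames = list(NULL, elems)))
  ri <- rowSums(er)
  out <- list(sample_id = survey$sample_id,
              er = er,
              er_grade = as.data.frame(lapply(er, grade_er)),
              ri = ri,
              ri_grade = grade_ri(ri))
  class(out) <- "eco_risk"
  out
}

#' @export
print.eco_risk <- function(x, ...) {
  cat("<eco_risk>", length(x$sample_id), "samples,",
      ncol(x$er), "elements\n")
  cat("RI range:", sprintf("%.2f - %.2f", min(x$ri), max(x$ri)), "\n")
  cat("RI grades:", paste(names(table(x$ri_grade)),
                          table(x$ri_grade), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.eco_risk <- function(x, ...) {
  cbind(data.frame(sample_id = x$sample_id),
        x$er,
        data.frame(RI = x$ri, RI_grade = x$ri_grade))
}
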