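# Combined Isotopic Impact Index (CISI): min-max-scaled chemical indices,
# isotopic deviation indices against fixed reference ratios, and their
# weighted aggregation, with PCA-based validation and a weight sensitivity
# sweep.

#' CISI configuration
#'
#' @param chemical_params Ordered chemical parameter names (default pH, Fe,
#'   Mn, Pb, Ca).
#' @param r206_207_ref,r208_207_ref Reference isotopic ratios (defaults 1.2
#'   and 2.5).
#' @param w1,w2 Weights of the mean chemical and mean isotopic index; must be
#'   non-negative and sum to 1 (defaults 0.6/0.4).
#' @param clamp_ii Clamp isotopic indices into \[0, 1\]? Off by default: large
#'   deviations are reported as negative values rather than hidden.
#' @return List of class `"cisi_config"`.
#' @export
cisi_config <- function(chemical_params = c("pH", "Fe", "Mn", "Pb", "Ca"),
                        r206_207_ref = 1.2, r208_207_ref = 2.5,
                        w1 = 0.6, w2 = 0.4, clamp_ii = FALSE) {
  if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-12) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (r206_207_ref <= 0 || r208_207_ref <= 0) {
    stop("reference ratios must be > 0", call. = FALSE)
  }
  out <- list(chemical_params = chemical_params,
              r206_207_ref = r206_207_ref, r208_207_ref = r208_207_ref,
              w1 = w1, w2 = w2, clamp_ii = clamp_ii)
  class(out) <- "cisi_config"
  out
}

#' Chemical index: min-max scaling
#'
#' `CI = (x - xmin) / (xmax - xmin)`, so the minimum-valued sample scores 0
#' and the maximum-valued sample scores 1. Values outside \[xmin, xmax\] are
#' clamped with a warning. Shift-invariant: adding a constant to x, xmin and
#' xmax leaves CI unchanged.
#'
#' @param x Parameter value(s).
#' @param xmin,xmax Reference range (xmax > xmin), by default taken from the
#'   analysed batch.
#' @return CI in \[0, 1\].
#' @export
#' @examples
#' chemical_index(5, 0, 10)  # 0.5
chemical_index <- function(x, xmin, xmax) {
  if (xmax <= xmin) {
    stop("degenerate range: xmax must exceed xmin", call. = FALSE)
  }
  if (any(x < xmin | x > xmax, na.rm = TRUE)) {
    warning("value(s) outside [xmin, xmax]; clamped", call. = FALSE)
    x <- pmin(pmax(x, xmin), xmax)
  }
  (x - xmin) / (xmax - xmin)
}

#' Isotopic index: relative deviation from a reference ratio
#'
#' `II = 1 - |r - r_ref| / r_ref`. Equals 1 at zero deviation and decreases
#' linearly with relative deviation; it may go negative for deviations over
#' 100% and is not clamped by default.
#'
#' @param r Observed ratio(s).
#' @param r_ref Reference ratio (> 0).
#' @param clamp Clamp into \[0, 1\]?
#' @return II (<= 1).
#' @export
#' @examples
#' isotopic_index(0.6, 1.2)  # 0.5
isotopic_index <- function(r, r_ref, clamp = FALSE) {
  if (r_ref <= 0) stop("reference ratio must be > 0", call. = FALSE)
  ii <- 1 - abs(r - r_ref) / r_ref
  if (clamp) ii <- pmin(pmax(ii, 0), 1)
  ii
}

#' Combined isotopic impact index
#'
#' `CISI = w1 * mean(CI) + w2 * mean(II)`: the weighted average of the mean
#' chemical index and the mean isotopic index. With all components in
#' \[0, 1\] and weights summing to 1, CISI lies in \[0, 1\] and is monotone
#' in every component.
#'
#' @param ci_values Numeric vector of chemical indices (>= 1 value; passing a
#'   single pre-averaged mean CI is allowed).
#' @param ii_values Numeric vector of isotopic indices.
#' @param config A [cisi_config()] (supplies the weights).
#' @return List of class `"cisi_result"`: `ci_mean`, `ii_mean`, `cisi`.
#' @export
#' @examples
#' compute_cisi(0.0778, c(0.1675, 0.5316))$cisi  # 0.1865 to 4 dp
compute_cisi <- function(ci_values, ii_values, config = cisi_config()) {
  if (!length(ci_values)) stop("at least one CI value required", call. = FALSE)
  if (!length(ii_values)) stop("at least one II value required", call. = FALSE)
  ci_mean <- mean(ci_values)
  ii_mean <- mean(ii_values)
  out <- list(ci_mean = ci_mean, ii_mean = ii_mean,
              cisi = config$w1 * ci_mean + config$w2 * ii_mean)
  class(out) <- "cisi_result"
  out
}

#' @export
print.cisi_result <- function(x, ...) {
  cat(sprintf("CISI = %.4f (mean CI %.4f, mean II %.4f)\n",
              x$cisi, x$ci_mean, x$ii_mean))
  invisible(x)
}

#' CISI for a table of samples
#'
#' Min-max scales each configured chemical parameter over the batch (or a
#' supplied external reference range), computes the two isotopic indices
#' against the configured reference ratios, aggregates per sample and ranks
#' (rank 1 = highest CISI = most impacted).
#'
#' @param chem data.frame with `sample_id` and the configured chemical
#'   parameter columns.
#' @param isotopes data.frame with `sample_id`, `r206_207`, `r208_207`.
#' @param config A [cisi_config()].
#' @param ranges Optional external reference ranges: data.frame with
#'   `param`, `min`, `max`; defaults to the batch min/max.
#' @return data.frame of class `"cisi_table"`: per-sample CI columns, II
#'   columns, `CI_mean`, `II_mean`, `CISI`, `rank`.
#' @export
cisi_assess <- function(chem, isotopes, config = cisi_config(),
                        ranges = NULL) {
  params <- intersect(config$chemical_params, names(chem))
  if (!length(params)) stop("none of the configured chemical parameters ",
                            "found in chem", call. = FALSE)
  m <- merge(chem, isotopes[, c("sample_id", "r206_207", "r208_207")],
             by = "sample_id", sort = FALSE)
  if (!nrow(m)) stop("no samples shared between chem and isotopes",
                     call. = FALSE)
  ci <- sapply(params, function(p) {
    if (!is.null(ranges) && p %in% ranges$param) {
      i <- match(p, ranges$param)
      chemical_index(m[[p]], ranges$min[i], ranges$max[i])
    } else {
      chemical_index(m[[p]], min(m[[p]], na.rm = TRUE),
                     max(m[[p]], na.rm = TRUE))
    }
  })
  ci <- matrix(ci, nrow = nrow(m),
               dimnames = list(NULL, paste0("CI_", params)))
  ii <- cbind(
    II_206_207 = isotopic_index(m$r206_207, config$r206_207_ref,
                                clamp = config$clamp_ii),
    II_208_207 = isotopic_index(m$r208_207, config$r208_207_ref,
                                clamp = config$clamp_ii)
  )
  ci_mean <- rowMeans(ci)
  ii_mean <- rowMeans(ii)
  cisi <- config$w1 * ci_mean + config$w2 * ii_mean
  out <- data.frame(sample_id = m$sample_id, ci, ii,
                    CI_mean = ci_mean, II_mean = ii_mean, CISI = cisi,
                    rank = rank(-cisi, ties.method = "min"),
                    stringsAsFactors = FALSE)
  class(out) <- c("cisi_table", "data.frame")
  out
}

#' PCA validation of the CISI feature space
#'
#' Principal component analysis of the CI and II columns (z-scored), with a
#' deterministic sign convention: each loading vector's largest-magnitude
#' element is made positive. Explained-variance fractions sum to 1 over all
#' components; loadings are orthonormal. Zero-variance columns are dropped
#' with a warning (rank-deficiency reduces the component count).
#'
#' @param features Numeric matrix/data.frame of CI and II columns (rows =
#'   samples; >= 3 samples and >= 2 features required).
#' @return List of class `"cisi_pca"`: `explained` (variance fractions),
#'   `loadings`, `scores`, `dropped` (names of constant columns).
#' @export
validate_pca <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3) stop("PCA needs at least 3 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("PCA needs at least 2 non-constant features",
                        call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- list(explained = pc$sdev^2 / sum(pc$sdev^2),
              loadings = rot, scores = scores, dropped = dropped)
  class(out) <- "cisi_pca"
  out
}

#' @export
print.cisi_pca <- function(x, ...) {
  cat("<cisi_pca>", length(x$explained), "components\n")
  cat("explained variance:",
      paste(sprintf("PC%d=%.1f%%", seq_along(x$explained),
                    100 * x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Weight sensitivity sweep
#'
#' Recomputes CISI across a grid of (w1, w2 = 1 - w1) weight pairs and
#' reports the between-sample variance of CISI at each grid point; the
#' argmax is the variance-maximising weighting (the procedure used to select
#' default weights).
#'
#' @param ci_mean,ii_mean Per-sample mean chemical and isotopic indices
#'   (equal length).
#' @param w1_grid Grid of w1 values in \[0, 1\].
#' @return data.frame: w1, w2, variance of CISI, plus attribute `"best_w1"`.
#' @export
sensitivity_weights <- function(ci_mean, ii_mean,
                                w1_grid = seq(0, 1, by = 0.05)) {
  stopifnot(length(ci_mean) == length(ii_mean))
  rows <- lapply(w1_grid, function(w1) {
    cisi <- w1 * ci_mean + (1 - w1) * ii_mean
    data.frame(w1 = w1, w2 = 1 - w1,
               cisi_var = if (length(cisi) > 1) stats::var(cisi) else 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_w1") <- out$w1[which.max(out$cisi_var)]
  out
}
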