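# Domain records and survey file I/O. Records are plain data.frames with a
# class tag; missing values are explicit NAs (PTE/isotope) or an "ND"
# below-detection flag (PAH), never silent zeros.

.land_uses <- c("industrial", "residential", "traffic", "green_space", "unknown")

#' Construct soil-sample records
#'
#' One row per surveyed location: PTE concentrations (mg/kg), pH and
#' electrical conductivity (uS/cm), plus a land-use tag.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param pte Data frame or matrix of element concentrations (mg/kg), columns
#'   named by element code (subset of [pte_elements()]).
#' @param ph Numeric pH values (0-14).
#' @param ec Numeric electrical conductivity (uS/cm, non-negative).
#' @param land_use Land-use tag per sample.
#' @return data.frame of class `"soil_survey"`.
#' @export
soil_survey <- function(sample_id, pte, ph = NA_real_, ec = NA_real_,
                        land_use = "unknown") {
  pte <- as.data.frame(pte)
  bad <- setdiff(colnames(pte), pte_elements())
  if (length(bad)) {
    stop("unknown element column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  land_use <- match.arg(land_use, .land_uses, several.ok = TRUE)
  out <- data.frame(sample_id = as.character(sample_id),
                    land_use = rep_len(land_use, length(sample_id)),
                    pte,
                    pH = rep_len(as.numeric(ph), length(sample_id)),
                    EC = rep_len(as.numeric(ec), length(sample_id)),
                    stringsAsFactors = FALSE)
  validate_survey(out, "pte")
  class(out) <- c("soil_survey", "data.frame")
  out
}

#' Construct PAH profile records
#'
#' @param sample_id Character vector of sample identifiers.
#' @param pah Data frame of per-compound concentrations (ug/kg); `NA` marks a
#'   not-detected (ND) measurement, which is a distinct state from 0.
#' @return data.frame of class `"pah_survey"`.
#' @export
pah_survey <- function(sample_id, pah) {
  pah <- as.data.frame(pah)
  bad <- setdiff(colnames(pah), pah_compounds())
  if (length(bad)) {
    stop("unknown PAH compound column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(sample_id), pah,
                    stringsAsFactors = FALSE)
  validate_survey(out, "pah")
  class(out) <- c("pah_survey", "data.frame")
  out
}

.isotope_ratio_cols <- c("r206_204", "r207_204", "r208_204",
                         "r206_207", "r208_207", "r208_206")

#' Construct Pb isotope measurement records
#'
#' Ratio columns: `r206_204`, `r207_204`, `r208_204`, `r206_207`,
#' `r208_207`, `r208_206` (all dimensionless, positive; any subset may be
#' present) plus `pb_conc` (mg/kg). Internal consistency of redundant ratios
#' (e.g. 206/207 vs 206/204 / 207/204) is checked to 0.5% and a warning is
#' issued on mismatch.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param ratios Data frame of ratio columns.
#' @param pb_conc Pb concentration, mg/kg.
#' @return data.frame of class `"isotope_survey"`.
#' @export
isotope_survey <- function(sample_id, ratios, pb_conc) {
  ratios <- as.data.frame(ratios)
  bad <- setdiff(colnames(ratios), .isotope_ratio_cols)
  if (length(bad)) {
    stop("unknown isotope ratio column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(sample_id), ratios,
                    pb_conc = as.numeric(pb_conc), stringsAsFactors = FALSE)
  validate_survey(out, "isotope")
  class(out) <- c("isotope_survey", "data.frame")
  out
}

#' Validate survey records against their type invariants
#'
#' Checks non-negativity of concentrations, pH range, positivity of isotope
#' ratios and (for isotope records) internal ratio consistency. Errors name
#' the offending row and column.
#'
#' @param df Survey data.frame.
#' @param schema One of `"pte"`, `"pah"`, `"isotope"`.
#' @return `df`, invisibly, on success.
#' @export
validate_survey <- function(df, schema = c("pte", "pah", "isotope")) {
  schema <- match.arg(schema)
  if (!"sample_id" %in% names(df)) {
    stop("schema error: missing mandatory column 'sample_id'", call. = FALSE)
  }
  num_cols <- switch(schema,
    pte = intersect(names(df), c(pte_elements(), "EC")),
    pah = intersect(names(df), pah_compounds()),
    isotope = intersect(names(df), c(.isotope_ratio_cols, "pb_conc"))
  )
  for (col in num_cols) {
    v <- df[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad)) {
      stop("validation error: negative value in column '", col,
           "', row ", bad[1], call. = FALSE)
    }
    if (schema == "isotope") {
      zero <- which(!is.na(v) & v == 0 & col != "pb_conc")
      if (length(zero)) {
        stop("validation error: non-positive isotope ratio in column '",
             col, "', row ", zero[1], call. = FALSE)
      }
    }
  }
  if (schema == "pte" && "pH" %in% names(df)) {
    bad <- which(!is.na(df$pH) & (df$pH < 0 | df$pH > 14))
    if (length(bad)) {
      stop("validation error: pH outside [0, 14], row ", bad[1],
           call. = FALSE)
    }
  }
  if (schema == "isotope") {
    .check_ratio_consistency(df)
  }
  invisible(df)
}

# warn when redundant ratios disagree by more than rel_tol
.check_ratio_consistency <- function(df, rel_tol = 0.005) {
  checks <- list(
    c("r206_207", "r206_204", "r207_204"),
    c("r208_207", "r208_204", "r207_204"),
    c("r208_206", "r208_204", "r206_204")
  )
  for (ch in checks) {
    if (all(ch %in% names(df))) {
      direct <- df[[ch[1]]]
      derived <- df[[ch[2]]] / df[[ch[3]]]
      ok <- is.na(direct) | is.na(derived) |
        abs(direct - derived) <= rel_tol * abs(derived)
      if (any(!ok)) {
        warning("isotope ratio consistency: ", ch[1], " differs from ",
                ch[2], "/", ch[3], " by >", rel_tol * 100, "% in row(s) ",
                paste(which(!ok), collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' Read and write survey tables
#'
#' Delimited text (CSV by default) with a header row; `"ND"` cells in PAH
#' tables are read as below-detection flags (stored as `NA`). Records are
#' validated against the schema's invariants on read.
#'
#' @param path File path.
#' @param schema One of `"pte"`, `"pah"`, `"isotope"`.
#' @param sep Field separator.
#' @return For `read_survey`, a validated survey data.frame; for
#'   `write_survey`, the path, invisibly.
#' @export
read_survey <- function(path, schema = c("pte", "pah", "isotope"), sep = ",") {
  schema <- match.arg(schema)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "ND"))
  required <- switch(schema,
    pte = character(),
    pah = character(),
    isotope = "pb_conc"
  )
  miss <- setdiff(c("sample_id", required), names(df))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_survey(df, schema)
  cls <- switch(schema, pte = "soil_survey", pah = "pah_survey",
                isotope = "isotope_survey")
  class(df) <- c(cls, "data.frame")
  df
}

#' @rdname read_survey
#' @param df Survey data.frame.
#' @export
write_survey <- function(df, path, sep = ",") {
  out <- as.data.frame(df)
  # preserve full precision; ND stored as the literal flag
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- format(out[[col]], digits = 17, trim = TRUE, scientific = FALSE)
      v[is.na(out[[col]])] <- "ND"
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics of analyte concentrations
#'
#' Per-analyte n, min, max, mean, sd, coefficient of variation (sd/mean),
#' adjusted Fisher-Pearson sample skewness and excess kurtosis. A constant
#' vector yields sd = 0, cv = 0 and `NA` shape statistics with
#' `shape_defined = FALSE` (never NaN propagation).
#'
#' @param values Numeric vector (NAs dropped).
#' @return List of class `"descriptive_stats"`.
#' @export
#' @examples
#' s <- compute_descriptive_stats(c(74, 120, 270))
#' s$cv
compute_descriptive_stats <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 1) stop("need at least one non-missing value", call. = FALSE)
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else 0
  cv <- if (m > 0 && s > 0) s / m else 0
  shape_defined <- n >= 3 && s > 0
  skew <- kurt <- NA_real_
  if (shape_defined) {
    z <- (x - m) / s
    g1 <- mean(((x - m))^3) / (sqrt(mean((x - m)^2)))^3
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    if (n >= 4) {
      g2 <- mean((x - m)^4) / (mean((x - m)^2))^2 - 3
      kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  }
  out <- list(n = n, min = min(x), max = max(x), mean = m, sd = s, cv = cv,
              skewness = skew, kurtosis = kurt, shape_defined = shape_defined)
  class(out) <- "descriptive_stats"
  out
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("n=%d min=%.4g max=%.4g mean=%.4g sd=%.4g cv=%.4g\n",
              x$n, x$min, x$max, x$mean, x$sd, x$cv))
  if (x$shape_defined) {
    cat(sprintf("skewness=%.4g kurtosis=%.4g\n", x$skewness, x$kurtosis))
  } else {
    cat("shape statistics undefined (constant or too-short vector)\n")
  }
  invisible(x)
}

#' Descriptive statistics table for a survey
#'
#' @param df Survey data.frame.
#' @param columns Analyte columns to summarise; defaults to all numeric
#'   analyte columns present.
#' @return data.frame, one row per analyte.
#' @export
survey_stats <- function(df, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(names(df),
                         c(pte_elements(), "pH", "EC", pah_compounds()))
  }
  rows <- lapply(columns, function(col) {
    s <- compute_descriptive_stats(df[[col]])
    data.frame(analyte = col, n = s$n, min = s$min, max = s$max,
               mean = s$mean, sd = s$sd, cv = s$cv,
               skewness = s$skewness, kurtosis = s$kurtosis)
  })
  do.call(rbind, rows)
}
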