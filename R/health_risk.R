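# USEPA-style human health risk for PTEs: average daily dose per exposure
# pathway, hazard quotient/index, and carcinogenic risk, for adult and child
# receptors.

#' Average daily dose for one exposure pathway
#'
#' \describe{
#'   \item{ingestion}{`C * IngR * CF * EF * ED / (BW * AT)`}
#'   \item{inhalation}{`C * InhR * EF * ED / (PEF * BW * AT)` in the default
#'     dimensionally consistent mode. With `strict_paper = TRUE` the literal
#'     published form `C * IngR * CF * EF * ED / (PEF * BW * AT)` is used
#'     (it carries the ingestion rate and a unit conversion factor into the
#'     inhalation dose; kept only for exact reproduction).}
#'   \item{dermal}{`C * SA * CF * AF * ABS * EF * ED / (BW * AT)`}
#' }
#' `AT` is the non-carcinogenic averaging time (`AT_nc = 365 * ED` days) when
#' `carcinogenic = FALSE`, else `AT_ca` (25550 days).
#'
#' @param c Concentration, mg/kg (vectorised).
#' @param pathway One of `"ingestion"`, `"inhalation"`, `"dermal"`.
#' @param profile An exposure profile from [default_registry()], e.g.
#'   `registry_lookup(reg, "exposure_profiles", "pte_adult")`.
#' @param carcinogenic Use the carcinogenic averaging time?
#' @param strict_paper Reproduce the literal published inhalation formula?
#' @return ADD in mg/(kg day).
#' @export
#' @examples
#' reg <- default_registry()
#' p <- registry_lookup(reg, "exposure_profiles", "pte_adult")
#' compute_add(27.04, "ingestion", p)  # ~3.70e-5
compute_add <- function(c, pathway = c("ingestion", "inhalation", "dermal"),
                        profile, carcinogenic = FALSE, strict_paper = FALSE) {
  pathway <- match.arg(pathway)
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  at <- if (carcinogenic) profile$AT_ca else profile$AT_nc
  if (is.null(at) || at <= 0) stop("averaging time AT must be > 0", call. = FALSE)
  denom <- profile$BW * at
  switch(pathway,
    ingestion = c * profile$IngR * profile$CF * profile$EF * profile$ED / denom,
    inhalation = if (strict_paper) {
      c * profile$IngR * profile$CF * profile$EF * profile$ED /
        (profile$PEF * denom)
    } else {
      c * profile$InhR * profile$EF * profile$ED / (profile$PEF * denom)
    },
    dermal = c * profile$SA * profile$CF * profile$AF * profile$ABS *
      profile$EF * profile$ED / denom
  )
}

#' Hazard quotient and hazard index
#'
#' `HQ = ADD / RfD`; the hazard index `HI` is the exact sum of HQs. HI < 1
#' is interpreted as no expected adverse non-carcinogenic effect.
#'
#' @param add Average daily dose, mg/(kg day).
#' @param rfd Reference dose, mg/(kg day), > 0.
#' @param hqs Numeric vector of hazard quotients.
#' @return HQ or HI, dimensionless.
#' @export
compute_hq <- function(add, rfd) {
  if (any(rfd <= 0)) stop("reference dose rfd must be > 0", call. = FALSE)
  add / rfd
}

#' @rdname compute_hq
#' @export
compute_hi <- function(hqs) {
  sum(hqs)
}

#' Carcinogenic risk of a PTE
#'
#' `CR = (ADD_ingestion + ADD_inhalation + ADD_dermal) * SF`. All three
#' pathway doses are required. The result is banded: `< 1e-6` negligible,
#' `[1e-6, 1e-4]` acceptable_range, `> 1e-4` unacceptable.
#'
#' @param adds Named numeric vector/list with elements `ingestion`,
#'   `inhalation`, `dermal` (carcinogenic ADDs).
#' @param sf Slope factor, (mg/kg/day)^-1, > 0.
#' @return List with `cr` and `band`.
#' @export
compute_cr <- function(adds, sf) {
  need <- c("ingestion", "inhalation", "dermal")
  if (!all(need %in% names(adds))) {
    stop("all three pathway doses required: ",
         paste(setdiff(need, names(adds)), collapse = ", "), call. = FALSE)
  }
  if (any(sf <= 0)) stop("slope factor sf must be > 0", call. = FALSE)
  cr <- (adds[["ingestion"]] + adds[["inhalation"]] + adds[["dermal"]]) * sf
  band <- cut(cr, breaks = c(-Inf, 1e-6, 1e-4, Inf), right = TRUE,
              labels = c("negligible", "acceptable_range", "unacceptable"))
  # cr < 1e-6 negligible (strict), [1e-6, 1e-4] acceptable, > 1e-4 unacceptable
  band[cr == 1e-6] <- "acceptable_range"
  list(cr = cr, band = band)
}

#' Health risk assessment of a soil survey
#'
#' Per-element, per-receptor hazard quotients (three pathways), hazard index
#' and carcinogenic risk (for elements with a slope factor in the registry).
#'
#' @param survey A [soil_survey()] data.frame.
#' @param registry A [default_registry()] object.
#' @param receptors Character vector drawn from `c("child", "adult")`.
#' @param strict_paper Passed to [compute_add()].
#' @return List of class `"health_risk"`: one data.frame per receptor with
#'   columns element, HQ_ingestion, HQ_inhalation, HQ_dermal, HI, CR, CR_band
#'   (element means across samples), plus per-sample HI matrices.
#' @export
health_risk <- function(survey, registry = default_registry(),
                        receptors = c("child", "adult"),
                        strict_paper = FALSE) {
  receptors <- match.arg(receptors, several.ok = TRUE)
  elems <- intersect(pte_elements(), names(survey))
  if (!length(elems)) stop("no PTE columns found in survey", call. = FALSE)
  out <- list(sample_id = survey$sample_id)
  for (rec in receptors) {
    prof <- registry_lookup(registry, "exposure_profiles",
                            paste0("pte_", rec))
    rows <- lapply(elems, function(el) {
      tox <- registry_lookup(registry, "toxicity", el)
      cbar <- mean(survey[[el]], na.rm = TRUE)
      hq <- vapply(c("ingestion", "inhalation", "dermal"), function(p) {
        compute_hq(compute_add(cbar, p, prof, strict_paper = strict_paper),
                   tox$RfD)
      }, numeric(1))
      hi <- compute_hi(hq)
      if (!is.na(tox$SF)) {
        adds_ca <- vapply(c("ingestion", "inhalation", "dermal"), function(p) {
          compute_add(cbar, p, prof, carcinogenic = TRUE,
                      strict_paper = strict_paper)
        }, numeric(1))
        crr <- compute_cr(adds_ca, tox$SF)
        cr <- crr$cr; band <- as.character(crr$band)
      } else {
        cr <- NA_real_; band <- NA_character_
      }
      data.frame(element = el, HQ_ingestion = hq[["ingestion"]],
                 HQ_inhalation = hq[["inhalation"]],
                 HQ_dermal = hq[["dermal"]], HI = hi, CR = cr,
                 CR_band = band, stringsAsFactors = FALSE)
    })
    out[[rec]] <- do.call(rbind, rows)
  }
  class(out) <- "health_risk"
  out
}

#' @export
print.health_risk <- function(x, ...) {
  cat("<health_risk>", length(x$sample_id), "samples\n")
  for (rec in intersect(c("child", "adult"), names(x))) {
    tab <- x[[rec]]
    cat(sprintf("  %s: max HI %.3g (%s); max CR %.3g\n", rec,
                max(tab$HI), tab$element[which.max(tab$HI)],
                suppressWarnings(max(tab$CR, na.rm = TRUE))))
  }
  invisible(x)
}
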