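# End-to-end pipeline: run every analysis stage on a survey bundle and
# assemble per-stage reports plus a combined per-sample summary. Reports are
# deterministic given the inputs; writers serialise at full precision
# (display rounding is left to the caller).

#' Run the full risk-assessment pipeline
#'
#' Stages: descriptive statistics, ecological risk (Er/RI + grades), human
#' health risk for PTEs (both receptors), PAH toxicity equivalents + ILCR +
#' ERL/ERM screening + composition, PAH risk quotients, Pb source
#' apportionment, and the combined isotopic impact index. Any subset can be
#' selected; stages whose inputs are absent from the bundle raise an explicit
#' error.
#'
#' @param bundle A [generate_survey()] bundle, or any list with elements
#'   `pte`, `pah`, `isotopes`, `chem` (each stage uses only what it needs).
#' @param stages Character vector of stage names (default: all).
#' @param registry A [default_registry()].
#' @param config A [cisi_config()].
#' @param tef_set `"paper"` or `"nisbet_lagoy"` TEF column.
#' @return List of class `"risk_report"` with one element per stage plus
#'   `summary` (per-sample grades, source fractions, CISI rank).
#' @export
#' @examples
#' rep <- run_pipeline(generate_survey(generator_spec(n_samples = 8)))
#' names(rep)
run_pipeline <- function(bundle,
                         stages = c("stats", "eco_risk", "health_risk",
                                    "pah_tox", "pah_rq", "pb_sources",
                                    "cisi"),
                         registry = default_registry(),
                         config = cisi_config(),
                         tef_set = c("paper", "nisbet_lagoy")) {
  stages <- match.arg(stages, several.ok = TRUE)
  tef_set <- match.arg(tef_set)
  need <- function(what) {
    if (is.null(bundle[[what]])) {
      stop("stage dependency missing: bundle has no '", what, "' table",
           call. = FALSE)
    }
    bundle[[what]]
  }
  out <- list()

  if ("stats" %in% stages) {
    out$stats <- survey_stats(need("pte"))
  }
  if ("eco_risk" %in% stages) {
    out$eco_risk <- eco_risk(need("pte"), registry)
  }
  if ("health_risk" %in% stages) {
    out$health_risk <- health_risk(need("pte"), registry)
  }
  if ("pah_tox" %in% stages) {
    pah <- need("pah")
    cols <- intersect(pah_compounds(), names(pah))
    tefs <- stats::setNames(
      registry$pah[[if (tef_set == "paper") "tef_paper" else "tef_nisbet_lagoy"]],
      registry$pah$compound)
    mean_conc <- vapply(cols, function(cp) mean(pah[[cp]], na.rm = TRUE),
                        numeric(1))
    mean_conc[is.nan(mean_conc)] <- NA_real_  # all-ND columns
    teq <- compute_teq(mean_conc, tefs)
    out$pah_tox <- list(
      teq = teq,
      ilcr = list(child = compute_ilcr(teq$teq, "child", registry),
                  adult = compute_ilcr(teq$teq, "adult", registry)),
      screening = screen_erl_erm(mean_conc, registry),
      composition = composition_summary(mean_conc)
    )
  }
  if ("pah_rq" %in% stages) {
    pah <- need("pah")
    cols <- intersect(pah_compounds(), names(pah))
    mean_conc <- vapply(cols, function(cp) mean(pah[[cp]], na.rm = TRUE),
                        numeric(1))
    mean_conc[is.nan(mean_conc)] <- NA_real_
    out$pah_rq <- pah_rq(mean_conc, registry)
  }
  if ("pb_sources" %in% stages) {
    iso <- need("isotopes")
    frac <- apportion_survey(iso)
    out$pb_sources <- list(fractions = frac,
                           summary = summarize_contributions(frac))
  }
  if ("cisi" %in% stages) {
    out$cisi <- cisi_assess(need("chem"), need("isotopes"), config)
  }

  # combined per-sample summary across the sample-resolved stages
  ids <- NULL
  if (!is.null(out$eco_risk)) ids <- out$eco_risk$sample_id
  else if (!is.null(out$cisi)) ids <- out$cisi$sample_id
  if (!is.null(ids)) {
    summary <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    if (!is.null(out$eco_risk)) {
      summary$RI <- out$eco_risk$ri
      summary$RI_grade <- as.character(out$eco_risk$ri_grade)
    }
    if (!is.null(out$pb_sources)) {
      summary <- merge(summary, out$pb_sources$fractions[
        c("sample_id", "F1", "F2", "F3")], by = "sample_id",
        all.x = TRUE, sort = FALSE)
    }
    if (!is.null(out$cisi)) {
      summary <- merge(summary,
                       out$cisi[c("sample_id", "CISI", "rank")],
                       by = "sample_id", all.x = TRUE, sort = FALSE)
    }
    out$summary <- summary
  }
  class(out) <- "risk_report"
  out
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> stages:",
      paste(setdiff(names(x), "summary"), collapse = ", "), "\n")
  if (!is.null(x$summary)) {
    cat("samples:", nrow(x$summary), "\n")
  }
  invisible(x)
}

#' Write a risk report to disk
#'
#' One CSV per tabular stage plus a JSON bundle of the scalar results. All
#' numbers are serialised at full precision.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  put_csv <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$stats)) put_csv(report$stats, "stats")
  if (!is.null(report$eco_risk)) {
    put_csv(as.data.frame(report$eco_risk), "eco_risk")
  }
  if (!is.null(report$health_risk)) {
    hr <- report$health_risk
    for (rec in intersect(c("child", "adult"), names(hr))) {
      put_csv(hr[[rec]], paste0("health_risk_", rec))
    }
  }
  if (!is.null(report$pah_rq)) put_csv(report$pah_rq$table, "pah_rq")
  if (!is.null(report$pb_sources)) {
    put_csv(report$pb_sources$fractions, "pb_sources")
  }
  if (!is.null(report$cisi)) put_csv(as.data.frame(report$cisi), "cisi")
  if (!is.null(report$summary)) put_csv(report$summary, "summary")
  scalars <- list()
  if (!is.null(report$pah_tox)) {
    scalars$pah_tox <- list(
      teq = report$pah_tox$teq$teq,
      teq_ratio = report$pah_tox$teq$teq_ratio,
      ilcr_child_total = report$pah_tox$ilcr$child$total,
      ilcr_adult_total = report$pah_tox$ilcr$adult$total,
      composition = report$pah_tox$composition
    )
  }
  if (!is.null(report$pah_rq)) {
    scalars$pah_rq_cumulative <- report$pah_rq$cumulative[
      c("sum_nc", "sum_mpc", "class")]
  }
  if (length(scalars)) {
    p <- file.path(dir, "scalars.json")
    jsonlite::write_json(scalars, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
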