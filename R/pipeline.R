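# One-call analysis pipeline with ancestry stratification and report output.

.strip_class <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, .strip_class)
    attr(x, "class") <- NULL
  }
  x
}

.analyse_stratum <- function(studies, name, model, contrast, pooling, correction) {
  eff <- study_effects(studies, model, contrast, correction)
  tables <- lapply(seq_len(nrow(studies)), function(i)
    build_contingency(studies[i, ], model, contrast))
  k <- nrow(eff)
  pooled <- list()
  for (tag in pooling) {
    pooled[[tag]] <- if (tag == "fixed_mh") pool_fixed_mh(tables) else
      switch(tag,
             fixed_iv = pool_fixed_iv(eff),
             random_dl = if (k >= 2L) pool_random_dl(eff) else NULL)
  }
  het <- if (k >= 2L) heterogeneity(eff) else NULL
  egger <- if (k >= 3L) tryCatch(egger_test(eff), error = function(e) NULL) else NULL
  tf <- if (k >= 3L) tryCatch(trim_and_fill(eff), error = function(e) NULL) else NULL
  n <- sum(vapply(tables, function(t) t$a + t$b + t$c + t$d, numeric(1)))
  if (model == "allelic") n <- n / 2  # allele counts double the subjects
  list(stratum = name, k = k, n = n, effects = eff, pooled = pooled,
       heterogeneity = het, egger = egger, trim_fill = tf)
}

#' Run the full meta-analysis pipeline
#'
#' Performs the overall pooled analysis plus one stratified analysis per
#' subgroup level with at least `min_cohorts` cohorts (smaller strata
#' are skipped with a notice, as a single-cohort stratum cannot be
#' meta-analysed), along with heterogeneity, publication-bias
#' diagnostics, leave-one-out sensitivity and cumulative-by-year
#' analyses.
#'
#' @param studies A [study_set()]; defaults to the packaged fixture.
#' @inheritParams build_contingency
#' @param pooling Pooling models to run (default all three).
#' @param subgroup Stratification column (default `"ancestry"`); `NULL`
#'   disables stratification.
#' @param min_cohorts Minimum cohorts for a stratum to be analysed.
#' @inheritParams study_effect
#' @return A `meta_report` list: `effects`, `analyses` (named list,
#'   `"all"` first), `sensitivity`, `cumulative`, `skipped`, `config`.
#' @examples
#' report <- run_pipeline(load_fixture())
#' report$analyses$all$pooled$fixed_iv
#' @export
run_pipeline <- function(studies = load_fixture(),
                         model = "dominant", contrast = "persistence",
                         pooling = c("fixed_iv", "fixed_mh", "random_dl"),
                         subgroup = "ancestry", min_cohorts = 2L,
                         correction = "add_half_if_zero") {
  if (nrow(studies) == 0L) stop("empty study set", call. = FALSE)
  analyses <- list(all = .analyse_stratum(studies, "all", model, contrast,
                                          pooling, correction))
  skipped <- data.frame(stratum = character(0), k = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (!is.null(subgroup)) {
    for (level in unique(studies[[subgroup]])) {
      sel <- studies[studies[[subgroup]] == level, ]
      if (nrow(sel) < min_cohorts) {
        message("skipping stratum '", level, "': ", nrow(sel),
                " cohort(s) < minimum of ", min_cohorts)
        skipped <- rbind(skipped, data.frame(stratum = level, k = nrow(sel),
                                             reason = "below minimum cohort count",
                                             stringsAsFactors = FALSE))
        next
      }
      analyses[[level]] <- .analyse_stratum(sel, level, model, contrast,
                                            pooling, correction)
    }
  }
  sens <- if (nrow(studies) >= 3L)
    leave_one_out(studies, model, contrast, "fixed_iv", correction) else NULL
  cumul <- cumulative_by_year(studies, model, contrast, "fixed_iv", correction)
  structure(list(
    effects = analyses$all$effects,
    analyses = analyses,
    sensitivity = sens,
    cumulative = cumul,
    skipped = skipped,
    config = list(model = model, contrast = contrast, pooling = pooling,
                  subgroup = subgroup, min_cohorts = min_cohorts,
                  correction = correction,
                  provenance = attr(studies, "provenance"),
                  package_version = as.character(utils::packageVersion("genemeta")))),
    class = "meta_report")
}

#' Write a pipeline report to disk
#'
#' Serialises the full report as machine-readable JSON (full precision,
#' no timestamp, so repeated runs on the same input are byte-identical),
#' a rendered text summary, sensitivity/cumulative CSVs and, optionally,
#' forest and funnel plots (PDF) per analysed stratum.
#'
#' @param report A `meta_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param plots Whether to write forest/funnel PDFs.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, plots = TRUE) {
  stopifnot(inherits(report, "meta_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.strip_class(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- utils::capture.output({
    print(report)
    cat("\nGenerated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"), "\n")
  })
  writeLines(txt, file.path(dir, "report.txt"))
  if (!is.null(report$sensitivity)) {
    utils::write.csv(report$sensitivity, file.path(dir, "sensitivity.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$cumulative, file.path(dir, "cumulative.csv"),
                   row.names = FALSE)
  if (plots) {
    for (an in report$analyses) {
      primary <- an$pooled[[1L]]
      forest <- render_forest(primary, an$effects)
      ggplot2::ggsave(file.path(dir, paste0("forest_", an$stratum, ".pdf")),
                      forest$plot, width = 7, height = 1 + 0.4 * an$k)
      funnel <- render_funnel(funnel_data(an$effects, primary))
      ggplot2::ggsave(file.path(dir, paste0("funnel_", an$stratum, ".pdf")),
                      funnel$plot, width = 6, height = 5)
    }
  }
  invisible(dir)
}

#' @export
print.meta_report <- function(x, ...) {
  cfg <- x$config
  cat("Genotype-count meta-analysis (", cfg$model, " model, ", cfg$contrast,
      " contrast)\n", sep = "")
  if (!is.null(cfg$provenance) && nzchar(cfg$provenance)) {
    cat("Input: ", cfg$provenance, "\n", sep = "")
  }
  for (an in x$analyses) {
    cat("\n== Stratum: ", an$stratum, " (k = ", an$k, ", N = ", an$n, ") ==\n", sep = "")
    for (tag in names(an$pooled)) if (!is.null(an$pooled[[tag]])) print(an$pooled[[tag]])
    if (!is.null(an$heterogeneity)) print(an$heterogeneity)
    if (!is.null(an$egger)) print(an$egger)
    if (!is.null(an$trim_fill)) {
      cat(sprintf("Trim-and-fill: k0 = %d, adjusted OR = %.2f (95%% CI %.2f-%.2f)\n",
                  an$trim_fill$k0, an$trim_fill$adjusted$or,
                  an$trim_fill$adjusted$ci_low, an$trim_fill$adjusted$ci_high))
    }
  }
  if (nrow(x$skipped) > 0L) {
    cat("\nSkipped strata:", paste0(x$skipped$stratum, " (k=", x$skipped$k, ")",
                                    collapse = ", "), "\n")
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("\nLeave-one-out pooled OR range: %.3f-%.3f\n",
                min(x$sensitivity$or), max(x$sensitivity$or)))
  }
  cat(sprintf("Cumulative pooled OR by year: %s\n",
              paste(sprintf("%d: %.3f", x$cumulative$through_year,
                            x$cumulative$or), collapse = "; ")))
  invisible(x)
}
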