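# Study records: per-cohort genotype counts split by smoking status.

.COUNT_COLS <- c("cur_vv", "cur_vm", "cur_mm", "nev_vv", "nev_vm", "nev_mm")
.OPT_COLS <- c("ever_vv", "ever_vm", "ever_mm", "former_vv", "former_vm", "former_mm")
.ANCESTRIES <- c("Asian", "Caucasian", "African", "other")

#' Construct a study set
#'
#' A study set is a data frame with one row per cohort, holding genotype
#' counts (Val/Val, Val/Met, Met/Met) for each smoking-status arm plus
#' study metadata. Row (insertion) order is preserved by all operations.
#'
#' @param studies Data frame with columns `label`, `year`, `ancestry` and
#'   the six count columns `cur_vv`, `cur_vm`, `cur_mm`, `nev_vv`,
#'   `nev_vm`, `nev_mm` (optionally `ever_*` / `former_*`).
#' @param provenance Free-text note on where the counts come from.
#' @return An object of class `study_set` (a data frame).
#' @export
study_set <- function(studies, provenance = "") {
  required <- c("label", "year", "ancestry", .COUNT_COLS)
  missing_cols <- setdiff(required, names(studies))
  if (length(missing_cols) > 0L) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  studies$label <- as.character(studies$label)
  if (anyDuplicated(studies$label)) {
    stop("study labels must be unique; duplicated: ",
         paste(unique(studies$label[duplicated(studies$label)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("year", .COUNT_COLS, .OPT_COLS), names(studies))) {
    studies[[col]] <- .check_count_column(studies[[col]], col, studies$label)
  }
  bad <- !studies$ancestry %in% .ANCESTRIES
  if (any(bad)) {
    stop("unknown ancestry '", studies$ancestry[which(bad)[1L]],
         "' (expected one of: ", paste(.ANCESTRIES, collapse = ", "), ")",
         call. = FALSE)
  }
  structure(as.data.frame(studies), provenance = provenance,
            class = c("study_set", "data.frame"))
}

.check_count_column <- function(x, col, labels) {
  xi <- suppressWarnings(as.integer(x))
  if (anyNA(xi) || any(xi != as.numeric(x))) {
    row <- which(is.na(xi) | as.integer(x) != as.numeric(x))[1L]
    stop("non-integer value in field '", col, "' for study '", labels[row], "'",
         call. = FALSE)
  }
  if (col != "year" && any(xi < 0L)) {
    row <- which(xi < 0L)[1L]
    stop("negative count in field '", col, "' for study '", labels[row], "'",
         call. = FALSE)
  }
  xi
}

#' Read a study table from delimited text
#'
#' Expects a header row naming `label`, `year`, `ancestry` and the six
#' genotype-count columns of the persistence contrast (see [study_set()]).
#' Comma-delimited by default; tab accepted via `sep = "\t"` or a `.tsv`
#' file extension.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field delimiter; `NULL` (default) picks `"\t"` for `.tsv`
#'   files and `","` otherwise.
#' @return A [study_set()].
#' @export
read_studies <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  study_set(raw, provenance = paste0("read from ", path))
}

#' Write a study table to delimited text
#'
#' Inverse of [read_studies()]: the written file round-trips to an
#' identical set of counts and metadata.
#'
#' @param studies A [study_set()].
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path, sep = ",") {
  utils::write.table(as.data.frame(studies), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Packaged transcription of the eight BDNF Val66Met smoking-persistence
# cohorts (current-smoker arm vv/vm/mm, then never-smoker arm vv/vm/mm).
.FIXTURE <- data.frame(
  label    = c("Lang2007", "Wang2007", "Montag2008", "Landi2009",
               "Zhang2012", "Zhang2015", "JiangEA2017", "JiangAA2017"),
  year     = c(2007L, 2007L, 2008L, 2009L, 2012L, 2015L, 2017L, 2017L),
  ancestry = c("Caucasian", "Asian", "Caucasian", "Caucasian",
               "Asian", "Asian", "Caucasian", "African"),
  cur_vv   = c(67L, 30L, 90L, 879L, 81L, 215L, 623L, 1543L),
  cur_vm   = c(41L, 51L, 47L, 521L, 177L, 456L, 235L, 121L),
  cur_mm   = c(6L, 20L, 6L, 62L, 64L, 173L, 17L, 1L),
  nev_vv   = c(105L, 12L, 264L, 458L, 74L, 114L, 508L, 1636L),
  nev_vm   = c(30L, 20L, 136L, 277L, 156L, 253L, 210L, 100L),
  nev_mm   = c(4L, 16L, 11L, 41L, 76L, 107L, 23L, 3L),
  stringsAsFactors = FALSE
)

#' Load the packaged BDNF Val66Met smoking-persistence cohorts
#'
#' Returns the eight case-control cohorts (10,160 participants in total)
#' of the rs6265 smoking-persistence meta-analysis: genotype counts for
#' current smokers and never smokers per cohort, with publication year
#' and ancestry. The same table ships as a CSV under
#' `system.file("extdata", "bdnf_val66met_table1.csv", package = "genemeta")`.
#'
#' @return A [study_set()] of 8 studies.
#' @examples
#' studies <- load_fixture()
#' sum(studies[, c("cur_vv", "cur_vm", "cur_mm", "nev_vv", "nev_vm", "nev_mm")])
#' @export
load_fixture <- function() {
  study_set(.FIXTURE, provenance = "packaged BDNF Val66Met smoking-persistence cohorts")
}

#' Extract one smoking-status arm of a study record
#'
#' @param record A single-row [study_set()] (or list with the count fields).
#' @param arm One of `"current"`, `"never"`, `"ever"`, `"former"`.
#' @return Named integer vector `c(vv, vm, mm)`, or `NULL` when the arm's
#'   columns are absent from the record.
#' @export
genotype_arm <- function(record, arm = c("current", "never", "ever", "former")) {
  arm <- match.arg(arm)
  prefix <- c(current = "cur", never = "nev", ever = "ever", former = "former")[[arm]]
  cols <- paste0(prefix, c("_vv", "_vm", "_mm"))
  if (!all(cols %in% names(record))) return(NULL)
  counts <- vapply(cols, function(cl) as.numeric(record[[cl]][1L]), numeric(1))
  if (anyNA(counts)) return(NULL)
  stats::setNames(as.integer(counts), c("vv", "vm", "mm"))
}

#' Validate a study record
#'
#' Checks the record invariants and returns findings rather than raising:
#' negative counts, and (when `declared_n` is given) disagreement between
#' the persistence-arm totals and the declared sample size.
#'
#' @param record A single-row [study_set()] or list with the count fields.
#' @param declared_n Optional declared sample size to reconcile against
#'   `current + never` totals.
#' @return Character vector of findings; empty when all invariants hold.
#' @export
validate_study <- function(record, declared_n = NULL) {
  findings <- character(0)
  for (col in intersect(c(.COUNT_COLS, .OPT_COLS), names(record))) {
    v <- as.numeric(record[[col]][1L])
    if (!is.na(v) && v < 0) {
      findings <- c(findings, paste0("negative count in field '", col, "'"))
    }
  }
  if (!is.null(declared_n)) {
    cur <- genotype_arm(record, "current")
    nev <- genotype_arm(record, "never")
    if (is.null(cur) || is.null(nev)) {
      findings <- c(findings, "cannot reconcile declared_n: persistence arms absent")
    } else if (sum(cur) + sum(nev) != declared_n) {
      findings <- c(findings, paste0("arm totals sum to ", sum(cur) + sum(nev),
                                     " but declared sample size is ", declared_n))
    }
  }
  findings
}

#' @export
print.study_set <- function(x, ...) {
  cat("Study set of", nrow(x), "cohort(s)")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(" (", prov, ")", sep = "")
  cat("\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
`[.study_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("label", .COUNT_COLS) %in% names(out))) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("study_set", "data.frame")
  }
  out
}
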