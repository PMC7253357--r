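# Genetic-model contrasts: collapse genotype counts into 2x2 tables,
# dose-trend test for the additive model, Hardy-Weinberg testing.

.CONTRAST_ARMS <- list(
  persistence = c(case = "current", control = "never"),
  initiation  = c(case = "ever",    control = "never"),
  cessation   = c(case = "current", control = "former")
)

#' Build an exposure-by-outcome 2x2 table under a genetic model
#'
#' Exposure is always the Val-containing genotype category and the case
#' arm is always the first (e.g. smoking-persistent) arm of the contrast,
#' so an odds ratio above 1 means Val carriers are over-represented among
#' cases. The dominant model contrasts Val/* (Val/Val + Val/Met) against
#' Met/Met; recessive contrasts Val/Val against Met/*; allelic counts
#' alleles (two per subject). The additive model has no single 2x2
#' collapse and is handled by [cochran_armitage_trend()].
#'
#' @param record Single-row [study_set()].
#' @param model `"dominant"` (default), `"recessive"` or `"allelic"`.
#' @param contrast `"persistence"` (current vs never, default),
#'   `"initiation"` (ever vs never) or `"cessation"` (current vs former).
#' @return A `two_by_two` object with cells `a` (cases exposed), `b`
#'   (cases unexposed), `c` (controls exposed), `d` (controls unexposed)
#'   and a `corrected` flag (continuity correction applied downstream).
#' @examples
#' build_contingency(load_fixture()[1, ])  # (108, 6, 135, 4)
#' @export
build_contingency <- function(record,
                              model = c("dominant", "recessive", "allelic", "additive"),
                              contrast = c("persistence", "initiation", "cessation")) {
  model <- match.arg(model)
  contrast <- match.arg(contrast)
  if (model == "additive") {
    stop("the additive model has no single 2x2 collapse; ",
         "use cochran_armitage_trend() for the Val-dose trend test", call. = FALSE)
  }
  arms <- .contrast_arms(record, contrast)
  case <- arms$case
  ctrl <- arms$control
  cells <- switch(model,
    dominant  = c(a = case[["vv"]] + case[["vm"]], b = case[["mm"]],
                  c = ctrl[["vv"]] + ctrl[["vm"]], d = ctrl[["mm"]]),
    recessive = c(a = case[["vv"]], b = case[["vm"]] + case[["mm"]],
                  c = ctrl[["vv"]], d = ctrl[["vm"]] + ctrl[["mm"]]),
    allelic   = c(a = 2 * case[["vv"]] + case[["vm"]], b = 2 * case[["mm"]] + case[["vm"]],
                  c = 2 * ctrl[["vv"]] + ctrl[["vm"]], d = 2 * ctrl[["mm"]] + ctrl[["vm"]])
  )
  structure(list(a = unname(cells["a"]), b = unname(cells["b"]),
                 c = unname(cells["c"]), d = unname(cells["d"]),
                 corrected = FALSE, model = model, contrast = contrast,
                 label = as.character(record[["label"]][1L])),
            class = "two_by_two")
}

.contrast_arms <- function(record, contrast) {
  arm_names <- .CONTRAST_ARMS[[contrast]]
  case <- genotype_arm(record, arm_names[["case"]])
  ctrl <- genotype_arm(record, arm_names[["control"]])
  if (is.null(case) || is.null(ctrl)) {
    absent <- c(arm_names[["case"]], arm_names[["control"]])[c(is.null(case), is.null(ctrl))]
    stop("contrast '", contrast, "' unavailable: arm(s) ",
         paste(absent, collapse = ", "), " absent from study '",
         record[["label"]][1L], "'", call. = FALSE)
  }
  list(case = case, control = ctrl)
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"), c("exposed", "unexposed")))
  cat(x$label, " (", x$model, " model, ", x$contrast, ")",
      if (isTRUE(x$corrected)) " [0.5 correction]", "\n", sep = "")
  print(m)
  invisible(x)
}

#' Cochran-Armitage trend test for a Val-allele dose effect
#'
#' Realises the additive genetic model as a 0/1/2 Val-dose trend test on
#' the 2x3 case/control-by-genotype table (scores Met/Met = 0,
#' Val/Met = 1, Val/Val = 2).
#'
#' @param record Single-row [study_set()].
#' @param contrast Phenotype contrast; see [build_contingency()].
#' @return List with `statistic` (trend chi-square, 1 df) and `p`
#'   (two-sided).
#' @export
cochran_armitage_trend <- function(record,
                                   contrast = c("persistence", "initiation", "cessation")) {
  contrast <- match.arg(contrast)
  arms <- .contrast_arms(record, contrast)
  # order genotypes by Val dose: mm = 0, vm = 1, vv = 2
  cases <- as.numeric(arms$case[c("mm", "vm", "vv")])
  ctrls <- as.numeric(arms$control[c("mm", "vm", "vv")])
  if (sum(cases) == 0 || sum(ctrls) == 0) {
    stop("degenerate input: an arm has zero total", call. = FALSE)
  }
  s <- c(0, 1, 2)
  n <- cases + ctrls
  N <- sum(n)
  R <- sum(cases)
  num <- N * sum(s * cases) - R * sum(s * n)
  den <- R * (N - R) * (N * sum(s^2 * n) - sum(s * n)^2)
  if (den == 0) {  # all subjects in one genotype class
    return(list(statistic = 0, p = 1))
  }
  chi2 <- N * num^2 / den
  list(statistic = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hardy-Weinberg equilibrium chi-square test on one genotype arm
#'
#' Estimates the Val-allele frequency from the counts, forms expected
#' genotype counts under Hardy-Weinberg proportions (p^2, 2pq, q^2) and
#' compares with a 1-df chi-square goodness-of-fit statistic. Genotyping
#' problems in controls typically surface as deviation from these
#' proportions.
#'
#' @param arm Named counts `c(vv, vm, mm)` as returned by
#'   [genotype_arm()], or an unnamed length-3 vector in that order.
#' @return An `hwe_result`: `chi2`, `p` (upper tail, 1 df),
#'   `allele_freq` (Val), and `monomorphic` flag. A monomorphic arm
#'   returns `chi2 = 0`, `p = 1` with the flag set.
#' @examples
#' hwe_chi_square(c(vv = 25, vm = 50, mm = 25))  # exact HWE: chi2 = 0
#' @export
hwe_chi_square <- function(arm) {
  if (is.null(names(arm))) names(arm) <- c("vv", "vm", "mm")
  obs <- as.numeric(arm[c("vv", "vm", "mm")])
  n <- sum(obs)
  if (n <= 0) stop("degenerate input: arm total is zero", call. = FALSE)
  p <- (2 * obs[1L] + obs[2L]) / (2 * n)
  if (p == 0 || p == 1) {
    return(structure(list(chi2 = 0, p = 1, allele_freq = p, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  expd <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
  chi2 <- sum((obs - expd)^2 / expd)
  structure(list(chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 allele_freq = p, monomorphic = FALSE),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (1 df), p = %.4g, Val-allele freq = %.3f%s\n",
              x$chi2, x$p, x$allele_freq,
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

#' Val-carrier genotype frequency of a study
#'
#' Percentage of Val/* (Val/Val or Val/Met) carriers across both
#' persistence arms, reported to one decimal — the per-study carrier
#' frequency column of the fixture table.
#'
#' @param record Single-row [study_set()].
#' @return Percentage rounded to one decimal.
#' @export
val_star_frequency <- function(record) {
  cur <- genotype_arm(record, "current")
  nev <- genotype_arm(record, "never")
  if (is.null(cur) || is.null(nev)) {
    stop("persistence arms absent from study '", record[["label"]][1L], "'",
         call. = FALSE)
  }
  total <- sum(cur) + sum(nev)
  if (total == 0) stop("degenerate input: study total is zero", call. = FALSE)
  carriers <- cur[["vv"]] + cur[["vm"]] + nev[["vv"]] + nev[["vm"]]
  round(100 * carriers / total, 1)
}
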