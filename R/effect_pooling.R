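# Per-study odds ratios and fixed/random-effects pooling.
#
# Conventions: effects are pooled on the natural-log scale; 95% intervals
# use the exact normal quantile 1.959964; two-sided p values come from the
# standard normal (pooled) or chi-square (heterogeneity) tails.

.Z95 <- 1.959964

#' Per-study log odds ratio with Woolf variance
#'
#' Computes `log(ad/(bc))` with variance `1/a + 1/b + 1/c + 1/d` from a
#' 2x2 table. Zero cells are handled by the continuity-correction policy:
#' `"add_half_if_zero"` (default) adds 0.5 to all four cells of a table
#' containing any zero before both formulas; `"always_half"` adds 0.5
#' unconditionally; `"none"` refuses tables with zero cells.
#'
#' @param table A `two_by_two` from [build_contingency()].
#' @param correction Continuity-correction policy.
#' @return An `effect_estimate`: `study_label`, `log_or`, `var`, `se`,
#'   and `ci_low`/`ci_high` on the odds-ratio scale.
#' @examples
#' tab <- build_contingency(load_fixture()[2, ])  # (81, 20, 32, 16)
#' exp(study_effect(tab)$log_or)                  # 2.025
#' @export
study_effect <- function(table,
                         correction = c("add_half_if_zero", "none", "always_half")) {
  correction <- match.arg(correction)
  cells <- c(table$a, table$b, table$c, table$d)
  if (cells[1L] + cells[2L] == 0 || cells[3L] + cells[4L] == 0) {
    stop("degenerate table: an arm of '", table$label, "' has zero total",
         call. = FALSE)
  }
  corrected <- isTRUE(table$corrected)
  if (correction == "always_half" || (correction == "add_half_if_zero" && any(cells == 0))) {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  if (any(cells == 0)) {
    stop("zero cell in '", table$label,
         "' with correction policy 'none'", call. = FALSE)
  }
  log_or <- log(cells[1L] * cells[4L] / (cells[2L] * cells[3L]))
  v <- sum(1 / cells)
  se <- sqrt(v)
  structure(list(study_label = table$label, log_or = log_or, var = v, se = se,
                 ci_low = exp(log_or - .Z95 * se), ci_high = exp(log_or + .Z95 * se),
                 corrected = corrected),
            class = "effect_estimate")
}

#' Per-study effects for a whole study set
#'
#' Convenience wrapper: builds one 2x2 table per study under the chosen
#' genetic model and contrast, then one [study_effect()] per table.
#'
#' @inheritParams build_contingency
#' @param studies A [study_set()].
#' @inheritParams study_effect
#' @return Data frame with one row per study: `study_label`, `log_or`,
#'   `var`, `se`, `or`, `ci_low`, `ci_high`.
#' @export
study_effects <- function(studies, model = "dominant", contrast = "persistence",
                          correction = "add_half_if_zero") {
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    e <- study_effect(build_contingency(studies[i, ], model, contrast), correction)
    data.frame(study_label = e$study_label, log_or = e$log_or, var = e$var,
               se = e$se, or = exp(e$log_or), ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Normalise the accepted effect inputs (a study_effects() data frame, a
# single effect_estimate, or a list of them) to a data frame.
.as_effects <- function(effects) {
  if (inherits(effects, "effect_estimate")) effects <- list(effects)
  if (is.data.frame(effects)) {
    stopifnot(all(c("log_or", "var") %in% names(effects)))
    df <- effects
    if (is.null(df$study_label)) df$study_label <- paste0("study", seq_len(nrow(df)))
  } else {
    df <- do.call(rbind, lapply(effects, function(e) {
      data.frame(study_label = e$study_label, log_or = e$log_or, var = e$var,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(df) || nrow(df) == 0L) stop("empty effect list", call. = FALSE)
  if (any(df$var <= 0)) stop("all effect variances must be positive", call. = FALSE)
  df[c("study_label", "log_or", "var")]
}

.pooled_result <- function(model, k, mu, se, tau2 = 0) {
  z <- mu / se
  structure(list(model = model, k = k, pooled_log_or = mu, se = se,
                 or = exp(mu), ci_low = exp(mu - .Z95 * se),
                 ci_high = exp(mu + .Z95 * se), z = z,
                 p = 2 * stats::pnorm(-abs(z)), tau2 = tau2),
            class = "pooled_result")
}

#' Inverse-variance fixed-effects pooling
#'
#' Pools per-study log odds ratios with Woolf inverse-variance weights
#' `w = 1/var`: the fixed-effects model assumes one common true effect
#' and attributes all observed variation to sampling error.
#'
#' @param effects A [study_effects()] data frame (or list of
#'   [study_effect()] results).
#' @return A `pooled_result`: pooled log OR, SE, OR with 95% CI, Z,
#'   two-sided p, `tau2 = 0`, `k`.
#' @export
pool_fixed_iv <- function(effects) {
  df <- .as_effects(effects)
  w <- 1 / df$var
  mu <- sum(w * df$log_or) / sum(w)
  .pooled_result("fixed_iv", nrow(df), mu, sqrt(1 / sum(w)))
}

#' Mantel-Haenszel fixed-effects pooling of 2x2 tables
#'
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over the stratified
#' tables, with the Robins-Breslow-Greenland variance estimator for
#' `log(OR_MH)`. Unlike inverse-variance weighting, this works directly
#' on counts and remains stable with sparse cells.
#'
#' @param tables List of `two_by_two` tables (a single table is accepted).
#' @return A `pooled_result` with model tag `"fixed_mh"`.
#' @export
pool_fixed_mh <- function(tables) {
  if (inherits(tables, "two_by_two")) tables <- list(tables)
  if (length(tables) == 0L) stop("empty table list", call. = FALSE)
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  cc <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + cc + d
  if (any(n <= 0)) stop("a stratum has zero total", call. = FALSE)
  R <- a * d / n
  S <- b * cc / n
  if (sum(S) == 0) stop("undefined Mantel-Haenszel ratio: sum(b*c/n) is zero",
                        call. = FALSE)
  or_mh <- sum(R) / sum(S)
  P <- (a + d) / n
  Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
       sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
       sum(Q * S) / (2 * sum(S)^2)
  .pooled_result("fixed_mh", length(tables), log(or_mh), sqrt(v))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance by the DerSimonian-Laird moment
#' estimator `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' from the fixed-effects Q, then re-pools with weights
#' `1 / (var + tau2)`. When `Q <= k - 1` the estimate truncates to zero
#' and the result coincides with [pool_fixed_iv()] (apart from the model
#' tag).
#'
#' @inheritParams pool_fixed_iv
#' @return A `pooled_result` with model tag `"random_dl"` and the `tau2`
#'   estimate.
#' @export
pool_random_dl <- function(effects) {
  df <- .as_effects(effects)
  k <- nrow(df)
  if (k < 2L) stop("random-effects pooling needs at least 2 studies", call. = FALSE)
  w <- 1 / df$var
  mu_f <- sum(w * df$log_or) / sum(w)
  q <- sum(w * (df$log_or - mu_f)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (df$var + tau2)
  mu <- sum(ws * df$log_or) / sum(ws)
  .pooled_result("random_dl", k, mu, sqrt(1 / sum(ws)), tau2 = tau2)
}

#' Cochran's Q and I-squared heterogeneity
#'
#' `Q = sum(w_i (y_i - mu_fixed)^2)` with inverse-variance weights,
#' compared to a chi-square with `k - 1` df; `I2 = max(0, 100 (Q - df)/Q)`
#' expresses the share of observed variation attributable to between-study
#' heterogeneity rather than chance, in percent and truncated at zero.
#'
#' @inheritParams pool_fixed_iv
#' @return A `heterogeneity_result`: `q`, `df`, `p_q`, `i2`.
#' @export
heterogeneity <- function(effects) {
  df_e <- .as_effects(effects)
  k <- nrow(df_e)
  if (k < 2L) stop("heterogeneity needs at least 2 studies", call. = FALSE)
  w <- 1 / df_e$var
  mu <- sum(w * df_e$log_or) / sum(w)
  q <- sum(w * (df_e$log_or - mu)^2)
  dfree <- k - 1L
  i2 <- if (q > dfree) 100 * (q - dfree) / q else 0
  structure(list(q = q, df = dfree,
                 p_q = stats::pchisq(q, dfree, lower.tail = FALSE), i2 = i2),
            class = "heterogeneity_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s pooling of %d studies: OR = %.2f (95%% CI %.2f-%.2f), Z = %.3f, p = %.4g",
              x$model, x$k, x$or, x$ci_low, x$ci_high, x$z, x$p))
  if (x$model == "random_dl") cat(sprintf(", tau2 = %.4g", x$tau2))
  cat("\n")
  invisible(x)
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (%d df), P_Q = %.3g, I2 = %.1f%%\n",
              x$q, x$df, x$p_q, x$i2))
  invisible(x)
}
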