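# Publication-bias diagnostics: funnel coordinates, Egger regression,
# Duval-Tweedie trim-and-fill.

#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `t_i = log_or_i /
#' se_i` on precision `1/se_i` (the classical unweighted form). Absent
#' small-study effects the line passes through the origin; a non-zero
#' intercept signals asymmetry. The intercept is tested against a t
#' distribution with `k - 2` df.
#'
#' @inheritParams pool_fixed_iv
#' @return An `egger_result`: `intercept`, `se_intercept`, `t`, `df`,
#'   `p` (two-sided).
#' @export
egger_test <- function(effects) {
  df_e <- .as_effects(effects)
  k <- nrow(df_e)
  if (k < 3L) stop("Egger's test needs at least 3 studies", call. = FALSE)
  se <- sqrt(df_e$var)
  prec <- 1 / se
  if (length(unique(prec)) == 1L) {
    stop("singular design: all studies have equal precision", call. = FALSE)
  }
  fit <- stats::lm(I(df_e$log_or / se) ~ prec)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  intercept <- cf[1L, 1L]
  se_int <- cf[1L, 2L]
  t_stat <- cf[1L, 3L]
  p <- cf[1L, 4L]
  scale <- max(1, mean(abs(df_e$log_or / se)))
  if (!is.finite(p) || sm$sigma < 1e-10 * scale) {
    # exactly collinear input: zero residual variance, so the intercept is
    # known without error — any non-zero value is then definitive asymmetry
    near_zero <- abs(intercept) < 1e-8 * scale
    intercept <- if (near_zero) 0 else intercept
    se_int <- 0
    t_stat <- if (near_zero) 0 else Inf
    p <- if (near_zero) 1 else 0
  }
  structure(list(intercept = intercept, se_intercept = se_int,
                 t = t_stat, df = k - 2L, p = p),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger regression: intercept = %.3f (SE %.3f), t = %.3f (%d df), p = %.3g\n",
              x$intercept, x$se_intercept, x$t, x$df, x$p))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' One point per study (x = log OR, y = its SE) plus pseudo-95%
#' confidence guide lines fanning out from the fixed-effects pooled
#' centre over the observed SE range. Rendered funnels orient the SE
#' axis increasing downward.
#'
#' @inheritParams pool_fixed_iv
#' @param pooled A `pooled_result` giving the funnel centre; defaults to
#'   [pool_fixed_iv()] of `effects`.
#' @return A `funnel_data` list: `points` (study_label, x, y), `centre`
#'   (pooled log OR) and `guides` (se, lo, hi).
#' @export
funnel_data <- function(effects, pooled = pool_fixed_iv(effects)) {
  df_e <- .as_effects(effects)
  pts <- data.frame(study_label = df_e$study_label, x = df_e$log_or,
                    y = sqrt(df_e$var), stringsAsFactors = FALSE)
  se_grid <- seq(0, max(pts$y) * 1.05, length.out = 50L)
  guides <- data.frame(se = se_grid,
                       lo = pooled$pooled_log_or - .Z95 * se_grid,
                       hi = pooled$pooled_log_or + .Z95 * se_grid)
  structure(list(points = pts, centre = pooled$pooled_log_or, guides = guides),
            class = "funnel_data")
}

#' Duval-Tweedie trim-and-fill adjustment
#'
#' Rank-based estimate of the number `k0` of studies presumed suppressed
#' from one side of the funnel, with a bias-adjusted pooled estimate
#' after imputing their mirror images. Iteratively: pool the retained
#' studies (inverse-variance fixed effects), rank absolute deviations
#' from the pooled value, estimate `k0` by the `L0` (signed-rank sum) or
#' `R0` (rightmost-run) estimator, trim the `k0` most extreme studies on
#' the heavy side, and repeat until `k0` stabilises. The imputed studies
#' mirror the trimmed ones about the final trimmed pooled value, with
#' variances copied.
#'
#' @inheritParams pool_fixed_iv
#' @param estimator `"L0"` (default) or `"R0"`.
#' @param side Which side of the funnel is over-represented: `"auto"`
#'   (default; the sign of the Egger intercept), `"left"` or `"right"`.
#' @param maxiter Iteration cap before declaring non-convergence.
#' @return A `trim_fill_result`: `k0`, `side`, `iterations`, `filled`
#'   (imputed effects, zero rows when `k0 = 0`), `adjusted` (fixed-effects
#'   pooling of observed + imputed) and `adjusted_random` (the same under
#'   DerSimonian-Laird). With `k0 = 0` the adjusted results equal the
#'   unadjusted poolings exactly.
#' @export
trim_and_fill <- function(effects, estimator = c("L0", "R0"),
                          side = c("auto", "left", "right"), maxiter = 20L) {
  estimator <- match.arg(estimator)
  side <- match.arg(side)
  df_e <- .as_effects(effects)
  k <- nrow(df_e)
  if (k < 3L) stop("trim-and-fill needs at least 3 studies", call. = FALSE)
  if (side == "auto") {
    side <- if (egger_test(df_e)$intercept >= 0) "right" else "left"
  }
  flip <- side == "left"
  y <- if (flip) -df_e$log_or else df_e$log_or
  v <- df_e$var

  k0 <- 0L
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    if (iterations > maxiter) {
      stop("trim-and-fill failed to converge in ", maxiter, " iterations",
           call. = FALSE)
    }
    keep <- seq_len(k)
    if (k0 > 0L) keep <- keep[-order(y, decreasing = TRUE)[seq_len(k0)]]
    w <- 1 / v[keep]
    mu_t <- sum(w * y[keep]) / sum(w)
    dev <- y - mu_t
    r <- rank(abs(dev), ties.method = "first")
    est <- if (estimator == "L0") {
      t_n <- sum(r[dev > 0])
      (4 * t_n - k * (k + 1)) / (2 * k - 1)
    } else {
      # length of the run of top-ranked deviations that sit on the heavy side
      ord <- order(r, decreasing = TRUE)
      run <- 0L
      for (i in ord) {
        if (dev[i] > 0) run <- run + 1L else break
      }
      run - 1L
    }
    k0_new <- max(0L, min(k - 1L, as.integer(round(est))))
    if (k0_new == k0) break
    k0 <- k0_new
  }

  if (k0 == 0L) {
    filled <- df_e[0, ]
    adjusted <- pool_fixed_iv(df_e)
    adjusted_random <- if (k >= 2L) pool_random_dl(df_e) else NULL
  } else {
    trimmed_idx <- order(y, decreasing = TRUE)[seq_len(k0)]
    w <- 1 / v[-trimmed_idx]
    mu_t <- sum(w * y[-trimmed_idx]) / sum(w)
    fill_y <- 2 * mu_t - y[trimmed_idx]
    if (flip) fill_y <- -fill_y
    filled <- data.frame(
      study_label = paste0("filled_", df_e$study_label[trimmed_idx]),
      log_or = fill_y, var = v[trimmed_idx], stringsAsFactors = FALSE)
    augmented <- rbind(df_e[c("study_label", "log_or", "var")], filled)
    adjusted <- pool_fixed_iv(augmented)
    adjusted_random <- pool_random_dl(augmented)
  }
  structure(list(k0 = k0, side = side, iterations = iterations,
                 filled = filled, adjusted = adjusted,
                 adjusted_random = adjusted_random),
            class = "trim_fill_result")
}

#' @export
print.trim_fill_result <- function(x, ...) {
  cat(sprintf("Trim-and-fill: k0 = %d imputed on the %s-light side (%d iteration(s))\n",
              x$k0, setdiff(c("left", "right"), x$side), x$iterations))
  cat("Adjusted: ")
  print(x$adjusted)
  invisible(x)
}
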