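# Synthetic case-control genotype cohorts with known true parameters.
#
# Controls are drawn from Hardy-Weinberg proportions at a given
# Val-allele frequency; cases tilt the Val/* genotype odds by a
# dominant-model odds ratio, so the analysis under test recovers the
# simulated OR exactly in expectation.

#' Simulation configuration
#'
#' @param k Number of studies per simulated meta-analysis.
#' @param p_val Val-allele frequency in controls. The presets mirror the
#'   populations in the packaged fixture: `"asian_like"` sets 0.515 and
#'   `"caucasian_like"` 0.784.
#' @param true_or True dominant-model odds ratio (Val/* vs Met/Met).
#' @param n_cases,n_controls Per-study arm sizes.
#' @param tau Between-study SD of the log odds ratio (0 = homogeneous).
#' @param seed RNG seed; `NULL` leaves the RNG stream untouched.
#' @param preset `NULL`, `"asian_like"` or `"caucasian_like"`; a preset
#'   overrides `p_val` and tags the ancestry accordingly.
#' @param ancestry Ancestry label stamped on simulated studies.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k = 8L, p_val = 0.515, true_or = 1.25,
                       n_cases = 500L, n_controls = 500L, tau = 0,
                       seed = NULL, preset = NULL, ancestry = "Asian") {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("asian_like", "caucasian_like"))
    p_val <- c(asian_like = 0.515, caucasian_like = 0.784)[[preset]]
    ancestry <- c(asian_like = "Asian", caucasian_like = "Caucasian")[[preset]]
  }
  stopifnot(k >= 1, p_val > 0, p_val < 1, true_or > 0, tau >= 0,
            n_cases >= 1, n_controls >= 1)
  structure(list(k = as.integer(k), p_val = p_val, true_or = true_or,
                 n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 tau = tau, seed = seed, ancestry = ancestry),
            class = "sim_config")
}

# One study from the current RNG stream (no re-seeding).
.sim_one <- function(config, label, year) {
  p <- config$p_val
  hwe_probs <- c(vv = p^2, vm = 2 * p * (1 - p), mm = (1 - p)^2)
  log_or_i <- log(config$true_or) + stats::rnorm(1L, 0, config$tau)
  # case genotype odds relative to Met/Met are the control odds times the
  # study's dominant-model OR for both Val-carrying genotypes
  case_probs <- hwe_probs * c(exp(log_or_i), exp(log_or_i), 1)
  case_probs <- case_probs / sum(case_probs)
  nev <- stats::rmultinom(1L, config$n_controls, hwe_probs)[, 1L]
  cur <- stats::rmultinom(1L, config$n_cases, case_probs)[, 1L]
  data.frame(label = label, year = year, ancestry = config$ancestry,
             cur_vv = cur[1L], cur_vm = cur[2L], cur_mm = cur[3L],
             nev_vv = nev[1L], nev_vm = nev[2L], nev_mm = nev[3L],
             stringsAsFactors = FALSE)
}

#' Simulate a single case-control genotype study
#'
#' Control genotypes are multinomial draws from Hardy-Weinberg
#' proportions at `p_val`; a study-level log OR is drawn as
#' `log(true_or) + Normal(0, tau^2)` and applied to the Val/* genotype
#' odds before drawing case genotypes.
#'
#' @param config A [sim_config()]; its `seed` (when non-`NULL`) is set
#'   before drawing, so repeated calls reproduce the same study.
#' @param label,year Metadata stamped on the simulated record.
#' @return A single-row [study_set()].
#' @export
simulate_study <- function(config, label = "sim1", year = 2001L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  study_set(.sim_one(config, label, year), provenance = "simulated")
}

#' Simulate a meta-analysis of k studies
#'
#' Draws `config$k` independent studies from one seeded RNG stream
#' (studies in order, one `set.seed` at the start), stamping publication
#' years `2001, 2002, ...` so cumulative analyses are exercised.
#'
#' @param config A [sim_config()].
#' @return A [study_set()] of `config$k` simulated studies.
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- lapply(seq_len(config$k), function(i)
    .sim_one(config, sprintf("sim%02d", i), 2000L + i))
  study_set(do.call(rbind, rows),
            provenance = sprintf("simulated (k=%d, p_val=%.3f, true OR=%.3g, tau=%.3g)",
                                 config$k, config$p_val, config$true_or, config$tau))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a meta-analysis and re-estimates the pooled
#' dominant-model odds ratio under fixed and random effects, summarising
#' bias, empirical SE, 95% CI coverage of the true OR, rejection rate of
#' the nominal 5% test and the mean DerSimonian-Laird tau-squared.
#'
#' @param config A [sim_config()]; replicate `r` reuses the stream
#'   seeded from `config$seed + r`.
#' @param replicates Number of simulated meta-analyses.
#' @return A `recovery_experiment` list: `per_replicate` (one row per
#'   replicate and model) and `summary` (one row per model).
#' @export
recovery_experiment <- function(config, replicates = 200L) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  rows <- lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- (base_seed + r) %% .Machine$integer.max
    eff <- study_effects(simulate_meta(cfg))
    fx <- pool_fixed_iv(eff)
    rd <- pool_random_dl(eff)
    data.frame(replicate = r, model = c("fixed_iv", "random_dl"),
               or = c(fx$or, rd$or), log_or = c(fx$pooled_log_or, rd$pooled_log_or),
               ci_low = c(fx$ci_low, rd$ci_low), ci_high = c(fx$ci_high, rd$ci_high),
               p = c(fx$p, rd$p), tau2 = c(fx$tau2, rd$tau2),
               stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, rows)
  true_log <- log(config$true_or)
  summary_df <- do.call(rbind, lapply(split(per_rep, per_rep$model), function(d) {
    data.frame(model = d$model[1L],
               mean_or = mean(d$or),
               bias_log_or = mean(d$log_or) - true_log,
               empirical_se = if (nrow(d) > 1L) stats::sd(d$log_or) else 0,
               coverage = mean(d$ci_low <= config$true_or & config$true_or <= d$ci_high),
               reject_rate = mean(d$p < 0.05),
               mean_tau2 = mean(d$tau2),
               stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  structure(list(per_replicate = per_rep, summary = summary_df, config = config),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicate(s), true OR = %.3g, tau = %.3g\n",
              max(x$per_replicate$replicate), x$config$true_or, x$config$tau))
  print(x$summary, ...)
  invisible(x)
}
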