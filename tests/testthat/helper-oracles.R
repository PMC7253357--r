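# Independently coded brute-force oracles, kept deliberately naive and
# separate from the package's implementation paths.

oracle_iv_pool <- function(y, v) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] / v[i]
    den <- den + 1 / v[i]
  }
  mu <- num / den
  se <- sqrt(1 / den)
  list(mu = mu, se = se, or = exp(mu),
       ci = exp(mu + c(-1, 1) * 1.959964 * se),
       p = 2 * pnorm(-abs(mu / se)))
}

oracle_dl_pool <- function(y, v) {
  fx <- oracle_iv_pool(y, v)
  q <- 0
  sw <- 0; sw2 <- 0
  for (i in seq_along(y)) {
    w <- 1 / v[i]
    q <- q + w * (y[i] - fx$mu)^2
    sw <- sw + w
    sw2 <- sw2 + w^2
  }
  tau2 <- max(0, (q - (length(y) - 1)) / (sw - sw2 / sw))
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    w <- 1 / (v[i] + tau2)
    num <- num + w * y[i]
    den <- den + w
  }
  list(mu = num / den, se = sqrt(1 / den), tau2 = tau2, q = q)
}

oracle_mh_pool <- function(cells) {  # cells: matrix with columns a, b, c, d
  sr <- 0; ss <- 0
  for (i in seq_len(nrow(cells))) {
    n <- sum(cells[i, ])
    sr <- sr + cells[i, 1] * cells[i, 4] / n
    ss <- ss + cells[i, 2] * cells[i, 3] / n
  }
  sr / ss
}

# One pass of the trim-and-fill rank estimators about a given centre,
# straight from the signed-rank definitions (heavy side = right).
oracle_rank_estimators <- function(y, mu) {
  dev <- y - mu
  r <- rank(abs(dev), ties.method = "first")
  n <- length(y)
  tn <- sum(r[dev > 0])
  l0 <- (4 * tn - n * (n + 1)) / (2 * n - 1)
  gamma <- 0
  for (rk in seq(n, 1)) {
    i <- which(r == rk)
    if (dev[i] > 0) gamma <- gamma + 1 else break
  }
  list(l0 = l0, r0 = gamma - 1)
}

# Naive full re-implementation of the trim-and-fill iteration (heavy side
# = right), kept as a separate code path from the package's.
oracle_trimfill <- function(y, v, estimator = "L0", maxiter = 50) {
  k <- length(y)
  k0 <- 0
  for (iter in seq_len(maxiter)) {
    retained_y <- y
    retained_v <- v
    if (k0 > 0) {
      drop <- order(y, decreasing = TRUE)[seq_len(k0)]
      retained_y <- y[-drop]
      retained_v <- v[-drop]
    }
    mu <- oracle_iv_pool(retained_y, retained_v)$mu
    est <- oracle_rank_estimators(y, mu)
    k0_new <- max(0, min(k - 1, round(if (estimator == "L0") est$l0 else est$r0)))
    if (k0_new == k0) break
    k0 <- k0_new
  }
  drop <- if (k0 > 0) order(y, decreasing = TRUE)[seq_len(k0)] else integer(0)
  keep <- setdiff(seq_len(k), drop)
  mu_t <- oracle_iv_pool(y[keep], v[keep])$mu
  fill_y <- 2 * mu_t - y[drop]
  adj <- oracle_iv_pool(c(y, fill_y), c(v, v[drop]))
  list(k0 = k0, mu_adjusted = adj$mu, fill_y = fill_y)
}

# A small constructed study set used across tests: three identical cohorts.
identical_studies <- function(k = 3) {
  study_set(data.frame(
    label = paste0("dup", seq_len(k)), year = 2000L + seq_len(k),
    ancestry = "other",
    cur_vv = 40L, cur_vm = 40L, cur_mm = 20L,
    nev_vv = 30L, nev_vm = 40L, nev_mm = 30L))
}

# Effects data frame straight from log ORs and variances.
make_effects <- function(y, v, labels = paste0("s", seq_along(y))) {
  data.frame(study_label = labels, log_or = y, var = v,
             stringsAsFactors = FALSE)
}

# Strip provenance/class so study sets compare on content alone.
unprov <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  x
}
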