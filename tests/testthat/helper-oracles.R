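# Independent oracles used to freeze expected values. These deliberately
# use the slowest, most literal formulation of each quantity.

# Exhaustive threshold-enumeration oracle for PR metrics: for every distinct
# score s (as a threshold meaning "predict positive iff score >= s"),
# recompute precision/recall from scratch.
pr_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prec <- rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    tp <- sum(pred & labels == 1)
    prec[i] <- tp / sum(pred)
    rec[i] <- tp / n_pos
  }
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # right-continuous step integration of precision over recall
  au <- sum(prec * diff(c(0, rec)))
  list(thresholds = ths, precision = prec, recall = rec,
       auprc = au,
       p_at_r = function(target) max(prec[rec >= target]),
       best_f1 = max(f1))
}

# Brute-force nearest point-to-polyline distance: literal double loop over
# every segment of every polyline.
nearest_distance_oracle <- function(point, lines) {
  best <- Inf
  for (m in lines) {
    for (i in seq_len(nrow(m) - 1)) {
      a <- m[i, ]; b <- m[i + 1, ]
      v <- b - a
      L2 <- sum(v^2)
      t <- if (L2 == 0) 0 else max(0, min(1, sum((point - a) * v) / L2))
      p <- a + t * v
      best <- min(best, sqrt(sum((point - p)^2)))
    }
  }
  best
}

# Mean of a normal truncated to [0, Inf), by numerical integration.
truncnorm_mean_oracle <- function(mu, sigma) {
  Z <- stats::integrate(function(x) stats::dnorm(x, mu, sigma), 0, Inf)$value
  stats::integrate(function(x) x * stats::dnorm(x, mu, sigma), 0, Inf)$value / Z
}

# Direct (non-log) evaluation of the two-density Bayes posterior.
posterior_oracle <- function(xi, mu0, s0, mu1, s1, d) {
  p1 <- exp(-(d - mu1)^2 / (2 * s1^2)) / (sqrt(2 * pi) * s1)
  p0 <- exp(-(d - mu0)^2 / (2 * s0^2)) / (sqrt(2 * pi) * s0)
  p1 * xi / (p0 * (1 - xi) + p1 * xi)
}
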