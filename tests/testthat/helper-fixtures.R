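# Shared fixtures and independent oracles.

# The four in vivo settings and the phantom protocol.
setting_params <- function(which) {
  switch(which,
    I = sequence_params(tm = 29, trf = 40, nrf = 10, b1 = 50),
    II = sequence_params(tm = 145, trf = 40, nrf = 10, b1 = 50),
    III = sequence_params(tm = 189, trf = 40, nrf = 10, b1 = 50),
    IV = sequence_params(tm = 145, trf = 40, nrf = 1, b1 = 100),
    phantom = sequence_params(tm = 145, trf = 200, nrf = 5, b1 = 50),
    stop("unknown setting"))
}

setting_schedule <- function(which) cycle_schedule(setting_params(which))

# Wrap a list of events for a scene without going through sample_events().
manual_events <- function(events, scene, repetitions) {
  structure(list(events = events, n_repetitions = as.integer(repetitions),
                 dim = scene$dim),
            class = "displacement_events")
}

# A compact elliptical footprint inside a muscle, uniform amplitude.
muscle_footprint <- function(scene, muscle, n_vox = 12, amplitude_um = 150) {
  vox <- which(scene$label_map == scene$label_names[[muscle]],
               arr.ind = TRUE)
  data.frame(row = vox[seq_len(n_vox), 1], col = vox[seq_len(n_vox), 2],
             amplitude_um = amplitude_um)
}

# Exhaustive sign-enumeration oracle for the paired Wilcoxon signed-rank
# two-sided p-value (no zeros, no ties), matching the 2*min(tail) convention.
oracle_signrank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Hand-ranked Friedman chi-square for an n x k table (no ties).
oracle_friedman_chi2 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  colsum <- colSums(r)
  12 / (n * k * (k + 1)) * sum(colsum^2) - 3 * n * (k + 1)
}

# Brute-force order-statistic median CI: widest symmetric order-statistic
# pair whose exact binomial coverage reaches the level.
oracle_median_ci <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  best <- NULL
  for (l in seq_len(floor(n / 2))) {
    cov <- 1 - 2 * pbinom(l - 1, n, 0.5)
    if (cov >= level) best <- list(lower = x[l], upper = x[n + 1 - l])
  }
  best
}
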