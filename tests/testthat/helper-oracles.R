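# Independent oracles and small fixture builders used across the suite.

# linear-ramp concentration series C(t) = k * t on the full sampling
ramp_series <- function(k, acq = acquisition_params(), id = "ramp") {
  tt <- post_times(acq)
  concentration_series(tt, k * tt, lesion_id = id)
}

# brute-force AUC: pair-counting probability, ties counted half
auc_pair_count <- function(scores, labels) {
  x <- scores[labels == "malignant"]
  y <- scores[labels == "benign"]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# exhaustive Youden scan over midpoints between consecutive unique scores
youden_exhaustive <- function(scores, labels) {
  pos <- labels == "malignant"
  u <- sort(unique(scores))
  if (length(u) == 1L) return(list(j = 0, cutoff = u))
  cand <- (head(u, -1) + tail(u, -1)) / 2
  j <- sapply(cand, function(cut)
    sum(scores >= cut & pos) / sum(pos) +
      sum(scores < cut & !pos) / sum(!pos) - 1)
  list(j = max(j), cutoff = cand[which.max(j)])
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
mw_exact_enumeration <- function(benign, malignant) {
  vals <- c(benign, malignant)
  n <- length(vals); m <- length(malignant)
  rk <- rank(vals)
  obs_w <- sum(rk[(length(benign) + 1):n]) - m * (m + 1) / 2
  combs <- combn(n, m)
  ws <- apply(combs, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  mu <- length(benign) * m / 2
  mean(abs(ws - mu) >= abs(obs_w - mu) - 1e-12)
}

# direct fine-grid convolution oracle for the extended Tofts model
tofts_oracle <- function(spec, t, grid_dt = 0.01, dose = 0.1) {
  g <- seq(0, max(t) + 1, by = grid_dt)
  cp <- population_aif(g, dose = dose)
  kep <- spec$ktrans / spec$ve / 60
  kt <- spec$ktrans / 60
  sapply(t, function(t0) {
    td <- t0 - spec$onset_delay
    if (td <= 0) return(0)
    idx <- g <= td
    tau <- g[idx]
    integrand <- cp[idx] * exp(-kep * (td - tau))
    vp_term <- spec$vp * approx(g, cp, td)$y
    vp_term + kt * sum((head(integrand, -1) + tail(integrand, -1)) / 2 *
                         diff(tau))
  })
}

# draw one Rician sample of each element of s
rician_draw <- function(s, sigma) {
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}
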