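#' Spoiled-gradient-echo signal equation
#'
#' `S = m0 sin(a) (1 - E) / (1 - E cos(a))` with `E = exp(-tr/t1)`. This is
#' the forward model behind both the dynamic series and the two-flip-angle
#' T1 map; all conversions in the package invert it.
#'
#' @param m0 Equilibrium signal scale (arbitrary units), > 0.
#' @param t1 Longitudinal relaxation time (ms), > 0. Vectorised.
#' @param tr Repetition time (ms), > 0.
#' @param alpha Flip angle (degrees), in (0, 90].
#' @return Signal in the units of `m0`.
#' @examples
#' spgr_signal(1000, 1000, 5.03, 10)
#' @export
spgr_signal <- function(m0, t1, tr, alpha) {
  if (any(t1 <= 0)) stop("t1 must be positive", call. = FALSE)
  if (any(tr <= 0)) stop("tr must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha > 90))
    stop("alpha must lie in (0, 90] degrees", call. = FALSE)
  a <- alpha * pi / 180
  E <- exp(-tr / t1)
  m0 * sin(a) * (1 - E) / (1 - E * cos(a))
}

#' Two-point variable-flip-angle T1 estimation
#'
#' Linearises the spoiled-gradient-echo equation: plotting `y = S/sin(a)`
#' against `x = S/tan(a)` puts both measurements on a line of slope
#' `E = exp(-tr/t1)`, so `t1 = -tr / log(E)` and `m0` follows from either
#' point. Exact on noiseless inputs; a slope outside (0, 1) means the signal
#' pair is inconsistent with the model (e.g. pure noise) and is rejected.
#'
#' @param s1,s2 Signals measured at `alpha1` and `alpha2`. Vectorised
#'   (voxelwise maps).
#' @param alpha1,alpha2 The two distinct flip angles (degrees).
#' @param tr Repetition time (ms).
#' @return A list with `t10` (ms) and `m0`; entries are `NA` (with a
#'   warning) where the slope is non-physical, or an error for scalar input.
#' @examples
#' s <- spgr_signal(500, 820, 5.03, c(2, 10))
#' fit_t1_vfa(s[1], s[2], 2, 10, 5.03)
#' @export
fit_t1_vfa <- function(s1, s2, alpha1, alpha2, tr) {
  if (any(s1 <= 0) || any(s2 <= 0))
    stop("signals must be positive", call. = FALSE)
  if (alpha1 == alpha2) stop("flip angles must be distinct", call. = FALSE)
  a1 <- alpha1 * pi / 180; a2 <- alpha2 * pi / 180
  y1 <- s1 / sin(a1); y2 <- s2 / sin(a2)
  x1 <- s1 / tan(a1); x2 <- s2 / tan(a2)
  E <- (y1 - y2) / (x1 - x2)
  bad <- !is.finite(E) | E <= 0 | E >= 1
  if (all(bad))
    stop("non-physical slope: signals inconsistent with the SPGR model",
         call. = FALSE)
  if (any(bad))
    warning(sprintf("%d voxel(s) with non-physical VFA slope set to NA",
                    sum(bad)))
  E[bad] <- NA_real_
  t10 <- -tr / log(E)
  m0 <- s1 * (1 - E * cos(a1)) / (sin(a1) * (1 - E))
  list(t10 = t10, m0 = m0)
}

#' Concentration series container
#'
#' A per-lesion concentration curve: sample times (s after injection start)
#' and concentrations (mmol/L), used by the kinetic-parameter operations.
#'
#' @param times Sample times (s), strictly increasing, positive.
#' @param values Concentrations (mmol/L); `NA` marks non-physical samples.
#' @param lesion_id Optional lesion identifier.
#' @param n_clipped Number of samples clipped up to zero (noise bookkeeping).
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(times, values, lesion_id = NA_character_,
                                 n_clipped = 0L) {
  stopifnot(length(times) == length(values), all(times > 0),
            !is.unsorted(times, strictly = TRUE))
  if (any(values < 0, na.rm = TRUE))
    stop("concentrations must be non-negative (clip before constructing)",
         call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 lesion_id = lesion_id, n_clipped = as.integer(n_clipped)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series%s: %d samples, %g-%g s, peak %.4g mmol/L\n",
              if (is.na(x$lesion_id)) "" else paste0(" [", x$lesion_id, "]"),
              length(x$times), min(x$times), max(x$times),
              max(x$values, na.rm = TRUE)))
  if (x$n_clipped > 0)
    cat(sprintf("  %d negative sample(s) clipped to 0\n", x$n_clipped))
  invisible(x)
}

#' Convert a dynamic signal curve to contrast-agent concentration
#'
#' Estimates `m0` from the mean pre-contrast signal and the baseline T1 at
#' the dynamic TR/flip angle, inverts the spoiled-gradient-echo equation per
#' timepoint for `T1(t)`, and maps relaxation-rate change to concentration:
#' `C(t) = (1/r1) (1/T1(t) - 1/T10)` with rates in s^-1. Samples whose
#' signal implies `E` outside (0, 1) are flagged non-physical and returned
#' as `NA`; negative concentrations from noise are clipped to 0 and counted.
#'
#' @param signal_curve Dynamic post-contrast signal values (a.u.).
#' @param s_pre Mean pre-contrast signal (a.u.), > 0.
#' @param t10 Baseline T1 (ms), > 0.
#' @param acq An [acquisition_params()] (dynamic TR/flip, relaxivity, times).
#' @param lesion_id Optional id carried into the result.
#' @return A [concentration_series()] sampled at `post_times(acq)`.
#' @export
signal_to_concentration <- function(signal_curve, s_pre, t10, acq,
                                    lesion_id = NA_character_) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (!(s_pre > 0)) stop("s_pre must be positive", call. = FALSE)
  if (!(t10 > 0)) stop("t10 must be positive", call. = FALSE)
  if (length(signal_curve) != acq$n_post)
    stop("signal_curve must have one sample per post-contrast phase",
         call. = FALSE)
  a <- acq$flip_dce * pi / 180
  E10 <- exp(-acq$tr_dce / t10)
  m0 <- s_pre * (1 - E10 * cos(a)) / (sin(a) * (1 - E10))
  sa <- m0 * sin(a)
  E <- (sa - signal_curve) / (sa - signal_curve * cos(a))
  bad <- !is.finite(E) | E <= 0 | E >= 1
  t1t <- rep(NA_real_, length(E))
  t1t[!bad] <- -acq$tr_dce / log(E[!bad])
  conc <- (1000 / t1t - 1000 / t10) / acq$r1     # rates in s^-1, T1 in ms
  n_clip <- sum(conc < 0, na.rm = TRUE)
  conc <- pmax(conc, 0)
  concentration_series(post_times(acq), conc, lesion_id = lesion_id,
                       n_clipped = n_clip)
}

#' Measure lesion concentration curves from rendered volumes
#'
#' The volume-level analysis path: averages the dynamic signal over each
#' lesion's voxel mask (a VOI-mean signal curve), fits the baseline T1 from
#' the VOI-mean two-flip-angle pair via [fit_t1_vfa()], and converts the
#' curve with [signal_to_concentration()].
#'
#' @param study A `synthetic_study` with rendered `volumes`
#'   (see [render_signal()]).
#' @return A list of [concentration_series()], one per lesion, in lesion
#'   table order.
#' @export
measure_study <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(study$volumes))
    stop("study has no rendered volumes; call render_signal() first",
         call. = FALSE)
  acq <- study$acquisition
  v <- study$volumes
  n_ph <- acq$n_pre + acq$n_post
  lapply(seq_len(nrow(study$lesions)), function(i) {
    sel <- v$mask == i
    sig <- vapply(seq_len(n_ph), function(p) {
      ph <- v$dynamic[, , , p]
      mean(ph[sel])
    }, numeric(1))
    s_pre <- mean(sig[seq_len(acq$n_pre)])
    t1fit <- fit_t1_vfa(mean(v$t1map$low[sel]), mean(v$t1map$high[sel]),
                        acq$flips_t1map[1], acq$flips_t1map[2], acq$tr_t1map)
    signal_to_concentration(sig[-seq_len(acq$n_pre)], s_pre, t1fit$t10, acq,
                            lesion_id = study$lesions$id[i])
  })
}
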