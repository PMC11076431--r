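#' Build the truncated dynamic sets
#'
#' A dynamic set is the series truncated to a given total phase count
#' (pre-contrast included); its scan duration is `phase_count * dt`. The
#' default phase counts 9, 12, ..., 30 at 4.5 s/phase give the eight scan
#' durations 40.5, 54, 67.5, 81, 94.5, 108, 121.5 and 135 s.
#'
#' @param acq An [acquisition_params()] object.
#' @param phase_counts Ascending total phase counts, each between
#'   `n_pre + 1` and `n_pre + n_post`.
#' @return A data frame of class `dynamic_sets` with columns `phase_count`,
#'   `duration` (s) and `label` (e.g. `"SD_67.5s"`).
#' @examples
#' build_dynamic_sets(acquisition_params())
#' @export
build_dynamic_sets <- function(acq = acquisition_params(),
                               phase_counts = c(9L, 12L, 15L, 18L, 21L,
                                                24L, 27L, 30L)) {
  stopifnot(inherits(acq, "acquisition_params"))
  phase_counts <- as.integer(phase_counts)
  if (is.unsorted(phase_counts, strictly = TRUE))
    stop("phase_counts must be strictly ascending", call. = FALSE)
  if (any(phase_counts < acq$n_pre + 1L))
    stop("each phase count must include at least one post-contrast phase",
         call. = FALSE)
  if (any(phase_counts > acq$n_pre + acq$n_post))
    stop("phase count exceeds available phases", call. = FALSE)
  duration <- phase_counts * acq$dt
  out <- data.frame(phase_count = phase_counts, duration = duration,
                    label = sprintf("SD_%gs", duration),
                    stringsAsFactors = FALSE)
  class(out) <- c("dynamic_sets", "data.frame")
  out
}

#' Truncate a concentration curve to a dynamic set
#'
#' Keeps the first `phase_count - n_pre` post-contrast samples; timestamps
#' are unchanged, so the last retained sample of the 9-phase set at
#' 4.5 s/phase falls at 36 s after injection start.
#'
#' @param curve A [concentration_series()] with the full post-contrast
#'   sampling.
#' @param set One row of [build_dynamic_sets()] output (or a list with
#'   `phase_count`).
#' @param acq The [acquisition_params()] object.
#' @return The truncated [concentration_series()].
#' @export
truncate_curve <- function(curve, set, acq) {
  stopifnot(inherits(curve, "concentration_series"),
            inherits(acq, "acquisition_params"))
  if (length(curve$times) != acq$n_post)
    stop("curve must carry the full post-contrast sampling", call. = FALSE)
  keep <- seq_len(set$phase_count - acq$n_pre)
  concentration_series(curve$times[keep], curve$values[keep],
                       lesion_id = curve$lesion_id,
                       n_clipped = curve$n_clipped)
}

# finite (time, value) pairs with the (0, 0) injection-time anchor prepended
anchored <- function(curve) {
  ok <- is.finite(curve$values)
  list(t = c(0, curve$times[ok]), c = c(0, curve$values[ok]))
}

#' Maximum slope of a concentration curve
#'
#' The steepest segment slope: the maximum over consecutive sample pairs of
#' `(C[i+1] - C[i]) / (t[i+1] - t[i])`, including the segment from the
#' injection-time baseline (t = 0, C = 0) to the first post-contrast sample.
#' A negative maximum (possible only on degenerate input) is floored at 0;
#' ties are broken towards the earliest segment. Non-finite samples are
#' dropped before slopes are formed. An optional 3-point moving average can
#' be applied first.
#'
#' @param curve A [concentration_series()] (typically truncated).
#' @param smooth Apply a 3-point moving average before taking slopes.
#' @return Maximum slope (mmol L^-1 s^-1), >= 0.
#' @examples
#' ramp <- concentration_series(seq(4.5, 36, by = 4.5),
#'                              0.01 * seq(4.5, 36, by = 4.5))
#' max_slope(ramp)  # 0.01 exactly
#' @export
max_slope <- function(curve, smooth = FALSE) {
  stopifnot(inherits(curve, "concentration_series"))
  a <- anchored(curve)
  if (length(a$t) < 2L)
    stop("fewer than 2 usable points: maximum slope undefined",
         call. = FALSE)
  cc <- a$c
  if (smooth && length(cc) >= 3L) {
    sm <- stats::filter(cc, rep(1 / 3, 3), sides = 2)
    cc[!is.na(sm)] <- sm[!is.na(sm)]
  }
  max(0, max(diff(cc) / diff(a$t)))
}

#' Initial area under the concentration curve
#'
#' Trapezoidal integral of the concentration from injection (t = 0, C = 0)
#' to `min(window, last timestamp)`. When the window end falls between
#' samples the concentration there is linearly interpolated; when the curve
#' ends before the window (the two shortest scan durations at a 60 s
#' window), the integral runs to the last timepoint and the result is
#' flagged truncated.
#'
#' @param curve A truncated [concentration_series()].
#' @param window Integration window (s after injection start); default 60.
#' @return A list with `iauc` (mmol L^-1 s), `iauc_window` (the window
#'   actually integrated, s) and `truncated` (logical).
#' @examples
#' tt <- seq(4.5, 130.5, by = 4.5)
#' iauc(concentration_series(tt, 0.01 * tt))$iauc  # 0.01 * 60^2 / 2 = 18
#' @export
iauc <- function(curve, window = 60) {
  stopifnot(inherits(curve, "concentration_series"), window > 0)
  a <- anchored(curve)
  if (length(a$t) < 2L)
    stop("empty curve: iAUC undefined", call. = FALSE)
  last_t <- max(a$t)
  w <- min(window, last_t)
  tt <- a$t[a$t <= w]; cc <- a$c[a$t <= w]
  if (max(tt) < w) {      # interpolate the window endpoint
    cw <- stats::approx(a$t, a$c, xout = w)$y
    tt <- c(tt, w); cc <- c(cc, cw)
  }
  list(iauc = sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2),
       iauc_window = w, truncated = last_t < window)
}

#' Per-lesion, per-duration kinetic parameters
#'
#' Truncates every lesion's concentration curve to every dynamic set and
#' computes maximum slope and iAUC, producing the long-format table the
#' diagnostic analysis consumes. Lesions whose parameters are undefined on a
#' set are recorded as missing with a reason.
#'
#' @param study A `synthetic_study` (its `curves` are used), or a list of
#'   [concentration_series()] plus a `labels` vector via the `curves` /
#'   `labels` arguments.
#' @param sets A [build_dynamic_sets()] table.
#' @param window iAUC window (s).
#' @param smooth Passed to [max_slope()].
#' @param curves,labels Alternative input: a list of full-length
#'   [concentration_series()] and per-lesion class labels (used when
#'   `study` is `NULL`, e.g. for measured curves).
#' @return A data frame of class `kinetic_records`: `lesion_id`, `label`,
#'   `duration_label`, `duration`, `ms`, `iauc`, `iauc_window`, `truncated`.
#' @examples
#' study <- simulate_cohort(cohort_spec(n_benign = 2, n_malignant = 2,
#'                                      seed = 1))
#' head(compute_parameters(study, build_dynamic_sets(study$acquisition)))
#' @export
compute_parameters <- function(study = NULL, sets, window = 60,
                               smooth = FALSE, curves = NULL, labels = NULL) {
  if (!is.null(study)) {
    stopifnot(inherits(study, "synthetic_study"))
    acq <- study$acquisition
    labels <- study$lesions$label
    curves <- lapply(seq_len(nrow(study$lesions)), function(i)
      concentration_series(study$timestamps, study$curves[i, ],
                           lesion_id = study$lesions$id[i]))
  } else {
    if (is.null(curves) || is.null(labels))
      stop("provide either a study or curves + labels", call. = FALSE)
    acq <- attr(curves, "acquisition")
    if (is.null(acq)) acq <- acquisition_params()
  }
  stopifnot(length(curves) == length(labels))
  rows <- vector("list", length(curves) * nrow(sets))
  k <- 0L
  for (i in seq_along(curves)) {
    for (j in seq_len(nrow(sets))) {
      k <- k + 1L
      tc <- truncate_curve(curves[[i]], sets[j, ], acq)
      res <- tryCatch({
        ia <- iauc(tc, window = window)
        data.frame(lesion_id = curves[[i]]$lesion_id, label = labels[i],
                   duration_label = sets$label[j],
                   duration = sets$duration[j],
                   ms = max_slope(tc, smooth = smooth),
                   iauc = ia$iauc, iauc_window = ia$iauc_window,
                   truncated = ia$truncated, stringsAsFactors = FALSE)
      }, error = function(e) {
        message(sprintf("lesion %s at %s skipped: %s",
                        curves[[i]]$lesion_id, sets$label[j],
                        conditionMessage(e)))
        NULL
      })
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kinetic_records", "data.frame")
  out
}
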