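#' Cohort bookkeeping: participants, lesions and group fractions
#'
#' Participants with bilateral disease contribute two lesions, so the lesion
#' count is `n_single + 2 * n_bilateral`. Group percentages are reported on
#' the lesion denominator, rounded to whole percent as in clinical cohort
#' tables (129 single + 11 bilateral participants give 151 lesions; 55
#' benign of 151 is 36%).
#'
#' @param n_single Participants with a single lesion.
#' @param n_bilateral Participants with bilateral lesions.
#' @param n_benign Benign lesion count (must not exceed the lesion total).
#' @return A list: `n_participants`, `n_lesions`, `n_benign`, `n_malignant`,
#'   `pct_benign`, `pct_malignant` (whole percent).
#' @examples
#' cohort_counts(129, 11, n_benign = 55)
#' @export
cohort_counts <- function(n_single, n_bilateral, n_benign) {
  n_single <- as.integer(n_single); n_bilateral <- as.integer(n_bilateral)
  stopifnot(n_single >= 0, n_bilateral >= 0)
  n_lesions <- n_single + 2L * n_bilateral
  n_benign <- as.integer(n_benign)
  if (n_benign < 0 || n_benign > n_lesions)
    stop("n_benign must lie between 0 and the lesion total", call. = FALSE)
  list(n_participants = n_single + n_bilateral,
       n_lesions = n_lesions,
       n_benign = n_benign,
       n_malignant = n_lesions - n_benign,
       pct_benign = round(100 * n_benign / n_lesions),
       pct_malignant = round(100 * (n_lesions - n_benign) / n_lesions))
}
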