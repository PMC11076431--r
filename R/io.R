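#' Write a synthetic study to disk
#'
#' Writes the lesion table as CSV, the concentration curves as long-format
#' CSV (`lesion_id,time_s,conc_mM`), a JSON sidecar with the acquisition
#' parameters and seed, and — when volumes have been rendered — the dynamic
#' series, the lesion masks and the two-flip-angle pair as NIfTI.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "lesions.csv")
  utils::write.csv(study$lesions, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "curves.csv")
  utils::write.csv(curves_long(study), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "study.json")
  jsonlite::write_json(
    list(seed = study$seed, dose = study$dose,
         acquisition = unclass(study$acquisition),
         n_lesions = nrow(study$lesions)),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (!is.null(study$volumes)) {
    v <- study$volumes
    f <- file.path(dir, "dynamic.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(v$dynamic), f)
    files <- c(files, f)
    f <- file.path(dir, "mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(v$mask), f)
    files <- c(files, f)
    for (nm in c("low", "high")) {
      f <- file.path(dir, sprintf("t1map_%s.nii.gz", nm))
      RNifti::writeNifti(RNifti::asNifti(v$t1map[[nm]]), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

curves_long <- function(study) {
  n <- nrow(study$lesions)
  data.frame(lesion_id = rep(study$lesions$id, each = length(study$timestamps)),
             time_s = rep(study$timestamps, n),
             conc_mM = as.numeric(t(study$curves)))
}

#' Read concentration curves from a long-format CSV
#'
#' Inverse of the curve export in [write_study()]: reads
#' `lesion_id,time_s,conc_mM` rows into a list of [concentration_series()].
#'
#' @param path CSV path.
#' @return Named list of [concentration_series()].
#' @export
read_curves_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lesion_id", "time_s", "conc_mM") %in% names(d)))
  out <- lapply(split(d, d$lesion_id), function(g)
    concentration_series(g$time_s, g$conc_mM, lesion_id = g$lesion_id[1]))
  out[unique(d$lesion_id)]
}

#' Write kinetic records to CSV
#'
#' Long-format export of a [compute_parameters()] table
#' (`lesion_id,label,duration_label,duration,ms,iauc,iauc_window,truncated`).
#'
#' @param records A `kinetic_records` table.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read kinetic records from CSV
#' @param path CSV path written by [write_records_csv()].
#' @return A `kinetic_records` data frame.
#' @export
read_records_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("kinetic_records", "data.frame")
  out
}
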