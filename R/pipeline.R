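#' Configuration for an end-to-end analysis run
#'
#' One object governs the whole pipeline: the cohort to simulate, the
#' acquisition, the analysis options and the seed. Serializable to YAML via
#' [write_config()] / [read_config()] and round-trippable.
#'
#' @param seed Integer seed for all randomness in the run.
#' @param profile `"curves"` (lesion-level concentration curves; fast) or
#'   `"volumes"` (full voxel rendering + relaxometry).
#' @param cohort A [cohort_spec()]; its seed is overridden by `seed`.
#' @param acquisition An [acquisition_params()] object.
#' @param analysis Options: `smooth` (3-point moving average before MS),
#'   `iauc_window` (s), `alpha`, `reread_sdlog` (log-scale measurement noise
#'   of the simulated second observer used for ICC).
#' @param outdir Optional output directory for intermediate artifacts.
#' @return An object of class `ufdce_config`.
#' @export
ufdce_config <- function(seed = 1L, profile = c("curves", "volumes"),
                         cohort = cohort_spec(),
                         acquisition = acquisition_params(),
                         analysis = list(), outdir = NULL) {
  profile <- match.arg(profile)
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(acquisition, "acquisition_params"))
  default <- list(smooth = FALSE, iauc_window = 60, alpha = 0.05,
                  reread_sdlog = 0.08)
  analysis <- utils::modifyList(default, analysis)
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), profile = profile,
                 cohort = cohort, acquisition = acquisition,
                 analysis = analysis, outdir = outdir),
            class = "ufdce_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [ufdce_config()] object.
#' @param path YAML file path.
#' @return `write_config()`: invisibly `path`; `read_config()`: the
#'   reconstructed [ufdce_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ufdce_config"))
  x <- list(seed = config$seed, profile = config$profile,
            cohort = unclass(config$cohort),
            acquisition = unclass(config$acquisition),
            analysis = config$analysis, outdir = config$outdir)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  ck <- function(kin) lapply(kin, as.numeric)
  cohort <- cohort_spec(n_benign = x$cohort$n_benign,
                        n_malignant = x$cohort$n_malignant,
                        benign_kinetics = ck(x$cohort$benign_kinetics),
                        malignant_kinetics = ck(x$cohort$malignant_kinetics),
                        t10_lesion = as.numeric(x$cohort$t10_lesion),
                        noise_sigma = x$cohort$noise_sigma,
                        seed = x$cohort$seed)
  acq <- acquisition_params(tr_dce = x$acquisition$tr_dce,
                            flip_dce = x$acquisition$flip_dce,
                            dt = x$acquisition$dt,
                            n_pre = x$acquisition$n_pre,
                            n_post = x$acquisition$n_post,
                            tr_t1map = x$acquisition$tr_t1map,
                            flips_t1map = as.numeric(x$acquisition$flips_t1map),
                            r1 = x$acquisition$r1)
  ufdce_config(seed = x$seed, profile = x$profile, cohort = cohort,
               acquisition = acq, analysis = x$analysis, outdir = x$outdir)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

#' Run the full scan-duration analysis
#'
#' Orchestrates simulate -> (render + relaxometry) -> kinetics ->
#' diagnostics: simulates the cohort, obtains per-lesion concentration
#' curves (directly, or through the voxel/relaxometry path under the
#' `"volumes"` profile), computes maximum slope and iAUC on all eight
#' truncated dynamic sets, and evaluates per-duration group differences,
#' paired cross-duration tests, ROC panels with Youden cutoffs, paired
#' DeLong AUC comparisons across durations, and simulated observer ICC.
#' Deterministic for a fixed seed. When `config$outdir` is set, all
#' intermediate tables are written there.
#'
#' @param config A [ufdce_config()].
#' @return An object of class `ufdce_run` with elements `study`, `records`,
#'   `group_table`, `roc_panel`, `paired` (four [paired_duration_tests()]
#'   matrices), `auc_pairs` (per-parameter Bonferroni-adjusted DeLong
#'   matrices), `icc_table` and `provenance`.
#' @examples
#' \donttest{
#' run <- run_end_to_end(ufdce_config(seed = 42,
#'   cohort = cohort_spec(n_benign = 10, n_malignant = 15)))
#' summary(run)
#' }
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "ufdce_config"))
  acq <- config$acquisition
  study <- simulate_cohort(config$cohort, acq)

  if (config$profile == "volumes") {
    study <- render_signal(study, config$cohort)
    curves <- measure_study(study)
    attr(curves, "acquisition") <- acq
    records <- compute_parameters(study = NULL, sets = build_dynamic_sets(acq),
                                  window = config$analysis$iauc_window,
                                  smooth = config$analysis$smooth,
                                  curves = curves,
                                  labels = study$lesions$label)
  } else {
    records <- compute_parameters(study, build_dynamic_sets(acq),
                                  window = config$analysis$iauc_window,
                                  smooth = config$analysis$smooth)
  }

  sets <- build_dynamic_sets(acq)
  params <- c("ms", "iauc")
  alpha <- config$analysis$alpha

  # per-duration benign-vs-malignant comparisons (group table)
  group_rows <- list()
  for (p in params) for (d in sets$label) {
    r <- records[records$duration_label == d, ]
    cmpr <- compare_groups(r[[p]][r$label == "benign"],
                           r[[p]][r$label == "malignant"], alpha)
    group_rows[[length(group_rows) + 1L]] <- data.frame(
      parameter = p, duration_label = d,
      benign_mean = cmpr$benign_mean, benign_sd = cmpr$benign_sd,
      malignant_mean = cmpr$malignant_mean, malignant_sd = cmpr$malignant_sd,
      test = cmpr$test, p_value = cmpr$p_value, stringsAsFactors = FALSE)
  }
  group_table <- do.call(rbind, group_rows)

  # ROC panel: Youden cutoff + DeLong AUC per parameter x duration
  roc_rows <- list(); roc_objects <- list()
  for (p in params) for (d in sets$label) {
    r <- records[records$duration_label == d, ]
    res <- youden_cutoff(r[[p]], r$label)
    roc_objects[[paste(p, d, sep = ".")]] <- res
    m <- res$metrics
    roc_rows[[length(roc_rows) + 1L]] <- data.frame(
      parameter = p, duration_label = d, cutoff = res$cutoff,
      auc = res$auc, auc_lo = res$auc_ci[1], auc_hi = res$auc_ci[2],
      sensitivity = m$sensitivity$pct, specificity = m$specificity$pct,
      ppv = m$ppv$pct, npv = m$npv$pct, accuracy = m$accuracy$pct,
      tp = m$counts[["tp"]], fp = m$counts[["fp"]],
      tn = m$counts[["tn"]], fn = m$counts[["fn"]],
      stringsAsFactors = FALSE)
  }
  roc_panel <- do.call(rbind, roc_rows)

  # paired cross-duration comparisons per parameter x group
  paired <- list()
  for (p in params) for (g in c("benign", "malignant"))
    paired[[paste(p, g, sep = ".")]] <-
    paired_duration_tests(records, p, g, alpha)

  # paired DeLong AUC comparisons across durations, Bonferroni-adjusted.
  # Identical score vectors (e.g. iAUC once the 60 s window is fully
  # covered) give a zero-variance difference; these are routine here, so
  # the degenerate-pair warnings are collected as a count instead.
  auc_pairs <- list(); n_degenerate_pairs <- 0L
  for (p in params) {
    k <- nrow(sets)
    mat <- matrix(NA_real_, k, k, dimnames = list(sets$label, sets$label))
    wide <- lapply(sets$label, function(d)
      records[records$duration_label == d, ])
    labels <- wide[[1]]$label
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pt <- withCallingHandlers(
        delong_paired_test(wide[[i]][[p]], wide[[j]][[p]], labels),
        warning = function(w) {
          n_degenerate_pairs <<- n_degenerate_pairs + 1L
          invokeRestart("muffleWarning")
        })
      mat[i, j] <- mat[j, i] <- min(1, pt$p_value * k * (k - 1) / 2)
    }
    auc_pairs[[p]] <- mat
  }
  if (n_degenerate_pairs > 0)
    message(sprintf("%d duration pair(s) had identical AUCs (zero-variance difference; p = 1)",
                    n_degenerate_pairs))

  # simulated second observer: multiplicative log-normal measurement noise
  icc_rows <- list()
  reread <- with_seed(config$seed + 2L, {
    f <- exp(stats::rnorm(nrow(records) * 2, 0, config$analysis$reread_sdlog))
    data.frame(ms = records$ms * f[seq_len(nrow(records))],
               iauc = records$iauc * f[nrow(records) + seq_len(nrow(records))])
  })
  for (p in params) for (d in sets$label) {
    sel <- records$duration_label == d
    icc <- icc_agreement(records[[p]][sel], reread[[p]][sel])
    icc_rows[[length(icc_rows) + 1L]] <- data.frame(
      parameter = p, duration_label = d, icc = icc$icc,
      icc_lo = icc$ci[1], icc_hi = icc$ci[2], stringsAsFactors = FALSE)
  }
  icc_table <- do.call(rbind, icc_rows)

  run <- structure(list(
    config = config, study = study, records = records,
    group_table = group_table, roc_panel = roc_panel,
    roc_objects = roc_objects, paired = paired, auc_pairs = auc_pairs,
    icc_table = icc_table, sets = sets,
    provenance = list(seed = config$seed, profile = config$profile,
                      config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("ufdce")))),
    class = "ufdce_run")

  if (!is.null(config$outdir)) write_report(run, config$outdir)
  run
}

#' Write a run's tables and provenance to a directory
#'
#' @param run A `ufdce_run` object.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(obj, name) {
    f <- file.path(dir, name)
    utils::write.csv(obj, f, row.names = inherits(obj, "matrix"))
    files <<- c(files, f)
  }
  write_records_csv(run$records, file.path(dir, "records.csv"))
  files <- c(files, file.path(dir, "records.csv"))
  wr(run$group_table, "group_comparisons.csv")
  wr(run$roc_panel, "roc_panel.csv")
  wr(run$icc_table, "icc.csv")
  for (nm in names(run$paired))
    wr(run$paired[[nm]]$adjusted, sprintf("paired_%s.csv", nm))
  for (nm in names(run$auc_pairs))
    wr(run$auc_pairs[[nm]], sprintf("auc_pairs_%s.csv", nm))
  write_config(run$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(dir, c("config.yaml", "provenance.json")))
  invisible(files)
}

#' @export
print.ufdce_run <- function(x, ...) {
  cat("Ultrafast DCE-MRI scan-duration analysis\n")
  print(x$study)
  cat(sprintf("  %d kinetic records over %d dynamic sets\n",
              nrow(x$records), nrow(x$sets)))
  cat(sprintf("  seed %d, profile '%s', config %s\n", x$provenance$seed,
              x$provenance$profile, substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}

# shortest duration whose AUC is not significantly below any longer one
optimal_duration <- function(run, parameter, alpha = 0.05) {
  mat <- run$auc_pairs[[parameter]]
  auc <- run$roc_panel$auc[run$roc_panel$parameter == parameter]
  labs <- run$sets$label
  for (i in seq_along(labs)) {
    later <- seq_along(labs) > i
    worse <- later & auc > auc[i] & mat[i, ] < alpha
    if (!any(worse, na.rm = TRUE)) return(labs[i])
  }
  labs[length(labs)]
}

#' @export
summary.ufdce_run <- function(object, ...) {
  x <- object
  cat("Scan-duration analysis summary\n")
  tab <- table(x$study$lesions$label)
  cat(sprintf("  cohort: %d benign, %d malignant\n",
              tab[["benign"]], tab[["malignant"]]))
  for (p in c("ms", "iauc")) {
    panel <- x$roc_panel[x$roc_panel$parameter == p, ]
    best <- panel[which.max(panel$auc), ]
    cat(sprintf("  %-4s best AUC %.3f at %s; shortest non-inferior duration: %s\n",
                toupper(p), best$auc, best$duration_label,
                optimal_duration(x, p)))
  }
  invisible(x)
}

# empirical ROC curve points (FPR, TPR) for plotting
roc_points <- function(scores, labels) {
  pos <- as_positive(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(cut) sum(scores >= cut & pos) / sum(pos),
                numeric(1))
  fpr <- vapply(thr, function(cut) sum(scores >= cut & !pos) / sum(!pos),
                numeric(1))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Plot a scan-duration analysis
#'
#' `type = "trend"` draws group-mean parameter values against scan duration
#' (one line per group, one panel per parameter); `type = "roc"` overlays
#' the ROC curves of all scan durations for one parameter.
#'
#' @param x A `ufdce_run`.
#' @param type `"trend"` or `"roc"`.
#' @param parameter For `type = "roc"`: `"ms"` or `"iauc"`.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.ufdce_run <- function(x, type = c("trend", "roc"),
                           parameter = "ms", ...) {
  type <- match.arg(type)
  if (type == "trend") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    for (p in c("ms", "iauc")) {
      g <- x$group_table[x$group_table$parameter == p, ]
      dur <- x$sets$duration
      ylim <- range(0, g$benign_mean, g$malignant_mean)
      graphics::plot(dur, g$malignant_mean, type = "b", col = "firebrick",
                     pch = 16, ylim = ylim, xaxt = "n",
                     xlab = "scan duration (s)",
                     ylab = sprintf("mean %s", toupper(p)))
      graphics::axis(1, at = dur, labels = format(dur))
      graphics::lines(dur, g$benign_mean, type = "b", col = "steelblue",
                      pch = 17)
      graphics::legend("topleft", c("malignant", "benign"),
                       col = c("firebrick", "steelblue"), pch = c(16, 17),
                       bty = "n")
    }
  } else {
    r <- x$records
    cols <- grDevices::hcl.colors(nrow(x$sets), "Zissou 1")
    graphics::plot(c(0, 1), c(0, 1), type = "n", xlab = "1 - specificity",
                   ylab = "sensitivity",
                   main = sprintf("ROC, %s", toupper(parameter)))
    graphics::abline(0, 1, lty = 3, col = "grey")
    for (j in seq_len(nrow(x$sets))) {
      d <- x$sets$label[j]
      sel <- r$duration_label == d
      pts <- roc_points(r[[parameter]][sel], r$label[sel])
      graphics::lines(pts$fpr, pts$tpr, col = cols[j])
    }
    graphics::legend("bottomright", x$sets$label, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Write the report figures as image files
#'
#' Duration-trend line plots per parameter and ROC overlays per parameter,
#' as PNG files in `dir`. Refuses degenerate reports (a missing group).
#'
#' @param run A `ufdce_run`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
make_figures <- function(run, dir) {
  stopifnot(inherits(run, "ufdce_run"))
  tab <- table(run$study$lesions$label)
  if (!all(c("benign", "malignant") %in% names(tab)) || any(tab == 0))
    stop("cannot draw group figures: a lesion group is empty", call. = FALSE)
  if (is.null(run$group_table) || is.null(run$roc_panel))
    stop("report tables missing; rerun the pipeline", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "trend.png")
  grDevices::png(f, width = 1200, height = 500, res = 120)
  plot(run, type = "trend")
  grDevices::dev.off()
  files <- c(files, f)
  for (p in c("ms", "iauc")) {
    f <- file.path(dir, sprintf("roc_%s.png", p))
    grDevices::png(f, width = 600, height = 600, res = 120)
    plot(run, type = "roc", parameter = p)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
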