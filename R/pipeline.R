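#' Run the full analysis pipeline
#'
#' Wires the package's stages into the standard workflow:
#' read FCS -> arcsinh transform -> sequential gating -> QC report ->
#' bin grids -> plots -> per-sample features -> two-group comparison.
#' Every artifact (CSVs, images, the resolved configuration, a stage log
#' with input/output checksums) lands under one output directory, and
#' re-running with the same config and inputs reproduces all CSV outputs
#' byte-identically.
#'
#' The configuration is a list (or a YAML file path) with elements:
#' \describe{
#'   \item{manifest}{CSV path or data.frame with `sample_id`, `group`, `path`.}
#'   \item{transform}{`cofactor` (default 0.1), `direction`, optional
#'     `channels`; set `transform: no` if files already hold asinh values.}
#'   \item{gates}{optional path to a gate YAML (see [read_gate_config()]).}
#'   \item{panel}{list of bin configurations (fields of [bin_config()]);
#'     default: [default_panel()].}
#'   \item{qc}{`markers` (default: panel markers), `min_cells` (default
#'     1000), `outlier_factor` (default 3), `exclude_flagged` (default
#'     `FALSE`: the paper-style manual exclusion is advisory, so flagged
#'     samples stay in the comparison unless explicitly excluded).}
#'   \item{plots}{`enabled` (default `TRUE`), `statistic` (default "msi"),
#'     `format` (default "png").}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config List or YAML path as described above.
#' @return The output directory, invisibly. Side effects: `gate_report.csv`,
#'   `qc/`, `grids/`, `plots/`, `features.csv` (+ panel sidecar),
#'   `comparison.csv`, `resolved_config.yaml`, `run_log.txt`,
#'   `checksums.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  stamp <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                      " | ", msg))
  }
  fail <- function(stage, sample, e) {
    writeLines(c(log_lines, paste("FAILED at stage:", stage, "sample:", sample,
                                  "error:", conditionMessage(e))),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed",
         if (!is.na(sample)) paste0(" on sample ", sample) else "", ": ",
         conditionMessage(e), call. = FALSE)
  }

  manifest <- config$manifest
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "group", "path") %in% names(manifest)))
  stamp(paste("run start:", nrow(manifest), "samples"))

  tf <- config$transform
  do_transform <- !identical(tf, FALSE) && !identical(tf, "no")
  tspec <- if (do_transform) {
    transform_spec(
      cofactor = if (is.null(tf$cofactor)) 0.1 else tf$cofactor,
      channels = tf$channels,
      direction = if (is.null(tf$direction)) "multiply" else tf$direction)
  }
  gates <- if (!is.null(config$gates)) {
    if (is.character(config$gates)) read_gate_config(config$gates)
    else config$gates
  }

  panel <- if (is.null(config$panel)) {
    default_panel()
  } else if (inherits(config$panel[[1]], "bin_config")) {
    config$panel
  } else {
    lapply(config$panel, function(p) do.call(bin_config, p))
  }

  ## stage: read + transform + gate
  gate_reports <- list()
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$sample_id[i]
    tab <- tryCatch(read_fcs(manifest$path[i]),
                    error = function(e) fail("read_fcs", sid, e))
    if (do_transform) {
      truth <- intersect("population", tab$markers)
      sp <- tspec
      if (length(truth) > 0 && is.null(sp$channels)) {
        sp$channels <- setdiff(unname(tab$markers), truth)
      }
      tab <- tryCatch(apply_transform(tab, sp),
                      error = function(e) fail("transform", sid, e))
    } else {
      tab$transformed <- TRUE
    }
    if (!is.null(gates)) {
      res <- tryCatch(apply_gates(tab, gates),
                      error = function(e) fail("gating", sid, e))
      tab <- res$table
      gate_reports[[sid]] <<- cbind(sample_id = sid, res$report)
    }
    list(sample_id = sid, group = manifest$group[i], table = tab)
  })
  if (length(gate_reports) > 0) {
    utils::write.csv(do.call(rbind, unname(gate_reports)),
                     file.path(out_dir, "gate_report.csv"), row.names = FALSE)
  }
  stamp("stage done: read/transform/gate")

  ## stage: QC
  qc_cfg <- config$qc
  qc_markers <- qc_cfg$markers
  if (is.null(qc_markers)) {
    qc_markers <- unique(unlist(lapply(panel, function(p) {
      c(p$x_marker, p$y_marker, p$z_marker)
    })))
  }
  groups_vec <- stats::setNames(manifest$group, manifest$sample_id)
  qc <- tryCatch(
    qc_report(samples, qc_markers, groups = groups_vec,
              min_cells = if (is.null(qc_cfg$min_cells)) 1000 else qc_cfg$min_cells,
              outlier_factor = if (is.null(qc_cfg$outlier_factor)) 3
                               else qc_cfg$outlier_factor),
    error = function(e) fail("qc", NA, e))
  write_qc_report(qc, file.path(out_dir, "qc"),
                  figures = !identical(config$plots$enabled, FALSE))
  stamp(paste("stage done: qc;", nrow(qc$flags), "flag(s)"))

  exclude <- isTRUE(qc_cfg$exclude_flagged)
  analysis_samples <- samples
  if (exclude && nrow(qc$flags) > 0) {
    drop <- unique(qc$flags$sample_id)
    stamp(paste("excluding flagged sample(s):", paste(drop, collapse = ", ")))
    analysis_samples <- Filter(function(s) !s$sample_id %in% drop, samples)
  } else if (nrow(qc$flags) > 0) {
    warning("QC flagged sample(s) ", paste(unique(qc$flags$sample_id),
                                           collapse = ", "),
            " but qc$exclude_flagged is FALSE; they remain in the analysis")
  }

  ## stage: grids + plots
  grids_dir <- file.path(out_dir, "grids")
  dir.create(grids_dir, showWarnings = FALSE)
  plots_cfg <- config$plots
  do_plots <- !identical(plots_cfg$enabled, FALSE)
  plot_stat <- if (is.null(plots_cfg$statistic)) "msi" else plots_cfg$statistic
  plot_fmt <- if (is.null(plots_cfg$format)) "png" else plots_cfg$format
  if (do_plots) dir.create(file.path(out_dir, "plots"), showWarnings = FALSE)
  for (s in analysis_samples) {
    for (cfg in panel) {
      grid <- tryCatch(compute_bin_grid(s$table, cfg),
                       error = function(e) fail("binning", s$sample_id, e))
      stem <- sprintf("%s_%s_%s_%s", s$sample_id, cfg$x_marker, cfg$y_marker,
                      cfg$z_marker)
      write_bin_grid(grid, file.path(grids_dir, paste0(stem, ".csv")))
      if (do_plots && any(grid$displayed)) {
        ann <- if (!is.null(cfg$x_threshold) && !is.null(cfg$y_threshold)) {
          quadrant_stats(s$table, cfg)
        }
        tryCatch(render_bin_plot(
          grid, statistic = plot_stat, annotations = ann,
          out = file.path(out_dir, "plots",
                          sprintf("%s_%s.%s", stem, plot_stat, plot_fmt))),
          error = function(e) fail("plotting", s$sample_id, e))
      }
    }
  }
  stamp("stage done: grids/plots")

  ## stage: features + comparison
  features <- tryCatch(build_feature_matrix(analysis_samples, panel),
                       error = function(e) fail("features", NA, e))
  write_feature_matrix(features, file.path(out_dir, "features.csv"))
  n_groups <- length(unique(stats::na.omit(features$group)))
  if (n_groups == 2L) {
    comparison <- tryCatch(compare_groups(features),
                           error = function(e) fail("comparison", NA, e))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  } else {
    stamp(paste("comparison skipped:", n_groups, "group(s) present"))
  }
  stamp("stage done: features/comparison")

  resolved <- list(
    manifest = manifest,
    transform = if (do_transform) unclass(tspec) else FALSE,
    gates = if (!is.null(gates)) lapply(gates$steps, unclass),
    panel = lapply(panel, unclass),
    qc = list(markers = qc_markers,
              min_cells = if (is.null(qc_cfg$min_cells)) 1000 else qc_cfg$min_cells,
              outlier_factor = if (is.null(qc_cfg$outlier_factor)) 3
                               else qc_cfg$outlier_factor,
              exclude_flagged = exclude),
    plots = list(enabled = do_plots, statistic = plot_stat, format = plot_fmt),
    out_dir = out_dir)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))

  csvs <- list.files(out_dir, pattern = "\\.csv$", recursive = TRUE,
                     full.names = TRUE)
  sums <- tools::md5sum(csvs)
  utils::write.csv(data.frame(file = sub(paste0("^", out_dir, "/?"), "",
                                         names(sums)),
                              md5 = unname(sums)),
                   file.path(out_dir, "checksums.csv"), row.names = FALSE)
  stamp("run complete")
  writeLines(log_lines, log_path)
  invisible(out_dir)
}
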