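#' Maximum bin-MSI of a grid
#'
#' The maximum of the per-bin mean z intensity over displayed bins only --
#' exactly the upper bound of a dynamic bin plot's color legend. This is the
#' package's main threshold-independent per-sample feature: it never
#' consults the z positivity threshold, only the display rule.
#'
#' @param grid A [compute_bin_grid()] result.
#' @return A single number, or `NA` if no bin is displayed.
#' @export
max_bin_msi <- function(grid) {
  v <- grid$msi[grid$displayed & !is.na(grid$msi)]
  if (length(v) == 0) NA_real_ else max(v)
}

#' Bin-MSI range of a grid
#'
#' Minimum and maximum per-bin MSI over displayed bins: the endpoints of the
#' dynamic color scale. Threshold-independent like [max_bin_msi()].
#'
#' @param grid A [compute_bin_grid()] result.
#' @return Numeric `c(min, max)`, or `c(NA, NA)` if no bin is displayed.
#' @export
bin_msi_range <- function(grid) {
  v <- grid$msi[grid$displayed & !is.na(grid$msi)]
  if (length(v) == 0) c(NA_real_, NA_real_) else range(v)
}

#' Quadrant percentages as named features
#'
#' Flattens a [quadrant_stats()] result into named scalars: `pct_Qk` (black
#' numbers, percent of all events) and, when z statistics are present,
#' `pct_zpos_Qk` (red numbers, percent of the quadrant's cells that are
#' z-positive).
#'
#' @param qs A [quadrant_stats()] result.
#' @return Named numeric vector.
#' @export
quadrant_features <- function(qs) {
  out <- stats::setNames(qs$pct_of_total, paste0("pct_", qs$quadrant))
  if (any(!is.na(qs$n_zpos))) {
    out <- c(out, stats::setNames(qs$pct_zpos, paste0("pct_zpos_", qs$quadrant)))
  }
  out
}

feature_prefix <- function(cfg, with_z = TRUE) {
  if (with_z && !is.null(cfg$z_marker)) {
    paste(cfg$x_marker, cfg$y_marker, cfg$z_marker, sep = "_")
  } else {
    paste(cfg$x_marker, cfg$y_marker, sep = "_")
  }
}

sample_panel_features <- function(table, panel) {
  feats <- numeric(0)
  seen_density <- character(0)
  for (cfg in panel) {
    prefix_z <- feature_prefix(cfg, with_z = TRUE)
    resolvable <- vapply(
      c(cfg$x_marker, cfg$y_marker, cfg$z_marker),
      function(m) tryCatch({ marker_column(table, m); TRUE },
                           error = function(e) FALSE),
      logical(1))
    if (!all(resolvable)) {
      warning("sample lacks marker(s) ",
              paste(c(cfg$x_marker, cfg$y_marker, cfg$z_marker)[!resolvable],
                    collapse = ", "),
              "; affected features set to missing")
      feats[paste0(prefix_z, "__max_bin_msi")] <- NA_real_
      next
    }
    grid <- compute_bin_grid(table, cfg)
    feats[paste0(prefix_z, "__max_bin_msi")] <- max_bin_msi(grid)
    rng <- bin_msi_range(grid)
    feats[paste0(prefix_z, "__min_bin_msi")] <- rng[1]

    if (!is.null(cfg$x_threshold) && !is.null(cfg$y_threshold)) {
      qs <- quadrant_stats(table, cfg)
      qf <- quadrant_features(qs)
      black <- grepl("^pct_Q", names(qf))
      prefix_xy <- feature_prefix(cfg, with_z = FALSE)
      # density (black) percentages depend only on the x/y pair: emit once
      if (!prefix_xy %in% seen_density) {
        feats[paste0(prefix_xy, "__", names(qf)[black])] <- qf[black]
        seen_density <- c(seen_density, prefix_xy)
      }
      if (any(!black)) {
        feats[paste0(prefix_z, "__", names(qf)[!black])] <- qf[!black]
      }
    }
  }
  feats
}

#' Build the per-sample feature matrix
#'
#' Runs every bin configuration of a panel over every sample and assembles
#' the engineered features into one row per sample: maximum and minimum
#' bin-MSI per (x, y, z) triple, quadrant density percentages per (x, y)
#' pair, and z+ quadrant percentages per triple when thresholds are set.
#' Feature names are deterministic functions of the configuration
#' (`CD90_CD44_CD86__max_bin_msi`, `CD90_CD44__pct_Q2`,
#' `CD90_CD44_CD27__pct_zpos_Q2`, ...). Missing markers yield missing
#' values, never zeros.
#'
#' @param samples A list of samples, each a list with `sample_id`, `group`
#'   and `table` (a transformed [event_table()]).
#' @param panel A list of [bin_config()] objects.
#' @return A `feature_matrix` data.frame (`sample_id`, `group`, one column
#'   per feature) with the panel attached as attribute `"panel"`.
#' @export
build_feature_matrix <- function(samples, panel) {
  stopifnot(length(samples) > 0, length(panel) > 0)
  if (inherits(panel, "bin_config")) panel <- list(panel)
  rows <- lapply(samples, function(s) {
    stopifnot(!is.null(s$sample_id), inherits(s$table, "event_table"))
    if (!s$table$transformed) {
      stop("sample ", s$sample_id, " is not transformed")
    }
    sample_panel_features(s$table, panel)
  })
  all_names <- unique(unlist(lapply(rows, names)))
  mat <- do.call(rbind, lapply(rows, function(r) {
    out <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
    out[names(r)] <- r
    out
  }))
  colnames(mat) <- all_names
  out <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    group = vapply(samples, function(s) {
      if (is.null(s$group)) NA_character_ else as.character(s$group)
    }, character(1)),
    mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("feature_matrix", "data.frame"), panel = panel)
}

#' Write a feature matrix with its panel sidecar
#'
#' The CSV holds the features; a YAML sidecar (`<path>.panel.yaml`) records
#' every bin configuration used, so the feature set is reproducible from the
#' two files alone.
#'
#' @param features A [build_feature_matrix()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  panel <- attr(features, "panel")
  if (!is.null(panel)) {
    yaml::write_yaml(lapply(panel, function(cfg) unclass(cfg)),
                     paste0(path, ".panel.yaml"))
  }
  invisible(path)
}

#' Default bin-plot panel on the CD90/CD44 plane
#'
#' The package's stock panel: CD90 on x, CD44 on y, and seven z markers
#' (CD86, CD27, Ki67, Tbet, Foxp3, KLRG1, PDL1), each with 0.2-wide bins and
#' the 5-cell display rule. Quadrant and positivity thresholds are
#' analyst-set quantities; the defaults here match the synthetic cohort of
#' [default_synthetic_spec()] and should be overridden for real data.
#'
#' @param x_threshold,y_threshold Quadrant cut points (asinh units).
#' @param z_thresholds Named numeric vector of positivity cuts per z marker.
#' @param bin_width,min_cells_per_bin Passed to [bin_config()].
#' @return A list of [bin_config()] objects.
#' @export
default_panel <- function(x_threshold = 2.6, y_threshold = 1.7,
                          z_thresholds = c(CD86 = 1.2, CD27 = 2.0,
                                           Ki67 = 1.4, Tbet = 1.5,
                                           Foxp3 = 1.5, KLRG1 = 1.1,
                                           PDL1 = 1.2),
                          bin_width = 0.2, min_cells_per_bin = 5L) {
  lapply(names(z_thresholds), function(z) {
    bin_config("CD90", "CD44", z, bin_width = bin_width,
               min_cells_per_bin = min_cells_per_bin,
               x_threshold = x_threshold, y_threshold = y_threshold,
               z_threshold = unname(z_thresholds[[z]]))
  })
}
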