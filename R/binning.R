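#' Bin plot configuration
#'
#' Parameters of one (x, y, z) bin-plot triple: the two markers spanning the
#' plane, the third marker whose statistic colors each bin, the fixed bin
#' width in asinh units, the minimum number of cells a bin needs before it is
#' displayed, and optional quadrant / positivity thresholds.
#'
#' All thresholds are in transformed (asinh) units. Events exactly on a
#' threshold count as positive/high (closed comparison, `>=`). The bin grid
#' is anchored at 0 in transformed space: an event maps to bin index
#' `floor(value / bin_width)` on each axis, so negative indices occur for
#' negative asinh values.
#'
#' @param x_marker,y_marker Markers spanning the plane.
#' @param z_marker Marker summarized per bin. May be omitted for pure
#'   density plots.
#' @param bin_width Bin side length in asinh units; default 0.2.
#' @param min_cells_per_bin Display threshold; bins with fewer cells are kept
#'   in the grid but flagged as not displayed. Default 5.
#' @param x_threshold,y_threshold Quadrant cut points (asinh units); required
#'   only by quadrant statistics.
#' @param z_threshold Positivity cut for the z marker; required only by
#'   z-positive statistics (MSI+, z+ frequencies).
#' @return A `bin_config` object.
#' @export
bin_config <- function(x_marker, y_marker, z_marker = NULL, bin_width = 0.2,
                       min_cells_per_bin = 5L, x_threshold = NULL,
                       y_threshold = NULL, z_threshold = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a single positive number")
  }
  min_cells_per_bin <- as.integer(min_cells_per_bin)
  if (is.na(min_cells_per_bin) || min_cells_per_bin < 1L) {
    stop("min_cells_per_bin must be a positive integer")
  }
  structure(list(
    x_marker = x_marker, y_marker = y_marker, z_marker = z_marker,
    bin_width = bin_width, min_cells_per_bin = min_cells_per_bin,
    x_threshold = x_threshold, y_threshold = y_threshold,
    z_threshold = z_threshold
  ), class = "bin_config")
}

#' Assign events to fixed-width bins
#'
#' Maps each (x, y) pair to the integer index pair
#' `(floor(x / bin_width), floor(y / bin_width))`. The grid is anchored at 0
#' in transformed space, so the assignment is deterministic and free of any
#' data-dependent origin. Events with a non-finite coordinate are flagged
#' `NA` and counted, never silently dropped.
#'
#' @param x,y Equal-length numeric vectors of transformed intensities.
#' @param bin_width Positive bin side length.
#' @return Integer matrix with columns `i`, `j` (one row per event; `NA`
#'   rows mark non-finite coordinates) and attribute `n_nonfinite`.
#' @export
assign_bins <- function(x, y, bin_width) {
  stopifnot(length(x) == length(y), bin_width > 0)
  ok <- is.finite(x) & is.finite(y)
  i <- ifelse(ok, floor(x / bin_width), NA_real_)
  j <- ifelse(ok, floor(y / bin_width), NA_real_)
  out <- cbind(i = as.integer(i), j = as.integer(j))
  attr(out, "n_nonfinite") <- sum(!ok)
  out
}

quadrant_names <- c("Q1", "Q2", "Q3", "Q4")

## Default quadrant layout: Q1 = low x / low y, Q2 = low x / high y,
## Q3 = high x / high y, Q4 = high x / low y. "High" means >= threshold.
quadrant_of <- function(x, y, x_threshold, y_threshold) {
  xh <- x >= x_threshold
  yh <- y >= y_threshold
  ifelse(!xh & !yh, 1L, ifelse(!xh & yh, 2L, ifelse(xh & yh, 3L, 4L)))
}

#' Compute the per-bin statistic grid
#'
#' Partitions the x-y plane into fixed-width bins and computes, per bin, the
#' cell count, the mean signal intensity of the z marker over all cells
#' (MSI), and -- when a z positivity threshold is configured -- the count of
#' z-positive cells, their mean intensity (MSI+), and the z+ frequency.
#'
#' All events enter the stored grid; the 5-cell display rule is carried as
#' the logical flags `displayed` (`n_cells >= min_cells_per_bin`) and
#' `displayed_pos` (`n_zpos >= min_cells_per_bin`) and applied only at
#' rendering / feature-extraction time.
#'
#' @param table A transformed [event_table()].
#' @param config A [bin_config()]; `z_marker` may be `NULL` for a pure
#'   density grid.
#' @return A `bin_grid`: a data.frame with one row per non-empty bin
#'   (columns `i`, `j`, `n_cells`, `msi`, `n_zpos`, `msi_pos`, `freq_zpos`,
#'   `displayed`, `displayed_pos`), ordered by `(i, j)`, with attributes
#'   `config`, `n_total_events` (finite events binned) and `n_excluded`
#'   (non-finite events).
#' @export
compute_bin_grid <- function(table, config) {
  stopifnot(inherits(table, "event_table"), inherits(config, "bin_config"))
  if (!table$transformed) {
    stop("compute_bin_grid expects a transformed event table")
  }
  x <- marker_values(table, config$x_marker)
  y <- marker_values(table, config$y_marker)
  has_z <- !is.null(config$z_marker)
  if (has_z) {
    z <- marker_values(table, config$z_marker)
    if (config$z_marker %in% c(config$x_marker, config$y_marker)) {
      warning("z marker coincides with a plane marker (degenerate bin plot)")
    }
  } else {
    z <- rep(NA_real_, length(x))
  }

  idx <- assign_bins(x, y, config$bin_width)
  ok <- !is.na(idx[, "i"])
  if (has_z) ok <- ok & is.finite(z)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " event(s) with non-finite coordinates excluded from binning")
  }

  zt <- config$z_threshold
  dt <- data.table::data.table(i = idx[ok, "i"], j = idx[ok, "j"], z = z[ok])
  if (has_z && !is.null(zt)) {
    grid <- dt[, {
      pos <- z >= zt
      list(n_cells = .N, msi = mean(z), n_zpos = sum(pos),
           msi_pos = if (any(pos)) mean(z[pos]) else NA_real_)
    }, by = c("i", "j")]
    grid[, "freq_zpos" := grid$n_zpos / grid$n_cells]
  } else if (has_z) {
    grid <- dt[, list(n_cells = .N, msi = mean(z)), by = c("i", "j")]
    grid[, c("n_zpos", "msi_pos", "freq_zpos") :=
           list(NA_integer_, NA_real_, NA_real_)]
  } else {
    grid <- dt[, list(n_cells = .N), by = c("i", "j")]
    grid[, c("msi", "n_zpos", "msi_pos", "freq_zpos") :=
           list(NA_real_, NA_integer_, NA_real_, NA_real_)]
  }
  grid[, "displayed" := grid$n_cells >= config$min_cells_per_bin]
  grid[, "displayed_pos" := !is.na(grid$n_zpos) &
         grid$n_zpos >= config$min_cells_per_bin]
  data.table::setorderv(grid, c("i", "j"))
  grid <- as.data.frame(grid)

  structure(grid, class = c("bin_grid", "data.frame"),
            config = config, n_total_events = sum(ok),
            n_excluded = n_excluded)
}

#' @export
print.bin_grid <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("bin_grid: %s x %s (z = %s), width %g, %d bins, %d events\n",
              cfg$x_marker, cfg$y_marker,
              if (is.null(cfg$z_marker)) "none" else cfg$z_marker,
              cfg$bin_width, nrow(x), attr(x, "n_total_events")))
  NextMethod()
}

#' Quadrant frequency statistics
#'
#' Splits the plane into four quadrants at the configured x/y thresholds and
#' computes, per quadrant, the cell count, the percentage of all events
#' (printed in black on bin plots), and -- when a z threshold is set -- the
#' count of z-positive cells and their percentage of that quadrant's cells
#' (printed in red). The black percentages always sum to 100; the red
#' percentage of an empty quadrant is reported as missing, not 0.
#'
#' @param table A transformed [event_table()].
#' @param config A [bin_config()] with `x_threshold` and `y_threshold` set.
#' @return A `quadrant_stats` data.frame with rows Q1..Q4 and columns
#'   `quadrant`, `n_cells`, `pct_of_total`, `n_zpos`, `pct_zpos`.
#' @export
quadrant_stats <- function(table, config) {
  stopifnot(inherits(table, "event_table"), inherits(config, "bin_config"))
  if (is.null(config$x_threshold) || is.null(config$y_threshold)) {
    stop("quadrant statistics need x_threshold and y_threshold")
  }
  x <- marker_values(table, config$x_marker)
  y <- marker_values(table, config$y_marker)
  has_z <- !is.null(config$z_marker) && !is.null(config$z_threshold)
  z <- if (has_z) marker_values(table, config$z_marker) else rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y)
  if (has_z) ok <- ok & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]

  q <- quadrant_of(x, y, config$x_threshold, config$y_threshold)
  n_total <- length(q)
  out <- data.frame(quadrant = quadrant_names,
                    n_cells = NA_integer_, pct_of_total = NA_real_,
                    n_zpos = NA_integer_, pct_zpos = NA_real_)
  for (k in 1:4) {
    in_q <- q == k
    n_q <- sum(in_q)
    out$n_cells[k] <- n_q
    out$pct_of_total[k] <- if (n_total > 0) 100 * n_q / n_total else NA_real_
    if (has_z) {
      n_pos <- sum(z[in_q] >= config$z_threshold)
      out$n_zpos[k] <- n_pos
      out$pct_zpos[k] <- if (n_q > 0) 100 * n_pos / n_q else NA_real_
    }
  }
  structure(out, class = c("quadrant_stats", "data.frame"),
            config = config, n_total_events = n_total)
}

#' Joint z1/z2 co-expression fractions per quadrant
#'
#' For a pair of z markers with positivity thresholds, computes within each
#' quadrant the fraction of cells in the four joint categories
#' z1+z2+, z1+z2-, z1-z2+, z1-z2- (the sectors of the co-expression pie
#' charts). Fractions within a non-empty quadrant sum to 1.
#'
#' @param table A transformed [event_table()].
#' @param config A [bin_config()] with quadrant thresholds, `z_marker` and
#'   `z_threshold` set (the first z marker, e.g. Ki67).
#' @param z2_marker,z2_threshold Second z marker (e.g. a transcription
#'   factor) and its positivity threshold.
#' @return A `coexpression_stats` data.frame with rows Q1..Q4 and columns
#'   `quadrant`, `n_cells`, `frac_pp`, `frac_pn`, `frac_np`, `frac_nn`
#'   (p/n = positive/negative for z1 then z2).
#' @export
coexpression_stats <- function(table, config, z2_marker, z2_threshold) {
  stopifnot(inherits(table, "event_table"), inherits(config, "bin_config"))
  if (is.null(config$x_threshold) || is.null(config$y_threshold)) {
    stop("co-expression statistics need x_threshold and y_threshold")
  }
  if (is.null(config$z_marker) || is.null(config$z_threshold)) {
    stop("co-expression statistics need z_marker and z_threshold")
  }
  if (identical(z2_marker, config$z_marker)) {
    warning("z2 marker equals z1 marker (degenerate co-expression)")
  }
  x <- marker_values(table, config$x_marker)
  y <- marker_values(table, config$y_marker)
  z1 <- marker_values(table, config$z_marker)
  z2 <- marker_values(table, z2_marker)
  ok <- is.finite(x) & is.finite(y) & is.finite(z1) & is.finite(z2)
  x <- x[ok]; y <- y[ok]; z1 <- z1[ok]; z2 <- z2[ok]

  q <- quadrant_of(x, y, config$x_threshold, config$y_threshold)
  p1 <- z1 >= config$z_threshold
  p2 <- z2 >= z2_threshold
  out <- data.frame(quadrant = quadrant_names, n_cells = NA_integer_,
                    frac_pp = NA_real_, frac_pn = NA_real_,
                    frac_np = NA_real_, frac_nn = NA_real_)
  for (k in 1:4) {
    in_q <- q == k
    n_q <- sum(in_q)
    out$n_cells[k] <- n_q
    if (n_q > 0) {
      out$frac_pp[k] <- sum(p1[in_q] & p2[in_q]) / n_q
      out$frac_pn[k] <- sum(p1[in_q] & !p2[in_q]) / n_q
      out$frac_np[k] <- sum(!p1[in_q] & p2[in_q]) / n_q
      out$frac_nn[k] <- sum(!p1[in_q] & !p2[in_q]) / n_q
    }
  }
  structure(out, class = c("coexpression_stats", "data.frame"),
            config = config, z2_marker = z2_marker,
            z2_threshold = z2_threshold)
}

#' Export a bin grid as CSV
#'
#' One row per bin with the bin's lower-left corner in asinh units alongside
#' the indices and statistics.
#'
#' @param grid A [compute_bin_grid()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bin_grid <- function(grid, path) {
  cfg <- attr(grid, "config")
  out <- data.frame(i = grid$i, j = grid$j,
                    x_lo = grid$i * cfg$bin_width,
                    y_lo = grid$j * cfg$bin_width,
                    n = grid$n_cells, msi = grid$msi,
                    n_zpos = grid$n_zpos, msi_pos = grid$msi_pos,
                    freq_zpos = grid$freq_zpos, displayed = grid$displayed,
                    displayed_pos = grid$displayed_pos)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export quadrant statistics as CSV
#'
#' @param qs A [quadrant_stats()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quadrant_stats <- function(qs, path) {
  utils::write.csv(as.data.frame(qs), path, row.names = FALSE)
  invisible(path)
}
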