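#' Color scale for bin plots
#'
#' Bin statistics are mapped through a piecewise-linear blue - yellow - red
#' palette quantized to `n_levels` colors: low values in shades of blue,
#' mid-range values yellow, high values red. Values are clamped to
#' `[v_min, v_max]` before mapping. With a degenerate scale
#' (`v_min == v_max`) every value maps to the palette midpoint.
#'
#' @param v_min,v_max Scale endpoints (statistic units).
#' @param mode `"dynamic"` (endpoints from one grid's displayed bins) or
#'   `"common"` (endpoints pooled over a panel); informational label.
#' @param n_levels Number of quantization levels (default 50).
#' @return A `color_scale` object.
#' @export
color_scale <- function(v_min, v_max, mode = c("dynamic", "common"),
                        n_levels = 50L) {
  mode <- match.arg(mode)
  if (!is.finite(v_min) || !is.finite(v_max) || v_min > v_max) {
    stop("invalid color scale endpoints")
  }
  structure(list(
    v_min = v_min, v_max = v_max, mode = mode, n_levels = as.integer(n_levels),
    colors = grDevices::colorRampPalette(c("blue", "yellow", "red"))(n_levels)
  ), class = "color_scale")
}

#' Map statistic values to palette colors
#'
#' Monotone: larger values never map to a lower palette index.
#'
#' @param values Numeric vector.
#' @param scale A [color_scale()].
#' @return Character vector of colors.
#' @export
map_color <- function(values, scale) {
  n <- scale$n_levels
  if (scale$v_max == scale$v_min) {
    return(rep(scale$colors[ceiling(n / 2)], length(values)))
  }
  v <- pmin(pmax(values, scale$v_min), scale$v_max)
  idx <- 1L + as.integer(floor((v - scale$v_min) / (scale$v_max - scale$v_min) *
                               (n - 1) + 0.5))
  scale$colors[pmin(idx, n)]
}

grid_stat_values <- function(grid, statistic) {
  switch(statistic,
    msi = grid$msi[grid$displayed & !is.na(grid$msi)],
    msi_pos = grid$msi_pos[grid$displayed_pos & !is.na(grid$msi_pos)],
    count = as.numeric(grid$n_cells[grid$displayed]),
    stop("unknown statistic: ", statistic))
}

#' Dynamic color range of a single grid
#'
#' Endpoints are the min and max of the statistic over the grid's displayed
#' bins -- exactly the numbers printed on a dynamic plot's legend.
#'
#' @param grid A [compute_bin_grid()] result.
#' @param statistic `"msi"`, `"msi_pos"` or `"count"`.
#' @inheritParams color_scale
#' @return A [color_scale()] with `mode = "dynamic"`.
#' @export
dynamic_range <- function(grid, statistic = "msi", n_levels = 50L) {
  v <- grid_stat_values(grid, statistic)
  if (length(v) == 0) stop("no displayed bins; cannot derive a color range")
  color_scale(min(v), max(v), mode = "dynamic", n_levels = n_levels)
}

#' Common color range over several grids
#'
#' Pools the displayed-bin statistic over all grids of a panel and returns
#' the joint min/max, so equal values render as equal colors across samples.
#' A single grid reduces to its dynamic range.
#'
#' @param grids List of [compute_bin_grid()] results.
#' @inheritParams dynamic_range
#' @return A [color_scale()] with `mode = "common"`.
#' @export
common_range <- function(grids, statistic = "msi", n_levels = 50L) {
  if (inherits(grids, "bin_grid")) grids <- list(grids)
  vals <- unlist(lapply(grids, grid_stat_values, statistic = statistic))
  if (length(vals) == 0) {
    stop("no displayed bins in any grid; cannot derive a common range")
  }
  color_scale(min(vals), max(vals), mode = "common", n_levels = n_levels)
}

## Percentages on plots are printed with 1 decimal, rounding half away from
## zero (sprintf would round half to even).
fmt_pct <- function(x) {
  formatC(sign(x) * floor(abs(x) * 10 + 0.5) / 10, format = "f", digits = 1)
}

draw_bin_plot <- function(grid, scale, statistic, annotations = NULL,
                          main = NULL) {
  cfg <- attr(grid, "config")
  w <- cfg$bin_width
  if (statistic == "msi_pos") {
    show <- grid$displayed  # n_cells rule; low-z+ bins drawn gray below
  } else {
    show <- grid$displayed
  }
  shown <- grid[show, , drop = FALSE]
  if (nrow(shown) == 0) {
    warning("no displayed bins; rendering axes only")
    xlim <- c(0, 1); ylim <- c(0, 1)
  } else {
    xlim <- range(c(shown$i * w, (shown$i + 1) * w))
    ylim <- range(c(shown$j * w, (shown$j + 1) * w))
  }
  if (!is.null(cfg$x_threshold)) xlim <- range(c(xlim, cfg$x_threshold))
  if (!is.null(cfg$y_threshold)) ylim <- range(c(ylim, cfg$y_threshold))

  graphics::par(mar = c(4.5, 4.5, 3, 6))
  plot(NA, xlim = xlim, ylim = ylim, xaxs = "i", yaxs = "i",
       xlab = paste0(cfg$x_marker, " (asinh)"),
       ylab = paste0(cfg$y_marker, " (asinh)"),
       main = if (is.null(main)) {
         sprintf("%s / %s / %s [%s]", cfg$x_marker, cfg$y_marker,
                 if (is.null(cfg$z_marker)) "density" else cfg$z_marker,
                 statistic)
       } else main)
  if (nrow(shown) > 0) {
    cols <- switch(statistic,
      msi = map_color(shown$msi, scale),
      count = map_color(as.numeric(shown$n_cells), scale),
      msi_pos = {
        cc <- rep("gray70", nrow(shown))
        ok <- shown$displayed_pos & !is.na(shown$msi_pos)
        cc[ok] <- map_color(shown$msi_pos[ok], scale)
        cc
      })
    graphics::rect(shown$i * w, shown$j * w, (shown$i + 1) * w,
                   (shown$j + 1) * w, col = cols, border = NA)
  }
  if (!is.null(cfg$x_threshold)) graphics::abline(v = cfg$x_threshold, lty = 2)
  if (!is.null(cfg$y_threshold)) graphics::abline(h = cfg$y_threshold, lty = 2)

  if (!is.null(annotations)) {
    xt <- cfg$x_threshold; yt <- cfg$y_threshold
    pos <- list(Q1 = c(xlim[1], ylim[1], 4, 3), Q2 = c(xlim[1], ylim[2], 4, 1),
                Q3 = c(xlim[2], ylim[2], 2, 1), Q4 = c(xlim[2], ylim[1], 2, 3))
    for (k in seq_len(nrow(annotations))) {
      qn <- annotations$quadrant[k]
      p <- pos[[qn]]
      graphics::text(p[1], p[2], labels = fmt_pct(annotations$pct_of_total[k]),
                     adj = c(if (p[3] == 4) 0 else 1, if (p[4] == 3) 0 else 1),
                     col = "black", font = 2)
      if (!is.na(annotations$pct_zpos[k])) {
        off <- 0.06 * diff(ylim) * (if (p[4] == 3) 1 else -1)
        graphics::text(p[1], p[2] + off,
                       labels = fmt_pct(annotations$pct_zpos[k]),
                       adj = c(if (p[3] == 4) 0 else 1, if (p[4] == 3) 0 else 1),
                       col = "red", font = 2)
      }
    }
  }
  # color legend with raw endpoints printed rounded
  usr <- graphics::par("usr")
  xl <- usr[2] + 0.02 * diff(usr[1:2]); xr <- usr[2] + 0.06 * diff(usr[1:2])
  yy <- seq(usr[3], usr[4], length.out = scale$n_levels + 1)
  graphics::par(xpd = TRUE)
  graphics::rect(xl, yy[-length(yy)], xr, yy[-1], col = scale$colors,
                 border = NA)
  graphics::text(xr, usr[3], labels = formatC(scale$v_min, digits = 3,
                                              format = "g"), pos = 4, cex = 0.8)
  graphics::text(xr, usr[4], labels = formatC(scale$v_max, digits = 3,
                                              format = "g"), pos = 4, cex = 0.8)
  graphics::par(xpd = FALSE)
  invisible(NULL)
}

open_device <- function(out, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(out))
  switch(ext,
    png = grDevices::png(out, width = width, height = height, units = "in",
                         res = 150),
    svg = grDevices::svg(out, width = width, height = height),
    stop("unsupported output format '.", ext, "' (use .png or .svg)"))
}

#' Render one bin plot
#'
#' Draws the grid as a color-coded heat map: for `statistic = "msi"` or
#' `"count"` only displayed bins (>= 5 cells by default) are drawn; for
#' `"msi_pos"` displayed bins whose z-positive count is below the display
#' threshold are drawn gray. Quadrant threshold lines and the black / red
#' percentage annotations are added when available, and the color legend
#' shows the scale endpoints. Output format follows the file extension
#' (`.png` or `.svg`); SVG output is byte-deterministic for identical
#' inputs.
#'
#' @param grid A [compute_bin_grid()] result.
#' @param scale A [color_scale()]; default: the grid's [dynamic_range()].
#' @param statistic `"msi"`, `"msi_pos"` or `"count"`.
#' @param annotations Optional [quadrant_stats()] result.
#' @param out Output file path (`.png` or `.svg`).
#' @param main Optional plot title.
#' @return `out`, invisibly.
#' @export
render_bin_plot <- function(grid, scale = NULL, statistic = "msi",
                            annotations = NULL, out, main = NULL) {
  if (is.null(scale)) scale <- dynamic_range(grid, statistic)
  open_device(out)
  on.exit(grDevices::dev.off())
  draw_bin_plot(grid, scale, statistic, annotations, main = main)
  invisible(out)
}

#' Render a side-by-side panel of bin plots
#'
#' Takes a samples-by-z collection of grids sharing one x-y plane, derives a
#' common color scale per z marker, writes one image per (sample, z) pair
#' with the deterministic name `{sample}_{x}_{y}_{z}_{stat}.{ext}`, plus a
#' contact sheet `panel_{x}_{y}_{stat}.{ext}` laying the plots out as a
#' samples-by-markers grid.
#'
#' @param grids Named nested list: `grids[[sample]][[z_marker]]` is a
#'   [compute_bin_grid()] result. All grids must share x/y markers and bin
#'   width.
#' @param out_dir Output directory (created if absent).
#' @param statistic Passed to [render_bin_plot()].
#' @param format `"png"` or `"svg"`.
#' @return Character vector of written file paths (contact sheet last).
#' @export
render_panel <- function(grids, out_dir, statistic = "msi", format = "png") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- names(grids)
  z_markers <- names(grids[[1]])
  cfg0 <- attr(grids[[1]][[1]], "config")
  for (s in samples) for (z in z_markers) {
    cfg <- attr(grids[[s]][[z]], "config")
    if (!identical(cfg$x_marker, cfg0$x_marker) ||
        !identical(cfg$y_marker, cfg0$y_marker) ||
        !identical(cfg$bin_width, cfg0$bin_width)) {
      stop("panel grids must share x/y markers and bin width")
    }
  }
  scales <- lapply(z_markers, function(z) {
    common_range(lapply(samples, function(s) grids[[s]][[z]]), statistic)
  })
  names(scales) <- z_markers

  paths <- character(0)
  for (s in samples) for (z in z_markers) {
    f <- file.path(out_dir, sprintf("%s_%s_%s_%s_%s.%s", s, cfg0$x_marker,
                                    cfg0$y_marker, z, statistic, format))
    render_bin_plot(grids[[s]][[z]], scale = scales[[z]],
                    statistic = statistic, out = f,
                    main = sprintf("%s: %s", s, z))
    paths <- c(paths, f)
  }
  sheet <- file.path(out_dir, sprintf("panel_%s_%s_%s.%s", cfg0$x_marker,
                                      cfg0$y_marker, statistic, format))
  open_device(sheet, width = 4 * length(z_markers), height = 4 * length(samples))
  graphics::par(mfrow = c(length(samples), length(z_markers)))
  for (s in samples) for (z in z_markers) {
    draw_bin_plot(grids[[s]][[z]], scales[[z]], statistic,
                  main = sprintf("%s: %s", s, z))
  }
  grDevices::dev.off()
  c(paths, sheet)
}

#' Render co-expression pie charts
#'
#' One pie per quadrant (2 x 2 layout) showing the four joint z1/z2
#' categories with a fixed category-to-color legend; sector angles are
#' proportional to the fractions. Empty quadrants are drawn as a placeholder
#' label instead of a pie.
#'
#' @param stats A [coexpression_stats()] result.
#' @param out Output file path (`.png` or `.svg`).
#' @return `out`, invisibly.
#' @export
render_coexpression_pies <- function(stats, out) {
  cfg <- attr(stats, "config")
  z1 <- cfg$z_marker; z2 <- attr(stats, "z2_marker")
  labs <- c(paste0(z1, "+", z2, "+"), paste0(z1, "+", z2, "-"),
            paste0(z1, "-", z2, "+"), paste0(z1, "-", z2, "-"))
  cols <- c("red", "orange", "steelblue", "gray80")
  open_device(out)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  for (qn in c("Q2", "Q3", "Q1", "Q4")) {  # upper quadrants on top row
    k <- match(qn, stats$quadrant)
    fr <- c(stats$frac_pp[k], stats$frac_pn[k], stats$frac_np[k],
            stats$frac_nn[k])
    if (stats$n_cells[k] == 0 || all(is.na(fr))) {
      plot.new(); graphics::title(main = qn)
      graphics::text(0.5, 0.5, "empty quadrant")
      next
    }
    keep <- fr > 0
    graphics::pie(fr[keep], labels = labs[keep], col = cols[keep],
                  main = sprintf("%s (n=%d)", qn, stats$n_cells[k]),
                  clockwise = TRUE)
  }
  invisible(out)
}
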