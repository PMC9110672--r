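test_that("bin index assignment is floor(v / width), negatives included", {
  idx <- assign_bins(c(0, 0.45, -0.1), c(0, 0.19, 0.3), 0.2)
  expect_equal(idx[, "i"], c(0L, 2L, -1L))
  expect_equal(idx[, "j"], c(0L, 0L, 1L))
  expect_equal(attr(idx, "n_nonfinite"), 0L)
})

test_that("non-finite coordinates are flagged and counted, not dropped silently", {
  idx <- assign_bins(c(1, NA, Inf, 2), c(1, 1, 1, NaN), 0.2)
  expect_equal(attr(idx, "n_nonfinite"), 3L)
  expect_true(all(is.na(idx[2:4, "i"])))
  tab <- event_table(cbind(x = c(1, NA, 2), y = c(1, 1, 1), z = c(1, 1, 1)),
                     transformed = TRUE)
  expect_message(g <- compute_bin_grid(tab, bin_config("x", "y", "z")),
                 "non-finite")
  expect_equal(attr(g, "n_excluded"), 1L)
  expect_equal(sum(g$n_cells), 2L)
})

test_that("a hand-computed bin gives the stated statistics", {
  tab <- event_table(cbind(x = rep(0.1, 6), y = rep(0.1, 6), z = 0:5),
                     transformed = TRUE)
  g <- compute_bin_grid(tab, bin_config("x", "y", "z", z_threshold = 2.5))
  expect_equal(nrow(g), 1)
  expect_equal(g$n_cells, 6L)
  expect_equal(g$msi, 2.5)
  expect_equal(g$n_zpos, 3L)
  expect_equal(g$msi_pos, 4.0)
  expect_equal(g$freq_zpos, 0.5)
  expect_true(g$displayed)  # 6 >= 5
})

test_that("bins with fewer than five cells are flagged as not displayed", {
  tab <- event_table(cbind(x = c(rep(0.1, 4), rep(0.5, 5)),
                           y = rep(0.1, 9), z = rep(1, 9)),
                     transformed = TRUE)
  g <- compute_bin_grid(tab, bin_config("x", "y", "z"))
  expect_equal(g$displayed[g$i == 0], FALSE)   # 4 cells
  expect_equal(g$displayed[g$i == 2], TRUE)    # 5 cells
  # the grid itself keeps every event regardless of display
  expect_equal(sum(g$n_cells), 9L)
})

test_that("grid statistics are invariant to event order and covariant to width-multiple shifts", {
  tab <- random_table(3000, seed = 21)
  cfg <- bin_config("x", "y", "z", z_threshold = 2)
  g <- compute_bin_grid(tab, cfg)

  perm <- sample(nrow(tab$values))
  tab_p <- event_table(tab$values[perm, ], transformed = TRUE)
  expect_equal(as.data.frame(compute_bin_grid(tab_p, cfg)), as.data.frame(g))

  shifted <- tab
  shifted$values[, "x"] <- shifted$values[, "x"] + 3 * cfg$bin_width
  g_s <- compute_bin_grid(shifted, cfg)
  expect_equal(g_s$i, g$i + 3L)
  expect_equal(g_s$j, g$j)
  expect_equal(g_s$msi, g$msi)
  expect_equal(g_s$n_cells, g$n_cells)
})

test_that("z threshold at -Inf degenerates MSI+ to MSI and red percentages to 100", {
  tab <- random_table(2000, seed = 33)
  cfg <- bin_config("x", "y", "z", z_threshold = -Inf,
                    x_threshold = 2, y_threshold = 2)
  g <- compute_bin_grid(tab, cfg)
  expect_equal(g$msi_pos, g$msi)
  expect_equal(g$freq_zpos, rep(1, nrow(g)))
  qs <- quadrant_stats(tab, cfg)
  expect_equal(qs$pct_zpos[qs$n_cells > 0], rep(100, sum(qs$n_cells > 0)))
})

test_that("quadrant percentages match a constructed 4/3/2/1 split", {
  xy <- rbind(
    matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE),   # Q1 low/low
    matrix(rep(c(1, 3), 3), ncol = 2, byrow = TRUE),   # Q2 low/high
    matrix(rep(c(3, 3), 2), ncol = 2, byrow = TRUE),   # Q3 high/high
    matrix(rep(c(3, 1), 1), ncol = 2, byrow = TRUE))   # Q4 high/low
  tab <- event_table(cbind(xy, z = c(rep(0, 9), 5)),
                     channels = c("x", "y", "z"), transformed = TRUE)
  qs <- quadrant_stats(tab, bin_config("x", "y", "z", x_threshold = 2,
                                       y_threshold = 2, z_threshold = 2.5))
  expect_equal(qs$pct_of_total, c(40, 30, 20, 10))
  expect_equal(sum(qs$pct_of_total), 100)
  expect_equal(qs$pct_zpos, c(0, 0, 0, 100))  # the lone z+ cell sits in Q4
})

test_that("events exactly on a threshold count as high, and empty quadrants report missing", {
  tab <- event_table(cbind(x = c(2, 2), y = c(2, 1), z = c(5, 0)),
                     transformed = TRUE)
  qs <- quadrant_stats(tab, bin_config("x", "y", "z", x_threshold = 2,
                                       y_threshold = 2, z_threshold = 2.5))
  expect_equal(qs$n_cells, c(0L, 0L, 1L, 1L))  # x == threshold goes high
  expect_true(all(is.na(qs$pct_zpos[1:2])))    # empty quadrants: missing
  expect_equal(qs$pct_zpos[3], 100)            # 1 of 1 z+ (quadrant with 2? no: Q3 holds (2,2))
})

test_that("co-expression fractions match constructed quadrant compositions", {
  # all four cells in Q3, one in each joint category
  tab <- event_table(cbind(x = rep(3, 4), y = rep(3, 4),
                           z1 = c(5, 5, 0, 0), z2 = c(5, 0, 5, 0)),
                     transformed = TRUE)
  cfg <- bin_config("x", "y", "z1", x_threshold = 2, y_threshold = 2,
                    z_threshold = 2.5)
  cs <- coexpression_stats(tab, cfg, "z2", 2.5)
  q3 <- cs[cs$quadrant == "Q3", ]
  expect_equal(unlist(q3[c("frac_pp", "frac_pn", "frac_np", "frac_nn")]),
               c(frac_pp = 0.25, frac_pn = 0.25, frac_np = 0.25,
                 frac_nn = 0.25))
  expect_true(all(is.na(cs$frac_pp[cs$quadrant != "Q3"])))

  # all z1+z2+ -> (1, 0, 0, 0)
  tab2 <- event_table(cbind(x = rep(3, 5), y = rep(3, 5), z1 = rep(5, 5),
                            z2 = rep(5, 5)), transformed = TRUE)
  cs2 <- coexpression_stats(tab2, cfg, "z2", 2.5)
  expect_equal(cs2$frac_pp[cs2$quadrant == "Q3"], 1)
  expect_equal(cs2$frac_nn[cs2$quadrant == "Q3"], 0)
})

test_that("co-expression fractions equal an exhaustive counting oracle and sum to 1", {
  tab <- random_table(4000, c("x", "y", "z1", "z2"), seed = 17)
  cfg <- bin_config("x", "y", "z1", x_threshold = 1.8, y_threshold = 2.1,
                    z_threshold = 2.0)
  cs <- coexpression_stats(tab, cfg, "z2", 2.4)
  v <- tab$values
  q <- ifelse(v[, "x"] < 1.8 & v[, "y"] < 2.1, 1,
              ifelse(v[, "x"] < 1.8, 2, ifelse(v[, "y"] >= 2.1, 3, 4)))
  for (k in 1:4) {
    rows <- q == k
    n <- sum(rows)
    expect_equal(cs$n_cells[k], n)
    if (n > 0) {
      p1 <- v[rows, "z1"] >= 2.0; p2 <- v[rows, "z2"] >= 2.4
      expect_equal(cs$frac_pp[k], sum(p1 & p2) / n)
      expect_equal(cs$frac_pn[k], sum(p1 & !p2) / n)
      expect_equal(cs$frac_np[k], sum(!p1 & p2) / n)
      expect_equal(cs$frac_nn[k], sum(!p1 & !p2) / n)
      expect_equal(cs$frac_pp[k] + cs$frac_pn[k] + cs$frac_np[k] +
                     cs$frac_nn[k], 1)
    }
  }
})

test_that("degenerate z markers warn but compute", {
  tab <- random_table(100, c("x", "y"), seed = 2)
  expect_warning(g <- compute_bin_grid(tab, bin_config("x", "y", "x")),
                 "degenerate")
  expect_equal(sum(g$n_cells), 100L)
  expect_error(compute_bin_grid(tab, bin_config("x", "y", "CD99")),
               "CD99")
})

test_that("bin grid CSV export carries corners and statistics", {
  tab <- random_table(500, seed = 12)
  g <- compute_bin_grid(tab, bin_config("x", "y", "z", z_threshold = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bin_grid(g, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(g))
  expect_equal(back$x_lo, g$i * 0.2)
  expect_equal(back$msi, g$msi, tolerance = 1e-12)
})
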