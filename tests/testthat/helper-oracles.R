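# Independent brute-force oracles and fixture builders used across the
# suite. Every oracle recomputes its quantity from first principles with a
# different traversal than the package, so agreement is a genuine check.

random_table <- function(n, markers = c("x", "y", "z"), seed = 1,
                         lo = -0.5, hi = 4, transformed = TRUE) {
  set.seed(seed)
  m <- matrix(stats::runif(n * length(markers), lo, hi), ncol = length(markers),
              dimnames = list(NULL, markers))
  event_table(m, transformed = transformed)
}

# naive per-event double loop over bins: no vectorized grouping
oracle_bin_grid <- function(table, config) {
  x <- marker_values(table, config$x_marker)
  y <- marker_values(table, config$y_marker)
  z <- marker_values(table, config$z_marker)
  w <- config$bin_width
  acc <- new.env()
  for (e in seq_along(x)) {
    if (!is.finite(x[e]) || !is.finite(y[e]) || !is.finite(z[e])) next
    key <- paste(floor(x[e] / w), floor(y[e] / w))
    cur <- get0(key, envir = acc, ifnotfound = list(z = numeric(0)))
    cur$z <- c(cur$z, z[e])
    assign(key, cur, envir = acc)
  }
  keys <- ls(acc)
  out <- do.call(rbind, lapply(keys, function(k) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    zs <- get(k, envir = acc)$z
    zt <- config$z_threshold
    pos <- if (is.null(zt)) rep(FALSE, length(zs)) else zs >= zt
    data.frame(i = ij[1], j = ij[2], n_cells = length(zs), msi = mean(zs),
               n_zpos = if (is.null(zt)) NA_integer_ else sum(pos),
               msi_pos = if (!is.null(zt) && any(pos)) mean(zs[pos]) else NA_real_,
               freq_zpos = if (is.null(zt)) NA_real_ else sum(pos) / length(zs))
  }))
  out[order(out$i, out$j), ]
}

# per-event boolean classification for quadrants (Q1 ll, Q2 lh, Q3 hh, Q4 hl)
oracle_quadrants <- function(table, config) {
  x <- marker_values(table, config$x_marker)
  y <- marker_values(table, config$y_marker)
  z <- marker_values(table, config$z_marker)
  counts <- integer(4); pos <- integer(4)
  for (e in seq_along(x)) {
    xh <- x[e] >= config$x_threshold; yh <- y[e] >= config$y_threshold
    q <- if (!xh && !yh) 1 else if (!xh && yh) 2 else if (xh && yh) 3 else 4
    counts[q] <- counts[q] + 1L
    if (!is.null(config$z_threshold) && z[e] >= config$z_threshold) {
      pos[q] <- pos[q] + 1L
    }
  }
  list(n_cells = counts, pct_of_total = 100 * counts / length(x),
       n_zpos = pos,
       pct_zpos = ifelse(counts > 0, 100 * pos / counts, NA_real_))
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a); n <- length(pooled)
  r <- rank(pooled)
  mu <- n_a * (n - n_a) / 2
  combos <- utils::combn(n, n_a)
  u_all <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# greedy Ward agglomeration via the Lance-Williams update on Euclidean
# distances (the ward.D2 criterion), tracking member sets and heights
oracle_ward <- function(profiles) {
  n <- nrow(profiles)
  d2 <- as.matrix(stats::dist(profiles))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  merges <- list()
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (d2[i, j] < best_d) { best_d <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_d))
    merges <- c(merges, list(sort(c(active[[i]], active[[j]]))))
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- numeric(k)
    for (h in seq_len(k)) {
      if (h == i || h == j) next
      nh <- sizes[h]
      new_row[h] <- ((ni + nh) * d2[i, h] + (nj + nh) * d2[j, h] -
                       nh * d2[i, j]) / (ni + nj + nh)
    }
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(heights = heights, merges = merges)
}

hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    members <- function(idx) {
      if (idx < 0) -idx else sets[[idx]]
    }
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# NRS oracle: direct eigendecomposition of the marker covariance matrix
oracle_nrs <- function(X, n_components = 3) {
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  k <- seq_len(n_components)
  colSums(t(abs(eg$vectors[, k, drop = FALSE])) * eg$values[k])
}
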