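#' Per-sample median expression profiles
#'
#' One row per sample, one column per biological marker, each entry the
#' exact median of that sample's transformed channel (for even event counts
#' the midpoint of the two central order statistics). These profiles feed
#' the MDS and Ward QC views.
#'
#' @param samples Named list of transformed [event_table()]s, or a list of
#'   lists with `sample_id` and `table`.
#' @param markers Character vector of marker labels to profile.
#' @return Numeric matrix `n_samples x n_markers` with sample ids as row
#'   names.
#' @export
median_profiles <- function(samples, markers) {
  samples <- normalize_sample_list(samples)
  out <- matrix(NA_real_, nrow = length(samples), ncol = length(markers),
                dimnames = list(vapply(samples, `[[`, character(1), "sample_id"),
                                markers))
  for (s in seq_along(samples)) {
    tab <- samples[[s]]$table
    for (m in markers) {
      ok <- tryCatch({ marker_column(tab, m); TRUE }, error = function(e) FALSE)
      if (!ok) {
        stop("sample ", samples[[s]]$sample_id, " lacks marker ", m)
      }
      out[s, m] <- stats::median(marker_values(tab, m))
    }
  }
  out
}

normalize_sample_list <- function(samples) {
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (inherits(s, "event_table")) {
      id <- names(samples)[i]
      if (is.null(id) || id == "") id <- paste0("sample", i)
      list(sample_id = id, table = s)
    } else {
      stopifnot(inherits(s$table, "event_table"))
      if (is.null(s$sample_id)) s$sample_id <- paste0("sample", i)
      s
    }
  })
}

#' Classical (metric) multidimensional scaling of sample profiles
#'
#' Embeds samples by eigendecomposition of the double-centered squared
#' Euclidean distance matrix of their median profiles (Torgerson MDS,
#' via [stats::cmdscale()]). When the profiles genuinely live in a
#' k-dimensional affine subspace the embedding reproduces the input
#' distances exactly.
#'
#' @param profiles A [median_profiles()] matrix.
#' @param k Number of embedding dimensions (default 2); must be smaller
#'   than the number of samples.
#' @return A list with `coords` (`n_samples x k`) and `eigenvalues`.
#' @export
classical_mds <- function(profiles, k = 2) {
  n <- nrow(profiles)
  if (n < 2L) stop("MDS needs at least 2 samples")
  if (k >= n) stop("k must be smaller than the number of samples")
  fit <- stats::cmdscale(stats::dist(profiles), k = k, eig = TRUE)
  coords <- as.matrix(fit$points)
  rownames(coords) <- rownames(profiles)
  list(coords = coords, eigenvalues = fit$eig)
}

#' Ward hierarchical clustering of sample profiles
#'
#' Agglomerative clustering on Euclidean distances minimizing Ward's
#' increase-in-within-cluster-variance criterion at every merge
#' ([stats::hclust()] with `method = "ward.D2"`, which applies Ward's rule
#' to the distances themselves). Merge heights are non-decreasing.
#'
#' @param profiles A [median_profiles()] matrix.
#' @return An `hclust` object.
#' @export
ward_clustering <- function(profiles) {
  if (nrow(profiles) < 2L) stop("clustering needs at least 2 samples")
  stats::hclust(stats::dist(profiles), method = "ward.D2")
}

#' Non-redundancy score (NRS) of markers
#'
#' Per sample, the cell-by-marker matrix (markers centered) is decomposed by
#' PCA and each marker m is scored as the sum over the top `n_components`
#' principal components of `eigenvalue_k * |loading_{m,k}|`. Markers whose
#' variation is captured by directions shared with other markers score low;
#' markers carrying unique variance score high. The cross-sample summary is
#' the per-marker mean score, ranked descending. NRS is deliberately not
#' scale-invariant: inputs must be arcsinh-transformed first so variances
#' are comparable.
#'
#' @param samples As in [median_profiles()].
#' @param markers Marker labels to score.
#' @param n_components Number of leading components (default 3).
#' @return A list with `per_sample` (`n_samples x n_markers` score matrix)
#'   and `summary` (named numeric vector of mean scores, sorted decreasing).
#' @export
nrs <- function(samples, markers, n_components = 3) {
  samples <- normalize_sample_list(samples)
  per_sample <- matrix(
    NA_real_, nrow = length(samples), ncol = length(markers),
    dimnames = list(vapply(samples, `[[`, character(1), "sample_id"), markers))
  for (s in seq_along(samples)) {
    tab <- samples[[s]]$table
    X <- vapply(markers, function(m) marker_values(tab, m),
                numeric(nrow(tab$values)))
    if (nrow(X) < n_components + 1L || ncol(X) < n_components) {
      stop("sample ", samples[[s]]$sample_id,
           " too small for NRS with ", n_components, " components")
    }
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- seq_len(min(n_components, length(pc$sdev)))
    ev <- pc$sdev[k]^2
    per_sample[s, ] <- colSums(t(abs(pc$rotation[, k, drop = FALSE])) * ev)
  }
  summary <- sort(colMeans(per_sample), decreasing = TRUE)
  list(per_sample = per_sample, summary = summary)
}

#' Sample-level quality-control report
#'
#' Collects per-sample cell counts, median profiles, the MDS embedding and
#' the Ward dendrogram, and flags suspicious samples: cell count below
#' `min_cells`, or MDS position farther from its group centroid than
#' `outlier_factor` times the median within-group centroid distance.
#' Flags are advisory -- no sample is ever dropped here; exclusion is an
#' explicit, logged pipeline choice.
#'
#' @param samples As in [median_profiles()].
#' @param markers Marker labels used for profiling.
#' @param groups Optional named character vector `sample_id -> group`; with
#'   no groups all samples form one group for the centroid rule.
#' @param min_cells Low-count flag threshold (default 1000 events).
#' @param outlier_factor Centroid-distance multiplier `c` (default 3).
#' @return A `qc_report` list: `counts`, `profiles`, `mds`, `dendrogram`,
#'   `flags` (data.frame `sample_id`, `reason`, `value`).
#' @export
qc_report <- function(samples, markers, groups = NULL, min_cells = 1000,
                      outlier_factor = 3) {
  samples <- normalize_sample_list(samples)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  counts <- stats::setNames(
    vapply(samples, function(s) nrow(s$table$values), numeric(1)), ids)
  profiles <- median_profiles(samples, markers)
  k <- min(2L, length(samples) - 1L)
  mds <- classical_mds(profiles, k = k)
  dend <- ward_clustering(profiles)

  flags <- data.frame(sample_id = character(0), reason = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
  low <- counts < min_cells
  if (any(low)) {
    flags <- rbind(flags, data.frame(sample_id = ids[low],
                                     reason = "low_cell_count",
                                     value = unname(counts[low])))
  }
  grp <- if (is.null(groups)) stats::setNames(rep("all", length(ids)), ids)
         else groups[ids]
  for (g in unique(grp)) {
    members <- ids[grp == g]
    if (length(members) < 3L) next  # centroid rule needs context
    pts <- mds$coords[members, , drop = FALSE]
    centroid <- colMeans(pts)
    d <- sqrt(rowSums(sweep(pts, 2, centroid)^2))
    cutoff <- outlier_factor * stats::median(d)
    out <- d > cutoff & cutoff > 0
    if (any(out)) {
      flags <- rbind(flags, data.frame(sample_id = members[out],
                                       reason = "mds_outlier",
                                       value = unname(d[out])))
    }
  }
  structure(list(counts = counts, profiles = profiles, mds = mds,
                 dendrogram = dend, flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d markers, %d flag(s)\n",
              length(x$counts), ncol(x$profiles), nrow(x$flags)))
  if (nrow(x$flags) > 0) print(x$flags)
  invisible(x)
}

#' Write QC report tables and figures
#'
#' Emits `qc_counts.csv`, `qc_mds.csv`, `qc_flags.csv` and, unless
#' `figures = FALSE`, an MDS scatter plot and the Ward dendrogram as PNG.
#'
#' @param report A [qc_report()] result.
#' @param dir Output directory (created if absent).
#' @param figures Render the two figures (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(report, dir, figures = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(sample_id = names(report$counts),
                              n_events = unname(report$counts)),
                   file.path(dir, "qc_counts.csv"), row.names = FALSE)
  coords <- report$mds$coords
  utils::write.csv(data.frame(sample_id = rownames(coords), coords,
                              check.names = FALSE),
                   file.path(dir, "qc_mds.csv"), row.names = FALSE)
  utils::write.csv(report$flags, file.path(dir, "qc_flags.csv"),
                   row.names = FALSE)
  if (figures) {
    grDevices::png(file.path(dir, "qc_mds.png"), width = 700, height = 700)
    plot(coords[, 1], if (ncol(coords) > 1) coords[, 2] else rep(0, nrow(coords)),
         xlab = "MDS 1", ylab = "MDS 2", pch = 19,
         main = "Median-profile MDS")
    graphics::text(coords[, 1],
                   if (ncol(coords) > 1) coords[, 2] else rep(0, nrow(coords)),
                   labels = rownames(coords), pos = 3, cex = 0.8)
    grDevices::dev.off()
    grDevices::png(file.path(dir, "qc_dendrogram.png"), width = 700, height = 700)
    plot(report$dendrogram, main = "Ward clustering of median profiles",
         xlab = "", sub = "")
    grDevices::dev.off()
  }
  invisible(dir)
}
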