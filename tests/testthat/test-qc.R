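tbl <- function(m, markers) event_table(m, channels = markers,
                                        transformed = TRUE)

test_that("median profiles are exact medians, midpoint for even n", {
  s1 <- tbl(cbind(A = c(1, 2, 3), B = c(10, 20, 30)), c("A", "B"))
  s2 <- tbl(cbind(A = c(1, 2, 3, 4), B = c(0, 0, 1, 1)), c("A", "B"))
  prof <- median_profiles(list(x = s1, y = s2), c("A", "B"))
  expect_equal(prof["x", "A"], 2)
  expect_equal(prof["y", "A"], 2.5)
  expect_equal(prof["y", "B"], 0.5)
})

test_that("median profiles match a full-sort oracle on random data", {
  set.seed(5)
  tab <- random_table(1001, c("A", "B"), seed = 5)
  prof <- median_profiles(list(s = tab), c("A", "B"))
  sorted <- sort(tab$values[, "A"])
  expect_equal(prof["s", "A"], sorted[501])
})

test_that("a missing marker is reported with sample and marker name", {
  s1 <- tbl(cbind(A = 1:3), "A")
  expect_error(median_profiles(list(bad = s1), c("A", "B")), "bad.*B")
})

test_that("two-point MDS reproduces the input distance exactly", {
  prof <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))   # distance 5
  fit <- classical_mds(prof, k = 1)
  expect_equal(unname(abs(fit$coords[1, 1] - fit$coords[2, 1])), 5)
})

test_that("a planar configuration embedded in 41 dimensions is recovered", {
  set.seed(8)
  n <- 10
  plane <- matrix(stats::rnorm(n * 2), ncol = 2)
  basis <- qr.Q(qr(matrix(stats::rnorm(41 * 2), ncol = 2)))
  prof <- plane %*% t(basis) + matrix(5, n, 41)
  rownames(prof) <- paste0("s", 1:n)
  fit <- classical_mds(prof, k = 2)
  expect_lt(max(abs(stats::dist(fit$coords) - stats::dist(prof))), 1e-8)
})

test_that("duplicated samples land on coincident MDS coordinates", {
  prof <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 7))
  fit <- classical_mds(prof, k = 2)
  # the second axis is degenerate here, so compare by distance
  expect_lt(sqrt(sum((fit$coords["a", ] - fit$coords["b", ])^2)), 1e-6)
  expect_error(classical_mds(prof, k = 3), "smaller")
})

test_that("MDS distances are invariant to marker order", {
  set.seed(13)
  prof <- matrix(stats::rnorm(6 * 8), nrow = 6,
                 dimnames = list(paste0("s", 1:6), paste0("m", 1:8)))
  d1 <- stats::dist(classical_mds(prof, 2)$coords)
  d2 <- stats::dist(classical_mds(prof[, sample(8)], 2)$coords)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-10)
})

test_that("Ward clustering: two samples merge at their Euclidean distance", {
  prof <- rbind(a = c(0, 0), b = c(3, 4))
  hc <- ward_clustering(prof)
  expect_equal(hc$height, 5)
})

test_that("Ward joins tight triplets before bridging them, heights monotone", {
  set.seed(2)
  prof <- rbind(matrix(stats::rnorm(6, sd = 0.01), ncol = 2),
                matrix(stats::rnorm(6, mean = 50, sd = 0.01), ncol = 2))
  rownames(prof) <- paste0("s", 1:6)
  hc <- ward_clustering(prof)
  expect_true(all(diff(hc$height) >= 0))
  sets <- hclust_merge_sets(hc)
  # last merge bridges the two triplets
  expect_equal(sets[[5]], 1:6)
  expect_true(all(vapply(sets[1:4], function(s) {
    all(s <= 3) || all(s >= 4)
  }, logical(1))))
})

test_that("Ward merge sequence matches the brute-force agglomeration oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    prof <- matrix(stats::rnorm(6 * 5), nrow = 6,
                   dimnames = list(paste0("s", 1:6), NULL))
    hc <- ward_clustering(prof)
    oracle <- oracle_ward(prof)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hclust_merge_sets(hc), oracle$merges)
  }
})

test_that("NRS concentrates on the only informative marker", {
  set.seed(31)
  m <- cbind(A = stats::rnorm(5000, sd = 1), B = 0.5, C = 0.5, D = 0.5)
  res <- nrs(list(s = tbl(m, colnames(m))), colnames(m))
  expect_gt(res$summary[["A"]], 0.99 * sum(res$summary))
  expect_equal(names(res$summary)[1], "A")
})

test_that("independent markers of equal variance score equal NRS", {
  set.seed(32)
  m <- cbind(A = stats::rnorm(10000), B = stats::rnorm(10000))
  res <- nrs(list(s = tbl(m, colnames(m))), colnames(m), n_components = 2)
  expect_equal(res$summary[["A"]], res$summary[["B"]], tolerance = 0.05)
})

test_that("NRS matches the covariance-eigendecomposition oracle", {
  set.seed(33)
  sigma <- crossprod(matrix(stats::rnorm(25), 5))
  m <- matrix(stats::rnorm(2000 * 5), ncol = 5) %*% chol(sigma)
  colnames(m) <- paste0("M", 1:5)
  res <- nrs(list(s = tbl(m, colnames(m))), colnames(m))
  oracle <- stats::setNames(oracle_nrs(m, 3), colnames(m))
  expect_equal(res$per_sample["s", names(oracle)], oracle, tolerance = 1e-8)
  # invariance to event and marker order
  res2 <- nrs(list(s = tbl(m[sample(2000), rev(colnames(m))],
                           rev(colnames(m)))), colnames(m))
  expect_equal(res2$per_sample["s", ], res$per_sample["s", ],
               tolerance = 1e-8)
})

test_that("qc_report flags low counts and MDS outliers, advisory only", {
  set.seed(41)
  mk <- c("A", "B", "C")
  mk_tbl <- function(n, mu) tbl(matrix(stats::rnorm(n * 3, mean = mu),
                                       ncol = 3, dimnames = list(NULL, mk)), mk)
  samples <- list(s1 = mk_tbl(5000, 1), s2 = mk_tbl(5000, 1),
                  s3 = mk_tbl(5000, 1), s4 = mk_tbl(5000, 1),
                  tiny = mk_tbl(100, 1), shifted = mk_tbl(5000, 8))
  groups <- stats::setNames(rep("g", 6),
                            c("s1", "s2", "s3", "s4", "tiny", "shifted"))
  rep <- qc_report(samples, mk, groups = groups, min_cells = 1000)
  expect_true("tiny" %in% rep$flags$sample_id[rep$flags$reason == "low_cell_count"])
  expect_true("shifted" %in% rep$flags$sample_id[rep$flags$reason == "mds_outlier"])
  expect_equal(length(rep$counts), 6)   # nothing dropped

  identical_samples <- list(a = mk_tbl(1, 0), b = mk_tbl(1, 0), c = mk_tbl(1, 0))
  # identical profiles: no outlier flags (counts below threshold still flag)
  rep2 <- qc_report(identical_samples, mk, min_cells = 0)
  expect_false("mds_outlier" %in% rep2$flags$reason)
})

test_that("qc report files are written", {
  mk <- c("A", "B")
  samples <- list(
    s1 = tbl(matrix(stats::rnorm(200), ncol = 2, dimnames = list(NULL, mk)), mk),
    s2 = tbl(matrix(stats::rnorm(200, 2), ncol = 2, dimnames = list(NULL, mk)), mk),
    s3 = tbl(matrix(stats::rnorm(200, 4), ncol = 2, dimnames = list(NULL, mk)), mk))
  dir <- withr::local_tempdir()
  write_qc_report(qc_report(samples, mk, min_cells = 10), dir)
  expect_true(all(file.exists(file.path(dir, c("qc_counts.csv", "qc_mds.csv",
                                               "qc_flags.csv", "qc_mds.png",
                                               "qc_dendrogram.png")))))
})
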