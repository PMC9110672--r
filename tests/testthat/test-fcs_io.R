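test_that("FCS write/read roundtrips event data at float32 precision", {
  set.seed(42)
  tab <- event_table(matrix(stats::runif(1000 * 12, 0, 10000), ncol = 12,
                            dimnames = list(NULL, paste0("Ch", 1:12))),
                     markers = stats::setNames(paste0("Marker ", 1:12),
                                               paste0("Ch", 1:12)))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  # float32 storage: relative error bounded by the 24-bit mantissa
  expect_lt(max(abs(back$values - tab$values) / pmax(abs(tab$values), 1)),
            2^-23)
  expect_identical(back$channels, tab$channels)
  expect_identical(back$markers, tab$markers)   # spaces in $PnS preserved
  expect_false(back$transformed)
})

test_that("a file declaring zero events reads back empty with channels intact", {
  tab <- event_table(matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("A", "B", "C"))))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  expect_equal(nrow(back$values), 0)
  expect_identical(back$channels, c("A", "B", "C"))
})

test_that("a large matrix roundtrips elementwise at float32", {
  set.seed(7)
  n <- 50000; p <- 41
  tab <- event_table(matrix(stats::rexp(n * p, rate = 1 / 100), ncol = p,
                            dimnames = list(NULL, paste0("Ch", seq_len(p)))))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  expect_equal(dim(back$values), c(n, p))
  expect_lt(max(abs(back$values - tab$values) / pmax(abs(tab$values), 1e-6)),
            2^-23)
})

test_that("write -> read -> write produces byte-identical files", {
  tab <- random_table(500, paste0("M", 1:5), seed = 3, transformed = FALSE)
  p1 <- withr::local_tempfile(fileext = ".fcs")
  p2 <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, p1)
  write_fcs(read_fcs(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("IO errors are informative", {
  expect_error(read_fcs("/nonexistent/file.fcs"), "not found")
  # corrupt $TOT: the error names the inconsistency
  tab <- random_table(100, c("A", "B"), seed = 1, transformed = FALSE)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  raw <- readBin(path, "raw", file.size(path))
  needle <- charToRaw("/$TOT/100/")
  hit <- NULL
  for (k in seq_len(length(raw) - length(needle) + 1)) {
    if (all(raw[k:(k + length(needle) - 1)] == needle)) { hit <- k; break }
  }
  raw[hit:(hit + length(needle) - 1)] <- charToRaw("/$TOT/999/")
  writeBin(raw, path)
  expect_error(read_fcs(path), "\\$TOT")
})

test_that("arcsinh transform follows the cofactor convention and is invertible", {
  tab <- event_table(matrix(c(0, 10, 100), ncol = 1,
                            dimnames = list(NULL, "M")))
  tr <- apply_transform(tab, transform_spec(cofactor = 0.1))
  expect_equal(unname(tr$values[1, 1]), 0)            # asinh(0) = 0
  expect_equal(unname(tr$values[2, 1]), asinh(1))     # 10 * 0.1 = 1
  expect_true(tr$transformed)

  set.seed(11)
  raw <- matrix(stats::runif(1000, 0, 5000), ncol = 1,
                dimnames = list(NULL, "M"))
  tr2 <- apply_transform(event_table(raw), transform_spec(0.1))
  recovered <- sinh(tr2$values) / 0.1
  expect_lt(max(abs(recovered - raw) / raw), 1e-6)
  # strict monotonicity: ranks preserved per channel
  expect_identical(rank(tr2$values[, 1]), rank(raw[, 1]))
})

test_that("the divide convention and channel subsetting are honoured", {
  raw <- matrix(c(5, 5), ncol = 2, dimnames = list(NULL, c("A", "B")))
  tr <- apply_transform(event_table(raw),
                        transform_spec(0.1, channels = "A",
                                       direction = "divide"))
  expect_equal(unname(tr$values[1, "A"]), asinh(50))
  expect_equal(unname(tr$values[1, "B"]), 5)  # excluded channel untouched
})

test_that("transforming twice is a state error", {
  tab <- apply_transform(random_table(10, "M", transformed = FALSE))
  expect_error(apply_transform(tab), "already transformed")
})

test_that("a full-range gate is the identity", {
  tab <- random_table(200, c("x", "y"), seed = 5)
  res <- apply_gates(tab, gate_spec(list(gate_step("all", "x", "y"))))
  expect_equal(res$table$values, tab$values)
  expect_equal(res$report$fraction_kept, 1)
})

test_that("a constructed rectangular gate keeps exactly the inside events", {
  xy <- cbind(x = c(1.5, 1.2, 1.9, 0.5, 2.5, 3, 1.4, 1.0, 2.0, 0.9),
              y = c(0.1, 5.0, 2.0, 1.0, 1.0, -1, -0.2, 0.0, 9.0, 2.0))
  tab <- event_table(xy, transformed = TRUE)
  res <- apply_gates(tab, gate_spec(list(
    gate_step("box", "x", "y", x_range = c(1, 2), y_range = c(0, Inf)))))
  # inside: rows with x in [1,2] and y >= 0: rows 1,2,3,8,10 minus y<0 ones
  inside <- which(xy[, 1] >= 1 & xy[, 1] <= 2 & xy[, 2] >= 0)
  expect_equal(res$table$values, xy[inside, , drop = FALSE],
               ignore_attr = "dimnames")
  expect_equal(res$report$n_out, length(inside))
})

test_that("a multi-step gate chain equals the brute-force intersection and is order-independent", {
  tab <- random_table(5000, c("a", "b", "c"), seed = 9)
  steps <- list(
    gate_step("s1", "a", "b", x_range = c(0.5, 3), y_range = c(-Inf, 3.5)),
    gate_step("s2", "b", "c", x_range = c(0, Inf), y_range = c(0.2, 3.8)),
    gate_step("s3", "a", "c", x_range = c(-Inf, 2.8), y_range = c(0.5, Inf)))
  res <- apply_gates(tab, gate_spec(steps))

  v <- tab$values
  keep <- v[, "a"] >= 0.5 & v[, "a"] <= 3 & v[, "b"] <= 3.5 &
          v[, "b"] >= 0 & v[, "c"] >= 0.2 & v[, "c"] <= 3.8 &
          v[, "a"] <= 2.8 & v[, "c"] >= 0.5
  expect_equal(res$table$values, v[keep, , drop = FALSE])

  res_rev <- apply_gates(tab, gate_spec(rev(steps)))
  expect_equal(res_rev$table$values, res$table$values)

  # idempotence: re-gating the survivors changes nothing
  res2 <- apply_gates(res$table, gate_spec(steps))
  expect_equal(res2$table$values, res$table$values)
  expect_true(all(res2$report$fraction_kept == 1))
})

test_that("unknown gate markers raise a configuration error naming the marker", {
  tab <- random_table(10, c("x", "y"))
  expect_error(
    apply_gates(tab, gate_spec(list(gate_step("bad", "x", "CD99")))),
    "CD99")
})

test_that("the shipped CD4 gate template parses into a five-step chain", {
  path <- system.file("extdata", "gates_cd4_template.yaml", package = "pribin")
  gates <- read_gate_config(path)
  expect_length(gates$steps, 5)
  expect_equal(gates$steps[[5]]$x_marker, "CD4")
  expect_equal(gates$steps[[1]]$y_range[1], -Inf)
})
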