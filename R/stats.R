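#' Mann-Whitney U test for two independent groups
#'
#' Computes the U statistic from midranks and a two-sided p-value. For
#' untied data with `n_a + n_b <= 20` (or whenever `mode = "exact"`), the
#' p-value is exact over all `choose(n_a + n_b, n_a)` group labelings; with
#' ties under `mode = "exact"` the labelings are enumerated explicitly,
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Groups that are identical up to ties everywhere
#' (zero rank variance) give p = 1.
#'
#' @param a,b Numeric vectors of per-sample feature values; missing values
#'   are dropped with a warning.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return A list with elements `U` (U statistic of group `a`), `p`
#'   (two-sided p-value), `method`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (anyNA(a) || anyNA(b)) {
    warning("missing values dropped before Mann-Whitney test")
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1L || n_b < 1L) stop("both groups must be non-empty after missing-value removal")

  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  n <- n_a + n_b

  exact_ok <- !ties && n <= 20L
  use_exact <- switch(mode,
    auto = exact_ok,
    exact = TRUE,
    approx = FALSE)

  if (use_exact && !ties) {
    # exact null distribution of U for untied data (stats::pwilcox)
    lo <- stats::pwilcox(u, n_a, n_b)
    hi <- 1 - stats::pwilcox(u - 1, n_a, n_b)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else if (use_exact) {
    p <- mw_enumerate_p(c(a, b), n_a)
    method <- "exact (enumeration, ties)"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity-corrected two-sided normal approximation
      zstat <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      zstat <- max(zstat, 0)
      p <- min(1, 2 * stats::pnorm(zstat, lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  list(U = u, p = p, method = method, n_a = n_a, n_b = n_b)
}

## Exact two-sided p by explicit enumeration of all group labelings:
## P(|U - n_a n_b / 2| >= |u_obs - n_a n_b / 2|) under the permutation null.
## Used when mode = "exact" is forced on tied data.
mw_enumerate_p <- function(pooled, n_a) {
  n <- length(pooled)
  n_b <- n - n_a
  if (choose(n, n_a) > 2e6) {
    stop("exact enumeration infeasible for n = ", n, "; use mode = 'approx'")
  }
  r <- rank(pooled)
  mu <- n_a * n_b / 2
  combos <- utils::combn(n, n_a)
  u_all <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  eps <- 1e-9
  mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
}

#' Significance star coding
#'
#' Maps a p-value to the conventional star string: `****` for p <= 0.0001,
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, else `ns`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Character vector of star codes.
#' @export
star_code <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  ifelse(p <= 1e-4, "****",
    ifelse(p <= 1e-3, "***",
      ifelse(p <= 0.01, "**",
        ifelse(p <= 0.05, "*", "ns"))))
}

#' Compare two sample groups feature by feature
#'
#' For every feature column of a [build_feature_matrix()] result, compares
#' the two groups with [mann_whitney()] and reports group medians, U, the
#' unadjusted two-sided p-value and its star code. Unadjusted p-values are
#' the primary output (one test per engineered feature, as is conventional
#' for this kind of panel); a Benjamini-Hochberg adjusted column `p_adj` is
#' appended as a clearly separated extension for readers who want
#' family-wise control.
#'
#' @param features A [build_feature_matrix()] result (or any data.frame with
#'   `sample_id`, `group` and numeric feature columns).
#' @param grouping Optional named character vector `sample_id -> group`
#'   overriding the `group` column.
#' @param mode Passed to [mann_whitney()].
#' @return A data.frame with one row per feature: `feature`, `n_a`, `n_b`,
#'   `n_missing`, `median_a`, `median_b`, `U`, `p_value`, `stars`, `p_adj`,
#'   plus attributes `group_a` / `group_b` naming the groups.
#' @export
compare_groups <- function(features, grouping = NULL, mode = "auto") {
  df <- as.data.frame(features)
  if (!is.null(grouping)) {
    df$group <- unname(grouping[df$sample_id])
  }
  if (is.null(df$group)) stop("no group labels available")
  groups <- sort(unique(stats::na.omit(df$group)))
  if (length(groups) != 2L) {
    stop("exactly two groups required, got: ", paste(groups, collapse = ", "))
  }
  feat_cols <- setdiff(names(df), c("sample_id", "group"))
  feat_cols <- feat_cols[vapply(df[feat_cols], is.numeric, logical(1))]

  rows <- lapply(feat_cols, function(f) {
    va <- df[[f]][df$group == groups[1]]
    vb <- df[[f]][df$group == groups[2]]
    n_missing <- sum(is.na(va)) + sum(is.na(vb))
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) == 0 || length(vb) == 0) {
      return(data.frame(feature = f, n_a = length(va), n_b = length(vb),
                        n_missing = n_missing, median_a = NA_real_,
                        median_b = NA_real_, U = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    mw <- suppressWarnings(mann_whitney(va, vb, mode = mode))
    data.frame(feature = f, n_a = mw$n_a, n_b = mw$n_b,
               n_missing = n_missing,
               median_a = stats::median(va), median_b = stats::median(vb),
               U = mw$U, p_value = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- NA_character_
  ok <- !is.na(out$p_value)
  out$stars[ok] <- star_code(out$p_value[ok])
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "group_a") <- groups[1]
  attr(out, "group_b") <- groups[2]
  out
}
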