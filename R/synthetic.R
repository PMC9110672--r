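#' Synthetic cohort specification
#'
#' Describes a CyTOF-like cohort as a Gaussian mixture in asinh space:
#' named cell populations with proportions, per-marker means and (diagonal)
#' standard deviations, plus group-specific mean shifts planted in selected
#' (population, marker) pairs. Generated samples carry a `population` truth
#' channel so any downstream statistic can be verified per population.
#'
#' @param markers Character vector of marker labels.
#' @param populations List of populations, each a list with `name`,
#'   `proportion`, `mean` (named numeric, asinh units) and `sd` (named
#'   numeric, > 0). Proportions must sum to 1.
#' @param n_events Events per sample.
#' @param groups Named list: group label -> list of effects, each a list
#'   with `population`, `marker`, `shift` (asinh units). An empty list means
#'   no planted effect.
#' @param n_samples Samples per group.
#' @param seed Base integer seed; sample-level seeds are derived
#'   deterministically from `(seed, group, sample_index)`.
#' @param write_raw If `TRUE` (default), [generate_cohort()] back-transforms
#'   values with `sinh(v) / cofactor` before writing FCS, so files hold
#'   raw-scale intensities and the standard read - transform - gate - bin
#'   pipeline runs unmodified.
#' @param cofactor Cofactor used for the raw back-transform.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(markers, populations, n_events = 50000L,
                           groups = list(), n_samples = 6L, seed = 1L,
                           write_raw = TRUE, cofactor = 0.1) {
  props <- vapply(populations, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-8) {
    stop("population proportions must sum to 1 (got ", sum(props), ")")
  }
  pop_names <- vapply(populations, `[[`, character(1), "name")
  problems <- character(0)
  for (p in populations) {
    for (field in c("mean", "sd")) {
      missing <- setdiff(markers, names(p[[field]]))
      if (length(missing) > 0) {
        problems <- c(problems, paste0("population '", p$name, "' lacks ",
                                       field, " for: ",
                                       paste(missing, collapse = ", ")))
      }
    }
    if (any(p$sd[markers] < 0, na.rm = TRUE)) {
      problems <- c(problems, paste0("population '", p$name,
                                     "' has negative sd"))
    }
  }
  for (g in names(groups)) {
    for (eff in groups[[g]]) {
      if (!eff$population %in% pop_names) {
        problems <- c(problems, paste0("group '", g,
                                       "' effect references unknown population '",
                                       eff$population, "'"))
      }
      if (!eff$marker %in% markers) {
        problems <- c(problems, paste0("group '", g,
                                       "' effect references unknown marker '",
                                       eff$marker, "'"))
      }
    }
  }
  if (length(problems) > 0) {
    stop("invalid synthetic spec:\n  ", paste(problems, collapse = "\n  "))
  }
  structure(list(markers = markers, populations = populations,
                 n_events = as.integer(n_events), groups = groups,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 write_raw = isTRUE(write_raw), cofactor = cofactor),
            class = "synthetic_spec")
}

## Deterministic per-sample seed below 2^31, mixing base seed, group and index.
derive_seed <- function(seed, group, sample_index) {
  h <- sum(utf8ToInt(group) * seq_along(utf8ToInt(group)))
  as.integer((as.numeric(seed) * 48271 + h * 104729 +
                sample_index * 7919) %% 2147483629)
}

#' Generate one synthetic sample
#'
#' Draws `n_events` cells from the spec's Gaussian mixture in asinh space,
#' applies the group's mean shifts to the designated populations, and stores
#' the population assignment as an extra integer channel `population`
#' (1-based index into `spec$populations`). Deterministic given
#' `(spec$seed, group, sample_index)`.
#'
#' @param spec A [synthetic_spec()].
#' @param group Group label (must exist in `spec$groups`, or be any label if
#'   `spec$groups` is empty).
#' @param sample_index Integer index of the sample within its group.
#' @return A transformed [event_table()] (values already in asinh space).
#' @export
generate_sample <- function(spec, group, sample_index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  effects <- spec$groups[[group]]
  if (length(spec$groups) > 0 && is.null(effects) &&
      !group %in% names(spec$groups)) {
    stop("unknown group: ", group)
  }
  set.seed(derive_seed(spec$seed, group, sample_index))
  n <- spec$n_events
  props <- vapply(spec$populations, `[[`, numeric(1), "proportion")
  pop <- sample.int(length(spec$populations), n, replace = TRUE, prob = props)

  shift <- matrix(0, nrow = length(spec$populations),
                  ncol = length(spec$markers),
                  dimnames = list(NULL, spec$markers))
  for (eff in effects) {
    p_idx <- match(eff$population,
                   vapply(spec$populations, `[[`, character(1), "name"))
    shift[p_idx, eff$marker] <- shift[p_idx, eff$marker] + eff$shift
  }

  values <- matrix(NA_real_, nrow = n, ncol = length(spec$markers) + 1L,
                   dimnames = list(NULL, c(spec$markers, "population")))
  for (p_idx in seq_along(spec$populations)) {
    rows <- which(pop == p_idx)
    if (length(rows) == 0) next
    p <- spec$populations[[p_idx]]
    for (m in spec$markers) {
      values[rows, m] <- stats::rnorm(length(rows),
                                      mean = p$mean[[m]] + shift[p_idx, m],
                                      sd = p$sd[[m]])
    }
  }
  values[, "population"] <- pop
  event_table(values, transformed = TRUE)
}

#' Generate and write a synthetic cohort
#'
#' Writes one FCS file per sample (raw-scale via `sinh(v) / cofactor` when
#' `spec$write_raw`, asinh-scale otherwise; the truth channel is written
#' unscaled either way), a `manifest.csv` (sample_id, group, path) and the
#' spec as `spec.yaml`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest data.frame, invisibly carrying `out_dir` as an
#'   attribute.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- if (length(spec$groups) > 0) names(spec$groups) else "all"
  manifest <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(seq_len(spec$n_samples), function(i) {
      tab <- generate_sample(spec, g, i)
      if (spec$write_raw) {
        keep <- setdiff(colnames(tab$values), "population")
        tab$values[, keep] <- sinh(tab$values[, keep]) / spec$cofactor
        tab$transformed <- FALSE
      }
      sid <- sprintf("%s_blood%d", g, i)
      path <- file.path(out_dir, paste0(sid, ".fcs"))
      write_fcs(tab, path)
      data.frame(sample_id = sid, group = g, path = path,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(synthetic_spec_to_list(spec),
                   file.path(out_dir, "spec.yaml"))
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}

synthetic_spec_to_list <- function(spec) {
  list(markers = spec$markers,
       populations = lapply(spec$populations, function(p) {
         list(name = p$name, proportion = p$proportion,
              mean = as.list(p$mean), sd = as.list(p$sd))
       }),
       n_events = spec$n_events,
       groups = lapply(spec$groups, function(effs) {
         lapply(effs, function(e) e[c("population", "marker", "shift")])
       }),
       n_samples = spec$n_samples, seed = spec$seed,
       write_raw = spec$write_raw, cofactor = spec$cofactor)
}

#' Read a synthetic spec from YAML
#'
#' @param path YAML file written by [generate_cohort()] or hand-authored in
#'   the same schema.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  synthetic_spec(
    markers = unlist(cfg$markers),
    populations = lapply(cfg$populations, function(p) {
      list(name = p$name, proportion = p$proportion,
           mean = unlist(p$mean), sd = unlist(p$sd))
    }),
    n_events = cfg$n_events, groups = cfg$groups,
    n_samples = cfg$n_samples, seed = cfg$seed,
    write_raw = cfg$write_raw, cofactor = cfg$cofactor)
}

#' Default CD4 T-cell cohort specification
#'
#' A two-group cohort (ineffective vs effective treatment, 6 samples each,
#' 50,000 events per sample) over a 9-marker CD4 T-helper panel, built from
#' four populations in asinh(0.1 x) space:
#'
#' * `naive` (45%): CD44-low, CD90 intermediate, CD27-positive, resting.
#' * `memory` (35%): CD44+, CD90-high.
#' * `activated` (15%): CD44+ CD90-high with elevated Ki67 and Tbet -- the
#'   treatment-responsive population.
#' * `treg` (5%): Foxp3-high regulatory cells.
#'
#' The effective-treatment group plants a +0.8 asinh CD86 shift and a
#' +0.5 asinh Ki67 shift in the `activated` population; every other marker
#' is null with respect to group, giving known positives and negatives for
#' downstream power checks.
#'
#' @param n_events Events per sample (default 50,000).
#' @param n_samples Samples per group (default 6).
#' @param seed Base seed.
#' @return A [synthetic_spec()].
#' @export
default_synthetic_spec <- function(n_events = 50000L, n_samples = 6L,
                                   seed = 1L) {
  markers <- c("CD90", "CD44", "CD86", "CD27", "Ki67", "Tbet", "Foxp3",
               "KLRG1", "PDL1")
  sd_all <- function(x) stats::setNames(rep(x, length(markers)), markers)
  pop <- function(name, proportion, ...) {
    m <- c(...)
    list(name = name, proportion = proportion, mean = m[markers],
         sd = sd_all(0.35))
  }
  populations <- list(
    pop("naive", 0.45, CD90 = 2.2, CD44 = 0.8, CD86 = 0.6, CD27 = 2.0,
        Ki67 = 0.5, Tbet = 0.5, Foxp3 = 0.4, KLRG1 = 0.4, PDL1 = 0.5),
    pop("memory", 0.35, CD90 = 3.0, CD44 = 2.6, CD86 = 1.0, CD27 = 1.6,
        Ki67 = 0.8, Tbet = 1.2, Foxp3 = 0.5, KLRG1 = 0.8, PDL1 = 0.8),
    pop("activated", 0.15, CD90 = 3.4, CD44 = 3.0, CD86 = 1.4, CD27 = 1.0,
        Ki67 = 2.0, Tbet = 2.2, Foxp3 = 0.6, KLRG1 = 1.2, PDL1 = 1.2),
    pop("treg", 0.05, CD90 = 2.8, CD44 = 2.4, CD86 = 0.9, CD27 = 1.8,
        Ki67 = 1.4, Tbet = 0.6, Foxp3 = 2.4, KLRG1 = 0.6, PDL1 = 1.0)
  )
  groups <- list(
    ineffective = list(),
    effective = list(
      list(population = "activated", marker = "CD86", shift = 0.8),
      list(population = "activated", marker = "Ki67", shift = 0.5)
    )
  )
  synthetic_spec(markers, populations, n_events = n_events, groups = groups,
                 n_samples = n_samples, seed = seed)
}
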