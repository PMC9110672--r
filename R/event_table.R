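#' Construct an event table
#'
#' The central container of the package: a numeric matrix of cytometry events
#' (rows) by channels (columns) together with a channel-to-marker map and a
#' flag recording whether intensities are on the raw or arcsinh scale.
#'
#' @param values Numeric matrix, `n_events x n_channels`.
#' @param channels Character vector of channel identifiers (detector names,
#'   `$PnN` in FCS terms). Defaults to `colnames(values)`.
#' @param markers Named character vector mapping channel identifiers to
#'   marker labels (`$PnS`). Unnamed entries default to the channel itself.
#'   Marker labels must be unique so that lookup by marker is unambiguous.
#' @param transformed Logical flag; `TRUE` only for tables produced by
#'   [apply_transform()] (or generated directly in asinh space).
#'
#' @return An object of class `event_table`.
#' @seealso [read_fcs()], [apply_transform()], [apply_gates()]
#' @export
event_table <- function(values, channels = colnames(values), markers = NULL,
                        transformed = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("event values must be numeric")
  if (is.null(channels)) channels <- paste0("Ch", seq_len(ncol(values)))
  channels <- as.character(channels)
  if (length(channels) != ncol(values)) {
    stop("length(channels) must equal ncol(values)")
  }
  if (anyDuplicated(channels)) stop("channel identifiers must be unique")
  if (is.null(markers)) {
    markers <- stats::setNames(channels, channels)
  } else {
    markers <- stats::setNames(as.character(markers), names(markers))
    missing <- setdiff(channels, names(markers))
    markers <- c(markers, stats::setNames(missing, missing))
    markers <- markers[channels]
  }
  if (anyDuplicated(markers)) {
    stop("marker labels must be unique after mapping: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  colnames(values) <- channels
  structure(
    list(values = values, channels = channels, markers = markers,
         transformed = isTRUE(transformed)),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d events x %d channels (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "transformed asinh" else "raw"))
  shown <- utils::head(x$markers, 10)
  cat("  markers:", paste(shown, collapse = ", "),
      if (length(x$markers) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

n_events <- function(table) nrow(table$values)

#' Resolve a marker label to its channel column
#'
#' Lookup works on marker labels first, then falls back to channel
#' identifiers, so gates and bin configurations can be written in terms of
#' whichever is convenient.
#'
#' @param table An `event_table`.
#' @param marker Single marker label or channel identifier.
#' @return Integer column index into `table$values`.
#' @export
marker_column <- function(table, marker) {
  stopifnot(inherits(table, "event_table"), length(marker) == 1L)
  hit <- which(table$markers == marker)
  if (length(hit) == 0L) hit <- which(table$channels == marker)
  if (length(hit) != 1L) {
    stop("marker not found in event table: ", marker, call. = FALSE)
  }
  hit
}

#' Extract one marker's intensity vector
#'
#' @inheritParams marker_column
#' @return Numeric vector of length `n_events`.
#' @export
marker_values <- function(table, marker) {
  table$values[, marker_column(table, marker)]
}

subset_events <- function(table, keep) {
  table$values <- table$values[keep, , drop = FALSE]
  table
}
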