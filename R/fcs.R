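## FCS 3.0/3.1 binary IO.
##
## List-mode files only. Reading supports $DATATYPE F (float32), D (double)
## and I (uniform-width unsigned integers); writing emits FCS 3.1, list mode,
## float32, little-endian ($BYTEORD 1,2,3,4) -- the dominant modern dialect.
## Offsets in the 58-byte header and in $BEGINDATA/$ENDDATA are 0-based and
## inclusive, per the standard.

FCS_DELIM <- "/"

## Split a TEXT segment on its delimiter, honouring the standard's
## escaped-delimiter convention (a doubled delimiter inside a value).
fcs_split_text <- function(body, delim) {
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(parts)) {
    tok <- parts[i]
    # an empty part between two others is a doubled (escaped) delimiter
    while (i + 2L <= length(parts) && parts[i + 1L] == "") {
      tok <- paste0(tok, delim, parts[i + 2L])
      i <- i + 2L
    }
    out <- c(out, tok)
    i <- i + 1L
  }
  out
}

fcs_keyword <- function(kw, name, default = NULL) {
  hit <- kw[[toupper(name)]]
  if (is.null(hit)) default else hit
}

#' Read an FCS file
#'
#' Parses the 58-byte header, the TEXT segment and the DATA segment of an
#' FCS 3.0/3.1 list-mode file and returns the event matrix together with the
#' channel names (`$PnN`) and marker labels (`$PnS`).
#'
#' @param path Path to an FCS file.
#' @return An [event_table()] with `transformed = FALSE`. The full keyword
#'   list is attached as attribute `"keywords"`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("FCS file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58L || substr(header, 1, 4) != "FCS3") {
    stop("not an FCS 3.x file (bad header): ", path)
  }
  offs <- vapply(seq_len(6L), function(i) {
    field <- substr(header, 11 + (i - 1) * 8, 10 + i * 8)
    v <- suppressWarnings(as.numeric(trimws(field)))
    if (is.na(v)) stop("malformed FCS header offset field ", i, " in ", path)
    v
  }, numeric(1))

  seek(con, offs[1])
  text_raw <- readBin(con, "raw", n = offs[2] - offs[1] + 1)
  text <- rawToChar(text_raw)
  Encoding(text) <- "latin1"
  delim <- substr(text, 1, 1)
  toks <- fcs_split_text(substring(text, 2), delim)
  if (length(toks) %% 2L == 1L) toks <- toks[-length(toks)]
  kw <- stats::setNames(as.list(toks[seq_along(toks) %% 2L == 0L]),
                        toupper(toks[seq_along(toks) %% 2L == 1L]))

  n_par <- as.integer(fcs_keyword(kw, "$PAR"))
  n_tot <- as.integer(fcs_keyword(kw, "$TOT"))
  dtype <- fcs_keyword(kw, "$DATATYPE", "F")
  byteord <- fcs_keyword(kw, "$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (is.na(n_par) || n_par < 1L) stop("missing or invalid $PAR keyword in ", path)
  if (is.na(n_tot) || n_tot < 0L) stop("missing or invalid $TOT keyword in ", path)

  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(fcs_keyword(kw, paste0("$P", i, "B"), "32"))
  }, integer(1))
  channels <- vapply(seq_len(n_par), function(i) {
    v <- fcs_keyword(kw, paste0("$P", i, "N"))
    if (is.null(v)) paste0("P", i) else v
  }, character(1))
  labels <- vapply(seq_len(n_par), function(i) {
    v <- fcs_keyword(kw, paste0("$P", i, "S"))
    if (is.null(v) || v == "") channels[i] else v
  }, character(1))

  data_beg <- as.numeric(fcs_keyword(kw, "$BEGINDATA", "0"))
  data_end <- as.numeric(fcs_keyword(kw, "$ENDDATA", "0"))
  if (data_beg <= 0) { data_beg <- offs[3]; data_end <- offs[4] }

  if (n_tot == 0L) {
    values <- matrix(numeric(0), nrow = 0, ncol = n_par)
  } else {
    bytes_per_event <- sum(bits) / 8
    expect <- n_tot * bytes_per_event
    avail <- data_end - data_beg + 1
    if (!isTRUE(all.equal(expect, avail))) {
      stop(sprintf(
        "inconsistent FCS data segment in %s: $TOT=%d with %d-bit channels implies %.0f bytes but segment holds %.0f",
        path, n_tot, bits[1], expect, avail))
    }
    seek(con, data_beg)
    n_vals <- n_tot * n_par
    vals <- switch(dtype,
      "F" = readBin(con, "numeric", n = n_vals, size = 4L, endian = endian),
      "D" = readBin(con, "numeric", n = n_vals, size = 8L, endian = endian),
      "I" = {
        if (length(unique(bits)) != 1L) {
          stop("integer FCS data with mixed $PnB widths is not supported: ", path)
        }
        sz <- bits[1] / 8
        as.numeric(readBin(con, "integer", n = n_vals, size = sz,
                           signed = sz > 2, endian = endian))
      },
      stop("unsupported $DATATYPE '", dtype, "' in ", path)
    )
    if (length(vals) < n_vals) {
      stop("truncated FCS data segment in ", path, " ($TOT=", n_tot, ")")
    }
    values <- matrix(vals, ncol = n_par, byrow = TRUE)
  }

  tab <- event_table(values, channels = channels,
                     markers = stats::setNames(labels, channels),
                     transformed = FALSE)
  attr(tab, "keywords") <- kw
  tab
}

#' Write an event table as an FCS 3.1 file
#'
#' Emits a list-mode, float32, little-endian FCS 3.1 file. Values therefore
#' round-trip at float32 precision. Marker labels are stored as `$PnS` and
#' channel identifiers as `$PnN`.
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  p <- ncol(table$values)
  n <- nrow(table$values)
  if (p < 1L) stop("cannot write an FCS file with no channels")

  rng <- function(i) {
    v <- table$values[, i]
    if (length(v) == 0 || !any(is.finite(v))) return("262144")
    format(max(1, ceiling(max(v[is.finite(v)])) + 1), scientific = FALSE)
  }
  kws <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = format(n, scientific = FALSE),
    "$PAR" = format(p, scientific = FALSE)
  )
  for (i in seq_len(p)) {
    ch <- table$channels[i]
    kws[[paste0("$P", i, "N")]] <- ch
    kws[[paste0("$P", i, "S")]] <- unname(table$markers[[ch]])
    kws[[paste0("$P", i, "B")]] <- "32"
    kws[[paste0("$P", i, "E")]] <- "0,0"
    kws[[paste0("$P", i, "R")]] <- rng(i)
  }
  if (any(grepl(FCS_DELIM, c(names(kws), unlist(kws)), fixed = TRUE))) {
    stop("keyword or value contains the TEXT delimiter '", FCS_DELIM, "'")
  }

  data_bytes <- 4 * n * p
  text_begin <- 58L
  # $BEGINDATA/$ENDDATA live inside TEXT, whose length depends on their digit
  # count; iterate until the layout is stable (converges in <= 3 rounds).
  beg_s <- "0"; end_s <- "0"
  for (iter in 1:5) {
    full <- c(kws, "$BEGINDATA" = beg_s, "$ENDDATA" = end_s)
    text <- paste0(FCS_DELIM,
                   paste0(names(full), FCS_DELIM, unlist(full), FCS_DELIM,
                          collapse = ""))
    text_end <- text_begin + nchar(text, type = "bytes") - 1L
    data_begin <- if (n > 0) text_end + 1L else 0L
    data_end <- if (n > 0) data_begin + data_bytes - 1L else 0L
    nb <- format(data_begin, scientific = FALSE)
    ne <- format(data_end, scientific = FALSE)
    if (identical(nb, beg_s) && identical(ne, end_s)) break
    beg_s <- nb; end_s <- ne
  }

  hdr_off <- function(x) {
    s <- format(x, scientific = FALSE)
    if (nchar(s) > 8) s <- "0"  # too large for the header; TEXT carries it
    formatC(s, width = 8)
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_begin), hdr_off(text_end),
                   hdr_off(if (n > 0) data_begin else 0),
                   hdr_off(if (n > 0) data_end else 0),
                   hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n > 0) {
    writeBin(as.numeric(t(table$values)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
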