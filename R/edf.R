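# Minimal EDF/EDF+ reader and writer (16-bit integer samples, ASCII
# headers).  Supports continuous multichannel recordings with one
# data-record duration, optional channel subsetting on read, and an
# optional EDF+ annotations channel (time-stamped annotation lists) for
# trial onsets/labels.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)   # left-justified, space padded
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

# shortest "g"-format representation fitting the 8-char physical-range field;
# the parsed-back value of this string is used for scaling, so reads invert
# writes exactly
.edf_phys <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8L) return(s)
  }
  formatC(x, format = "e", digits = 1)
}

#' Write a multichannel signal as an EDF(+) file
#'
#' Samples are stored as 16-bit integers with per-channel linear scaling
#' covering the observed amplitude range, in 1-second data records (the
#' signal is zero-padded to a whole number of records).  If `annotations`
#' are given, an EDF+ annotations channel is appended and the file is marked
#' `EDF+C`.
#'
#' @param path output file path.
#' @param X channels x samples numeric matrix (physical units, e.g.
#'   microvolts).
#' @param rate sampling rate in Hz (integer).
#' @param channels channel labels (default: rownames or CH1..CHn).
#' @param annotations optional data frame with columns `onset_s`,
#'   `duration_s`, `label`.
#' @return invisibly, the quantized signal actually stored (channels x
#'   samples, physical units) -- reading the file back returns exactly this.
#' @export
write_edf <- function(path, X, rate, channels = NULL, annotations = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  if (is.null(channels)) channels <- rownames(X)
  if (is.null(channels)) channels <- paste0("CH", seq_len(n))
  rate <- as.integer(rate)
  n_rec <- ceiling(ncol(X) / rate)
  Np <- n_rec * rate
  if (Np > ncol(X)) X <- cbind(X, matrix(0, n, Np - ncol(X)))

  pmin_ <- apply(X, 1L, min); pmax_ <- apply(X, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # widen by 0.1% so the 8-char header strings still bracket the data, and
  # use the parsed-back string values for scaling (exact read inversion)
  rng <- pmax_ - pmin_
  pmin_s <- vapply(pmin_ - 0.001 * rng, .edf_phys, character(1))
  pmax_s <- vapply(pmax_ + 0.001 * rng, .edf_phys, character(1))
  pmin_ <- as.numeric(pmin_s)
  pmax_ <- as.numeric(pmax_s)
  dmin <- -32768L; dmax <- 32767L
  dig <- matrix(0L, n, Np)
  for (c in seq_len(n))
    dig[c, ] <- pmin(dmax, pmax(dmin, as.integer(round(
      (X[c, ] - pmin_[c]) / (pmax_[c] - pmin_[c]) * (dmax - dmin) + dmin))))

  has_ann <- !is.null(annotations) && nrow(annotations) > 0L
  # annotation channel: time-stamped annotation lists (TALs) per record,
  # built as raw vectors (the TAL framing uses NUL bytes)
  ann_rec <- NULL
  ann_samples <- 0L
  if (has_ann) {
    tal <- function(onset, dur, lab)
      c(charToRaw(sprintf("%+g", onset)), as.raw(0x15),
        charToRaw(sprintf("%g", dur)), as.raw(0x14),
        charToRaw(lab), as.raw(0x14), as.raw(0))
    recs <- lapply(seq_len(n_rec) - 1L, function(r) {
      hdr <- c(charToRaw(sprintf("%+d", r)), as.raw(c(0x14, 0x14, 0)))
      sel <- which(annotations$onset_s >= r & annotations$onset_s < r + 1)
      body <- if (length(sel))
        unlist(lapply(sel, function(i)
          tal(annotations$onset_s[i], annotations$duration_s[i],
              as.character(annotations$label[i]))))
      else raw(0)
      c(hdr, body)
    })
    max_bytes <- max(vapply(recs, length, integer(1)))
    ann_samples <- as.integer(ceiling(max_bytes / 2))   # 2 bytes per "sample"
    ann_rec <- lapply(recs, function(r) c(r, raw(2L * ann_samples - length(r))))
  }

  ns_total <- n + as.integer(has_ann)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x) writeChar(x, con, eos = NULL)
  wr(.edf_pad("0", 8))                                  # version
  wr(.edf_pad("X X X X", 80))                           # patient id
  wr(.edf_pad(if (has_ann) "Startdate X X X X" else "X", 80))  # recording id
  wr(.edf_pad("01.01.00", 8)); wr(.edf_pad("00.00.00", 8))
  wr(.edf_num(256L * (1L + ns_total), 8))               # header bytes
  wr(.edf_pad(if (has_ann) "EDF+C" else "", 44))
  wr(.edf_num(n_rec, 8))
  wr(.edf_num(1L, 8))                                   # record duration (s)
  wr(.edf_num(ns_total, 4))
  lab <- c(channels, if (has_ann) "EDF Annotations")
  for (l in lab) wr(.edf_pad(l, 16))
  for (i in seq_len(ns_total)) wr(.edf_pad("", 80))     # transducer
  wr(paste(vapply(seq_len(ns_total), function(i)
    .edf_pad(if (i <= n) "uV" else "", 8), character(1)), collapse = ""))
  for (i in seq_len(ns_total))
    wr(.edf_pad(if (i <= n) pmin_s[i] else "-1", 8))
  for (i in seq_len(ns_total))
    wr(.edf_pad(if (i <= n) pmax_s[i] else "1", 8))
  for (i in seq_len(ns_total)) wr(.edf_num(dmin, 8))
  for (i in seq_len(ns_total)) wr(.edf_num(dmax, 8))
  for (i in seq_len(ns_total)) wr(.edf_pad("", 80))     # prefiltering
  for (i in seq_len(ns_total))
    wr(.edf_num(if (i <= n) rate else ann_samples, 8))
  for (i in seq_len(ns_total)) wr(.edf_pad("", 32))     # reserved

  # the stored physical values, for exact round-trip comparison
  stored <- matrix(0, n, Np)
  for (c in seq_len(n))
    stored[c, ] <- dig[c, ] * (pmax_[c] - pmin_[c]) / (dmax - dmin) +
      pmin_[c] - dmin * (pmax_[c] - pmin_[c]) / (dmax - dmin)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (c in seq_len(n))
      writeBin(dig[c, idx], con, size = 2L, endian = "little")
    if (has_ann) writeBin(ann_rec[[r]], con)
  }
  rownames(stored) <- channels
  invisible(stored)
}

#' Read an EDF(+) file
#'
#' Parses the fixed-width ASCII header, decodes 16-bit samples back to
#' physical units, and (for EDF+) parses time-stamped annotation lists into
#' an event table.
#'
#' @param path EDF file path.
#' @param channels optional character vector selecting (and ordering) a
#'   channel subset; an error names any requested channel that is absent.
#' @return list with `signal` (channels x samples, physical units), `rate`,
#'   `channels`, and `annotations` (data frame `onset_s`, `duration_s`,
#'   `label`, or `NULL`).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    trimws(out)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  data <- vector("list", ns)
  for (i in sig_idx) data[[i]] <- matrix(0L, nsamp[i], n_rec)
  ann_raw <- list()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw[[length(ann_raw) + 1L]] <- readBin(con, "raw", 2L * nsamp[i])
      } else {
        data[[i]][, r] <- readBin(con, "integer", nsamp[i], size = 2L,
                                  signed = TRUE, endian = "little")
      }
    }
  }
  sig_labels <- labels[sig_idx]
  X <- matrix(0, length(sig_idx), sum(nsamp[sig_idx[1L]] * n_rec))
  for (k in seq_along(sig_idx)) {
    i <- sig_idx[k]
    X[k, ] <- as.vector(data[[i]]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
      pmin_[i] - dmin[i] * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
  }
  rownames(X) <- sig_labels
  rate <- nsamp[sig_idx[1L]] / rec_dur

  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, sig_labels)
    if (length(missing_ch))
      stop("channel(s) not in file: ", paste(missing_ch, collapse = ", "),
           call. = FALSE)
    X <- X[channels, , drop = FALSE]
    sig_labels <- channels
  }

  annotations <- NULL
  if (length(ann_raw)) {
    bytes <- unlist(ann_raw)
    # TALs are NUL-delimited; fields inside use 0x14 (text) and 0x15 (duration)
    splits <- which(bytes == as.raw(0))
    starts <- c(1L, splits + 1L)
    ends <- c(splits - 1L, length(bytes))
    ev <- list()
    for (k in seq_along(starts)) {
      if (starts[k] > ends[k]) next
      seg <- bytes[starts[k]:ends[k]]
      tl <- rawToChar(seg)
      parts <- strsplit(tl, "\x14", useBytes = TRUE)[[1L]]
      if (length(parts) < 2L || !nzchar(parts[2L])) next  # record timestamp TAL
      od <- strsplit(parts[1L], "\x15", useBytes = TRUE)[[1L]]
      ev[[length(ev) + 1L]] <- data.frame(
        onset_s = as.numeric(od[1L]),
        duration_s = if (length(od) > 1L) as.numeric(od[2L]) else 0,
        label = parts[2L])
    }
    if (length(ev)) annotations <- do.call(rbind, ev)
  }
  list(signal = X, rate = rate, channels = sig_labels, annotations = annotations)
}
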