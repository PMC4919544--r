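# ChIP-nexus preprocessing: barcode stripping before alignment and
# barcode-aware duplicate removal after alignment.
#
# Nexus adapters put a 6 bp random barcode followed by a 4 bp fixed barcode
# at the 5' end of every read.  The random barcode distinguishes true
# re-occurrences of a stop site from PCR duplicates; the fixed barcode is a
# ligation check.

#' Read / write FASTQ as a plain data.frame
#'
#' Minimal four-line-record FASTQ I/O.  `write_fastq` emits `@read_id`,
#' sequence, `+`, quality; barcodes stripped by [strip_barcodes()] travel in
#' the read id after a `:` separator (the package's documented dialect).
#'
#' @param file path to an uncompressed FASTQ file.
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @return `read_fastq` returns a data.frame with `read_id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(file) {
  lines <- readLines(file)
  if (length(lines) %% 4L != 0L) cq_stop("FASTQ record count not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n)
  data.frame(read_id = sub("^@", "", lines[4L * idx - 3L]),
             sequence = lines[4L * idx - 2L],
             quality = lines[4L * idx],
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, file) {
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    idx <- seq_len(nrow(reads))
    out[4L * idx - 3L] <- paste0("@", reads$read_id)
    out[4L * idx - 2L] <- reads$sequence
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- reads$quality
  }
  writeLines(out, file)
  invisible(file)
}

#' Strip random and fixed barcodes from raw nexus reads
#'
#' Removes the leading 6 bp random barcode and the following 4 bp fixed
#' barcode from each read (sequence and quality).  The random barcode is
#' appended to the read id after a `:`.  Reads whose fixed barcode does not
#' match `expected_fixed` exactly, or that are too short to contain both
#' barcodes plus at least one insert base, are rejected and counted.
#'
#' @param reads FASTQ data.frame from [read_fastq()].
#' @param expected_fixed the 4-base fixed barcode (default `"CTGA"`).
#' @param random_len length of the random barcode (6).
#' @return list with `reads` (kept reads: `read_id`, `sequence`, `quality`,
#'   `random_barcode`, `fixed_barcode`) and `rejected` (data.frame of
#'   `reason`, `count` for `too_short` and `fixed_mismatch`).
#' @export
strip_barcodes <- function(reads, expected_fixed = "CTGA", random_len = 6L) {
  if (!is.character(expected_fixed) || length(expected_fixed) != 1L ||
      nchar(expected_fixed) != 4L ||
      !grepl("^[ACGT]+$", expected_fixed)) {
    cq_stop("expected_fixed must be a 4-base string over A/C/G/T")
  }
  random_len <- as.integer(random_len)
  prefix <- random_len + nchar(expected_fixed)
  len <- nchar(reads$sequence)
  too_short <- len <= prefix
  fixed <- substr(reads$sequence, random_len + 1L, prefix)
  mismatch <- !too_short & fixed != expected_fixed
  keep <- !too_short & !mismatch
  kept <- reads[keep, , drop = FALSE]
  random_bc <- substr(kept$sequence, 1L, random_len)
  out <- data.frame(
    read_id = paste(kept$read_id, random_bc, sep = ":"),
    sequence = substr(kept$sequence, prefix + 1L, nchar(kept$sequence)),
    quality = substr(kept$quality, prefix + 1L, nchar(kept$quality)),
    random_barcode = random_bc,
    fixed_barcode = substr(kept$sequence, random_len + 1L, prefix),
    stringsAsFactors = FALSE
  )
  list(reads = out,
       rejected = data.frame(reason = c("too_short", "fixed_mismatch"),
                             count = c(sum(too_short), sum(mismatch)),
                             stringsAsFactors = FALSE))
}

#' Barcode-aware duplicate removal
#'
#' Aligned nexus reads sharing a 5' coordinate are genuine duplicates only
#' if they also share the random barcode.  Within each
#' (chrom, strand, 5' position) group, reads with an identical barcode are
#' collapsed to the best alignment — highest mapq, ties broken by the
#' lexicographically smallest read id — while reads with distinct barcodes
#' are all retained.
#'
#' @param records alignment record data.frame with `chrom`, `start`,
#'   `strand`, `mapq`, `barcode`, `read_id`.
#' @return list with `records` (survivors, in input order) and `report`
#'   (data.frame with `reason` = `"duplicate_barcode"` and `count`).
#' @export
barcode_dedup <- function(records) {
  if (!"barcode" %in% names(records) || anyNA(records$barcode) ||
      any(records$barcode == "")) {
    bad <- if (!"barcode" %in% names(records)) "all" else {
      i <- which(is.na(records$barcode) | records$barcode == "")[1]
      if ("read_id" %in% names(records)) records$read_id[i] else sprintf("row %d", i)
    }
    cq_stop("record(s) without a random barcode (first: %s)", bad)
  }
  if (!"read_id" %in% names(records)) {
    records$read_id <- sprintf("read%06d", seq_len(nrow(records)))
  }
  dt <- data.table::as.data.table(records)
  dt[, .orig_order := .I]
  data.table::setorder(dt, chrom, strand, start, barcode, -mapq, read_id)
  keep <- !duplicated(dt[, list(chrom, strand, start, barcode)])
  removed <- sum(!keep)
  out <- dt[keep]
  data.table::setorder(out, .orig_order)
  out[, .orig_order := NULL]
  list(records = as.data.frame(out),
       report = data.frame(reason = "duplicate_barcode", count = removed,
                           stringsAsFactors = FALSE))
}
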