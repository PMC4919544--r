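# Plain-text I/O: bedGraph coverage tracks and the package's BED-derived
# alignment dialect (0-based half-open throughout).

#' Write / read a coverage track as 4-column bedGraph
#'
#' Runs of equal value are merged into intervals (chrom, start, end, value;
#' 0-based half-open).  Reading expands intervals back to a per-base track
#' (`bin_size = 1`); normalization state and read totals are not stored in
#' the format and must be supplied on read.
#'
#' @param track a [coverage_track()].
#' @param file path.
#' @param chrom_sizes named integer vector (read side).
#' @param normalization,total_reads metadata to attach on read.
#' @return `read_bedgraph` returns a [coverage_track()].
#' @export
write_bedgraph <- function(track, file) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    len <- track$chrom_sizes[[chrom]]
    data.table::data.table(chrom = chrom,
                           start = starts_bin * track$bin_size,
                           end = pmin(ends_bin * track$bin_size, len),
                           value = r$values)
  })
  dt <- data.table::rbindlist(pieces)
  dt <- dt[dt$value != 0, ]
  data.table::fwrite(dt, file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(file, chrom_sizes, normalization = "raw",
                          total_reads = 0L) {
  values <- lapply(names(chrom_sizes), function(chrom) numeric(chrom_sizes[[chrom]]))
  names(values) <- names(chrom_sizes)
  if (file.size(file) > 0) {
    dt <- data.table::fread(file, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"))
    df <- as.data.frame(dt)
    for (ch in unique(df$chrom)) {
      if (!ch %in% names(chrom_sizes)) {
        cq_stop("bedGraph chromosome '%s' not in chrom_sizes", ch)
      }
      sub <- df[df$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(sub))) {
        values[[ch]][(sub$start[r] + 1L):sub$end[r]] <- sub$value[r]
      }
    }
  }
  coverage_track(values, chrom_sizes, bin_size = 1L,
                 normalization = normalization, total_reads = total_reads)
}

#' Write / read alignment records in the package's BED dialect
#'
#' Columns 1-6 are chrom, start, end (start + 1: records locate the 5'
#' base), read_id, mapq, strand; optional `species` and `barcode` columns
#' follow as columns 7-8 (`.` when absent).
#'
#' @param records alignment record data.frame.
#' @param file path.
#' @return `read_alignments` returns an alignment record data.frame.
#' @export
write_alignments <- function(records, file) {
  dt <- data.table::data.table(
    chrom = records$chrom, start = records$start, end = records$start + 1L,
    read_id = records$read_id %||% sprintf("read%06d", seq_len(nrow(records))),
    mapq = records$mapq %||% 60L,
    strand = records$strand,
    species = records$species %||% ".",
    barcode = records$barcode %||% ".")
  data.table::fwrite(dt, file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(file) {
  dt <- data.table::fread(file, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "read_id",
                                        "mapq", "strand", "species", "barcode"))
  out <- data.frame(chrom = dt$chrom, start = dt$start, strand = dt$strand,
                    mapq = dt$mapq, read_id = dt$read_id,
                    stringsAsFactors = FALSE)
  if (any(dt$species != ".")) out$species <- dt$species
  if (any(dt$barcode != ".")) out$barcode <- dt$barcode
  out
}
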