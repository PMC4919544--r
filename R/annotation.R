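#' @importFrom stats cor dnbinom kmeans p.adjust pf phyper ppois pnorm pt
#'   qnorm rbinom rmultinom rnbinom runif rnorm sd setNames var quantile
#'   rgamma median ks.test punif
#' @importFrom utils head tail
#' @import data.table
NULL

# Five transcription-rate classes (mRNA/h) used to bin yeast genes by
# transcriptional frequency.
RATE_CLASSES <- c("<1", "1-3.9", "4-15.9", "16-50", ">50")

#' Validate a gene annotation table
#'
#' The annotation is an ordinary data.frame with one row per gene and the
#' columns `gene_id`, `chrom`, `start`, `end` (0-based, half-open), `strand`
#' (`"+"`/`"-"`) and optionally `rate_class` (one of `"<1"`, `"1-3.9"`,
#' `"4-15.9"`, `"16-50"`, `">50"` mRNA/h).
#'
#' @param annotation data.frame as described above.
#' @return the annotation, invisibly, after validation.
#' @export
validate_annotation <- function(annotation) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) cq_stop("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$gene_id)) cq_stop("gene_ids must be unique")
  if (any(annotation$start >= annotation$end)) cq_stop("every gene must have start < end")
  if (any(annotation$start < 0)) cq_stop("coordinates must be non-negative")
  if (!all(annotation$strand %in% c("+", "-"))) cq_stop("strand must be '+' or '-'")
  if ("rate_class" %in% names(annotation)) {
    rc <- annotation$rate_class
    bad <- !is.na(rc) & !(rc %in% RATE_CLASSES)
    if (any(bad)) {
      cq_stop("invalid rate_class value(s): %s",
              paste(unique(rc[bad]), collapse = ", "))
    }
  }
  invisible(annotation)
}

#' Transcription start sites of annotated genes
#'
#' With 0-based half-open gene intervals the TSS is `start` for `+` strand
#' genes and `end - 1` for `-` strand genes.
#'
#' @param annotation gene annotation data.frame.
#' @return integer vector of 0-based TSS positions, named by gene_id.
#' @export
tss_positions <- function(annotation) {
  validate_annotation(annotation)
  pos <- ifelse(annotation$strand == "+", annotation$start, annotation$end - 1L)
  setNames(as.integer(pos), annotation$gene_id)
}

#' Generate a toy single-chromosome genome annotation
#'
#' Places `n_genes` non-overlapping genes on one chromosome with at least
#' `min_gap` bases between consecutive gene bodies, random strands (both
#' strands represented whenever `n_genes >= 2`) and a transcription-rate
#' class drawn for each gene.  Gene lengths are drawn uniformly from
#' `gene_length` (default 500-2000 bp, around the yeast median of ~1.4 kb).
#'
#' @param n_genes number of genes (>= 0).
#' @param chrom_length chromosome length in bp.
#' @param min_gap minimum intergenic gap in bp (also enforced at the
#'   chromosome ends).
#' @param seed integer RNG seed; output is byte-identical for a fixed seed.
#' @param gene_length length-2 numeric range for gene lengths.
#' @param chrom chromosome name.
#' @return list with `annotation` (data.frame, see
#'   [validate_annotation()]) and `chrom_sizes` (named integer vector).
#' @examples
#' g <- make_toy_genome(20, 60000, min_gap = 300, seed = 1)
#' head(g$annotation)
#' @export
make_toy_genome <- function(n_genes, chrom_length, min_gap = 200, seed = 1,
                            gene_length = c(500, 2000), chrom = "chrS") {
  check_scalar_number(n_genes, "n_genes", lower = 0)
  check_scalar_number(chrom_length, "chrom_length", lower = 1)
  check_scalar_number(min_gap, "min_gap", lower = 0)
  n_genes <- as.integer(n_genes)
  sizes <- setNames(as.integer(chrom_length), chrom)
  if (n_genes == 0L) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), rate_class = character(),
                      stringsAsFactors = FALSE)
    return(list(annotation = ann, chrom_sizes = sizes))
  }
  with_seed(seed, {
    lens <- as.integer(round(runif(n_genes, gene_length[1], gene_length[2])))
    need <- sum(lens) + (n_genes + 1L) * as.integer(min_gap)
    if (need > chrom_length) {
      cq_stop(paste0("cannot place %d genes (total %d bp incl. gaps) on a ",
                     "%d bp chromosome; increase chrom_length or reduce ",
                     "n_genes/min_gap"), n_genes, need, as.integer(chrom_length))
    }
    # distribute the leftover space over the n_genes + 1 gaps at random
    slack <- as.integer(chrom_length) - need
    extra <- if (slack > 0) {
      as.vector(rmultinom(1, slack, rep(1, n_genes + 1L)))
    } else rep(0L, n_genes + 1L)
    gaps <- as.integer(min_gap) + extra
    starts <- integer(n_genes)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (n_genes >= 2L && length(unique(strand)) == 1L) {
      strand[n_genes] <- setdiff(c("+", "-"), strand[1])
    }
    # rough yeast-like mix: most genes transcribed at 1-16 mRNA/h
    rate_class <- sample(RATE_CLASSES, n_genes, replace = TRUE,
                         prob = c(0.15, 0.35, 0.35, 0.12, 0.03))
    ann <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom,
      start = starts,
      end = starts + lens,
      strand = strand,
      rate_class = rate_class,
      stringsAsFactors = FALSE
    )
    validate_annotation(ann)
    list(annotation = ann, chrom_sizes = sizes)
  })
}

#' Read/write the annotation as 6-column BED plus a rate-class sidecar
#'
#' BED columns are chrom, start, end, name, score (0), strand with 0-based
#' half-open coordinates.  `rate_class`, when present, is written to
#' `<file>.rates.tsv` with columns `gene_id` and `rate_class`.
#'
#' @param annotation gene annotation data.frame.
#' @param file path of the BED file.
#' @return `read_annotation_bed` returns the annotation data.frame.
#' @export
write_annotation_bed <- function(annotation, file) {
  validate_annotation(annotation)
  bed <- data.table::data.table(
    chrom = annotation$chrom, start = annotation$start, end = annotation$end,
    name = annotation$gene_id, score = 0L, strand = annotation$strand)
  data.table::fwrite(bed, file, sep = "\t", col.names = FALSE)
  if ("rate_class" %in% names(annotation)) {
    data.table::fwrite(
      data.table::data.table(gene_id = annotation$gene_id,
                             rate_class = annotation$rate_class),
      paste0(file, ".rates.tsv"), sep = "\t")
  }
  invisible(file)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(file) {
  bed <- data.table::fread(file, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end",
                                         "name", "score", "strand"))
  ann <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                    start = bed$start, end = bed$end, strand = bed$strand,
                    stringsAsFactors = FALSE)
  rates_file <- paste0(file, ".rates.tsv")
  if (file.exists(rates_file)) {
    rates <- data.table::fread(rates_file, sep = "\t")
    ann$rate_class <- rates$rate_class[match(ann$gene_id, rates$gene_id)]
  }
  validate_annotation(ann)
  ann
}

#' Read/write a chromosome size table (two-column TSV, no header)
#'
#' @param sizes named integer vector of chromosome lengths.
#' @param file path.
#' @return `read_chrom_sizes` returns a named integer vector.
#' @export
write_chrom_sizes <- function(sizes, file) {
  data.table::fwrite(data.table::data.table(chrom = names(sizes),
                                            length = as.integer(sizes)),
                     file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(file) {
  x <- data.table::fread(file, header = FALSE, sep = "\t",
                         col.names = c("chrom", "length"))
  setNames(as.integer(x$length), x$chrom)
}
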