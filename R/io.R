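#' Write sequences as FASTA with `gene|record` headers
#'
#' @param seqs Tibble with `gene_id`, `seq` and a record id column
#'   (`isoform` or `promoter_id`), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    set <- Biostrings::DNAStringSet(seqs)
  } else {
    id_col <- intersect(c("isoform", "promoter_id"), names(seqs))[1]
    nm <- if (is.na(id_col)) seqs$gene_id else paste0(seqs$gene_id, "|", seqs[[id_col]])
    set <- Biostrings::DNAStringSet(stats::setNames(seqs$seq, nm))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA of UTRs or promoters into a tibble
#'
#' Headers of the form `gene|record` are split into `gene_id` and the
#' record id; headers without `|` use the full name for both.
#'
#' @param path FASTA path.
#' @param record_col Name of the record id column (default `"isoform"`).
#' @return Tibble `gene_id`, `<record_col>`, `seq`.
#' @export
read_fasta <- function(path, record_col = "isoform") {
  set <- Biostrings::readDNAStringSet(path)
  nm <- names(set)
  parts <- strsplit(nm, "|", fixed = TRUE)
  out <- tibble(
    gene_id = vapply(parts, `[`, character(1), 1),
    record = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                    character(1)),
    seq = unname(as.character(set))
  )
  names(out)[2] <- record_col
  out
}

#' Write read pairs as a pair of FASTQ files
#'
#' @param pairs Tibble `pair_id`, `r1`, `r2`.
#' @param prefix Output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` with uniform quality.
#' @return The two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    sq <- Biostrings::DNAStringSet(
      stats::setNames(pairs[[c("r1", "r2")[i]]], pairs$pair_id))
    Biostrings::writeXStringSet(
      sq, paths[i], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(pairs[[c("r1", "r2")[i]]]))))
  }
  invisible(paths)
}

#' Read a pair of FASTQ files into a pairs tibble
#'
#' @param r1_path,r2_path FASTQ paths (records in matching order).
#' @return Tibble `pair_id`, `r1`, `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) != length(s2)) abort("FASTQ files differ in record count.")
  tibble(pair_id = sub("\\s.*$", "", names(s1)),
         r1 = unname(as.character(s1)), r2 = unname(as.character(s2)))
}

#' Write alignment records as BED-like TSV
#'
#' Columns: read_id, chrom, start, end, n_align (0-based half-open).
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_alignments <- function(alignments, path) {
  utils::write.table(
    alignments[, c("chrom", "start", "end", "read_id", "n_align")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED-like alignment records
#'
#' @param path TSV path (chrom, start, end, read_id, n_align).
#' @return Tibble `read_id`, `chrom`, `start`, `end`, `n_align`.
#' @export
read_bed_alignments <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "read_id", "n_align"))
  as_tibble(raw)[, c("read_id", "chrom", "start", "end", "n_align")]
}

#' Write a coverage pile as bedGraph
#'
#' Adjacent equal-valued positions are merged into intervals; zero-coverage
#' intervals are omitted.
#'
#' @param pile Numeric vector from [build_pile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(pile, path) {
  r <- rle(as.numeric(pile))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = attr(pile, "chrom"),
                   start = attr(pile, "start") + starts[keep],
                   end = attr(pile, "start") + ends[keep],
                   value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
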