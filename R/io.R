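#' Read sequences from FASTA into a tibble
#'
#' @param path FASTA file.
#' @return Tibble with columns `id` (first whitespace-delimited token),
#'   `description` (full header) and `seq`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  tibble(
    id = sub("\\s.*$", "", hdr),
    description = hdr,
    seq = unname(as.character(x))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Data frame with a `seq` column and either a `description` or
#'   an `id` column used as header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(seqs, path) {
  hdr <- if ("description" %in% names(seqs)) seqs$description else seqs$id
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read FASTQ into a tibble
#'
#' @param path FASTQ file (phred+33 qualities).
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq_tbl <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on import
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Data frame with columns `read_id`, `seq`, `qual` (phred+33).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_tbl <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

# GFF3 feature types used for rRNA annotations.
GENE_TYPES <- c(SSU_16S = "16S_rRNA", LSU_23S = "23S_rRNA",
                FiveS_5S = "5S_rRNA")

#' Read rRNA gene annotations from GFF3
#'
#' Imports a GFF3 file (1-based inclusive coordinates) and returns the rRNA
#' features as a tibble. Feature types `16S_rRNA`, `23S_rRNA` and `5S_rRNA`
#' are recognised, as are Barrnap-style `rRNA` features whose product
#' attribute names the subunit.
#'
#' @param path GFF3 file.
#' @return Tibble with columns `seqid`, `type` (one of `16S_rRNA`,
#'   `23S_rRNA`, `5S_rRNA`), `start`, `end`, `strand`.
#' @export
read_rrna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tab <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  # Barrnap writes type "rRNA" with Name=16S_rRNA etc.
  if (!is.null(gr$Name)) {
    nm <- as.character(gr$Name)
    generic <- tab$type == "rRNA" & !is.na(nm)
    tab$type[generic] <- nm[generic]
  }
  tab <- dplyr::filter(tab, .data$type %in% GENE_TYPES)
  tab$strand[!tab$strand %in% c("+", "-")] <- "+"
  tab
}

#' Write rRNA gene annotations to GFF3
#'
#' @param annotations Tibble with columns `seqid`, `type`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rrna_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$seqid,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand,
    type = annotations$type,
    source = "operonkit"
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
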