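#' In-silico PCR with degenerate primers
#'
#' Finds every amplicon a primer pair could produce from a template: sites
#' where the forward primer matches the forward strand and, downstream of
#' that site, the reverse primer matches the reverse strand (i.e. its
#' reverse complement matches the forward strand). Comparison is IUPAC
#' aware in the primer only (an `R` in the primer matches `A` or `G` in the
#' template), with up to `max_mismatch` mismatching positions per primer.
#' Reported intervals include both primer footprints.
#'
#' @param template A single nucleotide sequence (string, A/C/G/T).
#' @param fwd_primer,rev_primer IUPAC nucleotide strings; `rev_primer` is
#'   given 5'->3' on the reverse strand, as primers are ordered.
#' @param max_mismatch Maximum mismatches tolerated per primer (>= 0).
#' @param max_length Optional upper bound on amplicon length; site pairs
#'   farther apart are not reported (PCR cannot bridge them). `Inf` keeps
#'   all pairs.
#' @return Tibble with columns `start`, `end` (1-based inclusive, spanning
#'   both primer footprints) and `length`, ordered by `start` then `end`.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer,
                          max_mismatch = 0, max_length = Inf) {
  check_iupac(fwd_primer, "fwd_primer")
  check_iupac(rev_primer, "rev_primer")
  if (max_mismatch < 0) abort("max_mismatch must be >= 0")
  subj <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(
    Biostrings::DNAString(fwd_primer), subj,
    max.mismatch = max_mismatch, fixed = "subject")
  rpat <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  rhits <- Biostrings::matchPattern(
    rpat, subj, max.mismatch = max_mismatch, fixed = "subject")
  fs <- Biostrings::start(fhits); fe <- Biostrings::end(fhits)
  rs <- Biostrings::start(rhits); re <- Biostrings::end(rhits)
  if (length(fs) == 0 || length(rs) == 0) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  pairs <- tidyr::expand_grid(f = seq_along(fs), r = seq_along(rs))
  pairs <- dplyr::mutate(pairs,
    start = fs[.data$f], fend = fe[.data$f],
    rstart = rs[.data$r], end = re[.data$r],
    length = .data$end - .data$start + 1L)
  pairs <- dplyr::filter(pairs,
    .data$rstart > .data$fend, .data$length <= max_length)
  dplyr::arrange(
    dplyr::select(pairs, "start", "end", "length"),
    .data$start, .data$end)
}

# IUPAC alphabet check for primer strings
check_iupac <- function(x, what) {
  if (length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(paste0(what, " must be a single non-empty string"))
  }
  ok <- grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", x)
  if (!ok) abort(paste0(what, " contains non-IUPAC characters"))
  invisible(x)
}

#' Realise a degenerate IUPAC string as a concrete sequence
#'
#' Each ambiguity code is replaced by one of its compatible bases, drawn
#' from the current RNG stream. Used by the simulator to plant primer
#' binding sites that the degenerate primer matches exactly.
#'
#' @param iupac IUPAC nucleotide string.
#' @return Concrete A/C/G/T string of the same length.
#' @export
realize_iupac <- function(iupac) {
  codes <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(iupac), "")[[1]]
  picked <- vapply(chars, function(ch) {
    opts <- strsplit(codes[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(picked, collapse = "")
}
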