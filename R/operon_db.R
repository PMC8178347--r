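#' Chain nearby rRNA genes on one contig
#'
#' Genes are sorted by start and consecutive genes are merged into one
#' chain when the number of intervening bases (`start_next - end_prev - 1`
#' on 1-based inclusive coordinates) is strictly less than `max_gap` and
#' both genes lie on the same strand. With the default 2000 bp threshold a
#' linked operon's ITS (< 1500 bp by definition) always merges, so each
#' linked 16S-ITS-23S(-5S) locus becomes a single chain while unlinked
#' genes stay separate.
#'
#' @param genes Tibble of rRNA genes on a single contig: columns `seqid`,
#'   `type`, `start`, `end`, `strand`.
#' @param max_gap Strict upper bound on the intergenic distance, bp.
#' @return The input tibble, sorted by `start`, with an added integer
#'   `chain` column; chains are numbered in coordinate order.
#' @export
chain_rrna_genes <- function(genes, max_gap = 2000) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) return(dplyr::mutate(genes, chain = integer()))
  if (length(unique(genes$seqid)) > 1) {
    abort("chain_rrna_genes expects genes from a single contig")
  }
  if (any(genes$end < genes$start)) abort("gene end < start")
  genes <- dplyr::arrange(genes, .data$start, .data$end)
  gap <- genes$start[-1] - genes$end[-nrow(genes)] - 1L
  same_strand <- genes$strand[-1] == genes$strand[-nrow(genes)]
  new_chain <- c(TRUE, !(gap < max_gap & same_strand))
  dplyr::mutate(genes, chain = cumsum(new_chain))
}

#' Extract operon spans for gene chains
#'
#' Each chain yields the contiguous genomic substring from the first gene's
#' start to the last gene's end, intergenic spacers included (amplicons
#' include the ITS, so the database must too). Minus-strand chains are
#' reverse-complemented so every record reads 5'->3' through the operon.
#'
#' @param contig_seq The contig sequence (single string).
#' @param chained_genes Output of [chain_rrna_genes()].
#' @return Tibble with one row per chain: `chain`, `start`, `end`,
#'   `strand`, `member_genes` (comma-joined, in reading order), `seq`,
#'   `length`.
#' @export
extract_operon_sequences <- function(contig_seq, chained_genes) {
  if (nrow(chained_genes) == 0) {
    return(tibble(chain = integer(), start = integer(), end = integer(),
                  strand = character(), member_genes = character(),
                  seq = character(), length = integer()))
  }
  clen <- nchar(contig_seq)
  spans <- chained_genes |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     strand = dplyr::first(.data$strand),
                     member_genes = paste(
                       if (dplyr::first(.data$strand) == "+") .data$type
                       else rev(.data$type), collapse = ","),
                     .groups = "drop")
  bad <- spans$end > clen | spans$start < 1
  if (any(bad)) {
    abort(paste0("chain(s) exceed contig bounds: ",
                 paste(spans$chain[bad], collapse = ", ")))
  }
  spans <- dplyr::mutate(spans,
    seq = substring(contig_seq, .data$start, .data$end),
    length = .data$end - .data$start + 1L)
  spans$seq[spans$strand == "-"] <- revcomp(spans$seq[spans$strand == "-"])
  spans
}

#' Build an rRNA operon reference database
#'
#' Chains rRNA genes contig by contig, extracts the chain spans, drops
#' records shorter than `min_length` (strictly: a record of exactly
#' `min_length` is kept), drops records whose species name or taxid is in
#' `exclude_taxa`, and labels every record `taxid|accession` with the
#' organism description — the header convention downstream classification
#' and linkage reporting rely on.
#'
#' @param genomes Tibble with columns `accession`, `seq` (and optionally
#'   `taxid`, `description`; taxid is taken from `taxonomy`).
#' @param annotations rRNA gene tibble (`seqid`, `type`, `start`, `end`,
#'   `strand`), e.g. from [read_rrna_gff3()] or a `synthetic_community`.
#' @param taxonomy Taxonomy tibble (see [validate_taxonomy()]); every
#'   genome accession must appear.
#' @param min_length Minimum record length kept, bp.
#' @param max_gap Chaining threshold passed to [chain_rrna_genes()].
#' @param exclude_taxa Character vector of species names and/or taxids to
#'   drop from the finished database (database-ablation experiments).
#' @return An `operon_db`: list with `records` tibble (`db_id`, `taxid`,
#'   `accession`, `description`, `member_genes`, `contig`, `start`, `end`,
#'   `strand`, `length`, `seq`), the `taxonomy`, and `params`.
#' @export
build_operon_db <- function(genomes, annotations, taxonomy,
                            min_length = 1000, max_gap = 2000,
                            exclude_taxa = character()) {
  taxonomy <- validate_taxonomy(taxonomy)
  genomes <- as_tibble(genomes)
  missing_acc <- setdiff(genomes$accession, taxonomy$accession)
  if (length(missing_acc) > 0) {
    abort(paste0("accession(s) missing from taxonomy: ",
                 paste(missing_acc, collapse = ", ")))
  }
  records <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    acc <- genomes$accession[i]
    genes <- dplyr::filter(as_tibble(annotations), .data$seqid == acc)
    if (nrow(genes) == 0) return(NULL)
    chains <- chain_rrna_genes(genes, max_gap = max_gap)
    spans <- extract_operon_sequences(genomes$seq[i], chains)
    tax <- taxonomy[taxonomy$accession == acc, ][1, ]
    dplyr::transmute(spans,
      db_id = paste0(tax$taxid, "|", acc),
      taxid = tax$taxid, accession = acc,
      description = tax$species,
      member_genes = .data$member_genes, contig = acc,
      start = .data$start, end = .data$end, strand = .data$strand,
      length = .data$length, seq = .data$seq)
  })
  if (is.null(records) || nrow(records) == 0) {
    records <- tibble(db_id = character(), taxid = integer(),
                      accession = character(), description = character(),
                      member_genes = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      seq = character())
  }
  records <- dplyr::filter(records, .data$length >= min_length)
  if (length(exclude_taxa) > 0) {
    excl_tax <- suppressWarnings(as.integer(exclude_taxa))
    records <- dplyr::filter(records,
      !(.data$description %in% exclude_taxa |
          .data$taxid %in% excl_tax[!is.na(excl_tax)]))
  }
  structure(list(
    records = records, taxonomy = taxonomy,
    params = list(min_length = min_length, max_gap = max_gap,
                  exclude_taxa = as.character(exclude_taxa))),
    class = "operon_db")
}

#' @export
print.operon_db <- function(x, ...) {
  s <- db_stats(x)
  cat("<operon_db> ", s$n_sequences, " records; ", s$n_species,
      " species, ", s$n_genera, " genera\n", sep = "")
  invisible(x)
}

#' Summary statistics of an operon database
#'
#' @param db An `operon_db`.
#' @return A list with `n_sequences`, `n_genera`, `n_species` (distinct,
#'   ignoring empty rank names) and `length_summary` (quantiles of record
#'   lengths).
#' @export
db_stats <- function(db) {
  lin <- dplyr::left_join(db$records["taxid"],
                          dplyr::distinct(db$taxonomy[, c("taxid", RANKS)]),
                          by = "taxid")
  nz <- function(x) length(unique(x[!is.na(x) & x != ""]))
  list(
    n_sequences = nrow(db$records),
    n_genera = nz(lin$genus),
    n_species = nz(lin$species),
    length_summary = if (nrow(db$records) > 0) {
      stats::quantile(db$records$length, c(0, 0.25, 0.5, 0.75, 1))
    } else numeric(0)
  )
}

#' Write an operon database to FASTA with a JSON metadata sidecar
#'
#' FASTA headers are exactly `taxid|accession description`. The sidecar
#' (`<path>.json`) carries the per-record spans, build parameters and the
#' taxonomy so that [read_operon_db()] reproduces the object.
#'
#' @param db An `operon_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_operon_db <- function(db, path) {
  write_fasta_tbl(
    dplyr::transmute(db$records, id = .data$db_id,
      description = paste(.data$db_id, .data$description),
      seq = .data$seq), path)
  meta <- list(
    params = db$params,
    records = dplyr::select(db$records, -"seq"),
    taxonomy = db$taxonomy)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an operon database written by [write_operon_db()]
#'
#' @param path FASTA path (the `<path>.json` sidecar must sit beside it).
#' @return An `operon_db`.
#' @export
read_operon_db <- function(path) {
  fa <- read_fasta_tbl(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  records <- as_tibble(meta$records)
  records$seq <- fa$seq
  records$taxid <- as.integer(records$taxid)
  tax <- as_tibble(meta$taxonomy)
  tax$taxid <- as.integer(tax$taxid)
  tax[RANKS] <- lapply(tax[RANKS], function(x) tidyr::replace_na(x, ""))
  params <- meta$params
  params$exclude_taxa <- as.character(unlist(params$exclude_taxa))
  structure(list(records = records, taxonomy = validate_taxonomy(tax),
                 params = params), class = "operon_db")
}
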