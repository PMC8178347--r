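#' Validate a taxonomy table
#'
#' A taxonomy table maps sequence accessions to NCBI-style numeric taxids and
#' a seven-rank lineage (superkingdom, phylum, class, order, family, genus,
#' species). Lower ranks may be empty strings, but an empty rank may not be
#' followed by a non-empty one: lineages are truncated from the bottom only.
#'
#' @param taxonomy A data frame with columns `accession`, `taxid` and the
#'   seven rank columns of [taxonomic_ranks()].
#' @return The validated taxonomy as a tibble (invisibly unchanged).
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- as_tibble(taxonomy)
  need <- c("accession", "taxid", RANKS)
  missing_cols <- setdiff(need, names(taxonomy))
  if (length(missing_cols) > 0) {
    abort(paste0("taxonomy table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(taxonomy$taxid)) || any(taxonomy$taxid <= 0)) {
    abort("taxonomy taxids must be positive integers")
  }
  per_taxid <- dplyr::distinct(taxonomy[, c("taxid", RANKS)])
  if (anyDuplicated(per_taxid$taxid) > 0) {
    abort("a taxid maps to more than one lineage in the taxonomy table")
  }
  ranks <- as.matrix(taxonomy[, RANKS])
  ranks[is.na(ranks)] <- ""
  filled <- ranks != ""
  for (i in seq_len(nrow(filled))) {
    f <- filled[i, ]
    if (any(f & !cumprod(f))) {
      abort(paste0("lineage for accession ", taxonomy$accession[i],
                   " has a gap: an empty rank is followed by a named one"))
    }
  }
  taxonomy
}

#' Read a taxonomy table from TSV
#'
#' Expects columns accession, taxid, then the seven rank names.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A validated taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    taxid = readr::col_integer(),
    .default = readr::col_character()
  ))
  tab[RANKS] <- lapply(tab[RANKS], function(x) tidyr::replace_na(x, ""))
  validate_taxonomy(tab)
}

#' Write a taxonomy table to TSV
#' @param taxonomy A taxonomy tibble (see [validate_taxonomy()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(validate_taxonomy(taxonomy), path)
  invisible(path)
}

#' Lowest common ancestor of a set of lineages
#'
#' Compares lineages rank by rank from superkingdom downward and keeps ranks
#' on which all lineages agree (and are non-empty); every rank below the
#' first disagreement is blanked. Used to resolve ties between equally
#' well-matching database records.
#'
#' @param lineages A data frame whose columns include the seven ranks; one
#'   row per lineage.
#' @return A single-row tibble with the seven rank columns.
#' @export
lineage_lca <- function(lineages) {
  lineages <- as_tibble(lineages)[, RANKS, drop = FALSE]
  out <- setNames(rep("", length(RANKS)), RANKS)
  for (r in RANKS) {
    vals <- unique(lineages[[r]])
    if (length(vals) == 1 && !is.na(vals) && vals != "") out[r] <- vals
    else break
  }
  as_tibble(as.list(out))
}

#' Deepest named rank of a lineage
#'
#' @param lineage One-row data frame with the seven rank columns.
#' @return Rank name, or `NA_character_` if every rank is empty.
#' @export
deepest_rank <- function(lineage) {
  vals <- unlist(lineage[1, RANKS])
  named <- which(!is.na(vals) & vals != "")
  if (length(named) == 0) return(NA_character_)
  RANKS[max(named)]
}
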