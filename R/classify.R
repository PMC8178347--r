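#' Conservative rank thresholds for the k-mer classifier
#'
#' The classifier scores a read by the fraction of its canonical k-mers
#' found in the best database record, and resolves the read at the deepest
#' rank whose threshold the score clears — a rank-degradation scheme in
#' the spirit of conservative taxonomic assignment pipelines, with its own
#' documented thresholds (it makes no claim of equivalence to any external
#' tool's quality model). Thresholds decrease monotonically from species
#' to superkingdom.
#'
#' @param species,genus,family,order,class,phylum,superkingdom Minimum
#'   matched-k-mer fraction to resolve at each rank.
#' @return Named numeric vector ordered superkingdom to species.
#' @export
rank_thresholds <- function(species = 0.60, genus = 0.45, family = 0.30,
                            order = 0.20, class = 0.12, phylum = 0.05,
                            superkingdom = 0.02) {
  th <- c(superkingdom = superkingdom, phylum = phylum, class = class,
          order = order, family = family, genus = genus, species = species)
  if (any(diff(th) < 0)) {
    abort("thresholds must be non-decreasing from superkingdom to species")
  }
  th
}

#' Build a canonical k-mer index over an operon database
#'
#' Strand-collapsed k-mers of every record, deduplicated per record. The
#' heavy lookup structure lives in compiled code and is rebuilt from the
#' records at matching time; this object carries the database, the k, and
#' the distinct-k-mer count for inspection.
#'
#' @param db An `operon_db` with at least one record.
#' @param k Odd k-mer size in \[7, 31\].
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(db, k = 15) {
  if (k %% 2 == 0) abort("k must be odd")
  if (k < 7 || k > 31) abort("k must lie in [7, 31]")
  if (nrow(db$records) == 0) abort("empty database")
  structure(list(db = db, k = as.integer(k),
                 n_distinct_kmers = cpp_count_distinct_kmers(db$records$seq,
                                                             as.integer(k))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", nrow(x$db$records), " records, ",
      x$n_distinct_kmers, " distinct canonical k-mers\n", sep = "")
  invisible(x)
}

#' Assign reads to operon database records by shared k-mers
#'
#' For each read, the best-matching database record is the one sharing the
#' most canonical (strand-collapsed) k-mers with the read; the score is
#' that count divided by the read's k-mer count. Records tying for the
#' best score are merged to the lowest common ancestor of their lineages,
#' so an ambiguous read is resolved no deeper than the tied records agree.
#' The read's resolved rank is the deepest rank that both clears its score
#' threshold and is still named in the (possibly LCA-truncated) lineage;
#' reads with no matching record, a score below every threshold, or fewer
#' than one k-mer are unclassified.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param db An `operon_db` or a [build_kmer_index()] object.
#' @param k Odd k-mer size in \[7, 31\] (ignored when `db` is an index).
#' @param thresholds See [rank_thresholds()].
#' @return Tibble with one row per read: `read_id`, `db_id` (NA when
#'   unclassified), `score`, `resolved_rank` (`"unclassified"` when none),
#'   and the seven lineage columns truncated at the resolved rank.
#' @export
assign_reads <- function(reads, db, k = 15, thresholds = rank_thresholds()) {
  if (inherits(db, "kmer_index")) {
    k <- db$k
    db <- db$db
  }
  if (k %% 2 == 0) abort("k must be odd")
  if (k < 7 || k > 31) abort("k must lie in [7, 31]")
  if (nrow(db$records) == 0) abort("empty database")
  reads <- as_tibble(reads)
  res <- cpp_match_reads(db$records$seq, reads$seq, as.integer(k))
  lineages <- dplyr::left_join(db$records["taxid"],
                               dplyr::distinct(db$taxonomy[, c("taxid", RANKS)]),
                               by = "taxid")
  th <- thresholds
  n <- nrow(reads)
  score <- res$score
  hit <- lengths(res$tied) > 0 & score >= min(th) & res$n_kmers >= 1
  # deepest rank the score alone allows (thresholds increase toward species)
  allowed_depth <- vapply(score, function(s) sum(th <= s), integer(1))
  # resolve the LCA once per distinct tie set
  key <- vapply(res$tied, paste, collapse = ",", FUN.VALUE = character(1))
  lin_mat <- matrix("", n, length(RANKS), dimnames = list(NULL, RANKS))
  lca_depth <- integer(n)
  for (kk in unique(key[hit])) {
    tied <- as.integer(strsplit(kk, ",")[[1]])
    lca <- unlist(lineage_lca(lineages[tied, ])[1, ])
    sel <- hit & key == kk
    lin_mat[sel, ] <- matrix(lca, sum(sel), length(RANKS), byrow = TRUE)
    lca_depth[sel] <- sum(lca != "")
  }
  depth <- pmin(allowed_depth, lca_depth)
  unclassified <- !hit | depth == 0
  # blank ranks below the resolved depth
  below <- outer(depth, seq_along(RANKS), `<`)
  lin_mat[below] <- ""
  single <- lengths(res$tied) == 1 & hit & !unclassified
  db_id <- rep(NA_character_, n)
  db_id[single] <- db$records$db_id[unlist(res$tied[single])]
  out <- tibble(
    read_id = reads$read_id,
    db_id = db_id,
    score = score,
    resolved_rank = ifelse(unclassified, "unclassified", RANKS[pmax(depth, 1)]))
  dplyr::bind_cols(out, as_tibble(lin_mat))
}

#' Rank-wise taxon profiles from read assignments
#'
#' For each rank, reads whose lineage is named at that rank contribute to
#' that taxon's relative abundance; the rest (resolved only at a higher
#' rank, or unclassified) are pooled into the unassigned category, so
#' abundances sum to one at every rank.
#'
#' @param assignments Tibble from [assign_reads()].
#' @param ranks Ranks to profile (default all seven).
#' @return Tibble with columns `rank`, `taxon`, `abundance`, `n_reads`;
#'   unassigned mass appears as taxon [unassigned_label()].
#' @export
profile_sample <- function(assignments, ranks = taxonomic_ranks()) {
  assignments <- as_tibble(assignments)
  n <- nrow(assignments)
  purrr::map_dfr(ranks, function(r) {
    if (n == 0) {
      return(tibble(rank = character(), taxon = character(),
                    abundance = numeric(), n_reads = integer()))
    }
    taxon <- assignments[[r]]
    taxon[is.na(taxon) | taxon == ""] <- UNASSIGNED
    out <- dplyr::count(tibble(taxon = taxon), .data$taxon, name = "n_reads")
    dplyr::transmute(out, rank = r, taxon = .data$taxon,
                     abundance = .data$n_reads / n,
                     n_reads = .data$n_reads)
  })
}

#' Fraction of reads classified at each rank
#'
#' @param assignments Tibble from [assign_reads()].
#' @return Tibble `rank`, `fraction_assigned`; non-increasing from
#'   superkingdom to species.
#' @export
rank_assignment_rates <- function(assignments) {
  purrr::map_dfr(RANKS, function(r) {
    v <- assignments[[r]]
    tibble(rank = r,
           fraction_assigned = mean(!is.na(v) & v != ""))
  })
}
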