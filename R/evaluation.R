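#' Expected composition of a mock community
#'
#' @param expected Data frame with columns `taxon`, `abundance` (fractions
#'   summing to 1).
#' @param rank Rank the expectation refers to.
#' @return An `expected_mock` tibble with attribute `rank`.
#' @export
expected_mock <- function(expected, rank) {
  expected <- as_tibble(expected)
  if (abs(sum(expected$abundance) - 1) > 1e-9) {
    abort("expected abundances must sum to 1")
  }
  structure(dplyr::mutate(expected, rank = rank), class =
              c("expected_mock", class(expected)))
}

# align an observed profile (at one rank) with an expectation over the
# taxon union; unassigned and non-member mass may be pooled into one
# off-target coordinate
align_profile <- function(observed, expected, pool_offtarget = FALSE) {
  rank <- expected$rank[1]
  obs <- dplyr::filter(as_tibble(observed), .data$rank == !!rank)
  if (nrow(obs) == 0) abort(paste0("observed profile has no rows at rank ",
                                   rank))
  members <- expected$taxon
  if (pool_offtarget) {
    off <- sum(obs$abundance[!obs$taxon %in% members])
    obs <- dplyr::bind_rows(
      obs[obs$taxon %in% members, c("taxon", "abundance")],
      tibble(taxon = "(off-target)", abundance = off))
  } else {
    obs <- obs[, c("taxon", "abundance")]
  }
  full_join(obs, expected[, c("taxon", "abundance")], by = "taxon",
            suffix = c("_obs", "_exp")) |>
    dplyr::mutate(abundance_obs = tidyr::replace_na(.data$abundance_obs, 0),
                  abundance_exp = tidyr::replace_na(.data$abundance_exp, 0))
}

#' Bray-Curtis dissimilarity between two composition vectors
#'
#' @param x,y Non-negative numeric vectors over the same taxa.
#' @return `sum(|x - y|) / sum(x + y)`, in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (any(x < 0) || any(y < 0)) abort("compositions must be non-negative")
  sum(abs(x - y)) / sum(x + y)
}

#' Dissimilarity of an observed profile from the expected mock
#'
#' Bray-Curtis dissimilarity over the union of observed and expected taxa
#' at the expectation's rank. By default the observed vector keeps
#' unassigned and non-member taxa as their own coordinates (they carry
#' observed mass that the expectation lacks); `pool_offtarget = TRUE`
#' pools all off-member mass into a single coordinate instead — both
#' readings of "dissimilarity to the expected abundance" are available.
#'
#' @param observed Profile tibble (`rank`, `taxon`, `abundance`), e.g.
#'   from [profile_sample()].
#' @param expected An [expected_mock()].
#' @param pool_offtarget Pool non-member and unassigned mass into one
#'   coordinate.
#' @return Dissimilarity in \[0, 1\].
#' @export
mock_dissimilarity <- function(observed, expected, pool_offtarget = FALSE) {
  al <- align_profile(observed, expected, pool_offtarget)
  bray_curtis(al$abundance_obs, al$abundance_exp)
}

#' Percentage of mis- or unidentified reads
#'
#' Observed relative-abundance mass sitting on taxa outside the expected
#' member set, plus unassigned mass, as a percentage.
#'
#' @inheritParams mock_dissimilarity
#' @return Percentage in \[0, 100\].
#' @export
mis_or_unidentified <- function(observed, expected) {
  rank <- expected$rank[1]
  obs <- dplyr::filter(as_tibble(observed), .data$rank == !!rank)
  100 * sum(obs$abundance[!obs$taxon %in% expected$taxon])
}

#' Number of misidentified taxa
#'
#' Distinct taxa observed with positive abundance that are not community
#' members; the unassigned category does not count (it is unidentified,
#' not misidentified).
#'
#' @inheritParams mock_dissimilarity
#' @return Integer count.
#' @export
count_misidentified_taxa <- function(observed, expected) {
  rank <- expected$rank[1]
  obs <- dplyr::filter(as_tibble(observed), .data$rank == !!rank,
                       .data$abundance > 0,
                       .data$taxon != UNASSIGNED,
                       !.data$taxon %in% expected$taxon)
  length(unique(obs$taxon))
}

#' Taxon accumulation curve
#'
#' Number of distinct taxa observed as a function of the number of reads
#' sampled, averaged over random subsamples — the curve whose plateau
#' tells how many reads saturate the detectable taxa at a rank. The
#' default draws an independent subsample per replicate and size; nested
#' mode draws one read permutation per replicate and accumulates along
#' it, making every replicate's curve monotone by construction.
#'
#' @param assignments Tibble from [assign_reads()], or any tibble with a
#'   taxon column.
#' @param rank Column holding the taxon at the rank of interest;
#'   unassigned (empty or NA) entries never count as taxa.
#' @param step Curve step size in reads.
#' @param reps Number of random subsamples per curve point.
#' @param seed Integer seed.
#' @param nested Use nested (cumulative) subsamples.
#' @return Tibble with `n_reads`, `mean_taxa`, `sd_taxa`.
#' @export
accumulation_curve <- function(assignments, rank = "order", step = 1000,
                               reps = 10, seed = 1, nested = FALSE) {
  if (step < 1 || reps < 1) abort("step and reps must be >= 1")
  taxa <- as_tibble(assignments)[[rank]]
  taxa[taxa == ""] <- NA_character_
  n <- length(taxa)
  sizes <- unique(c(seq(step, n, by = step), n))
  withr::with_seed(seed, {
    if (nested) {
      counts <- matrix(0L, nrow = length(sizes), ncol = reps)
      for (r in seq_len(reps)) {
        perm <- taxa[sample(n)]
        # distinct taxa among the first m reads of this permutation
        firsts <- which(!duplicated(perm) & !is.na(perm))
        counts[, r] <- vapply(sizes, function(m) sum(firsts <= m),
                              integer(1))
      }
    } else {
      counts <- vapply(seq_len(reps), function(r) {
        vapply(sizes, function(m) {
          s <- taxa[sample(n, m)]
          length(unique(s[!is.na(s)]))
        }, integer(1))
      }, integer(length(sizes)))
      counts <- matrix(counts, nrow = length(sizes))
    }
    tibble(n_reads = sizes,
           mean_taxa = apply(counts, 1, mean),
           sd_taxa = apply(counts, 1, sd))
  })
}
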