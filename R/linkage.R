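#' Classify 16S rRNA genes as linked, unlinked or unjudgeable
#'
#' For every 16S gene on one subject (read or contig), the downstream
#' region in the gene's reading orientation is searched for the nearest
#' same-strand 23S gene. With `gap` the number of intervening bases to that
#' 23S and `window` the linkage threshold (1500 bp):
#' \itemize{
#'   \item linked: a 23S exists with `gap <= window`;
#'   \item unlinked: `gap > window`, or no downstream 23S but at least
#'     `window` bp of sequence remain after the 16S 3' end (the gene could
#'     have been seen and was not);
#'   \item unjudgeable: no downstream 23S and fewer than `window` bp remain
#'     — the read simply ends too soon to tell.
#' }
#' 23S genes on the opposite strand, or upstream of the 16S, never link:
#' they are not part of the same operon template.
#'
#' @param annotations rRNA gene tibble for a single subject: columns
#'   `type`, `start`, `end`, `strand`, and a subject id column (`read_id`
#'   or `seqid`).
#' @param subject_length Length of the read or contig in bp.
#' @param window Linkage threshold in bp.
#' @return Tibble with one row per 16S gene: subject id, `start`, `end`,
#'   `strand`, `status`, `gap` (NA when no downstream 23S),
#'   `downstream_available`.
#' @export
classify_16s_linkage <- function(annotations, subject_length, window = 1500) {
  ann <- as_tibble(annotations)
  idcol <- intersect(c("read_id", "seqid"), names(ann))[1]
  if (is.na(idcol)) abort("annotations need a read_id or seqid column")
  if (length(unique(ann[[idcol]])) > 1) {
    abort("classify_16s_linkage expects annotations from a single subject")
  }
  g16 <- dplyr::filter(ann, .data$type == "16S_rRNA")
  g23 <- dplyr::filter(ann, .data$type == "23S_rRNA")
  if (nrow(g16) == 0) {
    return(tibble(subject_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  status = character(), gap = integer(),
                  downstream_available = integer()))
  }
  purrr::map_dfr(seq_len(nrow(g16)), function(i) {
    g <- g16[i, ]
    if (g$strand == "+") {
      cand <- g23$start[g23$strand == "+" & g23$start > g$end]
      gap <- if (length(cand) > 0) min(cand) - g$end - 1L else NA_integer_
      avail <- as.integer(subject_length - g$end)
    } else {
      cand <- g23$end[g23$strand == "-" & g23$end < g$start]
      gap <- if (length(cand) > 0) g$start - max(cand) - 1L else NA_integer_
      avail <- as.integer(g$start - 1L)
    }
    status <- if (!is.na(gap)) {
      if (gap <= window) "linked" else "unlinked"
    } else if (avail >= window) "unlinked" else "unjudgeable"
    tibble(subject_id = g[[idcol]], start = g$start, end = g$end,
           strand = g$strand, status = status, gap = as.integer(gap),
           downstream_available = avail)
  })
}

#' Screen reads for unlinked rRNA genes
#'
#' Applies [classify_16s_linkage()] read by read and implements the
#' read-retention rules used for community-level accounting: reads without
#' a 16S gene are excluded (counting only 16S-bearing reads avoids double
#' counting organisms whose 16S and 23S travel on different fragments);
#' reads whose every 16S is unjudgeable are removed; a retained read
#' counts as unlinked-containing when at least one of its 16S genes is
#' called unlinked.
#'
#' @param annotations rRNA annotations in read coordinates: columns
#'   `read_id`, `type`, `start`, `end`, `strand` (e.g. the `annotations`
#'   tibble of a `shotgun_sim`).
#' @param read_lengths Tibble with columns `read_id`, `length` for every
#'   read in `annotations`.
#' @param window Linkage threshold in bp.
#' @return List with `calls` (per-16S tibble), `retained` (character
#'   vector of read ids kept), and `summary` (one-row tibble:
#'   `n_reads_with_rrna`, `n_reads_with_16s`, `n_retained`, `n_unlinked`,
#'   `n_unjudgeable_only`).
#' @export
screen_reads <- function(annotations, read_lengths, window = 1500) {
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0) {
    return(list(
      calls = tibble(), retained = character(),
      summary = tibble(n_reads_with_rrna = 0L, n_reads_with_16s = 0L,
                       n_retained = 0L, n_unlinked = 0L,
                       n_unjudgeable_only = 0L)))
  }
  lens <- setNames(read_lengths$length, read_lengths$read_id)
  calls <- ann |>
    dplyr::group_by(.data$read_id) |>
    dplyr::group_map(~ classify_16s_linkage(
      dplyr::mutate(.x, read_id = .y$read_id),
      subject_length = lens[[.y$read_id]], window = window)) |>
    dplyr::bind_rows()
  per_read <- if (nrow(calls) > 0) {
    calls |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        any_judgeable = any(.data$status != "unjudgeable"),
        any_unlinked = any(.data$status == "unlinked"), .groups = "drop")
  } else {
    tibble(subject_id = character(), any_judgeable = logical(),
           any_unlinked = logical())
  }
  retained <- per_read$subject_id[per_read$any_judgeable]
  list(
    calls = calls,
    retained = retained,
    summary = tibble(
      n_reads_with_rrna = length(unique(ann$read_id)),
      n_reads_with_16s = nrow(per_read),
      n_retained = length(retained),
      n_unlinked = sum(per_read$any_unlinked & per_read$any_judgeable),
      n_unjudgeable_only = sum(!per_read$any_judgeable)))
}

#' Type a genome as linked, unlinked or mixed
#'
#' Classifies every 16S copy with [classify_16s_linkage()], drops
#' unjudgeable copies, and types the genome: `mixed` when both linked and
#' unlinked copies are present, otherwise `linked` or `unlinked`;
#' `untypeable` when there is no judgeable 16S copy at all.
#'
#' @param annotations rRNA annotations of one genome (`seqid`, `type`,
#'   `start`, `end`, `strand`).
#' @param genome_length Contig length in bp.
#' @param window Linkage threshold in bp.
#' @return One-row tibble: `seqid`, `type`, `n_linked`, `n_unlinked`,
#'   `n_unjudgeable`.
#' @export
type_genome <- function(annotations, genome_length, window = 1500) {
  ann <- as_tibble(annotations)
  idcol <- intersect(c("seqid", "read_id"), names(ann))[1]
  sid <- if (nrow(ann) > 0) ann[[idcol]][1] else NA_character_
  calls <- classify_16s_linkage(ann, genome_length, window = window)
  nl <- sum(calls$status == "linked")
  nu <- sum(calls$status == "unlinked")
  nj <- sum(calls$status == "unjudgeable")
  type <- if (nl + nu == 0) "untypeable"
          else if (nl > 0 && nu > 0) "mixed"
          else if (nl > 0) "linked" else "unlinked"
  tibble(seqid = sid, type = type, n_linked = nl, n_unlinked = nu,
         n_unjudgeable = nj)
}

#' Summarise unlinked-taxon abundance across profiling methods
#'
#' For each method's taxon profile, sums the relative abundance of the
#' target taxa (e.g. the genera known to carry unlinked rRNA genes) and
#' reports all pairwise cross-method ratios — the quantity that exposes
#' how strongly an operon-spanning amplicon underestimates unlinked taxa
#' relative to 16S amplicon or shotgun profiling.
#'
#' @param profiles Named list of taxon-profile tibbles (columns `rank`,
#'   `taxon`, `abundance`), one per method.
#' @param target_taxa Character vector of taxon names.
#' @param rank Rank at which to sum.
#' @return List with `percent` (tibble `method`, `percent`), `ratios`
#'   (tibble `method_a`, `method_b`, `ratio` = percent_a / percent_b), and
#'   `absent_everywhere` (TRUE when no method observed any target taxon).
#' @export
unlinked_taxon_summary <- function(profiles, target_taxa, rank = "genus") {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  percent <- purrr::imap_dfr(profiles, function(p, nm) {
    p <- dplyr::filter(as_tibble(p), .data$rank == !!rank)
    tibble(method = nm,
           percent = 100 * sum(p$abundance[p$taxon %in% target_taxa]))
  })
  ratios <- tidyr::expand_grid(method_a = percent$method,
                               method_b = percent$method) |>
    dplyr::filter(.data$method_a != .data$method_b) |>
    dplyr::mutate(
      ratio = percent$percent[match(.data$method_a, percent$method)] /
        percent$percent[match(.data$method_b, percent$method)])
  list(percent = percent, ratios = ratios,
       absent_everywhere = all(percent$percent == 0))
}
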