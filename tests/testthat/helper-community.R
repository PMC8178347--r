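# Shared synthetic fixtures, built in code at test time.

# two members at equal abundance: one fully linked, one mixed
two_member_spec <- function(linked_fraction = 0.5, n_copies = 4) {
  community_spec(dplyr::bind_rows(
    community_member("Mixto unus", 0.5,
                     operon_architecture(n_copies = n_copies,
                                         linked_fraction = linked_fraction),
                     taxid = 101),
    community_member("Plenus duo", 0.5,
                     operon_architecture(n_copies = n_copies),
                     taxid = 102)))
}

# five fully linked bacteria-like members with uneven abundances
five_member_spec <- function() {
  ab <- c(0.30, 0.25, 0.20, 0.15, 0.10)
  sp <- c("Alphus unus", "Betus duo", "Gammus tres", "Deltus quattuor",
          "Epsilus quinque")
  community_spec(dplyr::bind_rows(purrr::map2(
    sp, seq_along(sp),
    ~ community_member(.x, ab[.y], operon_architecture(n_copies = 3),
                       taxid = 200 + .y))))
}

# three bacteria plus one archaea-like member missing the 27F site
archaeal_spec <- function() {
  community_spec(dplyr::bind_rows(
    community_member("Alphus unus", 0.35, operon_architecture(n_copies = 3),
                     taxid = 301),
    community_member("Betus duo", 0.30, operon_architecture(n_copies = 3),
                     taxid = 302),
    community_member("Gammus tres", 0.20, operon_architecture(n_copies = 3),
                     taxid = 303),
    community_member("Methanoides archaeum", 0.15,
                     operon_architecture(n_copies = 2,
                                         primer_sites = c("27F" = FALSE)),
                     taxid = 304, superkingdom = "Archaea")))
}

# annotation row helper
gene_row <- function(seqid, type, start, end, strand = "+") {
  tibble::tibble(seqid = seqid, type = type, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

# phred+33 quality string with the given per-base scores
qual_string <- function(scores) {
  intToUtf8(as.integer(scores) + 33L, multiple = FALSE)
}

# observed profile tibble at one rank
profile_tbl <- function(taxa, abundance, rank = "species") {
  tibble::tibble(rank = rank, taxon = taxa, abundance = abundance)
}
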