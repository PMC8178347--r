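#' Default degenerate primer set
#'
#' Standard literature primer sequences used as configurable defaults: 27F
#' and 1492R bracket the full-length 16S rRNA gene; A519F (inside the 16S)
#' and U2428R (inside the 23S) bracket the 16S-ITS-23S operon amplicon.
#' These are stand-ins the user can replace; any IUPAC nucleotide strings
#' are accepted wherever a primer is taken.
#'
#' @return Tibble with columns `name`, `seq`, `direction` (`fwd`/`rev`).
#' @export
default_primers <- function() {
  tibble(
    name = c("27F", "1492R", "A519F", "U2428R"),
    seq = c("AGAGTTTGATCMTGGCTCAG", "TACGGYTACCTTGTTACGACTT",
            "CAGCMGCCGCGGTAA", "CCRAMCTGTCTCACGACG"),
    direction = c("fwd", "rev", "fwd", "rev")
  )
}

#' Named primer pairs for the two amplicon strategies
#'
#' @param target `"16S"` (27F + 1492R, full-length 16S rRNA gene) or
#'   `"rrn"` (A519F + U2428R, 16S-ITS-23S operon).
#' @return Named character vector `c(fwd = ..., rev = ...)`.
#' @export
primer_pair <- function(target = c("rrn", "16S")) {
  target <- match.arg(target)
  p <- default_primers()
  if (target == "16S") {
    c(fwd = p$seq[p$name == "27F"], rev = p$seq[p$name == "1492R"])
  } else {
    c(fwd = p$seq[p$name == "A519F"], rev = p$seq[p$name == "U2428R"])
  }
}

#' Describe the rRNA operon architecture of a synthetic genome
#'
#' A genome carries `n_copies` rRNA operons. A fraction `linked_fraction` of
#' them are linked (16S and 23S separated by a short internal transcribed
#' spacer, `its_length` bp, under the 1500 bp linkage threshold); the rest
#' are unlinked, with the 23S placed `unlinked_gap` bp downstream of the
#' 16S. Real unlinked spacers average hundreds of kilobases; the default of
#' 50,000 bp exceeds every linkage threshold while staying practical, and is
#' configurable.
#'
#' @param n_copies Number of rRNA operon copies (>= 1).
#' @param linked_fraction Fraction of copies that are linked, in \[0, 1\].
#'   `round(n_copies * linked_fraction)` copies are linked.
#' @param its_length ITS length in bp for linked copies (< 1500).
#' @param unlinked_gap 16S-23S gap in bp for unlinked copies (> 1500).
#' @param primer_sites Named logical vector flagging, per primer name,
#'   whether its binding site is present in this genome. Defaults to all
#'   four default primers present. Setting e.g. `27F = FALSE` emulates an
#'   archaea-like genome invisible to the bacterial 16S primer set.
#' @return An `operon_architecture` object.
#' @export
operon_architecture <- function(n_copies = 4, linked_fraction = 1,
                                its_length = 400, unlinked_gap = 50000,
                                primer_sites = NULL) {
  if (n_copies < 1) abort("n_copies must be >= 1")
  if (linked_fraction < 0 || linked_fraction > 1) {
    abort("linked_fraction must be in [0, 1]")
  }
  if (its_length >= 1500) abort("its_length must be < 1500 (linked by definition)")
  if (unlinked_gap <= 1500) abort("unlinked_gap must be > 1500")
  sites <- setNames(rep(TRUE, 4), default_primers()$name)
  if (!is.null(primer_sites)) {
    bad <- setdiff(names(primer_sites), names(sites))
    if (length(bad) > 0) {
      abort(paste0("unknown primer name(s): ", paste(bad, collapse = ", ")))
    }
    sites[names(primer_sites)] <- primer_sites
  }
  structure(
    list(n_copies = as.integer(n_copies), linked_fraction = linked_fraction,
         n_linked = as.integer(round(n_copies * linked_fraction)),
         its_length = as.integer(its_length),
         unlinked_gap = as.integer(unlinked_gap), primer_sites = sites),
    class = "operon_architecture"
  )
}

#' Define one community member
#'
#' Builds the lineage from the species epithet when rank names are not
#' given: the genus defaults to the first word of `species` and higher
#' ranks get systematic suffixes, so distinct species are distinct at every
#' rank unless the caller says otherwise.
#'
#' @param species Species name (used as the record description).
#' @param abundance Expected relative abundance fraction.
#' @param architecture An [operon_architecture()].
#' @param taxid Positive integer taxid; must be unique within a community.
#' @param genus,family,order,class,phylum,superkingdom Optional rank names.
#' @return One-row tibble describing the member.
#' @export
community_member <- function(species, abundance,
                             architecture = operon_architecture(),
                             taxid,
                             genus = NULL, family = NULL, order = NULL,
                             class = NULL, phylum = NULL,
                             superkingdom = "Bacteria") {
  genus <- genus %||% strsplit(species, " ")[[1]][1]
  family <- family %||% paste0(genus, "aceae")
  order <- order %||% paste0(genus, "ales")
  class <- class %||% paste0(genus, "ia")
  phylum <- phylum %||% paste0(genus, "ota")
  tibble(
    taxid = as.integer(taxid),
    accession = sprintf("SYN_%06d.1", as.integer(taxid)),
    abundance = abundance,
    superkingdom = superkingdom, phylum = phylum, class = class,
    order = order, family = family, genus = genus, species = species,
    architecture = list(architecture)
  )
}

#' Assemble and validate a community specification
#'
#' @param members Tibble of rows from [community_member()] (bind them with
#'   `dplyr::bind_rows()`).
#' @return A `community_spec` object.
#' @export
community_spec <- function(members) {
  members <- as_tibble(members)
  bad <- members$abundance < 0 | members$abundance > 1 |
    !is.finite(members$abundance)
  if (any(bad)) {
    abort(paste0("invalid abundance for member(s): ",
                 paste(members$species[bad], collapse = ", ")))
  }
  if (abs(sum(members$abundance) - 1) > 1e-9) {
    abort(sprintf("member abundances must sum to 1 (got %.12f)",
                  sum(members$abundance)))
  }
  if (anyDuplicated(members$taxid) > 0) {
    abort("member taxids must be distinct")
  }
  structure(list(members = members), class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> ", nrow(x$members), " members\n", sep = "")
  print(dplyr::select(x$members, "taxid", "species", "abundance"))
  invisible(x)
}

#' Taxonomy table of a community specification
#' @param spec A `community_spec`.
#' @return A validated taxonomy tibble (accession, taxid, seven ranks).
#' @export
spec_taxonomy <- function(spec) {
  validate_taxonomy(
    dplyr::select(spec$members, "accession", "taxid",
                  dplyr::all_of(RANKS))
  )
}
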