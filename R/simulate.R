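#' Read error model
#'
#' Per-base substitution, insertion and deletion probabilities applied
#' independently, with phred+33 quality strings centred on the phred score
#' of the total error rate (+/- `quality_jitter`). This is a lightweight
#' stand-in for long-read error characteristics: it reproduces the rate and
#' the quality-score bookkeeping, not signal-level or homopolymer effects.
#'
#' @param substitution,insertion,deletion Per-base rates in \[0, 0.2\].
#' @param quality_jitter Half-width of the uniform jitter on per-base phred
#'   scores (integer >= 0).
#' @return An `error_model` object.
#' @export
error_model <- function(substitution = 0.005, insertion = 0.0025,
                        deletion = 0.0025, quality_jitter = 3) {
  rates <- c(substitution, insertion, deletion)
  if (any(rates < 0) || any(rates > 0.2)) {
    abort("error rates must lie in [0, 0.2]")
  }
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion,
                 quality_jitter = as.integer(quality_jitter)),
            class = "error_model")
}

#' Error-free model (identity sequences, maximum quality)
#' @return An `error_model` with all rates zero.
#' @export
perfect_reads <- function() error_model(0, 0, 0, quality_jitter = 0)

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant <- function(seq, site, at) {
  substr(seq, at, at + nchar(site) - 1L) <- site
  seq
}

# Geometry of the synthetic marker genes. The 16S carries the 27F site at
# its 5' end, the A519F site internally and the 1492R site at its 3' end;
# the 23S carries the U2428R site near its 3' end. The operon amplicon
# (A519F -> U2428R) therefore spans the ITS and lands in the 3500-5000 bp
# window for linked copies, while the 16S amplicon (27F -> 1492R) is
# 1500 bp regardless of linkage.
GENE_GEOM <- list(len_16s = 1500L, len_23s = 2900L, len_5s = 120L,
                  pos_27f = 1L, pos_a519f = 501L, gap_5s = 80L,
                  tail_23s = 30L)

make_marker_genes <- function(sites) {
  p <- default_primers()
  g <- GENE_GEOM
  s16 <- rand_seq(g$len_16s)
  if (sites[["27F"]]) {
    s16 <- plant(s16, realize_iupac(p$seq[p$name == "27F"]), g$pos_27f)
  }
  if (sites[["A519F"]]) {
    s16 <- plant(s16, realize_iupac(p$seq[p$name == "A519F"]), g$pos_a519f)
  }
  if (sites[["1492R"]]) {
    site <- revcomp(realize_iupac(p$seq[p$name == "1492R"]))
    s16 <- plant(s16, site, g$len_16s - nchar(site) + 1L)
  }
  s23 <- rand_seq(g$len_23s)
  if (sites[["U2428R"]]) {
    site <- revcomp(realize_iupac(p$seq[p$name == "U2428R"]))
    s23 <- plant(s23, site, g$len_23s - g$tail_23s - nchar(site) + 1L)
  }
  list(s16 = s16, s23 = s23, s5 = rand_seq(g$len_5s))
}

#' Generate a ground-truth synthetic community
#'
#' Builds one genome per community member with the requested rRNA operon
#' architecture: `round(n_copies * linked_fraction)` linked copies
#' (16S-ITS-23S-5S with a short ITS) and the remainder unlinked (23S placed
#' `unlinked_gap` bp downstream of the 16S). Marker genes are random
#' sequences with planted primer binding sites, identical across the copies
#' of one genome and distinct between members, so that downstream k-mer
#' classification can tell members apart without licensed reference data.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed; output is deterministic given `spec` and
#'   `seed`.
#' @return A `synthetic_community`: list with tibbles `genomes`
#'   (`accession`, `taxid`, `description`, `seq`), `annotations` (GFF3-style
#'   1-based `seqid`, `type`, `start`, `end`, `strand`, `copy_id`,
#'   `linked`), `taxonomy`, and the `spec`.
#' @export
generate_community <- function(spec, seed) {
  stopifnot(inherits(spec, "community_spec"))
  g <- GENE_GEOM
  withr::with_seed(seed, {
    genomes <- list(); annots <- list()
    for (i in seq_len(nrow(spec$members))) {
      m <- spec$members[i, ]
      arch <- m$architecture[[1]]
      genes <- make_marker_genes(arch$primer_sites)
      segs <- character(0); pos <- 0L; rows <- list()
      add <- function(s) {
        segs[[length(segs) + 1L]] <<- s
        st <- pos + 1L; pos <<- pos + nchar(s)
        c(st, pos)
      }
      ann <- function(type, span, copy, linked) {
        rows[[length(rows) + 1L]] <<- tibble(
          seqid = m$accession, type = type, start = span[1], end = span[2],
          strand = "+", copy_id = sprintf("%s_c%d", m$accession, copy),
          linked = linked)
      }
      add(rand_seq(1000L))
      for (copy in seq_len(arch$n_copies)) {
        linked <- copy <= arch$n_linked
        ann("16S_rRNA", add(genes$s16), copy, linked)
        add(rand_seq(if (linked) arch$its_length else arch$unlinked_gap))
        ann("23S_rRNA", add(genes$s23), copy, linked)
        add(rand_seq(g$gap_5s))
        ann("5S_rRNA", add(genes$s5), copy, linked)
        # inter-operon spacing well above the 2000 bp chaining threshold,
        # so distinct copies become distinct database records
        add(rand_seq(3000L))
      }
      genomes[[i]] <- tibble(
        accession = m$accession, taxid = m$taxid, description = m$species,
        seq = paste(unlist(segs), collapse = ""))
      annots[[i]] <- dplyr::bind_rows(rows)
    }
    structure(
      list(genomes = dplyr::bind_rows(genomes),
           annotations = dplyr::bind_rows(annots),
           taxonomy = spec_taxonomy(spec), spec = spec),
      class = "synthetic_community")
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community> ", nrow(x$genomes), " genomes, ",
      nrow(x$annotations), " rRNA annotations\n", sep = "")
  invisible(x)
}

#' Write a synthetic community to FASTA + GFF3 + taxonomy TSV
#'
#' @param community A `synthetic_community`.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_community <- function(community, dir, prefix = "community") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  tax <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
  write_fasta_tbl(
    dplyr::transmute(community$genomes, id = .data$accession,
                     description = paste(.data$accession, .data$description),
                     seq = .data$seq), fa)
  write_rrna_gff3(community$annotations, gff)
  write_taxonomy(community$taxonomy, tax)
  invisible(c(fasta = fa, gff3 = gff, taxonomy = tax))
}

apply_error_model <- function(seqs, model) {
  out <- cpp_mutate_reads(seqs, model$substitution, model$insertion,
                          model$deletion, model$quality_jitter)
  tibble(seq = out$seq, qual = out$qual)
}

#' Simulate amplicon long reads from a synthetic community
#'
#' Each member genome is screened with [in_silico_pcr()]; only copies where
#' both primers bind within `max_length` can yield reads, so unlinked rRNA
#' copies are invisible to an operon-spanning primer pair and members
#' lacking a primer site yield nothing. Sampling weight is member abundance
#' times its number of amplifiable copies.
#'
#' @param community A `synthetic_community` from [generate_community()].
#' @param primers Named character vector `c(fwd=, rev=)`, e.g.
#'   [primer_pair()].
#' @param n_reads Number of reads to draw (>= 1).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param max_mismatch Mismatches tolerated per primer site.
#' @param max_length Longest amplifiable product in bp.
#' @return An `amplicon_sim`: list with `reads` (tibble `read_id`, `seq`,
#'   `qual`), `truth` (tibble `read_id`, `taxid`, `accession`, `copy_id`,
#'   `start`, `end`), and `status` (`"ok"` or
#'   `"no_amplifiable_template"`).
#' @export
simulate_amplicon_reads <- function(community, primers, n_reads, model = error_model(),
                                    seed = 1, max_mismatch = 2,
                                    max_length = 6000) {
  stopifnot(inherits(community, "synthetic_community"), n_reads >= 1)
  members <- community$spec$members
  templates <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
    m <- members[i, ]
    gseq <- community$genomes$seq[community$genomes$accession == m$accession]
    amps <- in_silico_pcr(gseq, primers[["fwd"]], primers[["rev"]],
                          max_mismatch = max_mismatch,
                          max_length = max_length)
    if (nrow(amps) == 0) return(NULL)
    # copy whose 16S contains the forward site, for truth bookkeeping
    ann16 <- dplyr::filter(community$annotations,
                           .data$seqid == m$accession,
                           .data$type == "16S_rRNA")
    copy <- vapply(amps$start, function(s) {
      hit <- which(ann16$start <= s & ann16$end >= s)
      if (length(hit) > 0) ann16$copy_id[hit[1]] else NA_character_
    }, character(1))
    tibble(taxid = m$taxid, accession = m$accession,
           abundance = m$abundance, copy_id = copy,
           start = amps$start, end = amps$end,
           template = substring(gseq, amps$start, amps$end))
  })
  if (nrow(templates) == 0) {
    return(structure(list(
      reads = tibble(read_id = character(), seq = character(),
                     qual = character()),
      truth = tibble(read_id = character(), taxid = integer(),
                     accession = character(), copy_id = character(),
                     start = integer(), end = integer()),
      status = "no_amplifiable_template"), class = "amplicon_sim"))
  }
  withr::with_seed(seed, {
    idx <- sample(nrow(templates), n_reads, replace = TRUE,
                  prob = templates$abundance)
    mut <- apply_error_model(templates$template[idx], model)
    ids <- sprintf("amp_%06d", seq_len(n_reads))
    structure(list(
      reads = tibble(read_id = ids, seq = mut$seq, qual = mut$qual),
      truth = tibble(read_id = ids, taxid = templates$taxid[idx],
                     accession = templates$accession[idx],
                     copy_id = templates$copy_id[idx],
                     start = templates$start[idx],
                     end = templates$end[idx]),
      status = "ok"), class = "amplicon_sim")
  })
}

#' Shotgun fragment length model
#'
#' Log-normal read lengths clipped to `[min, max]` (and to the genome
#' length at draw time).
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @param min,max Length bounds in bp.
#' @return A `length_model` list.
#' @export
shotgun_length_model <- function(meanlog = log(3000), sdlog = 0.35,
                                 min = 1000, max = 20000) {
  if (min < 1 || max < min) abort("invalid length bounds")
  structure(list(meanlog = meanlog, sdlog = sdlog, min = as.integer(min),
                 max = as.integer(max)), class = "length_model")
}

#' Simulate shotgun long reads from a synthetic community
#'
#' Fragments are placed uniformly along genomes; member weight is abundance
#' times genome length. rRNA gene annotations overlapping each fragment are
#' reported in read coordinates (strand-adjusted, clipped to the read, with
#' a `partial` flag), which feeds the read-level linkage classifier. The
#' reported coordinates refer to the error-free fragment; indels in the
#' error model shift true positions slightly.
#'
#' @param community A `synthetic_community`.
#' @param n_reads Number of fragments.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param length_model A [shotgun_length_model()].
#' @param both_strands Draw fragments from both strands (default TRUE).
#' @return A `shotgun_sim`: list with `reads`, `truth` (tibble `read_id`,
#'   `taxid`, `accession`, `start`, `end`, `strand`, `length`), and
#'   `annotations` (tibble `read_id`, `type`, `start`, `end`, `strand`,
#'   `partial`, `copy_id`, `linked` in read coordinates).
#' @export
simulate_shotgun_reads <- function(community, n_reads, model = error_model(),
                                   seed = 1,
                                   length_model = shotgun_length_model(),
                                   both_strands = TRUE) {
  stopifnot(inherits(community, "synthetic_community"), n_reads >= 1)
  genomes <- community$genomes
  glen <- nchar(genomes$seq)
  if (length_model$min > max(glen)) {
    abort(sprintf("minimum fragment length (%d) exceeds every genome length (max %d)",
                  length_model$min, max(glen)))
  }
  members <- community$spec$members
  w <- members$abundance[match(genomes$accession, members$accession)] * glen
  withr::with_seed(seed, {
    gi <- sample(length(glen), n_reads, replace = TRUE, prob = w)
    len <- pmin(pmax(round(stats::rlnorm(n_reads, length_model$meanlog,
                                         length_model$sdlog)),
                     length_model$min), length_model$max)
    len <- pmin(len, glen[gi])
    s <- floor(runif(n_reads, 1, glen[gi] - len + 1 + 1))
    e <- s + len - 1L
    strand <- if (both_strands) sample(c("+", "-"), n_reads, replace = TRUE)
              else rep("+", n_reads)
    raw <- substring(genomes$seq[gi], s, e)
    raw[strand == "-"] <- revcomp(raw[strand == "-"])
    mut <- apply_error_model(raw, model)
    ids <- sprintf("shot_%06d", seq_len(n_reads))
    truth <- tibble(read_id = ids, taxid = genomes$taxid[gi],
                    accession = genomes$accession[gi],
                    start = as.integer(s), end = as.integer(e),
                    strand = strand, length = as.integer(len))
    reads <- tibble(read_id = ids, seq = mut$seq, qual = mut$qual)
    ann <- dplyr::inner_join(
      dplyr::rename(truth, g_start = "start", g_end = "end",
                    read_strand = "strand"),
      dplyr::rename(community$annotations, accession = "seqid",
                    a_start = "start", a_end = "end", a_strand = "strand"),
      by = "accession", relationship = "many-to-many")
    ann <- dplyr::filter(ann, .data$a_start <= .data$g_end,
                         .data$a_end >= .data$g_start)
    ann <- dplyr::mutate(ann,
      cs = pmax(.data$a_start, .data$g_start),
      ce = pmin(.data$a_end, .data$g_end),
      partial = .data$a_start < .data$g_start | .data$a_end > .data$g_end,
      start = ifelse(.data$read_strand == "+", .data$cs - .data$g_start + 1L,
                     .data$g_end - .data$ce + 1L),
      end = ifelse(.data$read_strand == "+", .data$ce - .data$g_start + 1L,
                   .data$g_end - .data$cs + 1L),
      strand = ifelse(.data$read_strand == "+", .data$a_strand,
                      chartr("+-", "-+", .data$a_strand)))
    ann <- dplyr::arrange(
      dplyr::select(ann, "read_id", "type", "start", "end", "strand",
                    "partial", "copy_id", "linked"),
      .data$read_id, .data$start)
    structure(list(reads = reads, truth = truth, annotations = ann,
                   status = "ok"), class = "shotgun_sim")
  })
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat("<amplicon_sim> ", nrow(x$reads), " reads (status: ", x$status, ")\n",
      sep = "")
  invisible(x)
}

#' @export
print.shotgun_sim <- function(x, ...) {
  cat("<shotgun_sim> ", nrow(x$reads), " reads\n", sep = "")
  invisible(x)
}
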