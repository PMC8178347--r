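test_that("a single-member single-copy spec yields one linked operon", {
  spec <- community_spec(
    community_member("Solus unus", 1,
                     operon_architecture(n_copies = 1, linked_fraction = 1,
                                         its_length = 400),
                     taxid = 7))
  comm <- generate_community(spec, seed = 3)
  ann <- comm$annotations
  expect_equal(sum(ann$type == "16S_rRNA"), 1)
  expect_equal(sum(ann$type == "23S_rRNA"), 1)
  gap <- ann$start[ann$type == "23S_rRNA"] - ann$end[ann$type == "16S_rRNA"] - 1
  expect_lte(gap, 1500)
  expect_equal(gap, 400)
})

test_that("copy counts and linked/unlinked layout follow the architecture", {
  spec <- two_member_spec(linked_fraction = 0.5, n_copies = 4)
  comm <- generate_community(spec, seed = 9)
  for (acc in comm$genomes$accession) {
    ann <- dplyr::filter(comm$annotations, seqid == acc)
    expect_equal(sum(ann$type == "16S_rRNA"), 4)
    expect_equal(sum(ann$type == "23S_rRNA"), 4)
  }
  mixed_acc <- comm$genomes$accession[comm$genomes$taxid == 101]
  typed <- type_genome(dplyr::filter(comm$annotations, seqid == mixed_acc),
                       nchar(comm$genomes$seq[comm$genomes$accession ==
                                                mixed_acc]))
  expect_equal(typed$type, "mixed")
  expect_equal(typed$n_linked, 2)
  expect_equal(typed$n_unlinked, 2)
})

test_that("generation and simulation are deterministic for a fixed seed", {
  spec <- two_member_spec()
  c1 <- generate_community(spec, seed = 21)
  c2 <- generate_community(spec, seed = 21)
  expect_identical(c1$genomes, c2$genomes)
  expect_identical(c1$annotations, c2$annotations)
  s1 <- simulate_amplicon_reads(c1, primer_pair("rrn"), 100, seed = 5)
  s2 <- simulate_amplicon_reads(c2, primer_pair("rrn"), 100, seed = 5)
  expect_identical(s1$reads, s2$reads)
  g1 <- simulate_shotgun_reads(c1, 100, seed = 5)
  g2 <- simulate_shotgun_reads(c2, 100, seed = 5)
  expect_identical(g1$reads, g2$reads)
  # byte-identical files
  d <- withr::local_tempdir()
  p1 <- write_community(c1, file.path(d, "a"))
  p2 <- write_community(c2, file.path(d, "b"))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  f1 <- file.path(d, "r1.fastq"); f2 <- file.path(d, "r2.fastq")
  write_fastq_tbl(s1$reads, f1); write_fastq_tbl(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid abundances name the offending member", {
  expect_error(
    community_spec(dplyr::bind_rows(
      community_member("Malus malus", -0.2, taxid = 1),
      community_member("Bonus bonus", 1.2, taxid = 2))),
    "Malus malus")
  expect_error(
    community_spec(dplyr::bind_rows(
      community_member("Unus", 0.6, taxid = 1),
      community_member("Duo", 0.6, taxid = 2))),
    "sum to 1")
})

test_that("error-free amplicon reads equal their template substrings", {
  spec <- community_spec(
    community_member("Solus unus", 1, operon_architecture(n_copies = 2),
                     taxid = 7))
  comm <- generate_community(spec, seed = 13)
  sim <- simulate_amplicon_reads(comm, primer_pair("rrn"), 50,
                                 model = perfect_reads(), seed = 2)
  expect_equal(sim$status, "ok")
  gseq <- comm$genomes$seq[1]
  for (i in seq_len(nrow(sim$reads))) {
    expect_identical(sim$reads$seq[i],
                     substring(gseq, sim$truth$start[i], sim$truth$end[i]))
  }
  # qualities at maximum for an error-free model
  expect_true(all(mean_read_quality(sim$reads$qual) == 41))
})

test_that("primer-site absence gates amplification", {
  spec <- archaeal_spec()
  comm <- generate_community(spec, seed = 31)
  sim16 <- simulate_amplicon_reads(comm, primer_pair("16S"), 2000, seed = 4)
  expect_equal(sum(sim16$truth$taxid == 304), 0)
  simrrn <- simulate_amplicon_reads(comm, primer_pair("rrn"), 2000, seed = 4)
  expect_gt(sum(simrrn$truth$taxid == 304), 0)
  # nothing amplifiable at all -> explicit status
  none <- community_spec(
    community_member("Nullus nullus", 1,
                     operon_architecture(
                       n_copies = 1,
                       primer_sites = c("27F" = FALSE, "1492R" = FALSE)),
                     taxid = 9))
  sim0 <- simulate_amplicon_reads(generate_community(none, 1),
                                  primer_pair("16S"), 100, seed = 1)
  expect_equal(sim0$status, "no_amplifiable_template")
  expect_equal(nrow(sim0$reads), 0)
})

test_that("amplicon sampling weights follow abundance x amplifiable copies", {
  spec <- two_member_spec(linked_fraction = 0.25, n_copies = 4)
  comm <- generate_community(spec, seed = 17)
  n <- 10000
  sim <- simulate_amplicon_reads(comm, primer_pair("rrn"), n,
                                 model = perfect_reads(), seed = 8)
  # mixed member amplifies 1 copy, competitor 4; equal abundance
  p_expect <- 1 / 5
  p_obs <- mean(sim$truth$taxid == 101)
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_obs - p_expect), 4 * se)
})

test_that("unlinked copies are invisible to operon-spanning primers", {
  spec <- two_member_spec(linked_fraction = 0.5, n_copies = 4)
  comm <- generate_community(spec, seed = 23)
  sim <- simulate_amplicon_reads(comm, primer_pair("rrn"), 2000, seed = 3)
  linked_copies <- comm$annotations |>
    dplyr::filter(type == "16S_rRNA", linked) |>
    dplyr::pull(copy_id)
  expect_true(all(sim$truth$copy_id %in% linked_copies))
  expect_true(all(nchar(sim$reads$seq) < 6000))
})

test_that("truth tables partition reads", {
  comm <- generate_community(two_member_spec(), seed = 2)
  sim <- simulate_amplicon_reads(comm, primer_pair("16S"), 500, seed = 1)
  expect_equal(nrow(sim$truth), 500)
  expect_equal(anyDuplicated(sim$truth$read_id), 0)
  expect_setequal(sim$truth$read_id, sim$reads$read_id)
  shot <- simulate_shotgun_reads(comm, 500, seed = 1)
  expect_equal(nrow(shot$truth), 500)
  expect_equal(anyDuplicated(shot$truth$read_id), 0)
})

test_that("shotgun read annotations preserve gene content in read coords", {
  spec <- community_spec(
    community_member("Solus unus", 1,
                     operon_architecture(n_copies = 3, linked_fraction = 1,
                                         its_length = 350),
                     taxid = 7))
  comm <- generate_community(spec, seed = 41)
  shot <- simulate_shotgun_reads(
    comm, 400, model = perfect_reads(), seed = 6,
    length_model = shotgun_length_model(meanlog = log(6000), sdlog = 0.2))
  gseq <- comm$genomes$seq[1]
  full <- dplyr::filter(shot$annotations, !partial)
  expect_gt(nrow(full), 0)
  checked <- dplyr::inner_join(full, shot$truth, by = "read_id") |>
    dplyr::slice_head(n = 40)
  gann <- comm$annotations
  for (i in seq_len(nrow(checked))) {
    row <- checked[i, ]
    read_seq <- shot$reads$seq[shot$reads$read_id == row$read_id]
    got <- substring(read_seq, row$start.x, row$end.x)
    if (row$strand.x == "-") got <- revcomp(got)
    src <- dplyr::filter(gann, copy_id == row$copy_id,
                         type == row$type)
    want <- substring(gseq, src$start, src$end)
    expect_identical(got, want)
  }
  # a read covering a full linked 16S and 23S keeps the ITS gap
  by_read <- split(full, full$read_id)
  spanning <- Filter(function(a) {
    any(a$type == "16S_rRNA") && any(a$type == "23S_rRNA")
  }, by_read)
  expect_gt(length(spanning), 0)
  a <- spanning[[1]]
  s16 <- a[a$type == "16S_rRNA", ][1, ]
  s23 <- a[a$type == "23S_rRNA", ][1, ]
  gap <- if (s16$start < s23$start) s23$start - s16$end - 1
         else s16$start - s23$end - 1
  expect_equal(gap, 350)
})

test_that("impossible fragment lengths are rejected", {
  comm <- generate_community(two_member_spec(), seed = 2)
  expect_error(
    simulate_shotgun_reads(comm, 10, length_model =
                             shotgun_length_model(min = 5e6, max = 6e6)),
    "exceeds every genome length")
})
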