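test_that("gene chaining follows the strict intergenic-distance rule", {
  genes <- dplyr::bind_rows(
    gene_row("c1", "16S_rRNA", 1, 1500),
    gene_row("c1", "23S_rRNA", 1800, 4700),
    gene_row("c1", "5S_rRNA", 4800, 4920))
  chains <- chain_rrna_genes(genes)
  expect_equal(chains$chain, c(1L, 1L, 1L))

  # intervening distance exactly 2000 splits (strict <)
  split2 <- chain_rrna_genes(dplyr::bind_rows(
    gene_row("c1", "16S_rRNA", 1, 1500),
    gene_row("c1", "23S_rRNA", 3501, 6400)))
  expect_equal(split2$chain, c(1L, 2L))
  # 1999 merges
  merged <- chain_rrna_genes(dplyr::bind_rows(
    gene_row("c1", "16S_rRNA", 1, 1500),
    gene_row("c1", "23S_rRNA", 3500, 6400)))
  expect_equal(merged$chain, c(1L, 1L))
})

test_that("singletons, strand breaks and contig mixing behave", {
  one <- chain_rrna_genes(gene_row("c1", "16S_rRNA", 5, 1400))
  expect_equal(one$chain, 1L)
  # opposite strands never merge even when adjacent
  opp <- chain_rrna_genes(dplyr::bind_rows(
    gene_row("c1", "16S_rRNA", 1, 1500, "+"),
    gene_row("c1", "23S_rRNA", 1600, 4500, "-")))
  expect_equal(opp$chain, c(1L, 2L))
  expect_error(chain_rrna_genes(dplyr::bind_rows(
    gene_row("c1", "16S_rRNA", 1, 1500),
    gene_row("c2", "23S_rRNA", 1800, 4700))), "single contig")
})

test_that("chaining partitions genes and is shuffle-invariant", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      n <- sample(2:12, 1)
      starts <- sort(sample(1:60000, n))
      genes <- tibble::tibble(
        seqid = "c1",
        type = sample(c("16S_rRNA", "23S_rRNA", "5S_rRNA"), n, TRUE),
        start = starts,
        end = starts + sample(100:2900, n, TRUE),
        strand = sample(c("+", "-"), n, TRUE))
      # avoid pathological overlaps for a clean partition check
      genes$end <- pmin(genes$end, c(genes$start[-1] - 1L, Inf))
      base <- chain_rrna_genes(genes)
      expect_equal(nrow(base), n)
      expect_equal(sum(table(base$chain)), n)
      shuf <- chain_rrna_genes(genes[sample(n), ])
      expect_identical(base, shuf)
    }
  })
})

test_that("operon spans include spacers and honor strand", {
  seq <- paste(rep(c("A", "C", "G", "T"), length.out = 6000), collapse = "")
  genes <- chain_rrna_genes(dplyr::bind_rows(
    gene_row("c1", "16S_rRNA", 1, 1500),
    gene_row("c1", "23S_rRNA", 1800, 4700),
    gene_row("c1", "5S_rRNA", 4800, 4920)))
  spans <- extract_operon_sequences(seq, genes)
  expect_equal(spans$length, 4920L)
  expect_identical(spans$seq, substring(seq, 1, 4920))
  expect_equal(spans$member_genes, "16S_rRNA,23S_rRNA,5S_rRNA")

  solo <- extract_operon_sequences(seq,
    chain_rrna_genes(gene_row("c1", "16S_rRNA", 1, 1500)))
  expect_equal(solo$length, 1500L)

  minus <- extract_operon_sequences(seq, chain_rrna_genes(dplyr::bind_rows(
    gene_row("c1", "23S_rRNA", 101, 3000, "-"),
    gene_row("c1", "16S_rRNA", 3301, 4800, "-"))))
  expect_identical(minus$seq, revcomp(substring(seq, 101, 4800)))
  expect_equal(minus$member_genes, "16S_rRNA,23S_rRNA")

  expect_error(
    extract_operon_sequences(substring(seq, 1, 4000), genes), "bounds")
})

make_tiny_db_inputs <- function(lengths = c(999, 1000, 4500)) {
  withr::with_seed(99, {
    genomes <- tibble::tibble(
      accession = paste0("ACC", seq_along(lengths)),
      seq = vapply(lengths + 200,
                   function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                     collapse = ""), character(1)))
    annotations <- tibble::tibble(
      seqid = genomes$accession, type = "16S_rRNA", start = 101L,
      end = as.integer(100 + lengths), strand = "+")
    taxonomy <- tibble::tibble(
      accession = genomes$accession, taxid = seq_along(lengths),
      superkingdom = "Bacteria", phylum = "P", class = "C", order = "O",
      family = "F", genus = paste0("G", seq_along(lengths)),
      species = paste0("G", seq_along(lengths), " sp", seq_along(lengths)))
    list(genomes = genomes, annotations = annotations, taxonomy = taxonomy)
  })
}

test_that("the length filter keeps exactly min_length and drops below", {
  x <- make_tiny_db_inputs(c(999, 1000, 4500))
  db <- build_operon_db(x$genomes, x$annotations, x$taxonomy)
  expect_equal(nrow(db$records), 2)
  expect_setequal(db$records$length, c(1000L, 4500L))
})

test_that("taxon exclusion removes a species from the database", {
  x <- make_tiny_db_inputs(rep(2000, 5))
  db_full <- build_operon_db(x$genomes, x$annotations, x$taxonomy)
  db_ablate <- build_operon_db(x$genomes, x$annotations, x$taxonomy,
                               exclude_taxa = "G2 sp2")
  expect_equal(nrow(db_full$records), 5)
  expect_equal(nrow(db_ablate$records), 4)
  expect_false("G2 sp2" %in% db_ablate$records$description)
  expect_equal(db_stats(db_full)$n_species - db_stats(db_ablate)$n_species, 1)
  # exclusion by taxid works too
  by_id <- build_operon_db(x$genomes, x$annotations, x$taxonomy,
                           exclude_taxa = "2")
  expect_identical(by_id$records$db_id, db_ablate$records$db_id)
})

test_that("empty inputs and missing taxonomy entries are handled", {
  x <- make_tiny_db_inputs(2000)
  empty <- build_operon_db(x$genomes[0, ], x$annotations[0, ], x$taxonomy)
  expect_s3_class(empty, "operon_db")
  expect_equal(nrow(empty$records), 0)
  expect_equal(db_stats(empty)$n_sequences, 0)
  expect_error(
    build_operon_db(dplyr::mutate(x$genomes, accession = "UNKNOWN"),
                    x$annotations, x$taxonomy),
    "UNKNOWN")
})

test_that("linked copies yield operon records, unlinked yield split records", {
  spec <- two_member_spec(linked_fraction = 0.5, n_copies = 4)
  comm <- generate_community(spec, seed = 53)
  db <- build_operon_db(comm$genomes, comm$annotations, comm$taxonomy)
  mixed <- dplyr::filter(db$records, taxid == 101)
  full_ops <- dplyr::filter(mixed, grepl("16S", member_genes) &
                              grepl("23S", member_genes))
  only16 <- dplyr::filter(mixed, member_genes == "16S_rRNA")
  expect_equal(nrow(full_ops), 2)  # the linked copies
  expect_equal(nrow(only16), 2)    # unlinked 16S singletons
  expect_true(all(dplyr::filter(db$records, taxid == 102) |>
                    dplyr::pull(member_genes) ==
                    "16S_rRNA,23S_rRNA,5S_rRNA"))
})

test_that("database round-trips through FASTA + sidecar", {
  x <- make_tiny_db_inputs(c(1500, 2500))
  db <- build_operon_db(x$genomes, x$annotations, x$taxonomy,
                        exclude_taxa = character())
  d <- withr::local_tempdir()
  path <- file.path(d, "db.fasta")
  write_operon_db(db, path)
  headers <- grep("^>", readLines(path), value = TRUE)
  expect_identical(headers,
                   paste0(">", db$records$db_id, " ",
                          db$records$description))
  back <- read_operon_db(path)
  expect_identical(back$records$seq, db$records$seq)
  expect_identical(back$records$db_id, db$records$db_id)
  expect_identical(back$taxonomy$species, db$taxonomy$species)
  expect_equal(back$params$min_length, db$params$min_length)
})

test_that("database stats count distinct species and genera", {
  x <- make_tiny_db_inputs(c(1500, 2500))
  # same species on both contigs
  x$taxonomy$species <- "G1 sp1"
  x$taxonomy$genus <- "G1"
  x$taxonomy$taxid <- c(1L, 1L)
  db <- build_operon_db(x$genomes, x$annotations, x$taxonomy)
  s <- db_stats(db)
  expect_equal(s$n_sequences, 2)
  expect_equal(s$n_species, 1)
  expect_equal(s$n_genera, 1)
})
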