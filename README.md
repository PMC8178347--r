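# operonkit

Toolkit for long-read metagenomic profiling of the bacterial and archaeal
**16S-ITS-23S rRNA operon**, and for measuring the two systematic biases
of operon-spanning amplicons: **unlinked rRNA genes** (a 16S whose 23S
lies > 1500 bp downstream, or out of reach entirely, cannot be amplified
as one operon) and **primer coverage** (a bacterial 16S primer pair such
as 27F + 1492R misses archaea that the operon pair A519F + U2428R and
shotgun sequencing both detect).

It is written for microbiome researchers who want to benchmark or sanity
check an rRNA-operon amplicon workflow — database construction,
filtering, assignment, mock-community scoring, multivariate statistics —
without depending on external sequencing data: a synthetic-community
simulator with configurable operon architectures provides ground truth
for every stage.

## What it does

* **Reference databases** (`build_operon_db`): chains rRNA genes on a
  contig when the intergenic distance is < 2000 bp (same strand),
  extracts the genomic span including spacers, drops records < 1000 bp,
  and writes FASTA with `taxid|accession description` headers plus a
  JSON sidecar. Species can be excluded for database-ablation
  experiments.
* **Linkage classification** (`classify_16s_linkage`, `screen_reads`,
  `type_genome`): a 16S is *linked* when a same-strand 23S starts within
  1500 bp downstream, *unlinked* when the gap exceeds 1500 bp or enough
  sequence was visible with no 23S, *unjudgeable* when the read ends too
  soon; genomes with both linked and unlinked copies are *mixed type*.
* **Read QC** (`filter_reads`, `subsample_reads`): error-probability
  mean quality, named presets for the published 16S / operon / shotgun
  filter chains, seeded subsampling.
* **Assignment** (`assign_reads`, `profile_sample`): a deliberately
  simple canonical k-mer matcher with lowest-common-ancestor tie-breaking
  and monotone rank thresholds — a documented stand-in for a KMA +
  CCMetagen style pipeline that preserves its conservative
  rank-degradation behaviour.
* **Evaluation** (`mock_dissimilarity`, `mis_or_unidentified`,
  `count_misidentified_taxa`, `accumulation_curve`): Bray–Curtis
  dissimilarity `Σ|x−y| / Σ(x+y)` to an expected mock composition,
  off-target percentages and counts, taxon-accumulation curves.
* **Statistics** (`bray_curtis_matrix`, `permanova`): a from-scratch
  multi-factor PERMANOVA with Gower centring, sequential (Type-I) sums of
  squares, pseudo-F against the residual, free-permutation p-values with
  the add-one convention, and exact enumeration for small designs. The
  decomposition table reports Df, SS, MS, F, R² and p; `tidy()` /
  `glance()` methods and `autoplot()` helpers follow tidyverse
  conventions throughout.
* **Simulation** (`generate_community`, `simulate_amplicon_reads`,
  `simulate_shotgun_reads`, `in_silico_pcr`): genomes with configurable
  linked/unlinked/mixed operon architectures, degenerate-primer in-silico
  PCR gating, nanopore-like per-base error model with phred+33 quality
  strings, and read-coordinate rRNA annotations with truth tables.

A thin command-line wrapper (`inst/exec/operonkit`, subcommands
`simulate`, `build-db`, `qc`, `classify`, `linkage`, `evaluate`,
`permanova`) exposes the same functions for shell pipelines.

## Worked example

Simulate the shipped five-member demo community (one member of mixed
linked/unlinked architecture, one archaea-like member lacking the 27F
primer site), build a database from its genomes, and profile its operon
amplicons:

```r
library(operonkit)
library(dplyr)

spec <- read_community_yaml(system.file("extdata", "demo_community.yaml",
                                        package = "operonkit"))
comm <- generate_community(spec, seed = 42)
db   <- build_operon_db(comm$genomes, comm$annotations, comm$taxonomy)
db
#> <operon_db> 19 records; 5 species, 5 genera

sim <- simulate_amplicon_reads(comm, primer_pair("rrn"), n_reads = 2000,
                               seed = 42)
qc  <- filter_reads(sim$reads, qc_presets("mock_rrn"))
asg <- assign_reads(qc$passed, db)
prof <- profile_sample(asg)
filter(prof, rank == "species")
#> # A tibble: 5 × 4
#>   rank    taxon               abundance n_reads
#>   <chr>   <chr>                   <dbl>   <int>
#> 1 species Alphabacter primus     0.376      751
#> 2 species Archaeoides quintus    0.0585     117
#> 3 species Betabacter secundus    0.288      577
#> 4 species Gammabacter tertius    0.187      374
#> 5 species Mixtobacter quartus    0.0905     181

expected <- expected_mock(tibble(taxon = spec$members$species,
                                 abundance = spec$members$abundance),
                          "species")
mock_dissimilarity(prof, expected)
#> [1] 0.114
mis_or_unidentified(prof, expected)
#> [1] 0
```

The dissimilarity of 0.11 is not classification error (0 % of reads were
mis- or unidentified): it is the amplification bias itself. Mixtobacter
(15 % of the community, but only half its 4 operon copies linked) is
recovered at 9 %, and the relative weighting by amplifiable copy number
shifts every other member accordingly. The same genome types as mixed:

```r
type_genome(filter(comm$annotations, seqid == "SYN_001004.1"),
            genome_length = 132200)
#> seqid        type  n_linked n_unlinked n_unjudgeable
#> SYN_001004.1 mixed        2          2             0
```

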