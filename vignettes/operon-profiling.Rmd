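---
title: "Profiling microbiomes with 16S-ITS-23S rRNA operon amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling microbiomes with 16S-ITS-23S rRNA operon amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonkit)
library(dplyr)
```

## The method and its assumptions

Amplicon sequencing of the near-complete 16S-ITS-23S rRNA operon (~4 kb on
a long-read platform) offers finer taxonomic resolution than the 16S rRNA
gene alone, at the cost of two systematic blind spots that this package
makes measurable:

1. **Unlinked rRNA genes.** In most bacteria the 16S and 23S genes sit in
   one transcription unit separated by a short internal transcribed spacer
   (ITS, < 1500 bp by definition for linked genes). Some lineages instead
   carry the 23S far away — often hundreds of kilobases. An
   operon-spanning primer pair cannot amplify such a copy, so taxa whose
   genomes carry some or only unlinked copies are under-represented in the
   amplicon pool relative to shotgun sequencing.
2. **Primer coverage.** A bacterial 16S primer pair (27F + 1492R) has no
   binding site in many archaeal genomes; the operon pair (A519F +
   U2428R) covers both domains. A taxon without a primer site simply
   vanishes from that amplicon library.

`operonkit` implements the full analysis chain around these phenomena:
reference-database construction from annotated genomes, linkage
classification of 16S genes on reads and genomes, long-read QC,
conservative taxonomic assignment, mock-community evaluation metrics, and
distance-based PERMANOVA. A synthetic-community simulator generates
genomes, amplicon reads and shotgun reads with known ground truth, so
every stage is testable offline.

## Reference database construction

`build_operon_db()` chains rRNA genes that lie on the same contig and
strand whenever the intergenic distance — counted as intervening bases,
`start_next - end_prev - 1` on 1-based inclusive coordinates — is
strictly below 2000 bp. The threshold is deliberately above the 1500 bp
ITS bound for linked genes, so every linked 16S-ITS-23S(-5S) locus
becomes one record while unlinked genes stay separate. Records are the
contiguous genomic span including spacers (amplicons contain the ITS, so
the database must too), reverse-complemented for minus-strand chains so
all records read 5'→3'. Records shorter than 1000 bp are dropped; a
record of exactly 1000 bp is kept (the filter removes strictly shorter
sequences). Headers follow the `taxid|accession description` convention
used by operon databases so that assignment tables are self-describing.

Two interpretation points were genuinely open and are fixed here as
package policy: genes on opposite strands never chain (they cannot be one
PCR template), and "concatenation" means extracting the genomic span, not
splicing gene sequences. Both are exercised by tests at the 1999/2000 bp
boundary.

## Linkage classification

`classify_16s_linkage()` implements the standard read-level criteria: a
16S gene is **unlinked** if the nearest same-strand downstream 23S starts
more than 1500 bp after the 16S ends, or if no 23S is found although at
least 1500 bp of sequence remain; it is **linked** if the gap is at most
1500 bp; and **unjudgeable** when the read ends within 1500 bp of the 16S
3' end with no 23S in sight. Downstream is read in the gene's orientation,
so the classification is invariant under reverse complement — a property
tested on a thousand random annotated reads. For community accounting,
`screen_reads()` keeps only 16S-bearing reads (counting both genes of an
unlinked pair would double-count the organism) and drops reads whose
every 16S is unjudgeable. A read with at least one unlinked 16S counts as
unlinked-containing; the choice is documented because a read could in
principle carry both a linked and an unlinked copy.

## Read quality control

`mean_read_quality()` averages per-base error probabilities before
converting back to phred (`-10 log10(mean p)`), the convention of
long-read QC tools — a few bad bases dominate the mean, as they should.
Named presets reproduce the published filter chain: pretrim at quality
≥ 10 with minimum lengths of 1300 bp (16S) or 3500 bp (operon), then
final windows of 1300–1950 bp or 3500–5000 bp at quality > 12 (mock) or
> 11 (fecal), and length ≥ 1000 bp at quality ≥ 10 for shotgun reads.
The "scores of 10" stages are read as non-strict and the "> 12"/"> 11"
stages as strict, following each threshold's wording; both comparisons
are switchable. Length windows are inclusive. `subsample_reads()` draws
uniformly without replacement, deterministically per seed, preserving
input order.

## Taxonomic assignment

`assign_reads()` is an explicitly simplified stand-in for a read-mapping
plus conservative-assignment pipeline (KMA + CCMetagen in the original
workflow); it reimplements neither tool. Reads are scored by the fraction
of their canonical (strand-collapsed) 15-mers shared with the best
database record. Records tying at the best score are merged to the
lowest common ancestor of their lineages, and the read is resolved at the
deepest rank whose threshold its score clears — defaults 0.60 (species),
0.45 (genus), 0.30 (family), 0.20 (order), 0.12 (class), 0.05 (phylum),
0.02 (superkingdom) on matched-k-mer fraction. The thresholds are the
package's own and make no claim of equivalence to any external tool's
quality model; what they reproduce is the *shape* of conservative rank
degradation: the fraction of reads named at a rank is non-increasing from
phylum to species. `k = 15` balances specificity against the error rates
the simulator emits; at a 1 % total error rate about `0.99^15 ≈ 86 %` of
a read's k-mers survive intact, keeping error-free and mildly noisy reads
above the species threshold while heavily corrupted reads degrade to
higher ranks.

## Evaluation metrics

For a mock community with known composition, `mock_dissimilarity()`
computes Bray–Curtis dissimilarity (`Σ|x−y| / Σ(x+y)`) between observed
and expected abundance vectors over the taxon union, with unassigned and
non-member mass kept in the observed vector (they are observed reads that
the expectation lacks). Whether off-target mass should be one pooled
coordinate or separate taxa is not universally agreed; both modes are
provided (`pool_offtarget`). `mis_or_unidentified()` is the percentage of
reads on non-member taxa plus unassigned reads;
`count_misidentified_taxa()` counts distinct spurious taxa, excluding the
unassigned category. `accumulation_curve()` subsamples assignments at
increasing depths to show where taxon discovery saturates; because file
order is arbitrary after subsampling, random subsamples (with a nested,
per-replicate cumulative mode for guaranteed monotonicity) replace read
order.

## PERMANOVA

`permanova()` is a from-scratch distance-based multivariate ANOVA: the
squared distance matrix is Gower-centred, total sum of squares is the
trace, and each factor's SS is the increase in `tr(HG)` as its dummy
columns enter the model. Sums of squares are sequential (Type-I) in the
declared factor order — the common default of multi-factor distance-based
ANOVA; the alternative marginal decomposition is deliberately not
implemented, and the choice is documented because published "default
settings" do not always say. p-values use free permutation of samples
with the add-one convention `(1 + #{F* ≥ F}) / (1 + n_perm)`; an exact
enumeration mode (all `n!` permutations, identity included) is available
for up to 8 samples and is seed-free. On Euclidean distances with one
factor the pseudo-F reproduces classical one-way ANOVA exactly, which the
tests check against an independently coded oracle, and the sequential
decomposition matches `vegan::adonis2(..., by = "terms")` to near machine
precision. Under the null (labels independent of data) the rejection rate
at α = 0.05 over 200 simulated datasets stays within [0.02, 0.10]; the
add-one convention and permutation ties make the test mildly
conservative, which is why the suite uses 499 permutations and twelve
samples for that calibration check.

`permanova_recompute()` rebuilds the derived columns (MS, pseudo-F, R²)
of any published PERMANOVA table from its Df and SS columns — the
package ships a reference mock-community table
(`inst/extdata/mock_permanova_published.tsv`, eight long-read runs;
factors: PCR target region, polymerase kit, reference database) whose
printed R², MS and F columns the recomputation reproduces to better than
10⁻⁴ relative error.

## The synthetic community simulator

`generate_community()` builds one genome per member. Marker genes are
random sequences with planted primer-binding sites and a fixed geometry:
the 16S (1500 bp) carries the 27F site at its 5' end, the A519F site
internally at position 501, and the 1492R site at its 3' end; the 23S
(2900 bp) carries the U2428R site near its 3' end. The 16S amplicon is
therefore 1500 bp (inside the 1300–1950 bp QC window) and the linked
operon amplicon about 4.3 kb (inside 3500–5000 bp). Copies of one genome
share identical marker genes; different members get independent random
genes, which makes taxa trivially separable by k-mers — intentional,
since the classifier stand-in is tested for its bookkeeping, not for
resolving real phylogenetic similarity. Real 16S/23S sequences are
deliberately not embedded: tests need distinguishable, license-free
sequences.

Architectural parameters per member: `n_copies` operon copies of which
`round(n_copies × linked_fraction)` are linked with a configurable ITS
(default 400 bp) and the rest unlinked with the 23S placed `unlinked_gap`
(default 50,000 bp) downstream. Real unlinked spacers average around
410 kb; 50 kb exceeds every threshold in the analysis while keeping
fixtures tractable, and the value is configurable. Copies are spaced
3000 bp apart — above the 2000 bp chaining threshold — so distinct copies
yield distinct database records, as in real genomes. Default primer
sequences are standard literature sequences (27F, 1492R, A519F, U2428R)
shipped as configurable stand-ins.

`simulate_amplicon_reads()` samples templates found by `in_silico_pcr()`
(IUPAC-aware matching, both primer footprints included, products capped
at 6 kb by default — an unlinked copy's 50 kb "amplicon" is not a PCR
product). Member weight is abundance × amplifiable copies, which is what
produces the underestimation phenomenon. `simulate_shotgun_reads()`
weights members by abundance × genome length, draws log-normal fragment
lengths, and reports rRNA annotations in read coordinates
(strand-adjusted, clipped, `partial`-flagged) for the linkage classifier.
The error model applies independent per-base substitution, insertion and
deletion (defaults 0.5 %/0.25 %/0.25 %) and emits phred+33 qualities
centred on the phred of the total error rate with ±3 jitter. It emulates
rate and quality bookkeeping only — no homopolymer or signal-level
structure, no chimeras — so passing tests demonstrate correct pipeline
arithmetic on nanopore-like inputs, not robustness to every real nanopore
artefact.

All randomness flows from one seeded generator per operation call;
identical spec and seed give byte-identical FASTA/FASTQ/GFF3/TSV output.

## The underestimation experiment

For a two-member community — one fully linked member and one mixed member
with linked fraction *f*, equal abundance and copy number — the expected
relative abundance of the mixed member is `k_m / (k_m + k_c)` in the
amplicon pool (k = amplifiable copies) and `L_m / (L_m + L_c)` in the
shotgun pool (L = genome length). The package's acceptance suite uses
8 copies with `f = 0.375` and the default 50 kb unlinked gap, for which
the derived amplicon/shotgun abundance ratio is ≈ 0.33 — inside the
quarter-to-third band reported for unlinked-gene taxa in equine feces.
The observed ratio over eight seeds at 20,000 reads per mode must bracket
that closed-form expectation within three standard errors; the
expectation is recomputed from the generated genomes at run time, never
hard-coded.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely from simulation:
20,000 reads for the underestimation and database-ablation experiments,
2000–5000 reads for the classification and primer-dropout checks, 200
simulated datasets at 499 permutations for the PERMANOVA null
calibration, and exhaustive enumeration (24 permutations) for the
four-sample oracle. These sizes were chosen so each property is measured
well inside its Monte-Carlo error at desk scale. Ties in permutation
F-statistics count as exceedances (with a small relative tolerance for
floating-point equality), keeping p-values valid rather than
anti-conservative. Degenerate inputs — empty communities, empty
databases, reads shorter than k, factors with one level, chains
exceeding contig bounds — raise typed errors or return explicit empty
results, never silent files.

## Known limitations

* The classifier is a stand-in: its absolute thresholds are not
  comparable to KMA/CCMetagen output, only its conservative-degradation
  behaviour is.
* Synthetic marker genes share no k-mers between taxa, so classification
  accuracy here is an upper bound; real communities with conserved rRNA
  stretches will resolve fewer reads at species level.
* The error model ignores homopolymer bias and chimeras; chimera
  filtering (and base-calling, adapter trimming, rRNA gene prediction)
  are upstream of this package's scope — annotations arrive as GFF3.
* PERMANOVA uses free permutation only; restricted permutation schemes
  for nested designs are out of scope.
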