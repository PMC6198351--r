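---
title: "Methods: tandem 3'UTR switching analysis with apatrend"
author: "apatrend maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem 3'UTR switching analysis with apatrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatrend)
```

# The problem

3'-end sequencing protocols capture one read per transcript, anchored at
the cleavage/polyadenylation position. For genes with several tandem
poly(A) sites in the terminal exon, the distribution of reads across
those sites measures relative isoform usage: a shift toward the proximal
site shortens the 3'UTR, a shift toward a distal site lengthens it.
`apatrend` turns aligned cleavage positions from a case-control design
into poly(A) site clusters, per-gene tandem 3'UTR profiles, and
gene-level switching calls, and accounts for the miRNA target sites that
lengthening gains or shortening loses.

All internal coordinates are 0-based, half-open (the BED convention);
GTF input is shifted on read. "Downstream" is always strand-relative.
These conventions are internal choices, documented here, and applied
uniformly so that every distance rule behaves identically on both
strands.

# Read-level filtering

Oligo-dT-primed protocols generate false cleavage signals where the
primer anneals to genomic A-rich tracts (internal priming). A record
cleaved at position $p$ is discarded when the strand-oriented genomic
window 1–20 nt downstream of $p$ contains `AAAAAAAA`, matches
`G A{4,} G A{3,} G` (one-or-more repetitions of each A run), or contains
more than 12 A's in total ("more than" read strictly, i.e. ≥13).
Windows truncated by a contig edge are evaluated as-is; records whose
window is entirely off-contig are kept with a warning, since there is no
evidence on which to discard them. The window is evaluated on the read's
strand (reverse-complemented for minus-strand records); whether the
original analyses used read-strand or reference-strand windows is not
derivable from published descriptions, so the strand-oriented choice is
declared and tested as such.

A trimming entry point (`trim_raw_reads()`) covers the FASTQ convenience
path: trailing runs of ≥8 A's (the oligo-dT remnant) are stripped, and
reads shorter than 20 nt after trimming or with >10% N are rejected.
The pipeline consumes pre-aligned cleavage positions by default, so
trimming parameters are exposed but not on the critical path.

# Site calling

Cleavage positions on the same chromosome and strand are joined by
single-linkage chaining with a 24-nt maximum gap: consecutive sorted
positions at most 24 nt apart belong to one cluster. The "within 24 nt
of each other" relation is applied transitively — the only reading that
is independent of input order — so a cluster may span more than 24 nt;
no span cap is applied. Clusters with at least two pooled reads (all
samples together) become poly(A) sites; singletons are removed. Each
site's representative position is its modal cleavage position, with ties
broken toward the strand-oriented 5' (proximal) end; the mode is robust
to the heterogeneity of cleavage around a true site, and since no
representative convention is published, this one is the package's own.

# Annotation and tandem profiles

Sites are annotated against two user-supplied catalogs (known transcript
ends, known poly(A) DB) at a 24-nt distance threshold, then against gene
models: annotated 3'UTR, ≤1 kb downstream of a gene end, CDS, noncoding
gene, intron, intergenic. Categories are mutually exclusive and resolved
in that priority order — knowns before novels, then decreasing
biological specificity, intergenic last. The priority is a package
decision; the categories themselves follow the standard three-type
(known end / known DB / novel with six attributes) scheme. Sites
overlapping an annotated 3'UTR of a same-strand gene are tandem sites of
that gene; known-category sites within 24 nt of a gene's annotated end
are tandem by fallback. A tandem site's 3'UTR length is the
strand-oriented distance from the base after the stop codon to its
representative position, inclusive (minimum 1 nt). Genes with at least
two tandem sites yield a `tandem_profile`: sites ordered by increasing
3'UTR length with a samples-by-sites count matrix. Equal-length sites
within a gene (possible only after representative-position collisions)
are merged with a warning.

# The switching test

For one gene in one (case, control) sample pair, the data form a 2×k
contingency table: rows are the two samples, columns the ordered tandem
sites. The test is the linear-by-linear association (trend) statistic

$$M^2 = (N - 1)\, r^2,$$

where $r$ is the Pearson correlation between the group indicator (0 =
control, 1 = case) and the column score over the $N$ individual reads,
and $M^2$ is referred to a 1-df chi-square. This is the only trend test
defined through a Pearson correlation, which is what makes the sign of
$r$ directly interpretable: positive $r$ = case reads at longer 3'UTRs =
lengthening. The $(N-1)$ variance convention is fixed and documented;
the alternative $N$ convention changes $M^2$ by a factor $(N-1)/N$,
immaterial at the read depths involved. Column scores default to the
3'UTR length in nt (site rank is available); by affine invariance of
$r$ the choice matters only for $k > 2$. Degenerate margins — all reads
in one sample, or all reads at one site — return $r = 0$, $p = 1$.

Within each pair, p-values are Benjamini–Hochberg adjusted across that
pair's tested genes (the FDR family is per-pair, because calls are then
counted per pair), and a gene/pair is significant at q < 0.01. A gene
must carry at least 10 reads in each sample of a pair to be tested there
(config `min_pair_reads`, 0 to disable): the trend test is meaningless
on near-empty tables, and excluded tables also leave the pair's FDR
family. This floor is a package addition. With 6 cases and 6 controls
all 36 pairs are evaluated; a gene is called switching when significant
in ≥10 pairs ("at least 10" is the operative reading of the published
criterion, exposed in config), with direction from the strict majority
sign of $r$ among its significant pairs (ties are ambiguous).

Supersite ratios (`supersite_ratio()`) pool sites into a proximal and a
distal group at a configurable split index (default: first site vs the
rest, since no split rule is published) and report their count ratio per
sample, flagging infinite ratios explicitly.

# Differential expression stand-in

Gene expression is the sum of reads over all of a gene's poly(A) sites.
The differential test is deliberately self-contained: counts are pooled
within each group, normalized by pooled library size, and each gene's
2×2 table (gene vs library remainder, case vs control) is tested with a
two-sided Fisher exact test, BH-adjusted across genes; log2 fold changes
use a 0.5 pseudocount on normalized pooled counts. This is the package's
own defined DE procedure, labelled as such in outputs — it ignores
replicate-level dispersion, so with biological replicates it is
anti-conservative relative to dispersion-aware NB models and its calls
should be read as a ranking, not calibrated error rates. The DE ×
switching cross-tabulation (`crosstab_de_switching()`) counts called
genes by direction and DE status.

# miRNA seed accounting

For each called gene, the 3'UTR from the stop codon to the distal site
is scanned for the three canonical seed-site types of each supplied
mature miRNA: 7mer-m8 (reverse complement of miRNA positions 2–8), 8mer
(7mer-m8 followed by A), and 7mer-A1 (reverse complement of positions
2–7 followed by A), on the DNA alphabet with overlapping occurrences
counted. At one locus only the longest type is reported (an 8mer
suppresses the 7mers it contains). The common region ends at the
proximal site (inclusive); the extended region runs to the distal site;
a hit belongs to the region containing its 5'-most base. Lengthened
genes gain their extended-region hits; shortened genes lose them.
Context scoring and conservation filtering are out of scope — counts are
pure seed matches.

# The synthetic experiment generator

The generator emulates a 6-vs-6 case-control 3'-end experiment at desk
scale. Per gene: 2–4 tandem sites spaced 150–600 nt apart in the 3'UTR;
baseline site usage drawn from a symmetric Dirichlet (concentration 5);
reads per gene per sample negative-binomial (default mean 200, size 10),
allocated to sites multinomially and jittered uniformly ±8 nt (within
the 24-nt cluster radius, so a site's reads stay single-linkage
connected while exercising cleavage heterogeneity). A programmed
fraction of genes (default 10%) switches: proximal-site usage 0.7 in one
group and 0.3 in the other, half lengthening, half shortening. Genes may
carry a 15-nt genomic A tract in the CDS; such genes emit
Poisson-distributed artifact records immediately upstream of the tract,
whose downstream windows therefore always trigger the priming filter. By
construction the 20-nt windows downstream of every position a true read
can take are A-free, so artifact and true records are perfectly
separable — this is the oracle behind the filter's end-to-end tests.
Optionally a miRNA's 8mer site is planted once in the extended region of
every programmed lengthened gene, with chance occurrences of its seed
core scrubbed from all 3'UTRs, making the expected gained-site total
exactly the number of such genes called.

Identical configurations (including the seed) give byte-identical
outputs. No published usage-distribution parameters exist for this kind
of study, so the defaults were chosen once for testability and realism
at desk scale, not to mimic any particular tissue; where they matter
they are exposed in `simulation_config()`.

**What the generator does not emulate** — sequencing base errors,
adapter chimeras, mappability, overlapping genes, multi-exon 3'UTRs,
per-sample usage heterogeneity within a group, and tumor purity mixtures.
Consequently, passing recovery tests shows the statistical machinery is
correct under the stated model, not that real-tissue switching calls
reach the same sensitivity; in real data biological within-group
variability will inflate the per-pair test's type-I error relative to
the multinomial null, which the pair-frequency criterion (≥10 of 36
pairs) is designed to absorb.

# Numerical and scale choices

Property tests run at sizes chosen for exhaustiveness per unit time:
10,900 windows for the filter oracle, 200 random instances (≤200
positions) for the clustering oracle, 1,000 random 2×k tables (k ≤ 5,
N ≤ 200, tolerance 1e-9) for the trend-test oracle. Null calibration
uses 1,000 genes × 36 pairs at 200 reads/gene/sample; parameter recovery
uses 500 genes with 10% switchers under the same depth, where the
pipeline attains sensitivity 1.0 and false-call rate 0 at the default
thresholds (recomputed, not asserted, by `scripts/acceptance.R`).
With integer counts and scores every sum in the trend statistic is an
exactly-representable integer, so group antisymmetry holds bitwise;
affine score invariance holds to rounding (≤1 ulp in the square-root).

# Known limitations

* Overlapping same-strand genes are resolved by first-listed assignment
  with a warning, not by expression-weighted deconvolution.
* The DE stand-in ignores replicate dispersion (see above).
* No cluster-span cap: a long chain of closely spaced cleavage events
  merges into one site.
* miRNA site counts are seed matches only; no context or conservation
  weighting.
* The per-pair FDR family makes q-values comparable within, not across,
  pairs; cross-pair aggregation is by counting, not by combined p-value.
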