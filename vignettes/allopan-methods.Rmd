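---
title: "Methods: pangenome classification, HE calling and homeolog expression bias in allopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome classification, HE calling and homeolog expression bias in allopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopan)
```

# Scope and model

`allopan` implements the desk-scale computational core of a gene-based and
graph-based pangenome analysis of an allotetraploid plant system (an AABB
tetraploid with two extant diploid progenitor lineages, A and B): orthogroup
category classification and saturation, read-depth homeologous exchange (HE)
detection, presence–absence variant (PAV) genotype analysis with cis-gene
annotation, homeolog expression bias (HEB) testing, permutation enrichment
tests, and molecular-evolution utilities. Upstream heavy lifting — assembly,
gene prediction, orthogroup inference, read mapping, SV calling — is
deliberately out of scope; the package consumes their standard outputs
(TSV/BED/GFF3/VCF-like/FASTA) and owns everything bespoke downstream.

All in-memory coordinates are 0-based half-open (BED convention). GFF3 input
is converted at the boundary; nothing else ever sees 1-based closed
coordinates. Window arithmetic and interval overlap are simplest in the
half-open convention, which is why it was chosen.

# Pangenome classification and saturation

With presence defined as at least one gene of an accession in a cluster, a
cluster present in all $N$ accessions is *core*, in exactly one accession
*private*, and in $2..N-1$ accessions *dispensable*. This makes the three
categories an exact partition of the cluster set, which is what lets the three
category shares sum to 100%; the alternative literal reading of
"missed in more than one accession" would double-book clusters and cannot
reproduce a partition.

Saturation curves report, for every subset size $k$, the mean and SD of the
pan size (union of clusters) and core size (intersection) over genome
subsets: all $\binom{N}{k}$ subsets when that count is at most
`max_exhaustive`, otherwise uniform random subsets. Averaging is over
*subsets*, not genome orderings — with order averaging every ordering's
prefix of size $k$ is a subset of size $k$, so subset averaging is the more
direct estimand; the `exhaustive` flag records the mode per row. Exhaustive
curves are provably monotone ($\mathrm{core}$ non-increasing,
$\mathrm{pan}$ non-decreasing in $k$), which the test suite asserts on
random matrices.

Category contrasts of per-gene properties (CDS length, log2(TPM+1), Ka/Ks)
use two-sided Wilcoxon rank-sum tests: exact when the combined sample is at
most 20 observations, tie-corrected normal approximation otherwise.

# HE calling from windowed depth

Reads of the tetraploid are mapped to the two concatenated parental
references, and mean depth is computed in fixed non-overlapping windows
(10 kb default). An HE replaces a recipient-subgenome segment with a second
copy of the donor segment, so the donor reference locus attracts roughly
twice the expected depth and the recipient locus almost none. The caller:

1. computes the length-weighted genome mean depth;
2. flags windows at or above `dup_factor` × mean (default 1.5, inclusive —
   the stated factor itself is actionable) as candidate duplications, and at
   or below `del_factor` × mean as deletions. "Low or no coverage" is not
   quantified in the field description this follows; 0.25 × mean is the
   package default and is exposed as a parameter;
3. links same-kind flagged windows whose gap (segment end to next start) is
   at most 50 kb — so five intervening 10-kb windows still link, the
   boundary case — absorbing the gap into the merged interval; and
4. retains segments strictly longer than 80 kb ("extending beyond 80 kb"
   read literally, so an exactly-80-kb segment is rejected).

Directional calls require an explicit homeolog interval map (syntenic blocks
between the parental genomes). A duplication on genome X is projected
piecewise-linearly through the map; if the projection reciprocally overlaps
a deletion on genome Y by at least 50% of both lengths (configurable), one
HE with direction X→Y is emitted, with the recipient deletion length as the
call length. Whether a depth-based HE should always require the reciprocal partner
cannot be determined from the method description, so unpaired segments are
always reported separately as unresolved rather than discarded.

The synthetic generator models depth as truncated Normal rather than
Poisson: the caller thresholds window *means*, so only location and scale
matter, and Normal noise keeps the recovery tolerance arithmetic simple.
Deletions are simulated at 0.05 × base depth, not zero, so the deletion
threshold is genuinely exercised rather than trivially satisfied. Passing
the recovery tests therefore shows correct thresholding/linking/length
logic under realistic dispersion, not robustness to mappability artifacts,
GC bias, or copy-number mosaicism that real depth tracks contain.

# PAV analysis

Merging of per-sample call sets is non-redundancy by greedy first-match:
records merge when they share type and chromosome, start within 1 kb, and
size ratio ≥ 0.8. Upstream merging pipelines apply tolerances of their own that are rarely
documented; these defaults are declared, not
inferred, and are surfaced as parameters. The merge is idempotent, and
genotypes combine with precedence present > absent > missing. Missing
genotypes are never imputed — downstream filters decide.

Filtering drops records by missing fraction (> 0.2 default) and optional
minor presence frequency; lineage differentiation reports records whose
presence-frequency difference between the A and B sample sets reaches
`min_freq_diff` (default 1.0, i.e. fixed difference — with three samples a
side, anything softer is noise-dominated). Genes are associated to PAVs when
the PAV overlaps the gene body extended 2 kb on both sides, strand-agnostic,
because "upstream and downstream" are both included anyway.

The DEG-overlap permutation test draws same-size gene sets uniformly from
the universe and uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so p is
never zero and is honestly bounded below by $1/(n_{\text{perm}}+1)$.

# Homeolog expression bias

Counts are normalized by median-of-ratios (RLE) size factors computed over
all samples: reference = per-gene geometric mean over genes positive in
every sample; factor = median ratio to the reference. Per pair and tissue,

$$\log_2\!\mathrm{FC} = \log_2\frac{\bar{B} + 0.5}{\bar{A} + 0.5}$$

with a 0.5 pseudocount (configurable) to keep zeros finite. Inference is a
two-sided paired test on the per-replicate log2 ratios: an exact sign-flip
permutation when a tissue has at most six replicates, a one-sample t-test
beyond that, with BH correction across pairs within each tissue and biased
defined as q < 0.05. This deliberately replaces a negative-binomial Wald
GLM: the acceptance surface of the package is recovery of simulated truth,
not coefficient equality with a particular GLM implementation, and the
paired log-ratio test is exact, assumption-light and fully specifiable. The
trade-off is resolution: with three replicates the smallest attainable
sign-flip p is $2/2^3 = 0.25$, so at that design the q-threshold cannot
fire and bias recovery is assessed by effect-size ranking (AUC of
|log2FC|); `method = "t"` is available when calibrated small-sample
p-values are preferred over exact ones.

Tissue-breadth counts report pairs biased in ≥ 1 and in all tissues (pairs
with an untestable tissue are excluded from "all" only). Chromosome-level
direction uses, by default, the one-sample Wilcoxon signed-rank test of the
per-pair log2FC against zero — the paired reading of a rank test between
matched homeologs — exact by sign enumeration up to n = 12 (valid under
ties, which `stats::wilcox.test` cannot do exactly) and tie-corrected
normal beyond; a two-sample rank-sum form (`paired = FALSE`) is also
implemented. Direction is B when the median log2FC is positive.

The DEG module mirrors the HEB machinery for two sample groups (exact label
permutation at ≤ 6 total replicates, Welch's t otherwise, BH across genes).
The same resolution limit applies at 3 + 3; power-style tests in the suite
use 4 + 4.

# Molecular evolution utilities

Ka/Ks is Nei–Gojobori (1986): the method description names only a
calculator tool, so the canonical counting method was chosen because it is
fully specifiable and admits an exhaustive brute-force oracle. Synonymous
sites per codon are $3 s/9$ with $s$ the number of synonymous
single-nucleotide changes (mutations to stops count as nonsynonymous),
averaged over the two sequences, so $S + N = 3 \times$ codons exactly.
Multi-difference codons average over all orderings of single steps;
pathways through stop codons are excluded with weights renormalized (if all
are blocked, all orderings are used). $p_S = S_d/S$ and $p_N = N_d/N$
receive the JC69 correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and
the ratio is undefined at $K_s = 0$. Universal code only; a code-table
parameter is reserved.

LTR insertion ages use $T = K/(2\mu)$ with $K$ the JC69-corrected 5′–3′ LTR
divergence. No default substitution rate is shipped: the source analysis
never prints its rate, and silently assuming one would fabricate ages, so
the rate is a required argument. TE family contrasts flag families whose
mean lineage sizes differ by ≥ 10 kb (inclusive), with genomes lacking a
family contributing 0 bp.

# Synthetic data and what passing tests mean

Every generator is deterministic given `seed` and returns a truth object
that is exactly re-derivable from the emitted data: orthogroup labels are
recovered exactly by the classifier; non-differentiated PAV genotype draws
that would be lineage-fixed by chance are rejected and redrawn so the
differentiated set is exact; sequence pairs implant one change per codon so
NG86 recovers $S_d$/$N_d$ without pathway ambiguity. Homeolog counts are
negative binomial (dispersion 0.05 default, means log-uniform on 20–2000)
with a per-tissue log-normal factor (sd 0.2) shared by both homeologs so
tissues differ without inducing spurious bias; the biased fraction,
log2FC and replicate structure default to the four-tissue, three-replicate design
the package targets. These fixtures validate the algorithms, not the wet-lab
realities (mappability, batch effects, isoform complexity) absent from the
generative models.

Default problem sizes used by the test suite and the acceptance script —
100 depth-track replicates of a 20-Mb genome, 10 000-cluster matrices over
20 seeds, 5 000 homeolog pairs, 200 permutation-calibration runs — were
chosen as the smallest scales at which the asserted properties are stable
across seeds.

# Numerical and degenerate-input choices

* Duplication/deletion/TE-difference/frequency thresholds are inclusive;
  the minimum HE length is strict. Each follows the literal wording it
  implements and is covered by an explicit boundary test.
* BH q-values are computed over non-NA p-values only; q ≥ p always.
* Empty depth tracks, all-missing lineages, empty gene sets, zero-variance
  genes and stop-containing codon alignments raise informative errors (or
  warnings with well-defined results where the spec of the operation allows
  partial output).
* The permutation p add-one estimator makes reported p-values conservative
  but never zero.

# Known limitations

* The HE caller assumes depth tracks on a fixed non-overlapping grid and
  does not model mappability or ploidy mosaicism; calls are candidates, not
  validated events.
* PAV merge tolerances are declared defaults, not values recovered from any
  upstream merging tool.
* The HEB test exchanges GLM shrinkage for exactness; with very few
  replicates its discrete p-values are conservative by construction.
* Ka/Ks supports the universal genetic code only, and LTR ages are
  meaningful only conditional on the user-supplied substitution rate.
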