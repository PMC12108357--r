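---
title: "Methods: codon usage bias statistics for mitochondrial PCGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias statistics for mitochondrial PCGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistics `mitocub` computes, the assumptions
behind them, the choices made where the design was genuinely open, and what
the synthetic-data generator does and does not establish about real data.

## The genetic code as the single source of truth

Every downstream statistic depends on the synonymous-family structure of
the genetic code, so `genetic_code()` derives it once and everything else
consumes it. The vertebrate mitochondrial code (NCBI translation table 2)
differs from the standard code in exactly the ways that matter here: AUA is
Met, UGA is Trp, and AGA/AGG are stops, leaving 60 sense codons partitioned
into 12 two-fold, 6 four-fold and 2 six-fold families with no single-codon
amino acid. The four-fold degenerate set used by PR2 is the 24 codons of
Ala, Arg, Gly, Pro, Thr and Val; the six-fold Leu and Ser families also
have free third positions but are excluded by the degeneracy-4 definition.
Some codon-usage software instead splits six-fold families at the first two
positions; `genetic_code(split_sixfold = TRUE)` exposes that convention,
but the default follows the code strictly.

The internal alphabet is RNA: inputs are T→U normalized on read (the
transformation is idempotent), and writers emit DNA. This avoids mixed
alphabets in codon tables, where printed sources alternate between T and U.

## CDS extraction and codonization

Minus-strand genes (ND6 in the canonical plan) are reverse-complemented to
mRNA sense on load, and *nothing downstream special-cases them*: ND6's
mirrored skews and PR2 position emerge purely from its composition. This is
a deliberate design point — the strand effect is a property of the data,
not of the code path.

Incomplete stop codons (a trailing T or TA completed to UAA by
polyadenylation in the transcript) cannot be counted as codons. The default
`stop_policy = "drop-partial"` excludes the 1–2 nt tail, which keeps the
accounting exact: 13 genes × 64 codons classifiable per genome. The
`"polyadenylate"` policy A-completes the tail for users who want
complete-stop accounting. An internal stop codon is treated as a
misannotation and aborts with the gene and codon position, rather than
silently corrupting counts. Codons containing ambiguity codes are dropped
with a tally. Coordinates are 1-based inclusive externally (the GenBank
convention) and 0-based half-open internally, converted in exactly one
function.

## RSCU, CUP classes and codon aversion

For codon $j$ in a family of size $k_i$ with family total $N_i > 0$,

$$\mathrm{RSCU}_{ij} = \frac{k_i\, n_{ij}}{N_i},$$

observed use relative to even use, independent of gene length and
amino-acid composition. Classification thresholds are the conventional
ones: unused (RSCU = 0), under-represented (0 < RSCU < 0.6),
over-represented (RSCU > 1.6), unbiased otherwise. The codon aversion motif
(CAM) of a gene is its unused set.

Three open points were resolved as follows:

* **Stop and start codons are counted.** Stop codons form a four-member
  pseudo-family for RSCU only (never for ENC or PR2), so stop-codon
  preference is visible alongside sense codons; initiator codons are
  counted in the Met family, which is how AUA-versus-AUG start preference
  becomes visible. Both inclusions can be switched off
  (`include_stops`, `include_initiator`).
* **Unobserved families.** A family with zero observations has no defined
  RSCU; members carry `NA` and `family_observed = FALSE`. For
  classification and CAM purposes they default to unused — their usage
  count *is* zero, and only this convention keeps the
  genes × 64 accounting closed.
* **Mean-then-classify.** Population summaries average per-individual RSCU
  per codon and classify the means (`mean_rscu()`), rather than pooling
  counts first; a pooled route is available via `pool_counts()`.

Display rounding is two decimals with round-half-up (the printed-table
convention, distinct from R's banker's rounding); persisted TSVs carry full
precision.

## Hierarchical clustering of RSCU profiles

Genes are clustered on their 64-dimensional mean-RSCU vectors. The package
defaults to Euclidean distance with average linkage — robust, deterministic
given inputs, and the common choice for expression-style heatmaps — with
both configurable. Clustering is delegated to `stats::hclust`; on
continuous RSCU profiles distance ties have measure zero, so no bespoke
tie-breaking rule is needed for reproducibility, and the test suite checks
the result against a from-scratch agglomerative implementation that
recomputes all inter-cluster distances at every merge. Missing RSCU values
are imputed as 0 with a message. Any published partition of genes into a
fixed number of groups depends on the underlying dataset and is not treated
as binding.

## ENC and the mutation-only curve

Wright's effective number of codons summarizes bias in one number: 20 when
every amino acid uses a single codon, the code's sense capacity when usage
is even. Per observed family with $n \ge 2$,

$$F = \frac{n \sum_j p_j^2 - 1}{n - 1},$$

class averages $\bar F_s$ over families of equal degeneracy $s$, and

$$\mathrm{ENC} = n_{\text{single}} + \sum_s N_s / \bar F_s.$$

Two modes are provided because the class structure is a genuine fork:

* `"code-derived"` (default) takes $N_s$ from the supplied code — for the
  mitochondrial code $12/\bar F_2 + 6/\bar F_4 + 2/\bar F_6$, range
  [20, 60].
* `"standard-compat"` applies the universal-code formulation
  $2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$ (range up to 61),
  matching codon-usage software that prints ENC values above 60 even for
  mitochondrial genes — values impossible under the strict mitochondrial
  family structure. The default stays code-derived; the compat mode exists
  for comparability with such outputs.

Numerical conventions: $F$ is the unbiased homozygosity estimator and can
legitimately reach 0 at small $n$ (two observations split 1/1), where its
reciprocal is unusable — families with $F \le 0$ or $n < 2$ are excluded
from their class average, as codon-usage software conventionally does. A
class with no estimable family is interpolated (the three-fold class as
$(\bar F_2 + \bar F_4)/2$, otherwise the mean of observed class averages)
and the gene is flagged `"interpolated"`. Results are capped to the mode's
theoretical range. GC3 counts all sense codons (stop codons excluded;
synonymity at the third position is undefined for the stop pseudo-family),
with a synonymous-only variant flag.

The mutation-only expectation $\mathrm{ENC} = 2 + GC3 + 29/[GC3^2 +
(1-GC3)^2]$ is evaluated on an inclusive $[0,1]$ grid, by default at 0.001
spacing (1001 points). The curve's value at GC3 = 0.5 is exactly 60.5;
note the analytic maximum sits marginally above 0.5 because the linear term
tilts the curve, so tests pin the value at 0.5 and the symmetry identity
$f(x) - x = f(1-x) - (1-x)$ rather than a "maximum at 0.5" claim.

## PR2 bias

Under strand-symmetric mutation and selection, within-strand A ≈ T and
G ≈ C (parity rule 2). At the third positions of four-fold degenerate
codons every base is synonymous, so deviations of
$A_3/(A_3{+}T_3)$ and $G_3/(G_3{+}C_3)$ from 0.5 measure strand-asymmetric
pressure with selection on the protein excluded by construction. The plot
convention — x = GC-bias, y = AT-bias — is centralized in one place since
published plots rarely label the axes explicitly. A coordinate exactly at
0.5 is labelled `on-axis` rather than forced into a quadrant, and genes
with fewer than 10 four-fold codons (ATP8-sized genes are the practical
case) carry a `low_support` flag because such ratios are noisy. Counts pool
across individuals within gene by default, with a per-individual option.

## The synthetic-data generator

`sim_spec()` + `simulate_mitogenomes()` stand in for real mitogenome
populations. The model: a fixed 13-gene plan (canonical lengths, ND6 on the
minus strand, ND4 with a 1 nt partial stop, the anomalous published COX1
length replaced by 513 whole codons); per-gene codon probabilities with
amino-acid marginals from a fixed hydrophobic-rich composition plan and
within-family weights drawn once per spec from a Dirichlet distribution
whose concentration `alpha` (default 12) is the bias dial — lower
concentration, stronger bias; one ancestor drawn codon-i.i.d. from those
probabilities; individuals derived by Poisson(μ × gene length)
substitutions at internal codons, synonymous-only by default (default
μ = 0.001 per site, the "low divergence within a population" regime), with
a `messy` flag for nonsynonymous changes. Codon-level rather than
nucleotide-level sampling is deliberate: every statistic the package
computes is a functional of codon counts, and fixed amino-acid plans keep
family totals stable.

The `"kansuensis-like"` preset encodes the A/C-rich third-position regime
of cervid-like mitogenomes (plus-strand weights A 0.45, C 0.32, U 0.15,
G 0.08, complemented for minus-strand genes so ND6's mirrored behaviour
emerges downstream rather than being injected); `"neutral"` is uniform
within families and strand-symmetric; `"extreme-bias"` puts all mass on
one codon per family.

Two notions of truth are recorded, and the distinction matters. The
*distributional* truth (expected RSCU and GC3 implied by the probability
vectors) is what large-sample runs recover; the *ancestral* truth (the
realized usage of the drawn ancestor) is what a population of
near-identical individuals recovers, because averaging over near-copies
cannot remove the ancestor's own sampling noise — the effective sample size
of pooled population counts is the ancestral count, not the pooled count.
Tests therefore check population means against ancestral truth at the
canonical gene plan, and distributional truth on a long single gene
(500,000 codons, giving every family class thousands of observations, the
regime where a ±0.1 RSCU tolerance is a multi-sigma bound).

What passing these tests shows: the estimators are correct functionals of
codon counts, the strand logic is right, and recovery behaves as sampling
theory predicts. What they do not show: anything about annotation quality,
sequencing error, heteroplasmy, selection heterogeneity along genes, or
phylogenetic structure — the generator draws codons i.i.d. within genes and
individuals from a star-shaped population, none of which is true of real
data.

## Problem sizes and determinism

The shipped test suite and acceptance script are sized for quick, exact
verification: 89-individual populations at the canonical ~11.4 kb coding
plan for qualitative pattern checks, a single 500k-codon gene for
distributional recovery, 100-instance oracle sweeps for RSCU/ENC/four-fold
extraction/clustering, 1000 random count tables for the family-sum
invariant, and a 5 × 4 concentration grid for the ENC-versus-bias rank
test. All randomness flows from explicit integer seeds through R's default
RNG; `run_pipeline()` output is a pure function of inputs and
configuration, and tables embed a content-derived run id so reruns are
byte-comparable.

## Known limitations

* GenBank parsing targets well-formed flat files with `CDS` features
  carrying `/gene` or `/product` qualifiers; exotic location operators
  beyond `complement()`/`join()` are not supported.
* ENC is Wright's estimator only; background-corrected variants are out of
  scope, as are CAI/Fop-style adaptation indices and correspondence
  analysis.
* Sliding-window skews (origin-of-replication detection) are not provided;
  skews are whole-sequence summaries.
* The generator does not simulate trees; divergence is star-shaped around
  one ancestor.
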