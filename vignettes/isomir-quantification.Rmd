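---
title: "IsomiR-aware miRNA quantification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IsomiR-aware miRNA quantification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRQuant)
```

## The measurement model

Small RNA libraries sequence ~22-nt RNAs end to end on short (here
36-cycle) reads. Because the insert is shorter than the read, the
sequencer reads through the insert into the 3′ adapter, so the first
computational step is to find the adapter and cut it off; what remains is
the insert ("tag"). Mature miRNAs are excised from hairpin precursors,
and the excision is imprecise: a miRNA is observed as a population of
isomiRs whose 5′ and 3′ termini are shifted by a few nucleotides around
the canonical ends. Quantification therefore happens at two levels — the
tag level (a unique sequence with a count) and the miRNA level (an
aggregate over the tags accepted as its isomiRs).

### The isomiR acceptance rule

A tag is accepted as an isomiR of mature miRNA $m$ on hairpin $h$ when an
ungapped placement of the tag on $h$ exists with at most one mismatch and
both terminal offsets within the window:

$$\mathrm{offset}_5 = s_{tag} - s_m \in [-4, +4], \qquad
  \mathrm{offset}_3 = e_{tag} - e_m \in [-4, +4],$$

with $s, e$ the 0-based half-open ends on the hairpin. Two readings of
"mature region ± 4 nt" exist; the per-terminus one implemented here is
the standard isomiR convention — the alternative ("anywhere inside the
expanded interval") would accept a 15-nt fragment floating in the middle
of a 30-nt window with neither end anchored, which no isomiR catalogue
does. Matching is ungapped (mismatches, never indels) and on the given
hairpin strand only; the scan itself is exhaustive (every placement with
≤ 1 mismatch), implemented in C++ and verified in the tests against a
brute-force pure-R oracle and against `Biostrings::matchPattern`.

Within one hairpin only the best placement of a tag survives: fewest
mismatches, then smallest $|\mathrm{offset}_5| + |\mathrm{offset}_3|$,
then the 5′-most — a total order, so results never depend on scan order.
Across hairpins a tag may legitimately multi-map (identical paralogs);
the default policy `all` credits every mature hit with the full count
(paralogs share reads), `fractional` splits the count, and `unique-only`
discards such tags. `all` is the default because collapsing paralogs is
what the naming conventions of miRNA families expect, but it makes
summed RPM exceed one million by the shared counts; `unique-only`
restores the exact partition of a million and is used wherever the tests
assert that identity.

### The two abundance estimators

Per miRNA and library, `sum_count` adds all accepted isomiR tag counts
and `dominant_count` takes the single most abundant isomiR (ties broken
toward the canonical tag, then lexicographically — deterministic). Both
are normalized to reads per million mapped with the *same* denominator:
the library's mapped read total, each read counted once regardless of
multi-mapping, computed after the low-count filter. Sharing the
denominator means any disagreement between the estimators reflects the
numerator choice only. Whether the original denominator was taken before
or after the count-<2 filter is not recoverable; "after" is the default
and the choice is a function argument.

### Differential calls without replicates

With one pooled library per condition the only available statistic is the
fold change, $\log_2((R_{case}+c)/(R_{ctrl}+c))$ with pseudocount
$c = 0.5$ RPM rescuing miRNAs undetected on one side; miRNAs undetected
on both sides are excluded rather than zero-filled. The up/down cutoff is
ambiguous in the source conventions — a log2 ratio beyond ±2 (4-fold) or
a plain 2-fold difference (log2 beyond ±1). The strict log2 ± 2 rule is
the default (`classify_fc(fc, threshold = 2)`, strict inequalities: a
fold change of exactly 2.0 is *unchanged*), and
`threshold_sensitivity()` always reports the calls under both readings so
the ambiguity is visible rather than silently resolved. No p-values are
produced by design.

### Groups

Clusters chain hairpin loci on the same chromosome and strand with
inter-locus gap ≤ 10 kb (single linkage, via `GenomicRanges::reduce`);
10 kb is the prevailing window for "miRNA cluster" and is configurable.
Families are either taken from an explicit map or derived from an
identical seed, mature positions 2–8, the determinant of target
recognition. The group statistic is **sign concordance**: the fraction of
detected members whose fold-change sign matches the majority sign, 0.5 on
an exact tie; magnitude is deliberately ignored because the claim being
scored is about direction — clustered and homologous miRNAs move
together even when their abundances differ by orders of magnitude (the
reported `expression_span`). Zero fold changes vote for neither sign but
stay in the denominator.

### Enrichment

The original web-service enrichment (its statistic, background and
annotation version unspecified) is replaced by a transparent
hypergeometric over-representation test on user-supplied gene sets:
$p = P(X \ge k)$ for $k$ of $n$ query genes in a $K$-gene set from an
$N$-gene background, BH-adjusted across sets. The background defaults to
all genes in the target table and is overridable. Printed p-values of the
original analysis are consequently *not* reproduction targets anywhere in
this package.

## The synthetic world

`sim_config()` defaults state the emulated study: 50 hairpins, 4 clusters
of 2 (gap ≤ 10 kb), 4 seed families of 3, mature lengths 20–24 nt,
36-cycle reads, the classic Solexa 3′ adapter, 0.5% per-base substitution
error, cleavage offsets {0: 0.6, ±1: 0.15, ±2: 0.05} drawn independently
at the two ends, $10^5$ reads per library, 20% of miRNAs differential at
$|\log_2 FC| = 3$ (half up, half down), 1% of reads emitted at Q2 to
exercise the quality filter, and a log-normal baseline (sdlog 2) giving
the several-orders-of-magnitude skew of real miRNA libraries (liver
libraries are dominated by a single miRNA). Offsets drawn beyond the
hairpin are resampled and counted. Reads are insert + adapter truncated
to 36 nt — read-through is always present when the insert is shorter than
the read, mirroring the 110–130 bp library size selection.

What the generator does **not** model: indel sequencing errors,
non-templated 3′ additions (e.g. uridylation), ligation bias,
position-dependent quality decay, and any 5′ adapter contamination. A
green recovery test therefore establishes that the pipeline inverts this
generative model, not that it is robust to every artefact of real
libraries.

Two details of the stated world deserve emphasis:

* **Nominal vs realized effects.** The truth table records the nominal
  effect (±3, or 0 for non-differential miRNAs) and per-condition
  abundances renormalized to sum to one. Renormalization means the
  *realized* RPM ratio of every miRNA carries an extra compositional
  shift of $\log_2(\sum_i a_i / \sum_i a_i 2^{\lambda_i})$ — exactly the
  bias RPM-only normalization suffers in real two-library designs when
  abundant species move, and the reason modern pipelines add TMM- or
  median-of-ratios factors. The analysis scripts quantify it as the
  median fold change of truly unchanged miRNAs and report the
  shift-corrected error alongside the raw one; the recovery criterion
  (median error ≤ 0.5 over differential miRNAs) is asserted on the raw
  error.
* **Detection floor.** Direction recovery is asserted for miRNAs with at
  least 10 expected reads in each condition
  ($\min_c a_{m,c} \times \mathrm{depth} \ge 10$): below that, the
  count-<2 filter and multinomial noise make the call a coin flip, and no
  method in this design can do better.

`make_profile(coherent_groups = TRUE)` additionally forces cluster and
family members to share their effect, the co-regulation pattern the
grouping module is meant to detect; it makes the exact DE counts
approximate and is off by default.

## Numerical and degenerate-input choices

* Quality filter: the instrument-side filter of the original platform is
  not recoverable; a configurable mean-Phred threshold (default Q20) is a
  declared substitute, not a reconstruction.
* Adapter search: leftmost position whose read-suffix/adapter-prefix
  overlap is ≥ 6 nt with mismatch rate ≤ 0.1 (budget
  $\lfloor 0.1\,\mathrm{overlap}\rfloor$, so overlaps under 10 nt must be
  exact). Reads with no hit are kept whole and flagged — a 36-cycle read
  can be all insert. Empty post-trim reads are rejected. Trimming is
  idempotent by construction (everything right of the leftmost hit is
  removed).
* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  is converted at the boundary. U is normalized to T on every ingestion
  path (reference hairpins are RNA; `Biostrings::readBStringSet` is used
  precisely because the DNA reader silently drops U).
* Mature-by-substring annotation: a mature occurring twice within one
  hairpin is ambiguous → error; occurring in several hairpins annotates
  each (paralogs). Arms come from `-5p`/`-3p` suffixes or the GFF3 `arm`
  attribute, else from the mature midpoint relative to the hairpin
  midpoint.
* A library with zero mapped reads raises an error naming the library
  rather than emitting NaN RPM. All tie-breaks (dominant isomiR, best
  placement) are total orders; reruns and row-shuffles give identical
  output, and the whole pipeline is byte-identical under a fixed seed and
  config.

## Limitations

Beyond the generator's declared simplifications: no between-library
normalization beyond RPM (faithful to the emulated design, with the
compositional caveat above), no replicate-aware testing, no novel-miRNA
discovery or genome-wide alignment, and enrichment results are only as
good as the supplied target table and gene sets — the bundled ones are
synthetic and labelled as such.
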