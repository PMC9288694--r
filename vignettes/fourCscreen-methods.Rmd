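---
title: "Methods: 4C-seq interaction quantification and enhancer screening"
author: "fourCscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4C-seq interaction quantification and enhancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourCscreen)
```

# Scope

fourCscreen analyses circular chromosome conformation capture (4C-seq)
experiments of the kind used to map the contact partners of a gene
promoter ("viewpoint") across conditions — for instance the myosin
heavy-chain (*Myh*) promoters in fast (quadriceps) versus slow (soleus)
skeletal muscle. The package starts from fragment-level read assignments
(mapping is out of scope) and covers: in-silico restriction digestion,
artifact filtering, windowed quantification and interaction calling,
replicate intersection, condition comparison and differential analysis,
a candidate-active-enhancer screen against H3K27ac and ATAC-seq peaks,
and E-box / position-weight-matrix motif scanning. A seeded simulator
plants enhancer contacts of known position and effect size so that every
stage can be validated end to end against ground truth.

All genomic coordinates in the package are 0-based, half-open (BED
convention), declared once here and used everywhere.

# The quantification model

## Digestion and artifact removal

`digest_sequence()` cuts at the first base of every recognition-site
occurrence (DpnII `GATC` by default, Csp6I `GTAC` in the catalogue for
two-enzyme designs). This blunt-cut abstraction ignores the enzyme's
true 4 nt overhang; at the 2 kb windowing resolution used downstream a
±4 bp offset is immaterial, and it keeps a brute-force oracle trivial.
IUPAC degeneracy is honoured in the site (`N` matches any base); `N` in
the *sequence* never produces a cut.

4C libraries carry two artifact read classes at the viewpoint:
non-digested templates (reads on the viewpoint fragment itself) and
self-ligation products (reads on its two flanking fragments).
`filter_invalid()` removes exactly those three fragments. The standard
quality gates are applied as printed in the field's QC practice: the
cis/overall read ratio must exceed 40% (strictly), and 1 Mb binned
interaction-site profiles of replicate pairs must correlate with
Pearson r > 0.4 (strictly).

## Windows, RPM and the interaction caller

Retained reads are credited to the fixed, non-overlapping 2 kb window
containing their fragment's midpoint (no splitting: fragments can reach
5 kb and straddle windows; the midpoint rule is deterministic). Counts
are normalized to RPM — reads per million per window — so that the RPM
track sums to $10^6$ exactly whenever all retained reads are windowed.

Interaction calling is cis-only. Windows overlapping the viewpoint
±10 kb are excluded: the over-represented near-cis zone would otherwise
dominate any background fit. Remaining cis windows are ordered by
distance from the viewpoint and a running median over 101 windows,
floored at 0.5 counts, provides the local background $\lambda_i$; each
window is tested with a one-sided upper-tail Poisson p-value
$P(K \ge k_i \mid \lambda_i)$ and Benjamini–Hochberg adjustment across
tested windows. A window is significant when the adjusted p-value is
below 0.05.

One refinement matters for calibration. Restriction fragments are not
uniformly spaced: the number of fragment midpoints per 2 kb window is
itself Poisson-variable (roughly 8 ± 3 at DpnII density), so window
counts are proportional to fragment content as well as to contact
frequency. A running median of *raw counts* therefore leaves substantial
extra-Poisson spread at any distance, and we measured a null
significant-window fraction around 0.11 with it — an order of magnitude
above the nominal level. `call_interactions()` consequently computes the
running median on *per-fragment rates* (count divided by the window's
fragment count) and rescales by each window's fragment content, the
usual fragment-density normalization of fragment-based chromosome
conformation methods. With it the measured null fraction is ~0.002 at
the simulator's default noise (the test suite checks ≤ 0.05 over 50
seeds). The plain count median remains available (`fmap = NULL`) and is
exact under uniform fragment density.

High-fidelity interaction sites are the intersection of the significant
windows of the two biological replicates — random inter-nucleus
collisions rarely replicate, so only replicate-shared windows are
carried forward, mirroring standard practice.

# Condition comparison

Profiles are compared on 1 Mb bins of intrachromosomal interaction-site
counts (a site straddling a bin boundary is assigned by its start
coordinate — with 2 kb sites the bias is negligible, and the rule is
deterministic). `correlation_cluster()` performs average-linkage
clustering on the distance $1 - r$; zero-variance profiles get `NA`
correlations and are excluded rather than poisoning the tree.
`pca_profiles()` is centred, unscaled PCA with a fixed sign convention
(largest-magnitude loading positive) for reproducibility.
`overlap_sets()` gives exact Venn partitions of two or three site sets
and the shared fraction $|\cap| / |\cup|$.

## Differential interaction sites

`differential()` tests raw counts at the high-fidelity windows between
two conditions with ≥ 2 replicates each, in the mould of count-based
differential expression:

* median-of-ratios size factors (all-positive windows; total-count
  fallback). When the tested windows are a small signal-enriched
  selection — which replicate-intersected sites are by construction —
  factors must be estimated on the full window grid and passed in,
  otherwise the normalization itself absorbs genuine condition effects;
  `run_pipeline()` does exactly that;
* log2 fold change of normalized condition means with a pseudocount of
  1: $\mathrm{LFC} = \log_2 \frac{\bar q_B + 1}{\bar q_A + 1}$;
* a negative-binomial Wald test: pooled within-condition
  method-of-moments dispersion $\hat\alpha = (s^2 - \bar q)/\bar q^2$
  floored at 0.01, delta-method standard error of the LFC, two-sided
  normal p-value, BH adjustment;
* a *significantly differential interaction site* (SDIS) requires
  |LFC| > 1 **and** adjusted p < 0.05.

Swapping the condition labels negates every LFC and leaves p-values
unchanged; identical inputs on both sides give LFC ≡ 0 and no SDIS.
`mean_abs_lfc()` reports the average |LFC| over all sites or over SDIS
only. One test cross-checks the LFC estimates against an independent
DESeq2 run on simulated negative-binomial counts (correlation > 0.9);
DESeq2 is never used as the implementation.

# The enhancer screen

`screen_enhancers()` implements the candidate-active-enhancer screen in
five ordered rules: (1) drop interchromosomal sites; (2) keep sites
overlapping — by at least 1 bp, the weakest consistent reading of
"simultaneous enrichment", exposed as `min_overlap` — both an H3K27ac
peak and an ATAC peak; (3) drop sites overlapping any annotated
promoter (promoters are an explicit BED input; no TSS-extension rule is
imposed); (4) merge adjacent surviving windows into regions, so one
broad element yields one candidate rather than one per window; (5)
within each region report the ≤ 1000 bp window with the maximum
integrated ATAC signal (sum of value × covered bp — robust to bedGraph
run fragmentation, unlike peak height), ties broken leftmost. A region
with no signal returns its leftmost window flagged `zero_summit`.
Overlap is half-open: touching intervals do not overlap. Candidates are
then annotated for ≥ 1 bp overlap with conserved elements.

The integrated-signal optimum is found exactly: the score as a function
of the window start is piecewise linear with breakpoints at signal-run
boundaries, so evaluating the cumulative integral at breakpoints and
their width-shifted images suffices; the test suite verifies equality
with an exhaustive per-bp scan on a thousand random step functions.

# Motif scanning

`ebox_scan()` reports every occurrence of the E-box `CANNTG` — the
myogenic regulatory factor (MYOD/MYOG) element — including overlapping
ones; the pattern class is its own reverse complement, so positions are
reported once, on the plus strand. `pwm_score()` scores position weight
matrices as log-odds in bits with uniform background and pseudocount
0.01: $\sum_j \log_2 \frac{p_j + c \cdot b}{(1 + c) b}$, `N` scoring 0
at its position, both strands scanned, hit threshold 80% of the maximum
attainable score. `rank_motifs()` tabulates per-matrix best scores and
hit counts over candidate sequences, sorted by best score with name
tie-breaks. Ranking is descriptive: no enrichment null against shuffled
sequences is computed, because the upstream web tools this mirrors do
not define one. The shipped matrices in `inst/extdata` are synthetic
stand-ins (two E-box factors, two non-muscle decoys), not database
matrices.

# The simulator and what it does (not) show

`sim_config()` defaults define the study conditions used throughout the
tests:

| knob | default | why |
|---|---|---|
| genome | chr1 6 Mb + two 0.8 Mb trans chromosomes | smallest genome giving ≥ 6 cis Mb-bins, thousands of background windows and real trans mass |
| forced site spacing | 4 kb | caps fragments at ~5 kb (`site_spacing` + site length) |
| viewpoint | chr1:3,000,000 | mid-chromosome promoter stand-in |
| reads/sample | 5 × 10⁵ | resolves 8-fold effects at Mb distances in minutes of compute |
| decay | $(1 + d/d_0)^{-\alpha}$, $\alpha = 1$, $d_0 = 10$ kb | standard polymer-contact shape; the upstream tools publish no explicit background law |
| cis fraction | 0.45 | inside the reported 18–68% range and just above the 40% gate, so lowering it exercises the gate's failure side |
| artifact fraction | 0.10 | split half undigested (viewpoint fragment), a quarter each self-ligated (flanks) |
| planted enhancers | 5, effect 8× in soleus only, footprint 2 kb | condition-specific contacts at 0.4–2.0 Mb offsets |
| replicate noise | Gamma multiplier, variance 0.05 | between the low-concordance regime real replicates show and the recovery regime the validation design requires |

The contact-effect footprint equals the 2 kb analysis window: a summit
landing on a window boundary then still delivers close to its nominal
fold change to each straddled window, which a narrower footprint halves.
The emitted peak footprints are 800 bp (peak centres jittered ≤ 200 bp
around summits), matching the sub-kb candidate widths the screen is
meant to recover; every planted summit also receives a consensus E-box
`CAGCTG` in the genome sequence so the motif stage has signal. Decoy
peaks are placed ≥ 50 kb from summits with H3K27ac and ATAC decoys
mutually disjoint, so no decoy can satisfy the both-marks rule.

Sample totals are exactly `n_reads`, multinomially split into artifact /
valid-cis / trans classes; everything is deterministic given `(seed,
condition, replicate)`.

The simulator emulates fragment-level 4C counts with distance decay,
planted effects, replicate noise and co-located epigenomic tracks. It
does **not** emulate sequence-level reads, PCR duplicates, mappability
or ligation bias, domain structure (TADs), or trans-contact hotspots;
trans reads are uniform. Passing tests therefore demonstrate that the
statistical machinery recovers planted truth under a clean generative
model — not that the thresholds are optimal for any particular real
library.

# Numerical and degenerate-input conventions

Running-median span 101 windows (error below 101 testable cis windows,
advising a larger genome); background floor 0.5 counts; dispersion floor
0.01; Wald statistic 0 when both SE and LFC are 0 (p = 1); PCA on a
constant matrix is an error, duplicated samples coincide; empty
interaction sets screen to empty results (not errors); an empty
conserved set gives conserved fraction 0; `region_width()` accepts
hyphen, en- or em-dash and comma separators and rejects empty spans.
Leaf order in clustering and all emitted text outputs are sorted for
byte-stable reruns.

# Problem sizes used in validation

The test suite validates oracle equivalence on ~1000 random fixtures per
scan operation, null calibration on 50 simulated seeds, and end-to-end
planted recovery (candidate summits within 500 bp; condition-specific
effects flagged SDIS) on 25 seeds at the default design above — sizes
chosen so the whole suite completes in a few minutes on one CPU while
leaving the binomial uncertainty of the measured rates well below the
asserted margins. `scripts/acceptance.R` re-runs the same computations
at reduced seed counts and writes the measured quantities as JSON.

# Known limitations

* The interaction caller is Poisson after fragment-density
  normalization; residual biological overdispersion in real libraries
  would make single-replicate calls anti-conservative — the replicate
  intersection is the package's main guard, as it is in practice.
* The Wald differential test with two replicates per condition relies on
  a moment dispersion estimate with a floor; it is exact in its stated
  model, not a shrinkage estimator, and users wanting borrowing of
  strength across windows should export counts to a dedicated
  differential package.
* Trans interactions are reported in window tracks but never called
  significant or screened; the enhancer screen is cis-only by design.
* The simulator's QC knobs make gate-failure regimes reachable but the
  defaults deliberately pass both gates; conclusions about gate
  behaviour on marginal real libraries require real data.
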