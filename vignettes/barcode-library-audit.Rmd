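---
title: "Auditing a DNA barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeaudit)
library(dplyr)
```

## The problem

A species-level DNA barcode reference library — typically COI-5′
sequences of ~658 bp, a handful of vouchered specimens per species —
is only useful for identification if species are mutually
diagnosable: every species' barcodes should be closer to each other
than to any other species' (the *barcode gap*). Curating such a
library is therefore an exercise in screening pairwise distances for
three kinds of signal:

* **low interspecific divergence / barcode sharing** — species pairs
  whose minimum distance is small or exactly zero, which either break
  identification or point at synonymy, hybridisation or recent
  speciation;
* **deep intraspecific splits** — conspecific haplotype clusters
  separated by more than a screening threshold (conventionally 2%),
  a flag for overlooked (cryptic) species, often with a geographic
  pattern;
* **inflated summary statistics** — mean intraspecific variation is
  sensitive to those split taxa, so it is reported both with and
  without them.

`barcodeaudit` implements this audit as a tidyverse-style pipeline:
a library is a tibble of specimens, the audit result is a set of
tibbles, and every screen above is a small, separately testable
function.

## Distance model

All distances are Kimura 2-parameter (K2P), the de-facto standard for
barcode work. For a pair of aligned sequences let `P` and `Q` be the
proportions of transitions (A↔G, C↔T) and transversions among the
sites where *both* sequences carry an unambiguous A/C/G/T
(*pairwise deletion*); then

```
d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)
```

Numerical conventions, chosen once and used everywhere:

* **Pairwise deletion, not complete deletion.** Libraries mix
  full-length 658 bp records with >500 bp fragments; deleting a
  site globally because one short record lacks it would discard most
  of the signal. Sites with `N`, gaps, or partial ambiguity codes
  (R, Y, …) are skipped for that pair only; partial ambiguities are
  *not* probabilistically resolved — at barcode-level divergences the
  effect is negligible and the simple rule is auditable.
* **`min_overlap` (default 300 sites).** A pair with fewer comparable
  sites than this is *missing*, not zero — a 100-site overlap that
  happens to be identical must not become a "barcode sharing" call.
* **Saturation.** If `1 - 2P - Q ≤ 0` or `1 - 2Q ≤ 0` the distance is
  undefined; such pairs are missing (never `Inf`), excluded from all
  minimum/maximum statistics, and counted in the `k2p_dist` object.
* **Units.** Proportions internally; percentages only in rendered
  reports, rounded half-up at 1 decimal (2 decimals for global
  means), matching how such tables are conventionally printed.
  Half-up is deliberate: base R's `round()` is round-half-even.

The per-pair site counting is compiled code (Rcpp); a 900-specimen
library (~400,000 pairs × 658 sites) takes about a second.

## The audit statistics

Given the distance matrix, per species:

* **MPD** — maximum intraspecific pairwise distance, the
  conventional measure of intraspecific variation. Undefined for
  singletons, which are excluded from the MPD histogram and from
  intraspecific means but kept in nearest-neighbour analysis.
* **Nearest neighbour (NN)** — the heterospecific species attaining
  the minimum specimen-to-specimen distance (minimum over specimen
  pairs, not centroids). Ties broken towards the lexicographically
  smaller species name, for determinism.
* **Flags** — `SHARING` (NN distance exactly 0), `DEEP_SPLIT`
  (MPD strictly greater than the 2% threshold), `LOW_DIVERGENCE`
  (NN within the report window, default (1%, 4%]), `SINGLETON`.

Global summaries are means over defined pairwise comparisons in four
strata (all interspecific; congeneric interspecific; intraspecific;
intraspecific after dropping every specimen of the deep-split
species). The reported SE is the descriptive `sd/sqrt(n)` over
comparisons. Pairwise comparisons share specimens and ancestry, so
this SE understates uncertainty; it is kept because it is the
convention in which such library summaries are reported, and it is
documented as descriptive only.

Three design points were genuinely open and were settled as follows:

* **Subclusters** of a deep-split species are connected components of
  single linkage at the threshold: two specimens are connected if
  their distance is ≤ 2%. Single linkage is the weakest clustering
  assumption consistent with "two lineages", and it lets a species be
  classified as a *single outlier* case (some subcluster is one
  specimen) versus *multiple individuals* per cluster — the two cases
  carry very different evidential weight for cryptic diversity.
  Region tags travel with the subcluster membership so geographically
  structured splits can be read directly off the report.
* **Boundaries are asymmetric by convention**: the deep-split screen
  is strict (`MPD > 2%`), the low-divergence window is half-open
  (`lower < d ≤ upper`), so a pair at exactly 4.0% appears in the
  table and a species at exactly 2.0% MPD is not flagged.
* **Resolution rate**: a species is *diagnosable* iff its minimum
  interspecific distance is strictly positive. Real curation also
  weighs extraterritorial and narrative evidence when deciding
  whether a species "may share" barcodes; the package implements the
  strict zero-distance criterion and leaves softer judgements to the
  curator (the specimen-level sharing evidence is reported for
  exactly that purpose).

## Neighbour-joining cluster trees

`build_nj()` is a deterministic Saitou–Nei implementation returning
an ape-compatible `phylo`: Q-criterion ties are broken by the
lexicographically smallest label pair, and negative branch-length
estimates are clamped to zero with the deficit moved to the sister
branch, preserving leaf-to-leaf path lengths. On additive matrices
the algorithm provably recovers the generating tree; the test suite
checks this against an exhaustive least-squares search over all
topologies for up to 6 leaves. Missing distances are never imputed —
the caller (or the CLI, which warns) must subset to a complete
submatrix, because silent imputation would bias exactly the
low-divergence neighbourhoods the audit cares about.

## The synthetic library generator

`simulate_library()` exists so that every stage of the audit can be
exercised against a known truth without downloading anything. It
emulates the statistical structure of a well-curated temperate-moth
COI library:

| parameter | default | meaning |
|---|---|---|
| `target_interspecific_d` | 0.13 | expected cross-genus K2P |
| `target_congeneric_d`    | 0.10 | expected within-genus, between-species K2P |
| `target_intraspecific_d` | 0.002 | expected conspecific K2P |
| `deep_split_d`           | 0.044 | separation of planted split clusters |
| `kappa`                  | 4    | transition/transversion rate ratio |
| `seq_length`             | 658  | COI-5′ amplicon length |

The defaults are the divergence levels reported for dense European
geometrid libraries (interspecific means near 13%, congeneric near
10%, clean intraspecific variation near 0.2%, documented splits near
4.4%); `kappa = 4` is typical for insect mitochondrial COI.

Mechanically, the generator evolves sequences down a star phylogeny:
genus ancestors radiate from a root at depth
`(interspecific − congeneric)/2`, species centroids from their genus
ancestor at `(congeneric − intraspecific)/2`, specimens from their
centroid at `intraspecific/2`. Each stage mutates sites independently
with the closed-form K2P substitution probabilities, under which the
expected *estimated* distance between ancestor and descendant equals
the target exactly, and distances are additive along paths — so the
specimen-level expectations hit the three targets without any
tuning. Anomalies are then injected:

* a **deep split** gives the species a second centroid `deep_split_d`
  away, with at least one specimen drawn from it, and distinct region
  tags per cluster (emulating the geographic lineages such splits
  typically show);
* **sharing** copies one donor specimen's haplotype verbatim into a
  recipient species (distance exactly 0). Note a consequence the
  truth tables record: the recipient *necessarily* also becomes a
  deep-split species, since the donated haplotype sits ~10% from its
  conspecifics — exactly as introgressed or misidentified material
  behaves in real libraries;
* optional **low-divergence pairs** re-derive one congeneric
  centroid at a requested small distance (e.g. 1.4%) from another;
* optional **short records** are truncated, to exercise length
  filters.

What the generator deliberately does *not* model: coalescent
genealogies within species, rate variation among lineages or sites,
indels, sequencing error, or realistic taxon sampling. Passing the
recovery tests therefore demonstrates that the audit statistics do
what they claim on data with the assumed distance structure — not
that a real library will be as clean; in real data the thresholds
(2% screen, 1–4% window) remain curator's conventions, not inferred
quantities.

## Test and verification strategy

The package is verified at three levels, all runnable offline:

* **Oracles.** K2P distances are compared (to 1e-12) against an
  independently coded per-site implementation on random pairs; the
  matrix against element-wise application; NN/MPD tables against a
  brute-force double loop; NJ against closed-form 3-taxon solutions
  and the exhaustive search above; distances also against
  `ape::dist.dna(model = "K80", pairwise.deletion = TRUE)` on clean
  sequences.
* **Properties.** Read/write round-trips, filter monotonicity and
  idempotence, K2P ≥ p-distance, label-permutation invariance,
  histogram count conservation, deletion monotonicity of MPD/NN,
  threshold monotonicity of the deep-split flag set, stratum
  partitioning, and byte-identical re-rendering of reports.
* **Study-scale recovery.** A library of 300 species × 3 specimens
  (the scale of a regional macro-moth fauna) with 20 planted deep
  splits at 4.4% and one sharing pair is audited end to end: all
  planted anomalies must be recovered with zero false negatives, and
  the stratum means must sit within 3 Monte-Carlo SEs of the targets.
  Two subtleties are handled deliberately. First, the SE used there
  is a cluster jackknife (over genera for interspecific strata, over
  species for intraspecific), because pairwise comparisons share
  ancestry and the naive `sd/sqrt(n)` over ~4×10⁵ pairs would be an
  order-of-magnitude underestimate. Second, target recovery is
  assessed on the anomaly-free backbone: a planted split lineage sits
  4.4% off its species position, so it genuinely (and intentionally)
  shifts the strata it touches — the same mechanism that makes the
  audit's with/without-deep-splits contrast informative.

## Limitations

* The aligner is trusted: sequences are assumed to share a common
  reading frame with no indels (the COI-5′ convention); the reader
  pads or trims to a fixed number of positions but performs no
  alignment.
* SEs on global means are descriptive (see above).
* The deep-split screen is a threshold rule, not a species-delimitation
  method; no ABGD/ASAP/GMYC-style inference is attempted.
* Saturated pairs are dropped from statistics rather than modelled;
  at barcode-level divergences they indicate data problems rather
  than genuine signal.
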