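---
title: "Community fingerprinting by T-RFLP: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community fingerprinting by T-RFLP: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Terminal restriction fragment length polymorphism (T-RFLP) fingerprints a
microbial community without sequencing every member. The 16S rRNA gene is
amplified from community DNA with the near-universal primers 27F and 1492R,
the forward primer carrying a fluorescent label. The ~1.46 kb amplicons are
digested with a restriction enzyme (BfaI, C^TAG, in the reference workflow)
and sized by capillary electrophoresis against an internal standard. Because
only the labelled (27F-proximal) fragment is detected, each taxon
contributes a single peak whose position is the distance from the 27F end to
the taxon's first cut site — the terminal restriction fragment (T-RF).
A community is thus reduced to a list of fragment sizes, and two communities
are compared by how many fragments they share.

`trflpr` implements the full computational chain of such a study:

1. **In-silico digestion** (`find_primer_sites`, `extract_amplicon`,
   `digest_positions`, `terminal_fragment`): predicts each taxon's T-RF from
   its sequence under IUPAC pattern semantics (degenerate bases in primers
   and recognition sites; `N` in a template matches everything).
2. **Enzyme screening** (`build_trf_table`, `discrimination_score`,
   `pick_enzymes`): ranks candidate enzymes by how many taxa of a clone
   library their T-RFs can tell apart. Two fragments are indistinguishable
   when they would co-migrate, i.e. merge under single linkage at the
   binning tolerance; the score is the number of resulting groups.
3. **Peak processing** (`read_peak_table`, `filter_peaks`,
   `replicate_consensus`, `bin_profiles`): filters electropherogram peaks to
   the size-standard window and detection threshold, keeps only peaks
   reproduced in both replicate runs of a sample, and bins fragment sizes
   across samples into a presence/absence matrix.
4. **Similarity** (`dice`, `similarity_matrix`, `group_summary`): the Dice
   (Sorensen) coefficient `S_ab = 2 N_ab / (N_a + N_b)` on shared peak
   counts, summarised within and between levels of the sampling design.
5. **Clone-library diversity** (`jc_distance_matrix`, `cluster_otus`,
   `rarefaction`): Jukes-Cantor distances with pairwise gap deletion,
   furthest-neighbour (complete-linkage) OTU clustering at a divergence
   threshold (5% by convention), and the analytic hypergeometric
   rarefaction curve `E[S(n)] = sum_i (1 - C(N - N_i, n) / C(N, n))`.
6. **Phylogenetics** (`neighbor_joining`, `bootstrap_support`,
   `write_newick`): standard NJ on the distance matrix, with bootstrap
   support by column resampling and bipartition counting.
7. **Ordination** (`correspondence_analysis`, `variance_explained`,
   `cluster_report`): correspondence analysis of the samples x bins table —
   chi-square standardisation, SVD, principal coordinates — with
   complete-linkage clustering of the sample scores for cluster
   interpretation.

`run_pipeline()` orchestrates all stages, writes every artifact with a
manifest of content digests, and is a pure function of (inputs, config,
seed): re-running with the same seed reproduces every file byte for byte.

## Key modelling assumptions

* **Presence/absence is the unit of information.** The Dice coefficient
  counts peaks, not intensities, so all downstream statistics (similarity,
  CA by default) run on presence/absence. Peak heights are carried through
  the profile objects and an abundance-weighted CA is available
  (`weights = "height"`), but nothing else uses intensities.
* **Forward-label only.** Only fragments anchored at the labelled 27F end
  are scored; bottom-strand fragments and partial digestion are out of
  scope.
* **Uncut amplicons** are retained in TRF tables with `cut_found = FALSE`
  and the full amplicon length (1460 bp), which places them outside the
  35-500 bp window of the size standard: they are invisible in profiles, as
  they would be in the instrument. Whether such pseudo-T-RFs should be
  scored at all is a genuine open question in the field; exclusion is this
  package's default, not a claim about any particular dataset.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `size_window` | [35, 500] | bp | span of a 500LIZ-type internal standard |
| `min_height` | 50 | fluorescence units | conventional detection threshold |
| `match_tolerance_bp` | 1.0 | bp | replicate peak alignment; duplicate runs of the same sample rarely drift more |
| `bin_tolerance_bp` | 0.5 | bp | cross-sample co-migration; single-base resolution of capillary sizing |
| `otu_threshold` | 0.05 | JC distance | conventional species-level OTU definition |
| `n_bootstrap` | 100 | replicates | standard support estimation |

Binning uses *single* linkage (a chain of peaks within tolerance
co-migrates as one bin), whereas OTU clustering uses *complete* linkage
(every pair inside an OTU must be within the divergence threshold) — the
respective conventions of fragment analysis and of distance-based OTU
callers.

## The synthetic-community generator

Real electropherograms for this kind of study are rarely deposited, so the
package ships a ground-truthed generator (`generator_config`,
`generate_taxon_pool`, `assemble_communities`,
`simulate_electropherograms`, `generate_clone_library`) whose defaults
define the reference study conditions used by the test suite:

* **Taxon pool.** A random 1500-bp root carries the 27F site at position 11
  and the reverse-complemented 1492R site closing a 1460-bp amplicon. Each
  of 36 taxa receives independent substitutions at rate 0.10 per site
  outside the priming sites (rates >= 0.25 are rejected because
  Jukes-Cantor distances saturate). A few directed edits then place each
  taxon's first BfaI cut at a taxon-specific length drawn from a 4-bp grid
  on [60, 476] bp: every fragment falls inside the detection window and no
  two taxa co-migrate, so community structure is identifiable from
  profiles. The directed edits are an order of magnitude fewer than the
  random substitutions and do not disturb the pool's divergence statistics.
* **Design and occupancy.** 4 host plants x 4 locations x 2 larvae, two
  replicate runs per larva, plus an optional artificial-diet group. Two
  core taxa occur in every sample (the ubiquitous dominant phylotypes);
  5 taxa per plant occur with probability 0.9 in matching samples; 2 per
  location with probability 0.3; everything else at a baseline occupancy of
  0.15. Host plant structuring communities more strongly than location is
  therefore built in, and swapping the two effect sizes provably reverses
  the ordering — the test suite verifies both directions.
* **Noise layer.** Fragment sizes get Gaussian jitter (SD 0.15 bp); each
  subdominant taxon's peak drops out of a run with probability 0.05; core
  peaks never drop (`core_dropout_prob = 0`) because dominant populations
  sit far above the detection threshold — a two-tier detection model rather
  than uniform peak loss (setting both probabilities to 1 recovers the
  degenerate empty-profile limit). A Poisson(0.5) number of spurious peaks
  per run lands uniformly in the window with low heights, and replicate
  consensus removes nearly all of them. These constants were calibrated
  once so that the mean within-larva replicate Dice lands near 0.91,
  the reproducibility typical of duplicate T-RFLP runs; across ten seeds
  the default configuration gives 0.909.
* **Artificial diet.** Modelled as an extra "plant" level reared at a "lab"
  location: it matches no field taxa and each non-core member is lost with
  probability 0.75, emulating an impoverished diet. Its profiles keep the
  core fragments (ubiquity is preserved) but share little else with field
  samples, so diet-vs-crop similarity falls below crop-vs-crop similarity.

**What passing tests do and do not show.** The generator draws taxa from a
star-like genealogy, gives every taxon a unique fragment, and makes
occupancy draws independent across taxa and samples. Real communities have
phylogenetically correlated membership, frequent T-RF co-migration between
unrelated taxa, abundance-driven detection, and PCR/chimera artefacts, none
of which are modelled. Recovery results on synthetic data therefore
validate the *computational chain* — that each statistic measures what it
claims under known truth — not the biological interpretability of any real
fingerprint.

## Numerical and design choices

* **Coordinates.** All positions are 1-based (R convention). Digestion cut
  positions are reported as prefix lengths — the number of bases 5' of the
  cut — so a terminal fragment's length equals its first cut position.
* **Replicate matching** is greedy nearest-first with ties broken toward
  the smaller fragment, which makes the consensus symmetric in its two
  arguments; matching is one-to-one and maximal at the tolerance.
* **OTU tie-breaks.** When two merges are equally close, the pair whose
  lexicographically smallest member id sorts first wins, making partitions
  deterministic even on degenerate (tied) distance matrices. Infinite
  (saturated) distances never merge.
* **NJ degeneracies.** Two taxa yield a single edge split evenly; three
  taxa use the closed-form three-point solution; negative branch-length
  estimates on non-additive inputs are clamped to zero with a message.
  On additive matrices the reconstruction is exact.
* **CA sign convention.** CA axes are sign-indeterminate; each axis is
  flipped so the first sample with a non-zero score is positive, making
  outputs reproducible. Tables with identical rows have zero inertia and
  are rejected as "no variation".
* **Ordination dimensionality for cluster recovery.** Plots use the first
  two axes, but recovering a g-level design factor generally needs g-1
  ordination dimensions; `cluster_report` defaults to 2 axes while the
  pipeline's purity summary and the recovery checks retain
  `(levels - 1)` axes. With the default 4-plant design this raises mean
  cluster purity from ~0.79 to ~0.93.
* **Both-empty profiles** raise an error in `dice` rather than returning 0:
  an empty electropherogram is a QC failure, not a biological zero.

## Problem sizes used for validation

The test suite checks each operation against an independent brute-force
oracle at sizes where exhaustive computation is feasible: all 4096 pairs of
length-6 presence vectors (plus 1e5 random pairs) for Dice; 1000 random
300-bp sequences x 3 enzymes for digestion; 100 random 6-taxon pools x 5
enzymes for enzyme ranking; 200 random matrices with up to 8 sequences for
OTU clustering; a 20-clone fixture with 1e4 Monte-Carlo resamples for
rarefaction; 50 random additive 5-taxon trees for NJ; 50 random 6x10
tables for CA conservation laws; and ten seeded generator runs of the full
34-sample design for the end-to-end recovery properties.

## Known limitations

* Multiple sequence alignment is delegated: alignments are inputs
  (the generator emits gap-free ones), never computed.
* No thermodynamic PCR model (primer efficiency, melting), no partial
  digestion, no chimera or sequencing-error simulation.
* Coverage statistics for clone libraries are deliberately not implemented:
  the common estimators disagree and no single convention is assumed.
* Bray-Curtis or other abundance-weighted similarities are out of scope;
  the Dice analysis is the package's contract.
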