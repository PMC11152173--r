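---
title: "Classifying RNA-RNA interaction sites: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RNA-RNA interaction sites: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Direct-duplex-detection protocols (PARIS, SPLASH, LIGR-seq) crosslink and
sequence RNA duplexes transcriptome-wide. After chimeric-read analysis,
each putative RNA-RNA interaction (RRI) site is a pair of short genomic
subsequences with a mapping-reliability score. These site lists are noisy:
ligation artifacts and mapping errors produce pairs that were never base
paired in the cell. `rriclass` turns replicated interactome tables into a
trained binary classifier that judges whether a candidate site is
biologically plausible, and applies it to new sites.

The pipeline has five stages, each exposed as tidyverse-style functions
that take and return tibbles:

1. **Curation** (`curate_trusted()`): a site is *trusted* when every
   replicate contains a concordant record — both arms overlapping by at
   least 30% of the shorter arm, arm pairing possibly swapped — and the
   representative's score is at least 1. The 30% default absorbs the
   boundary variation between detection protocols; the score cutoff keeps
   only reliably mapped interactions.
2. **Occupancy** (`build_occupied_library()`): every arm of any input
   interaction with score at least 0.5 — a deliberately conservative,
   lower cutoff — plus optional RNA-binding-protein intervals (crosslink
   tracks widened by 5 nt each side) forms a library of regions assumed
   unavailable for pairing.
3. **Duplex prediction** (`predict_duplexes()`): each arm is extended by
   150 nt of genomic context; inside the two windows a dynamic program
   finds up to 5 energetically best intermolecular duplexes that contain a
   *seed* of 5 consecutive base pairs inside the experimentally detected
   site, avoid occupied positions, and may stretch into the context.
   Using a set of suboptimals rather than a single structure reduces the
   bias of any one predicted geometry.
4. **Negatives** (`make_negative_instances()`): for every positive site
   the same windows are reused, the site itself is additionally masked,
   and "flanking" duplexes are predicted from the remaining context. Negatives
   are therefore local in sequence composition but disjoint from every
   reliable interaction site.
5. **Features and model** (`build_feature_table()`,
   `train_rri_model()`): hand-crafted interaction/sequence features plus
   an optional graph-kernel block feed a tree-ensemble classifier chosen
   by randomized search and site-grouped cross-validation.

## The energy model

The internal predictor scores a duplex — an ordered antiparallel chain of
base pairs — additively:

$$E = \sum_{\text{pairs}} e_{\text{type}} +
      0.5 \cdot \#\{\text{enclosed unpaired nucleotides}\},
\qquad e_{GC} = -2,\; e_{AU} = -1,\; e_{GU} = -0.5,$$

with at most 3 unpaired nucleotides between consecutive pairs on each
side, and helix-terminated ends. Units are arbitrary: only the ranking of
alternative duplexes matters downstream. This deliberately simple model is
exactly recomputable (`duplex_energy()`), which lets the test suite verify
the dynamic program against exhaustive enumeration; it ignores nearest-
neighbor stacking and intramolecular accessibility. When thermodynamic
fidelity matters, `external_predictor_adapter()` runs a user-supplied
hybridization tool under the same seed/suboptimal/exclusion constraints
and maps its output onto the same duplex representation, so everything
downstream is unchanged.

A practical consequence of additive scoring worth knowing: in long
unmasked windows of random sequence, chains of near-complementary
fragments accumulate arbitrarily low energies, so the minimum energy of an
instance partly reads out how much unmasked window it has. Dense occupancy
annotation (or the adapter) is the remedy; the synthetic fixture (below)
exploits exactly this property in reverse.

## Seeds, cores and polarity

Positive instances require the seed inside both site cores; the duplex may
extend into context but never across a masked position. Negative instances
mask the cores entirely, so negative duplexes cannot touch the site at
all — slightly stricter than requiring only the seed outside, and it
guarantees that negatives are genome-disjoint from every trusted arm. The
occupancy mask of a positive instance lifts out spans overlapping the
site's own arms; otherwise the replicate copies of the site (jittered by a
few nucleotides) would mask its own core.

## Features

Per instance, over its duplex set: minimum and mean energy, duplex count;
for the minimum-energy duplex: base-pair count, per-side and summed
lengths, GC/AU/GU pair counts, enclosed unpaired nucleotides, maximal
stack; energy normalized by length, by GC-pair count (guarded by an
indicator when no GC pair exists) and by pair count; per-side GC content,
mononucleotide fractions and k-mer entropies (k = 1, 2) of the
duplex-covered subsequence and of the site core. The graph block encodes
all suboptimals jointly: nucleotide-labeled nodes over the duplex-covered
spans, backbone edges within each side, one pair edge per distinct base
pair in any suboptimal; NSPDK-style features hash pairs of
Weisfeiler-Lehman-canonicalized neighborhoods (radius ≤ 2, distance ≤ 4)
into 2^16 L2-normalized buckets with a fixed hash, so vectors are
deterministic and invariant under node relabeling. Accessibility features
are not computed internally; they belong to the external predictor.

## Model selection

A random forest importance pass first drops features below 1e-4 (never all
of them); a bounded randomized search (50 draws, fixed seed) over
histogram gradient boosting (`xgboost`, `tree_method = "hist"`) and random
forest (`ranger`) follows, scored by mean F1 under stratified 5-fold
cross-validation. All instances derived from one site share a fold — the
positive and its context-local negative are highly correlated, and
splitting them across folds would leak. Classes are weighted inversely to
frequency by default, since real interactome training sets are imbalanced.
An iteration-bounded search was preferred over a wall-clock budget for
exact reproducibility. Selection by F1 on the positive class matches the
reporting metric; AUC-PR (step-wise, right-continuous integration —
avoiding the optimism of linear interpolation in PR space, with the chance
baseline equal to prevalence) is reported alongside.

`evaluate_sites()` refuses feature tables whose config fingerprint or
feature names mismatch the model unless forced; sites with no valid
duplex are reported with an `NA` label rather than a guess.

## The synthetic fixture

`sim_genome()` + `sim_interactome()` produce a fully specified study
condition: 2 chromosomes of 100 kb (i.i.d., GC 0.5), 150 planted site
pairs of 30-60 nt where site B is the reverse complement of site A mutated
at 10%, 3 replicates with ±5 nt uniform boundary jitter and scores
U(1, 5), plus 50 decoy rows per replicate (random non-complementary pairs,
scores U(0, 0.4), placed independently per replicate so they fail both
filters). Regeneration under one seed is byte-identical.

Two constructions make the fixture a fair test of "energy alone is not
enough":

* **Energy-matched decoy helices.** Into the flanking context of each
  planted arm the generator writes a GC-only helix whose reverse
  complement sits in the partner arm's flank; its length is calibrated
  from the site's own internally computed duplex energy
  (L = round(-E/2), the GC pair contributing -2), so the negative
  instance of each site has a minimum energy matched to its positive.
  Energy is thereby uninformative by construction while pair composition,
  duplex length and stacking pattern still separate the classes.
* **A background-occupancy track** covering the genomic context of every
  arm except the sites and decoy islands. Without it, the additive energy
  model's chance chains (above) would make the minimum energy a window-
  geometry readout — positives and negatives differ in masked-core
  geometry — and the energy baseline would look informative for the wrong
  reason. The track emulates a densely annotated interactome/protein
  occupancy landscape and is passed as `rbp_intervals`.

What the fixture does *not* emulate: realistic transcript structure,
nearest-neighbor thermodynamics, accessibility, protocol-specific ligation
biases, or chimeric-read noise upstream of the interaction table. Passing
the fixture shows the pipeline's machinery is correct and that the model
learns non-energy structure; it does not certify performance on real
interactome data.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; interaction tables are
  declared 1-based inclusive and converted once at the boundary; BED
  passes through untouched. Output identifiers are 1-based inclusive.
* T is mapped to U at read time; `N` and other ambiguity codes are kept
  but never pair. Strand-agnostic BED rows occupy both strands; stranded
  occupancy is strand-specific.
* Duplex ties are broken by energy, then the first pair's indices —
  output is deterministic. Suboptimals are distinct as base-pair sets;
  overlap between them is allowed.
* Replicate grouping is greedy: candidates by descending score, matches
  claimed by descending overlap; each record supports at most one trusted
  site. Mutual-best matching was considered and rejected as
  under-determined by the data.
* Instances with zero valid duplexes are excluded from the feature table
  and surface as `NA` classifications, never as imputed rows.
* Degenerate guards: empty sequences, single-class labels, too-few
  instances for the fold count, and zero-GC normalization all raise
  descriptive errors or indicator features rather than NaNs.

## Problem sizes used in the checks

The packaged tests run the full pipeline at the study scale above
(300 training instances) for the end-to-end properties, smaller seeded
fixtures (20-25 sites) for unit properties, and windows of at most 15 nt
for oracle equivalence of the dynamic program, where exhaustive
enumeration over every legal chain is feasible. The acceptance script
re-runs the study-scale pipeline, including full model selection, in a few
minutes on one CPU.

## Known limitations

* The simplified energy model is a ranking device, not thermodynamics;
  absolute energies are meaningless and accessibility is ignored.
* The exact feature list of the original method's supplementary material
  is operationalized by category (strength, length, pairing composition,
  complexity, GC, normalized variants), not reproduced item-by-item.
* Randomized search over two tree-ensemble families replaces a full AutoML
  ensemble; with few informative features this is adequate, but it will
  not discover exotic pipelines.
* Curation semantics when one record could support several trusted sites
  are resolved greedily; a global assignment could differ on pathological
  inputs.
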