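---
title: "Scanning alignments for group-exclusive convergent variants: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning alignments for group-exclusive convergent variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convarfinder)
```

This vignette documents the models implemented in `convarfinder`, the
assumptions behind them, and the choices made where the underlying
methodology leaves the design open. It states no empirical result that the
package's tests do not themselves compute.

## The exclusivity model

The unit of analysis is one alignment column (or codon) compared between a
target species group A and a background group B. The column is a *variant*
when the observed state sets are disjoint, and its Type (1–4) records
whether each group is internally uniform (a singleton state set) or
heterogeneous. Three conventions matter:

* **Gaps are states.** A deletion shared by all of group A against a
  residue in group B is biological signal (group-specific indel), so `-`
  participates in profiles like any residue. This is what makes profiles
  such as "V versus I,-" classifiable (Type 2).
* **Ambiguity is disqualifying, not ignorable.** Any `X` (amino acid) or
  `N` (nucleotide/codon) within either group makes the site unscannable,
  because the hidden state could intersect the other group's set and break
  exclusivity. This is deliberately conservative; the alternative (drop the
  ambiguous species from the profile) would overcall variants.
* **Every non-excluded species is assigned.** Group B defaults to "all
  species not in A and not excluded", so exclusivity means *not found in
  any other species*, which is the claim the method is designed to make.

Runs of two or more adjacent variant sites are removed and tallied as
continuous (putatively structural) variants, to keep the focus on point
mutations. The exact run threshold is not dictated by the underlying
methodology; 2 is the strictest value that still removes multi-residue
events and it is exposed as `run_length` so users can relax it. Adjacency
is measured in the coordinates of the scanned level (amino-acid columns for
protein scans, codon indices for codon scans), since a structural event at
one level is a structural event at the other in-frame.

At codon level, synonymy is defined through the translated profiles:
nonsynonymous iff the amino-acid sets are disjoint, which makes the set of
nonsynonymous codon variants coincide exactly with the amino-acid variant
sites of the translated alignment (a property the test suite checks on
simulated codon alignments). The nucleotide source of a codon variant is
decided per codon position: if some position is itself mutually exclusive
the variant is the product of single-nucleotide substitution (ConSNV when
group A is uniform at the *first* such position, DivSNV otherwise);
otherwise the codon-level exclusivity emerges only jointly, a complex
nonexclusive nucleotide variant (CNENV). When several positions qualify,
using the lowest-numbered one is an arbitrary but deterministic tie-break.

## Ancestral reconstruction

Evolutionary direction is verified on a fixed, rooted, user-supplied tree;
the package never re-estimates topology or branch lengths. Two in-house
reconstruction modes are provided, both restricted to the states observed
in the column (with `-` as a state and `X`/`N` as missing data):

* **Parsimony.** Unit-cost Sankoff dynamic programming with an up pass and
  a down pass, yielding for every internal node the *exact* set of states
  attained in at least one maximum-parsimony assignment; the posterior is
  uniform over that set. The test suite validates these sets against
  exhaustive enumeration of all internal assignments on 4-leaf trees and
  against an independent parsimony implementation.
* **Marginal ML.** Felsenstein's pruning recursion under a K-state
  equal-rates, time-reversible model with uniform equilibrium frequencies
  (the natural generalisation of the Jukes–Cantor model to the observed
  alphabet), followed by an outside pass to obtain per-node marginal
  posteriors. Branch lengths are taken as expected substitutions per site.
  This is intentionally the simplest defensible model: the goal is to
  orient substitutions on branches, not to fit rate parameters, and richer
  models (GTR, rate heterogeneity) would demand estimation the fixed-tree
  workflow does not provide. A reader for externally computed marginal
  reconstructions is included for parity checks.

MAP ties are reported as unresolved rather than broken by iteration order;
any classification that depends on a tied node returns `"unresolved"`. A
tree of total length zero makes the ML transition matrices the identity,
so that mode falls back to parsimony with a warning.

A target variant's history is *simple* (parallel) when (a) the parent
nodes of all target-clade origin branches share one reconstructed state,
and (b) each origin branch changes directly from that shared state to the
clade's derived state with no differing intermediate states inside the
clade. Everything else is *complex*. The simple/complex dichotomy is
illustrated rather than formally defined in the literature this package
follows; the (a)+(b) reading is one consistent formalisation and is the
one implemented. Requiring the parent state to *differ* from the derived
state means a variant already present at the ancestral node is never
called a simple origin on that branch.

## Lineages and branch features

A species combination's *independent lineages* are its maximal chosen-only
clades: a lineage is a maximal set of chosen species whose spanning
subtree contains no unchosen leaf. Its *apex* is the highest ancestor all
of whose leaf descendants are chosen — for a lone species with unchosen
relatives, the leaf itself; where the tree contains unary chains the apex
extends upward through them. The branch entering the apex is the lineage's
origin branch. A singleton nested inside a larger clade therefore counts
as an independent lineage, with its terminal branch as origin; this is the
reading under which a three-species songbird clade is one lineage while a
single hummingbird is another.

The four branch features of a combination are

* `POB` — product of the m origin-branch lengths,
* `PTB` — product of the k terminal-branch lengths,
* `DTB` — summed path lengths from the tree-wide MRCA to each chosen leaf,
* `DTN` — summed path lengths from the tree-wide MRCA to each leaf's
  parent node,

so `DTB − DTN` is identically the summed terminal branch lengths (checked
exactly in tests). An apex at the tree root has no origin branch and is a
hard error: silently defaulting its length would contaminate every POB
product. A zero-length origin branch yields `POB = 0` with a warning.

Unconstrained enumeration of k-subsets streams through a compiled
lexicographic-successor walk, so counting the 10,737,573 6-species subsets
of a 47-leaf tree takes seconds without materialising anything;
lineage-constrained enumeration materialises and filters and is intended
for moderate subset counts.

## Statistics

The statistical layer deliberately reuses the reference implementations a
practitioner would use, wrapped behind a stable interface: `lm` for OLS,
`rank`-based product-moment correlation for Spearman's rho (mid-ranks for
ties; p-value from the large-sample t approximation with n − 2 degrees of
freedom), `phyper` for the hypergeometric upper tail, and `p.adjust` for
the BH step-up. The outlier test studentizes residuals externally
(regression deletion), refers them to t with n − 3 degrees of freedom,
Bonferroni-multiplies by n, and reports at most `n_max` (default 3)
observations below `alpha`, largest |t| first — matching the behaviour of
the standard regression outlier test it mirrors. Two numerical guards are
worth noting: an essentially exact fit (all residuals at rounding-noise
scale relative to the fitted values) reports no outliers, and a deletion
fit with zero residual variance under a genuinely discrepant point is
treated as infinitely significant.

The substitution-score PCA sums BLOSUM62 scores over the chosen sites into
a species-by-species similarity matrix. A pair involving a gap scores the
matrix minimum (−4) — penalising indels without introducing a second gap
model — and a pair involving `X` scores 0; both are configurable. The
matrix is double-centered before eigendecomposition (the classical
multidimensional-scaling convention), because a raw similarity matrix
carries a dominant overall-size component that would swamp PC1; raw
decomposition is available via `center = FALSE` since the convention is
not universal. Coordinates are eigenvectors scaled by the square roots of
the non-negative eigenvalues.

## The simulator, and what passing tests mean

The generator evolves a uniform random root sequence down the tree under
an equal-rates substitution process (per-branch change probability
`(K−1)/K · (1 − e^{−Kt/(K−1)})`), optionally gaps whole codons at random,
and then overwrites the planted sites so the requested group-A/group-B
state sets are realised exactly; the truth table records every plant.
Plants at adjacent sites are a configuration error unless explicitly
allowed (the adjacent-plant fixture exists to exercise the continuous-run
filter). With the same seed, output is reproducible byte for byte.

The recovery fixtures use an invariant background (rate 0), so planted
precision/recall of 1.0 demonstrates that the scanner's set logic and
filter are correct — not that detection is robust to alignment error,
rate heterogeneity, codon bias, or selection, none of which the simulator
emulates. Background-rate fixtures (rates 0.3–0.7 on trees of total length
about 1) are used for the cross-level consistency and oracle-equivalence
properties, where chance exclusive sites are part of the test rather than
a nuisance.

Problem sizes throughout the test suite are chosen for exhaustive
verifiability: trees of 4–14 leaves, alignments up to 300 columns, 200
random scanner fixtures, enumeration against brute force on 12-leaf trees,
and hypergeometric enumeration up to universe 15. These sizes make the
independent oracles (exhaustive assignment enumeration, full draw
enumeration, brute-force subset filters) exact rather than approximate.

## Known limitations

* Frame errors in codon alignments are rejected, never repaired; upstream
  frameshift correction is out of scope.
* The ML reconstruction fits no substitution parameters; for data where
  rate structure matters, import an external reconstruction through the
  adapter instead.
* MAF handling follows the standard's column-wise alignment orientation;
  rows are never re-oriented, only coordinates are mapped. Species absent
  from a block are reported as absent (`.`), which downstream consumers
  must not conflate with deletions (`-`).
* The core-control template (two focal clades plus one outside clade) is
  fixed to the three-focal-clade design; other templates require filtering
  the enumerated combinations directly.
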