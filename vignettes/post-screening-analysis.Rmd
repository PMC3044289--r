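---
title: "Mining pharmacological interactions from virtual-screening poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining pharmacological interactions from virtual-screening poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A structure-based virtual screen docks a library of `N` compounds into a
protein binding site and ranks them by a physics-flavoured energy score.
Two chronic problems follow.  First, energy scores tend to favour large or
highly polar molecules, so the top of the ranking is biased.  Second, the
docked poses contain a signal the score ignores: if a residue group is
contacted by an anomalously large fraction of the *whole screening
library*, that group is likely to be a genuine anchor point of the pocket
— a *pharmacological interaction* — even when no active compound is known.
pharmint extracts that signal and feeds it back into the ranking.

## Interaction profiles

The binding site is derived from a bound reference ligand: every residue
with a heavy atom within `site_radius` (default 8.0 Å) of a reference
heavy atom is retained.  The default was chosen once, as the radius that
encloses a typical first contact shell around a ligand; it is
configuration, not a fitted value.  Each retained residue is split into a
main-chain group (N, CA, C, O, OXT) and a side-chain group (everything
else), so `K` residues give `2K` profile columns; a glycine contributes an
empty side-chain group that is still a column, keeping the column set
complete and comparable across proteins.

Per docked pose, pairwise energies are computed in three channels —
electrostatic (E), hydrogen bond (H), van der Waals (V) — with a
continuous piecewise-linear trapezoid per channel (clash ramp below
`d0`, descent to the well depth at `d1`, flat well to `d2`, decay to zero
at `d3`).  The defaults

| channel | d0–d3 (Å) | depth (kcal/mol) |
|---|---|---|
| H | 2.3, 2.6, 3.1, 3.6 | −2.5 |
| V | 2.9, 3.3, 4.5, 6.0 | −0.4 |
| E | 2.5, 3.0, 4.5, 6.0 | −2.5 |

were fixed so that *one ideal hydrogen bond exactly reaches the E/H
profile threshold* (−2.5 kcal/mol) while several van der Waals contacts
are needed to reach the V threshold (−4 kcal/mol).  They deliberately do
not reproduce any particular docking engine's parameters bit-exactly; all
of them are exposed through `potential_params()` and a YAML config.  For
the electrostatic channel the attractive well is sign-flipped for
like-charge pairs; the short-range clash penalty keeps its positive sign
in both cases, since a like-charge pair at clash distance is more, not
less, repulsive (a deliberate reading of the "sign-flip" rule as applying
to the attractive part only).

Energies are summed per (compound, residue group, channel), keeping one
pose per compound (the lowest total energy; ties go to the lowest pose
index).  Binarising at the channel thresholds — `e ≤ −2.5` inclusive for
E and H, `e < −4` strict for V, boundary semantics fixed for determinism —
gives three `N × 2K` binary profiles `P(E)`, `P(H)`, `P(V)`.

## The shuffle null and preference `W`

For each column `j` the observed interaction frequency is
`f_j = (1/N) Σ_i p_ij`.  Its null distribution is estimated from randomly
shuffled profiles (default 1000, configurable): the default scheme
permutes all `N × 2K` cells uniformly, which conserves the total number of
interactions and makes columns exchangeable.  Internally the
implementation redistributes the 1-cells as a uniform subset of all cell
positions, which is exactly the image of the ones under a uniform
permutation — the column counts are therefore hypergeometric, and the test
suite checks the estimated moments against that closed form.  Per-row
permutation (conserving each compound's contact count) is exposed as an
alternative; per-column permutation exists only as a degeneracy check.
Whether the null moments should be pooled across columns is moot under
the default scheme (columns are exchangeable), so per-column estimates
are used throughout.

With null mean `μ_j` and standard deviation `σ_j`,

```
z_j = (f_j − μ_j) / σ_j,      W_j = z_j / z_max
```

where `z_max` is the largest z-score of the channel, so the most conserved
column scores exactly `W = 1`.  A column is *called* pharmacological when
`W_j ≥ 0.4` (inclusive).  Degenerate cases are resolved conservatively:
`σ_j = 0` (all-zero or all-one profiles) gives `W_j = 0` with a warning,
and if no column beats the null (`z_max ≤ 0`) all preferences are zero —
no calls are ever produced from a profile with no signal.

## Pharmacological re-scoring

The combined score of compound `i` is

```
combined_i = E_total_i + Σ_channels Σ_j max(W_j, 0) · e_ij
```

i.e. the docked energy plus the compound's energy at preferred groups,
weighted by the preference.  The equation couples two scales: `W` is
dimensionless in `[0, 1]` and `e` is in kcal/mol, so the pharmacological
term is bounded by the energy the compound actually deposits at conserved
groups.  Negative preferences are clamped to zero — conservation is a
non-negative notion, and rewarding *anti*-conserved contacts would let a
compound gain score from avoiding the pocket's anchor points.  With all
preferences zero the combined score reduces exactly to the energy score,
which the tests assert including the induced ranking.  Rankings are
ascending (lower is better), 1-based, with ties broken lexicographically
by compound id so that ranks are reproducible.

## Consensus hot spots

When a set of known actives is available, the *consensus interaction
ratio* of a column is the fraction of actives showing the interaction; a
group with ratio ≥ 0.5 (inclusive) is a hot spot.
`compare_pharma_to_hotspots()` tabulates how many called pharmacological
interactions coincide with hot spots.  The package ships the published
preference/ratio values for two classical benchmark targets (estrogen
receptor α agonist site and HSV-1 thymidine kinase) as
`reference_pharmacology()`; running the two rules over those tables
reproduces the published agreement counts (ERA: 10 calls, 9 hot spots,
the single disagreement being the L387 hydrogen bond; TK: 14 calls, 8 hot
spots), and the acceptance script recomputes exactly that.

## Clustering for hit picking

Top-ranked compounds are often redundant.  Compounds are clustered
agglomeratively (average linkage by default) in two spaces: Euclidean
distance on the concatenated binary E|H|V profile rows (Jaccard exposed
for sparse profiles), and Euclidean distance on atomic composition —
normalised heavy-atom fractions over `{C, N, O, S, P, halogen, other}`,
an alphabet fixed once since the analogy to amino-acid composition
prescribes none.  The linkage is implemented in the package rather than
delegated to `stats::hclust` for one reason only: binary profiles produce
many exact distance ties, and the merge order is made deterministic and
*input-order invariant* by breaking ties on the lexicographically
smallest pair of member labels.  On distance matrices without ties the
result is identical to `hclust`, which the tests verify for all three
linkages.  Two separate trees are produced rather than one combined
distance; a weighted combination is trivial for the user to form, whereas
un-mixing a baked-in combination is not.  Trees export as Newick (labels
with metacharacters are single-quoted) and as Eisen CDT/GTR pairs for
tree-viewer software; one representative per cluster is picked by best
combined score.

## The synthetic fixtures, and what they do not show

Everything is testable offline through three generators.
`generate_profile()` plants conserved columns (independent Bernoulli
cells, `p_cons` vs `p_bg`) with ground truth returned.
`generate_pocket()` builds a ring of serine residues whose side-chain
hydroxyls point at the centre (ring radius 14 Å, backbone pushed outside
the 6 Å interaction cutoff), so an engineered contact at a prescribed
distance touches exactly one residue group — pocket → pose → decomposition
→ profile recovers the engineered bit pattern exactly.
`benchmark_set()` emulates a seeded screen: 10 actives and 990 decoys by
default, every compound with the same number of hydrogen-bond contacts
(so total energies are statistically matched and the energy ranking
carries no information about activity), actives hitting all planted
groups, decoys hitting each with probability 0.55 — high enough that the
planted columns are conserved across the library, which is precisely what
makes them minable without knowing the actives.  Contact distances are
drawn from the flat part of the H well (2.95–3.10 Å) so the H term is
constant and only a small van der Waals term breaks ties.

These fixtures exercise the statistics, the geometry kernel and the
plumbing under known truth; they do not emulate real chemistry.  Cells of
real profiles are not independent (compound series correlate rows),
decoys are not energy-matched in real screens, and molecules are
chain-bonded point sets rather than valence-correct structures.  Passing
tests therefore demonstrate correctness of the method's mechanics, not
screening performance on real targets.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10 000 shuffles for the
moment-matching oracles on 4×2 and 6×4 profiles (Monte-Carlo tolerance of
three standard errors), 100 replicate seeds of the 1000 × 20 planted
recovery experiment at the screening-scale operating point
(`p_cons = 0.6`, `p_bg = 0.05`, 4 planted columns — all planted called and
no background called in ≥ 95 of 100 seeds), and the full 1000-compound
benchmark for the enrichment comparison.  These sizes were chosen as the
smallest at which the statistical claims are sharp.  All randomness flows
through explicit seeds via `withr::with_seed`, so no global RNG state
leaks; the full pipeline writes byte-identical outputs for a fixed seed,
and the report's provenance deliberately excludes timestamps for that
reason.

## Known limitations

* Protein atom typing is template-based with implicit hydrogens: no
  protonation-state prediction, no metal coordination, no covalent
  ligands.
* Pose RMSD matches atoms by input order (after checking element
  sequences) and is not symmetry-corrected; ligand hydrogens, if present
  in input files, are excluded from all distance calculations.
* The energy kernel is a stand-in with configurable parameters; absolute
  energies are only meaningful relative to the fixed profile thresholds.
* Mining assumes the screening library is diverse; a library dominated by
  one chemotype will present that chemotype's contacts as
  "pharmacological".
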