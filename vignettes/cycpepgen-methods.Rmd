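---
title: "Template-based conformer generation for disulfide-cyclized peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based conformer generation for disulfide-cyclized peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycpepgen)
```

## The modeling problem

Peptides cyclized by a single disulfide bond — two cysteines whose SG atoms
form a covalent S–S bond of about 2.05 Å — are a major class of therapeutic
and venom-derived molecules.  Their rings are conformationally restrained
enough that backbone geometry recurs across unrelated proteins, which makes
template-based modeling attractive: rather than searching torsion space *ab
initio*, one mines disulfide-closed backbone fragments from known
structures, organizes them by ring length, and reuses them as scaffolds.

`cycpepgen` implements that strategy end to end: library mining and
clustering, probabilistic template selection, full-atom model assembly with
rotamer side chains and internal-coordinate tail growth, an ensemble
diversity filter, and RMSD-based evaluation with a size-dependent success
criterion.

## Cyclic backbone library

A *cyclic fragment* is the residue span between (and including) two
disulfide-bonded cysteines.  A span qualifies only if

* exactly those two cysteines participate — no further cysteine inside the
  span;
* its length `n_cyc` lies in [3, 30];
* every residue has a complete backbone (N, CA, C, O), and both terminal
  cysteines carry CB and SG;
* nonstandard residues are renamed to their standard parent when the file's
  MODRES annotation provides one; a span containing an unmapped nonstandard
  residue is discarded.

Fragments keep all heavy atoms of the two cysteines (the disulfide is the
ring's closure, so its side-chain geometry matters) and only the backbone of
other residues; interior side chains are rebuilt at modeling time.

Fragments are stratified into at most 28 sub-libraries (one per length) and
clustered on backbone RMSD after optimal superposition over all 4·`n_cyc`
backbone atoms.  The clustering cutoff grows with length,

$$\mathrm{cutoff}(n_\mathrm{cyc}) = 0.1\sqrt{n_\mathrm{cyc}}\ \text{Å},$$

i.e. 0.17 Å at length 3 up to 0.55 Å at length 30, compensating for the
tendency of RMSD to grow with fragment size.  The clustering algorithm is
deterministic greedy leader clustering: fragments are visited in a fixed
order (best resolution first, ties by source identifier and span), each
joins the first cluster whose leader is within the cutoff, and the final
representative is the cluster *centroid* — the member with the smallest
summed RMSD to the others.  Leader clustering was chosen over hierarchical
alternatives for its reproducibility and O(N·K) cost; the visiting order is
part of the library's provenance, so a rebuild from the same corpus is
bit-identical.

## Template selection

For a modeling request the sub-library matching the cyclic length is scored
against the target's cyclic sequence.  Template *i* receives

$$P_i \propto \exp\!\left(w_s \frac{s_i}{s_\max} + w_r \frac{r_i}{r_\max}\right),$$

where `s_i` is the gapless position-wise BLOSUM62 sum between the target
and template cyclic sequences (equal lengths by construction), `r_i` the
crystallographic resolution of the template's source structure, and
`s_max`, `r_max` the per-sub-library maxima that normalize the two
contributions.  The weights default to `w_s = 6.0` and `w_r = -1.0`:
sequence similarity dominates, and among comparably similar templates the
better-resolved one is preferred.  Probabilities are normalized to sum to 1
over the candidate set actually sampled (the sub-library's cluster
representatives) — sampling requires a proper distribution over that set.

Two numerical choices deserve note.  BLOSUM62 sums over short fragments can
be all-negative; when `s_max <= 0` the similarity term is dropped (uniform in
`s`) instead of dividing by a non-positive maximum.  Templates lacking a
resolution record (NMR or cryo-EM sources) are assigned a default of 3.0 Å
before `r_max` is computed, since the probability needs a finite `r_i`.

An identity filter supports leave-similarity-out experiments: templates
whose exact-match fraction to the target is at or above a cutoff are removed
before scoring (a cutoff of 100% removes only exact sequence matches).

## Model assembly

Each model is assembled in three stages:

1. **Cyclic part.**  The sampled template's backbone is copied verbatim
   (the model's cyclic backbone is bit-identical to a library
   representative, so provenance is exact), and the terminal cysteine side
   chains come with it.  Every interior residue receives a side-chain
   conformer drawn from the rotamer library (frequency-weighted), mapped
   through the residue's local backbone frame (origin CA, axes from
   N/CA/C); glycine gets none.
2. **Termini.**  Residues outside the cyclic span are grown one at a time —
   the N-terminal tail first (built outward in reverse), then the
   C-terminal tail — by natural-extension (NeRF) placement with ideal bond
   lengths (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å) and angles, and
   (phi, psi, omega) drawn from per-residue tables covering six coil basins
   (alpha-helical, beta-strand, polyproline-II, extended, bridge and the
   sparser left-handed helix; glycine broadened, proline restricted to
   phi ≈ -65°) with a 14° Gaussian jitter (3° for omega).  Steric clashes
   trigger a redraw.  The basin coverage matters beyond realism: the
   ensemble diversity filter can only be satisfied if the sampled tail
   space is rich enough to hold many mutually distinct conformations, so
   the table spans the full allowed Ramachandran map rather than the three
   most populated basins.
3. **Filters.**  A finished model must pass: peptide bonds within
   [1.23, 1.43] Å; disulfide SG–SG within [1.8, 2.5] Å; no pair of heavy
   atoms at least three bonds apart closer than 2.2 Å.  It is then compared
   with every accepted model: if any optimally-superposed backbone RMSD is
   below 1.0 Å the candidate is discarded.  Generation repeats until the
   requested ensemble size is reached or an attempt budget
   (`n_models x max_attempts_per_model`) is exhausted.

The clash threshold (2.2 Å, pairs separated by ≥ 3 bonds) and the
single-residue growth procedure are this package's own concrete choices for
steps the method family leaves open; both are deliberately permissive —
the goal is physically sane sampling scaffolds, not refined structures.
Ensembles are reproducible: one seeded random stream drives template draws,
rotamer draws and torsion jitter.

### The rotamer library

The bundled rotamer set is intentionally minimal: for each residue type, up
to three side-chain conformers built from idealized internal coordinates at
the staggered chi1 positions (-60°, 180°, +60°; proline uses the
ring-closing pucker), uniform frequencies, and trans-only omega tables.
It is documented plain text (`write_rotamer_library()` /
`read_rotamer_library()`), so a statistically derived library can be dropped
in without code changes.  Side-chain accuracy is explicitly out of scope
for a generator whose models feed downstream refinement and docking;
environment-dependent side-chain placement cannot be decided from the
peptide alone.

## Evaluation

Model quality against a reference structure uses three optimal-superposition
RMSDs: **cRMSD** over Cα atoms (the primary metric), **bRMSD** over N, CA,
C, O, and **aRMSD** over all heavy atoms present in both structures
(intersected per residue, so references with unresolved side-chain atoms are
compared on what they have).  Ensemble accuracy is the *best* (minimum) RMSD
among the first *k* models — the quantity that matters when an ensemble
feeds docking.  A prediction for an *n*-residue peptide succeeds when its
best cRMSD is within

$$\mathrm{rmsd}(n) = 1.0 \times \left[1 + \ln(n / n_0)\right]\ \text{Å},
\qquad n_0 = 3,$$

a cutoff that grows logarithmically so longer, more flexible peptides are
judged proportionally.  Benchmark reports aggregate per length bin, half-open
on the left — a peptide of length *n* falls in bin (a, b] iff a < n ≤ b —
with means of the three best-RMSD metrics and the percent success rate.

## The synthetic-structure generator

Everything above is testable offline because the package generates its own
PDB-format inputs.  A synthetic cyclic span is an ideal-geometry backbone
chain whose uniform period-2 (phi, psi) pattern solves a discrete-helix
closure condition — per-residue twist chosen so that after `n` residues the
chain has turned almost full circle, leaving the two terminal Cα atoms at
disulfide-bridging distance (~4.8 Å) rather than bonded contact.  Patterns
are solved numerically per length (Nelder-Mead on the screw parameters from
a fixed grid of starts), validated for self-avoidance, empirically screened
for construction robustness, and shipped as a table; `solve_ring_torsions()`
regenerates them.  Per-residue torsion jitter (sd 5°) gives seeded
variability, and the terminal cysteines receive CB/SG positions solving the
SG–SG ≈ 2.05 Å closure exactly.  Defective controls — an extra interior
cysteine, a deleted backbone oxygen, an overlong 31-residue span — are
injected at a configurable rate, and the corpus manifest records the
ground-truth qualifying-fragment count per file, which the extractor must
reproduce exactly.

What the fixtures do *not* emulate is equally important: real loops are not
period-2 torsion helices, real libraries contain thousands of fragments per
length rather than a handful, and real PDB headers are noisier than the
REMARK 2/SSBOND/MODRES records the generator writes.  Passing tests
therefore demonstrate the pipeline's correctness — filters, geometry,
scoring, reproducibility — not the biophysical accuracy that only a mined
library of experimental fragments can provide.

## Problem sizes used in the tests

The test suite and the reproduction script run on deliberately small
problems: corpora of 28-35 synthetic structures (one cyclic span per length
3-30 plus defective controls), ensembles of up to 100 models for a 15-mer
with a 10-residue cyclic span, and 50-model ensembles for the
template-recovery check.  These sizes exercise every code path while
keeping a full run in the minutes range on a single core.

## Known limitations

* Interior side chains come from the idealized rotamer set above; no
  environment-aware optimization is attempted.
* Terminus growth is single-residue; no helical-fragment shortcut for long
  tails, which makes very long non-cyclic parts slower to sample well.
* One disulfide per model; multi-bridge topologies are out of scope.
* mmCIF input, hydrogens, and NMR multi-model handling beyond MODEL 1 are
  not supported.
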