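---
title: "Screening predicted helix-receptor complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening predicted helix-receptor complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixscreen)
```

## The problem

Many regulatory interactions in the PP2A-B55 phosphatase system are
mediated not by short linear motifs but by α-helical elements that dock
onto a conserved surface of the B55 regulatory subunit. Structure
predictors can propose such complexes at scale, but raw predictions need
principled triage: which models are confidently predicted *at the
interface that matters*, and how does the helix sit on the receptor?

helixscreen implements that triage as a reusable pipeline:

1. **Interface detection** restricted to the conserved binding site,
2. **Confidence scoring** of the interface from per-residue pLDDT and the
   predicted aligned error (PAE) matrix,
3. **Register annotation** of the binding helix against the receptor's
   surface patches,
4. **Design QC** for refolded designed binders, and
5. **Saturation binding fits** for follow-up affinity measurements.

Every step is exercisable on synthetic fixtures whose ground truth is
prescribed, so the whole pipeline is testable end to end without any
external prediction run.

## Interface detection

Interacting residue pairs between binder and receptor chains are found in
two stages. Stage 1 computes distances between *representative
coordinates* — the Cβ atom, the Cα for glycine, the first atom as a
documented fallback — and keeps pairs within 8 Å (inclusive). Stage 2
measures all atom-atom distances for the surviving pairs and keeps those
with any distance at or below 4 Å, over all atoms present in the file
(hydrogens included if present; predicted models rarely have them).
Waters and heteroatoms never enter either stage. When a binding-site
definition is given, the receptor side is restricted to site members
before stage 1.

Reading "within 8 Å" and "cutoff of 4 Å" as inclusive (≤) is the
conventional interpretation and is applied consistently; the boundary
behaviour is pinned by tests. The Cα-for-glycine representative rule is
this package's documented choice — glycine has no Cβ and some convention
is required.

The two-stage procedure is an optimisation, not a definition, so the
package also ships `interface_residues_exhaustive()`, a single-stage
all-atom all-pairs oracle with the identical contract. The two agree
whenever no atom lies more than ~4.47 Å from its residue's representative
coordinate (if an atom pair touches at ≤ 4 Å and each atom is within
4.47 Å of its representative, the representative pair is within
4 + 2·4.47 < 13 Å; for the compact residues of predicted models the bound
that matters, 8 Å, holds comfortably — the property suite checks equality
on 100 random fixtures and also keeps one adversarial long-side-chain
fixture where the prefilter provably misses a contact).

Residues with pLDDT below 50 are discarded from the detected interface —
low-confidence flanks otherwise drag the interface metrics down. The
exclusion is applied on both chains; a switch
(`exclude_receptor_plddt = FALSE`) restricts it to the binder side, since
the published procedure does not state whether the receptor columns of
the PAE submatrix were shrunk as well.

## Confidence scoring and the screen

Two metrics summarise a model, both computed only if **strictly more
than 7** binder-side interface residues survive the exclusion:

* **ipLDDT** — the arithmetic mean pLDDT over the binder's interface
  residues (the binder is the partner whose confidence is informative;
  the receptor is a fixed, well-folded subunit);
* **iPAE** — the median of the PAE submatrix taken as *binder rows ×
  receptor columns*, in that single orientation. PAE is asymmetric; a
  symmetrised option exists (`symmetrize = TRUE`) but is off by default.

Models with 7 or fewer interface residues receive the sentinel report
(ipLDDT 0, iPAE 30), which by construction can never pass. The screen
itself is `iPAE < 10` **and** `ipLDDT > 70`, both strict, exactly as the
thresholds are printed. Medians of even-sized sets are the midpoint of
the two central values (the R convention; the source procedure does not
say, so the convention is documented and pinned: `{4, 5, 7, 20} → 6.0`).

## Register annotation

The binding helix docks with a recognisable register: hydrophobic
residues at positions *i* and *i + 4* engage patch 1 (the hydrophobic
pocket Y178/D197/M222/L225/V228 in B55α numbering), *i + 1* and/or
*i + 5* engage patch 2 (I284/S287), and the opposite face at *i + 2*
engages the electrostatic patch 3 (D340), with an aromatic flank
(Y337/F343) at the side of the pocket. All patch sets are overridable
via `binding_site()`.

Helices are assigned from backbone dihedrals alone: a residue is helical
iff φ ∈ (−100°, −30°) and ψ ∈ (−80°, −5°), and helices are maximal runs
of ≥ 4 such residues. This window is deterministic, needs no
hydrogen-bond energy model, and is configurable; termini lose one
dihedral each, so an ideal 12-residue helix scores ≥ 10.

The binding helix is the segment with the most patch-1-labelled
residues (ties: more total interface residues, then most N-terminal).
The anchor *i* is the most N-terminal residue whose *i*/*i + 4* pair
both carry patch 1; failing that, the patch-1 residue with the most
atomic contacts to patch-1 receptor residues. Register offsets are
limited to {0, 1, 2, 4, 5}; any other labelled contact — including
supplementary contacts from a preceding helix in helix-loop-helix
binders — is reported in `unassigned_contacts()` and never folded into
the register. Binders with no patch-1 contact raise an explicit
"non-canonical binder" error rather than a fabricated register; cases
where the *i + 2* role is played by a loop residue likewise surface via
`unassigned_contacts()` rather than a guess.

## Design QC

Refolded designed binders are judged on two numbers: the mean pLDDT of
the binder residues (pass requires strictly > 90) and the RMSD between
template and refold. The default RMSD is *pose-sensitive*: the two
models are superposed on their receptor-chain Cα atoms and the deviation
is then measured over binder Cα atoms without re-fitting, so a binder
that refolds perfectly but docks elsewhere scores poorly — the measure
is meant to capture whether the design adopts the structure *and pose*
it was designed to adopt. A fold-only mode (`mode = "fold"`) superposes
on the binder itself. Cα-only selection is the default because refolded
side chains are not comparable. Superposition uses the optimal
least-squares proper rotation (reflections are explicitly excluded);
collinear reference sets are computed but flagged.

## Binding fits

Saturation curves are fit to the one-site specific binding equation
`Y = Bmax · X / (Kd + X)` by unweighted Levenberg-Marquardt least
squares; Kd is exactly the half-saturation concentration. Initial values
come from the curve itself (Kd₀ the concentration nearest half the
maximum response, Bmax₀ the maximum). Standard errors derive from the
local curvature at the optimum. No nonspecific linear term is included
(the underlying equation has none) and concentrations are fixed to nM
internally. Steady-state SPR Req-vs-concentration data fit the same
model through the same function; kinetic global fitting is out of scope.

The default titration ladder is three-fold from 1.8 nM with the 500 nM
endpoint appended (1.8, 5.4, 16.2, 48.6, 145.8, 437.4, 500 nM). The
assayed range is printed as 1.8-500 nM and the ladder honours both
endpoints; a pure three-fold series cannot, and this is the package's
documented resolution.

## The synthetic generators

`make_helix_complex()` builds an ideal α-helix (φ = −57°, ψ = −47°,
ω = 180°, standard backbone geometry, tetrahedral Cβ) and places
single-residue receptor probes so that each prescribed (offset → patch)
contact attains its closest-approach distance *exactly* (the Cβ atoms
face each other at that distance; all other probe atoms are built
outward) while all unintended cross-chain residue pairs stay > 6 Å
apart. Infeasible demands — e.g. an approach distance so short that
probes collide with neighbouring residues — raise an explicit
infeasibility error. The receptor is probes, not a folded β-propeller,
deliberately: every quantity the screen computes depends only on
distances, confidence values and residue identities, all of which the
probes control exactly. A seeded rigid-body jitter de-aligns the frame
without touching any distance.

`make_pae()` / `make_confidence()` produce block-valued PAE matrices and
uniform-or-overridden pLDDT profiles with prescribed interface medians;
`make_binding_curve()` adds seeded Gaussian noise to the one-site curve.
All generators are pure functions of (spec, seed).

What the fixtures do **not** emulate: real PAE error structure (only
block values), side-chain rotamers, receptor fold context, crowded
interfaces, or experimental FP artefacts (g-factor drift, probe
depletion). Passing tests therefore demonstrate the correctness of the
computations, not the biological error rates of a live screen.

## Problem sizes and numerical choices

The property suite runs 100 random interface fixtures (binders of 8-20
residues, 3-8 probes), 50 register-recovery fixtures, 20 rigid-motion
superposition checks against a rotation-grid oracle (agreement within
1e-3 Å), and 200 noisy titrations at Kd 6 nM with noise at 2% of Bmax
(median relative Kd error must stay under 10%); these sizes give stable
statistics while keeping the suite quick to run. Distance cutoffs are
compared with a 1e-12 Å slack so that exactly-placed fixture contacts at
the boundary are kept; rigid-transform invariance is asserted at 1e-9 Å.
Chain roles default to "first chain is receptor" and are overridable
per file, since prediction servers differ in chain order; the
confidence index map always follows the structure's own residue order,
making the row/column convention of the PAE matrix explicit rather than
assumed.

## Known limitations

* Insertion codes and altloc variety are rejected/reduced at read time;
  multi-model files keep the first model only.
* The helix caller is a φ/ψ window, not DSSP: 3₁₀/π helices at window
  edges and distorted helices may be split or missed.
* `screen_count()` will reproduce a published screen tally only from the
  same per-model metrics table; recomputing those metrics requires the
  original predicted models.
* The register reports what the structure shows; it does not predict
  binding from sequence.
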