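---
title: "Electronegativity-equalization charges and their fragment approximations"
author: "eemkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronegativity-equalization charges and their fragment approximations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The Electronegativity Equalization Method (EEM) assigns every atom an
effective electronegativity that is linear in the partial charges and
requires all of them to equalize at a common molecular value
$\bar\chi$. For a molecule of $N$ atoms with positions in Ångström this
gives one linear equation per atom,

$$B_i\,q_i \;+\; \kappa \sum_{j \ne i} \frac{q_j}{R_{ij}} \;-\; \bar\chi
\;=\; -A_i ,$$

closed by the total-charge constraint $\sum_i q_i = Q$. The per-atom-type
constants $A_i$ (electronegativity-like) and $B_i > 0$ (hardness-like),
together with the set-level distance-coupling constant $\kappa > 0$, form
an *EEM parameter set*; they are empirical quantities fitted elsewhere
against quantum-mechanical reference charges, and their applicability is
limited to the atom types they were fitted for. `eemkit` treats parameter
sets as data (an XML template with either element or bond-order
granularity), checks applicability before every solve, and can alias one
element's parameters to another — the standard device for deuterated
structures, where D is kept as a first-class element and typically
receives the parameters of H.

Charges are in units of the elementary charge $e$; $\kappa/R$ must carry
the units of $B$ with $R$ in Å, so parameter sets must be transcribed in
Å-consistent units (stated in each set's provenance).

`solve_full_eem()` assembles the dense $(N{+}1)\times(N{+}1)$ augmented
system — the $(N{+}1)$-th unknown is $\bar\chi$, the last row the charge
constraint — and factorizes it directly (LAPACK), which is $O(N^3)$ time
and $O(N^2)$ memory. The 32-bit mode performs both assembly and
factorization in single precision, halving memory at some cost in
accuracy; results are returned in doubles.

### Numerical choices

* Coincident atoms make the $1/R$ coupling singular; pairs closer than
  $10^{-4}$ Å (below any meaningful coordinate precision) are rejected
  with both atom indices named.
* The direct factorization refuses silently ill-conditioned systems and
  reports a reciprocal-condition diagnostic instead.
* Charge conservation of the full solve is exact to solver tolerance
  ($10^{-6}\,e$ at 64-bit is asserted in the tests; typical residuals are
  far smaller).

## Fragment approximations for large systems

For systems beyond a few tens of thousands of atoms the dense solve is
impractical on desktop hardware. Two approximations trade a controlled
amount of accuracy for locality:

**Cutoff** builds, for *every* atom, the fragment of all atoms within a
cutoff radius $R$ (cell-grid neighbor search, cell edge $= R$, 27-cell
scan, so fragment construction is near-linear in $N$), solves each
fragment's EEM system, and takes each atom's charge from its own
fragment. **Cover** solves fragments only for a covering subset of atoms:
a greedy scan in input order makes an atom a center unless it already
lies within the assignment radius $R/2$ of an existing center, and every
atom then takes its charge from its nearest center's fragment — so each
atom sits at most $R/2$ from its fragment center, and whenever the
minimum interatomic spacing is below $R/2$ (always true at protein-like
density with the default radii) at most half the atoms become centers.
Peak memory of both methods is bounded by the largest fragment's system,
never $N^2$; the job tag records the largest matrix actually assembled.

### Fragment charge and the far-field refinement

A fragment's solve needs its own total-charge constraint. The first pass
allocates the molecular charge proportionally, $Q_f = Q\,m/N$ for a
fragment of $m$ atoms, which keeps fragments of neutral molecules
neutral and scales smoothly. That bare scheme, however, reproduces full
EEM only locally: full EEM transfers charge over arbitrary distances
(its polarizability grows superlinearly with size, a known artifact of
the classical model), and on globular systems the discrepancy
concentrates at the surface, where a local ball sees a maximally
asymmetric environment. Measured on 10,000-atom synthetic globules, the
bare scheme's worst-case deviation from full EEM is roughly twice the
accepted benchmark envelope for an 8 Å cutoff.

The default assembly therefore adds one *far-field refinement pass*:
after the first pass, each fragment is re-solved without its charge
constraint, embedded in the electrostatic potential of the frozen
first-pass charges outside it,

$$\bigl(\mathrm{diag}(B) + K_f\bigr)\,q_f
 \;=\; \bar\chi_{\mathrm{est}} - A_f - \varphi^{\mathrm{ext}}_f ,$$

where $\varphi^{\mathrm{ext}}$ is the $\kappa/R$ potential of the
first-pass charges beyond the fragment and
$\bar\chi_{\mathrm{est}}$ is the mean of the first-pass fragment
electronegativities. Every charge still comes from a small fragment
system; the refinement costs one extra sweep plus an $O(N^2)$-time,
$O(N)$-memory far-field accumulation that is negligible against the
$O(R^6 N)$ fragment solves at practical sizes. Exactly **one** pass is
performed: the underlying fixed-point iteration is not contractive at
small radii (we measured divergence at 8 Å even with damping), while a
single pass is uniformly beneficial. `refine = FALSE` exposes the bare
scheme.

Two properties the approximations keep exactly: with
$R \ge$ the molecular diameter every fragment is the whole molecule and
both methods reproduce the full solve to solver precision, and a cover
plan whose centers are all atoms reproduces the cutoff solve
identically. Conservation, however, is no longer exact: the assembled
charges carry a residual $\sum q - Q$ that is reported in the job tag
and left in place by default, because redistributing it would distort
the per-atom comparison against full EEM; `renormalize = TRUE` spreads
it uniformly when exact totals matter more.

## What the synthetic generator emulates — and what it does not

The test and benchmark molecules are seeded point clouds: uniform random
positions in a sphere at 0.1 atoms/Å$^3$ (protein-like density) with a
1.0 Å minimum separation, elements H/C/N/O drawn at frequencies
.5/.3/.1/.1, grouped into pseudo-residues of ten atoms; chains are
collinear atoms at fixed spacing (1.5 Å, a bond-like distance, for the
benchmark chain fixture). Parameter sets are drawn once per benchmark
with $A \in [2,8]$, $B \in [6,14]$, $\kappa \in [0.3,0.6]$ — ranges that
mimic published protein-applicable sets and keep the systems
well-conditioned (the suite audits condition numbers below $10^6$ at
$N = 50$ over 100 seeds). These fixtures reproduce the *scale*,
*density* and *composition* of protein systems, which is what the
fragment approximations are sensitive to. They have no bonds, no
secondary structure, and no physically meaningful geometry, so passing
tests demonstrate the numerics of the method — conservation, invariances,
fragment-versus-full accuracy, cover economy — not the chemical accuracy
of any particular published parameter set on real proteins.

Against that benchmark layout (three 10,000-atom globules, full EEM as
reference) the suite verifies the cutoff method's pooled deviations
within the accepted envelope: maximum below $0.015\,e$ and mean below
$0.008\,e$ at 8 Å, maximum below $0.008\,e$ and mean below $0.004\,e$ at
12 Å, with deviations non-increasing in the radius, and cover-center
counts at no more than half the atoms on every fixture.
`scripts/acceptance.R` recomputes exactly these quantities from scratch.

## The QSPR pKa workflow

Charges carry reactivity information: in a phenol or carboxylic acid the
most acidic proton is the H with the highest positive charge, and linear
QSPR models map a handful of charge descriptors to pK$_a$. `eemkit`
implements the complete workflow: descriptor extraction binds computed
charges to descriptor names through a per-molecule atom-name map (atoms
are identified by name and role, not index); `make_dissociated()` builds
the anion of an acid by deleting the acidic H and decrementing the total
charge; `fit_qspr()` is ordinary least squares with explicit
rank-deficiency diagnostics; `cross_validate()` follows the
repeated-random-subsampling convention (draw a training subset — by
default 35 of 45 — without replacement in each round, validate on the
rest; rounds independent), with disjoint $k$-fold mode as an option;
`ionized_fraction()` is the Henderson–Hasselbalch form
$10^{pH-pK_a}/(1+10^{pH-pK_a})$. Model parameters are data, not code:
models ship as JSON files. The bundled phenol model is synthetic and
illustrative — substitute a published, QM-calibrated model (transcribed
into the same JSON form) for real predictions.

## Design choices where the design was open

* **Altlocs** resolve to the highest-occupancy conformer, ties broken
  first-in-file; **multi-model** files use model 1 — the standard
  single-conformer conventions.
* **Element inference** for PDB/PQR files without element columns
  follows the surviving PDB v3 naming rules (ion names equal to their
  residue name, organic single-letter elements in standard residues,
  digit-free two-letter names for het atoms) and *fails loudly* on names
  readable two ways rather than guess.
* **Bond multiplicity** for bond-order-aware parameter sets is the
  highest order incident to the atom (aromatic counts as 2), taken from
  MOL/SDF/MOL2 bond blocks; PDB/PQR inputs carry no bond orders, so only
  element-granularity sets apply to them and anything else is an error.
* **Registry order** of built-in sets is a documented constant,
  user-overridable; default selection returns the first fully applicable
  set, else the least-missing set with a warning.
* **MOL2 dialect**: charges are written under `USER_CHARGES`, with
  coordinates and charges at 4 decimals, chosen so write/read round-trips
  are bit-stable at printed precision.
* **CLI**: one JSON config file per run, at most 10 computation-option
  combinations, JSON + CSV reports; per-job failures are recorded without
  aborting the run, and the exit status is non-zero only when every job
  fails. Default method by size: full below 20,000 atoms, cutoff below
  100,000, cover above — documented stand-ins for a size-adaptive
  default, with a 12 Å radius and 64-bit precision.

## Known limitations

* Classical EEM exaggerates long-range polarizability with growing
  system size; charges on very large single systems are best used
  comparatively (between conformers, residues or subunits), not as
  absolute values.
* The fragment methods' conservation residual grows with the surface
  area of the system (it is a sum of many small per-fragment
  truncations); inspect `charge_residual` in the job tag.
* No protonation, bond perception, or structure repair is attempted:
  inputs must be complete and properly protonated.
* The shipped parameter sets and the shipped QSPR model are synthetic
  demonstrations; scientific conclusions require published, validated
  parameter values loaded through the XML/JSON templates.
* PDBx/mmCIF input is not implemented.
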