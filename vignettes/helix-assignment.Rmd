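---
title: "Geometric helix assignment from C-alpha traces: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric helix assignment from C-alpha traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhelix)
```

## The model

polyhelix treats helix assignment as two separable problems: a
*minimization* problem (find, for every four consecutive Cα atoms, the
genuine helical curve that best fits them) and a *restraint satisfaction*
problem (decide from the fitted parameters which residues belong to which
helix type). The backbone is thus modelled as a series of short helical
curves — a polyhelix — rather than through hydrogen bonds or dihedral
angles.

A helical curve is parameterized as
$$\mathbf{c}(u) = \mathbf{r}_0 + \mathbf{R}\,\bigl(r\sin(ut),\; r\cos(ut),\; u\,p\bigr)^\top$$
with radius $r$ (Å), rise per residue $p$ (Å) and turn angle $t$ (degrees);
integer steps of $u$ advance one residue. We fix the parametrization so
that one residue advances the phase by $t$ and the axial coordinate by $p$:
this is the only reading under which the chord identity
$d^2 = p^2 + 4r^2\sin^2(t/2)$ links the consecutive Cα distance
$d \approx 3.8$ Å to the familiar α-helix geometry
($r = 2.314$ Å, $p = 1.516$ Å, $t = 100.1^\circ$), and under which the
turn-angle relation
$t = 2\arcsin\bigl(\tfrac12\sqrt{d^2-p^2}/r\bigr)$
is dimensionally consistent (the square root is required; without it the
arcsine argument has units of Å).

### Curve fitting

For each sliding quadruple the fit proceeds in three stages.

1. **Initial estimates.** A closed-form geometric construction: the two
   differences of successive virtual-bond vectors are perpendicular to the
   axis of any exact helix, so their cross product gives the axis
   direction; an algebraic (Kåsa) circle fit in the axis-normal plane gives
   the radius; the mean axial bond advance gives the rise; the chord
   identity gives the turn angle. For a quadruple lying exactly on a
   helical curve this reproduces the curve's $(r, p, t)$ to machine
   precision (a tested contract), and under 0.05 Å coordinate noise it
   stays within 0.1 Å / 5° of the generating parameters for 99% of draws.

2. **Grid search.** $r$ and $p$ are enumerated over
   $[r_m \pm 0.25]$ × $[p_m \pm 0.25]$ Å at a 0.01 Å step (endpoints
   inclusive); $t$ follows from the chord identity with the mean of the
   three consecutive distances (the pseudocode computes a single $t$ per
   cell, and the mean makes that single value well defined for noisy
   quadruples). Cells with impossible geometry ($r \le 0$, $p < 0$,
   $d \le p$, arcsine argument > 1) are skipped; if every cell is skipped
   the fit is marked invalid and the residue can never pass a threshold.

3. **Superposition.** Each candidate curve's four index points are
   superposed onto the quadruple by Kabsch/SVD with reflections excluded.
   The *objective* minimized across the grid is the index-paired RMSD; the
   *reported* Δ is the closest-point RMSD of the four atoms to the winning
   curve (each atom's parameter searched within ±1 residue of its index,
   to 1e-8 parameter tolerance, so the search cannot capture the next
   turn). For well-fitting quadruples the two numbers agree closely; both
   are exposed (`delta`, `rmsd_paired`) so the distinction is testable.
   Ties across grid cells break deterministically to the first-encountered
   cell in ascending $r$-then-$p$ order.

The helix axis is the rotated $+z$ direction, re-oriented to have positive
projection on the quadruple's N→C displacement so that the axis angle
$a_i$ between consecutive windows is well defined; $a_i = 0$ is assigned
to the first profiled residue of a segment, which has no predecessor axis.

### Scores and the combiner

Each fit is scored against the three standard protein helices:

| class | μ_r (Å) | σ_r | μ_p (Å) | σ_p | μ_t (°) | σ_t | σ_Δ (Å) |
|-------|---------|------|---------|------|---------|------|---------|
| α     | 2.314   | 0.061| 1.516   | 0.086| 100.1   | 2.56 | 0.031   |
| 3₁₀   | 2.109   | 0.118| 1.829   | 0.138| 107.4   | 5.90 | 0.038   |
| π     | 2.779   | 0.086| 1.196   | 0.056| 82.8    | 2.80 | 0.056   |

The default score is the **sum of the four squared z-scores**
$(x-\mu)^2/\sigma^2$ (with $\Delta^2/\sigma_\Delta^2$ for the RMSD term) —
a Mahalanobis-style distance, zero exactly at the class mean with Δ = 0.
This was a genuinely open design point and deserves its rationale. A
*product* of the four terms (available as `combiner = "product"`)
collapses to zero whenever any single parameter happens to sit at its
class mean, which destroys discrimination. A sum of the conventional
half-variance terms $(x-\mu)^2/2\sigma^2$ fails differently and more
subtly: an ideal α-helix then has a 3₁₀ score of
$1.51 + 2.57 + 0.77 + 0 = 4.85$, *below* the 3₁₀ threshold $g_T = 6$ — and
since the 3₁₀ pass runs before the α pass, every clean α-helix would be
swallowed as 3₁₀, which is irreconcilable with the ~95% α agreement this
family of methods shows against hydrogen-bond assignments. Dropping the
½ doubles the ideal-α 3₁₀ score to 9.69 > 6 while keeping every genuine
3₁₀ residue (score ≈ 0 at its own mean) well inside the threshold; all ten
default thresholds then separate the classes as intended. The sum-of-z²
combiner is therefore the package default, and the thresholds below are
interpreted on that scale.

### Assignment

Ten thresholds drive the sequential assignment — score bounds
$h_T = 20$, $h_{max} = 160$, $g_T = 6$, $\pi_T = 14$; axis-angle bounds
$a_T = 20°$ (α start), $a_G = 10°$ (3₁₀ start), $a_I = 20°$ (π start),
$a_{max} = 40°$ (merge/extension); RMSD bounds $\delta_G = 0.12$ Å (3₁₀
C-terminal extension) and $\delta_{max} = 0.3$ Å (α merge). π-helices are
assigned first (start requires $\pi_i < \pi_T$ and three consecutive axis
angles below $a_I$; the window tail claims four trailing residues), then
3₁₀ (start on $g_i < g_T$, $a_i < a_G$; two extra residues when two
consecutive $\delta$ values stay below $\delta_G$), then α (start on two
consecutive $h < h_T$ plus $a_i < a_T$), followed by α-only merging across
gaps of at most three residues (every gap residue must satisfy
$a \le a_{max}$, $h < h_{max}$, $\delta < \delta_{max}$) and a two-residue
C-terminal extension gated by $h_{max}$ and $a_{max}$. Minimum lengths
(α ≥ 4, 3₁₀ ≥ 3, π ≥ 5) are enforced post hoc; sub-minimal runs return
their residues to the unassigned pool. Left-handed helices are found by
mirroring the coordinates (negating x flips chirality exactly) and
re-running the three passes on whatever is still unassigned; the
right-handed passes run first, and a residue once assigned is never
reassigned.

Several bounds are silent in the bare pseudocode and are resolved
conservatively here: scores exist only for residues with a complete
4-residue window, and any threshold test on a missing value fails; tail
loops and extensions clip at the segment end and stop at the first
already-assigned residue; merging never bridges residues held by a 3₁₀ or
π helix.

## Input handling

Chains are read from PDB-format text (first model only), one Cα per
residue, with alternate locations resolved by highest occupancy and ties
by lowest altloc letter; HETATM Cα of modified residues such as MSE are
kept, waters and calcium ions (atom name "CA", element Ca) are not.
Chains are split into contiguous segments wherever a consecutive Cα–Cα
distance leaves the 2.5–4.3 Å window — wide enough for both trans
(~3.8 Å) and cis (~2.9 Å) peptide bonds; numbering gaps alone do not
split, because coordinates, not author numbering, are the authority on
contiguity. How the original data sets treated disordered residues is not
documented; splitting at geometric breaks is this package's answer, and
each segment is assigned independently.

## The synthetic generator and what tests show

All validation fixtures are generated, not downloaded. The generator
places residues at integer parameters of an exact helical curve and
optionally adds isotropic Gaussian coordinate noise (typical test values
0–0.15 Å, the scale of coordinate uncertainty in good crystal
structures). Composite fixtures embed a helix between extended-strand
flanks (E-class geometry: r = 0.96 Å, p = 3.34 Å, t = 177.9°), joined at a
3.8 Å step, or join two helices at a prescribed inter-axis kink.

Chosen study conditions: planted helices use each class's standard
parameters; the α plant is 12 residues, the π plant 8, and the 3₁₀ plant 8
(all inside the observed length ranges). The 3₁₀ length deserves a note: a
6-residue 3₁₀ plant between strand flanks yields *no* annotation under a
faithful hand-trace of the assignment pseudocode — the junction windows
inflate the first axis angle and the δ values, so the surviving g-run is
two residues and the minimum-length filter removes it. That is the
algorithm's honest behaviour at its resolution limit, and the test suite
pins it; the planted-fixture demonstration therefore uses 8 residues,
where the pseudocode cleanly yields exactly one 3₁₀ helix.

What these fixtures do *not* emulate: real coil (which is heterogeneous,
not ideal strand), sequence-dependent distortions, lattice contacts, and
the length/composition distributions of real proteins. Passing tests
therefore demonstrate correctness of the geometry, the scores and the
assignment logic under controlled conditions — not benchmark-level
agreement with hydrogen-bond assigners on the PDB, which is out of scope
here.

Problem sizes are kept at desk scale by design: 30-residue traces for
parameter-recovery checks, 50–100 random quadruples for the superposition
and grid-optimality oracles, 20-segment Monte-Carlo sweeps for noise
monotonicity. These sizes already exercise every code path; the method is
O(grid × windows) and scales linearly in chain length.

## Numerical choices and degenerate inputs

* Grid endpoints inclusive; 51 × 51 cells per window at the defaults.
* Collinear or coincident quadruples are flagged invalid (axis cross
  product below 1e-10 of the bond-length scale) and fail all thresholds;
  superposition refuses point sets whose second singular value is
  numerically zero.
* The closest-point search uses `stats::optimize` with both interval
  endpoints re-checked, since golden-section can miss an endpoint minimum
  by its tolerance.
* δ at residue *i* pools the squared closest-point distances of the
  windows starting at *i*−2 … *i*+1 (those that exist and are valid);
  with four atoms per window this equals the RMS of the available window
  Δ values. A per-window-mean alternative reading exists; the pooled form
  was chosen and is pinned by tests.
* σ in `fit_normal` uses the population (n) denominator — an arbitrary
  but fixed and documented convention.
* Greedy leader clustering (first-fit by representative RMSD, input
  order) stands in for the original geometric clustering algorithm, whose
  details are not part of this package's sources; its properties
  (partition, threshold monotonicity) are what the tests rely on.

## Limitations

* Pure Cα geometry: no hydrogen-bond evidence, so assignments near frayed
  helix termini can differ from hydrogen-bond-based tools by a residue or
  two — visible even on ideal fixtures, where junction windows shift the
  detected start one residue into a planted helix.
* Only α, 3₁₀ and π types; no strands, turns or polyproline helices.
* Helices shorter than the minimum lengths (and 3₁₀ shorter than ~7
  residues between non-helical flanks, see above) are not recoverable.
* Fixed-radius, fixed-pitch curves: super-helical coiled-coil curvature
  shows up as axis-angle drift, not as a model parameter.
* mmCIF input is not implemented; convert to PDB format first.
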