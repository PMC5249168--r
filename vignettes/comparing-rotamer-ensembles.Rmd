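---
title: "Comparing side-chain rotamer ensembles between crystal and solution"
author: "RotamerEnsembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing side-chain rotamer ensembles between crystal and solution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RotamerEnsembles)
```

## The question and the model

X-ray structures show most side chains in a single conformation, frozen
under the influence of the crystal lattice. When molecular dynamics
trajectories of the same protein are available both in a solvated crystal
unit cell and in bulk solution, one can ask, residue by residue, what the
lattice does to side-chain conformation and dynamics. This package
implements that comparison as a pipeline over discrete rotamer states.

Each rotameric residue (every type except alanine and glycine, and
excluding disulfide-bonded cysteines) is reduced, frame by frame, to the
nearest state of a rotamer library. For residue $i$ under condition $y$
(solution or crystal) the sampled frames give a normalized probability
vector $P_i^y(x)$ over the residue's $N_i$ library states. All statistics
are functionals of these vectors:

* **Likelihood score.** With $x_i^{xray}$ the state assigned to the X-ray
  side chain and a null model $P^{rand}(x) = 1/N_i$ in which every state is
  equally accessible,
  $L^y = \frac{1}{n_{res}} \sum_i P_i^y(x_i^{xray}) \, N_i$.
  Normalizing by $1/N_i$ stops small residues (three states) from
  dominating the average just because they match at random more easily.
  The quotient $L_{crystal}/L_{solution}$ is above 1 when the crystal
  ensembles track the X-ray conformations more closely.
* **Overlap coefficient.** $OC = \sum_x \min(p^S_x, p^C_x)$, 1 for
  identical histograms, 0 for disjoint ones; identically $1 - \tfrac12
  \lVert p^S - p^C \rVert_1$. A Kullback–Leibler divergence is computed
  alongside as a cross-check; over synthetic cohorts its rank correlation
  with OC is strongly negative, as expected for two measures of the same
  discrepancy.
* **Configurational entropy.** $S_{conf} = -k_B \sum_x p_x \ln p_x$ per
  residue, reported as $T\,S$ in kcal/mol with $T = 300$ K and
  $k_B = 0.0019872$ kcal/(mol·K). The intra-well (thermal) entropy term is
  deliberately not computed: it is assumed equal across states of a given
  side chain and cancels in the condition difference
  $T\Delta S_{conf} = T(S_{crystal} - S_{solution})$, which is the only
  quantity reported. Negative values mean the side chain is less dynamic
  in the crystal.
* **Rotamer agreement.** A simulated ensemble "agrees" with the X-ray
  model when the X-ray state is one of the two most populated sampled
  states. Ties with the second-most-populated state are all included, and
  never-visited states are never counted as dominant. By default the
  comparison uses assigned state IDs; a stricter mode re-checks the raw
  X-ray chi vector against the dominant states' modal angles with a
  ±30° per-angle tolerance, every angle having to match.
* **Region classification.** Each residue lands in one of four quadrants
  of the $(OC, T\Delta S_{conf})$ plane: I, little effect on conformation
  or dynamics ($OC \ge 0.5$, $|T\Delta S| \le 0.5$ kcal/mol); II, changed
  conformation with similar dynamics; III, both changed; IV, changed
  dynamics with maintained conformation. Boundaries are inclusive toward
  region I.

The model treats each residue's inter-well dynamics as independent of its
neighbours. That keeps the entropy additive and the statistics cheap; it
also means coupled side-chain motions are invisible to this analysis.

## Rotamer assignment

The library is a plain TSV shipped with the package
(`inst/extdata/rotamer_library.tsv`): one row per state with modal chi
angles in degrees, states ordered within each residue type so state IDs
line up with histogram axes built from the same table. Modal values follow
the penultimate rotamer library where tabulated; the lysine and arginine
terminal enumerations follow the standard gauche+/trans/gauche− well
naming at the published state counts (27 and 34). Any table in the same
dialect can be substituted via `loadRotamerLibrary(path)`, which is the
route to use if state IDs must match a specific published ordering
exactly.

"Nearest" is defined as the state minimizing the **maximum** per-angle
circular deviation, with ties broken toward the lower state ID. The max
metric was chosen over an RMS-style metric because it mirrors the
agreement criterion (every angle must match within tolerance): a chi
vector within a uniform tolerance of some state is guaranteed to be
assigned to a state at least that close. For the 2-fold degenerate
terminal dihedrals (PHE/TYR chi2, ASP chi2, GLU chi3) the two chemically
indistinguishable atom labelings differ by 180°; these angles are folded
into (−90°, 90°] and compared with period 180, so both labelings are
equidistant from every state. Without the period-180 metric, angles near
the fold boundary (e.g. 89° vs −89°) would appear maximally distant when
they are chemically 2° apart.

Assignment is deterministic, total on library residue types, and
idempotent on modal vectors; these properties are exercised as round-trip
tests over the entire library.

## Crystal environment

Crystal contacts: a residue is contacting when any heavy atom lies within
4.0 Å (boundary inclusive, the usual contact-program convention) of a
heavy atom of any symmetry- or translation-related copy of the asymmetric
unit. Copies are generated from a small built-in operator table (P1,
P2₁, P2₁2₁2₁, C2) and ±1 cell translations by default; the shell is
configurable. Hydrogens are excluded throughout, as are waters and
heteroatoms by default. Contact detection is validated against a
brute-force all-pairs oracle on toy mini-crystals and is exactly
monotone in the cutoff.

Solvent exposure: per-residue SASA is computed per chain in isolation
with a Shrake–Rupley procedure (probe 1.4 Å) using deterministic
golden-spiral test points at a target density of 15 points/Å², then
divided by the residue type's theoretical maximum in an extended
tripeptide (packaged table, source in its header). A residue is exposed
when this fraction is strictly greater than 0.2. Because point placement
differs between SASA implementations, exposed-residue counts reproduce
other programs only to within a residue or two near the threshold; the
package's own tests therefore allow a ±2-residue margin on
exposure-derived counts while requiring contact and rotamer counts to
match exactly.

## Windows, pooling, uncertainty

Trajectory frames are windowed before anything else; the default window is
the last half of each series (equilibrated production), with an optional
stride. Lattice copies in equivalent crystal environments (e.g. the two
copies of chain A in a unit cell simulated as P1) are pooled by summing
state counts before normalizing; the pooling map is configuration. An
X-ray side chain modelled with alternate locations contributes its A
conformer to the comparisons, with the other conformer's state recorded
as an alternate.

Sampling uncertainty is estimated by recomputing each per-residue
statistic on two equal-length, non-overlapping halves of the window (the
first half takes the extra frame when the window is odd). The min/max of
the two serve as lower/upper bounds, and the Pearson correlation of the
per-residue values between halves summarizes sampling adequacy for the
whole set. For stationary synthetic ensembles of 10,000 frames this
correlation exceeds 0.99; slowly-mixing trajectories will show visibly
less, which is the point of reporting it.

KL divergence on sampled histograms meets empty bins; by default a
pseudocount of $1/n_{frames}$ is added to every bin (then renormalized)
before the divergence is taken. With a pseudocount of zero the divergence
is returned as +Inf, with a warning rather than an error, so the OC — which
needs no smoothing — remains the primary overlap measure.

## The synthetic generator

The generator stands in for trajectories that cannot be shipped: each
residue is a stationary categorical mixture over library states with
wrapped-Gaussian within-well noise (default SD 8°, truncated at 3 SD
before wrapping so wells at typical separations cannot bleed into each
other). It reproduces the marginal, per-residue behaviour of an
equilibrated trajectory window and provides closed-form ground truth
($OC$ and $T\Delta S$ of the true mixtures), which is what makes
parameter-recovery testing possible. An optional sticky-Markov mode adds
frame-to-frame autocorrelation with the same stationary law, for
exercising the two-segment uncertainty machinery under slow mixing.

What the generator does **not** emulate: backbone-coupled rotamer
preferences, correlated motions between residues, non-rotameric tail
angles, force-field physics, or drift between conditions. Passing
recovery tests therefore demonstrates that the pipeline measures what it
defines on stationary ensembles; it says nothing about force-field
accuracy or convergence of any particular simulation.

`wellSeparatedStates()` selects states whose pairwise max-metric
separation exceeds a threshold (50° by default). Recovery experiments
draw mixtures over such states so that, with truncated noise, assignment
is exact and the only error left is binomial sampling noise — the regime
in which recovered $OC$ and $T\Delta S$ converge to truth as
$1/\sqrt{n_{frames}}$. The packaged validation uses 50 residues at 10,000
frames each, where worst-case recovery errors stay below 0.02 (in OC
units and kcal/mol respectively); these sizes keep the whole validation
run under a few seconds on one core.

## Degenerate inputs and numerical choices

* Empty frame windows are errors; empty state series assign to empty
  series rather than failing.
* Residues missing side-chain atoms are skipped with a warning and a
  machine-readable exclusion reason in the run manifest, never a crash.
* Disulfide detection uses an SG–SG distance of ≤ 2.3 Å, overridable.
* Probabilities are validated to sum to 1 within 1e−9; entropy uses
  $0 \ln 0 = 0$ exactly.
* Population (divide-by-$n$) standard deviations are used in set
  summaries, stated in the output header; with a handful of residues per
  set the distinction from sample SD is visible, so it is fixed and
  documented rather than configurable.
* All angle arithmetic lives in (−180°, 180°], with 180° mapped to +180°.

## Limitations

* The space-group operator table covers the common protein groups needed
  here, not the full 230; unsupported symbols are fatal errors rather
  than silent P1 fallbacks.
* The shipped rotamer library's ARG/LYS state enumerations carry the
  published state counts but not a verified published ordering; analyses
  that must match a specific table's state IDs should load that table
  explicitly.
* Exposure counts inherit the ±2-residue SASA-implementation margin
  discussed above.
* No inter-residue coupling, no enthalpy, no intra-well entropy: the
  output quantifies inter-well configurational effects only.
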