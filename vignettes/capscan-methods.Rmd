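---
title: "capscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscan)
```

`capscan` supports the engineering of light-activatable protein binders:
rank the hot-spot residues of a binder/antigen interface by ensemble
computational alanine scanning, then combine a photocaged tyrosine with
secondary alanine mutations so that the caged binder is OFF and the
uncaged binder is ON inside a cell. This vignette documents the models,
their assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## The surrogate pair potential

Published CAS servers score interfaces with proprietary or unpublished
empirical force fields. `capscan` instead ships a fully specified
surrogate so that every number it produces is reproducible and
hand-checkable. Heavy atoms carry classes from a fixed lookup table
(`nonpolar` = all C/S; `donor`/`acceptor` = backbone N and O/OXT plus the
usual side-chain nitrogens, oxygens and thiol/thioether sulfurs;
`positive` = Arg/Lys/His side-chain nitrogens; `negative` = Asp/Glu
carboxylates and OXT). A cross-partner atom pair at distance $d$
contributes

$$E(d) = E_\text{clash} + E_\text{np} + E_\text{hb} + E_\text{q},$$

where each class term uses the linear switch
$\mathrm{ramp}(d; \mathrm{on}, \mathrm{off})$ (1 below `on`, 0 above
`off`, linear between):

| term | condition | form | default |
|---|---|---|---|
| clash | $d < d_\text{clash}$ | $+k_\text{clash}(d_\text{clash}-d)/d_\text{clash}$ | $d_\text{clash}=2.5$ Å, $k_\text{clash}=25$ kJ/mol |
| nonpolar | both atoms nonpolar | $-k_\text{np}\,\mathrm{ramp}(d;3.4,6.0)$ | $k_\text{np}=0.4$ kJ/mol |
| H-bond | donor across from acceptor | $-k_\text{hb}\,\mathrm{ramp}(d;2.6,3.6)$ | $k_\text{hb}=4$ kJ/mol |
| charge | opposite (−) / like (+) charges | $\mp k_\text{q}\,\mathrm{ramp}(d;2.8,5.0)$ | $k_\text{q}=8$ kJ/mol |

Pairs at or beyond the global cutoff (8 Å) contribute nothing. The
magnitudes are ordered charge > hydrogen bond > dispersion, the ordering
any empirical interface potential encodes; the absolute values are a
design choice, not a fit, and the package makes no claim that its ΔΔG
values are comparable in magnitude to those of MD-based scans. ΔG of a
pose is the sum over all cross-partner pairs; more negative is stronger.

**Alanine scanning.** For each residue other than Gly/Ala, the side
chain beyond Cβ is removed (Cβ kept — the standard alanine convention;
proline is truncated like any residue, backbone and OXT are never
touched) and $\Delta\Delta G = \Delta G_\text{mut} - \Delta
G_\text{wt}$, so a positive value marks a residue that stabilises
binding. Because ΔG is a pair sum, the truncation effect equals minus
the summed energies of pairs involving removed atoms; the test suite
verifies this shortcut against literal truncation to $10^{-9}$ kJ/mol,
and it makes single-residue ΔΔGs of residues with disjoint contact sets
exactly additive — the additivity the planner assumes.

**Ensembles.** Scans run on every pose of a multi-model file (e.g. final
frames of independent MD runs); the reported ΔΔG is the arithmetic mean
across poses, with the sample SD as a stability diagnostic (0 for a
single model). Ranking uses `ddg_weighted`: the mean, optionally scaled
by `w_polar` for Asp/Glu/Arg/Lys/His. The down-weighting mirrors the
published observation that empirical CAS over-weights polar residues;
because the same literature suggests a 0.5 factor "could be too severe",
the default is `w_polar = 1` (off), with 0.5 one argument away. Ties are
broken by residue identifier so ranking is deterministic.

## Structure input

PDB (MODEL/ENDMDL) and mmCIF `atom_site` files are read with minimal
built-in parsers (no structure-reading package exists in the supported R
stack). Hydrogens are dropped (MD-derived files may or may not have
them; the potential is parameterised for heavy atoms), as are waters,
ions, ligands and modified residues — the tool scans the protein–protein
interface only. Alternate locations keep the highest occupancy, ties
broken by file order. Author residue numbering and insertion codes are
preserved throughout so output labels match published residue numbers
(an open question in the sources; author numbering is assumed because
published hot-spot labels match author numbering of the deposited
complexes).

## Interface annotation

A residue pair is an interface contact in a pose if any cross-partner
heavy-atom distance is ≤ 5 Å (default); `persistence` is the fraction of
poses containing the contact. Hydrogen bonds are proxied by
donor–acceptor heavy-atom pairs at ≤ 3.5 Å with no angle term —
hydrogens are unavailable, and the distance-only proxy is robust for
crystal structures. Cation-π contacts pair Tyr/Phe/Trp/His rings with
Arg guanidinium planes (centroid ≤ 6 Å and interplanar angle ≤ 30°,
capturing the "parallel, tightly packed" geometry) or Lys NZ (distance
only). The 6 Å/30° thresholds are exposed defaults; no numeric criteria
exist in the source literature. His is treated both as aromatic and as
(potentially) cationic in the class table, but only Arg/Lys act as
cations in the cation-π detector.

## Occupancy and the N/C read-out

`fold_change_ddg` is the bridge $\Delta\Delta G = RT\ln(\text{fold})$
with $R = 0.008314$ kJ/mol/K and $T = 298.15$ K by default. The
intracellular read-out models a binder::fluorophore fusion small enough
to diffuse freely across the nuclear membrane, binding an antigen
anchored in the nucleus (an NLS-tagged antigen is treated as fully
nuclear and immobile). With whole-cell binder concentration $N$,
nuclear antigen $A$, nuclear volume fraction $\phi$ and free binder $x$:

$$N = x + \phi A \frac{x}{K_d + x}, \qquad
\text{N/C} = \frac{x + A\,x/(K_d+x) + b}{x + b}.$$

The quadratic is solved in closed form (stable root; bisection fallback
at relative tolerance $10^{-10}$), and conservation is tested to
$10^{-9}$ relative. The optional background $b$ (default 0) caps the
predicted N/C, as measured ratios saturate around 3–4 in real images;
no attempt is made to fit measured N/C values quantitatively — the
required intracellular concentrations are unknown, so predictions are
scenario-based. All concentrations are micromolar internally;
`parse_concentration` normalises `nM`/`µM`/`mM` strings.

## The switch planner

Candidates are the scannable interface residues of the scanned side
minus the cage site. All subsets of size 0…`k_max` (default 2, matching
the single/double mutants explored experimentally) are enumerated:
$K_d^\text{on} = K_d^\text{wt}\exp(\sum \Delta\Delta G / RT)$ using the
secondary mutations' `ddg_weighted` (with the default `w_polar = 1` this
equals the ensemble mean), and $K_d^\text{off} = K_d^\text{on} \times
\text{fold}_\text{caged}$. The cage's effect is a user-supplied
fold-change (defaults 420 for NPY, 10,000 for ONBY, the published
in-vitro values) rather than a structural model: caging groups can form
their own stabilising contacts (e.g. a cation-π with an interface
arginine), so their in-context effect is not predictable from geometry
here, and no surrogate 3-D model is attempted. A plan passes when caged
occupancy ≤ `theta_off` (0.05) and uncaged occupancy ≥ `theta_on`
(0.5); `fail_on` (over-weakened, unable to bind even uncaged — the fate
of stacking two strong mutations on a cage) takes precedence over
`fail_off` when both thresholds fail, since a binder that cannot be
rescued by light is broken regardless of its caged state. Plans whose
secondary residues share contacted partner atoms are flagged
(`shared_contacts`), because additivity is least trustworthy there.
Output ordering is pass-first, then ON-occupancy descending, with
deterministic tie-breaks, and is invariant to input row order.

## Binding-curve fitting

`fit_one_site` fits $y = B_\text{max} x/(K_d + x)$ by least squares
(`nls`, port algorithm, parameter tolerance $10^{-10}$, $10^4$ iteration
cap, both parameters bounded below by 0). Starting values are
$B_\text{max}^0 = \max y$ and $K_d^0$ the concentration at half-maximal
mean response by linear interpolation. Replicates are fitted jointly
with equal weights — the presentation convention is means of replicates,
but the raw wells carry the information. Degenerate inputs (fewer than
4 distinct concentrations, all-equal or all-nonpositive responses) are
rejected rather than fitted. $R^2 = 1 - SS_\text{res}/SS_\text{tot}$
and the asymptotic standard error of $K_d$ are reported; `tidy()`,
`glance()`, `augment()` and `autoplot()` follow broom/ggplot2
conventions.

## Synthetic data: what it does and does not establish

The fixture generator is first-class, tested code; its defaults are the
stated world of the workflow, chosen once:

- **Complex fixtures** place one designed cross-chain atom pair per
  contact at an exact distance (salt bridge 3.0 Å, hydrogen bonds
  2.9–3.0 Å, nonpolar 3.4 Å — mid-ramp values typical of real
  interfaces), 30 Å apart per site, with 20 models and 0.2 Å isotropic
  Gaussian jitter as the ensemble stand-in (a crude proxy for MD pose
  spread; no physical realism is claimed). To make every energy exactly
  the designed single-pair term, the non-contact atoms of each residue
  are laid out on a stretched tail ≥ 8.5 Å behind the contact atom —
  deliberately non-physical geometry, since realistic bond lengths
  cannot keep neighbouring atoms outside an 8 Å cutoff around a 3 Å
  contact. Green tests on these fixtures establish the correctness of
  the energy bookkeeping, aggregation and ranking machinery — not the
  accuracy of the surrogate potential on real interfaces. ΔΔG ranges
  published for MD/BUDE-based scans of real nanobody complexes are not
  reproducible here and are not asserted anywhere in the suite.
- **Titration fixtures** use the four experimentally fitted affinities
  (0.76, 19.82, 106.10, 552.10 nM) as simulation truth, 8 log-spaced
  concentrations spanning $0.01 K_d$–$100 K_d$, Gaussian noise with
  σ = 5 % of $B_\text{max}$ and 3 replicates; the acceptance criterion
  is a median relative $K_d$ error ≤ 20 % over 200 seeds.
- **Synthetic cells** are concentric discs (cytoplasm 100 counts above a
  background of 10; nucleus `true_nc` times brighter) with optional
  Gaussian or Poisson noise. They validate the ratio arithmetic and its
  noise behaviour, not segmentation — masks are inputs by design, and
  the measured saturation of real N/C ratios near 4 is not modelled.

## Numerical and interface choices

- ΔΔG sign convention: mutant minus wild type, positive = hot-spot.
- Distances use strict comparisons as documented: interface `≤ cutoff`,
  H-bond `≤ 3.5` Å, energy zero at `d ≥ 8` Å.
- Seeds control every stochastic path (fixture jitter, noise); re-runs
  are byte-identical for fixtures written to PDB.
- Cytoplasm is cell-minus-nucleus with no erosion ring, and the default
  background estimate is the median outside all cells — the simplest
  deterministic protocol, since the imaging sources do not describe
  theirs. A numeric background or a mode estimate are available.
- The command-line wrapper reads plain-text formats only (PDB, CSV
  matrices for images): no TIFF reader exists in the supported R stack.

## Known limitations

- The surrogate potential has no entropy, no conformational relaxation
  after truncation, no solvation; it ranks, it does not predict
  calorimetric energies. Discordance between predicted and in-vivo
  behaviour of specific mutants (a scoring bias toward polar residues is
  one documented cause) is reported, not resolved, by the planner.
- ΔΔG additivity for combinations is exact in this pair potential but an
  approximation for real interfaces; `shared_contacts` marks where it is
  most doubtful.
- Caged residues are handled through fold-changes only; non-tyrosine
  cage sites are flagged but not scored differently.
- Kinetics (uncaging time courses, on/off rates), macromolecular
  crowding and nuclear transport rates are out of scope; the occupancy
  model is equilibrium-only.
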