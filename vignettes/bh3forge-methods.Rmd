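---
title: "Methods: grafting, design, maturation analytics and the concentration-threshold mechanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grafting, design, maturation analytics and the concentration-threshold mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bh3forge)
```

# Scope and scientific setting

BAK and BAX are the proapoptotic effectors of the BCL-2 family: once
activated, they dimerize and oligomerize to permeabilize the mitochondrial
outer membrane. Both carry a hydrophobic BH3-binding groove that accepts
short amphipathic helices whose conserved residues occupy the h1, h2, h3,
h3+1 and h3+2 pockets. `bh3forge` implements, as tested reusable
components, the computational workflow used to engineer high-affinity,
high-specificity groove binders of BAK and BAX, together with the
quantitative analysis of the assays used to characterize them:

1. **Motif grafting** -- scanning a helix-bundle scaffold for segments that
   can geometrically replace a groove-bound BH3-like helix, posing the
   whole scaffold into the target frame, clash-testing it, and threading
   the five conserved hotspot identities (Ile, Leu, Ile, Gly, Asp at motif
   positions 1, 5, 8, 9, 10).
2. **Interface sequence design** -- Monte Carlo simulated annealing over
   discrete side-chain candidates at surface positions near the target,
   first within an 8 Å shell, then 12 Å, under a simplified pairwise
   potential, with hotspots fixed and Pro/Cys/Trp/Gly excluded from
   designed positions.
3. **Design filters** -- predicted binding energy, a Lawrence-Colman-style
   shape-complementarity statistic, buried unsatisfied polar atoms, and
   the peptide-bond omega geometry check (cutoff 150°).
4. **Directed-evolution analytics** -- per-mutation enrichment from naive
   versus sorted site-saturation pools, the dual independent-enrichment
   selection rule (a mutation must enrich under *both* the affinity sort
   and the specificity sort), and degenerate-codon combinatorial library
   design under a diversity cap of 4×10⁷ protein variants.
5. **Assay models** -- global 1:1 kinetic fitting of biolayer-interferometry
   titrations, release-percent normalization and four-parameter-logistic
   IC~50~ fitting for liposome dye-release assays, and an equilibrium model
   of the concentration-threshold activation/inhibition mechanism.

Everything is driven by synthetic-data generators with known ground truth,
so the full pipeline is testable offline.

# Structure handling and superposition

Structures are flat atom tables (chain, author residue number, residue and
atom names, element, coordinates) wrapped in an S3 class; PDB parsing and
writing are delegated to `bio3d`. Author numbering is kept 1-based so that
residue citations map directly; alternate locations resolve to the
highest-occupancy conformer (ties to altloc 'A'). Only PDB is supported:
every structural input in this workflow is distributed in that format.

Superposition is the closed-form least-squares (SVD/Kabsch) fit with the
standard sign correction guarding against reflections. Atom pairing for
inter-structure RMSD is positional: residues pair by order within each
selection and atoms by name; unpaired atoms are dropped and reported, never
imputed. There is no outlier trimming -- reported RMSDs are plain RMSDs.
Selections use a small `chain:first-last:subset` grammar with subsets
`CA`, `backbone` (N, CA, C, O) and `heavy`.

# Motif grafting

`prepare_context_motif()` splits a target·peptide complex into the design
*context* (target chains) and a *motif*: the bound helix span reduced to
backbone + Cβ, every non-hotspot identity set to alanine, hotspot
identities preserved. `find_graft_sites()` then slides a window of the
motif's length along the scaffold; each window backbone is least-squares
superposed onto the motif backbone (full-backbone alignment), and two
geometric gates apply: full-backbone RMSD ≤ 3.0 Å and an endpoint RMSD
≤ 2.0 Å computed over the backbone atoms of the first and last motif
residues **under the same full-alignment transform**. The endpoint check
could alternatively be computed from an endpoint-only alignment; we apply
it post-alignment, which is the stricter and simpler reading.

Accepted windows then pose the whole scaffold into the context frame and a
clash test applies with cutoff 0. The glycine-reduction semantics is read
literally: glycine has no Cβ, so the scaffold is reduced to backbone
N, CA, C, O only. A clash is any (context heavy atom, scaffold backbone
atom) pair closer than the sum of vdW radii minus a 0.6 Å soft pad; the
grafted window itself is excluded because it legitimately replaces the
native bound peptide. The exact clash formula of the original tool chain is
unpublished; this rule is our declared stand-in, and "cutoff 0" therefore
means *no hard overlaps under this rule*. All acceptance on this module is
against brute-force window enumeration with independent RMSD evaluation,
not against any published clash values.

`apply_graft()` writes the hotspot identities onto the window positions
(side chains beyond Cβ trimmed; rebuilt at design time), reverts every
other position to the scaffold's native sequence, and records provenance
(window, RMSDs, clash count) as `REMARK 99` lines that survive PDB round
trips. Windows are scanned N→C and ties in RMSD (ideal-helix repeats are
exactly tied) break deterministically by window start.

# The simplified interface potential

The design stage does **not** reimplement a production molecular-mechanics
energy function. It uses a declared 4-term surrogate, built to make the
*pipeline logic* (shell selection, fixed hotspots, annealing, filter
gating) exercisable and testable:

* **Steric**: a 12-6 well on heavy-atom pairs with contact distance
  r₀ = r_i + r_j (element radii C 1.70, N 1.55, O 1.52, S 1.80 Å), depth
  0.05, clamped below 0.6·r₀ so every rotamer pair scores finite, and
  truncated 2.5 Å beyond contact.
* **Hydrogen bond**: a Gaussian well (optimum 2.9 Å, σ 0.3 Å, depth 2.0)
  on donor/acceptor heavy-atom pairs within 3.5 Å, scaled by the
  base-donor-acceptor angle (zero below 90°, full weight at 150°+). No
  explicit hydrogens.
* **Burial-of-polar penalty**: +1 per polar atom with ≥ 14 heavy neighbors
  within 5.5 Å and no complementary partner in hydrogen-bond range.
* **Reference energies**: small per-residue-type offsets discouraging
  gratuitous large/polar residues.

Bonded exclusions: within-residue pairs and adjacent-residue
backbone-backbone pairs are never scored. The total is exactly
decomposable into one-body and two-body terms, which the packer exploits
and the tests verify. Because the weights are not fitted to any published
scale, *no test or acceptance quantity asserts an absolute energy value*;
all checks are oracle-based (exhaustive enumeration) or property-based
(monotone improvement, symmetry, zero at separation).

Side chains are coarse united-atom chains built from an internal-coordinate
table (NeRF placement; branches as fixed dihedral offsets; aromatic rings
as planar closures). The rotamer library samples χ₁ and χ₂ on
(−60°, +60°, 180°) with deeper χ extended -- a backbone-independent grid.
The native identity and conformation is always candidate 1, so repack-only
moves can restore the input. This is a fidelity simplification relative to
curated rotamer libraries and gradient minimization; the protocol's final
"minimize-repack-minimize" relaxation is approximated by a repack-only
annealing pass at fixed identities.

# Position selection and the two-shell protocol

Designable positions satisfy three conditions: side-chain solvent
accessibility ≥ 30 Å² in the **isolated binder monomer** (the
surface-selection probe is 2.2 Å -- deliberately larger than water so that
marginally occluded surface sites count as surface; burial for hydrogen-bond
satisfaction uses the standard 1.4 Å probe, a two-probe policy), any heavy
atom within the shell distance of any target heavy atom, and not a hotspot.
Monomer-state SASA was chosen over complex-state SASA because the selection
should identify positions that are surface in the binder itself, not
positions already buried by the interface. Core positions never change
identity.

`design_protocol()` runs annealing at the 8 Å shell, then the 12 Å shell,
then the identity-fixed repack. The annealer proposes single-position
substitutions under a geometric temperature ladder (3 → 0.05 over 3000
steps by default), uses precomputed one-/two-body tables, runs a single
seeded RNG stream (position then candidate, in that order), and returns the
best-encountered state; best energy is therefore monotone within each
stage. The disallowed set {P, C, W, G} is interpreted as "never introduced
at designed positions" (native occurrences elsewhere are untouched).

SASA itself is deterministic Shrake-Rupley-style dot integration
(Fibonacci sphere, 960 dots/atom by default), validated against a
10⁴-dot evaluation; no external SASA library is required.

# Filters

* **Binding energy**: in the default mode, exactly the sum of
  inter-partner pairwise terms plus the change in burial penalty on
  complexation -- identically zero for non-contacting partners. An
  optional mode repacks each partner alone (fixed seed) and reports the
  bound-minus-unbound difference.
* **Shape complementarity**: dots on each partner's vdW sphere surface,
  restricted to an interface band (dots within 1.5 Å of the opposing
  surface); each dot scores the anti-alignment of its normal with its
  nearest opposing dot, weighted by exp(−0.5 d²); Sc is the mean of the
  two directional medians, in [−1, 1]. Dense smooth test walls at vdW
  contact score ≥ 0.8; tilting one wall strictly lowers Sc.
* **Buried unsatisfied polar atoms**: N/O donors/acceptors whose SASA at
  probe 1.4 Å falls below 0.01 Å² in the complex, were *not* already
  buried in the isolated partner (interface restriction), and have no
  partner within 3.5 Å at ≥ 90° base angle.
* **Omega check**: residue *i* fails when |ω_i| < 150°, i.e. the peptide
  bond deviates from trans by more than 30°; cis-proline is exempt by
  default. Gate thresholds for the first three filters are user-supplied
  configuration -- the original screening values were never published --
  and only the omega cutoff carries a stated default.

# Maturation analytics

Enrichment is the pseudocount-stabilized frequency-ratio statistic

$$e_m = \log_2 \frac{(c_{sel}(m)+p)/(T_{sel}+pM)}{(c_{naive}(m)+p)/(T_{naive}+pM)}$$

with p = 0.5 over the M mutations tracked in the naive pool; a mutation is
*enriched* when e_m > 1 and its naive coverage is ≥ 10 reads (both
configurable -- real campaigns tune sort-gate stringency per experiment,
so the defaults here are explicit package choices). Multi-mutant
reads are discarded: site-saturation libraries are single-substitution by
construction, so multi-hit reads are artifacts.

`dual_select()` intersects the enriched flags of the affinity and
specificity conditions and ranks by min(e_aff, e_spec) descending; wild-type
identities can never be selected. Combinatorial library design picks, per
position, the minimal-multiplicity IUPAC degenerate codon covering
{parent} ∪ {selected} (ties: fewest extra amino acids, then fewest stop
codons, then lexicographic). Protein diversity is the exact integer product
of encoded set sizes with stops excluded; amber (TAG) is tolerated inside
codons by default with a strict no-stop mode available. When diversity
reaches the 4×10⁷ cap the lowest-ranked mutations are dropped greedily, one
at a time, until the library fits; greedy-by-rank is the package's
documented choice of reduction rule.

# Assay models

**1:1 kinetics.** Association follows R(t) = R_eq(1 − e^{−(k_on C + k_off)t})
with R_eq = R_max C/(C + K_d), dissociation decays at k_off. Fitting is
*global* across the titration (shared k_on, k_off, R_max; free per-trace
baselines), log-parameterized for positivity, initialized from the
dissociation decay slope and the concentration dependence of the
association plateaus, with a small deterministic multistart. Global fitting is the stronger
convention for multi-concentration titrations and is what the package
implements. K_d = k_off/k_on holds exactly in every fit by
construction. Mass-transport and bivalent models are out of scope.

**Release percent and 4PL.** Release is normalized between the
buffer-only (0%) and detergent (100%) controls; out-of-range values are
flagged and clamped copies provided. Dose-response is the variable-slope
four-parameter logistic with log-parameterized IC~50~; orientation
(activation vs inhibition) is auto-detected from the dose trend, and the
fitted curve passes (top+bottom)/2 at IC~50~ by construction.

# The concentration-threshold mechanism

The mechanism is published as a schematic; this module's equilibrium
formulation is the package's declared quantitative reading:

1. Binder B engages target T 1:1 with apparent dissociation constant
   K_d,app = K_d·(1 + K9). K9 is a dose-independent intramolecular
   pre-equilibrium constant for the C-terminal α9 helix occupying its own
   groove -- 0 for BAK (α9 in the membrane) and C-terminally truncated
   BAX, large for cytosolic full-length BAX. This is the simplest form
   consistent with an intramolecular competitor.
2. Engagement activates: the activated fraction is
   min(1, c_B·θ_B + c_A·θ_A), with θ the equilibrium occupancies and c an
   *engagement-turnover multiplier* -- transient binding events activate
   more targets than are occupied at any instant (hit-and-run). This
   choice (rather than occupancy-equals-activation) is what produces
   activation at sub-stoichiometric binder; the data admit both readings
   and the multiplier is configurable.
3. Binder-bound targets cannot dimerize; free activated monomers
   partition into dimers with association constant K_dim, and release
   saturates as 100·D/(D + K_rel).

Occupancies are solved by monotone bisection on ligand conservation to
1e-10 relative tolerance. Defaults are fixed once as the study conditions:
T = 38 nM target, K_d = 0.4 nM (the tight-binder regime), K_dim = 1 nM⁻¹
and K_rel = 0.5 nM (an efficient, saturating pore readout), engagement
multiplier 10, and an activator treated as fully activating at its working
concentration (15 nM; a three-orders-larger figure appearing in one
protocol description is treated as a misprint -- the concentration is
always configuration, never hard-coded).

With these conditions the model reproduces the qualitative signatures the
assays show: a biphasic (unimodal) dose-response without activator;
descending-branch IC~50~ just above the total target concentration for a
tight binder (stoichiometric threshold -- about 46 nM against 38 nM target
in this parameterization); fold-excess required for inhibition growing
monotonically with K_d and with K9, so full-length BAX (large K9) needs
orders of magnitude more binder than truncated BAX at the same intrinsic
affinity; and release returning to baseline as binder saturates the pool.
All acceptance on this module is property- and regime-based; no wet-lab
dose-response number is asserted numerically, and modeling stops at dimers
(no higher-order oligomer or membrane-lattice treatment). Time courses are
out of scope; the liposome generator produces kinetic-looking traces whose
*endpoints* equal the equilibrium model.

# Synthetic data: what it emulates and what it does not

* `build_helix()` makes ideal-geometry peptides at requested dihedrals
  (±0.5° reproduction, verified) with coarse side chains.
* `build_toy_complex()` builds a two-helix groove with a 13-residue docked
  motif helix carrying the hotspot pattern -- poly-alanine with leucines
  lining the cleft, enough chemistry for the potential and filters to
  discriminate poses without pretending to be real BAK. The placement
  (groove separation 10.5 Å, motif height 7.5 Å) guarantees ≥ 3 inter-chain
  contacts under 5 Å and clash-free graft windows, so the end-to-end
  pipeline is exercised by construction.
* `build_toy_scaffold()` is a helix-loop-helix-loop-helix single chain
  whose ideal-helical segments are graft-compatible with any ideal helical
  motif.
* `simulate_ssm_pools()` emulates naive and sorted site-saturation pools:
  near-uniform naive frequencies (lognormal jitter, over-represented wild
  type), survival through a sort gate as plogis(effect − gate) with gate 2
  (neutral variants survive ~12%, strong effects approach 1 -- matching
  the contrast a stringent FACS gate produces), multinomial sampling at
  the requested depth. Amino-acid level only: no codon structure,
  sequencing error, or PCR artifacts.
* `simulate_liposome_traces()` adds saturating time courses and control
  channels around the mechanism model's endpoints.
* `synthetic_lineage_sequences()` provides stand-in binder lineages
  (explicitly synthetic; real construct sequences are not
  distributed here) whose pairwise Hamming distances
  reproduce the published mutation counts and rounded percentages; lineage
  lengths 118 (BAK) and 117 (BAX) are the lengths at which every printed
  rounded percentage is consistent with its printed count.

Passing tests on these generators demonstrates the *correctness of the
algorithms and analytics*, not performance on real crystallographic or
NGS data: real structures have loops, waters and alternate conformations;
real pools have sequencing errors and bottlenecks; real sensorgrams have
drift and mass-transport effects.

# Problem sizes, tolerances, and numerical choices

Test and acceptance runs use deliberately small problem sizes -- toy
scaffolds of ~52 residues, design state spaces ≤ 10⁴ for exhaustive
cross-checks, pool depth 10⁵, 50-seed noise studies, 60-point dose grids --
chosen so the full suite re-runs quickly on a single CPU while still
exercising every code path. Key numerical choices: SASA 960 dots/atom
(2% agreement with 10⁴ dots); Sc dot density 180/atom with a 1.5 Å
interface band and w = 0.5 Å⁻²; bisection tolerance 1e-10 relative;
annealing ties broken by proposal order under one seeded stream; graft
window ties broken by window start after rounding RMSD to 1e-6 Å.

# Interfaces

The package is an analysis library: its functions, the two orchestration
entry points (`run_design_pipeline()`, `run_maturation_pipeline()`), this
vignette and `scripts/acceptance.R` are the interface. No shell executable
is shipped -- users of this kind of package drive it from R scripts, and
the acceptance script shows the canonical end-to-end invocations. File
interfaces are plain text: PDB and FASTA for structures and sequences, CSV
for count tables, traces and ranked designs, JSON for manifests, library
specifications and reports.

# Known limitations

* The potential is a surrogate: energies are in model units and are not
  comparable to physical free energies; filter thresholds must be
  calibrated per application.
* No backbone flexibility, loop closure, or rigid-body/torsion
  minimization; repacking stands in for refinement.
* Single-segment helical grafts only (full-backbone alignment mode).
* Positional (not alignment-based) atom pairing in RMSD; no support for
  nucleic acids, anisotropic B-factors, or symmetry expansion.
* The mechanism model is an equilibrium endpoint model with dimers as the
  terminal species; kinetics of activation and higher-order
  oligomerization are out of scope.
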