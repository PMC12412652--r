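# bh3forge

Computational design and assay analytics for BH3-groove binders of the
proapoptotic effectors BAK and BAX.

BAK and BAX permeabilize the mitochondrial outer membrane once activated:
they dimerize, oligomerize, and form pores that release cytochrome *c*,
committing the cell to apoptosis. Both proteins carry a hydrophobic
BH3-binding groove that accepts short amphipathic helices whose conserved
residues (the h1, h2, h3, h3+1, h3+2 "hotspots" — Ile, Leu, Ile, Gly, Asp)
dock into defined pockets. `bh3forge` is an R implementation of the
computational pipeline used to engineer tight, selective groove binders of
BAK and BAX, and of the quantitative models used to characterize them.
It is aimed at protein engineers and biochemists who want each stage as a
tested, scriptable component:

* **Structure I/O and superposition** — PDB read/write (via `bio3d`), a
  flat atom-table data model, Kabsch least-squares superposition, and
  selection-based RMSD (`chain:first-last:subset` mini-grammar).
* **Motif grafting** — scan a helical scaffold for windows that can replace
  a groove-bound BH3-like helix (full-backbone RMSD ≤ 3.0 Å, endpoint
  RMSD ≤ 2.0 Å), pose the scaffold, clash-test it at cutoff 0 under
  glycine-reduction semantics, and thread the hotspot identities.
* **Interface design** — Monte Carlo simulated annealing over a coarse
  rotamer grid at surface positions (side-chain SASA ≥ 30 Å² at probe
  2.2 Å) within 8 Å then 12 Å of the target, hotspots fixed,
  Pro/Cys/Trp/Gly never introduced, under a declared simplified 4-term
  potential (softened steric, H-bond well, polar-burial penalty,
  reference energies).
* **Design filters** — predicted binding energy, Lawrence–Colman-style
  shape complementarity, buried unsatisfied polar atoms, and the
  peptide-bond ω geometry check (|ω| ≥ 150°, cis-Pro exempt).
* **Maturation analytics** — log2 frequency-ratio enrichment from naive vs
  sorted SSM pools, the dual independent-enrichment selection rule
  (mutations must enrich under *both* the affinity and specificity
  sorts), and minimal degenerate-codon combinatorial libraries capped at
  4×10⁷ protein variants.
* **Assay models** — global 1:1 kinetic fits of biosensor titrations
  (K_d = k_off/k_on exactly), release-percent normalization, 4PL IC₅₀
  fitting, and an equilibrium model of the concentration-threshold
  mechanism by which the binders *activate* their target at
  sub-stoichiometric doses but *inhibit* pore formation in excess, with
  the BAX α9 helix as an intramolecular competitor
  (K_d,app = K_d·(1+K9)).
* **Synthetic data** — deterministic generators (toy groove complexes,
  helical scaffolds, planted-effect SSM pools, noisy sensorgrams,
  liposome traces) so every stage is testable offline with known ground
  truth.

## The models in brief

**1:1 binding.** R(t) = R_eq(1 − e^{−(k_on C + k_off)t}),
R_eq = R_max·C/(C + K_d); dissociation decays at k_off. Fits are global
across a titration with per-trace baselines.

**Enrichment.** e_m = log2[ (c_sel+p)/(T_sel+pM) ÷ (c_naive+p)/(T_naive+pM) ],
p = 0.5; enriched iff e_m > 1 with naive coverage ≥ 10.

**4PL.** y = bottom + (top−bottom)/(1+(IC₅₀/x)^hill); y(IC₅₀) =
(top+bottom)/2 by construction.

**Threshold mechanism.** Binder occupancy θ_B from 1:1 mass action at
K_d,app; activated fraction min(1, c_B·θ_B + c_A·θ_A) (engagement
turnover); free activated monomers dimerize (K_dim); release =
100·D/(D + K_rel). Tight binders inhibit at doses tracking the *target
concentration*, not their K_d — the stoichiometric threshold.

## Worked example

```r
library(bh3forge)

## lineage distances on the packaged synthetic stand-in sequences
lin <- read_fasta(system.file("extdata", "synthetic_lineages.fasta",
                              package = "bh3forge"))
m <- mutation_count(lin$aBAK1, lin$aBAK2)
cat("aBAK1 -> aBAK2:", m$count, "mutations (", m$percent, "%)\n")

## fit a noisy five-concentration biosensor titration, 400 pM regime
traces <- simulate_1to1(kon = 1e6, koff = 4e-4, Rmax = 1,
                        concentrations = c(1e-10, 4e-10, 1.6e-9, 6.4e-9, 2.56e-8),
                        noise_sd = 0.02, seed = 1)
fit <- fit_1to1(traces)
print(fit)

## concentration-threshold mechanism: tight binder vs 38 nM target
p <- mechanism_params(Kd_bind = 0.4e-9, T_total = 38e-9,
                      activator_conc = 15e-9)
ts <- threshold_summary(p)
cat(sprintf("inhibition IC50: %.1f nM (%.2f-fold over the 38 nM target)\n",
            ts$inhibition_ic50 * 1e9, ts$fold_excess))
```

Output:

```
aBAK1 -> aBAK2: 12 mutations ( 10 %)
1:1 kinetic fit: kon 1.01e+06 /M/s, koff 0.000396 /s, Kd 3.91e-10 M (Rmax 0.997)
inhibition IC50: 46.4 nM (1.22-fold over the 38 nM target)
```

The recovered K_d lands in the high-picomolar regime of the tight BAK
binder, and the inhibition IC₅₀ sits just above the total target
concentration — the stoichiometric-threshold signature: a ~1.2-fold molar
excess of a 0.4 nM binder silences pore formation, while weak binders or
strong α9 competition (`K9 > 0`, the full-length-BAX situation) push the
required excess up by orders of magnitude.

End-to-end workflows are wrapped by `run_design_pipeline()`
(prepare → graft → design → filter → rank, with quarantine and a
reproducibility manifest) and `run_maturation_pipeline()`
(count → enrich → dual-select → library design). The methods vignette
(`vignettes/bh3forge-methods.Rmd`) documents every model, parameter and
design decision.

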