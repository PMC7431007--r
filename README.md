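# histbrace

Integrated NMR/EPR analysis of histidine-brace Cu(II) sites, the catalytic
centres of lytic polysaccharide monooxygenases (LPMOs). The package is for
spectroscopists and structural biologists who want to go from fitted
spin-Hamiltonian parameters and relaxation tables to electronic-structure
and structural conclusions: what substrate binding does to the copper
coordination sphere, and what that means for O2 activation.

## What it computes

**Ligand-field decomposition of the Cu hyperfine coupling.** For a Cu(II)
ion with a d(x²−y²) SOMO in a distorted square-pyramidal site, the
isotropic coupling satisfies

    A_iso = P_d [ −κ + (1/3) Σ_n Δg_n ],        Δg_n = g_n − 2.0023

so the Fermi contact −P_d·κ follows directly from A_iso and the g values
(P_d = 1180 MHz). The well-determined A₃ component obeys the rhombic
relation

    A₃ = −P_d [ κ + 4α²(a²−b²)/7 − (3a−3b)Δg₂/(14(a+3b))
                − (3a+3b)Δg₁/(14(a−3b)) − Δg₃ ]

with a, b the d(x²−y²)/d(z²) orbital coefficients (a²+b²=1) and α² the
spin density on Cu, which is solved for and decomposed into
Fermi/dipolar/orbital contributions (`fermi_contact`,
`solve_spin_density`, `decompose_hyperfine`, `delft_table`).

**CW powder EPR simulation and fitting.** Field-swept first-derivative
spectra for S = 1/2 ⊗ ⁶³Cu(I = 3/2) with nitrogen superhyperfine combs,
g/A strains and pseudo-Voigt lineshapes; Cu resonance fields from a
second-order treatment cross-checked against exact diagonalization, and
bounded least-squares refinement, optionally joint over X- and Q-band
spectra (`simulate_powder`, `eigenfields_exact`, `fit_spectrum`).

**HYSCORE-derived remote-nitrogen couplings.** Axial couplings A + 2T,
first-order cross-peak placement ν± = |ν_I ± A_eff/2|, and hydrogen-bond
classification from the ¹⁴N quadrupole asymmetry η (weak for
0.45 ≤ η ≤ 0.75, strong for η ≳ 0.85) (`axial_coupling`,
`cross_peak_frequencies`, `classify_hbond`, `substrate_shift_report`).

**Paramagnetic relaxation enhancement and tumbling.** Solomon–Bloembergen
Γ₂ from ⟨r⁻⁶⟩-averaged distances over a multi-model ensemble,
HSQC intensity ratios R₂e^(−Γ₂t)/(R₂+Γ₂), and the rotational correlation
time τ_c = (1/4πν_N)·√(6⟨T₁/T₂⟩−7) from ¹⁵N relaxation
(`read_ensemble`, `gamma2_sb`, `predict_pre_profile`, `estimate_tauc`).

**Synthetic data generators** (`synth_*`) produce seeded ensembles,
relaxation tables, spectra and intensity tables with ground truth attached,
so the whole pipeline is testable offline.

## Worked example

```r
library(histbrace)
systems <- lpmo_spin_systems()          # bundled fitted parameter sets

# Aiso branches under the quantum-chemical sign constraints
enumerate_hyperfine_signs(c(80, 85, 620), c("?", "-", "-"))$Aiso
#> [1] -208.3333 -261.6667

# ligand-field decomposition, substrate-free vs chitin-bound
delft_table(systems$apo_14N_X, systems$chitin_14N_X)[, c(1, 4, 5, 7, 9)]
#>      condition     fermi dipolar_para orbital_para spin_density
#> 1 no substrate -138.2660    -529.5551     331.8211    0.8180803
#> 2    substrate -323.6193    -558.6891     262.3085    0.8339606
#> 3    substrate -376.9527    -505.3558     262.3085    0.7543494
```

The Fermi contact roughly doubles (−138 → −324 MHz) while the spin density
and dipolar term barely move: the substrate-induced A_iso shift reflects
the five- to four-coordinate rearrangement of the copper, not a loss of
metal–ligand covalency.

The numbered scripts under `analysis/` run the full study in order
(spin-Hamiltonian summaries, ligand-field decomposition, EPR simulation
and recovery, remote-nitrogen hydrogen bonding, PRE and τ_c), each writing
its tables under `results/` and printing a short narrative;
`run_pipeline()` wires the same stages behind one configuration object.

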