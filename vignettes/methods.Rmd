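---
title: "Hybrid stochastic-deterministic simulation of omics-tailored cell fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid stochastic-deterministic simulation of omics-tailored cell fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`stochfate` simulates virtual populations of single epithelial cells whose
expression state is tailored to gene-level omics measurements, and asks how
stochastic gene expression propagates into cell-fate decisions — death,
division, arrest — under growth factors, kinase inhibitors, a death ligand,
and a chemotherapeutic. The model has two layers:

* a **stochastic expression layer**: every modeled gene is a two-state
  (telegraph) promoter whose copies switch on/off at global rates
  `k_gac`/`k_gin`, transcribe while active, and whose integer mRNA counts are
  born and degraded by an exact stochastic simulation algorithm;
* a **deterministic network layer** of about eighty species: two exemplar
  receptor classes (EGFR-like, transient through degradation-dominated
  trafficking; insulin-receptor-like, sustained through recycling), the
  Ras/Raf/MEK/ERK and PI3K/PTEN/AKT/mTOR cascades with one negative feedback
  loop per arm, AP1/cMyc transcriptional drives, a cyclin relaxation
  oscillator, a p53-MDM2-WIP1 DNA-damage module, and an intrinsic + extrinsic
  apoptosis network executed through a BAX-pore/caspase-3 switch.

The two layers exchange on a fixed 30-second window: mRNA counts are frozen
for the deterministic step, and signaling-derived transcription multipliers
are frozen for the stochastic step. Within each window the stochastic update
is the *joint* exact SSA over promoter switching and mRNA birth/death (not
operator-split — the joint simulation is exact and equally cheap, and in the
regime used here multiple switching events per window are rare anyway).
Proteins, which exist at 10^3–10^9 copies, are integrated deterministically
with a fixed-substep fourth-order Runge-Kutta scheme (default four substeps
of 7.5 s per window). An explicit scheme suffices because every rate constant
in the reduced network has a characteristic time of a minute or slower;
the halving-the-window and halving-the-substep invariance tests in the suite
are the guard on this choice. Rate stiffness was bounded at design time
precisely so that the per-window stepper stays accurate — the snap-action
apoptosis switch gets its abruptness from ultrasensitivity (Hill
coefficients, zero-order buffering), not from fast rate constants.

# Omics tailoring (the PREP phase)

Gene-level tables of copy number, mRNA and protein abundance (linear units:
UMI-like counts, iBAQ-like scores) and mRNA/protein half-lives define each
gene's expression parameters:

* replicates are quantile-normalized (standard rank/mean algorithm) and
  averaged;
* linear measurements are converted to molecules per cell by their share of
  fixed cellular pools: 400,000 mRNA molecules and 3.08×10⁹ protein
  molecules per average cell (the mRNA pool is the grid-rounded mean of three
  independent literature-style estimates, one of which is a dimensional
  conversion of 26 pg total RNA — reproduced by `total_mrna_from_rna_mass()`);
* degradation rate constants come from half-lives (`ln 2 / t_half`), the
  steady-state active-gene count from the telegraph stationary law, and
  transcription/translation rate constants by inverting the two-stage
  expression model at steady state (`k_bm = k_dm m_ss / g*_ss`,
  `k_bp = k_dp p_ss / m_ss`);
* functionally redundant gene products are summed into signaling
  *conglomerates* (e.g. ERK = MAPK1 + MAPK3) that the network layer operates
  on.

Genes measured at only one molecular level are imputed through the
cohort-median protein-to-mRNA ratio (with a warning). Measured zeros are kept
as true zeros: cFos is genuinely absent in the starved reference state and is
modeled as a purely induced gene whose translation rate constant is a network
parameter rather than a steady-state inversion.

Re-tailoring to a new context (`retailor()`) swaps the mRNA table, recomputes
protein steady states through the reference context's gene-specific
protein-to-mRNA ratios, and zeroes the translation rate of knockout genes
(removing their protein from the system).

# Initialization of the serum-starved average cell

Post-translational modification and complex formation redistribute protein
mass, so after assembling the full network the conserved-moiety totals no
longer equal the omics targets. `initialize_average_cell()` relaxes the
deterministic model to its zero-stimulus steady state and iteratively
rescales each gene's effective translation rate constant by
(target / simulated total). Two numerical choices matter:

* the rescaling is **damped** (square root of the ratio): global translation
  control couples all pools, and the undamped update oscillates;
* the apoptosis execution arm is folded back into its zymogen pools between
  iterations. The death switch is bistable by construction, and transients
  of a not-yet-converged parameter set must not latch it; the final fixed
  point is then verified to be non-cycling (no cyclin B activity in a 100-h
  probe) and non-apoptotic on its own.

All transcriptional-drive multipliers (AP1 to cFos/cJun, AKT to cMyc, FOXO
to BIM, p53 to PUMA/NOXA, the cyclin D gate) and the translation-control
factor are normalized to their converged starved values, so the tailored
steady state is an exact fixed point of the final rates and the Eq-style
round trip (holding `m_ss`, `p_ss` under deterministic integration) holds to
numerical precision.

# Design choices in the mechanistic layer

**Activity normalization.** Catalytic rate laws operate on activities
normalized to fixed average-cell reference totals (e.g. ppERK relative to
30% of the reference ERK pool). This keeps abundance dependence where the
science needs it — a cell (or variant) with more Raf signals harder, which
is what the transformation scan and the Raf-based fate prediction rest on —
and keeps the sustained ERK/AKT plateau flat during growth. The cost is that
freshly divided daughters transiently signal at roughly half strength until
their pools regrow; inter-division intervals beyond the first cycle are
therefore longer than the first, and all timing readouts in the package use
the first division.

**Translation control.** Free EIF4E (total minus the rapid-equilibrium
4E-BP1-bound fraction) sets a Hill multiplier on translation; mTOR
phosphorylates 4E-BP1 to release EIF4E. The EIF4E and 4E-BP1 pools
themselves are exempt from this multiplier (TOP-mRNA-like behavior): wiring
them in closes a positive feedback loop on global translation with gain
above one, which has no stable proteome. mTOR receives both an AKT input and
a smaller direct PIP3 input, so catalytic AKT inhibition under insulin
leaves global translation partially elevated — this is what makes
dual-pathway inhibition more lethal than plain starvation (short-lived
pro-death BH3 proteins accumulate faster than long-lived BCL2).

**Cyclin D gate and ignition.** Cyclin D transcription is the product of an
AP1 arm (Hill in AP1 activity, made sharp by cJun positive autoregulation)
and a cMyc arm (requiring the *product* of sustained AKT activity and cMyc
level, so neither high basal cMyc nor transient AKT suffices). Both arms
have comparable dynamic range (~6-7x) with an ignition threshold around 10x,
which is what makes the gate a genuine AND: either kinase inhibitor alone
drops one arm and blocks cycling, EGF alone is marginal, insulin alone is
silent, and the combination ignites. Because the cFos/cJun response Hills
are centered on the acute ERK peak, ignition is a race decided in the first
hours after stimulation — cells whose Raf levels put their ERK peak below
threshold never ignite, which is the mechanistic origin of the
Raf-predictability of cycle entry.

**Cell cycle.** A reduced relaxation oscillator (cyclin D -> E2F -> cyclin
E/A -> cyclin B -> Cdc20) integrated deterministically and not coupled to
the stochastic expression layer (coupling it deregulates the oscillator;
cyclin D mRNA is a deterministic species driven by the gate). The mitotic
switch uses dead-zone (shifted-Hill) activation thresholds for cyclin B
synthesis and Cdc20 activation — the continuous-Hill version leaks enough
APC activity to stall the oscillation at an intermediate fixed point.
Division fires when cyclin B collapses below 10% of a super-threshold peak:
molecular content is halved (mRNA binomially in stochastic mode), the cycle
module resets to G1, and ribosomes/volume halve. p21 and Chk1 brake the
oscillator; p21 is long-lived, so a sustained p53 response produces durable
(senescence-like) arrest.

**Growth.** Ribosome synthesis follows mTOR drive with a cell-size brake
(an undivided cell plateaus near 2.5x volume); volume is ribosome content
relative to the 6×10⁶ average-cell pool, and protein synthesis scales with
both the EIF4E multiplier and ribosome content. Under full mitogenic drive
the ribosome pool doubles over one cycle.

**Apoptosis.** Active BIM, tBID and PUMA form an activator pool buffered by
BCL2 (1:1 rapid-equilibrium binding; NOXA and active BAD reduce the
available BCL2). Free activator drives BAX activation; pore formation is
ultrasensitive (Hill n = 6) in active BAX, caspase-3 is buffered by a fixed
XIAP-like inhibitor pool (zero-order ultrasensitivity), and active caspase-3
feeds back on caspase-8. Together these give a quiescent basal state, a
latched all-or-none cPARP spike, and a death criterion of cleaved PARP
exceeding half the PARP moiety. The BCL2-family buffering constants are
absolute amounts (mitochondrial-membrane reactions), while the pore
threshold scales with cell size — the combination that neither spuriously
protects growing cells nor kills them wholesale. ERK phosphorylates and
inactivates BIM; ERK and AKT phosphorylate BAD; AKT exports FOXO from the
nucleus (the phospho-form degrades faster), and nuclear FOXO drives BIM
transcription ultrasensitively — contexts with high basal AKT therefore show
a strong BIM surge when AKT is inhibited.

**DNA damage.** Etoposide produces double-strand lesions proportionally to
dose times a Hill of p21-unmasked S-phase cyclin activity: quiescent or
arrested cells accrue essentially none, which makes the drug
cycle-dependent and the death curve plateau once p53-driven p21 arrests the
survivors. ATM activation is ultrasensitive in lesion load and inhibited by
WIP1; p53, stabilized by ATM/ATR, induces MDM2 and WIP1 through mRNA
intermediates, giving pulses of stable amplitude whose number grows with
lesion persistence. Repair capacity scales with BRCA2-like (double-strand)
and MSH6/MGMT-like (single-strand) pools and clears the lesion loads used
here within hours to a day.

# The stochastic fate-analysis pipeline

Per-cell predictors are conserved-moiety totals, either at treatment start
or trapezoid-averaged over 8-h/40-h windows intersected with each cell's
lifetime. Labels are death before 40 h (death experiments) and first
division within 30 h (proliferation experiments); population summaries use
S-phase entry by 24 h for percent-proliferating, mirroring a cytometry
S+G2/M readout minus the starved control. Feature selection is an
L1-penalized logistic fit with five-fold, class-stratified, seeded
cross-validation; classification is a linear support-vector machine on
predictors z-scored by the training split (200 train / 200 validation), and
performance is the held-out ROC/AUC, computed by a trapezoid construction
that equals the Mann-Whitney rank statistic exactly (asserted to 1e-12 in
the tests, and cross-checked against an independent ROC implementation).

The Latin-hypercube sensitivity scan perturbs all protein degradation rate
constants with a log-space normal design: the half-decade spread parameter
(3.16 = 10^0.5, applied as a log10 standard deviation of half that value)
keeps the bulk of draws within roughly two-to-four-fold of the tailored
values; a linear-space option is provided. Each sampled set is re-tailored
(translation rates re-derived), re-initialized — sets failing initialization
are discarded and reported — and run through the dual-inhibitor experiment.

# What the synthetic data emulate — and what they do not

The fixture generator builds replicate omics tables whose noiseless
round-trip through the tailoring pipeline reproduces a set of anchored
molecules-per-cell values for the signaling and apoptosis hubs, with
log-normal replicate noise (CV 0.2), log-uniform background genes carrying
the rest of the cellular pools, and a diploid genome with one homozygous
deletion. Unanchored choices — mRNA copy numbers, most half-lives, a few
protein abundances — were fixed once at values typical for mammalian
epithelial cells (mRNA pools of 2–120 copies; half-lives of hours for
immediate-early and BH3-only products, days for structural kinases). The
tables emulate gene-level linear abundance measurements only: no
sequencing-level artifacts (UMI saturation, batch effects), no
peptide-level proteomics structure, and no inter-gene covariance beyond
what the pools impose. Passing tests therefore demonstrate that the
pipeline and model behave correctly for data of this form, not that the
parameterization matches any particular laboratory's measurements.

Problem sizes in the test-suite and acceptance script (populations of
24–400 cells, 24–72 h; the predictability experiments use 400 cells with
200/200 train/validation splits) are the package's standard study
conditions.

# Known limitations

* Protein synthesis and degradation are deterministic; fluctuations from
  low-abundance degradation machinery are absent, so protein noise is a
  filtered image of mRNA noise plus the shared translation-capacity factor.
* Daughters inherit half of everything symmetrically and re-signal at
  reduced normalized strength until pools regrow; multi-generation lineage
  statistics are outside the validated envelope (first-passage readouts —
  first division, death — are the supported quantities).
* The p53 oscillator holds amplitude constant as designed, but inter-pulse
  troughs remain above half-maximum under sustained damage; pulse width is
  therefore only well-defined for the first pulse.
* The glioma-like re-tailored context reproduces the PTEN-null AKT-axis
  mechanism (elevated basal PIP3/AKT, FOXO/BIM surge under AKT inhibition)
  but not a quantitative inhibitor-sensitivity flip in percent death, and
  basal death calibration does not transfer across contexts — the basal
  caspase-8 activity knob (`k_c8_bas`) is documented configuration, not a
  solved problem.
* Cells are independent: no paracrine, autocrine, or contact effects.

# Reproducing the headline numbers

A worked example and the mapping from script output to quantities are in the
README. In short:

```{r}
library(stochfate)
gt <- reference_gene_table()              # fixture -> tailored parameters
init <- initialize_average_cell(build_model(gt))
pop <- spawn_population(init$model, init$cell, 100, base_seed = 1)
ex <- run_experiment(init$model, pop,
                     make_experiment_configs(n_cells = 100)$starved)
ex$summary
```

`scripts/acceptance.R` chains exactly these steps for every reported
quantity and writes them as JSON.
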