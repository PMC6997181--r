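---
title: "A mass-action model of mirtron-mediated synaptic homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-action model of mirtron-mediated synaptic homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synhomeo)
```

## The biological system

Cholinergic activation of the nicotinic acetylcholine receptor subunit
nAcRβ2 depolarizes Drosophila neurons and admits calcium. Two regulatory
motifs keep this response in check. First, an incoherent feedforward
loop: activity-dependent phosphorylation of the transcription factor
Adf-1 (downstream of CaMKII) releases transcription of the Shal
potassium channel and of SKIP, whose protein amplifies Shal's tempering
of the membrane potential. Second, a negative feedback loop: the mirtron
miR-1010 — a microRNA spliced out of a SKIP intron, so its production is
stoichiometrically tied to SKIP transcription — degrades nAcRβ2 mRNA,
removing the source of the depolarizing current. The experimental
genotypes dissect the two loops: deleting miR-1010 (or just its binding
site in the nAcRβ2 3'UTR) is lethal in the first larval instar, while
SKIP protein-null larvae, which still produce the mirtron, are viable
but delayed.

`synhomeo` encodes this network as a deterministic mass-action ODE
system, represents each genotype or drug treatment as a parameter-level
perturbation, reduces simulated responses to the phenotype metrics used
to compare genotypes, and carries a ΔΔCt RT-qPCR quantification pipeline
with a seeded synthetic-data generator so that every stage can be
validated end to end without raw data.

## The dynamical model

Eight species: nAcRβ2 mRNA $R$ and surface receptor $P$, the
membrane-potential proxy $V$ (0 = rest, dimensionless), the
phosphorylated Adf-1 fraction $A \in [0,1]$, SKIP transcript $S_t$ and
functional protein $S_p$, Shal channel $K$, and mature miR-1010 $M$:

$$
\begin{aligned}
\dot R &= k_R + a_R V - d_R R - k_{rep} M R \\
\dot P &= k_P R - d_P P \\
\dot V &= k_V\,u(t)\,P - k_{leak} V - g_K K (1 + \alpha S_p) V + e\\
\dot A &= k_{Aon} V (1 - A) - k_{Aoff} A \\
\dot S_t &= a_S A - d_{St} S_t, \qquad
\dot S_p = k_{Sp} S_t - d_{Sp} S_p \\
\dot K &= a_K A - d_K K, \qquad\;\;
\dot M = \eta\, a_S A - d_M M
\end{aligned}
$$

Every term is mass action. Choices that deserve comment:

* **Mirtron coupling.** $M$ is produced at rate $\eta\, a_S A$: the same
  transcription events that make SKIP transcript yield the mirtron, with
  maturation yield $\eta \in [0,1]$. This is what makes the SKIP
  protein-null (MiMIC truncation) distinct from the miR-1010 deletion —
  the former zeroes only $k_{Sp}$, leaving $M$ production intact.
* **Catalytic repression.** miR-1010 degrades $R$ at rate
  $k_{rep} M R$ without being consumed, the standard kinetic reading of
  miRNA-guided mRNA decay.
* **Adf-1 as an activated driver.** The biology is de-repression
  (unphosphorylated Adf-1 sits on the SKIP/Shal regulatory regions and
  pauses transcription); at this level of abstraction an
  activity-activated driver with saturating fraction $A$ is equivalent
  and needs fewer species.
* **SKIP amplification.** The tempering conductance is
  $g_K K (1+\alpha S_p)$: Shal tempers on its own, SKIP protein
  amplifies it (favouring the slow-inactivation mode), so losing SKIP
  protein weakens but does not abolish the feedforward arm.
* **Extra depolarization $e$.** Zero in wild type; the hook through
  which constitutive sodium-channel (NaChBac) overexpression enters.

Time is measured in receptor lifetimes ($1/d_P$, and $d_P = 1$ fixes the
unit); abundances are dimensionless. The stimulus $u(t)$ multiplies the
receptor-driven depolarization; the default is a unit step at $t = 0$ —
sustained receptor activation — because the distinguishing phenotype
(sustained potential in the miR-1010 null) only exists under sustained
input: after a transient pulse every genotype relaxes trivially. An
"impulse" option is implemented as a rectangular pulse of width 0.1
lifetimes, since a true Dirac input is not representable in the
right-hand side.

## Default parameters

All defaults are dimensionless O(1) values, labelled *default, not
fitted*. Decay rates are 1 except $d_M = 0.5$ (mature miRNAs outlive
mRNAs); productions and gains are $k_R = 1$, $a_R = 2$, $k_P = 1$,
$k_V = 2$, $k_{leak} = 1$, $k_{Aon} = 2$, $k_{Aoff} = 1$,
$a_S = k_{Sp} = a_K = 1$, $\eta = 1$. The two loop strengths were chosen
once, by scanning the $(k_{rep}, g_K, \alpha)$ grid, so that the model
reproduces the qualitative genotype panel under the step stimulus:
$k_{rep} = 16$ and $g_K = 2$ (with $\alpha = 4$). Weaker repression
(e.g. $k_{rep} \lesssim 8$ at $g_K = 1$) leaves even the wild-type
potential plateauing above 20% of its peak, so no genotype returns and
the switch behaviour collapses; the shipped values give a wild type that
returns to ~13% of peak within ~3 lifetimes, delayed-but-returning SKIP
and heterozygote responses, and a miR-1010 null sustained above 80% of
the wild-type peak for at least 50 lifetimes.

Genotype encodings (all parameter-level; a perturbation never edits a
species): miR-1010 null and heterozygote scale $\eta$ by 0 and 0.5 (the
simplest dosage model); the SKIP MiMIC sets $k_{Sp} = 0$; the 3'UTR
binding-site mutant sets $k_{rep} = 0$ with the mirtron intact; NaChBac
adds $e = 1$ (the same order as the stimulated drive); Kir2.1 triples
$k_{leak}$; nicotine multiplies the stimulus amplitude by 2 (0.1 mg/ml)
or 4 (0.5 mg/ml). The NaChBac/Kir2.1/nicotine magnitudes are not
constrained by printed data and are exposed in the configuration.

## Simulation, metrics and the switch

Each genotype is integrated from **its own** resting steady state (zero
stimulus), because each fly line develops at rest before stimulation;
`lsoda` with `rtol = 1e-8`, `atol = 1e-10` and at least 2,000 output
points, splitting at stimulus discontinuities. Curves are presented
normalized to the wild-type peak over the full simulated window (the
global peak). Fixed points are found by damped Newton iteration seeded
from a 100-lifetime integration, with a 500-lifetime integration
fallback, to a max-norm residual below 1e-9; non-convergence is reported
explicitly, never silently.

The return metric: the first output-grid time at or after a curve's own
peak from which the normalized potential stays below 20% of the
wild-type peak for the entire remaining grid (no debounce window —
deterministic ODE trajectories cannot chatter). Δt is that time minus
the wild type's. Classification: `sustained` if no such time exists
within the horizon (50 lifetimes for metrics; "long-term" is
operationalized as 50 lifetimes since the observations give no horizon),
`delayed` if Δt exceeds one grid step, else `homeostatic`. A yield scan
(`classify_switch`) over $\eta \in [0,1]$ reports the smallest grid
yield that returns — the switch point — and flags a non-monotone
pattern rather than repairing it.

## Calibration

Steady-state fold changes under the stimulated condition (each genotype
vs wild type, observables $R \to$ nAcRβ2 mRNA, $S_t \to$ SKIP
transcript, $K \to$ Shal, $M \to$ miR-1010) are compared with the
printed RT-qPCR fold changes on the log2 scale:
$L = \sum_i w_i(\log_2 \hat f_i - \log_2 f_i)^2$, unit weights —
fold changes are multiplicative and no error bars are printed, so
uncertainty weighting is impossible. "~" values are treated as exact
targets. The rescue-line SKIP ~10-fold row ships with weight 0: the
observation is explicitly unexplained and the condition has no
counterpart in a well-mixed model.

The search is derivative-free (Nelder–Mead on log parameters, Brent when
one-dimensional) from five seeded starts. Two deliberate restrictions:

* **Free set** `a_R, k_rep, g_K, alpha` only. Decay rates are fixed to
  preserve the time unit. The sensing and host-transcription gains
  (`k_Aon`, `k_Aoff`, `a_S`) are fixed because the saturating
  phospho-fraction makes them non-identifiable from steady-state fold
  changes — they trade off against the tempering gains.
* **Trust region** of a factor 1.5 around the starting values. The
  nicotine ~10-fold miR-1010 row is structurally unreachable at steady
  state (with $A$ saturating, the miR-1010 fold under raised agonist
  gain is capped near 2), and an unconstrained fit chases it into a
  regime that inverts the observed NaChBac and Kir2.1 directions and
  destroys the wild-type homeostatic return. The calibration is
  therefore a local refinement of the dynamically validated defaults;
  residual signs are always reported so direction failures stay visible.

This also records a known limitation: the printed 2-fold nAcRβ2 and
~10-fold miR-1010 increases under nicotine plausibly reflect transient
or spatially restricted responses; the well-mixed stimulated steady
state reproduces their directions for miR-1010 but not for nAcRβ2
(feedback dominates), and the model offers no mechanism for the lower
miR-1010 level at the higher nicotine dose.

## The qPCR pipeline and its synthetic twin

Relative quantification is 2^(−ΔΔCt) with an endogenous control (Rpl32
for mRNA, U27 for miRNA; no efficiency correction — no efficiencies are
printed). The expressed flag applies the strict mean-Ct < 33 cutoff to
the control group, where the baseline expression judgement belongs.
Significance follows the variance-decision procedure: a Bartlett test at
α = 0.05 decides between the pooled-variance Student t-test and the
Welch t-test, both two-sided, on the per-replicate ΔCt values (testing
on the ΔCt scale, not on fold changes, is the statistically standard
reading).

The synthetic generator draws independent Gaussian Ct values per well —
control target at the baseline Ct (24), condition target shifted by
−log2(true fold change), reference at its own mean (15) in both groups —
with SD 0.2 cycles (typical technical qPCR variability) and 9 replicates
per group, mirroring the study's "at least 9". One preset per printed
fold change ships with the package. What this emulates — and what it
does not: real Ct data carry batch structure (the study pooled
independent embryo batches), plate effects and occasional dropouts; the
generator's flat Gaussian model has none of these, so passing recovery
tests demonstrate correctness of the quantification arithmetic and
unbiasedness under the assumed noise, not robustness to structured
variation.

## Numerical choices and degenerate inputs

Solver tolerances as above; trajectories are accepted if all species
stay above −1e-8 and the phospho-fraction below 1 + 1e-8. Steady states
require residual < 1e-9. A wild type that never returns below the
threshold is raised as a configuration error (the metric is meaningless
without a returning reference). Zero-variance/equal-mean group pairs are
rejected by the variance-decision test; groups need at least 2
replicates; Ct values must lie in (0, 40]. Fold-change references below
1e-12 raise a degenerate-reference error. Problem sizes used throughout
the shipped tests: 50-lifetime horizons with ~1,000–2,000 output points,
500-seed Monte-Carlo recovery (2,000 for the small 1.24-fold effect,
where the estimator's spread is large relative to the effect).

## Known limitations

Well-mixed, deterministic, dimensionless: no spatial or cell-type
specificity (the mirtron's neuron-specific action is outside scope), no
stochastic transcription, no electrophysiological units or spike
dynamics — the potential is a long-term average proxy. Parameters are
order-of-magnitude defaults calibrated to qualitative phenotypes and a
handful of printed fold changes, not fitted kinetic constants. The
4E-BP stress readout is treated purely as a qPCR observable (it is
downstream of growth signalling, outside the network), as is the
rescue-line SKIP level.
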