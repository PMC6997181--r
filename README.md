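# synhomeo

Mass-action modelling of mirtron-mediated synaptic homeostasis, with the
RT-qPCR relative-quantification pipeline used to observe it.

## The problem

In Drosophila larvae, activation of the nicotinic acetylcholine receptor
β2 (nAcRβ2) depolarizes neurons. Two coupled motifs keep the response in
a viable range: an **incoherent feedforward loop** — neural activity
phosphorylates the transcription factor Adf-1, releasing expression of
the Shal K⁺ channel and of SKIP, whose protein amplifies Shal's
tempering of the membrane potential — and a **negative feedback loop** —
the mirtron miR-1010, spliced from a SKIP intron and therefore
co-produced with the SKIP transcript, degrades nAcRβ2 mRNA and removes
the depolarizing drive at its source. Loss of the mirtron (or of its
binding site in the nAcRβ2 3'UTR) is lethal early in larval life; loss
of SKIP protein only delays development.

`synhomeo` is for modellers and experimentalists who want to reproduce,
probe or extend this regulatory logic: it implements the eight-species
mass-action ODE system, genotypes-as-parameter-perturbations, the
phenotype metrics (peak overshoot, return delay Δt, homeostatic /
delayed / sustained classification, the miRNA-yield switch point),
least-squares calibration against printed fold-change observations, and
a ΔΔCt qPCR pipeline (2^(−ΔΔCt), strict Ct < 33 expression filter,
Bartlett-decided Student/Welch testing) together with a seeded synthetic
Ct-data generator.

## The model

With u(t) the agonist stimulus, the network is

    dR/dt  = k_R + a_R·V − d_R·R − k_rep·M·R        (nAcRβ2 mRNA)
    dP/dt  = k_P·R − d_P·P                          (surface receptor)
    dV/dt  = k_V·u(t)·P − k_leak·V − g_K·K·(1 + α·Sp)·V + e   (potential)
    dA/dt  = k_Aon·V·(1−A) − k_Aoff·A               (phospho-Adf-1 fraction)
    dSt/dt = a_S·A − d_St·St                        (SKIP transcript)
    dSp/dt = k_Sp·St − d_Sp·Sp                      (SKIP protein)
    dK/dt  = a_K·A − d_K·K                          (Shal channel)
    dM/dt  = η·a_S·A − d_M·M                        (mature miR-1010)

Time is measured in receptor lifetimes (1/d_P); the resting potential is
defined to 0; curves are normalized to the wild-type peak. Genotypes are
parameter edits: the miR-1010 null sets η = 0, the heterozygote η → η/2,
the SKIP MiMIC protein-null zeroes k_Sp only (the mirtron is still
made), the 3'UTR binding-site mutant zeroes k_rep, NaChBac adds constant
depolarization, Kir2.1 scales the leak, nicotine scales u.

## Worked example

```r
library(synhomeo)

genotype_metrics(c("wild-type", "miR-1010-null", "miR-1010-het", "SKIP-MiMIC"))
#>        genotype peak time_of_peak t_return delta_t terminal_level classification
#> 1     wild-type 1.00         1.12     2.93   0.000          0.129    homeostatic
#> 2 miR-1010-null 1.21         1.62       NA      NA          0.843      sustained
#> 3  miR-1010-het 1.06         1.23     3.45   0.525          0.176        delayed
#> 4    SKIP-MiMIC 1.03         1.23     4.17   1.250          0.152        delayed
```

Under a sustained unit stimulus the wild-type potential peaks and falls
back below 20% of its peak within ~3 receptor lifetimes. Halving the
mirtron yield or removing SKIP protein overshoots the wild-type peak
(peak > 1) and returns late (Δt > 0); removing the mirtron entirely
leaves the potential sustained at 84% of the wild-type peak — the yield
acts as a switch, whose grid location the scan reports:

```r
classify_switch()$eta_star
#> [1] 0.4
```

The qPCR side, on synthetic data whose ground truth is the printed
2-fold nicotine/nAcRβ2 observation:

```r
q <- delta_delta_ct(generate_ct_data(builtin_presets()[["nicotine-nAcRb2"]], seed = 1))
q$fold_change; q$test_used; q$stars
#> [1] 1.925
#> [1] "student"
#> [1] "***"
```

A single 9-replicate experiment at 0.2-cycle noise recovers the 2-fold
truth to within sampling error; the Bartlett decision kept the pooled
t-test. `fit_parameters(builtin_observation_table())` refines the loop
gains against all printed fold changes at once, and
`run_full_pipeline(resolve_config())` writes curves, metrics,
quantification CSVs and a seeded manifest in one call.

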