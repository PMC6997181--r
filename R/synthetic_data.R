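#' qPCR simulation preset
#'
#' Bundles the ground truth and noise model for one synthetic RT-qPCR
#' experiment: a true fold change taken from a printed observation, a
#' baseline target Ct, a reference-gene Ct, Gaussian per-well cycle noise
#' and the per-group replicate count.
#'
#' @param name Preset identifier.
#' @param observable qPCR observable name.
#' @param condition Genotype/treatment name, or a qPCR-only tag
#'   ("rescue-line", "4E-BP" conditions have no model counterpart).
#' @param true_fold_change Ground-truth fold change (> 0).
#' @param baseline_target_ct Mean control-group target Ct (default 24).
#' @param reference_ct Mean endogenous-control Ct (default 15).
#' @param ct_sd Per-well Ct standard deviation in cycles (default 0.2).
#' @param replicates_per_group Replicates per group (default 9, >= 2).
#' @param source Citation tag.
#' @return An object of class `qpcr_preset`.
#' @export
qpcr_preset <- function(name, observable, condition, true_fold_change,
                        baseline_target_ct = 24, reference_ct = 15,
                        ct_sd = 0.2, replicates_per_group = 9, source = "") {
  if (true_fold_change <= 0) stop("true_fold_change must be > 0", call. = FALSE)
  if (ct_sd < 0) stop("ct_sd must be >= 0", call. = FALSE)
  if (replicates_per_group < 2) stop("need >= 2 replicates per group", call. = FALSE)
  structure(
    list(name = name, observable = observable, condition = condition,
         true_fold_change = true_fold_change,
         baseline_target_ct = baseline_target_ct, reference_ct = reference_ct,
         ct_sd = ct_sd, replicates_per_group = replicates_per_group,
         source = source),
    class = "qpcr_preset"
  )
}

#' Built-in synthetic qPCR presets
#'
#' One preset per printed fold-change observation: the nicotine
#' experiments (2-fold nAcRb2, ~10-fold miR-1010 at both doses), the
#' miR-1010 deletion (~3-fold SKIP and Shal transcripts, 10-fold 4E-BP
#' stress marker at larval onset), the Kir2.1 silencing (1.24-fold
#' nAcRb2), the 3'UTR binding-site mutant (5-fold miR-1010) and the
#' neuronal rescue line (~10-fold SKIP transcript). Reference-gene
#' defaults mimic an Rpl32-style mRNA control; miRNA presets are read
#' against a U27-style small-RNA control — the arithmetic is identical.
#'
#' @return Named list of [qpcr_preset()] objects.
#' @export
builtin_presets <- function() {
  ps <- list(
    qpcr_preset("nicotine-nAcRb2", "nAcRb2_mRNA", "nicotine-low", 2,
                source = "nAcRb2 increased to 2-fold of control at 0.1 mg/ml nicotine"),
    qpcr_preset("nicotine-miR1010", "miR-1010", "nicotine-low", 10,
                source = "~10-fold miR-1010 increase under nicotine"),
    qpcr_preset("nicotine-high-miR1010", "miR-1010", "nicotine-high", 10,
                source = "~10-fold miR-1010 increase at both nicotine doses"),
    qpcr_preset("null-SKIP", "SKIP_transcript", "miR-1010-null", 3,
                source = "~3-fold SKIP transcript increase in the miR-1010 deletion"),
    qpcr_preset("null-Shal", "Shal", "miR-1010-null", 3,
                source = "~3-fold Shal increase in the miR-1010 deletion"),
    qpcr_preset("null-4EBP", "4E-BP", "miR-1010-null", 10,
                source = "10-fold 4E-BP increase at larval onset in the miR-1010 deletion"),
    qpcr_preset("Kir21-nAcRb2", "nAcRb2_mRNA", "Kir2.1", 1.24,
                source = "modest 1.24-fold nAcRb2 increase under Kir2.1"),
    qpcr_preset("delta1010-miR1010", "miR-1010", "nAcRb2-delta1010", 5,
                source = "miR-1010 peaking at 5-fold of wild type in the binding-site mutant"),
    qpcr_preset("rescue-SKIP", "SKIP_transcript", "rescue-line", 10,
                source = "SKIP mRNA ~10-fold higher in the neuronal rescue line")
  )
  setNames(ps, vapply(ps, `[[`, "", "name"))
}

# qPCR-only condition tags with no dynamical-model counterpart
qpcr_only_conditions <- function() c("rescue-line")
qpcr_only_observables <- function() c("4E-BP")

#' Generate synthetic Ct measurements for a preset
#'
#' Draws per-well Ct values: control target Ct ~ Normal(baseline, sd);
#' condition target Ct ~ Normal(baseline - log2(true fold change), sd);
#' reference Ct ~ Normal(reference mean, sd) in both groups. Deterministic
#' given the seed.
#'
#' @param preset A [qpcr_preset()].
#' @param seed Integer seed.
#' @return Data frame in the Ct CSV dialect (columns `sample_id`,
#'   `group`, `target_gene`, `target_ct`, `reference_gene`,
#'   `reference_ct`, `replicate_index`).
#' @export
generate_ct_data <- function(preset, seed = 1) {
  stopifnot(inherits(preset, "qpcr_preset"))
  set.seed(as.integer(seed))
  n <- preset$replicates_per_group
  shift <- log2(preset$true_fold_change)
  ref_gene <- if (preset$observable %in% c("miR-1010")) "U27" else "Rpl32"
  draw <- function(mu) stats::rnorm(n, mu, preset$ct_sd)
  data.frame(
    sample_id = sprintf("%s_%s_%02d", preset$name,
                        rep(c("ctrl", "cond"), each = n), c(1:n, 1:n)),
    group = rep(c("control", "condition"), each = n),
    target_gene = preset$observable,
    target_ct = c(draw(preset$baseline_target_ct),
                  draw(preset$baseline_target_ct - shift)),
    reference_gene = ref_gene,
    reference_ct = c(draw(preset$reference_ct), draw(preset$reference_ct)),
    replicate_index = c(1:n, 1:n),
    stringsAsFactors = FALSE
  )
}

#' Generate a noisy fold-change observation table
#'
#' Multiplies each preset truth by a log-normal factor
#' exp(Normal(0, relative_sd)); with `relative_sd = 0` the table equals
#' the preset truths. Useful for calibration robustness checks.
#'
#' @param presets List of [qpcr_preset()] objects.
#' @param relative_sd Log-scale relative noise (>= 0).
#' @param seed Integer seed.
#' @return Observation data frame (columns `observable`, `condition`,
#'   `value`, `weight`, `source`).
#' @export
generate_foldchange_table <- function(presets = builtin_presets(),
                                      relative_sd = 0, seed = 1) {
  stopifnot(relative_sd >= 0)
  set.seed(as.integer(seed))
  noise <- exp(stats::rnorm(length(presets), 0, relative_sd))
  data.frame(
    observable = vapply(presets, `[[`, "", "observable"),
    condition = vapply(presets, `[[`, "", "condition"),
    value = vapply(presets, `[[`, 0, "true_fold_change") * noise,
    weight = 1,
    source = vapply(presets, `[[`, "", "source"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Monte-Carlo fold-change recovery for a preset
#'
#' Generates `n_seeds` independent synthetic Ct datasets, runs
#' [delta_delta_ct()] on each, and summarizes the estimates: geometric
#' mean fold change, mean and standard error of the log2 estimates.
#'
#' @param preset A [qpcr_preset()].
#' @param n_seeds Number of replicate datasets.
#' @param base_seed Offset added to 1..n_seeds to form each dataset seed.
#' @return List: `geometric_mean_fc`, `mean_log2`, `se_log2`, `n_seeds`,
#'   `true_fold_change`.
#' @export
recover_fold_change <- function(preset, n_seeds = 500, base_seed = 0) {
  l2 <- vapply(seq_len(n_seeds), function(i) {
    delta_delta_ct(generate_ct_data(preset, seed = base_seed + i))$log2_fold_change
  }, numeric(1))
  list(
    geometric_mean_fc = 2^mean(l2),
    mean_log2 = mean(l2),
    se_log2 = stats::sd(l2) / sqrt(n_seeds),
    n_seeds = n_seeds,
    true_fold_change = preset$true_fold_change
  )
}
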