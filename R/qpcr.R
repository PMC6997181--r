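#' Baseline expression filter
#'
#' A target counts as expressed at meaningful levels when its mean Ct is
#' strictly below the cycle threshold (default 33 cycles): lower Ct means
#' more template.
#'
#' @param ct Numeric vector of Ct values (cycles).
#' @param threshold Cycle cutoff (default 33).
#' @return Logical: expressed or not.
#' @export
expression_filter <- function(ct, threshold = 33) {
  stopifnot(length(ct) >= 1, all(is.finite(ct)))
  mean(ct) < threshold
}

#' Variance-decision two-sample test
#'
#' Applies a Bartlett test for homogeneity of variances; when the
#' Bartlett p-value is at or above `alpha` the group means are compared
#' with a pooled-variance Student t-test, otherwise with a Welch t-test
#' for unequal variances. Both t-tests are two-sided.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param alpha Significance level for the Bartlett decision.
#' @return List with `test_used` ("student" or "welch"), `p_value`,
#'   `statistic`, `df`, `bartlett_p`.
#' @export
variance_decision_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      stop("both groups have zero variance and equal means: test degenerate",
           call. = FALSE)
    }
    return(list(test_used = "student", p_value = 0, statistic = Inf,
                df = length(a) + length(b) - 2, bartlett_p = 1))
  }
  bart <- stats::bartlett.test(list(a, b))
  use_student <- bart$p.value >= alpha
  tt <- stats::t.test(a, b, var.equal = use_student)
  list(
    test_used = if (use_student) "student" else "welch",
    p_value = unname(tt$p.value),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    bartlett_p = unname(bart$p.value)
  )
}

# internal: significance stars per the usual figure-legend convention
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Computes per-replicate delta-Ct (target Ct minus endogenous-control
#' Ct), the delta-delta-Ct between condition and control group means, the
#' fold change 2^(-ddCt), the expressed flag (mean control target Ct
#' strictly below the cycle threshold), and a variance-decision t-test on
#' the delta-Ct values.
#'
#' @param ct_data Data frame in the Ct CSV dialect: columns `sample_id`,
#'   `group` ("control" or "condition"), `target_gene`, `target_ct`,
#'   `reference_gene`, `reference_ct`, `replicate_index`.
#' @param alpha Bartlett decision level.
#' @param ct_threshold Expression cycle cutoff.
#' @return List of class `quantification_result`: `target_gene`,
#'   `fold_change`, `log2_fold_change`, `delta_ct_mean` and
#'   `delta_ct_sd` (named per group), `n` (per group), `expressed`,
#'   `test_used`, `p_value`, `stars`.
#' @export
delta_delta_ct <- function(ct_data, alpha = 0.05, ct_threshold = 33) {
  needed <- c("sample_id", "group", "target_gene", "target_ct",
              "reference_gene", "reference_ct")
  missing <- setdiff(needed, names(ct_data))
  if (length(missing)) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ct_data$group %in% c("control", "condition"))) {
    stop("group must be 'control' or 'condition'", call. = FALSE)
  }
  with_ct <- c(ct_data$target_ct, ct_data$reference_ct)
  if (any(!is.finite(with_ct)) || any(with_ct <= 0) || any(with_ct > 40)) {
    stop("Ct values must lie in (0, 40]", call. = FALSE)
  }
  if (length(unique(ct_data$reference_gene)) != 1L) {
    stop("reference gene must be consistent within an experiment", call. = FALSE)
  }
  dct <- ct_data$target_ct - ct_data$reference_ct
  ctrl <- dct[ct_data$group == "control"]
  cond <- dct[ct_data$group == "condition"]
  if (length(ctrl) < 2 || length(cond) < 2) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  ddct <- mean(cond) - mean(ctrl)
  fc <- 2^(-ddct)
  test <- variance_decision_test(ctrl, cond, alpha = alpha)
  structure(
    list(
      target_gene = unique(ct_data$target_gene)[1],
      fold_change = fc,
      log2_fold_change = -ddct,
      delta_ct_mean = c(control = mean(ctrl), condition = mean(cond)),
      delta_ct_sd = c(control = stats::sd(ctrl), condition = stats::sd(cond)),
      n = c(control = length(ctrl), condition = length(cond)),
      expressed = expression_filter(
        ct_data$target_ct[ct_data$group == "control"], ct_threshold
      ),
      test_used = test$test_used,
      p_value = test$p_value,
      stars = significance_stars(test$p_value)
    ),
    class = "quantification_result"
  )
}

#' Quantify a Ct CSV file
#'
#' Reads a Ct table (one target gene, two groups) and runs
#' [delta_delta_ct()].
#'
#' @param path CSV path in the Ct dialect.
#' @param alpha,ct_threshold Passed through.
#' @return A `quantification_result`.
#' @export
quantify_ct_csv <- function(path, alpha = 0.05, ct_threshold = 33) {
  delta_delta_ct(utils::read.csv(path, stringsAsFactors = FALSE),
                 alpha = alpha, ct_threshold = ct_threshold)
}
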