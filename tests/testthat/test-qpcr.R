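toy_ct <- function(target_ctrl, target_cond, ref_ctrl, ref_cond,
                   gene = "nAcRb2_mRNA", ref_gene = "Rpl32") {
  n1 <- length(target_ctrl); n2 <- length(target_cond)
  data.frame(
    sample_id = c(sprintf("c%02d", 1:n1), sprintf("x%02d", 1:n2)),
    group = rep(c("control", "condition"), c(n1, n2)),
    target_gene = gene,
    target_ct = c(target_ctrl, target_cond),
    reference_gene = ref_gene,
    reference_ct = c(ref_ctrl, ref_cond),
    replicate_index = c(1:n1, 1:n2),
    stringsAsFactors = FALSE
  )
}

test_that("expression filter uses a strict mean-Ct cutoff", {
  expect_true(expression_filter(c(30, 30, 30)))
  expect_false(expression_filter(c(33, 33, 33)))
  expect_true(expression_filter(c(32.999, 32.999)))
  expect_false(expression_filter(35))
})

test_that("a one-cycle delta-Ct shift is a two-fold change", {
  d <- toy_ct(c(20, 20, 20), c(19, 19, 19), rep(15, 3), rep(15, 3))
  q <- delta_delta_ct(d)
  expect_equal(q$fold_change, 2)
})

test_that("identical groups give fold change 1 and p near 1", {
  d <- toy_ct(c(20, 20.2, 19.8), c(20, 20.2, 19.8), rep(15, 3), rep(15, 3))
  q <- delta_delta_ct(d)
  expect_equal(q$fold_change, 1)
  expect_gt(q$p_value, 0.95)
  expect_equal(q$stars, "ns")
})

test_that("triplicate toy table matches the hand-computed fold change", {
  # control delta-Ct: 5.1, 5.0, 4.9 (mean 5.0); condition: 3.4, 3.5, 3.6
  # (mean 3.5); ddCt = -1.5; fold change = 2^1.5
  d <- toy_ct(c(20.1, 20.0, 19.9), c(18.4, 18.5, 18.6), rep(15, 3), rep(15, 3))
  q <- delta_delta_ct(d)
  expect_equal(q$fold_change, 2^1.5, tolerance = 1e-12)
  expect_equal(q$log2_fold_change, 1.5, tolerance = 1e-12)
  expect_equal(unname(q$delta_ct_mean), c(5.0, 3.5))
  expect_true(q$expressed)
})

test_that("fold change is identical via 2^(-ddCt) to 1e-12", {
  set.seed(5)
  d <- toy_ct(rnorm(5, 24, 0.3), rnorm(5, 22, 0.3), rnorm(5, 15, 0.3), rnorm(5, 15, 0.3))
  q <- delta_delta_ct(d)
  expect_equal(q$fold_change, 2^(-(q$delta_ct_mean[["condition"]] -
                                     q$delta_ct_mean[["control"]])),
               tolerance = 1e-12)
})

test_that("adding a constant to every Ct leaves the fold change unchanged", {
  set.seed(6)
  d <- toy_ct(rnorm(4, 24, 0.2), rnorm(4, 23, 0.2), rnorm(4, 15, 0.2), rnorm(4, 15, 0.2))
  q1 <- delta_delta_ct(d)
  d2 <- d
  d2$target_ct <- d2$target_ct + 3
  d2$reference_ct <- d2$reference_ct + 3
  q2 <- delta_delta_ct(d2)
  expect_equal(q2$fold_change, q1$fold_change, tolerance = 1e-12)
})

test_that("swapping control and condition inverts the fold change exactly", {
  set.seed(7)
  d <- toy_ct(rnorm(4, 24, 0.2), rnorm(4, 22.5, 0.2), rnorm(4, 15, 0.2), rnorm(4, 15, 0.2))
  q1 <- delta_delta_ct(d)
  d2 <- d
  d2$group <- ifelse(d$group == "control", "condition", "control")
  q2 <- delta_delta_ct(d2)
  expect_equal(q2$fold_change, 1 / q1$fold_change, tolerance = 1e-12)
})

test_that("insufficient replication and malformed tables are rejected", {
  d <- toy_ct(24, c(22, 22.1), 15, c(15, 15))
  expect_error(delta_delta_ct(d), "replicates")
  d2 <- toy_ct(c(24, 24), c(22, 22), c(15, 15), c(15, 15))
  d2$reference_gene <- c("Rpl32", "Rpl32", "U27", "U27")
  expect_error(delta_delta_ct(d2), "consistent")
  d3 <- toy_ct(c(24, 44), c(22, 22), c(15, 15), c(15, 15))
  expect_error(delta_delta_ct(d3), "Ct values")
})

test_that("variance decision picks Student for equal variances, Welch for unequal", {
  set.seed(8)
  a <- rnorm(9, 0, 1); b <- rnorm(9, 1, 1)
  eq <- variance_decision_test(a, b)
  expect_equal(eq$test_used, "student")
  b2 <- rnorm(9, 1, 10)
  uneq <- variance_decision_test(a, b2)
  expect_equal(uneq$test_used, "welch")
})

test_that("returned p-values match textbook recomputation, incl. Welch-Satterthwaite", {
  a <- c(5.1, 5.0, 4.9, 5.2, 4.8)
  b <- c(3.4, 3.5, 3.6, 3.3, 3.8)
  r <- variance_decision_test(a, b)
  oracle <- if (r$test_used == "student") hand_student_t(a, b) else hand_welch_t(a, b)
  expect_equal(r$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(r$df, oracle$df, tolerance = 1e-12)
  # a pair engineered into the Welch branch
  a2 <- c(10, 10.01, 9.99, 10.02, 9.98, 10, 10.01, 9.99, 10)
  b2 <- c(5, 8, 11, 3, 14, 6, 9, 2, 12)
  r2 <- variance_decision_test(a2, b2)
  expect_equal(r2$test_used, "welch")
  o2 <- hand_welch_t(a2, b2)
  expect_equal(r2$p_value, o2$p, tolerance = 1e-12)
  expect_equal(r2$df, o2$df, tolerance = 1e-12)
})

test_that("Student and Welch branches agree on equal-variance draws at n = 30", {
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(30, 0, 1); b <- rnorm(30, 0.5, 1)
    ps <- hand_student_t(a, b)$p
    pw <- hand_welch_t(a, b)$p
    expect_lt(abs(ps - pw), 0.02)
  }
})

test_that("degenerate zero-variance equal-mean input errors", {
  expect_error(variance_decision_test(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(synhomeo:::significance_stars(0.04), "*")
  expect_equal(synhomeo:::significance_stars(0.009), "**")
  expect_equal(synhomeo:::significance_stars(0.0009), "***")
  expect_equal(synhomeo:::significance_stars(0.2), "ns")
})

test_that("Ct CSV round-trips through quantify_ct_csv", {
  d <- toy_ct(c(20.1, 20.0, 19.9), c(18.4, 18.5, 18.6), rep(15, 3), rep(15, 3))
  path <- tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  q <- quantify_ct_csv(path)
  expect_equal(q$fold_change, 2^1.5, tolerance = 1e-12)
})
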