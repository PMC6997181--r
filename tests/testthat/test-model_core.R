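test_that("parameter validation names the offending field", {
  expect_error(default_parameters(bogus = 1), "bogus")
  expect_error(default_parameters(k_rep = -1), "k_rep")
  expect_error(default_parameters(eta = 1.5), "eta")
  p <- default_parameters()
  p <- p[setdiff(names(p), "d_M")]
  expect_error(validate_parameters(p), "d_M")
})

test_that("default network passes its construction contract", {
  net <- build_default_network()
  expect_s3_class(net, "reaction_network")
  expect_identical(net$species, species_names())
  expect_silent(validate_network(net))
  # every rate name resolvable, all stoichiometries integer >= 0
  for (r in net$reactions) {
    expect_true(all(r$rate %in% names(net$parameters)))
    expect_true(all(c(r$reactants, r$products) >= 0))
  }
})

test_that("pure-decay parameterization leaves only the decay term", {
  p <- default_parameters()
  p[] <- 0
  p["d_R"] <- 0.7
  p["d_P"] <- 1  # keeps the time unit defined
  net <- build_default_network(p)
  st <- setNames(c(2, 0, 0, 0, 0, 0, 0, 0), species_names())
  d <- evaluate_rhs(net, st, stimulus = 1)
  expect_equal(unname(d[["R"]]), -0.7 * 2)
  expect_equal(unname(d[names(d) != "R"]), rep(0, 7))
})

test_that("zero mirtron yield severs miR-1010 production", {
  net <- build_default_network(default_parameters(eta = 0))
  st <- random_state()
  d <- evaluate_rhs(net, st, stimulus = 1)
  expect_equal(unname(d[["M"]]), -net$parameters[["d_M"]] * st[["M"]])
})

test_that("single catalytic decay reaction follows the mass-action definition", {
  p <- default_parameters()
  p[] <- 0
  p["d_P"] <- 1
  p["k_rep"] <- 0.5
  net <- build_default_network(p)
  st <- zero <- setNames(numeric(8), species_names())
  st[["R"]] <- 2; st[["M"]] <- 1
  d <- evaluate_rhs(net, st, stimulus = 0)
  expect_equal(unname(d[["R"]]), -1.0)
})

test_that("all-zero state with only basal transcription produces only dR/dt", {
  p <- default_parameters()
  p[] <- 0
  p["d_P"] <- 1
  p["k_R"] <- 1
  net <- build_default_network(p)
  d <- evaluate_rhs(net, setNames(numeric(8), species_names()), stimulus = 1)
  expect_equal(unname(d[["R"]]), 1)
  expect_equal(unname(d[names(d) != "R"]), rep(0, 7))
})

test_that("generic RHS matches the hand-assembled equations term by term", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_parameters()
    st <- random_state()
    u <- runif(1, 0, 3)
    net <- build_default_network(p)
    expect_equal(unname(evaluate_rhs(net, st, stimulus = u)),
                 unname(hand_rhs(st, p, u)),
                 tolerance = 1e-12)
  }
})

test_that("compiled fast path agrees with the generic evaluation", {
  set.seed(12)
  for (i in 1:10) {
    p <- random_parameters()
    net <- build_default_network(p)
    f <- synhomeo:::compile_rhs(net)
    st <- random_state()
    u <- runif(1, 0, 2)
    expect_equal(f(unname(st[species_names()]), u),
                 unname(evaluate_rhs(net, st, stimulus = u)),
                 tolerance = 1e-14)
  }
})

test_that("RHS rejects malformed states", {
  net <- build_default_network()
  expect_error(evaluate_rhs(net, numeric(5)), "length")
  bad <- setNames(numeric(8), species_names())
  bad[["R"]] <- -1
  expect_error(evaluate_rhs(net, bad), "negative")
})

test_that("steady state solves the linear closed form k/d", {
  p <- default_parameters()
  p[] <- 0
  p["k_R"] <- 2
  p["d_R"] <- 0.5
  p["d_P"] <- 1
  net <- build_default_network(p)
  s <- steady_state(net, stimulus_amplitude = 0)
  expect_true(s$converged)
  expect_equal(unname(s$state[["R"]]), 4, tolerance = 1e-7)
})

test_that("steady-state miR-1010 is zero when the mirtron yield is zero", {
  net <- build_default_network(default_parameters(eta = 0))
  s <- steady_state(net, stimulus_amplitude = 1)
  expect_true(s$converged)
  expect_equal(unname(s$state[["M"]]), 0, tolerance = 1e-9)
})

test_that("full-network steady state matches the dense long-integration oracle", {
  p <- default_parameters()
  net <- build_default_network(p)
  s <- steady_state(net, stimulus_amplitude = 1)
  expect_true(s$converged)
  oracle <- hand_steady_state(p, u = 1)
  expect_equal(unname(s$state), unname(oracle), tolerance = 1e-6)
})

test_that("species with zeroth-order production and first-order decay relax to k/d", {
  # closed-form check of the trajectory, not just the fixed point
  p <- default_parameters()
  p[] <- 0
  p["k_R"] <- 1.5
  p["d_R"] <- 0.8
  p["d_P"] <- 1
  net <- build_default_network(p)
  times <- seq(0, 10, length.out = 501)
  analytic <- (1.5 / 0.8) * (1 - exp(-0.8 * times))
  f <- synhomeo:::compile_rhs(net)
  out <- deSolve::ode(setNames(numeric(8), species_names()), times,
                      function(t, y, parms) list(f(y, 0)), NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, "R"], analytic, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("trajectories stay non-negative from non-negative starts", {
  set.seed(21)
  for (i in 1:5) {
    p <- random_parameters()
    net <- build_default_network(p)
    tc <- simulate_timecourse(net, stimulus_spec("step"), horizon = 20, n_out = 501)
    expect_true(all(tc$states >= -1e-8))
    expect_true(all(tc$states[, "A"] <= 1 + 1e-8))
  }
})

test_that("steady-state nAcRb2 mRNA does not increase with the repression rate", {
  krep_grid <- seq(1, 30, length.out = 10)
  R_star <- vapply(krep_grid, function(k) {
    net <- build_default_network(default_parameters(k_rep = k))
    s <- steady_state(net, stimulus_amplitude = 1)
    expect_true(s$converged)
    unname(s$state[["R"]])
  }, numeric(1))
  expect_true(all(diff(R_star) <= 1e-9))
})

test_that("steady-state miR-1010 equals eta * a_S * A* / d_M", {
  for (eta in c(0.3, 1)) {
    p <- default_parameters(eta = eta)
    net <- build_default_network(p)
    s <- steady_state(net, stimulus_amplitude = 1)
    expect_true(s$converged)
    expect_equal(unname(s$state[["M"]]),
                 eta * p[["a_S"]] * unname(s$state[["A"]]) / p[["d_M"]],
                 tolerance = 1e-7)
  }
})

test_that("stimulus profiles follow their shapes", {
  st <- stimulus_spec("step", onset = 2, amplitude = 3)
  expect_equal(stimulus_value(st, c(0, 1.9, 2, 10)), c(0, 0, 3, 3))
  pu <- stimulus_spec("pulse", onset = 1, duration = 2, amplitude = 1)
  expect_equal(stimulus_value(pu, c(0.5, 1, 2.9, 3, 4)), c(0, 1, 1, 0, 0))
  im <- stimulus_spec("impulse", onset = 0, amplitude = 2)
  expect_equal(im$duration, 0.1)
  expect_error(stimulus_spec("step", amplitude = -1), "amplitude")
})
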