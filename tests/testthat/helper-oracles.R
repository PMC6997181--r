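# Independent oracles, assembled literally from the model's defining
# equations and textbook statistics formulas. They never call the
# package's evaluation path.

# Hand-assembled right-hand side of the eight-species system, term by term.
hand_rhs <- function(state, p, u) {
  R <- state[["R"]]; P <- state[["P"]]; V <- state[["V"]]; A <- state[["A"]]
  St <- state[["St"]]; Sp <- state[["Sp"]]; K <- state[["K"]]; M <- state[["M"]]
  c(
    R = p[["k_R"]] + p[["a_R"]] * V - p[["d_R"]] * R - p[["k_rep"]] * M * R,
    P = p[["k_P"]] * R - p[["d_P"]] * P,
    V = p[["k_V"]] * u * P - p[["k_leak"]] * V -
      p[["g_K"]] * K * (1 + p[["alpha"]] * Sp) * V + p[["extra_depol"]],
    A = p[["k_Aon"]] * V * (1 - A) - p[["k_Aoff"]] * A,
    St = p[["a_S"]] * A - p[["d_St"]] * St,
    Sp = p[["k_Sp"]] * St - p[["d_Sp"]] * Sp,
    K = p[["a_K"]] * A - p[["d_K"]] * K,
    M = p[["eta"]] * p[["a_S"]] * A - p[["d_M"]] * M
  )
}

# Fixed point by dense long integration with strict tolerances, via
# deSolve on the hand-assembled equations.
hand_steady_state <- function(p, u, horizon = 5000) {
  y0 <- setNames(rep(0, 8), species_names())
  out <- deSolve::ode(
    y = y0, times = seq(0, horizon, length.out = 501),
    func = function(t, y, parms) list(unname(hand_rhs(y, p, u))),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-14
  )
  setNames(as.numeric(out[nrow(out), -1]), species_names())
}

# Two-sample t statistics recomputed from the textbook formulas.
hand_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

hand_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(statistic = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Random valid state for property tests.
random_state <- function() {
  s <- setNames(runif(8, 0, 3), species_names())
  s[["A"]] <- runif(1)
  s
}

random_parameters <- function() {
  p <- default_parameters()
  p[] <- runif(length(p), 0.1, 3)
  p[["eta"]] <- runif(1)
  p[["extra_depol"]] <- runif(1, 0, 0.5)
  p
}
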