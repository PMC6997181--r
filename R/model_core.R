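#' Species of the synaptic homeostasis network
#'
#' Fixed ordering of the eight dynamical species: nAcRb2 mRNA (`R`),
#' nAcRb2 surface receptor (`P`), membrane-potential proxy (`V`, 0 = rest),
#' phosphorylated Adf-1 fraction (`A`, in \[0, 1\]), SKIP transcript (`St`),
#' functional SKIP protein (`Sp`), Shal channel (`K`) and mature miR-1010
#' (`M`). All abundances are dimensionless.
#'
#' @return Character vector of species names in canonical order.
#' @export
species_names <- function() c("R", "P", "V", "A", "St", "Sp", "K", "M")

#' Default rate parameters
#'
#' Dimensionless O(1) rate constants for the homeostasis network. The
#' receptor decay rate `d_P` defines the time unit: one receptor lifetime
#' equals `1/d_P`. `eta` is the miR-1010 maturation yield per SKIP
#' splicing event and lies in \[0, 1\]. `extra_depol` is an additive
#' zeroth-order depolarization term, zero in wild type; it is the hook
#' through which the NaChBac perturbation acts. These defaults are not
#' fitted to data: they were chosen once so that the wild-type response
#' is homeostatic (returns below 20% of its peak under a sustained unit
#' stimulus) while a complete loss of miR-1010 yield leaves the potential
#' sustained, reproducing the qualitative genotype phenotypes. Any value
#' can be overridden by name.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named numeric vector of rate parameters.
#' @examples
#' p <- default_parameters(eta = 0.5)
#' p[["eta"]]
#' @export
default_parameters <- function(...) {
  p <- c(
    k_R = 1, a_R = 2, k_P = 1, k_V = 2, k_leak = 1,
    g_K = 2, alpha = 4, k_Aon = 2, k_Aoff = 1,
    a_S = 1, k_Sp = 1, a_K = 1, eta = 1, k_rep = 16,
    d_R = 1, d_P = 1, d_St = 1, d_Sp = 1, d_K = 1, d_M = 0.5,
    extra_depol = 0
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(ov)] <- as.numeric(ov)
  }
  validate_parameters(p)
  p
}

#' Validate a rate-parameter vector
#'
#' Checks completeness, non-negativity, `eta` in \[0, 1\] and `d_P > 0`
#' (`d_P` carries the time unit).
#'
#' @param params Named numeric vector as returned by [default_parameters()].
#' @return The validated vector, invisibly.
#' @export
validate_parameters <- function(params) {
  required <- names(default_parameters_template())
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in required) {
    v <- params[[nm]]
    if (!is.finite(v)) stop("parameter '", nm, "' is not finite", call. = FALSE)
    if (v < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  }
  if (params[["eta"]] > 1) stop("parameter 'eta' must lie in [0, 1]", call. = FALSE)
  if (params[["d_P"]] <= 0) stop("parameter 'd_P' must be > 0 (defines the time unit)", call. = FALSE)
  invisible(params)
}

# internal: template without triggering validation recursion
default_parameters_template <- function() {
  c(
    k_R = 1, a_R = 2, k_P = 1, k_V = 2, k_leak = 1,
    g_K = 2, alpha = 4, k_Aon = 2, k_Aoff = 1,
    a_S = 1, k_Sp = 1, a_K = 1, eta = 1, k_rep = 16,
    d_R = 1, d_P = 1, d_St = 1, d_Sp = 1, d_K = 1, d_M = 0.5,
    extra_depol = 0
  )
}

#' Stimulus specification
#'
#' Describes the agonist input `u(t)` multiplying the receptor-driven
#' depolarization term. A `step` stays on from `onset`; a `pulse` is
#' rectangular with the given `duration`; an `impulse` is a short
#' rectangular pulse of width 0.1 receptor lifetimes. Amplitude 1 models
#' baseline activation; larger amplitudes model agonist (nicotine) doses.
#'
#' @param shape One of `"step"`, `"pulse"`, `"impulse"`.
#' @param onset Activation time in receptor lifetimes (>= 0).
#' @param duration Pulse length (pulse only; >= 0).
#' @param amplitude Activation multiplier (>= 0).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(shape = c("step", "pulse", "impulse"),
                          onset = 0, duration = 1, amplitude = 1) {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("stimulus amplitude must be >= 0", call. = FALSE)
  if (duration < 0) stop("stimulus duration must be >= 0", call. = FALSE)
  if (onset < 0) stop("stimulus onset must be >= 0", call. = FALSE)
  if (shape == "impulse") duration <- 0.1
  structure(
    list(shape = shape, onset = onset, duration = duration, amplitude = amplitude),
    class = "stimulus_spec"
  )
}

#' Evaluate the stimulus profile u(t)
#'
#' @param stimulus A [stimulus_spec()].
#' @param t Time (vectorized).
#' @return Numeric vector of stimulus amplitudes.
#' @export
stimulus_value <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  on <- t >= stimulus$onset
  if (stimulus$shape != "step") {
    on <- on & (t < stimulus$onset + stimulus$duration)
  }
  stimulus$amplitude * as.numeric(on)
}

# internal: one mass-action reaction record
reaction <- function(name, rate, reactants = NULL, products = NULL,
                     modifiers = character(), complement = character(),
                     stimulated = FALSE) {
  list(
    name = name, rate = rate,
    reactants = reactants %||% integer(), products = products %||% integer(),
    modifiers = modifiers, complement = complement, stimulated = stimulated
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the canonical reaction network
#'
#' Assembles the mass-action network coupling the receptor positive loop,
#' the incoherent feedforward loop (activity -> phospho-Adf-1 -> SKIP/Shal
#' -> potential tempering) and the mirtron negative feedback loop
#' (miR-1010 production stoichiometrically coupled to SKIP transcription;
#' catalytic degradation of nAcRb2 mRNA). Each reaction carries integer
#' stoichiometry, optional modifiers (catalysts, not consumed), an
#' optional complement modifier (the unphosphorylated Adf-1 fraction
#' `1 - A`) and the names of the rate constants whose product scales it.
#'
#' The assembled right-hand side is, term by term:
#' \deqn{dR/dt = k_R + a_R V - d_R R - k_{rep} M R}
#' \deqn{dP/dt = k_P R - d_P P}
#' \deqn{dV/dt = k_V u(t) P - k_{leak} V - g_K K (1 + \alpha S_p) V + extra}
#' \deqn{dA/dt = k_{Aon} V (1 - A) - k_{Aoff} A}
#' \deqn{dSt/dt = a_S A - d_{St} St;\quad dSp/dt = k_{Sp} St - d_{Sp} Sp}
#' \deqn{dK/dt = a_K A - d_K K;\quad dM/dt = \eta a_S A - d_M M}
#'
#' @param params Named parameter vector, see [default_parameters()].
#' @return An object of class `reaction_network` with fields `species`,
#'   `reactions`, `parameters` and `agonist_gain`.
#' @examples
#' net <- build_default_network()
#' length(net$reactions)
#' @export
build_default_network <- function(params = default_parameters()) {
  validate_parameters(params)
  rx <- list(
    reaction("R_basal_transcription", "k_R", products = c(R = 1L)),
    reaction("R_activity_transcription", "a_R", products = c(R = 1L), modifiers = "V"),
    reaction("R_decay", "d_R", reactants = c(R = 1L)),
    reaction("R_miRNA_repression", "k_rep", reactants = c(R = 1L), modifiers = "M"),
    reaction("P_translation", "k_P", products = c(P = 1L), modifiers = "R"),
    reaction("P_decay", "d_P", reactants = c(P = 1L)),
    reaction("V_depolarization", "k_V", products = c(V = 1L), modifiers = "P", stimulated = TRUE),
    reaction("V_extra_depolarization", "extra_depol", products = c(V = 1L)),
    reaction("V_leak", "k_leak", reactants = c(V = 1L)),
    reaction("V_Shal_tempering", "g_K", reactants = c(V = 1L), modifiers = "K"),
    reaction("V_Shal_SKIP_tempering", c("g_K", "alpha"), reactants = c(V = 1L), modifiers = c("K", "Sp")),
    reaction("A_phosphorylation", "k_Aon", products = c(A = 1L), modifiers = "V", complement = "A"),
    reaction("A_dephosphorylation", "k_Aoff", reactants = c(A = 1L)),
    reaction("St_transcription", "a_S", products = c(St = 1L), modifiers = "A"),
    reaction("St_decay", "d_St", reactants = c(St = 1L)),
    reaction("Sp_translation", "k_Sp", products = c(Sp = 1L), modifiers = "St"),
    reaction("Sp_decay", "d_Sp", reactants = c(Sp = 1L)),
    reaction("K_production", "a_K", products = c(K = 1L), modifiers = "A"),
    reaction("K_decay", "d_K", reactants = c(K = 1L)),
    reaction("M_mirtron_splicing", c("eta", "a_S"), products = c(M = 1L), modifiers = "A"),
    reaction("M_decay", "d_M", reactants = c(M = 1L))
  )
  net <- structure(
    list(species = species_names(), reactions = rx, parameters = params,
         agonist_gain = 1),
    class = "reaction_network"
  )
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks that every referenced rate constant exists in the parameter
#' vector, stoichiometric coefficients are non-negative integers, and
#' every species referenced exists in the species list.
#'
#' @param network A `reaction_network`.
#' @return The network, invisibly.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  sp <- network$species
  pn <- names(network$parameters)
  for (r in network$reactions) {
    bad_rate <- setdiff(r$rate, pn)
    if (length(bad_rate)) {
      stop("reaction '", r$name, "' references unknown rate constant(s): ",
           paste(bad_rate, collapse = ", "), call. = FALSE)
    }
    for (side in list(r$reactants, r$products)) {
      if (length(side)) {
        if (any(side < 0) || any(side != as.integer(side))) {
          stop("reaction '", r$name, "' has non-integer or negative stoichiometry",
               call. = FALSE)
        }
        bad_sp <- setdiff(names(side), sp)
        if (length(bad_sp)) {
          stop("reaction '", r$name, "' references unknown species: ",
               paste(bad_sp, collapse = ", "), call. = FALSE)
        }
      }
    }
    bad_mod <- setdiff(c(r$modifiers, r$complement), sp)
    if (length(bad_mod)) {
      stop("reaction '", r$name, "' references unknown modifier species: ",
           paste(bad_mod, collapse = ", "), call. = FALSE)
    }
  }
  invisible(network)
}

#' Evaluate the mass-action right-hand side
#'
#' Each reaction contributes rate = (product of its rate constants) x
#' (stimulus amplitude, if flagged) x (product of reactant abundances to
#' their stoichiometry) x (product of modifier abundances) x (product of
#' complement terms `1 - x`); the rate is added to products and
#' subtracted from reactants.
#'
#' @param network A `reaction_network`.
#' @param state Named numeric state vector in species order.
#' @param stimulus A [stimulus_spec()], or a single number treated as a
#'   constant amplitude.
#' @param t Time at which the stimulus profile is evaluated.
#' @return Named derivative vector, one entry per species, in network
#'   species order.
#' @export
evaluate_rhs <- function(network, state, stimulus = 1, t = 0) {
  sp <- network$species
  if (length(state) != length(sp)) {
    stop("state vector has length ", length(state), ", expected ", length(sp),
         call. = FALSE)
  }
  if (is.null(names(state))) names(state) <- sp else state <- state[sp]
  if (any(state < -1e-8)) {
    stop("negative abundance beyond tolerance in state: ",
         paste(names(state)[state < -1e-8], collapse = ", "), call. = FALSE)
  }
  u <- if (inherits(stimulus, "stimulus_spec")) {
    stimulus_value(stimulus, t)
  } else {
    as.numeric(stimulus)
  }
  u <- u * network$agonist_gain
  p <- network$parameters
  d <- setNames(numeric(length(sp)), sp)
  for (r in network$reactions) {
    rate <- prod(p[r$rate])
    if (r$stimulated) rate <- rate * u
    if (length(r$reactants)) rate <- rate * prod(state[names(r$reactants)]^r$reactants)
    if (length(r$modifiers)) rate <- rate * prod(state[r$modifiers])
    if (length(r$complement)) rate <- rate * prod(1 - state[r$complement])
    if (length(r$reactants)) d[names(r$reactants)] <- d[names(r$reactants)] - rate * r$reactants
    if (length(r$products)) d[names(r$products)] <- d[names(r$products)] + rate * r$products
  }
  d
}

# internal: compile a network into a fast rhs closure f(y, u) -> numeric.
# Index-based equivalent of evaluate_rhs (property-tested against it);
# avoids name lookups inside the integrator's inner loop.
compile_rhs <- function(network) {
  sp <- network$species
  n <- length(sp)
  rx <- network$reactions
  m <- length(rx)
  rate0 <- numeric(m)
  stim <- logical(m)
  ridx <- vector("list", m); rst <- vector("list", m)
  midx <- vector("list", m); cidx <- vector("list", m)
  S <- matrix(0, n, m)
  p <- network$parameters
  for (j in seq_len(m)) {
    r <- rx[[j]]
    rate0[j] <- prod(p[r$rate])
    stim[j] <- isTRUE(r$stimulated)
    ridx[[j]] <- match(names(r$reactants), sp)
    rst[[j]] <- as.numeric(r$reactants)
    midx[[j]] <- match(r$modifiers, sp)
    cidx[[j]] <- match(r$complement, sp)
    if (length(r$reactants)) S[ridx[[j]], j] <- S[ridx[[j]], j] - r$reactants
    if (length(r$products)) {
      pidx <- match(names(r$products), sp)
      S[pidx, j] <- S[pidx, j] + r$products
    }
  }
  gain <- network$agonist_gain
  function(y, u) {
    rates <- rate0
    for (j in seq_len(m)) {
      v <- rates[j]
      if (stim[j]) v <- v * u * gain
      if (length(ridx[[j]])) v <- v * prod(y[ridx[[j]]]^rst[[j]])
      if (length(midx[[j]])) v <- v * prod(y[midx[[j]]])
      if (length(cidx[[j]])) v <- v * prod(1 - y[cidx[[j]]])
      rates[j] <- v
    }
    drop(S %*% rates)
  }
}

#' Resting state used as the all-zero integration start
#' @return Named zero state vector.
#' @keywords internal
zero_state <- function() setNames(numeric(8), species_names())

#' Steady state under a constant stimulus
#'
#' Locates a fixed point of the network under a constant stimulus
#' amplitude by damped Newton iteration with a finite-difference
#' Jacobian, seeded from a 100-lifetime integration; if Newton fails to
#' reach a max-norm residual below `tol`, falls back to a long (500
#' receptor lifetimes) stiff integration and polishes again.
#'
#' @param network A `reaction_network`.
#' @param stimulus_amplitude Constant stimulus amplitude `u`.
#' @param init Named initial state (defaults to all-zero).
#' @param tol Max-norm residual required for convergence.
#' @return List with `state` (named vector), `converged` (logical) and
#'   `residual` (max-norm of the right-hand side at `state`).
#' @export
steady_state <- function(network, stimulus_amplitude = 0, init = zero_state(),
                         tol = 1e-9) {
  sp <- network$species
  if (is.null(names(init))) names(init) <- sp
  rhs <- compile_rhs(network)
  f <- function(y) rhs(pmax(y, 0), stimulus_amplitude)

  integrate_to <- function(y0, horizon) {
    out <- deSolve::ode(
      y = setNames(pmax(y0, 0), sp), times = c(0, horizon),
      func = function(t, y, parms) list(f(y)), parms = NULL,
      method = "lsoda", rtol = 1e-8, atol = 1e-10
    )
    as.numeric(out[nrow(out), -1])
  }

  newton <- function(y0, maxit = 50) {
    y <- pmax(as.numeric(y0), 0)
    for (it in seq_len(maxit)) {
      fy <- f(y)
      if (max(abs(fy)) < tol) return(list(y = y, ok = TRUE))
      J <- numeric_jacobian(f, y)
      step <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(step)) return(list(y = y, ok = FALSE))
      lambda <- 1
      improved <- FALSE
      for (k in 1:30) {
        y_new <- pmax(y + lambda * step, 0)
        f_new <- f(y_new)
        if (max(abs(f_new)) < max(abs(fy))) {
          y <- y_new
          improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (!improved) return(list(y = y, ok = FALSE))
    }
    list(y = y, ok = max(abs(f(y))) < tol)
  }

  seed <- integrate_to(as.numeric(init), 100)
  res <- newton(seed)
  if (!res$ok) {
    seed <- integrate_to(res$y, 500)
    res <- newton(seed)
  }
  state <- setNames(pmax(res$y, 0), sp)
  residual <- max(abs(f(state)))
  list(state = state, converged = residual < tol, residual = residual)
}

# internal: central finite-difference Jacobian
numeric_jacobian <- function(f, y, h = 1e-7) {
  n <- length(y)
  f0 <- f(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + hj
    ym <- y; ym[j] <- ym[j] - hj
    J[, j] <- (f(yp) - f(ym)) / (2 * hj)
  }
  J
}
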