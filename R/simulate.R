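#' Simulate a genotype time course
#'
#' Integrates the network from its own resting steady state (zero
#' stimulus, so V(0) = 0) with a stiff-capable implicit solver, splitting
#' the integration at stimulus discontinuities. Time is measured in
#' receptor lifetimes (1/d_P).
#'
#' @param network A `reaction_network` (already perturbed if modelling a
#'   genotype).
#' @param stimulus A [stimulus_spec()].
#' @param horizon Integration horizon in receptor lifetimes (> 0).
#' @param genotype Label stored with the trajectory.
#' @param n_out Number of output points (>= 2000 by default).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `timecourse`: list with `genotype`, `times`,
#'   `states` (matrix, one column per species), `stimulus`, `diagnostics`.
#' @export
simulate_timecourse <- function(network, stimulus = stimulus_spec("step"),
                                horizon = 50, genotype = "wild-type",
                                n_out = 2001, rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > 0, n_out >= 2)
  rest <- steady_state(network, stimulus_amplitude = 0)
  if (!rest$converged) {
    stop("no resting steady state found (residual ", format(rest$residual), ")",
         call. = FALSE)
  }
  times <- seq(0, horizon, length.out = n_out)
  breaks <- c(stimulus$onset,
              if (stimulus$shape != "step") stimulus$onset + stimulus$duration)
  breaks <- sort(unique(breaks[breaks > 0 & breaks < horizon]))
  u_of_t <- function(t) stimulus_value(stimulus, t)
  rhs <- compile_rhs(network)

  segments <- c(0, breaks, horizon)
  y <- rest$state
  rows <- list()
  for (i in seq_len(length(segments) - 1L)) {
    lo <- segments[i]; hi <- segments[i + 1L]
    # evaluate u just inside the segment so lsoda never straddles a jump
    mid <- (lo + hi) / 2
    seg_times <- unique(c(lo, times[times > lo & times < hi], hi))
    out <- tryCatch(
      deSolve::ode(
        y = y, times = seg_times,
        func = function(t, yy, parms) list(rhs(pmax(yy, 0), u_of_t(mid))),
        parms = NULL, method = "lsoda", rtol = rtol, atol = atol
      ),
      error = function(e) {
        stop("integration failed for genotype '", genotype, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (attr(out, "istate")[1] < 0) {
      stop("integration did not complete for genotype '", genotype, "'",
           call. = FALSE)
    }
    rows[[i]] <- out
    y <- setNames(as.numeric(out[nrow(out), -1]), network$species)
  }
  full <- do.call(rbind, lapply(rows, function(m) m[, , drop = FALSE]))
  full <- full[!duplicated(full[, "time"]), , drop = FALSE]
  keep <- full[, "time"] %in% times
  states <- full[keep, -1, drop = FALSE]
  colnames(states) <- network$species
  structure(
    list(
      genotype = genotype,
      times = full[keep, "time"],
      states = states,
      stimulus = stimulus,
      diagnostics = list(rtol = rtol, atol = atol,
                         resting_residual = rest$residual)
    ),
    class = "timecourse"
  )
}

#' Simulate one registered genotype under shipped defaults
#'
#' Convenience wrapper: builds the default network, applies the named
#' perturbation (including its agonist gain acting on the stimulus) and
#' integrates.
#'
#' @inheritParams simulate_timecourse
#' @param genotype Registered genotype name.
#' @param params Wild-type parameters.
#' @param registry Genotype registry.
#' @return A `timecourse`.
#' @export
simulate_genotype <- function(genotype, stimulus = stimulus_spec("step"),
                              horizon = 50, params = default_parameters(),
                              registry = builtin_genotypes(), n_out = 2001,
                              rtol = 1e-8, atol = 1e-10) {
  net <- apply_perturbation(build_default_network(params), get_genotype(genotype, registry))
  simulate_timecourse(net, stimulus = stimulus, horizon = horizon,
                      genotype = genotype, n_out = n_out, rtol = rtol, atol = atol)
}

#' Normalize a potential trace to the wild-type peak
#'
#' Divides the membrane-potential proxy by the maximum wild-type
#' potential, the presentation frame of the genotype comparison figure.
#'
#' @param tc A `timecourse` for the genotype of interest.
#' @param wt The wild-type `timecourse` simulated under the same stimulus
#'   and horizon.
#' @return An object of class `normalized_response`: `genotype`, `times`,
#'   `v_norm`, `reference_peak`.
#' @export
normalize_to_wildtype <- function(tc, wt) {
  stopifnot(inherits(tc, "timecourse"), inherits(wt, "timecourse"))
  ref <- max(wt$states[, "V"])
  if (ref <= 0) stop("wild-type peak potential is zero; cannot normalize", call. = FALSE)
  structure(
    list(
      genotype = tc$genotype,
      times = tc$times,
      v_norm = tc$states[, "V"] / ref,
      reference_peak = ref
    ),
    class = "normalized_response"
  )
}

#' Export a time course as a data frame
#'
#' @param x A `timecourse`.
#' @param ... Unused.
#' @return Data frame with `time` then one column per species.
#' @export
as.data.frame.timecourse <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}
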