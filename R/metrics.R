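#' Peak, return time and classification of a normalized response
#'
#' Reduces a normalized potential trace to the headline observables:
#' peak, time of peak, the first grid time after the peak at which the
#' trace falls and stays below `threshold` (a fraction of the wild-type
#' peak, which is 1 by construction), the delay relative to wild type,
#' the terminal level, and a classification. "Stays below" means below
#' the threshold at every subsequent grid time. A response that never
#' returns within the horizon is `sustained`; one that returns with delay
#' greater than `delay_tol` is `delayed`; otherwise `homeostatic`.
#'
#' @param resp A `normalized_response` for the genotype.
#' @param wt The wild-type `normalized_response` on the same time base.
#' @param threshold Return threshold as a fraction of the wild-type peak
#'   (default 0.2, i.e. 20% of the wild-type peak).
#' @param delay_tol Delay below which a returning response still counts
#'   as homeostatic; defaults to one output-grid step.
#' @return An object of class `response_metrics` (also a one-row list):
#'   `genotype`, `peak`, `time_of_peak`, `t_return`, `delta_t`,
#'   `terminal_level`, `classification`.
#' @export
compute_delta_t <- function(resp, wt, threshold = 0.2, delay_tol = NULL) {
  stopifnot(inherits(resp, "normalized_response"), inherits(wt, "normalized_response"))
  if (length(resp$times) != length(wt$times) ||
      max(abs(resp$times - wt$times)) > 1e-9) {
    stop("genotype and wild-type responses must share the same time grid",
         call. = FALSE)
  }
  if (is.null(delay_tol)) delay_tol <- diff(resp$times[1:2])
  wt_ret <- return_time(wt$times, wt$v_norm, threshold)
  if (is.na(wt_ret)) {
    stop("wild-type response never returns below the threshold within the ",
         "horizon; defaults must be re-examined", call. = FALSE)
  }
  m <- trace_metrics(resp$times, resp$v_norm, threshold)
  delta_t <- if (is.na(m$t_return)) NA_real_ else m$t_return - wt_ret
  classification <- if (is.na(m$t_return)) {
    "sustained"
  } else if (delta_t > delay_tol) {
    "delayed"
  } else {
    "homeostatic"
  }
  structure(
    list(
      genotype = resp$genotype,
      peak = m$peak,
      time_of_peak = m$time_of_peak,
      t_return = m$t_return,
      delta_t = delta_t,
      terminal_level = m$terminal_level,
      classification = classification
    ),
    class = "response_metrics"
  )
}

# internal: first grid time at/after the peak where the trace stays below
# threshold for the full remainder of the grid (brute contract: suffix max)
return_time <- function(times, v, threshold) {
  ipk <- which.max(v)
  suffix_max <- rev(cummax(rev(v)))
  idx <- which(seq_along(v) >= ipk & suffix_max < threshold)
  if (!length(idx)) NA_real_ else times[idx[1]]
}

# internal: raw trace observables
trace_metrics <- function(times, v, threshold) {
  ipk <- which.max(v)
  list(
    peak = v[ipk],
    time_of_peak = times[ipk],
    t_return = return_time(times, v, threshold),
    terminal_level = v[length(v)]
  )
}

#' Metrics for a set of genotypes under shipped defaults
#'
#' Simulates each genotype and the wild-type reference under a common
#' stimulus, normalizes to the wild-type peak and reduces each curve to
#' its [compute_delta_t()] metrics.
#'
#' @param genotypes Character vector of registered genotype names.
#' @param stimulus A [stimulus_spec()].
#' @param horizon Horizon in receptor lifetimes.
#' @param threshold Return threshold.
#' @param params Wild-type parameters.
#' @param n_out Output grid size.
#' @return Data frame with one row per genotype: peak, time_of_peak,
#'   t_return, delta_t, terminal_level, classification.
#' @export
genotype_metrics <- function(genotypes = names(builtin_genotypes()),
                             stimulus = stimulus_spec("step"),
                             horizon = 50, threshold = 0.2,
                             params = default_parameters(), n_out = 2001) {
  wt_tc <- simulate_genotype("wild-type", stimulus, horizon, params, n_out = n_out)
  wt_resp <- normalize_to_wildtype(wt_tc, wt_tc)
  rows <- lapply(genotypes, function(g) {
    tc <- if (g == "wild-type") wt_tc else simulate_genotype(g, stimulus, horizon, params, n_out = n_out)
    m <- compute_delta_t(normalize_to_wildtype(tc, wt_tc), wt_resp, threshold)
    data.frame(
      genotype = g, peak = m$peak, time_of_peak = m$time_of_peak,
      t_return = ifelse(is.na(m$t_return), NA_real_, m$t_return),
      delta_t = ifelse(is.na(m$delta_t), NA_real_, m$delta_t),
      terminal_level = m$terminal_level,
      classification = m$classification,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Scan the mirtron yield and locate the homeostatic switch
#'
#' Simulates the model over a grid of miR-1010 maturation yields
#' (`eta`), classifies each response against the wild-type (eta = 1)
#' reference, and reports the smallest grid yield at which the response
#' returns below the threshold within the horizon (`eta_star`). A
#' non-monotone classification pattern along the grid is reported, never
#' silently repaired.
#'
#' @param eta_grid Grid of yields in \[0, 1\], at least 11 points.
#' @param stimulus,horizon,threshold,params,n_out As in
#'   [genotype_metrics()].
#' @return List with `eta_star`, `monotone` (logical), and `table` (data
#'   frame of eta, classification, t_return, terminal_level).
#' @export
classify_switch <- function(eta_grid = seq(0, 1, length.out = 21),
                            stimulus = stimulus_spec("step"), horizon = 50,
                            threshold = 0.2, params = default_parameters(),
                            n_out = 2001) {
  stopifnot(length(eta_grid) >= 11, all(eta_grid >= 0 & eta_grid <= 1))
  eta_grid <- sort(eta_grid)
  wt_tc <- simulate_genotype("wild-type", stimulus, horizon, params, n_out = n_out)
  wt_resp <- normalize_to_wildtype(wt_tc, wt_tc)
  net0 <- build_default_network(params)
  rows <- lapply(eta_grid, function(e) {
    g <- genotype_perturbation(sprintf("eta=%g", e),
                               eta_scale = if (params[["eta"]] > 0) e / params[["eta"]] else 0)
    tc <- simulate_timecourse(apply_perturbation(net0, g), stimulus, horizon,
                              genotype = g$name, n_out = n_out)
    m <- compute_delta_t(normalize_to_wildtype(tc, wt_tc), wt_resp, threshold)
    data.frame(eta = e, classification = m$classification,
               t_return = ifelse(is.na(m$t_return), NA_real_, m$t_return),
               terminal_level = m$terminal_level, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  returning <- tab$classification != "sustained"
  eta_star <- if (any(returning)) tab$eta[which(returning)[1]] else NA_real_
  # monotone: sustained exactly on a prefix of the grid
  monotone <- !is.na(eta_star) && all(returning[tab$eta >= eta_star]) &&
    !any(returning[tab$eta < eta_star])
  list(eta_star = eta_star, monotone = monotone, table = tab)
}

#' Steady-state fold changes of the qPCR observables
#'
#' Computes, for each genotype, the stimulated steady state and reports
#' the fold change of each model observable relative to the wild-type
#' steady state. Observable map: `R` -> nAcRb2_mRNA, `St` ->
#' SKIP_transcript, `K` -> Shal, `M` -> miR-1010.
#'
#' @param genotypes Character vector of registered genotype names.
#' @param u Constant stimulus amplitude (a genotype's agonist gain
#'   multiplies it).
#' @param params Wild-type parameters.
#' @param registry Genotype registry.
#' @return Data frame with columns observable, condition, fold_change.
#' @export
steady_state_fold_changes <- function(genotypes = names(builtin_genotypes()),
                                      u = 1, params = default_parameters(),
                                      registry = builtin_genotypes()) {
  obs_map <- c(R = "nAcRb2_mRNA", St = "SKIP_transcript", K = "Shal", M = "miR-1010")
  net0 <- build_default_network(params)
  ss_of <- function(g) {
    # the genotype's agonist gain acts on u inside the network evaluation
    net <- apply_perturbation(net0, get_genotype(g, registry))
    s <- steady_state(net, stimulus_amplitude = u)
    if (!s$converged) {
      stop("steady state did not converge for genotype '", g, "' (residual ",
           format(s$residual), ")", call. = FALSE)
    }
    s$state
  }
  wt <- ss_of("wild-type")
  if (any(wt[names(obs_map)] < 1e-12)) {
    stop("wild-type steady state is degenerate (observable below 1e-12); ",
         "fold changes undefined", call. = FALSE)
  }
  rows <- lapply(genotypes, function(g) {
    s <- ss_of(g)
    data.frame(
      observable = unname(obs_map),
      condition = g,
      fold_change = unname(s[names(obs_map)] / wt[names(obs_map)]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
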