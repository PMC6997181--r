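#' Genotype or treatment as a parameter-level perturbation
#'
#' Every fly line and pharmacological treatment is encoded as a named
#' edit of the wild-type rate parameters; a perturbation never touches
#' species abundances directly.
#'
#' @param name Identifier.
#' @param eta_scale Multiplier on the miR-1010 maturation yield `eta`.
#' @param krep_scale Multiplier on the repression rate `k_rep` (0 removes
#'   the miRNA binding site).
#' @param skip_protein_functional If `FALSE`, zeroes the SKIP translation
#'   rate `k_Sp` only, leaving SKIP transcription and mirtron production
#'   intact (the MiMIC truncation).
#' @param extra_depolarization Additive constant in dV/dt (NaChBac).
#' @param leak_scale Multiplier on the potential leak rate `k_leak`
#'   (Kir2.1).
#' @param agonist_gain Multiplier on the stimulus amplitude (nicotine
#'   dose).
#' @return An object of class `genotype_perturbation`.
#' @export
genotype_perturbation <- function(name,
                                  eta_scale = 1,
                                  krep_scale = 1,
                                  skip_protein_functional = TRUE,
                                  extra_depolarization = 0,
                                  leak_scale = 1,
                                  agonist_gain = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(eta_scale, krep_scale, extra_depolarization, leak_scale, agonist_gain)) {
    if (!is.finite(v) || v < 0) {
      stop("perturbation multipliers must be finite and >= 0", call. = FALSE)
    }
  }
  structure(
    list(
      name = name,
      eta_scale = eta_scale,
      krep_scale = krep_scale,
      skip_protein_functional = isTRUE(skip_protein_functional),
      extra_depolarization = extra_depolarization,
      leak_scale = leak_scale,
      agonist_gain = agonist_gain
    ),
    class = "genotype_perturbation"
  )
}

#' Built-in genotype and treatment registry
#'
#' The fly lines and treatments of the study: wild type (identity),
#' homozygous and heterozygous miR-1010 deletions (mirtron yield 0 and
#' 0.5), the SKIP MiMIC protein-null (translation zeroed, transcription
#' and mirtron production preserved), the nAcRb2 3'UTR binding-site
#' mutant (repression removed, mirtron intact), NaChBac overexpression
#' (constitutive extra depolarization), Kir2.1 overexpression (increased
#' leak) and two nicotine doses (agonist gain).
#'
#' @return Named list of [genotype_perturbation()] objects.
#' @export
builtin_genotypes <- function() {
  gs <- list(
    genotype_perturbation("wild-type"),
    genotype_perturbation("miR-1010-null", eta_scale = 0),
    genotype_perturbation("miR-1010-het", eta_scale = 0.5),
    genotype_perturbation("SKIP-MiMIC", skip_protein_functional = FALSE),
    genotype_perturbation("nAcRb2-delta1010", krep_scale = 0),
    genotype_perturbation("NaChBac", extra_depolarization = 1),
    genotype_perturbation("Kir2.1", leak_scale = 3),
    genotype_perturbation("nicotine-low", agonist_gain = 2),
    genotype_perturbation("nicotine-high", agonist_gain = 4)
  )
  setNames(gs, vapply(gs, `[[`, "", "name"))
}

#' Look up a registered genotype by name
#'
#' @param name Genotype name.
#' @param registry Named list of perturbations, defaults to
#'   [builtin_genotypes()].
#' @return A `genotype_perturbation`.
#' @export
get_genotype <- function(name, registry = builtin_genotypes()) {
  if (!name %in% names(registry)) {
    stop("unknown genotype '", name, "'; registered: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  registry[[name]]
}

#' Apply a perturbation to a network
#'
#' Returns a new network whose parameters (and agonist gain) reflect the
#' perturbation; the input network is unmodified. Applying the identity
#' perturbation returns an equivalent network.
#'
#' @param network A `reaction_network`.
#' @param g A [genotype_perturbation()] or a registered genotype name.
#' @return A new `reaction_network`.
#' @export
apply_perturbation <- function(network, g) {
  if (is.character(g)) g <- get_genotype(g)
  stopifnot(inherits(g, "genotype_perturbation"))
  p <- network$parameters
  p[["eta"]] <- p[["eta"]] * g$eta_scale
  p[["k_rep"]] <- p[["k_rep"]] * g$krep_scale
  if (!g$skip_protein_functional) p[["k_Sp"]] <- 0
  p[["extra_depol"]] <- p[["extra_depol"]] + g$extra_depolarization
  p[["k_leak"]] <- p[["k_leak"]] * g$leak_scale
  out <- network
  out$parameters <- p
  out$agonist_gain <- network$agonist_gain * g$agonist_gain
  validate_network(out)
  out
}
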