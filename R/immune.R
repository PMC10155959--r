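#' Initial CTL clone size
#'
#' A new cognate CTL lineage starts at 2^n cells, n ~ Poisson(mu), modeling
#' the divisions the founder T cell underwent before thymic efflux.
#'
#' @param mu Poisson parameter (>= 0).
#' @param n number of clones to initialize.
#' @return numeric vector of integer powers of two.
#' @export
init_clone_size <- function(mu = 4, n = 1) {
  if (mu < 0) stop("mu must be nonnegative")
  2^stats::rpois(n, mu)
}

#' Clonal CTL expansion derivative
#'
#' dCTL_k/dt = CTL_k Td (C - 1) + ICB S_k Ta C. The first term is
#' homeostatic turnover tied to the shared nonspecific stimulus; the second
#' is antigen-driven influx, per capita in the antigen (the stimulus
#' available to each CTL decreases as clone size grows, which cancels the
#' clone size from the expansion term).
#'
#' @param ctl clone size (cells, >= 0).
#' @param S_k immunogenicity-weighted presented-cell count for the cognate
#'   neoantigen.
#' @param C nonspecific stimulus.
#' @param params an [immune_params()] object.
#' @return dCTL_k/dt (cells/day).
#' @export
clone_derivative <- function(ctl, S_k, C, params) {
  ag <- params$icb * S_k * params$Ta * C
  if (params$eq2_form == "massaction") ag <- ag * ctl
  ctl * params$Td * (C - 1) + ag
}

#' Tumor-ignorant CTL pool derivative
#'
#' dNSCTL/dt = NSCTL Td (C - 1): the pooled tumor-ignorant population only
#' responds to the shared nonspecific stimulus.
#'
#' @param nsctl pool size (cells).
#' @inheritParams clone_derivative
#' @return d(NSCTL)/dt (cells/day).
#' @export
nsctl_derivative <- function(nsctl, C, params) {
  nsctl * params$Td * (C - 1)
}

#' Nonspecific stimulus derivative
#'
#' dC/dt = kin - kin fout - kin (1 - fout) (NSCTL + sum CTL_k)/(ICB CTL_ss).
#' C is replenished at rate kin, consumed by non-CTLs (fraction fout) and by
#' all CTLs relative to the homeostatic population ICB * CTL_ss. C is clamped
#' at 0 during integration.
#'
#' @param total_ctl total CTL count, tumor-ignorant pool included (cells).
#' @param params an [immune_params()] object.
#' @return dC/dt (1/day).
#' @export
stimulus_derivative <- function(total_ctl, params) {
  params$kin - params$kin * params$fout -
    params$kin * (1 - params$fout) * total_ctl / (params$icb * params$CTL_ss)
}

#' Tumor-reactive CTL fraction for a lineage
#'
#' phi = sum_k CTL_k / (NSCTL + sum_k CTL_k), the sum running over the
#' neoantigens in the lineage's immunopeptidome (expressed with intact
#' presenting allele). Defined as 0 when the denominator vanishes.
#'
#' @param reactive summed cognate CTL cells for the lineage's peptidome.
#' @param nsctl tumor-ignorant pool size.
#' @return phi in [0, 1].
#' @export
reactive_fraction <- function(reactive, nsctl) {
  den <- nsctl + reactive
  ifelse(den > 0, reactive / den, 0)
}

# saturable killing kernel h(x), x = phi * k_kill
killing_kernel <- function(x, form = "ratio2") {
  switch(form,
         ratio2 = x / (1 + x^2),
         hill1 = x / (1 + x),
         hill2 = x^2 / (1 + x^2),
         stop("unknown killing_form: ", form))
}

#' Lineage-specific death rate
#'
#' kd_i = fdie + (k_mag + 1 - fdie) h(phi k_kill) with the saturable kernel
#' h(x) = x/(1 + x^2) by default. At phi = 0 only natural turnover fdie
#' remains; with k_mag = 1 the rate can exceed 1, allowing shrinkage, which
#' under the default parameters requires tumor-reactive CTLs to outnumber
#' tumor-ignorant CTLs roughly 3:1 (phi > ~0.75).
#'
#' @param phi tumor-reactive CTL fraction in [0, 1].
#' @param params an [immune_params()] object; `fdie` is taken from `tumor`.
#' @param fdie fraction of deaths not attributed to CTL killing.
#' @return kd_i >= 0.
#' @export
lineage_death_rate <- function(phi, params, fdie = 0.3) {
  x <- phi * params$k_kill
  fdie + (params$k_mag + 1 - fdie) * killing_kernel(x, params$killing_form)
}

#' Shannon entropy of the tumor-reactive TCR repertoire
#'
#' H = -sum p_k log p_k (nats) on clone frequencies p_k = size_k / sum sizes.
#' `mode = "wentropy"` instead returns the unnormalized -sum x^2 log x^2 on
#' the raw sizes (the MATLAB wentropy convention; scale-dependent, provided
#' for auditability only).
#'
#' @param sizes clone sizes (at least one positive).
#' @param mode `"shannon"` (default) or `"wentropy"`.
#' @return entropy (nats).
#' @export
tcr_entropy <- function(sizes, mode = c("shannon", "wentropy")) {
  mode <- match.arg(mode)
  sizes <- sizes[sizes > 0]
  if (!length(sizes)) stop("all clone sizes are zero")
  if (mode == "wentropy") return(-sum(sizes^2 * log(sizes^2)))
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}
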