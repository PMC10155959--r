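#' Neoantigen feature distribution parameters
#'
#' Parameters of the fitted distributions from which neoantigen feature
#' vectors are sampled: a Gaussian copula over (log MHC binding affinity,
#' log MHC binding stability, log agretopicity), an exponential transcript
#' abundance, a zero- and one-inflated beta foreignness, and a truncated
#' exponential for the intrinsic immunogenicity score R.
#'
#' The copula correlation matrix, inflation masses, beta shapes and the
#' exponential parameters are taken from fits to 146 NSCLC-derived TESLA
#' peptides. The three log-scale marginals coupled by the copula were not
#' published; the defaults below are log-normal with medians and spreads
#' typical of bioinformatically shortlisted candidate neoantigens (strong
#' predicted binders: affinity median 40 nM, stability median 1 h,
#' agretopicity median 1). Jointly with the copula and the foreignness
#' model they give a TESLA pass fraction of ~18%, i.e. a handful of bona
#' fide immunogenic clonal neoantigens for a median founder burden, and
#' they reproduce the reported scale of checkpoint-blockade response rates
#' in the virtual cohorts. They are fully configurable.
#'
#' @param rho 3x3 copula correlation matrix, order (affinity, stability,
#'   agretopicity) on the log scale.
#' @param lambda rate of the exponential transcript-abundance distribution
#'   (rate parameterization: mean = 1/lambda).
#' @param phat1 probability mass at foreignness exactly 0 (zero inflation).
#' @param phat2 probability mass at foreignness > 0.99 (one inflation,
#'   emitted as exactly 1).
#' @param alpha,beta shape parameters of the interior beta component of
#'   foreignness.
#' @param epsilon rate of the truncated-exponential immunogenicity density
#'   on [0, 1].
#' @param marginal_affinity,marginal_stability,marginal_agretopicity lists
#'   `list(meanlog=, sdlog=)` describing log-normal marginals (affinity in
#'   nM, stability in hours, agretopicity dimensionless).
#' @return object of class `tesla_feature_params`.
#' @export
tesla_feature_params <- function(rho = default_rho(),
                                 lambda = 6.6625,
                                 phat1 = 0.7603,
                                 phat2 = 0.0685,
                                 alpha = 0.0597,
                                 beta = 1.4404,
                                 epsilon = 6,
                                 marginal_affinity = list(meanlog = log(40), sdlog = 1.5),
                                 marginal_stability = list(meanlog = log(1), sdlog = 1.2),
                                 marginal_agretopicity = list(meanlog = 0, sdlog = 1.2)) {
  rho <- as.matrix(rho)
  if (!isTRUE(all.equal(dim(rho), c(3L, 3L))))
    stop("rho must be a 3x3 matrix")
  if (max(abs(rho - t(rho))) > 1e-12 || any(abs(diag(rho) - 1) > 1e-12))
    stop("rho must be symmetric with unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("rho must be positive definite")
  if (phat1 < 0 || phat2 < 0 || phat1 > 1 || phat2 > 1 || phat1 + phat2 > 1)
    stop("phat1, phat2 must lie in [0,1] with phat1 + phat2 <= 1")
  if (alpha <= 0 || beta <= 0 || lambda <= 0 || epsilon <= 0)
    stop("alpha, beta, lambda, epsilon must be positive")
  structure(list(rho = rho, lambda = lambda, phat1 = phat1, phat2 = phat2,
                 alpha = alpha, beta = beta, epsilon = epsilon,
                 marginal_affinity = marginal_affinity,
                 marginal_stability = marginal_stability,
                 marginal_agretopicity = marginal_agretopicity),
            class = "tesla_feature_params")
}

#' @rdname tesla_feature_params
#' @export
default_rho <- function() {
  matrix(c(1, -0.3495, -0.930,
           -0.3495, 1, 0.2041,
           -0.930, 0.2041, 1), 3, 3, byrow = TRUE,
         dimnames = list(c("affinity", "stability", "agretopicity"),
                         c("affinity", "stability", "agretopicity")))
}

#' TESLA immunogenicity criteria
#'
#' Threshold set separating putatively immunogenic from non-immunogenic
#' neoantigens. All comparisons are strict, and a neoantigen must satisfy all
#' four to pass: affinity < `affinity_max_nM`, stability > `stability_min_h`,
#' agretopicity > `agretopicity_min`, and foreignness below (or above, per
#' `foreignness_direction`) `foreignness_cutoff`. Transcript abundance is not
#' assessed (it conflates with clonality).
#'
#' @param affinity_max_nM maximum MHC binding affinity (nM; lower = stronger).
#' @param stability_min_h minimum MHC binding stability (hours).
#' @param agretopicity_min minimum mutant/wild-type affinity ratio.
#' @param foreignness_cutoff foreignness threshold.
#' @param foreignness_direction `"below"` (pass if foreignness < cutoff, as
#'   used here) or `"above"` (pass if > cutoff, the convention of the original
#'   TESLA analysis).
#' @return object of class `tesla_criteria`.
#' @export
tesla_criteria <- function(affinity_max_nM = 34,
                           stability_min_h = 1.4,
                           agretopicity_min = 0.1,
                           foreignness_cutoff = 1e-16,
                           foreignness_direction = c("below", "above")) {
  foreignness_direction <- match.arg(foreignness_direction)
  thr <- c(affinity_max_nM, stability_min_h, agretopicity_min, foreignness_cutoff)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all thresholds must be finite and positive")
  structure(list(affinity_max_nM = affinity_max_nM,
                 stability_min_h = stability_min_h,
                 agretopicity_min = agretopicity_min,
                 foreignness_cutoff = foreignness_cutoff,
                 foreignness_direction = foreignness_direction),
            class = "tesla_criteria")
}

#' Tumor compartment parameters
#'
#' @param kg crude birth rate of cancer cells (1/day).
#' @param fdie fraction of cancer cell deaths not attributed to the immune
#'   system (dimensionless).
#' @param cellVol approximate cancer cell volume (cm^3).
#' @param K carrying capacity (cells).
#' @param nG base neoantigen gain rate (per cell per day). Note the source
#'   table prints 2.5e+9/day, inconsistent with the loss rate and the ~33%
#'   expressed fraction; the corrected per-cell rate 2.5e-9 is used.
#' @param nGS log standard deviation of the per-tumor base gain rate
#'   (log-normal, ln scale; 2.303 = one decade).
#' @param nGSt log standard deviation of the day-to-day gain-rate jitter.
#' @param nL neoantigen loss rate (per cell per day).
#' @param hlaL MHC allele loss rate (per cell per day).
#' @param hlaL0 probability that the founder cell carries a clonal MHC loss.
#' @param n_mhc_alleles number of MHC alleles (2 mouse, 3 human).
#' @param g1,g2 shape and scale of the gamma distribution of founder clonal
#'   neoantigen burden.
#' @param gain_rate_convention `"median"` (mu = ln nG, the default) or
#'   `"mean"` preserving log-normal convention for the base gain rate.
#' @param extinction_threshold lineages with fewer cells are removed from the
#'   dynamics (cells).
#' @return object of class `tumor_params`.
#' @export
tumor_params <- function(kg = 0.02, fdie = 0.3, cellVol = 4.19e-9,
                         K = 5e11, nG = 2.5e-9, nGS = 2.303, nGSt = 2.303,
                         nL = 1.68e-9, hlaL = 1.68e-9, hlaL0 = 0.14,
                         n_mhc_alleles = 3L, g1 = 1.14, g2 = 56.24,
                         gain_rate_convention = c("median", "mean"),
                         extinction_threshold = 0.5) {
  gain_rate_convention <- match.arg(gain_rate_convention)
  if (kg <= 0 || K <= 0 || cellVol <= 0) stop("kg, K, cellVol must be positive")
  if (fdie < 0 || fdie > 1) stop("fdie must lie in [0,1]")
  if (any(c(nG, nGS, nGSt, nL, hlaL) < 0)) stop("rates must be nonnegative")
  if (hlaL0 < 0 || hlaL0 > 1) stop("hlaL0 must lie in [0,1]")
  if (g1 <= 0 || g2 < 0) stop("g1 must be positive, g2 nonnegative")
  structure(list(kg = kg, fdie = fdie, cellVol = cellVol, K = K,
                 nG = nG, nGS = nGS, nGSt = nGSt, nL = nL, hlaL = hlaL,
                 hlaL0 = hlaL0, n_mhc_alleles = as.integer(n_mhc_alleles),
                 g1 = g1, g2 = g2,
                 gain_rate_convention = gain_rate_convention,
                 extinction_threshold = extinction_threshold),
            class = "tumor_params")
}

#' Immune compartment parameters
#'
#' @param C0 initial nonspecific stimulus (dimensionless).
#' @param kin fractional turnover of the nonspecific stimulus (1/day).
#' @param fout fraction of stimulus consumption not attributable to CTLs.
#' @param CTL_ss steady-state T-cell population (cells).
#' @param TCR_other baseline tumor-ignorant T cells (cells). The pooled
#'   tumor-ignorant population is initialized to `TCR_other` minus the summed
#'   initial sizes of the antigen-specific clones, so that total CTLs start
#'   exactly at homeostasis.
#' @param Td naive T-cell fractional turnover (1/day).
#' @param mu Poisson parameter for the number of divisions before thymic
#'   efflux (initial clone size is 2^n, n ~ Poisson(mu)).
#' @param Ta scaling factor for clonal expansion per unit of antigen stimulus.
#' @param k_kill,k_mag shape parameters of the saturable killing function.
#' @param killing_form functional form of the saturable killing term h(x)
#'   with x = phi * k_kill: `"ratio2"` (default) h = x/(1+x^2), `"hill1"`
#'   h = x/(1+x), `"hill2"` h = x^2/(1+x^2).
#' @param eq2_form parse of the clonal-expansion equation: `"percapita"`
#'   (default) dCTL = CTL*Td*(C-1) + ICB*S*Ta*C, i.e. a per-capita antigen
#'   term S*Ta*C/CTL multiplied back by CTL; `"massaction"` multiplies the
#'   antigen term by CTL as well.
#' @param icb treatment multiplier (>= 1); scales both the antigen
#'   sensitivity term and the CTL carrying capacity.
#' @return object of class `immune_params`.
#' @export
immune_params <- function(C0 = 1, kin = 0.01, fout = 0.3,
                          CTL_ss = 1e11, TCR_other = 1e11,
                          Td = 0.05, mu = 4, Ta = 3e-2,
                          k_kill = 0.7, k_mag = 1,
                          killing_form = c("ratio2", "hill1", "hill2"),
                          eq2_form = c("percapita", "massaction"),
                          icb = 1) {
  killing_form <- match.arg(killing_form)
  eq2_form <- match.arg(eq2_form)
  if (any(c(C0, kin, CTL_ss, TCR_other, Td, Ta, k_kill, k_mag) < 0))
    stop("immune parameters must be nonnegative")
  if (fout < 0 || fout > 1) stop("fout must lie in [0,1]")
  if (mu < 0) stop("mu must be nonnegative")
  if (icb < 1) stop("icb must be >= 1")
  structure(list(C0 = C0, kin = kin, fout = fout, CTL_ss = CTL_ss,
                 TCR_other = TCR_other, Td = Td, mu = mu, Ta = Ta,
                 k_kill = k_kill, k_mag = k_mag,
                 killing_form = killing_form, eq2_form = eq2_form, icb = icb),
            class = "immune_params")
}

#' Species and histology presets
#'
#' Bundles tumor, immune and neoantigen parameters for the simulated
#' conditions:
#' \describe{
#'   \item{mouse_nsg}{immunodeficient mouse; no CTL expansion or killing
#'     (death rate identically fdie); fixed immunopeptidome.}
#'   \item{mouse_c57bl6}{immunocompetent mouse; CTL dynamics active; fixed
#'     immunopeptidome.}
#'   \item{mc38_immunodeficient, mc38_immunocompetent}{as the mouse presets
#'     with 50\% higher growth rate.}
#'   \item{human_nsclc}{human parameters; stochastic gain/loss/MHC-loss
#'     events enabled.}
#'   \item{rcc_like}{human with 50\% lower growth rate and 90\% lower gain,
#'     loss and MHC loss rates.}
#'   \item{msi_like}{human with 100\% higher growth rate and 200\% higher
#'     clonal neoantigen burden (gamma scale tripled).}
#' }
#'
#' @param name preset name.
#' @param overrides named list of parameter overrides keyed by the canonical
#'   config symbols (see [apply_config()]), applied after preset adjustments.
#' @return object of class `ip_preset`: list with elements `name`, `species`,
#'   `tumor`, `immune`, `features`, `criteria`, `immunodeficient`,
#'   `events_enabled`, `founder_cells`.
#' @export
preset <- function(name = c("human_nsclc", "rcc_like", "msi_like",
                            "mouse_nsg", "mouse_c57bl6",
                            "mc38_immunodeficient", "mc38_immunocompetent"),
                   overrides = NULL) {
  name <- match.arg(name)
  mouse <- grepl("^mouse|^mc38", name)
  if (mouse) {
    tum <- tumor_params(kg = 0.2, K = 7e8, nG = 0, nGS = 0, nGSt = 0,
                        nL = 0, hlaL = 0, hlaL0 = 0, n_mhc_alleles = 2L)
    imm <- immune_params(kin = 0.4, CTL_ss = 1e8, TCR_other = 1e8,
                         Td = 0.0333, Ta = 3e-3)
    founder_cells <- 4.77e7
  } else {
    tum <- tumor_params()
    imm <- immune_params()
    founder_cells <- 1
  }
  if (grepl("^mc38", name)) tum$kg <- tum$kg * 1.5
  if (name == "rcc_like") {
    tum$kg <- tum$kg * 0.5
    tum$nG <- tum$nG * 0.1; tum$nL <- tum$nL * 0.1; tum$hlaL <- tum$hlaL * 0.1
  }
  if (name == "msi_like") {
    tum$kg <- tum$kg * 2
    tum$g2 <- tum$g2 * 3
  }
  p <- structure(list(name = name,
                      species = if (mouse) "mouse" else "human",
                      tumor = tum, immune = imm,
                      features = tesla_feature_params(),
                      criteria = tesla_criteria(),
                      immunodeficient = name %in% c("mouse_nsg", "mc38_immunodeficient"),
                      events_enabled = !mouse,
                      founder_cells = founder_cells),
                 class = "ip_preset")
  if (!is.null(overrides)) p <- apply_config(p, overrides)
  p
}

#' @exportS3Method base::print
print.ip_preset <- function(x, ...) {
  cat("<ip_preset>", x$name, "\n")
  cat("  species:", x$species,
      if (x$immunodeficient) "(immunodeficient)" else "(immunocompetent)", "\n")
  cat("  events:", if (x$events_enabled) "enabled" else "disabled", "\n")
  cat(sprintf("  tumor: kg=%.3g /day, K=%.3g cells, fdie=%.2f\n",
              x$tumor$kg, x$tumor$K, x$tumor$fdie))
  cat(sprintf("  immune: CTL_ss=%.3g, Td=%.3g /day, Ta=%.3g, icb=%g\n",
              x$immune$CTL_ss, x$immune$Td, x$immune$Ta, x$immune$icb))
  invisible(x)
}

# canonical config symbols -> (component, field)
config_symbol_map <- function() {
  list(
    kg = c("tumor", "kg"), f_die = c("tumor", "fdie"),
    cellVol = c("tumor", "cellVol"), K = c("tumor", "K"),
    nG = c("tumor", "nG"), nGS = c("tumor", "nGS"), nGSt = c("tumor", "nGSt"),
    g_1 = c("tumor", "g1"), g_2 = c("tumor", "g2"),
    nL = c("tumor", "nL"), hlaL = c("tumor", "hlaL"), hlaL0 = c("tumor", "hlaL0"),
    n_mhc_alleles = c("tumor", "n_mhc_alleles"),
    extinction_threshold = c("tumor", "extinction_threshold"),
    gain_rate_convention = c("tumor", "gain_rate_convention"),
    C = c("immune", "C0"), k_in = c("immune", "kin"), f_out = c("immune", "fout"),
    T_ss = c("immune", "CTL_ss"), TCR_other = c("immune", "TCR_other"),
    T_d = c("immune", "Td"), mu = c("immune", "mu"), T_a = c("immune", "Ta"),
    k_kill = c("immune", "k_kill"), k_max = c("immune", "k_mag"),
    killing_form = c("immune", "killing_form"), eq2_form = c("immune", "eq2_form"),
    ICB = c("immune", "icb"),
    rho = c("features", "rho"), lambda = c("features", "lambda"),
    phat_1 = c("features", "phat1"), phat_2 = c("features", "phat2"),
    alpha = c("features", "alpha"), beta = c("features", "beta"),
    epsilon = c("features", "epsilon"),
    marginal_affinity = c("features", "marginal_affinity"),
    marginal_stability = c("features", "marginal_stability"),
    marginal_agretopicity = c("features", "marginal_agretopicity"),
    affinity_max_nM = c("criteria", "affinity_max_nM"),
    stability_min_h = c("criteria", "stability_min_h"),
    agretopicity_min = c("criteria", "agretopicity_min"),
    foreignness_cutoff = c("criteria", "foreignness_cutoff"),
    foreignness_direction = c("criteria", "foreignness_direction"),
    founder_cells = c(".", "founder_cells")
  )
}

#' Apply configuration overrides to a preset
#'
#' Overrides are keyed by the canonical parameter symbols (`kg`, `f_die`,
#' `cellVol`, `K`, `nG`, `nGS`, `nGSt`, `g_1`, `g_2`, `nL`, `hlaL`, `hlaL0`,
#' `k_in`, `f_out`, `T_ss`, `TCR_other`, `T_d`, `mu`, `T_a`, `k_kill`,
#' `k_max`, `ICB`, `rho`, `lambda`, `phat_1`, `phat_2`, `alpha`, `beta`,
#' `epsilon`, ...) so a configuration file can be audited directly against
#' the published parameter table. Unknown keys are rejected with the nearest
#' valid symbol suggested.
#'
#' @param preset an [preset()] object.
#' @param overrides named list of values.
#' @return the modified preset (re-validated).
#' @export
apply_config <- function(preset, overrides) {
  stopifnot(inherits(preset, "ip_preset"))
  if (length(overrides) == 0) return(preset)
  map <- config_symbol_map()
  keys <- names(overrides)
  if (is.null(keys) || any(keys == ""))
    stop("overrides must be a fully named list")
  for (key in keys) {
    if (!key %in% names(map)) {
      near <- agrep(key, names(map), max.distance = 2, value = TRUE,
                    ignore.case = TRUE)
      stop(sprintf("unknown config key '%s'%s", key,
                   if (length(near)) paste0("; did you mean '", near[1], "'?") else ""))
    }
    loc <- map[[key]]
    val <- overrides[[key]]
    if (loc[1] == ".") preset[[loc[2]]] <- val
    else preset[[loc[1]]][[loc[2]]] <- val
  }
  # re-validate through the constructors
  preset$tumor <- do.call(tumor_params, unclass(preset$tumor))
  preset$immune <- do.call(immune_params, unclass(preset$immune))
  preset$features <- do.call(tesla_feature_params, unclass(preset$features))
  preset$criteria <- do.call(tesla_criteria, unclass(preset$criteria))
  preset
}

#' Read or write a run configuration (YAML)
#'
#' Config files hold a preset name plus overrides keyed by the canonical
#' parameter symbols; [read_config()] validates keys on read.
#'
#' @param path file path.
#' @param config list with elements `preset` and (optionally) `overrides`,
#'   `seed`, `schedule`.
#' @return `read_config` returns the validated list; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || length(cfg) == 0) stop("empty config file: ", path)
  if (!is.null(cfg$overrides)) {
    if (!is.null(cfg$overrides$rho)) cfg$overrides$rho <- matrix(unlist(cfg$overrides$rho), 3, 3)
    # validate keys against a base preset
    invisible(preset(cfg$preset %||% "human_nsclc", overrides = cfg$overrides))
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (!is.null(config$overrides$rho))
    config$overrides$rho <- apply(config$overrides$rho, 1, as.list)
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
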