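#' Sample neoantigen feature vectors
#'
#' Draws `n` feature vectors (MHC binding affinity in nM, binding stability
#' in hours, agretopicity, transcript abundance, foreignness). Dependence
#' among log-affinity, log-stability and log-agretopicity follows the
#' Gaussian copula `params$rho` applied to log-normal marginals; transcript
#' abundance is an independent exponential draw (rate `lambda`); foreignness
#' comes from the zero- and one-inflated beta model ([sample_foreignness()]).
#'
#' @param n number of neoantigens (>= 0).
#' @param params a [tesla_feature_params()] object.
#' @return data.frame with columns `affinity_nM`, `stability_h`,
#'   `agretopicity`, `tpm`, `foreignness`.
#' @export
sample_features <- function(n, params = tesla_feature_params()) {
  stopifnot(inherits(params, "tesla_feature_params"))
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be a nonnegative count")
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(affinity_nM = numeric(0), stability_h = numeric(0),
                      agretopicity = numeric(0), tpm = numeric(0),
                      foreignness = numeric(0)))
  }
  Lc <- chol(params$rho)
  z <- matrix(stats::rnorm(3L * n), n, 3L) %*% Lc
  u <- stats::pnorm(z)
  data.frame(
    affinity_nM = stats::qlnorm(u[, 1], params$marginal_affinity$meanlog,
                                params$marginal_affinity$sdlog),
    stability_h = stats::qlnorm(u[, 2], params$marginal_stability$meanlog,
                                params$marginal_stability$sdlog),
    agretopicity = stats::qlnorm(u[, 3], params$marginal_agretopicity$meanlog,
                                 params$marginal_agretopicity$sdlog),
    tpm = stats::rexp(n, rate = params$lambda),
    foreignness = sample_foreignness(n, params)
  )
}

#' Sample foreignness values
#'
#' Zero- and one-inflated beta mixture: each draw is exactly 0 with
#' probability `phat1`, exactly 1 ("> 0.99", one-inflated) with probability
#' `phat2`, and otherwise Beta(alpha, beta).
#'
#' @inheritParams sample_features
#' @return numeric vector in [0, 1].
#' @export
sample_foreignness <- function(n, params = tesla_feature_params()) {
  stopifnot(inherits(params, "tesla_feature_params"))
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be a nonnegative count")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  comp <- stats::runif(n)
  out <- numeric(n)
  one <- comp >= params$phat1 & comp < params$phat1 + params$phat2
  mid <- comp >= params$phat1 + params$phat2
  out[one] <- 1
  nm <- sum(mid)
  if (nm) out[mid] <- stats::rbeta(nm, params$alpha, params$beta)
  out
}

#' Apply the TESLA criteria to a feature table
#'
#' All four comparisons are strict; transcript abundance is not assessed.
#'
#' @param features data.frame with columns `affinity_nM`, `stability_h`,
#'   `agretopicity`, `foreignness`.
#' @param criteria a [tesla_criteria()] object.
#' @return logical vector: TRUE where all four criteria pass.
#' @export
passes_tesla <- function(features, criteria = tesla_criteria()) {
  stopifnot(inherits(criteria, "tesla_criteria"))
  need <- c("affinity_nM", "stability_h", "agretopicity", "foreignness")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  fpass <- if (criteria$foreignness_direction == "below")
    features$foreignness < criteria$foreignness_cutoff
  else
    features$foreignness > criteria$foreignness_cutoff
  features$affinity_nM < criteria$affinity_max_nM &
    features$stability_h > criteria$stability_min_h &
    features$agretopicity > criteria$agretopicity_min &
    fpass
}

#' Assign intrinsic immunogenicity scores
#'
#' Failing neoantigens get R = 0. Passing neoantigens draw R from the
#' truncated exponential density proportional to exp(-epsilon * x) on [0, 1],
#' sampled exactly by inverse CDF:
#' F^{-1}(u) = -log(1 - u (1 - e^{-eps})) / eps.
#'
#' @param pass_flags logical vector from [passes_tesla()].
#' @param epsilon truncation-free exponential rate (> 0).
#' @return numeric vector of R values; 0 or in (0, 1].
#' @export
assign_immunogenicity <- function(pass_flags, epsilon = 6) {
  if (epsilon <= 0) stop("epsilon must be positive")
  r <- numeric(length(pass_flags))
  np <- sum(pass_flags)
  if (np) r[pass_flags] <- rtruncexp(np, epsilon)
  r
}

# inverse-CDF sampler for density ~ exp(-eps x) on [0,1]
rtruncexp <- function(n, eps) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-eps))) / eps
}

# analytic CDF of the truncated exponential on [0,1]
ptruncexp <- function(q, eps) {
  p <- (1 - exp(-eps * q)) / (1 - exp(-eps))
  pmin(pmax(p, 0), 1)
}

#' Sample a founder clonal neoantigen burden
#'
#' Gamma(shape = g1, scale = g2) rounded to the nearest integer. With
#' `round = FALSE` the raw gamma draw is returned (useful for checking the
#' configured distribution itself).
#'
#' @param n number of draws.
#' @param g1 gamma shape (> 0).
#' @param g2 gamma scale (>= 0).
#' @param round round to nearest nonnegative integer (default TRUE).
#' @return numeric vector.
#' @export
sample_founder_clonal_burden <- function(n = 1, g1 = 1.14, g2 = 56.24,
                                         round = TRUE) {
  if (g1 <= 0 || g2 < 0) stop("g1 must be positive, g2 nonnegative")
  x <- if (g2 == 0) numeric(n) else stats::rgamma(n, shape = g1, scale = g2)
  if (round) floor(x + 0.5) else x
}

#' Scale ELISpot scores to immunogenicity
#'
#' Min-max scaling of baseline-corrected ELISpot scores to [0, 1]. A
#' constant vector (no spread, hence no evidence of immunogenicity
#' differences) maps to all zeros.
#'
#' @param scores nonnegative numeric vector (at least one value).
#' @return numeric vector of R values in [0, 1].
#' @export
elispot_to_immunogenicity <- function(scores) {
  if (length(scores) < 1) stop("at least one score is required")
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("scores must be finite and nonnegative")
  rng <- range(scores)
  if (rng[2] - rng[1] == 0) return(numeric(length(scores)))
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Create a panel of neoantigens
#'
#' Composes feature sampling, TESLA filtering, immunogenicity assignment and
#' uniform MHC allele assignment into a neoantigen table.
#'
#' @param n number of neoantigens.
#' @param n_alleles number of host MHC alleles (2 mouse, 3 human; other
#'   values are allowed with a warning, for experimentation).
#' @param params a [tesla_feature_params()] object.
#' @param criteria a [tesla_criteria()] object.
#' @param id_start first id (ids are unique and monotone increasing).
#' @return data.frame with columns `id`, `R`, `mhc_allele` (0-based),
#'   `origin`, plus the five feature columns.
#' @export
make_neoantigens <- function(n, n_alleles = 3L,
                             params = tesla_feature_params(),
                             criteria = tesla_criteria(),
                             id_start = 1L) {
  if (!n_alleles %in% c(2L, 3L))
    warning("n_alleles outside {2, 3}; proceeding (experimental host)")
  n <- as.integer(n)
  feats <- sample_features(n, params)
  pass <- passes_tesla(feats, criteria)
  r <- assign_immunogenicity(pass, params$epsilon)
  allele <- if (n > 0) sample.int(n_alleles, n, replace = TRUE) - 1L else integer(0)
  cbind(data.frame(id = seq_len(n) + id_start - 1L, R = r,
                   mhc_allele = allele,
                   origin = rep("founder", n), stringsAsFactors = FALSE),
        feats)
}

#' Re-fit a Gaussian copula correlation from a sample
#'
#' Normal-scores (van der Waerden) estimator: ranks are mapped through the
#' standard normal quantile function and the Pearson correlation of the
#' scores is returned. This recovers the copula correlation matrix without
#' knowledge of the marginals.
#'
#' @param x numeric matrix or data.frame (observations x variables).
#' @return correlation matrix.
#' @export
fit_gaussian_copula <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  z <- apply(x, 2, function(col) stats::qnorm(rank(col) / (n + 1)))
  stats::cor(z)
}
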