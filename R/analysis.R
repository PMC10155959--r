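#' Maximal tumor shrinkage and RECIST-style response classification
#'
#' Shrinkage is the maximum over on-treatment days of (x0 - x(t))/x0, where
#' x0 is the tumor burden at treatment start. The default basis is volume
#' (equivalently, cell count): under the model's saturable killing function
#' the death rate is bounded at kd ~ 1.1, so diameter can shrink at most
#' ~20\% in a one-year treatment and the 30\% response threshold is only
#' meaningful on the volume scale on which tumor burden is simulated.
#' `basis = "diameter"` gives the strict RECIST 1.1 measurement. Negative
#' values indicate net growth. A tumor is a responder when maximal shrinkage
#' is at least 30\% (boundary inclusive).
#'
#' @param traj treatment trajectory data.frame with columns `day` and
#'   `diameter_cm` (day 0 = baseline), or a numeric diameter vector whose
#'   first element is baseline.
#' @param basis `"volume"` (default) or `"diameter"`.
#' @return `max_shrinkage`: signed fraction; `classify_response`: logical.
#' @export
max_shrinkage <- function(traj, basis = c("volume", "diameter")) {
  basis <- match.arg(basis)
  d <- if (is.data.frame(traj)) traj$diameter_cm else as.numeric(traj)
  if (length(d) < 2) stop("trajectory must contain a baseline and at least one on-treatment day")
  if (basis == "volume") d <- d^3
  d0 <- d[1]
  max((d0 - d[-1]) / d0)
}

#' @rdname max_shrinkage
#' @param x signed shrinkage fraction.
#' @export
classify_response <- function(x) {
  !is.na(x) & x >= 0.30
}

#' Rank-1 neoantigen metrics
#'
#' The rank-1 neoantigen is the most immunogenic one (highest R; ties broken
#' by higher clonality, then lower id). Clonality is the fraction of living
#' tumor cells presenting it; the clonality-weighted immunogenicity is the
#' product of the two. When no neoantigen has R > 0, all metrics are 0 and
#' `degenerate` is TRUE.
#'
#' @param sim an `ip_sim` (or a `tumor_state`).
#' @return list: `id`, `R`, `clonality`, `product`, `degenerate`.
#' @export
rank1_metrics <- function(sim) {
  state <- if (inherits(sim, "ip_sim")) sim$tumor else sim
  tot <- sum(state$N)
  R <- state$R
  if (!length(R) || max(R) <= 0 || tot <= 0)
    return(list(id = NA_integer_, R = 0, clonality = 0, product = 0,
                degenerate = TRUE))
  pc <- presented_cells(state)
  clon <- pc$raw / tot
  best <- which(R == max(R))
  if (length(best) > 1) {
    best <- best[clon[best] == max(clon[best])]
    best <- best[1]  # lowest id among remaining ties
  }
  list(id = best, R = R[best], clonality = clon[best],
       product = R[best] * clon[best], degenerate = FALSE)
}

#' Single-threshold biomarker sensitivity and specificity
#'
#' Chooses the threshold maximizing Youden's J = sensitivity + specificity -
#' 1 over the observed metric values (both classification directions are
#' tried) and returns the correctly classified fractions of responders and
#' non-responders at that threshold.
#'
#' @param metric numeric biomarker vector.
#' @param responder logical labels.
#' @return list: `sensitivity`, `specificity`, `threshold`, `direction`
#'   (">=" means metric >= threshold predicts responder), `youden`.
#' @export
biomarker_sens_spec <- function(metric, responder) {
  if (length(metric) != length(responder)) stop("length mismatch")
  responder <- as.logical(responder)
  if (all(responder) || !any(responder))
    stop("both responders and non-responders are required")
  cand <- sort(unique(metric))
  best <- list(youden = -Inf)
  for (thr in cand) {
    for (dir in c(">=", "<=")) {
      pred <- if (dir == ">=") metric >= thr else metric <= thr
      sens <- mean(pred[responder])
      spec <- mean(!pred[!responder])
      J <- sens + spec - 1
      if (J > best$youden)
        best <- list(sensitivity = sens, specificity = spec, threshold = thr,
                     direction = dir, youden = J)
    }
  }
  best
}

#' Shannon entropy of the immunopeptidome
#'
#' H = -sum w_k log w_k (nats) over presented-cell weights
#' w_k = raw_k / sum raw (the number of cells presenting neoantigen k).
#' `weighting = "lineage"` instead weights each presented neoantigen by the
#' number of living lineages carrying it.
#'
#' @param sim an `ip_sim` or `tumor_state`.
#' @param weighting `"cells"` (default) or `"lineage"`.
#' @return entropy (nats).
#' @export
immunopeptidome_entropy <- function(sim, weighting = c("cells", "lineage")) {
  weighting <- match.arg(weighting)
  state <- if (inherits(sim, "ip_sim")) sim$tumor else sim
  if (weighting == "cells") {
    w <- presented_cells(state)$raw
  } else {
    M <- nrow(state$registry)
    w <- numeric(M)
    for (i in which(state$N >= 1)) {
      p <- lineage_peptidome(state, i)
      if (length(p)) w[p] <- w[p] + 1
    }
  }
  w <- w[w > 0]
  if (!length(w)) stop("no presented neoantigen")
  p <- w / sum(w)
  -sum(p * log(p))
}

#' Responder fractions in entropy tails
#'
#' Ranks tumors by immunopeptidome entropy and reports the responder
#' fraction among the X\% most and X\% least entropic tumors (stable ranks;
#' both tails contain floor(n X / 100) tumors).
#'
#' @param entropy numeric entropy per tumor.
#' @param responder logical per tumor.
#' @param X tail percentage in (0, 50].
#' @return named numeric `c(most =, least =)`.
#' @export
entropy_percentile_response <- function(entropy, responder, X = 25) {
  if (X <= 0 || X > 50) stop("X must lie in (0, 50]")
  n <- length(entropy)
  if (n != length(responder)) stop("length mismatch")
  k <- floor(n * X / 100)
  if (k < 1) stop("tail is empty at this X")
  ord <- order(entropy)  # stable
  c(most = mean(responder[ord[(n - k + 1):n]]),
    least = mean(responder[ord[1:k]]))
}

#' New tumor-reactive CTL lineages under treatment
#'
#' Number of cognate CTL clones created during treatment (one per gained
#' neoantigen).
#'
#' @param treatment an `ip_treatment` from [run_icb()].
#' @return integer count.
#' @export
new_reactive_lineages <- function(treatment) {
  stopifnot(inherits(treatment, "ip_treatment"))
  treatment$summary$new_reactive_lineages
}

#' Normalized top-5 TCR clone trajectories
#'
#' The five most abundant clones are selected at the pre-treatment day; their
#' summed abundance is recorded daily and normalized to the cohort-wide
#' pre-treatment mean of that sum.
#'
#' @param top5_sums list (or matrix columns) of per-tumor daily top-5 summed
#'   abundances, day 0 first (as stored in an `ip_cohort`'s `top5`).
#' @return list of normalized numeric vectors (same names).
#' @export
top5_trajectory <- function(top5_sums) {
  if (is.matrix(top5_sums)) top5_sums <- asplit(top5_sums, 2)
  base <- mean(vapply(top5_sums, function(v) v[1], numeric(1)))
  if (base <= 0) stop("nonpositive pretreatment baseline")
  lapply(top5_sums, function(v) v / base)
}

#' Correlation with two-sided test
#'
#' Pearson product-moment or Spearman rank correlation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `estimate`, `p.value`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p.value = ct$p.value, method = method)
}

#' Local sensitivity analysis
#'
#' Re-simulates a small cohort after varying one parameter at a time up or
#' down by `delta` (default 20\%), with seeds matched to the baseline cohort.
#' For each condition the mean fold change (vs the matched baseline tumor) of
#' the unique-neoantigen count and of the tumor-reactive TCR Shannon entropy
#' is reported, together with a one-way ANOVA across conditions and
#' Bonferroni-adjusted pairwise t-tests on the log fold changes.
#'
#' @param preset an [preset()] object.
#' @param parameters character vector of config symbols to perturb (see
#'   [apply_config()]).
#' @param delta relative perturbation.
#' @param n cohort size per condition.
#' @param target_d growth target diameter (cm).
#' @param master_seed integer seed (matched across conditions).
#' @param max_days growth horizon.
#' @return list: `table` (data.frame: parameter, direction, metric, mean
#'   fold change, t-test p, Bonferroni-adjusted p), `anova` (data.frame per
#'   metric with F and p), `baseline` (per-tumor baseline metrics).
#' @export
local_sensitivity <- function(preset, parameters, delta = 0.20, n = 100,
                              target_d = 5, master_seed = 1, max_days = 6000) {
  if (n < 2) stop("n must be at least 2")
  map <- config_symbol_map()
  bad <- setdiff(parameters, names(map))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  run_cond <- function(pr) {
    co <- simulate_cohort(pr, n_tumors = n, targets = target_d,
                          master_seed = master_seed, max_days = max_days)
    ok <- co$tumors$reached
    data.frame(tumor = co$tumors$tumor,
               neo = ifelse(ok, co$tumors$total_neo, NA_real_),
               ent = ifelse(ok, co$tumors$tcr_entropy, NA_real_))
  }
  base <- run_cond(preset)
  get_value <- function(pr, key) {
    loc <- map[[key]]
    if (loc[1] == ".") pr[[loc[2]]] else pr[[loc[1]]][[loc[2]]]
  }
  rows <- list(); logfc_store <- list()
  for (par in parameters) {
    v0 <- get_value(preset, par)
    if (!is.numeric(v0) || length(v0) != 1)
      stop("parameter '", par, "' is not a scalar numeric")
    for (dir in c("down", "up")) {
      fac <- if (dir == "up") 1 + delta else 1 - delta
      ov <- list(); ov[[par]] <- v0 * fac
      cond <- if (delta == 0) base else run_cond(apply_config(preset, ov))
      for (metric in c("neo", "ent")) {
        fc <- cond[[metric]] / base[[metric]]
        fc <- fc[is.finite(fc) & fc > 0]
        lab <- paste(par, dir, sep = "_")
        logfc_store[[metric]][[lab]] <- log(fc)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = par, direction = dir,
          metric = if (metric == "neo") "unique_neoantigens" else "tcr_entropy",
          mean_fold_change = mean(fc),
          p_t = if (length(fc) > 1 && stats::var(log(fc)) > 0)
                  stats::t.test(log(fc))$p.value else NA_real_)
      }
    }
  }
  table <- do.call(rbind, rows)
  table$p_bonferroni <- pmin(stats::p.adjust(table$p_t, method = "bonferroni"), 1)
  anova_rows <- lapply(names(logfc_store), function(metric) {
    groups <- logfc_store[[metric]]
    dat <- data.frame(value = unlist(groups),
                      cond = rep(names(groups), lengths(groups)))
    if (length(unique(dat$cond)) < 2 || stats::var(dat$value) == 0)
      return(data.frame(metric = metric, F = NA_real_, p = NA_real_))
    fit <- stats::aov(value ~ cond, data = dat)
    s <- summary(fit)[[1]]
    data.frame(metric = metric, F = s$`F value`[1], p = s$`Pr(>F)`[1])
  })
  list(table = table, anova = do.call(rbind, anova_rows), baseline = base)
}
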