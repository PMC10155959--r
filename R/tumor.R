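#' Convert tumor diameter to cell number and back
#'
#' Assumes spherical tumors: N = (pi/6) d^3 / cellVol.
#'
#' @param d diameter (cm), positive.
#' @param N cell number, positive.
#' @param cellVol cell volume (cm^3).
#' @return cells (`diameter_to_cells`) or cm (`cells_to_diameter`).
#' @export
diameter_to_cells <- function(d, cellVol = 4.19e-9) {
  if (any(d <= 0)) stop("diameter must be positive")
  (pi / 6) * d^3 / cellVol
}

#' @rdname diameter_to_cells
#' @export
cells_to_diameter <- function(N, cellVol = 4.19e-9) {
  if (any(N <= 0)) stop("cell number must be positive")
  (6 * N * cellVol / pi)^(1 / 3)
}

#' Per-lineage logistic growth derivative
#'
#' dN_i/dt = kg N_i (1 - N/K) (1 - kd_i). The logistic brake uses the total
#' tumor cell number; the lineage-specific death rate kd_i may exceed 1,
#' giving shrinkage.
#'
#' @param N_i lineage cell count.
#' @param total_N total tumor cell count.
#' @param kd_i lineage-specific death rate (>= 0, dimensionless).
#' @param params a [tumor_params()] object.
#' @return dN_i/dt (cells/day).
#' @export
lineage_derivative <- function(N_i, total_N, kd_i, params) {
  params$kg * N_i * (1 - total_N / params$K) * (1 - kd_i)
}

# ---- tumor state -----------------------------------------------------------

new_tumor_state <- function(N, expr, mhc, registry, base_gain_rate = NA_real_) {
  L <- length(N)
  structure(list(
    N = as.numeric(N),
    lineage_id = seq_len(L),
    parent_id = rep(NA_integer_, L),
    expr = expr,                 # list of integer antigen ids (expression flags)
    mhc = mhc,                   # logical L x n_alleles (allele intactness)
    registry = registry,         # data.frame: one row per antigen ever created
    allele = registry$mhc_allele,# fast lookup (0-based allele per antigen id)
    R = registry$R,
    base_gain_rate = base_gain_rate,
    next_lineage_id = L + 1L
  ), class = "tumor_state")
}

#' @exportS3Method base::print
print.tumor_state <- function(x, ...) {
  cat("<tumor_state>\n")
  cat(sprintf("  %d living lineage(s), %.4g cells (%.3g cm diameter)\n",
              length(x$N), sum(x$N),
              if (sum(x$N) > 0) cells_to_diameter(sum(x$N)) else 0))
  cat(sprintf("  %d registered neoantigen(s), %d immunogenic (R > 0)\n",
              nrow(x$registry), sum(x$registry$R > 0)))
  invisible(x)
}

#' Initialize a founder tumor
#'
#' Mouse tumors start as a single lineage of `founder_cells` (~4.77e7 cells,
#' a 200 mm^3 tumor) carrying a fixed neoantigen panel with both MHC alleles
#' intact. Human tumors start from a single founder cell with a
#' gamma-distributed clonal neoantigen burden sampled from the configured
#' feature distributions; with probability `hlaL0` one of the three MHC
#' alleles (chosen uniformly) is lost clonally.
#'
#' @param preset an [preset()] object.
#' @param panel for mouse presets, a data.frame with columns `id`, `R`,
#'   `mhc_allele` (0-based); see [read_panel()] / [generate_fixture()].
#' @return a `tumor_state`.
#' @export
init_founder <- function(preset, panel = NULL) {
  stopifnot(inherits(preset, "ip_preset"))
  tp <- preset$tumor
  nal <- tp$n_mhc_alleles
  if (preset$species == "mouse") {
    if (is.null(panel)) stop("mouse presets require a neoantigen panel")
    validate_panel(panel, nal)
    registry <- data.frame(id = seq_len(nrow(panel)),
                           R = panel$R,
                           mhc_allele = as.integer(panel$mhc_allele),
                           origin = "founder",
                           day_gained = 0,
                           stringsAsFactors = FALSE)
    N <- preset$founder_cells
    expr <- list(registry$id)
    mhc <- matrix(TRUE, 1, nal)
  } else {
    burden <- sample_founder_clonal_burden(1, tp$g1, tp$g2)
    ants <- make_neoantigens(burden, nal, preset$features, preset$criteria)
    registry <- data.frame(id = ants$id, R = ants$R,
                           mhc_allele = ants$mhc_allele,
                           origin = rep("founder", nrow(ants)),
                           day_gained = rep(0, nrow(ants)),
                           stringsAsFactors = FALSE)
    registry <- cbind(registry, ants[, c("affinity_nM", "stability_h",
                                         "agretopicity", "tpm", "foreignness")])
    N <- preset$founder_cells
    expr <- list(registry$id)
    mhc <- matrix(TRUE, 1, nal)
    lost <- sample_clonal_mhc_loss(1, tp$hlaL0, nal)
    if (!is.na(lost)) mhc[1, lost] <- FALSE
  }
  st <- new_tumor_state(N, expr, mhc, registry)
  st$base_gain_rate <- sample_tumor_gain_rate(tp)
  st
}

#' Draw clonal MHC loss for founder cells
#'
#' With probability `hlaL0` a founder loses one allele, chosen uniformly.
#'
#' @param n number of founders.
#' @param hlaL0 clonal loss probability.
#' @param n_alleles number of alleles.
#' @return integer vector: lost allele index (1-based) or NA if none lost.
#' @export
sample_clonal_mhc_loss <- function(n, hlaL0 = 0.14, n_alleles = 3L) {
  lost <- stats::runif(n) < hlaL0
  out <- rep(NA_integer_, n)
  nl <- sum(lost)
  if (nl) out[lost] <- sample.int(n_alleles, nl, replace = TRUE)
  out
}

validate_panel <- function(panel, n_alleles) {
  need <- c("id", "R", "mhc_allele")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(panel) < 1) stop("panel must contain at least one neoantigen")
  if (any(panel$R < 0 | panel$R > 1)) stop("panel R values must lie in [0,1]")
  if (any(panel$mhc_allele < 0 | panel$mhc_allele >= n_alleles))
    stop("panel mhc_allele must be a 0-based index below ", n_alleles)
  invisible(TRUE)
}

# peptidome of lineage i: expressed antigens whose presenting allele is intact
lineage_peptidome <- function(state, i) {
  e <- state$expr[[i]]
  if (all(state$mhc[i, ])) return(e)
  e[state$mhc[i, state$allele[e] + 1L]]
}

#' Per-neoantigen presented cells and antigenic stimulus
#'
#' For each registered neoantigen k, `raw[k]` is the number of cells whose
#' immunopeptidome contains k (sum of N_i over lineages expressing k with the
#' presenting allele intact), and `S[k] = R_k * raw[k]` is the
#' immunogenicity-weighted antigenic stimulus.
#'
#' @param state a `tumor_state`.
#' @return list with numeric vectors `raw` and `S`, indexed by antigen id.
#' @export
presented_cells <- function(state) {
  M <- nrow(state$registry)
  raw <- numeric(M)
  for (i in seq_along(state$N)) {
    p <- lineage_peptidome(state, i)
    if (length(p)) raw[p] <- raw[p] + state$N[i]
  }
  list(raw = raw, S = state$R * raw)
}

#' Sample per-tumor and per-day neoantigen gain rates
#'
#' The per-tumor base rate is log-normal around `nG` (median-preserving by
#' default: base = nG exp(Normal(0, nGS))); the daily rate multiplies the
#' base by exp(Normal(0, nGSt)) to model day-to-day instability.
#'
#' @param params a [tumor_params()] object.
#' @param base a base rate from `sample_tumor_gain_rate`.
#' @return a positive rate (per cell per day).
#' @export
sample_tumor_gain_rate <- function(params) {
  mu <- log(params$nG)
  if (params$gain_rate_convention == "mean") mu <- mu - params$nGS^2 / 2
  if (params$nG == 0) return(0)
  exp(mu + stats::rnorm(1, 0, params$nGS))
}

#' @rdname sample_tumor_gain_rate
#' @export
daily_gain_rate <- function(base, params) {
  if (base == 0) return(0)
  base * exp(stats::rnorm(1, 0, params$nGSt))
}

#' Draw one day of stochastic immunopeptidome events
#'
#' For each living lineage (N_i >= 1) and each event type (neoantigen gain,
#' neoantigen loss, MHC allele loss), at most one branching event per day is
#' drawn with probability 1 - exp(-rate * N_i * dt) -- the probability that a
#' per-cell Poisson process of that rate fires at least once in the lineage;
#' same-day same-type firings coalesce into a single branching. Loss events
#' are only eligible when the lineage expresses at least one neoantigen, MHC
#' loss only when at least one allele is intact. Targets are chosen uniformly
#' among eligible targets.
#'
#' @param state a `tumor_state`.
#' @param day_rate that day's neoantigen gain rate (per cell per day).
#' @param params a [tumor_params()] object.
#' @param dt time step (days).
#' @return data.frame with columns `type` ("loss", "mhc_loss", "gain"),
#'   `lineage` (index into `state$N`) and `target` (antigen id for losses,
#'   1-based allele for MHC losses, NA for gains), ordered losses first, then
#'   MHC losses, then gains.
#' @export
draw_daily_events <- function(state, day_rate, params, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  L <- length(state$N)
  empty <- data.frame(type = character(0), lineage = integer(0),
                      target = integer(0))
  if (L == 0) return(empty)
  N <- state$N
  live <- N >= 1
  n_expr <- lengths(state$expr)
  n_mhc <- rowSums(state$mhc)
  p_loss <- ifelse(live & n_expr > 0, 1 - exp(-params$nL * N * dt), 0)
  p_mhc <- ifelse(live & n_mhc > 0, 1 - exp(-params$hlaL * N * dt), 0)
  p_gain <- ifelse(live, 1 - exp(-day_rate * N * dt), 0)
  rows <- list()
  hit <- which(stats::runif(L) < p_loss)
  if (length(hit)) {
    tgt <- vapply(hit, function(i) {
      e <- state$expr[[i]]
      if (length(e) == 1L) e else sample(e, 1L)
    }, integer(1))
    rows[[1]] <- data.frame(type = "loss", lineage = hit, target = tgt)
  }
  hit <- which(stats::runif(L) < p_mhc)
  if (length(hit)) {
    tgt <- vapply(hit, function(i) {
      a <- which(state$mhc[i, ])
      if (length(a) == 1L) a else sample(a, 1L)
    }, integer(1))
    rows[[2]] <- data.frame(type = "mhc_loss", lineage = hit, target = tgt)
  }
  hit <- which(stats::runif(L) < p_gain)
  if (length(hit))
    rows[[3]] <- data.frame(type = "gain", lineage = hit, target = NA_integer_)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Apply a stochastic event to the tumor state
#'
#' The parent lineage is deducted one cell and a near-identical child lineage
#' is created with N = 1, differing by exactly one modification: one
#' neoantigen's expression flipped to 0 (loss), one MHC allele flipped to 0
#' (MHC loss, removing all neoantigens presented by that allele from the
#' child's immunopeptidome), or one newly created neoantigen appended (gain).
#' Total cell number is conserved. Events whose parent has fewer than one
#' cell are discarded.
#'
#' @param state a `tumor_state`.
#' @param event one row of [draw_daily_events()] output (list or data.frame
#'   row with `type`, `lineage`, `target`).
#' @param neoantigen_factory for gain events: a function(id) returning a
#'   one-row data.frame like [make_neoantigens()] output.
#' @return list with elements `state` (updated), `applied` (logical),
#'   `child` (index of the new lineage or NA) and `new_antigen_id` (for
#'   gains).
#' @export
apply_event <- function(state, event, neoantigen_factory = NULL) {
  i <- as.integer(event$lineage)
  if (i < 1 || i > length(state$N)) stop("event references an unknown lineage")
  if (state$N[i] < 1)
    return(list(state = state, applied = FALSE, child = NA_integer_,
                new_antigen_id = NA_integer_))
  type <- as.character(event$type)
  new_id <- NA_integer_
  child_expr <- state$expr[[i]]
  child_mhc <- state$mhc[i, , drop = TRUE]
  if (type == "loss") {
    tgt <- as.integer(event$target)
    if (!tgt %in% child_expr)
      return(list(state = state, applied = FALSE, child = NA_integer_,
                  new_antigen_id = NA_integer_))
    child_expr <- child_expr[child_expr != tgt]
  } else if (type == "mhc_loss") {
    tgt <- as.integer(event$target)
    if (!child_mhc[tgt])
      return(list(state = state, applied = FALSE, child = NA_integer_,
                  new_antigen_id = NA_integer_))
    child_mhc[tgt] <- FALSE
  } else if (type == "gain") {
    if (is.null(neoantigen_factory)) stop("gain events need a neoantigen_factory")
    new_id <- nrow(state$registry) + 1L
    ant <- neoantigen_factory(new_id)
    reg_cols <- names(state$registry)
    row <- as.list(rep(NA, length(reg_cols)))
    names(row) <- reg_cols
    for (cn in intersect(reg_cols, names(ant))) row[[cn]] <- ant[[cn]]
    row$id <- new_id
    row$origin <- "gained"
    state$registry <- rbind(state$registry, as.data.frame(row, stringsAsFactors = FALSE))
    state$allele <- c(state$allele, as.integer(ant$mhc_allele))
    state$R <- c(state$R, ant$R)
    child_expr <- c(child_expr, new_id)
  } else stop("unknown event type: ", type)
  state$N[i] <- state$N[i] - 1
  state$N <- c(state$N, 1)
  state$lineage_id <- c(state$lineage_id, state$next_lineage_id)
  state$parent_id <- c(state$parent_id, state$lineage_id[i])
  state$next_lineage_id <- state$next_lineage_id + 1L
  state$expr <- c(state$expr, list(child_expr))
  state$mhc <- rbind(state$mhc, child_mhc)
  list(state = state, applied = TRUE, child = length(state$N),
       new_antigen_id = new_id)
}

#' Clonal and subclonal neoantigen burden
#'
#' With `method = "lineage"` (the literal reading) a neoantigen is clonal
#' when present in the immunopeptidome of every living lineage (N >= 1),
#' subclonal when present in at least one but not all. With
#' `method = "cells"` presence is cell-weighted, mirroring how clonality is
#' called from sequencing data with a detection limit: a neoantigen is
#' clonal when presented by at least `clonal_fraction` of living cells and
#' subclonal when presented by any smaller positive fraction. Under lineage
#' counting a single surviving one-cell branch demotes an antigen from
#' clonal, so late-stage tumors with many branching events have clonal
#' burden pinned at zero; cohort analytics therefore use the cell-weighted
#' form. Neoantigens presented by no living cell are excluded.
#'
#' @param state a `tumor_state`.
#' @param method `"lineage"` or `"cells"`.
#' @param clonal_fraction cell-fraction threshold for clonality (cells
#'   method).
#' @return named numeric vector `c(clonal =, subclonal =, total =)`.
#' @export
clonal_subclonal_burden <- function(state, method = c("lineage", "cells"),
                                    clonal_fraction = 0.95) {
  method <- match.arg(method)
  live <- which(state$N >= 1)
  if (!length(live)) stop("no living lineage")
  M <- nrow(state$registry)
  if (method == "lineage") {
    cnt <- integer(M)
    for (i in live) {
      p <- lineage_peptidome(state, i)
      if (length(p)) cnt[p] <- cnt[p] + 1L
    }
    nl <- length(live)
    return(c(clonal = sum(cnt == nl), subclonal = sum(cnt > 0 & cnt < nl),
             total = sum(cnt > 0)))
  }
  raw <- numeric(M)
  for (i in live) {
    p <- lineage_peptidome(state, i)
    if (length(p)) raw[p] <- raw[p] + state$N[i]
  }
  f <- raw / sum(state$N[live])
  c(clonal = sum(f >= clonal_fraction),
    subclonal = sum(f > 0 & f < clonal_fraction),
    total = sum(f > 0))
}
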