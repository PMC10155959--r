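#' Create a simulation from a preset
#'
#' Initializes the founder tumor, one cognate CTL clone per registered
#' neoantigen (size 2^n, n ~ Poisson(mu)), the pooled tumor-ignorant
#' population (TCR_other minus the summed clone sizes, so total CTLs start at
#' homeostasis) and the nonspecific stimulus C = C0.
#'
#' Internally, clones whose cognate neoantigen has R = 0 receive no antigen
#' stimulus and follow dX/dt = X Td (C - 1) exactly; they are therefore
#' propagated through a single shared log-factor Lambda(t) = integral of
#' Td (C - 1) dt rather than as individual ODE states. This is an exact
#' algebraic reduction.
#'
#' @param preset an [preset()] object.
#' @param panel neoantigen panel for mouse presets (see [init_founder()]).
#' @param seed optional integer seed.
#' @return object of class `ip_sim`.
#' @export
new_simulation <- function(preset, panel = NULL, seed = NULL) {
  stopifnot(inherits(preset, "ip_preset"))
  if (!is.null(seed)) set.seed(seed)
  tumor <- init_founder(preset, panel)
  immune <- NULL
  if (!preset$immunodeficient) {
    M <- nrow(tumor$registry)
    s0 <- if (M) init_clone_size(preset$immune$mu, M) else numeric(0)
    immune <- list(
      s0 = s0,                      # size at creation
      lam0 = numeric(M),            # Lambda at creation
      active = tumor$R > 0,         # clones integrated explicitly
      ctl_active = s0[tumor$R > 0], # current sizes of active clones
      Lambda = 0,
      NSCTL = max(preset$immune$TCR_other - sum(s0), 0),
      C = preset$immune$C0
    )
  }
  sim <- structure(list(
    day = 0L, preset = preset, tumor = tumor, immune = immune,
    struct = NULL,       # cached per-day structures (peptidomes, Pact, w)
    traj = list(), events = list(), n_discarded = 0L
  ), class = "ip_sim")
  sim <- rebuild_structures(sim)
  sim <- record_day(sim)
  sim
}

#' @exportS3Method base::print
print.ip_sim <- function(x, ...) {
  cat("<ip_sim>", x$preset$name, "- day", x$day, "\n")
  tot <- sum(x$tumor$N)
  cat(sprintf("  tumor: %.4g cells (%.3g cm), %d lineage(s), %d neoantigen(s)\n",
              tot, if (tot > 0) cells_to_diameter(tot, x$preset$tumor$cellVol) else 0,
              length(x$tumor$N), nrow(x$tumor$registry)))
  if (!is.null(x$immune))
    cat(sprintf("  immune: C=%.4g, NSCTL=%.4g, reactive=%.4g cells\n",
                x$immune$C, x$immune$NSCTL, sum(clone_sizes(x))))
  invisible(x)
}

#' Current CTL clone sizes
#'
#' @param sim an `ip_sim`.
#' @return numeric vector, one entry per registered neoantigen.
#' @export
clone_sizes <- function(sim) {
  im <- sim$immune
  if (is.null(im)) return(numeric(0))
  sizes <- im$s0 * exp(im$Lambda - im$lam0)
  sizes[im$active] <- im$ctl_active
  sizes
}

# rebuild cached peptidome structures after any change to lineages/clones
rebuild_structures <- function(sim) {
  tumor <- sim$tumor
  L <- length(tumor$N)
  im <- sim$immune
  # peptidomes: expression lists masked by MHC intactness (only lineages
  # with a lost allele need filtering)
  pept <- tumor$expr
  if (L) {
    broken <- which(rowSums(!tumor$mhc) > 0)
    allele <- tumor$allele
    for (i in broken) {
      e <- pept[[i]]
      pept[[i]] <- e[tumor$mhc[i, allele[e] + 1L]]
    }
  }
  if (is.null(im)) {
    sim$struct <- list(pept = pept)
    return(sim)
  }
  act_ids <- which(im$active)
  Ma <- length(act_ids)
  ws <- im$s0 * exp(-im$lam0)   # passive weights at Lambda = 0
  ws[im$active] <- 0
  w <- numeric(L)
  Pact <- NULL   # active-antigen presentation, antigens x lineages
  if (L) {
    len <- lengths(pept)
    idx <- unlist(pept, use.names = FALSE)
    lin <- rep.int(seq_len(L), len)
    if (length(idx)) {
      agg <- rowsum(ws[idx], lin)
      w[as.integer(rownames(agg))] <- agg[, 1]
      if (Ma) {
        keep <- which(idx %in% act_ids)
        Pact <- Matrix::sparseMatrix(i = match(idx[keep], act_ids),
                                     j = lin[keep],
                                     x = 1, dims = c(Ma, L))
      }
    }
  }
  if (is.null(Pact) && Ma) Pact <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                        x = numeric(0), dims = c(Ma, L))
  sim$struct <- list(pept = pept, act_ids = act_ids, Ma = Ma,
                     Pact = Pact, w = w, ws = ws, W_passive = sum(ws))
  sim
}

# append newly created lineages (and clones) to the cached structures
# without a full rebuild; exact because lineages and clones are append-only
# within a day (extinction triggers a full rebuild in drop_extinct)
append_structures <- function(sim, child_idx, new_clone_ids) {
  st <- sim$struct
  im <- sim$immune
  tu <- sim$tumor
  if (length(new_clone_ids)) {
    ws_new <- im$s0[new_clone_ids] * exp(-im$lam0[new_clone_ids])
    ws_new[im$active[new_clone_ids]] <- 0
    st$ws <- c(st$ws, ws_new)
    st$W_passive <- st$W_passive + sum(ws_new)
    new_act <- new_clone_ids[im$active[new_clone_ids]]
    if (length(new_act)) {
      st$act_ids <- c(st$act_ids, new_act)
      st$Ma <- length(st$act_ids)
      if (is.null(st$Pact)) {
        return(rebuild_structures(sim))  # first active clone: build fresh
      }
      st$Pact@Dim <- c(st$Ma, st$Pact@Dim[2])  # empty new rows
    }
  }
  k <- length(child_idx)
  pept_new <- vector("list", k)
  rows <- vector("list", k)
  for (c in seq_len(k)) {
    i <- child_idx[c]
    e <- tu$expr[[i]]
    if (!all(tu$mhc[i, ])) e <- e[tu$mhc[i, tu$allele[e] + 1L]]
    pept_new[[c]] <- e
    rows[[c]] <- sort(match(e, st$act_ids, nomatch = 0L))
    rows[[c]] <- rows[[c]][rows[[c]] > 0L]
  }
  st$pept <- c(st$pept, pept_new)
  st$w <- c(st$w, vapply(pept_new, function(p) sum(st$ws[p]), numeric(1)))
  if (!is.null(st$Pact) && k) {
    nr <- lengths(rows)
    newcols <- methods::new("dgCMatrix",
                            i = as.integer(unlist(rows, use.names = FALSE) - 1L),
                            p = as.integer(c(0L, cumsum(nr))),
                            x = rep(1, sum(nr)),
                            Dim = c(st$Ma, k))
    st$Pact <- methods::cbind2(st$Pact, newcols)
  }
  sim$struct <- st
  sim
}

# coupled RHS for one day of deterministic flow
make_rhs <- function(sim) {
  pr <- sim$preset
  tp <- pr$tumor; ip <- pr$immune
  L <- length(sim$tumor$N)
  st <- sim$struct
  immunodef <- pr$immunodeficient
  Ma <- if (immunodef) 0L else st$Ma
  R_act <- if (Ma) sim$tumor$R[st$act_ids] else numeric(0)
  iN <- seq_len(L)
  iA <- if (Ma) L + seq_len(Ma) else integer(0)
  iNS <- L + Ma + 1L; iC <- iNS + 1L; iLam <- iC + 1L
  function(t, y, parms) {
    N <- pmax(y[iN], 0)
    totN <- sum(N)
    if (immunodef) {
      dN <- tp$kg * N * (1 - totN / tp$K) * (1 - tp$fdie)
      return(list(c(dN, 0, 0, 0)))
    }
    CTLa <- if (Ma) pmax(y[iA], 0) else numeric(0)
    NSCTL <- max(y[iNS], 0)
    C <- max(y[iC], 0)
    eL <- exp(y[iLam])
    react <- st$w * eL
    if (Ma && L) react <- react + as.numeric(Matrix::crossprod(st$Pact, CTLa))
    den <- NSCTL + react
    phi <- ifelse(den > 0, react / den, 0)
    kd <- tp$fdie + (ip$k_mag + 1 - tp$fdie) *
      killing_kernel(phi * ip$k_kill, ip$killing_form)
    dN <- tp$kg * N * (1 - totN / tp$K) * (1 - kd)
    if (Ma) {
      S <- R_act * as.numeric(st$Pact %*% N)
      ag <- ip$icb * S * ip$Ta * C
      if (ip$eq2_form == "massaction") ag <- ag * CTLa
      dCTLa <- CTLa * ip$Td * (C - 1) + ag
    } else dCTLa <- numeric(0)
    dNS <- NSCTL * ip$Td * (C - 1)
    tot_ctl <- NSCTL + sum(CTLa) + st$W_passive * eL
    dC <- ip$kin - ip$kin * ip$fout -
      ip$kin * (1 - ip$fout) * tot_ctl / (ip$icb * ip$CTL_ss)
    dLam <- ip$Td * (C - 1)
    list(c(dN, dCTLa, dNS, dC, dLam))
  }
}

integrate_day <- function(sim, dt = 1) {
  L <- length(sim$tumor$N)
  im <- sim$immune
  if (is.null(im)) {
    y0 <- c(sim$tumor$N, 0, 0, 0)
  } else {
    y0 <- c(sim$tumor$N, im$ctl_active, im$NSCTL, im$C, im$Lambda)
  }
  Ma <- if (is.null(im)) 0L else sim$struct$Ma
  rhs <- make_rhs(sim)
  atol <- c(rep(1e-3, L + Ma), 1e-3, 1e-9, 1e-9)
  sol <- try(deSolve::ode(y = y0, times = c(0, dt), func = rhs, parms = NULL,
                          method = "adams", rtol = 1e-6, atol = atol,
                          maxsteps = 10000), silent = TRUE)
  bad <- inherits(sol, "try-error") ||
    anyNA(sol[nrow(sol), ]) || attr(sol, "istate")[1] < 0
  if (bad) {  # stiff-capable fallback at halved step
    sol <- deSolve::ode(y = y0, times = seq(0, dt, by = dt / 2), func = rhs,
                        parms = NULL, method = "lsoda", rtol = 1e-6,
                        atol = atol, maxsteps = 20000)
    if (anyNA(sol[nrow(sol), ]))
      stop("integration failed at day ", sim$day, "; state: ",
           paste(utils::head(signif(y0, 4), 20), collapse = ", "))
  }
  yf <- unname(sol[nrow(sol), -1])
  sim$tumor$N <- pmax(yf[seq_len(L)], 0)
  if (!is.null(im)) {
    if (Ma) sim$immune$ctl_active <- pmax(yf[L + seq_len(Ma)], 0)
    sim$immune$NSCTL <- max(yf[L + Ma + 1L], 0)
    sim$immune$C <- max(yf[L + Ma + 2L], 0)
    sim$immune$Lambda <- yf[L + Ma + 3L]
  }
  sim
}

drop_extinct <- function(sim) {
  thr <- sim$preset$tumor$extinction_threshold
  dead <- sim$tumor$N < thr
  if (!any(dead)) return(sim)
  keep <- which(!dead)
  tu <- sim$tumor
  tu$N <- tu$N[keep]
  tu$lineage_id <- tu$lineage_id[keep]
  tu$parent_id <- tu$parent_id[keep]
  tu$expr <- tu$expr[keep]
  tu$mhc <- tu$mhc[keep, , drop = FALSE]
  sim$tumor <- tu
  rebuild_structures(sim)
}

# applies one day's events with batched appends; semantically equivalent to
# repeated apply_event() (losses, then MHC losses, then gains; parents are
# pre-existing lineages, deducted one cell per applied event, children get
# N = 1 and exactly one modification; sub-one-cell parents discard events)
apply_daily_events <- function(sim) {
  pr <- sim$preset
  day_rate <- daily_gain_rate(sim$tumor$base_gain_rate, pr$tumor)
  ev <- draw_daily_events(sim$tumor, day_rate, pr$tumor)
  if (!nrow(ev)) return(sim)
  tu <- sim$tumor
  N <- tu$N
  keep <- logical(nrow(ev))
  for (r in seq_len(nrow(ev))) {   # sequential one-cell deductions
    i <- ev$lineage[r]
    if (N[i] >= 1) { N[i] <- N[i] - 1; keep[r] <- TRUE }
  }
  sim$n_discarded <- sim$n_discarded + sum(!keep)
  ev <- ev[keep, , drop = FALSE]
  nk <- nrow(ev)
  if (!nk) { sim$tumor$N <- N; return(sim) }
  gains <- which(ev$type == "gain")
  M0 <- nrow(tu$registry)
  if (length(gains)) {
    ants <- make_neoantigens(length(gains), pr$tumor$n_mhc_alleles,
                             pr$features, pr$criteria, id_start = M0 + 1L)
    reg_cols <- names(tu$registry)
    add <- as.data.frame(ants[, intersect(reg_cols, names(ants))])
    for (cn in setdiff(reg_cols, names(add))) add[[cn]] <- NA
    add$origin <- "gained"
    add$day_gained <- sim$day
    tu$registry <- rbind(tu$registry, add[, reg_cols])
    tu$allele <- c(tu$allele, as.integer(ants$mhc_allele))
    tu$R <- c(tu$R, ants$R)
    # spawn cognate CTL clones
    im <- sim$immune
    s0 <- init_clone_size(pr$immune$mu, length(gains))
    act <- ants$R > 0
    im$s0 <- c(im$s0, s0)
    im$lam0 <- c(im$lam0, rep(im$Lambda, length(gains)))
    im$active <- c(im$active, act)
    im$ctl_active <- c(im$ctl_active, s0[act])
    sim$immune <- im
  }
  child_expr <- vector("list", nk)
  child_mhc <- tu$mhc[ev$lineage, , drop = FALSE]
  target_out <- integer(nk)
  g <- 0L
  for (r in seq_len(nk)) {
    i <- ev$lineage[r]
    e <- tu$expr[[i]]
    if (ev$type[r] == "loss") {
      child_expr[[r]] <- e[e != ev$target[r]]
      target_out[r] <- ev$target[r]
    } else if (ev$type[r] == "mhc_loss") {
      child_expr[[r]] <- e
      child_mhc[r, ev$target[r]] <- FALSE
      target_out[r] <- ev$target[r]
    } else {
      g <- g + 1L
      child_expr[[r]] <- c(e, M0 + g)
      target_out[r] <- M0 + g
    }
  }
  child_ids <- tu$next_lineage_id + seq_len(nk) - 1L
  parent_ids <- tu$lineage_id[ev$lineage]
  tu$N <- c(N, rep(1, nk))
  tu$lineage_id <- c(tu$lineage_id, child_ids)
  tu$parent_id <- c(tu$parent_id, parent_ids)
  tu$next_lineage_id <- tu$next_lineage_id + nk
  tu$expr <- c(tu$expr, child_expr)
  tu$mhc <- rbind(tu$mhc, child_mhc)
  sim$tumor <- tu
  sim$events[[length(sim$events) + 1L]] <- data.frame(
    day = sim$day, type = as.character(ev$type), parent_id = parent_ids,
    child_id = child_ids, target = target_out, stringsAsFactors = FALSE)
  L0 <- length(tu$N) - nk
  append_structures(sim, child_idx = L0 + seq_len(nk),
                    new_clone_ids = if (length(gains)) M0 + seq_along(gains)
                                    else integer(0))
}

record_day <- function(sim) {
  tot <- sum(sim$tumor$N)
  row <- list(day = sim$day, total_N = tot,
              diameter_cm = if (tot > 0)
                cells_to_diameter(tot, sim$preset$tumor$cellVol) else 0,
              n_lineages = length(sim$tumor$N),
              n_neoantigens = nrow(sim$tumor$registry),
              C = if (is.null(sim$immune)) NA_real_ else sim$immune$C,
              NSCTL = if (is.null(sim$immune)) NA_real_ else sim$immune$NSCTL,
              reactive_total = if (is.null(sim$immune)) NA_real_
                               else sum(clone_sizes(sim)))
  sim$traj[[length(sim$traj) + 1L]] <- row
  sim
}

#' Advance a simulation by one day
#'
#' One hybrid step: (i) deterministic flow of the coupled tumor/CTL/stimulus
#' ODE system over one day (adaptive multistep integration with populations
#' floored at 0 and C clamped at 0, with a stiff-capable fallback at halved
#' step); (ii) removal of extinct lineages; (iii) if events are enabled,
#' stochastic gain/loss/MHC-loss events at that day's jittered gain rate,
#' each gain registering a new neoantigen and spawning its cognate CTL clone;
#' (iv) trajectory recording.
#'
#' @param sim an `ip_sim`.
#' @param dt step length in days (default 1; events are drawn once per call).
#' @return the advanced `ip_sim`.
#' @export
step_day <- function(sim, dt = 1) {
  stopifnot(inherits(sim, "ip_sim"))
  if (length(sim$tumor$N)) sim <- integrate_day(sim, dt)
  else if (!is.null(sim$immune)) sim <- integrate_day(sim, dt)  # tumor-free immune flow
  sim <- drop_extinct(sim)
  sim$day <- sim$day + 1L
  if (sim$preset$events_enabled && length(sim$tumor$N)) sim <- apply_daily_events(sim)
  record_day(sim)
}

#' Trajectory of a simulation
#'
#' @param sim an `ip_sim`, or a treatment result from [run_icb()].
#' @return data.frame with one row per recorded day.
#' @export
trajectory <- function(sim) {
  rows <- if (inherits(sim, "ip_sim")) sim$traj else sim$trajectory
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Event log of a simulation
#'
#' @param sim an `ip_sim`.
#' @return data.frame: day, type, parent_id, child_id, target.
#' @export
event_log <- function(sim) {
  if (!length(sim$events))
    return(data.frame(day = integer(0), type = character(0),
                      parent_id = integer(0), child_id = integer(0),
                      target = integer(0)))
  do.call(rbind, lapply(sim$events, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Simulate mouse tumor growth
#'
#' Five-week (by default) simulations of a fixed-panel tumor in an
#' immunodeficient (NSG-like) or immunocompetent (C57BL/6-like) host.
#' Immunopeptidomes are held constant (no stochastic events).
#'
#' @param preset a mouse [preset()].
#' @param panel neoantigen panel data.frame (`id`, `R`, `mhc_allele`).
#' @param weeks simulation length in weeks.
#' @param seed optional integer seed.
#' @return an `ip_sim` after `7 * weeks` daily steps.
#' @export
run_mouse <- function(preset, panel, weeks = 5, seed = NULL) {
  if (preset$species != "mouse") stop("run_mouse requires a mouse preset")
  sim <- new_simulation(preset, panel, seed = seed)
  for (d in seq_len(7 * weeks)) sim <- step_day(sim)
  sim
}

#' Grow a tumor to a target diameter
#'
#' Runs daily steps until the tumor diameter first reaches `target_d` (cm).
#' Tumors held in check by the immune response (or eradicated) within
#' `max_days` are reported with `reached = FALSE` -- immune control is a
#' valid outcome, not an error.
#'
#' @param preset an [preset()] object.
#' @param target_d target diameter (cm).
#' @param seed optional integer seed.
#' @param max_days growth horizon (days).
#' @param panel optional panel for mouse presets.
#' @param project_stop if TRUE, periodically extrapolate the trailing
#'   200-day growth rate and stop early (as not reached) once the projected
#'   arrival at the target lies beyond `max_days`. This prunes
#'   immune-controlled tumors without waiting out the full horizon; tumors
#'   whose growth later accelerates past the projection (late escape) are
#'   treated as controlled, exactly as the hard horizon would treat them.
#' @return an `ip_sim` with attribute-like fields `reached` (logical) and
#'   `target_d`.
#' @export
run_to_diameter <- function(preset, target_d, seed = NULL, max_days = 6000,
                            panel = NULL, project_stop = FALSE) {
  sim <- new_simulation(preset, panel, seed = seed)
  cellVol <- preset$tumor$cellVol
  target_N <- diameter_to_cells(target_d, cellVol)
  sim$target_d <- target_d
  if (sum(sim$tumor$N) >= target_N) {
    sim$reached <- TRUE
    return(sim)
  }
  check_at <- 700
  log_prev <- NA_real_
  repeat {
    sim <- step_day(sim)
    tot <- sum(sim$tumor$N)
    if (tot >= target_N) { sim$reached <- TRUE; break }
    if (tot <= 0 || sim$day >= max_days) { sim$reached <- FALSE; break }
    if (project_stop && sim$day >= check_at) {
      log_now <- log(tot)
      if (!is.na(log_prev)) {
        rate <- (log_now - log_prev) / 200
        if (rate <= 0 ||
            sim$day + (log(target_N) - log_now) / rate > max_days) {
          sim$reached <- FALSE
          break
        }
      }
      log_prev <- log_now
      check_at <- check_at + 200
    } else if (project_stop && sim$day == check_at - 200) {
      log_prev <- log(tot)
    }
  }
  sim
}

#' Simulate immune checkpoint blockade
#'
#' Applies an ICB multiplier to both the antigen-sensitivity term of clonal
#' expansion and the CTL carrying capacity in the stimulus balance, then runs
#' daily steps for `duration` days. Records the daily diameter, the summed
#' abundance of the five most abundant pre-treatment CTL clones, and the
#' presented-cell count of the pre-treatment rank-1 neoantigen.
#'
#' @param sim an `ip_sim` (typically from [run_to_diameter()]).
#' @param strength fold increase in CTL antigen sensitivity and carrying
#'   capacity (>= 1; 1 = untreated continuation).
#' @param duration treatment length (days).
#' @param seed optional integer seed (stochastic events continue under
#'   treatment).
#' @return list of class `ip_treatment`: `trajectory` (data.frame with day,
#'   diameter_cm, total_N, top5_sum, rank1_presented), `summary` (list with
#'   baseline_diameter, max_shrinkage, responder, new_reactive_lineages,
#'   immunoediting_fc, entropy_pre, entropy_post) and `state` (final
#'   `ip_sim`).
#' @export
run_icb <- function(sim, strength = 10, duration = 365, seed = NULL) {
  stopifnot(inherits(sim, "ip_sim"))
  if (strength < 1) stop("strength must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim$preset$immune$icb <- strength
  sizes0 <- clone_sizes(sim)
  top5 <- utils::head(order(sizes0, decreasing = TRUE), 5L)
  rk1 <- rank1_metrics(sim)
  rank1_id <- rk1$id
  M0 <- nrow(sim$tumor$registry)
  d0 <- cells_to_diameter(sum(sim$tumor$N), sim$preset$tumor$cellVol)
  entropy_pre <- if (length(sizes0)) tcr_entropy(sizes0) else NA_real_
  raw1 <- function(s) {
    # the rank-1 antigen has R > 0, hence an explicitly tracked clone: its
    # presented-cell count is the matching column of the cached structure
    if (is.na(rank1_id)) return(NA_real_)
    st <- s$struct
    j <- match(rank1_id, st$act_ids)
    if (is.na(j) || is.null(st$Pact)) return(0)
    sum(s$tumor$N[st$Pact[j, ] != 0])
  }
  rows <- vector("list", duration + 1L)
  rows[[1]] <- list(day = 0L, diameter_cm = d0, total_N = sum(sim$tumor$N),
                    top5_sum = sum(sizes0[top5]), rank1_presented = raw1(sim))
  for (d in seq_len(duration)) {
    if (sum(sim$tumor$N) <= 0) {
      rows[[d + 1L]] <- list(day = d, diameter_cm = 0, total_N = 0,
                             top5_sum = sum(clone_sizes(sim)[top5]),
                             rank1_presented = 0)
      next
    }
    sim <- step_day(sim)
    sz <- clone_sizes(sim)
    tot <- sum(sim$tumor$N)
    rows[[d + 1L]] <- list(
      day = d,
      diameter_cm = if (tot > 0) cells_to_diameter(tot, sim$preset$tumor$cellVol) else 0,
      total_N = tot,
      top5_sum = sum(sz[top5]),
      rank1_presented = raw1(sim))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  traj <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  shrink <- max_shrinkage(traj)
  first_raw <- traj$rank1_presented[1]
  last_raw <- traj$rank1_presented[nrow(traj)]
  fc <- if (is.na(first_raw) || (first_raw == 0 && last_raw == 0)) NA_real_
        else last_raw / first_raw
  sizes1 <- clone_sizes(sim)
  structure(list(
    trajectory = traj,
    summary = list(baseline_diameter = d0,
                   max_shrinkage = shrink,
                   responder = classify_response(shrink),
                   new_reactive_lineages = nrow(sim$tumor$registry) - M0,
                   immunoediting_fc = fc,
                   entropy_pre = entropy_pre,
                   entropy_post = if (length(sizes1)) tcr_entropy(sizes1) else NA_real_,
                   strength = strength),
    state = sim), class = "ip_treatment")
}

# deterministic derivation of per-tumor / per-run substream seeds
derive_seed <- function(master, tumor, run = 0L) {
  as.integer((as.numeric(master) + 1000003 * tumor + 7919 * run) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Target diameters mirroring the TRACERx 100 stage mix
#'
#' 26 stage I (1.5 cm), 36 stage IB (3.5 cm), 13 stage IIA (4.5 cm) and
#' 25 stage IIB/IIIA/IIIB (5 cm), scaled to `n` tumors.
#'
#' @param n cohort size.
#' @return numeric vector of `n` target diameters (cm).
#' @export
tracerx_targets <- function(n = 100) {
  mix <- rep(c(1.5, 3.5, 4.5, 5.0), times = c(26, 36, 13, 25))
  if (n == 100) return(mix)
  mix[ceiling(seq_len(n) * 100 / n)]
}

#' Simulate a virtual tumor cohort
#'
#' Grows `n_tumors` independent tumors to their target diameters (per-tumor
#' substreams derived deterministically from `master_seed`), collects
#' baseline immunopeptidome and TCR-repertoire metrics, and (optionally)
#' treats each tumor with ICB at one or more strengths. Tumors controlled by
#' the immune system before reaching their target are redrawn with a fresh
#' substream (the cohort is conditioned on reaching treatment size); redraw
#' counts are reported.
#'
#' @param preset an [preset()] object (or preset name).
#' @param n_tumors cohort size.
#' @param targets target diameters (cm), recycled to `n_tumors`.
#' @param master_seed integer master seed.
#' @param strengths ICB strengths to apply (NULL = no treatment).
#' @param duration treatment duration (days).
#' @param max_days growth horizon per tumor.
#' @param max_retries redraw limit per tumor slot.
#' @param keep_states keep final `ip_sim` objects (memory-heavy).
#' @return object of class `ip_cohort`: list with data.frames `tumors`
#'   (baseline features) and `treatments` (one row per tumor x strength),
#'   plus `top5` (named list of normalized top-5 clone trajectories) and
#'   `n_redrawn`.
#' @export
simulate_cohort <- function(preset, n_tumors = 100, targets = 5.0,
                            master_seed = 1, strengths = NULL,
                            duration = 365, max_days = 6000,
                            max_retries = 25, keep_states = FALSE) {
  if (is.character(preset)) preset <- preset(preset)
  targets <- rep_len(targets, n_tumors)
  tumors <- vector("list", n_tumors)
  treatments <- list()
  top5 <- list()
  states <- if (keep_states) vector("list", n_tumors) else NULL
  n_redrawn <- 0L
  for (t in seq_len(n_tumors)) {
    sim <- NULL
    for (r in 0:max_retries) {
      cand <- run_to_diameter(preset, targets[t],
                              seed = derive_seed(master_seed, t, r),
                              max_days = max_days)
      if (isTRUE(cand$reached)) { sim <- cand; break }
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(sim)) {
      tumors[[t]] <- data.frame(tumor = t, target_d = targets[t],
                                reached = FALSE, days = NA_real_,
                                diameter_cm = NA_real_, clonal = NA_real_,
                                subclonal = NA_real_, total_neo = NA_real_,
                                n_lineages = NA_real_, rank1_R = NA_real_,
                                rank1_clonality = NA_real_,
                                rank1_cwi = NA_real_,
                                peptidome_entropy = NA_real_,
                                tcr_entropy = NA_real_)
      next
    }
    bur <- clonal_subclonal_burden(sim$tumor, method = "cells")
    rk1 <- rank1_metrics(sim)
    sz <- clone_sizes(sim)
    tumors[[t]] <- data.frame(
      tumor = t, target_d = targets[t], reached = TRUE, days = sim$day,
      diameter_cm = cells_to_diameter(sum(sim$tumor$N), preset$tumor$cellVol),
      clonal = bur[["clonal"]], subclonal = bur[["subclonal"]],
      total_neo = bur[["total"]], n_lineages = length(sim$tumor$N),
      rank1_R = rk1$R, rank1_clonality = rk1$clonality, rank1_cwi = rk1$product,
      peptidome_entropy = immunopeptidome_entropy(sim),
      tcr_entropy = if (length(sz)) tcr_entropy(sz) else NA_real_)
    if (keep_states) states[[t]] <- sim
    for (s in strengths %||% numeric(0)) {
      tr <- run_icb(sim, strength = s, duration = duration,
                    seed = derive_seed(master_seed, t, 1000L + round(100 * s)))
      treatments[[length(treatments) + 1L]] <-
        data.frame(tumor = t, strength = s,
                   max_shrinkage = tr$summary$max_shrinkage,
                   responder = tr$summary$responder,
                   new_reactive_lineages = tr$summary$new_reactive_lineages,
                   immunoediting_fc = tr$summary$immunoediting_fc,
                   entropy_pre = tr$summary$entropy_pre,
                   entropy_post = tr$summary$entropy_post)
      top5[[sprintf("tumor%d_strength%g", t, s)]] <- tr$trajectory$top5_sum
    }
  }
  structure(list(
    tumors = do.call(rbind, tumors),
    treatments = if (length(treatments)) do.call(rbind, treatments) else NULL,
    top5 = top5, n_redrawn = n_redrawn, states = states,
    master_seed = master_seed, preset_name = preset$name),
    class = "ip_cohort")
}

#' @exportS3Method base::print
print.ip_cohort <- function(x, ...) {
  cat("<ip_cohort>", x$preset_name, "-", nrow(x$tumors), "tumor(s)\n")
  ok <- x$tumors$reached
  cat(sprintf("  reached target: %d/%d (%d redraw(s))\n",
              sum(ok), length(ok), x$n_redrawn))
  if (!is.null(x$treatments)) {
    agg <- stats::aggregate(responder ~ strength, data = x$treatments, FUN = mean)
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  ICB %gx: response rate %.2f\n",
                  agg$strength[i], agg$responder[i]))
  }
  invisible(x)
}
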