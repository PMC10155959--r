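# closed-form logistic solution with constant net rate kg (1 - fdie)
logistic_oracle <- function(t, N0, K, kg, fdie) {
  r <- kg * (1 - fdie)
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

# build a small fixed two-lineage / three-neoantigen tumor-immune system and
# return the full naive ODE right-hand side (every clone an explicit state),
# independent of the package's reduced integrator
make_toy_system <- function() {
  # lineage 1 presents antigens 1,2; lineage 2 presents antigens 2,3
  pres <- rbind(c(1, 1, 0),
                c(0, 1, 1))
  R <- c(0.6, 0, 0.25)
  pars <- list(kg = 0.02, fdie = 0.3, K = 5e11,
               kin = 0.01, fout = 0.3, CTL_ss = 1e11,
               Td = 0.05, Ta = 3e-2, k_kill = 0.7, k_mag = 1, icb = 1)
  y0 <- c(N = c(2e9, 5e8), CTL = c(32, 8, 16), NSCTL = 1e11 - 56, C = 1)
  rhs <- function(t, y, p) {
    N <- pmax(y[1:2], 0); CTL <- pmax(y[3:5], 0)
    NSCTL <- max(y[6], 0); C <- max(y[7], 0)
    raw <- as.numeric(t(pres) %*% N)
    S <- R * raw
    react <- as.numeric(pres %*% CTL)
    phi <- react / (NSCTL + react)
    x <- phi * p$k_kill
    kd <- p$fdie + (p$k_mag + 1 - p$fdie) * x / (1 + x^2)
    dN <- p$kg * N * (1 - sum(N) / p$K) * (1 - kd)
    dCTL <- CTL * p$Td * (C - 1) + p$icb * S * p$Ta * C
    dNS <- NSCTL * p$Td * (C - 1)
    dC <- p$kin - p$kin * p$fout -
      p$kin * (1 - p$fout) * (NSCTL + sum(CTL)) / (p$icb * p$CTL_ss)
    list(c(dN, dCTL, dNS, dC))
  }
  list(pres = pres, R = R, pars = pars, y0 = y0, rhs = rhs)
}

# package sim assembled to match make_toy_system exactly (events disabled)
make_toy_sim <- function() {
  toy <- make_toy_system()
  pr <- preset("human_nsclc")
  pr$events_enabled <- FALSE
  registry <- data.frame(id = 1:3, R = toy$R, mhc_allele = 0:2,
                         origin = "founder", day_gained = 0,
                         stringsAsFactors = FALSE)
  tumor <- immunoprey:::new_tumor_state(
    N = c(2e9, 5e8),
    expr = list(c(1L, 2L), c(2L, 3L)),
    mhc = matrix(TRUE, 2, 3), registry = registry)
  tumor$base_gain_rate <- 0
  sim <- new_simulation(pr, panel = NULL, seed = 1)
  sim$tumor <- tumor
  s0 <- c(32, 8, 16)
  sim$immune <- list(s0 = s0, lam0 = numeric(3), active = toy$R > 0,
                     ctl_active = s0[toy$R > 0], Lambda = 0,
                     NSCTL = 1e11 - 56, C = 1)
  sim$preset <- pr
  sim <- immunoprey:::rebuild_structures(sim)
  sim$traj <- list(); sim$day <- 0L
  sim <- immunoprey:::record_day(sim)
  sim
}

# small human preset that grows quickly to a small target (for event-path and
# sensitivity tests); scientifically a "fast" toy condition, not a study one
fast_human_preset <- function(...) {
  preset("human_nsclc", overrides = list(kg = 0.5, ...))
}
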