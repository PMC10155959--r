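test_that("diameter/cell conversions are exact inverses with the 4 pL cell", {
  # a 200 mm^3 (0.2 cm^3) tumor holds ~4.77e7 cells
  d200 <- (6 * 0.2 / pi)^(1 / 3)
  expect_equal(diameter_to_cells(d200), 0.2 / 4.19e-9, tolerance = 1e-12)
  expect_equal(diameter_to_cells(d200) / 4.77e7, 1, tolerance = 0.01)
  expect_equal(diameter_to_cells(5), (pi / 6) * 125 / 4.19e-9, tolerance = 1e-12)
  d <- c(0.3, 1.5, 5)
  expect_equal(cells_to_diameter(diameter_to_cells(d)), d, tolerance = 1e-12)
  expect_error(diameter_to_cells(0), "positive")
  expect_error(cells_to_diameter(-1), "positive")
})

test_that("lineage derivative follows modified logistic growth", {
  mp <- tumor_params(kg = 0.2, K = 7e8)
  # at carrying capacity the logistic factor vanishes regardless of kd
  expect_equal(lineage_derivative(1e6, 7e8, 5, mp), 0)
  # kd = 1 freezes the lineage
  expect_equal(lineage_derivative(1e6, 1e6, 1, mp), 0)
  # direct substitution oracle
  expect_equal(lineage_derivative(4.77e7, 4.77e7, 0.3, mp),
               0.2 * 4.77e7 * (1 - 4.77e7 / 7e8) * 0.7, tolerance = 1e-12)
  expect_equal(lineage_derivative(4.77e7, 4.77e7, 0.3, mp), 6.22e6,
               tolerance = 1e-3)
  # kd > 1 shrinks below capacity
  expect_lt(lineage_derivative(1e6, 2e6, 1.5, mp), 0)
})

make_two_lineage_state <- function() {
  registry <- data.frame(id = 1:5, R = c(0.5, 0, 0.8, 0, 0.2),
                         mhc_allele = c(0L, 1L, 2L, 0L, 1L),
                         origin = "founder", day_gained = 0,
                         stringsAsFactors = FALSE)
  immunoprey:::new_tumor_state(
    N = c(100, 50),
    expr = list(1:5, c(1L, 2L, 3L)),
    mhc = matrix(TRUE, 2, 3), registry = registry)
}

test_that("presented cells combine expression, MHC intactness and R", {
  st <- make_two_lineage_state()
  pc <- presented_cells(st)
  expect_equal(pc$raw, c(150, 150, 150, 100, 100))
  expect_equal(pc$S, c(0.5, 0, 0.8, 0, 0.2) * pc$raw)
  # single lineage oracle: N = 100, R = 0.5 -> S = 50
  st1 <- st; st1$N <- c(100, 0)
  expect_equal(presented_cells(st1)$S[1], 50)
  # MHC loss silences all antigens on that allele despite expression
  st2 <- st; st2$mhc[1, 1] <- FALSE
  pc2 <- presented_cells(st2)
  expect_equal(pc2$raw[1], 50)   # allele 0 lost in lineage 1
  expect_equal(pc2$raw[4], 0)    # antigen 4 only expressed in lineage 1
  # expression loss silences the antigen
  st3 <- st; st3$expr[[1]] <- c(2L, 3L, 4L, 5L)
  expect_equal(presented_cells(st3)$raw[1], 50)
})

test_that("gain-rate sampling conventions", {
  tp <- tumor_params()
  tp0 <- tumor_params(nGS = 0, nGSt = 0)
  set.seed(1)
  expect_equal(sample_tumor_gain_rate(tp0), tp0$nG)
  expect_equal(daily_gain_rate(tp0$nG, tp0), tp0$nG)
  set.seed(2)
  base <- replicate(20000, sample_tumor_gain_rate(tp))
  # median-preserving convention: sample median ~ nG
  expect_equal(median(base) / tp$nG, 1, tolerance = 0.05)
  # ln-sd 2.303 = one decade: ~68% of base rates within 10x of nG
  expect_equal(mean(base > tp$nG / 10 & base < tp$nG * 10), 0.683,
               tolerance = 0.02)
  # zero rate short-circuits
  expect_identical(sample_tumor_gain_rate(tumor_params(nG = 0)), 0)
})

test_that("daily events: eligibility, rates and coalesced-per-lineage law", {
  st <- make_two_lineage_state()
  tp0 <- tumor_params(nG = 0, nL = 0, hlaL = 0)
  expect_equal(nrow(draw_daily_events(st, 0, tp0)), 0)
  # all alleles lost -> no MHC loss events even at huge rate
  st_lost <- st
  st_lost$mhc[] <- FALSE
  tp <- tumor_params(nG = 0, nL = 0, hlaL = 1)
  set.seed(1)
  ev <- draw_daily_events(st_lost, 0, tp)
  expect_false(any(ev$type == "mhc_loss"))
  # per-lineage event probability equals 1 - exp(-rate N dt)
  st1 <- make_two_lineage_state()
  st1$N <- c(1e9, 0)
  tpl <- tumor_params(nG = 0, nL = 1.68e-9, hlaL = 0)
  set.seed(42)
  hits <- replicate(4000, sum(draw_daily_events(st1, 0, tpl)$type == "loss"))
  p_expect <- 1 - exp(-1.68e-9 * 1e9)
  expect_lt(abs(mean(hits) - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / 4000))
  # lineages below one cell generate no events
  st1$N <- c(0.9, 0.9)
  expect_equal(nrow(draw_daily_events(st1, 1, tumor_params(nL = 1, hlaL = 1))), 0)
})

test_that("event application conserves cells and branches by one modification", {
  st <- make_two_lineage_state()
  tot0 <- sum(st$N)
  # loss event
  res <- apply_event(st, list(type = "loss", lineage = 1, target = 3))
  expect_true(res$applied)
  st2 <- res$state
  expect_equal(sum(st2$N), tot0)
  expect_equal(length(st2$N), 3)
  expect_identical(st2$expr[[3]], c(1L, 2L, 4L, 5L))
  expect_equal(st2$N[3], 1)
  expect_equal(st2$N[1], 99)
  # MHC loss removes all antigens on that allele from the child peptidome
  res <- apply_event(st, list(type = "mhc_loss", lineage = 1, target = 1))
  child <- res$state
  p <- immunoprey:::lineage_peptidome(child, 3)
  expect_false(any(child$registry$mhc_allele[p] == 0L))
  expect_equal(sum(child$N), tot0)
  # gain event extends the registry and the child expression set
  fac <- function(id) data.frame(id = id, R = 0.4, mhc_allele = 1L,
                                 origin = "gained", affinity_nM = 10,
                                 stability_h = 2, agretopicity = 1,
                                 tpm = 0.1, foreignness = 0)
  res <- apply_event(st, list(type = "gain", lineage = 2, target = NA), fac)
  st3 <- res$state
  expect_equal(nrow(st3$registry), 6)
  expect_equal(res$new_antigen_id, 6L)
  expect_identical(st3$expr[[3]], c(1L, 2L, 3L, 6L))
  expect_equal(sum(st3$N), tot0)
  # events on sub-one-cell parents are discarded
  st$N[1] <- 0.5
  res <- apply_event(st, list(type = "loss", lineage = 1, target = 1))
  expect_false(res$applied)
  expect_identical(res$state$N, st$N)
})

test_that("founder initialization matches the species conventions", {
  pan <- generate_fixture("bbn963", seed = 1)
  prm <- preset("mouse_c57bl6")
  st <- init_founder(prm, pan)
  expect_equal(sum(st$N), 4.77e7)
  expect_equal(length(st$N), 1)
  expect_true(all(st$mhc))
  expect_equal(nrow(st$registry), 34)
  # human founder: one cell, clonal MHC loss at rate hlaL0
  prh <- preset("human_nsclc")
  set.seed(8)
  st <- init_founder(prh)
  expect_equal(sum(st$N), 1)
  set.seed(9)
  lost <- sample_clonal_mhc_loss(20000, 0.14, 3)
  frac <- mean(!is.na(lost))
  expect_lt(abs(frac - 0.14), 3 * sqrt(0.14 * 0.86 / 20000))
  expect_true(all(lost[!is.na(lost)] %in% 1:3))
  # hlaL0 = 0: all alleles intact
  pr0 <- preset("human_nsclc", overrides = list(hlaL0 = 0))
  set.seed(10)
  st0 <- init_founder(pr0)
  expect_true(all(st0$mhc))
})

test_that("clonal/subclonal counting: lineage and cell-weighted forms", {
  st <- make_two_lineage_state()  # lineage 1: antigens 1-5; lineage 2: 1-3
  expect_equal(clonal_subclonal_burden(st),
               c(clonal = 3, subclonal = 2, total = 5))
  # single lineage: everything clonal
  st1 <- st; st1$N <- c(100, 0.5)  # lineage 2 below living threshold
  expect_equal(clonal_subclonal_burden(st1),
               c(clonal = 5, subclonal = 0, total = 5))
  # antigen lost everywhere is excluded
  st2 <- st
  st2$expr <- list(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L))
  expect_equal(clonal_subclonal_burden(st2),
               c(clonal = 3, subclonal = 1, total = 4))
  # cell-weighted: a tiny branch does not demote a near-fixed antigen
  st3 <- st
  st3$N <- c(1e6, 1)  # antigens 4,5 in 99.9999% of cells
  expect_equal(clonal_subclonal_burden(st3, method = "cells"),
               c(clonal = 5, subclonal = 0, total = 5))
  st3$N <- c(100, 50) # antigens 4,5 in 2/3 of cells
  expect_equal(clonal_subclonal_burden(st3, method = "cells"),
               c(clonal = 3, subclonal = 2, total = 5))
  st_dead <- st; st_dead$N <- c(0, 0)
  expect_error(clonal_subclonal_burden(st_dead), "living")
})
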