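test_that("shrinkage and response classification with inclusive 30% boundary", {
  # monotone growth: shrinkage negative, non-responder
  up <- data.frame(day = 0:3, diameter_cm = c(5, 5.1, 5.2, 5.3))
  expect_lt(max_shrinkage(up), 0)
  expect_false(classify_response(max_shrinkage(up)))
  # diameter basis: d0 = 5, min 3.5 -> exactly 0.30, responder (inclusive)
  dd <- data.frame(day = 0:2, diameter_cm = c(5, 4.2, 3.5))
  expect_equal(max_shrinkage(dd, basis = "diameter"), 0.30)
  expect_true(classify_response(0.30))
  expect_equal(max_shrinkage(data.frame(day = 0:1, diameter_cm = c(5, 4.9)),
                             basis = "diameter"), 0.02, tolerance = 1e-12)
  expect_false(classify_response(0.02))
  # volume basis is the diameter ratio cubed
  expect_equal(max_shrinkage(dd), 1 - (3.5 / 5)^3, tolerance = 1e-12)
  expect_false(classify_response(NA))
  expect_error(max_shrinkage(data.frame(day = 0, diameter_cm = 5)), "baseline")
})

make_rank1_state <- function(N, expr, R) {
  registry <- data.frame(id = seq_along(R), R = R,
                         mhc_allele = rep(0L, length(R)),
                         origin = "founder", day_gained = 0,
                         stringsAsFactors = FALSE)
  immunoprey:::new_tumor_state(N = N, expr = expr,
                               mhc = matrix(TRUE, length(N), 3),
                               registry = registry)
}

test_that("rank-1 metrics: argmax R with clonality weighting and tie rules", {
  # single clonal antigen R = 0.8 in all cells
  st <- make_rank1_state(100, list(1L), R = 0.8)
  rk <- rank1_metrics(st)
  expect_equal(c(rk$R, rk$clonality, rk$product), c(0.8, 1, 0.8))
  # present in half the cells
  st <- make_rank1_state(c(50, 50), list(1L, integer(0)), R = 0.8)
  rk <- rank1_metrics(st)
  expect_equal(c(rk$R, rk$clonality, rk$product), c(0.8, 0.5, 0.4))
  # all R = 0: degenerate flag
  st <- make_rank1_state(100, list(c(1L, 2L)), R = c(0, 0))
  rk <- rank1_metrics(st)
  expect_true(rk$degenerate)
  expect_equal(c(rk$R, rk$clonality, rk$product), c(0, 0, 0))
  # ties broken by higher clonality, then lower id
  st <- make_rank1_state(c(60, 40), list(c(1L, 2L), 2L), R = c(0.5, 0.5))
  expect_equal(rank1_metrics(st)$id, 2L)
  st <- make_rank1_state(c(60, 40), list(c(1L, 2L), c(1L, 2L)), R = c(0.5, 0.5))
  expect_equal(rank1_metrics(st)$id, 1L)
})

test_that("biomarker threshold maximizes Youden's J in either direction", {
  # perfectly separating metric
  m <- c(1, 2, 3, 10, 11, 12)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  bs <- biomarker_sens_spec(m, lab)
  expect_equal(c(bs$sensitivity, bs$specificity), c(1, 1))
  # inverted labels give the same |J| with the reversed direction
  bs2 <- biomarker_sens_spec(m, !lab)
  expect_equal(bs2$youden, bs$youden)
  expect_false(bs2$direction == bs$direction)
  # label-independent metric: J near 0 on a large sample
  set.seed(4)
  m <- rnorm(4000)
  lab <- rep(c(TRUE, FALSE), 2000)
  bs3 <- biomarker_sens_spec(m, lab)
  expect_lt(bs3$youden, 0.12)
  expect_error(biomarker_sens_spec(m, rep(TRUE, 4000)), "non-responders")
})

test_that("immunopeptidome entropy over presented-cell weights", {
  st <- make_rank1_state(100, list(1L), R = 0.8)
  expect_equal(immunopeptidome_entropy(st), 0)
  st <- make_rank1_state(c(50, 50), list(c(1L, 2L), c(1L, 3L)), R = c(0, 0, 0))
  # weights (100, 50, 50)/200 = (0.5, 0.25, 0.25)
  expect_equal(immunopeptidome_entropy(st),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(immunopeptidome_entropy(st), 1.0397, tolerance = 1e-4)
  # two antigens presented by equal cell numbers
  st <- make_rank1_state(100, list(c(1L, 2L)), R = c(0, 0))
  expect_equal(immunopeptidome_entropy(st), log(2))
  # lineage weighting counts lineages, not cells
  st <- make_rank1_state(c(90, 10), list(1L, 2L), R = c(0, 0))
  expect_equal(immunopeptidome_entropy(st, weighting = "lineage"), log(2))
})

test_that("entropy-tail response fractions satisfy the partition identity", {
  ent <- c(5, 4, 3, 2, 1, 0.5, 0.2, 0.1)
  resp <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  # all responders: both tails are 1
  both <- entropy_percentile_response(ent, rep(TRUE, 8), X = 25)
  expect_equal(unname(both), c(1, 1))
  # X = 50 partitions the cohort: weighted tail average = overall rate
  tails <- entropy_percentile_response(ent, resp, X = 50)
  expect_equal(mean(tails), mean(resp))
  expect_error(entropy_percentile_response(ent, resp, X = 60), "X must")
  # independence: tail fractions near the overall rate (binomial oracle)
  set.seed(2)
  n <- 2000
  ent <- runif(n); resp <- runif(n) < 0.4
  t2 <- entropy_percentile_response(ent, resp, X = 25)
  se <- sqrt(0.4 * 0.6 / (n / 4))
  expect_lt(max(abs(t2 - 0.4)), 4 * se)
})

test_that("top-5 trajectory normalization and new-lineage counting", {
  curves <- list(a = c(10, 12, 14), b = c(30, 30, 20))
  norm <- top5_trajectory(curves)
  # day-0 cohort mean of normalized curves is 1 by construction
  expect_equal(mean(vapply(norm, function(v) v[1], numeric(1))), 1)
  expect_equal(norm$a, c(10, 12, 14) / 20)
  expect_error(top5_trajectory(list(c(0, 1), c(0, 2))), "baseline")
  # frozen clones give a flat curve
  expect_equal(top5_trajectory(list(c(7, 7, 7)))[[1]], rep(7 / 7, 3))
})

test_that("correlation wrapper matches the closed-form product-moment formula", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(2.0, 3.9, 2.5, 6.2, 4.0)
  # independent oracle: direct computation of Pearson's r
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$estimate, r_hand, tolerance = 1e-12)
  # perfect linear relation
  expect_equal(correlate(x, 2 * x)$estimate, 1, tolerance = 1e-12)
  # monotone nonlinearity: Spearman 1, Pearson < 1
  expect_equal(correlate(x, x^3, method = "spearman")$estimate, 1)
  expect_lt(correlate(x, x^3)$estimate, 1)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(x, y[1:3]), "equal length")
  # independent inputs: small correlation, non-significant
  set.seed(6)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(correlate(a, b)$estimate), 0.1)
})

test_that("local sensitivity: delta = 0 null case, matched seeds, key checks", {
  pr <- fast_human_preset()
  sens <- local_sensitivity(pr, parameters = c("nL", "cellVol"), delta = 0,
                            n = 3, target_d = 0.15, master_seed = 5,
                            max_days = 300)
  expect_true(all(sens$table$mean_fold_change == 1))
  expect_true(all(is.na(sens$anova$p) | sens$anova$p > 0.99))
  expect_error(local_sensitivity(pr, parameters = "kG", n = 3), "unknown")
  expect_error(local_sensitivity(pr, parameters = "nL", n = 1), "at least 2")
})
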