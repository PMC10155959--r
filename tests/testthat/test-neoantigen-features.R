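test_that("feature sampling: empty case, marginals and copula dependence", {
  expect_equal(nrow(sample_features(0)), 0)
  expect_error(sample_features(-1), "nonnegative")

  set.seed(11)
  n <- 40000
  f <- sample_features(n)
  # transcript abundance is exponential with the rate parameterization:
  # analytic mean 1/6.6625 = 0.150094
  se <- (1 / 6.6625) / sqrt(n)  # exponential: sd = mean
  expect_lt(abs(mean(f$tpm) - 1 / 6.6625), 3 * se)

  # re-fitting a Gaussian copula recovers all three off-diagonal entries
  rho_hat <- fit_gaussian_copula(log(f[, c("affinity_nM", "stability_h",
                                           "agretopicity")]))
  rho <- default_rho()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    se_r <- (1 - rho[pair[1], pair[2]]^2) / sqrt(n)
    expect_lt(abs(rho_hat[pair[1], pair[2]] - rho[pair[1], pair[2]]), 3 * se_r)
  }

  # non-positive-definite rho is rejected
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(tesla_feature_params(rho = bad), "positive definite")
})

test_that("foreignness mixture: inflation masses and interior beta law", {
  p <- tesla_feature_params()
  set.seed(7)
  n <- 100000
  x <- sample_foreignness(n, p)
  expect_true(all(x >= 0 & x <= 1))
  se1 <- sqrt(p$phat1 * (1 - p$phat1) / n)
  expect_lt(abs(mean(x == 0) - p$phat1), 3 * se1)
  se2 <- sqrt(p$phat2 * (1 - p$phat2) / n)
  # beta tail above 0.99 is negligible at these shapes
  expect_lt(abs(mean(x > 0.99) - p$phat2), 3 * se2 + pbeta(0.99, p$alpha, p$beta,
                                                           lower.tail = FALSE))
  # interior draws follow Beta(alpha, beta) (KS at alpha = 0.01)
  interior <- x[x > 0 & x < 0.99]
  ks <- suppressWarnings(ks.test(interior[seq_len(10000)], pbeta,
                                 p$alpha, p$beta))
  expect_gt(ks$p.value, 0.01)

  # degenerate mixture
  all0 <- sample_foreignness(500, tesla_feature_params(phat1 = 1, phat2 = 0))
  expect_true(all(all0 == 0))
  expect_error(tesla_feature_params(phat1 = 0.8, phat2 = 0.3), "phat")
})

test_that("TESLA criteria use strict inequalities over all four features", {
  mk <- function(aff, stab, agre, forn)
    data.frame(affinity_nM = aff, stability_h = stab, agretopicity = agre,
               foreignness = forn)
  expect_true(passes_tesla(mk(10, 2.0, 0.5, 0)))
  expect_false(passes_tesla(mk(34, 2.0, 0.5, 0)))   # boundary exclusive
  expect_false(passes_tesla(mk(10, 1.4, 0.5, 0)))
  expect_false(passes_tesla(mk(10, 2.0, 0.05, 0)))
  expect_false(passes_tesla(mk(10, 2.0, 0.5, 1e-16)))
  # direction flag flips the foreignness comparison
  crit_hi <- tesla_criteria(foreignness_direction = "above")
  expect_true(passes_tesla(mk(10, 2.0, 0.5, 0.5), crit_hi))
  expect_false(passes_tesla(mk(10, 2.0, 0.5, 0), crit_hi))
  expect_error(passes_tesla(data.frame(affinity_nM = 1)), "missing columns")
})

test_that("immunogenicity: R = 0 iff TESLA fail; truncated-exponential law", {
  expect_identical(assign_immunogenicity(c(FALSE, FALSE)), c(0, 0))
  set.seed(3)
  n <- 100000
  r <- assign_immunogenicity(rep(TRUE, n), epsilon = 6)
  expect_true(all(r > 0 & r <= 1))
  # analytic mean of density ~ exp(-6x) on [0,1]: 1/6 - e^-6/(1 - e^-6)
  m <- 1 / 6 - exp(-6) / (1 - exp(-6))
  expect_equal(mean(r), m, tolerance = 0.01)
  ks <- suppressWarnings(ks.test(r[seq_len(10000)],
                                 function(q) immunoprey:::ptruncexp(q, 6)))
  expect_gt(ks$p.value, 0.01)
  # epsilon -> 0 limit: uniform on [0,1]
  r0 <- assign_immunogenicity(rep(TRUE, 50000), epsilon = 1e-9)
  expect_equal(mean(r0), 0.5, tolerance = 0.01)
  expect_error(assign_immunogenicity(TRUE, epsilon = 0), "positive")
})

test_that("founder clonal burden is rounded gamma with the configured shape/scale", {
  set.seed(5)
  n <- 100000
  b <- sample_founder_clonal_burden(n)
  expect_true(all(b >= 0 & b == round(b)))
  # gamma mean = shape * scale = 1.14 * 56.24 = 64.11; sd = sqrt(shape)*scale
  se <- sqrt(1.14) * 56.24 / sqrt(n)
  expect_lt(abs(mean(b) - 1.14 * 56.24), 3 * se + 0.5)  # 0.5 rounding slack
  expect_identical(sample_founder_clonal_burden(10, g2 = 0), numeric(10))
  # MLE on raw draws recovers the shape
  raw <- sample_founder_clonal_burden(n, round = FALSE)
  fit <- MASS::fitdistr(raw, "gamma")
  expect_equal(unname(fit$estimate["shape"]), 1.14,
               tolerance = 3 * unname(fit$sd["shape"]) / 1.14 + 0.005)
})

test_that("ELISpot scaling is min-max with all-zero degenerate case", {
  expect_equal(elispot_to_immunogenicity(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(elispot_to_immunogenicity(c(3, 3, 3)), c(0, 0, 0))
  expect_equal(elispot_to_immunogenicity(c(0, 1, 2, 4)), c(0, 0.25, 0.5, 1))
  expect_error(elispot_to_immunogenicity(c(-1, 2)), "nonnegative")
  expect_error(elispot_to_immunogenicity(numeric(0)), "at least one")
})

test_that("make_neoantigens: ids, alleles, and R > 0 iff TESLA pass", {
  expect_equal(nrow(make_neoantigens(0)), 0)
  set.seed(9)
  n <- 30000
  ants <- make_neoantigens(n, n_alleles = 3)
  expect_identical(ants$id, seq_len(n))
  expect_true(all(ants$mhc_allele %in% 0:2))
  tab <- tabulate(ants$mhc_allele + 1L, 3)
  expect_lt(max(abs(tab / n - 1 / 3)), 3 * sqrt((1 / 3) * (2 / 3) / n))
  # dual route: fraction with R > 0 vs an independent pass estimate from
  # sample_features + passes_tesla on a fresh sample
  pass_hat <- mean(passes_tesla(sample_features(n)))
  se <- sqrt(pass_hat * (1 - pass_hat) / n)
  expect_lt(abs(mean(ants$R > 0) - pass_hat), 4 * se)
  # R > 0 iff the stored features pass
  expect_identical(ants$R > 0, unname(passes_tesla(ants)))
  expect_warning(make_neoantigens(5, n_alleles = 4), "n_alleles")
})

test_that("sampling is seed-reproducible", {
  set.seed(42); a <- sample_features(500)
  set.seed(42); b <- sample_features(500)
  expect_identical(a, b)
  set.seed(42); p1 <- make_neoantigens(100)
  set.seed(42); p2 <- make_neoantigens(100)
  expect_identical(p1, p2)
})
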