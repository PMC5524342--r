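test_that("permutation p-value follows (r + 1) / (B + 1) and its bounds", {
  g <- make_geno(24, 6, seed = 3, density = 0.15)
  set.seed(4)
  y <- sample(rep(c(1L, 0L), each = 12))
  fit <- doestrare(g, y, perms = 99, seed = 11, quiet = TRUE)
  expect_equal(fit$p.value, (fit$exceedances + 1) / (99 + 1))
  expect_gte(fit$p.value, 1 / 100)
  expect_lte(fit$p.value, 1)

  # independent recomputation: regenerate the same permutation stream and
  # re-count exceedances through the one-labeling statistic path
  g2 <- drop_monomorphic(g)
  obs <- doestrare_statistic(g2, y, bw = fit$bandwidth)$statistic
  set.seed(11)
  r <- 0L
  for (b in 1:99) {
    yp <- y[sample.int(length(y))]
    sb <- doestrare_statistic(g2, yp, bw = fit$bandwidth)$statistic
    if (sb >= obs) r <- r + 1L
  }
  expect_identical(fit$exceedances, r)
})

test_that("label-balanced duplicated data give p = 1 (all permutations tie or exceed)", {
  set.seed(9)
  x_half <- matrix(rbinom(6 * 5, 2, 0.25), nrow = 6)
  x_half[1, 1] <- max(x_half[1, 1], 1L)
  g <- region_genotypes(rbind(x_half, x_half),
                        sort(sample.int(3000, 5)), 3000)
  y <- c(rep(1L, 6), rep(0L, 6))
  fit <- doestrare(g, y, perms = 200, seed = 5, quiet = TRUE)
  expect_equal(fit$statistic, 0, tolerance = 1e-14)
  expect_equal(fit$p.value, 1)
})

test_that("the permutation stream is reproducible from the seed", {
  g <- make_geno(30, 8, seed = 21, density = 0.1)
  set.seed(22)
  y <- sample(rep(c(1L, 0L), each = 15))
  f1 <- doestrare(g, y, perms = 150, seed = 77, quiet = TRUE)
  f2 <- doestrare(g, y, perms = 150, seed = 77, quiet = TRUE)
  expect_identical(f1$p.value, f2$p.value)
  expect_identical(f1$exceedances, f2$exceedances)
})

test_that("null p-values are super-uniform (permutation validity)", {
  n_rep <- 200
  pvals <- numeric(n_rep)
  set.seed(123)
  rep_seeds <- sample.int(1e6, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r])
    pool <- make_test_pool(seed = rep_seeds[r], n_variants = 8,
                           n_haplotypes = 400)
    dat <- sample_case_control(pool, integer(0), n_cases = 30,
                               n_controls = 30)
    fit <- doestrare(dat$geno, dat$phenotypes, perms = 99, quiet = TRUE)
    pvals[r] <- fit$p.value
  }
  expect_true(all(!is.na(pvals)))
  for (alpha in c(0.01, 0.05, 0.1)) {
    mc_tol <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(pvals <= alpha), alpha + mc_tol)
  }
})

test_that("adaptive permutation stops early with r_stop = ceil(1/c^2) exceedances", {
  g <- make_geno(40, 8, seed = 31, density = 0.12)
  set.seed(32)
  y <- sample(rep(c(1L, 0L), each = 20))
  # a null-ish labeling has moderate-to-large p: with c = 0.2 (r_stop = 25)
  # and fine-grained batches, the expected permutation count is ~ 25 / p
  std <- doestrare(g, y, perms = 2000, seed = 55, quiet = TRUE)
  ada <- doestrare(g, y, adaptive = TRUE, precision = 0.2, alpha = 0.05,
                   max_perms = 2000, batch_size = 25, seed = 55,
                   quiet = TRUE)
  r_stop <- ceiling(1 / 0.2^2)
  expect_identical(r_stop, 25)
  if (!ada$hit_max_perms) {
    expect_gte(ada$exceedances, r_stop)
    expect_lt(ada$permutations, 2000)
    # negative-binomial expectation check, generous factor-3 band
    expect_lt(ada$permutations, 3 * r_stop / std$p.value + 2 * 25)
  }
  expect_equal(ada$p.value, (ada$exceedances + 1) / (ada$permutations + 1))
})

test_that("adaptive permutation falls back to the full budget when r_stop is unreachable", {
  pool <- make_test_pool(seed = 61, n_variants = 10, n_haplotypes = 600,
                         maf_range = c(0.05, 0.2))
  causal <- select_drvs(pool, scenario_spec("one_cluster", 0.5,
                                            odds_ratio = 8))
  dat <- sample_case_control(pool, causal,
                             model = scenario_spec("one_cluster", 0.5,
                                                   odds_ratio = 8),
                             n_cases = 150, n_controls = 150, seed = 62)
  ada <- doestrare(dat$geno, dat$phenotypes, adaptive = TRUE,
                   precision = 0.2, alpha = 1e-4, max_perms = 60,
                   batch_size = 20, seed = 63, quiet = TRUE)
  expect_true(ada$hit_max_perms)
  expect_identical(ada$permutations, 60L)
  expect_equal(ada$p.value, (ada$exceedances + 1) / 61)
})

test_that("adaptive and standard procedures share the permutation stream", {
  g <- make_geno(36, 7, seed = 71, density = 0.12)
  set.seed(72)
  y <- sample(rep(c(1L, 0L), each = 18))
  std <- doestrare(g, y, perms = 100, seed = 99, quiet = TRUE)
  ada <- doestrare(g, y, adaptive = TRUE, precision = 0.2,
                   max_perms = 100, batch_size = 100, seed = 99,
                   quiet = TRUE)
  # one batch of 100 permutations consumes the RNG exactly like B = 100
  expect_identical(ada$exceedances, std$exceedances)
  expect_identical(ada$p.value, std$p.value)

  ada2 <- doestrare(g, y, adaptive = TRUE, precision = 0.2,
                    max_perms = 100, batch_size = 100, seed = 99,
                    quiet = TRUE)
  expect_identical(ada$p.value, ada2$p.value)
})
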