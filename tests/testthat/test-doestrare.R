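test_that("control allele frequency uses the +1/+2 shrinkage and stays in (0,1)", {
  expect_equal(control_allele_frequency(0, 500), 1 / 1002)
  n <- 37
  expect_equal(control_allele_frequency(2 * n, n), (2 * n + 1) / (2 * n + 2))
  expect_lt(control_allele_frequency(2 * n, n), 1)
  expect_equal(control_allele_frequency(10, 167), 11 / 336)
  expect_error(control_allele_frequency(11, 5), "m_control")
})

test_that("binomial-tail variant weights match closed forms and term sums", {
  expect_equal(variant_weight(10, 5, 0.3), 1)       # full CDF at m = 2 n_case
  q <- 0.013
  expect_equal(variant_weight(0, 8, q), (1 - q)^16) # single-term closed form
  expect_equal(variant_weight(3, 5, 0.1), oracle_binom_cdf(3, 10, 0.1))
  expect_error(variant_weight(1, 5, 1.2), "q must")
})

test_that("variant weight is monotone in the count and in q (exhaustive sweep)", {
  for (n_case in 1:10) {           # 2 * n_case up to 20
    for (q in c(0.001, 0.01, 0.1, 0.4, 0.9)) {
      w <- variant_weight(0:(2 * n_case), n_case, q)
      expect_true(all(diff(w) >= 0))
      expect_true(all(w >= 0 & w <= 1))
      # exact agreement with term-by-term summation
      expected <- vapply(0:(2 * n_case),
                         function(m) oracle_binom_cdf(m, 2 * n_case, q),
                         numeric(1))
      expect_equal(w, expected, tolerance = 1e-12)
    }
    # non-increasing in q at fixed count
    m <- n_case
    wq <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.8),
                 function(q) variant_weight(m, n_case, q), numeric(1))
    expect_true(all(diff(wq) <= 0))
  }
})

test_that("density weights normalize counts and reject empty groups", {
  expect_equal(density_weights(c(2, 0, 2)), c(0.5, 0, 0.5))
  expect_equal(density_weights(5), 1)
  expect_error(density_weights(c(0, 0)), "no rare mutations")
  for (seed in 1:5) {
    set.seed(seed)
    m <- rpois(10, 2)
    if (sum(m) == 0) m[1] <- 1
    expect_equal(sum(density_weights(m)), 1, tolerance = 1e-12)
  }
})

test_that("position density matches the weighted Gaussian kernel formula", {
  # single variant: peak value 1/(bw * sqrt(2 pi)) at the variant position
  dc <- position_density(5000, 1, bw = 100, grid_size = 1001,
                         region_length = 10000)
  expect_s3_class(dc, "density_curve")
  peak <- which.max(dc$values)
  expect_lt(abs(dc$grid[peak] - 5000), 10000 / 1000)
  expect_equal(dc$values[peak], 1 / (100 * sqrt(2 * pi)), tolerance = 1e-3)
  expect_true(all(dc$values >= 0))

  # mirror-image variants give a curve symmetric about the region midpoint
  sym <- position_density(c(3000, 10000 + 1 - 3000), c(0.5, 0.5), bw = 400,
                          grid_size = 1000, region_length = 10000)
  expect_equal(sym$values, rev(sym$values), tolerance = 1e-9)

  # random configurations against the double-loop oracle
  for (seed in 1:3) {
    set.seed(seed)
    pos <- sort(sample.int(10000, 10))
    w <- density_weights(rpois(10, 3) + (seq_len(10) == 1))
    bw <- runif(1, 50, 500)
    dc <- position_density(pos, w, bw, grid_size = 200,
                           region_length = 10000)
    expect_equal(dc$values, oracle_kde(dc$grid, pos, w, bw),
                 tolerance = 1e-10)
  }

  expect_error(position_density(10, 0.5, bw = 100, region_length = 100),
               "normalized")
})

test_that("burden component is the weighted mean allele frequency", {
  # uniform weights reduce to the simple mean of m / (2 n)
  m <- c(1, 4, 2)
  expect_equal(burden_component(m, rep(0.7, 3), 50), mean(m / 100))
  expect_equal(burden_component(4, 1, 100), 0.02)
  expect_equal(burden_component(c(2, 6), c(0.2, 0.8), 10),
               (0.2 * 0.1 + 0.8 * 0.3) / 1.0)
  expect_error(burden_component(m, c(0, 0, 0), 50), "degenerate")
})

test_that("silverman bandwidth is permutation-free, floored, and positive", {
  pos <- c(100L, 5000L, 9000L)
  bw <- silverman_bandwidth(pos, c(3, 5, 2), 10000)
  expect_gt(bw, 0)
  # single distinct position: spread is zero, floor kicks in
  expect_equal(silverman_bandwidth(5000L, 10, 10000), 100)
  expect_equal(silverman_bandwidth(pos, c(0, 1, 0), 10000), 100)
})

test_that("statistic is zero for label-balanced duplicated data", {
  set.seed(42)
  x_half <- matrix(rbinom(8 * 6, 2, 0.2), nrow = 8)
  x_half[1, 1] <- max(x_half[1, 1], 1L)     # ensure mutations present
  g <- region_genotypes(rbind(x_half, x_half),
                        sort(sample.int(5000, 6)), 5000)
  y <- c(rep(1L, 8), rep(0L, 8))            # each case has a control clone
  st <- doestrare_statistic(g, y)
  expect_equal(st$status, "ok")
  expect_equal(st$statistic, 0, tolerance = 1e-14)
  expect_equal(st$p_case, st$p_control)
})

test_that("well-separated clusters give STAT close to p_case + p_control", {
  # cases mutated only near 2000, controls only near 8000, bw << distance,
  # so the scaled curves have essentially disjoint supports
  n <- 40
  x <- matrix(0L, 2 * n, 4)
  x[1:10, 1] <- 1L; x[1:10, 2] <- 1L          # cases, positions 1900/2100
  x[(n + 1):(n + 10), 3] <- 1L; x[(n + 1):(n + 10), 4] <- 1L
  g <- region_genotypes(x, c(1900L, 2100L, 7900L, 8100L), 10000)
  y <- rep(c(1L, 0L), each = n)
  st <- doestrare_statistic(g, y, bw = 150, grid_size = 4000)
  expect_equal(st$statistic, st$p_case + st$p_control, tolerance = 1e-3)
})

test_that("statistic agrees with a 100x finer-grid Riemann oracle", {
  for (seed in 1:3) {
    g <- make_geno(30, 10, seed = seed, density = 0.1)
    set.seed(seed + 100)
    y <- sample(rep(c(1L, 0L), each = 15))
    bw <- max(g$region_length / 200, 120)
    st <- doestrare_statistic(g, y, bw = bw, grid_size = 1000)
    expect_equal(st$status, "ok")
    oracle <- oracle_stat_finegrid(g, y, bw = bw, fine = 1e5)
    expect_lt(abs(st$statistic - oracle) / oracle, 0.01)
  }
})

test_that("undefined statuses flag a mutation-free group", {
  x <- rbind(c(0L, 0L), c(1L, 2L))
  g <- region_genotypes(x, c(10L, 20L), 100)
  st_case_empty <- doestrare_statistic(g, c(1L, 0L))
  expect_equal(st_case_empty$status, "undefined_no_case_mutations")
  expect_true(is.na(st_case_empty$statistic))
  st_control_empty <- doestrare_statistic(g, c(0L, 1L))
  expect_equal(st_control_empty$status, "undefined_no_control_mutations")
  fit <- doestrare(g, c(1L, 0L), perms = 10, seed = 1)
  expect_equal(fit$status, "undefined_no_case_mutations")
  expect_true(is.na(fit$p.value))
})

test_that("scaling both burden components rescales STAT and preserves ranks", {
  # the statistic built from exported primitives, with the two burden
  # components multiplied by a common constant
  stat_scaled <- function(g, y, bw, const) {
    cc <- count_rare_alleles(g, y)
    q <- control_allele_frequency(cc$m_control, cc$n_control)
    w <- variant_weight(cc$m_case, cc$n_case, q)
    pa <- const * burden_component(cc$m_case, w, cc$n_case)
    pu <- const * burden_component(cc$m_control, w, cc$n_control)
    fa <- position_density(g$positions, density_weights(cc$m_case), bw,
                           grid_size = 500, region_length = g$region_length)
    fu <- position_density(g$positions, density_weights(cc$m_control), bw,
                           grid_size = 500, region_length = g$region_length)
    d <- abs(pa * fa$values - pu * fu$values)
    dx <- fa$grid[2] - fa$grid[1]
    dx * (sum(d) - 0.5 * (d[1] + d[length(d)]))
  }
  g <- make_geno(40, 8, seed = 7, density = 0.15)
  set.seed(8)
  labelings <- c(list(rep(c(1L, 0L), each = 20)),
                 lapply(1:20, function(i) sample(rep(c(1L, 0L), each = 20))))
  s1 <- vapply(labelings, function(y) stat_scaled(g, y, 400, 1), numeric(1))
  s2 <- vapply(labelings, function(y) stat_scaled(g, y, 400, 7.3), numeric(1))
  expect_equal(s2, 7.3 * s1, tolerance = 1e-12)
  # exceedance ranks (hence permutation p-values) unchanged
  expect_identical(order(s1), order(s2))
  expect_identical(sum(s1[-1] >= s1[1]), sum(s2[-1] >= s2[1]))
})
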