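# Independent brute-force oracles. Each re-derives a quantity from its
# defining formula by explicit loops or enumeration, never through the
# package's own computational path.

# per-variant allele counts by phenotype, element-by-element
oracle_counts <- function(x, y) {
  m_case <- integer(ncol(x))
  m_control <- integer(ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    if (y[i] == 1) m_case[j] <- m_case[j] + x[i, j]
    else m_control[j] <- m_control[j] + x[i, j]
  }
  list(m_case = m_case, m_control = m_control)
}

# binomial CDF by term-by-term summation of C(size, k) q^k (1-q)^(size-k)
oracle_binom_cdf <- function(m, size, q) {
  total <- 0
  for (k in 0:m) total <- total + choose(size, k) * q^k * (1 - q)^(size - k)
  total
}

# weighted Gaussian KDE by a direct (grid point, variant) double loop
oracle_kde <- function(grid, positions, weights, bw) {
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    acc <- 0
    for (j in seq_along(positions)) {
      z <- (grid[g] - positions[j]) / bw
      acc <- acc + weights[j] * exp(-z^2 / 2) / sqrt(2 * pi)
    }
    out[g] <- acc / bw
  }
  out
}

# DoEstRare statistic evaluated on a much finer grid with a Riemann sum,
# building every ingredient from the printed formulas
oracle_stat_finegrid <- function(geno, y, bw, fine = 1e5) {
  x <- geno$matrix
  n_case <- sum(y)
  n_control <- sum(1 - y)
  m_case <- colSums(x[y == 1, , drop = FALSE])
  m_control <- colSums(x[y == 0, , drop = FALSE])
  wd_case <- m_case / sum(m_case)
  wd_control <- m_control / sum(m_control)
  q <- (m_control + 1) / (2 * n_control + 2)
  w <- vapply(seq_along(q),
              function(j) oracle_binom_cdf(m_case[j], 2 * n_case, q[j]),
              numeric(1))
  p_case <- sum(w * m_case / (2 * n_case)) / sum(w)
  p_control <- sum(w * m_control / (2 * n_control)) / sum(w)
  grid <- seq(1, geno$region_length, length.out = fine)
  dx <- grid[2] - grid[1]
  fa <- oracle_kde_fast(grid, geno$positions, wd_case, bw)
  fu <- oracle_kde_fast(grid, geno$positions, wd_control, bw)
  sum(abs(p_case * fa - p_control * fu)) * dx
}

# vectorized over variants but still formula-direct (the double loop above
# is too slow for 1e5 grid points)
oracle_kde_fast <- function(grid, positions, weights, bw) {
  out <- numeric(length(grid))
  for (j in seq_along(positions)) {
    z <- (grid - positions[j]) / bw
    out <- out + weights[j] * exp(-z^2 / 2) / sqrt(2 * pi)
  }
  out / bw
}

# two-sided Fisher exact p by exhaustive enumeration of 2x2 tables with the
# observed margins, summing probabilities of tables no more probable than
# the observed one
oracle_fisher_2x2 <- function(a, b, c, d) {
  # table: rows carrier status, cols phenotype; a = non-carrier controls,
  # b = non-carrier cases, c = carrier controls, d = carrier cases
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  prob_of <- function(aa) {
    bb <- row1 - aa; cc <- col1 - aa; dd <- n - row1 - col1 + aa
    if (min(bb, cc, dd) < 0) return(0)
    exp(lchoose(col1, aa) + lchoose(n - col1, bb) - lchoose(n, row1))
  }
  p_obs <- prob_of(a)
  total <- 0
  for (aa in 0:min(row1, col1)) {
    p <- prob_of(aa)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  min(total, 1)
}

# small deterministic genotype fixture: n x p matrix of 0/1/2 with the given
# rare-allele density
make_geno <- function(n, p, region_length = 10000, density = 0.05,
                      seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 2, density), nrow = n)
  if (all(colSums(x) == 0)) x[1, 1] <- 1L
  region_genotypes(x, sort(sample.int(region_length, p)), region_length)
}

# small haplotype pool with inflated MAFs so tiny samples stay polymorphic
make_test_pool <- function(seed, n_variants = 12, n_haplotypes = 1000,
                           maf_range = c(0.02, 0.1)) {
  haplotype_pool(n_variants = n_variants, region_length = 10000,
                 maf_range = maf_range, n_haplotypes = n_haplotypes,
                 seed = seed)
}
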