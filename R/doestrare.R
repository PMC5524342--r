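#' Control minor allele frequency estimate
#'
#' Shrunken estimate of the minor allele frequency of a variant in controls,
#' `(m + 1) / (2 * n_control + 2)`. The +1/+2 continuity correction keeps the
#' estimate strictly inside (0, 1) even when no (or only) rare alleles are
#' observed, so it can parameterize a binomial null distribution.
#'
#' @param m_control Rare-allele count(s) in controls (vectorized).
#' @param n_control Number of control individuals.
#' @return Frequency value(s) in (0, 1).
#' @export
control_allele_frequency <- function(m_control, n_control) {
  if (n_control < 1L) stop("n_control must be >= 1", call. = FALSE)
  if (any(m_control < 0) || any(m_control > 2 * n_control))
    stop("m_control must lie in [0, 2 * n_control]", call. = FALSE)
  (m_control + 1) / (2 * n_control + 2)
}

#' Binomial-tail variant weight
#'
#' Weight of a variant in the burden component: the probability, under the
#' null hypothesis that case counts follow Binomial(2 * n_case, q), of
#' observing at most the case count actually seen. Variants enriched in
#' cases relative to the control frequency `q` receive weights near 1.
#'
#' @param m_case Rare-allele count(s) in cases (vectorized).
#' @param n_case Number of case individuals.
#' @param q Null rare-allele frequency, typically from
#'   [control_allele_frequency()]; must lie strictly in (0, 1).
#' @return Weight(s) in \[0, 1\].
#' @export
variant_weight <- function(m_case, n_case, q) {
  if (any(q <= 0) || any(q >= 1)) stop("q must lie in (0, 1)", call. = FALSE)
  if (any(m_case < 0) || any(m_case > 2 * n_case))
    stop("m_case must lie in [0, 2 * n_case]", call. = FALSE)
  stats::pbinom(m_case, size = 2 * n_case, prob = q)
}

#' Mutation-count density weights
#'
#' Normalizes a group's per-variant rare-allele counts into kernel weights:
#' the share of the group's mutations falling at each variant position.
#'
#' @param m Non-negative per-variant counts for one phenotype group.
#' @return Weights summing to 1; zero-count variants get weight 0.
#' @export
density_weights <- function(m) {
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  s <- sum(m)
  if (s == 0) stop("no rare mutations in group", call. = FALSE)
  m / s
}

#' Weighted Gaussian kernel density of mutation positions
#'
#' Evaluates `f(pos) = (1/bw) * sum_j w_j * K((pos - l_j)/bw)` with `K` the
#' standard Gaussian density, on a grid of equally spaced points spanning
#' `[1, region_length]`. Kernel mass falling outside the region is not
#' re-normalized, so the restriction of the curve to the region may
#' integrate to slightly less than 1.
#'
#' @param positions Variant positions `l_j` (bp, 1-based).
#' @param weights Normalized mutation-share weights (sum to 1), e.g. from
#'   [density_weights()].
#' @param bw Bandwidth in bp (> 0).
#' @param grid_size Number of grid points (>= 2), default 1000.
#' @param region_length Region length `Lg` in bp.
#' @return An object of class `"density_curve"`: list with `grid`, `values`,
#'   `bandwidth`.
#' @export
position_density <- function(positions, weights, bw, grid_size = 1000,
                             region_length) {
  if (bw <= 0) stop("bw must be positive", call. = FALSE)
  if (grid_size < 2) stop("grid_size must be >= 2", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized to sum to 1", call. = FALSE)
  grid <- seq(1, region_length, length.out = grid_size)
  kmat <- kernel_matrix(grid, positions, bw)
  structure(list(grid = grid, values = as.vector(kmat %*% weights),
                 bandwidth = bw),
            class = "density_curve")
}

# Gaussian kernel matrix K[g, j] = dnorm((grid[g] - pos[j]) / bw) / bw.
kernel_matrix <- function(grid, positions, bw) {
  stats::dnorm(outer(grid, positions, "-") / bw) / bw
}

#' Weighted mean allele frequency (burden component)
#'
#' The burden component of the test statistic for one phenotype group: a
#' weighted average of per-variant allele frequencies,
#' `sum_j w_j * m_j / (2 n) / sum_j w_j`.
#'
#' @param m Per-variant rare-allele counts in the group.
#' @param w Variant weights (same for both groups), from [variant_weight()].
#' @param n_group Number of individuals in the group.
#' @return Non-negative scalar.
#' @export
burden_component <- function(m, w, n_group) {
  sw <- sum(w)
  if (sw <= 0) stop("degenerate weights: sum(w) must be positive",
                    call. = FALSE)
  sum(w * m / (2 * n_group)) / sw
}

#' Silverman bandwidth for mutation positions
#'
#' Rule-of-thumb bandwidth computed on the pooled, count-weighted sample of
#' mutation positions: `0.9 * min(sd, IQR / 1.34) * n^(-1/5)` where `n` is
#' the total number of rare alleles in the region. A floor of
#' `region_length / 100` guards against degenerate spreads (e.g. a single
#' distinct position). Because it depends on positions and pooled counts
#' only, the bandwidth is invariant under phenotype permutation.
#'
#' @param positions Variant positions (bp).
#' @param counts Pooled per-variant rare-allele counts (cases + controls).
#' @param region_length Region length in bp.
#' @return Bandwidth in bp.
#' @export
silverman_bandwidth <- function(positions, counts, region_length) {
  floor_bw <- region_length / 100
  n <- sum(counts)
  if (n < 2) return(floor_bw)
  x <- rep(positions, counts)
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  spread <- min(s, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) return(floor_bw)
  max(0.9 * spread * n^(-1 / 5), floor_bw)
}

# Precompute everything about a region that permutation does not change:
# grid, kernel matrix, trapezoid spacing, bandwidth, pooled counts.
der_prepare <- function(geno, bw = NULL, grid_size = 1000) {
  m_total <- colSums(geno$matrix)
  if (is.null(bw))
    bw <- silverman_bandwidth(geno$positions, m_total, geno$region_length)
  grid <- seq(1, geno$region_length, length.out = grid_size)
  list(geno = geno, bw = bw, grid = grid, dx = grid[2] - grid[1],
       kmat = kernel_matrix(grid, geno$positions, bw), m_total = m_total)
}

# Vectorized statistic over permutation columns. m_case is a P x B matrix of
# case counts (one column per labeling); n_case/n_control are fixed by the
# permutation scheme. A column whose group has zero mutations contributes a
# zero scaled curve for that group (p_hat = 0), which is exact for the
# degenerate-permutation rule and never occurs for the observed data (callers
# check that separately).
der_stat_block <- function(prep, m_case, n_case, n_control) {
  m_case <- as.matrix(m_case)
  p <- nrow(m_case)
  m_control <- prep$m_total - m_case
  s_case <- colSums(m_case)
  s_control <- colSums(m_control)

  wd_case <- sweep(m_case, 2, pmax(s_case, 1), "/")
  wd_control <- sweep(m_control, 2, pmax(s_control, 1), "/")

  q_control <- (m_control + 1) / (2 * n_control + 2)
  w <- matrix(stats::pbinom(m_case, size = 2 * n_case, prob = q_control),
              nrow = p)
  sw <- colSums(w)
  p_case <- colSums(w * m_case) / (2 * n_case) / sw
  p_control <- colSums(w * m_control) / (2 * n_control) / sw

  f_case <- prep$kmat %*% wd_case
  f_control <- prep$kmat %*% wd_control
  d <- abs(sweep(f_case, 2, p_case, "*") - sweep(f_control, 2, p_control, "*"))
  g <- nrow(d)
  stat <- prep$dx * (colSums(d) - 0.5 * (d[1, ] + d[g, ]))
  list(stat = as.vector(stat), p_case = p_case, p_control = p_control,
       f_case = f_case, f_control = f_control, w = w)
}

#' DoEstRare test statistic
#'
#' Area between the case and control mutation-position density curves, each
#' scaled by the group's weighted mean allele frequency:
#' `STAT = integral over [1, Lg] of |p_case * f_case(pos) - p_control *
#' f_control(pos)| d pos`, evaluated by the trapezoidal rule on an equally
#' spaced grid. Monomorphic variants must be removed beforehand (the
#' [doestrare()] driver does this).
#'
#' @param geno A [region_genotypes()] object.
#' @param phenotypes Binary vector, 1 = case, 0 = control.
#' @param bw Kernel bandwidth in bp; `NULL` (default) uses
#'   [silverman_bandwidth()] on the pooled counts.
#' @param grid_size Number of quadrature grid points, default 1000.
#' @return A list with `statistic`, `status` (`"ok"`,
#'   `"undefined_no_case_mutations"` or `"undefined_no_control_mutations"`;
#'   `statistic` is `NA` unless `"ok"`), the burden components `p_case`,
#'   `p_control`, the two [position_density()] curves, the variant weights
#'   `w` and the bandwidth used.
#' @export
doestrare_statistic <- function(geno, phenotypes, bw = NULL,
                                grid_size = 1000) {
  y <- check_phenotypes(geno, phenotypes)
  counts <- count_rare_alleles(geno, y)
  if (counts$n_case < 1L || counts$n_control < 1L)
    stop("both cases and controls are required", call. = FALSE)
  prep <- der_prepare(geno, bw = bw, grid_size = grid_size)
  status <- der_status(counts)
  if (status != "ok")
    return(list(statistic = NA_real_, status = status, p_case = NA_real_,
                p_control = NA_real_, bandwidth = prep$bw))
  blk <- der_stat_block(prep, cbind(counts$m_case),
                        counts$n_case, counts$n_control)
  curve <- function(v) structure(
    list(grid = prep$grid, values = as.vector(v), bandwidth = prep$bw),
    class = "density_curve")
  list(statistic = blk$stat, status = "ok",
       p_case = blk$p_case, p_control = blk$p_control,
       density_case = curve(blk$f_case), density_control = curve(blk$f_control),
       w = as.vector(blk$w), bandwidth = prep$bw)
}

der_status <- function(counts) {
  if (sum(counts$m_case) == 0L) "undefined_no_case_mutations"
  else if (sum(counts$m_control) == 0L) "undefined_no_control_mutations"
  else "ok"
}

# Draw n_perms permuted label vectors, one sample.int call per permutation so
# that standard and adaptive procedures consume the RNG stream identically.
permute_labels <- function(y, n_perms) {
  vapply(seq_len(n_perms), function(b) y[sample.int(length(y))],
         integer(length(y)))
}

#' DoEstRare rare-variant association test
#'
#' Tests a region of rare variants for case/control differences in either the
#' spatial distribution of mutations or the overall mutation burden. The
#' statistic is the area between the two kernel-estimated mutation-position
#' densities, each multiplied by the group's weighted mean allele frequency;
#' significance comes from phenotype permutation: `p = (r + 1) / (b + 1)`
#' where `r` counts permuted statistics `>=` the observed one among `b`
#' permutations.
#'
#' With `adaptive = TRUE`, permutations run in batches and stop early once
#' the exceedance count reaches `ceiling(1 / precision^2)`, giving the
#' p-value estimate a relative standard error of about `precision` while
#' spending few permutations on clearly non-significant regions. `max_perms`
#' defaults to `ceiling(ceiling(1 / precision^2) / alpha)` so that p-values
#' near the target level `alpha` remain resolvable.
#'
#' Monomorphic variants are dropped (with a message) before testing. If the
#' observed data have no rare mutations in one group the test is undefined
#' and the returned status says which group was empty. Permuted labelings
#' that empty one group are still used: the empty group's scaled density is
#' identically zero, so the permuted statistic reduces to the integral of the
#' other group's scaled curve.
#'
#' @param geno A [region_genotypes()] object.
#' @param phenotypes Binary vector, 1 = case, 0 = control.
#' @param perms Number of permutations `B` for the standard procedure.
#' @param adaptive Use the adaptive early-stopping procedure?
#' @param alpha Target significance level for the adaptive procedure (sets
#'   the default permutation budget).
#' @param precision Relative precision `c` of the adaptive p-value estimate;
#'   the stopping exceedance count is `ceiling(1 / c^2)`.
#' @param max_perms Adaptive permutation budget; see above for the default.
#' @param batch_size Number of permutations between interim checks of the
#'   adaptive stopping rule.
#' @param bw Kernel bandwidth in bp, or `NULL` for [silverman_bandwidth()].
#' @param grid_size Quadrature grid size, default 1000.
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @param quiet Suppress the dropped-monomorphic-variants message?
#'
#' @return An object of class `"doestrare"` (also `"rv_test"`): list with
#'   `statistic`, `p.value`, `permutations` (performed), `exceedances`,
#'   `status`, `adaptive`, `hit_max_perms`, burden components, density
#'   curves, `bandwidth`, `n_case`, `n_control` and the dropped-variant
#'   count.
#' @seealso [doestrare_statistic()], [cast_test()], [weighted_sum_test()]
#' @examples
#' pool <- haplotype_pool(n_variants = 20, n_haplotypes = 2000, seed = 1)
#' dat <- sample_case_control(pool, causal = integer(0), n_cases = 50,
#'                            n_controls = 50, seed = 2)
#' doestrare(dat$geno, dat$phenotypes, perms = 100, seed = 3)
#' @export
doestrare <- function(geno, phenotypes, perms = 500, adaptive = FALSE,
                      alpha = 5e-7, precision = 0.2, max_perms = NULL,
                      batch_size = 1000, bw = NULL, grid_size = 1000,
                      seed = NULL, quiet = FALSE) {
  y <- check_phenotypes(geno, phenotypes)
  geno <- drop_monomorphic(geno)
  if (is.null(geno))
    stop("no polymorphic variants in the region", call. = FALSE)
  n_dropped <- attr(geno, "n_dropped")
  if (!quiet && n_dropped > 0L)
    message(sprintf("dropped %d monomorphic variant(s)", n_dropped))

  counts <- count_rare_alleles(geno, y)
  if (counts$n_case < 1L || counts$n_control < 1L)
    stop("both cases and controls are required", call. = FALSE)
  prep <- der_prepare(geno, bw = bw, grid_size = grid_size)
  status <- der_status(counts)

  res <- structure(
    list(statistic = NA_real_, p.value = NA_real_, permutations = 0L,
         exceedances = NA_integer_, status = status, adaptive = adaptive,
         hit_max_perms = FALSE, p_case = NA_real_, p_control = NA_real_,
         density_case = NULL, density_control = NULL, bandwidth = prep$bw,
         n_case = counts$n_case, n_control = counts$n_control,
         n_variants = geno$n_variants, n_dropped_monomorphic = n_dropped,
         method = "DoEstRare", call = match.call()),
    class = c("doestrare", "rv_test"))
  if (status != "ok") return(res)

  obs <- der_stat_block(prep, cbind(counts$m_case),
                        counts$n_case, counts$n_control)
  curve <- function(v) structure(
    list(grid = prep$grid, values = as.vector(v), bandwidth = prep$bw),
    class = "density_curve")
  res$statistic <- obs$stat
  res$p_case <- obs$p_case
  res$p_control <- obs$p_control
  res$density_case <- curve(obs$f_case)
  res$density_control <- curve(obs$f_control)

  if (!is.null(seed)) set.seed(seed)
  x <- geno$matrix
  perm_stats <- function(n_perms) {
    yp <- permute_labels(y, n_perms)
    m_case_perm <- crossprod(x, yp)
    der_stat_block(prep, m_case_perm, counts$n_case, counts$n_control)$stat
  }

  if (!adaptive) {
    if (perms < 1) stop("perms must be >= 1", call. = FALSE)
    r <- sum(perm_stats(perms) >= res$statistic)
    res$permutations <- as.integer(perms)
    res$exceedances <- as.integer(r)
    res$p.value <- (r + 1) / (perms + 1)
    return(res)
  }

  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (precision <= 0 || precision >= 1)
    stop("precision must be in (0, 1)", call. = FALSE)
  r_stop <- ceiling(1 / precision^2)
  if (is.null(max_perms)) max_perms <- ceiling(r_stop / alpha)
  if (max_perms < 1) stop("max_perms must be >= 1", call. = FALSE)
  r <- 0L
  b <- 0L
  while (b < max_perms && r < r_stop) {
    nb <- min(batch_size, max_perms - b)
    r <- r + sum(perm_stats(nb) >= res$statistic)
    b <- b + nb
  }
  res$permutations <- as.integer(b)
  res$exceedances <- as.integer(r)
  res$p.value <- (r + 1) / (b + 1)
  res$hit_max_perms <- r < r_stop
  res
}
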