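#' Synthetic haplotype pool
#'
#' Builds a population of binary haplotypes over a region, emulating the
#' rare-variant content of a coalescent-simulated 10 kb gene: ~30 sites with
#' population minor allele frequencies in \[0.001, 0.01\]. Site MAFs are drawn
#' from a Beta(0.5, 50) truncated to `maf_range` (heavily skewed toward the
#' rare end), positions are distinct integers uniform over the region, and
#' sites are independent (no linkage disequilibrium). Haplotype alleles are
#' Bernoulli draws per site; any site whose realized pool frequency falls
#' outside `maf_range` is redrawn so the post-condition holds exactly.
#'
#' @param n_variants Number of rare variant sites, default 30.
#' @param region_length Region length in bp, default 10000.
#' @param maf_range Closed interval of admissible pool MAFs,
#'   default `c(0.001, 0.01)`.
#' @param n_haplotypes Pool size `H`, default 10000.
#' @param maf_shape Beta shape parameters of the MAF distribution,
#'   default `c(0.5, 50)`.
#' @param seed Optional integer seed.
#' @param max_tries Redraw attempts per site before giving up.
#' @return Object of class `"haplotype_pool"`: list with `haplotypes`
#'   (`n_haplotypes` x `n_variants` 0/1 matrix), `positions`, `maf`
#'   (realized pool frequencies), `target_maf`, `region_length`.
#' @export
haplotype_pool <- function(n_variants = 30, region_length = 10000,
                           maf_range = c(0.001, 0.01), n_haplotypes = 10000,
                           maf_shape = c(0.5, 50), seed = NULL,
                           max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < lower <= upper <= 0.5", call. = FALSE)
  if (n_haplotypes %% 2L != 0L)
    stop("n_haplotypes must be even", call. = FALSE)
  lo_count <- ceiling(maf_range[1] * n_haplotypes)
  hi_count <- floor(maf_range[2] * n_haplotypes)
  if (lo_count > hi_count)
    stop("maf_range is infeasible for this pool size: no attainable ",
         "allele count", call. = FALSE)
  if (n_variants > region_length)
    stop("more variants than base pairs in the region", call. = FALSE)

  # inverse-CDF draw from Beta(a, b) truncated to maf_range
  a <- maf_shape[1]; b <- maf_shape[2]
  plo <- stats::pbeta(maf_range[1], a, b)
  phi <- stats::pbeta(maf_range[2], a, b)
  target_maf <- stats::qbeta(stats::runif(n_variants, plo, phi), a, b)

  positions <- sort(sample.int(region_length, n_variants))
  hap <- matrix(0L, nrow = n_haplotypes, ncol = n_variants)
  counts <- integer(n_variants)
  for (j in seq_len(n_variants)) {
    for (try in seq_len(max_tries)) {
      col <- stats::rbinom(n_haplotypes, 1L, target_maf[j])
      cj <- sum(col)
      if (cj >= lo_count && cj <= hi_count) break
      col <- NULL
    }
    if (is.null(col))
      stop("could not realize a pool frequency inside maf_range for site ",
           j, call. = FALSE)
    hap[, j] <- col
    counts[j] <- cj
  }
  structure(
    list(haplotypes = hap, positions = positions,
         maf = counts / n_haplotypes, target_maf = target_maf,
         region_length = as.numeric(region_length)),
    class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants on [1, %g] bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$region_length))
  cat(sprintf("  pool MAF range: [%.4g, %.4g]\n", min(x$maf), max(x$maf)))
  invisible(x)
}

#' Disease-risk-variant placement scenario
#'
#' @param scenario `"uniform"` (causal variants scattered at random),
#'   `"one_cluster"` (a contiguous block around the median variant
#'   position), `"two_clusters"` (blocks around the 1/3 and 2/3 position
#'   quantiles), or `"null"` (no causal variants).
#' @param drv_proportion Fraction of variants that are causal (ignored for
#'   `"null"`).
#' @param odds_ratio Per-allele odds ratio of each causal variant, default 3.
#' @param prevalence Baseline probability of disease for an individual
#'   carrying no rare allele, default 0.05; sets the logistic intercept
#'   `log(prevalence / (1 - prevalence))`.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = c("uniform", "one_cluster",
                                       "two_clusters", "null"),
                          drv_proportion = 0.1, odds_ratio = 3,
                          prevalence = 0.05) {
  scenario <- match.arg(scenario)
  if (scenario != "null" &&
      (drv_proportion <= 0 || drv_proportion > 1))
    stop("drv_proportion must lie in (0, 1]", call. = FALSE)
  if (odds_ratio <= 0) stop("odds_ratio must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  structure(list(scenario = scenario, drv_proportion = drv_proportion,
                 odds_ratio = odds_ratio, prevalence = prevalence,
                 beta0 = log(prevalence / (1 - prevalence)),
                 log_or = log(odds_ratio)),
            class = "scenario_spec")
}

#' Select disease-risk variants under a placement scenario
#'
#' Chooses `round(drv_proportion * P)` causal variants (half-up rounding,
#' minimum 1). Under `"uniform"` they are a simple random sample; under
#' `"one_cluster"` a seed variant nearest the median variant position grows
#' by absorbing, at each step, the flanking neighbor whose position is
#' nearest the seed (left first on ties); `"two_clusters"` grows two such
#' blocks, seeded at the 1/3 and 2/3 position quantiles, alternating one
#' absorption per cluster and merging if they meet.
#'
#' @param pool A [haplotype_pool()].
#' @param scenario A [scenario_spec()] or a scenario name.
#' @param drv_proportion Causal fraction; defaults to the value in
#'   `scenario` when one is given.
#' @param seed Optional integer seed (only the `"uniform"` scenario is
#'   random).
#' @return Sorted integer vector of causal variant indices (empty for the
#'   null scenario).
#' @export
select_drvs <- function(pool, scenario, drv_proportion = NULL, seed = NULL) {
  if (inherits(scenario, "scenario_spec")) {
    if (is.null(drv_proportion)) drv_proportion <- scenario$drv_proportion
    scenario <- scenario$scenario
  }
  if (scenario == "null") return(integer(0))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(pool$haplotypes)
  n_drv <- max(1L, as.integer(floor(drv_proportion * p + 0.5)))
  if (n_drv > p)
    stop("requested more causal variants than exist in the pool",
         call. = FALSE)
  pos <- pool$positions
  switch(scenario,
    uniform = sort(sample.int(p, n_drv)),
    one_cluster = grow_clusters(pos,
                                which.min(abs(pos - stats::median(pos))),
                                n_drv),
    two_clusters = {
      s1 <- which.min(abs(pos - stats::quantile(pos, 1 / 3)))
      s2 <- which.min(abs(pos - stats::quantile(pos, 2 / 3)))
      if (s2 == s1) s2 <- min(s1 + 1L, p)
      grow_clusters(pos, unique(c(s1, s2)), n_drv)
    },
    stop("unknown scenario: ", scenario, call. = FALSE))
}

# Grow contiguous clusters of variant indices around seed indices until
# n_drv variants are selected. One absorption per cluster per round
# (alternating); each absorption takes the unselected flanking neighbor of
# the maximal selected run containing the seed whose position is nearest the
# seed's position, preferring the left flank on exact ties. Runs that meet
# merge automatically (the run is recomputed each step).
grow_clusters <- function(pos, seeds, n_drv) {
  p <- length(pos)
  seeds <- seeds[seq_len(min(length(seeds), n_drv))]
  sel <- rep(FALSE, p)
  sel[seeds] <- TRUE
  while (sum(sel) < n_drv) {
    grew <- FALSE
    for (s in seeds) {
      if (sum(sel) >= n_drv) break
      lo <- s; while (lo > 1L && sel[lo - 1L]) lo <- lo - 1L
      hi <- s; while (hi < p && sel[hi + 1L]) hi <- hi + 1L
      left <- if (lo > 1L) lo - 1L else NA_integer_
      right <- if (hi < p) hi + 1L else NA_integer_
      pick <- if (is.na(left) && is.na(right)) NA_integer_
        else if (is.na(right)) left
        else if (is.na(left)) right
        else if (abs(pos[left] - pos[s]) <= abs(pos[right] - pos[s])) left
        else right
      if (!is.na(pick)) {
        sel[pick] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break  # everything selected
  }
  which(sel)
}

#' Disease probability under the logistic risk model
#'
#' `P(Y = 1 | X) = plogis(beta0 + log(OR) * causal_burden)`: an individual
#' with no causal rare allele is affected with the baseline prevalence
#' (default 0.05), and each causal allele multiplies the odds by the odds
#' ratio.
#'
#' @param causal_burden Number of causal rare alleles carried (vectorized).
#' @param model A [scenario_spec()] supplying `beta0` and `log_or`.
#' @return Probability value(s) in (0, 1).
#' @export
disease_probability <- function(causal_burden, model = scenario_spec()) {
  stats::plogis(model$beta0 + model$log_or * causal_burden)
}

#' Simulate disease phenotypes from genotypes
#'
#' Draws binary disease status for each individual under the logistic model
#' `logit P(Y = 1 | X) = beta0 + sum_{j in causal} log(OR) * X_j`, i.e. only
#' causal rare alleles change the odds, each multiplying them by the odds
#' ratio.
#'
#' @param genotypes Matrix of rare-allele counts (individuals x variants) or
#'   a [region_genotypes()] object.
#' @param causal Integer indices of causal variants (possibly empty).
#' @param model A [scenario_spec()] supplying `beta0` and `log_or`; default
#'   uses prevalence 0.05 and odds ratio 3.
#' @return Integer 0/1 phenotype vector.
#' @export
simulate_phenotype <- function(genotypes, causal, model = scenario_spec()) {
  if (inherits(genotypes, "region_genotypes")) genotypes <- genotypes$matrix
  burden <- if (length(causal) == 0L) numeric(nrow(genotypes)) else
    rowSums(genotypes[, causal, drop = FALSE])
  stats::rbinom(nrow(genotypes), 1L, disease_probability(burden, model))
}

#' Sample a case/control dataset from a haplotype pool
#'
#' Forms diploid individuals by drawing two haplotypes with replacement from
#' the pool, assigns disease status with [simulate_phenotype()], and keeps
#' sampling until exactly `n_cases` cases and `n_controls` controls are
#' retained (excess individuals of a filled class are discarded). All pool
#' variants are kept in the genotype matrix; no sample-level MAF
#' re-filtering is applied.
#'
#' @param pool A [haplotype_pool()].
#' @param causal Integer indices of causal variants (empty for null data).
#' @param model A [scenario_spec()]; default prevalence 0.05, odds ratio 3.
#' @param n_cases,n_controls Required group sizes.
#' @param seed Optional integer seed.
#' @param max_draws Cap on total individuals drawn before aborting (guards
#'   against models in which one class is essentially unreachable).
#' @return Object of class `"cc_dataset"`: list with `geno`
#'   ([region_genotypes()]), `phenotypes` (1 = case, cases first), and
#'   `causal`.
#' @export
sample_case_control <- function(pool, causal, model = scenario_spec(),
                                n_cases, n_controls, seed = NULL,
                                max_draws = 1e7) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cases < 1L || n_controls < 1L)
    stop("n_cases and n_controls must be >= 1", call. = FALSE)
  h <- nrow(pool$haplotypes)
  case_rows <- vector("list", 0L)
  control_rows <- vector("list", 0L)
  n_case_have <- 0L
  n_control_have <- 0L
  drawn <- 0L
  batch <- max(1000L, 2L * (n_cases + n_controls))
  while (n_case_have < n_cases || n_control_have < n_controls) {
    if (drawn >= max_draws)
      stop("max_draws exhausted before filling both groups; check the ",
           "disease model", call. = FALSE)
    nb <- as.integer(min(batch, max_draws - drawn))
    g <- pool$haplotypes[sample.int(h, nb, replace = TRUE), , drop = FALSE] +
      pool$haplotypes[sample.int(h, nb, replace = TRUE), , drop = FALSE]
    yb <- simulate_phenotype(g, causal, model)
    drawn <- drawn + nb
    if (n_case_have < n_cases) {
      idx <- which(yb == 1L)
      take <- idx[seq_len(min(length(idx), n_cases - n_case_have))]
      if (length(take)) {
        case_rows[[length(case_rows) + 1L]] <- g[take, , drop = FALSE]
        n_case_have <- n_case_have + length(take)
      }
    }
    if (n_control_have < n_controls) {
      idx <- which(yb == 0L)
      take <- idx[seq_len(min(length(idx), n_controls - n_control_have))]
      if (length(take)) {
        control_rows[[length(control_rows) + 1L]] <- g[take, , drop = FALSE]
        n_control_have <- n_control_have + length(take)
      }
    }
  }
  x <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  structure(
    list(geno = region_genotypes(x, pool$positions, pool$region_length),
         phenotypes = c(rep(1L, n_cases), rep(0L, n_controls)),
         causal = as.integer(causal)),
    class = "cc_dataset")
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("cc_dataset: %d cases + %d controls, %d variants (%d causal)\n",
              sum(x$phenotypes), sum(1L - x$phenotypes),
              x$geno$n_variants, length(x$causal)))
  invisible(x)
}
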