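#' CAST-style carrier burden test
#'
#' Collapses each individual to a binary carrier indicator (any rare allele
#' in the region) and tests the 2x2 carrier-by-phenotype table with a
#' two-sided Fisher's exact test. No permutations are needed.
#'
#' @param geno A [region_genotypes()] object.
#' @param phenotypes Binary vector, 1 = case, 0 = control.
#' @return An `"rv_test"` object; `statistic` is the number of case
#'   carriers. When every individual has the same carrier status the table
#'   is degenerate and `p.value = 1` with status `"degenerate_carriers"`.
#' @export
cast_test <- function(geno, phenotypes) {
  y <- check_phenotypes(geno, phenotypes)
  if (sum(y) < 1L || sum(1L - y) < 1L)
    stop("both cases and controls are required", call. = FALSE)
  carrier <- as.integer(rowSums(geno$matrix) > 0L)
  res <- structure(
    list(statistic = sum(carrier * y), p.value = 1, permutations = 0L,
         status = "ok", method = "CAST", n_case = sum(y),
         n_control = sum(1L - y), call = match.call()),
    class = "rv_test")
  if (length(unique(carrier)) < 2L) {
    res$status <- "degenerate_carriers"
    return(res)
  }
  tab <- table(factor(carrier, levels = 0:1), factor(y, levels = 0:1))
  res$p.value <- stats::fisher.test(tab)$p.value
  res
}

#' Weighted-sum burden test
#'
#' Madsen--Browning-style weighted sum of rare-allele counts. Each
#' individual's score is `S_i = sum_j w_j X_ij` with inverse-variance
#' weights `w_j = 1 / sqrt(N * q_j (1 - q_j))` where `q_j` is the shrunken
#' control allele frequency. The statistic is the sum of case score ranks
#' over the pooled sample; significance comes from phenotype permutation
#' with weights recomputed from each permuted control group, and
#' `p = (r + 1)/(B + 1)` counting permuted rank sums `>=` the observed one.
#'
#' @param geno A [region_genotypes()] object.
#' @param phenotypes Binary vector, 1 = case, 0 = control.
#' @param perms Number of permutations `B`.
#' @param seed Optional integer seed for the permutation stream.
#' @return An `"rv_test"` object with the observed rank-sum statistic and
#'   permutation p-value.
#' @export
weighted_sum_test <- function(geno, phenotypes, perms = 500, seed = NULL) {
  y <- check_phenotypes(geno, phenotypes)
  if (sum(y) < 1L || sum(1L - y) < 1L)
    stop("both cases and controls are required", call. = FALSE)
  if (perms < 1) stop("perms must be >= 1", call. = FALSE)
  x <- geno$matrix
  n <- nrow(x)
  m_total <- colSums(x)

  rank_sum <- function(labels_mat) {
    m_case <- crossprod(x, labels_mat)
    m_control <- m_total - m_case
    n_control <- colSums(1L - labels_mat)
    q <- sweep(m_control + 1, 2, 2 * n_control + 2, "/")
    w <- 1 / sqrt(n * q * (1 - q))
    scores <- x %*% w
    vapply(seq_len(ncol(scores)),
           function(b) sum(rank(scores[, b]) * labels_mat[, b]),
           numeric(1))
  }

  obs <- rank_sum(cbind(y))
  if (!is.null(seed)) set.seed(seed)
  perm <- rank_sum(permute_labels(y, perms))
  r <- sum(perm >= obs)
  structure(
    list(statistic = obs, p.value = (r + 1) / (perms + 1),
         permutations = as.integer(perms), exceedances = as.integer(r),
         status = "ok", method = "WSS", n_case = sum(y),
         n_control = sum(1L - y), call = match.call()),
    class = "rv_test")
}

# Registry used by the replicate runner and the CLI. Every entry has
# signature (geno, phenotypes, perms, seed) and returns an rv_test-like list
# with elements statistic, p.value, permutations, status.
test_registry <- function() {
  list(
    doestrare = function(geno, phenotypes, perms, seed)
      doestrare(geno, phenotypes, perms = perms, seed = seed, quiet = TRUE),
    cast = function(geno, phenotypes, perms, seed)
      cast_test(geno, phenotypes),
    wss = function(geno, phenotypes, perms, seed)
      weighted_sum_test(geno, phenotypes, perms = perms, seed = seed)
  )
}
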