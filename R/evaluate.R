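#' Run simulation replicates and collect p-values
#'
#' Simulates `R` independent datasets under a scenario (a fresh haplotype
#' pool per replicate, as in replicated coalescent designs) and applies the
#' named tests to each. Replicate seeds are derived deterministically from
#' the master seed, so results are reproducible and independent of execution
#' order. Undefined test results (e.g. no rare mutations in one group) are
#' recorded with their status and an `NA` p-value rather than dropped.
#'
#' @param scenario A [scenario_spec()].
#' @param tests Character vector of registry names; available:
#'   `"doestrare"`, `"cast"`, `"wss"`.
#' @param R Number of replicates.
#' @param n_cases,n_controls Group sizes per replicate.
#' @param perms Permutations per permutation-based test, default 500.
#' @param pool_args List of arguments passed on to [haplotype_pool()]
#'   (e.g. `n_variants`, `n_haplotypes`).
#' @param seed Master integer seed.
#' @return `data.frame` with columns `replicate`, `test`, `scenario`,
#'   `drv_proportion`, `statistic`, `p_value`, `permutations`, `status`.
#' @export
run_replicates <- function(scenario, tests = "doestrare", R, n_cases,
                           n_controls, perms = 500, pool_args = list(),
                           seed = 1) {
  registry <- test_registry()
  unknown <- setdiff(tests, names(registry))
  if (length(unknown))
    stop("unknown test name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, R)

  rows <- vector("list", R * length(tests))
  k <- 0L
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    pool <- do.call(haplotype_pool, pool_args)
    causal <- select_drvs(pool, scenario)
    dat <- sample_case_control(pool, causal, model = scenario,
                               n_cases = n_cases, n_controls = n_controls)
    test_seeds <- sample.int(.Machine$integer.max, length(tests))
    for (t in seq_along(tests)) {
      fit <- tryCatch(
        registry[[tests[t]]](dat$geno, dat$phenotypes, perms, test_seeds[t]),
        error = function(e) list(statistic = NA_real_, p.value = NA_real_,
                                 permutations = 0L,
                                 status = paste0("error: ",
                                                 conditionMessage(e))))
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = r, test = tests[t], scenario = scenario$scenario,
        drv_proportion = if (scenario$scenario == "null") 0 else
          scenario$drv_proportion,
        statistic = fit$statistic, p_value = fit$p.value,
        permutations = fit$permutations, status = fit$status,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rejection-rate estimate with a binomial confidence band
#'
#' Fraction of p-values at or below `alpha`: the empirical type I error when
#' the data were simulated under the null, the empirical power otherwise.
#' Undefined results (`NA` p-values) are excluded from the denominator and
#' reported as a separate missingness fraction. The 95% band uses the normal
#' approximation to the binomial; for type-I-error displays it is centered
#' on the nominal level (`center = "nominal"`), for power on the point
#' estimate (`center = "estimate"`).
#'
#' @param pvalues Numeric vector, `NA` for undefined results.
#' @param alpha Nominal level, default 0.05.
#' @param center `"nominal"` or `"estimate"`.
#' @return Object of class `"error_rate_estimate"`: list with `rate`,
#'   `ci_low`, `ci_high`, `alpha`, `n_defined`, `n_total`,
#'   `missing_fraction`.
#' @export
estimate_rate <- function(pvalues, alpha = 0.05,
                          center = c("nominal", "estimate")) {
  center <- match.arg(center)
  n_total <- length(pvalues)
  if (n_total == 0L) stop("no p-values supplied", call. = FALSE)
  defined <- !is.na(pvalues)
  n <- sum(defined)
  if (n == 0L) stop("all p-values are undefined", call. = FALSE)
  rate <- sum(pvalues[defined] <= alpha) / n
  mid <- if (center == "nominal") alpha else rate
  half <- 1.96 * sqrt(mid * (1 - mid) / n)
  structure(
    list(rate = rate, ci_low = max(0, mid - half), ci_high = min(1, mid + half),
         alpha = alpha, n_defined = n, n_total = n_total,
         missing_fraction = 1 - n / n_total, center = center),
    class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rejection rate at alpha = %g: %.4f  [95%% band (%s-centered): %.4f, %.4f]\n",
    x$alpha, x$rate, x$center, x$ci_low, x$ci_high))
  if (x$missing_fraction > 0)
    cat(sprintf("  undefined results excluded: %.1f%%\n",
                100 * x$missing_fraction))
  invisible(x)
}

#' Summarize replicate p-values into a tidy rate table
#'
#' Groups the output of [run_replicates()] by test, scenario and causal
#' proportion and applies [estimate_rate()] to each group.
#'
#' @param results `data.frame` from [run_replicates()] (several calls may be
#'   row-bound).
#' @param alpha Nominal level.
#' @param center Confidence-band centering, see [estimate_rate()].
#' @return `data.frame` with columns `test`, `scenario`, `drv_proportion`,
#'   `alpha`, `R`, `rate`, `ci_low`, `ci_high`, `missing_fraction`.
#' @export
rate_table <- function(results, alpha = 0.05,
                       center = c("nominal", "estimate")) {
  center <- match.arg(center)
  key <- interaction(results$test, results$scenario,
                     results$drv_proportion, drop = TRUE)
  parts <- split(results, key)
  out <- lapply(parts, function(d) {
    est <- estimate_rate(d$p_value, alpha = alpha, center = center)
    data.frame(test = d$test[1], scenario = d$scenario[1],
               drv_proportion = d$drv_proportion[1], alpha = alpha,
               R = est$n_total, rate = est$rate, ci_low = est$ci_low,
               ci_high = est$ci_high,
               missing_fraction = est$missing_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$test, out$scenario, out$drv_proportion), , drop = FALSE]
}

#' Write a rate table as tab-separated text
#'
#' @param table Output of [rate_table()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
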