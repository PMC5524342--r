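#' @export
print.rv_test <- function(x, ...) {
  cat(sprintf("\n\t%s rare-variant association test\n\n", x$method))
  if (!is.na(x$statistic))
    cat(sprintf("statistic = %.6g", x$statistic))
  if (!is.null(x$permutations) && x$permutations > 0L)
    cat(sprintf(", permutations = %d", x$permutations))
  if (!is.na(x$p.value)) cat(sprintf(", p-value = %.4g\n", x$p.value))
  else cat(sprintf("\np-value undefined (status: %s)\n", x$status))
  invisible(x)
}

#' @export
summary.doestrare <- function(object, ...) {
  structure(object, class = c("summary.doestrare", class(object)))
}

#' @export
print.summary.doestrare <- function(x, ...) {
  print.rv_test(x)
  cat(sprintf("cases: %d, controls: %d, variants tested: %d (monomorphic dropped: %d)\n",
              x$n_case, x$n_control, x$n_variants, x$n_dropped_monomorphic))
  cat(sprintf("bandwidth: %.4g bp\n", x$bandwidth))
  if (!is.na(x$p_case))
    cat(sprintf("weighted mean allele frequency: cases %.4g, controls %.4g\n",
                x$p_case, x$p_control))
  if (isTRUE(x$adaptive))
    cat(sprintf("adaptive permutation: %d exceedances in %d permutations%s\n",
                x$exceedances, x$permutations,
                if (isTRUE(x$hit_max_perms)) " (budget exhausted)" else
                  " (stopped early)"))
  invisible(x)
}

#' Plot the scaled mutation-position densities of a fitted test
#'
#' Draws the case and control kernel densities of mutation positions, each
#' multiplied by its group's weighted mean allele frequency -- the two curves
#' whose enclosed area is the test statistic.
#'
#' @param x A fitted [doestrare()] object with status `"ok"`.
#' @param scaled Plot burden-scaled curves (default) or raw densities?
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.doestrare <- function(x, scaled = TRUE, ...) {
  if (is.null(x$density_case))
    stop("nothing to plot: test status is ", x$status, call. = FALSE)
  fa <- x$density_case$values
  fu <- x$density_control$values
  if (scaled) {
    fa <- fa * x$p_case
    fu <- fu * x$p_control
  }
  graphics::matplot(x$density_case$grid, cbind(fa, fu), type = "l",
                    lty = 1, col = c("red", "black"),
                    xlab = "position (bp)",
                    ylab = if (scaled) "scaled density" else "density", ...)
  graphics::legend("topright", legend = c("cases", "controls"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("density_curve: %d grid points on [%g, %g], bandwidth %.4g bp\n",
              length(x$grid), min(x$grid), max(x$grid), x$bandwidth))
  invisible(x)
}
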