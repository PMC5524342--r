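#' Region genotype container
#'
#' Bundles a rare-allele count matrix with the 1-based positions of its
#' variants inside a tested region (typically a gene or its coding sequence).
#' Entries of `matrix` count minor (rare) alleles, so each value is 0, 1 or 2.
#'
#' @param matrix Integer matrix, individuals in rows, variants in columns,
#'   entries in \{0, 1, 2\}.
#' @param positions Integer vector of variant positions within the region,
#'   1-based and sorted non-decreasingly; `1 <= positions[j] <= region_length`.
#' @param region_length Length of the region in base pairs.
#'
#' @return An object of class `"region_genotypes"`: a list with elements
#'   `matrix`, `positions`, `region_length`, `n_variants`, `n_individuals`.
#' @export
region_genotypes <- function(matrix, positions, region_length) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(matrix))
    stop("length(positions) must equal ncol(matrix)", call. = FALSE)
  if (ncol(matrix) < 1L)
    stop("at least one variant is required", call. = FALSE)
  if (anyNA(matrix))
    stop("missing genotypes are not allowed; impute upstream", call. = FALSE)
  if (any(matrix < 0L | matrix > 2L))
    stop("genotype entries must be rare-allele counts in {0, 1, 2}",
         call. = FALSE)
  if (is.unsorted(positions))
    stop("positions must be sorted non-decreasingly", call. = FALSE)
  if (any(positions < 1L) || any(positions > region_length))
    stop("positions must lie in [1, region_length]", call. = FALSE)
  structure(
    list(matrix = matrix, positions = positions,
         region_length = as.numeric(region_length),
         n_variants = ncol(matrix), n_individuals = nrow(matrix)),
    class = "region_genotypes")
}

#' @export
print.region_genotypes <- function(x, ...) {
  cat(sprintf("region_genotypes: %d individuals x %d variants on [1, %g] bp\n",
              x$n_individuals, x$n_variants, x$region_length))
  cat(sprintf("  total rare-allele count: %d\n", sum(x$matrix)))
  invisible(x)
}

# Validate a binary phenotype vector against a genotype container.
# Returns the vector as integer 0/1.
check_phenotypes <- function(geno, phenotypes) {
  phenotypes <- as.integer(phenotypes)
  if (length(phenotypes) != geno$n_individuals)
    stop("phenotype vector and genotype matrix disagree on the number of ",
         "individuals", call. = FALSE)
  if (anyNA(phenotypes) || !all(phenotypes %in% c(0L, 1L)))
    stop("phenotypes must be 0 (control) or 1 (case)", call. = FALSE)
  phenotypes
}

#' Per-variant rare-allele counts split by phenotype
#'
#' Column sums of the rare-allele count matrix within cases and within
#' controls: `m_case[j]` is the number of rare alleles observed at variant
#' `j` among cases, `m_control[j]` among controls.
#'
#' @param geno A [region_genotypes()] object.
#' @param phenotypes Binary vector (1 = case, 0 = control) of length
#'   `geno$n_individuals`.
#' @return A list with integer vectors `m_case` and `m_control` and the
#'   group sizes `n_case`, `n_control`.
#' @export
count_rare_alleles <- function(geno, phenotypes) {
  y <- check_phenotypes(geno, phenotypes)
  m_total <- colSums(geno$matrix)
  m_case <- as.vector(crossprod(geno$matrix, y))
  list(m_case = as.integer(m_case),
       m_control = as.integer(m_total - m_case),
       n_case = sum(y), n_control = sum(1L - y))
}

#' Drop monomorphic variants from a region
#'
#' Removes variants carrying zero rare alleles across all individuals.
#' These contribute nothing to either density and are excluded before
#' testing; the number removed is attached as attribute `"n_dropped"`.
#'
#' @param geno A [region_genotypes()] object.
#' @return A `region_genotypes` object (possibly identical), or `NULL` when
#'   every variant is monomorphic.
#' @export
drop_monomorphic <- function(geno) {
  keep <- colSums(geno$matrix) > 0L
  n_dropped <- sum(!keep)
  if (!any(keep)) return(NULL)
  out <- if (n_dropped == 0L) geno else
    region_genotypes(geno$matrix[, keep, drop = FALSE],
                     geno$positions[keep], geno$region_length)
  attr(out, "n_dropped") <- n_dropped
  out
}
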