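#' Region definition in genomic coordinates
#'
#' BED-style region: 0-based half-open interval on a chromosome. Genomic
#' position `start + k` (1-based VCF coordinate) maps to region offset `k`.
#'
#' @param chrom Chromosome name as it appears in the VCF.
#' @param start 0-based start (as in BED).
#' @param end End coordinate (exclusive in BED terms, i.e. the last covered
#'   1-based position).
#' @param label Optional region label (e.g. gene name).
#' @return Object of class `"region_spec"`.
#' @export
region_spec <- function(chrom, start, end, label = NULL) {
  if (start >= end) stop("start must be < end", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end),
                 label = if (is.null(label))
                   sprintf("%s:%d-%d", chrom, start, end) else label),
            class = "region_spec")
}

#' Read BED regions
#'
#' @param path BED file (first four columns chrom, start, end, name; name
#'   optional).
#' @return List of [region_spec()] objects.
#' @export
read_bed_regions <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(bed)), function(i)
    region_spec(bed[i, 1], bed[i, 2], bed[i, 3],
                label = if (ncol(bed) >= 4) bed[i, 4] else NULL))
}

#' Read a phenotype table
#'
#' Two-column tab-separated file with header `sample_id`, `status`
#' (0 = control, 1 = case).
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `sample_id`, `status`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(ph)))
    stop("phenotype table must have columns sample_id and status",
         call. = FALSE)
  if (!all(ph$status %in% c(0L, 1L)))
    stop("phenotype status must be 0 or 1", call. = FALSE)
  ph
}

# Count "1" alleles in a vector of GT strings ("0/0", "0|1", "./.", ...).
# Missing calls return NA. Multi-allelic codes must be filtered upstream.
gt_to_count <- function(gt) {
  lut <- vapply(unique(gt), function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }, integer(1))
  unname(lut[match(gt, names(lut))])
}

#' Extract region genotypes from a VCF
#'
#' Reads biallelic variants inside a region from a VCF 4.x file, orients
#' each variant to its minor allele in the combined sample (genotypes are
#' flipped when the alternate-allele frequency exceeds 0.5), imputes missing
#' genotypes to 0 rare alleles, drops variants that are monomorphic or whose
#' sample MAF is at or above `maf_threshold`, and converts genomic positions
#' to 1-based offsets within the region.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param region A [region_spec()].
#' @param phenotypes A phenotype `data.frame` (columns `sample_id`,
#'   `status`) or the path to such a TSV.
#' @param maf_threshold Variants with sample MAF at or above this value are
#'   excluded; default 0.01 (the usual rare-variant cutoff).
#' @return A list with `geno` ([region_genotypes()] or `NULL` when no
#'   variant survives the filters), `phenotypes` (integer vector in the
#'   phenotype-table sample order), `status` (`"ok"` or `"empty_region"`),
#'   `n_missing_imputed`, `n_flipped`, `n_filtered_common`,
#'   `n_filtered_monomorphic`, `n_skipped_multiallelic`.
#' @export
read_region_genotypes <- function(vcf_path, region, phenotypes,
                                  maf_threshold = 0.01) {
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt)
  missing_in_vcf <- setdiff(phenotypes$sample_id, vcf_samples)
  extra_in_vcf <- setdiff(vcf_samples, phenotypes$sample_id)
  if (length(missing_in_vcf) || length(extra_in_vcf))
    stop("sample-ID mismatch between VCF and phenotype table; ",
         "absent from VCF: [", paste(missing_in_vcf, collapse = ", "),
         "]; absent from phenotype table: [",
         paste(extra_in_vcf, collapse = ", "), "]", call. = FALSE)

  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.numeric(fix[, "POS"])
  in_region <- fix[, "CHROM"] == region$chrom &
    pos > region$start & pos <= region$end
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skipped_multi <- sum(in_region & multi)
  if (n_skipped_multi > 0)
    warning(n_skipped_multi,
            " multiallelic record(s) in region skipped; split them upstream")
  keep <- which(in_region & !multi)

  y <- as.integer(phenotypes$status)
  empty <- list(geno = NULL, phenotypes = y, status = "empty_region",
                n_missing_imputed = 0L, n_flipped = 0L,
                n_filtered_common = 0L, n_filtered_monomorphic = 0L,
                n_skipped_multiallelic = n_skipped_multi)
  if (length(keep) == 0L) return(empty)

  gt <- gt[keep, phenotypes$sample_id, drop = FALSE]
  pos <- pos[keep]
  n <- length(y)
  counts <- matrix(gt_to_count(as.vector(t(gt))), nrow = n)  # N x P
  n_missing <- sum(is.na(counts))
  alt_freq <- colMeans(counts, na.rm = TRUE) / 2
  alt_freq[is.nan(alt_freq)] <- 0
  flip <- alt_freq > 0.5
  counts[, flip] <- 2L - counts[, flip, drop = FALSE]
  counts[is.na(counts)] <- 0L

  maf <- colSums(counts) / (2 * n)
  mono <- maf == 0
  common <- maf >= maf_threshold
  keep_var <- !mono & !common
  empty$n_missing_imputed <- n_missing
  empty$n_flipped <- sum(flip)
  empty$n_filtered_common <- sum(common)
  empty$n_filtered_monomorphic <- sum(mono)
  if (!any(keep_var)) return(empty)

  ord <- order(pos[keep_var])
  region_pos <- (pos[keep_var] - region$start)[ord]
  geno <- region_genotypes(counts[, keep_var, drop = FALSE][, ord,
                                                            drop = FALSE],
                           region_pos, region$end - region$start)
  out <- empty
  out$geno <- geno
  out$status <- "ok"
  out
}

#' Write association results as tab-separated text
#'
#' One row per (region, test): columns `region`, `test`, `statistic`,
#' `p_value`, `permutations`, `status`. Rows are ordered by region then test
#' so output is deterministic; `append = TRUE` adds rows without a header.
#' P-values are serialized with full precision, preserving the
#' `1/(B + 1)` granularity even for very large permutation counts.
#'
#' @param results `data.frame` holding the columns above (extra columns are
#'   dropped).
#' @param path Destination TSV.
#' @param append Append without header?
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, append = FALSE) {
  cols <- c("region", "test", "statistic", "p_value", "permutations",
            "status")
  if (nrow(results) == 0L) {
    if (!append)
      writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols))
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- results[order(results$region, results$test), cols, drop = FALSE]
  d$statistic <- sprintf("%.15g", d$statistic)
  d$p_value <- sprintf("%.15g", d$p_value)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Serialize a simulated dataset to VCF and phenotype TSV
#'
#' Writes a minimal VCF 4.2 text file (GT field only, synthetic REF/ALT
#' alleles) placing region offset `k` at genomic position `start + k`, plus
#' a companion phenotype table, so simulated data can round-trip through
#' [read_region_genotypes()].
#'
#' @param dataset A `cc_dataset` from [sample_case_control()], or any list
#'   with elements `geno` and `phenotypes`.
#' @param vcf_path Destination VCF path.
#' @param pheno_path Destination phenotype TSV path (default: `vcf_path`
#'   with a `.pheno.tsv` extension).
#' @param chrom Chromosome name to emit, default `"1"`.
#' @param start 0-based region start to emit, default 0.
#' @return The region as a [region_spec()], invisibly.
#' @export
write_region_vcf <- function(dataset, vcf_path, pheno_path = NULL,
                             chrom = "1", start = 0) {
  geno <- dataset$geno
  y <- dataset$phenotypes
  n <- geno$n_individuals
  samples <- sprintf("S%04d", seq_len(n))
  if (is.null(pheno_path)) pheno_path <- sub("\\.vcf$", "", vcf_path)
  if (!grepl("\\.pheno\\.tsv$", pheno_path))
    pheno_path <- paste0(pheno_path, ".pheno.tsv")

  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            as.integer(start + geno$region_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(geno$n_variants), function(j) {
    paste(c(chrom, as.integer(start + geno$positions[j]),
            sprintf("var%d", j), "A", "T", ".", "PASS", ".", "GT",
            gt_codes[geno$matrix[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  utils::write.table(data.frame(sample_id = samples, status = y),
                     pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(region_spec(chrom, start, start + geno$region_length))
}
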