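#' Per-SNP association statistics for a genotype-count table
#'
#' Runs the full single-SNP battery on every row of a genotype-count table:
#' case and control minor allele frequencies, call rates, the
#' Cochran-Armitage trend test, the genotypic 2x3 chi-squared test, exact
#' Hardy-Weinberg p-values in cases and controls, and the allelic odds ratio
#' with its Wald confidence interval. Input row order is preserved.
#'
#' @param counts A genotype-count table as returned by [genotype_counts()] or
#'   [read_genotype_counts()].
#' @param weights Trend-test genotype scores, default additive `c(0, 1, 2)`.
#' @param level Confidence level for the odds-ratio interval, default 0.95.
#' @return A tibble with one row per SNP and columns `snp_id`, `chrom`, `pos`,
#'   `minor_allele`, `major_allele`, `maf_case`, `maf_control`,
#'   `call_rate_case`, `call_rate_control`, `trend_stat`, `p_trend`,
#'   `genotypic_stat`, `genotypic_df`, `p_genotypic`, `p_hwe_case`,
#'   `p_hwe_control`, `or_allelic`, `ci_low`, `ci_high`, `log_or`,
#'   `se_log_or`, `or_corrected`.
#' @examples
#' tsv <- system.file("extdata", "rit2_snp_counts.tsv", package = "gwasrx")
#' assoc_table(read_genotype_counts(tsv))
#' @export
assoc_table <- function(counts, weights = c(0, 1, 2), level = 0.95) {
  counts <- validate_genotype_counts(counts)
  one <- function(row) {
    ca <- c(row$case_hom_minor, row$case_het, row$case_hom_major)
    co <- c(row$control_hom_minor, row$control_het, row$control_hom_major)
    trend <- catt_test(ca, co, weights)
    geno <- genotypic_chi2_test(ca, co)
    orr <- allelic_or(ca, co, level)
    tibble::tibble(
      snp_id = row$snp_id,
      chrom = row$chrom,
      pos = row$pos,
      minor_allele = row$minor_allele,
      major_allele = row$major_allele,
      maf_case = compute_maf(ca),
      maf_control = compute_maf(co),
      call_rate_case = call_rate(sum(ca), sum(ca) + row$case_missing),
      call_rate_control = call_rate(sum(co), sum(co) + row$control_missing),
      trend_stat = trend$statistic,
      p_trend = trend$p_value,
      genotypic_stat = geno$statistic,
      genotypic_df = geno$df,
      p_genotypic = geno$p_value,
      p_hwe_case = hwe_exact_test(ca),
      p_hwe_control = hwe_exact_test(co),
      or_allelic = orr$or,
      ci_low = orr$ci_low,
      ci_high = orr$ci_high,
      log_or = orr$log_or,
      se_log_or = orr$se,
      or_corrected = orr$corrected
    )
  }
  counts |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map(one) |>
    purrr::list_rbind()
}

#' Plot-ready regional association data
#'
#' Converts an association table into the tidy form used for regional
#' (LocusZoom-style) plots: position, `-log10` trend p-value, and, when
#' supplied, LD `r2` to an index SNP. Rows are sorted by position.
#'
#' @param assoc An association tibble from [assoc_table()].
#' @param r2_to_index Optional named numeric vector of `r2` values keyed by
#'   `snp_id`; SNPs without an entry get `NA`.
#' @return A tibble with `snp_id`, `pos`, `minus_log10_p_trend`, `r2_to_index`.
#' @export
regional_plot_data <- function(assoc, r2_to_index = NULL) {
  assoc <- tibble::as_tibble(assoc)
  if (nrow(assoc) == 0L) abort("association table is empty")
  r2 <- if (is.null(r2_to_index)) rep(NA_real_, nrow(assoc)) else
    unname(r2_to_index[assoc$snp_id])
  assoc |>
    dplyr::transmute(
      snp_id = .data$snp_id,
      pos = .data$pos,
      minus_log10_p_trend = -log10(.data$p_trend),
      r2_to_index = r2
    ) |>
    dplyr::arrange(.data$pos)
}
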