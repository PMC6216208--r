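# Vectorised trend statistic on 3 x k matrices of genotype counts;
# returns the 1-df chi-square statistic (0 where the pooled sample is
# monomorphic and the score variance vanishes).
.catt_stat <- function(case, control, weights = c(0, 1, 2)) {
  case <- as.matrix(case); control <- as.matrix(control)
  tot <- case + control
  n1 <- colSums(case)
  n <- colSums(tot)
  pbar <- n1 / n
  u <- colSums(weights * case) - pbar * colSums(weights * tot)
  v <- pbar * (1 - pbar) * (colSums(weights^2 * tot) - colSums(weights * tot)^2 / n)
  stat <- ifelse(v > 0, u^2 / v, 0)
  stat
}

#' Cochran-Armitage trend test for a case-control genotype table
#'
#' The 1-df chi-square trend test across the three genotype classes, with
#' additive dose weights by default and no continuity correction. The p-value
#' is the upper tail of chi-square(1). The statistic is invariant to reversing
#' the genotype ordering simultaneously in both groups.
#'
#' @param case,control Genotype triples `(hom_minor, het, hom_major)`.
#' @param weights Genotype scores; the default `c(0, 1, 2)` counts minor
#'   alleles (the additive model standard in GWAS).
#' @return A one-row tibble with `statistic`, `df`, `p_value` and `degenerate`
#'   (`TRUE`, with a warning, when the pooled sample is monomorphic so the
#'   score variance is zero; then `statistic = 0`, `p_value = 1`).
#' @examples
#' catt_test(c(176, 477, 335), c(330, 1172, 1018))  # p ~ 1.37e-5
#' @export
catt_test <- function(case, control, weights = c(0, 1, 2)) {
  case <- .check_triple(case, "case triple")
  control <- .check_triple(control, "control triple")
  if (length(weights) != 3L || anyNA(weights)) {
    abort("weights must be three finite genotype scores")
  }
  tot <- case + control
  n <- sum(tot)
  v <- sum(weights^2 * tot) - sum(weights * tot)^2 / n
  degenerate <- v <= 0
  if (degenerate) {
    warn("pooled sample is monomorphic for the scored classes; trend statistic set to 0")
    stat <- 0
  } else {
    stat <- .catt_stat(matrix(case), matrix(control), weights)
  }
  tibble::tibble(
    statistic = unname(stat),
    df = 1L,
    p_value = pchisq(unname(stat), df = 1, lower.tail = FALSE),
    degenerate = degenerate
  )
}

#' Genotypic 2x3 chi-squared test
#'
#' Pearson chi-square on the case/control-by-genotype contingency table,
#' without continuity correction. Genotype columns with zero pooled count are
#' dropped and the degrees of freedom reduced accordingly.
#'
#' @inheritParams catt_test
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @examples
#' genotypic_chi2_test(c(176, 477, 335), c(330, 1172, 1018))  # p ~ 6.8e-5
#' @export
genotypic_chi2_test <- function(case, control) {
  case <- .check_triple(case, "case triple")
  control <- .check_triple(control, "control triple")
  keep <- (case + control) > 0
  if (sum(keep) < 2L) {
    abort("fewer than 2 non-empty genotype classes: genotypic test undefined")
  }
  tab <- rbind(case[keep], control[keep])
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = as.integer(fit$parameter),
    p_value = unname(fit$p.value)
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Enumerates every heterozygote count consistent with the observed allele
#' counts, computes each configuration's probability under the conditional
#' (hypergeometric) HWE null, and returns the summed probability of all
#' configurations no more probable than the observed one. This is the
#' standard exact test, not the mid-p variant. A monomorphic sample returns 1.
#'
#' @param counts Genotype triple `(hom_minor, het, hom_major)`.
#' @return The exact two-sided p-value.
#' @examples
#' hwe_exact_test(c(330, 1172, 1018))  # 0.8296 to 4 decimals
#' @export
hwe_exact_test <- function(counts) {
  counts <- .check_triple(counts)
  n <- sum(counts)
  n_minor <- 2 * counts[1] + counts[2]
  rare <- min(n_minor, 2 * n - n_minor)
  if (rare == 0) return(1)
  hets <- seq.int(rare %% 2, rare, by = 2L)
  homr <- (rare - hets) / 2
  homc <- n - homr - hets
  # log conditional probability of each heterozygote count given allele counts
  lp <- lgamma(n + 1) - lgamma(homr + 1) - lgamma(hets + 1) - lgamma(homc + 1) +
    hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[hets == counts[2]]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Asymptotic 1-df chi-square test of Hardy-Weinberg equilibrium
#'
#' The classical goodness-of-fit chi-square against expected proportions
#' `p^2, 2pq, q^2` at the sample allele frequency. Provided for comparison;
#' [hwe_exact_test()] is the default throughout the package because the
#' asymptotic approximation is poor at low minor-allele counts.
#'
#' @inheritParams hwe_exact_test
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
hwe_chisq_test <- function(counts) {
  counts <- .check_triple(counts)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1))
  }
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expd)^2 / expd)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Allelic odds ratio with Wald confidence interval
#'
#' Collapses genotype triples to allele counts (minor = `2*hom_minor + het`),
#' forms the 2x2 allele table, and reports the odds ratio of carrying the
#' minor allele in cases versus controls with a Wald interval on the log
#' scale. If any allele cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) and `corrected` is flagged.
#'
#' @inheritParams catt_test
#' @param level Two-sided confidence level, default 0.95.
#' @return A one-row tibble with `or`, `ci_low`, `ci_high`, `log_or`, `se`
#'   and `corrected`.
#' @examples
#' allelic_or(c(176, 477, 335), c(330, 1172, 1018))  # OR 1.27 (1.14-1.41)
#' @export
allelic_or <- function(case, control, level = 0.95) {
  case <- .check_triple(case, "case triple")
  control <- .check_triple(control, "control triple")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("level must be in (0, 1)")
  }
  cells <- c(
    case_minor = 2 * case[1] + case[2],
    case_major = 2 * case[3] + case[2],
    control_minor = 2 * control[1] + control[2],
    control_major = 2 * control[3] + control[2]
  )
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  if (cells["case_minor"] + cells["case_major"] <= 0 ||
      cells["control_minor"] + cells["control_major"] <= 0) {
    abort("a group has no observed alleles: odds ratio undefined")
  }
  log_or <- log(cells["case_minor"]) + log(cells["control_major"]) -
    log(cells["case_major"]) - log(cells["control_minor"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    or = exp(unname(log_or)),
    ci_low = exp(unname(log_or) - z * se),
    ci_high = exp(unname(log_or) + z * se),
    log_or = unname(log_or),
    se = unname(se),
    corrected = corrected
  )
}
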