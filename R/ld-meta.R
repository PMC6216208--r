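#' Linkage-disequilibrium r-squared from phased haplotype counts
#'
#' Computes the squared allelic correlation between two loci from the four
#' phased two-locus haplotype counts. With haplotype frequencies `p_AB` etc.,
#' `D = p_AB - p_A * p_B` and `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#'
#' @param haplotypes Numeric vector of four non-negative counts in the order
#'   `(AB, Ab, aB, ab)`; names, if present, are ignored.
#' @return `r2` in `[0, 1]`. Errors if either locus is monomorphic.
#' @examples
#' ld_r2(c(50, 0, 0, 50))       # 1: perfect LD
#' ld_r2(c(40, 10, 10, 40))     # 0.36
#' @export
ld_r2 <- function(haplotypes) {
  h <- as.numeric(haplotypes)
  if (length(h) != 4L || anyNA(h) || any(h < 0) || sum(h) < 1) {
    abort("haplotypes must be four non-negative counts (AB, Ab, aB, ab) summing to >= 1")
  }
  n <- sum(h)
  p_a <- (h[1] + h[2]) / n
  p_b <- (h[1] + h[3]) / n
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    abort("a locus is monomorphic: r-squared undefined")
  }
  d <- h[1] / n - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Inverse-variance fixed-effects meta-analysis of log odds ratios
#'
#' Pools per-study log odds ratios with weights `w_i = 1/se_i^2`:
#' `pooled = sum(w x) / sum(w)` with standard error `1/sqrt(sum(w))`, a
#' two-sided normal z test, and the confidence interval exponentiated to the
#' odds-ratio scale. A single study is returned unchanged.
#'
#' @param studies Data frame with columns `study_id`, `log_or` and `se`
#'   (per-study log odds ratio and its standard error, all `se > 0`).
#' @param level Confidence level for the pooled interval, default 0.95.
#' @return An object of class `fe_meta`; see [tidy.fe_meta()] for per-study
#'   rows and [glance.fe_meta()] for the pooled one-row summary.
#' @examples
#' studies <- tibble::tibble(study_id = c("discovery", "replication"),
#'                           log_or = c(0.2, 0.4), se = c(0.1, 0.2))
#' glance(fixed_effects_meta(studies))
#' @export
fixed_effects_meta <- function(studies, level = 0.95) {
  studies <- tibble::as_tibble(studies)
  need <- c("study_id", "log_or", "se")
  if (!all(need %in% names(studies))) {
    abort("studies needs columns study_id, log_or, se")
  }
  if (nrow(studies) == 0L) abort("meta-analysis of an empty study list is undefined")
  if (anyNA(studies$log_or) || anyNA(studies$se) || any(studies$se <= 0)) {
    abort("every study needs a finite log_or and a positive se")
  }
  w <- 1 / studies$se^2
  pooled <- sum(w * studies$log_or) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  q <- qnorm(1 - (1 - level) / 2)
  structure(
    list(
      studies = dplyr::mutate(studies, weight = w / sum(w)),
      pooled_log_or = pooled,
      pooled_se = pooled_se,
      or = exp(pooled),
      ci_low = exp(pooled - q * pooled_se),
      ci_high = exp(pooled + q * pooled_se),
      z = z,
      p = 2 * pnorm(-abs(z)),
      level = level
    ),
    class = "fe_meta"
  )
}

#' @export
print.fe_meta <- function(x, ...) {
  cat("Fixed-effects meta-analysis:", nrow(x$studies), "studies\n")
  cat(sprintf("  pooled OR %.3f (%d%% CI %.3f-%.3f), z = %.3f, p = %.3g\n",
              x$or, round(100 * x$level), x$ci_low, x$ci_high, x$z, x$p))
  invisible(x)
}

#' Per-study components of a fixed-effects meta-analysis
#'
#' @param x An `fe_meta` fit.
#' @param ... Unused.
#' @return A tibble with one row per study: `study_id`, `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high` and the normalised inverse-variance `weight`.
#' @method tidy fe_meta
#' @export
tidy.fe_meta <- function(x, ...) {
  q <- qnorm(1 - (1 - x$level) / 2)
  dplyr::mutate(x$studies,
                or = exp(.data$log_or),
                ci_low = exp(.data$log_or - q * .data$se),
                ci_high = exp(.data$log_or + q * .data$se))
}

#' One-row pooled summary of a fixed-effects meta-analysis
#'
#' @inheritParams tidy.fe_meta
#' @return A one-row tibble with `n_studies`, `pooled_log_or`, `pooled_se`,
#'   `or`, `ci_low`, `ci_high`, `z`, `p`.
#' @method glance fe_meta
#' @export
glance.fe_meta <- function(x, ...) {
  tibble::tibble(
    n_studies = nrow(x$studies),
    pooled_log_or = x$pooled_log_or,
    pooled_se = x$pooled_se,
    or = x$or,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    z = x$z,
    p = x$p
  )
}
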