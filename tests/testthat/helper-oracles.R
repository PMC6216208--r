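# Independent oracles, kept deliberately distinct from the package's own
# computation paths.

# RIT2 locus genotype counts bundled with the package (printed study counts)
rit2_counts <- function() {
  read_genotype_counts(system.file("extdata", "rit2_snp_counts.tsv",
                                   package = "gwasrx"))
}

# Exact HWE null distribution over heterozygote counts via the ratio
# recurrence P(h-2)/P(h) = h(h-1) / (4 (n_hom_rare + 1)(n_hom_common + 1)),
# a different route than the package's log-factorial closed form.
hwe_recurrence_p <- function(counts) {
  n <- sum(counts)
  rare <- min(2 * counts[1] + counts[2], 2 * counts[3] + counts[2])
  if (rare == 0) return(1)
  hets <- seq.int(rare %% 2, rare, by = 2L)
  w <- numeric(length(hets))
  w[length(hets)] <- 1
  for (k in rev(seq_along(hets))[-1]) {
    h <- hets[k + 1L]
    homr_next <- (rare - (h - 2)) / 2
    homc_next <- n - homr_next - (h - 2)
    w[k] <- w[k + 1L] * h * (h - 1) / (4 * homr_next * homc_next)
  }
  p <- w / sum(w)
  obs <- p[hets == counts[2]]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# Conditional permutation distribution of the trend statistic: random 2x3
# tables with the observed margins (case/control totals, genotype totals).
# Returns the strict and inclusive permutation p-values and their MC se.
catt_permutation_band <- function(case, control, n_resamples = 1e5) {
  obs <- catt_test(case, control)$statistic
  tabs <- stats::r2dtable(n_resamples, c(sum(case), sum(control)), case + control)
  ca <- vapply(tabs, function(t) t[1, ], numeric(3))
  w <- c(0, 1, 2)
  tot <- case + control
  n <- sum(tot)
  pbar <- sum(case) / n
  u <- colSums(w * ca) - pbar * sum(w * tot)
  v <- pbar * (1 - pbar) * (sum(w^2 * tot) - sum(w * tot)^2 / n)
  stats <- if (v > 0) u^2 / v else rep(0, n_resamples)
  incl <- mean(stats >= obs - 1e-9)
  strict <- mean(stats > obs + 1e-9)
  se <- sqrt(max(incl, 1 / n_resamples) * (1 - min(incl, 1 - 1 / n_resamples)) /
               n_resamples)
  list(strict = strict, inclusive = incl, se = se)
}
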