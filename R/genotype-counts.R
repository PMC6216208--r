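#' Build a validated genotype-count table
#'
#' Constructs the tibble that all association statistics consume: one row per
#' SNP, with case and control genotype counts in the fixed ordering
#' (hom-minor, het, hom-major). This is the in-memory mirror of the
#' genotype-count TSV dialect (see [read_genotype_counts()]).
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chrom Chromosome labels (character).
#' @param pos 1-based positions (positive integers). The genome build is a
#'   free-text label carried alongside, default `"hg19"`.
#' @param minor_allele,major_allele Single-nucleotide allele labels; must
#'   differ within each row.
#' @param case_hom_minor,case_het,case_hom_major Case genotype counts.
#' @param control_hom_minor,control_het,control_hom_major Control genotype counts.
#' @param case_missing,control_missing Samples attempted but not genotyped
#'   (default 0); used only for call rates.
#' @param build Genome build label (recycled), default `"hg19"`.
#'
#' @return A tibble of class `gwasrx_counts` with one row per SNP.
#' @examples
#' genotype_counts("rs4130047", "18", 40678235, "C", "T",
#'                 176, 477, 335, 330, 1172, 1018, control_missing = 1)
#' @export
genotype_counts <- function(snp_id, chrom, pos, minor_allele, major_allele,
                            case_hom_minor, case_het, case_hom_major,
                            control_hom_minor, control_het, control_hom_major,
                            case_missing = 0, control_missing = 0,
                            build = "hg19") {
  out <- tibble::tibble(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    minor_allele = toupper(as.character(minor_allele)),
    major_allele = toupper(as.character(major_allele)),
    case_hom_minor = as.integer(case_hom_minor),
    case_het = as.integer(case_het),
    case_hom_major = as.integer(case_hom_major),
    control_hom_minor = as.integer(control_hom_minor),
    control_het = as.integer(control_het),
    control_hom_major = as.integer(control_hom_major),
    case_missing = as.integer(case_missing),
    control_missing = as.integer(control_missing),
    build = as.character(build)
  )
  validate_genotype_counts(out)
}

#' Validate a genotype-count table
#'
#' Checks the invariants every downstream statistic relies on: unique SNP ids,
#' distinct alleles, positive positions, non-negative integer counts, and both
#' genotype triples summing to at least one sample.
#'
#' @param x A data frame shaped like the output of [genotype_counts()].
#' @return `x` as a `gwasrx_counts` tibble, invisibly usable downstream.
#' @export
validate_genotype_counts <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("snp_id", "chrom", "pos", "minor_allele", "major_allele",
            "case_hom_minor", "case_het", "case_hom_major",
            "control_hom_minor", "control_het", "control_hom_major")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("genotype-count table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"case_missing" %in% names(x)) x$case_missing <- 0L
  if (!"control_missing" %in% names(x)) x$control_missing <- 0L
  if (!"build" %in% names(x)) x$build <- "hg19"
  x$case_missing[is.na(x$case_missing)] <- 0L
  x$control_missing[is.na(x$control_missing)] <- 0L

  if (nrow(x) == 0L) abort("genotype-count table is empty")
  if (anyDuplicated(x$snp_id)) {
    dup <- unique(x$snp_id[duplicated(x$snp_id)])
    abort(paste0("duplicate snp_id: ", paste(dup, collapse = ", ")))
  }
  cnt <- c("case_hom_minor", "case_het", "case_hom_major",
           "control_hom_minor", "control_het", "control_hom_major",
           "case_missing", "control_missing")
  for (cc in cnt) {
    v <- x[[cc]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(sprintf("column %s has a missing, negative or non-integer count at row %d",
                    cc, bad[1]))
    }
  }
  case_n <- x$case_hom_minor + x$case_het + x$case_hom_major
  ctrl_n <- x$control_hom_minor + x$control_het + x$control_hom_major
  if (any(case_n < 1)) {
    abort(sprintf("case genotype triple sums to zero at row %d (snp %s)",
                  which(case_n < 1)[1], x$snp_id[which(case_n < 1)[1]]))
  }
  if (any(ctrl_n < 1)) {
    abort(sprintf("control genotype triple sums to zero at row %d (snp %s)",
                  which(ctrl_n < 1)[1], x$snp_id[which(ctrl_n < 1)[1]]))
  }
  same <- which(x$minor_allele == x$major_allele)
  if (length(same)) {
    abort(sprintf("minor and major allele identical at row %d (snp %s)",
                  same[1], x$snp_id[same[1]]))
  }
  if (any(is.na(x$pos) | x$pos < 1)) abort("pos must be a positive 1-based integer")
  class(x) <- c("gwasrx_counts", class(x))
  x
}

#' Minor allele frequency from a genotype triple
#'
#' @param counts Genotype triple `(hom_minor, het, hom_major)`.
#' @return The minor allele frequency `(2*hom_minor + het) / (2*n)`.
#' @examples
#' compute_maf(c(176, 477, 335))  # 0.4195...
#' @export
compute_maf <- function(counts) {
  counts <- .check_triple(counts)
  (2 * counts[1] + counts[2]) / (2 * sum(counts))
}

#' Genotyping call rate
#'
#' @param genotyped Number of samples successfully genotyped at the SNP.
#' @param total Cohort size attempted.
#' @return `genotyped / total`.
#' @examples
#' call_rate(2520, 2521)
#' @export
call_rate <- function(genotyped, total) {
  if (length(genotyped) != 1L || length(total) != 1L ||
      is.na(genotyped) || is.na(total) || total < 1 ||
      genotyped < 0 || genotyped > total) {
    abort("call_rate needs 0 <= genotyped <= total with total >= 1")
  }
  genotyped / total
}
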