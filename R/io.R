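# Print conventions for machine-readable tables: p-values in scientific
# notation with 3 significant digits (lower-case 'e'), fractions to 4 decimals.
.fmt_p <- function(p) formatC(p, format = "e", digits = 2)
.fmt_frac <- function(x) sprintf("%.4f", x)
.fmt_num <- function(x) sprintf("%.4f", x)

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], rows = which(keep))
}

#' Read a genotype-count TSV
#'
#' Reads the tab-separated genotype-count dialect: a header line with columns
#' `snp_id, chrom, pos, minor_allele, major_allele, case_hom_minor, case_het,
#' case_hom_major, control_hom_minor, control_het, control_hom_major` and
#' optional `case_missing, control_missing`; lines starting with `#` are
#' comments. Every record is validated (non-negative integer counts, triples
#' summing to at least one, unique SNP ids) with errors naming the offending
#' row and column.
#'
#' @param path Path to the TSV file.
#' @return A validated `gwasrx_counts` tibble (see [genotype_counts()]).
#' @examples
#' tsv <- system.file("extdata", "rit2_snp_counts.tsv", package = "gwasrx")
#' read_genotype_counts(tsv)
#' @export
read_genotype_counts <- function(path) {
  src <- .read_tsv_lines(path)
  if (length(src$lines) < 2L) abort("genotype-count file has no data rows")
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  need <- c("snp_id", "chrom", "pos", "minor_allele", "major_allele",
            "case_hom_minor", "case_het", "case_hom_major",
            "control_hom_minor", "control_het", "control_hom_major")
  if (!all(need %in% header)) {
    abort(paste0("genotype-count header lacks column(s): ",
                 paste(setdiff(need, header), collapse = ", ")))
  }
  body <- fields[-1]
  rows <- src$rows[-1]
  bad_len <- which(lengths(body) != length(header))
  if (length(bad_len)) {
    abort(sprintf("line %d has %d field(s), expected %d",
                  rows[bad_len[1]], lengths(body)[bad_len[1]], length(header)))
  }
  m <- do.call(rbind, body)
  colnames(m) <- header
  df <- tibble::as_tibble(m)
  int_cols <- c("pos", "case_hom_minor", "case_het", "case_hom_major",
                "control_hom_minor", "control_het", "control_hom_major",
                intersect(c("case_missing", "control_missing"), header))
  for (cc in int_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(sprintf("line %d, column %s: '%s' is not a non-negative integer",
                    rows[bad[1]], cc, df[[cc]][bad[1]]))
    }
    df[[cc]] <- as.integer(v)
  }
  validate_genotype_counts(df)
}

#' Write a genotype-count TSV
#'
#' Inverse of [read_genotype_counts()]: `read_genotype_counts(write_genotype_counts(x, f))`
#' returns `x`.
#'
#' @param counts A validated genotype-count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_counts <- function(counts, path) {
  counts <- validate_genotype_counts(counts)
  cols <- c("snp_id", "chrom", "pos", "minor_allele", "major_allele",
            "case_hom_minor", "case_het", "case_hom_major",
            "control_hom_minor", "control_het", "control_hom_major",
            "case_missing", "control_missing", "build")
  readr::write_tsv(counts[cols], path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' `#` starts a comment (whole-line or trailing); blank lines are skipped.
#' Symbols are uppercase-normalised and deduplicated.
#'
#' @param path Path to the text file.
#' @return Sorted character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  rows <- which(nzchar(lines))
  if (length(rows) == 0L) abort("gene list is empty")
  vals <- lines[rows]
  bad <- which(grepl("\\s", vals))
  if (length(bad)) {
    abort(sprintf("line %d is not a single gene symbol: '%s'", rows[bad[1]], vals[bad[1]]))
  }
  gene_set(vals)
}

#' Read an undirected PPI edge list
#'
#' Each non-comment line holds two whitespace-separated gene symbols (any
#' further columns are ignored). Edges are undirected: reversed duplicates
#' collapse to one record, self-loops are dropped, and the number removed is
#' reported.
#'
#' @param path Path to the edge file.
#' @param quiet Suppress the normalisation message.
#' @return A `ppi_network` tibble (see [ppi_network()]).
#' @export
read_ppi_edges <- function(path, quiet = FALSE) {
  src <- .read_tsv_lines(path)
  if (length(src$lines) == 0L) abort("PPI edge file is empty")
  toks <- strsplit(trimws(src$lines), "\\s+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    abort(sprintf("line %d does not contain two gene symbols", src$rows[bad[1]]))
  }
  first <- vapply(toks, `[[`, "", 1L)
  second <- vapply(toks, `[[`, "", 2L)
  # tolerate a header line naming the two columns
  if (tolower(first[1]) %in% c("gene_a", "gene1", "protein_a") ||
      tolower(second[1]) %in% c("gene_b", "gene2", "protein_b")) {
    first <- first[-1]; second <- second[-1]
  }
  ppi_network(tibble::tibble(a = first, b = second), quiet = quiet)
}

#' Read a drug-target TSV
#'
#' Header columns: `drug_id, drug_name, target_gene, approval_status` and
#' optionally `family_id`. `#` lines are comments. Duplicate
#' `(drug_id, target_gene)` records are collapsed with a message.
#'
#' @param path Path to the TSV file.
#' @param quiet Suppress the deduplication message.
#' @return A `drug_targets` tibble (see [drug_targets()]).
#' @export
read_drug_targets <- function(path, quiet = FALSE) {
  src <- .read_tsv_lines(path)
  if (length(src$lines) < 2L) abort("drug-target file has no data rows")
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  need <- c("drug_id", "drug_name", "target_gene", "approval_status")
  if (!all(need %in% header)) {
    abort(paste0("drug-target header lacks column(s): ",
                 paste(setdiff(need, header), collapse = ", ")))
  }
  body <- fields[-1]
  rows <- src$rows[-1]
  bad_len <- which(lengths(body) < length(header))
  if (length(bad_len)) {
    abort(sprintf("line %d has %d field(s), expected %d",
                  rows[bad_len[1]], lengths(body)[bad_len[1]], length(header)))
  }
  m <- do.call(rbind, lapply(body, function(x) x[seq_along(header)]))
  colnames(m) <- header
  drug_targets(tibble::as_tibble(m), quiet = quiet)
}

#' Write an association-results TSV
#'
#' Serialises an [assoc_table()] result with deterministic column order and
#' print precision: fractions (MAF, call rates, HWE p) to 4 decimals,
#' association p-values in scientific notation with 3 significant digits,
#' statistics and odds ratios to 4 decimals.
#'
#' @param assoc Association tibble from [assoc_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  assoc <- tibble::as_tibble(assoc)
  if (nrow(assoc) == 0L) abort("association table is empty")
  out <- assoc |>
    dplyr::transmute(
      snp_id = .data$snp_id,
      chrom = .data$chrom,
      pos = .data$pos,
      minor_allele = .data$minor_allele,
      major_allele = .data$major_allele,
      maf_case = .fmt_frac(.data$maf_case),
      maf_control = .fmt_frac(.data$maf_control),
      call_rate_case = .fmt_frac(.data$call_rate_case),
      call_rate_control = .fmt_frac(.data$call_rate_control),
      trend_stat = .fmt_num(.data$trend_stat),
      p_trend = .fmt_p(.data$p_trend),
      genotypic_stat = .fmt_num(.data$genotypic_stat),
      p_genotypic = .fmt_p(.data$p_genotypic),
      p_hwe_case = .fmt_frac(.data$p_hwe_case),
      p_hwe_control = .fmt_frac(.data$p_hwe_control),
      or_allelic = .fmt_num(.data$or_allelic),
      ci_low = .fmt_num(.data$ci_low),
      ci_high = .fmt_num(.data$ci_high)
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a screen report TSV
#'
#' The count cascade is written as `#`-prefixed key-value header lines,
#' followed by the candidate table (drug_id, drug_name, family, target_gene,
#' provenance). Stable and diff-friendly: identical inputs give
#' byte-identical files.
#'
#' @param report A `screen_report` from [screen_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  hdr <- vapply(names(report$counts),
                function(k) sprintf("# %s\t%d", k, report$counts[[k]]), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("drug_id", "drug_name", "family", "target_gene", "provenance"),
                   collapse = "\t"), con)
  if (nrow(report$candidates)) {
    apply_rows <- apply(report$candidates, 1L, paste, collapse = "\t")
    writeLines(apply_rows, con)
  }
  invisible(path)
}

#' Write plot-ready regional association data
#'
#' @param plot_data Tibble from [regional_plot_data()] (an [assoc_table()]
#'   result is also accepted and converted first). Rows are written sorted
#'   by position.
#' @param path Output path.
#' @param r2_to_index Passed to [regional_plot_data()] when `plot_data` is an
#'   association table.
#' @return `path`, invisibly.
#' @export
write_plotdata_tsv <- function(plot_data, path, r2_to_index = NULL) {
  plot_data <- tibble::as_tibble(plot_data)
  if (!"minus_log10_p_trend" %in% names(plot_data)) {
    plot_data <- regional_plot_data(plot_data, r2_to_index)
  }
  if (nrow(plot_data) == 0L) abort("plot data table is empty")
  out <- plot_data |>
    dplyr::arrange(.data$pos) |>
    dplyr::mutate(
      minus_log10_p_trend = .fmt_num(.data$minus_log10_p_trend),
      r2_to_index = ifelse(is.na(.data$r2_to_index), "NA",
                           .fmt_frac(.data$r2_to_index))
    )
  readr::write_tsv(out, path)
  invisible(path)
}
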