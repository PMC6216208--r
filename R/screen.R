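#' Normalise a set of gene symbols
#'
#' Uppercases, trims, drops empties and duplicates. All screen operations use
#' this normalisation, so inputs differing only by case are equivalent.
#'
#' @param genes Character vector of gene symbols.
#' @return Sorted unique uppercase symbols.
#' @export
gene_set <- function(genes) {
  g <- .norm_symbol(genes)
  g <- g[!is.na(g) & nzchar(g)]
  sort(unique(g))
}

#' Build a protein-protein-interaction edge table
#'
#' Normalises an undirected edge list: symbols are uppercased, self-loops
#' dropped, and duplicate or reversed edges collapsed, with the number of
#' records removed reported via a message.
#'
#' @param edges Data frame whose first two columns are gene symbols, or a
#'   two-column character matrix.
#' @param quiet Suppress the normalisation message.
#' @return A tibble of class `ppi_network` with columns `gene_a`, `gene_b`
#'   (`gene_a < gene_b` within each row, rows sorted).
#' @examples
#' ppi_network(data.frame(a = c("snca", "SNCA"), b = c("UCHL1", "uchl1")))
#' @export
ppi_network <- function(edges, quiet = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) abort("edge table needs two gene-symbol columns")
  a <- .norm_symbol(edges[[1]])
  b <- .norm_symbol(edges[[2]])
  keep <- nzchar(a) & nzchar(b) & !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n_in <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- tibble::tibble(gene_a = lo, gene_b = hi) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  dropped <- n_in - nrow(out)
  if (!quiet && dropped > 0) {
    inform(sprintf("ppi_network: removed %d self-loop/duplicate edge record(s)", dropped))
  }
  class(out) <- c("ppi_network", class(out))
  out
}

#' First PPI neighbors of a seed gene set
#'
#' Returns the union of direct interaction partners of the seed genes, with
#' the seeds themselves excluded, so that the combined disease gene set has
#' size `|seeds| + |neighbors|`. Seeds absent from the network contribute no
#' neighbors and are reported in a warning.
#'
#' @param network A `ppi_network` edge tibble (or coercible edge table).
#' @param seeds Character vector of seed gene symbols.
#' @return Sorted character vector of neighbor symbols (never overlapping
#'   the seeds).
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "A", "B", "C"),
#'                               b = c("B", "C", "C", "D")))
#' first_neighbors(net, "A")
#' @export
first_neighbors <- function(network, seeds) {
  seeds <- gene_set(seeds)
  if (length(seeds) == 0L) abort("seed gene set is empty")
  if (!inherits(network, "ppi_network")) network <- ppi_network(network, quiet = TRUE)
  in_net <- unique(c(network$gene_a, network$gene_b))
  absent <- setdiff(seeds, in_net)
  if (length(absent)) {
    warn(paste0("seed gene(s) absent from the network: ",
                paste(absent, collapse = ", ")))
  }
  hit_a <- network$gene_a %in% seeds
  hit_b <- network$gene_b %in% seeds
  nb <- c(network$gene_b[hit_a], network$gene_a[hit_b])
  setdiff(sort(unique(nb)), seeds)
}

#' Combine seeds and neighbors into a provenance-tagged disease gene set
#'
#' @param seeds,neighbors Character vectors of gene symbols; must be disjoint
#'   (as guaranteed by [first_neighbors()]).
#' @return A tibble with columns `gene` and `provenance`
#'   (`"seed"` or `"neighbor"`), sorted by gene.
#' @export
disease_gene_set <- function(seeds, neighbors) {
  seeds <- gene_set(seeds)
  neighbors <- gene_set(neighbors)
  overlap <- intersect(seeds, neighbors)
  if (length(overlap)) {
    abort(paste0("seeds and neighbors overlap (", paste(overlap, collapse = ", "),
                 "); derive neighbors with first_neighbors()"))
  }
  tibble::tibble(
    gene = c(seeds, neighbors),
    provenance = c(rep("seed", length(seeds)), rep("neighbor", length(neighbors)))
  ) |>
    dplyr::arrange(.data$gene)
}

#' Build a validated drug-target table
#'
#' @param drugs Data frame with columns `drug_id`, `drug_name`, `target_gene`,
#'   `approval_status` and optionally `family_id`. Target symbols are
#'   normalised; duplicate `(drug_id, target_gene)` records are collapsed
#'   with a message.
#' @param quiet Suppress the deduplication message.
#' @return A `drug_targets` tibble.
#' @export
drug_targets <- function(drugs, quiet = FALSE) {
  drugs <- tibble::as_tibble(drugs)
  need <- c("drug_id", "drug_name", "target_gene", "approval_status")
  if (!all(need %in% names(drugs))) {
    abort("drug table needs columns drug_id, drug_name, target_gene, approval_status")
  }
  if (!"family_id" %in% names(drugs)) drugs$family_id <- NA_character_
  drugs <- drugs |>
    dplyr::mutate(
      drug_id = as.character(.data$drug_id),
      drug_name = as.character(.data$drug_name),
      target_gene = .norm_symbol(.data$target_gene),
      approval_status = tolower(trimws(as.character(.data$approval_status))),
      family_id = dplyr::na_if(as.character(.data$family_id), "")
    )
  if (any(!nzchar(drugs$target_gene) | is.na(drugs$target_gene))) {
    abort("drug table contains an empty target gene symbol")
  }
  n_in <- nrow(drugs)
  drugs <- dplyr::distinct(drugs, .data$drug_id, .data$target_gene, .keep_all = TRUE)
  if (!quiet && nrow(drugs) < n_in) {
    inform(sprintf("drug_targets: collapsed %d duplicate (drug, target) record(s)",
                   n_in - nrow(drugs)))
  }
  class(drugs) <- c("drug_targets", class(drugs))
  drugs
}

#' Intersect a disease gene set with drug targets
#'
#' Restricts the drug table to the given approval statuses, intersects its
#' target genes with the disease gene set, and returns the hit genes plus the
#' candidate records (one row per drug-hit-gene pair, carrying the gene's
#' seed/neighbor provenance).
#'
#' @param disease A provenance-tagged tibble from [disease_gene_set()] (or a
#'   plain character vector, in which case provenance is `NA`).
#' @param drugs A `drug_targets` tibble.
#' @param status_filter Character vector of approval statuses to keep,
#'   default `"approved"`.
#' @return A list with `hit_genes` (sorted character vector) and `candidates`
#'   (tibble `drug_id`, `drug_name`, `family_id`, `target_gene`,
#'   `provenance`, sorted by `drug_id` then `target_gene`).
#' @export
map_drug_targets <- function(disease, drugs, status_filter = "approved") {
  if (is.character(disease)) {
    disease <- tibble::tibble(gene = gene_set(disease), provenance = NA_character_)
  }
  disease <- tibble::as_tibble(disease)
  if (!all(c("gene", "provenance") %in% names(disease)) || nrow(disease) == 0L) {
    abort("disease gene set must be non-empty with columns gene, provenance")
  }
  if (!inherits(drugs, "drug_targets")) drugs <- drug_targets(drugs, quiet = TRUE)
  if (nrow(drugs) == 0L) {
    warn("drug table is empty; no candidates")
    return(list(hit_genes = character(),
                candidates = drugs[0, c("drug_id", "drug_name", "family_id", "target_gene")] |>
                  dplyr::mutate(provenance = character())))
  }
  keep <- drugs |>
    dplyr::filter(.data$approval_status %in% tolower(status_filter))
  candidates <- keep |>
    dplyr::inner_join(disease, by = c(target_gene = "gene")) |>
    dplyr::select("drug_id", "drug_name", "family_id", "target_gene", "provenance") |>
    dplyr::arrange(.data$drug_id, .data$target_gene)
  list(
    hit_genes = sort(unique(candidates$target_gene)),
    candidates = candidates
  )
}

#' Group candidate drugs into drug families
#'
#' Applies the family rule: an explicit `family_id` (from the drug record or
#' an external `family_map`) groups drugs into one family; drugs without any
#' family information each form their own family. Conflicting assignments for
#' one drug are an error.
#'
#' @param candidates Candidate tibble from [map_drug_targets()].
#' @param family_map Optional named character vector mapping `drug_id` to
#'   `family_id`, overriding absent record-level family ids.
#' @return The candidates tibble with a resolved `family` column.
#' @export
group_families <- function(candidates, family_map = NULL) {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, family = character()))
  }
  rec <- candidates |>
    dplyr::distinct(.data$drug_id, .data$family_id)
  multi <- rec |> dplyr::count(.data$drug_id) |> dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    abort(paste0("conflicting family_id records for drug(s): ",
                 paste(multi$drug_id, collapse = ", ")))
  }
  fam <- setNames(rec$family_id, rec$drug_id)
  if (!is.null(family_map)) {
    mapped <- names(family_map)[names(family_map) %in% names(fam)]
    clash <- mapped[!is.na(fam[mapped]) & fam[mapped] != family_map[mapped]]
    if (length(clash)) {
      abort(paste0("family_map conflicts with record family_id for drug(s): ",
                   paste(clash, collapse = ", ")))
    }
    fam[mapped] <- family_map[mapped]
  }
  resolved <- ifelse(is.na(fam), names(fam), fam)
  dplyr::mutate(candidates, family = unname(resolved[.data$drug_id]))
}

#' Count candidate families with prior literature support
#'
#' Pure arithmetic over an externally supplied annotation list: how many
#' candidate families appear in it, and what fraction of all candidate
#' families that is.
#'
#' @param candidates A family-resolved candidates tibble
#'   (see [group_families()]).
#' @param reported Character vector of family (or drug) identifiers with
#'   reported support.
#' @return A one-row tibble with `n_families`, `n_reported`, `fraction`.
#' @export
annotate_literature <- function(candidates, reported) {
  candidates <- tibble::as_tibble(candidates)
  if (!"family" %in% names(candidates)) candidates <- group_families(candidates)
  fams <- unique(candidates$family)
  if (length(fams) == 0L) abort("no candidate families: fraction undefined")
  n_rep <- sum(fams %in% as.character(reported))
  tibble::tibble(n_families = length(fams), n_reported = n_rep,
                 fraction = n_rep / length(fams))
}

#' Run the full drug-repurposing screen
#'
#' The complete cascade: expand the seed risk genes by direct PPI neighbors,
#' form the provenance-tagged disease gene set, intersect with the targets of
#' drugs passing the approval filter, and group candidates into families.
#' Output ordering is deterministic (lexicographic by drug id, then target),
#' so identical inputs give byte-identical reports.
#'
#' @param seeds Character vector of risk-gene symbols.
#' @param network A `ppi_network` (or coercible edge table).
#' @param drugs A `drug_targets` tibble (or coercible data frame).
#' @param status_filter Approval statuses kept before intersection,
#'   default `"approved"`.
#' @param family_map Optional `drug_id -> family_id` named vector.
#' @return An object of class `screen_report`: a list with `counts` (named
#'   list: `n_seed`, `n_neighbor`, `n_disease_genes`, `n_drug_target_genes`,
#'   `n_hit_genes`, `n_candidate_drug_families`) and `candidates` (tibble with
#'   `drug_id`, `drug_name`, `family`, `target_gene`, `provenance`). Use
#'   [glance.screen_report()] for the count cascade as a one-row tibble and
#'   [tidy.screen_report()] for the candidate rows.
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "A", "C"), b = c("B", "C", "D")))
#' drugs <- drug_targets(data.frame(drug_id = "d1", drug_name = "drug one",
#'                                  target_gene = "B", approval_status = "approved"))
#' screen_report("A", net, drugs)
#' @export
screen_report <- function(seeds, network, drugs, status_filter = "approved",
                          family_map = NULL) {
  seeds <- gene_set(seeds)
  if (length(seeds) == 0L) abort("seed gene set is empty")
  if (!inherits(network, "ppi_network")) network <- ppi_network(network, quiet = TRUE)
  if (!inherits(drugs, "drug_targets")) drugs <- drug_targets(drugs, quiet = TRUE)
  neighbors <- first_neighbors(network, seeds)
  disease <- disease_gene_set(seeds, neighbors)
  approved <- drugs |>
    dplyr::filter(.data$approval_status %in% tolower(status_filter))
  mapped <- map_drug_targets(disease, drugs, status_filter)
  cand <- group_families(mapped$candidates, family_map) |>
    dplyr::select("drug_id", "drug_name", "family", "target_gene", "provenance") |>
    dplyr::arrange(.data$drug_id, .data$target_gene)
  structure(
    list(
      counts = list(
        n_seed = length(seeds),
        n_neighbor = length(neighbors),
        n_disease_genes = nrow(disease),
        n_drug_target_genes = length(unique(approved$target_gene)),
        n_hit_genes = length(mapped$hit_genes),
        n_candidate_drug_families = length(unique(cand$family))
      ),
      hit_genes = mapped$hit_genes,
      candidates = cand
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Drug-repurposing screen report\n")
  cat(sprintf("  seeds %d + PPI neighbors %d = disease genes %d\n",
              x$counts$n_seed, x$counts$n_neighbor, x$counts$n_disease_genes))
  cat(sprintf("  drug target genes (filtered) %d; hit genes %d; candidate drug families %d\n",
              x$counts$n_drug_target_genes, x$counts$n_hit_genes,
              x$counts$n_candidate_drug_families))
  invisible(x)
}

#' Candidate rows of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return The candidates tibble (one row per drug-hit-gene pair).
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) x$candidates

#' Count cascade of a screen report
#'
#' @inheritParams tidy.screen_report
#' @return A one-row tibble of the screen counts.
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) tibble::as_tibble(x$counts)
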