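#' Specify an additive allelic-odds disease model
#'
#' Parameterises the case-control simulator. Controls are drawn from
#' Hardy-Weinberg proportions at the population minor allele frequency; case
#' genotype probabilities are the same proportions tilted by
#' `or_per_allele^dose`, where dose is the minor-allele count, and
#' renormalised. Under this model the case minor allele frequency has the
#' closed form `p*OR / (1 - p + p*OR)` and the allelic odds ratio comparing
#' cases to controls equals `or_per_allele` exactly.
#'
#' @param maf_population Population minor allele frequency, in `(0, 0.5]`.
#' @param or_per_allele Multiplicative odds per minor allele (1 = null).
#' @param n_case,n_control Cohort sizes.
#' @param seed Optional integer seed making single draws reproducible.
#' @return A `disease_model` list.
#' @examples
#' disease_model(0.3635, 1.27, 988, 2521, seed = 1)
#' @export
disease_model <- function(maf_population, or_per_allele, n_case, n_control,
                          seed = NULL) {
  if (!is.numeric(maf_population) || maf_population <= 0 || maf_population > 0.5) {
    abort("maf_population must lie in (0, 0.5]")
  }
  if (!is.numeric(or_per_allele) || or_per_allele <= 0 || !is.finite(or_per_allele)) {
    abort("or_per_allele must be a positive finite number")
  }
  if (n_case < 1 || n_control < 1 || n_case != round(n_case) || n_control != round(n_control)) {
    abort("n_case and n_control must be positive integers")
  }
  structure(list(maf_population = maf_population, or_per_allele = or_per_allele,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 seed = seed),
            class = "disease_model")
}

# genotype-class probabilities, ordered (hom-minor, het, hom-major)
.model_probs <- function(p, or) {
  q <- 1 - p
  ctrl <- c(p^2, 2 * p * q, q^2)
  case <- ctrl * c(or^2, or, 1)
  list(control = ctrl, case = case / sum(case))
}

# n_sims case and control triples as 3 x n_sims matrices
.sim_triples <- function(model, n_sims) {
  pr <- .model_probs(model$maf_population, model$or_per_allele)
  list(case = rmultinom(n_sims, model$n_case, pr$case),
       control = rmultinom(n_sims, model$n_control, pr$control))
}

#' Simulate one SNP's case-control genotype counts
#'
#' @param model A [disease_model()]. If the model carries a `seed`, the draw
#'   is made under it (reproducibly, without disturbing the caller's RNG
#'   state); otherwise the current RNG stream is used.
#' @param snp_id,chrom,pos,minor_allele,major_allele Annotation for the
#'   emitted row.
#' @return A one-row genotype-count tibble (see [genotype_counts()]); triples
#'   sum exactly to `n_case` and `n_control`.
#' @examples
#' simulate_genotype_counts(disease_model(0.3, 1.2, 500, 500, seed = 7))
#' @export
simulate_genotype_counts <- function(model, snp_id = "sim1", chrom = "1",
                                     pos = 1L, minor_allele = "A",
                                     major_allele = "G") {
  stopifnot(inherits(model, "disease_model"))
  draw <- function() .sim_triples(model, 1L)
  tr <- if (!is.null(model$seed)) withr::with_seed(model$seed, draw()) else draw()
  genotype_counts(snp_id, chrom, pos, minor_allele, major_allele,
                  tr$case[1, 1], tr$case[2, 1], tr$case[3, 1],
                  tr$control[1, 1], tr$control[2, 1], tr$control[3, 1])
}

# trend-test rejection rate over n_sims simulated cohorts
.rejection_rate <- function(model, n_sims, alpha, weights = c(0, 1, 2)) {
  tr <- .sim_triples(model, n_sims)
  stat <- .catt_stat(tr$case, tr$control, weights)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  mean(p <= alpha)
}

#' Empirical type-I error of the trend test under the null model
#'
#' Simulates null cohorts (`or_per_allele = 1`) and reports the fraction of
#' replicates whose Cochran-Armitage trend p-value is at or below `alpha`.
#'
#' @param model A [disease_model()]; its `or_per_allele` should be 1 for a
#'   type-I error estimate (a warning is raised otherwise).
#' @param n_sims Number of replicates (>= 100).
#' @param alpha Nominal significance level.
#' @return The empirical rejection rate.
#' @export
type1_error <- function(model, n_sims, alpha = 0.05) {
  stopifnot(inherits(model, "disease_model"))
  if (n_sims < 100) abort("n_sims must be at least 100")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (model$or_per_allele != 1) {
    warn("or_per_allele != 1: the rejection rate estimates power, not type-I error")
  }
  run <- function() .rejection_rate(model, n_sims, alpha)
  if (!is.null(model$seed)) withr::with_seed(model$seed, run()) else run()
}

#' Trend-test power across a grid of allelic odds ratios
#'
#' @param model A [disease_model()] supplying the frequency and cohort sizes;
#'   its `or_per_allele` is replaced by each grid value in turn.
#' @param or_grid Vector of per-allele odds ratios.
#' @param n_sims Replicates per grid point.
#' @param alpha Nominal significance level.
#' @return A tibble with `or_per_allele`, `n_sims`, `rejection_rate`;
#'   rates are monotone non-decreasing in the odds ratio up to
#'   Monte-Carlo error.
#' @export
power_curve <- function(model, or_grid, n_sims = 2000, alpha = 0.05) {
  stopifnot(inherits(model, "disease_model"))
  if (length(or_grid) == 0L) abort("or_grid is empty")
  run <- function() {
    purrr::map_dbl(or_grid, function(or) {
      m <- model; m$or_per_allele <- or
      .rejection_rate(m, n_sims, alpha)
    })
  }
  rates <- if (!is.null(model$seed)) withr::with_seed(model$seed, run()) else run()
  tibble::tibble(or_per_allele = as.numeric(or_grid), n_sims = n_sims,
                 rejection_rate = rates)
}

#' Build a planted drug-screen instance with known truth
#'
#' Constructs a random PPI background graph, wires exactly
#' `n_neighbors_planted` non-seed genes to the seed set, and lays out a drug
#' table in which exactly `n_hits_planted` disease genes are targeted by
#' approved drugs (one family per drug by default), plus approval-filter and
#' off-target decoy records. The returned `truth` counts come from the
#' construction itself, never from running the screen, so
#' [screen_report()] can be validated against them.
#'
#' Background edges are sampled uniformly at random (Erdos-Renyi style)
#' among the pairs that cannot create unplanned seed neighbors; degree
#' realism is deliberately not modelled since the screen is purely set-based.
#'
#' @param n_genes Total genes in the universe.
#' @param n_edges Background edges (in addition to the planted seed-neighbor
#'   edges).
#' @param n_seeds Seed (risk) genes.
#' @param n_neighbors_planted Genes wired as direct PPI neighbors of seeds.
#' @param n_drugs Approved candidate drugs (= families under the default
#'   one-drug-one-family rule); 0 only if `n_hits_planted` is 0.
#' @param n_hits_planted Disease genes targeted by the candidate drugs.
#' @param seed Integer seed; instances are pure functions of parameters + seed.
#' @return A `planted_screen` list with `network`, `seeds`, `drugs` and
#'   `truth` (named count list matching [glance.screen_report()]).
#' @examples
#' inst <- make_planted_screen(200, 150, 5, 30, 4, 6, seed = 42)
#' glance(screen_report(inst$seeds, inst$network, inst$drugs))
#' @export
make_planted_screen <- function(n_genes, n_edges, n_seeds, n_neighbors_planted,
                                n_drugs, n_hits_planted, seed) {
  if (n_seeds < 1) abort("need at least one seed gene")
  if (n_seeds + n_neighbors_planted > n_genes) {
    abort("n_genes too small for the requested seeds + neighbors")
  }
  if (n_hits_planted > n_seeds + n_neighbors_planted) {
    abort("cannot plant more hit genes than disease genes")
  }
  if ((n_hits_planted == 0) != (n_drugs == 0)) {
    abort("n_hits_planted and n_drugs must be zero together (every candidate drug needs a hit)")
  }
  withr::with_seed(seed, {
    genes <- paste0("G", formatC(seq_len(n_genes), width = nchar(n_genes), flag = "0"))
    seeds <- genes[seq_len(n_seeds)]
    neighbors <- if (n_neighbors_planted > 0)
      genes[n_seeds + seq_len(n_neighbors_planted)] else character()
    others <- setdiff(genes, c(seeds, neighbors))

    # planted seed-neighbor edges, round-robin so seeds share coverage
    planted <- if (length(neighbors)) {
      tibble::tibble(gene_a = rep(seeds, length.out = length(neighbors)),
                     gene_b = neighbors)
    } else tibble::tibble(gene_a = character(), gene_b = character())

    # background edges must never join a seed to an unplanted gene
    is_seed <- genes %in% seeds
    is_other <- genes %in% others
    bg <- tibble::tibble(gene_a = character(), gene_b = character())
    tries <- 0L
    while (nrow(bg) < n_edges && tries < 50L) {
      k <- 2L * (n_edges - nrow(bg)) + 10L
      i <- sample.int(n_genes, k, replace = TRUE)
      j <- sample.int(n_genes, k, replace = TRUE)
      ok <- i != j &
        !((is_seed[i] & is_other[j]) | (is_other[i] & is_seed[j]))
      cand <- tibble::tibble(gene_a = pmin(genes[i[ok]], genes[j[ok]]),
                             gene_b = pmax(genes[i[ok]], genes[j[ok]]))
      bg <- dplyr::distinct(dplyr::bind_rows(bg, cand))
      tries <- tries + 1L
    }
    bg <- head(bg, n_edges)
    network <- ppi_network(dplyr::bind_rows(planted, bg), quiet = TRUE)

    disease <- c(seeds, neighbors)
    hit_genes <- if (n_hits_planted > 0) sample(disease, n_hits_planted) else character()

    drug_rows <- list()
    if (n_drugs > 0) {
      drug_ids <- paste0("D", formatC(seq_len(n_drugs), width = nchar(n_drugs), flag = "0"))
      # cover every hit gene and give every drug at least one target
      assign_drug <- rep(drug_ids, length.out = max(n_hits_planted, n_drugs))
      assign_gene <- c(hit_genes,
                       if (n_drugs > n_hits_planted)
                         sample(hit_genes, n_drugs - n_hits_planted, replace = TRUE)
                       else character())
      drug_rows$candidates <- tibble::tibble(
        drug_id = assign_drug[seq_along(assign_gene)],
        target_gene = assign_gene,
        approval_status = "approved"
      )
      # decoys: unapproved drugs on disease genes never count as candidates
      drug_rows$unapproved <- tibble::tibble(
        drug_id = paste0("X", seq_len(3L)),
        target_gene = sample(disease, 3L, replace = TRUE),
        approval_status = "investigational"
      )
    }
    # decoys: approved drugs targeting only background genes
    if (length(others) > 0) {
      drug_rows$offtarget <- tibble::tibble(
        drug_id = paste0("Y", seq_len(min(3L, length(others)))),
        target_gene = sample(others, min(3L, length(others))),
        approval_status = "approved"
      )
    }
    drug_tbl <- dplyr::bind_rows(drug_rows)
    if (nrow(drug_tbl) == 0L) {
      drug_tbl <- tibble::tibble(drug_id = character(), target_gene = character(),
                                 approval_status = character())
    }
    drug_tbl <- drug_tbl |>
      dplyr::mutate(drug_name = paste0("drug ", .data$drug_id),
                    family_id = NA_character_) |>
      dplyr::distinct(.data$drug_id, .data$target_gene, .keep_all = TRUE)
    drugs <- drug_targets(drug_tbl, quiet = TRUE)

    approved_targets <- unique(drug_tbl$target_gene[drug_tbl$approval_status == "approved"])
    truth <- list(
      n_seed = n_seeds,
      n_neighbor = n_neighbors_planted,
      n_disease_genes = n_seeds + n_neighbors_planted,
      n_drug_target_genes = length(approved_targets),
      n_hit_genes = n_hits_planted,
      n_candidate_drug_families = n_drugs
    )
    structure(list(network = network, seeds = seeds, drugs = drugs, truth = truth),
              class = "planted_screen")
  })
}
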