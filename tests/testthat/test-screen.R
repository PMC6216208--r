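toy_network <- function() {
  ppi_network(data.frame(a = c("A", "A", "B", "C"),
                         b = c("B", "C", "C", "D")), quiet = TRUE)
}

toy_drugs <- function() {
  drug_targets(data.frame(
    drug_id = c("d1", "d2", "d3", "d4", "d4"),
    drug_name = c("one", "two", "three", "four", "four"),
    target_gene = c("B", "Z", "C", "D", "Q"),
    approval_status = c("approved", "approved", "other", "approved", "approved")
  ), quiet = TRUE)
}

test_that("network normalisation collapses duplicates, reversals and self-loops", {
  expect_message(
    net <- ppi_network(data.frame(a = c("a", "B", "c", "c"),
                                  b = c("b", "A", "c", "C"))),
    "removed 3"
  )
  expect_equal(nrow(net), 1)
  expect_equal(net$gene_a, "A")
  expect_equal(net$gene_b, "B")
})

test_that("first neighbors exclude seeds and warn on absent seeds", {
  expect_equal(first_neighbors(toy_network(), "A"), c("B", "C"))
  expect_equal(first_neighbors(toy_network(), c("A", "B")), c("C"))
  expect_warning(nb <- first_neighbors(toy_network(), c("A", "ZZZ")), "ZZZ")
  expect_equal(nb, c("B", "C"))
  expect_error(first_neighbors(toy_network(), character()), "empty")
  empty_net <- ppi_network(data.frame(a = character(), b = character()))
  expect_warning(nb0 <- first_neighbors(empty_net, c("A", "B")), "A, B")
  expect_equal(nb0, character())
})

test_that("disease gene set is a provenance-tagged disjoint union", {
  ds <- disease_gene_set("A", c("B", "C"))
  expect_equal(ds$gene, c("A", "B", "C"))
  expect_equal(ds$provenance, c("seed", "neighbor", "neighbor"))
  expect_error(disease_gene_set("A", c("A", "B")), "overlap")
})

test_that("drug-target mapping filters by approval and keeps only in-set targets", {
  ds <- disease_gene_set("A", c("B", "C", "D"))
  hits <- map_drug_targets(ds, toy_drugs())
  expect_equal(hits$hit_genes, c("B", "D"))
  expect_equal(hits$candidates$drug_id, c("d1", "d4"))
  # d4 targets D and Q; only the in-set target D is listed
  expect_equal(hits$candidates$target_gene[hits$candidates$drug_id == "d4"], "D")
  none <- map_drug_targets(ds, toy_drugs(), status_filter = "withdrawn")
  expect_equal(nrow(none$candidates), 0)
})

test_that("family grouping defaults to one drug one family and checks conflicts", {
  cand <- map_drug_targets(disease_gene_set("A", c("B", "C", "D")),
                           toy_drugs())$candidates
  fams <- group_families(cand)
  expect_equal(sort(unique(fams$family)), c("d1", "d4"))
  fams2 <- group_families(cand, family_map = c(d1 = "f1", d4 = "f1"))
  expect_equal(unique(fams2$family), "f1")

  conflicted <- dplyr::mutate(cand,
                              family_id = ifelse(.data$drug_id == "d1", "fa", family_id))
  expect_error(group_families(conflicted, family_map = c(d1 = "fb")),
               "family_map conflicts")
})

test_that("literature annotation is plain arithmetic over families", {
  cand <- group_families(map_drug_targets(disease_gene_set("A", c("B", "C", "D")),
                                          toy_drugs())$candidates)
  ann <- annotate_literature(cand, c("d1"))
  expect_equal(ann$n_families, 2)
  expect_equal(ann$n_reported, 1)
  expect_equal(ann$fraction, 0.5)
  expect_equal(annotate_literature(cand, character())$fraction, 0)
  expect_equal(annotate_literature(cand, c("d1", "d4"))$fraction, 1)
  expect_equal(round(17 / 57, 3), 0.298)  # the fraction rule at study scale
  expect_error(annotate_literature(cand[0, ], "d1"), "no candidate families")
})

test_that("screen_report runs the cascade with the count identity", {
  rep <- screen_report("A", toy_network(), toy_drugs())
  gl <- glance(rep)
  expect_equal(gl$n_seed, 1)
  expect_equal(gl$n_neighbor, 2)
  expect_equal(gl$n_disease_genes, gl$n_seed + gl$n_neighbor)
  expect_equal(gl$n_hit_genes, 1)
  expect_equal(gl$n_candidate_drug_families, 1)
  expect_equal(tidy(rep)$drug_id, "d1")

  lonely <- suppressWarnings(
    screen_report("W", toy_network(), toy_drugs())
  )
  gl0 <- glance(lonely)
  expect_equal(gl0$n_seed, 1)
  expect_equal(gl0$n_neighbor, 0)
  expect_equal(gl0$n_hit_genes, 0)
  expect_equal(gl0$n_candidate_drug_families, 0)
})

test_that("screen results are invariant to symbol case and edge redundancy", {
  rep1 <- screen_report("a", data.frame(a = c("A", "a"), b = c("b", "C")),
                        toy_drugs())
  rep2 <- screen_report("A", toy_network()[1:2, ], toy_drugs())
  expect_equal(glance(rep1), glance(rep2))
  expect_equal(tidy(rep1), tidy(rep2))
})

test_that("adding edges and removing drugs moves counts the expected way", {
  base_edges <- data.frame(a = c("A", "A"), b = c("B", "C"))
  rep0 <- glance(screen_report("A", base_edges, toy_drugs()))
  # edge between two existing disease genes changes nothing
  rep1 <- glance(screen_report("A", rbind(base_edges, c("B", "C")), toy_drugs()))
  expect_equal(rep0, rep1)
  # seed-to-new-gene edge grows the disease set by exactly one
  rep2 <- glance(screen_report("A", rbind(base_edges, c("A", "E")), toy_drugs()))
  expect_equal(rep2$n_disease_genes, rep0$n_disease_genes + 1)
  # dropping a drug record never increases any count
  fewer <- toy_drugs()[toy_drugs()$drug_id != "d1", ]
  rep3 <- glance(screen_report("A", base_edges, fewer))
  expect_true(all(unlist(rep3) <= unlist(rep0)))
})

test_that("identical screen inputs give byte-identical written reports", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_screen_tsv(screen_report("A", toy_network(), toy_drugs()), f1)
  write_screen_tsv(screen_report("A", toy_network(), toy_drugs()), f2)
  expect_identical(readLines(f1), readLines(f2))
})
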