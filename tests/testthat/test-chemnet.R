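write_links <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(c("chemical\tpartner\tpartner_kind\tcombined_score", lines),
             path)
  path
}

test_that("score dialects are detected, normalized, and out-of-range rows rejected", {
  p_int <- write_links(c("dA\tP1\tprotein\t900", "dA\tP2\tprotein\t150",
                         "dB\tP1\tprotein\t700", "dB\tdA\tchemical\t400",
                         "dA\tP3\tprotein\t1500"))
  links <- read_stitch_links(p_int)
  expect_equal(attr(links, "dialect"), "integer_0_1000")
  expect_equal(links$score, c(0.9, 0.15, 0.7, 0.4))
  expect_equal(rejects(links)$row, 5L)

  p_real <- write_links(c("dA\tP1\tprotein\t0.73", "dB\tP1\tprotein\t0.2"))
  real <- read_stitch_links(p_real)
  expect_equal(attr(real, "dialect"), "real_0_1")
  expect_equal(real$score, c(0.73, 0.2))

  p_mixed <- write_links(c("dA\tP1\tprotein\t0.73", "dB\tP2\tprotein\t900"))
  expect_error(read_stitch_links(p_mixed), "mixed")
})

test_that("integer-dialect files re-written in real dialect parse identically", {
  p_int <- write_links(c("dA\tP1\tprotein\t900", "dB\tP2\tprotein\t432",
                         "dB\tP1\tprotein\t151"))
  a <- read_stitch_links(p_int)
  p_real <- withr::local_tempfile(fileext = ".tsv")
  out <- a
  utils::write.table(
    data.frame(chemical = out$chemical, partner = out$partner,
               partner_kind = out$partner_kind, combined_score = out$score),
    p_real, sep = "\t", row.names = FALSE, quote = FALSE)
  b <- read_stitch_links(p_real)
  expect_equal(b$score, a$score)
  expect_equal(attr(b, "dialect"), "real_0_1")
})

test_that("network construction filters by score and counts shared proteins", {
  links <- data.frame(
    chemical = c("dA", "dB", "dA"),
    partner = c("P1", "P1", "P2"),
    partner_kind = "protein",
    score = c(0.8, 0.8, 0.3), stringsAsFactors = FALSE)
  net <- build_chem_network(c("dA", "dB"), links, min_score = 0.4)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_true(all(igraph::E(net$graph)$type == "drug_protein"))
  expect_equal(nrow(net$shared_protein_pairs), 1)
  expect_equal(net$shared_protein_pairs$drug_a, "dA")

  # threshold above every score: edgeless, all drugs isolated
  top <- build_chem_network(c("dA", "dB"), links, min_score = 1)
  m <- network_metrics(top)
  expect_equal(m$n_edges, 0)
  expect_equal(m$isolated_drug_fraction, 1)

  all_in <- build_chem_network(c("dA", "dB"), links, min_score = 0)
  expect_equal(igraph::ecount(all_in$graph), 3)
  expect_error(build_chem_network(character(0), links), "non-empty")
  expect_error(build_chem_network("dA", links, min_score = 2), "min_score")
})

test_that("explicit chemical-chemical links become drug-drug edges", {
  links <- data.frame(
    chemical = c("dA", "dB", "dA"),
    partner = c("dB", "dA", "P1"),
    partner_kind = c("chemical", "chemical", "protein"),
    score = c(0.9, 0.9, 0.5), stringsAsFactors = FALSE)
  net <- build_chem_network(c("dA", "dB"), links, min_score = 0.4)
  types <- igraph::E(net$graph)$type
  expect_equal(sum(types == "drug_drug"), 1)  # symmetric pair collapses
  expect_equal(sum(types == "drug_protein"), 1)
})

test_that("metrics match the formulas and the brute-force oracle", {
  # 4 nodes, 3 edges: density 3/6
  links <- data.frame(chemical = c("dA", "dA", "dB"),
                      partner = c("P1", "P2", "P1"),
                      partner_kind = "protein",
                      score = 0.9, stringsAsFactors = FALSE)
  m <- network_metrics(build_chem_network(c("dA", "dB"), links, 0.4))
  expect_equal(m$density, 0.5)
  expect_equal(m$n_components, 1)

  lonely <- build_chem_network(paste0("d", 1:5),
                               links[0, , drop = FALSE], 0.4)
  ml <- network_metrics(lonely)
  expect_equal(ml$n_components, 5)
  expect_equal(ml$mean_degree, 0)

  set.seed(77)
  for (i in 1:10) {
    n_drugs <- sample(3:10, 1)
    n_prot <- sample(3:15, 1)
    n_links <- sample(5:40, 1)
    links <- data.frame(
      chemical = sample(paste0("drug", seq_len(n_drugs)), n_links,
                        replace = TRUE),
      partner = sample(paste0("prot", seq_len(n_prot)), n_links,
                       replace = TRUE),
      partner_kind = "protein",
      score = runif(n_links), stringsAsFactors = FALSE)
    thr <- runif(1, 0, 0.8)
    net <- build_chem_network(paste0("drug", seq_len(n_drugs)), links, thr)
    m <- network_metrics(net)
    kept <- unique(links[links$score >= thr, c("chemical", "partner")])
    nodes <- c(paste0("drug", seq_len(n_drugs)), unique(links$partner))
    want <- oracle_graph_metrics(nodes, kept$chemical, kept$partner)
    expect_equal(m$n_edges, want$n_edges)
    expect_equal(m$density, want$density)
    expect_equal(m$mean_degree, want$mean_degree)
    expect_equal(m$n_components, want$n_components)
  }
})

test_that("raising the threshold never increases connectivity", {
  set.seed(42)
  links <- data.frame(
    chemical = sample(paste0("d", 1:8), 60, replace = TRUE),
    partner = sample(paste0("P", 1:12), 60, replace = TRUE),
    partner_kind = "protein", score = runif(60), stringsAsFactors = FALSE)
  drugs <- paste0("d", 1:8)
  prev <- NULL
  for (thr in seq(0, 1, by = 0.1)) {
    m <- network_metrics(build_chem_network(drugs, links, thr))
    if (!is.null(prev)) {
      expect_lte(m$n_edges, prev$n_edges)
      expect_lte(m$density, prev$density)
      expect_lte(m$mean_degree, prev$mean_degree)
      expect_lte(m$shared_protein_pairs, prev$shared_protein_pairs)
    }
    prev <- m
  }
})

test_that("group comparison is antisymmetric and guards thresholds", {
  links <- data.frame(chemical = c("dA", "dB"), partner = c("P1", "P1"),
                      partner_kind = "protein", score = 0.9,
                      stringsAsFactors = FALSE)
  m1 <- network_metrics(build_chem_network(c("dA", "dB"), links, 0.4))
  m2 <- network_metrics(build_chem_network("dA", links, 0.4))
  same <- compare_groups(m1, m1)
  expect_true(all(same$table$diff == 0))
  expect_equal(same$denser, "tie")
  ab <- compare_groups(m1, m2)
  ba <- compare_groups(m2, m1)
  expect_equal(ab$table$diff, -ba$table$diff)
  m3 <- network_metrics(build_chem_network("dA", links, 0.8))
  expect_error(compare_groups(m1, m3), "threshold")
})

test_that("top MoA counts rank by drug count with alphabetical ties", {
  recs <- records_df(
    rec("d1", "A", "dis1", moa = "m1", phase = "approved", odd = TRUE,
        year = 2010L),
    rec("d2", "B", "dis2", moa = "m1", phase = "approved", odd = TRUE,
        year = 2011L),
    rec("d3", "C", "dis3", moa = "m1", phase = "approved", odd = FALSE,
        year = 2012L),
    rec("d3", "C", "dis4", moa = "m1", phase = "approved", odd = FALSE,
        year = 2012L),  # same drug, second indication: counted once
    rec("d4", "D", "dis5", moa = "m2", phase = "approved", odd = TRUE,
        year = 2013L),
    rec("d5", "E", "dis6", moa = "a_tie", phase = "approved", odd = TRUE,
        year = 2014L))
  top <- top_moa_counts(recs, n = 30)
  expect_equal(top$moa, c("m1", "a_tie", "m2"))
  expect_equal(top$n_drugs, c(3L, 1L, 1L))
  expect_equal(top_moa_counts(recs, n = 1)$moa, "m1")
  odd_only <- top_moa_counts(recs, odd = TRUE)
  expect_equal(odd_only$n_drugs[odd_only$moa == "m1"], 2L)
  # tie at the cutoff rank resolves alphabetically
  expect_equal(top_moa_counts(recs, n = 2)$moa, c("m1", "a_tie"))
})

test_that("pathway membership is a plain join with unmapped count", {
  pm <- data.frame(protein = c("P1", "P2", "P2"),
                   pathway = c("PW1", "PW1", "PW2"),
                   stringsAsFactors = FALSE)
  got <- pathway_membership(c("P1", "P2", "P9"), pm)
  expect_equal(got$pathway, c("PW1", "PW2"))
  expect_equal(got$n_proteins, c(2L, 1L))
  expect_equal(attr(got, "n_unmapped"), 1)
})
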