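test_that("solo and collaborative programs induce the right edge shapes", {
  solo <- build_network(rec("d1", "A", "dis"))
  g <- solo$graph
  expect_equal(sort(unique(igraph::V(g)$layer)), c("disease", "sponsor"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$type, "sponsor_disease")

  collab <- build_network(rec("d1", "A", "dis", collaborators = "X"))
  g2 <- collab$graph
  expect_setequal(igraph::E(g2)$type,
                  c("sponsor_collaborator", "collaborator_disease"))
  expect_equal(igraph::ecount(g2), 2)  # no direct sponsor-disease edge

  # two programs of one company on one disease: parallel annotated edges
  multi <- build_network(records_df(rec("d1", "A", "dis", moa = "m1"),
                                    rec("d2", "A", "dis", moa = "m2")))
  expect_equal(igraph::ecount(multi$graph), 2)
  expect_setequal(igraph::E(multi$graph)$asset, c("d1", "d2"))
})

test_that("records with blank sponsor or disease are rejected with a report", {
  recs <- records_df(rec("d1", "A", "dis"), rec("d2", "", "dis"),
                     rec("d3", "B", ""))
  net <- build_network(recs)
  expect_equal(net$rejects$row, c(2L, 3L))
  expect_equal(net$n_assets, 1)
})

test_that("disease activity counts active companies and deduplicates MoAs", {
  recs <- records_df(
    rec("d1", "A", "dis1", moa = "m1"),
    rec("d2", "B", "dis1", moa = "m1", collaborators = "X"),
    rec("d3", "C", "dis1", moa = "m2"),
    rec("d4", "A", "dis2", moa = "m3"))
  da <- disease_activity(build_network(recs))
  expect_equal(da$disease, c("dis1", "dis2"))
  expect_equal(da$n_companies, c(3L, 1L))
  expect_equal(da$n_moas, c(2L, 1L))  # m1 shared by two programs counts once
  expect_equal(nrow(disease_activity(build_network(recs[0, ]))), 0)
})

test_that("knockout matches the hand-worked examples", {
  recs <- records_df(
    rec("d1", "A", "dis_d", moa = "m1"),
    rec("d2", "B", "dis_d", moa = "m1"),
    rec("d3", "Solo", "dis_s", moa = "m9"),
    rec("d4", "B", "dis_o", moa = "m2"))
  net <- build_network(recs)

  sole <- knockout(net, "Solo")$impact
  row_s <- sole[sole$disease == "dis_s", ]
  expect_equal(row_s$companies_remaining, 0L)
  expect_equal(row_s$unique_moas_remaining, 0L)

  # removing a company with no asset on dis_o leaves it unchanged
  ka <- knockout(net, "A")$impact
  expect_equal(ka$delta_companies[ka$disease == "dis_o"], 0L)
  expect_equal(ka$delta_moas[ka$disease == "dis_o"], 0L)

  # A and B share MoA m1 on dis_d: removing A keeps the MoA richness
  row_d <- ka[ka$disease == "dis_d", ]
  expect_equal(row_d$companies_remaining, 1L)
  expect_equal(row_d$unique_moas_remaining, 1L)
  expect_equal(row_d$delta_moas, 0L)

  expect_error(knockout(net, "Nobody"), "Nobody")
})

test_that("knockout_all equals per-company knockouts and handles empties", {
  recs <- records_df(rec("d1", "A", "dis1", moa = "m1"),
                     rec("d2", "B", "dis2", moa = "m2"))
  net <- build_network(recs)
  long <- knockout_all(net)
  for (cm in c("A", "B")) {
    single <- knockout(net, cm)$impact
    block <- long[long$company == cm, names(single)]
    rownames(block) <- NULL
    expect_equal(block, single)
  }
  expect_equal(nrow(knockout_all(build_network(recs[0, ]))), 0)
})

test_that("a collaborator tied to a single sponsor is pruned on knockout", {
  recs <- records_df(
    rec("d1", "A", "dis1", collaborators = "OnlyA"),
    rec("d2", "B", "dis1", collaborators = "Shared"),
    rec("d3", "C", "dis2", collaborators = "Shared"))
  net <- build_network(recs)
  post <- orphanscape:::remove_company(net, "A")
  labels <- igraph::V(post$graph)$label
  expect_false("OnlyA" %in% labels)
  expect_true("Shared" %in% labels)
  # foreign programs through a shared collaborator keep reaching diseases
  post_b <- orphanscape:::remove_company(net, "B")
  da <- disease_activity(post_b)
  expect_equal(da$n_companies[da$disease == "dis2"], 1L)
})

test_that("knockout agrees with the rebuild oracle on random ecosystems", {
  set.seed(31)
  for (i in 1:15) {
    eco <- random_small_ecosystem(seed = 400 + i)
    recs <- eco$records
    net <- build_network(recs)
    pre <- disease_activity(net)
    for (cm in unique(recs$sponsor)) {
      imp <- knockout(net, cm)$impact
      oracle <- oracle_knockout(recs, cm)
      m <- match(imp$disease, oracle$disease)
      expect_equal(imp$companies_remaining, oracle$companies_remaining[m])
      expect_equal(imp$unique_moas_remaining,
                   oracle$unique_moas_remaining[m])
      # monotonicity and conservation
      expect_true(all(imp$delta_companies >= 0 & imp$delta_moas >= 0))
      pm <- match(imp$disease, pre$disease)
      expect_equal(imp$companies_remaining + imp$delta_companies,
                   pre$n_companies[pm])
      # locality: only diseases the company reaches change
      touched <- unique(recs$indication[recs$sponsor == cm])
      expect_true(all(imp$disease[imp$delta_companies > 0 |
                                    imp$delta_moas > 0] %in% touched))
    }
  }
})

test_that("collaboration counts rank sponsors by partnership volume", {
  recs <- records_df(
    rec("d1", "A", "dis1", collaborators = "X; Y"),
    rec("d2", "A", "dis2", collaborators = "X"),
    rec("d3", "B", "dis1", collaborators = "Z"),
    rec("d4", "C", "dis1"))
  cc <- collaboration_counts(recs)
  expect_equal(cc$company, c("A", "B"))
  expect_equal(cc$n_collaborations, c(3L, 1L))
  expect_equal(cc$n_partners, c(2L, 1L))
})

test_that("GraphML export preserves layers and edge annotations", {
  path <- withr::local_tempfile(fileext = ".graphml")
  net <- build_network(toy_records())
  write_network_graphml(net, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net$graph))
  expect_setequal(igraph::E(back)$moa, igraph::E(net$graph)$moa)
  expect_setequal(igraph::V(back)$layer, igraph::V(net$graph)$layer)
})
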