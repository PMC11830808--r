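rev_row <- function(drug, company, indication, revenue, fy = "2022-2023") {
  data.frame(drug_name = drug, company = company, indication = indication,
             revenue = revenue, fiscal_year = fy, stringsAsFactors = FALSE)
}

test_that("market shares are revenue fractions of an explicit grand total", {
  revs <- rbind(rev_row("x", "A", "dis1", 50), rev_row("y", "B", "dis1", 30),
                rev_row("z", "C", "dis2", 20))
  ms <- market_shares(revs, "company")
  expect_equal(ms$key, c("A", "B", "C"))
  expect_equal(ms$share_pct, c(50, 30, 20))
  expect_equal(attr(ms, "grand_total"), 100)

  single <- market_shares(rev_row("x", "A", "dis1", 7), "company")
  expect_equal(single$share_pct, 100)

  # 4 drugs across 2 diseases, hand-computed ratios
  revs2 <- rbind(rev_row("a", "A", "dis1", 10), rev_row("b", "B", "dis1", 30),
                 rev_row("c", "A", "dis2", 40), rev_row("d", "C", "dis2", 20))
  by_dis <- market_shares(revs2, "disease")
  expect_equal(by_dis$key, c("dis2", "dis1"))
  expect_equal(by_dis$share_pct, c(60, 40))
})

test_that("organ-system shares treat combination labels as atomic and bucket unmapped", {
  revs <- rbind(rev_row("a", "A", "dis1", 60), rev_row("b", "B", "dis2", 30),
                rev_row("c", "C", "dis3", 10))
  omap <- data.frame(indication = c("dis1", "dis2"),
                     organ_system = c("liver/heart/lung", "lung"),
                     stringsAsFactors = FALSE)
  expect_warning(ms <- market_shares(revs, "organ_system", organ_map = omap),
                 "unmapped")
  expect_setequal(ms$key, c("liver/heart/lung", "lung", "unmapped"))
  expect_equal(ms$share_pct[ms$key == "liver/heart/lung"], 60)
  expect_equal(sum(ms$share_pct), 100)
})

test_that("shares always sum to 100 and are scale invariant", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    revs <- data.frame(drug_name = paste0("d", seq_len(n)),
                       company = sample(LETTERS[1:6], n, replace = TRUE),
                       indication = sample(paste0("dis", 1:4), n,
                                           replace = TRUE),
                       revenue = rlnorm(n, 4, 2), fiscal_year = NA,
                       stringsAsFactors = FALSE)
    ms <- market_shares(revs, "company")
    expect_lt(abs(sum(ms$share_pct) - 100), 1e-6)
    scaled <- revs
    scaled$revenue <- scaled$revenue * 1e4
    expect_equal(market_shares(scaled, "company")$share_pct, ms$share_pct)
  }
})

test_that("ODD segmentation splits approvals and finds shared indications", {
  recs <- records_df(
    rec("d1", "A", "dis1", modality = "targeted therapy",
        phase = "approved", odd = TRUE, year = 2010L),
    rec("d2", "A", "dis2", modality = "gene therapy",
        phase = "approved", odd = TRUE, year = 2012L),
    rec("d3", "B", "dis1", modality = "targeted therapy",
        phase = "approved", odd = FALSE, year = 2015L),
    rec("d4", "B", "dis2", modality = "chemotherapy",
        phase = "approved", odd = FALSE, year = 2016L),
    rec("d5", "B", "dis3", modality = "targeted therapy",
        phase = "approved", odd = FALSE, year = 2016L),
    rec("d6", "C", "dis9"))  # pipeline record, ignored
  seg <- odd_segmentation(recs)
  expect_equal(seg$counts$n_odd, 2)
  expect_equal(seg$counts$n_nonodd, 3)
  expect_equal(seg$pct_odd, 40)
  expect_equal(seg$shared_indications, c("dis1", "dis2"))
  mb <- seg$modality_breakdown
  expect_equal(mb$pct[mb$group == "odd" & mb$modality == "gene therapy"], 50)
  tc <- seg$top_companies
  expect_equal(tc$company[tc$group == "non_odd"], "B")
  expect_equal(tc$n[tc$group == "non_odd"], 3L)

  all_odd <- odd_segmentation(recs[recs$odd_status %in% TRUE, ])
  expect_equal(all_odd$pct_odd, 100)
  expect_equal(all_odd$pct_nonodd, 0)
})

test_that("the approval timeline conserves counts and buckets unknown years", {
  recs <- records_df(
    rec("d1", "A", "dis1", phase = "approved", odd = TRUE, year = 2019L),
    rec("d2", "B", "dis2", phase = "approved", odd = TRUE, year = 2019L),
    rec("d3", "C", "dis3", phase = "approved", odd = FALSE, year = 2019L),
    rec("d4", "C", "dis3", phase = "approved", odd = FALSE, year = 1995L),
    rec("d5", "C", "dis4", phase = "approved", odd = FALSE))
  tl <- approval_timeline(recs)
  expect_equal(tl$year, c(1995L, 2019L))
  expect_equal(tl$n_odd[tl$year == 2019], 2L)
  expect_equal(tl$n_nonodd[tl$year == 2019], 1L)
  expect_equal(attr(tl, "n_unknown_year"), 1)
  expect_equal(sum(tl$n_total) + attr(tl, "n_unknown_year"),
               sum(recs$phase == "approved"))
  expect_equal(nrow(approval_timeline(recs[0, ])), 0)
})

test_that("revenue concentration and the leader correlation behave", {
  one <- top_asset_profile(rev_row("x", "A", "dis1", 5))
  expect_equal(one$table$top_asset_fraction, 1)
  expect_true(is.na(one$pearson_r))
  expect_match(one$note, "fewer than 3")

  revs <- rbind(rev_row("a1", "A", "d", 60), rev_row("a2", "A", "d", 40),
                rev_row("b1", "B", "d", 40), rev_row("b2", "B", "d", 10),
                rev_row("c1", "C", "d", 9), rev_row("c2", "C", "d", 1))
  prof <- top_asset_profile(revs)
  expect_equal(prof$table$total_revenue, c(100, 50, 10))
  expect_equal(prof$table$top_asset_revenue, c(60, 40, 9))
  expect_equal(prof$pearson_r,
               oracle_pearson(c(100, 50, 10), c(60, 40, 9)))

  flat <- rbind(rev_row("a", "A", "d", 10), rev_row("b", "B", "d", 10),
                rev_row("c", "C", "d", 10))
  deg <- top_asset_profile(flat)
  expect_true(is.na(deg$pearson_r))
  expect_match(deg$note, "zero variance")
})

test_that("tier boundaries include their lower edges and validate input", {
  expect_equal(classify_tier(c(6, 5.999, 2.5, 2.499, 0, 100)),
               c("market_leader", "upcoming_major", "upcoming_major",
                 "challenger", "challenger", "market_leader"))
  expect_error(classify_tier(-1), "\\[0, 100\\]")
  expect_error(classify_tier(101), "\\[0, 100\\]")
  expect_error(classify_tier(5, leader_min = 2, upcoming_min = 3),
               "boundaries")
  # scale invariance of the whole share -> tier chain
  revs <- rbind(rev_row("a", "A", "d", 70), rev_row("b", "B", "d", 25),
                rev_row("c", "C", "d", 5))
  t1 <- classify_tier(market_shares(revs, "company")$share_pct)
  revs$revenue <- revs$revenue * 1000
  t2 <- classify_tier(market_shares(revs, "company")$share_pct)
  expect_identical(t1, t2)
})
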