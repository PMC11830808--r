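#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (typically read from JSON) with
#' exactly one of:
#' \describe{
#'   \item{`inputs`}{paths: `portfolio` (required), optional `companies`,
#'     `aliases`, `revenues`, `organ_map`, `chem_links`.}
#'   \item{`simulate`}{arguments for [ecosystem_config()], plus an optional
#'     `chem` sub-list (`targets_per_drug`, `shared_target_prob`,
#'     `shared_target_prob_nonodd`) for [generate_chem_links()].}
#' }
#' plus optional `toggles` (`network`, `indexes`, `market`, `chemnet`, all
#' default `TRUE`), `thresholds` (`min_score`, `leader_min`,
#' `upcoming_min`), `rollup` flag and `seed`.
#'
#' All structural problems are reported at once.
#'
#' @param config Configuration list.
#' @return Character vector of error messages; empty when the configuration
#'   is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.list(config), "config must be a list")
  if (!is.list(config)) return(errs)
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  chk(xor(has_inputs, has_sim),
      "exactly one of 'inputs' or 'simulate' must be present")
  if (has_inputs) {
    chk(!is.null(config$inputs$portfolio), "inputs$portfolio is required")
    for (f in c("portfolio", "companies", "aliases", "revenues",
                "organ_map", "chem_links")) {
      p <- config$inputs[[f]]
      if (!is.null(p) && !file.exists(p)) {
        errs <- c(errs, paste0("inputs$", f, ": file not found: ", p))
      }
    }
  }
  if (has_sim) {
    sim <- config$simulate
    sim$chem <- NULL
    sim$seed <- sim$seed %||% config$seed %||% 1L
    cfg <- tryCatch(do.call(ecosystem_config, sim),
                    error = function(e) conditionMessage(e))
    if (is.character(cfg)) errs <- c(errs, cfg)
  }
  th <- config$thresholds %||% list()
  ms <- th$min_score %||% 0.4
  chk(is.numeric(ms) && ms >= 0 && ms <= 1, "thresholds$min_score in [0,1]")
  lm <- th$leader_min %||% 6
  um <- th$upcoming_min %||% 2.5
  chk(is.numeric(lm) && is.numeric(um) && um > 0 && lm > um,
      "tier boundaries must satisfy 0 < upcoming_min < leader_min")
  sd <- config$seed %||% 1L
  chk(is.numeric(sd) && length(sd) == 1 && is.finite(sd),
      "seed must be a single number")
  errs
}

#' Run the full landscape pipeline
#'
#' Orchestrates ingest (or simulation), entity normalization, the
#' tripartite network with its knockout simulation, competitive/innovative
#' indexes, market analytics (shares, ODD segmentation, timeline, revenue
#' concentration, tiers) and the chemical network, as toggled, and returns
#' everything in a single reproducible bundle. Identical configuration and
#' seed give an identical bundle; any stage failure aborts with the stage
#' name and cause.
#'
#' @param config Configuration list; see [validate_config()].
#' @return A `report_bundle` list of result tables plus `provenance`
#'   (config echo, package version, seed).
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop_("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  seed <- as.integer(config$seed %||% 1L)
  toggles <- utils::modifyList(list(network = TRUE, indexes = TRUE,
                                    market = TRUE, chemnet = TRUE),
                               config$toggles %||% list())
  th <- utils::modifyList(list(min_score = 0.4, leader_min = 6,
                               upcoming_min = 2.5),
                          config$thresholds %||% list())
  rollup <- isTRUE(config$rollup)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  sim_mode <- !is.null(config$simulate)
  if (sim_mode) {
    dat <- stage("simulate", {
      sim <- config$simulate
      chem_cfg <- sim$chem %||% list()
      sim$chem <- NULL
      sim$seed <- sim$seed %||% seed
      eco <- generate_ecosystem(do.call(ecosystem_config, sim))
      links <- if (toggles$chemnet) {
        do.call(generate_chem_links,
                c(list(records = eco$records,
                       seed = sim$seed), chem_cfg))
      } else NULL
      list(records = eco$records, companies = eco$companies,
           aliases = NULL, revenues = NULL, organ_map = NULL,
           links = links, ground_truth = eco$ground_truth)
    })
  } else {
    dat <- stage("ingest", {
      inp <- config$inputs
      read_opt <- function(path, schema) {
        if (is.null(path)) NULL else read_portfolio_table(path, schema)
      }
      list(records = read_portfolio_table(inp$portfolio, "portfolio"),
           companies = read_opt(inp$companies, "companies"),
           aliases = read_opt(inp$aliases, "aliases"),
           revenues = read_opt(inp$revenues, "revenues"),
           organ_map = read_opt(inp$organ_map, "organ_map"),
           links = if (is.null(inp$chem_links)) NULL else
             read_stitch_links(inp$chem_links),
           ground_truth = NULL)
    })
  }

  records <- stage("normalize", {
    normalize_entities(dat$records, aliases = dat$aliases,
                       companies = dat$companies, rollup = rollup)
  })

  bundle <- list(
    summary = stage("summary", summarize_dataset(records)),
    country_counts = if (!is.null(dat$companies)) {
      stage("summary", count_companies_by_country(dat$companies))
    })

  if (toggles$network) {
    net <- stage("network", build_network(records))
    bundle$disease_activity <- stage("network", disease_activity(net))
    bundle$knockout <- stage("knockout", knockout_all(net))
    bundle$collaborations <- stage("network", collaboration_counts(records))
  }
  if (toggles$indexes) {
    bundle$indexes <- stage("indexes", company_indexes(records))
  }
  if (toggles$market) {
    revs <- dat$revenues %||% revenue_records(records)
    if (nrow(revs)) {
      bundle$market_shares_company <- stage("market",
        market_shares(revs, "company"))
      bundle$market_shares_disease <- stage("market",
        market_shares(revs, "disease"))
      if (!is.null(dat$organ_map)) {
        bundle$market_shares_organ <- stage("market",
          market_shares(revs, "organ_system", organ_map = dat$organ_map))
      }
      bundle$top_assets <- stage("market", top_asset_profile(revs))
      shares <- bundle$market_shares_company
      bundle$tiers <- stage("market", data.frame(
        company = shares$key, share_pct = shares$share_pct,
        tier = classify_tier(shares$share_pct, th$leader_min,
                             th$upcoming_min), stringsAsFactors = FALSE))
    }
    bundle$segmentation <- stage("market", odd_segmentation(records))
    bundle$timeline <- stage("market", approval_timeline(records))
  }
  if (toggles$chemnet && !is.null(dat$links)) {
    bundle$chem <- stage("chemnet", {
      appr <- records[records$phase == "approved", , drop = FALSE]
      per_group <- function(flag) {
        ids <- unique(appr$drug_name[appr$odd_status %in% flag])
        if (!length(ids)) return(NULL)
        network_metrics(build_chem_network(ids, dat$links, th$min_score))
      }
      m_odd <- per_group(TRUE)
      m_non <- per_group(FALSE)
      list(metrics_odd = m_odd, metrics_nonodd = m_non,
           comparison = if (!is.null(m_odd) && !is.null(m_non)) {
             compare_groups(m_non, m_odd)
           })
    })
  }
  bundle$ground_truth <- dat$ground_truth
  bundle$provenance <- list(config = config, seed = seed,
                            thresholds = th, rollup = rollup,
                            package_version =
                              as.character(utils::packageVersion("orphanscape")))
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Landscape report bundle (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  sections: ",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the bundle's tables as CSV files plus a `report.json` with the
#' scalar results and the echoed configuration, into `dir`.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(bundle$country_counts, "country_counts")
  wr(bundle$disease_activity, "disease_activity")
  wr(bundle$knockout, "knockout")
  wr(bundle$collaborations, "collaborations")
  wr(bundle$indexes, "indexes")
  wr(bundle$market_shares_company, "market_shares_company")
  wr(bundle$market_shares_disease, "market_shares_disease")
  wr(bundle$market_shares_organ, "market_shares_organ")
  wr(bundle$tiers, "tiers")
  wr(bundle$timeline, "timeline")
  if (!is.null(bundle$top_assets)) wr(bundle$top_assets$table, "top_assets")
  scalars <- list(
    summary = unclass(bundle$summary),
    segmentation = if (!is.null(bundle$segmentation)) {
      list(counts = bundle$segmentation$counts,
           pct_odd = bundle$segmentation$pct_odd,
           shared_indications = bundle$segmentation$shared_indications)
    },
    pearson_r = if (!is.null(bundle$top_assets)) bundle$top_assets$pearson_r,
    chem = if (!is.null(bundle$chem)) {
      list(odd = if (!is.null(bundle$chem$metrics_odd))
             unclass(bundle$chem$metrics_odd),
           nonodd = if (!is.null(bundle$chem$metrics_nonodd))
             unclass(bundle$chem$metrics_nonodd),
           denser = if (!is.null(bundle$chem$comparison))
             bundle$chem$comparison$denser)
    },
    provenance = bundle$provenance)
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Benchmarks computable only from externally supplied source tables
#'
#' Published headline numbers for the rare-disease market (per-company
#' shares, the total market size, per-status indication counts) derive
#' from source portfolio and revenue tables that are not redistributed
#' with this package. When a directory containing `portfolio.tsv` (approved
#' records, `portfolio` schema) and `revenues.tsv` (`revenues` schema) is
#' supplied, this recomputes those benchmark quantities; otherwise it
#' returns a structured "unavailable" result instead of failing, so
#' conditional comparisons can be scripted.
#'
#' @param dir Directory with `portfolio.tsv` and `revenues.tsv`, or a path
#'   that does not exist.
#' @return A list with `available` (logical); when available also
#'   `n_odd_indications`, `n_nonodd_indications`, `n_shared_indications`,
#'   `company_shares` (a [market_shares()] table), `total_market_musd` and
#'   `therapy_area_pct` (per-group modality breakdown).
#' @export
supplementary_benchmarks <- function(dir) {
  pf <- file.path(dir, "portfolio.tsv")
  rv <- file.path(dir, "revenues.tsv")
  if (!dir.exists(dir) || !file.exists(pf) || !file.exists(rv)) {
    return(list(available = FALSE,
                reason = "supplementary tables not present"))
  }
  records <- read_portfolio_table(pf, "portfolio")
  revenues <- read_portfolio_table(rv, "revenues")
  seg <- odd_segmentation(records)
  shares <- market_shares(revenues, "company")
  ind <- seg$indication_freq
  list(available = TRUE,
       n_odd_indications =
         length(unique(ind$indication[ind$group == "odd"])),
       n_nonodd_indications =
         length(unique(ind$indication[ind$group == "non_odd"])),
       n_shared_indications = length(seg$shared_indications),
       company_shares = shares,
       total_market_musd = attr(shares, "grand_total"),
       therapy_area_pct = seg$modality_breakdown)
}
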