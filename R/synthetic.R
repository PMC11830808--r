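#' Configuration for the synthetic rare-disease ecosystem generator
#'
#' Bundles and validates the parameters of [generate_ecosystem()]. The
#' defaults emulate the scale of the EU rare-disease space the package is
#' built for: about 43 sponsors with a mean of 14 assets each (~600
#' programs), a few hundred candidate indications with strongly skewed
#' popularity (a handful of crowded indications such as multiple myeloma or
#' cystic fibrosis), roughly a third of assets approved, an ODD fraction of
#' 0.35 among approvals, and heavy-tailed (log-normal) per-asset revenues
#' whose total lands near the 10^5 million USD scale of the global
#' rare-disease market.
#'
#' @param n_companies,n_diseases,n_moas Pool sizes (companies, candidate
#'   indications, shared mechanism-of-action labels).
#' @param mean_assets_per_company Poisson mean for the number of programs a
#'   company runs.
#' @param disease_popularity_exponent Zipf exponent: disease of rank r is
#'   chosen with probability proportional to r^(-exponent); larger values
#'   crowd development into fewer indications.
#' @param collaboration_prob Probability an asset is co-developed with one
#'   collaborator drawn uniformly from the other companies.
#' @param odd_fraction Probability an approved asset carries orphan drug
#'   designation.
#' @param unique_moa_fraction Probability an asset receives a fresh,
#'   company-exclusive MoA label instead of drawing from the shared pool.
#' @param revenue_log_mean,revenue_log_sd Log-normal parameters (on the log
#'   scale) of per-asset revenue in million USD; applied to approved assets
#'   only.
#' @param approved_fraction Probability an asset is approved (the rest split
#'   evenly between early and late clinical).
#' @param year_range Inclusive approval-year span, length-2 integer vector.
#' @param seed Master seed; each emitted table consumes its own derived
#'   random stream so adding one table never perturbs the others.
#' @return An `ecosystem_config` list.
#' @export
ecosystem_config <- function(n_companies = 43, n_diseases = 295,
                             n_moas = 60, mean_assets_per_company = 14,
                             disease_popularity_exponent = 1,
                             collaboration_prob = 0.3, odd_fraction = 0.35,
                             unique_moa_fraction = 0.3,
                             revenue_log_mean = 5.5, revenue_log_sd = 1.5,
                             approved_fraction = 0.35,
                             year_range = c(1995L, 2021L), seed = 1L) {
  cfg <- list(n_companies = n_companies, n_diseases = n_diseases,
              n_moas = n_moas,
              mean_assets_per_company = mean_assets_per_company,
              disease_popularity_exponent = disease_popularity_exponent,
              collaboration_prob = collaboration_prob,
              odd_fraction = odd_fraction,
              unique_moa_fraction = unique_moa_fraction,
              revenue_log_mean = revenue_log_mean,
              revenue_log_sd = revenue_log_sd,
              approved_fraction = approved_fraction,
              year_range = as.integer(year_range), seed = as.integer(seed))
  errs <- validate_ecosystem_config(cfg)
  if (length(errs)) stop_("invalid ecosystem config: ",
                          paste(errs, collapse = "; "))
  class(cfg) <- "ecosystem_config"
  cfg
}

validate_ecosystem_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$n_companies) && cfg$n_companies >= 1, "n_companies must be >= 1")
  chk(num1(cfg$n_diseases) && cfg$n_diseases >= 1, "n_diseases must be >= 1")
  chk(num1(cfg$n_moas) && cfg$n_moas >= 1, "n_moas must be >= 1")
  chk(num1(cfg$mean_assets_per_company) && cfg$mean_assets_per_company > 0,
      "mean_assets_per_company must be > 0")
  chk(num1(cfg$disease_popularity_exponent) &&
        cfg$disease_popularity_exponent > 0,
      "disease_popularity_exponent must be > 0")
  for (p in c("collaboration_prob", "odd_fraction", "unique_moa_fraction",
              "approved_fraction")) {
    chk(num1(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1,
        paste(p, "must be in [0, 1]"))
  }
  chk(num1(cfg$revenue_log_mean), "revenue_log_mean must be finite")
  chk(num1(cfg$revenue_log_sd) && cfg$revenue_log_sd >= 0,
      "revenue_log_sd must be >= 0")
  chk(length(cfg$year_range) == 2 && !anyNA(cfg$year_range) &&
        cfg$year_range[1] <= cfg$year_range[2],
      "year_range must be an increasing pair of years")
  chk(num1(cfg$seed), "seed must be a single integer")
  errs
}

# HQ-country pool, weighted towards where rare-disease sponsors actually sit.
.hq_pool <- data.frame(
  country = c("United States", "Switzerland", "Germany", "France",
              "United Kingdom", "Netherlands", "Ireland", "Sweden", "Italy",
              "Spain", "Belgium", "Denmark", "Japan", "Australia"),
  weight = c(16, 3, 2.5, 2.5, 2.5, 1.5, 1.5, 1, 1, 1, 1, 1, 2, 1),
  stringsAsFactors = FALSE)

#' Generate a synthetic rare-disease development ecosystem
#'
#' Emits an intervention-record table, a company table, and the planted
#' ground truth used by parameter-recovery tests. Deterministic for a fixed
#' config (including its seed); company, asset, and revenue streams use
#' independent derived seeds.
#'
#' Structure of the emitted data: disease assignment follows a rank-based
#' power law (crowded top indications); each asset receives a fresh
#' company-exclusive MoA with probability `unique_moa_fraction`, else a label
#' from the shared pool; a collaborator is attached with probability
#' `collaboration_prob`; approved assets carry an ODD flag
#' (`odd_fraction`), a uniform approval year, and a log-normal revenue, while
#' pipeline assets carry none of those.
#'
#' @param config An [ecosystem_config()].
#' @return An `ecosystem` list: `records` (portfolio data frame), `companies`
#'   (company table), and `ground_truth` with per-company planted
#'   unique-MoA fractions, per-disease developer counts, and per-company
#'   total revenue.
#' @export
generate_ecosystem <- function(config) {
  if (!inherits(config, "ecosystem_config")) {
    config <- do.call(ecosystem_config, config)
  }
  cfg <- config
  company_names <- sprintf("Company_%02d", seq_len(cfg$n_companies))
  disease_names <- sprintf("Disease_%03d", seq_len(cfg$n_diseases))
  shared_moas <- sprintf("moa_shared_%03d", seq_len(cfg$n_moas))

  set.seed(derive_seed(cfg$seed, 1L))
  hq <- sample(.hq_pool$country, cfg$n_companies, replace = TRUE,
               prob = .hq_pool$weight)
  companies <- data.frame(name = company_names, hq_country = hq,
                          parent = NA_character_, stringsAsFactors = FALSE)

  set.seed(derive_seed(cfg$seed, 2L))
  n_assets <- stats::rpois(cfg$n_companies, cfg$mean_assets_per_company)
  total <- sum(n_assets)
  sponsor <- rep(company_names, n_assets)
  disease_prob <- seq_len(cfg$n_diseases)^(-cfg$disease_popularity_exponent)
  indication <- sample(disease_names, total, replace = TRUE,
                       prob = disease_prob)
  is_unique <- stats::runif(total) < cfg$unique_moa_fraction
  moa <- character(total)
  moa[!is_unique] <- sample(shared_moas, sum(!is_unique), replace = TRUE)
  # fresh labels namespaced by company: exclusive by construction
  if (any(is_unique)) {
    idx <- which(is_unique)
    per_company_counter <- stats::ave(seq_along(idx), sponsor[idx],
                                      FUN = seq_along)
    moa[idx] <- sprintf("moa_unique_%s_%02d", sponsor[idx],
                        per_company_counter)
  }
  modality_pool <- c("targeted therapy", "enzyme replacement therapy",
                     "gene therapy", "chemotherapy", "CAR-T",
                     "antisense RNA", "siRNA")
  modality <- sample(modality_pool, total, replace = TRUE,
                     prob = c(0.55, 0.12, 0.1, 0.08, 0.05, 0.05, 0.05))
  has_collab <- stats::runif(total) < cfg$collaboration_prob
  collaborators <- character(total)
  if (cfg$n_companies > 1 && any(has_collab)) {
    collaborators[has_collab] <- vapply(sponsor[has_collab], function(sp) {
      sample(setdiff(company_names, sp), 1)
    }, character(1))
  } else {
    has_collab[] <- FALSE
  }
  approved <- stats::runif(total) < cfg$approved_fraction
  phase <- ifelse(approved, "approved",
                  ifelse(stats::runif(total) < 0.5, "early_clinical",
                         "late_clinical"))
  odd <- rep(NA, total)
  odd[approved] <- stats::runif(sum(approved)) < cfg$odd_fraction
  year <- rep(NA_integer_, total)
  year[approved] <- sample(seq(cfg$year_range[1], cfg$year_range[2]),
                           sum(approved), replace = TRUE)

  set.seed(derive_seed(cfg$seed, 3L))
  revenue <- rep(NA_real_, total)
  revenue[approved] <- stats::rlnorm(sum(approved), cfg$revenue_log_mean,
                                     cfg$revenue_log_sd)

  records <- data.frame(
    drug_name = sprintf("DRUG_%04d", seq_len(total)),
    sponsor = sponsor, collaborators = collaborators,
    indication = indication, moa = moa, modality = modality, phase = phase,
    odd_status = odd, approval_year = year, revenue = revenue,
    organ_systems = character(total), stringsAsFactors = FALSE)

  planted_unique <- vapply(company_names, function(cm) {
    mine <- sponsor == cm
    if (!any(mine)) return(NA_real_)
    mean(is_unique[mine])
  }, numeric(1))
  dev_counts <- vapply(disease_names, function(d) {
    length(unique(sponsor[indication == d]))
  }, integer(1))
  dev_counts <- dev_counts[dev_counts > 0]
  company_rev <- vapply(company_names, function(cm) {
    sum(revenue[sponsor == cm], na.rm = TRUE)
  }, numeric(1))

  out <- list(records = records, companies = companies,
              ground_truth = list(
                company_unique_moa_fraction = planted_unique,
                disease_developer_count = dev_counts,
                company_revenue = company_rev),
              config = cfg)
  class(out) <- "ecosystem"
  out
}

#' @export
print.ecosystem <- function(x, ...) {
  cat(sprintf(paste0("Synthetic ecosystem: %d companies, %d assets, ",
                     "%d diseases in play (seed %d)\n"),
              nrow(x$companies), nrow(x$records),
              length(unique(x$records$indication)), x$config$seed))
  invisible(x)
}

#' Generate a confidence-scored chemical-protein link table
#'
#' Emulates a STITCH-style link table for the approved drugs of a record
#' set: each drug receives `targets_per_drug` protein links with confidence
#' scores uniform on [0.15, 0.999]. With probability `shared_target_prob` a
#' link reuses a protein already attached to another drug, creating
#' drug-drug connectivity through shared targets. Passing a higher
#' `shared_target_prob_nonodd` than `shared_target_prob` makes non-ODD drugs
#' share targets more than ODD drugs, emulating repositioned drugs that
#' carry their original target spectrum into the rare-disease space.
#'
#' @param records Portfolio records; approved drugs (deduplicated on
#'   `drug_name`) receive links.
#' @param targets_per_drug Number of protein links per drug.
#' @param shared_target_prob Probability a link reuses a protein already
#'   linked to another drug.
#' @param seed RNG seed for this table.
#' @param shared_target_prob_nonodd Optional override applied to drugs with
#'   `odd_status == FALSE` (ODD drugs keep `shared_target_prob`).
#' @return Data frame in the real-score dialect: `chemical`, `partner`,
#'   `partner_kind` (`"protein"`), `combined_score` in \[0, 1\].
#' @export
generate_chem_links <- function(records, targets_per_drug = 5,
                                shared_target_prob = 0.2, seed = 1L,
                                shared_target_prob_nonodd = NULL) {
  if (!nrow(records)) stop_("records must be non-empty")
  stopifnot(targets_per_drug >= 1,
            shared_target_prob >= 0, shared_target_prob <= 1)
  appr <- records[records$phase == "approved", , drop = FALSE]
  appr <- appr[!duplicated(appr$drug_name), , drop = FALSE]
  if (!nrow(appr)) stop_("no approved drugs to link")
  set.seed(derive_seed(seed, 4L))
  protein_counter <- 0L
  linked <- list()  # protein -> drugs already linked to it
  rows <- vector("list", nrow(appr) * targets_per_drug)
  k <- 0L
  for (i in seq_len(nrow(appr))) {
    drug <- appr$drug_name[i]
    p_share <- if (!is.null(shared_target_prob_nonodd) &&
                   isFALSE(appr$odd_status[i])) shared_target_prob_nonodd
               else shared_target_prob
    for (j in seq_len(targets_per_drug)) {
      foreign <- names(linked)[vapply(linked, function(d) {
        any(d != drug)
      }, logical(1))]
      if (length(foreign) && stats::runif(1) < p_share) {
        prot <- sample(foreign, 1)
      } else {
        protein_counter <- protein_counter + 1L
        prot <- sprintf("PROT_%05d", protein_counter)
      }
      linked[[prot]] <- unique(c(linked[[prot]], drug))
      k <- k + 1L
      rows[[k]] <- data.frame(chemical = drug, partner = prot,
                              partner_kind = "protein",
                              combined_score = stats::runif(1, 0.15, 0.999),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}
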