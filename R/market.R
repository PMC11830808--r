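#' Market shares by company, disease, or organ system
#'
#' Aggregates per-asset revenues (million USD) into total revenue and
#' percentage share per aggregation key. The grand total is the sum of all
#' supplied revenues and is always reported (attribute `grand_total`), so
#' the denominator of the percentages is explicit. For the organ-system key,
#' an asset's full revenue is counted once under the full combination label
#' of its indication (e.g. `"liver/heart/lung"`), treated as an atomic
#' category; indications absent from the mapping fall into an `"unmapped"`
#' bucket with a warning.
#'
#' @param revenues Revenue table (`drug_name`, `company`, `indication`,
#'   `revenue`, optional `fiscal_year`).
#' @param key One of `"company"`, `"disease"`, `"organ_system"`.
#' @param organ_map Indication-to-organ-system table (`indication`,
#'   `organ_system`); required when `key = "organ_system"`.
#' @return Data frame of `key`, `total_revenue`, `share_pct` sorted by
#'   descending revenue, with attributes `grand_total` and `key_kind`.
#'   Shares sum to 100 (within 1e-6).
#' @export
market_shares <- function(revenues, key = c("company", "disease",
                                            "organ_system"),
                          organ_map = NULL) {
  key <- match.arg(key)
  if (!nrow(revenues)) stop_("revenues must be non-empty")
  values <- switch(key,
    company = revenues$company,
    disease = revenues$indication,
    organ_system = {
      if (is.null(organ_map)) {
        stop_("key = 'organ_system' requires an organ_map")
      }
      hit <- match(revenues$indication, organ_map$indication)
      if (anyNA(hit)) {
        warning(sprintf("%d revenue row(s) with unmapped indication bucketed as 'unmapped'",
                        sum(is.na(hit))), call. = FALSE)
      }
      ifelse(is.na(hit), "unmapped", organ_map$organ_system[hit])
    })
  totals <- tapply(revenues$revenue, values, sum)
  grand <- sum(revenues$revenue)
  out <- data.frame(key = names(totals),
                    total_revenue = as.numeric(totals),
                    share_pct = 100 * as.numeric(totals) / grand,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_revenue, out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grand_total") <- grand
  attr(out, "key_kind") <- key
  out
}

#' ODD versus non-ODD segmentation of approved drugs
#'
#' Splits the approved records by orphan-drug-designation status and
#' reports: group counts and percentages, the therapy-area (modality)
#' percentage breakdown within each group, per-group indication frequency
#' tables, per-group top-company counts, and the list of indications served
#' by drugs of both statuses.
#'
#' @param records Portfolio records; only `phase == "approved"` rows are
#'   used. Approved rows with unknown ODD status are counted separately and
#'   excluded from the two groups.
#' @param top_n Number of companies kept in each top-company table.
#' @return An `odd_segmentation` list: `counts` (`n_odd`, `n_nonodd`,
#'   `n_unknown_status`, `n_approved`), `pct_odd`/`pct_nonodd` (percentages
#'   over the known-status approvals), `modality_breakdown`,
#'   `indication_freq`, `top_companies` (each a data frame with a `group`
#'   column), and `shared_indications`.
#' @export
odd_segmentation <- function(records, top_n = 20) {
  appr <- records[records$phase == "approved", , drop = FALSE]
  grp <- ifelse(is.na(appr$odd_status), NA_character_,
                ifelse(appr$odd_status, "odd", "non_odd"))
  n_odd <- sum(grp %in% "odd")
  n_nonodd <- sum(grp %in% "non_odd")
  denom <- n_odd + n_nonodd
  per_group <- function(fun) {
    blocks <- lapply(c(odd = "odd", non_odd = "non_odd"), function(g) {
      sub <- appr[grp %in% g, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      cbind(data.frame(group = g, stringsAsFactors = FALSE), fun(sub))
    })
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
    if (!length(blocks)) return(NULL)
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  }
  freq_table <- function(x, name) {
    tab <- sort(table(x), decreasing = TRUE)
    df <- data.frame(names(tab), as.integer(tab), stringsAsFactors = FALSE)
    names(df) <- c(name, "n")
    df
  }
  out <- list(
    counts = list(n_odd = n_odd, n_nonodd = n_nonodd,
                  n_unknown_status = sum(is.na(grp)),
                  n_approved = nrow(appr)),
    pct_odd = if (denom) 100 * n_odd / denom else NA_real_,
    pct_nonodd = if (denom) 100 * n_nonodd / denom else NA_real_,
    modality_breakdown = per_group(function(sub) {
      df <- freq_table(sub$modality, "modality")
      df$pct <- 100 * df$n / nrow(sub)
      df
    }),
    indication_freq = per_group(function(sub) {
      freq_table(sub$indication, "indication")
    }),
    top_companies = per_group(function(sub) {
      utils::head(freq_table(sub$sponsor, "company"), top_n)
    }),
    shared_indications = sort(intersect(appr$indication[grp %in% "odd"],
                                        appr$indication[grp %in% "non_odd"])))
  class(out) <- "odd_segmentation"
  out
}

#' @export
print.odd_segmentation <- function(x, ...) {
  cat(sprintf("Approved drugs: %d (ODD %d, non-ODD %d, unknown status %d)\n",
              x$counts$n_approved, x$counts$n_odd, x$counts$n_nonodd,
              x$counts$n_unknown_status))
  if (!is.na(x$pct_odd)) {
    cat(sprintf("  ODD share of known-status approvals: %.1f%%\n", x$pct_odd))
  }
  cat(sprintf("  indications served by both statuses: %d\n",
              length(x$shared_indications)))
  invisible(x)
}

#' Approval timeline split by ODD status
#'
#' @param records Portfolio records; approved rows with a known approval
#'   year enter the timeline, rows without a year are counted in the
#'   `n_unknown_year` attribute.
#' @return Data frame of `year`, `n_odd`, `n_nonodd`, `n_unknown_status`,
#'   `n_total`, one row per observed year in ascending order.
#' @export
approval_timeline <- function(records) {
  appr <- records[records$phase == "approved", , drop = FALSE]
  known <- !is.na(appr$approval_year)
  sub <- appr[known, , drop = FALSE]
  years <- sort(unique(sub$approval_year))
  out <- data.frame(
    year = years,
    n_odd = vapply(years, function(y) {
      sum(sub$approval_year == y & sub$odd_status %in% TRUE)
    }, integer(1)),
    n_nonodd = vapply(years, function(y) {
      sum(sub$approval_year == y & sub$odd_status %in% FALSE)
    }, integer(1)),
    n_unknown_status = vapply(years, function(y) {
      sum(sub$approval_year == y & is.na(sub$odd_status))
    }, integer(1)),
    stringsAsFactors = FALSE)
  out$n_total <- out$n_odd + out$n_nonodd + out$n_unknown_status
  attr(out, "n_unknown_year") <- sum(!known)
  out
}

#' Per-company revenue concentration and leader correlation
#'
#' For each company: total rare-disease revenue, the revenue of its highest
#' grossing asset, and that asset's fraction of the total. Across companies,
#' reports the Pearson correlation between total revenue and top-asset
#' revenue — the concentration signal used to stratify market leaders.
#'
#' @param revenues Revenue table (see [market_shares()]).
#' @return A `top_asset_profile` list: `table` (per-company data frame with
#'   `company`, `total_revenue`, `top_asset`, `top_asset_revenue`,
#'   `top_asset_fraction`), `pearson_r` (NA when fewer than 3 companies or
#'   zero variance), and `note` explaining an NA.
#' @export
top_asset_profile <- function(revenues) {
  if (!nrow(revenues)) stop_("revenues must be non-empty")
  by_c <- split(revenues, revenues$company)
  tab <- data.frame(
    company = names(by_c),
    total_revenue = vapply(by_c, function(x) sum(x$revenue), numeric(1)),
    top_asset = vapply(by_c, function(x) {
      x$drug_name[which.max(x$revenue)]
    }, character(1)),
    top_asset_revenue = vapply(by_c, function(x) max(x$revenue), numeric(1)),
    stringsAsFactors = FALSE)
  tab$top_asset_fraction <- ifelse(tab$total_revenue > 0,
                                   tab$top_asset_revenue / tab$total_revenue,
                                   NA_real_)
  tab <- tab[order(-tab$total_revenue, tab$company), , drop = FALSE]
  rownames(tab) <- NULL
  r <- NA_real_
  note <- NULL
  if (nrow(tab) < 3) {
    note <- "correlation unavailable: fewer than 3 companies"
  } else if (stats::sd(tab$total_revenue) == 0 ||
             stats::sd(tab$top_asset_revenue) == 0) {
    note <- "correlation undefined: zero variance across companies"
  } else {
    r <- stats::cor(tab$total_revenue, tab$top_asset_revenue)
  }
  out <- list(table = tab, pearson_r = r, note = note)
  class(out) <- "top_asset_profile"
  out
}

#' @export
print.top_asset_profile <- function(x, ...) {
  cat(sprintf("Revenue concentration across %d companies\n", nrow(x$table)))
  if (!is.na(x$pearson_r)) {
    cat(sprintf("  Pearson r (total vs top asset): %.3f\n", x$pearson_r))
  } else {
    cat("  ", x$note, "\n", sep = "")
  }
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Market-tier classification from share percentages
#'
#' Assigns the printed share bands of the rare-disease market: leaders at or
#' above 6%, upcoming major players in \[2.5%, 6%), challengers below 2.5%.
#' The published band edges come without open/closed notation; the defaults
#' take each band to include its lower edge, and the boundaries are
#' configurable.
#'
#' @param share Numeric vector of shares in percent, each in \[0, 100\].
#' @param leader_min,upcoming_min Lower band edges in percent.
#' @return Character vector over `{"market_leader", "upcoming_major",
#'   "challenger"}`.
#' @export
classify_tier <- function(share, leader_min = 6, upcoming_min = 2.5) {
  if (!is.numeric(share) || anyNA(share) ||
      any(share < 0 | share > 100)) {
    stop_("share must be numeric in [0, 100]")
  }
  if (!(upcoming_min > 0 && leader_min > upcoming_min)) {
    stop_("tier boundaries must satisfy 0 < upcoming_min < leader_min")
  }
  ifelse(share >= leader_min, "market_leader",
         ifelse(share >= upcoming_min, "upcoming_major", "challenger"))
}
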