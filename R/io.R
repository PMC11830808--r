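#' Read a landscape table (portfolio, companies, aliases, revenues, organ map)
#'
#' Reads a UTF-8 delimited table (TSV or CSV, chosen from the file extension)
#' into a validated data frame. One row corresponds to one record; malformed
#' rows are never fatal: they are skipped and reported in a rejects table
#' attached as the `"rejects"` attribute (see [rejects()]).
#'
#' Schemas and their columns (required unless marked optional):
#' \describe{
#'   \item{`portfolio`}{`drug_name`, `sponsor`, `indication`, `moa`,
#'     `modality`, `phase` (one of `early_clinical`, `late_clinical`,
#'     `approved`); optional `collaborators` (";"-separated),
#'     `odd_status` (true/false, blank for pipeline assets),
#'     `approval_year`, `revenue` (million USD), `organ_systems`
#'     (";"-separated).}
#'   \item{`companies`}{`name`, `hq_country`; optional `parent` (the owning
#'     company after a merger or acquisition).}
#'   \item{`aliases`}{`kind` (`company`, `disease` or `moa`), `raw`,
#'     `canonical`.}
#'   \item{`revenues`}{`drug_name`, `company`, `indication`, `revenue`
#'     (million USD); optional `fiscal_year`.}
#'   \item{`organ_map`}{`indication`, `organ_system` (a combination label
#'     such as `"liver/heart/lung"`, treated as atomic).}
#' }
#'
#' Empty cells and the tokens `na`, `n/a`, `none`, `-` are read as missing.
#' A row is rejected (with its row number and a reason) when a required text
#' field is blank, `phase` is not in the vocabulary, a year or revenue cell
#' is present but unparseable, revenue is negative, or an approval year is
#' given for a non-approved record. A record whose revenue is missing is kept
#' but excluded from market-share aggregations downstream.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param schema One of `"portfolio"`, `"companies"`, `"aliases"`,
#'   `"revenues"`, `"organ_map"`.
#' @return A data frame of clean records, with attributes `rejects`
#'   (data frame of `row`, `reason`) and `schema`.
#' @seealso [write_portfolio_table()], [normalize_entities()],
#'   [summarize_dataset()]
#' @export
read_portfolio_table <- function(path, schema = "portfolio") {
  schema <- match.arg(schema, c("portfolio", "companies", "aliases",
                                "revenues", "organ_map"))
  if (!file.exists(path)) stop_("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           encoding = "UTF-8", stringsAsFactors = FALSE)
  names(raw) <- trimws(tolower(names(raw)))
  required <- switch(schema,
    portfolio = c("drug_name", "sponsor", "indication", "moa", "modality",
                  "phase"),
    companies = c("name", "hq_country"),
    aliases   = c("kind", "raw", "canonical"),
    revenues  = c("drug_name", "company", "indication", "revenue"),
    organ_map = c("indication", "organ_system"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_("schema '", schema, "': missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  for (nm in names(raw)) raw[[nm]] <- trimws(raw[[nm]])
  out <- switch(schema,
    portfolio = clean_portfolio(raw),
    companies = clean_companies(raw),
    aliases   = clean_aliases(raw),
    revenues  = clean_revenues(raw),
    organ_map = list(records = data.frame(indication = raw$indication,
                                          organ_system = raw$organ_system,
                                          stringsAsFactors = FALSE),
                     rejects = empty_rejects()))
  res <- out$records
  attr(res, "rejects") <- out$rejects
  attr(res, "schema") <- schema
  res
}

empty_rejects <- function() {
  data.frame(row = integer(0), reason = character(0), stringsAsFactors = FALSE)
}

#' Rejected-row report of a read table
#'
#' @param x A table returned by [read_portfolio_table()].
#' @return Data frame with columns `row` (1-based data row number) and
#'   `reason`.
#' @export
rejects <- function(x) {
  attr(x, "rejects") %||% empty_rejects()
}

clean_portfolio <- function(raw) {
  n <- nrow(raw)
  opt <- function(nm, default = NA_character_) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, n)
  }
  yr <- parse_num(opt("approval_year"))
  rev <- parse_num(opt("revenue"))
  odd <- parse_logical(opt("odd_status"))
  phase <- tolower(opt("phase", ""))
  reasons <- character(n)
  flag <- function(cond, why) {
    reasons[cond & !nzchar(reasons)] <<- why
  }
  flag(!nzchar(raw$drug_name), "blank drug_name")
  flag(!nzchar(raw$sponsor), "blank sponsor")
  flag(!nzchar(raw$indication), "blank indication")
  flag(!(phase %in% c("early_clinical", "late_clinical", "approved")),
       "invalid phase")
  flag(!yr$ok, "unparseable approval_year")
  flag(!rev$ok, "unparseable revenue")
  flag(!odd$ok, "unparseable odd_status")
  flag(rev$ok & !is.na(rev$value) & rev$value < 0, "negative revenue")
  flag(yr$ok & !is.na(yr$value) & phase != "approved",
       "approval_year on non-approved record")
  keep <- !nzchar(reasons)
  records <- data.frame(
    drug_name = raw$drug_name[keep],
    sponsor = raw$sponsor[keep],
    collaborators = vapply(opt("collaborators", "")[keep], function(cell) {
      join_multi(split_multi(cell))
    }, character(1), USE.NAMES = FALSE),
    indication = raw$indication[keep],
    moa = raw$moa[keep],
    modality = raw$modality[keep],
    phase = phase[keep],
    odd_status = odd$value[keep],
    approval_year = as.integer(round(yr$value[keep])),
    revenue = rev$value[keep],
    organ_systems = vapply(opt("organ_systems", "")[keep], function(cell) {
      join_multi(split_multi(cell))
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  # a sponsor listed among its own collaborators is a redundancy, not an
  # error: drop it so the record invariant holds
  records$collaborators <- mapply(function(coll, sp) {
    join_multi(setdiff(split_multi(coll), sp))
  }, records$collaborators, records$sponsor, USE.NAMES = FALSE)
  list(records = records,
       rejects = data.frame(row = which(!keep), reason = reasons[!keep],
                            stringsAsFactors = FALSE))
}

clean_companies <- function(raw) {
  n <- nrow(raw)
  parent <- if ("parent" %in% names(raw)) raw$parent else rep("", n)
  parent[is_na_token(parent)] <- NA_character_
  reasons <- character(n)
  reasons[!nzchar(raw$name)] <- "blank name"
  keep <- !nzchar(reasons)
  records <- data.frame(name = raw$name[keep],
                        hq_country = raw$hq_country[keep],
                        parent = parent[keep], stringsAsFactors = FALSE)
  validate_company_parents(records)
  list(records = records,
       rejects = data.frame(row = which(!keep), reason = reasons[!keep],
                            stringsAsFactors = FALSE))
}

validate_company_parents <- function(companies) {
  has_parent <- !is.na(companies$parent)
  unknown <- setdiff(companies$parent[has_parent], companies$name)
  if (length(unknown)) {
    stop_("company parent(s) not present in the company table: ",
          paste(unknown, collapse = ", "))
  }
  parent_of <- stats::setNames(companies$parent, companies$name)
  for (start in companies$name[has_parent]) {
    seen <- character(0)
    cur <- start
    while (!is.na(parent_of[[cur]] %||% NA_character_) &&
           !is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop_("cycle in company parent chain at: ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      if (!cur %in% names(parent_of)) break
    }
  }
  invisible(companies)
}

clean_aliases <- function(raw) {
  n <- nrow(raw)
  kind <- tolower(raw$kind)
  reasons <- character(n)
  reasons[!(kind %in% c("company", "disease", "moa"))] <- "invalid kind"
  reasons[!nzchar(raw$raw) & !nzchar(reasons)] <- "blank raw"
  reasons[!nzchar(raw$canonical) & !nzchar(reasons)] <- "blank canonical"
  keep <- !nzchar(reasons)
  list(records = data.frame(kind = kind[keep], raw = raw$raw[keep],
                            canonical = raw$canonical[keep],
                            stringsAsFactors = FALSE),
       rejects = data.frame(row = which(!keep), reason = reasons[!keep],
                            stringsAsFactors = FALSE))
}

clean_revenues <- function(raw) {
  n <- nrow(raw)
  rev <- parse_num(raw$revenue)
  fy <- if ("fiscal_year" %in% names(raw)) raw$fiscal_year
        else rep(NA_character_, n)
  fy[is_na_token(fy)] <- NA_character_
  reasons <- character(n)
  reasons[!nzchar(raw$drug_name)] <- "blank drug_name"
  reasons[!nzchar(raw$company) & !nzchar(reasons)] <- "blank company"
  reasons[(!rev$ok | is.na(rev$value)) & !nzchar(reasons)] <-
    "missing or unparseable revenue"
  reasons[rev$ok & !is.na(rev$value) & rev$value < 0 & !nzchar(reasons)] <-
    "negative revenue"
  keep <- !nzchar(reasons)
  list(records = data.frame(drug_name = raw$drug_name[keep],
                            company = raw$company[keep],
                            indication = raw$indication[keep],
                            revenue = rev$value[keep],
                            fiscal_year = fy[keep], stringsAsFactors = FALSE),
       rejects = data.frame(row = which(!keep), reason = reasons[!keep],
                            stringsAsFactors = FALSE))
}

#' Write an intervention-record table
#'
#' Inverse of `read_portfolio_table(..., schema = "portfolio")`: writing a
#' record table and reading it back reproduces it field for field.
#'
#' @param records Portfolio record data frame.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_portfolio_table <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- records
  out$odd_status <- ifelse(is.na(out$odd_status), "",
                           ifelse(out$odd_status, "true", "false"))
  out$approval_year <- ifelse(is.na(out$approval_year), "",
                              as.character(out$approval_year))
  out$revenue <- ifelse(is.na(out$revenue), "",
                        formatC(out$revenue, format = "g", digits = 15))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Canonicalize entity names in intervention records
#'
#' Replaces company, disease and mechanism-of-action strings by their
#' canonical forms via an alias table, and optionally rolls acquired
#' subsidiaries up into their parent company (for example Celgene into
#' Bristol-Myers Squibb) so portfolios can be reported at the merged-entity
#' level. Alias matching is case-insensitive and ignores whitespace and
#' punctuation, so "Hoffmann-La Roche AG", "hoffmann la roche" and "ROCHE"
#' can all be mapped by the same entries.
#'
#' With `rollup = TRUE`, a sponsor that has a (transitive) parent in
#' `companies` is replaced by the top-level parent; the pre-rollup canonical
#' sponsor is kept in a `sponsor_original` column so "including"/"excluding
#' subsidiary" views remain possible. The operation is idempotent.
#'
#' @param records Portfolio records (see [read_portfolio_table()]).
#' @param aliases Alias table with columns `kind` (`company`/`disease`/`moa`),
#'   `raw`, `canonical`, or `NULL` for no aliasing.
#' @param companies Company table with columns `name`, `hq_country`,
#'   optional `parent`; required for `rollup = TRUE`.
#' @param rollup Replace subsidiary sponsors by their parent company?
#' @return The records with canonical names and a `sponsor_original` column.
#' @export
normalize_entities <- function(records, aliases = NULL, companies = NULL,
                               rollup = FALSE) {
  maps <- alias_maps(aliases)
  canon <- function(x, kind) {
    map <- maps[[kind]]
    if (is.null(map) || !length(map)) return(x)
    key <- fold_key(x)
    hit <- match(key, names(map))
    ifelse(is.na(hit), x, unname(map[hit]))
  }
  records$sponsor <- canon(records$sponsor, "company")
  records$indication <- canon(records$indication, "disease")
  records$moa <- canon(records$moa, "moa")
  records$collaborators <- vapply(records$collaborators, function(cell) {
    join_multi(canon(split_multi(cell), "company"))
  }, character(1), USE.NAMES = FALSE)

  if (!"sponsor_original" %in% names(records)) {
    records$sponsor_original <- records$sponsor
  }
  if (rollup) {
    if (is.null(companies)) stop_("rollup = TRUE requires a company table")
    companies$name <- canon(companies$name, "company")
    companies$parent <- ifelse(is.na(companies$parent), NA_character_,
                               canon(companies$parent, "company"))
    validate_company_parents(companies)
    root <- root_parent_map(companies)
    hit <- match(records$sponsor, names(root))
    records$sponsor <- ifelse(is.na(hit), records$sponsor, unname(root[hit]))
  }
  # rollup can make a sponsor collide with one of its collaborators
  records$collaborators <- mapply(function(coll, sp) {
    join_multi(setdiff(split_multi(coll), sp))
  }, records$collaborators, records$sponsor, USE.NAMES = FALSE)
  records
}

# Per-kind named vectors: fold_key(raw) -> canonical. Errors when an alias
# target is itself remapped to something else (non-idempotent table).
alias_maps <- function(aliases) {
  if (is.null(aliases) || !nrow(aliases)) return(list())
  maps <- lapply(split(aliases, aliases$kind), function(a) {
    stats::setNames(a$canonical, fold_key(a$raw))
  })
  bad <- character(0)
  for (kind in names(maps)) {
    map <- maps[[kind]]
    key <- fold_key(unname(map))
    hit <- match(key, names(map))
    off <- !is.na(hit) & unname(map[hit]) != unname(map)
    if (any(off)) bad <- c(bad, paste0(kind, ": ", unique(unname(map)[off])))
  }
  if (length(bad)) {
    stop_("alias table is not idempotent; canonical value(s) remapped: ",
          paste(bad, collapse = "; "))
  }
  maps
}

root_parent_map <- function(companies) {
  parent_of <- stats::setNames(companies$parent, companies$name)
  roots <- vapply(companies$name, function(nm) {
    cur <- nm
    while (cur %in% names(parent_of) && !is.na(parent_of[[cur]])) {
      cur <- parent_of[[cur]]
    }
    cur
  }, character(1))
  roots[roots != companies$name]
}

#' Dataset summary counts
#'
#' Headline counts of a normalized portfolio table: unique drugs, diseases,
#' mechanisms of action, modalities and companies, records per development
#' phase, and approved counts split by orphan-drug-designation status. A drug
#' marketed for several indications appears as several records sharing
#' `drug_name`; uniqueness counts deduplicate on the drug name.
#'
#' @param records Portfolio records.
#' @return A `landscape_summary` list of counts; `pct_odd_approved` is the
#'   percentage of approved drugs (with known status) carrying ODD.
#' @export
summarize_dataset <- function(records) {
  appr <- records[records$phase == "approved", , drop = FALSE]
  n_odd <- sum(appr$odd_status %in% TRUE)
  n_nonodd <- sum(appr$odd_status %in% FALSE)
  denom <- n_odd + n_nonodd
  out <- list(
    n_records = nrow(records),
    n_drugs = length(unique(records$drug_name)),
    n_diseases = length(unique(records$indication)),
    n_moas = length(unique(records$moa)),
    n_modalities = length(unique(records$modality)),
    n_companies = length(unique(records$sponsor)),
    n_approved = nrow(appr),
    n_early_clinical = sum(records$phase == "early_clinical"),
    n_late_clinical = sum(records$phase == "late_clinical"),
    n_odd_approved = n_odd,
    n_nonodd_approved = n_nonodd,
    pct_odd_approved = if (denom > 0) 100 * n_odd / denom else NA_real_)
  class(out) <- "landscape_summary"
  out
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("Rare-disease landscape summary\n")
  cat(sprintf("  records: %d   unique drugs: %d   diseases: %d\n",
              x$n_records, x$n_drugs, x$n_diseases))
  cat(sprintf("  MoAs: %d   modalities: %d   companies: %d\n",
              x$n_moas, x$n_modalities, x$n_companies))
  cat(sprintf("  approved: %d   early clinical: %d   late clinical: %d\n",
              x$n_approved, x$n_early_clinical, x$n_late_clinical))
  if (!is.na(x$pct_odd_approved)) {
    cat(sprintf("  approved with ODD: %d (%.1f%%)   without: %d (%.1f%%)\n",
                x$n_odd_approved, x$pct_odd_approved, x$n_nonodd_approved,
                100 - x$pct_odd_approved))
  }
  invisible(x)
}

#' Companies headquartered per country
#'
#' @param companies Company table (`name`, `hq_country`).
#' @return Data frame of `country`, `n_companies`, sorted by descending count
#'   then country name. Blank or missing countries are bucketed as
#'   `"unspecified"`.
#' @export
count_companies_by_country <- function(companies) {
  if (!nrow(companies)) {
    return(data.frame(country = character(0), n_companies = integer(0),
                      stringsAsFactors = FALSE))
  }
  country <- trimws(companies$hq_country)
  country[is.na(country) | !nzchar(country)] <- "unspecified"
  tab <- table(country)
  out <- data.frame(country = names(tab), n_companies = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_companies, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract revenue records from approved portfolio records
#'
#' Approved records with a known revenue become one revenue row each;
#' records without revenue are excluded (and their count reported via the
#' `n_dropped` attribute).
#'
#' @param records Portfolio records.
#' @param fiscal_year Optional fiscal-year label attached to every row.
#' @return Revenue data frame (`drug_name`, `company`, `indication`,
#'   `revenue`, `fiscal_year`).
#' @export
revenue_records <- function(records, fiscal_year = NA_character_) {
  appr <- records[records$phase == "approved", , drop = FALSE]
  keep <- !is.na(appr$revenue)
  out <- data.frame(drug_name = appr$drug_name[keep],
                    company = appr$sponsor[keep],
                    indication = appr$indication[keep],
                    revenue = appr$revenue[keep],
                    fiscal_year = fiscal_year, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
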