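#' Classify pipeline assets by competitive and mechanistic sharing
#'
#' For each asset, flags whether the sponsor is the sole developer of the
#' indication (`single_development`) or faces at least one other company on
#' it (`shared_disease`), and whether the asset's mechanism of action is
#' exclusive to the sponsor (`unique_moa`) or used by another company
#' (`shared_moa`). The two flags of each axis are mutually exclusive; MoA
#' comparison is exact-string on canonical labels.
#'
#' @param records Normalized portfolio records.
#' @param scope `"pipeline"` (default) restricts to non-approved assets, the
#'   scope on which development-stage competition is assessed; `"all"` keeps
#'   approved assets too.
#' @return The in-scope records with logical columns `single_development`,
#'   `shared_disease`, `unique_moa`, `shared_moa`.
#' @export
classify_assets <- function(records, scope = c("pipeline", "all")) {
  scope <- match.arg(scope)
  rec <- if (scope == "pipeline") {
    records[records$phase != "approved", , drop = FALSE]
  } else records
  rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  if (!nrow(rec)) {
    rec$single_development <- logical(0)
    rec$shared_disease <- logical(0)
    rec$unique_moa <- logical(0)
    rec$shared_moa <- logical(0)
    return(rec)
  }
  companies_per <- function(key) {
    tab <- unique(data.frame(key = key, company = rec$sponsor,
                             stringsAsFactors = FALSE))
    counts <- table(tab$key)
    as.integer(counts[match(key, names(counts))])
  }
  rec$shared_disease <- companies_per(rec$indication) > 1L
  rec$single_development <- !rec$shared_disease
  rec$unique_moa <- companies_per(rec$moa) == 1L
  rec$shared_moa <- !rec$unique_moa
  rownames(rec) <- NULL
  rec
}

#' Competitive and innovative indexes per company
#'
#' Asset-weighted fractions summarising each company's position:
#' \describe{
#'   \item{competitive index (disease axis)}{fraction of the company's
#'     assets whose indication is also developed by at least one other
#'     company.}
#'   \item{competitive index (MoA axis)}{fraction of assets whose mechanism
#'     of action is shared with another company.}
#'   \item{innovative index}{fraction of assets whose MoA is exclusive to
#'     the company.}
#' }
#' Because every asset's MoA is either shared or exclusive, the innovative
#' index and the MoA-axis competitive index sum to 1 for every company.
#'
#' @inheritParams classify_assets
#' @return Data frame of `company`, `n_assets`, `competitive_index_disease`,
#'   `competitive_index_moa`, `innovative_index`, one row per company with at
#'   least one in-scope asset.
#' @export
company_indexes <- function(records, scope = c("pipeline", "all")) {
  scope <- match.arg(scope)
  flagged <- classify_assets(records, scope)
  all_companies <- unique(records$sponsor)
  dropped <- setdiff(all_companies, unique(flagged$sponsor))
  if (length(dropped)) {
    warning(sprintf("%d company(ies) with no asset in scope '%s' excluded: %s",
                    length(dropped), scope,
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  if (!nrow(flagged)) {
    return(data.frame(company = character(0), n_assets = integer(0),
                      competitive_index_disease = numeric(0),
                      competitive_index_moa = numeric(0),
                      innovative_index = numeric(0),
                      stringsAsFactors = FALSE))
  }
  by_c <- split(flagged, flagged$sponsor)
  out <- data.frame(
    company = names(by_c),
    n_assets = vapply(by_c, nrow, integer(1)),
    competitive_index_disease = vapply(by_c, function(x) {
      mean(x$shared_disease)
    }, numeric(1)),
    competitive_index_moa = vapply(by_c, function(x) {
      mean(x$shared_moa)
    }, numeric(1)),
    innovative_index = vapply(by_c, function(x) {
      mean(x$unique_moa)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Heatmap-ready index matrix
#'
#' @param scores A [company_indexes()] result.
#' @return Numeric matrix (rows = companies, columns = the three indexes)
#'   sorted by descending disease-axis competitive index, ties broken
#'   alphabetically by company name.
#' @export
index_matrix <- function(scores) {
  if (!nrow(scores)) stop_("scores must be non-empty")
  ord <- order(-scores$competitive_index_disease, scores$company)
  m <- as.matrix(scores[ord, c("competitive_index_disease",
                               "competitive_index_moa", "innovative_index")])
  rownames(m) <- scores$company[ord]
  m
}
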