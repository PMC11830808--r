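#' Read a STITCH-dialect chemical-protein link table
#'
#' Parses a tab-separated link file with columns `chemical`, `partner` and
#' `combined_score` (an optional `partner_kind` column distinguishes
#' `protein` from `chemical` partners; it defaults to `protein`). Two score
#' dialects exist: integers on 0-1000 (the raw database convention) and
#' reals on 0-1. The dialect is detected per file and recorded in the
#' `dialect` attribute; integer-dialect scores are divided by 1000 so the
#' returned scores are always on \[0, 1\]. A file mixing both dialects is an
#' error; individual scores outside both ranges reject the row (reported via
#' [rejects()]).
#'
#' @param path Tab-separated link file. Column-name synonyms accepted:
#'   `protein` or `item_id_b` for `partner`, `item_id_a` for `chemical`,
#'   `score` for `combined_score`.
#' @return Data frame of `chemical`, `partner`, `partner_kind`, `score`
#'   (normalized), with attributes `dialect` and `rejects`.
#' @export
read_stitch_links <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           encoding = "UTF-8", stringsAsFactors = FALSE)
  names(raw) <- trimws(tolower(names(raw)))
  pick <- function(candidates) {
    hit <- candidates[candidates %in% names(raw)]
    if (!length(hit)) {
      stop_("missing required column (one of): ",
            paste(candidates, collapse = ", "))
    }
    raw[[hit[1]]]
  }
  chemical <- trimws(pick(c("chemical", "item_id_a")))
  partner <- trimws(pick(c("partner", "protein", "item_id_b")))
  score_raw <- trimws(pick(c("combined_score", "score")))
  kind <- if ("partner_kind" %in% names(raw)) {
    tolower(trimws(raw$partner_kind))
  } else rep("protein", nrow(raw))

  num <- parse_num(score_raw)
  reasons <- character(nrow(raw))
  reasons[!num$ok | is.na(num$value)] <- "unparseable score"
  score <- num$value
  out_of_range <- !is.na(score) & (score < 0 | score > 1000)
  reasons[out_of_range & !nzchar(reasons)] <- "score outside both dialects"
  reasons[!(kind %in% c("protein", "chemical")) & !nzchar(reasons)] <-
    "invalid partner_kind"
  keep <- !nzchar(reasons)
  score <- score[keep]

  is_int <- !length(score) || all(score == round(score))
  if (length(score) && max(score) > 1) {
    if (any(score != round(score) & score <= 1)) {
      stop_("mixed score dialects in one file (fractional and > 1 scores)")
    }
    if (!is_int) {
      stop_("mixed score dialects in one file (fractional scores above 1)")
    }
    dialect <- "integer_0_1000"
    score <- score / 1000
  } else {
    dialect <- "real_0_1"
  }

  out <- data.frame(chemical = chemical[keep], partner = partner[keep],
                    partner_kind = kind[keep], score = score,
                    stringsAsFactors = FALSE)
  attr(out, "dialect") <- dialect
  attr(out, "rejects") <- data.frame(row = which(!keep),
                                     reason = reasons[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Build a confidence-filtered drug-drug / drug-protein network
#'
#' Keeps the links at or above `min_score` that touch a listed drug and
#' assembles an undirected typed network: drug-protein edges from protein
#' links, drug-drug edges from explicit chemical-chemical links between two
#' listed drugs. The node set is threshold-independent — all listed drugs
#' plus every protein the source table links to them — so metrics computed
#' at different thresholds share one denominator and connectivity falls
#' monotonically as the threshold rises.
#' Proteins linked to two or more listed drugs additionally induce a
#' shared-protein drug-pair relation, counted and reported separately
#' rather than materialized as edges, so the explicit chemical-chemical
#' edge semantics stay intact.
#'
#' @param drugs Character vector of drug identifiers of interest.
#' @param links Link table from [read_stitch_links()] (or equivalent data
#'   frame with `chemical`, `partner`, `partner_kind`, `score`).
#' @param min_score Confidence threshold in \[0, 1\]; defaults to 0.4, the
#'   customary medium-confidence cutoff for combined scores.
#' @return A `chem_network` object: igraph `$graph` (node attribute `kind`,
#'   edge attributes `type` and `score`), `$drugs`, `$min_score`,
#'   `$shared_protein_pairs` (data frame of drug pairs and the number of
#'   proteins they share).
#' @export
build_chem_network <- function(drugs, links, min_score = 0.4) {
  if (!length(drugs)) stop_("drug list must be non-empty")
  if (!is.numeric(min_score) || min_score < 0 || min_score > 1) {
    stop_("min_score must be in [0, 1]")
  }
  drugs <- unique(drugs)
  if (is.null(links$score)) {
    if (is.null(links$combined_score)) {
      stop_("links need a 'score' or 'combined_score' column")
    }
    links$score <- links$combined_score
  }
  if (any(links$score < 0 | links$score > 1)) {
    stop_("link scores must be normalized to [0, 1]; see read_stitch_links()")
  }
  if (is.null(links$partner_kind)) links$partner_kind <- "protein"
  # node universe: the listed drugs plus every protein the source table
  # links to them, independent of the threshold; only edges are filtered.
  # A fixed universe keeps metrics comparable across a threshold sweep
  # (edge count, density and mean degree then fall monotonically as the
  # threshold rises).
  proteins <- unique(links$partner[links$partner_kind == "protein" &
                                     links$chemical %in% drugs])
  lk <- links[links$score >= min_score, , drop = FALSE]
  prot <- lk[lk$partner_kind == "protein" & lk$chemical %in% drugs, ,
             drop = FALSE]
  # a repeated chemical-protein association is one edge; keep the best score
  if (nrow(prot)) {
    prot <- prot[order(prot$chemical, prot$partner, -prot$score), ,
                 drop = FALSE]
    prot <- prot[!duplicated(prot[, c("chemical", "partner")]), ,
                 drop = FALSE]
  }
  chem <- lk[lk$partner_kind == "chemical" & lk$chemical %in% drugs &
               lk$partner %in% drugs, , drop = FALSE]
  # symmetric duplicates of chemical-chemical links collapse to one edge
  if (nrow(chem)) {
    pair <- t(apply(chem[, c("chemical", "partner")], 1, sort))
    chem <- chem[!duplicated(pair), , drop = FALSE]
    chem <- chem[chem$chemical != chem$partner, , drop = FALSE]
  }
  vertices <- data.frame(name = c(drugs, proteins),
                         kind = c(rep("drug", length(drugs)),
                                  rep("protein", length(proteins))),
                         stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(prot)) data.frame(from = prot$chemical, to = prot$partner,
                               type = "drug_protein", score = prot$score,
                               stringsAsFactors = FALSE),
    if (nrow(chem)) data.frame(from = chem$chemical, to = chem$partner,
                               type = "drug_drug", score = chem$score,
                               stringsAsFactors = FALSE))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), score = numeric(0),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  shared <- shared_protein_pairs(prot)
  out <- list(graph = g, drugs = drugs, min_score = min_score,
              shared_protein_pairs = shared)
  class(out) <- "chem_network"
  out
}

shared_protein_pairs <- function(prot) {
  empty <- data.frame(drug_a = character(0), drug_b = character(0),
                      n_shared_proteins = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(prot)) return(empty)
  links <- unique(prot[, c("chemical", "partner")])
  by_p <- split(links$chemical, links$partner)
  pairs <- list()
  for (dr in by_p) {
    dr <- sort(unique(dr))
    if (length(dr) < 2) next
    cmb <- utils::combn(dr, 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
    }
  }
  if (!length(pairs)) return(empty)
  split_keys <- strsplit(names(pairs), "\r", fixed = TRUE)
  out <- data.frame(drug_a = vapply(split_keys, `[`, character(1), 1),
                    drug_b = vapply(split_keys, `[`, character(1), 2),
                    n_shared_proteins = as.integer(unlist(pairs)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_shared_proteins, out$drug_a, out$drug_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.chem_network <- function(x, ...) {
  kind <- igraph::V(x$graph)$kind
  cat(sprintf(paste0("Chemical network (min score %.2f): %d drugs, ",
                     "%d proteins, %d edges, %d shared-protein pairs\n"),
              x$min_score, sum(kind == "drug"), sum(kind == "protein"),
              igraph::ecount(x$graph), nrow(x$shared_protein_pairs)))
  invisible(x)
}

#' Connectivity metrics of a chemical network
#'
#' @param network A [build_chem_network()] result.
#' @return A `chem_metrics` list: `n_drugs`, `n_proteins`, `n_edges`,
#'   `density` (2E / n(n-1) over all nodes, 0 for fewer than 2 nodes),
#'   `n_components`, `mean_degree`, `isolated_drug_fraction`,
#'   `shared_protein_pairs` (count of drug pairs with at least one common
#'   protein), and the `min_score` the network was built at.
#' @export
network_metrics <- function(network) {
  g <- network$graph
  kind <- igraph::V(g)$kind
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g, mode = "all")
  n_drugs <- sum(kind == "drug")
  out <- list(
    n_drugs = n_drugs,
    n_proteins = sum(kind == "protein"),
    n_edges = e,
    density = if (n >= 2) 2 * e / (n * (n - 1)) else 0,
    n_components = if (n > 0) igraph::count_components(g) else 0L,
    mean_degree = if (n > 0) mean(deg) else 0,
    isolated_drug_fraction = if (n_drugs > 0) {
      sum(deg[kind == "drug"] == 0) / n_drugs
    } else NA_real_,
    shared_protein_pairs = nrow(network$shared_protein_pairs),
    min_score = network$min_score)
  class(out) <- "chem_metrics"
  out
}

#' @export
print.chem_metrics <- function(x, ...) {
  cat(sprintf(paste0("Chem-network metrics (min score %.2f): %d drugs / ",
                     "%d proteins / %d edges\n"),
              x$min_score, x$n_drugs, x$n_proteins, x$n_edges))
  cat(sprintf(paste0("  density %.4f, components %d, mean degree %.2f, ",
                     "isolated drugs %.0f%%, shared-protein pairs %d\n"),
              x$density, x$n_components, x$mean_degree,
              100 * x$isolated_drug_fraction, x$shared_protein_pairs))
  invisible(x)
}

#' Compare connectivity between two drug-group networks
#'
#' Signed per-metric differences (group A minus group B) between metric
#' sets computed at the same confidence threshold, plus a verdict on which
#' group forms the denser, more connected network. Connectivity is judged
#' on four metrics: density and mean degree (higher = denser), component
#' count and isolated-drug fraction (lower = denser). No statistical test
#' is attached.
#'
#' @param metrics_a,metrics_b [network_metrics()] results for the two
#'   groups.
#' @return A `chem_comparison` list: `table` (metric, value_a, value_b,
#'   diff), `connectivity_votes_a`/`connectivity_votes_b` (out of 4) and
#'   `denser` (`"a"`, `"b"` or `"tie"`).
#' @export
compare_groups <- function(metrics_a, metrics_b) {
  if (!isTRUE(all.equal(metrics_a$min_score, metrics_b$min_score))) {
    stop_("metrics computed at different thresholds (",
          metrics_a$min_score, " vs ", metrics_b$min_score, ")")
  }
  fields <- c("n_drugs", "n_proteins", "n_edges", "density", "n_components",
              "mean_degree", "isolated_drug_fraction",
              "shared_protein_pairs")
  tab <- data.frame(metric = fields,
                    value_a = vapply(fields, function(f) {
                      as.numeric(metrics_a[[f]])
                    }, numeric(1)),
                    value_b = vapply(fields, function(f) {
                      as.numeric(metrics_b[[f]])
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  tab$diff <- tab$value_a - tab$value_b
  rownames(tab) <- NULL
  higher_denser <- c(density = 1, mean_degree = 1, n_components = -1,
                     isolated_drug_fraction = -1)
  votes_a <- 0L
  votes_b <- 0L
  for (f in names(higher_denser)) {
    d <- (metrics_a[[f]] - metrics_b[[f]]) * higher_denser[[f]]
    if (is.na(d)) next
    if (d > 0) votes_a <- votes_a + 1L
    if (d < 0) votes_b <- votes_b + 1L
  }
  out <- list(table = tab, connectivity_votes_a = votes_a,
              connectivity_votes_b = votes_b,
              denser = if (votes_a > votes_b) "a"
                       else if (votes_b > votes_a) "b" else "tie")
  class(out) <- "chem_comparison"
  out
}

#' @export
print.chem_comparison <- function(x, ...) {
  cat(sprintf("Network comparison: group %s denser (%d vs %d connectivity votes)\n",
              x$denser, x$connectivity_votes_a, x$connectivity_votes_b))
  print(x$table)
  invisible(x)
}

#' Most frequent mechanisms of action
#'
#' Ranks mechanisms of action by the number of distinct drugs using them,
#' optionally restricted to drugs with (or without) orphan drug
#' designation. A drug listed for several indications under one MoA counts
#' once.
#'
#' @param records Normalized portfolio records.
#' @param odd `TRUE` for ODD drugs only, `FALSE` for non-ODD only, `NULL`
#'   (default) for all records.
#' @param n Maximum number of MoAs returned (default 30).
#' @return Data frame of `moa`, `n_drugs`, descending by count with
#'   alphabetical tie-break, at most `n` rows.
#' @export
top_moa_counts <- function(records, odd = NULL, n = 30) {
  stopifnot(n >= 1)
  rec <- records
  if (!is.null(odd)) rec <- rec[rec$odd_status %in% odd, , drop = FALSE]
  rec <- unique(rec[, c("drug_name", "moa")])
  if (!nrow(rec)) {
    return(data.frame(moa = character(0), n_drugs = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(rec$moa)
  out <- data.frame(moa = names(tab), n_drugs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_drugs, out$moa), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Pathway membership counts for network proteins
#'
#' Joins the proteins of a chemical network (or an explicit protein vector)
#' against a user-supplied protein-to-pathway mapping and counts member
#' proteins per pathway. No enrichment statistic is computed.
#'
#' @param proteins A `chem_network` or character vector of protein
#'   identifiers.
#' @param pathway_map Data frame with columns `protein`, `pathway`.
#' @return Data frame of `pathway`, `n_proteins`, descending, plus an
#'   `n_unmapped` attribute.
#' @export
pathway_membership <- function(proteins, pathway_map) {
  if (inherits(proteins, "chem_network")) {
    kind <- igraph::V(proteins$graph)$kind
    proteins <- igraph::V(proteins$graph)$name[kind == "protein"]
  }
  proteins <- unique(proteins)
  hit <- pathway_map[pathway_map$protein %in% proteins, , drop = FALSE]
  tab <- sort(table(unique(hit[, c("protein", "pathway")])$pathway),
              decreasing = TRUE)
  out <- data.frame(pathway = names(tab), n_proteins = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(!proteins %in% pathway_map$protein)
  out
}
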