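#' Build the tripartite company-collaborator-disease network
#'
#' Represents a development ecosystem as a three-layer directed multigraph:
#' sponsor companies (layer 1), their collaborators (layer 2), and the
#' diseases under development (layer 3). Each program contributes one
#' annotated path from its sponsor to its disease: a direct sponsor-disease
#' edge when the sponsor develops alone, or sponsor-collaborator plus
#' collaborator-disease edges otherwise. A company with several programs on
#' one disease contributes one edge set per program (multigraph semantics),
#' and every edge carries the originating asset, its sponsor and its MoA.
#'
#' A company acting both as sponsor and as someone else's collaborator
#' appears as two role-specific nodes; [knockout()] removes both roles.
#'
#' @param records Normalized portfolio records.
#' @return A `tripartite_network` object wrapping an igraph graph, with a
#'   rejects report (records with blank sponsor or disease) in
#'   `$rejects`.
#' @seealso [disease_activity()], [knockout()], [knockout_all()],
#'   [write_network_graphml()]
#' @export
build_network <- function(records) {
  bad <- is.na(records$sponsor) | !nzchar(records$sponsor) |
    is.na(records$indication) | !nzchar(records$indication)
  rej <- data.frame(row = which(bad),
                    reason = rep("blank sponsor or indication", sum(bad)),
                    stringsAsFactors = FALSE)
  rec <- records[!bad, , drop = FALSE]

  sponsors <- unique(rec$sponsor)
  diseases <- unique(rec$indication)
  collab_sets <- lapply(rec$collaborators, split_multi)
  collaborators <- unique(unlist(collab_sets))

  pfx <- function(p, x) if (length(x)) paste0(p, x) else character(0)
  vertices <- data.frame(
    name = c(pfx("S::", sponsors), pfx("C::", collaborators),
             pfx("D::", diseases)),
    label = c(sponsors, collaborators, diseases),
    layer = c(rep("sponsor", length(sponsors)),
              rep("collaborator", length(collaborators)),
              rep("disease", length(diseases))),
    stringsAsFactors = FALSE)

  edges <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    sp <- rec$sponsor[i]
    d <- rec$indication[i]
    coll <- collab_sets[[i]]
    asset <- rec$drug_name[i]
    moa <- rec$moa[i]
    if (!length(coll)) {
      edges[[i]] <- data.frame(from = paste0("S::", sp),
                               to = paste0("D::", d),
                               type = "sponsor_disease", asset = asset,
                               sponsor = sp, disease = d, moa = moa,
                               stringsAsFactors = FALSE)
    } else {
      edges[[i]] <- rbind(
        data.frame(from = paste0("S::", sp), to = paste0("C::", coll),
                   type = "sponsor_collaborator", asset = asset,
                   sponsor = sp, disease = d, moa = moa,
                   stringsAsFactors = FALSE),
        data.frame(from = paste0("C::", coll), to = paste0("D::", d),
                   type = "collaborator_disease", asset = asset,
                   sponsor = sp, disease = d, moa = moa,
                   stringsAsFactors = FALSE))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               asset = character(0), sponsor = character(0),
               disease = character(0), moa = character(0),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  out <- list(graph = g, n_assets = nrow(rec), rejects = rej)
  class(out) <- "tripartite_network"
  out
}

#' @export
print.tripartite_network <- function(x, ...) {
  lay <- igraph::V(x$graph)$layer
  cat(sprintf(paste0("Tripartite development network: %d sponsors, ",
                     "%d collaborators, %d diseases, %d program edges\n"),
              sum(lay == "sponsor"), sum(lay == "collaborator"),
              sum(lay == "disease"), igraph::ecount(x$graph)))
  if (nrow(x$rejects)) {
    cat(sprintf("  (%d record(s) rejected; see $rejects)\n", nrow(x$rejects)))
  }
  invisible(x)
}

# Edge table of the disease-facing edges with their annotations.
disease_edge_table <- function(net) {
  g <- net$graph
  if (!igraph::ecount(g)) {
    return(data.frame(disease = character(0), sponsor = character(0),
                      moa = character(0), stringsAsFactors = FALSE))
  }
  type <- igraph::E(g)$type
  keep <- type %in% c("sponsor_disease", "collaborator_disease")
  data.frame(disease = igraph::E(g)$disease[keep],
             sponsor = igraph::E(g)$sponsor[keep],
             moa = igraph::E(g)$moa[keep], stringsAsFactors = FALSE)
}

#' Active companies and MoA richness per disease
#'
#' A company is active on a disease if any of its programs (solo or through
#' a collaborator) reaches that disease; the MoA count is the number of
#' distinct mechanisms of action among the programs reaching it. Diseases
#' with no incident program are absent from the table.
#'
#' @param network A [build_network()] result.
#' @return Data frame of `disease`, `n_companies`, `n_moas`, sorted by
#'   descending company count then disease name.
#' @export
disease_activity <- function(network) {
  et <- disease_edge_table(network)
  if (!nrow(et)) {
    return(data.frame(disease = character(0), n_companies = integer(0),
                      n_moas = integer(0), stringsAsFactors = FALSE))
  }
  by_d <- split(et, et$disease)
  out <- data.frame(
    disease = names(by_d),
    n_companies = vapply(by_d, function(x) length(unique(x$sponsor)),
                         integer(1)),
    n_moas = vapply(by_d, function(x) length(unique(x$moa)), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_companies, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a company leaving the ecosystem
#'
#' Removes a sponsor from layer 1 (and its collaborator-role node, if any),
#' deletes all edges induced by its programs, prunes collaborators left with
#' no sponsor, and reports the per-disease impact: companies and unique MoAs
#' remaining, and how many of each were lost. Diseases the company never
#' reached are unchanged by construction.
#'
#' @param network A [build_network()] result.
#' @param company Canonical sponsor name present in layer 1.
#' @return A `knockout_impact` object: `$removed_company` and `$impact`, a
#'   data frame of `disease`, `companies_remaining`, `unique_moas_remaining`,
#'   `delta_companies`, `delta_moas` covering every pre-removal disease.
#' @export
knockout <- function(network, company) {
  g <- network$graph
  lay <- igraph::V(g)$layer
  sponsors <- igraph::V(g)$label[lay == "sponsor"]
  if (!company %in% sponsors) {
    stop_("company not present in the sponsor layer: ", company)
  }
  pre <- disease_activity(network)
  post_net <- remove_company(network, company)
  post <- disease_activity(post_net)
  m <- match(pre$disease, post$disease)
  companies_remaining <- ifelse(is.na(m), 0L, post$n_companies[m])
  moas_remaining <- ifelse(is.na(m), 0L, post$n_moas[m])
  impact <- data.frame(
    disease = pre$disease,
    companies_remaining = as.integer(companies_remaining),
    unique_moas_remaining = as.integer(moas_remaining),
    delta_companies = pre$n_companies - as.integer(companies_remaining),
    delta_moas = pre$n_moas - as.integer(moas_remaining),
    stringsAsFactors = FALSE)
  out <- list(removed_company = company, impact = impact)
  class(out) <- "knockout_impact"
  out
}

#' @export
print.knockout_impact <- function(x, ...) {
  hit <- x$impact[x$impact$delta_companies > 0 | x$impact$delta_moas > 0, ,
                  drop = FALSE]
  cat(sprintf("Knockout of %s: %d of %d diseases affected\n",
              x$removed_company, nrow(hit), nrow(x$impact)))
  if (nrow(hit)) print(utils::head(hit, 10))
  invisible(x)
}

# Removal mechanics shared by knockout(): delete the company's program
# edges and sponsor node, then prune collaborators left with no incident
# edge. The collaborator-role node of the removed company survives while
# other sponsors still route programs through it, so those programs keep
# reaching their diseases (impact counts sponsors, not intermediaries).
remove_company <- function(network, company) {
  g <- network$graph
  if (igraph::ecount(g)) {
    g <- igraph::delete_edges(g, which(igraph::E(g)$sponsor == company))
  }
  g <- igraph::delete_vertices(g,
                               which(igraph::V(g)$name ==
                                       paste0("S::", company)))
  orphaned <- igraph::V(g)$layer == "collaborator" &
    igraph::degree(g, mode = "all") == 0
  g <- igraph::delete_vertices(g, which(orphaned))
  out <- list(graph = g, n_assets = NA_integer_,
              rejects = network$rejects)
  class(out) <- "tripartite_network"
  out
}

#' Knockout simulation over every sponsor
#'
#' Runs [knockout()] once per layer-1 company and stacks the per-disease
#' impact tables.
#'
#' @param network A [build_network()] result.
#' @return Long data frame of `company`, `disease`, `companies_remaining`,
#'   `unique_moas_remaining`, `delta_companies`, `delta_moas`.
#' @export
knockout_all <- function(network) {
  lay <- igraph::V(network$graph)$layer
  sponsors <- sort(igraph::V(network$graph)$label[lay == "sponsor"])
  blocks <- lapply(sponsors, function(cm) {
    imp <- knockout(network, cm)$impact
    if (!nrow(imp)) return(NULL)
    cbind(data.frame(company = cm, stringsAsFactors = FALSE), imp)
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (!length(blocks)) {
    return(data.frame(company = character(0), disease = character(0),
                      companies_remaining = integer(0),
                      unique_moas_remaining = integer(0),
                      delta_companies = integer(0), delta_moas = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Collaboration counts per sponsor
#'
#' @param records Normalized portfolio records.
#' @return Data frame of `company`, `n_collaborations` (program-collaborator
#'   pairs) and `n_partners` (distinct collaborators), sorted by descending
#'   collaboration count.
#' @export
collaboration_counts <- function(records) {
  coll <- lapply(records$collaborators, split_multi)
  n <- vapply(coll, length, integer(1))
  df <- data.frame(company = rep(records$sponsor, n),
                   partner = unlist(coll), stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(company = character(0), n_collaborations = integer(0),
                      n_partners = integer(0), stringsAsFactors = FALSE))
  }
  by_c <- split(df$partner, df$company)
  out <- data.frame(company = names(by_c),
                    n_collaborations = vapply(by_c, length, integer(1)),
                    n_partners = vapply(by_c, function(p) {
                      length(unique(p))
                    }, integer(1)), stringsAsFactors = FALSE)
  out <- out[order(-out$n_collaborations, out$company), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML
#'
#' Writes the graph with its layer, asset, sponsor, disease and MoA
#' attributes preserved, readable by standard network tools.
#'
#' @param network A [build_network()] or [build_chem_network()] result.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- network$graph
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
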