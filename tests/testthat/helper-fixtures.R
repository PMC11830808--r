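# Fixture builders and independent brute-force oracles used across tests.

# One intervention record; defaults give a pipeline-stage asset.
rec <- function(drug, sponsor, indication, moa = "m1",
                collaborators = "", modality = "targeted therapy",
                phase = "early_clinical", odd = NA,
                year = NA_integer_, revenue = NA_real_, organs = "") {
  data.frame(drug_name = drug, sponsor = sponsor,
             collaborators = collaborators, indication = indication,
             moa = moa, modality = modality, phase = phase,
             odd_status = odd, approval_year = as.integer(year),
             revenue = revenue, organ_systems = organs,
             stringsAsFactors = FALSE)
}

records_df <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# Five-record toy set: 2 companies, 3 diseases, mixed phases.
toy_records <- function() {
  records_df(
    rec("d1", "Alpha", "dis1", moa = "mA"),
    rec("d2", "Alpha", "dis2", moa = "mB", collaborators = "Gamma"),
    rec("d3", "Beta", "dis1", moa = "mA", phase = "late_clinical"),
    rec("d4", "Beta", "dis3", moa = "mC", phase = "approved", odd = TRUE,
        year = 2019L, revenue = 120),
    rec("d5", "Beta", "dis3", moa = "mD", phase = "approved", odd = FALSE,
        year = 2020L, revenue = 80))
}

# ---- independent oracles (no package internals, no igraph) ----

# Per-disease developer and MoA counts straight from the record rows.
oracle_disease_activity <- function(records) {
  records <- records[nzchar(records$sponsor) & nzchar(records$indication), ,
                     drop = FALSE]
  diseases <- sort(unique(records$indication))
  data.frame(
    disease = diseases,
    n_companies = vapply(diseases, function(d) {
      length(unique(records$sponsor[records$indication == d]))
    }, integer(1)),
    n_moas = vapply(diseases, function(d) {
      length(unique(records$moa[records$indication == d]))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Knockout oracle: rebuild the activity table from the records minus the
# company's sponsored rows; diseases losing all programs drop to zero.
oracle_knockout <- function(records, company) {
  pre <- oracle_disease_activity(records)
  post <- oracle_disease_activity(records[records$sponsor != company, ,
                                          drop = FALSE])
  m <- match(pre$disease, post$disease)
  data.frame(
    disease = pre$disease,
    companies_remaining = ifelse(is.na(m), 0L, post$n_companies[m]),
    unique_moas_remaining = ifelse(is.na(m), 0L, post$n_moas[m]),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Exhaustive pairwise sharing oracle for asset flags.
oracle_classify <- function(records) {
  n <- nrow(records)
  shared_disease <- logical(n)
  unique_moa <- logical(n)
  for (i in seq_len(n)) {
    others <- records[-i, , drop = FALSE]
    shared_disease[i] <- any(others$indication == records$indication[i] &
                               others$sponsor != records$sponsor[i])
    unique_moa[i] <- !any(others$moa == records$moa[i] &
                            others$sponsor != records$sponsor[i])
  }
  data.frame(shared_disease = shared_disease, unique_moa = unique_moa)
}

# Closed-form Pearson correlation from the sums, no call to cor().
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Brute-force graph metrics from an explicit edge list (character from/to
# vectors) over a known node set: adjacency matrix + BFS components.
oracle_graph_metrics <- function(nodes, from, to) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_along(from)) {
    adj[from[k], to[k]] <- TRUE
    adj[to[k], from[k]] <- TRUE
  }
  n_edges <- sum(adj[upper.tri(adj)])
  deg <- rowSums(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  list(n_edges = n_edges,
       density = if (n >= 2) 2 * n_edges / (n * (n - 1)) else 0,
       mean_degree = if (n > 0) mean(deg) else 0,
       n_components = cid)
}

# Tiny random ecosystem for oracle sweeps.
random_small_ecosystem <- function(seed, max_companies = 8) {
  cfg <- ecosystem_config(
    n_companies = sample(2:max_companies, 1),
    n_diseases = sample(3:10, 1),
    n_moas = sample(2:6, 1),
    mean_assets_per_company = runif(1, 1, 5),
    collaboration_prob = runif(1, 0, 0.6),
    unique_moa_fraction = runif(1),
    odd_fraction = runif(1),
    approved_fraction = runif(1),
    seed = seed)
  generate_ecosystem(cfg)
}
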