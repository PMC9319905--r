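# unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Filter a domain annotation to expressed isoforms
#'
#' Keeps only isoforms whose median TPM exceeds `min_median_tpm` (default
#' 1 TPM) in both conditions, the expression filter applied before network
#' construction. Domain rows for unexpressed isoforms, and isoforms present
#' in the annotation but absent from the expression table, are dropped
#' (counts recorded in attributes).
#'
#' @param es an [expression_set()].
#' @param annotation `data.frame` with columns `isoform_id`, `gene_id`,
#'   `domain_id` and optionally `exon_id`.
#' @param min_median_tpm expression cutoff, default 1.
#' @return the filtered annotation, with attributes `n_unexpressed` and
#'   `n_unquantified` (isoforms dropped for each reason).
#' @export
annotate_expressed_isoforms <- function(es, annotation, min_median_tpm = 1) {
  stopifnot(inherits(es, "expression_set"),
            all(c("isoform_id", "gene_id", "domain_id") %in%
                  names(annotation)))
  idx <- condition_index(es$condition)
  med1 <- apply(es$tpm[, idx$control, drop = FALSE], 1, stats::median)
  med2 <- apply(es$tpm[, idx$treatment, drop = FALSE], 1, stats::median)
  expressed <- rownames(es$tpm)[med1 > min_median_tpm &
                                med2 > min_median_tpm]
  known <- annotation$isoform_id %in% rownames(es$tpm)
  keep <- known & annotation$isoform_id %in% expressed
  out <- annotation[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unquantified") <-
    length(unique(annotation$isoform_id[!known]))
  attr(out, "n_unexpressed") <-
    length(unique(annotation$isoform_id[known])) -
    length(unique(out$isoform_id))
  out
}

#' Build the domain-supported interaction network
#'
#' A protein-protein interaction (A, B) is retained only when some
#' annotated isoform of A carries a domain dA and some isoform of B a
#' domain dB such that (dA, dB) is a known domain-domain interaction: the
#' edge must be supported by at least one pair of interacting domains.
#' Qualifying domain pairs are recorded per edge; self-interactions
#' (A = B) are allowed. PPI and DDI tables are deduplicated as unordered
#' pairs.
#'
#' @param annotation (filtered) domain annotation with `isoform_id`,
#'   `gene_id`, `domain_id`.
#' @param ppi `data.frame` with two gene columns (first two are used).
#' @param ddi `data.frame` with two domain columns (first two are used).
#' @return `data.frame` of class `interaction_edges`: `gene_a`, `gene_b`
#'   and list-columns `pairs` (qualifying "dA|dB" strings), `domains_a`,
#'   `domains_b` (the per-side domains occurring in qualifying pairs).
#' @export
build_network <- function(annotation, ppi, ddi) {
  ppi <- unique(data.frame(a = pmin(ppi[[1L]], ppi[[2L]]),
                           b = pmax(ppi[[1L]], ppi[[2L]]),
                           stringsAsFactors = FALSE))
  ddi_keys <- unique(pair_key(ddi[[1L]], ddi[[2L]]))
  dom_by_gene <- split(annotation$domain_id, annotation$gene_id)
  dom_by_gene <- lapply(dom_by_gene, unique)

  rows <- vector("list", nrow(ppi)); r <- 0L
  for (i in seq_len(nrow(ppi))) {
    da <- dom_by_gene[[ppi$a[i]]]
    db <- dom_by_gene[[ppi$b[i]]]
    if (is.null(da) || is.null(db)) next
    grid <- expand.grid(da = da, db = db, stringsAsFactors = FALSE)
    ok <- pair_key(grid$da, grid$db) %in% ddi_keys
    if (!any(ok)) next
    r <- r + 1L
    rows[[r]] <- list(gene_a = ppi$a[i], gene_b = ppi$b[i],
                      pairs = paste(grid$da[ok], grid$db[ok], sep = "|"),
                      domains_a = unique(grid$da[ok]),
                      domains_b = unique(grid$db[ok]))
  }
  rows <- rows[seq_len(r)]
  out <- data.frame(
    gene_a = vapply(rows, `[[`, character(1), "gene_a"),
    gene_b = vapply(rows, `[[`, character(1), "gene_b"),
    stringsAsFactors = FALSE)
  out$pairs <- lapply(rows, `[[`, "pairs")
  out$domains_a <- lapply(rows, `[[`, "domains_a")
  out$domains_b <- lapply(rows, `[[`, "domains_b")
  class(out) <- c("interaction_edges", "data.frame")
  out
}

#' Compute per-condition Interaction Scores (IS)
#'
#' For an edge (A, B) and a condition, the Interaction Score is the product
#' over the two partners of the summed condition-mean isoform fractions of
#' the isoforms predicted to carry the domain(s) involved in the
#' interaction:
#' `IS = (sum IF of A-isoforms carrying a qualifying A-side domain) x
#' (sum IF of B-isoforms carrying a qualifying B-side domain)`.
#' An isoform carrying several qualifying domains counts once. For a
#' self-interaction the square of the carrying-isoform IF sum is used.
#' Under per-gene IF normalisation, 0 <= IS <= 1.
#'
#' @param edges an `interaction_edges` table from [build_network()].
#' @param annotation domain annotation (isoform-to-domain map).
#' @param mean_ifs `data.frame` with `isoform_id`, `gene_id`,
#'   `mean_if_control`, `mean_if_treatment` (the `summary` element of an
#'   `if_table` has this shape); isoforms not retained in a condition
#'   contribute 0 there.
#' @return `edges` with numeric columns `is_control` and `is_treatment`
#'   (NA, with `flag_missing_if = TRUE`, when a partner gene is absent from
#'   the IF table).
#' @export
compute_edge_scores <- function(edges, annotation, mean_ifs) {
  stopifnot(inherits(edges, "interaction_edges"))
  ifc <- ifelse(is.na(mean_ifs$mean_if_control), 0,
                mean_ifs$mean_if_control)
  ift <- ifelse(is.na(mean_ifs$mean_if_treatment), 0,
                mean_ifs$mean_if_treatment)
  if (!is.null(mean_ifs$retained_control)) {
    ifc <- ifelse(mean_ifs$retained_control, ifc, 0)
    ift <- ifelse(mean_ifs$retained_treatment, ift, 0)
  }
  names(ifc) <- names(ift) <- mean_ifs$isoform_id
  iso_by_gene <- split(annotation$isoform_id, annotation$gene_id)
  dom_of_iso <- split(annotation$domain_id, annotation$isoform_id)

  side_sum <- function(gene, domains) {
    isos <- unique(iso_by_gene[[gene]])
    isos <- isos[isos %in% mean_ifs$isoform_id]
    carrying <- isos[vapply(isos, function(i) {
      any(dom_of_iso[[i]] %in% domains)
    }, logical(1))]
    c(sum(ifc[carrying]), sum(ift[carrying]))
  }

  n <- nrow(edges)
  isc <- ist <- rep(NA_real_, n)
  flag <- logical(n)
  genes_known <- unique(mean_ifs$gene_id)
  for (i in seq_len(n)) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (!(a %in% genes_known) || !(b %in% genes_known)) {
      flag[i] <- TRUE
      next
    }
    if (a == b) {
      s <- side_sum(a, union(edges$domains_a[[i]], edges$domains_b[[i]]))
      isc[i] <- s[1L]^2; ist[i] <- s[2L]^2
    } else {
      sa <- side_sum(a, edges$domains_a[[i]])
      sb <- side_sum(b, edges$domains_b[[i]])
      isc[i] <- sa[1L] * sb[1L]; ist[i] <- sa[2L] * sb[2L]
    }
  }
  edges$is_control <- isc
  edges$is_treatment <- ist
  edges$flag_missing_if <- flag
  edges
}

#' Compute the differential Interaction Score (dIS)
#'
#' `dIS = log2((IS_treatment + epsilon) / (IS_control + epsilon))`. The
#' treatment (silencing) condition sits in the numerator, so interactions
#' lost upon treatment have dIS < 0. The symmetric pseudocount `epsilon`
#' (default 1e-3) keeps the ratio finite when an IS is 0; with
#' `epsilon = 0` the score is the plain log2 ratio and is antisymmetric
#' under condition swap whenever both IS are positive.
#'
#' @param edges output of [compute_edge_scores()].
#' @param epsilon pseudocount, default 1e-3.
#' @return `edges` with a `dis` column (NA when either IS is missing).
#' @export
compute_dis <- function(edges, epsilon = 1e-3) {
  stopifnot(epsilon >= 0)
  edges$dis <- log2((edges$is_treatment + epsilon) /
                      (edges$is_control + epsilon))
  edges
}

#' Summarise a scored network
#'
#' Node degrees (a self-loop adds 2), hub ranking by degree, the per-node
#' fraction of incident edges with dIS < 0, the average degree and degree
#' range, and connected-component sizes.
#'
#' @param edges scored `interaction_edges` (after [compute_dis()]).
#' @return list of class `network_summary` with elements `nodes` (ranked
#'   `data.frame`), `n_edges`, `average_degree`, `degree_range`,
#'   `component_sizes`.
#' @export
summarize_network <- function(edges) {
  if (nrow(edges) == 0L) {
    return(structure(list(
      nodes = data.frame(gene_id = character(), degree = integer(),
                         frac_dis_negative = numeric(), rank = integer(),
                         stringsAsFactors = FALSE),
      n_edges = 0L, average_degree = NA_real_,
      degree_range = c(NA_integer_, NA_integer_),
      component_sizes = integer()), class = "network_summary"))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  deg <- igraph::degree(g, loops = TRUE)
  nodes <- names(deg)
  frac_neg <- vapply(nodes, function(v) {
    inc <- edges$gene_a == v | edges$gene_b == v
    d <- edges$dis[inc]
    if (all(is.na(d))) NA_real_ else mean(d < 0, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-deg, nodes)
  node_df <- data.frame(gene_id = nodes[ord], degree = as.integer(deg[ord]),
                        frac_dis_negative = frac_neg[ord],
                        rank = seq_along(ord), row.names = NULL,
                        stringsAsFactors = FALSE)
  comp <- igraph::components(g)
  structure(list(
    nodes = node_df, n_edges = nrow(edges),
    average_degree = mean(deg),
    degree_range = range(as.integer(deg)),
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE)),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "network_summary: %d nodes, %d edges; average degree %.2f (range %d-%d)\n",
    nrow(x$nodes), x$n_edges, x$average_degree,
    x$degree_range[1L], x$degree_range[2L]))
  if (nrow(x$nodes)) {
    cat(sprintf("top hub: %s (degree %d)\n", x$nodes$gene_id[1L],
                x$nodes$degree[1L]))
  }
  invisible(x)
}

#' Extract the regulated subnetwork
#'
#' Restricts the network to edges touching at least one qualifying seed
#' gene. A gene qualifies when it harbours a significant exon-skipping
#' event and its cohort inclusion levels correlate (p below
#' `correlation_p`) with the regulator genes' expression — with both
#' regulators by default (`require_both = TRUE`), with at least one
#' otherwise.
#'
#' @param edges scored `interaction_edges`.
#' @param calls output of [call_differential_events()] with `type` and
#'   `gene_id` columns.
#' @param correlations `data.frame` with `gene_id` (of the event's host
#'   gene), `regulator`, `p_value` — e.g. from
#'   [correlate_psi_expression()] joined to an event-to-gene map.
#' @param regulators character vector of regulator gene ids.
#' @param correlation_p significance cutoff, default 0.05.
#' @param require_both require correlation with every regulator (default)
#'   or any.
#' @return the edge subset; `attr(, "seed_genes")` lists the qualifying
#'   genes. Warns when no gene qualifies.
#' @export
extract_subnetwork <- function(edges, calls, correlations, regulators,
                               correlation_p = 0.05, require_both = TRUE) {
  sig_es <- unique(calls$gene_id[calls$significant & calls$type == "ES"])
  corr <- correlations[correlations$regulator %in% regulators &
                         !is.na(correlations$p_value) &
                         correlations$p_value < correlation_p, ,
                       drop = FALSE]
  n_reg <- tapply(corr$regulator, corr$gene_id,
                  function(r) length(unique(r)))
  need <- if (require_both) length(regulators) else 1L
  corr_genes <- names(n_reg)[n_reg >= need]
  seed <- intersect(sig_es, corr_genes)
  keep <- edges$gene_a %in% seed | edges$gene_b %in% seed
  if (!any(keep)) warning("no gene qualifies; subnetwork is empty")
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed_genes") <- seed
  out
}

#' Export a scored network
#'
#' Writes `nodes.tsv`, `edges.tsv`, a GraphML file (node attribute
#' `degree`; edge attributes `dIS`, `abs_dIS`, `is_cond1`, `is_cond2` and a
#' sign-coded `color`, the conventional blue-negative / red-positive
#' palette) and a SIF file. Empty networks export valid empty files.
#'
#' @param edges scored `interaction_edges`.
#' @param summary matching [summarize_network()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_network <- function(edges, summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv", "network.graphml",
                            "network.sif"))
  utils::write.table(summary$nodes, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  flat <- data.frame(
    gene_a = edges$gene_a, gene_b = edges$gene_b,
    domain_pairs = vapply(edges$pairs, paste, character(1), collapse = ";"),
    is_control = edges$is_control, is_treatment = edges$is_treatment,
    dis = edges$dis, stringsAsFactors = FALSE)
  utils::write.table(flat, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      flat[, c("gene_a", "gene_b")], directed = FALSE)
    igraph::V(g)$degree <-
      summary$nodes$degree[match(igraph::V(g)$name, summary$nodes$gene_id)]
    igraph::E(g)$dIS <- flat$dis
    igraph::E(g)$abs_dIS <- abs(flat$dis)
    igraph::E(g)$is_cond1 <- flat$is_control
    igraph::E(g)$is_cond2 <- flat$is_treatment
    igraph::E(g)$color <- ifelse(flat$dis < 0, "blue",
                                 ifelse(flat$dis > 0, "red", "grey"))
    igraph::write_graph(g, paths[3L], format = "graphml")
    writeLines(paste(flat$gene_a, "dd", flat$gene_b), paths[4L])
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::write_graph(g, paths[3L], format = "graphml")
    writeLines(character(0), paths[4L])
  }
  invisible(paths)
}
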