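# minimal two-gene fixture: A has a carrying (IF 0.6) and a non-carrying
# (IF 0.4) isoform; B has a single carrying isoform (IF 1.0)
worked_fixture <- function() {
  ann <- data.frame(
    isoform_id = c("A.i1", "B.i1"), gene_id = c("A", "B"),
    domain_id = c("dX", "dY"), exon_id = "E1", stringsAsFactors = FALSE)
  mean_ifs <- data.frame(
    isoform_id = c("A.i1", "A.i2", "B.i1"),
    gene_id = c("A", "A", "B"),
    mean_if_control = c(0.6, 0.4, 1.0),
    mean_if_treatment = c(0.3, 0.7, 1.0), stringsAsFactors = FALSE)
  ppi <- data.frame(gene_a = "A", gene_b = "B")
  ddi <- data.frame(domain_a = "dX", domain_b = "dY")
  list(ann = ann, mean_ifs = mean_ifs, ppi = ppi, ddi = ddi)
}

test_that("interaction scores follow the product-of-carrier-sums formula", {
  f <- worked_fixture()
  edges <- build_network(f$ann, f$ppi, f$ddi)
  expect_equal(nrow(edges), 1L)
  scored <- compute_edge_scores(edges, f$ann, f$mean_ifs)
  expect_equal(scored$is_control, 0.6 * 1.0)
  expect_equal(scored$is_treatment, 0.3 * 1.0)

  # no carrying isoform on one side: IS = 0
  ifs0 <- f$mean_ifs
  ifs0$mean_if_control[1] <- 0
  expect_equal(compute_edge_scores(edges, f$ann, ifs0)$is_control, 0)

  # self-interaction scores as the squared carrier sum
  ann_s <- data.frame(isoform_id = "S.i1", gene_id = "S",
                      domain_id = "dS", exon_id = "E1")
  ifs_s <- data.frame(isoform_id = c("S.i1", "S.i2"), gene_id = "S",
                      mean_if_control = c(0.5, 0.5),
                      mean_if_treatment = c(0.5, 0.5))
  e_s <- build_network(ann_s, data.frame(a = "S", b = "S"),
                       data.frame(a = "dS", b = "dS"))
  expect_equal(compute_edge_scores(e_s, ann_s, ifs_s)$is_control, 0.25)
})

test_that("dIS is a log2 ratio with the stated sign and symmetry", {
  edges <- build_network(worked_fixture()$ann, worked_fixture()$ppi,
                         worked_fixture()$ddi)
  edges$is_control <- 1.0
  edges$is_treatment <- 0.25
  expect_equal(compute_dis(edges, epsilon = 0)$dis, -2)

  # equal scores: exactly 0
  edges$is_treatment <- 1.0
  expect_equal(compute_dis(edges, epsilon = 0)$dis, 0)
  expect_equal(compute_dis(edges, epsilon = 1e-3)$dis, 0)

  # antisymmetry under condition swap at epsilon = 0
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1)
    e1 <- edges; e1$is_control <- a; e1$is_treatment <- b
    e2 <- edges; e2$is_control <- b; e2$is_treatment <- a
    expect_equal(compute_dis(e1, 0)$dis, -compute_dis(e2, 0)$dis)
  }
})

test_that("edges require at least one supporting domain pair", {
  f <- worked_fixture()
  expect_equal(nrow(build_network(f$ann, f$ppi, f$ddi)), 1L)
  # same PPI but the DDI table lacks the pair
  no_ddi <- data.frame(domain_a = "dX", domain_b = "dZ")
  expect_equal(nrow(build_network(f$ann, f$ppi, no_ddi)), 0L)
  # duplicated and reversed PPI rows collapse to one edge
  ppi2 <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "A", "B"))
  expect_equal(nrow(build_network(f$ann, ppi2, f$ddi)), 1L)
})

test_that("builder and scorer match the brute-force oracle on fixtures", {
  for (seed in 1:8) {
    f <- random_network_fixture(n_genes = 25, seed = seed)
    edges <- compute_dis(
      compute_edge_scores(build_network(f$annotation, f$ppi, f$ddi),
                          f$annotation, f$mean_ifs), epsilon = 0)
    got <- edges_for_comparison(edges)
    want <- brute_force_network(f$annotation, f$ppi, f$ddi, f$mean_ifs)
    expect_equal(got$gene_a, want$gene_a)
    expect_equal(got$gene_b, want$gene_b)
    expect_equal(got$is_control, want$is_control, tolerance = 1e-12)
    expect_equal(got$is_treatment, want$is_treatment, tolerance = 1e-12)
    expect_equal(got$dis, want$dis, tolerance = 1e-12)
  }
})

test_that("raising a carrier's treatment IF never lowers its edges' dIS", {
  f <- worked_fixture()
  edges <- build_network(f$ann, f$ppi, f$ddi)
  base <- compute_dis(compute_edge_scores(edges, f$ann, f$mean_ifs),
                      epsilon = 1e-3)$dis
  for (up in c(0.4, 0.6, 0.9)) {
    ifs <- f$mean_ifs
    ifs$mean_if_treatment[1] <- up
    d <- compute_dis(compute_edge_scores(edges, f$ann, ifs),
                     epsilon = 1e-3)$dis
    expect_gte(d, base)
    base <- d
  }
})

test_that("the expression filter keeps isoforms above median TPM", {
  tpm <- rbind(
    g1.i1 = c(5, 6, 5, 4, 5, 6),      # expressed in both
    g1.i2 = c(0.5, 0.6, 0.4, 5, 6, 5),# fails control median
    g2.i1 = c(2, 2, 2, 2, 2, 2),      # expressed
    g2.i2 = c(0.2, 0.2, 0.2, 0.3, 0.2, 0.2))  # fails both
  es <- expression_set(tpm, c("g1", "g1", "g2", "g2"),
                       factor(rep(c("a", "b"), each = 3),
                              levels = c("a", "b")))
  ann <- data.frame(
    isoform_id = c(rownames(tpm), "ghost.i1"),
    gene_id = c("g1", "g1", "g2", "g2", "ghost"),
    domain_id = "d1", exon_id = "E1")
  out <- annotate_expressed_isoforms(es, ann)
  expect_setequal(out$isoform_id, c("g1.i1", "g2.i1"))
  expect_equal(attr(out, "n_unquantified"), 1L)
  expect_equal(attr(out, "n_unexpressed"), 2L)
})

test_that("network summaries report degree, hubs and dIS balance", {
  # 5-edge star around H, plus one self-loop elsewhere
  edges <- build_network(
    data.frame(isoform_id = paste0(c("H", "a", "b", "c", "d", "e", "S"),
                                   ".i1"),
               gene_id = c("H", "a", "b", "c", "d", "e", "S"),
               domain_id = paste0("d",
                                  c("H", "a", "b", "c", "d", "e", "S")),
               exon_id = "E1"),
    data.frame(gene_a = c("H", "H", "H", "H", "H", "S"),
               gene_b = c("a", "b", "c", "d", "e", "S")),
    data.frame(domain_a = c(rep("dH", 5), "dS"),
               domain_b = c("da", "db", "dc", "dd", "de", "dS")))
  edges$is_control <- 1
  edges$is_treatment <- c(rep(0.5, 5), 2)   # star decreases, loop rises
  edges <- compute_dis(edges, epsilon = 0)
  s <- summarize_network(edges)
  expect_equal(s$nodes$gene_id[1], "H")
  expect_equal(s$nodes$degree[1], 5L)
  expect_equal(s$nodes$degree[s$nodes$gene_id == "S"], 2L)  # self-loop
  expect_true(all(s$nodes$degree[s$nodes$gene_id %in%
                                   c("a", "b", "c", "d", "e")] == 1L))
  expect_equal(s$nodes$frac_dis_negative[1], 1)
  expect_equal(s$nodes$frac_dis_negative[s$nodes$gene_id == "S"], 0)
  expect_equal(s$degree_range, c(1L, 5L))
  expect_equal(sort(s$component_sizes, decreasing = TRUE), c(6L, 1L))

  # empty network: empty summary, no error
  e0 <- edges[0, ]
  s0 <- summarize_network(e0)
  expect_equal(nrow(s0$nodes), 0L)
  expect_equal(s0$n_edges, 0L)
})

test_that("subnetwork extraction needs a significant ES and correlations", {
  genes <- sprintf("g%02d", 1:10)
  ann <- data.frame(isoform_id = paste0(genes, ".i1"), gene_id = genes,
                    domain_id = paste0("d", genes), exon_id = "E1")
  # ring of 10 edges
  ppi <- data.frame(gene_a = genes, gene_b = genes[c(2:10, 1)])
  ddi <- data.frame(domain_a = paste0("d", genes),
                    domain_b = paste0("d", genes[c(2:10, 1)]))
  edges <- build_network(ann, ppi, ddi)
  edges$is_control <- 1; edges$is_treatment <- 1
  edges <- compute_dis(edges)

  calls <- data.frame(event_id = paste0("ev", 1:10), type = "ES",
                      gene_id = genes,
                      significant = genes %in% c("g01", "g02", "g03",
                                                 "g07"))
  correlations <- rbind(
    expand.grid(gene_id = c("g01", "g02", "g03"),
                regulator = c("R1", "R2"), p_value = 0.01,
                stringsAsFactors = FALSE),
    # g07: significant ES but correlated with only one regulator
    data.frame(gene_id = "g07", regulator = "R1", p_value = 0.01),
    # g05: correlated with both but no significant ES
    data.frame(gene_id = "g05", regulator = c("R1", "R2"),
               p_value = 0.001))
  sub <- extract_subnetwork(edges, calls, correlations, c("R1", "R2"))
  expect_setequal(attr(sub, "seed_genes"), c("g01", "g02", "g03"))
  # edges touching a seed gene: by-hand filter over the ring
  want <- edges$gene_a %in% c("g01", "g02", "g03") |
    edges$gene_b %in% c("g01", "g02", "g03")
  expect_equal(nrow(sub), sum(want))

  # one-regulator reading pulls g07 in
  sub2 <- extract_subnetwork(edges, calls, correlations, c("R1", "R2"),
                             require_both = FALSE)
  expect_true("g07" %in% attr(sub2, "seed_genes"))

  # every gene qualifying returns the full network
  all_corr <- expand.grid(gene_id = genes, regulator = c("R1", "R2"),
                          p_value = 0.001, stringsAsFactors = FALSE)
  all_calls <- calls; all_calls$significant <- TRUE
  sub3 <- extract_subnetwork(edges, all_calls, all_corr, c("R1", "R2"))
  expect_equal(nrow(sub3), nrow(edges))

  # nothing qualifying warns and returns an empty edge set
  none <- calls; none$significant <- FALSE
  expect_warning(
    sub4 <- extract_subnetwork(edges, none, correlations, c("R1", "R2")),
    "empty")
  expect_equal(nrow(sub4), 0L)
})

test_that("network exports round-trip through GraphML and TSV", {
  f <- random_network_fixture(n_genes = 15, seed = 3)
  edges <- compute_dis(
    compute_edge_scores(build_network(f$annotation, f$ppi, f$ddi),
                        f$annotation, f$mean_ifs))
  summ <- summarize_network(edges)
  dir <- tempfile()
  export_network(edges, summ, dir)
  expect_true(all(file.exists(file.path(
    dir, c("nodes.tsv", "edges.tsv", "network.graphml", "network.sif")))))

  g <- igraph::read_graph(file.path(dir, "network.graphml"),
                          format = "graphml")
  expect_equal(igraph::ecount(g), nrow(edges))
  tsv <- read.table(file.path(dir, "edges.tsv"), header = TRUE, sep = "\t")
  expect_equal(sort(igraph::E(g)$dIS), sort(tsv$dis), tolerance = 1e-9)
  expect_equal(sort(igraph::V(g)$degree),
               sort(summ$nodes$degree))

  # empty network still exports valid files
  dir0 <- tempfile()
  export_network(edges[0, ], summarize_network(edges[0, ]), dir0)
  g0 <- igraph::read_graph(file.path(dir0, "network.graphml"),
                           format = "graphml")
  expect_equal(igraph::ecount(g0), 0)
})
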