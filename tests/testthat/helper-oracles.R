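# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately re-derive results by direct enumeration or
# brute force, independent of the package's implementation paths.

# --- expression fixtures -------------------------------------------------

make_expression <- function(tpm_list, n_rep = 3, noise = 0, seed = NULL) {
  # tpm_list: named list gene -> numeric vector of isoform baseline TPMs
  # (same value in both conditions unless a matrix with 2 columns is given)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in names(tpm_list)) {
    v <- tpm_list[[g]]
    if (is.null(dim(v))) v <- cbind(v, v)
    for (i in seq_len(nrow(v))) {
      base <- c(rep(v[i, 1], n_rep), rep(v[i, 2], n_rep))
      if (noise > 0) base <- base * rlnorm(2 * n_rep, 0, noise)
      rows[[paste0(g, ".i", i)]] <- c(gene = g, base)
    }
  }
  tpm <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(tpm) <- names(rows)
  colnames(tpm) <- c(paste0("c", seq_len(n_rep)), paste0("t", seq_len(n_rep)))
  expression_set(tpm, vapply(rows, `[[`, character(1), "gene"),
                 factor(rep(c("ctl", "kd"), each = n_rep),
                        levels = c("ctl", "kd")))
}

make_counts <- function(inc, skp, n_rep = 3, events = NULL) {
  # inc/skp: event x sample matrices (2 * n_rep columns)
  condition <- factor(rep(c("ctl", "kd"), each = n_rep),
                      levels = c("ctl", "kd"))
  colnames(inc) <- colnames(skp) <-
    c(paste0("c", seq_len(n_rep)), paste0("t", seq_len(n_rep)))
  junction_counts(inc, skp, condition, events = events)
}

# --- brute-force network oracle -----------------------------------------

# Direct double-loop reimplementation of the build + score + dIS chain:
# all PPI pairs x all domain pairs against the DDI list, carrier sums by
# explicit per-isoform loops.
brute_force_network <- function(annotation, ppi, ddi, mean_ifs,
                                epsilon = 0) {
  norm_pair <- function(a, b) paste(min(a, b), max(a, b), sep = "~")
  ddi_set <- unique(mapply(norm_pair, ddi[[1]], ddi[[2]]))
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(ppi))) {
    a <- min(ppi[[1]][i], ppi[[2]][i])
    b <- max(ppi[[1]][i], ppi[[2]][i])
    k <- paste(a, b)
    if (k %in% seen) next
    seen <- c(seen, k)
    dom_a <- unique(annotation$domain_id[annotation$gene_id == a])
    dom_b <- unique(annotation$domain_id[annotation$gene_id == b])
    qual_a <- character(0); qual_b <- character(0)
    for (da in dom_a) for (db in dom_b) {
      if (norm_pair(da, db) %in% ddi_set) {
        qual_a <- union(qual_a, da); qual_b <- union(qual_b, db)
      }
    }
    if (length(qual_a) == 0) next
    carrier_sum <- function(g, doms, col) {
      isos <- unique(annotation$isoform_id[annotation$gene_id == g])
      s <- 0
      for (iso in isos) {
        has <- any(annotation$domain_id[annotation$isoform_id == iso]
                   %in% doms)
        idx <- which(mean_ifs$isoform_id == iso)
        if (has && length(idx)) {
          v <- mean_ifs[[col]][idx]
          s <- s + ifelse(is.na(v), 0, v)
        }
      }
      s
    }
    if (a == b) {
      doms <- union(qual_a, qual_b)
      is1 <- carrier_sum(a, doms, "mean_if_control")^2
      is2 <- carrier_sum(a, doms, "mean_if_treatment")^2
    } else {
      is1 <- carrier_sum(a, qual_a, "mean_if_control") *
        carrier_sum(b, qual_b, "mean_if_control")
      is2 <- carrier_sum(a, qual_a, "mean_if_treatment") *
        carrier_sum(b, qual_b, "mean_if_treatment")
    }
    out[[k]] <- data.frame(
      gene_a = a, gene_b = b, is_control = is1, is_treatment = is2,
      dis = log2((is2 + epsilon) / (is1 + epsilon)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_a = character(), gene_b = character(),
                      is_control = numeric(), is_treatment = numeric(),
                      dis = numeric(), stringsAsFactors = FALSE)
  }
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

# random annotation/PPI/DDI/IF fixture for oracle comparisons
random_network_fixture <- function(n_genes = 30, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  domains <- sprintf("d%02d", seq_len(max(4, n_genes %/% 2)))
  ann <- do.call(rbind, lapply(genes, function(g) {
    k <- sample(1:3, 1)
    iso <- sprintf("%s.i%d", g, seq_len(k))
    do.call(rbind, lapply(iso, function(i) {
      nd <- sample(0:2, 1)
      if (nd == 0) return(NULL)
      data.frame(isoform_id = i, gene_id = g,
                 domain_id = sample(domains, nd),
                 exon_id = "E1", stringsAsFactors = FALSE)
    }))
  }))
  n_ppi <- n_genes * 2
  ppi <- data.frame(gene_a = sample(genes, n_ppi, TRUE),
                    gene_b = sample(genes, n_ppi, TRUE),
                    stringsAsFactors = FALSE)
  n_ddi <- length(domains) * 2
  ddi <- data.frame(domain_a = sample(domains, n_ddi, TRUE),
                    domain_b = sample(domains, n_ddi, TRUE),
                    stringsAsFactors = FALSE)
  isos <- unique(ann$isoform_id)
  mean_ifs <- data.frame(
    isoform_id = isos,
    gene_id = ann$gene_id[match(isos, ann$isoform_id)],
    mean_if_control = round(runif(length(isos)), 3),
    mean_if_treatment = round(runif(length(isos)), 3),
    stringsAsFactors = FALSE)
  list(annotation = ann, ppi = ppi, ddi = ddi, mean_ifs = mean_ifs)
}

# normalise package edges for comparison with the oracle
edges_for_comparison <- function(edges) {
  df <- data.frame(gene_a = pmin(edges$gene_a, edges$gene_b),
                   gene_b = pmax(edges$gene_a, edges$gene_b),
                   is_control = edges$is_control,
                   is_treatment = edges$is_treatment,
                   dis = edges$dis, stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

# --- brute-force PWM scan oracle ----------------------------------------

# Exhaustive enumeration over all 4^L words: integer score per word from
# the same integerised score matrix, p-value by direct summation of word
# probabilities, then a literal window-by-window rescan of the sequences.
brute_force_scan <- function(regions, p, p_cutoff = 0.001,
                             precision = 100) {
  sc <- spliceRewire:::pwm_int_scores(p, precision)
  L <- ncol(sc)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  w_score <- integer(nrow(words))
  w_prob <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    s <- 0L; pr <- 1
    for (j in seq_len(L)) {
      s <- s + sc[words[i, j], j]
      pr <- pr * p$bkg[words[i, j]]
    }
    w_score[i] <- s; w_prob[i] <- pr
  }
  pval_of <- function(s) sum(w_prob[w_score >= s])
  hits <- list(); h <- 0
  for (r in seq_len(nrow(regions))) {
    si <- spliceRewire:::seq_to_int(regions$seq[r])
    if (length(si) < L) next
    for (off in seq_len(length(si) - L + 1)) {
      win <- si[off:(off + L - 1)]
      s <- 0L
      for (j in seq_len(L)) {
        s <- s + if (win[j] == 5L) 0L else sc[win[j], j]
      }
      pv <- pval_of(s)
      if (pv < p_cutoff) {
        h <- h + 1
        hits[[h]] <- data.frame(
          motif_id = p$id, event_id = regions$event_id[r],
          region = regions$region[r], offset = off,
          p_value = pv, stringsAsFactors = FALSE)
      }
    }
  }
  if (h == 0) {
    return(data.frame(motif_id = character(), event_id = character(),
                      region = character(), offset = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run code under a temporary seed without disturbing the session RNG
with_seed_local <- function(seed, code) {
  spliceRewire:::with_seed(seed, code)
}
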