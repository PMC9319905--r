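# Run code under a derived seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults are
#' the study conditions the generator emulates: a two-condition knock-down
#' design with three biological replicates per condition, a planted usage /
#' inclusion shift of 0.3 on switch genes and regulated exon-skipping
#' events, log-normal multiplicative TPM noise, binomial junction counts
#' around ~100 reads per event, a planted interaction hub, motif planting
#' in up-regulated exon regions, and a tumor cohort of 774 samples (plus
#' 113 normals) with a planted Spearman correlation of 0.45, a planted
#' hazard ratio of 0.73 and a tumor-minus-normal dPSI of -0.33.
#'
#' @param seed master seed (integer).
#' @param n_genes number of simulated genes.
#' @param isoforms_per_gene integer range (min, max) of isoforms per gene.
#' @param n_replicates replicates per condition.
#' @param switch_fraction fraction of eligible genes with a planted switch;
#'   the same fraction of ES events is planted as regulated.
#' @param planted_dif usage/inclusion effect size in IF (and PSI) units.
#' @param tpm_dispersion sd of the log-normal multiplicative TPM noise.
#' @param read_depth_per_event mean total junction reads per event/sample.
#' @param n_events events per type; scalar or named vector over
#'   ES/MXE/A5SS/A3SS/RI.
#' @param regulated_types event types that receive planted regulation.
#' @param low_coverage_fraction fraction of events simulated at ~3 reads to
#'   exercise the read-support filter (never regulated).
#' @param hub_degree degree of the planted network hub.
#' @param n_decoy_ppi PPI edges planted without any supporting domain pair.
#' @param n_motifs number of PWMs in the simulated motif set.
#' @param motif_plant_rate target fold of motif occurrences in regulated
#'   exon regions over the background expectation (1 = no planting).
#' @param n_cohort_samples tumor cohort size.
#' @param n_normal normal-tissue cohort size.
#' @param planted_rho target Spearman correlation between the designated
#'   event's inclusion and the first regulator's expression.
#' @param planted_hr hazard ratio (high vs low inclusion) planted on the
#'   designated survival event.
#' @param planted_group_dpsi tumor-minus-normal inclusion difference
#'   planted on the designated group event.
#' @param censor_rate expected censoring proportion.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 300L,
                              isoforms_per_gene = c(1L, 4L),
                              n_replicates = 3L,
                              switch_fraction = 0.3,
                              planted_dif = 0.3,
                              tpm_dispersion = 0.15,
                              read_depth_per_event = 100,
                              n_events = c(ES = 150L, MXE = 30L,
                                           A5SS = 25L, A3SS = 25L,
                                           RI = 20L),
                              regulated_types = "ES",
                              low_coverage_fraction = 0.1,
                              hub_degree = 12L,
                              n_decoy_ppi = 25L,
                              n_motifs = 8L,
                              motif_plant_rate = 3,
                              n_cohort_samples = 774L,
                              n_normal = 113L,
                              planted_rho = 0.45,
                              planted_hr = 0.73,
                              planted_group_dpsi = -0.33,
                              censor_rate = 0.2) {
  if (length(n_events) == 1L && is.null(names(n_events))) {
    n_events <- c(ES = n_events, MXE = n_events, A5SS = n_events,
                  A3SS = n_events, RI = n_events)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              n_replicates = as.integer(n_replicates),
              switch_fraction = switch_fraction,
              planted_dif = planted_dif,
              tpm_dispersion = tpm_dispersion,
              read_depth_per_event = read_depth_per_event,
              n_events = n_events, regulated_types = regulated_types,
              low_coverage_fraction = low_coverage_fraction,
              hub_degree = as.integer(hub_degree),
              n_decoy_ppi = as.integer(n_decoy_ppi),
              n_motifs = as.integer(n_motifs),
              motif_plant_rate = motif_plant_rate,
              n_cohort_samples = as.integer(n_cohort_samples),
              n_normal = as.integer(n_normal),
              planted_rho = planted_rho, planted_hr = planted_hr,
              planted_group_dpsi = planted_group_dpsi,
              censor_rate = censor_rate)
  counts <- c(cfg$n_genes, cfg$n_replicates, cfg$n_events,
              cfg$n_cohort_samples, cfg$n_normal, cfg$n_motifs,
              cfg$hub_degree)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  props <- c(cfg$switch_fraction, cfg$low_coverage_fraction,
             cfg$censor_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$planted_dif <= 0 || cfg$planted_dif > 1) {
    stop("planted_dif must lie in (0, 1]")
  }
  if (cfg$planted_dif > 0.8) {
    stop("planted_dif above 0.8 is infeasible for the two-isoform switch",
         " construction")
  }
  if (abs(cfg$planted_rho) > 1) stop("planted_rho must lie in [-1, 1]")
  if (cfg$planted_hr <= 0) stop("planted_hr must be positive")
  if (cfg$isoforms_per_gene[1L] < 1L ||
      cfg$isoforms_per_gene[2L] < cfg$isoforms_per_gene[1L]) {
    stop("isoforms_per_gene must be an increasing range of counts >= 1")
  }
  if (cfg$switch_fraction > 0 && cfg$isoforms_per_gene[2L] < 2L) {
    stop("a planted switch needs genes with at least 2 isoforms")
  }
  structure(cfg, class = "simulation_config")
}

#' Plant an isoform switch on a pair of isoform fractions
#'
#' Shifts a designated isoform pair by `dif`: the first isoform of `pair`
#' gains `sign * dif`, the second loses it; other isoforms are untouched,
#' so the fractions still sum to 1.
#'
#' @param ifs numeric IF vector (sums to 1).
#' @param dif effect size in IF units.
#' @param pair indices of the (gaining, losing) isoforms.
#' @param sign +1 or -1.
#' @return shifted IF vector.
#' @export
plant_switch <- function(ifs, dif, pair = c(1L, 2L), sign = 1) {
  out <- ifs
  out[pair[1L]] <- out[pair[1L]] + sign * dif
  out[pair[2L]] <- out[pair[2L]] - sign * dif
  if (any(out < -1e-12) || any(out > 1 + 1e-12)) {
    stop("planted shift pushes an isoform fraction outside [0, 1]")
  }
  pmin(pmax(out, 0), 1)
}

#' Simulate a two-condition isoform expression table
#'
#' Per gene: an isoform count drawn from the configured range, a gene-level
#' TPM drawn above (90%) or below (10%) the 1-TPM filter, and Dirichlet
#' isoform fractions. A fraction `switch_fraction` of the well-expressed,
#' multi-isoform genes receives a planted switch: a designated isoform pair
#' shifted by exactly `planted_dif` between conditions (direction chosen at
#' random among the feasible ones). Sample TPMs are
#' `gene TPM x condition IF x log-normal noise`.
#'
#' @param config a [simulation_config()].
#' @return list with `expression` (an [expression_set()]) and `truth`
#'   (list with `isoforms` and `genes` data.frames).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 101L, {
    ng <- config$n_genes
    gene_id <- sprintf("G%04d", seq_len(ng))
    n_iso <- sample(seq(config$isoforms_per_gene[1L],
                        config$isoforms_per_gene[2L]), ng, replace = TRUE)
    lowly <- stats::runif(ng) < 0.1
    gene_tpm <- ifelse(lowly, stats::runif(ng, 0.1, 0.9),
                       exp(stats::runif(ng, log(2), log(200))))
    eligible <- which(!lowly & n_iso >= 2L)
    n_switch <- round(config$switch_fraction * length(eligible))
    switch_genes <- sort(eligible[sample.int(length(eligible), n_switch)])
    is_switch <- seq_len(ng) %in% switch_genes

    pair_total <- 0.9
    dif <- config$planted_dif
    iso_rows <- vector("list", ng)
    for (g in seq_len(ng)) {
      k <- n_iso[g]
      iso_id <- sprintf("%s.i%d", gene_id[g], seq_len(k))
      if (is_switch[g]) {
        pt <- if (k > 2L) pair_total else 1   # pair mass; rest shares 1-pt
        rest <- if (k > 2L) {
          w <- stats::rgamma(k - 2L, 1); (1 - pt) * w / sum(w)
        } else numeric(0)
        b_hi <- (pt - dif) / pt
        b <- stats::runif(1, min(0.05, b_hi / 2), b_hi)
        if1 <- c(b * pt, pt - b * pt, rest)
        sgn <- sample(c(1, -1), 1)
        # both pair members stay in [0, pair_total] for sign +1 on iso 1;
        # for sign -1 feasibility needs iso1 >= dif, so flip when needed
        if (sgn < 0 && (if1[1L] < dif || if1[2L] + dif > pt)) {
          sgn <- 1
        }
        if2 <- plant_switch(if1, dif, pair = c(1L, 2L), sign = sgn)
      } else {
        w <- stats::rgamma(k, 1)
        if1 <- w / sum(w)
        if2 <- if1
      }
      iso_rows[[g]] <- data.frame(
        isoform_id = iso_id, gene_id = gene_id[g],
        if_control = if1, if_treatment = if2,
        switch_pair = is_switch[g] & seq_len(k) <= 2L,
        stringsAsFactors = FALSE)
    }
    iso <- do.call(rbind, iso_rows)
    iso$dif_true <- iso$if_treatment - iso$if_control

    nr <- config$n_replicates
    condition <- factor(rep(c("control", "silencing"), each = nr),
                        levels = c("control", "silencing"))
    samples <- c(sprintf("ctrl_%d", seq_len(nr)),
                 sprintf("kd_%d", seq_len(nr)))
    gt <- gene_tpm[match(iso$gene_id, gene_id)]
    base <- cbind(matrix(gt * iso$if_control, nrow(iso), nr),
                  matrix(gt * iso$if_treatment, nrow(iso), nr))
    noise <- if (config$tpm_dispersion > 0) {
      matrix(stats::rlnorm(length(base),
                           meanlog = -config$tpm_dispersion^2 / 2,
                           sdlog = config$tpm_dispersion),
             nrow(base), ncol(base))
    } else 1
    tpm <- base * noise
    dimnames(tpm) <- list(iso$isoform_id, samples)

    truth <- list(
      isoforms = iso,
      genes = data.frame(gene_id = gene_id, n_isoforms = n_iso,
                         gene_tpm = gene_tpm, lowly_expressed = lowly,
                         switch = is_switch, stringsAsFactors = FALSE))
    list(expression = expression_set(tpm, iso$gene_id, condition),
         truth = truth)
  })
}

# synthetic gene-model layout: one event per 2000 bp block on chromosome
# "chrS"; returns an event_table plus block geometry used by the sequence
# simulator
layout_events <- function(n_total, gene_id_pool, types) {
  base <- 1000L + 2000L * (seq_len(n_total) - 1L)
  event_table(
    event_id = sprintf("%s_%04d", types, seq_len(n_total)),
    type = types,
    gene_id = gene_id_pool,
    chrom = "chrS",
    strand = rep_len(c("+", "-"), n_total),
    start = base + 600L, end = base + 750L,
    anchor_up_end = base + 100L, anchor_down_start = base + 1250L)
}

#' Simulate junction counts around planted true PSIs
#'
#' Creates the event annotation (a synthetic single-chromosome gene model)
#' and, per event and sample, draws a Poisson total read count around the
#' configured depth and a binomial inclusion count at the condition's true
#' PSI. Regulated events (planted only on the configured `regulated_types`,
#' by default ES, on switch genes) differ by exactly `planted_dif` between
#' conditions; a `low_coverage_fraction` of the unregulated events is
#' simulated at ~3 reads to exercise the read-support filter.
#'
#' @param config a [simulation_config()].
#' @param truth the truth list from [simulate_expression()].
#' @return list with `counts` (a [junction_counts()] with the event table
#'   attached), `events`, and the augmented `truth` (gains an `events`
#'   data.frame).
#' @export
simulate_junction_counts <- function(config, truth) {
  with_seed(config$seed + 202L, {
    ne <- config$n_events
    types <- rep(names(ne), ne)
    n_total <- sum(ne)
    genes <- truth$genes
    switch_genes <- genes$gene_id[genes$switch]
    ok_genes <- genes$gene_id[!genes$lowly_expressed]

    # regulated ES events sit on switch genes (an exon-skipping event is
    # the splicing change behind the switch); everything else is random
    gene_pool <- character(n_total)
    regulated <- logical(n_total)
    for (tp in names(ne)) {
      idx <- which(types == tp)
      if (tp %in% config$regulated_types && length(switch_genes) > 0) {
        n_reg <- min(round(config$switch_fraction * length(idx)),
                     length(switch_genes) * 3L)
        reg_idx <- idx[seq_len(n_reg)]
        regulated[reg_idx] <- TRUE
        gene_pool[reg_idx] <- rep_len(switch_genes, n_reg)
        gene_pool[setdiff(idx, reg_idx)] <-
          sample(ok_genes, length(idx) - n_reg, replace = TRUE)
      } else {
        gene_pool[idx] <- sample(genes$gene_id, length(idx),
                                 replace = TRUE)
      }
    }
    events <- layout_events(n_total, gene_pool, types)

    low <- !regulated &
      stats::runif(n_total) < config$low_coverage_fraction
    depth_mean <- ifelse(low, 3, config$read_depth_per_event)

    psi1 <- stats::runif(n_total, 0.05, 0.95)
    psi1[regulated] <- stats::runif(sum(regulated), 0.25, 0.75)
    psi2 <- psi1
    if (any(regulated)) {
      d <- config$planted_dif
      up_ok <- psi1 + d <= 0.98
      down_ok <- psi1 - d >= 0.02
      sgn <- ifelse(up_ok & down_ok,
                    sample(c(-1, 1), n_total, replace = TRUE),
                    ifelse(up_ok, 1, -1))
      psi2[regulated] <- psi1[regulated] + sgn[regulated] * d
    }

    nr <- config$n_replicates
    condition <- factor(rep(c("control", "silencing"), each = nr),
                        levels = c("control", "silencing"))
    samples <- c(sprintf("ctrl_%d", seq_len(nr)),
                 sprintf("kd_%d", seq_len(nr)))
    total <- matrix(stats::rpois(n_total * 2 * nr, depth_mean),
                    n_total, 2 * nr)
    truepsi <- cbind(matrix(psi1, n_total, nr), matrix(psi2, n_total, nr))
    inc <- matrix(stats::rbinom(length(total), total, truepsi),
                  n_total, 2 * nr)
    skp <- total - inc
    dimnames(inc) <- dimnames(skp) <- list(events$event_id, samples)

    truth$events <- data.frame(
      event_id = events$event_id, type = types, gene_id = gene_pool,
      psi_control = psi1, psi_treatment = psi2, dpsi_true = psi2 - psi1,
      regulated = regulated, low_coverage = low,
      stringsAsFactors = FALSE)
    list(counts = junction_counts(inc, skp, condition, events = events),
         events = events, truth = truth)
  })
}

#' Simulate a domain-annotated interactome with a planted hub
#'
#' Builds a domain annotation in which every switch gene carries a
#' gene-specific domain only on the isoform repressed by the treatment
#' (mirroring an exon-skipping event that removes the domain-coding exon),
#' while stable genes carry their domain on all isoforms. One switch gene
#' is the planted hub, wired to `hub_degree` stable partners through
#' supporting domain-domain pairs, so all its edges have a negative true
#' dIS; background edges (DDI-supported) and decoy PPI edges (no
#' supporting pair, absent from the built network by construction) are
#' added, plus one self-interaction on another switch gene. True
#' interaction scores are computed from the true isoform fractions with no
#' pseudocount.
#'
#' @param config a [simulation_config()].
#' @param truth truth list (needs `isoforms` and `genes`).
#' @return list with `annotation`, `ppi`, `ddi` data.frames and augmented
#'   `truth` (gains `edges`, `hub_gene`, `decoys`).
#' @export
simulate_interactome <- function(config, truth) {
  with_seed(config$seed + 303L, {
    genes <- truth$genes
    iso <- truth$isoforms
    gtpm <- stats::setNames(genes$gene_tpm, genes$gene_id)
    # network-bearing genes must keep their domain-carrying isoforms
    # above the 1-TPM median filter in both conditions; rank candidates
    # by that worst-case carrier TPM so the planted structure survives
    # quantification
    carrier_tpm_switch <- vapply(genes$gene_id[genes$switch],
                                 function(g) {
      rows <- iso[iso$gene_id == g & iso$switch_pair &
                    iso$dif_true < 0, , drop = FALSE]
      gtpm[g] * min(rows$if_control, rows$if_treatment)
    }, numeric(1))
    switch_genes <- names(sort(carrier_tpm_switch, decreasing = TRUE))
    carrier_tpm_stable <- vapply(
      genes$gene_id[!genes$switch & !genes$lowly_expressed],
      function(g) {
        gtpm[g] * max(iso$if_control[iso$gene_id == g])
      }, numeric(1))
    stable_genes <- names(carrier_tpm_stable)[carrier_tpm_stable > 3]
    if (length(switch_genes) < 2L ||
        length(stable_genes) < config$hub_degree + 2L) {
      stop("interactome simulation needs >= 2 switch genes and enough ",
           "well-expressed stable genes for the hub; increase n_genes ",
           "or switch_fraction")
    }
    domain_of <- function(g) paste0("D_", g)

    ann <- do.call(rbind, lapply(unique(iso$gene_id), function(g) {
      rows <- iso[iso$gene_id == g, ]
      if (genes$switch[genes$gene_id == g]) {
        # domain on the repressed pair member only (its exon is skipped
        # upon silencing)
        losing <- rows$isoform_id[rows$switch_pair &
                                    rows$dif_true < 0][1L]
        data.frame(isoform_id = losing, gene_id = g,
                   domain_id = domain_of(g),
                   exon_id = paste0(g, ":E3"), stringsAsFactors = FALSE)
      } else {
        data.frame(isoform_id = rows$isoform_id, gene_id = g,
                   domain_id = domain_of(g),
                   exon_id = paste0(g, ":E2"), stringsAsFactors = FALSE)
      }
    }))

    hub <- switch_genes[1L]
    partners <- sample(stable_genes, config$hub_degree)
    ppi <- data.frame(gene_a = hub, gene_b = partners,
                      stringsAsFactors = FALSE)
    ddi <- data.frame(domain_a = domain_of(hub),
                      domain_b = domain_of(partners),
                      stringsAsFactors = FALSE)

    # background DDI-supported edges among non-hub genes, capped in degree
    deg <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
    deg[partners] <- 1L
    cap <- max(config$hub_degree - 3L, 1L)
    n_bg <- max(round(length(stable_genes) / 3), 1L)
    pool <- c(setdiff(stable_genes, partners), switch_genes[-1L])
    for (i in seq_len(n_bg)) {
      pick <- sample(pool, 2L)
      if (pick[1L] == hub || pick[2L] == hub) next
      if (deg[pick[1L]] >= cap || deg[pick[2L]] >= cap) next
      ppi <- rbind(ppi, data.frame(gene_a = pick[1L], gene_b = pick[2L],
                                   stringsAsFactors = FALSE))
      ddi <- rbind(ddi, data.frame(domain_a = domain_of(pick[1L]),
                                   domain_b = domain_of(pick[2L]),
                                   stringsAsFactors = FALSE))
      deg[pick] <- deg[pick] + 1L
    }

    # one self-interaction on a switch gene (homodimer through the
    # domain encoded by the skipped exon)
    self_gene <- switch_genes[2L]
    ppi <- rbind(ppi, data.frame(gene_a = self_gene, gene_b = self_gene,
                                 stringsAsFactors = FALSE))
    ddi <- rbind(ddi, data.frame(domain_a = domain_of(self_gene),
                                 domain_b = domain_of(self_gene),
                                 stringsAsFactors = FALSE))

    # decoy PPI edges with no supporting domain pair
    ddi_keys <- pair_key(ddi$domain_a, ddi$domain_b)
    decoys <- list(); d <- 0L
    guard <- 0L
    while (d < config$n_decoy_ppi && guard < 50L * config$n_decoy_ppi) {
      guard <- guard + 1L
      pick <- sample(genes$gene_id, 2L)
      if (pair_key(domain_of(pick[1L]), domain_of(pick[2L])) %in%
            ddi_keys) next
      d <- d + 1L
      decoys[[d]] <- data.frame(gene_a = pick[1L], gene_b = pick[2L],
                                stringsAsFactors = FALSE)
    }
    decoys <- unique(do.call(rbind, decoys))
    ppi_all <- unique(rbind(ppi, decoys))

    # true IS/dIS from true IFs (isoforms carrying the gene's domain)
    if_sum <- function(g, cond) {
      carrying <- ann$isoform_id[ann$gene_id == g]
      sum(iso[[cond]][iso$isoform_id %in% carrying])
    }
    edge_truth <- do.call(rbind, lapply(seq_len(nrow(ppi)), function(i) {
      a <- ppi$gene_a[i]; b <- ppi$gene_b[i]
      if (a == b) {
        is1 <- if_sum(a, "if_control")^2
        is2 <- if_sum(a, "if_treatment")^2
      } else {
        is1 <- if_sum(a, "if_control") * if_sum(b, "if_control")
        is2 <- if_sum(a, "if_treatment") * if_sum(b, "if_treatment")
      }
      data.frame(gene_a = min(a, b), gene_b = max(a, b),
                 is_control_true = is1, is_treatment_true = is2,
                 dis_true = log2(is2 / is1), hub_edge = a == hub,
                 stringsAsFactors = FALSE)
    }))

    truth$edges <- edge_truth
    truth$hub_gene <- hub
    truth$self_gene <- self_gene
    truth$decoys <- decoys
    list(annotation = ann, ppi = ppi_all, ddi = unique(ddi),
         truth = truth)
  })
}

#' Simulate the genome sequence and motif set, with planted occurrences
#'
#' Generates an i.i.d. uniform-composition sequence for the synthetic
#' chromosome and a set of PWMs (position probability 0.85 for the
#' consensus base). Consensus occurrences of the first motif are inserted
#' into the alternative-exon regions of up-regulated events (`dPSI > 0`)
#' so that the expected hit frequency there is `motif_plant_rate` times
#' the background expectation at the p < 0.001 scan threshold; insertions
#' are reverse-complemented on minus-strand events so that
#' transcript-sense scanning recovers them.
#'
#' @param config a [simulation_config()].
#' @param truth truth list (needs `events`).
#' @return list with `genome` (named character vector, one chromosome),
#'   `pwms`, and augmented `truth` (gains `planted_motif`,
#'   `planted_sites`).
#' @export
simulate_sequences <- function(config, truth) {
  with_seed(config$seed + 404L, {
    n_total <- nrow(truth$events)
    chrlen <- 1000L + 2000L * n_total + 1000L
    chr <- paste(sample(c("A", "C", "G", "T"), chrlen, replace = TRUE),
                 collapse = "")

    extra <- if (config$n_motifs > 1L) {
      vapply(seq_len(config$n_motifs - 1L), function(i) {
        paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE),
              collapse = "")
      }, character(1))
    } else character(0)
    consensus <- c("TGGTGG", extra)
    pwms <- lapply(seq_along(consensus), function(k) {
      base <- strsplit(consensus[k], "")[[1L]]
      mat <- vapply(base, function(b) {
        col <- rep(0.05, 4); names(col) <- c("A", "C", "G", "T")
        col[b] <- 0.85
        col
      }, numeric(4))
      pwm(sprintf("M%02d", k),
          mat, name = if (k == 1L) "ESRP_like" else sprintf("RBP%02d", k))
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "id")

    # expected background hits per nt at the p<0.001 threshold
    null <- pwm_score_distribution(pwms[[1L]])
    ok <- null$p_value < 0.001
    p_hit <- if (any(ok)) max(null$p_value[ok]) else 0
    events <- truth$events
    up <- which(events$regulated & events$dpsi_true > 0)
    region_len <- 150L + 400L          # exon plus both flanks
    lambda <- max(config$motif_plant_rate - 1, 0) * p_hit * region_len
    motif <- consensus[1L]
    L <- nchar(motif)
    sites <- list(); s <- 0L
    for (i in up) {
      n_ins <- stats::rpois(1L, lambda)
      if (n_ins == 0L) next
      block <- 1000L + 2000L * (match(events$event_id[i],
                                      events$event_id) - 1L)
      lo <- block + 600L - 200L        # exon region with flanks, 0-based
      hi <- block + 750L + 200L
      pos <- sample(seq(lo, hi - L), n_ins)
      strand <- if (i %% 2L == 1L) "+" else "-"
      ins <- if (strand == "+") motif else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(motif)))
      for (p0 in pos) {
        substr(chr, p0 + 1L, p0 + L) <- ins
        s <- s + 1L
        sites[[s]] <- data.frame(event_id = events$event_id[i],
                                 region = "exon", genomic_start = p0,
                                 stringsAsFactors = FALSE)
      }
    }
    truth$planted_motif <- pwms[[1L]]$id
    truth$planted_sites <- if (s) do.call(rbind, sites) else
      data.frame(event_id = character(), region = character(),
                 genomic_start = integer(), stringsAsFactors = FALSE)
    list(genome = c(chrS = chr), pwms = pwms, truth = truth)
  })
}

#' Simulate a cohort with planted correlation, survival and group effects
#'
#' Generates a SpliceSeq-style PSI matrix over tumor and normal samples,
#' regulator/pathway gene expression, and a clinical table. Three
#' designated events carry the planted effects: a Gaussian-copula
#' correlation of `planted_rho` between inclusion and the first
#' regulator's expression; exponential survival with the hazard multiplied
#' by `planted_hr` for samples above the median inclusion; and a
#' tumor-minus-normal inclusion shift of `planted_group_dpsi`. Two
#' anticorrelated ten-gene pathway modules are planted in the expression
#' table.
#'
#' @param config a [simulation_config()].
#' @param truth truth list (needs `events` for coordinate-matched cohort
#'   events).
#' @return list with `psi` (event x sample), `expression`
#'   (gene x sample FPKM), `clinical`, `events` (cohort [event_table()]),
#'   `gene_sets`, and augmented `truth` (gains `cohort`).
#' @export
simulate_cohort <- function(config, truth) {
  with_seed(config$seed + 505L, {
    nt <- config$n_cohort_samples; nn <- config$n_normal
    n <- nt + nn
    samples <- c(sprintf("TUMOR_%04d", seq_len(nt)),
                 sprintf("NORMAL_%03d", seq_len(nn)))
    group <- factor(rep(c("tumor", "normal"), c(nt, nn)),
                    levels = c("tumor", "normal"))

    # cohort events mirror the first ES events, coordinates jittered but
    # overlapping
    es <- truth$events[truth$events$type == "ES", ]
    n_ev <- min(40L, nrow(es))
    src <- es[seq_len(n_ev), ]
    pe <- truth$events
    ids <- sprintf("SS_%03d", seq_len(n_ev))
    # same blocks as the source events, jittered by <= 20 bp (keeps the
    # reciprocal overlap needed by the event matcher)
    blk <- 1000L + 2000L * (match(src$event_id, pe$event_id) - 1L)
    jit <- sample(-20:20, n_ev, replace = TRUE)
    src_tab <- event_table(
      event_id = ids, type = "ES", gene_id = src$gene_id, chrom = "chrS",
      strand = rep_len(c("+", "-"), n_ev),
      start = blk + 600L + jit, end = blk + 750L + jit,
      anchor_up_end = blk + 100L, anchor_down_start = blk + 1350L)

    # regulator expression and copula-linked designated event
    r <- 2 * sin(pi * config$planted_rho / 6)
    z_reg <- stats::rnorm(n)
    z_psi <- r * z_reg + sqrt(1 - r^2) * stats::rnorm(n)
    reg1 <- stats::qlnorm(stats::pnorm(z_reg), log(20), 0.6)
    reg2 <- stats::qlnorm(stats::pnorm(0.8 * z_reg +
                                         sqrt(1 - 0.64) * stats::rnorm(n)),
                          log(12), 0.6)
    psi <- matrix(stats::rbeta(n_ev * n, 4, 4), n_ev, n,
                  dimnames = list(ids, samples))
    ev_rho <- ids[1L]
    psi[ev_rho, ] <- 0.1 + 0.8 * stats::qbeta(stats::pnorm(z_psi), 4, 4)

    # tumor/normal group effect on a second designated event
    ev_group <- ids[2L]
    mu <- ifelse(group == "tumor", 0.3, 0.3 - config$planted_group_dpsi)
    psi[ev_group, ] <- pmin(pmax(stats::rnorm(n, mu, 0.1), 0.01), 0.99)

    # survival driven by a third designated event (tumor samples)
    ev_surv <- ids[3L]
    base_rate <- log(2) / 36
    y <- psi[ev_surv, seq_len(nt)]
    high <- y > stats::median(y)
    rate <- base_rate * ifelse(high, config$planted_hr, 1)
    t_event <- stats::rexp(nt, rate)
    c_rate <- base_rate * config$censor_rate /
      max(1 - config$censor_rate, 1e-6)
    t_cens <- stats::rexp(nt, c_rate)
    os_time <- pmin(t_event, t_cens)
    os_status <- as.integer(t_event <= t_cens)
    dfs_event <- stats::rexp(nt, base_rate * 1.2)
    dfs_cens <- stats::rexp(nt, c_rate)

    # a sprinkle of missing PSIs away from the designated events
    miss <- cbind(sample(seq(4L, n_ev), 200L, replace = TRUE),
                  sample(n, 200L, replace = TRUE))
    psi[miss] <- NA_real_

    # two anticorrelated pathway modules
    sA <- stats::rnorm(n)
    sB <- -0.8 * sA + sqrt(1 - 0.64) * stats::rnorm(n)
    mkgenes <- function(score, tag) {
      t(vapply(seq_len(10L), function(j) {
        exp(log(10) + 0.8 * score + stats::rnorm(n, 0, 0.5))
      }, numeric(n)))
    }
    exprA <- mkgenes(sA, "A"); exprB <- mkgenes(sB, "B")
    rownames(exprA) <- sprintf("PWA_%02d", 1:10)
    rownames(exprB) <- sprintf("PWB_%02d", 1:10)
    expression <- rbind(REG1 = reg1, REG2 = reg2, exprA, exprB)
    colnames(expression) <- samples
    gene_sets <- list(pathway_A = rownames(exprA),
                      pathway_B = rownames(exprB))

    fga <- stats::pnorm(0.5 * z_reg + sqrt(0.75) * stats::rnorm(n)) * 0.8
    clinical <- data.frame(
      sample_id = samples, group = group,
      subtype = factor(sample(c("LumA", "LumB", "Her2"), n, TRUE,
                              prob = c(0.5, 0.35, 0.15))),
      menopause = factor(sample(c("pre", "post"), n, TRUE)),
      age = round(stats::rnorm(n, 60, 10)),
      fraction_genome_altered = fga,
      OS_time = c(os_time, rep(NA_real_, nn)),
      OS_status = c(os_status, rep(NA_integer_, nn)),
      DFS_time = c(pmin(dfs_event, dfs_cens), rep(NA_real_, nn)),
      DFS_status = c(as.integer(dfs_event <= dfs_cens),
                     rep(NA_integer_, nn)),
      stringsAsFactors = FALSE)

    truth$cohort <- list(
      event_rho = ev_rho, event_group = ev_group, event_surv = ev_surv,
      planted_rho = config$planted_rho,
      planted_hr = config$planted_hr,
      planted_group_dpsi = config$planted_group_dpsi,
      regulators = c("REG1", "REG2"))
    list(psi = psi, expression = expression, clinical = clinical,
         events = src_tab, gene_sets = gene_sets, truth = truth)
  })
}

#' Run the whole generator
#'
#' Convenience wrapper executing every simulation stage in dependency
#' order with seeds derived from the master seed; identical configurations
#' give identical output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `expression`, `counts`, `events`,
#'   `annotation`, `ppi`, `ddi`, `genome`, `pwms`, `cohort` (psi,
#'   expression, clinical, events, gene_sets) and the merged `truth`.
#' @export
simulate_all <- function(config) {
  ex <- simulate_expression(config)
  jc <- simulate_junction_counts(config, ex$truth)
  it <- simulate_interactome(config, jc$truth)
  sq <- simulate_sequences(config, it$truth)
  co <- simulate_cohort(config, sq$truth)
  list(expression = ex$expression, counts = jc$counts,
       events = jc$events, annotation = it$annotation, ppi = it$ppi,
       ddi = it$ddi, genome = sq$genome, pwms = sq$pwms,
       cohort = co[c("psi", "expression", "clinical", "events",
                     "gene_sets")],
       truth = co$truth)
}
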