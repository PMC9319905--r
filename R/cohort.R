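#' Match pipeline events to cohort events by coordinate overlap
#'
#' Two events match when they have the same type, chromosome and strand and
#' their alternative regions overlap by at least 1 bp. The assignment is
#' one-to-one by maximal overlap; ties are broken by the smaller distance
#' between region midpoints, then lexicographically by the id pair.
#' Coordinates must already be on a common assembly.
#'
#' @param query,subject event tables ([event_table()] or data.frames with
#'   `event_id`, `type`, `chrom`, `strand`, `start`, `end`).
#' @return `data.frame` with `query_id`, `subject_id`, `overlap` (bp).
#' @export
match_events <- function(query, subject) {
  cand <- merge(
    data.frame(query_id = query$event_id, type = query$type,
               chrom = query$chrom, strand = query$strand,
               qs = query$start, qe = query$end, stringsAsFactors = FALSE),
    data.frame(subject_id = subject$event_id, type = subject$type,
               chrom = subject$chrom, strand = subject$strand,
               ss = subject$start, se = subject$end,
               stringsAsFactors = FALSE),
    by = c("type", "chrom", "strand"))
  if (nrow(cand) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      overlap = integer(), stringsAsFactors = FALSE))
  }
  cand$overlap <- pmin(cand$qe, cand$se) - pmax(cand$qs, cand$ss)
  cand <- cand[cand$overlap >= 1L, , drop = FALSE]
  cand$dist <- abs((cand$qs + cand$qe) - (cand$ss + cand$se)) / 2
  cand <- cand[order(-cand$overlap, cand$dist, cand$query_id,
                     cand$subject_id), , drop = FALSE]
  used_q <- used_s <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$query_id[i] %in% used_q) &&
        !(cand$subject_id[i] %in% used_s)) {
      keep[i] <- TRUE
      used_q <- c(used_q, cand$query_id[i])
      used_s <- c(used_s, cand$subject_id[i])
    }
  }
  out <- cand[keep, c("query_id", "subject_id", "overlap")]
  rownames(out) <- NULL
  out
}

#' Correlate cohort event inclusion with gene expression
#'
#' Tie-corrected Spearman correlation between each event's PSI and each
#' regulator gene's expression, on pairwise-complete observations;
#' Benjamini-Hochberg adjustment across events, separately per gene.
#' Events with fewer than `min_pairs` complete pairs, or a constant PSI or
#' expression vector, are reported with missing statistics.
#'
#' @param psi event x sample PSI matrix (rownames = event ids).
#' @param expression gene x sample expression matrix (FPKM or similar),
#'   sample columns matching `psi`.
#' @param genes regulator gene ids (rows of `expression`).
#' @param min_pairs minimum complete pairs, default 10.
#' @return `data.frame`: `event_id`, `regulator`, `n`, `rho`, `p_value`,
#'   `q_value`.
#' @export
correlate_psi_expression <- function(psi, expression, genes,
                                     min_pairs = 10) {
  stopifnot(all(genes %in% rownames(expression)),
            identical(colnames(psi), colnames(expression)))
  out <- list(); k <- 0L
  for (g in genes) {
    x <- expression[g, ]
    res <- lapply(rownames(psi), function(ev) {
      y <- psi[ev, ]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < min_pairs || length(unique(y[ok])) < 2L ||
          length(unique(x[ok])) < 2L) {
        return(data.frame(event_id = ev, regulator = g, n = n,
                          rho = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      data.frame(event_id = ev, regulator = g, n = n,
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q_value <- NA_real_
    ok <- !is.na(res$p_value)
    res$q_value[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
    k <- k + 1L; out[[k]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# median stratification: high = strictly above the median, low = the rest
median_strata <- function(x) {
  m <- stats::median(x, na.rm = TRUE)
  factor(ifelse(x > m, "high", "low"), levels = c("low", "high"))
}

#' Compare event inclusion between expression strata
#'
#' Samples are split into highly and lowly expressed groups at the median
#' expression of `gene` (high = strictly above the median); each event's
#' PSI distributions are compared between the strata with a two-sided
#' Wilcoxon rank-sum test, with the effect reported as
#' `mean PSI(high) - mean PSI(low)`; BH adjustment across events.
#'
#' @param psi event x sample PSI matrix.
#' @param expression gene x sample expression matrix.
#' @param gene stratifying gene id.
#' @param min_per_stratum minimum non-missing PSIs per stratum (default 2);
#'   below it the event is reported untested with a reason.
#' @return `data.frame`: `event_id`, `n_high`, `n_low`, `delta_psi`,
#'   `p_value`, `q_value`, `skipped`.
#' @export
stratify_and_test <- function(psi, expression, gene, min_per_stratum = 2) {
  strata <- median_strata(expression[gene, ])
  res <- lapply(rownames(psi), function(ev) {
    y <- psi[ev, ]
    hi <- y[strata == "high" & !is.na(y)]
    lo <- y[strata == "low" & !is.na(y)]
    if (length(hi) < min_per_stratum || length(lo) < min_per_stratum) {
      return(data.frame(event_id = ev, n_high = length(hi),
                        n_low = length(lo), delta_psi = NA_real_,
                        p_value = NA_real_, skipped = "too few samples",
                        stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(hi, lo)$p.value)
    data.frame(event_id = ev, n_high = length(hi), n_low = length(lo),
               delta_psi = mean(hi) - mean(lo), p_value = p,
               skipped = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  rownames(out) <- NULL
  out
}

#' Associate a sample-level value with clinical covariates
#'
#' Continuous covariates are tested by Spearman correlation of the value
#' itself; categorical covariates by a Kruskal-Wallis test on the value,
#' and additionally by a chi-square test of the covariate against the
#' high/low median stratification of the value (flagged unreliable when
#' any expected cell count is below 5; Yates correction off). Covariates
#' with a single observed level are skipped with a reason.
#'
#' @param values named numeric vector (e.g. a gene's expression), names =
#'   sample ids.
#' @param clinical `data.frame` with rownames (or a `sample_id` column)
#'   matching `values`; numeric columns are treated as continuous, factors
#'   and characters as categorical.
#' @param covariates columns to test (default: all except `sample_id`).
#' @return `data.frame`: `covariate`, `method`, `estimate`, `statistic`,
#'   `p_value`, `unreliable`, `skipped`.
#' @export
test_clinical <- function(values, clinical, covariates = NULL) {
  if (!is.null(clinical$sample_id)) rownames(clinical) <- clinical$sample_id
  clinical <- clinical[names(values), , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- setdiff(names(clinical), "sample_id")
  }
  res <- list(); k <- 0L
  strata <- median_strata(values)
  for (cv in covariates) {
    x <- clinical[[cv]]
    ok <- !is.na(x) & !is.na(values)
    if (is.numeric(x)) {
      if (length(unique(x[ok])) < 2L) {
        k <- k + 1L
        res[[k]] <- data.frame(covariate = cv, method = "spearman",
                               estimate = NA_real_, statistic = NA_real_,
                               p_value = NA_real_, unreliable = FALSE,
                               skipped = "constant covariate",
                               stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(values[ok], x[ok],
                                             method = "spearman",
                                             exact = FALSE))
      k <- k + 1L
      res[[k]] <- data.frame(covariate = cv, method = "spearman",
                             estimate = unname(ct$estimate),
                             statistic = unname(ct$statistic),
                             p_value = ct$p.value, unreliable = FALSE,
                             skipped = NA_character_,
                             stringsAsFactors = FALSE)
    } else {
      f <- factor(x[ok])
      if (nlevels(droplevels(f)) < 2L) {
        k <- k + 1L
        res[[k]] <- data.frame(covariate = cv, method = "kruskal-wallis",
                               estimate = NA_real_, statistic = NA_real_,
                               p_value = NA_real_, unreliable = FALSE,
                               skipped = "single level",
                               stringsAsFactors = FALSE)
        next
      }
      kw <- stats::kruskal.test(values[ok], droplevels(f))
      k <- k + 1L
      res[[k]] <- data.frame(covariate = cv, method = "kruskal-wallis",
                             estimate = NA_real_,
                             statistic = unname(kw$statistic),
                             p_value = kw$p.value, unreliable = FALSE,
                             skipped = NA_character_,
                             stringsAsFactors = FALSE)
      tab <- table(droplevels(f), droplevels(strata[ok]))
      if (all(dim(tab) >= 2L)) {
        cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        k <- k + 1L
        res[[k]] <- data.frame(covariate = cv, method = "chi-square",
                               estimate = NA_real_,
                               statistic = unname(cs$statistic),
                               p_value = cs$p.value,
                               unreliable = any(cs$expected < 5),
                               skipped = NA_character_,
                               stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Survival association of event inclusion
#'
#' For each event, samples are stratified at the median PSI (high =
#' strictly above); the two strata are compared with a log-rank test and a
#' hazard ratio (high vs low) from a two-group Cox proportional-hazards
#' fit; BH adjustment of log-rank p-values across events. Events whose
#' samples all fall in one stratum are flagged unestimable.
#'
#' @param psi event x sample PSI matrix.
#' @param clinical `data.frame` with `sample_id` (or rownames), and the
#'   endpoint columns `<endpoint>_time` / `<endpoint>_status` (e.g.
#'   `OS_time`, `OS_status`; status 1 = event).
#' @param endpoint `"OS"` (default) or `"DFS"`.
#' @return `data.frame`: `event_id`, `n`, `hr`, `logrank_p`, `q_value`,
#'   `skipped`.
#' @export
survival_association <- function(psi, clinical, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  if (!is.null(clinical$sample_id)) rownames(clinical) <- clinical$sample_id
  clinical <- clinical[colnames(psi), , drop = FALSE]
  time <- clinical[[paste0(endpoint, "_time")]]
  status <- clinical[[paste0(endpoint, "_status")]]
  if (is.null(time) || is.null(status)) {
    stop("clinical table lacks ", endpoint, "_time/", endpoint, "_status")
  }
  res <- lapply(rownames(psi), function(ev) {
    y <- psi[ev, ]
    ok <- !is.na(y) & !is.na(time) & !is.na(status)
    strata <- median_strata(y[ok])
    if (nlevels(droplevels(strata)) < 2L) {
      return(data.frame(event_id = ev, n = sum(ok), hr = NA_real_,
                        logrank_p = NA_real_, skipped = "one stratum",
                        stringsAsFactors = FALSE))
    }
    s <- survival::Surv(time[ok], status[ok])
    sd <- survival::survdiff(s ~ strata)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    fit <- survival::coxph(s ~ strata)
    data.frame(event_id = ev, n = sum(ok),
               hr = unname(exp(stats::coef(fit))), logrank_p = p,
               skipped = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$logrank_p)
  out$q_value <- NA_real_
  out$q_value[ok] <- stats::p.adjust(out$logrank_p[ok], method = "BH")
  rownames(out) <- NULL
  out
}

#' Pathway activity scores from gene-set expression
#'
#' A transparent gene-set activity score: per gene, expression is
#' log2(x + 1)-transformed and z-scored across samples; the pathway score
#' is the mean over the set's genes, re-standardised so every pathway score
#' has mean 0 and sd 1 across samples.
#'
#' @param expression gene x sample matrix (FPKM or similar).
#' @param gene_sets named list of gene-id vectors.
#' @return pathway x sample score matrix.
#' @export
pathway_scores <- function(expression, gene_sets) {
  lg <- log2(expression + 1)
  z <- t(scale(t(lg)))
  out <- t(vapply(gene_sets, function(gs) {
    gs <- intersect(gs, rownames(z))
    if (length(gs) == 0L) return(rep(NA_real_, ncol(z)))
    s <- colMeans(z[gs, , drop = FALSE])
    as.numeric(scale(s))
  }, numeric(ncol(expression))))
  colnames(out) <- colnames(expression)
  out
}

#' Pathway-guided correlation of event inclusion
#'
#' Correlates each event's PSI with each pathway activity score (Spearman,
#' pairwise-complete), clusters pathways by average-linkage hierarchical
#' clustering on the 1 - rho distance between pathway score vectors, and
#' reports which correlations exceed `r_report` in absolute value.
#'
#' @param psi event x sample PSI matrix.
#' @param expression gene x sample expression matrix.
#' @param gene_sets named list of pathway gene sets.
#' @param r_report reporting threshold on |rho|, default 0.3.
#' @param k number of pathway clusters to cut (default 2).
#' @return list: `correlations` (event x pathway rho matrix), `reported`
#'   (long `data.frame` of |rho| > `r_report`), `scores`, `hclust`,
#'   `clusters`.
#' @export
pathway_correlation <- function(psi, expression, gene_sets,
                                r_report = 0.3, k = 2) {
  sc <- pathway_scores(expression, gene_sets)
  rho <- matrix(NA_real_, nrow(psi), nrow(sc),
                dimnames = list(rownames(psi), rownames(sc)))
  for (ev in rownames(psi)) for (pw in rownames(sc)) {
    ok <- !is.na(psi[ev, ]) & !is.na(sc[pw, ])
    if (sum(ok) >= 3L && length(unique(psi[ev, ok])) > 1L) {
      rho[ev, pw] <- suppressWarnings(
        stats::cor(psi[ev, ok], sc[pw, ok], method = "spearman"))
    }
  }
  pw_cor <- suppressWarnings(stats::cor(t(sc), method = "spearman"))
  hc <- stats::hclust(stats::as.dist(1 - pw_cor), method = "average")
  clusters <- stats::cutree(hc, k = min(k, nrow(sc)))
  idx <- which(abs(rho) > r_report, arr.ind = TRUE)
  reported <- data.frame(
    event_id = rownames(rho)[idx[, 1L]],
    pathway = colnames(rho)[idx[, 2L]],
    rho = rho[idx], stringsAsFactors = FALSE)
  list(correlations = rho, reported = reported, scores = sc,
       hclust = hc, clusters = clusters)
}

#' Compare event inclusion between two sample groups
#'
#' Per event: `dPSI = mean PSI(group level 1) - mean PSI(group level 2)`
#' (e.g. tumor minus normal), two-sided Wilcoxon rank-sum p, BH q. Events
#' with all-missing PSI in a group are skipped.
#'
#' @param psi event x sample PSI matrix.
#' @param groups two-level factor over samples.
#' @return `data.frame`: `event_id`, `dpsi`, `p_value`, `q_value`,
#'   `skipped`.
#' @export
compare_groups <- function(psi, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(psi))
  g1 <- groups == levels(groups)[1L]
  res <- lapply(rownames(psi), function(ev) {
    a <- psi[ev, g1]; b <- psi[ev, !g1]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) {
      return(data.frame(event_id = ev, dpsi = NA_real_,
                        p_value = NA_real_, skipped = "empty group",
                        stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(event_id = ev, dpsi = mean(a) - mean(b), p_value = p,
               skipped = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  rownames(out) <- NULL
  out
}
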