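#' Compute isoform fractions (IF) with expression filters
#'
#' The isoform fraction of isoform i in sample s is
#' `IF = TPM_iso / TPM_gene`, with the gene TPM taken as the sum of its
#' isoforms' TPM in that sample. Two filters mirror standard isoform-switch
#' practice: genes whose mean TPM is below `min_gene_tpm` (default 1 TPM) in
#' either condition are dropped entirely, and isoforms whose mean IF is
#' below `min_if` (default 0.01) in a condition are flagged as not retained
#' in that condition (dropped altogether when retained in neither). Samples
#' where the gene TPM is exactly 0 yield a missing IF (`NA`), never 0, and
#' are excluded from condition means.
#'
#' @param es an [expression_set()].
#' @param min_gene_tpm gene-level expression cutoff in TPM (default 1).
#' @param min_if minimum condition-mean isoform fraction (default 0.01).
#' @return An object of class `if_table`: list with the per-sample IF
#'   matrix (`ifs`, retained isoforms only), `gene_id`, `condition`, and a
#'   `summary` data.frame with per-condition mean IFs and retention flags.
#' @export
compute_isoform_fractions <- function(es, min_gene_tpm = 1, min_if = 0.01) {
  stopifnot(inherits(es, "expression_set"))
  idx <- condition_index(es$condition)
  if (length(idx$control) < 1L || length(idx$treatment) < 1L) {
    stop("at least one sample per condition is required")
  }
  gene_tpm <- rowsum(es$tpm, es$gene_id)            # gene x sample
  gmean1 <- rowMeans(gene_tpm[, idx$control, drop = FALSE])
  gmean2 <- rowMeans(gene_tpm[, idx$treatment, drop = FALSE])
  keep_gene <- rownames(gene_tpm)[gmean1 >= min_gene_tpm &
                                  gmean2 >= min_gene_tpm]
  sel <- es$gene_id %in% keep_gene
  if (!any(sel)) {
    stop("no gene passes the ", min_gene_tpm, "-TPM expression filter")
  }
  tpm <- es$tpm[sel, , drop = FALSE]
  gid <- es$gene_id[sel]
  denom <- gene_tpm[gid, , drop = FALSE]
  ifs <- tpm / denom
  ifs[denom == 0] <- NA_real_                       # missing, not zero

  mean1 <- rowMeans(ifs[, idx$control, drop = FALSE], na.rm = TRUE)
  mean2 <- rowMeans(ifs[, idx$treatment, drop = FALSE], na.rm = TRUE)
  mean1[is.nan(mean1)] <- NA_real_
  mean2[is.nan(mean2)] <- NA_real_
  ret1 <- !is.na(mean1) & mean1 >= min_if
  ret2 <- !is.na(mean2) & mean2 >= min_if
  keep <- ret1 | ret2

  summary <- data.frame(
    isoform_id = rownames(tpm)[keep], gene_id = gid[keep],
    mean_if_control = mean1[keep], mean_if_treatment = mean2[keep],
    retained_control = ret1[keep], retained_treatment = ret2[keep],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(
    list(ifs = ifs[keep, , drop = FALSE], gene_id = gid[keep],
         condition = es$condition, summary = summary,
         min_gene_tpm = min_gene_tpm, min_if = min_if,
         n_genes_dropped = length(unique(es$gene_id)) - length(keep_gene)),
    class = "if_table"
  )
}

#' @export
print.if_table <- function(x, ...) {
  cat(sprintf("if_table: %d isoforms (%d genes); %d genes below %g TPM\n",
              nrow(x$ifs), length(unique(x$gene_id)), x$n_genes_dropped,
              x$min_gene_tpm))
  invisible(x)
}

# Replicate-aware two-sided test used for both dIF and dPSI calls: a
# pooled-variance t-test on per-replicate values. With equal replicate
# numbers per condition and a shared noise model the pooled test is exact
# under the null and keeps its 2(n-1) degrees of freedom, which matters at
# n = 3 (the Satterthwaite approximation can drop to ~2 df and caps
# attainable p-values). When both groups are numerically constant the t
# statistic is undefined; the fallback is a strict separation rule: p = 0
# when every control value differs from every treatment value (here: the
# two constants differ), p = 1 otherwise. Groups with < 2 usable
# replicates give NA.
replicate_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx <= .Machine$double.eps^2 && vy <= .Machine$double.eps^2) {
    return(if (abs(mean(x) - mean(y)) > 0) 0 else 1)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Call isoform switches from an IF table
#'
#' For every retained isoform the usage difference
#' `dIF = mean IF(treatment) - mean IF(control)` is computed; a condition in
#' which the isoform fell below the IF-retention cutoff contributes a mean
#' of 0 (flagged in `partial`). Each isoform is tested with a two-sided
#' pooled-variance t-test on the per-replicate IFs (strict-separation
#' fallback for zero-variance groups), p-values are BH adjusted across
#' all tested isoforms, and an isoform is a significant switch when
#' `|dIF| > dif_cutoff` (strictly, by default) and `q <= q_cutoff`.
#'
#' @param ift an `if_table` from [compute_isoform_fractions()].
#' @param dif_cutoff minimum absolute usage change, default 0.1.
#' @param q_cutoff BH-adjusted p-value cutoff, default 0.05.
#' @param dif_strict if `TRUE` (default) the effect filter is `|dIF| >
#'   dif_cutoff`, otherwise `>=`.
#' @return `data.frame` with one row per isoform: condition means, `dif`,
#'   `p_value`, `q_value`, `partial` (isoform retained in only one
#'   condition) and `significant`.
#' @export
call_isoform_switches <- function(ift, dif_cutoff = 0.1, q_cutoff = 0.05,
                                  dif_strict = TRUE) {
  stopifnot(inherits(ift, "if_table"))
  idx <- condition_index(ift$condition)
  s <- ift$summary
  m1 <- ifelse(s$retained_control, s$mean_if_control, 0)
  m2 <- ifelse(s$retained_treatment, s$mean_if_treatment, 0)
  dif <- m2 - m1
  p <- vapply(seq_len(nrow(ift$ifs)), function(i) {
    replicate_t_test(ift$ifs[i, idx$control], ift$ifs[i, idx$treatment])
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  pass_dif <- if (dif_strict) abs(dif) > dif_cutoff else abs(dif) >= dif_cutoff
  out <- data.frame(
    isoform_id = s$isoform_id, gene_id = s$gene_id,
    mean_if_control = m1, mean_if_treatment = m2, dif = dif,
    p_value = p, q_value = q,
    partial = xor(s$retained_control, s$retained_treatment),
    significant = pass_dif & !is.na(q) & q <= q_cutoff,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- list(dif = dif_cutoff, q = q_cutoff,
                               dif_strict = dif_strict)
  out
}

#' Compute per-sample PSI from junction counts
#'
#' The percent-spliced-in value of an event in a sample is the ratio of the
#' (length-normalised) paths supporting inclusion over all paths:
#' `PSI = (I/eL_I) / (I/eL_I + S/eL_S)`. Effective path lengths default to
#' equal, i.e. the raw ratio `I / (I + S)`. Samples with `I + S = 0` yield a
#' missing PSI.
#'
#' @param jc a [junction_counts()] object.
#' @param eff_len optional two-column matrix or data.frame (`inc`, `skp`)
#'   of per-event effective lengths, rownames = event ids.
#' @return Object of class `psi_set`: the PSI matrix plus the counts.
#' @export
compute_psi <- function(jc, eff_len = NULL) {
  stopifnot(inherits(jc, "junction_counts"))
  li <- ls <- rep(1, nrow(jc$inclusion))
  if (!is.null(eff_len)) {
    el <- as.matrix(eff_len)
    if (any(el <= 0)) stop("effective lengths must be positive")
    li <- el[jc$event_id, 1L]; ls <- el[jc$event_id, 2L]
  }
  inc <- jc$inclusion / li
  skp <- jc$skipping / ls
  psi <- inc / (inc + skp)
  psi[jc$inclusion + jc$skipping == 0] <- NA_real_
  structure(list(psi = psi, counts = jc, condition = jc$condition,
                 events = jc$events),
            class = "psi_set")
}

#' @export
print.psi_set <- function(x, ...) {
  cat(sprintf("psi_set: %d events x %d samples (%.1f%% informative)\n",
              nrow(x$psi), ncol(x$psi), 100 * mean(!is.na(x$psi))))
  invisible(x)
}

#' Call differentially spliced events
#'
#' Applies the expression prefilter (an event is `expressed` when its
#' supporting reads `I + S` reach `min_reads` in at least `min_samples`
#' samples of each condition), computes
#' `dPSI = mean PSI(treatment) - mean PSI(control)` over informative
#' samples, tests each expressed event with a two-sided pooled t-test on
#' per-sample PSIs (strict-separation fallback for zero-variance groups),
#' adjusts with Benjamini-Hochberg across all tested events, and flags an
#' event significant when it is expressed, `|dPSI| >= dpsi_cutoff` (
#' inclusive by default) and `q <= q_cutoff`.
#'
#' @param ps a `psi_set` from [compute_psi()].
#' @param min_reads,min_samples read-support filter, defaults 10 reads in
#'   at least 2 samples per condition.
#' @param dpsi_cutoff,q_cutoff effect and significance cutoffs (0.1, 0.05).
#' @param dpsi_strict if `TRUE` the effect filter is strict `>`; default
#'   `FALSE` (inclusive `>=`).
#' @return `data.frame`, one row per event, with type (when the event table
#'   is attached), condition-mean PSIs, `dpsi`, `p_value`, `q_value`,
#'   `expressed` and `significant`; events with no informative sample at
#'   all are dropped and listed in `attr(, "dropped")`.
#' @export
call_differential_events <- function(ps, min_reads = 10, min_samples = 2,
                                     dpsi_cutoff = 0.1, q_cutoff = 0.05,
                                     dpsi_strict = FALSE) {
  stopifnot(inherits(ps, "psi_set"))
  idx <- condition_index(ps$condition)
  total <- ps$counts$inclusion + ps$counts$skipping
  n_ok1 <- rowSums(total[, idx$control, drop = FALSE] >= min_reads)
  n_ok2 <- rowSums(total[, idx$treatment, drop = FALSE] >= min_reads)
  expressed <- n_ok1 >= min_samples & n_ok2 >= min_samples

  informative <- rowSums(!is.na(ps$psi)) > 0
  dropped <- rownames(ps$psi)[!informative]

  psi <- ps$psi[informative, , drop = FALSE]
  expressed <- expressed[informative]
  m1 <- rowMeans(psi[, idx$control, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(psi[, idx$treatment, drop = FALSE], na.rm = TRUE)
  m1[is.nan(m1)] <- NA_real_; m2[is.nan(m2)] <- NA_real_
  dpsi <- m2 - m1
  p <- rep(NA_real_, nrow(psi))
  p[expressed] <- vapply(which(expressed), function(i) {
    replicate_t_test(psi[i, idx$control], psi[i, idx$treatment])
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  pass <- if (dpsi_strict) abs(dpsi) > dpsi_cutoff else abs(dpsi) >= dpsi_cutoff

  out <- data.frame(
    event_id = rownames(psi),
    mean_psi_control = m1, mean_psi_treatment = m2, dpsi = dpsi,
    p_value = p, q_value = q, expressed = expressed,
    significant = expressed & pass & !is.na(q) & q <= q_cutoff,
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(ps$events)) {
    out$type <- ps$events$type[match(out$event_id, ps$events$event_id)]
    out$gene_id <- ps$events$gene_id[match(out$event_id, ps$events$event_id)]
  }
  attr(out, "dropped") <- dropped
  attr(out, "cutoffs") <- list(min_reads = min_reads,
                               min_samples = min_samples,
                               dpsi = dpsi_cutoff, q = q_cutoff,
                               dpsi_strict = dpsi_strict)
  out
}

#' Tally significant events by splicing type
#'
#' @param calls output of [call_differential_events()] (needs a `type`
#'   column, present when the event table was attached to the counts).
#' @return `data.frame` with count and percentage of significant events per
#'   type (ES, MXE, A5SS, A3SS, RI); percentages sum to 100 (or are all 0
#'   when nothing is significant).
#' @export
tally_event_types <- function(calls) {
  if (is.null(calls$type)) stop("calls carry no event type annotation")
  types <- c("ES", "MXE", "A5SS", "A3SS", "RI")
  n <- vapply(types, function(tp) {
    sum(calls$significant & calls$type == tp, na.rm = TRUE)
  }, integer(1))
  tot <- sum(n)
  data.frame(type = types, n = n,
             percent = if (tot > 0) 100 * n / tot else rep(0, length(n)),
             row.names = NULL, stringsAsFactors = FALSE)
}
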