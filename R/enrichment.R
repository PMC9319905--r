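#' Extract event region sequences with ±200 nt flanks
#'
#' For each exon-skipping event, three regions are extracted: the upstream
#' intron, the alternative (cassette) exon and the downstream intron, each
#' extended by `flank` nucleotides on both sides (clipped at chromosome
#' boundaries). Sequences are returned transcript-sense: minus-strand
#' events are reverse-complemented and their upstream/downstream labels
#' refer to the transcript, not the genome.
#'
#' @param events an [event_table()] (only ES rows are used).
#' @param genome a named [Biostrings::DNAStringSet] (or a FASTA file path)
#'   with the chromosomes referenced by the events.
#' @param flank extension in nucleotides, default 200.
#' @return `data.frame` with `event_id`, `region` (`upstream_intron`,
#'   `exon`, `downstream_intron`), genomic `start`/`end` (0-based
#'   half-open, pre-reverse-complement) and `seq`.
#' @export
extract_event_regions <- function(events, genome, flank = 200) {
  if (is.character(genome)) {
    genome <- if (length(genome) == 1L && is.null(names(genome)) &&
                    file.exists(genome)) {
      Biostrings::readDNAStringSet(genome)
    } else Biostrings::DNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*", "", names(genome))
  ev <- events[events$type == "ES", , drop = FALSE]
  missing_chrom <- setdiff(unique(ev$chrom), names(genome))
  if (length(missing_chrom)) {
    bad <- ev$event_id[ev$chrom %in% missing_chrom][1L]
    stop("chromosome not in genome FASTA for event ", bad)
  }
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    len <- length(genome[[e$chrom]])
    # genomic-orientation regions: upstream intron, exon, downstream intron
    reg <- rbind(
      c(e$anchor_up_end, e$start),
      c(e$start, e$end),
      c(e$end, e$anchor_down_start))
    lab_genomic <- c("upstream_intron", "exon", "downstream_intron")
    if (e$strand == "-") lab_genomic <- rev(lab_genomic)
    start <- pmax(reg[, 1L] - flank, 0L)
    end <- pmin(reg[, 2L] + flank, len)
    seqs <- vapply(seq_len(3L), function(k) {
      s <- as.character(Biostrings::subseq(genome[[e$chrom]],
                                           start[k] + 1L, end[k]))
      if (e$strand == "-") {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      s
    }, character(1))
    rows[[i]] <- data.frame(
      event_id = e$event_id, region = lab_genomic,
      start = start, end = end, strand = e$strand, seq = seqs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample control sets of non-regulated events
#'
#' Draws `n_sets` control sets, each of the same cardinality as the
#' regulated set, from the pool of non-regulated events, defined (as
#' configured) by `|dPSI| < dpsi_null` and a raw p-value criterion
#' (`p < p_null` by default; set `p_greater = TRUE` for `p > p_null`).
#' Sampling is without replacement within a set and independent across
#' sets.
#'
#' @param calls output of [call_differential_events()].
#' @param n_regulated cardinality of the regulated set the controls must
#'   match.
#' @param n_sets number of control sets, default 100.
#' @param dpsi_null,p_null pool criteria, defaults 0.01 and 0.5.
#' @param p_greater interpret the p criterion as `p > p_null` instead of
#'   the default `p < p_null`.
#' @return list of `n_sets` character vectors of event ids.
#' @export
sample_control_sets <- function(calls, n_regulated, n_sets = 100,
                                dpsi_null = 0.01, p_null = 0.5,
                                p_greater = FALSE) {
  ok_p <- if (p_greater) calls$p_value > p_null else calls$p_value < p_null
  pool <- calls$event_id[!is.na(calls$dpsi) & abs(calls$dpsi) < dpsi_null &
                           !is.na(calls$p_value) & ok_p]
  if (length(pool) < n_regulated) {
    stop(sprintf(
      "non-regulated pool too small: %d events available, %d required",
      length(pool), n_regulated))
  }
  lapply(seq_len(n_sets), function(i) sample(pool, n_regulated))
}

#' Control-set z-score motif enrichment
#'
#' For every motif x region x direction of regulation, the observed motif
#' frequency in the regulated events is compared with the mean and standard
#' deviation of the same frequency over the control sets:
#' `z = (obs - mean_ctrl) / sd_ctrl`. The regulated sets are the
#' significant events (when the calls carry a `significant` flag) split by
#' direction, `dPSI > +cutoff` versus `dPSI < -cutoff`; an event
#' contributes to exactly one direction. The frequency
#' unit is hits per kilobase of scanned sequence (exact size matching even
#' after boundary clipping); `unit = "events"` switches to the proportion
#' of events with at least one hit. A motif is enriched when `z > z_cutoff`
#' (default 1.96); when the control standard deviation is 0 the z-score is
#' undefined and reported missing, never enriched.
#'
#' @param hits hit table from [scan_motifs()] over all (regulated and pool)
#'   event regions.
#' @param regions region table from [extract_event_regions()] (used for
#'   scanned lengths).
#' @param calls output of [call_differential_events()] defining dPSI
#'   directions.
#' @param control_sets list of event-id sets from [sample_control_sets()].
#' @param dpsi_cutoff direction cutoff, default 0.1.
#' @param z_cutoff enrichment threshold, default 1.96.
#' @param unit `"per_kb"` (default) or `"events"`.
#' @return `data.frame` with one row per motif x region x direction:
#'   `observed`, `control_mean`, `control_sd`, `z`, `enriched`.
#' @export
compute_enrichment <- function(hits, regions, calls, control_sets,
                               dpsi_cutoff = 0.1, z_cutoff = 1.96,
                               unit = c("per_kb", "events")) {
  unit <- match.arg(unit)
  sig <- if (!is.null(calls$significant)) calls$significant else
    rep(TRUE, nrow(calls))
  up <- calls$event_id[sig & !is.na(calls$dpsi) &
                         calls$dpsi > dpsi_cutoff]
  down <- calls$event_id[sig & !is.na(calls$dpsi) &
                           calls$dpsi < -dpsi_cutoff]
  motifs <- unique(hits$motif_id)
  region_labels <- unique(regions$region)

  # precomputed lookups: per motif x region, a named per-event hit-count
  # vector; per region, a named per-event scanned-length vector
  cnt_by_mr <- lapply(
    split(hits$event_id, paste(hits$motif_id, hits$region, sep = "\r")),
    function(ev) tapply(rep(1L, length(ev)), ev, sum))
  rlen <- if (!is.null(regions$end)) regions$end - regions$start else
    nchar(regions$seq)
  len_by_region <- lapply(split(seq_len(nrow(regions)), regions$region),
                          function(i) stats::setNames(rlen[i],
                                                      regions$event_id[i]))

  freq <- function(motif, region_label, ids) {
    lens <- len_by_region[[region_label]][ids]
    cnt <- cnt_by_mr[[paste(motif, region_label, sep = "\r")]]
    n_hit <- if (is.null(cnt)) numeric(0) else cnt[ids]
    if (unit == "per_kb") {
      kb <- sum(lens, na.rm = TRUE) / 1000
      if (kb == 0 || is.na(kb)) return(NA_real_)
      sum(n_hit, na.rm = TRUE) / kb
    } else {
      n_ev <- sum(!is.na(lens))
      if (n_ev == 0) return(NA_real_)
      sum(!is.na(n_hit) & n_hit > 0) / n_ev
    }
  }

  grid <- expand.grid(motif_id = motifs, region = region_labels,
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    ids <- if (g$direction == "up") up else down
    if (length(ids) == 0L) {
      return(data.frame(g, observed = NA_real_, control_mean = NA_real_,
                        control_sd = NA_real_, z = NA_real_,
                        enriched = FALSE, stringsAsFactors = FALSE))
    }
    obs <- freq(g$motif_id, g$region, ids)
    ctrl <- vapply(control_sets, function(ids_c) {
      freq(g$motif_id, g$region, ids_c)
    }, numeric(1))
    m <- mean(ctrl); s <- stats::sd(ctrl)
    z <- if (!is.na(s) && s > 0) (obs - m) / s else NA_real_
    data.frame(g, observed = obs, control_mean = m, control_sd = s,
               z = z, enriched = !is.na(z) && z > z_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
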