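#' Expression set: isoform-level TPM with a two-condition design
#'
#' Container for an isoform x sample TPM matrix together with the
#' isoform-to-gene map and the sample-to-condition assignment. Exactly two
#' conditions are supported; the first level of `condition` is treated as
#' the control and the second as the treatment (silencing) condition, and
#' every downstream difference (dIF, dPSI, dIS) is treatment minus control.
#'
#' @param tpm numeric matrix, isoforms x samples, finite and non-negative;
#'   rownames are isoform ids.
#' @param gene_id character vector, one gene per isoform (row of `tpm`).
#' @param condition factor (or coercible) of length `ncol(tpm)` with exactly
#'   two levels: control first, treatment second.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(tpm, gene_id, condition) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) stop("tpm must have isoform ids as rownames")
  if (length(gene_id) != nrow(tpm)) {
    stop("gene_id must have one entry per row of tpm")
  }
  if (anyNA(tpm) || any(!is.finite(tpm)) || any(tpm < 0)) {
    stop("TPM values must be finite and non-negative")
  }
  condition <- as.factor(condition)
  if (length(condition) != ncol(tpm)) {
    stop("condition must have one entry per column of tpm")
  }
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  structure(
    list(tpm = tpm, isoform_id = rownames(tpm),
         gene_id = as.character(gene_id), condition = condition),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "expression_set: %d isoforms, %d genes, %d samples (%s)\n",
    nrow(x$tpm), length(unique(x$gene_id)), ncol(x$tpm),
    paste(sprintf("%s: n=%d", levels(x$condition), table(x$condition)),
          collapse = ", ")))
  invisible(x)
}

#' Junction-count set for alternative-splicing events
#'
#' Per-event, per-sample inclusion (I) and skipping (S) junction read counts
#' under a two-condition design. `I + S = 0` is allowed (the sample is then
#' non-informative for that event).
#'
#' @param inclusion,skipping integer matrices, events x samples, with event
#'   ids as rownames; identical dimnames.
#' @param condition two-level factor over samples (control level first).
#' @param events optional event annotation `data.frame` (see
#'   [event_table()]), matched by `event_id`.
#' @return An object of class `junction_counts`.
#' @export
junction_counts <- function(inclusion, skipping, condition, events = NULL) {
  inclusion <- as.matrix(inclusion); skipping <- as.matrix(skipping)
  if (!identical(dim(inclusion), dim(skipping))) {
    stop("inclusion and skipping must have identical dimensions")
  }
  if (is.null(rownames(inclusion))) stop("event ids required as rownames")
  if (anyNA(inclusion) || anyNA(skipping) ||
      any(inclusion < 0) || any(skipping < 0)) {
    stop("junction counts must be non-negative")
  }
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  if (length(condition) != ncol(inclusion)) {
    stop("condition must have one entry per sample column")
  }
  if (!is.null(events) && !all(rownames(inclusion) %in% events$event_id)) {
    stop("all count rows must be present in the event table")
  }
  structure(
    list(inclusion = inclusion, skipping = skipping,
         event_id = rownames(inclusion), condition = condition,
         events = events),
    class = "junction_counts"
  )
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d events x %d samples\n",
              nrow(x$inclusion), ncol(x$inclusion)))
  invisible(x)
}

#' Event annotation table
#'
#' Builds the canonical event `data.frame` used across the package. The
#' alternative region (`start`, `end`) is 0-based half-open; for exon
#' skipping (ES) it is the cassette exon and the flanking anchors are the
#' ends of the neighbouring constitutive exons, so that
#' `[anchor_up_end, start)` is the upstream intron and
#' `[end, anchor_down_start)` the downstream intron (genomic orientation).
#'
#' @param event_id character ids.
#' @param type one of `"ES"`, `"MXE"`, `"A5SS"`, `"A3SS"`, `"RI"`.
#' @param gene_id,chrom,strand annotation columns; strand in `+`/`-`.
#' @param start,end 0-based half-open alternative-region coordinates.
#' @param anchor_up_end,anchor_down_start flanking anchor coordinates
#'   (defaults leave a 1 bp intron placeholder); required for region
#'   extraction of ES events.
#' @return `data.frame` of class `event_table`.
#' @export
event_table <- function(event_id, type, gene_id, chrom, strand, start, end,
                        anchor_up_end = start - 1L,
                        anchor_down_start = end + 1L) {
  type <- match.arg(type, c("ES", "MXE", "A5SS", "A3SS", "RI"),
                    several.ok = TRUE)
  if (any(end <= start)) stop("event end must exceed start")
  if (any(anchor_up_end > start) || any(anchor_down_start < end)) {
    stop("anchors must flank the alternative region")
  }
  out <- data.frame(
    event_id = as.character(event_id), type = type,
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = strand, start = as.integer(start), end = as.integer(end),
    anchor_up_end = as.integer(anchor_up_end),
    anchor_down_start = as.integer(anchor_down_start),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$event_id)) stop("duplicate event ids")
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(out) <- c("event_table", "data.frame")
  out
}

# internal: split sample indices by condition, control first
condition_index <- function(condition) {
  lev <- levels(condition)
  list(control = which(condition == lev[1L]),
       treatment = which(condition == lev[2L]),
       labels = lev)
}
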