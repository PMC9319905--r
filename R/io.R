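# Readers and writers for the plain-text exchange formats used by the
# pipeline. All tables are tab-separated with a header line; numbers are
# written with full precision via format(..., digits = 15) through
# write.table's defaults.

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an isoform TPM table
#'
#' Expects columns `isoform_id`, `gene_id`, then one column per sample.
#'
#' @param path TSV file.
#' @param condition sample-to-condition assignment: either a two-level
#'   factor over the sample columns, or a named character vector mapping
#'   sample names to condition labels (control level first).
#' @return an [expression_set()].
#' @export
read_expression_tsv <- function(path, condition) {
  df <- tsv_read(path)
  tpm <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(tpm) <- df$isoform_id
  if (!is.null(names(condition))) {
    condition <- condition[colnames(tpm)]
  }
  expression_set(tpm, df$gene_id, condition)
}

#' Read a junction-count table
#'
#' Expects columns `event_id`, then paired `<sample>.inc` / `<sample>.skp`
#' columns.
#'
#' @inheritParams read_expression_tsv
#' @param events optional [event_table()].
#' @return a [junction_counts()].
#' @export
read_junction_counts_tsv <- function(path, condition, events = NULL) {
  df <- tsv_read(path)
  inc_cols <- grep("\\.inc$", names(df), value = TRUE)
  skp_cols <- sub("\\.inc$", ".skp", inc_cols)
  inc <- as.matrix(df[, inc_cols, drop = FALSE])
  skp <- as.matrix(df[, skp_cols, drop = FALSE])
  samples <- sub("\\.inc$", "", inc_cols)
  dimnames(inc) <- dimnames(skp) <- list(df$event_id, samples)
  if (!is.null(names(condition))) condition <- condition[samples]
  junction_counts(inc, skp, condition, events = events)
}

#' Write a junction-count table
#' @param jc a [junction_counts()]. @param path output TSV.
#' @export
write_junction_counts_tsv <- function(jc, path) {
  samples <- colnames(jc$inclusion)
  df <- data.frame(event_id = jc$event_id, stringsAsFactors = FALSE)
  for (s in samples) {
    df[[paste0(s, ".inc")]] <- jc$inclusion[, s]
    df[[paste0(s, ".skp")]] <- jc$skipping[, s]
  }
  tsv_write(df, path)
}

#' Write an expression set as TSV
#' @param es an [expression_set()]. @param path output TSV.
#' @export
write_expression_tsv <- function(es, path) {
  tsv_write(data.frame(isoform_id = es$isoform_id, gene_id = es$gene_id,
                       es$tpm, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
}

#' Read an event-definition table
#' @param path TSV with the [event_table()] columns.
#' @return an [event_table()].
#' @export
read_events_tsv <- function(path) {
  df <- tsv_read(path)
  event_table(df$event_id, df$type, df$gene_id, df$chrom, df$strand,
              df$start, df$end, df$anchor_up_end, df$anchor_down_start)
}

#' Read a PPI edge list (two gene columns, BioGRID-tab-like)
#' @param path TSV; first two columns are the interacting genes.
#' @return `data.frame` with `gene_a`, `gene_b`.
#' @export
read_ppi_tsv <- function(path) {
  df <- tsv_read(path)
  stats::setNames(df[, 1:2], c("gene_a", "gene_b"))
}

#' Read a DDI pair list (two domain columns, 3did-like)
#' @param path TSV; first two columns are the interacting domains.
#' @return `data.frame` with `domain_a`, `domain_b`.
#' @export
read_ddi_tsv <- function(path) {
  df <- tsv_read(path)
  stats::setNames(df[, 1:2], c("domain_a", "domain_b"))
}

#' Read a domain-annotation table
#' @param path TSV with `isoform_id`, `gene_id`, `domain_id`, `exon_id`.
#' @return `data.frame`.
#' @export
read_annotation_tsv <- function(path) tsv_read(path)

#' Write a simulated data set to a directory
#'
#' Materialises every downstream input consumed by the pipeline as
#' plain-text files: `expression.tsv`, `junction_counts.tsv`,
#' `events.tsv`, `annotation.tsv`, `ppi.tsv`, `ddi.tsv`, `genome.fa`,
#' `motifs.meme`, `cohort_psi.tsv`, `cohort_expression.tsv`,
#' `clinical.tsv`, `cohort_events.tsv`, plus a `ground_truth/` bundle of
#' TSVs with the planted truth.
#'
#' @param sim result of [simulate_all()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_junction_counts_tsv(sim$counts,
                            file.path(dir, "junction_counts.tsv"))
  tsv_write(as.data.frame(sim$events), file.path(dir, "events.tsv"))
  tsv_write(sim$annotation, file.path(dir, "annotation.tsv"))
  tsv_write(sim$ppi, file.path(dir, "ppi.tsv"))
  tsv_write(sim$ddi, file.path(dir, "ddi.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), file.path(dir, "genome.fa"))
  write_meme(sim$pwms, file.path(dir, "motifs.meme"))
  tsv_write(data.frame(event_id = rownames(sim$cohort$psi),
                       sim$cohort$psi, check.names = FALSE),
            file.path(dir, "cohort_psi.tsv"))
  tsv_write(data.frame(gene_id = rownames(sim$cohort$expression),
                       sim$cohort$expression, check.names = FALSE),
            file.path(dir, "cohort_expression.tsv"))
  tsv_write(sim$cohort$clinical, file.path(dir, "clinical.tsv"))
  tsv_write(as.data.frame(sim$cohort$events),
            file.path(dir, "cohort_events.tsv"))
  gt <- file.path(dir, "ground_truth")
  dir.create(gt, showWarnings = FALSE)
  tsv_write(sim$truth$isoforms, file.path(gt, "isoforms.tsv"))
  tsv_write(sim$truth$genes, file.path(gt, "genes.tsv"))
  tsv_write(sim$truth$events, file.path(gt, "events.tsv"))
  tsv_write(sim$truth$edges, file.path(gt, "edges.tsv"))
  tsv_write(sim$truth$planted_sites, file.path(gt, "motif_sites.tsv"))
  invisible(dir)
}
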