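#' Detect gene-level isoform-switching events
#'
#' A gene exhibits an isoform switch when, between the two compared
#' conditions, at least one of its transcript variants is significantly
#' upregulated while another is significantly downregulated. Significance is
#' exactly the differential-transcript criterion (|log2FC| > 1, BH-FDR <
#' 0.05 under defaults); genes with a single tested transcript are
#' ineligible.
#'
#' @param det Transcript-level results from [differential_expression()].
#' @param tx2gene Named character vector transcript_id -> gene_id covering
#'   every tested transcript.
#' @return data.frame with one row per switching gene: gene_id,
#'   up_transcripts, down_transcripts (comma-separated, sorted), n_up,
#'   n_down.
#' @export
detect_switches <- function(det, tx2gene) {
  missing <- setdiff(det$feature_id, names(tx2gene))
  if (length(missing))
    stop("transcripts missing from tx2gene: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  gene <- tx2gene[det$feature_id]
  multi <- names(which(table(gene) >= 2L))
  out <- NULL
  for (g in sort(multi)) {
    d <- det[gene == g, , drop = FALSE]
    up <- sort(d$feature_id[d$is_significant & d$log2_fc > 0])
    down <- sort(d$feature_id[d$is_significant & d$log2_fc < 0])
    if (length(up) >= 1L && length(down) >= 1L)
      out <- rbind(out, data.frame(
        gene_id = g,
        up_transcripts = paste(up, collapse = ","),
        down_transcripts = paste(down, collapse = ","),
        n_up = length(up), n_down = length(down),
        stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(0), up_transcripts = character(0),
                      down_transcripts = character(0), n_up = integer(0),
                      n_down = integer(0))
  out
}

#' Per-sample isoform fractions
#'
#' Fraction of a gene's TPM carried by each transcript in each sample
#' (transcript TPM / gene TPM). Where the gene's total TPM is zero the
#' fraction is undefined and reported as `NA`; defined fractions sum to 1
#' per gene per sample. Fractions are invariant to per-sample scaling.
#'
#' @param em An `expression_matrix`.
#' @param tx2gene Named character vector covering every transcript in `em`.
#' @return Numeric matrix (transcripts x samples) of fractions with the
#'   row/column names of `em`.
#' @export
isoform_fractions <- function(em, tx2gene) {
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(rownames(em$values), names(tx2gene))
  if (length(missing))
    stop("transcripts missing from tx2gene: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  gene <- tx2gene[rownames(em$values)]
  gene_tot <- rowsum(em$values, group = gene)
  denom <- gene_tot[gene, , drop = FALSE]
  frac <- em$values / denom
  frac[denom == 0] <- NA_real_
  dimnames(frac) <- dimnames(em$values)
  frac
}
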