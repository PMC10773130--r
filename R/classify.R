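#' Structural categories assigned by the classifier
#' @export
STRUCTURAL_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC",
                           "antisense", "intergenic", "other_genic")

# Is `sub` a contiguous window of `full`? Both are junction data.frames on
# the same seq/strand. Returns the 0-based offset of the match, or -1L.
subchain_offset <- function(sub, full) {
  ns <- nrow(sub); nf <- nrow(full)
  if (ns == 0L || ns > nf) return(-1L)
  for (off in 0:(nf - ns)) {
    idx <- seq_len(ns) + off
    if (all(full$donor[idx] == sub$donor) &&
        all(full$acceptor[idx] == sub$acceptor))
      return(off)
  }
  -1L
}

overlaps_span <- function(qs, qe, s, e) qs < e & qe > s

# Exonic overlap in bp between a query model and a gene span.
exonic_overlap_bp <- function(t, gene_start, gene_end) {
  sum(pmax(0L, pmin(t$ends, gene_end) - pmax(t$starts, gene_start)))
}

# Genes on the given strand (or either) whose span overlaps the query span.
overlapping_genes <- function(ref, t, same_strand = TRUE) {
  g <- ref$genes
  keep <- g$seq_name == t$seq_name &
    overlaps_span(tx_start(t), tx_end(t), g$start, g$end) &
    (if (same_strand) g$strand == t$strand else g$strand != t$strand)
  g[keep, , drop = FALSE]
}

# Same-strand gene sharing the most junctions with the query; ties broken by
# exonic overlap bp, then lexicographic gene_id.
assign_gene <- function(ref, t, genes) {
  if (nrow(genes) == 0L) return(NA_character_)
  qjk <- junction_keys(t)
  shared <- vapply(genes$gene_id, function(g) {
    txs <- ref$transcripts[vapply(ref$transcripts, `[[`, "", "gene_id") == g]
    gjk <- unique(unlist(lapply(txs, junction_keys)))
    sum(qjk %in% gjk)
  }, 0L)
  bp <- vapply(seq_len(nrow(genes)), function(i)
    exonic_overlap_bp(t, genes$start[i], genes$end[i]), 0L)
  ord <- order(-shared, -bp, genes$gene_id)
  genes$gene_id[ord[1L]]
}

#' Classify one query transcript against a reference annotation
#'
#' Assigns exactly one structural category. For multi-exon queries the rules
#' are evaluated in order: an exact junction-chain match to a reference
#' transcript is a full-splice match (FSM); a contiguous sub-chain of a
#' reference chain is an incomplete-splice match (ISM); a chain whose splice
#' sites are all catalogued but whose combination is not is novel-in-catalogue
#' (NIC); any remaining query overlapping a same-strand gene is
#' novel-not-in-catalogue (NNC); opposite-strand overlap only is antisense;
#' no gene overlap is intergenic. FSM/ISM ignore terminal exon ends entirely —
#' the split is purely junction-based, with end artifacts handled by the
#' filter cascade. Splice-site matching is exact (0 bp tolerance).
#'
#' Mono-exon queries: exact interval match to a mono-exon reference
#' transcript is FSM; containment within a same-strand reference exon is ISM;
#' other same-strand gene-span overlap is `other_genic`; otherwise antisense
#' or intergenic as above.
#'
#' @param query A `transcript_model`.
#' @param ref A `reference_annotation`.
#' @return A one-row data.frame: transcript_id, category, assigned_gene,
#'   matched_ref, novel_site_count, novel_junction_count, subchain_offset.
#' @export
classify_transcript <- function(query, ref) {
  stopifnot(inherits(query, "transcript_model"),
            inherits(ref, "reference_annotation"))
  call <- function(category, gene = NA_character_, matched = NA_character_,
                   novel_sites = 0L, novel_junctions = 0L, offset = NA_integer_) {
    data.frame(transcript_id = query$transcript_id, category = category,
               assigned_gene = gene, matched_ref = matched,
               novel_site_count = novel_sites,
               novel_junction_count = novel_junctions,
               subchain_offset = offset, stringsAsFactors = FALSE)
  }
  same <- overlapping_genes(ref, query, same_strand = TRUE)
  anti <- overlapping_genes(ref, query, same_strand = FALSE)

  if (n_exons(query) == 1L) {
    for (rt in ref$transcripts) {
      if (n_exons(rt) == 1L && rt$seq_name == query$seq_name &&
          rt$strand == query$strand &&
          rt$starts[1L] == query$starts[1L] && rt$ends[1L] == query$ends[1L])
        return(call("FSM", rt$gene_id, rt$transcript_id))
    }
    for (id in sort(names(ref$transcripts))) {
      rt <- ref$transcripts[[id]]
      if (rt$seq_name == query$seq_name && rt$strand == query$strand &&
          any(rt$starts <= query$starts[1L] & rt$ends >= query$ends[1L]))
        return(call("ISM", rt$gene_id, rt$transcript_id, offset = 0L))
    }
    if (nrow(same) > 0L)
      return(call("other_genic", assign_gene(ref, query, same)))
    if (nrow(anti) > 0L)
      return(call("antisense", assign_gene(ref, query, anti)))
    return(call("intergenic"))
  }

  qchain <- junction_chain(query)
  ck <- chain_key(query)
  if (ck %in% names(ref$chain_index)) {
    matched <- ref$chain_index[[ck]][1L]
    return(call("FSM", ref$transcripts[[matched]]$gene_id, matched,
                offset = 0L))
  }
  for (id in sort(names(ref$transcripts))) {
    rt <- ref$transcripts[[id]]
    if (rt$seq_name != query$seq_name || rt$strand != query$strand) next
    off <- subchain_offset(qchain, junction_chain(rt))
    if (off >= 0L)
      return(call("ISM", rt$gene_id, id, offset = off))
  }
  novel_sites <- sum(!splice_site_keys(query) %in% ref$splice_sites)
  novel_junctions <- sum(!junction_keys(query) %in% ref$junctions)
  if (novel_sites == 0L)
    return(call("NIC", assign_gene(ref, query, same),
                novel_junctions = novel_junctions))
  if (nrow(same) > 0L)
    return(call("NNC", assign_gene(ref, query, same),
                novel_sites = novel_sites,
                novel_junctions = novel_junctions))
  if (nrow(anti) > 0L)
    return(call("antisense", assign_gene(ref, query, anti),
                novel_sites = novel_sites,
                novel_junctions = novel_junctions))
  call("intergenic", novel_sites = novel_sites,
       novel_junctions = novel_junctions)
}

#' Classify a set of query transcripts
#'
#' @param queries List of `transcript_model` with unique transcript_ids.
#' @param ref A `reference_annotation`.
#' @return A data.frame of structural calls (one row per query, same order)
#'   with a `tally` attribute: a named integer vector over all categories
#'   summing to `length(queries)`.
#' @export
classify_all <- function(queries, ref) {
  ids <- vapply(queries, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id across queries: ", ids[duplicated(ids)][1L])
  calls <- do.call(rbind, lapply(queries, classify_transcript, ref = ref))
  if (is.null(calls))
    calls <- data.frame(transcript_id = character(0), category = character(0),
                        assigned_gene = character(0), matched_ref = character(0),
                        novel_site_count = integer(0),
                        novel_junction_count = integer(0),
                        subchain_offset = integer(0))
  tally <- table(factor(calls$category, levels = STRUCTURAL_CATEGORIES))
  attr(calls, "tally") <- stats::setNames(as.integer(tally), names(tally))
  calls
}
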