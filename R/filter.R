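#' Filter-cascade configuration
#'
#' Defaults encode the standard artifact rules: every junction of a transcript must
#' be observed in short-read data (>= 1 pooled read), non-FSM transcripts
#' with 16 or more genomic adenines in the 20 bp downstream of the TTS are
#' discarded as intrapriming artifacts, 3'-truncated ISMs are dropped, and
#' merged transcripts must be detected in at least two biological replicates.
#'
#' @param min_junction_reads Minimum pooled read support per junction.
#' @param polyA_window Window size (bp) downstream of the TTS.
#' @param polyA_min_A Adenine count in the window at or above which a
#'   non-FSM transcript fails.
#' @param min_replicates Minimum number of samples a merged transcript must
#'   occur in.
#' @param filter_ism_ends Drop ISMs whose missing region is at the 3' end
#'   only (the canonical degradation artifact).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_junction_reads = 1, polyA_window = 20L,
                          polyA_min_A = 16L, min_replicates = 2L,
                          filter_ism_ends = TRUE) {
  stopifnot(polyA_min_A <= polyA_window, min_replicates >= 1L)
  structure(list(min_junction_reads = min_junction_reads,
                 polyA_window = as.integer(polyA_window),
                 polyA_min_A = as.integer(polyA_min_A),
                 min_replicates = as.integer(min_replicates),
                 filter_ism_ends = isTRUE(filter_ism_ends)),
            class = "filter_config")
}

filter_report <- function(ids, pass, rule, extra = NULL) {
  d <- data.frame(transcript_id = ids, pass = pass,
                  rule = ifelse(pass, NA_character_, rule),
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

calls_for <- function(models, calls) {
  ids <- vapply(models, `[[`, "", "transcript_id")
  missing <- setdiff(ids, calls$transcript_id)
  if (length(missing))
    stop("no structural call for transcript(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  calls[match(ids, calls$transcript_id), , drop = FALSE]
}

#' Short-read junction-support filter
#'
#' A multi-exon transcript passes only if every one of its junctions has
#' pooled short-read support of at least `min_junction_reads`; mono-exon
#' transcripts pass vacuously.
#'
#' @param models List of `transcript_model`.
#' @param calls Structural calls covering every model (used only for the
#'   coverage contract).
#' @param support A `junction_support` table.
#' @param cfg A [filter_config()].
#' @return A data.frame report: transcript_id, pass, rule
#'   (`"junction_support"` on failure), min_support.
#' @export
junction_support_filter <- function(models, calls, support, cfg = filter_config()) {
  calls_for(models, calls)
  res <- vapply(models, function(t) {
    ch <- junction_chain(t)
    if (nrow(ch) == 0L) return(Inf)
    min(vapply(seq_len(nrow(ch)), function(i)
      junction_support_count(support, t$seq_name, t$strand,
                             ch$donor[i], ch$acceptor[i]), 0))
  }, 0)
  filter_report(vapply(models, `[[`, "", "transcript_id"),
                res >= cfg$min_junction_reads, "junction_support",
                data.frame(min_support = res))
}

# Adenine count, on the transcript's strand, in the window genomically
# downstream of the 3' end. Plus strand reads [end, end+w); minus strand
# reads [start-w, start) reverse-complemented, so genomic T counts as A.
downstream_A_count <- function(t, genome, window) {
  if (t$strand == "+") {
    w <- genome_window(genome, t$seq_name, tx_end(t), tx_end(t) + window)
    n_a <- lengths(regmatches(w$seq, gregexpr("A", w$seq, fixed = TRUE)))
  } else {
    w <- genome_window(genome, t$seq_name, tx_start(t) - window, tx_start(t))
    n_a <- lengths(regmatches(w$seq, gregexpr("T", w$seq, fixed = TRUE)))
  }
  list(count = as.integer(n_a), truncated = w$truncated)
}

#' Intrapriming (genomic poly-A) filter
#'
#' Oligo-dT can prime on a genomic adenine tract instead of a true poly(A)
#' tail, creating false 3' ends. Non-FSM transcripts (ISM/NIC/NNC/antisense/
#' intergenic/other-genic) fail when the `polyA_window` bases genomically
#' downstream of the TTS contain `polyA_min_A` or more adenines on the
#' transcript strand. FSM transcripts always pass. Windows running off the
#' sequence end are truncated and counted as-is (flagged in the report).
#'
#' @inheritParams junction_support_filter
#' @param genome A `DNAStringSet` covering all model coordinates.
#' @return A report data.frame with columns transcript_id, pass, rule
#'   (`"intrapriming"`), A_count, window_truncated.
#' @export
intrapriming_filter <- function(models, calls, genome, cfg = filter_config()) {
  mc <- calls_for(models, calls)
  res <- lapply(models, downstream_A_count, genome = genome,
                window = cfg$polyA_window)
  count <- vapply(res, `[[`, 0L, "count")
  pass <- mc$category == "FSM" | count < cfg$polyA_min_A
  filter_report(vapply(models, `[[`, "", "transcript_id"),
                pass, "intrapriming",
                data.frame(A_count = count,
                           window_truncated = vapply(res, `[[`, FALSE,
                                                     "truncated")))
}

#' ISM 3'-end incompleteness filter
#'
#' Drops incomplete-splice matches whose missing region is at the 3' end
#' only (strand-aware): these are the canonical RNA-degradation /
#' incomplete-reverse-transcription artifacts. ISMs missing the 5' end or
#' both ends, and all other categories, pass.
#'
#' @inheritParams junction_support_filter
#' @return A report data.frame (rule `"ism_3prime"`).
#' @export
ism_end_filter <- function(models, calls, cfg = filter_config()) {
  mc <- calls_for(models, calls)
  if (is.null(mc$ref_chain_len)) mc$ref_chain_len <- NA_integer_
  pass <- rep(TRUE, length(models))
  for (i in seq_along(models)) {
    if (!cfg$filter_ism_ends || mc$category[i] != "ISM") next
    t <- models[[i]]
    nq <- max(0L, n_exons(t) - 1L)
    off <- mc$subchain_offset[i]
    nref <- mc$ref_chain_len[i]
    if (is.na(off) || is.na(nref) || nq == 0L) next
    missing_left <- off > 0L
    missing_right <- (off + nq) < nref
    missing_3p <- if (t$strand == "+") missing_right else missing_left
    missing_5p <- if (t$strand == "+") missing_left else missing_right
    if (missing_3p && !missing_5p) pass[i] <- FALSE
  }
  filter_report(vapply(models, `[[`, "", "transcript_id"), pass, "ism_3prime")
}

#' Merge per-sample transcript models into a non-redundant set
#'
#' Multi-exon transcripts with identical junction chains collapse into one
#' record whose ends are the outermost observed ends (the longest-transcript
#' convention of chain-collapse tools). Mono-exon transcripts merge by
#' single-linkage when reciprocal overlap is >= 50% on the same strand.
#' Occurrence counts record the number of distinct contributing samples.
#'
#' @param per_sample_models Named list: sample id -> list of
#'   `transcript_model`.
#' @return List with `models` (merged `transcript_model`s, ids from the
#'   lexicographically first contributor) and `occurrences` (data.frame
#'   transcript_id, n_samples, samples, member_ids).
#' @export
merge_nonredundant <- function(per_sample_models) {
  flat <- list(); samp <- character(0)
  for (s in names(per_sample_models))
    for (t in per_sample_models[[s]]) {
      flat[[length(flat) + 1L]] <- t
      samp <- c(samp, s)
    }
  if (length(flat) == 0L)
    return(list(models = list(),
                occurrences = data.frame(transcript_id = character(0),
                                         n_samples = integer(0),
                                         samples = character(0),
                                         member_ids = character(0))))
  multi <- vapply(flat, function(t) n_exons(t) > 1L, FALSE)
  groups <- integer(length(flat))
  # multi-exon: exact chain identity
  if (any(multi)) {
    keys <- vapply(flat[multi], chain_key, "")
    groups[multi] <- match(keys, unique(keys))
  }
  # mono-exon: single-linkage on >= 50% reciprocal overlap, same seq/strand
  if (any(!multi)) {
    idx <- which(!multi)
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      ta <- flat[[idx[a]]]; tb <- flat[[idx[b]]]
      if (ta$seq_name != tb$seq_name || ta$strand != tb$strand) next
      ov <- min(tx_end(ta), tx_end(tb)) - max(tx_start(ta), tx_start(tb))
      if (ov <= 0) next
      la <- tx_end(ta) - tx_start(ta); lb <- tx_end(tb) - tx_start(tb)
      if (ov / la >= 0.5 && ov / lb >= 0.5)
        parent[find(a)] <- find(b)
    }
    roots <- vapply(seq_along(idx), find, 0L)
    groups[idx] <- max(groups) + match(roots, unique(roots))
  }
  merged <- list(); occ <- NULL
  for (g in sort(unique(groups))) {
    members <- flat[groups == g]
    ids <- sort(vapply(members, `[[`, "", "transcript_id"))
    rep_t <- members[[order(vapply(members, `[[`, "", "transcript_id"))[1L]]]
    starts <- rep_t$starts; ends <- rep_t$ends
    starts[1L] <- min(vapply(members, tx_start, 0L))
    ends[length(ends)] <- max(vapply(members, tx_end, 0L))
    m <- transcript_model(ids[1L], rep_t$seq_name, rep_t$strand, starts, ends,
                          gene_id = rep_t$gene_id)
    ss <- sort(unique(samp[groups == g]))
    merged[[length(merged) + 1L]] <- m
    occ <- rbind(occ, data.frame(transcript_id = ids[1L],
                                 n_samples = length(ss),
                                 samples = paste(ss, collapse = ","),
                                 member_ids = paste(ids, collapse = ","),
                                 stringsAsFactors = FALSE))
  }
  list(models = merged, occurrences = occ)
}

#' Replicate-support filter
#'
#' Keeps merged transcripts detected in at least `min_replicates` distinct
#' samples.
#'
#' @param merged Output of [merge_nonredundant()].
#' @param cfg A [filter_config()].
#' @return `merged` restricted to passing transcripts, plus a `report`
#'   component.
#' @export
replicate_filter <- function(merged, cfg = filter_config()) {
  keep <- merged$occurrences$n_samples >= cfg$min_replicates
  report <- filter_report(merged$occurrences$transcript_id, keep, "replicates")
  list(models = merged$models[keep],
       occurrences = merged$occurrences[keep, , drop = FALSE],
       report = report)
}

#' Run the full post-classification filter cascade
#'
#' Order: structural classification (supplied) -> junction support ->
#' intrapriming -> ISM 3'-end -> cross-sample non-redundant merge ->
#' replicate filter. Per-sample evidence filters precede merging so that
#' occurrence counts reflect surviving observations.
#'
#' @param per_sample_models Named list: sample id -> list of models.
#' @param ref A `reference_annotation`.
#' @param genome A `DNAStringSet`.
#' @param support A `junction_support` table.
#' @param cfg A [filter_config()].
#' @return List: `models` (final transcript set), `occurrences`, `calls`
#'   (structural calls for unique inputs), `report` (per unique transcript:
#'   pass and first failing rule), `rule_counts`.
#' @export
filter_isoforms <- function(per_sample_models, ref, genome, support,
                            cfg = filter_config()) {
  # classify each distinct transcript id once (identical across samples)
  all_models <- unlist(unname(per_sample_models), recursive = FALSE)
  ids <- vapply(all_models, `[[`, "", "transcript_id")
  uniq <- all_models[!duplicated(ids)]
  calls <- classify_all(uniq, ref)
  # record matched reference chain length for the ISM end rule
  calls$ref_chain_len <- vapply(seq_len(nrow(calls)), function(i) {
    m <- calls$matched_ref[i]
    if (is.na(m)) NA_integer_ else nrow(junction_chain(ref$transcripts[[m]]))
  }, 0L)

  r_junc <- junction_support_filter(uniq, calls, support, cfg)
  r_polya <- intrapriming_filter(uniq, calls, genome, cfg)
  r_ism <- ism_end_filter(uniq, calls, cfg)
  pass <- r_junc$pass & r_polya$pass & r_ism$pass
  first_rule <- ifelse(!r_junc$pass, "junction_support",
                ifelse(!r_polya$pass, "intrapriming",
                ifelse(!r_ism$pass, "ism_3prime", NA_character_)))
  report <- data.frame(transcript_id = r_junc$transcript_id, pass = pass,
                       rule = first_rule, stringsAsFactors = FALSE)
  keep_ids <- report$transcript_id[report$pass]
  surviving <- lapply(per_sample_models, function(ms)
    ms[vapply(ms, `[[`, "", "transcript_id") %in% keep_ids])
  merged <- merge_nonredundant(surviving)
  final <- replicate_filter(merged, cfg)
  dropped_rep <- final$report$transcript_id[!final$report$pass]
  rule_counts <- c(junction_support = sum(!r_junc$pass),
                   intrapriming = sum(r_junc$pass & !r_polya$pass),
                   ism_3prime = sum(r_junc$pass & r_polya$pass & !r_ism$pass),
                   replicates = length(dropped_rep))
  list(models = final$models, occurrences = final$occurrences,
       calls = calls, report = report, rule_counts = rule_counts)
}
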