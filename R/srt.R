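#' Specific-RNA-transcript (SRT) caller configuration
#'
#' @param fold_threshold Tumour-over-normal fold threshold (default 10).
#' @param prevalence_tpm TPM above which a transcript counts as expressed in
#'   a tumour sample (default 0.5).
#' @param prevalence_fraction Fraction of tumour samples that must express
#'   the transcript, strict greater-than (default 0.05).
#' @param eps Pseudocount used for median-ratio fold changes in the
#'   metastasis caller.
#' @return A list of class `srt_config`.
#' @export
srt_config <- function(fold_threshold = 10, prevalence_tpm = 0.5,
                       prevalence_fraction = 0.05, eps = 0.01) {
  stopifnot(fold_threshold > 1, prevalence_fraction >= 0,
            prevalence_fraction < 1)
  structure(list(fold_threshold = fold_threshold,
                 prevalence_tpm = prevalence_tpm,
                 prevalence_fraction = prevalence_fraction, eps = eps),
            class = "srt_config")
}

srt_frame <- function(tumour, normal_max, cfg, ratio_mode) {
  med <- apply(tumour, 1L, stats::median)
  prevalence <- rowMeans(tumour > cfg$prevalence_tpm)
  if (ratio_mode == "max") {
    passes_i <- med >= cfg$fold_threshold * normal_max & med > 0
  } else {
    passes_i <- (med + cfg$eps) / (normal_max + cfg$eps) > cfg$fold_threshold
  }
  passes_ii <- prevalence > cfg$prevalence_fraction
  data.frame(transcript_id = rownames(tumour), median_tumour = med,
             max_normal = normal_max, prevalence = prevalence,
             passes_i = passes_i, passes_ii = passes_ii,
             is_srt = passes_i & passes_ii,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call tumour-specific RNA transcripts
#'
#' A transcript is an SRT when (i) its median TPM across tumour samples is
#' at least `fold_threshold` times the maximum TPM observed across all
#' normal samples (with median > 0 required, so all-zero transcripts are
#' never called), and (ii) it is expressed above `prevalence_tpm` in more
#' than `prevalence_fraction` of tumour samples.
#'
#' @param em An `expression_matrix`.
#' @param tumour_group,normal_group Group labels.
#' @param cfg An [srt_config()].
#' @param transcripts Optional transcript ids to restrict to; ids absent
#'   from the matrix are skipped with a warning.
#' @return data.frame: transcript_id, median_tumour, max_normal, prevalence,
#'   passes_i, passes_ii, is_srt.
#' @export
call_srt <- function(em, tumour_group, normal_group, cfg = srt_config(),
                     transcripts = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  st <- group_samples(em, tumour_group)
  sn <- group_samples(em, normal_group)
  vals <- em$values
  if (!is.null(transcripts)) {
    absent <- setdiff(transcripts, rownames(vals))
    if (length(absent))
      warning("skipping transcript(s) absent from matrix: ",
              paste(utils::head(absent, 3L), collapse = ", "))
    vals <- vals[intersect(transcripts, rownames(vals)), , drop = FALSE]
  }
  tumour <- vals[, st, drop = FALSE]
  normal_max <- apply(vals[, sn, drop = FALSE], 1L, max)
  srt_frame(tumour = tumour, normal_max = normal_max, cfg = cfg,
            ratio_mode = "max")
}

#' Call metastasis-specific transcripts
#'
#' Metastasis-specific transcripts have a median-TPM fold change strictly
#' greater than `fold_threshold` between metastatic and primary
#' (nonmetastatic) tumours, computed with pseudocount `eps`, and must pass
#' the same prevalence criterion as [call_srt()] over metastasis samples.
#' Optionally, when `normal_groups` are supplied and
#' `require_normal_low = TRUE`, candidates must also be barely expressed in
#' normals (max TPM < `prevalence_tpm`); off by default.
#'
#' @param em An `expression_matrix`.
#' @param metastasis_group,primary_group Group labels.
#' @param normal_groups Optional character vector of normal-tissue group
#'   labels.
#' @param require_normal_low Enforce the optional normal-tissue criterion.
#' @param cfg An [srt_config()].
#' @return data.frame as in [call_srt()], with `median_primary` and
#'   `fold_change` columns (`max_normal` reported when normals supplied).
#' @export
call_metastasis_srt <- function(em, metastasis_group, primary_group,
                                normal_groups = NULL,
                                require_normal_low = FALSE,
                                cfg = srt_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  sm <- group_samples(em, metastasis_group)
  sp <- group_samples(em, primary_group)
  met <- em$values[, sm, drop = FALSE]
  med_p <- apply(em$values[, sp, drop = FALSE], 1L, stats::median)
  out <- srt_frame(tumour = met, normal_max = med_p, cfg = cfg,
                   ratio_mode = "pseudocount")
  names(out)[names(out) == "max_normal"] <- "median_primary"
  names(out)[names(out) == "median_tumour"] <- "median_met"
  out$fold_change <- (out$median_met + cfg$eps) / (out$median_primary + cfg$eps)
  if (!is.null(normal_groups)) {
    sn <- unlist(lapply(normal_groups, group_samples, em = em))
    out$max_normal <- apply(em$values[, sn, drop = FALSE], 1L, max)
    if (require_normal_low) {
      out$passes_normal_low <- out$max_normal < cfg$prevalence_tpm
      out$is_srt <- out$is_srt & out$passes_normal_low
    }
  }
  out
}
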