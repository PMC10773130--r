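#' Pipeline configuration
#'
#' Bundles input paths and stage parameters for an end-to-end run:
#' classify -> filter cascade -> differential expression -> SRT calling ->
#' switch detection -> optional panel evaluation. A single global seed is
#' combined with a per-stage offset so stages are independently
#' reproducible.
#'
#' @param reference_gtf,genome_fa Reference annotation and genome paths.
#' @param query_gtfs Named character vector: sample id -> query GTF.
#' @param junction_tsvs Junction-support TSV paths.
#' @param expression_tsv,groups_tsv Expression matrix and sample-group map.
#' @param tx2gene_tsv Optional transcript-to-gene TSV (columns
#'   transcript_id, gene_id); defaults to the classifier's gene assignments.
#' @param out_dir Output directory.
#' @param tumour_group,normal_group,metastasis_group,primary_group Group
#'   labels in the groups TSV.
#' @param filter,srt,panel Stage configurations ([filter_config()],
#'   [srt_config()], [panel_eval_config()]).
#' @param lfc_threshold,fdr_threshold Differential-expression thresholds.
#' @param panel_transcripts Optional transcript ids: evaluate this panel for
#'   metastasis-vs-primary discrimination.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_gtf, genome_fa, query_gtfs,
                            junction_tsvs, expression_tsv, groups_tsv,
                            tx2gene_tsv = NULL, out_dir,
                            tumour_group = "tumour", normal_group = "normal",
                            metastasis_group = "metastasis",
                            primary_group = "primary",
                            filter = filter_config(), srt = srt_config(),
                            panel = panel_eval_config(),
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            panel_transcripts = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage sub-seed, kept within 32-bit integer range
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

check_input <- function(path, stage) {
  if (!all(file.exists(path)))
    stop("pipeline stage '", stage, "': missing input file(s): ",
         paste(path[!file.exists(path)], collapse = ", "))
}

#' Run the full pipeline on files
#'
#' Executes every stage, writes TSV artifacts plus a JSON run summary under
#' `cfg$out_dir`, and returns the summary. Re-running with the same config
#' and seed reproduces byte-identical artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the run summary list (per-stage feature counts, seed,
#'   config echo, wall times).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  times <- c(); counts <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  check_input(cfg$reference_gtf, "load_reference")
  check_input(cfg$genome_fa, "load_genome")
  check_input(unname(cfg$query_gtfs), "load_queries")
  check_input(cfg$junction_tsvs, "load_junctions")
  check_input(c(cfg$expression_tsv, cfg$groups_tsv), "load_expression")
  ref <- read_gtf(cfg$reference_gtf, "reference")
  genome <- read_genome(cfg$genome_fa)
  if (is.null(names(cfg$query_gtfs)))
    names(cfg$query_gtfs) <- sprintf("S%02d", seq_along(cfg$query_gtfs))
  per_sample <- lapply(names(cfg$query_gtfs), function(s)
    read_gtf(cfg$query_gtfs[[s]], "query", source_sample = s))
  names(per_sample) <- names(cfg$query_gtfs)
  support <- read_junction_support(cfg$junction_tsvs)
  em <- read_expression(cfg$expression_tsv, cfg$groups_tsv)
  times["load"] <- tic() - t0

  ## classification + filter cascade
  t0 <- tic()
  filt <- filter_isoforms(per_sample, ref, genome, support, cfg$filter)
  calls <- filt$calls
  utils::write.table(calls, file.path(cfg$out_dir, "structural_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(filt$report, file.path(cfg$out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gtf(filt$models, file.path(cfg$out_dir, "final_transcripts.gtf"))
  counts$classified <- as.list(attr(calls, "tally"))
  counts$filter_fail_by_rule <- as.list(filt$rule_counts)
  counts$final_transcripts <- length(filt$models)
  times["classify_filter"] <- tic() - t0

  ## tx2gene: supplied file or classifier assignment
  tx2gene <- if (!is.null(cfg$tx2gene_tsv)) {
    check_input(cfg$tx2gene_tsv, "tx2gene")
    d <- utils::read.table(cfg$tx2gene_tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    stats::setNames(d$gene_id, d$transcript_id)
  } else {
    g <- ifelse(is.na(calls$assigned_gene),
                paste0("NOVEL_", calls$transcript_id), calls$assigned_gene)
    stats::setNames(g, calls$transcript_id)
  }

  ## differential expression + decomposition
  t0 <- tic()
  det <- differential_expression(em, cfg$tumour_group, cfg$normal_group,
                                 level = "transcript", calls = calls,
                                 lfc_threshold = cfg$lfc_threshold,
                                 fdr_threshold = cfg$fdr_threshold)
  deg <- differential_expression(em, cfg$tumour_group, cfg$normal_group,
                                 level = "gene", tx2gene = tx2gene,
                                 calls = calls,
                                 lfc_threshold = cfg$lfc_threshold,
                                 fdr_threshold = cfg$fdr_threshold)
  dec <- overlap_decomposition(det, deg, tx2gene)
  utils::write.table(det, file.path(cfg$out_dir, "det.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(deg, file.path(cfg$out_dir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$det <- sum(det$is_significant)
  counts$deg <- sum(deg$is_significant)
  counts$overlap <- as.list(dec$counts)
  times["differential"] <- tic() - t0

  ## SRT calling (tumour and metastasis arms)
  t0 <- tic()
  srt <- call_srt(em, cfg$tumour_group, cfg$normal_group, cfg$srt)
  utils::write.table(srt, file.path(cfg$out_dir, "srt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$srt <- sum(srt$is_srt)
  met <- NULL
  if (cfg$metastasis_group %in% em$groups &&
      cfg$primary_group %in% em$groups) {
    met <- call_metastasis_srt(em, cfg$metastasis_group, cfg$primary_group,
                               cfg = cfg$srt)
    utils::write.table(met, file.path(cfg$out_dir, "srt_metastasis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$met_srt <- sum(met$is_srt)
  }
  times["srt"] <- tic() - t0

  ## isoform switches + fractions
  t0 <- tic()
  switches <- detect_switches(det, tx2gene)
  utils::write.table(switches, file.path(cfg$out_dir, "switch_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  frac <- isoform_fractions(em, tx2gene)
  utils::write.table(
    data.frame(transcript_id = rownames(frac), frac, check.names = FALSE),
    file.path(cfg$out_dir, "isoform_fractions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  counts$switch_events <- nrow(switches)
  times["switch"] <- tic() - t0

  ## optional panel evaluation on the metastasis arm
  if (!is.null(cfg$panel_transcripts) && !is.null(met)) {
    t0 <- tic()
    keep <- em$groups %in% c(cfg$metastasis_group, cfg$primary_group)
    sub <- expression_matrix(em$values[, names(em$groups)[keep], drop = FALSE],
                             em$groups[keep])
    pcfg <- cfg$panel
    pcfg$seed <- stage_seed(cfg$seed, "panel_eval")
    res <- evaluate_panel(sub, cfg$panel_transcripts,
                          sub$groups == cfg$metastasis_group, pcfg)
    counts$panel <- list(auc_train_cv = res$auc_train_cv,
                         auc_test = res$auc_test)
    times["panel"] <- tic() - t0
  }

  summary <- list(seed = cfg$seed, counts = counts,
                  stage_seconds = as.list(round(times, 3)),
                  thresholds = list(lfc = cfg$lfc_threshold,
                                    fdr = cfg$fdr_threshold,
                                    srt_fold = cfg$srt$fold_threshold,
                                    min_replicates = cfg$filter$min_replicates))
  summary_path <- file.path(cfg$out_dir, "run_summary.json")
  out <- summary
  out$stage_seconds <- NULL  # wall times vary run to run; keep JSON stable
  jsonlite::write_json(out, summary_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  summary$paths <- list(out_dir = cfg$out_dir, summary = summary_path)
  invisible(summary)
}
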