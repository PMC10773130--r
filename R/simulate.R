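#' Synthetic-cohort simulation configuration
#'
#' The generator emulates the structure of a paired tumour/normal long-read
#' cohort with an additional metastasis/primary arm: a multi-gene,
#' multi-isoform annotation with shared and novel splice sites, genomic
#' adenine tracts downstream of selected transcript 3' ends, short-read
#' junction support counts, and log-normal TPM cohorts with planted
#' tumour-exclusive transcripts and reciprocal up/down isoform pairs.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output files.
#' @param n_genes Number of reference genes.
#' @param transcripts_per_gene Integer range (min, max) of reference
#'   transcripts per gene.
#' @param exons_per_transcript Integer range (min, max) of exons in the
#'   longest transcript of each gene.
#' @param n_tumour,n_normal,n_metastasis,n_primary Samples per group.
#' @param n_lr_samples Long-read samples across which query transcripts are
#'   distributed (for the replicate filter).
#' @param srt_fraction Fraction of query transcripts planted as
#'   tumour-exclusive (normal TPM drawn uniformly in [0, 0.05]).
#' @param srt_effect Multiplicative tumour effect for planted SRTs
#'   (default 50).
#' @param met_srt_fraction,met_srt_effect Same for the metastasis arm.
#' @param switch_fraction Fraction of multi-isoform genes planted with a
#'   reciprocal 4x up/down isoform pair (gene-level sum conserved).
#' @param polyA_track_fraction Fraction of query transcripts given a genomic
#'   adenine tract immediately downstream of the TTS (strand-aware).
#' @param polyA_A_count Adenines written into the 20 bp downstream window of
#'   tract-planted transcripts.
#' @param unsupported_fraction Fraction of multi-exon query transcripts with
#'   one junction left without short-read support.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline TPM parameters.
#' @param noise_sdlog Multiplicative log-normal noise on TPM (rank- and
#'   threshold-based statistics downstream only need a right-skewed positive
#'   model).
#' @param n_seqs,seq_length Genome shape (random uniform ACGT outside
#'   planted tracts).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 24L,
                              transcripts_per_gene = c(2L, 3L),
                              exons_per_transcript = c(4L, 6L),
                              n_tumour = 10L, n_normal = 10L,
                              n_metastasis = 6L, n_primary = 6L,
                              n_lr_samples = 4L,
                              srt_fraction = 0.05, srt_effect = 50,
                              met_srt_fraction = 0.05, met_srt_effect = 50,
                              switch_fraction = 0.2,
                              polyA_track_fraction = 0.15,
                              polyA_A_count = 18L,
                              unsupported_fraction = 0.05,
                              baseline_meanlog = 3, baseline_sdlog = 1,
                              noise_sdlog = 0.4,
                              n_seqs = 2L, seq_length = 500000L) {
  fr <- c(srt_fraction, met_srt_fraction, switch_fraction,
          polyA_track_fraction, unsupported_fraction)
  stopifnot(all(fr >= 0 & fr <= 1),
            length(transcripts_per_gene) == 2L,
            length(exons_per_transcript) == 2L,
            exons_per_transcript[1L] >= 4L,
            n_genes >= 2L, n_lr_samples >= 2L)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# Build one gene: exon "slots" shared by all its transcripts. Returns slot
# start/end vectors plus reference transcript exon subsets.
build_gene <- function(gene_id, seq_name, strand, origin, cfg) {
  n_slots <- sample(seq(cfg$exons_per_transcript[1L],
                        cfg$exons_per_transcript[2L]), 1L)
  exon_len <- sample(100:300, n_slots, replace = TRUE)
  intron_len <- sample(200:2000, n_slots - 1L, replace = TRUE)
  starts <- origin + cumsum(c(0L, exon_len[-n_slots] + intron_len))
  ends <- starts + exon_len
  k <- sample(seq(cfg$transcripts_per_gene[1L], cfg$transcripts_per_gene[2L]), 1L)
  # T1 uses all slots; extra transcripts each skip one distinct interior slot
  subsets <- list(seq_len(n_slots))
  interior <- setdiff(seq_len(n_slots), c(1L, n_slots))
  skips <- utils::head(interior, k - 1L)
  for (s in skips) subsets[[length(subsets) + 1L]] <- setdiff(seq_len(n_slots), s)
  list(gene_id = gene_id, seq_name = seq_name, strand = strand,
       n_slots = n_slots, starts = starts, ends = ends, subsets = subsets,
       skipped = skips)
}

gene_tx <- function(g, i)
  transcript_model(sprintf("%s.R%d", g$gene_id, i), g$seq_name, g$strand,
                   g$starts[g$subsets[[i]]], g$ends[g$subsets[[i]]],
                   gene_id = g$gene_id)

# Candidate NIC chain: skip interior slot(s) such that the resulting exon
# subset differs from every reference subset. Verified against the built
# reference before acceptance.
nic_subsets <- function(g) {
  interior <- setdiff(seq_len(g$n_slots), c(1L, g$n_slots))
  singles <- lapply(setdiff(interior, g$skipped), function(s)
    setdiff(seq_len(g$n_slots), s))
  pairs <- if (length(interior) >= 2L)
    utils::combn(interior, 2L, function(p) list(setdiff(seq_len(g$n_slots), p)),
                 simplify = FALSE)
  else list()
  c(singles, lapply(pairs, `[[`, 1L))
}

#' Simulate a complete synthetic long-read cohort with ground truth
#'
#' Writes, under `out_dir`: `genome.fa`, `reference.gtf`, one query GTF per
#' long-read sample (`LR01.gtf`, ...), two junction-support TSVs,
#' `expression.tsv` + `groups.tsv`, `tx2gene.tsv`, and ground-truth tables
#' (`truth_transcripts.tsv`, `truth_genes.tsv`). Query transcripts are
#' constructed per intended structural category: FSM copies a reference
#' chain with jittered ends; ISM is a contiguous sub-chain missing the 5' or
#' 3' end; NIC recombines known donors/acceptors into an unseen chain; NNC
#' shifts one splice site to a position >= 10 bp from every reference site;
#' antisense copies a chain onto the opposite strand; intergenic models sit
#' >= 10 kb from every gene. Planted tumour-exclusive transcripts draw
#' tumour TPM from baseline x `srt_effect` and normal TPM uniformly from
#' [0, 0.05]; planted switch genes carry a reciprocal 4x isoform pair with
#' the gene-level sum conserved.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `config`, `paths`, `truth_transcripts`,
#'   `truth_genes`, plus in-memory `ref` (reference_annotation), `queries`
#'   (list of models), `per_sample_models`, `expression`
#'   (expression_matrix), `tx2gene`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), out_dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(cfg$seed)

  ## ---- genome scaffold and gene placement ----
  seq_names <- sprintf("chr%d", seq_len(cfg$n_seqs))
  genome_chars <- lapply(seq_len(cfg$n_seqs), function(i)
    sample(c("A", "C", "G", "T"), cfg$seq_length, replace = TRUE))
  names(genome_chars) <- seq_names

  gene_margin <- 12000L   # keeps gene spans (< ~12 kb) >= 10 kb apart
  genes <- list(); cursor <- stats::setNames(rep(5000L, cfg$n_seqs), seq_names)
  for (i in seq_len(cfg$n_genes)) {
    sq <- seq_names[(i - 1L) %% cfg$n_seqs + 1L]
    g <- build_gene(sprintf("G%02d", i), sq, sample(c("+", "-"), 1L),
                    cursor[sq], cfg)
    genes[[length(genes) + 1L]] <- g
    cursor[sq] <- max(g$ends) + gene_margin + 10000L
    if (cursor[sq] > cfg$seq_length - 30000L)
      stop("genome too short for ", cfg$n_genes, " genes; increase seq_length")
  }
  ref_models <- unlist(lapply(genes, function(g)
    lapply(seq_along(g$subsets), function(i) gene_tx(g, i))),
    recursive = FALSE)
  ref <- reference_annotation(ref_models)
  site_parts <- strsplit(ref$splice_sites, "|", fixed = TRUE)
  ref_sites_by_seq <- split(
    as.integer(vapply(site_parts, `[[`, "", 3L)),
    vapply(site_parts, `[[`, "", 1L))

  ## ---- query construction per intended category ----
  queries <- list(); truth <- NULL
  add_query <- function(t, category, gene_id, ism_missing = NA_character_) {
    queries[[length(queries) + 1L]] <<- t
    truth <<- rbind(truth, data.frame(
      transcript_id = t$transcript_id, gene_id = gene_id,
      category = category, ism_missing_end = ism_missing,
      stringsAsFactors = FALSE))
  }
  chain_known <- function(t) chain_key(t) %in% names(ref$chain_index)
  is_subchain <- function(t) {
    ch <- junction_chain(t)
    any(vapply(ref$transcripts, function(rt)
      rt$seq_name == t$seq_name && rt$strand == t$strand &&
        nrow(junction_chain(rt)) > nrow(ch) &&
        subchain_offset(ch, junction_chain(rt)) >= 0L, FALSE))
  }

  for (g in genes) {
    t1 <- gene_tx(g, 1L)
    n <- g$n_slots
    # FSM x2: reference chains with jittered terminal ends
    for (j in 1:2) {
      pick <- sample(seq_along(g$subsets), 1L)
      rt <- gene_tx(g, pick)
      st <- rt$starts; en <- rt$ends
      st[1L] <- max(0L, st[1L] - sample(0:50, 1L))
      en[length(en)] <- en[length(en)] + sample(0:50, 1L)
      add_query(transcript_model(sprintf("%s.FSM%d", g$gene_id, j),
                                 g$seq_name, g$strand, st, en),
                "FSM", g$gene_id)
    }
    # ISM x2: drop first exon (5'-missing on +) and last exon
    for (j in 1:2) {
      idx <- if (j == 1L) 2:n else 1:(n - 1L)
      t <- transcript_model(sprintf("%s.ISM%d", g$gene_id, j),
                            g$seq_name, g$strand, g$starts[idx], g$ends[idx])
      drop_left <- (j == 1L)
      missing <- if (drop_left == (g$strand == "+")) "5p" else "3p"
      if (!chain_known(t)) add_query(t, "ISM", g$gene_id, ism_missing = missing)
    }
    # NIC: an uncatalogued combination of catalogued sites
    for (sub in nic_subsets(g)) {
      t <- transcript_model(sprintf("%s.NIC1", g$gene_id), g$seq_name,
                            g$strand, g$starts[sub], g$ends[sub])
      if (!chain_known(t) && !is_subchain(t) &&
          all(splice_site_keys(t) %in% ref$splice_sites)) {
        add_query(t, "NIC", g$gene_id)
        break
      }
    }
    # NNC: shift one interior acceptor >= 10 bp from every reference site
    st <- g$starts; en <- g$ends
    slot <- sample(setdiff(seq_len(n), 1L), 1L)
    sites <- ref_sites_by_seq[[g$seq_name]]
    shifted <- NA_integer_
    for (delta in sample(c(-40:-12, 12:40))) {
      cand <- st[slot] + delta
      if (cand > en[slot - 1L] && cand < en[slot] - 20L &&
          all(abs(sites - cand) >= 10L)) { shifted <- cand; break }
    }
    if (!is.na(shifted)) {
      st[slot] <- shifted
      add_query(transcript_model(sprintf("%s.NNC1", g$gene_id), g$seq_name,
                                 g$strand, st, en), "NNC", g$gene_id)
    }
    # antisense: a reference chain on the opposite strand
    anti_strand <- if (g$strand == "+") "-" else "+"
    add_query(transcript_model(sprintf("%s.AS1", g$gene_id), g$seq_name,
                               anti_strand, t1$starts, t1$ends),
              "antisense", paste0(g$gene_id, ".AS"))
  }
  # intergenic: multi-exon models >= 10 kb from every gene span
  n_intergenic <- max(2L, round(cfg$n_genes / 2))
  gene_max <- vapply(seq_names, function(sq) {
    e <- vapply(genes, function(g)
      if (g$seq_name == sq) max(g$ends) else 0L, 0L)
    max(c(e, 0L))
  }, 0L)
  ig_cursor <- gene_max + 10000L
  for (i in seq_len(n_intergenic)) {
    sq <- seq_names[(i - 1L) %% cfg$n_seqs + 1L]
    lo <- ig_cursor[sq]
    ig_cursor[sq] <- ig_cursor[sq] + 2500L
    if (lo + 3000L > cfg$seq_length)
      stop("genome too short for ", n_intergenic, " intergenic models")
    starts <- lo + cumsum(c(0L, 200L + sample(300:800, 2L)))
    ends <- starts + sample(100:200, 3L, replace = TRUE)
    add_query(transcript_model(sprintf("GNOVEL%02d.IG1", i), sq,
                               sample(c("+", "-"), 1L), starts, ends),
              "intergenic", sprintf("GNOVEL%02d", i))
  }
  names(queries) <- truth$transcript_id

  ## ---- poly(A) tracts downstream of selected TTSs ----
  n_q <- length(queries)
  polyA_idx <- sort(sample(n_q, round(cfg$polyA_track_fraction * n_q)))
  truth$polyA_planted <- seq_len(n_q) %in% polyA_idx
  window <- 20L
  for (i in polyA_idx) {
    t <- queries[[i]]
    tract <- paste0(strrep("A", cfg$polyA_A_count),
                    paste(sample(c("C", "G", "T"),
                                 window - cfg$polyA_A_count, replace = TRUE),
                          collapse = ""))
    if (t$strand == "+") {
      pos <- tx_end(t); s <- tract
    } else {
      pos <- tx_start(t) - window; s <- revcomp(tract)
    }
    genome_chars[[t$seq_name]][(pos + 1L):(pos + window)] <-
      strsplit(s, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            "", collapse = ""))
  names(genome) <- seq_names
  truth$polyA_A_count <- vapply(queries, function(t)
    downstream_A_count(t, genome, window)$count, 0L)

  ## ---- distribute queries over long-read samples ----
  lr_samples <- sprintf("LR%02d", seq_len(cfg$n_lr_samples))
  n_obs <- sample(c(1L, 2L, 3L), n_q, replace = TRUE, prob = c(0.2, 0.4, 0.4))
  truth$n_samples <- pmin(n_obs, cfg$n_lr_samples)
  membership <- lapply(truth$n_samples, function(k) sample(lr_samples, k))
  per_sample_models <- stats::setNames(lapply(lr_samples, function(s) {
    idx <- which(vapply(membership, function(m) s %in% m, FALSE))
    lapply(queries[idx], function(t) { t$source_sample <- s; t })
  }), lr_samples)

  ## ---- short-read junction support ----
  # One support row per distinct junction across all queries. Transcripts
  # flagged unsupported lose one junction that no other query shares (so
  # the flag cannot be rescued by a shared junction).
  jk_list <- lapply(queries, junction_keys)
  jk_tab <- table(unlist(jk_list))
  private_keys <- lapply(jk_list, function(k) k[jk_tab[k] == 1L])
  droppable <- which(lengths(private_keys) > 0L)
  unsup_idx <- sort(sample(droppable,
                           min(round(cfg$unsupported_fraction * n_q),
                               length(droppable))))
  truth$junction_unsupported <- seq_len(n_q) %in% unsup_idx
  excluded <- vapply(unsup_idx, function(i) {
    ks <- private_keys[[i]]
    ks[sample(length(ks), 1L)]
  }, "")
  all_keys <- setdiff(unique(unlist(jk_list)), excluded)
  kp <- strsplit(all_keys, "|", fixed = TRUE)
  junc_rows <- data.frame(
    seq_name = vapply(kp, `[[`, "", 1L),
    start = as.integer(vapply(kp, `[[`, "", 3L)) + 1L,
    end = as.integer(vapply(kp, `[[`, "", 4L)),
    strand = vapply(kp, `[[`, "", 2L),
    count = stats::rpois(length(kp), 20) + 1L,
    stringsAsFactors = FALSE)
  junc_rows <- junc_rows[order(junc_rows$seq_name, junc_rows$start,
                               junc_rows$end, junc_rows$strand), ]
  split_1 <- stats::rbinom(nrow(junc_rows), junc_rows$count, 0.5)

  ## ---- expression cohorts with planted effects ----
  truth$tx2gene <- truth$gene_id
  all_samples <- c(sprintf("T%02d", seq_len(cfg$n_tumour)),
                   sprintf("N%02d", seq_len(cfg$n_normal)),
                   sprintf("M%02d", seq_len(cfg$n_metastasis)),
                   sprintf("P%02d", seq_len(cfg$n_primary)))
  groups <- stats::setNames(rep(c("tumour", "normal", "metastasis", "primary"),
                                c(cfg$n_tumour, cfg$n_normal,
                                  cfg$n_metastasis, cfg$n_primary)),
                            all_samples)
  baseline <- stats::rlnorm(n_q, cfg$baseline_meanlog, cfg$baseline_sdlog)
  noise <- function(n) stats::rlnorm(n, 0, cfg$noise_sdlog)

  # planted switch genes: reciprocal 4x pair, gene sum conserved
  # switch pairs drawn from non-ISM members only: ISMs are excluded from
  # differential testing downstream, so a planted pair must be testable
  testable <- truth$category %in% c("FSM", "NIC", "NNC")
  real_genes <- unique(truth$gene_id[!grepl("\\.AS$|^GNOVEL", truth$gene_id)])
  eligible <- real_genes[vapply(real_genes, function(g)
    sum(truth$gene_id == g & testable) >= 2L, FALSE)]
  switch_genes <- sort(sample(eligible,
                              round(cfg$switch_fraction * length(eligible))))
  truth_genes <- data.frame(gene_id = sort(unique(truth$gene_id)),
                            is_switch = FALSE,
                            up_transcript = NA_character_,
                            down_transcript = NA_character_,
                            stringsAsFactors = FALSE)
  switch_members <- character(0)
  mean_by <- list()
  for (g in switch_genes) {
    pair <- sample(truth$transcript_id[truth$gene_id == g & testable], 2L)
    m <- stats::rlnorm(1L, cfg$baseline_meanlog, cfg$baseline_sdlog)
    # up transcript: normal m -> tumour 4m; down: normal 4m -> tumour m
    mean_by[[pair[1L]]] <- list(tumour = 4 * m, other = m)
    mean_by[[pair[2L]]] <- list(tumour = m, other = 4 * m)
    switch_members <- c(switch_members, pair)
    k <- truth_genes$gene_id == g
    truth_genes$is_switch[k] <- TRUE
    truth_genes$up_transcript[k] <- pair[1L]
    truth_genes$down_transcript[k] <- pair[2L]
  }
  # planted SRTs (tumour arm) and metastasis SRTs; switch-gene members are
  # excluded so planted switches keep their gene-level sums conserved
  free <- truth$transcript_id[!truth$gene_id %in% switch_genes]
  srt_ids <- sort(sample(free, round(cfg$srt_fraction * n_q)))
  free <- setdiff(free, srt_ids)
  met_ids <- sort(sample(free, round(cfg$met_srt_fraction * n_q)))
  truth$is_srt <- truth$transcript_id %in% srt_ids
  truth$is_met_srt <- truth$transcript_id %in% met_ids

  values <- matrix(0, n_q, length(all_samples),
                   dimnames = list(truth$transcript_id, all_samples))
  grp_cols <- split(seq_along(all_samples), groups[all_samples])
  for (i in seq_len(n_q)) {
    id <- truth$transcript_id[i]
    for (grp in names(grp_cols)) {
      cols <- grp_cols[[grp]]
      base <- baseline[i]
      if (id %in% names(mean_by))
        base <- if (grp == "tumour") mean_by[[id]]$tumour else mean_by[[id]]$other
      v <- base * noise(length(cols))
      if (truth$is_srt[i]) {
        if (grp == "tumour") v <- baseline[i] * cfg$srt_effect * noise(length(cols))
        if (grp == "normal") v <- stats::runif(length(cols), 0, 0.05)
      }
      if (truth$is_met_srt[i]) {
        if (grp == "metastasis")
          v <- baseline[i] * cfg$met_srt_effect * noise(length(cols))
        if (grp == "primary") v <- stats::runif(length(cols), 0, 0.05)
      }
      values[i, cols] <- v
    }
  }
  em <- expression_matrix(values, groups)

  ## ---- write artifacts ----
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    reference = file.path(out_dir, "reference.gtf"),
    queries = stats::setNames(file.path(out_dir, paste0(lr_samples, ".gtf")),
                              lr_samples),
    junctions = file.path(out_dir, c("junctions_01.tsv", "junctions_02.tsv")),
    expression = file.path(out_dir, "expression.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    tx2gene = file.path(out_dir, "tx2gene.tsv"),
    truth_transcripts = file.path(out_dir, "truth_transcripts.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"))
  Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
  write_gtf(ref_models, paths$reference)
  for (s in lr_samples) write_gtf(per_sample_models[[s]], paths$queries[[s]])
  j1 <- junc_rows; j1$count <- split_1
  j2 <- junc_rows; j2$count <- junc_rows$count - split_1
  for (k in 1:2) {
    jk <- list(j1, j2)[[k]]
    jk <- jk[jk$count > 0, , drop = FALSE]
    utils::write.table(jk, paths$junctions[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_expression(em, paths$expression, paths$groups)
  utils::write.table(data.frame(transcript_id = truth$transcript_id,
                                gene_id = truth$tx2gene),
                     paths$tx2gene, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth_transcripts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(config = cfg, paths = paths,
                 truth_transcripts = truth, truth_genes = truth_genes,
                 ref = ref, queries = unname(queries),
                 per_sample_models = per_sample_models,
                 genome = genome, expression = em,
                 tx2gene = stats::setNames(truth$tx2gene,
                                           truth$transcript_id)))
}

#' Simulate a null expression cohort (no planted effects)
#'
#' Convenience generator for calibration studies: per-transcript log-normal
#' baselines with iid multiplicative noise in two groups, no signal.
#'
#' @param n_transcripts Number of features.
#' @param n_a,n_b Samples per group (labels `"a"`, `"b"`).
#' @param seed Integer seed.
#' @param meanlog,sdlog,noise_sdlog Log-normal parameters as in
#'   [simulation_config()].
#' @return An `expression_matrix`.
#' @export
simulate_null_expression <- function(n_transcripts, n_a, n_b, seed = 1L,
                                     meanlog = 3, sdlog = 1,
                                     noise_sdlog = 0.4) {
  set.seed(seed)
  base <- stats::rlnorm(n_transcripts, meanlog, sdlog)
  vals <- base * matrix(stats::rlnorm(n_transcripts * (n_a + n_b),
                                      0, noise_sdlog),
                        n_transcripts, n_a + n_b)
  dimnames(vals) <- list(sprintf("TX%05d", seq_len(n_transcripts)),
                         c(sprintf("A%03d", seq_len(n_a)),
                           sprintf("B%03d", seq_len(n_b))))
  expression_matrix(vals, stats::setNames(rep(c("a", "b"), c(n_a, n_b)),
                                          colnames(vals)))
}
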