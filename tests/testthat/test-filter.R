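ref <- fixture_ref()

mk_support <- function(rows) {
  f <- tempfile()
  writeLines(rows, f)
  read_junction_support(f)
}

test_that("junction filter requires every junction to be observed", {
  t2 <- transcript_model("Q1", "chr1", "+", c(100, 300, 500), c(200, 400, 600))
  calls <- classify_all(list(t2), ref)
  # support for only one of two junctions -> fail
  s <- mk_support("chr1\t201\t300\t+\t5")
  r <- junction_support_filter(list(t2), calls, s)
  expect_false(r$pass)
  expect_equal(r$rule, "junction_support")
  # both junctions at the threshold -> pass
  s2 <- mk_support(c("chr1\t201\t300\t+\t1", "chr1\t401\t500\t+\t1"))
  expect_true(junction_support_filter(list(t2), calls, s2)$pass)
  # mono-exon passes vacuously even with an empty table
  mono <- transcript_model("Q2", "chr2", "+", 50, 500)
  cm <- classify_all(list(mono), ref)
  expect_true(junction_support_filter(list(mono), cm,
                                      read_junction_support(character(0)))$pass)
  # missing structural call is a contract violation
  expect_error(junction_support_filter(list(mono), calls, s), "call")
})

test_that("intrapriming boundary: 15 A pass, 16 A fail, FSM exempt, strands symmetric", {
  genome <- fixture_genome()
  nic <- transcript_model("Q", "chr1", "+", c(100, 500), c(200, 600))
  calls <- classify_all(list(nic), ref)
  expect_equal(calls$category, "NIC")
  for (nA in c(15L, 16L, 20L)) {
    g <- genome_with(genome, "chr1", 600,
                     paste0(strrep("A", nA), strrep("G", 20 - nA)))
    r <- intrapriming_filter(list(nic), calls, g)
    expect_equal(r$A_count, nA)
    expect_equal(r$pass, nA < 16)
  }
  # FSM with a full downstream A-tract is retained
  fsm <- transcript_model("Q", "chr1", "+", c(100, 300, 500), c(200, 400, 600))
  cf <- classify_all(list(fsm), ref)
  expect_equal(cf$category, "FSM")
  g <- genome_with(genome, "chr1", 600, strrep("A", 20))
  expect_true(intrapriming_filter(list(fsm), cf, g)$pass)
  # minus strand: genomic T upstream reads as A on the transcript strand
  nnc_minus <- transcript_model("Q", "chr1", "-", c(2000, 2150), c(2100, 2300))
  cm <- classify_all(list(nnc_minus), ref)
  expect_equal(cm$category, "NNC")
  gt <- genome_with(genome, "chr1", 1980, strrep("T", 20))
  rm_ <- intrapriming_filter(list(nnc_minus), cm, gt)
  expect_equal(rm_$A_count, 20L)
  expect_false(rm_$pass)
})

test_that("window truncation at the sequence edge is counted and flagged", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 610)))
  nic <- transcript_model("Q", "chr1", "+", c(100, 500), c(200, 600))
  calls <- classify_all(list(nic), ref)
  r <- intrapriming_filter(list(nic), calls, genome)
  expect_true(r$window_truncated)
  expect_equal(r$A_count, 10L)  # only 10 bases remain downstream
  expect_true(r$pass)
})

test_that("ISM 3'-truncated models are dropped; 5'-truncated kept", {
  # 4-exon reference so sub-chains cannot coincide with another full chain
  ref_local <- reference_annotation(list(
    transcript_model("TD1", "chr1", "+", c(5000, 5200, 5400, 5600),
                     c(5100, 5300, 5500, 5700), gene_id = "GD")))
  ism_3p <- transcript_model("Q1", "chr1", "+", c(5000, 5200, 5400),
                             c(5100, 5300, 5500))
  ism_5p <- transcript_model("Q2", "chr1", "+", c(5220, 5400, 5600),
                             c(5300, 5500, 5680))
  models <- list(ism_3p, ism_5p)
  calls <- classify_all(models, ref_local)
  calls$ref_chain_len <- vapply(calls$matched_ref, function(m)
    nrow(junction_chain(ref_local$transcripts[[m]])), 0L)
  expect_equal(calls$category, c("ISM", "ISM"))
  r <- ism_end_filter(models, calls)
  expect_equal(r$pass, c(FALSE, TRUE))
  # disabled flag keeps both
  r2 <- ism_end_filter(models, calls, filter_config(filter_ism_ends = FALSE))
  expect_true(all(r2$pass))
})

test_that("non-redundant merge: chain identity, outermost ends, occurrence counts", {
  s1 <- list(transcript_model("A", "chr1", "+", c(100, 300), c(200, 400)))
  s2 <- list(transcript_model("B", "chr1", "+", c(120, 300), c(200, 450)))
  m <- merge_nonredundant(list(S1 = s1, S2 = s2))
  expect_length(m$models, 1)
  expect_equal(m$models[[1]]$starts[1], 100L)
  expect_equal(max(m$models[[1]]$ends), 450L)
  expect_equal(m$occurrences$n_samples, 2)
  # a chain differing in one junction stays separate
  s3 <- list(transcript_model("C", "chr1", "+", c(100, 310), c(200, 400)))
  m2 <- merge_nonredundant(list(S1 = s1, S3 = s3))
  expect_length(m2$models, 2)
})

test_that("mono-exon merge needs >= 50% reciprocal overlap", {
  a <- transcript_model("A", "chr1", "+", 0, 100)
  b <- transcript_model("B", "chr1", "+", 60, 160)    # 40/100 reciprocal
  c_ <- transcript_model("C", "chr1", "+", 40, 140)   # 60% with both
  expect_length(merge_nonredundant(list(S1 = list(a), S2 = list(b)))$models, 2)
  m <- merge_nonredundant(list(S1 = list(a), S2 = list(c_)))
  expect_length(m$models, 1)
  expect_equal(m$models[[1]]$ends, 140L)
})

test_that("replicate filter keeps transcripts seen in enough samples", {
  s1 <- list(transcript_model("A", "chr1", "+", c(100, 300), c(200, 400)),
             transcript_model("X", "chr1", "+", c(100, 320), c(200, 400)))
  s2 <- list(transcript_model("A2", "chr1", "+", c(100, 300), c(200, 400)))
  merged <- merge_nonredundant(list(S1 = s1, S2 = s2))
  kept <- replicate_filter(merged, filter_config(min_replicates = 2))
  expect_equal(vapply(kept$models, `[[`, "", "transcript_id"), "A")
  # min_replicates = 1 is the identity
  all_kept <- replicate_filter(merged, filter_config(min_replicates = 1))
  expect_length(all_kept$models, 2)
})

test_that("threshold monotonicity: stricter settings never grow the pass set", {
  set.seed(202)
  for (rep in 1:30) {
    sim <- simulate_dataset(simulation_config(
      seed = 300 + rep, n_genes = 4L, n_lr_samples = 3L,
      seq_length = 120000L, unsupported_fraction = 0.2,
      polyA_track_fraction = 0.3), file.path(tempdir(), paste0("mono", rep)))
    support <- read_junction_support(sim$paths$junctions)
    calls <- classify_all(sim$queries, sim$ref)
    prev <- NULL
    for (mjr in c(1, 5, 25)) {
      p <- junction_support_filter(sim$queries, calls, support,
                                   filter_config(min_junction_reads = mjr))
      ids <- p$transcript_id[p$pass]
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
    prev <- NULL
    for (minA in c(20, 16, 10, 1)) {
      p <- intrapriming_filter(sim$queries, calls, sim$genome,
                               filter_config(polyA_min_A = minA,
                                             polyA_window = 20))
      ids <- p$transcript_id[p$pass]
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
    merged <- merge_nonredundant(sim$per_sample_models)
    prev <- NULL
    for (mr in 1:3) {
      kept <- replicate_filter(merged, filter_config(min_replicates = mr))
      ids <- kept$occurrences$transcript_id
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("full cascade removes planted artifacts and keeps FSM with A-tracts", {
  sim <- simulate_dataset(simulation_config(seed = 5), file.path(tempdir(), "casc"))
  support <- read_junction_support(sim$paths$junctions)
  res <- filter_isoforms(sim$per_sample_models, sim$ref, sim$genome, support)
  truth <- sim$truth_transcripts
  rep_report <- res$report
  tract <- truth$polyA_A_count >= 16
  # every non-FSM transcript with a downstream A-tract is removed
  non_fsm_tract <- truth$transcript_id[tract & truth$category != "FSM"]
  expect_true(all(!rep_report$pass[rep_report$transcript_id %in% non_fsm_tract]))
  # FSM transcripts are never removed for intrapriming
  fsm_tract <- truth$transcript_id[tract & truth$category == "FSM"]
  fsm_rows <- rep_report[rep_report$transcript_id %in% fsm_tract, ]
  expect_true(all(fsm_rows$pass | fsm_rows$rule != "intrapriming"))
  # junction-unsupported transcripts all fail the junction rule
  unsup <- truth$transcript_id[truth$junction_unsupported]
  expect_true(all(rep_report$rule[rep_report$transcript_id %in% unsup] ==
                    "junction_support"))
})
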