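ref <- fixture_ref()

test_that("worked examples hit every multi-exon category", {
  # exact chain match
  q <- transcript_model("Q", "chr1", "+", c(120, 300, 500), c(200, 400, 580))
  c1 <- classify_transcript(q, ref)
  expect_equal(c1$category, "FSM")
  expect_equal(c1$matched_ref, "TA1")
  # contiguous sub-chain
  q <- transcript_model("Q", "chr1", "+", c(320, 500), c(400, 590))
  c2 <- classify_transcript(q, ref)
  expect_equal(c2$category, "ISM")
  expect_equal(c2$assigned_gene, "GA")
  # known sites, unseen combination: junction (200,300) from TA1/TA2 plus
  # (450,500) known only from TA3
  q <- transcript_model("Q", "chr1", "+", c(100, 300, 500), c(200, 450, 600))
  expect_equal(classify_transcript(q, ref)$category, "FSM")  # TA3 itself
  q <- transcript_model("Q", "chr1", "+", c(100, 420, 500), c(200, 450, 600))
  # acceptor 420 is novel -> NNC
  expect_equal(classify_transcript(q, ref)$category, "NNC")
  # antisense: minus-strand query over plus-strand gene GA
  q <- transcript_model("Q", "chr1", "-", c(100, 300), c(200, 400))
  expect_equal(classify_transcript(q, ref)$category, "antisense")
  # intergenic: far from all genes
  q <- transcript_model("Q", "chr1", "+", c(60000, 61000), c(60500, 61500))
  c6 <- classify_transcript(q, ref)
  expect_equal(c6$category, "intergenic")
  expect_true(is.na(c6$assigned_gene))
})

test_that("a recombined chain of known sites is NIC (brute-force confirmed)", {
  # TA1 chain (200,300),(400,500); TA3 chain (200,300),(450,500).
  # Query (200,300),(400,450->no)... use donor 400 with acceptor 500 known,
  # but skip the middle exon of TA1: chain (200,500) uses known donor 200
  # and known acceptor 500 in an uncatalogued junction.
  q <- transcript_model("Q", "chr1", "+", c(100, 500), c(200, 600))
  expect_equal(oracle_classify(q, fixture_ref_models()), "NIC")
  cl <- classify_transcript(q, ref)
  expect_equal(cl$category, "NIC")
  expect_equal(cl$assigned_gene, "GA")
})

test_that("mono-exon rules: FSM equality, ISM containment, other_genic, antisense", {
  expect_equal(classify_transcript(
    transcript_model("Q", "chr2", "+", 50, 500), ref)$category, "FSM")
  expect_equal(classify_transcript(
    transcript_model("Q", "chr2", "+", 100, 400), ref)$category, "ISM")
  # inside gene GA's span but not contained in any exon
  expect_equal(classify_transcript(
    transcript_model("Q", "chr1", "+", 230, 280), ref)$category,
    "other_genic")
  expect_equal(classify_transcript(
    transcript_model("Q", "chr2", "-", 100, 400), ref)$category, "antisense")
  expect_equal(classify_transcript(
    transcript_model("Q", "chr2", "+", 10000, 10100), ref)$category,
    "intergenic")
})

test_that("classify_all partitions queries and tallies to the input size", {
  qs <- list(
    transcript_model("Q1", "chr1", "+", c(120, 300, 500), c(200, 400, 580)),
    transcript_model("Q2", "chr1", "+", c(320, 500), c(400, 590)),
    transcript_model("Q3", "chr1", "-", c(100, 300), c(200, 400)),
    transcript_model("Q4", "chr2", "+", 10000, 10100))
  calls <- classify_all(qs, ref)
  tally <- attr(calls, "tally")
  expect_equal(sum(tally), 4)
  expect_true(all(calls$category %in% STRUCTURAL_CATEGORIES))
  expect_equal(nrow(classify_all(list(), ref)), 0)
  expect_error(classify_all(list(qs[[1]], qs[[1]]), ref), "duplicate")
})

test_that("classifier agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:120) {
    inst <- random_instance()
    r <- reference_annotation(inst$ref_models)
    got <- classify_transcript(inst$query, r)$category
    want <- oracle_classify(inst$query, inst$ref_models)
    expect_equal(got, want,
                 info = sprintf("instance %d: %s:%s", i,
                                inst$query$seq_name, inst$query$strand))
  }
})

test_that("adding reference transcripts never demotes an FSM", {
  set.seed(7)
  for (i in 1:25) {
    inst <- random_instance()
    r1 <- reference_annotation(inst$ref_models)
    if (classify_transcript(inst$query, r1)$category != "FSM") next
    extra <- random_instance()$ref_models
    extra <- lapply(seq_along(extra), function(j) {
      t <- extra[[j]]
      transcript_model(paste0("X", j), t$seq_name, t$strand, t$starts,
                       t$ends, gene_id = paste0("XG", j))
    })
    r2 <- reference_annotation(c(inst$ref_models, extra))
    expect_equal(classify_transcript(inst$query, r2)$category, "FSM")
  }
})

test_that("strand flip over a single-strand annotation maps genic categories to antisense", {
  set.seed(11)
  n_checked <- 0
  for (i in 1:60) {
    inst <- random_instance()
    strands <- vapply(inst$ref_models, `[[`, "", "strand")
    seqs <- vapply(inst$ref_models, `[[`, "", "seq_name")
    one_strand <- inst$ref_models[strands == "+" & seqs == "chr1"]
    if (length(one_strand) == 0) next
    r <- reference_annotation(one_strand)
    q <- inst$query
    if (q$seq_name != "chr1" || q$strand != "+") next
    cat0 <- classify_transcript(q, r)$category
    if (!cat0 %in% c("FSM", "ISM", "NIC", "NNC")) next
    flipped <- transcript_model("Q", q$seq_name, "-", q$starts, q$ends)
    expect_equal(classify_transcript(flipped, r)$category, "antisense")
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})
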