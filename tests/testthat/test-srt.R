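test_that("SRT thresholds behave as printed: >= 10x the max normal, > 5% prevalence", {
  em <- fixture_em(list(
    HIT  = c(rep(5, 10), rep(0.4, 10)),    # median 5 >= 10 x 0.4
    NEAR = c(rep(4, 10), c(rep(0.1, 9), 0.5)),  # 4 < 10 x 0.5
    ZERO = rep(0, 20)),
    n_a = 10, n_b = 10)
  res <- call_srt(em, "tumour", "normal")
  expect_equal(res$is_srt, c(TRUE, FALSE, FALSE))
  hit <- res[res$transcript_id == "HIT", ]
  expect_true(hit$passes_i && hit$passes_ii)
  expect_equal(hit$prevalence, 1)
  # all-zero transcript is blocked by the median > 0 guard, not prevalence
  zero <- res[res$transcript_id == "ZERO", ]
  expect_false(zero$passes_i)
})

test_that("boundary: exactly 10x the max normal is inclusive", {
  em <- fixture_em(list(EDGE = c(rep(4, 10), rep(0.4, 10))), n_a = 10, n_b = 10)
  expect_true(call_srt(em, "tumour", "normal")$is_srt)
})

test_that("prevalence is a strict greater-than", {
  # 1 of 20 tumour samples expressed = 5% exactly -> fails "more than 5%"
  em <- fixture_em(list(TX = c(c(10, rep(0, 19)), rep(0, 20))),
                   n_a = 20, n_b = 20)
  res <- call_srt(em, "tumour", "normal")
  expect_false(res$passes_ii)
  # 2 of 20 = 10% passes
  em2 <- fixture_em(list(TX = c(c(10, 10, rep(0, 18)), rep(0, 20))),
                    n_a = 20, n_b = 20)
  expect_true(call_srt(em2, "tumour", "normal")$passes_ii)
})

test_that("adding a normal sample never creates an SRT", {
  set.seed(12)
  vals <- matrix(rlnorm(50 * 11, 2, 1), 50,
                 dimnames = list(sprintf("TX%02d", 1:50),
                                 c(sprintf("t%d", 1:5), sprintf("n%d", 1:6))))
  groups <- setNames(rep(c("tumour", "normal"), c(5, 6)), colnames(vals))
  em_full <- expression_matrix(vals, groups)
  em_less <- expression_matrix(vals[, 1:10], groups[1:10])
  srt_full <- call_srt(em_full, "tumour", "normal")
  srt_less <- call_srt(em_less, "tumour", "normal")
  expect_true(all(srt_full$is_srt <= srt_less$is_srt))
})

test_that("scaling tumour samples up never removes a criterion (i) call", {
  set.seed(13)
  vals <- matrix(rlnorm(40 * 10, 1, 1.5), 40,
                 dimnames = list(sprintf("TX%02d", 1:40),
                                 c(sprintf("t%d", 1:5), sprintf("n%d", 1:5))))
  groups <- setNames(rep(c("tumour", "normal"), each = 5), colnames(vals))
  before <- call_srt(expression_matrix(vals, groups), "tumour", "normal")
  vals2 <- vals; vals2[, 1:5] <- vals2[, 1:5] * 3
  after <- call_srt(expression_matrix(vals2, groups), "tumour", "normal")
  expect_true(all(after$passes_i >= before$passes_i))
})

test_that("fold-threshold limits: infinity empties, 1-with-0-prevalence saturates", {
  sim_em <- simulate_null_expression(100, 8, 8, seed = 3)
  colnames(sim_em$values)
  em <- expression_matrix(sim_em$values,
                          setNames(rep(c("tumour", "normal"), each = 8),
                                   colnames(sim_em$values)))
  huge <- call_srt(em, "tumour", "normal", srt_config(fold_threshold = 1e12))
  expect_equal(sum(huge$is_srt), 0)
  lax <- call_srt(em, "tumour", "normal",
                  srt_config(fold_threshold = 1 + 1e-12,
                             prevalence_fraction = 0))
  manual <- apply(em$values[, 1:8], 1, median) >=
    apply(em$values[, 9:16], 1, max) &
    apply(em$values[, 1:8], 1, median) > 0
  expect_true(all(lax$is_srt[manual & lax$prevalence > 0]))
})

test_that("metastasis caller uses pseudocount median ratios with strict >", {
  em <- fixture_em(list(
    A = c(rep(8, 6), rep(0.1, 6)),    # (8.01/0.11) = 72.8 > 10
    B = c(rep(2, 6), rep(2, 6)),      # ratio 1
    C = c(rep(0.9, 6), rep(0, 6))),   # (0.91/0.01) = 91 > 10
    n_a = 6, n_b = 6, groups = c("metastasis", "primary"))
  res <- call_metastasis_srt(em, "metastasis", "primary")
  expect_equal(res$fold_change[1], 8.01 / 0.11, tolerance = 1e-12)
  expect_equal(res$is_srt, c(TRUE, FALSE, TRUE))
  # C passes only because prevalence (0.9 > 0.5 TPM in all samples) holds
  expect_true(res$passes_ii[3])
  # optional normal-tissue criterion
  em2 <- expression_matrix(
    cbind(em$values, n1 = c(0.1, 0.1, 5), n2 = c(0.2, 0.1, 6)),
    c(em$groups, n1 = "normal", n2 = "normal"))
  res2 <- call_metastasis_srt(em2, "metastasis", "primary",
                              normal_groups = "normal",
                              require_normal_low = TRUE)
  expect_equal(res2$is_srt, c(TRUE, FALSE, FALSE))
})

test_that("planted SRTs are recovered perfectly on the default cohort", {
  sim <- simulate_dataset(simulation_config(seed = 2),
                          file.path(tempdir(), "srtsim"))
  truth <- sim$truth_transcripts
  res <- call_srt(sim$expression, "tumour", "normal")
  expect_setequal(res$transcript_id[res$is_srt],
                  truth$transcript_id[truth$is_srt])
  met <- call_metastasis_srt(sim$expression, "metastasis", "primary")
  expect_setequal(met$transcript_id[met$is_srt],
                  truth$transcript_id[truth$is_met_srt])
})
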