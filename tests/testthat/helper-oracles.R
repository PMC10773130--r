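# Independent oracles, deliberately written from the category definitions /
# textbook formulas rather than sharing code with the implementation.

# ---- brute-force structural classifier -------------------------------------

oracle_chain <- function(t) {
  n <- length(t$starts)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(t$ends[-n], t$starts[-1])
}

oracle_chain_id <- function(ch) paste(ch[, 1], ch[, 2], sep = "-", collapse = ";")

# Literal application of the category definitions: enumerate every reference
# chain and every contiguous sub-chain, then check site catalogues and
# gene-span overlaps.
oracle_classify <- function(query, ref_models) {
  gid <- vapply(ref_models, `[[`, "", "gene_id")
  spans <- do.call(rbind, lapply(split(seq_along(ref_models), gid), function(i) {
    data.frame(gene_id = ref_models[[i[1]]]$gene_id,
               seq = ref_models[[i[1]]]$seq_name,
               strand = ref_models[[i[1]]]$strand,
               start = min(vapply(ref_models[i], function(t) t$starts[1], 0)),
               end = max(vapply(ref_models[i], function(t) max(t$ends), 0)))
  }))
  q_start <- query$starts[1]; q_end <- max(query$ends)
  hits_same <- spans$seq == query$seq_name & spans$strand == query$strand &
    q_start < spans$end & q_end > spans$start
  hits_anti <- spans$seq == query$seq_name & spans$strand != query$strand &
    q_start < spans$end & q_end > spans$start
  same_models <- ref_models[gid %in% spans$gene_id &
                              vapply(ref_models, function(t)
                                t$seq_name == query$seq_name &&
                                  t$strand == query$strand, FALSE)]

  if (length(query$starts) == 1) {
    for (rt in same_models)
      if (length(rt$starts) == 1 && rt$starts[1] == query$starts[1] &&
          rt$ends[1] == query$ends[1]) return("FSM")
    for (rt in same_models)
      if (any(rt$starts <= q_start & rt$ends >= q_end)) return("ISM")
    if (any(hits_same)) return("other_genic")
    if (any(hits_anti)) return("antisense")
    return("intergenic")
  }

  qch <- oracle_chain(query)
  qid <- oracle_chain_id(qch)
  # all reference chains
  for (rt in same_models) {
    rch <- oracle_chain(rt)
    if (nrow(rch) && oracle_chain_id(rch) == qid) return("FSM")
  }
  # all contiguous sub-chains of all reference chains
  for (rt in same_models) {
    rch <- oracle_chain(rt)
    if (nrow(rch) < nrow(qch)) next
    for (i in seq_len(nrow(rch) - nrow(qch) + 1))
      for (len in nrow(qch))
        if (oracle_chain_id(rch[i:(i + len - 1), , drop = FALSE]) == qid)
          return("ISM")
  }
  donors <- unique(unlist(lapply(same_models, function(t) oracle_chain(t)[, 1])))
  acceptors <- unique(unlist(lapply(same_models, function(t) oracle_chain(t)[, 2])))
  if (all(qch[, 1] %in% donors) && all(qch[, 2] %in% acceptors)) return("NIC")
  if (any(hits_same)) return("NNC")
  if (any(hits_anti)) return("antisense")
  "intergenic"
}

# Random small reference + query instances for oracle-equivalence testing.
random_instance <- function() {
  n_genes <- sample(1:10, 1)
  models <- list(); tid <- 0
  for (g in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    seqn <- sample(c("chr1", "chr2"), 1)
    origin <- sample(seq(0, 100000, by = 2000), 1)
    n_slots <- sample(2:6, 1)
    ex_len <- sample(50:150, n_slots, replace = TRUE)
    in_len <- sample(30:500, max(1, n_slots - 1), replace = TRUE)
    starts <- origin + cumsum(c(0, head(ex_len, -1) + head(in_len, n_slots - 1)))
    ends <- starts + ex_len
    for (k in seq_len(sample(1:5, 1))) {
      tid <- tid + 1
      keep <- sort(sample(n_slots, sample(seq_len(n_slots), 1)))
      models[[length(models) + 1]] <-
        transcript_model(sprintf("T%03d", tid), seqn, strand,
                         starts[keep], ends[keep],
                         gene_id = sprintf("G%02d", g))
    }
  }
  # query: perturb a reference transcript or invent one
  base <- models[[sample(length(models), 1)]]
  mode <- sample(c("copy", "window", "shift", "flip", "mono", "random"), 1)
  q <- switch(mode,
    copy = transcript_model("Q", base$seq_name, base$strand,
                            c(max(0, base$starts[1] - sample(0:40, 1)),
                              base$starts[-1]),
                            c(base$ends[-length(base$ends)],
                              max(base$ends) + sample(0:40, 1))),
    window = {
      n <- length(base$starts)
      i <- sort(sample(n, min(n, sample(1:4, 1))))
      i <- i[1]:i[length(i)]
      transcript_model("Q", base$seq_name, base$strand,
                       base$starts[i], base$ends[i])
    },
    shift = {
      st <- base$starts; en <- base$ends
      j <- sample(length(st), 1)
      st[j] <- st[j] + sample(c(-25:-5, 5:25), 1)
      if (any(st >= en) ||
          (length(st) > 1 && (is.unsorted(st, strictly = TRUE) ||
                              any(st[-1] <= en[-length(en)]))))
        base
      else transcript_model("Q", base$seq_name, base$strand, st, en)
    },
    flip = transcript_model("Q", base$seq_name,
                            if (base$strand == "+") "-" else "+",
                            base$starts, base$ends),
    mono = {
      p <- sample(0:120000, 1)
      transcript_model("Q", sample(c("chr1", "chr2"), 1),
                       sample(c("+", "-"), 1), p, p + sample(30:400, 1))
    },
    random = {
      p <- sample(0:120000, 1)
      st <- p + cumsum(c(0, sample(100:400, 2, replace = TRUE)))
      transcript_model("Q", sample(c("chr1", "chr2"), 1),
                       sample(c("+", "-"), 1), st, st + sample(40:90, 3,
                                                               replace = TRUE))
    })
  if (q$transcript_id != "Q")
    q <- transcript_model("Q", q$seq_name, q$strand, q$starts, q$ends)
  list(ref_models = models, query = q)
}

# ---- statistics oracles -----------------------------------------------------

# Exact two-sided rank-sum p by full enumeration of all C(m+n, m) group
# assignments, replicating the conventional doubled one-tail convention.
oracle_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(i) sum(ranks[i])) - m * (m + 1) / 2
  if (u_obs > m * n / 2) p <- 2 * mean(u_all >= u_obs)
  else p <- 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Literal Benjamini-Hochberg step-up adjusted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# AUC as the mean pairwise concordance (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Trapezoidal integration of an ROC step curve.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}
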