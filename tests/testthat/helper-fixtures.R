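# Shared in-code fixtures: a small two-gene annotation used across tests.
#
# Gene GA (+, chr1): TA1 exons [100,200) [300,400) [500,600)   chain (200,300),(400,500)
#                    TA2 exons [100,200) [300,400)             chain (200,300)
#                    TA3 exons [100,200) [300,450) [500,600)   chain (200,300),(450,500)
# Gene GB (-, chr1): TB1 exons [2000,2100) [2200,2300)         chain (2100,2200)
# Gene GC (+, chr2): TC1 mono-exon [50,500)
fixture_ref_models <- function() {
  list(
    transcript_model("TA1", "chr1", "+", c(100, 300, 500), c(200, 400, 600),
                     gene_id = "GA"),
    transcript_model("TA2", "chr1", "+", c(100, 300), c(200, 400),
                     gene_id = "GA"),
    transcript_model("TA3", "chr1", "+", c(100, 300, 500), c(200, 450, 600),
                     gene_id = "GA"),
    transcript_model("TB1", "chr1", "-", c(2000, 2200), c(2100, 2300),
                     gene_id = "GB"),
    transcript_model("TC1", "chr2", "+", 50, 500, gene_id = "GC"))
}

fixture_ref <- function() reference_annotation(fixture_ref_models())

# Expression matrix with explicit values and two groups of n each.
fixture_em <- function(rows, n_a = 3, n_b = 3,
                       groups = c("tumour", "normal")) {
  values <- do.call(rbind, rows)
  colnames(values) <- c(sprintf("a%d", seq_len(n_a)),
                        sprintf("b%d", seq_len(n_b)))
  expression_matrix(values,
                    setNames(rep(groups, c(n_a, n_b)), colnames(values)))
}

# A genome where every window is a given string; sequences named chr1/chr2.
fixture_genome <- function(len = 5000, fill = "C") {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep(fill, len),
                                  chr2 = strrep(fill, len)))
  g
}

# Replace genome bases on [start, end) (0-based) of one sequence.
genome_with <- function(genome, seq_name, start, s) {
  x <- as.character(genome[[seq_name]])
  substr(x, start + 1, start + nchar(s)) <- s
  out <- as.character(genome)
  out[seq_name] <- x
  Biostrings::DNAStringSet(out)
}
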