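#' Read transcript models or a reference annotation from GTF
#'
#' Parses exon features from a GTF file (1-based closed coordinates) into
#' 0-based half-open transcript models. With `kind = "reference"` the models
#' are indexed into a [reference_annotation()]; with `kind = "query"` a plain
#' list of [transcript_model()] objects is returned.
#'
#' @param path Path to a GTF file. Every exon line must carry a
#'   `transcript_id` attribute; reference files must also carry `gene_id`.
#' @param kind `"reference"` or `"query"`.
#' @param source_sample Optional sample label attached to every query model.
#' @return A `reference_annotation` or a list of `transcript_model`.
#' @export
read_gtf <- function(path, kind = c("reference", "query"),
                     source_sample = NA_character_) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF ", path, ": ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type)) gr <- gr[as.character(md$type) == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF ", path)
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  if (is.null(md$transcript_id) || anyNA(tid))
    stop("GTF parse error in ", path, ": exon feature(s) ",
         paste(utils::head(which(is.na(tid)), 3L), collapse = ", "),
         " lack a transcript_id attribute")
  gid <- if (is.null(md$gene_id)) rep(NA_character_, length(gr))
         else as.character(md$gene_id)
  if (kind == "reference" && anyNA(gid))
    stop("GTF parse error in ", path, ": reference exon(s) lack gene_id")
  df <- data.frame(
    seq_name = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    transcript_id = tid, gene_id = gid,
    stringsAsFactors = FALSE)
  models <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$seq_name)) != 1L || length(unique(d$strand)) != 1L)
      stop("transcript ", d$transcript_id[1L],
           " has exons on mixed sequences or strands in ", path)
    d <- d[order(d$start), , drop = FALSE]
    transcript_model(d$transcript_id[1L], d$seq_name[1L], d$strand[1L],
                     d$start, d$end, gene_id = d$gene_id[1L],
                     source_sample = source_sample)
  })
  models <- unname(models[order(names(models))])
  if (kind == "query") models else reference_annotation(models)
}

#' Write transcript models to GTF
#'
#' Emits one exon line per exon, converting back to GTF's 1-based closed
#' coordinates. Models lacking a gene_id are written with gene_id equal to
#' their transcript_id (GTF requires the attribute). Output is byte-for-byte
#' deterministic for a given model list.
#'
#' @param models List of `transcript_model`.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_gtf <- function(models, path, source = "isotrx") {
  lines <- unlist(lapply(models, function(t) {
    gid <- if (is.na(t$gene_id)) t$transcript_id else t$gene_id
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            t$seq_name, source, t$starts + 1L, t$ends, t$strand, gid,
            t$transcript_id)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Build an indexed reference annotation from transcript models
#'
#' Indexes splice sites, junctions, and whole junction chains so that
#' structural classification is a series of exact lookups. Gene spans are the
#' union of member transcript spans.
#'
#' @param models List of `transcript_model`, each with a gene_id.
#' @return An object of class `reference_annotation` with components
#'   `transcripts` (named list), `genes` (data.frame gene_id/seq_name/strand/
#'   start/end), `splice_sites`, `junctions` (character key sets), and
#'   `chain_index` (chain key to transcript ids).
#' @export
reference_annotation <- function(models) {
  ids <- vapply(models, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript_id in reference: ",
                               ids[duplicated(ids)][1L])
  if (anyNA(vapply(models, `[[`, "", "gene_id")))
    stop("all reference transcripts need a gene_id")
  names(models) <- ids
  gid <- vapply(models, `[[`, "", "gene_id")
  genes <- do.call(rbind, lapply(split(seq_along(models), gid), function(i) {
    ms <- models[i]
    strands <- unique(vapply(ms, `[[`, "", "strand"))
    seqs <- unique(vapply(ms, `[[`, "", "seq_name"))
    if (length(strands) != 1L || length(seqs) != 1L)
      stop("gene ", ms[[1L]]$gene_id, " mixes strands or sequences")
    data.frame(gene_id = ms[[1L]]$gene_id, seq_name = seqs, strand = strands,
               start = min(vapply(ms, tx_start, 0L)),
               end = max(vapply(ms, tx_end, 0L)),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  chain_keys <- vapply(models, chain_key, "")
  chain_index <- lapply(split(ids, chain_keys), sort)
  structure(
    list(transcripts = models,
         genes = genes,
         splice_sites = unique(unlist(lapply(models, splice_site_keys))),
         junctions = unique(unlist(lapply(models, junction_keys))),
         chain_index = chain_index),
    class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> %d gene(s), %d transcript(s), %d junction(s)\n",
              nrow(x$genes), length(x$transcripts), length(x$junctions)))
  invisible(x)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet` named by sequence.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# Fetch genome sequence on [start, end) (0-based half-open), truncating at
# sequence bounds. Returns a list(seq = character, truncated = logical).
genome_window <- function(genome, seq_name, start, end) {
  if (!seq_name %in% names(genome))
    stop("sequence not in genome: ", seq_name)
  len <- length(genome[[seq_name]])
  s <- max(0L, start); e <- min(len, end)
  truncated <- (s != start) || (e != end)
  seq <- if (s >= e) "" else
    as.character(Biostrings::subseq(genome[[seq_name]], s + 1L, e))
  list(seq = seq, truncated = truncated)
}

#' Read and pool short-read splice-junction support
#'
#' Each file is tab-delimited with columns seq_name, intron start (1-based
#' inclusive), intron end (1-based inclusive), strand, read count — the
#' dominant aligner junction-output convention. Counts are summed across
#' files and coordinates normalised to 0-based half-open intron intervals.
#' A `"."` strand row matches queries on either strand.
#'
#' @param paths Character vector of file paths (may be empty).
#' @return An object of class `junction_support`; query it with
#'   [junction_support_count()].
#' @export
read_junction_support <- function(paths) {
  counts <- numeric(0)
  for (p in paths) {
    if (!file.exists(p)) stop("junction support file not found: ", p)
    d <- utils::read.table(p, sep = "\t", header = FALSE,
                           col.names = c("seq_name", "start", "end",
                                         "strand", "count"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric"))
    if (nrow(d) == 0L) next
    if (any(d$count < 0)) stop("negative junction read count in ", p)
    if (any(!d$strand %in% c("+", "-", ".")))
      stop("bad strand symbol in junction file ", p)
    key <- paste0(d$seq_name, "|", d$strand, "|", d$start - 1L, "|", d$end)
    agg <- tapply(d$count, key, sum)
    for (k in names(agg))
      counts[k] <- (if (k %in% names(counts)) counts[k] else 0) + agg[[k]]
  }
  structure(list(counts = counts), class = "junction_support")
}

#' Look up pooled read support for a junction
#'
#' @param support A `junction_support` table.
#' @param seq_name,strand,donor,acceptor Junction identity (0-based half-open
#'   intron interval). Unstranded (`"."`) table rows match either strand.
#' @return Non-negative numeric count; absent junctions count 0.
#' @export
junction_support_count <- function(support, seq_name, strand, donor, acceptor) {
  stopifnot(inherits(support, "junction_support"))
  keys <- paste0(seq_name, "|", c(strand, "."), "|", donor, "|", acceptor)
  sum(support$counts[keys[keys %in% names(support$counts)]])
}

#' Construct an expression matrix with sample groups
#'
#' @param values Non-negative numeric matrix, rows transcripts (unique
#'   rownames), columns samples.
#' @param groups Named character vector mapping every sample (column) to a
#'   group label.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression matrix needs unique transcript rownames")
  if (is.null(colnames(values))) stop("expression matrix needs sample colnames")
  if (any(values < 0)) stop("expression values must be non-negative TPM")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d transcript(s) x %d sample(s); groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

group_samples <- function(em, group) {
  s <- names(em$groups)[em$groups == group]
  if (length(s) == 0L) stop("no samples in group '", group, "'")
  s
}

#' Read a TPM expression matrix and its sample-group map
#'
#' @param path TSV with a `transcript_id` column then one column per sample.
#' @param groups_path TSV with columns `sample_id`, `group` covering every
#'   sample in the matrix.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, groups_path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (colnames(d)[1L] != "transcript_id")
    stop("first column of ", path, " must be transcript_id")
  values <- as.matrix(d[, -1L, drop = FALSE])
  rownames(values) <- d$transcript_id
  g <- utils::read.table(groups_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  expression_matrix(values, stats::setNames(g$group, g$sample_id))
}

#' Write an expression matrix and its sample-group map
#'
#' Round-trips exactly through [read_expression()] (values are printed with
#' full precision).
#'
#' @param em An `expression_matrix`.
#' @param path,groups_path Output TSV paths.
#' @export
write_expression <- function(em, path, groups_path) {
  stopifnot(inherits(em, "expression_matrix"))
  header <- paste(c("transcript_id", colnames(em$values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(em$values)), function(i) {
    paste(c(rownames(em$values)[i],
            format(em$values[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  writeLines(c("sample_id\tgroup",
               paste(names(em$groups), em$groups, sep = "\t")), groups_path)
  invisible(path)
}
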