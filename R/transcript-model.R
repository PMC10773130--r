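#' Construct a transcript model
#'
#' A transcript model is a stranded, multi-exon structure on a single
#' sequence. Coordinates are 0-based half-open throughout the package;
#' conversion to and from GTF's 1-based closed convention happens only at
#' file I/O boundaries.
#'
#' @param transcript_id Unique transcript identifier.
#' @param seq_name Sequence (chromosome) name.
#' @param strand `"+"` or `"-"`. Unknown strand is rejected because structural
#'   classification is strand-dependent.
#' @param starts,ends Integer vectors of exon starts (0-based inclusive) and
#'   ends (0-based exclusive), sorted by start, non-overlapping, separated by
#'   at least 1 bp (an intron).
#' @param gene_id Gene identifier or `NA` (query models are typically
#'   unassigned).
#' @param source_sample Sample of origin or `NA`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, seq_name, strand, starts, ends,
                             gene_id = NA_character_,
                             source_sample = NA_character_) {
  if (!is.character(transcript_id) || length(transcript_id) != 1L || is.na(transcript_id))
    stop("transcript_id must be a single string")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id,
         " (got '", strand, "')")
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("transcript ", transcript_id, ": starts/ends must be non-empty and equal length")
  if (any(is.na(starts)) || any(is.na(ends)) || any(starts < 0L) || any(starts >= ends))
    stop("transcript ", transcript_id, ": exons must satisfy 0 <= start < end")
  if (is.unsorted(starts, strictly = TRUE) && length(starts) > 1L)
    stop("transcript ", transcript_id, ": exons must be sorted by start")
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("transcript ", transcript_id,
         ": consecutive exons must be separated by >= 1 bp (an intron)")
  structure(
    list(transcript_id = transcript_id,
         gene_id = as.character(gene_id),
         seq_name = as.character(seq_name),
         strand = strand,
         starts = starts,
         ends = ends,
         source_sample = as.character(source_sample)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s> %s:%s %d exon(s) [%d, %d)\n",
              x$transcript_id, x$seq_name, x$strand, length(x$starts),
              x$starts[1L], x$ends[length(x$ends)]))
  invisible(x)
}

n_exons <- function(t) length(t$starts)
tx_start <- function(t) t$starts[1L]
tx_end <- function(t) t$ends[length(t$ends)]

#' Splice-junction chain of a transcript model
#'
#' Returns the ordered intron intervals of a transcript: n exons yield n - 1
#' junctions; a mono-exon model yields an empty chain. Junction identity is
#' the half-open intron interval (donor = first intronic base, acceptor = one
#' past the last intronic base); exon end coordinates never participate.
#'
#' @param t A `transcript_model`.
#' @return A data.frame with integer columns `donor` and `acceptor`, plus
#'   attributes `seq_name` and `strand`.
#' @export
junction_chain <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- n_exons(t)
  if (n < 2L) {
    ch <- data.frame(donor = integer(0), acceptor = integer(0))
  } else {
    ch <- data.frame(donor = t$ends[-n], acceptor = t$starts[-1L])
  }
  attr(ch, "seq_name") <- t$seq_name
  attr(ch, "strand") <- t$strand
  ch
}

# Canonical string key of a junction chain; the identity used for FSM
# matching and for the non-redundant merge.
chain_key <- function(t) {
  ch <- junction_chain(t)
  paste0(t$seq_name, "|", t$strand, "|",
         paste(ch$donor, ch$acceptor, sep = "-", collapse = ";"))
}

junction_keys <- function(t) {
  ch <- junction_chain(t)
  if (nrow(ch) == 0L) return(character(0))
  paste0(t$seq_name, "|", t$strand, "|", ch$donor, "|", ch$acceptor)
}

splice_site_keys <- function(t) {
  ch <- junction_chain(t)
  if (nrow(ch) == 0L) return(character(0))
  c(paste0(t$seq_name, "|", t$strand, "|", ch$donor, "|donor"),
    paste0(t$seq_name, "|", t$strand, "|", ch$acceptor, "|acceptor"))
}
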