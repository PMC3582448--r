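#' Transcript model
#'
#' A transcript is a strand plus an ordered set of exon intervals on a named
#' chromosome. All internal coordinates are 0-based half-open; BED input is
#' taken as-is, GTF/GFF (1-based closed) is converted at parse time.
#'
#' @param transcript_id character scalar, unique transcript identifier.
#' @param chrom character scalar, chromosome name.
#' @param strand one of `"+"` or `"-"`. A `"."` from an input file is mapped
#'   to `"+"` with a warning before this constructor is reached.
#' @param exons two-column integer matrix of `[start, end)` intervals,
#'   0-based half-open, sorted ascending and non-overlapping.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(chrom), length(chrom) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got '", strand, "'", call. = FALSE)
  }
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript needs at least one exon", call. = FALSE)
  if (any(exons[, 1L] >= exons[, 2L])) {
    stop("exon with start >= end in transcript '", transcript_id, "'",
         call. = FALSE)
  }
  ord <- order(exons[, 1L])
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript '", transcript_id, "'", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons),
            class = "transcript_model")
}

#' Spliced transcript length
#'
#' @param tx a [transcript_model()].
#' @return Total exon length in nucleotides.
#' @export
transcript_length <- function(tx) {
  sum(tx$exons[, 2L] - tx$exons[, 1L])
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%s %d exon(s), %d nt\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              transcript_length(x)))
  invisible(x)
}

#' Genome sequence container
#'
#' A named set of uppercase nucleotide strings over `{A,C,G,T,N}`. Any IUPAC
#' ambiguity code or other character is masked to `N` at construction.
#'
#' @param sequences named character vector, one element per chromosome.
#' @return An object of class `genome_sequence`.
#' @export
genome_sequence <- function(sequences) {
  if (length(sequences) == 0L) stop("empty genome", call. = FALSE)
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every sequence needs a chromosome name", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(sequences)
  sequences <- gsub("[^ACGTN]", "N", sequences)
  structure(stats::setNames(as.character(sequences), nm),
            class = "genome_sequence")
}

#' Random access into a genome
#'
#' @param genome a [genome_sequence()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return The `end - start` characters of the interval.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  seq <- genome_chrom(genome, chrom)
  if (start < 0 || end > nchar(seq) || start > end) {
    stop("interval [", start, ",", end, ") out of bounds on '", chrom,
         "' (length ", nchar(seq), ")", call. = FALSE)
  }
  substr(seq, start + 1L, end)
}

genome_chrom <- function(genome, chrom) {
  idx <- match(chrom, names(genome))
  if (is.na(idx)) stop("unknown chromosome '", chrom, "'", call. = FALSE)
  unclass(genome)[[idx]]
}

#' Conservation score track
#'
#' Sparse per-base conservation scores in `[0, 1]`, e.g. phastCons. Positions
#' absent from the track are "missing" and count as 0 when averaged over a
#' transcript.
#'
#' @param chrom character vector of chromosome names, one per scored base.
#' @param pos integer vector of 0-based positions.
#' @param score numeric vector of scores in `[0, 1]`.
#' @return An object of class `conservation_track`: a per-chromosome list of
#'   sorted positions and their scores.
#' @export
conservation_track <- function(chrom = character(), pos = integer(),
                               score = numeric()) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(score))
  if (length(score) && (any(!is.finite(score)) ||
                        any(score < 0) || any(score > 1))) {
    stop("conservation scores must be finite and within [0, 1]", call. = FALSE)
  }
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    s <- score[sel]
    # last record wins at duplicated positions
    keep <- !duplicated(p, fromLast = TRUE)
    if (!all(keep)) {
      warning("overlapping conservation records on '", ch,
              "': keeping the last value at each position", call. = FALSE)
      p <- p[keep]
      s <- s[keep]
    }
    ord <- order(p)
    out[[ch]] <- list(pos = as.numeric(p[ord]), score = s[ord])
  }
  structure(out, class = "conservation_track")
}

# sum of scores over exonic positions present in the track
track_sum <- function(track, chrom, start, end) {
  per <- unclass(track)[[chrom]]
  if (is.null(per) || length(per$pos) == 0L) return(0)
  lo <- findInterval(start - 0.5, per$pos) + 1L
  hi <- findInterval(end - 0.5, per$pos)
  if (hi < lo) return(0)
  sum(per$score[lo:hi])
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
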