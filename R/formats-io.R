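#' Read transcript structures from a BED file
#'
#' Accepts BED12 (exons reconstructed from the block columns) and BED6
#' (single-exon fallback). BED's 0-based half-open convention is kept
#' unchanged; the name field becomes the transcript id. Unstranded records
#' (`.`) are treated as `+` with a warning.
#'
#' @param path path to a BED6/BED12 file.
#' @return A list of [transcript_model()] objects.
#' @export
parse_bed <- function(path) {
  lines <- read_text_lines(path)
  txs <- vector("list", length(lines$text))
  for (i in seq_along(lines$text)) {
    f <- strsplit(lines$text[[i]], "[ \t]+")[[1L]]
    lineno <- lines$lineno[[i]]
    if (!length(f) %in% c(6L, 12L)) {
      stop("BED parse error at line ", lineno, ": expected 6 or 12 columns, got ",
           length(f), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("BED parse error at line ", lineno, ": non-numeric coordinate",
           call. = FALSE)
    }
    strand <- bed_strand(f[6L], f[4L])
    if (length(f) == 6L) {
      exons <- cbind(start, end)
    } else {
      n_blocks <- suppressWarnings(as.integer(f[10L]))
      sizes <- parse_int_list(f[11L])
      offs <- parse_int_list(f[12L])
      if (is.na(n_blocks) || anyNA(sizes) || anyNA(offs) ||
          length(sizes) != n_blocks || length(offs) != n_blocks) {
        stop("BED parse error at line ", lineno,
             ": blockCount/blockSizes/blockStarts mismatch", call. = FALSE)
      }
      exons <- cbind(start + offs, start + offs + sizes)
    }
    txs[[i]] <- transcript_model(f[4L], f[1L], strand, exons)
  }
  txs
}

#' Read transcript structures from a GTF or GFF3 file
#'
#' Exon feature rows are grouped by transcript identifier: the
#' `transcript_id "x"` attribute (GTF dialect) or `Parent=`/`ID=` (GFF3
#' dialect). 1-based closed coordinates are converted to the internal 0-based
#' half-open convention; exons are sorted ascending regardless of file order.
#'
#' @param path path to a GTF/GFF file.
#' @return A list of [transcript_model()] objects, in order of first
#'   appearance of each transcript in the file.
#' @export
parse_gtf <- function(path) {
  lines <- read_text_lines(path)
  rows <- list()
  for (i in seq_along(lines$text)) {
    f <- strsplit(lines$text[[i]], "\t")[[1L]]
    lineno <- lines$lineno[[i]]
    if (length(f) < 9L) {
      stop("GTF/GFF parse error at line ", lineno, ": expected 9 tab-separated",
           " columns, got ", length(f), call. = FALSE)
    }
    if (f[3L] != "exon") next
    start <- suppressWarnings(as.numeric(f[4L]))
    end <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(start) || is.na(end)) {
      stop("GTF/GFF parse error at line ", lineno, ": non-numeric coordinate",
           call. = FALSE)
    }
    tid <- gtf_transcript_id(f[9L])
    if (is.na(tid)) {
      stop("GTF/GFF parse error at line ", lineno,
           ": exon without a transcript identifier (transcript_id/Parent/ID)",
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- list(tid = tid, chrom = f[1L],
                                      strand = bed_strand(f[7L], tid),
                                      start = start - 1, end = end)
  }
  if (!length(rows)) return(list())
  tids <- vapply(rows, `[[`, "", "tid")
  out <- list()
  for (tid in unique(tids)) {
    grp <- rows[tids == tid]
    chrom <- unique(vapply(grp, `[[`, "", "chrom"))
    strand <- unique(vapply(grp, `[[`, "", "strand"))
    if (length(chrom) > 1L) {
      stop("validation error: transcript '", tid, "' has exons on multiple ",
           "chromosomes (", paste(chrom, collapse = ", "), ")", call. = FALSE)
    }
    if (length(strand) > 1L) {
      stop("validation error: transcript '", tid, "' mixes strands",
           call. = FALSE)
    }
    exons <- cbind(vapply(grp, `[[`, 0, "start"), vapply(grp, `[[`, 0, "end"))
    out[[length(out) + 1L]] <- transcript_model(tid, chrom, strand, exons)
  }
  out
}

#' Read a genome FASTA
#'
#' Sequence names are the first whitespace-delimited token of each header.
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` is masked
#' to `N`.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A [genome_sequence()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- vapply(strsplit(names(set), "[ \t]+"), `[[`, "", 1L)
  genome_sequence(stats::setNames(as.character(set), nm))
}

#' Write a genome FASTA
#'
#' @param genome a [genome_sequence()].
#' @param path output path.
#' @param width line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(genome)) {
    seq <- genome_chrom(genome, chrom)
    writeLines(paste0(">", chrom), con)
    n <- nchar(seq)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a conservation score track
#'
#' Accepts WIG fixedStep, WIG variableStep, or bedGraph. WIG's 1-based starts
#' are converted to 0-based internal positions; bedGraph half-open intervals
#' are expanded per base. When the same position is given twice, the later
#' record wins (with a warning). Scores must lie within `[0, 1]`.
#'
#' @param path path to the track file.
#' @return A [conservation_track()].
#' @export
read_conservation <- function(path) {
  lines <- read_text_lines(path)$text
  if (!length(lines)) return(conservation_track())
  is_header <- grepl("^(fixedStep|variableStep)\\b", lines)
  chroms <- list(); positions <- list(); scores <- list()
  push <- function(ch, p, s) {
    k <- length(chroms) + 1L
    chroms[[k]] <<- rep(ch, length.out = length(p))
    positions[[k]] <<- p
    scores[[k]] <<- s
  }
  if (any(is_header)) {
    sect <- cumsum(is_header)
    if (sect[1L] == 0L) {
      stop("WIG parse error: data before the first fixedStep/variableStep ",
           "header", call. = FALSE)
    }
    for (k in seq_len(max(sect))) {
      hdr <- lines[is_header & sect == k]
      body <- lines[!is_header & sect == k]
      kv <- wig_header_fields(hdr)
      span <- as.integer(kv["span"] %||% "1")
      if (grepl("^fixedStep", hdr)) {
        start0 <- as.integer(kv["start"]) - 1L
        step <- as.integer(kv["step"] %||% "1")
        val <- parse_scores(body, path)
        base <- start0 + (seq_along(val) - 1L) * step
        push(kv[["chrom"]], rep(base, each = span) +
               rep(seq_len(span) - 1L, times = length(base)),
             rep(val, each = span))
      } else {
        f <- strsplit(body, "[ \t]+")
        p0 <- vapply(f, function(x) suppressWarnings(as.numeric(x[1L])), 0) - 1
        val <- parse_scores(vapply(f, `[[`, "", 2L), path)
        if (anyNA(p0)) stop("WIG parse error: non-numeric position in ", path,
                            call. = FALSE)
        push(kv[["chrom"]], rep(p0, each = span) +
               rep(seq_len(span) - 1L, times = length(p0)),
             rep(val, each = span))
      }
    }
  } else {
    f <- strsplit(lines, "[ \t]+")
    nfield <- lengths(f)
    if (any(nfield != 4L)) {
      stop("unknown track format in ", path, ": expected a WIG header or ",
           "4-column bedGraph lines", call. = FALSE)
    }
    ch <- vapply(f, `[[`, "", 1L)
    s0 <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 2L)))
    e0 <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 3L)))
    if (anyNA(s0) || anyNA(e0)) {
      stop("bedGraph parse error: non-numeric coordinate in ", path,
           call. = FALSE)
    }
    val <- parse_scores(vapply(f, `[[`, "", 4L), path)
    runs <- as.integer(e0 - s0)
    if (any(runs < 1L)) {
      stop("bedGraph parse error: interval with end <= start in ", path,
           call. = FALSE)
    }
    push(rep(ch, runs), rep(s0, runs) + (sequence(runs) - 1),
         rep(val, runs))
  }
  conservation_track(unlist(chroms), unlist(positions), unlist(scores))
}

#' Extract the spliced, strand-correct transcript sequence
#'
#' Exon subsequences are concatenated in ascending genomic order; for a minus
#' strand transcript the concatenation is reverse-complemented, so the result
#' is always the transcript's 5'->3' sequence.
#'
#' @param tx a [transcript_model()].
#' @param genome a [genome_sequence()].
#' @return Nucleotide string of length `transcript_length(tx)`.
#' @export
extract_sequence <- function(tx, genome) {
  chrom_seq <- genome_chrom(genome, tx$chrom)
  n <- nchar(chrom_seq)
  if (any(tx$exons[, 1L] < 0) || any(tx$exons[, 2L] > n)) {
    stop("coordinate error: exon of '", tx$transcript_id,
         "' exceeds bounds of '", tx$chrom, "' (length ", n, ")",
         call. = FALSE)
  }
  seq <- paste(substring(chrom_seq, tx$exons[, 1L] + 1L, tx$exons[, 2L]),
               collapse = "")
  if (tx$strand == "-") seq <- reverse_complement(seq)
  seq
}

#' Write predictions as a 3-column TSV
#'
#' One row per transcript: transcript id, label (`noncoding`/`coding`) and the
#' non-coding score printed with 4 decimals, mirroring the classifier's
#' report schema.
#'
#' @param preds a prediction data frame from [predict_transcripts()], or any
#'   data frame with columns `transcript_id`, `label`, `noncoding_score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write predictions to '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines("transcript_id\tlabel\tnoncoding_score", con)
  if (nrow(preds)) {
    writeLines(sprintf("%s\t%s\t%.4f", preds$transcript_id, preds$label,
                       preds$noncoding_score), con)
  }
  invisible(path)
}

#' Read a prediction TSV back
#'
#' @param path path written by [write_predictions()].
#' @return Data frame with columns `transcript_id`, `label`,
#'   `noncoding_score`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "label", "noncoding_score")
  if (!all(required %in% names(df))) {
    stop("prediction file ", path, " lacks columns: ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write transcripts as BED12
#'
#' @param txs list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(txs, path) {
  rows <- vapply(txs, function(tx) {
    start <- tx$exons[1L, 1L]
    end <- tx$exons[nrow(tx$exons), 2L]
    sizes <- tx$exons[, 2L] - tx$exons[, 1L]
    offs <- tx$exons[, 1L] - start
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            tx$chrom, as.integer(start), as.integer(end), tx$transcript_id,
            tx$strand, as.integer(start), as.integer(start), nrow(tx$exons),
            paste(as.integer(sizes), collapse = ","),
            paste(as.integer(offs), collapse = ","))
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Write transcripts as GTF exon rows
#'
#' @param txs list of [transcript_model()] objects.
#' @param path output path.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(txs, path, source = "lincsvm") {
  rows <- unlist(lapply(txs, function(tx) {
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            tx$chrom, source, as.integer(tx$exons[, 1L] + 1L),
            as.integer(tx$exons[, 2L]), tx$strand, tx$transcript_id,
            tx$transcript_id)
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Write a conservation track as bedGraph
#'
#' One line per scored base; scores are printed with 3 decimals.
#'
#' @param track a [conservation_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track)) {
    per <- unclass(track)[[chrom]]
    writeLines(sprintf("%s\t%d\t%d\t%.3f", chrom, as.integer(per$pos),
                       as.integer(per$pos) + 1L, per$score), con)
  }
  invisible(path)
}

# --- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
}

# non-empty, non-comment lines with their original line numbers
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !grepl("^(#|track\\b|browser\\b)", raw)
  list(text = raw[keep], lineno = which(keep))
}

parse_int_list <- function(x) {
  suppressWarnings(as.numeric(strsplit(sub(",$", "", x), ",")[[1L]]))
}

bed_strand <- function(strand, id) {
  if (strand == ".") {
    warning("unstranded record '", id, "' treated as '+'", call. = FALSE)
    return("+")
  }
  strand
}

gtf_transcript_id <- function(attrs) {
  m <- regmatches(attrs, regexec('transcript_id[ =]+"?([^";]+)"?', attrs))[[1L]]
  if (length(m) == 2L) return(m[[2L]])
  m <- regmatches(attrs, regexec("Parent=([^;]+)", attrs))[[1L]]
  if (length(m) == 2L) return(m[[2L]])
  m <- regmatches(attrs, regexec("ID=([^;]+)", attrs))[[1L]]
  if (length(m) == 2L) return(m[[2L]])
  NA_character_
}

wig_header_fields <- function(hdr) {
  toks <- strsplit(trimws(hdr), "[ \t]+")[[1L]][-1L]
  kv <- strsplit(toks, "=", fixed = TRUE)
  out <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  if (!"chrom" %in% names(out)) {
    stop("WIG parse error: header without chrom= field: ", hdr, call. = FALSE)
  }
  if (grepl("^fixedStep", hdr) && !"start" %in% names(out)) {
    stop("WIG parse error: fixedStep header without start= field", call. = FALSE)
  }
  out
}

parse_scores <- function(x, path) {
  val <- suppressWarnings(as.numeric(x))
  if (anyNA(val)) {
    stop("parse error: non-numeric score value in ", path, call. = FALSE)
  }
  if (any(val < 0 | val > 1)) {
    stop("validation error: conservation score outside [0, 1] in ", path,
         call. = FALSE)
  }
  val
}
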