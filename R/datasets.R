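#' Synthetic corpus specification
#'
#' Parameters of the generated two-class corpus. The defaults describe the
#' regime the classifier is built for: transcripts longer than the 200 nt
#' filter, coding transcripts carrying one long embedded ORF with GC-biased
#' codon usage and high exonic conservation, non-coding transcripts made of
#' AT-shifted random sequence with low conservation and only the short
#' spurious ORFs that arise by chance.
#'
#' @param n_coding,n_noncoding transcripts per class.
#' @param length_range spliced transcript length range in nt (min must
#'   exceed 200, the curation filter's regime).
#' @param orf_length_range embedded ORF length range in nt (multiples of 3,
#'   start and stop codon included); the minimum plus 30 nt of UTR must fit
#'   in the shortest transcript.
#' @param exon_count_range exons per transcript.
#' @param intron_length_range intron lengths in nt.
#' @param cons_mean_coding,cons_mean_noncoding per-class mean per-base
#'   conservation in `[0, 1]`.
#' @param cons_sd spread of per-base conservation (scores are clamped to
#'   `[0, 1]`).
#' @param coding_bias strength in `[0, 1]` of the GC-rich codon-usage bias
#'   inside embedded ORFs.
#' @param noncoding_at_bias strength in `[0, 1]` of the A/T composition
#'   shift of non-coding sequence.
#' @param noncoding_embed_orf when `TRUE`, non-coding transcripts are built
#'   through the same constructor as coding ones (embedded ORF, same codon
#'   bias) and differ only in their conservation mean. Setting this together
#'   with equal conservation means yields the null configuration in which
#'   the two classes are statistically exchangeable and any classifier can
#'   only reach chance accuracy.
#' @param n_chroms number of synthetic chromosomes transcripts are placed on.
#' @param gap_range intergenic gap range between neighbouring transcripts.
#' @param seed integer seed; the whole corpus is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_coding = 400L, n_noncoding = 400L,
                           length_range = c(300L, 2000L),
                           orf_length_range = c(240L, 1200L),
                           exon_count_range = c(1L, 5L),
                           intron_length_range = c(60L, 500L),
                           cons_mean_coding = 0.65,
                           cons_mean_noncoding = 0.12,
                           cons_sd = 0.15,
                           coding_bias = 0.8,
                           noncoding_at_bias = 0.25,
                           noncoding_embed_orf = FALSE,
                           n_chroms = 8L,
                           gap_range = c(200L, 500L),
                           seed = 1L) {
  spec <- list(n_coding = as.integer(n_coding),
               n_noncoding = as.integer(n_noncoding),
               length_range = as.integer(length_range),
               orf_length_range = as.integer(orf_length_range),
               exon_count_range = as.integer(exon_count_range),
               intron_length_range = as.integer(intron_length_range),
               cons_mean_coding = cons_mean_coding,
               cons_mean_noncoding = cons_mean_noncoding,
               cons_sd = cons_sd,
               coding_bias = coding_bias,
               noncoding_at_bias = noncoding_at_bias,
               noncoding_embed_orf = isTRUE(noncoding_embed_orf),
               n_chroms = as.integer(n_chroms),
               gap_range = as.integer(gap_range),
               seed = as.integer(seed))
  if (spec$length_range[1L] <= 200L) {
    stop("minimum transcript length must exceed 200 nt", call. = FALSE)
  }
  if (spec$n_coding < 1L || spec$n_noncoding < 1L) {
    stop("both classes need at least one transcript", call. = FALSE)
  }
  if (any(spec$orf_length_range %% 3L != 0L)) {
    stop("ORF length range must be multiples of 3", call. = FALSE)
  }
  if (spec$orf_length_range[1L] + 30L > spec$length_range[1L]) {
    stop("infeasible spec: minimum ORF length + 30 nt UTR exceeds the ",
         "minimum transcript length", call. = FALSE)
  }
  means <- c(spec$cons_mean_coding, spec$cons_mean_noncoding)
  if (any(means < 0 | means > 1)) {
    stop("conservation means must lie in [0, 1]", call. = FALSE)
  }
  if (spec$exon_count_range[1L] < 1L) {
    stop("transcripts need at least one exon", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-class corpus
#'
#' Emits a genome, BED12 and GTF annotations (mirrored encodings of the same
#' transcripts), a per-base bedGraph conservation track over exonic
#' positions, and truth labels — everything the training and prediction
#' pipeline consumes, reproducible byte-for-byte from the seed. Transcripts
#' never overlap each other ("intergenic" placement).
#'
#' @param spec a [synthetic_spec()].
#' @param outdir optional directory; when given, `genome.fa`,
#'   `transcripts.bed`, `transcripts.gtf`, `cons.bedGraph`, `truth.tsv` and
#'   `log.tsv` are written there.
#' @return A list with `genome`, `transcripts`, `track`, `truth` (data frame
#'   id/label), `log` (per-transcript generation record including the
#'   embedded ORF position in transcript coordinates), and `paths` when
#'   `outdir` was given.
#' @export
generate_corpus <- function(spec = synthetic_spec(), outdir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_total <- spec$n_coding + spec$n_noncoding
  classes <- rep(c("coding", "noncoding"), c(spec$n_coding, spec$n_noncoding))
  ids <- sprintf("%s_%04d", classes,
                 c(seq_len(spec$n_coding), seq_len(spec$n_noncoding)))

  base_probs <- noncoding_base_probs(spec$noncoding_at_bias)
  codon_tab <- biased_codon_table(spec$coding_bias)

  chrom_parts <- rep(list(list()), spec$n_chroms)
  cursors <- integer(spec$n_chroms)
  txs <- vector("list", n_total)
  log <- vector("list", n_total)
  cons_chrom <- vector("list", n_total)
  cons_pos <- vector("list", n_total)
  cons_score <- vector("list", n_total)

  with_seed(spec$seed, {
    for (i in seq_len(n_total)) {
      L <- sample_range(spec$length_range)
      if (classes[i] == "coding" || spec$noncoding_embed_orf) {
        orf_len <- sample_orf_length(spec$orf_length_range, L)
        orf_start <- sample.int(L - orf_len + 1L, 1L) - 1L
        orf_seq <- random_orf(orf_len, codon_tab)
        utr5 <- random_seq(orf_start, c(A = .25, C = .25, G = .25, T = .25))
        utr3 <- random_seq(L - orf_start - orf_len,
                           c(A = .25, C = .25, G = .25, T = .25))
        seq <- paste0(utr5, orf_seq, utr3)
        cons_mean <- if (classes[i] == "coding") spec$cons_mean_coding
                     else spec$cons_mean_noncoding
      } else {
        orf_len <- NA_integer_
        orf_start <- NA_integer_
        seq <- random_seq(L, base_probs)
        cons_mean <- spec$cons_mean_noncoding
      }

      n_ex <- sample_range(spec$exon_count_range)
      n_ex <- min(n_ex, L)
      ex_lens <- split_lengths(L, n_ex)
      strand <- sample(c("+", "-"), 1L)
      chrom_i <- (i - 1L) %% spec$n_chroms + 1L
      chrom <- sprintf("chr%d", chrom_i)
      gap <- sample_range(spec$gap_range)

      genomic_seq <- if (strand == "+") seq else reverse_complement(seq)
      genomic_lens <- if (strand == "+") ex_lens else rev(ex_lens)

      pieces <- list(random_seq(gap, c(A = .25, C = .25, G = .25, T = .25)))
      pos <- cursors[chrom_i] + gap
      exon_starts <- integer(n_ex)
      offset <- 0L
      for (e in seq_len(n_ex)) {
        if (e > 1L) {
          intron <- sample_range(spec$intron_length_range)
          pieces[[length(pieces) + 1L]] <-
            random_seq(intron, c(A = .25, C = .25, G = .25, T = .25))
          pos <- pos + intron
        }
        exon_starts[e] <- pos
        pieces[[length(pieces) + 1L]] <-
          substr(genomic_seq, offset + 1L, offset + genomic_lens[e])
        offset <- offset + genomic_lens[e]
        pos <- pos + genomic_lens[e]
      }
      chrom_parts[[chrom_i]] <- c(chrom_parts[[chrom_i]], pieces)
      cursors[chrom_i] <- pos

      exons <- cbind(exon_starts, exon_starts + genomic_lens)
      txs[[i]] <- transcript_model(ids[i], chrom, strand, exons)

      # per-base conservation over exonic genomic positions, clamped normal,
      # rounded to the 3 decimals the bedGraph serialization carries
      gpos <- unlist(lapply(seq_len(n_ex), function(e) {
        seq.int(exons[e, 1L], exons[e, 2L] - 1L)
      }))
      sc <- round(pmin(pmax(stats::rnorm(L, cons_mean, spec$cons_sd), 0), 1),
                  3L)
      cons_chrom[[i]] <- rep(chrom, L)
      cons_pos[[i]] <- gpos
      cons_score[[i]] <- sc

      log[[i]] <- data.frame(transcript_id = ids[i], label = classes[i],
                             chrom = chrom, strand = strand, length = L,
                             n_exons = n_ex, orf_start = orf_start,
                             orf_length = orf_len, stringsAsFactors = FALSE)
    }
  })

  sequences <- vapply(seq_len(spec$n_chroms), function(k) {
    paste(unlist(chrom_parts[[k]]), collapse = "")
  }, "")
  names(sequences) <- sprintf("chr%d", seq_len(spec$n_chroms))
  genome <- genome_sequence(sequences[nchar(sequences) > 0L])
  track <- conservation_track(unlist(cons_chrom), unlist(cons_pos),
                              unlist(cons_score))
  truth <- data.frame(transcript_id = ids,
                      label = ifelse(classes == "noncoding", "noncoding",
                                     "coding"),
                      stringsAsFactors = FALSE)
  log <- do.call(rbind, log)

  out <- list(genome = genome, transcripts = txs, track = track,
              truth = truth, log = log, spec = spec)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(outdir, "genome.fa"),
                  bed = file.path(outdir, "transcripts.bed"),
                  gtf = file.path(outdir, "transcripts.gtf"),
                  conservation = file.path(outdir, "cons.bedGraph"),
                  truth = file.path(outdir, "truth.tsv"),
                  log = file.path(outdir, "log.tsv"))
    write_fasta(genome, paths$genome)
    write_bed12(txs, paths$bed)
    write_gtf(txs, paths$gtf)
    write_bedgraph(track, paths$conservation)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(log, paths$log, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Length filter
#'
#' Keeps transcripts whose spliced length strictly exceeds `min_nt`,
#' the curation rule for the > 200 nt long-RNA regime.
#'
#' @param txs list of [transcript_model()] objects.
#' @param min_nt length cutoff (default 200).
#' @return List with `transcripts` (kept) and `dropped` (count).
#' @export
filter_by_length <- function(txs, min_nt = 200L) {
  keep <- vapply(txs, transcript_length, 0) > min_nt
  list(transcripts = txs[keep], dropped = sum(!keep))
}

#' Cross-annotation consistency filter
#'
#' `exclude_overlap` drops candidates sharing at least 1 bp of same-strand
#' exonic overlap with any reference transcript (the rule used to purge
#' lincRNA candidates that a coding annotation contradicts).
#' `require_consistent` keeps candidates whose id or exact exon structure
#' appears in the reference (the rule used to keep only consistently
#' annotated coding transcripts).
#'
#' @param candidates list of [transcript_model()] objects.
#' @param reference list of [transcript_model()] objects on the same genome.
#' @param mode `"exclude_overlap"` or `"require_consistent"`.
#' @return Filtered list of transcripts.
#' @export
cross_annotation_filter <- function(candidates, reference,
                                    mode = c("exclude_overlap",
                                             "require_consistent")) {
  mode <- match.arg(mode)
  if (mode == "exclude_overlap") {
    keep <- vapply(candidates, function(cand) {
      !any(vapply(reference, function(ref) {
        exonic_overlap(cand, ref)
      }, FALSE))
    }, FALSE)
    return(candidates[keep])
  }
  ref_ids <- vapply(reference, `[[`, "", "transcript_id")
  ref_keys <- vapply(reference, structure_key, "")
  keep <- vapply(candidates, function(cand) {
    cand$transcript_id %in% ref_ids || structure_key(cand) %in% ref_keys
  }, FALSE)
  candidates[keep]
}

#' Balanced train/test split
#'
#' Half of the positives (floor) plus an equal number of negatives form the
#' balanced training set; everything else becomes the testing set. The split
#' is seed-deterministic.
#'
#' @param pos [labeled_dataset()] of positives (noncoding).
#' @param neg [labeled_dataset()] of negatives (coding).
#' @param seed integer seed.
#' @return List with `train`, `test` and a `log` of class counts.
#' @export
make_split <- function(pos, neg, seed = 1L) {
  n_half <- length(pos$ids) %/% 2L
  if (n_half < 1L) stop("too few positives to split", call. = FALSE)
  if (length(neg$ids) < n_half) {
    stop("negatives (", length(neg$ids), ") fewer than half the positives (",
         n_half, ")", call. = FALSE)
  }
  split <- balance_dataset(pos, neg, seed = seed, n = n_half)
  list(train = split$train, test = split$remainder,
       log = data.frame(set = c("train", "test"),
                        noncoding = c(sum(split$train$labels == "noncoding"),
                                      sum(split$remainder$labels == "noncoding")),
                        coding = c(sum(split$train$labels == "coding"),
                                   sum(split$remainder$labels == "coding"))))
}

# --- generator internals ----------------------------------------------------

sample_range <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  sample.int(range[2L] - range[1L] + 1L, 1L) + range[1L] - 1L
}

sample_orf_length <- function(orf_range, L) {
  hi <- min(orf_range[2L], ((L - 30L) %/% 3L) * 3L)
  candidates <- seq.int(orf_range[1L], hi, by = 3L)
  candidates[sample.int(length(candidates), 1L)]
}

random_seq <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

noncoding_base_probs <- function(bias) {
  at_rich <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  uniform <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  (1 - bias) * uniform + bias * at_rich
}

# 61 sense codons with sampling weights pulled toward GC-rich codons at
# strength `bias`; stop codons are excluded so the embedded ORF has no
# internal in-frame stop
biased_codon_table <- function(bias) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  gc <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), 0)
  w <- (1 - bias) * 1 + bias * 2^gc
  list(codons = codons, weights = w / sum(w))
}

random_orf <- function(orf_len, codon_tab) {
  n_internal <- orf_len %/% 3L - 2L
  internal <- if (n_internal > 0L) {
    paste(sample(codon_tab$codons, n_internal, replace = TRUE,
                 prob = codon_tab$weights), collapse = "")
  } else ""
  paste0("ATG", internal, sample(c("TAA", "TAG", "TGA"), 1L))
}

# split total length into n positive integer parts (exon lengths)
split_lengths <- function(L, n) {
  if (n == 1L) return(L)
  cuts <- sort(sample.int(L - 1L, n - 1L))
  diff(c(0L, cuts, L))
}

exonic_overlap <- function(a, b) {
  if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
  for (i in seq_len(nrow(a$exons))) {
    if (any(a$exons[i, 1L] < b$exons[, 2L] & a$exons[i, 2L] > b$exons[, 1L])) {
      return(TRUE)
    }
  }
  FALSE
}

structure_key <- function(tx) {
  paste(tx$chrom, tx$strand, paste(as.integer(t(tx$exons)), collapse = ","),
        sep = ":")
}
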