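#' Feature configuration
#'
#' Declares which features are computed and in which fixed order: mean exonic
#' conservation (optional), longest-ORF length, ORF proportion, then the
#' configured k-mer frequencies. The default k-mer list is the six di- and
#' tri-nucleotide words GC, CT, TAG, TGT, ACG, TCG, which together with the
#' conservation and two ORF features form the classifier's feature set.
#'
#' @param kmers character vector of unique uppercase k-mers, each of length 2
#'   or 3, over `{A,C,G,T}`.
#' @param use_conservation include the mean per-base conservation feature?
#' @return An object of class `feature_config` with the derived
#'   `feature_order`.
#' @export
feature_config <- function(kmers = c("GC", "CT", "TAG", "TGT", "ACG", "TCG"),
                           use_conservation = TRUE) {
  kmers <- toupper(kmers)
  if (anyDuplicated(kmers)) stop("duplicate k-mers", call. = FALSE)
  if (length(kmers) && (!all(nchar(kmers) %in% 2:3) ||
                        any(grepl("[^ACGT]", kmers)))) {
    stop("k-mers must be strings over {A,C,G,T} of length 2 or 3",
         call. = FALSE)
  }
  order <- c(if (use_conservation) "conservation", "orf_length",
             "orf_proportion", kmers)
  structure(list(kmers = kmers, use_conservation = isTRUE(use_conservation),
                 feature_order = order),
            class = "feature_config")
}

#' Longest open reading frame
#'
#' Scans all three forward frames of the (already 5'->3' oriented) transcript
#' sequence for the longest ATG -> first-in-frame-stop substring, with the
#' stop codon included in the length. A codon containing `N` never matches
#' ATG or a stop and aborts any reading frame walking through it. Ties are
#' broken by the 5'-most start. The reverse strand is not scanned.
#'
#' @param seq uppercase nucleotide string over `{A,C,G,T,N}`.
#' @return A list with `found`, 0-based `start`, exclusive `end`, and
#'   `length_nt` (0 when not found).
#' @export
find_longest_orf <- function(seq) {
  if (!nzchar(seq)) {
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                length_nt = 0L))
  }
  .longest_orf(seq)
}

#' ORF length and proportion
#'
#' @param seq transcript sequence (5'->3').
#' @return Named numeric vector `c(orf_length, orf_proportion)`; both 0 when
#'   no complete ORF exists. The proportion is the ORF length divided by the
#'   total transcript length.
#' @export
orf_features <- function(seq) {
  stopifnot(nchar(seq) >= 1L)
  orf <- find_longest_orf(seq)
  c(orf_length = orf$length_nt,
    orf_proportion = orf$length_nt / nchar(seq))
}

#' Overlapping-window k-mer frequency
#'
#' Counts windows equal to `kmer` among all windows sliding by one, divided
#' by the number of windows containing no `N`. Returns 0 when no valid
#' windows exist.
#'
#' @param seq nucleotide string.
#' @param kmer k-mer of length 2 or 3.
#' @return Frequency in `[0, 1]`.
#' @export
kmer_frequency <- function(seq, kmer) {
  k <- nchar(kmer)
  stopifnot(k %in% 2:3)
  n <- nchar(seq)
  if (n < k) {
    warning("sequence shorter than k-mer; frequency set to 0", call. = FALSE)
    return(0)
  }
  windows <- substring(seq, 1:(n - k + 1L), k:n)
  valid <- !grepl("N", windows, fixed = TRUE)
  if (!any(valid)) return(0)
  sum(windows == kmer) / sum(valid)
}

#' Mean exonic conservation
#'
#' Arithmetic mean of per-base scores over all exonic genomic positions.
#' Positions missing from the track contribute 0, so the denominator is
#' always the spliced transcript length: an unalignable (unscored) base is
#' treated as unconserved.
#'
#' @param tx a [transcript_model()].
#' @param track a [conservation_track()].
#' @return Mean score in `[0, 1]`.
#' @export
conservation_feature <- function(tx, track) {
  total <- sum(vapply(seq_len(nrow(tx$exons)), function(i) {
    track_sum(track, tx$chrom, tx$exons[i, 1L], tx$exons[i, 2L])
  }, 0))
  total / transcript_length(tx)
}

#' Raw feature vector for one transcript
#'
#' @param tx a [transcript_model()].
#' @param genome a [genome_sequence()].
#' @param track a [conservation_track()]; may be empty when
#'   `cfg$use_conservation` is `FALSE`.
#' @param cfg a [feature_config()].
#' @return Named numeric vector in `cfg$feature_order`.
#' @export
build_feature_vector <- function(tx, genome, track,
                                 cfg = feature_config()) {
  seq <- extract_sequence(tx, genome)
  values <- c(if (cfg$use_conservation)
                c(conservation = conservation_feature(tx, track)),
              orf_features(seq),
              kmer_frequencies(seq, cfg$kmers))
  values[cfg$feature_order]
}

#' Raw feature matrix for a set of transcripts
#'
#' @param txs list of [transcript_model()] objects.
#' @inheritParams build_feature_vector
#' @return Numeric matrix, one row per transcript (rownames = transcript
#'   ids), columns in `cfg$feature_order`.
#' @export
build_feature_matrix <- function(txs, genome, track,
                                 cfg = feature_config()) {
  m <- t(vapply(txs, build_feature_vector,
                numeric(length(cfg$feature_order)),
                genome = genome, track = track, cfg = cfg))
  rownames(m) <- vapply(txs, `[[`, "", "transcript_id")
  if (anyNA(m) || any(!is.finite(m))) {
    stop("non-finite feature value produced", call. = FALSE)
  }
  m
}

# all configured k-mer frequencies at once (windows computed once per k)
kmer_frequencies <- function(seq, kmers) {
  if (!length(kmers)) return(numeric())
  out <- stats::setNames(numeric(length(kmers)), kmers)
  n <- nchar(seq)
  for (k in unique(nchar(kmers))) {
    sel <- nchar(kmers) == k
    if (n < k) {
      warning("sequence shorter than k-mer; frequency set to 0",
              call. = FALSE)
      next
    }
    windows <- substring(seq, 1:(n - k + 1L), k:n)
    valid <- !grepl("N", windows, fixed = TRUE)
    denom <- sum(valid)
    if (denom == 0L) next
    counts <- table(windows[valid])
    hits <- counts[kmers[sel]]
    hits[is.na(hits)] <- 0L
    out[sel] <- as.numeric(hits) / denom
  }
  out
}

#' Fit a min-max feature scaler
#'
#' Records the per-feature minimum and maximum observed on the training set;
#' scaled values are `(x - min) / (max - min)` in `[0, 1]`. Constant features
#' scale to 0. Scaler parameters are learned on the training set only and
#' persisted inside the model file.
#'
#' @param x numeric feature matrix (rows = instances).
#' @return An object of class `scaler_params` with `min` and `max` vectors.
#' @export
fit_scaler <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2L) {
    stop("scaler fitting needs at least 2 feature vectors", call. = FALSE)
  }
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max),
                 features = colnames(x)),
            class = "scaler_params")
}

#' Apply a fitted scaler
#'
#' @param x numeric feature matrix or vector (raw values).
#' @param params a [fit_scaler()] result.
#' @return Scaled matrix with every value clamped to `[0, 1]`.
#' @export
apply_scaler <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  range <- params$max - params$min
  scaled <- sweep(x, 2L, params$min, "-")
  scaled <- sweep(scaled, 2L, ifelse(range > 0, range, 1), "/")
  scaled[, range == 0] <- 0
  pmin(pmax(scaled, 0), 1)
}
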