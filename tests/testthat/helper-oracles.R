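# Independent oracles and small fixtures, kept deliberately naive so they
# share no code path with the implementation they check.

# brute force: enumerate every ATG, walk codons to the first in-frame stop;
# a codon containing N aborts the candidate; longest wins, ties to the
# 5'-most start
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best_start <- -1L
  best_len <- 0L
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (substr(seq, i, i + 2L) != "ATG") next
      j <- i
      while (j + 2L <= n) {
        codon <- substr(seq, j, j + 2L)
        if (grepl("N", codon, fixed = TRUE)) break
        if (codon %in% c("TAA", "TAG", "TGA")) {
          len <- j + 3L - i
          if (len > best_len) {
            best_len <- len
            best_start <- i - 1L
          }
          break
        }
        j <- j + 3L
      }
    }
  }
  if (best_start < 0L) list(found = FALSE, length_nt = 0L)
  else list(found = TRUE, start = best_start, length_nt = best_len)
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# MCC as the Pearson correlation of the truth/prediction indicator vectors
oracle_mcc <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  stats::cor(truth, pred)
}

# two well-separated gaussian clusters as a raw feature dataset
separable_blobs <- function(n_per_class = 30L, gap = 6, seed = 1L, d = 3L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d, 0), n_per_class),
             matrix(stats::rnorm(n_per_class * d, gap), n_per_class))
  colnames(x) <- paste0("f", seq_len(d))
  labeled_dataset(x, rep(c("noncoding", "coding"), each = n_per_class),
                  ids = paste0("t", seq_len(2L * n_per_class)))
}

blob_config <- function(d = 3L) {
  structure(list(kmers = character(), use_conservation = FALSE,
                 feature_order = paste0("f", seq_len(d))),
            class = "feature_config")
}

# small corpus spec for fast tests; the default-sized spec is exercised in
# the acceptance suite
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_coding = 40L, n_noncoding = 40L,
                 length_range = c(250L, 800L),
                 orf_length_range = c(150L, 450L),
                 exon_count_range = c(1L, 3L),
                 intron_length_range = c(40L, 120L),
                 gap_range = c(100L, 200L),
                 n_chroms = 4L, seed = seed, ...)
}
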