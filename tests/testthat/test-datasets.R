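test_that("filter_by_length keeps strictly longer transcripts", {
  mk <- function(len) transcript_model(paste0("t", len), "c", "+",
                                       cbind(0, len))
  txs <- lapply(c(200, 201, 500), mk)
  out <- filter_by_length(txs, 200)
  expect_equal(vapply(out$transcripts, transcript_length, 0), c(201, 500))
  expect_equal(out$dropped, 1)

  empty <- filter_by_length(list(), 200)
  expect_length(empty$transcripts, 0)
  expect_equal(empty$dropped, 0)

  expect_length(filter_by_length(txs, 0)$transcripts, 3)
})

test_that("cross_annotation_filter is strand-aware and structure-exact", {
  cand <- transcript_model("linc1", "c", "+", cbind(100, 300))
  ref_same <- transcript_model("pct1", "c", "+", cbind(250, 400))
  ref_anti <- transcript_model("pct2", "c", "-", cbind(250, 400))
  ref_away <- transcript_model("pct3", "c", "+", cbind(500, 700))

  expect_length(cross_annotation_filter(list(cand), list(ref_same),
                                        "exclude_overlap"), 0)
  expect_length(cross_annotation_filter(list(cand), list(ref_anti),
                                        "exclude_overlap"), 1)
  expect_length(cross_annotation_filter(list(cand), list(ref_away),
                                        "exclude_overlap"), 1)

  # require_consistent: id match or exact exon chain
  same_structure <- transcript_model("other_id", "c", "+", cbind(100, 300))
  expect_length(cross_annotation_filter(list(cand), list(same_structure),
                                        "require_consistent"), 1)
  expect_length(cross_annotation_filter(list(cand), list(ref_away),
                                        "require_consistent"), 0)
  by_id <- transcript_model("linc1", "c", "+", cbind(900, 1200))
  expect_length(cross_annotation_filter(list(cand), list(by_id),
                                        "require_consistent"), 1)
})

test_that("make_split takes half the positives plus equal negatives", {
  set.seed(50)
  n_pos <- 101L
  n_neg <- 240L
  x <- matrix(rnorm((n_pos + n_neg) * 2), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  pos <- labeled_dataset(x[1:n_pos, ], rep("noncoding", n_pos),
                         ids = paste0("p", 1:n_pos))
  neg <- labeled_dataset(x[-(1:n_pos), ], rep("coding", n_neg),
                         ids = paste0("n", 1:n_neg))
  split <- make_split(pos, neg, seed = 3)
  expect_equal(sum(split$train$labels == "noncoding"), 50)
  expect_equal(sum(split$train$labels == "coding"), 50)
  expect_equal(sum(split$test$labels == "noncoding"), 51)
  expect_equal(sum(split$test$labels == "coding"), 190)
  expect_length(intersect(split$train$ids, split$test$ids), 0)

  split2 <- make_split(pos, neg, seed = 3)
  expect_identical(split$train$ids, split2$train$ids)

  tiny_neg <- lincsvm:::dataset_subset(neg, 1:3)
  expect_error(make_split(pos, tiny_neg), "fewer than half")
})

test_that("synthetic_spec validates its ranges", {
  expect_error(synthetic_spec(length_range = c(150, 500)), "exceed 200")
  expect_error(synthetic_spec(orf_length_range = c(100, 300)),
               "multiples of 3")
  expect_error(synthetic_spec(length_range = c(250, 500),
                              orf_length_range = c(300, 600)), "infeasible")
  expect_error(synthetic_spec(cons_mean_coding = 1.5), "\\[0, 1\\]")
})

test_that("generated transcripts carry the embedded ORF where the log says", {
  corpus <- generate_corpus(small_spec(seed = 21))
  coding <- corpus$log[corpus$log$label == "coding", ]
  txs <- corpus$transcripts
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  for (i in seq_len(nrow(coding))) {
    row <- coding[i, ]
    seq <- extract_sequence(txs[[row$transcript_id]], corpus$genome)
    expect_equal(nchar(seq), row$length)
    orf <- substr(seq, row$orf_start + 1, row$orf_start + row$orf_length)
    expect_equal(substr(orf, 1, 3), "ATG")
    expect_true(substr(orf, row$orf_length - 2, row$orf_length) %in%
                  c("TAA", "TAG", "TGA"))
    # no internal in-frame stop
    internal <- substring(orf, seq(4, row$orf_length - 5, by = 3),
                          seq(6, row$orf_length - 3, by = 3))
    expect_false(any(internal %in% c("TAA", "TAG", "TGA")))
    # the longest-ORF finder recovers at least this ORF
    expect_gte(find_longest_orf(seq)$length_nt, row$orf_length)
  }
})

test_that("generated transcripts never overlap each other", {
  corpus <- generate_corpus(small_spec(seed = 22))
  by_chrom <- split(corpus$transcripts,
                    vapply(corpus$transcripts, `[[`, "", "chrom"))
  for (txs in by_chrom) {
    spans <- t(vapply(txs, function(tx) {
      c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2])
    }, numeric(2)))
    ord <- order(spans[, 1])
    spans <- spans[ord, , drop = FALSE]
    if (nrow(spans) > 1) {
      expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
    }
  }
})

test_that("the default length regime passes the curation length filter", {
  corpus <- generate_corpus(small_spec(seed = 23))
  expect_equal(filter_by_length(corpus$transcripts, 200)$dropped, 0)
})

test_that("corpus regeneration from one seed is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(small_spec(seed = 24), outdir = d1)
  generate_corpus(small_spec(seed = 24), outdir = d2)
  for (f in c("genome.fa", "transcripts.bed", "transcripts.gtf",
              "cons.bedGraph", "truth.tsv", "log.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed changes the corpus
  d3 <- withr::local_tempdir()
  generate_corpus(small_spec(seed = 25), outdir = d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("class feature distributions differ in the expected directions", {
  corpus <- generate_corpus(small_spec(seed = 26))
  m <- build_feature_matrix(corpus$transcripts, corpus$genome, corpus$track,
                            feature_config())
  lab <- corpus$truth$label[match(rownames(m), corpus$truth$transcript_id)]
  coding <- lab == "coding"
  expect_gt(mean(m[coding, "orf_proportion"]),
            mean(m[!coding, "orf_proportion"]))
  expect_gt(mean(m[coding, "orf_length"]), mean(m[!coding, "orf_length"]))
  expect_gt(mean(m[coding, "conservation"]),
            mean(m[!coding, "conservation"]))
})

test_that("the corpus round-trips through its own serialized files", {
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(small_spec(seed = 27), outdir = dir)
  txs <- parse_bed(corpus$paths$bed)
  expect_equal(txs, corpus$transcripts)
  expect_equal(parse_gtf(corpus$paths$gtf), corpus$transcripts)
  genome <- read_fasta(corpus$paths$genome)
  expect_equal(genome, corpus$genome)
  track <- read_conservation(corpus$paths$conservation)
  m_mem <- build_feature_matrix(corpus$transcripts, corpus$genome,
                                corpus$track, feature_config())
  m_file <- build_feature_matrix(txs, genome, track, feature_config())
  expect_equal(m_file, m_mem)
})

test_that("split_transcripts is balanced, disjoint and deterministic", {
  corpus <- generate_corpus(small_spec(seed = 28))
  s1 <- split_transcripts(corpus$transcripts, corpus$truth, seed = 4)
  s2 <- split_transcripts(corpus$transcripts, corpus$truth, seed = 4)
  expect_identical(s1$train$truth, s2$train$truth)
  expect_equal(sum(s1$train$truth$label == "noncoding"), 20)
  expect_equal(sum(s1$train$truth$label == "coding"), 20)
  expect_length(intersect(s1$train$truth$transcript_id,
                          s1$test$truth$transcript_id), 0)
  expect_equal(sort(c(s1$train$truth$transcript_id,
                      s1$test$truth$transcript_id)),
               sort(corpus$truth$transcript_id))
})
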