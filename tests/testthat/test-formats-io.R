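test_that("parse_bed reconstructs exons from BED12 blocks and falls back on BED6", {
  f <- withr::local_tempfile(lines = c(
    "chr1\t100\t200\ttx1\t0\t+\t100\t100\t0\t2\t20,30\t0,70",
    "chr2\t0\t250\ttx2\t0\t-"))
  txs <- parse_bed(f)
  expect_length(txs, 2L)
  expect_equal(unname(txs[[1]]$exons), cbind(c(100, 170), c(120, 200)))
  expect_equal(txs[[1]]$strand, "+")
  expect_equal(transcript_length(txs[[1]]), 50)
  expect_equal(unname(txs[[2]]$exons), cbind(0, 250))
  expect_equal(txs[[2]]$strand, "-")
})

test_that("parse_bed rejects malformed lines with their line number", {
  f <- withr::local_tempfile(lines = c(
    "chr1\t0\t300\tok\t0\t+",
    paste(c("chr1", "100", "200", "bad", "0", "+", "100", "100", "0", "2",
            "20,30"), collapse = "\t")))
  expect_error(parse_bed(f), "line 2")
  f2 <- withr::local_tempfile(lines = "chr1\tx\t200\ttx\t0\t+")
  expect_error(parse_bed(f2), "non-numeric")
  f3 <- withr::local_tempfile(lines = "chr1\t0\t90\ttx\t0\t+\t0\t0\t0\t2\t10,10\t0")
  expect_error(parse_bed(f3), "mismatch")
})

test_that("parse_gtf converts coordinates, sorts exons, validates strands", {
  f <- withr::local_tempfile(lines = c(
    'chr1\tsrc\texon\t171\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\tsrc\texon\t101\t120\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";'))
  txs <- parse_gtf(f)
  expect_length(txs, 1L)
  expect_equal(unname(txs[[1]]$exons), cbind(c(100, 170), c(120, 200)))

  # GFF3 dialect via Parent=
  f2 <- withr::local_tempfile(lines = c(
    "chr1\tsrc\texon\t101\t120\t.\t+\t.\tID=e1;Parent=tx9",
    "chr1\tsrc\texon\t171\t200\t.\t+\t.\tID=e2;Parent=tx9"))
  txs2 <- parse_gtf(f2)
  expect_equal(txs2[[1]]$transcript_id, "tx9")
  expect_equal(txs2[[1]]$exons, txs[[1]]$exons)

  f3 <- withr::local_tempfile(lines = c(
    'chr1\tsrc\texon\t101\t120\t.\t+\t.\ttranscript_id "mix";',
    'chr1\tsrc\texon\t171\t200\t.\t-\t.\ttranscript_id "mix";'))
  expect_error(parse_gtf(f3), "mixes strands")

  f4 <- withr::local_tempfile(lines = "chr1\tsrc\texon\t101\t120\t.\t+\t.\tfoo bar")
  expect_error(parse_gtf(f4), "transcript identifier")
})

test_that("GTF and BED encodings of one transcript agree", {
  tx <- transcript_model("tx1", "chr3", "-", cbind(c(10, 90), c(40, 150)))
  bed <- withr::local_tempfile()
  gtf <- withr::local_tempfile()
  write_bed12(list(tx), bed)
  write_gtf(list(tx), gtf)
  expect_equal(parse_bed(bed), parse_gtf(gtf))
})

test_that("BED12 -> model -> BED12 round trip is bit-exact", {
  corpus <- generate_corpus(small_spec(seed = 3), outdir = withr::local_tempdir())
  reparsed <- parse_bed(corpus$paths$bed)
  rewritten <- withr::local_tempfile()
  write_bed12(reparsed, rewritten)
  expect_identical(readLines(rewritten), readLines(corpus$paths$bed))
})

test_that("read_fasta uppercases, masks ambiguity codes, rejects duplicates", {
  f <- withr::local_tempfile(lines = c(">chr1 some description", "acgt", "ACGT"))
  g <- read_fasta(f)
  expect_equal(genome_subseq(g, "chr1", 0, 8), "ACGTACGT")

  f2 <- withr::local_tempfile(lines = c(">chr1", "ACRT"))
  expect_equal(genome_subseq(read_fasta(f2), "chr1", 0, 4), "ACNT")

  f3 <- withr::local_tempfile(lines = c(">chr1", "AAAA", ">chr1", "CCCC"))
  expect_error(read_fasta(f3), "duplicate")

  f4 <- withr::local_tempfile(lines = character())
  expect_error(read_fasta(f4))
})

test_that("read_conservation handles fixedStep, variableStep and bedGraph", {
  f <- withr::local_tempfile(lines = c("fixedStep chrom=chr1 start=11 step=1",
                                       "0.5", "0.7"))
  tr <- read_conservation(f)
  tx <- transcript_model("t", "chr1", "+", cbind(10, 12))
  expect_equal(conservation_feature(tx, tr), 0.6)

  f2 <- withr::local_tempfile(lines = c("variableStep chrom=chr2",
                                        "5 0.2", "9 0.4"))
  tr2 <- read_conservation(f2)
  expect_equal(conservation_feature(transcript_model("t", "chr2", "+",
                                                     cbind(4, 5)), tr2), 0.2)

  f3 <- withr::local_tempfile(lines = "chr1\t0\t3\t1.0")
  tr3 <- read_conservation(f3)
  expect_equal(conservation_feature(transcript_model("t", "chr1", "+",
                                                     cbind(0, 3)), tr3), 1.0)

  f4 <- withr::local_tempfile(lines = c("fixedStep chrom=chr1 start=1 step=1",
                                        "1.5"))
  expect_error(read_conservation(f4), "outside \\[0, 1\\]")

  f5 <- withr::local_tempfile(lines = "who knows what this is")
  expect_error(read_conservation(f5), "unknown track format")
})

test_that("overlapping conservation records: last one wins, with warning", {
  f <- withr::local_tempfile(lines = c("chr1\t0\t2\t0.1", "chr1\t1\t2\t0.9"))
  expect_warning(tr <- read_conservation(f), "overlapping")
  expect_equal(conservation_feature(transcript_model("t", "chr1", "+",
                                                     cbind(1, 2)), tr), 0.9)
})

test_that("extract_sequence splices exons and honours strand", {
  g <- genome_sequence(c(chrA = "AAACCCGGGTTT"))
  plus <- transcript_model("p", "chrA", "+", cbind(c(3, 9), c(6, 12)))
  minus <- transcript_model("m", "chrA", "-", cbind(c(3, 9), c(6, 12)))
  expect_equal(extract_sequence(plus, g), "CCCTTT")
  expect_equal(extract_sequence(minus, g), "AAAGGG")

  out_of_bounds <- transcript_model("o", "chrA", "+", cbind(10, 20))
  expect_error(extract_sequence(out_of_bounds, g), "coordinate error")
  expect_error(extract_sequence(transcript_model("u", "chrZ", "+",
                                                 cbind(0, 2)), g),
               "unknown chromosome")
})

test_that("minus-strand extraction is the reverse complement of plus-strand", {
  set.seed(42)
  g <- genome_sequence(c(c1 = random_dna(500)))
  for (i in 1:10) {
    starts <- c(0, 160, 330) + sample(0:50, 3)
    exons <- cbind(starts, starts + c(10, 15, 20))
    plus <- transcript_model("p", "c1", "+", exons)
    minus <- transcript_model("m", "c1", "-", exons)
    s_plus <- extract_sequence(plus, g)
    expect_identical(extract_sequence(minus, g),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(s_plus))))
    expect_equal(nchar(s_plus), transcript_length(plus))
  }
})

test_that("write_predictions emits the 3-column schema with 4-decimal scores", {
  f <- withr::local_tempfile()
  preds <- data.frame(transcript_id = c("tx1", "tx2"),
                      label = c("noncoding", "coding"),
                      noncoding_score = c(0.97, 1.0))
  write_predictions(preds, f)
  lines <- readLines(f)
  expect_equal(lines[1], "transcript_id\tlabel\tnoncoding_score")
  expect_equal(lines[2], "tx1\tnoncoding\t0.9700")
  expect_equal(lines[3], "tx2\tcoding\t1.0000")

  write_predictions(preds[0, ], f)
  expect_equal(readLines(f), "transcript_id\tlabel\tnoncoding_score")
})

test_that("unstranded records are treated as plus with a warning", {
  f <- withr::local_tempfile(lines = "chr1\t0\t250\ttx\t0\t.")
  expect_warning(txs <- parse_bed(f), "treated as '\\+'")
  expect_equal(txs[[1]]$strand, "+")
})
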