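test_that("synthetic genomes plant the requested repeat structure", {
  gs <- make_synthetic_genome(20000, list(n_families = 4L, copies = 3L,
                                          length = 250L, divergence = 0),
                              seed = 9)
  expect_equal(nchar(gs$genome[[1]]), 20000)
  expect_equal(nrow(gs$repeats), 12L)
  # copies of a family are identical at divergence 0 and non-overlapping
  for (f in 1:4) {
    rr <- gs$repeats[gs$repeats$family == f, ]
    seqs <- substring(gs$genome[[1]], rr$start, rr$end)
    expect_equal(length(unique(seqs)), 1L)
  }
  ir <- IRanges::IRanges(gs$repeats$start, gs$repeats$end)
  expect_equal(length(IRanges::reduce(ir)), 12L)
  # divergence: copies differ at about the requested rate
  gs2 <- make_synthetic_genome(20000, list(n_families = 1L, copies = 2L,
                                           length = 1000L, divergence = 0.05),
                               seed = 10)
  rr <- gs2$repeats
  a <- strsplit(substring(gs2$genome[[1]], rr$start[1], rr$end[1]), "")[[1]]
  b <- strsplit(substring(gs2$genome[[1]], rr$start[2], rr$end[2]), "")[[1]]
  expect_gt(mean(a != b), 0.01)
  expect_lt(mean(a != b), 0.12)
})

test_that("genome mutation respects the rate and the 2:1:1 split", {
  g <- make_synthetic_genome(1e6, seed = 21)$genome
  expect_identical(mutate_genome(g, 0, seed = 1)$genome, g)
  mut <- mutate_genome(g, 0.01, seed = 22)
  n <- nchar(g[[1]])
  frac <- nrow(mut$log) / n
  sd3 <- 3 * sqrt(0.01 * 0.99 / n)
  expect_lt(abs(frac - 0.01), sd3)
  # every logged change is real
  ch <- mut$log[sample(nrow(mut$log), 50), ]
  expect_true(all(substring(mut$genome[[1]], ch$pos, ch$pos) == ch$alt))
  expect_true(all(substring(g[[1]], ch$pos, ch$pos) == ch$ref))
  # transitions take half the mutation mass from each base
  cmut <- mut$log[mut$log$ref == "C", ]
  p <- mean(cmut$alt == "T")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(cmut)))
})

test_that("methylation and conversion follow context probabilities", {
  g <- make_synthetic_genome(3e5, seed = 31)$genome
  # fully methylated: nothing converts
  conv1 <- methylate_and_convert(g, 1, 1, seed = 32)
  expect_identical(conv1$top, g)
  expect_identical(conv1$bottom, g)
  conv <- methylate_and_convert(g, 0.80, 0.005, seed = 33)
  mm <- conv$meth_map
  # map covers every cytosine of both strands exactly once
  v <- seq_to_int(g[[1]])
  expect_equal(sum(mm$strand == "+"), sum(v == 2L))
  expect_equal(sum(mm$strand == "-"), sum(v == 3L))
  expect_false(any(duplicated(mm[, c("pos", "strand")])))
  # conversion fractions within 3 sigma binomial bounds
  for (str in c("+", "-")) {
    cpg <- mm[mm$context == "CpG" & mm$strand == str, ]
    ch <- mm[mm$context == "CH" & mm$strand == str, ]
    expect_lt(abs(mean(!cpg$methylated) - 0.20),
              3 * sqrt(0.2 * 0.8 / nrow(cpg)))
    expect_lt(abs(mean(!ch$methylated) - 0.995),
              3 * sqrt(0.995 * 0.005 / nrow(ch)))
  }
  # unmethylated forward cytosines read T, methylated stay C
  plus <- mm[mm$strand == "+", ]
  tops <- substring(conv$top[[1]], plus$pos, plus$pos)
  expect_true(all(tops[plus$methylated] == "C"))
  expect_true(all(tops[!plus$methylated] == "T"))
  # reverse-strand conversion shows as G -> A in forward coordinates
  minus <- mm[mm$strand == "-", ]
  bots <- substring(conv$bottom[[1]], minus$pos, minus$pos)
  expect_true(all(bots[minus$methylated] == "G"))
  expect_true(all(bots[!minus$methylated] == "A"))
})

test_that("read sampling is faithful and error injection is calibrated", {
  g <- make_synthetic_genome(50000, seed = 41)$genome
  conv <- methylate_and_convert(g, 0.8, 0.005, seed = 42)
  clean <- sample_reads(conv$top, 60, 500, error_rate = 0, seed = 43)
  expect_equal(nrow(clean$reads), 500)
  same <- vapply(seq_len(500), function(i)
    substr(conv$top[[1]], clean$truth$start[i], clean$truth$start[i] + 59) ==
      clean$reads$seq[i], logical(1))
  expect_true(all(same))
  expect_true(all(clean$truth$n_errors == 0))
  noisy <- sample_reads(conv$top, 60, 2000, error_rate = 0.03, seed = 44)
  frac <- sum(noisy$truth$n_errors) / (2000 * 60)
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / (2000 * 60)))
  # quality strings encode the error model
  eps <- decode_phred(noisy$reads$qual[1])[[1]]
  expect_true(all(abs(eps - 0.03) / 0.03 < 0.2))
  # determinism under a fixed seed
  again <- sample_reads(conv$top, 60, 2000, error_rate = 0.03, seed = 44)
  expect_identical(noisy, again)
  empty <- sample_reads(conv$top, 60, 0, seed = 45)
  expect_equal(nrow(empty$reads), 0)
})

test_that("evidence coverage hits the requested depth over candidates", {
  g <- make_synthetic_genome(30000, seed = 51)$genome
  conv <- methylate_and_convert(g, 0.8, 0.005, seed = 52)
  cand <- data.frame(contig = "chr1", start = c(1001L, 1021L, 5001L),
                     end = c(1076L, 1096L, 5076L), strand = "+")
  for (depth in c(3L, 25L)) {
    ev <- generate_unique_coverage(cand, conv, depth = depth,
                                   read_length = 76, error_rate = 0,
                                   seed = 53)
    expect_true(all(ev$strand == "+"))
    # per-position coverage over the candidate intervals near the target
    cov <- integer(nchar(g[[1]]))
    for (i in seq_len(nrow(ev)))
      cov[ev$start[i]:(ev$start[i] + 75L)] <- cov[ev$start[i]:(ev$start[i] + 75L)] + 1L
    inside <- unlist(lapply(seq_len(nrow(cand)), function(i)
      cand$start[i]:cand$end[i]))
    expect_gt(mean(cov[inside]), 0.5 * depth)
    expect_lt(mean(cov[inside]), 2.5 * depth)
    expect_true(all(cov[inside] >= 1L))
  }
  # reverse-strand candidates draw from the converted bottom strand
  cand_m <- data.frame(contig = "chr1", start = 2001L, end = 2076L,
                       strand = "-")
  evm <- generate_unique_coverage(cand_m, conv, depth = 5, read_length = 76,
                                  error_rate = 0, seed = 54)
  expect_true(all(evm$strand == "-"))
  i <- which.max(evm$start <= 2001)
  expect_equal(evm$seq[i],
               substr(conv$bottom[[1]], evm$start[i], evm$start[i] + 75L))
})

test_that("the full simulation pipeline is deterministic under its seed", {
  cfg <- simulation_config(genome_length = 30000, n_reads = 300,
                           repeat_spec = list(n_families = 3L, copies = 2L,
                                              length = 200L, divergence = 0),
                           seed = 61)
  s1 <- simulate_bs_experiment(cfg)
  s2 <- simulate_bs_experiment(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$mutation_log, s2$mutation_log)
  expect_identical(s1$converted, s2$converted)
  # FASTQ round trip is byte-identical
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})
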