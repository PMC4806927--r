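# Small randomized fixtures built in code.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_qual <- function(n, qmin = 10L, qmax = 40L, offset = 33L) {
  intToUtf8(sample(qmin:qmax, n, replace = TRUE) + offset)
}

# a random small assignment instance: one contig, one multiread with T
# candidate locations, r evidence reads scattered over the contig
random_instance <- function(seed, K_max = 5, T_max = 3, r_max = 4,
                            strands = c("+", "-")) {
  set.seed(seed)
  glen <- 60L
  contig <- rand_seq(glen)
  K <- sample(2:K_max, 1)
  T <- sample(2:T_max, 1)
  strand <- sample(strands, 1)
  starts <- sample(seq_len(glen - K + 1), T)
  reads <- data.frame(read_id = "mr1", seq = rand_seq(K),
                      qual = rand_qual(K), stringsAsFactors = FALSE)
  cand <- data.frame(read_id = "mr1", contig = "chr1", start = starts,
                     strand = strand, stringsAsFactors = FALSE)
  r <- sample(0:r_max, 1)
  unique_reads <- if (r > 0) {
    L <- sample(3:8, r, replace = TRUE)
    data.frame(read_id = paste0("u", seq_len(r)),
               contig = "chr1",
               start = vapply(L, function(l) sample(seq_len(glen - l + 1), 1), 1L),
               strand = sample(strands, r, replace = TRUE),
               seq = vapply(L, rand_seq, character(1)),
               qual = vapply(L, rand_qual, character(1)),
               mapq = sample(c(20L, 60L), r, replace = TRUE, prob = c(.2, .8)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(0), contig = character(0),
               start = integer(0), strand = character(0),
               seq = character(0), qual = character(0), mapq = integer(0),
               stringsAsFactors = FALSE)
  }
  list(reference = c(chr1 = contig),
       multireads = list(reads = reads, candidates = cand),
       unique_reads = unique_reads)
}

# scalar-API candidate descriptions for the same instance, with pileups
# from the package pileup builder
instance_candidates <- function(inst, config = scoring_config()) {
  reads <- inst$multireads$reads
  cand <- inst$multireads$candidates
  contig <- inst$reference[[1]]
  lapply(seq_len(nrow(cand)), function(i) {
    K <- nchar(reads$seq[1])
    start <- cand$start[i]
    list(M = strsplit(reads$seq[1], "")[[1]],
         R = strsplit(substr(contig, start, start + K - 1), "")[[1]],
         eps = decode_phred(reads$qual[1], config$phred_offset)[[1]],
         pileup = build_pileup(list(contig = "chr1", start = start, K = K,
                                    strand = cand$strand[i]),
                               inst$unique_reads, config),
         contexts = vapply(seq_len(K), function(k)
           oracle_context(contig, start + k - 1, cand$strand[i]), character(1)),
         strand = cand$strand[i],
         start = start)
  })
}

# deterministic evidence read data frame over one contig
evidence_frame <- function(ids, starts, seqs, quals, strand = "+",
                           mapq = 60L, contig = "chr1") {
  n <- length(ids)
  data.frame(read_id = ids, contig = rep_len(contig, n),
             start = starts, strand = rep_len(strand, n),
             seq = seqs, qual = quals, mapq = rep_len(mapq, n),
             stringsAsFactors = FALSE)
}

# constant-quality string: Q20 -> eps 0.01
q20 <- function(n) strrep("5", n)
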