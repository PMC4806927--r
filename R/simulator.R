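# Bisulfite read simulator: mutate a reference, assign per-cytosine
# methylation by context, bisulfite-convert both strands, emit directional
# reads with error injection, and generate unique-read evidence coverage
# over candidate loci. Every operation is deterministic under its seed.

#' Simulation configuration
#'
#' Study conditions for the synthetic benchmark. Defaults follow the
#' simulation settings the assignment model is calibrated for: per-base
#' mutation rate 0.001 split 2:1:1 between transition and transversions,
#' CpG methylation 0.80 (so 20% of CpG cytosines convert), CH methylation
#' 0.005 (99.5% convert), directional 76 bp reads, 30x evidence coverage.
#' The genome length, planted repeats, read count and the constant
#' per-base error rate (0.005, a typical Illumina HiSeq average) are
#' desk-scale stand-ins for the genome-scale originals.
#'
#' @param genome_length bases in the synthetic genome.
#' @param repeat_spec list with `n_families`, `copies`, `length`,
#'   `divergence`: planted repeat families that guarantee multireads.
#' @param mutation_rate per-base SNP probability applied to the genome.
#' @param cpg_meth_prob methylation probability of CpG cytosines.
#' @param ch_meth_prob methylation probability of CH cytosines.
#' @param read_length read length in bp (51, 76 and 101 mirror common
#'   library designs).
#' @param n_reads number of directional reads to draw.
#' @param coverage_depth evidence reads overlapping each candidate locus.
#' @param error_rate constant per-base miscall probability, or a vector of
#'   per-cycle probabilities of length `read_length`.
#' @param phred_offset quality encoding offset for emitted FASTQ.
#' @param seed integer seed governing all five stages.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 2e5,
                              repeat_spec = list(n_families = 30L,
                                                 copies = 2L,
                                                 length = 400L,
                                                 divergence = 0),
                              mutation_rate = 0.001,
                              cpg_meth_prob = 0.80,
                              ch_meth_prob = 0.005,
                              read_length = 76L,
                              n_reads = 20000L,
                              coverage_depth = 30L,
                              error_rate = 0.005,
                              phred_offset = 33L,
                              seed = 1L) {
  stopifnot(genome_length >= 2 * repeat_spec$length,
            mutation_rate >= 0, mutation_rate <= 1,
            cpg_meth_prob >= 0, cpg_meth_prob <= 1,
            ch_meth_prob >= 0, ch_meth_prob <= 1,
            read_length >= 20, n_reads >= 0, coverage_depth >= 1,
            all(error_rate >= 0), all(error_rate < 1),
            phred_offset %in% c(33, 64))
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic genome with planted repeat families
#'
#' Draws a uniform-random ACGT genome and plants `n_families` repeat
#' families of `copies` near-identical copies each at non-overlapping
#' positions. `divergence` is the expected per-base difference between
#' copies of a family; identical copies (`divergence = 0`) make every read
#' drawn from their interior a perfect multiread at the matching offsets.
#'
#' @param length genome length in bases.
#' @param repeat_spec list with `n_families`, `copies`, `length`,
#'   `divergence`.
#' @param seed integer seed.
#' @param contig_name name of the single contig.
#' @return List with `genome` (named character vector) and `repeats`
#'   (data frame: `family`, `copy`, `start`, `end`).
#' @export
make_synthetic_genome <- function(length, repeat_spec = list(n_families = 0L,
                                                             copies = 2L,
                                                             length = 0L,
                                                             divergence = 0),
                                  seed = 1L, contig_name = "chr1") {
  set.seed(seed)
  v <- sample.int(4L, length, replace = TRUE)
  nf <- repeat_spec$n_families %||% 0L
  reps <- NULL
  if (nf > 0L) {
    rl <- repeat_spec$length
    nc <- repeat_spec$copies
    div <- repeat_spec$divergence %||% 0
    total <- nf * nc
    if (total * rl > 0.6 * length)
      stop("repeat content exceeds 60% of the genome; reduce repeat_spec")
    occupied <- logical(length)
    starts <- integer(total)
    placed <- 0L
    tries <- 0L
    while (placed < total && tries < 200L * total) {
      tries <- tries + 1L
      s <- sample.int(length - rl + 1L, 1L)
      if (!any(occupied[s:(s + rl - 1L)])) {
        placed <- placed + 1L
        starts[placed] <- s
        occupied[max(1L, s - rl):(min(length, s + 2L * rl))] <- TRUE
      }
    }
    if (placed < total) stop("could not place all repeat copies; genome too small")
    fam <- rep(seq_len(nf), each = nc)
    cpy <- rep(seq_len(nc), nf)
    for (f in seq_len(nf)) {
      unit <- sample.int(4L, rl, replace = TRUE)
      for (k in seq_len(nc)) {
        copy <- unit
        if (div > 0) {
          nmut <- stats::rbinom(1L, rl, div)
          if (nmut > 0) {
            at <- sample.int(rl, nmut)
            copy[at] <- ((copy[at] - 1L + sample.int(3L, nmut, replace = TRUE)) %% 4L) + 1L
          }
        }
        s <- starts[(f - 1L) * nc + k]
        v[s:(s + rl - 1L)] <- copy
      }
    }
    reps <- data.frame(family = fam, copy = cpy, start = starts[seq_len(total)],
                       end = starts[seq_len(total)] + rl - 1L)
  }
  g <- stats::setNames(int_to_seq(v), contig_name)
  list(genome = g, repeats = reps)
}

# transversion alternatives for each base (rows: base 1..4)
.TRANSVERSIONS <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

#' Mutate a genome at a given SNP rate
#'
#' Every base mutates independently with probability `rate`; a mutating
#' base becomes its transition partner with probability 1/2 and each
#' transversion with probability 1/4 (transitions twice as frequent as
#' each transversion, e.g. C to T at `rate/2 = 0.0005` for the default
#' 0.001).
#'
#' @param genome named character vector of contigs.
#' @param rate per-base mutation probability.
#' @param seed integer seed.
#' @return List with `genome` (mutated) and `log` (data frame: `contig`,
#'   `pos`, `ref`, `alt`).
#' @export
mutate_genome <- function(genome, rate = 0.001, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  genome <- as_genome(genome)
  set.seed(seed)
  logs <- vector("list", length(genome))
  out <- genome
  for (ci in seq_along(genome)) {
    v <- seq_to_int(genome[[ci]])
    idx <- which(stats::runif(length(v)) < rate & v != 0L)
    if (length(idx)) {
      u <- stats::runif(length(idx))
      old <- v[idx]
      alt <- ifelse(u < 0.5, .TRANSITION[old],
                    ifelse(u < 0.75, .TRANSVERSIONS[old, 1L],
                           .TRANSVERSIONS[old, 2L]))
      v[idx] <- alt
      logs[[ci]] <- data.frame(contig = names(genome)[ci], pos = idx,
                               ref = .BASES[old], alt = .BASES[alt],
                               stringsAsFactors = FALSE)
      out[[ci]] <- int_to_seq(v)
    }
  }
  log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))]) %||%
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  list(genome = out, log = log)
}

#' Assign methylation states and bisulfite-convert both strands
#'
#' Each cytosine (C on the forward strand, G position for the reverse
#' strand) is independently methylated with the probability of its
#' context, classified on the mutated genome: CpG when the next base on
#' the cytosine's own strand is G, CH otherwise. Unmethylated cytosines
#' convert (C to T on the top strand; the reverse-strand conversion shows
#' as G to A in forward coordinates); methylated cytosines are protected.
#'
#' @param genome named character vector (typically the mutated genome).
#' @param cpg_meth_prob,ch_meth_prob methylation probabilities by context.
#' @param seed integer seed.
#' @return List with `top` and `bottom` (converted strands, both in
#'   forward coordinates) and `meth_map` (data frame: `contig`, `pos`,
#'   `strand`, `context`, `methylated`), covering every cytosine of both
#'   strands exactly once.
#' @export
methylate_and_convert <- function(genome, cpg_meth_prob = 0.80,
                                  ch_meth_prob = 0.005, seed = 1L) {
  genome <- as_genome(genome)
  set.seed(seed)
  top <- genome
  bottom <- genome
  maps <- vector("list", 2L * length(genome))
  for (ci in seq_along(genome)) {
    v <- seq_to_int(genome[[ci]])
    # forward strand cytosines
    cpos <- which(v == 2L)
    ctx <- contig_context(v, "+")[cpos]
    pm <- ifelse(ctx == 1L, cpg_meth_prob, ch_meth_prob)
    meth <- stats::runif(length(cpos)) < pm
    vf <- v
    vf[cpos[!meth]] <- 4L
    top[[ci]] <- int_to_seq(vf)
    maps[[2L * ci - 1L]] <- data.frame(contig = names(genome)[ci], pos = cpos,
                                       strand = "+",
                                       context = c("CpG", "CH")[ctx],
                                       methylated = meth,
                                       stringsAsFactors = FALSE)
    # reverse strand cytosines appear as G in forward coordinates
    gpos <- which(v == 3L)
    ctxr <- contig_context(v, "-")[gpos]
    pmr <- ifelse(ctxr == 1L, cpg_meth_prob, ch_meth_prob)
    methr <- stats::runif(length(gpos)) < pmr
    vr <- v
    vr[gpos[!methr]] <- 1L
    bottom[[ci]] <- int_to_seq(vr)
    maps[[2L * ci]] <- data.frame(contig = names(genome)[ci], pos = gpos,
                                  strand = "-",
                                  context = c("CpG", "CH")[ctxr],
                                  methylated = methr,
                                  stringsAsFactors = FALSE)
  }
  list(top = top, bottom = bottom, meth_map = do.call(rbind, maps))
}

# draw reads from given starts of one converted contig and inject errors;
# eps_cycle is the per-cycle miscall probability vector (length L)
.draw_reads <- function(contig_seq, contig_name, starts, L, eps_cycle,
                        phred_offset, prefix, strand = "+") {
  n <- length(starts)
  if (n == 0L)
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), start = integer(0),
                      n_errors = integer(0), stringsAsFactors = FALSE))
  v <- seq_to_int(contig_seq)
  idx <- rep(starts, each = L) + seq_len(L) - 1L
  m <- matrix(v[idx], nrow = L)
  err <- matrix(stats::runif(n * L) < eps_cycle, nrow = L)
  ne <- sum(err)
  if (ne > 0) {
    shift <- sample.int(3L, ne, replace = TRUE)
    m[err] <- ((m[err] - 1L + shift) %% 4L) + 1L
  }
  qual <- encode_phred(eps_cycle, phred_offset)
  data.frame(read_id = sprintf("%s_%06d", prefix, seq_len(n)),
             seq = apply(m, 2L, int_to_seq),
             qual = qual,
             start = starts,
             n_errors = as.integer(colSums(err)),
             stringsAsFactors = FALSE)
}

#' Sample directional bisulfite reads from the converted top strand
#'
#' Reads start uniformly at random on the top strand of the converted
#' genome (a directional library sequences only the bisulfite-converted
#' top strand). Per-position miscalls are injected according to
#' `error_rate` (constant or per-cycle profile) and the quality string
#' encodes those probabilities.
#'
#' @param converted_top named character vector: converted top strand.
#' @param read_length read length (must not exceed any contig length).
#' @param n_reads number of reads.
#' @param error_rate scalar or per-cycle miscall probability vector.
#' @param seed integer seed.
#' @param phred_offset quality encoding offset.
#' @param prefix read-name prefix.
#' @return List with `reads` (data frame `read_id`, `seq`, `qual`) and
#'   `truth` (data frame `read_id`, `contig`, `start`, `strand`,
#'   `n_errors`).
#' @export
sample_reads <- function(converted_top, read_length, n_reads,
                         error_rate = 0.005, seed = 1L, phred_offset = 33L,
                         prefix = "read") {
  converted_top <- as_genome(converted_top)
  L <- as.integer(read_length)
  stopifnot(all(nchar(converted_top) >= L))
  eps_cycle <- rep_len(error_rate, L)
  set.seed(seed)
  if (n_reads == 0L)
    return(list(reads = data.frame(read_id = character(0), seq = character(0),
                                   qual = character(0)),
                truth = data.frame(read_id = character(0), contig = character(0),
                                   start = integer(0), strand = character(0),
                                   n_errors = integer(0))))
  avail <- nchar(converted_top) - L + 1L
  ci <- sample.int(length(converted_top), n_reads, replace = TRUE,
                   prob = avail / sum(avail))
  out <- vector("list", length(converted_top))
  made <- 0L
  for (c0 in seq_along(converted_top)) {
    n_c <- sum(ci == c0)
    if (n_c == 0L) next
    starts <- sample.int(avail[c0], n_c, replace = TRUE)
    df <- .draw_reads(converted_top[[c0]], names(converted_top)[c0], starts,
                      L, eps_cycle, phred_offset,
                      sprintf("%s_%s", prefix, names(converted_top)[c0]))
    df$contig <- names(converted_top)[c0]
    out[[c0]] <- df
    made <- made + n_c
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  list(reads = df[, c("read_id", "seq", "qual")],
       truth = data.frame(read_id = df$read_id, contig = df$contig,
                          start = df$start, strand = "+",
                          n_errors = df$n_errors, stringsAsFactors = FALSE))
}

#' Generate unique-read evidence coverage over candidate loci
#'
#' Emits strand-matched reads from the converted genome so that every
#' candidate location is overlapped by about `depth` unique reads per
#' position. Overlapping candidate intervals are merged and reads are
#' staggered uniformly over each merged region (extended so edge positions
#' get full depth), with at least `min(20, read_length/2)` bases of
#' overlap.
#'
#' @param candidates data frame with `contig`, `start`, `end`, `strand`.
#' @param converted list with `top` and `bottom` converted strands (as
#'   returned by [methylate_and_convert()]); `"-"` candidates draw from
#'   `bottom`.
#' @param depth target per-position evidence coverage.
#' @param read_length evidence read length.
#' @param error_rate scalar or per-cycle miscall probabilities.
#' @param seed integer seed.
#' @param phred_offset quality encoding offset.
#' @param mapq mapping quality stamped on the evidence reads.
#' @return Data frame of unique reads (`read_id`, `contig`, `start`,
#'   `strand`, `seq`, `qual`, `mapq`, `cigar`).
#' @export
generate_unique_coverage <- function(candidates, converted, depth = 30L,
                                     read_length = 76L, error_rate = 0.005,
                                     seed = 1L, phred_offset = 33L,
                                     mapq = 60L) {
  stopifnot(depth >= 1)
  L <- as.integer(read_length)
  eps_cycle <- rep_len(error_rate, L)
  top <- as_genome(converted$top)
  bottom <- as_genome(converted$bottom %||% converted$top)
  set.seed(seed)
  ov_min <- min(20L, L %/% 2L)
  pieces <- list()
  pc <- 0L
  for (str in unique(candidates$strand)) {
    src <- if (str == "+") top else bottom
    for (cg in unique(candidates$contig[candidates$strand == str])) {
      sel <- candidates$strand == str & candidates$contig == cg
      ir <- IRanges::reduce(IRanges::IRanges(candidates$start[sel],
                                             candidates$end[sel]))
      clen <- nchar(src[[cg]])
      for (i in seq_along(ir)) {
        lo <- max(1L, IRanges::start(ir)[i] - (L - ov_min))
        hi <- min(clen - L + 1L, IRanges::end(ir)[i] - ov_min + 1L)
        if (hi < lo) { lo <- max(1L, min(lo, clen - L + 1L)); hi <- lo }
        span <- hi - lo + 1L
        n <- max(as.integer(depth), as.integer(ceiling(depth * span / L)))
        starts <- lo + sample.int(span, n, replace = TRUE) - 1L
        pc <- pc + 1L
        df <- .draw_reads(src[[cg]], cg, starts, L, eps_cycle, phred_offset,
                          sprintf("ev%04d", pc), strand = str)
        df$contig <- cg
        df$strand <- str
        pieces[[pc]] <- df
      }
    }
  }
  if (!length(pieces))
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), strand = character(0),
                      seq = character(0), qual = character(0),
                      mapq = integer(0), cigar = character(0)))
  df <- do.call(rbind, pieces)
  data.frame(read_id = df$read_id, contig = df$contig, start = df$start,
             strand = df$strand, seq = df$seq, qual = df$qual,
             mapq = mapq, cigar = paste0(L, "M"), stringsAsFactors = FALSE)
}

#' Run the full simulation pipeline
#'
#' Genome generation, mutation, methylation/conversion and read sampling
#' under one configuration, with per-stage seeds derived from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List with `reference` (the original, pre-mutation genome: the
#'   genome an aligner would be given), `repeats`, `mutated`,
#'   `mutation_log`, `converted` (`top`, `bottom`), `meth_map`, `reads`,
#'   `truth`, and the `config`.
#' @export
simulate_bs_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  s <- as.integer(config$seed) %% 536870912L
  gen <- make_synthetic_genome(config$genome_length, config$repeat_spec,
                               seed = s + 1L)
  mut <- mutate_genome(gen$genome, config$mutation_rate, seed = s + 2L)
  conv <- methylate_and_convert(mut$genome, config$cpg_meth_prob,
                                config$ch_meth_prob, seed = s + 3L)
  rd <- sample_reads(conv$top, config$read_length, config$n_reads,
                     config$error_rate, seed = s + 4L,
                     phred_offset = config$phred_offset)
  list(reference = gen$genome, repeats = gen$repeats,
       mutated = mut$genome, mutation_log = mut$log,
       converted = conv[c("top", "bottom")], meth_map = conv$meth_map,
       reads = rd$reads, truth = rd$truth, config = config)
}

#' Build a complete assignment benchmark fixture
#'
#' Runs [simulate_bs_experiment()], aligns the reads to the original
#' reference with [align_bs_reads()], and generates evidence coverage over
#' every candidate location of the resulting multireads. The fixture is
#' everything the assigner needs, plus the truth table for scoring.
#'
#' @param config a [simulation_config()].
#' @return List with `reference`, `multireads`, `unique_reads`, `truth`
#'   (for the multireads only), `n_total_reads`, `n_unmapped`, `sim` (the
#'   full simulation bundle).
#' @export
simulate_benchmark <- function(config = simulation_config()) {
  sim <- simulate_bs_experiment(config)
  aln <- align_bs_reads(sim$reads, sim$reference)
  cand <- aln$multireads$candidates
  ev <- if (nrow(cand)) {
    locs <- data.frame(contig = cand$contig, start = cand$start,
                       end = cand$start + config$read_length - 1L,
                       strand = cand$strand, stringsAsFactors = FALSE)
    generate_unique_coverage(locs, sim$converted, config$coverage_depth,
                             config$read_length, config$error_rate,
                             seed = (as.integer(config$seed) %% 536870912L) + 5L,
                             phred_offset = config$phred_offset)
  } else data.frame()
  list(reference = sim$reference,
       multireads = aln$multireads,
       unique_reads = ev,
       truth = sim$truth[sim$truth$read_id %in% aln$multireads$reads$read_id, ,
                         drop = FALSE],
       n_total_reads = nrow(sim$reads),
       n_unmapped = aln$n_unmapped,
       sim = sim)
}
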