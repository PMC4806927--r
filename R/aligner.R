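#' Align directional bisulfite reads in the three-letter alphabet
#'
#' A compact seed-and-extend aligner for fully synthetic benchmarks. Reads
#' and the forward strand of the reference are collapsed to a three-letter
#' alphabet (C to T, so bisulfite conversion can never cause a mismatch).
#' Two exact seeds per read (leading and central) are located with
#' `Biostrings::matchPDict`; every seed hit is extended to a full-length
#' comparison and kept when the collapsed mismatch count is at most
#' `max_mismatches`. Hits within `mismatch_slack` of the read's best hit
#' are its candidate locations ("similar fidelity"). Reads of a
#' directional library are only aligned to the top strand.
#'
#' Reads with one candidate are reported as uniquely mapped, reads with
#' two or more as multireads, and reads with none (or more than
#' `max_hits`) are discarded. This stands in for a production bisulfite
#' mapper when benchmarking the assignment model on planted-repeat
#' genomes.
#'
#' @param reads data frame with `read_id`, `seq`, `qual`.
#' @param reference named character vector of contigs (or path/DNAStringSet).
#' @param max_mismatches mismatch budget in the collapsed alphabet.
#' @param mismatch_slack candidates are kept within this many mismatches of
#'   the read's best hit.
#' @param max_hits reads with more candidate locations than this are
#'   dropped as unalignably repetitive.
#' @param seed_length exact seed length (shortened for very short reads).
#' @param unique_mapq mapping quality given to uniquely aligned reads.
#' @return List with `multireads` (`reads` + `candidates` data frames,
#'   candidate `mismatches` from the collapsed comparison), `unique_reads`,
#'   `n_unmapped`, `n_too_ambiguous`.
#' @export
align_bs_reads <- function(reads, reference, max_mismatches = 3L,
                           mismatch_slack = 1L, max_hits = 10L,
                           seed_length = 20L, unique_mapq = 60L) {
  reference <- as_genome(reference)
  n <- nrow(reads)
  clean <- grepl("^[ACGT]+$", reads$seq)
  collapsed <- chartr("C", "T", reads$seq)
  widths <- nchar(reads$seq)
  genome_c <- lapply(reference, function(x) chartr("C", "T", x))
  genome_int <- lapply(genome_c, utf8ToInt)
  read_int <- lapply(collapsed, utf8ToInt)

  pieces <- list()
  for (ci in seq_along(reference)) {
    subject <- Biostrings::DNAString(genome_c[[ci]])
    glen <- nchar(genome_c[[ci]])
    for (w in unique(widths[clean])) {
      idx <- which(clean & widths == w)
      sl <- min(seed_length, w %/% 2L)
      offs <- unique(c(1L, w - sl + 1L))       # leading and trailing seeds
      cand <- vector("list", length(offs))
      for (oi in seq_along(offs)) {
        off <- offs[oi]
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(
          substring(collapsed[idx], off, off + sl - 1L)))
        st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
        cnt <- lengths(st)
        cand[[oi]] <- data.frame(ridx = rep.int(idx, cnt),
                                 start = unlist(st, use.names = FALSE) - off + 1L)
      }
      hits <- unique(do.call(rbind, cand))
      hits <- hits[hits$start >= 1L & hits$start + w - 1L <= glen, ,
                   drop = FALSE]
      if (nrow(hits) == 0L) next
      # extension: mismatch count of the full collapsed read at each hit
      gi <- genome_int[[ci]]
      mm <- vapply(seq_len(nrow(hits)), function(i) {
        s <- hits$start[i]
        sum(read_int[[hits$ridx[i]]] != gi[s:(s + w - 1L)])
      }, integer(1))
      keep <- mm <= max_mismatches
      if (!any(keep)) next
      pieces[[length(pieces) + 1L]] <-
        data.frame(ridx = hits$ridx[keep], contig = names(reference)[ci],
                   start = hits$start[keep], nm = mm[keep],
                   stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(pieces)) do.call(rbind, pieces)
          else data.frame(ridx = integer(0), contig = character(0),
                          start = integer(0), nm = integer(0))
  # similar fidelity: within mismatch_slack of the per-read best hit
  if (nrow(hits)) {
    best <- stats::ave(hits$nm, hits$ridx, FUN = min)
    hits <- hits[hits$nm <= best + mismatch_slack, , drop = FALSE]
    hits <- hits[order(hits$ridx, hits$contig, hits$start), , drop = FALSE]
  }
  nh <- tabulate(hits$ridx, nbins = n)
  uni_idx <- which(nh == 1L)
  multi_idx <- which(nh >= 2L & nh <= max_hits)
  unique_reads <- {
    h <- hits[hits$ridx %in% uni_idx, , drop = FALSE]
    data.frame(read_id = reads$read_id[h$ridx], contig = h$contig,
               start = h$start, strand = rep("+", nrow(h)),
               seq = reads$seq[h$ridx], qual = reads$qual[h$ridx],
               mapq = rep(as.integer(unique_mapq), nrow(h)),
               cigar = sprintf("%dM", widths[h$ridx]),
               stringsAsFactors = FALSE)
  }
  cand <- {
    h <- hits[hits$ridx %in% multi_idx, , drop = FALSE]
    data.frame(read_id = reads$read_id[h$ridx], contig = h$contig,
               start = h$start, strand = rep("+", nrow(h)),
               cigar = sprintf("%dM", widths[h$ridx]),
               mismatches = h$nm, stringsAsFactors = FALSE)
  }
  list(multireads = list(reads = reads[multi_idx, c("read_id", "seq", "qual"),
                                       drop = FALSE],
                         candidates = cand),
       unique_reads = unique_reads,
       n_unmapped = sum(nh == 0L),
       n_too_ambiguous = sum(nh > max_hits))
}
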