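# Independent brute-force oracle: a literal, loop-based evaluation of the
# posterior formulas, kept deliberately separate from the package
# implementation. Priors are read from the prior_table data frame by
# subsetting (not through lookup_prior / the dense array).

oracle_prior <- function(table, ref, obs, context, strand) {
  df <- as.data.frame(table)
  row <- df[df$ref == ref & df$obs == obs & df$context == context &
              df$strand == strand, ]
  stopifnot(nrow(row) == 1)
  row$prob
}

oracle_eps <- function(qual, offset = 33) {
  e <- 10^(-(utf8ToInt(qual) - offset) / 10)
  pmin(pmax(e, 1e-10), 0.75)
}

oracle_base_lik <- function(d, m, ej, ek) {
  if (d == m) 1 - ej - ek + ej * ek else ej + ek - ej * ek
}

oracle_col_lik <- function(bases, epsj, m, ek) {
  tot <- 0
  for (j in seq_along(bases)) tot <- tot + oracle_base_lik(bases[j], m, epsj[j], ek)
  tot / length(bases)
}

oracle_complement_lik <- function(bases, epsj, m, ref, ek, table, context, strand) {
  alts <- setdiff(c("A", "C", "G", "T"), m)
  w <- sapply(alts, function(b) oracle_prior(table, ref, b, context, strand))
  if (sum(w) <= 0) w <- rep(1, 3)
  w <- w / sum(w)
  out <- 0
  for (i in seq_along(alts))
    out <- out + w[[i]] * oracle_col_lik(bases, epsj, alts[i], ek)
  out
}

oracle_position_posterior <- function(m, ref, bases, epsj, ek, table, context, strand) {
  if (!(m %in% c("A", "C", "G", "T")) || !(ref %in% c("A", "C", "G", "T")))
    return(NA_real_)
  keep <- bases %in% c("A", "C", "G", "T")
  bases <- bases[keep]; epsj <- epsj[keep]
  p <- oracle_prior(table, ref, m, context, strand)
  if (length(bases) == 0) return(p)
  if (p >= 1) return(1)
  if (p <= 0) return(0)
  num <- p * oracle_col_lik(bases, epsj, m, ek)
  den <- num + (1 - p) *
    oracle_complement_lik(bases, epsj, m, ref, ek, table, context, strand)
  if (den <= 0) return(p)
  num / den
}

# naive per-position pileup scan over the unique-read data frame
oracle_pileup <- function(contig, start, K, strand, unique_reads,
                          mapq_min = 30, offset = 33) {
  cols <- replicate(K, list(bases = character(0), eps = numeric(0)),
                    simplify = FALSE)
  for (i in seq_len(nrow(unique_reads))) {
    u <- unique_reads[i, ]
    if (u$contig != contig || u$strand != strand || u$mapq < mapq_min) next
    ub <- strsplit(u$seq, "")[[1]]
    ue <- oracle_eps(u$qual, offset)
    for (off in seq_along(ub)) {
      gpos <- u$start + off - 1
      k <- gpos - start + 1
      if (k >= 1 && k <= K && ub[off] %in% c("A", "C", "G", "T")) {
        cols[[k]]$bases <- c(cols[[k]]$bases, ub[off])
        cols[[k]]$eps <- c(cols[[k]]$eps, ue[off])
      }
    }
  }
  cols
}

# context of position pos on a contig string, per strand
oracle_context <- function(contig_seq, pos, strand) {
  n <- nchar(contig_seq)
  if (strand == "+") {
    if (pos >= n) return("CH")
    if (substr(contig_seq, pos + 1, pos + 1) == "G") "CpG" else "CH"
  } else {
    if (pos <= 1) return("CH")
    if (substr(contig_seq, pos - 1, pos - 1) == "C") "CpG" else "CH"
  }
}

oracle_read_log_posterior <- function(read_seq, read_qual, contig_seq, start,
                                      strand, unique_reads, table,
                                      mapq_min = 30, offset = 33,
                                      floor = 1e-300) {
  M <- strsplit(read_seq, "")[[1]]
  K <- length(M)
  ek <- oracle_eps(read_qual, offset)
  R <- strsplit(substr(contig_seq, start, start + K - 1), "")[[1]]
  pile <- oracle_pileup("chr1", start, K, strand, unique_reads, mapq_min,
                        offset)
  lp <- 0
  for (k in seq_len(K)) {
    ctx <- oracle_context(contig_seq, start + k - 1, strand)
    post <- oracle_position_posterior(M[k], R[k], pile[[k]]$bases,
                                      pile[[k]]$eps, ek[k], table, ctx, strand)
    if (is.na(post)) next
    lp <- lp + log(max(post, floor))
  }
  lp
}

# full oracle over a small instance: per-candidate log posteriors and S
oracle_assign <- function(reads, cand, contig_seq, unique_reads, table,
                          mapq_min = 30, offset = 33) {
  out <- data.frame(read_id = cand$read_id, log_posterior = NA_real_)
  for (i in seq_len(nrow(cand))) {
    ri <- which(reads$read_id == cand$read_id[i])
    out$log_posterior[i] <- oracle_read_log_posterior(
      reads$seq[ri], reads$qual[ri], contig_seq, cand$start[i],
      cand$strand[i], unique_reads, table, mapq_min, offset)
  }
  S <- sapply(unique(cand$read_id), function(id) {
    lp <- sort(out$log_posterior[out$read_id == id], decreasing = TRUE)
    lp[1] - lp[2]
  })
  list(log_posteriors = out, S = S)
}
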