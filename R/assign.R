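# Batch assignment engine. The per-read math is identical to
# read_log_posterior()/assign_multiread(); this path vectorises pileup
# construction and the per-position posterior across all candidates with
# data.table so that tens of thousands of candidate locations score in
# seconds. Agreement between the two paths is enforced by tests.

# aligned (read offset, reference position) pairs for one alignment.
# M/=/X consume read+ref, I and S consume read, D and N consume ref,
# H consumes nothing. Insertions and clips are skipped: the model is
# defined per aligned base pair.
cigar_ref_positions <- function(cigar, start, read_len) {
  if (is.null(cigar) || is.na(cigar) || cigar == "*")
    return(list(read_off = seq_len(read_len), ref_pos = start + seq_len(read_len) - 1L))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  ro <- integer(0); rp <- integer(0)
  cur_r <- 0L; cur_g <- start - 1L
  for (i in seq_along(ops)) {
    n <- lens[i]
    op <- ops[i]
    if (op %in% c("M", "=", "X")) {
      ro <- c(ro, cur_r + seq_len(n))
      rp <- c(rp, cur_g + seq_len(n))
      cur_r <- cur_r + n; cur_g <- cur_g + n
    } else if (op %in% c("I", "S")) {
      cur_r <- cur_r + n
    } else if (op %in% c("D", "N")) {
      cur_g <- cur_g + n
    }
  }
  list(read_off = ro, ref_pos = rp)
}

# expand unique reads into a long per-position evidence table
# (contig idx, strand idx, pos, base int, eps); N bases are dropped.
.evidence_table <- function(unique_reads, contig_names, phred_offset) {
  n <- nrow(unique_reads)
  empty <- data.frame(cid = integer(0), s = integer(0), pos = integer(0),
                      d = integer(0), eps = numeric(0))
  if (n == 0L) return(empty)
  seq_int <- lapply(unique_reads$seq, seq_to_int)
  eps_l <- decode_phred(unique_reads$qual, phred_offset)
  cigars <- if ("cigar" %in% names(unique_reads)) unique_reads$cigar else rep(NA_character_, n)
  simple <- is.na(cigars) | cigars == "*" | grepl("^[0-9]+M$", cigars)
  lens <- lengths(seq_int)
  pieces <- vector("list", 2L)
  if (any(simple)) {
    idx <- which(simple)
    L <- lens[idx]
    rows <- rep.int(idx, L)
    pieces[[1]] <- data.frame(
      cid = match(unique_reads$contig[rows], contig_names),
      s = match(unique_reads$strand[rows], c("+", "-")),
      pos = unique_reads$start[rows] + sequence(L) - 1L,
      d = unlist(seq_int[idx], use.names = FALSE),
      eps = unlist(eps_l[idx], use.names = FALSE))
  }
  if (any(!simple)) {
    idx <- which(!simple)
    lst <- lapply(idx, function(i) {
      ap <- cigar_ref_positions(cigars[i], unique_reads$start[i], lens[i])
      data.frame(
        cid = match(unique_reads$contig[i], contig_names),
        s = match(unique_reads$strand[i], c("+", "-")),
        pos = ap$ref_pos,
        d = seq_int[[i]][ap$read_off],
        eps = eps_l[[i]][ap$read_off])
    })
    pieces[[2]] <- do.call(rbind, lst)
  }
  ev <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  ev[ev$d != 0L, , drop = FALSE]
}

#' Assign a set of multireads to their most probable locations
#'
#' Runs the full Bayesian assignment over every multiread: builds the
#' pileup of strand-matched, MAPQ-filtered unique reads at each candidate
#' location, computes the per-position posteriors and per-candidate log
#' posteriors, scores `S` (best versus next-best log posterior), and
#' applies the `S0` cutoff plus the unique-read coverage rule.
#'
#' @param multireads a list with elements `reads` (data frame: `read_id`,
#'   `seq`, `qual`) and `candidates` (data frame: `read_id`, `contig`,
#'   `start` (1-based), `strand`, optional `cigar`, `mismatches`, and
#'   optional per-candidate `seq`/`qual` when the orientation differs from
#'   the primary record), as produced by [load_alignments()] or
#'   [align_bs_reads()].
#' @param unique_reads data frame of uniquely mapped evidence reads:
#'   `read_id`, `contig`, `start`, `strand`, `seq`, `qual`, `mapq`,
#'   optional `cigar`.
#' @param reference named character vector of contig sequences (or a
#'   `DNAStringSet`).
#' @param table a `prior_table`; defaults to [build_prior_table()] with
#'   default parameters in the mode named by `config$prior_mode`.
#' @param config a [scoring_config()].
#' @return An object of class `multiread_assignment`: a data frame with one
#'   row per multiread (`read_id`, `n_candidates`, chosen `contig`,
#'   `start`, `strand`, `S`, `status`, flags, coverage and log posterior
#'   diagnostics), with the per-candidate score table in
#'   `attr(, "candidates")`.
#' @export
assign_multireads <- function(multireads, unique_reads, reference,
                              table = NULL, config = scoring_config()) {
  reference <- as_genome(reference)
  table <- table %||% build_prior_table(prior_params(), mode = config$prior_mode)
  reads <- multireads$reads
  cand <- as.data.frame(multireads$candidates)
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)),
            all(c("read_id", "contig", "start", "strand") %in% names(cand)))
  if (nrow(cand) == 0L || nrow(reads) == 0L)
    return(.empty_assignment())

  # MAPQ filter on evidence
  unique_reads <- as.data.frame(unique_reads)
  if (nrow(unique_reads) > 0) {
    keep <- unique_reads$mapq >= config$mapq_min
    if (any(!keep))
      message(sum(!keep), " unique reads dropped below MAPQ ", config$mapq_min)
    unique_reads <- unique_reads[keep, , drop = FALSE]
  }

  contig_names <- names(reference)
  if (!all(cand$contig %in% contig_names))
    stop("candidate contig not present in the reference")
  ref_int <- lapply(reference, seq_to_int)
  ctx_f <- lapply(ref_int, contig_context, strand = "+")
  ctx_r <- lapply(ref_int, contig_context, strand = "-")
  arr <- attr(table, "array")

  # per-candidate read sequence/qualities (orientation-aware)
  ridx <- match(cand$read_id, reads$read_id)
  if (anyNA(ridx)) stop("candidate read_id missing from the read table")
  cseq <- if ("seq" %in% names(cand)) ifelse(is.na(cand$seq), reads$seq[ridx], cand$seq) else reads$seq[ridx]
  cqual <- if ("qual" %in% names(cand)) ifelse(is.na(cand$qual), reads$qual[ridx], cand$qual) else reads$qual[ridx]
  cig <- if ("cigar" %in% names(cand)) cand$cigar else rep(NA_character_, nrow(cand))

  nc <- nrow(cand)
  m_int <- lapply(cseq, seq_to_int)
  eps_l <- decode_phred(cqual, config$phred_offset)
  K <- lengths(m_int)
  bad <- K != lengths(eps_l)
  if (any(bad)) stop("read/quality length mismatch for ",
                     paste(unique(cand$read_id[bad]), collapse = ", "))
  cnd_cid <- match(cand$contig, contig_names)
  cnd_sid <- match(cand$strand, c("+", "-"))
  if (anyNA(cnd_sid)) stop("candidate strand must be '+' or '-'")
  clen <- vapply(ref_int, length, integer(1))

  # aligned pairs per candidate (fast path for gapless alignments)
  simple <- is.na(cig) | cig == "*" | grepl("^[0-9]+M$", cig)
  pairs <- vector("list", nc)
  for (i in which(!simple))
    pairs[[i]] <- cigar_ref_positions(cig[i], cand$start[i], K[i])

  nk <- K
  for (i in which(!simple)) nk[i] <- length(pairs[[i]]$read_off)
  rows <- rep.int(seq_len(nc), nk)
  pos <- unlist(lapply(seq_len(nc), function(i)
    if (simple[i]) cand$start[i] + seq_len(K[i]) - 1L else pairs[[i]]$ref_pos),
    use.names = FALSE)
  if (any(pos < 1L) || any(pos > clen[cnd_cid[rows]]))
    stop("candidate alignment extends outside its contig")

  COL <- data.table::data.table(
    cand = rows,
    cid = cnd_cid[rows],
    s = cnd_sid[rows],
    pos = pos,
    M = unlist(lapply(seq_len(nc), function(i) m_int[[i]][if (simple[i]) seq_len(K[i]) else pairs[[i]]$read_off]), use.names = FALSE),
    epsk = unlist(lapply(seq_len(nc), function(i) eps_l[[i]][if (simple[i]) seq_len(K[i]) else pairs[[i]]$read_off]), use.names = FALSE))
  COL$R <- {
    r <- integer(nrow(COL))
    for (ci in unique(COL$cid)) {
      w <- COL$cid == ci
      r[w] <- ref_int[[ci]][COL$pos[w]]
    }
    r
  }
  COL$ctx <- {
    x <- integer(nrow(COL))
    for (ci in unique(COL$cid)) {
      wf <- COL$cid == ci & COL$s == 1L
      wr <- COL$cid == ci & COL$s == 2L
      x[wf] <- ctx_f[[ci]][COL$pos[wf]]
      x[wr] <- ctx_r[[ci]][COL$pos[wr]]
    }
    x
  }
  valid <- COL$M != 0L & COL$R != 0L
  COL$p <- NA_real_
  COL$p[valid] <- arr[cbind(COL$R[valid], COL$M[valid], COL$ctx[valid], COL$s[valid])]
  pb <- matrix(NA_real_, nrow(COL), 4L)
  for (b in 1:4)
    pb[valid, b] <- arr[cbind(COL$R[valid], b, COL$ctx[valid], COL$s[valid])]
  COL$valid <- valid

  # evidence sorted by a single numeric (contig, strand, position) key so
  # each pileup column is a contiguous slice located with findInterval
  ev <- .evidence_table(unique_reads, contig_names, config$phred_offset)
  evkey <- ((ev$cid - 1) * 2 + (ev$s - 1)) * 2^31 + ev$pos
  o <- order(evkey)
  evkey <- evkey[o]
  ev_d <- ev$d[o]
  ev_eps <- ev$eps[o]

  # block-wise posterior computation
  lp <- numeric(nc)
  coverage <- numeric(nc)
  floored <- integer(nc)
  depth_guess <- if (nrow(ev)) max(1, nrow(ev) / max(1, sum(!duplicated(evkey))))
                 else 1
  block <- max(200L, as.integer(8e6 / (max(mean(nk), 1) * depth_guess)))
  col_cand <- COL$cand
  for (b0 in seq(1L, nc, by = block)) {
    b1 <- min(b0 + block - 1L, nc)
    sel <- which(col_cand >= b0 & col_cand <= b1)
    nsub <- length(sel)
    colkey <- ((COL$cid[sel] - 1) * 2 + (COL$s[sel] - 1)) * 2^31 + COL$pos[sel]
    hi <- findInterval(colkey, evkey)
    lo <- findInterval(colkey - 0.5, evkey) + 1L
    w <- hi - lo + 1L
    w[w < 0L] <- 0L
    rows <- sequence(w) + rep.int(lo - 1L, w)
    uid <- rep.int(seq_len(nsub), w)
    dj <- ev_d[rows]
    epsj <- ev_eps[rows]
    epsk <- rep.int(COL$epsk[sel], w)
    m0 <- epsj + epsk - epsj * epsk
    rr <- w
    A <- numeric(nsub)
    Bm <- matrix(0, nsub, 4L)
    if (length(rows)) {
      agg <- rowsum(m0, uid)
      A[as.integer(rownames(agg))] <- agg[, 1]
      aggb <- rowsum(1 - 2 * m0, (uid - 1L) * 4L + dj)
      gidx <- as.integer(rownames(aggb))
      Bm[cbind((gidx - 1L) %/% 4L + 1L, (gidx - 1L) %% 4L + 1L)] <- aggb[, 1]
    }
    Lmat <- (A + Bm) / pmax(rr, 1L)
    PDM <- Lmat[cbind(seq_len(nsub), pmax(COL$M[sel], 1L))]
    denom <- rowSums(pb[sel, , drop = FALSE] * Lmat)
    p <- COL$p[sel]
    post <- p                                  # r = 0 or degenerate prior
    iok <- which(rr > 0L & p > 0 & p < 1 & denom > 0)
    post[iok] <- p[iok] * PDM[iok] / denom[iok]
    i1 <- which(rr > 0L & p >= 1); post[i1] <- 1
    i0 <- which(rr > 0L & p <= 0); post[i0] <- 0
    post[!COL$valid[sel]] <- NA_real_
    fl <- !is.na(post) & post < config$min_posterior
    post[fl] <- config$min_posterior
    logp <- log(post)
    logp[is.na(logp)] <- 0
    agg <- rowsum(cbind(logp, as.numeric(rr), as.numeric(fl)), col_cand[sel])
    idx <- as.integer(rownames(agg))
    lp[idx] <- lp[idx] + agg[, 1]
    coverage[idx] <- coverage[idx] + agg[, 2]
    floored[idx] <- floored[idx] + as.integer(agg[, 3])
  }

  .collect_assignments(cand, lp, coverage, floored, config)
}

# per-read decision + result assembly (vectorised; must agree with
# assignment_score() + .assignment_decision() on every read)
.collect_assignments <- function(cand, lp, coverage, floored, config) {
  nrows <- nrow(cand)
  f <- factor(cand$read_id, levels = unique(cand$read_id))
  g <- as.integer(f)
  nper <- tabulate(g)
  if (any(nper[g] < 2L)) {
    drop <- nper[g] < 2L
    warning(sum(nper < 2L), " reads with fewer than 2 candidates skipped")
    cand <- cand[!drop, , drop = FALSE]
    lp <- lp[!drop]; coverage <- coverage[!drop]; floored <- floored[!drop]
    f <- droplevels(f[!drop]); g <- as.integer(f); nper <- tabulate(g)
    nrows <- nrow(cand)
  }
  ng <- nlevels(f)
  if (ng == 0L) return(.empty_assignment())
  rowidx <- seq_len(nrows)

  # posterior ordering: best and next-best candidate per read
  ord <- order(g, -lp, -coverage, cand$start)
  firsts <- which(!duplicated(g[ord]))
  best <- ord[firsts]
  nxt <- ord[firsts + 1L]
  S <- lp[best] - lp[nxt]
  tie <- lp[best] == lp[nxt]

  # coverage ordering: top and runner-up coverage per read
  ord2 <- order(g, -coverage, rowidx)
  firsts2 <- which(!duplicated(g[ord2]))
  cbest <- ord2[firsts2]
  c2 <- coverage[ord2[firsts2 + 1L]]
  c1 <- coverage[cbest]

  agg <- rowsum(cbind(coverage, as.numeric(floored)), g)
  totcov <- agg[, 1]
  nfl <- as.integer(agg[, 2])

  pass <- S >= config$S0
  covrule <- !pass & totcov > 0 & c1 > 0 &
    c1 >= config$coverage_factor * c2 & c1 > c2
  zerocov <- !pass & totcov == 0
  status <- ifelse(pass | covrule, "assigned", "unassignable")
  chosen <- ifelse(covrule, cbest, best)
  zero_flag <- covrule | zerocov

  cand_index <- stats::ave(rowidx, g, FUN = seq_along)
  out <- data.frame(
    read_id = levels(f), n_candidates = nper,
    contig = cand$contig[chosen], start = cand$start[chosen],
    strand = cand$strand[chosen], best_index = cand_index[chosen],
    S = S, status = status, tie_broken = tie,
    zero_coverage_rule_used = zero_flag,
    coverage_best = coverage[chosen],
    log_post_best = lp[best], log_post_next = lp[nxt],
    n_floored = nfl, stringsAsFactors = FALSE)
  detail <- data.frame(read_id = cand$read_id, cand_index = cand_index,
                       contig = cand$contig, start = cand$start,
                       strand = cand$strand, log_posterior = lp,
                       coverage = coverage, stringsAsFactors = FALSE)
  structure(out, candidates = detail,
            class = c("multiread_assignment", "data.frame"))
}

.empty_assignment <- function() {
  structure(data.frame(read_id = character(0), n_candidates = integer(0),
                       contig = character(0), start = integer(0),
                       strand = character(0), best_index = integer(0),
                       S = numeric(0), status = character(0),
                       tie_broken = logical(0),
                       zero_coverage_rule_used = logical(0),
                       coverage_best = numeric(0),
                       log_post_best = numeric(0), log_post_next = numeric(0),
                       n_floored = integer(0), stringsAsFactors = FALSE),
            candidates = NULL,
            class = c("multiread_assignment", "data.frame"))
}

#' @export
print.multiread_assignment <- function(x, ...) {
  cat(sprintf("Multiread assignment: %d reads, %d assigned (%.1f%%)\n",
              nrow(x), sum(x$status == "assigned"),
              if (nrow(x)) 100 * mean(x$status == "assigned") else 0))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.multiread_assignment <- function(object, ...) {
  n <- nrow(object)
  assigned <- sum(object$status == "assigned")
  out <- list(n_multireads = n, n_assigned = assigned,
              assignable_rate = if (n) assigned / n else NA_real_,
              median_S = stats::median(object$S),
              n_tie_broken = sum(object$tie_broken),
              n_zero_coverage_rule = sum(object$zero_coverage_rule_used))
  class(out) <- "summary.multiread_assignment"
  out
}

#' @export
print.summary.multiread_assignment <- function(x, ...) {
  cat(sprintf("%d multireads; %d assigned (%.2f%%); median S = %.4g\n",
              x$n_multireads, x$n_assigned, 100 * x$assignable_rate,
              x$median_S))
  cat(sprintf("ties broken: %d; coverage rule used: %d\n",
              x$n_tie_broken, x$n_zero_coverage_rule))
  invisible(x)
}

#' Write the per-read decision table
#'
#' Tab-separated output with one row per multiread: identifier, chosen
#' location, assignment score, status and diagnostic flags.
#'
#' @param assignment a `multiread_assignment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(assignment, path) {
  stopifnot(inherits(assignment, "multiread_assignment"))
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
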