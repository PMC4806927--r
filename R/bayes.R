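#' Scoring configuration
#'
#' Tuning knobs for the Bayesian multiread assignment.
#'
#' @param S0 assignment score cutoff; reads with score `S >= S0` are
#'   assigned to their best location, others are reported unassignable.
#'   0.05 suits clean simulated-style data; 0.2 is a safer choice for real
#'   libraries with uneven coverage.
#' @param mapq_min minimum mapping quality for a uniquely mapped read to be
#'   used as evidence.
#' @param phred_offset base-quality ASCII offset (33 or 64).
#' @param prior_mode `"informed"` or `"uniform"` (the "without prior"
#'   variant).
#' @param coverage_factor when `S < S0`, a candidate whose unique-read
#'   coverage exceeds every other candidate's by at least this factor is
#'   still assigned (the "more unique reads" rule for loci with little or
#'   no shared coverage).
#' @param mismatch_slack candidate locations are kept if their mismatch
#'   count is within this many edits of the read's best candidate.
#' @param min_posterior floor applied to a per-position posterior before
#'   taking logs, guarding against underflow.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(S0 = 0.05, mapq_min = 30, phred_offset = 33,
                           prior_mode = c("informed", "uniform"),
                           coverage_factor = 2, mismatch_slack = 1,
                           min_posterior = 1e-300) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(S0 >= 0, mapq_min >= 0, phred_offset %in% c(33, 64),
            coverage_factor >= 1, mismatch_slack >= 0, min_posterior > 0)
  structure(list(S0 = S0, mapq_min = mapq_min, phred_offset = phred_offset,
                 prior_mode = prior_mode, coverage_factor = coverage_factor,
                 mismatch_slack = mismatch_slack,
                 min_posterior = min_posterior),
            class = "scoring_config")
}

#' Likelihood of one unique-read base given the multiread base
#'
#' \eqn{P(d_{jk} \mid M_k)}: if the bases agree,
#' \eqn{1-\epsilon_{jk}-\epsilon_k+\epsilon_{jk}\epsilon_k}; otherwise
#' \eqn{\epsilon_{jk}+\epsilon_k-\epsilon_{jk}\epsilon_k}. This is the
#' probability that neither (resp. at least one) of the two independent
#' base calls is in error. Matching is literal: a unique-read T over a
#' multiread C is a mismatch; bisulfite ambiguity is carried entirely by
#' the prior.
#'
#' @param d unique-read base(s).
#' @param m multiread base.
#' @param eps_jk miscall probability of the unique-read base.
#' @param eps_k miscall probability of the multiread base.
#' @return Numeric vector of likelihoods, recycled over the longest input.
#' @export
base_likelihood <- function(d, m, eps_jk, eps_k) {
  stopifnot(all(eps_jk >= 0 & eps_jk < 1), all(eps_k >= 0 & eps_k < 1))
  mism <- eps_jk + eps_k - eps_jk * eps_k
  ifelse(toupper(d) == toupper(m), 1 - mism, mism)
}

#' Average likelihood of a pileup column
#'
#' \eqn{P(D_k \mid M_k) = \sum_j P(d_{jk} \mid M_k) / r}: the arithmetic
#' mean over the `r` unique reads covering the position, rather than their
#' product, so that deep columns are not penalised simply for having more
#' observations.
#'
#' @param bases bases observed by the covering unique reads.
#' @param eps_unique their miscall probabilities.
#' @param m multiread base.
#' @param eps_k multiread base miscall probability.
#' @return The mean likelihood; errors if the column is empty (columns with
#'   no coverage are handled by the prior-only rule in the posterior).
#' @export
column_likelihood <- function(bases, eps_unique, m, eps_k) {
  r <- length(bases)
  if (r == 0L) stop("empty pileup column; no unique-read coverage")
  stopifnot(length(eps_unique) == r)
  mean(base_likelihood(bases, m, eps_unique, eps_k))
}

# prior-weighted mixture weights over the three bases other than m
.complement_weights <- function(table, ref, m, context, strand) {
  alts <- setdiff(.BASES, toupper(m))
  w <- lookup_prior(table, rep(ref, 3), alts, context, strand)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) w <- rep(1 / 3, 3) else w <- w / tot
  names(w) <- alts
  w
}

#' Likelihood of a pileup column under the complementary hypothesis
#'
#' \eqn{P(D_k \mid \bar M_k)}, the likelihood that the multiread base is
#' *not* \eqn{M_k}, marginalised over the three alternative bases with
#' weights proportional to their prior probabilities given the reference
#' base: \eqn{\sum_{b \ne M_k} w_b \, P(D_k \mid b)} with
#' \eqn{w_b = \pi(b \mid R_k) / \sum_{b' \ne M_k} \pi(b' \mid R_k)}.
#' Under a uniform prior this reduces to the simple average over the three
#' alternatives.
#'
#' @inheritParams column_likelihood
#' @param ref reference base at the position.
#' @param table a [build_prior_table()] result.
#' @param context,strand sequence context and alignment strand used for the
#'   prior lookup.
#' @return The mixture likelihood.
#' @export
complement_likelihood <- function(bases, eps_unique, m, ref, eps_k, table,
                                  context = "CH", strand = "+") {
  w <- .complement_weights(table, ref, m, context, strand)
  sum(vapply(names(w), function(b)
    w[[b]] * column_likelihood(bases, eps_unique, b, eps_k), numeric(1)))
}

#' Posterior probability of the multiread base at one position
#'
#' \deqn{P(M_k \mid D_k, R_k) =
#'   \frac{\pi(M_k \mid R_k) P(D_k \mid M_k)}
#'        {\pi(M_k \mid R_k) P(D_k \mid M_k) +
#'         \pi(\bar M_k \mid R_k) P(D_k \mid \bar M_k)}}
#' with \eqn{\pi(\bar M_k \mid R_k) = 1 - \pi(M_k \mid R_k)}.
#'
#' Positions with no unique-read coverage (`length(bases) == 0`) return the
#' prior \eqn{\pi(M_k \mid R_k)} (Bayes' rule under a flat likelihood);
#' positions where either base is `N` return `NA` and are skipped by
#' [read_log_posterior()].
#'
#' @inheritParams complement_likelihood
#' @return A probability in `[0, 1]`, or `NA` for uninformative positions.
#' @export
position_posterior <- function(m, ref, bases, eps_unique, eps_k, table,
                               context = "CH", strand = "+") {
  if (base_to_int(m) == 0L || base_to_int(ref) == 0L) return(NA_real_)
  p <- lookup_prior(table, ref, m, context, strand)
  if (length(bases) == 0L) return(p)
  keep <- base_to_int(bases) != 0L
  bases <- bases[keep]; eps_unique <- eps_unique[keep]
  if (length(bases) == 0L) return(p)
  if (p >= 1) return(1)
  if (p <= 0) return(0)
  num <- p * column_likelihood(bases, eps_unique, m, eps_k)
  den <- num + (1 - p) * complement_likelihood(bases, eps_unique, m, ref,
                                               eps_k, table, context, strand)
  if (den <= 0) return(p)
  num / den
}

#' Log posterior of a multiread at one candidate location
#'
#' \eqn{\log P(X \mid D, R) = \sum_k \log P(M_k \mid D_k, R_k)}, the
#' per-position posteriors multiplied across the read (accumulated in log
#' space). `N` positions contribute 0; posteriors are floored at
#' `min_posterior` before the log and floored positions counted.
#'
#' @param M,R,eps multiread bases, reference bases and multiread miscall
#'   probabilities (equal length `K`).
#' @param pileup list of `K` columns, each a list with elements `bases` and
#'   `eps` holding the covering unique-read observations (possibly empty).
#' @param table a `prior_table`.
#' @param contexts per-position contexts (`"CpG"`/`"CH"`); computed by the
#'   caller from the reference.
#' @param strand alignment strand of the candidate.
#' @param min_posterior underflow floor.
#' @return List with `log_posterior`, `coverage` (total evidence bases over
#'   all columns) and `n_floored`.
#' @export
read_log_posterior <- function(M, R, eps, pileup, table,
                               contexts = rep("CH", length(M)), strand = "+",
                               min_posterior = 1e-300) {
  K <- length(M)
  stopifnot(length(R) == K, length(eps) == K, length(pileup) == K,
            length(contexts) == K)
  lp <- 0
  floored <- 0L
  coverage <- 0L
  for (k in seq_len(K)) {
    col <- pileup[[k]]
    coverage <- coverage + length(col$bases)
    post <- position_posterior(M[k], R[k], col$bases, col$eps, eps[k],
                               table, contexts[k], strand)
    if (is.na(post)) next
    if (post < min_posterior) {
      post <- min_posterior
      floored <- floored + 1L
    }
    lp <- lp + log(post)
  }
  list(log_posterior = lp, coverage = coverage, n_floored = floored)
}

#' Assignment score from per-candidate log posteriors
#'
#' The score of a multiread is the log odds of the posterior at the best
#' candidate location versus the next best,
#' \eqn{S = \log P(X|D)_{best} / P(X|D)_{next}} in natural log units, so
#' `S >= 0` always. Exact ties in log posterior are broken
#' deterministically by higher unique-read coverage, then by lower
#' coordinate.
#'
#' @param log_posteriors numeric vector, one per candidate (length >= 2).
#' @param coverage optional per-candidate total evidence coverage, used for
#'   tie-breaking.
#' @param starts optional per-candidate coordinates, used as the final
#'   tie-break.
#' @return List with `S`, `best`, `next_best` (candidate indices) and
#'   `tie_broken`.
#' @export
assignment_score <- function(log_posteriors, coverage = NULL, starts = NULL) {
  T <- length(log_posteriors)
  if (T < 2L) stop("a multiread needs at least 2 candidate locations")
  coverage <- coverage %||% rep(0L, T)
  starts <- starts %||% seq_len(T)
  ord <- order(-log_posteriors, -coverage, starts)
  best <- ord[1L]
  nxt <- ord[2L]
  list(S = log_posteriors[best] - log_posteriors[nxt],
       best = best, next_best = nxt,
       tie_broken = log_posteriors[best] == log_posteriors[nxt])
}

#' Assign one multiread across its candidate locations
#'
#' Scores each candidate with [read_log_posterior()], computes the
#' assignment score `S`, and decides: `S >= S0` assigns the read to the
#' best location; otherwise, if one candidate's unique-read coverage
#' exceeds every other's by at least `coverage_factor`, the read is
#' assigned there (loci without shared coverage are resolved by "more
#' unique reads"); otherwise the read is unassignable. Reads whose
#' candidates are all entirely uncovered are unassignable.
#'
#' @param candidates list of candidate descriptions, each a list with
#'   `M`, `R`, `eps`, `pileup`, and optionally `contexts`, `strand`,
#'   `start`.
#' @param table a `prior_table`.
#' @param config a [scoring_config()].
#' @return List of class `assignment_result`: `best`, `S`, `status`
#'   (`"assigned"`/`"unassignable"`), `log_posteriors`, `coverage`,
#'   `tie_broken`, `zero_coverage_rule_used`, `n_floored`.
#' @export
assign_multiread <- function(candidates, table, config = scoring_config()) {
  T <- length(candidates)
  if (T < 2L) stop("a multiread needs at least 2 candidate locations")
  scored <- lapply(candidates, function(cc) {
    read_log_posterior(cc$M, cc$R, cc$eps, cc$pileup, table,
                       contexts = cc$contexts %||% rep("CH", length(cc$M)),
                       strand = cc$strand %||% "+",
                       min_posterior = config$min_posterior)
  })
  lp <- vapply(scored, `[[`, numeric(1), "log_posterior")
  cov <- vapply(scored, `[[`, numeric(1), "coverage")
  fl <- sum(vapply(scored, `[[`, integer(1), "n_floored"))
  starts <- vapply(candidates, function(cc) as.numeric(cc$start %||% 0), numeric(1))
  sc <- assignment_score(lp, cov, starts)
  decision <- .assignment_decision(sc, lp, cov, config)
  structure(list(best = decision$best, S = sc$S, status = decision$status,
                 log_posteriors = lp, coverage = cov,
                 tie_broken = sc$tie_broken,
                 zero_coverage_rule_used = decision$zero_rule,
                 n_floored = fl),
            class = "assignment_result")
}

# shared decision rule between the single-read and the batch paths
.assignment_decision <- function(sc, lp, cov, config) {
  if (sc$S >= config$S0)
    return(list(status = "assigned", best = sc$best, zero_rule = FALSE))
  if (all(cov == 0))
    return(list(status = "unassignable", best = sc$best, zero_rule = TRUE))
  i <- which.max(cov)
  other <- max(cov[-i])
  if (cov[i] > 0 && cov[i] >= config$coverage_factor * other && cov[i] > other)
    return(list(status = "assigned", best = i, zero_rule = TRUE))
  list(status = "unassignable", best = sc$best, zero_rule = FALSE)
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("Multiread assignment: %s (S = %.4g, best candidate %d of %d)\n",
              x$status, x$S, x$best, length(x$log_posteriors)))
  if (x$tie_broken) cat("  note: exact tie broken by coverage/coordinate\n")
  if (x$zero_coverage_rule_used) cat("  note: unique-read coverage rule used\n")
  invisible(x)
}
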