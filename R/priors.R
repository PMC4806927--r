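#' Prior model parameters
#'
#' Bundles the quantities that drive the prior probability
#' \eqn{\pi(M_k \mid R_k)} of observing read base \eqn{M_k} over reference
#' base \eqn{R_k}: a per-base SNP rate split 2:1:1 between the transition
#' and the two transversions, and context-specific methylation
#' probabilities for cytosines.
#'
#' With the default `snp_rate = 0.001` the transition receives probability
#' 0.0005, each transversion 0.00025, and the no-mutation mass is 0.999.
#'
#' @param snp_rate per-base mutation (SNP) probability.
#' @param p_meth_cpg probability that a cytosine in CpG context is
#'   methylated (mammalian genomes: about 0.80).
#' @param p_meth_ch probability that a cytosine in CH context
#'   (H in A, C, T) is methylated (about 0.05).
#' @return An object of class `prior_params`.
#' @seealso [build_prior_table()]
#' @export
prior_params <- function(snp_rate = 0.001, p_meth_cpg = 0.80, p_meth_ch = 0.05) {
  for (p in c(snp_rate, p_meth_cpg, p_meth_ch)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("prior parameters must be single probabilities in [0, 1]")
  }
  structure(list(snp_rate = snp_rate,
                 p_meth_cpg = p_meth_cpg,
                 p_meth_ch = p_meth_ch,
                 p_transition = snp_rate / 2,
                 p_transversion = snp_rate / 4),
            class = "prior_params")
}

#' @export
print.prior_params <- function(x, ...) {
  cat("Prior parameters\n")
  cat(sprintf("  SNP rate: %g (transition %g, each transversion %g)\n",
              x$snp_rate, x$p_transition, x$p_transversion))
  cat(sprintf("  P(methylation): CpG %g, CH %g\n", x$p_meth_cpg, x$p_meth_ch))
  invisible(x)
}

# transition partner of each base (A<->G, C<->T), integer coded
.TRANSITION <- c(3L, 4L, 1L, 2L)

#' Build the prior probability table
#'
#' Populates \eqn{\pi(obs \mid ref, context, strand)} for all four
#' reference bases, four observed bases, both cytosine contexts
#' (CpG and CH) and both alignment strands of a directional bisulfite
#' library.
#'
#' On the forward strand, a reference C can be observed as: A or G (pure
#' transversion), C (no mutation and methylated, so protected from
#' conversion), or T (either a C-to-T transition, or no mutation with an
#' unmethylated C converted by bisulfite). Reference A, G and T have no
#' bisulfite effect on a forward read, so the observed base is the
#' reference with probability `1 - snp_rate` and a mutation otherwise.
#' Reverse-strand alignments mirror these rules in forward coordinates:
#' reference G plays the role of C and observed A the role of T, with CpG
#' context determined by the preceding forward base.
#'
#' `mode = "uniform"` replaces every entry by 1/4; this is the
#' "without prior" variant used to measure how much the informed prior
#' contributes to assignment accuracy.
#'
#' @param params a [prior_params()] object.
#' @param mode `"informed"` (default) or `"uniform"`.
#' @return An object of class `prior_table`: a data frame of 64 entries
#'   (`ref`, `obs`, `context`, `strand`, `prob`) carrying the dense lookup
#'   array and the parameters as attributes.
#' @examples
#' pt <- build_prior_table(prior_params(snp_rate = 0.001))
#' lookup_prior(pt, "C", "T", context = "CpG", strand = "+")
#' @export
build_prior_table <- function(params = prior_params(),
                              mode = c("informed", "uniform")) {
  mode <- match.arg(mode)
  if (!inherits(params, "prior_params")) params <- do.call(prior_params, params)
  arr <- array(NA_real_, dim = c(4, 4, 2, 2),
               dimnames = list(ref = .BASES, obs = .BASES,
                               context = c("CpG", "CH"),
                               strand = c("+", "-")))
  if (mode == "uniform") {
    arr[] <- 0.25
  } else {
    snp <- params$snp_rate
    ts <- params$p_transition
    tv <- params$p_transversion
    pm <- c(CpG = params$p_meth_cpg, CH = params$p_meth_ch)
    for (ctx in 1:2) {
      # forward strand: bisulfite acts on reference C only
      arr["C", "A", ctx, "+"] <- tv
      arr["C", "G", ctx, "+"] <- tv
      arr["C", "C", ctx, "+"] <- (1 - snp) * pm[ctx]
      arr["C", "T", ctx, "+"] <- ts + (1 - snp) * (1 - pm[ctx])
      for (ref in c("A", "G", "T")) {
        ri <- base_to_int(ref)
        for (obs in 1:4) {
          arr[ri, obs, ctx, "+"] <-
            if (obs == ri) 1 - snp else if (obs == .TRANSITION[ri]) ts else tv
        }
      }
      # reverse strand (forward coordinates): bisulfite acts on reference G,
      # converting the unmethylated reverse-strand cytosine so it is seen
      # as A here
      arr["G", "C", ctx, "-"] <- tv
      arr["G", "T", ctx, "-"] <- tv
      arr["G", "G", ctx, "-"] <- (1 - snp) * pm[ctx]
      arr["G", "A", ctx, "-"] <- ts + (1 - snp) * (1 - pm[ctx])
      for (ref in c("A", "C", "T")) {
        ri <- base_to_int(ref)
        for (obs in 1:4) {
          arr[ri, obs, ctx, "-"] <-
            if (obs == ri) 1 - snp else if (obs == .TRANSITION[ri]) ts else tv
        }
      }
    }
  }
  df <- expand.grid(ref = .BASES, obs = .BASES, context = c("CpG", "CH"),
                    strand = c("+", "-"), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$prob <- arr[cbind(base_to_int(df$ref), base_to_int(df$obs),
                       match(df$context, c("CpG", "CH")),
                       match(df$strand, c("+", "-")))]
  structure(df, array = arr, params = params, mode = mode,
            class = c("prior_table", "data.frame"))
}

#' @export
print.prior_table <- function(x, ...) {
  cat(sprintf("Prior table (%s mode), %d entries\n", attr(x, "mode"), nrow(x)))
  print(attr(x, "params"))
  arr <- attr(x, "array")
  cat("Forward strand, CpG context:\n")
  print(round(arr[, , "CpG", "+"], 6))
  invisible(x)
}

#' Look up a prior probability
#'
#' Vectorised accessor for \eqn{\pi(obs \mid ref)} entries of a
#' [build_prior_table()] result. `N` in either base position returns `NA`
#' (such positions carry no information and are skipped by the posterior).
#'
#' @param table a `prior_table`.
#' @param ref,obs reference and observed bases (`"A"`, `"C"`, `"G"`, `"T"`,
#'   or `"N"`).
#' @param context `"CpG"` or `"CH"`.
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of probabilities.
#' @export
lookup_prior <- function(table, ref, obs, context = "CH", strand = "+") {
  stopifnot(inherits(table, "prior_table"))
  arr <- attr(table, "array")
  ri <- base_to_int(ref)
  oi <- base_to_int(obs)
  bad <- !(toupper(ref) %in% c(.BASES, "N")) | !(toupper(obs) %in% c(.BASES, "N"))
  if (any(bad)) stop("unknown base: ", paste(unique(c(ref, obs)[c(bad, bad)]), collapse = ", "))
  n <- max(length(ri), length(oi), length(context), length(strand))
  ri <- rep_len(ri, n); oi <- rep_len(oi, n)
  ci <- rep_len(match(context, c("CpG", "CH")), n)
  si <- rep_len(match(strand, c("+", "-")), n)
  if (anyNA(ci)) stop("context must be 'CpG' or 'CH'")
  if (anyNA(si)) stop("strand must be '+' or '-'")
  out <- rep(NA_real_, n)
  ok <- ri > 0L & oi > 0L
  out[ok] <- arr[cbind(ri[ok], oi[ok], ci[ok], si[ok])]
  out
}

#' Export a prior table to a tab-separated file
#'
#' Writes the 64 entries as plain text (columns `ref`, `obs`, `context`,
#' `strand`, `probability`) for audit or for use as a CLI override.
#'
#' @param table a `prior_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prior_table <- function(table, path) {
  stopifnot(inherits(table, "prior_table"))
  df <- as.data.frame(table)
  names(df)[names(df) == "prob"] <- "probability"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a prior table written by [write_prior_table()]
#'
#' @param path tab-separated file with columns `ref`, `obs`, `context`,
#'   `strand`, `probability`.
#' @return A `prior_table` object. Row sums over the observed base are
#'   validated to 1 within 1e-6.
#' @export
read_prior_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("ref", "obs", "context", "strand", "probability")
  if (!all(need %in% names(df))) stop("prior table file must have columns: ",
                                      paste(need, collapse = ", "))
  arr <- array(NA_real_, dim = c(4, 4, 2, 2),
               dimnames = list(ref = .BASES, obs = .BASES,
                               context = c("CpG", "CH"),
                               strand = c("+", "-")))
  arr[cbind(base_to_int(df$ref), base_to_int(df$obs),
            match(df$context, c("CpG", "CH")),
            match(df$strand, c("+", "-")))] <- df$probability
  if (anyNA(arr)) stop("prior table file does not cover all 64 cases")
  sums <- apply(arr, c(1, 3, 4), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("prior table rows must sum to 1 over the observed base")
  out <- expand.grid(ref = .BASES, obs = .BASES, context = c("CpG", "CH"),
                     strand = c("+", "-"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$prob <- arr[cbind(base_to_int(out$ref), base_to_int(out$obs),
                        match(out$context, c("CpG", "CH")),
                        match(out$strand, c("+", "-")))]
  structure(out, array = arr, params = NULL, mode = "imported",
            class = c("prior_table", "data.frame"))
}
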