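# Internal base encoding shared across the package: A=1, C=2, G=3, T=4, N/other=0.
.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# lookup table from UTF-8 code point to base integer
.BASE_CODE <- local({
  x <- integer(128)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x[utf8ToInt("a")] <- 1L
  x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("g")] <- 3L
  x[utf8ToInt("t")] <- 4L
  x
})

# one DNA string -> integer vector
seq_to_int <- function(s) {
  .BASE_CODE[utf8ToInt(s)]
}

int_to_seq <- function(v) {
  out <- character(length(v))
  out[] <- "N"
  ok <- v >= 1L & v <= 4L
  out[ok] <- .BASES[v[ok]]
  paste(out, collapse = "")
}

base_to_int <- function(b) {
  i <- match(toupper(b), .BASES)
  i[is.na(i)] <- 0L
  i
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(s, function(x)
    intToUtf8(rev(utf8ToInt(x))), character(1), USE.NAMES = FALSE))
}

#' Decode Phred quality strings into miscall probabilities
#'
#' Converts ASCII-encoded base qualities into per-base miscall
#' probabilities \eqn{\epsilon = 10^{-Q/10}}. Probabilities are clamped to
#' \eqn{[10^{-10}, 0.75]} so that downstream likelihoods stay inside (0, 1).
#'
#' @param qual character vector of quality strings.
#' @param offset ASCII offset, 33 (Sanger/modern Illumina) or 64
#'   (legacy Illumina HiSeq).
#' @return A list of numeric vectors, one per input string.
#' @examples
#' decode_phred("II5", offset = 33)
#' @export
decode_phred <- function(qual, offset = 33) {
  stopifnot(offset %in% c(33, 64))
  lapply(qual, function(q) {
    eps <- 10^(-(utf8ToInt(q) - offset) / 10)
    pmin(pmax(eps, 1e-10), 0.75)
  })
}

# miscall probabilities -> quality string (used by the simulator)
encode_phred <- function(eps, offset = 33) {
  q <- round(-10 * log10(pmax(eps, 1e-10)))
  q <- pmin(pmax(q, 2L), 41L)
  intToUtf8(q + offset)
}

# Context of each position of a contig, per strand, as integers
# (1 = CpG, 2 = CH). On the forward strand the context of a cytosine is set
# by the next base downstream (G => CpG); on the reverse strand, read in
# forward coordinates, by the preceding base (C => CpG). Contig edges have
# no downstream base and default to CH.
contig_context <- function(ref_int, strand = c("+", "-")) {
  strand <- match.arg(strand)
  n <- length(ref_int)
  ctx <- rep(2L, n)
  if (n >= 2) {
    if (strand == "+") {
      ctx[which(ref_int[-1] == 3L)] <- 1L          # next base G
    } else {
      ctx[1L + which(ref_int[-n] == 2L)] <- 1L     # previous base C
    }
  }
  ctx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
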