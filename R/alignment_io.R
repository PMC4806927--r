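# Genome and read I/O plus alignment ingestion. Standard formats go
# through Biostrings (FASTA/FASTQ) and Rsamtools (SAM/BAM); SAM text input
# is converted to BAM on the fly with Rsamtools::asBam.

#' Coerce a reference to a named character vector of contigs
#'
#' Accepts a named character vector, a `Biostrings::DNAStringSet`, or a
#' FASTA file path.
#'
#' @param x reference genome in any of the supported representations.
#' @return Named character vector, one element per contig, upper case.
#' @export
as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x)))
    return(read_fasta(x))
  if (methods::is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("contig", seq_along(x))
    return(toupper(x))
  }
  stop("unsupported reference representation")
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write contigs to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return Data frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#' @param reads data frame with `read_id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write alignment records to a SAM file
#'
#' Minimal SAM emitter for the simulator and round-trip tests: a proper
#' header (`@HD`, `@SQ`) followed by one record per row with an `NM` tag.
#'
#' @param records data frame with `read_id`, `flag`, `contig`, `start`
#'   (1-based), `mapq`, `cigar`, `seq`, `qual`, optional `nm`.
#' @param ref_lengths named integer vector of contig lengths.
#' @param path output path ending in `.sam`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  if (nrow(records) > 0) {
    nm <- if ("nm" %in% names(records)) records$nm else rep(0L, nrow(records))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       records$read_id, as.integer(records$flag),
                       records$contig, as.integer(records$start),
                       as.integer(records$mapq), records$cigar,
                       records$seq, records$qual, as.integer(nm)), con)
  }
  invisible(path)
}

# read one SAM/BAM file into a flat data frame of mapped records
.read_alignment_file <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NM")
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !bitwAnd(b$flag, 4L)
  df <- data.frame(read_id = b$qname[keep],
                   flag = b$flag[keep],
                   contig = as.character(b$rname[keep]),
                   start = b$pos[keep],
                   strand = ifelse(bitwAnd(b$flag[keep], 16L) > 0L, "-", "+"),
                   mapq = b$mapq[keep],
                   cigar = b$cigar[keep],
                   seq = as.character(b$seq[keep]),
                   qual = as.character(b$qual[keep]),
                   nm = (b$tag$NM %||% rep(NA_integer_, length(b$flag)))[keep],
                   secondary = bitwAnd(b$flag[keep], 256L) > 0L,
                   stringsAsFactors = FALSE)
  # malformed records: sequence/quality length disagreement
  bad <- nchar(df$seq) != nchar(df$qual) & !(df$qual %in% c("", "*")) &
    !(df$seq %in% c("", "*"))
  if (any(bad)) {
    warning(sum(bad), " records rejected (read/quality length mismatch)")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Load aligner output for assignment
#'
#' Reads uniquely mapped evidence reads and the ambiguous (multi-mapping)
#' stream. Unique reads below `config$mapq_min` are dropped (with a logged
#' count). The ambiguous input is either a SAM/BAM holding several records
#' per read name (secondary alignments as candidates) or, to stay
#' aligner-version agnostic, a read-to-candidates table
#' (`candidates_path`, TSV with `read_id`, `contig`, `start`, `strand`,
#' optional `mismatches`) paired with the reads' FASTQ (`fastq_path`).
#' Candidate locations are kept when their mismatch count is within
#' `config$mismatch_slack` of the read's best candidate; reads left with
#' fewer than 2 candidates are dropped.
#'
#' @param unique_path SAM/BAM of uniquely mapped reads.
#' @param ambiguous_path SAM/BAM of multi-mapping records (ignored when
#'   `candidates_path` is given).
#' @param config a [scoring_config()].
#' @param candidates_path optional candidate table TSV.
#' @param fastq_path FASTQ with the multiread sequences, required with
#'   `candidates_path`.
#' @return List with `unique_reads` (data frame), `multireads`
#'   (list of `reads` and `candidates` data frames), `n_unique_dropped`,
#'   `n_multireads_dropped`.
#' @export
load_alignments <- function(unique_path, ambiguous_path = NULL,
                            config = scoring_config(),
                            candidates_path = NULL, fastq_path = NULL) {
  uni <- .read_alignment_file(unique_path)
  n_drop_u <- sum(uni$mapq < config$mapq_min)
  if (n_drop_u > 0)
    message(n_drop_u, " unique reads dropped below MAPQ ", config$mapq_min)
  uni <- uni[uni$mapq >= config$mapq_min,
             c("read_id", "contig", "start", "strand", "seq", "qual",
               "mapq", "cigar"), drop = FALSE]

  if (!is.null(candidates_path)) {
    if (is.null(fastq_path))
      stop("fastq_path is required with a candidate table")
    cand <- utils::read.table(candidates_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    need <- c("read_id", "contig", "start", "strand")
    if (!all(need %in% names(cand)))
      stop("candidate table must have columns: ", paste(need, collapse = ", "))
    reads <- read_fastq(fastq_path)
    reads <- reads[reads$read_id %in% cand$read_id, , drop = FALSE]
  } else {
    amb <- .read_alignment_file(ambiguous_path)
    # primary record carries the sequence; fill secondary records whose
    # SEQ is "*" and flip orientation where strands differ
    prim <- amb[!amb$secondary & !(amb$seq %in% c("", "*")), , drop = FALSE]
    prim <- prim[!duplicated(prim$read_id), , drop = FALSE]
    reads <- data.frame(read_id = prim$read_id, seq = prim$seq,
                        qual = prim$qual, stringsAsFactors = FALSE)
    pidx <- match(amb$read_id, prim$read_id)
    if (anyNA(pidx)) {
      warning(sum(is.na(pidx)), " ambiguous records without a primary record skipped")
      amb <- amb[!is.na(pidx), , drop = FALSE]
      pidx <- pidx[!is.na(pidx)]
    }
    flip <- amb$strand != prim$strand[pidx]
    noseq <- amb$seq %in% c("", "*")
    noq <- amb$qual %in% c("", "*")
    cseq <- ifelse(noseq, prim$seq[pidx], amb$seq)
    cqual <- ifelse(noq, prim$qual[pidx], amb$qual)
    cseq[flip & noseq] <- revcomp(cseq[flip & noseq])
    cqual[flip & noq] <- vapply(cqual[flip & noq],
      function(q) intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
    cand <- data.frame(read_id = amb$read_id, contig = amb$contig,
                       start = amb$start, strand = amb$strand,
                       cigar = amb$cigar, mismatches = amb$nm,
                       seq = cseq, qual = cqual, stringsAsFactors = FALSE)
  }

  cand <- filter_candidates(cand, config$mismatch_slack)
  tt <- table(cand$read_id)
  keep_ids <- names(tt)[tt >= 2L]
  n_drop_m <- length(setdiff(unique(cand$read_id), keep_ids))
  if (n_drop_m > 0)
    message(n_drop_m, " multireads dropped with fewer than 2 candidate locations")
  cand <- cand[cand$read_id %in% keep_ids, , drop = FALSE]
  reads <- reads[reads$read_id %in% keep_ids, , drop = FALSE]
  list(unique_reads = uni,
       multireads = list(reads = reads, candidates = cand),
       n_unique_dropped = n_drop_u, n_multireads_dropped = n_drop_m)
}

#' Keep candidate locations of similar fidelity
#'
#' Candidates whose mismatch count exceeds the read's minimum by more than
#' `slack` edits are removed; reads without a `mismatches` column pass
#' through unchanged.
#'
#' @param cand candidate data frame with `read_id` and optional
#'   `mismatches`.
#' @param slack allowed edits above the per-read minimum.
#' @return Filtered candidate data frame.
#' @export
filter_candidates <- function(cand, slack = 1) {
  if (!"mismatches" %in% names(cand) || all(is.na(cand$mismatches)))
    return(cand)
  mm <- ifelse(is.na(cand$mismatches), 0L, cand$mismatches)
  best <- stats::ave(mm, cand$read_id, FUN = min)
  cand[mm <= best + slack, , drop = FALSE]
}

#' Build the pileup of unique-read evidence over a candidate location
#'
#' For each of the `K` aligned positions of the candidate, collects the
#' bases and miscall probabilities of the overlapping, strand-matched
#' unique reads. `N` evidence bases are dropped; deleted positions of a
#' gapped unique read contribute nothing. Columns may be empty (`r = 0`).
#'
#' @param candidate list with `contig`, `start` (1-based), `K` (number of
#'   positions) and `strand`.
#' @param unique_reads evidence data frame (`read_id`, `contig`, `start`,
#'   `strand`, `seq`, `qual`, `mapq`, optional `cigar`).
#' @param config a [scoring_config()]; supplies the MAPQ threshold and the
#'   Phred offset.
#' @param strand_match if `TRUE` (default) only evidence from the
#'   candidate's strand is used, as bisulfite conversion patterns are
#'   strand-specific in a directional library.
#' @return List of `K` columns, each `list(bases =, eps =)`.
#' @export
build_pileup <- function(candidate, unique_reads, config = scoring_config(),
                         strand_match = TRUE) {
  K <- candidate$K
  stopifnot(!is.null(K), K >= 1)
  lo <- candidate$start
  hi <- candidate$start + K - 1L
  cols <- replicate(K, list(bases = character(0), eps = numeric(0)),
                    simplify = FALSE)
  if (nrow(unique_reads) == 0L) return(cols)
  sel <- unique_reads$contig == candidate$contig &
    unique_reads$mapq >= config$mapq_min
  if (strand_match) sel <- sel & unique_reads$strand == candidate$strand
  ur <- unique_reads[sel, , drop = FALSE]
  for (i in seq_len(nrow(ur))) {
    L <- nchar(ur$seq[i])
    ap <- cigar_ref_positions(if ("cigar" %in% names(ur)) ur$cigar[i] else NA,
                              ur$start[i], L)
    inwin <- ap$ref_pos >= lo & ap$ref_pos <= hi
    if (!any(inwin)) next
    bases <- strsplit(ur$seq[i], "")[[1]][ap$read_off[inwin]]
    eps <- decode_phred(ur$qual[i], config$phred_offset)[[1]][ap$read_off[inwin]]
    ks <- ap$ref_pos[inwin] - lo + 1L
    ok <- bases %in% .BASES
    for (j in which(ok)) {
      k <- ks[j]
      cols[[k]]$bases <- c(cols[[k]]$bases, bases[j])
      cols[[k]]$eps <- c(cols[[k]]$eps, eps[j])
    }
  }
  cols
}
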