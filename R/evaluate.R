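#' Score an assignment against the simulator's truth table
#'
#' Computes the benchmark metrics: assignable rate (assigned / multireads),
#' accuracy rate (correct / assigned), error rate (1 - accuracy), and
#' error per read, the number of wrongly assigned multireads divided by
#' the total number of reads in the evaluated dataset (so it stays far
#' below the per-assigned error rate). An assignment is correct when the
#' chosen contig and strand match the true origin and the start coordinate
#' is within `slop` bases of it (0 by default).
#'
#' @param assignment a `multiread_assignment` from [assign_multireads()].
#' @param truth data frame with `read_id`, `contig`, `start`, `strand`
#'   (the simulator's truth records).
#' @param n_total_reads total reads in the dataset, the denominator of
#'   error per read; defaults to the number of evaluated multireads.
#' @param slop positional tolerance in bases (real aligners can shift
#'   soft-clipped starts).
#' @return Object of class `bs_eval`: counts plus `assignable_rate`,
#'   `accuracy_rate`, `error_rate`, `error_per_read` (all in `[0, 1]`;
#'   accuracy and error are `NA` when nothing was assigned).
#' @export
evaluate_assignments <- function(assignment, truth, n_total_reads = NULL,
                                 slop = 0) {
  stopifnot(inherits(assignment, "multiread_assignment"))
  a <- as.data.frame(assignment)
  n_multi <- nrow(a)
  assigned <- a[a$status == "assigned", , drop = FALSE]
  ti <- match(assigned$read_id, truth$read_id)
  if (anyNA(ti))
    stop("truth records missing for assigned reads: ",
         paste(utils::head(assigned$read_id[is.na(ti)], 3), collapse = ", "))
  correct <- assigned$contig == truth$contig[ti] &
    assigned$strand == truth$strand[ti] &
    abs(assigned$start - truth$start[ti]) <= slop
  n_assigned <- nrow(assigned)
  n_correct <- sum(correct)
  n_total <- n_total_reads %||% n_multi
  out <- list(n_multireads = n_multi,
              n_assigned = n_assigned,
              n_correct = n_correct,
              n_total_reads = n_total,
              assignable_rate = if (n_multi) n_assigned / n_multi else NA_real_,
              accuracy_rate = if (n_assigned) n_correct / n_assigned else NA_real_,
              error_rate = if (n_assigned) (n_assigned - n_correct) / n_assigned else NA_real_,
              error_per_read = if (n_total) (n_assigned - n_correct) / n_total else 0)
  class(out) <- "bs_eval"
  out
}

#' @export
print.bs_eval <- function(x, ...) {
  cat("Multiread assignment evaluation\n")
  cat(sprintf("  multireads: %d, assigned: %d, correct: %d\n",
              x$n_multireads, x$n_assigned, x$n_correct))
  cat(sprintf("  assignable rate: %.2f%%\n", 100 * x$assignable_rate))
  if (is.na(x$accuracy_rate)) {
    cat("  accuracy rate: not applicable (no reads assigned)\n")
  } else {
    cat(sprintf("  accuracy rate: %.2f%%  error rate: %.2f%%\n",
                100 * x$accuracy_rate, 100 * x$error_rate))
  }
  cat(sprintf("  error per read: %.4g%% (of %d total reads)\n",
              100 * x$error_per_read, x$n_total_reads))
  invisible(x)
}

#' @export
as.data.frame.bs_eval <- function(x, ...) {
  data.frame(n_multireads = x$n_multireads, n_assigned = x$n_assigned,
             n_correct = x$n_correct, n_total_reads = x$n_total_reads,
             assignable_rate = x$assignable_rate,
             accuracy_rate = x$accuracy_rate, error_rate = x$error_rate,
             error_per_read = x$error_per_read)
}

#' Simulate, assign and evaluate under one configuration
#'
#' End-to-end benchmark run: [simulate_benchmark()], then
#' [assign_multireads()] with the requested prior mode, then
#' [evaluate_assignments()]. A prebuilt fixture can be passed to score the
#' same data under several prior modes or cutoffs (paired comparisons).
#'
#' @param config a [simulation_config()].
#' @param prior_mode `"informed"` or `"uniform"`.
#' @param scoring a [scoring_config()]; its `prior_mode` is overridden by
#'   the `prior_mode` argument.
#' @param fixture optional result of [simulate_benchmark()] to reuse.
#' @return List with `evaluation` (a `bs_eval`), `assignment`, `fixture`.
#' @export
run_assignment_study <- function(config = simulation_config(),
                                 prior_mode = c("informed", "uniform"),
                                 scoring = scoring_config(),
                                 fixture = NULL) {
  prior_mode <- match.arg(prior_mode)
  scoring$prior_mode <- prior_mode
  scoring$phred_offset <- config$phred_offset
  fixture <- fixture %||% simulate_benchmark(config)
  table <- build_prior_table(prior_params(), mode = prior_mode)
  assignment <- assign_multireads(fixture$multireads, fixture$unique_reads,
                                  fixture$reference, table, scoring)
  ev <- evaluate_assignments(assignment, fixture$truth,
                             n_total_reads = fixture$n_total_reads)
  list(evaluation = ev, assignment = assignment, fixture = fixture)
}

#' Sweep simulation parameters and collect evaluation summaries
#'
#' Runs [run_assignment_study()] over the cross product of the supplied
#' parameter values and seeds, one row per cell per seed per prior mode.
#' The simulation fixture is shared between prior modes within a cell, so
#' with/without-prior comparisons are paired.
#'
#' @param base_config the [simulation_config()] every cell starts from.
#' @param vary named list of `simulation_config` fields to vary, e.g.
#'   `list(read_length = c(51, 76, 101))`.
#' @param seeds integer vector of seeds.
#' @param prior_modes character vector, subset of
#'   `c("informed", "uniform")`.
#' @param scoring a [scoring_config()].
#' @return Long-format data frame: varied fields, `seed`, `prior_mode`,
#'   and the evaluation columns.
#' @export
sweep_assignments <- function(base_config = simulation_config(),
                              vary = list(), seeds = 1L,
                              prior_modes = "informed",
                              scoring = scoring_config()) {
  grid <- if (length(vary)) do.call(expand.grid, c(vary, KEEP.OUT.ATTRS = FALSE,
                                                   stringsAsFactors = FALSE))
          else data.frame(.dummy = 1)
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    for (seed in seeds) {
      cfg <- base_config
      for (nm in setdiff(names(grid), ".dummy")) cfg[[nm]] <- grid[gi, nm]
      cfg$seed <- seed
      fixture <- simulate_benchmark(cfg)
      for (pm in prior_modes) {
        st <- run_assignment_study(cfg, prior_mode = pm, scoring = scoring,
                                   fixture = fixture)
        row <- cbind(grid[gi, setdiff(names(grid), ".dummy"), drop = FALSE],
                     data.frame(seed = seed, prior_mode = pm),
                     as.data.frame(st$evaluation))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation summary as TSV
#'
#' @param evaluation a `bs_eval` or the data frame from
#'   [sweep_assignments()].
#' @param path output path. A header comment documents the error-per-read
#'   denominator.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path) {
  df <- if (inherits(evaluation, "bs_eval")) as.data.frame(evaluation) else evaluation
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# error_per_read = wrongly assigned multireads / total reads in dataset", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
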