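#' Learnability of every single feature/electrode combination
#'
#' Runs [run_learnability()] once per candidate of the 35-element input
#' space (5 signal features x 7 electrodes), giving the grid from which
#' minimization strategies order their candidates.
#'
#' @param table Feature table.
#' @param scheme Partitioning scheme (the study uses within-animal).
#' @param spec A [classifier_spec()].
#' @param n_repeats Training repeats per candidate.
#' @param seed Root seed.
#' @param candidates Optional subset of [candidate_grid()] rows.
#' @return A `learnability_grid`: list with `results` (one per candidate)
#'   and `summary` (data frame: electrode, sf, column, fl_mean, fl_sem).
#' @export
single_feature_grid <- function(table, scheme = "WIA",
                                spec = classifier_spec(), n_repeats = 10,
                                seed = 1L, candidates = candidate_grid()) {
  results <- lapply(seq_len(nrow(candidates)), function(i) {
    run_learnability(table, candidates$column[i], scheme, spec, n_repeats,
                     derive_seed(seed, i))
  })
  summary <- cbind(candidates,
                   fl_mean = vapply(results, `[[`, 0, "fl_mean"),
                   fl_sem = vapply(results, `[[`, 0, "fl_sem"))
  structure(list(results = results, summary = summary),
            class = "learnability_grid")
}

#' @export
print.learnability_grid <- function(x, ...) {
  s <- x$summary[order(-x$summary$fl_mean, x$summary$fl_sem), ]
  cat("Single feature/electrode learnability grid (top 10):\n")
  print(utils::head(s, 10), row.names = FALSE)
  invisible(x)
}

#' Order candidates for input minimization
#'
#' `input_rank` orders the 35 candidates by their individual learnability
#' (global rank). `electrode_rank` first ranks electrodes by the mean
#' learnability of their five features, then emits candidates
#' electrode-block by electrode-block (within a block, by the feature's
#' own rank) -- prioritizing electrodes over the global candidate order.
#' Electrode ties break by the electrode's best single-candidate
#' learnability, then by index.
#'
#' @param grid A `learnability_grid`.
#' @param strategy `"input_rank"` or `"electrode_rank"`.
#' @return The grid's summary rows in candidate order.
#' @export
order_candidates <- function(grid, strategy = c("input_rank", "electrode_rank")) {
  strategy <- match.arg(strategy)
  s <- grid$summary
  if (strategy == "input_rank")
    return(s[order(-s$fl_mean, s$fl_sem, s$column), ])
  e_mean <- tapply(s$fl_mean, s$electrode, mean)
  e_best <- tapply(s$fl_mean, s$electrode, max)
  e_order <- order(-e_mean, -e_best, as.integer(names(e_mean)))
  blocks <- lapply(as.integer(names(e_mean))[e_order], function(e) {
    b <- s[s$electrode == e, ]
    b[order(-b$fl_mean, b$fl_sem, b$column), ]
  })
  do.call(rbind, blocks)
}

#' Adapted sequential forward search for minimal inputs
#'
#' Greedy forward selection toward near-benchmark learnability, with the
#' defining adaptation that candidates rejected in one round stay in the
#' pool and are re-tested in every later round (after each new best subset
#' is established). Under the `input_rank` strategy every pooled candidate
#' is evaluated each round; under `electrode_rank` evaluation is restricted
#' to the remaining features of the active electrode (the highest-ranked
#' electrode with features still in the pool), mirroring the
#' electrode-minimizing strategy. The search stops when the current set's
#' learnability is not significantly different from the benchmark
#' ([near_benchmark()]) or the pool is exhausted. A benchmark whose mean
#' learnability is itself near chance is flagged degenerate and cannot
#' terminate the search (being "near" a chance-level benchmark is
#' meaningless).
#'
#' @param table Feature table.
#' @param strategy `"input_rank"` or `"electrode_rank"`.
#' @param benchmark A `learnability_result` with per-animal values (all 35
#'   inputs, within-animal scheme).
#' @param scheme Partitioning scheme for the evaluations.
#' @param spec A [classifier_spec()].
#' @param grid Optional precomputed [single_feature_grid()].
#' @param n_repeats Repeats per evaluation.
#' @param alpha Level of the near-benchmark test.
#' @param seed Root seed.
#' @param min_inputs Do not terminate on near-benchmark before the accepted
#'   set reaches this size (useful when comparing against exhaustive
#'   optima over fixed subset sizes).
#' @param degenerate_benchmark_fl Benchmark means below this are flagged
#'   degenerate (chance is 25%).
#' @return A `selection_trace`: per-round evaluations, the accepted
#'   candidate sequence, terminal result, terminal p-value and status.
#' @export
adapted_sfs <- function(table, strategy = c("input_rank", "electrode_rank"),
                        benchmark, scheme = "WIA", spec = classifier_spec(),
                        grid = NULL, n_repeats = 10, alpha = 0.05, seed = 1L,
                        min_inputs = 1L, degenerate_benchmark_fl = 40) {
  strategy <- match.arg(strategy)
  if (is.null(benchmark$per_animal_fl))
    stop("benchmark must carry per-animal learnability values")
  if (is.null(grid))
    grid <- single_feature_grid(table, scheme, spec, n_repeats,
                                derive_seed(seed, 1000L))
  ordered <- order_candidates(grid, strategy)
  degenerate <- benchmark$fl_mean < degenerate_benchmark_fl

  pool <- ordered$column
  electrode_of <- stats::setNames(ordered$electrode, ordered$column)
  current <- character(0)
  current_result <- NULL
  rounds <- list()
  status <- "pool_exhausted"
  terminal_p <- NA_real_

  round_i <- 0L
  while (length(pool)) {
    round_i <- round_i + 1L
    eligible <- if (strategy == "input_rank") pool else {
      active <- electrode_of[pool][1]  # pool keeps the strategy order
      pool[electrode_of[pool] == active]
    }
    evals <- lapply(seq_along(eligible), function(j) {
      run_learnability(table, c(current, eligible[j]), scheme, spec,
                       n_repeats, derive_seed(seed, round_i, j))
    })
    ranked <- rank_results(evals)
    best_idx <- attr(ranked, "ranking")[1]
    best <- evals[[best_idx]]
    accepted <- eligible[best_idx]

    rounds[[round_i]] <- data.frame(
      round = round_i,
      candidate = eligible,
      fl_mean = vapply(evals, `[[`, 0, "fl_mean"),
      fl_sem = vapply(evals, `[[`, 0, "fl_sem"),
      accepted = eligible == accepted,
      row.names = NULL
    )
    current <- c(current, accepted)
    current_result <- best
    pool <- setdiff(pool, accepted)

    nb <- near_benchmark(current_result, benchmark, alpha)
    terminal_p <- nb$p
    if (nb$is_near && !degenerate && length(current) >= min_inputs) {
      status <- "near_benchmark"
      break
    }
  }

  structure(list(
    strategy = strategy,
    rounds = do.call(rbind, rounds),
    terminal_set = current,
    terminal_result = current_result,
    terminal_p = terminal_p,
    status = status,
    benchmark_degenerate = degenerate
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Adapted SFS (%s): %s after %d round(s)\n", x$strategy,
              x$status, if (is.null(x$rounds)) 0L else max(x$rounds$round)))
  cat("terminal set:", paste(x$terminal_set, collapse = ", "), "\n")
  if (!is.null(x$terminal_result))
    cat(sprintf("terminal learnability %.1f +/- %.1f %% (p vs benchmark = %.3g)\n",
                x$terminal_result$fl_mean, x$terminal_result$fl_sem,
                x$terminal_p))
  if (x$benchmark_degenerate)
    cat("note: benchmark is near chance; near-benchmark termination disabled\n")
  invisible(x)
}

#' Count (and optionally evaluate) all subsets of given sizes
#'
#' The count is the exact binomial sum `sum_k choose(n, k)`; with 10
#' candidates and sizes 3-6 it equals 792, and with all 35 candidates it
#' exceeds two million, which is why the study resorts to the adapted
#' sequential search. When `table` is supplied every subset is evaluated
#' at `n_repeats` repeats and the top `rescore_top` subsets are re-scored
#' at `rescore_repeats` before the best is returned.
#'
#' @param candidates Character vector of candidate feature columns.
#' @param sizes Integer subset sizes.
#' @param table Optional feature table; triggers evaluation.
#' @param scheme,spec,n_repeats,seed Evaluation parameters.
#' @param rescore_top,rescore_repeats Final re-scoring of the leaders.
#' @return A list: `count`, and when evaluated `best` (a
#'   `learnability_result`), `best_subset`, and `summary` (all subsets).
#' @export
exhaustive_subsets <- function(candidates, sizes, table = NULL,
                               scheme = "WIA", spec = classifier_spec(),
                               n_repeats = 3, seed = 1L,
                               rescore_top = 10, rescore_repeats = 10) {
  n <- length(candidates)
  sizes <- sizes[sizes >= 1 & sizes <= n]
  count <- sum(choose(n, sizes))
  if (is.null(table)) return(list(count = count))

  subsets <- unlist(lapply(sizes, function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  results <- lapply(seq_along(subsets), function(i) {
    run_learnability(table, subsets[[i]], scheme, spec, n_repeats,
                     derive_seed(seed, i))
  })
  ranked_idx <- attr(rank_results(results), "ranking")
  top <- utils::head(ranked_idx, rescore_top)
  rescored <- lapply(seq_along(top), function(j) {
    run_learnability(table, subsets[[top[j]]], scheme, spec,
                     rescore_repeats, derive_seed(seed, 5000L, j))
  })
  best <- rank_results(rescored)[[1]]
  list(count = count,
       best = best,
       best_subset = best$input_columns,
       summary = data.frame(
         subset = vapply(subsets, paste, "", collapse = "+"),
         size = vapply(subsets, length, 0L),
         fl_mean = vapply(results, `[[`, 0, "fl_mean"),
         fl_sem = vapply(results, `[[`, 0, "fl_sem")
       ))
}
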