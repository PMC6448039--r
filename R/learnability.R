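#' Min-max normalize feature columns to \[-1, 1\]
#'
#' Per-feature affine map sending the observed minimum to -1 and maximum to
#' +1, as the classifier expects. Constant columns map to 0 (with a
#' warning). The transform is recorded so it can be inverted or re-applied
#' to new data.
#'
#' @param table A feature table (or any data frame); only numeric feature
#'   columns (those matching `e<i>_<sf>`) are rescaled unless `columns` is
#'   given.
#' @param columns Columns to rescale (default: all feature columns present).
#' @return The rescaled table with a `transform` attribute (data frame of
#'   per-column min/max).
#' @export
normalize_features <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(input_columns(), names(table))
  lo <- vapply(table[columns], min, 0, na.rm = TRUE)
  hi <- vapply(table[columns], max, 0, na.rm = TRUE)
  const <- hi <= lo
  if (any(const))
    warning("constant feature(s) mapped to 0: ",
            paste(columns[const], collapse = ", "))
  for (j in seq_along(columns)) {
    x <- table[[columns[j]]]
    table[[columns[j]]] <- if (const[j]) 0 * x else
      -1 + 2 * (x - lo[j]) / (hi[j] - lo[j])
  }
  attr(table, "transform") <- data.frame(column = columns, min = lo, max = hi,
                                         constant = const, row.names = NULL)
  table
}

#' Invert a recorded normalization
#'
#' @param table A table produced by [normalize_features()] (or sharing its
#'   columns).
#' @param transform The `transform` attribute recorded at normalization.
#' @return The table on the original scale.
#' @export
denormalize_features <- function(table, transform = attr(table, "transform")) {
  stopifnot(!is.null(transform))
  for (j in seq_len(nrow(transform))) {
    cl <- transform$column[j]
    if (transform$constant[j]) {
      table[[cl]] <- rep(transform$min[j], nrow(table))
    } else {
      table[[cl]] <- transform$min[j] +
        (table[[cl]] + 1) / 2 * (transform$max[j] - transform$min[j])
    }
  }
  attr(table, "transform") <- NULL
  table
}

#' Split trials into training / validation / test sets
#'
#' Random, nerve-stratified assignment. For the within-animal (`WIA`) and
#' pooled-population (`PP`) schemes the fractions are 70/15/15; for the
#' leave-one-animal-out (`LOO`) scheme the pool (all but the held-out
#' animal) is split 70/30 into training/validation, and the test set is
#' every trial of the held-out animal. Within each nerve, validation and
#' test sizes are floors of the fractions; the remainder goes to training.
#' If any split ends up missing a class the draw is repeated once, after
#' which an error is raised (guards degenerate, tiny tables).
#'
#' @param table Feature table (for `WIA`, already restricted to one animal).
#' @param scheme `"WIA"`, `"PP"` or `"LOO"`.
#' @param seed Integer seed.
#' @param holdout_animal For `LOO`: the animal whose trials form the test
#'   set.
#' @return A list of integer row-index vectors `train`, `val`, `test`.
#' @export
partition <- function(table, scheme = c("WIA", "PP", "LOO"), seed = 1L,
                      holdout_animal = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "LOO") {
    if (is.null(holdout_animal)) stop("LOO requires holdout_animal")
    if (length(unique(table$animal)) < 2) stop("LOO requires >= 2 animals")
    test <- which(table$animal == holdout_animal)
    pool <- which(table$animal != holdout_animal)
    for (attempt in 1:2) {
      sp <- with_seed(derive_seed(seed, attempt),
                      stratified_split(table$nerve[pool], c(0.70, 0.30)))
      out <- list(train = pool[sp[[1]]], val = pool[sp[[2]]], test = test)
      if (all_classes_present(table, out)) return(out)
    }
    stop("could not produce a split with all classes present")
  }
  if (scheme == "WIA" && length(unique(table$animal)) != 1)
    stop("WIA partitions operate on a single animal's trials")
  for (attempt in 1:2) {
    sp <- with_seed(derive_seed(seed, attempt),
                    stratified_split(table$nerve, c(0.70, 0.15, 0.15)))
    out <- list(train = sp[[1]], val = sp[[2]], test = sp[[3]])
    if (all_classes_present(table, out)) return(out)
  }
  stop("could not produce a split with all classes present")
}

## Per-class random assignment: later fractions get floor(frac * n_class),
## the remainder goes to the first (training) pool.
stratified_split <- function(classes, fractions) {
  idx_by_class <- split(seq_along(classes), classes)
  out <- rep(list(integer(0)), length(fractions))
  for (idx in idx_by_class) {
    idx <- sample(idx)
    sizes <- floor(fractions[-1] * length(idx))
    sizes <- c(length(idx) - sum(sizes), sizes)
    stop_at <- cumsum(sizes)
    start_at <- c(1, utils::head(stop_at, -1) + 1)
    for (j in seq_along(fractions)) {
      if (sizes[j] > 0)
        out[[j]] <- c(out[[j]], idx[start_at[j]:stop_at[j]])
    }
  }
  lapply(out, sort)
}

all_classes_present <- function(table, split) {
  all(vapply(split, function(i)
    length(i) == 0 || length(unique(table$nerve[i])) == 4, TRUE))
}

#' Train once and evaluate on the test set
#'
#' Trains the specified network on the training rows with early stopping
#' on the validation rows, then computes the row-normalized 4x4 confusion
#' matrix (in %) on the test rows only. If training never trips the early
#' stopping rule the final-epoch weights are still evaluated and the
#' result flagged as non-converged.
#'
#' @param X Numeric input matrix (rows = trials, normalized).
#' @param y Integer class labels (1-4, ordered as [nerve_labels()]).
#' @param split A [partition()] result.
#' @param spec A [classifier_spec()].
#' @param seed Seed for the weight initialization.
#' @return A 4x4 confusion matrix (%) with attribute `converged`.
#' @export
train_eval_once <- function(X, y, split, spec = classifier_spec(), seed = 1L) {
  if (length(unique(y[split$train])) < 4)
    stop("all four classes must be present in the training set")
  fit <- mlp_train(X[split$train, , drop = FALSE], y[split$train],
                   X[split$val, , drop = FALSE], y[split$val], spec, seed)
  pred <- mlp_predict(fit$weights, X[split$test, , drop = FALSE])
  cm <- confusion_matrix(y[split$test], pred)
  attr(cm, "converged") <- fit$converged
  cm
}

#' Feature-learnability of an input configuration
#'
#' Trains the classifier `n_repeats` times per pool with fresh random
#' splits and initial weights, averages the test-set confusion matrices,
#' and scores feature-learnability as the mean of the averaged matrix's
#' diagonal, with an SEM taken across the four class accuracies. Under
#' `WIA` each animal is learned separately (its 10-repeat average gives a
#' per-animal confusion and per-animal learnability) and the cohort matrix
#' is the across-animal average; under `PP` all animals are pooled; under
#' `LOO` each animal serves once as the test set for a network trained on
#' the remaining animals, with per-fold repeat-averaging.
#'
#' @param table A feature table.
#' @param inputs Character vector of feature columns, or a list
#'   `list(electrodes =, sfs =)` expanded via [input_columns()].
#' @param scheme Partitioning scheme: `"WIA"`, `"PP"` or `"LOO"`.
#' @param spec A [classifier_spec()].
#' @param n_repeats Training repeats per pool.
#' @param seed Root seed; all repeats and folds derive from it.
#' @return A `learnability_result`: input descriptor, averaged confusion
#'   matrix, `fl_mean`, `fl_sem`, `per_animal_fl` (WIA/LOO), `n_repeats`.
#' @export
run_learnability <- function(table, inputs = input_columns(),
                             scheme = c("WIA", "PP", "LOO"),
                             spec = classifier_spec(), n_repeats = 10,
                             seed = 1L) {
  scheme <- match.arg(scheme)
  if (is.list(inputs))
    inputs <- input_columns(inputs$electrodes, inputs$sfs)
  missing_cols <- setdiff(inputs, names(table))
  if (length(missing_cols))
    stop("inputs not in table: ", paste(missing_cols, collapse = ", "))

  keep <- stats::complete.cases(table[inputs])
  table <- table[keep, , drop = FALSE]
  y <- as.integer(factor(as.character(table$nerve), levels = NERVES))
  animals <- sort(unique(table$animal))

  avg <- function(ms) {
    m <- Reduce(`+`, ms) / length(ms)
    attr(m, "converged") <- NULL
    m
  }

  if (scheme == "WIA") {
    per_animal <- lapply(seq_along(animals), function(ai) {
      rows <- which(table$animal == animals[ai])
      sub <- table[rows, , drop = FALSE]
      X <- as.matrix(normalize_features(sub, inputs)[inputs])
      cms <- lapply(seq_len(n_repeats), function(r) {
        sp <- partition(sub, "WIA", derive_seed(seed, ai, r))
        train_eval_once(X, y[rows], sp, spec, derive_seed(seed, ai, r, 99L))
      })
      avg(cms)
    })
    confusion <- avg(per_animal)
    per_animal_fl <- vapply(per_animal, function(m) mean(diag(m)), 0)
    names(per_animal_fl) <- animals
  } else if (scheme == "PP") {
    X <- as.matrix(normalize_features(table, inputs)[inputs])
    cms <- lapply(seq_len(n_repeats), function(r) {
      sp <- partition(table, "PP", derive_seed(seed, r))
      train_eval_once(X, y, sp, spec, derive_seed(seed, r, 99L))
    })
    confusion <- avg(cms)
    per_animal_fl <- NULL
  } else {
    if (length(animals) < 2) stop("LOO requires >= 2 animals")
    X <- as.matrix(normalize_features(table, inputs)[inputs])
    folds <- lapply(seq_along(animals), function(ai) {
      cms <- lapply(seq_len(n_repeats), function(r) {
        sp <- partition(table, "LOO", derive_seed(seed, ai, r),
                        holdout_animal = animals[ai])
        train_eval_once(X, y, sp, spec, derive_seed(seed, ai, r, 99L))
      })
      avg(cms)
    })
    confusion <- avg(folds)
    per_animal_fl <- vapply(folds, function(m) mean(diag(m)), 0)
    names(per_animal_fl) <- animals
  }

  score <- learnability_score(confusion)
  structure(list(
    inputs = paste(sort(inputs), collapse = "+"),
    input_columns = inputs,
    scheme = scheme,
    confusion = confusion,
    fl_mean = score$fl_mean,
    fl_sem = score$fl_sem,
    per_animal_fl = per_animal_fl,
    n_repeats = n_repeats,
    n_trials = nrow(table)
  ), class = "learnability_result")
}

#' Feature-learnability score of a confusion matrix
#'
#' The mean of the diagonal (correct classifications per class) with an
#' SEM across the four class accuracies -- a spread over outcomes, not
#' over animals.
#'
#' @param confusion Row-normalized 4x4 confusion matrix (%).
#' @return A list with `fl_mean` and `fl_sem`.
#' @export
learnability_score <- function(confusion) {
  d <- diag(confusion)
  list(fl_mean = mean(d), fl_sem = stats::sd(d) / sqrt(length(d)))
}

#' @export
print.learnability_result <- function(x, digits = 1, ...) {
  cat(sprintf("Feature-learnability (%s): %.1f +/- %.1f %% (n = %d trials, %d repeats)\n",
              x$scheme, x$fl_mean, x$fl_sem, x$n_trials, x$n_repeats))
  cat("inputs:", x$inputs, "\n")
  print(round(x$confusion, digits))
  invisible(x)
}

#' Rank learnability results
#'
#' Descending by mean learnability; exact ties broken by the smaller SEM,
#' residual ties by the lexicographic order of the input descriptor
#' (stable).
#'
#' @param results A list of `learnability_result` objects.
#' @return The list reordered, with attribute `ranking` (integer order).
#' @export
rank_results <- function(results) {
  fl <- vapply(results, `[[`, 0, "fl_mean")
  sem <- vapply(results, `[[`, 0, "fl_sem")
  desc <- vapply(results, `[[`, "", "inputs")
  ord <- order(-fl, sem, desc)
  structure(results[ord], ranking = ord)
}

## Logit transform for percentage accuracies near the ceiling, with the
## usual 0.025 boundary adjustment.
logit_pct <- function(v, adjust = 0.025) {
  q <- adjust + (1 - 2 * adjust) * (v / 100)
  log(q / (1 - q))
}

#' Is a configuration's learnability near the benchmark?
#'
#' Paired t-test of per-animal learnability between a candidate
#' configuration and the benchmark (all 35 inputs, within-animal scheme).
#' When either result has values above 95% (ceiling effects) both are
#' logit-transformed first. "Near-benchmark" means the test does not
#' reject at level `alpha`.
#'
#' @param candidate,benchmark `learnability_result` objects carrying
#'   per-animal values over the same animals.
#' @param alpha Test level.
#' @return A list: `is_near` (logical), `p`, `statistic`, `df`.
#' @export
near_benchmark <- function(candidate, benchmark, alpha = 0.05) {
  a <- candidate$per_animal_fl
  b <- benchmark$per_animal_fl
  if (is.null(a) || is.null(b))
    stop("both results must carry per-animal learnability values")
  if (!identical(sort(names(a)), sort(names(b))))
    stop("mismatched animal sets")
  if (length(a) < 2) stop("paired test needs at least 2 animals")
  b <- b[names(a)]
  if (any(c(a, b) > 95)) {
    a <- logit_pct(a)
    b <- logit_pct(b)
  }
  d <- a - b
  if (stats::sd(d) < 1e-12) {
    ## degenerate pairing: identical results are trivially near, a constant
    ## non-zero shift is unambiguously different
    near <- all(abs(d) < 1e-12)
    return(list(is_near = near, p = as.numeric(near), statistic = NA_real_,
                df = length(d) - 1))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(is_near = tt$p.value >= alpha, p = tt$p.value,
       statistic = unname(tt$statistic), df = unname(tt$parameter))
}
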