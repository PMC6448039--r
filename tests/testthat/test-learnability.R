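make_result <- function(fl_mean, fl_sem, per_animal = NULL, inputs = "x") {
  structure(list(inputs = inputs, input_columns = inputs, scheme = "WIA",
                 confusion = NULL, fl_mean = fl_mean, fl_sem = fl_sem,
                 per_animal_fl = per_animal, n_repeats = 10, n_trials = 0),
            class = "learnability_result")
}

test_that("feature normalization maps to [-1, 1] and inverts exactly", {
  tab <- data.frame(e1_n1_latency = c(2, 4, 6), e1_p1n1_slope = c(5, 5, 5))
  expect_warning(out <- normalize_features(tab, names(tab)), "constant")
  expect_equal(out$e1_n1_latency, c(-1, 0, 1))
  expect_equal(out$e1_p1n1_slope, c(0, 0, 0))

  set.seed(1)
  tab2 <- as.data.frame(matrix(stats::rnorm(50 * 35, 10, 4), 50, 35,
                               dimnames = list(NULL, input_columns())))
  norm <- normalize_features(tab2)
  expect_true(all(vapply(norm[input_columns()], min, 0) == -1))
  expect_true(all(vapply(norm[input_columns()], max, 0) == 1))
  back <- denormalize_features(norm)
  expect_equal(as.matrix(back), as.matrix(tab2), tolerance = 1e-12)
})

test_that("partitions follow the 70/15/15 design with floor rounding", {
  tab <- data.frame(animal = "A1",
                    nerve = factor(rep(nerve_labels(), each = 220),
                                   levels = nerve_labels()),
                    trial = 1:880)
  sp <- partition(tab, "WIA", seed = 4)
  expect_length(sp$train, 616)
  expect_length(sp$val, 132)
  expect_length(sp$test, 132)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:880)

  sp2 <- partition(tab, "WIA", seed = 4)
  expect_identical(sp, sp2)

  ## each split is nerve-balanced
  for (s in sp) expect_true(all(table(tab$nerve[s]) == length(s) / 4))
})

test_that("leave-one-out folds hold out exactly one animal completely", {
  tab <- small_cohort_table()
  animals <- unique(tab$animal)
  for (a in animals) {
    sp <- partition(tab, "LOO", seed = 2, holdout_animal = a)
    expect_setequal(sp$test, which(tab$animal == a))
    expect_length(intersect(c(sp$train, sp$val), sp$test), 0)
    expect_setequal(c(sp$train, sp$val, sp$test), seq_len(nrow(tab)))
  }
  expect_error(partition(tab, "LOO", seed = 1), "holdout")
})

test_that("the network learns separable clusters and stays at chance on noise", {
  set.seed(7)
  n <- 60
  centers <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(stats::rnorm(n * 2, 0, 0.2), n, 2), 2, centers[k, ], "+")))
  y <- rep(1:4, each = n)
  sp <- list(train = seq_along(y), val = seq_along(y), test = seq_along(y))
  cm <- train_eval_once(X, y, sp, classifier_spec(), seed = 1)
  expect_equal(unname(diag(cm)), rep(100, 4))
  expect_equal(unname(rowSums(cm)), rep(100, 4))

  ## two classes drawn from one distribution confuse mostly each other
  X2 <- X
  X2[y == 2, ] <- sweep(matrix(stats::rnorm(n * 2, 0, 0.2), n, 2), 2,
                        centers[1, ], "+")
  idx <- sample(length(y))
  tr_i <- idx[1:160]; te_i <- idx[161:240]
  cm2 <- train_eval_once(X2, y, list(train = tr_i, val = te_i, test = te_i),
                         classifier_spec(), seed = 2)
  err1 <- cm2[1, -1]; err2 <- cm2[2, -2]
  expect_gt(cm2[1, 2] + cm2[2, 1], 0.5 * (sum(err1) + sum(err2)))
})

test_that("learnability scoring uses the diagonal mean and across-class SEM", {
  cm <- diag(c(100, 100, 90, 90))
  cm[3, 1] <- 10; cm[4, 2] <- 10
  dimnames(cm) <- list(true = nerve_labels(), predicted = nerve_labels())
  sc <- learnability_score(cm)
  expect_equal(sc$fl_mean, 95)
  expect_equal(sc$fl_sem, 2.8868, tolerance = 1e-4)

  ident <- diag(rep(100, 4))
  expect_equal(learnability_score(ident), list(fl_mean = 100, fl_sem = 0))
})

test_that("results rank by mean, then smaller SEM, then input order", {
  a <- make_result(90, 2, inputs = "a")
  b <- make_result(90, 1, inputs = "b")
  expect_equal(rank_results(list(a, b))[[1]]$inputs, "b")

  c1 <- make_result(95, 5, inputs = "c")
  d <- make_result(90, 0.1, inputs = "d")
  expect_equal(rank_results(list(d, c1))[[1]]$inputs, "c")

  e <- make_result(90, 1, inputs = "e")
  f <- make_result(90, 1, inputs = "f")
  expect_equal(vapply(rank_results(list(f, e)), `[[`, "", "inputs"),
               c("e", "f"))
})

test_that("near-benchmark decisions follow the paired test on animals", {
  pa <- c(A1 = 96, A2 = 97, A3 = 95, A4 = 96.5)
  bench <- make_result(96.1, 0.5, per_animal = pa)
  same <- make_result(96.1, 0.5, per_animal = pa)
  nb <- near_benchmark(same, bench)
  expect_true(nb$is_near)
  expect_equal(nb$p, 1)

  worse <- make_result(86, 0.5, per_animal = pa - 10 + stats::rnorm(4, 0, 0.5))
  nb2 <- near_benchmark(worse, bench)
  expect_false(nb2$is_near)
  expect_lt(nb2$p, 0.05)

  solo <- make_result(96, 0.5, per_animal = c(A1 = 96))
  expect_error(near_benchmark(solo, make_result(96, 0.5,
                                                per_animal = c(A1 = 96))),
               "at least 2")
  expect_error(near_benchmark(make_result(90, 1), bench), "per-animal")
  expect_error(
    near_benchmark(make_result(90, 1, per_animal = c(B1 = 90, B2 = 91)),
                   bench),
    "mismatched")
})

test_that("an independent classifier implementation agrees on separable data", {
  skip_if_not_installed("nnet")
  tab <- small_cohort_table()
  one <- tab[tab$animal == "A1", ]
  X <- normalize_features(one, input_columns())
  sp <- partition(one, "WIA", seed = 8)
  y <- factor(as.character(one$nerve), levels = nerve_labels())

  cm <- train_eval_once(as.matrix(X[input_columns()]), as.integer(y), sp,
                        classifier_spec(), seed = 1)
  fit <- nnet::nnet(x = as.matrix(X[input_columns()])[sp$train, ],
                    y = stats::model.matrix(~ y - 1)[sp$train, ],
                    size = 20, softmax = TRUE, maxit = 200, trace = FALSE)
  pred <- max.col(stats::predict(fit,
                                 as.matrix(X[input_columns()])[sp$test, ]))
  acc_nnet <- mean(pred == as.integer(y)[sp$test]) * 100
  expect_gt(mean(diag(cm)), 95)
  expect_gt(acc_nnet, 95)
})

test_that("learnability is high within animals and ordered WIA >= PP >= LOO", {
  tab <- small_cohort_table()
  spec <- fast_spec()
  wia <- run_learnability(tab, scheme = "WIA", spec = spec, n_repeats = 4,
                          seed = 3)
  pp <- run_learnability(tab, scheme = "PP", spec = spec, n_repeats = 4,
                         seed = 3)
  loo <- run_learnability(tab, scheme = "LOO", spec = spec, n_repeats = 4,
                          seed = 3)
  expect_gt(wia$fl_mean, 90)
  expect_gte(wia$fl_mean + 2, pp$fl_mean)
  expect_gte(pp$fl_mean + 2, loo$fl_mean)
  expect_equal(unname(rowSums(wia$confusion)), rep(100, 4), tolerance = 1e-6)
  expect_equal(unname(rowSums(loo$confusion)), rep(100, 4), tolerance = 1e-6)
  expect_length(wia$per_animal_fl, 3)
  expect_null(pp$per_animal_fl)

  ## adding an informative input does not meaningfully hurt learnability
  single <- run_learnability(tab, "e4_hf_integral", scheme = "WIA",
                             spec = spec, n_repeats = 4, seed = 5)
  expect_gt(single$fl_mean, 25)
  pair <- run_learnability(tab, c("e4_hf_integral", "e4_p1n1_amplitude"),
                           scheme = "WIA", spec = spec, n_repeats = 4,
                           seed = 5)
  expect_gte(pair$fl_mean + 2, single$fl_mean)
})
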