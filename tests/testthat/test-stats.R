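test_that("feature-pair correlations pool electrodes and sort by |r|", {
  set.seed(5)
  tab <- synthetic_sf_table(n_per_nerve = 50)
  ## duplicate one feature into another: their correlation must be 1
  for (e in 1:7) tab[[paste0("e", e, "_hf_integral")]] <-
    tab[[paste0("e", e, "_hf_peak_count")]]
  fc <- feature_pair_correlations(tab)
  expect_equal(nrow(fc), 10)
  top <- fc[1, ]
  expect_setequal(c(top$feature_a, top$feature_b),
                  c("hf_peak_count", "hf_integral"))
  expect_equal(top$r, 1)

  ## independent noise columns stay uncorrelated at large n
  set.seed(6)
  big <- synthetic_sf_table(n_per_nerve = 360)  # ~10^4 pooled values per SF
  fc2 <- feature_pair_correlations(big)
  expect_lt(max(abs(fc2$r)), 0.05)

  expect_error(feature_pair_correlations(big[1:2, ]), "at least 3")
})

test_that("locus categories map nerve pairs onto the five classes", {
  expect_equal(dcnfl:::locus_category("LSN", "RSN"), "LSNvRSN")
  expect_equal(dcnfl:::locus_category("RSN", "LSN"), "LSNvRSN")
  expect_equal(dcnfl:::locus_category("LPN", "RPN"), "LPNvRPN")
  expect_equal(dcnfl:::locus_category("RPN", "RSN"), "RPNvRSN")
  expect_equal(dcnfl:::locus_category("LPN", "LSN"), "LPNvLSN")
  expect_equal(dcnfl:::locus_category("LPN", "RSN"), "cross")
  expect_equal(dcnfl:::locus_category("RPN", "LSN"), "cross")
})

## Build a table where one electrode/feature cell has controlled nerve
## means; remaining cells are widely separated so they contribute no loci.
loci_sim_table <- function(n, means, sd = 1) {
  tab <- synthetic_sf_table(n_per_nerve = n, mean = 0, sd = 0.01)
  sep <- c(RSN = 0, LSN = 1000, RPN = 2000, LPN = 3000)
  for (col in input_columns()) {
    tab[[col]] <- sep[as.character(tab$nerve)] + stats::rnorm(nrow(tab), 0, sd)
  }
  tab$e4_p1n1_amplitude <- means[as.character(tab$nerve)] +
    stats::rnorm(nrow(tab), 0, sd)
  tab
}

test_that("a true-null nerve pair is flagged as a non-significant locus", {
  set.seed(11)
  hits <- 0; extra <- 0
  n_sim <- 60
  for (s in seq_len(n_sim)) {
    tab <- loci_sim_table(220, c(RSN = 10, LSN = 10, RPN = 300, LPN = 600))
    loci <- nonsignificant_loci(tab)
    hit <- any(loci$category == "LSNvRSN" & loci$electrode == 4 &
                 loci$sf == "p1n1_amplitude")
    hits <- hits + hit
    extra <- extra + (nrow(loci) - hit)
  }
  expect_gte(hits / n_sim, 0.9)        # power for the true null pair
  expect_lte(extra / n_sim, 0.25)      # separated cells contribute ~nothing
})

test_that("fully separated nerves produce essentially no loci", {
  set.seed(12)
  misses <- 0
  for (s in 1:25) {
    tab <- loci_sim_table(100, c(RSN = 0, LSN = 100, RPN = 200, LPN = 300),
                          sd = 1)  # >= 10 within-nerve SDs apart
    misses <- misses + (nrow(nonsignificant_loci(tab)) > 0)
  }
  expect_lte(misses / 25, 0.01 + 1 / 25)
})

test_that("degenerate all-equal cells record every pair, flagged", {
  tab <- synthetic_sf_table(n_per_nerve = 12)
  tab$e1_n1_latency <- 7  # constant across all nerves
  loci <- nonsignificant_loci(tab)
  deg <- loci[loci$degenerate, ]
  expect_equal(nrow(deg), 6)
  expect_true(all(deg$electrode == 1 & deg$sf == "n1_latency"))
})

test_that("locus counts regress linearly on learnability errors", {
  counts <- c(2, 4, 6, 8, 10)
  errors <- c(1, 2, 3, 4, 5)
  fit <- suppressWarnings(loci_fl_regression(counts, errors))
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)

  expect_error(loci_fl_regression(rep(3, 5), errors), "zero variance")
  expect_error(loci_fl_regression(1:2, 1:2), "at least 3")
})

test_that("side dominance detects a doubled left response", {
  set.seed(13)
  tab <- synthetic_sf_table(n_per_nerve = 220, mean = 10, sd = 1)
  left <- tab$nerve %in% c("LSN", "LPN")
  for (col in input_columns()) tab[[col]][left] <- tab[[col]][left] * 2
  for (scope in c("e4", "TRM")) {
    dom <- side_dominance(tab, scope)
    expect_true(all(dom$dominant == "L"))
    expect_true(all(dom$p <= 0.05))
  }
  expect_match(attr(side_dominance(tab, "e4"), "note"), "latency")
})

test_that("dominance tests hold their nominal level under symmetry", {
  set.seed(14)
  n_sim <- 120
  rejections <- 0
  tests <- 0
  for (s in seq_len(n_sim)) {
    tab <- synthetic_sf_table(n_per_nerve = 60, mean = 10, sd = 1,
                              animals = "A1")
    dom <- side_dominance(tab, "e4")
    rejections <- rejections + sum(dom$dominant != "none")
    tests <- tests + nrow(dom)
  }
  rate <- rejections / tests  # 1200 pair tests under the null
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("bilateral confusion errors average the mirror cells", {
  cm <- matrix(25, 4, 4, dimnames = list(nerve_labels(), nerve_labels()))
  expect_equal(e4_bilateral_ml_error(cm, "sural"), 25)
  expect_equal(e4_bilateral_ml_error(cm, "peroneal"), 25)

  ident <- diag(rep(100, 4))
  dimnames(ident) <- list(nerve_labels(), nerve_labels())
  expect_equal(e4_bilateral_ml_error(ident, "peroneal"), 0)

  cm2 <- ident
  cm2["RPN", "LPN"] <- 10; cm2["RPN", "RPN"] <- 90
  cm2["LPN", "RPN"] <- 20; cm2["LPN", "LPN"] <- 80
  expect_equal(e4_bilateral_ml_error(cm2, "peroneal"), 15)

  expect_error(e4_bilateral_ml_error(matrix(1, 3, 3)), "malformed")
})

test_that("dominance-error association uses Pearson chi-squared with fallback", {
  dom <- data.frame(
    animal = rep(sprintf("A%d", 1:35), each = 2),
    sf = rep(sf_names(), 14),
    dominant = c(rep(c("L", "R"), 20), rep(c("none", "R"), 15)))
  err <- data.frame(animal = rep(sprintf("A%d", 1:35), each = 2),
                    sf = rep(sf_names(), 14),
                    error = c(rep(10, 40), rep(40, 30)))
  res <- dominance_error_association(dom, unique(err))
  expect_equal(res$method, "pearson_chisq")
  expect_lt(res$p, 1e-6)

  ## a zero margin forces the exact-test fallback
  dom0 <- dom; dom0$dominant <- "L"
  res0 <- dominance_error_association(dom0, unique(err))
  expect_true(res0$fallback)
  expect_equal(res0$method, "fisher")
})

test_that("association p-values are calibrated under independence", {
  set.seed(15)
  ps <- replicate(300, {
    n <- 200
    dom <- data.frame(animal = sprintf("A%d", 1:n), sf = "n1_latency",
                      dominant = sample(c("L", "none"), n, TRUE))
    err <- data.frame(animal = sprintf("A%d", 1:n), sf = "n1_latency",
                      error = stats::runif(n, 0, 50))
    dominance_error_association(dom, err)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("dominance counts correlate with per-feature learnability", {
  counts <- c(1, 3, 5, 7, 9)
  fl <- 50 + 5 * counts
  res <- dominance_fl_correlation(counts, fl)
  expect_equal(res$pearson_r, 1)
  expect_lt(res$p, 0.001)
  expect_error(dominance_fl_correlation(rep(2, 5), fl), "zero variance")

  ## permutation symmetry: shuffled pairings centre on zero
  set.seed(16)
  perm <- replicate(200, dominance_fl_correlation(sample(counts), fl)$pearson_r)
  expect_lt(abs(mean(perm)), 0.2)
})

test_that("learnability errors are exact complements", {
  expect_equal(fl_error(c(0, 25, 96.8, 100)), c(100, 75, 3.2, 0))
})
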