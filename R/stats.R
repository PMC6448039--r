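## Long view of a feature table: one row per (trial, electrode) with the
## five signal features as columns.
pooled_feature_values <- function(table) {
  out <- lapply(1:7, function(e) {
    cols <- feature_column(e, SF_NAMES)
    d <- table[, cols]
    names(d) <- SF_NAMES
    d$electrode <- e
    d$animal <- table$animal
    d$nerve <- table$nerve
    d
  })
  do.call(rbind, out)
}

#' Pearson correlations between all signal-feature pairs
#'
#' Pools every recording across trials, electrodes and animals and
#' correlates each of the 10 feature pairs, sorted by |r| descending.
#' Features measuring the same underlying burst (the high-frequency
#' integral and peak count) are expected to top the list.
#'
#' @param table Feature table.
#' @return Data frame: `feature_a`, `feature_b`, `r`, `p`.
#' @export
feature_pair_correlations <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 trials")
  long <- pooled_feature_values(table)
  pairs <- utils::combn(SF_NAMES, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- long[[pairs[1, j]]]
    b <- long[[pairs[2, j]]]
    ok <- stats::complete.cases(a, b)
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    data.frame(feature_a = pairs[1, j], feature_b = pairs[2, j],
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, out)
  out[order(-abs(out$r)), ]
}

## The five non-significant-locus categories; the two crossed pairs share
## one category.
locus_category <- function(nerve_a, nerve_b) {
  key <- paste(sort(c(nerve_a, nerve_b)), collapse = "-")
  switch(key,
         "LSN-RSN" = "LSNvRSN",
         "LPN-RPN" = "LPNvRPN",
         "RPN-RSN" = "RPNvRSN",
         "LPN-LSN" = "LPNvLSN",
         "LPN-RSN" = "cross",
         "LSN-RPN" = "cross",
         stop("unknown nerve pair: ", key))
}

#' Non-significant loci: nerve pairs a feature cannot separate
#'
#' For every (animal, signal feature, electrode) cell a linear model of the
#' feature magnitude on nerve (4 levels) is fit and all six pairwise nerve
#' contrasts are tested with Tukey-family adjustment (or
#' Benjamini-Yekutieli FDR control). Contrasts failing to reach
#' significance (adjusted p > alpha) are recorded as non-significant loci
#' -- the statistically predicted sites of classifier confusion -- and
#' assigned to one of five categories (left-vs-right sural, left-vs-right
#' peroneal, the two ipsilateral pairs, and the crossed pairs). Magnitudes
#' (absolute values) are compared, so sign conventions of amplitude and
#' slope cannot invert the comparison. A cell whose values are all equal is
#' degenerate: every pair is recorded and flagged.
#'
#' @param table Feature table.
#' @param alpha Significance level.
#' @param adjust `"tukey"` or `"BY"`.
#' @param use_magnitude Compare |value| (default) rather than signed values.
#' @return Data frame: `animal`, `sf`, `electrode`, `nerve_a`, `nerve_b`,
#'   `category`, `p_adj`, `degenerate`.
#' @export
nonsignificant_loci <- function(table, alpha = 0.05,
                                adjust = c("tukey", "BY"),
                                use_magnitude = TRUE) {
  adjust <- match.arg(adjust)
  pair_names <- utils::combn(NERVES, 2)
  out <- list()
  for (an in unique(table$animal)) {
    sub_a <- table[table$animal == an, ]
    for (sf in SF_NAMES) {
      for (e in 1:7) {
        v <- sub_a[[feature_column(e, sf)]]
        if (use_magnitude) v <- abs(v)
        nerve <- factor(as.character(sub_a$nerve), levels = NERVES)
        ok <- !is.na(v)
        v <- v[ok]; nerve <- nerve[ok]
        if (stats::sd(v) < 1e-12) {
          for (j in seq_len(ncol(pair_names)))
            out[[length(out) + 1L]] <- data.frame(
              animal = an, sf = sf, electrode = e,
              nerve_a = pair_names[1, j], nerve_b = pair_names[2, j],
              category = locus_category(pair_names[1, j], pair_names[2, j]),
              p_adj = 1, degenerate = TRUE)
          next
        }
        padj <- pairwise_nerve_p(v, nerve, adjust)
        ns <- padj[padj$p_adj > alpha, , drop = FALSE]
        if (nrow(ns)) {
          ns$animal <- an; ns$sf <- sf; ns$electrode <- e
          ns$category <- mapply(locus_category, ns$nerve_a, ns$nerve_b)
          ns$degenerate <- FALSE
          out[[length(out) + 1L]] <-
            ns[, c("animal", "sf", "electrode", "nerve_a", "nerve_b",
                   "category", "p_adj", "degenerate")]
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(animal = character(0), sf = character(0),
                      electrode = integer(0), nerve_a = character(0),
                      nerve_b = character(0), category = character(0),
                      p_adj = numeric(0), degenerate = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Adjusted p for all six pairwise nerve contrasts of one cell.
pairwise_nerve_p <- function(v, nerve, adjust) {
  if (adjust == "tukey") {
    hsd <- stats::TukeyHSD(stats::aov(v ~ nerve))$nerve
    parts <- strsplit(rownames(hsd), "-", fixed = TRUE)
    data.frame(nerve_a = vapply(parts, `[`, "", 2),
               nerve_b = vapply(parts, `[`, "", 1),
               p_adj = hsd[, "p adj"], row.names = NULL)
  } else {
    pt <- stats::pairwise.t.test(v, nerve, p.adjust.method = "BY")$p.value
    idx <- which(!is.na(pt), arr.ind = TRUE)
    data.frame(nerve_a = colnames(pt)[idx[, 2]],
               nerve_b = rownames(pt)[idx[, 1]],
               p_adj = pt[idx], row.names = NULL)
  }
}

#' Relate non-significant-locus counts to learnability errors
#'
#' Pearson correlation and least-squares line of the number of
#' non-significant loci (summed per signal feature or per electrode) on
#' the matching feature-learnability errors (100 - learnability).
#'
#' @param loci_counts Numeric vector of locus counts.
#' @param fl_errors Matching learnability errors (%).
#' @return A list: `pearson_r`, `slope`, `intercept`, `r_squared`, `p`.
#' @export
loci_fl_regression <- function(loci_counts, fl_errors) {
  stopifnot(length(loci_counts) == length(fl_errors))
  if (length(loci_counts) < 3) stop("need at least 3 paired observations")
  if (stats::sd(loci_counts) == 0 || stats::sd(fl_errors) == 0)
    stop("zero variance in loci counts or learnability errors")
  ct <- stats::cor.test(loci_counts, fl_errors)
  fit <- stats::lm(loci_counts ~ fl_errors)
  list(pearson_r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       p = ct$p.value)
}

#' Side dominance of signal features for bilateral nerve pairs
#'
#' For each animal, signal feature and bilateral pair (left/right sural,
#' left/right peroneal), tests whether the feature magnitude is
#' significantly greater on one side. At the central electrode
#' (`scope = "e4"`) a linear model of |value| on side is used; for the
#' total response magnitude (`scope = "TRM"`, the per-trial sum of |value|
#' across all 7 electrodes) a Student's t-test. The dominant side is the
#' one with the greater mean when p <= alpha, otherwise `"none"`. N1
#' latency is compared on the latency value itself; a left-side latency
#' dominance therefore indicates *shorter* right-side latencies (see the
#' `note` attribute).
#'
#' @param table Feature table.
#' @param scope `"e4"` (single central electrode) or `"TRM"`.
#' @param alpha Significance level.
#' @param electrode Electrode used for the `"e4"` scope.
#' @return Data frame: `animal`, `sf`, `scope`, `pair`, `dominant`
#'   (`"L"`/`"R"`/`"none"`), `p`, `mean_L`, `mean_R`.
#' @export
side_dominance <- function(table, scope = c("e4", "TRM"), alpha = 0.05,
                           electrode = 4) {
  scope <- match.arg(scope)
  pairs <- list(sural = c("LSN", "RSN"), peroneal = c("LPN", "RPN"))
  out <- list()
  for (an in unique(table$animal)) {
    sub_a <- table[table$animal == an, ]
    for (sf in SF_NAMES) {
      vals <- if (scope == "e4") {
        abs(sub_a[[feature_column(electrode, sf)]])
      } else {
        rowSums(abs(sub_a[, feature_column(1:7, sf)]))
      }
      for (pn in names(pairs)) {
        iL <- sub_a$nerve == pairs[[pn]][1]
        iR <- sub_a$nerve == pairs[[pn]][2]
        vL <- vals[iL]; vR <- vals[iR]
        if (!length(vL) || !length(vR))
          stop("missing pair member for ", pn, " in animal ", an)
        p <- if (scope == "e4") {
          side <- factor(c(rep("L", length(vL)), rep("R", length(vR))))
          fit <- stats::lm(c(vL, vR) ~ side)
          stats::anova(fit)[["Pr(>F)"]][1]
        } else {
          stats::t.test(vL, vR)$p.value
        }
        dominant <- if (!is.na(p) && p <= alpha) {
          if (mean(vL) > mean(vR)) "L" else "R"
        } else "none"
        out[[length(out) + 1L]] <- data.frame(
          animal = an, sf = sf, scope = scope, pair = pn,
          dominant = dominant, p = p,
          mean_L = mean(vL), mean_R = mean(vR))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "note") <-
    "n1_latency dominance is on the latency value: L-dominance = shorter right-side latencies"
  res
}

#' Bilateral misclassification error at a confusion matrix
#'
#' Mean of the two mirror off-diagonal cells of a bilateral pair (e.g.
#' right peroneal classified as left peroneal and vice versa). Chance
#' reference for a 4-class task is 25%.
#'
#' @param confusion Row-normalized 4x4 confusion matrix (%).
#' @param pair `"sural"` or `"peroneal"`.
#' @return The mean mirror error (%).
#' @export
e4_bilateral_ml_error <- function(confusion, pair = c("sural", "peroneal")) {
  pair <- match.arg(pair)
  if (!all(dim(confusion) == c(4, 4)) || any(!is.finite(confusion)))
    stop("malformed confusion matrix")
  if (any(abs(rowSums(confusion) - 100) > 1e-6))
    stop("confusion matrix rows must sum to 100")
  nv <- if (pair == "sural") c("LSN", "RSN") else c("LPN", "RPN")
  mean(c(confusion[nv[1], nv[2]], confusion[nv[2], nv[1]]))
}

#' Association between missing side dominance and bilateral error
#'
#' Cross-tabulates, over matched (animal, signal feature) instances,
#' whether both bilateral pairs displayed a side dominance against whether
#' the bilateral machine-learning error reached chance (>= 25%), and
#' applies Pearson's chi-squared test. If any margin of the 2x2 table is
#' zero the test degenerates and Fisher's exact test is used instead
#' (flagged in the output).
#'
#' @param dominance Output of [side_dominance()] (scope `"e4"`).
#' @param errors Data frame with `animal`, `sf` and `error` (the e4 mean
#'   bilateral ML error, %, per instance; typically the max over the two
#'   pairs or per-pair rows matched upstream).
#' @param chance Error threshold (%).
#' @return A list: `statistic`, `p`, `table`, `method`, `fallback`.
#' @export
dominance_error_association <- function(dominance, errors, chance = 25) {
  dom <- stats::aggregate(dominant ~ animal + sf, data = dominance,
                          FUN = function(d) all(d != "none"))
  names(dom)[3] <- "both_dominant"
  m <- merge(dom, errors, by = c("animal", "sf"))
  if (!nrow(m)) stop("no matched (animal, sf) instances")
  tab <- table(factor(m$both_dominant, levels = c(TRUE, FALSE)),
               factor(m$error >= chance, levels = c(FALSE, TRUE)),
               dnn = c("both_dominant", "error_at_chance"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p = ft$p.value, table = tab,
                method = "fisher", fallback = TRUE))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab,
       method = "pearson_chisq", fallback = FALSE)
}

#' Correlation between side-dominance counts and learnability per feature
#'
#' Pearson correlation between the number of side-dominant bilateral nerve
#' pairs per signal feature (total response magnitude scope) and the
#' feature-learnability of that feature across all electrodes.
#'
#' @param dominance_counts Numeric vector, one count per signal feature.
#' @param fl Matching feature-learnability values (%).
#' @return A list: `pearson_r`, `p`.
#' @export
dominance_fl_correlation <- function(dominance_counts, fl) {
  stopifnot(length(dominance_counts) == length(fl))
  if (stats::sd(dominance_counts) == 0 || stats::sd(fl) == 0)
    stop("zero variance")
  ct <- stats::cor.test(dominance_counts, fl)
  list(pearson_r = unname(ct$estimate), p = ct$p.value)
}

#' Learnability and machine-learning error
#'
#' Errors are complements of accuracy: `fl_error = 100 - learnability`.
#'
#' @param fl Learnability or accuracy values (%).
#' @return Error values (%).
#' @export
fl_error <- function(fl) 100 - fl
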