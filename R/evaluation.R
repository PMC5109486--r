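#' Confusion counts at a similarity threshold
#'
#' Labels every compound-target combination of the matrix universe at a TC
#' threshold. Predicted positives are the materialised candidates with
#' \code{tc_max >= threshold}; everything unscored (no co-binder, or below
#' the materialisation floor used at scoring) counts as predicted-negative.
#' Known-inactive pairs are excluded from the evaluation universe by
#' default — they are a separate candidate class, neither false positive
#' nor true negative — and can be counted as negatives with
#' \code{include_known_inactives = TRUE}.
#'
#' @param candidates a \code{candidate_scores} data frame (classified or
#'   not) scored on \code{matrix}.
#' @param matrix the \code{interaction_matrix}.
#' @param threshold TC threshold; must be at or above the materialisation
#'   floor the candidates were scored with, otherwise false-positive and
#'   true-negative counts would be wrong.
#' @param include_known_inactives logical; see above.
#' @return a list of class \code{confusion_counts} with integer-valued
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn} and the \code{universe}
#'   size.
#' @export
confusion_at_threshold <- function(candidates, matrix, threshold,
                                   include_known_inactives = FALSE) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  floor_tc <- attr(candidates, "min_tc")
  if (!is.null(floor_tc) && threshold < floor_tc)
    stop(sprintf(paste0("threshold %.3f is below the materialisation floor ",
                        "%.3f used at scoring; unscored combinations cannot ",
                        "be labelled"), threshold, floor_tc))

  n_comb <- as.numeric(length(matrix$compounds)) * length(matrix$targets)
  inactive_keys <- .pair_key(matrix$known_inactives)
  universe <- if (include_known_inactives) n_comb else
    n_comb - length(inactive_keys)

  key <- paste(candidates$compound_id, candidates$target_id, sep = "\r")
  pred <- candidates$tc_max >= threshold
  if (!include_known_inactives) pred <- pred & !(key %in% inactive_keys)
  pos_keys <- .pair_key(matrix$positives)
  tp <- sum(pred & key %in% pos_keys)
  fp <- sum(pred) - tp
  fn <- nrow(matrix$positives) - tp
  tn <- universe - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, universe = universe),
            class = "confusion_counts")
}

#' Sensitivity, specificity, precision and enrichment factor over thresholds
#'
#' Evaluates recovery of the known interactions at each TC threshold:
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), precision =
#' tp/(tp+fp) (0, flagged, when nothing is predicted positive) and the
#' enrichment factor, precision divided by the positive base rate of the
#' evaluation universe, so EF = 1 at a threshold admitting everything.
#'
#' @inheritParams confusion_at_threshold
#' @param thresholds numeric vector of TC thresholds within
#'   [materialisation floor, 1].
#' @return a data frame of class \code{metric_curve} with one row per
#'   threshold: the four counts and the four metrics, plus
#'   \code{precision_defined}.
#' @export
metric_curve <- function(candidates, matrix, thresholds,
                         include_known_inactives = FALSE) {
  if (nrow(matrix$positives) == 0L)
    stop("no positive pairs: recovery metrics are undefined")
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    cc <- confusion_at_threshold(candidates, matrix, th,
                                 include_known_inactives)
    base_rate <- (cc$tp + cc$fn) / cc$universe
    prec_def <- (cc$tp + cc$fp) > 0
    precision <- if (prec_def) cc$tp / (cc$tp + cc$fp) else 0
    data.frame(threshold = th, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               tn = cc$tn,
               sensitivity = cc$tp / (cc$tp + cc$fn),
               specificity = cc$tn / (cc$tn + cc$fp),
               precision = precision,
               enrichment_factor = precision / base_rate,
               precision_defined = prec_def)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_curve", "data.frame")
  out
}

#' @rdname metric_curve
#' @param curve a \code{metric_curve}.
#' @param path output TSV path.
#' @export
write_metric_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Random hold-out validation of interaction recovery
#'
#' Splits the positive pairs uniformly at random into a training and a test
#' set at the pair level, rebuilds the reference standard from the training
#' pairs only (the min-target filter is re-applied, so compounds losing too
#' many pairs drop out), scores candidates on the training matrix, ranks the
#' non-training candidates by descending score (ties by compound then
#' target id), and measures recovery of the held-out pairs at each rank
#' cutoff. Test pairs whose compound or target vanished from the training
#' universe cannot be scored; sensitivity is reported both over the
#' scoreable test pairs and over all test pairs.
#'
#' @param matrix an \code{interaction_matrix} (the pre-split standard), or
#'   a positive-pair data frame.
#' @param train_fraction fraction of positive pairs placed in training, in
#'   (0, 1); the study design uses 0.8 and 0.6.
#' @param seed integer seed driving the split.
#' @param rank_thresholds integer rank cutoffs (top-N); default a geometric
#'   grid scaled to the number of ranked candidates.
#' @param config \code{\link{curation_config}} used to rebuild the training
#'   matrix.
#' @param min_tc materialisation floor for scoring on the training matrix.
#' @return a list of class \code{holdout_result}: split sizes, unscoreable
#'   count, and a per-rank metric data frame with tp, fp, tn,
#'   sensitivity (scoreable denominator), sensitivity_all (all test pairs)
#'   and specificity over the training-universe negatives.
#' @export
holdout_validate <- function(matrix, train_fraction = 0.8, seed = 1L,
                             rank_thresholds = NULL,
                             config = curation_config(), min_tc = 0.5) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  pairs <- if (inherits(matrix, "interaction_matrix")) matrix$positives
           else matrix
  stopifnot(all(c("compound_id", "target_id") %in% names(pairs)))
  n <- nrow(pairs)
  n_train <- round(train_fraction * n)
  if (n_train < 1L) stop("empty training set")
  if (n_train >= n) stop("empty test set")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  train_idx <- sample.int(n, n_train)
  train <- pairs[train_idx, , drop = FALSE]
  test <- pairs[-train_idx, , drop = FALSE]

  train_matrix <- build_interaction_matrix(train, config = config)
  tipfs <- build_tipfs(train_matrix)
  cand <- score_candidates(tipfs, train_matrix, min_tc = min_tc)
  cand <- classify_candidates(cand, train_matrix)
  ranked <- cand[cand$status != "known_positive", , drop = FALSE]
  ranked <- ranked[order(-ranked$tc_max, ranked$compound_id,
                         ranked$target_id), , drop = FALSE]

  scoreable <- test$compound_id %in% train_matrix$compounds &
    test$target_id %in% train_matrix$targets
  n_unscoreable <- sum(!scoreable)
  test_keys <- .pair_key(test[scoreable, , drop = FALSE])
  ranked_keys <- .pair_key(ranked)

  n_comb <- as.numeric(length(train_matrix$compounds)) *
    length(train_matrix$targets)
  n_neg <- n_comb - nrow(train_matrix$positives) - length(test_keys) -
    nrow(train_matrix$known_inactives)

  if (is.null(rank_thresholds)) {
    top <- max(1L, nrow(ranked))
    rank_thresholds <- unique(pmin(top, ceiling(top * c(0.05, 0.1, 0.2, 0.4,
                                                        0.7, 1))))
  }
  rank_thresholds <- sort(unique(as.integer(rank_thresholds)))
  is_test_hit <- ranked_keys %in% test_keys
  cum_tp <- cumsum(is_test_hit)
  rows <- lapply(rank_thresholds, function(N) {
    k <- min(N, length(ranked_keys))
    tp <- if (k > 0L) cum_tp[k] else 0L
    fp <- k - tp
    tn <- n_neg - fp
    data.frame(rank = N, tp = tp, fp = fp, tn = tn,
               sensitivity = if (length(test_keys)) tp / length(test_keys)
                             else NA_real_,
               sensitivity_all = tp / nrow(test),
               specificity = tn / n_neg)
  })
  structure(list(train_fraction = train_fraction, seed = seed,
                 n_train = nrow(train), n_test = nrow(test),
                 n_test_scoreable = length(test_keys),
                 n_test_unscoreable = n_unscoreable,
                 train_matrix = train_matrix,
                 metrics = do.call(rbind, rows)),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf(paste0("Hold-out validation: %.0f%% train (seed %d), %d train ",
                     "/ %d test pairs (%d unscoreable)\n"),
              100 * x$train_fraction, x$seed, x$n_train, x$n_test,
              x$n_test_unscoreable))
  print(x$metrics)
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided test of independence under the minimum-likelihood
#' convention: with the margins fixed, the p-value is the sum of the
#' hypergeometric probabilities of every table no more probable than the
#' observed one (a relative tolerance of 1e-7 guards the comparison against
#' floating-point ties). Probabilities are computed from binomial
#' coefficients. A table with a zero row or column margin has p = 1. The
#' one-sided upper-tail p (probability of at least the observed count in
#' the top-left cell) is available via \code{alternative = "greater"}.
#'
#' @param table a 2x2 matrix of non-negative counts, or a length-4 vector
#'   read row-wise (a, b, c, d).
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}.
#' @return the p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table, alternative = c("two.sided",
                                                          "greater")) {
  alternative <- match.arg(alternative)
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L || any(is.na(x)) || any(x < 0) ||
      any(x != round(x)))
    stop("table must be four non-negative integer counts")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if (a + b + c + d == 0) stop("all-zero table: no observations")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)

  k <- max(0, c1 - r2):min(r1, c1)
  # hypergeometric pmf via log binomial coefficients (exact for these sizes)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[k == a]
  if (alternative == "greater") return(min(1, sum(p[k >= a])))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' @rdname fisher_exact_two_sided
#' @param path output JSON path; the table, method and p-value are written.
#' @export
write_fisher_result <- function(table, path,
                                alternative = "two.sided") {
  p <- fisher_exact_two_sided(table, alternative)
  x <- as.vector(t(as.matrix(table)))
  jsonlite::write_json(list(table = as.integer(x), method = "fisher_exact",
                            alternative = alternative, p_value = p),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(p)
}
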