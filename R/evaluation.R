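#' Classify a query by its nearest neighbour
#'
#' Runs [knn_search()] with `k = 1` against the labelled training collection
#' and returns the label of the top-ranked neighbour.
#'
#' @param query An [mts_item()].
#' @param training A labelled [mts_dataset()].
#' @param config A [search_config()] naming the measure.
#' @return Predicted class label (character scalar).
#' @export
one_nn_classify <- function(query, training, config = search_config()) {
  labs <- item_labels(training)
  if (anyNA(labs)) stop("every training item must carry a label")
  res <- suppressWarnings(knn_search(query, training, k = 1L, config = config))
  if (!nrow(res$neighbors)) stop("search returned no neighbour for '", query$id, "'")
  unname(labs[[res$neighbors$id[[1L]]]])
}

#' Repeated stratified k-fold cross-validated 1-NN error
#'
#' Splits the dataset into `folds` stratified folds (each class spread as
#' evenly as possible), uses each fold in turn as the test set with the rest
#' as training, classifies every test item by [one_nn_classify()], and
#' reports the percentage misclassified per fold. The whole procedure is
#' repeated `repeats` times with fresh fold assignments; all randomness is
#' drawn from `seed`, so a fixed seed gives a bit-identical report.
#'
#' @param dataset A labelled [mts_dataset()].
#' @param config A [search_config()].
#' @param folds Number of folds (reduced with a warning if a class has fewer
#'   members than folds would need for stratification to be meaningful).
#' @param repeats Number of independent repetitions.
#' @param seed Integer RNG seed.
#' @return An object of class `eval_report`: `measure`, `p` (component count
#'   actually used, from the variance rule or `config$p`), `errors`
#'   (`repeats x folds` matrix of fold error percentages), `mean_error`
#'   (mean of per-repeat means), `config`, `seed`.
#' @export
cross_validate <- function(dataset, config = search_config(), folds = 10L,
                           repeats = 10L, seed = 1L) {
  labs <- item_labels(dataset)
  if (anyNA(labs)) stop("every item must carry a label for cross-validation")
  if (length(unique(labs)) < 2L)
    warning("single-class dataset: the error rate is trivially 0")
  cmin <- min(table(labs))
  if (cmin < folds && cmin >= 2L) {
    warning(sprintf("smallest class has %d members; reducing folds to %d", cmin, cmin))
    folds <- cmin
  }
  ids <- names(dataset$items)
  set.seed(as.integer(seed))
  errors <- matrix(NA_real_, nrow = repeats, ncol = folds)
  p_used <- NA_integer_
  for (r in seq_len(repeats)) {
    fold_of <- stats::setNames(integer(length(ids)), ids)
    for (cl in unique(labs)) {
      members <- sample(ids[labs == cl])
      fold_of[members] <- rep_len(seq_len(folds), length(members))
    }
    for (f in seq_len(folds)) {
      test_ids <- ids[fold_of[ids] == f]
      train <- mts_dataset(dataset$items[setdiff(ids, test_ids)])
      wrong <- 0L
      for (qid in test_ids) {
        pred <- one_nn_classify(dataset$items[[qid]], train, config = config)
        if (pred != labs[[qid]]) wrong <- wrong + 1L
      }
      errors[r, f] <- 100 * wrong / length(test_ids)
    }
  }
  if (is.null(config$p)) {
    eig <- lapply(dataset$items, function(it) fit_pca(it)$eigenvalues)
    p_used <- choose_num_components(eig, config$threshold)
  } else p_used <- config$p
  structure(list(measure = config$measure, p = p_used, errors = errors,
                 mean_error = mean(rowMeans(errors)), config = config,
                 seed = as.integer(seed), folds = folds, repeats = repeats),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, p = %d: %dx%d-fold CV error %.1f%% (seed %d)\n",
              toupper(x$measure), x$p, x$repeats, x$folds, x$mean_error, x$seed))
  invisible(x)
}

#' Scan retained component counts for the best classification error
#'
#' Evaluates consecutive component counts `p`, starting at the smallest `p`
#' that passes the variance-retention rule (smaller values are never
#' considered), and stops as soon as the error rises above the best seen so
#' far (first local minimum) or `p` reaches the number of variables.
#'
#' @param dataset A labelled [mts_dataset()].
#' @param config A [search_config()]; its `p` is overridden during the scan.
#' @param seed RNG seed passed to each evaluation.
#' @param repeats CV repeats per evaluated `p` (default 1 for tractability;
#'   raise for the full protocol).
#' @param folds CV folds per evaluated `p`.
#' @param eval_fn Optional function `p -> error` replacing the internal
#'   cross-validation (used to audit the stopping rule in isolation).
#' @return List: `best_p`, `best_error`, and `table` (data frame of every
#'   evaluated `p` with its error, so alternate readings can be audited).
#' @export
scan_components <- function(dataset, config = search_config(), seed = 1L,
                            repeats = 1L, folds = 10L, eval_fn = NULL) {
  eig <- lapply(dataset$items, function(it) fit_pca(it)$eigenvalues)
  p_min <- choose_num_components(eig, config$threshold)
  n <- dataset$n
  if (is.null(eval_fn)) {
    eval_fn <- function(p) {
      cfg <- config; cfg$p <- p
      cross_validate(dataset, cfg, folds = folds, repeats = repeats,
                     seed = seed)$mean_error
    }
  }
  ps <- integer(0); errs <- numeric(0)
  best_p <- NA_integer_; best_err <- Inf
  for (p in seq.int(p_min, n)) {
    e <- eval_fn(p)
    ps <- c(ps, p); errs <- c(errs, e)
    if (e < best_err) { best_err <- e; best_p <- p }
    else if (e > best_err) break   # risen past the minimum: stop the scan
  }
  list(best_p = best_p, best_error = best_err,
       table = data.frame(p = ps, error = errs))
}

#' Wilcoxon signed-rank test for paired error rates
#'
#' The matched-pairs comparison used to decide whether one similarity measure
#' improves on another across datasets. Differences `y - x` are formed, zero
#' differences dropped, absolute differences ranked with average ranks for
#' ties, and `W+` (the sum of ranks of positive differences) referred to the
#' normal approximation `z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` without
#' continuity correction; the two-sided p-value comes from the normal tail.
#'
#' @param x,y Paired numeric vectors of equal length (at least 2 pairs).
#' @return An object of class `paired_test`: `W` (W+), `z`, `p_value`
#'   (two-sided), `n_nonzero`.
#' @examples
#' wilcoxon_signed_rank(c(27.7, 52.6, 53.4, 15.9, 9.8, 24.0),
#'                      c(27.7, 50.4, 52.4, 13.0, 8.1, 21.3))
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all differences are zero; the test is undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  z <- (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(W = W, z = z, p_value = p, n_nonzero = n),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("<paired_test> W+ = %g, z = %.4f, two-sided p = %.4f (n = %d)\n",
              x$W, x$z, x$p_value, x$n_nonzero))
  invisible(x)
}
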