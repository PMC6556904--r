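## Two-step feature selection: mRMR ranking to 100 optimal feature candidates
## (OFCs), then forward selection maximizing 5-fold cross-validated AUC.

#' Discretize a feature column into three levels
#'
#' Classic mRMR discretization: values at or above `mean + sd` map to +1, at
#' or below `mean - sd` to -1, otherwise 0. The population standard deviation
#' is used and the comparisons are inclusive, so a balanced 0/1 indicator
#' column lands exactly on its thresholds and still yields two distinct
#' levels. Constant columns map entirely to 0.
#'
#' @param x Numeric vector (finite values).
#' @return Integer vector over \{-1, 0, 1\}.
#' @export
discretize <- function(x) {
  if (any(!is.finite(x))) stop("discretize: non-finite values")
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)
  if (is.na(s) || s == 0) return(rep(0L, n))
  out <- integer(n)
  out[x >= m + s] <- 1L
  out[x <= m - s] <- -1L
  out
}

#' Empirical mutual information between two discrete vectors
#'
#' Estimated from empirical joint frequencies with the convention
#' `0 * log(0) = 0`; natural logarithm (nats).
#'
#' @param a,b Vectors of equal length (treated as categorical).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

# fast MI for small positive-integer codes
.mi_codes <- function(a, b, na, nb) {
  joint <- tabulate((a - 1L) * nb + b, nbins = na * nb)
  n <- sum(joint)
  p <- joint / n
  pm <- matrix(p, nrow = na, ncol = nb, byrow = TRUE)
  px <- rowSums(pm)
  py <- colSums(pm)
  idx <- pm > 0
  sum(pm[idx] * log(pm[idx] / outer(px, py)[idx]))
}

#' mRMR feature ranking (greedy MID criterion)
#'
#' Ranks features by maximum relevance to the labels and minimum redundancy
#' among themselves, on mean-plus/minus-sd discretized codes
#' ([discretize()]). The first feature maximizes `I(f; y)`; each subsequent
#' one maximizes `I(f; y) - mean(I(f; s))` over the already selected set `S`
#' (the MID, difference, form). Deterministic; ties resolved toward the
#' lowest column index.
#'
#' @param features Numeric feature matrix (samples x features).
#' @param labels 0/1 labels (both classes required).
#' @param n_candidates Number of features to rank (default 100, the OFC
#'   count; capped at `ncol(features)`).
#' @return `data.frame` with columns `rank`, `index`, `column`, `relevance`,
#'   `redundancy`, `score`, ordered by selection step.
#' @export
mrmr_rank <- function(features, labels, n_candidates = 100L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  stopifnot(nrow(features) == length(labels))
  p <- ncol(features)
  n_candidates <- min(as.integer(n_candidates), p)
  codes <- apply(features, 2L, discretize) + 2L  # 1..3
  y <- labels + 1L                               # 1..2
  rel <- vapply(seq_len(p), function(j) .mi_codes(codes[, j], y, 3L, 2L),
                numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  red_at_pick <- numeric(0)
  score_at_pick <- numeric(0)
  avail <- rep(TRUE, p)
  for (step in seq_len(n_candidates)) {
    if (step == 1L) {
      score <- rel
    } else {
      last <- selected[step - 1L]
      upd <- which(avail)
      red_sum[upd] <- red_sum[upd] + vapply(upd, function(j) {
        .mi_codes(codes[, j], codes[, last], 3L, 3L)
      }, numeric(1))
      score <- rel - red_sum / (step - 1L)
    }
    score[!avail] <- -Inf
    pick <- which.max(score)  # first max = lowest column index on ties
    selected <- c(selected, pick)
    red_at_pick <- c(red_at_pick, if (step == 1L) 0 else red_sum[pick] / (step - 1L))
    score_at_pick <- c(score_at_pick, score[pick])
    avail[pick] <- FALSE
  }
  cols <- colnames(features)
  if (is.null(cols)) cols <- paste0("V", seq_len(p))
  data.frame(rank = seq_len(n_candidates), index = selected,
             column = cols[selected], relevance = rel[selected],
             redundancy = red_at_pick, score = score_at_pick,
             stringsAsFactors = FALSE)
}

#' Stratified cross-validation fold assignment
#'
#' @param labels 0/1 labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`, with each class spread
#'   evenly across folds.
#' @export
make_folds <- function(labels, folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

# min-max scaling parameters learned on training rows only
.scale_fit <- function(x) {
  mins <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - mins
  rng[rng == 0] <- 1
  list(min = mins, range = rng)
}

.scale_apply <- function(x, sc) {
  sweep(sweep(x, 2L, sc$min, "-"), 2L, sc$range, "/")
}

#' Mean cross-validated AUC of the SVR pipeline
#'
#' For each fold: min-max scaling fitted on the training rows, an RBF-kernel
#' epsilon-SVR fitted on 0/1 targets, validation rows scored, and the fold
#' AUC computed; the mean over folds is returned.
#'
#' @param features Feature matrix.
#' @param labels 0/1 labels.
#' @param fold_id Fold assignment from [make_folds()].
#' @param cost,gamma,epsilon SVR hyperparameters.
#' @return Mean fold AUC.
#' @export
cv_svr_auc <- function(features, labels, fold_id, cost = 1,
                       gamma = 1 / ncol(features), epsilon = 0.1) {
  labels <- as.integer(labels)
  aucs <- vapply(sort(unique(fold_id)), function(k) {
    tr <- fold_id != k
    sc <- .scale_fit(features[tr, , drop = FALSE])
    fit <- e1071::svm(.scale_apply(features[tr, , drop = FALSE], sc),
                      labels[tr], type = "eps-regression", kernel = "radial",
                      cost = cost, gamma = gamma, epsilon = epsilon,
                      scale = FALSE)
    sc_val <- .scale_apply(features[!tr, , drop = FALSE], sc)
    roc_auc(as.numeric(stats::predict(fit, sc_val)), labels[!tr])$auc
  }, numeric(1))
  mean(aucs)
}

#' Default SVR hyperparameter grid
#'
#' Powers-of-two grid over `C` in 2^-5..2^5 and `gamma` in 2^-7..2^3 (step
#' 2^2, the libsvm practice-guide convention) crossed with
#' `epsilon` in \{0.01, 0.1\}.
#'
#' @return `data.frame` with columns `cost`, `gamma`, `epsilon`.
#' @export
default_svr_grid <- function() {
  expand.grid(cost = 2^seq(-5, 5, by = 2), gamma = 2^seq(-7, 3, by = 2),
              epsilon = c(0.01, 0.1), KEEP.OUT.ATTRS = FALSE)
}

#' Grid search for SVR hyperparameters by mean CV AUC
#'
#' @param features Feature matrix.
#' @param labels 0/1 labels.
#' @param grid Hyperparameter `data.frame` (default [default_svr_grid()]).
#' @param fold_id Fold assignment (shared across all grid points).
#' @return List with `best` (row of `grid` as a list, plus `cv_auc`) and
#'   `results` (the grid with a `cv_auc` column). Ties keep the earliest grid
#'   row, so the choice is deterministic.
#' @export
svr_grid_search <- function(features, labels, grid = default_svr_grid(),
                            fold_id) {
  auc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_svr_auc(features, labels, fold_id, cost = grid$cost[i],
               gamma = grid$gamma[i], epsilon = grid$epsilon[i])
  }, numeric(1))
  results <- cbind(grid, cv_auc = auc)
  best <- which.max(auc)
  list(best = list(cost = grid$cost[best], gamma = grid$gamma[best],
                   epsilon = grid$epsilon[best], cv_auc = auc[best]),
       results = results)
}

#' Forward feature selection over an mRMR ranking
#'
#' Starting from the top-ranked feature, features are added one at a time in
#' ranking order; at each prefix size `k` the mean 5-fold cross-validated AUC
#' of the SVR pipeline is recorded, with the fold assignment held fixed
#' across all `k` (otherwise the curve would not be comparable). The selected
#' subset is the smallest `k` achieving the maximum AUC. One set of SVR
#' hyperparameters, tuned by grid search on the full ranked set, is reused at
#' every step.
#'
#' @param features Feature matrix (full columns; the ranking indexes into it).
#' @param labels 0/1 labels.
#' @param ranking `data.frame` from [mrmr_rank()].
#' @param folds Number of CV folds (default 5).
#' @param seed Seed fixing the fold assignment.
#' @param params Optional list with `cost`, `gamma`, `epsilon` to skip the
#'   grid search.
#' @param grid Hyperparameter grid for the single tuning pass (default
#'   [default_svr_grid()]).
#' @return List with `curve` (`data.frame` of `n_features`, `cv_auc`),
#'   `selected` (the chosen prefix of `ranking`), `params` and `fold_id`.
#' @export
forward_select <- function(features, labels, ranking, folds = 5L, seed = 1L,
                           params = NULL, grid = default_svr_grid()) {
  if (nrow(ranking) == 0L) stop("empty ranking")
  cols <- ranking$index
  fold_id <- make_folds(labels, folds, seed)
  if (is.null(params)) {
    params <- svr_grid_search(features[, cols, drop = FALSE], labels, grid,
                              fold_id)$best
  }
  auc <- numeric(nrow(ranking))
  for (k in seq_len(nrow(ranking))) {
    auc[k] <- tryCatch(
      cv_svr_auc(features[, cols[seq_len(k)], drop = FALSE], labels, fold_id,
                 cost = params$cost, gamma = params$gamma,
                 epsilon = params$epsilon),
      error = function(e) stop("forward selection failed at step ", k, ": ",
                               conditionMessage(e)))
  }
  k_best <- which.max(auc)  # smallest k on the plateau
  list(curve = data.frame(n_features = seq_len(nrow(ranking)), cv_auc = auc),
       selected = ranking[seq_len(k_best), , drop = FALSE],
       params = params, fold_id = fold_id)
}
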