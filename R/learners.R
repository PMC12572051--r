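# Cross-fitted nuisance estimation. Propensity pi(X) = P(T=1|X) and the
# two potential-outcome regressions g(1,X), g(0,X) are fit on the
# out-of-split portion of the sample and predicted in-split, so no
# observation is ever predicted by a model trained on it. Two learner
# families: a bagged CART probability forest (compiled; 500 trees,
# mtry = floor(sqrt(p)), maximum depth tuned on a grid by 3-fold CV
# log-loss) and L1-penalized logistic regression with CV-chosen penalty.

#' Learner specification
#'
#' @param kind "random_forest" or "lasso".
#' @param depth_grid maximum tree depths tried during tuning; default is
#'   the reference grid 3, 4, 6, 8, 10, 12, 14, 16, 18, 20.
#' @param cv_folds folds for tuning (depth or lasso penalty); >= 2.
#' @param n_trees trees per forest (default 500).
#' @param min_leaf minimum leaf size of a tree.
#' @param tune if \code{FALSE}, skip depth tuning and use
#'   \code{fixed_depth} (a pragmatic fast path for large simulation
#'   studies; the reference configuration tunes for each split in every
#'   resample).
#' @param fixed_depth depth used when \code{tune = FALSE}.
#' @return an object of class \code{shockdml_learner}.
#' @export
learner_spec <- function(kind = c("random_forest", "lasso"),
                         depth_grid = c(3, 4, 6, 8, 10, 12, 14, 16, 18, 20),
                         cv_folds = 3L, n_trees = 500L, min_leaf = 5L,
                         tune = TRUE, fixed_depth = 8L) {
  kind <- match.arg(kind)
  if (!length(depth_grid)) abort_fmt("depth_grid must be non-empty")
  if (cv_folds < 2) abort_fmt("cv_folds must be >= 2")
  structure(list(kind = kind, depth_grid = as.integer(sort(depth_grid)),
                 cv_folds = as.integer(cv_folds),
                 n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf), tune = isTRUE(tune),
                 fixed_depth = as.integer(fixed_depth)),
            class = "shockdml_learner")
}

PROPENSITY_CLIP <- c(0.01, 0.99)

#' Random partition into K splits of near-equal size
#'
#' @param ids vector to partition (typically row indices).
#' @param K number of splits (>= 2, <= length(ids)).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return integer vector of split labels 1..K, aligned with \code{ids};
#'   split sizes differ by at most one.
#' @export
partition <- function(ids, K, seed) {
  n <- length(ids)
  if (K > n) abort_fmt("K = %d exceeds the number of units (%d)", K, n)
  if (K < 2) abort_fmt("K must be >= 2")
  with_seed(seed, sample(rep_len(seq_len(K), n)))
}

# binary cross-entropy with clipped predictions
log_loss <- function(y, p) {
  p <- clip(p, 1e-6, 1 - 1e-6)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# design matrix from a sample's covariate block
model_matrix <- function(sample, cols = sample_covariates(sample)) {
  as.matrix(sample[, cols, with = FALSE])
}

rf_fit_predict <- function(Xtr, ytr, Xte, spec, depth) {
  mtry <- max(1L, floor(sqrt(ncol(Xtr))))
  forest_fit_predict(Xtr, as.numeric(ytr), Xte, spec$n_trees, mtry,
                     as.integer(depth), spec$min_leaf)
}

lasso_fit_predict <- function(Xtr, ytr, Xte, spec) {
  if (length(unique(ytr)) < 2L) {
    return(rep(mean(ytr), nrow(Xte)))
  }
  # guard against constant columns only; glmnet needs >= 2 columns
  if (ncol(Xtr) < 2L) {
    Xtr <- cbind(Xtr, 0)
    Xte <- cbind(Xte, 0)
  }
  fit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                           nfolds = spec$cv_folds)
  as.numeric(predict(fit, Xte, s = "lambda.min", type = "response"))
}

#' Tune the maximum tree depth by cross-validated log-loss
#'
#' @param X numeric feature matrix of the training rows.
#' @param y binary target.
#' @param spec a \code{\link{learner_spec}} (random forest).
#' @param seed seed controlling the CV fold assignment and forest
#'   randomness.
#' @return the chosen depth (smallest grid value on ties). A degenerate
#'   single-class target returns the smallest depth with a warning.
#' @export
tune_depth <- function(X, y, spec, seed) {
  if (length(unique(y)) < 2L) {
    warning("degenerate target: single class; returning smallest depth")
    return(min(spec$depth_grid))
  }
  if (length(spec$depth_grid) == 1L) return(spec$depth_grid)
  if (nrow(X) < spec$cv_folds) abort_fmt("fewer rows than cv_folds")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(spec$cv_folds), nrow(X)))
    losses <- vapply(spec$depth_grid, function(d) {
      fl <- vapply(seq_len(spec$cv_folds), function(k) {
        tr <- fold != k
        p <- rf_fit_predict(X[tr, , drop = FALSE], y[tr],
                            X[!tr, , drop = FALSE], spec, d)
        log_loss(y[!tr], p)
      }, numeric(1))
      mean(fl)
    }, numeric(1))
    spec$depth_grid[which.min(losses)]
  })
}

#' Cross-fitted nuisance predictions
#'
#' Partitions the sample into K splits; for each split, the propensity
#' model is trained on all out-of-split rows and the outcome models on
#' the out-of-split treated/untreated rows respectively, then predicted
#' in-split. If some training fold lacks a treatment arm the partition is
#' redrawn with a fresh sub-seed (logged); persistent failure aborts.
#'
#' @param sample a \code{shockdml_sample}.
#' @param spec a \code{\link{learner_spec}}.
#' @param K number of splits (default 5).
#' @param seed seed for partitioning, tuning and fitting.
#' @return data.table (row, pi, g1, g0) covering every sample row, with
#'   \code{pi} clipped to \[0.01, 0.99\] (attribute \code{clip}).
#' @export
fit_predict_crossfit <- function(sample, spec, K = 5L, seed = 1L) {
  n <- nrow(sample)
  t_vec <- sample$treated
  y_vec <- sample$y
  if (length(unique(t_vec)) < 2L) {
    abort_fmt("sample needs both treated and control rows")
  }
  X <- model_matrix(sample)

  seeds <- child_seeds(seed, 24L)
  split <- NULL
  for (attempt in seq_len(20L)) {
    cand <- partition(seq_len(n), K, seeds[attempt])
    ok <- all(vapply(seq_len(K), function(k) {
      tr <- cand != k
      length(unique(t_vec[tr])) == 2L
    }, logical(1)))
    if (ok) {
      split <- cand
      if (attempt > 1L) {
        message(sprintf("crossfit: redrew partition %d time(s)", attempt - 1L))
      }
      break
    }
  }
  if (is.null(split)) {
    abort_fmt("a training fold has no treated units after 20 redraws")
  }

  pi_hat <- g1_hat <- g0_hat <- rep(NA_real_, n)
  fold_seeds <- child_seeds(seeds[21L], K)
  for (k in seq_len(K)) {
    te <- split == k
    tr <- !te
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    sk <- child_seeds(fold_seeds[k], 6L)
    if (spec$kind == "random_forest") {
      fit_one <- function(rows, target, seed_tune, seed_fit) {
        d <- if (spec$tune) {
          tune_depth(Xtr[rows, , drop = FALSE], target[rows], spec, seed_tune)
        } else {
          spec$fixed_depth
        }
        with_seed(seed_fit,
                  rf_fit_predict(Xtr[rows, , drop = FALSE], target[rows],
                                 Xte, spec, d))
      }
      pi_hat[te] <- fit_one(rep(TRUE, sum(tr)), t_vec[tr], sk[1], sk[2])
      g1_hat[te] <- fit_one(t_vec[tr] == 1L, y_vec[tr], sk[3], sk[4])
      g0_hat[te] <- fit_one(t_vec[tr] == 0L, y_vec[tr], sk[5], sk[6])
    } else {
      pi_hat[te] <- with_seed(sk[2], lasso_fit_predict(Xtr, t_vec[tr], Xte,
                                                       spec))
      g1_hat[te] <- with_seed(sk[4], lasso_fit_predict(
        Xtr[t_vec[tr] == 1L, , drop = FALSE], y_vec[tr][t_vec[tr] == 1L],
        Xte, spec))
      g0_hat[te] <- with_seed(sk[6], lasso_fit_predict(
        Xtr[t_vec[tr] == 0L, , drop = FALSE], y_vec[tr][t_vec[tr] == 0L],
        Xte, spec))
    }
  }

  out <- data.table::data.table(
    row = seq_len(n),
    pi = clip(pi_hat, PROPENSITY_CLIP[1], PROPENSITY_CLIP[2]),
    g1 = clip(g1_hat, 0, 1),
    g0 = clip(g0_hat, 0, 1))
  data.table::setattr(out, "clip", PROPENSITY_CLIP)
  data.table::setattr(out, "split", split)
  out
}
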