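# SVM classifier with Platt-calibrated continuous fQRS score.
#
# The SVM is solved by sequential minimal optimisation (compiled); kernels:
# linear, polynomial, RBF. Hyperparameters are tuned by seeded, grouped
# cross-validated grid search (a deterministic, dependency-light substitute
# for a Bayesian optimiser: no claims are attached to the optimiser itself).
# Features are z-scored with training statistics before the kernel; Platt's
# sigmoid is fitted on out-of-fold decision values to avoid
# calibration-on-training bias.

KERNEL_CODES <- c(linear = 0L, poly = 1L, rbf = 2L)

svm_fit_raw <- function(X, y01, kernel, C, gamma = 1, coef0 = 1, degree = 3,
                        tol = 1e-2) {
  y <- ifelse(y01 == 1, 1, -1)
  sol <- .svm_smo_cpp(X, y, C, KERNEL_CODES[[kernel]], gamma, coef0,
                      as.integer(degree), tol)
  list(X = X, y = y, alpha = sol$alpha, b = sol$b, kernel = kernel,
       C = C, gamma = gamma, coef0 = coef0, degree = degree)
}

svm_decision <- function(fit, Xnew) {
  .svm_decision_cpp(fit$X, fit$y, fit$alpha, fit$b, Xnew,
                    KERNEL_CODES[[fit$kernel]], fit$gamma, fit$coef0,
                    as.integer(fit$degree))
}

# Platt's sigmoid P(y = 1 | f) = 1 / (1 + exp(A f + B)), fitted by the
# regularized Newton method of Lin, Lin & Weng (2007). Deterministic.
platt_fit <- function(dec, y01, max_iter = 100) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0)
    stop("Platt calibration needs both classes", call. = FALSE)
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n0 + 2)
  t <- ifelse(y01 == 1, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  fval <- function(A, B) {
    z <- A * dec + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    z <- A * dec + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dec * dec * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      f2 <- fval(A2, B2)
      if (f2 < fv + 1e-4 * step * gd) { A <- A2; B <- B2; fv <- f2; break }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

platt_prob <- function(platt, dec) {
  z <- platt$A * dec + platt$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

# deterministic grouped K-fold assignment for a vector of group ids
grouped_folds <- function(groups, k, seed) {
  ug <- unique(groups)
  k <- min(k, length(ug))
  perm <- with_seed(seed, sample(ug))
  fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(perm)),
                                   perm)
  unname(fold_of_group[as.character(groups)])
}

default_grid <- function(kernel, n_features) {
  Cs <- 10^seq(-3, 3, by = 2)
  switch(kernel,
    linear = expand.grid(C = Cs, gamma = 1, degree = 3),
    poly = expand.grid(C = Cs, gamma = 1 / n_features, degree = 2:4),
    rbf = expand.grid(C = Cs, gamma = 10^seq(-3, 1, by = 4 / 3), degree = 3))
}

#' Train an fQRS classifier
#'
#' Fits an SVM on per-lead feature vectors with binary fragmentation labels.
#' Hyperparameters are selected by `cv`-fold cross-validation grouped by
#' recording (no recording contributes leads to both sides of a fold), the
#' model is refit on all data, and a Platt sigmoid is calibrated on
#' out-of-fold decision values so [fqrs_score()] returns the probability of
#' the fragmented class.
#'
#' @param features numeric matrix or data.frame of the 10 per-lead features
#'   (columns named as in `FEATURE_NAMES`).
#' @param labels binary labels (1 = fragmented), one per row.
#' @param groups recording identifier per row (split integrity); defaults to
#'   one group per row.
#' @param kernel `"linear"`, `"poly"` or `"rbf"`.
#' @param cv number of cross-validation folds.
#' @param seed seed controlling fold assignment.
#' @param grid optional data.frame of candidate `C`/`gamma`/`degree` rows;
#'   default log-grid (C in 1e-3..1e3, RBF gamma in 1e-3..1e1, degree 2--4).
#' @return An `fqrs_model`.
#' @export
fqrs_train <- function(features, labels, groups = NULL,
                       kernel = c("linear", "poly", "rbf"), cv = 5,
                       seed = 1L, grid = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("labels/features size mismatch",
                                      call. = FALSE)
  if (nrow(X) < 20) stop("need at least 20 samples to train", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("training error: both classes must be present", call. = FALSE)
  if (any(!is.finite(X)))
    stop("non-finite feature values in training data", call. = FALSE)
  if (is.null(groups)) groups <- seq_len(nrow(X))

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  if (is.null(grid)) grid <- default_grid(kernel, ncol(X))
  folds <- grouped_folds(groups, cv, seed)
  k <- max(folds)
  # hyperparameter search uses 3 of the folds (the search only ranks
  # candidates); Platt calibration below uses all cv folds
  k_tune <- min(3L, k)

  cv_auc <- vapply(seq_len(nrow(grid)), function(gi) {
    dec <- rep(NA_real_, nrow(Xs))
    for (f in seq_len(k_tune)) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      fit <- svm_fit_raw(Xs[tr, , drop = FALSE], labels[tr], kernel,
                         C = grid$C[gi], gamma = grid$gamma[gi],
                         degree = grid$degree[gi])
      dec[!tr] <- svm_decision(fit, Xs[!tr, , drop = FALSE])
    }
    ok <- is.finite(dec)
    if (length(unique(labels[ok])) < 2) return(NA_real_)
    rank_auc(dec[ok], labels[ok])
  }, numeric(1))
  best <- which.max(round(cv_auc, 10)) # ties -> first grid row (smallest C)
  pars <- grid[best, ]

  fit <- svm_fit_raw(Xs, labels, kernel, C = pars$C, gamma = pars$gamma,
                     degree = pars$degree)
  # out-of-fold decision values for unbiased Platt calibration
  dec_oof <- rep(NA_real_, nrow(Xs))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2) next
    ffit <- svm_fit_raw(Xs[tr, , drop = FALSE], labels[tr], kernel,
                        C = pars$C, gamma = pars$gamma, degree = pars$degree)
    dec_oof[!tr] <- svm_decision(ffit, Xs[!tr, , drop = FALSE])
  }
  ok <- is.finite(dec_oof)
  platt <- platt_fit(dec_oof[ok], labels[ok])

  structure(list(kernel = kernel, params = as.list(pars), svm = fit,
                 center = ctr, scale = scl, platt = platt,
                 feature_names = colnames(X),
                 cv = data.frame(grid, auc = cv_auc)),
            class = "fqrs_model")
}

#' @export
print.fqrs_model <- function(x, ...) {
  cat(sprintf("<fqrs_model> kernel=%s C=%g gamma=%g degree=%d | Platt A=%.3f B=%.3f\n",
              x$kernel, x$params$C, x$params$gamma, x$params$degree,
              x$platt$A, x$platt$B))
  cat(sprintf("  %d support vectors of %d samples, best CV AUC %.3f\n",
              sum(x$svm$alpha > 0), length(x$svm$alpha),
              max(x$cv$auc, na.rm = TRUE)))
  invisible(x)
}

#' Continuous fQRS score for feature vectors
#'
#' Platt-calibrated probability of the fragmented class, strictly monotone in
#' the SVM decision value.
#'
#' @param model an `fqrs_model`.
#' @param features matrix/data.frame of feature rows (column names, when
#'   present, must match the training features) or a single named vector.
#' @return numeric scores in `[0, 1]`.
#' @export
fqrs_score <- function(model, features) {
  stopifnot(inherits(model, "fqrs_model"))
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), model$feature_names))
      stop("feature columns do not match the model: expected ",
           paste(model$feature_names, collapse = ", "), call. = FALSE)
    X <- X[, model$feature_names, drop = FALSE]
  } else if (ncol(X) != length(model$feature_names)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("scoring error: non-finite value in feature '",
         model$feature_names[bad[1, 2]], "'", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  platt_prob(model$platt, svm_decision(model$svm, Xs))
}

#' @rdname fqrs_score
#' @export
fqrs_decision <- function(model, features) {
  stopifnot(inherits(model, "fqrs_model"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X))) X <- X[, model$feature_names, drop = FALSE]
  else if (ncol(X) != length(model$feature_names))
    stop("feature dimension mismatch", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  svm_decision(model$svm, Xs)
}

#' Binarize a continuous score
#'
#' The boundary is inclusive: a score exactly at the threshold maps to
#' class 1.
#'
#' @param score scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return integer vector of 0/1.
#' @export
binarize <- function(score, threshold = 0.5) {
  stopifnot(all(score >= 0 & score <= 1, na.rm = TRUE))
  as.integer(score >= threshold)
}

#' Recording-level train/test splits
#'
#' Splits are drawn at recording (patient) level: no recording contributes
#' leads to both sides. `n_repeats` independent splits are derived from the
#' seed.
#'
#' @param groups recording identifier per sample row.
#' @param train_frac fraction of recordings assigned to training.
#' @param n_repeats number of independent splits.
#' @param seed split seed.
#' @return list of `n_repeats` lists with integer index vectors `train`,
#'   `test`.
#' @export
split_by_recording <- function(groups, train_frac = 0.8, n_repeats = 10,
                               seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < 2) stop("need at least 2 recordings to split",
                           call. = FALSE)
  n_train <- round(train_frac * length(ug))
  n_train <- min(max(n_train, 1L), length(ug) - 1L)
  with_seed(seed, lapply(seq_len(n_repeats), function(i) {
    tr_g <- sample(ug, n_train)
    list(train = which(groups %in% tr_g),
         test = which(!groups %in% tr_g))
  }))
}

#' Balance classes by subsampling the majority
#'
#' Keeps all fragmented samples and an equal-size uniform random subset of
#' the non-fragmented ones.
#'
#' @param labels binary labels (1 = fragmented, assumed minority).
#' @param seed subsampling seed.
#' @return integer row indices of the balanced subset (original order).
#' @export
balance_classes <- function(labels, seed = 1L) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0)
    stop("no fragmented samples to balance against", call. = FALSE)
  if (length(neg) <= length(pos)) return(sort(c(pos, neg)))
  keep_neg <- with_seed(seed, sample(neg, length(pos)))
  sort(c(pos, keep_neg))
}
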