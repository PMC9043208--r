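# SVM + Platt classifier, splits and balancing.

sep_clouds <- function(n = 100, d = 10, gap = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, gap), n))
  colnames(X) <- paste0("f", 1:d)
  list(X = X, y = rep(c(0L, 1L), each = n))
}

test_that("all kernels separate two well-separated clouds", {
  cl <- sep_clouds()
  for (k in c("linear", "poly", "rbf")) {
    m <- fqrs_train(cl$X, cl$y, kernel = k, seed = 1)
    acc <- mean(binarize(fqrs_score(m, cl$X)) == cl$y)
    expect_gte(acc, 0.95)
  }
})

test_that("permuted labels give chance-level cross-validated AUC", {
  cl <- sep_clouds(n = 150)
  set.seed(9)
  yp <- sample(cl$y)
  m <- fqrs_train(cl$X, yp, kernel = "linear", seed = 1)
  expect_gte(max(m$cv$auc, na.rm = TRUE), 0.4)
  expect_lte(stats::median(m$cv$auc, na.rm = TRUE), 0.6)
})

test_that("rbf beats linear on XOR by a wide margin", {
  set.seed(4)
  n <- 60
  Xx <- rbind(cbind(rnorm(n, 0, .3), rnorm(n, 0, .3)),
              cbind(rnorm(n, 2, .3), rnorm(n, 2, .3)),
              cbind(rnorm(n, 0, .3), rnorm(n, 2, .3)),
              cbind(rnorm(n, 2, .3), rnorm(n, 0, .3)))
  colnames(Xx) <- c("f1", "f2")
  yx <- rep(c(0L, 0L, 1L, 1L), each = n)
  cv_acc <- function(kernel) {
    folds <- rep(1:5, length.out = length(yx))
    pred <- integer(length(yx))
    for (f in 1:5) {
      m <- fqrs_train(Xx[folds != f, ], yx[folds != f], kernel = kernel,
                      seed = 2)
      pred[folds == f] <- binarize(fqrs_score(m, Xx[folds == f, ]))
    }
    mean(pred == yx)
  }
  expect_gte(cv_acc("rbf") - cv_acc("linear"), 0.2)
})

test_that("training guards its preconditions", {
  cl <- sep_clouds()
  expect_error(fqrs_train(cl$X, rep(1L, nrow(cl$X)), kernel = "linear"),
               "both classes")
  expect_error(fqrs_train(cl$X[1:10, ], cl$y[1:10], kernel = "linear"),
               "at least 20")
  Xbad <- cl$X; Xbad[3, 2] <- NA
  expect_error(fqrs_train(Xbad, cl$y, kernel = "linear"), "non-finite")
})

test_that("scores are calibrated probabilities, monotone in the margin", {
  cl <- sep_clouds(n = 120)
  m <- fqrs_train(cl$X, cl$y, kernel = "rbf", seed = 3)
  set.seed(7)
  Xn <- matrix(rnorm(5000 * 10, 1.5, 2), 5000)
  s <- fqrs_score(m, Xn)
  expect_true(all(s >= 0 & s <= 1))
  d <- fqrs_decision(m, Xn)
  expect_identical(order(s), order(d)) # same ranking
  # deep inside the negative cloud -> low score; positive cloud -> high
  expect_lt(fqrs_score(m, matrix(0, 1, 10)), 0.5)
  expect_gt(fqrs_score(m, matrix(3, 1, 10)), 0.5)
})

test_that("scoring validates feature names and finiteness", {
  cl <- sep_clouds()
  m <- fqrs_train(cl$X, cl$y, kernel = "linear", seed = 1)
  bad <- cl$X[1:2, ]
  colnames(bad) <- paste0("g", 1:10)
  expect_error(fqrs_score(m, bad), "do not match")
  nf <- cl$X[1:2, ]
  nf[2, "f4"] <- Inf
  expect_error(fqrs_score(m, nf), "f4")
  # column order must not matter
  shuf <- cl$X[1:5, sample(10)]
  expect_equal(fqrs_score(m, shuf), fqrs_score(m, cl$X[1:5, ]))
})

test_that("hyperparameter selection is invariant to row order", {
  cl <- sep_clouds(n = 60, gap = 1.5)
  groups <- rep(1:40, length.out = nrow(cl$X))
  m1 <- fqrs_train(cl$X, cl$y, groups = groups, kernel = "linear", seed = 5)
  set.seed(31)
  perm <- sample(nrow(cl$X))
  m2 <- fqrs_train(cl$X[perm, ], cl$y[perm], groups = groups[perm],
                   kernel = "linear", seed = 5)
  expect_equal(m1$params, m2$params)
  # scores agree closely (SMO iteration order differs, so not bitwise)
  expect_lt(max(abs(fqrs_score(m1, cl$X[1:20, ]) -
                      fqrs_score(m2, cl$X[1:20, ]))), 0.05)
})

test_that("binarize uses an inclusive boundary", {
  expect_equal(binarize(c(0.51, 0.5, 0.49)), c(1L, 1L, 0L))
  expect_equal(binarize(0.3, threshold = 0.2), 1L)
  expect_error(binarize(1.4), "score")
})

test_that("splits are at recording level, disjoint and reproducible", {
  groups <- rep(sprintf("r%02d", 1:10), each = 11)
  sp <- split_by_recording(groups, 0.8, 10, seed = 4)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(intersect(groups[s$train], groups[s$test]), 0)
    expect_equal(length(unique(groups[s$train])), 8L)
    expect_equal(length(unique(groups[s$test])), 2L)
    expect_equal(sort(c(s$train, s$test)), seq_along(groups))
  }
  sp2 <- split_by_recording(groups, 0.8, 10, seed = 4)
  expect_identical(sp, sp2)
  # every recording reaches at least one test set in this seeded run
  tested <- unique(unlist(lapply(sp, function(s) groups[s$test])))
  expect_setequal(tested, unique(groups))
  expect_error(split_by_recording(rep("a", 5)), "at least 2")
})

test_that("class balancing keeps all positives plus matched negatives", {
  labels <- c(rep(1L, 30), rep(0L, 100))
  idx <- balance_classes(labels, seed = 3)
  expect_length(idx, 60)
  expect_equal(sum(labels[idx] == 1), 30)
  expect_equal(sum(labels[idx] == 0), 30)
  expect_identical(idx, balance_classes(labels, seed = 3))
  # already balanced -> unchanged
  lab2 <- rep(c(1L, 0L), 15)
  expect_identical(balance_classes(lab2, seed = 1), seq_along(lab2))
  expect_error(balance_classes(rep(0L, 10)), "no fragmented")
})

test_that("model JSON archive round trips", {
  cl <- sep_clouds()
  m <- fqrs_train(cl$X, cl$y, kernel = "rbf", seed = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_model(m, tmp)
  back <- load_model(tmp)
  expect_equal(fqrs_score(back, cl$X), fqrs_score(m, cl$X), tolerance = 1e-10)
  expect_error(load_model(tempfile()), "")
})
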