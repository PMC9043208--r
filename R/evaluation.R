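# Performance metrics: confusion-matrix rates, ROC / PR AUC, Cohen's kappa
# with a threshold sweep, and Pearson correlation against ordinal labels.

#' Sensitivity, specificity and PPV
#'
#' Undefined ratios (empty denominators) are reported as `NA`, never as 0.
#'
#' @param binary_pred predicted 0/1 labels.
#' @param labels reference 0/1 labels.
#' @return named numeric vector `(sens, spec, ppv)`.
#' @export
confusion_metrics <- function(binary_pred, labels) {
  if (length(binary_pred) != length(labels))
    stop("prediction/label length mismatch", call. = FALSE)
  tp <- sum(binary_pred == 1 & labels == 1)
  fn <- sum(binary_pred == 0 & labels == 1)
  tn <- sum(binary_pred == 0 & labels == 0)
  fp <- sum(binary_pred == 1 & labels == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sens = safe(tp, tp + fn), spec = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp))
}

# Mann-Whitney / rank formulation of the ROC AUC, tie-corrected via midranks.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC and PR areas under the curve
#'
#' ROC AUC via the rank (Mann--Whitney) formulation with midrank tie
#' correction; PR AUC as interpolation-free step summation (average
#' precision).
#'
#' @param scores continuous scores.
#' @param labels reference 0/1 labels (both classes must be present).
#' @return named numeric vector `(roc_auc, pr_auc)`.
#' @export
roc_pr_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2)
    stop("both classes required for ROC/PR curves", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  pr <- sum(prec[y == 1]) / sum(labels == 1)
  c(roc_auc = rank_auc(scores, labels), pr_auc = pr)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement. Degenerate marginals (`p_e = 1`)
#' yield `NA`.
#'
#' @param binary_pred predicted 0/1 labels.
#' @param labels reference 0/1 labels.
#' @return scalar kappa in `[-1, 1]`, or NA.
#' @export
cohen_kappa <- function(binary_pred, labels) {
  if (length(binary_pred) != length(labels))
    stop("prediction/label length mismatch", call. = FALSE)
  n <- length(labels)
  po <- mean(binary_pred == labels)
  pe <- mean(binary_pred == 1) * mean(labels == 1) +
    mean(binary_pred == 0) * mean(labels == 0)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

kappa_grid <- function(n_thresholds) {
  grid <- seq(0, 1, length.out = n_thresholds)
  # make the fixed 0.5 threshold an exact grid point
  grid[which.min(abs(grid - 0.5))] <- 0.5
  grid
}

#' Kappa threshold sweep
#'
#' Evaluates Cohen's kappa of the binarized scores at `n_thresholds`
#' uniformly spaced thresholds in `[0, 1]` (the grid point closest to 0.5 is
#' snapped to exactly 0.5, so the fixed-threshold metric is a grid case) and
#' returns the maximum; ties resolve to the lowest threshold.
#'
#' @param scores continuous scores in `[0, 1]`.
#' @param labels reference 0/1 labels.
#' @param n_thresholds grid size (100 by default).
#' @return list `(best_kappa, best_threshold, grid, kappas)`.
#' @export
kappa_sweep <- function(scores, labels, n_thresholds = 100) {
  grid <- kappa_grid(n_thresholds)
  kappas <- vapply(grid, function(th)
    cohen_kappa(binarize(scores, th), labels), numeric(1))
  best <- which.max(kappas) # ties -> lowest threshold (first index)
  list(best_kappa = kappas[best], best_threshold = grid[best],
       grid = grid, kappas = kappas)
}

#' Pearson correlation of scores against ordinal labels
#'
#' @param scores continuous scores.
#' @param ordinal_labels integer labels (0..5 observer-agreement counts).
#' @return list `(r, p, ci)` with the 95% confidence interval via Fisher's z.
#' @export
ordinal_correlation <- function(scores, ordinal_labels) {
  if (length(scores) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(ordinal_labels) == 0)
    stop("ordinal labels have zero variance", call. = FALSE)
  ct <- stats::cor.test(scores, ordinal_labels, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int))
}

#' Full metric report for one scored test set
#'
#' @param scores continuous scores in `[0, 1]`.
#' @param labels binary reference labels.
#' @param ordinal_labels optional ordinal (0..5) labels for the Pearson
#'   correlation entry.
#' @param threshold binarization threshold for the fixed-threshold metrics.
#' @param n_thresholds kappa sweep grid size.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(scores, labels, ordinal_labels = NULL,
                          threshold = 0.5, n_thresholds = 100) {
  pred <- binarize(scores, threshold)
  cm <- confusion_metrics(pred, labels)
  auc <- roc_pr_auc(scores, labels)
  sweep <- kappa_sweep(scores, labels, n_thresholds)
  rep <- list(sens = unname(cm["sens"]), spec = unname(cm["spec"]),
              ppv = unname(cm["ppv"]),
              roc_auc = unname(auc["roc_auc"]),
              pr_auc = unname(auc["pr_auc"]),
              kappa = cohen_kappa(pred, labels),
              kappa_best = sweep$best_kappa,
              kappa_best_threshold = sweep$best_threshold,
              n_pos = sum(labels == 1), n_neg = sum(labels == 0),
              pearson_r = NA_real_, pearson_p = NA_real_)
  if (!is.null(ordinal_labels)) {
    oc <- ordinal_correlation(scores, ordinal_labels)
    rep$pearson_r <- oc$r
    rep$pearson_p <- oc$p
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "sens %.3f  spec %.3f  ppv %.3f  ROC AUC %.3f  PR AUC %.3f\n",
    x$sens, x$spec, x$ppv, x$roc_auc, x$pr_auc))
  cat(sprintf("kappa@0.5 %.3f  best kappa %.3f @ %.3f  (n+ %d / n- %d)\n",
              x$kappa, x$kappa_best, x$kappa_best_threshold,
              x$n_pos, x$n_neg))
  if (is.finite(x$pearson_r))
    cat(sprintf("Pearson r vs ordinal labels %.3f (p = %.2g)\n",
                x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Write a metric report (or several) as JSON or flat CSV rows
#'
#' @param reports a `metric_report` or named list of them.
#' @param path output file (`.json` or `.csv`).
#' @export
write_metric_report <- function(reports, path) {
  if (inherits(reports, "metric_report")) reports <- list(report = reports)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    df <- do.call(rbind, lapply(names(reports), function(nm)
      cbind(data.frame(set = nm), as.data.frame(unclass(reports[[nm]])))))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
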