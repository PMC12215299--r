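#' Classification metric report
#'
#' Precision, recall, F1 and Jaccard score (per class, aggregated by the
#' chosen averaging mode), plus Hamming loss (the fraction of misclassified
#' samples) and the multiclass Matthews correlation coefficient, all computed
#' from the confusion matrix. Per-class ratios with zero denominators are set
#' to 0 with a warning.
#'
#' @param data A data frame holding the true and predicted labels.
#' @param truth,estimate Columns of `data` with the true and predicted class
#'   labels (tidy evaluation; defaults to columns named `truth` and
#'   `estimate`).
#' @param averaging `"macro"` (default), `"micro"`, or `"weighted"` (by class
#'   support).
#' @param classes Optional explicit class set; defaults to the classes seen in
#'   `truth`. A predicted label outside the class set is an error.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `hamming_loss`,
#'   `jaccard`, `mcc`, `averaging`, `n`.
#' @examples
#' df <- data.frame(truth = c(0, 1, 2), estimate = c(0, 1, 1))
#' classification_report(df)
#' @export
classification_report <- function(data, truth = truth, estimate = estimate,
                                  averaging = c("macro", "micro", "weighted"),
                                  classes = NULL) {
  averaging <- match.arg(averaging)
  y_true <- rlang::eval_tidy(rlang::enquo(truth), data)
  y_pred <- rlang::eval_tidy(rlang::enquo(estimate), data)
  if (length(y_true) != length(y_pred)) {
    stop("truth and estimate differ in length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(y_true)))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (!all(y_pred %in% classes)) {
    stop("predicted label outside the known class set", call. = FALSE)
  }
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  cm <- table(truth = ft, estimate = fp)
  n <- length(y_true)
  tp <- diag(cm)
  support <- rowSums(cm)        # true per class
  predicted <- colSums(cm)      # predicted per class
  fp_k <- predicted - tp
  fn_k <- support - tp

  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning("zero denominator in per-class ", what, "; setting to 0",
              call. = FALSE)
    }
    out <- ifelse(bad, 0, num / den)
    out
  }
  prec_k <- safe_div(tp, predicted, "precision")
  rec_k <- safe_div(tp, support, "recall")
  f1_k <- safe_div(2 * prec_k * rec_k, prec_k + rec_k, "F1")
  jac_k <- safe_div(tp, tp + fp_k + fn_k, "Jaccard")

  agg <- function(per_class, micro_num, micro_den) {
    switch(averaging,
      macro = mean(per_class),
      weighted = sum(per_class * support) / sum(support),
      micro = micro_num / micro_den
    )
  }
  total_tp <- sum(tp)
  precision <- agg(prec_k, total_tp, sum(predicted))
  recall <- agg(rec_k, total_tp, sum(support))
  f1 <- if (averaging == "micro") {
    2 * precision * recall / (precision + recall)
  } else {
    agg(f1_k, NA, NA)
  }
  jaccard <- agg(jac_k, total_tp, sum(tp + fp_k + fn_k))
  hamming <- 1 - total_tp / n

  # multiclass MCC from the confusion matrix
  s <- n
  c_sum <- total_tp
  num <- c_sum * s - sum(as.numeric(support) * as.numeric(predicted))
  den <- sqrt(s^2 - sum(as.numeric(predicted)^2)) *
    sqrt(s^2 - sum(as.numeric(support)^2))
  mcc <- if (den == 0) 0 else num / den

  tibble::tibble(
    precision = precision, recall = recall, f1 = f1,
    hamming_loss = hamming, jaccard = jaccard, mcc = mcc,
    averaging = averaging, n = n
  )
}

#' Regression metric report
#'
#' MAE, MSE, RMSE, R-squared, RMSLE and SMAPE from their definitions. SMAPE is
#' the symmetric 0-200% form, reported in percent, with `0/0` terms defined as
#' 0. RMSLE requires every value to exceed -1; R-squared requires non-constant
#' truth and is `NA` (with a warning) for a single pair.
#'
#' @param data A data frame holding the true and predicted values.
#' @param truth,estimate Numeric columns of `data` (tidy evaluation; defaults
#'   to columns named `truth` and `estimate`).
#' @return A one-row tibble: `mae`, `mse`, `rmse`, `r2`, `rmsle`,
#'   `smape_pct`, `n`.
#' @examples
#' regression_report(data.frame(truth = c(1, 2, 3), estimate = c(1.1, 1.9, 3.2)))
#' @export
regression_report <- function(data, truth = truth, estimate = estimate) {
  y <- as.numeric(rlang::eval_tidy(rlang::enquo(truth), data))
  p <- as.numeric(rlang::eval_tidy(rlang::enquo(estimate), data))
  if (length(y) != length(p)) {
    stop("truth and estimate differ in length", call. = FALSE)
  }
  n <- length(y)
  if (n < 1) stop("no value pairs supplied", call. = FALSE)
  e <- p - y
  mae <- mean(abs(e))
  mse <- mean(e^2)
  rmse <- sqrt(mse)
  if (n < 2) {
    warning("R-squared needs at least 2 pairs; reporting NA", call. = FALSE)
    r2 <- NA_real_
  } else {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      stop("truth values are constant: R-squared is undefined", call. = FALSE)
    }
    r2 <- 1 - sum(e^2) / sst
  }
  if (any(y <= -1) || any(p <= -1)) {
    stop("RMSLE requires all values > -1", call. = FALSE)
  }
  rmsle <- sqrt(mean((log1p(p) - log1p(y))^2))
  denom <- abs(p) + abs(y)
  terms <- ifelse(denom == 0, 0, 2 * abs(e) / denom)
  smape <- 100 * mean(terms)
  tibble::tibble(mae = mae, mse = mse, rmse = rmse, r2 = r2,
                 rmsle = rmsle, smape_pct = smape, n = n)
}
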