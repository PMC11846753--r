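# Erosion prediction framework: enumerate 1-3 predictor logistic models,
# screen out correlated multi-predictor models, evaluate each by
# leave-one-out AUC, and wrap the procedure in bootstrap replicates for
# AUC averages, 90% percentile confidence intervals and cumulated ROC
# curves.

#' Enumerate candidate predictor subsets
#'
#' All subsets of size 1..`max_size` of the named predictors. With
#' `correlation_screen = TRUE`, multi-predictor subsets containing any
#' pair with Pearson correlation p < 0.05 (computed once on the full
#' table) are dropped; single-predictor models are never screened.
#'
#' @param table Predictor table (one row per patient).
#' @param predictors Predictor names; default [erosion_predictors()]
#'   intersected with the table is NOT used - missing predictors are an
#'   error naming them.
#' @param max_size Largest subset size (default 3).
#' @param correlation_screen Apply the Pearson screening rule.
#' @param alpha Screening significance level (default 0.05).
#' @return List of character vectors (model specs).
#' @export
enumerate_models <- function(table, predictors = erosion_predictors(),
                             max_size = 3, correlation_screen = FALSE,
                             alpha = 0.05) {
  missing <- setdiff(predictors, names(table))
  if (length(missing)) {
    stop(sprintf("predictors missing from table: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  specs <- unlist(lapply(seq_len(max_size), function(k) {
    utils::combn(predictors, k, simplify = FALSE)
  }), recursive = FALSE)
  if (!correlation_screen) return(specs)

  p <- length(predictors)
  cor_p <- matrix(1, p, p, dimnames = list(predictors, predictors))
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      ct <- stats::cor.test(table[[predictors[i]]], table[[predictors[j]]])
      cor_p[i, j] <- cor_p[j, i] <- ct$p.value
    }
  }
  keep <- vapply(specs, function(s) {
    if (length(s) == 1) return(TRUE)
    pairs <- utils::combn(s, 2)
    all(cor_p[cbind(pairs[1, ], pairs[2, ])] >= alpha)
  }, logical(1))
  specs[keep]
}

label_to_binary <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) return(as.integer(label != 0))
  as.integer(label == "erosion")
}

#' Fit a ridge-stabilized logistic regression
#'
#' Predictors are standardized with the training-set mean and SD, and the
#' maximum-likelihood fit runs iteratively reweighted least squares with a
#' small ridge penalty (`lambda`, default 1e-4, not applied to the
#' intercept) so that complete separation - inevitable at n = 16 - still
#' converges deterministically.
#'
#' @param table Predictor table with a `label` column.
#' @param spec Character vector of predictor names (1-3).
#' @param lambda Ridge penalty on standardized coefficients.
#' @param max_iter,tol IRLS controls.
#' @return An object of class `erosion_logit`.
#' @export
fit_logistic <- function(table, spec, lambda = 1e-4, max_iter = 50, tol = 1e-10) {
  y <- label_to_binary(table$label)
  if (length(unique(y)) < 2) stop("training set has a single class", call. = FALSE)
  X_raw <- as.matrix(table[spec])
  centers <- colMeans(X_raw)
  scales <- apply(X_raw, 2, stats::sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  X <- cbind(1, sweep(sweep(X_raw, 2, centers), 2, scales, "/"))
  k <- ncol(X)
  beta <- numeric(k)
  pen <- diag(c(0, rep(lambda, k - 1)), k)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  structure(
    list(spec = spec, coefficients = stats::setNames(drop(beta), c("(Intercept)", spec)),
         centers = centers, scales = scales, lambda = lambda,
         n = length(y), n_pos = sum(y)),
    class = "erosion_logit"
  )
}

#' @export
predict.erosion_logit <- function(object, newdata, type = "response", ...) {
  X_raw <- as.matrix(newdata[object$spec])
  X <- cbind(1, sweep(sweep(X_raw, 2, object$centers), 2, object$scales, "/"))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.erosion_logit <- function(x, ...) {
  cat(sprintf("<erosion_logit> %s (n = %d, ridge %.1e)\n",
              paste(x$spec, collapse = " + "), x$n, x$lambda))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy erosion_logit
#' @export
tidy.erosion_logit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance erosion_logit
#' @export
glance.erosion_logit <- function(x, ...) {
  tibble::tibble(n = x$n, n_pos = x$n_pos, n_predictors = length(x$spec),
                 lambda = x$lambda)
}

#' Leave-one-out out-of-sample probabilities
#'
#' The i-th probability comes from a model never trained on row i. Folds
#' whose training set holds a single class fall back to the training
#' prevalence (flagged in the `degenerate` attribute).
#'
#' Because each held-out patient is scored by a different model, raw
#' probabilities are not rank-comparable across folds: leaving out a
#' positive lowers that fold's training prevalence, which systematically
#' depresses the held-out positive's probability and biases the
#' cross-validated AUC below 0.5 for weak predictors. The `scores`
#' attribute therefore carries the fold-comparable ranking score
#' `logit(p_i) - logit(training-fold prevalence)`, which removes the
#' prevalence shift while staying strictly out-of-sample; [auc()] on
#' these scores is calibrated to 0.5 under label permutation.
#'
#' @param table Predictor table with `label`.
#' @param spec Predictor subset.
#' @param lambda Ridge penalty, as [fit_logistic()].
#' @return Numeric vector of n out-of-sample probabilities, with
#'   attributes `scores` (prevalence-centered logit scores) and
#'   `degenerate` (single-class training folds, scored 0).
#' @export
loo_predict <- function(table, spec, lambda = 1e-4) {
  n <- nrow(table)
  if (n < 3) stop("leave-one-out needs n >= 3", call. = FALSE)
  y <- label_to_binary(table$label)
  probs <- numeric(n)
  scores <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    y_train <- y[-i]
    if (length(unique(y_train)) < 2) {
      probs[i] <- mean(y_train)
      scores[i] <- 0
      degenerate[i] <- TRUE
      next
    }
    fit <- fit_logistic(table[-i, , drop = FALSE], spec, lambda = lambda)
    eta <- predict(fit, table[i, , drop = FALSE], type = "link")
    probs[i] <- stats::plogis(eta)
    scores[i] <- eta - stats::qlogis(mean(y_train))
  }
  attr(probs, "scores") <- scores
  attr(probs, "degenerate") <- degenerate
  probs
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Concordant positive/negative pairs plus half ties over all pairs;
#' computed via midranks, which is algebraically the same count.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (1/TRUE/"erosion" = positive).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  y <- label_to_binary(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined with a single class", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores,labels As [auc()].
#' @return Tibble with `threshold`, `fpr`, `tpr`, monotone nondecreasing.
#' @export
roc_points <- function(scores, labels) {
  y <- label_to_binary(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  thr <- unique(s)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  cum_tp <- cumsum(y == 1); cum_fp <- cumsum(y == 0)
  last_of_thr <- cumsum(rle(s)$lengths)
  tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, cum_tp[last_of_thr] / n_pos),
    fpr = c(0, cum_fp[last_of_thr] / n_neg)
  )
}

#' Bootstrap evaluation of one model
#'
#' Each replicate draws n patients with replacement (redrawn until both
#' classes are present), runs leave-one-out prediction within the
#' replicate and computes the replicate AUC from the fold-comparable
#' centered scores (see [loo_predict()]). Reports the AUC average, the
#' 5th/95th percentile 90% confidence interval, the per-replicate AUCs
#' and the ROC of the cumulated (score, label) pairs across replicates.
#'
#' @param table Predictor table with `label`.
#' @param spec Predictor subset.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param resamples Optional list of precomputed row-index vectors (used
#'   by [rank_models()] to share resamples across models).
#' @param lambda Ridge penalty.
#' @return An object of class `erosion_prediction`.
#' @export
bootstrap_evaluate <- function(table, spec, n_boot = 100, seed = 1,
                               resamples = NULL, lambda = 1e-4) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  y_all <- label_to_binary(table$label)
  if (length(unique(y_all)) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(resamples)) {
    resamples <- draw_resamples(nrow(table), y_all, n_boot, seed)
  }
  aucs <- numeric(length(resamples))
  pooled_scores <- vector("list", length(resamples))
  pooled_labels <- vector("list", length(resamples))
  for (b in seq_along(resamples)) {
    idx <- resamples[[b]]
    rep_table <- table[idx, , drop = FALSE]
    probs <- loo_predict(rep_table, spec, lambda = lambda)
    sc <- attr(probs, "scores")
    aucs[b] <- auc(sc, rep_table$label)
    pooled_scores[[b]] <- sc
    pooled_labels[[b]] <- label_to_binary(rep_table$label)
  }
  scores <- unlist(pooled_scores)
  labels <- unlist(pooled_labels)
  structure(
    list(spec = spec,
         auc_average = mean(aucs),
         ci90 = stats::quantile(aucs, c(0.05, 0.95), names = FALSE),
         replicate_aucs = aucs,
         roc = roc_points(scores, labels),
         cumulated_auc = auc(scores, labels),
         n = nrow(table), n_boot = length(resamples), seed = seed),
    class = "erosion_prediction"
  )
}

# bootstrap row resamples; replicates with a single class are redrawn
draw_resamples <- function(n, y, n_boot, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  redraws <- 0L
  out <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      redraws <- redraws + 1L
    }
    out[[b]] <- idx
  }
  attr(out, "redraws") <- redraws
  out
}

#' @export
print.erosion_prediction <- function(x, ...) {
  cat(sprintf("<erosion_prediction> %s\n  AUC average %.3f, 90%% CI (%.3f, %.3f) over %d bootstrap replicates\n",
              paste(x$spec, collapse = " + "), x$auc_average, x$ci90[1], x$ci90[2], x$n_boot))
  invisible(x)
}

#' @method tidy erosion_prediction
#' @export
tidy.erosion_prediction <- function(x, ...) {
  tibble::tibble(model = paste(x$spec, collapse = " + "),
                 n_predictors = length(x$spec),
                 auc_average = x$auc_average,
                 ci_low = x$ci90[1], ci_high = x$ci90[2])
}

#' @method glance erosion_prediction
#' @export
glance.erosion_prediction <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, seed = x$seed,
                 cumulated_auc = x$cumulated_auc)
}

#' Rank candidate models by bootstrap AUC
#'
#' Evaluates every spec on the same bootstrap resamples (fair comparison)
#' and sorts by AUC average descending, ties broken by smaller subset
#' then lexicographic predictor names.
#'
#' @param table Predictor table with `label`.
#' @param specs List of predictor subsets, as [enumerate_models()].
#' @param n_boot,seed,lambda As [bootstrap_evaluate()].
#' @return Tibble (one row per model, sorted) with a `result` list-column
#'   of `erosion_prediction` objects.
#' @export
rank_models <- function(table, specs, n_boot = 100, seed = 1, lambda = 1e-4) {
  stopifnot(length(specs) >= 1)
  y_all <- label_to_binary(table$label)
  resamples <- draw_resamples(nrow(table), y_all, n_boot, seed)
  results <- purrr::map(specs, function(s) {
    bootstrap_evaluate(table, s, n_boot = n_boot, seed = seed,
                       resamples = resamples, lambda = lambda)
  })
  out <- purrr::map_dfr(results, tidy)
  out$result <- results
  key <- paste(vapply(specs, paste, character(1), collapse = " "))
  ord <- order(-out$auc_average, out$n_predictors, key)
  out[ord, ]
}
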