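#' Fit per-gene class-conditional Gaussian models
#'
#' For every gene the expression values are modelled, conditional on the
#' biological sample label y, as Gaussian with class means `mu0`, `mu1` and
#' a common standard deviation `sigma` (pooled maximum-likelihood estimate,
#' denominator N).  The dual logistic representation of the Bayes posterior
#' P(y = 1 | x) = logistic(w x + b) is derived from the same parameters:
#' `w = (mu1 - mu0) / sigma^2` and
#' `b = (mu0^2 - mu1^2) / (2 sigma^2) + log(prior1 / (1 - prior1))`.
#'
#' @param es an [expression_set()].
#' @param subset optional character vector of gene ids to fit (default all).
#' @param sigma_floor lower bound for `sigma` (default `1e-6`); guards
#'   constant genes against zero variance.
#' @return A data frame of class `hyb_gene_models` with one row per gene:
#'   `gene_id`, `mu0`, `mu1`, `sigma`, `prior1`, `w`, `b`.
#' @export
fit_gene_models <- function(es, subset = NULL, sigma_floor = 1e-6) {
  validate_expression_set(es)
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop("gene subset is empty", call. = FALSE)
    es <- subset_genes(es, subset)
  }
  v <- es$values
  y <- es$obs$y
  n <- ncol(v)
  mu0 <- rowMeans(v[, y == 0L, drop = FALSE])
  mu1 <- rowMeans(v[, y == 1L, drop = FALSE])
  fitted <- outer(mu0, as.numeric(y == 0L)) + outer(mu1, as.numeric(y == 1L))
  sigma <- pmax(sqrt(rowSums((v - fitted)^2) / n), sigma_floor)
  prior1 <- mean(y == 1L)
  w <- (mu1 - mu0) / sigma^2
  b <- (mu0^2 - mu1^2) / (2 * sigma^2) + log(prior1 / (1 - prior1))
  out <- data.frame(gene_id = es$gene_ids, mu0 = mu0, mu1 = mu1,
                    sigma = sigma, prior1 = prior1, w = w, b = b,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hyb_gene_models", "data.frame")
  out
}

## internal: align models to an expression set, error on mismatch
align_models <- function(es, models) {
  idx <- match(es$gene_ids, models$gene_id)
  if (anyNA(idx))
    stop("models are missing gene(s): ",
         paste(es$gene_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  models[idx, , drop = FALSE]
}

#' Gaussian-model log-likelihood of an experiment
#'
#' Sum over genes and observations of the log Gaussian density of each
#' expression value under its gene's class-conditional model, i.e. the
#' log-likelihood of the per-gene linear (ANOVA-type) model of the whole
#' experiment, in nats.
#'
#' @param es an [expression_set()].
#' @param models a [fit_gene_models()] result covering the genes of `es`.
#' @return A single number (nats).
#' @export
loglik_linear <- function(es, models) {
  validate_expression_set(es)
  models <- align_models(es, models)
  y <- es$obs$y
  mu <- outer(models$mu0, as.numeric(y == 0L)) +
    outer(models$mu1, as.numeric(y == 1L))
  sum(stats::dnorm(es$values, mean = mu, sd = models$sigma, log = TRUE))
}

#' Naive-Bayes posterior probability of sample label 1
#'
#' The logistic dual of the class-conditional Gaussian model:
#' `P(y = 1 | x) = logistic(w x + b)`, clipped to `[eps, 1 - eps]`.
#'
#' @param x numeric vector of expression values.
#' @param model a single-row [fit_gene_models()] result (or any list with
#'   elements `w` and `b`).
#' @param eps clipping bound (default `1e-6`); set to 0 for the exact
#'   logistic value.
#' @return Posterior probabilities in `[eps, 1 - eps]`.
#' @export
nb_posterior <- function(x, model, eps = 1e-6) {
  p <- stats::plogis(model$w * x + model$b)
  pmin(pmax(p, eps), 1 - eps)
}

## internal: posterior matrix P(y=1 | x_gn) for all genes x observations
posterior_matrix <- function(values, models, eps = 1e-6) {
  p <- stats::plogis(values * models$w + models$b)  # recycles along rows
  pmin(pmax(p, eps), 1 - eps)
}

#' Naive-Bayes log-likelihood of the sample labels
#'
#' Sum over genes and observations of the log posterior probability of the
#' observed sample label, `sum log P(y_n | x_gn)`, with posteriors from
#' [nb_posterior()].  This is the naive-Bayes classifier likelihood up to a
#' label-independent additive constant, which is omitted because it cancels
#' in any protocol comparison.  Always `<= 0`.
#'
#' @inheritParams loglik_linear
#' @param eps posterior clipping bound passed to [nb_posterior()].
#' @return A single non-positive number (nats).
#' @export
loglik_nb <- function(es, models, eps = 1e-6) {
  validate_expression_set(es)
  models <- align_models(es, models)
  p1 <- posterior_matrix(es$values, models, eps)
  y1 <- es$obs$y == 1L
  sum(log(p1[, y1])) + sum(log1p(-p1[, !y1, drop = FALSE]))
}

#' Leave-slides-out cross-testing of the per-gene classifiers
#'
#' Splits the experiment into folds of whole slides (both channel
#' observations of a slide stay together, preventing leakage), fits the
#' per-gene models on the remaining slides and evaluates the naive-Bayes
#' posterior on the held-out observations.  With `folds = "loo"` each slide
#' forms its own fold, so every slide is used exactly once as the
#' independent test sample.
#'
#' @param es an [expression_set()].
#' @param folds `"loo"` or an integer number of folds (at most the number
#'   of slides); slides are assigned to folds in contiguous blocks, so the
#'   result is deterministic.
#' @param sigma_floor,eps passed to [fit_gene_models()] / [nb_posterior()].
#' @return An object of class `hyb_xtest`: list with `posterior` (genes x
#'   observations matrix of held-out P(y = 1 | x)), `y`, `gene_ids`,
#'   `fold` (per observation), `prior1` (training-fold prior per
#'   observation) and `eps`.
#' @export
cross_test <- function(es, folds = "loo", sigma_floor = 1e-6, eps = 1e-6) {
  validate_expression_set(es)
  slides <- unique(es$obs$slide)
  n_folds <- if (identical(folds, "loo")) length(slides) else as.integer(folds)
  if (n_folds < 2L || n_folds > length(slides))
    stop("'folds' must be \"loo\" or an integer in [2, number of slides]",
         call. = FALSE)
  fold_of_slide <- as.integer(cut(seq_along(slides), n_folds))
  names(fold_of_slide) <- slides
  fold_of_obs <- fold_of_slide[es$obs$slide]
  post <- matrix(NA_real_, nrow(es$values), ncol(es$values),
                 dimnames = dimnames(es$values))
  prior1 <- numeric(ncol(es$values))
  for (f in seq_len(n_folds)) {
    test <- which(fold_of_obs == f)
    train <- which(fold_of_obs != f)
    if (length(unique(es$obs$slide[train])) < 2L)
      stop("fewer than 2 slides left for training in fold ", f,
           call. = FALSE)
    models <- fit_gene_models(subset_obs(es, train),
                              sigma_floor = sigma_floor)
    post[, test] <- posterior_matrix(es$values[, test, drop = FALSE],
                                     models, eps)
    prior1[test] <- models$prior1[1L]
  }
  structure(list(posterior = post, y = es$obs$y, gene_ids = es$gene_ids,
                 fold = unname(fold_of_obs), prior1 = prior1, eps = eps),
            class = "hyb_xtest")
}

#' Generalization accuracy of the cross-tested classifiers
#'
#' Percentage of correct held-out sample-label predictions, averaged over
#' all genes and test observations.  An observation is predicted as label 1
#' when its posterior exceeds 0.5; a posterior of exactly 0.5 predicts
#' label 0 (deterministic tie rule), so an uninformative balanced
#' experiment scores exactly 50.
#'
#' @param ct a [cross_test()] result.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
generalization_accuracy <- function(ct) {
  stopifnot(inherits(ct, "hyb_xtest"))
  pred1 <- ct$posterior > 0.5
  correct <- sweep(pred1, 2L, ct$y == 1L, "==")
  100 * mean(correct)
}

#' Gene-averaged ROC curve and mean AUC
#'
#' Computes, for each gene, the ROC curve of its held-out posteriors
#' against the true sample labels (threshold enumeration; tied scores give
#' diagonal segments) and the area under it (trapezoid rule, equivalent to
#' the rank statistic with ties counted 1/2).  The summary curve is the
#' vertical average of the per-gene true-positive rates on a fixed
#' false-positive-rate grid; it passes through (0,0) and (1,1).
#'
#' @param ct a [cross_test()] result.
#' @param grid_points number of points of the FPR grid (default 101).
#' @return List with `curve` (data frame `fpr`, `tpr`), `mean_auc`, and
#'   `auc` (named per-gene AUCs).
#' @export
roc_summary <- function(ct, grid_points = 101L) {
  stopifnot(inherits(ct, "hyb_xtest"))
  y <- ct$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("both classes must be present in the test labels", call. = FALSE)
  grid <- seq(0, 1, length.out = grid_points)
  aucs <- numeric(nrow(ct$posterior))
  tpr_grid <- matrix(NA_real_, nrow(ct$posterior), grid_points)
  for (g in seq_len(nrow(ct$posterior))) {
    s <- ct$posterior[g, ]
    r <- rank(s)
    aucs[g] <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ## curve points: one per tie group of descending scores
    ord <- order(s, decreasing = TRUE)
    ys <- y[ord]; ss <- s[ord]
    grp_end <- cumsum(rle(ss)$lengths)
    tp <- cumsum(ys == 1L)[grp_end] / n1
    fp <- cumsum(ys == 0L)[grp_end] / n0
    ## collapse vertical segments: keep the max TPR per distinct FPR
    keep <- !duplicated(fp, fromLast = TRUE)
    fp <- fp[keep]; tp <- tp[keep]
    if (fp[1L] > 0) { fp <- c(0, fp); tp <- c(0, tp) }
    tpr_grid[g, ] <- stats::approx(fp, tp, xout = grid, method = "linear",
                                   rule = 2)$y
  }
  names(aucs) <- ct$gene_ids
  curve <- data.frame(fpr = grid, tpr = colMeans(tpr_grid))
  curve$tpr[1L] <- 0; curve$tpr[grid_points] <- 1
  list(curve = curve, mean_auc = mean(aucs), auc = aucs)
}

#' Mutual-information bit rate of the cross-tested classifiers
#'
#' Finite-sample estimate of the average information (in bits per gene)
#' that the expression measurements carry about the sample label: per gene
#' the mean over held-out observations of
#' `log2(P(y_n | x_gn) / P(y_n))`, with the label prior taken from the
#' training fold, then averaged over genes.  The estimate may be slightly
#' negative for uninformative genes and is deliberately not clipped.
#'
#' @param ct a [cross_test()] result.
#' @param per_gene if `TRUE` return the per-gene bit rates instead of their
#'   mean.
#' @return Mean bit rate (or named per-gene vector).
#' @export
mutual_information <- function(ct, per_gene = FALSE) {
  stopifnot(inherits(ct, "hyb_xtest"))
  y1 <- ct$y == 1L
  p_lab <- ct$posterior
  p_lab[, !y1] <- 1 - p_lab[, !y1, drop = FALSE]
  prior_lab <- ifelse(y1, ct$prior1, 1 - ct$prior1)
  bits <- sweep(log2(p_lab), 2L, log2(prior_lab), "-")
  gene_bits <- rowMeans(bits)
  names(gene_bits) <- ct$gene_ids
  if (per_gene) gene_bits else mean(gene_bits)
}

#' Score competing hybridization protocols
#'
#' Computes the joint quality measures for each protocol's experiment on a
#' common gene subset: the Gaussian-model and naive-Bayes log-likelihoods
#' at the maximum-likelihood fit, and the model-free cross-tested measures
#' (generalization accuracy, mean AUC, mutual-information bit rate).
#' Optionally also the number of significant differentially expressed genes
#' at a BH-FDR cutoff.
#'
#' @param es_list named list of [expression_set()] objects, one per
#'   protocol; all must share gene ids and design shape.  Unnamed lists use
#'   each experiment's protocol label.
#' @param subset optional character vector of gene ids scored (default all).
#' @param folds passed to [cross_test()].
#' @param fdr_cutoff if non-`NULL`, a dye-swap t test with BH correction is
#'   run per protocol and `n_sig` at this q cutoff is reported.
#' @param sigma_floor,eps numerical guards, see [fit_gene_models()].
#' @return Data frame with one row per protocol: `protocol`,
#'   `loglik_linear`, `loglik_nb`, `accuracy_pct`, `mean_auc`, `bitrate`,
#'   `n_sig`, `subset`.
#' @export
score_protocol <- function(es_list, subset = NULL, folds = "loo",
                           fdr_cutoff = NULL, sigma_floor = 1e-6,
                           eps = 1e-6) {
  stopifnot(is.list(es_list), length(es_list) >= 1L)
  if (is.null(names(es_list)))
    names(es_list) <- vapply(es_list, function(e) e$obs$protocol[1L], "")
  ids <- es_list[[1L]]$gene_ids
  for (e in es_list)
    if (!identical(e$gene_ids, ids))
      stop("protocols do not share the same gene ids", call. = FALSE)
  sub_desc <- if (is.null(subset)) "all_genes" else
    sprintf("subset_%d_genes", length(subset))
  rows <- lapply(names(es_list), function(k) {
    es <- es_list[[k]]
    if (!is.null(subset)) es <- subset_genes(es, subset)
    models <- fit_gene_models(es, sigma_floor = sigma_floor)
    ct <- cross_test(es, folds = folds, sigma_floor = sigma_floor,
                     eps = eps)
    n_sig <- NA_integer_
    if (!is.null(fdr_cutoff)) {
      de <- de_test(dye_swap_log_ratios(es))
      n_sig <- count_significant(de, fdr_cutoff)
    }
    data.frame(protocol = k,
               loglik_linear = loglik_linear(es, models),
               loglik_nb = loglik_nb(es, models, eps = eps),
               accuracy_pct = generalization_accuracy(ct),
               mean_auc = roc_summary(ct)$mean_auc,
               bitrate = mutual_information(ct),
               n_sig = n_sig, subset = sub_desc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a protocol score report
#'
#' Writes the [score_protocol()] table as TSV.
#'
#' @param scores a [score_protocol()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
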