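# Ridge-regression genome-wide prediction (rrBLUP / GBLUP) and the
# cross-validation designs used to benchmark it: random k-fold CV,
# training-size and marker-count sweeps, marker-selection strategies, and
# across-subpopulation validation with matched random baselines.

#' Fit a ridge-regression BLUP model
#'
#' Whole-genome regression `y = mu + Z alpha + e` with a common marker
#' effect variance: `alpha ~ N(0, sigma2_m I)`. The shrinkage parameter
#' `lambda = sigma2_e / sigma2_m` is estimated by spectral REML on the
#' equivalent individual-level model (covariance `Z Z'`), and the marker
#' effects solve the mixed-model equations
#' `alpha = Z' (Z Z' + lambda I)^{-1} (y - mu)`. Markers are centered by
#' their training means; missing calls are mean-imputed.
#'
#' @param y Training response: a [estimate_blups()] result, `(genotype_id,
#'   blup)` data frame, or named numeric vector.
#' @param gt A [genotype_table()] covering the training individuals.
#' @param lambda Optional fixed shrinkage parameter (REML when `NULL`).
#' @return An object of class `ridge_model` with `effects` (named by
#'   locus), `intercept`, `lambda`, `sigma2_m`, `sigma2_e`, `center` (the
#'   training locus means) and `train_ids`.
#' @export
fit_ridge_blup <- function(y, gt, lambda = NULL) {
  al <- align_response(y, gt = gt)
  n <- length(al$y)
  if (n < 10) stop("need at least 10 training individuals", call. = FALSE)
  if (stats::sd(al$y) == 0) stop("training response has zero variance", call. = FALSE)
  sub <- gt[al$ids, ]
  X <- impute_mean(sub)
  center <- colMeans(X)
  Z <- sweep(X, 2, center)
  K <- tcrossprod(Z)
  ones <- matrix(1, n, 1)
  if (is.null(lambda)) {
    fit <- reml_mixed(al$y, ones, K)
    lambda <- fit$delta
    sigma2_m <- fit$sigma2_g
    sigma2_e <- fit$sigma2_e
  } else {
    if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
    sigma2_m <- sigma2_e <- NA_real_
  }
  ek <- eigen(K, symmetric = TRUE)
  rot <- gls_rotate(al$y, ones, ek, lambda)
  mu <- drop(rot$beta)
  r <- al$y - mu
  Vinv_r <- ek$vectors %*% (crossprod(ek$vectors, r) /
                              (pmax(ek$values, 0) + lambda))
  alpha <- drop(crossprod(Z, Vinv_r))
  names(alpha) <- sub$loci$locus_id
  structure(
    list(effects = alpha, intercept = mu, lambda = lambda,
         sigma2_m = sigma2_m, sigma2_e = sigma2_e,
         center = center, train_ids = al$ids,
         marker_ids = sub$loci$locus_id),
    class = "ridge_model"
  )
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d markers, %d training individuals\n",
              length(x$effects), length(x$train_ids)))
  cat(sprintf("  lambda = %.4g (sigma2_m = %.4g, sigma2_e = %.4g)\n",
              x$lambda, x$sigma2_m, x$sigma2_e))
  invisible(x)
}

#' Predict genomic values with a fitted ridge model
#'
#' @param object A [fit_ridge_blup()] model.
#' @param gt A [genotype_table()] containing the model's markers. Missing
#'   calls and centering both use the training locus means.
#' @param ... Unused.
#' @return Named numeric vector of predicted values.
#' @export
predict.ridge_model <- function(object, gt, ...) {
  j <- match(object$marker_ids, gt$loci$locus_id)
  if (anyNA(j)) stop("genotypes lack markers used in the model", call. = FALSE)
  X <- gt$dosage[, j, drop = FALSE]
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- object$center[idx[, 2]]
  Z <- sweep(X, 2, object$center)
  stats::setNames(drop(object$intercept + Z %*% object$effects),
                  gt$individual_ids)
}

#' Tidy / summarize a ridge model
#' @param x A `ridge_model`.
#' @param ... Unused.
#' @return `tidy()`: tibble of per-marker effects; `glance()`: one-row
#'   tibble of shrinkage and variance components.
#' @export
tidy.ridge_model <- function(x, ...) {
  tibble::tibble(locus_id = names(x$effects), effect = unname(x$effects))
}

#' @rdname tidy.ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  tibble::tibble(n_markers = length(x$effects),
                 n_train = length(x$train_ids), lambda = x$lambda,
                 sigma2_m = x$sigma2_m, sigma2_e = x$sigma2_e)
}

#' Prediction accuracy from predictive ability
#'
#' Rescales the predictive ability `r` (correlation between observed and
#' predicted BLUPs) by the ceiling imposed by trait repeatability:
#' `Accu = r / sqrt(H2)`.
#'
#' @param r Predictive ability.
#' @param h2 Broad-sense heritability in `(0, 1]`.
#' @return Accuracy on the correlation scale.
#' @export
accuracy <- function(r, h2) {
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]", call. = FALSE)
  r / sqrt(h2)
}

# GBLUP engine used by the cross-validation designs: predictions from the
# individual-level equivalent model, with the marker cross-product P =
# X X' precomputed once so each fold only pays O(n^2) for centering.
# Algebraically identical to predicting from fit_ridge_blup()'s marker
# effects (the rrBLUP/GBLUP duality).
gblup_fold <- function(y, X_imp, P, train, test) {
  c_tr <- colMeans(X_imp[train, , drop = FALSE])
  Xc <- drop(X_imp %*% c_tr)
  cc <- sum(c_tr^2)
  Kc <- P - outer(Xc, rep(1, length(Xc))) -
    outer(rep(1, length(Xc)), Xc) + cc
  K_tr <- Kc[train, train]
  ones <- matrix(1, length(train), 1)
  fit <- reml_mixed(y[train], ones, K_tr)
  ek <- eigen(K_tr, symmetric = TRUE)
  rot <- gls_rotate(y[train], ones, ek, fit$delta)
  mu <- drop(rot$beta)
  Vinv_r <- ek$vectors %*% (crossprod(ek$vectors, y[train] - mu) /
                              (pmax(ek$values, 0) + fit$delta))
  pred <- mu + drop(Kc[test, train, drop = FALSE] %*% Vinv_r)
  list(pred = pred, delta = fit$delta)
}

cv_metrics <- function(obs, pred, fold = NULL) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(c(r = NA_real_, b0 = NA_real_, b1 = NA_real_))
  }
  # predictive ability: pooled correlation after within-fold centering, so
  # that fold-to-fold intercept jitter (pronounced under heavy shrinkage)
  # does not masquerade as (anti-)signal
  if (is.null(fold)) {
    oc <- obs - mean(obs)
    pc <- pred - mean(pred)
  } else {
    oc <- obs - stats::ave(obs, fold)
    pc <- pred - stats::ave(pred, fold)
  }
  r <- if (stats::sd(pc) == 0) NA_real_ else stats::cor(oc, pc)
  # calibration is assessed on the raw scale
  b1 <- stats::cov(obs, pred) / stats::var(pred)
  b0 <- mean(obs) - b1 * mean(pred)
  c(r = r, b0 = b0, b1 = b1)
}

stratified_folds <- function(ids, folds, strata = NULL) {
  n <- length(ids)
  assign <- integer(n)
  if (is.null(strata)) strata <- rep("all", n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    assign[idx] <- sample(rep_len(sample(folds), length(idx)))
  }
  assign
}

#' Random k-fold cross-validation of genome-wide prediction
#'
#' Individuals are partitioned into `folds` folds (stratified by
#' subpopulation when labels are available and `stratify = TRUE`); for each
#' fold a ridge/GBLUP model is fitted on the remaining individuals only —
#' shrinkage re-estimated, markers re-centered, and any informed marker
#' selection re-run within the training set — and the held-out individuals
#' are predicted. Each repeat pools the held-out predictions and records
#' the predictive ability `r = cor(observed, predicted)`, the accuracy
#' `r / sqrt(H2)`, and the calibration intercept/slope of
#' `observed ~ predicted`.
#'
#' @param blups A [estimate_blups()] result (its `H2` feeds the accuracy),
#'   or a named vector/data frame plus an explicit `h2`.
#' @param gt A [genotype_table()].
#' @param folds Number of folds (2 to n); training fraction is
#'   `(folds - 1) / folds`.
#' @param repeats Number of random repetitions.
#' @param n_markers Optional marker-subset size per training fold.
#' @param marker_strategy `"random"`, `"gwas_p"` or `"effect_size"`
#'   (see [select_markers()]).
#' @param h2 Broad-sense heritability override.
#' @param stratify Stratify folds by the table's subpopulation labels.
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @return An object of class `cv_result`; `tidy()` gives per-repeat rows,
#'   `glance()` the mean/SD summary.
#' @export
cross_validate <- function(blups, gt, folds = 10, repeats = 100,
                           n_markers = NULL, marker_strategy = "random",
                           h2 = NULL, stratify = TRUE, seed = 1) {
  al <- align_response(blups, gt = gt)
  n <- length(al$y)
  if (folds < 2 || folds > n) stop("fold count must be between 2 and n", call. = FALSE)
  if (is.null(h2) && inherits(blups, "trait_blups")) h2 <- blups$h2
  sub <- gt[al$ids, ]
  X_imp <- impute_mean(sub)
  strata <- if (stratify && !is.null(sub$subpop)) sub$subpop else NULL
  full_P <- if (is.null(n_markers)) tcrossprod(X_imp) else NULL

  reps <- purrr::map_dfr(seq_len(repeats), function(rep_i) {
    with_seed(seed + rep_i * 1000L, {
      fold_of <- stratified_folds(al$ids, folds, strata)
      pred <- rep(NA_real_, n)
      for (f in seq_len(folds)) {
        test <- which(fold_of == f)
        train <- which(fold_of != f)
        if (length(test) == 0) next
        if (is.null(n_markers)) {
          pred[test] <- gblup_fold(al$y, X_imp, full_P, train, test)$pred
        } else {
          sel <- select_markers(sub[train, ], al$y[train],
                                strategy = marker_strategy,
                                n_markers = n_markers,
                                seed = seed + rep_i * 1000L + f)
          jj <- match(sel, sub$loci$locus_id)
          Xs <- X_imp[, jj, drop = FALSE]
          pred[test] <- gblup_fold(al$y, Xs, tcrossprod(Xs), train, test)$pred
        }
      }
      met <- cv_metrics(al$y, pred, fold = fold_of)
      tibble::tibble(repeat_id = rep_i, r = met["r"],
                     accu = if (!is.null(h2)) accuracy(met["r"], h2) else NA_real_,
                     b0 = met["b0"], b1 = met["b1"])
    })
  })
  structure(
    list(repeats = reps,
         scheme = list(type = "random_kfold", folds = folds,
                       repeats = repeats, n = n, n_markers = n_markers,
                       marker_strategy = if (is.null(n_markers)) "all"
                                         else marker_strategy,
                       h2 = h2, stratified = !is.null(strata), seed = seed)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  s <- glance.cv_result(x)
  cat(sprintf("<cv_result> %s: %d repeats (n = %d)\n", x$scheme$type,
              x$scheme$repeats, x$scheme$n))
  cat(sprintf("  r = %.3f (SD %.3f), Accu = %.3f, b0 = %.3f, b1 = %.3f\n",
              s$mean_r, s$sd_r, s$mean_accu, s$mean_b0, s$mean_b1))
  invisible(x)
}

#' Tidy / summarize a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return `tidy()`: per-repeat tibble (`repeat_id`, `r`, `accu`, `b0`,
#'   `b1`); `glance()`: one-row mean/SD summary with the scheme
#'   descriptors.
#' @export
tidy.cv_result <- function(x, ...) x$repeats

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  r <- x$repeats
  tibble::tibble(
    type = x$scheme$type, folds = x$scheme$folds %||% NA_integer_,
    repeats = nrow(r), n = x$scheme$n,
    n_markers = x$scheme$n_markers %||% NA_integer_,
    marker_strategy = x$scheme$marker_strategy %||% "all",
    mean_r = mean(r$r, na.rm = TRUE), sd_r = stats::sd(r$r, na.rm = TRUE),
    mean_accu = mean(r$accu, na.rm = TRUE),
    mean_b0 = mean(r$b0, na.rm = TRUE), mean_b1 = mean(r$b1, na.rm = TRUE)
  )
}

#' Marker selection for prediction
#'
#' Chooses a marker subset using training data only: `"random"` (seeded),
#' `"gwas_p"` (lowest mixed-model association p-values within the training
#' set, kinship computed from the training genotypes), or `"effect_size"`
#' (largest absolute ridge-estimated effects within the training set).
#' Ties are broken by locus order.
#'
#' @param gt_train Training [genotype_table()].
#' @param y_train Named numeric vector (or BLUP object) for the training
#'   individuals.
#' @param strategy `"random"`, `"gwas_p"` or `"effect_size"`.
#' @param n_markers Subset size (>= 1). If it meets or exceeds the number
#'   of available markers, all markers are returned with a warning.
#' @param seed Seed for the random strategy.
#' @return Character vector of selected locus ids.
#' @export
select_markers <- function(gt_train, y_train,
                           strategy = c("random", "gwas_p", "effect_size"),
                           n_markers, seed = 1) {
  strategy <- match.arg(strategy)
  if (n_markers < 1) stop("n_markers must be >= 1", call. = FALSE)
  m <- n_loci(gt_train)
  if (n_markers >= m) {
    if (n_markers > m) warning("n_markers exceeds available markers; returning all",
                               call. = FALSE)
    return(gt_train$loci$locus_id)
  }
  if (strategy == "random") {
    return(with_seed(seed, gt_train$loci$locus_id[sort(sample(m, n_markers))]))
  }
  if (strategy == "gwas_p") {
    K <- ibs_kinship(gt_train)
    null <- fit_null_mlm(y_train, K)
    p <- tidy(emmax_scan(null, gt_train))$p_value
    p[is.na(p)] <- Inf
    ord <- order(p, seq_along(p))
  } else {
    fit <- fit_ridge_blup(y_train, gt_train)
    ord <- order(-abs(fit$effects), seq_along(fit$effects))
  }
  gt_train$loci$locus_id[sort(ord[seq_len(n_markers)])]
}

#' Across-subpopulation cross-validation
#'
#' One deterministic evaluation training on every individual of
#' `train_label` and predicting every individual of `test_label`, compared
#' against `n_baseline` random partitions of identical training/test sizes
#' drawn from all individuals. A drop of the across-subpopulation `r` below
#' the random band quantifies how much prediction relies on structure and
#' relatedness.
#'
#' @param blups Trait BLUPs (as in [cross_validate()]).
#' @param gt A [genotype_table()].
#' @param labels Named character vector of subpopulation labels (defaults
#'   to the table's own labels).
#' @param train_label,test_label Labels defining the split.
#' @param n_baseline Number of matched random partitions.
#' @param h2 Broad-sense heritability for the accuracy rescaling.
#' @param seed Master seed for the baselines.
#' @return A list of class `cv_subpop_result`: `across` (one-row tibble),
#'   `baseline` (a `cv_result`-style tibble of the random partitions) and
#'   `scheme`.
#' @export
cross_validate_subpops <- function(blups, gt, labels = NULL,
                                   train_label, test_label,
                                   n_baseline = 100, h2 = NULL, seed = 1) {
  al <- align_response(blups, gt = gt)
  if (is.null(h2) && inherits(blups, "trait_blups")) h2 <- blups$h2
  sub <- gt[al$ids, ]
  if (is.null(labels)) {
    if (is.null(sub$subpop)) stop("no subpopulation labels available", call. = FALSE)
    labels <- stats::setNames(sub$subpop, sub$individual_ids)
  }
  labels <- labels[al$ids]
  if (!train_label %in% labels) stop("unknown label: ", train_label, call. = FALSE)
  if (!test_label %in% labels) stop("unknown label: ", test_label, call. = FALSE)
  train <- which(labels == train_label)
  test <- which(labels == test_label)
  if (length(train) < 2) stop("training set too small", call. = FALSE)
  X_imp <- impute_mean(sub)
  P <- tcrossprod(X_imp)
  gb <- gblup_fold(al$y, X_imp, P, train, test)
  met <- cv_metrics(al$y[test], gb$pred)
  across <- tibble::tibble(
    r = met["r"],
    accu = if (!is.null(h2)) accuracy(met["r"], h2) else NA_real_,
    b0 = met["b0"], b1 = met["b1"],
    n_train = length(train), n_test = length(test)
  )
  n <- length(al$y)
  baseline <- purrr::map_dfr(seq_len(n_baseline), function(b) {
    with_seed(seed + b, {
      tr <- sample(n, length(train))
      te <- sample(setdiff(seq_len(n), tr), length(test))
      gbb <- gblup_fold(al$y, X_imp, P, tr, te)
      mb <- cv_metrics(al$y[te], gbb$pred)
      tibble::tibble(repeat_id = b, r = mb["r"],
                     accu = if (!is.null(h2)) accuracy(mb["r"], h2) else NA_real_,
                     b0 = mb["b0"], b1 = mb["b1"])
    })
  })
  structure(
    list(across = across, baseline = baseline,
         scheme = list(type = "across_subpop", train_label = train_label,
                       test_label = test_label, n_baseline = n_baseline,
                       h2 = h2, seed = seed)),
    class = "cv_subpop_result"
  )
}

#' @export
print.cv_subpop_result <- function(x, ...) {
  cat(sprintf("<cv_subpop_result> train %s (n=%d) -> test %s (n=%d)\n",
              x$scheme$train_label, x$across$n_train,
              x$scheme$test_label, x$across$n_test))
  cat(sprintf("  across-subpop r = %.3f; random baseline r = %.3f (SD %.3f, %d reps)\n",
              x$across$r, mean(x$baseline$r, na.rm = TRUE),
              stats::sd(x$baseline$r, na.rm = TRUE), nrow(x$baseline)))
  invisible(x)
}
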