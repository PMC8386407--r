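#' Patient-level cross-validation folds
#'
#' Partitions patients (never individual visits) into `k` folds per repeat,
#' with fold sizes differing by at most one; all visits of a patient share
#' its fold, so held-out patients are entirely unseen during training.
#' Repeats use distinct seeds derived from the master seed and are fully
#' reproducible.
#'
#' @param patient_ids Character/factor vector of patient ids (duplicates
#'   allowed; folds are assigned per unique patient).
#' @param k Number of folds (study default 10, holding out 10% of
#'   patients).
#' @param repeats Number of repeated partitions (study default 30).
#' @param seed Master seed.
#' @return Tibble with `repeat_id`, `patient_id`, `fold`.
#' @export
make_patient_folds <- function(patient_ids, k = 10, repeats = 30, seed = 1) {
  patients <- sort(unique(as.character(patient_ids)))
  n <- length(patients)
  if (k > n) {
    abort(sprintf("k = %d folds exceed the %d available patients", k, n))
  }
  purrr::map(seq_len(repeats), function(r) {
    withr::with_seed(derive_seed(seed, paste0("fold-repeat-", r)), {
      shuffled <- sample(patients)
      tibble(
        repeat_id = r,
        patient_id = shuffled,
        fold = rep_len(seq_len(k), n)
      )
    })
  }) %>%
    dplyr::bind_rows()
}

impute_train_means <- function(x, means = NULL) {
  if (is.null(means)) {
    means <- colMeans(x, na.rm = TRUE)
    means[!is.finite(means)] <- 0 # all-missing column: neutral constant
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- means[j]
  }
  list(x = x, means = means)
}

#' Fit an elastic-net linear model with inner hyperparameter selection
#'
#' Penalized linear regression combining L1 and L2 penalties. When a grid
#' is given, the mixing parameter `alpha` and penalty strength `lambda` are
#' chosen by inner patient-level cross-validation on the training data
#' (minimum pooled RMSE); with a single `(alpha, lambda)` pair the model is
#' fitted directly. Features are standardized internally on the training
#' data and missing entries imputed with training-column means; both sets
#' of parameters are stored for test-time reuse, so no information flows
#' from evaluation data into preprocessing.
#'
#' @param x Numeric feature matrix (or data frame) of the training visits.
#' @param y Numeric training outcome.
#' @param patients Patient id per training row (inner folds are grouped by
#'   patient; defaults to row-level folds).
#' @param alpha Mixing grid in (0, 1]; default `seq(0.1, 1, by = 0.1)`.
#' @param lambda Optional explicit penalty grid; default: 50 log-spaced
#'   values chosen by glmnet per alpha.
#' @param nlambda Size of the automatic penalty path.
#' @param inner_k Inner folds for hyperparameter selection.
#' @param seed Seed for the inner folds.
#' @param thresh Coordinate-descent convergence threshold.
#' @return A `psymon_enet` object with `predict()` and [tidy()] methods.
#' @export
fit_elastic_net <- function(x, y, patients = NULL,
                            alpha = seq(0.1, 1, by = 0.1),
                            lambda = NULL, nlambda = 50, inner_k = 5,
                            seed = 1, thresh = 1e-9) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(y) != nrow(x)) abort("x and y sizes differ")
  if (length(unique(y)) < 2) abort("all-constant outcome: nothing to fit")
  if (nrow(x) < 3) abort("need at least 3 training observations")
  imp <- impute_train_means(x)
  x <- imp$x
  feature_names <- colnames(x)
  if (ncol(x) == 1) {
    # glmnet needs >= 2 columns; pad with an inert constant
    x <- cbind(x, .pad = 0)
  }
  if (is.null(patients)) patients <- as.character(seq_len(nrow(x)))
  patients <- as.character(patients)

  single <- length(alpha) == 1 && !is.null(lambda) && length(lambda) == 1
  if (single) {
    chosen <- list(alpha = alpha, lambda = lambda)
  } else {
    inner_k_eff <- min(inner_k, length(unique(patients)))
    if (inner_k_eff < 2) abort("need >= 2 training patients for selection")
    folds <- make_patient_folds(patients, k = inner_k_eff, repeats = 1,
                                seed = derive_seed(seed, "inner-cv"))
    fold_of <- setNames(folds$fold, folds$patient_id)
    row_fold <- fold_of[patients]
    grid_rmse <- purrr::map(alpha, function(a) {
      # one shared path per alpha so inner errors are comparable
      path <- glmnet::glmnet(x, y, alpha = a, lambda = lambda,
                             nlambda = nlambda, thresh = thresh)
      lams <- path$lambda
      sq_err <- matrix(NA_real_, nrow(x), length(lams))
      for (f in sort(unique(row_fold))) {
        test <- row_fold == f
        if (all(test) || !any(test)) next
        fit_f <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                                alpha = a, lambda = lams, thresh = thresh)
        pred <- predict(fit_f, x[test, , drop = FALSE], s = lams)
        sq_err[test, seq_len(ncol(pred))] <- (pred - y[test])^2
      }
      tibble(alpha = a, lambda = lams,
             rmse = sqrt(colMeans(sq_err, na.rm = TRUE)))
    }) %>% dplyr::bind_rows()
    best <- grid_rmse[which.min(grid_rmse$rmse), ]
    chosen <- list(alpha = best$alpha, lambda = best$lambda)
  }

  fit <- glmnet::glmnet(x, y, alpha = chosen$alpha,
                        lambda = chosen$lambda, thresh = thresh)
  structure(
    list(
      fit = fit,
      alpha = chosen$alpha,
      lambda = chosen$lambda,
      feature_means = imp$means,
      feature_names = feature_names,
      padded = ncol(x) > length(feature_names)
    ),
    class = "psymon_enet"
  )
}

#' @export
predict.psymon_enet <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  x <- impute_train_means(x, means = object$feature_means)$x
  if (isTRUE(object$padded)) x <- cbind(x, .pad = 0)
  as.vector(predict(object$fit, x, s = object$lambda))
}

#' Out-of-sample R-squared
#'
#' \eqn{R^2 = (SST - SSE) / SST}, with the total sum of squares taken about
#' the mean of the observed values in the evaluation set. Computed on
#' held-out predictions this may be negative: predictions worse than the
#' held-out mean.
#'
#' @param y_true Observed outcomes (not constant, length >= 2).
#' @param y_pred Predictions.
#' @return A real number `<= 1`.
#' @examples
#' r2_out_of_sample(c(0, 1, 2), c(2, 2, 2)) # -1.5
#' @export
r2_out_of_sample <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  if (length(y_true) < 2) abort("need at least 2 observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) abort("constant y_true: out-of-sample R^2 undefined")
  sse <- sum((y_true - y_pred)^2)
  (sst - sse) / sst
}

#' Patient-level repeated cross-validation of an elastic-net model
#'
#' The prediction engine of the pipeline: for each repeat, patients are
#' partitioned into `k` folds; for each fold an elastic net is trained on
#' the remaining patients (imputation, standardization and hyperparameter
#' selection all confined to the training split) and the held-out visits
#' predicted. Per repeat, the pooled out-of-sample predictions give one
#' RMSE and one out-of-sample R-squared; the result reports their mean and
#' SD across repeats. Repeats in which any fold cannot be fitted (e.g. a
#' constant training outcome) are skipped with a warning and counted.
#'
#' @param data Tibble with patient ids, the outcome and feature columns.
#' @param outcome Outcome column name.
#' @param features Feature column names (default: all numeric columns
#'   except the outcome and identifiers).
#' @param patient Patient id column name.
#' @param k,repeats,seed Cross-validation scheme (defaults 10 folds, 30
#'   repeats).
#' @param alpha,nlambda,inner_k,thresh Passed to [fit_elastic_net()].
#' @param keep_preprocess Store each fold's imputation means (used to
#'   audit that preprocessing never sees test data).
#' @return A `psymon_cv` object; see [tidy.psymon_cv()] and
#'   [glance.psymon_cv()].
#' @export
cross_validate <- function(data, outcome, features = NULL,
                           patient = "patient_id", k = 10, repeats = 30,
                           seed = 1, alpha = seq(0.1, 1, by = 0.1),
                           nlambda = 50, inner_k = 5, thresh = 1e-9,
                           keep_preprocess = FALSE) {
  if (is.null(features)) {
    num <- vapply(data, is.numeric, logical(1))
    features <- setdiff(names(data)[num], c(outcome, patient))
  }
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (nrow(d) == 0) abort("no rows with an observed outcome")
  y <- d[[outcome]]
  pats <- as.character(d[[patient]])
  x <- as.matrix(d[, features, drop = FALSE])
  storage.mode(x) <- "double"

  folds <- make_patient_folds(pats, k = k, repeats = repeats, seed = seed)
  by_repeat <- vector("list", repeats)
  hyper <- vector("list", repeats)
  preprocess <- if (keep_preprocess) list() else NULL
  n_skipped <- 0L
  for (r in seq_len(repeats)) {
    fr <- folds[folds$repeat_id == r, ]
    fold_of <- setNames(fr$fold, fr$patient_id)
    row_fold <- fold_of[pats]
    preds <- rep(NA_real_, nrow(d))
    hp <- vector("list", k)
    failed <- FALSE
    for (f in seq_len(k)) {
      test <- row_fold == f
      if (!any(test)) next
      fit <- tryCatch(
        fit_elastic_net(
          x[!test, , drop = FALSE], y[!test], patients = pats[!test],
          alpha = alpha, nlambda = nlambda, inner_k = inner_k,
          seed = derive_seed(seed, paste0("cv-", r, "-", f)),
          thresh = thresh
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        failed <- TRUE
        break
      }
      preds[test] <- predict(fit, x[test, , drop = FALSE])
      hp[[f]] <- tibble(repeat_id = r, fold = f,
                        alpha = fit$alpha, lambda = fit$lambda)
      if (keep_preprocess) {
        preprocess[[paste(r, f, sep = "-")]] <- fit$feature_means
      }
    }
    if (failed || !any(!is.na(preds))) {
      warn(sprintf("repeat %d skipped: a fold could not be fitted", r))
      n_skipped <- n_skipped + 1L
      next
    }
    ok <- !is.na(preds)
    by_repeat[[r]] <- tibble(
      repeat_id = r,
      rmse = sqrt(mean((y[ok] - preds[ok])^2)),
      r2 = r2_out_of_sample(y[ok], preds[ok]),
      n_pred = sum(ok)
    )
    hyper[[r]] <- dplyr::bind_rows(hp)
  }
  by_repeat <- dplyr::bind_rows(by_repeat)
  if (nrow(by_repeat) == 0) abort("every repeat failed; nothing to report")
  structure(
    list(
      outcome = outcome,
      features = features,
      by_repeat = by_repeat,
      hyper = dplyr::bind_rows(hyper),
      preprocess = preprocess,
      n_skipped = n_skipped,
      scheme = list(k = k, repeats = repeats, unit = "patient", seed = seed,
                    sd_across = "repeats"),
      summary = tibble(
        outcome = outcome,
        rmse_mean = mean(by_repeat$rmse), rmse_sd = sd(by_repeat$rmse),
        r2_mean = mean(by_repeat$r2), r2_sd = sd(by_repeat$r2),
        n_repeats = nrow(by_repeat)
      )
    ),
    class = "psymon_cv"
  )
}

#' @export
print.psymon_cv <- function(x, ...) {
  cat("Patient-level repeated CV (", x$scheme$k, "-fold x ",
      x$scheme$repeats, " repeats) for '", x$outcome, "'\n", sep = "")
  print(x$summary)
  invisible(x)
}
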