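#' SMOTE oversampling settings
#'
#' @param k_neighbors Nearest same-class neighbors considered when
#'   interpolating (default 5; must be below the minority class size).
#' @param target_total Total size of the balanced dataset (default 100).
#' @param seed Seed for the draws.
#' @return A `smote_spec` list.
#' @export
smote_spec <- function(k_neighbors = 5, target_total = 100, seed = 1) {
  stopifnot(k_neighbors >= 1, target_total >= 2)
  structure(list(k_neighbors = k_neighbors, target_total = target_total,
                 seed = seed), class = "smote_spec")
}

#' SMOTE class balancing by convex interpolation
#'
#' Balances a two-class dataset toward `target_total` samples split evenly
#' between the classes. Each synthetic sample is drawn by picking an original
#' sample of the class, one of its `k_neighbors` nearest same-class
#' neighbors (Euclidean), and a uniform interpolation weight, so every
#' synthetic point lies on the segment between two real same-class points.
#' Original samples are preserved verbatim and never removed; a class
#' already at or above its target is left untouched.
#'
#' @param features Numeric matrix (samples x features); extra numeric
#'   columns (e.g. the regression target) may be bound in so they are
#'   interpolated consistently.
#' @param labels Two-class factor.
#' @param spec A [smote_spec()].
#' @return List with `features` (matrix) and `labels` (factor); original
#'   rows come first.
#' @export
smote_oversample <- function(features, labels, spec = smote_spec()) {
  x <- as.matrix(unclass(features))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("SMOTE requires exactly two classes")
  cnt <- table(labels)
  if (min(cnt) <= spec$k_neighbors) {
    stop("minority class (", min(cnt), ") too small for k_neighbors = ",
         spec$k_neighbors, "; use a smaller k")
  }
  target <- spec$target_total %/% 2
  targets <- stats::setNames(c(target, spec$target_total - target),
                             names(sort(cnt, decreasing = TRUE)))
  set.seed(spec$seed)
  synth_x <- list(); synth_y <- character()
  for (cl in names(targets)) {
    n_new <- targets[[cl]] - cnt[[cl]]
    if (n_new <= 0) next
    xi <- x[labels == cl, , drop = FALSE]
    dm <- as.matrix(stats::dist(xi))
    diag(dm) <- Inf
    ord <- apply(dm, 1, function(r) order(r)[seq_len(spec$k_neighbors)])
    nn <- if (is.matrix(ord)) t(ord) else matrix(ord, ncol = 1)
    seed_i <- sample(nrow(xi), n_new, replace = TRUE)
    nbr_i <- nn[cbind(seed_i, sample(spec$k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    synth_x[[cl]] <- xi[seed_i, , drop = FALSE] +
      u * (xi[nbr_i, , drop = FALSE] - xi[seed_i, , drop = FALSE])
    synth_y <- c(synth_y, rep(cl, n_new))
  }
  if (length(synth_x)) {
    sx <- do.call(rbind, synth_x)
    rownames(sx) <- sprintf("synth_%03d", seq_len(nrow(sx)))
    out_x <- rbind(x, sx)
    out_y <- factor(c(as.character(labels), synth_y), levels = levels(labels))
  } else {
    out_x <- x; out_y <- labels
  }
  list(features = out_x, labels = out_y)
}

#' Relative root mean square error
#'
#' `100 * RMSE / mean(measured)`, in percent. Scale-invariant: scaling both
#' vectors by the same positive constant leaves it unchanged. The companion
#' prediction accuracy is reported as `100 - RRMSE`.
#'
#' @param measured,predicted Equal-length numeric vectors;
#'   `mean(measured)` must be positive.
#' @return RRMSE in percent.
#' @examples
#' rrmse(c(10, 10), c(11, 9)) # 10
#' @export
rrmse <- function(measured, predicted) {
  if (length(measured) != length(predicted) || !length(measured)) {
    stop("`measured` and `predicted` must have equal, nonzero length")
  }
  mbar <- mean(measured)
  if (mbar <= 0) stop("mean of measured values must be positive")
  100 * sqrt(mean((measured - predicted)^2)) / mbar
}

# seeded k-fold assignment
.make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

.fit_predict <- function(algorithm, x_tr, y_tr, x_te, spec) {
  switch(algorithm,
    linear = {
      df <- data.frame(y = y_tr, x_tr, check.names = TRUE)
      fit <- stats::lm(y ~ ., data = df)
      nd <- data.frame(x_te, check.names = TRUE)
      names(nd) <- names(df)[-1]
      unname(stats::predict(fit, nd))
    },
    svm_radial = {
      fit <- e1071::svm(x = x_tr, y = y_tr, kernel = "radial")
      unname(stats::predict(fit, x_te))
    },
    rf = {
      fit <- ranger::ranger(y = y_tr, x = as.data.frame(x_tr),
                            num.trees = spec$n_trees,
                            mtry = max(1, floor(ncol(x_tr) / 3)),
                            seed = spec$seed, num.threads = 1)
      stats::predict(fit, as.data.frame(x_te))$predictions
    },
    stop("unknown algorithm: ", algorithm))
}

#' Benchmark regression algorithms by cross-validated RMSE
#'
#' Heuristic comparison of linear regression, radial-kernel SVM and random
#' forest regression on the original and the SMOTE-balanced training data,
#' by 5-fold cross-validation RMSE. Balancing interpolates the target
#' together with the features so synthetic samples stay consistent.
#'
#' @param features Numeric matrix (samples x ASVs).
#' @param target Numeric response (a process parameter); must not be
#'   constant.
#' @param labels HRT class factor used for SMOTE balancing; `NULL` skips the
#'   balanced arm.
#' @param spec An [rf_spec()] (forest size/seed; also seeds the folds).
#' @param smote A [smote_spec()].
#' @param k_folds Folds (default 5).
#' @return Long data frame: `algorithm`, `dataset`, `fold`, `rmse`.
#' @export
benchmark_regressors <- function(features, target, labels = NULL,
                                 spec = rf_spec(), smote = smote_spec(),
                                 k_folds = 5) {
  x <- as.matrix(unclass(features))
  if (length(target) != nrow(x)) stop("target length must match samples")
  if (stats::var(target) == 0) stop("target is constant")
  if (nrow(x) < 2 * k_folds) stop("need at least ", 2 * k_folds, " samples")
  datasets <- list(original = list(x = x, y = target))
  if (!is.null(labels)) {
    bal <- smote_oversample(cbind(x, .target = target), labels, smote)
    datasets$balanced <- list(x = bal$features[, colnames(x), drop = FALSE],
                              y = bal$features[, ".target"])
  }
  out <- list()
  for (ds in names(datasets)) {
    d <- datasets[[ds]]
    folds <- .make_folds(length(d$y), k_folds, spec$seed)
    for (alg in c("linear", "svm_radial", "rf")) {
      for (f in seq_len(k_folds)) {
        tr <- folds != f
        pred <- .fit_predict(alg, d$x[tr, , drop = FALSE], d$y[tr],
                             d$x[!tr, , drop = FALSE], spec)
        out[[length(out) + 1L]] <- data.frame(
          algorithm = alg, dataset = ds, fold = f,
          rmse = sqrt(mean((d$y[!tr] - pred)^2)))
      }
    }
  }
  do.call(rbind, out)
}

#' Random-forest regression of a process parameter across reactors
#'
#' Fits a regression forest (via [ranger::ranger()], 2000 trees,
#' `mtry = max(1, floor(p/3))`) of a process parameter on the ASV relative
#' abundances of the training reactor only, and evaluates predictions on the
#' held-out test reactor. Training performance is the out-of-bag explained
#' variance, `100 * (1 - MSE_oob / Var(target))`; test performance is RMSE,
#' RRMSE and the least-squares line of predicted on measured. Bioindicator
#' ASVs absent from the test table are zero-filled.
#'
#' @param train_features,test_features Numeric matrices (samples x ASVs) for
#'   the two reactors; columns are aligned by name.
#' @param train_target,test_target Numeric parameter values (no missing
#'   values).
#' @param asv_ids Optional character vector restricting the features (e.g. a
#'   `bioindicator_set`'s `asv_id`); default all shared columns.
#' @param spec An [rf_spec()].
#' @param parameter Name tag for the report.
#' @return List of class `prediction_report`: `parameter`,
#'   `explained_variance_train` (%), `predicted`, `measured`, `rmse`,
#'   `rrmse` (%), `accuracy` (% = 100 - RRMSE), `fit` (slope, intercept,
#'   r_squared), `importance` (ranked node-impurity importances).
#' @export
rf_regress <- function(train_features, train_target, test_features,
                       test_target, asv_ids = NULL, spec = rf_spec(),
                       parameter = "parameter") {
  xtr <- as.matrix(unclass(train_features))
  xte <- as.matrix(unclass(test_features))
  if (anyNA(train_target) || anyNA(test_target)) {
    bad <- c(rownames(xtr)[is.na(train_target)], rownames(xte)[is.na(test_target)])
    stop("missing target values for sample(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(asv_ids)) asv_ids <- colnames(xtr)
  miss_tr <- setdiff(asv_ids, colnames(xtr))
  if (length(miss_tr)) stop("ASV(s) absent from training table: ",
                            paste(miss_tr, collapse = ", "))
  miss_te <- setdiff(asv_ids, colnames(xte))
  if (length(miss_te)) {
    xte <- cbind(xte, matrix(0, nrow(xte), length(miss_te),
                             dimnames = list(rownames(xte), miss_te)))
  }
  xtr <- xtr[, asv_ids, drop = FALSE]
  xte <- xte[, asv_ids, drop = FALSE]
  vy <- stats::var(train_target)
  if (vy == 0) {
    return(structure(list(parameter = parameter,
                          explained_variance_train = -Inf,
                          predictable = FALSE),
                     class = "prediction_report"))
  }
  fit <- ranger::ranger(y = train_target, x = as.data.frame(xtr),
                        num.trees = spec$n_trees,
                        mtry = max(1, floor(ncol(xtr) / 3)),
                        importance = "impurity", seed = spec$seed,
                        num.threads = 1)
  pred <- stats::predict(fit, as.data.frame(xte))$predictions
  lsq <- stats::lm(pred ~ test_target)
  imp <- fit$variable.importance
  structure(list(
    parameter = parameter,
    explained_variance_train = 100 * fit$r.squared,
    predicted = pred,
    measured = test_target,
    rmse = sqrt(mean((test_target - pred)^2)),
    rrmse = rrmse(test_target, pred),
    accuracy = 100 - rrmse(test_target, pred),
    fit = list(slope = unname(stats::coef(lsq)[2]),
               intercept = unname(stats::coef(lsq)[1]),
               r_squared = summary(lsq)$r.squared),
    importance = .rank_importance(imp),
    predictable = TRUE
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> ", x$parameter, ": %Var(train) = ",
      format(x$explained_variance_train, digits = 4), sep = "")
  if (isTRUE(x$predictable)) {
    cat(", RRMSE = ", format(x$rrmse, digits = 3), "%", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Select non-HRT bioindicators for a process parameter
#'
#' Fits a regression forest of the parameter on all ASVs of one reactor and
#' takes the 15 top-ranked features by node-impurity (residual-sum-of-
#' squares) importance — the ASVs that track the parameter's numeric values
#' regardless of HRT class, capturing community assembly over time.
#'
#' @param features Numeric matrix (samples x all ASVs) of one reactor,
#'   restricted to the labeled intervals.
#' @param target Parameter values for those samples (complete).
#' @param k Set size (default 15).
#' @param spec An [rf_spec()].
#' @param parameter,reactor Tags stored on the result.
#' @return A `bioindicator_set` with target `parameter`.
#' @export
select_nonhrt_bioindicators <- function(features, target, k = 15,
                                        spec = rf_spec(),
                                        parameter = "parameter",
                                        reactor = NA_character_) {
  x <- as.matrix(unclass(features))
  if (anyNA(target)) stop("missing target values")
  fit <- ranger::ranger(y = target, x = as.data.frame(x),
                        num.trees = spec$n_trees,
                        mtry = max(1, floor(ncol(x) / 3)),
                        importance = "impurity", seed = spec$seed,
                        num.threads = 1)
  ranking <- .rank_importance(fit$variable.importance)
  sel <- utils::head(ranking, k)
  sel$rank <- seq_len(nrow(sel))
  new_bioindicator_set(sel, target = parameter, reactor = reactor,
                       explained_variance_train = 100 * fit$r.squared)
}

#' HRT bioindicators irrespective of time
#'
#' The HRT bioindicators that are *not* among any of the supplied non-HRT
#' bioindicator sets: ASVs discriminating the HRT regimes that do not merely
#' track a process parameter's drift over time. Order is preserved from the
#' HRT set.
#'
#' @param hrt_set Shared HRT `bioindicator_set`.
#' @param nonhrt_sets List of non-HRT `bioindicator_set`s (one per process
#'   parameter considered).
#' @return A `bioindicator_set` (possibly empty, with a warning).
#' @export
time_independent_set <- function(hrt_set, nonhrt_sets) {
  if (inherits(nonhrt_sets, "bioindicator_set")) nonhrt_sets <- list(nonhrt_sets)
  covered <- unique(unlist(lapply(nonhrt_sets, `[[`, "asv_id")))
  keep <- !hrt_set$asv_id %in% covered
  if (!any(keep)) warning("non-HRT bioindicators cover the entire HRT set")
  df <- as.data.frame(hrt_set)[keep, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  new_bioindicator_set(df, target = "HRT_time_independent",
                       reactor = attr(hrt_set, "reactor"))
}

#' Replicate subsampled-RRMSE evaluation
#'
#' The final accuracy protocol: over `n_replicates` replicates, draw
#' `subsample_size` ASVs uniformly without replacement from a bioindicator
#' set (4 of the HRT bioindicators, 5 of a non-HRT set, by default), fit the
#' regression forest on the training reactor and record the RRMSE on the
#' test reactor. Reports the mean and the full distribution; a parameter is
#' declared predictable when the mean RRMSE is below the 10% cutoff.
#'
#' @inheritParams rf_regress
#' @param set A `bioindicator_set` to subsample from.
#' @param n_replicates Number of replicates (default 100).
#' @param subsample_size ASVs drawn per replicate; must not exceed the set
#'   size.
#' @param rrmse_cutoff Predictability cutoff in percent (default 10).
#' @return List: `mean_rrmse`, `rrmse` (length `n_replicates`),
#'   `predictable`, `subsample_size`, `parameter`.
#' @export
replicate_rrmse <- function(train_features, train_target, test_features,
                            test_target, set, n_replicates = 100,
                            subsample_size = 4, spec = rf_spec(),
                            parameter = "parameter", rrmse_cutoff = 10) {
  ids <- if (inherits(set, "bioindicator_set")) set$asv_id else set
  if (subsample_size > length(ids)) {
    stop("subsample_size (", subsample_size, ") exceeds set size (",
         length(ids), ")")
  }
  set.seed(spec$seed)
  sub_seeds <- sample.int(2^31 - 2, n_replicates)
  vals <- vapply(seq_len(n_replicates), function(i) {
    set.seed(sub_seeds[i])
    pick <- sample(ids, subsample_size)
    rep_spec <- rf_spec(spec$n_trees, spec$m_try, sub_seeds[i])
    rf_regress(train_features, train_target, test_features, test_target,
               asv_ids = pick, spec = rep_spec, parameter = parameter)$rrmse
  }, 0)
  list(mean_rrmse = mean(vals), rrmse = vals,
       predictable = mean(vals) < rrmse_cutoff,
       subsample_size = subsample_size, parameter = parameter)
}
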