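#' Random-forest classifier settings
#'
#' Hyperparameters of the HRT-phase classifier: 2000 trees with 40 candidate
#' variables per split (capped at the current feature count — 40 applies in
#' the full 71-ASV setting and shrinks with the eliminated feature sets).
#'
#' @param n_trees Number of trees (default 2000).
#' @param m_try Candidate variables per split (default 40; the effective
#'   value is `min(m_try, n_features)`).
#' @param seed Seed for the forest (default 1).
#' @return An `rf_spec` list.
#' @export
rf_spec <- function(n_trees = 2000, m_try = 40, seed = 1) {
  stopifnot(n_trees >= 1, m_try >= 1)
  structure(list(n_trees = n_trees, m_try = m_try, seed = seed),
            class = "rf_spec")
}

# rank a Gini importance vector with the package-wide tie-break:
# importance descending, then ASV id ascending
.rank_importance <- function(imp) {
  ord <- order(-imp, names(imp))
  data.frame(asv_id = names(imp)[ord],
             importance = unname(imp[ord]),
             share = unname(imp[ord]) / sum(imp),
             rank = seq_along(imp),
             stringsAsFactors = FALSE)
}

#' Train the HRT-phase random-forest classifier
#'
#' Fits a classification forest of HRT class (`HRT8` vs `HRT2`) on ASV
#' relative abundances, reports the out-of-bag (OOB) error and the mean
#' decrease in Gini importance of every ASV. Cross-reactor generalization is
#' assessed separately with [classify_heldout()] so the test reactor never
#' enters training.
#'
#' @param features Numeric matrix or relative-mode [abundance_table()]
#'   (samples x ASVs), restricted to the labeled sampling intervals.
#' @param labels Factor of HRT class labels (two classes, each with at least
#'   two samples).
#' @param spec An [rf_spec()].
#' @return List of class `hrt_classifier`: `model` (randomForest),
#'   `oob_error`, `importance` (ranked data frame with Gini shares), `spec`.
#' @export
train_hrt_classifier <- function(features, labels, spec = rf_spec()) {
  x <- unclass(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("labels contain a single class")
  if (any(table(labels) < 2)) stop("each class needs at least two samples")
  if (length(labels) != nrow(x)) stop("labels must match the sample rows")
  set.seed(spec$seed)
  fit <- randomForest::randomForest(
    x = x, y = labels, ntree = spec$n_trees,
    mtry = min(spec$m_try, ncol(x)))
  imp <- fit$importance[, "MeanDecreaseGini"]
  structure(list(model = fit,
                 oob_error = unname(fit$err.rate[spec$n_trees, "OOB"]),
                 importance = .rank_importance(imp),
                 spec = spec),
            class = "hrt_classifier")
}

#' @rdname train_hrt_classifier
#' @param classifier A fitted `hrt_classifier`.
#' @param test_features Feature matrix for the held-out reactor.
#' @param test_labels True labels for the held-out reactor.
#' @return `classify_heldout`: list with `accuracy`, `predicted`, `confusion`.
#' @export
classify_heldout <- function(classifier, test_features, test_labels) {
  x <- unclass(test_features)
  need <- rownames(classifier$model$importance)
  missing <- setdiff(need, colnames(x))
  if (length(missing)) { # zero-fill ASVs absent from the test table
    x <- cbind(x, matrix(0, nrow(x), length(missing),
                         dimnames = list(rownames(x), missing)))
  }
  pred <- stats::predict(classifier$model, x[, need, drop = FALSE])
  test_labels <- factor(test_labels, levels = levels(pred))
  list(accuracy = mean(pred == test_labels),
       predicted = pred,
       confusion = table(predicted = pred, truth = test_labels))
}

#' Recursive Gini-importance feature elimination
#'
#' Starting from all features, repeatedly refits the HRT classifier and drops
#' the feature(s) with the smallest Gini importance — one per round by
#' default, with exactly tied minima removed together — until two features
#' remain. Each round records the feature set, OOB error rate and ranked
#' importances. The forest seed advances with the round index so rounds are
#' reproducible but not correlated by seed reuse.
#'
#' @inheritParams train_hrt_classifier
#' @return List of class `elimination_trace`; element `rounds` is a list of
#'   `(features, n_features, oob_error, importance)`, element `summary` a
#'   data frame of round sizes and errors.
#' @export
recursive_gini_elimination <- function(features, labels, spec = rf_spec()) {
  x <- unclass(features)
  keep <- colnames(x)
  rounds <- list()
  round_i <- 0L
  while (length(keep) >= 2) {
    round_i <- round_i + 1L
    rspec <- rf_spec(spec$n_trees, spec$m_try, spec$seed + round_i)
    fit <- train_hrt_classifier(x[, keep, drop = FALSE], labels, rspec)
    rounds[[round_i]] <- list(features = keep,
                              n_features = length(keep),
                              oob_error = fit$oob_error,
                              importance = fit$importance)
    if (length(keep) == 2) break
    imp <- stats::setNames(fit$importance$importance, fit$importance$asv_id)
    low <- names(imp)[imp == min(imp)]
    if (length(low) >= length(keep)) low <- utils::tail(sort(low), length(keep) - 2)
    keep <- setdiff(keep, low)
  }
  summary <- data.frame(
    round = seq_along(rounds),
    n_features = vapply(rounds, `[[`, 1L, "n_features"),
    oob_error = vapply(rounds, `[[`, 0, "oob_error"))
  structure(list(rounds = rounds, summary = summary, spec = spec),
            class = "elimination_trace")
}

#' Select bioindicators from an elimination trace
#'
#' Two rules combine: (1) the candidate pool is every feature whose Gini
#' share exceeds `threshold_share` (1% of the summed Gini scores) in the
#' all-feature ranking; (2) the final set is the `k` (15) top-ranked features
#' of the trace round with the lowest OOB error rate. Both are reported.
#' When several rounds tie at the lowest error (common once the informative
#' features dominate), the earliest such round supplies the ranking: its
#' forest saw the most features, so redundant co-indicators share importance
#' instead of being pruned along the elimination path. Ties in importance
#' break by ASV id.
#'
#' @param trace An `elimination_trace` from [recursive_gini_elimination()].
#' @param threshold_share Gini-share candidate threshold (default 0.01).
#' @param k Final set size (default 15).
#' @param reactor Optional training-reactor tag stored in the result.
#' @param target Predicted target tag (default `"HRT"`).
#' @return A `bioindicator_set`: data frame (`asv_id`, `rank`, `importance`,
#'   `share`) with attributes `target`, `reactor`, `oob_error` (of the
#'   chosen round), `candidates` (threshold-rule pool) and `best_round`.
#' @export
select_bioindicators <- function(trace, threshold_share = 0.01, k = 15,
                                 reactor = NA_character_, target = "HRT") {
  stopifnot(inherits(trace, "elimination_trace"))
  full <- trace$rounds[[1]]$importance
  candidates <- full$asv_id[full$share > threshold_share]
  # the top-k rule presupposes a model with at least k features, so the
  # round is chosen among those; earliest minimum-error round wins
  eligible <- which(trace$summary$n_features >= k)
  if (!length(eligible)) eligible <- seq_along(trace$rounds)
  errs <- trace$summary$oob_error[eligible]
  best <- eligible[which.min(errs)]
  ranking <- trace$rounds[[best]]$importance
  if (nrow(ranking) < k) {
    warning("only ", nrow(ranking), " features available; returning all")
  }
  if (all(ranking$importance == ranking$importance[1]) && nrow(ranking) > k) {
    warning("all importances tied; selection falls back to ASV id order")
  }
  sel <- utils::head(ranking, k)
  sel$rank <- seq_len(nrow(sel))
  new_bioindicator_set(sel, target = target, reactor = reactor,
                       oob_error = errs[best], candidates = candidates,
                       best_round = best)
}

new_bioindicator_set <- function(df, target, reactor = NA_character_, ...) {
  structure(df[, c("asv_id", "rank", "importance", "share")],
            target = target, reactor = reactor, ...,
            class = c("bioindicator_set", "data.frame"))
}

#' @export
print.bioindicator_set <- function(x, ...) {
  cat("<bioindicator_set> target=", attr(x, "target"),
      " reactor=", attr(x, "reactor"), " n=", nrow(x), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Intersection of two bioindicator sets
#'
#' ASVs selected in both reactors' sets (the shared "HRT bioindicators").
#' Importance shares are averaged and the result is ordered by that mean,
#' descending, ties by ASV id.
#'
#' @param a,b `bioindicator_set`s with the same target.
#' @return A `bioindicator_set` of the shared ASVs.
#' @export
shared_set <- function(a, b) {
  if (!identical(attr(a, "target"), attr(b, "target"))) {
    stop("bioindicator sets target different variables: ",
         attr(a, "target"), " vs ", attr(b, "target"))
  }
  ids <- intersect(a$asv_id, b$asv_id)
  if (!length(ids)) warning("bioindicator sets are disjoint")
  share <- (a$share[match(ids, a$asv_id)] + b$share[match(ids, b$asv_id)]) / 2
  imp <- (a$importance[match(ids, a$asv_id)] +
            b$importance[match(ids, b$asv_id)]) / 2
  ord <- order(-share, ids)
  df <- data.frame(asv_id = ids[ord], rank = seq_along(ids),
                   importance = imp[ord], share = share[ord],
                   stringsAsFactors = FALSE)
  new_bioindicator_set(df, target = attr(a, "target"),
                       reactor = paste0(attr(a, "reactor"), "&",
                                        attr(b, "reactor")))
}

#' Serialize a bioindicator set
#'
#' Writes the set as TSV (optionally annotated with genus from a taxonomy
#' table) or JSON.
#'
#' @param set A `bioindicator_set`.
#' @param path Output path; extension `.json` selects JSON, anything else TSV.
#' @param taxonomy Optional data frame from [read_taxonomy()].
#' @export
write_bioindicator_set <- function(set, path, taxonomy = NULL) {
  df <- as.data.frame(set)
  if (!is.null(taxonomy)) {
    df$genus <- taxonomy$genus[match(df$asv_id, taxonomy$asv_id)]
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(target = attr(set, "target"),
                              reactor = attr(set, "reactor"),
                              oob_error = attr(set, "oob_error"),
                              asvs = df),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
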