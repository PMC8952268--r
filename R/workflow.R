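#' Run the two-step bioindicator workflow
#'
#' End-to-end orchestration across both train/test reactor orientations.
#' Step 1 (classification): per reactor, recursive Gini elimination on the
#' labeled sampling intervals yields the per-reactor HRT bioindicator sets
#' (top 15); their intersection is the shared HRT bioindicator set;
#' cross-reactor accuracy is measured on the reactor never seen in training.
#' Step 2 (regression): each process parameter is predicted from the shared
#' set across reactors; parameters whose out-of-bag explained variance
#' exceeds the 80% gate in both training orientations proceed to the
#' replicate subsampled-RRMSE protocol. Non-HRT bioindicators (top-15
#' regression importances over all ASVs, computed on the pooled labeled
#' samples of both reactors) are derived per parameter, and the HRT
#' bioindicators irrespective of time are the shared set minus the non-HRT
#' sets of `nonhrt_parameters`.
#'
#' @param abundance Counts-mode [abundance_table()] (rarefied to even
#'   depth); converted to relative abundances internally for all models.
#' @param metadata Data frame as from [read_metadata()] (interval and
#'   `hrt_label` are assigned if absent).
#' @param parameters Metadata columns to predict (default: the
#'   concentrations, productivities and yields present, plus
#'   `observed_asvs`).
#' @param nonhrt_parameters Parameters whose non-HRT sets define the
#'   time-independent subtraction (default C6 and C8 productivity).
#' @param replicate_parameters Gated parameters for which the replicate
#'   RRMSE protocol is run (default same as `nonhrt_parameters`).
#' @param spec An [rf_spec()].
#' @param variance_gate Explained-variance gate in percent (default 80).
#' @param rrmse_cutoff Predictability cutoff in percent (default 10).
#' @param n_replicates Replicates of the subsampled-RRMSE protocol
#'   (default 100).
#' @param hrt_subsample,nonhrt_subsample ASVs drawn per replicate from the
#'   HRT set (default 4) and from non-HRT sets (default 5).
#' @param ground_truth Optional planted truth from [simulate_experiment()];
#'   adds recovery metrics to the report.
#' @return A `workflow_report` list; see Details in the package vignette.
#' @export
run_two_step_workflow <- function(abundance, metadata,
                                  parameters = NULL,
                                  nonhrt_parameters = c("prod_C6", "prod_C8"),
                                  replicate_parameters = nonhrt_parameters,
                                  spec = rf_spec(),
                                  variance_gate = 80, rrmse_cutoff = 10,
                                  n_replicates = 100,
                                  hrt_subsample = 4, nonhrt_subsample = 5,
                                  ground_truth = NULL) {
  stopifnot(inherits(abundance, "abund_table"), is.data.frame(metadata))
  if (!all(c("interval", "hrt_label") %in% names(metadata))) {
    metadata <- assign_interval_and_label(metadata)
  }
  miss <- setdiff(rownames(abundance), metadata$sample_id)
  if (length(miss)) stop("samples missing from metadata: ",
                         paste(miss, collapse = ", "))
  metadata <- metadata[match(rownames(abundance), metadata$sample_id), ]
  metadata$observed_asvs <- unname(observed_asvs(abundance))
  rel <- if (abund_mode(abundance) == "counts") to_relative(abundance) else abundance
  if (is.null(parameters)) {
    parameters <- c(grep("^(conc|prod|yield)_", names(metadata), value = TRUE),
                    "observed_asvs")
  }
  reactors <- sort(unique(metadata$reactor))
  if (length(reactors) != 2) stop("workflow expects exactly two reactors")
  labeled <- !is.na(metadata$hrt_label)

  rows_of <- function(r, only_labeled = TRUE) {
    which(metadata$reactor == r & (labeled | !only_labeled))
  }
  feat <- function(rows) unclass(rel)[rows, , drop = FALSE]

  ## ---- step 1: HRT bioindicator selection ------------------------------
  sets <- list(); traces <- list(); accuracy <- list()
  for (r in reactors) {
    tr <- rows_of(r)
    other <- setdiff(reactors, r)
    te <- rows_of(other)
    trace <- recursive_gini_elimination(feat(tr), metadata$hrt_label[tr], spec)
    traces[[r]] <- trace
    sets[[r]] <- select_bioindicators(trace, reactor = r)
    full_model <- train_hrt_classifier(feat(tr), metadata$hrt_label[tr], spec)
    accuracy[[paste0(r, "->", other)]] <-
      classify_heldout(full_model, feat(te), metadata$hrt_label[te])$accuracy
  }
  shared <- shared_set(sets[[reactors[1]]], sets[[reactors[2]]])

  ## ---- step 2: regression, gates, non-HRT sets -------------------------
  orient <- list(c(train = reactors[1], test = reactors[2]),
                 c(train = reactors[2], test = reactors[1]))
  step2 <- list(); nonhrt <- list()
  for (p in parameters) {
    if (anyNA(metadata[[p]][labeled])) {
      stop("parameter ", p, " has missing values on labeled samples")
    }
    reports <- list(); allphase <- list()
    for (o in orient) {
      tr <- rows_of(o[["train"]]); te <- rows_of(o[["test"]])
      key <- paste0(o[["train"]], "->", o[["test"]])
      reports[[key]] <- rf_regress(
        feat(tr), metadata[[p]][tr], feat(te), metadata[[p]][te],
        asv_ids = shared$asv_id, spec = spec, parameter = p)
      te_all <- rows_of(o[["test"]], only_labeled = FALSE)
      allphase[[key]] <- rf_regress(
        feat(tr), metadata[[p]][tr], feat(te_all), metadata[[p]][te_all],
        asv_ids = shared$asv_id, spec = spec, parameter = p)
    }
    pooled <- which(labeled)
    nh <- select_nonhrt_bioindicators(feat(pooled), metadata[[p]][pooled],
                                      spec = spec, parameter = p,
                                      reactor = paste(reactors, collapse = "+"))
    nonhrt[[p]] <- nh
    # the gate asks the non-HRT set, like the HRT set, to explain > 80% of
    # the training variance in both orientations
    nh_ev <- vapply(orient, function(o) {
      tr <- rows_of(o[["train"]]); te <- rows_of(o[["test"]])
      rf_regress(feat(tr), metadata[[p]][tr], feat(te), metadata[[p]][te],
                 asv_ids = nh$asv_id, spec = spec,
                 parameter = p)$explained_variance_train
    }, 0)
    names(nh_ev) <- vapply(orient, function(o)
      paste0(o[["train"]], "->", o[["test"]]), "")
    hrt_ev <- vapply(reports, `[[`, 0, "explained_variance_train")
    step2[[p]] <- list(
      reports = reports, allphase = allphase,
      explained_variance_hrt = hrt_ev,
      explained_variance_nonhrt = nh_ev,
      passes_gate = all(hrt_ev > variance_gate) && all(nh_ev > variance_gate))
  }

  time_indep <- time_independent_set(shared, nonhrt[nonhrt_parameters])

  ## ---- replicate RRMSE protocol on gated parameters --------------------
  replicate <- list()
  for (p in intersect(replicate_parameters, parameters)) {
    if (!step2[[p]]$passes_gate) next
    per_orient <- list()
    for (o in orient) {
      tr <- rows_of(o[["train"]]); te <- rows_of(o[["test"]])
      key <- paste0(o[["train"]], "->", o[["test"]])
      per_orient[[key]] <- list(
        hrt = replicate_rrmse(
          feat(tr), metadata[[p]][tr], feat(te), metadata[[p]][te],
          set = shared, n_replicates = n_replicates,
          subsample_size = min(hrt_subsample, nrow(shared)), spec = spec,
          parameter = p, rrmse_cutoff = rrmse_cutoff),
        nonhrt = replicate_rrmse(
          feat(tr), metadata[[p]][tr], feat(te), metadata[[p]][te],
          set = nonhrt[[p]], n_replicates = n_replicates,
          subsample_size = nonhrt_subsample, spec = spec,
          parameter = p, rrmse_cutoff = rrmse_cutoff))
    }
    replicate[[p]] <- per_orient
  }

  ## ---- ground-truth recovery -------------------------------------------
  recovery <- NULL
  if (!is.null(ground_truth)) {
    recovery <- list(
      responders_in_shared = sum(ground_truth$responders %in% shared$asv_id),
      n_responders = length(ground_truth$responders),
      time_independent_recovered =
        sum(ground_truth$time_independent %in% time_indep$asv_id),
      n_time_independent = length(ground_truth$time_independent))
  }

  structure(list(
    reactors = reactors,
    hrt_sets = sets, shared_set = shared, traces = traces,
    heldout_accuracy = unlist(accuracy),
    step2 = step2, nonhrt_sets = nonhrt,
    time_independent = time_indep,
    replicate = replicate, recovery = recovery,
    labeled_counts = table(metadata$hrt_label[labeled]),
    settings = list(spec = spec, variance_gate = variance_gate,
                    rrmse_cutoff = rrmse_cutoff,
                    n_replicates = n_replicates,
                    parameters = parameters,
                    nonhrt_parameters = nonhrt_parameters)
  ), class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report>\n")
  cat("  held-out accuracy:",
      paste(names(x$heldout_accuracy),
            format(x$heldout_accuracy, digits = 3), collapse = ", "), "\n")
  cat("  shared HRT bioindicators:", nrow(x$shared_set), "\n")
  cat("  time-independent:", nrow(x$time_independent),
      paste0("(", paste(x$time_independent$asv_id, collapse = ", "), ")"), "\n")
  gated <- names(Filter(function(p) p$passes_gate, x$step2))
  cat("  parameters passing the 80% variance gate:",
      if (length(gated)) paste(gated, collapse = ", ") else "none", "\n")
  for (p in names(x$replicate)) {
    for (o in names(x$replicate[[p]])) {
      cat(sprintf("  %s %s: mean RRMSE %.2f%% (HRT set), %.2f%% (non-HRT)\n",
                  p, o, x$replicate[[p]][[o]]$hrt$mean_rrmse,
                  x$replicate[[p]][[o]]$nonhrt$mean_rrmse))
    }
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  ground truth: %d/%d responders in shared set, %d/%d time-independent recovered\n",
                x$recovery$responders_in_shared, x$recovery$n_responders,
                x$recovery$time_independent_recovered,
                x$recovery$n_time_independent))
  }
  invisible(x)
}
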