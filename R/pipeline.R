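#' Cross-validate the three input tables
#'
#' Checks that abundance sample ids match the metadata, that every abundance
#' ASV is present in the taxonomy, and summarizes the labeled-interval class
#' balance (e.g. 14 vs 40 samples for HRT 8 d vs 2 d on the study layout).
#'
#' @param abundance An [abundance_table()].
#' @param metadata Data frame from [read_metadata()].
#' @param taxonomy Optional data frame from [read_taxonomy()].
#' @return List: `n_samples`, `n_asvs`, `labeled_counts` (named HRT8/HRT2),
#'   `reactors`. Errors describe any id mismatch.
#' @export
validate_inputs <- function(abundance, metadata, taxonomy = NULL) {
  stopifnot(inherits(abundance, "abund_table"))
  a_ids <- rownames(abundance)
  only_a <- setdiff(a_ids, metadata$sample_id)
  only_m <- setdiff(metadata$sample_id, a_ids)
  if (length(only_a) || length(only_m)) {
    stop("sample id mismatch; only in abundance: [",
         paste(only_a, collapse = ", "), "]; only in metadata: [",
         paste(only_m, collapse = ", "), "]")
  }
  if (!is.null(taxonomy)) {
    miss <- setdiff(colnames(abundance), taxonomy$asv_id)
    if (length(miss)) stop("ASV(s) missing from taxonomy: ",
                           paste(miss, collapse = ", "))
  }
  md <- if ("hrt_label" %in% names(metadata)) metadata
        else assign_interval_and_label(metadata)
  lc <- table(md$hrt_label)
  list(n_samples = nrow(abundance), n_asvs = ncol(abundance),
       labeled_counts = c(HRT8 = unname(lc["HRT8"]), HRT2 = unname(lc["HRT2"])),
       reactors = table(md$reactor))
}

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (directory holding `abundance.tsv`,
#' `metadata.tsv`, `taxonomy.tsv`) or `simulation` (a
#' [simulation_config()]) must be given.
#'
#' @param out_dir Output directory.
#' @param input_dir Directory of input tables, or `NULL` to simulate.
#' @param simulation A [simulation_config()], or `NULL` to read inputs.
#' @param seed Master seed recorded in every output (default 42).
#' @param rarefaction_depth Depth for [rarefy()]; `NULL` skips rarefaction
#'   (appropriate for simulated tables already at even depth).
#' @param n_permutations PERMANOVA permutations (default 1000).
#' @param rf Classifier/regressor settings, an [rf_spec()].
#' @param parameters,nonhrt_parameters,replicate_parameters Passed to
#'   [run_two_step_workflow()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, simulation = NULL,
                            seed = 42, rarefaction_depth = NULL,
                            n_permutations = 1000, rf = rf_spec(seed = seed),
                            parameters = NULL,
                            nonhrt_parameters = c("prod_C6", "prod_C8"),
                            replicate_parameters = nonhrt_parameters) {
  if (is.null(input_dir) == is.null(simulation)) {
    stop("exactly one of `input_dir` or `simulation` must be given")
  }
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulation = simulation, seed = seed,
                 rarefaction_depth = rarefaction_depth,
                 n_permutations = n_permutations, rf = rf,
                 parameters = parameters,
                 nonhrt_parameters = nonhrt_parameters,
                 replicate_parameters = replicate_parameters),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulation`
#' mapping is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  if (!is.null(y$rf)) y$rf <- do.call(rf_spec, y$rf)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the two-reactor dataset, then run diversity statistics
#' (alpha diversity, Bray-Curtis, NMDS, PERMANOVA on the labeled HRT
#' classes), the two-step bioindicator workflow and the co-occurrence
#' network, writing all tables, a JSON report and a manifest with md5
#' hashes under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the in-memory result bundle (elements `data`,
#'   `diversity`, `workflow`, `network`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tables_dir <- file.path(config$out_dir, "tables")
  reports_dir <- file.path(config$out_dir, "reports")
  for (d in c(tables_dir, reports_dir)) {
    dir.create(d, showWarnings = FALSE)
  }

  ## ---- inputs ----------------------------------------------------------
  if (!is.null(config$simulation)) {
    bundle <- simulate_experiment(config$simulation)
  } else {
    bundle <- list(
      abundance = read_abundance_table(file.path(config$input_dir, "abundance.tsv")),
      metadata = read_metadata(file.path(config$input_dir, "metadata.tsv")),
      taxonomy = {
        tp <- file.path(config$input_dir, "taxonomy.tsv")
        if (file.exists(tp)) read_taxonomy(tp) else NULL
      },
      ground_truth = NULL)
  }
  validate_inputs(bundle$abundance, bundle$metadata, bundle$taxonomy)
  counts <- bundle$abundance
  if (!is.null(config$rarefaction_depth) && abund_mode(counts) == "counts") {
    counts <- rarefy(counts, config$rarefaction_depth, seed = config$seed)
    bundle$metadata <- bundle$metadata[
      match(rownames(counts), bundle$metadata$sample_id), ]
  }
  md <- bundle$metadata
  if (!all(c("interval", "hrt_label") %in% names(md))) {
    md <- assign_interval_and_label(md)
  }

  ## ---- diversity -------------------------------------------------------
  alpha <- data.frame(sample_id = rownames(counts),
                      observed_asvs = unname(observed_asvs(counts)),
                      shannon = unname(shannon(counts)))
  dm <- bray_curtis(counts)
  ord <- nmds(dm, seed = config$seed)
  labeled <- !is.na(md$hrt_label)
  perm_hrt <- permanova(as.matrix(dm)[labeled, labeled],
                        md$hrt_label[labeled],
                        n_permutations = config$n_permutations,
                        seed = config$seed)
  # reactor effect, restricted to samples at matching HRT (labeled intervals)
  perm_reactor <- permanova(as.matrix(dm)[labeled, labeled],
                            md$reactor[labeled],
                            n_permutations = config$n_permutations,
                            seed = config$seed)
  diversity <- list(alpha = alpha, distance = dm, nmds = ord,
                    permanova_hrt = perm_hrt,
                    permanova_reactor = perm_reactor)

  ## ---- two-step workflow ----------------------------------------------
  wf <- run_two_step_workflow(
    counts, md, parameters = config$parameters,
    nonhrt_parameters = config$nonhrt_parameters,
    replicate_parameters = config$replicate_parameters,
    spec = config$rf, ground_truth = bundle$ground_truth)

  ## ---- co-occurrence network ------------------------------------------
  abiotic_cols <- intersect(
    c("hrt", "conc_C4", "conc_C6", "conc_C8", "conc_lactate",
      grep("^(prod|yield)_C[468]$", names(md), value = TRUE)),
    names(md))
  netmat <- cbind(unclass(counts), as.matrix(md[, abiotic_cols, drop = FALSE]))
  sp <- spearman_matrix(netmat)
  net <- build_network(sp$rho, sp$p, taxonomy = bundle$taxonomy)

  ## ---- outputs ---------------------------------------------------------
  write_abundance_table(counts, file.path(tables_dir, "rarefied_abundance.tsv"))
  utils::write.table(alpha, file.path(tables_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(ord$points), ord$points),
                     file.path(tables_dir, "nmds_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(dm), as.data.frame(dm)),
                     file.path(tables_dir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (r in names(wf$hrt_sets)) {
    write_bioindicator_set(wf$hrt_sets[[r]],
                           file.path(tables_dir, paste0(r, "_hrt_bioindicators.tsv")),
                           taxonomy = bundle$taxonomy)
  }
  write_bioindicator_set(wf$shared_set,
                         file.path(tables_dir, "shared_hrt_bioindicators.tsv"),
                         taxonomy = bundle$taxonomy)
  write_bioindicator_set(wf$time_independent,
                         file.path(tables_dir, "time_independent_bioindicators.tsv"),
                         taxonomy = bundle$taxonomy)
  write_edge_list(net, file.path(tables_dir, "network_edges.tsv"))
  export_gexf(net, file.path(tables_dir, "network.gexf"))

  report <- list(
    seed = config$seed,
    permanova = list(hrt = list(pseudo_F = perm_hrt$pseudo_F,
                                p_value = perm_hrt$p_value),
                     reactor = list(pseudo_F = perm_reactor$pseudo_F,
                                    p_value = perm_reactor$p_value)),
    nmds_stress = ord$stress,
    heldout_accuracy = as.list(wf$heldout_accuracy),
    shared_hrt_bioindicators = wf$shared_set$asv_id,
    time_independent = wf$time_independent$asv_id,
    gate = lapply(wf$step2, function(p)
      list(passes = p$passes_gate,
           explained_variance_hrt = as.list(p$explained_variance_hrt))),
    replicate_rrmse = lapply(wf$replicate, function(p)
      lapply(p, function(o) list(hrt = o$hrt$mean_rrmse,
                                 nonhrt = o$nonhrt$mean_rrmse))),
    recovery = wf$recovery,
    network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                   hubs = network_hubs(net)$id))
  report_path <- file.path(reports_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- data.frame(
    file = sub(paste0("^", config$out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = config$seed, files = manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = bundle, diversity = diversity, workflow = wf,
                 network = net, manifest = manifest))
}
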