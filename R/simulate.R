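#' Configuration for the two-reactor synthetic experiment
#'
#' Describes a simulated pair of semi-continuous chain-elongation bioreactors
#' sampled in parallel over a 211-day operation. Reactor A steps its
#' hydraulic retention time (HRT) down gradually (8 -> 6 -> 4 -> 2 days at
#' days 51/101/141); reactor B stays at 8 days until day 140 and then drops
#' straight to 2 days. A planted subset of ASVs responds to the HRT regime;
#' a second, disjoint subset drifts monotonically with time to confound
#' HRT-response with community assembly over time.
#'
#' @param n_asvs Number of ASVs (default 71).
#' @param n_timepoints Sampling time points per reactor (default 59); the
#'   default calendar spaces them evenly over days 0..211 and rounds to
#'   integer days.
#' @param days Optional explicit vector of sampling days (overrides
#'   `n_timepoints`).
#' @param n_responders Number of HRT-responding ASVs (default 11).
#' @param overlap_time_independent How many responders are left out of the
#'   productivity coupling so that they respond to HRT but do not predict the
#'   process parameters (default 4); these are the planted "HRT bioindicators
#'   irrespective of time".
#' @param n_drift Number of non-responding ASVs with a monotone time trend
#'   (default 12).
#' @param effect_size Log-scale abundance shift of responders between the
#'   8-day and 2-day HRT regimes (default 2 log units).
#' @param ar1_rho Temporal autocorrelation of the latent log-abundance
#'   deviations, in `[0, 1)` (default 0.6).
#' @param noise_sd Stationary standard deviation of those deviations on the
#'   log scale (default 0.3).
#' @param read_depth Reads per sample for the multinomial sequencing draw
#'   (default 13518).
#' @param prod_noise_cv Multiplicative coefficient of variation of the
#'   process-parameter measurement noise (default 0.02).
#' @param transition_days Width of the logistic regime response of the
#'   time-independent responders after an HRT shift (default 7 d): they
#'   switch with the regime itself.
#' @param adaptation_days Width of the logistic response of the coupled
#'   responders — and of the process performance they drive — after an HRT
#'   shift (default 14 d), the visible adaptation lag of the process.
#' @param drift_magnitude Total log-scale drift of time-trend ASVs over the
#'   run (default 0.8).
#' @param seed Master seed; all substreams (abundances, reads, noise,
#'   coupling) derive from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_asvs = 71, n_timepoints = 59, days = NULL,
                              n_responders = 11, overlap_time_independent = 4,
                              n_drift = 12, effect_size = 2, ar1_rho = 0.6,
                              noise_sd = 0.3, read_depth = 13518,
                              prod_noise_cv = 0.02, transition_days = 7,
                              adaptation_days = 14, drift_magnitude = 0.8,
                              seed = 42) {
  if (is.null(days)) days <- unique(round(seq(0, 211, length.out = n_timepoints)))
  stopifnot(n_responders <= n_asvs,
            overlap_time_independent <= n_responders,
            n_drift <= n_asvs - n_responders,
            ar1_rho >= 0, ar1_rho < 1,
            effect_size >= 0,
            all(days >= 0), all(days <= 211))
  if (read_depth <= 0) stop("`read_depth` must be positive")
  structure(list(
    n_asvs = n_asvs, days = days, n_responders = n_responders,
    overlap_time_independent = overlap_time_independent, n_drift = n_drift,
    effect_size = effect_size, ar1_rho = ar1_rho, noise_sd = noise_sd,
    read_depth = read_depth, prod_noise_cv = prod_noise_cv,
    transition_days = transition_days, adaptation_days = adaptation_days,
    drift_magnitude = drift_magnitude, seed = seed
  ), class = "sim_config")
}

#' HRT operating schedule of the two reactors
#'
#' Reactor A: 8 d (days 0-50), 6 d (51-100), 4 d (101-140), 2 d (141-211).
#' Reactor B: 8 d until day 140, then 2 d.
#'
#' @param reactor `"A"` or `"B"`.
#' @param day Numeric day(s) in `[0, 211]`.
#' @return HRT in days.
#' @export
hrt_schedule <- function(reactor, day) {
  reactor <- match.arg(reactor, c("A", "B"))
  if (reactor == "A") {
    ifelse(day <= 50, 8, ifelse(day <= 100, 6, ifelse(day <= 140, 4, 2)))
  } else {
    ifelse(day <= 140, 8, 2)
  }
}

# Smoothed HRT-regime signal in [0, 1]: 0 at HRT 8 d, 1 at HRT 2 d, with a
# causal logistic response of ~`width` days starting at each HRT step change.
.regime_signal <- function(reactor, day, width) {
  steps <- if (reactor == "A") {
    data.frame(at = c(51, 101, 141), to = (8 - c(6, 4, 2)) / 6)
  } else {
    data.frame(at = 141, to = 1)
  }
  s <- rep(0, length(day))
  from <- 0
  for (i in seq_len(nrow(steps))) {
    s <- s + (steps$to[i] - from) * stats::plogis(day - steps$at[i] - width / 2,
                                                  scale = width / 4)
    from <- steps$to[i]
  }
  s
}

# genus pool for the synthetic taxonomy; the four time-independent planted
# responders get the chain-elongation guild genera in order
.genus_pool <- c("Olsenella", "Lactobacillus", "Syntrophococcus", "Clostridium IV",
                 "Caproiciproducens", "Pseudoramibacter", "Megasphaera",
                 "Prevotella", "Ruminococcus", "Bifidobacterium",
                 "Clostridium sensu stricto", "Eubacterium", "Bacteroides",
                 "Acetobacterium", "Oscillibacter")

#' Simulate a two-reactor chain-elongation experiment
#'
#' Generates an ASV read-count table, per-sample process metadata and the
#' planted ground truth. Latent log-abundances follow an AR(1) process around
#' an ASV baseline; responder baselines shift by `effect_size` with the
#' smoothed HRT-regime signal; drift ASVs move monotonically with day.
#' Per-sample compositions are closed to one and sequenced as a multinomial
#' draw at `read_depth`. C4/C6/C8 productivities are linear in the latent
#' relative abundances of the coupled responders, with a smaller
#' community-assembly term over the drift ASVs, times multiplicative noise;
#' concentrations are productivity x HRT; yields are concentration over the
#' feed carbon with truncated Gaussian noise; lactate concentration is
#' negatively coupled to C4 to mimic its consumption by chain elongation.
#'
#' @param config A [simulation_config()].
#' @return List with elements `abundance` (counts [abundance_table()]),
#'   `metadata` (data frame with HRT, interval, label and process columns),
#'   `taxonomy` (synthetic genus assignments) and `ground_truth` (list:
#'   `responders`, `time_independent`, `drift`, `coupling`, plus the latent
#'   relative abundances).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub <- sample.int(2^31 - 2, 4) # substreams: layout, abundance, reads, process

  n <- config$n_asvs
  asv_ids <- sprintf("ASV%03d", seq_len(n))
  days <- config$days

  # --- layout: which ASVs respond, drift, couple -------------------------
  set.seed(sub[1])
  responders <- sort(sample(asv_ids, config$n_responders))
  time_indep <- sort(sample(responders, config$overlap_time_independent))
  coupled <- setdiff(responders, time_indep)
  drift <- sort(sample(setdiff(asv_ids, responders), config$n_drift))
  # responders are moderately abundant taxa (bioindicators of the process);
  # the bulk community spans a wider log-abundance range
  baseline <- stats::rnorm(n, 0, 1.5)
  names(baseline) <- asv_ids
  baseline[responders] <- stats::rnorm(length(responders), 0, 0.7)
  baseline[coupled] <- baseline[coupled] + 0.5
  # coupled responders (the producer guild) increase in relative abundance
  # as the HRT shortens, identically in both reactors; the time-independent
  # responders reorganize with lineage-dependent direction and magnitude
  # (founder effects and competitive exclusion between the two reactor
  # lineages), so each reactor's classifier sees them as crisp regime
  # markers while they carry no consistent quantitative process signal
  resp_sign <- stats::setNames(rep(1, length(responders)), responders)
  ti_magnitude <- matrix(stats::runif(2 * length(time_indep), 0.8, 1.4),
                         nrow = 2, dimnames = list(c("A", "B"), time_indep))
  ti_positive_in_A <- sample(c(TRUE, FALSE), length(time_indep), replace = TRUE)
  ti_magnitude["A", ] <- ti_magnitude["A", ] * ifelse(ti_positive_in_A, 1, -1)
  ti_magnitude["B", ] <- ti_magnitude["B", ] * ifelse(ti_positive_in_A, -1, 1)
  drift_sign <- stats::setNames(
    sample(c(1, -1), length(drift), replace = TRUE), drift)
  # productivity couples linearly to the coupled responders (the direct
  # producers) and, with smaller weight, to the drift ASVs (community
  # assembly over time), so non-HRT bioindicator discovery has a genuine
  # time-coupled signal to find
  coupling <- list(
    C4 = list(b0 = 60,  k = 700, kd = 350, w = stats::runif(length(coupled), 0.5, 1.5)),
    C6 = list(b0 = 18,  k = 500, kd = 250, w = stats::runif(length(coupled), 0.5, 1.5)),
    C8 = list(b0 = 2,   k = 55,  kd = 28,  w = stats::runif(length(coupled), 0.5, 1.5))
  )
  for (p in names(coupling)) {
    names(coupling[[p]]$w) <- coupled
    # skewed weights: a few drift taxa carry most of the assembly signal
    coupling[[p]]$wd <- stats::setNames(
      stats::rexp(length(drift)) + 0.1, drift)
  }

  # --- latent log-abundances and compositions ----------------------------
  set.seed(sub[2])
  samples <- expand.grid(day = days, reactor = c("A", "B"),
                         stringsAsFactors = FALSE)[, c("reactor", "day")]
  samples <- samples[order(samples$reactor, samples$day), ]
  sample_ids <- sprintf("%s_d%03d", samples$reactor, samples$day)
  latent_rel <- matrix(0, nrow(samples), n,
                       dimnames = list(sample_ids, asv_ids))
  for (r in c("A", "B")) {
    rows <- which(samples$reactor == r)
    d <- samples$day[rows]
    s_fast <- .regime_signal(r, d, config$transition_days)
    s_slow <- .regime_signal(r, d, config$adaptation_days)
    mu <- matrix(baseline, length(d), n, byrow = TRUE)
    for (a in responders) {
      s <- if (a %in% time_indep) s_fast * ti_magnitude[r, a] else s_slow
      mu[, a == asv_ids] <- mu[, a == asv_ids] +
        resp_sign[a] * config$effect_size * s
    }
    for (a in drift) {
      mu[, a == asv_ids] <- mu[, a == asv_ids] +
        drift_sign[a] * config$drift_magnitude * d / 211
    }
    # stationary AR(1) deviations, innovation sd chosen for stationary
    # sd == noise_sd
    e <- matrix(0, length(d), n)
    e[1, ] <- stats::rnorm(n, 0, config$noise_sd)
    if (length(d) > 1) {
      inn <- config$noise_sd * sqrt(1 - config$ar1_rho^2)
      for (t in 2:length(d)) {
        e[t, ] <- config$ar1_rho * e[t - 1, ] + stats::rnorm(n, 0, inn)
      }
    }
    lat <- exp(mu + e)
    latent_rel[rows, ] <- lat / rowSums(lat)
  }

  # --- sequencing: multinomial reads at fixed depth ----------------------
  set.seed(sub[3])
  counts <- t(apply(latent_rel, 1, function(p) {
    stats::rmultinom(1, config$read_depth, p)[, 1]
  }))
  dimnames(counts) <- dimnames(latent_rel)
  storage.mode(counts) <- "double"

  # --- process parameters ------------------------------------------------
  set.seed(sub[4])
  hrt <- hrt_schedule_vec(samples$reactor, samples$day)
  md <- data.frame(sample_id = sample_ids, reactor = samples$reactor,
                   day = samples$day, hrt = hrt, stringsAsFactors = FALSE)
  feed_cmol <- 770 # feed carbon, mmol C per litre of feed medium
  mnoise <- function(m) exp(stats::rnorm(length(m), 0, config$prod_noise_cv))
  for (p in c("C4", "C6", "C8")) {
    cp <- coupling[[p]]
    wm <- as.vector(latent_rel[, coupled, drop = FALSE] %*% cp$w) / sum(cp$w)
    wmd <- if (length(drift)) {
      as.vector(latent_rel[, drift, drop = FALSE] %*% cp$wd) / sum(cp$wd)
    } else {
      0
    }
    prod <- (cp$b0 + cp$k * wm + cp$kd * wmd) * mnoise(wm)
    md[[paste0("prod_", p)]] <- prod
    md[[paste0("conc_", p)]] <- prod * hrt
    md[[paste0("yield_", p)]] <- pmax(0, prod * hrt / feed_cmol +
                                        stats::rnorm(length(prod), 0, 0.01))
  }
  md$conc_lactate <- pmax(0, 50 - 0.4 * md$prod_C4 +
                            stats::rnorm(nrow(md), 0, 2))
  md <- assign_interval_and_label(md)

  # --- synthetic taxonomy ------------------------------------------------
  genus <- rep("unclassified", n)
  names(genus) <- asv_ids
  genus[time_indep] <- .genus_pool[seq_along(time_indep)]
  others <- setdiff(asv_ids, time_indep)
  pool_rest <- if (length(time_indep)) {
    .genus_pool[-seq_along(time_indep)]
  } else {
    .genus_pool
  }
  genus[others] <- sample(pool_rest, length(others), replace = TRUE)
  taxonomy <- data.frame(asv_id = asv_ids, phylum = "Firmicutes",
                         class = "Clostridia", order = "unclassified",
                         family = "unclassified", genus = unname(genus),
                         stringsAsFactors = FALSE)

  list(
    abundance = abundance_table(counts, mode = "counts"),
    metadata = md,
    taxonomy = taxonomy,
    ground_truth = list(
      responders = responders,
      time_independent = time_indep,
      coupled = coupled,
      drift = drift,
      responder_sign = resp_sign,
      ti_magnitude = ti_magnitude,
      coupling = coupling,
      latent_relative = latent_rel
    ),
    config = config
  )
}

#' @rdname hrt_schedule
#' @export
hrt_schedule_vec <- function(reactor, day) {
  out <- numeric(length(day))
  for (r in unique(reactor)) {
    i <- reactor == r
    out[i] <- hrt_schedule(r, day[i])
  }
  out
}

#' Write a simulated bundle to standard fixture files
#'
#' Emits `abundance.tsv`, `metadata.tsv` and `taxonomy.tsv` in the formats
#' consumed by [read_abundance_table()], [read_metadata()] and
#' [read_taxonomy()], plus a `ground_truth.json` sidecar recording the
#' planted structure. Output is byte-identical across runs with the same
#' configuration seed.
#'
#' @param bundle Result of [simulate_experiment()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  paths <- c(abundance = file.path(out_dir, "abundance.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  write_abundance_table(bundle$abundance, paths["abundance"])
  md <- bundle$metadata
  md$interval <- as.character(md$interval)
  md$hrt_label <- as.character(md$hrt_label)
  utils::write.table(md, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- bundle$ground_truth
  gt$latent_relative <- NULL
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
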