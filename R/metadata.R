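#' Carbon atoms per molecule for the fermentation compounds
#'
#' C-mol bookkeeping basis: lactate 3, acetate 2, n-butyrate (C4) 4,
#' n-caproate (C6) 6, n-caprylate (C8) 8, xylose 5. All concentrations and
#' productivities in this package are expressed in mmol carbon per litre
#' (mmol C L^-1), so compound amounts in mmol are converted through this
#' table.
#'
#' @return Named integer vector of carbon counts.
#' @export
carbon_spec <- function() {
  c(lactate = 3L, acetate = 2L, C4 = 4L, C6 = 6L, C8 = 8L, xylose = 5L)
}

#' Convert mmol of a compound to mmol carbon
#'
#' @param mmol Amount in mmol (non-negative).
#' @param compound Compound name present in [carbon_spec()].
#' @param spec Carbon table, defaults to [carbon_spec()].
#' @return Amount in mmol C.
#' @examples
#' mmol_to_cmol(10, "C6") # 60 mmol C
#' @export
mmol_to_cmol <- function(mmol, compound, spec = carbon_spec()) {
  if (!compound %in% names(spec)) stop("unknown compound: ", compound)
  if (any(mmol < 0)) stop("negative amount")
  mmol * spec[[compound]]
}

#' Volumetric productivity from concentration and HRT
#'
#' For a semi-continuous stirred tank at (quasi) steady state, the daily
#' feed-and-draw replaces a fraction 1/HRT of the working volume, so the
#' volumetric productivity of a product accumulating to concentration `conc`
#' is `conc / hrt` (mmol C L^-1 d^-1).
#'
#' @param conc Concentration in mmol C L^-1 (non-negative).
#' @param hrt Hydraulic retention time in days (positive).
#' @return Productivity in mmol C L^-1 d^-1.
#' @export
derive_productivity <- function(conc, hrt) {
  if (any(hrt <= 0)) stop("`hrt` must be positive")
  if (any(conc < 0)) stop("negative concentration")
  conc / hrt
}

#' Product yield on a C-mol basis
#'
#' Ratio of product carbon formed to substrate carbon consumed
#' (C-mol product per C-mol substrate, dimensionless).
#'
#' @param product_cmol Product formed, mmol C (non-negative).
#' @param substrate_consumed_cmol Substrate consumed, mmol C (positive).
#' @return Dimensionless yield.
#' @export
derive_yield <- function(product_cmol, substrate_consumed_cmol) {
  if (any(substrate_consumed_cmol <= 0)) stop("substrate consumption must be positive")
  if (any(product_cmol < 0)) stop("negative product amount")
  product_cmol / substrate_consumed_cmol
}

# Sampling-interval boundaries (days); closed ranges as printed in the
# operation schedule: 0-50, 51-100, 101-140, 141-211.
.interval_levels <- c("0-50", "51-100", "101-140", "141-211")

#' Assign sampling intervals and HRT class labels
#'
#' The 211-day operation is divided into four sampling intervals (0-50,
#' 51-100, 101-140 and 141-211 days). Samples in the first interval carry the
#' classification label `HRT8` and samples in the last carry `HRT2`; the two
#' middle (transition) intervals are unlabeled and serve only as all-phase
#' controls.
#'
#' @param metadata Data frame with at least a numeric `day` column in
#'   `[0, 211]`.
#' @return `metadata` with columns `interval` (factor with the four interval
#'   levels) and `hrt_label` (factor `HRT8`/`HRT2`, `NA` for transition
#'   intervals).
#' @export
assign_interval_and_label <- function(metadata) {
  stopifnot(is.data.frame(metadata), "day" %in% names(metadata))
  day <- metadata$day
  if (any(is.na(day)) || any(day < 0) || any(day > 211)) {
    stop("`day` must lie within the 0-211 d operation schedule")
  }
  idx <- findInterval(day, c(0, 50, 100, 140), left.open = TRUE) # day 50 -> 1
  idx[day == 0] <- 1L
  metadata$interval <- factor(.interval_levels[idx], levels = .interval_levels)
  lab <- rep(NA_character_, nrow(metadata))
  lab[idx == 1L] <- "HRT8"
  lab[idx == 4L] <- "HRT2"
  metadata$hrt_label <- factor(lab, levels = c("HRT8", "HRT2"))
  metadata
}

#' Read sample metadata
#'
#' Reads the per-sample process table (tab- or comma-separated). Required
#' columns: `sample_id`, `reactor`, `day`, `hrt`. Optional columns follow the
#' fixed naming `conc_<p>`, `prod_<p>`, `yield_<p>` for products
#' `lactate`, `C4`, `C6`, `C8` (concentrations in mmol C L^-1,
#' productivities in mmol C L^-1 d^-1, yields dimensionless), plus
#' `cell_mass` (g L^-1). Missing productivity columns are derived as
#' concentration / HRT. Sampling intervals and HRT labels are assigned.
#'
#' @param path File path.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return Data frame with `interval` and `hrt_label` columns added.
#' @export
read_metadata <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "reactor", "day", "hrt")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (any(md$hrt <= 0)) stop("`hrt` must be positive")
  num <- grep("^(conc|prod|yield)_|^cell_mass$", names(md), value = TRUE)
  for (cl in num) {
    if (any(md[[cl]] < 0, na.rm = TRUE)) stop("negative values in column ", cl)
  }
  # derive productivities from concentration / HRT only when absent
  for (p in c("C4", "C6", "C8", "lactate")) {
    cc <- paste0("conc_", p); pc <- paste0("prod_", p)
    if (cc %in% names(md) && !pc %in% names(md)) {
      md[[pc]] <- derive_productivity(md[[cc]], md$hrt)
    }
  }
  assign_interval_and_label(md)
}

#' Read an ASV taxonomy table
#'
#' Columns: `asv_id` plus any of `phylum`, `class`, `order`, `family`,
#' `genus`. Empty or missing ranks are filled with `"unclassified"`.
#'
#' @param path File path (TSV or CSV by extension).
#' @return Data frame keyed by `asv_id`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tx <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"asv_id" %in% names(tx)) stop("taxonomy table must have an `asv_id` column")
  if (anyDuplicated(tx$asv_id)) stop("duplicate asv_id in taxonomy table")
  for (rk in c("phylum", "class", "order", "family", "genus")) {
    if (!rk %in% names(tx)) tx[[rk]] <- "unclassified"
    tx[[rk]][is.na(tx[[rk]]) | tx[[rk]] == ""] <- "unclassified"
  }
  tx
}
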