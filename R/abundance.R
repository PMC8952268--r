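#' ASV abundance table
#'
#' Container for a samples x ASVs abundance matrix, either raw read counts or
#' per-sample relative abundances. Rows are samples, columns are amplicon
#' sequence variants (ASVs). Relative-mode rows must sum to one.
#'
#' @param values Numeric matrix with unique sample ids as rownames and unique
#'   ASV ids as colnames. No negative entries.
#' @param mode `"counts"`, `"relative"`, or `"auto"` (default). In auto mode
#'   the table is classified as counts when every entry is a whole number,
#'   or relative when every row sums to 1 within 1e-9; anything else is an
#'   error naming the first offending sample.
#' @return An object of class `abund_table`: the matrix with a `mode`
#'   attribute.
#' @examples
#' m <- matrix(c(3, 1, 0, 4), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' tab <- abundance_table(m)
#' abund_mode(tab) # "counts"
#' @export
abundance_table <- function(values, mode = c("auto", "counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x ASVs)")
  }
  if (nrow(values) == 0L) stop("no samples")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample ids as rownames and ASV ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate ASV ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (anyNA(values)) stop("missing values in abundance matrix")
  if (any(values < 0)) stop("negative abundance values are not allowed")

  rs <- rowSums(values)
  if (mode == "auto") {
    if (all(values == floor(values))) {
      mode <- "counts"
    } else if (all(abs(rs - 1) <= 1e-9)) {
      mode <- "relative"
    } else {
      bad <- rownames(values)[which(abs(rs - 1) > 1e-9)[1]]
      stop("cannot infer mode: non-integer entries but row '", bad,
           "' does not sum to 1")
    }
  }
  if (mode == "relative") {
    if (any(abs(rs - 1) > 1e-9)) {
      bad <- rownames(values)[which(abs(rs - 1) > 1e-9)[1]]
      stop("relative-mode row '", bad, "' does not sum to 1 (sum = ", rs[bad], ")")
    }
  }
  structure(values, mode = mode, class = c("abund_table", "matrix", "array"))
}

#' @rdname abundance_table
#' @param x An `abund_table`.
#' @export
abund_mode <- function(x) attr(x, "mode")

#' @export
print.abund_table <- function(x, ...) {
  cat("<abund_table> ", nrow(x), " samples x ", ncol(x), " ASVs (",
      attr(x, "mode"), ")\n", sep = "")
  invisible(x)
}

#' Read and write abundance tables
#'
#' Plain-text readers/writers for the samples x ASVs table. The file has a
#' header row of ASV ids and the first column holds sample ids. Mode (counts
#' vs relative) is inferred as in [abundance_table()]. `write_abundance_table`
#' prints numerics with full precision so a read/write round trip reproduces
#' the values exactly.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return `read_abundance_table`: an [abundance_table()].
#' @export
read_abundance_table <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- ids
  abundance_table(m)
}

#' @rdname read_abundance_table
#' @param table An `abund_table`.
#' @export
write_abundance_table <- function(table, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  m <- unclass(table)
  chr <- if (all(m == floor(m))) {
    matrix(format(m, scientific = FALSE, trim = TRUE), nrow(m))
  } else {
    matrix(formatC(m, digits = 17, format = "g"), nrow(m))
  }
  dimnames(chr) <- dimnames(m)
  df <- data.frame(sample_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table from a BIOM file
#'
#' Thin reader over the `biomformat` package for the standard BIOM
#' interchange format (sparse JSON or HDF5). Read-only.
#'
#' @param path Path to a .biom file.
#' @return An [abundance_table()] (samples x ASVs).
#' @export
read_biom_abundance <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the 'biomformat' package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
  abundance_table(t(m))
}

#' Rarefy a count table to even depth
#'
#' Subsamples every sample's reads without replacement (a multivariate
#' hypergeometric draw per sample, via [vegan::rrarefy()]) so each retained
#' sample totals exactly `depth` reads. Samples with fewer than `depth` reads
#' are dropped with a warning. The draw is deterministic given `seed`.
#'
#' @param table An [abundance_table()] in counts mode.
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed controlling the subsample (default 42).
#' @return A counts-mode `abund_table` whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 42) {
  stopifnot(inherits(table, "abund_table"))
  if (abund_mode(table) != "counts") stop("rarefy() requires a counts-mode table")
  if (length(depth) != 1L || is.na(depth) || depth <= 0 || depth != floor(depth)) {
    stop("`depth` must be a positive integer")
  }
  m <- unclass(table)
  attr(m, "mode") <- NULL
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[!keep], collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  set.seed(seed)
  out <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      # vegan flags tables whose smallest entry exceeds 1 as "not counts";
      # our integer tables are genuine counts, so the advisory is noise
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(out) <- "double"
  abundance_table(out, mode = "counts")
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one. The workflow
#' applies this after rarefaction, so downstream features are rarefied
#' relative abundances.
#'
#' @param table An [abundance_table()] in counts mode.
#' @return A relative-mode `abund_table`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  if (abund_mode(table) == "relative") return(table)
  m <- unclass(table)
  attr(m, "mode") <- NULL
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("all-zero sample(s): ", paste(rownames(m)[rs == 0], collapse = ", "))
  }
  abundance_table(sweep(m, 1, rs, "/"), mode = "relative")
}
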