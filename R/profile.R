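#' Marker-frequency profile container
#'
#' Per-bin relative copy number over a circular chromosome, either predicted
#' by the replication model (`source = "model"`, normalised to 1 at active
#' origins) or derived from sequencing counts (`source = "data"`, mean-scaled
#' to 1). Masked bins (low-coverage control, flagged artifact loci) are `NA`.
#'
#' @param values Numeric vector, one value per bin; `NA` = masked.
#' @param bin_size Bin width in bp.
#' @param length_bp Chromosome length in bp.
#' @param source `"model"` or `"data"`.
#' @param normalisation Free-text provenance of the scaling applied.
#' @return An object of class `mfa_profile`.
#' @export
mfa_profile <- function(values, bin_size, length_bp,
                        source = c("model", "data"), normalisation = "") {
  source <- match.arg(source)
  n <- n_bins(length_bp, bin_size)
  if (length(values) != n)
    stop(sprintf("expected %d bins for length %s at bin size %s, got %d",
                 n, length_bp, bin_size, length(values)))
  if (any(values < 0, na.rm = TRUE)) stop("profile values must be non-negative")
  structure(list(values = as.numeric(values), bin_size = bin_size,
                 length_bp = length_bp, source = source,
                 normalisation = normalisation),
            class = "mfa_profile")
}

#' @export
print.mfa_profile <- function(x, ...) {
  v <- x$values
  cat(sprintf("<mfa_profile> %d bins x %d bp (%s)%s\n  range [%.3g, %.3g], %d masked\n",
              length(v), as.integer(x$bin_size), x$source,
              if (nzchar(x$normalisation)) paste0("; ", x$normalisation) else "",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

same_binning <- function(a, b) {
  a$bin_size == b$bin_size && a$length_bp == b$length_bp &&
    length(a$values %||% a$counts) == length(b$values %||% b$counts)
}

#' Binned read counts
#'
#' @param counts Non-negative integer vector, one count per bin.
#' @param bin_size Bin width in bp.
#' @param length_bp Chromosome length in bp.
#' @param label Sample label.
#' @return An object of class `binned_counts` with `total = sum(counts)`.
#' @export
binned_counts <- function(counts, bin_size, length_bp, label = "") {
  n <- n_bins(length_bp, bin_size)
  if (length(counts) != n) stop("counts length does not match the binning")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = as.numeric(counts), total = sum(counts),
                 bin_size = bin_size, length_bp = length_bp, label = label),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %s: %d bins x %d bp, %s reads\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$counts), as.integer(x$bin_size),
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Mix marker-frequency profiles of cell classes
#'
#' Per-bin weighted sum of class profiles: the population profile of a culture
#' in which a fraction `weights[i]` of cells replicates according to
#' `profiles[[i]]`.
#'
#' @param profiles List of [mfa_profile] objects on identical bins.
#' @param weights Non-negative weights summing to 1.
#' @return An [mfa_profile] with the mixture weights stored as attribute
#'   `"weights"`.
#' @export
mixture_profile <- function(profiles, weights) {
  stopifnot(length(profiles) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  p1 <- profiles[[1]]
  for (p in profiles[-1]) if (!same_binning(p1, p)) stop("binning mismatch between profiles")
  vals <- Reduce(`+`, Map(function(p, w) w * p$values, profiles, weights))
  out <- mfa_profile(vals, p1$bin_size, p1$length_bp, source = p1$source,
                     normalisation = sprintf("mixture of %d classes", length(profiles)))
  attr(out, "weights") <- weights
  out
}

# ----------------------------------------------------------------------------
# TSV / bedGraph I/O. TSV columns: bin_start, bin_end, value (or count), with
# '#'-prefixed provenance headers carrying the binning.
# ----------------------------------------------------------------------------

write_binned_tsv <- function(values, bin_size, length_bp, path, column,
                             label = "", extra_header = character()) {
  n <- n_bins(length_bp, bin_size)
  starts <- (seq_len(n) - 1) * bin_size
  ends <- pmin(starts + bin_size, length_bp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# forktrap %s", column),
               sprintf("# bin_size=%d length_bp=%d label=%s",
                       as.integer(bin_size), as.integer(length_bp), label),
               extra_header), con)
  utils::write.table(data.frame(bin_start = starts, bin_end = ends, value = values),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("bin_start", "bin_end", column))
  invisible(path)
}

read_binned_tsv <- function(path) {
  head <- readLines(path, n = 20L)
  meta <- grep("^# bin_size=", head, value = TRUE)
  if (!length(meta)) stop("missing '# bin_size=' header in ", path)
  g <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]*"), meta))
    sub(paste0(key, "="), "", m)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(values = tab[[3]], bin_size = as.numeric(g("bin_size")),
       length_bp = as.numeric(g("length_bp")), label = g("label"))
}

#' Write/read binned counts as TSV
#' @param x A [binned_counts] object.
#' @param path File path.
#' @param extra_header Extra `#` header lines (provenance).
#' @return `path` (write) or a [binned_counts] (read).
#' @export
write_counts_tsv <- function(x, path, extra_header = character()) {
  write_binned_tsv(x$counts, x$bin_size, x$length_bp, path, "count",
                   label = x$label, extra_header = extra_header)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  r <- read_binned_tsv(path)
  binned_counts(r$values, r$bin_size, r$length_bp, label = r$label)
}

#' Write/read a marker-frequency profile as TSV
#' @param x An [mfa_profile].
#' @param path File path.
#' @param extra_header Extra `#` header lines (provenance).
#' @return `path` (write) or an [mfa_profile] (read).
#' @export
write_profile_tsv <- function(x, path, extra_header = character()) {
  write_binned_tsv(x$values, x$bin_size, x$length_bp, path, "value",
                   label = x$source,
                   extra_header = c(sprintf("# normalisation=%s", x$normalisation),
                                    extra_header))
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  r <- read_binned_tsv(path)
  norm <- grep("^# normalisation=", readLines(path, n = 20L), value = TRUE)
  mfa_profile(r$values, r$bin_size, r$length_bp,
              source = if (identical(r$label, "model")) "model" else "data",
              normalisation = if (length(norm)) sub("^# normalisation=", "", norm[1]) else "")
}

#' Write a profile as bedGraph
#' @param x An [mfa_profile].
#' @param path File path.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(x, path, chrom = "chr") {
  n <- n_bins(x$length_bp, x$bin_size)
  starts <- (seq_len(n) - 1) * x$bin_size
  ends <- pmin(starts + x$bin_size, x$length_bp)
  keep <- !is.na(x$values)
  utils::write.table(data.frame(chrom, starts[keep], ends[keep], x$values[keep]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
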