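#' Construct a peak table
#'
#' A peak table is the in-memory form of a direct-infusion mass-spectrometry
#' experiment: a vector of consensus m/z values and a samples-by-peaks matrix
#' of non-negative intensities, with optional per-sample class labels.
#'
#' @param mz numeric vector of m/z values (Daltons per charge), strictly
#'   increasing after construction (rows are reordered if needed).
#' @param intensities numeric matrix, rows = samples, columns = peaks;
#'   finite and >= 0.
#' @param sample_ids character vector of unique sample identifiers.
#' @param labels optional per-sample class, one of `"control"`, `"case"`,
#'   `"unknown"`. Defaults to `"unknown"`.
#' @return An object of class `peak_table`: a list with elements `mz`,
#'   `intensities`, `sample_ids`, `labels`.
#' @export
peak_table <- function(mz, intensities, sample_ids, labels = NULL) {
  mz <- as.numeric(mz)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_ids <- as.character(sample_ids)
  if (is.null(labels)) labels <- rep("unknown", length(sample_ids))
  labels <- as.character(labels)

  if (length(mz) != ncol(intensities)) {
    stop("length(mz) must equal the number of intensity columns")
  }
  if (nrow(intensities) != length(sample_ids)) {
    stop("number of intensity rows must equal length(sample_ids)")
  }
  if (length(labels) != length(sample_ids)) {
    stop("labels must have one entry per sample")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(labels %in% c("control", "case", "unknown"))) {
    stop("labels must be 'control', 'case' or 'unknown'")
  }
  if (any(!is.finite(mz))) stop("mz values must be finite")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0")
  }

  ord <- order(mz)
  mz <- mz[ord]
  intensities <- intensities[, ord, drop = FALSE]
  if (any(diff(mz) <= 0)) stop("mz values must be strictly increasing")

  dimnames(intensities) <- list(sample_ids, NULL)
  structure(
    list(mz = mz, intensities = intensities,
         sample_ids = sample_ids, labels = labels),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d samples x %d peaks, m/z %.4f-%.4f\n",
              length(x$sample_ids), length(x$mz),
              if (length(x$mz)) min(x$mz) else NA_real_,
              if (length(x$mz)) max(x$mz) else NA_real_))
  tab <- table(factor(x$labels, levels = c("control", "case", "unknown")))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

n_peaks <- function(table) length(table$mz)
n_samples <- function(table) length(table$sample_ids)

# Keep a subset of peak columns, preserving order of `keep` as given.
subset_peaks <- function(table, keep) {
  peak_table(table$mz[keep], table$intensities[, keep, drop = FALSE],
             table$sample_ids, table$labels)
}
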