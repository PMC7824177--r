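#' Total-signal intensity normalization
#'
#' Rescales every sample so that its summed intensity equals `target_sum`
#' (total-ion-current style normalization). Zeros stay exactly zero and
#' within-sample intensity ratios are preserved.
#'
#' @param table a [peak_table()].
#' @param target_sum positive scalar; default 1e4.
#' @return The normalized [peak_table()].
#' @export
normalize_intensities <- function(table, target_sum = 1e4) {
  if (target_sum <= 0) stop("target_sum must be > 0")
  sums <- rowSums(table$intensities)
  zero <- sums == 0
  if (any(zero)) {
    stop("sample(s) with all-zero intensities: ",
         paste(table$sample_ids[zero], collapse = ", "))
  }
  peak_table(table$mz, table$intensities * (target_sum / sums),
             table$sample_ids, table$labels)
}

#' Align peak lists across spectra
#'
#' Pools all peaks, sorts them by m/z and groups them greedily: a new
#' consensus group opens when the gap between the next peak and the running
#' group mean exceeds `tol_ppm` (a gap of exactly `tol_ppm` stays in the
#' group). The consensus m/z of a group is the intensity-weighted mean of its
#' members; a sample contributing two or more peaks to one group keeps their
#' summed intensity, and a sample absent from a group gets intensity 0.
#'
#' @param spectra list of per-sample spectra, each a list (or data.frame) with
#'   numeric elements `mz` (sorted ascending) and `intensity`.
#' @param tol_ppm grouping tolerance in parts per million; must be > 0.
#' @param sample_ids optional sample identifiers (default `S1`, `S2`, ...).
#' @return list with `table` (the consensus [peak_table()]) and `map` (the
#'   alignment map: `consensus_mz` plus one integer vector per spectrum
#'   mapping original peak index to consensus peak index).
#' @export
align_peaks <- function(spectra, tol_ppm, sample_ids = NULL) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  n_spec <- length(spectra)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_spec))
  mz <- unlist(lapply(spectra, function(s) as.numeric(s$mz)), use.names = FALSE)
  intensity <- unlist(lapply(spectra, function(s) as.numeric(s$intensity)),
                      use.names = FALSE)
  spec_of <- rep(seq_len(n_spec),
                 vapply(spectra, function(s) length(s$mz), integer(1)))
  idx_in_spec <- unlist(lapply(spectra, function(s) seq_along(s$mz)),
                        use.names = FALSE)
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  spec_of <- spec_of[ord]; idx_in_spec <- idx_in_spec[ord]

  group <- integer(length(mz))
  if (length(mz)) {
    g <- 1L
    run_sum <- mz[1]; run_n <- 1L
    group[1] <- g
    for (i in seq_along(mz)[-1]) {
      run_mean <- run_sum / run_n
      if ((mz[i] - run_mean) > tol_ppm * run_mean / 1e6) {
        g <- g + 1L
        run_sum <- mz[i]; run_n <- 1L
      } else {
        run_sum <- run_sum + mz[i]; run_n <- run_n + 1L
      }
      group[i] <- g
    }
  }
  n_groups <- if (length(group)) max(group) else 0L

  consensus_mz <- vapply(seq_len(n_groups), function(g) {
    sel <- group == g
    w <- intensity[sel]
    if (sum(w) > 0) sum(mz[sel] * w) / sum(w) else mean(mz[sel])
  }, numeric(1))

  mat <- matrix(0, nrow = n_spec, ncol = n_groups)
  for (i in seq_along(mz)) {
    mat[spec_of[i], group[i]] <- mat[spec_of[i], group[i]] + intensity[i]
  }

  map <- lapply(seq_len(n_spec), function(s) {
    out <- integer(length(spectra[[s]]$mz))
    sel <- spec_of == s
    out[idx_in_spec[sel]] <- group[sel]
    out
  })
  names(map) <- sample_ids

  list(table = peak_table(consensus_mz, mat, sample_ids),
       map = list(consensus_mz = consensus_mz, per_spectrum = map))
}

#' Prevalence (noise) filter
#'
#' Keeps the peaks whose intensity is nonzero in at least
#' `min_nonzero_samples` samples; the default of 10 implements the rule that
#' a peak must be present in more than nine samples to count as signal.
#'
#' @param table a [peak_table()].
#' @param min_nonzero_samples integer >= 1.
#' @return Filtered [peak_table()] (possibly with zero peaks).
#' @export
filter_by_prevalence <- function(table, min_nonzero_samples = 10) {
  if (min_nonzero_samples < 1) stop("min_nonzero_samples must be >= 1")
  keep <- colSums(table$intensities > 0) >= min_nonzero_samples
  subset_peaks(table, which(keep))
}

#' Detection mass-range filter
#'
#' Keeps peaks with `low <= mz <= high` (closed interval, matching a closed
#' instrument detection range).
#'
#' @param table a [peak_table()].
#' @param low,high range bounds in m/z; `low < high` required.
#' @return Filtered [peak_table()].
#' @export
filter_mass_range <- function(table, low = 45, high = 900) {
  if (low >= high) stop("mass range must satisfy low < high")
  keep <- table$mz >= low & table$mz <= high
  subset_peaks(table, which(keep))
}

#' Run the standard preprocessing chain
#'
#' Mass-range filter, prevalence filter, then total-signal normalization,
#' with per-stage peak counts reported.
#'
#' @param table a [peak_table()].
#' @param config a [default_config()] list.
#' @param quiet suppress count messages.
#' @return The preprocessed [peak_table()], with the per-stage counts in the
#'   `"counts"` attribute.
#' @export
preprocess_peak_table <- function(table, config = default_config(),
                                  quiet = FALSE) {
  counts <- c(input = n_peaks(table))
  table <- filter_mass_range(table, config$mz_range[1], config$mz_range[2])
  counts["after_mass_range"] <- n_peaks(table)
  table <- filter_by_prevalence(table, config$min_nonzero_samples)
  counts["after_prevalence"] <- n_peaks(table)
  table <- normalize_intensities(table, config$target_sum)
  if (!quiet) {
    message(sprintf(
      "preprocess: %d peaks in, %d after mass range [%g, %g], %d after prevalence >= %d",
      counts["input"], counts["after_mass_range"], config$mz_range[1],
      config$mz_range[2], counts["after_prevalence"],
      config$min_nonzero_samples))
  }
  attr(table, "counts") <- counts
  table
}
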