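#' Leave-one-out Z-scores for one sample
#'
#' For every peak, the held-out sample's intensity is standardized against the
#' mean and sample standard deviation (n-1 denominator) of the reference
#' population with that sample removed. With a degenerate (zero) reference
#' standard deviation the z-score is 0 when the sample equals the constant and
#' +/-Inf (flagged abnormal) when it deviates from it.
#'
#' @param table a [peak_table()] with at least 3 samples.
#' @param sample_id the held-out sample.
#' @param reference `"all"` (every other sample, the default) or `"controls"`
#'   (control-labeled samples only, still excluding the held-out sample).
#' @param log_transform apply `log10(x + 1)` before standardizing.
#' @return numeric vector of z-scores, one per peak (may contain `Inf`).
#' @export
loo_zscore <- function(table, sample_id, reference = c("all", "controls"),
                       log_transform = FALSE) {
  reference <- match.arg(reference)
  s <- match(sample_id, table$sample_ids)
  if (is.na(s)) stop("unknown sample_id: ", sample_id)
  if (n_samples(table) < 3) stop("need >= 3 samples for leave-one-out z-scores")

  x_mat <- table$intensities
  if (log_transform) x_mat <- log10(x_mat + 1)
  x <- x_mat[s, ]

  ref_rows <- if (reference == "all") {
    setdiff(seq_len(nrow(x_mat)), s)
  } else {
    setdiff(which(table$labels == "control"), s)
  }
  if (length(ref_rows) < 2) {
    stop("reference population must keep >= 2 samples after leave-one-out")
  }
  rest <- x_mat[ref_rows, , drop = FALSE]
  n_r <- nrow(rest)
  m <- colMeans(rest)
  ss <- colSums(rest^2) - n_r * m^2
  sd_rest <- sqrt(pmax(ss, 0) / (n_r - 1))

  scale <- pmax(abs(m), 1)
  degenerate <- sd_rest <= 1e-12 * scale
  z <- numeric(length(x))
  ok <- !degenerate
  z[ok] <- (x[ok] - m[ok]) / sd_rest[ok]
  dev <- degenerate & abs(x - m) > 1e-9 * scale
  z[dev] <- sign(x[dev] - m[dev]) * Inf
  z
}

#' Select abnormal metabolites from a z-score profile
#'
#' Peaks with `|z| >= z_threshold` (including the degenerate-deviation `Inf`
#' flags) are abnormal; the selection is the union of their retained
#' annotations, intersected with the universe.
#'
#' @param z numeric z-score vector from [loo_zscore()].
#' @param z_threshold positive threshold; default 2 (two-sided).
#' @param annotations an `annotation_table`.
#' @param universe character vector of annotatable compounds.
#' @return A [selection()]; the `abnormal_peaks` attribute holds the peak
#'   indices.
#' @export
select_abnormal <- function(z, z_threshold = 2, annotations, universe) {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  abnormal <- which(abs(z) >= z_threshold)
  ids <- intersect(retained_compounds(annotations, abnormal), universe)
  sel <- selection(ids, universe)
  attr(sel, "abnormal_peaks") <- abnormal
  sel
}

#' Profile one individual against the four set collections
#'
#' Composes [loo_zscore()], [select_abnormal()] and [score_collection()]: the
#' sample's abnormal peaks are mapped through the retained annotations to a
#' metabolite selection, which is then scored against every collection. An
#' individual with an empty selection (no abnormal annotated peaks) gets
#' all-zero scores — the "healthy" output.
#'
#' @param table a [peak_table()].
#' @param sample_id the individual to profile.
#' @param annotations an `annotation_table` for `table`.
#' @param collections named list of [metabolite_set_collection()]s.
#' @param config a [default_config()] list (uses `z_threshold`, `n_perm`,
#'   `seed`, `log_transform`).
#' @param reference LOO reference population; default `"all"` so that an
#'   individual can be profiled without cohort labels. Pass `"controls"` to
#'   standardize against control samples only.
#' @return list with `sample_id`, `z`, `abnormal_peaks`, `selection`, and
#'   `scores` (named list of [score_collection()] data.frames).
#' @export
profile_individual <- function(table, sample_id, annotations, collections,
                               config = default_config(),
                               reference = "all") {
  if (reference == "controls" &&
      !any(table$labels == "control" & table$sample_ids != sample_id)) {
    warning("no control samples available; falling back to reference = 'all'")
    reference <- "all"
  }
  universe <- retained_compounds(annotations)
  if (!length(universe)) stop("annotation table retains no compounds")
  z <- loo_zscore(table, sample_id, reference = reference,
                  log_transform = isTRUE(config$log_transform))
  sel <- select_abnormal(z, config$z_threshold, annotations, universe)
  s_pos <- match(sample_id, table$sample_ids)
  base_seed <- (config$seed * 1009 + s_pos * 13) %% (.Machine$integer.max - 10)
  scores <- lapply(seq_along(collections), function(ci) {
    suppressWarnings(
      score_collection(sel, collections[[ci]],
                       n_perm = config$n_perm, seed = base_seed + ci)
    )
  })
  names(scores) <- if (!is.null(names(collections))) {
    names(collections)
  } else {
    vapply(collections, function(cl) cl$category, character(1))
  }
  list(sample_id = sample_id, z = z,
       abnormal_peaks = attr(sel, "abnormal_peaks"),
       selection = sel, scores = scores)
}
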