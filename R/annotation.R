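#' Look up candidate metabolite annotations for one m/z value
#'
#' Every (compound, adduct) pair whose theoretical adduct m/z,
#' `(monoisotopic_mass + mass_shift) / |charge|`, lies within `tol_ppm` of the
#' query is returned together with its signed mass error in ppm.
#'
#' @param mz query m/z value.
#' @param db metabolite database data.frame (see [read_metabolite_db()]).
#' @param adducts data.frame with columns `name`, `mass_shift`, `charge`
#'   (see [default_adducts()]).
#' @param tol_ppm mass tolerance in parts per million; must be > 0.
#' @param peak_index optional integer stored in the result rows.
#' @return data.frame with columns `peak_index`, `mz`, `compound_id`,
#'   `adduct`, `mass_error_ppm`; zero rows if nothing matches.
#' @export
lookup_candidates <- function(mz, db, adducts = default_adducts(),
                              tol_ppm = 10, peak_index = NA_integer_) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (!nrow(db)) {
    return(empty_candidates())
  }
  out <- vector("list", nrow(adducts))
  for (a in seq_len(nrow(adducts))) {
    theo <- (db$monoisotopic_mass + adducts$mass_shift[a]) /
      abs(adducts$charge[a])
    hit <- abs(mz - theo) <= tol_ppm * mz / 1e6
    if (any(hit)) {
      out[[a]] <- data.frame(
        peak_index = peak_index,
        mz = mz,
        compound_id = db$compound_id[hit],
        adduct = adducts$name[a],
        mass_error_ppm = (mz - theo[hit]) / theo[hit] * 1e6,
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) empty_candidates() else do.call(rbind, out)
}

empty_candidates <- function() {
  data.frame(peak_index = integer(0), mz = numeric(0),
             compound_id = character(0), adduct = character(0),
             mass_error_ppm = numeric(0), stringsAsFactors = FALSE)
}

#' Look up candidates for every peak of a table
#'
#' @param table a [peak_table()].
#' @inheritParams lookup_candidates
#' @return data.frame of candidate rows for all peaks (submitted
#'   peak/metabolite pairs).
#' @export
lookup_table_candidates <- function(table, db, adducts = default_adducts(),
                                    tol_ppm = 10) {
  rows <- lapply(seq_along(table$mz), function(i) {
    lookup_candidates(table$mz[i], db, adducts, tol_ppm, peak_index = i)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_candidates() else out
}

#' Build the peak intensity-correlation graph
#'
#' Pearson correlation of every peak pair across samples; peaks are connected
#' when `|r| >= corr_threshold`. Zero-variance peaks get no edges. Compounds
#' in the same pathway tend to have correlated concentrations, which is what
#' the context annotation step exploits.
#'
#' @param table a [peak_table()] with at least 3 samples.
#' @param corr_threshold absolute-correlation threshold in (0, 1].
#' @return An object of class `correlation_graph`: list with `n_peaks` and
#'   `edges` (data.frame `i`, `j`, `r` with `i < j`).
#' @export
build_correlation_graph <- function(table, corr_threshold = 0.7) {
  if (n_samples(table) < 3) stop("need >= 3 samples for peak correlations")
  if (corr_threshold <= 0 || corr_threshold > 1) {
    stop("corr_threshold must be in (0, 1]")
  }
  r <- suppressWarnings(cor(table$intensities))
  r[!is.finite(r)] <- 0  # zero-variance peaks
  hit <- which(abs(r) >= corr_threshold & upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(i = hit[, 1], j = hit[, 2],
                      r = r[hit], row.names = NULL)
  structure(list(n_peaks = n_peaks(table), edges = edges),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph> %d peaks, %d edges\n",
              x$n_peaks, nrow(x$edges)))
  invisible(x)
}

# adjacency list (neighbors per peak) of a correlation graph
corr_neighbors <- function(corr) {
  nb <- vector("list", corr$n_peaks)
  for (k in seq_len(nrow(corr$edges))) {
    i <- corr$edges$i[k]; j <- corr$edges$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(v)))
}

#' Context-based annotation: decline false candidates
#'
#' For each peak, every candidate compound is scored by the number of
#' distinct correlated peaks whose own candidates lie within
#' `pathway_distance` of it in the pathway graph (the true annotation must be
#' bunched, in pathway space, around the annotations of co-varying peaks).
#' Within a peak, candidates of maximal support are retained, provided that
#' support reaches `min_support`; ties retain all tied candidates (putative
#' annotation permits multiplicity). A peak whose best support falls short of
#' `min_support` retains nothing.
#'
#' @param candidates data.frame of candidate rows as produced by
#'   [lookup_table_candidates()].
#' @param corr a [build_correlation_graph()] result.
#' @param pathways a [pathway_graph()].
#' @param pathway_distance maximum pathway shortest-path distance counted as
#'   "bunched"; default 1 (co-membership adjacency).
#' @param min_support minimum support for retention; default 1.
#' @param n_masses_submitted total number of m/z values submitted to the
#'   search (defaults to the number of distinct peaks in `candidates`).
#' @return An object of class `annotation_table`: list with `assignments`
#'   (candidate rows plus `support` and `retained` columns) and `stats`.
#' @export
context_annotate <- function(candidates, corr, pathways,
                             pathway_distance = 1, min_support = 1,
                             n_masses_submitted = NULL) {
  if (is.null(n_masses_submitted)) {
    n_masses_submitted <- length(unique(candidates$peak_index))
  }
  assignments <- candidates
  assignments$support <- integer(nrow(candidates))
  assignments$retained <- logical(nrow(candidates))

  if (nrow(candidates)) {
    comps <- unique(candidates$compound_id)
    in_graph <- comps[comps %in% igraph::V(pathways$graph)$name]
    dmat <- matrix(Inf, length(comps), length(comps),
                   dimnames = list(comps, comps))
    diag(dmat) <- 0
    if (length(in_graph) >= 1) {
      dmat[in_graph, in_graph] <- igraph::distances(pathways$graph,
                                                    v = in_graph,
                                                    to = in_graph)
    }
    close_mat <- dmat <= pathway_distance

    nb <- corr_neighbors(corr)
    cand_by_peak <- split(seq_len(nrow(candidates)), candidates$peak_index)
    comp_idx <- match(candidates$compound_id, comps)
    peaks <- as.integer(names(cand_by_peak))

    for (p in seq_along(peaks)) {
      rows_i <- cand_by_peak[[p]]
      peak <- peaks[p]
      neigh <- if (peak <= length(nb)) nb[[peak]] else integer(0)
      support <- integer(length(rows_i))
      for (j in neigh) {
        pj <- match(j, peaks)
        if (is.na(pj)) next
        cj <- unique(comp_idx[cand_by_peak[[pj]]])
        # one correlated peak contributes at most one vote per candidate
        votes <- rowSums(close_mat[comp_idx[rows_i], cj, drop = FALSE]) > 0
        support <- support + as.integer(votes)
      }
      assignments$support[rows_i] <- support
      best <- max(support)
      if (best >= min_support) {
        assignments$retained[rows_i] <- support == best
      }
    }
  }

  retained <- assignments[assignments$retained, , drop = FALSE]
  stats <- list(
    n_masses_submitted = n_masses_submitted,
    n_pairs_submitted = nrow(candidates),
    n_peaks_annotated = length(unique(retained$peak_index)),
    n_unique_compounds = length(unique(retained$compound_id))
  )
  structure(list(assignments = assignments, stats = stats),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<annotation_table> %d masses submitted, %d pairs, ",
                     "%d peaks annotated, %d unique compounds\n"),
              s$n_masses_submitted, s$n_pairs_submitted,
              s$n_peaks_annotated, s$n_unique_compounds))
  invisible(x)
}

#' Summary counts of an annotation table
#'
#' @param table an `annotation_table`.
#' @return list with `n_masses_submitted`, `n_pairs_submitted`,
#'   `n_peaks_annotated`, `n_unique_compounds`.
#' @export
annotation_stats <- function(table) {
  table$stats
}

#' Retained compounds of a set of peaks
#'
#' @param annotations an `annotation_table`.
#' @param peaks integer vector of peak indices (default: all).
#' @return character vector of unique retained compound ids.
#' @export
retained_compounds <- function(annotations, peaks = NULL) {
  a <- annotations$assignments
  a <- a[a$retained, , drop = FALSE]
  if (!is.null(peaks)) a <- a[a$peak_index %in% peaks, , drop = FALSE]
  unique(a$compound_id)
}

#' Annotate a peak table end to end
#'
#' Candidate lookup, correlation graph construction and context-based
#' disambiguation in one call.
#'
#' @param table a [peak_table()].
#' @param db metabolite database data.frame.
#' @param pathways a [pathway_graph()].
#' @param config a [default_config()] list.
#' @return An `annotation_table`.
#' @export
annotate_peak_table <- function(table, db, pathways,
                                config = default_config()) {
  candidates <- lookup_table_candidates(table, db, config$adducts,
                                        config$mass_tol_ppm)
  corr <- build_correlation_graph(table, config$corr_threshold)
  context_annotate(candidates, corr, pathways,
                   pathway_distance = config$pathway_distance,
                   min_support = config$min_support,
                   n_masses_submitted = n_peaks(table))
}
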