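#' Construct a metabolite selection
#'
#' A selection is the set of metabolites picked out by an analysis step (a
#' case-control contrast or one individual's abnormal peaks) together with the
#' universe of compounds a random draw could have produced — all compounds the
#' assay-plus-annotation can see, not the whole database.
#'
#' @param metabolite_ids character vector of selected compound ids.
#' @param universe character vector of eligible compound ids; must contain
#'   `metabolite_ids` and be nonempty.
#' @return An object of class `selection`.
#' @export
selection <- function(metabolite_ids, universe) {
  metabolite_ids <- unique(as.character(metabolite_ids))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("selection universe must be nonempty")
  if (!all(metabolite_ids %in% universe)) {
    stop("selected metabolites must be a subset of the universe")
  }
  structure(list(metabolite_ids = metabolite_ids, universe = universe),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> %d of %d compounds\n",
              length(x$metabolite_ids), length(x$universe)))
  invisible(x)
}

#' Project a selection on one metabolite set
#'
#' @param sel a [selection()].
#' @param met_set character vector of compound ids.
#' @return integer overlap size.
#' @export
project_selection <- function(sel, met_set) {
  length(intersect(sel$metabolite_ids, unique(met_set)))
}

# n_perm draws of k compound indices from a universe of size m, as a
# k x n_perm integer matrix (0 x n_perm when k == 0).
draw_null_indices <- function(m, k, n_perm, seed) {
  if (k > m) stop("selection size k exceeds the universe size")
  with_seed(seed, {
    if (k == 0) {
      matrix(integer(0), nrow = 0, ncol = n_perm)
    } else {
      matrix(vapply(seq_len(n_perm), function(i) sample.int(m, k),
                    integer(k)),
             nrow = k, ncol = n_perm)
    }
  })
}

#' Monte-Carlo null overlap counts
#'
#' Draws `n_perm` random selections of `k` compounds from the universe
#' (uniformly, without replacement) and returns the overlap of each draw with
#' `met_set`. The counts follow the hypergeometric distribution with the
#' universe as population.
#'
#' @param universe character vector of eligible compound ids.
#' @param k selection size; `k <= length(universe)`.
#' @param met_set character vector of compound ids.
#' @param n_perm number of draws; the pipeline default is 30,000.
#' @param seed RNG seed; identical seeds give identical draws.
#' @return integer vector of `n_perm` overlap counts.
#' @export
permutation_null <- function(universe, k, met_set, n_perm = 30000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  universe <- unique(as.character(universe))
  idx <- draw_null_indices(length(universe), k, n_perm, seed)
  memb <- universe %in% met_set
  if (k == 0) return(integer(n_perm))
  as.integer(.colSums(memb[idx], nrow(idx), ncol(idx)))
}

#' Representation score from an observed overlap and its null
#'
#' The empirical p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)` and is mapped to the
#' 0-100 representation scale by `score = clip(100 (1 - 2 p), 0, 100)`:
#' a selection at the null median scores about 0 and a selection never
#' reached by the null saturates towards 100.
#'
#' @param observed integer observed overlap.
#' @param null_counts integer vector of null overlaps (nonempty).
#' @return list with `observed_overlap`, `empirical_p`, `score`.
#' @export
representation_score <- function(observed, null_counts) {
  if (!length(null_counts)) stop("null_counts must be nonempty")
  n <- length(null_counts)
  p <- (1 + sum(null_counts >= observed)) / (n + 1)
  list(observed_overlap = as.integer(observed),
       empirical_p = p,
       score = min(100, max(0, 100 * (1 - 2 * p))))
}

#' Score every set of a collection against one selection
#'
#' All sets are scored against null selections of the same size
#' `k = |selection|`; the same `n_perm` draws are reused across the sets of
#' the collection, so results are deterministic under a fixed seed.
#'
#' @param sel a [selection()].
#' @param collection a [metabolite_set_collection()].
#' @param n_perm number of null draws.
#' @param seed RNG seed.
#' @return data.frame with columns `set_name`, `category`, `observed`,
#'   `empirical_p`, `score`, one row per set.
#' @export
score_collection <- function(sel, collection, n_perm = 30000, seed = 1) {
  k <- length(sel$metabolite_ids)
  if (k == 0) warning("empty selection: all representation scores are 0")
  universe <- sel$universe
  idx <- draw_null_indices(length(universe), k, n_perm, seed)
  nm <- names(collection$sets)
  observed <- integer(length(nm))
  p <- numeric(length(nm))
  score <- numeric(length(nm))
  for (s in seq_along(nm)) {
    met_set <- collection$sets[[s]]
    observed[s] <- project_selection(sel, met_set)
    null_counts <- if (k == 0) {
      integer(n_perm)
    } else {
      memb <- universe %in% met_set
      as.integer(.colSums(memb[idx], nrow(idx), ncol(idx)))
    }
    rs <- representation_score(observed[s], null_counts)
    p[s] <- rs$empirical_p
    score[s] <- rs$score
  }
  data.frame(set_name = nm %||% character(0),
             category = rep(collection$category, length(nm)),
             observed = observed, empirical_p = p, score = score,
             stringsAsFactors = FALSE)
}

#' Top-n sets by representation score
#'
#' Sorted by score descending with ties broken by set name ascending.
#'
#' @param scores data.frame as returned by [score_collection()] (needs
#'   columns `set_name`, `score`).
#' @param n how many sets to return; if more than available, all are returned
#'   with a warning.
#' @return the first `n` rows of the stable sort.
#' @export
top_sets <- function(scores, n = 20) {
  if (n < 1) stop("n must be >= 1")
  if (n > nrow(scores)) {
    warning(sprintf("requested top %d of %d sets; returning all",
                    n, nrow(scores)))
    n <- nrow(scores)
  }
  ord <- order(-scores$score, scores$set_name)
  scores[ord[seq_len(n)], , drop = FALSE]
}
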