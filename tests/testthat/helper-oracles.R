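# Brute-force oracles and tiny fixture builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed seed without disturbing the ambient RNG state
with_seed_for_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# literal scan over every (compound, adduct) pair
bf_lookup <- function(mz, db, adducts, tol_ppm) {
  rows <- list()
  for (c_i in seq_len(nrow(db))) {
    for (a_i in seq_len(nrow(adducts))) {
      theo <- (db$monoisotopic_mass[c_i] + adducts$mass_shift[a_i]) /
        abs(adducts$charge[a_i])
      if (abs(mz - theo) <= tol_ppm * mz / 1e6) {
        rows[[length(rows) + 1]] <- data.frame(
          compound_id = db$compound_id[c_i], adduct = adducts$name[a_i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    data.frame(compound_id = character(0), adduct = character(0))
  } else {
    do.call(rbind, rows)
  }
}

# all-pairs shortest paths by Floyd-Warshall over an explicit edge list
bf_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- match(edges[e, 1], nodes); j <- match(edges[e, 2], nodes)
      d[i, j] <- 1; d[j, i] <- 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# exhaustive enumeration of (peak, candidate, correlated peak,
# neighbor-candidate) tuples; returns candidates with support and retained
bf_context <- function(candidates, corr_edges, nodes, pathway_edges,
                       pathway_distance, min_support) {
  d <- bf_distances(nodes, pathway_edges)
  close_to <- function(a, b) {
    if (a == b) return(TRUE)
    if (!(a %in% nodes) || !(b %in% nodes)) return(FALSE)
    d[a, b] <= pathway_distance
  }
  out <- candidates
  out$support <- 0L
  out$retained <- FALSE
  peaks <- unique(candidates$peak_index)
  neighbors <- function(i) {
    unique(c(corr_edges$j[corr_edges$i == i], corr_edges$i[corr_edges$j == i]))
  }
  for (row in seq_len(nrow(candidates))) {
    i <- candidates$peak_index[row]
    c_id <- candidates$compound_id[row]
    votes <- 0L
    for (j in neighbors(i)) {
      cands_j <- candidates$compound_id[candidates$peak_index == j]
      if (any(vapply(cands_j, close_to, logical(1), a = c_id))) {
        votes <- votes + 1L
      }
    }
    out$support[row] <- votes
  }
  for (p in peaks) {
    rows <- which(out$peak_index == p)
    best <- max(out$support[rows])
    if (best >= min_support) out$retained[rows] <- out$support[rows] == best
  }
  out
}

# exhaustive threshold sweep: every distinct score plus +/-Inf sentinels
bf_roc <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n_case <- sum(labels == "case"); n_ctrl <- sum(labels == "control")
  acc <- sens <- spec <- numeric(length(thr))
  for (t_i in seq_along(thr)) {
    call_case <- scores >= thr[t_i]
    tp <- sum(call_case & labels == "case")
    tn <- sum(!call_case & labels == "control")
    sens[t_i] <- 100 * tp / n_case
    spec[t_i] <- 100 * tn / n_ctrl
    acc[t_i] <- 100 * (tp + tn) / length(scores)
  }
  # AUC via the Mann-Whitney statistic (independent of any sweep)
  case_s <- scores[labels == "case"]; ctrl_s <- scores[labels == "control"]
  wins <- 0
  for (a in case_s) for (b in ctrl_s) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  list(max_accuracy = max(acc),
       points = unique(data.frame(sensitivity = sens, specificity = spec)),
       auc = wins / (length(case_s) * length(ctrl_s)))
}

# a tiny deterministic peak table
tiny_table <- function() {
  peak_table(mz = c(100.0, 200.0, 300.0),
             intensities = rbind(c(2, 3, 5), c(4, 6, 10), c(1, 0, 9)),
             sample_ids = c("a", "b", "c"),
             labels = c("control", "case", "control"))
}

random_peak_table <- function(n_samples, n_peaks, seed) {
  set.seed(seed)
  peak_table(mz = sort(runif(n_peaks, 50, 900)),
             intensities = matrix(rexp(n_samples * n_peaks, rate = 1e-3),
                                  n_samples, n_peaks),
             sample_ids = sprintf("s%02d", seq_len(n_samples)))
}

# random small annotation instance for oracle-equivalence checks
random_context_instance <- function(seed) {
  set.seed(seed)
  n_comp <- sample(5:30, 1)
  n_peaks <- sample(3:15, 1)
  nodes <- sprintf("X%02d", seq_len(n_comp))
  n_edges <- sample(0:min(25, n_comp * (n_comp - 1) / 2), 1)
  pe <- if (n_edges) {
    pairs <- t(utils::combn(nodes, 2))
    pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
  } else {
    matrix(character(0), ncol = 2)
  }
  cand <- do.call(rbind, lapply(seq_len(n_peaks), function(p) {
    k <- sample(0:3, 1)
    if (!k) return(NULL)
    data.frame(peak_index = p, mz = 100 + p,
               compound_id = sample(nodes, k), adduct = "[M+H]+",
               mass_error_ppm = 0, stringsAsFactors = FALSE)
  }))
  n_ce <- sample(0:min(20, n_peaks * (n_peaks - 1) / 2), 1)
  ce <- if (n_ce) {
    pp <- t(utils::combn(seq_len(n_peaks), 2))
    pp <- pp[sample(nrow(pp), n_ce), , drop = FALSE]
    data.frame(i = pp[, 1], j = pp[, 2], r = 1)
  } else {
    data.frame(i = integer(0), j = integer(0), r = numeric(0))
  }
  list(
    candidates = if (is.null(cand)) {
      data.frame(peak_index = integer(0), mz = numeric(0),
                 compound_id = character(0), adduct = character(0),
                 mass_error_ppm = numeric(0))
    } else {
      cand
    },
    corr = structure(list(n_peaks = n_peaks, edges = ce),
                     class = "correlation_graph"),
    nodes = nodes,
    pathway_edges = pe,
    pathways = pathway_graph(
      membership = NULL,
      db = data.frame(compound_id = nodes, name = nodes,
                      monoisotopic_mass = seq_along(nodes) + 100)
    ) |> (function(pg) {
      pg$graph <- igraph::add_edges(pg$graph, t(pe))
      pg
    })(),
    distance = sample(1:3, 1),
    min_support = sample(1:2, 1)
  )
}
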