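#' Case-control contrast of representation scores
#'
#' Per set: the arithmetic mean score within each label group and their
#' difference (case minus control), the over-representation of the set in the
#' case group. Rows are sorted by decreasing difference.
#'
#' @param score_matrix numeric matrix, rows = samples, columns = sets (column
#'   names = set names); no missing values allowed.
#' @param labels per-sample `"control"`/`"case"` labels.
#' @return data.frame with columns `set_name`, `mean_control`, `mean_case`,
#'   `over_representation`.
#' @export
group_contrast <- function(score_matrix, labels) {
  score_matrix <- as.matrix(score_matrix)
  if (length(labels) != nrow(score_matrix)) {
    stop("labels must have one entry per score row")
  }
  is_ctrl <- labels == "control"
  is_case <- labels == "case"
  if (!any(is_ctrl) || !any(is_case)) {
    stop("need at least one control and one case")
  }
  if (any(is.na(score_matrix))) {
    stop("scores must be complete: missing score for a sample/set pair")
  }
  mean_control <- colMeans(score_matrix[is_ctrl, , drop = FALSE])
  mean_case <- colMeans(score_matrix[is_case, , drop = FALSE])
  out <- data.frame(
    set_name = colnames(score_matrix) %||% paste0("set", seq_len(ncol(score_matrix))),
    mean_control = unname(mean_control),
    mean_case = unname(mean_case),
    over_representation = unname(mean_case - mean_control),
    stringsAsFactors = FALSE)
  out[order(-out$over_representation, out$set_name), , drop = FALSE]
}

#' Per-person diagnostic score
#'
#' The sum of the person's representation scores over the top overrepresented
#' sets (by default the top 20 of the case-control contrast).
#'
#' @param person_scores named numeric vector, set name -> score.
#' @param top_set_names character vector of set names to sum over.
#' @return numeric scalar.
#' @export
diagnostic_score <- function(person_scores, top_set_names) {
  missing <- setdiff(top_set_names, names(person_scores))
  if (length(missing)) {
    stop("missing score for set(s): ", paste(head(missing, 5), collapse = ", "))
  }
  sum(person_scores[top_set_names])
}

#' ROC curve with accuracy-optimal operating point
#'
#' Thresholds are the midpoints between consecutive distinct sorted scores
#' plus -Inf/+Inf sentinels; a sample is called a case when its score is at
#' least the threshold. Sensitivity, specificity and accuracy are reported in
#' percent for every threshold. The optimal point maximizes accuracy, with
#' ties broken by the larger sensitivity+specificity sum and then the lower
#' threshold; AUC is the trapezoid integral of sensitivity over
#' 1-specificity. The Youden-optimal point (max sensitivity+specificity) is
#' also reported.
#'
#' @param scores numeric diagnostic scores, one per sample.
#' @param labels per-sample `"control"`/`"case"` labels (both present).
#' @return list of class `roc_result`: `points` (data.frame `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`), `optimal` (one row),
#'   `youden` (one row), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  is_case <- labels == "case"
  is_ctrl <- labels == "control"
  if (!any(is_case) || !any(is_ctrl)) {
    stop("need both classes to draw a ROC curve")
  }
  n_case <- sum(is_case); n_ctrl <- sum(is_ctrl); n <- n_case + n_ctrl

  u <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  pts <- lapply(thresholds, function(t) {
    call_case <- scores >= t
    tp <- sum(call_case & is_case)
    tn <- sum(!call_case & is_ctrl)
    c(threshold = t,
      sensitivity = 100 * tp / n_case,
      specificity = 100 * tn / n_ctrl,
      accuracy = 100 * (tp + tn) / n)
  })
  points <- as.data.frame(do.call(rbind, pts))

  pick <- order(-points$accuracy,
                -(points$sensitivity + points$specificity),
                points$threshold)[1]
  youden <- order(-(points$sensitivity + points$specificity),
                  -points$accuracy, points$threshold)[1]

  fpr <- 1 - points$specificity / 100
  tpr <- points$sensitivity / 100
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)

  structure(list(points = points,
                 optimal = points[pick, , drop = FALSE],
                 youden = points[youden, , drop = FALSE],
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  o <- x$optimal
  cat(sprintf(paste0("<roc_result> AUC %.3f; optimal: accuracy %.1f%%, ",
                     "sensitivity %.1f%%, specificity %.1f%% at threshold %g\n"),
              x$auc, o$accuracy, o$sensitivity, o$specificity, o$threshold))
  invisible(x)
}

#' Label-permutation null of the diagnostic score's operating accuracy
#'
#' The classical permutation test for a diagnostic score: the per-sample
#' scores are held fixed and the case/control labels are permuted; for each
#' permutation the accuracy-optimal ROC operating point is recomputed. The
#' returned accuracies estimate how well label noise alone can be "classified"
#' by the same score, and the observed accuracy is compared against them.
#'
#' Note that this null holds the score definition fixed. Re-running the full
#' pipeline on permuted labels is not a chance-level reference here, because
#' the pipeline re-selects the top-k sets by the (permuted) contrast on the
#' same samples it then evaluates; that selection step alone lifts in-sample
#' optimal accuracy well above 50% for any labels (see the methods vignette).
#'
#' @param scores numeric diagnostic scores, one per sample (e.g.
#'   `report$diagnostic_scores` from [evaluate_pipeline()]).
#' @param labels per-sample `"control"`/`"case"` labels (both present).
#' @param n_perm number of label permutations.
#' @param seed optional integer seed; the ambient RNG state is restored.
#' @return list: `accuracies` (length `n_perm`), `observed` (the
#'   accuracy-optimal accuracy under the given labels), `p_value`
#'   `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#' @export
label_permutation_null <- function(scores, labels, n_perm = 1000,
                                   seed = NULL) {
  observed <- roc_curve(scores, labels)$optimal$accuracy
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      roc_curve(scores, sample(labels))$optimal$accuracy
    }, numeric(1))
  }
  accs <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(accuracies = accs,
       observed = observed,
       p_value = (1 + sum(accs >= observed)) / (n_perm + 1))
}

#' Evaluate the LDT on a labeled cohort
#'
#' Profiles every sample by leave-one-out z-scores (reference population per
#' `config$loo_reference`; default controls-only, so an individual is
#' standardized against the normal population), scores all four collections,
#' contrasts case and control means per set, picks the top-k overrepresented
#' sets by contrast (per category and pooled across categories), sums each
#' person's scores over the pooled top-k into a diagnostic score, and
#' estimates ROC performance of that score — plus per-set and per-category
#' operating points laid out like a diagnostic-criteria table.
#'
#' @param table a labeled [peak_table()] (or pass `labels`).
#' @param annotations an `annotation_table` for `table`.
#' @param collections named list of [metabolite_set_collection()]s.
#' @param config a [default_config()] list.
#' @param labels optional label vector overriding `table$labels`.
#' @return list of class `ldt_report`: `per_category` (for each collection:
#'   `scores` matrix, `contrast` table with per-set ROC columns, `top`,
#'   `diagnostic_scores`, `roc`), `pooled_top`, `diagnostic_scores`, `roc`,
#'   `summary`.
#' @export
evaluate_pipeline <- function(table, annotations, collections,
                              config = default_config(), labels = NULL) {
  if (is.null(labels)) labels <- table$labels
  if (!any(labels == "control") || !any(labels == "case")) {
    stop("cohort must contain both control and case samples")
  }
  if (is.null(names(collections))) {
    names(collections) <- vapply(collections, function(cl) cl$category,
                                 character(1))
  }
  work <- table
  work$labels <- labels
  reference <- config$loo_reference %||% "controls"

  profiles <- lapply(table$sample_ids, function(sid) {
    profile_individual(work, sid, annotations, collections, config,
                       reference = reference)
  })
  names(profiles) <- table$sample_ids

  per_category <- list()
  pooled_contrast <- list()
  for (cat_name in names(collections)) {
    set_names <- names(collections[[cat_name]]$sets)
    mat <- do.call(rbind, lapply(profiles, function(pr) {
      setNames(pr$scores[[cat_name]]$score, pr$scores[[cat_name]]$set_name)[set_names]
    }))
    rownames(mat) <- table$sample_ids
    contrast <- group_contrast(mat, labels)
    # per-set operating points, Table-2 style
    per_set <- t(vapply(contrast$set_name, function(sn) {
      o <- roc_curve(mat[, sn], labels)$optimal
      c(o$sensitivity, o$specificity, o$accuracy)
    }, numeric(3)))
    contrast$sensitivity <- per_set[, 1]
    contrast$specificity <- per_set[, 2]
    contrast$accuracy <- per_set[, 3]

    k_cat <- min(config$top_k, nrow(contrast))
    top_cat <- contrast$set_name[seq_len(k_cat)]
    diag_cat <- vapply(table$sample_ids, function(sid) {
      diagnostic_score(mat[sid, ], top_cat)
    }, numeric(1))
    per_category[[cat_name]] <- list(
      scores = mat, contrast = contrast, top = top_cat,
      diagnostic_scores = diag_cat,
      roc = roc_curve(diag_cat, labels))
    pc <- contrast[, c("set_name", "mean_control", "mean_case",
                       "over_representation")]
    pc$category <- cat_name
    pooled_contrast[[cat_name]] <- pc
  }

  pooled <- do.call(rbind, pooled_contrast)
  pooled <- pooled[order(-pooled$over_representation, pooled$set_name), ]
  k <- min(config$top_k, nrow(pooled))
  pooled_top <- pooled[seq_len(k), c("category", "set_name",
                                     "mean_control", "mean_case",
                                     "over_representation")]
  diag_scores <- vapply(table$sample_ids, function(sid) {
    sum(vapply(seq_len(k), function(i) {
      per_category[[pooled_top$category[i]]]$scores[sid, pooled_top$set_name[i]]
    }, numeric(1)))
  }, numeric(1))
  roc <- roc_curve(diag_scores, labels)

  structure(list(
    per_category = per_category,
    pooled_top = pooled_top,
    diagnostic_scores = diag_scores,
    roc = roc,
    labels = setNames(labels, table$sample_ids),
    summary = list(
      accuracy = roc$optimal$accuracy,
      sensitivity = roc$optimal$sensitivity,
      specificity = roc$optimal$specificity,
      auc = roc$auc,
      n_control = sum(labels == "control"),
      n_case = sum(labels == "case"),
      top_sets = paste(pooled_top$category, pooled_top$set_name, sep = ":"))
  ), class = "ldt_report")
}

#' @export
print.ldt_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<ldt_report> %d controls / %d cases; diagnostic score ",
                     "ROC: accuracy %.1f%%, sensitivity %.1f%%, specificity ",
                     "%.1f%%, AUC %.3f\n"),
              s$n_control, s$n_case, s$accuracy, s$sensitivity,
              s$specificity, s$auc))
  cat("  top overrepresented sets:\n")
  for (nm in head(s$top_sets, 5)) cat("   -", nm, "\n")
  invisible(x)
}
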