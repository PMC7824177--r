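test_that("group contrast is case mean minus control mean, sorted descending", {
  m <- cbind(setA = c(10, 30, 50, 70), setB = c(5, 5, 6, 6))
  labels <- c("control", "control", "case", "case")
  gc <- group_contrast(m, labels)
  expect_equal(gc$over_representation[gc$set_name == "setA"], 40)
  expect_equal(gc$over_representation[gc$set_name == "setB"], 1)
  expect_equal(gc$set_name, c("setA", "setB"))
  # identical groups contrast to zero
  gc0 <- group_contrast(rbind(m[1:2, ], m[1:2, ]), labels)
  expect_true(all(gc0$over_representation == 0))
  expect_error(group_contrast(m, rep("case", 4)), "control")
  m[2, 1] <- NA
  expect_error(group_contrast(m, labels), "complete")
})

test_that("group contrast is anti-symmetric under label swap", {
  set.seed(81)
  m <- matrix(runif(8 * 5, 0, 100), 8, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  labels <- rep(c("control", "case"), 4)
  swapped <- ifelse(labels == "case", "control", "case")
  a <- group_contrast(m, labels)
  b <- group_contrast(m, swapped)
  b <- b[match(a$set_name, b$set_name), ]
  expect_equal(a$over_representation, -b$over_representation)
})

test_that("diagnostic score sums the person's scores over the top sets", {
  ps <- c(A = 10, B = 20, C = 5)
  expect_equal(diagnostic_score(ps, c("A", "B")), 30)
  expect_equal(diagnostic_score(setNames(rep(0, 3), names(ps)), names(ps)), 0)
  expect_error(diagnostic_score(ps, c("A", "missing")), "missing")
  set.seed(82)
  for (i in 1:10) {
    ps <- setNames(runif(10, 0, 100), sprintf("s%02d", 1:10))
    top <- sample(names(ps), 4)
    expect_equal(diagnostic_score(ps, top), sum(ps[top]))
  }
})

test_that("ROC of perfectly separated groups is perfect", {
  roc <- roc_curve(c(1, 2, 3, 4, 5, 6),
                   c(rep("control", 3), rep("case", 3)))
  expect_equal(roc$optimal$accuracy, 100)
  expect_equal(roc$optimal$sensitivity, 100)
  expect_equal(roc$optimal$specificity, 100)
  expect_equal(roc$auc, 1.0)
  expect_error(roc_curve(1:3, rep("case", 3)), "both classes")
})

test_that("ROC optimal accuracy matches the exhaustive sweep on the interleaved example", {
  roc <- roc_curve(c(1, 3, 2, 4), c("control", "control", "case", "case"))
  expect_equal(roc$optimal$accuracy, 75)
  expect_equal(bf_roc(c(1, 3, 2, 4),
                      c("control", "control", "case", "case"))$max_accuracy, 75)
})

test_that("ROC equals the brute-force threshold sweep on random inputs", {
  set.seed(83)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    scores <- round(runif(n, 0, 10), sample(0:1, 1))  # force some ties
    labels <- sample(c("control", "case"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- roc_curve(scores, labels)
    want <- bf_roc(scores, labels)
    expect_equal(got$optimal$accuracy, want$max_accuracy)
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
    got_pts <- unique(got$points[, c("sensitivity", "specificity")])
    expect_setequal(paste(got_pts$sensitivity, got_pts$specificity),
                    paste(want$points$sensitivity, want$points$specificity))
    # the trivial-classifier bound
    prev <- max(mean(labels == "case"), mean(labels == "control"))
    expect_gte(got$optimal$accuracy, 100 * prev - 1e-9)
  }
})

test_that("shuffled labels give chance-level AUC on average", {
  set.seed(84)
  aucs <- replicate(100, {
    scores <- runif(30)
    labels <- sample(rep(c("control", "case"), 15))
    roc_curve(scores, labels)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("a two-sample cohort gives a degenerate but valid ROC", {
  roc <- roc_curve(c(1, 2), c("control", "case"))
  expect_equal(roc$optimal$accuracy, 100)
  roc_flip <- roc_curve(c(2, 1), c("control", "case"))
  expect_true(roc_flip$optimal$accuracy %in% c(50, 100))
  expect_equal(roc_flip$auc, 0)
})

test_that("cohort evaluation recovers a planted group effect and ranks it first", {
  ref <- generate_reference(seed = 91)
  effect_set <- names(ref$collections$disease$sets)[3]
  cohort <- generate_cohort(ref, effect_sets = effect_set, effect_size = 3,
                            seed = 92)
  cfg <- default_config(n_perm = 400)
  ann <- annotate_peak_table(cohort$table, ref$db, ref$pathways, cfg)
  report <- evaluate_pipeline(cohort$table, ann, ref$collections, cfg)
  expect_gte(report$summary$accuracy, 70)
  contrast <- report$per_category$disease$contrast
  # the planted set leads its category (top 5; sibling sets sharing its
  # pathway fragments legitimately co-rank)
  expect_true(effect_set %in% contrast$set_name[1:5])
  expect_gt(contrast$over_representation[contrast$set_name == effect_set],
            stats::median(contrast$over_representation))
  # contrast table carries Table-2-style per-set operating points
  expect_true(all(c("sensitivity", "specificity", "accuracy") %in%
                    names(contrast)))
  expect_true(all(contrast$accuracy >= 0 & contrast$accuracy <= 100))
})

test_that("an effect-free cohort is exchangeable: real labels look like permuted labels", {
  ref <- generate_reference(seed = 93)
  cohort <- generate_cohort(ref, effect_size = 1, seed = 94)
  cfg <- default_config(n_perm = 300)
  ann <- annotate_peak_table(cohort$table, ref$db, ref$pathways, cfg)
  report <- evaluate_pipeline(cohort$table, ann, ref$collections, cfg)
  # under exchangeability, a full re-run on permuted labels has the same
  # distribution as the real-label run (both carry the same in-sample
  # selection optimism), so their accuracies must be close
  perm_labels <- with_seed_for_test(95, sample(cohort$table$labels))
  perm_report <- evaluate_pipeline(cohort$table, ann, ref$collections, cfg,
                                   labels = perm_labels)
  expect_lt(abs(report$summary$accuracy - perm_report$summary$accuracy), 20)
  # the fixed-score permutation null sits at chance even though the observed
  # accuracy does not: the top-k sets were selected on the real labels, so
  # the in-sample operating accuracy is optimistic even with no effect
  null <- label_permutation_null(report$diagnostic_scores,
                                 unname(report$labels),
                                 n_perm = 400, seed = 96)
  expect_gt(mean(null$accuracies), 45)
  expect_lt(mean(null$accuracies), 70)
  expect_gt(null$observed, mean(null$accuracies))
})

test_that("label permutation null is chance-level, seeded, and rejects a real separation", {
  scores <- c(1:14, 31:44)  # perfectly separated 14 vs 14
  labels <- c(rep("control", 14), rep("case", 14))
  null <- label_permutation_null(scores, labels, n_perm = 300, seed = 7)
  expect_length(null$accuracies, 300)
  expect_equal(null$observed, 100)
  expect_lte(null$p_value, 0.05)
  # permuted accuracies hover at chance plus in-sample threshold optimism
  expect_gt(mean(null$accuracies), 45)
  expect_lt(mean(null$accuracies), 70)
  # determinism under the same seed; RNG state restored
  before <- with_seed_for_test(8, runif(1))
  set.seed(8)
  null2 <- label_permutation_null(scores, labels, n_perm = 300, seed = 7)
  expect_identical(null$accuracies, null2$accuracies)
  expect_identical(runif(1), before)
})
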