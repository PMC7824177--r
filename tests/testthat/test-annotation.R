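glucose_db <- function() {
  data.frame(compound_id = "C00031", name = "D-Glucose",
             monoisotopic_mass = 180.0634, stringsAsFactors = FALSE)
}

test_that("candidate lookup matches a protonated glucose peak at ~1.8 ppm", {
  hits <- lookup_candidates(181.0710, glucose_db(),
                            default_adducts(), tol_ppm = 10)
  hit <- hits[hits$adduct == "[M+H]+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$compound_id, "C00031")
  expect_equal(hit$mass_error_ppm, 1.79, tolerance = 0.1)
  # outside tolerance: nothing
  expect_equal(nrow(lookup_candidates(181.0750, glucose_db(),
                                      default_adducts(), 10)), 0)
  expect_equal(nrow(lookup_candidates(181.0710, glucose_db()[0, ],
                                      default_adducts(), 10)), 0)
  expect_error(lookup_candidates(181.0710, glucose_db(),
                                 default_adducts(), 0), "tol_ppm")
})

test_that("lookup equals a brute-force scan over all compound x adduct pairs", {
  set.seed(17)
  for (trial in 1:25) {
    db <- data.frame(compound_id = sprintf("C%03d", 1:40),
                     name = sprintf("c%03d", 1:40),
                     monoisotopic_mass = runif(40, 50, 880))
    adducts <- default_adducts()
    mz <- runif(1, 50, 900)
    # sometimes aim straight at an adduct mass to force hits
    if (trial %% 2 == 0) {
      mz <- (sample(db$monoisotopic_mass, 1) + 1.007276) * (1 + runif(1, -8e-6, 8e-6))
    }
    got <- lookup_candidates(mz, db, adducts, tol_ppm = 10)
    want <- bf_lookup(mz, db, adducts, tol_ppm = 10)
    expect_setequal(paste(got$compound_id, got$adduct),
                    paste(want$compound_id, want$adduct))
  }
})

test_that("correlation graph handles perfect, negated and sub-threshold peaks", {
  base <- c(1, 2, 3, 4, 5, 7, 6, 9, 8, 10)
  x <- cbind(base, base, max(base) - base, rep(3, 10))
  set.seed(3)
  x <- cbind(x, runif(10))
  tab <- peak_table(c(100, 110, 120, 130, 140), x, sprintf("s%d", 1:10))
  g <- build_correlation_graph(tab, corr_threshold = 0.95)
  key <- paste(g$edges$i, g$edges$j)
  expect_true("1 2" %in% key)
  expect_equal(g$edges$r[key == "1 2"], 1.0)
  expect_true("1 3" %in% key)
  expect_equal(g$edges$r[key == "1 3"], -1.0)  # |r| passes, sign kept
  # the constant (zero-variance) peak 4 gets no edges
  expect_false(any(g$edges$i == 4 | g$edges$j == 4))
  expect_error(build_correlation_graph(subset_samples <- peak_table(
    c(100), matrix(1:2, 2, 1), c("a", "b")), 0.5), ">= 3 samples")
})

test_that("correlation edges equal an all-pairs brute force on random data", {
  tab <- random_peak_table(20, 10, seed = 19)
  g <- build_correlation_graph(tab, corr_threshold = 0.3)
  r <- cor(tab$intensities)
  want <- which(abs(r) >= 0.3 & upper.tri(r), arr.ind = TRUE)
  expect_setequal(paste(g$edges$i, g$edges$j), paste(want[, 1], want[, 2]))
})

test_that("context annotation retains the pathway-bunched candidate and declines the isolated one", {
  # pathway edge A-B, compound C isolated; peak 1 ~ {A, C}, peak 2 ~ {B},
  # peaks 1 and 2 correlated
  db <- data.frame(compound_id = c("A", "B", "C"), name = c("a", "b", "c"),
                   monoisotopic_mass = c(101, 102, 103))
  pg <- pathway_graph(data.frame(pathway_id = "P", compound_id = c("A", "B")),
                      db)
  candidates <- data.frame(
    peak_index = c(1L, 1L, 2L), mz = c(102, 102, 103),
    compound_id = c("A", "C", "B"), adduct = "[M+H]+", mass_error_ppm = 0,
    stringsAsFactors = FALSE)
  corr <- structure(list(n_peaks = 2,
                         edges = data.frame(i = 1L, j = 2L, r = 0.9)),
                    class = "correlation_graph")
  ann <- context_annotate(candidates, corr, pg,
                          pathway_distance = 1, min_support = 1)
  a <- ann$assignments
  expect_true(a$retained[a$compound_id == "A"])
  expect_equal(a$support[a$compound_id == "A"], 1L)
  expect_false(a$retained[a$compound_id == "C"])
  expect_equal(a$support[a$compound_id == "C"], 0L)
  expect_true(a$retained[a$compound_id == "B"])  # supported back by peak 1
})

test_that("without correlation edges no candidate is retained at min_support 1", {
  db <- data.frame(compound_id = c("A", "B"), name = c("a", "b"),
                   monoisotopic_mass = c(101, 102))
  pg <- pathway_graph(data.frame(pathway_id = "P", compound_id = c("A", "B")), db)
  candidates <- data.frame(peak_index = c(1L, 2L), mz = c(102, 103),
                           compound_id = c("A", "B"), adduct = "[M+H]+",
                           mass_error_ppm = 0, stringsAsFactors = FALSE)
  corr <- structure(list(n_peaks = 2,
                         edges = data.frame(i = integer(0), j = integer(0),
                                            r = numeric(0))),
                    class = "correlation_graph")
  ann <- context_annotate(candidates, corr, pg, 1, 1)
  expect_false(any(ann$assignments$retained))
  expect_equal(annotation_stats(ann)$n_peaks_annotated, 0)
})

test_that("context annotation equals exhaustive brute force on random instances", {
  for (seed in 1:40) {
    inst <- random_context_instance(seed)
    if (!nrow(inst$candidates)) next
    got <- context_annotate(inst$candidates, inst$corr, inst$pathways,
                            inst$distance, inst$min_support)$assignments
    want <- bf_context(inst$candidates, inst$corr$edges, inst$nodes,
                       inst$pathway_edges, inst$distance, inst$min_support)
    expect_equal(got$support, want$support,
                 info = sprintf("seed %d support", seed))
    expect_equal(got$retained, want$retained,
                 info = sprintf("seed %d retained", seed))
  }
})

test_that("support is monotone in pathway distance and in correlation threshold", {
  for (seed in 41:50) {
    inst <- random_context_instance(seed)
    if (!nrow(inst$candidates)) next
    s1 <- context_annotate(inst$candidates, inst$corr, inst$pathways,
                           pathway_distance = 1, min_support = 0)$assignments$support
    s2 <- context_annotate(inst$candidates, inst$corr, inst$pathways,
                           pathway_distance = 3, min_support = 0)$assignments$support
    expect_true(all(s2 >= s1))
    # dropping correlation edges can only lower support
    fewer <- inst$corr
    fewer$edges <- fewer$edges[0, , drop = FALSE]
    s3 <- context_annotate(inst$candidates, fewer, inst$pathways,
                           pathway_distance = 1, min_support = 0)$assignments$support
    s4 <- context_annotate(inst$candidates, inst$corr, inst$pathways,
                           pathway_distance = 1, min_support = 0)$assignments$support
    expect_true(all(s3 <= s4))
  }
})

test_that("annotation stats count annotated peaks and deduplicated compounds", {
  empty <- context_annotate(
    data.frame(peak_index = integer(0), mz = numeric(0),
               compound_id = character(0), adduct = character(0),
               mass_error_ppm = numeric(0)),
    structure(list(n_peaks = 0, edges = data.frame(i = integer(0),
                                                   j = integer(0),
                                                   r = numeric(0))),
              class = "correlation_graph"),
    pathway_graph(NULL, data.frame(compound_id = "A", name = "a",
                                   monoisotopic_mass = 101)))
  st <- annotation_stats(empty)
  expect_equal(unlist(st), c(n_masses_submitted = 0, n_pairs_submitted = 0,
                             n_peaks_annotated = 0, n_unique_compounds = 0))

  # two peaks both retaining compound X count once in unique compounds
  ann <- list(assignments = data.frame(
    peak_index = c(1L, 2L), compound_id = c("X", "X"),
    retained = c(TRUE, TRUE)), stats = NULL)
  ann$stats <- list(n_masses_submitted = 2, n_pairs_submitted = 2,
                    n_peaks_annotated = 2, n_unique_compounds = 1)
  class(ann) <- "annotation_table"
  expect_equal(annotation_stats(ann)$n_peaks_annotated, 2)
  expect_equal(annotation_stats(ann)$n_unique_compounds, 1)
  expect_identical(retained_compounds(ann), "X")
})

test_that("annotation stats agree with the generator's bookkeeping", {
  ref <- generate_reference(seed = 5)
  cohort <- generate_cohort(ref, seed = 6)
  cfg <- default_config()
  ann <- annotate_peak_table(cohort$table, ref$db, ref$pathways, cfg)
  st <- annotation_stats(ann)
  expect_equal(st$n_masses_submitted, length(cohort$table$mz))
  retained <- ann$assignments[ann$assignments$retained, ]
  expect_equal(st$n_peaks_annotated, length(unique(retained$peak_index)))
  expect_equal(st$n_unique_compounds, length(unique(retained$compound_id)))
  # the generator's true compound is retained for every annotated peak
  truth <- cohort$ground_truth$true_annotations
  hit <- tapply(retained$compound_id == truth[retained$peak_index],
                retained$peak_index, any)
  expect_true(all(hit))
})
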