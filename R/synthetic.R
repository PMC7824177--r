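#' Generate a synthetic metabolite reference
#'
#' Builds a compound database with well-separated monoisotopic masses
#' (minimum 5 ppm mutual spacing, so adduct lookup is unambiguous unless
#' ambiguity is injected), a pathway graph of disjoint random compound
#' blocks, and four metabolite set collections assembled as random unions of
#' pathway fragments. The default collection sizes are one-tenth-scale
#' mirrors of a full reference (631 disease, 808 pathway, 352
#' abnormal-concentration and 110 location sets).
#'
#' @param n_compounds number of compounds; must be at least the maximum
#'   pathway size.
#' @param n_pathways number of disjoint pathways to carve out.
#' @param pathway_size_range integer range of pathway sizes.
#' @param n_sets_per_category named integer vector over
#'   [set_categories()].
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return list with `db`, `membership` (pathway membership data.frame),
#'   `pathways` (a [pathway_graph()]), `collections` (named list of four
#'   [metabolite_set_collection()]s) and a `ground_truth` skeleton.
#' @export
generate_reference <- function(n_compounds = 160,
                               n_pathways = 25,
                               pathway_size_range = c(4, 8),
                               n_sets_per_category = c(
                                 disease = 63, pathway = 81,
                                 abnormal_concentration = 35, location = 11),
                               seed = 1) {
  if (n_compounds < max(pathway_size_range)) {
    stop("n_compounds must be >= the maximum pathway size")
  }
  cats <- set_categories()
  if (is.null(names(n_sets_per_category))) {
    names(n_sets_per_category) <- cats[seq_along(n_sets_per_category)]
  }
  with_seed(seed, {
    masses <- spaced_masses(n_compounds, low = 45, high = 900, min_ppm = 5)
    ids <- sprintf("C%04d", seq_len(n_compounds))
    db <- data.frame(compound_id = ids,
                     name = sprintf("Compound %04d", seq_len(n_compounds)),
                     monoisotopic_mass = masses,
                     kegg_id = sprintf("K%05d", seq_len(n_compounds)),
                     stringsAsFactors = FALSE)

    pool <- sample(ids)
    sizes <- sample(seq(pathway_size_range[1], pathway_size_range[2]),
                    n_pathways, replace = TRUE)
    membership <- list()
    used <- 0
    for (p in seq_len(n_pathways)) {
      if (used + sizes[p] > length(pool)) break
      members <- pool[(used + 1):(used + sizes[p])]
      used <- used + sizes[p]
      membership[[sprintf("PW%03d", p)]] <- members
    }
    membership_df <- data.frame(
      pathway_id = rep(names(membership), lengths(membership)),
      compound_id = unlist(membership, use.names = FALSE),
      stringsAsFactors = FALSE)

    collections <- lapply(cats, function(cat) {
      n_sets <- n_sets_per_category[[cat]]
      if (is.null(n_sets) || is.na(n_sets)) n_sets <- 10
      sets <- lapply(seq_len(n_sets), function(s) {
        n_frag <- sample(1:3, 1)
        pws <- sample(names(membership), min(n_frag, length(membership)))
        unique(unlist(lapply(pws, function(pw) {
          members <- membership[[pw]]
          take <- sample(seq(2, max(2, length(members))), 1)
          sample(members, min(take, length(members)))
        })))
      })
      names(sets) <- sprintf("%s_set_%03d", cat, seq_len(n_sets))
      metabolite_set_collection(sets, cat)
    })
    names(collections) <- cats

    list(db = db,
         membership = membership_df,
         pathways = pathway_graph(membership_df, db = db),
         collections = collections,
         ground_truth = list(true_annotations = NULL,
                             effect_sets = character(0),
                             effect_size = NA_real_,
                             decoys = character(0),
                             planted_abnormal = list()))
  })
}

# n masses uniform in [low, high] with a minimum pairwise spacing of min_ppm,
# by iterative resampling of violating draws.
spaced_masses <- function(n, low = 45, high = 900, min_ppm = 5) {
  # crude feasibility: total span needed at the high end
  if (n * (min_ppm * 1e-6 * high) > (high - low) / 2) {
    stop("mass spacing of ", min_ppm, " ppm is infeasible for n = ", n)
  }
  masses <- sort(runif(n, low, high))
  for (iter in seq_len(1000)) {
    gaps_ok <- c(TRUE, diff(masses) / masses[-n] * 1e6 >= min_ppm)
    if (all(gaps_ok)) return(masses)
    masses[!gaps_ok] <- runif(sum(!gaps_ok), low, high)
    masses <- sort(masses)
  }
  stop("could not satisfy the ", min_ppm, " ppm mass spacing after 1000 rounds")
}

#' Inject mass-ambiguity decoys into a reference
#'
#' Adds decoy compounds whose monoisotopic masses sit within `tol_ppm` of
#' randomly chosen existing compounds, so that candidate lookup returns
#' several candidates per peak and the context annotation step has something
#' to disambiguate. Decoys belong to no pathway (isolated pathway-graph
#' nodes) and are recorded in the ground truth.
#'
#' @param reference a [generate_reference()] result.
#' @param n_collisions how many decoys to add (at most one per target
#'   compound).
#' @param tol_ppm the lookup tolerance the decoys must fall inside; decoys
#'   are placed within half of it.
#' @param seed RNG seed.
#' @return the modified reference.
#' @export
inject_ambiguity <- function(reference, n_collisions, tol_ppm = 10, seed = 1) {
  if (n_collisions == 0) return(reference)
  if (n_collisions > nrow(reference$db)) {
    stop("n_collisions exceeds the number of target compounds")
  }
  with_seed(seed, {
    targets <- sample(seq_len(nrow(reference$db)), n_collisions)
    delta_ppm <- runif(n_collisions, -0.5, 0.5) * tol_ppm
    decoys <- data.frame(
      compound_id = sprintf("DECOY%03d", seq_len(n_collisions)),
      name = sprintf("Decoy of %s", reference$db$compound_id[targets]),
      monoisotopic_mass = reference$db$monoisotopic_mass[targets] *
        (1 + delta_ppm * 1e-6),
      kegg_id = rep(NA_character_, n_collisions),
      stringsAsFactors = FALSE)
    reference$db <- rbind(reference$db, decoys)
    reference$pathways <- pathway_graph(reference$membership,
                                        db = reference$db)
    reference$ground_truth$decoys <- c(reference$ground_truth$decoys,
                                       decoys$compound_id)
    reference
  })
}

#' Generate a synthetic case-control cohort
#'
#' One peak per compound at its protonated m/z. Intensities are log-normal
#' with a shared per-sample pathway latent factor so that same-pathway peaks
#' correlate at about `within_pathway_corr`; case samples have the
#' intensities of the effect sets' member compounds multiplied by
#' `effect_size`. Defaults emulate a 28 control / 28 case cohort.
#'
#' @param reference a [generate_reference()] result.
#' @param n_controls,n_cases group sizes (default 28 each).
#' @param effect_sets names of sets (in any collection) whose members carry
#'   the planted case effect.
#' @param effect_size multiplicative intensity shift on case samples;
#'   1 = no effect.
#' @param within_pathway_corr target Pearson correlation of log-intensities
#'   within a pathway, in \[0, 1).
#' @param noise_cv coefficient of variation of the log-normal intensity noise.
#' @param n_decoy_peaks unannotatable extra peaks at random m/z.
#' @param seed RNG seed.
#' @return list with `table` (labeled [peak_table()]), `ground_truth`
#'   (true peak-to-compound annotations, effect sets/compounds, decoy peaks)
#'   and `reference`.
#' @export
generate_cohort <- function(reference, n_controls = 28, n_cases = 28,
                            effect_sets = character(0), effect_size = 1,
                            within_pathway_corr = 0.8, noise_cv = 0.3,
                            n_decoy_peaks = 0, seed = 1) {
  if (within_pathway_corr < 0 || within_pathway_corr >= 1) {
    stop("within_pathway_corr must be in [0, 1)")
  }
  all_sets <- unlist(lapply(reference$collections, function(cl) cl$sets),
                     recursive = FALSE)
  names(all_sets) <- unlist(lapply(reference$collections,
                                   function(cl) names(cl$sets)))
  missing <- setdiff(effect_sets, names(all_sets))
  if (length(missing)) {
    stop("effect set(s) not found in the collections: ",
         paste(missing, collapse = ", "))
  }
  effect_compounds <- unique(unlist(all_sets[effect_sets], use.names = FALSE))

  with_seed(seed, {
    db <- reference$db
    n_c <- nrow(db)
    n_samp <- n_controls + n_cases
    sample_ids <- c(sprintf("CTRL%02d", seq_len(n_controls)),
                    sprintf("CASE%02d", seq_len(n_cases)))
    labels <- c(rep("control", n_controls), rep("case", n_cases))

    pw_of <- setNames(reference$membership$pathway_id,
                      reference$membership$compound_id)[db$compound_id]
    pw_ids <- unique(pw_of[!is.na(pw_of)])

    sigma <- sqrt(log(1 + noise_cv^2))
    rho <- within_pathway_corr
    mu <- runif(n_c, log(1e3), log(1e5))

    latent <- matrix(rnorm(n_samp * length(pw_ids)), n_samp, length(pw_ids),
                     dimnames = list(NULL, pw_ids))
    eps <- matrix(rnorm(n_samp * n_c), n_samp, n_c)
    z <- eps
    has_pw <- !is.na(pw_of)
    if (any(has_pw)) {
      z[, has_pw] <- sqrt(rho) * latent[, pw_of[has_pw], drop = FALSE] +
        sqrt(1 - rho) * eps[, has_pw, drop = FALSE]
    }
    x <- exp(matrix(mu, n_samp, n_c, byrow = TRUE) + sigma * z)

    if (effect_size != 1 && length(effect_compounds)) {
      eff_cols <- db$compound_id %in% effect_compounds
      x[labels == "case", eff_cols] <- x[labels == "case", eff_cols] * effect_size
    }

    mz <- (db$monoisotopic_mass + 1.007276) / 1
    true_ann <- db$compound_id
    if (n_decoy_peaks > 0) {
      decoy_mz <- runif(n_decoy_peaks, 46, 901)
      decoy_x <- exp(matrix(runif(n_decoy_peaks, log(1e3), log(1e5)),
                            n_samp, n_decoy_peaks, byrow = TRUE) +
                     sigma * matrix(rnorm(n_samp * n_decoy_peaks),
                                    n_samp, n_decoy_peaks))
      mz <- c(mz, decoy_mz)
      x <- cbind(x, decoy_x)
      true_ann <- c(true_ann, rep(NA_character_, n_decoy_peaks))
    }

    ord <- order(mz)
    table <- peak_table(mz[ord], x[, ord, drop = FALSE], sample_ids, labels)
    ground_truth <- reference$ground_truth
    ground_truth$true_annotations <- true_ann[ord]
    ground_truth$effect_sets <- effect_sets
    ground_truth$effect_size <- effect_size
    ground_truth$effect_compounds <- effect_compounds
    ground_truth$decoy_peaks <- which(is.na(true_ann[ord]))

    list(table = table, ground_truth = ground_truth, reference = reference)
  })
}

#' Plant per-sample abnormal concentrations
#'
#' Spikes one sample's peaks for the given compounds to
#' `mean_rest + n_sd * sd_rest` (computed over all other samples), the
#' planted-abnormality fixture for individual-profiling tests.
#'
#' @param cohort a [generate_cohort()] result.
#' @param sample_id the sample to modify.
#' @param compound_ids compounds whose peaks are spiked.
#' @param n_sd size of the shift in reference standard deviations; default 5.
#' @return the modified cohort, with the plant recorded in the ground truth.
#' @export
plant_abnormalities <- function(cohort, sample_id, compound_ids, n_sd = 5) {
  table <- cohort$table
  s <- match(sample_id, table$sample_ids)
  if (is.na(s)) stop("unknown sample_id: ", sample_id)
  peaks <- which(cohort$ground_truth$true_annotations %in% compound_ids)
  if (!length(peaks)) stop("no peaks correspond to the requested compounds")
  rest <- table$intensities[-s, peaks, drop = FALSE]
  m <- colMeans(rest)
  sd_rest <- apply(rest, 2, sd)
  table$intensities[s, peaks] <- pmax(0, m + n_sd * sd_rest)
  cohort$table <- table
  cohort$ground_truth$planted_abnormal[[sample_id]] <-
    unique(c(cohort$ground_truth$planted_abnormal[[sample_id]], compound_ids))
  cohort
}

#' Write a synthetic reference and cohort to disk
#'
#' Emits every fixture the pipeline readers consume: the peak table, the
#' metabolite database, the pathway membership, the four GMT collections,
#' sample labels, a default run config and the ground truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @param config a [default_config()] list to write alongside.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = default_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- cohort$reference
  paths <- c(
    peak_table = file.path(dir, "peaks.tsv"),
    metabolite_db = file.path(dir, "metabolite_db.tsv"),
    pathway_membership = file.path(dir, "pathway_membership.tsv"),
    labels = file.path(dir, "labels.tsv"),
    config = file.path(dir, "config.txt"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_peak_table(cohort$table, paths[["peak_table"]])
  write_metabolite_db(ref$db, paths[["metabolite_db"]])
  write_pathway_membership(ref$pathways, paths[["pathway_membership"]])
  write.table(data.frame(sample_id = cohort$table$sample_ids,
                         label = cohort$table$labels),
              paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  for (cat in names(ref$collections)) {
    p <- file.path(dir, paste0("sets_", cat, ".gmt"))
    write_gmt(ref$collections[[cat]], p)
    paths[[paste0("gmt_", cat)]] <- p
  }
  gt <- cohort$ground_truth
  gt$decoy_peaks <- as.integer(gt$decoy_peaks)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       null = "null", na = "null")
  write_run_config(config, paths[["config"]],
                   extra = as.list(paths[!names(paths) %in% "config"]))
  invisible(paths)
}
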