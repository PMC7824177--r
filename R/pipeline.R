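#' Run the full LDT pipeline from a config file
#'
#' Reads every input named in the flat key=value config (`peak_table`,
#' `metabolite_db`, `pathway_membership`, `labels`, `gmt_disease`,
#' `gmt_pathway`, `gmt_abnormal_concentration`, `gmt_location`, `mode`,
#' optionally `sample_id` and `out_dir`), preprocesses the peak table,
#' annotates it, and then either evaluates the labeled cohort
#' (`mode=evaluate`) or profiles one individual (`mode=profile`). All result
#' tables (TSV), summaries (JSON), name clouds (SVG), a run log with
#' parameter echo and stage counts, and a manifest are written under the run
#' directory.
#'
#' @param config_path path to the config file.
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return list with `report` (or `profile`) and `artifacts` (named paths),
#'   invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- read_run_config(config_path)
  extra <- attr(cfg, "extra")
  mode <- extra$mode %||% "evaluate"
  if (!mode %in% c("evaluate", "profile")) {
    stop("config error: mode must be 'evaluate' or 'profile', got '",
         mode, "'")
  }
  out_dir <- out_dir %||% extra$out_dir %||% dirname(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  resolve <- function(key) {
    p <- extra[[key]]
    if (is.null(p)) stop("config error: missing input path '", key, "'")
    if (!file.exists(p)) {
      p2 <- file.path(dirname(config_path), p)
      if (!file.exists(p2)) stop("config error: input '", key,
                                 "' not found at ", p)
      p <- p2
    }
    p
  }

  say("config: %s", config_path)
  say("parameters: tol=%g ppm, mz=[%g,%g], min_nonzero=%d, corr>=%g, d<=%d, min_support=%d, n_perm=%d, z>=%g, top_k=%d, seed=%d",
      cfg$mass_tol_ppm, cfg$mz_range[1], cfg$mz_range[2],
      as.integer(cfg$min_nonzero_samples), cfg$corr_threshold,
      as.integer(cfg$pathway_distance), as.integer(cfg$min_support),
      as.integer(cfg$n_perm), cfg$z_threshold, as.integer(cfg$top_k),
      as.integer(cfg$seed))

  labels <- read_labels(resolve("labels"))
  table <- read_peak_table(resolve("peak_table"), labels = labels)
  db <- read_metabolite_db(resolve("metabolite_db"))
  pathways <- read_pathway_membership(resolve("pathway_membership"), db = db)
  collections <- list()
  for (cat in set_categories()) {
    key <- paste0("gmt_", cat)
    if (!is.null(extra[[key]])) {
      collections[[cat]] <- read_gmt(resolve(key), cat)
    }
  }
  if (!length(collections)) stop("config error: no gmt_* collection given")
  say("inputs: %d samples x %d peaks, %d compounds, %d collections",
      n_samples(table), n_peaks(table), nrow(db), length(collections))

  table <- preprocess_peak_table(table, cfg, quiet = TRUE)
  counts <- attr(table, "counts")
  say("preprocess: %d peaks in, %d after mass range, %d after prevalence",
      counts["input"], counts["after_mass_range"], counts["after_prevalence"])

  annotations <- annotate_peak_table(table, db, pathways, cfg)
  st <- annotation_stats(annotations)
  say("annotate: %d masses, %d pairs, %d peaks annotated, %d unique compounds",
      st$n_masses_submitted, st$n_pairs_submitted, st$n_peaks_annotated,
      st$n_unique_compounds)

  artifacts <- c(log = log_path)
  ann_path <- file.path(out_dir, "annotations.tsv")
  write.table(annotations$assignments, ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(st, file.path(out_dir, "annotation_stats.json"),
                       auto_unbox = TRUE)
  artifacts["annotations"] <- ann_path
  artifacts["annotation_stats"] <- file.path(out_dir, "annotation_stats.json")

  result <- NULL
  if (mode == "evaluate") {
    report <- evaluate_pipeline(table, annotations, collections, cfg)
    for (cat in names(report$per_category)) {
      p <- file.path(out_dir, sprintf("contrast_%s.tsv", cat))
      df <- report$per_category[[cat]]$contrast
      df_out <- df
      num <- vapply(df_out, is.numeric, logical(1))
      df_out[num] <- lapply(df_out[num], function(v) round(v, 4))
      write.table(df_out, p, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts[paste0("contrast_", cat)] <- p
      cloud <- file.path(out_dir, sprintf("cloud_%s.svg", cat))
      render_cloud(data.frame(set_name = df$set_name,
                              score = df$over_representation), cloud)
      artifacts[paste0("cloud_", cat)] <- cloud
    }
    diag_path <- file.path(out_dir, "diagnostic_scores.tsv")
    write.table(data.frame(sample_id = names(report$diagnostic_scores),
                           label = unname(report$labels),
                           diagnostic_score = round(unname(report$diagnostic_scores), 6)),
                diag_path, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts["diagnostic_scores"] <- diag_path
    jsonlite::write_json(
      c(report$summary,
        list(youden = as.list(report$roc$youden))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    artifacts["summary"] <- file.path(out_dir, "summary.json")
    say("evaluate: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f",
        report$summary$accuracy, report$summary$sensitivity,
        report$summary$specificity, report$summary$auc)
    result <- report
  } else {
    sid <- extra$sample_id
    if (is.null(sid)) stop("config error: mode=profile needs sample_id")
    prof <- profile_individual(table, sid, annotations, collections, cfg,
                               reference = cfg$loo_reference %||% "all")
    for (cat in names(prof$scores)) {
      p <- file.path(out_dir, sprintf("profile_%s_%s.tsv", sid, cat))
      write.table(prof$scores[[cat]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      artifacts[paste0("profile_", cat)] <- p
      cloud <- file.path(out_dir, sprintf("cloud_%s_%s.svg", sid, cat))
      render_cloud(prof$scores[[cat]], cloud)
      artifacts[paste0("cloud_", cat)] <- cloud
    }
    jsonlite::write_json(
      list(sample_id = sid,
           n_abnormal_peaks = length(prof$abnormal_peaks),
           selection = prof$selection$metabolite_ids,
           max_scores = lapply(prof$scores, function(s) {
             if (nrow(s)) max(s$score) else 0
           })),
      file.path(out_dir, sprintf("profile_%s.json", sid)),
      auto_unbox = TRUE, digits = NA)
    artifacts["profile_summary"] <- file.path(out_dir,
                                              sprintf("profile_%s.json", sid))
    say("profile %s: %d abnormal peaks, %d selected metabolites",
        sid, length(prof$abnormal_peaks),
        length(prof$selection$metabolite_ids))
    result <- prof
  }

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(as.list(artifacts), manifest, auto_unbox = TRUE)
  artifacts["manifest"] <- manifest
  writeLines(log_lines, log_path)
  invisible(list(result = result, artifacts = artifacts, config = cfg))
}
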