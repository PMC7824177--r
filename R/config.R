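#' Default run configuration
#'
#' Parameters of the full LDT pipeline with their defaults: 10 ppm mass
#' tolerance, positive-mode \[M+H\]+ and \[M+Na\]+ adducts, detection mass
#' range 45-900 m/z, prevalence threshold of 10 nonzero samples ("more than
#' nine"), Pearson correlation threshold 0.7, pathway adjacency distance 1,
#' minimum context support 1, 30,000 permutation draws, LOO z threshold 2,
#' top-20 diagnostic sum, total-signal normalization target 1e4.
#'
#' @param ... named overrides of individual fields.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    mass_tol_ppm = 10,
    adducts = default_adducts(),
    mz_range = c(45, 900),
    min_nonzero_samples = 10,
    corr_threshold = 0.7,
    pathway_distance = 1,
    min_support = 1,
    n_perm = 30000,
    z_threshold = 2,
    top_k = 20,
    seed = 1,
    target_sum = 1e4,
    loo_reference = "controls",
    log_transform = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "run_config"))
}

#' Default positive-mode adduct list
#'
#' \[M+H\]+ (shift +1.007276 Da) and \[M+Na\]+ (shift +22.989218 Da), both
#' singly charged.
#' @return data.frame with columns `name`, `mass_shift`, `charge`.
#' @export
default_adducts <- function() {
  data.frame(name = c("[M+H]+", "[M+Na]+"),
             mass_shift = c(1.007276, 22.989218),
             charge = c(1L, 1L),
             stringsAsFactors = FALSE)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$mass_tol_ppm > 0,
    nrow(cfg$adducts) >= 1,
    length(cfg$mz_range) == 2, cfg$mz_range[1] < cfg$mz_range[2],
    cfg$min_nonzero_samples >= 1,
    cfg$corr_threshold > 0, cfg$corr_threshold <= 1,
    cfg$pathway_distance >= 0,
    cfg$min_support >= 0,
    cfg$n_perm >= 1,
    cfg$z_threshold > 0,
    cfg$top_k >= 1,
    cfg$target_sum > 0,
    cfg$loo_reference %in% c("all", "controls")
  )
  cfg
}

#' Read a flat key=value run configuration file
#'
#' Unset keys take the [default_config()] values. Adducts are written as
#' `name:shift:charge` triplets separated by commas; `mz_range` as `low,high`.
#'
#' @param path path to the config file.
#' @return A `run_config` list; extra (non-config) keys such as input paths
#'   are kept in the `extra` attribute.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  known_num <- c("mass_tol_ppm", "min_nonzero_samples", "corr_threshold",
                 "pathway_distance", "min_support", "n_perm", "z_threshold",
                 "top_k", "seed", "target_sum")
  overrides <- list()
  extra <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]; val <- vals[i]
    if (key %in% known_num) {
      overrides[[key]] <- as.numeric(val)
    } else if (key == "mz_range") {
      overrides[[key]] <- as.numeric(strsplit(val, ",")[[1]])
    } else if (key == "adducts") {
      parts <- strsplit(strsplit(val, ",")[[1]], ":")
      overrides[[key]] <- data.frame(
        name = vapply(parts, `[`, character(1), 1),
        mass_shift = as.numeric(vapply(parts, `[`, character(1), 2)),
        charge = as.integer(vapply(parts, `[`, character(1), 3)),
        stringsAsFactors = FALSE)
    } else if (key == "loo_reference") {
      overrides[[key]] <- val
    } else if (key == "log_transform") {
      overrides[[key]] <- toupper(val) %in% c("TRUE", "1", "YES")
    } else {
      extra[[key]] <- val
    }
  }
  cfg <- do.call(default_config, overrides)
  attr(cfg, "extra") <- extra
  cfg
}

#' Write a run configuration as flat key=value text
#' @param cfg a `run_config` list.
#' @param path output path.
#' @param extra optional named character list appended verbatim (input paths,
#'   mode, ...).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path, extra = NULL) {
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("mass_tol_ppm=", fmt_num(cfg$mass_tol_ppm)),
    paste0("adducts=", paste(sprintf("%s:%s:%d", cfg$adducts$name,
                                     fmt_num(cfg$adducts$mass_shift),
                                     cfg$adducts$charge), collapse = ",")),
    paste0("mz_range=", paste(fmt_num(cfg$mz_range), collapse = ",")),
    paste0("min_nonzero_samples=", fmt_num(cfg$min_nonzero_samples)),
    paste0("corr_threshold=", fmt_num(cfg$corr_threshold)),
    paste0("pathway_distance=", fmt_num(cfg$pathway_distance)),
    paste0("min_support=", fmt_num(cfg$min_support)),
    paste0("n_perm=", fmt_num(cfg$n_perm)),
    paste0("z_threshold=", fmt_num(cfg$z_threshold)),
    paste0("top_k=", fmt_num(cfg$top_k)),
    paste0("seed=", fmt_num(cfg$seed)),
    paste0("target_sum=", fmt_num(cfg$target_sum)),
    paste0("loo_reference=", cfg$loo_reference),
    paste0("log_transform=", cfg$log_transform)
  )
  if (!is.null(extra)) {
    lines <- c(lines, paste0(names(extra), "=", unlist(extra)))
  }
  writeLines(lines, path)
  invisible(path)
}
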