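#' Read a wide-format peak table
#'
#' The on-disk layout is peaks-as-rows: the first column, headed `mz`, holds
#' the m/z values and every remaining column is one sample. In memory the
#' table is transposed to samples x peaks.
#'
#' @param path path to the file.
#' @param dialect `"wide_tsv"` (default) or `"wide_csv"`.
#' @param labels optional named character vector (or data.frame with columns
#'   `sample_id`, `label`) assigning `"control"`/`"case"`/`"unknown"` labels.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("wide_tsv", "wide_csv"),
                            labels = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "wide_tsv") "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2 || names(df)[1] != "mz") {
    stop("peak table must have a first column named 'mz' and >= 1 sample")
  }
  sample_ids <- names(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df)))
  )
  num <- matrix(num, nrow = nrow(df), dimnames = list(NULL, names(df)))
  bad <- which(is.na(num) & !is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1, 1], names(df)[bad[1, 2]]))
  }
  lab <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- setNames(as.character(labels$label), labels$sample_id)
    }
    lab <- unname(labels[sample_ids])
    lab[is.na(lab)] <- "unknown"
  }
  peak_table(mz = num[, 1],
             intensities = t(num[, -1, drop = FALSE]),
             sample_ids = sample_ids, labels = lab)
}

#' Write a peak table in wide format
#'
#' @param table a [peak_table()].
#' @param path output path.
#' @param dialect `"wide_tsv"` or `"wide_csv"`.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, dialect = c("wide_tsv", "wide_csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "wide_tsv") "\t" else ","
  df <- data.frame(mz = table$mz, t(table$intensities), check.names = FALSE)
  names(df) <- c("mz", table$sample_ids)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a metabolite set collection
#'
#' @param sets named list of character vectors of compound ids.
#' @param category one of `"disease"`, `"pathway"`, `"abnormal_concentration"`,
#'   `"location"`.
#' @return An object of class `metabolite_set_collection`.
#' @export
metabolite_set_collection <- function(sets, category) {
  category <- match.arg(category, set_categories())
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop("set names must be unique and non-empty")
    }
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(lengths(sets) == 0)) stop("empty metabolite set not allowed")
  }
  structure(list(category = category, sets = sets),
            class = "metabolite_set_collection")
}

#' @export
print.metabolite_set_collection <- function(x, ...) {
  cat(sprintf("<metabolite_set_collection> category=%s, %d sets\n",
              x$category, length(x$sets)))
  invisible(x)
}

#' The four metabolite set categories
#'
#' Disease-associated, pathway-associated, abnormal-concentration and
#' location-based sets, in their conventional order.
#' @return character vector of length 4.
#' @export
set_categories <- function() {
  c("disease", "pathway", "abnormal_concentration", "location")
}

#' Read a GMT metabolite set file
#'
#' Each line is `set_name TAB description TAB member TAB member ...`.
#' Members are deduplicated; a line with fewer than three fields is an error.
#'
#' @param path path to the GMT file.
#' @param category the collection category (see [set_categories()]).
#' @return A [metabolite_set_collection()].
#' @export
read_gmt <- function(path, category) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); expected >= 3",
                   i, length(fields)))
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  metabolite_set_collection(sets, category)
}

#' Write a metabolite set collection as GMT
#'
#' @param collection a [metabolite_set_collection()].
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  nm <- names(collection$sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], descriptions[i], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolite database table
#'
#' TSV with columns `compound_id`, `name`, `monoisotopic_mass` and optionally
#' further cross-reference columns, which are kept as-is.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per compound.
#' @export
read_metabolite_db <- function(path) {
  db <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("compound_id", "name", "monoisotopic_mass")
  missing <- setdiff(required, names(db))
  if (length(missing)) {
    stop("metabolite db is missing column(s): ", paste(missing, collapse = ", "))
  }
  db$monoisotopic_mass <- as.numeric(db$monoisotopic_mass)
  if (any(!is.finite(db$monoisotopic_mass)) || any(db$monoisotopic_mass <= 0)) {
    stop("monoisotopic_mass must be a positive number for every compound")
  }
  if (anyDuplicated(db$compound_id)) {
    stop("duplicate compound_id in metabolite db")
  }
  db
}

#' Write a metabolite database table
#' @param db data.frame as returned by [read_metabolite_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_db <- function(db, path) {
  write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pathway graph from membership rows
#'
#' Compounds sharing at least one pathway are connected (clique expansion of
#' each pathway's member list), matching the adjacency notion used by the
#' context annotation step: true annotations must be bunched in the pathway
#' neighborhood of correlated peaks.
#'
#' @param membership data.frame with columns `pathway_id`, `compound_id`.
#' @param db optional metabolite database; its compounds become (possibly
#'   isolated) nodes, and membership compounds absent from the db trigger a
#'   warning but are kept as nodes.
#' @return An object of class `pathway_graph`: list with `graph` (igraph),
#'   `membership` (named list pathway -> compound ids).
#' @export
pathway_graph <- function(membership, db = NULL) {
  if (!is.null(membership) && nrow(membership)) {
    required <- c("pathway_id", "compound_id")
    if (!all(required %in% names(membership))) {
      stop("membership needs columns pathway_id, compound_id")
    }
    membership <- unique(membership[, required])
    by_pw <- split(as.character(membership$compound_id),
                   as.character(membership$pathway_id))
  } else {
    by_pw <- list()
  }
  nodes <- unique(c(if (!is.null(db)) as.character(db$compound_id),
                    unlist(by_pw, use.names = FALSE)))
  if (!is.null(db)) {
    unknown <- setdiff(unlist(by_pw, use.names = FALSE), db$compound_id)
    if (length(unknown)) {
      warning("membership references compound(s) absent from db: ",
              paste(head(unknown, 5), collapse = ", "),
              if (length(unknown) > 5) ", ...")
    }
  }
  edges <- character(0)
  for (members in by_pw) {
    m <- unique(members)
    if (length(m) >= 2) {
      pairs <- utils::combn(sort(m), 2)
      edges <- c(edges, paste(pairs[1, ], pairs[2, ], sep = "\r"))
    }
  }
  edges <- unique(edges)
  edge_mat <- if (length(edges)) {
    do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
  } else {
    matrix(character(0), ncol = 2)
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edge_mat, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  structure(list(graph = g, membership = by_pw), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d compounds, %d edges, %d pathways\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$membership)))
  invisible(x)
}

#' Read pathway membership rows and build the pathway graph
#'
#' @param path TSV with columns `pathway_id`, `compound_id`.
#' @param db optional metabolite database (see [pathway_graph()]).
#' @return A [pathway_graph()].
#' @export
read_pathway_membership <- function(path, db = NULL) {
  membership <- read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  pathway_graph(membership, db = db)
}

#' Write pathway membership rows
#' @param graph a [pathway_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_membership <- function(graph, path) {
  df <- data.frame(
    pathway_id = rep(names(graph$membership), lengths(graph$membership)),
    compound_id = unlist(graph$membership, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample labels
#' @param path TSV with columns `sample_id`, `label`.
#' @return named character vector, names = sample ids.
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.character(df$label), as.character(df$sample_id))
}
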