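# Dataset input/output: one CSV edge list per relation (header `src,dst`),
# a label file `patient_id,label`, and a JSON stats report.

relation_file <- c(`P-D` = "pd.csv", `D-P` = "dp.csv",
                   `P-O` = "po.csv", `O-P` = "op.csv")

read_edge_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing edge file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L || !identical(trimws(lines[1]), "src,dst")) {
    stop(sprintf("malformed CSV %s: line 1 (expected header 'src,dst')", path))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(data.frame(src = character(0), dst = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed CSV %s: line %d", path, bad[1] + 1L))
  }
  data.frame(src = vapply(parts, `[[`, "", 1L),
             dst = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
}

adj_to_edges <- function(A, src_ids, dst_ids) {
  T <- methods::as(A, "TsparseMatrix")
  o <- order(T@i, T@j)
  data.frame(src = src_ids[T@i[o] + 1L], dst = dst_ids[T@j[o] + 1L],
             stringsAsFactors = FALSE)
}

#' Write a heterogeneous graph dataset to a directory
#'
#' Emits one CSV per relation (`pd.csv`, `dp.csv`, `po.csv`, `op.csv`, header
#' `src,dst`), a `nodes.csv` listing every node (so isolated nodes round-trip),
#' and, when labels are given, `labels.csv` with header `patient_id,label`.
#'
#' @param graph a [het_graph()].
#' @param dir output directory (created if needed).
#' @param labels optional integer/character vector of per-patient disease
#'   labels, aligned with `graph$nodes$P`.
#' @return `dir`, invisibly.
#' @export
write_het_graph <- function(graph, dir, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src_ids <- list(`P-D` = graph$nodes$P, `D-P` = graph$nodes$D,
                  `P-O` = graph$nodes$P, `O-P` = graph$nodes$O)
  dst_ids <- list(`P-D` = graph$nodes$D, `D-P` = graph$nodes$P,
                  `P-O` = graph$nodes$O, `O-P` = graph$nodes$P)
  for (r in RELATIONS) {
    df <- adj_to_edges(graph$adj[[r]], src_ids[[r]], dst_ids[[r]])
    utils::write.csv(df, file.path(dir, relation_file[[r]]),
                     row.names = FALSE, quote = FALSE)
  }
  nodes <- data.frame(
    type = rep(c("P", "D", "O"),
               times = vapply(graph$nodes, length, 0L)),
    id = c(graph$nodes$P, graph$nodes$D, graph$nodes$O),
    stringsAsFactors = FALSE)
  utils::write.csv(nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(graph$nodes$P))
    utils::write.csv(data.frame(patient_id = graph$nodes$P, label = labels),
                     file.path(dir, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a heterogeneous graph dataset from a directory
#'
#' Reads the CSV layout written by [write_het_graph()]. Malformed rows raise an
#' error naming the file and line.
#'
#' @param dir directory containing the relation CSVs.
#' @return A list with `graph` (a [het_graph()]) and `labels` (integer or
#'   character vector aligned with `graph$nodes$P`, or `NULL` when absent).
#' @export
read_het_graph <- function(dir) {
  ed <- lapply(RELATIONS, function(r) read_edge_csv(file.path(dir, relation_file[[r]])))
  names(ed) <- RELATIONS
  patients <- drugs <- procedures <- NULL
  nodes_path <- file.path(dir, "nodes.csv")
  if (file.exists(nodes_path)) {
    nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                             colClasses = "character")
    patients <- nodes$id[nodes$type == "P"]
    drugs <- nodes$id[nodes$type == "D"]
    procedures <- nodes$id[nodes$type == "O"]
  }
  graph <- het_graph(pd_edges = ed[["P-D"]], po_edges = ed[["P-O"]],
                     dp_edges = ed[["D-P"]], op_edges = ed[["O-P"]],
                     patients = patients, drugs = drugs,
                     procedures = procedures)
  labels <- NULL
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "label") %in% names(lab))) {
      stop(sprintf("malformed CSV %s: line 1 (expected header 'patient_id,label')",
                   lab_path))
    }
    pos <- match(graph$nodes$P, as.character(lab$patient_id))
    if (anyNA(pos)) stop("labels.csv does not cover every patient")
    labels <- lab$label[pos]
  }
  list(graph = graph, labels = labels)
}

#' Write a graph statistics report as JSON
#'
#' @param stats a [graph_stats()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  out <- list(
    n_patients = unname(stats$node_counts[["P"]]),
    n_drugs = unname(stats$node_counts[["D"]]),
    n_procedures = unname(stats$node_counts[["O"]]),
    edges = as.list(stats$edge_counts),
    metapath_instances = as.list(stats$metapath_instances),
    sparsity = stats$sparsity)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
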