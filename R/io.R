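# File I/O: edge-list and GraphML graphs, CSV/JSON results.
#
# Edge-list format: one edge per line, two whitespace-separated 0-based
# integer node ids; `#` starts a comment. Node ids are made contiguous by
# taking N = max id + 1.

#' Read a population graph from a file
#'
#' @param path Path to the file.
#' @param format `"edgelist"` (two 0-based integer node ids per line,
#'   `#` comments allowed) or `"graphml"`.
#' @return A validated igraph object. Malformed lines, self-loops and
#'   duplicate edges are reported with their line numbers.
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(validate_graph(igraph::as_undirected(g, mode = "each")))
  }
  raw <- readLines(path)
  stripped <- trimws(sub("#.*$", "", raw))
  keep <- which(nzchar(stripped))
  if (length(keep) == 0) stop("no edges in ", path)
  toks <- strsplit(stripped[keep], "[[:space:]]+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0)
    stop(sprintf("malformed line %d in %s: expected two node ids",
                 keep[bad[1]], path))
  ids <- suppressWarnings(
    matrix(as.integer(unlist(toks)), ncol = 2, byrow = TRUE)
  )
  nonint <- suppressWarnings(
    which(rowSums(is.na(ids)) > 0 |
            ids[, 1] != as.numeric(sapply(toks, `[`, 1)) |
            ids[, 2] != as.numeric(sapply(toks, `[`, 2)))
  )
  if (length(nonint) > 0)
    stop(sprintf("malformed line %d in %s: node ids must be non-negative integers",
                 keep[nonint[1]], path))
  if (any(ids < 0))
    stop(sprintf("malformed line %d in %s: negative node id",
                 keep[which(rowSums(ids < 0) > 0)[1]], path))
  loops <- which(ids[, 1] == ids[, 2])
  if (length(loops) > 0)
    stop(sprintf("self-loop at line %d in %s", keep[loops[1]], path))
  canon <- paste(pmin(ids[, 1], ids[, 2]), pmax(ids[, 1], ids[, 2]))
  dup <- which(duplicated(canon))
  if (length(dup) > 0)
    stop(sprintf("duplicate edge at line %d in %s", keep[dup[1]], path))
  validate_graph(graph_from_edges(ids, max(ids) + 1L))
}

#' Write a population graph to a file
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param format `"edgelist"` (0-based ids, canonical i < j per line) or
#'   `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  validate_graph(graph)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- as_edge_matrix(graph)
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}

#' Write analysis results to disk
#'
#' Scalar summaries (fixation estimates, optimization summaries) are
#' written as JSON with the resolved configuration embedded; tabular
#' series (trajectories) as CSV.
#'
#' @param x A `fixation_estimate`, `trajectory_record` or `opt_result`.
#' @param path Output path (JSON for summaries, CSV for trajectories).
#' @param ... Extra fields (e.g. `seed`) stored alongside JSON summaries.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.fixation_estimate <- function(x, path, ...) {
  jsonlite::write_json(c(unclass(x), list(...)), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
write_results.trajectory_record <- function(x, path, ...) {
  write.csv(x$mean, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.opt_result <- function(x, path, ...) {
  done <- !is.na(x$times)
  summary <- list(
    objective = x$problem$objective, s = x$problem$s,
    mutation_sd = x$problem$mutation_sd, theta = x$problem$theta,
    n_rep = x$n_rep, n_censored = x$n_censored,
    mean_time_to_threshold = if (any(done)) mean(x$times[done]) else NA,
    times = x$times
  )
  jsonlite::write_json(c(summary, list(...)), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
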