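# T-graphs: directed graphs of significant pairwise outperformance
# relations, drawn after transitive reduction (a direct edge is omitted
# whenever its endpoints are already connected through an indirect path).

# nodes reachable from `from` (excluding `from` unless on a cycle)
.reachable <- function(adj, from) {
  seen <- character(0)
  stack <- adj[[from]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, adj[[v]])
  }
  seen
}

#' Build a T-graph from pairwise contrasts
#'
#' For every significant contrast an edge points from the outperforming
#' option (larger relative effect) to the outperformed one. The graph must
#' be acyclic (the rank-based contrasts are transitive; a significance
#' cycle indicates inconsistent input) and is returned after transitive
#' reduction, which preserves reachability exactly.
#'
#' @param contrasts An `iat_contrasts` table from
#'   [tukey_relative_contrasts()].
#' @return An object of class `tgraph`: list with `nodes`, `edges`
#'   (data.frame `from`, `to` after reduction) and `edges_full` (before
#'   reduction).
#' @export
build_tgraph <- function(contrasts) {
  stopifnot(inherits(contrasts, "iat_contrasts"))
  nodes <- names(attr(contrasts, "relative_effects"))
  sig <- contrasts[contrasts$significant, , drop = FALSE]
  from <- ifelse(sig$effect > 0, sig$group_i, sig$group_j)
  to <- ifelse(sig$effect > 0, sig$group_j, sig$group_i)
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))

  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
  }
  for (v in nodes) {
    if (v %in% .reachable(adj, v)) {
      stop("significance cycle involving '", v,
           "'; transitive contrasts cannot produce this", call. = FALSE)
    }
  }
  # edge u->v is redundant iff some other successor w of u reaches v
  keep <- rep(TRUE, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    u <- edges$from[i]; v <- edges$to[i]
    for (w in setdiff(adj[[u]], v)) {
      if (v %in% .reachable(adj, w)) { keep[i] <- FALSE; break }
    }
  }
  structure(list(nodes = nodes,
                 edges = edges[keep, , drop = FALSE],
                 edges_full = edges),
            class = "tgraph")
}

#' All reachable pairs of a T-graph
#'
#' @param graph A `tgraph`.
#' @param full Use the pre-reduction edge set?
#' @return Data.frame of (`from`, `to`) reachability pairs.
#' @export
tgraph_reachability <- function(graph, full = FALSE) {
  stopifnot(inherits(graph, "tgraph"))
  edges <- if (full) graph$edges_full else graph$edges
  adj <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
  }
  out <- do.call(rbind, lapply(graph$nodes, function(u) {
    r <- .reachable(adj, u)
    if (!length(r)) return(NULL)
    data.frame(from = u, to = sort(r), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(from = character(0), to = character(0))
  }
  out[order(out$from, out$to), , drop = FALSE]
}

#' Export a T-graph as DOT
#'
#' @param graph A `tgraph`.
#' @param path Optional file path; when `NULL` the DOT source is returned.
#' @return The DOT source string, invisibly when written to a file.
#' @export
tgraph_dot <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "tgraph"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph tgraph {",
             paste0("  ", q(graph$nodes), ";"),
             if (nrow(graph$edges)) {
               paste0("  ", q(graph$edges$from), " -> ", q(graph$edges$to), ";")
             },
             "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}

#' Export a T-graph as node-link JSON
#'
#' @param graph A `tgraph`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to a file.
#' @export
tgraph_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "tgraph"))
  obj <- list(nodes = lapply(graph$nodes, function(n) list(id = n)),
              links = lapply(seq_len(nrow(graph$edges)), function(i) {
                list(source = graph$edges$from[i],
                     target = graph$edges$to[i])
              }))
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.tgraph <- function(x, ...) {
  cat(sprintf("<tgraph> %d node(s), %d edge(s) after transitive reduction (%d before)\n",
              length(x$nodes), nrow(x$edges), nrow(x$edges_full)))
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}
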