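# Neighbourhood structure over areas for the ICAR prior.

#' Build an adjacency graph over areas
#'
#' Symmetrizes and deduplicates an undirected edge list, rejects
#' self-edges, and records per-area neighbour counts and connected
#' components. Isolated areas (no neighbours) are allowed: they are kept
#' in the model but excluded from the ICAR field (they receive only the
#' exchangeable random effect).
#'
#' @param edges Two-column matrix or data frame of area id pairs.
#' @param areas Optional character vector of all modelled area ids
#'   (defaults to the ids appearing in `edges`); ids present here but not
#'   in `edges` become isolated areas.
#' @return An object of class `adjacency_graph`: list with `ids`,
#'   `nbr` (list of neighbour indices per area), `n_i` (neighbour counts),
#'   `comp` (1-based component index among non-isolated areas, `NA` for
#'   isolated), `n_comp`, `edges` (2-column index matrix, i < j).
#' @export
adjacency_graph <- function(edges, areas = NULL) {
  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(e) < 2) stop("edges must have two columns")
  a <- as.character(e[[1]]); b <- as.character(e[[2]])
  if (any(a == b)) stop("self-edge not allowed: ", a[which(a == b)[1]])
  ids <- if (is.null(areas)) sort(unique(c(a, b))) else as.character(areas)
  missing_ids <- setdiff(c(a, b), ids)
  if (length(missing_ids) > 0)
    warning("edge id(s) not in area list, dropped: ",
            paste(unique(missing_ids), collapse = ", "))
  keep <- a %in% ids & b %in% ids
  a <- a[keep]; b <- b[keep]
  i <- match(a, ids); j <- match(b, ids)
  lo <- pmin(i, j); hi <- pmax(i, j)
  em <- unique(cbind(lo, hi))
  n <- length(ids)
  nbr <- vector("list", n)
  for (k in seq_len(n)) nbr[[k]] <- integer()
  if (nrow(em) > 0) {
    for (k in seq_len(nrow(em))) {
      nbr[[em[k, 1]]] <- c(nbr[[em[k, 1]]], em[k, 2])
      nbr[[em[k, 2]]] <- c(nbr[[em[k, 2]]], em[k, 1])
    }
  }
  nbr <- lapply(nbr, sort)
  n_i <- vapply(nbr, length, integer(1))
  comp <- rep(NA_integer_, n)
  if (nrow(em) > 0) {
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_len(n)]
    live <- n_i > 0
    comp[live] <- match(memb[live], sort(unique(memb[live])))
  }
  structure(list(ids = ids, nbr = nbr, n_i = n_i, comp = comp,
                 n_comp = length(unique(comp[!is.na(comp)])),
                 edges = em),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("adjacency_graph:", length(x$ids), "areas,", nrow(x$edges),
      "edges,", x$n_comp, "connected component(s),",
      sum(x$n_i == 0), "isolated\n")
  invisible(x)
}

#' Read an adjacency edge list
#'
#' Whitespace-delimited two-column file of undirected area id pairs;
#' duplicates (in either orientation) are collapsed.
#'
#' @param path File path.
#' @inheritParams adjacency_graph
#' @return An [adjacency_graph()].
#' @export
read_adjacency <- function(path, areas = NULL) {
  e <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("from", "to"))
  adjacency_graph(e, areas = areas)
}

#' Write an adjacency edge list
#'
#' @param graph An [adjacency_graph()].
#' @param path File path.
#' @export
write_adjacency <- function(graph, path) {
  em <- graph$edges
  utils::write.table(data.frame(from = graph$ids[em[, 1]],
                                to = graph$ids[em[, 2]]),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rook-contiguity adjacency for a rectangular grid
#'
#' Utility used by the synthetic geography: areas laid out row-major on an
#' `nrow x ncol` grid are neighbours when they share an edge.
#'
#' @param nrow,ncol Grid dimensions.
#' @param ids Area ids in row-major order (default `"A1"..`).
#' @return An [adjacency_graph()].
#' @export
grid_adjacency <- function(nrow, ncol, ids = NULL) {
  n <- nrow * ncol
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      k <- (r - 1) * ncol + c
      if (c < ncol) { from <- c(from, ids[k]); to <- c(to, ids[k + 1]) }
      if (r < nrow) { from <- c(from, ids[k]); to <- c(to, ids[k + ncol]) }
    }
  }
  adjacency_graph(data.frame(from, to), areas = ids)
}
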