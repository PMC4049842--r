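#' Build a genotype network from binary genotype strings
#'
#' Nodes are the distinct strings; an edge joins two nodes whose strings have
#' Hamming distance exactly one.  Construction is sub-quadratic in the number
#' of distinct genotypes: for each node, its \code{k} single-bit-flip
#' neighbours are generated and looked up in a membership index, so the cost
#' is O(V * k) lookups rather than all-pairs comparison.  The all-pairs
#' construction is available as \code{\link{buildNetworkAllPairs}} and serves
#' as an independent oracle in the test suite.
#'
#' @param genotypes non-empty character vector of equal-length strings over
#'   the alphabet \{"0", "1"\}; duplicates are counted per node.
#' @return A \linkS4class{GenotypeNetwork}.
#' @examples
#' net <- buildNetwork(c("000", "001", "011", "011"))
#' networkProperties(net)
#' @export
buildNetwork <- function(genotypes) {
  nodes <- checkGenotypes(genotypes)
  k <- nchar(nodes[1L])
  counts <- table(genotypes)
  nodeCounts <- stats::setNames(as.integer(counts), names(counts))
  nodeCounts <- nodeCounts[nodes]  # order by first appearance
  idx <- seq_along(nodes)
  from <- integer(0)
  to <- integer(0)
  for (j in seq_len(k)) {
    flipped <- nodes
    bit <- substr(nodes, j, j)
    substr(flipped, j, j) <- ifelse(bit == "0", "1", "0")
    m <- match(flipped, nodes)
    hit <- !is.na(m) & m > idx   # each unordered pair is seen from both ends
    from <- c(from, idx[hit])
    to <- c(to, m[hit])
  }
  newGenotypeNetwork(nodes, cbind(from, to), nodeCounts, k,
                     length(genotypes))
}

#' All-pairs construction of a genotype network
#'
#' Quadratic reference construction: computes the full Hamming distance matrix
#' between distinct genotypes and keeps pairs at distance one.  Used as an
#' independent oracle against \code{\link{buildNetwork}}.
#'
#' @inheritParams buildNetwork
#' @return A \linkS4class{GenotypeNetwork}.
#' @export
buildNetworkAllPairs <- function(genotypes) {
  nodes <- checkGenotypes(genotypes)
  k <- nchar(nodes[1L])
  counts <- table(genotypes)
  nodeCounts <- stats::setNames(as.integer(counts), names(counts))[nodes]
  M <- matrix(as.integer(unlist(strsplit(nodes, "", fixed = TRUE))),
              nrow = length(nodes), byrow = TRUE)
  D <- M %*% t(1L - M) + (1L - M) %*% t(M)
  e <- which(D == 1L & upper.tri(D), arr.ind = TRUE)
  newGenotypeNetwork(nodes, e, nodeCounts, k, length(genotypes))
}

checkGenotypes <- function(genotypes) {
  if (length(genotypes) == 0L)
    stop("empty genotype list")
  lens <- unique(nchar(genotypes))
  if (length(lens) != 1L)
    stop("genotype strings must all have the same length")
  if (any(grepl("[^01]", genotypes)))
    stop("genotype strings must contain only '0' and '1'")
  unique(genotypes)
}

newGenotypeNetwork <- function(nodes, edges, nodeCounts, k, nHaplotypes) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(edges[, 1L], edges[, 2L]))
  new("GenotypeNetwork", graph = g, nodeCounts = nodeCounts,
      k = as.integer(k), nHaplotypes = as.integer(nHaplotypes))
}

setMethod("show", "GenotypeNetwork", function(object) {
  cat("GenotypeNetwork over", object@k, "SNV sites:",
      igraph::vcount(object@graph), "vertices,",
      igraph::ecount(object@graph), "edges (",
      object@nHaplotypes, "haplotypes )\n")
})

#' Genotype network properties
#'
#' The four summary statistics of a genotype network, plus their composite:
#' \describe{
#'   \item{\code{nVertices}}{number of distinct genotypes (equivalently,
#'     Nei's number of distinct haplotypes in the window); measures how much
#'     of genotype space the sample occupies.}
#'   \item{\code{averagePathLength}}{mean shortest-path length over all
#'     connected unordered node pairs (pairs in different components are
#'     excluded from numerator and denominator); \code{NA} when no connected
#'     pair exists.  Measures extension/heterogeneity in genotype space.}
#'   \item{\code{nComponents}}{number of maximal connected subgraphs; isolated
#'     nodes count.  High values indicate a fragmented network.}
#'   \item{\code{averageDegree}}{mean neighbour count over all nodes,
#'     isolated nodes contributing zero (equals 2E/V); measures the stability
#'     of the network to single point mutations.}
#'   \item{\code{verticesPerComponent}}{\code{nVertices / nComponents}, the
#'     composite used to flag networks with few components but many vertices.}
#' }
#' \code{networkProperties} bundles all five into a one-row data frame and
#' also accepts a character vector of genotype strings directly.
#'
#' @param net a \linkS4class{GenotypeNetwork} (or, for
#'   \code{networkProperties}, a character vector of genotype strings).
#' @return Scalars; \code{networkProperties} returns a one-row data frame with
#'   columns \code{n_vertices}, \code{avg_path_length}, \code{n_components},
#'   \code{avg_degree}, \code{vertices_per_component}.
#' @name networkProperties
NULL

#' @rdname networkProperties
#' @export
setMethod("nVertices", "GenotypeNetwork",
          function(net) igraph::vcount(net@graph))

#' @rdname networkProperties
#' @export
setMethod("averagePathLength", "GenotypeNetwork", function(net) {
  if (igraph::ecount(net@graph) == 0L) return(NA_real_)
  igraph::mean_distance(net@graph, directed = FALSE, unconnected = TRUE)
})

#' @rdname networkProperties
#' @export
setMethod("nComponents", "GenotypeNetwork",
          function(net) igraph::components(net@graph)$no)

#' @rdname networkProperties
#' @export
setMethod("averageDegree", "GenotypeNetwork",
          function(net) mean(igraph::degree(net@graph)))

#' @rdname networkProperties
#' @export
setMethod("verticesPerComponent", "GenotypeNetwork",
          function(net) nVertices(net) / nComponents(net))

#' @rdname networkProperties
#' @export
setMethod("networkProperties", "GenotypeNetwork", function(net) {
  data.frame(n_vertices = nVertices(net),
             avg_path_length = averagePathLength(net),
             n_components = nComponents(net),
             avg_degree = averageDegree(net),
             vertices_per_component = verticesPerComponent(net))
})

#' @rdname networkProperties
#' @export
setMethod("networkProperties", "character",
          function(net) networkProperties(buildNetwork(net)))

#' Single-bit-flip neighbourhood of a genotype
#'
#' All genotypes reachable from \code{genotype} by one point mutation: exactly
#' \code{k} candidate neighbours for a string of length \code{k}.
#'
#' @param genotype a single binary string.
#' @return Character vector of the \code{k} single-mutation neighbours, in
#'   site order.
#' @examples
#' mutationNeighbours("01100")
#' @export
mutationNeighbours <- function(genotype) {
  stopifnot(length(genotype) == 1L, !grepl("[^01]", genotype))
  k <- nchar(genotype)
  vapply(seq_len(k), function(j) {
    flipped <- genotype
    substr(flipped, j, j) <- if (substr(genotype, j, j) == "0") "1" else "0"
    flipped
  }, character(1))
}

#' Export a genotype network for external tools
#'
#' \code{exportEdgeList} writes a two-column tab-separated edge list (plus an
#' isolated-node list as comment lines); \code{exportGraphML} writes GraphML
#' via \pkg{igraph}, suitable for Cytoscape and friends.
#'
#' @param net a \linkS4class{GenotypeNetwork}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportEdgeList <- function(net, path) {
  el <- igraph::as_edgelist(net@graph, names = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  iso <- names(which(igraph::degree(net@graph) == 0))
  for (v in iso) writeLines(paste0("# isolated\t", v), con)
  utils::write.table(el, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname exportEdgeList
#' @export
exportGraphML <- function(net, path) {
  igraph::write_graph(net@graph, path, format = "graphml")
  invisible(path)
}
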