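# shared helpers: tiny constructors and independent oracles

# all 2^k genotype strings of length k (the full hypercube)
allStrings <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("0", "1")), k),
                              stringsAsFactors = FALSE))
}

randomGenotypes <- function(n, k) {
  apply(matrix(sample(0:1, n * k, replace = TRUE), n), 1L,
        paste, collapse = "")
}

# independent O(V^2 k) Hamming-distance oracle on strings
hammingPairsOracle <- function(strings) {
  nodes <- unique(strings)
  v <- length(nodes)
  if (v < 2L) return(matrix(character(0), ncol = 2L))
  chars <- strsplit(nodes, "")
  out <- list()
  for (i in seq_len(v - 1L)) for (j in seq(i + 1L, v)) {
    if (sum(chars[[i]] != chars[[j]]) == 1L)
      out[[length(out) + 1L]] <- c(nodes[i], nodes[j])
  }
  if (length(out) == 0L) return(matrix(character(0), ncol = 2L))
  do.call(rbind, out)
}

# canonical sorted edge-key representation for set comparison
edgeKeys <- function(net) {
  el <- igraph::as_edgelist(net@graph, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])))
}

# BFS all-pairs average shortest path length over connected pairs (oracle)
aplOracle <- function(strings) {
  pairs <- hammingPairsOracle(strings)
  nodes <- unique(strings)
  v <- length(nodes)
  adj <- lapply(seq_len(v), function(i) integer(0))
  if (nrow(pairs) > 0L) for (e in seq_len(nrow(pairs))) {
    i <- match(pairs[e, 1L], nodes)
    j <- match(pairs[e, 2L], nodes)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  tot <- 0; cnt <- 0
  for (s in seq_len(v)) {
    dist <- rep(NA_integer_, v)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[u]]) if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- which(!is.na(dist) & seq_len(v) > s)
    tot <- tot + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  if (cnt == 0L) NA_real_ else tot / cnt
}

# tiny HaplotypeMatrix from genotype strings
hmFromStrings <- function(strings, populations = "ALL",
                          positions = NULL, chromosome = "chr1") {
  k <- nchar(strings[1L])
  a <- matrix(as.integer(unlist(strsplit(strings, ""))), byrow = TRUE,
              nrow = length(strings))
  if (is.null(positions)) positions <- seq_len(k) * 100L
  HaplotypeMatrix(a, positions = positions, chromosome = chromosome,
                  populations = populations)
}

# small deterministic simulation configs used across test files
smallNeutralConfig <- function(seed = 1L, nHap = 60L)
  simulationConfig(nHaplotypesPerPop = nHap, neAncestral = 400,
                   neAfrican = 400, neOoaBottleneck = 80, neEuropean = 250,
                   neAsian = 250, ooaSplitGenerations = 240,
                   eurasianSplitGenerations = 120, burnInFactor = 8,
                   regionLengthBp = 6e4, scale = 1, seed = seed)

panmicticConfig <- function(seed = 1L, nHap = 100L, ne = 300,
                            regionLength = 5e4)
  simulationConfig(nHaplotypesPerPop = nHap, neAncestral = ne,
                   ooaSplitGenerations = 0, eurasianSplitGenerations = 0,
                   regionLengthBp = regionLength, scale = 1, seed = seed)
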