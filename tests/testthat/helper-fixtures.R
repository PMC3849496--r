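# Shared toy fixtures, all built in code.

# 5-term diamond: root -> A, B; A, B -> C; C -> L
diamondDAG <- function() {
  ontologyDAG(data.frame(
    child  = c("A", "B", "C", "C", "L"),
    parent = c("root", "root", "A", "B", "C")))
}

# 8-gene corpus on the diamond; counts: root 8, A 4, B 3, C 2, L 1
diamondAnnotations <- function(dag = diamondDAG()) {
  upPropagate(annotationSet(list(
    g1 = "L",            # L, C, A, B, root
    g2 = "C",            # C, A, B, root
    g3 = "A", g4 = "A",  # A, root
    g5 = "B",            # B, root
    g6 = "root", g7 = "root", g8 = "root")), dag)
}

# brute-force transitive ancestor closure by repeated parent expansion
bruteAncestors <- function(dag, term) {
  out <- term
  repeat {
    more <- unique(c(out, unlist(dag@parents[out], use.names = FALSE)))
    if (length(more) == length(out)) return(sort(out))
    out <- more
  }
}

# dense symmetric adjacency for a random toy network (no self-loops)
randomAdjacency <- function(n, density = 0.4) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  A[ut] <- vals
  A <- A + t(A)
  dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  A
}

randomNetwork <- function(n, density = 0.4) {
  weightedNetwork(randomAdjacency(n, density))
}

# small trained-shape fixture: feature map and random W over d coords
randomPhi <- function(n, d, sparsity = 0.6) {
  phi <- matrix(stats::runif(n * d), n, d)
  phi[matrix(stats::runif(n * d) < sparsity, n, d)] <- 0
  rownames(phi) <- paste0("g", seq_len(n))
  colnames(phi) <- paste0("g", seq_len(d))
  phi
}
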