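# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and where possible the library
# calls) used by the package itself.

# Benjamini-Hochberg step-up by direct enumeration over ranks:
# adj_i = min over j with p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson r from first principles.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Upper-tail hypergeometric P by exhaustive enumeration of all C(N, n)
# draws from a labelled universe in which genes 1..K form the set.
hyper_enum_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# k-core peeling on an adjacency matrix: repeatedly delete vertices of
# degree < k; the highest k-core is the largest k with a non-empty result.
peel_kcore <- function(adj, k) {
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE])[alive]
    drop <- deg < k
    if (!any(drop) || !any(alive)) break
    alive[alive][drop] <- FALSE
    if (!any(alive)) break
  }
  which(alive)
}

# MCODE vertex weight oracle: highest k-core of the closed neighbourhood,
# weight = k * density, via exhaustive peeling over increasing k.
mcode_weight_oracle <- function(adj) {
  n <- nrow(adj)
  w <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) == 0) next
    vs <- c(v, nb)
    sub <- adj[vs, vs, drop = FALSE]
    kmax <- 0; core <- seq_along(vs)
    for (k in seq_len(length(vs))) {
      kept <- peel_kcore(sub, k)
      if (length(kept) == 0) break
      kmax <- k; core <- kept
    }
    m <- length(core)
    dens <- if (m < 2) 0 else sum(sub[core, core]) / (m * (m - 1))
    w[v] <- kmax * dens
  }
  w
}

# Random undirected graph as an adjacency matrix (labelled, p-edge model).
random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

adj_to_igraph <- function(adj) {
  rownames(adj) <- colnames(adj) <- sprintf("v%02d", seq_len(nrow(adj)))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Tiny hand-rolled expression profile for io tests.
toy_profile <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   5, 6, 7, 8,
                   2, 2, 9, 9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("LNCA", "GENEA", "GENEB"),
                                 c("s1", "s2", "s3", "s4")))
  expression_profile(
    vals,
    c(LNCA = "lncRNA", GENEA = "mRNA", GENEB = "mRNA"),
    c(s1 = "case", s2 = "case", s3 = "control", s4 = "control"))
}

# Minimal ceRNA motif: L1 - m1 - {G1, G2}.
minimal_motif <- function() {
  dels <- data.frame(feature_id = "L1", feature_class = "lncRNA", trend = "up")
  demis <- data.frame(feature_id = "m1", feature_class = "miRNA", trend = "down")
  dems <- data.frame(feature_id = c("G1", "G2"), feature_class = "mRNA",
                     trend = "up")
  inter <- data.frame(mirna = "m1", target = c("L1", "G1", "G2"),
                      target_class = c("lncRNA", "mRNA", "mRNA"),
                      source = "x")
  assemble_cerna(dels, demis, dems, inter)
}
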