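# Independent oracles used across test files.

# Brute-force marginals of a factor graph by exhaustive summation over all
# 2^p joint states. Independent of the message-passing implementation.
enumerate_marginals <- function(graph) {
  p <- length(graph$genes)
  marg <- matrix(0, p, 2L, dimnames = list(graph$genes, c("0", "1")))
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  joint <- apply(states, 1L, function(s) {
    prod(vapply(graph$factors, function(f) {
      idx <- 1L + sum(s[f$vars] * 2L^(seq_along(f$vars) - 1L))
      f$table[idx]
    }, 0))
  })
  joint <- joint / sum(joint)
  for (v in seq_len(p)) {
    marg[v, 1L] <- sum(joint[states[, v] == 0L])
    marg[v, 2L] <- sum(joint[states[, v] == 1L])
  }
  marg
}

# Mutual information computed by direct summation over an explicit joint
# count table (rows = states of x, cols = states of y).
mi_from_counts <- function(counts) {
  pj <- counts / sum(counts)
  px <- rowSums(pj)
  py <- colSums(pj)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (pj[i, j] > 0) s <- s + pj[i, j] * log(pj[i, j] / (px[i] * py[j]))
  }
  s
}

# Conditional entropy H(t | conditioning set) by direct enumeration over the
# observed configurations, used as the oracle for greedy parent selection.
cond_entropy_oracle <- function(t_lab, cond) {
  key <- apply(as.matrix(cond), 1L, paste, collapse = "|")
  s <- 0
  n <- length(t_lab)
  for (k in unique(key)) {
    sel <- key == k
    pk <- mean(sel)
    tt <- table(t_lab[sel]) / sum(sel)
    s <- s + pk * (-sum(tt * log(tt)))
  }
  s
}

# A small expression matrix with a linear regulatory chain G1 -> G2 -> G3.
make_chain_expr <- function(n = 200, noise = 0.2, seed = 11) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, 0, noise)
  x3 <- x2 + rnorm(n, 0, noise)
  expression_matrix(rbind(G1 = x1, G2 = x2, G3 = x3))
}

# A hand-built acyclic CPT network over given genes from an edge list
# (data frame source/target/weight); returns a gene_network.
edges_to_network <- function(genes, edges) {
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (nrow(edges)) W[cbind(edges$source, edges$target)] <- edges$weight
  gene_network(W)
}
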