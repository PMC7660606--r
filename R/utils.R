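# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standardise columns to zero mean, unit variance (denominator n-1).
# Constant columns map to all-zero columns so they drop out of PLS scores.
standardize_cols <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  s[s < .Machine$double.eps] <- Inf
  sweep(Xc, 2L, s, "/")
}

# Kahn topological sort on a logical adjacency matrix (edge i -> j at [i, j]).
# Returns the order of node indices, or NULL if the graph has a cycle.
topological_order <- function(A) {
  p <- nrow(A)
  indeg <- colSums(A)
  ord <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA_real_
  while (length(avail)) {
    u <- avail[1L]
    avail <- avail[-1L]
    ord <- c(ord, u)
    for (v in which(A[u, ])) {
      indeg[v] <- indeg[v] - 1
      if (!is.na(indeg[v]) && indeg[v] == 0) {
        avail <- c(avail, v)
        indeg[v] <- NA_real_
      }
    }
  }
  if (length(ord) < p) NULL else ord
}

# Find one directed cycle by DFS; returns node indices v1 -> ... -> vk -> v1
# (without repeating v1), or NULL if the graph is acyclic.
find_directed_cycle <- function(A) {
  p <- nrow(A)
  color <- integer(p)
  res <- NULL
  dfs <- function(u, path) {
    color[u] <<- 1L
    for (v in which(A[u, ])) {
      if (!is.null(res)) return(invisible())
      if (color[v] == 0L) {
        dfs(v, c(path, v))
      } else if (color[v] == 1L) {
        i <- match(v, path)
        res <<- path[i:length(path)]
      }
    }
    color[u] <<- 2L
  }
  for (s in seq_len(p)) {
    if (!is.null(res)) break
    if (color[s] == 0L) dfs(s, s)
  }
  res
}
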