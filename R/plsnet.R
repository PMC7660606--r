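#' Parameters for the PLS ensemble network scorer
#'
#' @param m Number of PLS components (default 4).
#' @param k Number of candidate regulators sampled per ensemble iteration;
#'   `NULL` (default) means `round(sqrt(p))`, resolved when the expression
#'   matrix is seen.
#' @param T Number of ensemble iterations per target gene (default 1000).
#' @param seed Integer seed making the sampling reproducible.
#' @return A list of class `plsnet_params`.
#' @export
plsnet_params <- function(m = 4L, k = NULL, T = 1000L, seed = 1L) {
  if (m < 1L) stop("m must be >= 1")
  if (T < 1L) stop("T must be >= 1")
  structure(list(m = as.integer(m),
                 k = if (is.null(k)) NULL else as.integer(k),
                 T = as.integer(T), seed = as.integer(seed)),
            class = "plsnet_params")
}

#' PLS importance scores of predictors for one response
#'
#' Fits `m` partial-least-squares components by NIPALS on standardised
#' inputs and scores predictor `j` as the sum over components of the
#' response variance explained by the component times the squared normalised
#' loading weight of `j` in that component. Scores are non-negative and a
#' zero-variance (all-zero) predictor scores exactly 0.
#'
#' @param X Standardised predictor matrix, n observations x q predictors.
#' @param y Standardised response vector of length n.
#' @param m Number of PLS components, at most `min(n - 1, q)`.
#' @return Numeric vector of q non-negative importance scores.
#' @export
pls_importance <- function(X, y, m) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  q <- ncol(X)
  if (n < 3L) stop("at least 3 observations are required")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (m < 1L || m > min(n - 1L, q))
    stop("m must lie in [1, min(n - 1, q)]")
  scores <- numeric(q)
  eps <- 1e-12
  for (h in seq_len(m)) {
    w <- as.numeric(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < eps) break
    w <- w / nw
    t_h <- as.numeric(X %*% w)
    tt <- sum(t_h^2)
    if (tt < eps) break
    q_h <- sum(t_h * y) / tt
    scores <- scores + (q_h^2 * tt) * w^2
    p_h <- as.numeric(crossprod(X, t_h)) / tt
    X <- X - tcrossprod(t_h, p_h)
    y <- y - q_h * t_h
  }
  scores
}

#' Infer a regulator-target network by ensemble PLS scoring
#'
#' Decomposes the p-gene inference problem into p per-target subproblems.
#' For each target gene, `T` times, `k` candidate regulators are sampled
#' uniformly without replacement from the other p - 1 genes and scored by
#' [pls_importance()]; the weight of edge j -> i is the accumulated score of
#' candidate j for target i averaged over the `T` iterations. Deterministic
#' given `params$seed`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param params A [plsnet_params()] object.
#' @return A [gene_network()] with weights `(regulator, target)`.
#' @export
infer_network <- function(expr, params = plsnet_params()) {
  expr <- validate_expression(expr)
  p <- nrow(expr)
  n <- ncol(expr)
  if (p < 3L) stop("at least 3 genes are required")
  k <- params$k %||% max(1L, as.integer(round(sqrt(p))))
  m <- params$m
  if (!(m >= 1L && m <= k && k <= p - 1L))
    stop("require 1 <= m <= k <= p - 1 (m = ", m, ", k = ", k, ", p = ", p, ")")
  if (m > n - 1L) stop("m exceeds n - 1")
  Xs <- standardize_cols(t(expr))
  const <- colSums(Xs != 0) == 0L
  if (any(const))
    warning("constant gene(s) scored 0: ",
            paste(rownames(expr)[const], collapse = ", "))
  set.seed(params$seed)
  W <- plsnet_ensemble_cpp(Xs, m, k, params$T)
  dimnames(W) <- list(rownames(expr), rownames(expr))
  diag(W) <- 0
  gene_network(W)
}

#' Rescale edge weights by regulator hub strength
#'
#' Multiplies row i (the outgoing edges of gene i) by a hub factor equal to
#' the root-mean-square of the row's off-diagonal weights, rescaled so the
#' factors average 1 across genes. Genes that regulate many targets strongly
#' are promoted globally while within-row rankings are untouched. An all-zero
#' network is returned unchanged.
#'
#' @param network A `gene_network`.
#' @return A `gene_network` with hub-adjusted weights.
#' @export
hub_refine <- function(network) {
  W <- network$weights
  off <- W
  diag(off) <- NA_real_
  h <- sqrt(rowMeans(off^2, na.rm = TRUE))
  if (all(h == 0)) return(network)
  h <- h / mean(h)
  gene_network(W * h, directed = network$directed)
}

#' Keep the strongest fraction of possible directed edges
#'
#' Retains the top `ceiling(f * p * (p - 1))` off-diagonal entries by
#' weight, out of all possible directed edges, zeroing the rest. Ties at the
#' boundary are broken by (source, target) lexicographic order so the
#' selection is deterministic, which also makes retained edge sets nested
#' across increasing fractions.
#'
#' @param network A `gene_network`.
#' @param f Fraction of possible edges to keep, in (0, 1].
#' @return The thresholded `gene_network`.
#' @export
threshold_network <- function(network, f) {
  if (!(f > 0 && f <= 1)) stop("f must lie in (0, 1]")
  W <- network$weights
  p <- nrow(W)
  g <- rownames(W)
  K <- ceiling(f * p * (p - 1L))
  idx <- which(row(W) != col(W))
  ord <- order(-W[idx], g[row(W)[idx]], g[col(W)[idx]], method = "radix")
  keep <- idx[ord[seq_len(min(K, length(idx)))]]
  W2 <- matrix(0, p, p, dimnames = dimnames(W))
  W2[keep] <- W[keep]
  gene_network(W2, directed = network$directed)
}

#' Classify gene roles by in- and out-degree
#'
#' In a thresholded network a regulator (`R`) has in-degree 0 and positive
#' out-degree, a target (`T`) has out-degree 0 and positive in-degree, an
#' intermediate (`I`) has both, and a gene touching no edge is `isolated`.
#'
#' @param network A sparse (thresholded) `gene_network`.
#' @return Named character vector of roles, one per gene.
#' @export
classify_roles <- function(network) {
  W <- network$weights
  indeg <- colSums(W > 0)
  outdeg <- rowSums(W > 0)
  role <- rep("isolated", nrow(W))
  role[indeg == 0 & outdeg > 0] <- "R"
  role[outdeg == 0 & indeg > 0] <- "T"
  role[indeg > 0 & outdeg > 0] <- "I"
  names(role) <- rownames(W)
  role
}

#' Gene-role frequencies over repeated seeded runs
#'
#' Runs the full score-refine-threshold-classify chain `n_runs` times (run r
#' is seeded `params$seed + r`) and counts, per gene and threshold fraction,
#' how often the gene was classified regulator, target or intermediate.
#' Isolated genes are counted in none, so R + T + I <= n_runs.
#'
#' @param expr Expression matrix.
#' @param params [plsnet_params()]; `seed` is the base seed.
#' @param n_runs Number of repeated runs (default 100).
#' @param fractions Threshold fractions to sweep (default 2/5/10/15/20%).
#' @return A long-format data frame of class `role_freq_table` with columns
#'   `gene`, `fraction`, `R`, `T`, `I` and attribute `n_runs`.
#' @export
role_frequencies <- function(expr, params = plsnet_params(), n_runs = 100L,
                             fractions = c(0.02, 0.05, 0.10, 0.15, 0.20)) {
  expr <- validate_expression(expr)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  p <- nrow(expr)
  genes <- rownames(expr)
  counts <- array(0L, dim = c(p, length(fractions), 3L),
                  dimnames = list(genes, NULL, c("R", "T", "I")))
  for (r in seq_len(n_runs)) {
    pr <- params
    pr$seed <- params$seed + r
    net <- hub_refine(infer_network(expr, pr))
    for (fi in seq_along(fractions)) {
      role <- classify_roles(threshold_network(net, fractions[fi]))
      for (lab in c("R", "T", "I"))
        counts[, fi, lab] <- counts[, fi, lab] + (role == lab)
    }
  }
  out <- do.call(rbind, lapply(seq_along(fractions), function(fi) {
    data.frame(gene = genes, fraction = fractions[fi],
               R = counts[, fi, "R"], T = counts[, fi, "T"],
               I = counts[, fi, "I"], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, n_runs = as.integer(n_runs), class = c("role_freq_table",
                                                        "data.frame"))
}

#' Call candidate regulators from a role-frequency table
#'
#' @param table A `role_freq_table` from [role_frequencies()].
#' @param fraction Threshold fraction at which to read the counts; must be
#'   present in the table.
#' @param min_freq Minimum proportion of runs in which a gene must appear as
#'   a regulator (default 0.5).
#' @return Character vector of regulator gene identifiers (possibly empty).
#' @export
identify_regulators <- function(table, fraction, min_freq = 0.5) {
  if (!inherits(table, "role_freq_table"))
    stop("table must come from role_frequencies()")
  sub <- table[abs(table$fraction - fraction) < 1e-9, , drop = FALSE]
  if (!nrow(sub)) stop("fraction ", fraction, " is not present in the table")
  n_runs <- attr(table, "n_runs")
  sub$gene[sub$R / n_runs >= min_freq]
}
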