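std <- function(v) (v - mean(v)) / sd(v)

test_that("pls_importance ranks the true predictor first", {
  set.seed(42)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6)
  y <- std(X[, 1])
  Xs <- apply(X, 2, std)
  sc <- pls_importance(Xs, y, m = 2)
  # oracle: per-predictor single-variable least-squares R-squared
  r2 <- as.numeric(cor(Xs, y))^2
  expect_identical(which.max(sc), which.max(r2))
  expect_identical(which.max(sc), 1L)
  expect_true(all(sc >= 0))
})

test_that("an all-zero predictor column scores exactly 0", {
  set.seed(5)
  X <- cbind(std(rnorm(50)), 0, std(rnorm(50)))
  y <- std(rnorm(50))
  expect_identical(pls_importance(X, y, m = 2)[2], 0)
})

test_that("with one component the score ranking equals squared correlation", {
  set.seed(9)
  n <- 80
  Xs <- apply(matrix(rnorm(n * 5), n, 5), 2, std)
  y <- std(Xs %*% runif(5) + rnorm(n))
  sc <- pls_importance(Xs, y, m = 1)
  r2 <- as.numeric(cor(Xs, y))^2
  expect_identical(order(sc), order(r2))
})

test_that("pls_importance validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(pls_importance(X, rnorm(10), m = 3), "m must lie")
  expect_error(pls_importance(X[1:2, ], rnorm(2), m = 1), "3 observations")
  expect_error(pls_importance(X, rnorm(9), m = 1), "length")
})

test_that("pls importance agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(31)
  n <- 60
  Xs <- apply(matrix(rnorm(n * 4), n, 4), 2, std)
  y <- std(Xs %*% c(1, 0.5, 0, 0) + rnorm(n, 0, 0.5))
  fit <- mixOmics::pls(Xs, y, ncomp = 2, mode = "regression", scale = FALSE)
  w <- fit$loadings$X  # normalised weight vectors per component
  tt <- fit$variates$X
  q <- vapply(1:2, function(h) sum(tt[, h] * fit$Y) / sum(tt[, h]^2), 0)
  oracle <- as.numeric((q^2 * colSums(tt^2)) %*% t(w^2))
  mine <- pls_importance(Xs, y, m = 2)
  expect_equal(order(mine), order(oracle))
  expect_gt(cor(mine, oracle), 0.99)
})

test_that("the ensemble scorer matches the reference implementation when saturated", {
  set.seed(17)
  spec <- synthetic_spec(p = 6, n = 60, r = 1, out_degree = 3, seed = 2)
  expr <- simulate_expression(generate_dag(spec), spec)
  # with k = p - 1 and T = 1, every candidate is drawn, so column i of the
  # weight matrix must equal pls_importance of gene i on all others
  net <- infer_network(expr, plsnet_params(m = 2, k = 5, T = 1, seed = 4))
  Xs <- apply(t(expr), 2, std)
  for (i in seq_len(6)) {
    sc <- pls_importance(Xs[, -i, drop = FALSE], Xs[, i], m = 2)
    expect_equal(unname(net$weights[-i, i]), sc, tolerance = 1e-10)
  }
})

test_that("chain data concentrate weight on the true undirected links", {
  expr <- make_chain_expr()
  net <- infer_network(expr, plsnet_params(m = 2, k = 2, T = 300, seed = 5))
  W <- net$weights
  pair <- function(a, b) max(W[a, b], W[b, a])
  # the spurious G1-G3 link is strictly weaker than both true links
  expect_gt(pair("G1", "G2"), max(W["G1", "G3"], W["G3", "G1"]))
  expect_gt(pair("G2", "G3"), max(W["G1", "G3"], W["G3", "G1"]))
})

test_that("inference is deterministic given the seed", {
  spec <- synthetic_spec(p = 8, n = 40, r = 2, out_degree = 2, seed = 6)
  expr <- simulate_expression(generate_dag(spec), spec)
  a <- infer_network(expr, plsnet_params(m = 2, T = 50, seed = 99))
  b <- infer_network(expr, plsnet_params(m = 2, T = 50, seed = 99))
  expect_identical(a$weights, b$weights)
  c <- infer_network(expr, plsnet_params(m = 2, T = 50, seed = 100))
  expect_false(identical(a$weights, c$weights))
})

test_that("a constant gene yields a zero row and column plus a warning", {
  spec <- synthetic_spec(p = 6, n = 50, r = 1, out_degree = 2, seed = 8)
  expr <- simulate_expression(generate_dag(spec), spec)
  expr[3, ] <- 7
  expect_warning(net <- infer_network(expr, plsnet_params(m = 2, k = 3, T = 20, seed = 1)),
                 "constant")
  expect_true(all(net$weights[3, ] == 0))
  expect_true(all(net$weights[, 3] == 0))
})

test_that("hub refinement preserves within-row ranking and fixed points", {
  g <- paste0("G", 1:4)
  U <- matrix(1, 4, 4, dimnames = list(g, g))
  diag(U) <- 0
  expect_equal(hub_refine(gene_network(U))$weights, U)

  zero <- gene_network(matrix(0, 4, 4, dimnames = list(g, g)))
  expect_identical(hub_refine(zero)$weights, zero$weights)

  set.seed(3)
  W <- matrix(runif(16), 4, 4, dimnames = list(g, g))
  diag(W) <- 0
  out <- hub_refine(gene_network(W))$weights
  for (i in 1:4) expect_identical(order(out[i, ]), order(W[i, ]))
})

test_that("hub refinement promotes a planted hub in the global ranking", {
  set.seed(12)
  g <- paste0("G", 1:8)
  W <- matrix(runif(64, 0, 0.2), 8, 8, dimnames = list(g, g))
  diag(W) <- 0
  W[1, 2:6] <- 0.8            # gene 1 is a hub with 5 strong outgoing edges
  W[7, 8] <- 0.85             # slightly stronger edge from a non-hub
  rank_of <- function(M, i, j) {
    idx <- which(row(M) != col(M))
    match(paste(i, j), paste(row(M)[idx], col(M)[idx])[order(-M[idx])])
  }
  # before refinement the lone non-hub edge outranks every hub edge
  expect_lt(rank_of(W, 7, 8), rank_of(W, 1, 2))
  after_W <- hub_refine(gene_network(W))$weights
  # afterwards all five hub out-edges rise above it
  for (j in 2:6)
    expect_lt(rank_of(after_W, 1, j), rank_of(after_W, 7, 8))
})

test_that("thresholding keeps the exact top fraction with nested edge sets", {
  set.seed(21)
  g <- paste0("G", 1:20)
  W <- matrix(runif(400), 20, 20, dimnames = list(g, g))
  diag(W) <- 0
  net <- gene_network(W)

  expect_equal(threshold_network(net, 1)$weights, W)
  expect_identical(sum(threshold_network(net, 0.10)$weights > 0), 38L)

  fr <- c(0.02, 0.05, 0.10, 0.15, 0.20)
  kept <- lapply(fr, function(f) which(threshold_network(net, f)$weights > 0))
  for (i in seq_len(length(fr) - 1))
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  expect_error(threshold_network(net, 0), "\\(0, 1\\]")
})

test_that("role classification follows the degree definitions", {
  g <- c("A", "B", "C", "D")
  edges <- data.frame(source = c("A", "A", "B"),
                      target = c("B", "C", "C"),
                      weight = 1, stringsAsFactors = FALSE)
  roles <- classify_roles(edges_to_network(g, edges))
  expect_identical(unname(roles["A"]), "R")   # out only
  expect_identical(unname(roles["B"]), "I")   # in and out
  expect_identical(unname(roles["C"]), "T")   # in only
  expect_identical(unname(roles["D"]), "isolated")
})

test_that("role frequencies are conserved and deterministic", {
  spec <- synthetic_spec(p = 8, n = 40, r = 2, out_degree = 3, seed = 14)
  expr <- simulate_expression(generate_dag(spec), spec)
  par <- plsnet_params(m = 2, T = 50, seed = 2)
  tab <- role_frequencies(expr, par, n_runs = 5, fractions = c(0.1, 0.3))
  expect_true(all(tab$R + tab$T + tab$I <= 5))
  expect_true(all(tab$R >= 0 & tab$T >= 0 & tab$I >= 0))
  tab2 <- role_frequencies(expr, par, n_runs = 5, fractions = c(0.1, 0.3))
  expect_identical(tab, tab2)
  # single run assigns each gene to at most one role
  one <- role_frequencies(expr, par, n_runs = 1, fractions = 0.1)
  expect_true(all(one$R + one$T + one$I <= 1))
})

test_that("regulator calling honours the frequency cutoff", {
  tab <- data.frame(gene = c("A", "B", "C"), fraction = 0.05,
                    R = c(100L, 49L, 50L), T = 0L, I = 0L,
                    stringsAsFactors = FALSE)
  attr(tab, "n_runs") <- 100L
  class(tab) <- c("role_freq_table", "data.frame")
  expect_identical(identify_regulators(tab, 0.05), c("A", "C"))
  expect_identical(identify_regulators(tab, 0.05, min_freq = 0.51), "A")
  expect_error(identify_regulators(tab, 0.10), "not present")

  none <- tab
  none$R <- 0L
  expect_length(identify_regulators(none, 0.05), 0)
})
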