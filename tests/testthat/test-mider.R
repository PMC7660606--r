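test_that("equal-frequency binning splits samples with ties going low", {
  x <- expression_matrix(rbind(A = c(3, 1, 4, 6, 5, 2),
                               B = c(1, 1, 1, 2, 3, 4)))
  d <- discretize_equal_frequency(x, b = 2)
  expect_identical(as.integer(table(d$labels["A", ])), c(3L, 3L))
  # oracle: explicit quantile threshold; the three tied minima share bin 0
  expect_identical(unname(d$labels["B", ]), c(0L, 0L, 0L, 1L, 1L, 1L))

  cst <- expression_matrix(rbind(A = rep(2, 6), B = 1:6))
  dc <- discretize_equal_frequency(cst, b = 3)
  expect_true(all(dc$labels["A", ] == 0L))
  expect_identical(entropy(dc$labels["A", ]), 0)
})

test_that("entropy matches closed forms in nats", {
  expect_equal(entropy(c(0, 0, 1, 1)), log(2))
  expect_equal(entropy(rep(7, 10)), 0)
  expect_equal(entropy(c(1, 2, 3, 4)), log(4))
  expect_error(entropy(integer(0)), "empty")
})

test_that("mutual information obeys its identities and matches direct summation", {
  x <- c(0, 0, 1, 1)
  y <- c(0, 1, 0, 1)
  expect_equal(mutual_information(x, y), 0)
  expect_equal(mutual_information(x, x), entropy(x))

  # counts (3,1; 1,3): oracle sums over the explicit joint distribution
  xs <- rep(c(0, 0, 1, 1), c(3, 1, 1, 3))
  ys <- rep(c(0, 1, 0, 1), c(3, 1, 1, 3))
  expect_equal(mutual_information(xs, ys),
               mi_from_counts(matrix(c(3, 1, 1, 3), 2, 2)))
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("information inequalities hold across random discrete pairs", {
  set.seed(33)
  for (rep in 1:25) {
    x <- sample(0:3, 60, replace = TRUE)
    y <- sample(0:2, 60, replace = TRUE)
    Hx <- entropy(x)
    Hy <- entropy(y)
    Hxy <- joint_entropy(x, y)
    I <- mutual_information(x, y)
    expect_gte(Hx, 0)
    expect_lte(Hxy, Hx + Hy + 1e-12)
    expect_lte(conditional_entropy(y, x), Hy + 1e-12)
    expect_gte(I, -1e-12)
    expect_lte(I, min(Hx, Hy) + 1e-12)
    expect_equal(I, mutual_information(y, x))
  }
})

test_that("the exp(-I) distance matrix is a monotone symmetric map", {
  spec <- synthetic_spec(p = 6, n = 80, r = 1, out_degree = 3, seed = 2)
  expr <- simulate_expression(generate_dag(spec), spec)
  est <- entropy_estimates(discretize_equal_frequency(expr))
  d <- mi_distance_matrix(est)
  expect_equal(d, t(d))
  expect_true(all(d > 0 & d <= 1 + 1e-12))
  expect_equal(diag(d), exp(-est$H))
  expect_equal(d[1, 2], exp(-est$I[1, 2]))
  # strictly larger I gives strictly smaller d
  o <- order(est$I[upper.tri(est$I)])
  expect_identical(o, order(-d[upper.tri(d)]))
})

test_that("greedy entropy reduction finds single and joint parents", {
  set.seed(44)
  a <- sample(0:1, 400, replace = TRUE)
  b <- sample(0:1, 400, replace = TRUE)
  noise <- matrix(sample(0:1, 2 * 400, replace = TRUE), 2)
  # target copies A exactly
  labs <- rbind(A = a, B = b, T1 = a, N1 = noise[1, ], N2 = noise[2, ])
  disc <- structure(list(labels = labs, b = 2L), class = "disc_matrix")
  ps <- select_parents(disc, "T1")
  expect_identical(as.character(ps), "A")
  expect_equal(conditional_entropy(labs["T1", ], labs["A", ]), 0)

  # target is the XOR of A and B: pairwise MI is ~0 but the joint
  # conditional entropy vanishes; oracle = exhaustive 1/2-parent search
  labs2 <- rbind(A = a, B = b, X = xor(a, b) * 1L,
                 N1 = noise[1, ], N2 = noise[2, ])
  disc2 <- structure(list(labels = labs2, b = 2L), class = "disc_matrix")
  cands <- c("A", "B", "N1", "N2")
  pair_h <- sapply(combn(cands, 2, simplify = FALSE), function(uv)
    cond_entropy_oracle(labs2["X", ], t(labs2[uv, ])))
  best_pair <- combn(cands, 2, simplify = FALSE)[[which.min(pair_h)]]
  expect_setequal(best_pair, c("A", "B"))
  ps2 <- select_parents(disc2, "X")
  expect_setequal(as.character(ps2), c("A", "B"))
  expect_lt(cond_entropy_oracle(labs2["X", ], t(labs2[c("A", "B"), ])), 1e-12)

  # never more than two parents, whatever the tuple of dependencies
  labs3 <- rbind(labs2, C = a)
  disc3 <- structure(list(labels = labs3, b = 2L), class = "disc_matrix")
  expect_lte(length(select_parents(disc3, "X")), 2L)
})

test_that("direction assignment follows the parent, entropy and tie rules", {
  set.seed(55)
  # U is a fine-grained regulator whose level coarse-grains into V (with a
  # little switching noise): U determines V almost fully, V leaves most of
  # U's detail open, so the normalised conditional entropy points U -> V
  u_lab <- sample(0:3, 401, replace = TRUE)
  flip <- runif(401) < 0.1
  v_lab <- ifelse(flip, 1L - as.integer(u_lab >= 2), as.integer(u_lab >= 2))
  labs <- rbind(U = u_lab, V = v_lab, W = sample(0:3, 401, replace = TRUE))
  disc <- structure(list(labels = labs, b = 4L), class = "disc_matrix")
  est <- entropy_estimates(disc)

  # rule (a): explicit parent relation wins
  psets <- list(U = character(0), V = "U", W = character(0))
  expect_identical(assign_direction("U", "V", psets, est), c("U", "V"))
  expect_identical(assign_direction("V", "U", psets, est), c("U", "V"))

  # rule (b): direct toward the endpoint with smaller normalised
  # conditional entropy; oracle computes both ratios explicitly
  none <- list(U = character(0), V = character(0), W = character(0))
  rv <- conditional_entropy(labs["V", ], labs["U", ]) / est$H["V"]
  ru <- conditional_entropy(labs["U", ], labs["V", ]) / est$H["U"]
  expect_lt(rv, ru)
  expect_identical(assign_direction("U", "V", none, est), c("U", "V"))
  expect_identical(assign_direction("V", "U", none, est), c("U", "V"))

  # rule (c): exact ties fall back to lexicographic order
  est_tie <- est
  est_tie$H[] <- 1
  est_tie$Hjoint[] <- 1.5
  expect_identical(assign_direction("W", "U", none, est_tie), c("U", "W"))
})

test_that("network inference recovers a copy pair and prunes indirect links", {
  set.seed(66)
  x <- rnorm(200)
  expr2 <- expression_matrix(rbind(A = x, B = x, C = rnorm(200)))
  disc2 <- discretize_equal_frequency(expr2)
  net2 <- infer_network_mider(expr2, mider_params(fraction = 0.2))
  expect_equal(max(net2$weights["A", "B"], net2$weights["B", "A"]),
               entropy(disc2$labels["A", ]), tolerance = 1e-12)

  # chain: the entropy-reduction step prefers the direct parent, and the
  # A-C link carries less information than either true link
  expr3 <- make_chain_expr(n = 500, noise = 0.4, seed = 67)
  net3 <- infer_network_mider(expr3, mider_params(fraction = 0.35))
  W <- net3$weights
  expect_lt(max(W["G1", "G3"], W["G3", "G1"]),
            min(max(W["G1", "G2"], W["G2", "G1"]),
                max(W["G2", "G3"], W["G3", "G2"])))
})

test_that("independent genes yield only weak, parent-free links", {
  set.seed(77)
  expr <- expression_matrix(matrix(rnorm(6 * 500), 6, 500,
                                   dimnames = list(paste0("G", 1:6), NULL)))
  params <- mider_params(fraction = 0.05)
  disc <- discretize_equal_frequency(expr)
  for (g in rownames(expr))
    expect_length(select_parents(disc, g, params), 0)
  net <- infer_network_mider(expr, params)
  # permutation oracle: the MI of shuffled labels bounds chance-level MI
  perm <- vapply(1:50, function(i) {
    mutual_information(disc$labels[1, ], sample(disc$labels[2, ]))
  }, 0)
  expect_lt(max(net$weights), max(perm) * 3)
})

test_that("mider inference is invariant to sample ordering", {
  spec <- synthetic_spec(p = 8, n = 60, r = 2, out_degree = 3, seed = 4)
  expr <- simulate_expression(generate_dag(spec), spec)
  net <- infer_network_mider(expr)
  perm <- sample(ncol(expr))
  net2 <- infer_network_mider(expression_matrix(expr[, perm]))
  expect_equal(net$weights, net2$weights)
})
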