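#' Specification of a planted-regulator benchmark dataset
#'
#' Describes a ground-truth directed acyclic network with `r` regulator
#' genes of in-degree 0 and an expression matrix simulated from it, the
#' setting that degree-based role classification is designed to detect.
#'
#' @param p Number of genes.
#' @param n Number of samples.
#' @param r Number of planted regulators (in-degree 0), `r < p`.
#' @param out_degree Targets per regulator, assigned as disjoint regulons
#'   (default 6; capped at `floor((p - r) / r)`).
#' @param density Probability of an extra forward edge between two
#'   non-regulator genes (default 0.05).
#' @param link Child link function, `"linear"` or `"sigmoid"` (tanh).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0.9, comparable to the unit-variance regulator signal).
#' @param group_shift Optional case/control mean offset applied to
#'   `shift_genes` for the second half of the samples.
#' @param shift_genes Genes receiving the group shift (default: the
#'   regulators).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(p = 16L, n = 100L, r = 2L, out_degree = 6L,
                           density = 0.05, link = c("linear", "sigmoid"),
                           noise_sd = 0.9, group_shift = NULL,
                           shift_genes = NULL, seed = 1L) {
  link <- match.arg(link)
  if (r >= p) stop("r must be smaller than p")
  if (r < 0) stop("r must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (r > 0 && out_degree > p - r)
    stop("out_degree cannot exceed the number of non-regulator genes")
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  structure(list(p = as.integer(p), n = as.integer(n), r = as.integer(r),
                 out_degree = as.integer(out_degree), density = density,
                 link = link, noise_sd = noise_sd,
                 group_shift = group_shift, shift_genes = shift_genes,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a ground-truth DAG with planted regulators
#'
#' Genes are placed in a random topological order with the `r` regulators
#' first; every edge points forward in that order and no edge enters a
#' regulator, so regulators have in-degree 0 and the graph is acyclic by
#' construction. Each regulator receives `out_degree` targets sampled from
#' the non-regulators; forward non-regulator pairs are wired with
#' probability `density`. Generative coefficients are drawn uniformly from
#' +/-[0.6, 1.2]; truth weights are their magnitudes.
#'
#' @param spec A [synthetic_spec()].
#' @return A `gene_network` with attributes `coefficients` (signed),
#'   `regulators` and `order` (the topological order of gene indices).
#' @export
generate_dag <- function(spec) {
  set.seed(spec$seed)
  p <- spec$p
  r <- spec$r
  genes <- sprintf("G%02d", seq_len(p))
  reg_idx <- seq_len(r)
  nonreg_idx <- setdiff(seq_len(p), reg_idx)
  ord <- c(if (r > 0) sample(reg_idx, r) else integer(0),
           if (length(nonreg_idx) > 1L) sample(nonreg_idx) else nonreg_idx)
  pos <- match(seq_len(p), ord)
  coef <- matrix(0, p, p, dimnames = list(genes, genes))
  if (r > 0) {
    # disjoint regulons: each regulator drives its own target module, the
    # hub structure degree-based role classification is designed to detect
    pool <- if (length(nonreg_idx) > 1L) sample(nonreg_idx) else nonreg_idx
    take <- max(1L, min(spec$out_degree, floor(length(pool) / r)))
    for (ri in seq_len(r)) {
      sel <- (seq_len(take) + (ri - 1L) * take - 1L) %% length(pool) + 1L
      coef[reg_idx[ri], pool[sel]] <- 1
    }
  }
  if (length(nonreg_idx) > 1L && spec$density > 0) {
    for (i in nonreg_idx) for (j in nonreg_idx) {
      if (pos[i] < pos[j] && stats::runif(1) < spec$density)
        coef[i, j] <- 1
    }
  }
  ne <- sum(coef != 0)
  coef[coef != 0] <- stats::runif(ne, 0.6, 1.2) *
    sample(c(-1, 1), ne, replace = TRUE)
  net <- gene_network(abs(coef))
  attr(net, "coefficients") <- coef
  attr(net, "regulators") <- genes[reg_idx]
  attr(net, "order") <- ord
  net
}

#' Simulate an expression matrix from a ground-truth DAG
#'
#' Regulators and parentless genes draw standard-normal values; every other
#' gene is the link function of the coefficient-weighted sum of its parents
#' plus Gaussian noise, evaluated in topological order. When
#' `spec$group_shift` is set, the second half of the samples form group
#' `"case"` and the designated genes get the mean offset, so the true
#' standardised shift is known.
#'
#' @param truth A `gene_network` from [generate_dag()] (with its
#'   `coefficients` attribute).
#' @param spec The matching [synthetic_spec()].
#' @return An [expression_matrix()], with a `groups` attribute when a
#'   group shift is requested.
#' @export
simulate_expression <- function(truth, spec) {
  coef <- attr(truth, "coefficients")
  if (is.null(coef)) stop("truth must carry its coefficients attribute")
  ord <- attr(truth, "order")
  genes <- rownames(truth$weights)
  p <- spec$p
  n <- spec$n
  set.seed(spec$seed + 1000003L)
  E <- matrix(0, p, n, dimnames = list(genes, paste0("S", seq_len(n))))
  linkf <- if (spec$link == "sigmoid") tanh else identity
  for (i in ord) {
    pa <- which(coef[, i] != 0)
    if (!length(pa)) {
      E[i, ] <- stats::rnorm(n)
    } else {
      s <- as.numeric(crossprod(coef[pa, i], E[pa, , drop = FALSE]))
      E[i, ] <- linkf(s) + stats::rnorm(n, 0, spec$noise_sd)
    }
  }
  groups <- NULL
  if (!is.null(spec$group_shift)) {
    groups <- rep(c("control", "case"), c(ceiling(n / 2), floor(n / 2)))
    shift_genes <- spec$shift_genes %||% attr(truth, "regulators")
    E[shift_genes, groups == "case"] <-
      E[shift_genes, groups == "case"] + spec$group_shift
  }
  expression_matrix(E, groups = groups)
}

#' Fixed benchmark suite of planted-regulator fixtures
#'
#' A deterministic set of (truth, expression) fixtures spanning p in
#' \{10, 16, 20\}, n in \{20, 100, 500\}, r in \{0, 2, 4\} and both link
#' functions; regenerable bit-identically from `seed`. Optionally written
#' to disk as `expression.tsv` / `truth_edges.tsv` per fixture.
#'
#' @param seed Base seed (fixture i uses `seed + i`).
#' @param out_dir Optional directory for on-disk copies.
#' @return Named list of fixtures, each with `spec`, `truth` and `expr`.
#' @export
make_benchmark_suite <- function(seed = 1L, out_dir = NULL) {
  grid <- list(
    list(p = 10L, n = 20L,  r = 0L, link = "linear"),
    list(p = 10L, n = 100L, r = 2L, link = "sigmoid"),
    list(p = 16L, n = 100L, r = 2L, link = "linear"),
    list(p = 16L, n = 20L,  r = 4L, link = "linear"),
    list(p = 16L, n = 500L, r = 4L, link = "sigmoid"),
    list(p = 20L, n = 100L, r = 2L, link = "linear"),
    list(p = 20L, n = 500L, r = 0L, link = "sigmoid"))
  out <- lapply(seq_along(grid), function(i) {
    g <- grid[[i]]
    spec <- synthetic_spec(p = g$p, n = g$n, r = g$r, link = g$link,
                           seed = seed + i)
    truth <- generate_dag(spec)
    expr <- simulate_expression(truth, spec)
    list(spec = spec, truth = truth, expr = expr)
  })
  names(out) <- vapply(grid, function(g)
    sprintf("p%02d_n%03d_r%d_%s", g$p, g$n, g$r, g$link), "")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      d <- file.path(out_dir, nm)
      dir.create(d, showWarnings = FALSE)
      write_expression(out[[nm]]$expr, file.path(d, "expression.tsv"))
      write_network(out[[nm]]$truth, file.path(d, "truth_edges.tsv"))
    }
  }
  out
}
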