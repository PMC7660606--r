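#' Two-level Gaussian-mixture quantisation of expression
#'
#' Each gene is fitted with a two-component univariate normal mixture by
#' expectation-maximisation (deterministic initialisation of the component
#' means at the 25th/75th percentiles, shared initial standard deviation,
#' equal initial weights, log-likelihood tolerance 1e-8, iteration cap) and
#' every sample is labelled by its maximum-posterior component. Label 0 is
#' the lower-mean component. When the components collapse (means within
#' 1e-6) or EM degenerates, the gene falls back to a median split; a
#' constant gene gets all-zero labels with a warning.
#'
#' @param expr Expression matrix with at least 4 samples.
#' @param levels Number of quantisation levels; only 2 is supported.
#' @return A list of class `quant_matrix` with binary `labels` (genes x
#'   samples) and a genes x 2 matrix `means` of component means (lower
#'   first).
#' @export
gmm_quantize <- function(expr, levels = 2L) {
  if (levels != 2L) stop("only two quantisation levels are supported")
  expr <- validate_expression(expr)
  if (ncol(expr) < 4L) stop("at least 4 samples are required")
  p <- nrow(expr)
  labs <- matrix(0L, p, ncol(expr), dimnames = dimnames(expr))
  mns <- matrix(NA_real_, p, 2L,
                dimnames = list(rownames(expr), c("low", "high")))
  for (i in seq_len(p)) {
    fit <- fit_gmm2(expr[i, ])
    if (isTRUE(fit$constant))
      warning("constant gene quantised to a single level: ", rownames(expr)[i])
    labs[i, ] <- fit$labels
    mns[i, ] <- fit$means
  }
  structure(list(labels = labs, means = mns), class = "quant_matrix")
}

fit_gmm2 <- function(x, max_iter = 200L, tol = 1e-8) {
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps)
    return(list(labels = rep.int(0L, length(x)), means = c(x[1L], x[1L]),
                constant = TRUE))
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sd0 <- stats::sd(x)
  sds <- c(sd0, sd0)
  pi1 <- 0.5
  ll_old <- -Inf
  ok <- TRUE
  g <- rep(0.5, length(x))
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1L], sds[1L])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2L], sds[2L])
    tot <- d1 + d2
    if (any(!is.finite(tot)) || any(tot <= 0)) { ok <- FALSE; break }
    g <- d1 / tot
    ll <- sum(log(tot))
    s1 <- sum(g)
    s2 <- length(x) - s1
    if (s1 <= 0 || s2 <= 0) { ok <- FALSE; break }
    pi1 <- s1 / length(x)
    mu <- c(sum(g * x) / s1, sum((1 - g) * x) / s2)
    sds <- sqrt(c(sum(g * (x - mu[1L])^2) / s1,
                  sum((1 - g) * (x - mu[2L])^2) / s2))
    sds <- pmax(sds, 1e-6 * diff(rng))
    if (any(!is.finite(c(mu, sds)))) { ok <- FALSE; break }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (!ok || abs(mu[1L] - mu[2L]) < 1e-6) {
    med <- stats::median(x)
    lab <- as.integer(x > med)
    m0 <- mean(x[lab == 0L])
    m1 <- if (any(lab == 1L)) mean(x[lab == 1L]) else m0
    return(list(labels = lab, means = c(m0, m1), fallback = TRUE))
  }
  lab_c1 <- as.integer(g < 0.5)  # 1 when component 2 is the argmax
  if (mu[1L] <= mu[2L]) {
    list(labels = lab_c1, means = sort(mu))
  } else {
    list(labels = 1L - lab_c1, means = sort(mu))
  }
}

#' Maximum-likelihood conditional probability tables with add-one smoothing
#'
#' For each gene the table of its binary state given every configuration of
#' its parents in the network is estimated from joint label counts with
#' Laplace (add-one) smoothing; a parent configuration never observed
#' therefore yields (1/2, 1/2), and a root gene gets its smoothed marginal.
#'
#' @param quant A `quant_matrix` from [gmm_quantize()].
#' @param structure An acyclic `gene_network` (edge i -> j means i is a
#'   parent of j).
#' @param cap Maximum allowed number of parents per gene (default 8).
#' @return Named list, one entry per gene, each with `parents` (character)
#'   and `table` (2^n_parents x 2 row-stochastic matrix; parent
#'   configurations are indexed little-endian in `parents` order).
#' @export
estimate_cpts <- function(quant, structure, cap = 8L) {
  W <- structure$weights
  genes <- rownames(W)
  A <- W > 0
  if (is.null(topological_order(A)))
    stop("structure must be acyclic; break cycles first")
  L <- quant$labels[genes, , drop = FALSE]
  n <- ncol(L)
  out <- vector("list", length(genes))
  names(out) <- genes
  for (j in seq_along(genes)) {
    pa <- genes[A[, j]]
    npa <- length(pa)
    if (npa > cap)
      stop("gene ", genes[j], " has ", npa, " parents (cap ", cap,
           "); use a tighter edge threshold")
    nconf <- 2L^npa
    conf <- if (npa) {
      as.integer(colSums(L[pa, , drop = FALSE] * 2^(seq_len(npa) - 1L)))
    } else {
      integer(n)
    }
    idx <- conf * 2L + L[genes[j], ]
    counts <- matrix(tabulate(idx + 1L, nbins = 2L * nconf),
                     nrow = nconf, byrow = TRUE)
    cpt <- counts + 1
    cpt <- cpt / rowSums(cpt)
    colnames(cpt) <- c("0", "1")
    out[[j]] <- list(parents = pa, table = cpt)
  }
  out
}

#' Break directed cycles by deleting minimum-weight cycle edges
#'
#' While the network contains a directed cycle, the minimum-weight edge on
#' one such cycle is deleted (ties broken by (source, target) lexicographic
#' order). Deletions are returned so validation stays transparent.
#'
#' @param network A `gene_network`.
#' @return List with the acyclic `network` and a data frame
#'   `removed_edges` (`source`, `target`, `weight`).
#' @export
break_cycles <- function(network) {
  W <- network$weights
  g <- rownames(W)
  removed <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  repeat {
    cyc <- find_directed_cycle(W > 0)
    if (is.null(cyc)) break
    src <- cyc
    tgt <- c(cyc[-1L], cyc[1L])
    wts <- W[cbind(src, tgt)]
    o <- order(wts, g[src], g[tgt], method = "radix")[1L]
    removed <- rbind(removed,
                     data.frame(source = g[src[o]], target = g[tgt[o]],
                                weight = wts[o], stringsAsFactors = FALSE))
    W[src[o], tgt[o]] <- 0
  }
  list(network = gene_network(W, directed = network$directed),
       removed_edges = removed)
}

#' Convert a gene network into a factor graph
#'
#' Cycles are first broken with [break_cycles()]; genes whose in-degree
#' still exceeds `cap` then have their weakest in-edges pruned (ties
#' lexicographic, deletions logged alongside the cycle deletions) so the
#' conditional probability tables stay estimable. The resulting directed
#' acyclic structure is encoded as a bipartite factor graph with one binary
#' variable node per gene and one factor node per gene holding the gene's
#' conditional probability table given its parents (factor degree =
#' 1 + number of parents).
#'
#' @param structure A `gene_network` (may contain cycles).
#' @param cpts Conditional probability tables from [estimate_cpts()]
#'   matching the acyclic structure; when `NULL` they are estimated from
#'   `quant` after cycle breaking.
#' @param quant A `quant_matrix`, required when `cpts` is `NULL`.
#' @param cap Parent cap forwarded to [estimate_cpts()].
#' @return A list of class `factor_graph` with `genes`, `factors` (each a
#'   list with `child`, `vars` (indices, parents then child) and `table`, a
#'   `2^d`-long array indexed little-endian over `vars`), and the
#'   `removed_edges` log.
#' @export
build_factor_graph <- function(structure, cpts = NULL, quant = NULL,
                               cap = 8L) {
  bf <- break_cycles(structure)
  net <- bf$network
  genes <- rownames(net$weights)
  removed <- bf$removed_edges
  if (is.null(cpts)) {
    if (is.null(quant)) stop("supply either cpts or quant")
    W <- net$weights
    for (j in seq_along(genes)) {
      pa <- which(W[, j] > 0)
      if (length(pa) > cap) {
        o <- order(W[pa, j], genes[pa], method = "radix")
        drop <- pa[o[seq_len(length(pa) - cap)]]
        removed <- rbind(removed,
                         data.frame(source = genes[drop], target = genes[j],
                                    weight = W[drop, j],
                                    stringsAsFactors = FALSE))
        W[drop, j] <- 0
      }
    }
    net <- gene_network(W, directed = net$directed)
    cpts <- estimate_cpts(quant, net, cap)
  }
  factors <- lapply(seq_along(genes), function(j) {
    cp <- cpts[[genes[j]]]
    pidx <- match(cp$parents, genes)
    d <- length(pidx) + 1L
    tab <- numeric(2L^d)
    nconf <- 2L^(d - 1L)
    for (s in 0:1)
      tab[seq_len(nconf) + s * nconf] <- cp$table[, s + 1L]
    list(child = j, vars = c(pidx, j), table = tab)
  })
  structure(list(genes = genes, factors = factors,
                 removed_edges = removed),
            class = "factor_graph")
}

#' Loopy belief propagation (sum-product) on a factor graph
#'
#' Synchronous (flooding) schedule: every factor-to-variable and
#' variable-to-variable message is recomputed from the previous iteration's
#' messages, normalised after each update, starting from uniform messages.
#' The algorithm stops when the largest absolute message change falls below
#' `tol`; non-convergence within `max_iter` is reported via the `converged`
#' flag, not an error.
#'
#' @param graph A `factor_graph`.
#' @param max_iter Iteration cap (default 500).
#' @param tol Convergence tolerance on message change (default 1e-6).
#' @return List with `marginals` (genes x 2, rows summing to 1),
#'   `iterations` used and a logical `converged`.
#' @export
loopy_belief_propagation <- function(graph, max_iter = 500L, tol = 1e-6) {
  fs <- graph$factors
  nf <- length(fs)
  p <- length(graph$genes)
  bits <- lapply(fs, function(f) {
    d <- length(f$vars)
    m <- matrix(0L, 2L^d, d)
    for (l in seq_len(d))
      m[, l] <- rep(rep(0:1, each = 2L^(l - 1L)), length.out = 2L^d)
    m
  })
  inc <- vector("list", p)
  for (fi in seq_len(nf))
    for (j in seq_along(fs[[fi]]$vars)) {
      v <- fs[[fi]]$vars[j]
      inc[[v]] <- rbind(inc[[v]], c(fi, j))
    }
  mv <- lapply(fs, function(f) matrix(0.5, length(f$vars), 2L))
  mf <- lapply(fs, function(f) matrix(0.5, length(f$vars), 2L))
  converged <- FALSE
  iters <- max_iter
  for (it in seq_len(max_iter)) {
    mf_new <- mf
    mv_new <- mv
    for (fi in seq_len(nf)) {
      f <- fs[[fi]]
      d <- length(f$vars)
      B <- bits[[fi]]
      for (j in seq_len(d)) {
        prodv <- f$table
        if (d > 1L)
          for (l in seq_len(d)[-j])
            prodv <- prodv * mv[[fi]][l, B[, l] + 1L]
        msg <- c(sum(prodv[B[, j] == 0L]), sum(prodv[B[, j] == 1L]))
        s <- sum(msg)
        mf_new[[fi]][j, ] <- if (is.finite(s) && s > 0) msg / s else c(0.5, 0.5)
      }
    }
    for (v in seq_len(p)) {
      iv <- inc[[v]]
      nr <- nrow(iv)
      for (r in seq_len(nr)) {
        msg <- c(1, 1)
        for (r2 in seq_len(nr))
          if (r2 != r) msg <- msg * mf[[iv[r2, 1L]]][iv[r2, 2L], ]
        s <- sum(msg)
        mv_new[[iv[r, 1L]]][iv[r, 2L], ] <-
          if (is.finite(s) && s > 0) msg / s else c(0.5, 0.5)
      }
    }
    delta <- 0
    for (fi in seq_len(nf))
      delta <- max(delta, abs(mf_new[[fi]] - mf[[fi]]),
                   abs(mv_new[[fi]] - mv[[fi]]))
    mf <- mf_new
    mv <- mv_new
    if (delta < tol) {
      converged <- TRUE
      iters <- it
      break
    }
  }
  marg <- matrix(0.5, p, 2L, dimnames = list(graph$genes, c("0", "1")))
  for (v in seq_len(p)) {
    iv <- inc[[v]]
    m <- c(1, 1)
    for (r in seq_len(nrow(iv)))
      m <- m * mf[[iv[r, 1L]]][iv[r, 2L], ]
    s <- sum(m)
    marg[v, ] <- if (is.finite(s) && s > 0) m / s else c(0.5, 0.5)
  }
  list(marginals = marg, iterations = iters, converged = converged)
}

#' Observed per-gene state proportions
#'
#' @param quant A `quant_matrix`.
#' @return Genes x 2 matrix of empirical proportions of levels 0 and 1;
#'   rows sum to 1 exactly.
#' @export
observed_states <- function(quant) {
  L <- quant$labels
  cbind(`0` = rowMeans(L == 0L), `1` = rowMeans(L == 1L))
}

#' Pearson correlation of predicted marginals against observed proportions
#'
#' Both quantisation levels of every gene enter the comparison (2p values a
#' side), mirroring the two-column layout of a marginals-versus-states
#' report.
#'
#' @param predicted,observed Equal-length numeric vectors or genes x 2
#'   matrices of probabilities.
#' @return List with the correlation `r` and the two-sided `p_value`.
#' @export
validation_correlation <- function(predicted, observed) {
  pv <- as.numeric(predicted)
  ov <- as.numeric(observed)
  if (length(pv) != length(ov)) stop("vectors differ in length")
  if (stats::sd(pv) == 0 || stats::sd(ov) == 0)
    stop("zero-variance probability vector")
  ct <- stats::cor.test(pv, ov)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Validate a network against the expression data it was inferred from
#'
#' Quantises the data to two levels, builds the factor graph (breaking any
#' cycles), runs loopy belief propagation and correlates the predicted
#' marginals with the observed state proportions.
#'
#' @param expr Expression matrix.
#' @param network The `gene_network` to validate.
#' @param max_iter,tol Forwarded to [loopy_belief_propagation()].
#' @param cap Parent cap forwarded to [estimate_cpts()].
#' @return A list of class `validation_report` with `marginals`,
#'   `observed`, `r`, `p_value`, `iterations`, `converged` and
#'   `removed_edges`.
#' @export
validate_network <- function(expr, network, max_iter = 500L, tol = 1e-6,
                             cap = 8L) {
  quant <- gmm_quantize(expr)
  fg <- build_factor_graph(network, quant = quant, cap = cap)
  lbp <- loopy_belief_propagation(fg, max_iter = max_iter, tol = tol)
  obs <- observed_states(quant)
  cc <- validation_correlation(lbp$marginals, obs)
  structure(list(marginals = lbp$marginals, observed = obs, r = cc$r,
                 p_value = cc$p_value, iterations = lbp$iterations,
                 converged = lbp$converged,
                 removed_edges = fg$removed_edges),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("validation_report: r = %.4f (p = %.3g), ",
                     "%d LBP iterations, converged = %s\n"),
              x$r, x$p_value, x$iterations, x$converged))
  invisible(x)
}
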