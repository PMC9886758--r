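# Cluster-based permutation test (CBPT) of node-wise strength-behaviour
# association. Node statistic: covariate-adjusted Spearman correlation
# (partial Pearson on mid-ranks). Clusters: connected components, under the
# grid adjacency, of nodes significant at alpha_node, split by sign.
# Cluster score: Fisher-Z mass, sum(atanh(rho)). Family-wise calibration:
# the maximum absolute cluster mass over random joint permutations of the
# (behaviour, covariates) rows against the strength maps.

rank_cols <- function(X) {
  apply(X, 2L, rank)   # mid-ranks for ties
}

# residualize columns of M on [1, C] via the thin-Q of the design
resid_on <- function(M, Q) {
  M - Q %*% crossprod(Q, M)
}

#' Covariate-adjusted Spearman correlation
#'
#' Rank-transforms `x`, `y` and each covariate (mid-ranks for ties), then
#' computes the partial Pearson correlation of the ranked `x` and `y` given
#' the ranked covariates, with a p-value from the t distribution on
#' `n - 2 - ncov` degrees of freedom. Without covariates this is the plain
#' Spearman correlation with the t approximation.
#'
#' @param x,y numeric vectors, no NA, length `n >= ncov + 3`.
#' @param covariates optional vector, matrix or data frame of covariates.
#' @return List with `rho`, `p`, `n`, `df`. If `x` or `y` has zero rank
#'   variance, `rho` and `p` are `NA` with a `degenerate` flag.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  res <- partial_spearman_map(matrix(x, ncol = 1L), y, covariates)
  list(rho = res$rho[1L], p = res$p[1L], n = res$n, df = res$df,
       degenerate = is.na(res$rho[1L]))
}

#' Node-wise covariate-adjusted Spearman map
#'
#' Vectorized [partial_spearman()] of every column of `X` against `y`,
#' sharing one covariate projection — the node-statistic map of the CBPT.
#'
#' @param X numeric matrix, subjects x nodes.
#' @param y numeric behaviour vector.
#' @param covariates optional covariates (vector/matrix/data frame).
#' @return List with vectors `rho` and `p` (length `ncol(X)`), scalars `n`
#'   and `df`. Columns with zero rank variance get `NA`.
#' @export
partial_spearman_map <- function(X, y, covariates = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  C <- prepare_covariates(covariates, n)
  ncov <- ncol(C)
  if (n < ncov + 3L) stop("need n >= ncov + 3 subjects")
  if (anyNA(X) || anyNA(y) || anyNA(C)) stop("NA in inputs")
  if (ncov > 0L && qr(cbind(1, C))$rank < ncov + 1L)
    stop("covariates are collinear")
  Rx <- rank_cols(X)
  ry <- rank(y)
  RC <- if (ncov > 0L) rank_cols(C) else NULL
  Q <- qr.Q(qr(cbind(rep(1, n), RC)))
  ex <- resid_on(Rx, Q)
  ey <- as.numeric(resid_on(matrix(ry, ncol = 1L), Q))
  sx <- colSums(ex^2)
  sy <- sum(ey^2)
  rho <- rep(NA_real_, ncol(X))
  ok <- sx > 1e-10 & sy > 1e-10
  rho[ok] <- colSums(ex[, ok, drop = FALSE] * ey) / sqrt(sx[ok] * sy)
  rho <- pmin(1, pmax(-1, rho))
  df <- n - 2L - ncov
  tval <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p[!is.na(p) & p <= 0] <- .Machine$double.xmin
  list(rho = rho, p = p, n = n, df = df)
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0))
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  if (nrow(C) != n) stop("covariates must have one row per subject")
  C
}

#' Form candidate clusters from a node-statistic map
#'
#' Thresholds the node map at `p < alpha_node`, splits the significant nodes
#' by the sign of their correlation, takes connected components under the
#' spatial adjacency, and discards components smaller than `min_size`
#' (default 1% of the grid — 12 nodes for a 1202-node grid).
#'
#' @param rho,p per-node statistic and p-value vectors.
#' @param adjacency a `grid_adjacency` over the same nodes.
#' @param alpha_node node-wise threshold (two-sided p).
#' @param min_size minimum cluster extent; `NULL` for 1% of the grid,
#'   `max(1, floor(0.01 * N))` (12 nodes on a 1202-node grid).
#' @return List of candidate clusters, each a list with `nodes` (sorted
#'   ids), `sign` (+1/-1) and `mass` (Fisher-Z sum). Empty list if nothing
#'   survives.
#' @export
form_clusters <- function(rho, p, adjacency, alpha_node = 0.001,
                          min_size = NULL) {
  N <- attr(adjacency, "n")
  if (length(rho) != N || length(p) != N)
    stop("stat map and adjacency cover different node sets")
  if (is.null(min_size)) min_size <- max(1L, floor(0.01 * N))
  sig <- which(!is.na(p) & p < alpha_node)
  out <- list()
  for (sgn in c(1, -1)) {
    nodes <- sig[sign(rho[sig]) == sgn]
    for (comp in connected_components(nodes, adjacency)) {
      if (length(comp) < min_size) next
      out[[length(out) + 1L]] <- list(
        nodes = comp, sign = sgn, mass = cluster_mass(rho[comp])
      )
    }
  }
  out
}

#' Fisher-Z cluster mass
#'
#' `mass = sum(atanh(rho_i))` over the member correlations — the
#' variance-stabilized cluster-mass statistic.
#'
#' @param rhos member correlation coefficients, all `|rho| < 1`.
#' @return Scalar mass.
#' @export
cluster_mass <- function(rhos) {
  if (any(abs(rhos) >= 1))
    stop("|rho| = 1 gives infinite Fisher Z; cluster mass undefined")
  sum(atanh(rhos))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' Cluster-based permutation test of strength maps against behaviour
#'
#' Runs the full CBPT: node-wise covariate-adjusted Spearman map, spatial
#' clustering of significant nodes at `alpha_node` split by sign, Fisher-Z
#' cluster masses, and a max-|mass| permutation null. Each permutation
#' jointly re-assigns the (behaviour, covariate) rows to the subjects'
#' strength maps (preserving the behaviour-covariate dependence while
#' breaking the map-behaviour link); with `perm_scheme = "freedman_lane"`
#' the ranked behaviour is residualized on the ranked covariates and the
#' residuals are permuted. Cluster p-values use the add-one estimator
#' `p = (1 + #{max null mass >= |observed|}) / (n_perm + 1)`. If `n_perm`
#' exceeds `n!` the permutation distribution is enumerated exhaustively
#' (with a warning).
#'
#' @param strength subjects x nodes matrix of strength (or any per-node FC)
#'   maps.
#' @param behavior per-subject behavioural score.
#' @param covariates optional covariates (e.g. age).
#' @param grid a `source_grid` (used to build the adjacency) — or pass
#'   `adjacency` directly.
#' @param adjacency optional precomputed `grid_adjacency`.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draw.
#' @param alpha_node node-wise two-sided threshold.
#' @param alpha_cluster family-wise cluster significance level.
#' @param min_size minimum cluster extent; `NULL` for 1% of the grid.
#' @param perm_scheme `"joint"` (default) or `"freedman_lane"`.
#' @return An object of class `cbpt`: list with `clusters` (each with
#'   `nodes`, `sign`, `mass`, `p_perm`, `significant`, and `marker` = the
#'   per-subject mean strength over the member nodes), `node_rho`,
#'   `node_p`, `null_max_mass`, and the settings.
#' @export
cbpt_run <- function(strength, behavior, covariates = NULL, grid = NULL,
                     adjacency = NULL, n_perm = 5000, seed = 1,
                     alpha_node = 0.001, alpha_cluster = 0.05,
                     min_size = NULL,
                     perm_scheme = c("joint", "freedman_lane")) {
  perm_scheme <- match.arg(perm_scheme)
  strength <- as.matrix(strength)
  n <- nrow(strength)
  N <- ncol(strength)
  if (n < 5L) stop("need at least 5 subjects")
  if (n_perm < 100L) stop("need n_perm >= 100")
  if (is.null(adjacency)) {
    if (is.null(grid)) stop("supply grid or adjacency")
    adjacency <- build_adjacency(grid)
  }
  if (attr(adjacency, "n") != N)
    stop("adjacency does not match the number of nodes")
  if (is.null(min_size)) min_size <- max(1L, floor(0.01 * N))
  C <- prepare_covariates(covariates, n)
  ncov <- ncol(C)

  obs <- partial_spearman_map(strength, behavior, if (ncov) C else NULL)
  clusters <- form_clusters(obs$rho, obs$p, adjacency, alpha_node, min_size)

  # permutation null of the maximum absolute cluster mass
  set.seed(seed)
  exhaustive <- FALSE
  if (n <= 10 && factorial(n) <= n_perm) {
    warning(sprintf(
      "n_perm = %d exceeds n! = %d; enumerating all permutations", n_perm,
      factorial(n)
    ))
    perms <- all_permutations(n)
    n_perm <- length(perms)
    exhaustive <- TRUE
  }
  Rx <- rank_cols(strength)
  ry <- rank(behavior)
  RC <- if (ncov) rank_cols(C) else NULL
  df <- n - 2L - ncov
  tcrit <- stats::qt(1 - alpha_node / 2, df)
  rcrit <- tcrit / sqrt(df + tcrit^2)    # |rho| threshold equivalent
  if (perm_scheme == "freedman_lane") {
    Q0 <- qr.Q(qr(cbind(rep(1, n), RC)))
    fit0 <- as.numeric(Q0 %*% crossprod(Q0, matrix(ry, ncol = 1L)))
    res0 <- ry - fit0
  }
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- if (exhaustive) perms[[b]] else sample.int(n)
    if (perm_scheme == "joint") {
      ry_b <- ry[idx]
      RC_b <- if (ncov) RC[idx, , drop = FALSE] else NULL
    } else {
      ry_b <- fit0 + res0[idx]
      RC_b <- RC
    }
    Q <- qr.Q(qr(cbind(rep(1, n), RC_b)))
    ex <- resid_on(Rx, Q)
    ey <- as.numeric(resid_on(matrix(ry_b, ncol = 1L), Q))
    rho_b <- colSums(ex * ey) / sqrt(colSums(ex^2) * sum(ey^2))
    # at tiny n a permutation can produce |rho| = 1 exactly; keep the
    # Fisher-Z mass finite (any such permutation dominates the max anyway)
    rho_b <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rho_b))
    hits <- which(abs(rho_b) > rcrit)
    if (!length(hits)) next
    m <- 0
    for (sgn in c(1, -1)) {
      nodes <- hits[sign(rho_b[hits]) == sgn]
      for (comp in connected_components(nodes, adjacency)) {
        if (length(comp) < min_size) next
        m <- max(m, abs(sum(atanh(rho_b[comp]))))
      }
    }
    null_max[b] <- m
  }

  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    cl$p_perm <- (1 + sum(null_max >= abs(cl$mass))) / (n_perm + 1)
    cl$significant <- cl$p_perm < alpha_cluster
    cl$marker <- rowMeans(strength[, cl$nodes, drop = FALSE])
    clusters[[k]] <- cl
  }
  ord <- order(vapply(clusters, function(cl) -abs(cl$mass), numeric(1)))
  structure(
    list(clusters = clusters[ord], node_rho = obs$rho, node_p = obs$p,
         null_max_mass = null_max, n_perm = n_perm, n_subjects = n,
         alpha_node = alpha_node, alpha_cluster = alpha_cluster,
         min_size = min_size, perm_scheme = perm_scheme,
         exhaustive = exhaustive, seed = seed),
    class = "cbpt"
  )
}

#' Significant clusters of a CBPT result
#'
#' @param x a `cbpt` object.
#' @return The sublist of clusters with `p_perm < alpha_cluster`.
#' @export
significant_clusters <- function(x) {
  stopifnot(inherits(x, "cbpt"))
  Filter(function(cl) isTRUE(cl$significant), x$clusters)
}

#' @export
print.cbpt <- function(x, ...) {
  cat(sprintf(
    "CBPT: %d subjects, %d nodes, %d permutations%s (min cluster %d nodes)\n",
    x$n_subjects, length(x$node_rho), x$n_perm,
    if (x$exhaustive) " [exhaustive]" else "", x$min_size
  ))
  if (!length(x$clusters)) {
    cat("  no candidate clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf(
        "  %s cluster: %d nodes, mass %.3f, p_perm = %.4g%s\n",
        if (cl$sign > 0) "positive" else "negative", length(cl$nodes),
        cl$mass, cl$p_perm, if (cl$significant) " *" else ""
      ))
    }
  }
  invisible(x)
}

#' @export
summary.cbpt <- function(object, ...) {
  d <- data.frame(
    size = vapply(object$clusters, function(cl) length(cl$nodes), integer(1)),
    sign = vapply(object$clusters, function(cl) cl$sign, numeric(1)),
    mass = vapply(object$clusters, function(cl) cl$mass, numeric(1)),
    p_perm = vapply(object$clusters, function(cl) cl$p_perm, numeric(1)),
    significant = vapply(object$clusters, function(cl) cl$significant,
                         logical(1))
  )
  d
}
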