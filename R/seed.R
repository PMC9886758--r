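# Seed-based secondary analysis: for a seed cluster, every node's mean PLV
# to the seed, and a CBPT on those seed-link maps.

#' Mean connectivity of every node to a seed cluster
#'
#' For node `j`, the average PLV between `j` and the seed nodes, excluding
#' any self-connection: seed-internal nodes average over the *other* seed
#' members (the diagonal PLV of 1 would otherwise bias them upward). With a
#' single-node seed, the value at the seed node itself is undefined and set
#' to `NA`. If the seed is the whole grid this reduces exactly to the
#' normalized nodal strength.
#'
#' @param plv symmetric PLV matrix.
#' @param seed_nodes nonempty integer vector of node ids within the matrix.
#' @return Numeric vector of per-node seed-link FC values in `[0, 1]`.
#' @export
seed_link_fc <- function(plv, seed_nodes) {
  n <- nrow(plv)
  seed_nodes <- unique(as.integer(seed_nodes))
  if (!length(seed_nodes)) stop("seed_nodes must be nonempty")
  if (any(seed_nodes < 1L | seed_nodes > n))
    stop("seed_nodes outside the matrix")
  s <- rowSums(plv[, seed_nodes, drop = FALSE])
  denom <- rep(length(seed_nodes), n)
  inseed <- seq_len(n) %in% seed_nodes
  s[inseed] <- s[inseed] - diag(plv)[inseed]
  denom[inseed] <- denom[inseed] - 1L
  out <- ifelse(denom > 0, s / denom, NA_real_)
  out
}

# mean PLV over the block primary x secondary, self-pairs excluded (the two
# sets may overlap)
block_mean_fc <- function(plv, primary, secondary) {
  sub <- plv[primary, secondary, drop = FALSE]
  total <- sum(sub)
  npairs <- length(sub)
  both <- intersect(primary, secondary)
  if (length(both)) {
    total <- total - sum(diag(plv)[both])
    npairs <- npairs - length(both)
  }
  if (npairs == 0L) return(NA_real_)
  total / npairs
}

#' Seed-based cluster permutation analysis
#'
#' Computes each subject's seed-link FC map (mean PLV of every node to the
#' seed cluster) and reruns the CBPT on those maps in place of the strength
#' maps. The marker of each resulting secondary cluster is the per-subject
#' mean PLV of the primary-by-secondary block (the strength of the
#' anteroposterior-style link), not the plain member mean.
#'
#' @param plv_list list of per-subject symmetric PLV matrices.
#' @param seed_nodes node ids of the (primary) seed cluster.
#' @param behavior,covariates,grid,adjacency,n_perm,seed,... passed on to
#'   [cbpt_run()].
#' @return An object of class `seed_cbpt` (also `cbpt`), whose clusters
#'   carry the block-mean `marker` and the `seed_nodes` used.
#' @export
seed_cbpt <- function(plv_list, seed_nodes, behavior, covariates = NULL,
                      grid = NULL, adjacency = NULL, n_perm = 5000,
                      seed = 1, ...) {
  stopifnot(is.list(plv_list), length(plv_list) >= 1L)
  seed_nodes <- unique(as.integer(seed_nodes))
  maps <- t(vapply(plv_list, seed_link_fc, numeric(nrow(plv_list[[1L]])),
                   seed_nodes = seed_nodes))
  if (anyNA(maps)) {
    # single-node seed: its own node is undefined; carry it as a dead node
    dead <- which(colSums(is.na(maps)) > 0)
    maps[, dead] <- 0
  } else dead <- integer(0)
  res <- cbpt_run(maps, behavior, covariates = covariates, grid = grid,
                  adjacency = adjacency, n_perm = n_perm, seed = seed, ...)
  if (length(dead)) {
    res$node_rho[dead] <- NA_real_
    res$node_p[dead] <- NA_real_
  }
  for (k in seq_along(res$clusters)) {
    cl <- res$clusters[[k]]
    cl$marker <- vapply(plv_list, block_mean_fc, numeric(1),
                        primary = seed_nodes, secondary = cl$nodes)
    res$clusters[[k]] <- cl
  }
  res$seed_nodes <- seed_nodes
  res$seed_maps <- maps
  class(res) <- c("seed_cbpt", class(res))
  res
}
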