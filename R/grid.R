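#' Build a cubic-lattice source grid
#'
#' Constructs a connected cubic lattice of source positions with contiguous
#' region labels, emulating a volumetric source model (e.g. a 1 cm grid of
#' 1202 positions labelled by 78 cortical areas). Nodes are laid out in a
#' bounding box and taken in plane-by-plane (lexicographic) order, which
#' guarantees the retained set is connected under the 26-neighbourhood rule
#' used by [build_adjacency()].
#'
#' @param n_nodes number of source positions (at least 2, so that every node
#'   has a neighbour).
#' @param n_regions number of region labels; regions are contiguous,
#'   near-equal-size runs of nodes in lattice order.
#' @param spacing lattice spacing in cm.
#' @param seed optional integer; the construction is deterministic, the seed
#'   is accepted for interface uniformity with the simulation functions.
#' @return An object of class `source_grid`: a list with `nodes` (data frame
#'   with columns `node`, `x`, `y`, `z`, `region`), `spacing` and `dims`.
#' @examples
#' g <- make_grid(27, 3)
#' table(g$nodes$region)
#' @export
make_grid <- function(n_nodes, n_regions, spacing = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- as.integer(n_nodes)
  n_regions <- as.integer(n_regions)
  if (n_nodes < 2L)
    stop("n_nodes must be >= 2: a single node has no spatial neighbour")
  if (n_regions < 1L || n_regions > n_nodes)
    stop("need n_nodes >= n_regions >= 1")
  if (spacing <= 0) stop("spacing must be positive")

  L <- ceiling(n_nodes^(1 / 3))
  nz <- ceiling(n_nodes / (L * L))
  # plane-by-plane, row-by-row fill of an L x L x nz box
  idx <- seq_len(n_nodes) - 1L
  x <- idx %% L
  y <- (idx %/% L) %% L
  z <- idx %/% (L * L)
  region <- factor(sprintf("R%03d", 1L + floor(idx * n_regions / n_nodes)))
  nodes <- data.frame(
    node = seq_len(n_nodes),
    x = x * spacing, y = y * spacing, z = z * spacing,
    region = region
  )
  structure(
    list(nodes = nodes, spacing = spacing, dims = c(L, L, nz)),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf(
    "source_grid: %d nodes, %d regions, %.3g cm spacing (box %s)\n",
    nrow(x$nodes), nlevels(x$nodes$region), x$spacing,
    paste(x$dims, collapse = "x")
  ))
  invisible(x)
}

#' Spatial adjacency of a source grid
#'
#' Two nodes are adjacent iff their Euclidean distance is at most
#' `sqrt(3) * spacing + eps` — the 26-neighbourhood of a cubic lattice.
#' The relation is symmetric and irreflexive.
#'
#' @param grid a `source_grid`.
#' @param eps numerical slack on the distance threshold.
#' @return An object of class `grid_adjacency`: a list of integer vectors,
#'   element `j` holding the neighbours of node `j`.
#' @export
build_adjacency <- function(grid, eps = 1e-6) {
  stopifnot(inherits(grid, "source_grid"))
  xyz <- as.matrix(grid$nodes[, c("x", "y", "z")])
  n <- nrow(xyz)
  thr2 <- (sqrt(3) * grid$spacing + eps)^2
  # block over columns to keep the distance computation vectorised but bounded
  nb <- vector("list", n)
  sq <- rowSums(xyz^2)
  block <- 256L
  for (start in seq(1L, n, by = block)) {
    cols <- start:min(start + block - 1L, n)
    d2 <- outer(sq, sq[cols], "+") - 2 * (xyz %*% t(xyz[cols, , drop = FALSE]))
    for (k in seq_along(cols)) {
      j <- cols[k]
      hit <- which(d2[, k] <= thr2)
      nb[[j]] <- hit[hit != j]
    }
  }
  structure(nb, class = "grid_adjacency", n = n)
}

#' @export
print.grid_adjacency <- function(x, ...) {
  deg <- lengths(x)
  cat(sprintf(
    "grid_adjacency: %d nodes, degree %d-%d (median %g)\n",
    attr(x, "n"), min(deg), max(deg), stats::median(deg)
  ))
  invisible(x)
}

# connected components of `nodes` (integer vector) under an adjacency list,
# by breadth-first search restricted to `nodes`
connected_components <- function(nodes, adjacency) {
  if (length(nodes) == 0L) return(list())
  inset <- logical(attr(adjacency, "n"))
  inset[nodes] <- TRUE
  seen <- logical(length(inset))
  comps <- list()
  for (s in nodes) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nxt <- adjacency[[v]]
      nxt <- nxt[inset[nxt] & !seen[nxt]]
      if (length(nxt)) {
        seen[nxt] <- TRUE
        queue <- c(queue, nxt)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
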