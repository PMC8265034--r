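# Shared low-level volume utilities: separable Gaussian smoothing and
# 26-connected component labelling. No installed R package offers n-D
# labelling, so adjacency is built explicitly and resolved with igraph.

# Separable Gaussian blur of a 3-D array, kernel truncated at 3*sigma.
# Rows of the 1-D operator are renormalized so boundaries are not darkened.
gauss_smooth3d <- function(arr, sigma = 1) {
  if (sigma <= 0) return(arr)
  dm <- dim(arr)
  half <- max(1L, ceiling(3 * sigma))
  ker <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    if (n == 1L) return(a)
    K <- matrix(0, n, n)
    for (o in seq(-half, half)) {
      j <- seq_len(n) + o
      ok <- j >= 1 & j <= n
      K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] +
        ker[o + half + 1]
    }
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, dim(a)[axis])
    ap <- array(m, dim(a)[perm])
    aperm(ap, order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Label 26-connected components of a binary volume
#'
#' Voxels sharing a face, edge or corner belong to the same component.
#' Components are numbered 1..K in order of their smallest linear index, so
#' labelling is deterministic.
#'
#' @param mask Binary (logical or 0/1) 3-D array.
#' @return Integer array of the same shape; 0 denotes background.
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  if (length(dm) != 3L) stop("mask must be a 3-D array")
  idx <- which(mask != 0)
  lab <- array(0L, dm)
  if (!length(idx)) return(lab)
  id <- integer(prod(dm))
  id[idx] <- seq_along(idx)
  coord <- arrayInd(idx, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
               (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]  # 13 half-space offsets
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nc <- sweep(coord, 2, offs[k, ], "+")
    inb <- nc[, 1] >= 1 & nc[, 1] <= dm[1] &
           nc[, 2] >= 1 & nc[, 2] <= dm[2] &
           nc[, 3] >= 1 & nc[, 3] <= dm[3]
    if (!any(inb)) next
    nlin <- nc[inb, 1] + (nc[inb, 2] - 1) * dm[1] +
      (nc[inb, 3] - 1) * dm[1] * dm[2]
    nid <- id[nlin]
    sel <- nid > 0L
    if (any(sel)) {
      edges[[k]] <- cbind(id[idx[inb]][sel], nid[sel])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  # renumber by first (smallest linear index) appearance
  first <- tapply(seq_along(idx), memb, min)
  ord <- order(first)
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  lab[idx] <- remap[memb]
  lab
}

# Binary dilation/erosion with a 6-connected (face) structuring element,
# implemented by axis shifts.
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(0, dm)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(dm[ax]) - d[ax]
    s[s >= 1 & s <= dm[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    s <- seq_len(dm[ax])
    s[s - d[ax] >= 1 & s - d[ax] <= dm[ax]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6 <- function(mask) {
  m <- mask != 0
  out <- m
  for (ax in 1:3) {
    for (s in c(-1, 1)) {
      d <- c(0, 0, 0); d[ax] <- s
      out <- out | (shift_array(m, d) != 0)
    }
  }
  out
}

erode6 <- function(mask) {
  m <- mask != 0
  out <- m
  for (ax in 1:3) {
    for (s in c(-1, 1)) {
      d <- c(0, 0, 0); d[ax] <- s
      out <- out & (shift_array(m, d) != 0)
    }
  }
  out
}
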