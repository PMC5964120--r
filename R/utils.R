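#' @useDynLib synaptrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Run expr with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. All stochastic code in the package goes
# through this so nothing leaks into or depends on the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along the first axis of an n-d array with edge replication,
# as a sum over kernel taps of index-shifted slabs (vectorized).
conv_axis1 <- function(a, kernel) {
  d <- dim(a)
  n <- d[1]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  array(out, dim = d)
}

# Separable isotropic Gaussian blur for 2-d or 3-d arrays.
gaussian_blur <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gaussian_kernel_1d(sigma)
  d <- dim(a)
  nd <- length(d)
  for (axis in seq_len(nd)) {
    perm <- c(axis, setdiff(seq_len(nd), axis))
    a <- aperm(conv_axis1(aperm(a, perm), k), order(perm))
  }
  a
}

# Connected components of a logical mask with 8-connectivity (2-d) or
# 26-connectivity (3-d), via a union of pixel-adjacency edges.
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  fg <- which(mask)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) return(labels)
  lut <- array(0L, dim = d)
  lut[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets suffice: each edge found once
  keep <- apply(offsets, 1, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  offsets <- offsets[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[i, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (a in seq_len(nd)) ok <- ok & nb[, a] >= 1L & nb[, a] <= d[a]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1]
    if (nd >= 2) nb_lin <- nb_lin + (nb[ok, 2] - 1L) * d[1]
    if (nd == 3) nb_lin <- nb_lin + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_id <- lut[nb_lin]
    hit <- nb_id > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb_id[hit])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

# Relative integer offsets covering the Euclidean ball of given pixel radius.
ball_offsets <- function(radius, nd) {
  r <- as.integer(ceiling(radius))
  g <- as.matrix(do.call(expand.grid, rep(list(-r:r), nd)))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

# Local maxima of `intensity` restricted to `mask`, with greedy suppression
# of maxima closer than min_separation (brightest kept first).
local_maxima <- function(intensity, mask = NULL, min_separation = 1) {
  d <- dim(intensity)
  nd <- length(d)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  cand <- which(mask)
  if (length(cand) == 0L) return(matrix(numeric(0), 0, nd))
  coords <- arrayInd(cand, d)
  vals <- intensity[cand]
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  is_max <- rep(TRUE, length(cand))
  for (i in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[i, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (a in seq_len(nd)) ok <- ok & nb[, a] >= 1L & nb[, a] <= d[a]
    nb_lin <- nb[ok, 1]
    if (nd >= 2) nb_lin <- nb_lin + (nb[ok, 2] - 1L) * d[1]
    if (nd == 3) nb_lin <- nb_lin + (nb[ok, 3] - 1L) * d[1] * d[2]
    is_max[which(ok)[intensity[nb_lin] > vals[ok]]] <- FALSE
  }
  peaks <- coords[is_max, , drop = FALSE]
  pv <- vals[is_max]
  o <- order(-pv)
  peaks <- peaks[o, , drop = FALSE]
  kept <- matrix(numeric(0), 0, nd)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (nrow(kept) == 0L ||
        all(sqrt(rowSums(sweep(kept, 2, p)^2)) >= min_separation)) {
      kept <- rbind(kept, p)
    }
  }
  unname(kept)
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}
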