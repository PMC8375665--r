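#' Batch self-organizing map
#'
#' Minimal, deterministic batch SOM on a rectangular node grid with a
#' Gaussian neighborhood kernel. Each sweep assigns every observation to its
#' best-matching node (minimum Euclidean distance to the codebook vector) and
#' replaces each codebook vector by the kernel-weighted mean of the
#' observations assigned near it; the kernel width shrinks linearly from a
#' third of the grid diagonal to 0.5 node spacings. Initialization draws
#' codebook vectors from the data rows (with replacement when the data are
#' few), seeded, so training is reproducible.
#'
#' @param x numeric matrix (observations x features), already scaled.
#' @param grid_dim c(rows, cols) of the node grid.
#' @param epochs number of batch sweeps.
#' @param seed integer seed for the codebook initialization.
#' @return list with `codebook` (nodes x features), `grid` (nodes x 2 node
#'   coordinates), `bmu` (best-matching node per observation) and the
#'   training parameters.
#' @export
som_fit <- function(x, grid_dim = c(10, 10), epochs = 50, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 1, all(is.finite(x)), epochs >= 1)
  n_nodes <- prod(grid_dim)
  grid <- cbind(rep(seq_len(grid_dim[1]), times = grid_dim[2]),
                rep(seq_len(grid_dim[2]), each = grid_dim[1]))
  gd2 <- as.matrix(stats::dist(grid))^2
  set.seed(seed)
  init <- sample.int(nrow(x), n_nodes, replace = nrow(x) < n_nodes)
  w <- x[init, , drop = FALSE] +
    matrix(stats::rnorm(n_nodes * ncol(x), 0, 1e-6), n_nodes)
  sigma0 <- sqrt(sum(grid_dim^2)) / 3
  xsq <- rowSums(x^2)
  bmu <- integer(nrow(x))
  for (e in seq_len(epochs)) {
    d2 <- outer(xsq, rowSums(w^2), "+") - 2 * x %*% t(w)
    bmu <- max.col(-d2, ties.method = "first")
    sigma <- max(0.5, sigma0 * (1 - (e - 1) / epochs))
    h <- exp(-gd2 / (2 * sigma^2))
    cnt <- tabulate(bmu, n_nodes)
    sums <- matrix(0, n_nodes, ncol(x))
    rs <- rowsum(x, bmu)
    sums[as.integer(rownames(rs)), ] <- rs
    num <- h %*% sums
    den <- as.vector(h %*% cnt)
    upd <- den > 1e-12
    w[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  d2 <- outer(xsq, rowSums(w^2), "+") - 2 * x %*% t(w)
  bmu <- max.col(-d2, ties.method = "first")
  list(codebook = w, grid = grid, bmu = bmu, grid_dim = grid_dim,
       epochs = epochs, seed = seed)
}

som_map <- function(codebook, x) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(x^2), rowSums(codebook^2), "+") -
    2 * x %*% t(codebook)
  max.col(-d2, ties.method = "first")
}
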