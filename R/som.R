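#' Center-scale a feature matrix
#'
#' Each column is shifted to mean 0 and scaled to standard deviation 1;
#' constant columns become all zeros rather than NaN.
#'
#' @param x numeric matrix (rows = regions, columns = features).
#' @return scaled matrix with attributes `center` and `scale`.
#' @export
center_scale <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  out <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

# Hexagonal lattice positions in an offset-coordinate Euclidean
# embedding: odd rows shifted by 0.5, row spacing sqrt(3)/2. Node order
# is row-major.
hex_grid_coords <- function(width, height) {
  row <- rep(seq_len(height), each = width)
  col <- rep(seq_len(width), times = height)
  x <- col + ifelse(row %% 2 == 0, 0.5, 0)
  y <- row * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Train a self-organizing map on a hexagonal grid
#'
#' Online (stochastic) SOM training: per step a sample row is drawn in a
#' seeded per-epoch shuffle, its best-matching unit (BMU) found by
#' Euclidean distance, and all codebook vectors within the current
#' neighborhood radius sigma are moved toward the sample,
#' c <- c + alpha * h * (x - c) with Gaussian h = exp(-d^2 / (2 sigma^2))
#' (h = 1 at the BMU itself). The learning rate decays linearly from
#' `lr[1]` to `lr[2]` and the radius linearly from two thirds of the grid
#' diagonal to 0 over the run. The codebook is initialized by seeded
#' sampling of input rows. Fully deterministic given the seed.
#'
#' @param features numeric matrix, typically from [center_scale()].
#' @param width,height grid dimensions (default 10 x 10).
#' @param epochs passes over the data (default 100).
#' @param lr learning-rate bounds, start and end (default 0.05 -> 0.01),
#'   used by the linear schedule.
#' @param lr_schedule "linear" (default) or "inverse". The inverse
#'   schedule sets alpha = 1/(t + 2) at step t, under which a single-node
#'   (or radius-0) map computes an exact running mean of the presented
#'   samples — the textbook online k-means limit.
#' @param radius starting neighborhood radius; default (2/3) of the grid
#'   diagonal, decaying to 0.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param presentation_order optional list of per-epoch index vectors
#'   overriding the seeded shuffle (used for oracle comparisons).
#' @return list of class `som_model`: `codebook` (nodes x features),
#'   `grid` (node positions), `width`, `height`, `assignments`
#'   (per-row BMU), `quantization_error`, schedule parameters and seed.
#' @export
train_som <- function(features, width = 10, height = 10, epochs = 100,
                      lr = c(0.05, 0.01), lr_schedule = c("linear", "inverse"),
                      radius = NULL, seed, presentation_order = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("train_som: empty input")
  if (!all(is.finite(features))) stop("train_som: non-finite feature values")
  if (missing(seed)) stop("train_som: seed is mandatory")
  n <- nrow(features); d <- ncol(features)
  n_nodes <- width * height
  grid <- hex_grid_coords(width, height)
  gdist2 <- as.matrix(stats::dist(grid))^2
  diag_len <- sqrt((max(grid[, 1]) - min(grid[, 1]))^2 +
                   (max(grid[, 2]) - min(grid[, 2]))^2)
  r0 <- if (is.null(radius)) 2 / 3 * max(diag_len, 1e-9) else radius
  set.seed(seed)
  codebook <- features[sample.int(n, n_nodes, replace = n < n_nodes), , drop = FALSE]
  total_steps <- epochs * n
  step <- 0
  for (epoch in seq_len(epochs)) {
    if (is.null(presentation_order)) {
      set.seed(child_seed(seed, paste0("epoch", epoch)))
      order_idx <- sample.int(n)
    } else {
      order_idx <- presentation_order[[epoch]]
    }
    for (i in order_idx) {
      x <- features[i, ]
      dx <- codebook - matrix(x, n_nodes, d, byrow = TRUE)
      bmu <- which.min(rowSums(dx * dx))
      frac <- step / max(total_steps - 1, 1)
      alpha <- if (lr_schedule == "linear") {
        lr[1] + (lr[2] - lr[1]) * frac
      } else 1 / (step + 2)
      sigma <- r0 * (1 - frac)
      g2 <- gdist2[bmu, ]
      if (sigma > 0) {
        nb <- which(g2 <= sigma^2)
        h <- exp(-g2[nb] / (2 * sigma^2))
        codebook[nb, ] <- codebook[nb, , drop = FALSE] +
          alpha * h * -dx[nb, , drop = FALSE]
      } else {
        codebook[bmu, ] <- codebook[bmu, ] + alpha * -dx[bmu, ]
      }
      step <- step + 1
    }
  }
  model <- structure(list(codebook = codebook, grid = grid,
                          width = width, height = height,
                          epochs = epochs, lr = lr, radius0 = r0,
                          seed = seed),
                     class = "som_model")
  model$assignments <- bmu_assign(model, features)
  dmin <- vapply(seq_len(n), function(i) {
    dx <- codebook[model$assignments[i], ] - features[i, ]
    sum(dx * dx)
  }, 0)
  model$quantization_error <- mean(dmin)
  model
}

#' Best-matching unit for query vectors
#'
#' Argmin of Euclidean distance over the codebook; ties resolve to the
#' lowest node index.
#'
#' @param model a `som_model`.
#' @param x a query vector or matrix of query rows.
#' @return integer node index (vector for matrix input).
#' @export
bmu_assign <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  cb <- model$codebook
  vapply(seq_len(nrow(x)), function(i) {
    dx <- cb - matrix(x[i, ], nrow(cb), ncol(cb), byrow = TRUE)
    which.min(rowSums(dx * dx))
  }, 0L)
}

#' Per-node feature means, ranked by a chosen feature
#'
#' Summarizes member regions of each SOM node by the mean of each
#' feature track, with the node order ranked (descending) by the chosen
#' feature's node average — the ranked-heatmap layout. Empty nodes are
#' reported with count 0 and NA means.
#'
#' @param model a `som_model` with assignments.
#' @param features the feature matrix used for training (or any aligned
#'   per-region tracks).
#' @param rank_by column name to rank nodes by (default first column).
#' @return data.frame: node, count, one mean column per feature, ordered
#'   by decreasing `rank_by` mean.
#' @export
node_summaries <- function(model, features, rank_by = colnames(features)[1]) {
  features <- as.matrix(features)
  n_nodes <- nrow(model$codebook)
  assign <- model$assignments
  out <- do.call(rbind, lapply(seq_len(n_nodes), function(k) {
    rows <- which(assign == k)
    means <- if (length(rows)) colMeans(features[rows, , drop = FALSE])
             else rep(NA_real_, ncol(features))
    df <- data.frame(node = k, count = length(rows))
    for (j in seq_len(ncol(features))) df[[colnames(features)[j]]] <- means[j]
    df
  }))
  out[order(-ifelse(is.na(out[[rank_by]]), -Inf, out[[rank_by]])), ]
}
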