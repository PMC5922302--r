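# Batch-trained self-organising maps on a hexagonal grid, with masked
# distances for missing entries. Batch (not online) training makes the
# result independent of sample order and exactly reproducible from the
# seed and parameters.

#' Hexagonal SOM grid
#'
#' Neurons are laid out row-major on a pointy-top hexagonal offset grid:
#' odd rows sit at integer x positions, even rows are shifted right by 0.5,
#' and rows are sqrt(3)/2 apart, so every nearest-neighbour pair is at
#' planar distance exactly 1.
#'
#' @param rows,cols positive integers.
#' @return An object of class `som_grid`: `rows`, `cols`, `n_units`,
#'   `pos` (n_units x 2 planar coordinates), `topology = "hexagonal"`.
#' @export
som_grid <- function(rows, cols) {
  stopifnot(rows >= 1L, cols >= 1L)
  rows <- as.integer(rows); cols <- as.integer(cols)
  idx <- seq_len(rows * cols) - 1L
  r <- idx %/% cols
  c <- idx %% cols
  pos <- cbind(x = c + 0.5 * (r %% 2L), y = r * sqrt(3) / 2)
  structure(list(rows = rows, cols = cols, n_units = rows * cols,
                 pos = pos, topology = "hexagonal"),
            class = "som_grid")
}

#' Pairwise planar distances between grid neurons
#' @param grid a [som_grid()].
#' @return n_units x n_units matrix of Euclidean distances on the hex
#'   layout (nearest neighbours at distance 1).
#' @export
grid_distances <- function(grid) {
  as.matrix(stats::dist(grid$pos))
}

#' SOM training parameters
#'
#' @param grid `NULL` for automatic sizing (about `5 * sqrt(n)` neurons
#'   with the aspect ratio set from the two leading data-covariance
#'   eigenvalues), or integer `c(rows, cols)`.
#' @param epochs number of batch epochs (>= 1).
#' @param radius_init initial Gaussian neighbourhood radius in grid units;
#'   `NULL` selects a third of the grid diameter (at least 1).
#' @param radius_final final radius; the radius shrinks linearly between
#'   the two across epochs. A radius of 0 degenerates to a hard
#'   (k-means-style) assignment update.
#' @param init `"pca"` for principal-plane initialization (deterministic,
#'   data-driven) or `"random"` (uniform within per-column data ranges,
#'   governed by `seed`).
#' @param seed integer RNG seed.
#' @return An object of class `som_params`.
#' @export
som_params <- function(grid = NULL, epochs = 30L, radius_init = NULL,
                       radius_final = 0.5, init = c("pca", "random"),
                       seed = 1L) {
  init <- match.arg(init)
  stopifnot(epochs >= 1L, radius_final >= 0)
  if (!is.null(radius_init)) {
    stopifnot(radius_init > 0, radius_init >= radius_final)
  }
  if (!is.null(grid)) stopifnot(length(grid) == 2L, all(grid >= 1))
  structure(list(grid = grid, epochs = as.integer(epochs),
                 radius_init = radius_init, radius_final = radius_final,
                 init = init, seed = as.integer(seed)),
            class = "som_params")
}

auto_grid_size <- function(X) {
  n <- nrow(X)
  n_units <- max(2, ceiling(5 * sqrt(n)))
  # aspect from the two leading covariance eigenvalues (sqrt ratio, capped)
  Xi <- apply(X, 2L, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (anyNA(x)) x[] <- 0.5
    x
  })
  ratio <- 1
  if (ncol(Xi) >= 2L && nrow(Xi) >= 3L) {
    ev <- eigen(stats::cov(Xi), symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-12]
    if (length(ev) >= 2L) ratio <- min(4, max(1, sqrt(ev[1L] / ev[2L])))
  }
  rows <- max(1L, round(sqrt(n_units * ratio)))
  cols <- max(1L, ceiling(n_units / rows))
  c(rows, cols)
}

# masked squared distances between samples (rows of X, NA allowed) and
# codebook rows; sum of squared differences over observed dimensions only
masked_dist2 <- function(X, obs, codebook) {
  X0 <- X
  X0[!obs] <- 0
  a <- rowSums(X0^2)
  cross <- X0 %*% t(codebook)
  b <- (obs * 1) %*% t(codebook^2)
  d2 <- a - 2 * cross + b
  d2[d2 < 0] <- 0
  d2
}

init_codebook <- function(X, obs, grid, init) {
  d <- ncol(X)
  Xi <- X
  for (j in seq_len(d)) {
    cm <- mean(X[obs[, j], j])
    if (!is.finite(cm)) cm <- 0.5
    Xi[!obs[, j], j] <- cm
  }
  if (init == "random" || d < 2L || nrow(X) < 3L) {
    lo <- apply(Xi, 2L, min)
    hi <- apply(Xi, 2L, max)
    cb <- matrix(stats::runif(grid$n_units * d), ncol = d)
    return(sweep(sweep(cb, 2L, hi - lo, `*`), 2L, lo, `+`))
  }
  # principal plane: span the grid along the two leading eigenvectors
  ctr <- colMeans(Xi)
  cv <- stats::cov(Xi)
  eg <- eigen(cv, symmetric = TRUE)
  u1 <- eg$vectors[, 1L]; u2 <- eg$vectors[, 2L]
  # deterministic sign convention
  if (u1[which.max(abs(u1))] < 0) u1 <- -u1
  if (u2[which.max(abs(u2))] < 0) u2 <- -u2
  s1 <- sqrt(max(eg$values[1L], 0)); s2 <- sqrt(max(eg$values[2L], 0))
  ax <- if (grid$cols > 1L) {
    2 * (grid$pos[, 1L] - min(grid$pos[, 1L])) /
      (max(grid$pos[, 1L]) - min(grid$pos[, 1L])) - 1
  } else rep(0, grid$n_units)
  ay <- if (grid$rows > 1L) {
    2 * (grid$pos[, 2L] - min(grid$pos[, 2L])) /
      (max(grid$pos[, 2L]) - min(grid$pos[, 2L])) - 1
  } else rep(0, grid$n_units)
  cb <- matrix(rep(ctr, each = grid$n_units), ncol = d)
  cb + outer(ax, 2 * s1 * u1) + outer(ay, 2 * s2 * u2)
}

#' Train a self-organising map on one MMS dataset
#'
#' Batch Kohonen training: every epoch assigns each area to its best
#' matching unit (BMU) under the masked Euclidean distance (missing
#' entries and degenerate indicators are excluded from distance terms),
#' then replaces each codebook vector by the neighbourhood-weighted mean
#' of the data, with a Gaussian neighbourhood whose radius shrinks
#' linearly from `radius_init` to `radius_final`. Missing entries are also
#' excluded from the update, never imputed.
#'
#' @param table an [mms_table()] in original units, or the list returned
#'   by [normalize_mms()]; raw tables are normalized internally.
#' @param params a [som_params()].
#' @return An object of class `trained_som`: `grid`, `codebook`
#'   (n_units x indicators, normalized scale), `scaler`, `assignments`
#'   (named neuron index per area), `quality` (`quantization_error`,
#'   `topographic_error`), `meta` (dataset, parameters, seed,
#'   initial QE).
#' @export
train_som <- function(table, params = som_params()) {
  if (inherits(table, "mms_table")) {
    norm <- if (isTRUE(table$normalized)) {
      stop("pass the list returned by normalize_mms(), or a raw table")
    } else normalize_mms(table)
  } else if (is.list(table) && inherits(table$table, "mms_table") &&
             inherits(table$scaler, "mms_scaler")) {
    norm <- table
  } else {
    stop("table must be an mms_table or the result of normalize_mms()")
  }
  stopifnot(inherits(params, "som_params"))
  X <- norm$table$values
  if (nrow(X) < 2L) stop("need at least 2 areas to train a SOM")
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0L)) {
    stop("all-missing row(s): ",
         paste(rownames(X)[rowSums(obs) == 0L], collapse = ", "))
  }
  # degenerate indicators carry no distance information
  dist_obs <- obs
  dist_obs[, norm$scaler$degenerate] <- FALSE

  gsize <- if (is.null(params$grid)) auto_grid_size(X) else params$grid
  grid <- som_grid(gsize[1L], gsize[2L])
  if (grid$n_units > 10L * nrow(X)) {
    warning("grid has more than 10x as many neurons as areas")
  }
  set.seed(params$seed)
  codebook <- init_codebook(X, obs, grid, params$init)
  colnames(codebook) <- colnames(X)

  D2g <- grid_distances(grid)^2
  r0 <- params$radius_init
  if (is.null(r0)) r0 <- max(1, max(sqrt(D2g)) / 3)
  rf <- params$radius_final
  X0 <- X; X0[!obs] <- 0
  obs_num <- obs * 1

  qe_initial <- mean(sqrt(pmax(
    apply(masked_dist2(X, dist_obs, codebook), 1L, min), 0)))

  for (t in seq_len(params$epochs)) {
    sigma <- if (params$epochs == 1L) rf else {
      r0 + (t - 1) / (params$epochs - 1) * (rf - r0)
    }
    d2 <- masked_dist2(X, dist_obs, codebook)
    bmus <- max.col(-d2, ties.method = "first")
    H <- if (sigma <= 0) (D2g[bmus, , drop = FALSE] == 0) * 1 else {
      exp(-D2g[bmus, , drop = FALSE] / (2 * sigma^2))
    }
    num <- t(H) %*% X0
    den <- t(H) %*% obs_num
    upd <- den > 0
    codebook[upd] <- num[upd] / den[upd]
  }

  d2 <- masked_dist2(X, dist_obs, codebook)
  bmus <- max.col(-d2, ties.method = "first")
  assignments <- stats::setNames(bmus, rownames(X))
  som <- structure(
    list(grid = grid, codebook = codebook, scaler = norm$scaler,
         assignments = assignments, quality = NULL,
         meta = list(dataset = norm$table$dataset,
                     areas = norm$table$areas,
                     epochs = params$epochs, radius_init = r0,
                     radius_final = rf, init = params$init,
                     seed = params$seed, qe_initial = qe_initial)),
    class = "trained_som"
  )
  som$quality <- quality_metrics(som, norm$table)
  som
}

#' @export
print.trained_som <- function(x, ...) {
  cat(sprintf(
    "Trained %s-SOM: %dx%d hexagonal grid, %d areas, QE %.4f, TE %.4f\n",
    x$meta$dataset, x$grid$rows, x$grid$cols, length(x$assignments),
    x$quality$quantization_error, x$quality$topographic_error))
  invisible(x)
}

#' Best matching unit for a normalized indicator vector
#'
#' @param som a [train_som()] result.
#' @param vector numeric vector on the normalized scale, one entry per
#'   indicator of the SOM's dataset; `NA` entries are excluded from the
#'   distance (masked distance).
#' @return The neuron index minimizing the masked Euclidean distance;
#'   ties break to the lowest index.
#' @export
bmu <- function(som, vector) {
  stopifnot(inherits(som, "trained_som"))
  if (length(vector) != ncol(som$codebook)) {
    stop("vector length ", length(vector), " != ", ncol(som$codebook),
         " indicators")
  }
  obs <- !is.na(vector) & !som$scaler$degenerate
  if (!any(obs)) stop("vector has no usable (non-missing) entries")
  d2 <- masked_dist2(matrix(vector, nrow = 1L),
                     matrix(obs, nrow = 1L), som$codebook)
  which.min(d2[1L, ])
}

#' Quantization and topographic error of a trained SOM
#'
#' Quantization error is the mean masked distance from each area to its
#' BMU; topographic error is the fraction of areas whose first and second
#' BMUs are not grid neighbours (planar distance 1 on the hex layout).
#'
#' @param som a [train_som()] result.
#' @param table the normalized `mms_table` the SOM was trained on
#'   (defaults to reconstructing assignments from the stored codebook is
#'   not possible, so the table must be supplied).
#' @return List with `quantization_error` and `topographic_error`.
#' @export
quality_metrics <- function(som, table) {
  stopifnot(inherits(som, "trained_som"), inherits(table, "mms_table"))
  X <- table$values
  obs <- !is.na(X)
  obs[, som$scaler$degenerate] <- FALSE
  d2 <- masked_dist2(X, obs, som$codebook)
  qe <- mean(sqrt(pmax(apply(d2, 1L, min), 0)))
  if (ncol(d2) < 2L) {
    te <- 0
  } else {
    Dg <- grid_distances(som$grid)
    te <- mean(vapply(seq_len(nrow(d2)), function(i) {
      ord <- order(d2[i, ])[1:2]
      Dg[ord[1L], ord[2L]] > 1.0001
    }, logical(1L)))
  }
  list(quantization_error = qe, topographic_error = te)
}

#' Component plane of one indicator
#'
#' The denormalized codebook column: the indicator's value, in original
#' units, carried by each neuron, ordered by neuron index. All component
#' planes of one SOM share the same neuron layout.
#'
#' @param som a [train_som()] result.
#' @param code indicator code present in the SOM's dataset.
#' @return Numeric vector, one value per neuron, original units.
#' @export
component_plane <- function(som, code) {
  stopifnot(inherits(som, "trained_som"))
  if (!code %in% colnames(som$codebook)) {
    stop("indicator ", code, " not in this SOM (", som$meta$dataset, ")")
  }
  unname(denormalize_mms(som$codebook[, code], som$scaler,
                         codes = rep(code, nrow(som$codebook))))
}

#' Unit clusters: neurons shared by two or more areas
#'
#' A neuron onto which more than one area maps marks a unit cluster of
#' closely similar areas.
#'
#' @param som a [train_som()] result.
#' @return Named list, neuron index (as name) -> character vector of area
#'   labels; only neurons with at least two areas are listed.
#' @export
unit_clusters <- function(som) {
  stopifnot(inherits(som, "trained_som"))
  sp <- split(names(som$assignments), som$assignments)
  sp[vapply(sp, length, 0L) >= 2L]
}

#' Persist a trained SOM as JSON
#'
#' The JSON carries the grid, codebook, scaler, assignments, quality
#' metrics and training metadata; writing is deterministic (full-precision
#' numbers, fixed key order), so identical SOMs yield byte-identical
#' files.
#'
#' @param som a [train_som()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_som <- function(som, path) {
  stopifnot(inherits(som, "trained_som"))
  obj <- list(
    dataset = som$meta$dataset,
    grid = list(rows = som$grid$rows, cols = som$grid$cols,
                topology = som$grid$topology),
    codes = colnames(som$codebook),
    codebook = unname(som$codebook),
    scaler = list(code = som$scaler$code, min = som$scaler$min,
                  max = som$scaler$max, degenerate = som$scaler$degenerate,
                  constant = som$scaler$constant, method = som$scaler$method),
    assignments = as.list(som$assignments),
    areas = som$meta$areas,
    quality = som$quality,
    training = list(epochs = som$meta$epochs,
                    radius_init = som$meta$radius_init,
                    radius_final = som$meta$radius_final,
                    init = som$meta$init, seed = som$meta$seed,
                    qe_initial = som$meta$qe_initial)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a trained SOM from JSON written by [write_som()]
#' @param path path to the JSON file.
#' @return A `trained_som` object.
#' @export
read_som <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- som_grid(obj$grid$rows, obj$grid$cols)
  codebook <- matrix(unlist(obj$codebook), nrow = grid$n_units, byrow = FALSE)
  if (is.matrix(obj$codebook)) codebook <- obj$codebook
  colnames(codebook) <- obj$codes
  scaler <- structure(
    list(code = obj$scaler$code, min = obj$scaler$min, max = obj$scaler$max,
         degenerate = obj$scaler$degenerate,
         constant = as.numeric(obj$scaler$constant),
         method = obj$scaler$method),
    class = "mms_scaler")
  structure(
    list(grid = grid, codebook = codebook, scaler = scaler,
         assignments = unlist(obj$assignments),
         quality = obj$quality,
         meta = list(dataset = obj$dataset, areas = as.data.frame(obj$areas),
                     epochs = obj$training$epochs,
                     radius_init = obj$training$radius_init,
                     radius_final = obj$training$radius_final,
                     init = obj$training$init, seed = obj$training$seed,
                     qe_initial = obj$training$qe_initial)),
    class = "trained_som")
}
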