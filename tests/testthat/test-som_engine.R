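test_that("hex grid has uniform unit nearest-neighbour distances", {
  for (dims in list(c(3, 4), c(5, 5), c(1, 6), c(4, 1))) {
    g <- som_grid(dims[1L], dims[2L])
    expect_equal(g$n_units, dims[1L] * dims[2L])
    D <- grid_distances(g)
    nn <- apply(D + diag(Inf, g$n_units), 1L, min)
    expect_equal(unname(nn), rep(1, g$n_units), tolerance = 1e-12)
  }
})

test_that("identical areas collapse to a degenerate fixed point", {
  v <- matrix(rep(c(3, 6, 9, 2, 5, 8), each = 6), nrow = 6)
  tab <- make_use_table(v)
  som <- train_som(normalize_mms(tab), som_params(grid = c(2, 2), epochs = 10))
  # every indicator is constant -> degenerate -> codebook pinned at 0.5
  expect_equal(unname(som$codebook),
               matrix(0.5, 4, 6), tolerance = 1e-12)
  expect_equal(som$quality$quantization_error, 0)
  expect_equal(som$quality$topographic_error, 0)
  plane <- component_plane(som, "U1")
  expect_equal(plane, rep(3, 4))  # constant plane, original units
})

test_that("vanishing neighbourhood reaches the k-means fixed point", {
  set.seed(99)
  v <- abs(rbind(matrix(rnorm(60, 2, 0.1), ncol = 6),
                 matrix(rnorm(60, 8, 0.1), ncol = 6)))
  nm <- normalize_mms(make_use_table(v))
  som <- train_som(nm, som_params(grid = c(1, 2), epochs = 40,
                                  radius_init = 1, radius_final = 0,
                                  seed = 1))
  # independent oracle: k-means from the converged centers must not move
  km <- suppressWarnings(stats::kmeans(nm$table$values,
                                       centers = som$codebook,
                                       iter.max = 50))
  expect_equal(unname(som$codebook), unname(km$centers), tolerance = 1e-6)
  # and the codebook rows equal the two cluster means
  cl <- som$assignments
  for (j in unique(cl)) {
    expect_equal(unname(som$codebook[j, ]),
                 unname(colMeans(nm$table$values[cl == j, , drop = FALSE])),
                 tolerance = 1e-6)
  }
})

test_that("training is bitwise reproducible from seed and parameters", {
  sys <- generate_system(paper_like_config(seed = 6))
  nm <- normalize_mms(sys$tables$AVA)
  p <- som_params(epochs = 15, seed = 21, init = "random")
  s1 <- train_som(nm, p); s2 <- train_som(nm, p)
  expect_identical(s1$codebook, s2$codebook)
  expect_identical(s1$assignments, s2$assignments)
  s3 <- train_som(nm, som_params(epochs = 15, seed = 22, init = "random"))
  expect_false(identical(s1$codebook, s3$codebook))
})

test_that("bmu matches exhaustive search and breaks ties to lowest index", {
  sys <- generate_system(paper_like_config(seed = 8))
  nm <- normalize_mms(sys$tables$USE)
  som <- train_som(nm, som_params(grid = c(3, 4), epochs = 10, seed = 2))
  # exact codebook rows map to themselves
  for (k in c(1L, 5L, 12L)) {
    expect_equal(bmu(som, som$codebook[k, ]), k)
  }
  # random vectors (with missing entries) against the brute-force oracle
  set.seed(123)
  for (i in 1:50) {
    v <- runif(6)
    if (i %% 3L == 0L) v[sample(6, 2)] <- NA
    expect_equal(bmu(som, v), brute_bmu(som$codebook, v))
  }
  # a deliberate tie between neurons 2 and 7 resolves to 2
  som2 <- som
  som2$codebook[7L, ] <- som2$codebook[2L, ]
  expect_equal(bmu(som2, som2$codebook[7L, ]), 2L)
  expect_error(bmu(som, rep(NA_real_, 6)), "no usable")
})

test_that("quality metrics match hand arithmetic on a 3-area toy", {
  v <- cbind(U1 = c(0, 4, 8), U2 = c(0, 4, 8), U3 = c(1, 2, 3),
             U4 = c(1, 2, 3), U5 = c(1, 2, 3), U6 = c(1, 2, 3))
  nm <- normalize_mms(make_use_table(v))
  som <- train_som(nm, som_params(grid = c(1, 3), epochs = 30,
                                  radius_init = 1, radius_final = 0))
  X <- nm$table$values
  d <- vapply(seq_len(3), function(i) {
    sqrt(sum((X[i, ] - som$codebook[som$assignments[i], ])^2))
  }, 0)
  expect_equal(som$quality$quantization_error, mean(d), tolerance = 1e-12)
  expect_gte(som$quality$topographic_error, 0)
  expect_lte(som$quality$topographic_error, 1)
})

test_that("training does not increase quantization error over initialization", {
  for (s in 1:3) {
    sys <- generate_system(paper_like_config(seed = s))
    for (ds in c("AVA", "USE")) {
      som <- train_som(normalize_mms(sys$tables[[ds]]),
                       som_params(epochs = 20, seed = s))
      expect_lte(som$quality$quantization_error, som$meta$qe_initial)
    }
  }
})

test_that("masked distance reduces to Euclidean distance when complete", {
  set.seed(5)
  X <- matrix(runif(40), nrow = 5)
  C <- matrix(runif(64), nrow = 8)
  obs <- matrix(TRUE, 5, 8)
  d2 <- somnet:::masked_dist2(X, obs, C)
  ref <- as.matrix(dist(rbind(X, C)))[1:5, 6:13]^2
  expect_equal(unname(d2), unname(ref), tolerance = 1e-12)
})

test_that("missing entries are excluded from training, not imputed", {
  v <- cbind(U1 = c(1, 2, 3, 4), U2 = c(4, 3, 2, 1), U3 = c(1, 1, 2, 2),
             U4 = c(2, 2, 1, 1), U5 = c(1, 2, 1, 2), U6 = c(5, 6, 7, 8))
  v[2L, "U1"] <- NA
  nm <- normalize_mms(make_use_table(v))
  expect_no_error(som <- train_som(nm, som_params(grid = c(2, 2),
                                                  epochs = 10)))
  expect_true(all(is.finite(som$codebook)))
  expect_length(som$assignments, 4L)
})

test_that("unit clusters list exactly the neurons with two or more areas", {
  sys <- generate_system(paper_like_config(seed = 13))
  som <- train_som(normalize_mms(sys$tables$AVA),
                   som_params(epochs = 20, seed = 3))
  cl <- unit_clusters(som)
  expect_true(all(vapply(cl, length, 0L) >= 2L))
  # areas appear in exactly one cluster or none
  all_labs <- unlist(cl)
  expect_false(anyDuplicated(all_labs) > 0)
  for (n in names(cl)) {
    expect_setequal(cl[[n]],
                    names(som$assignments)[som$assignments == as.integer(n)])
  }
  # hand-built assignment map
  som2 <- som
  som2$assignments <- c(a1 = 3L, a2 = 3L, a3 = 5L)
  expect_equal(unit_clusters(som2), list(`3` = c("a1", "a2")))
  som2$assignments <- c(a1 = 1L, a2 = 2L, a3 = 3L)
  expect_length(unit_clusters(som2), 0L)
})

test_that("SOM JSON persistence round-trips and is byte-stable", {
  sys <- generate_system(paper_like_config(seed = 17))
  som <- train_som(normalize_mms(sys$tables$USE),
                   som_params(epochs = 10, seed = 5))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "som1.json"); f2 <- file.path(d, "som2.json")
  write_som(som, f1); write_som(som, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_som(f1)
  expect_equal(back$codebook, som$codebook)
  expect_equal(back$assignments, som$assignments)
  expect_equal(back$scaler$min, som$scaler$min)
  expect_equal(bmu(back, som$codebook[3L, ]), 3L)
})
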