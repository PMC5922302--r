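# small paired SOMs for network tests
paired_soms <- function(n = 12, seed = 1, grid_in = c(2, 2),
                        grid_out = c(2, 2), epochs = 15) {
  sys <- make_mini_system(n = n, seed = seed)
  list(
    wof = train_som(normalize_mms(sys$WOF),
                    som_params(grid = grid_in, epochs = epochs, seed = seed)),
    use = train_som(normalize_mms(sys$USE),
                    som_params(grid = grid_out, epochs = epochs, seed = seed))
  )
}

test_that("association with a vanishing kernel is hard BMU co-occurrence", {
  ps <- paired_soms(n = 5, seed = 3)
  # single area: exactly one 1 at (BMU_in, BMU_out)
  one_in <- ps$wof; one_out <- ps$use
  one_in$assignments <- one_in$assignments[1L]
  one_out$assignments <- one_out$assignments[1L]
  net <- build_association(one_in, one_out, radius = 0)
  expect_equal(sum(net$M), 1)
  expect_equal(net$M[one_in$assignments, one_out$assignments], 1)
  # duplicating an area leaves the normalized matrix unchanged
  dup_in <- ps$wof; dup_out <- ps$use
  dup_in$assignments <- rep(one_in$assignments, 2L)
  names(dup_in$assignments) <- c("a", "a2")
  dup_out$assignments <- rep(one_out$assignments, 2L)
  names(dup_out$assignments) <- c("a", "a2")
  net2 <- build_association(dup_in, dup_out, radius = 0)
  expect_equal(net2$M, net$M)
})

test_that("association matches the brute-force double loop", {
  for (seed in 1:3) {
    ps <- paired_soms(n = 7, seed = seed, grid_in = c(2, 2),
                      grid_out = c(3, 2))
    for (radius in c(0, 0.7, 1)) {
      net <- build_association(ps$wof, ps$use, radius = radius)
      expect_equal(net$M, brute_association(ps$wof, ps$use, radius),
                   tolerance = 1e-9)
    }
  }
  # supported rows are row-stochastic, others all-zero
  ps <- paired_soms(n = 6, seed = 5, grid_in = c(4, 4), grid_out = c(2, 2))
  net <- build_association(ps$wof, ps$use, radius = 0.5)
  rs <- rowSums(net$M)
  expect_equal(unname(rs[net$support]),
               rep(1, sum(net$support)), tolerance = 1e-9)
  expect_true(all(rs[!net$support] == 0))
  expect_true(all(net$M >= 0))
  expect_error(build_association(ps$wof, ps$wof, radius = -1))
})

test_that("mismatched area sets are rejected", {
  ps <- paired_soms(n = 6, seed = 2)
  bad <- ps$use
  names(bad$assignments)[1L] <- "ZZ"
  expect_error(build_association(ps$wof, bad), "same area set")
})

test_that("activation is a max-normalized product of Gaussian kernels", {
  ps <- paired_soms(n = 8, seed = 4, grid_in = c(1, 3))
  som <- ps$wof
  # constraint equal to a neuron's codebook value peaks there at 1
  code <- "W1"
  rng <- scaler_range(som$scaler, code)
  x <- as.numeric(rng[1L] + som$codebook[2L, code] * diff(rng))
  act <- activation(som, setNames(x, code), sigma = 0.1)
  expect_equal(act[2L], 1)
  expect_true(all(act <= 1 & act >= 0))
  # hand-built 3-neuron toy: codebook values {0, 0.5, 1}, constraint 0
  toy <- som
  toy$codebook[, code] <- c(0, 0.5, 1)
  toy$scaler$min[toy$scaler$code == code] <- 0
  toy$scaler$max[toy$scaler$code == code] <- 1
  act0 <- activation(toy, setNames(0, code), sigma = 0.5)
  expect_equal(unname(act0), c(1, exp(-0.5), exp(-2)), tolerance = 1e-12)
  # two constraints multiply before renormalization
  c2 <- c(W1 = x, W2 = rng[1L])
  a_joint <- activation(som, c2, sigma = 0.2)
  a1 <- activation(som, c2[1L], sigma = 0.2)
  a2 <- activation(som, c2[2L], sigma = 0.2)
  prod12 <- a1 * a2
  expect_equal(a_joint, prod12 / max(prod12), tolerance = 1e-12)
  expect_error(activation(som, numeric(0)), "constraint")
  expect_error(activation(som, c(U9 = 1)), "U9")
})

test_that("propagation is the max-normalized matrix product", {
  ps <- paired_soms(n = 10, seed = 6, grid_in = c(2, 2), grid_out = c(2, 3))
  net <- build_association(ps$wof, ps$use, radius = 1)
  set.seed(8)
  act <- runif(4)
  f <- propagate(net, act, "input-driven")
  ref <- as.numeric(act %*% net$M)
  expect_equal(f$weights, ref / max(ref), tolerance = 1e-12)
  # identity association leaves activations unchanged
  idnet <- net
  idnet$M <- diag(4); idnet$support <- rep(TRUE, 4)
  fid <- propagate(idnet, act, "input-driven")
  expect_equal(fid$weights, act / max(act), tolerance = 1e-12)
  # activation concentrated on row j picks out M[j, ]
  e3 <- c(0, 0, 1, 0)
  f3 <- propagate(net, e3, "input-driven")
  expect_equal(f3$weights, net$M[3L, ] / max(net$M[3L, ]), tolerance = 1e-12)
  # output-driven propagation equals input-driven on the transpose
  act6 <- runif(6)
  fo <- propagate(net, act6, "output-driven")
  tnet <- net
  tnet$M <- t(net$M)
  ft <- propagate(tnet, act6, "input-driven")
  expect_equal(fo$weights, ft$weights, tolerance = 1e-12)
  expect_true(all(f$weights >= 0))
})

test_that("region selection keeps the quantile top with ties, never empty", {
  ps <- paired_soms(n = 10, seed = 7, grid_in = c(2, 2), grid_out = c(2, 5))
  net <- build_association(ps$wof, ps$use, radius = 1)
  f <- propagate(net, runif(4), "input-driven")
  f$weights <- seq(0.1, 1.0, by = 0.1)
  sel <- select_region(f, q = 0.8)
  # the 0.8 quantile of 0.1..1.0 is 0.82: the top two neurons
  expect_equal(sel$mask, c(9L, 10L))
  f$weights <- rep(0.4, 10)
  expect_equal(select_region(f, q = 0.8)$mask, 1:10)
  f$weights <- seq(0.1, 1.0, by = 0.1)
  expect_equal(select_region(f, q = 1e-9)$mask, 1:10)
})

test_that("estimates are weight-averaged plane values with categories", {
  ps <- paired_soms(n = 12, seed = 9, grid_out = c(2, 2))
  net <- build_association(ps$wof, ps$use, radius = 1)
  f <- propagate(net, c(1, 0, 0, 0), "input-driven")
  # hand-set two-neuron region with weights 1 and 3 over values 2 and 6
  f$weights <- c(1, 3, 0.1, 0.1)
  f$mask <- c(1L, 2L)
  som <- ps$use
  plane <- component_plane(som, "U1")
  est <- estimate_indicators(som, f, "U1")
  expect_equal(est$value, (1 * plane[1L] + 3 * plane[2L]) / 4)
  expect_equal(est$region_size, 2L)
  rng <- scaler_range(som$scaler, "U1")
  expect_equal(est$category,
               categorize(est$value, make_scale(rng[1L], rng[2L])))
  # single-neuron region returns that neuron's plane value
  f$mask <- 3L
  expect_equal(estimate_indicators(som, f, "U1")$value, plane[3L])
  # uniform weights give the arithmetic mean
  f$weights <- rep(1, 4); f$mask <- 1:4
  expect_equal(estimate_indicators(som, f, "U1")$value, mean(plane))
  f$mask <- integer(0)
  expect_error(estimate_indicators(som, f, "U1"), "region")
})

test_that("input-driven estimates recover a planted proportional dependency", {
  # zero noise, outputs depend monotonically on the inputs
  cfg <- synth_config(seed = 15, noise_sd = 0)
  sys <- generate_system(cfg)
  soms <- lapply(sys$tables, function(t) {
    train_som(normalize_mms(t), som_params(epochs = 25, seed = 15))
  })
  nets <- lapply(soms[c("AVA", "PLA", "WOF")], build_association,
                 output_som = soms$USE, radius = 1)
  rng <- scaler_range(soms$WOF$scaler, "W1")
  probes <- seq(rng[1L] + 0.2 * diff(rng), rng[2L] - 0.2 * diff(rng),
                length.out = 5)
  est <- vapply(probes, function(x) {
    run_query(nets, soms,
              conditional_query("input-driven", c(W1 = x)))$estimates$value
  }, numeric(6))
  for (k in 1:6) {
    expect_gte(cor(est[k, ], probes, method = "spearman"), 0.8)
  }
})

test_that("queries validate their constraint datasets", {
  ps <- paired_soms(n = 8, seed = 10)
  nets <- list(WOF = build_association(ps$wof, ps$use, radius = 1))
  soms <- list(WOF = ps$wof, USE = ps$use)
  expect_error(
    run_query(nets, soms, conditional_query("input-driven", c(A1 = 1))),
    "no network")
  expect_error(
    run_query(nets, soms, conditional_query("output-driven", c(U1 = 1))),
    "report")
  expect_error(
    run_query(nets, soms, conditional_query("output-driven", c(W1 = 1),
                                            report = "W1")),
    "must all be")
})
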