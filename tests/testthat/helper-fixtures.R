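# Shared fixtures: all built in code at test time.

# Published acute-care table of (value, observed range, category label)
# combinations: expert-provided ideals, expert input values, and
# model-estimated values with their printed category labels.
table2_triples <- function() {
  rng <- list(
    U1 = c(0.41, 5.88), U2 = c(11.89, 34.23), U3 = c(0.00, 36.88),
    A1 = c(0.16, 0.89), P1 = c(7.13, 26.68), W1 = c(0.16, 5.23),
    W2 = c(0.33, 10.55), W3 = c(1.84, 24.40)
  )
  tr <- rbind(
    # expert ideals for the three acute-care outputs
    c("U1", 2.50, "low-medium"), c("U2", 19.00, "low-medium"),
    c("U3", 10.00, "low-medium"),
    # expert-provided input values
    c("A1", 0.35, "low-medium"), c("P1", 12.50, "low-medium"),
    c("W1", 3.00, "medium"), c("W2", 5.50, "medium"),
    c("W3", 14.00, "medium"),
    # estimated outputs conditional on A1
    c("U1", 2.59, "low-medium"), c("U2", 17.74, "low-medium"),
    c("U3", 10.75, "low-medium"),
    # conditional on P1
    c("U1", 2.46, "low-medium"), c("U2", 18.75, "low-medium"),
    c("U3", 10.79, "low-medium"),
    # conditional on W1 = 3.00
    c("U1", 2.75, "medium"), c("U2", 24.00, "medium"),
    c("U3", 8.39, "low-medium"),
    # output-driven estimate of W1
    c("W1", 1.94, "low-medium"),
    # conditional on the new W1 = 1.94
    c("U1", 2.42, "low-medium"), c("U2", 19.30, "low-medium"),
    c("U3", 10.93, "low-medium"),
    # conditional on W2
    c("U1", 2.44, "low-medium"), c("U2", 19.63, "low-medium"),
    c("U3", 10.67, "low-medium"),
    # conditional on W3
    c("U1", 2.44, "low-medium"), c("U2", 19.63, "low-medium"),
    c("U3", 10.67, "low-medium")
  )
  data.frame(
    code = tr[, 1L],
    value = as.numeric(tr[, 2L]),
    label = tr[, 3L],
    min = vapply(tr[, 1L], function(cc) rng[[cc]][1L], 0),
    max = vapply(tr[, 1L], function(cc) rng[[cc]][2L], 0)
  )
}

# small USE-dataset table from an explicit value matrix
make_use_table <- function(values, region = "Catalonia") {
  tax <- mms_taxonomy()
  ind <- tax[tax$dataset == "USE", ]
  values <- as.matrix(values)
  stopifnot(ncol(values) == 6L)
  areas <- data.frame(label = paste0("C", seq_len(nrow(values))),
                      region = region)
  mms_table("USE", areas, values, ind)
}

# aligned four-dataset toy system with n areas of positive values
make_mini_system <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  tax <- mms_taxonomy()
  areas <- data.frame(label = paste0("C", seq_len(n)), region = "Catalonia")
  lapply(stats::setNames(unique(tax$dataset), unique(tax$dataset)),
         function(ds) {
    ind <- tax[tax$dataset == ds, ]
    v <- matrix(stats::rlnorm(n * nrow(ind), 1, 0.4), nrow = n)
    mms_table(ds, areas, v, ind)
  })
}

# brute-force masked BMU search, independent of the package's linear
# algebra path
brute_bmu <- function(codebook, vector) {
  best <- Inf; arg <- NA_integer_
  for (j in seq_len(nrow(codebook))) {
    d <- 0
    for (k in seq_along(vector)) {
      if (!is.na(vector[k])) d <- d + (vector[k] - codebook[j, k])^2
    }
    if (d < best - 1e-15) { best <- d; arg <- j }
  }
  arg
}

# brute-force association matrix: explicit double loop over neuron pairs
brute_association <- function(input_som, output_som, radius) {
  gin <- grid_distances(input_som$grid)
  gout <- grid_distances(output_som$grid)
  h <- function(D) if (radius <= 0) (D == 0) * 1 else exp(-D^2 / (2 * radius^2))
  M <- matrix(0, nrow(gin), nrow(gout))
  for (a in seq_along(input_som$assignments)) {
    bi <- input_som$assignments[a]
    bo <- output_som$assignments[a]
    for (j in seq_len(nrow(gin))) {
      for (k in seq_len(nrow(gout))) {
        M[j, k] <- M[j, k] + h(gin)[j, bi] * h(gout)[k, bo]
      }
    }
  }
  for (j in seq_len(nrow(M))) {
    if (sum(M[j, ]) > 0) M[j, ] <- M[j, ] / sum(M[j, ])
  }
  M
}
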