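# Synthetic three-region MMS systems with known (planted) structure:
# region-specific lognormal input KPIs, a linear input->output dependency
# with Gaussian noise, and multiplicative extreme-value outliers applied
# last so ground truth stays unambiguous.

#' Configuration for the synthetic MMS generator
#'
#' @param areas_per_region named integer vector, region name -> number of
#'   catchment areas (default the bundled 74/19/13 three-region layout).
#' @param seed integer RNG seed; the emitted system is a pure function of
#'   the configuration.
#' @param cluster_tightness named numeric, per-region within-cluster spread
#'   on the log scale (smaller = tighter). Catalonia's spread is realized
#'   through dispersed sub-cluster centers plus this within-sub-cluster
#'   term.
#' @param n_subclusters number of sub-cluster centers for the dispersed
#'   region (Catalonia), 4-6 is realistic.
#' @param subcluster_spread half-width of the bounded uniform sub-cluster
#'   center log-offsets for the dispersed region.
#' @param dependency 6 x 58 matrix of linear coefficients mapping the 58
#'   input KPIs (A1..A12, P1..P13, W1..W33) to the 6 output KPIs (U1..U6);
#'   default [default_dependency()].
#' @param noise_sd output noise scale: each output KPI receives Gaussian
#'   noise with standard deviation `noise_sd` times its typical magnitude.
#' @param outliers data frame with columns `label`, `code`, `multiplier`
#'   (> 0): extreme values planted multiplicatively after everything else.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(areas_per_region = c(Catalonia = 74L, Biscay = 19L,
                                              Gipuzkoa = 13L),
                         seed = 1L,
                         cluster_tightness = c(Catalonia = 0.10,
                                               Biscay = 0.07,
                                               Gipuzkoa = 0.07),
                         n_subclusters = 5L,
                         subcluster_spread = 0.45,
                         dependency = default_dependency(),
                         noise_sd = 0.1,
                         outliers = NULL) {
  stopifnot(all(areas_per_region >= 1L), noise_sd >= 0,
            n_subclusters >= 1L, subcluster_spread >= 0)
  input_codes <- c(paste0("A", 1:12), paste0("P", 1:13), paste0("W", 1:33))
  if (!is.matrix(dependency) || nrow(dependency) != 6L ||
      ncol(dependency) != length(input_codes)) {
    stop("dependency must be a 6 x ", length(input_codes), " matrix")
  }
  if (is.null(rownames(dependency))) rownames(dependency) <- paste0("U", 1:6)
  if (is.null(colnames(dependency))) colnames(dependency) <- input_codes
  if (!is.null(outliers)) {
    stopifnot(is.data.frame(outliers),
              all(c("label", "code", "multiplier") %in% names(outliers)),
              all(outliers$multiplier > 0))
  }
  structure(
    list(areas_per_region = areas_per_region, seed = as.integer(seed),
         cluster_tightness = cluster_tightness,
         n_subclusters = as.integer(n_subclusters),
         subcluster_spread = subcluster_spread,
         dependency = dependency, noise_sd = noise_sd,
         outliers = outliers),
    class = "synth_config"
  )
}

#' Default linear input-to-output dependency matrix
#'
#' Sparse non-negative coefficients mapping resource inputs to utilisation
#' outputs, scaled so outputs land on magnitudes comparable to published
#' acute-care KPI ranges (discharge about 0.4-6 per 1,000, length of stay
#' about 12-34 days, re-admission 0-37 per 100 discharges). Every output
#' loads positively on W1 (acute-care psychiatrists) so input-driven
#' monotonicity is a planted, testable property.
#'
#' @return A 6 x 58 matrix, rows U1..U6, columns A1..A12, P1..P13, W1..W33.
#' @export
default_dependency <- function() {
  input_codes <- c(paste0("A", 1:12), paste0("P", 1:13), paste0("W", 1:33))
  D <- matrix(0, nrow = 6L, ncol = length(input_codes),
              dimnames = list(paste0("U", 1:6), input_codes))
  D["U1", c("A1", "P1", "W1", "W2")] <- c(1.4, 0.04, 0.18, 0.04)
  D["U2", c("P1", "W3", "W1")] <- c(0.8, 0.9, 0.3)
  D["U3", c("A1", "P1", "W1")] <- c(4.0, 0.25, 1.2)
  D["U4", c("A8", "P1", "W20", "W1")] <- c(6.0, 0.3, 1.5, 0.5)
  D["U5", c("A8", "P1", "W21", "W1")] <- c(2.0, 0.08, 0.5, 0.25)
  D["U6", c("A8", "P1", "W20", "W23", "W1")] <- c(10.0, 1.0, 3.0, 2.0, 1.0)
  D
}

# typical magnitude of each output KPI; scales the Gaussian output noise
OUTPUT_SCALE <- c(U1 = 2.5, U2 = 19, U3 = 10, U4 = 15, U5 = 5, U6 = 40)

# deterministic per-indicator base medians: dataset-level magnitude with a
# three-step variety cycle so columns are not interchangeable
input_base_medians <- function(input_codes) {
  ds_base <- c(A = 0.5, P = 12, W = 4)
  cyc <- c(0.7, 1, 1.4)
  base <- ds_base[substr(input_codes, 1L, 1L)]
  unname(base * cyc[(seq_along(input_codes) - 1L) %% 3L + 1L])
}

# fixed region log-effects: Catalonia is the baseline; Biscay and Gipuzkoa
# take opposite +/- offsets on every indicator (alternating sign across
# indicators), so the two tight regions are separated from each other and
# from the baseline on every KPI and the pooled per-indicator spread never
# collapses
region_log_effect <- function(region_index, n_ind) {
  i <- seq_len(n_ind)
  if (region_index == 1L) return(numeric(n_ind))
  eff <- 0.35 * ifelse(i %% 2L == 0L, 1, -1)
  if (region_index == 3L) eff <- -eff    # mirror for the third region
  eff
}

#' Generate a synthetic MMS system
#'
#' Input KPIs are drawn from region-specific lognormal distributions around
#' per-region median vectors; the dispersed region's areas are spread over
#' sub-cluster centers. Output KPIs are `dependency %*% inputs` plus
#' Gaussian noise, clipped at zero. The workforce total W3 is rebuilt as
#' W1 + W2 + other professionals so the bundled consistency rule holds.
#' Planted outliers are applied last, multiplicatively.
#'
#' @param config a [synth_config()].
#' @return List with `tables` (named list of four [mms_table()] objects:
#'   AVA, PLA, WOF, USE) and `truth` (ground truth: per-area `region`,
#'   `subcluster`, the per-region expected mean vectors `region_means`,
#'   the `dependency` matrix used, and the planted `outliers`).
#' @examples
#' sys <- generate_system(paper_like_config(seed = 7))
#' nrow(sys$tables$USE$values)   # 106 areas
#' @export
generate_system <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  taxonomy <- mms_taxonomy()
  input_codes <- taxonomy$code[taxonomy$dataset != "USE"]
  regions <- names(config$areas_per_region)
  registry <- region_registry()
  prefixes <- ifelse(regions %in% registry$region,
                     registry$prefix[match(regions, registry$region)],
                     toupper(substr(regions, 1L, 1L)))
  if (anyDuplicated(prefixes)) stop("region label prefixes must be unique")

  n_ind <- length(input_codes)
  base_mu <- log(input_base_medians(input_codes))

  areas <- list()
  X <- list()
  subcl <- list()
  region_means <- list()
  for (r in seq_along(regions)) {
    n_r <- config$areas_per_region[[r]]
    tight <- config$cluster_tightness[[regions[r]]]
    if (is.null(tight) || is.na(tight)) tight <- 0.1
    beta <- region_log_effect(r, n_ind)
    dispersed <- regions[r] == "Catalonia"
    n_sub <- if (dispersed) config$n_subclusters else 1L
    gamma <- if (n_sub > 1L) {
      # evenly spaced, bounded log-offsets shared across indicators: the
      # dispersed region's sub-clusters form a small-to-large resource
      # gradient, so its spread stays bounded and non-degenerate under
      # every linear combination of indicators (no spurious extremes)
      spaced <- seq(-config$subcluster_spread, config$subcluster_spread,
                    length.out = n_sub)
      matrix(rep(spaced, n_ind), nrow = n_sub)
    } else {
      matrix(0, nrow = 1L, ncol = n_ind)
    }
    assign_sub <- if (n_sub > 1L) {
      sample(rep_len(seq_len(n_sub), n_r))   # balanced, shuffled
    } else {
      rep(1L, n_r)
    }
    z <- matrix(stats::rnorm(n_r * n_ind, 0, tight), nrow = n_r)
    logx <- sweep(gamma[assign_sub, , drop = FALSE] + z, 2L, base_mu + beta, `+`)
    X[[r]] <- exp(logx)
    areas[[r]] <- data.frame(label = paste0(prefixes[r], seq_len(n_r)),
                             region = regions[r])
    subcl[[r]] <- assign_sub
    # exact expected means: lognormal mean over the sub-cluster mixture
    region_means[[regions[r]]] <- stats::setNames(
      exp(base_mu + beta + tight^2 / 2) * colMeans(exp(gamma)), input_codes)
  }
  areas <- do.call(rbind, areas)
  X <- do.call(rbind, X)
  colnames(X) <- input_codes
  rownames(X) <- areas$label

  # W3 = W1 + W2 + other professionals; the other-staff contingent is
  # proportional to the clinical staff (about a quarter), so W3 inherits
  # the same relative dispersion as its components
  other <- 0.25 * (X[, "W1"] + X[, "W2"]) * exp(stats::rnorm(nrow(X), 0, 0.1))
  X[, "W3"] <- X[, "W1"] + X[, "W2"] + other
  iw <- match(c("W1", "W2", "W3"), input_codes)
  for (reg in names(region_means)) {
    w12 <- region_means[[reg]][iw[1L]] + region_means[[reg]][iw[2L]]
    region_means[[reg]][iw[3L]] <- w12 * (1 + 0.25 * exp(0.1^2 / 2))
  }

  Y <- X %*% t(config$dependency)
  if (config$noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(Y)), nrow = nrow(Y)) *
      rep(config$noise_sd * OUTPUT_SCALE[colnames(Y)], each = nrow(Y))
    Y <- Y + noise
  }
  Y <- pmax(Y, 0)

  all_values <- cbind(X, Y)
  if (!is.null(config$outliers)) {
    for (k in seq_len(nrow(config$outliers))) {
      lab <- config$outliers$label[k]
      code <- config$outliers$code[k]
      if (!lab %in% rownames(all_values)) {
        stop("outlier label ", lab, " not among generated areas")
      }
      if (!code %in% colnames(all_values)) {
        stop("outlier code ", code, " unknown")
      }
      all_values[lab, code] <- all_values[lab, code] *
        config$outliers$multiplier[k]
    }
  }

  tables <- lapply(DATASET_TAGS, function(ds) {
    ind <- taxonomy[taxonomy$dataset == ds, ]
    mms_table(ds, areas, all_values[, ind$code, drop = FALSE], ind)
  })
  names(tables) <- DATASET_TAGS

  truth <- list(
    region = stats::setNames(areas$region, areas$label),
    subcluster = stats::setNames(unlist(subcl), areas$label),
    region_means = region_means,
    dependency = config$dependency,
    outliers = config$outliers,
    seed = config$seed
  )
  list(tables = tables, truth = truth)
}

#' Synthetic configuration mimicking the bundled three-region study system
#'
#' 74 + 19 + 13 = 106 catchment areas with tight Biscay and Gipuzkoa
#' clusters and a dispersed Catalonia, plus four planted extreme-value
#' outlier areas: three Catalonia areas (C63, C64, C74) extreme on
#' availability indicators and one Biscay area (B19) extreme on the
#' outpatient utilisation indicators U4 (treated prevalence), U5 (treated
#' incidence) and U6 (frequency).
#'
#' @param seed integer RNG seed.
#' @return A [synth_config()].
#' @export
paper_like_config <- function(seed = 20180425L) {
  synth_config(
    seed = seed,
    outliers = data.frame(
      label = c("C63", "C64", "C74", "B19", "B19", "B19"),
      code = c("A1", "A3", "A5", "U4", "U5", "U6"),
      multiplier = c(10, 10, 10, 10, 10, 10)
    )
  )
}
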