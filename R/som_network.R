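# Networking SOMs trained on different datasets over the same catchment
# areas: a non-negative association matrix links input-map neurons to
# output-map neurons via kernel-smoothed BMU co-activation, enabling
# input-driven and output-driven conditional KPI estimation.

#' Build the association network between two SOMs
#'
#' For every shared area, its BMU on each map is smoothed with a Gaussian
#' kernel over grid distance (radius `radius`); the association matrix
#' accumulates the outer product of the two smoothed activations:
#' `M[j, k] = sum_areas h_in(j, BMU_in) * h_out(k, BMU_out)`. Rows with
#' support are normalized to sum to 1. With `radius = 0` the kernel is a
#' hard assignment and `M` counts BMU co-occurrences.
#'
#' @param input_som,output_som [train_som()] results trained on the same
#'   areas in the same order.
#' @param radius kernel radius in grid units (default 1).
#' @return An object of class `som_association`: `M` (input neurons x
#'   output neurons, supported rows row-stochastic), `support` (logical,
#'   rows with nonzero mass), `radius`, `n_areas`, dataset tags.
#' @export
build_association <- function(input_som, output_som, radius = 1) {
  stopifnot(inherits(input_som, "trained_som"),
            inherits(output_som, "trained_som"), radius >= 0)
  a_in <- names(input_som$assignments)
  a_out <- names(output_som$assignments)
  if (!identical(a_in, a_out)) {
    stop("SOMs were not trained on the same area set in the same order")
  }
  kern <- function(som) {
    Dg <- grid_distances(som$grid)
    if (radius <= 0) (Dg == 0) * 1 else exp(-Dg^2 / (2 * radius^2))
  }
  K_in <- kern(input_som)
  K_out <- kern(output_som)
  M <- matrix(0, nrow = input_som$grid$n_units,
              ncol = output_som$grid$n_units)
  for (i in seq_along(a_in)) {
    M <- M + tcrossprod(K_in[, input_som$assignments[i]],
                        K_out[, output_som$assignments[i]])
  }
  rs <- rowSums(M)
  support <- rs > 0
  M[support, ] <- M[support, , drop = FALSE] / rs[support]
  structure(
    list(M = M, support = support, radius = radius,
         n_areas = length(a_in),
         input_dataset = input_som$meta$dataset,
         output_dataset = output_som$meta$dataset),
    class = "som_association"
  )
}

#' @export
print.som_association <- function(x, ...) {
  cat(sprintf(
    "Association %s-SOM -> %s-SOM: %d x %d, radius %g, %d areas, %d/%d rows supported\n",
    x$input_dataset, x$output_dataset, nrow(x$M), ncol(x$M), x$radius,
    x$n_areas, sum(x$support), length(x$support)))
  invisible(x)
}

#' Neuron activation for a set of indicator constraints
#'
#' Each constraint `(code, value in original units)` is normalized with the
#' SOM's scaler and compared to the codebook with a Gaussian kernel of
#' width `sigma` on the normalized scale; joint constraints combine as the
#' product of their activations (independent evidence). The result is
#' max-normalized to [0, 1].
#'
#' @param som a [train_som()] result.
#' @param constraints named numeric vector, indicator code -> value in
#'   original units.
#' @param sigma Gaussian kernel width on the normalized scale (default
#'   0.1).
#' @return Numeric vector, one activation per neuron, max 1.
#' @export
activation <- function(som, constraints, sigma = 0.1) {
  stopifnot(inherits(som, "trained_som"), sigma > 0)
  if (length(constraints) == 0L) stop("at least one constraint is required")
  if (is.null(names(constraints)) || any(!nzchar(names(constraints)))) {
    stop("constraints must be named by indicator code")
  }
  if (any(!is.finite(constraints))) stop("constraint values must be finite")
  bad <- setdiff(names(constraints), colnames(som$codebook))
  if (length(bad)) {
    stop("constraint code(s) not in the ", som$meta$dataset, "-SOM: ",
         paste(bad, collapse = ", "))
  }
  act <- rep(1, nrow(som$codebook))
  for (code in names(constraints)) {
    rng <- scaler_range(som$scaler, code)
    idx <- match(code, som$scaler$code)
    xn <- if (som$scaler$degenerate[idx]) 0.5 else {
      (constraints[[code]] - rng[1L]) / (rng[2L] - rng[1L])
    }
    act <- act * exp(-(som$codebook[, code] - xn)^2 / (2 * sigma^2))
  }
  m <- max(act)
  if (m <= 0 || !is.finite(m)) {
    # numerically underflowed joint kernel: no neuron is compatible
    stop("activation underflow: constraints jointly match no neuron")
  }
  act / m
}

#' Propagate an activation through the association network
#'
#' Input-driven: an activation over the input SOM is pushed through `M` to
#' yield a weight per output-SOM neuron. Output-driven: an activation over
#' the output SOM is pushed through `t(M)` to weight the input SOM. The
#' field is max-normalized.
#'
#' @param network a [build_association()] result.
#' @param act numeric activation over the source-side SOM's neurons.
#' @param direction `"input-driven"` or `"output-driven"`.
#' @return An object of class `weight_field`: `weights` (per target
#'   neuron, max 1), `direction`, `target_dataset`, and (after
#'   [select_region()]) `mask` and `quantile`.
#' @export
propagate <- function(network, act,
                      direction = c("input-driven", "output-driven")) {
  stopifnot(inherits(network, "som_association"))
  direction <- match.arg(direction)
  if (direction == "input-driven") {
    if (length(act) != nrow(network$M)) {
      stop("activation length ", length(act), " != ", nrow(network$M),
           " input neurons")
    }
    w <- as.numeric(act %*% network$M)
    target <- network$output_dataset
  } else {
    if (length(act) != ncol(network$M)) {
      stop("activation length ", length(act), " != ", ncol(network$M),
           " output neurons")
    }
    w <- as.numeric(network$M %*% act)
    target <- network$input_dataset
  }
  if (any(w < 0)) w[w < 0] <- 0
  m <- max(w)
  if (m <= 0) {
    stop("propagation has no support: the activation touches only ",
         "unsupported association rows")
  }
  structure(list(weights = w / m, direction = direction,
                 target_dataset = target, mask = NULL, quantile = NULL),
            class = "weight_field")
}

#' Select the most-weighted region of a weight field
#'
#' The mask keeps all neurons whose weight is at or above the `q`-quantile
#' of the field's weights (linear-interpolation quantile); ties at the
#' threshold are included, so the mask is never empty.
#'
#' @param field a [propagate()] result.
#' @param q region quantile in (0, 1); higher keeps fewer neurons.
#' @return The field with `mask` (integer neuron indices) and `quantile`
#'   filled in.
#' @export
select_region <- function(field, q = 0.8) {
  stopifnot(inherits(field, "weight_field"), q > 0, q < 1)
  thr <- stats::quantile(field$weights, q, type = 7, names = FALSE)
  # small tolerance so ties at the threshold are included despite the
  # floating-point interpolation in the quantile
  tol <- 1e-8 * max(diff(range(field$weights)), 1e-300)
  field$mask <- which(field$weights >= thr - tol)
  field$quantile <- q
  field
}

#' @export
print.weight_field <- function(x, ...) {
  cat(sprintf("Weight field on the %s-SOM (%s): %d neurons%s\n",
              x$target_dataset, x$direction, length(x$weights),
              if (!is.null(x$mask)) {
                sprintf(", region of %d at q=%g", length(x$mask), x$quantile)
              } else ""))
  invisible(x)
}

#' Estimate indicator values over a selected region
#'
#' Per indicator: the weight-averaged denormalized codebook value over the
#' masked neurons, plus its qualitative category on the indicator's
#' observed [min, max] range (five 20% levels).
#'
#' @param som the [train_som()] carrying the target map's codebook.
#' @param field a [select_region()] result over that map.
#' @param codes indicator codes to estimate (default: all of the SOM's).
#' @return Data frame with `code`, `value` (original units), `category`,
#'   `region_size`.
#' @export
estimate_indicators <- function(som, field, codes = colnames(som$codebook)) {
  stopifnot(inherits(som, "trained_som"), inherits(field, "weight_field"))
  if (is.null(field$mask) || length(field$mask) == 0L) {
    stop("field has no selected region; call select_region() first")
  }
  bad <- setdiff(codes, colnames(som$codebook))
  if (length(bad)) {
    stop("code(s) not in the ", som$meta$dataset, "-SOM: ",
         paste(bad, collapse = ", "))
  }
  w <- field$weights[field$mask]
  out <- lapply(codes, function(code) {
    plane <- component_plane(som, code)
    value <- sum(w * plane[field$mask]) / sum(w)
    rng <- scaler_range(som$scaler, code)
    category <- if (is.finite(rng[1L]) && is.finite(rng[2L]) &&
                    rng[2L] > rng[1L]) {
      categorize(value, make_scale(rng[1L], rng[2L]))
    } else NA_character_
    data.frame(code = code, value = value, category = category,
               region_size = length(field$mask))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Conditional query specification
#'
#' @param direction `"input-driven"` (condition on resource inputs,
#'   estimate utilisation outputs) or `"output-driven"` (condition on
#'   outputs, estimate inputs).
#' @param constraints named numeric vector, indicator code -> value in
#'   original units.
#' @param sigma activation kernel width on the normalized scale.
#' @param q region-selection quantile in (0, 1).
#' @param report for output-driven queries, the input indicator codes to
#'   estimate; ignored for input-driven queries (which report the whole
#'   output dataset).
#' @return An object of class `conditional_query`.
#' @export
conditional_query <- function(direction = c("input-driven", "output-driven"),
                              constraints, sigma = 0.1, q = 0.8,
                              report = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(constraints) >= 1L, sigma > 0, q > 0, q < 1)
  structure(list(direction = direction, constraints = constraints,
                 sigma = sigma, q = q, report = report),
            class = "conditional_query")
}

#' Run a conditional input-driven or output-driven query
#'
#' Composes [activation()], [propagate()], [select_region()] and
#' [estimate_indicators()]. Input-driven: constraints are grouped by
#' input dataset, each group's activation is propagated to the output map
#' through its network, joint evidence from several input datasets
#' combines multiplicatively, and all output indicators are estimated.
#' Output-driven: the constraint activation on the output map is
#' propagated backwards through each network owning a requested input
#' indicator, and those indicators are estimated on their input maps.
#'
#' @param networks named list of [build_association()] results, keyed by
#'   input dataset tag (e.g. `AVA`, `PLA`, `WOF`), all sharing one output
#'   map.
#' @param soms named list of [train_som()] results keyed by dataset tag,
#'   including the output dataset.
#' @param query a [conditional_query()].
#' @return List with `fields` (named list of `weight_field`, one per
#'   target map) and `estimates` (data frame as in
#'   [estimate_indicators()], plus a `dataset` column).
#' @export
run_query <- function(networks, soms, query) {
  stopifnot(inherits(query, "conditional_query"))
  out_ds <- networks[[1L]]$output_dataset
  out_som <- soms[[out_ds]]
  if (is.null(out_som)) stop("output SOM ", out_ds, " missing from soms")
  codes <- names(query$constraints)
  if (query$direction == "input-driven") {
    ds_of <- dataset_of_code(codes)
    missing_net <- setdiff(unique(ds_of), names(networks))
    if (length(missing_net)) {
      stop("no network for constraint dataset(s): ",
           paste(missing_net, collapse = ", "))
    }
    combined <- NULL
    for (ds in unique(ds_of)) {
      act <- activation(soms[[ds]], query$constraints[ds_of == ds],
                        sigma = query$sigma)
      f <- propagate(networks[[ds]], act, "input-driven")
      combined <- if (is.null(combined)) f$weights else combined * f$weights
    }
    if (max(combined) <= 0) stop("joint propagation has no support")
    field <- structure(
      list(weights = combined / max(combined), direction = "input-driven",
           target_dataset = out_ds, mask = NULL, quantile = NULL),
      class = "weight_field")
    field <- select_region(field, query$q)
    est <- estimate_indicators(out_som, field)
    est$dataset <- out_ds
    list(fields = stats::setNames(list(field), out_ds), estimates = est)
  } else {
    if (!all(dataset_of_code(codes) == out_ds)) {
      stop("output-driven constraints must all be ", out_ds, " indicators")
    }
    report <- query$report
    if (is.null(report) || !length(report)) {
      stop("output-driven queries must name the input indicator(s) to report")
    }
    rep_ds <- dataset_of_code(report)
    missing_net <- setdiff(unique(rep_ds), names(networks))
    if (length(missing_net)) {
      stop("no network for requested dataset(s): ",
           paste(missing_net, collapse = ", "))
    }
    act <- activation(out_som, query$constraints, sigma = query$sigma)
    fields <- list()
    ests <- list()
    for (ds in unique(rep_ds)) {
      f <- propagate(networks[[ds]], act, "output-driven")
      f <- select_region(f, query$q)
      fields[[ds]] <- f
      e <- estimate_indicators(soms[[ds]], f, report[rep_ds == ds])
      e$dataset <- ds
      ests[[ds]] <- e
    }
    list(fields = fields, estimates = do.call(rbind, ests))
  }
}
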