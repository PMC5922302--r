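# Data model and I/O for the minimum metadata set (MMS): 64 mental-health
# KPIs in four datasets (AVA availability, PLA placement, WOF workforce,
# USE utilisation) over small catchment areas grouped in regions.

DATASET_TAGS <- c("AVA", "PLA", "WOF", "USE")
DATASET_PREFIX <- c(AVA = "A", PLA = "P", WOF = "W", USE = "U")
DATASET_SIZES <- c(AVA = 12L, PLA = 13L, WOF = 33L, USE = 6L)

UNIT_PER_100K <- "per 100,000 inhabitants"
UNIT_PER_1K <- "per 1,000 inhabitants"
UNIT_DAYS <- "days"
UNIT_PER_100_DISCH <- "per 100 discharges"

#' The bundled MMS indicator taxonomy
#'
#' Returns the 64-KPI minimum metadata set: 12 service-availability (A1-A12),
#' 13 placement-capacity (P1-P13) and 33 workforce-capacity (W1-W33) input
#' indicators plus 6 resource-utilisation (U1-U6) output indicators, each
#' with its main type of care, measured quantity and unit. Availability,
#' placement and workforce KPIs are rates per 100,000 inhabitants;
#' utilisation KPIs use per-1,000-inhabitant rates except length of stay
#' (days) and re-admission (per 100 discharges). W3 is defined as
#' W1 + W2 + other professionals.
#'
#' @return A data frame with columns `code`, `dataset`, `care_type`,
#'   `measure`, `unit`; one row per KPI, 64 rows.
#' @examples
#' table(mms_taxonomy()$dataset)
#' @export
mms_taxonomy <- function() {
  ava_care <- c(
    "Acute hospital care", "Non-acute hospital care",
    "Non-acute non-hospital care", "Residential care",
    "Acute health day care", "Non-acute health day care",
    "Day care (others)", "Non-acute non-mobile outpatient care",
    "High intensity residential care", "Residential care (others)",
    "Work-related day care", "Non-health day care"
  )
  ava <- data.frame(
    code = paste0("A", 1:12), dataset = "AVA", care_type = ava_care,
    measure = "clinical teams", unit = UNIT_PER_100K
  )
  pla_care <- c(
    "Acute hospital care", "Non-acute hospital care",
    "Non-acute non-hospital care", "Residential care",
    "Acute health day care", "Non-acute health day care",
    "Day care (others)", "High intensity residential care",
    "Residential care (others)", "Acute and non-acute health day care",
    "Work-related day care", "Non-health day care",
    "24-h medical support hospital and residential care"
  )
  pla <- data.frame(
    code = paste0("P", 1:13), dataset = "PLA", care_type = pla_care,
    measure = "beds and places", unit = UNIT_PER_100K
  )
  wof_def <- list(
    c("Acute hospital care", "psychiatrists"),
    c("Acute hospital care", "psychologists, nurses"),
    c("Acute hospital care", "total professionals"),
    c("Non-acute hospital care", "psychiatrists"),
    c("Non-acute hospital care", "psychologists, nurses"),
    c("Non-acute hospital care", "total professionals"),
    c("Non-acute non-hospital care", "psychiatrists"),
    c("Non-acute non-hospital care", "psychologists, nurses"),
    c("Non-acute non-hospital care", "total professionals"),
    c("Residential care", "psychiatrists"),
    c("Residential care", "psychologists"),
    c("Residential care", "nurses"),
    c("Residential care", "total professionals"),
    c("Acute health day care", "psychiatrists"),
    c("Acute health day care", "psychologists, nurses"),
    c("Acute health day care", "total professionals"),
    c("Non-acute health day care", "psychologists"),
    c("Non-acute health day care", "total professionals"),
    c("Day care (others)", "total professionals"),
    c("Non-acute non-mobile outpatient care", "psychiatrists"),
    c("Non-acute non-mobile outpatient care", "psychologists"),
    c("Non-acute non-mobile outpatient care", "nurses"),
    c("Non-acute non-mobile outpatient care", "total professionals"),
    c("High intensity residential care", "psychiatrists"),
    c("High intensity residential care", "nurses"),
    c("Acute and non-acute health day care", "psychologists"),
    c("Acute and non-acute health day care", "nurses"),
    c("Acute and non-acute health day care", "total professionals"),
    c("Work-related day care", "total professionals"),
    c("Non-health day care", "total professionals"),
    c("24-h medical support hospital and residential care", "total professionals"),
    c("24-h medical support non-acute hospital and residential care", "psychiatrists"),
    c("24-h medical support non-acute hospital and residential care", "total professionals")
  )
  wof <- data.frame(
    code = paste0("W", 1:33), dataset = "WOF",
    care_type = vapply(wof_def, `[`, "", 1L),
    measure = paste0("full-time equivalents (", vapply(wof_def, `[`, "", 2L), ")"),
    unit = UNIT_PER_100K
  )
  use <- data.frame(
    code = paste0("U", 1:6), dataset = "USE",
    care_type = c(rep("Acute hospital care", 3),
                  rep("Non-acute non-mobile outpatient care", 3)),
    measure = c("discharge", "length of stay", "re-admission",
                "treated prevalence", "treated incidence", "frequency"),
    unit = c(UNIT_PER_1K, UNIT_DAYS, UNIT_PER_100_DISCH,
             UNIT_PER_1K, UNIT_PER_1K, UNIT_PER_1K)
  )
  out <- rbind(ava, pla, wof, use)
  rownames(out) <- NULL
  out
}

#' The bundled three-region registry
#'
#' The three regional mental-health systems with their label prefix, number
#' of small catchment areas and population: Catalonia (C, 74 areas,
#' 7,555,830 inhabitants), Biscay (B, 19 areas, 1,148,302) and Gipuzkoa
#' (G, 13 areas, 719,282).
#'
#' @return A data frame with columns `region`, `prefix`, `n_areas`,
#'   `population`.
#' @export
region_registry <- function() {
  data.frame(
    region = c("Catalonia", "Biscay", "Gipuzkoa"),
    prefix = c("C", "B", "G"),
    n_areas = c(74L, 19L, 13L),
    population = c(7555830L, 1148302L, 719282L)
  )
}

#' Area labels and regions for the bundled three-region system
#'
#' Expands [region_registry()] into one row per catchment area, labelled by
#' region initial plus number (C1..C74, B1..B19, G1..G13).
#'
#' @return A data frame with columns `label`, `region`.
#' @export
area_registry <- function() {
  reg <- region_registry()
  do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    data.frame(
      label = paste0(reg$prefix[i], seq_len(reg$n_areas[i])),
      region = reg$region[i]
    )
  }))
}

dataset_of_code <- function(code) {
  prefix <- substr(code, 1L, 1L)
  tag <- names(DATASET_PREFIX)[match(prefix, DATASET_PREFIX)]
  if (any(is.na(tag))) {
    stop("unknown indicator code(s): ", paste(code[is.na(tag)], collapse = ", "))
  }
  tag
}

#' Construct an MMS table for one dataset
#'
#' @param dataset one of `"AVA"`, `"PLA"`, `"WOF"`, `"USE"`.
#' @param areas data frame with columns `label`, `region` (and optionally
#'   `population`); one row per catchment area.
#' @param values numeric matrix, areas x indicators, original units; `NA`
#'   marks missing entries.
#' @param indicators data frame of indicator definitions (as in
#'   [mms_taxonomy()]) restricted to this dataset, in column order.
#' @return An object of class `mms_table`.
#' @export
mms_table <- function(dataset, areas, values, indicators) {
  dataset <- match.arg(dataset, DATASET_TAGS)
  stopifnot(is.data.frame(areas), all(c("label", "region") %in% names(areas)))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(areas$label)) {
    stop("duplicate area label(s): ",
         paste(unique(areas$label[duplicated(areas$label)]), collapse = ", "))
  }
  if (anyDuplicated(indicators$code)) stop("duplicate indicator codes")
  if (!all(indicators$dataset == dataset)) {
    stop("indicator dataset membership does not match table dataset ", dataset)
  }
  if (!all(substr(indicators$code, 1L, 1L) == DATASET_PREFIX[[dataset]])) {
    stop("indicator code prefix inconsistent with dataset ", dataset)
  }
  if (nrow(values) != nrow(areas) || ncol(values) != nrow(indicators)) {
    stop("values matrix shape ", nrow(values), "x", ncol(values),
         " inconsistent with ", nrow(areas), " areas x ",
         nrow(indicators), " indicators")
  }
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative value for indicator ", indicators$code[bad[2L]],
         " in area ", areas$label[bad[1L]])
  }
  dimnames(values) <- list(areas$label, indicators$code)
  structure(
    list(dataset = dataset, areas = areas, values = values,
         indicators = indicators),
    class = "mms_table"
  )
}

#' @export
print.mms_table <- function(x, ...) {
  cat(sprintf("MMS table %s: %d areas x %d indicators (%d missing cells)\n",
              x$dataset, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Load an MMS system from CSV plus metadata JSON
#'
#' The CSV has one row per catchment area: an `area` label column, a
#' `region` column, then one numeric column per indicator code declared in
#' the metadata; empty cells are missing values. The metadata JSON carries
#' the indicator taxonomy (code, dataset, care type, measure, unit) and the
#' region registry; [write_mms_metadata()] emits the bundled schema.
#'
#' @param data_path path to the MMS CSV.
#' @param meta_path path to the metadata JSON.
#' @return Named list of [mms_table()] objects, one per dataset tag present
#'   in the metadata, columns in metadata order.
#' @export
load_mms <- function(data_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  indicators <- as.data.frame(meta$indicators)
  need <- c("code", "dataset", "care_type", "measure", "unit")
  if (!all(need %in% names(indicators))) {
    stop("metadata JSON lacks indicator fields: ",
         paste(setdiff(need, names(indicators)), collapse = ", "))
  }
  df <- utils::read.csv(data_path, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("area", "region") %in% names(df))) {
    stop("MMS CSV must have 'area' and 'region' columns")
  }
  value_cols <- setdiff(names(df), c("area", "region"))
  unknown <- setdiff(value_cols, indicators$code)
  if (length(unknown)) {
    stop("CSV column(s) not declared in metadata: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(indicators$code, value_cols)
  if (length(absent)) {
    stop("metadata indicator(s) missing from CSV: ",
         paste(absent, collapse = ", "))
  }
  if (anyDuplicated(df$area)) {
    stop("duplicate area label(s) in CSV: ",
         paste(unique(df$area[duplicated(df$area)]), collapse = ", "))
  }
  areas <- data.frame(label = df$area, region = df$region)
  values <- vapply(indicators$code, function(cc) {
    v <- df[[cc]]
    v[!nzchar(trimws(v))] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(areas$label, indicators$code))
  tabs <- lapply(split(indicators, factor(indicators$dataset,
                                          levels = unique(indicators$dataset))),
                 function(ind) {
    mms_table(ind$dataset[1L], areas, values[, ind$code, drop = FALSE], ind)
  })
  tabs[intersect(DATASET_TAGS, names(tabs))]
}

#' Write an MMS system to canonical CSV
#'
#' Emits the comma-separated, UTF-8 exchange format read by [load_mms()]:
#' header `area,region,<codes...>`, missing values as empty cells, full
#' precision numbers. Loading and re-writing a canonical file reproduces it
#' byte for byte.
#'
#' @param tables named list of [mms_table()] objects sharing one area set.
#' @param data_path output CSV path.
#' @return `data_path`, invisibly.
#' @export
write_mms <- function(tables, data_path) {
  stopifnot(length(tables) >= 1L)
  areas <- tables[[1L]]$areas
  for (t in tables) {
    if (!identical(t$areas$label, areas$label)) {
      stop("tables do not share one area set")
    }
  }
  values <- do.call(cbind, lapply(tables, `[[`, "values"))
  num <- vapply(seq_len(ncol(values)), function(j) {
    v <- vapply(values[, j], function(x) {
      if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
    }, "")
    v
  }, character(nrow(values)))
  lines <- c(
    paste(c("area", "region", colnames(values)), collapse = ","),
    vapply(seq_len(nrow(values)), function(i) {
      paste(c(areas$label[i], areas$region[i], num[i, ]), collapse = ",")
    }, "")
  )
  writeLines(lines, data_path, useBytes = TRUE)
  invisible(data_path)
}

#' Write metadata JSON for an MMS system
#'
#' @param indicators indicator taxonomy data frame (default the bundled
#'   64-KPI set from [mms_taxonomy()]).
#' @param regions region registry data frame (default [region_registry()]).
#' @param meta_path output JSON path.
#' @return `meta_path`, invisibly.
#' @export
write_mms_metadata <- function(meta_path, indicators = mms_taxonomy(),
                               regions = region_registry()) {
  jsonlite::write_json(
    list(indicators = indicators, regions = regions),
    meta_path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(meta_path)
}

#' Validate an MMS system
#'
#' Runs the structural checks on a loaded system: dataset cardinalities
#' (12/13/33/6), value non-negativity, the workforce consistency rule
#' W3 >= W1 + W2 (a warning-level check, since "other professionals" are
#' unrecorded but non-negative), and per-indicator missingness fractions.
#'
#' @param tables named list of [mms_table()] objects.
#' @return An object of class `mms_validation`: list with `checks` (data
#'   frame: `check`, `dataset`, `status` in pass/fail/warn, `detail`),
#'   `n_indicators`, `missingness` (named numeric per indicator) and `ok`
#'   (no fail-level findings).
#' @export
validate_mms <- function(tables) {
  checks <- list()
  add <- function(check, dataset, status, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, dataset = dataset, status = status, detail = detail)
  }
  n_ind <- 0L
  missingness <- numeric(0)
  for (tab in tables) {
    ds <- tab$dataset
    n_ind <- n_ind + ncol(tab$values)
    expected <- DATASET_SIZES[[ds]]
    add("cardinality", ds,
        if (ncol(tab$values) == expected) "pass" else "fail",
        sprintf("%d indicators (expected %d)", ncol(tab$values), expected))
    neg <- sum(tab$values < 0, na.rm = TRUE)
    add("non-negativity", ds, if (neg == 0L) "pass" else "fail",
        sprintf("%d negative cells", neg))
    mf <- colMeans(is.na(tab$values))
    missingness <- c(missingness, mf)
    add("missingness", ds, "pass",
        sprintf("max fraction %.3f (%s)", max(mf),
                colnames(tab$values)[which.max(mf)]))
    if (ds == "WOF" && all(c("W1", "W2", "W3") %in% colnames(tab$values))) {
      w <- tab$values[, c("W1", "W2", "W3")]
      complete <- stats::complete.cases(w)
      bad <- complete & (w[, "W3"] < w[, "W1"] + w[, "W2"] - 1e-9)
      add("W3 >= W1 + W2", ds, if (any(bad)) "warn" else "pass",
          if (any(bad)) {
            paste("violated in:", paste(rownames(w)[bad], collapse = ", "))
          } else sprintf("holds on %d complete rows", sum(complete)))
    }
  }
  checks <- do.call(rbind, checks)
  structure(
    list(checks = checks, n_indicators = n_ind, missingness = missingness,
         ok = !any(checks$status == "fail")),
    class = "mms_validation"
  )
}

#' @export
print.mms_validation <- function(x, ...) {
  cat(sprintf("MMS validation: %d indicators, %s\n", x$n_indicators,
              if (x$ok) "no failures" else "FAILURES present"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' Min-max normalize an MMS table to the [0, 1] scale
#'
#' Per indicator, maps `x` to `(x - min) / (max - min)` over the observed
#' values; missing entries stay missing. A degenerate indicator (fewer than
#' two distinct non-missing values) maps to 0.5 everywhere and is flagged;
#' degenerate indicators are excluded from SOM distance terms downstream.
#'
#' @param table an [mms_table()].
#' @return List with `table` (normalized `mms_table`) and `scaler` (class
#'   `mms_scaler`: data frame `code`, `min`, `max`, `degenerate` plus the
#'   method tag).
#' @export
normalize_mms <- function(table) {
  stopifnot(inherits(table, "mms_table"))
  v <- table$values
  if (nrow(v) == 0L || ncol(v) == 0L) stop("cannot normalize an empty table")
  mins <- apply(v, 2L, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  maxs <- apply(v, 2L, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  mins[!is.finite(mins)] <- NA_real_
  maxs[!is.finite(maxs)] <- NA_real_
  degenerate <- !is.finite(mins) | !is.finite(maxs) | (maxs - mins) == 0
  out <- v
  for (j in seq_len(ncol(v))) {
    if (degenerate[j]) {
      out[!is.na(v[, j]), j] <- 0.5
      out[is.na(v[, j]), j] <- NA_real_
    } else {
      out[, j] <- (v[, j] - mins[j]) / (maxs[j] - mins[j])
    }
  }
  scaler <- structure(
    list(code = colnames(v), min = unname(mins), max = unname(maxs),
         degenerate = unname(degenerate), method = "min-max",
         constant = unname(ifelse(degenerate, mins, NA_real_))),
    class = "mms_scaler"
  )
  ntab <- table
  ntab$values <- out
  ntab$normalized <- TRUE
  list(table = ntab, scaler = scaler)
}

#' Map normalized values back to original units
#'
#' Exact inverse of [normalize_mms()] for non-degenerate indicators;
#' degenerate indicators restore their constant value.
#'
#' @param values numeric vector or matrix of normalized values; if a matrix,
#'   columns must be named with indicator codes, if a vector either named or
#'   accompanied by `codes`.
#' @param scaler an `mms_scaler` from [normalize_mms()].
#' @param codes indicator codes aligned with `values` (defaults to its
#'   names/colnames).
#' @return Values in original units, same shape as `values`.
#' @export
denormalize_mms <- function(values, scaler, codes = NULL) {
  stopifnot(inherits(scaler, "mms_scaler"))
  if (is.null(codes)) {
    codes <- if (is.matrix(values)) colnames(values) else names(values)
  }
  if (is.null(codes)) stop("indicator codes required to denormalize")
  idx <- match(codes, scaler$code)
  if (any(is.na(idx))) {
    stop("indicator(s) absent from scaler: ",
         paste(codes[is.na(idx)], collapse = ", "))
  }
  mins <- scaler$min[idx]
  rng <- scaler$max[idx] - scaler$min[idx]
  deg <- scaler$degenerate[idx]
  back <- function(x, k) {
    if (deg[k]) ifelse(is.na(x), NA_real_, scaler$constant[idx[k]])
    else mins[k] + x * rng[k]
  }
  if (is.matrix(values)) {
    out <- values
    for (k in seq_len(ncol(values))) out[, k] <- back(values[, k], k)
    out
  } else {
    out <- values
    for (k in seq_along(values)) out[k] <- back(values[k], k)
    out
  }
}

#' Observed range of one indicator from a scaler
#' @param scaler an `mms_scaler`.
#' @param code indicator code.
#' @return Numeric `c(min, max)`.
#' @export
scaler_range <- function(scaler, code) {
  idx <- match(code, scaler$code)
  if (is.na(idx)) stop("indicator ", code, " absent from scaler")
  c(scaler$min[idx], scaler$max[idx])
}
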