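# Extreme-value system outliers: robust per-indicator scores flag
# candidate areas; an explicit policy (expert input) decides whether each
# flagged area is dropped, winsorized to a high percentile, or kept.

#' Flag extreme-value outlier areas per indicator
#'
#' For every indicator the robust score of an area is
#' `(x - median) / (1.4826 * MAD)` over the non-missing values; areas with
#' absolute score at or above `threshold` are listed with their direction.
#' Indicators with zero MAD carry no scale information and are skipped
#' with a note.
#'
#' @param table an [mms_table()] in original units.
#' @param threshold robust-z cutoff (default 3.5).
#' @return An object of class `outlier_report`: data frame `entries`
#'   (`label`, `code`, `direction`, `score`), the `threshold`, and
#'   `skipped` (codes with zero MAD).
#' @export
flag_outliers <- function(table, threshold = 3.5) {
  stopifnot(inherits(table, "mms_table"), threshold > 0)
  if (nrow(table$values) < 5L) stop("need at least 5 areas to flag outliers")
  entries <- list()
  skipped <- character(0)
  for (code in colnames(table$values)) {
    x <- table$values[, code]
    ok <- !is.na(x)
    med <- stats::median(x[ok])
    mad <- stats::mad(x[ok], constant = 1)
    if (!is.finite(mad) || mad == 0) {
      skipped <- c(skipped, code)
      next
    }
    score <- (x - med) / (1.4826 * mad)
    hit <- ok & abs(score) >= threshold
    if (any(hit)) {
      entries[[length(entries) + 1L]] <- data.frame(
        label = names(x)[hit], code = code,
        direction = ifelse(score[hit] > 0, "high", "low"),
        score = unname(score[hit])
      )
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else {
    data.frame(label = character(0), code = character(0),
               direction = character(0), score = numeric(0))
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, threshold = threshold,
                 dataset = table$dataset, skipped = skipped),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report (%s, |robust z| >= %g): %d flags\n",
              x$dataset, x$threshold, nrow(x$entries)))
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  if (length(x$skipped)) {
    cat("skipped (zero MAD):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Outlier processing policy
#'
#' Maps area labels to actions: `drop` removes the area from every
#' dataset, `winsorize` replaces its values on the listed indicators by a
#' high percentile of the other areas' distribution, `keep` leaves it
#' unchanged. Which flagged areas to drop versus adjust is domain-expert
#' input (connectivity with the rest of the system), so the policy is
#' explicit configuration.
#'
#' @param drop character vector of area labels to remove.
#' @param winsorize named list, area label -> character vector of
#'   indicator codes to adjust.
#' @param keep character vector of labels explicitly kept (documentation
#'   only).
#' @param percentile winsorization percentile, in (50, 100); default 97.5.
#' @return An object of class `outlier_policy`.
#' @export
outlier_policy <- function(drop = character(0), winsorize = list(),
                           keep = character(0), percentile = 97.5) {
  stopifnot(percentile > 50, percentile < 100)
  if (length(winsorize)) stopifnot(!is.null(names(winsorize)))
  structure(list(drop = drop, winsorize = winsorize, keep = keep,
                 percentile = percentile),
            class = "outlier_policy")
}

#' The bundled three-region outlier processing preset
#'
#' Drops the three remote Catalonia availability outliers (C63, C64, C74)
#' and the privately-managed Biscay utilisation outlier (B19), and
#' winsorizes the re-admission indicator U3 of the three urban,
#' well-connected Catalonia outliers (C17, C25, C35) to the 97.5th
#' percentile of the remaining areas. Applied to the bundled 106-area
#' system this leaves 102 areas in every dataset.
#'
#' @return An [outlier_policy()].
#' @export
paper_preset_policy <- function() {
  outlier_policy(
    drop = c("C63", "C64", "C74", "B19"),
    winsorize = list(C17 = "U3", C25 = "U3", C35 = "U3"),
    keep = character(0),
    percentile = 97.5
  )
}

#' Apply an outlier policy to an aligned set of MMS tables
#'
#' Dropped areas are removed from every table so the datasets stay
#' row-aligned. Winsorized cells are replaced by the policy percentile
#' (linear interpolation between order statistics) of that indicator
#' computed over all other areas, i.e. excluding dropped areas and the
#' areas being winsorized on that indicator. No other cell changes.
#'
#' @param tables named list of [mms_table()] objects over one area set.
#' @param policy an [outlier_policy()].
#' @return Named list of processed `mms_table` objects.
#' @export
apply_policy <- function(tables, policy) {
  stopifnot(inherits(policy, "outlier_policy"))
  labels <- tables[[1L]]$areas$label
  targets <- c(policy$drop, names(policy$winsorize), policy$keep)
  unknown <- setdiff(targets, labels)
  if (length(unknown)) {
    stop("policy references unknown area label(s): ",
         paste(unknown, collapse = ", "))
  }
  keep_rows <- !(labels %in% policy$drop)
  lapply(tables, function(tab) {
    v <- tab$values[keep_rows, , drop = FALSE]
    for (lab in names(policy$winsorize)) {
      if (!(lab %in% rownames(v))) next   # dropped as well
      for (code in policy$winsorize[[lab]]) {
        if (!code %in% colnames(v)) next  # indicator lives in another table
        donors <- setdiff(rownames(v), names(policy$winsorize)[
          vapply(policy$winsorize, function(cc) code %in% cc, logical(1L))])
        x <- v[donors, code]
        x <- x[!is.na(x)]
        if (!length(x)) stop("no donor values to winsorize ", code)
        v[lab, code] <- stats::quantile(x, policy$percentile / 100,
                                        type = 7, names = FALSE)
      }
    }
    mms_table(tab$dataset, tab$areas[keep_rows, , drop = FALSE], v,
              tab$indicators)
  })
}
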