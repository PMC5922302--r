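#' Five-level qualitative category scale over an indicator range
#'
#' Divides the observed range `[min, max]` of an indicator into five equal
#' 20% intervals labelled `low`, `low-medium`, `medium`, `medium-high`,
#' `high`. Intervals are left-closed and right-open; the top interval is
#' closed so that `max` categorizes as `high`.
#'
#' @param min,max numeric range bounds in the indicator's original units;
#'   `max` must exceed `min`.
#' @return An object of class `category_scale` with elements `min`, `max`,
#'   `levels` (character, length 5) and `boundaries` (the four interior
#'   cut points at `min + k * 0.2 * (max - min)`, k = 1..4).
#' @examples
#' sc <- make_scale(0, 10)
#' sc$boundaries   # 2 4 6 8
#' categorize(5, sc)
#' @export
make_scale <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1L, length(max) == 1L)
  if (!is.finite(min) || !is.finite(max)) {
    stop("scale bounds must be finite")
  }
  if (max <= min) {
    stop("category scale requires max > min (got [", min, ", ", max, "])")
  }
  structure(
    list(
      min = min,
      max = max,
      levels = c("low", "low-medium", "medium", "medium-high", "high"),
      boundaries = min + (max - min) * (1:4) / 5
    ),
    class = "category_scale"
  )
}

#' Categorize a value on a five-level 20%-interval scale
#'
#' Values outside `[min, max]` clamp to the end labels rather than erroring:
#' winsorization and region-averaged estimation can push a value slightly
#' past the observed bounds without changing its qualitative reading.
#'
#' @param value numeric vector of values in the indicator's original units.
#' @param scale a [make_scale()] object.
#' @return Character vector of level labels, one per value.
#' @examples
#' sc <- make_scale(0.16, 5.23)
#' categorize(c(3.00, 1.94), sc)   # "medium" "low-medium"
#' @export
categorize <- function(value, scale) {
  stopifnot(inherits(scale, "category_scale"), is.numeric(value))
  if (any(!is.finite(value))) stop("values to categorize must be finite")
  # left-closed, right-open; findInterval counts boundaries <= value,
  # which is exactly the left-closed convention at interior cuts
  idx <- findInterval(value, scale$boundaries) + 1L
  idx[value < scale$min] <- 1L
  idx[value >= scale$max] <- 5L
  scale$levels[idx]
}

#' @export
print.category_scale <- function(x, ...) {
  cuts <- format(c(x$min, x$boundaries, x$max), digits = 6)
  cat("Five-level 20%-interval scale on [", cuts[1L], ", ", cuts[6L], "]\n", sep = "")
  for (k in 1:5) {
    cat(sprintf("  %-11s [%s, %s%s\n", x$levels[k], cuts[k], cuts[k + 1L],
                if (k == 5) "]" else ")"))
  }
  invisible(x)
}
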