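# Quality filtering of raw position fixes.

#' Define a quality filter
#'
#' A fix is retained iff `dop < dop_max`, `cn < cn_max`, `rn > rn_min`, and
#' (when a perimeter is given) the fix lies inside the lake perimeter. The
#' shipped defaults mirror the two-stage practice for these systems: a
#' permissive raw filter (DOP < 10, CN < 10, RN > 0) and a strict filter
#' (DOP < 1, CN < 10, RN > 1) ahead of HMM smoothing. The published
#' inequalities are read as retention conditions (see the methods vignette
#' for the reading of the thresholds).
#'
#' @param dop_max,cn_max Upper thresholds (exclusive), `dop_max > 0`,
#'   `cn_max >= 1`.
#' @param rn_min Lower threshold (exclusive) on the redundancy number.
#' @param perimeter Optional polygon (tibble with `x`, `y`).
#' @return A list of class `apt_filter_spec`.
#' @export
filter_spec <- function(dop_max, cn_max, rn_min, perimeter = NULL) {
  stopifnot(dop_max > 0, cn_max >= 1)
  structure(list(dop_max = dop_max, cn_max = cn_max, rn_min = rn_min,
                 perimeter = perimeter),
            class = "apt_filter_spec")
}

#' @rdname filter_spec
#' @export
raw_filter_spec <- function(perimeter = NULL)
  filter_spec(10, 10, 0, perimeter)

#' @rdname filter_spec
#' @export
strict_filter_spec <- function(perimeter = NULL)
  filter_spec(1, 10, 1, perimeter)

#' Partition fixes by a quality filter
#'
#' @param fixes Fix tibble with `dop`, `cn`, `rn` (and `x_m`, `y_m` when the
#'   spec carries a perimeter).
#' @param spec An [filter_spec()].
#' @return List with tibbles `kept` and `dropped`; together they partition
#'   the input.
#' @export
apply_quality_filter <- function(fixes, spec) {
  stopifnot(inherits(spec, "apt_filter_spec"))
  if (nrow(fixes) == 0) return(list(kept = fixes, dropped = fixes))
  ok <- fixes$dop < spec$dop_max & fixes$cn < spec$cn_max &
    fixes$rn > spec$rn_min
  ok[is.na(ok)] <- FALSE
  if (!is.null(spec$perimeter)) {
    ok <- ok & point_in_polygon(fixes$x_m, fixes$y_m, spec$perimeter)
  }
  list(kept = fixes[ok, , drop = FALSE], dropped = fixes[!ok, , drop = FALSE])
}
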