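#' @title Generics
#' @name AmpBias-generics
#' @keywords internal
NULL

#' Coefficient of variation of coverage depth
#'
#' 100 times the sample standard deviation of per-base depth divided by the
#' mean per-base depth, per contig. Computed on the full per-base depth
#' vector (no edge exclusion). Returns `NA` when the mean depth is zero.
#'
#' @param x a [DepthProfile-class] or a numeric depth vector.
#' @param ... unused.
#' @return percent CV (numeric scalar), `NA` if mean depth is 0.
#' @examples
#' coverageCV(c(2, 4)) # 47.14%
#' @export
setGeneric("coverageCV", function(x, ...) standardGeneric("coverageCV"))

#' Windowed depth view of a profile
#'
#' Mean depth over non-overlapping tiles of `window_size` bp, excluding any
#' tile whose span intersects the first or last `edge_exclusion` bp.
#'
#' @param x a [DepthProfile-class].
#' @param ... unused.
#' @return data.frame with columns `start` (0-based), `end` (exclusive) and
#'   `mean_depth`; zero rows when no window survives the edge rule.
#' @export
setGeneric("windowedDepth", function(x, ...) standardGeneric("windowedDepth"))
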