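#' Spatial block index of a coordinate
#'
#' Assigns each coordinate pair to an axis-aligned grid cell of
#' `cell_deg` degrees (default 0.1 degrees = 6 arcmin). The index is
#' `floor(coord / cell_deg)` per axis, with a tiny rounding guard so that
#' values that are representable multiples of the cell size land in the
#' cell they nominally start (e.g. `-0.1 / 0.1` is exactly `-1`, not `-2`).
#'
#' @param lon,lat Numeric vectors of coordinates in degrees.
#' @param cell_deg Cell size in degrees.
#' @return A tibble with `east`, `north` (integer grid indices) and
#'   `block` (a "east:north" key).
#' @export
block_id <- function(lon, lat, cell_deg = 0.1) {
  assert_that(all(lon >= -180 & lon <= 180, na.rm = FALSE) &&
                all(lat >= -90 & lat <= 90),
              "coordinates out of range")
  guard <- 1e-9
  east <- as.integer(floor(lon / cell_deg + guard))
  north <- as.integer(floor(lat / cell_deg + guard))
  tibble(east = east, north = north,
         block = paste(east, north, sep = ":"))
}

#' Assign spatial blocks to folds, balancing plot counts
#'
#' Greedy longest-processing-time scheduling: blocks are sorted by
#' descending plot count (ties by block key) and each is assigned to the
#' currently lightest fold (ties by lowest fold index). Every plot of a
#' block lands in the block's fold, so near-duplicate plots from the same
#' cell can never straddle a train/test boundary, and fold sizes are
#' approximately equal even when plots cluster heavily in space.
#'
#' @param block_counts Named integer vector: plots per block.
#' @param k Number of folds.
#' @param seed Unused by the deterministic scheduler; kept so callers can
#'   treat fold assignment like the other seeded operations.
#' @return A list of class `fold_assignment`: `k`, `block_fold` (named
#'   integer, folds 1..k) and `fold_sizes`.
#' @export
assign_folds <- function(block_counts, k = 10, seed = 1L) {
  assert_that(is_count(k), "k must be a positive integer")
  assert_that(k <= length(block_counts),
              "k exceeds the number of spatial blocks")
  ord <- order(-block_counts, names(block_counts), method = "radix")
  loads <- numeric(k)
  fold <- integer(length(block_counts))
  for (i in ord) {
    f <- which.min(loads)
    fold[i] <- f
    loads[f] <- loads[f] + block_counts[i]
  }
  structure(list(k = as.integer(k),
                 block_fold = stats::setNames(fold, names(block_counts)),
                 fold_sizes = loads),
            class = "fold_assignment")
}

#' Spatial block cross-validation folds for a header table
#'
#' Convenience wrapper: blocks the plots with [block_id()], balances the
#' blocks into `k` folds with [assign_folds()], and returns the per-plot
#' assignment.
#'
#' @param headers A `veg_headers` tibble.
#' @param k Number of folds.
#' @param cell_deg Block size in degrees.
#' @param seed Passed to [assign_folds()].
#' @return A tibble `plot_id`, `block`, `fold`.
#' @export
spatial_folds <- function(headers, k = 10, cell_deg = 0.1, seed = 1L) {
  blocks <- block_id(headers$lon, headers$lat, cell_deg)
  counts <- table(blocks$block)
  fa <- assign_folds(stats::setNames(as.integer(counts), names(counts)),
                     k = k, seed = seed)
  tibble(plot_id = headers$plot_id,
         block = blocks$block,
         fold = unname(fa$block_fold[blocks$block]))
}
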