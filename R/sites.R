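# Monitoring-site resolution: one canonical (MLI, x, y) per physical site.
#
# Two passes, in this order: coordinate duplicates for one MLI are merged
# when every pairwise Euclidean distance is within the configured threshold
# (merging can create the exact coordinate equality the second pass needs);
# then MLI duplicates at one exact coordinate pair collapse to the MLI that
# appears first in input order.

#' Resolve duplicate coordinates for a Monitoring Location Identifier
#'
#' For each MLI reported with more than one distinct coordinate pair: if all
#' pairwise Euclidean distances are within \code{threshold_m}, every record
#' receives the coordinate pair that appears first in input
#' (\code{record_id}) order and \code{combine_coords_flag = "combine"};
#' otherwise the coordinates are left untouched and flagged
#' \code{"keep_separate"}. Distances exactly at the threshold merge. MLIs
#' with a single coordinate pair are flagged \code{"one_coord_set"}.
#' Records with missing coordinates pass through unflagged.
#'
#' @param records Data frame with columns \code{record_id},
#'   \code{orig_MLI}, \code{orig_x}, \code{orig_y}.
#' @param threshold_m Merge threshold in meters (default 400).
#' @return \code{records} with columns \code{new_x}, \code{new_y},
#'   \code{num_coords_at_loc}, \code{dup_coords_flag},
#'   \code{combine_coords_flag} added.
#' @export
resolve_coordinates <- function(records, threshold_m = 400) {
  n <- nrow(records)
  ord <- order(records$record_id)
  new_x <- records$orig_x
  new_y <- records$orig_y
  num_coords <- rep(NA_integer_, n)
  dup_flag <- rep(NA_character_, n)
  combine_flag <- rep(NA_character_, n)

  has_xy <- !is.na(records$orig_x) & !is.na(records$orig_y)
  idx <- ord[has_xy[ord]]                      # record_id order, coords present
  for (rows in split(idx, records$orig_MLI[idx])) {
    key <- paste(records$orig_x[rows], records$orig_y[rows])
    first <- rows[!duplicated(key)]            # first appearance of each pair
    k <- length(first)
    num_coords[rows] <- k
    if (k == 1L) {
      dup_flag[rows] <- "one_coord_set"
      next
    }
    dup_flag[rows] <- "dup_coords"
    xs <- records$orig_x[first]; ys <- records$orig_y[first]
    dmax <- max(dist(cbind(xs, ys)))
    if (dmax <= threshold_m) {
      combine_flag[rows] <- "combine"
      new_x[rows] <- xs[1L]
      new_y[rows] <- ys[1L]
    } else {
      combine_flag[rows] <- "keep_separate"
    }
  }
  records$new_x <- new_x
  records$new_y <- new_y
  records$num_coords_at_loc <- num_coords
  records$dup_coords_flag <- dup_flag
  records$combine_coords_flag <- combine_flag
  records
}

#' Resolve duplicate MLIs at one coordinate pair
#'
#' After coordinate resolution, each exact \code{(new_x, new_y)} pair
#' reported under more than one MLI collapses to the MLI that appears first
#' in input (\code{record_id}) order; the original MLI is retained in
#' \code{orig_MLI}.
#'
#' @param records Data frame with \code{record_id}, \code{orig_MLI},
#'   \code{new_x}, \code{new_y} (from \code{\link{resolve_coordinates}}).
#' @return \code{records} with \code{new_MLI}, \code{num_MLIs_at_loc},
#'   \code{dup_MLI_flag} added.
#' @export
resolve_mlis <- function(records) {
  n <- nrow(records)
  ord <- order(records$record_id)
  new_mli <- records$orig_MLI
  num_mlis <- rep(1L, n)
  dup_flag <- rep("one_MLI", n)

  has_xy <- !is.na(records$new_x) & !is.na(records$new_y)
  idx <- ord[has_xy[ord]]
  key <- paste(records$new_x[idx], records$new_y[idx])
  for (rows in split(idx, key)) {
    mlis <- unique(records$orig_MLI[rows])
    num_mlis[rows] <- length(mlis)
    if (length(mlis) > 1L) {
      dup_flag[rows] <- "dup_MLI"
      new_mli[rows] <- mlis[1L]                # first appearance wins
    }
  }
  num_mlis[!has_xy] <- NA_integer_
  dup_flag[!has_xy] <- NA_character_
  records$new_MLI <- new_mli
  records$num_MLIs_at_loc <- num_mlis
  records$dup_MLI_flag <- dup_flag
  records
}

#' Resolve monitoring sites
#'
#' Convenience wrapper running \code{\link{resolve_coordinates}} then
#' \code{\link{resolve_mlis}}.
#'
#' @inheritParams resolve_coordinates
#' @return The records with all site-resolution columns added.
#' @export
resolve_sites <- function(records, threshold_m = 400) {
  resolve_mlis(resolve_coordinates(records, threshold_m))
}
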