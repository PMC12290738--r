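#' Layout of local-continuous units over a 3D volume
#'
#' A 3D volume of shape L x H x W (slices along the first axis) is split into
#' \code{K} uniform segments along the slice axis.  A unit stacks one clip of
#' \code{2J + 1} consecutive slices from every segment into a
#' \code{K (2J + 1)} channel 2D image, so a 2D network sees both local slice
#' continuity (within a clip) and global coverage (one clip per segment).
#'
#' When \code{K} does not divide \code{L}, earlier segments receive the extra
#' slices (segment lengths differ by at most one).  When \code{K (2J + 1)}
#' does not divide \code{L}, the trailing clip(s) of a segment are completed
#' by replicating the segment's last slice; replicated outputs are dropped at
#' reassembly so that every real slice is generated exactly once.
#'
#' @param L,H,W volume dimensions (slices, height, width), positive integers.
#' @param K number of segments along the slice axis.
#' @param J neighbour slices on each side of a clip centre (clip length
#'   \code{2J + 1}).  Every segment must be at least one clip long.
#' @return An object of class \code{"unit_layout"}: list with the dimensions,
#'   \code{clip_len}, \code{segment_bounds} (K x 2 matrix of half-open
#'   0-based intervals), \code{units_per_volume}, and \code{pad_plan} (number
#'   of replicated slots per segment).
#' @examples
#' unit_layout(12, 16, 16, K = 2, J = 1)
#' @export
unit_layout <- function(L, H, W, K = 5L, J = 1L) {
  for (nm in c("L", "H", "W"))
    if (get(nm) < 1 || get(nm) != round(get(nm)))
      stop(sprintf("'%s' must be a positive integer", nm))
  if (K < 1 || K != round(K)) stop("'K' must be a positive integer")
  if (J < 0 || J != round(J)) stop("'J' must be a non-negative integer")
  L <- as.integer(L); H <- as.integer(H); W <- as.integer(W)
  K <- as.integer(K); J <- as.integer(J)
  clip_len <- 2L * J + 1L
  base <- L %/% K; extra <- L %% K
  seg_len <- base + as.integer(seq_len(K) <= extra)
  if (min(seg_len) < clip_len)
    stop(sprintf("segment length %d shorter than clip length %d; reduce K or J",
                 min(seg_len), clip_len))
  seg_start <- cumsum(c(0L, seg_len[-K]))
  units_per_volume <- as.integer(ceiling(L / (K * clip_len)))
  pad_plan <- units_per_volume * clip_len - seg_len
  structure(list(L = L, H = H, W = W, K = K, J = J, clip_len = clip_len,
                 segment_bounds = cbind(start = seg_start,
                                        end = seg_start + seg_len),
                 units_per_volume = units_per_volume,
                 pad_plan = pad_plan),
            class = "unit_layout")
}

#' @export
print.unit_layout <- function(x, ...) {
  cat(sprintf(
    "Unit layout: %d x %d x %d volume, K = %d segments, clips of %d slices\n",
    x$L, x$H, x$W, x$K, x$clip_len))
  cat(sprintf("  unit shape %d x %d x %d; %d generation units; %d padded slots\n",
              x$H, x$W, x$K * x$clip_len, x$units_per_volume, sum(x$pad_plan)))
  invisible(x)
}

#' Ordered generation units of a layout
#'
#' The i-th generation unit takes the i-th consecutive clip from every
#' segment.  Across all units every real slice index appears exactly once;
#' slots beyond a segment's end replicate its last slice and are flagged
#' \code{real = FALSE} (dropped at reassembly).
#'
#' @param layout a [unit_layout()].
#' @return List of length \code{units_per_volume}; each element has
#'   \code{indices} (1-based slice indices, length \code{K * clip_len}) and
#'   \code{real} (logical, same length).
#' @export
generation_units <- function(layout) {
  cl <- layout$clip_len
  lapply(seq_len(layout$units_per_volume), function(i) {
    idx <- integer(0); real <- logical(0)
    for (s in seq_len(layout$K)) {
      a <- layout$segment_bounds[s, "start"]
      len <- layout$segment_bounds[s, "end"] - a
      off <- (i - 1L) * cl + seq_len(cl) - 1L     # 0-based within segment
      r <- off < len
      off[!r] <- len - 1L                         # replicate last slice
      idx <- c(idx, a + off + 1L)                 # 1-based
      real <- c(real, r)
    }
    list(indices = idx, real = real)
  })
}

#' Randomly sample one training unit from a volume
#'
#' Draws one clip centre uniformly from each segment, skipping the first and
#' last \code{J} slices of the segment so that the full clip stays inside it,
#' and stacks the K clips in segment order.  Uses R's global RNG stream.
#'
#' @param volume L x H x W array matching the layout.
#' @param layout a [unit_layout()].
#' @return H x W x \code{K*clip_len} unit array with attribute
#'   \code{"indices"} (the source slice indices in volume order).
#' @export
sample_training_unit <- function(volume, layout) {
  check_volume(volume, layout)
  idx <- integer(0)
  for (s in seq_len(layout$K)) {
    a <- layout$segment_bounds[s, "start"]
    b <- layout$segment_bounds[s, "end"]
    centre <- if (b - a == layout$clip_len) a + layout$J else
      a + layout$J + sample.int(b - a - 2L * layout$J, 1L) - 1L
    idx <- c(idx, (centre - layout$J):(centre + layout$J) + 1L)
  }
  extract_unit(volume, idx)
}

#' Extract a unit (slice stack) from a volume
#'
#' @param volume L x H x W array.
#' @param indices 1-based slice indices along the first axis.
#' @return H x W x \code{length(indices)} array with the indices attached as
#'   attribute \code{"indices"}.
#' @export
extract_unit <- function(volume, indices) {
  if (any(indices < 1L) || any(indices > dim(volume)[1]))
    stop("slice indices out of range")
  u <- aperm(volume[indices, , , drop = FALSE], c(2, 3, 1))
  attr(u, "indices") <- as.integer(indices)
  u
}

#' Reassemble generated units into a volume
#'
#' The inverse of extracting units at the layout's generation indices: each
#' unit's channels are written back to their source slices; replicated
#' padding slots are discarded.  Units may be supplied in any order; they are
#' matched to generation units by their \code{"indices"} attribute.
#'
#' @param units list of H x W x \code{K*clip_len} arrays, each carrying an
#'   \code{"indices"} attribute, jointly covering the layout's generation
#'   units.
#' @param layout a [unit_layout()].
#' @return L x H x W volume.
#' @export
assemble_units <- function(units, layout) {
  gus <- generation_units(layout)
  keys <- vapply(gus, function(g) paste(g$indices, collapse = ","), "")
  vol <- array(NA_real_, dim = c(layout$L, layout$H, layout$W))
  seen <- logical(length(gus))
  for (u in units) {
    idx <- attr(u, "indices")
    if (is.null(idx)) stop("unit lacks an 'indices' attribute")
    k <- match(paste(idx, collapse = ","), keys)
    if (is.na(k)) stop("unit indices do not match any generation unit")
    if (seen[k]) stop("duplicated generation unit")
    seen[k] <- TRUE
    g <- gus[[k]]
    for (j in which(g$real)) vol[g$indices[j], , ] <- u[, , j]
  }
  if (!all(seen)) stop("missing generation units: volume coverage incomplete")
  vol
}

check_volume <- function(volume, layout) {
  if (!all(dim(volume) == c(layout$L, layout$H, layout$W)))
    stop("volume shape does not match layout")
  invisible(TRUE)
}
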