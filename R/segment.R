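#' Automatic intensity threshold by Otsu's method
#'
#' Builds a 256-bin histogram over the image's intensity range and returns
#' the bin edge that maximizes the between-class variance of the two
#' classes it induces (Otsu's criterion). Ties are broken toward the lower
#' threshold. Class means are computed from bin midpoints, so the result is
#' exactly the value an exhaustive search over the 255 candidate bin edges
#' would return.
#'
#' @param image a numeric matrix of non-negative finite intensities (at
#'   least 2 x 2 pixels), or a `nucleus_pair` channel matrix.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold intensity (numeric scalar); pixels strictly above
#'   it form the foreground class. The attribute `method` records
#'   `"otsu"` so alternative auto-threshold variants can be added behind
#'   the same contract.
#' @export
#' @examples
#' img <- matrix(c(rep(10, 100), rep(200, 100)), 10, 20)
#' auto_threshold(img)
auto_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  if (length(x) < 4L) stop("auto_threshold: image must be at least 2 x 2",
                           call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("auto_threshold: intensities must be finite and non-negative",
         call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("auto_threshold: degenerate input (constant image)", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  p <- counts / length(x)
  w0 <- cumsum(p)[-n_bins]            # class 0 = bins 1..k
  m0 <- cumsum(p * mids)[-n_bins]     # unnormalized class-0 mean
  mt <- sum(p * mids)
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)             # which.max takes the first (lowest) tie
  structure(breaks[k + 1L], method = "otsu")
}

# label 8-connected components of a logical matrix; returns integer matrix
# (0 = background). EBImage::bwlabel is 4-connected, so diagonal adjacency
# is resolved here through an explicit pixel graph.
.label8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  fgid <- integer(nr * nc)
  fgid[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  row0 <- ((idx - 1L) %% nr) + 1L
  col0 <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- row0 + s[1L]; c2 <- col0 + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- fg[j]
    if (any(keep)) {
      edges[[length(edges) + 1L]] <-
        cbind(fgid[idx[ok][keep]], fgid[j[keep]])
    }
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  lab[idx] <- as.integer(memb)
  lab
}

#' Segment the nucleus from the diffuse (YFP) channel
#'
#' Reproduces the nucleus-edge identification step of mintbody-based
#' co-localization analysis: the sparse nucleus-wide reporter distribution
#' is auto-thresholded ([auto_threshold()]), the image is binarized, the
#' largest 8-connected foreground component is kept, and interior holes
#' (e.g. locus-dark or heterochromatin-dark pixels) are filled so the
#' correlation domain is a solid region.
#'
#' A threshold alone cannot tell "nucleus" from "noise": on an image with
#' no real structure, Otsu still splits the noise distribution and the
#' spurious foreground percolates into one large component. The segmenter
#' therefore also requires genuine class separation: the foreground and
#' background means must differ by at least `min_separation` pooled
#' within-class standard deviations, otherwise the image is declared to
#' contain no nucleus.
#'
#' @param yfp numeric intensity matrix of the diffuse channel.
#' @param min_area_px minimum acceptable component area in pixels (default
#'   50); smaller largest-components raise a segmentation failure.
#' @param min_separation minimum (foreground mean - background mean) /
#'   pooled within-class sd required to accept the thresholding (default 3).
#' @return An object of class `nucleus_mask`: list with `mask` (logical
#'   matrix, one filled 8-connected component), `area_px`, `threshold_used`
#'   and `method`.
#' @export
#' @examples
#' sim <- simulate_nucleus(preset_params("her1", seed = 1))
#' m <- segment_nucleus(sim$pair$yfp)
#' m$area_px
segment_nucleus <- function(yfp, min_area_px = 50L, min_separation = 3) {
  thr <- auto_threshold(yfp)
  fg <- yfp > as.numeric(thr)
  lab <- .label8(fg)
  if (max(lab) == 0L)
    stop("segment_nucleus: nucleus not found (no foreground)", call. = FALSE)
  hi <- yfp[fg]; lo <- yfp[!fg]
  v0 <- function(x) if (length(x) > 1L) stats::var(x) else 0
  pooled <- sqrt((length(hi) * v0(hi) + length(lo) * v0(lo)) / length(yfp))
  if (is.finite(pooled) && pooled > 0 &&
      (mean(hi) - mean(lo)) / pooled < min_separation)
    stop("segment_nucleus: nucleus not found (intensity classes not separable)",
         call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which.max(sizes)
  mask <- lab == biggest
  # fill interior holes; EBImage::fillHull operates on 0/1 rasters
  mask <- EBImage::fillHull(mask * 1L) > 0
  area <- sum(mask)
  if (area < min_area_px)
    stop(sprintf(
      "segment_nucleus: nucleus not found (largest component %d px < %d px)",
      area, as.integer(min_area_px)), call. = FALSE)
  structure(list(mask = mask, area_px = as.integer(area),
                 threshold_used = as.numeric(thr),
                 method = attr(thr, "method")),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d px at threshold %.4g (%s)\n",
              x$area_px, x$threshold_used, x$method))
  invisible(x)
}
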