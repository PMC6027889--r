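#' Write one nucleus pair as a two-page 16-bit TIFF
#'
#' Channel pages are written in the order YFP then CFP (the manifest
#' convention; see `channel_order` in [read_nucleus_tiff()] for microscope
#' exports that differ). Intensities are treated as arbitrary-unit floats
#' internally and stored as 16-bit unsigned integers with saturation
#' clipping at 65535; simulated noisy images are already integer detector
#' units, so writing and re-reading them is exact. A sidecar JSON
#' (`<path>.json`) records the simulation parameters and ground truth when
#' present; the true nucleus mask is not serialized because it is a filled
#' disk fully determined by the recorded centre and radius.
#'
#' @param pair a `nucleus_pair`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_nucleus_tiff <- function(pair, path) {
  stopifnot(inherits(pair, "nucleus_pair"))
  enc <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(enc(pair$yfp), enc(pair$cfp)), path,
                  bits.per.sample = 16L)
  side <- list(nucleus_id = pair$nucleus_id, group = pair$group,
               frame = pair$frame, time_min = pair$time_min)
  if (!is.null(pair$params)) side$params <- unclass(pair$params)
  if (!is.null(pair$truth)) {
    tr <- pair$truth
    side$truth <- list(spot_position = tr$spot_position,
                       enrichment_used = tr$enrichment_used,
                       expression_factor = tr$expression_factor,
                       territory_centers = tr$territory_centers,
                       spot_track = tr$spot_track)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read one two-channel nucleus TIFF
#'
#' @param path TIFF path written by [write_nucleus_tiff()] or any two-page
#'   (or two-sample) grayscale TIFF.
#' @param channel_order which channel comes first in the file; default
#'   `c("YFP", "CFP")`.
#' @return A `nucleus_pair`. When a sidecar JSON is present, simulation
#'   parameters and ground truth (with the true disk mask reconstructed)
#'   are restored.
#' @export
read_nucleus_tiff <- function(path, channel_order = c("YFP", "CFP")) {
  stopifnot(length(channel_order) == 2L,
            setequal(channel_order, c("YFP", "CFP")))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    a <- pages[[1]]
    pages <- list(a[, , 1L], a[, , 2L])
  }
  if (length(pages) != 2L)
    stop(sprintf("read_nucleus_tiff: '%s' does not hold exactly 2 channels",
                 path), call. = FALSE)
  chans <- lapply(pages, function(m) round(m * 65535))
  names(chans) <- channel_order
  pair <- .new_pair(chans[["YFP"]], chans[["CFP"]],
                    nucleus_id = tools::file_path_sans_ext(basename(path)),
                    group = NA_character_, frame = 0L, time_min = 0,
                    params = NULL, truth = NULL)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pair$nucleus_id <- side$nucleus_id %||% pair$nucleus_id
    pair$group <- side$group %||% NA_character_
    pair$frame <- as.integer(side$frame %||% 0L)
    pair$time_min <- as.numeric(side$time_min %||% 0)
    if (!is.null(side$params)) {
      pr <- side$params
      pr$image_size <- as.integer(pr$image_size)
      pair$params <- do.call(sim_params, pr)
    }
    if (!is.null(side$truth) && !is.null(pair$params)) {
      tr <- side$truth
      tc <- tr$territory_centers
      if (is.matrix(tc)) tc <- lapply(seq_len(nrow(tc)), function(i) tc[i, ])
      pair$truth <- structure(list(
        true_mask = .true_mask(pair$params),
        spot_position = as.numeric(tr$spot_position),
        enrichment_used = tr$enrichment_used,
        expression_factor = tr$expression_factor,
        territory_centers = tc,
        spot_track = if (!is.null(tr$spot_track))
          matrix(unlist(tr$spot_track), ncol = 2L,
                 dimnames = list(NULL, c("row", "col"))) else NULL),
        class = "ground_truth")
    }
  }
  pair
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort of nucleus pairs to a directory
#'
#' Writes one two-page TIFF (plus sidecar JSON) per nucleus and a manifest
#' CSV (`manifest.csv`, columns `path`, `group`, `nucleus_id`, `frame`)
#' indexing them.
#'
#' @param pairs list of `nucleus_pair` objects.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(pairs, dir) {
  stopifnot(length(pairs) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(pairs, function(p) {
    fn <- sprintf("%s_f%02d.tif", p$nucleus_id, p$frame)
    write_nucleus_tiff(p, file.path(dir, fn))
    data.frame(path = fn, group = p$group, nucleus_id = p$nucleus_id,
               frame = p$frame, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the TIFFs it lists.
#' @param channel_order see [read_nucleus_tiff()].
#' @return A list of `nucleus_pair` objects in manifest order. Unreadable
#'   entries are returned as objects of class `nucleus_read_error` (with
#'   `nucleus_id`, `path`, `message`) rather than dropped.
#' @export
read_cohort <- function(dir, channel_order = c("YFP", "CFP")) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp))
    stop(sprintf("read_cohort: no manifest.csv in '%s'", dir), call. = FALSE)
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  if (!nrow(manifest))
    stop("read_cohort: manifest is empty", call. = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    path <- file.path(dir, row$path)
    out <- tryCatch(read_nucleus_tiff(path, channel_order),
                    error = function(e) {
                      structure(list(nucleus_id = row$nucleus_id,
                                     path = path,
                                     message = conditionMessage(e)),
                                class = "nucleus_read_error")
                    })
    if (inherits(out, "nucleus_pair")) {
      out$group <- row$group
      out$nucleus_id <- row$nucleus_id
      out$frame <- as.integer(row$frame)
    }
    out
  })
}

#' Export a nucleus mask as an 8-bit TIFF
#'
#' Writes the mask as a single-channel 8-bit image (background 0,
#' nucleus 255), the conventional exchange format for binary masks.
#'
#' @param mask a `nucleus_mask` or logical matrix.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (inherits(mask, "nucleus_mask")) mask <- mask$mask
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)  # 1.0 -> 255
  invisible(path)
}
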