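#' Construct a three-channel field-of-view image
#'
#' A field image holds three registered 2-D intensity matrices: a nuclear
#' stain channel (e.g. DAPI), the EGFP (green) channel and the mCherry (red)
#' channel of the tandem LC3B reporter. All downstream quantification
#' consumes this container.
#'
#' @param nuclei,green,red numeric matrices of identical dimensions with
#'   finite, nonnegative intensities.
#' @param pixel_size_um optional physical pixel size in micrometres.
#' @param source_id free-text identifier carried into results tables.
#' @return an object of class \code{field_image} with elements
#'   \code{channels} (named list of the three matrices),
#'   \code{pixel_size_um} and \code{source_id}.
#' @export
field_image <- function(nuclei, green, red, pixel_size_um = NULL,
                        source_id = "") {
  chans <- list(nuclei = nuclei, green = green, red = red)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop(sprintf("channel '%s' must be a numeric matrix", nm), call. = FALSE)
    if (any(!is.finite(ch)))
      stop(sprintf("channel '%s' contains non-finite values", nm), call. = FALSE)
    if (any(ch < 0))
      stop(sprintf("channel '%s' contains negative intensities", nm), call. = FALSE)
  }
  d <- dim(chans[[1]])
  if (!all(vapply(chans, function(ch) identical(dim(ch), d), logical(1))))
    stop("all three channels must share identical dimensions", call. = FALSE)
  structure(list(channels = chans,
                 pixel_size_um = pixel_size_um,
                 source_id = as.character(source_id)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels$nuclei)
  cat(sprintf("<field_image> %s  %d x %d px, channels: %s\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              d[1], d[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# 16-bit storage scale for TIFF round trips
.INT_SCALE <- 65535

#' Write a field image as a 16-bit multi-page TIFF
#'
#' Channels are stored as three pages in the fixed order nuclei, green, red
#' (the order [read_field_tiff()] assumes unless told otherwise). Intensities
#' are clipped to [0, 65535] and stored at 16-bit depth.
#'
#' @param image a [field_image()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_field_tiff <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  pages <- lapply(image$channels, function(ch)
    pmin(pmax(ch, 0), .INT_SCALE) / .INT_SCALE)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a field image
#'
#' @param path TIFF file with one page per channel.
#' @param channel_order character vector naming the page order; must be a
#'   permutation of \code{c("nuclei", "green", "red")}.
#' @param pixel_size_um,source_id passed to [field_image()];
#'   \code{source_id} defaults to the file name.
#' @return a [field_image()]. Intensities are rescaled back to 0-65535.
#' @export
read_field_tiff <- function(path, channel_order = c("nuclei", "green", "red"),
                            pixel_size_um = NULL, source_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!setequal(channel_order, c("nuclei", "green", "red")) ||
      length(channel_order) != 3L)
    stop("channel_order must be a permutation of nuclei, green, red",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L)
    stop(sprintf("expected a 3-page TIFF, got %d page(s): %s",
                 length(pages), path), call. = FALSE)
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grey stored as RGB
    pg * .INT_SCALE
  })
  names(pages) <- channel_order
  field_image(pages$nuclei, pages$green, pages$red,
              pixel_size_um = pixel_size_um,
              source_id = source_id %||% basename(path))
}
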