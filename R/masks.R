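#' Binary silhouette masks
#'
#' A binary mask is an integer matrix of 0/1 values, row-major with origin at
#' the top-left (row 1 = top of the image), where foreground (1) marks needle
#' or base-plate material. Masks carry their physical scale as an attribute so
#' downstream stages can convert between pixels and microns.
#'
#' @param pixels integer/logical matrix of 0/1 values.
#' @param scale an [image_scale()] giving microns per pixel.
#' @param geometry optional list describing the rendered array (needle
#'   centers, pitch, base-strip thickness); attached by the renderers.
#' @return an object of class `binary_mask` (an integer matrix with
#'   attributes).
#' @export
binary_mask <- function(pixels, scale = image_scale(), geometry = NULL) {
  if (is.logical(pixels)) {
    storage.mode(pixels) <- "integer"
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric or logical matrix")
  }
  if (!all(pixels %in% c(0L, 1L))) {
    stop("mask values must be strictly binary (0/1)")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "binary_mask", scale = scale, geometry = geometry)
}

#' @export
print.binary_mask <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<binary_mask %d x %d px, %.3g um/px, %d foreground px%s>\n",
              nrow(x), ncol(x), attr(x, "scale")$microns_per_pixel,
              sum(x), if (!is.null(g)) sprintf(", %d needles", g$n_needles) else ""))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

mask_scale <- function(mask) {
  sc <- attr(mask, "scale")
  if (is.null(sc)) image_scale() else sc
}

#' Physical image scale
#'
#' @param microns_per_pixel physical size of one pixel in microns. The default
#'   of 25 um/px makes a 150-pixel tile span 3750 um, enough for the tallest
#'   (3000 um) needle design plus the base strip.
#' @param tile_size side length, in pixels, of a single-needle tile.
#' @return a list of class `image_scale`.
#' @export
image_scale <- function(microns_per_pixel = 25, tile_size = 150) {
  stopifnot(microns_per_pixel > 0, tile_size >= 1)
  structure(list(microns_per_pixel = microns_per_pixel,
                 tile_size = as.integer(tile_size)),
            class = "image_scale")
}

# strip mask attributes, returning the bare integer matrix
mask_matrix <- function(mask) {
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  m
}

with_mask_attrs <- function(pixels, template) {
  binary_mask(pixels, scale = mask_scale(template),
              geometry = attr(template, "geometry"))
}

#' Read and write masks as 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask a [binary_mask()].
#' @param path file path.
#' @param scale scale to attach on read.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  png::writePNG(mask_matrix(mask) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, scale = image_scale()) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  binary_mask((img > 0.5) * 1L, scale = scale)
}

# Euclidean-distance-transform erosion/dilation by a disc of radius r pixels.
# distmap-based so that erosions at increasing radii are exactly nested.
erode_mask <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  d <- as.matrix(EBImage::distmap(mask_matrix(mask)))
  with_mask_attrs((d > r_px) * 1L, mask)
}

dilate_mask <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  d <- as.matrix(EBImage::distmap(1L - mask_matrix(mask)))
  with_mask_attrs((d <= r_px) * 1L, mask)
}

# connected components above the base strip; returns the component count
count_components_above_base <- function(mask, base_strip_um = NULL) {
  g <- attr(mask, "geometry")
  if (is.null(base_strip_um)) {
    base_strip_um <- if (!is.null(g)) g$base_strip_um else 0
  }
  mpp <- mask_scale(mask)$microns_per_pixel
  strip_rows <- sum(((nrow(mask) - seq_len(nrow(mask)) + 0.5) * mpp) < base_strip_um)
  body <- mask_matrix(mask)
  if (strip_rows > 0) body <- body[seq_len(nrow(mask) - strip_rows), , drop = FALSE]
  lab <- EBImage::bwlabel(body)
  max(as.matrix(lab))
}
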