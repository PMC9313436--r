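#' Binarize a grayscale image
#'
#' Thresholds a single-channel image into a foreground/background mask,
#' foreground meaning material. The default Otsu method picks the threshold
#' maximizing between-class variance over a 256-level histogram and is fully
#' deterministic.
#'
#' @param image numeric matrix; values may be on `[0, 1]` or 0--255.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold on the normalized `[0, 1]` scale, required for
#'   `method = "fixed"`.
#' @param invert complement the resulting mask (for inverted-polarity inputs
#'   where material is dark).
#' @param scale an [image_scale()] to attach to the result.
#' @return a [binary_mask()].
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     invert = FALSE, scale = image_scale()) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a single-channel numeric matrix")
  }
  img <- image
  if (max(img) > 1) img <- img / 255
  if (method == "otsu") {
    if (diff(range(img)) == 0) {
      stop("degenerate histogram: constant image has no Otsu threshold")
    }
    threshold <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  } else if (is.null(threshold)) {
    stop("`threshold` is required for method = \"fixed\"")
  }
  fg <- img > threshold
  if (invert) fg <- !fg
  binary_mask(fg * 1L, scale = scale)
}

#' Split an array mask into single-needle tiles
#'
#' Locates needle centers as runs of the vertical-projection profile of the
#' region above the base strip (robust to stringing, which adds only a thin
#' floor to the profile), cuts at midpoints between adjacent centers, and
#' pads each cut to a `tile_size` x `tile_size` tile with the needle
#' horizontally centered.
#'
#' @param array_mask a [binary_mask()] of a one-row array.
#' @param n_needles expected needle count.
#' @param scale an [image_scale()]; its `tile_size` sets the tile dimensions.
#' @param base_strip_um base-strip thickness; taken from the mask's geometry
#'   when present.
#' @param profile_frac fraction of the tallest profile column below which a
#'   column is not considered part of a needle.
#' @return a list of `n_needles` tiles ([binary_mask()]s) ordered left to
#'   right. Each tile records its source column window in attribute `cut`
#'   (`c(from, to)`) and its detected center column in attribute
#'   `center_col`.
#' @export
split_array <- function(array_mask, n_needles, scale = mask_scale(array_mask),
                        base_strip_um = NULL, profile_frac = 0.3) {
  stopifnot(is_binary_mask(array_mask), n_needles >= 1)
  g <- attr(array_mask, "geometry")
  mpp <- scale$microns_per_pixel
  if (is.null(base_strip_um)) {
    base_strip_um <- if (!is.null(g)) g$base_strip_um else {
      # fall back: strip = maximal bottom block of near-full rows
      frac <- rowSums(array_mask) / ncol(array_mask)
      full <- rev(cumprod(rev(frac > 0.9)))
      sum(full) * mpp
    }
  }
  y_bottom <- (nrow(array_mask) - seq_len(nrow(array_mask)) + 0.5) * mpp
  body <- mask_matrix(array_mask)[y_bottom >= base_strip_um, , drop = FALSE]
  profile <- colSums(body)
  if (max(profile) == 0) stop("detected 0 needle peaks, expected ", n_needles)
  above <- profile >= profile_frac * max(profile)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  # merge runs separated by tiny gaps (roughness notches)
  segs <- cbind(starts[keep], ends[keep])
  if (nrow(segs) > 1) {
    merged <- segs[1, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      if (segs[i, 1] - merged[nrow(merged), 2] <= 3) {
        merged[nrow(merged), 2] <- segs[i, 2]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
    segs <- merged
  }
  if (nrow(segs) < n_needles) {
    stop("detected ", nrow(segs), " needle peaks, expected ", n_needles)
  }
  mass <- apply(segs, 1, function(s) sum(profile[s[1]:s[2]]))
  if (nrow(segs) > n_needles) {
    segs <- segs[order(mass, decreasing = TRUE)[seq_len(n_needles)], ,
                 drop = FALSE]
    segs <- segs[order(segs[, 1]), , drop = FALSE]
  }
  centers <- vapply(seq_len(nrow(segs)), function(i) {
    cols <- segs[i, 1]:segs[i, 2]
    sum(cols * profile[cols]) / sum(profile[cols])
  }, numeric(1))
  # cut boundaries at midpoints between adjacent centers; a column belongs
  # to the needle on its right when the midpoint falls inside it
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  half <- if (length(centers) > 1) stats::median(diff(centers)) / 2 else
    scale$tile_size / 2
  from <- c(max(1, floor(centers[1] - half) + 1), floor(mids) + 1)
  to <- c(floor(mids),
          min(ncol(array_mask), ceiling(centers[length(centers)] + half)))
  ts <- scale$tile_size
  lapply(seq_len(n_needles), function(i) {
    tile <- matrix(0L, ts, ts)
    cols <- from[i]:to[i]
    # horizontal placement: detected center lands on the tile's center
    # column, nudged only as far as needed to keep the whole cut inside
    dest <- cols - round(centers[i]) + ceiling(ts / 2)
    if (length(cols) <= ts) {
      if (min(dest) < 1) dest <- dest - min(dest) + 1L
      if (max(dest) > ts) dest <- dest - (max(dest) - ts)
    }
    ok <- dest >= 1 & dest <= ts
    src_rows <- max(1, nrow(array_mask) - ts + 1):nrow(array_mask)
    dst_rows <- (ts - length(src_rows) + 1):ts
    tile[dst_rows, dest[ok]] <- mask_matrix(array_mask)[src_rows, cols[ok]]
    out <- binary_mask(tile, scale = scale)
    attr(out, "cut") <- c(from[i], to[i])
    attr(out, "center_col") <- centers[i]
    attr(out, "needle_index") <- i
    out
  })
}

foreground_centroid_col <- function(mask) {
  m <- mask_matrix(mask)
  cs <- colSums(m)
  sum(seq_along(cs) * cs) / sum(cs)
}

bottom_foreground_row <- function(mask) {
  rs <- rowSums(mask_matrix(mask))
  max(which(rs > 0))
}

pad_to <- function(mask, nr, nc) {
  m <- mask_matrix(mask)
  out <- matrix(0L, nr, nc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Align a fabricated mask to its CAD reference
#'
#' Estimates an integer-pixel translation of the fabricated mask onto the CAD
#' mask. The `"centroid"` method matches the bottom foreground row and the
#' horizontal foreground centroid (the direct automation of a manual overlay
#' step). The default `"xcorr"` method uses the centroid estimate only as a
#' starting point and refines it by maximizing pixel overlap (true positives)
#' over a local search window, breaking ties toward the smaller shift; this
#' keeps the recovered shift stable when asymmetric artifacts (strings,
#' roughness) perturb the centroid by a rounding step.
#'
#' @param printed,cad [binary_mask()]s with non-empty foreground.
#' @param method `"xcorr"` (default) or `"centroid"`.
#' @param refine half-width, in pixels, of the local search window around the
#'   centroid estimate.
#' @return an `aligned_pair`: list with `cad` and `printed` masks of common
#'   dimensions and the applied `shift = c(dy, dx)`.
#' @export
align_masks <- function(printed, cad, method = c("xcorr", "centroid"),
                        refine = 5) {
  method <- match.arg(method)
  stopifnot(is_binary_mask(printed), is_binary_mask(cad))
  if (sum(printed) == 0) stop("empty foreground in printed mask")
  if (sum(cad) == 0) stop("empty foreground in CAD mask")
  nr <- max(nrow(printed), nrow(cad)); nc <- max(ncol(printed), ncol(cad))
  p <- pad_to(printed, nr, nc); cc <- pad_to(cad, nr, nc)
  dy0 <- bottom_foreground_row(binary_mask(cc)) -
    bottom_foreground_row(binary_mask(p))
  if (method == "centroid") {
    dx0 <- round(foreground_centroid_col(binary_mask(cc)) -
                   foreground_centroid_col(binary_mask(p)))
    shift <- c(dy0, dx0)
  } else {
    # initialize the horizontal shift from the 1-D projection-profile
    # cross-correlation: unlike the centroid it is insensitive to mass lost
    # asymmetrically (a truncated outer needle drags the centroid by many
    # pixels but barely moves the profile optimum)
    pp <- colSums(p); cp <- colSums(cc)
    w <- min(nc - 1, 60)
    cors <- vapply(-w:w, function(dx) {
      if (dx >= 0) sum(pp[seq_len(nc - dx)] * cp[seq_len(nc - dx) + dx])
      else sum(pp[seq_len(nc + dx) - dx] * cp[seq_len(nc + dx)])
    }, numeric(1))
    cand <- (-w:w)[cors == max(cors)]
    dx0 <- cand[which.min(abs(cand))]
    best <- NULL
    for (dy in dy0 + (-refine:refine)) {
      for (dx in dx0 + (-refine:refine)) {
        tp <- sum(shift_matrix(p, dy, dx) & cc)
        cand <- list(tp = tp, dy = dy, dx = dx,
                     pen = abs(dy) + abs(dx))
        if (is.null(best) || tp > best$tp ||
            (tp == best$tp && cand$pen < best$pen) ||
            (tp == best$tp && cand$pen == best$pen &&
             (dy < best$dy || (dy == best$dy && dx < best$dx)))) {
          best <- cand
        }
      }
    }
    shift <- c(best$dy, best$dx)
  }
  sc <- mask_scale(cad)
  structure(list(cad = binary_mask(cc, scale = sc),
                 printed = binary_mask(shift_matrix(p, shift[1], shift[2]),
                                       scale = sc),
                 shift = shift),
            class = "aligned_pair")
}

#' Pixel confusion counts
#'
#' TP/TN/FP/FN pixel counts from one CAD-vs-fabricated comparison. A pixel is
#' "positive" when it belongs to needle material; it is "true" when both
#' masks agree. The same container serves instance-level 2x2 classification
#' tables.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @export
pixel_confusion <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "pixel_confusion")
}

#' @export
print.pixel_confusion <- function(x, ...) {
  cat(sprintf("<pixel_confusion TP=%d TN=%d FP=%d FN=%d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Compare an aligned mask pair pixel by pixel
#'
#' @param pair an `aligned_pair` from [align_masks()], or any list with
#'   equal-dimension `cad` and `printed` masks.
#' @return a [pixel_confusion()]; counts always sum to the image area.
#' @export
compare_pixels <- function(pair) {
  cad <- mask_matrix(pair$cad); printed <- mask_matrix(pair$printed)
  if (!all(dim(cad) == dim(printed))) {
    stop("dimension mismatch: cad is ", paste(dim(cad), collapse = "x"),
         ", printed is ", paste(dim(printed), collapse = "x"))
  }
  tp <- sum(printed == 1L & cad == 1L)
  tn <- sum(printed == 0L & cad == 0L)
  fp <- sum(printed == 1L & cad == 0L)
  fn <- sum(printed == 0L & cad == 1L)
  pixel_confusion(tp, tn, fp, fn)
}

#' Write a four-color comparison overlay
#'
#' Renders TP (white), TN (black), FP (red) and FN (blue) pixels of an
#' aligned pair into an RGB PNG, the standard visual for CAD-vs-print
#' agreement.
#'
#' @param pair an `aligned_pair`.
#' @param path output PNG path.
#' @export
write_overlay_png <- function(pair, path) {
  cad <- mask_matrix(pair$cad); printed <- mask_matrix(pair$printed)
  r <- (printed == 1L & cad == 1L) * 1 + (printed == 1L & cad == 0L) * 1
  g <- (printed == 1L & cad == 1L) * 1
  b <- (printed == 1L & cad == 1L) * 1 + (printed == 0L & cad == 1L) * 1
  png::writePNG(array(c(r, g, b), dim = c(nrow(cad), ncol(cad), 3)), path)
  invisible(path)
}
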