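#' Microneedle design parameters
#'
#' A needle design is the trio of geometric features used throughout the
#' quality model: base diameter, height, and draft angle. The draft angle is
#' measured from the vertical needle axis and applied symmetrically to both
#' flanks, so the side-view silhouette is a symmetric trapezoid (a rectangle
#' at zero draft, a triangle when the taper closes before the full height).
#'
#' @param base_diameter_um needle base diameter in microns (> 0).
#' @param height_um needle height in microns (> 0).
#' @param draft_angle_deg taper angle in degrees from the vertical axis,
#'   in `[0, 90)`.
#' @return a list of class `mn_design`.
#' @examples
#' d <- mn_design(1000, 2000, 5)
#' tip_width_um(d)  # 1000 - 2*2000*tan(5 deg) ~ 650.1
#' @export
mn_design <- function(base_diameter_um, height_um, draft_angle_deg) {
  stopifnot(is.numeric(base_diameter_um), base_diameter_um > 0,
            is.numeric(height_um), height_um > 0,
            is.numeric(draft_angle_deg),
            draft_angle_deg >= 0, draft_angle_deg < 90)
  structure(list(base_diameter_um = base_diameter_um,
                 height_um = height_um,
                 draft_angle_deg = draft_angle_deg),
            class = "mn_design")
}

#' @rdname mn_design
#' @param design an `mn_design`.
#' @export
tip_width_um <- function(design) {
  w <- design$base_diameter_um -
    2 * design$height_um * tan(design$draft_angle_deg * pi / 180)
  max(0, w)
}

#' The ten studied needle designs
#'
#' The design table of the study: base diameters of 1000/1500 um, heights of
#' 2000/2500/3000 um and draft angles of 0/5/10 degrees, in ten combinations.
#'
#' @return a data.frame with columns `design_id`, `base_diameter_um`,
#'   `height_um`, `draft_angle_deg`.
#' @export
study_designs <- function() {
  data.frame(
    design_id = sprintf("d%02d", 1:10),
    base_diameter_um = c(1000, 1000, 1000, 1000, 1500, 1500, 1500, 1500, 1000, 1500),
    height_um        = c(2000, 2000, 2500, 2500, 2000, 2000, 2500, 2500, 3000, 3000),
    draft_angle_deg  = c(0, 5, 0, 5, 0, 5, 0, 5, 5, 10),
    stringsAsFactors = FALSE
  )
}

#' The etching doses applied in the study
#'
#' Four KOH concentrations crossed with six exposure durations.
#' @return a list with `concentrations_m` and `durations_h`.
#' @export
study_doses <- function() {
  list(concentrations_m = c(3, 4, 5, 6),
       durations_h = c(4, 7, 14, 18, 21, 24))
}

# per-row half-width of the needle silhouette, in um, at height h above the
# needle base; negative above the apex of a closed (conical) taper
needle_halfwidth_um <- function(design, h_um) {
  design$base_diameter_um / 2 - h_um * tan(design$draft_angle_deg * pi / 180)
}

# paint one needle into a logical matrix. Pixel centers are at
# (col - 0.5) * mpp horizontally and (nrow - row + 0.5) * mpp above the
# image bottom; a pixel is foreground when its center falls inside the
# trapezoid.
paint_needle <- function(px, design, cx_um, base_strip_um, mpp) {
  nr <- nrow(px); nc <- ncol(px)
  y_bottom <- (nr - seq_len(nr) + 0.5) * mpp      # per row, um above bottom
  x_center <- (seq_len(nc) - 0.5) * mpp           # per col, um from left
  body <- y_bottom >= base_strip_um &
    y_bottom < base_strip_um + design$height_um
  for (r in which(body)) {
    hw <- needle_halfwidth_um(design, y_bottom[r] - base_strip_um)
    if (hw <= 0) next
    px[r, abs(x_center - cx_um) <= hw] <- TRUE
  }
  px
}

paint_base_strip <- function(px, base_strip_um, mpp) {
  nr <- nrow(px)
  y_bottom <- (nr - seq_len(nr) + 0.5) * mpp
  px[y_bottom < base_strip_um, ] <- TRUE
  px
}

#' Render the ideal (CAD) silhouette of a single needle
#'
#' Draws the design's symmetric trapezoid standing on a base strip,
#' horizontally centered in a `tile_size` x `tile_size` mask. Rendering is
#' deterministic: the same design and scale always give a bit-identical mask.
#'
#' @param design an [mn_design()].
#' @param scale an [image_scale()].
#' @param base_strip_um thickness of the base plate strip at the bottom of
#'   the silhouette, in microns.
#' @return a [binary_mask()] of size `tile_size` x `tile_size`.
#' @export
render_needle_profile <- function(design, scale = image_scale(),
                                  base_strip_um = 250) {
  mpp <- scale$microns_per_pixel
  extent_um <- scale$tile_size * mpp
  if (design$height_um + base_strip_um > extent_um ||
      design$base_diameter_um > extent_um) {
    stop("design does not fit at this scale: needle plus base strip exceeds ",
         "the tile extent of ", extent_um, " um")
  }
  px <- matrix(FALSE, scale$tile_size, scale$tile_size)
  px <- paint_base_strip(px, base_strip_um, mpp)
  px <- paint_needle(px, design, cx_um = extent_um / 2,
                     base_strip_um = base_strip_um, mpp = mpp)
  binary_mask(px, scale = scale,
              geometry = list(n_needles = 1L,
                              centers_um = extent_um / 2,
                              pitch_um = NA_real_,
                              base_strip_um = base_strip_um,
                              design = design))
}

#' Render the ideal silhouette of a one-row needle array
#'
#' Places `n_needles` identical needle profiles on a shared base strip at a
#' uniform center-to-center pitch. The mask is `tile_size` rows tall and wide
#' enough for the row of needles plus a margin on each side.
#'
#' @inheritParams render_needle_profile
#' @param n_needles number of needles in the row.
#' @param pitch_um center-to-center needle spacing in microns; must be at
#'   least the base diameter so adjacent needles do not overlap.
#' @param margin_um blank margin on each side of the row; defaults to half a
#'   pitch so the outermost needles have the same clearance as interior ones.
#' @return a [binary_mask()] with geometry metadata (`n_needles`,
#'   `centers_um`, `pitch_um`, `base_strip_um`, `design`).
#' @export
render_array <- function(design, n_needles = 10, pitch_um = 2500,
                         scale = image_scale(), base_strip_um = 250,
                         margin_um = pitch_um / 2) {
  stopifnot(n_needles >= 1)
  if (pitch_um < design$base_diameter_um) {
    stop("needles overlap: pitch (", pitch_um, " um) is smaller than the ",
         "base diameter (", design$base_diameter_um, " um)")
  }
  mpp <- scale$microns_per_pixel
  if (design$height_um + base_strip_um > scale$tile_size * mpp) {
    stop("design does not fit at this scale: needle plus base strip exceeds ",
         "the tile extent of ", scale$tile_size * mpp, " um")
  }
  width_px <- ceiling(n_needles * pitch_um / mpp) + 2 * ceiling(margin_um / mpp)
  centers_um <- margin_um + (seq_len(n_needles) - 0.5) * pitch_um
  px <- matrix(FALSE, scale$tile_size, width_px)
  px <- paint_base_strip(px, base_strip_um, mpp)
  for (cx in centers_um) {
    px <- paint_needle(px, design, cx_um = cx,
                       base_strip_um = base_strip_um, mpp = mpp)
  }
  binary_mask(px, scale = scale,
              geometry = list(n_needles = as.integer(n_needles),
                              centers_um = centers_um,
                              pitch_um = pitch_um,
                              base_strip_um = base_strip_um,
                              design = design))
}

#' Full-factorial grid of fabrication conditions
#'
#' Crosses a design table with etching concentrations and durations into the
#' deterministic design-major ordering used throughout: for each design, all
#' concentrations; for each concentration, all durations.
#'
#' @param designs data.frame as returned by [study_designs()] (columns
#'   `design_id`, `base_diameter_um`, `height_um`, `draft_angle_deg`).
#' @param concentrations_m KOH concentrations in mol/L.
#' @param durations_h etch exposure durations in hours.
#' @return a data.frame with one row per condition and a unique
#'   `condition_id`.
#' @examples
#' nrow(condition_grid(study_designs(), c(3, 4, 5, 6), c(4, 7, 14, 18, 21, 24)))
#' @export
condition_grid <- function(designs = study_designs(),
                           concentrations_m = study_doses()$concentrations_m,
                           durations_h = study_doses()$durations_h) {
  stopifnot(nrow(designs) > 0, length(concentrations_m) > 0,
            length(durations_h) > 0)
  rows <- vector("list", nrow(designs) * length(concentrations_m) *
                   length(durations_h))
  k <- 1L
  for (i in seq_len(nrow(designs))) {
    for (conc in concentrations_m) {
      for (dur in durations_h) {
        rows[[k]] <- data.frame(
          condition_id = sprintf("%s_c%04.1f_t%04.1f",
                                 designs$design_id[i], conc, dur),
          design_id = designs$design_id[i],
          base_diameter_um = designs$base_diameter_um[i],
          height_um = designs$height_um[i],
          draft_angle_deg = designs$draft_angle_deg[i],
          concentration_m = conc,
          duration_h = dur,
          stringsAsFactors = FALSE
        )
        k <- k + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a condition grid to CSV
#'
#' @param grid a data.frame from [condition_grid()].
#' @param path output file.
#' @export
write_condition_grid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

design_from_row <- function(row) {
  mn_design(row$base_diameter_um, row$height_um, row$draft_angle_deg)
}
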