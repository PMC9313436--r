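#' Etching dose
#'
#' KOH concentration and exposure duration. The concentration range mirrors
#' the predictor's validated input interval: 3 M (below which etching is
#' inefficient) to 21.6 M (saturation of KOH in water at 25 C).
#'
#' @param concentration_m KOH concentration in mol/L, in `[3, 21.6]`.
#' @param duration_h exposure duration in hours, `>= 0`.
#' @export
etching_dose <- function(concentration_m, duration_h) {
  if (!is.numeric(concentration_m) || concentration_m < 3 ||
      concentration_m > 21.6) {
    stop("concentration out of validated range [3, 21.6] M: ", concentration_m)
  }
  if (!is.numeric(duration_h) || duration_h < 0) {
    stop("duration must be >= 0 h")
  }
  structure(list(concentration_m = concentration_m, duration_h = duration_h),
            class = "etching_dose")
}

#' Print-artifact parameters
#'
#' Parameterizes the fused-deposition artifacts the simulator adds to a CAD
#' silhouette. The dominant artifact is stringing: thin horizontal traces the
#' nozzle leaves between adjacent needles. Over-extrusion (`dilation_um`)
#' defaults to zero because a uniform flank dilation below half a pixel is
#' not representable at the default 25 um/px working scale; stringing,
#' boundary roughness and tip truncation carry the imperfections instead.
#'
#' @param dilation_um uniform over-extrusion depth in microns.
#' @param p_string probability of a string forming in each gap between
#'   adjacent needles.
#' @param string_thickness_um string band thickness; thin enough (default
#'   40 um) that mild etch doses remove strings before needle flanks erode
#'   materially.
#' @param p_defect probability that a needle's tip is truncated during
#'   printing.
#' @param roughness_sigma_um scale of Gaussian boundary perturbation; a
#'   boundary pixel flips with the probability that a `N(0, sigma)`
#'   displacement exceeds half a pixel.
#' @param seed RNG seed for the dataset stream.
#' @export
print_params <- function(dilation_um = 0, p_string = 0.7,
                         string_thickness_um = 40, p_defect = 0.15,
                         roughness_sigma_um = 10, seed = 1L) {
  stopifnot(p_string >= 0, p_string <= 1, p_defect >= 0, p_defect <= 1,
            dilation_um >= 0, string_thickness_um >= 0,
            roughness_sigma_um >= 0)
  structure(list(dilation_um = dilation_um, p_string = p_string,
                 string_thickness_um = string_thickness_um,
                 p_defect = p_defect, roughness_sigma_um = roughness_sigma_um,
                 seed = as.integer(seed)),
            class = "print_params")
}

# Deterministic 31-bit substream seed derived from a base seed and a string
# key, so per-design / per-condition streams are reproducible independently
# of processing order.
substream_seed <- function(seed, key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

# run expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# column span (pixel indices) of needle i in a rendered array, with margin
needle_col_span <- function(mask, i, margin_um = 0) {
  g <- attr(mask, "geometry")
  mpp <- mask_scale(mask)$microns_per_pixel
  half <- g$design$base_diameter_um / 2 + margin_um
  cx <- g$centers_um[i]
  x_center <- (seq_len(ncol(mask)) - 0.5) * mpp
  which(abs(x_center - cx) <= half)
}

# rows (pixel indices) whose centers lie in [y_lo, y_hi) um above the bottom
rows_in_band <- function(mask, y_lo, y_hi) {
  mpp <- mask_scale(mask)$microns_per_pixel
  y_bottom <- (nrow(mask) - seq_len(nrow(mask)) + 0.5) * mpp
  which(y_bottom >= y_lo & y_bottom < y_hi)
}

#' Simulate fused-deposition printing of a CAD array
#'
#' Applies, in order: uniform over-extrusion (dilation), inter-needle strings
#' (thin horizontal traces bridging adjacent needle flanks, one per gap with
#' probability `p_string`), Gaussian boundary roughness, and tip truncation
#' (with probability `p_defect` a needle loses a random 30--60% of its
#' height). All randomness is drawn from a substream keyed by the mask's
#' design and the `seed` in `params`, so reruns are bit-identical and every
#' etching dose of one design sees the same printed realization.
#'
#' @param cad a rendered array mask from [render_array()].
#' @param params a [print_params()].
#' @param stream_key string used to derive the RNG substream; defaults to the
#'   design's identity.
#' @return a list with elements `mask` (the printed [binary_mask()]) and
#'   `ground_truth`, a data.frame with one row per needle: `needle_index`,
#'   `truncated`, `string_touch`, `label_print`
#'   (`"defective"`/`"non-defective"` at print time), and the string records
#'   needed to re-assess labels after etching (attribute `strings`).
#' @export
simulate_print <- function(cad, params = print_params(), stream_key = NULL) {
  if (!is_binary_mask(cad)) stop("`cad` must be a binary_mask")
  g <- attr(cad, "geometry")
  if (is.null(g)) stop("`cad` must carry array geometry (use render_array())")
  mpp <- mask_scale(cad)$microns_per_pixel
  n <- g$n_needles
  if (is.null(stream_key)) {
    d <- g$design
    stream_key <- sprintf("print_%g_%g_%g", d$base_diameter_um, d$height_um,
                          d$draft_angle_deg)
  }
  seed <- substream_seed(params$seed, stream_key)

  with_seed(seed, {
    out <- cad
    # over-extrusion
    if (params$dilation_um > 0) {
      out <- dilate_mask(out, round(params$dilation_um / mpp))
    }
    # stringing between adjacent needles
    strings <- list()
    string_touch <- rep(FALSE, n)
    if (n >= 2 && params$p_string > 0 && params$string_thickness_um > 0) {
      for (i in seq_len(n - 1)) {
        if (stats::runif(1) >= params$p_string) next
        d <- g$design
        y0 <- g$base_strip_um +
          stats::runif(1, 0.15, 0.60) * d$height_um   # string height position
        half_t <- params$string_thickness_um / 2
        rows <- rows_in_band(out, y0 - half_t, y0 + half_t)
        if (length(rows) == 0) next
        hw <- max(0, needle_halfwidth_um(d, y0 - g$base_strip_um))
        x_from <- g$centers_um[i] + hw
        x_to <- g$centers_um[i + 1] - hw
        x_center <- (seq_len(ncol(out)) - 0.5) * mpp
        cols <- which(x_center > x_from & x_center < x_to)
        if (length(cols) == 0) next
        out[rows, cols] <- 1L
        string_touch[c(i, i + 1)] <- TRUE
        strings[[length(strings) + 1]] <-
          list(gap = i, rows = rows, cols = cols)
      }
    }
    # boundary roughness
    if (params$roughness_sigma_um > 0) {
      p_flip <- 2 * stats::pnorm(-(mpp / 2) / params$roughness_sigma_um)
      m <- mask_matrix(out)
      pad <- rbind(0L, cbind(0L, m, 0L), 0L)
      nr <- nrow(m); nc <- ncol(m)
      neigh <- pad[1:nr, 2:(nc + 1)] + pad[3:(nr + 2), 2:(nc + 1)] +
        pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 3:(nc + 2)]
      boundary <- (m == 1L & neigh < 4L) | (m == 0L & neigh > 0L)
      flips <- boundary & matrix(stats::runif(length(m)) < p_flip, nr, nc)
      m[flips] <- 1L - m[flips]
      out <- with_mask_attrs(m, out)
    }
    # tip truncation
    truncated <- rep(FALSE, n)
    if (params$p_defect > 0) {
      d <- g$design
      for (i in seq_len(n)) {
        if (stats::runif(1) >= params$p_defect) next
        frac <- stats::runif(1, 0.30, 0.60)    # fraction of height removed
        truncated[i] <- TRUE
        y_cut <- g$base_strip_um + (1 - frac) * d$height_um
        rows <- rows_in_band(out, y_cut, Inf)
        cols <- needle_col_span(out, i, margin_um = params$dilation_um + 2 * mpp)
        out[rows, cols] <- 0L
      }
    }
    gt <- data.frame(needle_index = seq_len(n),
                     truncated = truncated,
                     string_touch = string_touch,
                     label_print = ifelse(truncated | string_touch,
                                          "defective", "non-defective"),
                     stringsAsFactors = FALSE)
    attr(gt, "strings") <- strings
    out <- binary_mask(mask_matrix(out), scale = mask_scale(cad), geometry = g)
    attr(out, "print_seed") <- seed
    list(mask = out, ground_truth = gt)
  })
}

#' Simulate KOH etching of a printed array
#'
#' Etching is modelled as morphological erosion by a disc whose radius grows
#' linearly with dose: `d = etch_rate * concentration * duration` microns,
#' rounded to the nearest pixel. Structures thinner than `2d` (strings,
#' roughness speckle) vanish before needle bodies erode materially. The
#' default rate of 0.2667 um per M.h is calibrated so that a 1000-um base
#' etched at 5 M for 18 h loses ~24 um per side, reproducing the measured
#' ~952 um of the reference case. At strong doses, tall (>= `brittle_height_um`)
#' needles additionally break with probability `p_brittle`, losing a random
#' 20--50% of their height (the high-aspect brittleness seen experimentally).
#'
#' @param printed a printed [binary_mask()] (from [simulate_print()]; a plain
#'   rendered mask also works, in which case brittleness is skipped).
#' @param dose an [etching_dose()].
#' @param etch_rate_um_per_mh erosion depth per unit of concentration x
#'   duration, in um / (M h).
#' @param brittle_height_um minimum design height for brittle breakage.
#' @param brittle_depth_um minimum erosion depth (um) before breakage can
#'   trigger.
#' @param p_brittle breakage probability per tall needle at qualifying doses.
#' @param seed RNG seed for the brittleness draws; defaults to the print
#'   substream recorded on the mask.
#' @return the etched [binary_mask()]; needles broken by brittleness are
#'   recorded in attribute `broken` (logical per needle).
#' @export
simulate_etch <- function(printed, dose, etch_rate_um_per_mh = 0.2667,
                          brittle_height_um = 2750, brittle_depth_um = 30,
                          p_brittle = 0.6, seed = NULL) {
  if (!is_binary_mask(printed)) stop("`printed` must be a binary_mask")
  if (!inherits(dose, "etching_dose")) {
    dose <- etching_dose(dose[[1]], dose[[2]])
  }
  stopifnot(etch_rate_um_per_mh > 0)
  mpp <- mask_scale(printed)$microns_per_pixel
  depth_um <- etch_rate_um_per_mh * dose$concentration_m * dose$duration_h
  r_px <- round(depth_um / mpp)
  out <- erode_mask(printed, r_px)
  g <- attr(printed, "geometry")
  broken <- if (!is.null(g)) rep(FALSE, g$n_needles) else logical(0)
  if (!is.null(g) && g$design$height_um >= brittle_height_um &&
      depth_um >= brittle_depth_um && p_brittle > 0) {
    if (is.null(seed)) seed <- attr(printed, "print_seed")
    if (is.null(seed)) seed <- 0L
    with_seed(substream_seed(seed, "brittle"), {
      for (i in seq_len(g$n_needles)) {
        u <- stats::runif(1)
        frac <- stats::runif(1, 0.20, 0.50)
        if (u < p_brittle) {
          broken[i] <- TRUE
          y_cut <- g$base_strip_um + (1 - frac) * g$design$height_um
          rows <- rows_in_band(out, y_cut, Inf)
          cols <- needle_col_span(out, i, margin_um = 2 * mpp)
          out[rows, cols] <- 0L
        }
      }
    })
  }
  out <- binary_mask(mask_matrix(out), scale = mask_scale(printed), geometry = g)
  attr(out, "broken") <- broken
  attr(out, "etch_depth_um") <- depth_um
  out
}

#' Measure realized needle dimensions from a mask
#'
#' Base diameter is the foreground width, in microns, of the first needle row
#' above the base strip; height is the extent from the needle base to the
#' topmost foreground pixel within the needle's column span.
#'
#' @param mask an array [binary_mask()] with geometry metadata.
#' @return data.frame with `needle_index`, `base_um`, `height_um`.
#' @export
measure_needles <- function(mask) {
  g <- attr(mask, "geometry")
  if (is.null(g)) stop("mask carries no array geometry")
  mpp <- mask_scale(mask)$microns_per_pixel
  y_bottom <- (nrow(mask) - seq_len(nrow(mask)) + 0.5) * mpp
  out <- data.frame(needle_index = seq_len(g$n_needles),
                    base_um = NA_real_, height_um = NA_real_)
  for (i in seq_len(g$n_needles)) {
    cols <- needle_col_span(mask, i, margin_um = 2 * mpp)
    body_rows <- which(y_bottom >= g$base_strip_um)
    sub <- mask[body_rows, cols, drop = FALSE]
    if (sum(sub) == 0) {
      out$base_um[i] <- 0; out$height_um[i] <- 0
      next
    }
    # first needle row above the strip that still has material
    base_row <- max(which(rowSums(sub) > 0))
    out$base_um[i] <- sum(sub[base_row, ]) * mpp
    top_row <- min(which(rowSums(sub) > 0))
    out$height_um[i] <- y_bottom[body_rows[top_row]] + mpp / 2 - g$base_strip_um
  }
  out
}

# does visible string material remain next to needle i after etching?
# sub-resolution specks (a few leftover pixels at the flank junction) are
# not counted: a reviewer flags a trace, not a speck
string_residue <- function(etched, strings, min_px = 4) {
  g <- attr(etched, "geometry")
  touch <- rep(FALSE, g$n_needles)
  for (s in strings) {
    # interior of the recorded string rectangle, away from needle flanks
    cols <- s$cols
    if (length(cols) > 4) cols <- cols[3:(length(cols) - 2)]
    if (sum(etched[s$rows, cols]) >= min_px) {
      touch[c(s$gap, s$gap + 1)] <- TRUE
    }
  }
  touch
}

#' Generate a labelled synthetic fabrication dataset
#'
#' For each fabrication condition: renders the CAD array, simulates printing
#' (one printed realization per design, shared across that design's doses)
#' and etching, measures realized needle dimensions, and assigns per-needle
#' defect labels from the etched product. A needle is defective when its tip
#' was truncated in printing, it broke during etching, or residual string
#' material still touches it after etching.
#'
#' @param conditions data.frame from [condition_grid()].
#' @param params a [print_params()].
#' @param scale an [image_scale()].
#' @param n_needles,pitch_um,base_strip_um array layout passed to
#'   [render_array()].
#' @param etch_rate_um_per_mh passed to [simulate_etch()].
#' @param per_condition optional callback `function(record)`; when supplied
#'   its return value replaces the full record in the output list, which
#'   keeps memory flat for large runs (masks can be dropped or reduced to
#'   tiles as they stream past).
#' @param out_dir optional directory; when given, `cad/printed/etched` PNG
#'   masks and a `ground_truth.csv` / `manifest.yaml` are written there.
#' @return a list with one element per condition. Each full record holds
#'   `condition` (the grid row), `cad`, `printed`, `etched` masks and
#'   `ground_truth` (per-needle labels and realized dimensions).
#' @export
generate_dataset <- function(conditions, params = print_params(),
                             scale = image_scale(), n_needles = 10,
                             pitch_um = 2500, base_strip_um = 250,
                             etch_rate_um_per_mh = 0.2667,
                             per_condition = NULL, out_dir = NULL) {
  if (is.null(conditions) || nrow(conditions) == 0) {
    stop("empty condition list")
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  cad_cache <- list()
  print_cache <- list()
  records <- vector("list", nrow(conditions))
  gt_rows <- list()
  for (k in seq_len(nrow(conditions))) {
    cond <- conditions[k, ]
    rec <- tryCatch({
      did <- cond$design_id
      if (is.null(cad_cache[[did]])) {
        design <- design_from_row(cond)
        cad_cache[[did]] <- render_array(design, n_needles = n_needles,
                                         pitch_um = pitch_um, scale = scale,
                                         base_strip_um = base_strip_um)
        print_cache[[did]] <- simulate_print(cad_cache[[did]], params,
                                             stream_key = did)
      }
      cad <- cad_cache[[did]]
      pr <- print_cache[[did]]
      dose <- etching_dose(cond$concentration_m, cond$duration_h)
      etched <- simulate_etch(pr$mask, dose,
                              etch_rate_um_per_mh = etch_rate_um_per_mh)
      gt <- pr$ground_truth
      dims <- measure_needles(etched)
      residue <- string_residue(etched, attr(gt, "strings"))
      broken <- attr(etched, "broken")
      gt2 <- data.frame(condition_id = cond$condition_id,
                        needle_index = gt$needle_index,
                        label = ifelse(gt$truncated | broken | residue,
                                       "defective", "non-defective"),
                        label_print = gt$label_print,
                        base_um = dims$base_um,
                        height_um = dims$height_um,
                        stringsAsFactors = FALSE)
      list(condition = cond, cad = cad, printed = pr$mask, etched = etched,
           ground_truth = gt2)
    }, error = function(e) {
      stop("failed at condition ", cond$condition_id, ": ",
           conditionMessage(e))
    })
    gt_rows[[k]] <- rec$ground_truth
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, cond$condition_id)
      dir.create(cdir, showWarnings = FALSE)
      write_mask_png(rec$cad, file.path(cdir, "cad.png"))
      write_mask_png(rec$printed, file.path(cdir, "printed.png"))
      write_mask_png(rec$etched, file.path(cdir, "etched.png"))
    }
    records[k] <- list(if (is.null(per_condition)) rec else per_condition(rec))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(do.call(rbind, gt_rows),
                     file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    yaml::write_yaml(list(params = unclass(params),
                          scale = unclass(scale),
                          n_needles = n_needles, pitch_um = pitch_um,
                          base_strip_um = base_strip_um,
                          etch_rate_um_per_mh = etch_rate_um_per_mh,
                          n_conditions = nrow(conditions)),
                     file.path(out_dir, "manifest.yaml"))
  }
  names(records) <- conditions$condition_id
  records
}
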