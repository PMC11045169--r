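# Synthetic histology sections and the 2-mm-band ground-truth quantifier.
#
# A section mimics an inked H&E slide: an ink polyline along the resection
# margin, tissue on one side, and a per-pixel class mask (tumor / fat /
# connective / background). The quantifier measures, inside the band up to
# 2 mm under the ink, the tissue area percentages (tumor from the
# annotation mask; the healthy remainder split fat vs connective by a
# green-channel threshold), the tumor-margin distances, and the binary
# label (malignant iff any tumor in the band).

.MASK_BACKGROUND <- 0L
.MASK_TUMOR <- 1L
.MASK_FAT <- 2L
.MASK_CONNECTIVE <- 3L

# RGB palette (0-255). Green channel separates the classes: fat brightest,
# tumor darkest; the fat/connective threshold sits between 230 and 140.
.SECTION_PALETTE <- list(
  background = c(250, 250, 250),
  tumor = c(150, 40, 160),
  fat = c(235, 230, 240),
  connective = c(225, 140, 190)
)

#' Construct a section image object
#'
#' @param label_mask Integer matrix (rows x cols): 0 background, 1 tumor,
#'   2 fat, 3 connective.
#' @param rgb Numeric array (rows x cols x 3), intensities 0-255.
#' @param ink_polyline Numeric matrix (n >= 2 rows, columns `x`, `y`) in
#'   pixel coordinates (x = column, y = row, pixel centers, 1-based).
#' @param pixel_size_um Pixel edge length in micrometers (> 0).
#' @return Object of class `section_image`.
#' @export
section_image <- function(label_mask, rgb, ink_polyline, pixel_size_um) {
  stopifnot(is.matrix(label_mask), length(dim(rgb)) == 3L,
            all(dim(rgb)[1:2] == dim(label_mask)), dim(rgb)[3] == 3L)
  if (pixel_size_um <= 0) abort_input("pixel_size_um must be > 0")
  ink_polyline <- as.matrix(ink_polyline)
  if (nrow(ink_polyline) < 2L) abort_input("ink polyline needs >= 2 points")
  colnames(ink_polyline) <- c("x", "y")
  structure(list(label_mask = label_mask, rgb = rgb,
                 ink_polyline = ink_polyline,
                 pixel_size_um = pixel_size_um),
            class = "section_image")
}

#' Render a synthetic histology section from a ground-truth record
#'
#' Draws a horizontal ink line with tissue below it. For a malignant record
#' the tumor's upper edge follows the truth's min/central/max margin
#' distances (piecewise linear across the width) and its thickness is
#' solved so that the tumor area inside the 2-mm band reproduces
#' `truth$tumor_pct`; when the recorded distances leave too little band
#' area for the recorded percentage, the edge is scaled toward the ink
#' until the percentage is reachable (the area percentage, not the
#' distances, is the round-trip invariant). The healthy remainder is
#' assigned fat vs connective per pixel so that the in-band split matches
#' the truth's fat/connective ratio. Uses the global RNG for that
#' assignment.
#'
#' @param truth One-row ground-truth record (see [simulate_cohort()]).
#' @param width_px,ink_row Image geometry (pixels).
#' @param pixel_size_um Pixel size in micrometers (default 20).
#' @param band_depth_mm Band depth used to size the image (default 2).
#' @return A [section_image()].
#' @export
render_section <- function(truth, width_px = 160L, ink_row = 12L,
                           pixel_size_um = 20, band_depth_mm = 2) {
  if (pixel_size_um <= 0) abort_input("pixel_size_um must be > 0")
  px_per_mm <- 1000 / pixel_size_um
  band_px <- round(band_depth_mm * px_per_mm)
  h <- as.integer(ink_row + band_px + round(0.5 * px_per_mm) + 10L)
  w <- as.integer(width_px)
  mask <- matrix(.MASK_BACKGROUND, nrow = h, ncol = w)
  tissue_rows <- (ink_row + 1L):h

  # healthy fill, fat share chosen to match the truth's in-band ratio
  healthy_total <- truth$fat_pct + truth$connective_pct
  p_fat <- if (healthy_total > 0) truth$fat_pct / healthy_total else 0
  fill <- ifelse(stats::runif(length(tissue_rows) * w) < p_fat,
                 .MASK_FAT, .MASK_CONNECTIVE)
  mask[tissue_rows, ] <- fill

  if (truth$tumor_pct > 0) {
    d <- c(truth$margin_distance_min, truth$margin_distance_central,
           truth$margin_distance_max) * px_per_mm
    if (anyNA(d)) d <- c(0, 0, 0)
    # upper tumor edge across the width: min -> central -> max
    xs <- seq_len(w)
    half <- ceiling(w / 2)
    top <- c(seq(d[1], d[2], length.out = half),
             seq(d[2], d[3], length.out = w - half + 1L)[-1])
    top <- pmax(1, round(top))
    target <- truth$tumor_pct / 100 * (band_px * w)
    area_at <- function(tp, t) sum(pmin(t, pmax(0L, band_px - tp + 1L)))
    # shrink the edge toward the ink if the recorded distances cannot
    # accommodate the recorded area percentage
    shrink <- 1
    while (area_at(top, band_px) < target && shrink > 1e-3) {
      shrink <- shrink * 0.9
      top <- pmax(1, round(top * shrink))
    }
    t_lo <- 0L
    t_hi <- as.integer(band_px + max(top))
    while (t_hi - t_lo > 1L) {
      mid <- (t_lo + t_hi) %/% 2L
      if (area_at(top, mid) < target) t_lo <- mid else t_hi <- mid
    }
    thick <- if (abs(area_at(top, t_lo) - target) <=
                 abs(area_at(top, t_hi) - target)) t_lo else t_hi
    if (thick > 0L) {
      for (cx in xs) {
        r1 <- ink_row + top[cx]
        r2 <- min(h, r1 + thick - 1L)
        if (r1 <= h) mask[r1:r2, cx] <- .MASK_TUMOR
      }
    }
  }

  rgb <- array(0, dim = c(h, w, 3L))
  pal <- .SECTION_PALETTE
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], h, w)
    plane[mask == .MASK_TUMOR] <- pal$tumor[ch]
    plane[mask == .MASK_FAT] <- pal$fat[ch]
    plane[mask == .MASK_CONNECTIVE] <- pal$connective[ch]
    plane[ink_row, ] <- 0 # ink drawn over the margin
    rgb[, , ch] <- plane
  }
  section_image(mask, rgb,
                ink_polyline = cbind(x = c(1, w), y = c(ink_row, ink_row)),
                pixel_size_um = pixel_size_um)
}

# Distance (pixels) from every pixel center to a polyline, plus the signed
# side of each pixel relative to the overall polyline direction.
.pixel_polyline_distance <- function(h, w, polyline) {
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), times = w)
  dmin <- rep(Inf, h * w)
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]
    b <- polyline[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, h * w) else
      pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    dx <- px - (a[1] + t * ab[1])
    dy <- py - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  a <- polyline[1L, ]
  b <- polyline[nrow(polyline), ]
  side <- sign((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]))
  list(distance = matrix(dmin, h, w), side = matrix(side, h, w))
}

#' Band region up to a given depth under the ink
#'
#' Selects pixels within `depth_mm` of the ink polyline that lie on the
#' tissue side, where the tissue side is the sign (relative to the
#' polyline direction) holding the majority of non-background pixels.
#'
#' @param section A [section_image()].
#' @param depth_mm Band depth in millimeters (default 2).
#' @return Object of class `band_region`: `member` (logical matrix),
#'   `distance_px` (distance-to-ink matrix), `depth_mm`, `side`.
#' @export
band_region <- function(section, depth_mm = 2) {
  stopifnot(inherits(section, "section_image"))
  dims <- dim(section$label_mask)
  geo <- .pixel_polyline_distance(dims[1], dims[2], section$ink_polyline)
  tissue <- section$label_mask != .MASK_BACKGROUND
  if (!any(tissue)) abort_input("section contains no tissue")
  side_counts <- c(`-1` = sum(geo$side[tissue] < 0),
                   `1` = sum(geo$side[tissue] > 0))
  tissue_side <- if (side_counts["1"] >= side_counts["-1"]) 1 else -1
  depth_px <- depth_mm * 1000 / section$pixel_size_um
  member <- geo$distance <= depth_px & geo$side == tissue_side
  if (depth_mm > 0 && !any(member & tissue)) {
    abort_input("band region contains no tissue (polyline outside tissue?)")
  }
  structure(list(member = member, distance_px = geo$distance,
                 depth_mm = depth_mm, side = tissue_side),
            class = "band_region")
}

#' Tissue area percentages inside the band
#'
#' Tumor from the annotation mask; the remaining (non-tumor,
#' non-background) pixels are split fat vs connective by a green-channel
#' threshold. Percentages are over tissue pixels in the band and sum to
#' 100.
#'
#' @param section A [section_image()].
#' @param region A [band_region()].
#' @param green_threshold Green intensity above which a healthy pixel
#'   counts as fat (default 200 of 255, calibrated to the renderer's
#'   palette).
#' @return Named numeric: `tumor_pct`, `fat_pct`, `connective_pct`.
#' @export
tissue_percentages <- function(section, region, green_threshold = 200) {
  stopifnot(inherits(section, "section_image"),
            inherits(region, "band_region"))
  sel <- region$member & section$label_mask != .MASK_BACKGROUND
  n <- sum(sel)
  if (n == 0) abort_input("band region is entirely background")
  tumor <- sel & section$label_mask == .MASK_TUMOR
  green <- section$rgb[, , 2L]
  healthy <- sel & !tumor
  fat <- healthy & green > green_threshold
  c(tumor_pct = 100 * sum(tumor) / n,
    fat_pct = 100 * sum(fat) / n,
    connective_pct = 100 * sum(healthy & !fat) / n)
}

#' Tumor-margin distances
#'
#' The ink polyline is sampled at one-pixel arc spacing; each sample's
#' distance to the nearest tumor pixel in the band (capped at the band
#' depth) approximates the perpendicular ink-to-tumor-edge distance. The
#' minimum and maximum are taken over all samples, the central distance at
#' the arc-length midpoint, and the mean is the average of the three.
#'
#' @param section A [section_image()].
#' @param region A [band_region()].
#' @return Named numeric (`min`, `central`, `max`, `mean`) in millimeters,
#'   or `NULL` when the band holds no tumor (healthy location).
#' @export
margin_distances <- function(section, region) {
  stopifnot(inherits(section, "section_image"),
            inherits(region, "band_region"))
  tumor_idx <- which(region$member & section$label_mask == .MASK_TUMOR,
                     arr.ind = TRUE)
  if (!nrow(tumor_idx)) return(NULL)
  poly <- section$ink_polyline
  seg_len <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                           poly[-nrow(poly), , drop = FALSE])^2))
  total <- sum(seg_len)
  s_grid <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg_len))
  sample_pt <- function(s) {
    k <- max(which(cum <= s + 1e-9))
    k <- min(k, nrow(poly) - 1L)
    f <- if (seg_len[k] == 0) 0 else (s - cum[k]) / seg_len[k]
    poly[k, ] + f * (poly[k + 1L, ] - poly[k, ])
  }
  pts <- t(vapply(s_grid, sample_pt, numeric(2)))
  tx <- tumor_idx[, "col"]
  ty <- tumor_idx[, "row"]
  d <- vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((tx - pts[i, 1])^2 + (ty - pts[i, 2])^2))
  }, numeric(1))
  depth_px <- region$depth_mm * 1000 / section$pixel_size_um
  d <- pmin(d, depth_px)
  central <- d[which.min(abs(s_grid - total / 2))]
  mm <- section$pixel_size_um / 1000
  out <- c(min = min(d), central = central, max = max(d))
  out <- out * mm
  c(out, mean = mean(out))
}

#' Binary location label from the tumor percentage
#'
#' Malignant iff any tumor tissue is present in the band (`tumor_pct > 0`);
#' healthy otherwise.
#'
#' @param tumor_pct Tumor area percentage in `[0, 100]`.
#' @return `"malignant"` or `"healthy"`.
#' @export
label_location <- function(tumor_pct) {
  if (tumor_pct < 0 || tumor_pct > 100) {
    abort_input("tumor_pct must be in [0, 100]")
  }
  if (tumor_pct > 0) "malignant" else "healthy"
}

#' Quantify a section into a ground-truth record
#'
#' Convenience wrapper: band region, tissue percentages, distances, label.
#'
#' @param section A [section_image()].
#' @param depth_mm Band depth (default 2 mm).
#' @param green_threshold Fat/connective green-channel cut.
#' @return One-row data.frame mirroring the ground-truth schema.
#' @export
quantify_section <- function(section, depth_mm = 2, green_threshold = 200) {
  region <- band_region(section, depth_mm)
  pct <- tissue_percentages(section, region, green_threshold)
  d <- margin_distances(section, region)
  data.frame(
    tumor_pct = pct[["tumor_pct"]], fat_pct = pct[["fat_pct"]],
    connective_pct = pct[["connective_pct"]],
    margin_distance_min = if (is.null(d)) NA_real_ else d[["min"]],
    margin_distance_central = if (is.null(d)) NA_real_ else d[["central"]],
    margin_distance_max = if (is.null(d)) NA_real_ else d[["max"]],
    margin_distance_mean = if (is.null(d)) NA_real_ else d[["mean"]],
    label = label_location(pct[["tumor_pct"]]),
    stringsAsFactors = FALSE)
}
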