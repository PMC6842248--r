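# Quantification of submerged-culture macromorphology from binary images.
#
# Structures are 8-connected foreground components (thin diagonal hyphae
# stay connected). Euclidean descriptors follow the conventions of automated
# pellet/dispersed quantification pipelines: area from the pixel count,
# Feret diameters as the extreme caliper widths of the convex hull, aspect
# ratio as max/min Feret, and solidity as area over convex-hull area. The
# hull is built on pixel corners (each pixel contributes its four corners),
# so a 1-pixel-wide hyphal fragment has a minimum Feret of one pixel rather
# than zero -- this keeps the aspect ratio finite.

#' Label connected structures in a binary image
#'
#' Finds 8-connected components of the foreground. The image must be
#' strictly binary: 0 for background and a single positive value (e.g. 255
#' or 1) for foreground.
#'
#' @param image numeric/integer matrix; rows are image rows.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return List of `structure_mask` objects, each with `object_id`,
#'   `pixels` (n x 2 matrix of row/col indices) and `pixel_size_um`,
#'   numbered in raster-scan order of their first pixel. Empty list for a
#'   blank image.
#' @export
label_structures <- function(image, pixel_size_um) {
  check_that(is.matrix(image) && is.numeric(image),
             "`image` must be a numeric matrix")
  check_that(is_scalar_number(pixel_size_um) && pixel_size_um > 0,
             "`pixel_size_um` must be positive")
  mx <- max(image)
  vals <- unique(as.vector(image))
  if (!all(vals %in% c(0, mx)) || mx < 0) {
    stop("image is not binary: values must be {0, max}", call. = FALSE)
  }
  fg <- image > 0
  if (!any(fg)) return(list())

  nr <- nrow(image); nc <- ncol(image)
  pix <- which(fg, arr.ind = TRUE)           # raster (column-major) order
  n_fg <- nrow(pix)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_len(n_fg)

  # edges to 4 forward neighbours (E, S, SE, SW) give full 8-connectivity
  edges <- lapply(list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                  function(off) {
                    nb_r <- pix[, 1] + off[1]
                    nb_c <- pix[, 2] + off[2]
                    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
                    nb <- integer(n_fg)
                    nb[ok] <- id[cbind(nb_r[ok], nb_c[ok])]
                    keep <- nb > 0L
                    cbind(seq_len(n_fg)[keep], nb[keep])
                  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  member <- igraph::components(g)$membership

  # renumber components by first pixel in raster order
  first <- match(sort(unique(member)), member)
  ord <- rank(first)
  member <- ord[member]

  lapply(seq_len(max(member)), function(i) {
    structure(list(object_id = i,
                   pixels = pix[member == i, , drop = FALSE],
                   pixel_size_um = pixel_size_um),
              class = "structure_mask")
  })
}

# 4 corner points (x, y) in pixel units for every pixel of a mask
pixel_corners <- function(pixels) {
  x <- pixels[, 2]; y <- pixels[, 1]
  cbind(x = c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
        y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}

# shoelace area of an ordered polygon
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# max and min caliper widths of a convex point set
feret_extremes <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  # max Feret: attained between two hull vertices
  fmax <- max(stats::dist(hull))
  # min Feret: for a convex polygon, attained perpendicular to an edge
  nxt <- c(seq_len(n)[-1], 1L)
  widths <- vapply(seq_len(n), function(i) {
    e <- hull[nxt[i], ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- (hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]
    max(abs(proj))
  }, numeric(1))
  list(feret_max = fmax, feret_min = min(widths), hull = hull)
}

#' Euclidean shape descriptors of a labelled structure
#'
#' Area is the pixel count scaled by the pixel area; Feret maximum/minimum
#' are the extreme caliper widths of the convex hull of the pixel corners;
#' aspect ratio is their quotient; solidity is area over hull area (<= 1 by
#' construction, since the pixel squares lie inside their hull).
#'
#' @param mask a `structure_mask` from [label_structures()].
#' @return One-row data.frame: `object_id`, `area_um2`, `feret_max_um`,
#'   `feret_min_um`, `aspect_ratio`, `solidity`.
#' @export
shape_descriptors <- function(mask) {
  check_that(inherits(mask, "structure_mask"), "`mask` must be a structure_mask")
  ps <- mask$pixel_size_um
  n_px <- nrow(mask$pixels)
  check_that(n_px >= 1L, "mask is empty")
  fer <- feret_extremes(pixel_corners(mask$pixels))
  area <- n_px * ps^2
  hull_area <- polygon_area(fer$hull) * ps^2
  data.frame(object_id = mask$object_id,
             area_um2 = area,
             feret_max_um = fer$feret_max * ps,
             feret_min_um = fer$feret_min * ps,
             aspect_ratio = fer$feret_max / fer$feret_min,
             solidity = area / hull_area)
}

#' Classify a structure by area
#'
#' Pellets are structures of at least `pellet_min` square micrometres;
#' dispersed mycelia occupy `[dispersed_min, pellet_min)`; anything smaller
#' is excluded from measurement (debris, single spores). Both boundaries
#' are inclusive on the left, so an area of exactly 500 is a pellet and
#' exactly 95 is dispersed.
#'
#' @param area_um2 numeric vector of positive areas.
#' @param dispersed_min,pellet_min class boundaries in square micrometres.
#' @return Character vector in `{"pellet", "dispersed", "excluded"}`.
#' @export
#' @examples
#' classify_structure(c(94.9, 95, 499.9, 500))
classify_structure <- function(area_um2, dispersed_min = 95, pellet_min = 500) {
  check_that(is.numeric(area_um2) && all(is.finite(area_um2)) &&
               all(area_um2 > 0), "areas must be positive")
  check_that(is_scalar_number(dispersed_min) && is_scalar_number(pellet_min) &&
               0 < dispersed_min && dispersed_min < pellet_min,
             "need 0 < dispersed_min < pellet_min")
  ifelse(area_um2 >= pellet_min, "pellet",
         ifelse(area_um2 >= dispersed_min, "dispersed", "excluded"))
}

#' Dimensionless Morphology Number
#'
#' `MN = 2 * sqrt(Area) * Solidity / (sqrt(pi) * Feret * AspectRatio)`:
#' 1 for a perfect circle, approaching 0 for a one-dimensional line. Units
#' cancel when area is in square micrometres and the Feret diameter in
#' micrometres. MN increases with solidity and decreases with aspect ratio
#' at fixed area and Feret diameter.
#'
#' @param area_um2 structure area (> 0).
#' @param solidity area / convex hull area, in `(0, 1]`.
#' @param feret_max_um maximum Feret (caliper) diameter (> 0).
#' @param aspect_ratio max/min Feret quotient (>= 1).
#' @return Numeric vector of Morphology Numbers.
#' @export
#' @examples
#' r <- 50
#' morphology_number(pi * r^2, 1, 2 * r, 1)  # exactly 1
morphology_number <- function(area_um2, solidity, feret_max_um, aspect_ratio) {
  check_that(all(area_um2 > 0) && all(feret_max_um > 0),
             "area and Feret diameter must be positive")
  check_that(all(solidity > 0) && all(solidity <= 1),
             "solidity must lie in (0, 1]")
  check_that(all(aspect_ratio >= 1), "aspect ratio must be >= 1")
  2 * sqrt(area_um2) * solidity / (sqrt(pi) * feret_max_um * aspect_ratio)
}

#' Measure every structure in a binary culture image
#'
#' Labels 8-connected structures, computes shape descriptors, classifies by
#' area and evaluates the Morphology Number for measured (pellet or
#' dispersed) structures; excluded structures keep their descriptors but
#' get `NA` for MN.
#'
#' @inheritParams label_structures
#' @inheritParams classify_structure
#' @return data.frame, one row per structure: descriptors plus `size_class`
#'   and `morphology_number`.
#' @export
measure_structures <- function(image, pixel_size_um,
                               dispersed_min = 95, pellet_min = 500) {
  masks <- label_structures(image, pixel_size_um)
  if (length(masks) == 0L) {
    return(data.frame(object_id = integer(), area_um2 = numeric(),
                      feret_max_um = numeric(), feret_min_um = numeric(),
                      aspect_ratio = numeric(), solidity = numeric(),
                      size_class = character(), morphology_number = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(masks, shape_descriptors))
  df$size_class <- classify_structure(df$area_um2, dispersed_min, pellet_min)
  df$morphology_number <- ifelse(
    df$size_class == "excluded", NA_real_,
    morphology_number(df$area_um2, df$solidity, df$feret_max_um,
                      df$aspect_ratio))
  rownames(df) <- NULL
  df
}

#' Summarise the morphology of one culture image
#'
#' The pellet area fraction is the pelleted share of the measured fungal
#' area -- excluded structures contribute to neither numerator nor
#' denominator -- reported as a percentage. Morphology Numbers are
#' summarised over pellets only, matching how pellet MN distributions are
#' reported. With no measured structures the fraction is `NA` (undefined),
#' not 0.
#'
#' @param metrics data.frame from [measure_structures()] (may be empty).
#' @return A `culture_summary`: list with `n_pellets`, `n_dispersed`,
#'   `n_excluded`, `pellet_area_fraction_pct`, `mn_values`, `mn_mean`,
#'   `mn_median`.
#' @export
summarize_culture <- function(metrics) {
  check_that(is.data.frame(metrics) &&
               all(c("area_um2", "size_class") %in% names(metrics)),
             "`metrics` must come from measure_structures()")
  cls <- metrics$size_class
  pellet_area <- sum(metrics$area_um2[cls == "pellet"])
  measured_area <- sum(metrics$area_um2[cls != "excluded"])
  mn <- if ("morphology_number" %in% names(metrics)) {
    metrics$morphology_number[cls == "pellet"]
  } else {
    numeric()
  }
  structure(list(
    n_pellets = sum(cls == "pellet"),
    n_dispersed = sum(cls == "dispersed"),
    n_excluded = sum(cls == "excluded"),
    pellet_area_fraction_pct =
      if (measured_area > 0) 100 * pellet_area / measured_area else NA_real_,
    mn_values = mn,
    mn_mean = if (length(mn) > 0) mean(mn) else NA_real_,
    mn_median = if (length(mn) > 0) stats::median(mn) else NA_real_),
    class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat(sprintf(paste0("Culture morphology: %d pellets, %d dispersed, ",
                     "%d excluded\n"),
              x$n_pellets, x$n_dispersed, x$n_excluded))
  if (is.na(x$pellet_area_fraction_pct)) {
    cat("  pellet area fraction: undefined (no measured structures)\n")
  } else {
    cat(sprintf("  pellet area fraction: %.1f%% of measured fungal area\n",
                x$pellet_area_fraction_pct))
  }
  if (length(x$mn_values) > 0) {
    cat(sprintf("  pellet MN: mean %.3f, median %.3f (n = %d)\n",
                x$mn_mean, x$mn_median, length(x$mn_values)))
  }
  invisible(x)
}
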