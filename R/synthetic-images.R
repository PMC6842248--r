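# Rendering of binary culture images with known shape ground truth.
#
# Submerged cultures of filamentous fungi contain large compact pellets and
# small dispersed mycelial fragments. The renderer produces pre-thresholded
# binary masks directly (no simulated illumination): the downstream
# quantification operates on thresholded structures, so grayscale realism
# would add nothing testable.

#' Specify a pellet (rough-edged ellipse) for rendering
#'
#' @param center_um numeric length-2, object centre (x, y) in micrometres
#'   from the image's top-left corner.
#' @param major_um,minor_um full axis lengths in micrometres.
#' @param orientation_deg rotation of the major axis, degrees
#'   counter-clockwise.
#' @param roughness boundary modulation amplitude in `[0, 0.3]`; the radius
#'   is modulated by `1 + roughness * cos(6 * angle + phase)` and rescaled so
#'   the enclosed area still equals `pi * major * minor / 4`.
#' @return A `pellet_spec` list.
#' @export
pellet_spec <- function(center_um, major_um, minor_um = major_um,
                        orientation_deg = 0, roughness = 0) {
  check_that(is.numeric(center_um) && length(center_um) == 2L,
             "`center_um` must be (x, y)")
  check_that(is_scalar_number(major_um) && major_um > 0 &&
               is_scalar_number(minor_um) && minor_um > 0 &&
               major_um >= minor_um,
             "axes must be positive with major >= minor")
  check_that(is_scalar_number(roughness) && roughness >= 0 && roughness <= 0.3,
             "`roughness` must lie in [0, 0.3]")
  structure(list(center_um = as.numeric(center_um), major_um = major_um,
                 minor_um = minor_um, orientation_deg = orientation_deg,
                 roughness = roughness),
            class = "pellet_spec")
}

#' Specify a dispersed fragment (small blob or hyphal line) for rendering
#'
#' @param center_um numeric length-2 centre in micrometres.
#' @param area_um2 requested area; dispersed structures occupy `[95, 500)`
#'   square micrometres but any positive area may be requested.
#' @param kind `"blob"` (compact) or `"line"` (elongated, hyphae-like).
#' @return A `fragment_spec` list.
#' @export
fragment_spec <- function(center_um, area_um2, kind = c("blob", "line")) {
  kind <- match.arg(kind)
  check_that(is.numeric(center_um) && length(center_um) == 2L,
             "`center_um` must be (x, y)")
  check_that(is_scalar_number(area_um2) && area_um2 > 0,
             "`area_um2` must be positive")
  structure(list(center_um = as.numeric(center_um), area_um2 = area_um2,
                 kind = kind),
            class = "fragment_spec")
}

#' Specify a synthetic culture image
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param pellets list of [pellet_spec()] objects.
#' @param fragments list of [fragment_spec()] objects.
#' @param seed integer seed (controls boundary-roughness phases).
#' @return An `image_spec` list.
#' @export
image_spec <- function(width_px, height_px, pixel_size_um,
                       pellets = list(), fragments = list(), seed = 1L) {
  check_that(is_count(width_px, 1L) && is_count(height_px, 1L),
             "image dimensions must be positive counts")
  check_that(is_scalar_number(pixel_size_um) && pixel_size_um > 0,
             "`pixel_size_um` must be positive")
  check_that(all(vapply(pellets, inherits, logical(1), "pellet_spec")),
             "`pellets` must be pellet_spec objects")
  check_that(all(vapply(fragments, inherits, logical(1), "fragment_spec")),
             "`fragments` must be fragment_spec objects")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 pellets = pellets, fragments = fragments,
                 seed = as.integer(seed)),
            class = "image_spec")
}

# conservative bounding radius in um, used for overlap/bounds checks
object_radius_um <- function(obj, pixel_size_um) {
  if (inherits(obj, "pellet_spec")) {
    obj$major_um / 2 * (1 + obj$roughness)
  } else {
    n_px <- max(1, round(obj$area_um2 / pixel_size_um^2))
    dims <- fragment_box_px(n_px, obj$kind)
    sqrt(sum(dims^2)) / 2 * pixel_size_um
  }
}

# width/height in px of the bounding box a fragment's pixels are packed into
fragment_box_px <- function(n_px, kind) {
  if (kind == "line") {
    h <- max(1L, floor(sqrt(n_px / 8)))
  } else {
    h <- max(1L, round(sqrt(n_px)))
  }
  w <- ceiling(n_px / h)
  c(w = w, h = h)
}

#' Render a binary culture image with its ground-truth table
#'
#' Pellets are rasterised by pixel-centre inclusion inside an (optionally
#' rough-edged) ellipse; fragments are packed pixel sets whose rendered area
#' matches the request to within one pixel. Objects must lie fully inside
#' the image and keep a >= 2 pixel gap from each other so that 8-connected
#' labelling never merges them.
#'
#' @param spec an [image_spec()].
#' @return list with `image` (integer matrix, 0 background / 255 foreground),
#'   `truth` (data.frame: object_id, kind, true_area_um2, true_major_um,
#'   true_minor_um, size_class) and `pixel_size_um`.
#' @export
#' @examples
#' sp <- image_spec(200, 200, 1, pellets = list(pellet_spec(c(100, 100), 60)))
#' out <- render_culture_image(sp)
#' out$truth
render_culture_image <- function(spec) {
  check_that(inherits(spec, "image_spec"), "`spec` must be an image_spec")
  ps <- spec$pixel_size_um
  w_um <- spec$width_px * ps
  h_um <- spec$height_px * ps
  objects <- c(spec$pellets, spec$fragments)

  if (length(objects) > 0) {
    radii <- vapply(objects, object_radius_um, numeric(1), pixel_size_um = ps)
    centers <- t(vapply(objects, `[[`, numeric(2), "center_um"))
    margin <- 2 * ps
    inside <- centers[, 1] - radii >= margin & centers[, 1] + radii <= w_um - margin &
      centers[, 2] - radii >= margin & centers[, 2] + radii <= h_um - margin
    if (!all(inside)) {
      stop("objects ", paste(which(!inside), collapse = ", "),
           " extend outside the image", call. = FALSE)
    }
    if (length(objects) > 1) {
      d <- as.matrix(stats::dist(centers))
      sep <- outer(radii, radii, `+`) + margin
      diag(d) <- Inf
      if (any(d <= sep)) {
        stop("objects overlap or touch (minimum 2-pixel gap required)",
             call. = FALSE)
      }
    }
  }

  img <- matrix(0L, spec$height_px, spec$width_px)
  truth <- list()
  obj_id <- 0L

  phases <- with_seed(spec$seed,
                      stats::runif(max(1L, length(spec$pellets)), 0, 2 * pi))

  # pixel-centre coordinate grids in um
  xc <- (seq_len(spec$width_px) - 0.5) * ps
  yc <- (seq_len(spec$height_px) - 0.5) * ps

  for (i in seq_along(spec$pellets)) {
    p <- spec$pellets[[i]]
    obj_id <- obj_id + 1L
    a <- p$major_um / 2
    b <- p$minor_um / 2
    theta <- p$orientation_deg * pi / 180
    # restrict to the bounding box for speed
    rmax <- a * (1 + p$roughness)
    jx <- which(abs(xc - p$center_um[1]) <= rmax + ps)
    iy <- which(abs(yc - p$center_um[2]) <= rmax + ps)
    dx <- outer(rep(1, length(iy)), xc[jx] - p$center_um[1])
    dy <- outer(yc[iy] - p$center_um[2], rep(1, length(jx)))
    u <- (cos(theta) * dx + sin(theta) * dy) / a
    v <- (-sin(theta) * dx + cos(theta) * dy) / b
    rho2 <- u^2 + v^2
    if (p$roughness > 0) {
      phi <- atan2(v, u)
      bound <- (1 + p$roughness * cos(6 * phi + phases[i])) /
        sqrt(1 + p$roughness^2 / 2)
      keep <- rho2 <= bound^2
    } else {
      keep <- rho2 <= 1
    }
    img[iy, jx][keep] <- 255L
    area <- pi * a * b
    truth[[obj_id]] <- data.frame(
      object_id = obj_id, kind = "pellet", true_area_um2 = area,
      true_major_um = p$major_um, true_minor_um = p$minor_um,
      size_class = classify_structure(area), stringsAsFactors = FALSE)
  }

  for (f in spec$fragments) {
    obj_id <- obj_id + 1L
    n_px <- max(1L, round(f$area_um2 / ps^2))
    box <- fragment_box_px(n_px, f$kind)
    j0 <- round(f$center_um[1] / ps - box["w"] / 2)
    i0 <- round(f$center_um[2] / ps - box["h"] / 2)
    cells <- seq_len(n_px) - 1L
    rows <- i0 + 1L + cells %/% box["w"]
    cols <- j0 + 1L + cells %% box["w"]
    img[cbind(rows, cols)] <- 255L
    truth[[obj_id]] <- data.frame(
      object_id = obj_id, kind = f$kind, true_area_um2 = f$area_um2,
      true_major_um = box[["w"]] * ps, true_minor_um = box[["h"]] * ps,
      size_class = classify_structure(f$area_um2), stringsAsFactors = FALSE)
  }

  truth_df <- if (length(truth) > 0) {
    do.call(rbind, truth)
  } else {
    data.frame(object_id = integer(), kind = character(),
               true_area_um2 = numeric(), true_major_um = numeric(),
               true_minor_um = numeric(), size_class = character(),
               stringsAsFactors = FALSE)
  }
  rownames(truth_df) <- NULL
  list(image = img, truth = truth_df, pixel_size_um = ps)
}

#' Write or read a binary image as 8-bit grayscale PNG
#'
#' Foreground pixels are stored as 255, background as 0.
#'
#' @param image integer/numeric matrix with values in `{0, 255}`.
#' @param path file path.
#' @return `read_culture_image` returns an integer 0/255 matrix;
#'   `write_culture_image` returns `path` invisibly.
#' @export
write_culture_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_culture_image
#' @export
read_culture_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grayscale saved as RGB
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
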