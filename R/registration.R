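#' Anatomical key-points of a cortical window
#'
#' Three landmarks visible through a transcranial window that anchor the
#' atlas alignment: bregma, a second point posterior along the superior
#' sagittal sinus (both on the midline), and the boundary between olfactory
#' bulb and frontal cortex (anterior midline).
#'
#' @param bregma_px,sinus_px,ob_frontal_px numeric `(x, y)` pixel
#'   coordinates (x = column rightward, y = row downward, 0-based pixel
#'   centers).
#' @return object of class `key_points`.
#' @export
key_points <- function(bregma_px, sinus_px, ob_frontal_px) {
  kp <- list(bregma_px = as.numeric(bregma_px),
             sinus_px = as.numeric(sinus_px),
             ob_frontal_px = as.numeric(ob_frontal_px))
  if (any(vapply(kp, length, 1L) != 2L)) stopf("key-points must be (x, y) pairs")
  m <- do.call(rbind, kp)
  if (any(duplicated(m))) stopf("key-points must be distinct")
  class(kp) <- "key_points"
  kp
}

# Matching atlas-frame coordinates (mm from bregma; x = ML toward the right
# hemisphere, y = AP, anterior positive) for the three key-points. The sinus
# point sits 4 mm posterior on the midline, the olfactory-bulb/frontal
# boundary ~3.2 mm anterior on the midline.
#' @rdname key_points
#' @export
atlas_key_points <- function() {
  rbind(bregma = c(ML = 0, AP = 0),
        sinus = c(ML = 0, AP = -4),
        ob_frontal = c(ML = 0, AP = 3.2))
}

#' Default cortical region coordinate table
#'
#' The ten named dorsal-cortex regions used throughout the region-level
#' analyses, with their anterior-posterior (AP) and mediolateral (ML)
#' distances from bregma in mm. The values are editable defaults placed at
#' standard Common Coordinate Framework positions; they are configuration,
#' not measured quantities.
#'
#' @param hemisphere `"right"` (ML > 0), `"left"` (ML < 0).
#' @return object of class `region_set`: data.frame with columns `name`,
#'   `AP_mm`, `ML_mm` and (after [place_regions()]) `x_px`, `y_px`,
#'   `in_mask`.
#' @export
default_regions <- function(hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  rs <- data.frame(
    name = c("ALM", "M2", "wM1", "aBC", "pBC",
             "HL", "FL", "lPTA", "RS", "V1"),
    AP_mm = c(2.5, 1.5, 1.0, -0.6, -1.8,
              -1.0, 0.2, -2.0, -2.8, -3.6),
    ML_mm = c(1.5, 0.9, 1.3, 3.0, 3.2,
              1.7, 2.2, 2.2, 0.6, 2.5),
    stringsAsFactors = FALSE
  )
  if (hemisphere == "left") rs$ML_mm <- -rs$ML_mm
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Fit a similarity transform from atlas coordinates to image pixels
#'
#' Least-squares similarity transform (rotation + isotropic scale +
#' translation, no shear) mapping atlas-frame mm coordinates onto window
#' pixels, such that the bregma-to-sinus axis maps onto the atlas midline.
#' The atlas AP axis (anterior positive) is flipped into the image row
#' direction (rows grow downward/posterior), and the fit is solved in closed
#' form as a complex linear regression, which remains well-posed for the
#' collinear midline key-point triple.
#'
#' @param kp a [key_points()] object.
#' @param atlas_kp_mm 3x2 matrix of matching atlas `(ML, AP)` mm coordinates,
#'   rows in the order bregma, sinus, ob_frontal (default
#'   [atlas_key_points()]).
#' @return object of class `similarity_transform` with fields `scale`
#'   (mm/pixel), `rotation` (radians), `translation` (pixels) and the
#'   internal complex coefficients.
#' @export
fit_transform <- function(kp, atlas_kp_mm = atlas_key_points()) {
  stopifnot(inherits(kp, "key_points"))
  px <- rbind(kp$bregma_px, kp$sinus_px, kp$ob_frontal_px)
  if (nrow(atlas_kp_mm) != 3L) stopf("need 3 matching atlas key-points")
  # image-frame atlas coordinates: x = ML, y = -AP (anterior is up)
  za <- complex(real = atlas_kp_mm[, 1L], imaginary = -atlas_kp_mm[, 2L])
  zp <- complex(real = px[, 1L], imaginary = px[, 2L])
  za_c <- za - mean(za)
  denom <- sum(Mod(za_c)^2)
  if (denom < 1e-12) stopf("atlas key-points are coincident; cannot fit")
  alpha <- sum(Conj(za_c) * (zp - mean(zp))) / denom
  if (Mod(alpha) < 1e-12) stopf("degenerate key-points; transform not invertible")
  beta <- mean(zp) - alpha * mean(za)
  tr <- list(scale = 1 / Mod(alpha), rotation = Arg(alpha),
             translation = c(Re(beta), Im(beta)),
             alpha = alpha, beta = beta)
  class(tr) <- "similarity_transform"
  tr
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("Similarity transform: %.2f um/px, rotation %.2f deg, translation (%.1f, %.1f) px\n",
              1000 * x$scale, 180 / pi * x$rotation,
              x$translation[1L], x$translation[2L]))
  invisible(x)
}

#' Map atlas mm coordinates to image pixels (and back)
#'
#' @param tr a fitted `similarity_transform`.
#' @param mm matrix/data.frame with columns `(ML_mm, AP_mm)`.
#' @return matrix with columns `x_px`, `y_px` (for the inverse, `ML_mm`,
#'   `AP_mm`).
#' @export
transform_mm_to_px <- function(tr, mm) {
  mm <- as.matrix(mm)
  z <- tr$alpha * complex(real = mm[, 1L], imaginary = -mm[, 2L]) + tr$beta
  cbind(x_px = Re(z), y_px = Im(z))
}

#' @rdname transform_mm_to_px
#' @param px matrix with columns `(x_px, y_px)`.
#' @export
transform_px_to_mm <- function(tr, px) {
  px <- as.matrix(px)
  z <- (complex(real = px[, 1L], imaginary = px[, 2L]) - tr$beta) / tr$alpha
  cbind(ML_mm = Re(z), AP_mm = -Im(z))
}

#' Place named regions on the imaging window
#'
#' Maps each region's (AP, ML) mm coordinates through the fitted transform,
#' rounds to the nearest pixel center, and flags regions whose location falls
#' outside the provided mask. Regions outside the image bounds are an error
#' (named), since their time series cannot be extracted at all.
#'
#' @param tr a fitted `similarity_transform`.
#' @param rs a `region_set` (e.g. [default_regions()]).
#' @param mask H x W logical matrix of in-window pixels.
#' @return the `region_set` with `x_px`, `y_px` (0-based) and `in_mask`
#'   columns filled.
#' @export
place_regions <- function(tr, rs, mask) {
  pts <- transform_mm_to_px(tr, cbind(rs$ML_mm, rs$AP_mm))
  x <- round(pts[, 1L]); y <- round(pts[, 2L])
  h <- nrow(mask); w <- ncol(mask)
  out <- x < 0 | x > w - 1L | y < 0 | y > h - 1L
  if (any(out))
    stopf("region(s) outside image bounds: %s",
          paste(rs$name[out], collapse = ", "))
  rs$x_px <- as.integer(x)
  rs$y_px <- as.integer(y)
  rs$in_mask <- mask[cbind(y + 1L, x + 1L)]
  rs
}

#' Serialize / restore a similarity transform as JSON
#' @param tr transform; `path` file path.
#' @rdname fit_transform
#' @export
write_transform <- function(tr, path) {
  jsonlite::write_json(list(scale = tr$scale, rotation = tr$rotation,
                            translation = tr$translation,
                            alpha = c(Re(tr$alpha), Im(tr$alpha)),
                            beta = c(Re(tr$beta), Im(tr$beta))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_transform
#' @param path JSON file written by `write_transform`.
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- list(scale = j$scale, rotation = j$rotation,
             translation = j$translation,
             alpha = complex(real = j$alpha[1L], imaginary = j$alpha[2L]),
             beta = complex(real = j$beta[1L], imaginary = j$beta[2L]))
  class(tr) <- "similarity_transform"
  tr
}
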