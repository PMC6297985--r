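# Leaf-area estimation: greenish-pixel counting on RGB images,
# pixel -> area calibration by ordinary least squares, and cubic-spline
# interpolation of leaf area over experiment time.

#' Count plant (greenish) pixels in an RGB image
#'
#' Converts RGB to HSV and counts pixels whose hue falls inside the
#' green window and whose saturation reaches the threshold. Defaults
#' (hue 60-180 degrees, saturation >= 0.15) suit plants photographed in
#' front of a blue background; both are per-species tunables.
#'
#' @param image Numeric array `height x width x 3` with values in
#'   \[0, 1\] (values in \[0, 255\] are rescaled automatically), or a path
#'   to an ASCII PPM (P3) file.
#' @param hue_min,hue_max Hue window, degrees (default 60-180).
#' @param min_saturation Saturation threshold, fraction (default 0.15).
#' @return Integer pixel count.
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 3] <- 1  # all blue
#' count_plant_pixels(img)  # 0
#' @export
count_plant_pixels <- function(image, hue_min = 60, hue_max = 180,
                               min_saturation = 0.15) {
  if (is.character(image)) image <- read_ppm(image)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    cf_stop_input("`image` must be a height x width x 3 RGB array")
  if (length(image) == 0L || any(dim(image)[1:2] == 0L))
    cf_stop_input("empty image")
  if (max(image) > 1) image <- image / 255
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 1)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  sum(hue >= hue_min & hue <= hue_max & sat >= min_saturation)
}

#' Fit a pixel-count to leaf-area calibration line
#'
#' Ordinary least squares `area = slope * pixels + intercept` on
#' calibration plants of known (destructively measured) leaf area. A
#' through-origin variant is available.
#'
#' @param pixel_counts Numeric vector of extracted pixel counts.
#' @param areas_cm2 Matching measured leaf areas, cm2.
#' @param through_origin Force `intercept = 0` (default `FALSE`).
#' @return Object of class `leaf_area_calibration` with `slope`
#'   (cm2/pixel), `intercept` (cm2), `r_squared`, `n_points`.
#' @export
fit_calibration <- function(pixel_counts, areas_cm2, through_origin = FALSE) {
  if (length(pixel_counts) != length(areas_cm2))
    cf_stop_input("`pixel_counts` and `areas_cm2` lengths differ")
  if (length(pixel_counts) < 2L)
    cf_stop(sprintf("calibration needs >= 2 points, got %d", length(pixel_counts)),
            "cf_fit_error")
  if (length(unique(pixel_counts)) < 2L)
    cf_stop("degenerate design: all pixel counts equal", "cf_fit_error")
  if (through_origin) {
    fit <- lm(areas_cm2 ~ pixel_counts - 1)
    slope <- unname(coef(fit)[1]); intercept <- 0
  } else {
    fit <- lm(areas_cm2 ~ pixel_counts)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  }
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((areas_cm2 - mean(areas_cm2))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, n_points = length(pixel_counts)),
            class = "leaf_area_calibration")
}

#' @export
print.leaf_area_calibration <- function(x, ...) {
  cat(sprintf("<leaf_area_calibration> area = %.6g * pixels + %.6g cm2 (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Estimate leaf area from a pixel count via a fitted calibration
#'
#' @param calibration A [fit_calibration()] result.
#' @param pixel_counts Pixel count(s).
#' @return Estimated leaf area(s), cm2.
#' @export
estimate_area <- function(calibration, pixel_counts) {
  if (!inherits(calibration, "leaf_area_calibration"))
    cf_stop_input("`calibration` must be a leaf_area_calibration")
  calibration$slope * pixel_counts + calibration$intercept
}

#' Leaf-area timeline with natural cubic-spline interpolation
#'
#' Leaf area is measured photographically only every few days; rates at
#' intermediate timestamps use a natural cubic spline through the
#' measurements. When several images per time point are available their
#' pixel counts are averaged before calibration.
#'
#' @param times_days Measurement times, days since experiment start,
#'   strictly increasing.
#' @param areas_m2 Measured leaf areas, m2 (> 0).
#' @return Object of class `leaf_area_timeline`.
#' @export
leaf_area_timeline <- function(times_days, areas_m2) {
  times_days <- as.numeric(times_days); areas_m2 <- as.numeric(areas_m2)
  if (length(times_days) != length(areas_m2) || length(times_days) < 1L)
    cf_stop_input("times and areas must be equal-length, non-empty")
  if (any(diff(times_days) <= 0))
    cf_stop_input("`times_days` must be strictly increasing")
  if (any(!is.finite(areas_m2)) || any(areas_m2 <= 0))
    cf_stop_input("`areas_m2` must be positive and finite")
  structure(list(times_days = times_days, areas_m2 = areas_m2),
            class = "leaf_area_timeline")
}

#' Interpolate leaf area at arbitrary experiment times
#'
#' Natural cubic-spline evaluation of a [leaf_area_timeline()];
#' measurement times return the measured values exactly, and
#' extrapolation beyond the first/last measurement is refused.
#'
#' @param timeline A [leaf_area_timeline()].
#' @param query_days Query times, days since experiment start.
#' @return Interpolated areas, m2.
#' @export
interpolate_area <- function(timeline, query_days) {
  if (!inherits(timeline, "leaf_area_timeline"))
    cf_stop_input("`timeline` must be a leaf_area_timeline")
  t <- timeline$times_days; a <- timeline$areas_m2
  eps <- 1e-9 * max(1, diff(range(t)))
  if (any(query_days < min(t) - eps) || any(query_days > max(t) + eps))
    cf_stop(sprintf("query outside measured range [%g, %g] days; extrapolation refused",
                    min(t), max(t)), "cf_range_error")
  query_days <- pmin(pmax(query_days, min(t)), max(t))
  if (length(t) == 1L) return(rep_len(a, length(query_days)))
  if (length(t) == 2L) return(approx(t, a, xout = query_days)$y)
  splinefun(t, a, method = "natural")(query_days)
}

# -- ASCII PPM (P3) raster I/O ----------------------------------------
# Plain-text raster format: portable, diff-able, adequate for the small
# synthetic calibration images used in tests.

#' Read / write ASCII PPM (P3) images
#'
#' Minimal plain-text raster I/O used for synthetic calibration images.
#' `read_ppm()` returns a `height x width x 3` array scaled to \[0, 1\].
#'
#' @param path File path.
#' @return `read_ppm()`: RGB array.
#' @export
read_ppm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tokens <- scan(text = paste(txt, collapse = " "), what = character(),
                 quiet = TRUE)
  if (length(tokens) < 4L || tokens[1] != "P3")
    cf_stop_input(sprintf("%s: not an ASCII PPM (P3) file", path))
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != 3L * w * h)
    cf_stop_input(sprintf("%s: expected %d samples, found %d", path,
                          3L * w * h, length(vals)))
  # PPM stores row-major RGB triplets
  arr <- array(0, c(h, w, 3))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  for (ch in 1:3) arr[, , ch] <- matrix(m[, ch], nrow = h, byrow = TRUE)
  arr / maxval
}

#' @param image RGB array (values in \[0, 1\]).
#' @param maxval Sample max value written to file (default 255).
#' @rdname read_ppm
#' @export
write_ppm <- function(image, path, maxval = 255) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    cf_stop_input("`image` must be a height x width x 3 RGB array")
  h <- dim(image)[1]; w <- dim(image)[2]
  vals <- round(pmin(pmax(image, 0), 1) * maxval)
  m <- cbind(as.vector(t(vals[, , 1])), as.vector(t(vals[, , 2])),
             as.vector(t(vals[, , 3])))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxval)), con)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}
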