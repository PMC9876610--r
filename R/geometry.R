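#' Pixels per degree of visual angle
#'
#' Converts degrees of visual angle to on-screen pixels for a flat screen
#' viewed head-on. The default geometry is a 24-inch 16:9 monitor
#' (531 x 299 mm active area) at 1920 x 1080 px viewed from 60 cm, the
#' typical desktop eye-tracking arrangement this pipeline targets.
#'
#' @param screen_width_px horizontal resolution in pixels.
#' @param screen_width_mm physical width of the display area in mm.
#' @param distance_mm viewing distance in mm.
#' @return pixels subtended by one degree at the screen centre.
#' @export
px_per_degree <- function(screen_width_px = 1920, screen_width_mm = 531,
                          distance_mm = 600) {
  mm_per_deg <- distance_mm * tan(pi / 180)
  mm_per_deg * screen_width_px / screen_width_mm
}

#' Construct a rectangle
#'
#' Rectangles are half-open: a point (x, y) is inside iff
#' x0 <= x < x1 and y0 <= y < y1. Screen origin is top-left.
#'
#' @param x0,y0 top-left corner (pixels).
#' @param x1,y1 bottom-right corner (pixels, exclusive).
#' @return named numeric vector of class `gaze_rect`.
#' @export
aoi_rect <- function(x0, y0, x1, y1) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.numeric(x1), is.numeric(y1))
  if (x1 <= x0 || y1 <= y0) stop("rectangle must have positive extent")
  structure(c(x0 = unname(x0), y0 = unname(y0),
              x1 = unname(x1), y1 = unname(y1)), class = "gaze_rect")
}

#' Test points against a rectangle (half-open convention)
#'
#' @param x,y point coordinates in pixels (vectorised).
#' @param r a rectangle from [aoi_rect()].
#' @return logical vector; NA coordinates give FALSE.
#' @export
in_rect <- function(x, y, r) {
  inside <- x >= r["x0"] & x < r["x1"] & y >= r["y0"] & y < r["y1"]
  inside & !is.na(inside)
}

#' Areas of interest for the face-viewing task
#'
#' An AOI set holds the eyes rectangle (both eyes jointly), the face
#' rectangle, and the screen size. The eyes rectangle must lie fully
#' inside the face rectangle; fixation centroids are labelled `eyes` if
#' inside the eyes rectangle, else `face` if inside the face rectangle,
#' else `off`.
#'
#' @param eyes_rect,face_rect rectangles from [aoi_rect()].
#' @param screen c(width, height) in pixels.
#' @return list of class `aoi_set`.
#' @export
aoi_set <- function(eyes_rect, face_rect, screen = c(1920, 1080)) {
  stopifnot(inherits(eyes_rect, "gaze_rect"), inherits(face_rect, "gaze_rect"))
  if (eyes_rect["x0"] < face_rect["x0"] || eyes_rect["x1"] > face_rect["x1"] ||
      eyes_rect["y0"] < face_rect["y0"] || eyes_rect["y1"] > face_rect["y1"]) {
    stop("eyes_rect must lie fully inside face_rect")
  }
  structure(list(eyes = eyes_rect, face = face_rect, screen = screen),
            class = "aoi_set")
}

#' Default AOI geometry
#'
#' The face is a centred square subtending `face_deg` degrees of visual
#' angle (default 20 x 20 deg, the stimulus size of the task this pipeline
#' models); the eyes AOI is a full-width band from 25% to 45% of face
#' height measured from the top of the face, covering both eyes jointly.
#' Real studies should measure their AOIs on the stimuli and pass them in;
#' these defaults exist so that the simulator and the preprocessing stage
#' share one geometry.
#'
#' @param screen c(width, height) pixels.
#' @param face_deg face extent in degrees of visual angle.
#' @param ppd pixels per degree, see [px_per_degree()].
#' @param eyes_band_frac c(top, bottom) of the eyes band as fractions of
#'   face height from the top of the face.
#' @return an [aoi_set()].
#' @export
default_aois <- function(screen = c(1920, 1080), face_deg = 20,
                         ppd = px_per_degree(),
                         eyes_band_frac = c(0.25, 0.45)) {
  side <- face_deg * ppd
  cx <- screen[1] / 2
  cy <- screen[2] / 2
  face <- aoi_rect(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
  eyes <- aoi_rect(face["x0"], face["y0"] + eyes_band_frac[1] * side,
               face["x1"], face["y0"] + eyes_band_frac[2] * side)
  aoi_set(eyes, face, screen)
}
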