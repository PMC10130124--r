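#' Bounding-box centre in image coordinates
#'
#' The detector reports each hand as an axis-aligned box (left, top, width,
#' height) in image coordinates, origin at the top-left corner with y pointing
#' downward. The hand's location is taken to be the centre of that box.
#'
#' @param left,top,width,height Box coordinates in pixels; vectorised.
#' @return A tibble with columns `cx` and `cy_image` (pixels, image
#'   coordinates), one row per box.
#' @export
#' @examples
#' bbox_centre(100, 40, 56, 20)   # cx 128, cy_image 50
#' bbox_centre(0, 0, 456, 256)    # the centre of a full frame: (228, 128)
bbox_centre <- function(left, top, width, height) {
  if (any(!is.finite(width)) || any(!is.finite(height)) ||
      any(width <= 0) || any(height <= 0)) {
    abort("invalid box: width and height must be finite and > 0")
  }
  if (any(!is.finite(left)) || any(!is.finite(top))) {
    abort("invalid box: left and top must be finite")
  }
  tibble::tibble(cx = left + width / 2, cy_image = top + height / 2)
}

#' Convert an image-coordinate y to Cartesian screen coordinates
#'
#' Image coordinates place the origin at the top-left corner with y growing
#' downward; plots and hemiscene reasoning use Cartesian coordinates with the
#' origin at the bottom-left. The conversion reflects y about the horizontal
#' midline: `y = frame_height - cy_image`. The vertical midline of the frame
#' is a fixed point.
#'
#' @param cy_image Vertical centre coordinate in image coordinates (pixels);
#'   vectorised.
#' @param frame_height Frame height in pixels (scalar or vector recycled
#'   against `cy_image`).
#' @return Cartesian y in pixels, 0 at the bottom edge.
#' @export
#' @examples
#' to_cartesian(0, 256)    # image top -> 256
#' to_cartesian(128, 256)  # midline is fixed
to_cartesian <- function(cy_image, frame_height) {
  if (any(!is.finite(cy_image)) || any(cy_image < 0) ||
      any(cy_image > frame_height)) {
    abort("cy_image outside [0, frame_height]")
  }
  frame_height - cy_image
}

#' Classify hand-centre points into hemiscenes, quadrants and laterality
#'
#' Splits the frame by its vertical and horizontal midlines (`width/2`,
#' `height/2`, real-valued) and assigns each Cartesian centre point to an
#' upper/lower vertical hemiscene, a left/right horizontal hemiscene, the
#' quadrant formed by the two, and — when a hand side is supplied — an
#' ipsilateral/contralateral zone (a left hand in the left hemiscene is
#' ipsilateral).
#'
#' Points falling exactly on a midline are assigned by the `tie` rule;
#' with real-valued centres these ties have essentially measure zero, but the
#' rule is exposed so its (in)sensitivity can be demonstrated. The default
#' sends midline points to the lower and left zones.
#'
#' @param x,y Cartesian centre coordinates in pixels (0 = left edge, 0 =
#'   bottom edge); vectorised.
#' @param frame_width,frame_height Frame geometry in pixels (recycled).
#' @param side Optional hand side (`"left"`/`"right"`, recycled); enables the
#'   `laterality` column.
#' @param tie Midline tie-break: `"lower_left"` (default) or `"upper_right"`.
#' @return A tibble with columns `vertical` (`"upper"`/`"lower"`),
#'   `horizontal` (`"left"`/`"right"`), `quadrant` (`"UL"`, `"UR"`, `"LL"`,
#'   `"LR"`) and `laterality` (`"ipsilateral"`/`"contralateral"`, `NA` when no
#'   side was given).
#' @export
#' @examples
#' classify_location(100, 50, 456, 256, side = "left")  # LL, ipsilateral
#' classify_location(300, 200, 456, 256, side = "left") # UR, contralateral
classify_location <- function(x, y, frame_width, frame_height, side = NULL,
                              tie = c("lower_left", "upper_right")) {
  tie <- match.arg(tie)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("non-finite centre coordinates")
  }
  if (any(x < 0 | x > frame_width | y < 0 | y > frame_height)) {
    abort("centre point outside frame")
  }
  xmid <- frame_width / 2
  ymid <- frame_height / 2
  if (tie == "lower_left") {
    vertical <- ifelse(y > ymid, "upper", "lower")
    horizontal <- ifelse(x > xmid, "right", "left")
  } else {
    vertical <- ifelse(y >= ymid, "upper", "lower")
    horizontal <- ifelse(x >= xmid, "right", "left")
  }
  quadrant <- paste0(ifelse(vertical == "upper", "U", "L"),
                     ifelse(horizontal == "right", "R", "L"))
  if (is.null(side)) {
    laterality <- rep(NA_character_, length(quadrant))
  } else {
    if (!all(is.na(side) | side %in% SIDE_LEVELS)) {
      abort("side must be \"left\" or \"right\"")
    }
    side <- rep_len(side, length(horizontal))
    laterality <- ifelse(is.na(side), NA_character_,
                         ifelse(horizontal == side, "ipsilateral", "contralateral"))
  }
  tibble::tibble(vertical = vertical, horizontal = horizontal,
                 quadrant = quadrant, laterality = laterality)
}
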