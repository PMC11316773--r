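#' Arena geometry and behavioural zones
#'
#' Describes the recording arena, the target object (food container or wired
#' social cage), the distance normalizer and the concentric zone radii used to
#' classify neurons as pro/neutral/anti with respect to the target.
#'
#' Default zone radii follow the behavioural definitions used for BLA
#' population imaging: feeding assays use a 5 cm pro-food and 17 cm anti-food
#' radius around the food container; social assays use 10 cm and 20 cm around
#' the wired cage. Distances are normalized by `norm_radius_cm` (typically the
#' chamber radius) and clipped to [0, 1].
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param center_x_cm,center_y_cm Arena center, cm.
#' @param radius_cm Radius for circular arenas, cm.
#' @param width_cm,height_cm Side lengths for rectangular arenas, cm.
#' @param target_x_cm,target_y_cm Target (food container / cage center), cm;
#'   must lie inside the arena.
#' @param norm_radius_cm Distance normalizer, cm (> 0). Normalized distance is
#'   `min(dist / norm_radius_cm, 1)`.
#' @param zone_inner_cm,zone_outer_cm Inner ("pro") and outer ("anti") zone
#'   radii, cm; `0 < inner < outer`.
#' @return An object of class `"arena_spec"`.
#' @examples
#' a <- arena_spec("circle", radius_cm = 24.5, target_x_cm = 10, target_y_cm = 0,
#'                 norm_radius_cm = 24.5, zone_inner_cm = 10, zone_outer_cm = 20)
#' @export
arena_spec <- function(shape = c("circle", "rectangle"),
                       center_x_cm = 0, center_y_cm = 0,
                       radius_cm = NULL, width_cm = NULL, height_cm = NULL,
                       target_x_cm = center_x_cm, target_y_cm = center_y_cm,
                       norm_radius_cm = NULL,
                       zone_inner_cm = 5, zone_outer_cm = 17) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    if (is.null(radius_cm) || radius_cm <= 0)
      stop("circular arena requires radius_cm > 0")
    if (is.null(norm_radius_cm)) norm_radius_cm <- radius_cm
  } else {
    if (is.null(width_cm) || is.null(height_cm) || width_cm <= 0 || height_cm <= 0)
      stop("rectangular arena requires width_cm > 0 and height_cm > 0")
    if (is.null(norm_radius_cm)) norm_radius_cm <- max(width_cm, height_cm) / 2
  }
  if (!is.finite(norm_radius_cm) || norm_radius_cm <= 0)
    stop("norm_radius_cm must be > 0")
  if (!(zone_inner_cm > 0 && zone_inner_cm < zone_outer_cm))
    stop("zone radii must satisfy 0 < zone_inner_cm < zone_outer_cm")
  a <- structure(list(
    shape = shape, center_x_cm = center_x_cm, center_y_cm = center_y_cm,
    radius_cm = radius_cm, width_cm = width_cm, height_cm = height_cm,
    target_x_cm = target_x_cm, target_y_cm = target_y_cm,
    norm_radius_cm = norm_radius_cm,
    zone_inner_cm = zone_inner_cm, zone_outer_cm = zone_outer_cm
  ), class = "arena_spec")
  if (!arena_contains(a, target_x_cm, target_y_cm))
    stop("target must lie inside the arena")
  a
}

#' Test whether points lie inside an arena
#'
#' @param arena An [arena_spec()].
#' @param x_cm,y_cm Coordinate vectors, cm.
#' @return Logical vector.
#' @export
arena_contains <- function(arena, x_cm, y_cm) {
  stopifnot(inherits(arena, "arena_spec"))
  if (arena$shape == "circle") {
    (x_cm - arena$center_x_cm)^2 + (y_cm - arena$center_y_cm)^2 <=
      arena$radius_cm^2 + 1e-12
  } else {
    hw <- arena$width_cm / 2; hh <- arena$height_cm / 2
    abs(x_cm - arena$center_x_cm) <= hw + 1e-12 &
      abs(y_cm - arena$center_y_cm) <= hh + 1e-12
  }
}

# Fold a coordinate into [lo, hi] by reflection at the boundaries
# (triangle-wave fold; exact containment guaranteed by final clamp).
.reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  u <- (v - lo) %% (2 * w)
  u <- ifelse(u > w, 2 * w - u, u)
  pmin(pmax(lo + u, lo), hi)
}

# Reflect points into the arena. Circles reflect radially, rectangles per axis.
.arena_reflect <- function(arena, x, y) {
  if (arena$shape == "rectangle") {
    hw <- arena$width_cm / 2; hh <- arena$height_cm / 2
    list(x = .reflect_into(x, arena$center_x_cm - hw, arena$center_x_cm + hw),
         y = .reflect_into(y, arena$center_y_cm - hh, arena$center_y_cm + hh))
  } else {
    dx <- x - arena$center_x_cm; dy <- y - arena$center_y_cm
    r <- sqrt(dx^2 + dy^2)
    out <- r > arena$radius_cm
    if (any(out)) {
      rr <- .reflect_into(r[out], 0, arena$radius_cm)
      scl <- ifelse(r[out] > 0, rr / r[out], 0)
      dx[out] <- dx[out] * scl
      dy[out] <- dy[out] * scl
    }
    list(x = arena$center_x_cm + dx, y = arena$center_y_cm + dy)
  }
}

#' @export
print.arena_spec <- function(x, ...) {
  dims <- if (x$shape == "circle") sprintf("radius %.1f cm", x$radius_cm)
          else sprintf("%.1f x %.1f cm", x$width_cm, x$height_cm)
  cat(sprintf("Arena: %s (%s), target at (%.1f, %.1f) cm\n",
              x$shape, dims, x$target_x_cm, x$target_y_cm))
  cat(sprintf("Zones: pro <= %.1f cm, anti > %.1f cm; norm radius %.1f cm\n",
              x$zone_inner_cm, x$zone_outer_cm, x$norm_radius_cm))
  invisible(x)
}
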