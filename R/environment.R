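# Room geometry: planar surfaces, the invisible goal zone, and the set of
# surfaces that constitute "the goal area" for fixation classification.
#
# Coordinate convention: right-handed room frame, origin at one room corner,
# x along the long (8.55 m) axis, y along the short (4.30 m) axis, z up.
# Meters everywhere; angles in degrees.

PLANARITY_TOL <- 1e-6

#' Construct an environment model
#'
#' Builds a validated description of the experimental room: its footprint, a
#' set of labeled planar polygons (wall panels and the floor), the square goal
#' zone on the floor, and the subset of surfaces defining the goal area.
#'
#' When `surfaces` is `NULL` a default layout is generated: `n_panels`
#' vertical wall panels of variable width (3 m high) tiling the four walls,
#' plus one `"floor"` polygon. When `goal_area_surface_ids` is `NULL` it
#' defaults to the panels whose horizontal distance to the goal center is at
#' most `goal_area_radius`, plus the floor; floor fixations additionally must
#' fall inside `goal_floor_polygon` (goal zone inflated by
#' `goal_floor_margin` on each side) to count as goal-area fixations.
#'
#' @param room_length room extent along x, meters.
#' @param room_width room extent along y, meters.
#' @param goal_center 2D center of the goal zone, meters; `NULL` places it at
#'   the center of the northwest quadrant of the room.
#' @param goal_side side of the square goal zone, meters.
#' @param surfaces optional list of surfaces, each `list(id=, vertices=)` with
#'   `vertices` an n x 3 matrix of coplanar points (room frame, meters).
#' @param goal_area_surface_ids optional character vector of surface ids
#'   constituting the goal area.
#' @param goal_floor_polygon optional k x 2 matrix bounding goal-area floor
#'   hits.
#' @param n_panels number of wall panels for the default layout.
#' @param wall_height panel height, meters.
#' @param goal_area_radius horizontal radius used to pick default goal-area
#'   panels, meters.
#' @param goal_floor_margin inflation of the goal zone for the default
#'   goal-area floor polygon, meters.
#' @return an object of class `nav_environment`.
#' @export
environment_model <- function(room_length = 8.55, room_width = 4.30,
                              goal_center = NULL, goal_side = 0.80,
                              surfaces = NULL,
                              goal_area_surface_ids = NULL,
                              goal_floor_polygon = NULL,
                              n_panels = 19L, wall_height = 3.0,
                              goal_area_radius = 2.2,
                              goal_floor_margin = 0.8) {
  stopifnot(is.numeric(room_length), room_length > 0,
            is.numeric(room_width), room_width > 0,
            is.numeric(goal_side), goal_side > 0)
  # default: center of the northwest quadrant
  if (is.null(goal_center)) goal_center <- c(room_length / 4, 3 * room_width / 4)
  stopifnot(length(goal_center) == 2L, is.numeric(goal_center))
  half <- goal_side / 2
  if (goal_center[1] - half < 0 || goal_center[1] + half > room_length ||
      goal_center[2] - half < 0 || goal_center[2] + half > room_width) {
    stop_nav("goal zone (center ", paste(signif(goal_center, 4), collapse = ", "),
             ", side ", goal_side, " m) does not lie fully inside the room footprint")
  }
  if (is.null(surfaces)) {
    surfaces <- default_panel_layout(room_length, room_width, n_panels, wall_height)
  }
  surfaces <- lapply(surfaces, prepare_surface)
  ids <- vapply(surfaces, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_nav("duplicate surface ids: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(surfaces) <- ids
  if (is.null(goal_area_surface_ids)) {
    goal_area_surface_ids <- default_goal_area_ids(surfaces, goal_center, goal_area_radius)
  }
  missing_ids <- setdiff(goal_area_surface_ids, ids)
  if (length(missing_ids) > 0) {
    stop_nav("goal_area_surface_ids name surfaces that do not exist: ",
             paste(missing_ids, collapse = ", "))
  }
  if (is.null(goal_floor_polygon)) {
    g <- half + goal_floor_margin
    goal_floor_polygon <- cbind(
      pmin(pmax(goal_center[1] + c(-g, g, g, -g), 0), room_length),
      pmin(pmax(goal_center[2] + c(-g, -g, g, g), 0), room_width))
  }
  goal_floor_polygon <- as.matrix(goal_floor_polygon)
  if (ncol(goal_floor_polygon) != 2L || nrow(goal_floor_polygon) < 3L) {
    stop_nav("goal_floor_polygon must be a k x 2 matrix with k >= 3")
  }
  structure(list(room_length = room_length, room_width = room_width,
                 surfaces = surfaces,
                 goal_zone = list(center = as.numeric(goal_center), side = goal_side),
                 goal_area_surface_ids = goal_area_surface_ids,
                 goal_floor_polygon = goal_floor_polygon),
            class = "nav_environment")
}

# Tile the four walls with vertical panels of variable width, plus the floor.
default_panel_layout <- function(room_length, room_width, n_panels, wall_height) {
  n_panels <- as.integer(n_panels)
  stopifnot(n_panels >= 4L)
  # distribute panels over walls proportionally to wall length
  per <- 2 * (room_length + room_width)
  raw <- n_panels * c(room_width, room_length, room_width, room_length) / per
  counts <- pmax(1L, floor(raw))
  while (sum(counts) < n_panels) {
    i <- which.max(raw - counts); counts[i] <- counts[i] + 1L
  }
  while (sum(counts) > n_panels) {
    i <- which.min(raw - counts); counts[i] <- counts[i] - 1L
  }
  surfaces <- list()
  add_wall <- function(surfaces, prefix, p0, p1, k) {
    # p0, p1: 2D endpoints of the wall segment
    for (j in seq_len(k)) {
      a <- p0 + (j - 1) / k * (p1 - p0)
      b <- p0 + j / k * (p1 - p0)
      v <- rbind(c(a, 0), c(b, 0), c(b, wall_height), c(a, wall_height))
      surfaces[[length(surfaces) + 1L]] <-
        list(id = paste0("panel_", prefix, j), vertices = v)
    }
    surfaces
  }
  surfaces <- add_wall(surfaces, "w", c(0, 0), c(0, room_width), counts[1])
  surfaces <- add_wall(surfaces, "n", c(0, room_width), c(room_length, room_width), counts[2])
  surfaces <- add_wall(surfaces, "e", c(room_length, room_width), c(room_length, 0), counts[3])
  surfaces <- add_wall(surfaces, "s", c(room_length, 0), c(0, 0), counts[4])
  surfaces[[length(surfaces) + 1L]] <- list(
    id = "floor",
    vertices = rbind(c(0, 0, 0), c(room_length, 0, 0),
                     c(room_length, room_width, 0), c(0, room_width, 0)))
  surfaces
}

default_goal_area_ids <- function(surfaces, goal_center, radius) {
  ids <- character(0)
  for (s in surfaces) {
    if (s$id == "floor") next
    d <- point_segmentset_distance(goal_center, s$vertices[, 1:2, drop = FALSE])
    if (d <= radius) ids <- c(ids, s$id)
  }
  c(ids, "floor")
}

# horizontal distance from a 2D point to the footprint of a (vertical) polygon
point_segmentset_distance <- function(p, verts2d) {
  verts2d <- unique(verts2d)
  if (nrow(verts2d) == 1L) return(sqrt(sum((p - verts2d[1, ])^2)))
  a <- verts2d[1, ]; b <- verts2d[nrow(verts2d), ]
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

# Validate planarity, precompute plane + 2D projection for fast ray casting.
prepare_surface <- function(s) {
  if (is.null(s$id) || !nzchar(s$id)) stop_nav("surface without an id")
  v <- as.matrix(s$vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 3L || nrow(v) < 3L) {
    stop_nav("surface '", s$id, "': vertices must be an n x 3 matrix with n >= 3")
  }
  e1 <- v[2, ] - v[1, ]
  # pick a second edge not collinear with the first
  nrm <- c(0, 0, 0); k <- 3L
  while (sum(nrm^2) < 1e-12 && k <= nrow(v)) {
    nrm <- cross3(e1, v[k, ] - v[1, ]); k <- k + 1L
  }
  if (sum(nrm^2) < 1e-12) stop_nav("surface '", s$id, "': degenerate (collinear) vertices")
  nrm <- nrm / sqrt(sum(nrm^2))
  dist <- abs((v - matrix(v[1, ], nrow(v), 3, byrow = TRUE)) %*% nrm)
  if (max(dist) > PLANARITY_TOL) {
    stop_nav("surface '", s$id, "': vertices are not coplanar (max deviation ",
             signif(max(dist), 3), " m exceeds ", PLANARITY_TOL, " m)")
  }
  drop_axis <- which.max(abs(nrm))
  keep <- setdiff(1:3, drop_axis)
  list(id = s$id, vertices = v, normal = nrm, origin = v[1, ],
       proj_axes = keep, poly2d = v[, keep, drop = FALSE])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Even-odd point-in-polygon test
#'
#' @param px,py coordinates of the query points.
#' @param poly k x 2 matrix of polygon vertices.
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Load an environment description from a YAML or JSON file
#'
#' Omitted fields fall back to the defaults of [environment_model()]. The
#' file may describe surfaces explicitly (`surfaces:` entries with `id` and
#' `vertices`) or request the default panel layout via `n_panels`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a validated `nav_environment`.
#' @export
load_environment <- function(path) {
  if (!file.exists(path)) stop_nav("environment file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  env_from_config(cfg)
}

env_from_config <- function(cfg) {
  surfaces <- NULL
  if (!is.null(cfg$surfaces)) {
    surfaces <- lapply(cfg$surfaces, function(s) {
      list(id = s$id, vertices = do.call(rbind, lapply(s$vertices, as.numeric)))
    })
  }
  gz <- cfg$goal_zone %||% list()
  args <- list(
    surfaces = surfaces,
    goal_area_surface_ids = unlist(cfg$goal_area_surface_ids) %||% NULL,
    goal_floor_polygon = if (!is.null(cfg$goal_floor_polygon))
      do.call(rbind, lapply(cfg$goal_floor_polygon, as.numeric)) else NULL)
  for (nm in c("room_length", "room_width", "wall_height",
               "goal_area_radius", "goal_floor_margin")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- as.numeric(cfg[[nm]])
  }
  if (!is.null(cfg$n_panels)) args$n_panels <- as.integer(cfg$n_panels)
  if (!is.null(gz$center)) args$goal_center <- as.numeric(unlist(gz$center))
  if (!is.null(gz$side)) args$goal_side <- as.numeric(gz$side)
  do.call(environment_model, args)
}

#' Write an environment model to a YAML file
#'
#' Round-trips through [load_environment()] losslessly (within 1e-9).
#'
#' @param env a `nav_environment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "nav_environment"))
  cfg <- list(
    room_length = env$room_length, room_width = env$room_width,
    goal_zone = list(center = env$goal_zone$center, side = env$goal_zone$side),
    goal_area_surface_ids = env$goal_area_surface_ids,
    goal_floor_polygon = lapply(seq_len(nrow(env$goal_floor_polygon)),
                                function(i) env$goal_floor_polygon[i, ]),
    surfaces = lapply(env$surfaces, function(s) {
      list(id = s$id,
           vertices = lapply(seq_len(nrow(s$vertices)), function(i) s$vertices[i, ]))
    }))
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' @export
print.nav_environment <- function(x, ...) {
  cat("<nav_environment> ", x$room_length, " m x ", x$room_width, " m, ",
      length(x$surfaces), " surfaces; goal ", x$goal_zone$side, " m square at (",
      paste(signif(x$goal_zone$center, 4), collapse = ", "), "); goal area: ",
      length(x$goal_area_surface_ids), " surfaces\n", sep = "")
  invisible(x)
}
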