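# Nest geometry: axis-aligned chambers joined by short opening corridors,
# wall-aware distances on an occupancy grid, camera-to-nest affine alignment,
# and projection of stray points back into the walkable region.
#
# Coordinate convention: nest frame in mm, origin at the entrance midpoint,
# x increasing into the nest. All rectangles are closed sets.

#' Construct a nest geometry
#'
#' A nest is a set of axis-aligned rectangular chambers (mm) connected by
#' narrow wall openings. Each opening becomes a short rectangular corridor of
#' the stated width so that the walkable region is a single connected union of
#' rectangles. One opening may connect a chamber to the outside; its midpoint
#' on the chamber wall is the default entrance reference point.
#'
#' @param chambers Data frame with columns `x0`, `y0`, `width`, `height`
#'   (mm): lower-left corner and dimensions of each chamber.
#' @param openings Data frame with columns `a` (chamber index), `b` (chamber
#'   index, or 0 for the outside), optional `center` (coordinate of the opening
#'   midpoint along the shared wall; default midpoint of the wall overlap),
#'   optional `width` (mm, default 6), and optional `side` (for outside
#'   openings: `"left"`, `"right"`, `"bottom"` or `"top"` of chamber `a`;
#'   default `"left"`).
#' @param entrance_point Optional 2-vector overriding the entrance reference
#'   point. Defaults to the midpoint of the outside opening on the chamber
#'   wall.
#' @param corridor_length Length (mm) of the corridor rectangle modelling each
#'   opening; chambers connected by an opening must be separated by exactly
#'   this gap (or touch, when 0).
#' @return An object of class `nest_geometry`.
#' @seealso [nest_one_chamber()], [nest_four_chamber()], [build_nest()]
#' @export
nest_geometry <- function(chambers, openings, entrance_point = NULL,
                          corridor_length = 2) {
  chambers <- as_tibble(chambers)
  openings <- as_tibble(openings)
  stopifnot(nrow(chambers) >= 1)
  if (any(chambers$width <= 0) || any(chambers$height <= 0)) {
    abort("all chamber dimensions must be positive", class = "antnest_config_error")
  }
  ch <- cbind(
    x0 = chambers$x0, y0 = chambers$y0,
    x1 = chambers$x0 + chambers$width, y1 = chambers$y0 + chambers$height
  )
  # overlapping chamber interiors are a configuration error
  if (nrow(ch) > 1) {
    for (i in seq_len(nrow(ch) - 1)) {
      for (j in seq(i + 1, nrow(ch))) {
        if (ch[i, "x0"] < ch[j, "x1"] && ch[j, "x0"] < ch[i, "x1"] &&
            ch[i, "y0"] < ch[j, "y1"] && ch[j, "y0"] < ch[i, "y1"]) {
          abort(sprintf("chambers %d and %d overlap", i, j),
                class = "antnest_config_error")
        }
      }
    }
  }

  if (!"width" %in% names(openings)) openings$width <- 6
  if (!"center" %in% names(openings)) openings$center <- NA_real_
  if (!"side" %in% names(openings)) openings$side <- NA_character_
  openings$width[is.na(openings$width)] <- 6
  if (any(openings$width <= 0)) {
    abort("opening width must be positive", class = "antnest_config_error")
  }
  nch <- nrow(ch)
  if (any(openings$a < 1 | openings$a > nch) ||
      any(openings$b < 0 | openings$b > nch)) {
    abort("opening references a non-existent chamber", class = "antnest_config_error")
  }

  corridors <- matrix(numeric(0), ncol = 4,
                      dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  entrance <- NULL
  for (k in seq_len(nrow(openings))) {
    op <- openings[k, ]
    w <- op$width
    if (op$b == 0) {
      side <- if (is.na(op$side)) "left" else op$side
      r <- ch[op$a, ]
      cen <- op$center
      if (side %in% c("left", "right")) {
        cy <- if (is.na(cen)) (r["y0"] + r["y1"]) / 2 else cen
        if (cy - w / 2 < r["y0"] || cy + w / 2 > r["y1"]) {
          abort("entrance does not fit on the chamber wall", class = "antnest_config_error")
        }
        xw <- if (side == "left") r["x0"] else r["x1"]
        xs <- if (side == "left") c(xw - corridor_length, xw) else c(xw, xw + corridor_length)
        if (corridor_length > 0) {
          corridors <- rbind(corridors, c(xs[1], cy - w / 2, xs[2], cy + w / 2))
        }
        entrance_k <- c(xw, cy)
      } else {
        cx <- if (is.na(cen)) (r["x0"] + r["x1"]) / 2 else cen
        if (cx - w / 2 < r["x0"] || cx + w / 2 > r["x1"]) {
          abort("entrance does not fit on the chamber wall", class = "antnest_config_error")
        }
        yw <- if (side == "bottom") r["y0"] else r["y1"]
        ys <- if (side == "bottom") c(yw - corridor_length, yw) else c(yw, yw + corridor_length)
        if (corridor_length > 0) {
          corridors <- rbind(corridors, c(cx - w / 2, ys[1], cx + w / 2, ys[2]))
        }
        entrance_k <- c(cx, yw)
      }
      if (is.null(entrance)) entrance <- entrance_k
    } else {
      ra <- ch[op$a, ]; rb <- ch[op$b, ]
      # facing vertical walls (a left of b or vice versa), else horizontal
      if (isTRUE(all.equal(unname(rb["x0"] - ra["x1"]), corridor_length)) ||
          isTRUE(all.equal(unname(ra["x0"] - rb["x1"]), corridor_length))) {
        lo <- max(ra["y0"], rb["y0"]); hi <- min(ra["y1"], rb["y1"])
        cy <- if (is.na(op$center)) (lo + hi) / 2 else op$center
        if (cy - w / 2 < lo || cy + w / 2 > hi) {
          abort("opening does not fit in the wall overlap", class = "antnest_config_error")
        }
        xs <- sort(c(min(ra["x1"], rb["x1"]), max(ra["x0"], rb["x0"])))
        if (corridor_length > 0) {
          corridors <- rbind(corridors, c(xs[1], cy - w / 2, xs[2], cy + w / 2))
        }
      } else if (isTRUE(all.equal(unname(rb["y0"] - ra["y1"]), corridor_length)) ||
                 isTRUE(all.equal(unname(ra["y0"] - rb["y1"]), corridor_length))) {
        lo <- max(ra["x0"], rb["x0"]); hi <- min(ra["x1"], rb["x1"])
        cx <- if (is.na(op$center)) (lo + hi) / 2 else op$center
        if (cx - w / 2 < lo || cx + w / 2 > hi) {
          abort("opening does not fit in the wall overlap", class = "antnest_config_error")
        }
        ys <- sort(c(min(ra["y1"], rb["y1"]), max(ra["y0"], rb["y0"])))
        if (corridor_length > 0) {
          corridors <- rbind(corridors, c(cx - w / 2, ys[1], cx + w / 2, ys[2]))
        }
      } else {
        abort(sprintf(
          "chambers %d and %d are not separated by the corridor length (%g mm)",
          op$a, op$b, corridor_length), class = "antnest_config_error")
      }
    }
  }

  if (!is.null(entrance_point)) entrance <- as.numeric(entrance_point)
  nest <- structure(
    list(
      chambers = ch,
      corridors = corridors,
      openings = openings,
      entrance_point = entrance,
      corridor_length = corridor_length,
      cache = new.env(parent = emptyenv())
    ),
    class = "nest_geometry"
  )

  # chamber connectivity through the declared openings
  if (nch > 1) {
    g <- igraph::graph_from_edgelist(
      as.matrix(openings[openings$b > 0, c("a", "b")]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nch - igraph::vcount(g)))
    if (igraph::count_components(g) > 1) {
      abort("nest layout is disconnected", class = "antnest_config_error")
    }
  }
  nest
}

#' @export
print.nest_geometry <- function(x, ...) {
  cat(sprintf(
    "<nest_geometry> %d chamber(s), %d corridor(s), walkable area %.1f mm^2\n",
    nrow(x$chambers), nrow(x$corridors), nest_area(x)))
  if (!is.null(x$entrance_point)) {
    cat(sprintf("  entrance at (%.1f, %.1f) mm\n",
                x$entrance_point[1], x$entrance_point[2]))
  }
  invisible(x)
}

#' Total walkable area of a nest
#'
#' @param nest A [nest_geometry()].
#' @param include_corridors Include the opening-corridor rectangles (default
#'   TRUE); FALSE gives the chamber area alone (65 x 40 = 2600 mm^2 per
#'   standard chamber).
#' @return Area in mm^2.
#' @export
nest_area <- function(nest, include_corridors = TRUE) {
  r <- if (include_corridors) rbind(nest$chambers, nest$corridors) else
    nest$chambers
  sum((r[, "x1"] - r[, "x0"]) * (r[, "y1"] - r[, "y0"]))
}

all_rects <- function(nest) rbind(nest$chambers, nest$corridors)

# which rectangle (chamber or corridor) contains each point; 0 if none
rect_index <- function(x, y, rects) {
  idx <- integer(length(x))
  for (r in seq_len(nrow(rects))) {
    hit <- idx == 0L &
      x >= rects[r, "x0"] & x <= rects[r, "x1"] &
      y >= rects[r, "y0"] & y <= rects[r, "y1"]
    idx[hit] <- r
  }
  idx
}

#' Test whether points lie in the walkable region
#'
#' @param x,y Coordinates in mm (vectors of equal length).
#' @param nest A [nest_geometry()].
#' @return Logical vector.
#' @export
in_nest <- function(x, y, nest) rect_index(x, y, all_rects(nest)) > 0L

#' Which chamber contains each point
#'
#' @inheritParams in_nest
#' @return Integer chamber index per point; 0 for points in an opening
#'   corridor; NA for points outside the walkable region.
#' @export
chamber_of <- function(x, y, nest) {
  ci <- rect_index(x, y, nest$chambers)
  out <- !in_nest(x, y, nest)
  ci[out] <- NA_integer_
  ci
}

#' Project points onto the walkable region
#'
#' Points already inside the region are returned unchanged; any other point is
#' replaced by the nearest point of the region in Euclidean distance (ties
#' broken by chamber order). The operation is idempotent.
#'
#' @param x,y Coordinates in mm.
#' @param nest A [nest_geometry()].
#' @return A tibble with columns `x`, `y` of projected coordinates.
#' @export
project_into_nest <- function(x, y, nest) {
  rects <- all_rects(nest)
  n <- length(x)
  bx <- x; by <- y; bd <- rep(Inf, n)
  for (r in seq_len(nrow(rects))) {
    cx <- pmin(pmax(x, rects[r, "x0"]), rects[r, "x1"])
    cy <- pmin(pmax(y, rects[r, "y0"]), rects[r, "y1"])
    d <- (cx - x)^2 + (cy - y)^2
    upd <- d < bd - 1e-12
    bx[upd] <- cx[upd]; by[upd] <- cy[upd]; bd[upd] <- d[upd]
  }
  tibble(x = bx, y = by)
}

# ---- occupancy grid -------------------------------------------------------

# Lazily built occupancy grid over the nest bounding box. Cells are res x res
# squares; a cell is walkable when its centre lies in the (closed) region.
nest_grid <- function(nest, res = 0.5) {
  key <- sprintf("grid_%g", res)
  if (!is.null(nest$cache[[key]])) return(nest$cache[[key]])
  rects <- all_rects(nest)
  xmin <- min(rects[, "x0"]); xmax <- max(rects[, "x1"])
  ymin <- min(rects[, "y0"]); ymax <- max(rects[, "y1"])
  nx <- max(1L, ceiling((xmax - xmin) / res))
  ny <- max(1L, ceiling((ymax - ymin) / res))
  cx <- xmin + (seq_len(nx) - 0.5) * res
  cy <- ymin + (seq_len(ny) - 0.5) * res
  pts <- expand.grid(x = cx, y = cy)  # column-major: x fastest
  walk <- matrix(in_nest(pts$x, pts$y, nest), nrow = nx, ncol = ny)
  id <- matrix(0L, nx, ny)
  id[walk] <- seq_len(sum(walk))
  g <- list(res = res, xmin = xmin, ymin = ymin, nx = nx, ny = ny,
            walk = walk, id = id, cx = cx, cy = cy,
            cells = which(walk, arr.ind = TRUE))
  nest$cache[[key]] <- g
  g
}

# nearest walkable cell id for arbitrary in-region points
grid_cell_of <- function(x, y, grid) {
  i <- pmin(pmax(ceiling((x - grid$xmin) / grid$res), 1L), grid$nx)
  j <- pmin(pmax(ceiling((y - grid$ymin) / grid$res), 1L), grid$ny)
  ids <- grid$id[cbind(i, j)]
  if (any(ids == 0L)) {
    # snap to the nearest walkable cell centre (rare: thin boundary slivers)
    bad <- which(ids == 0L)
    cc <- grid$cells
    ccx <- grid$cx[cc[, 1]]; ccy <- grid$cy[cc[, 2]]
    for (b in bad) {
      ids[b] <- grid$id[cc[which.min((ccx - x[b])^2 + (ccy - y[b])^2), , drop = FALSE]]
    }
  }
  ids
}

# igraph lattice over walkable cells; connectivity 4 (rectilinear, edge
# weight res) or 8 (adds diagonals at res*sqrt(2), with a corner-cut guard).
nest_lattice <- function(nest, res = 0.5, connectivity = 8) {
  key <- sprintf("lat_%g_%d", res, connectivity)
  if (!is.null(nest$cache[[key]])) return(nest$cache[[key]])
  grid <- nest_grid(nest, res)
  W <- grid$walk; id <- grid$id; nx <- grid$nx; ny <- grid$ny
  edge_list <- list(); wt_list <- list()
  add_edges <- function(di, dj, w, guard = FALSE) {
    i <- seq_len(nx - max(di, 0) - max(-di, 0))
    if (di > 0) ii <- seq_len(nx - di) else ii <- seq(1 - min(di, 0), nx)
    jj <- if (dj > 0) seq_len(ny - dj) else seq(1 - min(dj, 0), ny)
    A <- W[ii, jj, drop = FALSE] & W[ii + di, jj + dj, drop = FALSE]
    if (guard) {
      # diagonal moves must not cut a wall corner
      A <- A & W[ii + di, jj, drop = FALSE] & W[ii, jj + dj, drop = FALSE]
    }
    from <- id[ii, jj, drop = FALSE][A]
    to <- id[ii + di, jj + dj, drop = FALSE][A]
    edge_list[[length(edge_list) + 1]] <<- rbind(from, to)
    wt_list[[length(wt_list) + 1]] <<- rep(w, length(from))
  }
  add_edges(1L, 0L, res)
  add_edges(0L, 1L, res)
  if (connectivity == 8) {
    add_edges(1L, 1L, res * sqrt(2), guard = TRUE)
    add_edges(1L, -1L, res * sqrt(2), guard = TRUE)
  }
  edges <- do.call(cbind, edge_list)
  g <- igraph::make_empty_graph(n = sum(W), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::E(g)$weight <- unlist(wt_list)
  out <- list(graph = g, grid = grid)
  nest$cache[[key]] <- out
  out
}

# ---- wall-aware distances -------------------------------------------------

#' Wall-aware (geodesic) distance between points in the nest
#'
#' Length of the shortest path between two points that stays inside the
#' walkable region ("the ants can move around walls but they cannot go
#' through them"). Within a single rectangle the path is the straight line;
#' otherwise the distance is computed on an 8-connected occupancy grid, so it
#' is accurate to about one grid step.
#'
#' @param p,q Numeric 2-vectors, or 2-column matrices of matched points (mm).
#' @param nest A [nest_geometry()].
#' @param res Grid resolution in mm (default 0.5).
#' @param cutoff Optional distance threshold: pairs whose Euclidean distance
#'   (a lower bound on the wall-aware distance) already exceeds `cutoff` keep
#'   the Euclidean value, skipping the grid computation. Safe whenever the
#'   caller only compares distances against a radius `<= cutoff`.
#' @return Numeric vector of distances (mm).
#' @export
geodesic_distance <- function(p, q, nest, res = 0.5, cutoff = Inf) {
  p <- rbind(p); q <- rbind(q)
  stopifnot(nrow(p) == nrow(q))
  rects <- all_rects(nest)
  rp <- rect_index(p[, 1], p[, 2], rects)
  rq <- rect_index(q[, 1], q[, 2], rects)
  if (any(rp == 0L) || any(rq == 0L)) {
    abort("point outside the walkable region; project_into_nest() first",
          class = "antnest_domain_error")
  }
  d <- sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)
  cross <- which(rp != rq & d <= cutoff)
  if (length(cross)) {
    grid <- nest_grid(nest, res)
    from <- grid_cell_of(p[cross, 1], p[cross, 2], grid)
    to <- grid_cell_of(q[cross, 1], q[cross, 2], grid)
    D <- grid_field_distances(nest, res, unique(from))
    d[cross] <- pmax(D[cbind(match(from, rownames(D)), to)], d[cross])
  }
  unname(d)
}

# Distance fields from source cells over all walkable cells, Dijkstra on the
# 8-connected lattice, cached per source cell on the nest object.
grid_field_distances <- function(nest, res, src_cells) {
  key <- sprintf("dfields_%g", res)
  if (is.null(nest$cache[[key]])) nest$cache[[key]] <- new.env(parent = emptyenv())
  fields <- nest$cache[[key]]
  missing_src <- src_cells[!vapply(as.character(src_cells), exists,
                                   logical(1), envir = fields)]
  if (length(missing_src)) {
    lat <- nest_lattice(nest, res, connectivity = 8)
    Dm <- igraph::distances(lat$graph, v = missing_src, algorithm = "dijkstra")
    for (k in seq_along(missing_src)) {
      assign(as.character(missing_src[k]), Dm[k, ], envir = fields)
    }
  }
  out <- do.call(rbind, lapply(as.character(src_cells), get, envir = fields))
  rownames(out) <- as.character(src_cells)
  out
}

# Full pairwise wall-aware distance matrix for a set of in-nest points.
# Same-rectangle pairs are exact Euclidean; cross-rectangle pairs within
# `cutoff` (Euclidean lower bound) use the cached grid fields.
geodesic_distance_matrix <- function(x, y, nest, res = 0.5, cutoff = Inf) {
  n <- length(x)
  rects <- all_rects(nest)
  ri <- rect_index(x, y, rects)
  if (any(ri == 0L)) {
    abort("point outside the walkable region; project_into_nest() first",
          class = "antnest_domain_error")
  }
  D <- as.matrix(dist(cbind(x, y)))
  cross <- outer(ri, ri, `!=`) & D <= cutoff
  if (any(cross)) {
    grid <- nest_grid(nest, res)
    ids <- grid_cell_of(x, y, grid)
    need <- which(cross, arr.ind = TRUE)
    need <- need[need[, 1] < need[, 2], , drop = FALSE]
    from <- ids[need[, 1]]; to <- ids[need[, 2]]
    G <- grid_field_distances(nest, res, unique(from))
    dg <- pmax(G[cbind(match(from, rownames(G)), to)],
               D[need])
    D[need] <- dg
    D[need[, c(2, 1), drop = FALSE]] <- dg
  }
  D
}

#' Rectilinear wall-aware distance to the nest entrance
#'
#' Length of the shortest path from a point to the entrance reference point
#' using only moves parallel or perpendicular to the nest walls and staying
#' inside the walkable region. For points in the entrance chamber this is the
#' exact L1 distance; elsewhere it is computed by breadth-first search on a
#' 4-connected occupancy grid (accurate to about one grid step) and never
#' reported below the unconstrained L1 distance.
#'
#' @param x,y Coordinates in mm (vectors).
#' @param nest A [nest_geometry()]; must have an entrance.
#' @param res Grid resolution in mm (default 0.5).
#' @return Numeric vector of distances (mm).
#' @export
distance_to_entrance <- function(x, y, nest, res = 0.5) {
  ep <- nest$entrance_point
  if (is.null(ep)) abort("nest has no entrance point", class = "antnest_config_error")
  if (any(!in_nest(x, y, nest))) {
    abort("point outside the walkable region; project_into_nest() first",
          class = "antnest_domain_error")
  }
  l1 <- abs(x - ep[1]) + abs(y - ep[2])
  # entrance chamber (or entrance corridor): rectangles with the entrance on
  # their boundary are L1-convex, so the L-shaped path is feasible and exact
  rects <- all_rects(nest)
  on_rect <- ep[1] >= rects[, "x0"] & ep[1] <= rects[, "x1"] &
    ep[2] >= rects[, "y0"] & ep[2] <= rects[, "y1"]
  exact <- rep(FALSE, length(x))
  for (r in which(on_rect)) {
    exact <- exact | (x >= rects[r, "x0"] & x <= rects[r, "x1"] &
                        y >= rects[r, "y0"] & y <= rects[r, "y1"])
  }
  d <- l1
  rest <- which(!exact)
  if (length(rest)) {
    fld <- entrance_distance_field(nest, res)
    ids <- grid_cell_of(x[rest], y[rest], fld$grid)
    d[rest] <- pmax(fld$dist[ids], l1[rest])
  }
  unname(d)
}

# distance field (per walkable cell) from the entrance cell, 4-connected
entrance_distance_field <- function(nest, res = 0.5) {
  key <- sprintf("efield_%g", res)
  if (!is.null(nest$cache[[key]])) return(nest$cache[[key]])
  lat <- nest_lattice(nest, res, connectivity = 4)
  ep <- nest$entrance_point
  src <- grid_cell_of(ep[1], ep[2], lat$grid)
  d <- as.vector(igraph::distances(lat$graph, v = src, algorithm = "dijkstra"))
  out <- list(dist = d, grid = lat$grid)
  nest$cache[[key]] <- out
  out
}

# ---- affine camera alignment ----------------------------------------------

#' Fit the least-squares affine transform from pixel to nest coordinates
#'
#' Finds the affine map (2x2 linear part plus offset) that best aligns marked
#' pixel locations of the chamber corners with their known positions in the
#' nest frame.
#'
#' @param src Matrix or data frame of at least 3 non-collinear source (pixel)
#'   points, columns x, y.
#' @param dst Matching destination (mm) points.
#' @return An object of class `affine_transform` with elements `A` (2x2),
#'   `b` (length 2) and `residuals` (per-corner Euclidean residual, mm).
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 3) abort("need at least 3 point correspondences",
                           class = "antnest_rank_error")
  X <- cbind(1, src)
  if (qr(X)$rank < 3) {
    abort("source corners are collinear", class = "antnest_rank_error")
  }
  beta <- qr.solve(X, dst)          # 3 x 2: [offset; linear part]
  fittedv <- X %*% beta
  structure(
    list(A = t(beta[2:3, , drop = FALSE]), b = as.numeric(beta[1, ]),
         residuals = sqrt(rowSums((dst - fittedv)^2))),
    class = "affine_transform"
  )
}

#' Apply an affine transform to points
#'
#' @param points Matrix or data frame of points (columns x, y).
#' @param transform An [fit_affine()] result.
#' @return A tibble with transformed columns `x`, `y`.
#' @export
apply_affine <- function(points, transform) {
  p <- as.matrix(points)
  out <- p %*% t(transform$A)
  tibble(x = out[, 1] + transform$b[1], y = out[, 2] + transform$b[2])
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n  linear part:\n")
  print(round(x$A, 6))
  cat(sprintf("  offset: (%.4f, %.4f)\n  max corner residual: %.3g mm\n",
              x$b[1], x$b[2], max(x$residuals)))
  invisible(x)
}

# ---- standard layouts and config ------------------------------------------

#' Standard one-chamber (high-density) nest
#'
#' A single 65 x 40 mm chamber with a 6 mm entrance at the midpoint of the
#' left wall; origin at the entrance, x increasing into the nest.
#'
#' @param width,height Chamber dimensions (mm).
#' @param entrance_width Entrance width (mm).
#' @param corridor_length Length of the entrance tunnel rectangle (mm).
#' @return A [nest_geometry()].
#' @export
nest_one_chamber <- function(width = 65, height = 40, entrance_width = 6,
                             corridor_length = 2) {
  nest_geometry(
    chambers = tibble(x0 = 0, y0 = -height / 2, width = width, height = height),
    openings = tibble(a = 1L, b = 0L, center = 0, width = entrance_width,
                      side = "left"),
    corridor_length = corridor_length
  )
}

#' Standard chained multi-chamber (low-density) nest
#'
#' `n_chambers` identical chambers chained in series along x from the entrance
#' chamber to the queen chamber, connected by openings of the stated width.
#'
#' @param n_chambers Number of chambers (default 4).
#' @inheritParams nest_one_chamber
#' @param opening_width Width of the inter-chamber openings (mm).
#' @return A [nest_geometry()].
#' @export
nest_four_chamber <- function(n_chambers = 4, width = 65, height = 40,
                              entrance_width = 6, opening_width = 6,
                              corridor_length = 2) {
  stopifnot(n_chambers >= 1)
  step <- width + corridor_length
  chambers <- tibble(
    x0 = (seq_len(n_chambers) - 1) * step, y0 = -height / 2,
    width = width, height = height
  )
  openings <- tibble(a = 1L, b = 0L, center = 0, width = entrance_width,
                     side = "left")
  if (n_chambers > 1) {
    openings <- bind_rows(openings, tibble(
      a = seq_len(n_chambers - 1), b = seq_len(n_chambers - 1) + 1L,
      center = 0, width = opening_width, side = NA_character_
    ))
  }
  nest_geometry(chambers, openings, corridor_length = corridor_length)
}

#' Build a nest from a configuration mapping or file
#'
#' Accepts either a list with elements `chambers` (each `x0, y0, width,
#' height`), `openings` (each `a, b, center, width, side`; `b = 0` for the
#' outside), and optional `corridor_length` / `entrance_point`, or the path of
#' a YAML file with the same structure.
#'
#' @param config List or path to a YAML config file.
#' @return A [nest_geometry()].
#' @export
build_nest <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$chambers)) {
    abort("config must contain a 'chambers' entry", class = "antnest_config_error")
  }
  to_tbl <- function(x) {
    if (is.data.frame(x)) as_tibble(x) else bind_rows(lapply(x, as_tibble))
  }
  chambers <- to_tbl(config$chambers)
  openings <- if (is.null(config$openings)) {
    tibble(a = integer(), b = integer(), center = numeric(),
           width = numeric(), side = character())
  } else to_tbl(config$openings)
  nest_geometry(
    chambers, openings,
    entrance_point = config$entrance_point,
    corridor_length = config$corridor_length %||% 2
  )
}
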