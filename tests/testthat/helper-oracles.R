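# Independent oracles used across the suite. These deliberately avoid the
# package's distance / community-detection code paths: plain-R Dijkstra and
# BFS on an occupancy grid built from the raw rectangles, and exhaustive
# modularity maximization by set-partition enumeration.

# occupancy grid straight from the rectangle list (not via nest_grid)
oracle_grid <- function(nest, res) {
  rects <- rbind(nest$chambers, nest$corridors)
  xmin <- min(rects[, "x0"]); xmax <- max(rects[, "x1"])
  ymin <- min(rects[, "y0"]); ymax <- max(rects[, "y1"])
  nx <- max(1L, ceiling((xmax - xmin) / res))
  ny <- max(1L, ceiling((ymax - ymin) / res))
  cx <- xmin + (seq_len(nx) - 0.5) * res
  cy <- ymin + (seq_len(ny) - 0.5) * res
  inside <- function(x, y) {
    ok <- rep(FALSE, length(x))
    for (r in seq_len(nrow(rects))) {
      ok <- ok | (x >= rects[r, "x0"] & x <= rects[r, "x1"] &
                    y >= rects[r, "y0"] & y <= rects[r, "y1"])
    }
    ok
  }
  pts <- expand.grid(x = cx, y = cy)
  list(nx = nx, ny = ny, cx = cx, cy = cy, res = res,
       walk = matrix(inside(pts$x, pts$y), nx, ny))
}

oracle_cell <- function(g, p) {
  i <- min(max(ceiling((p[1] - (g$cx[1] - g$res / 2)) / g$res), 1), g$nx)
  j <- min(max(ceiling((p[2] - (g$cy[1] - g$res / 2)) / g$res), 1), g$ny)
  c(i, j)
}

# Dijkstra distances from one source cell over the whole grid.
# connectivity 8: diagonal moves cost res*sqrt(2) and must not cut corners;
# connectivity 4: rectilinear moves only (equivalent to weighted BFS).
oracle_dijkstra_field <- function(g, src, connectivity = 8) {
  nx <- g$nx; ny <- g$ny
  n <- nx * ny
  walk <- as.vector(g$walk)
  dist <- rep(Inf, n)
  active <- rep(Inf, n)          # Inf also marks visited / blocked cells
  s <- (src[2] - 1) * nx + src[1]
  dist[s] <- 0; active[s] <- 0
  moves <- if (connectivity == 8) {
    cbind(c(1, -1, 0, 0, 1, 1, -1, -1), c(0, 0, 1, -1, 1, -1, 1, -1))
  } else {
    cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  }
  cost <- g$res * sqrt(rowSums(moves^2))
  repeat {
    u <- which.min(active)
    if (!is.finite(active[u])) break
    active[u] <- Inf             # visited
    ui <- (u - 1) %% nx + 1; uj <- (u - 1) %/% nx + 1
    du <- dist[u]
    for (k in seq_len(nrow(moves))) {
      vi <- ui + moves[k, 1]; vj <- uj + moves[k, 2]
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      v <- (vj - 1) * nx + vi
      if (!walk[v]) next
      if (connectivity == 8 && moves[k, 1] != 0 && moves[k, 2] != 0 &&
          (!g$walk[vi, uj] || !g$walk[ui, vj])) next
      nd <- du + cost[k]
      # a strictly shorter tentative distance implies v is unvisited
      # (visited distances are final with non-negative edge costs)
      if (nd < dist[v]) {
        dist[v] <- nd
        active[v] <- nd
      }
    }
  }
  matrix(dist, nx, ny)
}

oracle_grid_distance <- function(nest, p, q, res, connectivity = 8) {
  g <- oracle_grid(nest, res)
  fld <- oracle_dijkstra_field(g, oracle_cell(g, p), connectivity)
  qc <- oracle_cell(g, q)
  fld[qc[1], qc[2]]
}

# hand-rolled Newman modularity for a weighted undirected graph (no
# self-loops), membership as an integer vector
oracle_modularity <- function(W, mem) {
  W <- replace(W, is.na(W), 0)
  m2 <- sum(W)  # = 2m
  k <- rowSums(W)
  same <- outer(mem, mem, `==`)
  sum((W - outer(k, k) / m2)[same]) / m2
}

# all set partitions of 1..n (restricted growth strings)
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxg) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (gr in seq_len(maxg + 1)) {
      rec(c(prefix, gr), max(maxg, gr))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive modularity maximization over every partition
oracle_best_partition <- function(W) {
  parts <- oracle_partitions(nrow(W))
  scores <- vapply(parts, function(m) oracle_modularity(W, m), numeric(1))
  list(membership = parts[[which.max(scores)]], modularity = max(scores))
}

# agreement between two labelings, maximized over label matching (greedy on
# the contingency table; exact for the well-separated cases used in tests)
label_agreement <- function(a, b) {
  tab <- table(a, b)
  matched <- 0
  while (any(tab > 0)) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = FALSE]
    matched <- matched + tab[idx]
    tab <- tab[-idx[1], -idx[2], drop = FALSE]
    if (any(dim(tab) == 0)) break
  }
  matched / length(a)
}
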