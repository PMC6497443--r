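# Continuous-time correlated random walk with spatially varying potential
# and motility surfaces.
#
# Velocity follows dv = -beta (v - mu(x)) dt + c(x) dW with drift
# mu(x) = -c(x) grad P(x) (ants drift downhill on the potential P). A
# second-order discretization gives a position model depending on the two
# previous positions:
#   x_t = x_{t-1} (2 - beta h) + x_{t-2} (beta h - 1)
#         + beta h^2 mu(x_{t-2}) + N(0, h^3 c^2(x_{t-2}))
# applied per axis with a shared scalar beta. Both surfaces are estimated on
# a piecewise-constant cell basis with a squared discrete-Laplacian penalty,
# in three steps: (1) beta and the drift field assuming uniform motility,
# (2) the motility surface from the step-1 residuals, (3) a re-fit of beta
# and the drift field weighted by the estimated motility.

#' Second-difference regression records from tracks
#'
#' One record per second with three consecutive in-nest positions: the
#' second-difference target, the backward velocity, and the reference
#' position two steps back (where drift and motility are evaluated).
#' Records straddling outside spells are dropped.
#'
#' @param tracks Complete track tibble.
#' @param h Time step (s, default 1).
#' @return Tibble `ant_id, t, target_x, target_y, vel_x, vel_y, x_ref, y_ref`.
#' @export
build_regression <- function(tracks, h = 1) {
  per_ant <- function(df) {
    if (nrow(df) < 3) {
      warn(sprintf("track %s shorter than 3 s; skipped", df$ant_id[1]))
      return(NULL)
    }
    df <- arrange(df, .data$t)
    inn <- df$presence != "outside"
    n <- nrow(df)
    k <- 3:n
    ok <- inn[k] & inn[k - 1] & inn[k - 2] &
      (df$t[k] - df$t[k - 1] == h) & (df$t[k - 1] - df$t[k - 2] == h)
    k <- k[ok]
    if (!length(k)) return(NULL)
    tibble(
      ant_id = df$ant_id[1], t = df$t[k],
      target_x = df$x[k] - 2 * df$x[k - 1] + df$x[k - 2],
      target_y = df$y[k] - 2 * df$y[k - 1] + df$y[k - 2],
      vel_x = (df$x[k - 1] - df$x[k - 2]) / h,
      vel_y = (df$y[k - 1] - df$y[k - 2]) / h,
      x_ref = df$x[k - 2], y_ref = df$y[k - 2]
    )
  }
  bind_rows(lapply(split(tracks, tracks$ant_id), per_ant))
}

# squared discrete-Laplacian penalty matrix over walkable cells (sparse).
# L has one row per cell: sum over walkable 4-neighbours minus degree*self.
laplacian_penalty <- function(grid) {
  W <- grid$walk; id <- grid$id; nx <- grid$nx; ny <- grid$ny
  m <- sum(W)
  ii <- list(); jj <- list(); vv <- list()
  deg <- rep(0, m)
  push <- function(di, dj) {
    iw <- which(W, arr.ind = TRUE)
    ni <- iw[, 1] + di; nj <- iw[, 2] + dj
    ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
    ok[ok] <- W[cbind(ni[ok], nj[ok])]
    from <- id[iw[ok, , drop = FALSE]]
    to <- id[cbind(ni[ok], nj[ok])]
    ii[[length(ii) + 1]] <<- from; jj[[length(jj) + 1]] <<- to
    vv[[length(vv) + 1]] <<- rep(1, length(from))
    deg[from] <<- deg[from] + 1
  }
  push(1, 0); push(-1, 0); push(0, 1); push(0, -1)
  L <- Matrix::sparseMatrix(
    i = c(unlist(ii), seq_len(m)), j = c(unlist(jj), seq_len(m)),
    x = c(unlist(vv), -deg), dims = c(m, m))
  Matrix::crossprod(L)
}

# ridge-type penalized least squares with GCV selection of lambda
penalized_lm <- function(Z, y, K, lambda = NULL, weights = NULL,
                         lambda_grid = 10^seq(-4, 4, length.out = 9)) {
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    Z <- Z * sw
    y <- y * sw
  }
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  K <- as.matrix(K)
  n <- length(y)
  fit_one <- function(lam) {
    A <- ZtZ + lam * K
    coefv <- solve(A, Zty)
    edf <- sum(diag(solve(A, ZtZ)))
    rss <- sum(y^2) - 2 * sum(coefv * Zty) + as.numeric(t(coefv) %*% ZtZ %*% coefv)
    gcv <- n * rss / (n - edf)^2
    list(coef = coefv, edf = edf, rss = rss, gcv = gcv, lambda = lam)
  }
  if (!is.null(lambda)) return(fit_one(lambda))
  fits <- lapply(lambda_grid, fit_one)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "gcv"))]]
}

#' Fit the movement SDE (beta, potential and motility surfaces)
#'
#' Three-step iterative estimate: (1) fit the autocorrelation parameter beta
#' and the drift field assuming uniform motility; (2) estimate the motility
#' surface c(x) from the step-1 squared residuals; (3) re-fit beta and the
#' drift field weighted by the estimated motility. The potential surface is
#' then recovered by least-squares integration of `grad P = -mu / c` and
#' anchored to mean zero.
#'
#' @param records Tibble from [build_regression()].
#' @param nest A [nest_geometry()].
#' @param grid_mm Cell size of the piecewise-constant surface basis (mm).
#' @param h Time step (s).
#' @param lambda_drift,lambda_motility Penalty weights; NULL (default)
#'   selects them by generalized cross-validation.
#' @return Object of class `sde_fit`: `beta`, `surfaces` (tibble `cell_x,
#'   cell_y, chamber, drift_x, drift_y, motility, potential, n_records`),
#'   `grid_mm`, `h`, `lambda` (chosen weights), `sigma2` (residual variance
#'   scale), `n_records`.
#' @export
fit_sde <- function(records, nest, grid_mm = 5, h = 1,
                    lambda_drift = NULL, lambda_motility = NULL) {
  grid <- nest_grid(nest, res = grid_mm)
  m <- sum(grid$walk)
  n <- nrow(records)
  if (n < 10 * m) {
    warn(sprintf("only %d records for %d basis cells; surfaces will be heavily smoothed",
                 n, m))
  }
  cell <- grid_cell_of(records$x_ref, records$y_ref, grid)
  # stacked per-axis response and sparse design [beta | drift_x | drift_y]
  y <- c(records$target_x, records$target_y)
  a <- -h^2 * c(records$vel_x, records$vel_y)
  ridx <- seq_len(2 * n)
  Z <- Matrix::sparseMatrix(
    i = c(ridx, seq_len(n), n + seq_len(n)),
    j = c(rep(1L, 2 * n), 1L + cell, 1L + m + cell),
    x = c(a, rep(1, 2 * n)),
    dims = c(2 * n, 1 + 2 * m))
  Kcell <- laplacian_penalty(grid)
  zero1 <- Matrix::sparseMatrix(i = integer(), j = integer(), dims = c(1, 1))
  K <- Matrix::bdiag(zero1, Kcell, Kcell)

  step1 <- penalized_lm(Z, y, K, lambda = lambda_drift)
  resid1 <- y - as.numeric(Z %*% step1$coef)

  # motility from squared residuals: E[r^2] = h^3 c^2(cell)
  Zc <- Matrix::sparseMatrix(i = ridx, j = rep(cell, 2), x = 1,
                             dims = c(2 * n, m))
  step2 <- penalized_lm(Zc, resid1^2, Kcell, lambda = lambda_motility)
  c2 <- pmax(step2$coef / h^3, 1e-10)
  cmot <- sqrt(c2)

  w <- 1 / (h^3 * c2[rep(cell, 2)])
  step3 <- penalized_lm(Z, y, K, lambda = step1$lambda, weights = w)
  beta <- step3$coef[1] / h
  drift_x <- step3$coef[1 + seq_len(m)]
  drift_y <- step3$coef[1 + m + seq_len(m)]
  if (beta <= 0) warn("estimated beta is non-positive; fit is unstable")
  mu_x <- drift_x / (beta * h^2)
  mu_y <- drift_y / (beta * h^2)

  # integrate grad P = -mu / c over the cell graph (least squares, mean 0)
  gx <- -mu_x / cmot
  gy <- -mu_y / cmot
  P <- integrate_gradient(grid, gx, gy)

  cells <- grid$cells
  cx <- grid$cx[cells[, 1]]; cy <- grid$cy[cells[, 2]]
  surfaces <- tibble(
    cell_x = cx, cell_y = cy,
    chamber = chamber_of(cx, cy, nest),
    drift_x = drift_x, drift_y = drift_y,
    motility = cmot, potential = P,
    n_records = as.integer(tabulate(cell, nbins = m))
  )
  structure(list(
    beta = beta, surfaces = surfaces, grid_mm = grid_mm, h = h,
    lambda = c(drift = step1$lambda, motility = step2$lambda),
    sigma2 = mean((y - as.numeric(Z %*% step3$coef))^2),
    n_records = n, grid = grid
  ), class = "sde_fit")
}

# least-squares integration of a gridded gradient field, anchored to mean 0
integrate_gradient <- function(grid, gx, gy) {
  W <- grid$walk; id <- grid$id; res <- grid$res
  m <- sum(W)
  rows <- list()
  edge_rows <- function(di, dj, gfield) {
    iw <- which(W, arr.ind = TRUE)
    ni <- iw[, 1] + di; nj <- iw[, 2] + dj
    ok <- ni >= 1 & ni <= grid$nx & nj >= 1 & nj <= grid$ny
    ok[ok] <- W[cbind(ni[ok], nj[ok])]
    from <- id[iw[ok, , drop = FALSE]]
    to <- id[cbind(ni[ok], nj[ok])]
    list(from = from, to = to,
         g = (gfield[from] + gfield[to]) / 2 * res)
  }
  ex <- edge_rows(1, 0, gx)
  ey <- edge_rows(0, 1, gy)
  from <- c(ex$from, ey$from); to <- c(ex$to, ey$to)
  gval <- c(ex$g, ey$g)
  ne <- length(from)
  G <- Matrix::sparseMatrix(
    i = c(seq_len(ne), seq_len(ne)), j = c(to, from),
    x = c(rep(1, ne), rep(-1, ne)), dims = c(ne, m))
  A <- Matrix::crossprod(G) + Matrix::Diagonal(m, 1e-8)
  P <- as.numeric(Matrix::solve(A, Matrix::crossprod(G, gval)))
  P - mean(P)
}

#' @export
print.sde_fit <- function(x, ...) {
  cat(sprintf(
    "<sde_fit> beta = %.4f /s on a %g mm grid (%d cells, %d records)\n",
    x$beta, x$grid_mm, nrow(x$surfaces), x$n_records))
  cat(sprintf("  motility range %.3f - %.3f, penalty weights (%.3g, %.3g)\n",
              min(x$surfaces$motility), max(x$surfaces$motility),
              x$lambda[1], x$lambda[2]))
  invisible(x)
}

#' Gridded surface tables and per-chamber motility summary
#'
#' @param fit An [fit_sde()] result.
#' @return List with `surfaces` (the per-cell table) and `chamber_motility`
#'   (tibble `chamber, mean_motility`, corridor cells excluded).
#' @export
surface_report <- function(fit) {
  list(
    surfaces = fit$surfaces,
    chamber_motility = fit$surfaces %>%
      filter(!is.na(.data$chamber), .data$chamber > 0) %>%
      group_by(.data$chamber) %>%
      summarise(mean_motility = mean(.data$motility))
  )
}

# ---- drift / motility specifications for simulation ------------------------

# drift mu(x) specification -> function(x, y) returning cbind(mu_x, mu_y)
drift_fun <- function(potential, motility_f) {
  if (is.null(potential)) {
    return(function(x, y) cbind(rep(0, length(x)), rep(0, length(x))))
  }
  if (inherits(potential, "sde_fit")) {
    fit <- potential
    grid <- fit$grid
    function(x, y) {
      cell <- grid_cell_of(x, y, grid)
      mu_x <- fit$surfaces$drift_x[cell] / (fit$beta * fit$h^2)
      mu_y <- fit$surfaces$drift_y[cell] / (fit$beta * fit$h^2)
      cbind(mu_x, mu_y)
    }
  } else if (is.function(potential)) {
    # potential is a gradient function returning cbind(dP/dx, dP/dy)
    function(x, y) {
      g <- potential(x, y)
      -motility_f(x, y) * g
    }
  } else if (is.list(potential) && !is.null(potential$center)) {
    ctr <- potential$center; k <- potential$strength
    function(x, y) {
      cbind(-motility_f(x, y) * k * (x - ctr[1]),
            -motility_f(x, y) * k * (y - ctr[2]))
    }
  } else {
    abort("unsupported potential specification")
  }
}

motility_fun <- function(motility) {
  if (is.numeric(motility) && length(motility) == 1) {
    function(x, y) rep(motility, length(x))
  } else if (is.function(motility)) {
    motility
  } else {
    abort("motility must be a scalar or function(x, y)")
  }
}

#' Simulate the discretized movement SDE
#'
#' Forward simulation of the second-order scheme, projecting every step into
#' the walkable region. Bit-reproducible for a fixed seed.
#'
#' @param beta Velocity autocorrelation parameter (1/s).
#' @param potential NULL (flat), a quadratic well `list(center, strength)`,
#'   a gradient function `function(x, y) -> cbind(dP/dx, dP/dy)`, or an
#'   [fit_sde()] result (its fitted drift field is used directly).
#' @param motility Scalar noise scale or `function(x, y)`.
#' @param x0 Start position (2-vector, inside the nest).
#' @param v0 Start velocity (2-vector, default zero).
#' @param duration_s Number of seconds to simulate.
#' @param nest A [nest_geometry()].
#' @param seed Integer seed.
#' @param h Time step (s).
#' @param ant_id Label for the output track.
#' @return Complete track tibble (t = 0 ... duration_s).
#' @export
simulate_sde <- function(beta, potential = NULL, motility = 1, x0, v0 = c(0, 0),
                         duration_s = RECORDING_DURATION_S, nest, seed = 1L,
                         h = 1, ant_id = "sim") {
  stopifnot(all(in_nest(x0[1], x0[2], nest)))
  mot <- motility_fun(motility)
  mu <- drift_fun(potential, mot)
  n_steps <- as.integer(duration_s / h)
  xs <- matrix(NA_real_, n_steps + 1, 2)
  xs[1, ] <- x0
  p1 <- project_into_nest(x0[1] + h * v0[1], x0[2] + h * v0[2], nest)
  if (n_steps >= 1) xs[2, ] <- c(p1$x, p1$y)
  withr::with_seed(seed, {
    for (t in seq_len(n_steps - 1) + 2) {
      xp <- xs[t - 1, ]; xpp <- xs[t - 2, ]
      m <- mu(xpp[1], xpp[2])
      cv <- mot(xpp[1], xpp[2])
      nxt <- xp * (2 - beta * h) + xpp * (beta * h - 1) +
        beta * h^2 * as.numeric(m) +
        rnorm(2, 0, sqrt(h^3) * cv)
      pr <- project_into_nest(nxt[1], nxt[2], nest)
      xs[t, ] <- c(pr$x, pr$y)
    }
  })
  tibble(ant_id = ant_id, t = as.integer(seq(0, duration_s, by = h)),
         x = xs[, 1], y = xs[, 2], presence = "in_nest")
}
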