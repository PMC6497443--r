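# Synthetic colonies with known ground truth: planted spatial-fidelity
# groups realised as per-group potential wells in the movement SDE, and
# trophallaxis initiations drawn from the same discretized IHPP the
# inference module fits. Generation and inference deliberately share the
# simulate/covariate code paths so that recovery tests exercise the real
# pipeline.

#' Describe a synthetic colony scenario
#'
#' Defaults emulate the study conditions: about 80 workers recorded for four
#' hours at 1 Hz, two planted spatial groups anchored in the entrance and
#' queen chambers (roughly 40/60 split), correlated-random-walk movement
#' with quadratic potential wells, and IHPP trophallaxis coefficients of the
#' magnitude reported for the annular density effects.
#'
#' @param n_ants Number of ants.
#' @param nest A [nest_geometry()] (default four-chamber layout).
#' @param group_fractions Numeric vector of planted group proportions
#'   (one entry per group; groups are anchored at `group_homes`).
#' @param group_homes Matrix/list of anchor points, one per group; default:
#'   entrance-chamber centre and queen-chamber centre (and evenly spaced
#'   chambers for more groups).
#' @param beta Velocity autocorrelation parameter (1/s).
#' @param motility Movement noise scale c (constant over the nest).
#' @param well_strength Quadratic potential well curvature (per mm); larger
#'   values give tighter spatial fidelity.
#' @param ihpp_coefs Named vector with `intercept` and one entry per annulus
#'   (`n5, n10, n15, n20`) on the log-rate scale.
#' @param duration_s Recording length (s).
#' @param n_outside Number of ants kept outside the nest for the whole
#'   recording (ground-truth group 0).
#' @param start_sd Spread (mm) of start positions around the group anchor.
#' @return A `colony_scenario` list.
#' @export
colony_scenario <- function(n_ants = 80,
                            nest = nest_four_chamber(),
                            group_fractions = c(0.4, 0.6),
                            group_homes = NULL,
                            beta = 0.5,
                            motility = 1.0,
                            well_strength = 0.1,
                            ihpp_coefs = c(intercept = -5.8, n5 = 0.18,
                                           n10 = 0.05, n15 = -0.41,
                                           n20 = -0.26),
                            duration_s = RECORDING_DURATION_S,
                            n_outside = 0,
                            start_sd = 4) {
  stopifnot(n_ants >= 1, all(group_fractions > 0))
  group_fractions <- group_fractions / sum(group_fractions)
  k <- length(group_fractions)
  if (is.null(group_homes)) {
    ch <- nest$chambers
    pick <- round(seq(1, nrow(ch), length.out = k))
    group_homes <- cbind((ch[pick, "x0"] + ch[pick, "x1"]) / 2,
                         (ch[pick, "y0"] + ch[pick, "y1"]) / 2)
  } else {
    group_homes <- rbind(group_homes)
  }
  if (!all(in_nest(group_homes[, 1], group_homes[, 2], nest))) {
    abort("group homes must lie inside the walkable region")
  }
  n_in <- n_ants - n_outside
  sizes <- diff(round(cumsum(c(0, group_fractions)) * n_in))
  sizes[k] <- n_in - sum(sizes[-k])
  structure(list(
    n_ants = n_ants, nest = nest,
    group_sizes = sizes, group_homes = group_homes,
    beta = beta, motility = motility, well_strength = well_strength,
    ihpp_coefs = ihpp_coefs, duration_s = duration_s,
    n_outside = n_outside, start_sd = start_sd
  ), class = "colony_scenario")
}

#' Simulate per-second tracks for a synthetic colony
#'
#' Every in-nest ant follows the discretized movement SDE (see [fit_sde()])
#' with a quadratic potential well centred on its planted group's anchor,
#' producing spatial fidelity; each step is projected into the nest. Ants
#' designated as outside-only produce `presence = "outside"` rows.
#'
#' @param scenario A [colony_scenario()].
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return List: `tracks` (complete track tibble) and `truth` (tibble
#'   `ant_id, group` of planted labels; group 0 = outside-only).
#' @export
simulate_tracks <- function(scenario, seed = 1L) {
  sc <- scenario
  nest <- sc$nest
  k <- length(sc$group_sizes)
  n_in <- sum(sc$group_sizes)
  ids <- sprintf("a%03d", seq_len(sc$n_ants))
  group <- c(rep(seq_len(k), sc$group_sizes), rep(0L, sc$n_outside))
  homes_x <- sc$group_homes[pmax(group, 1), 1]
  homes_y <- sc$group_homes[pmax(group, 1), 2]
  Tn <- as.integer(sc$duration_s)
  X <- matrix(NA_real_, Tn + 1, sc$n_ants)
  Y <- matrix(NA_real_, Tn + 1, sc$n_ants)
  inn <- group > 0
  withr::with_seed(seed, {
    sx <- homes_x + rnorm(sc$n_ants, 0, sc$start_sd)
    sy <- homes_y + rnorm(sc$n_ants, 0, sc$start_sd)
    p0 <- project_into_nest(sx, sy, nest)
    X[1, inn] <- p0$x[inn]; Y[1, inn] <- p0$y[inn]
    if (Tn >= 1) { X[2, ] <- X[1, ]; Y[2, ] <- Y[1, ] }  # zero start velocity
    h <- 1
    bh <- sc$beta * h
    cmot <- sc$motility
    kk <- sc$well_strength
    nin <- sum(inn)
    for (t in seq_len(Tn - 1) + 2) {
      xpp <- X[t - 2, inn]; ypp <- Y[t - 2, inn]
      mux <- -cmot * kk * (xpp - homes_x[inn])
      muy <- -cmot * kk * (ypp - homes_y[inn])
      nx <- X[t - 1, inn] * (2 - bh) + xpp * (bh - 1) + bh * h * mux +
        rnorm(nin, 0, sqrt(h^3) * cmot)
      ny <- Y[t - 1, inn] * (2 - bh) + ypp * (bh - 1) + bh * h * muy +
        rnorm(nin, 0, sqrt(h^3) * cmot)
      pr <- project_into_nest(nx, ny, nest)
      X[t, inn] <- pr$x; Y[t, inn] <- pr$y
    }
  })
  tracks <- tibble(
    ant_id = rep(ids, each = Tn + 1),
    t = rep(0:Tn, sc$n_ants),
    x = as.vector(X), y = as.vector(Y),
    presence = ifelse(rep(inn, each = Tn + 1), "in_nest", "outside")
  )
  list(tracks = tracks, truth = tibble(ant_id = ids, group = group))
}

#' Simulate trophallaxis events from the IHPP
#'
#' For every pair and second with the pair at risk (both in the nest and
#' within 20 mm of each other), an initiation occurs with probability
#' `1 - exp(-lambda_t)` where `log lambda_t` is the linear predictor from
#' the scenario coefficients and the annular neighbour counts. Pairs further
#' apart never initiate. Event durations are `2 + rgeom(duration_p)` seconds
#' and, while a pair is engaged, neither partner initiates a new event.
#'
#' @param tracks Complete track tibble (ignored, and may be NULL, when
#'   precomputed `records` are supplied).
#' @param nest A [nest_geometry()].
#' @param coefs Named coefficients (`intercept`, `n5`, `n10`, `n15`, `n20`).
#' @param seed Integer seed.
#' @param lags Annulus radii (mm).
#' @param at_risk_radius At-risk pair distance (mm).
#' @param duration_p Geometric parameter of the event-duration distribution.
#' @param exclusive Enforce that an engaged ant cannot start another event
#'   until the current one ends (default TRUE).
#' @param metric Distance metric passed to [pair_covariates()].
#' @param records Optional precomputed at-risk records from
#'   [pair_covariates()] on these tracks (with no events); skips the
#'   covariate computation.
#' @return Event tibble `ant_i, ant_j, start, end`.
#' @export
simulate_trophallaxis <- function(tracks, nest, coefs, seed = 1L,
                                  lags = LAG_RADII_MM, at_risk_radius = 20,
                                  duration_p = 0.2, exclusive = TRUE,
                                  metric = c("auto", "euclidean", "geodesic"),
                                  records = NULL) {
  metric <- match.arg(metric)
  empty_events <- tibble(ant_i = character(), ant_j = character(),
                         start = numeric(), end = numeric())
  rec <- records %||% pair_covariates(tracks, empty_events, nest, lags = lags,
                                      at_risk_radius = at_risk_radius,
                                      metric = metric)
  if (!nrow(rec)) return(empty_events)
  lag_names <- paste0("n", lags)
  eta <- coefs[["intercept"]] +
    as.matrix(rec[lag_names]) %*% coefs[lag_names]
  lambda <- exp(as.numeric(eta))
  p_init <- 1 - exp(-lambda)
  withr::with_seed(seed, {
    cand <- which(runif(nrow(rec)) < p_init)
    durations <- 2 + rgeom(length(cand), duration_p)
  })
  if (!length(cand)) return(empty_events)
  cand_tbl <- rec[cand, c("ant_i", "ant_j", "t")] %>%
    mutate(duration = durations) %>%
    arrange(.data$t)
  all_ants <- unique(c(cand_tbl$ant_i, cand_tbl$ant_j))
  busy_until <- stats::setNames(rep(-Inf, length(all_ants)), all_ants)
  out_i <- character(); out_j <- character(); out_s <- numeric(); out_e <- numeric()
  for (r in seq_len(nrow(cand_tbl))) {
    i <- cand_tbl$ant_i[r]; j <- cand_tbl$ant_j[r]; t0 <- cand_tbl$t[r]
    if (exclusive && (t0 <= busy_until[[i]] || t0 <= busy_until[[j]])) next
    tend <- t0 + cand_tbl$duration[r]
    out_i <- c(out_i, i); out_j <- c(out_j, j)
    out_s <- c(out_s, t0); out_e <- c(out_e, tend)
    busy_until[i] <- tend; busy_until[j] <- tend
  }
  tibble(ant_i = out_i, ant_j = out_j, start = out_s, end = out_e)
}

#' Simulate a full colony: tracks, planted groups and trophallaxis events
#'
#' @param scenario A [colony_scenario()].
#' @param seed Integer seed (split internally between movement and events).
#' @return List `tracks`, `events`, `truth` (planted group labels and the
#'   generating parameters).
#' @export
simulate_colony <- function(scenario, seed = 1L) {
  trk <- simulate_tracks(scenario, seed = seed)
  events <- simulate_trophallaxis(
    trk$tracks, scenario$nest, scenario$ihpp_coefs, seed = seed + 1L)
  list(tracks = trk$tracks, events = events,
       truth = list(groups = trk$truth,
                    ihpp_coefs = scenario$ihpp_coefs,
                    beta = scenario$beta, motility = scenario$motility,
                    well_strength = scenario$well_strength))
}
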