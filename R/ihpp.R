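# Pair-based inhomogeneous Poisson process (IHPP) regression of trophallaxis
# initiation. Time is discretized to one-second intervals with the rate
# constant within each second; seconds when a pair is more than 20 mm apart
# are structural zeros (the rate is 0, and those pair-seconds drop out of the
# likelihood). The per-second likelihood prod lambda_t^y_t exp(-lambda_t)
# over at-risk seconds is exactly a Poisson regression with log link.

LAG_RADII_MM <- c(5, 10, 15, 20)

# tracks -> aligned wide matrices (one column per ant, one row per second)
tracks_wide <- function(tracks) {
  ants <- sort(unique(tracks$ant_id))
  ts <- sort(unique(tracks$t))
  n <- length(ants); Tn <- length(ts)
  X <- matrix(NA_real_, Tn, n, dimnames = list(NULL, ants))
  Y <- X
  idx <- cbind(match(tracks$t, ts), match(tracks$ant_id, ants))
  X[idx] <- tracks$x
  Y[idx] <- tracks$y
  IN <- matrix(FALSE, Tn, n, dimnames = list(NULL, ants))
  IN[idx] <- tracks$presence != "outside"
  list(ants = ants, t = ts, X = X, Y = Y, IN = IN)
}

#' Pair-second covariate records for the IHPP analysis
#'
#' For each unordered pair of ants and each second, computes whether the pair
#' is at risk of initiating trophallaxis (both in the nest and within
#' `at_risk_radius` of each other), whether an initiation occurred, and the
#' annular local-density covariates: the number of additional ants (beyond
#' the focal pair) within successive distance bands of the pair centroid.
#' An ant at distance d increments exactly one of n5 (d <= 5), n10
#' (5 < d <= 10), n15 (10 < d <= 15) or n20 (15 < d <= 20).
#'
#' @param tracks Complete track tibble.
#' @param events Event tibble (may be empty).
#' @param nest A [nest_geometry()].
#' @param pairs Optional 2-column matrix/data frame of ant id pairs; default
#'   all unordered pairs of ants in `tracks`.
#' @param lags Annulus outer radii (mm, increasing; default 5, 10, 15, 20).
#' @param at_risk_radius Pair distance beyond which the rate is structurally
#'   zero (mm, default 20).
#' @param metric `"euclidean"` (fast, exact in a single convex chamber),
#'   `"geodesic"` (wall-aware grid distances, slow), or `"auto"` (euclidean
#'   for single-chamber nests, geodesic otherwise).
#' @param res Grid resolution for geodesic distances (mm).
#' @param keep_all Keep non-at-risk pair-seconds (default FALSE: only at-risk
#'   seconds enter the likelihood, so only they are returned).
#' @param censor_ongoing Treat seconds during an ongoing event of the focal
#'   pair as not at risk (default FALSE: kept at risk with y = 0).
#' @return Tibble `pair_id, ant_i, ant_j, t, at_risk, y, n5, n10, n15, n20`.
#' @export
pair_covariates <- function(tracks, events, nest, pairs = NULL,
                            lags = LAG_RADII_MM, at_risk_radius = 20,
                            metric = c("auto", "euclidean", "geodesic"),
                            res = 0.5, keep_all = FALSE,
                            censor_ongoing = FALSE) {
  metric <- match.arg(metric)
  w <- tracks_wide(tracks)
  if (metric == "auto") {
    metric <- if (nrow(nest$chambers) == 1) "euclidean" else "geodesic"
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(w$ants, 2))
  } else {
    pairs <- as.matrix(pairs)
    if (!all(pairs %in% w$ants)) abort("pair not in the track roster")
  }
  ev_key <- if (nrow(events)) {
    paste(pmin(events$ant_i, events$ant_j),
          pmax(events$ant_i, events$ant_j), floor(events$start))
  } else character()
  nlag <- length(lags)
  lag_names <- paste0("n", lags)
  out <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    xi <- w$X[, i]; yi <- w$Y[, i]; xj <- w$X[, j]; yj <- w$Y[, j]
    both_in <- w$IN[, i] & w$IN[, j]
    dpair <- rep(NA_real_, length(w$t))
    bi <- which(both_in)
    if (length(bi)) {
      dpair[bi] <- if (metric == "euclidean") {
        sqrt((xi[bi] - xj[bi])^2 + (yi[bi] - yj[bi])^2)
      } else {
        geodesic_distance(cbind(xi[bi], yi[bi]), cbind(xj[bi], yj[bi]),
                          nest, res = res, cutoff = at_risk_radius)
      }
    }
    y <- as.integer(paste(min(i, j), max(i, j), w$t) %in% ev_key)
    at_risk <- both_in & !is.na(dpair) & dpair <= at_risk_radius
    at_risk[y == 1] <- TRUE  # an observed initiation is at risk by definition
    if (censor_ongoing && nrow(events)) {
      evp <- events[pmin(events$ant_i, events$ant_j) == min(i, j) &
                      pmax(events$ant_i, events$ant_j) == max(i, j), ]
      for (e in seq_len(nrow(evp))) {
        ongoing <- w$t > evp$start[e] & w$t <= evp$end[e]
        at_risk[ongoing & y == 0] <- FALSE
      }
    }
    rows <- if (keep_all) seq_along(w$t) else which(at_risk)
    if (!length(rows)) next
    counts <- matrix(0L, length(rows), nlag, dimnames = list(NULL, lag_names))
    ar <- intersect(rows, which(at_risk))
    ari <- match(ar, rows)
    if (length(ar)) {
      cx <- (xi[ar] + xj[ar]) / 2
      cy <- (yi[ar] + yj[ar]) / 2
      proj <- project_into_nest(cx, cy, nest)
      others <- setdiff(w$ants, c(i, j))
      if (length(others)) {
        DX <- w$X[ar, others, drop = FALSE] - proj$x
        DY <- w$Y[ar, others, drop = FALSE] - proj$y
        D <- sqrt(DX * DX + DY * DY)
        D[!w$IN[ar, others, drop = FALSE]] <- Inf
        if (metric == "geodesic") {
          # refine near-threshold Euclidean distances with the wall-aware
          # metric (Euclidean is a lower bound, so only candidates within
          # the outermost lag can change annulus)
          cand <- which(D <= max(lags), arr.ind = TRUE)
          if (nrow(cand)) {
            gpt <- cbind(proj$x[cand[, 1]], proj$y[cand[, 1]])
            opt <- cbind(w$X[ar, others, drop = FALSE][cand],
                         w$Y[ar, others, drop = FALSE][cand])
            D[cand] <- geodesic_distance(gpt, opt, nest, res = res,
                                         cutoff = max(lags))
          }
        }
        prev <- 0
        for (k in seq_len(nlag)) {
          tot <- rowSums(D <= lags[k])
          counts[ari, k] <- as.integer(tot - prev)
          prev <- tot
        }
      }
    }
    out[[p]] <- tibble(
      pair_id = paste(min(i, j), max(i, j), sep = "--"),
      ant_i = min(i, j), ant_j = max(i, j),
      t = w$t[rows], at_risk = at_risk[rows], y = y[rows]
    ) %>% bind_cols(as_tibble(counts))
  }
  bind_rows(out)
}

#' Attach observed initiations to precomputed pair-second records
#'
#' Fast path for workflows that compute [pair_covariates()] once (without
#' events) and then overlay one or more simulated event sets: sets `y = 1`
#' at each record where an event between the pair starts.
#'
#' @param records Tibble from [pair_covariates()].
#' @param events Event tibble (`ant_i, ant_j, start, end`).
#' @return `records` with `y` replaced.
#' @export
attach_initiations <- function(records, events) {
  key <- paste(records$ant_i, records$ant_j, records$t)
  ev_key <- if (nrow(events)) {
    paste(pmin(events$ant_i, events$ant_j),
          pmax(events$ant_i, events$ant_j), floor(events$start))
  } else character()
  records$y <- as.integer(key %in% ev_key)
  records
}

#' Censor pair-seconds while either partner is engaged elsewhere
#'
#' When events are generated (or recorded) under exclusive engagement — an
#' ant in a trophallaxis event cannot start another one until it ends — the
#' seconds during which either member of a pair is engaged in *any* ongoing
#' event carry no initiation risk for that pair. Dropping them aligns the
#' discretized likelihood with that exclusivity; rows with an observed
#' initiation are always kept.
#'
#' @param records Tibble from [pair_covariates()] (with `y` attached).
#' @param events Event tibble; a second t is engaged for an ant when
#'   `start < t <= end` for one of its events.
#' @return `records` without the engaged pair-seconds.
#' @export
censor_engaged_seconds <- function(records, events) {
  if (!nrow(events)) return(records)
  busy <- unlist(lapply(seq_len(nrow(events)), function(k) {
    ts <- seq(floor(events$start[k]) + 1, floor(events$end[k]))
    c(paste(events$ant_i[k], ts), paste(events$ant_j[k], ts))
  }))
  drop <- (paste(records$ant_i, records$t) %in% busy) |
    (paste(records$ant_j, records$t) %in% busy)
  records[!drop | records$y == 1, ]
}

#' Fit the discretized IHPP regression of trophallaxis initiation
#'
#' Maximizes the per-second likelihood `prod lambda_t^y_t exp(-lambda_t)`
#' over at-risk pair-seconds (the rate is structurally zero elsewhere) with
#' `log lambda_t` linear in colony intercepts, treatment, the annular
#' local-density covariates, and colony x density interactions. The
#' colony x treatment interaction is fitted and dropped from the final model
#' when no term is significant at the 5% level (set
#' `colony_treatment = "always"`/`"never"` to override).
#'
#' @param records Tibble from [pair_covariates()], optionally with `colony`
#'   and `treatment` columns when several recordings are stacked.
#' @param lags Annulus radii matching the `n*` columns in `records`.
#' @param colony_density_interactions Include colony x density interactions
#'   when more than one colony is present (default TRUE).
#' @param colony_treatment `"auto"`, `"always"` or `"never"`.
#' @return Object of class `ihpp_fit`: list with `fit` (glm), `coefficients`
#'   tibble (`term, estimate, se, z, p_value`), `log_lik`, `n_at_risk`,
#'   `n_events`, and `colony_treatment_dropped`.
#' @export
fit_ihpp <- function(records, lags = LAG_RADII_MM,
                     colony_density_interactions = TRUE,
                     colony_treatment = c("auto", "always", "never")) {
  colony_treatment <- match.arg(colony_treatment)
  d <- records %>% filter(.data$at_risk)
  if (!nrow(d) || sum(d$y) == 0) {
    abort("no at-risk seconds with an initiation; nothing to fit",
          class = "antnest_no_events")
  }
  lag_names <- paste0("n", lags)
  has_colony <- "colony" %in% names(d) && length(unique(d$colony)) > 1
  has_trt <- "treatment" %in% names(d) && length(unique(d$treatment)) > 1
  if (has_colony) d$colony <- factor(d$colony)
  if (has_trt) d$treatment <- factor(d$treatment, levels = c("low", "high"))
  terms <- lag_names
  if (has_trt) terms <- c("treatment", terms)
  if (has_colony && colony_density_interactions) {
    terms <- c(terms, paste0("colony:", lag_names))
  }
  base <- if (has_colony) "0 + colony" else "1"
  make_fit <- function(extra = NULL) {
    f <- stats::reformulate(c(base, terms, extra), response = "y")
    glm(f, family = poisson(), data = d, model = FALSE, y = FALSE)
  }
  dropped <- FALSE
  if (has_colony && has_trt && colony_treatment != "never") {
    fit_ct <- make_fit("colony:treatment")
    sm <- summary(fit_ct)$coefficients
    ct_terms <- grepl("^colony.*:treatment|^treatment.*:colony", rownames(sm))
    if (colony_treatment == "always" || any(sm[ct_terms, 4] < 0.05)) {
      fit <- fit_ct
    } else {
      fit <- make_fit()
      dropped <- TRUE
    }
  } else {
    fit <- make_fit()
  }
  if (!fit$converged) {
    abort("IHPP fit did not converge (possible complete separation)",
          class = "antnest_convergence_error")
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    z = sm[, 3], p_value = sm[, 4]
  )
  structure(list(
    fit = fit, coefficients = coefs,
    log_lik = as.numeric(stats::logLik(fit)),
    n_at_risk = nrow(d), n_events = sum(d$y),
    lags = lags,
    colony_treatment_dropped = dropped
  ), class = "ihpp_fit")
}

#' @export
print.ihpp_fit <- function(x, ...) {
  cat(sprintf(
    "<ihpp_fit> %d initiations over %d at-risk pair-seconds, logLik %.1f\n",
    x$n_events, x$n_at_risk, x$log_lik))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Percent change in trophallaxis rate per additional nearby ant
#'
#' Converts fitted log-rate coefficients to the percent change in the
#' initiation rate when one additional ant is present in each distance band,
#' per colony: `100 * (exp(coefficient + colony interaction) - 1)`.
#'
#' @param fit An [fit_ihpp()] result.
#' @return Tibble `colony, lag_mm, percent_change`.
#' @export
rate_effects <- function(fit) {
  coefs <- fit$coefficients
  lag_names <- paste0("n", fit$lags)
  cf <- stats::setNames(coefs$estimate, coefs$term)
  colonies <- unique(sub("^colony", "",
                         grep("^colony[^:]*$", coefs$term, value = TRUE)))
  if (!length(colonies)) colonies <- NA_character_
  purrr::map_dfr(colonies, function(col) {
    purrr::map_dfr(lag_names, function(ln) {
      b <- if (ln %in% names(cf)) cf[[ln]] else 0
      if (!is.na(col)) {
        int <- paste0("colony", col, ":", ln)
        if (int %in% names(cf)) b <- b + cf[[int]]
      }
      tibble(colony = col, lag_mm = as.numeric(sub("^n", "", ln)),
             percent_change = 100 * (exp(b) - 1))
    })
  })
}
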