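# Annular covariate coding uses stationary ants placed at exact distances
# from the pair centroid; tracks are built in code.

pair_with_neighbours <- function(neighbour_dists, pair_gap = 4,
                                 centroid = c(30, 0), t_max = 0) {
  base <- dplyr::bind_rows(
    fixed_track("p1", centroid[1] - pair_gap / 2, centroid[2], t_max = t_max),
    fixed_track("p2", centroid[1] + pair_gap / 2, centroid[2], t_max = t_max))
  if (length(neighbour_dists)) {
    nb <- purrr::imap_dfr(neighbour_dists, function(d, k) {
      # place neighbours vertically so the distance to the centroid is exact
      fixed_track(sprintf("n%02d", k), centroid[1], centroid[2] + d,
                  t_max = t_max)
    })
    base <- dplyr::bind_rows(base, nb)
  }
  base
}

test_that("annular counts code each neighbour into exactly one band", {
  n1 <- nest_one_chamber()
  # neighbours at 7 and 17 mm from the centroid -> (0, 1, 0, 1)
  tr <- pair_with_neighbours(c(7, 17))
  rec <- pair_covariates(tr, empty_events(), n1, pairs = cbind("p1", "p2"))
  expect_equal(unname(unlist(rec[1, c("n5", "n10", "n15", "n20")])),
               c(0L, 1L, 0L, 1L))
  # a neighbour at 12 mm falls in the (10, 15] band
  tr12 <- pair_with_neighbours(c(12))
  rec12 <- pair_covariates(tr12, empty_events(), n1, pairs = cbind("p1", "p2"))
  expect_equal(unname(unlist(rec12[1, c("n5", "n10", "n15", "n20")])),
               c(0L, 0L, 1L, 0L))
  # five ants at 2, 4, 9, 14, 19 mm -> (2, 1, 1, 1)
  tr5 <- pair_with_neighbours(c(2, 4, 9, 14, 19))
  rec5 <- pair_covariates(tr5, empty_events(), n1, pairs = cbind("p1", "p2"))
  expect_equal(unname(unlist(rec5[1, c("n5", "n10", "n15", "n20")])),
               c(2L, 1L, 1L, 1L))
  # no other ants: all counts zero
  tr0 <- pair_with_neighbours(numeric(0))
  rec0 <- pair_covariates(tr0, empty_events(), n1, pairs = cbind("p1", "p2"))
  expect_equal(sum(unlist(rec0[1, c("n5", "n10", "n15", "n20")])), 0L)
})

test_that("annular counts conserve the total number of ants within 20 mm", {
  n1 <- nest_one_chamber()
  set.seed(31)
  for (rep in 1:3) {
    tr <- dplyr::bind_rows(lapply(1:10, function(k) {
      p <- project_into_nest(runif(1, 0, 65), runif(1, -20, 20), n1)
      fixed_track(sprintf("w%02d", k), p$x, p$y, t_max = 0)
    }))
    rec <- pair_covariates(tr, empty_events(), n1, keep_all = TRUE)
    w <- antnest:::tracks_wide(tr)
    for (r in sample(nrow(rec), 10)) {
      if (!rec$at_risk[r]) next
      i <- rec$ant_i[r]; j <- rec$ant_j[r]
      cx <- (w$X[1, i] + w$X[1, j]) / 2
      cy <- (w$Y[1, i] + w$Y[1, j]) / 2
      others <- setdiff(w$ants, c(i, j))
      d <- sqrt((w$X[1, others] - cx)^2 + (w$Y[1, others] - cy)^2)
      expect_equal(rec$n5[r] + rec$n10[r] + rec$n15[r] + rec$n20[r],
                   sum(d <= 20))
    }
  }
})

test_that("pairs beyond 20 mm are structural zeros", {
  n1 <- nest_one_chamber()
  tr <- dplyr::bind_rows(fixed_track("p1", 5, 0, t_max = 5),
                         fixed_track("p2", 55, 0, t_max = 5))
  rec <- pair_covariates(tr, empty_events(), n1)
  expect_equal(nrow(rec), 0)
  rec_all <- pair_covariates(tr, empty_events(), n1, keep_all = TRUE)
  expect_equal(nrow(rec_all), 6)
  expect_false(any(rec_all$at_risk))
  # and the generator therefore produces no events
  ev <- simulate_trophallaxis(tr, n1, c(intercept = 2, n5 = 0, n10 = 0,
                                        n15 = 0, n20 = 0), seed = 1)
  expect_equal(nrow(ev), 0)
})

test_that("unknown pairs and event-free fits raise errors", {
  n1 <- nest_one_chamber()
  tr <- pair_with_neighbours(numeric(0), t_max = 3)
  expect_error(pair_covariates(tr, empty_events(), n1,
                               pairs = cbind("p1", "zz")), "roster")
  rec <- pair_covariates(tr, empty_events(), n1)
  expect_error(fit_ihpp(rec), class = "antnest_no_events")
})

test_that("an intercept-only fit recovers the generating rate", {
  # records built directly: 1e5 at-risk pair-seconds at rate 0.005/s
  set.seed(41)
  n <- 1e5; lambda <- 0.005
  rec <- tibble::tibble(
    pair_id = "p", ant_i = "a", ant_j = "b", t = seq_len(n),
    at_risk = TRUE, y = rbinom(n, 1, 1 - exp(-lambda)),
    n5 = 0L, n10 = 0L, n15 = 0L, n20 = 0L)
  fit <- fit_ihpp(rec)
  est <- tidy(fit)
  expect_equal(est$term[1], "(Intercept)")
  expect_lt(abs(est$estimate[1] - log(lambda)), 2 * est$se[1])
  # mean matching: total fitted intensity equals observed initiations
  expect_equal(sum(fitted(fit$fit)), sum(rec$y), tolerance = 1e-6)
})

test_that("density coefficients are recovered from simulated records", {
  set.seed(47)
  n <- 2e5
  truth <- c(intercept = -5.2, n5 = 0.18, n10 = 0.05, n15 = -0.41,
             n20 = -0.26)
  rec <- tibble::tibble(
    pair_id = "p", ant_i = "a", ant_j = "b", t = seq_len(n), at_risk = TRUE,
    n5 = rpois(n, 0.6), n10 = rpois(n, 1.2), n15 = rpois(n, 1.5),
    n20 = rpois(n, 1.5))
  eta <- truth["intercept"] + as.matrix(rec[c("n5", "n10", "n15", "n20")]) %*%
    truth[c("n5", "n10", "n15", "n20")]
  rec$y <- rbinom(n, 1, 1 - exp(-exp(eta)))
  fit <- fit_ihpp(rec)
  est <- tidy(fit)
  for (term in c("n5", "n10", "n15", "n20")) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$se)
  }
})

test_that("rate effects convert log coefficients to percent changes", {
  fit <- list(
    coefficients = tibble::tibble(
      term = c("(Intercept)", "n5", "n10", "n15", "n20"),
      estimate = c(-5, 0, log(2), -0.41, 0.1),
      se = 0.1, z = 1, p_value = 0.5),
    lags = c(5, 10, 15, 20))
  class(fit) <- "ihpp_fit"
  eff <- rate_effects(fit)
  expect_equal(eff$percent_change[eff$lag_mm == 5], 0)
  expect_equal(eff$percent_change[eff$lag_mm == 10], 100)
  expect_equal(eff$percent_change[eff$lag_mm == 15], 100 * (exp(-0.41) - 1))
  expect_equal(round(eff$percent_change[eff$lag_mm == 15], 1), -33.6)
})

test_that("colony interactions shift the per-colony rate effects", {
  set.seed(53)
  n <- 6e4
  rec <- dplyr::bind_rows(
    tibble::tibble(pair_id = "p1", ant_i = "a", ant_j = "b", t = seq_len(n),
                   at_risk = TRUE, colony = "1",
                   n5 = rpois(n, 0.8), n10 = 0L, n15 = 0L, n20 = 0L),
    tibble::tibble(pair_id = "p2", ant_i = "c", ant_j = "d", t = seq_len(n),
                   at_risk = TRUE, colony = "2",
                   n5 = rpois(n, 0.8), n10 = 0L, n15 = 0L, n20 = 0L))
  eta <- ifelse(rec$colony == "1", -4.5 + 0.2 * rec$n5, -4.8 + 0.5 * rec$n5)
  rec$y <- rbinom(nrow(rec), 1, 1 - exp(-exp(eta)))
  fit <- fit_ihpp(rec)
  eff <- rate_effects(fit)
  e5 <- eff[eff$lag_mm == 5, ]
  expect_lt(abs(e5$percent_change[e5$colony == "1"] - 100 * (exp(0.2) - 1)), 12)
  expect_lt(abs(e5$percent_change[e5$colony == "2"] - 100 * (exp(0.5) - 1)), 20)
})

test_that("engaged ants are censored from every pair's risk set", {
  n1 <- nest_one_chamber()
  # three ants close together: pairs (p1,p2), (p1,n01), (p2,n01)
  tr <- pair_with_neighbours(c(7), t_max = 9)
  rec <- pair_covariates(tr, empty_events(), n1)
  ev <- tibble::tibble(ant_i = "p1", ant_j = "n01", start = 2, end = 6)
  out <- censor_engaged_seconds(attach_initiations(rec, ev), ev)
  # seconds 3..6: p1 and n01 are engaged, so every pair containing either
  # loses those seconds; the untouched pair keeps all ten
  kept <- table(out$pair_id)
  # the initiation row (t = 2) precedes the engaged window 3..6
  expect_equal(unname(kept[["n01--p1"]]), 10 - 4)
  expect_equal(unname(kept[["p1--p2"]]), 10 - 4)
  expect_equal(unname(kept[["n01--p2"]]), 10 - 4)
  expect_identical(censor_engaged_seconds(rec, empty_events()), rec)
})

test_that("ongoing events can be censored from the risk set by flag", {
  n1 <- nest_one_chamber()
  tr <- pair_with_neighbours(numeric(0), t_max = 9)
  ev <- tibble::tibble(ant_i = "p1", ant_j = "p2", start = 2, end = 6)
  rec_keep <- pair_covariates(tr, ev, n1)
  expect_true(all(rec_keep$at_risk))
  expect_equal(sum(rec_keep$y), 1)
  rec_cens <- pair_covariates(tr, ev, n1, censor_ongoing = TRUE)
  expect_equal(nrow(rec_cens), 10 - 4)  # seconds 3..6 censored
})
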