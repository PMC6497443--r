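# Local density: wall-aware neighbour counts within a radius, temporal
# decorrelation by subsampling, a mixed-model treatment test, and the
# random-diffusion null expectation.

#' Per-ant local density at one or more times
#'
#' Number of other in-nest ants within `radius` mm of each ant, measured
#' along the shortest wall-aware path (ants can move around walls but not
#' through them). Ants outside the nest are excluded and receive no count.
#'
#' @param tracks Complete track tibble.
#' @param nest A [nest_geometry()].
#' @param times Integer vector of seconds at which to count (default: every
#'   second present in `tracks`).
#' @param radius Neighbourhood radius (mm, default 15).
#' @param res Grid resolution for wall-aware distances (mm).
#' @return Tibble `t, ant_id, n_neighbours`.
#' @export
local_density <- function(tracks, nest, times = NULL, radius = 15, res = 0.5) {
  if (is.null(times)) times <- sort(unique(tracks$t))
  inn <- tracks %>%
    filter(.data$t %in% times, .data$presence != "outside")
  res_list <- lapply(split(inn, inn$t), function(df) {
    n <- nrow(df)
    if (n == 0) return(NULL)
    cnt <- if (n == 1) 0L else {
      D <- geodesic_distance_matrix(df$x, df$y, nest, res = res,
                                    cutoff = radius)
      as.integer(colSums(D <= radius) - 1L)
    }
    tibble(t = df$t, ant_id = df$ant_id, n_neighbours = cnt)
  })
  bind_rows(res_list) %>% arrange(.data$t, .data$ant_id)
}

#' Colony-mean local density series with temporal decorrelation
#'
#' Averages per-ant neighbour counts over ants at each second, then subsamples
#' the mean series at a fixed interval (default 25 min = 1500 s, starting at
#' t = 0) so that successive retained points are effectively independent.
#' A lag-1 autocorrelation permutation test on the retained points is
#' reported as a diagnostic.
#'
#' @param density Tibble from [local_density()] (per-ant counts).
#' @param interval Subsampling interval in seconds (default 1500).
#' @param n_perm Permutations for the lag-1 autocorrelation test.
#' @param seed Integer seed for the permutation test.
#' @return List with `mean_series` (tibble `t, mean_density`), `subsampled`
#'   (tibble `t, mean_density`), and `autocorrelation` (one-row tibble
#'   `lag1_cor, p_value`; NA correlation for constant series counts as a
#'   pass).
#' @export
decorrelate <- function(density, interval = 1500, n_perm = 2000, seed = 1L) {
  if (interval <= 0) abort("interval must be positive")
  mean_series <- density %>%
    group_by(.data$t) %>%
    summarise(mean_density = mean(.data$n_neighbours)) %>%
    arrange(.data$t)
  sub <- mean_series %>% filter((.data$t - min(.data$t)) %% interval == 0)
  x <- sub$mean_density
  if (length(x) < 3 || sd(x) == 0) {
    ac <- tibble(lag1_cor = NA_real_, p_value = NA_real_, pass = TRUE)
  } else {
    r <- cor(head(x, -1), tail(x, -1))
    perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      s <- sample(x)
      cor(head(s, -1), tail(s, -1))
    }, numeric(1)))
    p <- (1 + sum(abs(perm) >= abs(r) - 1e-12)) / (n_perm + 1)
    ac <- tibble(lag1_cor = r, p_value = p, pass = p > 0.05)
  }
  list(mean_series = mean_series, subsampled = sub, autocorrelation = ac)
}

#' Mixed-model test of the treatment effect on local density
#'
#' Linear mixed model for subsampled colony-mean local density with a fixed
#' effect for nest set-up (high- vs low-density) and a random intercept per
#' colony; the treatment effect is tested with a Wald chi-square.
#'
#' @param data Tibble with columns `colony`, `treatment` (`"high"`/`"low"`),
#'   `mean_density` (one row per retained subsample point).
#' @return Object of class `density_model`: list with `fit` (lmerMod),
#'   `effect` (one-row tibble `estimate, se, wald_chisq, p_value` for the
#'   high-vs-low contrast) and `means` (per-treatment model means).
#' @export
fit_density_model <- function(data) {
  data <- as_tibble(data)
  if (length(unique(data$treatment)) < 2) {
    abort("both treatment levels are required")
  }
  data$treatment <- factor(data$treatment, levels = c("low", "high"))
  fit <- lme4::lmer(mean_density ~ treatment + (1 | colony), data = data,
                    REML = TRUE)
  est <- lme4::fixef(fit)[["treatmenthigh"]]
  se <- sqrt(as.matrix(vcov(fit))["treatmenthigh", "treatmenthigh"])
  w <- (est / se)^2
  means <- data %>%
    group_by(.data$treatment) %>%
    summarise(mean_density = mean(.data$mean_density))
  structure(list(
    fit = fit,
    effect = tibble(estimate = est, se = se, wald_chisq = w,
                    p_value = pchisq(w, df = 1, lower.tail = FALSE)),
    means = means
  ), class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("<density_model> high - low local density effect:\n")
  print(as.data.frame(x$effect), row.names = FALSE)
  invisible(x)
}

#' Expected density reduction under random diffusion
#'
#' If ants spread uniformly over a nest enlarged by `area_ratio`, local
#' density falls by `100 * (1 - 1/area_ratio)` percent; quadrupling the area
#' gives the 75% null reduction.
#'
#' @param area_ratio Ratio of enlarged to original walkable area (>= 1).
#' @return Percent reduction in density.
#' @export
diffusion_null_reduction <- function(area_ratio) {
  if (any(area_ratio < 1)) abort("area_ratio must be >= 1")
  100 * (1 - 1 / area_ratio)
}
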