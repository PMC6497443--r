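# Per-second interaction-rate modelling and trophallaxis-network
# assortativity with jackknife standard errors.

#' Per-second initiation count series
#'
#' Counts of trophallaxis events whose start falls in each second of the
#' recording; the series has `duration_s + 1` entries (t = 0 ... duration_s)
#' and its total equals the number of events.
#'
#' @param events Event tibble (`ant_i, ant_j, start, end`).
#' @param duration_s Recording duration (s, default 14,400).
#' @return Tibble `t, count`.
#' @export
interaction_count_series <- function(events, duration_s = RECORDING_DURATION_S) {
  if (nrow(events) && any(events$start < 0 | events$start > duration_s)) {
    abort("event starts outside the recording window", class = "antnest_event_error")
  }
  tt <- factor(floor(events$start), levels = 0:duration_s)
  tibble(t = 0:duration_s, count = as.integer(table(tt)))
}

#' Stack per-recording count series into the full GLM design
#'
#' @param events_by_recording Tibble of events with additional `colony` and
#'   `treatment` columns identifying the recording.
#' @param duration_s Recording duration (s).
#' @return Tibble `colony, treatment, t, count` with one row per second per
#'   colony-treatment recording (14,401 x 2 x 3 = 86,406 for the full
#'   3-colony design).
#' @export
stack_interaction_series <- function(events_by_recording,
                                     duration_s = RECORDING_DURATION_S) {
  events_by_recording %>%
    group_by(.data$colony, .data$treatment) %>%
    dplyr::group_modify(~ interaction_count_series(.x, duration_s)) %>%
    ungroup()
}

#' Poisson regression of per-second interaction counts
#'
#' Generalized linear model with Poisson distribution and log link predicting
#' the number of interactions initiated each second from colony, treatment
#' and their interaction, under sum-to-zero (effects) coding so that the
#' intercept is the grand mean log rate and the reported levels mirror
#' "Colony 1", "Colony 2", "Treatment high". Pairwise contrasts of the
#' per-colony treatment effects are included.
#'
#' @param design Tibble from [stack_interaction_series()]
#'   (`colony, treatment, t, count`).
#' @return Object of class `rate_glm`: list with `fit`, `coefficients`
#'   (tibble `term, estimate, se, wald_stat, ci_lo, ci_hi, p_value`), and
#'   `treatment_contrasts` (per-colony high-vs-low log-rate effects and their
#'   pairwise differences, Wald tests).
#' @export
fit_rate_glm <- function(design) {
  design <- as_tibble(design)
  design$colony <- factor(design$colony)
  design$treatment <- factor(design$treatment, levels = c("high", "low"))
  if (any(table(design$colony, design$treatment) == 0)) {
    abort("every colony x treatment cell must be present")
  }
  fit <- glm(count ~ colony * treatment, family = poisson(), data = design,
             contrasts = list(colony = "contr.sum", treatment = "contr.sum"),
             model = FALSE, y = FALSE)
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, 1], se = sm[, 2],
    wald_stat = (sm[, 1] / sm[, 2])^2,
    ci_lo = sm[, 1] - 1.96 * sm[, 2],
    ci_hi = sm[, 1] + 1.96 * sm[, 2],
    p_value = sm[, 4]
  )
  # per-colony high - low log-rate effect via linear combinations
  V <- vcov(fit)
  beta <- coef(fit)
  lev <- levels(design$colony)
  newd <- tidyr::expand_grid(colony = factor(lev, levels = lev),
                             treatment = factor(c("high", "low"),
                                                levels = c("high", "low")))
  X <- stats::model.matrix(~ colony * treatment, newd,
                           contrasts.arg = list(colony = "contr.sum",
                                                treatment = "contr.sum"))
  Ldiff <- X[newd$treatment == "high", , drop = FALSE] -
    X[newd$treatment == "low", , drop = FALSE]
  rownames(Ldiff) <- lev
  per_colony <- tibble(
    contrast = paste0("colony", lev, ": high - low"),
    estimate = as.numeric(Ldiff %*% beta),
    se = sqrt(diag(Ldiff %*% V %*% t(Ldiff)))
  )
  pairs <- utils::combn(seq_along(lev), 2)
  Lpair <- Ldiff[pairs[1, ], , drop = FALSE] - Ldiff[pairs[2, ], , drop = FALSE]
  pairwise <- tibble(
    contrast = paste0("(high - low) colony", lev[pairs[1, ]],
                      " vs colony", lev[pairs[2, ]]),
    estimate = as.numeric(Lpair %*% beta),
    se = sqrt(diag(Lpair %*% V %*% t(Lpair)))
  )
  contrasts <- bind_rows(per_colony, pairwise) %>%
    mutate(z = .data$estimate / .data$se,
           p_value = 2 * pnorm(-abs(.data$z)))
  structure(list(fit = fit, coefficients = coefs,
                 treatment_contrasts = contrasts),
            class = "rate_glm")
}

#' @export
print.rate_glm <- function(x, ...) {
  cat("<rate_glm> Poisson log-link fit of per-second interaction counts\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build the weighted trophallaxis network
#'
#' Undirected graph whose nodes are the colony roster (or the ants appearing
#' in events) and whose edge weights are the number of trophallaxis events
#' per dyad.
#'
#' @param events Event tibble.
#' @param roster Optional character vector of all ant ids to include as nodes.
#' @return An igraph graph with edge attribute `weight`.
#' @export
build_network <- function(events, roster = NULL) {
  if (nrow(events) && any(events$ant_i == events$ant_j)) {
    abort("self-paired trophallaxis event", class = "antnest_event_error")
  }
  dyads <- if (nrow(events)) {
    tibble(a = pmin(events$ant_i, events$ant_j),
           b = pmax(events$ant_i, events$ant_j)) %>%
      count(.data$a, .data$b, name = "weight")
  } else tibble(a = character(), b = character(), weight = integer())
  nodes <- sort(unique(c(roster, dyads$a, dyads$b)))
  g <- igraph::graph_from_data_frame(dyads, directed = FALSE,
                                     vertices = tibble(name = nodes))
  g
}

# group-group mixing matrix from a weighted graph and a node->group map;
# entries sum to 1 over both directions of each edge
mixing_matrix <- function(graph, groups) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  gl <- sort(unique(groups))
  gi <- factor(groups[el[, 1]], levels = gl)
  gj <- factor(groups[el[, 2]], levels = gl)
  k <- length(gl)
  E <- matrix(0, k, k, dimnames = list(gl, gl))
  for (e in seq_len(nrow(el))) {
    E[gi[e], gj[e]] <- E[gi[e], gj[e]] + w[e]
    E[gj[e], gi[e]] <- E[gj[e], gi[e]] + w[e]
  }
  E / sum(E)
}

assort_r <- function(E) {
  ab <- sum(rowSums(E) * colSums(E))
  if (abs(1 - ab) < 1e-12) return(NA_real_)
  (sum(diag(E)) - ab) / (1 - ab)
}

#' Assortativity of the trophallaxis network by spatial group
#'
#' Discrete (categorical) assortativity of the weighted interaction network
#' with respect to the spatial partition: `r = (sum_i e_ii - sum_i a_i b_i) /
#' (1 - sum_i a_i b_i)` on the edge mixing matrix, each event counted once.
#' The standard error is the edge jackknife: every unit of edge weight is
#' removed in turn, r recomputed, and `se = sqrt(sum_i (r_i - r)^2)`.
#'
#' @param graph Weighted igraph graph from [build_network()].
#' @param partition `spatial_partition` tibble (or tibble `ant_id, group`)
#'   labelling every node.
#' @return One-row tibble `r, se, z, n_edges` of class `assortativity_result`.
#' @export
assortativity_groups <- function(graph, partition) {
  nodes <- igraph::V(graph)$name
  groups <- partition$group[match(nodes, partition$ant_id)]
  if (any(is.na(groups))) abort("every node must have a group label")
  names(groups) <- nodes
  E <- mixing_matrix(graph, groups)
  r <- assort_r(E)
  if (is.na(r)) {
    abort("assortativity undefined: all edges in a single group",
          class = "antnest_degenerate_network")
  }
  # jackknife over unit edges: remove one event's worth of weight at a time
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  m <- sum(w)
  gl <- rownames(E)
  Eraw <- E * (2 * m)  # unnormalized double-counted mixing matrix
  r_jack <- numeric(0)
  for (e in seq_len(nrow(el))) {
    gi <- match(as.character(groups[el[e, 1]]), gl)
    gj <- match(as.character(groups[el[e, 2]]), gl)
    Ei <- Eraw
    Ei[gi, gj] <- Ei[gi, gj] - 1
    Ei[gj, gi] <- Ei[gj, gi] - 1
    ri <- assort_r(Ei / (2 * (m - 1)))
    r_jack <- c(r_jack, rep(if (is.na(ri)) r else ri, w[e]))
  }
  se <- sqrt(sum((r_jack - r)^2))
  out <- tibble(r = r, se = se, z = if (se > 0) r / se else Inf,
                n_edges = as.integer(m))
  class(out) <- c("assortativity_result", class(out))
  out
}
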