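# Spatial-fidelity groups from movement signatures.
#
# Each ant's spatial signature is the distribution of its wall-aware
# rectilinear distance to the entrance over all in-nest seconds. Pairwise
# similarity is 1 minus the two-sample Kolmogorov-Smirnov statistic; Louvain
# community detection on the resulting weighted network yields the spatial
# groups, relabelled 1..k by increasing mean entrance distance, with group 0
# reserved for ants that never entered the nest.

#' Spatial signatures of all ants
#'
#' One entrance-distance sample per in-nest (or imputed) second per ant.
#' Ants that were outside for the whole recording yield no rows here and are
#' routed to spatial group 0 downstream.
#'
#' @param tracks Complete track tibble (`ant_id, t, x, y, presence`).
#' @param nest A [nest_geometry()].
#' @param res Grid resolution (mm) for the wall-aware distance.
#' @return Tibble `ant_id, t, dist` (mm).
#' @export
spatial_signatures <- function(tracks, nest, res = 0.5) {
  inn <- tracks %>% filter(.data$presence != "outside")
  if (!nrow(inn)) return(tibble(ant_id = character(), t = integer(), dist = numeric()))
  inn %>%
    mutate(dist = distance_to_entrance(.data$x, .data$y, nest, res = res)) %>%
    select("ant_id", "t", "dist")
}

#' Kolmogorov-Smirnov similarity of two spatial signatures
#'
#' `1 - sup |F_a - F_b|` over the pooled sample points, where F are the
#' empirical CDFs of the two distance samples. The statistic is invariant
#' under any common monotone rescaling of both samples.
#'
#' @param a,b Numeric vectors of distance samples (non-empty).
#' @return Similarity in `[0, 1]`; 1 for identical distributions.
#' @export
ks_similarity <- function(a, b) {
  if (!length(a) || !length(b)) {
    abort("similarity undefined for an empty signature (route ant to group 0)",
          class = "antnest_empty_signature")
  }
  vals <- sort(unique(c(a, b)))
  Fa <- findInterval(vals, sort(a)) / length(a)
  Fb <- findInterval(vals, sort(b)) / length(b)
  1 - max(abs(Fa - Fb))
}

#' Build the ant-to-ant KS similarity network
#'
#' Complete weighted network over all ants with non-empty signatures; edge
#' weight is [ks_similarity()] of the two signatures.
#'
#' @param signatures Tibble from [spatial_signatures()].
#' @return An object of class `similarity_network`: list with `ants` (tibble
#'   `ant_id`, `mean_dist`, `n_samples`) and `weights` (symmetric matrix,
#'   diagonal NA).
#' @export
build_similarity_network <- function(signatures) {
  ants <- signatures %>%
    group_by(.data$ant_id) %>%
    summarise(mean_dist = mean(.data$dist), n_samples = n()) %>%
    arrange(.data$ant_id)
  n <- nrow(ants)
  if (n < 2) abort("need at least 2 non-empty signatures")
  sigs <- split(signatures$dist, signatures$ant_id)[ants$ant_id]
  # ECDFs evaluated on the pooled support; the KS sup is attained there
  vals <- sort(unique(signatures$dist))
  Fm <- matrix(0, n, length(vals))
  for (i in seq_len(n)) {
    Fm[i, ] <- findInterval(vals, sort(sigs[[i]])) / length(sigs[[i]])
  }
  W <- matrix(NA_real_, n, n, dimnames = list(ants$ant_id, ants$ant_id))
  for (i in seq_len(n - 1)) {
    di <- abs(sweep(Fm[seq(i + 1, n), , drop = FALSE], 2, Fm[i, ]))
    s <- 1 - apply(di, 1, max)
    W[i, seq(i + 1, n)] <- s
    W[seq(i + 1, n), i] <- s
  }
  structure(list(ants = ants, weights = W), class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d ants, %d edges, mean similarity %.3f\n",
              nrow(x$ants), choose(nrow(x$ants), 2),
              mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

louvain_membership <- function(W, seed) {
  n <- nrow(W)
  if (n == 1) return(stats::setNames(1L, rownames(W)))
  g <- igraph::graph_from_adjacency_matrix(
    replace(W, is.na(W), 0), mode = "undirected", weighted = TRUE)
  withr::with_seed(seed, {
    # shuffle vertex order so tie-breaking is governed by the seed
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    mem <- igraph::membership(igraph::cluster_louvain(gp))
    mem <- mem[perm]  # vertex i of g is vertex perm[i] of gp
  })
  stats::setNames(as.integer(mem), rownames(W))
}

#' Detect spatial groups by Louvain community detection
#'
#' Modularity-maximizing partition of the similarity network, with groups
#' relabelled 1..k by increasing mean entrance distance (group 1 closest to
#' the entrance). Ants listed in `outside_ants` are appended as group 0.
#'
#' @param net A [build_similarity_network()] result.
#' @param seed Integer seed controlling Louvain tie-breaking.
#' @param outside_ants Character vector of outside-only ant ids to append as
#'   group 0.
#' @return A `spatial_partition` tibble with columns `ant_id`, `group`,
#'   `mean_dist`; attribute `modularity`.
#' @export
detect_groups <- function(net, seed = 1L, outside_ants = character()) {
  mem <- louvain_membership(net$weights, seed)
  part <- net$ants %>% mutate(group = mem[.data$ant_id])
  ord <- part %>%
    group_by(.data$group) %>%
    summarise(gd = mean(.data$mean_dist)) %>%
    arrange(.data$gd)
  relab <- stats::setNames(seq_len(nrow(ord)), ord$group)
  part$group <- as.integer(relab[as.character(part$group)])
  W0 <- replace(net$weights, is.na(net$weights), 0)
  g <- igraph::graph_from_adjacency_matrix(W0, mode = "undirected", weighted = TRUE)
  mod <- igraph::modularity(g, part$group, weights = igraph::E(g)$weight)
  if (length(outside_ants)) {
    part <- bind_rows(part, tibble(
      ant_id = outside_ants, mean_dist = NA_real_,
      n_samples = 0L, group = 0L))
  }
  out <- part %>% select("ant_id", "group", "mean_dist") %>%
    arrange(.data$ant_id)
  attr(out, "modularity") <- mod
  class(out) <- c("spatial_partition", class(out))
  out
}

#' Detect spatial groups straight from a track table
#'
#' Convenience wrapper: signatures, similarity network, Louvain detection and
#' group-0 assignment of outside-only ants in one call.
#'
#' @inheritParams spatial_signatures
#' @param seed Integer seed for Louvain tie-breaking.
#' @return A `spatial_partition` tibble (see [detect_groups()]).
#' @export
spatial_partition <- function(tracks, nest, seed = 1L, res = 0.5) {
  sig <- spatial_signatures(tracks, nest, res = res)
  outside <- setdiff(unique(tracks$ant_id), unique(sig$ant_id))
  net <- build_similarity_network(sig)
  detect_groups(net, seed = seed, outside_ants = outside)
}

# changed-group rule: ant i changed iff fewer than half of the ants she was
# grouped with in the smaller of (reference group, replicate group) are also
# in the larger; ties in size resolve toward the reference group. With C the
# overlap count (focal included) and sizes nr, ng this is
#   (C - 1) < (min(nr, ng) - 1) / 2
changed_ants <- function(ref_mem, new_mem) {
  tab <- table(ref_mem, new_mem)
  nr <- table(ref_mem); ng <- table(new_mem)
  C <- tab[cbind(as.character(ref_mem), as.character(new_mem))]
  smaller <- pmin(nr[as.character(ref_mem)], ng[as.character(new_mem)])
  unname((C - 1) < (smaller - 1) / 2)
}

#' Robustness of spatial groups under beta perturbation of the network
#'
#' Each replicate resamples every edge weight from a beta distribution whose
#' mean is the observed similarity (mean 0.001 where the similarity is 0) and
#' whose second shape parameter is `beta_shape`; groups are re-detected and
#' each ant is flagged as changed by the smaller-group overlap rule. Reports
#' the fraction of ants changing group, averaged over replicates.
#'
#' @param net A [build_similarity_network()] result.
#' @param reference Partition from [detect_groups()] on `net`.
#' @param n_reps Number of perturbed replicates (default 1000).
#' @param beta_shape Second shape parameter of the beta distribution
#'   (default 4).
#' @param zero_similarity_mean Replacement mean for zero-similarity edges.
#' @param seed Integer seed.
#' @return One-row tibble: `mean_changed_fraction`, `max_changed_fraction`,
#'   `n_reps`.
#' @export
perturb_and_score <- function(net, reference, n_reps = 1000, beta_shape = 4,
                              zero_similarity_mean = 0.001, seed = 1L) {
  if (n_reps < 1) abort("n_reps must be at least 1")
  W <- net$weights
  n <- nrow(W)
  ut <- upper.tri(W)
  mu <- W[ut]
  mu[mu <= 0] <- zero_similarity_mean
  mu <- pmin(mu, 1 - 1e-9)
  alpha <- beta_shape * mu / (1 - mu)
  ref_mem <- reference$group[match(rownames(W), reference$ant_id)]
  fracs <- withr::with_seed(seed, vapply(seq_len(n_reps), function(r) {
    w <- rbeta(length(mu), alpha, beta_shape)
    Wp <- matrix(0, n, n, dimnames = dimnames(W))
    Wp[ut] <- w
    Wp <- Wp + t(Wp)
    new_mem <- louvain_membership(Wp, seed = sample.int(.Machine$integer.max, 1))
    mean(changed_ants(ref_mem, new_mem))
  }, numeric(1)))
  tibble(mean_changed_fraction = mean(fracs),
         max_changed_fraction = max(fracs),
         n_reps = as.integer(n_reps))
}

#' Cross-treatment consistency of spatial groups
#'
#' Spearman rank correlation between an ant's group label in two partitions
#' (e.g. high- vs low-density treatment), with a two-sided permutation
#' p-value. Only ants present in both partitions are used (case-wise
#' deletion of ants that died between treatments is assumed done upstream;
#' ants absent from either partition are dropped here). Outside-only ants
#' carry label 0 and participate in the correlation.
#'
#' @param high,low `spatial_partition` tibbles (or any tibble with `ant_id`,
#'   `group`).
#' @param n_perm Number of label permutations (default 40,000).
#' @param seed Integer seed.
#' @return One-row tibble: `rho`, `p_value`, `n_ants`, `n_perm`.
#' @export
group_consistency <- function(high, low, n_perm = 40000, seed = 1L) {
  shared <- dplyr::inner_join(
    tibble(ant_id = high$ant_id, g1 = high$group),
    tibble(ant_id = low$ant_id, g2 = low$group), by = "ant_id")
  if (nrow(shared) < 3) abort("need at least 3 shared ants")
  r1 <- rank(shared$g1); r2 <- rank(shared$g2)
  if (sd(r1) == 0 || sd(r2) == 0) {
    abort("a partition with a single group has no rank variation")
  }
  rho <- cor(r1, r2)
  r1c <- r1 - mean(r1)
  denom <- sqrt(sum(r1c^2)) * sd(r2) * sqrt(length(r2) - 1)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sum(r1c * sample(r2)) / denom
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  tibble(rho = rho, p_value = p, n_ants = nrow(shared),
         n_perm = as.integer(n_perm))
}
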