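test_that("spatial signatures count in-nest seconds and route outside ants away", {
  n1 <- nest_one_chamber()
  ep <- n1$entrance_point
  tracks <- dplyr::bind_rows(
    fixed_track("at_door", ep[1], ep[2], t_max = 9),
    fixed_track("away", 10, 0, t_max = 9, presence = "outside"),
    tibble::tibble(ant_id = "alt", t = 0:9,
                   x = rep(c(10, 30), 5), y = 0, presence = "in_nest"))
  sig <- spatial_signatures(tracks, n1)
  expect_equal(unique(sig$dist[sig$ant_id == "at_door"]), 0)
  expect_false("away" %in% sig$ant_id)
  alt <- sig$dist[sig$ant_id == "alt"]
  expect_equal(sort(unique(alt)), c(10, 30))
  expect_equal(mean(alt == 10), 0.5)
})

test_that("KS similarity matches hand-computed CDF gaps and stats::ks.test", {
  expect_equal(ks_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ks_similarity(rep(10, 5), rep(30, 7)), 0)
  # uniform on {10, 20} vs point mass at 20: max CDF gap is 0.5
  expect_equal(ks_similarity(c(10, 20), c(20, 20)), 0.5)
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(60, mean = runif(1, 0, 2))
    expect_equal(1 - ks_similarity(a, b),
                 unname(stats::ks.test(a, b)$statistic))
  }
})

test_that("similarity is scale-invariant and bounded in [0, 1]", {
  set.seed(2)
  sig <- tibble::tibble(
    ant_id = rep(sprintf("a%d", 1:6), each = 30),
    t = rep(1:30, 6),
    dist = abs(rnorm(180, rep(c(10, 10, 40, 40, 80, 80), each = 30), 5)))
  net <- build_similarity_network(sig)
  w <- net$weights[upper.tri(net$weights)]
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(sum(!is.na(net$weights)) / 2, choose(6, 2))
  net2 <- build_similarity_network(dplyr::mutate(sig, dist = 2 * dist))
  expect_equal(net2$weights, net$weights)
  # pairwise entries agree with the scalar operation
  expect_equal(net$weights["a1", "a3"],
               ks_similarity(sig$dist[sig$ant_id == "a1"],
                             sig$dist[sig$ant_id == "a3"]))
})

test_that("Louvain detection matches exhaustive modularity maximization", {
  net <- block_network(c(4, 4), within = 0.9, between = 0.1)
  part <- detect_groups(net, seed = 1)
  oracle <- oracle_best_partition(net$weights)
  expect_equal(label_agreement(part$group, oracle$membership), 1)
  expect_equal(attr(part, "modularity"), oracle$modularity, tolerance = 1e-9)
  expect_equal(sort(unique(part$group)), c(1, 2))
  # groups are ordered by mean entrance distance
  mean_by_group <- tapply(part$mean_dist, part$group, mean)
  expect_true(all(diff(mean_by_group) > 0))

  # equal-weight complete graph: no split beats the single group
  net_flat <- block_network(c(6), within = 0.5, between = 0.5)
  part_flat <- detect_groups(net_flat, seed = 1)
  expect_equal(unique(part_flat$group), 1L)
  oracle_flat <- oracle_best_partition(net_flat$weights)
  expect_lte(oracle_flat$modularity, attr(part_flat, "modularity") + 1e-9)
})

test_that("detection is invariant to node relabelling and bounded by 1..n", {
  net <- block_network(c(3, 5), within = 0.85, between = 0.05)
  part <- detect_groups(net, seed = 3)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  net_p <- net
  net_p$weights <- net$weights[perm, perm]
  net_p$ants <- net$ants[perm, ]
  part_p <- detect_groups(net_p, seed = 3)
  m <- match(part$ant_id, part_p$ant_id)
  expect_equal(label_agreement(part$group, part_p$group[m]), 1)
  expect_gte(min(part$group), 1)
  expect_lte(dplyr::n_distinct(part$group), nrow(net$ants))
})

test_that("a single ant forms a single group", {
  net1 <- structure(list(
    ants = tibble::tibble(ant_id = "a01", mean_dist = 5, n_samples = 10L),
    weights = matrix(NA_real_, 1, 1, dimnames = list("a01", "a01"))),
    class = "similarity_network")
  part <- detect_groups(net1, seed = 1)
  expect_equal(part$group, 1L)
})

test_that("outside-only ants are appended as group 0", {
  net <- block_network(c(4, 4), within = 0.9, between = 0.1)
  part <- detect_groups(net, seed = 1, outside_ants = c("z1", "z2"))
  expect_equal(part$group[part$ant_id %in% c("z1", "z2")], c(0L, 0L))
  expect_equal(sum(part$group == 0), 2)
})

test_that("the smaller-group overlap rule flags exactly the right ants", {
  # reference: {1,2,3,4} {5,6,7,8}; replicate moves ant 4 across
  ref <- c(1, 1, 1, 1, 2, 2, 2, 2)
  new <- c(1, 1, 1, 2, 2, 2, 2, 2)
  ch <- antnest:::changed_ants(ref, new)
  # ant 4: smaller group is its replicate... reference group {1,2,3,4} vs
  # replicate group {4,5,...}: sizes 4 and 5; of the 3 ants it was grouped
  # with in the smaller (reference) group, none are in the larger -> changed
  expect_true(ch[4])
  expect_false(any(ch[-4]))
  # identical partitions never flag anyone
  expect_false(any(antnest:::changed_ants(ref, ref)))
  # singleton groups can never be flagged (no groupmates)
  expect_false(antnest:::changed_ants(c(1, 2, 2), c(2, 2, 1))[1])
})

test_that("perturbation leaves well-separated groups essentially intact", {
  net <- block_network(c(6, 6), within = 0.95, between = 0.02)
  ref <- detect_groups(net, seed = 1)
  res <- perturb_and_score(net, ref, n_reps = 200, seed = 11)
  expect_lt(res$mean_changed_fraction, 0.05)
  expect_error(perturb_and_score(net, ref, n_reps = 0), "n_reps")
  # a single reference group cannot change under the matching rule
  net_flat <- block_network(c(5), within = 0.6, between = 0.6)
  ref_flat <- detect_groups(net_flat, seed = 1)
  res_flat <- perturb_and_score(net_flat, ref_flat, n_reps = 50, seed = 2)
  expect_equal(res_flat$max_changed_fraction, 0)
})

test_that("group consistency recovers perfect, inverted, and null orderings", {
  p1 <- tibble::tibble(ant_id = sprintf("a%02d", 1:12),
                       group = rep(1:3, each = 4))
  expect_equal(group_consistency(p1, p1, n_perm = 500, seed = 1)$rho, 1)
  p_inv <- dplyr::mutate(p1, group = 4L - group)
  expect_equal(group_consistency(p1, p_inv, n_perm = 500, seed = 1)$rho, -1)
  # independent random labels: small correlation, p roughly uniform
  set.seed(33)
  rhos <- numeric(20); ps <- numeric(20)
  for (i in 1:20) {
    pa <- tibble::tibble(ant_id = sprintf("a%02d", 1:80),
                         group = sample(0:3, 80, replace = TRUE))
    pb <- dplyr::mutate(pa, group = sample(group))
    gc <- group_consistency(pa, pb, n_perm = 400, seed = i)
    rhos[i] <- gc$rho; ps[i] <- gc$p_value
  }
  expect_true(all(abs(rhos) < 0.3))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(group_consistency(p1[1:2, ], p1[1:2, ]), "3 shared")
})

test_that("ants missing from either treatment drop out before correlating", {
  p1 <- tibble::tibble(ant_id = c("a", "b", "c", "d"), group = c(1, 1, 2, 2))
  p2 <- tibble::tibble(ant_id = c("a", "b", "c", "x"), group = c(1, 1, 2, 2))
  gc <- group_consistency(p1, p2, n_perm = 200, seed = 1)
  expect_equal(gc$n_ants, 3L)
})
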