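# Shared fixtures, built in code.

# small two-chamber nest (chambers 20 x 16 mm, 3 mm openings) used where a
# fine-grid oracle must stay cheap
small_two_chamber <- function(res_gap = 2) {
  nest_geometry(
    chambers = tibble::tibble(x0 = c(0, 20 + res_gap), y0 = -8,
                              width = 20, height = 16),
    openings = tibble::tibble(a = c(1L, 1L), b = c(0L, 2L), center = 0,
                              width = 3, side = c("left", NA)),
    corridor_length = res_gap
  )
}

small_four_chamber <- function() {
  nest_four_chamber(n_chambers = 4, width = 16, height = 10,
                    entrance_width = 3, opening_width = 3, corridor_length = 2)
}

# a stationary track for one ant
fixed_track <- function(ant_id, x, y, t_max = 10, presence = "in_nest") {
  tibble::tibble(ant_id = ant_id, t = 0:t_max, x = x, y = y,
                 presence = presence)
}

# block-structured similarity network: `sizes` groups, given within/between
# weights; returns a similarity_network object
block_network <- function(sizes, within, between, mean_dists = NULL) {
  n <- sum(sizes)
  ids <- sprintf("a%02d", seq_len(n))
  grp <- rep(seq_along(sizes), sizes)
  W <- matrix(between, n, n, dimnames = list(ids, ids))
  for (g in seq_along(sizes)) {
    W[grp == g, grp == g] <- within
  }
  diag(W) <- NA
  if (is.null(mean_dists)) mean_dists <- grp * 10
  structure(list(
    ants = tibble::tibble(ant_id = ids, mean_dist = mean_dists,
                          n_samples = 100L),
    weights = W
  ), class = "similarity_network")
}

empty_events <- function() {
  tibble::tibble(ant_i = character(), ant_j = character(),
                 start = numeric(), end = numeric())
}
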