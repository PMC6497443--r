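# Track preprocessing: clock alignment across camera segments, optional
# pixel-to-mm conversion, projection of stray points, and gap interpolation,
# producing one row per ant per second over the whole recording.
#
# Track tables are long tibbles with columns:
#   ant_id (chr), t (int s), x, y (mm), presence ("in_nest"|"outside"|"imputed")
# Outside seconds carry NA coordinates.

PRESENCE_LEVELS <- c("in_nest", "outside", "imputed")

#' Map per-segment local times to the global recording clock
#'
#' Continuous recordings arrive as consecutive video segments from cameras
#' whose nominal segment lengths differ (17 min 35 s, or 26 min ~4.5 s for the
#' silver model which drifts by half a second per video, corrected by
#' subtracting one second from every second silver segment). Segment start
#' times on the global clock are the cumulative corrected lengths plus any
#' stated inter-camera start offset.
#'
#' @param segments Data frame with one row per video segment in order:
#'   `camera` (`"hero3"` or `"hero3_silver"`), `nominal_length` (s; defaults
#'   1055 and 1564.5 by camera when NA or absent), optional `start_offset`
#'   (s, added to this and all later segments; default 0).
#' @param segment Integer vector: which segment each observation came from.
#' @param local_time Numeric vector of times within that segment (s).
#' @return Numeric vector of global times (s).
#' @export
align_clocks <- function(segments, segment, local_time) {
  segments <- as_tibble(segments)
  n <- nrow(segments)
  stopifnot(n >= 1, all(segment >= 1), all(segment <= n))
  if (!"nominal_length" %in% names(segments)) segments$nominal_length <- NA_real_
  if (!"start_offset" %in% names(segments)) segments$start_offset <- 0
  segments$start_offset[is.na(segments$start_offset)] <- 0
  default_len <- c(hero3 = 1055, hero3_silver = 1564.5)
  len <- segments$nominal_length
  len[is.na(len)] <- default_len[segments$camera[is.na(len)]]
  if (any(is.na(len))) abort("unknown camera model and no nominal_length given")
  # the silver model drifts half a second per video; rounded to whole
  # seconds, every second silver video (and everything after it) is shifted
  # back by one second
  silver <- segments$camera == "hero3_silver"
  correction <- silver & (cumsum(silver) %% 2 == 0)
  starts <- cumsum(c(0, head(len, -1))) + cumsum(segments$start_offset) -
    cumsum(correction)
  if (n > 1 && any(diff(starts) <= 0)) {
    abort("corrected segments overlap", class = "antnest_alignment_error")
  }
  starts[segment] + local_time
}

#' Fill missing seconds of a track by linear interpolation
#'
#' Ants moving between chambers drop out of view for a few seconds; those
#' gaps are filled by linear interpolation between the flanking observed
#' positions, with any interpolated point that falls outside the nest
#' projected back in. Interpolated rows are flagged `presence = "imputed"`.
#' Spells flagged `"outside"` (foraging trips) are never interpolated across.
#'
#' @param track Tibble with columns `ant_id`, `t`, `x`, `y`, `presence` for a
#'   single ant; missing seconds may be absent rows or NA positions.
#' @param nest A [nest_geometry()].
#' @param t_range Integer range of seconds the track should span (default the
#'   observed range). Gaps at the boundary are trimmed with a warning.
#' @return Complete track tibble, one row per second of `t_range`.
#' @export
interpolate_gaps <- function(track, nest, t_range = NULL) {
  track <- as_tibble(track)
  stopifnot(length(unique(track$ant_id)) == 1)
  if (is.null(t_range)) t_range <- range(track$t)
  full_t <- seq(t_range[1], t_range[2])
  out <- tibble(ant_id = track$ant_id[1], t = full_t) %>%
    left_join(track, by = c("ant_id", "t"))
  known <- !is.na(out$x) | (!is.na(out$presence) & out$presence == "outside")
  obs <- which(!is.na(out$x))
  if (!length(obs)) abort("track has no observed positions")
  if (obs[1] > 1 || max(which(known)) < length(full_t)) {
    first_known <- min(which(known)); last_known <- max(which(known))
    if (first_known > 1 || last_known < length(full_t)) {
      warn("trimming unobserved seconds at the track boundary")
      out <- out[seq(first_known, last_known), ]
      known <- known[seq(first_known, last_known)]
    }
  }
  miss <- which(is.na(out$x) & (is.na(out$presence) | out$presence != "outside"))
  if (length(miss)) {
    obs <- which(!is.na(out$x))
    # interpolate only gaps flanked by observed in-nest positions with no
    # outside spell in between
    xi <- approx(out$t[obs], out$x[obs], xout = out$t[miss])$y
    yi <- approx(out$t[obs], out$y[obs], xout = out$t[miss])$y
    ok <- !is.na(xi)
    proj <- project_into_nest(xi[ok], yi[ok], nest)
    out$x[miss[ok]] <- proj$x
    out$y[miss[ok]] <- proj$y
    out$presence[miss[ok]] <- "imputed"
  }
  out$presence[is.na(out$presence) & !is.na(out$x)] <- "in_nest"
  out$presence[is.na(out$presence)] <- "outside"
  out
}

#' Preprocess a raw track table into a complete per-second table
#'
#' Applies, in order: optional clock alignment, optional pixel-to-mm affine
#' conversion, projection of out-of-nest points onto the walkable region, and
#' per-ant gap interpolation over the full recording window.
#'
#' @param tracks Tibble with columns `ant_id`, `t`, `x`, `y` and optionally
#'   `presence`; coordinates in mm, or in pixels when `transform` is given.
#' @param nest A [nest_geometry()].
#' @param transform Optional [fit_affine()] result applied to `x`, `y`.
#' @param duration_s Recording duration; output covers t = 0 ... `duration_s`.
#' @return Complete track tibble (one row per ant per second).
#' @export
preprocess_tracks <- function(tracks, nest, transform = NULL,
                              duration_s = RECORDING_DURATION_S) {
  tracks <- as_tibble(tracks)
  if (!"presence" %in% names(tracks)) tracks$presence <- NA_character_
  if (!is.null(transform)) {
    keep <- !is.na(tracks$x)
    mm <- apply_affine(cbind(tracks$x[keep], tracks$y[keep]), transform)
    tracks$x[keep] <- mm$x; tracks$y[keep] <- mm$y
  }
  keep <- !is.na(tracks$x)
  proj <- project_into_nest(tracks$x[keep], tracks$y[keep], nest)
  tracks$x[keep] <- proj$x; tracks$y[keep] <- proj$y
  tracks %>%
    group_by(.data$ant_id) %>%
    dplyr::group_modify(~ interpolate_gaps(
      mutate(.x, ant_id = .y$ant_id), nest,
      t_range = c(0L, as.integer(duration_s))
    ) %>% select(-"ant_id")) %>%
    ungroup() %>%
    arrange(.data$ant_id, .data$t)
}

#' Read / write track and trophallaxis event tables
#'
#' Delimited-text I/O for the two tabular formats used throughout: track
#' tables (`ant_id, t, x, y, presence`) and event tables
#' (`ant_i, ant_j, start, end`), both with a header row.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    ant_id = readr::col_character(),
                    t = readr::col_integer(),
                    x = readr::col_double(),
                    y = readr::col_double(),
                    presence = readr::col_character()
                  ))
}

#' @rdname read_tracks
#' @param tracks Track tibble.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname read_tracks
#' @export
read_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    ant_i = readr::col_character(),
                    ant_j = readr::col_character(),
                    start = readr::col_double(),
                    end = readr::col_double()
                  ))
}

#' @rdname read_tracks
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Validate a trophallaxis event table
#'
#' Checks the dyadic event invariants: no self-pairings, durations of at
#' least the minimum recordable length (2 s), and starts within the recording
#' window.
#'
#' @param events Tibble with columns `ant_i`, `ant_j`, `start`, `end`.
#' @param duration_s Recording duration (s).
#' @param min_duration Minimum event duration (s, default 2).
#' @return The validated tibble, invisibly; errors on violation.
#' @export
validate_events <- function(events, duration_s = RECORDING_DURATION_S,
                            min_duration = 2) {
  events <- as_tibble(events)
  if (any(events$ant_i == events$ant_j)) {
    abort("self-paired trophallaxis event", class = "antnest_event_error")
  }
  if (any(events$end - events$start < min_duration)) {
    abort(sprintf("event shorter than %g s", min_duration),
          class = "antnest_event_error")
  }
  if (any(events$start < 0 | events$start > duration_s)) {
    abort("event starts outside the recording window",
          class = "antnest_event_error")
  }
  invisible(events)
}
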