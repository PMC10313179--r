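#' Per-frame active-event counts
#'
#' Number of events of one type active at each frame (an event covers the
#' half-open interval `[start_frame, end_frame)`).
#'
#' @param events An events tibble.
#' @param frames Integer vector of frames to count over.
#' @param type Event type to count (default `"chase"`).
#' @return Integer vector aligned with `frames`.
#' @export
count_events_per_frame <- function(events, frames, type = "chase") {
  ev <- events[events$type == type, , drop = FALSE]
  counts <- integer(length(frames))
  if (nrow(ev) == 0) return(counts)
  for (i in seq_len(nrow(ev))) {
    sel <- frames >= ev$start_frame[i] & frames < ev$end_frame[i]
    counts[sel] <- counts[sel] + 1L
  }
  counts
}

#' Compute the full metrics report for one arena recording
#'
#' Bundles every quantitative readout into one object: the per-frame
#' behavior indexes (chasing, singing, chaining), the time-based chaining
#' index, per-fly courtship indexes, social space, encounter count,
#' foraging visits/dwell (when the config has a food region), and
#' locomotion states.
#'
#' @param tracks A tracks tibble.
#' @param events An events tibble.
#' @param chains A chain-record tibble ([detect_chaining()]).
#' @param config An [arena_config()].
#' @param params A [metric_params()].
#' @return An object of class `fly_metrics`; see [tidy.fly_metrics()] and
#'   [glance.fly_metrics()].
#' @export
compute_metrics <- function(tracks, events, chains, config,
                            params = metric_params()) {
  frames <- seq(min(tracks$frame), max(tracks$frame))
  n <- config$n_flies

  chase_bd <- count_events_per_frame(events, frames, "chase")
  sing_bd <- count_events_per_frame(events, frames, "wing_ext")
  chain_bd <- chains$chain_count[match(frames, chains$frame)]
  chain_bd[is.na(chain_bd)] <- 0L

  idx_chase <- behavior_index(chase_bd, n, "chase", frames = frames)
  idx_sing <- behavior_index(sing_bd, n, "sing", frames = frames)
  idx_chain <- behavior_index(chain_bd, n, "chain", frames = frames)

  ids <- sort(unique(tracks$track_id))
  courting <- courting_flags(events, frames, ids)
  ci <- vapply(ids, function(id) courtship_index(courting[, as.character(id)]),
               0)

  ss <- social_space(tracks, config, params)
  ss_mean <- dplyr::summarise(dplyr::group_by(ss, .data$track_id),
                              nn_mm = mean(.data$nn_mm),
                              n_neighbors = mean(.data$n_neighbors),
                              .groups = "drop")

  enc <- count_encounters(tracks, config, params)

  forage <- if (!is.null(config$food_roi)) {
    foraging_metrics(tracks, config, params)
  } else NULL

  loco <- locomotion_summary(locomotion_classify(tracks, config, params))

  structure(list(
    n_flies = n,
    n_frames = length(frames),
    fps = config$fps,
    index_chase = idx_chase,
    index_sing = idx_sing,
    index_chain = idx_chain,
    chaining_index_time = chaining_index_time(chains),
    courtship_index = tibble(track_id = ids, ci = ci),
    social_space = ss_mean,
    encounters = as.integer(enc),
    foraging = forage,
    locomotion = loco
  ), class = "fly_metrics")
}

# frames x ids logical matrix: is the fly the actor of any event that frame
courting_flags <- function(events, frames, ids) {
  m <- matrix(FALSE, length(frames), length(ids),
              dimnames = list(NULL, as.character(ids)))
  if (nrow(events) == 0) return(m)
  for (i in seq_len(nrow(events))) {
    col <- match(events$actor_id[i], ids)
    if (is.na(col)) next
    sel <- frames >= events$start_frame[i] & frames < events$end_frame[i]
    m[sel, col] <- TRUE
  }
  m
}

#' @export
print.fly_metrics <- function(x, ...) {
  cat("<fly_metrics>", x$n_flies, "flies,", x$n_frames, "frames at",
      x$fps, "fps\n")
  cat(sprintf("  chasing index:       %6.2f %%\n", x$index_chase$index))
  cat(sprintf("  singing index:       %6.2f %%\n", x$index_sing$index))
  cat(sprintf("  chaining index:      %6.2f %%\n", x$index_chain$index))
  cat(sprintf("  chaining (time):     %6.2f %%\n", x$chaining_index_time))
  cat(sprintf("  mean courtship idx:  %6.2f %%\n",
              mean(x$courtship_index$ci, na.rm = TRUE)))
  cat(sprintf("  mean NN distance:    %6.2f mm\n",
              mean(x$social_space$nn_mm)))
  cat(sprintf("  encounters:          %6d\n", x$encounters))
  if (!is.null(x$foraging)) {
    cat(sprintf("  foraging visits:     %6d (total)\n", sum(x$foraging$visits)))
  }
  invisible(x)
}

#' Tidy a metrics report into a per-fly table
#'
#' @param x A `fly_metrics` object.
#' @param ... Unused.
#' @return A tibble with one row per fly: courtship index, mean
#'   nearest-neighbor distance and neighbor count, foraging visits/dwell
#'   (`NA` without a food region) and locomotion state fractions.
#' @method tidy fly_metrics
#' @export
tidy.fly_metrics <- function(x, ...) {
  out <- dplyr::left_join(x$courtship_index, x$social_space, by = "track_id")
  if (!is.null(x$foraging)) {
    out <- dplyr::left_join(out, x$foraging, by = "track_id")
  } else {
    out$visits <- NA_integer_
    out$dwell_s <- NA_real_
  }
  loco_wide <- tidyr::pivot_wider(
    x$locomotion[, c("track_id", "state", "fraction_pct")],
    names_from = "state", values_from = "fraction_pct",
    names_prefix = "pct_")
  dplyr::left_join(out, loco_wide, by = "track_id")
}

#' One-row summary of a metrics report
#'
#' @param x A `fly_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the group-level readouts.
#' @method glance fly_metrics
#' @export
glance.fly_metrics <- function(x, ...) {
  tibble(
    n_flies = x$n_flies,
    n_frames = x$n_frames,
    chasing_index = x$index_chase$index,
    singing_index = x$index_sing$index,
    chaining_index = x$index_chain$index,
    chaining_index_time = x$chaining_index_time,
    mean_ci = mean(x$courtship_index$ci, na.rm = TRUE),
    mean_nn_mm = mean(x$social_space$nn_mm),
    mean_neighbors = mean(x$social_space$n_neighbors),
    encounters = x$encounters,
    total_foraging_visits = if (is.null(x$foraging)) NA_integer_ else
      sum(x$foraging$visits)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
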