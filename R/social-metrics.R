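#' Metric parameters
#'
#' Thresholds for the descriptive social/locomotion readouts. All distances
#' are in millimetres and are converted to pixels through the arena scale.
#'
#' @param neighbor_radius_mm Radius for the neighbor count. Default 5.
#' @param encounter_radius_mm Pair gap defining a social encounter.
#'   Default 5.
#' @param encounter_min_frames Minimum duration of an encounter bout.
#'   Default 15.
#' @param forage_min_frames Minimum in-ROI run counting as a foraging
#'   visit. Default 30 (1 s at 30 fps).
#' @param forage_gap_frames Two in-ROI runs separated by fewer than this
#'   many frames outside merge into one visit. Default 15.
#' @param rest_max_mm_s Speed at or below which a fly is resting.
#'   Default 0.5.
#' @param walk_max_mm_s Speed at or below which a moving fly is walking
#'   (faster is running). Default 10.
#' @param jump_min_body_lengths_per_frame Single-frame displacement, in
#'   body lengths, at or above which the frame is a jump. Default 4.
#' @return A list of class `metric_params`.
#' @export
metric_params <- function(neighbor_radius_mm = 5,
                          encounter_radius_mm = 5,
                          encounter_min_frames = 15,
                          forage_min_frames = 30,
                          forage_gap_frames = 15,
                          rest_max_mm_s = 0.5,
                          walk_max_mm_s = 10,
                          jump_min_body_lengths_per_frame = 4) {
  stopifnot(neighbor_radius_mm > 0, encounter_radius_mm > 0,
            encounter_min_frames > 0, forage_min_frames > 0,
            forage_gap_frames > 0, rest_max_mm_s > 0,
            walk_max_mm_s > rest_max_mm_s,
            jump_min_body_lengths_per_frame > 0)
  structure(list(neighbor_radius_mm = neighbor_radius_mm,
                 encounter_radius_mm = encounter_radius_mm,
                 encounter_min_frames = encounter_min_frames,
                 forage_min_frames = forage_min_frames,
                 forage_gap_frames = forage_gap_frames,
                 rest_max_mm_s = rest_max_mm_s,
                 walk_max_mm_s = walk_max_mm_s,
                 jump_min_body_lengths_per_frame = jump_min_body_lengths_per_frame),
            class = "metric_params")
}

#' Behavior index: Index = B(d) / B(max) x 100
#'
#' Scores a per-frame detected-event count against the maximum possible
#' count for that behavior in a group of N flies: `B(max) = N` for chasing
#' and singing (every fly can act at once) and `B(max) = N - 1` for
#' chaining (a closed ring of N flies yields N - 1 chain events). The index
#' is computed per frame and averaged over frames; the per-frame series is
#' retained for rug plots. Five chases detected in every frame of a 10-fly
#' group give 50%; a full ring gives 100%.
#'
#' @param b_d Per-frame detected event counts (non-negative numeric
#'   vector).
#' @param n_flies Group size N (must be >= 2).
#' @param behavior One of `"chase"`, `"sing"`, `"chain"`.
#' @param frames Optional frame indices for the series (default
#'   `seq_along(b_d) - 1`).
#' @return An object of class `behavior_index` with the mean index (`$index`,
#'   percent), `B(max)`, and the per-frame series; see
#'   [tidy.behavior_index()] and [glance.behavior_index()].
#' @export
behavior_index <- function(b_d, n_flies, behavior = c("chase", "sing", "chain"),
                           frames = NULL) {
  behavior <- match.arg(behavior)
  n_flies <- as.integer(n_flies)
  if (is.na(n_flies) || n_flies < 2L) {
    stop("`n_flies` must be >= 2 (chaining B(max) would be < 1).", call. = FALSE)
  }
  if (length(b_d) == 0) stop("`b_d` must have at least one frame.", call. = FALSE)
  if (any(b_d < 0)) stop("`b_d` must be non-negative.", call. = FALSE)
  b_max <- if (behavior == "chain") n_flies - 1L else n_flies
  if (any(b_d > b_max)) {
    warning(sprintf("%d frame(s) have B(d) > B(max) = %d; capping at B(max)",
                    sum(b_d > b_max), b_max), call. = FALSE)
    b_d <- pmin(b_d, b_max)
  }
  if (is.null(frames)) frames <- seq_along(b_d) - 1L
  series <- tibble(frame = as.integer(frames), b_d = as.numeric(b_d),
                   index = 100 * b_d / b_max)
  structure(list(behavior = behavior, n_flies = n_flies, b_max = b_max,
                 index = mean(series$index), series = series),
            class = "behavior_index")
}

#' @export
print.behavior_index <- function(x, ...) {
  cat(sprintf("<behavior_index> %s: %.2f%% (N = %d, B(max) = %d, %d frames)\n",
              x$behavior, x$index, x$n_flies, x$b_max, nrow(x$series)))
  invisible(x)
}

#' Tidy a behavior index into its per-frame series
#'
#' @param x A [behavior_index()] object.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `b_d`, `index`.
#' @method tidy behavior_index
#' @export
tidy.behavior_index <- function(x, ...) x$series

#' One-row summary of a behavior index
#'
#' @param x A [behavior_index()] object.
#' @param ... Unused.
#' @return A one-row tibble: `behavior`, `n_flies`, `b_max`, `n_frames`,
#'   `index`.
#' @method glance behavior_index
#' @export
glance.behavior_index <- function(x, ...) {
  tibble(behavior = x$behavior, n_flies = x$n_flies, b_max = x$b_max,
         n_frames = nrow(x$series), index = x$index)
}

#' Courtship index
#'
#' CI = the percentage of observed time a fly performed any courtship step.
#'
#' @param courting Logical per-frame flags (TRUE when the fly performs a
#'   courtship step that frame); `NA` frames count as unobserved.
#' @param observed Optional logical vector of observed frames (default:
#'   non-`NA` entries of `courting`).
#' @return CI in percent, or `NA` when no frame was observed.
#' @export
courtship_index <- function(courting, observed = NULL) {
  if (is.null(observed)) observed <- !is.na(courting)
  n_obs <- sum(observed)
  if (n_obs == 0) return(NA_real_)
  100 * sum(courting & observed, na.rm = TRUE) / n_obs
}

#' Time-based chaining index
#'
#' The percentage of observed time during which at least three flies are
#' engaged in courtship, i.e. frames with at least one chain component.
#'
#' @param chains A chain-record tibble ([detect_chaining()]).
#' @param n_frames Total number of observed frames (default
#'   `nrow(chains)`).
#' @return Percent of frames with chaining, or `NA` when `n_frames` is 0.
#' @export
chaining_index_time <- function(chains, n_frames = nrow(chains)) {
  if (n_frames == 0) return(NA_real_)
  100 * sum(chains$chain_count > 0) / n_frames
}

#' Two-choice preference index
#'
#' The percentage of courtship time directed at target A:
#' `100 * frames(A) / (frames(A) + frames(B))`. Frames without courtship do
#' not enter the denominator; a male that never courts has an undefined
#' (missing) preference — never 0.
#'
#' @param target_labels Character per-frame labels in
#'   `c("A", "B", "none")`.
#' @return Preference toward A in percent, or `NA` if no courtship frame
#'   exists.
#' @export
preference_index <- function(target_labels) {
  bad <- setdiff(unique(target_labels), c("A", "B", "none", NA))
  if (length(bad) > 0) {
    stop("target labels must be 'A', 'B' or 'none'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_a <- sum(target_labels == "A", na.rm = TRUE)
  n_b <- sum(target_labels == "B", na.rm = TRUE)
  if (n_a + n_b == 0) return(NA_real_)
  100 * n_a / (n_a + n_b)
}

#' Social space: nearest-neighbor distance and neighbor count
#'
#' For every fly and frame, the distance to its nearest neighbor (in mm)
#' and the number of other flies within `neighbor_radius_mm`.
#'
#' @param tracks A tracks tibble (or any tibble with `frame`, `track_id`,
#'   `cx`, `cy`).
#' @param config An [arena_config()].
#' @param params A [metric_params()].
#' @param frames Optional subset of frames to measure (e.g. after a
#'   settling period); default all frames present.
#' @return A tibble with columns `frame`, `track_id`, `nn_mm`,
#'   `n_neighbors`.
#' @export
social_space <- function(tracks, config, params = metric_params(),
                         frames = NULL) {
  if (!is.null(frames)) tracks <- tracks[tracks$frame %in% frames, , drop = FALSE]
  if (nrow(tracks) == 0) stop("no track points in the requested frames.", call. = FALSE)
  by_f <- split(seq_len(nrow(tracks)), tracks$frame)
  radius_px <- params$neighbor_radius_mm / config$mm_per_px
  out <- lapply(by_f, function(idx) {
    n <- length(idx)
    if (n < 2) stop("social_space needs >= 2 flies per frame.", call. = FALSE)
    d <- as.matrix(stats::dist(cbind(tracks$cx[idx], tracks$cy[idx])))
    diag(d) <- Inf
    tibble(frame = tracks$frame[idx],
           track_id = tracks$track_id[idx],
           nn_mm = unname(apply(d, 1, min)) * config$mm_per_px,
           n_neighbors = as.integer(unname(rowSums(d <= radius_px))))
  })
  dplyr::bind_rows(out)
}

#' Count pairwise social encounters
#'
#' An encounter is a maximal run of at least `encounter_min_frames`
#' consecutive frames during which one pair's centroid gap stays at or
#' below `encounter_radius_mm`.
#'
#' @param tracks A tracks tibble.
#' @param config An [arena_config()].
#' @param params A [metric_params()].
#' @return The total number of encounters (integer), with attribute
#'   `bouts`: a tibble of `id_a`, `id_b`, `start_frame`, `end_frame`
#'   (half-open).
#' @export
count_encounters <- function(tracks, config, params = metric_params()) {
  tm <- track_matrices(tracks)
  n_id <- length(tm$ids)
  if (n_id < 2) stop("count_encounters needs >= 2 tracks.", call. = FALSE)
  radius_px <- params$encounter_radius_mm / config$mm_per_px
  bouts <- list()
  for (a in seq_len(n_id - 1)) {
    for (b in seq(a + 1, n_id)) {
      gap <- sqrt((tm$cx[, a] - tm$cx[, b])^2 + (tm$cy[, a] - tm$cy[, b])^2)
      close_f <- tm$frames[which(!is.na(gap) & gap <= radius_px)]
      runs <- frames_to_runs(close_f, gap = 0)
      runs <- runs[runs$len >= params$encounter_min_frames, , drop = FALSE]
      if (nrow(runs) > 0) {
        bouts[[length(bouts) + 1L]] <- tibble(
          id_a = tm$ids[a], id_b = tm$ids[b],
          start_frame = as.integer(runs$start),
          end_frame = as.integer(runs$end + 1L))
      }
    }
  }
  bouts <- if (length(bouts) > 0) dplyr::bind_rows(bouts) else
    tibble(id_a = integer(), id_b = integer(),
           start_frame = integer(), end_frame = integer())
  structure(nrow(bouts), bouts = bouts)
}

#' Foraging visits and dwell time
#'
#' A visit is a maximal run of at least `forage_min_frames` frames inside
#' the food ROI; in-ROI runs separated by fewer than `forage_gap_frames`
#' frames outside are merged before the length test. Dwell is the total
#' in-ROI time in seconds regardless of visit structure, so a brief entry
#' too short to count as a visit still contributes dwell.
#'
#' @param tracks A tracks tibble.
#' @param config An [arena_config()] with a `food_roi`.
#' @param params A [metric_params()].
#' @return A tibble with columns `track_id`, `visits`, `dwell_s`.
#' @export
foraging_metrics <- function(tracks, config, params = metric_params()) {
  if (is.null(config$food_roi)) {
    stop("foraging_metrics requires a food_roi in the config.", call. = FALSE)
  }
  inside <- in_food_roi(tracks$cx, tracks$cy, config)
  ids <- sort(unique(tracks$track_id))
  out <- lapply(ids, function(id) {
    sel <- tracks$track_id == id
    fr <- sort(tracks$frame[sel & inside])
    runs <- frames_to_runs(fr, gap = params$forage_gap_frames - 1L)
    tibble(track_id = id,
           visits = sum(runs$len >= params$forage_min_frames),
           dwell_s = length(fr) / config$fps)
  })
  dplyr::bind_rows(out)
}

#' Classify locomotion states
#'
#' Speed at frame f is the centroid displacement from f to f + 1 (the last
#' frame reuses the preceding step), converted to mm/s. A frame whose
#' single-frame displacement reaches
#' `jump_min_body_lengths_per_frame x body_length_mm` is `jumping`;
#' otherwise the frame is `resting` (speed <= `rest_max_mm_s`), `walking`
#' (<= `walk_max_mm_s`) or `running`. Coasting frames (unobserved) are
#' `resting`. Events are maximal same-state runs.
#'
#' @param tracks A tracks tibble.
#' @param config An [arena_config()].
#' @param params A [metric_params()].
#' @return A tibble with columns `frame`, `track_id`, `speed_mm_s`,
#'   `state`.
#' @seealso [locomotion_summary()]
#' @export
locomotion_classify <- function(tracks, config, params = metric_params()) {
  tm <- track_matrices(tracks)
  if (length(tm$frames) < 2) stop("locomotion needs >= 2 frames.", call. = FALSE)
  kin <- step_kinematics(tm$cx, tm$cy)
  disp_mm <- kin$disp * config$mm_per_px
  speed <- disp_mm * config$fps
  jump_mm <- params$jump_min_body_lengths_per_frame * config$body_length_mm
  state <- matrix("walking", nrow(speed), ncol(speed))
  state[speed <= params$rest_max_mm_s] <- "resting"
  state[speed > params$walk_max_mm_s] <- "running"
  state[disp_mm >= jump_mm] <- "jumping"
  out <- tibble(
    frame = rep(tm$frames, times = length(tm$ids)),
    track_id = rep(tm$ids, each = length(tm$frames)),
    speed_mm_s = as.vector(speed),
    state = as.vector(state)
  )
  out <- out[!is.na(out$speed_mm_s), , drop = FALSE]
  # coasting frames inherit resting
  if ("observed" %in% names(tracks)) {
    key <- paste(tracks$frame, tracks$track_id)
    coasting <- key[!tracks$observed]
    if (length(coasting) > 0) {
      out$state[paste(out$frame, out$track_id) %in% coasting] <- "resting"
    }
  }
  dplyr::arrange(out, .data$track_id, .data$frame)
}

LOCOMOTION_STATES <- c("resting", "walking", "running", "jumping")

#' Per-fly locomotion summary
#'
#' @param locomotion Output of [locomotion_classify()].
#' @return A tibble with one row per `(track_id, state)` for all four
#'   states: `n_frames`, `fraction_pct` (per-fly fractions sum to 100) and
#'   `n_events` (maximal same-state runs).
#' @export
locomotion_summary <- function(locomotion) {
  ids <- sort(unique(locomotion$track_id))
  out <- lapply(ids, function(id) {
    sub <- locomotion[locomotion$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    total <- nrow(sub)
    runs <- rle(sub$state)
    tibble(track_id = id, state = LOCOMOTION_STATES,
           n_frames = unname(vapply(LOCOMOTION_STATES,
                                    function(s) sum(sub$state == s), 0L)),
           fraction_pct = unname(vapply(LOCOMOTION_STATES,
                                        function(s) 100 * sum(sub$state == s) / total, 0)),
           n_events = unname(vapply(LOCOMOTION_STATES,
                                    function(s) sum(runs$values == s), 0L)))
  })
  dplyr::bind_rows(out)
}
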