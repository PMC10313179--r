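#' Kinematic chase-classifier parameters
#'
#' Thresholds for classifying "following" (chase) behavior from
#' trajectories alone, used when no detector-labeled chase boxes are
#' available. An ordered pair (actor, target) is instantaneously chasing
#' when the actor-to-target gap is at most `d_max_mm`, the actor moves at
#' `v_min_mm_s` or faster, and the actor's heading is within
#' `align_max_rad` of the bearing to the target.
#'
#' @param d_max_mm Maximum actor-to-target centroid gap, mm. Default 5.
#' @param v_min_mm_s Minimum actor speed, mm/s. Default 2.
#' @param align_max_rad Maximum |heading - bearing| angle, radians.
#'   Default pi/6 (30 degrees).
#' @param min_frames Minimum sustained duration of an episode, frames.
#'   Default 15 (0.5 s at 30 fps).
#' @param merge_gap_frames Maximum gap bridged between episodes, frames.
#'   Default 5.
#' @return A list of class `chase_params`.
#' @export
chase_params <- function(d_max_mm = 5, v_min_mm_s = 2,
                         align_max_rad = pi / 6, min_frames = 15,
                         merge_gap_frames = 5) {
  stopifnot(d_max_mm > 0, v_min_mm_s > 0, align_max_rad > 0,
            align_max_rad < pi, min_frames > 0, merge_gap_frames > 0)
  structure(list(d_max_mm = d_max_mm, v_min_mm_s = v_min_mm_s,
                 align_max_rad = align_max_rad, min_frames = min_frames,
                 merge_gap_frames = merge_gap_frames),
            class = "chase_params")
}

# wrap angle difference into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# per-track frame-aligned matrices (frames x ids); NA where a track has no
# point at a frame
track_matrices <- function(tracks) {
  ids <- sort(unique(tracks$track_id))
  frames <- seq(min(tracks$frame), max(tracks$frame))
  fi <- match(tracks$frame, frames)
  ti <- match(tracks$track_id, ids)
  mk <- function(v) {
    m <- matrix(NA_real_, nrow = length(frames), ncol = length(ids))
    m[cbind(fi, ti)] <- v
    m
  }
  list(ids = ids, frames = frames,
       cx = mk(tracks$cx), cy = mk(tracks$cy), heading = mk(tracks$heading))
}

# per-frame direction of motion and speed (px/frame); at frame f the step
# f -> f+1, last frame reuses the preceding step
step_kinematics <- function(cx, cy) {
  nf <- nrow(cx)
  dx <- rbind(cx[-1, , drop = FALSE] - cx[-nf, , drop = FALSE],
              if (nf > 1) cx[nf, ] - cx[nf - 1, ] else rep(0, ncol(cx)))
  dy <- rbind(cy[-1, , drop = FALSE] - cy[-nf, , drop = FALSE],
              if (nf > 1) cy[nf, ] - cy[nf - 1, ] else rep(0, ncol(cy)))
  disp <- sqrt(dx^2 + dy^2)
  vdir <- atan2(-dy, dx)          # y-up mathematical frame
  vdir[disp == 0] <- NA_real_     # no direction when stationary
  list(disp = disp, vdir = vdir)
}

#' Classify chases kinematically from trajectories
#'
#' Evaluates the instantaneous chase predicate (see [chase_params()]) for
#' every ordered fly pair and frame, enforces that a fly is the actor of at
#' most one chase per frame (conflicts resolved by smallest gap, then
#' smallest alignment angle), bridges interruptions of up to
#' `merge_gap_frames`, and keeps maximal runs of at least `min_frames`
#' frames as chase events. Frames where a track has no heading use the
#' direction of motion instead; a stationary, heading-less frame is
#' unclassifiable.
#'
#' @param tracks A tracks tibble (with `heading` where available).
#' @param config An [arena_config()].
#' @param params A [chase_params()].
#' @return An events tibble (`type = "chase"`, `source = "kinematic"`),
#'   half-open intervals `[start_frame, end_frame)`.
#' @export
classify_kinematic_chases <- function(tracks, config, params = chase_params()) {
  if (length(unique(tracks$track_id)) < 2) return(empty_events())
  tm <- track_matrices(tracks)
  kin <- step_kinematics(tm$cx, tm$cy)
  nf <- length(tm$frames)
  n_id <- length(tm$ids)
  speed_mm_s <- kin$disp * config$mm_per_px * config$fps
  dir <- ifelse(is.na(tm$heading), kin$vdir, tm$heading)

  pairs <- expand.grid(a = seq_len(n_id), t = seq_len(n_id))
  pairs <- pairs[pairs$a != pairs$t, , drop = FALSE]
  np <- nrow(pairs)
  gap_mm <- matrix(NA_real_, nf, np)
  align <- matrix(NA_real_, nf, np)
  ok <- matrix(FALSE, nf, np)
  for (p in seq_len(np)) {
    a <- pairs$a[p]; t <- pairs$t[p]
    gx <- tm$cx[, t] - tm$cx[, a]
    gy <- tm$cy[, t] - tm$cy[, a]
    gap_mm[, p] <- sqrt(gx^2 + gy^2) * config$mm_per_px
    bearing <- atan2(-gy, gx)
    align[, p] <- abs(wrap_angle(dir[, a] - bearing))
    ok[, p] <- !is.na(gap_mm[, p]) & !is.na(align[, p]) &
      gap_mm[, p] <= params$d_max_mm &
      speed_mm_s[, a] >= params$v_min_mm_s &
      align[, p] <= params$align_max_rad
  }

  # actor uniqueness: per frame, an actor keeps only its best passing target
  active <- matrix(FALSE, nf, np)
  for (a in seq_len(n_id)) {
    cols <- which(pairs$a == a)
    if (length(cols) == 0) next
    sub_ok <- ok[, cols, drop = FALSE]
    any_ok <- which(rowSums(sub_ok) > 0)
    if (length(any_ok) == 0) next
    g <- gap_mm[any_ok, cols, drop = FALSE]
    al <- align[any_ok, cols, drop = FALSE]
    g[!sub_ok[any_ok, , drop = FALSE]] <- Inf
    # min gap, ties by alignment: lexicographic via small epsilon-free pass
    best <- max.col(-g, ties.method = "first")
    for (r in seq_along(any_ok)) {
      row_g <- g[r, ]
      tied <- which(row_g == row_g[best[r]])
      if (length(tied) > 1) best[r] <- tied[which.min(al[r, tied])]
    }
    active[cbind(any_ok, cols[best])] <- TRUE
  }

  events <- list()
  for (p in seq_len(np)) {
    fr <- which(active[, p])
    if (length(fr) == 0) next
    runs <- frames_to_runs(tm$frames[fr], params$merge_gap_frames)
    runs <- runs[runs$len >= params$min_frames, , drop = FALSE]
    if (nrow(runs) == 0) next
    events[[length(events) + 1L]] <- tibble(
      type = "chase",
      start_frame = as.integer(runs$start),
      end_frame = as.integer(runs$end + 1L),
      actor_id = tm$ids[pairs$a[p]],
      target_id = tm$ids[pairs$t[p]],
      source = "kinematic"
    )
  }
  if (length(events) == 0) return(empty_events())
  out <- dplyr::bind_rows(events)
  dplyr::arrange(out, .data$start_frame, .data$actor_id, .data$type)
}

# collapse a sorted frame vector into maximal runs, bridging gaps of up to
# `gap` missing frames; returns start/end (inclusive) and covered length
frames_to_runs <- function(frames, gap = 0) {
  if (length(frames) == 0) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  brk <- c(0L, which(diff(frames) > gap + 1L), length(frames))
  starts <- frames[brk[-length(brk)] + 1L]
  ends <- frames[brk[-1L]]
  data.frame(start = starts, end = ends, len = ends - starts + 1L)
}

#' Attribute detector-labeled event boxes to tracks
#'
#' Each `chase`/`mount` box is attributed to the two tracks whose body
#' boxes it overlaps most (overlap area as a fraction of the body box);
#' the chase actor is the member whose heading points toward the other.
#' A `wing_ext` box is attributed to the single best-overlapping track,
#' with an optional target: the nearest other fly inside the singer's
#' heading cone (within `params$align_max_rad` and `params$d_max_mm`).
#' Consecutive frames with the same (type, actor, target) merge into one
#' event interval.
#'
#' @param event_detections A detections tibble; rows with labels `chase`,
#'   `wing_ext`, `mount` are used.
#' @param tracks A tracks tibble covering the same frames.
#' @param config An [arena_config()].
#' @param params A [chase_params()] (cone/gap used for wing_ext targets).
#' @return An events tibble with `source = "detector"` and attribute
#'   `dropped_events` counting boxes that overlapped too few tracks.
#' @export
attribute_detector_events <- function(event_detections, tracks, config,
                                      params = chase_params()) {
  ev <- event_detections[event_detections$label %in% c("chase", "wing_ext", "mount"), ,
                         drop = FALSE]
  if (nrow(ev) == 0 || nrow(tracks) == 0) return(empty_events())
  if (!("cx" %in% names(ev))) {
    ev$cx <- ev$x + ev$w / 2
    ev$cy <- ev$y + ev$h / 2
  }
  tr_by_frame <- split(seq_len(nrow(tracks)), tracks$frame)
  dropped <- 0L
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    f <- as.character(ev$frame[i])
    ti <- tr_by_frame[[f]]
    if (is.null(ti)) { dropped <- dropped + 1L; next }
    # overlap area as fraction of each body box
    left <- pmax(ev$x[i], tracks$x[ti])
    right <- pmin(ev$x[i] + ev$w[i], tracks$x[ti] + tracks$w[ti])
    top <- pmax(ev$y[i], tracks$y[ti])
    bottom <- pmin(ev$y[i] + ev$h[i], tracks$y[ti] + tracks$h[ti])
    frac <- pmax(right - left, 0) * pmax(bottom - top, 0) /
      (tracks$w[ti] * tracks$h[ti])
    need <- if (ev$label[i] == "wing_ext") 1L else 2L
    cand <- which(frac > 0)
    if (length(cand) < need) { dropped <- dropped + 1L; next }
    cdist <- sqrt((tracks$cx[ti] - ev$cx[i])^2 + (tracks$cy[ti] - ev$cy[i])^2)
    o <- order(-frac, cdist)
    pick <- o[seq_len(need)]
    if (need == 2L) {
      id1 <- ti[pick[1]]; id2 <- ti[pick[2]]
      # actor: heading points toward the other member
      a12 <- heading_toward(tracks, id1, id2)
      a21 <- heading_toward(tracks, id2, id1)
      if (!is.na(a12) && (is.na(a21) || a12 <= a21)) {
        actor <- id1; target <- id2
      } else if (!is.na(a21)) {
        actor <- id2; target <- id1
      } else {
        actor <- if (tracks$track_id[id1] <= tracks$track_id[id2]) id1 else id2
        target <- if (actor == id1) id2 else id1
      }
      rows[[length(rows) + 1L]] <- list(
        type = ev$label[i], frame = ev$frame[i],
        actor_id = tracks$track_id[actor], target_id = tracks$track_id[target])
    } else {
      actor <- ti[pick[1]]
      target_id <- wing_ext_target(tracks, ti, actor, config, params)
      rows[[length(rows) + 1L]] <- list(
        type = ev$label[i], frame = ev$frame[i],
        actor_id = tracks$track_id[actor], target_id = target_id)
    }
  }
  if (length(rows) == 0) {
    out <- empty_events()
    attr(out, "dropped_events") <- dropped
    return(out)
  }
  df <- dplyr::bind_rows(lapply(rows, as_tibble))
  out <- merge_frame_events(df)
  out$source <- "detector"
  attr(out, "dropped_events") <- dropped
  dplyr::arrange(out, .data$start_frame, .data$actor_id, .data$type)
}

# |angle between row a's heading and the bearing a -> b|; NA if no heading
heading_toward <- function(tracks, row_a, row_b) {
  h <- tracks$heading[row_a]
  if (is.na(h)) return(NA_real_)
  bearing <- atan2(-(tracks$cy[row_b] - tracks$cy[row_a]),
                   tracks$cx[row_b] - tracks$cx[row_a])
  abs(wrap_angle(h - bearing))
}

wing_ext_target <- function(tracks, frame_rows, actor_row, config, params) {
  others <- setdiff(frame_rows, actor_row)
  if (length(others) == 0) return(NA_integer_)
  h <- tracks$heading[actor_row]
  if (is.na(h)) return(NA_integer_)
  gx <- tracks$cx[others] - tracks$cx[actor_row]
  gy <- tracks$cy[others] - tracks$cy[actor_row]
  gap_mm <- sqrt(gx^2 + gy^2) * config$mm_per_px
  ang <- abs(wrap_angle(h - atan2(-gy, gx)))
  qual <- which(ang <= params$align_max_rad & gap_mm <= params$d_max_mm)
  if (length(qual) == 0) return(NA_integer_)
  tracks$track_id[others[qual[which.min(gap_mm[qual])]]]
}

# merge per-frame (type, actor, target) rows into half-open intervals over
# consecutive frames
merge_frame_events <- function(df) {
  df$key <- paste(df$type, df$actor_id, df$target_id, sep = "|")
  out <- list()
  for (k in unique(df$key)) {
    sub <- df[df$key == k, , drop = FALSE]
    runs <- frames_to_runs(sort(unique(sub$frame)), gap = 0)
    out[[length(out) + 1L]] <- tibble(
      type = sub$type[1],
      start_frame = as.integer(runs$start),
      end_frame = as.integer(runs$end + 1L),
      actor_id = as.integer(sub$actor_id[1]),
      target_id = as.integer(sub$target_id[1]),
      source = NA_character_
    )
  }
  dplyr::bind_rows(out)
}

#' Aggregate per-frame chase relations into chaining records
#'
#' Chaining is scored per frame from the directed chase graph (one edge per
#' active chase, actor to target): the weakly connected components with at
#' least two edges — i.e. at least two chase events sharing a structure,
#' which always involves three or more flies — are the chain components,
#' and the per-frame chain count is `B(d) = sum(|component| - 1)` over
#' them. A single isolated chase edge never counts as chaining.
#'
#' @param events An events tibble; rows with `type == "chase"` are used.
#' @param frames Integer vector of frames to score (typically
#'   `seq(0, n_frames - 1)`).
#' @param n_flies Group size N (for the `chain_count <= N - 1` invariant).
#' @return A chain-record tibble: `frame`, `chain_count`, `components`
#'   (list of integer id vectors per frame).
#' @export
detect_chaining <- function(events, frames, n_flies) {
  ch <- events[events$type == "chase", , drop = FALSE]
  frames <- as.integer(frames)
  chain_count <- integer(length(frames))
  components <- rep(list(list()), length(frames))
  if (nrow(ch) > 0) {
    # expand events to per-frame edges
    reps <- ch$end_frame - ch$start_frame
    edge_frame <- rep(ch$start_frame, reps) +
      unlist(lapply(reps, seq_len), use.names = FALSE) - 1L
    edge_actor <- rep(ch$actor_id, reps)
    edge_target <- rep(ch$target_id, reps)
    keep <- edge_frame %in% frames
    edge_frame <- edge_frame[keep]
    edge_actor <- edge_actor[keep]
    edge_target <- edge_target[keep]
    if (length(edge_frame) > 0) {
      by_f <- split(seq_along(edge_frame), edge_frame)
      fpos <- match(as.integer(names(by_f)), frames)
      for (j in seq_along(by_f)) {
        idx <- by_f[[j]]
        if (length(idx) < 2) next  # a lone chase is never chaining
        res <- chain_components_igraph(edge_actor[idx], edge_target[idx])
        components[[fpos[j]]] <- res$components
        chain_count[fpos[j]] <- res$chain_count
      }
    }
  }
  if (any(chain_count > n_flies - 1L)) {
    stop("chain_count exceeded N - 1; inconsistent chase edges.", call. = FALSE)
  }
  tibble(frame = frames, chain_count = chain_count, components = components)
}

# weakly connected components of the chase digraph; components with >= 2
# edges qualify as chains
chain_components_igraph <- function(actors, targets) {
  verts <- sort(unique(c(actors, targets)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(actors), to = as.character(targets)),
    directed = TRUE,
    vertices = data.frame(name = as.character(verts))
  )
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership
  edge_comp <- membership[as.character(actors)]
  edge_tab <- table(edge_comp)
  keep <- as.integer(names(edge_tab)[edge_tab >= 2])
  comps <- lapply(keep, function(ci) {
    sort(as.integer(names(membership)[membership == ci]))
  })
  list(components = comps,
       chain_count = sum(vapply(comps, length, 0L) - 1L))
}
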