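#' Tracker parameters
#'
#' @param gate_px Maximum track-to-detection match distance in pixels per
#'   frame step. Default 30.
#' @param fixed_population If `TRUE` (default) the tracker keeps exactly the
#'   set of tracks opened in the first populated frame; surplus detections
#'   in later frames are dropped with a warning. If `FALSE`, unmatched
#'   detections open new tracks.
#' @param head_overlap_min Minimum fraction of a head box's area that must
#'   overlap a body box for head-to-body assignment. Default 0.25.
#' @return A list of class `tracker_params`.
#' @export
tracker_params <- function(gate_px = 30, fixed_population = TRUE,
                           head_overlap_min = 0.25) {
  stopifnot(gate_px > 0, head_overlap_min > 0, head_overlap_min <= 1)
  structure(list(gate_px = gate_px,
                 fixed_population = isTRUE(fixed_population),
                 head_overlap_min = head_overlap_min),
            class = "tracker_params")
}

#' Link per-frame body detections into identity-stable tracks
#'
#' Implements greedy distance-sort linking: IDs `1..k` are assigned in the
#' first populated frame by ascending `(y, x)` of the bbox centroid. In
#' every later frame, all candidate (track, detection) pairs whose centroid
#' distance is at most `gate_px` are sorted by ascending distance and
#' accepted greedily while both sides are unmatched, so each fly inherits
#' the ID of its nearest neighbour in the previous frame. A track with no
#' match emits a coasting point that replicates its last observed position
#' (`observed = FALSE`) — the ID stays parked there until the fly
#' reappears. Ties in distance are broken by detection `(y, x)` and then by
#' track id, making the output deterministic.
#'
#' @param detections A detections tibble ([read_detections()] dialect);
#'   only `label == "body"` rows are linked.
#' @param config An [arena_config()].
#' @param params A [tracker_params()].
#' @return A tracks tibble (see [read_tracks()]), with attribute `dropped`
#'   giving the number of surplus detections discarded under
#'   `fixed_population`.
#' @export
link_detections <- function(detections, config, params = tracker_params()) {
  body <- detections[detections$label == "body", , drop = FALSE]
  if (nrow(body) == 0) return(empty_tracks())
  if (!("cx" %in% names(body))) {
    body$cx <- body$x + body$w / 2
    body$cy <- body$y + body$h / 2
  }
  frames <- seq(min(body$frame), max(body$frame))
  by_frame <- split(seq_len(nrow(body)), factor(body$frame, levels = frames))

  # first populated frame: ids by ascending (y, x) of centroid
  first_idx <- by_frame[[1]]
  ord <- order(body$cy[first_idx], body$cx[first_idx])
  first_idx <- first_idx[ord]
  k <- length(first_idx)
  if (params$fixed_population && k != config$n_flies) {
    warning(sprintf(
      "first populated frame has %d body detections but config says N = %d; proceeding with %d tracks",
      k, config$n_flies, k), call. = FALSE)
  }

  # live track state (anchor geometry = last observed)
  st <- list(x = body$x[first_idx], y = body$y[first_idx],
             w = body$w[first_idx], h = body$h[first_idx],
             cx = body$cx[first_idx], cy = body$cy[first_idx],
             conf = body$conf[first_idx])

  n_alloc <- length(frames) * max(k, 1L) * 2L
  out <- matrix(NA_real_, nrow = n_alloc, ncol = 8)
  n_out <- 0L
  dropped <- 0L
  emit <- function(frame, ids, x, y, w, h, conf, observed) {
    m <- length(ids)
    if (m == 0L) return(invisible(NULL))
    while (n_out + m > nrow(out)) {
      out <<- rbind(out, matrix(NA_real_, nrow = nrow(out), ncol = 8))
    }
    out[n_out + seq_len(m), ] <<- cbind(frame, ids, x, y, w, h, conf, observed)
    n_out <<- n_out + m
    invisible(NULL)
  }

  emit(frames[1], seq_len(k), st$x, st$y, st$w, st$h, st$conf, 1)

  for (fi in seq_along(frames)[-1]) {
    det_idx <- by_frame[[fi]]
    n_tr <- length(st$cx)
    if (length(det_idx) == 0L) {
      emit(frames[fi], seq_len(n_tr), st$x, st$y, st$w, st$h, rep(0, n_tr), 0)
      next
    }
    dx <- outer(st$cx, body$cx[det_idx], "-")
    dy <- outer(st$cy, body$cy[det_idx], "-")
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist <= params$gate_px, arr.ind = TRUE)
    tr_match <- rep(NA_integer_, n_tr)
    dt_match <- rep(NA_integer_, length(det_idx))
    if (nrow(cand) > 0) {
      d <- dist[cand]
      di <- cand[, 2L]
      o <- order(d, body$cy[det_idx[di]], body$cx[det_idx[di]], cand[, 1L])
      for (ci in o) {
        tr <- cand[ci, 1L]; dt <- cand[ci, 2L]
        if (is.na(tr_match[tr]) && is.na(dt_match[dt])) {
          tr_match[tr] <- dt
          dt_match[dt] <- tr
        }
      }
    }
    matched_tr <- which(!is.na(tr_match))
    if (length(matched_tr) > 0) {
      gi <- det_idx[tr_match[matched_tr]]
      st$x[matched_tr] <- body$x[gi];  st$y[matched_tr] <- body$y[gi]
      st$w[matched_tr] <- body$w[gi];  st$h[matched_tr] <- body$h[gi]
      st$cx[matched_tr] <- body$cx[gi]; st$cy[matched_tr] <- body$cy[gi]
      st$conf[matched_tr] <- body$conf[gi]
    }
    surplus <- which(is.na(dt_match))
    if (length(surplus) > 0) {
      if (params$fixed_population) {
        dropped <- dropped + length(surplus)
      } else {
        gi <- det_idx[surplus]
        o2 <- order(body$cy[gi], body$cx[gi])
        gi <- gi[o2]
        st$x <- c(st$x, body$x[gi]);   st$y <- c(st$y, body$y[gi])
        st$w <- c(st$w, body$w[gi]);   st$h <- c(st$h, body$h[gi])
        st$cx <- c(st$cx, body$cx[gi]); st$cy <- c(st$cy, body$cy[gi])
        st$conf <- c(st$conf, body$conf[gi])
        tr_match <- c(tr_match, seq_along(gi))  # mark new tracks observed
        matched_tr <- c(matched_tr, n_tr + seq_along(gi))
        n_tr <- n_tr + length(gi)
      }
    }
    observed <- as.numeric(seq_len(n_tr) %in% matched_tr)
    conf_out <- ifelse(observed == 1, st$conf, 0)
    emit(frames[fi], seq_len(n_tr), st$x, st$y, st$w, st$h, conf_out, observed)
  }

  if (dropped > 0) {
    warning(sprintf("dropped %d surplus body detection(s) under fixed_population",
                    dropped), call. = FALSE)
  }
  m <- out[seq_len(n_out), , drop = FALSE]
  res <- tibble(
    frame = as.integer(m[, 1]), track_id = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6],
    conf = m[, 7], observed = m[, 8] == 1, heading = NA_real_
  )
  res <- dplyr::mutate(res, cx = .data$x + .data$w / 2,
                       cy = .data$y + .data$h / 2)
  res <- dplyr::arrange(res, .data$frame, .data$track_id)
  attr(res, "dropped") <- dropped
  res
}

# overlap of each head box (rows) with each body box (cols), as a fraction
# of the head box area
overlap_fraction <- function(hx, hy, hw, hh, bx, by, bw, bh) {
  left <- outer(hx, bx, pmax)
  right <- outer(hx + hw, bx + bw, pmin)
  top <- outer(hy, by, pmax)
  bottom <- outer(hy + hh, by + bh, pmin)
  iw <- pmax(right - left, 0)
  ih <- pmax(bottom - top, 0)
  (iw * ih) / (hw * hh)
}

#' Assign head detections to body tracks and compute headings
#'
#' Each head box is assigned to the body track whose box it overlaps most
#' (as a fraction of the head box area, at least `head_overlap_min`; ties
#' go to the nearest body centroid). The heading is the angle of the vector
#' from body centroid to head centroid, in a y-up mathematical frame (image
#' y is negated), in (-pi, pi]: a head exactly to the right gives 0, a head
#' directly above (smaller image y) gives +pi/2. Frames with no assigned
#' head keep `heading = NA`.
#'
#' @param tracks A tracks tibble.
#' @param head_detections A detections tibble; only `label == "head"` rows
#'   are used.
#' @param params A [tracker_params()] (for `head_overlap_min`).
#' @return `tracks` with the `heading` column filled where possible, plus
#'   attribute `skipped_heads` counting head boxes that overlapped no body
#'   above the threshold.
#' @export
assign_heads <- function(tracks, head_detections, params = tracker_params()) {
  heads <- head_detections[head_detections$label == "head", , drop = FALSE]
  if (nrow(heads) == 0 || nrow(tracks) == 0) {
    attr(tracks, "skipped_heads") <- nrow(heads)
    return(tracks)
  }
  if (!("cx" %in% names(heads))) {
    heads$cx <- heads$x + heads$w / 2
    heads$cy <- heads$y + heads$h / 2
  }
  tracks <- dplyr::arrange(tracks, .data$frame, .data$track_id)
  skipped <- 0L
  heading <- tracks$heading
  tr_rows_by_frame <- split(seq_len(nrow(tracks)), tracks$frame)
  hd_rows_by_frame <- split(seq_len(nrow(heads)), heads$frame)
  common <- intersect(names(tr_rows_by_frame), names(hd_rows_by_frame))
  for (f in common) {
    ti <- tr_rows_by_frame[[f]]
    hi <- hd_rows_by_frame[[f]]
    ov <- overlap_fraction(heads$x[hi], heads$y[hi], heads$w[hi], heads$h[hi],
                           tracks$x[ti], tracks$y[ti], tracks$w[ti], tracks$h[ti])
    cdist <- sqrt(outer(heads$cx[hi], tracks$cx[ti], "-")^2 +
                  outer(heads$cy[hi], tracks$cy[ti], "-")^2)
    # best body per head: max overlap, ties -> nearest centroid
    best_ov <- numeric(length(ti))   # per track: overlap of its chosen head
    best_head <- rep(NA_integer_, length(ti))
    for (r in seq_along(hi)) {
      qual <- which(ov[r, ] >= params$head_overlap_min)
      if (length(qual) == 0) { skipped <- skipped + 1L; next }
      top <- qual[ov[r, qual] == max(ov[r, qual])]
      if (length(top) > 1) top <- top[which.min(cdist[r, top])]
      # a body keeps its best head if several heads map to it
      if (is.na(best_head[top]) || ov[r, top] > best_ov[top] ||
          (ov[r, top] == best_ov[top] &&
           cdist[r, top] < cdist[best_head[top], top])) {
        best_head[top] <- r
        best_ov[top] <- ov[r, top]
      }
    }
    sel <- which(!is.na(best_head))
    if (length(sel) > 0) {
      hr <- hi[best_head[sel]]
      tr <- ti[sel]
      heading[tr] <- atan2(-(heads$cy[hr] - tracks$cy[tr]),
                           heads$cx[hr] - tracks$cx[tr])
    }
  }
  tracks$heading <- heading
  attr(tracks, "skipped_heads") <- skipped
  tracks
}

#' Apply manual ID-switch corrections
#'
#' A correction `(frame, id_a, id_b)` exchanges the identities of the two
#' tracks on all points at frames `>= frame` (inclusive). Corrections are
#' applied in the order given; applying the same correction twice restores
#' the input.
#'
#' @param tracks A tracks tibble.
#' @param corrections A tibble with columns `frame`, `id_a`, `id_b`.
#' @return The corrected tracks tibble, re-sorted by `(frame, track_id)`.
#' @export
apply_corrections <- function(tracks, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0) return(tracks)
  ids <- unique(tracks$track_id)
  for (i in seq_len(nrow(corrections))) {
    f <- corrections$frame[i]
    a <- corrections$id_a[i]
    b <- corrections$id_b[i]
    if (a == b) stop("correction ", i, ": id_a and id_b must differ.", call. = FALSE)
    for (id in c(a, b)) {
      if (!(id %in% ids)) {
        stop("correction ", i, ": unknown track id ", id, ".", call. = FALSE)
      }
    }
    sel_a <- tracks$track_id == a & tracks$frame >= f
    sel_b <- tracks$track_id == b & tracks$frame >= f
    tracks$track_id[sel_a] <- b
    tracks$track_id[sel_b] <- a
  }
  dplyr::arrange(tracks, .data$frame, .data$track_id)
}

#' Read an ID-correction file
#'
#' CSV with header `frame,id_a,id_b`, one correction per row.
#'
#' @param path Path to a corrections CSV.
#' @return A tibble with integer columns `frame`, `id_a`, `id_b`.
#' @export
read_corrections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = "iii", progress = FALSE)
  needed <- c("frame", "id_a", "id_b")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("corrections file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw[, needed]
}
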