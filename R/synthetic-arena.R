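#' Scenario directives for the arena simulator
#'
#' Directives override the free random-walk motion of the flies they
#' involve. `dir_chase()` puts an actor and a target on a shared circular
#' orbit, the actor trailing the target by a fixed chord (`gap_px`) with
#' its heading locked on the target — a sustained following episode.
#' `dir_ring()` arranges members equally spaced on one orbit, each chasing
#' the member ahead of it — the closed chaining ring. `dir_goto_food()`
#' sends a fly straight to the food region, where it stays.
#' `dir_decapitated()` pins a fly at its initial position with no head (a
#' static courtship target).
#'
#' Orbital motion is used for chases because it guarantees the chase
#' geometry (constant gap, constant speed, bounded alignment angle) for
#' any duration without ever meeting the chamber wall.
#'
#' @param actor,target,fly,members Fly ids (1-based).
#' @param start,end Frame range \[start, end) the directive covers.
#' @param gap_px Actor-to-target chord distance in px.
#' @param orbit_r_px Orbit radius in px.
#' @param speed_px Tangential speed in px/frame.
#' @param cx,cy Orbit centre in px (`NA` = chamber centre).
#' @param phase Starting phase angle of the orbit, radians.
#' @name directives
NULL

#' @rdname directives
#' @export
dir_chase <- function(actor, target, start, end, gap_px = 50,
                      orbit_r_px = 80, speed_px = 8 / 3,
                      cx = NA, cy = NA, phase = 0) {
  stopifnot(actor != target, start < end, gap_px > 0,
            gap_px < 2 * orbit_r_px, speed_px > 0)
  list(kind = "chase", actor = actor, target = target, start = start,
       end = end, gap_px = gap_px, orbit_r_px = orbit_r_px,
       speed_px = speed_px, cx = cx, cy = cy, phase = phase)
}

#' @rdname directives
#' @export
dir_ring <- function(members, start, end, orbit_r_px = 100,
                     speed_px = 8 / 3, cx = NA, cy = NA, phase = 0) {
  stopifnot(length(members) >= 3, !anyDuplicated(members), start < end,
            orbit_r_px > 0, speed_px > 0)
  list(kind = "ring", members = members, start = start, end = end,
       orbit_r_px = orbit_r_px, speed_px = speed_px, cx = cx, cy = cy,
       phase = phase)
}

#' @rdname directives
#' @export
dir_goto_food <- function(fly, start, speed_px = 8 / 3) {
  stopifnot(speed_px > 0)
  list(kind = "goto_food", fly = fly, start = start, speed_px = speed_px)
}

#' @rdname directives
#' @export
dir_decapitated <- function(fly) {
  list(kind = "decapitated", fly = fly)
}

#' Build a scenario script
#'
#' A scenario is N flies moving for `duration` frames: by default a
#' clamped-Gaussian random walk (steps drawn N(0, `step_sigma_px`) per
#' axis, clamped at 3 sigma, reflected at the circular chamber wall),
#' optionally tethered to per-fly home territories; directives
#' (see [directives]) override the motion of the flies they involve.
#' Detection noise is a per-(fly, frame) dropout probability and a
#' Gaussian centroid jitter. All randomness comes from `seed`; the same
#' script simulates to byte-identical outputs.
#'
#' @param n_flies Number of flies.
#' @param duration Number of frames (0-based frames `0 .. duration - 1`).
#' @param step_sigma_px Random-walk step sigma, px/frame.
#' @param tether_r_px Optional territory radius: each free fly is
#'   reflected inside a disc of this radius around its home point. With
#'   homes laid out on a grid this keeps flies permanently separated —
#'   used for well-separated tracking scenarios. `NULL` = free roaming.
#' @param dropout Per-(fly, frame) probability that the detector misses
#'   the fly (body and head both absent). In \[0, 1).
#' @param jitter_sigma_px Gaussian noise added to detected centroids, px.
#' @param emit_detector_events If `TRUE`, emit a `chase`-labeled event box
#'   over every scripted chase pair each frame.
#' @param directives List of directives.
#' @param seed Integer RNG seed.
#' @return A list of class `scenario_script`.
#' @export
scenario_script <- function(n_flies, duration, step_sigma_px = 2,
                            tether_r_px = NULL, dropout = 0,
                            jitter_sigma_px = 0,
                            emit_detector_events = FALSE,
                            directives = list(), seed = 1L) {
  stopifnot(n_flies >= 1, duration >= 1, step_sigma_px >= 0,
            dropout >= 0, dropout < 1, jitter_sigma_px >= 0)
  script <- structure(
    list(n_flies = as.integer(n_flies), duration = as.integer(duration),
         step_sigma_px = step_sigma_px, tether_r_px = tether_r_px,
         dropout = dropout, jitter_sigma_px = jitter_sigma_px,
         emit_detector_events = isTRUE(emit_detector_events),
         directives = directives, seed = as.integer(seed)),
    class = "scenario_script")
  validate_script(script)
  script
}

# a directive "controls" (fly, frame) pairs; no fly may be controlled by
# two directives at once
validate_script <- function(script) {
  n <- script$n_flies
  dur <- script$duration
  spans <- list()
  for (d in script$directives) {
    flies <- switch(d$kind,
                    chase = c(d$actor, d$target),
                    ring = d$members,
                    goto_food = d$fly,
                    decapitated = d$fly)
    if (any(flies < 1 | flies > n)) {
      stop("directive references fly id outside 1..", n, call. = FALSE)
    }
    rng <- switch(d$kind,
                  chase = c(d$start, d$end),
                  ring = c(d$start, d$end),
                  goto_food = c(d$start, dur),
                  decapitated = c(0L, dur))
    if (rng[1] < 0 || rng[2] > dur) {
      stop("directive frame range [", rng[1], ", ", rng[2],
           ") outside 0..", dur, call. = FALSE)
    }
    for (fl in flies) {
      for (s in spans) {
        if (s$fly == fl && rng[1] < s$rng[2] && s$rng[1] < rng[2]) {
          stop("fly ", fl, " is controlled by two directives over ",
               "overlapping frames; scripts must not overconstrain a fly.",
               call. = FALSE)
        }
      }
      spans[[length(spans) + 1L]] <- list(fly = fl, rng = rng)
    }
  }
  invisible(script)
}

BODY_W <- 12
BODY_H <- 6
HEAD_W <- 4
HEAD_H <- 4
HEAD_AHEAD_PX <- 3

#' Simulate a scenario
#'
#' Runs the agent-based simulation and returns the emitted detection
#' stream together with complete ground truth: the true tracks (with
#' headings), the scripted behavior events, and the per-frame chain
#' records implied by the scripted chase structure.
#'
#' Body boxes are 12 x 6 px centred on the fly (about a 2.5 mm fly at
#' 0.05 mm/px); head boxes are 4 x 4 px centred 3 px ahead of the centroid
#' along the heading. Decapitated flies emit no head box.
#'
#' @param script A [scenario_script()].
#' @param config An [arena_config()].
#' @return A list with elements `detections`, `truth_tracks`,
#'   `truth_events`, `truth_chains`, plus the `script` and `config`.
#' @export
simulate_arena <- function(script, config) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(script$seed)

  n <- script$n_flies
  dur <- script$duration
  cc <- config$chamber
  margin <- BODY_W  # keep boxes clear of the wall
  r_eff <- unname(cc["r"]) - margin

  # frame x fly position/heading matrices, filled frame by frame
  px <- matrix(NA_real_, dur, n)
  py <- matrix(NA_real_, dur, n)
  hd <- matrix(NA_real_, dur, n)   # heading, y-up frame; NA = headless

  controlled <- matrix(FALSE, dur, n)
  edges <- list()  # scripted chase edges: actor, target, start, end

  # resolve directive orbits and mark controlled (fly, frame) cells
  dirs <- lapply(script$directives, function(d) {
    if (d$kind %in% c("chase", "ring")) {
      if (is.na(d$cx)) d$cx <- unname(cc["cx"])
      if (is.na(d$cy)) d$cy <- unname(cc["cy"])
      if (sqrt((d$cx - cc["cx"])^2 + (d$cy - cc["cy"])^2) + d$orbit_r_px > r_eff) {
        stop("directive orbit does not fit inside the chamber.", call. = FALSE)
      }
    }
    d
  })
  for (d in dirs) {
    flies <- switch(d$kind, chase = c(d$actor, d$target), ring = d$members,
                    goto_food = d$fly, decapitated = d$fly)
    rng <- switch(d$kind, chase = c(d$start, d$end), ring = c(d$start, d$end),
                  goto_food = c(d$start, dur), decapitated = c(0L, dur))
    if (rng[2] > rng[1]) {
      controlled[(rng[1] + 1L):rng[2], flies] <- TRUE
    }
  }

  # initial free placement: rejection-sampled with minimum separation,
  # or grid homes when tethered
  min_sep <- max(4 * script$step_sigma_px, 3 * BODY_W)
  if (!is.null(script$tether_r_px)) {
    homes <- grid_homes(n, cc, r_eff, script$tether_r_px, min_sep)
  } else {
    homes <- scatter_points(n, cc, r_eff, min_sep)
  }
  pos_x <- homes$x
  pos_y <- homes$y

  # directive starting positions override
  for (d in dirs) {
    op <- orbit_positions(d, 0L)
    if (!is.null(op)) {
      active0 <- switch(d$kind, chase = , ring = d$start == 0L, FALSE)
      if (active0) { pos_x[op$fly] <- op$x; pos_y[op$fly] <- op$y }
    }
    if (d$kind == "decapitated") hd[, d$fly] <- NA_real_
  }

  steps_x <- matrix(clamp3(stats::rnorm(dur * n, 0, script$step_sigma_px),
                           script$step_sigma_px), dur, n)
  steps_y <- matrix(clamp3(stats::rnorm(dur * n, 0, script$step_sigma_px),
                           script$step_sigma_px), dur, n)

  goto_state <- rep(FALSE, n)  # arrived at food
  for (f in seq_len(dur)) {
    frame <- f - 1L
    free <- !controlled[f, ]
    # free flies: random-walk step with reflection
    if (any(free)) {
      idx <- which(free)
      nx <- pos_x[idx] + steps_x[f, idx]
      ny <- pos_y[idx] + steps_y[f, idx]
      refl <- reflect_into(nx, ny, cc["cx"], cc["cy"], r_eff)
      if (!is.null(script$tether_r_px)) {
        refl <- reflect_into(refl$x, refl$y, homes$x[idx], homes$y[idx],
                             script$tether_r_px)
      }
      moved <- sqrt((refl$x - pos_x[idx])^2 + (refl$y - pos_y[idx])^2) > 0
      hd[f, idx[moved]] <- atan2(-(refl$y - pos_y[idx]),
                                 refl$x - pos_x[idx])[moved]
      if (f > 1) hd[f, idx[!moved]] <- hd[f - 1L, idx[!moved]]
      pos_x[idx] <- refl$x
      pos_y[idx] <- refl$y
    }
    # directive-controlled flies
    for (d in dirs) {
      if (d$kind %in% c("chase", "ring")) {
        if (frame >= d$start && frame < d$end) {
          op <- orbit_positions(d, frame - d$start)
          pos_x[op$fly] <- op$x
          pos_y[op$fly] <- op$y
          hd[f, op$fly] <- op$heading
        }
      } else if (d$kind == "goto_food") {
        if (frame >= d$start) {
          if (is.null(config$food_roi)) {
            stop("goto_food directive needs a food_roi in the config.",
                 call. = FALSE)
          }
          tgt <- food_anchor(config$food_roi)
          dx <- tgt[1] - pos_x[d$fly]
          dy <- tgt[2] - pos_y[d$fly]
          dd <- sqrt(dx^2 + dy^2)
          if (!goto_state[d$fly] && dd > d$speed_px) {
            pos_x[d$fly] <- pos_x[d$fly] + dx / dd * d$speed_px
            pos_y[d$fly] <- pos_y[d$fly] + dy / dd * d$speed_px
            hd[f, d$fly] <- atan2(-dy, dx)
          } else {
            goto_state[d$fly] <- TRUE
            pos_x[d$fly] <- tgt[1]
            pos_y[d$fly] <- tgt[2]
            if (f > 1) hd[f, d$fly] <- hd[f - 1L, d$fly]
          }
        }
      } else if (d$kind == "decapitated") {
        hd[f, d$fly] <- NA_real_  # pinned, headless
      }
    }
    px[f, ] <- pos_x
    py[f, ] <- pos_y
  }

  # scripted chase edges -> truth events
  for (d in dirs) {
    if (d$kind == "chase") {
      edges[[length(edges) + 1L]] <- tibble(
        type = "chase", start_frame = as.integer(d$start),
        end_frame = as.integer(d$end), actor_id = as.integer(d$actor),
        target_id = as.integer(d$target), source = "truth")
    } else if (d$kind == "ring") {
      m <- length(d$members)
      nxt <- d$members[c(2:m, 1)]
      edges[[length(edges) + 1L]] <- tibble(
        type = "chase", start_frame = as.integer(d$start),
        end_frame = as.integer(d$end), actor_id = as.integer(d$members),
        target_id = as.integer(nxt), source = "truth")
    }
  }
  truth_events <- if (length(edges) > 0) dplyr::bind_rows(edges) else
    empty_events()
  truth_events <- dplyr::arrange(truth_events, .data$start_frame,
                                 .data$actor_id, .data$type)

  frames <- 0:(dur - 1L)
  truth_chains <- detect_chaining(truth_events, frames, n)

  truth_tracks <- tibble(
    frame = rep(frames, times = n),
    track_id = rep(seq_len(n), each = dur),
    x = as.vector(px) - BODY_W / 2,
    y = as.vector(py) - BODY_H / 2,
    w = BODY_W, h = BODY_H, conf = 1, observed = TRUE,
    heading = as.vector(hd),
    cx = as.vector(px), cy = as.vector(py)
  )
  truth_tracks <- dplyr::arrange(truth_tracks, .data$frame, .data$track_id)

  detections <- emit_detections(script, px, py, hd, dirs, truth_events)

  list(detections = detections, truth_tracks = truth_tracks,
       truth_events = truth_events, truth_chains = truth_chains,
       script = script, config = config)
}

clamp3 <- function(x, sigma) pmin(pmax(x, -3 * sigma), 3 * sigma)

# radial reflection into a disc of radius r around (cx, cy)
reflect_into <- function(x, y, cx, cy, r) {
  dx <- x - cx
  dy <- y - cy
  d <- sqrt(dx^2 + dy^2)
  out <- d > r
  if (any(out)) {
    cxv <- rep_len(cx, length(x))
    cyv <- rep_len(cy, length(y))
    scale <- (2 * r - d[out]) / d[out]
    scale[scale < 0] <- 0  # pathological overshoot: park at centre side
    x[out] <- cxv[out] + dx[out] * scale
    y[out] <- cyv[out] + dy[out] * scale
  }
  list(x = unname(x), y = unname(y))
}

food_anchor <- function(roi) {
  if (roi$type == "circle") c(roi$cx, roi$cy) else c(mean(roi$x), mean(roi$y))
}

# place n points inside the effective radius with pairwise gap >= min_sep
scatter_points <- function(n, cc, r_eff, min_sep) {
  xs <- numeric(0)
  ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 20000L) stop("cannot place flies with requested separation.",
                             call. = FALSE)
    a <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt(stats::runif(1)) * r_eff
    x <- unname(cc["cx"]) + rr * cos(a)
    y <- unname(cc["cy"]) + rr * sin(a)
    if (length(xs) == 0 || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_sep)) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
  }
  list(x = xs, y = ys)
}

# tethered homes on a centred grid with spacing 2*tether + min_sep
grid_homes <- function(n, cc, r_eff, tether_r, min_sep) {
  spacing <- 2 * tether_r + min_sep
  k <- ceiling(sqrt(n))
  gx <- rep(seq_len(k), times = k)
  gy <- rep(seq_len(k), each = k)
  xs <- (gx - (k + 1) / 2) * spacing + unname(cc["cx"])
  ys <- (gy - (k + 1) / 2) * spacing + unname(cc["cy"])
  if (any(sqrt((xs - cc["cx"])^2 + (ys - cc["cy"])^2) + tether_r > r_eff)) {
    stop("tethered homes do not fit in the chamber; reduce tether_r_px ",
         "or group size.", call. = FALSE)
  }
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# positions of a chase/ring directive's members at elapsed frame `t_el`
orbit_positions <- function(d, t_el) {
  if (!(d$kind %in% c("chase", "ring"))) return(NULL)
  omega <- d$speed_px / d$orbit_r_px
  if (d$kind == "chase") {
    delta <- 2 * asin(d$gap_px / (2 * d$orbit_r_px))
    th_target <- d$phase + delta + omega * t_el
    th_actor <- d$phase + omega * t_el
    th <- c(th_actor, th_target)
    fly <- c(d$actor, d$target)
  } else {
    m <- length(d$members)
    th <- d$phase + (seq_len(m) - 1) * 2 * pi / m + omega * t_el
    fly <- d$members
  }
  x <- d$cx + d$orbit_r_px * cos(th)
  y <- d$cy + d$orbit_r_px * sin(th)
  # heading: actor aims at its target; the chase target (last slot of a
  # chase pair) moves tangentially
  if (d$kind == "chase") {
    hx <- x[2] - x[1]
    hy <- y[2] - y[1]
    heading <- c(atan2(-hy, hx), tangent_heading(th[2], omega))
  } else {
    m <- length(fly)
    nxt <- c(2:m, 1)
    heading <- atan2(-(y[nxt] - y), x[nxt] - x)
  }
  list(fly = fly, x = x, y = y, heading = heading)
}

# y-up heading of tangential motion at orbit angle th (d theta/dt > 0)
tangent_heading <- function(th, omega) {
  vx <- -sin(th) * omega
  vy <- cos(th) * omega
  atan2(-vy, vx)
}

emit_detections <- function(script, px, py, hd, dirs, truth_events) {
  dur <- nrow(px)
  n <- ncol(px)
  drop_mat <- if (script$dropout > 0) {
    matrix(stats::runif(dur * n) < script$dropout, dur, n)
  } else matrix(FALSE, dur, n)
  jx <- if (script$jitter_sigma_px > 0) {
    matrix(stats::rnorm(dur * n, 0, script$jitter_sigma_px), dur, n)
  } else matrix(0, dur, n)
  jy <- if (script$jitter_sigma_px > 0) {
    matrix(stats::rnorm(dur * n, 0, script$jitter_sigma_px), dur, n)
  } else matrix(0, dur, n)

  keep <- which(!drop_mat)
  f_idx <- ((keep - 1L) %% dur) + 1L
  fly_idx <- ((keep - 1L) %/% dur) + 1L
  cx <- px[keep] + jx[keep]
  cy <- py[keep] + jy[keep]
  body <- tibble(
    frame = f_idx - 1L, label = "body", conf = 1,
    x = cx - BODY_W / 2, y = cy - BODY_H / 2, w = BODY_W, h = BODY_H,
    cx = cx, cy = cy
  )
  headless <- vapply(dirs, function(d)
    if (d$kind == "decapitated") as.integer(d$fly) else NA_integer_, 0L)
  headless <- headless[!is.na(headless)]
  has_head <- !is.na(hd[keep]) & !(fly_idx %in% headless)
  hk <- keep[has_head]
  hcx <- px[hk] + HEAD_AHEAD_PX * cos(hd[hk]) + jx[hk]
  hcy <- py[hk] - HEAD_AHEAD_PX * sin(hd[hk]) + jy[hk]  # image y down
  head <- tibble(
    frame = f_idx[has_head] - 1L, label = "head", conf = 1,
    x = hcx - HEAD_W / 2, y = hcy - HEAD_H / 2, w = HEAD_W, h = HEAD_H,
    cx = hcx, cy = hcy
  )
  out <- dplyr::bind_rows(body, head)

  if (script$emit_detector_events && nrow(truth_events) > 0) {
    ev_rows <- list()
    for (i in seq_len(nrow(truth_events))) {
      a <- truth_events$actor_id[i]
      t <- truth_events$target_id[i]
      fr <- (truth_events$start_frame[i] + 1L):truth_events$end_frame[i]
      x1 <- pmin(px[fr, a], px[fr, t]) - BODY_W / 2 - 2
      y1 <- pmin(py[fr, a], py[fr, t]) - BODY_H / 2 - 2
      x2 <- pmax(px[fr, a], px[fr, t]) + BODY_W / 2 + 2
      y2 <- pmax(py[fr, a], py[fr, t]) + BODY_H / 2 + 2
      ev_rows[[length(ev_rows) + 1L]] <- tibble(
        frame = fr - 1L, label = "chase", conf = 1,
        x = x1, y = y1, w = x2 - x1, h = y2 - y1,
        cx = (x1 + x2) / 2, cy = (y1 + y2) / 2)
    }
    out <- dplyr::bind_rows(out, dplyr::bind_rows(ev_rows))
  }
  dplyr::arrange(out, .data$frame, .data$label, .data$x, .data$y)
}

#' Bundled worked-example fixtures
#'
#' Two noiseless scenarios that exercise the behavior-index arithmetic
#' end-to-end. Fixture A: a 10-fly group in which 5 simultaneous chase
#' pairs run for the whole clip — the chasing index must come out at 50%.
#' Fixture B: the same group forming a closed chasing ring (every fly
#' chasing the next) — chasing index 100%, and the ring's chain count is
#' N - 1 = 9 every frame, so the chaining index is 100% as well.
#'
#' @param duration Clip length in frames (default 900 = 30 s at 30 fps).
#' @param seed RNG seed passed to the scripts. Both fixtures are fully
#'   scripted and noiseless, so the outputs do not depend on it; it is
#'   recorded in the scripts for provenance.
#' @return A list with elements `A` and `B`, each a list of `script` and
#'   `config`.
#' @export
make_worked_examples <- function(duration = 900, seed = 1L) {
  config <- arena_config(n_flies = 10, mm_per_px = 0.05, fps = 30,
                         chamber = c(cx = 400, cy = 400, r = 400))
  # five separated orbit anchors for the chase pairs
  ang <- 2 * pi * (0:4) / 5
  dirs_a <- lapply(0:4, function(k) {
    dir_chase(actor = 2 * k + 1, target = 2 * k + 2, start = 0,
              end = duration, gap_px = 50, orbit_r_px = 80,
              speed_px = 8 / 3,
              cx = 400 + 250 * cos(ang[k + 1]),
              cy = 400 + 250 * sin(ang[k + 1]),
              phase = 0)
  })
  script_a <- scenario_script(n_flies = 10, duration = duration,
                              step_sigma_px = 0, directives = dirs_a,
                              seed = seed)
  script_b <- scenario_script(
    n_flies = 10, duration = duration, step_sigma_px = 0,
    directives = list(dir_ring(members = 1:10, start = 0, end = duration,
                               orbit_r_px = 100, speed_px = 8 / 3)),
    seed = seed)
  list(A = list(script = script_a, config = config),
       B = list(script = script_b, config = config))
}
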