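# Independent oracles and small fixture builders used across the suite.

# Exhaustive chain-component oracle: weakly connected components via plain
# union-find (no graph library), chains = components with >= 2 edges,
# count = sum(|component| - 1).
oracle_chain <- function(actors, targets) {
  verts <- sort(unique(c(actors, targets)))
  parent <- seq_along(verts)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_along(actors)) {
    ra <- find(match(actors[k], verts))
    rt <- find(match(targets[k], verts))
    if (ra != rt) parent[rt] <- ra
  }
  roots <- vapply(seq_along(verts), find, 0L)
  edge_roots <- vapply(seq_along(actors),
                       function(k) find(match(actors[k], verts)), 0L)
  comps <- list()
  for (r in unique(roots)) {
    if (sum(edge_roots == r) >= 2) {
      comps[[length(comps) + 1L]] <- sort(verts[roots == r])
    }
  }
  list(components = comps,
       chain_count = if (length(comps) == 0) 0L else
         sum(vapply(comps, length, 0L) - 1L))
}

# O(N^2) brute-force nearest neighbour distances and radius counts
oracle_nn <- function(x, y, radius) {
  n <- length(x)
  nn <- numeric(n)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
      if (d <= radius) cnt[i] <- cnt[i] + 1L
    }
    nn[i] <- best
  }
  list(nn = nn, count = cnt)
}

test_config <- function(n_flies = 10, food = FALSE) {
  roi <- if (food) list(type = "circle", cx = 400, cy = 400, r = 60) else NULL
  arena_config(n_flies = n_flies, mm_per_px = 0.05, fps = 30,
               chamber = c(cx = 400, cy = 400, r = 400), food_roi = roi)
}

# minimal hand-built track tibble from per-fly centroid matrices
build_tracks <- function(cx, cy, w = 12, h = 6, observed = TRUE,
                         heading = NA_real_) {
  nf <- nrow(cx)
  n <- ncol(cx)
  tibble::tibble(
    frame = rep(0:(nf - 1L), times = n),
    track_id = rep(seq_len(n), each = nf),
    x = as.vector(cx) - w / 2, y = as.vector(cy) - h / 2,
    w = w, h = h, conf = 1,
    observed = observed, heading = heading,
    cx = as.vector(cx), cy = as.vector(cy)
  )
}

# detection rows from centroids (one frame)
det_rows <- function(frame, cx, cy, label = "body", w = 12, h = 6, conf = 1) {
  tibble::tibble(frame = frame, label = label, conf = conf,
                 x = cx - w / 2, y = cy - h / 2, w = w, h = h,
                 cx = cx, cy = cy)
}

# Optimal per-frame assignment oracle through scipy's Hungarian solver.
# `det` must have columns scenario, frame, cx, cy (body detections only).
# Returns a tibble scenario, frame, track_id (first-frame (y, x) rank),
# cx, cy of the optimally assigned detection chain.
hungarian_oracle <- function(det) {
  py <- Sys.which("python")
  if (py == "") stop("python not found on PATH")
  inp <- tempfile(fileext = ".csv")
  outp <- tempfile(fileext = ".csv")
  readr::write_csv(det, inp)
  script <- test_path("hungarian_oracle.py")
  res <- system2(py, c(script, inp, outp), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outp)) stop("hungarian oracle failed: ",
                               paste(res, collapse = "\n"))
  readr::read_csv(outp, col_types = "iiidd", progress = FALSE)
}

# well-separated tethered scenario for tracking-oracle comparisons
separated_script <- function(n_flies, duration, seed) {
  scenario_script(n_flies = n_flies, duration = duration,
                  step_sigma_px = 2, tether_r_px = 20, seed = seed)
}
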