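chase_ev <- function(actor, target, start = 0L, end = 1L) {
  tibble::tibble(type = "chase", start_frame = as.integer(start),
                 end_frame = as.integer(end), actor_id = as.integer(actor),
                 target_id = as.integer(target), source = "truth")
}

test_that("chaining criterion: two chases on one object chain, one does not", {
  # a single chase edge is never chaining
  ch1 <- detect_chaining(chase_ev(1, 2), frames = 0L, n_flies = 5)
  expect_equal(ch1$chain_count, 0L)
  expect_equal(ch1$components[[1]], list())

  # two independent chases targeting the same object -> one 3-fly chain
  ev <- dplyr::bind_rows(chase_ev(1, 3), chase_ev(2, 3))
  ch2 <- detect_chaining(ev, frames = 0L, n_flies = 5)
  expect_equal(ch2$chain_count, 2L)
  expect_equal(ch2$components[[1]], list(c(1L, 2L, 3L)))
})

test_that("paths and rings over N flies give chain_count N - 1", {
  for (n in c(3, 5, 10, 13)) {
    ring <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      chase_ev(i, if (i == n) 1L else i + 1L)
    }))
    expect_equal(detect_chaining(ring, 0L, n)$chain_count, n - 1L)
    path <- dplyr::bind_rows(lapply(seq_len(n - 1), function(i) {
      chase_ev(i, i + 1L)
    }))
    expect_equal(detect_chaining(path, 0L, n)$chain_count, n - 1L)
  }
})

test_that("random digraphs match the exhaustive component oracle", {
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(3:8, 1)
    n_edges <- sample(1:10, 1)
    actors <- sample(n, n_edges, replace = TRUE)
    targets <- sample(n, n_edges, replace = TRUE)
    keep <- actors != targets
    if (!any(keep)) next
    pairs <- unique(data.frame(a = actors[keep], t = targets[keep]))
    ev <- dplyr::bind_rows(Map(chase_ev, pairs$a, pairs$t))
    got <- detect_chaining(ev, 0L, n)
    exp <- oracle_chain(pairs$a, pairs$t)
    expect_equal(got$chain_count, exp$chain_count)
    expect_equal(got$components[[1]], exp$components)
  }
})

test_that("kinematic predicate rejects slow, far, and misaligned pairs", {
  cfg <- test_config(2)
  # two stationary flies 10 mm (200 px) apart: speed predicate fails
  still <- build_tracks(cx = matrix(c(100, 100, 300, 300), 2, 2),
                        cy = matrix(100, 2, 2))
  expect_equal(nrow(classify_kinematic_chases(still, cfg)), 0L)

  # follower within 3 mm but heading 180 degrees away: alignment fails
  nf <- 60
  cx <- cbind(seq(200, by = 4, length.out = nf),
              seq(260, by = 4, length.out = nf))
  away <- build_tracks(cx = cx, cy = matrix(300, nf, 2))
  away$heading <- ifelse(away$track_id == 1L, pi, 0)  # 1 faces away from 2
  expect_equal(sum(classify_kinematic_chases(away, cfg)$actor_id == 1L), 0L)
})

test_that("a scripted follower yields exactly one covering chase event", {
  cfg <- test_config(2)
  sim <- simulate_arena(
    scenario_script(n_flies = 2, duration = 60, step_sigma_px = 0,
                    directives = list(
                      dir_chase(1, 2, start = 0, end = 60, gap_px = 60)),
                    seed = 1), cfg)
  ev <- classify_kinematic_chases(sim$truth_tracks, cfg)
  ev1 <- ev[ev$actor_id == 1L, ]
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$target_id, 2L)
  expect_gte(ev1$end_frame - ev1$start_frame, 55L)
})

test_that("loosening chase thresholds never decreases total chase frames", {
  cfg <- test_config(6)
  sim <- simulate_arena(
    scenario_script(n_flies = 6, duration = 200, step_sigma_px = 3,
                    seed = 9), cfg)
  trk <- sim$truth_tracks
  frames_of <- function(params) {
    ev <- classify_kinematic_chases(trk, cfg, params)
    sum(ev$end_frame - ev$start_frame)
  }
  base <- chase_params()
  expect_lte(frames_of(base),
             frames_of(chase_params(d_max_mm = 10)))
  expect_lte(frames_of(base),
             frames_of(chase_params(align_max_rad = pi / 2)))
  expect_lte(frames_of(base),
             frames_of(chase_params(min_frames = 5)))
})

test_that("chase actors are unique per frame", {
  cfg <- test_config(10)
  fx <- make_worked_examples(duration = 120)
  sim <- simulate_arena(fx$B$script, fx$B$config)
  ev <- classify_kinematic_chases(sim$truth_tracks, fx$B$config)
  # expand to frames and check one target per (actor, frame)
  per_frame <- dplyr::bind_rows(lapply(seq_len(nrow(ev)), function(i) {
    tibble::tibble(frame = ev$start_frame[i]:(ev$end_frame[i] - 1L),
                   actor = ev$actor_id[i])
  }))
  expect_equal(anyDuplicated(per_frame[, c("frame", "actor")]), 0L)
})

test_that("detector event boxes are attributed to the right pairs", {
  cfg <- test_config(3)
  # chase box exactly covering flies 1 and 2; fly 1 heads at fly 2
  trk <- build_tracks(cx = matrix(c(100, 160, 400), 1, 3),
                      cy = matrix(100, 1, 3))
  trk$heading[trk$track_id == 1L] <- 0        # 1 faces +x, toward 2
  trk$heading[trk$track_id == 2L] <- pi / 2   # 2 faces away
  box <- tibble::tibble(frame = 0L, label = "chase", conf = 1,
                        x = 90, y = 90, w = 80, h = 20,
                        cx = 130, cy = 100)
  ev <- attribute_detector_events(box, trk, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$actor_id, 1L)
  expect_equal(ev$target_id, 2L)

  # wing_ext over fly 3 alone, no neighbour in its cone
  wbox <- tibble::tibble(frame = 0L, label = "wing_ext", conf = 1,
                         x = 390, y = 90, w = 24, h = 20, cx = 402, cy = 100)
  trk$heading[trk$track_id == 3L] <- pi  # faces -x; flies 1/2 are 12+ mm off
  wev <- attribute_detector_events(wbox, trk, cfg)
  expect_equal(wev$type, "wing_ext")
  expect_equal(wev$actor_id, 3L)
  expect_true(is.na(wev$target_id))
})

test_that("jittered detector boxes still attribute with full accuracy", {
  cfg <- test_config(10)
  fx <- make_worked_examples(duration = 30)
  script <- fx$A$script
  script$emit_detector_events <- TRUE
  sim <- simulate_arena(script, fx$A$config)
  det <- sim$detections
  is_ev <- det$label == "chase"
  expect_gte(sum(is_ev), 100)
  set.seed(31)
  det$x[is_ev] <- det$x[is_ev] + stats::runif(sum(is_ev), -2, 2)
  det$y[is_ev] <- det$y[is_ev] + stats::runif(sum(is_ev), -2, 2)
  det$cx <- det$x + det$w / 2
  det$cy <- det$y + det$h / 2
  trk <- assign_heads(link_detections(det, fx$A$config), det)
  ev <- attribute_detector_events(det, trk, fx$A$config)
  got_pairs <- unique(ev[, c("actor_id", "target_id")])
  truth_pairs <- unique(sim$truth_events[, c("actor_id", "target_id")])
  # tracker ids equal truth ids up to the first-frame (y, x) rank; map truth
  f0 <- sim$truth_tracks[sim$truth_tracks$frame == 0, ]
  rank <- order(f0$cy, f0$cx)
  id_map <- integer(10)
  id_map[f0$track_id[rank]] <- seq_len(10)
  truth_pairs$actor_id <- id_map[truth_pairs$actor_id]
  truth_pairs$target_id <- id_map[truth_pairs$target_id]
  expect_setequal(paste(got_pairs$actor_id, got_pairs$target_id),
                  paste(truth_pairs$actor_id, truth_pairs$target_id))
  expect_equal(attr(ev, "dropped_events"), 0L)
})
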