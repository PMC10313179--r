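test_that("behavior index reproduces the N-fly worked arithmetic", {
  # five chasing pairs in a 10-fly group -> 50%
  bi <- behavior_index(rep(5, 100), 10, "chase")
  expect_equal(bi$index, 50)
  # a full ring of 10 -> 100%
  expect_equal(behavior_index(rep(10, 100), 10, "chase")$index, 100)
  # chaining B(max) is N - 1
  expect_equal(behavior_index(rep(9, 10), 10, "chain")$b_max, 9L)
  expect_equal(behavior_index(rep(9, 10), 10, "chain")$index, 100)
  expect_equal(behavior_index(rep(0, 50), 10, "chase")$index, 0)
})

test_that("behavior index caps at 100, rejects N < 2, is monotone in B(d)", {
  expect_warning(bi <- behavior_index(c(5, 12), 10, "chase"), "capping")
  expect_equal(max(bi$series$index), 100)
  expect_error(behavior_index(rep(1, 10), 1, "chase"), ">= 2")
  set.seed(1)
  for (i in 1:20) {
    b1 <- pmin(stats::rpois(50, 3), 9)
    bump <- pmin(b1 + stats::rbinom(50, 1, 0.3), 9)
    expect_lte(behavior_index(b1, 10, "chase")$index,
               behavior_index(bump, 10, "chase")$index)
  }
})

test_that("tidy/glance expose the per-frame series and summary", {
  bi <- behavior_index(c(0, 5, 10), 10, "chase")
  td <- tidy(bi)
  expect_equal(td$index, c(0, 50, 100))
  gl <- glance(bi)
  expect_equal(gl$index, 50)
  expect_equal(gl$n_frames, 3L)
})

test_that("courtship index is the courting share of observed time", {
  expect_equal(courtship_index(rep(TRUE, 100)), 100)
  expect_equal(courtship_index(rep(FALSE, 100)), 0)
  expect_equal(courtship_index(c(rep(TRUE, 450), rep(FALSE, 1350))), 25)
  expect_true(is.na(courtship_index(rep(NA, 10))))
  # complement conservation
  flags <- c(rep(TRUE, 123), rep(FALSE, 877))
  expect_equal(courtship_index(flags) + courtship_index(!flags), 100)
})

test_that("time-based chaining index is the chaining share of frames", {
  mk <- function(counts) tibble::tibble(frame = seq_along(counts) - 1L,
                                        chain_count = counts,
                                        components = list(list()))
  expect_equal(chaining_index_time(mk(rep(0L, 100))), 0)
  expect_equal(chaining_index_time(mk(rep(2L, 100))), 100)
  counts <- c(rep(2L, 900), rep(0L, 17100))
  expect_equal(chaining_index_time(mk(counts)), 5)
  expect_true(is.na(chaining_index_time(mk(integer(0)))))
})

test_that("preference index divides by courtship time only", {
  expect_equal(preference_index(rep("A", 50)), 100)
  expect_equal(preference_index(c(rep("A", 300), rep("B", 100),
                                  rep("none", 600))), 75)
  expect_true(is.na(preference_index(rep("none", 100))))
  expect_error(preference_index(c("A", "C")), "C")
})

test_that("social space matches brute force and handles degenerate cases", {
  cfg <- test_config(2)
  two <- build_tracks(cx = matrix(c(100, 200), 1, 2),
                      cy = matrix(100, 1, 2))
  ss <- social_space(two, cfg)
  expect_equal(ss$nn_mm, c(5, 5))  # 100 px at 0.05 mm/px

  set.seed(7)
  cfg13 <- test_config(13)
  x <- stats::runif(13, 100, 700)
  y <- stats::runif(13, 100, 700)
  one <- build_tracks(cx = matrix(x, 1), cy = matrix(y, 1))
  got <- social_space(one, cfg13)
  exp <- oracle_nn(x, y, radius = 5 / 0.05)
  expect_equal(got$nn_mm, exp$nn * 0.05)
  expect_equal(got$n_neighbors, exp$count)

  # all flies coincident
  co <- build_tracks(cx = matrix(rep(400, 5), 1), cy = matrix(rep(400, 5), 1))
  gco <- social_space(co, test_config(5))
  expect_equal(gco$nn_mm, rep(0, 5))
  expect_equal(gco$n_neighbors, rep(4L, 5))

  expect_error(social_space(build_tracks(cx = matrix(1, 1, 1),
                                         cy = matrix(1, 1, 1)), cfg),
               ">= 2")
})

test_that("encounters are maximal close-contact runs of sufficient length", {
  cfg <- test_config(2)
  # 7 bouts of 20 close frames separated by 30 far frames
  bouts <- 7
  pattern <- rep(rep(c(TRUE, FALSE), bouts), times = rep(c(20, 30), bouts))
  cx2 <- 200 + ifelse(pattern, 50, 400)
  trk <- build_tracks(cx = cbind(rep(200, length(pattern)), cx2),
                      cy = matrix(300, length(pattern), 2))
  enc <- count_encounters(trk, cfg)
  expect_equal(as.integer(enc), bouts)
  expect_equal(nrow(attr(enc, "bouts")), bouts)

  # never close -> 0
  far <- build_tracks(cx = cbind(rep(100, 60), rep(700, 60)),
                      cy = matrix(300, 60, 2))
  expect_equal(as.integer(count_encounters(far, cfg)), 0L)

  # a single 60-frame contact -> 1
  onebout <- build_tracks(cx = cbind(rep(200, 60), rep(250, 60)),
                          cy = matrix(300, 60, 2))
  expect_equal(as.integer(count_encounters(onebout, cfg)), 1L)
})

test_that("foraging visits gate on duration but dwell counts everything", {
  cfg <- test_config(1, food = TRUE)  # ROI: circle r=60 at (400, 400)
  inroi <- c(400, 400)
  outroi <- c(700, 400)
  mk_track <- function(inside) {
    build_tracks(cx = matrix(ifelse(inside, inroi[1], outroi[1]), ncol = 1),
                 cy = matrix(400, length(inside), 1))
  }
  # never entering
  never <- mk_track(rep(FALSE, 100))
  fn <- foraging_metrics(never, cfg)
  expect_equal(fn$visits, 0L)
  expect_equal(fn$dwell_s, 0)

  # two 60-frame entries separated by 300 frames -> 2 visits, 4 s dwell
  pat <- c(rep(TRUE, 60), rep(FALSE, 300), rep(TRUE, 60))
  f2 <- foraging_metrics(mk_track(pat), cfg)
  expect_equal(f2$visits, 2)
  expect_equal(f2$dwell_s, 4)

  # a 10-frame entry is no visit but still dwells 1/3 s
  f3 <- foraging_metrics(mk_track(c(rep(FALSE, 20), rep(TRUE, 10),
                                    rep(FALSE, 20))), cfg)
  expect_equal(f3$visits, 0)
  expect_equal(f3$dwell_s, 10 / 30, tolerance = 1e-12)

  # gaps shorter than forage_gap_frames merge into one visit
  merged <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 20))
  f4 <- foraging_metrics(mk_track(merged), cfg)
  expect_equal(f4$visits, 1)

  expect_error(foraging_metrics(never, test_config(1)), "food_roi")
})

test_that("locomotion states follow the speed thresholds", {
  cfg <- test_config(1)
  # stationary -> all resting, one resting event
  still <- build_tracks(cx = matrix(300, 50, 1), cy = matrix(300, 50, 1))
  lc <- locomotion_classify(still, cfg)
  expect_true(all(lc$state == "resting"))
  ls <- locomotion_summary(lc)
  expect_equal(ls$n_events[ls$state == "resting"], 1L)
  expect_equal(sum(ls$fraction_pct), 100)

  # constant 5 mm/s -> walking (0.5 < 5 <= 10); 5/30 mm/frame = 10/3 px
  walk <- build_tracks(cx = matrix(100 + (0:49) * 10 / 3, ncol = 1),
                       cy = matrix(300, 50, 1))
  expect_true(all(locomotion_classify(walk, cfg)$state == "walking"))

  # a 12 mm single-frame displacement is a jump (12 / 2.5 = 4.8 >= 4)
  cxj <- c(rep(300, 10), rep(300 + 240, 10))  # 240 px = 12 mm
  jump <- build_tracks(cx = matrix(cxj, ncol = 1), cy = matrix(300, 20, 1))
  lj <- locomotion_classify(jump, cfg)
  expect_equal(lj$state[lj$frame == 9L], "jumping")

  # coasting frames classify as resting
  coast <- build_tracks(cx = matrix(100 + (0:49) * 10 / 3, ncol = 1),
                        cy = matrix(300, 50, 1))
  coast$observed[25] <- FALSE
  lcc <- locomotion_classify(coast, cfg)
  expect_equal(lcc$state[lcc$frame == 24L], "resting")

  # per-fly fractions always sum to 100
  set.seed(3)
  sim <- simulate_arena(scenario_script(n_flies = 5, duration = 100,
                                        step_sigma_px = 4, seed = 8),
                        test_config(5))
  fr <- locomotion_summary(locomotion_classify(sim$truth_tracks,
                                               test_config(5)))
  sums <- tapply(fr$fraction_pct, fr$track_id, sum)
  expect_equal(as.numeric(sums), rep(100, 5))
})

test_that("the metrics report composes all readouts with valid ranges", {
  fx <- make_worked_examples(duration = 120)
  sim <- simulate_arena(fx$B$script, fx$B$config)
  res <- run_pipeline(sim$detections, fx$B$config)
  m <- res$metrics
  gl <- glance(m)
  pct_cols <- c("chasing_index", "singing_index", "chaining_index",
                "chaining_index_time", "mean_ci")
  for (cl in pct_cols) {
    expect_gte(gl[[cl]], 0)
    expect_lte(gl[[cl]], 100)
  }
  td <- tidy(m)
  expect_equal(nrow(td), 10L)
  expect_true(all(td$ci >= 0 & td$ci <= 100))
  # every ring member courts every frame -> CI 100
  expect_equal(td$ci, rep(100, 10))
})
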