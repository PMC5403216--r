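test_that("linking follows the 300 nm / memory rules", {
  # 200 nm apart in consecutive frames: one track
  tab <- loc_table(frame = c(0, 1), x = c(0, 200), y = c(0, 0))
  tr <- link_localizations(tab, radius = 300, memory = 1, interval_time = 1)
  expect_length(unique(tr$track_id), 1L)

  # 400 nm apart: two tracks
  tab2 <- loc_table(frame = c(0, 1), x = c(0, 400), y = c(0, 0))
  tr2 <- link_localizations(tab2, radius = 300, memory = 1, interval_time = 1)
  expect_length(unique(tr2$track_id), 2L)

  # memory 1 bridges a single missing frame but not two
  tab3 <- loc_table(frame = c(1, 2, 4), x = rep(0, 3), y = rep(0, 3))
  tr3 <- link_localizations(tab3, radius = 300, memory = 1, interval_time = 1)
  expect_length(unique(tr3$track_id), 1L)
  tab4 <- loc_table(frame = c(1, 2, 5), x = rep(0, 3), y = rep(0, 3))
  tr4 <- link_localizations(tab4, radius = 300, memory = 1, interval_time = 1)
  expect_length(unique(tr4$track_id), 2L)

  unsorted <- data.frame(frame = c(2L, 1L), x_nm = c(0, 0), y_nm = c(0, 0),
                         sigma_x_nm = 100, sigma_y_nm = 100,
                         intensity = 1000, background = 50)
  expect_error(link_localizations(unsorted, interval_time = 1), "sorted")
})

test_that("conflicts resolve by ascending distance with stable ties", {
  # two heads compete for one localization: the closer head wins
  tab <- loc_table(frame = c(0, 0, 1), x = c(0, 500, 100), y = c(0, 0, 0))
  tr <- link_localizations(tab, radius = 300, memory = 0, interval_time = 1)
  s <- track_summary(tr)
  expect_identical(tr$track_id[3L], tr$track_id[1L])
  expect_length(unique(tr$track_id), 2L)
})

test_that("linking is idempotent and covers every localization exactly once", {
  st <- acquisition_settings(0.5, 1, 120)
  tab <- gen_localization_table(
    track_sim_params(8, n_molecules = 60, seed = 21), st,
    mixture_spec(n_diffusing = 60))
  tr <- link_localizations(tab)
  expect_identical(nrow(tr), nrow(tab))
  expect_false(anyNA(tr$track_id))
  expect_true(all(tr$track_id >= 1L))

  # relink the linked output (as a plain table) and compare partitions
  tr2 <- link_localizations(as.data.frame(tr)[names(tab)],
                            interval_time = 1)
  part <- function(id) as.integer(factor(id, levels = unique(id)))
  expect_identical(part(tr2$track_id), part(tr$track_id))

  # frames strictly increase within every track
  by_track <- split(tr$frame, tr$track_id)
  expect_true(all(vapply(by_track, function(f) all(diff(f) > 0),
                         logical(1))))
})

test_that("fragment linking merges by gap and distance, transitively", {
  # fragments 100 nm apart separated by 3 frames: merged
  tab <- loc_table(frame = c(0, 1, 5, 6), x = c(0, 0, 100, 100),
                   y = rep(0, 4))
  tr <- link_localizations(tab, interval_time = 1)
  expect_length(unique(tr$track_id), 2L)
  merged <- link_track_fragments(tr, max_gap = 4, radius = 300)
  expect_length(unique(merged$track_id), 1L)

  # gap of 5 frames: not merged
  tab2 <- loc_table(frame = c(0, 1, 7, 8), x = c(0, 0, 100, 100),
                    y = rep(0, 4))
  merged2 <- link_track_fragments(link_localizations(tab2, interval_time = 1),
                                  max_gap = 4, radius = 300)
  expect_length(unique(merged2$track_id), 2L)

  # three chainable fragments collapse to one track (fixed point)
  tab3 <- loc_table(frame = c(0, 1, 5, 6, 10, 11),
                    x = c(0, 0, 50, 50, 100, 100), y = rep(0, 6))
  merged3 <- link_track_fragments(link_localizations(tab3, interval_time = 1),
                                  max_gap = 4, radius = 300)
  expect_length(unique(merged3$track_id), 1L)
})

test_that("immobile filter applies the PSF thresholds to track means", {
  tab <- rbind(
    loc_table(frame = c(0, 1), x = c(0, 0), y = c(0, 0),
              sigma_x = 150, sigma_y = 200),
    loc_table(frame = c(0, 1), x = c(5000, 5000), y = c(0, 0),
              sigma_x = 180, sigma_y = 200)
  )
  tab <- tab[order(tab$frame), ]
  tr <- link_localizations(tab, interval_time = 1)
  kept <- filter_immobile(tr, threshold_x = 170, threshold_y = 215)
  s <- track_summary(kept)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean_sigma_x, 150)
})

test_that("minimum-localization thresholds follow the per-interval map", {
  mk <- function(n_loc, interval) {
    tab <- loc_table(frame = seq_len(n_loc) - 1L, x = rep(0, n_loc),
                     y = rep(0, n_loc))
    link_localizations(tab, interval_time = interval)
  }
  # interval 1 s: tracks with < 4 localizations removed, L = 4 s
  out <- apply_min_localization_threshold(mk(3L, 1), interval_time = 1)
  expect_identical(nrow(out$tracks), 0L)
  expect_identical(out$truncation_point, 4)
  out2 <- apply_min_localization_threshold(mk(4L, 1), interval_time = 1)
  expect_identical(length(unique(out2$tracks$track_id)), 1L)

  # interval 10 s: < 2 localizations removed, L = 20 s
  out3 <- apply_min_localization_threshold(mk(1L, 10), interval_time = 10)
  expect_identical(nrow(out3$tracks), 0L)
  out4 <- apply_min_localization_threshold(mk(2L, 10), interval_time = 10)
  expect_identical(out4$truncation_point, 20)

  # all tracks above threshold: unchanged
  tr <- mk(6L, 1)
  out5 <- apply_min_localization_threshold(tr, interval_time = 1)
  expect_identical(out5$tracks$track_id, tr$track_id)

  expect_error(apply_min_localization_threshold(tr, interval_time = 3),
               "threshold")
})

test_that("rebinding gaps are the time between a track end and the next start", {
  # two tracks at the same spot separated by 10 frames at 2 s interval
  tab <- loc_table(frame = c(0, 1, 11, 12), x = c(0, 0, 10, 10),
                   y = rep(0, 4))
  tr <- link_localizations(tab, interval_time = 2)
  expect_length(unique(tr$track_id), 2L)
  expect_equal(detect_rebinding(tr, radius = 300), 20)

  # tracks 500 nm apart: no event
  tab2 <- loc_table(frame = c(0, 1, 11, 12), x = c(0, 0, 500, 500),
                    y = rep(0, 4))
  expect_length(detect_rebinding(link_localizations(tab2, interval_time = 2),
                                 radius = 300), 0L)

  # repeated-binder stream: K binding events yield K - 1 gaps
  k <- 5L
  frames <- unlist(lapply(seq_len(k), function(i) (i - 1) * 20 + 0:2))
  tab3 <- loc_table(frame = frames, x = rep(0, 3 * k), y = rep(0, 3 * k))
  tr3 <- link_localizations(tab3, interval_time = 2)
  expect_length(unique(tr3$track_id), k)
  gaps <- detect_rebinding(tr3, radius = 300)
  expect_length(gaps, k - 1L)
  expect_equal(gaps, rep((20 - 2) * 2, k - 1L))
})
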