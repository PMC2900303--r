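params2 <- detection_params(min_area_px = 2)

test_that("noise-free block scenes produce the exact expected events", {
  # constant stack: nothing to detect
  const <- ratio_stack(array(1.7, c(8, 8, 6)), dt_s = 15)
  expect_equal(nrow(detect_events(const)), 0)

  # 2x2 block elevated frames 2-3 (0-based): one 30-s transient
  ev <- list(pixels = rect_pixels(8, 3, 4, 3, 4), onset = 3, offset = 4, amp = 1)
  tab <- detect_events(make_block_scene(8, 8, 6, list(ev)), params2)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$onset_frame, 2L)
  expect_equal(tab$offset_frame, 3L)
  expect_equal(tab$duration_s, 30)
  expect_equal(tab$area_px, 4L)
  expect_equal(tab$label, "transient")
  expect_equal(tab$peak_delta_ratio, 1)
  expect_equal(tab$centroid_row, 2.5)  # 0-based centroid of rows 3:4
  expect_setequal(tab$footprint[[1]], ev$pixels)

  # same block elevated frames 1-5: sustained, 75 s
  ev_long <- list(pixels = ev$pixels, onset = 2, offset = 6, amp = 1)
  tab2 <- detect_events(make_block_scene(8, 8, 6, list(ev_long)), params2)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$duration_s, 75)
  expect_equal(tab2$label, "sustained")

  # two simultaneous disjoint blocks: two events with distinct ids
  evA <- list(pixels = rect_pixels(8, 1, 2, 1, 2), onset = 3, offset = 4, amp = 1)
  evB <- list(pixels = rect_pixels(8, 6, 7, 6, 7), onset = 3, offset = 4, amp = 0.5)
  tab3 <- detect_events(make_block_scene(8, 8, 6, list(evA, evB)), params2)
  expect_equal(nrow(tab3), 2)
  expect_equal(length(unique(tab3$id)), 2)

  expect_error(detect_events(ratio_stack(array(1, c(4, 4, 1)), dt_s = 15)),
               class = "caltrace_validation_error")
  allna <- ratio_stack(array(NA_real_, c(4, 4, 4)),
                       array(FALSE, c(4, 4, 4)), dt_s = 15)
  expect_equal(nrow(detect_events(allna)), 0)
})

test_that("persistence boundary: 30 s is transient, 45 s is sustained", {
  px <- rect_pixels(10, 4, 6, 4, 6)
  two <- detect_events(make_block_scene(10, 10, 8, list(
    list(pixels = px, onset = 3, offset = 4, amp = 0.8))))
  three <- detect_events(make_block_scene(10, 10, 8, list(
    list(pixels = px, onset = 3, offset = 5, amp = 0.8))))
  expect_equal(two$duration_s, 30)
  expect_equal(two$label, "transient")
  expect_equal(three$duration_s, 45)
  expect_equal(three$label, "sustained")

  expect_equal(classify_duration(30), "transient")
  expect_equal(classify_duration(45), "sustained")
  expect_equal(classify_duration(15), "transient")
  expect_equal(classify_duration(30 + 1e-9), "sustained")
  expect_error(classify_duration(0), class = "caltrace_validation_error")
  expect_error(classify_duration(15, d_max_s = -1), class = "caltrace_validation_error")
})

test_that("detector equals the brute-force 3D oracle on random block scenes", {
  set.seed(404)
  n_scenes <- 40
  for (i in seq_len(n_scenes)) {
    sc <- random_block_scene()
    got <- detect_events(sc$stack, detection_params())
    want <- oracle_detect(sc$stack, min_area_px = 4)
    expect_equal(nrow(got), nrow(want), info = sprintf("scene %d: count", i))
    expect_identical(event_signature(got), event_signature(want),
                     info = sprintf("scene %d: events", i))
    expect_identical(sort(got$label), sort(want$label),
                     info = sprintf("scene %d: labels", i))
  }
})

test_that("raising the threshold never increases the event count", {
  set.seed(77)
  sim <- simulate_scene(small_session(seed = 5, rate = 25))
  ratios <- compute_ratio(sim$stack, compute_embryo_mask(sim$stack))
  counts <- vapply(c(2, 4, 6, 10), function(k) {
    nrow(detect_events(ratios, detection_params(k_sigma = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("shifting the scene shifts centroids by exactly the same offset", {
  base_events <- list(
    list(pixels = rect_pixels(16, 3, 5, 3, 5), onset = 3, offset = 4, amp = 1),
    list(pixels = disc_pixels(16, 16, 10, 10, 2), onset = 9, offset = 9, amp = 0.6))
  tab0 <- detect_events(make_block_scene(16, 16, 14, base_events))
  for (shift in list(c(2, 1), c(0, 3), c(4, 4))) {
    shifted <- lapply(base_events, function(ev) {
      r <- (ev$pixels - 1) %% 16 + 1 + shift[1]
      c <- (ev$pixels - 1) %/% 16 + 1 + shift[2]
      ev$pixels <- (c - 1) * 16 + r
      ev
    })
    tab1 <- detect_events(make_block_scene(16, 16, 14, shifted))
    expect_equal(tab1$centroid_row, tab0$centroid_row + shift[1])
    expect_equal(tab1$centroid_col, tab0$centroid_col + shift[2])
    expect_equal(tab1$onset_frame, tab0$onset_frame)
  }
})

test_that("events in disjoint regions detect identically alone or together", {
  evA <- list(pixels = rect_pixels(16, 2, 4, 2, 4), onset = 3, offset = 4, amp = 0.9)
  evB <- list(pixels = disc_pixels(16, 16, 12, 12, 2), onset = 8, offset = 10, amp = 0.5)
  tabA <- detect_events(make_block_scene(16, 16, 14, list(evA)))
  tabB <- detect_events(make_block_scene(16, 16, 14, list(evB)))
  tabAB <- detect_events(make_block_scene(16, 16, 14, list(evA, evB)))
  expect_equal(nrow(tabAB), nrow(tabA) + nrow(tabB))
  expect_identical(event_signature(tabAB),
                   c(event_signature(tabA), event_signature(tabB)))
})

test_that("a rise on top of a sustained plateau is a separate transient", {
  # sustained domain from frame 2 onward; a transient pops on top of it
  dom <- list(pixels = rect_pixels(12, 4, 9, 4, 9), onset = 2, offset = 16, amp = 0.4)
  pop <- list(pixels = rect_pixels(12, 5, 7, 5, 7), onset = 8, offset = 9, amp = 0.5)
  h <- 12; hw <- 12 * 12
  r <- array(1, c(12, 12, 16))
  for (t in dom$onset:min(16, dom$offset)) r[dom$pixels + (t - 1) * hw] <- 1 + dom$amp
  for (t in pop$onset:pop$offset) {
    r[pop$pixels + (t - 1) * hw] <- r[pop$pixels + (t - 1) * hw] + pop$amp
  }
  tab <- detect_events(ratio_stack(r, dt_s = 15))
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$label), c("sustained", "transient"))
  tr <- tab[tab$label == "transient", ]
  expect_equal(tr$onset_frame, pop$onset - 1L)
  expect_equal(tr$duration_s, 30)
  expect_equal(tr$peak_delta_ratio, pop$amp)
})

test_that("detection parameters validate their domains", {
  expect_error(detection_params(k_sigma = 0), class = "caltrace_validation_error")
  expect_error(detection_params(min_area_px = 0), class = "caltrace_validation_error")
  expect_error(detection_params(d_max_s = -5), class = "caltrace_validation_error")
  expect_error(detection_params(link_min_overlap = 0), class = "caltrace_validation_error")
  expect_error(detection_params(link_min_overlap = 1.2), class = "caltrace_validation_error")
  expect_s3_class(detection_params(), "detection_params")
})
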