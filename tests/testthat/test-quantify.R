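make_rate_table <- function(onsets_s, labels = NULL, dt_s = 15, n_frames = 480) {
  n <- length(onsets_s)
  if (is.null(labels)) labels <- rep("transient", n)
  caltrace:::new_event_table(
    tibble::tibble(
      id = seq_len(max(n, 0)), onset_frame = as.integer(onsets_s / dt_s),
      offset_frame = as.integer(onsets_s / dt_s) + 1L,
      duration_s = rep(30, n), centroid_row = rep(1, n), centroid_col = rep(1, n),
      area_px = rep(4L, n), peak_delta_ratio = rep(0.5, n), label = labels,
      footprint = replicate(n, 1:4, simplify = FALSE)),
    dt_s = dt_s, height = 64, width = 64, n_frames = n_frames)
}

test_that("stage clock and window arithmetic", {
  expect_equal(window_hours(stage_clock(2, 3), 6, 12), 2)
  expect_equal(window_hours(stage_clock(2, 6), 6, 12), 1)
  expect_error(window_hours(stage_clock(), 12, 6), class = "caltrace_validation_error")
  expect_error(stage_clock(somites_per_hour = 0), class = "caltrace_validation_error")
})

test_that("transients per hour counts onsets in the stage window", {
  clock <- stage_clock(s0 = 2, somites_per_hour = 5)  # 6->12 somites = 1.2 h
  empty <- make_rate_table(numeric(0))
  expect_equal(rate_per_hour(empty, clock, 6, 12), 0)

  # 4 transients in a 0.75-h window -> 5.333...
  clock2 <- stage_clock(s0 = 6, somites_per_hour = 8)  # [6, 12] = 0.75 h
  tab <- make_rate_table(c(100, 500, 900, 1300), n_frames = 240)
  expect_equal(rate_per_hour(tab, clock2, 6, 12), 4 / 0.75)

  # sustained events are excluded: 10 events, 3 sustained, 1-h window
  clock3 <- stage_clock(s0 = 6, somites_per_hour = 6)
  onsets <- seq(0, 3400, length.out = 10)
  labs <- rep("transient", 10); labs[c(2, 5, 9)] <- "sustained"
  tab3 <- make_rate_table(onsets, labs, n_frames = 240)
  expect_equal(rate_per_hour(tab3, clock3, 6, 12), 7)

  # window outside the session span errors
  expect_error(rate_per_hour(make_rate_table(100, n_frames = 60), clock, 6, 12),
               class = "caltrace_validation_error")
})

test_that("rates are additive over adjacent windows", {
  set.seed(9)
  clock <- stage_clock(2, 5)
  tab <- make_rate_table(sort(runif(40, 0, 7200)))
  n_total <- sum(
    rate_per_hour(tab, clock, 4, 7) * window_hours(clock, 4, 7),
    rate_per_hour(tab, clock, 7, 12) * window_hours(clock, 7, 12))
  expect_equal(n_total,
               rate_per_hour(tab, clock, 4, 12) * window_hours(clock, 4, 12))
})

test_that("Fisher exact two-tailed p follows the small-probability rule", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, 2)), 2 / choose(20, 10))

  x <- matrix(c(8, 1, 2, 9), 2, 2)
  expect_equal(fisher_exact_2x2(x), fisher_oracle(x), tolerance = 1e-12)
  # independent route: stats::fisher.test uses the same two-sided convention
  expect_equal(fisher_exact_2x2(x), stats::fisher.test(x)$p.value, tolerance = 1e-9)

  expect_error(fisher_exact_2x2(matrix(c(1, 2, 3), 1, 3)),
               class = "caltrace_validation_error")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2, 2)),
               class = "caltrace_validation_error")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2)),
               class = "caltrace_validation_error")
})

test_that("Fisher p is invariant to transposition and simultaneous row/col swaps", {
  set.seed(31)
  for (i in 1:25) {
    x <- matrix(rpois(4, 6) + 1, 2, 2)
    p <- fisher_exact_2x2(x)
    expect_equal(fisher_exact_2x2(t(x)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(x[2:1, 2:1]), p, tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(x)$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA matches hand-computed sums of squares and base R", {
  # identical group means -> F = 0, p = 1
  d0 <- tibble::tibble(rate = rep(c(1, 3), 3),
                       group = rep(c("a", "b", "c"), each = 2))
  fit0 <- anova_oneway_tukey(d0)
  expect_equal(fit0$f_statistic, 0)
  expect_equal(fit0$p_value, 1)

  # {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6, df 2 and 6 -> F = 3
  d1 <- tibble::tibble(rate = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                       group = rep(c("g1", "g2", "g3"), each = 3))
  fit1 <- anova_oneway_tukey(d1)
  expect_equal(fit1$f_statistic, 3)
  expect_equal(fit1$df_between, 2)
  expect_equal(fit1$df_within, 6)

  # cross-check F, p and Tukey adjusted p against aov/TukeyHSD
  set.seed(42)
  d2 <- tibble::tibble(rate = rnorm(18, rep(c(5, 9, 6), each = 6), 2),
                       group = rep(c("wt", "mo", "resc"), each = 6))
  fit2 <- anova_oneway_tukey(d2)
  ref <- stats::aov(rate ~ group, data = d2)
  ref_f <- summary(ref)[[1]]$`F value`[1]
  ref_p <- summary(ref)[[1]]$`Pr(>F)`[1]
  expect_equal(fit2$f_statistic, ref_f, tolerance = 1e-10)
  expect_equal(fit2$p_value, ref_p, tolerance = 1e-10)
  ref_tk <- stats::TukeyHSD(ref)$group
  got <- tidy(fit2)
  for (i in seq_len(nrow(got))) {
    key <- paste0(got$group2[i], "-", got$group1[i])
    key2 <- paste0(got$group1[i], "-", got$group2[i])
    row <- if (key %in% rownames(ref_tk)) ref_tk[key, ] else ref_tk[key2, ]
    expect_equal(got$p_adj[i], unname(row["p adj"]), tolerance = 1e-6)
  }
  # glance returns the omnibus row
  expect_equal(glance(fit2)$f_statistic, ref_f, tolerance = 1e-10)

  expect_error(anova_oneway_tukey(d1[1:3, ]), class = "caltrace_validation_error")
  expect_error(anova_oneway_tukey(tibble::tibble(rate = c(1, 1, 2, 2),
                                                 group = c("a", "a", "b", "b"))),
               class = "caltrace_degenerate_error")
})

test_that("ANOVA F is invariant to shifting and scaling all observations", {
  set.seed(13)
  d <- tibble::tibble(rate = rnorm(12, rep(c(2, 6, 3, 9), each = 3)),
                      group = rep(letters[1:4], each = 3))
  f0 <- anova_oneway_tukey(d)$f_statistic
  expect_equal(anova_oneway_tukey(dplyr::mutate(d, rate = rate + 100))$f_statistic, f0)
  expect_equal(anova_oneway_tukey(dplyr::mutate(d, rate = rate * 7.3))$f_statistic, f0)
})

test_that("group summaries aggregate per-embryo rates in the report shape", {
  clock <- stage_clock(s0 = 6, somites_per_hour = 6)  # [6,12] = 1 h
  one <- make_rate_table(seq(100, 3500, length.out = 5), n_frames = 240)
  res <- summarize_groups(list(wt = list(one)), clock, 6, 12)
  expect_equal(res$summary$mean_rate, 5)
  expect_equal(res$summary$n, 1L)
  expect_null(res$anova)

  # two identical groups -> F = 0 (embryos differ within group)
  two <- make_rate_table(seq(100, 3500, length.out = 7), n_frames = 240)
  res2 <- summarize_groups(list(a = list(one, two), b = list(one, two)),
                           clock, 6, 12)
  expect_equal(res2$anova$f_statistic, 0)
  expect_equal(sort(res2$summary$mean_rate), c(6, 6))

  expect_error(summarize_groups(list(list(one)), clock, 6, 12),
               class = "caltrace_validation_error")
})
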