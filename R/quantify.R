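#' Developmental stage clock
#'
#' Maps acquisition time to somite stage: `stage(t) = s0 +
#' somites_per_hour * t / 3600`, with `t` in seconds from acquisition
#' start. The default (start at somite 2, 5 somites added per hour) makes a
#' 2-hour session span roughly somites 2 to 12; both values are
#' configuration, not biology baked in.
#'
#' @param s0 Somite number at `t = 0`. Default 2.
#' @param somites_per_hour Rate of somite addition (> 0). Default 5.
#' @return A `stage_clock`.
#' @export
stage_clock <- function(s0 = 2, somites_per_hour = 5) {
  if (!is.numeric(somites_per_hour) || somites_per_hour <= 0) {
    stop_validation("somites_per_hour must be > 0")
  }
  structure(list(s0 = s0, somites_per_hour = somites_per_hour),
            class = "stage_clock")
}

stage_at <- function(clock, t_s) clock$s0 + clock$somites_per_hour * t_s / 3600

#' Duration of a somite-stage window in hours
#'
#' @param clock A [stage_clock()].
#' @param s_lo,s_hi Window bounds in somite numbers, `s_lo < s_hi`.
#' @return Hours: `(s_hi - s_lo) / somites_per_hour`.
#' @export
window_hours <- function(clock, s_lo, s_hi) {
  stopifnot(inherits(clock, "stage_clock"))
  if (!is.numeric(s_lo) || !is.numeric(s_hi) || s_lo >= s_hi) {
    stop_validation("stage window requires s_lo < s_hi")
  }
  (s_hi - s_lo) / clock$somites_per_hour
}

#' Transients per hour within a developmental-stage window
#'
#' Counts transient events whose onset time falls inside the half-open
#' stage window `[s_lo, s_hi)` (half-open so that adjacent windows
#' partition a session) and divides by the window duration in hours.
#'
#' @param table An event table with `dt_s` metadata.
#' @param clock A [stage_clock()].
#' @param s_lo,s_hi Stage window, `s_lo < s_hi`.
#' @param check_span Validate that the window lies within the session's
#'   stage span (requires `n_frames` metadata)? Default `TRUE` when the
#'   metadata is present.
#' @return Events per hour (numeric scalar).
#' @export
rate_per_hour <- function(table, clock, s_lo, s_hi, check_span = TRUE) {
  stopifnot(inherits(clock, "stage_clock"))
  hours <- window_hours(clock, s_lo, s_hi)
  dt_s <- attr(table, "dt_s")
  t0_s <- attr(table, "t0_s") %||% 0
  if (is.null(dt_s) || is.na(dt_s)) stop_validation("event table lacks dt_s metadata")
  nf <- attr(table, "n_frames")
  if (isTRUE(check_span) && !is.null(nf) && !is.na(nf)) {
    # n frames at dt sampling cover n * dt of session time
    span <- stage_at(clock, t0_s + c(0, nf * dt_s))
    if (s_lo < span[1] || s_hi > span[2]) {
      stop_validation(sprintf(
        "stage window [%g, %g] outside the session span [%g, %g]",
        s_lo, s_hi, span[1], span[2]))
    }
  }
  tr <- table[table$label == "transient", , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  s_on <- stage_at(clock, t0_s + tr$onset_frame * dt_s)
  sum(s_on >= s_lo & s_on < s_hi) / hours
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution of the
#' top-left cell given fixed margins. The two-tailed p-value follows the
#' sum-of-small-probabilities rule: the sum of probabilities of all tables
#' with the same margins whose point probability does not exceed that of
#' the observed table (ties admitted within relative tolerance 1e-7).
#'
#' @param x 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!identical(dim(x), c(2L, 2L))) stop_validation("x must be a 2x2 table")
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop_validation("x must contain non-negative integers")
  }
  r <- rowSums(x); cs <- colSums(x)
  if (any(r == 0) || any(cs == 0)) stop_validation("all margins must be positive")
  n <- sum(x)
  support <- max(0, r[1] - cs[2]):min(r[1], cs[1])
  pk <- dhyper(support, cs[1], cs[2], r[1])
  p_obs <- dhyper(x[1, 1], cs[1], cs[2], r[1])
  p <- sum(pk[pk <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Textbook one-way analysis of variance on per-embryo rates (or any
#' per-unit measurements), followed by Tukey's honestly-significant-
#' difference test on all group pairs (Tukey-Kramer for unequal group
#' sizes), using the studentized-range distribution. All pairs are tested
#' regardless of the omnibus F.
#'
#' @param data A data frame with one row per observation.
#' @param value,group Columns holding the measurement and the group label
#'   (tidy-eval; defaults `rate` and `group`).
#' @return An `anova_tukey` object; see [tidy()] for the pairwise table and
#'   [glance()] for the omnibus row.
#' @export
anova_oneway_tukey <- function(data, value = rate, group = group) {
  df <- tibble(value = dplyr::pull(data, {{ value }}),
               group = as.character(dplyr::pull(data, {{ group }})))
  if (anyNA(df$value)) stop_validation("missing values in measurements")
  sizes <- table(df$group)
  k <- length(sizes)
  if (k < 2) stop_validation("need at least 2 groups")
  if (any(sizes < 2)) stop_validation("every group needs at least 2 observations")
  n_tot <- nrow(df)
  means <- tapply(df$value, df$group, mean)
  grand <- mean(df$value)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((df$value - means[df$group])^2)
  df_between <- k - 1
  df_within <- n_tot - k
  if (ss_within == 0) stop_degenerate("zero within-group variance")
  ms_within <- ss_within / df_within
  f_stat <- (ss_between / df_between) / ms_within
  p_val <- pf(f_stat, df_between, df_within, lower.tail = FALSE)

  gl <- names(means)
  pairs <- utils::combn(gl, 2)
  tukey <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = as.numeric(means[pairs[2, ]] - means[pairs[1, ]]),
    q = abs(.data$diff) /
      sqrt(ms_within / 2 * (1 / as.numeric(sizes[pairs[1, ]]) +
                            1 / as.numeric(sizes[pairs[2, ]]))),
    p_adj = ptukey(.data$q, nmeans = k, df = df_within, lower.tail = FALSE)
  )
  structure(
    list(f_statistic = f_stat, df_between = df_between, df_within = df_within,
         p_value = p_val, ms_within = ms_within,
         group_means = tibble(group = gl, n = as.integer(sizes[gl]),
                              mean = as.numeric(means[gl])),
         tukey = tukey),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat("Tukey HSD adjusted p-values:\n")
  print(as.data.frame(x$tukey), digits = 4)
  invisible(x)
}

#' @rdname anova_oneway_tukey
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @method tidy anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @rdname anova_oneway_tukey
#' @method glance anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df_between = x$df_between,
         df_within = x$df_within, p_value = x$p_value)
}

#' Per-group transient-rate summary with group statistics
#'
#' Applies [rate_per_hour()] to each embryo's event table, aggregates per
#' group (mean rate, n), and, when at least two groups have two or more
#' embryos, runs [anova_oneway_tukey()] across groups.
#'
#' @param tables Named list: group label -> list of per-embryo event
#'   tables.
#' @param clock A [stage_clock()].
#' @param s_lo,s_hi Stage window.
#' @param ... Passed to [rate_per_hour()].
#' @return A list with `rates` (tibble: group, embryo, rate), `summary`
#'   (tibble: group, n, mean_rate) and `anova` (an `anova_tukey` or NULL).
#' @export
summarize_groups <- function(tables, clock, s_lo, s_hi, ...) {
  if (!is.list(tables) || is.null(names(tables)) || any(names(tables) == "")) {
    stop_validation("tables must be a named list of per-group table lists")
  }
  if (any(lengths(tables) < 1)) stop_validation("every group needs >= 1 embryo")
  rates <- bind_rows(lapply(names(tables), function(g) {
    tibble(group = g, embryo = seq_along(tables[[g]]),
           rate = map_dbl(tables[[g]], rate_per_hour, clock = clock,
                          s_lo = s_lo, s_hi = s_hi, ...))
  }))
  summary <- rates |>
    group_by(.data$group) |>
    summarise(n = n(), mean_rate = mean(.data$rate), .groups = "drop")
  fit <- NULL
  eligible <- sum(lengths(tables) >= 2) >= 2
  if (eligible) {
    sub <- rates[rates$group %in% names(tables)[lengths(tables) >= 2], ]
    fit <- anova_oneway_tukey(sub, value = rate, group = group)
  }
  list(rates = rates, summary = summary, anova = fit)
}
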