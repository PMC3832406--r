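#' Coral recovery between two bleaching events
#'
#' Summarises post-bleaching recovery the way management tables report it:
#' coral cover immediately after the first event (read the day after the
#' event), the absolute increase in cover (percentage points) up to the eve
#' of the second event (read the day before), and the relative increase as
#' a percentage of the post-event cover. When cover does not increase the
#' recovery fields are flagged (`recovered = FALSE`) rather than reported
#' as negative changes.
#'
#' @param traj a `reef_trajectory` (or an ensemble-mean state matrix with a
#'   `days` attribute; see [ensemble_mean_trajectory()] — a plain matrix is
#'   assumed to start at day 0).
#' @param first_event_year,second_event_year the two event years
#'   (`first < second`, both within the horizon).
#' @return Object of class `"coral_recovery"`: list with `cover_post_event`
#'   (% cover), `cover_pre_second` (%), `absolute_increase` (percentage
#'   points), `relative_increase` (% of post-event cover), `recovered`
#'   flag, and rounded whole-percent versions (`cover_post_round`,
#'   `absolute_round`, `relative_round`) matching tabulated output.
#' @export
coral_recovery <- function(traj, first_event_year = 20,
                           second_event_year = 38) {
  if (first_event_year >= second_event_year)
    stop("events out of order: first_event_year must be < second_event_year")
  states <- if (inherits(traj, "reef_trajectory")) traj$states else
    as.matrix(traj)
  n_days <- nrow(states) - 1
  d_post <- round(first_event_year * 365) + 1
  d_pre <- round(second_event_year * 365) - 1
  if (d_post < 0 || d_pre > n_days)
    stop("event years outside the simulated horizon")
  post <- unname(100 * states[d_post + 1, "coral"])
  pre2 <- unname(100 * states[d_pre + 1, "coral"])
  abs_inc <- pre2 - post
  recovered <- abs_inc > 0
  rel_inc <- if (recovered && post > 0) 100 * abs_inc / post else NA_real_
  structure(list(cover_post_event = post, cover_pre_second = pre2,
                 absolute_increase = if (recovered) abs_inc else NA_real_,
                 relative_increase = rel_inc, recovered = recovered,
                 cover_post_round = round(post),
                 absolute_round = if (recovered) round(abs_inc) else
                   NA_real_,
                 relative_round = if (recovered && post > 0)
                   round(100 * abs_inc / post) else NA_real_),
            class = "coral_recovery")
}

#' @export
print.coral_recovery <- function(x, ...) {
  if (x$recovered)
    cat(sprintf("Coral recovery: post-event cover %.1f%%, +%.1f points (+%.0f%% relative)\n",
                x$cover_post_event, x$absolute_increase,
                x$relative_increase))
  else
    cat(sprintf("Coral recovery: post-event cover %.1f%%, no recovery\n",
                x$cover_post_event))
  invisible(x)
}

#' Time until coral cover collapses to a threshold
#'
#' First day at which coral cover is at or below `threshold`, converted to
#' years (day / 365, rounded up). The default threshold of 0.5% cover is the
#' point at which cover rounds to zero at the whole-percent resolution used
#' to report reef state; the model's constant external larval supply keeps
#' cover strictly positive, so literal zero is never reached.
#'
#' @param traj a `reef_trajectory` or state matrix (daily rows from day 0).
#' @param threshold collapse threshold in % cover (default 0.5).
#' @return Years to collapse (0 if the initial state is already at or below
#'   the threshold), or `NA` if the threshold is never reached.
#' @export
time_to_collapse <- function(traj, threshold = 0.5) {
  if (threshold < 0) stop("threshold must be >= 0")
  states <- if (inherits(traj, "reef_trajectory")) traj$states else
    as.matrix(traj)
  hit <- which(100 * states[, "coral"] <= threshold + 1e-12)
  if (!length(hit)) return(NA_real_)
  ceiling((hit[1] - 1) / 365)
}

#' Ensemble summary at selected years
#'
#' Mean and standard deviation of every state variable across the replicate
#' runs of an ensemble at the requested years, plus the combined `algae`
#' series (macroturf + macroalgal cover), as plotted in ensemble trajectory
#' figures.
#'
#' @param ensemble a `reef_ensemble`.
#' @param years years to summarise (default every year of the horizon).
#' @return Object of class `"ensemble_summary"`: data frame with columns
#'   `year`, `variable`, `mean`, `sd` (covers as proportions, biomasses in
#'   g m-2; `algae = macroturf + macroalgae`).
#' @export
ensemble_summary <- function(ensemble, years = NULL) {
  if (is.null(years)) years <- 0:ensemble$horizon_years
  if (any(years < 0 | years > ensemble$horizon_years))
    stop("years outside the ensemble horizon")
  snaps <- lapply(ensemble$trajectories, trajectory_at_years, years = years)
  vars <- colnames(snaps[[1]])
  rows <- list()
  for (yi in seq_along(years)) {
    vals <- t(vapply(snaps, function(s) s[yi, ], numeric(length(vars))))
    vals <- cbind(vals, algae = vals[, "macroturf"] + vals[, "macroalgae"])
    rows[[yi]] <- data.frame(year = years[yi],
                             variable = colnames(vals),
                             mean = colMeans(vals),
                             sd = apply(vals, 2, sd),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' @export
plot.ensemble_summary <- function(x, variables = c("coral", "algae",
                                                   "herbivore"), ...) {
  op <- par(mfrow = c(length(variables), 1), mar = c(3, 4, 1, 1))
  on.exit(par(op))
  for (v in variables) {
    s <- x[x$variable == v, ]
    plot(s$year, s$mean, type = "l", xlab = "year", ylab = v, ...)
    lines(s$year, s$mean + s$sd, lty = 2)
    lines(s$year, pmax(s$mean - s$sd, 0), lty = 2)
  }
  invisible(x)
}

#' Table of recovery metrics across sites and fishing scenarios
#'
#' Convenience reduction producing a Table-5-shaped data frame: one row per
#' (site, fishing scenario), with post-event cover, absolute and relative
#' increase between two fixed bleaching events, computed on the
#' ensemble-mean trajectory.
#'
#' @param ensembles named list of `reef_ensemble` objects (names used as row
#'   labels, e.g. "lucero_like/high").
#' @param first_event_year,second_event_year the two fixed event years.
#' @return Data frame with columns `run`, `site`, `scenario`,
#'   `cover_post`, `absolute`, `relative`, `recovered`.
#' @export
recovery_table <- function(ensembles, first_event_year = 20,
                           second_event_year = 38) {
  rows <- lapply(names(ensembles), function(nm) {
    en <- ensembles[[nm]]
    rec <- coral_recovery(ensemble_mean_trajectory(en),
                          first_event_year, second_event_year)
    data.frame(run = nm, site = en$site_label,
               scenario = en$scenario$fishing_level,
               cover_post = rec$cover_post_round,
               absolute = rec$absolute_round,
               relative = rec$relative_round,
               recovered = rec$recovered, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @importFrom graphics lines par plot
NULL
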