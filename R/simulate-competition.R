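#' Growth model for a two- or three-strain competition
#'
#' Growth over each sampling interval is effective exponential at rate
#' ln(2)/T: the reference strain doubles every `T` hours, the competitor
#' every `T * (1 + delta)` hours, so the expected log count ratio
#' (reference/competitor) gains
#' `interval * ln(2) * (1/T - 1/(T * (1 + delta)))` per interval, plus
#' `marker_offset` (a per-day slope offset mimicking the fitness burden of
#' the fluorescent markers themselves).
#'
#' @param T Reference doubling time in hours (default 4.5).
#' @param delta Fractional doubling-time difference of the competitor (> -1).
#' @param interval Sampling interval in hours (default 24).
#' @param events_per_day Gated events recorded per measurement (default
#'   10000).
#' @param marker_offset Additional per-day slope on the log ratio (default 0).
#' @param wt_delta Fractional doubling-time difference of the unmarked wild
#'   type in triple competitions (default 0).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(T = 4.5, delta = 0, interval = 24,
                         events_per_day = 10000L, marker_offset = 0,
                         wt_delta = 0) {
  stopifnot(T > 0, delta > -1, wt_delta > -1, interval > 0,
            events_per_day >= 1)
  structure(list(T = T, delta = delta, interval = interval,
                 events_per_day = as.integer(events_per_day),
                 marker_offset = marker_offset, wt_delta = wt_delta),
            class = "growth_model")
}

#' Fluorescent subpopulation description
#'
#' Event intensities are lognormal per channel: a positive channel is drawn
#' around `median` with coefficient of variation `cv`; negative channels draw
#' from a shared autofluorescence lognormal (the same one used for the
#' non-fluorescent control).
#'
#' @param median Median intensity of the positive channel(s), arbitrary
#'   units.
#' @param cv Lognormal coefficient of variation (>= 0).
#' @return A list used by [simulate_competition()].
#' @export
fluor_population <- function(median = 1e4, cv = 0.25) {
  stopifnot(median > 0, cv >= 0)
  list(median = median, cv = cv)
}

rlnorm_cv <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  median * exp(stats::rnorm(n, 0, sdlog))
}

#' Simulate a non-fluorescent control well
#'
#' @param n Number of events.
#' @param autofluor Autofluorescence population (a [fluor_population()]).
#' @param seed Optional integer seed.
#' @return Event data frame with columns `mng`, `mcherry`.
#' @export
simulate_control_events <- function(n, autofluor = fluor_population(10, 0.4),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(mng = rlnorm_cv(n, autofluor$median, autofluor$cv),
             mcherry = rlnorm_cv(n, autofluor$median, autofluor$cv))
}

#' Simulate a competition assay sampled daily by flow cytometry
#'
#' Two (or, with `wild_type = TRUE`, three) strains grow exponentially; every
#' `interval` hours the co-culture is sampled by recording
#' `events_per_day` events drawn multinomially from the current population
#' fractions. The mNG-marked strain grows at ln(2)/T, the mCherry-marked
#' strain at ln(2)/(T(1+delta)), the optional unmarked wild type at ln(2)/T.
#' Daily dilution is not modeled explicitly: it multiplies all populations
#' equally and cancels from every count ratio.
#'
#' @param model A [growth_model()].
#' @param days Number of post-baseline days (measurements at day 0..days).
#' @param populations List with elements `mng`, `mcherry`, `autofluor`
#'   ([fluor_population()]s) controlling event intensities.
#' @param wild_type Include an unmarked wild-type strain (triple
#'   competition)?
#' @param init_fractions Starting population fractions (recycled/normalized);
#'   default equal.
#' @param events Also return the per-event intensity table? (Set `FALSE` for
#'   large replicate runs where only the counts are needed.)
#' @param well Well label written into the event table.
#' @param seed Optional integer seed.
#' @return A list with `counts` (true-label per-day counts, columns as in
#'   [count_series()]), `events` (event table with `well`, `day`, `event_id`,
#'   `mng`, `mcherry`, or `NULL`), and `expected_alpha`, the closed-form
#'   slope of ln(n_mng/n_mcherry) per day.
#' @examples
#' sim <- simulate_competition(growth_model(delta = 0.05), days = 3, seed = 1)
#' estimate_alpha(sim$counts)
#' @export
simulate_competition <- function(model = growth_model(), days = 3,
                                 populations = list(
                                   mng = fluor_population(1e4, 0.25),
                                   mcherry = fluor_population(1e4, 0.25),
                                   autofluor = fluor_population(10, 0.4)),
                                 wild_type = FALSE,
                                 init_fractions = NULL,
                                 events = TRUE, well = "A1", seed = NULL) {
  stopifnot(inherits(model, "growth_model"), days >= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- if (wild_type) c("mng", "mcherry", "wt") else c("mng", "mcherry")
  k <- length(classes)
  if (is.null(init_fractions)) init_fractions <- rep(1 / k, k)
  stopifnot(length(init_fractions) == k, all(init_fractions > 0))
  f0 <- init_fractions / sum(init_fractions)

  day_rate <- function(T_hours) model$interval * log(2) / T_hours
  r <- c(mng = day_rate(model$T) + model$marker_offset,
         mcherry = day_rate(model$T * (1 + model$delta)),
         wt = day_rate(model$T * (1 + model$wt_delta)))[classes]

  af <- populations$autofluor
  ev_list <- if (events) vector("list", days + 1L) else NULL
  cnt <- matrix(0L, days + 1L, k, dimnames = list(NULL, classes))
  for (d in 0:days) {
    w <- f0 * exp(r * d)
    p <- w / sum(w)
    n <- stats::rmultinom(1L, model$events_per_day, p)[, 1L]
    cnt[d + 1L, ] <- n
    if (events) {
      mng_i <- c(rlnorm_cv(n["mng"], populations$mng$median,
                           populations$mng$cv),
                 rlnorm_cv(sum(n) - n["mng"], af$median, af$cv))
      mch_i <- c(rlnorm_cv(n["mng"], af$median, af$cv),
                 rlnorm_cv(n["mcherry"], populations$mcherry$median,
                           populations$mcherry$cv),
                 rlnorm_cv(if (wild_type) n["wt"] else 0L, af$median, af$cv))
      ev_list[[d + 1L]] <- data.frame(
        well = well, day = d, event_id = seq_len(sum(n)),
        mng = mng_i, mcherry = mch_i)
    }
  }
  counts <- data.frame(day = 0:days,
                       n_mng = cnt[, "mng"],
                       n_mcherry = cnt[, "mcherry"],
                       n_double = 0L,
                       n_wt = if (wild_type) cnt[, "wt"] else 0L)
  counts$n_total <- counts$n_mng + counts$n_mcherry + counts$n_double +
    counts$n_wt
  list(counts = counts,
       events = if (events) do.call(rbind, ev_list) else NULL,
       expected_alpha = model$interval * log(2) *
         (1 / model$T - 1 / (model$T * (1 + model$delta))) +
         model$marker_offset)
}
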