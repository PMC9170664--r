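#' Experience-sampling schedule settings
#'
#' Defaults emulate a typical smartphone ESM protocol: ten beeps per day
#' placed by stratified random sampling in a 10:00-22:00 window (mean gap
#' of 72 minutes between consecutive beeps) and 87% compliance.
#'
#' @param days number of days.
#' @param beeps_per_day beeps per day (default 10).
#' @param window_start,window_end daily window in clock hours (defaults 10
#'   and 22).
#' @param compliance probability that a beep is answered (default 0.87).
#' @return a validated settings list.
#' @export
scheduleConfig <- function(days, beeps_per_day = 10L, window_start = 10,
                           window_end = 22, compliance = 0.87) {
    stopifnot(days >= 1, beeps_per_day >= 1, window_end > window_start,
              compliance > 0, compliance <= 1)
    list(days = as.integer(days), beeps_per_day = as.integer(beeps_per_day),
         window_start = window_start, window_end = window_end,
         compliance = compliance)
}

#' Generate a stratified-random beep schedule
#'
#' Splits each day's window into \code{beeps_per_day} equal strata and
#' draws one beep time uniformly within each stratum, so times are
#' strictly increasing within a day. Each beep is independently missed
#' with probability \code{1 - compliance}. Uses R's RNG; seed with
#' \code{set.seed} for reproducibility.
#'
#' @param config settings from \code{\link{scheduleConfig}}.
#' @return data frame with columns \code{time} (hours since the start of
#'   day 0), \code{day} and \code{answered}.
#' @examples
#' set.seed(1)
#' sched <- esmSchedule(scheduleConfig(days = 2))
#' head(sched)
#' @export
esmSchedule <- function(config) {
    b <- config$beeps_per_day
    width <- (config$window_end - config$window_start) / b
    out <- lapply(seq_len(config$days) - 1L, function(d) {
        starts <- config$window_start + width * (seq_len(b) - 1L)
        times <- d * 24 + starts + stats::runif(b) * width
        data.frame(time = times, day = d,
                   answered = stats::runif(b) < config$compliance)
    })
    do.call(rbind, out)
}

# Sample one point from a probability field: draw a cell proportional to
# its mass, then jitter uniformly within the cell (sub-cell placement is
# not resolved by the lattice, so uniform is the natural choice).
.sampleField <- function(field, k = 1L) {
    n <- field@grid@n
    delta <- field@grid@delta
    cells <- sample.int(n * n, k, replace = TRUE, prob = field@mass)
    i <- (cells - 1L) %% n
    j <- (cells - 1L) %/% n
    cbind((i + stats::runif(k)) * delta, (j + stats::runif(k)) * delta)
}

#' Simulate an affect time series on a beep schedule
#'
#' The first answered beep of each day is drawn from the stationary
#' Boltzmann field; every later answered beep within the day is drawn from
#' the lattice-propagated conditional field given the previous answered
#' observation and the true inter-beep interval. Missed beeps keep their
#' slot with \code{NA} values. Uses R's RNG.
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param schedule data frame from \code{\link{esmSchedule}}.
#' @param grid an \linkS4class{AffectGrid} (default 30 x 30).
#' @return an \linkS4class{AffectTimeSeries}.
#' @export
simulateSeries <- function(params, schedule, grid = buildGrid(30)) {
    surface <- tabulatePotential(params, grid)
    kernel <- buildKernel(surface, params@D)
    stat <- stationaryField(surface)
    k <- nrow(schedule)
    vals <- matrix(NA_real_, k, 2)
    prev <- NULL
    prev_time <- NA_real_
    prev_day <- NA_integer_
    for (r in seq_len(k)) {
        if (!schedule$answered[r]) next
        if (is.na(prev_day) || schedule$day[r] != prev_day) {
            vals[r, ] <- .sampleField(stat)
        } else {
            cond <- propagate(deltaField(grid, prev), kernel,
                              schedule$time[r] - prev_time)$field
            vals[r, ] <- .sampleField(cond)
        }
        prev <- vals[r, ]
        prev_time <- schedule$time[r]
        prev_day <- schedule$day[r]
    }
    affectTimeSeries(schedule$time, vals, day = schedule$day,
                     valid = schedule$answered)
}

# Enlarged data set for the recovery experiment: along the chain of the
# base series, draw `multiplier` points from every within-day conditional
# field (conditioning on the base chain's previous true observation).
.enlargedPairSet <- function(params, series, multiplier,
                             grid = buildGrid(30)) {
    surface <- tabulatePotential(params, grid)
    kernel <- buildKernel(surface, params@D)
    pr <- .seriesPairs(series, likelihoodOptions())
    m <- length(pr$from)
    from <- series@values[pr$from, , drop = FALSE]
    to <- matrix(NA_real_, m * multiplier, 2)
    to_pair <- rep(seq_len(m), each = multiplier)
    for (q in seq_len(m)) {
        cond <- propagate(deltaField(grid, from[q, ]), kernel,
                          pr$interval[q])$field
        to[(q - 1L) * multiplier + seq_len(multiplier), ] <-
            .sampleField(cond, multiplier)
    }
    .pairSet(from, pr$interval, to, to_pair)
}

#' Parameter-recovery experiment
#'
#' For each true parameter set, simulates a base-size series on a fresh
#' ESM schedule and an enlarged data set with \code{multiplier} draws from
#' every conditional density along the same chain, fits the model to both
#' by differential evolution, and tabulates true against estimated values
#' for every parameter.
#'
#' @param true_params_list list of \linkS4class{AIMParameters}.
#' @param multiplier draws per conditional density for the enlarged
#'   condition (the full-scale design uses 100; scaled runs use less).
#' @param schedule_config settings from \code{\link{scheduleConfig}}.
#' @param de_config settings from \code{\link{deConfig}}.
#' @param options settings from \code{\link{likelihoodOptions}}.
#' @return data frame with columns \code{set}, \code{size}
#'   (\code{"base"} or \code{"enlarged"}), \code{parameter}, \code{true},
#'   \code{estimate}, \code{n_obs}.
#' @export
recoveryExperiment <- function(true_params_list, multiplier = 100L,
                               schedule_config = scheduleConfig(days = 7),
                               de_config = deConfig(),
                               options = likelihoodOptions()) {
    stopifnot(length(true_params_list) >= 1)
    rows <- list()
    for (s in seq_along(true_params_list)) {
        truth <- true_params_list[[s]]
        sched <- esmSchedule(schedule_config)
        base <- simulateSeries(truth, sched,
                               buildGrid(options$grid_n))
        enlarged <- .enlargedPairSet(truth, base, multiplier,
                                     buildGrid(options$grid_n))
        fit_base <- fitModel(base, modelId(truth), de_config, options)
        fit_big <- fitModel(enlarged, modelId(truth), de_config, options)
        tv <- paramVector(truth)
        for (cond in c("base", "enlarged")) {
            est <- paramVector(
                if (cond == "base") fit_base@params else fit_big@params)
            rows[[length(rows) + 1L]] <- data.frame(
                set = s, size = cond, parameter = names(tv), true = tv,
                estimate = est,
                n_obs = if (cond == "base") sum(base@valid)
                        else nrow(enlarged$to),
                row.names = NULL)
        }
    }
    do.call(rbind, rows)
}
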