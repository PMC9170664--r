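#' Likelihood evaluation settings
#'
#' @param grid_n lattice resolution (default 30; the resolution at which
#'   slider self-reports are informative).
#' @param initial_mode how the very first observation of a series enters
#'   the likelihood: \code{"skip"} (contributes nothing, only conditions
#'   the next point) or \code{"stationary"} (evaluated under the Boltzmann
#'   density).
#' @param night_mode how pairs straddling a day change are handled:
#'   \code{"skip_pairs"} (the overnight transition is dropped and the first
#'   observation of the day only conditions) or \code{"stationary_restart"}
#'   (the first observation of the day is evaluated under the Boltzmann
#'   density).
#' @param density_floor conditional densities are floored at this value so
#'   the objective stays finite on zero-mass cells.
#' @param step_budget cap on the total number of lattice updates one
#'   likelihood evaluation may spend; evaluations over budget return
#'   \code{Inf}. Guards the optimizer against near-stationary members whose
#'   tiny step size would ask for an enormous number of updates.
#' @return a validated settings list.
#' @export
likelihoodOptions <- function(grid_n = 30L,
                              initial_mode = c("skip", "stationary"),
                              night_mode = c("skip_pairs",
                                             "stationary_restart"),
                              density_floor = 1e-300,
                              step_budget = Inf) {
    stopifnot(density_floor > 0, step_budget > 0)
    list(grid_n = as.integer(grid_n),
         initial_mode = match.arg(initial_mode),
         night_mode = match.arg(night_mode),
         density_floor = density_floor,
         step_budget = step_budget)
}

#' Construct an affect time series
#'
#' @param time strictly increasing time stamps in hours.
#' @param values k x 2 matrix of (PA, NA) coordinates in the unit square;
#'   \code{NA} on invalid rows.
#' @param day integer day label per observation; defaults to
#'   \code{floor(time / 24)}.
#' @param valid logical flag per observation; defaults to complete rows.
#' @return an \linkS4class{AffectTimeSeries}.
#' @export
affectTimeSeries <- function(time, values, day = NULL, valid = NULL) {
    values <- as.matrix(values)
    if (is.null(day)) day <- as.integer(floor(time / 24))
    if (is.null(valid)) valid <- stats::complete.cases(values)
    new("AffectTimeSeries", time = as.numeric(time), values = values,
        day = as.integer(day), valid = as.logical(valid))
}

#' Rescale raw instrument ratings onto the unit square
#'
#' Maps ratings affinely from \code{[instrument_min, instrument_max]} to
#' \code{[0, 1]}. When several item columns are given per dimension they
#' are averaged first (the usual construction of PA and NA scores from
#' emotion items).
#'
#' @param raw data frame or matrix. Either two columns (PA, NA) or, with
#'   \code{pa_cols} / \code{na_cols}, named item columns to average.
#' @param instrument_min,instrument_max instrument scale limits, e.g. 0
#'   and 100 for percent sliders.
#' @param time time stamps in hours (default: row index).
#' @param day optional day labels.
#' @param pa_cols,na_cols optional character vectors of item columns to
#'   average into the PA and NA scores.
#' @return an \linkS4class{AffectTimeSeries}.
#' @export
rescaleSeries <- function(raw, instrument_min, instrument_max,
                          time = NULL, day = NULL, pa_cols = NULL,
                          na_cols = NULL) {
    if (instrument_max <= instrument_min)
        stop("instrument_max must exceed instrument_min")
    raw <- as.data.frame(raw)
    if (!is.null(pa_cols) || !is.null(na_cols)) {
        pa <- rowMeans(raw[, pa_cols, drop = FALSE])
        na_ <- rowMeans(raw[, na_cols, drop = FALSE])
    } else {
        pa <- raw[[1]]
        na_ <- raw[[2]]
    }
    vals <- unname(cbind(as.numeric(pa), as.numeric(na_)))
    bad <- which(!is.na(vals) &
                 (vals < instrument_min | vals > instrument_max),
                 arr.ind = TRUE)
    if (nrow(bad))
        stop("values outside the instrument range in rows: ",
             paste(sort(unique(bad[, 1])), collapse = ", "))
    scaled <- (vals - instrument_min) / (instrument_max - instrument_min)
    scaled <- pmin(pmax(scaled, 0), 1)
    if (is.null(time)) time <- seq_len(nrow(scaled))
    affectTimeSeries(time, scaled, day = day)
}

# Shared per-parameter-set state: surface, kernel and (lazily) the
# stationary field are built once and reused for every pair.
.likPrep <- function(params, options) {
    grid <- buildGrid(options$grid_n)
    surface <- tabulatePotential(params, grid)
    kernel <- buildKernel(surface, params@D)
    env <- new.env(parent = emptyenv())
    env$grid <- grid
    env$surface <- surface
    env$kernel <- kernel
    env$stationary <- NULL
    env$getStationary <- function() {
        if (is.null(env$stationary))
            env$stationary <- stationaryField(surface)
        env$stationary
    }
    env
}

.pairSteps <- function(interval, dt) {
    pmax(1L, as.integer(round(interval / dt)))
}

#' Negative log conditional density of one observation pair
#'
#' Places a point mass at \code{x_from}, propagates it over
#' \code{interval} hours with the lattice solver, and returns
#' \code{-log(max(density at x_to, density_floor))}.
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param x_from,x_to points in the closed unit square.
#' @param interval positive elapsed time in hours.
#' @param options settings from \code{\link{likelihoodOptions}}.
#' @return scalar negative log density.
#' @export
pairNegLogLik <- function(params, x_from, x_to, interval,
                          options = likelihoodOptions()) {
    if (!is.numeric(interval) || interval <= 0)
        stop("interval must be positive")
    prep <- .likPrep(params, options)
    n <- prep$grid@n
    a <- prep$kernel@accept
    nll_pairs_cpp(a$down1, a$up1, a$down2, a$up2,
                  .cellIndex(x_from[1], n) - 1L,
                  .cellIndex(x_from[2], n) - 1L,
                  .pairSteps(interval, prep$kernel@dt),
                  .cellIndex(x_to[1], n) - 1L,
                  .cellIndex(x_to[2], n) - 1L,
                  0L, prep$grid@delta^2, options$density_floor)
}

# Decompose a series into evaluated transition pairs plus the points that
# enter through the stationary density, honouring validity flags (gaps
# are bridged from the previous valid observation to the next) and the
# night protocol.
.seriesPairs <- function(series, options) {
    idx <- which(series@valid)
    from <- integer(0); to <- integer(0); interval <- numeric(0)
    stat_pts <- integer(0)
    if (length(idx)) {
        first <- idx[1]
        if (options$initial_mode == "stationary")
            stat_pts <- first
        if (length(idx) > 1) {
            a <- idx[-length(idx)]
            b <- idx[-1]
            night <- series@day[a] != series@day[b]
            from <- a[!night]; to <- b[!night]
            interval <- series@time[to] - series@time[from]
            if (options$night_mode == "stationary_restart")
                stat_pts <- c(stat_pts, b[night])
        }
    }
    list(from = from, to = to, interval = interval, stat_pts = stat_pts)
}

# Core pair-sum evaluator shared by series and pair-set likelihoods.
# from_xy: m x 2 matrix; to_xy: M x 2; to_pair: 1-based pair index per row
# of to_xy (non-decreasing); interval: per pair.
.nllCore <- function(params, from_xy, to_xy, to_pair, interval, stat_xy,
                     options, prep = NULL) {
    if (is.null(prep)) prep <- .likPrep(params, options)
    n <- prep$grid@n
    total <- 0
    if (length(interval)) {
        steps <- .pairSteps(interval, prep$kernel@dt)
        if (sum(steps) > options$step_budget) return(Inf)
        ord <- order(to_pair)
        a <- prep$kernel@accept
        total <- total + nll_pairs_cpp(
            a$down1, a$up1, a$down2, a$up2,
            .cellIndex(from_xy[, 1], n) - 1L,
            .cellIndex(from_xy[, 2], n) - 1L,
            steps,
            .cellIndex(to_xy[ord, 1], n) - 1L,
            .cellIndex(to_xy[ord, 2], n) - 1L,
            as.integer(to_pair[ord] - 1L),
            prep$grid@delta^2, options$density_floor)
    }
    if (!is.null(stat_xy) && nrow(stat_xy)) {
        stat <- prep$getStationary()
        for (r in seq_len(nrow(stat_xy))) {
            d <- densityAt(stat, stat_xy[r, ])
            total <- total - log(max(d, options$density_floor))
        }
    }
    if (!is.finite(total)) Inf else total
}

#' Negative log-likelihood of a parameter set given a series
#'
#' Sums negative log conditional densities over consecutive valid
#' observations. Missed beeps are skipped and the gap bridged from the
#' previous to the next valid observation. Overnight pairs are dropped
#' (\code{night_mode = "skip_pairs"}, the default protocol: the first
#' observation of a day only conditions) or evaluated under the Boltzmann
#' density (\code{"stationary_restart"}). The first observation of the
#' series contributes the Boltzmann density when
#' \code{initial_mode = "stationary"}, otherwise nothing.
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param series an \linkS4class{AffectTimeSeries}.
#' @param options settings from \code{\link{likelihoodOptions}}.
#' @return scalar negative log-likelihood (\code{Inf} if over the step
#'   budget).
#' @export
negLogLikelihood <- function(params, series,
                             options = likelihoodOptions()) {
    if (length(series@time) == 0L) stop("empty series")
    pr <- .seriesPairs(series, options)
    .nllCore(params,
             series@values[pr$from, , drop = FALSE],
             series@values[pr$to, , drop = FALSE],
             seq_along(pr$to), pr$interval,
             series@values[pr$stat_pts, , drop = FALSE],
             options)
}

# Pair-set container used by the recovery experiment's enlarged data sets:
# several target draws per conditioning observation.
# from: m x 2; interval: length m; to: M x 2; to_pair in 1..m.
.pairSet <- function(from, interval, to, to_pair) {
    list(from = from, interval = interval, to = to,
         to_pair = as.integer(to_pair))
}

.nllPairSet <- function(params, ps, options) {
    .nllCore(params, ps$from, ps$to, ps$to_pair, ps$interval, NULL, options)
}
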