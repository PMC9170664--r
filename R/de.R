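#' Differential-evolution settings
#'
#' Classic rand/1/bin: mutation by a weighted difference of two random
#' agents added to a third, binomial crossover with one guaranteed mutant
#' coordinate, greedy parent-child selection.
#'
#' @param NP population size (default 50; at least 4 so three distinct
#'   donors besides the target exist).
#' @param CR crossover rate in [0, 1] (default 0.6).
#' @param generations number of population updates (default 1000).
#' @param mutation_weight differential weight applied to the donor
#'   difference (default 0.7).
#' @param seed integer seed.
#' @param prior_scales named list of prior scales for population
#'   initialisation: exponential means for \code{lambda}, \code{theta},
#'   \code{n}, and the two-sided exponential scale for \code{lambda12}.
#'   The initial \code{D} is always drawn from an exponential calibrated so
#'   the expected per-pair lattice step count is
#'   \code{target_steps} (default 25), which favours dynamical over
#'   near-stationary solutions early in the search.
#' @param target_steps expected per-pair step count for the initial D draw.
#' @return a validated settings list.
#' @export
deConfig <- function(NP = 50L, CR = 0.6, generations = 1000L,
                     mutation_weight = 0.7, seed = 1L,
                     prior_scales = list(lambda = 10, theta = 10, n = 5,
                                         lambda12 = 10),
                     target_steps = 25) {
    stopifnot(NP >= 4L, CR >= 0, CR <= 1, generations >= 1L,
              mutation_weight > 0, target_steps > 0)
    list(NP = as.integer(NP), CR = CR,
         generations = as.integer(generations),
         mutation_weight = mutation_weight, seed = as.integer(seed),
         prior_scales = prior_scales, target_steps = target_steps)
}

# Feasibility clip for flat parameter vectors. D is floored at a tiny
# positive value so the lattice step size stays finite.
.clipFeasible <- function(v, model) {
    if (model == "aim") {
        v[c(1, 2, 4, 5, 6, 7)] <- pmax(v[c(1, 2, 4, 5, 6, 7)], 0)
        v[8] <- max(v[8], 1e-8)
    } else {
        v[1:2] <- pmin(pmax(v[1:2], 1e-6), 1 - 1e-6)
        v[3:4] <- pmax(v[3:4], 1e-6)
        # shrink the off-diagonal until the curvature is positive definite
        lim <- sqrt(v[3] * v[4]) * 0.999
        v[5] <- pmin(pmax(v[5], -lim), lim)
        v[6] <- max(v[6], 1e-8)
    }
    v
}

.drawPrior <- function(config, model, tau_bar, delta) {
    ps <- config$prior_scales
    d_mean <- config$target_steps * delta^2 / (5 * tau_bar)
    if (model == "aim") {
        c(stats::rexp(2, rate = 1 / ps$lambda),
          stats::rexp(1, rate = 1 / ps$lambda12) * sample(c(-1, 1), 1),
          stats::rexp(2, rate = 1 / ps$theta),
          stats::rexp(2, rate = 1 / ps$n),
          stats::rexp(1, rate = 1 / d_mean))
    } else {
        v <- c(stats::runif(2, 0.1, 0.9),
               stats::rexp(2, rate = 1 / ps$lambda),
               stats::rnorm(1, 0, ps$lambda),
               stats::rexp(1, rate = 1 / d_mean))
        .clipFeasible(v, "ou")
    }
}

#' Initialise a differential-evolution population
#'
#' Draws \code{NP} feasible parameter vectors from the prior. The
#' diffusion constant is exponential with mean
#' \code{target_steps * delta^2 / (5 * tau_bar)}, where \code{tau_bar} is
#' the mean evaluated inter-observation interval of the data, so that the
#' expected number of lattice updates per pair in the first generation is
#' \code{target_steps}. Fitness is evaluated for every member.
#'
#' @param config settings from \code{\link{deConfig}}.
#' @param objective function mapping a flat parameter vector to a scalar.
#' @param tau_bar mean evaluated inter-observation interval in hours.
#' @param delta lattice bin width the objective uses.
#' @param model "aim" or "ou".
#' @return a DE state list (population matrix, fitness, generation).
#' @export
initializePopulation <- function(config, objective, tau_bar, delta,
                                 model = "aim") {
    if (!is.finite(tau_bar) || tau_bar <= 0)
        stop("series too short to define a mean interval")
    d <- if (model == "aim") 8L else 6L
    pop <- t(vapply(seq_len(config$NP),
                    function(i) .drawPrior(config, model, tau_bar, delta),
                    numeric(d)))
    fitness <- apply(pop, 1, objective)
    list(pop = pop, fitness = fitness, generation = 0L, model = model,
         evaluations = config$NP)
}

#' One differential-evolution generation
#'
#' For every parent, builds a donor from three distinct other agents,
#' applies binomial crossover with one guaranteed mutant coordinate, clips
#' the child into the feasible region, and replaces the parent only if the
#' child's objective is strictly smaller (greedy selection; the summed
#' population fitness can only decrease).
#'
#' @param state a DE state from \code{\link{initializePopulation}}.
#' @param objective function mapping a flat parameter vector to a scalar.
#' @param config settings from \code{\link{deConfig}}.
#' @return the updated state.
#' @export
deGeneration <- function(state, objective, config) {
    NP <- nrow(state$pop)
    if (NP < 4L) stop("NP must be at least 4")
    d <- ncol(state$pop)
    children <- state$pop
    child_fit <- state$fitness
    for (i in seq_len(NP)) {
        donors <- sample(seq_len(NP)[-i], 3L)
        v <- state$pop[donors[1], ] + config$mutation_weight *
            (state$pop[donors[2], ] - state$pop[donors[3], ])
        u <- state$pop[i, ]
        cross <- stats::runif(d) < config$CR
        cross[sample.int(d, 1L)] <- TRUE
        u[cross] <- v[cross]
        u <- .clipFeasible(u, state$model)
        f <- objective(u)
        if (f < state$fitness[i]) {  # strict: ties keep the parent
            children[i, ] <- u
            child_fit[i] <- f
        }
    }
    state$pop <- children
    state$fitness <- child_fit
    state$generation <- state$generation + 1L
    state$evaluations <- state$evaluations + NP
    state
}

#' Fit a model to a series by differential evolution
#'
#' Minimises \code{\link{negLogLikelihood}} over the flat parameter space.
#' The whole run is reproducible from \code{config$seed}.
#'
#' @param series an \linkS4class{AffectTimeSeries}, or an internal pair
#'   set as produced by the recovery experiment.
#' @param model "aim" or "ou".
#' @param config settings from \code{\link{deConfig}}.
#' @param options settings from \code{\link{likelihoodOptions}}.
#' @return a \linkS4class{FitResult}.
#' @examples
#' \donttest{
#' truth <- aimParameters(lambda1 = 4, lambda2 = 3, lambda12 = 2,
#'                        theta1 = 2, theta2 = 3, n1 = 2, n2 = 2,
#'                        D = 0.005)
#' set.seed(7)
#' sched <- esmSchedule(scheduleConfig(days = 4))
#' series <- simulateSeries(truth, sched, buildGrid(30))
#' fit <- fitModel(series, "aim",
#'                 deConfig(NP = 8, generations = 10, seed = 1))
#' fit
#' }
#' @export
fitModel <- function(series, model = c("aim", "ou"),
                     config = deConfig(),
                     options = likelihoodOptions()) {
    model <- match.arg(model)
    set.seed(config$seed)
    if (is(series, "AffectTimeSeries")) {
        pr <- .seriesPairs(series, options)
        intervals <- pr$interval
        objective <- function(v)
            negLogLikelihood(paramsFromVector(v, model), series, options)
    } else {
        intervals <- series$interval
        objective <- function(v)
            .nllPairSet(paramsFromVector(v, model), series, options)
    }
    tau_bar <- mean(intervals)
    delta <- 1 / options$grid_n
    state <- initializePopulation(config, objective, tau_bar, delta, model)
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
        state <- deGeneration(state, objective, config)
        trace[g] <- min(state$fitness)
    }
    best <- which.min(state$fitness)
    new("FitResult",
        params = paramsFromVector(state$pop[best, ], model),
        nll = state$fitness[best], trace = trace,
        evaluations = state$evaluations,
        config = list(de = config, likelihood = options, model = model,
                      seed = config$seed))
}

#' @describeIn diffusionConstant of a fit result
#' @export
setMethod("diffusionConstant", "FitResult",
          function(x) x@params@D)

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult (%s): NLL = %.4f after %d generations, %g evaluations\n",
                object@config$model, object@nll, length(object@trace),
                object@evaluations))
    print(round(paramVector(object@params), 4))
})
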