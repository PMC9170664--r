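#' Euler-Maruyama simulation settings
#'
#' @param dt positive simulation time step in hours. The reference choice
#'   ties it to the lattice step at the finest grid used for comparisons,
#'   \code{(1/240)^2 / (5 D)}; see \code{\link{emReferenceDt}}.
#' @param n_traj number of trajectories.
#' @param boundary_margin trajectories are clamped into
#'   \code{[margin, 1 - margin]} after every step; the diverging inward
#'   drift of the entropy terms then pushes them back off the wall.
#' @param seed integer seed for the simulator's generator.
#' @return a validated list of class settings.
#' @export
emConfig <- function(dt, n_traj = 1e5, boundary_margin = 1e-6, seed = 1L) {
    stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
              n_traj >= 1, boundary_margin > 0, boundary_margin < 0.5)
    list(dt = dt, n_traj = as.integer(n_traj),
         boundary_margin = boundary_margin, seed = as.integer(seed))
}

#' Reference Euler-Maruyama step size
#'
#' The lattice step size at bin width \code{1/n_ref}:
#' \code{(1/n_ref)^2 / (5 D)}. Used so the trajectory oracle resolves time
#' at least as finely as the finest lattice it is compared against.
#'
#' @param D diffusion constant.
#' @param n_ref reference grid size (default 240).
#' @export
emReferenceDt <- function(D, n_ref = 240) {
    (1 / n_ref)^2 / (5 * D)
}

.modelCode <- function(params) if (is(params, "AIMParameters")) 1L else 2L

.gradPars <- function(params) {
    if (is(params, "AIMParameters"))
        c(params@lambda1, params@lambda2, params@lambda12, params@theta1,
          params@theta2, params@n1, params@n2)
    else
        c(params@mu, params@a11, params@a22, params@a12)
}

#' Simulate Euler-Maruyama endpoints
#'
#' Independent Monte-Carlo oracle for the conditional density: simulates
#' \code{n_traj} trajectories of
#' \code{dy = -D grad F(y) dt + sqrt(2 D) dW} from \code{y0}, each for
#' \code{duration} hours (\code{ceiling(duration/dt)} steps, the final step
#' truncated to land exactly on \code{duration}), clamping into
#' \code{[margin, 1 - margin]} after every step.
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param y0 strictly interior starting point.
#' @param duration nonnegative time in hours; may be a sorted vector, in
#'   which case the same trajectories are recorded at each duration.
#' @param config settings from \code{\link{emConfig}}.
#' @param D diffusion constant; defaults to the one in \code{params}.
#'   \code{D = 0} is accepted as the degenerate no-motion limit.
#' @return an \code{n_traj} x 2 matrix of endpoints, or a list of such
#'   matrices when \code{duration} has several elements.
#' @export
simulateEndpoints <- function(params, y0, duration, config,
                              D = diffusionConstant(params)) {
    .checkInterior(y0)
    if (any(duration < 0)) stop("duration must be nonnegative")
    if (is.unsorted(duration)) stop("durations must be sorted ascending")
    stopifnot(D >= 0)
    snaps <- em_simulate_cpp(y0[1], y0[2], config$n_traj, config$dt,
                             .modelCode(params), .gradPars(params), D,
                             config$boundary_margin, as.numeric(duration),
                             as.numeric(config$seed))
    if (length(duration) == 1L) snaps[[1]] else snaps
}

#' Histogram endpoints into a probability field
#'
#' Bins endpoints over the grid cells with the same half-open assignment
#' rule as \code{\link{deltaField}} and normalises to total mass one. No
#' kernel smoothing is applied.
#'
#' @param endpoints matrix with two columns of unit-square coordinates.
#' @param grid an \linkS4class{AffectGrid}.
#' @return a \linkS4class{ProbabilityField}.
#' @export
endpointsToField <- function(endpoints, grid) {
    endpoints <- as.matrix(endpoints)
    if (nrow(endpoints) == 0L) stop("empty endpoint set")
    if (any(endpoints < 0) || any(endpoints > 1))
        stop("endpoints must lie in the closed unit square")
    n <- grid@n
    i <- .cellIndex(endpoints[, 1], n)
    j <- .cellIndex(endpoints[, 2], n)
    counts <- matrix(tabulate((j - 1L) * n + i, nbins = n * n), n, n)
    asField(grid, counts / nrow(endpoints))
}

#' Write endpoints as a two-column CSV
#' @param endpoints matrix with two columns.
#' @param path output path.
#' @export
writeEndpointsCSV <- function(endpoints, path) {
    utils::write.csv(data.frame(y1 = endpoints[, 1], y2 = endpoints[, 2]),
                     path, row.names = FALSE)
    invisible(path)
}
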