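#' Build an affect grid
#'
#' @param n number of interior cells per dimension (default 30, matching
#'   the resolution at which self-report slider data are informative).
#' @return an \linkS4class{AffectGrid} with bin width \code{1/n}.
#' @examples
#' g <- buildGrid(30)
#' binWidth(g)
#' @export
buildGrid <- function(n = 30L) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 2L)
        stop("n must be a single integer >= 2")
    new("AffectGrid", n = n, delta = 1 / n)
}

#' Interior cell centers along one axis
#'
#' @param grid an \linkS4class{AffectGrid}.
#' @return numeric vector \code{(2m+1) delta / 2} for \code{m = 0..n-1}.
#' @export
cellCenters <- function(grid) {
    (2 * seq_len(grid@n) - 1) * grid@delta / 2
}

#' @describeIn gridSize of a grid
#' @export
setMethod("gridSize", "AffectGrid", function(x) x@n)
#' @describeIn gridSize of a field
#' @export
setMethod("gridSize", "ProbabilityField", function(x) x@grid@n)
#' @describeIn binWidth of a grid
#' @export
setMethod("binWidth", "AffectGrid", function(x) x@delta)
#' @describeIn binWidth of a field
#' @export
setMethod("binWidth", "ProbabilityField", function(x) x@grid@delta)
#' @describeIn cellMasses n x n matrix of masses
#' @export
setMethod("cellMasses", "ProbabilityField", function(x) x@mass)
#' @describeIn stepCount lattice updates applied so far
#' @export
setMethod("stepCount", "ProbabilityField", function(x) x@steps)
#' @describeIn stepSize lattice time step of a kernel
#' @export
setMethod("stepSize", "TransitionKernel", function(x) x@dt)
#' @describeIn diffusionConstant of a kernel
#' @export
setMethod("diffusionConstant", "TransitionKernel", function(x) x@D)

#' Build the Metropolis-Hastings transition kernel
#'
#' Acceptance toward each of the four lattice neighbors is
#' \code{min(1, exp(F_cell - F_neighbor))}; it is computed as
#' \code{exp(-max(0, F_neighbor - F_cell))} so that moves toward the
#' infinite ghost layer come out exactly zero without arithmetic on
#' infinities. The lattice time step is fixed by the bin width and the
#' diffusion constant: \code{dt = delta^2 / (5 D)}.
#'
#' @param surface a \linkS4class{PotentialSurface}.
#' @param D positive diffusion constant (1/hours); defaults to the one in
#'   the surface's parameter set.
#' @return a \linkS4class{TransitionKernel}.
#' @export
buildKernel <- function(surface, D = diffusionConstant(surface@params)) {
    if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
        stop("D must be a positive scalar")
    n <- surface@grid@n
    Fv <- surface@values
    inner <- Fv[2:(n + 1), 2:(n + 1)]
    acc <- function(neigh) {
        d <- neigh - inner
        d[d < 0] <- 0
        k <- exp(-d)
        k[is.infinite(neigh)] <- 0  # ghost neighbor: acceptance exactly 0
        k
    }
    accept <- list(
        down1 = acc(Fv[1:n, 2:(n + 1)]),
        up1   = acc(Fv[3:(n + 2), 2:(n + 1)]),
        down2 = acc(Fv[2:(n + 1), 1:n]),
        up2   = acc(Fv[2:(n + 1), 3:(n + 2)]))
    new("TransitionKernel", grid = surface@grid, D = D,
        dt = surface@grid@delta^2 / (5 * D), accept = accept)
}

# Cell index (1-based) containing a coordinate: half-open cells
# [m delta, (m+1) delta) with y = 1 clamped into the last cell.
.cellIndex <- function(y, n) {
    pmin(pmax(floor(y * n), 0), n - 1) + 1L
}

#' Point mass field
#'
#' Places unit mass in the cell containing \code{y0}. Cells are half-open,
#' \code{[m delta, (m+1) delta)}; points with a coordinate equal to 1 are
#' assigned to the last cell.
#'
#' @param grid an \linkS4class{AffectGrid}.
#' @param y0 2-vector in the closed unit square.
#' @return a \linkS4class{ProbabilityField}.
#' @export
deltaField <- function(grid, y0) {
    if (length(y0) != 2L || any(!is.finite(y0)) || any(y0 < 0) ||
        any(y0 > 1))
        stop("y0 must lie in the closed unit square")
    m <- matrix(0, grid@n, grid@n)
    m[.cellIndex(y0[1], grid@n), .cellIndex(y0[2], grid@n)] <- 1
    new("ProbabilityField", grid = grid, mass = m, steps = 0)
}

#' Uniform field
#'
#' @param grid an \linkS4class{AffectGrid}.
#' @return a \linkS4class{ProbabilityField} with mass \code{1/n^2} per cell.
#' @export
uniformField <- function(grid) {
    new("ProbabilityField", grid = grid,
        mass = matrix(1 / grid@n^2, grid@n, grid@n), steps = 0)
}

#' Wrap a mass matrix as a field
#'
#' @param grid an \linkS4class{AffectGrid}.
#' @param mass n x n matrix of nonnegative masses summing to one.
#' @param steps elapsed-steps counter, default 0.
#' @return a \linkS4class{ProbabilityField}.
#' @export
asField <- function(grid, mass, steps = 0) {
    new("ProbabilityField", grid = grid, mass = mass, steps = steps)
}

.checkSameGrid <- function(a, b) {
    if (a@grid@n != b@grid@n)
        stop("objects live on different grids")
}

#' One Metropolis-Hastings lattice update
#'
#' Moves probability mass between neighboring cells according to the net
#' flux: out-flux \code{p * sum(accept)/5}, in-flux the mirrored sum over
#' neighbors. Total mass is conserved and every cell retains at least a
#' fifth of its mass.
#'
#' @param field a \linkS4class{ProbabilityField}.
#' @param kernel a \linkS4class{TransitionKernel} on the same grid.
#' @return the updated \linkS4class{ProbabilityField}.
#' @export
mhStep <- function(field, kernel) {
    .checkSameGrid(field, kernel)
    a <- kernel@accept
    m <- mh_propagate_cpp(field@mass, a$down1, a$up1, a$down2, a$up2, 1L)
    new("ProbabilityField", grid = field@grid, mass = m,
        steps = field@steps + 1)
}

#' Propagate a field over a time interval
#'
#' Applies \code{k = max(1, round(duration / dt))} lattice updates for
#' positive durations (zero updates for \code{duration = 0}), where
#' \code{dt = delta^2/(5D)} is the kernel's step size. Rounding to the
#' nearest step keeps the effective elapsed time closest to the requested
#' one; the one-step floor keeps distinct observation times from collapsing
#' onto the identity.
#'
#' @param field a \linkS4class{ProbabilityField}.
#' @param kernel a \linkS4class{TransitionKernel} on the same grid.
#' @param duration nonnegative time in hours.
#' @return list with elements \code{field} (the propagated
#'   \linkS4class{ProbabilityField}) and \code{steps} (updates applied).
#' @export
propagate <- function(field, kernel, duration) {
    if (!is.numeric(duration) || length(duration) != 1L ||
        !is.finite(duration) || duration < 0)
        stop("duration must be a nonnegative scalar")
    .checkSameGrid(field, kernel)
    k <- if (duration == 0) 0L else max(1L, as.integer(round(duration / kernel@dt)))
    if (k == 0L)
        return(list(field = field, steps = 0L))
    a <- kernel@accept
    m <- mh_propagate_cpp(field@mass, a$down1, a$up1, a$down2, a$up2, k)
    list(field = new("ProbabilityField", grid = field@grid, mass = m,
                     steps = field@steps + k),
         steps = k)
}

#' Stationary Boltzmann field
#'
#' The invariant distribution of the lattice propagator: cell masses
#' proportional to \code{exp(-F)} over the interior cells, the discrete
#' analogue of the Boltzmann distribution \code{exp(-F)/Z}.
#'
#' @param surface a \linkS4class{PotentialSurface}.
#' @return a \linkS4class{ProbabilityField}.
#' @export
stationaryField <- function(surface) {
    n <- surface@grid@n
    Fv <- surface@values[2:(n + 1), 2:(n + 1)]
    w <- exp(-(Fv - min(Fv)))  # shift for overflow safety
    Z <- sum(w)
    if (!is.finite(Z) || Z <= 0)
        stop("degenerate surface: no finite Boltzmann weight")
    new("ProbabilityField", grid = surface@grid, mass = w / Z, steps = 0)
}

#' Probability density at a point
#'
#' Converts cell mass to density: (mass of the cell containing \code{y})
#' divided by \code{delta^2}, using the same cell-assignment rule as
#' \code{\link{deltaField}}.
#'
#' @param field a \linkS4class{ProbabilityField}.
#' @param y 2-vector in the closed unit square.
#' @return nonnegative scalar density.
#' @export
densityAt <- function(field, y) {
    if (length(y) != 2L || any(!is.finite(y)) || any(y < 0) || any(y > 1))
        stop("y must lie in the closed unit square")
    n <- field@grid@n
    field@mass[.cellIndex(y[1], n), .cellIndex(y[2], n)] / field@grid@delta^2
}

#' Write a probability field as a plain-text matrix
#'
#' Rows index the first affect dimension; values are cell masses.
#'
#' @param field a \linkS4class{ProbabilityField}.
#' @param path output path.
#' @export
writeField <- function(field, path) {
    utils::write.table(field@mass, path, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read a probability field written by \code{\link{writeField}}
#'
#' @param path input path.
#' @return a \linkS4class{ProbabilityField}.
#' @export
readField <- function(path) {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    asField(buildGrid(nrow(m)), m / sum(m))
}

setMethod("show", "AffectGrid", function(object) {
    cat(sprintf("AffectGrid: %d x %d interior cells, delta = %.4g\n",
                object@n, object@n, object@delta))
})

setMethod("show", "TransitionKernel", function(object) {
    cat(sprintf("TransitionKernel: n = %d, D = %.4g /h, dt = %.4g h\n",
                object@grid@n, object@D, object@dt))
})

setMethod("show", "ProbabilityField", function(object) {
    cat(sprintf(
        "ProbabilityField: %d x %d cells, %g lattice updates, mass %.6f\n",
        object@grid@n, object@grid@n, object@steps, sum(object@mass)))
})
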