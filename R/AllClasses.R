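#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib affectfp, .registration = TRUE
NULL

#' Lattice discretisation of the affect space
#'
#' The unit square is divided into \code{n} x \code{n} interior cells of
#' width \code{delta = 1/n}, with cell centers at
#' \code{((2m+1)delta/2, (2k+1)delta/2)} for 0-based indices \code{m, k}.
#' A layer of ghost cells (one cell on every side, infinite free energy)
#' surrounds the interior and implements the no-flux boundary condition.
#'
#' @slot n integer, number of interior cells per dimension.
#' @slot delta numeric, bin width \code{1/n}.
#' @export
setClass("AffectGrid", representation(n = "integer", delta = "numeric"))

setValidity("AffectGrid", function(object) {
    if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
        return("n must be a single integer >= 2")
    if (abs(object@delta - 1 / object@n) > 1e-15)
        return("delta must equal 1/n")
    TRUE
})

#' Model parameters (virtual parent)
#'
#' Parent class for parameter sets of bounded gradient-drift diffusion
#' models on the unit square. Concrete classes: \linkS4class{AIMParameters}
#' and \linkS4class{BoundedOUParameters}.
#'
#' @slot D numeric, diffusion constant (1/hours); sets the time scale of
#'   both drift and noise.
#' @export
setClass("ModelParameters", representation("VIRTUAL", D = "numeric"))

#' Affective Ising Model parameters
#'
#' The eight parameters of the Affective Ising Model free energy
#' \deqn{F(y) = \sum_i [-\Lambda_i y_i^2 + \Theta_i y_i +
#'   N_i (y_i \ln y_i + (1-y_i)\ln(1-y_i))] + \Lambda_{12} y_1 y_2.}
#' \code{lambda1}, \code{lambda2} are nonnegative self-excitation weights,
#' \code{lambda12} the cross-interaction (positive = mutual inhibition),
#' \code{theta1}, \code{theta2} nonnegative thresholds, \code{n1},
#' \code{n2} nonnegative entropy weights, and \code{D > 0} the diffusion
#' constant.
#'
#' @export
setClass("AIMParameters", contains = "ModelParameters",
         representation(lambda1 = "numeric", lambda2 = "numeric",
                        lambda12 = "numeric", theta1 = "numeric",
                        theta2 = "numeric", n1 = "numeric", n2 = "numeric"))

setValidity("AIMParameters", function(object) {
    v <- c(lambda1 = object@lambda1, lambda2 = object@lambda2,
           lambda12 = object@lambda12, theta1 = object@theta1,
           theta2 = object@theta2, n1 = object@n1, n2 = object@n2,
           D = object@D)
    if (any(lengths(list(object@lambda1, object@lambda2, object@lambda12,
                         object@theta1, object@theta2, object@n1,
                         object@n2, object@D)) != 1L))
        return("all parameters must be scalars")
    if (any(!is.finite(v)))
        return("all parameters must be finite")
    nonneg <- v[c("lambda1", "lambda2", "theta1", "theta2", "n1", "n2")]
    if (any(nonneg < 0))
        return("lambda, theta and entropy weights must be nonnegative")
    if (object@D <= 0)
        return("D must be positive")
    TRUE
})

#' Bounded Ornstein-Uhlenbeck parameters
#'
#' Quadratic free energy \eqn{F(y) = (y-\mu)^T A (y-\mu)/2} on the unit
#' square, giving interior drift \eqn{-D A (y-\mu)}: an
#' Ornstein-Uhlenbeck process confined to the unit square by the no-flux
#' boundary. \code{mu} must lie in the open unit square and the curvature
#' matrix \code{A = [[a11, a12], [a12, a22]]} must be positive definite.
#'
#' @export
setClass("BoundedOUParameters", contains = "ModelParameters",
         representation(mu = "numeric", a11 = "numeric", a22 = "numeric",
                        a12 = "numeric"))

setValidity("BoundedOUParameters", function(object) {
    if (length(object@mu) != 2L || any(!is.finite(object@mu)))
        return("mu must be a finite 2-vector")
    if (any(object@mu <= 0) || any(object@mu >= 1))
        return("mu must lie in the open unit square")
    if (object@a11 <= 0 || object@a22 <= 0 ||
        object@a11 * object@a22 - object@a12^2 <= 0)
        return("curvature matrix must be positive definite")
    if (object@D <= 0)
        return("D must be positive")
    TRUE
})

#' Tabulated free-energy surface
#'
#' Free energy evaluated at every interior cell center of an
#' \linkS4class{AffectGrid}, stored as an (n+2) x (n+2) matrix whose outer
#' ghost layer is \code{Inf} (no-flux boundary sentinel).
#'
#' @slot grid the \linkS4class{AffectGrid}.
#' @slot values (n+2) x (n+2) numeric matrix; rows index the first affect
#'   dimension.
#' @slot params the \linkS4class{ModelParameters} used (provenance).
#' @export
setClass("PotentialSurface",
         representation(grid = "AffectGrid", values = "matrix",
                        params = "ModelParameters"))

setValidity("PotentialSurface", function(object) {
    n <- object@grid@n
    v <- object@values
    if (!all(dim(v) == n + 2L))
        return("values must be (n+2) x (n+2)")
    inner <- v[2:(n + 1), 2:(n + 1)]
    if (any(!is.finite(inner)))
        return("interior free energies must be finite")
    ghost <- c(v[1, ], v[n + 2, ], v[, 1], v[, n + 2])
    if (any(is.finite(ghost)))
        return("ghost layer must carry the infinity sentinel")
    TRUE
})

#' Precomputed Metropolis-Hastings transition kernel
#'
#' Per-cell acceptance probabilities \code{min(1, exp(F_cell - F_neighbor))}
#' toward the four lattice neighbors (zero toward ghost cells), together
#' with the lattice time step \code{dt = delta^2 / (5 D)}.
#'
#' @slot grid the \linkS4class{AffectGrid}.
#' @slot D diffusion constant used.
#' @slot dt lattice step size in hours.
#' @slot accept list of four n x n matrices \code{down1}, \code{up1},
#'   \code{down2}, \code{up2}: acceptance toward (m-1,k), (m+1,k), (m,k-1),
#'   (m,k+1) respectively.
#' @export
setClass("TransitionKernel",
         representation(grid = "AffectGrid", D = "numeric", dt = "numeric",
                        accept = "list"))

setValidity("TransitionKernel", function(object) {
    n <- object@grid@n
    if (!identical(sort(names(object@accept)),
                   sort(c("down1", "up1", "down2", "up2"))))
        return("accept must hold down1, up1, down2, up2")
    for (k in object@accept) {
        if (!all(dim(k) == n)) return("acceptance matrices must be n x n")
        if (any(k < 0 | k > 1)) return("acceptances must lie in [0, 1]")
    }
    if (any(object@accept$down1[1, ] != 0) ||
        any(object@accept$up1[n, ] != 0) ||
        any(object@accept$down2[, 1] != 0) ||
        any(object@accept$up2[, n] != 0))
        return("acceptance toward ghost cells must be exactly zero")
    if (object@D <= 0) return("D must be positive")
    if (abs(object@dt - object@grid@delta^2 / (5 * object@D)) >
        1e-15 * object@dt)
        return("dt must equal delta^2 / (5 D)")
    TRUE
})

#' Probability mass field on the affect grid
#'
#' Nonnegative per-cell masses over the interior cells, summing to one.
#' Densities are masses divided by \code{delta^2}.
#'
#' @slot grid the \linkS4class{AffectGrid}.
#' @slot mass n x n numeric matrix of cell masses; rows index the first
#'   affect dimension.
#' @slot steps number of lattice updates applied since construction.
#' @export
setClass("ProbabilityField",
         representation(grid = "AffectGrid", mass = "matrix",
                        steps = "numeric"))

setValidity("ProbabilityField", function(object) {
    n <- object@grid@n
    if (!all(dim(object@mass) == n))
        return("mass must be n x n")
    if (any(object@mass < 0))
        return("masses must be nonnegative")
    if (abs(sum(object@mass) - 1) > 1e-9)
        return("masses must sum to one")
    TRUE
})

#' Irregularly sampled bivariate affect time series
#'
#' Time-ordered observations of (positive affect, negative affect) on the
#' unit square with a day label and a validity flag per beep. Invalid
#' (missed) beeps keep their time slot but carry \code{NA} values.
#'
#' @slot time numeric, strictly increasing time stamps in hours.
#' @slot values k x 2 matrix of (PA, NA) in [0,1]; \code{NA} on invalid rows.
#' @slot day integer day label per observation.
#' @slot valid logical flag per observation.
#' @export
setClass("AffectTimeSeries",
         representation(time = "numeric", values = "matrix",
                        day = "integer", valid = "logical"))

setValidity("AffectTimeSeries", function(object) {
    k <- length(object@time)
    if (nrow(object@values) != k || ncol(object@values) != 2L)
        return("values must be a k x 2 matrix")
    if (length(object@day) != k || length(object@valid) != k)
        return("day and valid must match the number of observations")
    if (k > 1 && any(diff(object@time) <= 0))
        return("time stamps must be strictly increasing")
    v <- object@values[object@valid, , drop = FALSE]
    if (any(is.na(v)))
        return("valid observations must not contain NA")
    if (length(v) && (any(v < 0) || any(v > 1)))
        return("observations must lie in the unit square")
    TRUE
})

#' Result of a differential-evolution model fit
#'
#' @slot params best \linkS4class{ModelParameters} found.
#' @slot nll the minimised negative log-likelihood.
#' @slot trace best objective value after each generation (non-increasing).
#' @slot evaluations total number of objective evaluations.
#' @slot config list echoing the optimizer and likelihood settings and seed.
#' @export
setClass("FitResult",
         representation(params = "ModelParameters", nll = "numeric",
                        trace = "numeric", evaluations = "numeric",
                        config = "list"))
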