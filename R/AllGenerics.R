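#' Evaluate the free energy at a point
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param y numeric 2-vector strictly inside the unit square (the entropy
#'   terms of the AIM are undefined on the boundary).
#' @return scalar free energy.
#' @export
setGeneric("freeEnergy", function(params, y) standardGeneric("freeEnergy"))

#' Gradient of the free energy at an interior point
#'
#' @inheritParams freeEnergy
#' @return numeric 2-vector of partial derivatives.
#' @export
setGeneric("freeEnergyGradient",
           function(params, y) standardGeneric("freeEnergyGradient"))

#' Tabulate the free energy on a grid
#'
#' Evaluates the free energy at every interior cell center and surrounds
#' the table with a ghost layer carrying the infinity sentinel.
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param grid an \linkS4class{AffectGrid}.
#' @return a \linkS4class{PotentialSurface}.
#' @export
setGeneric("tabulatePotential",
           function(params, grid) standardGeneric("tabulatePotential"))

#' Model identifier string
#' @param params a \linkS4class{ModelParameters} object.
#' @return "aim" or "ou".
#' @export
setGeneric("modelId", function(params) standardGeneric("modelId"))

#' Flat parameter vector for the optimizer
#'
#' AIM order: (lambda1, lambda2, lambda12, theta1, theta2, n1, n2, D).
#' Bounded OU order: (mu1, mu2, a11, a22, a12, D).
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @return named numeric vector.
#' @export
setGeneric("paramVector", function(params) standardGeneric("paramVector"))

#' Number of interior cells per dimension
#' @param x an object carrying an \linkS4class{AffectGrid}.
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' Bin width of the lattice
#' @param x an object carrying an \linkS4class{AffectGrid}.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Matrix of cell masses
#' @param x a \linkS4class{ProbabilityField}.
#' @export
setGeneric("cellMasses", function(x) standardGeneric("cellMasses"))

#' Diffusion constant
#' @param x a \linkS4class{ModelParameters}, \linkS4class{TransitionKernel}
#'   or \linkS4class{FitResult}.
#' @export
setGeneric("diffusionConstant",
           function(x) standardGeneric("diffusionConstant"))

#' Lattice time step delta^2 / (5 D)
#' @param x a \linkS4class{TransitionKernel}.
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))

#' Number of lattice updates applied to a field
#' @param x a \linkS4class{ProbabilityField}.
#' @export
setGeneric("stepCount", function(x) standardGeneric("stepCount"))
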