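#' Construct Affective Ising Model parameters
#'
#' @param lambda1,lambda2 nonnegative self-excitation weights.
#' @param lambda12 cross-interaction; positive values make the two affect
#'   dimensions mutually inhibiting.
#' @param theta1,theta2 nonnegative thresholds.
#' @param n1,n2 nonnegative entropy weights.
#' @param D positive diffusion constant (1/hours).
#' @return an \linkS4class{AIMParameters} object.
#' @examples
#' p <- aimParameters(lambda1 = 4, lambda2 = 3, lambda12 = 2,
#'                    theta1 = 2, theta2 = 3, n1 = 2, n2 = 2, D = 0.005)
#' freeEnergy(p, c(0.5, 0.5))
#' @export
aimParameters <- function(lambda1 = 0, lambda2 = 0, lambda12 = 0,
                          theta1 = 0, theta2 = 0, n1 = 0, n2 = 0, D = 1) {
    new("AIMParameters", lambda1 = as.numeric(lambda1),
        lambda2 = as.numeric(lambda2), lambda12 = as.numeric(lambda12),
        theta1 = as.numeric(theta1), theta2 = as.numeric(theta2),
        n1 = as.numeric(n1), n2 = as.numeric(n2), D = as.numeric(D))
}

#' Construct bounded Ornstein-Uhlenbeck parameters
#'
#' @param mu attractor location, a 2-vector in the open unit square.
#' @param a11,a22,a12 entries of the positive-definite curvature matrix.
#' @param D positive diffusion constant (1/hours).
#' @return a \linkS4class{BoundedOUParameters} object.
#' @export
ouParameters <- function(mu = c(0.5, 0.5), a11 = 8, a22 = 8, a12 = 0,
                         D = 1) {
    new("BoundedOUParameters", mu = as.numeric(mu), a11 = as.numeric(a11),
        a22 = as.numeric(a22), a12 = as.numeric(a12), D = as.numeric(D))
}

.checkInterior <- function(y) {
    if (length(y) != 2L || any(!is.finite(y)))
        stop("y must be a finite 2-vector")
    if (any(y <= 0) || any(y >= 1))
        stop("y must lie strictly inside the unit square")
    invisible(y)
}

#' @describeIn freeEnergy AIM free energy: self-excitation, threshold and
#'   entropy terms per dimension plus the interaction term
#'   \code{lambda12 * y1 * y2}.
#' @export
setMethod("freeEnergy", "AIMParameters", function(params, y) {
    .checkInterior(y)
    ent <- y * log(y) + (1 - y) * log1p(-y)
    lam <- c(params@lambda1, params@lambda2)
    th <- c(params@theta1, params@theta2)
    nw <- c(params@n1, params@n2)
    sum(-lam * y^2 + th * y + nw * ent) + params@lambda12 * y[1] * y[2]
})

#' @describeIn freeEnergy bounded OU quadratic form
#'   \code{(y - mu)^T A (y - mu) / 2}.
#' @export
setMethod("freeEnergy", "BoundedOUParameters", function(params, y) {
    .checkInterior(y)
    d <- y - params@mu
    0.5 * (params@a11 * d[1]^2 + params@a22 * d[2]^2 +
           2 * params@a12 * d[1] * d[2])
})

#' @describeIn freeEnergyGradient AIM gradient; the entropy term
#'   \code{n_i * log(y_i / (1 - y_i))} diverges toward the boundary, which
#'   is what keeps the process inside the unit square.
#' @export
setMethod("freeEnergyGradient", "AIMParameters", function(params, y) {
    .checkInterior(y)
    logit <- log(y) - log1p(-y)
    c(-2 * params@lambda1 * y[1] + params@theta1 + params@n1 * logit[1] +
          params@lambda12 * y[2],
      -2 * params@lambda2 * y[2] + params@theta2 + params@n2 * logit[2] +
          params@lambda12 * y[1])
})

#' @describeIn freeEnergyGradient bounded OU gradient \code{A (y - mu)}.
#' @export
setMethod("freeEnergyGradient", "BoundedOUParameters", function(params, y) {
    .checkInterior(y)
    d <- y - params@mu
    c(params@a11 * d[1] + params@a12 * d[2],
      params@a12 * d[1] + params@a22 * d[2])
})

#' @describeIn tabulatePotential evaluate on the cell centers of
#'   \code{grid}, vectorised over cells.
#' @export
setMethod("tabulatePotential", "ModelParameters", function(params, grid) {
    n <- grid@n
    ctr <- cellCenters(grid)
    vals <- matrix(Inf, n + 2L, n + 2L)
    y1 <- matrix(ctr, n, n)
    y2 <- matrix(ctr, n, n, byrow = TRUE)
    vals[2:(n + 1), 2:(n + 1)] <- .freeEnergyMatrix(params, y1, y2)
    new("PotentialSurface", grid = grid, values = vals, params = params)
})

# Vectorised interior free energy on matrices of coordinates.
.freeEnergyMatrix <- function(params, y1, y2) {
    if (is(params, "AIMParameters")) {
        ent1 <- y1 * log(y1) + (1 - y1) * log1p(-y1)
        ent2 <- y2 * log(y2) + (1 - y2) * log1p(-y2)
        -params@lambda1 * y1^2 + params@theta1 * y1 + params@n1 * ent1 +
            -params@lambda2 * y2^2 + params@theta2 * y2 + params@n2 * ent2 +
            params@lambda12 * y1 * y2
    } else {
        d1 <- y1 - params@mu[1]
        d2 <- y2 - params@mu[2]
        0.5 * (params@a11 * d1^2 + params@a22 * d2^2 +
               2 * params@a12 * d1 * d2)
    }
}

#' @describeIn modelId AIM
#' @export
setMethod("modelId", "AIMParameters", function(params) "aim")

#' @describeIn modelId bounded OU
#' @export
setMethod("modelId", "BoundedOUParameters", function(params) "ou")

#' @describeIn paramVector AIM order (lambda1, lambda2, lambda12, theta1,
#'   theta2, n1, n2, D).
#' @export
setMethod("paramVector", "AIMParameters", function(params) {
    c(lambda1 = params@lambda1, lambda2 = params@lambda2,
      lambda12 = params@lambda12, theta1 = params@theta1,
      theta2 = params@theta2, n1 = params@n1, n2 = params@n2, D = params@D)
})

#' @describeIn paramVector bounded OU order (mu1, mu2, a11, a22, a12, D).
#' @export
setMethod("paramVector", "BoundedOUParameters", function(params) {
    c(mu1 = params@mu[1], mu2 = params@mu[2], a11 = params@a11,
      a22 = params@a22, a12 = params@a12, D = params@D)
})

#' Rebuild parameters from a flat vector
#'
#' Inverse of \code{\link{paramVector}}; the optimizer works on these flat
#' vectors.
#'
#' @param v numeric vector in the documented order.
#' @param model "aim" (length 8) or "ou" (length 6).
#' @return a \linkS4class{ModelParameters} object.
#' @export
paramsFromVector <- function(v, model = c("aim", "ou")) {
    model <- match.arg(model)
    if (model == "aim") {
        stopifnot(length(v) == 8L)
        aimParameters(lambda1 = v[1], lambda2 = v[2], lambda12 = v[3],
                      theta1 = v[4], theta2 = v[5], n1 = v[6], n2 = v[7],
                      D = v[8])
    } else {
        stopifnot(length(v) == 6L)
        ouParameters(mu = c(v[1], v[2]), a11 = v[3], a22 = v[4], a12 = v[5],
                     D = v[6])
    }
}

#' @describeIn diffusionConstant of a parameter set
#' @export
setMethod("diffusionConstant", "ModelParameters", function(x) x@D)

#' Write model parameters to JSON
#'
#' Serialises the parameter set with explicit field names and a
#' \code{model_id} tag, re-loadable with \code{\link{readParamsJSON}}.
#'
#' @param params a \linkS4class{ModelParameters} object.
#' @param path output file path.
#' @export
writeParamsJSON <- function(params, path) {
    rec <- c(list(model_id = modelId(params)),
             as.list(paramVector(params)))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path a file written by \code{\link{writeParamsJSON}}.
#' @return a \linkS4class{ModelParameters} object.
#' @export
readParamsJSON <- function(path) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(rec$model_id))
        stop("missing model_id field")
    if (rec$model_id == "aim") {
        aimParameters(lambda1 = rec$lambda1, lambda2 = rec$lambda2,
                      lambda12 = rec$lambda12, theta1 = rec$theta1,
                      theta2 = rec$theta2, n1 = rec$n1, n2 = rec$n2,
                      D = rec$D)
    } else if (rec$model_id == "ou") {
        ouParameters(mu = c(rec$mu1, rec$mu2), a11 = rec$a11,
                     a22 = rec$a22, a12 = rec$a12, D = rec$D)
    } else stop("unknown model_id: ", rec$model_id)
}

setMethod("show", "AIMParameters", function(object) {
    cat("AIMParameters\n")
    print(round(paramVector(object), 6))
})

setMethod("show", "BoundedOUParameters", function(object) {
    cat("BoundedOUParameters\n")
    print(round(paramVector(object), 6))
})

setMethod("show", "PotentialSurface", function(object) {
    n <- object@grid@n
    inner <- object@values[2:(n + 1), 2:(n + 1)]
    cat(sprintf("PotentialSurface on %d x %d grid (%s), F in [%.4g, %.4g]\n",
                n, n, modelId(object@params), min(inner), max(inner)))
})
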