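#' Rebin a probability field to another resolution
#'
#' Coarsening (source n a multiple of target n) sums equal square blocks;
#' refining (target n a multiple of source n) splits each cell's mass
#' equally among its sub-cells. Total mass is preserved exactly.
#'
#' @param field a \linkS4class{ProbabilityField}.
#' @param target_n target interior grid size.
#' @return a \linkS4class{ProbabilityField} on the target grid.
#' @export
rebinField <- function(field, target_n) {
    n <- field@grid@n
    target_n <- as.integer(target_n)
    if (target_n == n) return(field)
    if (n %% target_n == 0L) {
        f <- n %/% target_n
        gi <- rep(seq_len(target_n), each = f)
        m <- rowsum(field@mass, gi)
        m <- t(rowsum(t(m), gi))
    } else if (target_n %% n == 0L) {
        f <- target_n %/% n
        idx <- rep(seq_len(n), each = f)
        m <- field@mass[idx, idx] / f^2
    } else {
        stop("grid sizes are incompatible: one must divide the other")
    }
    dimnames(m) <- NULL
    asField(buildGrid(target_n), m, steps = field@steps)
}

#' Distance between two probability fields
#'
#' Computed on cell masses: \code{L2} is the Euclidean norm of the
#' per-cell mass differences, \code{Linf} their maximum absolute value.
#'
#' @param p,q \linkS4class{ProbabilityField}s on the same grid.
#' @param metric "L2" or "Linf".
#' @return nonnegative scalar.
#' @export
fieldDifference <- function(p, q, metric = c("L2", "Linf")) {
    metric <- match.arg(metric)
    .checkSameGrid(p, q)
    d <- p@mass - q@mass
    if (metric == "L2") sqrt(sum(d^2)) else max(abs(d))
}

#' Cross-validate the lattice propagator against Euler-Maruyama
#'
#' For each parameter set, draws a random initial condition (uniform over
#' the unit square, so no lattice resolution is favoured by having the
#' point mass aligned with its own cell centers), computes the lattice
#' conditional
#' field at each grid size and the Euler-Maruyama endpoint histogram at
#' each time horizon, rebins everything to 30 x 30, and reports the median
#' L2 and Linf differences per (grid size, time multiplier). Time horizons
#' are \code{t * (1/30)^2 / (5 D)} for each multiplier \code{t}, so the
#' lattice solver at n = 30 takes exactly \code{t} updates. The
#' Euler-Maruyama step is tied to the lattice step of the finest grid in
#' the study. Uses R's RNG for the initial conditions; the trajectory
#' oracle is seeded per parameter set from \code{em_seed}.
#'
#' @param params_list list of \linkS4class{ModelParameters}.
#' @param grid_sizes integer vector of lattice resolutions (multiples or
#'   divisors of 30).
#' @param t_multipliers time multipliers (default c(5, 50, 100, 500)).
#' @param n_traj Euler-Maruyama trajectories per parameter set.
#' @param em_seed base seed for the trajectory oracle.
#' @return data frame with columns \code{n}, \code{t}, \code{median_l2},
#'   \code{median_linf}.
#' @export
convergenceStudy <- function(params_list,
                             grid_sizes = c(15, 30, 60, 120),
                             t_multipliers = c(5, 50, 100, 500),
                             n_traj = 1e5, em_seed = 1L) {
    stopifnot(length(params_list) >= 1, length(grid_sizes) >= 1,
              length(t_multipliers) >= 1)
    grid_sizes <- sort(as.integer(grid_sizes))
    t_multipliers <- sort(t_multipliers)
    n_fine <- max(grid_sizes)
    ref <- buildGrid(30)
    l2 <- array(NA_real_,
                c(length(params_list), length(grid_sizes),
                  length(t_multipliers)))
    linf <- l2
    for (s in seq_along(params_list)) {
        params <- params_list[[s]]
        D <- params@D
        y0 <- stats::runif(2)
        durations <- t_multipliers * (1 / 30)^2 / (5 * D)
        cfg <- emConfig(dt = (1 / n_fine)^2 / (5 * D), n_traj = n_traj,
                        seed = em_seed + s)
        em_fields <- lapply(simulateEndpoints(params, y0, durations, cfg),
                            endpointsToField, grid = ref)
        for (gi in seq_along(grid_sizes)) {
            n <- grid_sizes[gi]
            grid <- buildGrid(n)
            surface <- tabulatePotential(params, grid)
            kernel <- buildKernel(surface, D)
            start <- deltaField(grid, y0)
            for (ti in seq_along(durations)) {
                field <- propagate(start, kernel, durations[ti])$field
                coarse <- rebinField(field, 30L)
                l2[s, gi, ti] <- fieldDifference(coarse, em_fields[[ti]],
                                                 "L2")
                linf[s, gi, ti] <- fieldDifference(coarse, em_fields[[ti]],
                                                   "Linf")
            }
        }
    }
    out <- expand.grid(n = grid_sizes, t = t_multipliers)
    out$median_l2 <- as.vector(apply(l2, c(2, 3), stats::median))
    out$median_linf <- as.vector(apply(linf, c(2, 3), stats::median))
    out
}
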