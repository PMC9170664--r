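# Shared fixtures. A moderate bimodal-ish AIM parameter set used as the
# canonical "truth" throughout, and a sampler of realistic fitted-like
# parameter sets (self-excitation and thresholds of order a few units,
# entropy weights of order one, D of order 0.005/h so a typical 72-min
# gap costs a few dozen lattice updates).

canonicalAim <- function(D = 0.005) {
    aimParameters(lambda1 = 4, lambda2 = 3, lambda12 = 2, theta1 = 2,
                  theta2 = 3, n1 = 2, n2 = 2, D = D)
}

randomAim <- function() {
    aimParameters(lambda1 = runif(1, 0, 6), lambda2 = runif(1, 0, 6),
                  lambda12 = runif(1, -2, 4), theta1 = runif(1, 0, 4),
                  theta2 = runif(1, 0, 4), n1 = runif(1, 0.5, 3),
                  n2 = runif(1, 0.5, 3),
                  D = exp(runif(1, log(0.002), log(0.02))))
}

flatParams <- function(D = 1) aimParameters(D = D)

# Minimum per-cell stay probability implied by a kernel.
minStayProbability <- function(kernel) {
    a <- kernel@accept
    min(1 - 0.2 * (a$down1 + a$up1 + a$down2 + a$up2))
}

# Conditional mean and per-dimension variance of a field.
fieldMoments <- function(field) {
    ctr <- cellCenters(field@grid)
    m <- cellMasses(field)
    m1 <- sum(rowSums(m) * ctr)
    m2 <- sum(colSums(m) * ctr)
    list(mean = c(m1, m2),
         var = c(sum(rowSums(m) * ctr^2) - m1^2,
                 sum(colSums(m) * ctr^2) - m2^2))
}
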