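test_that("free energy matches hand-computed values and symmetry", {
    expect_equal(freeEnergy(flatParams(), c(0.37, 0.81)), 0)
    # pure entropy at the center: 2 * 0.5 log 0.5 twice
    expect_equal(freeEnergy(aimParameters(n1 = 1, n2 = 1, D = 1),
                            c(0.5, 0.5)),
                 2 * log(0.5), tolerance = 1e-12)
    # pure interaction
    expect_equal(freeEnergy(aimParameters(lambda12 = 2, D = 1),
                            c(0.5, 0.5)), 0.5)
    # swapping the two dimensions' parameters and coordinates leaves F
    p <- aimParameters(4, 1, 2, 0.5, 3, 2, 0.7, D = 1)
    q <- aimParameters(1, 4, 2, 3, 0.5, 0.7, 2, D = 1)
    y <- c(0.3, 0.8)
    expect_equal(freeEnergy(p, y), freeEnergy(q, rev(y)))
    expect_error(freeEnergy(p, c(0, 0.5)), "strictly inside")
})

test_that("analytic gradients agree with finite differences", {
    set.seed(42)
    h <- 1e-6
    models <- list(canonicalAim(),
                   aimParameters(theta1 = 0.3, D = 1),
                   ouParameters(mu = c(0.4, 0.6), a11 = 10, a22 = 6,
                                a12 = 2, D = 1))
    for (p in models) {
        for (i in 1:100) {
            y <- runif(2, 0.05, 0.95)
            g <- freeEnergyGradient(p, y)
            fd <- c((freeEnergy(p, y + c(h, 0)) -
                         freeEnergy(p, y - c(h, 0))) / (2 * h),
                    (freeEnergy(p, y + c(0, h)) -
                         freeEnergy(p, y - c(0, h))) / (2 * h))
            expect_lt(max(abs(g - fd)), 1e-5)
        }
    }
    # spot values
    expect_equal(freeEnergyGradient(flatParams(), c(0.2, 0.9)), c(0, 0))
    expect_equal(freeEnergyGradient(aimParameters(theta1 = 0.3, D = 1),
                                    c(0.5, 0.5)), c(0.3, 0))
    expect_equal(freeEnergyGradient(aimParameters(n1 = 1, D = 1),
                                    c(0.25, 0.5)),
                 c(log(1 / 3), 0), tolerance = 1e-12)
})

test_that("entropy wall steepens toward the boundary", {
    p <- aimParameters(n1 = 1, D = 1)
    g <- vapply(c(1e-2, 1e-3, 1e-4),
                function(e) abs(freeEnergyGradient(p, c(e, 0.5))[1]),
                numeric(1))
    expect_true(all(diff(g) > 0))
})

test_that("tabulation fills interior from cell centers and Inf ghosts", {
    g <- buildGrid(30)
    s <- tabulatePotential(flatParams(), g)
    expect_true(all(s@values[2:31, 2:31] == 0))
    expect_true(all(is.infinite(s@values[1, ])))
    expect_true(all(is.infinite(s@values[, 32])))

    p <- canonicalAim()
    s <- tabulatePotential(p, g)
    ctr <- cellCenters(g)
    for (idx in list(c(1, 1), c(15, 7), c(30, 30))) {
        expect_equal(s@values[idx[1] + 1, idx[2] + 1],
                     freeEnergy(p, ctr[idx]))
    }
    # idempotence
    expect_identical(s@values, tabulatePotential(p, g)@values)

    # bounded OU minimum sits at the cells nearest the attractor
    ou <- ouParameters(mu = c(0.5, 0.5), a11 = 8, a22 = 8, a12 = 0, D = 1)
    so <- tabulatePotential(ou, g)
    inner <- so@values[2:31, 2:31]
    best <- which(inner == min(inner), arr.ind = TRUE)
    expect_true(all(best %in% c(15, 16)))
})

test_that("parameter vectors and JSON round-trip", {
    p <- canonicalAim()
    v <- paramVector(p)
    expect_named(v, c("lambda1", "lambda2", "lambda12", "theta1", "theta2",
                      "n1", "n2", "D"))
    expect_equal(paramVector(paramsFromVector(v, "aim")), v)

    ou <- ouParameters(mu = c(0.3, 0.7), a11 = 5, a22 = 9, a12 = -1,
                       D = 0.1)
    expect_equal(paramVector(paramsFromVector(paramVector(ou), "ou")),
                 paramVector(ou))

    path <- tempfile(fileext = ".json")
    writeParamsJSON(p, path)
    expect_equal(paramVector(readParamsJSON(path)), v)

    expect_error(aimParameters(lambda1 = -1), "nonnegative")
    expect_error(ouParameters(a11 = 1, a22 = 1, a12 = 2),
                 "positive definite")
})
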