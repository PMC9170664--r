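test_that("grid geometry follows the cell-center convention", {
    g <- buildGrid(30)
    expect_equal(binWidth(g), 1 / 30)
    expect_equal(round(binWidth(g), 3), 0.033)
    expect_equal(cellCenters(buildGrid(2)), c(0.25, 0.75))
    for (n in c(2, 7, 30)) {
        ctr <- cellCenters(buildGrid(n))
        expect_equal(ctr[1], 1 / (2 * n))
        expect_equal(ctr[n], 1 - 1 / (2 * n))
    }
    expect_error(buildGrid(1), ">= 2")
})

test_that("kernel acceptances follow min(1, exp(dF)) with zero ghosts", {
    g <- buildGrid(30)
    flat <- buildKernel(tabulatePotential(flatParams(), g), 1)
    a <- flat@accept
    # all interior-neighbor acceptances are exactly 1 on a flat surface
    expect_true(all(a$down1[-1, ] == 1))
    expect_true(all(a$up2[, -30] == 1))
    # ghost-ward acceptances exactly zero
    expect_true(all(a$down1[1, ] == 0))
    expect_true(all(a$up1[30, ] == 0))
    expect_true(all(a$down2[, 1] == 0))
    expect_true(all(a$up2[, 30] == 0))
    expect_equal(stepSize(flat), 1 / 4500)

    # uphill move F = 0.5 -> 1.0 is accepted with exp(-0.5)
    p <- canonicalAim()
    s <- tabulatePotential(p, g)
    k <- buildKernel(s, p@D)
    i <- 10; j <- 17
    dF <- s@values[i + 1 + 1, j + 1] - s@values[i + 1, j + 1]
    expect_equal(k@accept$up1[i, j], min(1, exp(-dF)))
    expect_equal(min(1, exp(0.5 - 1.0)), 0.606531, tolerance = 1e-6)
    expect_error(buildKernel(s, 0), "positive")
})

test_that("delta fields land in the half-open cell containing the point", {
    g <- buildGrid(30)
    f <- deltaField(g, c(0.5, 0.5))
    expect_equal(sum(cellMasses(f)), 1)
    expect_equal(which(cellMasses(f) != 0, arr.ind = TRUE)[1, ],
                 c(row = 16, col = 16))  # 0-based cell (15, 15)
    f <- deltaField(g, c(1, 0))
    expect_equal(which(cellMasses(f) != 0, arr.ind = TRUE)[1, ],
                 c(row = 30, col = 1))  # clamped to (29, 0)
    expect_error(deltaField(g, c(1.1, 0)), "unit square")
})

test_that("one lattice update spreads mass 1/5 to accepted neighbors", {
    g <- buildGrid(30)
    k <- buildKernel(tabulatePotential(flatParams(), g), 1)
    f1 <- mhStep(deltaField(g, c(0.5, 0.5)), k)
    m <- cellMasses(f1)
    expect_equal(m[16, 16], 0.2)
    expect_equal(m[15, 16], 0.2)
    expect_equal(m[17, 16], 0.2)
    expect_equal(m[16, 15], 0.2)
    expect_equal(m[16, 17], 0.2)
    expect_equal(stepCount(f1), 1)
    # corner: two proposals rejected by the ghost layer
    mc <- cellMasses(mhStep(deltaField(g, c(0, 0)), k))
    expect_equal(mc[1, 1], 3 / 5)
    expect_equal(mc[2, 1], 1 / 5)
    expect_equal(mc[1, 2], 1 / 5)
})

test_that("Boltzmann field satisfies detailed balance and is invariant", {
    g <- buildGrid(30)
    p <- canonicalAim()
    s <- tabulatePotential(p, g)
    k <- buildKernel(s, p@D)
    st <- stationaryField(s)
    pi_ <- cellMasses(st)
    # detailed balance across vertical neighbor pairs, to 1e-14
    lhs <- pi_[-30, ] * 0.2 * k@accept$up1[-30, ]
    rhs <- pi_[-1, ] * 0.2 * k@accept$down1[-1, ]
    expect_lt(max(abs(lhs - rhs)), 1e-14)
    lhs <- pi_[, -30] * 0.2 * k@accept$up2[, -30]
    rhs <- pi_[, -1] * 0.2 * k@accept$down2[, -1]
    expect_lt(max(abs(lhs - rhs)), 1e-14)
    # invariance under one update
    st1 <- mhStep(st, k)
    expect_lt(max(abs(cellMasses(st1) - pi_)), 1e-14)
})

test_that("mass is conserved and no cell loses more than 4/5 per step", {
    set.seed(3)
    g <- buildGrid(30)
    for (rep in 1:5) {
        p <- randomAim()
        k <- buildKernel(tabulatePotential(p, g), p@D)
        m0 <- matrix(rexp(900), 30, 30)
        f <- asField(g, m0 / sum(m0))
        before <- cellMasses(f)
        f1 <- mhStep(f, k)
        expect_lt(abs(sum(cellMasses(f1)) - sum(before)), 1e-15)
        expect_true(all(cellMasses(f1) >= before / 5 - 1e-15))
    }
})

test_that("propagate takes round(duration/dt) steps with a 1-step floor", {
    g <- buildGrid(30)
    p <- canonicalAim()
    k <- buildKernel(tabulatePotential(p, g), p@D)
    f <- deltaField(g, c(0.5, 0.5))
    for (t in c(5, 50, 100, 500)) {
        expect_equal(propagate(f, k, t * (1 / 30)^2 / (5 * p@D))$steps, t)
    }
    expect_equal(propagate(f, k, 0)$steps, 0)
    expect_equal(propagate(f, k, stepSize(k) * 1e-3)$steps, 1)
    expect_error(propagate(f, k, -1), "nonnegative")
})

test_that("long propagation converges to the Boltzmann field", {
    g <- buildGrid(30)
    p <- canonicalAim()
    s <- tabulatePotential(p, g)
    k <- buildKernel(s, p@D)
    st <- stationaryField(s)
    out <- propagate(deltaField(g, c(0.1, 0.9)), k, 1e5 * stepSize(k))
    expect_equal(out$steps, 1e5)
    expect_lt(fieldDifference(out$field, st, "Linf"), 1e-8)
})

test_that("stationary field weights cells by exp(-F)", {
    g <- buildGrid(30)
    u <- stationaryField(tabulatePotential(flatParams(), g))
    expect_true(all(abs(cellMasses(u) - 1 / 900) < 1e-15))
    # two-level surface: mass ratio e between low and high cells
    vals <- matrix(Inf, 32, 32)
    lev <- matrix(rep(c(0, 1), length.out = 900), 30, 30)
    vals[2:31, 2:31] <- lev
    s <- new("PotentialSurface", grid = g, values = vals,
             params = flatParams())
    st <- cellMasses(stationaryField(s))
    expect_equal(st[lev == 0][1] / st[lev == 1][1], exp(1))
})

test_that("density queries convert cell mass to density", {
    g <- buildGrid(30)
    expect_equal(densityAt(uniformField(g), c(0.123, 0.9)), 1.0)
    f <- deltaField(g, c(0.5, 0.5))
    expect_equal(densityAt(f, c(0.5, 0.5)), 900)
    expect_equal(densityAt(f, c(0.1, 0.1)), 0)
})

test_that("fields round-trip through plain-text export", {
    g <- buildGrid(15)
    p <- canonicalAim()
    st <- stationaryField(tabulatePotential(p, buildGrid(15)))
    path <- tempfile(fileext = ".txt")
    writeField(st, path)
    back <- readField(path)
    expect_equal(gridSize(back), 15)
    expect_lt(fieldDifference(st, back, "Linf"), 1e-12)
})
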