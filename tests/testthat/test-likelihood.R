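test_that("instrument rescaling maps and averages item columns", {
    s <- rescaleSeries(data.frame(pa = c(50, 0), na = c(50, 100)), 0, 100)
    expect_equal(s@values[1, ], c(0.5, 0.5))
    expect_equal(s@values[2, ], c(0.0, 1.0))
    items <- data.frame(euphoric = 60, happy = 80, relaxed = 40,
                        depressed = 10, stressed = 20, anxious = 0,
                        angry = 10)
    s <- rescaleSeries(items, 0, 100,
                       pa_cols = c("euphoric", "happy", "relaxed"),
                       na_cols = c("depressed", "stressed", "anxious",
                                   "angry"))
    expect_equal(s@values[1, 1], 0.6)
    expect_equal(s@values[1, 2], 0.1)
    expect_error(rescaleSeries(data.frame(pa = 120, na = 10), 0, 100),
                 "rows: 1")
})

test_that("pair likelihoods reduce to the uniform density on a flat surface", {
    p <- flatParams(D = 0.05)
    # long interval: the conditional is the uniform stationary density 1
    nll <- pairNegLogLik(p, c(0.2, 0.8), c(0.7, 0.3), 100)
    expect_lt(abs(nll), 1e-6)
    # zero-mass target cell is floored
    p2 <- canonicalAim()
    nll <- pairNegLogLik(p2, c(0.1, 0.1), c(0.9, 0.9),
                         stepSize(buildKernel(tabulatePotential(
                             p2, buildGrid(30)), p2@D)))
    expect_equal(nll, -log(1e-300), tolerance = 1e-6)
    expect_error(pairNegLogLik(p, c(0.5, 0.5), c(0.5, 0.5), 0),
                 "positive")
})

test_that("lattice conditional densities agree with the trajectory oracle", {
    # Monte-Carlo cross-check at a moderate horizon (100 lattice updates on
    # the default grid). The band combines 3 binomial SEs on the log scale
    # with a 0.15 allowance for the n = 30 lattice discretisation bias.
    set.seed(21)
    n_traj <- 2e4
    for (rep in 1:3) {
        p <- randomAim()
        x_from <- c(runif(1, 0.3, 0.7), runif(1, 0.3, 0.7))
        interval <- 100 * (1 / 30)^2 / (5 * p@D)
        g <- buildGrid(30)
        cond <- propagate(deltaField(g, x_from),
                          buildKernel(tabulatePotential(p, g), p@D),
                          interval)$field
        mode_cell <- which(cellMasses(cond) == max(cellMasses(cond)),
                           arr.ind = TRUE)[1, ]
        x_to <- cellCenters(g)[mode_cell]
        nll <- pairNegLogLik(p, x_from, x_to, interval)
        cfg <- emConfig(dt = emReferenceDt(p@D, 120), n_traj = n_traj,
                        seed = 100 + rep)
        ep <- simulateEndpoints(p, x_from, interval, cfg)
        m_hat <- densityAt(endpointsToField(ep, g), x_to) / 900
        se_log <- sqrt((1 - m_hat) / (m_hat * n_traj))
        expect_lt(abs(nll - (-log(m_hat * 900))), 3 * se_log + 0.15)
    }
})

test_that("series likelihood honours nights, gaps and the first point", {
    p <- canonicalAim()
    opts <- likelihoodOptions()
    # single observation, skipped initial point
    s1 <- affectTimeSeries(1, matrix(c(0.5, 0.5), 1), day = 0L)
    expect_equal(negLogLikelihood(p, s1, opts), 0)

    set.seed(17)
    # two days: only within-day pairs are evaluated, so the total equals
    # the sum of the per-day likelihoods (concatenation additivity)
    tms <- c(10, 11.5, 13, 34, 35.2, 36.4)
    vals <- matrix(runif(12, 0.2, 0.8), 6, 2)
    day <- as.integer(c(0, 0, 0, 1, 1, 1))
    s <- affectTimeSeries(tms, vals, day = day)
    sA <- affectTimeSeries(tms[1:3], vals[1:3, ], day = day[1:3])
    sB <- affectTimeSeries(tms[4:6], vals[4:6, ], day = day[4:6])
    expect_equal(negLogLikelihood(p, s, opts),
                 negLogLikelihood(p, sA, opts) +
                     negLogLikelihood(p, sB, opts))

    # a missed beep bridges the gap: dropping the row entirely is identical
    valid <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
    s_miss <- affectTimeSeries(tms, vals, day = day, valid = valid)
    s_drop <- affectTimeSeries(tms[valid], vals[valid, ],
                               day = day[valid])
    expect_equal(negLogLikelihood(p, s_miss, opts),
                 negLogLikelihood(p, s_drop, opts))

    # flat potential, long gaps, stationary initial point: everything is
    # the uniform density 1
    pf <- flatParams(D = 0.05)
    s2 <- affectTimeSeries(c(0, 100), matrix(runif(4), 2), day = c(0L, 0L))
    expect_lt(abs(negLogLikelihood(
        pf, s2, likelihoodOptions(initial_mode = "stationary"))), 1e-6)

    # stationary_restart evaluates the first point of the new day
    opts_r <- likelihoodOptions(night_mode = "stationary_restart")
    st <- stationaryField(tabulatePotential(p, buildGrid(30)))
    expect_equal(negLogLikelihood(p, s, opts_r) -
                     negLogLikelihood(p, s, opts),
                 -log(densityAt(st, vals[4, ])))
    expect_error(negLogLikelihood(p, affectTimeSeries(numeric(0),
                 matrix(numeric(0), 0, 2), integer(0), logical(0))),
                 "empty")
})

test_that("likelihood is finite everywhere and lowest near the truth", {
    set.seed(31)
    truth <- canonicalAim()
    g <- buildGrid(30)
    half <- paramsFromVector(replace(paramVector(truth), 8, truth@D / 2),
                             "aim")
    dbl <- paramsFromVector(replace(paramVector(truth), 8, truth@D * 2),
                            "aim")
    votes_half <- 0; votes_dbl <- 0
    n_series <- 50
    for (r in 1:n_series) {
        sched <- esmSchedule(scheduleConfig(days = 3))
        s <- simulateSeries(truth, sched, g)
        n0 <- negLogLikelihood(truth, s)
        expect_true(is.finite(n0))
        votes_half <- votes_half + (n0 <= negLogLikelihood(half, s))
        votes_dbl <- votes_dbl + (n0 <= negLogLikelihood(dbl, s))
    }
    expect_gt(votes_half, n_series / 2)
    expect_gt(votes_dbl, n_series / 2)
})

test_that("step budget turns oversized evaluations into Inf", {
    p <- canonicalAim()
    s <- affectTimeSeries(c(1, 2, 3), matrix(runif(6, 0.3, 0.7), 3),
                          day = c(0L, 0L, 0L))
    expect_true(is.finite(negLogLikelihood(p, s)))
    expect_identical(negLogLikelihood(p, s,
                                      likelihoodOptions(step_budget = 1)),
                     Inf)
})
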