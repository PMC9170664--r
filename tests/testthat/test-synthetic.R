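test_that("stratified schedules stay in the window with a 72-minute gap", {
    set.seed(14)
    sched <- esmSchedule(scheduleConfig(days = 1000))
    tod <- sched$time %% 24
    expect_true(all(tod >= 10 & tod <= 22))
    expect_true(all(tapply(sched$time, sched$day, function(x)
        all(diff(x) > 0))))
    gaps <- unlist(tapply(sched$time, sched$day, diff)) * 60
    expect_lt(abs(mean(gaps) - 72), 1.5)
    # full compliance answers every beep
    set.seed(15)
    full <- esmSchedule(scheduleConfig(days = 20, compliance = 1))
    expect_true(all(full$answered))
    expect_equal(nrow(full), 200)
    # default compliance misses ~13%
    set.seed(16)
    part <- esmSchedule(scheduleConfig(days = 500))
    expect_lt(abs(mean(part$answered) - 0.87), 0.02)
})

test_that("schedules and series are reproducible under a fixed seed", {
    gen <- function() {
        set.seed(23)
        sched <- esmSchedule(scheduleConfig(days = 3))
        simulateSeries(canonicalAim(), sched, buildGrid(30))
    }
    a <- gen(); b <- gen()
    expect_identical(a@values, b@values)
    expect_identical(a@time, b@time)
})

test_that("first-of-day draws follow the stationary field", {
    # flat potential: stationary field is uniform, so first-of-day cells
    # are uniform over the 900 cells up to binomial noise
    set.seed(25)
    p <- flatParams(D = 0.05)
    g <- buildGrid(30)
    n_days <- 3000
    sched <- data.frame(time = (seq_len(n_days) - 1) * 24 + 12,
                        day = seq_len(n_days) - 1, answered = TRUE)
    s <- simulateSeries(p, sched, g)
    expect_true(all(s@values >= 0 & s@values <= 1))
    cells <- endpointsToField(s@values, g)
    p0 <- 1 / 900
    se <- sqrt(p0 * (1 - p0) / n_days)
    expect_lt(max(abs(cellMasses(cells) - p0)), 5 * se)
})

test_that("many-day marginals converge to the Boltzmann distribution", {
    # chi-square on the 900 grid cells for stationary draws
    set.seed(26)
    p <- canonicalAim()
    g <- buildGrid(30)
    st <- stationaryField(tabulatePotential(p, g))
    n <- 1e4
    draws <- affectfp:::.sampleField(st, n)
    counts <- cellMasses(endpointsToField(draws, g)) * n
    expected <- cellMasses(st) * n
    keep <- expected > 0
    stat <- sum((counts[keep] - expected[keep])^2 / expected[keep])
    df <- sum(keep) - 1
    expect_gt(stats::pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("tiny D keeps consecutive within-day draws in place often", {
    # with less than one expected lattice update per gap (floored to one
    # step), the self-transition bound keeps P(same cell) >= 1/5
    set.seed(27)
    p <- canonicalAim(D = 1e-5)
    g <- buildGrid(30)
    sched <- esmSchedule(scheduleConfig(days = 60, compliance = 1))
    s <- simulateSeries(p, sched, g)
    same <- 0; tot <- 0
    idx <- which(s@valid)
    for (r in 2:length(idx)) {
        a <- idx[r - 1]; b <- idx[r]
        if (s@day[a] != s@day[b]) next
        tot <- tot + 1
        ca <- floor(s@values[a, ] * 30)
        cb <- floor(s@values[b, ] * 30)
        same <- same + all(ca == cb)
    }
    expect_gt(same / tot, 0.2 - 3 * sqrt(0.2 * 0.8 / tot))
})

test_that("recovery experiments tabulate true against estimated values", {
    set.seed(29)
    out <- recoveryExperiment(
        list(canonicalAim()), multiplier = 2L,
        schedule_config = scheduleConfig(days = 2),
        de_config = deConfig(NP = 6, generations = 3, seed = 1),
        options = likelihoodOptions(step_budget = 5e4))
    expect_equal(nrow(out), 16)  # 8 parameters x 2 size conditions
    expect_setequal(unique(out$size), c("base", "enlarged"))
    expect_equal(out$true[out$parameter == "D"],
                 rep(0.005, 2))
    expect_true(all(is.finite(out$estimate)))
})
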