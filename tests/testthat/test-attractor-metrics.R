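test_that("eigenvalue time constants match closed forms and flags", {
    tc <- timeConstants(diag(c(exp(-1), 0.9)), frameRate = 10)
    expect_equal(sort(tc@tauFrames), sort(c(1, abs(1 / log(0.9)))),
                 tolerance = 1e-9)
    expect_equal(sort(round(tc@tauFrames, 3)), c(1, 9.491))
    expect_equal(sort(tc@tauSeconds)[1], 0.1)

    tcInf <- timeConstants(diag(c(1, 0.5)))
    expect_true(any(is.infinite(tcInf@tauFrames)))
    expect_true("infinite" %in% tcInf@flags)
    tc0 <- timeConstants(matrix(0, 2, 2))
    expect_true(all(tc0@flags == "zero"))
    tcU <- timeConstants(diag(c(1.2, 0.5)))
    expect_true("unstable" %in% tcU@flags)
    expect_error(timeConstants(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("line-attractor score is the log2 tau ratio, scale-free", {
    expect_equal(lineAttractorScore(c(4, 1)), 2)
    expect_equal(lineAttractorScore(c(3, 3)), 0)
    expect_equal(lineAttractorScore(c(10, 2)), log2(5), tolerance = 1e-12)
    expect_equal(round(lineAttractorScore(c(10, 2)), 4), 2.3219)
    expect_equal(lineAttractorScore(c(2, 8, 1)),
                 lineAttractorScore(10 * c(2, 8, 1)))
    expect_error(lineAttractorScore(5), "two")
})

test_that("autocorrelation uses the biased 1/T estimator", {
    y <- c(1, 3, 2, 5, 4, 6, 2, 3)
    a <- autocorrelation(y, maxLag = 3)
    # direct evaluation of the printed formula
    T <- length(y); yb <- mean(y)
    ck <- vapply(0:3, function(k)
        sum((y[1:(T - k)] - yb) * (y[(1 + k):T] - yb)) / T, 0)
    expect_equal(a@c, ck, tolerance = 1e-12)
    expect_equal(a@r, ck / ck[1], tolerance = 1e-12)
    expect_equal(a@r[1], 1)
    expect_error(autocorrelation(rep(2, 100)), "zero-variance")
})

test_that("AR(1) autocorrelation matches its closed form", {
    set.seed(21)
    T <- 10000
    y <- as.numeric(arima.sim(list(ar = 0.8), T))
    a <- autocorrelation(y, maxLag = 5)
    expect_equal(a@r[2], 0.8, tolerance = 0.02)
    w <- rnorm(T)
    aw <- autocorrelation(w, maxLag = 5)
    expect_lt(abs(aw@r[2]), 2 / sqrt(T) * 1.5)
})

test_that("autocorrelation half-width interpolates the 0.5 crossing", {
    r <- 0.5^(0:20)
    a <- new("AutocorrFunction", lags = 0:20, r = r, c = r, c0 = 1,
             mean = 0, n = 1000L)
    expect_equal(as.numeric(autocorrHalfWidth(a, frameRate = 10)), 0.1)
    r2 <- exp(-(0:100) / 20)
    a2 <- new("AutocorrFunction", lags = 0:100, r = r2, c = r2, c0 = 1,
              mean = 0, n = 1000L)
    hw <- autocorrHalfWidth(a2, frameRate = 10)
    expect_equal(as.numeric(hw), 20 * log(2) / 10, tolerance = 1e-3)
    expect_false(attr(hw, "censored"))
    r3 <- rep(0.9, 11); r3[1] <- 1
    a3 <- new("AutocorrFunction", lags = 0:10, r = r3, c = r3, c0 = 1,
              mean = 0, n = 1000L)
    expect_true(attr(autocorrHalfWidth(a3, 10), "censored"))
})

test_that("half-width grows monotonically with the planted AR timescale", {
    set.seed(22)
    hw <- vapply(c(0.6, 0.9, 0.98), function(a)
        as.numeric(autocorrHalfWidth(
            as.numeric(arima.sim(list(ar = a), 8000)), frameRate = 10)), 0)
    expect_true(all(diff(hw) > 0))
})

test_that("Eq.-5 tau equals the simulated e-folding time within one frame", {
    for (lam in c(0.8, 0.95, 0.99)) {
        tau <- timeConstants(matrix(lam, 1, 1), frameRate = 1)@tauFrames
        imp <- lam^(0:2000)
        tEfold <- which(imp <= exp(-1))[1] - 1
        expect_lt(abs(tau - tEfold), 1)
    }
})

test_that("flow fields vanish at fixed points and respect eigenstructure", {
    A <- matrix(c(0.9, 0, 0, 0.8), 2, 2)
    b <- c(0.5, 0.2)
    C <- matrix(rnorm(8), 4, 2)
    p <- RSLDSParams(A = A, C = C, b = b)
    xstar <- solve(diag(2) - A, b)
    ff <- flowField(p, xlim = xstar[1] + c(-1e-9, 1e-9),
                    ylim = xstar[2] + c(-1e-9, 1e-9), n = 2)
    expect_lt(max(sqrt(rowSums(ff@velocity^2))), 1e-6)

    pI <- RSLDSParams(A = diag(2), C = C)
    ffI <- flowField(pI, n = 5)
    expect_equal(max(abs(ffI@velocity)), 0)

    # planted line attractor: motion along the slow eigenvector is far
    # slower than along the fast one at equal displacement
    pLA <- RSLDSParams(A = diag(c(0.999, 0.905)), C = C)
    vSlow <- abs((0.999 - 1) * 1)
    vFast <- abs((0.905 - 1) * 1)
    expect_lt(vSlow / vFast, 0.1)
    ff2 <- flowField(pLA, xlim = c(1, 1), ylim = c(0, 0), n = 1)
    expect_equal(as.numeric(ff2@velocity), c(-0.001, 0), tolerance = 1e-12)
})

test_that("ramp and decay metrics recover planted kinetics", {
    fr <- 10
    tt <- seq(0, 99.9, by = 0.1)
    ev <- data.frame(start_s = 10, stop_s = 30, label = "attack")
    ramp <- ifelse(tt < 10, 0, ifelse(tt < 30, 0.2 * (tt - 10), 4))
    x <- ramp
    x[tt >= 30] <- 4 * exp(-(tt[tt >= 30] - 30) / 60)
    m <- rampDecayMetrics(x, ev, frameRate = fr)
    expect_equal(m$rampRatePerS[1], 0.2, tolerance = 1e-6)
    expect_equal(m$decayTauS[1], 60, tolerance = 1)

    flat <- rampDecayMetrics(rep(0, 1000), ev, frameRate = fr)
    expect_equal(flat$rampRatePerS[1], 0)
    expect_true(flat$degenerate[1])
    expect_error(rampDecayMetrics(rep(0, 50),
                                  data.frame(start_s = 100, stop_s = 110),
                                  frameRate = fr), "outside")
})
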