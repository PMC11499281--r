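test_that("weight matrices follow the two-block sampling scheme", {
    cfg0 <- lifConfig(N = 300, Np = 60, sigma = 0, backgroundDensity = 0)
    W0 <- buildWeightMatrix(cfg0, seed = 1)
    expect_equal(length(W0@W@x), 0L)
    expect_equal(spectralRadius(W0), 0)

    cfg <- lifConfig(sigma = 0.1, backgroundDensity = 0)
    lam <- vapply(1:5, function(s)
        spectralRadius(buildWeightMatrix(cfg, seed = s)), 0)
    expect_lt(abs(mean(lam) - 0.1 * sqrt(200) / 2), 0.05)

    cfgHot <- lifConfig(sigma = 0.2, backgroundDensity = 0)
    expect_gt(spectralRadius(buildWeightMatrix(cfgHot, seed = 2)), 1)

    Wm <- buildWeightMatrix(lifConfig(N = 200, Np = 50, sigma = 0.3), 3)@W
    expect_true(all(Matrix::diag(Wm) == 0))
    expect_true(all(Wm@x >= 0 & Wm@x <= 1 / sqrt(50)))
    expect_error(lifConfig(sigma = 1.5), "densities")
})

test_that("spectral radius concentrates across seeds", {
    cfg <- lifConfig(sigma = 0.1)
    lam <- vapply(1:50, function(s)
        spectralRadius(buildWeightMatrix(cfg, seed = s)), 0)
    expect_lt(sd(lam) / mean(lam), 0.05)
})

test_that("analytic network tau follows tau_s / |1 - lambda_max|", {
    expect_equal(as.numeric(analyticNetworkTau(0.9, tauS = 20)), 200)
    expect_equal(as.numeric(analyticNetworkTau(0, tauS = 20)), 20)
    unst <- analyticNetworkTau(1, tauS = 20)
    expect_true(is.na(unst))
    expect_true(attr(unst, "unstable"))
})

test_that("quiescent networks stay quiescent and track constant input", {
    cfg <- lifConfig(N = 50, Np = 10, sigma = 0, backgroundDensity = 0,
                     noiseScale = 0)
    W <- buildWeightMatrix(cfg, seed = 1)
    sim <- simulateLIF(cfg, W, duration = 1, seed = 1)
    expect_equal(nrow(sim@spikes), 0L)
    expect_equal(max(sim@popRate), 0)

    # constant sub-threshold input: fixed point at w * s = 0.05
    inp <- list(s = rep(1, 1000), w = rep(0.05, 50))
    sim2 <- simulateLIF(cfg, W, duration = 1, seed = 1, input = inp)
    expect_equal(nrow(sim2@spikes), 0L)
})

test_that("simulations are bit-identical under a shared seed", {
    cfg <- lifConfig(N = 100, Np = 20, sigma = 0.2)
    W <- buildWeightMatrix(cfg, seed = 4)
    a <- simulateLIF(cfg, W, duration = 2, seed = 7)
    b <- simulateLIF(cfg, W, duration = 2, seed = 7)
    expect_identical(a@spikes, b@spikes)
    expect_identical(a@binned, b@binned)
    cfg0 <- cfg; cfg0@gInh <- 0
    c2 <- simulateLIFInhibition(cfg0, W, duration = 2, seed = 7)
    expect_identical(a@spikes, c2@spikes)
})

test_that("supercritical excitatory networks run away without inhibition", {
    cfg <- lifConfig(sigma = 0.2, tauS = 20, gInh = 0)
    W <- buildWeightMatrix(cfg, seed = 1)
    expect_gt(spectralRadius(W), 1)
    inp <- makePulseInput(cfg, 95, nPulses = 4, isiS = 20, startS = 5,
                          fracDriven = 0.5, seed = 2)
    sim <- simulateLIF(cfg, W, duration = 95, seed = 3, input = inp)
    pr <- sim@popRate
    base <- mean(pr[1:4000])
    # population rate grows across interstimulus intervals instead of
    # returning to baseline
    isiEnd <- vapply(inp$onsets[1:3] + 20, function(tt)
        mean(pr[(tt * 1000 - 1000):(tt * 1000)]), 0)
    expect_true(all(diff(isiEnd) > 0))
    expect_gt(isiEnd[3], 3 * base)
})

test_that("linearized rate dynamics decay at the analytic network tau", {
    cfg <- lifConfig(N = 200, Np = 40, sigma = 0.1, backgroundDensity = 0.01,
                     tauS = 5)
    W <- buildWeightMatrix(cfg, seed = 6)
    lam <- spectralRadius(W)
    tauN <- as.numeric(analyticNetworkTau(W, tauS = cfg@tauS))
    # Euler-integrate tau_s dp/dt = -p + W p from the dominant mode
    v <- rep(1, 200)
    for (i in 1:200) v <- as.numeric(W@W %*% v) / sqrt(sum(v^2))
    v <- v / sqrt(sum(v^2))
    dt <- 0.01
    p <- v
    steps <- 4000
    nrm <- numeric(steps)
    for (t in seq_len(steps)) {
        p <- p + dt / cfg@tauS * (-p + as.numeric(W@W %*% p))
        nrm[t] <- sqrt(sum(p^2))
    }
    tEmp <- dt * which(nrm <= exp(-1))[1]
    expect_rel_equal(tEmp, tauN, 0.10)
})

test_that("pulse inputs are disjoint, seeded and cover the driven fraction", {
    cfg <- lifConfig(N = 200, Np = 40, sigma = 0.1)
    inpAll <- makePulseInput(cfg, 30, nPulses = 2, isiS = 10,
                             fracDriven = 1, seed = 1)
    expect_true(all(inpAll$w > 0))
    inp <- makePulseInput(cfg, 100, nPulses = 4, isiS = 20, seed = 5)
    expect_equal(length(inp$onsets), 4L)
    expect_true(all(diff(inp$onsets) == 22))
    expect_equal(length(inp$driven), 50L)
    inp2 <- makePulseInput(cfg, 100, nPulses = 4, isiS = 20, seed = 5)
    expect_identical(inp$driven, inp2$driven)
    # between-pulse troughs return to zero
    mid <- round((inp$onsets[1] + 2 + 10) / cfg@dt)
    expect_lt(inp$s[mid], 1e-6)
})

test_that("phase diagram recovers the limiting rows and columns", {
    cfg <- lifConfig(N = 500, Np = 100, backgroundDensity = 0)
    pd <- phaseDiagram(sigmaGrid = c(0, 0.04, 0.08, 0.12, 0.25),
                       tauSGrid = c(0.1, 0.3, 20), cfg = cfg, seeds = 3)
    # sigma = 0 row: tau_n = tau_s exactly (no connectivity)
    expect_equal(pd$tau[1, ], c(0.1, 0.3, 20), ignore_attr = TRUE)
    # tau_s = 20 column increases monotonically with density while stable
    col <- pd$tau[, 3]
    stable <- which(!pd$unstable[, 3])
    expect_true(all(diff(col[stable]) > 0))
    # fast-synapse columns stay below 1 s on this grid (lambda <= ~0.6,
    # bounded away from 1)
    expect_true(all(pd$tau[1:4, 1:2] < 1, na.rm = TRUE))
    # the densest row is supercritical (lambda > 1) and masked
    expect_true(pd$unstable[5, 3])
    expect_true(is.na(pd$tau[5, 3]))
})

test_that("calcium convolution has exponential impulse and plateau response", {
    # single spike in one bin at 10 Hz
    rates <- matrix(0, 1, 200)
    rates[1, 50] <- 10            # one spike / 0.1 s bin = 10 Hz
    ca <- rateToCalcium(rates, kernelTau = 1.5, frameRate = 10, binRate = 10)
    pk <- which.max(ca[1, ])
    expect_equal(pk, 50L)
    after <- ca[1, pk + 15]        # one kernel tau later (1.5 s)
    expect_rel_equal(after / ca[1, pk], exp(-1), 0.01)

    expect_equal(max(abs(rateToCalcium(matrix(0, 2, 100), 1.5, 10, 10))), 0)

    rho <- 7
    const <- rateToCalcium(matrix(rho, 1, 4000), kernelTau = 1.5,
                           frameRate = 10, binRate = 100)
    expect_rel_equal(const[1, ncol(const)], rho * 1.5, 0.02)
})
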