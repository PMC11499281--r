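# Differential traces (perturbed minus unperturbed replay of the same
# session noise) isolate the stimulation effect exactly.
stimPair <- function(ses, targets, gain = 0.05, nPulses = 4, isi = 20) {
    prot <- generateStimProtocol(nPulses, isi, 2, 20, targets = targets,
                                 gain = gain, startS = 20)
    list(prot = prot, run = simulateTargetedStim(ses, prot))
}

test_that("zero-gain stimulation replays the session exactly", {
    ses <- stimSession()
    prot <- generateStimProtocol(4, 20, 2, 20,
                                 targets = selectTopNeurons(
                                     dimensionWeights(groundTruth(ses)), 1, 5),
                                 gain = 0, startS = 20)
    run <- simulateTargetedStim(ses, prot)
    expect_identical(activityMatrix(run$activity), activityMatrix(ses))
    expect_identical(run$latents@x, latentFactors(ses))
})

test_that("unknown targets and overlong protocols are rejected", {
    ses <- stimSession()
    expect_error(simulateTargetedStim(
        ses, generateStimProtocol(2, 20, 2, 20, targets = 9999L)), "targets")
    expect_error(simulateTargetedStim(
        ses, generateStimProtocol(20, 20, 2, 20, targets = 1L)), "duration")
})

test_that("slow-dimension targeting integrates; fast-dimension decays", {
    ses <- stimSession()
    wt <- dimensionWeights(groundTruth(ses))
    s1 <- stimPair(ses, selectTopNeurons(wt, "x1", 5))
    s2 <- stimPair(ses, selectTopNeurons(wt, "x2", 5))
    # stimulation effect in latent space, noise cancelled exactly
    d1 <- s1$run$latents@x[1, ] - latentFactors(ses)[1, ]
    d2 <- s2$run$latents@x[2, ] - latentFactors(ses)[2, ]
    W <- lineattractor:::.isiWindows(s1$prot, 10, length(d1), skipS = 1)
    isiEnd1 <- d1[W[, 2]]
    isiEnd2 <- d2[W[, 2]]
    expect_true(all(diff(isiEnd1[1:3]) > 0))          # leaky integration
    pulseAmp2 <- max(d2)
    expect_lt(max(abs(isiEnd2)), 0.05 * pulseAmp2)     # full relaxation

    pk1 <- isiPeakTable(d1, s1$prot, frameRate = 10)
    pk2 <- isiPeakTable(d2, s2$prot, frameRate = 10)
    expect_true(pk1$integration)
    expect_false(pk2$integration)
})

test_that("projection inverts the emission map and tracks stimulation", {
    ses <- stimSession()
    tr <- groundTruth(ses)
    y0 <- tr@C %*% latentFactors(ses) + tr@d
    pr <- projectOntoDimension(y0, tr, dim = 1, method = "pinv")
    expect_gt(cor(pr, latentFactors(ses)[1, ])^2, 0.999)
    yc <- matrix(rep(tr@C %*% c(1, 1) + tr@d, 30), nrow = nNeurons(ses))
    expect_lt(sd(projectOntoDimension(yc, tr, 1, "pinv")), 1e-10)
    expect_error(projectOntoDimension(y0, tr, dim = 7), "invalid")

    wt <- dimensionWeights(tr)
    s1 <- stimPair(ses, selectTopNeurons(wt, "x1", 5))
    dx1 <- projectOntoDimension(s1$run$activity, tr, 1, "pinv") -
        projectOntoDimension(ses@activity, tr, 1, "pinv")
    dx2 <- projectOntoDimension(s1$run$activity, tr, 2, "pinv") -
        projectOntoDimension(ses@activity, tr, 2, "pinv")
    W <- lineattractor:::.isiWindows(s1$prot, 10, length(dx1), skipS = 1)
    expect_gt(mean(dx1[W[, 2]]), 10 * abs(mean(dx2[W[, 2]])))
})

test_that("state-space displacement matches Euclidean geometry", {
    prot <- generateStimProtocol(2, 10, 2, 20, targets = 1L, startS = 5)
    xs <- matrix(0, 2, 300)
    d0 <- stateSpaceDisplacement(LatentTrajectory(xs), prot, 10)
    expect_true(all(abs(c(d0$dStimEnd, d0$dPostStim)) < 1e-12))

    xs2 <- matrix(0, 2, 300)
    xs2[, 71] <- c(3, 4)    # stim end of pulse 1 (7 s at 10 Hz)
    d1 <- stateSpaceDisplacement(LatentTrajectory(xs2), prot, 10)
    expect_equal(d1$dStimEnd[1], 5)

    # translation invariance
    ses <- stimSession()
    wt <- dimensionWeights(groundTruth(ses))
    s1 <- stimPair(ses, selectTopNeurons(wt, "x1", 5))
    da <- stateSpaceDisplacement(s1$run$latents, s1$prot, 10)
    shifted <- LatentTrajectory(s1$run$latents@x + 7.3, s1$run$latents@z)
    db <- stateSpaceDisplacement(shifted, s1$prot, 10)
    expect_equal(da, db, tolerance = 1e-12)

    # planted integrator: cumulative displacement; fast dim: relaxation
    diffLat <- LatentTrajectory(s1$run$latents@x - latentFactors(ses))
    dInt <- stateSpaceDisplacement(diffLat, s1$prot, 10)
    expect_true(all(diff(dInt$dPostStim[1:3]) > 0))
    s2 <- stimPair(ses, selectTopNeurons(wt, "x2", 5))
    diffLat2 <- LatentTrajectory(s2$run$latents@x - latentFactors(ses))
    dFast <- stateSpaceDisplacement(diffLat2, s2$prot, 10)
    expect_lt(max(dFast$dPostStim), 0.05 * max(dFast$dStimEnd))
})

test_that("influence scores are near zero for uncoupled ensembles", {
    coh <- generateUnitaryStimCohort(nX1 = 8, nX2 = 8, couplingDensity = 0,
                                     couplingZ = 0, crossMaxZ = 1e-6,
                                     seed = 3)
    im <- influenceScores(coh$activities, coh$protocols, coh$positions,
                          labels = coh$labels,
                          baselineWindow = coh$baselineWindow)
    sc <- im@scores[!im@mask]
    expect_lt(max(abs(sc), na.rm = TRUE), 0.2)
})

test_that("coupled ensembles separate within-group from cross-group scores", {
    coh <- generateUnitaryStimCohort(nX1 = 10, nX2 = 10,
                                     couplingDensity = 0.9, seed = 4)
    im <- influenceScores(coh$activities, coh$protocols, coh$positions,
                          labels = coh$labels,
                          baselineWindow = coh$baselineWindow)
    g <- im@groups
    s11 <- im@scores[, g == "x1"][!im@mask[, g == "x1"]]
    s12 <- im@scores[, g == "x2"][!im@mask[, g == "x2"]]
    expect_gt(median(s11, na.rm = TRUE), max(s12, na.rm = TRUE))
})

test_that("followers inside the exclusion radius are fully masked", {
    coh <- generateUnitaryStimCohort(nX1 = 4, nX2 = 4, seed = 5)
    pos <- coh$positions
    pos$x_um <- 0; pos$y_um <- 0        # everyone within 50 um
    im <- influenceScores(coh$activities, coh$protocols, pos,
                          labels = coh$labels,
                          baselineWindow = coh$baselineWindow)
    expect_true(all(is.na(im@scores)))
    expect_error(influenceScores(coh$activities, coh$protocols,
                                 positions = NULL, labels = coh$labels,
                                 baselineWindow = coh$baselineWindow),
                 "positions")
})

test_that("connectivity fraction thresholds at the maximum cross pair", {
    im <- new("InfluenceMatrix",
              scores = matrix(c(NA, 1, 2, 3, 2.5), 1, 5),
              mask = matrix(c(TRUE, rep(FALSE, 4)), 1, 5),
              targets = 1L, groups = c("x1", "x1", "x1", "x1", "x2"))
    expect_equal(connectivityFraction(im), 1 / 3)
    imLow <- new("InfluenceMatrix",
                 scores = matrix(c(NA, 0.1, 0.2, 0.9), 1, 4),
                 mask = matrix(c(TRUE, rep(FALSE, 3)), 1, 4),
                 targets = 1L, groups = c("x1", "x1", "x1", "x2"))
    expect_equal(connectivityFraction(imLow), 0)
    imEmpty <- new("InfluenceMatrix",
                   scores = matrix(c(NA, 0.5), 1, 2),
                   mask = matrix(c(TRUE, FALSE), 1, 2),
                   targets = 1L, groups = c("x1", "x1"))
    expect_error(connectivityFraction(imEmpty), "present")
})

test_that("stability-connectivity regression behaves at both extremes", {
    x <- c(10, 20, 30, 40)
    out <- stabilityConnectivityCorrelation(x, 2 * x + 1)
    expect_equal(out$r2, 1, tolerance = 1e-12)
    expect_equal(out$slope, 2, tolerance = 1e-12)
    set.seed(6)
    outR <- stabilityConnectivityCorrelation(rnorm(100), rnorm(100))
    expect_lt(outR$r2, 0.1)
    expect_error(stabilityConnectivityCorrelation(rep(1, 5), rnorm(5)),
                 "degenerate")
    expect_error(stabilityConnectivityCorrelation(1:2, 1:2), "three")

    # shared planted cause: per-session coupling drives both tau and the
    # evoked connectivity metric
    set.seed(7)
    cpl <- runif(12, 0.3, 0.5)
    tau <- 20 / (1 - cpl)
    conn <- 2 * cpl + rnorm(12, 0, 0.05)
    expect_gt(stabilityConnectivityCorrelation(tau, conn)$r2, 0.8)
})

test_that("ISI AUC integrates z-scored responses trapezoidally", {
    prot <- generateStimProtocol(1, 10, 2, 20, targets = 1L, startS = 1)
    z <- rep(1, 140)
    auc <- isiAUC(z, prot, frameRate = 10, skipS = 1)
    # constant 1 over a ~9 s window -> AUC close to the window length
    expect_gt(auc, 7); expect_lt(auc, 10)
    expect_equal(isiAUC(rep(0, 140), prot, 10), 0)
})
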