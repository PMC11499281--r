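test_that("planted dynamics eigenvalues follow exp(-1/(tau * rate))", {
    ses <- generateLineAttractorSession(nNeurons = 10, nFrames = 100,
                                        slowTauS = 100, fastTauS = 1,
                                        frameRate = 10, seed = 0)
    lam <- sort(Mod(eigen(groundTruth(ses)@A[[1]])$values))
    expect_equal(lam, c(exp(-1 / 10), exp(-1 / 1000)), tolerance = 1e-10)
    expect_equal(round(lam, 4), c(0.9048, 0.9990))
})

test_that("zero emission noise gives activity exactly C x + d", {
    ses <- generateLineAttractorSession(nNeurons = 12, nFrames = 200,
                                        emissionNoiseFrac = 0, seed = 2)
    tr <- groundTruth(ses)
    expect_equal(activityMatrix(ses),
                 unname(tr@C %*% latentFactors(ses) + tr@d),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ground-truth line-attractor score is log2 of the tau ratio", {
    ses <- generateLineAttractorSession(nNeurons = 10, nFrames = 100, seed = 0)
    expect_equal(lineAttractorScore(groundTruth(ses)), log2(100 / 1),
                 tolerance = 1e-8)
})

test_that("sessions are reproducible from the seed and taus round-trip", {
    a <- generateLineAttractorSession(nNeurons = 15, nFrames = 300, seed = 7)
    b <- generateLineAttractorSession(nNeurons = 15, nFrames = 300, seed = 7)
    expect_identical(activityMatrix(a), activityMatrix(b))
    expect_identical(latentFactors(a), latentFactors(b))
    c <- generateLineAttractorSession(nNeurons = 15, nFrames = 300, seed = 8)
    expect_false(identical(activityMatrix(a), activityMatrix(c)))

    tc <- timeConstants(groundTruth(a), frameRate = 10)
    tc <- tc[[attr(tc, "slowestState")]]
    expect_equal(sort(tc@tauSeconds, decreasing = TRUE), c(100, 1),
                 tolerance = 1e-9)
})

test_that("config invariants are enforced", {
    expect_error(generateLineAttractorSession(nNeurons = 1, nFrames = 100))
    expect_error(generateLineAttractorSession(10, 100, slowTauS = 1,
                                              fastTauS = 5), "slowTauS")
    expect_error(generateLineAttractorSession(10, 100,
                                              emissionNoiseFrac = -1))
    expect_error(generateLineAttractorSession(10, 100, slowTauS = Inf),
                 "finite")
})

test_that("more emission noise monotonically degrades reconstruction", {
    r2 <- vapply(c(0.05, 0.3, 1.0), function(fr) {
        ses <- generateLineAttractorSession(nNeurons = 20, nFrames = 500,
                                            emissionNoiseFrac = fr, seed = 11)
        lat <- inferLatents(groundTruth(ses), activityMatrix(ses),
                            inputs = ses@inputSchedule)
        yhat <- groundTruth(ses)@C %*% lat@x + groundTruth(ses)@d
        y <- activityMatrix(ses)
        1 - sum((y - yhat)^2) / sum((y - rowMeans(y))^2)
    }, 0)
    expect_true(all(diff(r2) < 0))
})

test_that("stimulation protocols place pulses at the documented onsets", {
    expect_equal(generateStimProtocol(4, 20, 2, 20, 1:5)@onsets,
                 c(0, 22, 44, 66))
    expect_equal(generateStimProtocol(4, 8, 2, 20, 1:5)@onsets,
                 c(0, 10, 20, 30))
    p <- generateStimProtocol(1, 20, 2, 20, 1)
    expect_equal(p@offsets - p@onsets, 2)
})

test_that("cell positions respect the field of view and labels", {
    pos <- generateCellPositions(50, fovUm = c(400, 300), seed = 1)
    expect_equal(nrow(pos), 50L)
    expect_true(all(pos$x_um >= 0 & pos$x_um <= 400))
    expect_true(all(pos$y_um >= 0 & pos$y_um <= 300))
    expect_true(all(pos$dim_label %in% c("x1", "x2", "neither")))
    expect_equal(nrow(generateCellPositions(1, seed = 1)), 1L)
    clus <- generateCellPositions(60, clustered = TRUE, seed = 2)
    m1 <- mean(clus$x_um[clus$dim_label == "x1"])
    m2 <- mean(clus$x_um[clus$dim_label == "x2"])
    expect_gt(abs(m1 - m2), 100)
})

test_that("motion features are unit-variance, smooth and deterministic", {
    mf <- generateMotionFeatures(600, nDims = 10, seed = 3)
    expect_equal(dim(mf), c(10L, 600L))
    expect_equal(apply(mf, 1, sd), rep(1, 10), tolerance = 1e-10)
    expect_identical(mf, generateMotionFeatures(600, nDims = 10, seed = 3))
    # low-pass: lag-1 autocorrelation well above white noise
    expect_gt(cor(mf[1, -1], mf[1, -600]), 0.7)
})
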