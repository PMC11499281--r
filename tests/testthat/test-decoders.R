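test_that("bout merging joins gaps under 5 s and keeps labels separate", {
    b <- data.frame(start_s = c(0, 12, 30, 3), stop_s = c(10, 20, 40, 8),
                    label = c("attack", "attack", "attack", "other"))
    m <- mergeBouts(b)
    att <- m[m$label == "attack", ]
    expect_equal(nrow(att), 2L)
    expect_equal(att$start_s, c(0, 30))
    expect_equal(att$stop_s, c(20, 40))
    expect_error(mergeBouts(data.frame(start_s = 5, stop_s = 2,
                                       label = "attack")), "start")
})

test_that("a separable signal decodes perfectly, noise decodes at chance", {
    fr <- 10
    b <- data.frame(start_s = c(10, 40, 70, 100),
                    stop_s = c(20, 50, 80, 110),
                    label = "attack")
    T <- 1300
    pos <- lineattractor:::.frameLabels(b, "attack", T, fr)
    sep <- ifelse(pos, 1, 0)
    dSep <- framewiseAttackDecoder(sep, b, frameRate = fr, seed = 1)
    expect_equal(dSep@accuracy, 1)

    set.seed(2)
    dNoise <- framewiseAttackDecoder(rnorm(T), b, frameRate = fr, seed = 1)
    expect_lt(abs(dNoise@accuracy - 0.5), 0.1)

    expect_error(framewiseAttackDecoder(rnorm(100),
        data.frame(start_s = 0, stop_s = 10, label = "attack"),
        frameRate = fr), "classes")
})

test_that("a 2-SD planted effect is decodable and beats its shuffle null", {
    fr <- 10
    T <- 3000
    b <- data.frame(start_s = c(20, 80, 140, 200, 260),
                    stop_s = c(50, 110, 170, 230, 290),
                    label = "attack")
    bAll <- rbind(b, data.frame(start_s = c(60, 180), stop_s = c(70, 190),
                                label = "other"))
    set.seed(3)
    sig <- rnorm(T)
    pos <- lineattractor:::.frameLabels(b, "attack", T, fr)
    sig[pos] <- sig[pos] + 2
    dec <- framewiseAttackDecoder(sig, bAll, frameRate = fr, seed = 1)
    # Bayes-optimal balanced accuracy at 2 SD separation is pnorm(1) = 0.84
    expect_gt(dec@accuracy, 0.8)
    nulls <- shuffleNull(sig, bAll, nShuffles = 100, frameRate = fr, seed = 1)
    dec <- attachNull(dec, nulls)
    expect_gt(dec@accuracy, quantile(nulls, 0.95, na.rm = TRUE))
    expect_lt(dec@pValue, 0.05)
})

test_that("decoding is invariant to strictly monotone signal transforms", {
    fr <- 10
    b <- data.frame(start_s = c(10, 40, 70), stop_s = c(20, 50, 80),
                    label = "attack")
    set.seed(4)
    sig <- rnorm(1000)
    pos <- lineattractor:::.frameLabels(b, "attack", 1000, fr)
    sig[pos] <- sig[pos] + 1.5
    a1 <- framewiseAttackDecoder(sig, b, frameRate = fr, seed = 2)@accuracy
    a2 <- framewiseAttackDecoder(exp(sig), b, frameRate = fr, seed = 2)@accuracy
    expect_equal(a1, a2)
})

test_that("frozen thresholds transfer across conditions symmetrically", {
    fr <- 10
    b <- data.frame(start_s = c(10, 40, 70, 100),
                    stop_s = c(25, 55, 85, 115), label = "attack")
    T <- 1300
    pos <- lineattractor:::.frameLabels(b, "attack", T, fr)
    set.seed(5)
    sig <- rnorm(T) + ifelse(pos, 1, -1)     # classes symmetric about 0
    dec <- framewiseAttackDecoder(sig, b, frameRate = fr, seed = 1)
    accSame <- crossConditionDecode(dec, sig, b, frameRate = fr)
    expect_gt(accSame, 0.75)
    accInv <- crossConditionDecode(dec, -sig, b, frameRate = fr)
    expect_lt(abs(accInv - (1 - accSame)), 0.06)
})

test_that("shuffle nulls are seeded, sized and centred at chance", {
    fr <- 10
    b <- data.frame(start_s = c(10, 40, 70, 100, 130, 160),
                    stop_s = c(20, 50, 80, 110, 140, 170),
                    label = rep(c("attack", "other"), 3))
    set.seed(6)
    sig <- rnorm(1800)
    n1 <- shuffleNull(sig, b, nShuffles = 1, frameRate = fr, seed = 3)
    expect_length(n1, 1L)
    n2 <- shuffleNull(sig, b, nShuffles = 30, frameRate = fr, seed = 3)
    n3 <- shuffleNull(sig, b, nShuffles = 30, frameRate = fr, seed = 3)
    expect_identical(n2, n3)
    expect_lt(abs(mean(n2, na.rm = TRUE) - 0.5), 0.06)
})

test_that("spatial decoder separates clustered labels but not uniform ones", {
    posU <- generateCellPositions(80, clustered = FALSE, seed = 3)
    dU <- spatialClusterDecoder(posU, nShuffles = 10, seed = 1)
    expect_lt(abs(dU@accuracy - mean(dU@nullAccuracies)), 0.15)

    posC <- generateCellPositions(80, clustered = TRUE, seed = 3)
    dC <- spatialClusterDecoder(posC, nShuffles = 10, seed = 1)
    expect_gt(dC@accuracy, 0.9)
    expect_lt(abs(mean(dC@nullAccuracies) - 0.5), 0.12)

    posOne <- posU; posOne$dim_label <- "x1"
    expect_error(spatialClusterDecoder(posOne), "both")

    posSame <- posU; posSame$x_um <- 1; posSame$y_um <- 1
    dS <- spatialClusterDecoder(posSame, nShuffles = 2, seed = 1)
    expect_equal(dS@accuracy, max(table(posSame$dim_label)) / nrow(posSame))
})

test_that("the motion GLM recovers planted lagged filters", {
    fr <- 10
    T <- 1200
    mf <- generateMotionFeatures(T, nDims = 4, seed = 5)
    lagF <- 20                       # 2 s of history
    X <- lineattractor:::.laggedDesign(mf, lagF)
    set.seed(6)
    beta <- rnorm(ncol(X), 0, 0.5)
    yEx <- as.numeric(X %*% beta)
    y <- c(rep(0, lagF), yEx)
    gEx <- motionGLM(y, mf, lagS = 2, folds = 5, frameRate = fr, seed = 1)
    expect_gt(gEx@cvR2[1], 95)

    set.seed(7)
    gInd <- motionGLM(rnorm(T), mf, lagS = 2, folds = 5, frameRate = fr,
                      seed = 1)
    expect_lt(gInd@cvR2[1], 10)

    yNoisy <- y + rnorm(T, 0, 0.3 * sd(y))
    gN <- motionGLM(yNoisy, mf, lagS = 2, folds = 5, frameRate = fr,
                    seed = 1)
    expect_lt(gN@cvR2[1], gEx@cvR2[1])   # noise can only hurt
    bhat <- gN@beta[-1, 1]
    expect_gt(cor(bhat, beta), 0.9)
})
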