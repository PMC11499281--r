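#' @include rslds-sample.R
NULL

# Default intruder-presence schedule: three presence epochs separated by
# removal periods, mirroring repeated introduction of an intruder within a
# session.
.defaultInputSchedule <- function(nFrames) {
    s <- numeric(nFrames)
    on <- rbind(c(0.10, 0.25), c(0.40, 0.55), c(0.70, 0.85))
    for (i in seq_len(nrow(on))) {
        a <- max(1L, ceiling(on[i, 1] * nFrames))
        b <- floor(on[i, 2] * nFrames)
        s[a:b] <- 1
    }
    s
}

# Ground-truth parameter set with a planted line attractor: a diagonal
# dynamics matrix with one slow (integration) and one fast eigenvalue
# lambda = exp(-1 / (tau * frameRate)), an input matrix driving chiefly the
# slow dimension, and an emission matrix with disjoint dominant-weight
# neuron groups for the two dimensions.
.lineAttractorParams <- function(nNeurons, frameRate, slowTauS, fastTauS,
                                 seed) {
    lamS <- exp(-1 / (slowTauS * frameRate))
    lamF <- exp(-1 / (fastTauS * frameRate))
    A <- diag(c(lamS, lamF))
    # stationary latent SD of 1 per dimension
    Q <- diag(c(1 - lamS^2, 1 - lamF^2))
    # intruder input drives the slow latent toward ~3 stationary SDs, with a
    # small transient contribution to the fast dimension
    B <- matrix(c(3 * (1 - lamS), 0.3 * (1 - lamF)), 2, 1)
    # discrete state 2 (attractor-engaged) becomes likely once the slow
    # latent exceeds ~1 SD
    Rw <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE)
    rv <- c(0, -4)
    set.seed(.substream(seed, "emission-weights"))
    n1 <- floor(nNeurons / 2)
    C <- matrix(0, nNeurons, 2)
    C[seq_len(n1), 1] <- runif(n1, 0.8, 1.2)
    C[(n1 + 1):nNeurons, 2] <- runif(nNeurons - n1, 0.8, 1.2)
    RSLDSParams(A = list(A, A), C = C,
                Q = list(Q, Q),
                Rw = list(Rw, Rw), rv = list(rv, rv),
                B = B, K = 2,
                S = rep(0, nNeurons))
}

# Bout annotations derived from the input schedule (bout = contiguous
# input-on period, labelled "attack"), plus distractor bouts in the off
# periods labelled "other".
.boutsFromSchedule <- function(schedule, frameRate, seed) {
    r <- rle(schedule > 0)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    on <- which(r$values)
    bouts <- data.frame(start_s = (starts[on] - 1) / frameRate,
                        stop_s = ends[on] / frameRate,
                        label = rep("attack", length(on)),
                        stringsAsFactors = FALSE)
    set.seed(.substream(seed, "distractor-bouts"))
    off <- which(!r$values)
    extra <- list()
    for (i in off) {
        lenS <- (ends[i] - starts[i] + 1) / frameRate
        if (lenS < 25) next
        dur <- runif(1, 8, 15)
        a <- (starts[i] - 1) / frameRate + runif(1, 3, lenS - dur - 3)
        extra[[length(extra) + 1L]] <-
            data.frame(start_s = a, stop_s = a + dur, label = "other",
                       stringsAsFactors = FALSE)
    }
    out <- rbind(bouts, do.call(rbind, extra))
    out[order(out$start_s), , drop = FALSE]
}

#' Generate a synthetic session with planted line-attractor structure
#'
#' Samples a full recording session from a ground-truth recurrent switching
#' LDS whose dynamics matrix has one slow (integration) and one fast
#' eigenvalue, `lambda = exp(-1 / (tau * frameRate))` per frame.  A binary
#' intruder-presence input drives the slow dimension; behaviour bouts are
#' derived from the input schedule; cell positions are drawn over a
#' rectangular field of view; emission noise is additive Gaussian with SD
#' equal to `emissionNoiseFrac` times each neuron's signal SD.
#'
#' All randomness flows from `seed`, split into named substreams (latents,
#' emission noise, positions, bouts), so identical arguments give identical
#' sessions.
#'
#' @param nNeurons number of neurons (>= 2).
#' @param nFrames number of frames.
#' @param frameRate acquisition rate, Hz (default 10).
#' @param slowTauS time constant of the integration dimension, seconds.
#' @param fastTauS time constant of the fast dimension, seconds
#'   (`slowTauS > fastTauS > 0`).
#' @param emissionNoiseFrac emission noise SD as a fraction of each neuron's
#'   signal SD (>= 0).
#' @param inputSchedule optional binary intruder-presence series (length
#'   `nFrames`); a default three-epoch schedule is used when `NULL`.
#' @param clusteredPositions if TRUE, x1 and x2 cells are drawn from two
#'   separated spatial clusters; by default positions are uniform (no
#'   spatial clustering, as observed).
#' @param seed integer session seed.
#' @return A [SyntheticSession-class].
#' @examples
#' ses <- generateLineAttractorSession(nNeurons = 20, nFrames = 400, seed = 1)
#' ses
#' @export
generateLineAttractorSession <- function(nNeurons = 100, nFrames = 3000,
                                         frameRate = 10, slowTauS = 100,
                                         fastTauS = 1,
                                         emissionNoiseFrac = 0.2,
                                         inputSchedule = NULL,
                                         clusteredPositions = FALSE,
                                         seed = 0) {
    stopifnot(nNeurons >= 2, nFrames >= 10)
    if (!all(is.finite(c(nNeurons, nFrames, frameRate, slowTauS, fastTauS,
                         emissionNoiseFrac))))
        stop("configuration values must be finite")
    if (!(slowTauS > fastTauS && fastTauS > 0))
        stop("slowTauS > fastTauS > 0 is required")
    if (emissionNoiseFrac < 0) stop("emissionNoiseFrac must be >= 0")
    if (frameRate <= 0) stop("frameRate must be > 0")
    if (is.null(inputSchedule)) inputSchedule <- .defaultInputSchedule(nFrames)
    stopifnot(length(inputSchedule) == nFrames)

    truth <- .lineAttractorParams(nNeurons, frameRate, slowTauS, fastTauS,
                                  seed)
    draw <- sampleRSLDS(truth, T = nFrames, inputs = inputSchedule,
                        seed = seed, frameRate = frameRate)
    x <- draw$latents@x
    signal <- truth@C %*% x
    sdSig <- pmax(apply(signal, 1, sd), 1e-8)
    S <- (emissionNoiseFrac * sdSig)^2
    truth@S <- as.numeric(S)

    set.seed(.substream(seed, "emission"))
    noise <- matrix(rnorm(nNeurons * nFrames), nNeurons, nFrames) * sqrt(S)
    Y <- signal + truth@d + noise

    n1 <- floor(nNeurons / 2)
    labels <- c(rep("x1", n1), rep("x2", nNeurons - n1))
    positions <- generateCellPositions(nNeurons, clustered = clusteredPositions,
                                       labels = labels,
                                       seed = .substream(seed, "positions"))
    bouts <- .boutsFromSchedule(inputSchedule, frameRate, seed)

    activity <- CalciumActivity(Y, frameRate = frameRate,
                                positions = positions[, c("x_um", "y_um",
                                                          "dim_label")])
    new("SyntheticSession", activity = activity, truth = truth,
        latents = draw$latents, bouts = bouts, positions = positions,
        inputSchedule = as.numeric(inputSchedule), seed = as.integer(seed))
}

#' Generate a pulse-train stimulation protocol
#'
#' Pulse onsets are spaced `pulseDurS + isiS` apart starting at `startS`;
#' each interstimulus interval (ISI) runs from a pulse's offset to the next
#' onset (the final ISI has the same length).
#'
#' @param nPulses number of pulses (>= 1).
#' @param isiS interstimulus interval, seconds (must exceed `pulseDurS`...
#'   strictly positive and non-overlapping).
#' @param pulseDurS pulse duration, seconds (default 2).
#' @param pulseRateHz within-pulse stimulation rate, Hz (default 20).
#' @param targets indices of targeted cells.
#' @param gain laser-power proxy: latent drive per frame (default 0.05).
#' @param startS onset of the first pulse, seconds (default 0).
#' @param exclusionRadius,offTargetRadius follower/off-target radii, um.
#' @return A [StimProtocol-class].
#' @examples
#' generateStimProtocol(4, 20, 2, 20, targets = 1:5)  # onsets 0, 22, 44, 66
#' @export
generateStimProtocol <- function(nPulses, isiS, pulseDurS = 2,
                                 pulseRateHz = 20, targets = integer(0),
                                 gain = 0.05, startS = 0,
                                 exclusionRadius = 50, offTargetRadius = 15) {
    stopifnot(nPulses >= 1, pulseDurS >= 0)
    if (isiS <= 0) stop("isiS must be > 0")
    if (isiS <= pulseDurS)
        warning("ISI shorter than the pulse duration")
    onsets <- startS + (seq_len(nPulses) - 1) * (pulseDurS + isiS)
    offsets <- onsets + pulseDurS
    new("StimProtocol", onsets = onsets, offsets = offsets,
        pulseRate = pulseRateHz, targets = as.integer(targets),
        gain = gain, isi = isiS, exclusionRadius = exclusionRadius,
        offTargetRadius = offTargetRadius)
}

#' Generate cell positions over a rectangular field of view
#'
#' @param n number of cells (>= 1).
#' @param fovUm field-of-view size `c(width, height)` in um.
#' @param clustered if TRUE, x1 and x2 cells are drawn from two Gaussian
#'   clusters separated by `clusterSepUm`; otherwise positions are uniform
#'   (independent of label).
#' @param labels per-cell dimension label ("x1", "x2" or "neither"); defaults
#'   to an even x1/x2 split.
#' @param clusterSepUm,clusterSdUm separation and SD of the two clusters.
#' @param seed RNG seed.
#' @return A data frame with `cell_id`, `x_um`, `y_um`, `dim_label`.
#' @export
generateCellPositions <- function(n, fovUm = c(500, 500), clustered = FALSE,
                                  labels = NULL, clusterSepUm = 250,
                                  clusterSdUm = 30, seed = 0) {
    stopifnot(n >= 1)
    if (is.null(labels)) {
        n1 <- floor(n / 2)
        labels <- c(rep("x1", n1), rep("x2", n - n1))
    }
    stopifnot(length(labels) == n,
              all(labels %in% c("x1", "x2", "neither")))
    set.seed(seed)
    if (!clustered) {
        x <- runif(n, 0, fovUm[1])
        y <- runif(n, 0, fovUm[2])
    } else {
        cx <- fovUm[1] / 2 + ifelse(labels == "x1", -clusterSepUm / 2,
                                    clusterSepUm / 2)
        cy <- rep(fovUm[2] / 2, n)
        x <- pmin(pmax(rnorm(n, cx, clusterSdUm), 0), fovUm[1])
        y <- pmin(pmax(rnorm(n, cy, clusterSdUm), 0), fovUm[2])
    }
    data.frame(cell_id = seq_len(n), x_um = x, y_um = y, dim_label = labels,
               stringsAsFactors = FALSE)
}

#' Generate smooth synthetic motion features
#'
#' Low-pass-filtered Gaussian noise, one unit-variance series per feature
#' dimension -- a stand-in for the leading principal components of video
#' motion energy.
#'
#' @param nFrames series length.
#' @param nDims number of feature dimensions (>= 1).
#' @param smoothTauFrames exponential smoothing time constant, frames.
#' @param seed RNG seed.
#' @return An `nDims x nFrames` matrix, unit variance per row.
#' @export
generateMotionFeatures <- function(nFrames, nDims = 10, smoothTauFrames = 10,
                                   seed = 0) {
    stopifnot(nDims >= 1, nFrames >= 2)
    set.seed(seed)
    a <- exp(-1 / smoothTauFrames)
    out <- matrix(0, nDims, nFrames)
    for (i in seq_len(nDims)) {
        e <- rnorm(nFrames)
        x <- as.numeric(stats::filter(e, a, method = "recursive"))
        out[i, ] <- (x - mean(x)) / sd(x)
    }
    out
}

#' Generate a unitary-stimulation cohort with planted coupling density
#'
#' Builds a set of single-target stimulation runs over an ensemble of x1 and
#' x2 cells in which each ordered x1 -> x1 pair is functionally coupled with
#' probability `couplingDensity`.  Coupled followers respond in the
#' post-pulse ISI windows with evoked amplitude `couplingZ` (in baseline-SD
#' units); x1 -> x2 "cross" responses are drawn below `crossMaxZ`, setting
#' the connectivity-fraction threshold.  Feeding the runs through
#' [influenceScores()] and [connectivityFraction()] recovers the planted
#' density.
#'
#' @param nX1,nX2 ensemble sizes.
#' @param couplingDensity probability that an ordered x1 -> x1 pair is
#'   coupled (default 0.36).
#' @param couplingZ evoked response of coupled followers, baseline-SD units.
#' @param crossMaxZ upper bound of the x1 -> x2 evoked response (default
#'   0.6).
#' @param nPulses,isiS,pulseDurS protocol shape per run.
#' @param baselineS baseline period before the first pulse, seconds.
#' @param frameRate Hz.
#' @param seed RNG seed.
#' @return A list with `activities` (one matrix per targeted x1 cell),
#'   `protocols` (matching [StimProtocol-class] list), `positions`,
#'   `labels`, `baselineWindow` (frames) and `couplingMask` (the planted
#'   x1 x x1 coupling indicator).
#' @export
generateUnitaryStimCohort <- function(nX1 = 12, nX2 = 12,
                                      couplingDensity = 0.36,
                                      couplingZ = 3, crossMaxZ = 0.6,
                                      nPulses = 5, isiS = 10, pulseDurS = 2,
                                      baselineS = 30, frameRate = 10,
                                      seed = 0) {
    n <- nX1 + nX2
    labels <- c(rep("x1", nX1), rep("x2", nX2))
    # grid positions spaced beyond the exclusion radius
    spacing <- 120
    gx <- ((seq_len(n) - 1) %% 8) * spacing
    gy <- ((seq_len(n) - 1) %/% 8) * spacing
    positions <- data.frame(cell_id = seq_len(n), x_um = gx, y_um = gy,
                            dim_label = labels, stringsAsFactors = FALSE)

    set.seed(.substream(seed, "coupling"))
    couplingMask <- matrix(rbinom(nX1 * nX1, 1, couplingDensity) == 1,
                           nX1, nX1)
    diag(couplingMask) <- FALSE
    crossAmp <- matrix(runif(nX1 * nX2, 0.2 * crossMaxZ, crossMaxZ),
                       nX1, nX2)

    durS <- baselineS + nPulses * (pulseDurS + isiS)
    T <- round(durS * frameRate)
    baselineWindow <- c(1L, as.integer(baselineS * frameRate))

    activities <- vector("list", nX1)
    protocols <- vector("list", nX1)
    for (i in seq_len(nX1)) {
        prot <- generateStimProtocol(nPulses, isiS, pulseDurS,
                                     targets = i, startS = baselineS)
        set.seed(.substream(seed, paste0("run", i)))
        Y <- matrix(rnorm(n * T), n, T)
        isiW <- .isiWindows(prot, frameRate, T, skipS = 1)
        for (wrow in seq_len(nrow(isiW))) {
            idx <- isiW[wrow, 1]:isiW[wrow, 2]
            Y[i, idx] <- Y[i, idx] + couplingZ * 1.5   # targeted cell itself
            resp1 <- which(couplingMask[i, ])
            for (j in resp1) Y[j, idx] <- Y[j, idx] + couplingZ
            for (j in seq_len(nX2))
                Y[nX1 + j, idx] <- Y[nX1 + j, idx] + crossAmp[i, j]
        }
        activities[[i]] <- Y
        protocols[[i]] <- prot
    }
    list(activities = activities, protocols = protocols,
         positions = positions, labels = labels,
         baselineWindow = baselineWindow, couplingMask = couplingMask)
}
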