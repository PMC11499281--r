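#' @include synthetic.R
NULL

# Frame-index ISI windows (offset + skip -> next onset) for a protocol; the
# final ISI uses the protocol's stored interval.  Rows: (first, last) frame.
.isiWindows <- function(protocol, frameRate, T, skipS = 1) {
    n <- length(protocol@onsets)
    out <- matrix(0L, n, 2)
    for (p in seq_len(n)) {
        a <- .seconds2frames(protocol@offsets[p] + skipS, frameRate)
        bS <- if (p < n) protocol@onsets[p + 1] else
            protocol@offsets[p] + protocol@isi
        b <- min(.seconds2frames(bS, frameRate) - 1L, T)
        out[p, ] <- c(min(a, T), max(min(b, T), min(a, T)))
    }
    out
}

.pulseEnvelope <- function(protocol, frameRate, T) {
    env <- numeric(T)
    for (p in seq_along(protocol@onsets)) {
        a <- .seconds2frames(protocol@onsets[p], frameRate)
        b <- min(.seconds2frames(protocol@offsets[p], frameRate) - 1L, T)
        if (a <= T && b >= a) env[a:b] <- 1
    }
    env
}

#' Simulate targeted photostimulation of a synthetic session
#'
#' Re-runs the session's generative model with an added latent drive during
#' stimulation pulses: the drive direction is the (normalized) sum of the
#' targeted neurons' emission rows, i.e. stimulation enters the latent
#' update through `C^T` weighting.  With `gain = 0` the output is identical
#' to the unperturbed session (all randomness is replayed from the session
#' seed).
#'
#' @param session a [SyntheticSession-class].
#' @param protocol a [StimProtocol-class] whose `targets` index neurons of
#'   the session.
#' @return A list with `activity` ([CalciumActivity-class], perturbed) and
#'   `latents` ([LatentTrajectory-class], perturbed).
#' @export
simulateTargetedStim <- function(session, protocol) {
    stopifnot(is(session, "SyntheticSession"), is(protocol, "StimProtocol"))
    N <- nNeurons(session); T <- nFrames(session)
    rate <- frameRate(session)
    if (length(protocol@targets) &&
        (min(protocol@targets) < 1L || max(protocol@targets) > N))
        stop("protocol targets outside the session")
    if (max(protocol@offsets) > T / rate)
        stop("protocol extends beyond the session duration")
    truth <- session@truth
    v <- colSums(truth@C[protocol@targets, , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    env <- .pulseEnvelope(protocol, rate, T)
    drive <- outer(v, env) * protocol@gain
    draw <- sampleRSLDS(truth, T = T, inputs = session@inputSchedule,
                        seed = session@seed, frameRate = rate, drive = drive)
    draw
}

#' Project activity onto a latent dimension
#'
#' Returns a scalar series for the requested latent dimension.  The default
#' `"posterior"` mode uses smoothed latents inferred under the model; the
#' `"pinv"` mode applies the Moore-Penrose pseudo-inverse of the emission
#' matrix to `y - d` (fast linear readout).
#'
#' @param y activity (matrix, [CalciumActivity-class] or the list returned
#'   by [simulateTargetedStim()]).
#' @param params an [RSLDSParams-class] or [RSLDSFit-class].
#' @param dim latent dimension id (integer or "x1"/"x2").
#' @param method "posterior" or "pinv".
#' @param inputs optional input series for posterior inference.
#' @return A numeric series of length T.
#' @export
projectOntoDimension <- function(y, params, dim = 1,
                                 method = c("posterior", "pinv"),
                                 inputs = NULL) {
    method <- match.arg(method)
    if (is(params, "RSLDSFit")) params <- params@params
    if (is.list(y) && !is.null(y$activity)) y <- y$activity
    Y <- .asActivityMatrix(y)
    if (is.character(dim)) dim <- as.integer(sub("^x", "", dim))
    if (dim < 1 || dim > params@D) stop("invalid latent dimension")
    if (method == "pinv") {
        x <- .pinv(params@C) %*% (Y - params@d)
    } else {
        x <- inferLatents(params, Y, inputs = inputs)@x
    }
    as.numeric(x[dim, ])
}

#' Baseline and per-ISI summary of a projected series
#'
#' Computes the baseline mean of the series plus the mean and peak in each
#' interstimulus window (skipping the first second after pulse offset).
#' The integration flag is TRUE when the ISI means rise across the first
#' three pulses by more than `relTol` of the first baseline-referenced
#' level (guards against flat series flagged by numerical jitter); the
#' saturation pulse is the first pulse whose baseline-referenced increment
#' falls below 10% of the previous level.
#'
#' @param proj scalar series (e.g. from [projectOntoDimension()]).
#' @param protocol a [StimProtocol-class].
#' @param frameRate Hz.
#' @param skipS seconds skipped after each pulse offset (default 1).
#' @param baselineWindow optional frame interval; defaults to all frames
#'   before the first pulse.
#' @param relTol relative increment required to call integration (default
#'   0.05).
#' @return A list: `table` (per-pulse data frame with `isiMean`, `isiPeak`),
#'   `baseline`, `integration` (flag), `saturationPulse` (index or NA).
#' @export
isiPeakTable <- function(proj, protocol, frameRate = 10, skipS = 1,
                         baselineWindow = NULL, relTol = 0.05) {
    proj <- as.numeric(proj)
    T <- length(proj)
    if (is.null(baselineWindow)) {
        b <- .seconds2frames(protocol@onsets[1], frameRate) - 1L
        baselineWindow <- c(1L, max(b, 1L))
    }
    baseline <- mean(proj[baselineWindow[1]:baselineWindow[2]])
    W <- .isiWindows(protocol, frameRate, T, skipS = skipS)
    tab <- data.frame(pulse = seq_len(nrow(W)),
                      isiMean = NA_real_, isiPeak = NA_real_)
    for (p in seq_len(nrow(W))) {
        seg <- proj[W[p, 1]:W[p, 2]]
        tab$isiMean[p] <- mean(seg)
        tab$isiPeak[p] <- max(seg)
    }
    nInt <- min(3L, nrow(tab))
    lev1 <- tab$isiMean[1] - baseline
    integration <- nInt >= 2L && lev1 > 0 &&
        all(diff(tab$isiMean[seq_len(nInt)]) > relTol * lev1)
    saturation <- NA_integer_
    if (nrow(tab) >= 2L) {
        lev <- tab$isiMean - baseline
        for (p in 2:nrow(tab)) {
            if (lev[p - 1] > 0 && (lev[p] - lev[p - 1]) < 0.1 * lev[p - 1]) {
                saturation <- p
                break
            }
        }
    }
    list(table = tab, baseline = baseline, integration = integration,
         saturationPulse = saturation)
}

#' State-space displacement across stimulation pulses
#'
#' Euclidean distance in latent space between the baseline point
#' (`t_initial`, the last frame before the first pulse) and, for each
#' pulse, the end-of-stimulation point (`t_stim-end`) and the end of the
#' following interstimulus interval (`t_post-stim`).  Translation of all
#' latents leaves the metrics unchanged.
#'
#' @param latents a [LatentTrajectory-class] (or D x T matrix).
#' @param protocol a [StimProtocol-class].
#' @param frameRate Hz.
#' @return A data frame with one row per pulse: `dStimEnd`, `dPostStim`.
#' @export
stateSpaceDisplacement <- function(latents, protocol, frameRate = 10) {
    x <- if (is(latents, "LatentTrajectory")) latents@x else as.matrix(latents)
    T <- ncol(x)
    t0 <- max(.seconds2frames(protocol@onsets[1], frameRate) - 1L, 1L)
    x0 <- x[, t0]
    n <- length(protocol@onsets)
    out <- data.frame(pulse = seq_len(n), dStimEnd = NA_real_,
                      dPostStim = NA_real_)
    for (p in seq_len(n)) {
        tse <- min(.seconds2frames(protocol@offsets[p], frameRate), T)
        tpsS <- if (p < n) protocol@onsets[p + 1] else
            protocol@offsets[p] + protocol@isi
        tps <- min(.seconds2frames(tpsS, frameRate) - 1L, T)
        out$dStimEnd[p] <- sqrt(sum((x[, tse] - x0)^2))
        out$dPostStim[p] <- sqrt(sum((x[, tps] - x0)^2))
    }
    out
}

#' Pairwise influence scores from unitary stimulation runs
#'
#' For each single-target run, every neuron's activity is z-scored against
#' the baseline window and the influence score of a (target, follower) pair
#' is the follower's mean z-scored activity over the post-pulse ISI windows.
#' Self pairs and pairs within the exclusion radius of the target are
#' masked; targeted cells are excluded as followers of other runs only by
#' the radius rule.
#'
#' @param activities a single activity (matrix/[CalciumActivity-class]) or
#'   a list of them, one per unitary run.
#' @param protocols a [StimProtocol-class] or list matching `activities`;
#'   each must carry exactly one target.
#' @param positions cell position table with `x_um`, `y_um` (required for
#'   the exclusion mask).
#' @param labels per-cell group labels ("x1"/"x2"/"neither"); defaults to
#'   the `dim_label` column of `positions`.
#' @param baselineWindow frame interval used for z-scoring.
#' @param frameRate Hz.
#' @param skipS seconds skipped after pulse offsets (default 1).
#' @return An [InfluenceMatrix-class].
#' @export
influenceScores <- function(activities, protocols, positions, labels = NULL,
                            baselineWindow, frameRate = 10, skipS = 1) {
    if (!is.list(activities) || is(activities, "CalciumActivity"))
        activities <- list(activities)
    if (is(protocols, "StimProtocol")) protocols <- list(protocols)
    stopifnot(length(activities) == length(protocols))
    if (is.null(positions) || !all(c("x_um", "y_um") %in% names(positions)))
        stop("cell positions with x_um/y_um are required")
    if (is.null(labels)) labels <- positions$dim_label
    nRun <- length(activities)
    N <- nrow(.asActivityMatrix(activities[[1]]))
    scores <- matrix(NA_real_, nRun, N)
    mask <- matrix(FALSE, nRun, N)
    targets <- integer(nRun)
    for (i in seq_len(nRun)) {
        prot <- protocols[[i]]
        if (length(prot@targets) != 1L)
            stop("influence scores require unitary (single-target) protocols")
        tgt <- prot@targets
        targets[i] <- tgt
        Y <- .asActivityMatrix(activities[[i]])
        T <- ncol(Y)
        base <- Y[, baselineWindow[1]:baselineWindow[2], drop = FALSE]
        mu <- rowMeans(base)
        sdv <- pmax(apply(base, 1, sd), 1e-8)
        Z <- (Y - mu) / sdv
        W <- .isiWindows(prot, frameRate, T, skipS = skipS)
        idx <- unlist(lapply(seq_len(nrow(W)), function(p) W[p, 1]:W[p, 2]))
        sc <- rowMeans(Z[, idx, drop = FALSE])
        dist <- sqrt((positions$x_um - positions$x_um[tgt])^2 +
                     (positions$y_um - positions$y_um[tgt])^2)
        excl <- dist < prot@exclusionRadius
        excl[tgt] <- TRUE
        sc[excl] <- NA_real_
        scores[i, ] <- sc
        mask[i, ] <- excl
    }
    new("InfluenceMatrix", scores = scores, mask = mask,
        targets = targets, groups = as.character(labels))
}

#' Fraction of within-ensemble pairs above the cross-ensemble maximum
#'
#' The functional-coupling estimate: the threshold is the highest
#' x1 -> x2 influence score, and the connectivity fraction is the
#' proportion of x1 -> x1 scores strictly above it.
#'
#' @param scores an [InfluenceMatrix-class] with both pair classes present.
#' @return The fraction in `[0, 1]`.
#' @export
connectivityFraction <- function(scores) {
    stopifnot(is(scores, "InfluenceMatrix"))
    g <- scores@groups
    tgtGroups <- g[scores@targets]
    s11 <- as.numeric(scores@scores[tgtGroups == "x1", g == "x1",
                                    drop = FALSE])
    s12 <- as.numeric(scores@scores[tgtGroups == "x1", g == "x2",
                                    drop = FALSE])
    s11 <- s11[!is.na(s11)]
    s12 <- s12[!is.na(s12)]
    if (!length(s11) || !length(s12))
        stop("both x1->x1 and x1->x2 pair classes must be present")
    mean(s11 > max(s12))
}

#' Correlation between attractor stability and functional connectivity
#'
#' Ordinary least-squares regression of a per-session connectivity metric
#' (mean evoked z or area under the curve) on the per-session integration
#' time constant; returns the r-squared, slope and two-sided p-value.
#'
#' @param perSessionTau per-session integration-dimension time constants,
#'   seconds.
#' @param perSessionConnectivity matching connectivity metric values.
#' @return A list with `r2`, `slope`, `p`.
#' @export
stabilityConnectivityCorrelation <- function(perSessionTau,
                                             perSessionConnectivity) {
    x <- as.numeric(perSessionTau)
    y <- as.numeric(perSessionConnectivity)
    stopifnot(length(x) == length(y))
    if (length(x) < 3) stop("at least three sessions required")
    if (sd(x) < 1e-12 || sd(y) < 1e-12)
        stop("degenerate variance in one of the variables")
    fit <- lm(y ~ x)
    sm <- suppressWarnings(summary(fit))   # exact collinearity is legitimate
    list(r2 = sm$r.squared, slope = unname(coef(fit)[2]),
         p = sm$coefficients[2, 4])
}

#' Area under the z-scored response curve in ISI windows
#'
#' Trapezoidal AUC of a z-scored series over the interstimulus windows of a
#' protocol; a per-session connectivity metric alternative to the mean.
#'
#' @param z z-scored scalar series.
#' @param protocol a [StimProtocol-class].
#' @param frameRate Hz.
#' @param skipS seconds skipped after pulse offsets.
#' @return Total AUC (z x seconds).
#' @export
isiAUC <- function(z, protocol, frameRate = 10, skipS = 1) {
    z <- as.numeric(z)
    W <- .isiWindows(protocol, frameRate, length(z), skipS = skipS)
    total <- 0
    for (p in seq_len(nrow(W))) {
        seg <- z[W[p, 1]:W[p, 2]]
        if (length(seg) > 1)
            total <- total + sum((seg[-1] + seg[-length(seg)]) / 2) / frameRate
    }
    total
}
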