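#' @include AllClasses.R
NULL

# Largest-modulus eigenvalue of a nonnegative sparse matrix by power
# iteration (Perron root), with a dense eigensolver fallback when the
# iteration stalls.
.spectralRadius <- function(W, tol = 1e-8, maxIter = 2000) {
    n <- ncol(W)
    if (n == 0L || length(W@x) == 0L) return(0)
    v <- rep(1 / sqrt(n), n)
    lam <- 0
    for (i in seq_len(maxIter)) {
        v2 <- as.numeric(W %*% v)
        nrm <- sqrt(sum(v2^2))
        if (nrm == 0) return(0)
        v2 <- v2 / nrm
        if (abs(nrm - lam) < tol * max(nrm, 1e-12)) return(nrm)
        lam <- nrm
        v <- v2
    }
    max(Mod(eigen(as.matrix(W), only.values = TRUE)$values))
}

#' Build the synaptic weight matrix of the LIF network
#'
#' The integration-subnetwork block (first `Np` neurons) has entries nonzero
#' with probability `sigma`, sampled `U(0, 1/sqrt(Np))`; all remaining
#' entries are nonzero with probability `backgroundDensity`, sampled
#' `U(0, 1/sqrt(N))`.  The diagonal is zero.  The spectral radius
#' `lambda_max` is computed by power iteration (the matrix is nonnegative,
#' so the dominant eigenvalue is the real Perron root).
#'
#' @param cfg an [LIFNetworkConfig-class].
#' @param seed RNG seed.
#' @param lambdaMode "full" computes `lambda_max` on the whole matrix
#'   (default); "subnetwork" on the subnetwork block only.
#' @return A [WeightMatrix-class].
#' @examples
#' W <- buildWeightMatrix(lifConfig(sigma = 0.1), seed = 1)
#' spectralRadius(W)
#' @export
buildWeightMatrix <- function(cfg, seed = 0,
                              lambdaMode = c("full", "subnetwork")) {
    stopifnot(is(cfg, "LIFNetworkConfig"))
    validObject(cfg)
    lambdaMode <- match.arg(lambdaMode)
    N <- cfg@N; Np <- cfg@Np
    set.seed(seed)
    # subnetwork block
    maskP <- which(runif(Np * Np) < cfg@sigma)
    iP <- ((maskP - 1) %% Np) + 1
    jP <- ((maskP - 1) %/% Np) + 1
    wP <- runif(length(maskP), 0, 1 / sqrt(Np))
    # background: everything outside the Np x Np block
    nBg <- N * N - Np * Np
    maskB <- which(runif(nBg) < cfg@backgroundDensity)
    # map linear index over the complement of the block to (i, j)
    colsTall <- N - Np            # rows Np+1..N of the first Np columns
    nTall <- colsTall * Np
    iB <- integer(length(maskB)); jB <- integer(length(maskB))
    inTall <- maskB <= nTall
    iB[inTall] <- Np + ((maskB[inTall] - 1) %% colsTall) + 1
    jB[inTall] <- ((maskB[inTall] - 1) %/% colsTall) + 1
    rest <- maskB[!inTall] - nTall
    iB[!inTall] <- ((rest - 1) %% N) + 1
    jB[!inTall] <- Np + ((rest - 1) %/% N) + 1
    wB <- runif(length(maskB), 0, 1 / sqrt(N))
    ii <- c(iP, iB); jj <- c(jP, jB); ww <- c(wP, wB)
    keep <- ii != jj
    W <- sparseMatrix(i = ii[keep], j = jj[keep], x = ww[keep],
                      dims = c(N, N))
    lam <- if (lambdaMode == "full") .spectralRadius(W)
           else .spectralRadius(W[seq_len(Np), seq_len(Np)])
    new("WeightMatrix", W = W, subnet = seq_len(Np), lambdaMax = lam)
}

#' Analytic network time constant
#'
#' `tau_n = tau_s / |1 - lambda_max|`: the decay timescale of the slowest
#' mode of the linearized recurrent excitatory network.  Spectral radii at
#' or above 1 indicate runaway excitation; the result is then `NA` with
#' attribute `unstable = TRUE`.
#'
#' @param W a [WeightMatrix-class] or a numeric `lambda_max`.
#' @param tauS synaptic conductance time constant, seconds.
#' @return Network time constant in seconds (attribute `unstable`).
#' @examples
#' analyticNetworkTau(0.9, tauS = 20)  # 200
#' @export
analyticNetworkTau <- function(W, tauS) {
    lam <- if (is(W, "WeightMatrix")) W@lambdaMax else as.numeric(W)
    stopifnot(tauS > 0)
    if (lam >= 1) {
        out <- NA_real_
        attr(out, "unstable") <- TRUE
        return(out)
    }
    out <- tauS / abs(1 - lam)
    attr(out, "unstable") <- FALSE
    out
}

#' Pulse-train external input for the LIF network
#'
#' A smoothened step function (Gaussian-smoothed square pulses, 100 ms SD)
#' of `nPulses` pulses separated by `isiS`, driving a random `fracDriven`
#' subset of neurons with weight `amplitude`.
#'
#' @param cfg an [LIFNetworkConfig-class] (provides N and dt).
#' @param duration total input duration, seconds.
#' @param nPulses number of pulses (default 4).
#' @param isiS interstimulus interval, seconds (default 20).
#' @param pulseDurS pulse duration, seconds (default 2).
#' @param fracDriven fraction of neurons receiving the input (default
#'   0.25).
#' @param amplitude input weight of driven neurons; the default 2 drives
#'   them to near-saturation spiking during pulses, which the slow synaptic
#'   filter needs in order to accumulate drive across pulses.
#' @param startS onset of the first pulse (default 10 s).
#' @param smoothSdS Gaussian smoothing SD, seconds (default 0.1).
#' @param seed RNG seed for the driven subset.
#' @return A list: `s` (per-timestep input), `w` (per-neuron weights),
#'   `onsets` (pulse onset times, s), `driven` (driven indices).
#' @export
makePulseInput <- function(cfg, duration, nPulses = 4, isiS = 20,
                           pulseDurS = 2, fracDriven = 0.25,
                           amplitude = 2, startS = 10, smoothSdS = 0.1,
                           seed = 0) {
    stopifnot(fracDriven > 0, fracDriven <= 1)
    dt <- cfg@dt
    steps <- round(duration / dt)
    s <- numeric(steps)
    onsets <- startS + (seq_len(nPulses) - 1) * (pulseDurS + isiS)
    for (o in onsets) {
        a <- max(1L, round(o / dt)); b <- min(steps, round((o + pulseDurS) / dt))
        if (a <= steps && b >= a) s[a:b] <- 1
    }
    # Gaussian smoothing of the step edges
    ksd <- max(1L, round(smoothSdS / dt))
    kx <- seq(-3 * ksd, 3 * ksd)
    kern <- exp(-0.5 * (kx / ksd)^2)
    kern <- kern / sum(kern)
    s <- as.numeric(stats::filter(c(rep(0, 3 * ksd), s, rep(0, 3 * ksd)),
                                  kern, sides = 2))[3 * ksd + seq_len(steps)]
    s[is.na(s)] <- 0
    set.seed(seed)
    driven <- sort(sample.int(cfg@N, max(1L, round(fracDriven * cfg@N))))
    w <- numeric(cfg@N)
    w[driven] <- amplitude
    list(s = s, w = w, onsets = onsets, driven = driven)
}

#' Simulate the excitatory LIF network
#'
#' Euler integration (step `cfg@dt`) of the membrane and synaptic-current
#' dynamics with per-step additive Gaussian membrane noise.  When the
#' membrane crosses the threshold it is reset to zero and the instantaneous
#' rate is a one-timestep unit impulse feeding the synaptic filter.
#' `simulateLIF` forces the inhibitory gain to zero; use
#' [simulateLIFInhibition()] for the variant with a single graded
#' feedback-inhibition unit driven by the population-mean rate.
#'
#' @param cfg an [LIFNetworkConfig-class].
#' @param W a [WeightMatrix-class] from [buildWeightMatrix()].
#' @param duration simulated time, seconds.
#' @param seed RNG seed (same seed, same raster).
#' @param input optional list from [makePulseInput()]; zero input when
#'   `NULL`.
#' @param binRate binning rate for per-neuron spike counts, Hz (default 10).
#' @return A [NetworkSimResult-class].
#' @export
simulateLIF <- function(cfg, W, duration, seed = 0, input = NULL,
                        binRate = 10) {
    cfg@gInh <- 0
    simulateLIFInhibition(cfg, W, duration, seed = seed, input = input,
                          binRate = binRate)
}

#' @rdname simulateLIF
#' @export
simulateLIFInhibition <- function(cfg, W, duration, seed = 0, input = NULL,
                                  binRate = 10) {
    stopifnot(is(cfg, "LIFNetworkConfig"), is(W, "WeightMatrix"),
              duration >= cfg@dt, cfg@gInh >= 0)
    steps <- round(duration / cfg@dt)
    if (is.null(input)) {
        s <- numeric(steps)
        wIn <- numeric(cfg@N)
    } else {
        s <- input$s[seq_len(steps)]
        s[is.na(s)] <- 0
        wIn <- input$w
    }
    binSteps <- max(1L, round(1 / (binRate * cfg@dt)))
    set.seed(seed)
    res <- .lif_simulate(W@W, cfg@g, cfg@gInh, cfg@tauM, cfg@tauS, cfg@tauI,
                         cfg@theta, cfg@dt, s, wIn, cfg@noiseScale,
                         as.integer(binSteps), 5000000L)
    new("NetworkSimResult", spikes = res$spikes, binned = res$binned,
        binRate = 1 / (binSteps * cfg@dt), popRate = as.numeric(res$popRate),
        Iinh = as.numeric(res$Iinh), dt = cfg@dt, duration = duration,
        truncated = isTRUE(res$truncated), config = cfg)
}

#' Phase diagram of the network time constant
#'
#' Mean analytic `tau_n` over seeds on a subnetwork-density x synaptic-time-
#' constant grid; grid cells whose mean spectral radius reaches 1 are masked
#' unstable (NA in `tau`, TRUE in `unstable`).
#'
#' @param sigmaGrid subnetwork densities.
#' @param tauSGrid synaptic time constants, seconds.
#' @param cfg base [LIFNetworkConfig-class] (N, Np, background density).
#' @param seeds number of weight-matrix seeds per cell (default 20).
#' @param lambdaMode passed to [buildWeightMatrix()].
#' @return A list of matrices (`tau`, `lambda`, `unstable`) with rows
#'   indexed by `sigmaGrid` and columns by `tauSGrid`.
#' @export
phaseDiagram <- function(sigmaGrid, tauSGrid, cfg = lifConfig(),
                         seeds = 20, lambdaMode = "full") {
    stopifnot(length(sigmaGrid) >= 1, length(tauSGrid) >= 1)
    lamMean <- numeric(length(sigmaGrid))
    lamAll <- matrix(0, length(sigmaGrid), seeds)
    for (i in seq_along(sigmaGrid)) {
        cfgI <- cfg
        cfgI@sigma <- sigmaGrid[i]
        lamAll[i, ] <- vapply(seq_len(seeds), function(s)
            buildWeightMatrix(cfgI, seed = s,
                              lambdaMode = lambdaMode)@lambdaMax, 0)
        lamMean[i] <- mean(lamAll[i, ])
    }
    tau <- matrix(NA_real_, length(sigmaGrid), length(tauSGrid),
                  dimnames = list(sigma = signif(sigmaGrid, 4),
                                  tauS = signif(tauSGrid, 4)))
    unstable <- matrix(FALSE, length(sigmaGrid), length(tauSGrid))
    for (j in seq_along(tauSGrid))
        for (i in seq_along(sigmaGrid)) {
            taus <- tauSGrid[j] / abs(1 - lamAll[i, lamAll[i, ] < 1])
            if (mean(lamAll[i, ] >= 1) > 0.5 || !length(taus)) {
                unstable[i, j] <- TRUE
            } else {
                tau[i, j] <- mean(taus)
                unstable[i, j] <- any(lamAll[i, ] >= 1)
            }
        }
    list(tau = tau, lambda = lamMean, unstable = unstable,
         sigmaGrid = sigmaGrid, tauSGrid = tauSGrid)
}

#' Convolve firing rates into calcium-like traces
#'
#' Causal exponential-kernel convolution (`k(t) = exp(-t / kernelTau)`,
#' unit peak) of binned firing rates, followed by downsampling to the
#' target frame rate.  A single spike yields a trace that peaks at the
#' spike time and decays with `kernelTau`; a constant rate `rho` plateaus
#' at `rho * kernelTau`.
#'
#' @param rates neurons x bins spike counts or rates, or a
#'   [NetworkSimResult-class] (its `binned` counts are converted to Hz).
#' @param kernelTau indicator decay time constant, seconds (default 1.5,
#'   GCaMP7s-like).
#' @param frameRate output rate, Hz (default 10).
#' @param binRate input binning rate, Hz; taken from the simulation result
#'   when available.
#' @return A neurons x frames matrix of calcium-like traces.
#' @export
rateToCalcium <- function(rates, kernelTau = 1.5, frameRate = 10,
                          binRate = NULL) {
    stopifnot(kernelTau > 0)
    if (is(rates, "NetworkSimResult")) {
        binRate <- rates@binRate
        rates <- rates@binned * binRate   # counts per bin -> Hz
    }
    if (is.null(binRate)) binRate <- frameRate
    rates <- if (is.null(dim(rates))) matrix(rates, 1) else as.matrix(rates)
    nb <- ncol(rates)
    dtBin <- 1 / binRate
    decay <- exp(-dtBin / kernelTau)
    out <- matrix(0, nrow(rates), nb)
    acc <- numeric(nrow(rates))
    for (t in seq_len(nb)) {
        acc <- acc * decay + rates[, t] * dtBin
        out[, t] <- acc
    }
    ds <- max(1L, round(binRate / frameRate))
    out[, seq(ds, nb, by = ds), drop = FALSE]
}
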