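#' @include utils.R
NULL

#' Sample latents and activity from a recurrent switching LDS
#'
#' Draws a discrete state path from the recurrent softmax transitions, a
#' continuous latent trajectory from the state-conditioned linear-Gaussian
#' dynamics, and observations from the linear-Gaussian emission model.
#'
#' @param params an [RSLDSParams-class] object.
#' @param T number of frames to sample.
#' @param inputs optional input series (vector or U x T matrix); requires
#'   `params` to carry input matrices `B`.
#' @param seed integer RNG seed.
#' @param x0 initial latent state; defaults to `params@x0`.
#' @param z0 initial discrete state (default 1).
#' @param frameRate frame rate attached to the returned activity (Hz).
#' @param drive optional D x T matrix added to the latent update at each
#'   frame (used to model targeted photostimulation entering through the
#'   emission weights).
#' @return A list with elements `latents` ([LatentTrajectory-class]) and
#'   `activity` ([CalciumActivity-class]).
#' @examples
#' p <- RSLDSParams(A = 0.5 * diag(2), C = matrix(rnorm(20), 10, 2),
#'                  Q = 1e-12 * diag(2), S = rep(1e-12, 10))
#' s <- sampleRSLDS(p, T = 20, seed = 1, x0 = c(1, 1))
#' @export
sampleRSLDS <- function(params, T, inputs = NULL, seed = 0, x0 = NULL,
                        z0 = 1L, frameRate = 10, drive = NULL) {
    stopifnot(is(params, "RSLDSParams"), T >= 2)
    validObject(params)
    u <- .asInputMatrix(inputs, T)
    if (!is.null(u) && !length(params@B))
        stop("params carry no input matrix B but inputs were supplied")
    D <- params@D; K <- params@K; N <- nrow(params@C)
    if (is.null(x0)) x0 <- params@x0
    if (!is.null(drive)) stopifnot(nrow(drive) == D, ncol(drive) == T)

    set.seed(.substream(seed, "latents"))
    x <- matrix(0, D, T)
    z <- integer(T)
    xprev <- x0; zprev <- as.integer(z0)
    sqQ <- lapply(params@Q, function(Qk) {
        e <- eigen(Qk, symmetric = TRUE)
        e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    })
    for (t in seq_len(T)) {
        zt <- if (K == 1L) 1L else
            sample.int(K, 1L, prob = .transitionProbs(params, zprev, xprev))
        mu <- params@A[[zt]] %*% xprev + params@b[[zt]]
        if (!is.null(u)) mu <- mu + params@B[[zt]] %*% u[, t]
        if (!is.null(drive)) mu <- mu + drive[, t]
        x[, t] <- mu + sqQ[[zt]] %*% rnorm(D)
        z[t] <- zt
        xprev <- x[, t]; zprev <- zt
    }

    set.seed(.substream(seed, "emission"))
    noise <- matrix(rnorm(N * T), N, T) * sqrt(params@S)
    y <- params@C %*% x + params@d + noise

    list(latents = LatentTrajectory(x, z),
         activity = CalciumActivity(y, frameRate = frameRate))
}

#' Noise-free forward rollout of the mean dynamics
#'
#' Simulates the deterministic skeleton of the model from a starting point:
#' at each step the most-probable discrete state given the current latent
#' position is selected and the mean linear update applied.
#'
#' @param params an [RSLDSParams-class] object.
#' @param x0 starting latent point.
#' @param inputs optional input series (vector or U x T matrix).
#' @param T number of steps.
#' @param z0 initial discrete state (default 1).
#' @return A [LatentTrajectory-class] of length `T`.
#' @export
forwardSimulate <- function(params, x0, inputs = NULL, T, z0 = 1L) {
    stopifnot(is(params, "RSLDSParams"))
    u <- .asInputMatrix(inputs, T)
    D <- params@D; K <- params@K
    x <- matrix(0, D, T)
    z <- integer(T)
    xprev <- as.numeric(x0); zprev <- as.integer(z0)
    for (t in seq_len(T)) {
        zt <- if (K == 1L) 1L else
            which.max(.transitionProbs(params, zprev, xprev))
        mu <- params@A[[zt]] %*% xprev + params@b[[zt]]
        if (!is.null(u) && length(params@B)) mu <- mu + params@B[[zt]] %*% u[, t]
        x[, t] <- mu
        z[t] <- zt
        xprev <- x[, t]; zprev <- zt
    }
    LatentTrajectory(x, z)
}

#' Forward-simulation accuracy of a fitted model
#'
#' Variance explained (percent, in observation space) by a noise-free mean
#' rollout of the fitted dynamics from the inferred initial latent state,
#' under the given inputs.  One documented interpretation of
#' "forward simulation accuracy"; see the methods vignette.
#'
#' @param params an [RSLDSParams-class] (or [RSLDSFit-class]).
#' @param y activity matrix or [CalciumActivity-class].
#' @param inputs optional input series.
#' @return Percent variance explained.
#' @export
forwardSimAccuracy <- function(params, y, inputs = NULL) {
    if (is(params, "RSLDSFit")) params <- params@params
    Y <- .asActivityMatrix(y)
    lat <- inferLatents(params, Y, inputs = inputs)
    roll <- forwardSimulate(params, x0 = lat@x[, 1], inputs = inputs,
                            T = ncol(Y), z0 = lat@z[1])
    yhat <- params@C %*% roll@x + params@d
    100 * .r2(as.numeric(Y), as.numeric(yhat), refMean = rowMeans(Y))
}
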