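#' @include AllClasses.R
NULL

# Deterministic sub-seed for a named substream of a session seed.  Keeps all
# derived seeds positive and below 2^31.
.substream <- function(seed, name) {
    h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
    as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

.softmax <- function(eta) {
    m <- max(eta)
    e <- exp(eta - m)
    e / sum(e)
}

# Transition probabilities out of previous state k at latent position x.
.transitionProbs <- function(params, k, x) {
    eta <- as.numeric(params@Rw[[k]] %*% x) + params@rv[[k]]
    .softmax(eta)
}

.pinv <- function(M, tol = 1e-10) {
    s <- svd(M)
    keep <- s$d > tol * max(s$d)
    if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
    s$v[, keep, drop = FALSE] %*%
        (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Coerce activity input (matrix / CalciumActivity / SyntheticSession) to a
# plain neurons x frames matrix.
.asActivityMatrix <- function(y) {
    if (is(y, "SyntheticSession")) return(assay(y@activity, "activity"))
    if (is(y, "CalciumActivity")) return(assay(y, "activity"))
    as.matrix(y)
}

# Inputs as a U x T matrix (or NULL).
.asInputMatrix <- function(inputs, T) {
    if (is.null(inputs)) return(NULL)
    if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
    stopifnot(ncol(inputs) == T)
    inputs
}

.seconds2frames <- function(s, frameRate) as.integer(round(s * frameRate)) + 1L

# R^2 of predictions against observations, optionally with an external
# reference mean (e.g. training-fold means for held-out scoring).
.r2 <- function(y, yhat, refMean = NULL) {
    if (is.null(refMean)) refMean <- mean(y)
    sst <- sum((y - refMean)^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y - yhat)^2) / sst
}
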