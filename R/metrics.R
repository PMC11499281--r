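#' @include rslds-fit.R
NULL

#' Eigenvalue time constants of a dynamics matrix
#'
#' Each eigenvalue modulus `|lambda|` of the per-frame dynamics matrix maps
#' to a time constant `tau = |1 / log(|lambda|)|` in frames (natural log),
#' converted to seconds by the frame rate.  `|lambda| = 1` is reported as an
#' infinite tau ("infinite" flag), `|lambda| = 0` as zero tau ("zero"), and
#' `|lambda| > 1` as unstable.
#'
#' For a fitted switching model, pass an [RSLDSParams-class] or
#' [RSLDSFit-class] to obtain one [TimeConstantSet-class] per discrete
#' state; the element for the attractor-expressing state (largest leading
#' tau) is marked by the `"slowestState"` attribute.
#'
#' @param A a square dynamics matrix, or an
#'   [RSLDSParams-class]/[RSLDSFit-class].
#' @param frameRate acquisition rate, Hz (default 10).
#' @param state state id recorded in the result (matrix input only).
#' @return A [TimeConstantSet-class], or a list of them for multi-state
#'   parameters.
#' @examples
#' tc <- timeConstants(diag(c(exp(-1), 0.9)), frameRate = 10)
#' tc@tauFrames  # 1 and 1/|log 0.9|
#' @export
timeConstants <- function(A, frameRate = 10, state = 1L) {
    if (is(A, "RSLDSFit")) A <- A@params
    if (is(A, "RSLDSParams")) {
        out <- lapply(seq_len(A@K), function(k)
            timeConstants(A@A[[k]], frameRate = frameRate, state = k))
        lead <- vapply(out, function(tc) max(tc@tauFrames), 0)
        attr(out, "slowestState") <- which.max(lead)
        if (length(out) == 1L) return(out[[1L]])
        return(out)
    }
    A <- as.matrix(A)
    if (nrow(A) != ncol(A)) stop("dynamics matrix must be square")
    if (!all(is.finite(A))) stop("dynamics matrix must be finite")
    lam <- Mod(eigen(A, only.values = TRUE)$values)
    flags <- rep("ok", length(lam))
    flags[lam > 1] <- "unstable"
    flags[lam == 1] <- "infinite"
    flags[lam == 0] <- "zero"
    tauF <- ifelse(lam == 0, 0,
                   ifelse(lam == 1, Inf, abs(1 / log(lam))))
    new("TimeConstantSet", lambdaMod = lam, tauFrames = tauF,
        tauSeconds = tauF / frameRate, frameRate = frameRate,
        state = as.integer(state), flags = flags)
}

#' Line-attractor score
#'
#' `log2(t_n / t_{n-1})` where `t_n` and `t_{n-1}` are the largest and
#' second-largest time constants of the dynamics: a large score means a
#' single dominant slow mode, the signature of an approximate line
#' attractor.  Invariant to the ordering and common rescaling of the taus.
#'
#' For switching parameters the score is computed from the
#' attractor-expressing state (the state with the largest leading tau).
#'
#' @param taus a [TimeConstantSet-class], a numeric vector of taus, or an
#'   [RSLDSParams-class]/[RSLDSFit-class].
#' @param frameRate Hz; used only when parameters are supplied.
#' @return The score in log2 units.
#' @examples
#' lineAttractorScore(c(4, 1))  # 2
#' @export
lineAttractorScore <- function(taus, frameRate = 10) {
    if (is(taus, "RSLDSFit") || is(taus, "RSLDSParams")) {
        tc <- timeConstants(taus, frameRate = frameRate)
        if (is.list(tc)) tc <- tc[[attr(tc, "slowestState")]]
        taus <- tc
    }
    if (is(taus, "TimeConstantSet")) taus <- taus@tauFrames
    taus <- taus[is.finite(taus) & taus > 0]
    if (length(taus) < 2) stop("at least two finite positive taus required")
    s <- sort(taus, decreasing = TRUE)
    log2(s[1] / s[2])
}

#' Sample autocorrelation function
#'
#' Autocorrelation `r_k = c_k / c_0` with the biased (1/T) autocovariance
#' estimator `c_k = (1/T) sum_t (y_t - ybar)(y_{t+k} - ybar)`.
#'
#' @param y a numeric series.
#' @param maxLag maximum lag in frames (default `min(T - 1, 10 * sqrt(T))`).
#' @return An [AutocorrFunction-class] with lags 0..maxLag.
#' @export
autocorrelation <- function(y, maxLag = NULL) {
    y <- as.numeric(y)
    T <- length(y)
    if (!all(is.finite(y))) stop("series must be finite")
    if (is.null(maxLag)) maxLag <- min(T - 1, ceiling(10 * sqrt(T)))
    if (T <= maxLag) stop("series must be longer than maxLag")
    ybar <- mean(y)
    c0 <- mean((y - ybar)^2)
    if (c0 == 0) stop("zero-variance series has no autocorrelation")
    r <- as.numeric(acf(y, lag.max = maxLag, plot = FALSE,
                        demean = TRUE)$acf)
    new("AutocorrFunction", lags = 0:maxLag, r = r, c = r * c0, c0 = c0,
        mean = ybar, n = as.integer(T))
}

#' Autocorrelation half-width (ACHW)
#'
#' The first lag at which the autocorrelation falls to 0.5 (half its
#' zero-lag value), linearly interpolated between lags and converted to
#' seconds.  If the autocorrelation never reaches 0.5 within the computed
#' lags, the result is the maximum lag with attribute `censored = TRUE`.
#'
#' @param acf an [AutocorrFunction-class] (or a numeric series, in which
#'   case [autocorrelation()] is applied first).
#' @param frameRate acquisition rate, Hz.
#' @param maxLag passed to [autocorrelation()] when `acf` is a raw series.
#' @return Half-width in seconds (attribute `censored` flags truncation).
#' @export
autocorrHalfWidth <- function(acf, frameRate = 10, maxLag = NULL) {
    if (!is(acf, "AutocorrFunction"))
        acf <- autocorrelation(acf, maxLag = maxLag)
    r <- acf@r
    below <- which(r < 0.5)
    if (!length(below)) {
        out <- max(acf@lags) / frameRate
        attr(out, "censored") <- TRUE
        return(out)
    }
    k <- below[1]                       # index into r; lag = k - 1
    if (k == 1L) {                      # r drops below 0.5 immediately
        out <- 0 / frameRate
        attr(out, "censored") <- FALSE
        return(out)
    }
    r0 <- r[k - 1]; r1 <- r[k]
    frac <- (r0 - 0.5) / (r0 - r1)
    out <- ((k - 2) + frac) / frameRate
    attr(out, "censored") <- FALSE
    out
}

#' Latent-space flow field of a fitted model
#'
#' Evaluates the one-frame mean displacement `v(x) = A_k x + b_k + B_k u - x`
#' on a 2-D grid, where `k = k(x)` is the most-probable discrete state at
#' latent position x under the recurrent softmax (averaged over previous
#' states).
#'
#' @param params an [RSLDSParams-class] or [RSLDSFit-class] with D = 2.
#' @param xlim,ylim grid ranges for the two latent dimensions.
#' @param n grid points per axis (default 20).
#' @param inputLevel input level u the field is evaluated at (default 0).
#' @return A [FlowField-class]; the speed map `sqrt(rowSums(velocity^2))`
#'   is a simplified dynamic velocity landscape.
#' @export
flowField <- function(params, xlim = c(-3, 3), ylim = c(-3, 3), n = 20,
                      inputLevel = 0) {
    if (is(params, "RSLDSFit")) params <- params@params
    if (params@D != 2) stop("flow fields are defined for D = 2 models")
    gx <- seq(xlim[1], xlim[2], length.out = n)
    gy <- seq(ylim[1], ylim[2], length.out = n)
    pts <- as.matrix(expand.grid(x1 = gx, x2 = gy))
    K <- params@K
    vel <- matrix(0, nrow(pts), 2)
    st <- integer(nrow(pts))
    for (i in seq_len(nrow(pts))) {
        x <- pts[i, ]
        k <- if (K == 1L) 1L else {
            eta <- rowMeans(vapply(seq_len(K), function(kk)
                as.numeric(params@Rw[[kk]] %*% x) + params@rv[[kk]],
                numeric(K)))
            which.max(eta)
        }
        mu <- params@A[[k]] %*% x + params@b[[k]]
        if (length(params@B) && inputLevel != 0)
            mu <- mu + params@B[[k]] %*% rep(inputLevel, ncol(params@B[[k]]))
        vel[i, ] <- as.numeric(mu) - x
        st[i] <- k
    }
    new("FlowField", points = pts, velocity = vel, state = st,
        inputLevel = inputLevel)
}

#' Ramp and decay metrics of the integration dimension
#'
#' For each behaviour event, the ramp rate is the least-squares slope of the
#' slow-dimension signal in a fixed window after event onset (per second),
#' and the decay time constant is an exponential fit
#' `x(t) = a exp(-t / tau) + c` over the window from event offset to the
#' next onset (or series end).  Flat windows are flagged degenerate.
#'
#' @param x1 the slow-dimension (integration) series.
#' @param events a bout table with `start_s` and `stop_s` columns.
#' @param frameRate Hz.
#' @param rampWindowS ramp-fit window after onset, seconds (default 10).
#' @return A data frame with one row per event: `rampRatePerS`,
#'   `decayTauS`, `degenerate`.
#' @export
rampDecayMetrics <- function(x1, events, frameRate = 10, rampWindowS = 10) {
    x1 <- as.numeric(x1)
    T <- length(x1)
    out <- data.frame(event = seq_len(nrow(events)),
                      rampRatePerS = NA_real_, decayTauS = NA_real_,
                      degenerate = FALSE)
    for (i in seq_len(nrow(events))) {
        a <- .seconds2frames(events$start_s[i], frameRate)
        b <- min(.seconds2frames(events$start_s[i] + rampWindowS, frameRate), T)
        if (a >= T || b <= a)
            stop("ramp window falls outside the series")
        tt <- (seq(a, b) - a) / frameRate
        seg <- x1[a:b]
        out$rampRatePerS[i] <- unname(coef(lm(seg ~ tt))[2])

        dStart <- .seconds2frames(events$stop_s[i], frameRate)
        dEnd <- if (i < nrow(events))
            .seconds2frames(events$start_s[i + 1], frameRate) - 1L else T
        dEnd <- min(dEnd, T)
        if (dStart >= dEnd - 3L) next
        seg <- x1[dStart:dEnd]
        if (sd(seg) < 1e-10) { out$degenerate[i] <- TRUE; next }
        tt <- (seq_along(seg) - 1) / frameRate
        # starting values deliberately off the data hull: exact-interpolation
        # starts can present a rank-deficient gradient to the optimizer
        spread <- diff(range(seg))
        fit <- tryCatch(
            minpack.lm::nlsLM(seg ~ a0 * exp(-tt / tau) + c0,
                              start = list(a0 = 0.9 * (seg[1] - min(seg)),
                                           tau = max(diff(range(tt)) / 3, 0.2),
                                           c0 = min(seg) - 0.05 * spread),
                              control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
            out$degenerate[i] <- TRUE
            next
        }
        out$decayTauS[i] <- coef(fit)[["tau"]]
    }
    out
}
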