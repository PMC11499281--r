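#' @include rslds-sample.R
NULL

# ---------------------------------------------------------------------------
# Structured variational EM for the recurrent switching LDS.
#
# E-step alternates (i) exact Kalman smoothing of the continuous latents
# under the current most-probable discrete path and (ii) forward-backward
# over the discrete chain given the smoothed latent means, with transition
# probabilities from the recurrent softmax.  M-steps are closed-form
# weighted regressions using the full smoothed second moments; the softmax
# transition parameters are refit by ridge-regularized multinomial logistic
# regression.  For K = 1 the scheme reduces to exact EM for a linear
# dynamical system and the recorded objective is the exact marginal
# log-likelihood (hence non-decreasing); for K > 1 the objective is the
# joint log-likelihood surrogate at the most-probable path.
# ---------------------------------------------------------------------------

.paramCubes <- function(params) {
    D <- params@D; K <- params@K
    hasB <- length(params@B) > 0L
    U <- if (hasB) ncol(params@B[[1]]) else 0L
    list(A = array(unlist(params@A), c(D, D, K)),
         b = matrix(unlist(params@b), D, K),
         Q = array(unlist(params@Q), c(D, D, K)),
         B = if (hasB) array(unlist(params@B), c(D, U, K))
             else array(0, c(D, 0, 1)),
         U = U)
}

.smoothSegment <- function(params, Y, u, z) {
    pc <- .paramCubes(params)
    if (is.null(u)) u <- matrix(0, 0, ncol(Y))
    .kalman_smoother_tv(Y, params@C, params@d, pmax(params@S, 1e-10),
                        pc$A, pc$b, pc$Q, pc$B, u,
                        as.integer(z), params@x0, params@P0)
}

# State-conditional log-density of the latent one-step transitions.
.dynLoglik <- function(params, xhat, u) {
    D <- params@D; K <- params@K; T <- ncol(xhat)
    L <- matrix(0, K, T)
    for (k in seq_len(K)) {
        pred <- params@A[[k]] %*% xhat[, -T, drop = FALSE] + params@b[[k]]
        if (!is.null(u) && length(params@B))
            pred <- pred + params@B[[k]] %*% u[, -1, drop = FALSE]
        resid <- xhat[, -1, drop = FALSE] - pred
        Qk <- params@Q[[k]] + 1e-10 * diag(D)
        ch <- chol(Qk)
        w <- backsolve(ch, resid, transpose = TRUE)
        L[k, -1] <- -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(ch))) +
                            colSums(w^2))
    }
    L
}

# log p(z_{t+1} = j | z_t = k, x_t) for every t; K x K x (T-1) array.
.transLogProbs <- function(params, xhat) {
    K <- params@K; T <- ncol(xhat)
    out <- array(0, c(K, K, T - 1))
    for (k in seq_len(K)) {
        eta <- params@Rw[[k]] %*% xhat[, -T, drop = FALSE] + params@rv[[k]]
        m <- apply(eta, 2, max)
        lse <- m + log(colSums(exp(sweep(eta, 2, m))))
        out[k, , ] <- sweep(eta, 2, lse)
    }
    out
}

.fbDiscrete <- function(L, logP) {
    K <- nrow(L); T <- ncol(L)
    lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
    la <- matrix(-Inf, K, T)
    la[, 1] <- L[, 1] - log(K)
    for (t in 2:T)
        for (j in seq_len(K))
            la[j, t] <- lse(la[, t - 1] + logP[, j, t - 1]) + L[j, t]
    lb <- matrix(0, K, T)
    for (t in (T - 1):1)
        for (k in seq_len(K))
            lb[k, t] <- lse(logP[k, , t] + L[, t + 1] + lb[, t + 1])
    ll <- lse(la[, T])
    lg <- la + lb - ll
    gamma <- exp(sweep(lg, 2, apply(lg, 2, lse)))
    xi <- array(0, c(K, K, T - 1))
    for (t in seq_len(T - 1))
        for (k in seq_len(K))
            xi[k, , t] <- exp(la[k, t] + logP[k, , t] + L[, t + 1] +
                              lb[, t + 1] - ll)
    list(gamma = gamma, xi = xi, loglik = ll)
}

.viterbiDiscrete <- function(L, logP) {
    K <- nrow(L); T <- ncol(L)
    if (K == 1L) return(rep(1L, T))
    delta <- matrix(-Inf, K, T)
    back <- matrix(1L, K, T)
    delta[, 1] <- L[, 1] - log(K)
    for (t in 2:T)
        for (j in seq_len(K)) {
            v <- delta[, t - 1] + logP[, j, t - 1]
            back[j, t] <- which.max(v)
            delta[j, t] <- max(v) + L[j, t]
        }
    z <- integer(T)
    z[T] <- which.max(delta[, T])
    for (t in (T - 1):1) z[t] <- back[z[t + 1], t + 1]
    z
}

# Ridge-penalized multinomial logistic regression with fractional response
# weights; logits of state 1 are pinned at zero for identifiability.
.ridgeMultinomial <- function(Xf, Xi, theta0 = NULL, lambda = 1e-3) {
    n <- nrow(Xf); P <- ncol(Xf); K <- ncol(Xi)
    tot <- rowSums(Xi)
    if (is.null(theta0)) theta0 <- matrix(0, K - 1, P)
    obj <- function(th) {
        th <- matrix(th, K - 1, P)
        eta <- cbind(0, Xf %*% t(th))
        m <- apply(eta, 1, max)
        lse <- m + log(rowSums(exp(eta - m)))
        -(sum(Xi * eta) - sum(tot * lse)) + 0.5 * lambda * sum(th^2)
    }
    grad <- function(th) {
        th <- matrix(th, K - 1, P)
        eta <- cbind(0, Xf %*% t(th))
        m <- apply(eta, 1, max)
        pr <- exp(eta - m); pr <- pr / rowSums(pr)
        G <- -(t(Xi[, -1, drop = FALSE] - tot * pr[, -1, drop = FALSE]) %*% Xf) +
            lambda * th
        as.numeric(G)
    }
    fit <- optim(as.numeric(theta0), obj, grad, method = "BFGS",
                 control = list(maxit = 100))
    matrix(fit$par, K - 1, P)
}

# Weighted sums of smoothed second moments needed by the M-steps.
.momentSums <- function(sm, u) {
    xhat <- sm$xs
    D <- nrow(xhat); T <- ncol(xhat)
    Vflat <- matrix(sm$Vs, D * D, T)
    Cflat <- matrix(sm$cross, D * D, max(T - 1, 0))
    list(xhat = xhat, Vflat = Vflat, Cflat = Cflat, D = D, T = T, u = u)
}

# Dynamics regression sufficient statistics for one state, weights w over
# t = 2..T (the frame the transition lands on).
.dynStats <- function(ms, w) {
    D <- ms$D; T <- ms$T
    xprev <- ms$xhat[, -T, drop = FALSE]
    xcur <- ms$xhat[, -1, drop = FALSE]
    U <- if (is.null(ms$u)) 0L else nrow(ms$u)
    ucur <- if (U) ms$u[, -1, drop = FALSE] else NULL
    wp <- sweep(xprev, 2, w, `*`)
    Epp <- wp %*% t(xprev) + matrix(ms$Vflat[, -T, drop = FALSE] %*% w, D, D)
    Ecp <- sweep(xcur, 2, w, `*`) %*% t(xprev) +
        matrix(ms$Cflat %*% w, D, D)
    Ecc <- sweep(xcur, 2, w, `*`) %*% t(xcur) +
        matrix(ms$Vflat[, -1, drop = FALSE] %*% w, D, D)
    sp <- as.numeric(wp %*% rep(1, T - 1))
    sc <- as.numeric(sweep(xcur, 2, w, `*`) %*% rep(1, T - 1))
    sw <- sum(w)
    P <- D + U + 1L
    G <- matrix(0, P, P)
    H <- matrix(0, D, P)
    G[1:D, 1:D] <- Epp
    G[1:D, P] <- sp; G[P, 1:D] <- sp; G[P, P] <- sw
    H[, 1:D] <- Ecp; H[, P] <- sc
    if (U) {
        uw <- sweep(ucur, 2, w, `*`)
        G[D + 1:U, D + 1:U] <- uw %*% t(ucur)
        G[1:D, D + 1:U] <- wp %*% t(ucur)
        G[D + 1:U, 1:D] <- t(G[1:D, D + 1:U])
        su <- as.numeric(uw %*% rep(1, T - 1))
        G[D + 1:U, P] <- su; G[P, D + 1:U] <- su
        H[, D + 1:U] <- sweep(xcur, 2, w, `*`) %*% t(ucur)
    }
    list(G = G, H = H, Ecc = Ecc, sw = sw, U = U)
}

.psdFloor <- function(M, eps = 1e-8) {
    M <- 0.5 * (M + t(M))
    e <- eigen(M, symmetric = TRUE)
    e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
}

.emInit <- function(Ylist, D, K, Ulist, seed) {
    Y <- do.call(cbind, Ylist)
    N <- nrow(Y); Ttot <- ncol(Y)
    d0 <- rowMeans(Y)
    sds <- pmax(apply(Y, 1, sd), 1e-8)
    fa <- tryCatch(
        suppressWarnings(factanal(t(Y), factors = D, scores = "regression")),
        error = function(e) NULL)
    if (!is.null(fa)) {
        C0 <- unclass(fa$loadings) * sds
        xall <- t(fa$scores)
        S0 <- pmax(fa$uniquenesses, 1e-4) * sds^2
    } else {
        pr <- prcomp(t(Y), center = TRUE)
        C0 <- pr$rotation[, seq_len(D), drop = FALSE]
        xall <- t(pr$x[, seq_len(D), drop = FALSE])
        resid <- Y - d0 - C0 %*% xall
        S0 <- pmax(rowMeans(resid^2), 1e-6)
    }
    set.seed(.substream(seed, "init"))
    z <- if (K > 1L)
        as.integer(kmeans(t(xall), centers = K, nstart = 5)$cluster)
    else rep(1L, Ttot)
    U <- if (is.null(Ulist[[1]])) 0L else nrow(Ulist[[1]])
    A <- vector("list", K); b <- vector("list", K); Q <- vector("list", K)
    Blist <- if (U) vector("list", K) else list()
    uall <- if (U) do.call(cbind, Ulist) else NULL
    xprev <- xall[, -Ttot, drop = FALSE]
    xcur <- xall[, -1, drop = FALSE]
    zc <- z[-1]
    for (k in seq_len(K)) {
        idx <- which(zc == k)
        if (length(idx) < D + U + 2L) idx <- seq_len(Ttot - 1L)
        Phi <- rbind(xprev[, idx, drop = FALSE],
                     if (U) uall[, idx + 1L, drop = FALSE], 1)
        G <- Phi %*% t(Phi) + 1e-6 * diag(nrow(Phi))
        W <- xcur[, idx, drop = FALSE] %*% t(Phi) %*% solve(G)
        A[[k]] <- W[, seq_len(D), drop = FALSE]
        if (U) Blist[[k]] <- W[, D + seq_len(U), drop = FALSE]
        b[[k]] <- as.numeric(W[, D + U + 1L])
        resid <- xcur[, idx, drop = FALSE] - W %*% Phi
        Q[[k]] <- .psdFloor(resid %*% t(resid) / length(idx), 1e-6)
    }
    # initialize the recurrent softmax from the k-means path, so the first
    # forward-backward pass is gated by latent position rather than by
    # residual likelihoods alone
    Rw0 <- rep(list(matrix(0, K, D)), K)
    rv0 <- rep(list(rep(0, K)), K)
    if (K > 1L) {
        Xf <- cbind(1, t(xall[, -Ttot, drop = FALSE]))
        znext <- z[-1]
        for (k in seq_len(K)) {
            rows <- which(z[-Ttot] == k)
            if (length(rows) < 5L || length(unique(znext[rows])) < 2L) next
            Xi <- matrix(0, length(rows), K)
            Xi[cbind(seq_along(rows), znext[rows])] <- 1
            th <- .ridgeMultinomial(Xf[rows, , drop = FALSE], Xi,
                                    lambda = 1e-2)
            Rw0[[k]] <- rbind(0, th[, -1, drop = FALSE])
            rv0[[k]] <- c(0, th[, 1])
        }
    }
    params <- RSLDSParams(A = A, C = C0, b = b, Q = Q, d = d0, S = S0,
                          Rw = Rw0, rv = rv0,
                          B = if (U) Blist else NULL,
                          x0 = xall[, 1], P0 = diag(D), K = K)
    Tlens <- vapply(Ylist, ncol, 0L)
    ends <- cumsum(Tlens)
    starts <- c(1L, head(ends, -1L) + 1L)
    list(params = params,
         xhat = Map(function(s, e) xall[, s:e, drop = FALSE], starts, ends),
         z = Map(function(s, e) z[s:e], starts, ends))
}

.fitEngine <- function(Ylist, D, K, Ulist, maxIter = 50, tol = 1e-5,
                       seed = 0) {
    init <- .emInit(Ylist, D, K, Ulist, seed)
    params <- init$params
    xhatL <- init$xhat
    zL <- init$z
    nSeg <- length(Ylist)
    objTrace <- numeric(0)
    converged <- FALSE

    for (iter in seq_len(maxIter)) {
        gammaL <- vector("list", nSeg)
        xiL <- vector("list", nSeg)
        obj <- 0
        smL <- vector("list", nSeg)
        for (s in seq_len(nSeg)) {
            if (K > 1L) {
                L <- .dynLoglik(params, xhatL[[s]], Ulist[[s]])
                logP <- .transLogProbs(params, xhatL[[s]])
                fb <- .fbDiscrete(L, logP)
                gammaL[[s]] <- fb$gamma
                xiL[[s]] <- fb$xi
                zL[[s]] <- .viterbiDiscrete(L, logP)
                tp <- sum(logP[cbind(zL[[s]][-length(zL[[s]])],
                                     zL[[s]][-1],
                                     seq_len(length(zL[[s]]) - 1L))])
                obj <- obj + tp
            } else {
                gammaL[[s]] <- matrix(1, 1, ncol(Ylist[[s]]))
            }
            sm <- .smoothSegment(params, Ylist[[s]], Ulist[[s]], zL[[s]])
            smL[[s]] <- sm
            xhatL[[s]] <- sm$xs
            obj <- obj + sm$loglik
        }
        objTrace <- c(objTrace, obj)

        # ---- M-steps ----
        msL <- Map(function(sm, u) .momentSums(sm, u), smL, Ulist)
        U <- if (is.null(Ulist[[1]])) 0L else nrow(Ulist[[1]])
        P <- D + U + 1L
        newA <- params@A; newb <- params@b; newQ <- params@Q
        newB <- params@B
        for (k in seq_len(K)) {
            G <- matrix(0, P, P); H <- matrix(0, D, P)
            Ecc <- matrix(0, D, D); sw <- 0
            for (s in seq_len(nSeg)) {
                w <- gammaL[[s]][k, -1]
                st <- .dynStats(msL[[s]], w)
                G <- G + st$G; H <- H + st$H
                Ecc <- Ecc + st$Ecc; sw <- sw + st$sw
            }
            if (sw < D + U + 2) next
            Gr <- G + 1e-8 * mean(diag(G)) * diag(P)
            Wmat <- H %*% solve(Gr)
            newA[[k]] <- Wmat[, seq_len(D), drop = FALSE]
            if (U) newB[[k]] <- Wmat[, D + seq_len(U), drop = FALSE]
            newb[[k]] <- as.numeric(Wmat[, P])
            Qk <- (Ecc - Wmat %*% t(H) - H %*% t(Wmat) +
                   Wmat %*% G %*% t(Wmat)) / sw
            newQ[[k]] <- .psdFloor(Qk, 1e-8)
        }

        # emission
        N <- nrow(Ylist[[1]])
        Exx <- matrix(0, D, D); Ex <- rep(0, D); Ttot <- 0
        Hy <- matrix(0, N, D); sy <- rep(0, N); syy <- rep(0, N)
        for (s in seq_len(nSeg)) {
            ms <- msL[[s]]
            Exx <- Exx + ms$xhat %*% t(ms$xhat) +
                matrix(ms$Vflat %*% rep(1, ms$T), D, D)
            Ex <- Ex + rowSums(ms$xhat)
            Ttot <- Ttot + ms$T
            Hy <- Hy + Ylist[[s]] %*% t(ms$xhat)
            sy <- sy + rowSums(Ylist[[s]])
            syy <- syy + rowSums(Ylist[[s]]^2)
        }
        Ge <- rbind(cbind(Exx, Ex), c(Ex, Ttot))
        Ge <- Ge + 1e-10 * mean(diag(Ge)) * diag(D + 1)
        He <- cbind(Hy, sy)
        CD <- He %*% solve(Ge)
        newC <- CD[, seq_len(D), drop = FALSE]
        newd <- as.numeric(CD[, D + 1])
        Svec <- (syy - 2 * rowSums(CD * He) + rowSums((CD %*% Ge) * CD)) / Ttot
        newS <- pmax(Svec, 1e-8)

        # transitions
        newRw <- params@Rw; newrv <- params@rv
        if (K > 1L) {
            for (k in seq_len(K)) {
                Xf <- NULL; Xi <- NULL
                for (s in seq_len(nSeg)) {
                    Ts <- ncol(xhatL[[s]])
                    Xf <- rbind(Xf, cbind(1, t(xhatL[[s]][, -Ts, drop = FALSE])))
                    Xi <- rbind(Xi, t(xiL[[s]][k, , , drop = TRUE]))
                }
                if (sum(Xi) < 1e-6) next
                th0 <- cbind(params@rv[[k]][-1] - params@rv[[k]][1],
                             sweep(params@Rw[[k]][-1, , drop = FALSE], 2,
                                   params@Rw[[k]][1, ], `-`))
                th <- .ridgeMultinomial(Xf, Xi, theta0 = th0)
                newRw[[k]] <- rbind(0, th[, -1, drop = FALSE])
                newrv[[k]] <- c(0, th[, 1])
            }
        }

        params <- new(Class = "RSLDSParams", K = params@K, D = params@D,
                      A = newA, b = newb, Q = newQ, Rw = newRw, rv = newrv,
                      C = newC, d = newd, S = newS, B = newB,
                      x0 = params@x0, P0 = params@P0)

        if (iter > 1L) {
            rel <- abs(objTrace[iter] - objTrace[iter - 1L]) /
                (1 + abs(objTrace[iter - 1L]))
            if (rel < tol) { converged <- TRUE; break }
        }
    }

    list(params = params, xhat = xhatL, z = zL,
         objective = objTrace, converged = converged)
}

#' Fit a recurrent switching linear dynamical system
#'
#' Fits the model by structured variational EM: exact Kalman smoothing of
#' the continuous latents given the most-probable discrete path,
#' forward-backward over the recurrent softmax chain given the latents,
#' closed-form regression M-steps using full smoothed second moments, and
#' ridge-regularized multinomial logistic regression for the transition
#' parameters.  The emission matrix is initialized by factor analysis (with
#' a PCA fallback), discrete states by k-means on the initial latents.
#'
#' @param y activity: matrix (neurons x frames), [CalciumActivity-class] or
#'   [SyntheticSession-class].
#' @param D latent dimensionality (default 2).
#' @param K number of discrete states (default 2).
#' @param inputs optional input series (vector or U x T matrix); adds input
#'   matrices `B_k` to the latent update.
#' @param maxIter maximum EM iterations.
#' @param tol relative objective-change convergence tolerance.
#' @param seed RNG seed (k-means initialization).
#' @return An [RSLDSFit-class]; if the objective did not converge within
#'   `maxIter` the best-so-far parameters are returned with
#'   `diagnostics(fit)@converged == FALSE` and a warning.
#' @examples
#' \donttest{
#' ses <- generateLineAttractorSession(nNeurons = 30, nFrames = 600, seed = 1)
#' fit <- fitRSLDS(ses, D = 2, K = 2, maxIter = 15)
#' }
#' @export
fitRSLDS <- function(y, D = 2, K = 2, inputs = NULL, maxIter = 50,
                     tol = 1e-5, seed = 0) {
    Y <- .asActivityMatrix(y)
    if (!all(is.finite(Y))) stop("activity must be finite")
    T <- ncol(Y)
    if (T <= D * K * 5L) stop("too few frames for the requested model size")
    if (max(apply(Y, 1, var)) < 1e-12)
        stop("degenerate data: no variance to model")
    u <- .asInputMatrix(inputs, T)
    res <- .fitEngine(list(Y), as.integer(D), as.integer(K), list(u),
                      maxIter = maxIter, tol = tol, seed = seed)
    if (!res$converged)
        warning("EM did not converge within maxIter; returning best-so-far")
    diag <- new("FitDiagnostics", objective = res$objective,
                cvR2 = NA_real_, forwardSimR2 = NA_real_,
                folds = integer(0), converged = res$converged)
    new("RSLDSFit", params = res$params, diagnostics = diag,
        latents = LatentTrajectory(res$xhat[[1]], res$z[[1]]))
}

#' Infer latent states under fixed parameters
#'
#' Posterior inference of the continuous latents (Kalman smoother) and the
#' most-probable discrete path (Viterbi over the recurrent softmax chain),
#' alternated for a few sweeps.
#'
#' @param params an [RSLDSParams-class] (or [RSLDSFit-class]).
#' @param y activity (matrix or [CalciumActivity-class]).
#' @param inputs optional input series.
#' @param nSweeps number of discrete/continuous alternations.
#' @return A [LatentTrajectory-class].
#' @export
inferLatents <- function(params, y, inputs = NULL, nSweeps = 3) {
    if (is(params, "RSLDSFit")) params <- params@params
    Y <- .asActivityMatrix(y)
    if (nrow(Y) != nrow(params@C))
        stop("activity rows do not match the emission matrix")
    T <- ncol(Y)
    u <- .asInputMatrix(inputs, T)
    xhat <- .pinv(params@C) %*% (Y - params@d)
    z <- rep(1L, T)
    for (s in seq_len(nSweeps)) {
        if (params@K > 1L) {
            L <- .dynLoglik(params, xhat, u)
            logP <- .transLogProbs(params, xhat)
            z <- .viterbiDiscrete(L, logP)
        }
        sm <- .smoothSegment(params, Y, u, z)
        xhat <- sm$xs
        if (params@K == 1L) break
    }
    LatentTrajectory(xhat, z)
}

#' Cross-validated variance explained of an rSLDS model
#'
#' Five-fold (by default) cross-validation over contiguous time blocks: the
#' model is fit on the remaining blocks (as independent segments, so no
#' dynamics are fit across the seam), latents are inferred on the held-out
#' block under the trained parameters, and held-out activity is
#' reconstructed as `C x + d`.  Variance explained is computed against the
#' training-fold neuron means and averaged over folds.
#'
#' @inheritParams fitRSLDS
#' @param folds number of contiguous folds (default 5).
#' @return Mean held-out variance explained, percent.
#' @export
crossValidatedR2 <- function(y, D = 2, K = 2, folds = 5, seed = 0,
                             inputs = NULL, maxIter = 30, tol = 1e-5) {
    Y <- .asActivityMatrix(y)
    T <- ncol(Y)
    if (folds < 2L) stop("folds must be >= 2")
    if (T < folds * 40L) stop("too few frames for contiguous cross-validation")
    u <- .asInputMatrix(inputs, T)
    bounds <- floor(seq(0, T, length.out = folds + 1))
    r2 <- numeric(folds)
    for (f in seq_len(folds)) {
        test <- (bounds[f] + 1):bounds[f + 1]
        segs <- list(); usegs <- list()
        if (bounds[f] >= 40L) {
            segs <- c(segs, list(Y[, 1:bounds[f], drop = FALSE]))
            usegs <- c(usegs, list(if (is.null(u)) NULL
                                   else u[, 1:bounds[f], drop = FALSE]))
        }
        if (T - bounds[f + 1] >= 40L) {
            segs <- c(segs, list(Y[, (bounds[f + 1] + 1):T, drop = FALSE]))
            usegs <- c(usegs, list(if (is.null(u)) NULL
                                   else u[, (bounds[f + 1] + 1):T, drop = FALSE]))
        }
        res <- .fitEngine(segs, as.integer(D), as.integer(K), usegs,
                          maxIter = maxIter, tol = tol, seed = seed)
        lat <- inferLatents(res$params, Y[, test, drop = FALSE],
                            inputs = if (is.null(u)) NULL
                                     else u[, test, drop = FALSE])
        yhat <- res$params@C %*% lat@x + res$params@d
        trainMean <- rowMeans(do.call(cbind, segs))
        r2[f] <- .r2(as.numeric(Y[, test]), as.numeric(yhat),
                     refMean = trainMean)
    }
    100 * mean(r2)
}

#' Sweep the number of discrete states by cross-validation
#'
#' @inheritParams crossValidatedR2
#' @param Ks integer vector of state counts to evaluate.
#' @return A data frame with columns `K` and `cvR2` (percent).
#' @export
stateCountSweep <- function(y, Ks = 1:3, D = 2, folds = 5, seed = 0,
                            inputs = NULL, maxIter = 30) {
    cv <- vapply(Ks, function(k)
        crossValidatedR2(y, D = D, K = k, folds = folds, seed = seed,
                         inputs = inputs, maxIter = maxIter), 0)
    data.frame(K = Ks, cvR2 = cv)
}
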