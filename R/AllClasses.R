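#' @include lineattractor-package.R
NULL

# ---------------------------------------------------------------------------
# Central data containers.  Population activity lives in a thin extension of
# SummarizedExperiment (rows = neurons, columns = frames); model parameters,
# latent trajectories and simulation results are plain S4 value objects with
# validity methods.
# ---------------------------------------------------------------------------

#' CalciumActivity: population calcium traces
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a single
#' `activity` assay of neurons x frames calcium traces (dF/F or z-scored),
#' plus the acquisition frame rate and an optional baseline window used for
#' z-scoring in perturbation analyses.  Cell metadata (positions, dimension
#' labels) go in `rowData`; per-frame covariates (time, input schedule) in
#' `colData`.
#'
#' @slot frameRate acquisition rate in Hz.
#' @slot baselineWindow integer frame interval `c(first, last)` used as the
#'   baseline epoch, or `integer(0)` when none is defined.
#' @export
setClass("CalciumActivity",
    contains = "SummarizedExperiment",
    representation(frameRate = "numeric", baselineWindow = "integer"))

setValidity("CalciumActivity", function(object) {
    msg <- NULL
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
        msg <- c(msg, "frameRate must be a single positive number")
    if (!"activity" %in% names(assays(object)))
        msg <- c(msg, "an assay named 'activity' is required")
    else if (!all(is.finite(assay(object, "activity"))))
        msg <- c(msg, "activity matrix must be finite")
    bw <- object@baselineWindow
    if (length(bw) && (length(bw) != 2L || bw[1] < 1L || bw[2] > ncol(object) ||
                       bw[1] > bw[2]))
        msg <- c(msg, "baselineWindow must be c(first, last) within frames")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CalciumActivity object
#'
#' @param activity neurons x frames numeric matrix.
#' @param frameRate acquisition rate in Hz (default 10).
#' @param baselineWindow optional frame interval `c(first, last)` marking the
#'   baseline epoch.
#' @param positions optional data frame of cell metadata (e.g. `x_um`,
#'   `y_um`, `dim_label`) with one row per neuron, stored in `rowData`.
#' @return A [CalciumActivity-class] object.
#' @examples
#' y <- CalciumActivity(matrix(rnorm(50), 5, 10), frameRate = 10)
#' nFrames(y)
#' @export
CalciumActivity <- function(activity, frameRate = 10,
                            baselineWindow = integer(0), positions = NULL) {
    activity <- as.matrix(activity)
    if (is.null(rownames(activity)))
        rownames(activity) <- paste0("cell", seq_len(nrow(activity)))
    cd <- DataFrame(time_s = (seq_len(ncol(activity)) - 1) / frameRate)
    rd <- if (is.null(positions)) DataFrame(row.names = rownames(activity))
          else DataFrame(positions, row.names = rownames(activity))
    se <- SummarizedExperiment(assays = list(activity = activity),
                               rowData = rd, colData = cd)
    new("CalciumActivity", se, frameRate = as.numeric(frameRate),
        baselineWindow = as.integer(baselineWindow))
}

#' RSLDSParams: parameters of a recurrent switching LDS
#'
#' Full parameter set of the generative model
#' \deqn{p(z_{t+1} | z_t = k, x_t) = \mathrm{softmax}(R_k x_t + r_k)}
#' \deqn{x_t = A_{z_t} x_{t-1} + b_{z_t} + B_{z_t} u_t + \epsilon_t,\quad
#'       \epsilon_t \sim N(0, Q_{z_t})}
#' \deqn{y_t = C x_t + d + \delta_t,\quad \delta_t \sim N(0, \mathrm{diag}(S))}
#'
#' @slot K number of discrete states.
#' @slot D latent dimensionality.
#' @slot A list of K dynamics matrices (D x D).
#' @slot b list of K bias vectors (length D).
#' @slot Q list of K innovation covariances (D x D, PSD).
#' @slot Rw list of K recurrent transition weight matrices (K x D); row j of
#'   `Rw[[k]]` holds the logit weights for next state j given previous state k.
#' @slot rv list of K transition offset vectors (length K).
#' @slot C emission matrix (N x D).
#' @slot d emission offset (length N).
#' @slot S diagonal observation variances (length N).
#' @slot B list of K input matrices (D x U); empty list when the model has no
#'   input term.
#' @slot x0 prior mean of the initial latent state.
#' @slot P0 prior covariance of the initial latent state.
#' @export
setClass("RSLDSParams",
    representation(K = "integer", D = "integer",
                   A = "list", b = "list", Q = "list",
                   Rw = "list", rv = "list",
                   C = "matrix", d = "numeric", S = "numeric",
                   B = "list", x0 = "numeric", P0 = "matrix"))

setValidity("RSLDSParams", function(object) {
    msg <- NULL
    K <- object@K; D <- object@D
    if (K < 1L || D < 1L) msg <- c(msg, "K and D must be >= 1")
    for (nm in c("A", "b", "Q", "Rw", "rv"))
        if (length(slot(object, nm)) != K)
            msg <- c(msg, sprintf("%s must have K = %d elements", nm, K))
    for (k in seq_len(min(K, length(object@A)))) {
        if (!all(dim(object@A[[k]]) == c(D, D)))
            msg <- c(msg, "each A[[k]] must be D x D")
        Qk <- object@Q[[k]]
        if (!all(dim(Qk) == c(D, D)) || max(abs(Qk - t(Qk))) > 1e-8 ||
            min(eigen(Qk, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
            msg <- c(msg, "each Q[[k]] must be symmetric positive semi-definite")
    }
    if (ncol(object@C) != D) msg <- c(msg, "C must have D columns")
    if (length(object@d) != nrow(object@C)) msg <- c(msg, "length(d) != nrow(C)")
    if (length(object@S) != nrow(object@C) || any(object@S < 0))
        msg <- c(msg, "S must be nonnegative with one entry per neuron")
    if (length(object@x0) != D) msg <- c(msg, "x0 must have length D")
    if (is.null(msg)) TRUE else msg
})

#' Construct an RSLDSParams object
#'
#' Single matrices/vectors are recycled across states, so a one-state LDS can
#' be written `RSLDSParams(A = 0.5 * diag(2), C = C)`.
#'
#' @param A dynamics matrix or list of K matrices.
#' @param b bias vector or list; defaults to zeros.
#' @param Q innovation covariance or list; defaults to identity.
#' @param C emission matrix (N x D).
#' @param d emission offset; defaults to zeros.
#' @param S diagonal observation variances; defaults to 1 per neuron.
#' @param Rw recurrent transition weights (K x D matrix or list of K);
#'   defaults to zeros (state-independent transitions).
#' @param rv transition offsets (length-K vector or list of K); defaults to
#'   zeros (uniform).
#' @param B optional input matrix (D x U) or list of K.
#' @param x0,P0 prior mean/covariance of the initial latent state.
#' @param K number of discrete states; inferred from `A` when a list.
#' @return An [RSLDSParams-class] object.
#' @export
RSLDSParams <- function(A, C, b = NULL, Q = NULL, d = NULL, S = NULL,
                        Rw = NULL, rv = NULL, B = NULL, x0 = NULL, P0 = NULL,
                        K = NULL) {
    if (!is.list(A)) A <- list(A)
    if (is.null(K)) K <- length(A)
    K <- as.integer(K)
    D <- ncol(A[[1]])
    rep_k <- function(x, default) {
        if (is.null(x)) x <- default
        if (!is.list(x)) x <- list(x)
        if (length(x) == 1L && K > 1L) x <- rep(x, K)
        x
    }
    A <- rep_k(A, NULL)
    b <- rep_k(b, rep(0, D))
    Q <- rep_k(Q, diag(D))
    Rw <- rep_k(Rw, matrix(0, K, D))
    rv <- rep_k(rv, rep(0, K))
    C <- as.matrix(C)
    N <- nrow(C)
    if (is.null(d)) d <- rep(0, N)
    if (is.null(S)) S <- rep(1, N)
    if (is.matrix(S)) S <- diag(S)
    Blist <- if (is.null(B)) list() else if (is.list(B)) B else rep(list(B), K)
    if (is.null(x0)) x0 <- rep(0, D)
    if (is.null(P0)) P0 <- diag(D)
    new(Class = "RSLDSParams", K = K, D = as.integer(D), A = A, b = b, Q = Q,
        Rw = Rw, rv = rv, C = C, d = as.numeric(d), S = as.numeric(S),
        B = Blist, x0 = as.numeric(x0), P0 = as.matrix(P0))
}

#' LatentTrajectory: continuous latents and discrete states
#'
#' @slot x continuous latent factors, D x T.
#' @slot z discrete state labels, length T, values in 1..K.
#' @export
setClass("LatentTrajectory",
    representation(x = "matrix", z = "integer"))

setValidity("LatentTrajectory", function(object) {
    if (ncol(object@x) != length(object@z))
        "x and z must cover the same number of frames"
    else if (length(object@z) && min(object@z) < 1L)
        "state labels must be >= 1"
    else TRUE
})

#' @rdname LatentTrajectory-class
#' @param x continuous latent matrix (D x T).
#' @param z discrete state vector (length T); defaults to state 1 throughout.
#' @export
LatentTrajectory <- function(x, z = NULL) {
    x <- as.matrix(x)
    if (is.null(z)) z <- rep(1L, ncol(x))
    new("LatentTrajectory", x = x, z = as.integer(z))
}

#' FitDiagnostics: convergence and validation summaries of an rSLDS fit
#'
#' @slot objective per-iteration objective trace (exact marginal
#'   log-likelihood for K = 1; a joint surrogate for K > 1).
#' @slot cvR2 cross-validated variance explained, percent (NA until computed).
#' @slot forwardSimR2 forward-simulation accuracy, percent (NA until computed).
#' @slot folds fold assignment used for cross-validation.
#' @slot converged whether the objective change fell below tolerance.
#' @export
setClass("FitDiagnostics",
    representation(objective = "numeric", cvR2 = "numeric",
                   forwardSimR2 = "numeric", folds = "integer",
                   converged = "logical"))

#' RSLDSFit: a fitted rSLDS model
#'
#' Returned by [fitRSLDS()]; bundles parameters, diagnostics and the
#' latent trajectory inferred on the training data.  Access with
#' [modelParams()], [diagnostics()], [latentFactors()] and [discreteStates()].
#' @slot params fitted [RSLDSParams-class].
#' @slot diagnostics a [FitDiagnostics-class].
#' @slot latents posterior [LatentTrajectory-class] on the training data.
#' @export
setClass("RSLDSFit",
    representation(params = "RSLDSParams", diagnostics = "FitDiagnostics",
                   latents = "LatentTrajectory"))

#' StimProtocol: a pulse-train photostimulation protocol
#'
#' @slot onsets,offsets pulse boundaries in seconds.
#' @slot pulseRate within-pulse stimulation rate, Hz.
#' @slot targets indices of targeted cells.
#' @slot gain laser-power proxy; latent drive per frame per unit emission
#'   weight.
#' @slot isi interstimulus interval (offset to next onset), seconds.
#' @slot exclusionRadius radius (um) around a target within which cells are
#'   excluded as putative followers (off-target conservatism).
#' @slot offTargetRadius radius (um) within which responses are attributed to
#'   direct light spillover (reporting only).
#' @export
setClass("StimProtocol",
    representation(onsets = "numeric", offsets = "numeric",
                   pulseRate = "numeric", targets = "integer",
                   gain = "numeric", isi = "numeric",
                   exclusionRadius = "numeric", offTargetRadius = "numeric"))

setValidity("StimProtocol", function(object) {
    msg <- NULL
    if (length(object@onsets) != length(object@offsets))
        msg <- c(msg, "onsets and offsets must have equal length")
    else {
        if (any(object@offsets < object@onsets))
            msg <- c(msg, "each offset must be >= its onset")
        n <- length(object@onsets)
        if (n > 1L && any(object@onsets[-1] < object@offsets[-n]))
            msg <- c(msg, "pulses must not overlap")
    }
    if (object@exclusionRadius < 0 || object@offTargetRadius < 0)
        msg <- c(msg, "radii must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticSession: a generated recording session with ground truth
#'
#' @slot activity a [CalciumActivity-class] (noisy observations).
#' @slot truth the generating [RSLDSParams-class].
#' @slot latents the generating [LatentTrajectory-class].
#' @slot bouts behaviour bout table: `start_s`, `stop_s`, `label`.
#' @slot positions cell position table: `cell_id`, `x_um`, `y_um`, `dim_label`.
#' @slot inputSchedule binary intruder-presence series (one entry per frame).
#' @slot seed integer seed the session was generated from.
#' @export
setClass("SyntheticSession",
    representation(activity = "CalciumActivity", truth = "RSLDSParams",
                   latents = "LatentTrajectory", bouts = "data.frame",
                   positions = "data.frame", inputSchedule = "numeric",
                   seed = "integer"))

setValidity("SyntheticSession", function(object) {
    msg <- NULL
    if (nrow(object@activity) != nrow(object@truth@C))
        msg <- c(msg, "activity rows must match emission matrix C")
    if (ncol(object@activity) != ncol(object@latents@x))
        msg <- c(msg, "latent trajectory must cover all frames")
    if (is.null(msg)) TRUE else msg
})

#' TimeConstantSet: eigenvalue time constants of a dynamics matrix
#'
#' @slot lambdaMod eigenvalue moduli (per frame).
#' @slot tauFrames time constants in frames, `|1 / log(|lambda|)|`.
#' @slot tauSeconds time constants in seconds (`tauFrames / frameRate`).
#' @slot frameRate Hz.
#' @slot state discrete-state id the dynamics matrix belongs to.
#' @slot flags per-dimension flag: "ok", "infinite" (|lambda| = 1), "zero"
#'   (|lambda| = 0) or "unstable" (|lambda| > 1).
#' @export
setClass("TimeConstantSet",
    representation(lambdaMod = "numeric", tauFrames = "numeric",
                   tauSeconds = "numeric", frameRate = "numeric",
                   state = "integer", flags = "character"))

#' AutocorrFunction: sample autocorrelation of a series
#'
#' @slot lags lags in frames (starting at 0).
#' @slot r autocorrelation values `c_k / c_0`.
#' @slot c biased (1/T) sample autocovariances `c_k`.
#' @slot c0 sample variance `c_0`.
#' @slot mean sample mean of the series.
#' @slot n series length T.
#' @export
setClass("AutocorrFunction",
    representation(lags = "integer", r = "numeric", c = "numeric",
                   c0 = "numeric", mean = "numeric", n = "integer"))

#' FlowField: latent-space velocity field of a fitted model
#'
#' @slot points grid points, n x 2.
#' @slot velocity one-frame displacement `A_k x + b_k + B_k u - x` at each
#'   point, n x 2.
#' @slot state most-probable discrete state at each point.
#' @slot inputLevel input level u the field was evaluated at.
#' @export
setClass("FlowField",
    representation(points = "matrix", velocity = "matrix",
                   state = "integer", inputLevel = "numeric"))

#' InfluenceMatrix: pairwise evoked-response scores
#'
#' Rows are targeted cells (unitary stimulation runs), columns all cells.
#' `scores[i, j]` is the average evoked z-scored activity of cell j in the
#' post-pulse ISI windows of the run targeting cell i; masked pairs (self,
#' within the exclusion radius) are NA.
#'
#' @slot scores targets x cells score matrix.
#' @slot mask logical matrix, TRUE where the pair is excluded.
#' @slot targets indices of the targeted cells (row order).
#' @slot groups per-cell dimension label ("x1", "x2" or "neither").
#' @export
setClass("InfluenceMatrix",
    representation(scores = "matrix", mask = "matrix",
                   targets = "integer", groups = "character"))

#' LIFNetworkConfig: parameters of the mechanistic spiking network
#'
#' Defaults follow the excitatory LIF integration-subnetwork model: N = 1000
#' neurons of which Np = 200 form the integration subnetwork, membrane time
#' constant 20 ms, spike threshold 0.1, recurrent gain 1, per-step membrane
#' noise N(0,1)/5, Euler step 1 ms, inhibitory time constant 50 ms.
#'
#' @slot N network size.
#' @slot Np subnetwork size.
#' @slot sigma subnetwork connection density (fraction in `[0,1]`).
#' @slot backgroundDensity connection density outside the subnetwork block.
#' @slot tauM membrane time constant, seconds.
#' @slot tauS synaptic conductance time constant, seconds.
#' @slot tauI inhibitory time constant, seconds.
#' @slot theta spike threshold.
#' @slot g recurrent gain.
#' @slot gInh inhibitory gain (0 = purely excitatory network).
#' @slot dt Euler integration step, seconds.
#' @slot noiseScale per-step additive membrane noise SD.
#' @export
setClass("LIFNetworkConfig",
    representation(N = "integer", Np = "integer", sigma = "numeric",
                   backgroundDensity = "numeric", tauM = "numeric",
                   tauS = "numeric", tauI = "numeric", theta = "numeric",
                   g = "numeric", gInh = "numeric", dt = "numeric",
                   noiseScale = "numeric"))

setValidity("LIFNetworkConfig", function(object) {
    msg <- NULL
    if (object@Np > object@N) msg <- c(msg, "Np must be <= N")
    if (object@sigma < 0 || object@sigma > 1 ||
        object@backgroundDensity < 0 || object@backgroundDensity > 1)
        msg <- c(msg, "densities must lie in [0, 1]")
    if (any(c(object@tauM, object@tauS, object@tauI, object@dt) <= 0))
        msg <- c(msg, "all time constants and dt must be > 0")
    if (object@dt >= min(object@tauM, object@tauI))
        msg <- c(msg, "dt must be smaller than min(tauM, tauI)")
    if (is.null(msg)) TRUE else msg
})

#' Construct an LIFNetworkConfig
#'
#' @param N,Np network and subnetwork sizes.
#' @param sigma subnetwork connection density.
#' @param backgroundDensity density outside the subnetwork (default 1%,
#'   keeping the background spectral contribution small so subnetwork
#'   dynamics dominate).
#' @param tauM,tauS,tauI membrane / synaptic / inhibitory time constants (s).
#' @param theta spike threshold.
#' @param g,gInh recurrent and inhibitory gains.
#' @param dt Euler step (s).
#' @param noiseScale per-step membrane noise SD (default 1/5).
#' @return An [LIFNetworkConfig-class] object.
#' @examples
#' cfg <- lifConfig(sigma = 0.1, tauS = 20)
#' @export
lifConfig <- function(N = 1000L, Np = 200L, sigma = 0.1,
                      backgroundDensity = 0.01, tauM = 0.02, tauS = 20,
                      tauI = 0.05, theta = 0.1, g = 1, gInh = 0,
                      dt = 0.001, noiseScale = 0.2) {
    new("LIFNetworkConfig", N = as.integer(N), Np = as.integer(Np),
        sigma = sigma, backgroundDensity = backgroundDensity, tauM = tauM,
        tauS = tauS, tauI = tauI, theta = theta, g = g, gInh = gInh,
        dt = dt, noiseScale = noiseScale)
}

#' WeightMatrix: synaptic weights with spectral summary
#'
#' @slot W sparse nonnegative N x N weight matrix (zero diagonal).
#' @slot subnet indices of the integration-subnetwork neurons.
#' @slot lambdaMax largest eigenvalue modulus (spectral radius).
#' @export
setClass("WeightMatrix",
    representation(W = "Matrix", subnet = "integer", lambdaMax = "numeric"))

#' NetworkSimResult: output of an LIF network simulation
#'
#' @slot spikes two-column matrix of stored spike events (neuron, step);
#'   may be truncated for runaway networks (see `truncated`).
#' @slot binned per-neuron spike counts in bins of `1/binRate` seconds.
#' @slot binRate binning rate of `binned`, Hz.
#' @slot popRate per-step fraction of neurons spiking.
#' @slot Iinh per-step inhibitory current.
#' @slot dt integration step, seconds.
#' @slot duration simulated duration, seconds.
#' @slot truncated TRUE if the stored spike list was capped.
#' @slot config the [LIFNetworkConfig-class] used.
#' @export
setClass("NetworkSimResult",
    representation(spikes = "matrix", binned = "matrix", binRate = "numeric",
                   popRate = "numeric", Iinh = "numeric", dt = "numeric",
                   duration = "numeric", truncated = "logical",
                   config = "LIFNetworkConfig"))

#' DecoderResult: a frame-wise or spatial decoder outcome
#'
#' @slot accuracy held-out accuracy, fraction in `[0, 1]`.
#' @slot threshold fitted 1-D decision threshold (NA for the spatial SVM).
#' @slot direction "above" if values above threshold are called positive.
#' @slot nullAccuracies accuracies of label-shuffled decoders.
#' @slot pValue permutation p-value of accuracy against the null.
#' @export
setClass("DecoderResult",
    representation(accuracy = "numeric", threshold = "numeric",
                   direction = "character", nullAccuracies = "numeric",
                   pValue = "numeric"))

#' MotionGLMResult: lagged motion-feature ridge regression
#'
#' @slot beta coefficient array, (features * lags + 1) x neurons, first row
#'   the intercept.
#' @slot cvR2 per-neuron cross-validated R2, percent.
#' @slot lambda ridge strength used.
#' @slot folds number of cross-validation folds.
#' @slot lagFrames number of lags (frames) per feature.
#' @slot nFeatures number of motion features.
#' @export
setClass("MotionGLMResult",
    representation(beta = "matrix", cvR2 = "numeric", lambda = "numeric",
                   folds = "integer", lagFrames = "integer",
                   nFeatures = "integer"))

# ------------------------------ show methods -------------------------------

setMethod("show", "CalciumActivity", function(object) {
    cat(sprintf("CalciumActivity: %d neurons x %d frames at %g Hz (%.1f s)\n",
                nrow(object), ncol(object), object@frameRate,
                ncol(object) / object@frameRate))
    if (length(object@baselineWindow))
        cat(sprintf("  baseline window: frames %d-%d\n",
                    object@baselineWindow[1], object@baselineWindow[2]))
})

setMethod("show", "RSLDSParams", function(object) {
    cat(sprintf("RSLDSParams: K = %d states, D = %d latents, N = %d neurons%s\n",
                object@K, object@D, nrow(object@C),
                if (length(object@B)) sprintf(", %d input(s)",
                                              ncol(object@B[[1]])) else ""))
})

setMethod("show", "RSLDSFit", function(object) {
    d <- object@diagnostics
    cat(sprintf("RSLDSFit: K = %d, D = %d; %d iterations, %s\n",
                object@params@K, object@params@D, length(d@objective),
                if (isTRUE(d@converged)) "converged" else "not converged"))
    if (length(d@objective))
        cat(sprintf("  final objective: %.2f\n", tail(d@objective, 1)))
    if (!is.na(d@cvR2)) cat(sprintf("  cvR2: %.1f%%\n", d@cvR2))
})

setMethod("show", "SyntheticSession", function(object) {
    cat(sprintf("SyntheticSession (seed %d): %d neurons x %d frames, %d bout(s)\n",
                object@seed, nrow(object@activity), ncol(object@activity),
                nrow(object@bouts)))
})

setMethod("show", "StimProtocol", function(object) {
    cat(sprintf("StimProtocol: %d pulse(s) at %g Hz, targets {%s}, gain %g\n",
                length(object@onsets), object@pulseRate,
                paste(object@targets, collapse = ","), object@gain))
})

setMethod("show", "WeightMatrix", function(object) {
    cat(sprintf("WeightMatrix: %d x %d, subnetwork %d, lambda_max = %.4f\n",
                nrow(object@W), ncol(object@W), length(object@subnet),
                object@lambdaMax))
})

setMethod("show", "NetworkSimResult", function(object) {
    cat(sprintf("NetworkSimResult: %d neurons, %.1f s at dt = %g s, %d stored spikes%s\n",
                nrow(object@binned), object@duration, object@dt,
                nrow(object@spikes),
                if (object@truncated) " (truncated)" else ""))
})

setMethod("show", "InfluenceMatrix", function(object) {
    cat(sprintf("InfluenceMatrix: %d target(s) x %d cells, %d masked pair(s)\n",
                nrow(object@scores), ncol(object@scores), sum(object@mask)))
})

setMethod("show", "DecoderResult", function(object) {
    cat(sprintf("DecoderResult: accuracy %.3f", object@accuracy))
    if (length(object@nullAccuracies))
        cat(sprintf(" (null mean %.3f, p = %.4g)",
                    mean(object@nullAccuracies), object@pValue))
    cat("\n")
})

setMethod("show", "TimeConstantSet", function(object) {
    cat(sprintf("TimeConstantSet (state %d): tau = %s s [%s]\n", object@state,
                paste(signif(object@tauSeconds, 4), collapse = ", "),
                paste(object@flags, collapse = ", ")))
})
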