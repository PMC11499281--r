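#' @include utils.R
NULL

#' Merge behaviour bouts separated by short gaps
#'
#' Same-label bouts separated by less than `gap` seconds are merged into
#' single "trials"; the result is sorted and non-overlapping per label.
#'
#' @param bouts data frame with `start_s`, `stop_s`, `label`.
#' @param gap merge gap, seconds (default 5).
#' @return A merged bout table.
#' @export
mergeBouts <- function(bouts, gap = 5) {
    stopifnot(all(c("start_s", "stop_s", "label") %in% names(bouts)))
    if (any(bouts$start_s >= bouts$stop_s))
        stop("each bout must satisfy start < stop")
    out <- list()
    for (lab in unique(bouts$label)) {
        b <- bouts[bouts$label == lab, , drop = FALSE]
        b <- b[order(b$start_s), , drop = FALSE]
        cur <- b[1, , drop = FALSE]
        for (i in seq_len(nrow(b))[-1]) {
            if (b$start_s[i] - cur$stop_s < gap) {
                cur$stop_s <- max(cur$stop_s, b$stop_s[i])
            } else {
                out[[length(out) + 1L]] <- cur
                cur <- b[i, , drop = FALSE]
            }
        }
        out[[length(out) + 1L]] <- cur
    }
    res <- do.call(rbind, out)
    res[order(res$start_s), , drop = FALSE]
}

# Per-frame class labels (TRUE inside positive-label bouts) at a frame rate.
.frameLabels <- function(bouts, positiveLabel, T, frameRate) {
    pos <- rep(FALSE, T)
    b <- bouts[bouts$label == positiveLabel, , drop = FALSE]
    for (i in seq_len(nrow(b))) {
        a <- max(1L, .seconds2frames(b$start_s[i], frameRate))
        z <- min(T, .seconds2frames(b$stop_s[i], frameRate) - 1L)
        if (a <= z) pos[a:z] <- TRUE
    }
    pos
}

# Exhaustive 1-D threshold maximizing balanced accuracy -- the
# maximal-margin separator for one dimension, fully deterministic.
.fitThreshold <- function(x, y) {
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    npos <- sum(ys); nneg <- length(ys) - npos
    cumPos <- cumsum(ys)
    cumNeg <- cumsum(!ys)
    # candidate cut after position i: below = 1..i, above = rest
    accAbove <- ((npos - cumPos) / npos + cumNeg / nneg) / 2
    accBelow <- (cumPos / npos + (nneg - cumNeg) / nneg) / 2
    iA <- which.max(accAbove)
    iB <- which.max(accBelow)
    if (accAbove[iA] >= accBelow[iB]) {
        thr <- if (iA < length(xs)) (xs[iA] + xs[iA + 1]) / 2 else xs[iA]
        list(threshold = thr, direction = "above", acc = accAbove[iA])
    } else {
        thr <- if (iB < length(xs)) (xs[iB] + xs[iB + 1]) / 2 else xs[iB]
        list(threshold = thr, direction = "below", acc = accBelow[iB])
    }
}

.applyThreshold <- function(x, thr, direction)
    if (direction == "above") x > thr else x <= thr

# Balance classes by seeded random undersampling of the majority class.
.balanceFrames <- function(idx, pos, seed) {
    ip <- idx[pos[idx]]; im <- idx[!pos[idx]]
    if (!length(ip) || !length(im)) return(integer(0))
    set.seed(seed)
    n <- min(length(ip), length(im))
    c(sample(ip, n), sample(im, n))
}

.decodeCore <- function(signal, bouts, positiveLabel, frameRate, seed) {
    T <- length(signal)
    merged <- mergeBouts(bouts)
    pos <- .frameLabels(merged, positiveLabel, T, frameRate)
    if (!any(pos) || all(pos))
        stop("both classes must be present after merging")
    # trials: one per merged positive bout; frames are assigned to the
    # nearest trial (boundaries at midpoints between consecutive bouts)
    pb <- merged[merged$label == positiveLabel, , drop = FALSE]
    centers <- .seconds2frames((pb$start_s + pb$stop_s) / 2, frameRate)
    trial <- vapply(seq_len(T), function(t) which.min(abs(centers - t)), 0L)
    nTrial <- nrow(pb)
    accs <- numeric(nTrial)
    for (tr in seq_len(nTrial)) {
        trainIdx <- .balanceFrames(which(trial != tr), pos,
                                   .substream(seed, paste0("bal", tr)))
        testIdx <- .balanceFrames(which(trial == tr), pos,
                                  .substream(seed, paste0("test", tr)))
        if (!length(trainIdx) || !length(testIdx)) { accs[tr] <- NA; next }
        f <- .fitThreshold(signal[trainIdx], pos[trainIdx])
        pred <- .applyThreshold(signal[testIdx], f$threshold, f$direction)
        accs[tr] <- mean(pred == pos[testIdx])
    }
    allIdx <- .balanceFrames(seq_len(T), pos, .substream(seed, "balAll"))
    fAll <- .fitThreshold(signal[allIdx], pos[allIdx])
    list(accuracy = mean(accs, na.rm = TRUE), threshold = fAll$threshold,
         direction = fAll$direction)
}

#' Frame-wise behaviour decoder on the integration dimension
#'
#' Merges bouts separated by less than 5 s into trials, balances frames
#' across the two classes by seeded undersampling, and fits a 1-D
#' maximal-margin threshold on the integration-dimension signal (exhaustive
#' balanced-accuracy search, the deterministic equivalent of a linear SVM
#' in one dimension).  Accuracy is the leave-one-trial-out average of
#' held-out frame accuracy.
#'
#' @param signal normalized integration-dimension series.
#' @param bouts behaviour bout table (`start_s`, `stop_s`, `label`).
#' @param positiveLabel the bout label decoded against all other frames
#'   (default "attack").
#' @param frameRate Hz.
#' @param seed seed for the balancing subsamples.
#' @return A [DecoderResult-class] (no null distribution; see
#'   [shuffleNull()]).
#' @export
framewiseAttackDecoder <- function(signal, bouts, positiveLabel = "attack",
                                   frameRate = 10, seed = 0) {
    res <- .decodeCore(as.numeric(signal), bouts, positiveLabel, frameRate,
                       seed)
    new("DecoderResult", accuracy = res$accuracy, threshold = res$threshold,
        direction = res$direction, nullAccuracies = numeric(0),
        pValue = NA_real_)
}

#' Apply a trained threshold decoder to a second condition
#'
#' Freezes the threshold and direction of a trained [DecoderResult-class]
#' and reports balanced-frame accuracy on a new signal/bout pair.
#'
#' @param trained a [DecoderResult-class] from [framewiseAttackDecoder()].
#' @param signal the second-condition series.
#' @param bouts the second-condition bout table.
#' @param positiveLabel positive bout label.
#' @param frameRate Hz.
#' @param seed balancing seed.
#' @return Accuracy (fraction).
#' @export
crossConditionDecode <- function(trained, signal, bouts,
                                 positiveLabel = "attack", frameRate = 10,
                                 seed = 0) {
    signal <- as.numeric(signal)
    merged <- mergeBouts(bouts)
    pos <- .frameLabels(merged, positiveLabel, length(signal), frameRate)
    idx <- .balanceFrames(seq_along(signal), pos, .substream(seed, "xcond"))
    if (!length(idx)) stop("both classes must be present")
    pred <- .applyThreshold(signal[idx], trained@threshold,
                            trained@direction)
    mean(pred == pos[idx])
}

#' Shuffle null for the frame-wise decoder
#'
#' Randomly reassigns the bout labels across bouts and refits the threshold
#' decoder for each shuffle, giving the null distribution of accuracies.
#'
#' @inheritParams framewiseAttackDecoder
#' @param nShuffles number of label shuffles (default 1000).
#' @return Numeric vector of null accuracies (length `nShuffles`).
#' @export
shuffleNull <- function(signal, bouts, nShuffles = 1000,
                        positiveLabel = "attack", frameRate = 10, seed = 0) {
    stopifnot(nShuffles >= 1)
    signal <- as.numeric(signal)
    out <- numeric(nShuffles)
    for (s in seq_len(nShuffles)) {
        set.seed(.substream(seed, paste0("shuf", s)))
        shuffled <- bouts
        shuffled$label <- sample(bouts$label)
        out[s] <- tryCatch(
            .decodeCore(signal, shuffled, positiveLabel, frameRate,
                        .substream(seed, paste0("dec", s)))$accuracy,
            error = function(e) NA_real_)
    }
    out
}

#' Attach a shuffle null and permutation p-value to a decoder result
#'
#' @param result a [DecoderResult-class].
#' @param nulls numeric vector from [shuffleNull()].
#' @return The updated [DecoderResult-class].
#' @export
attachNull <- function(result, nulls) {
    nulls <- nulls[!is.na(nulls)]
    result@nullAccuracies <- nulls
    result@pValue <- (1 + sum(nulls >= result@accuracy)) / (1 + length(nulls))
    result
}

#' Spatial-cluster decoder of dimension labels from cell positions
#'
#' A linear support vector machine separating the (x, y) positions of x1
#' and x2 cells, scored by 5-fold cross-validation; the null is the mean
#' cross-validated accuracy over `nShuffles` label shuffles.
#'
#' @param positions cell position table with `x_um`, `y_um`, `dim_label`.
#' @param nShuffles number of label shuffles (default 20).
#' @param seed RNG seed (fold assignment and shuffles).
#' @return A [DecoderResult-class] (threshold is NA; the classifier is
#'   two-dimensional).
#' @export
spatialClusterDecoder <- function(positions, nShuffles = 20, seed = 0) {
    keep <- positions$dim_label %in% c("x1", "x2")
    df <- positions[keep, , drop = FALSE]
    lab <- factor(df$dim_label)
    if (nlevels(droplevels(lab)) < 2)
        stop("both x1 and x2 labels must be present")
    X <- as.matrix(df[, c("x_um", "y_um")])
    cvAcc <- function(labels, sd) {
        set.seed(sd)
        if (length(unique(as.matrix(X))) <= 2) {  # degenerate positions
            return(max(table(labels)) / length(labels))
        }
        fit <- e1071::svm(X, labels, kernel = "linear", cross = 5,
                          scale = FALSE)
        fit$tot.accuracy / 100
    }
    acc <- cvAcc(lab, .substream(seed, "cv"))
    nulls <- vapply(seq_len(nShuffles), function(s) {
        set.seed(.substream(seed, paste0("perm", s)))
        cvAcc(sample(lab), .substream(seed, paste0("permcv", s)))
    }, 0)
    new("DecoderResult", accuracy = acc, threshold = NA_real_,
        direction = "above", nullAccuracies = nulls,
        pValue = (1 + sum(nulls >= acc)) / (1 + length(nulls)))
}

# Lagged design matrix: frames (rows) x (features * (lagFrames + 1)).
.laggedDesign <- function(features, lagFrames) {
    Tn <- ncol(features)
    nd <- nrow(features)
    rows <- (lagFrames + 1):Tn
    X <- matrix(0, length(rows), nd * (lagFrames + 1))
    for (l in 0:lagFrames)
        X[, l * nd + seq_len(nd)] <- t(features[, rows - l, drop = FALSE])
    X
}

#' Lagged motion-feature GLM with ridge regularization
#'
#' Predicts each neuron's activity from motion features at lags 0..`lagS`
#' seconds (a per-neuron behaviour filter), fit by ridge regression with
#' contiguous k-fold cross-validation.  The ridge strength is selected by
#' inner cross-validation on the training folds (via `glmnet`) unless
#' supplied.
#'
#' @param y neuron activity: vector or neurons x frames matrix.
#' @param features motion-feature matrix, features x frames.
#' @param lagS filter length, seconds (default 10).
#' @param folds number of contiguous cross-validation folds (default 10).
#' @param frameRate Hz.
#' @param lambda optional fixed ridge strength.
#' @param seed RNG seed.
#' @return A [MotionGLMResult-class]; `cvR2` holds per-neuron held-out
#'   variance explained, percent.
#' @export
motionGLM <- function(y, features, lagS = 10, folds = 10, frameRate = 10,
                      lambda = NULL, seed = 0) {
    Y <- if (is.null(dim(y))) matrix(y, 1) else as.matrix(y)
    Tn <- ncol(Y)
    stopifnot(ncol(features) == Tn)
    lagFrames <- as.integer(round(lagS * frameRate))
    if (lagFrames + folds >= Tn) stop("lag window too long for the series")
    X <- .laggedDesign(features, lagFrames)
    Yl <- Y[, (lagFrames + 1):Tn, drop = FALSE]
    n <- nrow(X)
    bounds <- floor(seq(0, n, length.out = folds + 1))
    nNeur <- nrow(Yl)
    cvr2 <- numeric(nNeur)
    lamUsed <- numeric(nNeur)
    beta <- matrix(0, ncol(X) + 1, nNeur)
    set.seed(seed)
    for (j in seq_len(nNeur)) {
        yv <- Yl[j, ]
        pred <- numeric(n)
        lamFold <- numeric(folds)
        for (f in seq_len(folds)) {
            test <- (bounds[f] + 1):bounds[f + 1]
            train <- setdiff(seq_len(n), test)
            if (is.null(lambda)) {
                cvfit <- glmnet::cv.glmnet(X[train, , drop = FALSE],
                                           yv[train], alpha = 0, nfolds = 5)
                lamFold[f] <- cvfit$lambda.min
                pred[test] <- predict(cvfit, X[test, , drop = FALSE],
                                      s = "lambda.min")
            } else {
                fit <- glmnet::glmnet(X[train, , drop = FALSE], yv[train],
                                      alpha = 0, lambda = lambda)
                lamFold[f] <- lambda
                pred[test] <- predict(fit, X[test, , drop = FALSE])
            }
        }
        cvr2[j] <- 100 * .r2(yv, pred)
        lamUsed[j] <- mean(lamFold)
        fitAll <- glmnet::glmnet(X, yv, alpha = 0, lambda = lamUsed[j])
        beta[, j] <- as.numeric(coef(fitAll))
    }
    new("MotionGLMResult", beta = beta, cvR2 = cvr2,
        lambda = mean(lamUsed), folds = as.integer(folds),
        lagFrames = lagFrames, nFeatures = nrow(features))
}
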