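#' @include rslds-fit.R
NULL

#' Per-neuron emission weights on each latent dimension
#'
#' The columns of the emission matrix C define the latent dimensions; each
#' neuron's absolute weight per column measures its contribution to that
#' dimension.  A neuron is assigned to the dimension of its largest absolute
#' weight, or to "neither" when all its weights fall below `minWeight`.
#'
#' @param params an [RSLDSParams-class] (or [RSLDSFit-class]).
#' @param minWeight absolute-weight floor below which a neuron is assigned
#'   to no dimension (default 1e-8).
#' @return A data frame with `neuron`, one `w_x<d>` column of absolute
#'   weights per latent dimension, `assigned` ("x1", "x2", ... or
#'   "neither") and per-dimension rank columns `rank_x<d>`.
#' @export
dimensionWeights <- function(params, minWeight = 1e-8) {
    if (is(params, "RSLDSFit")) params <- params@params
    W <- abs(params@C)
    D <- ncol(W)
    dimNames <- paste0("x", seq_len(D))
    assigned <- dimNames[max.col(W, ties.method = "first")]
    assigned[apply(W, 1, max) < minWeight] <- "neither"
    out <- data.frame(neuron = seq_len(nrow(W)))
    for (dd in seq_len(D)) {
        out[[paste0("w_", dimNames[dd])]] <- W[, dd]
        out[[paste0("rank_", dimNames[dd])]] <- rank(-W[, dd],
                                                     ties.method = "first")
    }
    out$assigned <- assigned
    out
}

#' Select the top-weight neurons for a latent dimension
#'
#' Returns the indices of the `k` neurons with the largest absolute emission
#' weight on the requested dimension; ties are broken toward the lower
#' neuron index (stable).
#'
#' @param weights a weight table from [dimensionWeights()], or an
#'   [RSLDSParams-class]/[RSLDSFit-class] from which one is computed.
#' @param dim dimension id: an integer or a name such as "x1".
#' @param k number of neurons to select (default 5, as in concurrent
#'   five-cell targeting).
#' @return Integer vector of `k` neuron indices, ordered by decreasing
#'   weight.
#' @export
selectTopNeurons <- function(weights, dim = 1, k = 5) {
    if (!is.data.frame(weights)) weights <- dimensionWeights(weights)
    if (is.numeric(dim)) dim <- paste0("x", dim)
    col <- paste0("w_", dim)
    if (!col %in% names(weights)) stop("unknown dimension: ", dim)
    if (k > nrow(weights)) stop("k exceeds the number of neurons")
    ord <- order(-weights[[col]], weights$neuron)
    weights$neuron[ord[seq_len(k)]]
}

#' Principal angle between the two emission-dimension subspaces
#'
#' For a two-column emission matrix, the angle between the two columns in
#' degrees, folded into `[0, 90]`.  Near-orthogonal columns justify
#' assigning neurons to dimensions by their emission weights.
#'
#' @param C an emission matrix with two nonzero columns (or an
#'   [RSLDSParams-class]/[RSLDSFit-class]).
#' @return Angle in degrees.
#' @examples
#' subspaceAngle(cbind(c(1, 0), c(1, 1)))  # 45
#' @export
subspaceAngle <- function(C) {
    if (is(C, "RSLDSFit")) C <- C@params@C
    if (is(C, "RSLDSParams")) C <- C@C
    C <- as.matrix(C)
    if (ncol(C) != 2) stop("subspaceAngle requires exactly two dimensions")
    n1 <- sqrt(sum(C[, 1]^2)); n2 <- sqrt(sum(C[, 2]^2))
    if (n1 == 0 || n2 == 0) stop("emission columns must be nonzero")
    ct <- abs(sum(C[, 1] * C[, 2])) / (n1 * n2)
    acos(min(max(ct, 0), 1)) * 180 / pi
}
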