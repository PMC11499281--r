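#' @include AllClasses.R
NULL

#' Save / load rSLDS parameters as JSON
#'
#' Serializes the full parameter set (dynamics, transition, emission and
#' prior terms) to a single JSON file and restores it losslessly.
#'
#' @param params an [RSLDSParams-class].
#' @param path file path.
#' @return `loadRSLDSParams` returns the restored [RSLDSParams-class];
#'   `saveRSLDSParams` returns `path` invisibly.
#' @export
saveRSLDSParams <- function(params, path) {
    stopifnot(is(params, "RSLDSParams"))
    # every matrix is stored as a column-major vector; shapes are implied
    # by K, D, N and (for inputs) U
    flat <- function(lst) lapply(lst, function(m) as.numeric(m))
    obj <- list(K = params@K, D = params@D, N = nrow(params@C),
                U = if (length(params@B)) ncol(params@B[[1]]) else 0L,
                A = flat(params@A), b = flat(params@b), Q = flat(params@Q),
                Rw = flat(params@Rw), rv = flat(params@rv),
                C = as.numeric(params@C), d = params@d, S = params@S,
                B = flat(params@B), x0 = params@x0,
                P0 = as.numeric(params@P0))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
    invisible(path)
}

#' @rdname saveRSLDSParams
#' @export
loadRSLDSParams <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    D <- as.integer(o$D); K <- as.integer(o$K)
    N <- as.integer(o$N); U <- as.integer(o$U)
    asList <- function(x) if (is.list(x)) x else
        lapply(seq_len(nrow(x)), function(i) x[i, ])   # simplified to matrix
    mats <- function(x, d1, d2)
        lapply(asList(x), function(v) matrix(as.numeric(v), d1, d2))
    vecs <- function(x) lapply(asList(x), as.numeric)
    new(Class = "RSLDSParams", K = K, D = D,
        A = mats(o$A, D, D), b = vecs(o$b), Q = mats(o$Q, D, D),
        Rw = mats(o$Rw, K, D), rv = vecs(o$rv),
        C = matrix(as.numeric(o$C), N, D), d = as.numeric(o$d),
        S = as.numeric(o$S),
        B = if (U > 0L) mats(o$B, D, U) else list(),
        x0 = as.numeric(o$x0), P0 = matrix(as.numeric(o$P0), D, D))
}

#' Save / load a synthetic session as plain-text files
#'
#' Writes a directory of CSV/JSON files: `activity.csv` (neurons x frames),
#' `latents.csv`, `states.csv`, `bouts.csv`, `positions.csv`,
#' `input_schedule.csv`, `params.json` and `meta.json`.
#'
#' @param session a [SyntheticSession-class].
#' @param dir output directory (created if needed).
#' @return `loadSession` returns the restored [SyntheticSession-class];
#'   `saveSession` returns `dir` invisibly.
#' @export
saveSession <- function(session, dir) {
    stopifnot(is(session, "SyntheticSession"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(activityMatrix(session),
              file.path(dir, "activity.csv"), row.names = FALSE)
    write.csv(session@latents@x, file.path(dir, "latents.csv"),
              row.names = FALSE)
    write.csv(data.frame(state = session@latents@z),
              file.path(dir, "states.csv"), row.names = FALSE)
    write.csv(session@bouts, file.path(dir, "bouts.csv"), row.names = FALSE)
    write.csv(session@positions, file.path(dir, "positions.csv"),
              row.names = FALSE)
    write.csv(data.frame(input = session@inputSchedule),
              file.path(dir, "input_schedule.csv"), row.names = FALSE)
    saveRSLDSParams(session@truth, file.path(dir, "params.json"))
    jsonlite::write_json(list(frameRate = frameRate(session),
                              seed = session@seed),
                         file.path(dir, "meta.json"), auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname saveSession
#' @export
loadSession <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    Y <- as.matrix(read.csv(file.path(dir, "activity.csv")))
    x <- as.matrix(read.csv(file.path(dir, "latents.csv")))
    z <- read.csv(file.path(dir, "states.csv"))$state
    bouts <- read.csv(file.path(dir, "bouts.csv"),
                      stringsAsFactors = FALSE)
    positions <- read.csv(file.path(dir, "positions.csv"),
                          stringsAsFactors = FALSE)
    sched <- read.csv(file.path(dir, "input_schedule.csv"))$input
    truth <- loadRSLDSParams(file.path(dir, "params.json"))
    dimnames(Y) <- NULL
    dimnames(x) <- NULL
    activity <- CalciumActivity(Y, frameRate = meta$frameRate,
                                positions = positions[, c("x_um", "y_um",
                                                          "dim_label")])
    new("SyntheticSession", activity = activity, truth = truth,
        latents = LatentTrajectory(x, z), bouts = bouts,
        positions = positions, inputSchedule = as.numeric(sched),
        seed = as.integer(meta$seed))
}
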