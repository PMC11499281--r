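# Shared fixtures, built lazily and cached for the test session.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, builder(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

# A small one-state linear dynamical system with known taus.
simpleLDSParams <- function(N = 20, lam = c(0.98, 0.85), noise = 0.1,
                            seed = 42) {
    set.seed(seed)
    C <- matrix(rnorm(N * 2), N, 2)
    RSLDSParams(A = diag(lam), C = C,
                Q = diag(1 - lam^2), S = rep(noise, N))
}

# Two-state planted model with steep position-gated transitions: state 1
# holds a fixed point at the origin, state 2 at (3, 0); the gate switches
# near x1 = 1.5.  Dynamics eigenvalues are shared across states, so the
# planted per-dimension taus are unambiguous.
gatedTwoStateParams <- function(N = 50, slowTauS = 5, fastTauS = 0.5,
                                frameRate = 10, noise = 0.04, seed = 500) {
    lamS <- exp(-1 / (slowTauS * frameRate))
    lamF <- exp(-1 / (fastTauS * frameRate))
    A <- diag(c(lamS, lamF))
    set.seed(seed)
    n1 <- floor(N / 2)
    C <- matrix(0, N, 2)
    C[seq_len(n1), 1] <- runif(n1, 0.8, 1.2)
    C[(n1 + 1):N, 2] <- runif(N - n1, 0.8, 1.2)
    RSLDSParams(A = list(A, A), C = C,
                Q = diag(c(1 - lamS^2, 1 - lamF^2)),
                b = list(c(0, 0), c(3 * (1 - lamS), 0)),
                Rw = matrix(c(0, 0, 20, 0), 2, 2, byrow = TRUE),
                rv = c(0, -30), S = rep(noise, N), K = 2)
}

# Default line-attractor session (100 s / 1 s planted taus).
defaultSession <- function() fixture("defaultSession", function()
    generateLineAttractorSession(nNeurons = 40, nFrames = 1500, seed = 1))

# Flat-input session used by the stimulation tests.
stimSession <- function() fixture("stimSession", function()
    generateLineAttractorSession(nNeurons = 60, nFrames = 1200,
                                 inputSchedule = rep(0, 1200), seed = 5))

# Session with a 10 s integrator and five intruder epochs: per-frame
# attack decoding is genuinely possible here (the slow latent decays
# between epochs), unlike under the 100 s default.
decodableSession <- function() fixture("decodableSession", function() {
    T <- 6000
    sched <- numeric(T)
    for (a in c(0.08, 0.26, 0.44, 0.62, 0.80))
        sched[(a * T):(a * T + 0.10 * T)] <- 1
    generateLineAttractorSession(nNeurons = 40, nFrames = T,
                                 slowTauS = 10, fastTauS = 0.5,
                                 inputSchedule = sched, seed = 9)
})

expect_rel_equal <- function(actual, expected, tol) {
    expect_lt(abs(actual - expected) / abs(expected), tol)
}
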