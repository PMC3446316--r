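## Run expr with a private RNG stream: set the given seed, evaluate, then
## restore the caller's .Random.seed so package functions never perturb the
## user's random sequence.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
        stop("seed must be a single finite integer", call. = FALSE)
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic sub-seed derivation so each simulated component (manifest,
## arrays, controls, ...) has an independent reproducible stream. Kept below
## 2^31 - 1.
subSeed <- function(seed, k) {
    (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
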