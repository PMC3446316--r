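## Small in-code fixtures and the independent naive reference implementation
## used as the oracle for the normalization path.

## Manifest with every design x body-CpG stratum populated.
tinyManifest <- function(n = 60, seed = 11) {
    withr::with_seed(seed, {
        design <- rep(c("I", "II"), length.out = n)
        cnt <- integer(n)
        cnt[design == "I"] <- rep(1:3, length.out = sum(design == "I"))
        cnt[design == "II"] <- rep(1:3, length.out = sum(design == "II"))
        data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
                   design_type = design, body_cpg_count = cnt,
                   chromosome = sample(c(paste0("chr", 1:5), "chrX", "chrY"),
                                       n, TRUE),
                   position = sample.int(1e6, n),
                   island = sample(c(TRUE, FALSE), n, TRUE))
    })
}

## Random-intensity dataset over a manifest; design I brighter so the
## negative-extrapolation path is reachable.
randomDataset <- function(manifest, nSamples = 2, seed = 21,
                          nControls = 20) {
    n <- nrow(manifest)
    withr::with_seed(seed, {
        scale <- ifelse(manifest$design_type == "I", 8, 7)
        sampleIds <- paste0("S", seq_len(nSamples))
        meth <- matrix(rlnorm(n * nSamples, scale, 0.6), n,
                       dimnames = list(manifest$probe_id, sampleIds))
        unmeth <- matrix(rlnorm(n * nSamples, scale, 0.6), n,
                         dimnames = list(manifest$probe_id, sampleIds))
        nc <- function() matrix(rlnorm(nControls * nSamples, 4.5, 0.3),
                                nControls, dimnames = list(NULL, sampleIds))
        MethylArraySet(manifest, meth, unmeth, nc(), nc())
    })
}

## A SwanSubset built by hand (bypassing the random draw) from explicit
## per-stratum probe ids.
handSubset <- function(strata, seed = 0L) {
    N <- length(strata[[1]])
    methods::new("SwanSubset", strata = strata, N = as.integer(N),
                 seed = as.integer(seed))
}

## ---- naive reference implementation: explicit loops, no vectorization ----

## binary search for the knot interval, then straight-line interpolation;
## displacement rules outside the subset range
naiveInterpolate <- function(x, xs, a) {
    K <- length(xs)
    if (x > xs[K]) return(a[K] + (x - xs[K]))
    if (x < xs[1]) return(a[1] - (xs[1] - x))
    lo <- 1; hi <- K
    while (hi - lo > 1) {
        mid <- (lo + hi) %/% 2
        if (xs[mid] <= x) lo <- mid else hi <- mid
    }
    if (xs[hi] == xs[lo]) return((a[lo] + a[hi]) / 2)
    a[lo] + (a[hi] - a[lo]) * (x - xs[lo]) / (xs[hi] - xs[lo])
}

naiveSwanNormalize <- function(ds, subset) {
    man <- probeManifest(ds)
    out <- list(Meth = getMeth(ds), Unmeth = getUnmeth(ds))
    for (ch in c("Meth", "Unmeth")) {
        for (j in seq_len(ncol(ds))) {
            x <- out[[ch]][, j]
            names(x) <- man$probe_id
            sorted <- list()
            for (d in c("I", "II")) {
                ids <- subsetProbes(subset, d)
                ord <- order(x[ids], ids)   # stable tie-break by probe id
                sorted[[d]] <- list(ids = ids[ord], x = unname(x[ids][ord]))
            }
            a <- numeric(length(sorted$I$x))
            for (k in seq_along(a))
                a[k] <- (sorted$I$x[k] + sorted$II$x[k]) / 2
            xn <- x
            for (d in c("I", "II")) {
                for (k in seq_along(a)) xn[sorted[[d]]$ids[k]] <- a[k]
                rest <- setdiff(man$probe_id[man$design_type == d],
                                sorted[[d]]$ids)
                for (id in rest)
                    xn[id] <- naiveInterpolate(x[id], sorted[[d]]$x, a)
            }
            for (id in man$probe_id) {
                if (xn[id] <= 0)
                    xn[id] <- median(negControls(ds, ch)[, j])
            }
            out[[ch]][, j] <- unname(xn[man$probe_id])
        }
    }
    out
}
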