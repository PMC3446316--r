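#' Select the stratum-balanced normalization subset
#'
#' Randomly draws N probes from each of the six strata formed by crossing the
#' two probe designs with a body-CpG count of 1, 2 and 3, where N is the
#' minimum stratum size. The resulting 3N probes per design define the
#' "biologically similar" pool whose quantiles are averaged during
#' normalization.
#'
#' @param manifest data.frame probe manifest (see [MethylArraySet()]).
#' @param seed integer; the draw is deterministic given the seed and the
#'   caller's RNG state is left untouched.
#' @param eligibleCounts integer vector of body-CpG counts defining the
#'   strata. The default 1:3 reflects the observation that both designs are
#'   well represented at one to three body CpGs; probes with other counts are
#'   never subset candidates but are still normalized by interpolation.
#' @return A \linkS4class{SwanSubset}.
#' @export
selectSubset <- function(manifest, seed, eligibleCounts = 1:3) {
    manifest <- as.data.frame(manifest)
    strata <- list()
    for (d in c("I", "II")) for (cc in eligibleCounts) {
        ids <- manifest$probe_id[manifest$design_type == d &
                                 manifest$body_cpg_count == cc]
        if (length(ids) == 0)
            stop(sprintf("empty subset stratum (%s, %d): no design-%s probes with %d body CpGs",
                         d, cc, d, cc), call. = FALSE)
        strata[[paste(d, cc, sep = ".")]] <- ids
    }
    N <- min(vapply(strata, length, integer(1)))
    drawn <- withSeed(seed, lapply(strata, function(ids)
        ids[sample.int(length(ids), N)]))
    new("SwanSubset", strata = drawn, N = as.integer(N),
        seed = as.integer(seed))
}

#' Build the quantile map for one design
#'
#' For one channel of one sample, sorts the 3N subset intensities of each
#' design and pairs the requested design's sorted intensities with the
#' averaged targets: target k is the mean of the k-th smallest design-I and
#' design-II subset intensity (the standard quantile step restricted to the
#' subset).
#'
#' @param intensities named numeric vector of one channel's intensities for
#'   one sample, covering at least all subset probes.
#' @param subset a \linkS4class{SwanSubset}.
#' @param design \code{"I"} or \code{"II"}: which design's map to return.
#' @return A \linkS4class{QuantileMap}. The \code{target} slot is identical
#'   whichever design is requested.
#' @export
buildQuantileMap <- function(intensities, subset, design = c("I", "II")) {
    design <- match.arg(design)
    idsI <- subsetProbes(subset, "I")
    idsII <- subsetProbes(subset, "II")
    missing <- setdiff(c(idsI, idsII), names(intensities))
    if (length(missing) > 0)
        stop(sprintf("subset probe(s) absent from intensity vector: %s%s",
                     paste(utils::head(missing, 3), collapse = ", "),
                     if (length(missing) > 3) ", ..." else ""), call. = FALSE)
    sortedI <- sort(intensities[idsI], method = "radix")
    sortedII <- sort(intensities[idsII], method = "radix")
    target <- (sortedI + sortedII) / 2
    new("QuantileMap",
        xSub = unname(if (design == "I") sortedI else sortedII),
        target = unname(target), design = design)
}

#' Map intensities through a quantile map
#'
#' Intensities inside the subset range are piecewise-linearly interpolated
#' through the (subset intensity, target) pairs. Outside the range the
#' displacement rules apply: a probe exceeding the subset maximum by d is
#' assigned the maximum target plus d, and a probe below the subset minimum
#' by d is assigned the minimum target minus d.
#'
#' Tied subset intensities are collapsed to a single interpolation knot whose
#' target is the mean of their targets, so the interpolant is a function and
#' within-design monotonicity is preserved.
#'
#' @param x numeric vector of intensities to normalize.
#' @param qmap a \linkS4class{QuantileMap}.
#' @return numeric vector of normalized intensities, same length as \code{x}.
#' @export
interpolateIntensity <- function(x, qmap) {
    xs <- qmap@xSub
    tg <- qmap@target
    if (anyDuplicated(xs)) {
        tg <- as.numeric(tapply(tg, xs, mean))
        xs <- sort(unique(qmap@xSub))
    }
    lo <- min(qmap@xSub); hi <- max(qmap@xSub)
    tlo <- min(qmap@target); thi <- max(qmap@target)
    out <- numeric(length(x))
    inside <- x >= lo & x <= hi
    if (any(inside)) {
        if (length(xs) == 1) out[inside] <- tg  # degenerate: single knot
        else out[inside] <- stats::approx(xs, tg, xout = x[inside],
                                          ties = "ordered")$y
    }
    out[x > hi] <- thi + (x[x > hi] - hi)
    out[x < lo] <- tlo - (lo - x[x < lo])
    out
}

## One channel of one sample: assign subset probes their averaged target at
## their within-design rank (ties broken stably by probe id), interpolate
## everything else per design.
.swanChannelSample <- function(x, manifest, subset) {
    out <- x
    idsByDesign <- list(I = subsetProbes(subset, "I"),
                        II = subsetProbes(subset, "II"))
    sorted <- lapply(idsByDesign, function(ids) {
        ord <- order(x[ids], ids, method = "radix")
        list(ids = ids[ord], x = unname(x[ids][ord]))
    })
    target <- (sorted$I$x + sorted$II$x) / 2
    for (d in c("I", "II")) {
        qmap <- new("QuantileMap", xSub = sorted[[d]]$x, target = target,
                    design = d)
        out[sorted[[d]]$ids] <- target
        rest <- manifest$probe_id[manifest$design_type == d]
        rest <- setdiff(rest, idsByDesign[[d]])
        if (length(rest) > 0)
            out[rest] <- interpolateIntensity(x[rest], qmap)
    }
    out
}

#' Subset-quantile within-array normalization
#'
#' Equalizes the intensity distributions of the two probe designs within each
#' array. For each sample, the methylated and unmethylated channels are
#' processed fully independently: the 3N-probe subset of each design is
#' sorted by increasing intensity and every rank is assigned the mean of the
#' two designs' intensities at that rank; all remaining probes are then
#' mapped onto the averaged subset distribution by linear interpolation
#' (with linear displacement beyond the subset range). Any resulting
#' intensity at or below zero is replaced by the median of that sample's
#' negative-control intensities for that channel.
#'
#' @param object a \linkS4class{MethylArraySet}.
#' @param seed integer seed for the random subset draw (ignored when
#'   \code{subset} is supplied).
#' @param subset optional pre-drawn \linkS4class{SwanSubset}; one subset is
#'   shared across all samples so between-array comparisons use a common
#'   reference frame.
#' @param perArraySubset logical; draw an independent subset per array
#'   (sub-seeded from \code{seed}) instead of sharing one.
#' @return A \linkS4class{SwanMethylArraySet} with the same manifest, sample
#'   set and negative controls, normalized intensities, and provenance (seed
#'   and per-sample substitution counts).
#' @export
swanNormalize <- function(object, seed = 1L, subset = NULL,
                          perArraySubset = FALSE) {
    stopifnot(is(object, "MethylArraySet"))
    manifest <- probeManifest(object)
    if (is.null(subset) && !perArraySubset)
        subset <- selectSubset(manifest, seed)
    if (!is.null(subset)) {
        miss <- setdiff(c(subsetProbes(subset, "I"), subsetProbes(subset, "II")),
                        manifest$probe_id)
        if (length(miss) > 0)
            stop("subset contains probes absent from the dataset's manifest",
                 call. = FALSE)
        seed <- subset@seed
    }
    nS <- ncol(object)
    subs <- matrix(0L, 2, nS, dimnames = list(c("Meth", "Unmeth"),
                                              colnames(object)))
    assays <- list(Meth = getMeth(object), Unmeth = getUnmeth(object))
    for (j in seq_len(nS)) {
        subj <- if (perArraySubset)
            selectSubset(manifest, subSeed(seed, j)) else subset
        for (ch in c("Meth", "Unmeth")) {
            x <- assays[[ch]][, j]
            names(x) <- manifest$probe_id
            xn <- .swanChannelSample(x, manifest, subj)
            bad <- xn <= 0
            if (any(bad)) {
                xn[bad] <- stats::median(negControls(object, ch)[, j])
                subs[ch, j] <- sum(bad)
            }
            assays[[ch]][, j] <- unname(xn[manifest$probe_id])
        }
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(manifest,
                                       row.names = manifest$probe_id))
    out <- new("SwanMethylArraySet", se,
               negMeth = object@negMeth, negUnmeth = object@negUnmeth,
               swanSeed = as.integer(seed), substitutions = subs)
    S4Vectors::metadata(out)$swan <- list(
        seed = as.integer(seed),
        perArraySubset = perArraySubset,
        N = if (!is.null(subset)) subsetSize(subset) else NA_integer_,
        substitutions = sum(subs))
    out
}
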