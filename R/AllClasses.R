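#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.MANIFEST_COLS <- c("probe_id", "design_type", "body_cpg_count",
                    "chromosome", "position")

## Shared invariant checks, usable both by the S4 validity method and by
## validateDataset() on raw components (which reports instead of stopping).
.manifestViolations <- function(manifest) {
    v <- character(0)
    missing <- setdiff(.MANIFEST_COLS, colnames(manifest))
    if (length(missing) > 0)
        return(sprintf("manifest missing column(s): %s",
                       paste(missing, collapse = ", ")))
    if (anyDuplicated(manifest$probe_id))
        v <- c(v, "duplicate probe_id values in manifest")
    bad <- which(!manifest$design_type %in% c("I", "II"))
    if (length(bad) > 0)
        v <- c(v, sprintf("design_type outside {I, II} at row(s) %s",
                          paste(utils::head(bad, 5), collapse = ", ")))
    cc <- manifest$body_cpg_count
    if (!is.numeric(cc) || any(!is.finite(cc)) || any(cc < 0) ||
        any(cc != round(cc)))
        v <- c(v, "body_cpg_count must be finite non-negative integers")
    pos <- manifest$position
    if (!is.numeric(pos) || any(!is.finite(pos)) || any(pos < 1))
        v <- c(v, "position must be positive (1-based)")
    v
}

.datasetViolations <- function(manifest, meth, unmeth, negMeth, negUnmeth) {
    v <- .manifestViolations(manifest)
    if (!identical(dim(meth), dim(unmeth)))
        v <- c(v, "meth and unmeth shapes differ")
    if (nrow(meth) != nrow(manifest))
        v <- c(v, "row misalignment: intensity rows != manifest rows")
    if (!identical(colnames(meth), colnames(unmeth)))
        v <- c(v, "sample columns differ between meth and unmeth")
    if (anyDuplicated(colnames(meth)))
        v <- c(v, "duplicate sample ids")
    for (nm in c("meth", "unmeth", "negMeth", "negUnmeth")) {
        m <- switch(nm, meth = meth, unmeth = unmeth,
                    negMeth = negMeth, negUnmeth = negUnmeth)
        if (any(!is.finite(m)))
            v <- c(v, sprintf("non-finite intensity in %s", nm))
        else if (any(m < 0))
            v <- c(v, sprintf("negative intensity in %s", nm))
    }
    if (nrow(negMeth) < 1 || nrow(negUnmeth) < 1)
        v <- c(v, "negative-control matrices need >= 1 row")
    if (ncol(negMeth) != ncol(meth) || ncol(negUnmeth) != ncol(meth))
        v <- c(v, "negative-control sample columns != intensity sample columns")
    v
}

#' Dual-design methylation array container
#'
#' An extension of \linkS4class{SummarizedExperiment} holding the methylated
#' (\code{"Meth"}) and unmethylated (\code{"Unmeth"}) intensity matrices of a
#' dual-design (Infinium I/II) methylation array, the probe manifest as
#' \code{rowData}, and the negative-control intensities for both channels as
#' dedicated slots. Negative controls have their own probe set, so they live
#' beside the main assays rather than inside them.
#'
#' @slot negMeth,negUnmeth numeric matrices (controls x samples) of
#'   negative-control intensities for the methylated and unmethylated channel.
#'
#' @seealso [MethylArraySet()] for construction, [swanNormalize()] for
#'   normalization.
#' @export
setClass("MethylArraySet",
    contains = "SummarizedExperiment",
    representation(negMeth = "matrix", negUnmeth = "matrix"))

setValidity("MethylArraySet", function(object) {
    v <- .datasetViolations(
        manifest  = as.data.frame(SummarizedExperiment::rowData(object)),
        meth      = SummarizedExperiment::assay(object, "Meth"),
        unmeth    = SummarizedExperiment::assay(object, "Unmeth"),
        negMeth   = object@negMeth,
        negUnmeth = object@negUnmeth)
    if (length(v) == 0) TRUE else v
})

#' Normalized dual-design methylation array
#'
#' A \linkS4class{MethylArraySet} produced by [swanNormalize()]. Carries
#' provenance (the subset seed and the per-sample count of intensities that
#' were substituted by the negative-control median) and additionally requires
#' every intensity to be strictly positive.
#'
#' @slot swanSeed integer seed used for subset selection.
#' @slot substitutions integer matrix (2 x samples, rows \code{Meth}/
#'   \code{Unmeth}) counting negative-control median substitutions.
#' @export
setClass("SwanMethylArraySet",
    contains = "MethylArraySet",
    representation(swanSeed = "integer", substitutions = "matrix"))

setValidity("SwanMethylArraySet", function(object) {
    v <- character(0)
    if (any(SummarizedExperiment::assay(object, "Meth") <= 0) ||
        any(SummarizedExperiment::assay(object, "Unmeth") <= 0))
        v <- c(v, "normalized intensities must be strictly positive")
    if (!identical(rownames(object@substitutions), c("Meth", "Unmeth")))
        v <- c(v, "substitutions must have rows Meth, Unmeth")
    if (length(v) == 0) TRUE else v
})

#' Stratified probe subset for within-array normalization
#'
#' The randomly drawn, stratum-balanced probe subset on which the average
#' quantile distribution is computed: N probes from each of the six strata
#' (design I/II crossed with 1, 2 or 3 CpGs in the probe body), giving 3N
#' probes per design.
#'
#' @slot strata named list of six character vectors of probe ids, named
#'   \code{"I.1"}, \code{"I.2"}, \code{"I.3"}, \code{"II.1"}, \code{"II.2"},
#'   \code{"II.3"}.
#' @slot N integer, probes drawn per stratum (the minimum stratum size).
#' @slot seed integer seed the draw was made with.
#' @export
setClass("SwanSubset",
    representation(strata = "list", N = "integer", seed = "integer"))

setValidity("SwanSubset", function(object) {
    v <- character(0)
    nms <- names(object@strata)
    des <- sub("\\..*$", "", nms)
    cnt <- sub("^[^.]*\\.", "", nms)
    if (is.null(nms) || !all(des %in% c("I", "II")) ||
        !setequal(cnt[des == "I"], cnt[des == "II"]))
        v <- c(v, "strata must be named <design>.<count> with the same counts for both designs")
    else {
        n <- vapply(object@strata, length, integer(1))
        if (any(n != object@N))
            v <- c(v, "every stratum must hold exactly N probe ids")
        for (d in c("I", "II")) {
            ids <- unlist(object@strata[des == d], use.names = FALSE)
            if (anyDuplicated(ids))
                v <- c(v, sprintf("duplicate probe ids within design %s", d))
        }
    }
    if (object@N < 1) v <- c(v, "N must be positive")
    if (length(v) == 0) TRUE else v
})

#' Quantile map for one design, channel and sample
#'
#' The ascending pairing between a design's sorted subset intensities and the
#' averaged target quantiles shared by both designs: target k is the mean of
#' the k-th smallest design-I and design-II subset intensity.
#'
#' @slot xSub numeric, the design's subset intensities sorted ascending
#'   (length 3N).
#' @slot target numeric, the averaged target intensities (length 3N,
#'   non-decreasing; identical for both designs of one channel/sample).
#' @slot design character, \code{"I"} or \code{"II"}.
#' @export
setClass("QuantileMap",
    representation(xSub = "numeric", target = "numeric", design = "character"))

setValidity("QuantileMap", function(object) {
    v <- character(0)
    if (length(object@xSub) != length(object@target))
        v <- c(v, "xSub and target must have equal length")
    if (is.unsorted(object@xSub))
        v <- c(v, "xSub must be sorted ascending")
    if (is.unsorted(object@target))
        v <- c(v, "target must be non-decreasing")
    if (!object@design %in% c("I", "II"))
        v <- c(v, "design must be I or II")
    if (length(v) == 0) TRUE else v
})
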