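#' Construct a MethylArraySet
#'
#' Bundles a probe manifest, methylated/unmethylated intensity matrices and
#' negative-control intensities into a validated container.
#'
#' @param manifest data.frame with columns \code{probe_id},
#'   \code{design_type} (\code{"I"}/\code{"II"}), \code{body_cpg_count},
#'   \code{chromosome}, \code{position} and optionally \code{island}.
#' @param meth,unmeth numeric matrices (probes x samples) of methylated and
#'   unmethylated intensities, rows aligned to \code{manifest}, identical
#'   column (sample) names.
#' @param negMeth,negUnmeth numeric matrices (controls x samples) of
#'   negative-control intensities per channel.
#' @return A \linkS4class{MethylArraySet}.
#' @examples
#' man <- data.frame(probe_id = paste0("cg", 1:4),
#'                   design_type = c("I", "I", "II", "II"),
#'                   body_cpg_count = c(2, 3, 1, 1),
#'                   chromosome = "chr1", position = 1:4 * 100L)
#' m <- matrix(1000, 4, 2, dimnames = list(man$probe_id, c("S1", "S2")))
#' nc <- matrix(100, 10, 2, dimnames = list(NULL, c("S1", "S2")))
#' MethylArraySet(man, m, m / 2, nc, nc)
#' @export
MethylArraySet <- function(manifest, meth, unmeth, negMeth, negUnmeth) {
    manifest <- as.data.frame(manifest)
    meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
    negMeth <- as.matrix(negMeth); negUnmeth <- as.matrix(negUnmeth)
    v <- .datasetViolations(manifest, meth, unmeth, negMeth, negUnmeth)
    if (length(v) > 0)
        stop("invalid methylation dataset:\n  - ",
             paste(v, collapse = "\n  - "), call. = FALSE)
    rownames(meth) <- rownames(unmeth) <- manifest$probe_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(Meth = meth, Unmeth = unmeth),
        rowData = S4Vectors::DataFrame(manifest, row.names = manifest$probe_id))
    new("MethylArraySet", se, negMeth = negMeth, negUnmeth = negUnmeth)
}

#' Validate a methylation dataset and report violations
#'
#' Checks the container invariants (manifest schema and uniqueness, matrix
#' alignment, finite non-negative intensities, presence of negative controls)
#' and returns an itemized report instead of stopping, so malformed raw
#' components can be inspected.
#'
#' @param object a \linkS4class{MethylArraySet}, or a manifest data.frame when
#'   raw components are supplied.
#' @param meth,unmeth,negMeth,negUnmeth raw matrices, only when \code{object}
#'   is a manifest data.frame.
#' @return list with \code{valid} (logical) and \code{violations}
#'   (character vector, empty when valid).
#' @export
validateDataset <- function(object, meth = NULL, unmeth = NULL,
                            negMeth = NULL, negUnmeth = NULL) {
    if (is(object, "MethylArraySet")) {
        v <- .datasetViolations(probeManifest(object),
                                getMeth(object), getUnmeth(object),
                                object@negMeth, object@negUnmeth)
    } else {
        v <- .datasetViolations(as.data.frame(object), as.matrix(meth),
                                as.matrix(unmeth), as.matrix(negMeth),
                                as.matrix(negUnmeth))
    }
    list(valid = length(v) == 0, violations = v)
}

#' @describeIn MethylArraySet-accessors methylated-channel intensity matrix
#' @export
getMeth <- function(object) SummarizedExperiment::assay(object, "Meth")

#' @describeIn MethylArraySet-accessors unmethylated-channel intensity matrix
#' @export
getUnmeth <- function(object) SummarizedExperiment::assay(object, "Unmeth")

#' Accessors for MethylArraySet
#'
#' @param object a \linkS4class{MethylArraySet}.
#' @param channel \code{"Meth"} or \code{"Unmeth"}.
#' @name MethylArraySet-accessors
#' @return matrices, data.frames or character vectors as named.
NULL

#' @describeIn MethylArraySet-accessors probe manifest as a data.frame
#' @export
probeManifest <- function(object)
    as.data.frame(SummarizedExperiment::rowData(object))

#' @describeIn MethylArraySet-accessors per-probe design type ("I"/"II")
#' @export
designType <- function(object)
    SummarizedExperiment::rowData(object)$design_type

#' @describeIn MethylArraySet-accessors per-probe body CpG count
#' @export
bodyCpGCount <- function(object)
    SummarizedExperiment::rowData(object)$body_cpg_count

#' @describeIn MethylArraySet-accessors negative-control matrix for a channel
#' @export
negControls <- function(object, channel = c("Meth", "Unmeth")) {
    channel <- match.arg(channel)
    if (channel == "Meth") object@negMeth else object@negUnmeth
}

#' @describeIn MethylArraySet-accessors sample identifiers
#' @export
sampleIds <- function(object) colnames(object)

setMethod("show", "MethylArraySet", function(object) {
    cat(sprintf("%s: %d probes x %d samples\n", class(object),
                nrow(object), ncol(object)))
    tab <- table(designType(object))
    cat(sprintf("  design I: %d, design II: %d; negative controls: %d (Meth), %d (Unmeth)\n",
                sum(designType(object) == "I"), sum(designType(object) == "II"),
                nrow(object@negMeth), nrow(object@negUnmeth)))
    cat("  samples:", paste(utils::head(colnames(object), 6), collapse = ", "),
        if (ncol(object) > 6) "..." else "", "\n")
    invisible(tab)
})

setMethod("show", "SwanMethylArraySet", function(object) {
    callNextMethod()
    cat(sprintf("  normalized (subset seed %d); %d intensities set to the negative-control median\n",
                object@swanSeed, sum(object@substitutions)))
})

#' @describeIn SwanMethylArraySet-accessors subset seed recorded at
#'   normalization time
#' @export
swanSeed <- function(object) object@swanSeed

#' Accessors for SwanMethylArraySet provenance
#' @param object a \linkS4class{SwanMethylArraySet}.
#' @name SwanMethylArraySet-accessors
NULL

#' @describeIn SwanMethylArraySet-accessors 2 x samples matrix counting
#'   negative-control median substitutions per channel
#' @export
substitutionCounts <- function(object) object@substitutions

setMethod("show", "SwanSubset", function(object) {
    cat(sprintf("SwanSubset: N = %d per stratum (3N = %d per design), seed = %d\n",
                object@N, 3L * object@N, object@seed))
    invisible(NULL)
})

#' @describeIn SwanSubset-accessors probe ids of one design's pooled subset
#' @param design \code{"I"} or \code{"II"}.
#' @export
subsetProbes <- function(object, design = c("I", "II")) {
    design <- match.arg(design)
    keep <- sub("\\..*$", "", names(object@strata)) == design
    unlist(object@strata[keep], use.names = FALSE)
}

#' Accessors for SwanSubset
#' @param object a \linkS4class{SwanSubset}.
#' @name SwanSubset-accessors
NULL

#' @describeIn SwanSubset-accessors probes drawn per stratum
#' @export
subsetSize <- function(object) object@N
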