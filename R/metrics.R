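#' Beta values
#'
#' Proportion of total signal from the methylated channel,
#' beta = Meth / (Unmeth + Meth + offset). With the default offset of 0 the
#' formula is the classic definition; entries where Meth + Unmeth = 0 are
#' then undefined and returned as \code{NA} (excluded downstream). A positive
#' offset (100 is conventional) stabilizes low-intensity probes.
#'
#' @param object a \linkS4class{MethylArraySet}.
#' @param offset non-negative real added to the denominator.
#' @return numeric matrix (probes x samples) in \[0, 1\] with attribute
#'   \code{"offset"}.
#' @export
getBeta <- function(object, offset = 0) {
    if (!is.numeric(offset) || length(offset) != 1 || offset < 0)
        stop("offset must be a single non-negative number", call. = FALSE)
    m <- getMeth(object); u <- getUnmeth(object)
    den <- m + u + offset
    beta <- m / den
    beta[den == 0] <- NA_real_
    attr(beta, "offset") <- offset
    beta
}

#' M-values
#'
#' log2 ratio of methylated to unmethylated intensity,
#' log2((Meth + epsilon) / (Unmeth + epsilon)). The epsilon guard (default 1
#' intensity unit) keeps the value finite at zero intensities; the plain
#' log2(Meth/Unmeth) is recovered as epsilon tends to 0.
#'
#' @param object a \linkS4class{MethylArraySet}.
#' @param epsilon positive real guard added to both intensities.
#' @return numeric matrix (probes x samples) with attribute \code{"epsilon"}.
#' @export
getMvalues <- function(object, epsilon = 1) {
    if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
        stop("epsilon must be a single positive number", call. = FALSE)
    mv <- log2((getMeth(object) + epsilon) / (getUnmeth(object) + epsilon))
    attr(mv, "epsilon") <- epsilon
    mv
}

#' Locate the unmethylated and methylated density peaks
#'
#' Estimates a Gaussian kernel density of the beta values on a regular grid
#' over \[0, 1\] and reports the grid argmax on each side of 0.5: \code{pU}
#' restricted to \[0, 0.5) (the unmethylated peak) and \code{pM} restricted
#' to (0.5, 1\] (the methylated peak). If no beta values fall on one side of
#' 0.5, that peak is reported as \code{NA} rather than fabricated.
#'
#' @param beta numeric vector of beta values in \[0, 1\] (NAs dropped).
#' @param gridStep grid spacing over \[0, 1\] (default 0.001).
#' @param bandwidth kernel bandwidth; \code{NULL} for Silverman's
#'   rule-of-thumb (\code{\link[stats]{bw.nrd0}}).
#' @return list with \code{pU}, \code{pM}, \code{bandwidth}, \code{gridStep}.
#' @export
findPeaks <- function(beta, gridStep = 0.001, bandwidth = NULL) {
    beta <- beta[!is.na(beta)]
    if (length(beta) < 100)
        stop("need >= 100 defined beta values for a meaningful density",
             call. = FALSE)
    if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(beta)
    n <- round(1 / gridStep) + 1
    d <- stats::density(beta, bw = bandwidth, from = 0, to = 1, n = n)
    below <- d$x < 0.5
    above <- d$x > 0.5
    pU <- if (any(beta < 0.5)) d$x[below][which.max(d$y[below])] else NA_real_
    pM <- if (any(beta > 0.5)) d$x[above][which.max(d$y[above])] else NA_real_
    list(pU = pU, pM = pM, bandwidth = bandwidth, gridStep = gridStep)
}

#' Peak-position offset between the two probe designs
#'
#' Computes, for one sample, the position of the unmethylated (beta < 0.5)
#' and methylated (beta > 0.5) density peaks separately for design-I and
#' design-II probes and returns the absolute differences
#' \code{dPU = |pU_I - pU_II|} and \code{dPM = |pM_I - pM_II|}. Large values
#' diagnose the design-II compression artifact; normalization should shrink
#' them.
#'
#' @param beta beta matrix from [getBeta()] (or a \linkS4class{MethylArraySet},
#'   in which case betas are computed at offset 0).
#' @param manifest probe manifest aligned to the rows of \code{beta}; taken
#'   from the object when one is supplied.
#' @param sample sample id or column index.
#' @param ... passed to [findPeaks()].
#' @return data.frame with one row: peak positions per design, \code{dPU},
#'   \code{dPM}, bandwidths and grid step used.
#' @export
deltaP <- function(beta, manifest = NULL, sample = 1, ...) {
    if (is(beta, "MethylArraySet")) {
        manifest <- probeManifest(beta)
        beta <- getBeta(beta)
    }
    manifest <- as.data.frame(manifest)
    if (nrow(manifest) != nrow(beta))
        stop("manifest and beta matrix are misaligned", call. = FALSE)
    b <- beta[, sample]
    pI <- findPeaks(b[manifest$design_type == "I"], ...)
    pII <- findPeaks(b[manifest$design_type == "II"], ...)
    data.frame(sample = if (is.character(sample)) sample else
                   colnames(beta)[sample] %||% as.character(sample),
               pU_I = pI$pU, pM_I = pI$pM, pU_II = pII$pU, pM_II = pII$pM,
               dPU = abs(pI$pU - pII$pU), dPM = abs(pI$pM - pII$pM),
               bw_I = pI$bandwidth, bw_II = pII$bandwidth,
               gridStep = pI$gridStep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agreement between technical replicates
#'
#' Compares two probe-aligned beta (or M-value) vectors with the two-sample
#' Kolmogorov-Smirnov test on their distributions (larger p = more similar
#' distributions) and the Pearson correlation of the paired values.
#'
#' @param a,b equal-length, probe-aligned numeric vectors; pairs with an NA
#'   are dropped.
#' @return list with \code{ks_statistic}, \code{ks_pvalue}, \code{pearson_r},
#'   and \code{n} pairs used.
#' @export
replicateAgreement <- function(a, b) {
    if (length(a) != length(b))
        stop("replicate vectors must be probe-aligned with equal length",
             call. = FALSE)
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    ks <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    list(ks_statistic = unname(ks$statistic), ks_pvalue = ks$p.value,
         pearson_r = stats::cor(a, b), n = length(a))
}
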