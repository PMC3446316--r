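#' Detection p-values from negative-control probes
#'
#' Per sample, a normal background model for total signal is fit from the
#' negative controls: mean = median(neg Meth) + median(neg Unmeth), sd =
#' MAD(neg Meth) + MAD(neg Unmeth) (MADs scaled to the sd of a normal). The
#' detection p-value of a probe is the upper-tail probability of its observed
#' Meth + Unmeth under that background, so probes indistinguishable from
#' background get large p.
#'
#' @param object a \linkS4class{MethylArraySet} with at least 10 negative
#'   controls per channel.
#' @return numeric matrix (probes x samples) of p-values in \[0, 1\], with
#'   attribute \code{"background"}: a data.frame of per-sample (mu, sigma).
#' @export
detectionPValues <- function(object) {
    nm <- negControls(object, "Meth"); nu <- negControls(object, "Unmeth")
    if (nrow(nm) < 10 || nrow(nu) < 10)
        stop("background not estimable: need >= 10 negative controls per channel",
             call. = FALSE)
    total <- getMeth(object) + getUnmeth(object)
    mu <- apply(nm, 2, stats::median) + apply(nu, 2, stats::median)
    sigma <- apply(nm, 2, stats::mad) + apply(nu, 2, stats::mad)
    p <- total
    for (j in seq_len(ncol(total)))
        p[, j] <- stats::pnorm(total[, j], mean = mu[j], sd = sigma[j],
                               lower.tail = FALSE)
    attr(p, "background") <- data.frame(sample = colnames(total),
                                        mu = mu, sigma = sigma,
                                        row.names = NULL)
    p
}

#' Filter undetected probes and unwanted chromosomes
#'
#' Removes every probe whose detection p-value exceeds the threshold in one
#' or more samples, then probes on the listed chromosomes (case-insensitive
#' label match; sex chromosomes by default, as mixed-sex designs confound
#' them).
#'
#' @param object a \linkS4class{MethylArraySet}.
#' @param detP detection p-value matrix from [detectionPValues()]; computed
#'   internally when \code{NULL}.
#' @param threshold detection p-value cutoff (default 0.01).
#' @param dropChromosomes character vector of chromosome labels to remove.
#' @return The filtered object. \code{metadata(x)$filter} records the number
#'   of probes removed by each rule (the two rules commute; counts are
#'   reported against the full probe set).
#' @export
filterProbes <- function(object, detP = NULL, threshold = 0.01,
                         dropChromosomes = c("chrX", "chrY")) {
    if (is.null(detP)) detP <- detectionPValues(object)
    if (nrow(detP) != nrow(object))
        stop("detection p-value matrix is misaligned with the dataset",
             call. = FALSE)
    man <- probeManifest(object)
    failDet <- rowSums(detP > threshold) >= 1
    onDrop <- tolower(man$chromosome) %in% tolower(dropChromosomes)
    keep <- !failDet & !onDrop
    out <- object[keep, ]
    S4Vectors::metadata(out)$filter <- list(
        detection_removed = sum(failDet),
        chromosome_removed = sum(onDrop),
        removed = sum(!keep), kept = sum(keep),
        threshold = threshold, dropped_chromosomes = dropChromosomes)
    out
}

#' Empirical-Bayes variance shrinkage
#'
#' Squeezes per-probe sample variances toward a common prior value by
#' treating each s^2 as s0^2 times an F(d, d0) variable and estimating
#' (d0, s0^2) by moment matching on log s^2: the excess variance of log s^2
#' over trigamma(d/2) identifies trigamma(d0/2), solved by monotone
#' Newton root-finding, and the mean identifies s0^2. Posterior variances are
#' the usual precision-weighted means (d0 s0^2 + d s^2) / (d0 + d). When the
#' log-variances are underdispersed relative to chi-square sampling noise the
#' prior df is infinite and every posterior variance equals s0^2.
#'
#' @param s2 numeric vector of per-probe sample variances (>= 50 values).
#' @param df residual degrees of freedom of each variance (scalar or vector).
#' @return list with \code{d0} (prior df, possibly \code{Inf}), \code{s02}
#'   (prior variance), \code{postVar} (posterior variances, same length as
#'   \code{s2}) and \code{df}.
#' @export
squeezeVariances <- function(s2, df) {
    if (length(s2) < 50)
        stop("need >= 50 variances to estimate the prior", call. = FALSE)
    if (any(df < 1)) stop("residual df must be >= 1", call. = FALSE)
    df <- rep_len(df, length(s2))
    pos <- s2 > 0
    if (stats::var(s2) == 0) {             # all variances identical
        return(list(d0 = Inf, s02 = s2[1], postVar = s2, df = df))
    }
    ## moment matching on z = log s^2 (probes with s^2 = 0 are excluded from
    ## the fit but still shrunk)
    z <- log(s2[pos])
    dz <- df[pos]
    e <- z - digamma(dz / 2) + log(dz / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dz / 2))
    if (evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- exp(emean)
    }
    postVar <- if (is.infinite(d0)) rep(s02, length(s2)) else
        (d0 * s02 + df * s2) / (d0 + df)
    list(d0 = d0, s02 = s02, postVar = postVar, df = df)
}

#' Posterior variance for given prior parameters
#'
#' The precision-weighted posterior mean (d0 s0^2 + df s^2) / (d0 + df),
#' exposed so the limiting behavior (d0 = 0 returns the sample variances,
#' d0 = Inf returns the prior) can be used and checked directly.
#'
#' @param s2 sample variances; @param df residual df; @param d0 prior df
#'   (may be \code{Inf}); @param s02 prior variance.
#' @return numeric vector of posterior variances.
#' @export
posteriorVariance <- function(s2, df, d0, s02) {
    if (is.infinite(d0)) return(rep(s02, length(s2)))
    (d0 * s02 + df * s2) / (d0 + df)
}

## Newton iteration for trigamma^{-1}(x); trigamma is monotone decreasing on
## (0, Inf). Update in 1/y space for stability (Newton on 1/trigamma is
## nearly linear).
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (abs(dif) / y < 1e-8) break
    }
    y
}

#' Two-group differential methylation by moderated F-test
#'
#' For each probe, an F statistic comparing two sample groups on the M-value
#' scale: between-group mean square over the pooled within-group variance,
#' with the denominator replaced by the empirical-Bayes posterior variance
#' when shrinkage is on (recommended for small sample sizes). P-values come
#' from the F distribution with (1, d0 + d) df under shrinkage and (1, d)
#' otherwise; q-values are Benjamini-Hochberg adjusted. Without shrinkage
#' the statistic is exactly the squared pooled two-sample t statistic.
#'
#' @param mvalues M-value matrix (probes x samples), or a
#'   \linkS4class{MethylArraySet} (M-values and beta differences are then
#'   computed internally).
#' @param groups two-level factor (or coercible) over the samples, >= 2
#'   samples per group.
#' @param shrink logical; squeeze the per-probe variances (default TRUE).
#' @param betas optional beta matrix aligned to \code{mvalues} used to report
#'   the group beta difference; computed at offset 0 when an object is given.
#' @return data.frame, one row per probe, ordered by p-value: group mean
#'   M-values, \code{delta_beta} (group 2 minus group 1, NA when betas are
#'   unavailable), \code{F}, \code{p}, \code{q}.
#' @export
dmpFinder <- function(mvalues, groups, shrink = TRUE, betas = NULL) {
    if (is(mvalues, "MethylArraySet")) {
        if (is.null(betas)) betas <- getBeta(mvalues)
        mvalues <- getMvalues(mvalues)
    }
    groups <- factor(groups)
    if (nlevels(groups) != 2)
        stop("groups must have exactly two levels", call. = FALSE)
    if (any(table(groups) < 2))
        stop("each group needs >= 2 samples", call. = FALSE)
    if (length(groups) != ncol(mvalues))
        stop("groups length must match the number of samples", call. = FALSE)
    g1 <- groups == levels(groups)[1]
    n1 <- sum(g1); n2 <- sum(!g1)
    m1 <- rowMeans(mvalues[, g1, drop = FALSE])
    m2 <- rowMeans(mvalues[, !g1, drop = FALSE])
    ss1 <- rowSums((mvalues[, g1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((mvalues[, !g1, drop = FALSE] - m2)^2)
    d <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / d
    msb <- (m1 - m2)^2 / (1 / n1 + 1 / n2)   # between-group mean square, 1 df
    if (shrink) {
        sq <- squeezeVariances(s2, d)
        denom <- sq$postVar
        dfDen <- if (is.infinite(sq$d0)) Inf else sq$d0 + d
    } else {
        denom <- s2
        dfDen <- d
    }
    Fstat <- ifelse(denom > 0, msb / denom, ifelse(msb > 0, Inf, 0))
    Fstat[msb == 0] <- 0                      # constant probes: no signal
    p <- stats::pf(Fstat, 1, dfDen, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    db <- if (is.null(betas)) rep(NA_real_, nrow(mvalues)) else
        rowMeans(betas[, !g1, drop = FALSE]) -
        rowMeans(betas[, g1, drop = FALSE])
    res <- data.frame(probe_id = rownames(mvalues) %||%
                          as.character(seq_len(nrow(mvalues))),
                      mean_m_group1 = m1, mean_m_group2 = m2,
                      delta_beta = db, F = Fstat, p = p, q = q,
                      row.names = NULL)
    res[order(res$p, -res$F), , drop = FALSE]
}

#' Evaluate a differential-methylation ranking against a truth table
#'
#' Labels each truth locus positive when the absolute reference beta
#' difference exceeds \code{posCut} and negative when below \code{negCut}
#' (loci in between are unlabeled and ignored). Reports the percentage of
#' positives recovered at each q-value threshold, and a ROC curve obtained by
#' sweeping the p-value ranking over the labeled loci with trapezoidal AUC.
#'
#' @param result data.frame from [dmpFinder()].
#' @param truth data.frame with columns \code{probe_id},
#'   \code{ref_beta_group1}, \code{ref_beta_group2}.
#' @param qThresholds q-value grid for the true-positive percentages.
#' @param posCut,negCut labeling cutoffs on |reference beta difference|
#'   (defaults 0.25 and 0.05).
#' @return list with \code{labels} (per shared locus), \code{tp_pct}
#'   (data.frame threshold/percent), \code{roc} (data.frame fpr/tpr),
#'   \code{auc}, and label counts.
#' @export
evaluateAgainstTruth <- function(result, truth,
                                 qThresholds = c(0.01, 0.05, 0.1, 0.2),
                                 posCut = 0.25, negCut = 0.05) {
    truth <- as.data.frame(truth)
    shared <- intersect(result$probe_id, truth$probe_id)
    if (length(shared) == 0)
        stop("result and truth share no locus keys", call. = FALSE)
    res <- result[match(shared, result$probe_id), ]
    tr <- truth[match(shared, truth$probe_id), ]
    dref <- abs(tr$ref_beta_group2 - tr$ref_beta_group1)
    label <- ifelse(dref > posCut, "positive",
                    ifelse(dref < negCut, "negative", "unlabeled"))
    nPos <- sum(label == "positive"); nNeg <- sum(label == "negative")
    if (nPos == 0) stop("no labeled positives in the truth set", call. = FALSE)
    tp_pct <- data.frame(
        q_threshold = qThresholds,
        tp_percent = vapply(qThresholds, function(th)
            100 * sum(res$q < th & label == "positive") / nPos, numeric(1)))
    ## ROC by sweeping the p-value ranking over labeled loci
    lab <- label != "unlabeled"
    ord <- order(res$p[lab], -res$F[lab])
    isPos <- (label[lab] == "positive")[ord]
    tpr <- c(0, cumsum(isPos) / nPos)
    fpr <- c(0, cumsum(!isPos) / max(nNeg, 1))
    auc <- if (nNeg > 0) sum(diff(fpr) * (utils::head(tpr, -1) +
                                          utils::tail(tpr, -1)) / 2)
           else NA_real_
    list(labels = data.frame(probe_id = shared, label = label,
                             ref_delta_beta = dref),
         tp_pct = tp_pct, roc = data.frame(fpr = fpr, tpr = tpr),
         auc = auc, n_positive = nPos, n_negative = nNeg)
}
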