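#' Simulation configuration for synthetic dual-design arrays
#'
#' Assembles and validates the parameters of the array simulator with
#' defaults chosen to mirror the qualitative structure of a real dual-design
#' methylation BeadChip: design I enriched for CpG-dense (island) probes and
#' hence higher body-CpG counts, bimodal methylation conditional on island
#' status, design- and channel-specific log-normal intensity scales, a
#' multiplicative compression of the design-II methylated fraction toward
#' 0.5, per-array technical jitter, and a normal negative-control background.
#'
#' @param nProbes total probes (default 20000).
#' @param typeIFraction fraction of probes with design I (default 0.28).
#' @param countPropsI,countPropsII distribution of body-CpG counts 0..5 per
#'   design; the defaults skew design I toward more body CpGs.
#' @param islandProbByCount probability a probe is flagged as island, by body
#'   CpG count 0..5 (increasing in count).
#' @param mixIsland,mixNonIsland mixture weights (unmethylated, intermediate,
#'   methylated) of true beta conditional on island status.
#' @param betaShapes list of \code{c(shape1, shape2)} for the unmethylated,
#'   intermediate and methylated beta components.
#' @param lnMeanlog,lnSdlog named (\code{I}, \code{II}) log-normal location
#'   and scale of per-probe total intensity.
#' @param channelScale list per design of named (\code{Meth}, \code{Unmeth})
#'   channel scale multipliers.
#' @param lambda design-II compression factor in (0, 1]: the observed
#'   methylated fraction of a design-II probe is 0.5 + lambda * (beta - 0.5),
#'   so lambda = 1 injects no artifact.
#' @param noiseSdLog sd of the per-probe per-channel multiplicative
#'   log-normal measurement noise.
#' @param arrayJitterSdLog sd of the multiplicative technical scale jitter,
#'   drawn independently per array, design and channel so the relative
#'   offset between the two designs varies from array to array.
#' @param groupSizes arrays per group (length 1 for a single group of
#'   technical replicates; length 2 for a two-group design).
#' @param piAffected fraction of probes with a group effect.
#' @param deltaBeta absolute beta effect added (with random sign, clipped to
#'   \[0, 1\]) to affected probes in group 2.
#' @param nControls negative-control probes per channel.
#' @param negMean,negSd named (\code{Meth}, \code{Unmeth}) normal background
#'   parameters of the negative controls, in intensity units.
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nProbes = 20000L,
                             typeIFraction = 0.28,
                             countPropsI = c(0.04, 0.12, 0.20, 0.26, 0.22, 0.16),
                             countPropsII = c(0.22, 0.40, 0.25, 0.10, 0.02, 0.01),
                             islandProbByCount = c(0.10, 0.20, 0.35, 0.55, 0.70, 0.80),
                             mixIsland = c(0.75, 0.10, 0.15),
                             mixNonIsland = c(0.25, 0.15, 0.60),
                             betaShapes = list(unmeth = c(2, 18),
                                               mid = c(5, 5),
                                               meth = c(18, 2)),
                             lnMeanlog = c(I = 8.3, II = 7.9),
                             lnSdlog = c(I = 0.4, II = 0.4),
                             channelScale = list(I = c(Meth = 1, Unmeth = 1),
                                                 II = c(Meth = 1, Unmeth = 1)),
                             lambda = 0.8,
                             noiseSdLog = 0.15,
                             arrayJitterSdLog = 0.05,
                             groupSizes = c(3L, 3L),
                             piAffected = 0.05,
                             deltaBeta = 0.3,
                             nControls = 100L,
                             negMean = c(Meth = 100, Unmeth = 100),
                             negSd = c(Meth = 20, Unmeth = 20)) {
    cfg <- list(nProbes = as.integer(nProbes), typeIFraction = typeIFraction,
                countPropsI = countPropsI / sum(countPropsI),
                countPropsII = countPropsII / sum(countPropsII),
                islandProbByCount = islandProbByCount,
                mixIsland = mixIsland / sum(mixIsland),
                mixNonIsland = mixNonIsland / sum(mixNonIsland),
                betaShapes = betaShapes, lnMeanlog = lnMeanlog,
                lnSdlog = lnSdlog, channelScale = channelScale,
                lambda = lambda, noiseSdLog = noiseSdLog,
                arrayJitterSdLog = arrayJitterSdLog,
                groupSizes = as.integer(groupSizes),
                piAffected = piAffected, deltaBeta = deltaBeta,
                nControls = as.integer(nControls),
                negMean = negMean, negSd = negSd)
    stopifnot(cfg$lambda > 0, cfg$lambda <= 1,
              cfg$piAffected >= 0, cfg$piAffected <= 1,
              cfg$deltaBeta > 0, cfg$deltaBeta < 1,
              all(cfg$lnSdlog > 0), cfg$noiseSdLog >= 0,
              cfg$arrayJitterSdLog >= 0, all(cfg$groupSizes >= 1),
              cfg$nControls >= 10, all(cfg$negSd > 0), all(cfg$negMean > 0),
              length(cfg$countPropsI) == 6, length(cfg$countPropsII) == 6,
              length(cfg$islandProbByCount) == 6)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key/value document; every key is optional and falls back to the
#' [simulationConfig()] default.
#'
#' @param path YAML file path.
#' @return a \code{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown) > 0)
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "), call. = FALSE)
    vals <- vals[intersect(names(vals), known)]
    ## restore names on named defaults that YAML may deliver unnamed
    for (k in c("lnMeanlog", "lnSdlog"))
        if (k %in% names(vals) && is.null(names(vals[[k]])))
            names(vals[[k]]) <- c("I", "II")
    for (k in c("negMean", "negSd"))
        if (k %in% names(vals) && is.null(names(vals[[k]])))
            names(vals[[k]]) <- c("Meth", "Unmeth")
    do.call(simulationConfig, vals)
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf("SimulationConfig: %d probes (%.0f%% design I), lambda = %.2f, groups = %s\n",
                x$nProbes, 100 * x$typeIFraction, x$lambda,
                paste(x$groupSizes, collapse = "v")))
    invisible(x)
}

#' Simulate a probe manifest
#'
#' Draws per-design body-CpG counts from the configured distributions (the
#' default profile gives design I the higher mean, matching the CpG-density
#' skew of real dual-design arrays), island flags with probability increasing
#' in body-CpG count, and uniform genomic positions over autosomes plus a
#' small fraction of chrX/chrY probes.
#'
#' @param config a \code{SimulationConfig}; @param seed integer.
#' @return manifest data.frame.
#' @export
simulateManifest <- function(config = simulationConfig(), seed = 1L) {
    withSeed(seed, {
        n <- config$nProbes
        nI <- round(n * config$typeIFraction)
        design <- c(rep("I", nI), rep("II", n - nI))
        cnt <- integer(n)
        cnt[design == "I"] <- sample(0:5, nI, TRUE, config$countPropsI)
        cnt[design == "II"] <- sample(0:5, n - nI, TRUE, config$countPropsII)
        island <- stats::runif(n) < config$islandProbByCount[cnt + 1]
        chrom <- sample(c(paste0("chr", 1:22), "chrX", "chrY"), n, TRUE,
                        prob = c(rep(0.95 / 22, 22), 0.04, 0.01))
        data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
                   design_type = design, body_cpg_count = cnt,
                   chromosome = chrom,
                   position = sample.int(2^28, n, replace = TRUE),
                   island = island)
    })
}

## noiseless observed methylated fraction: identity for design I,
## compression toward 0.5 by lambda for design II
.compressFraction <- function(beta, design, lambda) {
    ifelse(design == "II", 0.5 + lambda * (beta - 0.5), beta)
}

#' Simulate a dual-design methylation dataset with known truth
#'
#' True beta values are drawn from an island-conditional three-component
#' beta mixture (bimodal overall). The observed methylated fraction is the
#' true beta for design-I probes and is compressed toward 0.5 by the factor
#' \code{lambda} for design-II probes — the injected probe-type artifact.
#' Each array draws its own per-probe total intensity (log-normal with
#' design-specific location), per-array scale jitter and per-channel
#' multiplicative noise, so arrays within a group are technical replicates
#' sharing true beta. When two groups are configured, a random subset of
#' probes (fraction \code{piAffected}) receives a signed beta shift of
#' magnitude \code{deltaBeta} (clipped to \[0, 1\]) in group 2. Negative
#' controls are drawn from the normal background model that detection
#' p-values assume.
#'
#' @param manifest manifest data.frame, e.g. from [simulateManifest()].
#' @param config a \code{SimulationConfig}; @param seed integer.
#' @return list with \code{dataset} (a validated
#'   \linkS4class{MethylArraySet}), \code{truth} (list: \code{trueBeta} per
#'   probe and group, \code{affected} probe ids, \code{effects} signed
#'   shifts, \code{groups} factor over samples, \code{arrayJitter}).
#' @export
simulateDataset <- function(manifest, config = simulationConfig(), seed = 1L) {
    manifest <- as.data.frame(manifest)
    n <- nrow(manifest)
    withSeed(subSeed(seed, 1), {
        ## biology: island-conditional bimodal true methylation
        state <- integer(n)
        isl <- if ("island" %in% colnames(manifest)) manifest$island
               else rep(FALSE, n)
        state[isl] <- sample.int(3, sum(isl), TRUE, config$mixIsland)
        state[!isl] <- sample.int(3, sum(!isl), TRUE, config$mixNonIsland)
        sh <- config$betaShapes
        shapes <- rbind(sh$unmeth, sh$mid, sh$meth)
        trueBeta <- stats::rbeta(n, shapes[state, 1], shapes[state, 2])
        names(trueBeta) <- manifest$probe_id

        ## two-group effects
        nGroups <- length(config$groupSizes)
        beta2 <- trueBeta
        affected <- character(0); effects <- numeric(0)
        if (nGroups >= 2 && config$piAffected > 0) {
            nAff <- round(config$piAffected * n)
            idx <- sample.int(n, nAff)
            sgn <- sample(c(-1, 1), nAff, TRUE)
            effects <- sgn * config$deltaBeta
            beta2[idx] <- pmin(1, pmax(0, trueBeta[idx] + effects))
            affected <- manifest$probe_id[idx]
            names(effects) <- affected
        }
        groups <- factor(rep(paste0("g", seq_len(nGroups)),
                             config$groupSizes))
        nArr <- sum(config$groupSizes)
        sampleIds <- sprintf("S%02d", seq_len(nArr))

        des <- manifest$design_type
        meth <- matrix(0, n, nArr, dimnames = list(manifest$probe_id, sampleIds))
        unmeth <- meth
        ## technical jitter: one multiplicative factor per array, design and
        ## channel, so the relative offset between the two designs varies
        ## array by array — the between-array component a within-array
        ## normalization can act on
        jitter <- array(exp(stats::rnorm(4 * nArr, 0,
                                         config$arrayJitterSdLog)),
                        dim = c(2, 2, nArr),
                        dimnames = list(c("I", "II"), c("Meth", "Unmeth"),
                                        NULL))
        isII <- des == "II"
        csM <- ifelse(isII, config$channelScale$II["Meth"],
                      config$channelScale$I["Meth"])
        csU <- ifelse(isII, config$channelScale$II["Unmeth"],
                      config$channelScale$I["Unmeth"])
        for (j in seq_len(nArr)) {
            b <- if (groups[j] == "g2") beta2 else trueBeta
            g <- .compressFraction(b, des, config$lambda)
            total <- stats::rlnorm(n, config$lnMeanlog[des],
                                   config$lnSdlog[des])
            meth[, j] <- total * g * csM * jitter[des, "Meth", j] *
                exp(stats::rnorm(n, 0, config$noiseSdLog))
            unmeth[, j] <- total * (1 - g) * csU * jitter[des, "Unmeth", j] *
                exp(stats::rnorm(n, 0, config$noiseSdLog))
        }
        negMeth <- matrix(pmax(stats::rnorm(config$nControls * nArr,
                                            config$negMean["Meth"],
                                            config$negSd["Meth"]), 0.01),
                          config$nControls, nArr,
                          dimnames = list(NULL, sampleIds))
        negUnmeth <- matrix(pmax(stats::rnorm(config$nControls * nArr,
                                              config$negMean["Unmeth"],
                                              config$negSd["Unmeth"]), 0.01),
                            config$nControls, nArr,
                            dimnames = list(NULL, sampleIds))
        ds <- MethylArraySet(manifest, meth, unmeth, negMeth, negUnmeth)
        list(dataset = ds,
             truth = list(trueBeta = trueBeta, trueBetaGroup2 = beta2,
                          affected = affected, effects = effects,
                          groups = groups, arrayJitter = jitter,
                          seed = as.integer(seed)))
    })
}

#' Truth table from a simulation
#'
#' Formats the simulated per-probe reference beta values of the two groups as
#' the tab-delimited truth schema used by [evaluateAgainstTruth()].
#'
#' @param truth the \code{truth} element returned by [simulateDataset()].
#' @return data.frame with \code{probe_id}, \code{ref_beta_group1},
#'   \code{ref_beta_group2}.
#' @export
truthTable <- function(truth) {
    data.frame(probe_id = names(truth$trueBeta),
               ref_beta_group1 = unname(truth$trueBeta),
               ref_beta_group2 = unname(truth$trueBetaGroup2))
}
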