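test_that("subset selection takes the minimum stratum size from each stratum", {
    ## strata sizes I: 5,7,6 / II: 9,8,5 -> N = 5, 15 ids per design
    sizes <- c("I.1" = 5, "I.2" = 7, "I.3" = 6,
               "II.1" = 9, "II.2" = 8, "II.3" = 5)
    rows <- do.call(rbind, lapply(names(sizes), function(s) {
        d <- sub("\\..*", "", s); cc <- as.integer(sub(".*\\.", "", s))
        data.frame(design_type = d, body_cpg_count = cc,
                   n = seq_len(sizes[[s]]))
    }))
    man <- data.frame(probe_id = sprintf("p%03d", seq_len(nrow(rows))),
                      design_type = rows$design_type,
                      body_cpg_count = rows$body_cpg_count,
                      chromosome = "chr1",
                      position = seq_len(nrow(rows)))
    sub <- selectSubset(man, seed = 3)
    expect_identical(subsetSize(sub), 5L)
    expect_length(subsetProbes(sub, "I"), 15L)
    expect_length(subsetProbes(sub, "II"), 15L)
    expect_false(anyDuplicated(subsetProbes(sub, "I")) > 0)
    ## drawn without replacement from the right stratum
    for (s in names(sizes)) {
        d <- sub("\\..*", "", s); cc <- as.integer(sub(".*\\.", "", s))
        pool <- man$probe_id[man$design_type == d & man$body_cpg_count == cc]
        expect_true(all(sub@strata[[s]] %in% pool))
    }

    ## determinism: same manifest, same seed -> identical subsets
    expect_identical(sub@strata, selectSubset(man, seed = 3)@strata)
    expect_false(identical(sub@strata, selectSubset(man, seed = 4)@strata))

    ## an empty stratum is named in the error
    expect_error(selectSubset(man[!(man$design_type == "I" &
                                    man$body_cpg_count == 3), ], seed = 1),
                 "\\(I, 3\\)")
})

test_that("quantile map averages the ranked intensities of the two designs", {
    strata <- list("I.1" = "a1", "I.2" = "a2", "I.3" = "a3",
                   "II.1" = "b1", "II.2" = "b2", "II.3" = "b3")
    sub <- handSubset(strata)
    x <- c(a1 = 1, a2 = 3, a3 = 2, b1 = 6, b2 = 2, b3 = 4)
    qmI <- buildQuantileMap(x, sub, "I")
    qmII <- buildQuantileMap(x, sub, "II")
    expect_equal(qmI@xSub, c(1, 2, 3))
    expect_equal(qmII@xSub, c(2, 4, 6))
    expect_equal(qmI@target, c(1.5, 3, 4.5))
    expect_equal(qmII@target, qmI@target)  # shared target per channel/sample

    ## identical subset intensities for both designs -> target is the
    ## common sorted vector
    y <- c(a1 = 5, a2 = 1, a3 = 9, b1 = 9, b2 = 5, b3 = 1)
    expect_equal(buildQuantileMap(y, sub, "I")@target, c(1, 5, 9))

    expect_error(buildQuantileMap(x[-1], sub, "I"), "absent")
})

test_that("quantile map matches a sort-then-average oracle on random draws", {
    withr::with_seed(42, {
        for (rep in 1:20) {
            N <- sample(2:8, 1)
            strata <- list()
            for (d in c("I", "II")) for (cc in 1:3)
                strata[[paste(d, cc, sep = ".")]] <-
                    sprintf("%s%d_%02d", d, cc, seq_len(N))
            sub <- handSubset(strata)
            ids <- unlist(strata, use.names = FALSE)
            x <- stats::setNames(rlnorm(length(ids), 7, 1), ids)
            oracle <- (sort(x[subsetProbes(sub, "I")]) +
                       sort(x[subsetProbes(sub, "II")])) / 2
            qm <- buildQuantileMap(x, sub, "II")
            expect_equal(qm@target, unname(oracle), tolerance = 1e-12)
            expect_equal(qm@xSub, unname(sort(x[subsetProbes(sub, "II")])))
        }
    })
})

test_that("interpolation follows the in-range and displacement rules", {
    qm <- new("QuantileMap", xSub = c(2, 4, 6), target = c(1.5, 3, 4.5),
              design = "I")
    expect_equal(interpolateIntensity(5, qm), 3.75)   # midpoint of a segment
    expect_equal(interpolateIntensity(7, qm), 5.5)    # above max: 4.5 + 1
    expect_equal(interpolateIntensity(1, qm), 0.5)    # below min: 1.5 - 1
    expect_equal(interpolateIntensity(c(2, 4, 6), qm), c(1.5, 3, 4.5))
    ## vectorized and monotone
    xs <- seq(-1, 9, by = 0.1)
    ys <- interpolateIntensity(xs, qm)
    expect_true(all(diff(ys) >= -1e-12))
    ## tied knots collapse to the mean of their targets
    qmTie <- new("QuantileMap", xSub = c(2, 4, 4, 6),
                 target = c(1, 2, 4, 5), design = "I")
    expect_equal(interpolateIntensity(4, qmTie), 3)
})

test_that("normalization equalizes the subset distributions and keeps order", {
    man <- tinyManifest(120, seed = 5)
    ds <- randomDataset(man, nSamples = 3, seed = 6)
    norm <- swanNormalize(ds, seed = 9)
    sub <- selectSubset(man, seed = 9)
    man$row <- seq_len(nrow(man))
    for (ch in c("Meth", "Unmeth")) {
        raw <- if (ch == "Meth") getMeth(ds) else getUnmeth(ds)
        m <- if (ch == "Meth") getMeth(norm) else getUnmeth(norm)
        for (j in 1:3) {
            ## subset-distribution identity
            expect_equal(sort(m[subsetProbes(sub, "I"), j]),
                         sort(m[subsetProbes(sub, "II"), j]),
                         tolerance = 1e-9, ignore_attr = TRUE)
            ## within-design monotonicity
            for (d in c("I", "II")) {
                rows <- man$row[man$design_type == d]
                ord <- order(raw[rows, j])
                expect_true(all(diff(m[rows, j][ord]) >= -1e-12))
            }
        }
    }
    ## positivity and provenance
    expect_true(all(getMeth(norm) > 0) && all(getUnmeth(norm) > 0))
    expect_identical(swanSeed(norm), 9L)
    ## determinism: bitwise-stable given the seed
    norm2 <- swanNormalize(ds, seed = 9)
    expect_identical(getMeth(norm2), getMeth(norm))
    expect_identical(getUnmeth(norm2), getUnmeth(norm))
    ## with unequal strata (N < every stratum size) the draw is seed-sensitive
    man2 <- tinyManifest(130, seed = 5)
    ds2 <- randomDataset(man2, nSamples = 1, seed = 6)
    expect_false(identical(getMeth(swanNormalize(ds2, seed = 10)),
                           getMeth(swanNormalize(ds2, seed = 11))))
})

test_that("already-identical design distributions are a fixed point on the subset", {
    ## both designs share identical subset intensities -> targets equal the
    ## originals, so subset probes are unchanged
    strata <- list("I.1" = "a1", "I.2" = "a2", "I.3" = "a3",
                   "II.1" = "b1", "II.2" = "b2", "II.3" = "b3")
    man <- data.frame(probe_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                      design_type = rep(c("I", "II"), each = 3),
                      body_cpg_count = rep(1:3, 2),
                      chromosome = "chr1", position = 1:6)
    vals <- c(a1 = 10, a2 = 30, a3 = 20, b1 = 20, b2 = 10, b3 = 30)
    m <- cbind(S1 = vals[man$probe_id])
    nc <- cbind(S1 = rep(5, 10))
    ds <- MethylArraySet(man, m, m, nc, nc)
    norm <- swanNormalize(ds, subset = handSubset(strata))
    expect_equal(getMeth(norm)[, 1], vals[man$probe_id],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("non-positive normalized intensities take the negative-control median", {
    ## design-I intensities high, one non-subset design-I probe at 0:
    ## extrapolation below the subset minimum goes negative and must be
    ## substituted by the control median
    man <- data.frame(probe_id = c("a1", "a2", "a3", "alow",
                                   "b1", "b2", "b3"),
                      design_type = c("I", "I", "I", "I", "II", "II", "II"),
                      body_cpg_count = c(1:3, 0, 1:3),
                      chromosome = "chr1", position = 1:7)
    m <- cbind(S1 = c(1000, 1200, 1400, 0, 10, 20, 30))
    nc <- cbind(S1 = c(7, 7, 8, 9, 9, 9, 10, 11, 12, 13))
    ds <- MethylArraySet(man, m, m + 1, nc, nc)
    norm <- swanNormalize(ds, seed = 2)
    ## subset min target = (1000 + 10)/2 = 505; displacement 1000 -> x' < 0
    expect_equal(unname(getMeth(norm)["alow", 1]), 9)  # median of controls
    expect_identical(sum(substitutionCounts(norm)["Meth", ]), 1L)
    expect_true(all(getMeth(norm) > 0))
})

test_that("normalization matches the explicit-loop reference implementation", {
    for (seed in 1:3) {
        man <- tinyManifest(150, seed = seed)
        ds <- randomDataset(man, nSamples = 2, seed = seed + 100)
        sub <- selectSubset(man, seed = seed)
        norm <- swanNormalize(ds, subset = sub)
        ref <- naiveSwanNormalize(ds, sub)
        expect_equal(getMeth(norm), ref$Meth, tolerance = 1e-9)
        expect_equal(getUnmeth(norm), ref$Unmeth, tolerance = 1e-9)
    }
})

test_that("per-array subsets are drawn independently but reproducibly", {
    man <- tinyManifest(120, seed = 5)
    ds <- randomDataset(man, nSamples = 2, seed = 6)
    n1 <- swanNormalize(ds, seed = 4, perArraySubset = TRUE)
    n2 <- swanNormalize(ds, seed = 4, perArraySubset = TRUE)
    expect_identical(getMeth(n1), getMeth(n2))
    ## a subset drawn from a foreign manifest is rejected
    other <- tinyManifest(60, seed = 99)
    other$probe_id <- paste0("xx", other$probe_id)
    expect_error(swanNormalize(ds, subset = selectSubset(other, 1)),
                 "absent from the dataset")
})
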