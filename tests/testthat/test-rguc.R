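test_that("rarity thresholds are strict on both criteria", {
    # 10 pops of 10: band A at exactly 10% overall (excluded), band B at
    # 5% overall in 4/10 pops (occupancy 40%, excluded), band C at 5%
    # in 3/10 pops (included)
    counts <- matrix(0L, 10, 3)
    counts[1, 1] <- 10L                         # A: 10/100 = 0.10
    counts[1:4, 2] <- c(2L, 1L, 1L, 1L)         # B: 5/100, 4 pops
    counts[1:3, 3] <- c(2L, 2L, 1L)             # C: 5/100, 3 pops
    bm <- bmFromCounts(counts, sizes = rep(10, 10))
    rare <- findRareBands(bm)
    expect_equal(rare$locus, "L3")
    expect_equal(rare$p, 0.05)
    expect_equal(rare$N, 3L)
    expect_equal(rare$meanFreqOccupied, mean(c(0.2, 0.2, 0.1)))
    # an 11-population layout admits occupancy 4 (36.4% < 40%)
    counts2 <- matrix(0L, 11, 1)
    counts2[1:4, 1] <- 1L
    bm2 <- bmFromCounts(counts2, sizes = rep(8, 11))
    expect_equal(nrow(findRareBands(bm2)), 1)
})

test_that("loss probabilities follow (1-p)^(2N)", {
    expect_equal(lossProbability(0.5, 1), 0.25)
    expect_equal(lossProbability(0.1, 1), 0.81)
    expect_equal(lossProbability(0.05, 2), 0.95^4)
    expect_equal(lossProbability(0.05, 2), 0.81450625)
    expect_error(lossProbability(0, 1), "strictly")
    expect_error(lossProbability(1, 2), "strictly")
})

test_that("R-value has its closed forms and matches an OLS oracle", {
    rec <- function(f, N) data.frame(locus = paste0("L", seq_along(f)),
                                     p = f / 2, N = N,
                                     meanFreqOccupied = f,
                                     Lo = lossProbability(f, N),
                                     Le = lossProbability(f, 1))
    f <- c(0.05, 0.10, 0.15, 0.22, 0.30)
    expect_equal(rValue(rec(f, rep(1L, 5)))$R, 1, tolerance = 1e-12)
    expect_equal(rValue(rec(f, rep(2L, 5)))$R, 0.5, tolerance = 1e-12)
    expect_equal(rValue(rec(f, rep(3L, 5)))$R, 1 / 3, tolerance = 1e-12)

    # heterogeneous occupancies against an independent regression oracle
    N <- c(1L, 3L, 2L, 4L, 2L)
    r <- rValue(rec(f, N))
    ols <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
        sum((x - mean(x))^2)
    so <- ols(f, -log(lossProbability(f, N)))
    se <- ols(f, -log(lossProbability(f, 1)))
    expect_equal(r$slopeObs, so, tolerance = 1e-10)
    expect_equal(r$slopeExp, se, tolerance = 1e-10)
    expect_equal(r$R, se / so, tolerance = 1e-10)
    expect_lt(r$R, 1)

    expect_error(rValue(rec(f, N)[1:2, ]), ">= 3")
    expect_error(rValue(rec(rep(0.1, 4), c(1L, 2L, 1L, 2L))), "constant")
})

test_that("PSA assignment maximizes cluster occupancy with carrier ties", {
    # 9 pops: cluster 1 = P1..P5, cluster 2 = P6..P9
    clusters <- setNames(c(rep(1L, 5), rep(2L, 4)), paste0("P", 1:9))
    counts <- matrix(0L, 9, 3)
    counts[6:7, 1] <- 2L               # L1 exclusive to cluster 2
    counts[1:2, 2] <- 1L; counts[6, 2] <- 2L  # L2: 2/5 vs 1/4 pops,
    counts[1, 3] <- 1L; counts[6, 3] <- 1L    # L3: 1/5 vs 1/4 + carriers
    bm <- bmFromCounts(counts, sizes = rep(10, 9))
    rare <- findRareBands(bm, freqThresh = 0.2, occThresh = 0.4)
    rare <- rare[match(c("L1", "L2", "L3"), rare$locus), ]
    out <- assignPSA(rare, clusters, bm)
    expect_equal(out$psa, c(2L, 1L, 2L))
    # L2: fraction 0.40 beats 0.25 despite fewer carriers
    # L3: fractions 0.20 vs 0.25 -> cluster 2
})

test_that("the population-count rule solves P = 1 - FST^n and rounds up", {
    res <- nPopulations(0.5, 0.75)          # 0.25 = 0.5^n -> n = 2
    expect_equal(res$nReal, 2, tolerance = 1e-12)
    expect_equal(res$nInteger, 2L)
    expect_equal(nPopulations(0.3, 1 - 0.3)$nReal, 1, tolerance = 1e-12)
    expect_equal(nPopulations(0.3, 0.9)$nInteger,
                 as.integer(ceiling(log(0.1) / log(0.3))))
    # monotone: higher targets and higher differentiation need more pops
    expect_gt(nPopulations(0.25, 0.999)$nReal,
              nPopulations(0.25, 0.99)$nReal)
    expect_gt(nPopulations(0.4, 0.99)$nReal,
              nPopulations(0.25, 0.99)$nReal)
    expect_error(nPopulations(1, 0.9), "strictly")
    expect_error(nPopulations(0.2, 1))
})

test_that("optimal proportions average normalized shares and R-values", {
    u <- optimalProportions(c(1, 1, 1) / 3, c(0.5, 0.5, 0.5))
    expect_equal(unname(u$proportions), rep(1 / 3, 3), tolerance = 1e-12)
    s <- c(0.45, 1 / 3, 0.2167)
    r <- c(0.4423, 0.3178, 0.5750)
    got <- optimalProportions(s, r)$proportions
    manual <- (s / sum(s) + r / sum(r)) / 2
    expect_equal(unname(got), unname(manual / sum(manual)),
                 tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    # a cluster holding every rare band cannot rank below the others
    one <- optimalProportions(c(1, 0, 0), c(0.3, 0.9, 0.9))$proportions
    expect_true(one[1] >= max(one[-1]))
    expect_error(optimalProportions(c(0, 0), c(0, 0)), "positive")
})

test_that("RGUC selection takes top diversity per cluster and captures more", {
    sim <- smallSim(seed = 15)
    desc <- popDescriptors(sim$bm)
    clusters <- sim$truth$cluster
    rare <- findRareBands(sim$bm)$locus
    sel <- selectRGUCs(sim$bm, desc, clusters, 2, rare)
    expect_length(sel$selected, 6)
    for (k in 1:3) {
        members <- desc[clusters[desc$population] == k, ]
        top <- members$population[order(-members$neiGD, -members$dw,
                                        members$population)][1:2]
        expect_equal(sel$perCluster[[k]], top)
    }
    # selected set captures at least as much as any single population
    for (p in popNames(sim$bm)) {
        single <- RGUCkit:::.captureStats(sim$bm, p, rare)
        expect_gte(sel$capture["allBands"], single["allBands"])
    }
    # cluster of 3 with n = 3 selects everything; n = 4 errors
    expect_length(selectRGUCs(sim$bm, desc, clusters, 3,
                              rare)$selected, 9)
    expect_error(selectRGUCs(sim$bm, desc, clusters, 4, rare),
                 "cannot select")
})

test_that("capture is monotone in the number of selected populations", {
    sim <- smallSim(seed = 16)
    desc <- popDescriptors(sim$bm)
    clusters <- sim$truth$cluster
    rare <- findRareBands(sim$bm)$locus
    caps <- vapply(1:3, function(n)
        selectRGUCs(sim$bm, desc, clusters, n, rare)$capture["allBands"],
        numeric(1))
    expect_true(all(diff(caps) >= 0))
})

test_that("the random baseline is reproducible and saturates at full choice", {
    sim <- smallSim(seed = 17)
    clusters <- sim$truth$cluster
    rare <- findRareBands(sim$bm)$locus
    full <- randomCaptureBaseline(sim$bm, clusters, 3, rare, reps = 5,
                                  seed = 1)
    expect_equal(full$allBands, 100)
    expect_equal(full$rareBands, 100)
    a <- randomCaptureBaseline(sim$bm, clusters, 1, rare, reps = 20,
                               seed = 9)
    b <- randomCaptureBaseline(sim$bm, clusters, 1, rare, reps = 20,
                               seed = 9)
    expect_identical(a, b)
    expect_lt(a$allBands, 100)
})
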