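test_that("dominant-marker allele frequencies match hand arithmetic", {
    # P1 (n=16): L1 4 carriers -> x = 0.75 >= 3/n, Taylor correction on
    bm <- bmFromCounts(rbind(c(4, 16), c(2, 0)), sizes = c(16, 16))
    af <- alleleFrequencies(bm)
    x <- 0.75; v <- x * (1 - x) / 16
    expect_equal(af$q["L1", "P1"], sqrt(x) * (1 + v / (8 * x^2)),
                 tolerance = 1e-12)
    expect_equal(af$p["L1", "P1"], 1 - af$q["L1", "P1"])
    # x = 0.875 in P2 for L1
    x2 <- 0.875; v2 <- x2 * (1 - x2) / 16
    expect_equal(af$q["L1", "P2"], sqrt(x2) * (1 + v2 / (8 * x2^2)),
                 tolerance = 1e-12)
    # fixed band: x clamped to 1/(2n+1), below 3/n so no Taylor factor
    expect_equal(af$q["L2", "P1"], sqrt(1 / 33), tolerance = 1e-12)
    expect_equal(attr(af, "clamped"), 1L)
    # absent band: q = 1 exactly
    expect_equal(af$q["L2", "P2"], 1)
})

test_that("coancestry matches hand computation on a two-locus toy", {
    bm <- bmFromCounts(rbind(c(2, 1), c(3, 2)), sizes = c(4, 4))
    af <- alleleFrequencies(bm)
    F <- coancestry(bm)
    manual <- mean(af$p[, 1] * af$p[, 2] + af$q[, 1] * af$q[, 2])
    expect_equal(F["P1", "P2"], manual, tolerance = 1e-12)
    expect_equal(F["P1", "P1"], mean(af$p[, 1]^2 + af$q[, 1]^2),
                 tolerance = 1e-12)
    expect_equal(F, t(F))
})

test_that("coancestry boundary identities hold on exact frequencies", {
    # identical populations: f_ij = f_ii
    p <- cbind(A = c(0.3, 0.8), B = c(0.3, 0.8))
    F <- coancestryFromFrequencies(p)
    expect_equal(F["A", "B"], F["A", "A"], tolerance = 1e-12)
    # fixation for alternative alleles at every locus: f_ij = 0
    p2 <- cbind(A = c(1, 1), B = c(0, 0))
    expect_equal(coancestryFromFrequencies(p2)["A", "B"], 0)
    # duplicated populations in a band matrix give equal rows
    m <- bandValues(bmFromCounts(rbind(c(2, 1), c(2, 1)), c(4, 4)))
    bm <- BandMatrix(m, population = rep(c("X", "Y"), each = 4))
    Fb <- coancestry(bm)
    expect_equal(Fb["X", "Y"], Fb["X", "X"], tolerance = 1e-12)
})

test_that("Dmax maximization recovers the closed-form uniform optimum", {
    # F = f * I: minimum of c'Fc on the simplex is uniform, value f/n
    for (f in c(0.3, 0.8)) {
        F <- diag(rep(f, 4))
        dimnames(F) <- list(paste0("P", 1:4), paste0("P", 1:4))
        plan <- maximizeDmax(F, replicates = 20, seed = 2)
        expect_equal(unname(plan$contributions), rep(0.25, 4),
                     tolerance = 1e-5)
        expect_equal(plan$Dmax, 1 - f / 4, tolerance = 1e-8)
    }
})

test_that("Dmax matches 0.01-resolution simplex grid search (<= 3 pops)", {
    gridBest <- function(F) {
        n <- nrow(F)
        best <- Inf
        step <- 0.01
        if (n == 2) {
            for (a in seq(0, 1, step)) {
                c <- c(a, 1 - a)
                best <- min(best, drop(crossprod(c, F %*% c)))
            }
        } else {
            for (a in seq(0, 1, step)) for (b in seq(0, 1 - a, step)) {
                c <- c(a, b, 1 - a - b)
                best <- min(best, drop(crossprod(c, F %*% c)))
            }
        }
        1 - best
    }
    set.seed(31)
    for (rep in 1:8) {
        n <- sample(2:3, 1)
        A <- matrix(runif(n * n, 0.2, 0.9), n)
        F <- (A + t(A)) / 2
        diag(F) <- pmax(diag(F), apply(F, 1, max) * runif(n, 0.7, 1.1))
        dimnames(F) <- list(paste0("P", 1:n), paste0("P", 1:n))
        plan <- maximizeDmax(F, replicates = 40, seed = rep)
        expect_gte(plan$Dmax, gridBest(F) - 1e-3)
        expect_equal(sum(plan$contributions), 1, tolerance = 1e-9)
        expect_true(all(plan$contributions >= 0))
    }
    # a dominating population (cheap self-coancestry, zero cross) can
    # still be beaten by mixing: compare against the same grid oracle
    F <- diag(c(0.1, 0.5, 0.5))
    dimnames(F) <- list(paste0("P", 1:3), paste0("P", 1:3))
    plan <- maximizeDmax(F, replicates = 40, seed = 5)
    expect_equal(plan$Dmax, gridBest(F), tolerance = 1e-3)
    expect_true(which.max(plan$contributions) == 1)
    expect_error(maximizeDmax(matrix(c(1, 0, 0.5, 1), 2)), "symmetric")
})

test_that("duplicate populations share an interchangeable contribution", {
    F3 <- matrix(c(0.6, 0.6, 0.2,
                   0.6, 0.6, 0.2,
                   0.2, 0.2, 0.7), 3, byrow = TRUE,
                 dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
    plan <- maximizeDmax(F3, replicates = 50, seed = 7)
    # merging the duplicates gives a 2-population problem with the same
    # optimum; only the sum of the twins' contributions is determined
    F2 <- matrix(c(0.6, 0.2, 0.2, 0.7), 2,
                 dimnames = list(c("P12", "P3"), c("P12", "P3")))
    plan2 <- maximizeDmax(F2, replicates = 50, seed = 7)
    expect_equal(plan$Dmax, plan2$Dmax, tolerance = 1e-6)
    expect_equal(unname(plan$contributions[1] + plan$contributions[2]),
                 unname(plan2$contributions["P12"]), tolerance = 1e-4)
})

test_that("leave-one-out contributions are additive and sign-correct", {
    sim <- smallSim(seed = 18)
    loo <- leaveOneOutContributions(sim$bm)
    expect_equal(loo$dHt, loo$dHnei + loo$dHdist, tolerance = 1e-6)
    # independent recomputation oracle for one population
    af <- alleleFrequencies(sim$bm)
    H <- function(p, q) mean(colMeans(2 * p * q))
    Dbar <- function(p, q) {
        n <- ncol(p); s <- 0
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            s <- s + mean(((p[, i] - p[, j])^2 + (q[, i] - q[, j])^2) / 2)
        s / choose(n, 2)
    }
    i <- 4
    nei <- 100 * (H(af$p, af$q) - H(af$p[, -i], af$q[, -i])) /
        H(af$p, af$q)
    dst <- 100 * (Dbar(af$p, af$q) - Dbar(af$p[, -i], af$q[, -i])) /
        Dbar(af$p, af$q)
    expect_equal(loo$dHnei[i], nei, tolerance = 1e-9)
    expect_equal(loo$dHdist[i], dst, tolerance = 1e-9)
    expect_error(leaveOneOutContributions(sim$bm,
                                          scope = popNames(sim$bm)[1:2]),
                 ">= 3")
})

test_that("identical populations contribute nothing to either term", {
    m <- bandValues(bmFromCounts(rbind(c(2, 1, 3)), sizes = 4))
    m <- rbind(m, m, m)
    rownames(m) <- paste0("i", 1:12)
    bm <- BandMatrix(m, population = rep(c("A", "B", "C"), each = 4))
    loo <- leaveOneOutContributions(bm)
    expect_equal(loo$dHnei, rep(0, 3))
    expect_equal(loo$dHdist, rep(0, 3))
})

test_that("the random-pool baseline never beats the optimum", {
    sim <- smallSim(seed = 19)
    F <- coancestry(sim$bm)
    plan <- maximizeDmax(F, replicates = 30, seed = 1)
    base <- randomPoolBaseline(F, reps = 100, seed = 2)
    expect_lte(base$mean, plan$Dmax)
    expect_true(all(base$perRep <= plan$Dmax + 1e-9))
    expect_identical(base, randomPoolBaseline(F, reps = 100, seed = 2))
})

test_that("optimized pools beat random pools across replicate studies", {
    gains <- vapply(1:20, function(s) {
        sim <- smallSim(seed = 300 + s, nLoci = 40, nPerPop = 10)
        F <- coancestry(sim$bm)
        plan <- maximizeDmax(F, replicates = 15, seed = s)
        base <- randomPoolBaseline(F, reps = 30, seed = s)
        (plan$Dmax - base$mean) / base$mean
    }, numeric(1))
    expect_true(all(gains > 0))
})
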