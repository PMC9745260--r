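test_that("collinearity filtering keeps one member per planted block", {
    set.seed(40)
    n <- 60
    A <- rnorm(n); B <- rnorm(n); C <- rnorm(n)
    X <- cbind(a1 = A, a2 = A + rnorm(n, 0, 0.05),
               b1 = B, b2 = B + rnorm(n, 0, 0.05), c1 = C)
    keep <- vifFilter(X, r2Thresh = 0.7)
    expect_length(keep, 3)
    expect_true("c1" %in% keep)
    expect_equal(sum(c("a1", "a2") %in% keep), 1)
    expect_equal(sum(c("b1", "b2") %in% keep), 1)
    # independent layers all retained; duplicated layer: exactly one kept
    Xi <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n))
    expect_length(vifFilter(Xi), 3)
    Xd <- cbind(u = A, v = A)
    expect_length(vifFilter(Xd), 1)
    expect_error(vifFilter(cbind(k = rep(1, n), l = rep(2, n))),
                 "degenerate")
})

test_that("a planted step signal dominates predictor importance", {
    ps <- plantedSignal(seed = 50)
    model <- fitTurnover(ps$bm, ps$preds, nTrees = 60, seed = 1)
    expect_equal(names(which.max(model@importance)), "A")
    expect_gt(model@importance["A"], 1.5 * max(model@importance[-1]))
    # the signal loci are retained with good out-of-bag skill
    sig <- model@loci[1:4, ]
    expect_true(all(sig$retained))
    expect_true(all(sig$weight > 0.5))
})

test_that("constant predictors carry zero importance", {
    ps <- plantedSignal(seed = 51, nPred = 3)
    preds <- cbind(ps$preds, Konst = 1)
    model <- fitTurnover(ps$bm, preds, nTrees = 40, seed = 2)
    expect_equal(unname(model@importance["Konst"]), 0)
})

test_that("monomorphic loci are skipped with a log message", {
    ps <- plantedSignal(seed = 52, nNoise = 3)
    m <- bandValues(ps$bm)
    m[, 5] <- 1L
    bm <- BandMatrix(m, population = as.character(populations(ps$bm)))
    expect_message(model <- fitTurnover(bm, ps$preds, nTrees = 20,
                                        seed = 3),
                   "monomorphic")
    expect_false(model@loci$retained[5])
    expect_true(is.na(model@loci$oobError[5]))
})

test_that("cumulative importance functions are monotone with max = total", {
    ps <- plantedSignal(seed = 53)
    model <- fitTurnover(ps$bm, ps$preds, nTrees = 40, seed = 4)
    for (v in names(model@importance)) {
        f <- model@cumimp[[v]]
        expect_true(all(diff(f$y) >= -1e-12))
        expect_equal(max(f$y), unname(model@importance[v]),
                     tolerance = 1e-12)
    }
})

test_that("total importance is invariant to locus order and stable in seed", {
    ps <- plantedSignal(seed = 54, nNoise = 5)
    model <- fitTurnover(ps$bm, ps$preds, nTrees = 30, seed = 7)
    m <- bandValues(ps$bm)
    perm <- sample(ncol(m))
    bm2 <- BandMatrix(m[, perm],
                      population = as.character(populations(ps$bm)))
    model2 <- fitTurnover(bm2, ps$preds, nTrees = 30, seed = 7)
    expect_equal(model2@importance, model@importance, tolerance = 1e-12)
    # RF-seed stability of the total importance when retention is clear
    # cut (total importance = mean retained-locus weight, so boundary
    # loci, not tree noise, are what moves it)
    psc <- plantedSignal(seed = 58, nNoise = 0, nSignal = 6)
    tots <- vapply(1:6, function(s)
        sum(fitTurnover(psc$bm, psc$preds, nTrees = 200,
                        seed = 100 + s)@importance),
        numeric(1))
    expect_lt(sd(tots) / mean(tots), 0.05)
})

test_that("transform applies the cumulative step functions exactly", {
    ps <- plantedSignal(seed = 55)
    model <- fitTurnover(ps$bm, ps$preds, nTrees = 40, seed = 5)
    v <- "A"
    f <- model@cumimp[[v]]
    pts <- matrix(runif(40, -0.5, 1.5), ncol = 4)
    colnames(pts) <- colnames(ps$preds)
    got <- transformClimate(model, pts)
    stepOracle <- function(x) {
        y <- c(0, f$y)
        y[findInterval(x, f$x) + 1]
    }
    expect_equal(got[, v], stepOracle(pts[, v]), tolerance = 1e-12)
    # below the training range -> 0; above -> total importance
    lohi <- matrix(c(-10, 10, rep(0.5, 6)), 2,
                   dimnames = list(NULL, colnames(ps$preds)))
    tl <- transformClimate(model, lohi)
    expect_equal(as.numeric(tl[1, v]), 0)
    expect_equal(as.numeric(tl[2, v]), unname(model@importance[v]))
    expect_gt(attr(tl, "clamped"), 0)
    bad <- pts[, 1:3]
    expect_error(transformClimate(model, bad), "missing predictor")
})

test_that("mapGroups recovers well-separated climate regimes", {
    regimeA <- rep(c(0.05, 0.5, 0.95), each = 3)
    ps <- plantedSignal(seed = 56, npops = 9, Avals = regimeA)
    model <- fitTurnover(ps$bm, ps$preds, nTrees = 50, seed = 6)
    # grid with three blocks of the adaptive predictor A
    nr <- 6; nc <- 9
    Araster <- matrix(rep(c(0.05, 0.5, 0.95), each = nr * 3), nr, nc)
    regime <- matrix(rep(1:3, each = nr * 3), nr, nc)
    layers <- list(A = Araster)
    for (nm in colnames(ps$preds)[-1])
        layers[[nm]] <- matrix(0.5, nr, nc)
    st <- ClimateStack(layers, xll = 0, yll = 0, cellsize = 1)
    aris <- vapply(1:5, function(s) {
        psi <- plantedSignal(seed = 60 + s, npops = 9, Avals = regimeA)
        mod <- fitTurnover(psi$bm, psi$preds, nTrees = 50, seed = s)
        mp <- mapGroups(mod, psi$preds, st, nGroups = 3, nAxes = 3)
        mclust::adjustedRandIndex(as.vector(mp@groupRaster),
                                  as.vector(regime))
    }, numeric(1))
    expect_gt(mean(aris > 0.9), 0.5)
    mp <- mapGroups(model, ps$preds, st, nGroups = 3, nAxes = 3)
    # population pixels inherit their own group in the separable case
    popCells <- match(ps$preds[, "A"], c(0.05, 0.5, 0.95))
    firstCol <- c(1, 4, 7)
    cellGroup <- mp@groupRaster[cbind(1, firstCol[popCells])]
    expect_equal(unname(cellGroup), unname(mp@popGroups[rownames(ps$preds)]))
    expect_error(mapGroups(model, ps$preds, st, nGroups = 20), "groups")
    # a constant grid has no structure to map
    flat <- ClimateStack(lapply(layers, function(x) x * 0 + 0.5),
                         xll = 0, yll = 0, cellsize = 1)
    expect_error(mapGroups(model, ps$preds, flat, nGroups = 3),
                 "constant")
})

test_that("scenario averaging is exact and freezes group identities", {
    ps <- plantedSignal(seed = 57, npops = 9)
    model <- fitTurnover(ps$bm, ps$preds, nTrees = 50, seed = 8)
    nr <- 5; nc <- 6
    mk <- function(shift) {
        layers <- list(A = matrix(seq(0, 1, length.out = nr * nc) + shift,
                                  nr, nc))
        for (nm in colnames(ps$preds)[-1])
            layers[[nm]] <- matrix(0.5, nr, nc)
        ClimateStack(layers, xll = 0, yll = 0, cellsize = 1)
    }
    cur <- mk(0)
    map <- mapGroups(model, ps$preds, cur, nGroups = 2, nAxes = 2)
    same <- scenarioAverage(list(cur, cur), model, map)
    expect_identical(same@groupRaster, map@groupRaster)
    expect_identical(same@centroids, map@centroids)
    # averaging two stacks equals transforming and averaging per pixel
    warm <- mk(0.3)
    avg <- scenarioAverage(list(cur, warm), model, map)
    tCur <- transformClimate(model, cur)
    tWarm <- transformClimate(model, warm)
    manual <- (unclass(tCur) + unclass(tWarm)) / 2
    scores <- sweep(manual, 2, map@pca$center) %*%
        map@pca$rotation[, 1:2]
    coords <- attr(tCur, "coords")
    expect_equal(avg@scoreGrid[cbind(coords$row, coords$col, 1)],
                 unname(scores[, 1]), tolerance = 1e-12)
    mismatched <- mk(0)
    mismatched@cellsize <- 2
    expect_error(scenarioAverage(list(cur, mismatched), model, map),
                 "share")
})
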