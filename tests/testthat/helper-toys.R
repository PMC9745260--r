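# deterministic toy band matrices used across test files

# 4 individuals, 2 populations, 3 loci
toyBandMatrix <- function() {
    m <- matrix(c(1, 0, 1,
                  1, 1, 0,
                  0, 0, 1,
                  0, 1, 1), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("i", 1:4), c("L1", "L2", "L3")))
    BandMatrix(m, population = c("A", "A", "B", "B"))
}

# band matrix with specified per-population carrier counts
# counts: matrix (populations x loci), sizes: individuals per population
bmFromCounts <- function(counts, sizes,
                         pops = paste0("P", seq_len(nrow(counts)))) {
    stopifnot(nrow(counts) == length(sizes))
    rows <- lapply(seq_len(nrow(counts)), function(k) {
        vapply(seq_len(ncol(counts)), function(l)
            rep(c(1L, 0L), c(counts[k, l], sizes[k] - counts[k, l])),
            integer(sizes[k]))
    })
    m <- do.call(rbind, rows)
    rownames(m) <- paste0(rep(pops, sizes), "_",
                          unlist(lapply(sizes, seq_len)))
    colnames(m) <- paste0("L", seq_len(ncol(counts)))
    BandMatrix(m, population = rep(pops, sizes))
}

# small study simulation used where full scale is not needed
smallSim <- function(seed = 1, ...) {
    args <- utils::modifyList(
        list(K = 3, popsPerCluster = c(3, 3, 3), nPerPop = 12,
             nLoci = 60, nAdaptiveLoci = 0, rareFraction = 0.25),
        list(...))
    simulateStudy(do.call(simConfig, args), seed = seed)
}

# flat grid ClimateStack from a named list of constants or matrices
flatStack <- function(layers, nr = 6, nc = 8, xll = 0, yll = 0,
                      cellsize = 1) {
    layers <- lapply(layers, function(v)
        if (is.matrix(v)) v else matrix(v, nr, nc))
    ClimateStack(layers, xll = xll, yll = yll, cellsize = cellsize)
}

expect_setequalNames <- function(x, y) expect_setequal(names(x), names(y))

# populations along a climate gradient A with signal loci whose
# frequencies step up at locus-specific thresholds of A; other
# predictors and loci are noise
plantedSignal <- function(seed, nNoise = 8, npops = 8, nPer = 15,
                          nSignal = 4, nPred = 4, Avals = NULL,
                          noiseFlat = FALSE) {
    set.seed(seed)
    A <- if (is.null(Avals)) seq(0, 1, length.out = npops) else Avals
    preds <- cbind(A, matrix(runif(npops * (nPred - 1)), npops))
    colnames(preds) <- c("A", paste0("N", seq_len(nPred - 1)))
    rownames(preds) <- paste0("P", seq_len(npops))
    thr <- seq(0.25, 0.75, length.out = nSignal)
    fSig <- vapply(thr, function(t) plogis(12 * (A - t)), numeric(npops))
    fNoise <- if (noiseFlat) matrix(0.5, npops, nNoise)
              else matrix(runif(npops * nNoise, 0.3, 0.7), npops)
    f <- cbind(fSig, fNoise)
    n <- npops * nPer
    m <- do.call(rbind, lapply(seq_len(npops), function(k)
        vapply(seq_len(ncol(f)),
               function(l) rbinom(nPer, 1L, f[k, l]), integer(nPer))))
    dimnames(m) <- list(paste0("i", seq_len(n)),
                        paste0("L", seq_len(ncol(f))))
    bm <- BandMatrix(m, population = rep(rownames(preds), each = nPer))
    list(bm = bm, preds = preds)
}
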