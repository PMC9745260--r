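#' Configuration for the synthetic dominant-marker study generator
#'
#' Defaults emulate the shape of a range-wide AFLP survey of a Mediterranean
#' conifer: 11 populations of 17-27 trees in K = 3 genetic clusters, 203
#' binary bands of which ~30\% are rare (overall carrier frequency < 10\%,
#' present in < 40\% of populations), species-wide differentiation around
#' 0.247, and a small set of loci whose population frequencies follow a
#' bioclimatic gradient.
#'
#' @param K number of genetic clusters
#' @param popsPerCluster integer vector, populations per cluster
#' @param nPerPop individuals per population (length = total populations)
#' @param nLoci total binary loci
#' @param fstTarget total differentiation (intraclass correlation) of
#'   population band frequencies, in (0,1)
#' @param clusterShare fraction of the total drift placed between clusters
#'   (the rest is within-cluster), in [0,1]
#' @param rareFraction fraction of loci seeded as rare, in [0,1)
#' @param nAdaptiveLoci loci linked to the designated climate layer (only
#'   realized when a climate covariate is supplied)
#' @param beta logistic slope of adaptive-locus frequency on the
#'   standardized climate covariate
#' @param divHet half-width of the log-uniform per-population diversity
#'   factor: populations with a larger factor drift less (higher gene
#'   diversity) and preferentially host rare bands, reproducing the
#'   diversity-rarity coupling seen in range-wide marker surveys
#' @param rareMaxFreq,rareMaxOcc rarity thresholds used for seeding
#'   (strict upper bounds on overall frequency and population occupancy)
#' @param nLayers number of climate layers
#' @param gridDim c(rows, cols) of the climate grid
#' @param bbox c(xmin, xmax, ymin, ymax) in decimal degrees; must give
#'   square cells with \code{gridDim}
#' @return a validated list of class \code{SimConfig}
#' @export
simConfig <- function(K = 3,
                      popsPerCluster = c(5, 4, 2),
                      nPerPop = c(24, 23, 26, 24, 25, 17, 18, 23, 24, 24, 27),
                      nLoci = 203,
                      fstTarget = 0.247,
                      clusterShare = 0.5,
                      rareFraction = 0.30,
                      nAdaptiveLoci = 10,
                      beta = 6,
                      divHet = 0.8,
                      rareMaxFreq = 0.10,
                      rareMaxOcc = 0.40,
                      nLayers = 5,
                      gridDim = c(20, 40),
                      bbox = c(-9, 7, 30, 38)) {
    stopifnot(K >= 1, length(popsPerCluster) == K, all(popsPerCluster >= 1),
              nLoci >= 1, fstTarget > 0, fstTarget < 1,
              clusterShare >= 0, clusterShare <= 1,
              rareFraction >= 0, rareFraction < 1,
              nAdaptiveLoci >= 0, beta >= 0, divHet >= 0, nLayers >= 1,
              length(gridDim) == 2, all(gridDim >= 5),
              length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3])
    npops <- sum(popsPerCluster)
    if (length(nPerPop) == 1L) nPerPop <- rep(nPerPop, npops)
    stopifnot(length(nPerPop) == npops, all(nPerPop >= 2))
    csx <- (bbox[2] - bbox[1]) / gridDim[2]
    csy <- (bbox[4] - bbox[3]) / gridDim[1]
    if (abs(csx - csy) > 1e-9)
        stop("bbox and gridDim must give square cells")
    cfg <- list(K = K, popsPerCluster = popsPerCluster, nPerPop = nPerPop,
                nLoci = nLoci, fstTarget = fstTarget,
                clusterShare = clusterShare, rareFraction = rareFraction,
                nAdaptiveLoci = nAdaptiveLoci, beta = beta,
                divHet = divHet,
                rareMaxFreq = rareMaxFreq, rareMaxOcc = rareMaxOcc,
                nLayers = nLayers, gridDim = as.integer(gridDim),
                bbox = bbox, cellsize = csx)
    class(cfg) <- "SimConfig"
    cfg
}

#' Validate a population metadata table
#'
#' @param df data.frame with columns \code{population}, \code{lon},
#'   \code{lat}, \code{n} and optionally \code{cluster}
#' @return \code{df}, invisibly checked: coordinates finite and in range,
#'   cluster labels (when present) covering 1..K without gaps
#' @export
populationFrame <- function(df) {
    need <- c("population", "lon", "lat", "n")
    if (!all(need %in% colnames(df)))
        stop("population frame needs columns: ",
             paste(need, collapse = ", "))
    stopifnot(all(is.finite(df$lon)), all(is.finite(df$lat)),
              all(abs(df$lat) <= 90), all(abs(df$lon) <= 180),
              !anyDuplicated(df$population))
    if ("cluster" %in% colnames(df) && !all(is.na(df$cluster))) {
        cl <- as.integer(df$cluster)
        if (anyNA(cl) || !setequal(unique(cl), seq_len(max(cl))))
            stop("cluster labels must cover 1..K with no gaps")
        df$cluster <- cl
    }
    df
}

#' Simulate population locations for a synthetic study
#'
#' Cluster centres are spread along the longitudinal axis of the bounding
#' box; populations are scattered around their centre and clipped to the
#' box interior.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param seed integer RNG seed
#' @return a population frame (see \code{\link{populationFrame}})
#' @export
simulatePopulations <- function(cfg, seed = 1L) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(seed)
    b <- cfg$bbox
    cx <- seq(b[1] + 0.15 * (b[2] - b[1]), b[2] - 0.15 * (b[2] - b[1]),
              length.out = cfg$K)
    cy <- runif(cfg$K, b[3] + 0.25 * (b[4] - b[3]),
                b[4] - 0.25 * (b[4] - b[3]))
    cluster <- rep(seq_len(cfg$K), cfg$popsPerCluster)
    npops <- sum(cfg$popsPerCluster)
    lon <- pmin(pmax(cx[cluster] + stats::rnorm(npops, 0, 0.08 * (b[2] - b[1])),
                     b[1] + cfg$cellsize), b[2] - cfg$cellsize)
    lat <- pmin(pmax(cy[cluster] + stats::rnorm(npops, 0, 0.10 * (b[4] - b[3])),
                     b[3] + cfg$cellsize), b[4] - cfg$cellsize)
    populationFrame(data.frame(
        population = sprintf("P%02d", seq_len(npops)),
        lon = lon, lat = lat, n = cfg$nPerPop, cluster = cluster,
        stringsAsFactors = FALSE))
}

# Balding-Nichols style draw: beta around mean p with drift intensity F
.rbetaBN <- function(n, p, F) {
    if (F < 1e-8) return(rep(p, length.out = n))
    rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a band matrix with cluster structure and seeded rare loci
#'
#' Neutral loci follow a two-level Balding-Nichols model: cluster means
#' drift around an ancestral frequency, population frequencies drift around
#' their cluster mean, with the two levels composed so the intraclass
#' correlation of population band frequencies equals \code{fstTarget}.
#' Rare loci are seeded in few populations (preferentially within one home
#' cluster) at low frequency, and re-drawn after sampling until their
#' realized overall frequency and occupancy satisfy the strict rarity
#' thresholds. When a per-population climate covariate is supplied,
#' \code{nAdaptiveLoci} loci get frequencies
#' \eqn{\mathrm{logit}^{-1}(\alpha + \beta z)} of the standardized
#' covariate. Individuals are Bernoulli draws per locus.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param seed integer RNG seed
#' @param popFrame optional population frame (default: simulated from
#'   \code{cfg} with the same seed)
#' @param covariate optional numeric per-population climate value enabling
#'   the adaptive loci
#' @return list with \code{bm} (\linkS4class{BandMatrix}), \code{popFrame}
#'   and \code{truth} (cluster labels, rare/adaptive locus ids, the
#'   population frequency matrix and the drift parameters)
#' @export
simulateBandMatrix <- function(cfg, seed = 1L, popFrame = NULL,
                               covariate = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(popFrame))
        popFrame <- simulatePopulations(cfg, seed)
    set.seed(seed + 1L)
    npops <- nrow(popFrame)
    sizes <- popFrame$n
    N <- sum(sizes)
    nRare <- round(cfg$rareFraction * cfg$nLoci)
    nAdapt <- if (is.null(covariate)) 0L else as.integer(cfg$nAdaptiveLoci)
    nNeutral <- cfg$nLoci - nRare - nAdapt
    if (nNeutral < 0)
        stop("rare_fraction and adaptive loci exceed the locus count")
    if (nRare > 0) {
        if (N < 1 / cfg$rareMaxFreq)
            stop("infeasible rare fraction: even a single carrier exceeds ",
                 "the overall rare-frequency threshold at this sample size")
        if (1 / npops >= cfg$rareMaxOcc)
            stop("infeasible rare fraction: occupancy of one population ",
                 "already reaches the rare-occupancy threshold")
    }
    Fb <- 1 - (1 - cfg$fstTarget)^cfg$clusterShare
    Fw <- 1 - (1 - cfg$fstTarget)^(1 - cfg$clusterShare)
    cluster <- popFrame$cluster
    freq <- matrix(0, npops, cfg$nLoci)

    # populations differ in diversity (real surveys couple high gene
    # diversity with richer rare-band complements): a per-population
    # factor scales drift down and attracts rare-band placement
    divFac <- exp(runif(npops, -cfg$divHet, cfg$divHet))
    divFac <- divFac * mean(1 / divFac)  # keep mean drift at the target
    Fpop <- pmin(0.95, Fw / divFac)
    if (nNeutral > 0) {
        pAnc <- runif(nNeutral, 0.1, 0.9)
        for (l in seq_len(nNeutral)) {
            cm <- .rbetaBN(cfg$K, pAnc[l], Fb)
            freq[, l] <- vapply(seq_len(npops), function(k)
                .rbetaBN(1, cm[cluster[k]], Fpop[k]), numeric(1))
        }
    }
    rareIdx <- if (nRare > 0) nNeutral + seq_len(nRare) else integer(0)
    maxOcc <- max(1L, ceiling(npops * cfg$rareMaxOcc) - 1L)
    wsample <- function(idx, size, w) {
        if (size >= length(idx)) return(idx)
        idx[sample.int(length(idx), size, prob = w)]
    }
    drawRare <- function(home, shrink = 1) {
        m <- sample.int(maxOcc, 1L)
        inHome <- which(cluster == home)
        occ <- if (length(inHome) >= m)
                   wsample(inHome, m, divFac[inHome]^2)
               else {
                   rest <- setdiff(seq_len(npops), inHome)
                   c(inHome, wsample(rest, m - length(inHome),
                                     divFac[rest]^2))
               }
        fcap <- 0.8 * cfg$rareMaxFreq * N / sum(sizes[occ])
        f <- rep(0, npops)
        # within-population frequency largely independent of occupancy so
        # loss probabilities span the frequency axis at every N
        f[occ] <- runif(m, 0.05, min(0.25, fcap)) * shrink
        f
    }
    homes <- rep_len(seq_len(cfg$K), nRare)
    for (j in seq_along(rareIdx))
        freq[, rareIdx[j]] <- drawRare(homes[j])
    adaptIdx <- if (nAdapt > 0) nNeutral + nRare + seq_len(nAdapt)
                else integer(0)
    if (nAdapt > 0) {
        z <- as.numeric(scale(covariate))
        if (any(!is.finite(z))) z <- rep(0, npops)
        alpha <- runif(nAdapt, -0.5, 0.5)
        for (j in seq_len(nAdapt))
            freq[, adaptIdx[j]] <- plogis(alpha[j] + cfg$beta * z)
    }

    drawLocus <- function(f) {
        unlist(lapply(seq_len(npops),
                      function(k) rbinom(sizes[k], 1L, f[k])))
    }
    m <- vapply(seq_len(cfg$nLoci), function(l) drawLocus(freq[, l]),
                integer(N))
    popOf <- rep(popFrame$population, sizes)

    # re-assert seeded rarity on the realized sample; shrink and redraw
    # violators, falling back to a single carrier in one population
    for (j in seq_along(rareIdx)) {
        l <- rareIdx[j]
        for (it in seq_len(25L)) {
            carriers <- sum(m[, l])
            occFrac <- length(unique(popOf[m[, l] == 1L])) / npops
            if (carriers >= 1L && carriers / N < cfg$rareMaxFreq &&
                occFrac < cfg$rareMaxOcc) break
            if (it < 25L) {
                freq[, l] <- drawRare(homes[j], shrink = 0.8^it)
                m[, l] <- drawLocus(freq[, l])
            } else {
                m[, l] <- 0L
                pick <- which(popOf == popFrame$population[
                    which(cluster == homes[j])[1]])[1]
                m[pick, l] <- 1L
            }
        }
    }
    # a band never observed would not be in a real scored matrix
    for (l in setdiff(seq_len(cfg$nLoci), rareIdx)) {
        it <- 0L
        while (sum(m[, l]) == 0L && it < 10L) {
            m[, l] <- drawLocus(pmax(freq[, l], 0.02))
            it <- it + 1L
        }
        if (sum(m[, l]) == 0L) m[sample.int(N, 1L), l] <- 1L
    }

    locusIds <- sprintf("L%03d", seq_len(cfg$nLoci))
    dimnames(m) <- list(paste0(popOf, "_", unlist(lapply(sizes, seq_len))),
                        locusIds)
    truth <- list(cluster = setNames(cluster, popFrame$population),
                  rareLoci = locusIds[rareIdx],
                  adaptiveLoci = locusIds[adaptIdx],
                  popFreq = `dimnames<-`(freq, list(popFrame$population,
                                                    locusIds)),
                  divFactor = setNames(divFac, popFrame$population),
                  Fb = Fb, Fw = Fw)
    list(bm = BandMatrix(m, population = popOf), popFrame = popFrame,
         truth = truth)
}

# separable 1-2-1 smoothing pass over a matrix (reflective edges)
.smooth2d <- function(m, passes = 2L) {
    for (i in seq_len(passes)) {
        p <- rbind(m[1, ], m, m[nrow(m), ])
        m <- (p[seq_len(nrow(m)), ] + 2 * p[1 + seq_len(nrow(m)), ] +
              p[2 + seq_len(nrow(m)), ]) / 4
        p <- cbind(m[, 1], m, m[, ncol(m)])
        m <- (p[, seq_len(ncol(m))] + 2 * p[, 1 + seq_len(ncol(m))] +
              p[, 2 + seq_len(ncol(m))]) / 4
    }
    m
}

#' Simulate a bioclimatic raster stack and population covariates
#'
#' Each layer is a smooth spatial field: a random low-order polynomial
#' trend in the (standardized) grid coordinates plus smoothed Gaussian
#' noise, standardized to zero mean and unit variance. Layer 1 is the
#' designated adaptive gradient used by \code{\link{simulateStudy}}.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param popFrame population frame giving the locations to sample
#' @param seed integer RNG seed
#' @return list with \code{stack} (\linkS4class{ClimateStack}) and
#'   \code{popCovariates} (populations x layers matrix)
#' @export
simulateClimate <- function(cfg, popFrame, seed = 1L) {
    stopifnot(inherits(cfg, "SimConfig"), nrow(popFrame) >= 1)
    set.seed(seed)
    nr <- cfg$gridDim[1]; nc <- cfg$gridDim[2]
    u <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
    v <- matrix(seq(1, -1, length.out = nr), nr, nc)
    layers <- list()
    for (k in seq_len(cfg$nLayers)) {
        b <- stats::rnorm(5)
        trend <- b[1] * u + b[2] * v + b[3] * u * v + b[4] * u^2 +
            b[5] * v^2
        noise <- .smooth2d(matrix(stats::rnorm(nr * nc, 0, 1), nr, nc), 3L)
        f <- trend + 0.6 * noise
        layers[[sprintf("Bio%d", k)]] <- (f - mean(f)) / sd(f)
    }
    stack <- ClimateStack(layers, xll = cfg$bbox[1], yll = cfg$bbox[3],
                          cellsize = cfg$cellsize)
    cov <- extractAt(stack, popFrame$lon, popFrame$lat)
    rownames(cov) <- popFrame$population
    list(stack = stack, popCovariates = cov)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates \code{\link{simulatePopulations}},
#' \code{\link{simulateClimate}} and \code{\link{simulateBandMatrix}}: the
#' adaptive loci follow layer \code{Bio1} sampled at the population
#' locations. Repeated calls with the same seed are bit-identical.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param seed integer RNG seed (derived stage seeds stay below 2^31)
#' @return list with \code{bm}, \code{popFrame}, \code{stack},
#'   \code{popCovariates} and \code{truth}
#' @export
simulateStudy <- function(cfg = simConfig(), seed = 1L) {
    seed <- as.integer(seed) %% 2000000000L
    pf <- simulatePopulations(cfg, seed)
    clim <- simulateClimate(cfg, pf, seed + 1009L)
    sim <- simulateBandMatrix(cfg, seed + 2003L, popFrame = pf,
                              covariate = clim$popCovariates[, 1])
    sim$truth$adaptiveLayer <- layerNames(clim$stack)[1]
    c(sim, clim)
}
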