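#' Pairwise genetic distances between individuals
#'
#' Proportion of mismatched loci between every pair of individuals.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @return symmetric matrix with zero diagonal, entries in [0, 1]
#' @export
geneticDistances <- function(bm) {
    m <- bandValues(bm)
    L <- ncol(m)
    # mismatches = x(1-y) + (1-x)y expressed with cross products
    ones <- tcrossprod(m, 1 - m)
    d <- (ones + t(ones)) / L
    dimnames(d) <- list(rownames(m), rownames(m))
    diag(d) <- 0
    d
}

#' Pairwise great-circle distances between individuals
#'
#' Haversine distances (sphere of radius 6371 km) between the population
#' coordinates of every pair of individuals (individuals of the same
#' population are at distance zero).
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param popFrame population frame with \code{population}, \code{lon},
#'   \code{lat}
#' @return symmetric matrix of distances in km
#' @export
geographicDistances <- function(bm, popFrame) {
    pop <- as.character(populations(bm))
    idx <- match(pop, popFrame$population)
    if (anyNA(idx)) stop("populations missing from the population frame")
    pts <- cbind(popFrame$lon, popFrame$lat)[idx, , drop = FALSE]
    n <- nrow(pts)
    d <- matrix(0, n, n, dimnames = list(rownames(bandValues(bm)),
                                         rownames(bandValues(bm))))
    for (i in seq_len(n - 1)) {
        j <- (i + 1):n
        d[i, j] <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                            pts[j, , drop = FALSE],
                                            r = 6371) # km
        d[j, i] <- d[i, j]
    }
    d
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the lower triangles of the genetic distance
#' matrix and the natural log of geographic distance (log(km + 1), the +1
#' guarding zero within-population distances), with a permutation p-value
#' using the +1/(n+1) convention: p = (number of permuted r >= observed
#' + 1)/(nPerm + 1).
#'
#' @param genetic,geographic conformable symmetric distance matrices (see
#'   \code{\link{geneticDistances}}, \code{\link{geographicDistances}})
#' @param nPerm number of permutations (>= 99)
#' @param seed integer RNG seed
#' @param logGeo log-transform the geographic matrix (default TRUE)
#' @return list with \code{r}, \code{p} and \code{nPerm}
#' @export
mantelTest <- function(genetic, geographic, nPerm = 999, seed = 1L,
                       logGeo = TRUE) {
    stopifnot(identical(dim(genetic), dim(geographic)), nPerm >= 99)
    g <- if (logGeo) log(geographic + 1) else geographic
    lt <- lower.tri(g)
    if (sd(genetic[lt]) == 0 || sd(g[lt]) == 0)
        stop("constant distance matrix: Mantel r undefined")
    set.seed(seed)
    fit <- vegan::mantel(as.dist(genetic), as.dist(g),
                         permutations = nPerm)
    list(r = unname(fit$statistic), p = unname(fit$signif), nPerm = nPerm)
}

#' Spatial autocorrelation over geographic distance classes
#'
#' Pairs of individuals are binned into \code{nClasses} equal-pair-count
#' classes of geographic distance; the statistic per class is the average
#' genetic distance Ay among its pairs. Significance per class is a
#' two-sided permutation test shuffling individual locations (joint row
#' and column permutation of the geographic matrix), p-values with the
#' +1/(n+1) convention. Under isolation by distance Ay increases with
#' class rank.
#'
#' @param genetic,geographic symmetric distance matrices
#' @param nClasses number of distance classes (>= 2)
#' @param nPerm permutation replicates
#' @param seed integer RNG seed
#' @return data.frame per class: pair count, distance-class upper bound,
#'   \code{Ay} and \code{p}
#' @export
spatialAutocorrelation <- function(genetic, geographic, nClasses = 5,
                                   nPerm = 1000, seed = 1L) {
    stopifnot(identical(dim(genetic), dim(geographic)), nClasses >= 2)
    lt <- which(lower.tri(geographic))
    geo <- geographic[lt]
    gen <- genetic[lt]
    br <- quantile(geo, probs = seq(0, 1, length.out = nClasses + 1))
    cls <- cut(geo, breaks = unique(br), include.lowest = TRUE)
    if (nlevels(cls) < nClasses)
        warning("tied distances reduced the number of usable classes to ",
                nlevels(cls))
    if (any(table(cls) == 0))
        stop("empty distance class: reduce nClasses")
    obs <- as.numeric(tapply(gen, cls, mean))
    set.seed(seed)
    n <- nrow(genetic)
    ge <- vapply(seq_len(nPerm), function(i) {
        perm <- sample.int(n)
        tapply(genetic[perm, perm][lt], cls, mean)
    }, numeric(nlevels(cls)))
    ge <- matrix(ge, nrow = nlevels(cls))
    pHi <- (rowSums(ge >= obs - 1e-12) + 1) / (nPerm + 1)
    pLo <- (rowSums(ge <= obs + 1e-12) + 1) / (nPerm + 1)
    data.frame(class = seq_len(nlevels(cls)),
               upper = as.numeric(tapply(geo, cls, max)),
               nPairs = as.integer(table(cls)),
               Ay = as.numeric(obs),
               p = pmin(1, 2 * pmin(pHi, pLo)))
}

# AMOVA variance components on squared Euclidean phenotype distances
.amovaComponents <- function(d2, grouping) {
    n <- length(grouping)
    sizes <- table(grouping)
    k <- length(sizes)
    ssdTotal <- sum(d2) / (2 * n)
    ssdWithin <- 0
    for (g in names(sizes)) {
        idx <- which(grouping == g)
        ssdWithin <- ssdWithin + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssdAmong <- ssdTotal - ssdWithin
    dfA <- k - 1
    dfW <- n - k
    sigmaW <- ssdWithin / dfW
    nc <- (n - sum(sizes^2) / n) / dfA
    sigmaA <- (ssdAmong / dfA - sigmaW) / nc
    phi <- sigmaA / (sigmaA + sigmaW)
    list(sigmaA = sigmaA, sigmaW = sigmaW, phi = phi,
         ssdAmong = ssdAmong, ssdWithin = ssdWithin)
}

#' AMOVA Phi-ST on binary band phenotypes
#'
#' Analysis of molecular variance on pairwise squared Euclidean distances
#' between individual 0/1 phenotype vectors (for binary data the squared
#' Euclidean distance is the mismatch count). Phi-ST =
#' sigma2_among / (sigma2_among + sigma2_within); the p-value permutes
#' individuals among populations (+1/(n+1) convention).
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param grouping optional factor per individual (default: populations)
#' @param nPerm permutations for the p-value; 0 skips the test
#' @param seed integer RNG seed
#' @return list with \code{phi}, \code{sigmaAmong}, \code{sigmaWithin},
#'   \code{p} (NA when nPerm = 0) and \code{nPerm}
#' @export
phiSt <- function(bm, grouping = NULL, nPerm = 0, seed = 1L) {
    if (is.null(grouping)) grouping <- populations(bm)
    grouping <- as.character(grouping)
    sizes <- table(grouping)
    if (length(sizes) < 2) stop("need >= 2 groups")
    if (any(sizes < 2)) stop("every group needs >= 2 individuals")
    m <- bandValues(bm)
    sq <- rowSums(m)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(m) # squared Euclidean
    comp <- .amovaComponents(d2, grouping)
    p <- NA_real_
    if (nPerm > 0) {
        set.seed(seed)
        obs <- comp$phi
        exceed <- sum(vapply(seq_len(nPerm), function(i) {
            .amovaComponents(d2, sample(grouping))$phi >= obs - 1e-12
        }, logical(1)))
        p <- (exceed + 1) / (nPerm + 1)
    }
    list(phi = comp$phi, sigmaAmong = comp$sigmaA,
         sigmaWithin = comp$sigmaW, p = p, nPerm = nPerm)
}

#' K-means surrogate for Bayesian genetic clustering
#'
#' Cluster labels are normally an input (e.g. from a Bayesian structure
#' analysis); this surrogate k-means on the population band-frequency
#' vectors lets synthetic pipelines run end to end. When \code{K} is not
#' given it is chosen from 2..(number of populations - 1) by maximizing
#' the mean silhouette width.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param K number of clusters, or NULL to select by silhouette
#' @param nStart random restarts for k-means
#' @param seed integer RNG seed
#' @return named integer cluster label (1..K) per population, relabelled
#'   in order of first appearance
#' @export
surrogateClusters <- function(bm, K = NULL, nStart = 50, seed = 1L) {
    bf <- bandFrequencies(bm)
    X <- t(bf$perPop)                        # populations x loci
    npops <- nrow(X)
    if (!is.null(K)) {
        stopifnot(K >= 1, K <= npops)
        if (K > npops) stop("K exceeds the number of populations")
    }
    set.seed(seed)
    fitK <- function(k) {
        if (k == npops) return(seq_len(npops))
        kmeans(X, centers = k, nstart = nStart, iter.max = 100)$cluster
    }
    if (is.null(K)) {
        cand <- 2:max(2, npops - 1)
        sil <- vapply(cand, function(k) {
            cl <- fitK(k)
            mean(cluster::silhouette(cl, dist(X))[, "sil_width"])
        }, numeric(1))
        K <- cand[which.max(sil)]
    }
    cl <- if (K == 1) rep(1L, npops) else fitK(K)
    # stable labels: number clusters by first appearance
    relabel <- match(cl, unique(cl))
    setNames(as.integer(relabel), rownames(X))
}
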