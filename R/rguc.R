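#' Probability that a rare band is lost when sampling
#'
#' L = (1 - p)^(2N) for a band of carrier frequency p present in N
#' populations: the chance that a sample misses the band entirely.
#'
#' @param p band frequency in (0, 1)
#' @param N occupancy (number of populations carrying the band), integer
#'   >= 1
#' @return numeric loss probability in (0, 1]
#' @export
lossProbability <- function(p, N) {
    stopifnot(all(N >= 1), all(N == round(N)))
    if (any(p <= 0 | p >= 1))
        stop("band frequency must lie strictly between 0 and 1")
    (1 - p)^(2 * N)
}

#' Identify rare bands
#'
#' A band is rare when its overall carrier frequency is strictly below
#' \code{freqThresh} and it occurs in strictly fewer than
#' \code{occThresh} of the populations. For each rare band the observed
#' loss probability Lo uses the observed occupancy N and the expected
#' loss probability Le uses N = 1 (sampling a single population), both at
#' the band's mean frequency across the populations where it occurs.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param freqThresh overall-frequency threshold (default 0.10)
#' @param occThresh occupancy threshold as a fraction of populations
#'   (default 0.40)
#' @return data.frame per rare band: \code{locus}, overall frequency
#'   \code{p}, occupancy \code{N}, \code{meanFreqOccupied}, \code{Lo},
#'   \code{Le} (possibly zero rows)
#' @export
findRareBands <- function(bm, freqThresh = 0.10, occThresh = 0.40) {
    stopifnot(freqThresh > 0, freqThresh < 1, occThresh > 0, occThresh < 1)
    bf <- bandFrequencies(bm)
    npops <- ncol(bf$perPop)
    occ <- rowSums(bf$perPop > 0)
    rare <- which(bf$overall < freqThresh & occ / npops < occThresh &
                  occ >= 1)
    meanOcc <- vapply(rare, function(l) {
        f <- bf$perPop[l, ]
        mean(f[f > 0])
    }, numeric(1))
    data.frame(locus = rownames(bf$perPop)[rare],
               p = as.numeric(bf$overall[rare]),
               N = as.integer(occ[rare]),
               meanFreqOccupied = as.numeric(meanOcc),
               Lo = lossProbability(meanOcc, occ[rare]),
               Le = lossProbability(meanOcc, 1L),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' R-value from loss-probability regressions
#'
#' Ordinary least-squares regressions (with intercept) of -ln(L) on the
#' mean band frequency over occupied populations, fitted separately for
#' the observed (Lo, observed occupancy) and expected (Le, single
#' population) loss probabilities. The R-value — the proportion of rare
#' bands captured when sampling a single population — is the ratio of the
#' expected to the observed slope, so R is 1 when every band sits in one
#' population and decreases as occupancy grows.
#'
#' @param records data.frame from \code{\link{findRareBands}} (>= 3 rows
#'   with non-constant mean frequency)
#' @return list with \code{slopeObs}, \code{slopeExp}, \code{R} (in
#'   (0, 1]) and \code{Rpct}
#' @export
rValue <- function(records) {
    if (nrow(records) < 3)
        stop("need >= 3 rare bands to fit the loss regressions")
    x <- records$meanFreqOccupied
    if (sd(x) == 0) stop("mean band frequencies are constant")
    slopeObs <- unname(coef(lm(-log(records$Lo) ~ x))[2])
    slopeExp <- unname(coef(lm(-log(records$Le) ~ x))[2])
    if (slopeObs <= 0 || slopeExp <= 0)
        warning("non-positive loss-regression slope; R-value unreliable")
    R <- slopeExp / slopeObs
    list(slopeObs = slopeObs, slopeExp = slopeExp, R = R, Rpct = 100 * R)
}

#' Assign each rare band to its preferred sampling area (PSA)
#'
#' The PSA of a rare band is the genetic cluster where capturing it is
#' most likely: the cluster maximizing the fraction of its populations
#' that carry the band, ties broken by the number of carrier individuals
#' in the cluster, then by the lower cluster index (deterministic,
#' reported in the \code{tie} column).
#'
#' @param records data.frame from \code{\link{findRareBands}}
#' @param clusters named integer cluster label per population (1..K)
#' @param bm the \linkS4class{BandMatrix} the records came from
#' @return \code{records} with columns \code{psa} and \code{tie} appended
#' @export
assignPSA <- function(records, clusters, bm) {
    pops <- popNames(bm)
    if (!all(pops %in% names(clusters)))
        stop("cluster labels must cover all populations")
    cl <- clusters[pops]
    K <- max(cl)
    m <- bandValues(bm)
    pop <- populations(bm)
    counts <- rowsum(m, pop)[pops, , drop = FALSE] # populations x loci
    psa <- integer(nrow(records))
    tie <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
        cnt <- counts[, records$locus[i]]
        if (sum(cnt) == 0) stop("band ", records$locus[i],
                                " absent everywhere")
        popFrac <- vapply(seq_len(K),
                          function(k) mean(cnt[cl == k] > 0), numeric(1))
        carriers <- vapply(seq_len(K),
                           function(k) sum(cnt[cl == k]), numeric(1))
        best <- which(popFrac == max(popFrac))
        if (length(best) > 1) {
            best <- best[carriers[best] == max(carriers[best])]
            tie[i] <- length(best) > 1
        }
        psa[i] <- min(best)
    }
    records$psa <- psa
    records$tie <- tie
    records
}

#' Number of populations needed to retain a diversity target
#'
#' Solves P = 1 - FST^n for n: the number of populations whose joint
#' sampling retains a fraction P of the total genetic diversity given
#' species- or cluster-level differentiation FST. The integer count is
#' always rounded up so conservation goals are not underestimated.
#'
#' @param fst differentiation in (0, 1)
#' @param P diversity target in (0, 1)
#' @return list with \code{nReal} and \code{nInteger} (= ceiling(nReal))
#' @export
nPopulations <- function(fst, P) {
    if (any(fst <= 0 | fst >= 1))
        stop("FST must lie strictly between 0 and 1")
    stopifnot(all(P > 0), all(P < 1))
    nReal <- log(1 - P) / log(fst)
    list(nReal = nReal, nInteger = as.integer(ceiling(nReal - 1e-12)))
}

#' Optimal sampling proportions across genetic clusters
#'
#' Combines the PSA shares (fraction of rare bands assigned to each
#' cluster) with the per-cluster R-values. The default strategy averages
#' the normalized PSA shares and normalized R-values and renormalizes;
#' alternative combination rules can be plugged in via \code{strategy}.
#'
#' @param psaShares numeric per cluster, summing to 1 (renormalized if
#'   not)
#' @param rValues numeric per cluster in (0, 1]
#' @param strategy function(shares, r) -> unnormalized weights; default
#'   the arithmetic-mean rule
#' @return named list: \code{proportions} (sums to 1) and
#'   \code{strategy} name
#' @export
optimalProportions <- function(psaShares, rValues,
                               strategy = NULL) {
    if (sum(psaShares) <= 0 || sum(rValues) <= 0)
        stop("shares and R-values must have positive sums")
    stopifnot(length(psaShares) == length(rValues))
    if (is.null(strategy)) {
        name <- "mean(normalized PSA share, normalized R-value)"
        strategy <- function(s, r) (s / sum(s) + r / sum(r)) / 2
    } else {
        name <- deparse(substitute(strategy))
    }
    w <- strategy(psaShares, rValues)
    if (any(w < 0)) stop("strategy produced negative weights")
    list(proportions = w / sum(w), strategy = name)
}

# bands captured (any carrier) by a set of populations
.captureStats <- function(bm, selected, rareLoci) {
    bf <- bandFrequencies(bm)
    present <- bf$perPop[, selected, drop = FALSE] > 0
    everywhere <- rowSums(bf$perPop > 0) > 0
    capAll <- 100 * sum(rowSums(present) > 0) / sum(everywhere)
    capRare <- if (length(rareLoci) == 0) NA_real_ else {
        pr <- present[rareLoci, , drop = FALSE]
        100 * mean(rowSums(pr) > 0)
    }
    c(allBands = capAll, rareBands = capRare)
}

#' Select relevant genetic units for conservation (RGUCs)
#'
#' Within each genetic cluster the \code{nPerCluster[k]} populations with
#' the highest Nei gene diversity are selected (DW rarity breaks ties,
#' then label order; deterministic). Capture statistics report the
#' percentage of all bands and of rare bands present in at least one
#' selected population.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param descriptors data.frame from \code{\link{popDescriptors}}
#' @param clusters named integer cluster label per population
#' @param nPerCluster integer per cluster (recycled if length 1)
#' @param rareLoci character vector of rare-band locus ids (for the rare
#'   capture statistic), e.g. \code{findRareBands(bm)$locus}
#' @return list with \code{selected} (character per cluster),
#'   \code{capture} (percentages) and the selection table
#' @export
selectRGUCs <- function(bm, descriptors, clusters, nPerCluster,
                        rareLoci = character(0)) {
    pops <- descriptors$population
    cl <- clusters[pops]
    K <- max(cl)
    nPerCluster <- rep_len(nPerCluster, K)
    chosen <- character(0)
    perCluster <- vector("list", K)
    for (k in seq_len(K)) {
        members <- descriptors[cl == k, , drop = FALSE]
        if (nPerCluster[k] > nrow(members))
            stop("cluster ", k, " has only ", nrow(members),
                 " populations; cannot select ", nPerCluster[k])
        ord <- order(-members$neiGD, -members$dw, members$population)
        perCluster[[k]] <- members$population[ord[seq_len(nPerCluster[k])]]
        chosen <- c(chosen, perCluster[[k]])
    }
    list(selected = chosen, perCluster = perCluster,
         capture = .captureStats(bm, chosen, rareLoci))
}

#' Random-selection capture baseline
#'
#' Mean capture percentages when the same number of populations per
#' cluster is drawn uniformly at random (without replacement), over
#' \code{reps} repetitions.
#'
#' @inheritParams selectRGUCs
#' @param reps repetitions (default 100)
#' @param seed integer RNG seed
#' @return list with \code{allBands} and \code{rareBands} mean capture
#'   percentages and the per-rep matrix
#' @export
randomCaptureBaseline <- function(bm, clusters, nPerCluster,
                                  rareLoci = character(0), reps = 100,
                                  seed = 1L) {
    stopifnot(reps >= 1)
    pops <- popNames(bm)
    cl <- clusters[pops]
    K <- max(cl)
    nPerCluster <- rep_len(nPerCluster, K)
    set.seed(seed)
    draws <- vapply(seq_len(reps), function(r) {
        sel <- unlist(lapply(seq_len(K), function(k) {
            members <- pops[cl == k]
            members[sample.int(length(members), nPerCluster[k])]
        }))
        .captureStats(bm, sel, rareLoci)
    }, numeric(2))
    list(allBands = mean(draws["allBands", ]),
         rareBands = mean(draws["rareBands", ]),
         perRep = t(draws))
}
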