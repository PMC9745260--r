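#' Nei's gene diversity for dominant markers
#'
#' Default (\code{method = "phenotype"}): the band-phenotype estimator
#' with small-sample correction, GD = mean over loci of
#' \eqn{\frac{n}{n-1} 2 f (1-f)} where f is the within-population band
#' carrier frequency and n the population size. Loci monomorphic
#' species-wide are included in the mean. \code{method = "lynch"} instead
#' estimates allele frequencies by the square-root (null homozygote)
#' route with Taylor bias correction and averages expected heterozygosity
#' \eqn{2\hat p\hat q}; the two routes differ and the phenotype form is
#' the documented default.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param method \code{"phenotype"} (default) or \code{"lynch"}
#' @return named numeric, one gene-diversity value per population
#' @export
neiGeneDiversity <- function(bm, method = c("phenotype", "lynch")) {
    method <- match.arg(method)
    bf <- bandFrequencies(bm)
    n <- bf$popSizes
    if (any(n < 2))
        stop("gene diversity needs >= 2 individuals per population")
    if (method == "phenotype") {
        gd <- vapply(seq_along(n), function(k) {
            f <- bf$perPop[, k]
            mean((n[k] / (n[k] - 1)) * 2 * f * (1 - f))
        }, numeric(1))
    } else {
        af <- alleleFrequencies(bm)
        gd <- vapply(seq_along(n),
                     function(k) mean(2 * af$p[, k] * af$q[, k]),
                     numeric(1))
    }
    setNames(gd, names(n))
}

#' Frequency down-weighted marker value (DW rarity index)
#'
#' For each population, DW sums over bands the population's share of the
#' band's total occurrences: (carriers in the population) / (carriers in
#' the whole data set). A band private to one population contributes
#' exactly 1 there; bands absent from the data set contribute 0, so the
#' per-band contributions across populations sum to 1 whenever the band is
#' present.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @return named numeric, one DW value per population
#' @export
dwRarity <- function(bm) {
    m <- bandValues(bm)
    pop <- populations(bm)
    counts <- rowsum(m, pop)                 # populations x loci
    tot <- colSums(counts)
    share <- sweep(counts, 2, pmax(tot, 1), "/")
    share[, tot == 0] <- 0
    setNames(rowSums(share), rownames(counts))
}

#' Per-population diversity and rarity descriptors
#'
#' The classic AFLP summary table: number of bands present
#' (\code{fragTot}), percentage of those that are polymorphic within the
#' population (0 < f < 1; \code{fragPoly}), number of private bands
#' (\code{fragPriv}), Nei's gene diversity (\code{neiGD}) and the DW
#' rarity index (\code{dw}).
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param gdMethod estimator passed to \code{\link{neiGeneDiversity}}
#' @return data.frame with one row per population
#' @export
popDescriptors <- function(bm, gdMethod = "phenotype") {
    bf <- bandFrequencies(bm)
    f <- bf$perPop                           # loci x populations
    present <- f > 0
    fragTot <- colSums(present)
    fragPoly <- 100 * colSums(f > 0 & f < 1) / pmax(fragTot, 1)
    nPopsWith <- rowSums(present)
    fragPriv <- colSums(present & nPopsWith == 1)
    data.frame(population = colnames(f),
               fragTot = as.integer(fragTot),
               fragPoly = as.numeric(fragPoly),
               fragPriv = as.integer(fragPriv),
               neiGD = as.numeric(neiGeneDiversity(bm, gdMethod)),
               dw = as.numeric(dwRarity(bm)),
               stringsAsFactors = FALSE)
}

#' Inverse-distance-weighted surface of a per-population value
#'
#' Plain IDW interpolation (power 2 by default) of population values onto
#' the grid of a \linkS4class{ClimateStack}, exact at the cell containing
#' each population. Intended for visual inspection of diversity/rarity
#' patterns, not for inference.
#'
#' @param values named numeric, one value per population
#' @param popFrame population frame with \code{population}, \code{lon},
#'   \code{lat}
#' @param stack a \linkS4class{ClimateStack} supplying the grid
#' @param power IDW exponent
#' @return numeric matrix on the stack's grid (masked cells NA)
#' @export
interpolateSurface <- function(values, popFrame, stack, power = 2) {
    stopifnot(nrow(popFrame) >= 3, is(stack, "ClimateStack"))
    v <- values[popFrame$population]
    if (anyNA(v)) stop("values must cover every population")
    key <- paste(popFrame$lon, popFrame$lat)
    if (any(duplicated(key))) {
        for (k in unique(key[duplicated(key)]))
            if (length(unique(v[key == k])) > 1)
                stop("coincident populations with different values")
    }
    cc <- cellCoords(stack)
    d <- gridDim(stack)
    # cell containing a population takes that population's value exactly
    col <- floor((popFrame$lon - stack@xll) / stack@cellsize) + 1L
    row <- d[1] - floor((popFrame$lat - stack@yll) / stack@cellsize)
    popCell <- (col - 1L) * d[1] + row       # column-major index
    out <- matrix(NA_real_, d[1], d[2])
    # squared-degree planar distance is adequate at map scale for a
    # display surface
    for (i in seq_len(nrow(cc))) {
        if (!stack@mask[cc$row[i], cc$col[i]]) next
        idx <- (cc$col[i] - 1L) * d[1] + cc$row[i]
        hit <- popCell == idx
        if (any(hit)) {
            out[cc$row[i], cc$col[i]] <- mean(v[hit])
        } else {
            dd <- (popFrame$lon - cc$lon[i])^2 +
                (popFrame$lat - cc$lat[i])^2
            out[cc$row[i], cc$col[i]] <-
                sum(v / dd^(power / 2)) / sum(1 / dd^(power / 2))
        }
    }
    out
}
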