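#' Allele frequencies from dominant band phenotypes
#'
#' Square-root (null-homozygote) estimator for dominant biallelic
#' markers: with band-phenotype frequency x of the recessive (band-absent)
#' class per population, the null-allele frequency is
#' \eqn{\hat q = \sqrt{x}\,(1 + V(x)/(8x^2))} with the first-order Taylor
#' bias correction of the square root, \eqn{V(x) = x(1-x)/n}; the
#' correction is dropped below the usual x < 3/n reliability bound.
#' Populations fixed for the band (x = 0) are clamped to x = 1/(2n + 1)
#' so no allele is estimated as absent; the number of clamped cells is
#' reported via an attribute.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @return list with matrices \code{p} (band allele) and \code{q} (null
#'   allele), loci x populations, and attribute \code{clamped}
#' @export
alleleFrequencies <- function(bm) {
    bf <- bandFrequencies(bm)
    x <- 1 - bf$perPop                       # null phenotype frequency
    n <- bf$popSizes
    clamped <- 0L
    for (k in seq_along(n)) {
        fix <- x[, k] <= 0
        clamped <- clamped + sum(fix)
        x[fix, k] <- 1 / (2 * n[k] + 1)
    }
    v <- sweep(x * (1 - x), 2, n, "/")
    corr <- 1 + v / (8 * x^2)
    # the Taylor correction is only reliable away from x = 0; below the
    # usual 3/n rule the uncorrected square root is used
    small <- sweep(x, 2, 3 / n, "<")
    corr[small] <- 1
    q <- pmin(sqrt(x) * corr, 1)
    out <- list(p = 1 - q, q = q)
    attr(out, "clamped") <- clamped
    out
}

#' Average coancestry between populations
#'
#' f_ij is the probability that two alleles drawn from populations i and
#' j are identical: the mean over loci of
#' \eqn{\hat p_i \hat p_j + \hat q_i \hat q_j} with allele frequencies
#' from \code{\link{alleleFrequencies}}. The diagonal is the uncorrected
#' expected gene identity of each population.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @return symmetric populations x populations matrix with entries in
#'   [0, 1]
#' @export
coancestry <- function(bm) {
    af <- alleleFrequencies(bm)
    coancestryFromFrequencies(af$p, af$q)
}

#' @rdname coancestry
#' @param p,q loci x populations matrices of band- and null-allele
#'   frequencies (columns sum to 1 per locus); use this entry point when
#'   allele frequencies come from an external (e.g. codominant) estimate
#' @export
coancestryFromFrequencies <- function(p, q = 1 - p) {
    stopifnot(identical(dim(p), dim(q)),
              max(abs(p + q - 1)) < 1e-8)
    L <- nrow(p)
    f <- (crossprod(p) + crossprod(q)) / L
    (f + t(f)) / 2
}

# Euclidean projection onto the probability simplex (Duchi et al. 2008)
.projectSimplex <- function(y) {
    u <- sort(y, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u - (css - 1) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(y - theta, 0)
}

#' Maximize pooled gene diversity over population contributions
#'
#' Finds the contribution vector c on the simplex maximizing
#' \eqn{D_{max} = 1 - \sum_{ij} f_{ij} c_i c_j}, i.e. minimizing the
#' quadratic form c'Fc, by projected gradient descent with backtracking
#' from many random Dirichlet starts; the best solution over all
#' replicates is kept. Contributions below 1e-6 are reported as exactly
#' zero (then renormalized). Contributions are also expressed as seed
#' counts for a synthetic pool of \code{poolSize} individuals.
#'
#' @param F symmetric coancestry matrix (see \code{\link{coancestry}})
#' @param replicates random restarts (default 100)
#' @param seed integer RNG seed
#' @param poolSize synthetic-pool size used for count reporting
#' @return list with \code{contributions} (named, sums to 1),
#'   \code{counts}, \code{Dmax} and \code{value} (= c'Fc)
#' @export
maximizeDmax <- function(F, replicates = 100, seed = 1L, poolSize = 1000) {
    F <- as.matrix(F)
    if (max(abs(F - t(F))) > 1e-8)
        stop("coancestry matrix must be symmetric")
    n <- nrow(F)
    qf <- function(c) drop(crossprod(c, F %*% c))
    set.seed(seed)
    best <- NULL
    bestVal <- Inf
    for (r in seq_len(replicates)) {
        c0 <- if (r == 1) rep(1 / n, n) else {
            g <- -log(runif(n))
            g / sum(g)
        }
        c <- c0
        step <- 1 / max(1e-8, 2 * max(abs(F)))
        val <- qf(c)
        for (it in seq_len(500L)) {
            grad <- 2 * drop(F %*% c)
            cand <- .projectSimplex(c - step * grad)
            vNew <- qf(cand)
            if (vNew <= val - 1e-14) {
                if (max(abs(cand - c)) < 1e-12) { c <- cand; val <- vNew; break }
                c <- cand; val <- vNew
                step <- step * 1.2
            } else {
                step <- step / 2
                if (step < 1e-14) break
            }
        }
        if (val < bestVal) { bestVal <- val; best <- c }
    }
    best[best < 1e-6] <- 0
    best <- best / sum(best)
    bestVal <- qf(best)
    names(best) <- rownames(F)
    list(contributions = best,
         counts = round(best * poolSize),
         Dmax = 1 - bestVal, value = bestVal)
}

# within-population diversity and mean pairwise distance for a set of pops
.poolSummaries <- function(p, q) {
    H <- colMeans(2 * p * q)                 # per population
    npop <- ncol(p)
    dsum <- 0
    for (i in seq_len(npop - 1)) for (j in (i + 1):npop)
        dsum <- dsum + mean(((p[, i] - p[, j])^2 + (q[, i] - q[, j])^2) / 2)
    list(Hs = mean(H), Dbar = dsum / (npop * (npop - 1) / 2))
}

#' Leave-one-out population contributions to diversity and distance
#'
#' For every population in scope, the analysis is repeated without it and
#' the proportional change is reported: dHnei for the mean
#' within-population gene diversity, dHdist for the mean pairwise Nei
#' minimum distance \eqn{D_{ij} = \overline{((p_i-p_j)^2+(q_i-q_j)^2)/2}},
#' and their sum dHt. The sign convention is positive when removing the
#' population decreases the indicator (the population sustains it);
#' negative values are legitimate.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param scope optional character vector of population labels (default:
#'   all); at least 3 populations
#' @return data.frame per population: \code{dHnei}, \code{dHdist},
#'   \code{dHt} (percent)
#' @export
leaveOneOutContributions <- function(bm, scope = NULL) {
    af <- alleleFrequencies(bm)
    pops <- colnames(af$p)
    if (is.null(scope)) scope <- pops
    if (!all(scope %in% pops)) stop("unknown population in scope")
    if (length(scope) < 3)
        stop("scope of ", length(scope),
             " populations: pairwise distance term needs >= 3")
    p <- af$p[, scope, drop = FALSE]
    q <- af$q[, scope, drop = FALSE]
    full <- .poolSummaries(p, q)
    out <- t(vapply(seq_along(scope), function(i) {
        red <- .poolSummaries(p[, -i, drop = FALSE], q[, -i, drop = FALSE])
        # degenerate scopes (identical populations) contribute 0, not 0/0
        nei <- if (full$Hs == 0) 0 else 100 * (full$Hs - red$Hs) / full$Hs
        dst <- if (full$Dbar == 0) 0 else
            100 * (full$Dbar - red$Dbar) / full$Dbar
        c(dHnei = nei, dHdist = dst, dHt = nei + dst)
    }, numeric(3)))
    data.frame(population = scope, out, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Random seed-bank baseline
#'
#' Expected pooled gene diversity 1 - c'Fc when the contribution vector
#' is drawn uniformly on the simplex, averaged over \code{reps} draws.
#'
#' @param F symmetric coancestry matrix
#' @param reps draws (default 100)
#' @param seed integer RNG seed
#' @return list with \code{mean} pooled diversity and the per-rep vector
#' @export
randomPoolBaseline <- function(F, reps = 100, seed = 1L) {
    stopifnot(reps >= 1)
    F <- as.matrix(F)
    n <- nrow(F)
    set.seed(seed)
    vals <- vapply(seq_len(reps), function(r) {
        g <- -log(runif(n))
        c <- g / sum(g)
        1 - drop(crossprod(c, F %*% c))
    }, numeric(1))
    list(mean = mean(vals), perRep = vals)
}
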