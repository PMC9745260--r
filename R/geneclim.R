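#' Collinearity filter for environmental predictors
#'
#' Iterative pairwise filter: while any pair of predictors has squared
#' Pearson correlation above \code{r2Thresh}, the member of the worst
#' pair with the larger mean squared correlation against all remaining
#' predictors is dropped (ties drop the later column; deterministic).
#' Constant layers are removed first with a warning since their
#' correlation is undefined.
#'
#' @param X numeric matrix or data.frame (samples x predictors, >= 2
#'   predictors and >= predictors + 2 rows)
#' @param r2Thresh squared-correlation threshold (default 0.7)
#' @return character vector of retained predictor names, with attribute
#'   \code{dropped}
#' @export
vifFilter <- function(X, r2Thresh = 0.7) {
    X <- as.matrix(X)
    stopifnot(ncol(X) >= 2, nrow(X) >= ncol(X) + 2)
    keep <- colnames(X)
    const <- apply(X, 2, sd) == 0
    if (all(const)) stop("all predictors are degenerate")
    if (any(const)) {
        warning("dropping constant layers: ",
                paste(keep[const], collapse = ", "))
        keep <- keep[!const]
    }
    dropped <- colnames(X)[const]
    while (length(keep) > 1) {
        r2 <- cor(X[, keep, drop = FALSE])^2
        diag(r2) <- 0
        if (max(r2) <= r2Thresh) break
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        meanR2 <- rowMeans(r2)
        cand <- keep[worst]
        out <- if (meanR2[worst[1]] > meanR2[worst[2]]) cand[1]
               else if (meanR2[worst[2]] > meanR2[worst[1]]) cand[2]
               else cand[which.max(worst)]
        dropped <- c(dropped, out)
        keep <- setdiff(keep, out)
    }
    if (length(keep) == 0) stop("all predictors are degenerate")
    attr(keep, "dropped") <- dropped
    keep
}

# deterministic 31-bit hash of a string, for per-locus RNG streams
.seedFromString <- function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
    as.integer(h)
}

# one bagged classification-tree ensemble for a single binary locus;
# returns oob error and per-split (predictor, position, improvement)
.locusEnsemble <- function(y, X, nTrees, mtry, control) {
    n <- length(y)
    votes1 <- numeric(n)
    votesN <- numeric(n)
    splits <- list()
    yf <- factor(y, levels = c(0, 1))
    for (t in seq_len(nTrees)) {
        boot <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(boot))
        vars <- sample(colnames(X), mtry)
        if (length(unique(y[boot])) < 2) {
            # single-class bootstrap: a stump voting that class
            if (length(oob) > 0) {
                votes1[oob] <- votes1[oob] + y[boot][1]
                votesN[oob] <- votesN[oob] + 1
            }
            next
        }
        df <- data.frame(.y = yf[boot], X[boot, vars, drop = FALSE],
                         check.names = FALSE)
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = control)
        if (!is.null(fit$splits) && nrow(fit$splits) > 0) {
            s <- fit$splits
            splits[[length(splits) + 1L]] <- data.frame(
                var = rownames(s), pos = s[, "index"],
                improve = s[, "improve"], stringsAsFactors = FALSE)
        }
        if (length(oob) > 0) {
            pr <- predict(fit,
                          newdata = data.frame(X[oob, vars, drop = FALSE],
                                               check.names = FALSE),
                          type = "class")
            votes1[oob] <- votes1[oob] + (pr == "1")
            votesN[oob] <- votesN[oob] + 1
        }
    }
    seen <- votesN > 0
    pred <- as.integer(votes1[seen] / votesN[seen] > 0.5)
    oobErr <- mean(pred != y[seen])
    list(oobError = oobErr,
         splits = if (length(splits)) do.call(rbind, splits) else NULL)
}

#' Fit a genetic-turnover model along environmental gradients
#'
#' For every locus a bagged classification-tree ensemble is fitted to the
#' individual presence/absence scores with population-level predictor
#' values attached to each individual (bootstrap rows and a random
#' predictor subspace per tree; per-split Gini improvements are
#' recorded). A locus is retained when its out-of-bag error is strictly
#' below the majority-class null error; its weight is the out-of-bag
#' R-squared analogue 1 - oobError/nullError. Split improvements are
#' pooled per predictor into \code{nBins} fixed-width bins over the
#' predictor's training range — each locus's improvements normalized to
#' proportions and weighted by the locus weight, then averaged over
#' retained loci — and cumulated into a non-decreasing genetic-importance
#' function per predictor whose maximum is the predictor's overall
#' importance.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param predictors matrix/data.frame of predictor values per population
#'   (rownames = population labels), e.g. from
#'   \code{\link{simulateClimate}} or \code{\link{extractAt}}
#' @param nTrees trees per locus (default 500)
#' @param seed integer RNG seed
#' @param nBins bins per predictor range (default 200)
#' @param mtry predictors sampled per tree (default ceiling(sqrt(p)))
#' @return a \linkS4class{TurnoverModel}; monomorphic loci are skipped
#'   and reported in the loci table
#' @export
fitTurnover <- function(bm, predictors, nTrees = 500, seed = 1L,
                        nBins = 200, mtry = NULL) {
    predictors <- as.matrix(predictors)
    pops <- popNames(bm)
    if (!all(pops %in% rownames(predictors)))
        stop("predictor rows must cover all populations")
    stopifnot(ncol(predictors) >= 1)
    if (nlevels(populations(bm)) < 5 && nIndividuals(bm) < 30)
        stop("need >= 5 populations or >= 30 individuals")
    X <- predictors[as.character(populations(bm)), , drop = FALSE]
    rownames(X) <- NULL
    vars <- colnames(X)
    p <- length(vars)
    if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(p)))
    mtry <- min(mtry, p)
    m <- bandValues(bm)
    ranges <- apply(X, 2, range)
    edges <- lapply(vars, function(v)
        seq(ranges[1, v], ranges[2, v], length.out = nBins + 1))
    names(edges) <- vars
    control <- rpart::rpart.control(minsplit = 5, minbucket = 2,
                                    cp = 0.005, xval = 0, maxcompete = 0,
                                    maxsurrogate = 0, usesurrogate = 0)
    lociTab <- data.frame(locus = colnames(m), oobError = NA_real_,
                          nullError = NA_real_, weight = 0,
                          retained = FALSE, stringsAsFactors = FALSE)
    binned <- lapply(vars, function(v) numeric(nBins))
    names(binned) <- vars
    skipped <- 0L
    nRetained <- 0L
    for (l in seq_len(ncol(m))) {
        y <- m[, l]
        if (length(unique(y)) < 2) { skipped <- skipped + 1L; next }
        # per-locus stream keyed on the locus name: results do not depend
        # on locus order or on which other loci are present
        set.seed((seed + .seedFromString(colnames(m)[l])) %% 2147483647L)
        nullErr <- min(mean(y), 1 - mean(y))
        ens <- .locusEnsemble(y, X, nTrees, mtry, control)
        w <- max(0, 1 - ens$oobError / nullErr)
        lociTab$oobError[l] <- ens$oobError
        lociTab$nullError[l] <- nullErr
        lociTab$weight[l] <- w
        retained <- ens$oobError < nullErr
        lociTab$retained[l] <- retained
        if (!retained || is.null(ens$splits)) next
        nRetained <- nRetained + 1L
        tot <- sum(ens$splits$improve)
        if (tot <= 0) next
        for (v in unique(ens$splits$var)) {
            s <- ens$splits[ens$splits$var == v, ]
            b <- findInterval(s$pos, edges[[v]], rightmost.closed = TRUE,
                              all.inside = TRUE)
            add <- numeric(nBins)
            for (i in seq_len(nrow(s)))
                add[b[i]] <- add[b[i]] + s$improve[i]
            binned[[v]] <- binned[[v]] + w * add / tot
        }
    }
    if (skipped > 0)
        message(skipped, " monomorphic loci skipped")
    denom <- max(1L, nRetained)
    cumimp <- lapply(vars, function(v) {
        data.frame(x = edges[[v]][-1], y = cumsum(binned[[v]] / denom))
    })
    names(cumimp) <- vars
    importance <- vapply(cumimp, function(f) f$y[nBins], numeric(1))
    new("TurnoverModel", importance = importance, cumimp = cumimp,
        loci = lociTab, ranges = ranges, nTrees = as.integer(nTrees))
}

#' Transform environmental values into genetic importance values
#'
#' Maps every predictor value through its cumulative genetic-importance
#' function (a right-continuous non-decreasing step function). Values
#' below the training range map to 0, values above it to the predictor's
#' total importance; the number of clamped values is attached as
#' attribute \code{clamped}.
#'
#' @param model a \linkS4class{TurnoverModel}
#' @param x a \linkS4class{ClimateStack} or a matrix/data.frame with the
#'   model's predictors as columns
#' @return matrix of genetic importance values (rows = points or unmasked
#'   grid cells, with \code{coords} attribute for stacks)
#' @export
transformClimate <- function(model, x) {
    vars <- names(model@importance)
    coords <- NULL
    if (is(x, "ClimateStack")) {
        if (!all(vars %in% layerNames(x)))
            stop("missing layer(s): ",
                 paste(setdiff(vars, layerNames(x)), collapse = ", "))
        tab <- stackTable(x)
        coords <- tab[, c("row", "col", "lon", "lat")]
        x <- tab[, vars, drop = FALSE]
    }
    x <- as.matrix(x)
    if (!all(vars %in% colnames(x)))
        stop("missing predictor(s): ",
             paste(setdiff(vars, colnames(x)), collapse = ", "))
    clamped <- 0L
    out <- vapply(vars, function(v) {
        f <- model@cumimp[[v]]
        xi <- x[, v]
        clamped <<- clamped + sum(xi < model@ranges[1, v] |
                                  xi > model@ranges[2, v])
        idx <- findInterval(xi, f$x)        # 0 => below all bins => 0
        c(0, f$y)[idx + 1]
    }, numeric(nrow(x)))
    out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), vars))
    attr(out, "clamped") <- clamped
    if (!is.null(coords)) attr(out, "coords") <- coords
    out
}

#' Group populations and pixels in genetic-importance space
#'
#' Grid cells are transformed into genetic importance values, a PCA is
#' fitted on the grid, populations are projected into the same space,
#' Ward hierarchical clustering of the population scores (first
#' \code{nAxes} axes) is cut at \code{nGroups}, and every unmasked pixel
#' is assigned to the nearest group centroid (Euclidean distance in the
#' score space).
#'
#' @param model a \linkS4class{TurnoverModel}
#' @param popPredictors matrix/data.frame of predictor values per
#'   population (rownames = population labels)
#' @param stack a \linkS4class{ClimateStack} transformed by the same
#'   model
#' @param nGroups number of groups (default 3)
#' @param nAxes PCA axes used (default 3, capped at the predictor count)
#' @return a \linkS4class{GeneticImportanceMap}
#' @export
mapGroups <- function(model, popPredictors, stack, nGroups = 3,
                      nAxes = 3) {
    popPredictors <- as.matrix(popPredictors)
    if (nGroups > nrow(popPredictors))
        stop("more groups requested than populations")
    gridT <- transformClimate(model, stack)
    coords <- attr(gridT, "coords")
    popT <- transformClimate(model, popPredictors)
    if (max(apply(gridT, 2, sd)) < 1e-12)
        stop("transformed grid is constant: no structure to map")
    pca <- prcomp(gridT, center = TRUE, scale. = FALSE)
    nAxes <- min(nAxes, ncol(pca$rotation))
    gridScores <- pca$x[, seq_len(nAxes), drop = FALSE]
    popScores <- sweep(popT, 2, pca$center) %*%
        pca$rotation[, seq_len(nAxes), drop = FALSE]
    rownames(popScores) <- rownames(popPredictors)
    if (max(dist(popScores)) < 1e-12)
        stop("populations indistinguishable in genetic-importance space")
    hc <- hclust(dist(popScores), method = "ward.D2")
    groups <- cutree(hc, k = nGroups)
    centroids <- rowsum(popScores, groups) /
        as.vector(table(groups))
    d <- gridDim(stack)
    assigned <- .nearestCentroid(gridScores, centroids)
    groupRaster <- matrix(NA_integer_, d[1], d[2])
    groupRaster[cbind(coords$row, coords$col)] <- assigned
    scoreGrid <- array(NA_real_, c(d, nAxes))
    for (a in seq_len(nAxes)) {
        mm <- matrix(NA_real_, d[1], d[2])
        mm[cbind(coords$row, coords$col)] <- gridScores[, a]
        scoreGrid[, , a] <- mm
    }
    new("GeneticImportanceMap", popScores = popScores,
        popGroups = setNames(as.integer(groups), rownames(popScores)),
        centroids = as.matrix(centroids), groupRaster = groupRaster,
        scoreGrid = scoreGrid,
        pca = list(rotation = pca$rotation, center = pca$center,
                   sdev = pca$sdev),
        dendrogram = hc, nAxes = as.integer(nAxes))
}

.nearestCentroid <- function(scores, centroids) {
    d2 <- vapply(seq_len(nrow(centroids)), function(g)
        rowSums(sweep(scores, 2, centroids[g, ])^2),
        numeric(nrow(scores)))
    max.col(-matrix(d2, nrow = nrow(scores)), ties.method = "first")
}

#' Average future scenarios onto a fitted genetic-importance map
#'
#' Each scenario stack is transformed through the model, the transformed
#' values are averaged per pixel, projected into the PCA space of the
#' current-climate map, and assigned to its frozen group centroids so
#' group identities stay comparable across time slices.
#'
#' @param stacks list of \linkS4class{ClimateStack} objects sharing one
#'   grid
#' @param model the \linkS4class{TurnoverModel} used for the current map
#' @param map the current-climate \linkS4class{GeneticImportanceMap}
#' @return a \linkS4class{GeneticImportanceMap} for the averaged scenario
#'   (population slots carried over from \code{map})
#' @export
scenarioAverage <- function(stacks, model, map) {
    stopifnot(length(stacks) >= 1)
    ref <- stacks[[1]]
    for (s in stacks)
        if (!identical(gridDim(s), gridDim(ref)) ||
            abs(s@cellsize - ref@cellsize) > 1e-9 ||
            !identical(s@mask, ref@mask))
            stop("scenario stacks must share one grid and mask")
    trans <- lapply(stacks, function(s) transformClimate(model, s))
    coords <- attr(trans[[1]], "coords")
    avg <- Reduce(`+`, lapply(trans, unclass)) / length(trans)
    nAxes <- map@nAxes
    scores <- sweep(avg, 2, map@pca$center) %*%
        map@pca$rotation[, seq_len(nAxes), drop = FALSE]
    assigned <- .nearestCentroid(scores, map@centroids)
    d <- gridDim(ref)
    groupRaster <- matrix(NA_integer_, d[1], d[2])
    groupRaster[cbind(coords$row, coords$col)] <- assigned
    scoreGrid <- array(NA_real_, c(d, nAxes))
    for (a in seq_len(nAxes)) {
        mm <- matrix(NA_real_, d[1], d[2])
        mm[cbind(coords$row, coords$col)] <- scores[, a]
        scoreGrid[, , a] <- mm
    }
    new("GeneticImportanceMap", popScores = map@popScores,
        popGroups = map@popGroups, centroids = map@centroids,
        groupRaster = groupRaster, scoreGrid = scoreGrid,
        pca = map@pca, dendrogram = map@dendrogram,
        nAxes = nAxes)
}
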