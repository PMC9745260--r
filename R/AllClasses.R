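#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats as.dist cor cutree dist hclust kmeans lm coef plogis
#'   prcomp predict quantile rbeta rbinom runif sd setNames var
#' @importFrom utils read.table read.csv write.csv head
NULL

#' BandMatrix: binary dominant-marker scores with a population partition
#'
#' A \code{BandMatrix} holds presence/absence scores for dominant markers
#' (e.g. AFLP bands) as a \linkS4class{SummarizedExperiment}: loci are rows,
#' individuals are columns, and \code{colData()} carries the population
#' label of every individual. All downstream stages (diversity descriptors,
#' AMOVA, rare-band analysis, coancestry, genotype-environment turnover)
#' consume this container.
#'
#' Validity requires a complete matrix of 0/1 values (no missing cells),
#' unique locus and individual identifiers, and at least two individuals in
#' every population.
#'
#' @seealso \code{\link{readBandMatrix}}, \code{\link{bandFrequencies}}
#' @export
setClass("BandMatrix", contains = "SummarizedExperiment")

setValidity("BandMatrix", function(object) {
    if (!"bands" %in% SummarizedExperiment::assayNames(object))
        return("assay 'bands' is missing")
    m <- SummarizedExperiment::assay(object, "bands")
    if (anyNA(m))
        return("band matrix contains missing values")
    if (!all(m %in% c(0L, 1L)))
        return("band matrix entries must be 0 or 1")
    if (nrow(m) < 1L)
        return("at least one locus is required")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("locus identifiers must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        return("individual identifiers must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"population" %in% colnames(cd))
        return("colData must contain a 'population' column")
    pop <- as.character(cd$population)
    if (anyNA(pop))
        return("every individual must map to a population")
    if (any(table(pop) < 2L))
        return("every population needs at least 2 individuals")
    TRUE
})

#' Construct a BandMatrix
#'
#' @param values integer or numeric matrix of 0/1 scores, individuals in
#'   rows and loci in columns (the usual file layout for dominant-marker
#'   tables); row names are individual ids, column names are locus ids.
#' @param population character or factor of population labels, one per
#'   individual (row of \code{values}).
#' @return a validated \linkS4class{BandMatrix}
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 0, 1, 1), nrow = 4,
#'             dimnames = list(paste0("i", 1:4), c("L1", "L2")))
#' bm <- BandMatrix(m, population = c("A", "A", "B", "B"))
#' nLoci(bm)
#' @export
BandMatrix <- function(values, population) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("ind", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("locus", seq_len(ncol(values)))
    storage.mode(values) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(bands = t(values)),
        colData = S4Vectors::DataFrame(
            population = as.character(population),
            row.names = rownames(values)))
    new("BandMatrix", se)
}

#' ClimateStack: aligned raster layers on a regular lon/lat grid
#'
#' Named environmental layers (e.g. bioclimatic variables) sharing one
#' regular WGS84 lon/lat grid. Cells are treated as cell-centred, stored
#' row-major from the north-west corner (row 1 is the northernmost row).
#' A shared mask marks cells where any layer has no data.
#'
#' @slot values numeric array (nrow x ncol x nlayers) with layer names on
#'   the third dimension; masked cells are \code{NA} in every layer.
#' @slot xll,yll numeric, lon/lat of the lower-left grid corner (degrees).
#' @slot cellsize numeric, cell edge in degrees.
#' @slot mask logical matrix, \code{TRUE} where cells carry data.
#' @seealso \code{\link{readClimateStack}}, \code{\link{readAsciiGrid}}
#' @export
setClass("ClimateStack", representation(
    values = "array", xll = "numeric", yll = "numeric",
    cellsize = "numeric", mask = "matrix"))

setValidity("ClimateStack", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L)
        return("values must be a 3-d array (rows x cols x layers)")
    ln <- dimnames(v)[[3]]
    if (is.null(ln) || anyDuplicated(ln))
        return("layer names must be present and unique")
    if (!identical(dim(object@mask), dim(v)[1:2]))
        return("mask geometry does not match layers")
    if (object@cellsize <= 0)
        return("cellsize must be positive")
    ok <- !is.na(v)
    for (k in seq_len(dim(v)[3]))
        if (!identical(unname(ok[, , k]), unname(object@mask)))
            return(sprintf("layer '%s' has NA cells outside the shared mask",
                           ln[k]))
    TRUE
})

#' Construct a ClimateStack from matrices
#'
#' @param layers named list of numeric matrices on the same grid; \code{NA}
#'   marks nodata and is propagated to all layers (union mask).
#' @param xll,yll lon/lat of the lower-left corner (degrees)
#' @param cellsize cell edge in degrees
#' @return a \linkS4class{ClimateStack}
#' @export
ClimateStack <- function(layers, xll, yll, cellsize) {
    stopifnot(is.list(layers), length(layers) >= 1L,
              !is.null(names(layers)))
    d <- dim(layers[[1]])
    for (nm in names(layers))
        if (!identical(dim(layers[[nm]]), d))
            stop("layer '", nm, "' does not match the grid of layer '",
                 names(layers)[1], "'")
    mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
    a <- array(NA_real_, c(d, length(layers)),
               dimnames = list(NULL, NULL, names(layers)))
    for (k in seq_along(layers)) {
        m <- layers[[k]]
        m[!mask] <- NA_real_
        a[, , k] <- m
    }
    new("ClimateStack", values = a, xll = as.numeric(xll),
        yll = as.numeric(yll), cellsize = as.numeric(cellsize),
        mask = mask)
}

#' TurnoverModel: per-predictor cumulative genetic-importance functions
#'
#' Result of \code{\link{fitTurnover}}. For each environmental predictor the
#' model stores a non-decreasing step function of cumulative genetic
#' importance over the predictor's training range, plus overall predictor
#' importances and the per-locus out-of-bag fit summary.
#'
#' @slot importance named numeric, overall importance per predictor (mean
#'   weighted importance over retained loci).
#' @slot cumimp named list; per predictor a data.frame with columns
#'   \code{x} (split positions, bin upper edges) and \code{y} (cumulative
#'   importance, non-decreasing, max = overall importance).
#' @slot loci data.frame with per-locus \code{oobError}, \code{nullError},
#'   \code{weight} (out-of-bag R-squared analogue) and \code{retained}.
#' @slot ranges numeric matrix (2 x predictors) of training ranges.
#' @slot nTrees integer, trees per locus ensemble.
#' @export
setClass("TurnoverModel", representation(
    importance = "numeric", cumimp = "list", loci = "data.frame",
    ranges = "matrix", nTrees = "integer"))

setValidity("TurnoverModel", function(object) {
    if (!identical(names(object@importance), names(object@cumimp)))
        return("importance and cumimp predictors disagree")
    for (nm in names(object@cumimp)) {
        f <- object@cumimp[[nm]]
        if (any(diff(f$y) < -1e-12))
            return(sprintf("cumulative importance for '%s' decreases", nm))
    }
    TRUE
})

#' GeneticImportanceMap: PCA scores and group assignment over a grid
#'
#' Result of \code{\link{mapGroups}} / \code{\link{scenarioAverage}}: grid
#' cells transformed into genetic importance values, rotated by a PCA
#' fitted on the grid, with populations projected into the same space and
#' every non-masked pixel assigned to the nearest of G group centroids
#' (Euclidean distance in the first \code{nAxes} PCA scores).
#'
#' @slot popScores matrix (populations x axes) of PCA scores
#' @slot popGroups named integer group per population
#' @slot centroids matrix (groups x axes)
#' @slot groupRaster integer matrix; NA outside the mask
#' @slot scoreGrid numeric array (nrow x ncol x axes) of pixel PCA scores
#' @slot pca list with \code{rotation}, \code{center}, \code{sdev}
#' @slot dendrogram the hclust tree of population scores
#' @slot nAxes integer, PCA axes used for grouping
#' @export
setClass("GeneticImportanceMap", representation(
    popScores = "matrix", popGroups = "integer", centroids = "matrix",
    groupRaster = "matrix", scoreGrid = "array", pca = "list",
    dendrogram = "ANY", nAxes = "integer"))
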