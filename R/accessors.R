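#' Accessors for BandMatrix and ClimateStack
#'
#' \code{bandValues} returns the scores as an individuals x loci 0/1 matrix
#' (the file layout); \code{populations} the per-individual population
#' factor; \code{popNames} the population labels in order of first
#' appearance; \code{nLoci}/\code{nIndividuals} the dimensions;
#' \code{locusNames} the locus identifiers.
#'
#' @param x a \linkS4class{BandMatrix}
#' @return see description
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))
#' @rdname accessors
#' @export
setMethod("bandValues", "BandMatrix", function(x)
    t(SummarizedExperiment::assay(x, "bands")))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setMethod("populations", "BandMatrix", function(x) {
    pop <- as.character(SummarizedExperiment::colData(x)$population)
    factor(pop, levels = unique(pop))
})

#' @rdname accessors
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))
#' @rdname accessors
#' @export
setMethod("popNames", "BandMatrix", function(x) levels(populations(x)))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setMethod("nLoci", "BandMatrix", function(x) nrow(x))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setMethod("nIndividuals", "BandMatrix", function(x) ncol(x))

#' @rdname accessors
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))
#' @rdname accessors
#' @export
setMethod("locusNames", "BandMatrix", function(x) rownames(x))

setMethod("show", "BandMatrix", function(object) {
    pop <- populations(object)
    cat("BandMatrix:", nIndividuals(object), "individuals x",
        nLoci(object), "loci,", nlevels(pop), "populations\n")
    sz <- table(pop)
    cat("  populations:",
        paste0(names(sz), " (", as.integer(sz), ")", collapse = ", "),
        "\n")
})

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setMethod("layerNames", "ClimateStack", function(x) dimnames(x@values)[[3]])

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setMethod("nLayers", "ClimateStack", function(x) dim(x@values)[3])

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setMethod("gridDim", "ClimateStack", function(x) dim(x@values)[1:2])

#' Extract one layer of a ClimateStack as a matrix
#' @param x a \linkS4class{ClimateStack}
#' @param name layer name
#' @return numeric matrix (row 1 = northernmost row)
#' @export
getLayer <- function(x, name) {
    stopifnot(is(x, "ClimateStack"), name %in% layerNames(x))
    x@values[, , name]
}

#' Cell-centre coordinates of a ClimateStack
#' @param x a \linkS4class{ClimateStack}
#' @return data.frame with \code{row}, \code{col}, \code{lon}, \code{lat}
#'   for every cell (masked cells included; see \code{stackTable} for the
#'   unmasked subset with layer values)
#' @export
cellCoords <- function(x) {
    d <- gridDim(x)
    g <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
    g$lon <- x@xll + (g$col - 0.5) * x@cellsize
    g$lat <- x@yll + (d[1] - g$row + 0.5) * x@cellsize
    g
}

#' Tabulate a ClimateStack over its unmasked cells
#' @param x a \linkS4class{ClimateStack}
#' @return data.frame: \code{row}, \code{col}, \code{lon}, \code{lat} and
#'   one column per layer, one line per unmasked cell
#' @export
stackTable <- function(x) {
    g <- cellCoords(x)
    keep <- x@mask[cbind(g$row, g$col)]
    vals <- vapply(layerNames(x),
                   function(nm) x@values[, , nm][cbind(g$row, g$col)],
                   numeric(nrow(g)))
    out <- cbind(g, as.data.frame(vals))
    out[keep, , drop = FALSE]
}

#' Sample a ClimateStack at point locations
#' @param x a \linkS4class{ClimateStack}
#' @param lon,lat numeric vectors of coordinates (degrees)
#' @return matrix (points x layers); \code{NA} for points outside the grid
#'   or on masked cells
#' @export
extractAt <- function(x, lon, lat) {
    stopifnot(length(lon) == length(lat))
    d <- gridDim(x)
    col <- floor((lon - x@xll) / x@cellsize) + 1L
    row <- d[1] - floor((lat - x@yll) / x@cellsize)
    ok <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
    out <- matrix(NA_real_, length(lon), nLayers(x),
                  dimnames = list(NULL, layerNames(x)))
    for (k in seq_len(nLayers(x)))
        out[ok, k] <- x@values[, , k][cbind(row[ok], col[ok])]
    out
}

setMethod("show", "ClimateStack", function(object) {
    d <- gridDim(object)
    cat("ClimateStack:", nLayers(object), "layers on a", d[1], "x", d[2],
        "grid (cell", object@cellsize, "deg)\n")
    cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
    cat("  masked cells:", sum(!object@mask), "of", prod(d), "\n")
})

setMethod("show", "TurnoverModel", function(object) {
    cat("TurnoverModel:", length(object@importance), "predictors,",
        sum(object@loci$retained), "of", nrow(object@loci),
        "loci retained,", object@nTrees, "trees per locus\n")
    imp <- sort(object@importance, decreasing = TRUE)
    cat("  importance:",
        paste0(names(imp), " = ", signif(imp, 3), collapse = ", "), "\n")
})

setMethod("show", "GeneticImportanceMap", function(object) {
    cat("GeneticImportanceMap:", nrow(object@centroids), "groups,",
        object@nAxes, "PCA axes,", sum(!is.na(object@groupRaster)),
        "assigned pixels\n")
    cat("  population groups:",
        paste0(names(object@popGroups), ":", object@popGroups,
               collapse = " "), "\n")
})
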