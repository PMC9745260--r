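#' Read a dominant-marker band matrix from delimited text
#'
#' Expects a header line of locus identifiers preceded by the individual-id
#' and population columns, then one row per individual:
#' \code{id,population,L1,L2,...} with 0/1 scores. Comma- or tab-delimited
#' files are auto-detected. Missing or non-binary cells are a hard error
#' naming the offending cell; \code{impute = TRUE} instead fills missing
#' cells with the rounded population mean for that locus and reports how
#' many cells were imputed via a warning.
#'
#' @param path file path
#' @param impute impute missing cells from population means (default FALSE:
#'   missing data are rejected)
#' @return a \linkS4class{BandMatrix}; row and column order of the file is
#'   preserved
#' @export
readBandMatrix <- function(path, impute = FALSE) {
    stopifnot(file.exists(path))
    first <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t"
           else ","
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
    if (ncol(df) < 3L)
        stop("expected columns: individual id, population, and >=1 locus")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate individual id: ",
             ids[anyDuplicated(ids)])
    pop <- as.character(df[[2]])
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    bad <- which(!(is.na(m) | m == 0 | m == 1), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-binary value '%s' at individual '%s', locus '%s'",
                     m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                     colnames(m)[bad[1, 2]]))
    if (anyNA(m)) {
        miss <- which(is.na(m), arr.ind = TRUE)
        if (!impute)
            stop(sprintf(
                "missing value at individual '%s', locus '%s' (%d missing cells; use impute = TRUE to fill from population means)",
                ids[miss[1, 1]], colnames(m)[miss[1, 2]], nrow(miss)))
        for (j in unique(miss[, 2])) {
            rows <- miss[miss[, 2] == j, 1]
            for (i in rows) {
                same <- which(pop == pop[i])
                mu <- mean(m[same, j], na.rm = TRUE)
                m[i, j] <- if (is.nan(mu)) 0 else round(mu)
            }
        }
        warning(sprintf("imputed %d missing cells from population means",
                        nrow(miss)))
    }
    rownames(m) <- ids
    BandMatrix(m, population = pop)
}

#' Write a BandMatrix to CSV
#'
#' Inverse of \code{\link{readBandMatrix}}: the written file round-trips
#' bit-exactly.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeBandMatrix <- function(bm, path) {
    m <- bandValues(bm)
    df <- data.frame(id = rownames(m),
                     population = as.character(populations(bm)),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Per-population and overall band frequencies
#'
#' Band (phenotype) carrier frequencies: for locus l and population k,
#' freq(l, k) = carriers in k / size of k; the overall frequency pools all
#' individuals.
#'
#' @param bm a \linkS4class{BandMatrix}
#' @return list with \code{perPop} (loci x populations matrix),
#'   \code{overall} (named numeric per locus) and \code{popSizes}
#' @export
bandFrequencies <- function(bm) {
    m <- bandValues(bm)                      # individuals x loci
    pop <- populations(bm)
    counts <- rowsum(m, pop)                 # populations x loci carriers
    sizes <- as.integer(table(pop)[rownames(counts)])
    perPop <- t(counts / sizes)              # loci x populations
    list(perPop = perPop,
         overall = colSums(m) / nrow(m),
         popSizes = setNames(sizes, rownames(counts)))
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (\code{ncols nrows
#' xllcorner yllcorner cellsize NODATA_value}) followed by rows of cell
#' values from the northern edge southwards.
#'
#' @param path file path
#' @return list with \code{values} (matrix, NA for nodata), \code{xll},
#'   \code{yll}, \code{cellsize}
#' @export
readAsciiGrid <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    hdr <- list()
    i <- 1L
    while (grepl("^[A-Za-z]", lines[i])) {
        kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
        hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
        i <- i + 1L
    }
    need <- c("ncols", "nrows", "cellsize")
    if (!all(need %in% names(hdr)))
        stop("ASCII grid header incomplete in ", path)
    xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
           else hdr$xllcenter - hdr$cellsize / 2
    yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
           else hdr$yllcenter - hdr$cellsize / 2
    vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                 quiet = TRUE)
    if (length(vals) != hdr$ncols * hdr$nrows)
        stop("ASCII grid body has ", length(vals), " values, expected ",
             hdr$ncols * hdr$nrows, " in ", path)
    m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
    if (!is.null(hdr$nodata_value))
        m[m == hdr$nodata_value] <- NA_real_
    list(values = m, xll = xll, yll = yll, cellsize = hdr$cellsize)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = northernmost row); NA written as
#'   the nodata value
#' @param path output file
#' @param xll,yll lower-left corner (degrees)
#' @param cellsize cell edge (degrees)
#' @param nodata nodata sentinel (default -9999)
#' @return \code{path}, invisibly
#' @export
writeAsciiGrid <- function(values, path, xll, yll, cellsize,
                           nodata = -9999) {
    m <- values
    m[is.na(m)] <- nodata
    hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
             sprintf("xllcorner %.10g", xll),
             sprintf("yllcorner %.10g", yll),
             sprintf("cellsize %.10g", cellsize),
             sprintf("NODATA_value %.10g", nodata))
    body <- apply(m, 1, function(r) paste(sprintf("%.10g", r),
                                          collapse = " "))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read several ASCII grids into a ClimateStack
#'
#' All grids must share the same geometry (dimensions, origin, cell size);
#' a mismatch is a hard error naming the offending layer. Nodata masks are
#' unioned across layers.
#'
#' @param paths character vector of ASCII-grid files, or a directory
#'   containing \code{.asc} files
#' @param names layer names (default: file names without extension)
#' @return a \linkS4class{ClimateStack}
#' @export
readClimateStack <- function(paths, names = NULL) {
    if (length(paths) == 1L && dir.exists(paths))
        paths <- sort(list.files(paths, pattern = "\\.asc$",
                                 full.names = TRUE))
    stopifnot(length(paths) >= 1L)
    if (is.null(names))
        names <- sub("\\.[^.]*$", "", basename(paths))
    grids <- lapply(paths, readAsciiGrid)
    ref <- grids[[1]]
    for (k in seq_along(grids)) {
        g <- grids[[k]]
        if (!identical(dim(g$values), dim(ref$values)) ||
            abs(g$cellsize - ref$cellsize) > 1e-9 ||
            abs(g$xll - ref$xll) > 1e-6 || abs(g$yll - ref$yll) > 1e-6)
            stop("raster grid mismatch: layer '", names[k],
                 "' does not share the geometry of '", names[1], "'")
    }
    ClimateStack(setNames(lapply(grids, `[[`, "values"), names),
                 xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize)
}

#' Write every layer of a ClimateStack as ASCII grids
#' @param stack a \linkS4class{ClimateStack}
#' @param dir output directory (created if needed)
#' @return the written paths, invisibly
#' @export
writeClimateStack <- function(stack, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(layerNames(stack), ".asc"))
    for (k in seq_len(nLayers(stack)))
        writeAsciiGrid(stack@values[, , k], paths[k], stack@xll,
                       stack@yll, stack@cellsize)
    invisible(paths)
}
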