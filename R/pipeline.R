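#' Run the full conservation-genetics pipeline
#'
#' Orchestrates simulate/load, diversity descriptors, structure
#' diagnostics, RGUC selection, seed-bank optimization and (optionally)
#' the genotype-environment turnover stage with one configuration,
#' writing per-stage CSV/ASCII-grid artifacts and a JSON manifest that
#' echoes parameters, seeds and the package version. Deterministic stages
#' are bit-identical across reruns with the same configuration. On a
#' stage failure a \code{.partial} marker is left next to the outputs
#' already written.
#'
#' Configuration entries (all optional unless noted): \code{outDir}
#' (required), \code{bands}/\code{meta} (input CSV paths) or
#' \code{simulate = TRUE} with \code{simArgs} (passed to
#' \code{\link{simConfig}}), \code{clustersFrom} ("meta" or "kmeans"),
#' \code{fst} (default: estimated AMOVA Phi-ST), \code{target} (P,
#' default 0.999), \code{freqThresh}, \code{occThresh}, \code{reps},
#' \code{seed}, \code{geneclim} (logical; default TRUE when a climate
#' stack is available), \code{rasters} (directory of ASCII grids),
#' \code{nTrees}, \code{nGroups}, \code{nAxes}.
#'
#' @param config a named list, or the path of a YAML file holding one
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("reading YAML configs needs the 'yaml' package")
        config <- yaml::read_yaml(config)
    }
    defaults <- list(simulate = FALSE, simArgs = list(),
                     clustersFrom = "meta", target = 0.999,
                     freqThresh = 0.10, occThresh = 0.40, reps = 100,
                     seed = 42L, nTrees = 500, nGroups = 3, nAxes = 3,
                     nPerm = 999)
    config <- utils::modifyList(defaults, config)
    if (is.null(config$outDir)) stop("config needs an outDir")

    # validate referenced paths before any compute
    for (p in c(config$bands, config$meta, config$rasters))
        if (!is.null(p) && !file.exists(p) && !dir.exists(p))
            stop("configured path does not exist: ", p)
    if (!isTRUE(config$simulate) &&
        (is.null(config$bands) || is.null(config$meta)))
        stop("either simulate = TRUE or bands + meta paths are required")
    if (isTRUE(config$geneclim) && !isTRUE(config$simulate) &&
        is.null(config$rasters))
        stop("geneclim stage requested but no rasters directory given")

    outDir <- config$outDir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    partial <- file.path(outDir, ".partial")
    file.create(partial)   # removed on success; left behind on failure
    seed <- as.integer(config$seed)
    files <- character(0)
    emit <- function(df, name) {
        path <- file.path(outDir, name)
        write.csv(df, path, row.names = FALSE)
        files <<- c(files, path)
        path
    }

    stack <- NULL; popCov <- NULL
    if (isTRUE(config$simulate)) {
        cfg <- do.call(simConfig, config$simArgs)
        sim <- simulateStudy(cfg, seed)
        bm <- sim$bm; popFrame <- sim$popFrame
        stack <- sim$stack; popCov <- sim$popCovariates
        writeBandMatrix(bm, file.path(outDir, "bands.csv"))
        emit(popFrame, "meta.csv")
        jsonlite::write_json(
            lapply(sim$truth[c("rareLoci", "adaptiveLoci")], identity),
            file.path(outDir, "truth.json"))
        files <- c(files, file.path(outDir, c("bands.csv", "truth.json")))
    } else {
        bm <- readBandMatrix(config$bands)
        popFrame <- populationFrame(read.csv(config$meta,
                                             stringsAsFactors = FALSE))
        if (!is.null(config$rasters))
            stack <- readClimateStack(config$rasters)
        if (!is.null(stack))
            popCov <- extractAt(stack, popFrame$lon, popFrame$lat)
        if (!is.null(popCov)) rownames(popCov) <- popFrame$population
    }
    doGeneclim <- if (is.null(config$geneclim)) !is.null(stack)
                  else isTRUE(config$geneclim)

    desc <- popDescriptors(bm)
    emit(desc, "descriptors.csv")

    clusters <- if (config$clustersFrom == "meta" &&
                    "cluster" %in% colnames(popFrame) &&
                    !all(is.na(popFrame$cluster)))
        setNames(as.integer(popFrame$cluster), popFrame$population)
    else surrogateClusters(bm, K = NULL, seed = seed + 1L)

    gen <- geneticDistances(bm)
    geo <- geographicDistances(bm, popFrame)
    mt <- mantelTest(gen, geo, nPerm = config$nPerm, seed = seed + 2L)
    phi <- phiSt(bm, nPerm = min(config$nPerm, 199), seed = seed + 3L)
    emit(data.frame(statistic = c("mantel_r", "mantel_p", "phi_st",
                                  "phi_st_p"),
                    value = c(mt$r, mt$p, phi$phi, phi$p)),
         "structure.csv")

    fst <- if (!is.null(config$fst)) config$fst else phi$phi
    rare <- findRareBands(bm, config$freqThresh, config$occThresh)
    rguc <- NULL
    if (nrow(rare) >= 3) {
        rare <- assignPSA(rare, clusters, bm)
        emit(rare, "rare_bands.csv")
        K <- max(clusters)
        nPop <- nPopulations(fst, config$target)
        nInt <- rep(min(nPop$nInteger, min(table(clusters[popFrame$population]))), K)
        sel <- selectRGUCs(bm, desc, clusters, nInt, rare$locus)
        base <- randomCaptureBaseline(bm, clusters, nInt, rare$locus,
                                      reps = config$reps,
                                      seed = seed + 4L)
        rv <- rValue(rare)
        rguc <- data.frame(
            quantity = c("n_real", "n_integer", "r_value_pct",
                         "capture_all_pct", "capture_rare_pct",
                         "random_capture_all_pct",
                         "random_capture_rare_pct"),
            value = c(nPop$nReal, nPop$nInteger, rv$Rpct,
                      sel$capture["allBands"], sel$capture["rareBands"],
                      base$allBands, base$rareBands))
        emit(rguc, "rguc_summary.csv")
        emit(data.frame(cluster = rep(seq_len(K), lengths(sel$perCluster)),
                        population = unlist(sel$perCluster)),
             "selected_populations.csv")
    }

    F <- coancestry(bm)
    plan <- maximizeDmax(F, replicates = config$reps, seed = seed + 5L)
    basePool <- randomPoolBaseline(F, reps = config$reps,
                                   seed = seed + 6L)
    sb <- data.frame(population = names(plan$contributions),
                     contribution = as.numeric(plan$contributions),
                     count1000 = as.numeric(plan$counts))
    emit(sb, "seedbank.csv")
    emit(data.frame(quantity = c("Dmax", "random_pool_mean"),
                    value = c(plan$Dmax, basePool$mean)),
         "seedbank_summary.csv")
    if (nlevels(populations(bm)) >= 3)
        emit(leaveOneOutContributions(bm), "leave_one_out.csv")

    geneclimOut <- NULL
    if (doGeneclim && !is.null(stack) && !is.null(popCov)) {
        keep <- vifFilter(popCov, r2Thresh = 0.7)
        model <- fitTurnover(bm, popCov[, keep, drop = FALSE],
                             nTrees = config$nTrees, seed = seed + 7L)
        emit(data.frame(predictor = names(model@importance),
                        importance = as.numeric(model@importance)),
             "geneclim_importance.csv")
        if (sum(model@importance) > 0) {
            map <- mapGroups(model, popCov[, keep, drop = FALSE], stack,
                             nGroups = config$nGroups,
                             nAxes = config$nAxes)
            writeAsciiGrid(map@groupRaster,
                           file.path(outDir, "genetic_groups.asc"),
                           stack@xll, stack@yll, stack@cellsize)
            files <- c(files, file.path(outDir, "genetic_groups.asc"))
            emit(data.frame(population = rownames(map@popScores),
                            group = as.integer(map@popGroups),
                            map@popScores),
                 "geneclim_population_scores.csv")
            geneclimOut <- list(retainedLayers = keep,
                                importance = as.list(model@importance))
        }
    }

    manifest <- list(
        package = "RGUCkit",
        version = as.character(utils::packageVersion("RGUCkit")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        parameters = config[setdiff(names(config), "outDir")],
        clusters = as.list(clusters),
        fst = fst,
        files = basename(files),
        geneclim = geneclimOut)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    file.remove(partial)
    invisible(manifest)
}
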