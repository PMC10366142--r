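# Orchestration and format plumbing: plain-text PGM raster IO, YAML run
# configuration, deterministic stage seeding and the end-to-end pipeline
# (simulate -> correct -> detect -> summarize; domains; overlap).

#' Plain-text PGM raster IO
#'
#' Reads and writes 16-bit grayscale rasters as plain-text PGM (P2), a
#' portable, lossless text format for integer images (readable by ImageJ
#' and scikit-image). Values are rounded and clipped to [0, maxval] on
#' writing.
#'
#' @param path file path.
#' @param m numeric or integer matrix.
#' @param maxval maximum gray value written to the header (default 65535).
#' @return \code{readImagePGM}: an integer matrix; \code{writeImagePGM}: the
#'   path, invisibly.
#' @examples
#' p <- tempfile(fileext = ".pgm")
#' writeImagePGM(matrix(1:6, 2, 3), p)
#' readImagePGM(p)
#' @export
writeImagePGM <- function(m, path, maxval = 65535L) {
    m <- round(as.matrix(m))
    m[m < 0] <- 0; m[m > maxval] <- maxval
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
    writeLines(apply(m, 1, paste, collapse = " "), con)
    invisible(path)
}

#' @rdname writeImagePGM
#' @export
readImagePGM <- function(path) {
    toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (toks[1] != "P2") stop("not a plain (P2) PGM file")
    nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
    vals <- as.integer(toks[-(1:4)])
    if (length(vals) != nr * nc) stop("truncated PGM data")
    matrix(vals, nr, nc, byrow = TRUE)
}

#' Derive a deterministic per-stage seed from a global seed
#'
#' Stage names are hashed into the seed so stages are reproducible
#' independently of one another; the result stays below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return an integer seed.
#' @export
stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 65521
    as.integer((as.numeric(seed) * 31 + h * 2654435 + 1) %% 2147483629)
}

#' Default run configuration
#'
#' A complete configuration list mirroring the pipeline defaults (every
#' parameter echoes the published value where one exists); edit and pass to
#' \code{\link{runPipeline}}, or save with \code{\link{writeRunConfig}}.
#'
#' @return a nested list.
#' @export
defaultRunConfig <- function() {
    list(
        stages = c("simulate", "correct", "detect"),
        seed = 1L,
        simulate = list(
            width_px = 512L, height_px = 512L, pixel_size_um = 0.16,
            n_nuclei = 5L, nucleus_diameter_px_range = c(90, 140),
            condensates_per_nucleus = 3, condensate_count_model = "fixed",
            condensate_diameter_um_range = c(0.8, 2.0),
            phenotype_mix = FALSE, large_cell_fraction = 0.5,
            small_diameter_um_range = c(0.8, 0.9),
            large_diameter_um_range = c(1.5, 2.0),
            condensate_peak_intensity = 200,
            nuclear_background_intensity = 200, camera_offset = 100,
            vignette_strength = 0.3, noise_sigma = 20),
        illumination = list(smoothing_sigma_px = 50, floor_fraction = 1e-3),
        detection = list(
            nucleus_diameter_px_range = c(80, 300),
            remove_border_nuclei = TRUE,
            speckle_feature_diameter_px = 40,
            round1_diameter_px_range = c(6, 40),
            round1_adaptive_window_px = 50,
            robust_trim_low = 0.05, robust_trim_high = 0.05, robust_n_sd = 2,
            round2_diameter_px_range = c(8, 40),
            otsu_correction_factor = 0.5,
            large_condensate_min_diameter_um = 1.25,
            large_condensate_min_count = 2,
            expression_gate_range = c(-Inf, Inf)),
        domains = list(mode = "rank_slope", fixed_cutoff_bp = 96000,
                       window = 10, slope_threshold = 1.0,
                       bed = NULL,
                       simulate = list(n = 250L, regime = "piecewise")),
        overlap = list(iters = 20L, a = NULL, b = NULL, universe = NULL,
                       simulate = list(universe_size = 1000L, n_a = 100L,
                                       n_b = 50L, planted_overlap = 20L)))
}

#' Read and write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return \code{readRunConfig}: the configuration list;
#'   \code{writeRunConfig}: the path, invisibly.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

configToDetectionParams <- function(d) {
    detectionParams(
        nucleusDiameterPxRange = d$nucleus_diameter_px_range,
        removeBorderNuclei = d$remove_border_nuclei,
        speckleFeatureDiameterPx = d$speckle_feature_diameter_px,
        round1DiameterPxRange = d$round1_diameter_px_range,
        round1AdaptiveWindowPx = d$round1_adaptive_window_px,
        robustTrimLow = d$robust_trim_low,
        robustTrimHigh = d$robust_trim_high,
        robustNSD = d$robust_n_sd,
        round2DiameterPxRange = d$round2_diameter_px_range,
        otsuCorrectionFactor = d$otsu_correction_factor,
        largeCondensateMinDiameterUm = d$large_condensate_min_diameter_um,
        largeCondensateMinCount = d$large_condensate_min_count,
        expressionGateRange = d$expression_gate_range)
}

configToSimSpec <- function(s, seed) {
    simImageSpec(
        widthPx = s$width_px, heightPx = s$height_px,
        pixelSizeUm = s$pixel_size_um, nNuclei = s$n_nuclei,
        nucleusDiameterPxRange = s$nucleus_diameter_px_range,
        condensatesPerNucleus = s$condensates_per_nucleus,
        condensateCountModel = s$condensate_count_model,
        condensateDiameterUmRange = s$condensate_diameter_um_range,
        phenotypeMix = s$phenotype_mix,
        largeCellFraction = s$large_cell_fraction,
        smallDiameterUmRange = s$small_diameter_um_range,
        largeDiameterUmRange = s$large_diameter_um_range,
        condensatePeakIntensity = s$condensate_peak_intensity,
        nuclearBackgroundIntensity = s$nuclear_background_intensity,
        cameraOffset = s$camera_offset,
        vignetteStrength = s$vignette_strength,
        noiseSigma = s$noise_sigma,
        seed = seed)
}

writeJsonFile <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in the fixed order simulate, correct,
#' detect, domains, overlap, writing every artifact under \code{outdir} and
#' finishing with a \code{manifest.json} listing each output file with its
#' MD5 checksum, the fully resolved configuration and the seed. Identical
#' configuration and seed give byte-identical manifests. Any stage failure
#' aborts with the stage name in the error message.
#'
#' @param config a configuration list (see \code{\link{defaultRunConfig}})
#'   or a YAML path.
#' @param outdir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir) {
    if (is.character(config) && length(config) == 1L)
        config <- readRunConfig(config)
    base <- defaultRunConfig()
    config <- utils::modifyList(base, config)
    stages <- config$stages
    known <- c("simulate", "correct", "detect", "domains", "overlap")
    if (length(stages) == 0L) stop("nothing to run: no stages selected")
    if (!all(stages %in% known))
        stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
    stages <- known[known %in% stages]
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    addFile <- function(p) files <<- c(files, p)
    inStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    }
    seed <- config$seed
    state <- list()

    if ("simulate" %in% stages) inStage("simulate", {
        spec <- configToSimSpec(config$simulate, stageSeed(seed, "simulate"))
        sim <- simulateMicrograph(spec)
        state$sim <- sim
        for (nm in c("raw", "empty", "emptyFluorophore")) {
            p <- file.path(outdir, paste0(nm, ".pgm"))
            writeImagePGM(imageValues(sim[[nm]]), p)
            addFile(p)
        }
        p <- file.path(outdir, "nuclei.pgm")
        writeImagePGM(sim$nucleusLabels, p); addFile(p)
        p <- file.path(outdir, "truth_condensates.csv")
        write.csv(sim$truth$condensates, p, row.names = FALSE); addFile(p)
        p <- file.path(outdir, "truth_cells.csv")
        write.csv(sim$truth$cells, p, row.names = FALSE); addFile(p)
    })

    if ("correct" %in% stages) inStage("correct", {
        if (is.null(state$sim))
            stop("the correct stage requires the simulate stage (or supply images programmatically)")
        il <- config$illumination
        fld <- computeIlluminationFunction(state$sim$emptyFluorophore,
                                           state$sim$empty,
                                           il$smoothing_sigma_px,
                                           il$floor_fraction)
        corrected <- applyFlatField(state$sim$raw, state$sim$empty, fld)
        state$corrected <- corrected
        p <- file.path(outdir, "corrected.pgm")
        writeImagePGM(imageValues(corrected), p); addFile(p)
    })

    if ("detect" %in% stages) inStage("detect", {
        if (is.null(state$corrected))
            stop("the detect stage requires the correct stage")
        params <- configToDetectionParams(config$detection)
        nuclei <- filterNuclei(state$sim$nucleusLabels, params)
        enhanced <- enhanceSpeckles(state$corrected,
                                    params@speckleFeatureDiameterPx)
        det <- detectCondensates(enhanced, nuclei, params)
        meas <- measureCondensates(state$corrected, det$labels, nuclei)
        called <- callLargePositiveCells(meas$cells, meas$objects, params)
        p <- file.path(outdir, "objects.csv")
        write.csv(meas$objects, p, row.names = FALSE); addFile(p)
        p <- file.path(outdir, "cells.csv")
        write.csv(called$cells, p, row.names = FALSE); addFile(p)
        p <- file.path(outdir, "labels.pgm")
        writeImagePGM(det$labels, p); addFile(p)
        p <- file.path(outdir, "run.json")
        writeJsonFile(list(
            n_nuclei = nrow(called$cells),
            n_condensates = nrow(meas$objects),
            fraction_large_positive = called$fractionPositive,
            seed = seed, detection = config$detection), p)
        addFile(p)
    })

    if ("domains" %in% stages) inStage("domains", {
        dcfg <- config$domains
        gr <- if (!is.null(dcfg$bed)) readDomainsBed(dcfg$bed) else {
            simArgs <- dcfg$simulate
            ds <- simulateDomainSizes(simArgs$n, simArgs$regime,
                                      seed = stageSeed(seed, "domains"))
            sizes <- ds$sizes
            starts <- cumsum(c(1, sizes[-length(sizes)] + 1000))
            GenomicRanges::GRanges("chrS",
                IRanges::IRanges(starts, width = sizes))
        }
        cls <- classifyLargeDomains(gr, mode = dcfg$mode,
                                    fixedCutoffBp = dcfg$fixed_cutoff_bp,
                                    window = dcfg$window,
                                    slopeThreshold = dcfg$slope_threshold)
        writeDomainsBed(cls$large, file.path(outdir, "large.bed"))
        addFile(file.path(outdir, "large.bed"))
        writeDomainsBed(cls$small, file.path(outdir, "small.bed"))
        addFile(file.path(outdir, "small.bed"))
        cut <- cls$cutoff
        info <- if (is(cut, "CutoffResult")) list(
            mode = dcfg$mode, cutoff_bp = cutoffBp(cut),
            crossing_index = crossingIndex(cut), n = length(gr),
            n_large = nLarge(cut), window = dcfg$window,
            slope_threshold = dcfg$slope_threshold, status = cut@status)
        else list(mode = dcfg$mode, cutoff_bp = cls$cutoffBp,
                  n = length(gr), n_large = length(cls$large))
        writeJsonFile(info, file.path(outdir, "cutoff.json"))
        addFile(file.path(outdir, "cutoff.json"))
        if (is(cut, "CutoffResult")) {
            writeCurveTsv(cut, file.path(outdir, "curve.tsv"))
            addFile(file.path(outdir, "curve.tsv"))
        }
    })

    if ("overlap" %in% stages) inStage("overlap", {
        ocfg <- config$overlap
        oseed <- stageSeed(seed, "overlap")
        if (!is.null(ocfg$a) && !is.null(ocfg$b) && !is.null(ocfg$universe)) {
            a <- readGeneSet(ocfg$a); b <- readGeneSet(ocfg$b)
            u <- readGeneSet(ocfg$universe)
        } else {
            sa <- ocfg$simulate
            gs <- simulateGeneSets(sa$universe_size, sa$n_a, sa$n_b,
                                   sa$planted_overlap, seed = oseed)
            a <- gs$setA; b <- gs$setB; u <- gs$universe
        }
        ov <- geneSetOverlap(a, b, u, iters = ocfg$iters, seed = oseed)
        writeJsonFile(list(
            n_a_only = ov@nAOnly, n_b_only = ov@nBOnly,
            observed_overlap = ov@observedOverlap,
            expected_random_mean = ov@expectedRandomMean,
            expected_random_sd = ov@expectedRandomSD,
            expected_analytic = ov@expectedAnalytic,
            representation_factor = ov@representationFactor,
            p_value = ov@pValue, iters = ov@iters,
            universe_size = ov@universeSize, seed = oseed),
            file.path(outdir, "overlap.json"))
        addFile(file.path(outdir, "overlap.json"))
    })

    checks <- tools::md5sum(files)
    manifest <- list(
        seed = seed,
        stages = stages,
        config = config,
        files = lapply(seq_along(files), function(i) list(
            path = basename(files[i]), md5 = unname(checks[i]))))
    writeJsonFile(manifest, file.path(outdir, "manifest.json"))
    invisible(manifest)
}
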