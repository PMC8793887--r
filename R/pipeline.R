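#' Write a flow dataset to NIfTI volumes
#'
#' Writes the three velocity components (one 4-D NIfTI per component,
#' frames on the 4th axis), the magnitude, the lumen mask (0/1) and a JSON
#' sidecar carrying venc, frame duration, spacing and origin.
#'
#' @param field a [FlowField-class].
#' @param mask 3-D logical array (may be NULL).
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
writeFlowField <- function(field, mask = NULL, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sp <- field@spacing
    for (c in 1:3) {
        v <- field@velocity[, , , , c]
        RNifti::writeNifti(RNifti::asNifti(v, pixdim = c(sp, field@frameDuration)),
                           file.path(dir, paste0("vel_", c("x", "y", "z")[c], ".nii.gz")))
    }
    RNifti::writeNifti(RNifti::asNifti(field@magnitude,
                                       pixdim = c(sp, field@frameDuration)),
                       file.path(dir, "mag.nii.gz"))
    if (!is.null(mask))
        RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask)),
                                           pixdim = sp),
                           file.path(dir, "mask.nii.gz"))
    side <- file.path(dir, "sidecar.json")
    jsonlite::write_json(list(venc = field@venc,
                              frameDuration = field@frameDuration,
                              spacing = sp, origin = field@origin),
                         side, auto_unbox = TRUE, digits = NA)
    invisible(side)
}

#' Read a flow dataset written by [writeFlowField()]
#'
#' @param dir directory with vel_x/y/z, mag, optional mask and the sidecar.
#' @return list with \code{field} ([FlowField-class]) and \code{mask}
#'   (logical array or NULL).
#' @export
readFlowField <- function(dir) {
    side <- file.path(dir, "sidecar.json")
    if (!file.exists(side))
        stop("missingInput: no sidecar.json in ", dir)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    plain <- function(f) {
        x <- RNifti::readNifti(f)
        array(as.numeric(x), dim(x))
    }
    comp <- lapply(c("x", "y", "z"), function(a) {
        f <- file.path(dir, paste0("vel_", a, ".nii.gz"))
        if (!file.exists(f)) stop("missingInput: ", f)
        plain(f)
    })
    vel <- array(0, c(dim(comp[[1]]), 3L))
    for (c in 1:3) vel[, , , , c] <- comp[[c]]
    magf <- file.path(dir, "mag.nii.gz")
    mag <- if (file.exists(magf)) plain(magf) else NULL
    maskf <- file.path(dir, "mask.nii.gz")
    mask <- if (file.exists(maskf)) plain(maskf) > 0.5 else NULL
    list(field = flowField(vel, mag, spacing = meta$spacing,
                           origin = meta$origin,
                           frameDuration = meta$frameDuration,
                           venc = meta$venc),
         mask = mask)
}

.validateRunConfig <- function(config) {
    cst <- config$constants
    if (!is.null(cst)) {
        for (nm in intersect(names(cst), c("rho", "mu", "stasisThreshold",
                                           "voxelVolume")))
            if (!is.numeric(cst[[nm]]) || cst[[nm]] <= 0)
                stop("invalidConfig: constant '", nm, "' must be positive")
    }
    if (is.null(config$input) && is.null(config$phantom))
        stop("invalidConfig: either 'input' (directory) or 'phantom' (spec) required")
    if (!is.null(config$boundaries)) {
        b <- as.numeric(config$boundaries)
        if (length(b) != 4L || any(diff(b) <= 0))
            stop("invalidConfig: boundaries must be 4 increasing values")
    }
    invisible(TRUE)
}

.loadConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config
}

#' Run the full per-subject analysis
#'
#' Orchestrates preprocessing (noise mask, velocity anti-aliasing,
#' eddy-current correction, Maxwell stub, PC-MRA), 1 mm isotropic
#' resampling, centreline extraction, nearest-plane voxel matching, the
#' five-region split, the voxel-wise parameter maps, diameters and the
#' regional summary, then writes maps (NIfTI), projections (PNG), the
#' regional summary (CSV) and a provenance record (JSON). On failure any
#' partially written outputs are removed.
#'
#' @param config list or path to a YAML file. Fields: \code{input}
#'   (directory readable by [readFlowField()]) or \code{phantom} (arguments
#'   to [phantomSpec()]); \code{boundaries} (four arc lengths in mm, or
#'   fractions of the span when all below 1; default 0.10/0.45/0.60/0.80);
#'   \code{constants} (overrides for rho, mu, stasisThreshold);
#'   \code{subject} (id), \code{bsa} or \code{height}+\code{weight};
#'   \code{out} (output directory, optional); \code{seed}.
#' @return invisibly, a result bundle: field, mask, pcmra, centerline,
#'   assignment, labels, maps, diameters, geometry, summary, reynolds,
#'   qc, paths.
#' @export
runSubject <- function(config) {
    config <- .loadConfig(config)
    .validateRunConfig(config)
    cst <- do.call(flowConstants, config$constants %||% list())
    if (!is.null(config$input)) {
        ds <- readFlowField(config$input)
        if (is.null(ds$mask)) stop("missingInput: no mask.nii.gz in input")
        field <- ds$field; mask <- ds$mask
    } else {
        spec <- do.call(phantomSpec, config$phantom)
        ph <- .generatePhantom(spec)
        field <- ph$field; mask <- ph$truth$mask
    }
    qc <- list()
    keep <- noiseMask(field)
    field <- unwrapVelocity(field)
    qc$irresolvableWraps <- attr(field, "qcIrresolvable")
    field <- correctEddy(field)
    field <- suppressMessages(correctMaxwell(field))
    pcmra <- computePCMRA(field)
    iso <- interpolateIsotropic(field, mask & keep)
    cl <- extractCenterline(iso$mask, spacing = iso$field@spacing,
                            origin = iso$field@origin)
    asg <- assignVoxels(iso$mask, cl, spacing = iso$field@spacing,
                        origin = iso$field@origin)
    ori <- orientByFlow(cl, asg, iso$field)
    cl <- ori$centerline; asg <- ori$assignment
    qc$centerlineFlipped <- ori$flipped
    b <- as.numeric(config$boundaries %||% c(0.10, 0.45, 0.60, 0.80))
    if (all(b < 1)) b <- b * max(cl@arcLength)
    labels <- splitRegions(cl, asg, b)
    maps <- computeVoxelMaps(iso$field, iso$mask, asg, cl, cst)
    dia <- measureDiameters(iso$mask, cl, labels, asg,
                            spacing = iso$field@spacing,
                            origin = iso$field@origin)
    qc$emptyStations <- dia$qcEmptyStations
    sbsa <- config$bsa %||%
        if (!is.null(config$height)) bsa(config$height, config$weight) else NA
    geo <- if (is.finite(sbsa)) aorticGeometryReport(dia$regions, sbsa) else NULL
    summ <- regionalSummary(maps, labels, asg, geo)
    re <- reynoldsNumber(maps, asg, dia, cst)

    paths <- NULL
    if (!is.null(config$out)) {
        out <- config$out
        created <- !dir.exists(out)
        tryCatch({
            dir.create(out, showWarnings = FALSE, recursive = TRUE)
            sp <- iso$field@spacing
            for (p in c("ff", "rf", "stasis", "ke", "peakVelocity")) {
                m <- slot(maps, p)
                m[is.na(m)] <- 0
                RNifti::writeNifti(RNifti::asNifti(m, pixdim = sp),
                                   file.path(out, paste0(p, ".nii.gz")))
                grDevices::png(file.path(out, paste0(p, "_meanproj.png")),
                               width = 480, height = 480)
                graphics::image(meanProjection(slot(maps, p), "y"),
                                main = p, useRaster = TRUE)
                grDevices::dev.off()
            }
            RNifti::writeNifti(RNifti::asNifti(pcmra$data,
                                               pixdim = field@spacing),
                               file.path(out, "pcmra.nii.gz"))
            units <- c(ff = "mL/cycle", rf = "mL/cycle", stasis = "%",
                       ke = "uJ", peakVelocity = "m/s")
            long <- do.call(rbind, lapply(names(units), function(p)
                data.frame(subject = config$subject %||% "subject",
                           region = summ$region, parameter = p,
                           value = summ[[p]], units = units[[p]])))
            utils::write.csv(long, file.path(out, "regional_summary.csv"),
                             row.names = FALSE)
            jsonlite::write_json(list(
                package = "VoxelFlow",
                version = as.character(utils::packageVersion("VoxelFlow")),
                constants = unclass(cst), boundaries = b,
                seed = config$seed %||% NA,
                systoleFrames = maps@systoleFrames,
                reynolds = re, qc = qc),
                file.path(out, "provenance.json"),
                auto_unbox = TRUE, digits = NA, force = TRUE)
            paths <- out
        }, error = function(e) {
            if (created) unlink(out, recursive = TRUE)
            stop(e)
        })
    }
    invisible(list(field = iso$field, mask = iso$mask, pcmra = pcmra,
                   centerline = cl, assignment = asg, labels = labels,
                   maps = maps, diameters = dia, geometry = geo,
                   summary = summ, reynolds = re, qc = qc, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort aggregation and statistics stage
#'
#' Assembles a subject-level cohort table (or accepts one, e.g. from
#' [synthCohort()]) and runs the declared analysis plan: per-parameter
#' group comparisons, effect-size-gated correlations against a dependent
#' variable, and the standardized multivariable model. Subjects with type-2
#' or unknown valve phenotype are excluded from valve-type contrasts.
#'
#' @param table subject-level data.frame (one row per subject; regional
#'   parameter columns named \code{<region>_<parameter>}).
#' @param plan list with optional entries: \code{compare} (character of
#'   columns to compare between cohorts; default every regional column),
#'   \code{correlate} (list: \code{dependent}, \code{with}, \code{group}),
#'   \code{model} (list: \code{dependent}, \code{candidates},
#'   \code{group}). An empty list runs no statistics.
#' @param out optional output directory for CSV/JSON reports.
#' @return list: \code{table}, \code{comparisons}, \code{correlations},
#'   \code{model}.
#' @export
runCohort <- function(table, plan = cohortAnalysisPlan(table), out = NULL) {
    res <- list(table = table, comparisons = NULL, correlations = NULL,
                model = NULL)
    nCohorts <- length(unique(table$cohort))
    if (length(plan) == 0) return(res)
    if (!is.null(plan$compare)) {
        if (nCohorts < 2L) {
            warning("single-cohort input; group statistics skipped")
        } else {
            res$comparisons <- do.call(rbind, lapply(plan$compare, function(p)
                compareGroups(table, p)))
        }
    }
    if (!is.null(plan$correlate)) {
        sub <- table
        if (!is.null(plan$correlate$group))
            sub <- table[table$cohort == plan$correlate$group, , drop = FALSE]
        if (!is.null(sub$valveType))
            sub <- sub[!sub$valveType %in% c("2", "unknown"), , drop = FALSE]
        res$correlations <- do.call(rbind, lapply(plan$correlate$with,
            function(p) correlate(sub, p, plan$correlate$dependent)))
    }
    if (!is.null(plan$model)) {
        sub <- table
        if (!is.null(plan$model$group))
            sub <- table[table$cohort == plan$model$group, , drop = FALSE]
        if (!is.null(sub$valveType))
            sub <- sub[!sub$valveType %in% c("2", "unknown"), , drop = FALSE]
        res$model <- multivariateModel(sub, plan$model$dependent,
                                       plan$model$candidates)
    }
    if (!is.null(out)) {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(table, file.path(out, "cohort_table.csv"),
                         row.names = FALSE)
        if (!is.null(res$comparisons))
            utils::write.csv(res$comparisons,
                             file.path(out, "comparisons.csv"),
                             row.names = FALSE)
        if (!is.null(res$correlations))
            utils::write.csv(res$correlations,
                             file.path(out, "correlations.csv"),
                             row.names = FALSE)
        rep <- res[c("comparisons", "correlations")]
        rep$model <- if (!is.null(res$model))
            res$model[c("coefficients", "overallR", "dropped")] else NULL
        jsonlite::write_json(rep, file.path(out, "stats_report.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    res
}

#' Default cohort analysis plan
#'
#' Mirrors the standard analysis: compare every regional parameter between
#' cohorts; within the patient cohort, correlate the BSA-indexed AAo
#' diameter with age and the AAo hemodynamic parameters; build the
#' multivariable model on the same candidates.
#'
#' @param table the cohort table (used to enumerate regional columns and
#'   find the patient cohort label).
#' @return a plan list for [runCohort()].
#' @export
cohortAnalysisPlan <- function(table) {
    regional <- grep(paste0("^(", paste(aorticRegions, collapse = "|"), ")_"),
                     names(table), value = TRUE)
    patients <- setdiff(unique(table$cohort), "control")[1]
    dep <- intersect("AAo_indexedDiameter", names(table))
    cand <- intersect(paste0("AAo_", c("ff", "rf", "stasis", "peakVelocity",
                                       "ke")), names(table))
    plan <- list(compare = regional)
    if (length(dep) && length(cand) && !is.na(patients)) {
        plan$correlate <- list(dependent = dep, with = c("age", cand),
                               group = patients)
        plan$model <- list(dependent = dep, candidates = cand,
                           group = patients)
    }
    plan
}
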