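#' Build a pipeline run configuration
#'
#' Collects every named constant of the detection pipeline: 1.0 mm
#' isotropic resampling, a 128-voxel ROI cube, the three sphere-radius
#' model tags (3, 5, 7 mm), the 0.5/0.9 probability thresholds, the 1.1 mm
#' clustering threshold, 64/32 sliding-window geometry, surrogate backend
#' parameters and the master seed.
#'
#' @param backend backend name; only \code{"surrogate"} is provided.
#' @param radii sphere-radius tags in mm (default c(3, 5, 7)).
#' @param targetSpacing isotropic target in mm (default 1.0).
#' @param roiSize ROI edge in voxels (default 128).
#' @param roiCenter explicit ROI centre (world mm) or NA to centre on the
#'   reference landmarks.
#' @param lowThreshold,highThreshold probability thresholds (0.5, 0.9).
#' @param linkThreshold clustering threshold in mm (1.1).
#' @param jitterSd,backgroundScore surrogate parameters (0.5 mm, 0.05).
#' @param window,stride sliding-window voxels (64, 32).
#' @param useSlidingWindow run the backend through the sliding window
#'   instead of whole-volume (default FALSE; the surrogate is window-size
#'   independent).
#' @param seed master seed.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(backend = "surrogate", radii = c(3, 5, 7),
                      targetSpacing = 1.0, roiSize = 128L,
                      roiCenter = c(NA_real_, NA_real_, NA_real_),
                      lowThreshold = 0.5, highThreshold = 0.9,
                      linkThreshold = 1.1, jitterSd = 0.5,
                      backgroundScore = 0.05, window = 64L, stride = 32L,
                      useSlidingWindow = FALSE, seed = 1L) {
    new("RunConfig", backend = backend, radii = radii,
        targetSpacing = targetSpacing, roiSize = as.integer(roiSize),
        roiCenter = as.numeric(roiCenter), lowThreshold = lowThreshold,
        highThreshold = highThreshold, linkThreshold = linkThreshold,
        jitterSd = jitterSd, backgroundScore = backgroundScore,
        window = as.integer(window), stride = as.integer(stride),
        useSlidingWindow = useSlidingWindow, seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
    cat(sprintf(paste0(
        "RunConfig: backend %s, radii %s mm, %g mm iso, ROI %d^3\n",
        "  thresholds %.2g/%.2g, link %.2g mm, jitter %.2g mm, seed %d\n"),
        object@backend, paste(object@radii, collapse = "/"),
        object@targetSpacing, object@roiSize, object@lowThreshold,
        object@highThreshold, object@linkThreshold, object@jitterSd,
        object@seed))
})

.config_fields <- c("backend", "radii", "targetSpacing", "roiSize",
                    "roiCenter", "lowThreshold", "highThreshold",
                    "linkThreshold", "jitterSd", "backgroundScore",
                    "window", "stride", "useSlidingWindow", "seed")

#' Write a run configuration as YAML
#' @param config a [RunConfig-class].
#' @param path YAML output path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    obj <- lapply(.config_fields, function(f) slot(config, f))
    names(obj) <- .config_fields
    yaml::write_yaml(obj, path)
    invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [writeRunConfig()].
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
    obj <- yaml::read_yaml(path)
    do.call(runConfig, obj[intersect(names(obj), .config_fields)])
}

#' Run the full landmark-detection pipeline on one volume
#'
#' Executes resample (isotropic) -> crop (fixed ROI) -> window-normalise ->
#' backend prediction once per sphere radius -> probability-map fusion ->
#' threshold/cluster/centroid landmark extraction -> annular-plane
#' reconstruction with coronary heights. The ROI centre must be supplied
#' either in the config or through the reference landmarks (centroid of
#' the five points, the protocol used at validation time); for genuinely
#' unseen volumes pass an explicit \code{roiCenter}.
#'
#' @param config a [RunConfig-class].
#' @param volume a [CTVolume-class] or a NIfTI file path.
#' @param referenceLandmarks a [LandmarkSet-class] or landmark JSON path;
#'   required by the surrogate backend (which emulates a trained model
#'   around the true positions) and, when \code{roiCenter} is NA, used to
#'   centre the ROI.
#' @param outDir optional output directory; when given, landmark JSON,
#'   measurements CSV and diagnostics CSV are written.
#' @param id case identifier used in output file names.
#' @return list: landmarks ([LandmarkSet-class]), measurements (named
#'   numeric), diagnostics (data.frame), roiCenter.
#' @export
runDetection <- function(config, volume, referenceLandmarks,
                         outDir = NULL, id = "case") {
    if (is.character(volume)) volume <- readVolume(volume)
    if (is.character(referenceLandmarks))
        referenceLandmarks <- readLandmarks(referenceLandmarks)
    if (config@backend != "surrogate")
        stop("unknown backend: ", config@backend)
    roiCenter <- config@roiCenter
    if (any(is.na(roiCenter))) {
        if (is.null(referenceLandmarks))
            stop("an ROI centre is required: supply roiCenter in the ",
                 "config or reference landmarks to centre on")
        roiCenter <- colMeans(landmarkPoints(referenceLandmarks))
    }
    iso <- resampleIsotropic(volume, config@targetSpacing)
    roi <- suppressWarnings(cropCentered(iso, roiCenter, config@roiSize))
    norm <- normalizeVolume(roi)
    perRadius <- lapply(config@radii, function(r) {
        backend <- surrogateBackend(r, referenceLandmarks,
                                    jitterSd = config@jitterSd,
                                    backgroundScore = config@backgroundScore,
                                    seed = config@seed)
        if (config@useSlidingWindow)
            slidingWindowPredict(norm, backend, config@window,
                                 config@stride)
        else predictProbabilities(backend, norm)
    })
    fused <- fuseProbabilityMaps(perRadius)
    det <- detectLandmarks(fused, low = config@lowThreshold,
                           high = config@highThreshold,
                           linkThreshold = config@linkThreshold)
    meas <- deriveMeasurements(det$landmarks)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeLandmarks(det$landmarks,
                       file.path(outDir, paste0(id, "_predicted.json")))
        writeMeasurements(meas,
                          file.path(outDir, paste0(id, "_measurements.csv")),
                          patientId = id)
        utils::write.csv(det$diagnostics,
                         file.path(outDir, paste0(id, "_diagnostics.csv")),
                         row.names = FALSE)
    }
    list(landmarks = det$landmarks, measurements = meas,
         diagnostics = det$diagnostics, roiCenter = roiCenter)
}

#' Synthetic end-to-end validation run
#'
#' Generates a seeded phantom cohort, runs the full detection pipeline on
#' every case, and reproduces the validation statistics against the known
#' phantom truth: per-class and pooled median (LQ-UQ) landmark errors,
#' plus coronary-height agreement (r^2 and Bland-Altman bias/limits).
#' Failed cases are counted and reported, never silently dropped.
#'
#' @param config a [RunConfig-class].
#' @param n cohort size (>= 5).
#' @param seed master cohort seed.
#' @param dir working directory for cohort files (default a tempdir).
#' @param shape,spacing phantom grid parameters (see [phantomSpec()]).
#' @param verbose print one line per case (default FALSE).
#' @return list: errors (distance table), summary (Table-2-style
#'   data.frame with columns class, n, median, lq, uq, shapiro_p,
#'   paired_diff_mean, paired_diff_sd, p_value), heights (per-case
#'   data.frame), heightAgreement (Table-3-style data.frame), failures
#'   (character vector of failed case ids), manifest.
#' @export
runValidation <- function(config, n, seed, dir = tempfile("cohort"),
                          shape = c(160L, 160L, 160L), spacing = 0.7,
                          verbose = FALSE) {
    if (n < 5L) stop("n must be >= 5")
    manifest <- generateCohort(n, seed, dir, shape = shape,
                               spacing = spacing)
    rows <- list()
    heights <- list()
    failures <- character()
    for (i in seq_len(n)) {
        truth <- readLandmarks(manifest$landmarks[i])
        caseConfig <- config
        caseConfig@seed <- as.integer(manifest$seed[i])
        res <- tryCatch(
            runDetection(caseConfig, manifest$volume[i], truth),
            error = function(e) e)
        if (inherits(res, "error")) {
            failures <- c(failures, manifest$id[i])
            if (verbose) message(manifest$id[i], " FAILED: ",
                                 conditionMessage(res))
            next
        }
        err <- landmarkErrors(res$landmarks, truth)
        rows[[i]] <- distanceTable(rep(manifest$id[i], 5L), names(err),
                                   unname(err))
        tm <- deriveMeasurements(truth)
        heights[[i]] <- data.frame(
            case = manifest$id[i],
            lco_pred = res$measurements[["lco_height_mm"]],
            lco_true = tm[["lco_height_mm"]],
            rco_pred = res$measurements[["rco_height_mm"]],
            rco_true = tm[["rco_height_mm"]])
        if (verbose) message(manifest$id[i], " pooled median err ",
                             round(stats::median(err), 3), " mm")
    }
    errors <- do.call(rbind, rows)
    if (is.null(errors)) stop("all cases failed")
    summary <- summarizeDistances(errors)
    summary$paired_diff_mean <- NA_real_
    summary$paired_diff_sd <- NA_real_
    summary$p_value <- NA_real_
    hdf <- do.call(rbind, heights)
    heightAgreement <- do.call(rbind, lapply(
        c(lco = "lco", rco = "rco"), function(side) {
            pred <- hdf[[paste0(side, "_pred")]]
            tru <- hdf[[paste0(side, "_true")]]
            ba <- blandAltman(pred, tru)
            pd <- pairedDifferenceTest(pred, tru)
            data.frame(measure = paste0(toupper(side), " height"),
                       r2 = correlationR2(pred, tru),
                       median_pred = stats::median(pred),
                       median_true = stats::median(tru),
                       bias = ba$bias, loa_lower = ba$loaLower,
                       loa_upper = ba$loaUpper, p_value = pd$p)
        }))
    list(errors = errors, summary = summary, heights = hdf,
         heightAgreement = heightAgreement, failures = failures,
         manifest = manifest)
}

#' Compare two completed landmark runs (Table-2-style)
#'
#' Given per-landmark error lists of two methods against one ground truth
#' (e.g. automatic vs a second observer), reports per-class and pooled
#' median (LQ-UQ) for both, the paired difference d1 - d2 (mean +/- sd)
#' and its Wilcoxon signed-rank p-value.
#'
#' @param table1,table2 distance tables from [distanceTable()] with
#'   matching case/class rows.
#' @return data.frame: class, median1, lq1, uq1, median2, lq2, uq2,
#'   paired_diff_mean, paired_diff_sd, p_value.
#' @export
compareRuns <- function(table1, table2) {
    key1 <- paste(table1$case, table1$class)
    key2 <- paste(table2$case, table2$class)
    if (!setequal(key1, key2)) stop("tables do not cover the same pairs")
    table2 <- table2[match(key1, key2), ]
    per <- function(sub1, sub2, label) {
        q1 <- stats::quantile(sub1, c(0.25, 0.5, 0.75), type = 7,
                              names = FALSE)
        q2 <- stats::quantile(sub2, c(0.25, 0.5, 0.75), type = 7,
                              names = FALSE)
        pd <- pairedDifferenceTest(sub1, sub2)
        data.frame(class = label, median1 = q1[2], lq1 = q1[1], uq1 = q1[3],
                   median2 = q2[2], lq2 = q2[1], uq2 = q2[3],
                   paired_diff_mean = pd$mean, paired_diff_sd = pd$sd,
                   p_value = pd$p)
    }
    out <- do.call(rbind, lapply(
        intersect(.LANDMARK_CLASSES, unique(table1$class)), function(cl) {
            s <- table1$class == cl
            per(table1$error[s], table2$error[s], cl)
        }))
    rbind(out, per(table1$error, table2$error, "All"))
}
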