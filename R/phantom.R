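#' Draw a seeded phantom specification
#'
#' Materialises every random parameter of a synthetic contrast-enhanced
#' aortic-root CT volume from one seed and records the draws, so the same
#' spec always renders identically. Defaults emulate clinical TAVI
#' acquisitions: annular radius ~ U(10,14) mm (20-28 mm diameter), annular
#' plane tilted up to 20 deg from axial, hinge points at 90/210/330 deg
#' (+/- U(-10,10) jitter), ostium heights ~ U(10,20) mm bracketing typical
#' clinical medians, contrast-filled lumen ~ N(350,30) HU over soft tissue
#' ~ N(40,10) HU, Poisson(3) calcific deposits at U(700,1500) HU near the
#' hinge points, additive Gaussian noise (20 HU), and optional Gaussian
#' motion blur (1.5 mm when on). Default spacing 0.7 mm so isotropic
#' resampling is genuinely exercised.
#'
#' @param seed integer seed.
#' @param shape voxel counts (default 160^3).
#' @param spacing mm per voxel, scalar or length 3 (default 0.7).
#' @param noiseSd additive noise sd in HU (default 20).
#' @param motionBlurSd motion blur sd in mm (default 0 = off; 1.5 when on).
#' @param annulusRadius,planeTilt,lcoHeight,rcoHeight,lumenHU,tissueHU
#'   optional overrides of the seeded draws.
#' @param calciumCount optional override of the Poisson(3) deposit count.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(seed, shape = c(160L, 160L, 160L), spacing = 0.7,
                        noiseSd = 20, motionBlurSd = 0,
                        annulusRadius = NULL, planeTilt = NULL,
                        lcoHeight = NULL, rcoHeight = NULL,
                        lumenHU = NULL, tissueHU = NULL,
                        calciumCount = NULL) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    set.seed(as.integer(seed))
    draw <- list(
        annulusRadius = stats::runif(1, 10, 14),
        planeTilt = stats::runif(1, 0, 20),
        tiltAzimuth = stats::runif(1, 0, 360),
        hingeJitter = stats::runif(3, -10, 10),
        lcoHeight = stats::runif(1, 10, 20),
        rcoHeight = stats::runif(1, 10, 20),
        lumenHU = stats::rnorm(1, 350, 30),
        tissueHU = stats::rnorm(1, 40, 10),
        calciumCount = stats::rpois(1, 3),
        ostiumAngleJitter = stats::runif(2, -15, 15),
        ostiumRadiusFrac = stats::runif(2, 0.55, 0.85))
    nCa <- if (is.null(calciumCount)) draw$calciumCount else calciumCount
    calciumHU <- if (nCa > 0) stats::runif(nCa, 700, 1500) else numeric()
    calciumOffsets <- matrix(stats::rnorm(max(nCa, 1) * 3, 0, 1.5),
                             ncol = 3)[seq_len(nCa), , drop = FALSE]
    calciumRadii <- if (nCa > 0) stats::runif(nCa, 1.2, 2.5) else numeric()
    blurAxis <- sample.int(3L, 1L)
    new("PhantomSpec",
        shape = as.integer(shape), spacing = as.numeric(spacing),
        seed = as.integer(seed),
        annulusRadius = annulusRadius %||% draw$annulusRadius,
        planeTilt = planeTilt %||% draw$planeTilt,
        tiltAzimuth = draw$tiltAzimuth,
        hingeAngles = c(90, 210, 330) + draw$hingeJitter,
        ostiumAngles = c(90, 330) + draw$ostiumAngleJitter,
        ostiumRadii = draw$ostiumRadiusFrac *
            (annulusRadius %||% draw$annulusRadius),
        lcoHeight = lcoHeight %||% draw$lcoHeight,
        rcoHeight = rcoHeight %||% draw$rcoHeight,
        lumenHU = lumenHU %||% draw$lumenHU,
        tissueHU = tissueHU %||% draw$tissueHU,
        calciumHU = calciumHU, calciumOffsets = calciumOffsets,
        calciumRadii = calciumRadii,
        noiseSd = noiseSd, motionBlurSd = motionBlurSd,
        blurAxis = blurAxis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(paste0(
        "PhantomSpec seed %d: %s voxels @ %s mm\n",
        "  annulus r = %.1f mm, tilt %.1f deg, heights LCO %.1f / RCO %.1f mm\n",
        "  lumen %.0f HU, tissue %.0f HU, %d calcium deposits, noise %g HU%s\n"),
        object@seed, paste(object@shape, collapse = "x"),
        paste(format(object@spacing), collapse = "x"),
        object@annulusRadius, object@planeTilt, object@lcoHeight,
        object@rcoHeight, object@lumenHU, object@tissueHU,
        length(object@calciumHU), object@noiseSd,
        if (object@motionBlurSd > 0)
            sprintf(", motion blur %.1f mm", object@motionBlurSd) else ""))
})

# True landmark geometry implied by a spec: hinge points on a circle of
# annulusRadius in the tilted annular plane, ostia at the spec'd
# perpendicular heights above it.
.phantom_geometry <- function(spec, center) {
    th <- spec@planeTilt * pi / 180
    ph <- spec@tiltAzimuth * pi / 180
    axis <- c(cos(ph), sin(ph), 0)            # tilt axis in the xy plane
    n <- c(sin(th) * -axis[2], sin(th) * axis[1], cos(th))
    n <- n / sqrt(sum(n^2))
    e1 <- .cross3(if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0), n)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- .cross3(n, e1)
    circ <- function(angleDeg, r)
        center + r * (cos(angleDeg * pi / 180) * e1 +
                      sin(angleDeg * pi / 180) * e2)
    hinges <- t(vapply(seq_len(3),
                       function(i) circ(spec@hingeAngles[i],
                                        spec@annulusRadius),
                       numeric(3)))
    lco <- circ(spec@ostiumAngles[1], spec@ostiumRadii[1]) +
        spec@lcoHeight * n
    rco <- circ(spec@ostiumAngles[2], spec@ostiumRadii[2]) +
        spec@rcoHeight * n
    list(center = center, normal = n, e1 = e1, e2 = e2,
         landmarks = landmarkSet(list(LCC = hinges[1, ], NCC = hinges[2, ],
                                      RCC = hinges[3, ], LCO = lco,
                                      RCO = rco)))
}

# Gaussian blur along one array axis; sigma in voxels.
.blur_axis <- function(arr, axis, sigmaVox) {
    if (sigmaVox <= 0) return(arr)
    half <- max(1L, ceiling(3 * sigmaVox))
    k <- stats::dnorm(-half:half, sd = sigmaVox)
    k <- k / sum(k)
    d <- dim(arr)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    n <- da[1]
    # mirror-pad then convolve each column
    idx <- c(pmin(half + 1 - 1:half, n), 1:n, pmax(n - (1:half), 1))
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in -half:half)
        out <- out + k[o + half + 1] * padded[(half + 1 + o):(half + n + o), ,
                                              drop = FALSE]
    a <- array(out, da)
    aperm(a, order(perm))
}

#' Render a synthetic aortic-root CT phantom
#'
#' Renders the volume implied by a [PhantomSpec-class]: a contrast-filled
#' lumen (aortic root and ascending segment, with a sinus bulge at annulus
#' level) along the tilted annular axis, soft-tissue background, calcific
#' deposits near the hinge points, then optional Gaussian motion blur and
#' additive Gaussian noise. The returned landmark set is the exact
#' pre-noise geometry; by construction [deriveMeasurements()] on it
#' returns the spec's ostium heights.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{volume} (a [CTVolume-class], HU) and
#'   \code{landmarks} (a [LandmarkSet-class]).
#' @export
generatePhantom <- function(spec) {
    g <- gridGeometry(spec@shape, spec@spacing,
                      origin = -spec@spacing * (spec@shape - 1) / 2)
    center <- c(0, 0, 0)                     # grid centre by construction
    geo <- .phantom_geometry(spec, center)
    P <- landmarkPoints(geo$landmarks)
    idx <- worldToVoxel(g, P)
    if (any(idx < 0) || any(t(idx) > spec@shape - 1))
        stop("phantom spec places landmarks outside the grid")
    coords <- .voxel_coord_arrays(g)
    rx <- coords$X - center[1]
    ry <- coords$Y - center[2]
    rz <- coords$Z - center[3]
    tAx <- rx * geo$normal[1] + ry * geo$normal[2] + rz * geo$normal[3]
    rad2 <- rx^2 + ry^2 + rz^2 - tAx^2
    rm(rx, ry, rz)
    # lumen: sinus bulge (1.35 r) blending to tubular ascending aorta (1.15 r)
    maxH <- max(spec@lcoHeight, spec@rcoHeight)
    bulge <- 1.35 - 0.2 * pmin(pmax(tAx / 8, 0), 1)
    lumenR <- spec@annulusRadius * bulge
    inLumen <- (tAx >= -10) & (tAx <= maxH + 12) & (rad2 <= lumenR^2)
    vol <- array(spec@tissueHU, dim = spec@shape)
    vol[inLumen] <- spec@lumenHU
    rm(bulge, lumenR, inLumen, rad2, tAx)
    for (ci in seq_along(spec@calciumHU)) {
        hinge <- P[((ci - 1) %% 3) + 1, ]
        ctr <- hinge + spec@calciumOffsets[ci, ]
        d2 <- .voxel_dist2(g, ctr, coords)
        vol[d2 <= spec@calciumRadii[ci]^2] <- spec@calciumHU[ci]
    }
    rm(coords)
    if (spec@motionBlurSd > 0)
        vol <- .blur_axis(vol, spec@blurAxis,
                          spec@motionBlurSd / spec@spacing[spec@blurAxis])
    if (spec@noiseSd > 0) {
        set.seed(spec@seed + 1L)
        vol <- vol + array(stats::rnorm(length(vol), 0, spec@noiseSd),
                           dim = dim(vol))
    }
    list(volume = ctVolume(vol, g, unit = "HU"), landmarks = geo$landmarks)
}

#' Generate a cohort of phantoms on disk
#'
#' Writes \code{n} phantom volumes (NIfTI, int16 HU) and their true
#' landmark JSON files, with per-item seeds derived from the master seed.
#' Artefact flags are assigned deterministically to match the emulated
#' clinical mix: 40\% of cases get motion blur (1.5 mm) and 40\% heavy
#' noise (double sd); a manifest CSV records ids, seeds, flags and true
#' ostium heights.
#'
#' @param n cohort size (>= 1).
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @param shape,spacing,noiseSd passed to [phantomSpec()].
#' @param writeVolumes write NIfTI volumes (default TRUE); landmark JSON
#'   and the manifest are always written.
#' @return the manifest data.frame (also written to
#'   \code{file.path(dir, "manifest.csv")}), with columns id, seed,
#'   motion, noise_heavy, lco_height, rco_height, volume, landmarks.
#' @export
generateCohort <- function(n, seed, dir, shape = c(160L, 160L, 160L),
                           spacing = 0.7, noiseSd = 20,
                           writeVolumes = TRUE) {
    if (n < 1L) stop("n must be >= 1")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(as.integer(seed))
    itemSeeds <- sample.int(2^30, n)
    nFlag <- floor(0.4 * n)
    motion <- seq_len(n) %in% sample.int(n, nFlag)
    noiseHeavy <- seq_len(n) %in% sample.int(n, nFlag)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        spec <- phantomSpec(itemSeeds[i], shape = shape, spacing = spacing,
                            noiseSd = if (noiseHeavy[i]) 2 * noiseSd
                                      else noiseSd,
                            motionBlurSd = if (motion[i]) 1.5 else 0)
        ph <- generatePhantom(spec)
        id <- sprintf("phantom%03d", i)
        volPath <- file.path(dir, paste0(id, ".nii.gz"))
        lmPath <- file.path(dir, paste0(id, "_landmarks.json"))
        if (writeVolumes)
            writeVolume(ph$volume, volPath, datatype = "int16")
        writeLandmarks(ph$landmarks, lmPath)
        rows[[i]] <- data.frame(
            id = id, seed = itemSeeds[i], motion = motion[i],
            noise_heavy = noiseHeavy[i],
            lco_height = spec@lcoHeight, rco_height = spec@rcoHeight,
            volume = if (writeVolumes) volPath else NA_character_,
            landmarks = lmPath)
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    manifest
}
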