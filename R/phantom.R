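## Synthetic thoracic phantom generator.
##
## Scene model (all positions in physical mm, scaled to the grid extent):
## an air background at -1000 HU, a soft-tissue elliptical-cylinder trunk at
## 40 HU, two lung ellipsoids at -800 HU, a cardiac blood pool ellipsoid
## (45 HU non-contrast, 200 HU with contrast), and a pericardial effusion
## modelled as the shell between the heart surface and an outward-scaled
## copy of it.  The shell scale is solved numerically so the truth-mask
## volume lands on the requested target.  An optional pleural effusion is a
## crescent around the posterior half of one lung, always disjoint from the
## pericardial truth mask.  Finally i.i.d. Gaussian noise is added and the
## volume is rounded to integer HU (CT scanners emit integer HU).

#' Cohort attenuation statistics used by the generator
#'
#' Per-class mean and standard deviation of the per-case median effusion
#' attenuation (HU), pooled and split by contrast administration, as
#' observed in a clinical chest-CT cohort of hemopericardium and simple
#' pericardial effusion cases.  The generator draws each phantom's effusion
#' attenuation from these distributions; the calibration simulation uses
#' the pooled rows.
#'
#' @return A nested list: \code{$hemopericardium} and \code{$simple_pef},
#'   each with \code{$pooled}, \code{$contrast} and \code{$noncontrast}
#'   \code{c(mean=, sd=)} entries (HU).
#' @examples
#' huClassStats()$hemopericardium$pooled
#' @export
huClassStats <- function() {
    list(hemopericardium = list(pooled      = c(mean = 36.10, sd = 9.72),
                                contrast    = c(mean = 36.86, sd = 9.65),
                                noncontrast = c(mean = 33.99, sd = 10.08)),
         simple_pef      = list(pooled      = c(mean = 19.20, sd = 5.52),
                                contrast    = c(mean = 20.97, sd = 6.35),
                                noncontrast = c(mean = 17.59, sd = 4.12)))
}

#' Construct a PhantomSpec
#'
#' @param effusionClass \code{"none"}, \code{"simple_pef"} or
#'   \code{"hemopericardium"}.
#' @param targetVolumeMl target truth-mask volume (mL).  Defaults to 200 mL
#'   for positives and 25 mL (a physiological rim) for class \code{"none"}.
#' @param gridShape,spacing voxel grid; default 128^3 at 2 mm isotropic.
#' @param contrast whether the case is contrast-enhanced (raises the blood
#'   pool to 200 HU and selects the contrast arm of the attenuation
#'   distribution).
#' @param pleuralEffusion add an adjacent pleural effusion confounder.
#' @param noiseSdHu SD of the global Gaussian voxel noise (HU); default 8.
#' @param perCaseMeanHu effusion attenuation; \code{NA} (default) draws it
#'   from the class/arm distribution of \code{\link{huClassStats}}.
#' @param seed integer; fully determines the phantom.
#' @param keepScene also return the painted scene components (for
#'   geometric verification).
#' @return A validated \code{\linkS4class{PhantomSpec}}.
#' @export
phantomSpec <- function(effusionClass = c("simple_pef", "hemopericardium", "none"),
                        targetVolumeMl = NULL,
                        gridShape = c(128L, 128L, 128L),
                        spacing = c(2, 2, 2),
                        contrast = FALSE, pleuralEffusion = FALSE,
                        noiseSdHu = 8, perCaseMeanHu = NA_real_, seed = 1L,
                        keepScene = FALSE) {
    effusionClass <- match.arg(effusionClass)
    if (is.null(targetVolumeMl))
        targetVolumeMl <- if (effusionClass == "none") 25 else 200
    new("PhantomSpec", gridShape = as.integer(gridShape),
        spacing = as.numeric(spacing), effusionClass = effusionClass,
        targetVolumeMl = as.numeric(targetVolumeMl),
        contrast = isTRUE(contrast), pleuralEffusion = isTRUE(pleuralEffusion),
        noiseSdHu = as.numeric(noiseSdHu),
        perCaseMeanHu = as.numeric(perCaseMeanHu), seed = as.integer(seed),
        keepScene = isTRUE(keepScene))
}

## squared normalized ellipsoid radius on the voxel-center grid, as a 3-D
## array built from three 1-D profiles (memory-lean outer sum)
.ellipsoidR2 <- function(xs, ys, zs, center, semi) {
    ax <- ((xs - center[1]) / semi[1])^2
    ay <- ((ys - center[2]) / semi[2])^2
    az <- ((zs - center[3]) / semi[3])^2
    nx <- length(ax); ny <- length(ay); nz <- length(az)
    array(rep(ax, times = ny * nz), dim = c(nx, ny, nz)) +
        rep(rep(ay, each = nx), times = nz) +
        rep(az, each = nx * ny)
}

## run expr with a private RNG stream; global .Random.seed is untouched
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Generate one synthetic thoracic phantom
#'
#' Builds a chest CT phantom and its ground-truth pericardial-effusion mask.
#' The effusion shell scale is solved by bisection so the truth-mask volume
#' is within 5\% of \code{targetVolumeMl} (tighter on fine grids).
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return A list with elements \code{ct} (\code{\linkS4class{CTVolume}},
#'   integer HU), \code{mask} (truth \code{\linkS4class{SegMask}}) and
#'   \code{truth} (one-row data.frame: \code{case_id},
#'   \code{effusion_class}, \code{true_volume_ml} — exactly voxel count
#'   times voxel volume —, \code{per_case_mean_hu}, \code{contrast},
#'   \code{pleural}, \code{seed}).
#' @details The same spec always returns bit-identical output.  If the
#'   requested volume cannot be realized on the grid (the outer shell
#'   surface would leave the trunk), a generation error names the limiting
#'   axis.
#' @examples
#' p <- generatePhantom(phantomSpec("simple_pef", 200, gridShape = c(64, 64, 64),
#'                                  spacing = c(4, 4, 4), seed = 7))
#' p$truth$true_volume_ml
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    .withSeed(spec@seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
    dims <- spec@gridShape; sp <- spec@spacing
    ext <- dims * sp                       # physical extent, mm
    xs <- (seq_len(dims[1]) - 0.5) * sp[1]
    ys <- (seq_len(dims[2]) - 0.5) * sp[2]
    zs <- (seq_len(dims[3]) - 0.5) * sp[3]

    ## effusion attenuation for this case (drawn first: fixed RNG layout)
    huDraw <- rnorm(1)
    meanHu <- spec@perCaseMeanHu
    if (is.na(meanHu)) {
        cls <- if (spec@effusionClass == "none") "simple_pef"
               else spec@effusionClass
        arm <- if (spec@contrast) "contrast" else "noncontrast"
        par <- huClassStats()[[cls]][[arm]]
        meanHu <- par["mean"] + par["sd"] * huDraw
    }
    meanHu <- unname(meanHu)

    ## trunk: elliptical cylinder
    cx <- ext[1] / 2; cy <- ext[2] / 2
    bodyA <- 0.42 * ext[1]; bodyB <- 0.36 * ext[2]
    bodyXY <- outer(((xs - cx) / bodyA)^2, ((ys - cy) / bodyB)^2, "+") <= 1
    zIn <- zs >= 0.02 * ext[3] & zs <= 0.98 * ext[3]
    body <- array(bodyXY, dim = dims) &
        rep(zIn, each = dims[1] * dims[2])

    ## lungs: two ellipsoids spanning the thorax; the crop box derives
    ## from their bounding box, so the heart sits between them
    lungSemi <- c(0.13 * ext[1], 0.25 * ext[2], 0.35 * ext[3])
    lungZ <- 0.55 * ext[3]
    lungCtr1 <- c(cx - 0.21 * ext[1], cy - 0.03 * ext[2], lungZ)
    lungCtr2 <- c(cx + 0.21 * ext[1], cy - 0.03 * ext[2], lungZ)
    lung1 <- .ellipsoidR2(xs, ys, zs, lungCtr1, lungSemi)
    lung2 <- .ellipsoidR2(xs, ys, zs, lungCtr2, lungSemi)
    lungs <- lung1 <= 1 | lung2 <= 1

    ## heart: blood-pool ellipsoid between the lungs
    heartSemi <- c(42, 48, 55)             # mm
    heartCtr <- c(0.48 * ext[1], 0.52 * ext[2], 0.50 * ext[3])
    rHeart2 <- .ellipsoidR2(xs, ys, zs, heartCtr, heartSemi)

    ## effusion shell: 1 < r <= s inside the trunk; solve s for the target
    voxMl <- voxelVolumeMl(sp)
    nTarget <- spec@targetVolumeMl / voxMl
    shellCount <- function(s) sum(rHeart2 > 1 & rHeart2 <= s * s & body)
    sMax <- .maxShellScale(heartCtr, heartSemi, ext, bodyA, bodyB, cx, cy)
    if (nTarget > 0 && shellCount(sMax) < 0.95 * nTarget) {
        lim <- .limitingAxis(heartCtr, heartSemi, ext, bodyA, bodyB, cx, cy)
        stop(sprintf(paste0("target volume %.0f mL is unattainable on this grid: ",
                            "maximum shell volume is %.0f mL (limited along the %s axis)"),
                     spec@targetVolumeMl, shellCount(sMax) * voxMl, lim),
             call. = FALSE)
    }
    if (nTarget > 0) {
        lo <- 1; hi <- sMax
        for (i in seq_len(60)) {
            mid <- (lo + hi) / 2
            if (shellCount(mid) < nTarget) lo <- mid else hi <- mid
        }
        sOut <- hi
        shell <- rHeart2 > 1 & rHeart2 <= sOut * sOut & body
    } else {
        sOut <- 1
        shell <- array(FALSE, dim = dims)
    }

    ## paint the scene
    vol <- array(-1000, dim = dims)
    vol[body] <- 40
    vol[lungs & body] <- -800
    pleural <- array(FALSE, dim = dims)
    if (spec@pleuralEffusion) {
        postHalf <- rep(rep(ys > cy, each = dims[1]), times = dims[3])
        pleural <- lung1 > 1 & lung1 <= 1.3^2 & body & postHalf &
            rHeart2 > sOut * sOut & !shell
        vol[pleural] <- 10
    }
    vol[shell] <- meanHu
    heart <- rHeart2 <= 1
    vol[heart] <- if (spec@contrast) 200 else 45
    lungsPainted <- lungs & body & !shell & !pleural & !heart
    vol <- round(vol + rnorm(length(vol), 0, spec@noiseSdHu))

    ct <- ctVolume(vol, spacing = sp)
    mask <- segMask(array(as.integer(shell), dim = dims), spacing = sp,
                    label = "truth")
    truth <- data.frame(case_id = sprintf("phantom_%s_seed%d",
                                          spec@effusionClass, spec@seed),
                        effusion_class = spec@effusionClass,
                        true_volume_ml = sum(mask@data) * voxMl,
                        per_case_mean_hu = meanHu,
                        contrast = spec@contrast,
                        pleural = spec@pleuralEffusion,
                        seed = spec@seed, stringsAsFactors = FALSE)
    out <- list(ct = ct, mask = mask, truth = truth)
    if (isTRUE(spec@keepScene))
        out$scene <- list(body = body, lungs = lungsPainted,
                          heart = heart, pleural = pleural,
                          shellScale = sOut)
    out
}

## largest shell scale that keeps the outer surface inside trunk and grid,
## assessed along the axis directions from the heart center
.shellScaleLimits <- function(ctr, semi, ext, bodyA, bodyB, cx, cy) {
    ## x/y: stay inside the trunk ellipse cross-section; z: inside the grid
    availX <- bodyA * sqrt(max(0, 1 - ((ctr[2] - cy) / bodyB)^2)) - abs(ctr[1] - cx)
    availY <- bodyB * sqrt(max(0, 1 - ((ctr[1] - cx) / bodyA)^2)) - abs(ctr[2] - cy)
    availZ <- min(ctr[3], ext[3] - ctr[3]) * 0.96
    c(x = availX / semi[1], y = availY / semi[2], z = availZ / semi[3])
}

.maxShellScale <- function(ctr, semi, ext, bodyA, bodyB, cx, cy)
    max(1, min(.shellScaleLimits(ctr, semi, ext, bodyA, bodyB, cx, cy)))

.limitingAxis <- function(ctr, semi, ext, bodyA, bodyB, cx, cy)
    names(which.min(.shellScaleLimits(ctr, semi, ext, bodyA, bodyB, cx, cy)))

#' Draw the per-case parameters of a synthetic cohort
#'
#' Performs all cohort-level randomness (volumes, per-case attenuation,
#' contrast and pleural assignment, per-case seeds) and returns one
#' \code{\linkS4class{PhantomSpec}} per case plus the matching metadata,
#' without generating any image.  \code{\link{generateCohort}} is a thin
#' wrapper that also renders and writes the phantoms.
#'
#' @inheritParams generateCohort
#' @return list(specs = list of \code{\linkS4class{PhantomSpec}},
#'   meta = data.frame with case_id, class, target_volume_ml,
#'   per_case_mean_hu, contrast, pleural, seed).
#' @export
cohortSpecs <- function(nHemo = 39L, nSimple = 61L, nNegative = 0L,
                        baseSeed = 1L, gridShape = c(128L, 128L, 128L),
                        spacing = c(2, 2, 2), noiseSdHu = 8,
                        pleuralProb = 0.25) {
    stopifnot(nHemo >= 0, nSimple >= 0, nNegative >= 0)
    n <- nHemo + nSimple + nNegative
    if (n == 0) stop("empty cohort requested", call. = FALSE)
    classes <- rep(c("hemopericardium", "simple_pef", "none"),
                   times = c(nHemo, nSimple, nNegative))
    ## log-normal matched to mean 198.2 / SD 159.8 mL by moment inversion
    lnSigma <- sqrt(log(1 + (159.78 / 198.20)^2))
    lnMu <- log(198.20) - lnSigma^2 / 2

    draws <- .withSeed(baseSeed, {
        pos <- classes != "none"
        vols <- numeric(n)
        for (i in seq_len(n)) {
            if (pos[i]) {
                v <- rlnorm(1, lnMu, lnSigma)
                while (v < 60 || v > 900) v <- rlnorm(1, lnMu, lnSigma)
                vols[i] <- v
            } else vols[i] <- runif(1, 10, 40)
        }
        contrast <- ifelse(pos, rbinom(n, 1, 0.58), rbinom(n, 1, 0.52)) == 1
        pleural <- rbinom(n, 1, pleuralProb) == 1
        stats <- huClassStats()
        hu <- vapply(seq_len(n), function(i) {
            cls <- if (classes[i] == "none") "simple_pef" else classes[i]
            arm <- if (contrast[i]) "contrast" else "noncontrast"
            p <- stats[[cls]][[arm]]
            rnorm(1, p["mean"], p["sd"])
        }, numeric(1))
        list(vols = vols, contrast = contrast, pleural = pleural, hu = hu)
    })

    specs <- vector("list", n)
    seeds <- integer(n)
    for (i in seq_len(n)) {
        seeds[i] <- as.integer((as.double(baseSeed) + 7919 * i) %%
                                   .Machine$integer.max)
        specs[[i]] <- phantomSpec(classes[i],
                                  targetVolumeMl = draws$vols[i],
                                  gridShape = gridShape, spacing = spacing,
                                  contrast = draws$contrast[i],
                                  pleuralEffusion = draws$pleural[i],
                                  noiseSdHu = noiseSdHu,
                                  perCaseMeanHu = draws$hu[i],
                                  seed = seeds[i])
    }
    meta <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                       class = classes,
                       target_volume_ml = draws$vols,
                       per_case_mean_hu = draws$hu,
                       contrast = draws$contrast, pleural = draws$pleural,
                       seed = seeds, stringsAsFactors = FALSE)
    list(specs = specs, meta = meta)
}

#' Generate a synthetic cohort with ground truth
#'
#' Writes CT/mask NIfTI pairs and a truth manifest CSV.  Default class sizes
#' (39 hemopericardium / 61 simple effusion) mirror the positive test cohort
#' the attenuation statistics come from.  Positive volumes are drawn from a
#' log-normal with mean 198 mL and SD 160 mL truncated to [60, 900] mL;
#' negatives carry a physiological rim drawn uniformly from [10, 40] mL.
#' Contrast is assigned to 58\% of positives and 52\% of negatives; a
#' pleural-effusion confounder to 25\% of cases.
#'
#' @param nHemo,nSimple,nNegative class counts (default 39/61/0).
#' @param baseSeed integer; determines every case.
#' @param outDir output directory (created if needed).
#' @param gridShape,spacing,noiseSdHu forwarded to each
#'   \code{\link{phantomSpec}}.
#' @param pleuralProb probability of the pleural-effusion confounder.
#' @return The manifest data.frame (also written to
#'   \code{outDir/manifest.csv}) with columns \code{case_id}, \code{class},
#'   \code{true_volume_ml}, \code{per_case_mean_hu}, \code{contrast},
#'   \code{pleural}, \code{seed}, \code{ct_path}, \code{mask_path}.
#' @export
generateCohort <- function(nHemo = 39L, nSimple = 61L, nNegative = 0L,
                           baseSeed = 1L, outDir,
                           gridShape = c(128L, 128L, 128L),
                           spacing = c(2, 2, 2), noiseSdHu = 8,
                           pleuralProb = 0.25) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory: %s", outDir),
             call. = FALSE)
    if (file.access(outDir, mode = 2) != 0)
        stop(sprintf("output directory not writable: %s", outDir),
             call. = FALSE)
    cohort <- cohortSpecs(nHemo, nSimple, nNegative, baseSeed = baseSeed,
                          gridShape = gridShape, spacing = spacing,
                          noiseSdHu = noiseSdHu, pleuralProb = pleuralProb)
    n <- nrow(cohort$meta)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        ph <- generatePhantom(cohort$specs[[i]])
        caseId <- cohort$meta$case_id[i]
        ctPath <- file.path(outDir, paste0(caseId, "_ct.nii.gz"))
        maskPath <- file.path(outDir, paste0(caseId, "_mask.nii.gz"))
        saveVolume(ph$ct, ctPath, datatype = "int16")
        saveMask(ph$mask, maskPath)
        rows[[i]] <- data.frame(case_id = caseId,
                                class = cohort$meta$class[i],
                                true_volume_ml = ph$truth$true_volume_ml,
                                per_case_mean_hu = cohort$meta$per_case_mean_hu[i],
                                contrast = cohort$meta$contrast[i],
                                pleural = cohort$meta$pleural[i],
                                seed = cohort$meta$seed[i],
                                ct_path = ctPath, mask_path = maskPath,
                                stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
    manifest
}
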