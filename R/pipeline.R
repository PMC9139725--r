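## Orchestration: simulate -> quantify -> calibrate -> evaluate.  The run
## configuration is a flat serializable list embedded in every artifact so
## each number in a bundle is reproducible from config + seed alone.

#' Build a run configuration
#'
#' Precedence when used through the command-line wrapper is CLI flags over
#' config file over these defaults.
#'
#' @param outDir output directory for the report bundle.
#' @param simulate list(nHemo, nSimple, nNegative) to generate a synthetic
#'   cohort, or \code{NULL} to analyse existing data via
#'   \code{inputManifest}.
#' @param inputManifest CSV with \code{case_id}, \code{ct_path},
#'   \code{mask_path} (and optionally \code{class},
#'   \code{true_volume_ml}, \code{contrast}, \code{pleural}) when not
#'   simulating.
#' @param thresholds decision thresholds, see \code{\link{pefThresholds}}.
#' @param crop whether to run the chest crop before quantification.
#' @param cropMarginMm margin around the lung bounding box, mm.
#' @param seed master seed; drives the cohort simulation.
#' @param gridShape,spacing,noiseSdHu phantom geometry for simulation.
#' @return A validated config list of class \code{"RunConfig"}.
#' @export
runConfig <- function(outDir,
                      simulate = list(nHemo = 39L, nSimple = 61L,
                                      nNegative = 0L),
                      inputManifest = NULL,
                      thresholds = pefThresholds(),
                      crop = TRUE, cropMarginMm = 20, seed = 1L,
                      gridShape = c(128L, 128L, 128L), spacing = c(2, 2, 2),
                      noiseSdHu = 8) {
    if (is.null(simulate) && is.null(inputManifest))
        stop("either simulation counts or an input manifest are required",
             call. = FALSE)
    cfg <- list(outDir = outDir, simulate = simulate,
                inputManifest = inputManifest, thresholds = thresholds,
                crop = isTRUE(crop), cropMarginMm = cropMarginMm,
                seed = as.integer(seed), gridShape = as.integer(gridShape),
                spacing = as.numeric(spacing), noiseSdHu = noiseSdHu)
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, quantifies and classifies each case,
#' writes per-case JSON reports and the cohort CSV, calibrates the HU
#' threshold on the positive cohort (ROC, AUC, Youden and closest-top-left
#' operating points), computes detection/classification accuracy against
#' the truth, and assembles the alert list.  Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return Invisibly, a summary list: \code{manifest}, \code{cohort}
#'   (per-case report data.frame), \code{roc}, \code{evaluation},
#'   \code{alerts}, \code{failures} (per-case error messages), and
#'   \code{ok} (TRUE when no case failed).
#' @details A failing case is logged to stderr with its case id and
#'   skipped; the summary then has \code{ok = FALSE}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    outDir <- config$outDir
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory: %s", outDir),
             call. = FALSE)

    if (!is.null(config$simulate)) {
        s <- config$simulate
        manifest <- generateCohort(nHemo = s$nHemo, nSimple = s$nSimple,
                                   nNegative = s$nNegative,
                                   baseSeed = config$seed,
                                   outDir = file.path(outDir, "cases"),
                                   gridShape = config$gridShape,
                                   spacing = config$spacing,
                                   noiseSdHu = config$noiseSdHu)
    } else {
        if (!file.exists(config$inputManifest))
            stop(sprintf("input manifest not found: %s",
                         config$inputManifest), call. = FALSE)
        manifest <- tryCatch(read.csv(config$inputManifest,
                                      stringsAsFactors = FALSE),
                             error = function(e) data.frame())
        need <- c("case_id", "ct_path", "mask_path")
        if (nrow(manifest) == 0 || !all(need %in% names(manifest)))
            stop("input manifest must have rows and columns case_id, ct_path, mask_path",
                 call. = FALSE)
    }

    reportDir <- file.path(outDir, "reports")
    dir.create(reportDir, showWarnings = FALSE)
    reports <- vector("list", nrow(manifest))
    failures <- character()
    for (i in seq_len(nrow(manifest))) {
        cid <- manifest$case_id[i]
        reports[[i]] <- tryCatch({
            ct <- loadVolume(manifest$ct_path[i])
            mask <- loadMask(manifest$mask_path[i], ct, label = "reference")
            box <- NULL
            if (config$crop) {
                cr <- cropToChest(ct, list(mask),
                                  marginMm = config$cropMarginMm)
                ct <- cr$ct; mask <- cr$masks[[1]]; box <- cr$box
            }
            rep <- classifyCase(ct, mask, thresholds = config$thresholds,
                                caseId = cid)
            payload <- c(as.list(as.data.frame(rep)),
                         list(crop_box = if (is.null(box)) NULL
                              else cropBoxAsList(box),
                              config = unclass(config)[
                                  c("thresholds", "crop", "cropMarginMm",
                                    "seed", "spacing", "noiseSdHu")]))
            jsonlite::write_json(payload,
                                 file.path(reportDir, paste0(cid, ".json")),
                                 auto_unbox = TRUE, digits = NA,
                                 null = "null", pretty = TRUE)
            as.data.frame(rep)
        }, error = function(e) {
            message(sprintf("[%s] FAILED: %s", cid, conditionMessage(e)))
            failures[[cid]] <<- conditionMessage(e)
            NULL
        })
    }
    cohort <- do.call(rbind, reports)
    if (is.null(cohort) || nrow(cohort) == 0)
        stop("no case could be processed", call. = FALSE)
    write.csv(cohort, file.path(outDir, "cohort.csv"), row.names = FALSE)

    ## calibration on the positive cohort (hemopericardium vs simple)
    rocOut <- NULL
    if ("class" %in% names(manifest)) {
        m <- manifest[manifest$case_id %in% cohort$case_id, ]
        posCohort <- m$class %in% c("hemopericardium", "simple_pef")
        scores <- cohort$median_hu[match(m$case_id[posCohort],
                                         cohort$case_id)]
        labs <- m$class[posCohort] == "hemopericardium"
        keep <- !is.na(scores)
        if (sum(labs[keep]) > 0 && sum(!labs[keep]) > 0) {
            r <- rocCurve(scores[keep], labs[keep])
            atCut <- list(
                cutoff = config$thresholds$hu,
                sensitivity = 100 * mean(scores[keep][labs[keep]] >
                                             config$thresholds$hu),
                specificity = 100 * mean(scores[keep][!labs[keep]] <=
                                             config$thresholds$hu))
            rocOut <- list(auc = r@auc,
                           youden_threshold = youdenThreshold(r),
                           topleft_threshold = topLeftThreshold(r),
                           n_pos = r@nPos, n_neg = r@nNeg,
                           at_configured_cutoff = atCut)
            jsonlite::write_json(c(rocOut,
                                   list(curve = rocTable(r),
                                        config = unclass(config)[
                                            c("thresholds", "seed")])),
                                 file.path(outDir, "roc.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
        }
    }

    ## detection + classification accuracy against the truth
    evalOut <- NULL
    if (all(c("class", "true_volume_ml") %in% names(manifest))) {
        m <- manifest[match(cohort$case_id, manifest$case_id), ]
        detTruth <- m$true_volume_ml > 50
        det <- accuracyStats(cohort$pef_present, detTruth)
        hemoTruth <- m$class == "hemopericardium"
        hemo <- accuracyStats(cohort$hemopericardium, hemoTruth)
        fmt <- function(a) list(
            tp = a$tp, fp = a$fp, tn = a$tn, fn = a$fn,
            sensitivity_pct = a$sensitivity$pct,
            sensitivity_ci = if (a$sensitivity$defined)
                c(a$sensitivity$ci@lower, a$sensitivity$ci@upper),
            specificity_pct = a$specificity$pct,
            specificity_ci = if (a$specificity$defined)
                c(a$specificity$ci@lower, a$specificity$ci@upper))
        evalOut <- list(detection = fmt(det),
                        hemopericardium = fmt(hemo))
        jsonlite::write_json(c(evalOut, list(config = unclass(config)[
            c("thresholds", "seed")])),
            file.path(outDir, "evaluation.json"),
            auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    }

    alerts <- cohort[cohort$alert, , drop = FALSE]
    write.csv(alerts, file.path(outDir, "alerts.csv"), row.names = FALSE)

    out <- list(manifest = manifest, cohort = cohort, roc = rocOut,
                evaluation = evalOut, alerts = alerts,
                failures = failures, ok = length(failures) == 0)
    invisible(out)
}
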