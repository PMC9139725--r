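test_that("identical specs generate bit-identical phantoms", {
    a <- testPhantom("simple_pef", 200, seed = 7)
    b <- testPhantom("simple_pef", 200, seed = 7)
    expect_identical(imgData(a$ct), imgData(b$ct))
    expect_identical(imgData(a$mask), imgData(b$mask))
    expect_identical(a$truth, b$truth)

    # and identical bytes on disk
    d <- withr::local_tempdir()
    f1 <- file.path(d, "a.nii"); f2 <- file.path(d, "b.nii")
    saveVolume(a$ct, f1, datatype = "int16")
    saveVolume(b$ct, f2, datatype = "int16")
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
})

test_that("negatives carry a physiological rim below the detection cutoff", {
    for (seed in 1:3) {
        p <- testPhantom("none", seed = seed)
        expect_lt(p$truth$true_volume_ml, 50)
        expect_gt(p$truth$true_volume_ml, 0)
    }
})

test_that("truth volume equals voxel count times voxel volume and hits the target", {
    for (target in c(60, 200, 450, 900)) {
        p <- testPhantom("simple_pef", target, seed = 11)
        expect_identical(p$truth$true_volume_ml,
                         sum(imgData(p$mask)) * voxelVolumeMl(testSpacing))
        expect_lt(abs(p$truth$true_volume_ml - target) / target, 0.05)
    }
})

test_that("filtered median attenuation tracks the per-case mean", {
    # symmetric voxel noise about the per-case mean cancels in the median
    p <- generatePhantom(phantomSpec("hemopericardium", 300,
                                     gridShape = testGrid,
                                     spacing = testSpacing,
                                     noiseSdHu = 8, seed = 3))
    hu <- extractFilteredHu(p$ct, p$mask)
    expect_lt(abs(medianHu(hu) - p$truth$per_case_mean_hu), 2)
})

test_that("an unattainable target volume raises an error naming the limit", {
    expect_error(testPhantom("simple_pef", 5000, seed = 1),
                 "unattainable.*axis")
})

test_that("the truth mask never intersects the pleural effusion", {
    p <- generatePhantom(phantomSpec("simple_pef", 250,
                                     gridShape = testGrid,
                                     spacing = testSpacing,
                                     pleuralEffusion = TRUE,
                                     seed = 5, keepScene = TRUE))
    expect_gt(sum(p$scene$pleural), 0)
    expect_identical(sum(p$scene$pleural & imgData(p$mask) == 1L), 0L)
})

test_that("cohort manifest has the requested composition and ground truth", {
    d <- withr::local_tempdir()
    man <- generateCohort(0, 0, 5, baseSeed = 3, outDir = d,
                          gridShape = testGrid, spacing = testSpacing)
    expect_identical(nrow(man), 5L)
    expect_true(all(man$true_volume_ml < 50))
    expect_true(all(file.exists(man$ct_path)))
    expect_true(all(file.exists(man$mask_path)))

    specs <- cohortSpecs(39, 61, 0, baseSeed = 1)
    expect_identical(nrow(specs$meta), 100L)
    expect_identical(sum(specs$meta$class == "hemopericardium"), 39L)

    # per-case attenuation means follow the cohort statistics (~2 SE band)
    hemoHu <- specs$meta$per_case_mean_hu[specs$meta$class == "hemopericardium"]
    expect_lt(abs(mean(hemoHu) - 36.10), 3.2)

    # positive volumes respect the truncation bounds
    vols <- specs$meta$target_volume_ml[specs$meta$class != "none"]
    expect_true(all(vols >= 60 & vols <= 900))
})

test_that("generated classes separate on the filtered median statistic", {
    # one-sided test on per-case generator means at cohort size 39/61;
    # image-level medians track these means (checked above)
    specs <- cohortSpecs(39, 61, 0, baseSeed = 11)
    hemo <- specs$meta$per_case_mean_hu[specs$meta$class == "hemopericardium"]
    simple <- specs$meta$per_case_mean_hu[specs$meta$class == "simple_pef"]
    p <- t.test(hemo, simple, alternative = "greater")$p.value
    expect_lt(p, 0.01)
})

test_that("unwritable output locations fail cleanly", {
    expect_error(generateCohort(0, 0, 1, outDir = "/proc/nope"), "director")
})
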