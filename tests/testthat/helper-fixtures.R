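# Shared fixtures.  Test phantoms run at 64^3 / 4 mm (same 256 mm physical
# extent as the package default grid) so each case builds in well under a
# second; attenuation statistics are grid-independent.

testGrid <- c(64L, 64L, 64L)
testSpacing <- c(4, 4, 4)

testPhantom <- function(class = "simple_pef", targetMl = NULL, seed = 1L,
                        ...) {
    generatePhantom(phantomSpec(class, targetMl, gridShape = testGrid,
                                spacing = testSpacing, seed = seed, ...))
}

# a tiny in-memory CT/mask pair on a uniform background
tinyCt <- function(value = 40, dims = c(8L, 8L, 8L), spacing = c(1, 1, 1)) {
    ctVolume(array(value, dims), spacing = spacing)
}

tinyMask <- function(on, dims = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                     label = "reference") {
    m <- array(0L, dims)
    m[on] <- 1L
    segMask(m, spacing = spacing, label = label)
}

# CT whose mask voxels carry exactly the given HU values
ctWithValues <- function(values, spacing = c(1, 1, 1)) {
    n <- length(values)
    side <- ceiling(n^(1 / 3)) + 1L
    dims <- rep(max(4L, side), 3L)
    a <- array(0, dims)
    m <- array(0L, dims)
    a[seq_len(n)] <- values
    m[seq_len(n)] <- 1L
    list(ct = ctVolume(a, spacing),
         mask = segMask(m, spacing, label = "reference"))
}
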