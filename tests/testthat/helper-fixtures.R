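# Shared fixtures, built once per test run.

# the default phantom is reused across files; generating it is ~1 s
default_phantom <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- make_phantom(phantom_spec())
        cache
    }
})

small_phantom <- function(n_lesions = 4, seed = 7)
    make_phantom(phantom_spec(shape = c(32, 32, 48), n_lesions = n_lesions,
                              curvature_amplitude = 3,
                              curvature_period = 120, seed = seed))

axial_affine <- function(spacing = c(0.6, 0.6, 3.3), origin = c(0, 0, 0)) {
    A <- diag(c(spacing, 1))
    A[1:3, 4] <- origin
    A
}

mask_from <- function(a, affine = axial_affine(rep(1, 3)))
    binary_mask(a, affine)

# put a solid box into an array (1-based inclusive ranges)
add_box <- function(a, xs, ys, zs) {
    a[xs, ys, zs] <- 1
    a
}

# Toy chunk triplet for the stacked-vs-averaged recall comparison:
# chunk 1 holds two ground-truth lesions of which the prediction finds one,
# chunks 2 and 3 hold one detected lesion each. Chunk 2 has a smaller
# in-plane footprint so stacking must pad it.
fig4_chunks <- function() {
    sp <- c(0.6, 0.6, 3.3)
    g1 <- add_box(array(0, c(16, 16, 8)), 4:6, 4:6, 2:3)   # lesion A
    g1 <- add_box(g1, 11:13, 11:13, 5:6)                   # lesion B
    p1 <- add_box(array(0, c(16, 16, 8)), 4:6, 4:6, 2:3)   # finds A only
    g2 <- add_box(array(0, c(12, 12, 8)), 5:7, 5:7, 3:5)   # lesion C
    p2 <- add_box(array(0, c(12, 12, 8)), 5:7, 5:6, 3:5)   # 2/3 of C
    g3 <- add_box(array(0, c(16, 16, 8)), 8:10, 8:10, 4:5) # lesion D
    p3 <- g3                                               # finds D exactly
    z <- function(i) axial_affine(sp, c(0, 0, -8 * 3.3 * (i - 1)))
    list(gt = list(binary_mask(g1, z(1)), binary_mask(g2, z(2)),
                   binary_mask(g3, z(3))),
         pred = list(binary_mask(p1, z(1)), binary_mask(p2, z(2)),
                     binary_mask(p3, z(3))))
}
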