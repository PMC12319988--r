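straight_tube <- function(d = c(20, 20, 12), r = 4) {
    a <- array(0, d)
    ix <- matrix(0:(d[1] - 1), d[1], d[2])
    iy <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
    disk <- ((ix - (d[1] - 1) / 2)^2 + (iy - (d[2] - 1) / 2)^2 <= r^2) + 0
    for (k in seq_len(d[3])) a[, , k] <- disk
    binary_mask(a, axial_affine(c(1, 1, 3)))
}

test_that("a straight tube yields a vertical centerline and identity warp", {
    tube <- straight_tube()
    cl <- extract_centerline(tube)
    expect_equal(nrow(cl), 12)
    # all points on the tube axis
    expect_equal(max(abs(sweep(cl[, 1:2], 2, cl[1, 1:2]))), 0,
                 tolerance = 1e-9)
    tr <- build_transform(cl, tube)
    expect_equal(max(abs(tr$forward_mm)), 0, tolerance = 1e-9)
    out <- apply_transform(tube, tr, "forward", "linear")
    expect_identical(out$data, tube$data)
})

test_that("centerline covers exactly the slices holding cord", {
    tube <- straight_tube()
    part <- tube$data
    part[, , c(1:3, 10:12)] <- 0       # cord on slices 4-9 only
    cl <- extract_centerline(binary_mask(part, tube$affine))
    expect_equal(nrow(cl), 6)
    expect_equal(attr(cl, "slices"), 3:8)
    empty <- binary_mask(array(0, dim(tube$data)), tube$affine)
    expect_error(extract_centerline(empty), "empty cord")
})

test_that("phantom centerline is recovered within half an in-plane voxel", {
    p <- default_phantom()
    cl <- extract_centerline(p$cord)
    rms <- sqrt(mean(rowSums((cl[, 1:2] - p$centerline[, 1:2])^2)))
    expect_lt(rms, p$image$spacing[1] / 2)
})

test_that("displacements equal centerline minus reference axis, inverse negates", {
    p <- small_phantom()
    cl <- extract_centerline(p$cord)
    tr <- build_transform(cl, p$cord)
    vox <- spineval:::world_to_voxel(cl, p$cord$affine)
    expect_equal(tr$forward_vox,
                 sweep(vox[, 1:2], 2, colMeans(vox[, 1:2])),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(tr$forward_mm + tr$inverse_mm,
                 matrix(0, nrow(tr$forward_mm), 2))
    expect_error(build_transform(cl[1, , drop = FALSE], p$cord),
                 "degenerate")
})

test_that("straightening recenters the cord onto the reference axis", {
    p <- default_phantom()
    tr <- build_transform(extract_centerline(p$cord), p$cord)
    # partial-volume-weighted centroids of the straightened (soft) cord;
    # binarization quantizes slice shifts to the grid, so soft centroids
    # measure the transform itself
    soft <- apply_transform(anat_volume(p$cord$data, p$cord$affine),
                            tr, "forward", "linear")
    ref <- as.vector(tr$reference_axis)[1:2]
    d <- dim(soft$data)
    devs <- vapply(seq_len(d[3]), function(k) {
        sl <- soft$data[, , k]
        w <- which(sl > 0, arr.ind = TRUE) - 1L
        ww <- sl[sl > 0]
        ctr <- c(sum(w[, 1] * ww), sum(w[, 2] * ww)) / sum(ww)
        max(abs(spineval:::voxel_to_world(c(ctr, k - 1L),
                                          soft$affine)[1:2] - ref))
    }, 0.0)
    expect_lt(max(devs), p$image$spacing[1] / 2)
    # binarized masks deviate by at most the half-voxel quantization bound
    hard <- apply_transform(p$cord, tr, "forward", "linear")
    cl2 <- extract_centerline(hard, smooth_window = 1)
    expect_lt(max(abs(sweep(cl2[, 1:2], 2, ref))),
              p$image$spacing[1] / 2 + 0.05)
})

test_that("straightening conserves per-slice cord area within tolerance", {
    p <- default_phantom()
    tr <- build_transform(extract_centerline(p$cord), p$cord)
    st <- apply_transform(p$cord, tr, "forward", "linear")
    a0 <- apply(p$cord$data, 3, sum)
    a1 <- apply(st$data, 3, sum)
    expect_lt(max(abs(a1 - a0) / a0), 0.05)
})

test_that("forward-then-inverse is lossless for nearest interpolation", {
    p <- default_phantom()
    tr <- build_transform(extract_centerline(p$cord), p$cord)
    fw <- apply_transform(p$lesions, tr, "forward", "nearest")
    bk <- apply_transform(fw, tr, "inverse", "nearest")
    # nearest round trip can only lose voxels leaving the field of view
    expect_gte(voxel_dice(bk, p$lesions), 0.97)
})

test_that("lesion masks survive the linear 0.5-threshold round trip", {
    p <- default_phantom()
    tr <- build_transform(extract_centerline(p$cord), p$cord)
    fw <- apply_transform(p$lesions, tr, "forward", "linear")
    bk <- apply_transform(fw, tr, "inverse", "linear")
    cc <- label_lesions(p$lesions)
    # lesion count conserved for lesions >= 8 voxels
    big <- cc$table$id[cc$table$voxels >= 8]
    cc_bk <- label_lesions(bk)
    expect_gte(nrow(cc_bk$table), length(big))
    for (id in cc$table$id[cc$table$volume_mm3 >= 10]) {
        g <- binary_mask((cc$labels == id) + 0, p$lesions$affine)
        pr <- binary_mask(bk$data * (cc$labels == id), p$lesions$affine)
        expect_gte(voxel_dice(g, pr), 0.9)
    }
})

test_that("transforms reject mismatched geometry and serialize to JSON", {
    p <- small_phantom()
    tr <- build_transform(extract_centerline(p$cord), p$cord)
    other <- binary_mask(array(0, c(8, 8, 8)), diag(4))
    expect_error(apply_transform(other, tr), "geometry mismatch")
    f <- withr::local_tempfile(fileext = ".json")
    write_transform(tr, f)
    tr2 <- read_transform(f)
    expect_equal(tr2$forward_mm, tr$forward_mm, ignore_attr = TRUE)
    expect_equal(tr2$geometry$affine, tr$geometry$affine,
                 ignore_attr = TRUE)
    fw1 <- apply_transform(p$lesions, tr, "forward", "linear")
    fw2 <- apply_transform(p$lesions, tr2, "forward", "linear")
    expect_identical(fw1$data, fw2$data)
})

test_that("cropping to the straightened cord reduces the in-plane field", {
    p <- small_phantom()
    tr <- build_transform(extract_centerline(p$cord), p$cord)
    st_img <- apply_transform(p$image, tr, "forward", "linear")
    st_cord <- apply_transform(p$cord, tr, "forward", "linear")
    cr <- crop_to_cord(st_img, st_cord, margin_mm = 2)
    expect_true(all(dim(cr$data)[1:2] < dim(st_img$data)[1:2]))
    expect_identical(dim(cr$data)[3], dim(st_img$data)[3])
    # world positions preserved: re-read a voxel through both affines
    w <- spineval:::voxel_to_world(c(0, 0, 0), cr$affine)
    idx <- round(spineval:::world_to_voxel(w, st_img$affine))
    expect_equal(cr$data[1, 1, 1],
                 st_img$data[idx[1] + 1, idx[2] + 1, idx[3] + 1])
})
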