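#' Ordered set of acquisition chunks sharing one world frame
#'
#' Container for the per-region stacks of a chunked whole-spine
#' acquisition, ordered cranio-caudally (cervical, thoracic, lumbar).
#' Ordering is validated against the world superior-inferior coordinate of
#' each chunk's centroid.
#'
#' @param images List of >= 2 [anat_volume()] chunks.
#' @param cord,lesion Optional parallel lists of [binary_mask()].
#' @param manifest Optional data frame of provenance (source paths, order).
#' @return Object of class `chunk_set`.
#' @export
chunk_set <- function(images, cord = NULL, lesion = NULL, manifest = NULL) {
    stopifnot(is.list(images), length(images) >= 2L,
              all(vapply(images, inherits, TRUE, "anat_volume")))
    for (m in list(cord, lesion)) {
        if (!is.null(m)) {
            stopifnot(length(m) == length(images),
                      all(vapply(m, inherits, TRUE, "binary_mask")))
            for (i in seq_along(m))
                stop_if_geometry_differs(m[[i]], images[[i]],
                                         "chunk mask and image")
        }
    }
    si <- vapply(images, function(v) {
        ctr <- voxel_to_world((dim(v$data) - 1) / 2, v$affine)
        ctr[3]   # world z: + is superior
    }, 0.0)
    if (is.unsorted(rev(si)))
        stop("chunks must be ordered cranio-caudally ",
             "(non-increasing superior-inferior centroid)")
    structure(list(images = images, cord = cord, lesion = lesion,
                   manifest = manifest),
              class = "chunk_set")
}

#' @export
print.chunk_set <- function(x, ...) {
    cat(sprintf("<chunk_set> %d chunks (%s), masks: %s\n",
                length(x$images),
                paste(vapply(x$images,
                             function(v) paste(dim(v$data), collapse = "x"),
                             ""), collapse = "; "),
                paste(c("cord", "lesion")[!vapply(list(x$cord, x$lesion),
                                                  is.null, TRUE)],
                      collapse = "+")))
    invisible(x)
}

#' Plan a stitched whole-spine grid for a chunk set
#'
#' Computes the common target grid the chunks will be merged on: candidate
#' rotations are the direction-cosine matrices of the chunks' own affines;
#' the rotation minimizing the axis-aligned bounding volume of all corner
#' points is selected; the target spacing is the per-axis minimum over
#' chunks; the grid covers every corner point. For each chunk an occupancy
#' map (where its footprint covers the target voxel centers) and a blending
#' weight (ramping linearly from the chunk interior to 0 at its
#' superior-inferior boundary, renormalized to sum to 1 wherever any chunk
#' is present) are stored.
#'
#' A gap between consecutive chunks larger than `gap_tol_mm` produces a
#' warning (the plan is still returned; gap voxels stay fill-valued), the
#' situation arising from suboptimal scan planning.
#'
#' @param cs [chunk_set()].
#' @param ramp_width Ramp extent in target slices; default is the maximum
#'   number of shared slices between adjacent chunks (full-overlap ramp).
#' @param gap_tol_mm Tolerated world gap between consecutive chunks, mm.
#' @return Object of class `stitch_plan` with fields `target_affine`,
#'   `target_shape`, `occupancy` (list of [binary_mask()]) and `weights`
#'   (list of arrays summing to 1 over covered voxels).
#' @export
plan_stitch <- function(cs, ramp_width = NULL, gap_tol_mm = 10) {
    stopifnot(inherits(cs, "chunk_set"))
    chunks <- cs$images
    corners <- do.call(rbind, lapply(chunks, corner_points))

    cands <- lapply(chunks, function(v) {
        R <- v$affine[1:3, 1:3]
        sweep(R, 2, sqrt(colSums(R^2)), "/")
    })
    vols <- vapply(cands, function(R) {
        q <- corners %*% R
        prod(apply(q, 2, max) - apply(q, 2, min))
    }, 0.0)
    R <- cands[[which.min(vols)]]

    sp <- do.call(pmin, lapply(chunks, function(v) v$spacing))
    q <- corners %*% R
    qmin <- apply(q, 2, min); qmax <- apply(q, 2, max)
    shape <- as.integer(ceiling((qmax - qmin) / sp - 1e-6)) + 1L
    target_affine <- rbind(cbind(R %*% diag(sp), R %*% qmin), c(0, 0, 0, 1))

    ones <- lapply(chunks, function(v)
        binary_mask(array(1, dim(v$data)), v$affine))
    occupancy <- lapply(ones, resample_to_grid, target_affine = target_affine,
                        target_shape = shape, interp = "nearest")

    zocc <- lapply(occupancy, function(o)
        which(apply(o$data, 3, function(sl) any(sl > 0))))
    for (o in zocc) if (length(o) == 0)
        stop("a chunk has no footprint on the target grid")

    # warn on world gaps along the stitch axis (chunk order on the target
    # index axis depends on the grid's direction cosines, so use the
    # symmetric separation of the two occupied slice ranges)
    for (i in seq_len(length(chunks) - 1)) {
        z1 <- range(zocc[[i]]); z2 <- range(zocc[[i + 1]])
        gap <- (max(z1[1], z2[1]) - min(z1[2], z2[2]) - 1) * sp[3]
        if (gap > gap_tol_mm)
            warning(sprintf("gap of %.1f mm between chunks %d and %d; %s",
                            gap, i, i + 1,
                            "gap voxels will keep the fill value"))
    }

    if (is.null(ramp_width)) {
        shared <- vapply(seq_len(length(chunks) - 1), function(i)
            length(intersect(zocc[[i]], zocc[[i + 1]])), 0L)
        ramp_width <- max(1L, max(shared))
    }

    weights <- vector("list", length(chunks))
    for (i in seq_along(chunks)) {
        z0 <- min(zocc[[i]]); z1 <- max(zocc[[i]])
        wz <- rep(0, shape[3])
        zz <- z0:z1
        wz[zz] <- pmin(1, (zz - z0 + 1) / ramp_width,
                       (z1 - zz + 1) / ramp_width)
        weights[[i]] <- occupancy[[i]]$data *
            rep(wz, each = shape[1] * shape[2])
    }
    tot <- Reduce(`+`, weights)
    cover <- tot > 0
    for (i in seq_along(weights))
        weights[[i]][cover] <- weights[[i]][cover] / tot[cover]

    structure(list(target_affine = target_affine, target_shape = shape,
                   occupancy = occupancy, weights = weights,
                   ramp_width = ramp_width, n_chunks = length(chunks)),
              class = "stitch_plan")
}

#' @export
print.stitch_plan <- function(x, ...) {
    cat(sprintf("<stitch_plan> target %s @ %s mm, %d chunks, ramp %d slices\n",
                paste(x$target_shape, collapse = "x"),
                paste(signif(affine_spacing(x$target_affine), 3),
                      collapse = "x"),
                x$n_chunks, x$ramp_width))
    invisible(x)
}

check_plan <- function(cs, plan) {
    stopifnot(inherits(plan, "stitch_plan"))
    if (length(cs) != plan$n_chunks)
        stop("plan was made for ", plan$n_chunks, " chunks, got ", length(cs))
    invisible(TRUE)
}

#' Stitch chunk images into one whole-spine volume
#'
#' Each chunk is resampled (linear) onto the planned grid; overlap voxels
#' are blended by the plan's ramp weights (a weighted average, weights
#' summing to 1), voxels covered by a single chunk copy that chunk's value,
#' and uncovered voxels keep the fill value 0.
#'
#' @param cs [chunk_set()].
#' @param plan [plan_stitch()] output produced from `cs`.
#' @return Stitched [anat_volume()].
#' @export
stitch_image <- function(cs, plan) {
    stopifnot(inherits(cs, "chunk_set"))
    check_plan(cs$images, plan)
    out <- array(0, plan$target_shape)
    for (i in seq_along(cs$images)) {
        r <- resample_to_grid(cs$images[[i]], plan$target_affine,
                              plan$target_shape, "linear")
        out <- out + plan$weights[[i]] * r$data
    }
    anat_volume(out, plan$target_affine)
}

#' Stitch chunk masks into one whole-spine binary mask
#'
#' `"linear_threshold"` (default) blends linearly-resampled masks with the
#' plan weights and thresholds at 0.5, the package-wide binarization rule;
#' `"nearest"` copies, at every voxel, the nearest-resampled value of the
#' chunk holding the largest weight there.
#'
#' @param masks List of per-chunk [binary_mask()] (e.g. `cs$lesion`).
#' @param plan [plan_stitch()] output for the matching chunk set.
#' @param mode `"linear_threshold"` or `"nearest"`.
#' @return Stitched [binary_mask()].
#' @export
stitch_mask <- function(masks, plan, mode = c("linear_threshold", "nearest")) {
    mode <- match.arg(mode)
    stopifnot(all(vapply(masks, inherits, TRUE, "binary_mask")))
    check_plan(masks, plan)
    if (mode == "linear_threshold") {
        acc <- array(0, plan$target_shape)
        for (i in seq_along(masks)) {
            r <- resample_affine_cpp(as.double(masks[[i]]$data),
                                     dim(masks[[i]]$data),
                                     solve(masks[[i]]$affine) %*%
                                         plan$target_affine,
                                     plan$target_shape, TRUE)
            dim(r) <- plan$target_shape
            acc <- acc + plan$weights[[i]] * r
        }
        binary_mask((acc >= 0.5) + 0, plan$target_affine)
    } else {
        out <- array(0, plan$target_shape)
        best <- array(0, plan$target_shape)
        for (i in seq_along(masks)) {
            r <- resample_to_grid(masks[[i]], plan$target_affine,
                                  plan$target_shape, "nearest")
            sel <- plan$weights[[i]] > best
            out[sel] <- r$data[sel]
            best <- pmax(best, plan$weights[[i]])
        }
        binary_mask(out, plan$target_affine)
    }
}
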