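#' Specification of the synthetic whole-spine phantom
#'
#' Defines the geometry and lesion statistics of the synthetic phantom used
#' throughout the package as a stand-in for patient data. Defaults mirror a
#' common axial T2w spine protocol: ~0.6 mm in-plane resolution with 3.3 mm
#' slices (anisotropy ~5.5x), a gently curved cord of ~4 mm radius, and
#' intramedullary lesion volumes drawn log-normally with most mass between
#' 10 and 200 mm^3 so that all detection-rate size bins are populated.
#'
#' @param shape Grid size in voxels (x, y, slices).
#' @param spacing Voxel size in mm per axis.
#' @param curvature_amplitude Peak in-plane deviation of the cord
#'   centerline from the vertical, mm.
#' @param curvature_period Superior-inferior period of the centerline
#'   curve, mm.
#' @param cord_radius Cord tube radius, mm.
#' @param n_lesions Number of lesions to place inside the cord.
#' @param lesion_volume_law Named vector `c(meanlog=, sdlog=)` of the
#'   log-normal lesion-volume law (mm^3). Draws are rejected outside the
#'   law's 1st-99th percentiles and below ~3 voxel volumes.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units; background/cord/lesion means are 100/180/260).
#' @param orientation Orientation code the phantom is generated in.
#' @param seed RNG seed; the phantom is fully deterministic given the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 144),
                         spacing = c(0.6, 0.6, 3.3),
                         curvature_amplitude = 6,
                         curvature_period = 180,
                         cord_radius = 4,
                         n_lesions = 12,
                         lesion_volume_law = c(meanlog = log(45), sdlog = 0.8),
                         noise_sd = 8,
                         orientation = "RPI",
                         seed = 42) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 8L),
              length(spacing) == 3L, all(spacing > 0),
              cord_radius > 0, n_lesions >= 0, noise_sd >= 0,
              curvature_period > 0,
              all(c("meanlog", "sdlog") %in% names(lesion_volume_law)))
    parse_orientation(orientation)
    structure(list(shape = shape, spacing = as.double(spacing),
                   curvature_amplitude = curvature_amplitude,
                   curvature_period = curvature_period,
                   cord_radius = cord_radius,
                   n_lesions = as.integer(n_lesions),
                   lesion_volume_law = lesion_volume_law,
                   noise_sd = noise_sd, orientation = orientation,
                   seed = as.integer(seed)),
              class = "phantom_spec")
}

phantom_affine <- function(spec) {
    # built in RAS with the cord centered in-plane, then reoriented
    s <- spec$spacing
    A <- diag(c(s, 1))
    A[1:3, 4] <- c(-(spec$shape[1] - 1) / 2 * s[1],
                   -(spec$shape[2] - 1) / 2 * s[2], 0)
    A
}

# in-plane centerline position (voxel units) as a function of slice index
centerline_voxel <- function(spec, k) {
    s <- spec$spacing
    zmm <- k * s[3]
    cx <- (spec$shape[1] - 1) / 2 +
        spec$curvature_amplitude / s[1] *
            sin(2 * pi * zmm / spec$curvature_period)
    cy <- (spec$shape[2] - 1) / 2 +
        0.5 * spec$curvature_amplitude / s[2] *
            sin(2 * pi * zmm / spec$curvature_period + 1)
    cbind(cx, cy)
}

#' Generate the synthetic whole-spine phantom
#'
#' Builds a curved tubular "spinal cord" around a smooth sinusoidal
#' centerline, places hyperintense ellipsoidal lesions strictly inside the
#' cord (elongated along the slice axis, as intramedullary lesions are),
#' and adds Gaussian noise. Intensity ordering is
#' lesion > cord > background by construction.
#'
#' @param spec [phantom_spec()].
#' @return Object of class `phantom_truth`: a list with `image`
#'   ([anat_volume()]), `cord` and `lesions` ([binary_mask()]),
#'   `centerline` (one world-mm point per slice) and `lesion_table`
#'   (data frame: `id`, `centroid_[xyz]_mm`, `voxels`, `volume_mm3`).
#' @examples
#' p <- make_phantom(phantom_spec(shape = c(32, 32, 48), n_lesions = 4))
#' p$lesion_table
#' @export
make_phantom <- function(spec = phantom_spec()) {
    stopifnot(inherits(spec, "phantom_spec"))
    with_seed(spec$seed, make_phantom_impl(spec))
}

make_phantom_impl <- function(spec) {
    d <- spec$shape; s <- spec$spacing
    affine <- phantom_affine(spec)
    ks <- 0:(d[3] - 1)
    ctr <- centerline_voxel(spec, ks)

    ix <- matrix(0:(d[1] - 1), d[1], d[2])
    iy <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
    cord <- array(0, d)
    for (k in seq_len(d[3])) {
        r2 <- ((ix - ctr[k, 1]) * s[1])^2 + ((iy - ctr[k, 2]) * s[2])^2
        cord[, , k] <- (r2 <= spec$cord_radius^2) + 0
    }

    lesions <- array(0, d)
    lesion_ids <- array(0L, d)
    vox_vol <- prod(s)
    n <- spec$n_lesions
    if (n > 0) {
        law <- spec$lesion_volume_law
        qlo <- max(stats::qlnorm(0.01, law["meanlog"], law["sdlog"]),
                   3 * vox_vol)
        qhi <- stats::qlnorm(0.99, law["meanlog"], law["sdlog"])
        if (qlo >= qhi)
            stop("lesion volume law incompatible with the voxel size: ",
                 "its 99th percentile is below 3 voxels")
        # draw all lesion shapes first, then lay them out along S-I with a
        # one-slice clearance so components never merge
        vols <- vapply(seq_len(n), function(i) {
            vol <- Inf
            while (vol < qlo || vol > qhi)
                vol <- stats::rlnorm(1, law["meanlog"], law["sdlog"])
            vol
        }, 0.0)
        ratios <- stats::runif(n, 2, 3)              # S-I elongation
        aa <- (3 * vols / (4 * pi * ratios))^(1 / 3) # in-plane semi-axis mm
        czs <- ratios * aa                           # S-I semi-axis mm
        rks <- ceiling(czs / s[3])
        need <- 2L * rks + 2L                        # extent + clearance
        if (sum(need) > d[3])
            stop("cannot place ", n, " lesions in ", d[3],
                 " slices: their S-I extents need ", sum(need))
        slack <- d[3] - sum(need)
        extra <- tabulate(sample.int(n + 1L, slack, replace = TRUE),
                          nbins = n + 1L)
        cursor <- extra[1]
        for (i in seq_len(n)) {
            vol <- vols[i]; a <- aa[i]; cz <- czs[i]
            k0 <- cursor + rks[i]
            cursor <- cursor + need[i] + extra[i + 1L]
            c0 <- centerline_voxel(spec, k0)
            # widest in-plane extent the tilted cord must accommodate:
            # the ellipsoid cross-section shrinks away from its equator
            # while the centerline drifts with slice index
            rk0 <- ceiling(cz / s[3])
            dz <- -rk0:rk0
            ck <- centerline_voxel(spec, pmin(pmax(k0 + dz, 0), d[3] - 1))
            drift <- sqrt(((ck[, 1] - c0[1]) * s[1])^2 +
                              ((ck[, 2] - c0[2]) * s[2])^2)
            sect <- a * sqrt(pmax(0, 1 - (dz * s[3] / cz)^2))
            room <- spec$cord_radius - 0.2 - max(sect + drift)
            if (room < 0)
                stop("lesion ", i, " (volume ", signif(vol, 3),
                     " mm^3, semi-axis ", signif(a, 2),
                     " mm) cannot fit inside a cord of radius ",
                     spec$cord_radius, " mm")
            off_r <- stats::runif(1, 0, room)
            off_th <- stats::runif(1, 0, 2 * pi)
            cxv <- c0[1] + off_r * cos(off_th) / s[1]
            cyv <- c0[2] + off_r * sin(off_th) / s[2]
            # voxelize the ellipsoid in a local box
            ri <- ceiling(a / s[1]) + 1L; rk <- ceiling(cz / s[3]) + 1L
            xs <- max(0, floor(cxv) - ri):min(d[1] - 1, ceiling(cxv) + ri)
            ys <- max(0, floor(cyv) - ri):min(d[2] - 1, ceiling(cyv) + ri)
            zs <- max(0, k0 - rk):min(d[3] - 1, k0 + rk)
            g <- expand.grid(x = xs, y = ys, z = zs)
            e <- (((g$x - cxv) * s[1])^2 + ((g$y - cyv) * s[2])^2) / a^2 +
                ((g$z - k0) * s[3])^2 / cz^2
            inside <- g[e <= 1, , drop = FALSE]
            li <- cbind(inside$x + 1L, inside$y + 1L, inside$z + 1L)
            keep <- cord[li] > 0
            li <- li[keep, , drop = FALSE]
            if (nrow(li) == 0)
                stop("lesion ", i, " voxelized to an empty mask")
            lesions[li] <- 1
            lesion_ids[li] <- i
        }
    }

    img <- array(100, d) + 80 * cord + 80 * lesions
    if (spec$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, spec$noise_sd)

    image <- anat_volume(img, affine)
    cord_m <- binary_mask(cord, affine)
    les_m <- binary_mask(lesions, affine)
    if (spec$orientation != orientation_code(image)) {
        image <- reorient(image, spec$orientation)
        cord_m <- reorient(cord_m, spec$orientation)
        les_m <- reorient(les_m, spec$orientation)
    }

    centerline <- voxel_to_world(cbind(ctr, ks), affine)
    # cranio-caudal order: superior (world +z) first
    centerline <- centerline[order(-centerline[, 3]), , drop = FALSE]
    lesion_table <- phantom_lesion_table(lesion_ids, affine, vox_vol)

    structure(list(image = image, cord = cord_m, lesions = les_m,
                   centerline = centerline, lesion_table = lesion_table,
                   spec = spec),
              class = "phantom_truth")
}

phantom_lesion_table <- function(lesion_ids, affine, vox_vol) {
    ids <- sort(unique(lesion_ids[lesion_ids > 0]))
    rows <- lapply(ids, function(i) {
        w <- which(lesion_ids == i, arr.ind = TRUE) - 1L
        ctr <- voxel_to_world(colMeans(w), affine)
        data.frame(id = i, centroid_x_mm = ctr[1], centroid_y_mm = ctr[2],
                   centroid_z_mm = ctr[3], voxels = nrow(w),
                   volume_mm3 = nrow(w) * vox_vol)
    })
    if (length(rows) == 0)
        return(data.frame(id = integer(), centroid_x_mm = double(),
                          centroid_y_mm = double(), centroid_z_mm = double(),
                          voxels = integer(), volume_mm3 = double()))
    do.call(rbind, rows)
}

#' @export
print.phantom_truth <- function(x, ...) {
    cat(sprintf("<phantom_truth> %s voxels, %d lesions (%.0f-%.0f mm^3)\n",
                paste(dim(x$image$data), collapse = "x"),
                nrow(x$lesion_table),
                if (nrow(x$lesion_table)) min(x$lesion_table$volume_mm3) else NA,
                if (nrow(x$lesion_table)) max(x$lesion_table$volume_mm3) else NA))
    invisible(x)
}

#' Split a phantom into overlapping acquisition chunks
#'
#' Emulates the chunked whole-spine acquisition: the phantom is cut along
#' the superior-inferior axis into `n_chunks` stacks (numbered 1..n in the
#' cranio-caudal direction), with consecutive chunks sharing exactly
#' `overlap_slices` axial slice positions in world space. Each chunk
#' carries its own affine. With `max_rotation_deg > 0` every chunk grid is
#' additionally given a random in-plane rotation (emulating independent
#' scanner planning) and the chunk data are resampled from the phantom onto
#' the rotated grid.
#'
#' @param p [make_phantom()] output.
#' @param n_chunks Number of chunks (>= 2).
#' @param overlap_slices Shared axial slices between consecutive chunks.
#' @param max_rotation_deg Per-chunk in-plane rotation range; 0 disables.
#' @param seed RNG seed for the rotations.
#' @return A [chunk_set()] carrying chunk images plus cord and lesion masks.
#' @export
split_into_chunks <- function(p, n_chunks = 3, overlap_slices = 4,
                              max_rotation_deg = 0, seed = 1) {
    stopifnot(inherits(p, "phantom_truth"), n_chunks >= 2, overlap_slices >= 0)
    nz <- dim(p$image$data)[3]
    cuts <- round(seq(0, nz, length.out = n_chunks + 1))
    lo <- floor(overlap_slices / 2); hi <- overlap_slices - lo
    starts <- pmax(0L, as.integer(cuts[-(n_chunks + 1)]) -
                       c(0L, rep(lo, n_chunks - 1)))
    ends <- pmin(nz - 1L, as.integer(cuts[-1]) - 1L +
                     c(rep(hi, n_chunks - 1), 0L))
    if (any(ends - starts + 1L <= overlap_slices))
        stop("overlap_slices (", overlap_slices,
             ") is larger than a chunk extent")
    thetas <- if (max_rotation_deg > 0)
        with_seed(seed, stats::runif(n_chunks, -max_rotation_deg,
                                     max_rotation_deg)) * pi / 180
    else rep(0, n_chunks)

    take <- function(v, z0, z1, cls = "anat_volume") {
        A <- v$affine
        A[1:3, 4] <- A[1:3, 4] + A[1:3, 3] * z0
        dat <- v$data[, , (z0 + 1):(z1 + 1), drop = FALSE]
        if (cls == "binary_mask") binary_mask(dat, A) else anat_volume(dat, A)
    }
    images <- vector("list", n_chunks)
    cords <- vector("list", n_chunks)
    lesions <- vector("list", n_chunks)
    for (i in seq_len(n_chunks)) {
        z0 <- starts[i]; z1 <- ends[i]
        if (thetas[i] == 0) {
            images[[i]] <- take(p$image, z0, z1)
            cords[[i]] <- take(p$cord, z0, z1, "binary_mask")
            lesions[[i]] <- take(p$lesions, z0, z1, "binary_mask")
        } else {
            A <- rotate_inplane_affine(take(p$image, z0, z1), thetas[i])
            shp <- c(dim(p$image$data)[1:2], z1 - z0 + 1L)
            images[[i]] <- resample_to_grid(p$image, A, shp, "linear")
            cords[[i]] <- resample_to_grid(p$cord, A, shp, "nearest")
            lesions[[i]] <- resample_to_grid(p$lesions, A, shp, "nearest")
        }
    }
    chunk_set(images, cord = cords, lesion = lesions,
              manifest = data.frame(chunk = seq_len(n_chunks),
                                    start_slice = starts, end_slice = ends))
}

# rotate a chunk's grid in-plane about its center, keeping the center fixed
rotate_inplane_affine <- function(v, theta) {
    A <- v$affine
    Rz <- diag(4)
    Rz[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                             -sin(theta), cos(theta)), 2, 2)
    ctr_idx <- c((dim(v$data) - 1) / 2, 1)
    ctr_w <- (A %*% ctr_idx)[1:3]
    A2 <- Rz %*% A
    A2[1:3, 4] <- A2[1:3, 4] + ctr_w - (Rz %*% c(ctr_w, 1))[1:3]
    A2
}

#' Controlled degradation of a mask into a synthetic "prediction"
#'
#' Produces predictions with known error structure for exercising the
#' evaluation protocol: removes `fn_components` whole lesions (false
#' negatives), adds `fp_components` spurious components away from existing
#' lesions (false positives), and flips boundary voxels at a given rate
#' (boundary jitter). Deterministic given `seed`.
#'
#' @param m [binary_mask()] of ground-truth lesions.
#' @param fn_components Whole components to delete (chosen at random).
#' @param fp_components Spurious 3x3x2-voxel components to add.
#' @param boundary_flip_rate Probability that each boundary voxel (inner or
#'   outer, 6-connectivity) is flipped.
#' @param seed RNG seed.
#' @return Degraded [binary_mask()].
#' @export
degrade_prediction <- function(m, fn_components = 0, fp_components = 0,
                               boundary_flip_rate = 0, seed = 1) {
    stopifnot(inherits(m, "binary_mask"))
    with_seed(seed, {
        cc <- label_lesions(m)
        n <- nrow(cc$table)
        if (fn_components > n)
            stop("fn_components (", fn_components,
                 ") exceeds the number of components (", n, ")")
        data <- m$data
        if (fn_components > 0) {
            drop <- sample(cc$table$id, fn_components)
            data[cc$labels %in% drop] <- 0
        }
        if (fp_components > 0)
            data <- add_fp_blobs(data, fp_components)
        if (boundary_flip_rate > 0)
            data <- flip_boundary(data, boundary_flip_rate)
        binary_mask(data, m$affine)
    })
}

add_fp_blobs <- function(data, n_blobs) {
    d <- dim(data)
    placed <- 0L; tries <- 0L
    while (placed < n_blobs) {
        if ((tries <- tries + 1L) > 2000L)
            stop("cannot place ", n_blobs, " false-positive components (",
                 placed, " placed)")
        i <- sample.int(d[1] - 4L, 1L) + 1L
        j <- sample.int(d[2] - 4L, 1L) + 1L
        k <- sample.int(max(1L, d[3] - 3L), 1L) + 1L
        xs <- i:(i + 2L); ys <- j:(j + 2L); zs <- k:min(d[3], k + 1L)
        # keep a 1-voxel clearance so the blob is a separate component
        gx <- max(1L, i - 1L):min(d[1], i + 3L)
        gy <- max(1L, j - 1L):min(d[2], j + 3L)
        gz <- max(1L, k - 1L):min(d[3], k + 2L)
        if (any(data[gx, gy, gz] > 0)) next
        data[xs, ys, zs] <- 1
        placed <- placed + 1L
    }
    data
}

boundary_voxels <- function(data) {
    d <- dim(data)
    pad <- array(0, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- data
    nb <- array(0, d + 2L)
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        ix <- (2:(d[1] + 1)) + sh[1]
        iy <- (2:(d[2] + 1)) + sh[2]
        iz <- (2:(d[3] + 1)) + sh[3]
        nb[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
            nb[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] + pad[ix, iy, iz]
    }
    core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    nbc <- nb[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    inner <- core > 0 & nbc < 6   # mask voxel with a background 6-neighbor
    outer <- core == 0 & nbc > 0  # background voxel touching the mask
    list(inner = inner, outer = outer)
}

flip_boundary <- function(data, rate) {
    b <- boundary_voxels(data)
    cand <- which(b$inner | b$outer)
    flip <- cand[stats::runif(length(cand)) < rate]
    data[flip] <- 1 - data[flip]
    data
}
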