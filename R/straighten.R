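#' Extract the spinal-cord centerline from a cord mask
#'
#' One point per axial slice: the in-plane centroid of the cord mask,
#' mapped to world mm and smoothed along the superior-inferior axis with a
#' moving local-linear fit (an order-1 Savitzky-Golay window; unlike a
#' plain moving average it does not bias the curve inward at the volume
#' ends). Slices without cord are excluded.
#'
#' @param cord [binary_mask()] of the spinal cord.
#' @param smooth_window Odd moving-average window length in slices.
#' @return n x 3 matrix of world-mm points, ordered by slice, with
#'   attribute `slices` (0-based slice indices carrying cord).
#' @export
extract_centerline <- function(cord, smooth_window = 5) {
    stopifnot(inherits(cord, "binary_mask"), smooth_window >= 1)
    d <- dim(cord$data)
    ks <- which(apply(cord$data, 3, sum) > 0)
    if (length(ks) == 0) stop("empty cord mask: no centerline to extract")
    cent <- t(vapply(ks, function(k) {
        w <- which(cord$data[, , k] > 0, arr.ind = TRUE) - 1L
        colMeans(w)
    }, c(0, 0)))
    pts <- voxel_to_world(cbind(cent, ks - 1L), cord$affine)
    if (smooth_window > 1)
        pts <- apply(pts, 2, runline_partial, w = smooth_window)
    structure(pts, slices = ks - 1L)
}

# centered local-linear smoother with shrinking windows at the edges
runline_partial <- function(x, w) {
    h <- floor(w / 2)
    n <- length(x)
    vapply(seq_len(n), function(i) {
        idx <- max(1, i - h):min(n, i + h)
        if (length(idx) < 3) return(mean(x[idx]))
        t <- idx - i
        tm <- mean(t)
        beta <- sum((t - tm) * x[idx]) / sum((t - tm)^2)
        mean(x[idx]) - beta * tm
    }, 0.0)
}

#' Build an invertible straightening transform from a centerline
#'
#' The straightened space shares the native grid; each axial slice is
#' rigidly translated in-plane so the cord centerline lands on the
#' reference axis — the vertical line through the mean in-plane centerline
#' position. The per-slice forward displacement is (centerline point −
#' reference axis); the inverse field is stored explicitly as its
#' negation, so composing forward and inverse is exactly zero by
#' construction. Slices not covered by the centerline reuse the nearest
#' covered slice's displacement.
#'
#' @param centerline Output of [extract_centerline()] (or any n x 3 matrix
#'   of world points with a `slices` attribute).
#' @param geometry The native-space [anat_volume()] (or a list with
#'   `affine` and `shape`) the transform applies to.
#' @return Object of class `straighten_transform` with per-slice in-plane
#'   displacement fields in mm and voxel units.
#' @export
build_transform <- function(centerline, geometry) {
    if (inherits(geometry, "anat_volume"))
        geometry <- list(affine = geometry$affine, shape = dim(geometry$data))
    stopifnot(is.matrix(centerline), ncol(centerline) == 3)
    if (nrow(centerline) < 2)
        stop("degenerate centerline: need at least 2 slices")
    slices <- attr(centerline, "slices")
    if (is.null(slices)) slices <- seq_len(nrow(centerline)) - 1L

    # work in voxel coordinates of the native grid; in-plane = axes 1-2
    vox <- world_to_voxel(centerline, geometry$affine)
    ref_vox <- colMeans(vox[, 1:2, drop = FALSE])
    disp_vox_cl <- sweep(vox[, 1:2, drop = FALSE], 2, ref_vox)

    nz <- geometry$shape[3]
    idx <- vapply(0:(nz - 1), function(k) which.min(abs(slices - k)), 0L)
    disp_vox <- disp_vox_cl[idx, , drop = FALSE]
    inplane <- geometry$affine[1:2, 1:2]
    disp_mm <- t(inplane %*% t(disp_vox))
    ref_world <- voxel_to_world(c(ref_vox, 0), geometry$affine)

    structure(list(forward_mm = disp_mm, inverse_mm = -disp_mm,
                   forward_vox = disp_vox,
                   reference_axis = ref_world,
                   geometry = geometry),
              class = "straighten_transform")
}

#' @export
print.straighten_transform <- function(x, ...) {
    cat(sprintf(paste0("<straighten_transform> %d slices, max in-plane ",
                       "displacement %.1f mm\n"),
                nrow(x$forward_mm),
                max(sqrt(rowSums(x$forward_mm^2)))))
    invisible(x)
}

#' Apply a straightening transform (or its inverse)
#'
#' Translates every axial slice in-plane by the per-slice displacement:
#' `"forward"` maps curved (native) space to straightened space,
#' `"inverse"` restores straightened volumes — typically model predictions
#' — to native space. Binary masks moved with linear interpolation are
#' thresholded at 0.5 and re-binarized, mirroring the pipeline's
#' binarization rule.
#'
#' @param v [anat_volume()] or [binary_mask()] on the transform's grid.
#' @param t [build_transform()] output.
#' @param direction `"forward"` (straighten) or `"inverse"` (unwarp).
#' @param interp `"linear"` or `"nearest"`.
#' @return Same class as `v`.
#' @export
apply_transform <- function(v, t, direction = c("forward", "inverse"),
                            interp = c("linear", "nearest")) {
    stopifnot(inherits(v, "anat_volume"),
              inherits(t, "straighten_transform"))
    direction <- match.arg(direction)
    interp <- match.arg(interp)
    if (!identical(dim(v$data), as.integer(t$geometry$shape)) ||
        max(abs(v$affine - t$geometry$affine)) > 1e-4)
        stop("geometry mismatch: volume does not match the transform's ",
             "source geometry")
    sgn <- if (direction == "forward") 1 else -1
    out <- shift_slices_cpp(as.double(v$data), dim(v$data),
                            sgn * t$forward_vox[, 1],
                            sgn * t$forward_vox[, 2],
                            interp == "linear")
    dim(out) <- dim(v$data)
    if (inherits(v, "binary_mask")) {
        if (interp == "linear") out <- (out >= 0.5) + 0
        binary_mask(out, v$affine)
    } else {
        anat_volume(out, v$affine)
    }
}

#' Crop a straightened volume to the cord's in-plane bounding box
#'
#' Straightening leaves the cord in a narrow vertical column; cropping to
#' its in-plane bounding box (plus a margin) emulates the reduced field of
#' view of a straightened scan. The affine translation is updated so world
#' coordinates are preserved.
#'
#' @param v Volume to crop.
#' @param cord Straightened cord [binary_mask()] defining the bounding box.
#' @param margin_mm In-plane margin, mm.
#' @return Cropped volume of the same class as `v`.
#' @export
crop_to_cord <- function(v, cord, margin_mm = 10) {
    stop_if_geometry_differs(v, cord, "volume and cord")
    w <- which(cord$data > 0, arr.ind = TRUE)
    if (nrow(w) == 0) stop("empty cord mask")
    mv <- ceiling(margin_mm / v$spacing[1:2])
    d <- dim(v$data)
    x0 <- max(1L, min(w[, 1]) - mv[1]); x1 <- min(d[1], max(w[, 1]) + mv[1])
    y0 <- max(1L, min(w[, 2]) - mv[2]); y1 <- min(d[2], max(w[, 2]) + mv[2])
    A <- v$affine
    A[1:3, 4] <- A[1:3, 4] + A[1:3, 1] * (x0 - 1L) + A[1:3, 2] * (y0 - 1L)
    dat <- v$data[x0:x1, y0:y1, , drop = FALSE]
    if (inherits(v, "binary_mask")) binary_mask(dat, A)
    else anat_volume(dat, A)
}

#' Serialize / restore a straightening transform
#'
#' JSON round trip for [build_transform()] output, so predictions computed
#' elsewhere can be unwarped later (see the `unwarp` CLI subcommand).
#'
#' @param t [build_transform()] output.
#' @param path JSON file path.
#' @return `write_transform`: `path`, invisibly; `read_transform`: the
#'   restored `straighten_transform`.
#' @export
write_transform <- function(t, path) {
    stopifnot(inherits(t, "straighten_transform"))
    jsonlite::write_json(
        list(forward_mm = t$forward_mm, forward_vox = t$forward_vox,
             reference_axis = as.vector(t$reference_axis),
             affine = t$geometry$affine, shape = t$geometry$shape),
        path, digits = NA, auto_unbox = FALSE)
    invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    disp_mm <- matrix(unlist(j$forward_mm), ncol = 2)
    structure(list(forward_mm = disp_mm, inverse_mm = -disp_mm,
                   forward_vox = matrix(unlist(j$forward_vox), ncol = 2),
                   reference_axis = matrix(j$reference_axis, 1),
                   geometry = list(affine = matrix(unlist(j$affine), 4, 4),
                                   shape = as.integer(j$shape))),
              class = "straighten_transform")
}
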