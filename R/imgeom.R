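#' Anatomical volume: a 3D scalar grid with a voxel-to-world affine
#'
#' `anat_volume` is the carrier of every image in the package: a 3D array
#' plus a 4x4 affine mapping *0-based* voxel indices to world millimetres
#' (the NIfTI convention: the affine maps integer indices to the mm
#' position of voxel *centers*, in the RAS+ world frame). Per-axis spacing
#' is derived from the affine column norms.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix, invertible, last row `(0,0,0,1)`.
#' @return An object of class `anat_volume` with fields `data`, `affine`,
#'   `spacing` and `orientation_code`.
#' @seealso [binary_mask()], [read_volume()], [orientation_code()]
#' @export
anat_volume <- function(data, affine) {
    if (!is.array(data) || length(dim(data)) != 3L)
        stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
    affine <- validate_affine(affine)
    v <- structure(
        list(data = data, affine = affine,
             spacing = affine_spacing(affine),
             orientation_code = orientation_from_affine(affine)),
        class = "anat_volume")
    v
}

#' Binary mask sharing the anat_volume geometry
#'
#' A [anat_volume()] whose data are strictly 0/1 (spinal cord masks, lesion
#' masks, occupancy maps). Any numeric input is accepted but must contain
#' only the values 0 and 1.
#'
#' @inheritParams anat_volume
#' @return Object of class `c("binary_mask", "anat_volume")`.
#' @export
binary_mask <- function(data, affine) {
    v <- anat_volume(data, affine)
    check_binary(v$data)
    class(v) <- c("binary_mask", "anat_volume")
    v
}

#' Coerce an anatomical volume to a binary mask
#'
#' @param v [anat_volume()] whose data are already 0/1.
#' @return A [binary_mask()] with the same geometry.
#' @export
as_binary_mask <- function(v) {
    stopifnot(inherits(v, "anat_volume"))
    binary_mask(v$data, v$affine)
}

check_binary <- function(data) {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
        stop("mask is not binary; values outside {0,1} present: ",
             paste(utils::head(setdiff(u, c(0, 1)), 3), collapse = ", "))
    invisible(TRUE)
}

validate_affine <- function(affine) {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
        stop("affine must be a 4x4 matrix")
    affine <- matrix(as.double(affine), 4L, 4L)   # drop names/attributes
    if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
        stop("affine last row must be (0, 0, 0, 1)")
    if (abs(det(affine[1:3, 1:3])) < 1e-12)
        stop("affine is singular")
    storage.mode(affine) <- "double"
    affine
}

affine_spacing <- function(affine) {
    unname(sqrt(colSums(affine[1:3, 1:3]^2)))
}

#' @export
print.anat_volume <- function(x, ...) {
    cat(sprintf("<%s> %s voxels, spacing %s mm, orientation %s\n",
                class(x)[1], paste(dim(x$data), collapse = "x"),
                paste(signif(x$spacing, 3), collapse = "x"),
                x$orientation_code))
    invisible(x)
}

#' @export
dim.anat_volume <- function(x) dim(x$data)

same_geometry <- function(a, b, tol = 1e-4) {
    identical(dim(a$data), dim(b$data)) &&
        max(abs(a$affine - b$affine)) <= tol
}

stop_if_geometry_differs <- function(a, b, what = "masks") {
    if (!same_geometry(a, b))
        stop("geometry mismatch: ", what,
             " must share shape and affine (shapes ",
             paste(dim(a$data), collapse = "x"), " vs ",
             paste(dim(b$data), collapse = "x"), ")")
    invisible(TRUE)
}

# world coordinates of 0-based voxel indices (n x 3 matrix or length-3 vector)
voxel_to_world <- function(idx, affine) {
    idx <- rbind(t(matrix(idx, ncol = 3)), 1)
    t((affine %*% idx)[1:3, , drop = FALSE])
}

world_to_voxel <- function(pts, affine) {
    pts <- rbind(t(matrix(pts, ncol = 3)), 1)
    t((solve(affine) %*% pts)[1:3, , drop = FALSE])
}

AXIS_LETTERS <- c("R", "L", "A", "P", "S", "I")

# letter for (world_axis, sign): +x -> R, -x -> L, +y -> A, -y -> P, +z -> S, -z -> I
axis_letter <- function(world_axis, sgn) {
    AXIS_LETTERS[2L * (world_axis - 1L) + ifelse(sgn > 0, 1L, 2L)]
}

letter_axis <- function(letter) {
    i <- match(letter, AXIS_LETTERS)
    if (is.na(i)) stop("invalid orientation letter: ", letter)
    list(world_axis = (i + 1L) %/% 2L, sgn = if (i %% 2L == 1L) 1 else -1)
}

orientation_from_affine <- function(affine) {
    R <- affine[1:3, 1:3]
    dom <- apply(abs(R), 2, which.max)
    if (length(unique(dom)) != 3L)
        stop("affine has no dominant axis decomposition; cannot assign ",
             "an orientation code")
    sgn <- sign(R[cbind(dom, 1:3)])
    paste(mapply(axis_letter, dom, sgn), collapse = "")
}

#' Orientation code of a volume
#'
#' Three letters naming the anatomical direction each voxel axis points
#' toward (e.g. `"RPI"`: the first voxel axis runs toward the subject's
#' Right, the second toward Posterior, the third toward Inferior). Computed
#' from the dominant world axis of each affine column; the world frame is
#' NIfTI RAS+.
#'
#' @param v [anat_volume()].
#' @return Length-1 character, e.g. `"RAS"`.
#' @export
orientation_code <- function(v) {
    stopifnot(inherits(v, "anat_volume"))
    orientation_from_affine(v$affine)
}

parse_orientation <- function(code) {
    if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
        stop("orientation code must be a 3-letter string, got ",
             deparse(code))
    letters3 <- strsplit(toupper(code), "")[[1]]
    ax <- lapply(letters3, letter_axis)
    world <- vapply(ax, `[[`, 1L, "world_axis")
    if (length(unique(world)) != 3L)
        stop("invalid orientation code '", code,
             "': axes must cover R/L, A/P and S/I once each")
    list(world_axis = world, sgn = vapply(ax, `[[`, 1, "sgn"))
}

#' Reorient a volume to a target orientation code
#'
#' Permutes and flips the voxel axes so the volume's orientation code
#' becomes `code`, updating the affine so that the world position of every
#' voxel is unchanged. Typical use is converting scans to `"RPI"` before
#' any further processing.
#'
#' @param v [anat_volume()] or [binary_mask()].
#' @param code Target 3-letter code, a signed permutation of the anatomical
#'   axes (letters from R/L, A/P, S/I).
#' @return Same class as `v`, in the requested orientation.
#' @examples
#' v <- anat_volume(array(1:24, c(2, 3, 4)), diag(4))
#' w <- reorient(v, "LAS")
#' orientation_code(w)
#' @export
reorient <- function(v, code) {
    stopifnot(inherits(v, "anat_volume"))
    target <- parse_orientation(code)
    cur <- parse_orientation(v$orientation_code)
    # source voxel axis supplying each target axis
    perm <- match(target$world_axis, cur$world_axis)
    flip <- cur$sgn[perm] != target$sgn
    if (all(perm == 1:3) && !any(flip)) return(v)

    d <- dim(v$data)
    data <- aperm(v$data, perm)
    affine <- v$affine
    A <- affine[1:3, perm, drop = FALSE]
    t0 <- affine[1:3, 4]
    for (ax in 1:3) {
        if (flip[ax]) {
            n <- d[perm[ax]]
            idx <- switch(ax,
                          list(n:1, TRUE, TRUE),
                          list(TRUE, n:1, TRUE),
                          list(TRUE, TRUE, n:1))
            data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
            t0 <- t0 + A[, ax] * (n - 1)   # new index i' = (n-1) - i
            A[, ax] <- -A[, ax]
        }
    }
    out <- rbind(cbind(A, t0), c(0, 0, 0, 1))
    if (inherits(v, "binary_mask")) binary_mask(data, out)
    else anat_volume(data, out)
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/2 file into an [anat_volume()] (or [binary_mask()] when
#' `mask = TRUE`), taking the affine from the file's xform. Only 3D images
#' are accepted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Logical; validate as a binary mask.
#' @return [anat_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    im <- RNifti::readNifti(path)
    d <- dim(im)
    if (length(d) == 4L && d[4] == 1L) {
        im2 <- array(as.numeric(im), dim = d[1:3])
    } else if (length(d) != 3L) {
        stop("expected a 3D image, got ", length(d), "D: ", path)
    } else {
        im2 <- array(as.numeric(im), dim = d)
    }
    affine <- validate_affine(unclass(RNifti::xform(im)))
    if (mask) binary_mask(im2, affine) else anat_volume(im2, affine)
}

#' Write a volume to NIfTI
#'
#' @param v [anat_volume()] or [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype; masks default to `"uint8"`, images to
#'   `"double"` so round trips are lossless.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path,
                         datatype = if (inherits(v, "binary_mask")) "uint8"
                                    else "double") {
    stopifnot(inherits(v, "anat_volume"))
    im <- RNifti::asNifti(v$data)
    RNifti::sform(im) <- structure(v$affine, code = 2L)
    RNifti::writeNifti(im, path, datatype = datatype)
    invisible(path)
}

#' Z-score intensity normalization
#'
#' Rescales intensities to zero mean and unit standard deviation over the
#' whole volume, the normalization applied to every scan before model
#' ingestion. Geometry is untouched.
#'
#' @param v [anat_volume()].
#' @return Normalized [anat_volume()].
#' @export
zscore_normalize <- function(v) {
    stopifnot(inherits(v, "anat_volume"))
    s <- stats::sd(as.vector(v$data))
    if (!is.finite(s) || s < 1e-12)
        stop("cannot Z-score a constant image (zero intensity variance)")
    anat_volume((v$data - mean(v$data)) / s, v$affine)
}

#' Resample a volume onto a target grid
#'
#' Pull-resampling through the composed affine map: each target voxel
#' center is mapped into the source voxel grid and interpolated. Voxels
#' mapping outside the source field of view are filled with 0. Binary
#' masks resampled with `interp = "linear"` are thresholded at 0.5 and
#' re-binarized; `"nearest"` keeps them binary by construction.
#'
#' @param v [anat_volume()] or [binary_mask()].
#' @param target_affine 4x4 voxel-to-world affine of the target grid.
#' @param target_shape Integer 3-vector.
#' @param interp `"linear"` or `"nearest"`.
#' @return Same class as `v`, on the target grid.
#' @export
resample_to_grid <- function(v, target_affine, target_shape,
                             interp = c("linear", "nearest")) {
    stopifnot(inherits(v, "anat_volume"))
    interp <- match.arg(interp)
    target_affine <- validate_affine(target_affine)
    target_shape <- as.integer(target_shape)
    stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
    M <- solve(v$affine) %*% target_affine
    out <- resample_affine_cpp(as.double(v$data), dim(v$data), M,
                               target_shape, interp == "linear")
    dim(out) <- target_shape
    if (inherits(v, "binary_mask")) {
        if (interp == "linear") out <- (out >= 0.5) + 0
        binary_mask(out, target_affine)
    } else {
        anat_volume(out, target_affine)
    }
}

#' World coordinates of the eight corner voxels
#'
#' The world-mm positions (voxel-center convention) of the extreme voxel
#' indices 0 and `dim - 1` along each axis — the corner points from which
#' a stitching bounding box is planned.
#'
#' @param v [anat_volume()].
#' @return 8x3 matrix of world coordinates in mm.
#' @export
corner_points <- function(v) {
    stopifnot(inherits(v, "anat_volume"))
    d <- dim(v$data) - 1L
    idx <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
    voxel_to_world(idx, v$affine)
}
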