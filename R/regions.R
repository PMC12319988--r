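#' Region-based overlapping labels for joint cord/lesion segmentation
#'
#' Reframes the two-class cord/lesion task as two *overlapping* binary
#' targets forming a hierarchy: the first channel is the union of the
#' spinal cord and lesion masks, the second is the lesion mask. Training
#' against overlapping regions (rather than mutually exclusive classes)
#' gives the larger structure's gradients to the smaller one early on.
#'
#' @param cord,lesion [binary_mask()] pair sharing geometry.
#' @return Object of class `region_labels` with [binary_mask()] fields
#'   `region_union` (cord ∪ lesion) and `region_lesion`.
#' @export
build_region_labels <- function(cord, lesion) {
    stopifnot(inherits(cord, "binary_mask"), inherits(lesion, "binary_mask"))
    stop_if_geometry_differs(cord, lesion, "cord and lesion")
    structure(list(
        region_union = binary_mask(pmax(cord$data, lesion$data), cord$affine),
        region_lesion = lesion), class = "region_labels")
}

#' Per-channel sigmoid probabilities for the two region channels
#'
#' @param p_union,p_lesion Arrays in `[0, 1]` (channel-wise sigmoid
#'   outputs), sharing shape.
#' @param affine Voxel-to-world affine of the grid.
#' @return Object of class `channel_probs`.
#' @export
channel_probs <- function(p_union, p_lesion, affine = diag(4)) {
    stopifnot(identical(dim(p_union), dim(p_lesion)),
              length(dim(p_union)) == 3L)
    rng <- range(p_union, p_lesion)
    if (rng[1] < 0 || rng[2] > 1)
        stop("channel probabilities must lie in [0, 1]")
    structure(list(p_union = p_union, p_lesion = p_lesion,
                   affine = validate_affine(affine)),
              class = "channel_probs")
}

#' Decode region-channel probabilities back to cord and lesion masks
#'
#' Thresholds each channel and restores the hierarchy: lesion voxels are
#' forced into the cord mask (hierarchy enforcement at decode preserves
#' lesion sensitivity rather than letting the cord channel gate lesions
#' away).
#'
#' @param p [channel_probs()].
#' @param threshold Decision threshold, default 0.5.
#' @return List with [binary_mask()] elements `cord` (the union channel,
#'   containing every lesion voxel) and `lesion`.
#' @export
decode_regions <- function(p, threshold = 0.5) {
    stopifnot(inherits(p, "channel_probs"))
    lesion <- (p$p_lesion >= threshold) + 0
    cord <- pmax((p$p_union >= threshold) + 0, lesion)
    list(cord = binary_mask(cord, p$affine),
         lesion = binary_mask(lesion, p$affine))
}

#' Compound Dice + binary cross-entropy segmentation objective
#'
#' The loss each region channel is optimized with: per channel,
#' `(1 - softDice) + BCE`, averaged over the two channels. Soft Dice uses
#' additive smoothing `s`:
#' `softDice = (2*sum(p*y) + s) / (sum(p) + sum(y) + s)`; BCE is the
#' voxel-mean cross-entropy with probabilities clipped to
#' `[eps, 1 - eps]` before the log terms.
#'
#' @param p [channel_probs()].
#' @param y [build_region_labels()] output on the same grid.
#' @param smooth Additive Dice smoothing `s`.
#' @param eps Probability clipping bound.
#' @return Single non-negative number.
#' @export
dice_bce_loss <- function(p, y, smooth = 1e-5, eps = 1e-7) {
    stopifnot(inherits(p, "channel_probs"), inherits(y, "region_labels"))
    if (!identical(dim(p$p_union), dim(y$region_union$data)))
        stop("geometry mismatch between probabilities and labels")
    one <- function(pc, yc) {
        dice <- (2 * sum(pc * yc) + smooth) / (sum(pc) + sum(yc) + smooth)
        pc <- pmin(pmax(pc, eps), 1 - eps)   # clip for the log terms only
        bce <- -mean(yc * log(pc) + (1 - yc) * log(1 - pc))
        (1 - dice) + bce
    }
    (one(p$p_union, y$region_union$data) +
        one(p$p_lesion, y$region_lesion$data)) / 2
}
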