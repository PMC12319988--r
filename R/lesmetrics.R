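#' Stack per-chunk masks along the superior-inferior axis
#'
#' The evaluation-time concatenation used so lesion-wise metrics are
#' computed once per patient instead of once per chunk: each chunk is
#' zero-padded symmetrically in-plane to the largest in-plane shape (the
#' smaller chunk centered; an odd difference puts the extra voxel on the
#' high side), then the chunks are concatenated along the slice axis in
#' cranio-caudal order. Overlapping anatomy is deliberately *not*
#' de-duplicated. The result carries a nominal axis-aligned affine with
#' the first chunk's spacing — stacking is a bookkeeping operation, not a
#' geometric one.
#'
#' @param masks Ordered (cranio-caudal) list of >= 2 [binary_mask()].
#' @return Stacked [binary_mask()].
#' @export
stack_chunks <- function(masks) {
    stopifnot(is.list(masks), length(masks) >= 2L,
              all(vapply(masks, inherits, TRUE, "binary_mask")))
    dirs <- lapply(masks, function(m) {
        R <- m$affine[1:3, 1:3]
        sweep(R[, 1:2, drop = FALSE], 2,
              sqrt(colSums(R[, 1:2, drop = FALSE]^2)), "/")
    })
    for (i in seq_along(dirs)[-1])
        if (max(abs(dirs[[i]] - dirs[[1]])) > 1e-3)
            stop("inconsistent in-plane orientation between chunks 1 and ",
                 i, "; resample the chunks to a shared in-plane grid first")
    shp <- vapply(masks, function(m) dim(m$data)[1:2], c(0L, 0L))
    tgt <- c(max(shp[1, ]), max(shp[2, ]))
    nz <- sum(vapply(masks, function(m) dim(m$data)[3], 0L))
    out <- array(0, c(tgt, nz))
    z <- 0L
    for (m in masks) {
        d <- dim(m$data)
        px <- floor((tgt[1] - d[1]) / 2); py <- floor((tgt[2] - d[2]) / 2)
        out[px + seq_len(d[1]), py + seq_len(d[2]), z + seq_len(d[3])] <-
            m$data
        z <- z + d[3]
    }
    sp <- masks[[1]]$spacing
    binary_mask(out, diag(c(sp, 1)))
}

#' Label lesion connected components
#'
#' 3D connected-component labeling of a binary lesion mask under 6-, 18-
#' or 26-connectivity (default 26), with per-component voxel counts and
#' volumes in mm^3 derived from the affine.
#'
#' @param m [binary_mask()].
#' @param connectivity 6, 18 or 26.
#' @return Object of class `lesion_components`: `labels` (integer array,
#'   ids dense from 1), `table` (data frame `id`, `voxels`, `volume_mm3`),
#'   `connectivity`, `affine`.
#' @export
label_lesions <- function(m, connectivity = 26) {
    stopifnot(inherits(m, "binary_mask"))
    if (!connectivity %in% c(6, 18, 26))
        stop("connectivity must be 6, 18 or 26")
    lab <- label_components_cpp(as.integer(m$data != 0), dim(m$data),
                                as.integer(connectivity))
    dim(lab) <- dim(m$data)
    vox_vol <- abs(det(m$affine[1:3, 1:3]))
    n <- max(lab)
    counts <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer()
    structure(list(labels = lab,
                   table = data.frame(id = seq_len(n), voxels = counts,
                                      volume_mm3 = counts * vox_vol),
                   connectivity = connectivity, affine = m$affine),
              class = "lesion_components")
}

#' @export
print.lesion_components <- function(x, ...) {
    cat(sprintf("<lesion_components> %d components, %d-connectivity\n",
                nrow(x$table), x$connectivity))
    invisible(x)
}

#' Match predicted lesion components to ground truth at an overlap
#' criterion
#'
#' A ground-truth lesion counts as detected (true positive) if predicted
#' voxels cover at least `min_overlap` of its volume (the 10% criterion;
#' the boundary is inclusive and the denominator is the GT lesion volume).
#' Each detected GT lesion is paired with the predicted component
#' overlapping it most (ties: smaller predicted id). A predicted component
#' is a false positive iff it shares no voxel with any detected GT lesion.
#'
#' @param gt,pred [label_lesions()] outputs on the same grid.
#' @param min_overlap Minimum covered fraction of the GT lesion.
#' @return Object of class `lesion_match`: `pairs` (data frame `gt_id`,
#'   `pred_id`, `overlap_fraction`), `unmatched_gt` (FN ids),
#'   `unmatched_pred` (FP ids), `n_gt`, `n_pred`, `min_overlap`.
#' @export
match_lesions <- function(gt, pred, min_overlap = 0.1) {
    stopifnot(inherits(gt, "lesion_components"),
              inherits(pred, "lesion_components"))
    if (!identical(dim(gt$labels), dim(pred$labels)))
        stop("geometry mismatch between GT and predicted components")
    n_gt <- nrow(gt$table); n_pred <- nrow(pred$table)

    both <- gt$labels > 0 & pred$labels > 0
    ov <- if (any(both)) {
        tab <- table(gt = gt$labels[both], pred = pred$labels[both])
        as.data.frame(tab, stringsAsFactors = FALSE)
    } else {
        data.frame(gt = integer(), pred = integer(), Freq = integer())
    }
    ov <- ov[ov$Freq > 0, , drop = FALSE]
    ov$gt <- as.integer(as.character(ov$gt))
    ov$pred <- as.integer(as.character(ov$pred))

    coverage <- rep(0, n_gt)
    if (nrow(ov) > 0) {
        agg <- tapply(ov$Freq, ov$gt, sum)
        coverage[as.integer(names(agg))] <- as.numeric(agg)
    }
    coverage <- coverage / pmax(gt$table$voxels, 1L)
    detected <- which(coverage >= min_overlap)

    pairs <- data.frame(gt_id = integer(), pred_id = integer(),
                        overlap_fraction = double())
    for (g in detected) {
        cand <- ov[ov$gt == g, , drop = FALSE]
        cand <- cand[order(-cand$Freq, cand$pred), , drop = FALSE]
        pairs <- rbind(pairs, data.frame(gt_id = g, pred_id = cand$pred[1],
                                         overlap_fraction = coverage[g]))
    }
    tp_preds <- unique(ov$pred[ov$gt %in% detected])
    structure(list(pairs = pairs,
                   unmatched_gt = setdiff(seq_len(n_gt), detected),
                   unmatched_pred = setdiff(seq_len(n_pred), tp_preds),
                   n_gt = n_gt, n_pred = n_pred, min_overlap = min_overlap),
              class = "lesion_match")
}

#' Lesion-wise detection scores from a match result
#'
#' Recall = TP/(TP+FN), PPV = TP/(TP+FP), F1 = their harmonic mean, and
#' the absolute lesion-count difference |n_ref - n_pred|. Empty-mask
#' conventions: both masks empty gives recall = PPV = F1 = 1 and
#' count_diff = 0 (the model was right to predict nothing); an empty side
#' with a nonempty other gives 0 for the undefined ratios. The
#' `empty_case_flag` marks any case where either mask was empty.
#'
#' @param r [match_lesions()] output.
#' @return List: `recall`, `ppv`, `f1`, `count_diff`, `tp`, `fn`, `fp`,
#'   `empty_case_flag`.
#' @export
lesion_scores <- function(r) {
    stopifnot(inherits(r, "lesion_match"))
    tp <- nrow(r$pairs)
    fn <- length(r$unmatched_gt)
    fp <- length(r$unmatched_pred)
    empty <- r$n_gt == 0 || r$n_pred == 0
    if (r$n_gt == 0 && r$n_pred == 0) {
        recall <- ppv <- f1 <- 1
    } else {
        recall <- if (r$n_gt > 0) tp / (tp + fn) else 0
        ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
        f1 <- if (recall + ppv > 0) 2 * recall * ppv / (recall + ppv) else 0
    }
    list(recall = recall, ppv = ppv, f1 = f1,
         count_diff = abs(r$n_gt - r$n_pred),
         tp = tp, fn = fn, fp = fp, empty_case_flag = empty)
}

#' Voxel-wise Dice coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)`, with the empty-mask convention of the
#' evaluation protocol: both masks empty scores 1 (correctly predicting no
#' lesion is a success), exactly one empty scores 0.
#'
#' @param gt,pred [binary_mask()] pair sharing geometry.
#' @return Number in `[0, 1]`.
#' @export
voxel_dice <- function(gt, pred) {
    stop_if_geometry_differs(gt, pred, "GT and prediction")
    a <- sum(gt$data); b <- sum(pred$data)
    if (a + b == 0) return(1)
    2 * sum(gt$data * pred$data) / (a + b)
}

#' Normalized surface distance
#'
#' The fraction of boundary surface points of the two masks lying within
#' `tolerance_mm` of the other mask's boundary (symmetric):
#' `(|S_gt within tol of S_pred| + |S_pred within tol of S_gt|) /
#' (|S_gt| + |S_pred|)`. Boundary voxels are mask voxels with a background
#' 6-neighbor (the volume edge counts as background); distances are
#' Euclidean in world mm. Both masks empty scores 1, exactly one empty 0.
#'
#' @param gt,pred [binary_mask()] pair sharing geometry.
#' @param tolerance_mm Surface tolerance in mm.
#' @return Number in `[0, 1]`.
#' @export
nsd <- function(gt, pred, tolerance_mm = 1.0) {
    stop_if_geometry_differs(gt, pred, "GT and prediction")
    a <- sum(gt$data); b <- sum(pred$data)
    if (a + b == 0) return(1)
    if (a == 0 || b == 0) return(0)
    sa <- surface_points(gt)
    sb <- surface_points(pred)
    da <- nn_min_dist_cpp(sa, sb)
    db <- nn_min_dist_cpp(sb, sa)
    (sum(da <= tolerance_mm) + sum(db <= tolerance_mm)) /
        (length(da) + length(db))
}

surface_points <- function(m) {
    b <- boundary_voxels(m$data)
    idx <- which(b$inner, arr.ind = TRUE) - 1L
    voxel_to_world(idx, m$affine)
}

#' Relative volume error
#'
#' Signed percentage volume error `100 * (|pred| - |gt|) / |gt|` (0% is
#' perfect; an empty prediction against a nonempty reference gives -100%).
#'
#' @param gt,pred [binary_mask()] pair sharing geometry; `gt` nonempty.
#' @return Signed percentage.
#' @export
rve <- function(gt, pred) {
    stop_if_geometry_differs(gt, pred, "GT and prediction")
    a <- sum(gt$data)
    if (a == 0) stop("RVE is undefined for an empty reference mask")
    100 * (sum(pred$data) - a) / a
}

#' Lesion detection rates by volume bin
#'
#' Assigns each ground-truth lesion to a half-open volume bin —
#' `[0, e1)`, `[e1, e2)`, ..., `[e_last, Inf)` for edges `e` in mm^3 — and
#' reports the detected fraction per bin. Bins containing no GT lesion are
#' absent from the output rather than reported as 0.
#'
#' @param gt [label_lesions()] output for the GT mask.
#' @param r [match_lesions()] output against that GT.
#' @param bin_edges Ascending volume bin edges, mm^3. The published edges
#'   are 10 and 50 mm^3; the default adds 200 mm^3 as the upper category
#'   boundary.
#' @return Data frame: `bin`, `n`, `detected`, `rate`.
#' @export
detection_by_size <- function(gt, r, bin_edges = c(10, 50, 200)) {
    stopifnot(inherits(gt, "lesion_components"), inherits(r, "lesion_match"))
    if (is.unsorted(bin_edges, strictly = TRUE))
        stop("bin_edges must be strictly ascending")
    edges <- c(0, bin_edges, Inf)
    labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
    bin <- cut(gt$table$volume_mm3, edges, labels = labs, right = FALSE)
    det <- gt$table$id %in% r$pairs$gt_id
    out <- do.call(rbind, lapply(split(det, bin), function(d)
        data.frame(n = length(d), detected = sum(d))))
    out <- data.frame(bin = rownames(out), out, row.names = NULL)
    out <- out[out$n > 0, , drop = FALSE]
    out$rate <- out$detected / out$n
    out
}

#' Evaluation configuration
#'
#' Bundles the tunables of [evaluate_scan()]: overlap criterion,
#' component connectivity, surface tolerance and volume bin edges.
#'
#' @param min_overlap TP criterion: minimum predicted coverage of a GT
#'   lesion.
#' @param connectivity Component connectivity (6, 18 or 26).
#' @param nsd_tolerance_mm NSD surface tolerance, mm.
#' @param bin_edges Volume bin edges for detection rates, mm^3.
#' @return List of class `eval_config`.
#' @export
eval_config <- function(min_overlap = 0.1, connectivity = 26,
                        nsd_tolerance_mm = 1.0, bin_edges = c(10, 50, 200)) {
    structure(list(min_overlap = min_overlap, connectivity = connectivity,
                   nsd_tolerance_mm = nsd_tolerance_mm,
                   bin_edges = bin_edges), class = "eval_config")
}

#' Evaluate one scan: cord and lesion masks against ground truth
#'
#' Composes the full per-scan evaluation protocol. Cord metrics
#' (when cord masks are supplied): voxel Dice, NSD and RVE. Lesion
#' metrics: voxel Dice, NSD, lesion-wise recall/PPV/F1 at the overlap
#' criterion, absolute lesion-count difference, and detection rates by
#' lesion-volume bin, with the empty-mask conventions of [voxel_dice()]
#' and [lesion_scores()].
#'
#' @param gt_lesion,pred_lesion Lesion [binary_mask()] pair.
#' @param gt_cord,pred_cord Optional cord [binary_mask()] pair.
#' @param config [eval_config()].
#' @return Object of class `metrics_report`: lists `cord` (`dice`, `nsd`,
#'   `rve`) and `lesion` (`dice`, `nsd`, `recall`, `ppv`, `f1`,
#'   `count_diff`), `by_size` (data frame), `match` ([match_lesions()]
#'   result) and `empty_case_flag`.
#' @export
evaluate_scan <- function(gt_lesion, pred_lesion,
                          gt_cord = NULL, pred_cord = NULL,
                          config = eval_config()) {
    stop_if_geometry_differs(gt_lesion, pred_lesion,
                             "GT and predicted lesion masks")
    cord <- NULL
    if (!is.null(gt_cord) && !is.null(pred_cord)) {
        stop_if_geometry_differs(gt_cord, pred_cord,
                                 "GT and predicted cord masks")
        stop_if_geometry_differs(gt_cord, gt_lesion,
                                 "cord and lesion masks")
        cord <- list(dice = voxel_dice(gt_cord, pred_cord),
                     nsd = nsd(gt_cord, pred_cord, config$nsd_tolerance_mm),
                     rve = rve(gt_cord, pred_cord))
    }
    gcc <- label_lesions(gt_lesion, config$connectivity)
    pcc <- label_lesions(pred_lesion, config$connectivity)
    m <- match_lesions(gcc, pcc, config$min_overlap)
    sc <- lesion_scores(m)
    lesion <- list(dice = voxel_dice(gt_lesion, pred_lesion),
                   nsd = nsd(gt_lesion, pred_lesion,
                             config$nsd_tolerance_mm),
                   recall = sc$recall, ppv = sc$ppv, f1 = sc$f1,
                   count_diff = sc$count_diff)
    structure(list(cord = cord, lesion = lesion,
                   by_size = detection_by_size(gcc, m, config$bin_edges),
                   match = m, empty_case_flag = sc$empty_case_flag,
                   config = config),
              class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
    if (!is.null(x$cord))
        cat(sprintf("cord:   Dice %.3f  NSD %.3f  RVE %+.1f%%\n",
                    x$cord$dice, x$cord$nsd, x$cord$rve))
    cat(sprintf(paste0("lesion: Dice %.3f  NSD %.3f  recall %.3f  ",
                       "PPV %.3f  F1 %.3f  |n_ref-n_pred| %d%s\n"),
                x$lesion$dice, x$lesion$nsd, x$lesion$recall,
                x$lesion$ppv, x$lesion$f1, x$lesion$count_diff,
                if (x$empty_case_flag) "  [empty-mask case]" else ""))
    if (nrow(x$by_size) > 0) {
        cat("detection by lesion volume (mm^3):\n")
        print(x$by_size, row.names = FALSE)
    }
    invisible(x)
}
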