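# Independent brute-force oracles: plain-R set operations over voxel index
# sets, sharing no code with the package implementation.

# connected components as a list of linear-index sets, by iterative
# frontier expansion over an explicit neighbor offset table
oracle_components <- function(a, connectivity = 26) {
    d <- dim(a)
    offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    m <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
    keep <- m > 0 & m <= switch(as.character(connectivity),
                                "6" = 1, "18" = 2, "26" = 3)
    offs <- offs[keep, ]
    remaining <- which(a != 0)
    comps <- list()
    while (length(remaining) > 0) {
        comp <- remaining[1]
        frontier <- comp
        while (length(frontier) > 0) {
            fi <- arrayInd(frontier, d)
            nb <- unique(unlist(lapply(seq_len(nrow(offs)), function(r) {
                ni <- sweep(fi, 2, -as.numeric(offs[r, ]))
                ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] &
                    ni[, 2] >= 1 & ni[, 2] <= d[2] &
                    ni[, 3] >= 1 & ni[, 3] <= d[3]
                ni <- ni[ok, , drop = FALSE]
                ni[, 1] + d[1] * (ni[, 2] - 1) + d[1] * d[2] * (ni[, 3] - 1)
            })))
            frontier <- setdiff(intersect(nb, remaining), comp)
            comp <- union(comp, frontier)
        }
        comps[[length(comps) + 1]] <- sort(comp)
        remaining <- setdiff(remaining, comp)
    }
    comps
}

# full lesion-wise metric set by direct set arithmetic
oracle_lesion_metrics <- function(ga, pa, min_overlap = 0.1,
                                  connectivity = 26) {
    G <- oracle_components(ga, connectivity)
    P <- oracle_components(pa, connectivity)
    pvox <- which(pa != 0)
    gvox <- which(ga != 0)
    cover <- vapply(G, function(g)
        length(intersect(g, pvox)) / length(g), 0.0)
    detected <- which(cover >= min_overlap)
    det_vox <- unlist(G[detected])
    fp_flags <- vapply(P, function(p)
        length(intersect(p, det_vox)) == 0, TRUE)
    tp <- length(detected); fn <- length(G) - tp; fp <- sum(fp_flags)
    if (length(G) == 0 && length(P) == 0) {
        recall <- ppv <- f1 <- 1
    } else {
        recall <- if (length(G) > 0) tp / (tp + fn) else 0
        ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
        f1 <- if (recall + ppv > 0) 2 * recall * ppv / (recall + ppv) else 0
    }
    dice <- if (length(gvox) + length(pvox) == 0) 1 else
        2 * length(intersect(gvox, pvox)) / (length(gvox) + length(pvox))
    list(dice = dice, recall = recall, ppv = ppv, f1 = f1,
         count_diff = abs(length(G) - length(P)),
         rve = if (length(gvox) > 0)
             100 * (length(pvox) - length(gvox)) / length(gvox) else NA,
         n_gt = length(G), n_pred = length(P))
}

# direct-summation compound Dice + BCE, written with explicit loops
oracle_dice_bce <- function(pu, pl, yu, yl, smooth = 1e-5, eps = 1e-7) {
    total <- 0
    for (ch in list(list(p = pu, y = yu), list(p = pl, y = yl))) {
        num <- 0; sp <- 0; sy <- 0; bce <- 0
        pv <- as.vector(ch$p); yv <- as.vector(ch$y)
        for (i in seq_along(pv)) {
            num <- num + pv[i] * yv[i]
            sp <- sp + pv[i]
            sy <- sy + yv[i]
            pc <- min(max(pv[i], eps), 1 - eps)  # clipped in the logs only
            bce <- bce - (yv[i] * log(pc) + (1 - yv[i]) * log(1 - pc))
        }
        dice <- (2 * num + smooth) / (sp + sy + smooth)
        total <- total + (1 - dice) + bce / length(pv)
    }
    total / 2
}

# surface distance fraction by exhaustive pairwise distances
oracle_nsd <- function(ga, pa, affine, tol) {
    surf <- function(a) {
        d <- dim(a)
        idx <- which(a != 0, arr.ind = TRUE)
        keep <- apply(idx, 1, function(v) {
            for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
                w <- v + sh
                if (any(w < 1) || any(w > d)) return(TRUE)
                if (a[w[1], w[2], w[3]] == 0) return(TRUE)
            }
            FALSE
        })
        idx <- idx[keep, , drop = FALSE] - 1
        t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
    }
    sa <- surf(ga); sb <- surf(pa)
    dmin <- function(A, B) apply(A, 1, function(p)
        min(sqrt(colSums((t(B) - p)^2))))
    (sum(dmin(sa, sb) <= tol) + sum(dmin(sb, sa) <= tol)) /
        (nrow(sa) + nrow(sb))
}

# random blobby binary mask on a small grid (components of varied size)
random_mask <- function(d = c(16, 16, 16), n_seeds = 3, p_empty = 0.1) {
    a <- array(0, d)
    if (stats::runif(1) < p_empty) return(a)
    for (s in seq_len(sample(n_seeds, 1))) {
        c0 <- sapply(d, function(n) sample(n, 1))
        r <- stats::runif(1, 1, 3.5)
        idx <- which(array(TRUE, d), arr.ind = TRUE)
        dist2 <- rowSums(sweep(idx, 2, c0)^2)
        a[idx[dist2 <= r^2, , drop = FALSE]] <- 1
    }
    a
}
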