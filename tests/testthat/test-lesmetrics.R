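test_that("stacking pads chunks symmetrically to the largest in-plane shape", {
    sp <- c(0.6, 0.6, 3.3)
    m1 <- binary_mask(add_box(array(0, c(64, 64, 4)), 30:33, 30:33, 2:3),
                      axial_affine(sp, c(0, 0, 40)))
    m2 <- binary_mask(add_box(array(0, c(80, 80, 4)), 40:43, 40:43, 2:3),
                      axial_affine(sp))
    st <- stack_chunks(list(m1, m2))
    expect_equal(dim(st$data), c(80L, 80L, 8L))
    # small chunk centered with 8-voxel pads
    expect_equal(which(st$data[, , 2] == 1, arr.ind = TRUE)[1, ],
                 c(row = 38, col = 38))
    expect_equal(sum(st$data), sum(m1$data) + sum(m2$data))
})

test_that("stacking one lesion with empty chunks keeps one component", {
    sp <- c(1, 1, 3)
    e <- binary_mask(array(0, c(10, 10, 4)), axial_affine(sp, c(0, 0, 24)))
    l <- binary_mask(add_box(array(0, c(10, 10, 4)), 4:6, 4:6, 2:3),
                     axial_affine(sp, c(0, 0, 12)))
    e2 <- binary_mask(array(0, c(10, 10, 4)), axial_affine(sp))
    st <- stack_chunks(list(e, l, e2))
    expect_equal(nrow(label_lesions(st)$table), 1)
})

test_that("component labeling honours the chosen connectivity", {
    a <- array(0, c(12, 12, 8))
    a <- add_box(a, 2:4, 2:4, 2:4)       # 27-voxel cube
    a <- add_box(a, 8:10, 8:10, 5:7)     # second cube, far away
    cc <- label_lesions(mask_from(a))
    expect_equal(cc$table$voxels, c(27, 27))

    b <- array(0, c(8, 8, 8))
    b <- add_box(b, 2:3, 2:3, 2:3)
    b <- add_box(b, 4:5, 4:5, 4:5)       # touches only at one corner
    expect_equal(nrow(label_lesions(mask_from(b), 26)$table), 1)
    expect_equal(nrow(label_lesions(mask_from(b), 6)$table), 2)

    expect_equal(nrow(label_lesions(mask_from(array(0, c(4, 4, 4))))$table),
                 0)
    # volumes derive from the affine
    cc2 <- label_lesions(binary_mask(a, axial_affine(c(0.6, 0.6, 3.3))))
    expect_equal(cc2$table$volume_mm3, c(27, 27) * 0.6 * 0.6 * 3.3)
})

test_that("the 10% overlap criterion is boundary-inclusive on the GT side", {
    a <- array(0, c(20, 10, 5))
    a[1:10, 2, 2] <- 1                  # GT lesion of 10 voxels
    for (npred in c(1, 2)) {
        b <- array(0, c(20, 10, 5))
        b[1:npred, 2, 2] <- 1           # overlap npred/10
        m <- match_lesions(label_lesions(mask_from(a)),
                           label_lesions(mask_from(b)))
        expect_equal(nrow(m$pairs), 1)  # 0.10 >= 0.10: detected
        expect_equal(m$pairs$overlap_fraction, npred / 10)
    }
    b <- array(0, c(20, 10, 5))
    b[1:10, 5, 2] <- 1                  # disjoint prediction
    m <- match_lesions(label_lesions(mask_from(a)),
                       label_lesions(mask_from(b)))
    expect_equal(nrow(m$pairs), 0)
    expect_equal(m$unmatched_gt, 1L)
    expect_equal(m$unmatched_pred, 1L)
})

test_that("4 GT lesions with 3 detected give recall 0.75, PPV 1, F1 6/7", {
    a <- array(0, c(24, 24, 6))
    for (i in 0:3) a <- add_box(a, (2 + 5 * i):(4 + 5 * i), 2:4, 2:3)
    b <- array(0, c(24, 24, 6))
    for (i in 0:2) b <- add_box(b, (2 + 5 * i):(4 + 5 * i), 2:4, 2:3)
    m <- match_lesions(label_lesions(mask_from(a)),
                       label_lesions(mask_from(b)))
    s <- lesion_scores(m)
    expect_equal(s$recall, 0.75)
    expect_equal(s$ppv, 1)
    expect_equal(s$f1, 6 / 7)
    expect_equal(s$count_diff, 1)
    o <- oracle_lesion_metrics(a, b)
    expect_equal(s$f1, o$f1)
})

test_that("empty-mask conventions for lesion scores", {
    e <- mask_from(array(0, c(8, 8, 4)))
    two <- mask_from(add_box(add_box(array(0, c(8, 8, 4)), 2:3, 2:3, 2),
                             6:7, 6:7, 3))
    # both empty: perfect by convention
    s <- lesion_scores(match_lesions(label_lesions(e), label_lesions(e)))
    expect_equal(c(s$recall, s$ppv, s$f1, s$count_diff), c(1, 1, 1, 0))
    expect_true(s$empty_case_flag)
    # empty GT, 2 predicted components
    s2 <- lesion_scores(match_lesions(label_lesions(e), label_lesions(two)))
    expect_equal(c(s2$recall, s2$ppv, s2$f1), c(0, 0, 0))
    expect_equal(s2$count_diff, 2)
    expect_true(s2$empty_case_flag)
    # nonempty GT, empty prediction
    s3 <- lesion_scores(match_lesions(label_lesions(two), label_lesions(e)))
    expect_equal(c(s3$recall, s3$ppv, s3$f1), c(0, 0, 0))
    expect_true(s3$empty_case_flag)
})

test_that("voxel Dice follows its formula and empty conventions", {
    e <- mask_from(array(0, c(6, 6, 3)))
    expect_equal(voxel_dice(e, e), 1)
    a <- mask_from(add_box(array(0, c(6, 6, 3)), 1:4, 1, 1))
    b <- mask_from(add_box(array(0, c(6, 6, 3)), 3:6, 1, 1))
    expect_equal(voxel_dice(a, a), 1)
    expect_equal(voxel_dice(a, b), 0.5)   # |a|=4, |b|=4, overlap 2
    expect_equal(voxel_dice(a, b), voxel_dice(b, a))
    expect_equal(voxel_dice(a, e), 0)
})

test_that("NSD matches a brute-force surface computation", {
    aff <- axial_affine(c(1, 1, 1))
    a <- add_box(array(0, c(12, 12, 12)), 4:8, 4:8, 4:8)
    ma <- binary_mask(a, aff)
    expect_equal(nsd(ma, ma), 1)
    # 1-voxel face dilation at tolerance >= voxel size scores 1
    b <- a
    b[3:9, 4:8, 4:8] <- pmax(b[3:9, 4:8, 4:8], 1)
    b[4:8, 3:9, 4:8] <- pmax(b[4:8, 3:9, 4:8], 1)
    b[4:8, 4:8, 3:9] <- pmax(b[4:8, 4:8, 3:9], 1)
    mb <- binary_mask(b, aff)
    expect_equal(nsd(ma, mb, tolerance_mm = 1), 1)
    expect_equal(nsd(ma, mb, tolerance_mm = 1),
                 oracle_nsd(a, b, aff, 1))
    expect_lt(nsd(ma, mb, tolerance_mm = 0.5), 1)
    expect_equal(nsd(ma, mb, tolerance_mm = 0.5),
                 oracle_nsd(a, b, aff, 0.5))
    # 10 mm offset at 1 mm tolerance: no surface agreement
    c1 <- add_box(array(0, c(30, 12, 12)), 2:5, 2:5, 2:5)
    c2 <- add_box(array(0, c(30, 12, 12)), 14:17, 2:5, 2:5)
    expect_lt(nsd(binary_mask(c1, aff), binary_mask(c2, aff)), 0.01)
    # empty conventions
    e <- binary_mask(array(0, c(12, 12, 12)), aff)
    expect_equal(nsd(e, e), 1)
    expect_equal(nsd(ma, e), 0)
})

test_that("relative volume error is a signed percentage of the reference", {
    a <- mask_from(add_box(array(0, c(10, 10, 4)), 1:10, 1:10, 1))
    expect_equal(rve(a, a), 0)
    b <- mask_from(add_box(array(0, c(10, 10, 4)), 1:10, 1:10, 1:2))
    b$data[1:10, 1:9, 2] <- 0   # 110 voxels vs 100
    expect_equal(rve(a, b), 10)
    e <- mask_from(array(0, c(10, 10, 4)))
    expect_equal(rve(a, e), -100)
    expect_error(rve(e, a), "empty reference")
})

test_that("detection rates bin GT lesions by volume with half-open bins", {
    aff <- axial_affine(c(1, 1, 1))
    a <- array(0, c(30, 12, 8))
    a <- add_box(a, 1:2, 1:2, 1)        # 4 mm^3  -> [0,10)
    a <- add_box(a, 6:8, 1:5, 1:2)      # 30 mm^3 -> [10,50)
    a <- add_box(a, 12:16, 1:5, 1:4)    # 100 mm^3 -> [50,200)
    ga <- binary_mask(a, aff)
    gcc <- label_lesions(ga)
    # perfect prediction: every nonempty bin at rate 1
    m <- match_lesions(gcc, label_lesions(ga))
    tab <- detection_by_size(gcc, m)
    expect_equal(tab$rate, rep(1, 3))
    expect_equal(tab$bin, c("[0,10)", "[10,50)", "[50,200)"))
    expect_false("[200,Inf)" %in% tab$bin)   # empty bin absent, not 0
    # prediction missing only the small lesion
    b <- a; b[1:2, 1:2, 1] <- 0
    m2 <- match_lesions(gcc, label_lesions(binary_mask(b, aff)))
    tab2 <- detection_by_size(gcc, m2)
    expect_equal(tab2$rate[tab2$bin == "[0,10)"], 0)
    expect_equal(tab2$rate[tab2$bin != "[0,10)"], c(1, 1))
    expect_error(detection_by_size(gcc, m2, bin_edges = c(50, 10)),
                 "ascending")
})

test_that("deleting more lesions never increases any bin's detection rate", {
    p <- default_phantom()
    gcc <- label_lesions(p$lesions)
    prev <- NULL
    for (fn in c(0, 3, 6)) {
        pred <- degrade_prediction(p$lesions, fn_components = fn, seed = 4)
        m <- match_lesions(gcc, label_lesions(pred))
        tab <- detection_by_size(gcc, m)
        rates <- setNames(tab$rate, tab$bin)
        if (!is.null(prev)) {
            shared <- intersect(names(rates), names(prev))
            expect_true(all(rates[shared] <= prev[shared] + 1e-12))
        }
        prev <- rates
    }
})

test_that("lesion F1 is invariant to component id permutation", {
    p <- small_phantom(n_lesions = 4, seed = 5)
    pred <- degrade_prediction(p$lesions, fn_components = 1,
                               fp_components = 1, seed = 6)
    gcc <- label_lesions(p$lesions)
    pcc <- label_lesions(pred)
    base <- lesion_scores(match_lesions(gcc, pcc))$f1
    # relabel predicted components in reverse order
    n <- nrow(pcc$table)
    relab <- pcc
    relab$labels <- ifelse(pcc$labels > 0, n + 1L - pcc$labels, 0L)
    relab$table <- relab$table[order(n + 1L - relab$table$id), ]
    relab$table$id <- seq_len(n)
    expect_equal(lesion_scores(match_lesions(gcc, relab))$f1, base)
})

test_that("evaluate_scan composes all metrics", {
    p <- small_phantom(n_lesions = 4, seed = 21)
    perfect <- evaluate_scan(p$lesions, p$lesions, p$cord, p$cord)
    expect_equal(perfect$cord$dice, 1)
    expect_equal(perfect$cord$nsd, 1)
    expect_equal(perfect$cord$rve, 0)
    expect_equal(perfect$lesion$dice, 1)
    expect_equal(perfect$lesion$f1, 1)
    expect_equal(perfect$lesion$count_diff, 0)
    expect_false(perfect$empty_case_flag)

    pred <- degrade_prediction(p$lesions, fn_components = 1, seed = 2)
    r <- evaluate_scan(p$lesions, pred)
    expect_equal(r$lesion$recall, 0.75)
    expect_equal(r$lesion$count_diff, 1)

    bad <- binary_mask(array(0, c(4, 4, 4)), diag(4))
    expect_error(evaluate_scan(p$lesions, bad), "geometry mismatch")
})
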