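test_that("detection filter keeps fragments per condition group independently", {
    d <- makeDesign(times = c(0, 2), reps = 3,
                    backgrounds = "tagged_bait")
    s0 <- d$sample_id[d$time_min == 0]
    s2 <- d$sample_id[d$time_min == 2]
    # fragment f1: 1 detection at t0, 3 at t2; f2: 2 and 0; f3: all missing
    fr <- makeFragments(list(
        "P|pep|f1" = setNames(c(10, NA, NA, 20, 21, 22), c(s0, s2)),
        "P|pep|f2" = setNames(c(10, 11, NA, NA, NA, NA), c(s0, s2)),
        "P|pep|f3" = setNames(rep(NA_real_, 6), c(s0, s2))), d)
    fe <- detectionFilter(FragmentExperiment(fr, d), minDetect = 2)
    out <- fragmentData(fe)
    # brute-force enumeration of the retained (fragment, group) pairs
    expect_setequal(unique(paste(out$fragment_id,
                                 d$time_min[match(out$sample_id,
                                                  d$sample_id)])),
                    c("f1 2", "f2 0"))
    # minDetect = 1 keeps everything except all-missing groups
    out1 <- fragmentData(detectionFilter(FragmentExperiment(fr, d), 1))
    expect_setequal(unique(paste(out1$fragment_id,
                                 d$time_min[match(out1$sample_id,
                                                  d$sample_id)])),
                    c("f1 0", "f1 2", "f2 0"))
})

test_that("detection filter enumerates a 10-fragment fixture like brute force", {
    d <- makeDesign(times = c(0, 2), reps = 3, backgrounds = "tagged_bait")
    set.seed(31)
    frag <- lapply(1:10, function(i) {
        v <- runif(6, 10, 100)
        v[sample(6, sample(0:5, 1))] <- NA
        setNames(v, d$sample_id)
    })
    names(frag) <- sprintf("P|pep%d|f%d", rep(1:5, each = 2), 1:10)
    fr <- makeFragments(frag, d)
    out <- fragmentData(detectionFilter(FragmentExperiment(fr, d), 2))
    # independent oracle: count detections per fragment x group by hand
    grp <- d$time_min[match(fr$sample_id, d$sample_id)]
    keyAll <- paste(fr$fragment_id, grp)
    det <- tapply(!is.na(fr$intensity), keyAll, sum)
    expected <- names(det)[det >= 2]
    got <- unique(paste(out$fragment_id,
                        d$time_min[match(out$sample_id, d$sample_id)]))
    expect_setequal(got, expected)
})

test_that("reliability filter keeps proportional and drops discordant fragments", {
    d <- makeDesign(times = 0, reps = 6, backgrounds = "tagged_bait")
    base <- c(100, 130, 180, 260, 380, 560)
    prop <- list(  # exact scalar multiples: identity expected
        "P|pep|f1" = setNames(base, d$sample_id),
        "P|pep|f2" = setNames(base * 2, d$sample_id),
        "P|pep|f3" = setNames(base * 0.5, d$sample_id),
        "P|pep|f5" = setNames(base * 1.3, d$sample_id))
    fe <- FragmentExperiment(makeFragments(prop, d), d)
    expect_identical(fragmentData(reliabilityFilter(fe, 2, 0.25)),
                     fragmentData(fe))

    # anti-correlated sibling (r = -1 against the reference) is removed
    anti <- c(prop, list("P|pep|f4" = setNames(rev(base) * 1.5,
                                               d$sample_id)))
    out <- fragmentData(reliabilityFilter(
        FragmentExperiment(makeFragments(anti, d), d), 2, 0.25))
    expect_setequal(unique(out$fragment_id), c("f1", "f2", "f3", "f5"))

    # single-fragment peptides pass unchanged
    single <- list("Q|pep|f1" = setNames(base, d$sample_id))
    fe1 <- FragmentExperiment(makeFragments(single, d), d)
    expect_identical(fragmentData(reliabilityFilter(fe1, 2, 0.25)),
                     fragmentData(fe1))
})

test_that("deviation rule matches an independent reimplementation", {
    d <- makeDesign(times = 0, reps = 8, backgrounds = "tagged_bait")
    set.seed(77)
    shape <- exp(rnorm(8, log(100), 1))
    frag <- lapply(1:5, function(i)
        setNames(shape * exp(rnorm(8, 0, 0.05)), d$sample_id))
    # fragment 6 wanders at ~5x the spread of its siblings
    frag[[6]] <- setNames(shape * exp(rnorm(8, 0, 1.5)), d$sample_id)
    names(frag) <- sprintf("P|pep|f%d", 1:6)
    fr <- makeFragments(frag, d)
    out <- fragmentData(reliabilityFilter(
        FragmentExperiment(fr, d), sdFactor = 2, minCorrelation = -1))

    # brute force: reference = per-sample median, centered mean-abs deviation
    m <- log2(t(vapply(frag, identity, numeric(8))))
    ref <- apply(m, 2, median)
    dev <- apply(m, 1, function(x) {
        r <- x - ref
        mean(abs(r - mean(r)))
    })
    keep <- sub("^P\\|pep\\|", "", names(dev)[dev <= 2 * mean(dev)])
    expect_setequal(unique(out$fragment_id), keep)
    expect_false("f6" %in% out$fragment_id)
})

test_that("filters only remove rows and never alter intensities", {
    sim <- simulateExperiment(simConfig(nBackground = 20, nInteractors = 2,
                                        timePoints = c(0, 2), seed = 13))
    fr0 <- fragmentData(sim$experiment)
    key <- function(x) paste(x$protein_id, x$peptide_id, x$fragment_id,
                             x$sample_id)
    fr1 <- fragmentData(reliabilityFilter(detectionFilter(sim$experiment, 2),
                                          2, 0.25))
    expect_true(all(key(fr1) %in% key(fr0)))
    m <- match(key(fr1), key(fr0))
    expect_identical(fr1$intensity, fr0$intensity[m])
})

test_that("roll-up sums match a group-by oracle and conserve intensity", {
    d <- makeDesign(times = 0, reps = 2, backgrounds = "tagged_bait")
    fr <- makeFragments(list(
        "P|pepA|f1" = setNames(c(100, 90), d$sample_id),
        "P|pepA|f2" = setNames(c(50, NA), d$sample_id),
        "P|pepB|f1" = setNames(c(NA, NA), d$sample_id),
        "Q|pepC|f1" = setNames(c(7, 8), d$sample_id)), d)
    fe <- FragmentExperiment(fr, d)
    mats <- rollUp(fe)
    pep <- quantData(mats$peptide)
    expect_equal(pep["P|pepA", ], setNames(c(150, 90), d$sample_id))
    expect_true(all(is.na(pep["P|pepB", ])))   # missing only when all missing
    prot <- quantData(mats$protein)
    expect_equal(prot["Q", ], setNames(c(7, 8), d$sample_id))
    # conservation: per-sample protein totals equal retained fragment totals
    expect_equal(colSums(prot, na.rm = TRUE),
                 c(tapply(fr$intensity, fr$sample_id, sum, na.rm = TRUE)[
                     colnames(prot)]))
    # oracle: independent aggregate()
    ag <- aggregate(intensity ~ protein_id + sample_id, data = fr, FUN = sum,
                    na.rm = TRUE, na.action = na.pass)
    for (i in seq_len(nrow(ag)))
        if (!is.na(ag$intensity[i]))
            expect_equal(prot[ag$protein_id[i], ag$sample_id[i]],
                         ag$intensity[i], ignore_attr = TRUE)
})

test_that("imputation fills from the analyte's own low quantile", {
    d <- makeDesign(times = c(0, 2), reps = 2, backgrounds = "tagged_bait")
    m <- rbind(A = c(10, 20, 30, NA),
               B = c(5, 5, 5, 5),
               C = rep(NA_real_, 4))
    colnames(m) <- d$sample_id
    qm <- makeProteinQm(m, d)
    out <- imputeMissing(qm, 0.01)
    q <- quantData(out)
    # oracle: linear-interpolation (type 7) quantile of the observed values
    expect_equal(q["A", 4], unname(quantile(c(10, 20, 30), 0.01, type = 7)))
    expect_equal(q["A", 4], 10.2)
    expect_identical(q["B", ], m["B", ])            # no missing -> unchanged
    expect_identical(S4Vectors::metadata(out)$dropped_analytes, "C")
    expect_false("C" %in% rownames(q))
    # imputed positions flagged; observed ones not
    expect_true(SummarizedExperiment::assay(out, "imputed")["A", 4])
    expect_false(any(SummarizedExperiment::assay(out, "imputed")["B", ]))
    # idempotent
    expect_identical(quantData(imputeMissing(out, 0.01)), q)
    # imputed value stays at the low end of the observed range
    expect_lte(q["A", 4], min(m["A", ], na.rm = TRUE) + 0.2 + 1e-12)
    expect_error(imputeMissing(qm, 1.5), "imputeQuantile")
})

test_that("bait normalization divides per sample and flags bad baits", {
    d <- makeDesign(times = 0, reps = 2)
    m <- rbind(BAIT = c(100, 200, 50, 80),
               PREY = c(50, 100, 25, 40),
               OTHER = c(10, 10, 10, 10))
    colnames(m) <- d$sample_id
    qm <- makeProteinQm(m, d)
    out <- normalizeToBait(qm, "BAIT")
    expect_identical(scaleType(out), "bait_normalized")
    q <- quantData(out)
    expect_equal(q["BAIT", ], setNames(rep(1, 4), colnames(m)))
    expect_equal(q["PREY", ], setNames(rep(0.5, 4), colnames(m)))
    expect_equal(q, sweep(m, 2, m["BAIT", ], `/`))  # element-wise oracle

    m2 <- m; m2["BAIT", 1] <- 0
    expect_error(normalizeToBait(makeProteinQm(m2, d), "BAIT"),
                 d$sample_id[1])
    expect_error(normalizeToBait(qm, "NOPE"), "absent")
})
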