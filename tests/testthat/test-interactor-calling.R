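statsTable <- function(ids, fc, q) {
    data.frame(protein_id = ids, median_log2_fc = fc, n_peptides = 3,
               p_value = q / 2, q_value = q)
}

test_that("specific calling applies fold, FDR, condition-count and contaminant gates", {
    p <- callingParams("mouse")
    conds <- paste0("t", c(0, 2, 5, 15))
    # P1 enriched in exactly one of four conditions
    st <- lapply(conds, function(cn)
        statsTable(c("P1", "KRT14", "P3"),
                   fc = c(if (cn == "t2") 3 else 0.5, 4, 4),
                   q = c(0.001, 0.001, 0.001)))
    names(st) <- conds
    calls <- callSpecific(st, p)
    expect_false(calls$is_specific[calls$protein_id == "P1"])
    expect_equal(calls$n_enriched[calls$protein_id == "P1"], 1L)
    # keratin prefix: enriched everywhere but removed as contaminant
    expect_true(calls$removed_as_contaminant[calls$protein_id == "KRT14"])
    expect_false(calls$is_specific[calls$protein_id == "KRT14"])
    expect_true(calls$is_specific[calls$protein_id == "P3"])
    expect_error(callSpecific(list(), p), "empty")
})

test_that("specific calls equal a brute-force application of the rule", {
    p <- callingParams("mouse")   # >3-fold, q < 0.01, >= 2 conditions
    set.seed(23)
    ids <- sprintf("P%02d", 1:30)
    conds <- c("c1", "c2", "c3")
    st <- lapply(conds, function(cn)
        statsTable(ids, fc = runif(30, 0, 4), q = runif(30, 0, 0.05)))
    names(st) <- conds
    calls <- callSpecific(st, p, contaminantList())
    # independent enumeration
    enr <- sapply(st, function(s)
        s$median_log2_fc > log2(3) & s$q_value < 0.01)
    expected <- rowSums(enr) >= 2
    expect_identical(calls$is_specific[match(ids, calls$protein_id)],
                     unname(expected))
})

test_that("dynamic calling gates on two-sided fold change and FDR", {
    p <- callingParams("mouse")
    spec <- callSpecific(list(c1 = statsTable(c("A", "B", "C"), c(3, 3, 3),
                                              c(1e-4, 1e-4, 1e-4)),
                              c2 = statsTable(c("A", "B", "C"), c(3, 3, 3),
                                              c(1e-4, 1e-4, 1e-4))), p)
    dyn <- callDynamic(list(
        d1 = statsTable(c("A", "B", "C"),
                        fc = c(log2(1.5), 2, -2),   # 1.5x fails the gate
                        q = c(0.001, 0.01, 0.01))), spec, p)
    expect_false(dyn$is_dynamic[dyn$protein_id == "A"])
    expect_true(dyn$is_dynamic[dyn$protein_id == "B"])   # 4-fold, q = 0.01
    expect_true(dyn$is_dynamic[dyn$protein_id == "C"])   # loss counts too
    expect_true(all(dyn$protein_id[dyn$is_dynamic] %in%
                    dyn$protein_id[dyn$is_specific]))
    expect_error(callDynamic(list(d1 = statsTable("A", 2, 0.01)),
                             spec[0, ], p), "specific")
})

test_that("raising thresholds never increases the number of calls", {
    set.seed(41)
    ids <- sprintf("P%02d", 1:40)
    st <- lapply(c("c1", "c2", "c3"), function(cn)
        statsTable(ids, fc = runif(40, 0, 5), q = runif(40, 0, 0.05)))
    names(st) <- c("c1", "c2", "c3")
    nCalls <- function(fc, fdr, mc)
        sum(callSpecific(st, callingParams(enrichmentFcThreshold = fc,
                                           enrichmentFdr = fdr,
                                           minConditions = mc),
                         contaminantList())$is_specific)
    expect_true(nCalls(6, 0.01, 2) <= nCalls(3, 0.01, 2))
    expect_true(nCalls(3, 0.001, 2) <= nCalls(3, 0.01, 2))
    expect_true(nCalls(3, 0.01, 3) <= nCalls(3, 0.01, 2))
})

test_that("contaminant removal commutes with enrichment testing", {
    p <- callingParams("mouse")
    set.seed(57)
    ids <- c(sprintf("P%02d", 1:20), "KRT5", "TUBB", "MYH9")
    st <- lapply(c("c1", "c2"), function(cn)
        statsTable(ids, fc = runif(23, 1, 4), q = runif(23, 0, 0.02)))
    names(st) <- c("c1", "c2")
    # filter after testing (the implementation's order)
    after <- callSpecific(st, p)
    # filter before testing: drop contaminant rows from the stats first
    cl <- defaultContaminants()
    stPre <- lapply(st, function(s) s[!isContaminant(s$protein_id, cl), ])
    before <- callSpecific(stPre, p)
    expect_setequal(after$protein_id[after$is_specific],
                    before$protein_id[before$is_specific])
})

test_that("volcano table is a deterministic projection", {
    st <- statsTable(c("B", "A"), c(1, 2), c(0.01, 0.5))
    v <- volcanoTable(st)
    expect_equal(v$neg_log10_q[v$protein_id == "B"], 2)   # -log10(0.01)
    expect_identical(v$protein_id, c("B", "A"))           # q-sorted
    expect_identical(names(volcanoTable(st[0, ])),
                     c("protein_id", "median_log2_fc", "neg_log10_q"))
    expect_equal(nrow(volcanoTable(st[0, ])), 0L)
})

test_that("heatmap rows are per-time means normalized to their maximum", {
    d <- makeDesign(times = c(0, 2, 5, 15), reps = 2)
    m <- matrix(1, 2, nrow(d), dimnames = list(c("P", "Q"), d$sample_id))
    # P: per-time means (2, 4, 8, 4) in the tagged arm
    for (tp in c(0, 2, 5, 15)) {
        v <- c(`0` = 2, `2` = 4, `5` = 8, `15` = 4)[as.character(tp)]
        m["P", d$sample_id[d$background == "tagged_bait" &
                           d$time_min == tp]] <- v
    }
    h <- heatmapTable(makeProteinQm(m, d), c("P", "Q"))
    expect_equal(unname(h["P", ]), c(0.25, 0.5, 1, 0.5))
    expect_equal(unname(h["Q", ]), rep(1, 4))     # constant row -> all 1
    expect_true(all(h >= 0 & h <= 1))
    expect_equal(unname(apply(h, 1, max)), c(1, 1))
    # independent mean-then-divide oracle for P
    tagged <- d$background == "tagged_bait"
    mp <- sapply(c(0, 2, 5, 15), function(tp)
        mean(m["P", d$sample_id[tagged & d$time_min == tp]]))
    expect_equal(unname(h["P", ]), mp / max(mp))
    m["Q", ] <- 0
    expect_error(heatmapTable(makeProteinQm(m, d), c("P", "Q")), "Q")
    expect_error(heatmapTable(makeProteinQm(m, d), character(0)), "empty")
})

test_that("phospho-site profiles are bait-normalized with flags", {
    d <- makeDesign(times = c(0, 2), reps = 1, backgrounds = "tagged_bait")
    pep <- matrix(c(2, 20, 40, 30), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, d$sample_id))
    rd <- data.frame(protein_id = c("BAIT@SEQ[ph]", "BAIT"),
                     peptide_id = c("SEQ[ph]", "SEQ"))
    pepQm <- QuantMatrix(pep, d, level = "peptide", rowData = rd)
    prot <- matrix(c(100, 200), 1, 2,
                   dimnames = list("BAIT", d$sample_id))
    protQm <- makeProteinQm(prot, d)
    pr <- phosphoSiteProfile(pepQm, protQm, "SEQ[ph]", "SEQ", "BAIT")
    ph <- pr[pr$form == "phospho", ]
    un <- pr[pr$form == "unmodified", ]
    # element-wise division oracle
    expect_equal(ph$normalized_intensity, c(2 / 100, 20 / 200))
    expect_equal(un$normalized_intensity, c(40 / 100, 30 / 200))
    # phospho form rises after stimulation; unmodified falls
    expect_gt(ph$normalized_intensity[2], ph$normalized_intensity[1])
    expect_lt(un$normalized_intensity[2], un$normalized_intensity[1])
    expect_false(any(pr$imputed))
    expect_error(phosphoSiteProfile(pepQm, protQm, "nope", "SEQ", "BAIT"),
                 "unknown")

    # constant bait: normalization is a global rescale
    prot2 <- makeProteinQm(matrix(100, 1, 2,
                                  dimnames = list("BAIT", d$sample_id)), d)
    pr2 <- phosphoSiteProfile(pepQm, prot2, "SEQ[ph]", "SEQ", "BAIT")
    expect_equal(pr2$normalized_intensity * 100,
                 c(pep[1, ], pep[2, ]), ignore_attr = TRUE)
})
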