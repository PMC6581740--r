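test_that("simulation is a pure function of config and seed", {
    cfg <- simConfig(nBackground = 15, nInteractors = 3, nContaminants = 1,
                     timePoints = c(0, 2), seed = 9)
    a <- simulateExperiment(cfg)
    b <- simulateExperiment(cfg)
    expect_identical(fragmentData(a$experiment), fragmentData(b$experiment))
    expect_identical(a$truth, b$truth)
    expect_identical(a$sequences, b$sequences)
    # a different seed changes the data
    cfg2 <- cfg; cfg2@seed <- 10
    expect_false(identical(fragmentData(a$experiment),
                           fragmentData(simulateExperiment(cfg2)$experiment)))
    # the global RNG stream is untouched
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(simulateExperiment(cfg)); after <- runif(1)
    expect_identical(before, after)
})

test_that("null config gives equal background expectation in both arms", {
    cfg <- simConfig(nBackground = 40, nInteractors = 0, nContaminants = 0,
                     missingRate = 0, timePoints = 0, nReplicates = 6,
                     cv = 0.05, simulatePhospho = FALSE, seed = 4)
    sim <- simulateExperiment(cfg)
    fr <- fragmentData(sim$experiment)
    d <- sampleDesign(sim$experiment)
    fr <- merge(fr, d[, c("sample_id", "background")], by = "sample_id")
    tot <- tapply(fr$intensity[fr$protein_id != "BAIT"],
                  list(fr$protein_id[fr$protein_id != "BAIT"],
                       fr$background[fr$protein_id != "BAIT"]),
                  sum)
    ratio <- log2(tot[, "tagged_bait"] / tot[, "untagged_control"])
    expect_lt(max(abs(ratio)), 0.3)
})

test_that("spiked interactors realize their programmed fold change", {
    # 500 background, 20 interactors, cv = 0.2, 3 replicates
    cfg <- simConfig(nBackground = 500, nInteractors = 20, interactorFold = 8,
                     occupancy = 0.1, timePoints = 2, missingRate = 0, seed = 7)
    sim <- simulateExperiment(cfg)
    fr <- fragmentData(sim$experiment)
    d <- sampleDesign(sim$experiment)
    ints <- sprintf("INT%03d", 1:20)
    fr <- fr[fr$protein_id %in% ints, ]
    fr <- merge(fr, d[, c("sample_id", "background")], by = "sample_id")
    tot <- tapply(fr$intensity, list(fr$protein_id, fr$background),
                  function(x) sum(x, na.rm = TRUE) / 3)
    fc <- log2(tot[, "tagged_bait"] / tot[, "untagged_control"])
    # programmed value: constitutive kinetics at the peak -> log2(fold)
    expect_true(all(abs(fc - log2(8)) < 0.3))
})

test_that("iBAQ-inverting scaling makes occupancy the intensity design", {
    cfg <- simConfig(nBackground = 5, nInteractors = 2,
                     occupancy = c(0.2, 0.05), missingRate = 0, cv = 1e-9,
                     timePoints = 2, simulatePhospho = FALSE, seed = 2)
    sim <- simulateExperiment(cfg)
    fr <- fragmentData(sim$experiment)
    tot <- tapply(fr$intensity[fr$sample_id == "bait_t2_r1"],
                  fr$protein_id[fr$sample_id == "bait_t2_r1"], sum)
    cnt <- vapply(sim$sequences, theoreticalPeptideCount, numeric(1))
    ibaq <- tot[names(cnt)] / cnt
    expect_equal(unname(ibaq["INT001"] / ibaq["BAIT"]), 0.2, tolerance = 1e-6)
    expect_equal(unname(ibaq["INT002"] / ibaq["BAIT"]), 0.05, tolerance = 1e-6)
    # sequence digestion count matches the truth record
    expect_identical(unname(cnt[sim$truth$protein_id]),
                     as.numeric(sim$truth$theoretical_peptide_count))
})

test_that("kinetic profiles shape the tagged arm only", {
    cfg <- simConfig(nBackground = 2, nInteractors = 1, occupancy = 0.5,
                     kinetics = list(transientKinetics()), missingRate = 0,
                     cv = 1e-9, timePoints = c(0, 2, 15),
                     simulatePhospho = FALSE, seed = 6)
    sim <- simulateExperiment(cfg)
    fr <- fragmentData(sim$experiment)
    one <- fr[fr$protein_id == "INT001" & grepl("_r1$", fr$sample_id), ]
    tot <- tapply(one$intensity, one$sample_id, sum)
    k <- transientKinetics()
    expect_equal(unname(tot["bait_t0_r1"] / tot["bait_t2_r1"]),
                 unname(k["0"] / k["2"]), tolerance = 1e-6)
    # control carry-over is constant over time
    expect_equal(unname(tot["ctrl_t0_r1"]), unname(tot["ctrl_t15_r1"]),
                 tolerance = 1e-6)
})

test_that("config validation rejects out-of-range parameters", {
    expect_error(simConfig(occupancy = 1.2), "occupancy")
    expect_error(simConfig(missingRate = 1), "missingRate")
    expect_error(simConfig(cv = -0.1), "cv")
    expect_error(simConfig(interactorFold = 1), "interactorFold")
    expect_error(simulateSilacExperiment(simConfig(silac = FALSE)), "silac")
    expect_error(simulateExperiment(simConfig(silac = TRUE)), "silac")
})

test_that("SILAC channels split the programmed origin mixture", {
    lf <- c(1, 1, 0.5, 0, rep(0.5, 10))  # bait, then 3 interactors, 10 bg
    cfg <- simConfig(nBackground = 10, nInteractors = 3, occupancy = 0.2,
                     timePoints = 2, silac = TRUE, lightFraction = lf,
                     missingRate = 0, simulatePhospho = FALSE, seed = 8)
    sim <- simulateSilacExperiment(cfg)
    fr <- fragmentData(sim$experiment)
    d <- sampleDesign(sim$experiment)
    expect_setequal(unique(d$silac_channel), c("light", "heavy"))

    heavyOfLightOnly <- fr$intensity[fr$protein_id == "INT001" &
        fr$sample_id %in% d$sample_id[d$silac_channel == "heavy"]]
    expect_true(all(is.na(heavyOfLightOnly)))  # all-light -> heavy missing

    # 0.5 mixture: empirical light/heavy ratio near 1
    half <- fr[fr$protein_id == "INT002", ]
    ch <- d$silac_channel[match(half$sample_id, d$sample_id)]
    ratio <- sum(half$intensity[ch == "light"]) /
        sum(half$intensity[ch == "heavy"])
    expect_equal(ratio, 1, tolerance = 0.1)

    expect_identical(fragmentData(simulateSilacExperiment(cfg)$experiment),
                     fr)
})
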