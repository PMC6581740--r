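# End-to-end orchestration: simulate/read -> filter -> roll up -> impute ->
# test -> call -> stoichiometry, with a deterministic report bundle.

#' Assemble a pipeline configuration
#'
#' Exactly one of \code{simConfig} (synthetic mode) or the triple
#' \code{fragments}/\code{design}/\code{sequences} (file paths or in-memory
#' objects) must be supplied.
#'
#' @param simConfig a \linkS4class{SimConfig}, or \code{NULL}.
#' @param fragments,design fragment table / design (paths or objects).
#' @param sequences named character vector of protein sequences or FASTA
#'   path (needed for stoichiometry).
#' @param filterParams,callingParams,digestParams parameter objects; the
#'   defaults are the reference analysis settings (detection >= 2 per
#'   condition, sd factor 2, min correlation 0.25, impute quantile 0.01,
#'   3-fold enrichment at FDR 0.01 in >= 2 conditions, 2-fold dynamic
#'   change at FDR 0.05).
#' @param contaminants a \code{"ContaminantList"}.
#' @param baitId bait protein id.
#' @param stoichTime time point (minutes) whose tagged replicates are
#'   averaged for stoichiometry; default: the earliest stimulated time
#'   point.
#' @param outDir optional output directory for the report bundle.
#' @param seed overrides the simulator seed when given.
#' @return a \code{"PipelineConfig"} list.
#' @export
pipelineConfig <- function(simConfig = NULL, fragments = NULL, design = NULL,
                           sequences = NULL,
                           filterParams = baitprey::filterParams(),
                           callingParams = baitprey::callingParams("mouse"),
                           digestParams = baitprey::digestParams(),
                           contaminants = defaultContaminants(),
                           baitId = "BAIT", stoichTime = NULL,
                           outDir = NULL, seed = NULL) {
    synthetic <- !is.null(simConfig)
    if (synthetic == (!is.null(fragments) || !is.null(design)))
        .stopf("supply exactly one of simConfig or fragments+design")
    if (!synthetic && (is.null(fragments) || is.null(design)))
        .stopf("real-data mode needs both fragments and design")
    structure(list(simConfig = simConfig, fragments = fragments,
                   design = design, sequences = sequences,
                   filterParams = filterParams,
                   callingParams = callingParams,
                   digestParams = digestParams, contaminants = contaminants,
                   baitId = baitId, stoichTime = stoichTime, outDir = outDir,
                   seed = seed),
              class = "PipelineConfig")
}

#' Run the full interactome analysis
#'
#' Executes every stage in order: data acquisition (simulation or file
#' input), phosphopeptide routing, per-condition detection filter, fragment
#' reliability filter, peptide/protein roll-up, quantile imputation,
#' bait-vs-control protein statistics per condition, specific-interactor
#' calling with contaminant removal, bait normalization,
#' stimulated-vs-baseline dynamic statistics and calling, iBAQ
#' stoichiometry, and the volcano/heatmap report tables. Rerunning with an
#' identical configuration (and seed) yields identical results; when
#' \code{outDir} is set, byte-identical files.
#'
#' @param config a \code{"PipelineConfig"} from \code{\link{pipelineConfig}}.
#' @return a list: \code{calls}, \code{specificStats} (per condition),
#'   \code{dynamicStats} (per contrast), \code{volcano} (per condition),
#'   \code{heatmap}, \code{stoichiometry}, \code{proteinMatrix},
#'   \code{peptideMatrix}, \code{summary} (stage-wise counts),
#'   \code{runLog} (parameters actually applied), and in synthetic mode
#'   \code{truth} and \code{sim}.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "PipelineConfig"))
        .stopf("config must come from pipelineConfig()")
    fp <- config$filterParams
    cp <- config$callingParams
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            .stopf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
    }

    # -- acquire -------------------------------------------------------------
    sim <- NULL
    if (!is.null(config$simConfig)) {
        sc <- config$simConfig
        if (!is.null(config$seed)) sc@seed <- config$seed
        sim <- stage("simulate", if (sc@silac) simulateSilacExperiment(sc)
                                 else simulateExperiment(sc))
        fe <- sim$experiment
        sequences <- sim$sequences
    } else {
        fe <- stage("read", {
            fr <- if (is.character(config$fragments))
                readFragmentTable(config$fragments) else
                as.data.table(config$fragments)
            de <- if (is.character(config$design))
                readSampleDesign(config$design) else config$design
            FragmentExperiment(fr, de)
        })
        sequences <- if (is.character(config$sequences) &&
                         length(config$sequences) == 1L &&
                         file.exists(config$sequences))
            readProteinFasta(config$sequences) else config$sequences
    }
    counts <- data.table(stage = "input",
                         fragment_rows = nrow(fragmentData(fe)))

    # -- process -------------------------------------------------------------
    fe <- stage("phospho_routing", routePhosphopeptides(fe))
    fe <- stage("detection_filter",
                detectionFilter(fe, fp@minDetectPerCondition))
    counts <- rbind(counts, data.table(stage = "detection_filter",
                                       fragment_rows = nrow(fragmentData(fe))))
    fe <- stage("reliability_filter",
                reliabilityFilter(fe, fp@sdFactor, fp@minCorrelation))
    counts <- rbind(counts, data.table(stage = "reliability_filter",
                                       fragment_rows = nrow(fragmentData(fe))))
    mats <- stage("rollup", rollUp(fe))
    pepQm <- stage("impute_peptide",
                   imputeMissing(mats$peptide, fp@imputeQuantile))
    protQm <- stage("impute_protein",
                    imputeMissing(mats$protein, fp@imputeQuantile))

    d <- sampleDesign(fe)
    baitId <- config$baitId
    excludeIds <- grep(paste0("^", baitId, "($|@)"),
                       rownames(quantData(protQm)), value = TRUE)

    # -- specific interactors (bait vs control, un-normalized) --------------
    times <- sort(unique(d$time_min))
    cond <- d$condition[1L]
    tlab <- function(tp) format(tp, trim = TRUE, scientific = FALSE)
    hasCtrl <- "untagged_control" %in% d$background
    specificStats <- list()
    if (hasCtrl) {
        for (tp in times) {
            ga <- sprintf("tagged_bait:%s:%s", cond, tlab(tp))
            gb <- sprintf("untagged_control:%s:%s", cond, tlab(tp))
            specificStats[[sprintf("bait_vs_ctrl_t%s", tlab(tp))]] <-
                stage("specific_stats", testContrast(pepQm, ga, gb))
        }
    }
    calls <- if (length(specificStats))
        stage("call_specific",
              callSpecific(specificStats, cp, config$contaminants,
                           exclude = excludeIds))
    else NULL

    # -- dynamic interactors (bait-normalized, stim vs baseline) ------------
    dynamicStats <- list()
    if (length(times) > 1L) {
        b <- quantData(protQm)[baitId, ]
        qn <- sweep(quantData(pepQm), 2L, b[colnames(quantData(pepQm))], `/`)
        pepNorm <- QuantMatrix(qn, d, level = "peptide",
                               scaleType = "bait_normalized",
                               rowData = as.data.frame(rowData(pepQm)))
        t0 <- times[1L]
        for (tp in times[-1L]) {
            ga <- sprintf("tagged_bait:%s:%s", cond, tlab(tp))
            gb <- sprintf("tagged_bait:%s:%s", cond, tlab(t0))
            dynamicStats[[sprintf("t%s_vs_t%s", tlab(tp), tlab(t0))]] <-
                stage("dynamic_stats", testContrast(pepNorm, ga, gb))
        }
        if (!is.null(calls))
            calls <- stage("call_dynamic", callDynamic(dynamicStats, calls, cp))
    }

    specific <- if (!is.null(calls)) calls$protein_id[calls$is_specific]
                else character(0)
    counts <- rbind(counts,
                    data.table(stage = c("proteins_tested",
                                         "specific_interactors",
                                         "dynamic_interactors"),
                               fragment_rows = c(nrow(quantData(protQm)),
                                                 length(specific),
                                                 if (!is.null(calls) &&
                                                     "is_dynamic" %in%
                                                     names(calls))
                                                     sum(calls$is_dynamic)
                                                 else 0L)))

    # -- reports -------------------------------------------------------------
    volcano <- lapply(specificStats, volcanoTable)
    heat <- if (length(specific))
        stage("heatmap", heatmapTable(protQm, sort(specific))) else NULL

    stoich <- NULL
    if (!is.null(sequences) && length(specific)) {
        st <- config$stoichTime
        if (is.null(st)) st <- if (length(times) > 1L) times[2L] else times[1L]
        grp <- sprintf("tagged_bait:%s:%s", cond, tlab(st))
        stoich <- stage("stoichiometry",
                        stoichiometryAt(protQm, sequences, grp, baitId,
                                        config$digestParams,
                                        proteins = setdiff(specific,
                                                           excludeIds)))
    }

    runLog <- data.table(
        parameter = c("mode", "seed", "bait_id", "min_detect_per_condition",
                      "sd_factor", "min_correlation", "impute_quantile",
                      "enrichment_fc_threshold", "enrichment_fdr",
                      "min_conditions", "dynamic_fc_threshold", "dynamic_fdr",
                      "digest_min_len", "digest_max_len",
                      "digest_missed_cleavages", "dropped_analytes_protein"),
        value = as.character(c(
            if (is.null(sim)) "files" else "synthetic",
            if (!is.null(config$simConfig)) {
                if (!is.null(config$seed)) config$seed
                else config$simConfig@seed
            } else NA,
            baitId, fp@minDetectPerCondition, fp@sdFactor,
            fp@minCorrelation, fp@imputeQuantile, cp@enrichmentFcThreshold,
            cp@enrichmentFdr, cp@minConditions, cp@dynamicFcThreshold,
            cp@dynamicFdr, config$digestParams@minLen,
            config$digestParams@maxLen, config$digestParams@missedCleavages,
            length(metadata(protQm)$dropped_analytes))))

    res <- list(calls = calls, specificStats = specificStats,
                dynamicStats = dynamicStats, volcano = volcano,
                heatmap = heat, stoichiometry = stoich,
                proteinMatrix = protQm, peptideMatrix = pepQm,
                summary = counts, runLog = runLog,
                truth = if (!is.null(sim)) sim$truth else NULL,
                sim = sim)

    if (!is.null(config$outDir)) .writeBundle(res, config)
    res
}

.writeBundle <- function(res, config) {
    tabs <- list(summary = res$summary, run_log = res$runLog)
    if (!is.null(res$calls)) tabs$calls <- res$calls
    for (nm in names(res$volcano))
        tabs[[paste0("volcano_", nm)]] <- res$volcano[[nm]]
    for (nm in names(res$specificStats))
        tabs[[paste0("stats_", nm)]] <- res$specificStats[[nm]]
    for (nm in names(res$dynamicStats))
        tabs[[paste0("stats_", nm)]] <- res$dynamicStats[[nm]]
    if (!is.null(res$heatmap))
        tabs$heatmap <- data.table(protein_id = rownames(res$heatmap),
                                   as.data.table(res$heatmap))
    if (!is.null(res$stoichiometry)) tabs$stoichiometry <- res$stoichiometry
    q <- quantData(res$proteinMatrix)
    tabs$protein_matrix <- data.table(protein_id = rownames(q),
                                      as.data.table(q))
    if (!is.null(res$truth)) tabs$truth <- res$truth
    writeResultTables(tabs, config$outDir)
}

#' SILAC origin analysis of a labeled AP-MS experiment
#'
#' Convenience wrapper for the SILAC branch: per-condition detection filter,
#' fragment reliability filter, roll-up (no imputation, so an undetected
#' channel stays undetected), channel splitting, floored light/heavy ratios
#' and origin classification.
#'
#' @param fe a \linkS4class{FragmentExperiment} with light/heavy channel
#'   samples.
#' @param proteins optional protein ids to restrict the report to.
#' @param filterParams a \linkS4class{FilterParams}.
#' @param floorQuantile,floor see \code{\link{silacRatios}}.
#' @param exclusiveThreshold see \code{\link{classifyOrigin}}.
#' @return the classified \code{\link{silacRatios}} table.
#' @export
silacOriginAnalysis <- function(fe, proteins = NULL,
                                filterParams = baitprey::filterParams(),
                                floorQuantile = 0.01, floor = NULL,
                                exclusiveThreshold = 0.95) {
    fe <- detectionFilter(fe, filterParams@minDetectPerCondition)
    fe <- reliabilityFilter(fe, filterParams@sdFactor,
                            filterParams@minCorrelation)
    protQm <- rollUp(fe)$protein
    ch <- splitSilacChannels(protQm)
    # the floor is a property of the whole run (1% lowest detected value),
    # so ratios are computed on the full matrices before any subsetting
    res <- classifyOrigin(silacRatios(ch$light, ch$heavy, floorQuantile,
                                      floor),
                          exclusiveThreshold)
    if (!is.null(proteins)) {
        fl <- attr(res, "floor")
        res <- res[res$protein_id %in% proteins, ]
        setattr(res, "floor", fl)
    }
    res[]
}
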