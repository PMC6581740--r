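# SILAC light/heavy ratio analysis and cellular-origin classification.

#' Per-protein SILAC light/heavy ratios with a detection floor
#'
#' The floor is the \code{floorQuantile} quantile (linear interpolation) of
#' all detected intensities pooled across both channels (an explicit
#' \code{floor} overrides it); undetected channel entries are replaced by
#' the floor before ratio computation, so a protein detected in one channel
#' only still yields a finite, sign-stable ratio. Ratios are computed per
#' replicate (light / heavy in the same replicate) and averaged;
#' \code{light_fraction = ratio / (1 + ratio)}.
#'
#' @param lightMatrix,heavyMatrix numeric matrices, proteins x replicates,
#'   matched row and column order; \code{NA} = channel not detected.
#' @param floorQuantile quantile of pooled detected intensities used as the
#'   floor (default 0.01, i.e. the 1\% lowest detected value).
#' @param floor optional explicit floor value overriding the quantile.
#' @return data.table with \code{protein_id}, \code{light_intensity},
#'   \code{heavy_intensity} (replicate means after flooring), \code{ratio},
#'   \code{light_fraction}, \code{floor_applied} (none/light/heavy/both),
#'   \code{warn_undetected} (TRUE when no channel was ever detected), plus
#'   the floor used in \code{attr(, "floor")}.
#' @export
silacRatios <- function(lightMatrix, heavyMatrix, floorQuantile = 0.01,
                        floor = NULL) {
    if (!all(dim(lightMatrix) == dim(heavyMatrix)) ||
        !identical(rownames(lightMatrix), rownames(heavyMatrix)))
        .stopf("light and heavy matrices must match in shape and protein set")
    if (is.null(rownames(lightMatrix)))
        .stopf("matrices need protein ids as rownames")
    pooled <- c(lightMatrix, heavyMatrix)
    pooled <- pooled[!is.na(pooled)]
    if (!length(pooled)) .stopf("no detected intensity in either channel")
    if (is.null(floor)) {
        if (floorQuantile <= 0 || floorQuantile >= 1)
            .stopf("floorQuantile must be in (0, 1)")
        floor <- type7Quantile(pooled, floorQuantile)
    }
    lNA <- is.na(lightMatrix)
    hNA <- is.na(heavyMatrix)
    L <- ifelse(lNA, floor, lightMatrix)
    H <- ifelse(hNA, floor, heavyMatrix)
    ratio <- rowMeans(L / H)
    out <- data.table(
        protein_id = rownames(lightMatrix),
        light_intensity = rowMeans(L),
        heavy_intensity = rowMeans(H),
        ratio = ratio,
        light_fraction = ratio / (1 + ratio),
        floor_applied = ifelse(rowSums(lNA) > 0 & rowSums(hNA) > 0, "both",
                        ifelse(rowSums(lNA) > 0, "light",
                        ifelse(rowSums(hNA) > 0, "heavy", "none"))),
        warn_undetected = rowSums(!lNA) + rowSums(!hNA) == 0)
    if (any(out$warn_undetected))
        warning("protein(s) undetected in both channels (floor assigned): ",
                paste(out$protein_id[out$warn_undetected], collapse = ", "))
    setattr(out, "floor", floor)
    out[]
}

#' Classify the cellular origin of each interactor
#'
#' Proteins whose light fraction is at least \code{exclusiveThreshold} come
#' exclusively from the light-labeled cell (the tagged T cell); at most
#' \code{1 - exclusiveThreshold}, exclusively from the heavy-labeled
#' antigen-presenting cell; anything in between is of mixed origin.
#' Classification is monotone in the light fraction.
#'
#' @param results output of \code{\link{silacRatios}}.
#' @param exclusiveThreshold threshold in (0.5, 1), default 0.95.
#' @return \code{results} with an added \code{origin} column
#'   (\code{"t_cell_exclusive"}, \code{"apc_exclusive"}, \code{"mixed"}).
#' @export
classifyOrigin <- function(results, exclusiveThreshold = 0.95) {
    if (exclusiveThreshold <= 0.5 || exclusiveThreshold >= 1)
        .stopf("exclusiveThreshold must be in (0.5, 1)")
    out <- as.data.table(results)
    out[, origin := ifelse(light_fraction >= exclusiveThreshold,
                           "t_cell_exclusive",
                    ifelse(light_fraction <= 1 - exclusiveThreshold,
                           "apc_exclusive", "mixed"))]
    out[]
}

#' Split an imputation-free protein matrix into SILAC channels
#'
#' Pairs light/heavy samples of the same physical injection (matched by
#' background, condition, time and replicate) and returns one matrix per
#' channel with replicate-labeled columns, ready for
#' \code{\link{silacRatios}}.
#'
#' @param qm a protein-level \linkS4class{QuantMatrix} whose design carries
#'   \code{silac_channel} light/heavy samples.
#' @return list with matrices \code{light} and \code{heavy}.
#' @export
splitSilacChannels <- function(qm) {
    stopifnot(is(qm, "QuantMatrix"))
    d <- sampleDesign(qm)
    q <- quantData(qm)
    li <- d$silac_channel == "light"
    hi <- d$silac_channel == "heavy"
    if (!any(li) || !any(hi))
        .stopf("design has no light/heavy channel samples")
    key <- function(x) paste(x$background, x$condition, x$time_min,
                             x$replicate, sep = ":")
    lk <- key(d[li, ]); hk <- key(d[hi, ])
    common <- intersect(lk, hk)
    if (!length(common)) .stopf("no paired light/heavy samples")
    L <- q[, d$sample_id[li][match(common, lk)], drop = FALSE]
    H <- q[, d$sample_id[hi][match(common, hk)], drop = FALSE]
    colnames(L) <- colnames(H) <- common
    list(light = L, heavy = H)
}
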