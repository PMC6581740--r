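#' Simulation configuration
#'
#' Describes a synthetic AP-MS experiment with known ground truth: a tagged
#' bait purified against an untagged-control background, over a pervanadate
#' time course with paired biological replicates, quantified at the fragment
#' level with log-normal noise and missing values.
#'
#' The abundance model: a true interactor's expected protein-level quantity
#' in a tagged sample at time t is
#' \code{baitAbundance * occupancy * kinetic(t) * (nPep_prey / nPep_bait)},
#' where the peptide-count factor makes iBAQ normalization exactly
#' invertible, so prey-iBAQ / bait-iBAQ at the peak time point recovers the
#' programmed occupancy fraction. Its non-specific carry-over level in
#' control purifications is the peak tagged level divided by
#' \code{interactorFold}, so the programmed bait-vs-control log2 fold change
#' at time t is \code{log2(interactorFold * kinetic(t))}. Background
#' proteins have equal expected intensity in both backgrounds; simulated
#' contaminants are enriched "sticky" binders (constitutive, occupancy
#' 0.05) carrying keratin/tubulin/myosin-style identifiers so that
#' list-based removal is exercised end to end.
#'
#' @slot nBackground number of non-interacting background proteins.
#' @slot nInteractors number of true interactors.
#' @slot occupancy fraction of bait molecules bound at peak, in (0,1];
#'   recycled over interactors (default 0.1).
#' @slot interactorFold fold enrichment of an interactor's peak tagged level
#'   over its control carry-over level (default 8); recycled.
#' @slot baitFold fold enrichment of the bait itself over its carry-over in
#'   untagged-control purifications (default 64): the untagged bait protein
#'   is expressed in control cells and binds the resin non-specifically at a
#'   low level, as the large but finite bait fold change on enrichment
#'   volcanoes shows.
#' @slot kinetics list recycled over interactors; each element \code{NULL}
#'   (constitutive recruitment) or a named numeric vector time -> relative
#'   recruitment, rescaled so its maximum over the configured time points
#'   is 1. See \code{\link{transientKinetics}}.
#' @slot baitAbundance expected raw protein-level intensity of the bait in
#'   tagged samples (arbitrary units, default 1e6).
#' @slot peptidesPerProtein,fragmentsPerPeptide integer ranges
#'   (\code{c(min,max)}) sampled per protein / per peptide.
#' @slot cv biological coefficient of variation of the log-normal replicate
#'   noise (default 0.2).
#' @slot missingRate per-fragment missing probability (default 0.1).
#' @slot missingMode \code{"uniform"} (default: each fragment measurement is
#'   missing independently with \code{missingRate}, which is neutral for
#'   ratio estimates) or \code{"censored"} (detection probability falls off
#'   logistically below a limit at the \code{missingRate} quantile of
#'   expected intensities, emulating the left-censored dropout of DIA
#'   detection; this regime biases faint analytes low, which is exactly the
#'   situation the low-quantile imputation rule addresses).
#' @slot nContaminants number of sticky contaminant proteins (default 0).
#' @slot nReplicates paired biological replicates per condition (default 3).
#' @slot timePoints stimulation time points in minutes.
#' @slot condition stimulation label used in the design.
#' @slot silac logical; generate light/heavy channels.
#' @slot lightFraction per-protein fraction of signal originating from the
#'   light-labeled cell (recycled over all proteins; default 1).
#' @slot simulatePhospho logical; add a phospho/unmodified ITIM-like peptide
#'   pair on the bait whose phosphorylated fraction rises transiently after
#'   stimulation.
#' @slot seed integer driving one deterministic generator; no global RNG
#'   state is touched.
#' @export
setClass("SimConfig",
         slots = c(nBackground = "numeric", nInteractors = "numeric",
                   occupancy = "numeric", interactorFold = "numeric",
                   baitFold = "numeric",
                   kinetics = "list", baitAbundance = "numeric",
                   peptidesPerProtein = "numeric",
                   fragmentsPerPeptide = "numeric", cv = "numeric",
                   missingRate = "numeric", missingMode = "character",
                   nContaminants = "numeric", nReplicates = "numeric",
                   timePoints = "numeric", condition = "character",
                   silac = "logical", lightFraction = "numeric",
                   simulatePhospho = "logical", seed = "numeric"))

setValidity("SimConfig", function(object) {
    if (object@nBackground < 0 || object@nInteractors < 0 ||
        object@nContaminants < 0)
        return("protein counts must be non-negative")
    if (length(object@occupancy) &&
        (any(object@occupancy <= 0) || any(object@occupancy > 1)))
        return("occupancy fractions must lie in (0, 1]")
    if (any(object@interactorFold <= 1))
        return("interactorFold must be > 1")
    if (object@baitFold <= 1)
        return("baitFold must be > 1")
    if (object@cv < 0) return("cv must be >= 0")
    if (object@missingRate < 0 || object@missingRate >= 1)
        return("missingRate must be in [0, 1)")
    if (!object@missingMode %in% c("uniform", "censored"))
        return("missingMode must be uniform or censored")
    if (length(object@peptidesPerProtein) != 2 ||
        object@peptidesPerProtein[1] < 1 ||
        diff(object@peptidesPerProtein) < 0)
        return("peptidesPerProtein must be an increasing range c(min, max)")
    if (length(object@fragmentsPerPeptide) != 2 ||
        object@fragmentsPerPeptide[1] < 1 ||
        diff(object@fragmentsPerPeptide) < 0)
        return("fragmentsPerPeptide must be an increasing range c(min, max)")
    if (object@nReplicates < 1) return("nReplicates >= 1")
    if (!length(object@timePoints) || any(object@timePoints < 0))
        return("timePoints must be non-negative minutes")
    if (any(object@lightFraction < 0) || any(object@lightFraction > 1))
        return("lightFraction must be in [0, 1]")
    TRUE
})

#' @rdname SimConfig-class
#' @param nBackground,nInteractors,occupancy,interactorFold,baitFold,kinetics,baitAbundance,peptidesPerProtein,fragmentsPerPeptide,cv,missingRate,missingMode,nContaminants,nReplicates,timePoints,condition,silac,lightFraction,simulatePhospho,seed
#'   see the corresponding slots.
#' @export
simConfig <- function(nBackground = 500, nInteractors = 20, occupancy = 0.1,
                      interactorFold = 8, baitFold = 64, kinetics = list(),
                      baitAbundance = 1e6, peptidesPerProtein = c(4, 9),
                      fragmentsPerPeptide = c(5, 6), cv = 0.2,
                      missingRate = 0.1, missingMode = "uniform",
                      nContaminants = 0, nReplicates = 3,
                      timePoints = c(0, 2, 5, 15), condition = "pervanadate",
                      silac = FALSE, lightFraction = 1,
                      simulatePhospho = TRUE, seed = 1) {
    new("SimConfig", nBackground = nBackground, nInteractors = nInteractors,
        occupancy = occupancy, interactorFold = interactorFold,
        baitFold = baitFold,
        kinetics = kinetics, baitAbundance = baitAbundance,
        peptidesPerProtein = peptidesPerProtein,
        fragmentsPerPeptide = fragmentsPerPeptide, cv = cv,
        missingRate = missingRate, missingMode = missingMode,
        nContaminants = nContaminants, nReplicates = nReplicates,
        timePoints = timePoints, condition = condition, silac = silac,
        lightFraction = lightFraction, simulatePhospho = simulatePhospho,
        seed = seed)
}

#' Canonical transient recruitment profile
#'
#' A recruitment curve that is low before stimulation, peaks around 2
#' minutes and decays, mirroring the transient tyrosine-phosphorylation
#' kinetics of coinhibitory receptor signalosomes under pervanadate.
#'
#' @return named numeric vector, time (min) to relative recruitment.
#' @export
transientKinetics <- function() {
    c(`0` = 0.05, `0.5` = 0.8, `2` = 1, `5` = 0.6, `15` = 0.25)
}

# Evaluate a kinetic profile at the configured time points and rescale so
# the maximum over those points is exactly 1 (the occupancy fraction refers
# to the peak).
.evalKinetics <- function(profile, timePoints) {
    if (is.null(profile)) return(rep(1, length(timePoints)))
    tt <- as.numeric(names(profile))
    v <- approx(tt, as.numeric(profile), xout = timePoints, rule = 2)$y
    v / max(v)
}

# Phosphorylated fraction of the bait ITIM-like peptide over time.
.phosphoFraction <- function(timePoints) {
    prof <- c(`0` = 0.05, `0.5` = 0.6, `2` = 0.9, `5` = 0.7, `15` = 0.4)
    approx(as.numeric(names(prof)), prof, xout = timePoints, rule = 2)$y
}

.AA_NONCLEAVING <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                     "Q", "S", "T", "V", "W", "Y")

# One fully tryptic peptide: (len-1) non-K/R/P residues followed by K, so a
# concatenation of such peptides digests back into exactly these peptides
# (no K/R internally, never followed by P).
.randomPeptide <- function(len) {
    paste0(paste(sample(.AA_NONCLEAVING, len - 1L, replace = TRUE),
                 collapse = ""), "K")
}

.simRoster <- function(config) {
    nI <- config@nInteractors
    nC <- config@nContaminants
    nB <- config@nBackground
    contamPrefix <- rep(c("KRT", "TUB", "MYH"), length.out = max(nC, 1L))
    data.table(
        protein_id = c("BAIT",
                       if (nI) sprintf("INT%03d", seq_len(nI)),
                       if (nC) sprintf("%s9%02d_SIM", contamPrefix[seq_len(nC)],
                                       seq_len(nC)),
                       if (nB) sprintf("BG%04d", seq_len(nB))),
        role = c("bait", rep("interactor", nI), rep("contaminant", nC),
                 rep("background", nB)))
}

#' Simulate a fragment-level AP-MS experiment
#'
#' Generates a complete synthetic dataset: fragment intensities for a
#' tagged-bait vs untagged-control purification time course, the matching
#' sample design, protein sequences whose tryptic digestion yields a known
#' peptide count per protein, and a ground-truth table. Fragment intensity =
#' protein quantity x peptide weight x fragment weight x log-normal noise,
#' with weights drawn once per analyte and fixed across samples, which
#' reproduces the within-peptide fragment-profile correlation the
#' reliability filter assumes. Generation is a pure function of the
#' configuration (including its seed).
#'
#' @param config a \linkS4class{SimConfig} with \code{silac = FALSE}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{FragmentExperiment}), \code{truth} (data.table),
#'   \code{sequences} (named character vector) and \code{config}.
#' @examples
#' sim <- simulateExperiment(simConfig(nBackground = 20, nInteractors = 2,
#'                                     seed = 42))
#' sim$experiment
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    if (config@silac)
        .stopf("config has silac=TRUE; use simulateSilacExperiment()")
    withSeed(config@seed, .simulate(config))
}

#' Simulate a SILAC-labeled AP-MS experiment
#'
#' As \code{\link{simulateExperiment}} but every tagged-bait sample is split
#' into a light and a heavy channel sample (design column
#' \code{silac_channel}; sample ids suffixed \code{_L}/\code{_H}). Each
#' protein's expected intensity is divided between the channels by its
#' \code{lightFraction} before noise; a channel with zero expected signal is
#' entirely missing. Only tagged-bait purifications are generated (origin
#' ratios are computed on already-called interactors).
#'
#' @param config a \linkS4class{SimConfig} with \code{silac = TRUE}.
#' @return as \code{\link{simulateExperiment}}; the truth table carries the
#'   programmed \code{light_fraction}.
#' @export
simulateSilacExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    if (!config@silac)
        .stopf("config has silac=FALSE; set silac=TRUE for SILAC simulation")
    withSeed(config@seed, .simulate(config))
}

.simulate <- function(config) {
    roster <- .simRoster(config)
    nP <- nrow(roster)
    nI <- config@nInteractors
    nC <- config@nContaminants

    # -- per-protein truth ---------------------------------------------------
    pepRange <- as.integer(config@peptidesPerProtein)
    nPep <- sample(seq(pepRange[1], pepRange[2]), nP, replace = TRUE)
    # the bait dominates the eluate and is quantified with maximal sequence
    # coverage; give it the top of the configured peptide range
    nPep[1L] <- pepRange[2]
    occ <- rep(NA_real_, nP)
    fold <- rep(NA_real_, nP)
    kin <- matrix(1, nP, length(config@timePoints))
    if (nI) {
        ii <- which(roster$role == "interactor")
        occ[ii] <- rep(config@occupancy, length.out = nI)
        fold[ii] <- rep(config@interactorFold, length.out = nI)
        kinList <- if (length(config@kinetics))
            rep(config@kinetics, length.out = nI) else vector("list", nI)
        for (j in seq_len(nI))
            kin[ii[j], ] <- .evalKinetics(kinList[[j]], config@timePoints)
    }
    if (nC) {
        ci <- which(roster$role == "contaminant")
        occ[ci] <- 0.05
        fold[ci] <- rep(config@interactorFold, length.out = nC)
    }
    lightFrac <- rep(config@lightFraction, length.out = nP)

    # -- sequences: exactly nPep countable tryptic peptides ------------------
    pepLen <- lapply(nPep, function(n) sample(6:24, n, replace = TRUE))
    peptides <- lapply(pepLen, function(ls)
        vapply(ls, .randomPeptide, character(1)))
    sequences <- setNames(vapply(peptides, paste, character(1), collapse = ""),
                          roster$protein_id)

    # -- design --------------------------------------------------------------
    backgrounds <- if (config@silac) "tagged_bait" else .BACKGROUNDS
    design <- do.call(rbind, lapply(backgrounds, function(bg) {
        do.call(rbind, lapply(config@timePoints, function(tp) {
            data.frame(sample_id = sprintf("%s_t%s_r%d",
                                           if (bg == "tagged_bait") "bait"
                                           else "ctrl",
                                           format(tp, trim = TRUE,
                                                  scientific = FALSE),
                                           seq_len(config@nReplicates)),
                       background = bg, condition = config@condition,
                       time_min = tp, replicate = seq_len(config@nReplicates),
                       silac_channel = "none",
                       stringsAsFactors = FALSE)
        }))
    }))
    if (config@silac) {
        design <- design[rep(seq_len(nrow(design)), each = 2L), ]
        chan <- rep(c("light", "heavy"), length.out = nrow(design))
        design$silac_channel <- chan
        design$sample_id <- paste0(design$sample_id,
                                   ifelse(chan == "light", "_L", "_H"))
        rownames(design) <- NULL
    }
    nS <- nrow(design)

    # -- expected protein quantity per sample --------------------------------
    scaleFac <- nPep / nPep[1L]   # iBAQ-inverting peptide-count scaling
    tIdx <- match(design$time_min, config@timePoints)
    tagged <- design$background == "tagged_bait"
    A <- matrix(0, nP, nS, dimnames = list(roster$protein_id,
                                           design$sample_id))
    # non-specific background spans the wide dynamic range of an AP eluate
    # (log-uniform over ~3.5 orders of magnitude below/around the bait)
    bgAbund <- config@baitAbundance * 10^runif(nP, -3, 0.5)
    for (s in seq_len(nS)) {
        a <- numeric(nP)
        for (p in seq_len(nP)) {
            a[p] <- switch(roster$role[p],
                bait = config@baitAbundance *
                    (if (tagged[s]) 1 else 1 / config@baitFold),
                background = bgAbund[p],
                { # interactor or contaminant
                    peak <- config@baitAbundance * occ[p] * scaleFac[p]
                    if (tagged[s]) peak * kin[p, tIdx[s]] else peak / fold[p]
                })
        }
        A[, s] <- a
    }
    if (config@silac) {
        for (s in seq_len(nS)) {
            f <- if (design$silac_channel[s] == "light") lightFrac
                 else 1 - lightFrac
            A[, s] <- A[, s] * f
        }
    }

    # -- analyte table: one row per fragment ion -----------------------------
    fragRange <- as.integer(config@fragmentsPerPeptide)
    anaList <- vector("list", nP)
    for (p in seq_len(nP)) {
        peps <- peptides[[p]]
        # moderate spread: quantified peptides of one protein (and the top-N
        # fragments of one peptide) respond within a few-fold range
        w <- rlnorm(length(peps), 0, 0.3)
        w <- w / sum(w)
        role <- rep("none", length(peps))
        if (p == 1L && config@simulatePhospho && length(peps) >= 1L) {
            # split peptide 1 of the bait into unmodified + phospho forms;
            # the pair carries a small fixed share (2%) of the bait signal,
            # as a single site-bearing peptide does of a real bait digest
            w <- w / sum(w[-1L]) * 0.98
            w[1L] <- 0.02
            peps <- c(peps, paste0(peps[1L], "[ph]"))
            w <- c(w, w[1L])
            role <- c(role, "phospho")
            role[1L] <- "unmod"
        }
        pl <- vector("list", length(peps))
        for (k in seq_along(peps)) {
            nf <- sample(seq(fragRange[1], fragRange[2]), 1L)
            fw <- rlnorm(nf, 0, 0.3)
            fw <- fw / sum(fw)
            pl[[k]] <- data.table(protein_id = roster$protein_id[p],
                                  peptide_id = peps[k],
                                  fragment_id = sprintf("f%d", seq_len(nf)),
                                  pepW = w[k], fragW = fw, phosRole = role[k])
        }
        anaList[[p]] <- rbindlist(pl)
    }
    ana <- rbindlist(anaList)
    nA <- nrow(ana)

    # -- fragment intensities ------------------------------------------------
    ai <- rep(seq_len(nA), each = nS)
    si <- rep(seq_len(nS), times = nA)
    pidx <- match(ana$protein_id, roster$protein_id)[ai]
    mu <- A[pidx + (si - 1L) * nP] * ana$pepW[ai] * ana$fragW[ai]
    phi <- .phosphoFraction(config@timePoints)[tIdx[si]]
    pr <- ana$phosRole[ai]
    mu <- mu * ifelse(pr == "phospho", phi, ifelse(pr == "unmod", 1 - phi, 1))

    sigma <- sqrt(log(1 + config@cv^2))
    eps <- rlnorm(length(mu), -sigma^2 / 2, sigma)
    intensity <- mu * eps
    intensity[mu == 0] <- NA_real_

    if (config@missingRate > 0) {
        u <- runif(length(mu))
        if (config@missingMode == "uniform") {
            pMiss <- config@missingRate
        } else {
            # left-censored dropout: detection probability falls off
            # logistically (width one log2 unit) below a limit placed at the
            # missingRate quantile of expected intensities, so the overall
            # missing fraction is close to missingRate while intense signals
            # are essentially always detected
            pos <- mu[mu > 0]
            lim <- type7Quantile(pos, config@missingRate)
            pMiss <- stats::plogis(log2(lim / pmax(mu,
                                                   .Machine$double.xmin)))
            pMiss[mu == 0] <- 0   # structural absence already handled
        }
        intensity[u < pMiss] <- NA_real_
    }

    fragments <- data.table(protein_id = ana$protein_id[ai],
                            peptide_id = ana$peptide_id[ai],
                            fragment_id = ana$fragment_id[ai],
                            sample_id = design$sample_id[si],
                            intensity = intensity)
    setorder(fragments, protein_id, peptide_id, fragment_id, sample_id)

    kinStr <- apply(kin, 1L, function(v)
        paste(sprintf("%s=%.4g", format(config@timePoints, trim = TRUE), v),
              collapse = ";"))
    enriched <- roster$role %in% c("interactor", "contaminant")
    truth <- data.table(
        protein_id = roster$protein_id, role = roster$role,
        is_true_interactor = roster$role == "interactor",
        is_contaminant = roster$role == "contaminant",
        occupancy_fraction = occ, fold_enrichment = fold,
        kinetic_profile = ifelse(enriched, kinStr, NA_character_),
        is_dynamic_truth = roster$role == "interactor" &
            apply(kin, 1L, function(v) {
                # >= 2-fold change of any stimulated point vs baseline
                any(abs(log2(v[-1L] / max(v[1L], 1e-12))) >= 1)
            }),
        theoretical_peptide_count = nPep,
        light_fraction = if (config@silac) lightFrac else NA_real_)

    list(experiment = FragmentExperiment(fragments, design),
         truth = truth, sequences = sequences, config = config)
}
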