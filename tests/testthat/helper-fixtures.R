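# Shared in-code fixtures: tiny experiments built by hand so expected
# behaviour can be enumerated independently of the implementation.

# design with b backgrounds x t time points x r replicates
makeDesign <- function(times = c(0, 2), reps = 3,
                       backgrounds = c("tagged_bait", "untagged_control"),
                       condition = "stim") {
    d <- expand.grid(replicate = seq_len(reps), time_min = times,
                     background = backgrounds, stringsAsFactors = FALSE)
    d$condition <- condition
    d$silac_channel <- "none"
    d$sample_id <- sprintf("%s_t%s_r%d",
                           ifelse(d$background == "tagged_bait", "b", "c"),
                           format(d$time_min, trim = TRUE), d$replicate)
    d[, c("sample_id", "background", "condition", "time_min", "replicate",
          "silac_channel")]
}

# long fragment table from a named list: fragments[["prot|pep|frag"]] is a
# named intensity vector over sample ids (NA = missing)
makeFragments <- function(spec, design) {
    rows <- lapply(names(spec), function(key) {
        k <- strsplit(key, "|", fixed = TRUE)[[1]]
        v <- spec[[key]]
        data.frame(protein_id = k[1], peptide_id = k[2], fragment_id = k[3],
                   sample_id = names(v), intensity = as.numeric(v),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

fullVec <- function(design, value) {
    stats::setNames(rep(value, nrow(design)), design$sample_id)
}

# protein-level QuantMatrix straight from a matrix
makeProteinQm <- function(mat, design, scale = "raw") {
    QuantMatrix(mat, design, level = "protein", scaleType = scale)
}
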