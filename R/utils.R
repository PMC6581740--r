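# Internal helpers shared across modules.

.datatable.aware <- TRUE

#' Condition-group label for each design row
#'
#' A "condition group" throughout the pipeline is the triple
#' (background, condition, time_min): the replicate set over which detection
#' is counted and between which paired contrasts are formed.
#'
#' @param design sample design data.frame.
#' @return character vector of labels, one per design row, formatted as
#'   \code{"background:condition:time"}.
#' @export
groupLabel <- function(design) {
    paste(design$background, design$condition,
          format(design$time_min, trim = TRUE, scientific = FALSE),
          sep = ":")
}

# Evaluate `expr` under a locally seeded RNG, restoring global RNG state.
# All simulator randomness flows through this: one integer seed, no global
# side effects.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Linear-interpolation quantile (type 7), the convention fixed for all
# quantile-based rules (imputation, SILAC floor).
type7Quantile <- function(x, q) {
    unname(quantile(x, probs = q, type = 7, names = FALSE))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
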