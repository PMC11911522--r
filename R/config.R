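#' Run configuration
#'
#' A validated named list of every tunable the command-line workflow uses,
#' with lossless JSON (de)serialization. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults, by name.
#' @return a named list of class `"RunConfig"`.
#' @examples
#' cfg <- runConfig(seed = 7, k = 4)
#' cfg$tau
#' @export
runConfig <- function(...) {
    defaults <- list(
        seed = 1L, k = "auto", k_min = 2L, k_max = 8L, reps = 1L,
        n_init = 1000L, per_type = 100L, g_markers = 50L, tau = 1.0,
        tol_a = NA_real_, rmse_tol = 1e-4, min_frac = 0.05, max_frac = 1.0,
        threshold = 0.3, max_iter = 300L, use_log = FALSE)
    over <- list(...)
    if (length(over)) {
        unknown <- setdiff(names(over), names(defaults))
        if (length(unknown))
            stop("unknown RunConfig field(s): ",
                 paste(unknown, collapse = ", "))
        defaults[names(over)] <- over
    }
    if (!identical(defaults$k, "auto")) defaults$k <- as.integer(defaults$k)
    structure(defaults, class = "RunConfig")
}

#' Write a RunConfig to JSON
#'
#' @param config a [runConfig()] object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
    invisible(path)
}

#' Read a RunConfig from JSON
#'
#' @param path JSON file written by [writeRunConfig()] (or hand-authored;
#'   unknown keys are rejected).
#' @return a [runConfig()] object.
#' @export
readRunConfig <- function(path) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
    vals <- lapply(vals, function(v) if (is.null(v)) NA_real_ else v)
    ints <- c("seed", "k_min", "k_max", "reps", "n_init", "per_type",
              "g_markers", "max_iter")
    for (f in intersect(ints, names(vals))) vals[[f]] <- as.integer(vals[[f]])
    do.call(runConfig, vals)
}

# Translate a RunConfig into the deconvControl() list the pipeline takes.
configToControl <- function(cfg) {
    deconvControl(minFrac = cfg$min_frac, maxFrac = cfg$max_frac,
                  useLog = isTRUE(cfg$use_log), kMin = cfg$k_min,
                  kMax = cfg$k_max, reps = cfg$reps, nInit = cfg$n_init,
                  perType = cfg$per_type, gMarkers = cfg$g_markers,
                  tau = cfg$tau, rmseTol = cfg$rmse_tol,
                  maxIter = cfg$max_iter)
}
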