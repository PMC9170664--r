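#' Read an affect time series from CSV
#'
#' Expects columns \code{time}, \code{pa}, \code{na} and optionally
#' \code{day}. \code{time} may be ISO 8601 date-times (day labels are then
#' derived from the date, and times converted to hours since the first
#' midnight) or decimal hours, in which case a \code{day} column is
#' required. Empty \code{pa}/\code{na} cells mark missed beeps: the row is
#' kept in sequence and flagged invalid. Ratings are rescaled from the
#' instrument range onto the unit square.
#'
#' @param path CSV file.
#' @param instrument_min,instrument_max instrument scale limits (defaults
#'   0 and 100, percent sliders).
#' @return an \linkS4class{AffectTimeSeries}.
#' @export
readSeriesCSV <- function(path, instrument_min = 0, instrument_max = 100) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("time", "pa", "na")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
        stop("missing required columns: ",
             paste(missing_cols, collapse = ", "))
    if (is.character(df$time)) {
        stamp <- as.POSIXct(df$time, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%d %H:%M"))
        if (any(is.na(stamp)))
            stop("unparseable time stamps; use ISO 8601 or decimal hours")
        origin <- as.POSIXct(format(min(stamp), "%Y-%m-%d"), tz = "UTC")
        hours <- as.numeric(difftime(stamp, origin, units = "hours"))
        day <- if ("day" %in% names(df)) as.integer(df$day)
               else as.integer(floor(hours / 24))
    } else {
        hours <- as.numeric(df$time)
        if (!"day" %in% names(df))
            stop("decimal-hour time stamps require an explicit day column")
        day <- as.integer(df$day)
    }
    ord <- order(hours)
    if (anyDuplicated(hours))
        stop("duplicated time stamps")
    df <- df[ord, ]
    hours <- hours[ord]
    day <- day[ord]
    vals <- cbind(df$pa, df$na)
    bad <- which(!is.na(vals) &
                 (vals < instrument_min | vals > instrument_max),
                 arr.ind = TRUE)
    if (nrow(bad))
        stop("ratings outside the instrument range in rows: ",
             paste(sort(unique(bad[, 1])), collapse = ", "))
    scaled <- (vals - instrument_min) / (instrument_max - instrument_min)
    affectTimeSeries(hours, scaled, day = day)
}

#' Write an affect time series as CSV
#'
#' Inverse of \code{\link{readSeriesCSV}} with decimal-hour time stamps:
#' columns \code{time}, \code{pa}, \code{na}, \code{day}, with ratings
#' mapped back to the instrument scale and missed beeps as empty cells.
#'
#' @param series an \linkS4class{AffectTimeSeries}.
#' @param path output path.
#' @param instrument_min,instrument_max instrument scale limits.
#' @export
writeSeriesCSV <- function(series, path, instrument_min = 0,
                           instrument_max = 100) {
    span <- instrument_max - instrument_min
    df <- data.frame(time = series@time,
                     pa = instrument_min + series@values[, 1] * span,
                     na = instrument_min + series@values[, 2] * span,
                     day = series@day)
    df$pa[!series@valid] <- NA
    df$na[!series@valid] <- NA
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Write a fit result as JSON
#'
#' Stores the named parameters, model id, best negative log-likelihood,
#' the per-generation trace, the optimizer settings, the seed, and the
#' package version, for provenance and re-simulation.
#'
#' @param result a \linkS4class{FitResult}.
#' @param path output path.
#' @export
writeFitResult <- function(result, path) {
    de <- result@config$de
    rec <- list(
        model_id = result@config$model,
        parameters = as.list(paramVector(result@params)),
        nll = result@nll,
        trace = result@trace,
        evaluations = result@evaluations,
        config = list(NP = de$NP, CR = de$CR,
                      generations = de$generations,
                      mutation_weight = de$mutation_weight,
                      grid_n = result@config$likelihood$grid_n,
                      initial_mode = result@config$likelihood$initial_mode,
                      night_mode = result@config$likelihood$night_mode),
        seed = result@config$seed,
        package_version = as.character(utils::packageVersion("affectfp")))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a fit result written by \code{\link{writeFitResult}}
#'
#' @param path JSON file.
#' @return list with elements \code{params} (a
#'   \linkS4class{ModelParameters}), \code{nll}, \code{trace},
#'   \code{config}, \code{seed}.
#' @export
readFitResult <- function(path) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    v <- unlist(rec$parameters)
    params <- paramsFromVector(as.numeric(v),
                               if (rec$model_id == "aim") "aim" else "ou")
    list(params = params, nll = rec$nll, trace = rec$trace,
         config = rec$config, seed = rec$seed)
}

setMethod("show", "AffectTimeSeries", function(object) {
    cat(sprintf(
        "AffectTimeSeries: %d beeps over %d days, %d answered (%.0f%%)\n",
        length(object@time), length(unique(object@day)),
        sum(object@valid), 100 * mean(object@valid)))
})
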