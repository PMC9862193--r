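# Readers and writers for the delimited interchange formats, plus run
# manifests. All tables are plain CSV so runs are diff-able and portable.

#' Write an observation bundle to tidy CSV
#'
#' Single file with columns `table` (concentration/flux/enrichment),
#' `series` (species or reaction), `time_s`, `value`, `sd`, `unit`.
#' Round-trip stable with [read_bundle()].
#' @param bundle an `observation_bundle`
#' @param path output file
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "observation_bundle"))
  part <- function(df, tab, key, unit) {
    if (!nrow(df)) return(NULL)
    data.frame(table = tab, series = df[[key]], time_s = df$time_s,
               value = df$value, sd = df$sd, unit = unit,
               stringsAsFactors = FALSE)
  }
  out <- rbind(part(bundle$concentrations, "concentration", "species", "mM"),
               part(bundle$fluxes, "flux", "reaction", "mM/s"),
               part(bundle$enrichment, "enrichment", "species", "percent"))
  out$value <- sprintf("%.17g", out$value)
  out$sd <- sprintf("%.17g", out$sd)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation bundle from tidy CSV
#'
#' Accepts rows in any order (the bundle canonicalizes ordering). A missing
#' `sd` column gets a 10%-of-value default with a warning; malformed rows
#' are reported with their row number.
#' @param path CSV file from [write_bundle()]
#' @param provenance provenance tag to attach
#' @param cycle_length cycle length (s)
#' @return an `observation_bundle`
#' @export
read_bundle <- function(path, provenance = "synthetic", cycle_length = 400) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("table", "series", "time_s", "value")
  if (!all(need %in% names(df)))
    stop("bundle file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$sd)) {
    warning("no sd column; defaulting to 10% of |value|")
    df$sd <- abs(df$value) * 0.1 + 1e-6
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value) | !is.finite(df$sd))
  if (length(bad))
    stop("malformed bundle rows: ", paste(head(bad, 5) + 1L, collapse = ", "))
  pick <- function(tab, key) {
    d <- df[df$table == tab, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    setNames(d[, c("series", "time_s", "value", "sd")],
             c(key, "time_s", "value", "sd"))
  }
  observation_bundle(pick("concentration", "species"),
                     pick("flux", "reaction"),
                     pick("enrichment", "species"),
                     provenance = provenance, cycle_length = cycle_length)
}

#' Write a trajectory as tidy CSV
#' @param traj an `ff_trajectory`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$value <- sprintf("%.17g", df$value)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest next to command outputs
#'
#' Records the effective configuration, seed, package and R versions, and a
#' timestamp, so any output directory is re-runnable.
#' @param dir output directory
#' @param command subcommand name
#' @param config named list of effective options
#' @param seed RNG seed used
#' @export
write_manifest <- function(dir, command, config, seed) {
  obj <- list(command = command, config = config, seed = seed,
              package = as.character(utils::packageVersion("feastfamine")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(obj)
}
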