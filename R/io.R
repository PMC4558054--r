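# Readers and writers for the pipeline's CSV interchange formats, plus the
# run manifest that stamps every artifact with its seed and input hashes.

check_columns <- function(tab, need, what) {
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' Read / write measurement tables
#'
#' CSV with columns `culture`, `output`, `time_h`, `value`, `sd` (optional
#' `censored`). Writing formats numerics at full double precision so a
#' write-read round trip is exact.
#'
#' @param path CSV path.
#' @return Measurement data frame.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("culture", "output", "time_h", "value", "sd"),
                "measurement table")
  if (is.null(tab$censored)) tab$censored <- logical(nrow(tab))
  tab$time_h <- as.numeric(tab$time_h)
  tab$value <- as.numeric(tab$value)
  tab$sd <- as.numeric(tab$sd)
  tab
}

#' @rdname read_measurements
#' @param measurements Measurement data frame to write.
#' @export
write_measurements <- function(measurements, path) {
  check_columns(measurements, c("culture", "output", "time_h", "value", "sd"),
                "measurement table")
  write_table(measurements, path)
}

#' Read / write viability tables
#'
#' CSV with columns `culture`, `time_h`, `viability_pct`.
#'
#' @param path CSV path.
#' @return Viability data frame.
#' @export
read_viability <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("culture", "time_h", "viability_pct"),
                "viability table")
  tab$time_h <- as.numeric(tab$time_h)
  tab$viability_pct <- as.numeric(tab$viability_pct)
  tab
}

#' @rdname read_viability
#' @param viability Viability data frame to write.
#' @export
write_viability <- function(viability, path) {
  check_columns(viability, c("culture", "time_h", "viability_pct"),
                "viability table")
  write_table(viability, path)
}

#' Write a table at full double precision
#'
#' CSV writer whose numeric columns survive a write-read round trip exactly
#' (17 significant digits).
#'
#' @param table Data frame.
#' @param path Output path.
#' @export
write_table <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         sprintf("%.17g", out[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Convert a trajectory to tidy long format
#'
#' @param trajectory `SimulationTrajectory`.
#' @param what `"states"`, `"fluxes"` or both.
#' @return Data frame: `time`, `variable`, `value`.
#' @export
trajectory_to_long <- function(trajectory, what = c("states", "fluxes")) {
  what <- match.arg(what, several.ok = TRUE)
  out <- list()
  for (w in what) {
    m <- trajectory[[w]]
    out[[w]] <- data.frame(
      time = rep(trajectory$times, ncol(m)),
      variable = rep(colnames(m), each = nrow(m)),
      value = as.vector(m))
  }
  do.call(rbind, out)
}

#' Write a run manifest
#'
#' Records the seed, the md5 of every input file, package and R versions and
#' a timestamp next to a run's outputs, so identical manifests imply
#' identical artifacts.
#'
#' @param path Output YAML path.
#' @param seed Integer seed used by the run.
#' @param inputs Character vector of input file paths to hash.
#' @param extra Optional named list merged into the manifest.
#' @export
write_manifest <- function(path, seed, inputs = character(), extra = list()) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs)
    stats::setNames(as.list(unname(h)), basename(inputs))
  } else list()
  manifest <- c(list(seed = as.integer(seed),
                     package = "choflux",
                     package_version = as.character(
                       utils::packageVersion("choflux")),
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     inputs = hashes),
                extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
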