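#' Write a cohort to delimited files
#'
#' Writes four CSV tables — `encounters.csv` (demographics, ISO-8601
#' admission/discharge timestamps), `segments.csv` (care-location
#' segments), `observations.csv` (labs/vitals/coma events) and
#' `medications.csv` (administrations with start/end) — plus
#' `manifest.yaml` recording the seed, the generating configuration and
#' MD5 digests of every file. Event times are absolute ISO-8601 UTC
#' timestamps derived from the admission time. The latent severity trace
#' is written only if `include_latent = TRUE` (it exists for oracle checks
#' and is never a model input).
#'
#' @param cohort A `ci_cohort`.
#' @param dir Output directory (created if needed).
#' @param include_latent Also write `latent.csv`?
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir, include_latent = FALSE) {
  stopifnot(inherits(cohort, "ci_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  enc <- cohort$encounters
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  abs_time <- function(ids, hrs)
    iso(enc$admit_time[match(ids, enc$encounter_id)] + round(hrs * 3600))
  out <- data.table::copy(enc)
  out[, `:=`(admit_time = iso(admit_time), discharge_time = iso(discharge_time))]
  data.table::fwrite(out, file.path(dir, "encounters.csv"))
  seg <- cohort$segments[, .(encounter_id, location,
                             start_time = abs_time(encounter_id, start_hr),
                             end_time = abs_time(encounter_id, end_hr))]
  data.table::fwrite(seg, file.path(dir, "segments.csv"))
  ev <- cohort$events[, .(encounter_id, timestamp = abs_time(encounter_id, time_hr),
                          kind, variable_id, value)]
  data.table::fwrite(ev, file.path(dir, "observations.csv"))
  md <- cohort$medications[, .(encounter_id, class_id,
                               start_time = abs_time(encounter_id, start_hr),
                               end_time = abs_time(encounter_id, end_hr))]
  data.table::fwrite(md, file.path(dir, "medications.csv"))
  files <- c("encounters.csv", "segments.csv", "observations.csv", "medications.csv")
  if (include_latent) {
    data.table::fwrite(cohort$latent, file.path(dir, "latent.csv"))
    files <- c(files, "latent.csv")
  }
  manifest <- list(
    seed = cohort$seed,
    n_admissions = cohort$config$n_admissions,
    generated_by = paste("cidyn", utils::packageVersion("cidyn")),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' Reconstructs the internal representation (times as hours since
#' admission). The configuration is not round-tripped; supply it if
#' downstream steps need panels.
#'
#' @param dir Directory containing the cohort files.
#' @param config Optional `ci_cohort_config` to attach.
#' @return A `ci_cohort` (without latent trace unless `latent.csv` exists).
#' @export
read_cohort <- function(dir, config = NULL) {
  parse_iso <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  enc <- data.table::fread(file.path(dir, "encounters.csv"))
  enc[, `:=`(admit_time = parse_iso(admit_time),
             discharge_time = parse_iso(discharge_time))]
  rel_time <- function(ids, ts)
    as.numeric(difftime(parse_iso(ts), enc$admit_time[match(ids, enc$encounter_id)],
                        units = "hours"))
  seg <- data.table::fread(file.path(dir, "segments.csv"))
  seg <- seg[, .(encounter_id, location,
                 start_hr = rel_time(encounter_id, start_time),
                 end_hr = rel_time(encounter_id, end_time))]
  ev <- data.table::fread(file.path(dir, "observations.csv"))
  ev <- ev[, .(encounter_id, time_hr = rel_time(encounter_id, timestamp),
               kind, variable_id, value)]
  md <- data.table::fread(file.path(dir, "medications.csv"))
  md <- md[, .(encounter_id, class_id,
               start_hr = rel_time(encounter_id, start_time),
               end_hr = rel_time(encounter_id, end_time))]
  latent_path <- file.path(dir, "latent.csv")
  latent <- if (file.exists(latent_path)) data.table::fread(latent_path)
  else data.table::data.table(encounter_id = integer(), hour = integer(),
                              severity = numeric(), location = character())
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  structure(list(encounters = enc, segments = seg, events = ev,
                 medications = md, latent = latent,
                 config = config, seed = man$seed),
            class = "ci_cohort")
}
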