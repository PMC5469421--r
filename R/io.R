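#' Read and write single-measurement spectra files
#'
#' The on-disk layout is one CSV per measurement: column `wavelength_nm`
#' followed by the six channel columns `BF1,BF2,BF3,BF1per,BF2per,BF3per`.
#' Both LF and CRLF line endings are accepted on read.
#'
#' @param spectra One measurement's spectra (tibble `wavelength_nm` + six
#'   channels; a `measurement_id` column is dropped on write).
#' @param path File path.
#' @return `read_measurement()` returns the spectra tibble;
#'   `write_measurement()` returns `path` invisibly.
#' @export
write_measurement <- function(spectra, path) {
  cols <- c("wavelength_nm", channel_names())
  missing <- setdiff(cols, names(spectra))
  if (length(missing) > 0) {
    abort(paste0("missing channel column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_csv(spectra[cols], path)
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("wavelength_nm", channel_names()), names(df))
  if (length(missing) > 0) {
    abort(paste0("missing channel column(s): ", paste(missing, collapse = ", ")))
  }
  if (is.unsorted(df$wavelength_nm, strictly = TRUE)) {
    abort("wavelengths must be strictly ascending")
  }
  as_tibble(df[c("wavelength_nm", channel_names())])
}

#' Write a cohort to a directory
#'
#' Writes `manifest.csv`, one spectra CSV per measurement under `spectra/`,
#' per-session calibration CSVs (`<id>_white.csv`, `<id>_dark.csv`) under
#' `calibrations/` plus a JSON sidecar with integration time and per-channel
#' throughput `P` and collection area `A`.
#'
#' @param cohort An `oprs_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "calibrations"), showWarnings = FALSE)
  manifest <- mutate(
    cohort$manifest,
    spectra_path = file.path("spectra", paste0(.data$measurement_id, ".csv"))
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  for (id in manifest$measurement_id) {
    write_measurement(
      filter(cohort$spectra, .data$measurement_id == id),
      file.path(dir, "spectra", paste0(id, ".csv"))
    )
  }
  for (cid in unique(cohort$calibrations$calibration_id)) {
    cal <- filter(cohort$calibrations, .data$calibration_id == cid)
    for (role in c("white", "dark")) {
      write_measurement(
        filter(cal, .data$role == !!role),
        file.path(dir, "calibrations", paste0(cid, "_", role, ".csv"))
      )
    }
  }
  sidecar <- list(
    t_seconds = unique(cohort$manifest$t_seconds),
    P = setNames(as.list(cohort$probe$P), cohort$probe$channel),
    A = setNames(as.list(cohort$probe$A), cohort$probe$channel),
    depth90_um = setNames(as.list(cohort$probe$depth90_um), cohort$probe$channel),
    seed = cohort$seed
  )
  jsonlite::write_json(sidecar, file.path(dir, "calibrations", "probe.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with `manifest`, `spectra`, `calibrations`, `probe`.
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  spectra <- bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
    df <- read_measurement(file.path(dir, manifest$spectra_path[i]))
    mutate(df, measurement_id = manifest$measurement_id[i], .before = 1)
  }))
  cal_files <- list.files(file.path(dir, "calibrations"),
    pattern = "_(white|dark)\\.csv$"
  )
  calibrations <- bind_rows(lapply(cal_files, function(f) {
    parts <- regmatches(f, regexec("^(.*)_(white|dark)\\.csv$", f))[[1]]
    df <- read_measurement(file.path(dir, "calibrations", f))
    mutate(df, calibration_id = parts[2], role = parts[3], .before = 1)
  }))
  sidecar <- jsonlite::read_json(
    file.path(dir, "calibrations", "probe.json"),
    simplifyVector = TRUE
  )
  probe <- default_probe(
    depth90_um = unlist(sidecar$depth90_um),
    P = unlist(sidecar$P), A = unlist(sidecar$A)
  )
  list(
    manifest = manifest, spectra = spectra, calibrations = calibrations,
    probe = probe
  )
}

#' Serialize / restore a task configuration
#'
#' Written alongside analysis outputs so a run can be reproduced exactly.
#'
#' @param config A [task_config()].
#' @param path JSON file path.
#' @return `read_task_config()` returns the restored `oprs_task_config`.
#' @export
write_task_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(task_config, x[!vapply(x, is.null, logical(1))])
}
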