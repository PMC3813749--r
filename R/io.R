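#' Write a source waveform as CSV
#'
#' Two-column CSV with header `time_s,amplitude`; optionally a JSON
#' metadata sidecar with the sampling rate and normalization flag.
#'
#' @param wf A `source_waveform` (or list with `t`, `y`).
#' @param path Output CSV path.
#' @param meta_path Optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path, meta_path = NULL) {
  utils::write.csv(data.frame(time_s = wf$t, amplitude = wf$y), path,
                   row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(fs_hz = wf$fs, normalized = isTRUE(wf$normalized),
                 n_samples = length(wf$y))
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a source waveform CSV
#'
#' @param path CSV with columns `time_s`, `amplitude`.
#' @return A `source_waveform`; the sampling rate is inferred from the
#'   median time step.
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(d)))
    stop("waveform CSV must have columns time_s, amplitude")
  fs <- if (nrow(d) > 1) 1 / stats::median(diff(d$time_s)) else NA_real_
  structure(list(t = d$time_s, y = d$amplitude, fs = fs,
                 normalized = NA), class = "source_waveform")
}

#' Write model parameters to YAML or JSON
#'
#' @param params Named numeric vector or list of natural-scale parameters.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  params <- as.list(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(params, path)
  else if (ext == "json")
    jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported extension: ", ext)
  invisible(path)
}

#' Read model parameters from YAML or JSON
#'
#' @param path Input path (`.yaml`/`.yml` or `.json`).
#' @return Named numeric vector.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported extension: ", ext)
  unlist(lst)
}

#' Write a posterior report as JSON
#'
#' Structured report of an [em_gauss_newton()] fit: latent means and
#' standard deviations, natural-scale values, free energy, noise variance,
#' iteration count, and the nonzero decision for every shrinkage-prior
#' connection.
#'
#' @param posterior An `nmm_posterior`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "nmm_posterior"))
  sq <- posterior$priors$name[posterior$priors$class == "sq"]
  nz <- lapply(sq, function(nm) connection_nonzero(posterior, nm))
  names(nz) <- sq
  rep <- list(eta = as.list(posterior$eta), sd = as.list(posterior$sd),
              natural = as.list(posterior$natural), F = posterior$F,
              sigma2 = posterior$sigma2, n_iter = posterior$n_iter,
              converged = posterior$converged, nonzero = nz)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
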