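#' Write a TRES dataset as delimited text
#'
#' Tab-separated matrix: first row is the wavelength grid (nm) with an
#' empty leading cell, first column the channel time (ns). A JSON sidecar
#' (`<path>.json`) carries the metadata.
#'
#' @param data A `tres` dataset.
#' @param path Output path (e.g. `tres.tsv`).
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_tres <- function(data, path, sidecar = TRUE) {
  stopifnot(inherits(data, "tres"))
  m <- cbind(data$axis$edges_ns, data$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time_ns", data$wavelengths_nm), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  if (sidecar && length(data$metadata))
    jsonlite::write_json(data$metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a TRES dataset written by [write_tres()] (or any delimited matrix
#' with the same axis headers)
#'
#' @param path Input path.
#' @return A `tres` dataset. Metadata is restored from the JSON sidecar
#'   when present.
#' @export
read_tres <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  wl <- as.numeric(hdr[-1])
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  t_ns <- m[, 1]
  counts <- unname(m[, -1, drop = FALSE])
  n <- length(t_ns)
  dt <- if (n > 1) t_ns[2] - t_ns[1] else 1
  axis <- time_axis(n, dt * n)
  meta <- list()
  sc <- paste0(path, ".json")
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  tres_dataset(counts, axis, wl, meta)
}

#' Write decay-associated spectra as CSV
#'
#' One row per wavelength; one column per component, headers carrying the
#' lifetimes in ns.
#'
#' @param fit A `das_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_das <- function(fit, path) {
  stopifnot(inherits(fit, "das_fit"))
  df <- data.frame(wavelength_nm = fit$wavelengths_nm, t(fit$das))
  names(df)[-1] <- paste0("tau_", signif(fit$lifetimes_ns, 6), "_ns")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a global-fit report as JSON
#'
#' @param fit A `das_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "das_fit"))
  jsonlite::write_json(list(
    lifetimes_ns = fit$lifetimes_ns,
    t0_ns = fit$t0_ns,
    chi2_reduced = fit$chi2_reduced,
    n_components = fit$n_components,
    converged = fit$converged,
    iterations = fit$iterations,
    wavelength_range_nm = range(fit$wavelengths_nm)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
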