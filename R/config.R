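#' Default pipeline configuration
#'
#' Builds the nested configuration list consumed by [detect_s34()] and the
#' lower-level stage functions. Every tunable of the pipeline has a named
#' default here; pass overrides either as nested lists (`lowpass =
#' list(cutoff_hz = 500)`) or load them from a YAML/JSON file with
#' [read_config()].
#'
#' Keys (units in the name where applicable):
#' \describe{
#'   \item{lowpass}{`cutoff_hz` (600), `order` (6). Zero-phase Butterworth
#'     low-pass; heart-sound energy lies almost entirely below 600 Hz.}
#'   \item{se}{`smooth_ms` (20). Moving-average window applied to the
#'     Shannon energy before peak picking; must stay well below
#'     `seg$merge_ms` so it cannot fuse distinct sounds.}
#'   \item{seg}{`threshold_frac` (0.70) primary peak threshold as a fraction
#'     of the Shannon-energy maximum; `secondary_frac` (0.50) threshold used
#'     inside uncertain intervals; `merge_ms` (50) minimum peak spacing;
#'     `tie_tol` (0.10) relative difference under which neighbouring
#'     intervals are deemed ambiguous; `gap_factor` (1.5) multiples of the
#'     median inter-peak interval above which an interval is flagged
#'     uncertain (likely missed peak).}
#'   \item{emd}{`sd_tol` (0.2) Cauchy-type sifting stop criterion;
#'     `max_sifts` (100); `max_imfs` (12); `boundary_extrema` (2) extrema
#'     mirrored at each end for the spline envelopes.}
#'   \item{hht}{`ridge` ("max_amplitude"): per-sample component selection
#'     rule; "max_frequency" is available for comparison.}
#'   \item{detect}{`s3_window_ms` (80, 250) latency window after S2 for S3;
#'     `s4_window_ms` (40, 200) lead window before the next S1 for S4;
#'     `gap_ms` (60) merge gap for abnormal-point runs; `latency_tol_ms`
#'     (50) periodicity tolerance; `presence_frac` (0.5) fraction of cycles
#'     required to call a sound present in the record; `recover_frac` (0.6)
#'     magnitude fraction (of the median detected magnitude) required to
#'     recover a missed event; `decimate` (8) stride for diastolic ridge
#'     sampling (1 ms at 8000 Hz); `trim_after_s2_ms` (70) and
#'     `trim_before_s1_ms` (60) margins that keep the S2/S1 burst skirts out
#'     of the clustered point set.}
#'   \item{kmeans}{`restarts` (10) random restarts of the k-means step.}
#' }
#'
#' @param ... nested overrides, e.g. `detect = list(gap_ms = 80)`.
#' @return A nested list of class `"hs_config"`.
#' @seealso [read_config()], [detect_s34()]
#' @export
#' @examples
#' cfg <- hs_config(lowpass = list(cutoff_hz = 500))
#' cfg$lowpass$cutoff_hz
hs_config <- function(...) {
  cfg <- list(
    lowpass = list(cutoff_hz = 600, order = 6L),
    se      = list(smooth_ms = 20),
    seg     = list(threshold_frac = 0.70, secondary_frac = 0.50,
                   merge_ms = 50, tie_tol = 0.10, gap_factor = 1.5),
    emd     = list(sd_tol = 0.2, max_sifts = 100L, max_imfs = 12L,
                   boundary_extrema = 2L),
    hht     = list(ridge = "max_amplitude"),
    detect  = list(s3_window_ms = c(80, 250), s4_window_ms = c(40, 200),
                   gap_ms = 60, latency_tol_ms = 50, presence_frac = 0.5,
                   recover_frac = 0.6, decimate = 8L,
                   trim_after_s2_ms = 70, trim_before_s1_ms = 60),
    kmeans  = list(restarts = 10L)
  )
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "hs_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values in the file override the defaults of [hs_config()]; keys absent
#' from the file keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file with the nested key
#'   structure of [hs_config()].
#' @return An `"hs_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  structure(merge_config(unclass(hs_config()), raw), class = "hs_config")
}

# recursive modifyList that keeps vectors (e.g. window pairs) atomic
merge_config <- function(base, new) {
  if (length(new) == 0) return(base)
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' @export
print.hs_config <- function(x, ...) {
  cat("Heart-sound detection configuration\n")
  for (sec in names(x)) {
    vals <- vapply(x[[sec]], function(v) paste(format(v), collapse = ","),
                   character(1))
    cat(sprintf("  %-7s %s\n", sec,
                paste(names(vals), vals, sep = "=", collapse = "  ")))
  }
  invisible(x)
}
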