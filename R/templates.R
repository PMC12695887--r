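#' Spectral component of a photoacoustic emitter
#'
#' One damped sinusoid in the time-domain model of a photoacoustic (PA)
#' trace. A rendered component contributes
#' `amplitude * exp(-(t - tau)/damping_time) * sin(2*pi*frequency*(t - tau) + phase)`
#' for `t >= tau`, where `tau` is the acoustic travel delay set by the
#' acquisition geometry.
#'
#' @param frequency Oscillation frequency in Hz (positive).
#' @param amplitude Peak amplitude in mV (non-negative).
#' @param damping_time Exponential decay constant in seconds (positive).
#' @param phase Phase offset in radians, wrapped into `[0, 2*pi)`.
#'
#' @return An object of class `pa_component`.
#' @seealso [species_template()], [generate_signal()]
#' @export
spectral_component <- function(frequency, amplitude, damping_time, phase = 0) {
  if (!is_scalar_num(frequency) || frequency <= 0)
    stop_pa("component frequency must be a positive number (Hz)")
  if (!is_scalar_num(amplitude) || amplitude < 0)
    stop_pa("component amplitude must be non-negative (mV)")
  if (!is_scalar_num(damping_time) || damping_time <= 0)
    stop_pa("component damping_time must be positive (s)")
  if (!is_scalar_num(phase))
    stop_pa("component phase must be a finite number (rad)")
  structure(
    list(frequency = frequency, amplitude = amplitude,
         damping_time = damping_time, phase = phase %% (2 * pi)),
    class = "pa_component"
  )
}

#' Parametric spectral template for one class of emitter
#'
#' A template is an ordered set of [spectral_component()]s plus the
#' measurement-to-measurement variability of the class. The component with
#' the largest amplitude is the dominant one; red-blood-cell templates keep
#' it near 4 MHz, the feature all species share. `variability_scale`
#' multiplies both jitters and is `> 1` for whole-blood templates, whose
#' complex matrix makes repeated measurements spread more.
#'
#' @param name Class label (non-empty string).
#' @param components List of [spectral_component()]s, at least one; exactly
#'   one component must carry the maximal amplitude.
#' @param amplitude_jitter Relative standard deviation of per-measurement
#'   amplitude scatter (dimensionless, >= 0).
#' @param frequency_jitter Relative standard deviation of per-measurement
#'   frequency scatter (dimensionless, >= 0).
#' @param variability_scale Multiplier (>= 1) applied to both jitters.
#'
#' @return An object of class `pa_template`.
#' @export
species_template <- function(name, components, amplitude_jitter = 0.05,
                             frequency_jitter = 0.002,
                             variability_scale = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_pa("template name must be a non-empty string")
  if (!is.list(components) || length(components) < 1L)
    stop_pa("template needs at least one spectral component")
  ok <- vapply(components, inherits, logical(1), what = "pa_component")
  if (!all(ok)) stop_pa("all components must be built by spectral_component()")
  amps <- vapply(components, `[[`, numeric(1), "amplitude")
  # a unique dominant component, except for the degenerate all-silent case
  if (max(amps) > 0 && sum(amps == max(amps)) != 1L)
    stop_pa("template '%s' must have exactly one largest-amplitude component",
            name)
  if (!is_scalar_num(amplitude_jitter) || amplitude_jitter < 0)
    stop_pa("amplitude_jitter must be >= 0")
  if (!is_scalar_num(frequency_jitter) || frequency_jitter < 0)
    stop_pa("frequency_jitter must be >= 0")
  if (!is_scalar_num(variability_scale) || variability_scale < 1)
    stop_pa("variability_scale must be >= 1")
  structure(
    list(name = name, components = components,
         amplitude_jitter = amplitude_jitter,
         frequency_jitter = frequency_jitter,
         variability_scale = variability_scale),
    class = "pa_template"
  )
}

#' Dominant component of a template
#'
#' @param template A [species_template()].
#' @return The `pa_component` with the largest amplitude.
#' @export
dominant_component <- function(template) {
  stopifnot(inherits(template, "pa_template"))
  amps <- vapply(template$components, `[[`, numeric(1), "amplitude")
  template$components[[which.max(amps)]]
}

#' @export
print.pa_template <- function(x, ...) {
  dom <- dominant_component(x)
  cat(sprintf(
    "<pa_template> %s: %d component(s), dominant %.3g MHz, variability x%g\n",
    x$name, length(x$components), dom$frequency / 1e6, x$variability_scale))
  invisible(x)
}

# Component shorthand used by the default inventories: freq in MHz,
# amplitude in mV, damping in microseconds.
comp_mhz <- function(f_mhz, amp, damp_us, phase = 0) {
  spectral_component(f_mhz * 1e6, amp, damp_us * 1e-6, phase)
}

#' Built-in template inventories
#'
#' The template sets behind the package's synthetic studies. All
#' red-blood-cell (RBC) and whole-blood templates share a dominant peak in
#' the 3.5--4.5 MHz band (sheep at 3.9 MHz), differing only in small
#' dominant-frequency offsets and weaker secondary components, so the five
#' spectra look alike and classification must exploit subtle structure.
#' Whole-blood templates reuse the RBC frequency layout of the shared
#' species but with `variability_scale = 3`, emulating the larger
#' measurement-to-measurement deviations of a complex blood matrix. The
#' four gold-nanoparticle (AuNP) geometries instead have strongly distinct
#' fingerprints (pairwise cosine similarity of noiseless spectra < 0.95).
#'
#' @param kind One of `"rbc_species"` (pig, sheep, turkey, goat, llama),
#'   `"whole_blood"` (pig, sheep, turkey, goat, horse) or
#'   `"aunp_geometry"` (nanosphere, nanorod, nanocube, nanoshell).
#'
#' @return A named list of [species_template()]s (5, 5 or 4 entries).
#' @export
#' @examples
#' tpl <- default_templates("rbc_species")
#' dominant_component(tpl$sheep)$frequency / 1e6 # 3.9 MHz
default_templates <- function(kind = c("rbc_species", "whole_blood",
                                       "aunp_geometry")) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("rbc_species", "whole_blood", "aunp_geometry"))
    stop_pa(paste0(
      "unsupported template inventory '%s'; valid kinds: rbc_species, ",
      "whole_blood, aunp_geometry"), as.character(kind)[1])

  # Washed red blood cells: a nearly common dominant peak (class offsets
  # comparable to the per-measurement frequency jitter) and weak
  # species-specific secondary components, so raw spectra of the five
  # species look alike and intermingle under PCA while remaining
  # machine-separable.
  rbc_layout <- list(
    pig    = list(c(3.95, 1.00, 5), c(5.65, 0.16, 3), c(2.32, 0.12, 4)),
    sheep  = list(c(3.90, 1.00, 5), c(5.80, 0.14, 3), c(2.05, 0.14, 4)),
    turkey = list(c(3.98, 1.00, 5), c(5.95, 0.18, 3), c(2.50, 0.10, 4)),
    goat   = list(c(3.93, 1.00, 5), c(5.50, 0.12, 3), c(2.20, 0.15, 4)),
    llama  = list(c(4.01, 1.00, 5), c(6.10, 0.15, 3), c(1.90, 0.11, 4))
  )
  # Whole blood: somewhat wider characteristic differences between
  # species (the matrix shapes the fingerprint) but three-fold larger
  # measurement-to-measurement variability.
  wb_layout <- list(
    pig    = list(c(3.98, 1.00, 5), c(5.60, 0.22, 3), c(2.30, 0.15, 4)),
    sheep  = list(c(3.90, 1.00, 5), c(5.85, 0.18, 3), c(1.95, 0.18, 4)),
    turkey = list(c(4.06, 1.00, 5), c(6.10, 0.24, 3), c(2.55, 0.12, 4)),
    goat   = list(c(3.94, 1.00, 5), c(5.40, 0.16, 3), c(2.15, 0.20, 4)),
    horse  = list(c(4.02, 1.00, 5), c(5.95, 0.20, 3), c(2.70, 0.16, 4))
  )
  build <- function(name, rows, aj, fj, vs) {
    comps <- lapply(rows, function(r) comp_mhz(r[1], r[2], r[3]))
    species_template(name, comps, amplitude_jitter = aj,
                     frequency_jitter = fj, variability_scale = vs)
  }

  if (kind == "rbc_species") {
    species <- c("pig", "sheep", "turkey", "goat", "llama")
    out <- lapply(species, function(s)
      build(s, rbc_layout[[s]], aj = 0.10, fj = 0.004, vs = 1))
  } else if (kind == "whole_blood") {
    species <- c("pig", "sheep", "turkey", "goat", "horse")
    out <- lapply(species, function(s)
      build(s, wb_layout[[s]], aj = 0.05, fj = 0.004, vs = 3))
  } else {
    layout <- list(
      nanosphere = list(c(2.60, 1.00, 2.0), c(6.00, 0.50, 1.5)),
      nanorod    = list(c(3.40, 1.00, 3.0), c(9.20, 0.70, 1.0)),
      nanocube   = list(c(5.20, 1.00, 2.5), c(7.60, 0.60, 2.0)),
      nanoshell  = list(c(1.70, 1.00, 4.0), c(4.80, 0.40, 2.0))
    )
    species <- names(layout)
    out <- lapply(species, function(s)
      build(s, layout[[s]], aj = 0.03, fj = 0.005, vs = 1))
  }
  names(out) <- species
  out
}

#' Serialize template sets to and from YAML or JSON
#'
#' @param templates Named list of [species_template()]s.
#' @param path Output (or input) file; extension `.yaml`/`.yml` or `.json`.
#' @return `write_templates()` returns `path` invisibly; `read_templates()`
#'   returns a named list of templates.
#' @export
write_templates <- function(templates, path) {
  stopifnot(is.list(templates))
  rec <- lapply(templates, function(tp) {
    stopifnot(inherits(tp, "pa_template"))
    list(
      name = tp$name,
      amplitude_jitter = tp$amplitude_jitter,
      frequency_jitter = tp$frequency_jitter,
      variability_scale = tp$variability_scale,
      components = lapply(tp$components, function(cc)
        list(frequency_hz = cc$frequency, amplitude_mv = cc$amplitude,
             damping_time_s = cc$damping_time, phase_rad = cc$phase))
    )
  })
  names(rec) <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  out <- lapply(rec, function(tp) {
    comps <- lapply(tp$components, function(cc)
      spectral_component(cc$frequency_hz, cc$amplitude_mv,
                         cc$damping_time_s, cc$phase_rad))
    species_template(tp$name, comps,
                     amplitude_jitter = tp$amplitude_jitter,
                     frequency_jitter = tp$frequency_jitter,
                     variability_scale = tp$variability_scale)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
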