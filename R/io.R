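## Serialization: spin systems to YAML, curves/scans to CSV with JSON
## provenance sidecars. Key names carry units (ppm, Hz, Angstrom, s).

#' Write a spin system to a YAML file
#'
#' The file is a complete, lossless description (isotopes, labels, shift
#' tensors in ppm, J couplings in Hz, dipolar couplings in Hz with unit
#' axes and motional scales, coordinates in Angstrom if present) and can be
#' read back with [read_spin_system()].
#'
#' @param sys A [spin_system()].
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_spin_system <- function(sys, file) {
  obj <- list(
    name = sys$name,
    spins = lapply(seq_len(n_spins(sys)), function(i) {
      s <- list(index = i, isotope = sys$isotope[i], label = sys$label[i],
                iso_ppm = sys$shift$iso_ppm[i])
      if (sys$shift$aniso_ppm[i] != 0) {
        s$aniso_ppm <- sys$shift$aniso_ppm[i]
        s$eta <- sys$shift$eta[i]
        s$euler_pas_deg <- as.numeric(sys$shift[i, c("alpha", "beta", "gamma")]) *
          180 / pi
      }
      s
    }),
    j_couplings_hz = lapply(seq_len(nrow(sys$j)), function(k)
      list(i = sys$j$i[k], j = sys$j$j[k], J_hz = sys$j$J_hz[k])),
    dipolar_couplings = lapply(seq_len(nrow(sys$dipolar)), function(k)
      list(i = sys$dipolar$i[k], j = sys$dipolar$j[k],
           b_hz = sys$dipolar$b_hz[k],
           axis = c(sys$dipolar$ax[k], sys$dipolar$ay[k], sys$dipolar$az[k]),
           motional_scale = sys$dipolar$scale[k])))
  if (!is.null(sys$coords)) {
    obj$coords_angstrom <- lapply(seq_len(nrow(sys$coords)), function(i)
      as.numeric(sys$coords[i, ]))
  }
  yaml::write_yaml(obj, file, precision = 15L)
  invisible(file)
}

#' Read a spin system from a YAML file written by [write_spin_system()]
#' @param file Path to the YAML file.
#' @return A [spin_system()].
#' @export
read_spin_system <- function(file) {
  obj <- yaml::read_yaml(file)
  L <- length(obj$spins)
  shift <- data.frame(iso_ppm = numeric(L), aniso_ppm = 0, eta = 0,
                      alpha = 0, beta = 0, gamma = 0)
  isotope <- character(L); label <- character(L)
  for (s in obj$spins) {
    i <- s$index
    isotope[i] <- s$isotope; label[i] <- s$label
    shift$iso_ppm[i] <- s$iso_ppm
    if (!is.null(s$aniso_ppm)) {
      shift$aniso_ppm[i] <- s$aniso_ppm
      shift$eta[i] <- s$eta %||% 0
      e <- (s$euler_pas_deg %||% c(0, 0, 0)) * pi / 180
      shift$alpha[i] <- e[1]; shift$beta[i] <- e[2]; shift$gamma[i] <- e[3]
    }
  }
  jt <- if (length(obj$j_couplings_hz))
    do.call(rbind, lapply(obj$j_couplings_hz, function(x)
      data.frame(i = x$i, j = x$j, J_hz = x$J_hz)))
  dt <- if (length(obj$dipolar_couplings))
    do.call(rbind, lapply(obj$dipolar_couplings, function(x)
      data.frame(i = x$i, j = x$j, b_hz = x$b_hz, ax = x$axis[1],
                 ay = x$axis[2], az = x$axis[3],
                 scale = x$motional_scale)))
  coords <- if (!is.null(obj$coords_angstrom)) {
    m <- do.call(rbind, obj$coords_angstrom)
    rownames(m) <- label; colnames(m) <- c("x", "y", "z")
    m
  }
  spin_system(isotope, label, shift = shift, j = jt, dipolar = dt,
              name = obj$name %||% "spin_system", coords = coords)
}

## Canonical JSON + md5 of a configuration for provenance stamping.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

.config_provenance <- function(config) {
  pw <- config$powder
  core <- list(b0_proton_mhz = config$b0_proton_mhz, nu_r_hz = config$nu_r,
               carrier_ppm = config$carrier_ppm,
               steps_per_rotor_period = config$steps_per_rotor_period,
               max_mixing_time_s = config$max_mixing_time,
               tau_grid_s = config$tau_grid,
               dream_mode = config$dream_mode,
               n_orientations = nrow(pw),
               powder_hash = config_hash(round(as.matrix(pw), 12)))
  core$config_hash <- config_hash(core)
  core
}

#' Write a buildup curve as CSV with a JSON provenance sidecar
#'
#' The CSV has a `tau_ms` column and one column of transfer efficiencies
#' per destination spin label; `<file>.json` records the full configuration
#' (field, spinning rate, carrier, powder set size and hash, integration
#' controls, program parameters) plus a hash of that configuration, so any
#' parameter change changes the recorded hash.
#'
#' @param curve A `buildup_curve` from [propagate()].
#' @param file CSV output path.
#' @return The CSV path, invisibly.
#' @export
write_buildup_csv <- function(curve, file) {
  tab <- data.frame(tau_ms = curve$times * 1e3, curve$efficiency,
                    check.names = FALSE)
  write.table(tab, file, sep = ",", row.names = FALSE, quote = FALSE)
  side <- list(kind = "buildup_curve", system = curve$system,
               source = curve$source, program = curve$program,
               program_params = curve$program_params,
               config = .config_provenance(curve$config))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE, force = TRUE),
             paste0(file, ".json"))
  invisible(file)
}

#' Write a scan result as CSV with a JSON provenance sidecar
#' @param scan A `scan_result`.
#' @param file CSV output path.
#' @return The CSV path, invisibly.
#' @export
write_scan_csv <- function(scan, file) {
  write.table(as.data.frame(scan), file, sep = ",", row.names = FALSE,
              quote = FALSE)
  side <- list(kind = "scan_result", variable = attr(scan, "variable"),
               units = attr(scan, "units"), sequence = attr(scan, "sequence"),
               config = attr(scan, "config"))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE, force = TRUE),
             paste0(file, ".json"))
  invisible(file)
}

#' Read a buildup table written by this package or an external simulator
#'
#' Accepts a delimited table whose first column is the mixing time (ms) and
#' whose remaining columns are transfer efficiencies per destination spin —
#' the format written by [write_buildup_csv()] and easily produced from
#' external simulation output — so externally computed curves can be
#' compared against [propagate()] results.
#'
#' @param file Path to a CSV/TSV table.
#' @param sep Field separator (default auto: comma, then whitespace).
#' @return List with `times` (s) and `efficiency` (matrix, one column per
#'   destination).
#' @export
read_buildup_table <- function(file, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl(",", first)) "," else ""
  }
  tab <- read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(tab) < 2L) stop("buildup table needs a time column and at least one efficiency column")
  list(times = tab[[1]] * 1e-3,
       efficiency = as.matrix(tab[, -1, drop = FALSE]))
}
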