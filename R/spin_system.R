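#' Construct a spin system
#'
#' A spin system bundles the isotopes, chemical-shift tensors, scalar (J) and
#' dipolar couplings of a small group of nuclei in a molecule-fixed frame.
#' All simulations operate on the full Hilbert space of dimension `2^L`,
#' where `L` is the number of spins, so systems are practical up to 6-7 spins.
#'
#' Shift tensors follow the Haeberlen convention: `iso_ppm` is the isotropic
#' shift, `aniso_ppm` the anisotropy (the zz principal value of the traceless
#' part), and `eta` the asymmetry in `[0, 1]`. The tensor orientation is given
#' by ZYZ active Euler angles (radians) rotating the principal-axis system
#' into the molecule frame.
#'
#' @param isotope Character vector of isotopes, one per spin (`"1H"`, `"13C"`,
#'   `"15N"`).
#' @param label Character vector of short spin labels (e.g. `"CA"`, `"CD1"`).
#'   Must be unique.
#' @param shift Data frame with one row per spin and columns `iso_ppm`,
#'   `aniso_ppm`, `eta`, `alpha`, `beta`, `gamma`. Missing columns default
#'   to zero (isotropic tensor).
#' @param j Data frame of scalar couplings with columns `i`, `j` (spin
#'   indices, 1-based, `i < j`) and `J_hz`. May be empty or `NULL`.
#' @param dipolar Data frame of dipolar couplings with columns `i`, `j`,
#'   `b_hz` (the coupling constant \eqn{b/2\pi = -(\mu_0/4\pi)
#'   \gamma_i\gamma_j\hbar/r^3}, sign retained), `ax`, `ay`, `az` (unit
#'   internuclear axis in the molecule frame) and `scale` (a motional
#'   scaling factor in `(0, 1]`, stored separately and applied when the
#'   Hamiltonian is built). May be empty or `NULL`.
#' @param name Name of the system.
#' @param coords Optional `L x 3` matrix of coordinates in Angstrom (kept
#'   for provenance; not used by the engine).
#'
#' @return An object of class `spin_system`.
#' @seealso [build_alanine_model()], [build_leucine_system()],
#'   [dipolar_from_geometry()], [subsystem()]
#' @export
spin_system <- function(isotope, label = NULL, shift = NULL, j = NULL,
                        dipolar = NULL, name = "spin_system", coords = NULL) {
  L <- length(isotope)
  if (L < 1L) stop("a spin system needs at least one spin")
  gamma_of(isotope)  # validates isotopes
  if (is.null(label)) label <- paste0(isotope, seq_len(L))
  if (anyDuplicated(label)) stop("spin labels must be unique")

  shift <- .complete_shift(shift, L)
  j <- .complete_pairs(j, L, c(J_hz = 0))
  dipolar <- .complete_pairs(dipolar, L,
                             c(b_hz = 0, ax = 0, ay = 0, az = 1, scale = 1))
  sys <- structure(
    list(isotope = as.character(isotope), label = as.character(label),
         shift = shift, j = j, dipolar = dipolar,
         name = name, coords = coords),
    class = "spin_system")
  validate_spin_system(sys)
  sys
}

.complete_shift <- function(shift, L) {
  tmpl <- data.frame(iso_ppm = numeric(L), aniso_ppm = numeric(L),
                     eta = numeric(L), alpha = numeric(L),
                     beta = numeric(L), gamma = numeric(L))
  if (is.null(shift)) return(tmpl)
  shift <- as.data.frame(shift)
  if (nrow(shift) != L) stop("shift table must have one row per spin")
  for (col in names(tmpl)) if (!col %in% names(shift)) shift[[col]] <- 0
  shift[names(tmpl)]
}

.complete_pairs <- function(tab, L, defaults) {
  cols <- c("i", "j", names(defaults))
  if (is.null(tab) || NROW(tab) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$i <- integer(0); out$j <- integer(0)
    return(out)
  }
  tab <- as.data.frame(tab)
  for (k in seq_along(defaults)) {
    col <- names(defaults)[k]
    if (!col %in% names(tab)) tab[[col]] <- defaults[[k]]
  }
  if (any(tab$i >= tab$j)) stop("coupling pairs must have i < j")
  if (any(tab$i < 1L | tab$j > L)) stop("coupling references invalid spin index")
  if (anyDuplicated(tab[c("i", "j")])) stop("duplicate coupling pair")
  tab$i <- as.integer(tab$i); tab$j <- as.integer(tab$j)
  tab <- tab[cols]
  rownames(tab) <- NULL
  tab
}

validate_spin_system <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  L <- length(sys$isotope)
  with(sys$shift, {
    if (any(eta < 0 | eta > 1)) stop("shift tensor eta must lie in [0, 1]")
  })
  if (nrow(sys$dipolar)) {
    n <- sqrt(sys$dipolar$ax^2 + sys$dipolar$ay^2 + sys$dipolar$az^2)
    if (any(abs(n - 1) > 1e-12 & sys$dipolar$b_hz != 0))
      stop("dipolar axis must be a unit vector (|axis| - 1| <= 1e-12)")
    if (any(sys$dipolar$scale <= 0 | sys$dipolar$scale > 1))
      stop("dipolar motional scale must lie in (0, 1]")
  }
  if (!is.null(sys$coords) && !identical(dim(sys$coords), c(L, 3L)) &&
      !identical(dim(sys$coords), as.integer(c(L, 3))))
    stop("coords must be an L x 3 matrix")
  invisible(sys)
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %s: %d spins (%s)\n", x$name,
              length(x$isotope),
              paste(paste0(x$label, "/", x$isotope), collapse = ", ")))
  cat(sprintf("  %d scalar coupling(s), %d dipolar coupling(s)\n",
              nrow(x$j), nrow(x$dipolar)))
  invisible(x)
}

#' Number of spins in a system
#' @param sys A [spin_system()].
#' @return Integer spin count.
#' @export
n_spins <- function(sys) length(sys$isotope)

#' Dipolar coupling from internuclear geometry
#'
#' Computes the dipolar coupling constant
#' \eqn{b/2\pi = -(\mu_0/4\pi)\,\gamma_i \gamma_j \hbar / r^3} (in Hz, sign
#' retained) for two nuclei a distance `r` apart. For a directly bonded
#' 13C-13C pair (r = 1.53 A) this gives |b| of about 2.1 kHz. The motional
#' scaling factor (e.g. 1/3 for a methyl proton averaged by fast rotation
#' about the threefold axis) is stored alongside, not pre-multiplied into
#' `b`; the engine applies it when the Hamiltonian is assembled.
#'
#' @param isotope_i,isotope_j Isotopes of the two nuclei.
#' @param r Internuclear distance in Angstrom. Must be positive.
#' @param motional_scale Dimensionless scaling in `(0, 1]`.
#' @param axis Unit internuclear vector in the molecule frame (default z).
#' @param i,j Optional spin indices to stamp into the returned row.
#' @return One-row data frame with columns `i`, `j`, `b_hz`, `ax`, `ay`,
#'   `az`, `scale`.
#' @export
#' @examples
#' dipolar_from_geometry("13C", "13C", 1.53)$b_hz / 1e3   # ~ -2.12 kHz
#' dipolar_from_geometry("1H", "13C", 1.09, motional_scale = 1/3)
dipolar_from_geometry <- function(isotope_i, isotope_j, r, motional_scale = 1,
                                  axis = c(0, 0, 1), i = 1L, j = 2L) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("internuclear distance r must be a positive number (Angstrom)")
  if (motional_scale <= 0 || motional_scale > 1)
    stop("motional_scale must lie in (0, 1]")
  gi <- gamma_of(isotope_i); gj <- gamma_of(isotope_j)
  r_m <- r * 1e-10
  b_hz <- -(.mu0 / (4 * pi)) * gi * gj * .hbar / r_m^3 / (2 * pi)
  axis <- axis / sqrt(sum(axis^2))
  data.frame(i = as.integer(i), j = as.integer(j), b_hz = b_hz,
             ax = axis[1], ay = axis[2], az = axis[3],
             scale = motional_scale)
}

#' Extract an induced subsystem
#'
#' Keeps the listed spins and every coupling whose members are all kept;
#' indices are remapped to be contiguous. Used, e.g., to derive the linear
#' (C5) leucine topology from the branched (C6) one, or a two-carbon system
#' from the four-spin alanine model.
#'
#' @param sys A [spin_system()].
#' @param keep Integer indices or character labels of spins to keep.
#' @param name Optional new name.
#' @return A [spin_system()].
#' @export
subsystem <- function(sys, keep, name = NULL) {
  validate_spin_system(sys)
  if (is.character(keep)) {
    idx <- match(keep, sys$label)
    if (any(is.na(idx))) stop("unknown spin label(s): ",
                              paste(keep[is.na(idx)], collapse = ", "))
    keep <- idx
  }
  keep <- sort(unique(as.integer(keep)))
  if (any(keep < 1L | keep > n_spins(sys))) stop("spin index out of range")
  remap <- match(seq_len(n_spins(sys)), keep)
  filt <- function(tab) {
    tab <- tab[tab$i %in% keep & tab$j %in% keep, , drop = FALSE]
    tab$i <- remap[tab$i]; tab$j <- remap[tab$j]
    rownames(tab) <- NULL
    tab
  }
  spin_system(
    isotope = sys$isotope[keep], label = sys$label[keep],
    shift = sys$shift[keep, , drop = FALSE],
    j = filt(sys$j), dipolar = filt(sys$dipolar),
    name = name %||% paste0(sys$name, "_sub"),
    coords = if (!is.null(sys$coords)) sys$coords[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spin_index <- function(sys, which) {
  if (is.character(which)) {
    idx <- match(which, sys$label)
    if (any(is.na(idx))) stop("unknown spin label(s): ",
                              paste(which[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(which)
}
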