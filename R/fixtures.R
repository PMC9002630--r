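## Embedded model spin systems and their default NMR parameters.
##
## Chemical shifts are typical solid-state values; CSA magnitudes are
## literature-typical defaults (aliphatic 13C: 20 ppm, eta 0.5; carbonyl:
## -76 ppm, eta 0.6; 1H: 5 ppm). All of them are plain columns of the
## returned system and can be overridden via make_system().

.csa_defaults <- function(isotope, label) {
  aniso <- ifelse(isotope == "1H", 5,
           ifelse(label %in% c("C", "CO"), -76, 20))
  eta <- ifelse(isotope == "1H", 0,
         ifelse(label %in% c("C", "CO"), 0.6, 0.5))
  list(aniso = aniso, eta = eta)
}

#' The four-spin alanine model system (HA-CA-CB-HB)
#'
#' Two 13C and two 1H spins on an idealized alanine fragment: one-bond
#' J(CC) = 33 Hz, one-bond J(HC) = 145 Hz, all pairwise dipolar couplings
#' from the embedded geometry (C-C 1.53 A, C-H 1.09 A, tetrahedral angles).
#' Only one methyl proton is retained and its H-C dipolar coupling carries a
#' motional scale of 1/3, emulating fast rotation of the CH3 group about
#' the C-C axis.
#'
#' @return A [spin_system()] with spins CA, CB, HA, HB.
#' @export
#' @examples
#' sys <- build_alanine_model()
#' sys$j    # 33 Hz CC and 145 Hz CH couplings
build_alanine_model <- function() {
  coords <- alanine_coords()
  isotope <- c("13C", "13C", "1H", "1H")
  label <- rownames(coords)
  csa <- .csa_defaults(isotope, label)
  shift <- data.frame(
    iso_ppm = c(50.8, 19.8, 3.8, 1.4),
    aniso_ppm = csa$aniso, eta = csa$eta,
    alpha = 0, beta = 0, gamma = 0)
  j <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 4L),
                  J_hz = c(33, 145, 145))
  dip <- dipolar_table_from_coords(coords, isotope,
                                   scale_pairs = list("CB-HB" = 1 / 3))
  spin_system(isotope, label, shift = shift, j = j, dipolar = dip,
              name = "alanine_4spin", coords = coords)
}

#' Leucine 13C side-chain spin systems (branched C6 / linear C5)
#'
#' Exclusively-carbon model of a leucine residue: C', CA, CB, CG, CD1, CD2
#' on a canonical rotamer geometry. One-bond J couplings are 33 Hz between
#' aliphatic carbons and 50 Hz for the CA-C' pair; two-bond J couplings are
#' 3 Hz; longer-range J couplings are neglected. All 13C-13C dipolar
#' couplings derive from the embedded coordinates. The linear topology
#' removes CD2 together with every coupling that references it, emulating
#' the 12C-D3-labelled methyl of a linearized (C5) isotopomer; it is the
#' exact induced subsystem of the branched one.
#'
#' @param topology `"branched_C6"` or `"linear_C5"`.
#' @param include_carbonyl Keep the backbone carbonyl spin (default TRUE).
#' @return A [spin_system()].
#' @export
#' @examples
#' c6 <- build_leucine_system("branched_C6")
#' c5 <- build_leucine_system("linear_C5")
#' n_spins(c6); n_spins(c5)
build_leucine_system <- function(topology = c("branched_C6", "linear_C5"),
                                 include_carbonyl = TRUE) {
  topology <- match.arg(topology)
  coords <- leucine_coords()
  isotope <- rep("13C", 6)
  label <- rownames(coords)
  csa <- .csa_defaults(isotope, label)
  shift <- data.frame(
    iso_ppm = c(176, 55, 40, 25, 23, 21),  # C', CA, CB, CG, CD1, CD2
    aniso_ppm = csa$aniso, eta = csa$eta,
    alpha = 0, beta = 0, gamma = 0)
  ## bond graph: C-CA, CA-CB, CB-CG, CG-CD1, CG-CD2
  j <- data.frame(
    i = c(1L, 2L, 3L, 4L, 4L,   1L, 2L, 3L, 3L, 5L),
    j = c(2L, 3L, 4L, 5L, 6L,   3L, 4L, 5L, 6L, 6L),
    J_hz = c(50, 33, 33, 33, 33,  3, 3, 3, 3, 3))
  dip <- dipolar_table_from_coords(coords, isotope)
  sys <- spin_system(isotope, label, shift = shift, j = j, dipolar = dip,
                     name = "leucine_c6", coords = coords)
  if (!include_carbonyl) sys <- subsystem(sys, setdiff(label, "C"),
                                          name = "leucine_c5_noC")
  if (topology == "linear_C5")
    sys <- subsystem(sys, setdiff(sys$label, "CD2"), name = "leucine_c5")
  sys
}

.fixture_registry <- list(
  alanine_4spin = function() build_alanine_model(),
  alanine_cc    = function() subsystem(build_alanine_model(), c("CA", "CB"),
                                       name = "alanine_cc"),
  leucine_c6    = function() build_leucine_system("branched_C6"),
  leucine_c5    = function() build_leucine_system("linear_C5")
)

#' List the names of the embedded fixture systems
#' @return Character vector of fixture names accepted by [make_system()].
#' @export
fixture_names <- function() names(.fixture_registry)

#' Build an embedded fixture system, with optional parameter overrides
#'
#' Delegates to the spin-system builders and then merges overrides. Supported
#' override fields: `iso_ppm` (named by spin label), `aniso_ppm`, `eta`
#' (likewise), `J_hz` (data frame with `i`, `j` or `label_i`, `label_j` and
#' `J_hz`), and `name`. Unknown fields raise an error so configuration typos
#' cannot pass silently.
#'
#' @param fixture_name One of [fixture_names()].
#' @param overrides Named list of overrides (may be empty).
#' @return A [spin_system()].
#' @export
#' @examples
#' make_system("leucine_c6", list(iso_ppm = c(CD1 = 24.5)))
make_system <- function(fixture_name, overrides = list()) {
  fn <- .fixture_registry[[fixture_name]]
  if (is.null(fn))
    stop("unknown fixture '", fixture_name, "'; available: ",
         paste(fixture_names(), collapse = ", "))
  sys <- fn()
  known <- c("iso_ppm", "aniso_ppm", "eta", "J_hz", "name")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override field(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "))
  for (col in c("iso_ppm", "aniso_ppm", "eta")) {
    ov <- overrides[[col]]
    if (is.null(ov)) next
    idx <- spin_index(sys, names(ov))
    sys$shift[[col]][idx] <- as.numeric(ov)
  }
  if (!is.null(overrides$J_hz)) {
    tab <- as.data.frame(overrides$J_hz)
    if (all(c("label_i", "label_j") %in% names(tab))) {
      tab$i <- spin_index(sys, tab$label_i)
      tab$j <- spin_index(sys, tab$label_j)
    }
    for (k in seq_len(nrow(tab))) {
      i <- min(tab$i[k], tab$j[k]); j <- max(tab$i[k], tab$j[k])
      hit <- sys$j$i == i & sys$j$j == j
      if (any(hit)) sys$j$J_hz[hit] <- tab$J_hz[k]
      else sys$j <- rbind(sys$j, data.frame(i = i, j = j, J_hz = tab$J_hz[k]))
    }
  }
  if (!is.null(overrides$name)) sys$name <- overrides$name
  validate_spin_system(sys)
  sys
}

#' Manifest of the embedded fixtures
#'
#' One row per fixture with the spin count and an md5 checksum of its full
#' serialized parameter set, so configuration provenance can record exactly
#' which fixture version produced a result.
#'
#' @return Data frame with columns `name`, `n_spins`, `md5`.
#' @export
fixture_manifest <- function() {
  rows <- lapply(fixture_names(), function(nm) {
    sys <- make_system(nm)
    f <- tempfile(fileext = ".yaml")
    on.exit(unlink(f))
    write_spin_system(sys, f)
    data.frame(name = nm, n_spins = n_spins(sys),
               md5 = unname(tools::md5sum(f)))
  })
  do.call(rbind, rows)
}
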