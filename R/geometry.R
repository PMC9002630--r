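## Internal-coordinate construction of the embedded model geometries.
## Only distances matter for the dipolar couplings; orientations enter the
## powder average anyway, so idealized tetrahedral fragments are used.

## Place atom D bonded to C with |CD| = bond, angle(B,C,D) = ang and
## dihedral(A,B,C,D) = dih (degrees) -- the standard NeRF construction.
zmat_place <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180; dih <- dih * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Idealized alanine HA-CA-CB-HB fragment: C-C 1.53 A, C-H 1.09 A,
## tetrahedral angles, HA anti to HB.
alanine_coords <- function() {
  ca <- c(0, 0, 0)
  cb <- c(1.53, 0, 0)
  ha <- zmat_place(c(0, 0, 1), cb, ca, 1.09, 109.471, 0)    # in xy-plane
  hb <- zmat_place(ha, ca, cb, 1.09, 109.471, 180)
  m <- rbind(CA = ca, CB = cb, HA = ha, HB = hb)
  colnames(m) <- c("x", "y", "z")
  m
}

## Canonical leucine side-chain rotamer (mt: chi1 = -60, chi2 = 180),
## carbons only: C' (backbone carbonyl), CA, CB, CG, CD1, CD2.
leucine_coords <- function() {
  ca <- c(0, 0, 0)
  cb <- c(1.53, 0, 0)
  cg <- zmat_place(c(0, 0, 1), ca, cb, 1.53, 109.471, 0)
  co <- zmat_place(cg, cb, ca, 1.52, 109.471, 60)   # gauche to CG
  cd1 <- zmat_place(ca, cb, cg, 1.53, 109.471, 180) # anti to CA
  cd2 <- zmat_place(ca, cb, cg, 1.53, 109.471, -60)
  m <- rbind(C = co, CA = ca, CB = cb, CG = cg, CD1 = cd1, CD2 = cd2)
  colnames(m) <- c("x", "y", "z")
  m
}

## All pairwise dipolar couplings of a coordinate set.
dipolar_table_from_coords <- function(coords, isotope, scale_pairs = NULL) {
  L <- nrow(coords)
  rows <- list()
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      v <- coords[j, ] - coords[i, ]
      r <- sqrt(sum(v^2))
      sc <- 1
      if (!is.null(scale_pairs)) {
        key <- paste(rownames(coords)[c(i, j)], collapse = "-")
        if (key %in% names(scale_pairs)) sc <- scale_pairs[[key]]
      }
      rows[[length(rows) + 1L]] <-
        dipolar_from_geometry(isotope[i], isotope[j], r,
                              motional_scale = sc, axis = v / r,
                              i = i, j = j)
    }
  }
  do.call(rbind, rows)
}

#' Read coordinates of named atoms of one residue from a PDB file
#'
#' Optional convenience loader (requires the `bio3d` package) for replacing
#' the embedded idealized geometries with crystallographic coordinates. Only
#' extracts coordinates; no other record types are interpreted.
#'
#' @param file Path to a PDB file.
#' @param resno Residue number.
#' @param atoms Character vector of atom names (e.g. `c("C","CA","CB","CG","CD1","CD2")`).
#' @param chain Optional chain identifier.
#' @return Matrix of coordinates (Angstrom) with one row per requested atom.
#' @export
read_residue_coords <- function(file, resno, atoms, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_residue_coords() requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  sel <- a$resno == resno & a$elety %in% atoms
  if (!is.null(chain)) sel <- sel & a$chain == chain
  a <- a[sel, , drop = FALSE]
  if (nrow(a) != length(atoms))
    stop("expected ", length(atoms), " atoms, found ", nrow(a))
  m <- as.matrix(a[match(atoms, a$elety), c("x", "y", "z")])
  rownames(m) <- atoms
  m
}
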