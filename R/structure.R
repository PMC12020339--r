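# Molecular structures for projected-area estimation.
#
# A molecular_structure is a data.frame with columns
#   element (symbol), x, y, z (nm), radius (van der Waals, nm)
# plus a "name" attribute. Structures come from PDB files or from the
# internal idealized peptide builder.

# Bondi van der Waals radii (nm) keyed by element symbol.
.bondi_radius <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
  P = 0.180, F = 0.147, Cl = 0.175, Br = 0.185, I = 0.198
)
.default_vdw <- 0.17

#' Van der Waals radii for element symbols
#'
#' Bondi radii; unknown elements fall back to 0.17 nm with a warning.
#'
#' @param elements Character vector of element symbols.
#' @return Radii in nm.
#' @export
vdw_radius <- function(elements) {
  el <- sub("^(.)(.*)$", "\\U\\1\\L\\2", trimws(elements), perl = TRUE)
  r <- .bondi_radius[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using fallback vdW radius ", .default_vdw, " nm")
    r[is.na(r)] <- .default_vdw
  }
  unname(r)
}

#' Construct a molecular structure
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix (n x 3) of coordinates in nm.
#' @param radius Optional vdW radii in nm; defaults to Bondi by element.
#' @param name Label.
#' @return A \code{molecular_structure} data.frame (element, x, y, z, radius).
#' @export
molecular_structure <- function(element, xyz, radius = NULL, name = "structure") {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("structure must contain at least one atom", call. = FALSE)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns", call. = FALSE)
  if (length(element) != nrow(xyz))
    stop("element and xyz lengths differ", call. = FALSE)
  if (is.null(radius)) radius <- vdw_radius(element)
  if (any(radius <= 0)) stop("all radii must be positive", call. = FALSE)
  structure(
    data.frame(element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               radius = radius),
    name = name, class = c("molecular_structure", "data.frame"))
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat(sprintf("Molecular structure '%s': %d atoms\n",
              attr(x, "name"), nrow(x)))
  ext <- apply(x[, c("x", "y", "z")], 2, function(v) diff(range(v)))
  cat(sprintf("  extent (nm): %.2f x %.2f x %.2f\n", ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Read a molecular structure from a PDB file
#'
#' Keeps ATOM/HETATM records; for alternate locations only the first altLoc
#' is retained. Coordinates are converted from Angstrom to nm and Bondi
#' radii are assigned by element.
#'
#' @param path PDB file.
#' @param name Label; defaults to the file name.
#' @return A [molecular_structure()].
#' @export
read_structure_pdb <- function(path, name = basename(path)) {
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    keep <- at$alt %in% c(NA, "", "A")
    at <- at[keep, , drop = FALSE]
    el <- at$elesy
    if (is.null(el) || all(is.na(el) | el == ""))
      el <- substr(trimws(at$elety), 1L, 1L)
    el[is.na(el) | el == ""] <- substr(trimws(at$elety[is.na(el) | el == ""]), 1L, 1L)
    return(molecular_structure(el, cbind(at$x, at$y, at$z) / 10, name = name))
  }
  lines <- readLines(path)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  alt <- substr(lines, 17, 17)
  lines <- lines[alt %in% c(" ", "A")]
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54))) / 10
  el <- trimws(substr(lines, 77, 78))
  fallback <- el == ""
  el[fallback] <- substr(trimws(substr(lines[fallback], 13, 16)), 1, 1)
  molecular_structure(el, xyz, name = name)
}

## ---- idealized peptide builder -------------------------------------------

# Place atom D given positions A, B, C (nm), bond |CD|, angle B-C-D (deg)
# and dihedral A-B-C-D (deg). Standard internal-coordinate (NeRF) placement.
.place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Side-chain templates: per residue, a matrix of rows
# (atom, element, ref1, ref2, ref3, bond_A, angle_deg, dihedral_deg).
# Refs name backbone atoms (N, CA, C) or earlier side-chain atoms of the
# same residue. Bond lengths/angles are standard idealized values; chain
# dihedrals follow the residue's most common rotamer (chi1 gauche-,
# further chis trans). Heavy atoms only.
.sidechain_templates <- local({
  tpl <- list()
  cb <- c("CB", "C", "C", "N", "CA", "1.530", "110.5", "-122.6")
  tpl$A <- rbind(cb)
  tpl$G <- NULL
  tpl$S <- rbind(cb, c("OG", "O", "N", "CA", "CB", "1.417", "110.8", "-65"))
  tpl$C <- rbind(cb, c("SG", "S", "N", "CA", "CB", "1.808", "113.8", "-65"))
  tpl$c <- rbind(cb,
    c("SG", "S", "N", "CA", "CB", "1.808", "113.8", "-65"),
    c("CM", "C", "CA", "CB", "SG", "1.81", "100.2", "180"),
    c("CO", "C", "CB", "SG", "CM", "1.52", "112", "180"),
    c("NM", "N", "SG", "CM", "CO", "1.33", "116", "0"),
    c("OM", "O", "SG", "CM", "CO", "1.23", "121", "180"))
  tpl$T <- rbind(cb,
    c("OG1", "O", "N", "CA", "CB", "1.433", "109.6", "-65"),
    c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "175"))
  tpl$V <- rbind(cb,
    c("CG1", "C", "N", "CA", "CB", "1.521", "110.5", "-65"),
    c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "175"))
  tpl$L <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.530", "116.3", "-65"),
    c("CD1", "C", "CA", "CB", "CG", "1.521", "110.7", "180"),
    c("CD2", "C", "CA", "CB", "CG", "1.521", "110.7", "60"))
  tpl$I <- rbind(cb,
    c("CG1", "C", "N", "CA", "CB", "1.530", "110.4", "-65"),
    c("CG2", "C", "N", "CA", "CB", "1.521", "110.5", "175"),
    c("CD1", "C", "CA", "CB", "CG1", "1.513", "113.8", "180"))
  tpl$M <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "-65"),
    c("SD", "S", "CA", "CB", "CG", "1.803", "112.7", "180"),
    c("CE", "C", "CB", "CG", "SD", "1.791", "100.9", "180"))
  tpl$D <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.516", "112.6", "-65"),
    c("OD1", "O", "CA", "CB", "CG", "1.249", "118.4", "-20"),
    c("OD2", "O", "CA", "CB", "CG", "1.249", "118.4", "160"))
  tpl$N <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.516", "112.6", "-65"),
    c("OD1", "O", "CA", "CB", "CG", "1.231", "120.8", "-20"),
    c("ND2", "N", "CA", "CB", "CG", "1.328", "116.4", "160"))
  tpl$E <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "-65"),
    c("CD", "C", "CA", "CB", "CG", "1.516", "112.6", "180"),
    c("OE1", "O", "CB", "CG", "CD", "1.249", "118.4", "-20"),
    c("OE2", "O", "CB", "CG", "CD", "1.249", "118.4", "160"))
  tpl$Q <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "-65"),
    c("CD", "C", "CA", "CB", "CG", "1.516", "112.6", "180"),
    c("OE1", "O", "CB", "CG", "CD", "1.231", "120.8", "-20"),
    c("NE2", "N", "CB", "CG", "CD", "1.328", "116.4", "160"))
  tpl$K <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "-65"),
    c("CD", "C", "CA", "CB", "CG", "1.520", "111.3", "180"),
    c("CE", "C", "CB", "CG", "CD", "1.520", "111.3", "180"),
    c("NZ", "N", "CG", "CD", "CE", "1.489", "111.9", "180"))
  tpl$R <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.520", "114.1", "-65"),
    c("CD", "C", "CA", "CB", "CG", "1.520", "111.3", "180"),
    c("NE", "N", "CB", "CG", "CD", "1.461", "112.0", "180"),
    c("CZ", "C", "CG", "CD", "NE", "1.329", "124.2", "180"),
    c("NH1", "N", "CD", "NE", "CZ", "1.326", "120.0", "0"),
    c("NH2", "N", "CD", "NE", "CZ", "1.326", "120.0", "180"))
  ring6 <- function(stem, d1 = "90") rbind(
    c("CD1", "C", "CA", "CB", "CG", "1.39", "120.8", d1),
    c("CD2", "C", "CA", "CB", "CG", "1.39", "120.8",
      sprintf("%g", as.numeric(d1) - 180)),
    c("CE1", "C", "CB", "CG", "CD1", "1.39", "120", "180"),
    c("CE2", "C", "CB", "CG", "CD2", "1.39", "120", "180"),
    c("CZ", "C", "CG", "CD1", "CE1", "1.39", "120", "0"))
  tpl$F <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.502", "113.8", "-65"),
    ring6("F"))
  tpl$Y <- rbind(tpl$F,
    c("OH", "O", "CD1", "CE1", "CZ", "1.376", "120", "180"))
  tpl$H <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.497", "113.8", "-65"),
    c("ND1", "N", "CA", "CB", "CG", "1.378", "122.7", "90"),
    c("CD2", "C", "CA", "CB", "CG", "1.356", "131.1", "-90"),
    c("CE1", "C", "CB", "CG", "ND1", "1.32", "109.2", "180"),
    c("NE2", "N", "CB", "CG", "CD2", "1.374", "107.2", "180"))
  # indole approximated as fused planar rings built sequentially
  tpl$W <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.498", "113.6", "-65"),
    c("CD1", "C", "CA", "CB", "CG", "1.365", "126.9", "90"),
    c("CD2", "C", "CA", "CB", "CG", "1.433", "126.7", "-90"),
    c("NE1", "N", "CB", "CG", "CD1", "1.374", "110.2", "180"),
    c("CE2", "C", "CB", "CG", "CD2", "1.409", "107.2", "180"),
    c("CE3", "C", "CB", "CG", "CD2", "1.398", "133.9", "0"),
    c("CZ2", "C", "CG", "CD2", "CE2", "1.394", "122.4", "180"),
    c("CZ3", "C", "CG", "CD2", "CE3", "1.382", "118.6", "180"),
    c("CH2", "C", "CD2", "CE2", "CZ2", "1.368", "117.5", "0"))
  tpl$P <- rbind(cb,
    c("CG", "C", "N", "CA", "CB", "1.492", "104.5", "-25"),
    c("CD", "C", "CA", "CB", "CG", "1.503", "106.1", "35"))
  tpl
})

#' Build an idealized 3D peptide conformer
#'
#' Constructs heavy-atom coordinates for a peptide from idealized internal
#' coordinates (standard bond lengths and angles, trans peptide bonds) at
#' fixed backbone dihedrals. The default backbone is polyproline-II-like
#' (phi = -75, psi = +145 degrees), the consensus conformation of short
#' arginine-rich peptides in water; side chains use the residue's most
#' common rotamer (chi1 gauche-, remaining chis trans). Bondi van der Waals
#' radii are assigned by element.
#'
#' This is a desk-scale stand-in for a solution conformer: no energy
#' refinement is performed and hydrogens are omitted.
#'
#' @param sequence One-letter residue string (lowercase \code{"c"} =
#'   carbamidomethyl cysteine).
#' @param phi,psi Backbone dihedrals in degrees, recycled over residues.
#' @param name Label.
#' @return A [molecular_structure()] in nm.
#' @examples
#' r7g <- build_peptide_structure("RRRRRRRG")
#' @export
build_peptide_structure <- function(sequence, phi = -75, psi = 145,
                                    name = sequence) {
  tokens <- .check_tokens(.split_residues(sequence))
  n <- length(tokens)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  # backbone geometry (Angstrom / degrees)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7; a_CaCO <- 120.8

  atoms <- list()  # each: list(name, element, resno, pos)
  add <- function(nm, el, res, pos)
    atoms[[length(atoms) + 1L]] <<- list(name = nm, element = el,
                                         resno = res, pos = pos)
  # seed first residue backbone in a canonical frame
  Npos <- c(0, 0, 0)
  CApos <- c(b_NCa, 0, 0)
  th <- (180 - a_NCaC) * pi / 180
  Cpos <- CApos + b_CaC * c(cos(th), sin(th), 0)
  add("N", "N", 1L, Npos); add("CA", "C", 1L, CApos); add("C", "C", 1L, Cpos)

  prevN <- Npos; prevCA <- CApos; prevC <- Cpos
  for (i in seq_len(n)) {
    # carbonyl oxygen: trans to the next-residue N (psi + 180 about CA-C)
    Opos <- .place_atom(prevN, prevCA, prevC, b_CO, a_CaCO, psi[i] + 180)
    add("O", "O", i, Opos)
    # side chain
    tmpl <- .sidechain_templates[[tokens[i]]]
    if (!is.null(tmpl)) {
      ref <- list(N = prevN, CA = prevCA, C = prevC)
      for (k in seq_len(nrow(tmpl))) {
        row <- tmpl[k, ]
        pos <- .place_atom(ref[[row[3]]], ref[[row[4]]], ref[[row[5]]],
                           as.numeric(row[6]), as.numeric(row[7]),
                           as.numeric(row[8]))
        add(row[1], row[2], i, pos)
        ref[[row[1]]] <- pos
      }
    }
    if (i == n) {
      # C-terminal carboxylate OXT opposite the carbonyl O
      add("OXT", "O", i, .place_atom(prevN, prevCA, prevC, b_CO, a_CaCO, psi[i]))
      break
    }
    nextN <- .place_atom(prevN, prevCA, prevC, b_CN, a_CaCN, psi[i])
    nextCA <- .place_atom(prevCA, prevC, nextN, b_NCa, a_CNCa, 180)  # omega
    nextC <- .place_atom(prevC, nextN, nextCA, b_CaC, a_NCaC, phi[i + 1L])
    add("N", "N", i + 1L, nextN)
    add("CA", "C", i + 1L, nextCA)
    add("C", "C", i + 1L, nextC)
    prevN <- nextN; prevCA <- nextCA; prevC <- nextC
  }
  xyz <- do.call(rbind, lapply(atoms, `[[`, "pos")) / 10  # Angstrom -> nm
  el <- vapply(atoms, `[[`, "", "element")
  st <- molecular_structure(el, xyz, name = name)
  st$atom <- vapply(atoms, `[[`, "", "name")
  st$resno <- vapply(atoms, `[[`, 1L, "resno")
  st
}
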