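#' Measure a signed dihedral angle
#'
#' Signed torsion angle of the quadruple a-b-c-d about the b-c bond,
#' IUPAC sign convention (clockwise positive looking from b to c),
#' reported in degrees in (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees.
#' @export
measure_torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("collinear triplet: dihedral undefined")
  }
  b2h <- b2 / sqrt(sum(b2^2))
  m1 <- .cross3(b2h, n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Natural-extension (NeRF) placement: position D bonded to C such that
# |CD| = bond, angle(B,C,D) = angle and dihedral(A,B,C,D) = dih.
.place_atom <- function(a, b, c, bond, angle, dih) {
  th <- angle * pi / 180
  ph <- dih * pi / 180
  d2 <- c(-bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("collinear reference atoms in placement")
  n <- n / nn
  m <- .cross3(n, bc)
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an all-atom conformation from torsions
#'
#' Constructs heavy-atom Cartesian coordinates for a capped model
#' tripeptide (Ace-Gly-Yyy-Gly-Nme, glycan-linked where the modification
#' state requires it) by sequential internal-to-Cartesian extension from
#' idealized bond lengths and angles.  Requested dihedrals are realized
#' exactly (to numerical precision).
#'
#' @param state a [ptm_state()] object.
#' @param torsions a [torsion_set()]; `chi` arity must match the state's
#'   topology (see [ptm_topology()]).
#' @param rotamer rotamer label from the state's [enumerate_rotamer_scheme()]
#'   (`"-"` for single-rotamer states).
#' @param backbone_index integer pairing key recorded on the conformation.
#' @return object of class `conformation`: atom table (`name`, `element`,
#'   `resid`, `resname`, `het`, `x`, `y`, `z`), bond list, torsions,
#'   rotamer, state and backbone index.
#' @export
build_conformation <- function(state, torsions, rotamer = "-", backbone_index = NA_integer_) {
  stopifnot(inherits(state, "ptm_state"), inherits(torsions, "torsion_set"))
  topo <- ptm_topology(state, rotamer)
  if (length(torsions$chi) != topo$n_chi) {
    stop(sprintf("torsion/topology mismatch: state '%s' expects %d chi angles, got %d",
                 state$state, topo$n_chi, length(torsions$chi)))
  }
  vars <- .torsion_vars(torsions, topo, rotamer)
  zm <- topo$zmatrix
  n <- nrow(zm)
  xyz <- matrix(NA_real_, n, 3)
  for (r in seq_len(n)) {
    if (r == 1L) {
      xyz[1, ] <- c(0, 0, 0)
    } else if (r == 2L) {
      xyz[2, ] <- c(zm$bond[2], 0, 0)
    } else {
      dih <- zm$dih[r]
      if (is.na(dih)) dih <- 0  # angle-only rows (third atom)
      if (!is.na(zm$dvar[r])) {
        v <- vars[[zm$dvar[r]]]
        if (is.null(v)) stop("unresolved torsion variable '", zm$dvar[r], "'")
        dih <- wrap_angle(v + zm$doff[r])
      }
      i <- zm$i[r]; j <- zm$j[r]; k <- zm$k[r]
      aref <- if (r == 3L) xyz[j, ] + c(0, 0, 1) else xyz[k, ]
      xyz[r, ] <- .place_atom(aref, xyz[j, ], xyz[i, ], zm$bond[r], zm$angle[r], dih)
    }
  }
  atoms <- data.frame(
    name = zm$name, element = zm$element, resid = zm$resid,
    resname = zm$resname, het = zm$het,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  structure(list(
    sequence = topo$sequence,
    atoms = atoms,
    bonds = topo$bonds,
    torsions = torsions,
    rotamer = rotamer,
    state = state,
    backbone_index = backbone_index
  ), class = "conformation")
}

# Resolve named torsion variables for z-matrix evaluation.  Flanking Gly
# residues use a fixed extended backbone; caps come from the torsion set.
.torsion_vars <- function(torsions, topo, rotamer) {
  vars <- list(
    phi = torsions$phi, psi = torsions$psi,
    phi1 = -150, psi1 = 150, phi3 = -150, psi3 = 150,
    ace = unname(torsions$caps["ace"]), nme = unname(torsions$caps["nme"])
  )
  for (k in seq_along(torsions$chi)) vars[[paste0("chi", k)]] <- torsions$chi[k]
  if (!is.null(topo$rotamer_angle)) vars$rot <- topo$rotamer_angle
  vars
}

#' Measure a named torsion on a built conformation
#'
#' @param conf a `conformation`.
#' @param atoms character vector of four atom names (optionally
#'   `"resid:name"` to disambiguate; bare names match residue 3 first).
#' @return dihedral in degrees.
#' @export
conformation_torsion <- function(conf, atoms) {
  idx <- vapply(atoms, function(nm) .find_atom(conf$atoms, nm), integer(1))
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  measure_torsion(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
}

.find_atom <- function(atoms, nm) {
  if (grepl(":", nm, fixed = TRUE)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    hit <- which(atoms$resid == as.integer(parts[1]) & atoms$name == parts[2])
  } else {
    hit <- which(atoms$resid == 3L & atoms$name == nm)
    if (length(hit) == 0) hit <- which(atoms$name == nm)
  }
  if (length(hit) == 0) stop("atom '", nm, "' not found")
  hit[1]
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: %s [%s/%s] rotamer=%s, %d atoms, backbone #%s\n",
              x$sequence, x$state$residue, x$state$state, x$rotamer,
              nrow(x$atoms), x$backbone_index))
  invisible(x)
}
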