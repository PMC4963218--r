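# Idealized heavy-atom internal-coordinate templates.  Each atom row is
# (name, element, resid, resname, het, i, j, k, bond, angle, dih|dvar+doff):
# the atom is bonded to i, the bond angle is at (j, i, new) and the
# dihedral is measured on (k, j, i, new).  Chains are built by NeRF
# extension; glycan rings are rigid near-4C1-chair templates attached via
# the linkage torsions.  Bond lengths/angles are standard values (amide
# C-N 1.33, Csp3-Csp3 1.52-1.53, C=O 1.23, C-O 1.42-1.43 Angstrom).

.zmx_new <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$extra_bonds <- list()
  env
}

.zmx_add <- function(env, name, element, resid, resname, i = NA, j = NA, k = NA,
                     bond = NA, angle = NA, dih = NA, dvar = NA, doff = 0,
                     het = FALSE) {
  env$rows[[length(env$rows) + 1L]] <- data.frame(
    name = name, element = element, resid = as.integer(resid),
    resname = resname, het = het,
    i = as.integer(i), j = as.integer(j), k = as.integer(k),
    bond = bond, angle = angle, dih = dih,
    dvar = as.character(dvar), doff = doff,
    stringsAsFactors = FALSE
  )
  length(env$rows)
}

.zmx_bond <- function(env, a, b) {
  env$extra_bonds[[length(env$extra_bonds) + 1L]] <- c(a, b)
}

.zmx_finish <- function(env) {
  zm <- do.call(rbind, env$rows)
  bonded <- cbind(zm$i[!is.na(zm$i)], which(!is.na(zm$i)))
  extra <- if (length(env$extra_bonds)) do.call(rbind, env$extra_bonds) else NULL
  list(zmatrix = zm, bonds = rbind(bonded, extra))
}

# Backbone Ace-Gly-Yyy-Gly-Nme; flanking Gly are fixed extended
# (phi = -150, psi = 150), central-residue phi/psi are free variables.
.add_backbone <- function(z, yyy) {
  CH3a <- .zmx_add(z, "CH3", "C", 1, "ACE")
  Ca   <- .zmx_add(z, "C", "C", 1, "ACE", i = CH3a, bond = 1.52)
  N1   <- .zmx_add(z, "N", "N", 2, "GLY", i = Ca, j = CH3a, bond = 1.33, angle = 116)
  .zmx_add(z, "O", "O", 1, "ACE", i = Ca, j = N1, k = CH3a,
           bond = 1.23, angle = 122.5, dih = 180)
  CA1 <- .zmx_add(z, "CA", "C", 2, "GLY", i = N1, j = Ca, k = CH3a,
                  bond = 1.45, angle = 121, dvar = "ace")
  C1 <- .zmx_add(z, "C", "C", 2, "GLY", i = CA1, j = N1, k = Ca,
                 bond = 1.52, angle = 110, dvar = "phi1")
  .zmx_add(z, "O", "O", 2, "GLY", i = C1, j = CA1, k = N1,
           bond = 1.23, angle = 120.5, dvar = "psi1", doff = 180)
  N2 <- .zmx_add(z, "N", "N", 3, yyy, i = C1, j = CA1, k = N1,
                 bond = 1.33, angle = 116, dvar = "psi1")
  CA2 <- .zmx_add(z, "CA", "C", 3, yyy, i = N2, j = C1, k = CA1,
                  bond = 1.45, angle = 121, dih = 180)
  C2 <- .zmx_add(z, "C", "C", 3, yyy, i = CA2, j = N2, k = C1,
                 bond = 1.52, angle = 110, dvar = "phi")
  .zmx_add(z, "O", "O", 3, yyy, i = C2, j = CA2, k = N2,
           bond = 1.23, angle = 120.5, dvar = "psi", doff = 180)
  N3 <- .zmx_add(z, "N", "N", 4, "GLY", i = C2, j = CA2, k = N2,
                 bond = 1.33, angle = 116, dvar = "psi")
  CA3 <- .zmx_add(z, "CA", "C", 4, "GLY", i = N3, j = C2, k = CA2,
                  bond = 1.45, angle = 121, dih = 180)
  C3 <- .zmx_add(z, "C", "C", 4, "GLY", i = CA3, j = N3, k = C2,
                 bond = 1.52, angle = 110, dvar = "phi3")
  .zmx_add(z, "O", "O", 4, "GLY", i = C3, j = CA3, k = N3,
           bond = 1.23, angle = 120.5, dvar = "psi3", doff = 180)
  N4 <- .zmx_add(z, "N", "N", 5, "NME", i = C3, j = CA3, k = N3,
                 bond = 1.33, angle = 116, dvar = "psi3")
  .zmx_add(z, "CH3", "C", 5, "NME", i = N4, j = C3, k = CA3,
           bond = 1.45, angle = 121, dvar = "nme")
  list(N = N2, CA = CA2, C = C2, Cprev = C1)
}

.add_cb <- function(z, bb, resname) {
  .zmx_add(z, "CB", "C", 3, resname, i = bb$CA, j = bb$N, k = bb$Cprev,
           bond = 1.53, angle = 110.5, dvar = "phi", doff = 122.5)
}

# Rigid GalNAc/GlcNAc pyranose template attached at linkage atom L.
# linkvar places C1 about the P-L bond; ringvar places O5 about L-C1;
# anomeric configuration sets which side of the L/O5 plane C2 occupies,
# and Gal vs Glc differ in the O4 axial/equatorial position.
.add_glycan <- function(z, L, P, PP, linkvar, ringvar, anomeric, sugar,
                        link_bond = 1.41) {
  C1 <- .zmx_add(z, "C1", "C", 6, sugar, i = L, j = P, k = PP,
                 bond = link_bond, angle = 117, dvar = linkvar, het = TRUE)
  O5 <- .zmx_add(z, "O5", "O", 6, sugar, i = C1, j = L, k = P,
                 bond = 1.43, angle = 108, dvar = ringvar, het = TRUE)
  c2off <- if (anomeric == "alpha") 120 else -120
  C2 <- .zmx_add(z, "C2", "C", 6, sugar, i = C1, j = L, k = P,
                 bond = 1.53, angle = 110, dvar = ringvar, doff = c2off, het = TRUE)
  C3 <- .zmx_add(z, "C3", "C", 6, sugar, i = C2, j = C1, k = O5,
                 bond = 1.52, angle = 110, dih = -55, het = TRUE)
  C4 <- .zmx_add(z, "C4", "C", 6, sugar, i = C3, j = C2, k = C1,
                 bond = 1.52, angle = 110, dih = 55, het = TRUE)
  C5 <- .zmx_add(z, "C5", "C", 6, sugar, i = C4, j = C3, k = C2,
                 bond = 1.52, angle = 110, dih = -55, het = TRUE)
  .zmx_bond(z, C5, O5)
  N2 <- .zmx_add(z, "N2", "N", 6, sugar, i = C2, j = C1, k = O5,
                 bond = 1.46, angle = 110, dih = -175, het = TRUE)
  C7 <- .zmx_add(z, "C7", "C", 6, sugar, i = N2, j = C2, k = C1,
                 bond = 1.35, angle = 122, dih = 180, het = TRUE)
  .zmx_add(z, "O7", "O", 6, sugar, i = C7, j = N2, k = C2,
           bond = 1.23, angle = 122, dih = 0, het = TRUE)
  .zmx_add(z, "C8", "C", 6, sugar, i = C7, j = N2, k = C2,
           bond = 1.50, angle = 116, dih = 180, het = TRUE)
  .zmx_add(z, "O3", "O", 6, sugar, i = C3, j = C2, k = C1,
           bond = 1.43, angle = 110, dih = -65, het = TRUE)
  o4dih <- if (sugar == "GAL") -65 else 175
  .zmx_add(z, "O4", "O", 6, sugar, i = C4, j = C3, k = C2,
           bond = 1.43, angle = 110, dih = o4dih, het = TRUE)
  C6 <- .zmx_add(z, "C6", "C", 6, sugar, i = C5, j = C4, k = C3,
                 bond = 1.52, angle = 112, dih = -170, het = TRUE)
  .zmx_add(z, "O6", "O", 6, sugar, i = C6, j = C5, k = C4,
           bond = 1.43, angle = 110, dih = 60, het = TRUE)
  invisible(NULL)
}

# Parse an Arg guanidinium rotamer label like "NH1:0" or "NH2:a".
.parse_nh_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("NH1", "NH2")) {
    stop("invalid guanidinium rotamer label '", label, "'")
  }
  list(site = parts[1], tag = parts[2])
}

#' Heavy-atom topology for a modification state
#'
#' Returns the internal-coordinate template (z-matrix), bond list,
#' sequence label and expected chi arity for one residue/state, with the
#' rotamer label resolved into the added-group dihedral where the state
#' has one.
#'
#' @param state a [ptm_state()].
#' @param rotamer rotamer label (see [enumerate_rotamer_scheme()]).
#' @return list with `zmatrix`, `bonds`, `sequence`, `n_chi`,
#'   `rotamer_angle`.
#' @export
ptm_topology <- function(state, rotamer = "-") {
  stopifnot(inherits(state, "ptm_state"))
  key <- paste(state$residue, state$state, rotamer, sep = "|")
  hit <- get0(key, envir = .topology_cache)
  if (!is.null(hit)) return(hit)
  out <- .build_topology(state, rotamer)
  assign(key, out, envir = .topology_cache)
  out
}

.topology_cache <- new.env(parent = emptyenv())

.build_topology <- function(state, rotamer) {
  z <- .zmx_new()
  bb <- .add_backbone(z, state$residue)
  key <- paste(state$residue, state$state, sep = "/")
  n_chi <- switch(state$residue, LYS = 4L, ARG = 4L, SER = 1L, THR = 1L, ASN = 2L)
  rotamer_angle <- NA_real_

  if (state$residue == "LYS") {
    CB <- .add_cb(z, bb, "LYS")
    CG <- .zmx_add(z, "CG", "C", 3, "LYS", i = CB, j = bb$CA, k = bb$N,
                   bond = 1.52, angle = 114, dvar = "chi1")
    CD <- .zmx_add(z, "CD", "C", 3, "LYS", i = CG, j = CB, k = bb$CA,
                   bond = 1.52, angle = 111, dvar = "chi2")
    CE <- .zmx_add(z, "CE", "C", 3, "LYS", i = CD, j = CG, k = CB,
                   bond = 1.52, angle = 111, dvar = "chi3")
    NZ <- .zmx_add(z, "NZ", "N", 3, "LYS", i = CE, j = CD, k = CG,
                   bond = 1.49, angle = 112, dvar = "chi4")
    if (state$state == "acetyl") {
      rotamer_angle <- as.numeric(rotamer)
      C7 <- .zmx_add(z, "C7", "C", 3, "LYS", i = NZ, j = CE, k = CD,
                     bond = 1.35, angle = 120, dvar = "rot")
      .zmx_add(z, "O7", "O", 3, "LYS", i = C7, j = NZ, k = CE,
               bond = 1.23, angle = 122, dih = 0)
      .zmx_add(z, "C8", "C", 3, "LYS", i = C7, j = NZ, k = CE,
               bond = 1.50, angle = 116, dih = 180)
    } else if (state$state %in% c("monomethyl", "dimethyl", "trimethyl")) {
      rotamer_angle <- if (state$state == "trimethyl") 180 else as.numeric(rotamer)
      .zmx_add(z, "CM1", "C", 3, "LYS", i = NZ, j = CE, k = CD,
               bond = 1.47, angle = 110, dvar = "rot")
      if (state$state %in% c("dimethyl", "trimethyl")) {
        .zmx_add(z, "CM2", "C", 3, "LYS", i = NZ, j = CE, k = CD,
                 bond = 1.47, angle = 110, dvar = "rot", doff = 120)
      }
      if (state$state == "trimethyl") {
        .zmx_add(z, "CM3", "C", 3, "LYS", i = NZ, j = CE, k = CD,
                 bond = 1.47, angle = 110, dvar = "rot", doff = -120)
      }
    }
  } else if (state$residue == "ARG") {
    CB <- .add_cb(z, bb, "ARG")
    CG <- .zmx_add(z, "CG", "C", 3, "ARG", i = CB, j = bb$CA, k = bb$N,
                   bond = 1.52, angle = 114, dvar = "chi1")
    CD <- .zmx_add(z, "CD", "C", 3, "ARG", i = CG, j = CB, k = bb$CA,
                   bond = 1.52, angle = 111, dvar = "chi2")
    NE <- .zmx_add(z, "NE", "N", 3, "ARG", i = CD, j = CG, k = CB,
                   bond = 1.46, angle = 112, dvar = "chi3")
    CZ <- .zmx_add(z, "CZ", "C", 3, "ARG", i = NE, j = CD, k = CG,
                   bond = 1.33, angle = 124, dvar = "chi4")
    NH1 <- .zmx_add(z, "NH1", "N", 3, "ARG", i = CZ, j = NE, k = CD,
                    bond = 1.33, angle = 120, dih = 0)
    NH2 <- .zmx_add(z, "NH2", "N", 3, "ARG", i = CZ, j = NE, k = CD,
                    bond = 1.33, angle = 120, dih = 180)
    sites <- c(NH1 = NH1, NH2 = NH2)
    if (state$state == "monomethyl-NE") {
      .zmx_add(z, "CM1", "C", 3, "ARG", i = NE, j = CD, k = CG,
               bond = 1.46, angle = 118, dvar = "chi4", doff = 180)
    } else if (state$state == "monomethyl-NH") {
      lab <- .parse_nh_label(rotamer)
      rotamer_angle <- as.numeric(lab$tag)
      .zmx_add(z, "CM1", "C", 3, "ARG", i = sites[[lab$site]], j = CZ, k = NE,
               bond = 1.46, angle = 120, dvar = "rot")
    } else if (state$state == "dimethyl-sym") {
      rotamer_angle <- as.numeric(rotamer)
      .zmx_add(z, "CM1", "C", 3, "ARG", i = NH1, j = CZ, k = NE,
               bond = 1.46, angle = 120, dvar = "rot")
      .zmx_add(z, "CM2", "C", 3, "ARG", i = NH2, j = CZ, k = NE,
               bond = 1.46, angle = 120, dvar = "rot")
    } else if (state$state == "dimethyl-asym") {
      lab <- .parse_nh_label(rotamer)
      d1 <- if (lab$tag == "a") 0 else 180
      .zmx_add(z, "CM1", "C", 3, "ARG", i = sites[[lab$site]], j = CZ, k = NE,
               bond = 1.46, angle = 120, dih = d1)
      .zmx_add(z, "CM2", "C", 3, "ARG", i = sites[[lab$site]], j = CZ, k = NE,
               bond = 1.46, angle = 120, dih = wrap_angle(d1 + 180))
    }
  } else if (state$residue %in% c("SER", "THR")) {
    CB <- .add_cb(z, bb, state$residue)
    OG <- .zmx_add(z, if (state$residue == "SER") "OG" else "OG1", "O", 3,
                   state$residue, i = CB, j = bb$CA, k = bb$N,
                   bond = 1.42, angle = 110.5, dvar = "chi1")
    if (state$residue == "THR") {
      .zmx_add(z, "CG2", "C", 3, "THR", i = CB, j = bb$CA, k = bb$N,
               bond = 1.52, angle = 110.5, dvar = "chi1", doff = -120)
    }
    if (state$modified) {
      n_chi <- 3L
      sugar <- if (state$state == "GalNAc-alpha") "GAL" else "GLC"
      anom <- if (state$state == "GalNAc-alpha") "alpha" else "beta"
      .add_glycan(z, OG, CB, bb$CA, "chi2", "chi3", anom, sugar)
    }
  } else if (state$residue == "ASN") {
    CB <- .add_cb(z, bb, "ASN")
    CG <- .zmx_add(z, "CG", "C", 3, "ASN", i = CB, j = bb$CA, k = bb$N,
                   bond = 1.52, angle = 112.5, dvar = "chi1")
    .zmx_add(z, "OD1", "O", 3, "ASN", i = CG, j = CB, k = bb$CA,
             bond = 1.23, angle = 121, dvar = "chi2")
    ND2 <- .zmx_add(z, "ND2", "N", 3, "ASN", i = CG, j = CB, k = bb$CA,
                    bond = 1.33, angle = 116.5, dvar = "chi2", doff = 180)
    if (state$modified) {
      n_chi <- 4L
      .add_glycan(z, ND2, CG, CB, "chi3", "chi4", "beta", "GLC", link_bond = 1.45)
    }
  }

  fin <- .zmx_finish(z)
  seq_label <- sprintf("Ace-Gly-%s-Gly-Nme",
                       paste0(substr(state$residue, 1, 1),
                              tolower(substr(state$residue, 2, 3))))
  list(zmatrix = fin$zmatrix, bonds = fin$bonds, sequence = seq_label,
       n_chi = n_chi, rotamer_angle = rotamer_angle)
}
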