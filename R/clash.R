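# van der Waals radii (Angstrom) for the heavy elements in the templates
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Bond-graph distance matrix for a conformation's topology, cached per
# template (residue/state/rotamer-site) since it is coordinate-independent.
.bond_dist_cache <- new.env(parent = emptyenv())

.bond_distances <- function(conf) {
  key <- paste(conf$state$residue, conf$state$state,
               sub(":.*$", "", conf$rotamer), nrow(conf$atoms), sep = "|")
  hit <- get0(key, envir = .bond_dist_cache)
  if (!is.null(hit)) return(hit)
  g <- igraph::graph_from_edgelist(conf$bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(conf$atoms) - igraph::vcount(g)))
  d <- igraph::distances(g)
  assign(key, d, envir = .bond_dist_cache)
  d
}

#' Detect atomic overlaps in a conformation
#'
#' Flags atom pairs closer than `overlap_factor` times the sum of their
#' van der Waals radii, excluding pairs separated by at most
#' `bond_exclusion_depth` bonds.  The permissive default (0.5 x sum of
#' vdW radii, 1-2/1-3/1-4 pairs excluded) flags genuine steric collisions
#' while keeping rejection sampling feasible.
#'
#' @param conf a `conformation`.
#' @param overlap_factor multiple of the vdW-radius sum below which a
#'   pair counts as clashing (default 0.5).
#' @param bond_exclusion_depth pairs within this many bonds are ignored
#'   (default 3).
#' @return data frame of clashing pairs (`i`, `j`, `distance`,
#'   `threshold`); zero rows when clash-free.
#' @export
detect_clashes <- function(conf, overlap_factor = 0.5, bond_exclusion_depth = 3L) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  r <- .VDW[conf$atoms$element]
  dmat <- as.matrix(stats::dist(xyz))
  thr <- overlap_factor * outer(r, r, "+")
  bd <- .bond_distances(conf)
  cand <- which(upper.tri(dmat) & dmat < thr & bd > bond_exclusion_depth,
                arr.ind = TRUE)
  data.frame(
    i = cand[, 1], j = cand[, 2],
    distance = dmat[cand], threshold = thr[cand]
  )
}

#' Is a conformation free of atomic overlaps?
#'
#' @inheritParams detect_clashes
#' @return logical scalar.
#' @export
is_clash_free <- function(conf, overlap_factor = 0.5, bond_exclusion_depth = 3L) {
  nrow(detect_clashes(conf, overlap_factor, bond_exclusion_depth)) == 0L
}
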