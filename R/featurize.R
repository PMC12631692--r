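#' @name features
#' @title The 35-entry node feature vector
#'
#' @description
#' Every node (heavy atom) carries 35 fixed features: 14 atomic features
#' describing the atom itself, then 21 molecule-level features - 15 chemical
#' descriptors and 6 conformer-derived geometric descriptors - broadcast
#' identically to every node of the molecule. Broadcasting global
#' information to the nodes is what lets a small message-passing network
#' read global structure without deep stacks; the dimensional ledger
#' 14 + 15 + 6 = 35 is asserted throughout the package.
#'
#' Three atomic features are affinely rescaled with fixed constants:
#' mass `(A - 10.812)/116.092`, van der Waals radius `(R - 1.5)/0.6`,
#' covalent radius `(R - 0.64)/0.76`. No other feature is standardized.
NULL

.atomic_feature_names <- c(
  "atom_degree", "atomic_number", "num_hydrogens", "atomic_valence",
  "num_radical_electrons", "atom_formal_charge", "atom_hybridization",
  "electronegativity", "has_electronegativity", "has_implicit_hydrogens",
  "hydroxyl_group", "atomic_mass_scaled", "vdw_radius_scaled",
  "covalent_radius_scaled")

.molecular_feature_names <- c(
  "has_ring", "is_aromatic", "formal_charge", "min_degree",
  "num_hbond_donors", "num_rings", "num_rotatable_bonds",
  "polar_surface_area", "molecular_weight", "num_atoms", "hba", "hbd",
  "fraction_sp2", "valence", "general_electronegativity")

.geometry_feature_names <- c(
  "volume", "width", "length", "height", "dipole_moment",
  "orientation_angle")

#' Names of the node features, in column order
#'
#' @param which One of `"all"`, `"atomic"`, `"molecular"`, `"geometry"`.
#' @return Character vector of feature names (35, 14, 15 or 6 entries).
#' @export
feature_names <- function(which = c("all", "atomic", "molecular",
                                    "geometry")) {
  which <- match.arg(which)
  switch(which,
         atomic = .atomic_feature_names,
         molecular = .molecular_feature_names,
         geometry = .geometry_feature_names,
         all = c(.atomic_feature_names, .molecular_feature_names,
                 .geometry_feature_names))
}

#' Fixed affine feature scalings
#'
#' The three scaled atomic features use fixed affine maps:
#' `scale_atomic_mass(A) = (A - 10.812)/116.092` (zero at boron's mass
#' scale, one near iodine), `scale_vdw_radius(r) = (r - 1.5)/0.6` and
#' `scale_covalent_radius(r) = (r - 0.64)/0.76`. Inputs must be positive;
#' the constants are part of the model definition, not data-derived.
#'
#' @param mass,r Positive numeric vector (daltons, angstroms).
#' @return Numeric vector of the same length.
#' @export
scale_atomic_mass <- function(mass) {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    rlang::abort("atomic mass must be positive and finite")
  }
  (mass - 10.812) / 116.092
}

#' @rdname scale_atomic_mass
#' @export
scale_vdw_radius <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    rlang::abort("van der Waals radius must be positive and finite")
  }
  (r - 1.5) / 0.6
}

#' @rdname scale_atomic_mass
#' @export
scale_covalent_radius <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    rlang::abort("covalent radius must be positive and finite")
  }
  (r - 0.64) / 0.76
}

#' Per-atom features of a molecule
#'
#' Computes the 14 atomic features for every heavy atom (or one atom) of a
#' parsed molecule. Electronegativities come from a fixed Pauling-scale
#' table; elements without a defined value get `electronegativity = 0` and
#' `has_electronegativity = 0`. `hydroxyl_group` is 1 for an oxygen bonded
#' to at least one hydrogen and exactly one heavy neighbor.
#'
#' @param mol A `molgat_mol` from [parse_smiles()].
#' @param atom_index Optional single 1-based atom index; default all atoms.
#' @return A tibble with one row per requested atom and 14 feature columns.
#' @export
atom_features <- function(mol, atom_index = NULL) {
  stopifnot(inherits(mol, "molgat_mol"))
  a <- mol$atoms
  if (!is.null(atom_index)) {
    if (!is.numeric(atom_index) || any(atom_index < 1) ||
        any(atom_index > nrow(a))) {
      rlang::abort(paste0("atom_index out of range 1..", nrow(a)))
    }
    a <- a[atom_index, ]
  }
  en <- element_electronegativity(a$atomic_number)
  tibble::tibble(
    atom_degree = as.numeric(a$degree),
    atomic_number = as.numeric(a$atomic_number),
    num_hydrogens = as.numeric(a$n_h),
    atomic_valence = as.numeric(a$valence),
    num_radical_electrons = as.numeric(a$radical_electrons),
    atom_formal_charge = as.numeric(a$formal_charge),
    atom_hybridization = as.numeric(a$hybridization),
    electronegativity = ifelse(is.na(en), 0, en),
    has_electronegativity = as.numeric(!is.na(en)),
    has_implicit_hydrogens = as.numeric(a$has_implicit_h),
    hydroxyl_group = as.numeric(a$element == "O" & a$n_h >= 1 &
                                  a$degree == 1),
    atomic_mass_scaled = scale_atomic_mass(element_mass(a$atomic_number)),
    vdw_radius_scaled = scale_vdw_radius(
      element_vdw_radius(a$atomic_number)),
    covalent_radius_scaled = scale_covalent_radius(
      element_covalent_radius(a$atomic_number)))
}

#' Molecule-level chemical descriptors
#'
#' The 15 chemical descriptors broadcast to every node: ring and
#' aromaticity flags, net formal charge, minimum heavy-atom degree,
#' hydrogen-bond donor/acceptor counts (two donor definitions are kept, a
#' Lipinski-style count and the toolkit default), rotatable bonds,
#' topological polar surface area (A^2), molecular weight (Da), heavy-atom
#' count, fraction of sp2-hybridized heavy atoms, summed atomic valence,
#' and the mean Pauling electronegativity over atoms with a defined value.
#'
#' @param mol A `molgat_mol`.
#' @return A one-row tibble with 15 columns.
#' @export
molecular_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molgat_mol"))
  a <- mol$atoms
  if (nrow(a) < 1L) rlang::abort("molecule has no heavy atoms")
  d <- mol$descriptors
  en <- element_electronegativity(a$atomic_number)
  tibble::tibble(
    has_ring = as.numeric(d$num_rings > 0),
    is_aromatic = as.numeric(any(a$aromatic)),
    formal_charge = as.numeric(d$net_formal_charge),
    min_degree = as.numeric(min(a$degree)),
    num_hbond_donors = as.numeric(d$num_hbond_donors),
    num_rings = as.numeric(d$num_rings),
    num_rotatable_bonds = as.numeric(d$num_rotatable_bonds),
    polar_surface_area = as.numeric(d$tpsa),
    molecular_weight = as.numeric(d$mw),
    num_atoms = as.numeric(nrow(a)),
    hba = as.numeric(d$hba),
    hbd = as.numeric(d$hbd),
    fraction_sp2 = mean(a$hybridization == 3L),
    valence = as.numeric(sum(a$valence)),
    general_electronegativity = mean(en[!is.na(en)]))
}

#' Conformer-derived geometric descriptors
#'
#' The 6 geometric descriptors measured on the molecule's 3D conformer
#' (seeded distance-geometry embedding, force-field relaxation):
#' grid-based molecular volume (A^3); the three heavy-atom coordinate
#' extents sorted so that `length >= width >= height` (A); the magnitude of
#' the partial-charge dipole `||sum_i q_i r_i||` over all atoms including
#' hydrogens (e*A); and the orientation angle between the conformer's
#' first principal axis and the x-axis, in `[0, pi]` radians.
#'
#' @param mol A `molgat_mol` parsed with `gen3d = TRUE`.
#' @return A one-row tibble with 6 columns.
#' @export
geometry_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molgat_mol"))
  if (!is.null(mol$geometry_error)) {
    rlang::abort(paste0("geometry failed for ", mol$smiles, ": ",
                        mol$geometry_error),
                 class = "molgat_geometry_failure")
  }
  g <- mol$geometry
  if (is.null(g)) {
    rlang::abort("molecule has no conformer; parse with gen3d = TRUE",
                 class = "molgat_geometry_failure")
  }
  heavy <- g$coords[seq_len(g$n_heavy), , drop = FALSE]
  ranges <- sort(apply(heavy, 2L, function(v) diff(range(v))),
                 decreasing = TRUE)
  dip <- sqrt(sum(colSums(g$coords * g$charges)^2))
  angle <- 0
  if (nrow(heavy) >= 2L) {
    centered <- sweep(heavy, 2L, colMeans(heavy))
    ev <- eigen(crossprod(centered) / nrow(heavy), symmetric = TRUE)
    u <- ev$vectors[, 1L]
    k <- which.max(abs(u))
    if (u[k] < 0) u <- -u
    angle <- acos(min(1, max(-1, u[1L])))
  }
  tibble::tibble(
    volume = g$volume,
    width = ranges[2L],
    length = ranges[1L],
    height = ranges[3L],
    dipole_moment = dip,
    orientation_angle = angle)
}

#' Assemble the N x 35 node feature matrix
#'
#' Row i concatenates the atomic features of atom i with the molecule-level
#' and geometric descriptors, which are therefore identical in every row.
#' Row order is the SMILES atom-token order.
#'
#' @param mol A `molgat_mol` parsed with `gen3d = TRUE`.
#' @return A numeric matrix, `n_atoms` x 35, with feature column names.
#' @export
node_feature_matrix <- function(mol) {
  af <- as.matrix(atom_features(mol))
  glob <- c(as.numeric(molecular_descriptors(mol)),
            as.numeric(geometry_descriptors(mol)))
  n <- nrow(af)
  out <- cbind(af, matrix(glob, nrow = n, ncol = 21L, byrow = TRUE))
  colnames(out) <- feature_names()
  stopifnot(ncol(out) == 35L)
  out
}
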