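# Geometric annotations used in the structural arguments: distance-based
# hydrogen-bond detection between atom selections (e.g. the N-terminal
# beta-strand vs the first extracellular loop) and Shrake-Rupley solvent
# accessible surface area, from which dimer interface areas follow.

#' Hydrogen-bond criteria
#'
#' X-ray models at typical resolution lack hydrogens, so the primary
#' criterion is the donor-acceptor heavy-atom distance; an angular term is
#' applied only where the hydrogen position is inferable from covalent
#' geometry (backbone amides).
#'
#' @param d_max Donor-acceptor distance ceiling, angstrom (default 3.5).
#' @param d_min Lower bound excluding covalent contacts (default 2.4).
#' @param angle_min Minimum donor-H...acceptor angle in degrees where the
#'   amide hydrogen can be placed; ignored otherwise (default 90).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, d_min = 2.4, angle_min = 90) {
  stopifnot(d_min > 0, d_max > d_min)
  structure(list(d_max = d_max, d_min = d_min, angle_min = angle_min),
            class = "hbond_criteria")
}

# donor / acceptor atom names per residue (N/O chemistry only)
sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", HOH = "O", WAT = "O"
)
sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  HOH = "O", WAT = "O"
)

#' Parse an atom selection string
#'
#' Syntax `"chain"` (whole chain) or `"chain:first-last"` (inclusive author
#' residue-number range), e.g. `"A:42-49"`.
#'
#' @param model A [structure_model()].
#' @param sel Selection string, or a logical/integer vector of atom rows
#'   (passed through).
#' @return Integer indices into `model$atoms`.
#' @export
select_atoms <- function(model, sel) {
  at <- model$atoms
  if (is.logical(sel)) return(which(sel))
  if (is.numeric(sel)) return(as.integer(sel))
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  keep <- at$chain == parts[1]
  if (length(parts) > 1) {
    rng <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
    keep <- keep & at$resno >= rng[1] & at$resno <= rng[2]
  }
  idx <- which(keep)
  if (length(idx) == 0) abort(paste0("selection '", sel,
                                     "' matches no atoms"))
  idx
}

hbond_capable <- function(atoms, table) {
  role <- logical(nrow(atoms))
  # backbone
  if (identical(table, "donor"))    role <- atoms$elety == "N" & !atoms$het &
                                            atoms$resid != "PRO"
  if (identical(table, "acceptor")) role <- atoms$elety %in% c("O", "OXT") &
                                            !atoms$het
  tab <- if (identical(table, "donor")) sidechain_donors else sidechain_acceptors
  for (res in names(tab)) {
    role <- role | (atoms$resid == res & atoms$elety %in% tab[[res]])
  }
  role
}

#' Detect hydrogen bonds between two selections
#'
#' Enumerates donor-acceptor pairs with the donor in one selection and the
#' acceptor in the other (both directions are examined, so the result is
#' symmetric in the selection order) and keeps pairs within the distance
#' window. For backbone amide donors the hydrogen is placed from the N, CA
#' and preceding C positions and the donor-H...acceptor angle must reach
#' `angle_min`.
#'
#' @param model A [structure_model()].
#' @param selection_a,selection_b Selections (see [select_atoms()]).
#' @param criteria An [hbond_criteria()].
#' @return A tibble sorted by distance: donor chain/resno/resid/atom,
#'   acceptor chain/resno/resid/atom, `distance` (angstrom), `angle`
#'   (degrees, `NA` where not inferable).
#' @export
detect_hbonds <- function(model, selection_a, selection_b,
                          criteria = hbond_criteria()) {
  at <- model$atoms
  ia <- select_atoms(model, selection_a)
  ib <- select_atoms(model, selection_b)
  don <- hbond_capable(at, "donor")
  acc <- hbond_capable(at, "acceptor")
  bonds <- bind_rows(
    hbond_pairs(at, intersect(ia, which(don)), intersect(ib, which(acc)),
                criteria),
    hbond_pairs(at, intersect(ib, which(don)), intersect(ia, which(acc)),
                criteria)
  )
  if (nrow(bonds) == 0) return(bonds)
  bonds |>
    distinct(.data$donor_chain, .data$donor_resno, .data$donor_atom,
             .data$acceptor_chain, .data$acceptor_resno, .data$acceptor_atom,
             .keep_all = TRUE) |>
    arrange(.data$distance)
}

hbond_pairs <- function(at, idx_don, idx_acc, criteria) {
  empty <- tibble(donor_chain = character(0), donor_resno = integer(0),
                  donor_resid = character(0), donor_atom = character(0),
                  acceptor_chain = character(0), acceptor_resno = integer(0),
                  acceptor_resid = character(0), acceptor_atom = character(0),
                  distance = numeric(0), angle = numeric(0))
  if (length(idx_don) == 0 || length(idx_acc) == 0) return(empty)
  D <- as.matrix(at[idx_don, c("x", "y", "z")])
  A <- as.matrix(at[idx_acc, c("x", "y", "z")])
  d2 <- outer(rowSums(D^2), rep(1, nrow(A))) +
    outer(rep(1, nrow(D)), rowSums(A^2)) - 2 * D %*% t(A)
  hits <- which(d2 >= criteria$d_min^2 & d2 <= criteria$d_max^2,
                arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  out <- tibble(
    donor_chain = at$chain[idx_don[hits[, 1]]],
    donor_resno = at$resno[idx_don[hits[, 1]]],
    donor_resid = at$resid[idx_don[hits[, 1]]],
    donor_atom = at$elety[idx_don[hits[, 1]]],
    acceptor_chain = at$chain[idx_acc[hits[, 2]]],
    acceptor_resno = at$resno[idx_acc[hits[, 2]]],
    acceptor_resid = at$resid[idx_acc[hits[, 2]]],
    acceptor_atom = at$elety[idx_acc[hits[, 2]]],
    distance = sqrt(pmax(d2[hits], 0)),
    angle = NA_real_
  )
  # same residue / adjacent-in-chain backbone contacts are covalent context
  out <- filter(out, !(.data$donor_chain == .data$acceptor_chain &
                         abs(.data$donor_resno - .data$acceptor_resno) < 1))
  if (nrow(out) == 0) return(out)
  ang <- map_dbl(seq_len(nrow(out)), function(k) {
    amide_angle(at, out$donor_chain[k], out$donor_resno[k],
                out$donor_atom[k],
                c(out$acceptor_chain[k], out$acceptor_resno[k],
                  out$acceptor_atom[k]))
  })
  out$angle <- ang
  filter(out, is.na(.data$angle) | .data$angle >= criteria$angle_min)
}

# donor-H...acceptor angle for a backbone amide donor; NA when the hydrogen
# position cannot be inferred (chain break, non-amide donor)
amide_angle <- function(at, chain, resno, donor_atom, acceptor) {
  if (donor_atom != "N") return(NA_real_)
  get_xyz <- function(ch, rn, ele) {
    i <- which(at$chain == ch & at$resno == rn & at$elety == ele)
    if (length(i) != 1) return(NULL)
    as.numeric(at[i, c("x", "y", "z")])
  }
  n_pos <- get_xyz(chain, resno, "N")
  ca <- get_xyz(chain, resno, "CA")
  c_prev <- get_xyz(chain, resno - 1L, "C")
  a_pos <- get_xyz(acceptor[1], as.integer(acceptor[2]), acceptor[3])
  if (is.null(n_pos) || is.null(ca) || is.null(c_prev) || is.null(a_pos)) {
    return(NA_real_)
  }
  u1 <- normalize(n_pos - ca); u2 <- normalize(n_pos - c_prev)
  h <- n_pos + normalize(u1 + u2) * 1.01
  v1 <- normalize(n_pos - h); v2 <- normalize(a_pos - h)
  acos(pmin(pmax(sum(v1 * v2), -1), 1)) * 180 / pi
}

normalize <- function(v) v / sqrt(sum(v^2))

#' Default van der Waals radii (angstrom)
#'
#' Bondi-style element radii used for surface-area calculations; the
#' `fallback` entry covers elements absent from the table.
#'
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90, FE = 2.00, ZN = 1.39,
    MG = 1.73, "NA" = 2.27, fallback = 1.70)
}

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the model: each atom's expanded sphere (van der
#' Waals radius + probe) is sampled with a deterministic near-uniform point
#' set and the accessible fraction is the fraction of points outside all
#' neighbouring expanded spheres.
#'
#' @param model A [structure_model()].
#' @param probe Probe radius, angstrom (default 1.4, water).
#' @param n_points Sample points per atom (default 960).
#' @param radii Named element-radius vector with a `fallback` entry, see
#'   [default_vdw_radii()].
#' @return A tibble with one row per atom (`chain`, `resno`, `elety`,
#'   `area` in square angstrom) and attribute `total`.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               radii = default_vdw_radii()) {
  at <- model$atoms
  r <- radii[at$element]
  missing_el <- is.na(r)
  if (any(missing_el)) {
    if (!"fallback" %in% names(radii)) {
      abort(paste0("no van der Waals radius for element(s): ",
                   paste(unique(at$element[missing_el]), collapse = ", ")))
    }
    r[missing_el] <- radii[["fallback"]]
  }
  r <- unname(r) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  d2 <- outer(rowSums(xyz^2), rep(1, n)) +
    outer(rep(1, n), rowSums(xyz^2)) - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p_i <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        dj <- rowSums(sweep(p_i, 2, xyz[j, ])^2)
        # strict interior, plus a tie-break so exactly duplicated atoms
        # count once (the earlier atom keeps its surface)
        buried <- buried | dj < r[j]^2 - 1e-9 |
          (j < i & dj < r[j]^2 + 1e-9)
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * r[i]^2 * acc / n_points
  }
  out <- tibble(chain = at$chain, resno = at$resno, elety = at$elety,
                area = area)
  attr(out, "total") <- sum(area)
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  out
}

#' Total solvent-accessible surface area
#'
#' @param model A [structure_model()].
#' @inheritParams shrake_rupley_sasa
#' @return Total SASA in square angstrom.
#' @export
total_sasa <- function(model, probe = 1.4, n_points = 960,
                       radii = default_vdw_radii()) {
  attr(shrake_rupley_sasa(model, probe, n_points, radii), "total")
}

#' Buried interface area between two chain sets
#'
#' Half the surface area buried on complex formation:
#' `(SASA(A) + SASA(B) - SASA(A+B)) / 2`, the convention used for
#' monomer-monomer interfaces of membrane-protein oligomers.
#'
#' @param model A [structure_model()] containing both chain sets.
#' @param chains_a,chains_b Disjoint character vectors of chain ids.
#' @inheritParams shrake_rupley_sasa
#' @return Interface area in square angstrom.
#' @export
interface_area <- function(model, chains_a, chains_b, probe = 1.4,
                           n_points = 960, radii = default_vdw_radii()) {
  if (length(intersect(chains_a, chains_b)) > 0) {
    abort("chain sets must be disjoint")
  }
  at <- model$atoms
  if (!all(c(chains_a, chains_b) %in% at$chain)) {
    abort("chain set(s) absent from model")
  }
  sub <- function(chains) {
    structure_model(filter(at, .data$chain %in% chains), id = model$id)
  }
  sa <- total_sasa(sub(chains_a), probe, n_points, radii)
  sb <- total_sasa(sub(chains_b), probe, n_points, radii)
  sab <- total_sasa(sub(c(chains_a, chains_b)), probe, n_points, radii)
  max((sa + sb - sab) / 2, 0)
}
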