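# Point-charge (plus optional atomic-dipole) electrostatic models evaluated
# on van der Waals shell grids. Units: coordinates and radii in bohr,
# charges in e, potentials in kcal mol^-1 e^-1, dipoles in atomic units.

#' Construct a molecule
#'
#' @param elements Character vector of element symbols.
#' @param coords n x 3 numeric matrix of Cartesian coordinates (bohr).
#' @param radii Per-atom van der Waals radii (bohr), all > 0.
#' @param net_charge Total charge of the system (e).
#' @return A `molecule` object.
#' @export
molecule <- function(elements, coords, radii, net_charge = 0) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(elements) || length(radii) != length(elements)) {
    abort("elements, coords rows, and radii must have equal length.")
  }
  if (!all(is.finite(coords))) abort("Coordinates must be finite.")
  if (any(radii <= 0)) abort("vdW radii must be positive.")
  structure(list(elements = elements, coords = coords,
                 radii = as.numeric(radii), net_charge = net_charge),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("Molecule: %d atoms (%s), net charge %g e\n",
              length(x$elements), paste(x$elements, collapse = " "),
              x$net_charge))
  invisible(x)
}

#' Read an XYZ-style geometry with a vdW radius column
#'
#' Whitespace-delimited rows `element x y z radius`, coordinates and radii
#' in bohr. Lines starting with `#` and blank lines are skipped; an
#' optional leading atom-count line (a single integer) is tolerated.
#'
#' @param path File path.
#' @param net_charge Net charge of the system (e).
#' @return A `molecule`.
#' @export
read_xyzr <- function(path, net_charge = 0) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0 && grepl("^[0-9]+$", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) < 5)) {
    abort("Each atom line must be: element x y z radius.")
  }
  mat <- do.call(rbind, parts)
  molecule(mat[, 1],
           apply(mat[, 2:4, drop = FALSE], 2, as.numeric),
           as.numeric(mat[, 5]), net_charge)
}

#' Build a uniform van der Waals shell grid
#'
#' Lays down a cubic lattice (axis-aligned, origin at the molecule's
#' geometric center) with the given spacing, then keeps the points p that
#' lie in the vdW shell: at least `inner` times the vdW radius away from
#' every atom and within `outer` times the vdW radius of at least one atom.
#' Point order is deterministic (lexicographic in lattice index).
#'
#' @param mol A `molecule`.
#' @param inner,outer Shell bounds as multiples of each atom's vdW radius
#'   (defaults 1.4 and 2.0).
#' @param spacing Lattice spacing in bohr.
#' @return An `esp_grid`: list with `points` (m x 3 matrix), `reference`
#'   (`NULL` until filled), `inner`, `outer`, `spacing`.
#' @export
build_vdw_shell_grid <- function(mol, inner = 1.4, outer = 2.0, spacing = 0.4) {
  if (!(inner > 0 && inner < outer)) abort("Need 0 < inner < outer.")
  if (spacing <= 0) abort("spacing must be positive.")
  center <- colMeans(mol$coords)
  pad <- outer * max(mol$radii)
  lo <- apply(mol$coords, 2, min) - pad
  hi <- apply(mol$coords, 2, max) + pad
  axes <- lapply(1:3, function(d) {
    k <- seq(ceiling((lo[d] - center[d]) / spacing),
             floor((hi[d] - center[d]) / spacing))
    center[d] + k * spacing
  })
  pts <- as.matrix(expand.grid(z = axes[[3]], y = axes[[2]], x = axes[[1]])
                   )[, c("x", "y", "z"), drop = FALSE]
  keep <- shell_predicate(pts, mol, inner, outer)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) abort("Shell grid is empty; reduce spacing.")
  dimnames(pts) <- NULL
  structure(list(points = pts, reference = NULL,
                 inner = inner, outer = outer, spacing = spacing),
            class = "esp_grid")
}

shell_predicate <- function(pts, mol, inner, outer) {
  n_atoms <- nrow(mol$coords)
  inside_any <- rep(FALSE, nrow(pts))
  within_any <- rep(FALSE, nrow(pts))
  for (a in seq_len(n_atoms)) {
    d <- sqrt(rowSums(sweep(pts, 2, mol$coords[a, ])^2))
    inside_any <- inside_any | (d < inner * mol$radii[a])
    within_any <- within_any | (d <= outer * mol$radii[a])
  }
  !inside_any & within_any
}

#' @export
print.esp_grid <- function(x, ...) {
  cat(sprintf("vdW shell grid: %d points, shell %.1f-%.1f x R_vdW, spacing %g bohr\n",
              nrow(x$points), x$inner, x$outer, x$spacing))
  invisible(x)
}

#' Electrostatic potential of a point-charge model
#'
#' Coulomb sum V(p) = C * sum_a q_a / |p - r_a| with distances in bohr,
#' charges in e, and C = 627.509474 converting hartree/e to
#' kcal mol^-1 e^-1.
#'
#' @param mol A `molecule`.
#' @param charges Per-atom charges (e).
#' @param points m x 3 matrix of evaluation points (bohr), or an
#'   `esp_grid`.
#' @return Numeric vector of potentials (kcal mol^-1 e^-1).
#' @export
point_charge_potential <- function(mol, charges, points) {
  if (inherits(points, "esp_grid")) points <- points$points
  if (length(charges) != nrow(mol$coords)) {
    abort("Need one charge per atom.")
  }
  v <- numeric(nrow(points))
  for (a in seq_len(nrow(mol$coords))) {
    d <- sqrt(rowSums(sweep(points, 2, mol$coords[a, ])^2))
    if (any(d == 0)) abort("Grid point coincides with an atom (singularity).")
    v <- v + charges[a] / d
  }
  HARTREE_TO_KCALMOL * v
}

#' Molecular dipole of a point-charge (+ atomic dipole) model
#'
#' mu = sum_a q_a r_a + sum_a d_a in atomic units. For a charged system the
#' dipole is origin-dependent; the center of nuclear charge is used then.
#'
#' @param mol A `molecule`.
#' @param charges Per-atom charges (e).
#' @param atomic_dipoles Optional n x 3 matrix of per-atom dipoles (au).
#' @return Length-3 dipole vector (au).
#' @export
model_dipole <- function(mol, charges, atomic_dipoles = NULL) {
  origin <- c(0, 0, 0)
  if (abs(sum(charges)) > 1e-12) {
    z <- atomic_number(mol$elements)
    origin <- colSums(mol$coords * z) / sum(z)
  }
  mu <- colSums(sweep(mol$coords, 2, origin) * charges)
  if (!is.null(atomic_dipoles)) mu <- mu + colSums(atomic_dipoles)
  mu
}

#' ESP and dipole errors of a point-charge model
#'
#' RMSE of the model potential against the reference over the (uniformly
#' weighted) grid; RRMSE expresses it as a percentage of the RMSE of the
#' zero-charge model (i.e. the root mean square of the reference itself);
#' Delta mu compares dipole magnitudes as a signed percentage. Including
#' atomic dipoles lets the model reproduce the reference molecular dipole
#' exactly.
#'
#' @param model Model potentials (kcal mol^-1 e^-1).
#' @param reference Reference potentials, same length and grid.
#' @param mol A `molecule`.
#' @param charges Per-atom charges (e).
#' @param mu_ref Reference dipole: length-3 vector or magnitude (au).
#' @param atomic_dipoles Optional n x 3 matrix of atomic dipoles (au).
#' @return An `esp_result` one-row tibble: `rmse`, `rmse_zero`, `rrmse`
#'   (%), `mu_model` (au magnitude), `mu_ref`, `delta_mu` (%).
#' @export
esp_errors <- function(model, reference, mol, charges, mu_ref,
                       atomic_dipoles = NULL) {
  if (length(model) != length(reference)) {
    abort("model and reference potentials must have equal length.")
  }
  rmse <- sqrt(mean((model - reference)^2))
  rmse_zero <- sqrt(mean(reference^2))
  if (rmse_zero == 0) {
    abort("Reference potential is identically zero; RRMSE undefined.")
  }
  mu_vec <- model_dipole(mol, charges, atomic_dipoles)
  mu_ref_mag <- if (length(mu_ref) == 3) sqrt(sum(mu_ref^2)) else abs(mu_ref)
  if (mu_ref_mag <= 0) abort("Need |mu_ref| > 0 for Delta mu.")
  out <- tibble::tibble(
    rmse = rmse, rmse_zero = rmse_zero, rrmse = 100 * rmse / rmse_zero,
    mu_model = sqrt(sum(mu_vec^2)), mu_ref = mu_ref_mag,
    delta_mu = 100 * (sqrt(sum(mu_vec^2)) - mu_ref_mag) / mu_ref_mag)
  class(out) <- c("esp_result", class(out))
  out
}

#' Dipole-exact charges for a symmetric bent triatomic
#'
#' A bent, C2v-symmetric A-B-A molecule (e.g. water) has its NACs uniquely
#' determined by the molecular dipole moment: with the two terminal atoms
#' constrained equal by symmetry, q_B + 2 q_A = Q and the dipole along the
#' symmetry axis fix both charges. The molecule's atom order must place the
#' two symmetry-equivalent terminal atoms around the distinct central atom
#' in any order; the central atom is identified as the one equidistant from
#' the other two equal-element atoms.
#'
#' @param mol A `molecule` with exactly 3 atoms.
#' @param mu_ref Reference dipole vector (au, length 3) or scalar magnitude
#'   taken along the symmetry axis (pointing from the terminal-atom midpoint
#'   toward the central atom).
#' @param net_charge Total charge Q (e).
#' @param tol Geometric and off-axis tolerance.
#' @return Named per-atom charge vector (e), in the molecule's atom order.
#' @export
triatomic_dipole_charges <- function(mol, mu_ref, net_charge = 0,
                                     tol = 1e-8) {
  if (nrow(mol$coords) != 3) abort("Need exactly 3 atoms.")
  el <- mol$elements
  center_idx <- NULL
  for (b in 1:3) {
    a <- setdiff(1:3, b)
    if (el[a[1]] == el[a[2]]) {
      d1 <- sqrt(sum((mol$coords[a[1], ] - mol$coords[b, ])^2))
      d2 <- sqrt(sum((mol$coords[a[2], ] - mol$coords[b, ])^2))
      if (abs(d1 - d2) < tol * max(1, d1)) {
        center_idx <- b
        break
      }
    }
  }
  if (is.null(center_idx)) {
    abort("Molecule is not a symmetric A-B-A triatomic.")
  }
  term <- setdiff(1:3, center_idx)
  r_b <- mol$coords[center_idx, ]
  mid <- colMeans(mol$coords[term, , drop = FALSE])
  axis <- r_b - mid
  axis_len <- sqrt(sum(axis^2))
  if (axis_len < tol) {
    abort("Degenerate (linear) geometry: dipole is insensitive to the charges.")
  }
  u <- axis / axis_len

  if (length(mu_ref) == 3) {
    mu_axis <- sum(mu_ref * u)
    off_axis <- sqrt(sum((mu_ref - mu_axis * u)^2))
    if (off_axis > tol * max(1, abs(mu_axis))) {
      abort("Reference dipole has a component off the C2v symmetry axis.")
    }
  } else {
    mu_axis <- mu_ref
  }

  # charged systems: dipole taken about the center of nuclear charge
  origin <- c(0, 0, 0)
  if (abs(net_charge) > 1e-12) {
    z <- atomic_number(el)
    origin <- colSums(mol$coords * z) / sum(z)
  }
  # mu.u = q_B (r_B - o).u + q_A [(r_1 - o) + (r_2 - o)].u, q_B = Q - 2 q_A
  b_proj <- sum((r_b - origin) * u)
  a_proj <- sum((colSums(mol$coords[term, , drop = FALSE]) - 2 * origin) * u)
  denom <- a_proj - 2 * b_proj
  if (abs(denom) < tol) {
    abort("Degenerate geometry: charges do not affect the axial dipole.")
  }
  q_a <- (mu_axis - net_charge * b_proj) / denom
  q <- numeric(3)
  q[term] <- q_a
  q[center_idx] <- net_charge - 2 * q_a
  setNames(q, el)
}
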