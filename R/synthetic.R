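# Synthetic correlated-NAC generator with known latent-factor ground truth,
# corruption injection for the consistency checker, and toy molecules with
# self-consistent reference ESP grids.
#
# Each atom carries two latent patterns t_i and u_i (iid standard normal,
# centered within its molecule). Method alpha reports
#   q_i = scale * (cos(angle) t_i + sin(angle) u_i + noise * eps_i)
# plus a uniform per-molecule shift that makes every molecular charge sum
# exactly equal to the molecule's integer net charge. The implied
# large-sample correlation between two methods is
#   cos(angle_a - angle_b) / sqrt((1 + noise_a^2)(1 + noise_b^2)).

#' Method specification for the synthetic generator
#'
#' @param name Method names.
#' @param scale Per-method charge-transfer scale sigma (e), > 0.
#' @param noise Per-method noise level eta (dimensionless), >= 0; larger
#'   noise lowers all of the method's correlations.
#' @param angle Latent factor angle theta (radians); methods sharing an
#'   angle load on the same factor, and the angle gap sets the
#'   between-block correlation cos(angle_a - angle_b).
#' @return A tibble with one row per method.
#' @export
synth_methods <- function(name, scale, noise, angle = 0) {
  out <- tibble::tibble(name = name, scale = scale, noise = noise,
                        angle = angle)
  if (nrow(out) < 2) abort("Need at least 2 methods.")
  if (any(out$scale <= 0)) abort("scale must be > 0.")
  if (any(out$noise < 0)) abort("noise must be >= 0.")
  out
}

#' Default 20-method profile
#'
#' One main block of 14 methods sharing the primary latent factor plus two
#' 3-method side blocks on tilted factors, with charge-transfer scales
#' spanning 0.13-0.63 e — the topology and scale range observed for real
#' charge-assignment method families (a dominant mutually highly correlated
#' core with weakly connected satellites).
#'
#' @return A method-specification tibble (see [synth_methods()]).
#' @export
default_method_profile <- function() {
  synth_methods(
    name = sprintf("meth%02d", 1:20),
    scale = round(seq(0.13, 0.63, length.out = 20), 4),
    noise = c(0.10, 0.14, 0.18, 0.22, 0.26, 0.30, 0.12, 0.16, 0.20, 0.24,
              0.28, 0.32, 0.15, 0.25,          # main block (14)
              0.20, 0.25, 0.30,                # side block A (3)
              0.20, 0.25, 0.30),               # side block B (3)
    angle = c(rep(0, 14), rep(0.7, 3), rep(-0.7, 3))
  )
}

#' Synthetic dataset configuration
#'
#' @param n_molecules Number of molecules.
#' @param atoms_min,atoms_max Uniform range of atoms per molecule.
#' @param charge_probs Named probabilities over net charges `-1`, `0`, `+1`.
#' @param methods Method specification tibble, see [synth_methods()].
#' @param seed Integer seed; fully determines the output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_molecules = 400, atoms_min = 3, atoms_max = 8,
                         charge_probs = c("-1" = 0.05, "0" = 0.9, "1" = 0.05),
                         methods = default_method_profile(), seed = 1) {
  if (n_molecules < 1) abort("n_molecules must be >= 1.")
  if (atoms_min < 1 || atoms_max < atoms_min) abort("Bad atoms range.")
  if (abs(sum(charge_probs) - 1) > 1e-9) abort("charge_probs must sum to 1.")
  structure(list(n_molecules = n_molecules, atoms_min = atoms_min,
                 atoms_max = atoms_max, charge_probs = charge_probs,
                 methods = methods, seed = as.integer(seed)),
            class = "synth_config")
}

#' Theoretical correlation matrix implied by a method specification
#'
#' @param methods Method specification tibble.
#' @return Correlation matrix with entries
#'   cos(angle_a - angle_b) / sqrt((1 + noise_a^2)(1 + noise_b^2)) off the
#'   diagonal and 1 on it.
#' @export
theoretical_correlation <- function(methods) {
  f <- sqrt(1 + methods$noise^2)
  Omega <- outer(methods$angle, methods$angle,
                 function(a, b) cos(a - b)) / tcrossprod(f)
  diag(Omega) <- 1
  dimnames(Omega) <- list(methods$name, methods$name)
  Omega
}

# two independent RNG streams so corruption/noise choices cannot perturb
# the latent structure drawn from the primary seed
.stream_seed <- function(seed, stream) {
  (as.integer(seed) + 777003L * stream) %% 2147483629L
}

#' Generate a synthetic NAC table with known ground truth
#'
#' @param config A `synth_config`.
#' @return List with `table` (a `nac_table`) and `truth` (list: `latents`
#'   tibble of per-atom t and u, `Omega_theory`, `expected_top` — the
#'   method maximizing the theoretical summed correlation).
#' @examples
#' cfg <- synth_config(n_molecules = 30, seed = 42,
#'                     methods = synth_methods(c("a", "b"), c(0.3, 0.3),
#'                                             c(0, 1)))
#' d <- generate_nac_dataset(cfg)
#' nac_net_charges(d$table)
#' @export
generate_nac_dataset <- function(config) {
  methods <- config$methods
  V <- nrow(methods)

  set.seed(.stream_seed(config$seed, 0L))
  n_atoms <- sample(config$atoms_min:config$atoms_max, config$n_molecules,
                    replace = TRUE)
  charges <- sample(as.integer(names(config$charge_probs)),
                    config$n_molecules, replace = TRUE,
                    prob = config$charge_probs)
  N <- sum(n_atoms)
  mol <- rep(seq_len(config$n_molecules), n_atoms)
  t_lat <- rnorm(N)
  u_lat <- rnorm(N)
  t_lat <- t_lat - stats::ave(t_lat, mol)
  u_lat <- u_lat - stats::ave(u_lat, mol)
  t_lat[n_atoms[mol] == 1] <- 0
  u_lat[n_atoms[mol] == 1] <- 0

  set.seed(.stream_seed(config$seed, 1L))
  eps <- matrix(rnorm(N * V), N, V)

  vals <- matrix(0, N, V, dimnames = list(NULL, methods$name))
  for (a in seq_len(V)) {
    q <- methods$scale[a] * (cos(methods$angle[a]) * t_lat +
                               sin(methods$angle[a]) * u_lat +
                               methods$noise[a] * eps[, a])
    # uniform per-molecule shift: exact integer molecular sums
    shift <- (charges[mol] - stats::ave(q, mol) * n_atoms[mol]) / n_atoms[mol]
    vals[, a] <- q + shift
  }

  tbl <- as_nac_table(dplyr::bind_cols(
    tibble::tibble(
      molecule_id = sprintf("mol%05d", mol),
      atom_index = unlist(lapply(n_atoms, seq_len)) - 1L,
      element = "C",
      net_charge = charges[mol]),
    tibble::as_tibble(vals)))

  Omega_theory <- theoretical_correlation(methods)
  truth <- list(
    latents = tibble::tibble(molecule_id = sprintf("mol%05d", mol),
                             atom_index = unlist(lapply(n_atoms, seq_len)) - 1L,
                             t = t_lat, u = u_lat),
    Omega_theory = Omega_theory,
    expected_top = methods$name[which.max(rowSums(Omega_theory))]
  )
  list(table = tbl, truth = truth)
}

#' Inject controlled corruptions into a NAC table
#'
#' Emulates the three error classes seen in real NAC compilations: small
#' integration jitter spread over a whole method column, missing entries,
#' and isolated erroneously reported values.
#'
#' @param table A `nac_table`.
#' @param spec List of corruption actions, each a list with `action` one of
#'   `"jitter"` (fields `method`, `amplitude`: adds uniform noise on
#'   (-amplitude, amplitude) to every cell of the method), `"delete_cell"`
#'   (fields `molecule_id`, `atom_index`, `method`), or `"offset_cell"`
#'   (those fields plus `delta`).
#' @param seed Seed for the jitter stream (independent of the generator's).
#' @return List with `table` (modified copy) and `log` (tibble of every
#'   changed cell: `molecule_id`, `atom_index`, `method`, `action`, `old`,
#'   `new`).
#' @export
corrupt_dataset <- function(table, spec, seed = 1) {
  set.seed(.stream_seed(seed, 2L))
  log <- tibble::tibble(molecule_id = character(), atom_index = integer(),
                        method = character(), action = character(),
                        old = numeric(), new = numeric())
  record <- function(log, rows, method, action, old, new) {
    dplyr::bind_rows(log, tibble::tibble(
      molecule_id = table$molecule_id[rows],
      atom_index = table$atom_index[rows],
      method = method, action = action, old = old, new = new))
  }
  for (cor in spec) {
    act <- cor$action %||% abort("Corruption entry lacks an 'action' field.")
    if (!is.null(cor$method) && !cor$method %in% nac_methods(table)) {
      abort(paste0("Unknown method: ", cor$method))
    }
    if (act == "jitter") {
      old <- table[[cor$method]]
      jit <- runif(nrow(table), -cor$amplitude, cor$amplitude)
      table[[cor$method]] <- old + jit
      log <- record(log, seq_len(nrow(table)), cor$method, "jitter", old,
                    table[[cor$method]])
    } else if (act %in% c("delete_cell", "offset_cell")) {
      row <- which(table$molecule_id == cor$molecule_id &
                     table$atom_index == cor$atom_index)
      if (length(row) != 1) {
        abort("Corruption targets a cell outside the table.")
      }
      old <- table[[cor$method]][row]
      new <- if (act == "delete_cell") NA_real_ else old + cor$delta
      table[[cor$method]][row] <- new
      log <- record(log, row, cor$method, act, old, new)
    } else {
      abort(paste0("Unknown corruption action: ", act))
    }
  }
  list(table = table, log = log)
}

#' Toy molecules with self-consistent reference ESP grids
#'
#' Fixed geometries whose reference potentials are generated from designated
#' "true" point charges, so a model evaluated with the true charges must
#' score RRMSE = 0% and Delta mu = 0%.
#'
#' @param kind `"bent_AB2"` (water-like: O at the origin, two H at bond
#'   length 1.81 bohr and angle 104.5 degrees, vdW radii O 3.31 and H 2.73
#'   bohr, true charges q_O = -0.7), `"diatomic"` (HF-like polar diatomic),
#'   or `"point"` (a single neutral atom — its reference potential is
#'   identically zero, so ESP errors are undefined by construction).
#' @param spacing Grid spacing (bohr) for the reference shell grid.
#' @return List with `mol`, `charges` (true charges), `grid` (an
#'   `esp_grid` with `reference` filled), and `mu_ref` (au vector).
#' @export
make_toy_molecule <- function(kind = c("bent_AB2", "diatomic", "point"),
                              spacing = 0.4) {
  kind <- match.arg(kind)
  if (kind == "bent_AB2") {
    half <- (104.5 / 2) * pi / 180
    bond <- 1.81
    mol <- molecule(
      c("O", "H", "H"),
      rbind(c(0, 0, 0),
            c(bond * sin(half), 0, -bond * cos(half)),
            c(-bond * sin(half), 0, -bond * cos(half))),
      radii = c(3.31, 2.73, 2.73))
    charges <- c(-0.7, 0.35, 0.35)
  } else if (kind == "diatomic") {
    mol <- molecule(c("H", "F"),
                    rbind(c(0, 0, 0), c(0, 0, 1.73)),
                    radii = c(2.73, 2.78))
    charges <- c(0.4, -0.4)
  } else {
    mol <- molecule("He", rbind(c(0, 0, 0)), radii = 2.65)
    charges <- 0
  }
  grid <- build_vdw_shell_grid(mol, spacing = spacing)
  grid$reference <- point_charge_potential(mol, charges, grid)
  list(mol = mol, charges = charges, grid = grid,
       mu_ref = model_dipole(mol, charges))
}
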