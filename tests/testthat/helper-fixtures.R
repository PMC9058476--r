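# Small fixtures built in code.

# hand-written 3-atom, 2-method table
tiny_nac_table <- function() {
  as_nac_table(tibble::tibble(
    molecule_id = c("w1", "w1", "w1"),
    atom_index = 0:2,
    element = c("O", "H", "H"),
    net_charge = 0L,
    mkA = c(-0.70, 0.35, 0.35),
    mkB = c(-0.64, 0.32, 0.32)
  ))
}

# clean multi-molecule synthetic table, small enough for fast tests
small_synth <- function(seed = 7, n_molecules = 60, methods = NULL) {
  methods <- methods %||% synth_methods(
    name = c("low", "mid", "high", "tilt"),
    scale = c(0.3, 0.2, 0.4, 0.25),
    noise = c(0.1, 0.3, 0.5, 0.2),
    angle = c(0, 0, 0, 0.5))
  generate_nac_dataset(synth_config(n_molecules = n_molecules, seed = seed,
                                    methods = methods))
}

# random correlated pair: shared signal plus independent noise
random_pair <- function(n = 50, slope_sign = 1) {
  s <- rnorm(n)
  list(x = 1.3 * s + 0.4 * rnorm(n) + 0.2,
       y = slope_sign * 0.8 * s + 0.5 * rnorm(n) - 1)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

`%||%` <- function(a, b) if (is.null(a)) b else a
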