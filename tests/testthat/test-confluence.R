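# Two standardized variables with correlation 0.5 give, by direct
# construction, S = (1.5, 1.5), S_phi = sqrt(3), Omega(alpha, phi) =
# 1.5/sqrt(3) = 0.86603 (cov(w1, phi) = 0.75, sigma_phi = sqrt(0.75)).

# builds data whose population correlation matrix is exactly Omega
data_with_correlation <- function(Omega, n = 400) {
  ch <- chol(Omega)
  raw <- matrix(rnorm(n * ncol(Omega)), n)
  W <- standardized_matrix(raw %*% ch)
  # re-impose the target correlation exactly via whitening
  C <- crossprod(W) / n
  W <- W %*% solve(chol(C)) %*% chol(Omega)
  colnames(W) <- colnames(Omega)
  W
}

# random mutually positively correlated ("confluent") correlation matrix
random_confluent_omega <- function(V, noise_max = 0.6) {
  eta <- runif(V, 0.05, noise_max)
  f <- sqrt(1 + eta^2)
  Omega <- 1 / tcrossprod(f)
  diag(Omega) <- 1
  dimnames(Omega) <- list(paste0("m", seq_len(V)), paste0("m", seq_len(V)))
  Omega
}

test_that("relative charge-transfer magnitudes normalize by the reference", {
  withr::local_seed(21)
  d <- small_synth(seed = 21, n_molecules = 40)
  mags <- charge_transfer_magnitudes(d$table, reference = "mid")
  expect_equal(mags$relative[mags$method == "mid"], 1.0)
  expect_equal(mags$sigma, sort(mags$sigma))  # ascending like the summary table
  s <- correlation_summary(d$table)
  expect_equal(mags$relative,
               unname(sort(s$sigma) / s$sigma["mid"]), tolerance = 1e-12)
  expect_error(charge_transfer_magnitudes(d$table, "nope"), "Unknown")
})

test_that("confluence scores match the two-variable construction", {
  withr::local_seed(31)
  W <- data_with_correlation(matrix(c(1, 0.5, 0.5, 1), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  sc <- confluence_scores(W)
  expect_equal(sc$scores$S_alpha, c(1.5, 1.5), tolerance = 1e-10)
  expect_equal(sc$S_phi, sqrt(3), tolerance = 1e-10)
  expect_equal(sc$scores$omega_phi, rep(1.5 / sqrt(3), 2), tolerance = 1e-10)
  expect_equal(sc$sigma_phi, sqrt(0.75), tolerance = 1e-10)
  # Omega(alpha, phi) equals the directly computed correlation with phi
  direct <- cor(W[, "a"], sc$phi)
  expect_equal(sc$scores$omega_phi[1], direct, tolerance = 1e-10)

  # mutually uncorrelated group: S_alpha = 1, S_phi = sqrt(V)
  W0 <- data_with_correlation(diag(3) |>
                                `dimnames<-`(list(letters[1:3], letters[1:3])))
  expect_warning(sc0 <- confluence_scores(W0), "not mutually positive")
  expect_equal(sc0$scores$S_alpha, rep(1, 3), tolerance = 1e-10)
  expect_equal(sc0$S_phi, sqrt(3), tolerance = 1e-10)
})

test_that("correlation PCA: spectrum, conservation, degeneracy, and sign convention", {
  p2 <- nac_pca(matrix(c(1, 0.8, 0.8, 1), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(p2$values, c(1.8, 0.2))
  expect_equal(unname(p2$vectors[, 1]), rep(1 / sqrt(2), 2))
  expect_equal(p2$percent_explained[1], 90)

  pid <- nac_pca(diag(3))
  expect_equal(pid$values, rep(1, 3))
  expect_true(all(pid$degenerate))

  withr::local_seed(41)
  Omega <- random_confluent_omega(20)
  p <- nac_pca(Omega)
  expect_equal(sum(p$values), 20, tolerance = 1e-9)
  expect_true(all(colSums(p$vectors[, 1, drop = FALSE]) > 0))
  expect_equal(crossprod(p$vectors), diag(20), tolerance = 1e-9,
               ignore_attr = TRUE)
  # per-variable decomposition: sum_k lambda_k v_ak^2 = 1
  expect_equal(as.vector(p$vectors^2 %*% p$values), rep(1, 20),
               tolerance = 1e-9)

  expect_error(nac_pca(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("pc_correlation equals the data-level correlation to component scores", {
  expect_equal(pc_correlation(0, 5), 0)
  withr::local_seed(51)
  Omega <- matrix(c(1, 0.8, 0.8, 1), 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  W <- data_with_correlation(Omega)
  p <- nac_pca(Omega)
  expect_equal(pc_correlation(p$vectors["a", 1], p$values[1]),
               sqrt(1.8) / sqrt(2), tolerance = 1e-10)  # 0.94868
  scores1 <- W %*% p$vectors[, 1]
  expect_equal(cor(W[, "a"], scores1)[1],
               pc_correlation(p$vectors["a", 1], p$values[1]),
               tolerance = 1e-10)
  # result lies in [-1, 1] for every variable/component
  all_corr <- sweep(p$vectors, 2, sqrt(p$values), `*`)
  expect_true(all(abs(all_corr) <= 1 + 1e-12))
})

test_that("power iteration from the all-ones trial approximates the MPC", {
  Omega <- matrix(c(1, 0.8, 0.8, 1), 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  one_step <- power_iteration_mpc(Omega, p = 1)
  expect_equal(unname(one_step$vector), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_error(power_iteration_mpc(Omega, trial = c(1, -1)), "orthogonal")

  withr::local_seed(61)
  for (i in 1:5) {
    O20 <- random_confluent_omega(20)
    p <- nac_pca(O20)
    S <- rowSums(O20)
    expect_lt(max(abs(S / sqrt(sum(S^2)) - p$vectors[, 1])), 0.02)
    converged <- power_iteration_mpc(O20, p = 200)
    expect_equal(unname(converged$vector), unname(p$vectors[, 1]),
                 tolerance = 1e-8)
    expect_equal(converged$lambda, p$values[1], tolerance = 1e-8)
  }
})

test_that("S_MPC / S_phi equals the brute-force correlation of phi with MPC scores", {
  withr::local_seed(71)
  for (i in 1:5) {
    Omega <- random_confluent_omega(6)
    W <- data_with_correlation(Omega, n = 300)
    sc <- confluence_scores(W)
    p <- nac_pca(Omega)
    m <- mpc_summary(sc, p)
    scores1 <- W %*% p$vectors[, 1]
    expect_equal(m$omega_phi_mpc, cor(sc$phi, scores1)[1], tolerance = 1e-10)
    expect_lte(m$omega_phi_mpc, 1 + 1e-12)
  }
  # V = 2: phi is proportional to the MPC scores, correlation exactly 1
  O2 <- matrix(c(1, 0.37, 0.37, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  W2 <- data_with_correlation(O2)
  expect_equal(mpc_summary(confluence_scores(W2), nac_pca(O2))$omega_phi_mpc,
               1, tolerance = 1e-10)
  expect_error(mpc_summary(confluence_scores(W2), nac_pca(diag(2))),
               "degenerate|not unique")
})

test_that("threshold counts include self and honor strictness", {
  O3 <- matrix(c(1, .95, .85, .95, 1, .7, .85, .7, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(unname(threshold_counts(diag(3) + 0, cut = 0.8)), rep(1L, 3))
  expect_equal(unname(threshold_counts(O3, 0.9)), c(2L, 2L, 1L))
  expect_equal(unname(threshold_counts(O3, 0.8)), c(3L, 2L, 2L))
  expect_equal(unname(threshold_counts(O3, 0.85, strict = FALSE)),
               c(3L, 2L, 2L))
  expect_equal(unname(threshold_counts(O3, 0.85, strict = TRUE)),
               c(2L, 2L, 1L))
})

test_that("ranking criteria agree where the confluence identities force them to", {
  O3 <- matrix(c(1, .95, .85, .95, 1, .7, .85, .7, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  withr::local_seed(81)
  W <- data_with_correlation(O3, n = 200)
  s <- correlation_summary(W)
  sc <- confluence_scores(W)
  expect_equal(sc$scores$S_alpha, c(2.80, 2.65, 2.55), tolerance = 1e-10)
  expect_equal(sc$superdelegate, "a")
  rk <- rank_methods(s, sc, nac_pca(s$Omega))
  expect_equal(rk$method[rk$criterion == "S_alpha"], c("a", "b", "c"))

  # identities: S_alpha vs omega_phi, and MPC coefficient vs omega_mpc
  for (i in 1:50) {
    O <- random_confluent_omega(sample(3:8, 1))
    Wi <- data_with_correlation(O, n = 150)
    si <- correlation_summary(Wi)
    sci <- confluence_scores(Wi)
    rki <- rank_methods(si, sci, nac_pca(si$Omega))
    expect_equal(rki$method[rki$criterion == "S_alpha"],
                 rki$method[rki$criterion == "omega_phi"])
    expect_equal(rki$method[rki$criterion == "mpc_coefficient"],
                 rki$method[rki$criterion == "omega_mpc"])
  }
})

test_that("block detection recovers connected components and factor structure", {
  O3 <- matrix(c(1, .95, .85, .95, 1, .7, .85, .7, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fb <- find_blocks(O3, 0.9)
  expect_equal(fb$membership$block[fb$membership$method %in% c("a", "b")],
               c(1L, 1L))
  expect_false(fb$membership$block[fb$membership$method == "c"] == 1L)
  expect_equal(fb$adjacency$a, "b")

  expect_equal(sort(table(find_blocks(diag(5) + 0, 0.9)$membership$block)),
               sort(table(1:5)), ignore_attr = TRUE)

  # two tilted factors with low noise separate at a high cut
  methods <- synth_methods(name = sprintf("m%d", 1:6),
                           scale = rep(0.3, 6),
                           noise = rep(0.05, 6),
                           angle = c(0, 0, 0, 1.05, 1.05, 1.05))
  d <- generate_nac_dataset(synth_config(n_molecules = 400, seed = 91,
                                         methods = methods))
  fb2 <- find_blocks(correlation_summary(d$table)$Omega, 0.9)
  got <- split(fb2$membership$method, fb2$membership$block)
  expect_equal(sort(vapply(got, length, integer(1)), decreasing = TRUE),
               c(3L, 3L), ignore_attr = TRUE)
  expect_true(setequal(got[[fb2$membership$block[1]]],
                       c("m1", "m2", "m3")))
})

test_that("phi maximizes summed correlation over random unit combinations", {
  withr::local_seed(111)
  d <- small_synth(seed = 111, n_molecules = 100)
  W <- standardized_matrix(d$table)
  sc <- confluence_scores(d$table)
  n <- nrow(W)
  for (i in 1:200) {
    u <- rnorm(ncol(W))
    tau <- as.vector(W %*% u)
    tau <- (tau - mean(tau)) / sqrt(mean((tau - mean(tau))^2))
    S_tau <- sum(vapply(seq_len(ncol(W)),
                        function(j) sum(tau * W[, j]) / n, numeric(1)))
    expect_lte(S_tau, sc$S_phi + 1e-9)
  }
})

test_that("the MPC maximizes variance and summed squared correlation", {
  withr::local_seed(121)
  d <- small_synth(seed = 121, n_molecules = 100)
  W <- standardized_matrix(d$table)
  s <- correlation_summary(d$table)
  p <- nac_pca(s$Omega)
  lambda_mpc <- p$values[1]
  n <- nrow(W)
  for (i in 1:200) {
    u <- rnorm(ncol(W))
    u <- u / sqrt(sum(u^2))
    comb <- as.vector(W %*% u)
    expect_lte(sum(comb^2) / n, lambda_mpc + 1e-9)
    corr2 <- sum(vapply(seq_len(ncol(W)), function(j) {
      cor(comb, W[, j])^2
    }, numeric(1)))
    expect_lte(corr2, lambda_mpc + 1e-9)
  }
})

test_that("confluent groups keep phi- and MPC-correlations close", {
  withr::local_seed(131)
  for (i in 1:10) {
    Omega <- random_confluent_omega(12, noise_max = 0.5)
    W <- data_with_correlation(Omega, n = 200)
    sc <- confluence_scores(W)
    p <- nac_pca(Omega)
    omega_mpc <- pc_correlation(p$vectors[, 1], p$values[1])
    expect_lt(max(abs(sc$scores$omega_phi - omega_mpc)), 0.02)
  }
  # two methods each highly correlated to phi are highly correlated together
  withr::local_seed(132)
  Omega <- random_confluent_omega(10, noise_max = 0.35)
  W <- data_with_correlation(Omega, n = 300)
  sc <- confluence_scores(W)
  hi <- which(sc$scores$omega_phi > 0.97)
  if (length(hi) >= 2) {
    pairs <- utils::combn(hi, 2)
    expect_true(all(Omega[t(pairs)] > 0.9))
  }
})

test_that("correlation-based outputs are scale invariant; covariance PCA is not", {
  withr::local_seed(141)
  d <- small_synth(seed = 141, n_molecules = 60)
  tbl <- d$table
  scaled <- tbl
  scaled$low <- scaled$low * 7.3
  s1 <- correlation_summary(tbl)
  s2 <- correlation_summary(scaled)
  expect_equal(s1$Omega, s2$Omega, tolerance = 1e-12)
  expect_equal(confluence_scores(tbl)$scores,
               confluence_scores(scaled)$scores, tolerance = 1e-12)
  expect_equal(nac_pca(s1$Omega)$values, nac_pca(s2$Omega)$values,
               tolerance = 1e-12)
  rk1 <- rank_methods(s1, confluence_scores(tbl), nac_pca(s1$Omega))
  rk2 <- rank_methods(s2, confluence_scores(scaled), nac_pca(s2$Omega))
  expect_equal(rk1$method, rk2$method)
  # covariance-kind PCA shifts
  expect_false(isTRUE(all.equal(nac_pca(s1, kind = "covariance")$values,
                                nac_pca(s2, kind = "covariance")$values)))
})
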