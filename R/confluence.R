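# Confluence metrics: the average standardized variable phi, summed
# correlations S_alpha, PCA of the correlation matrix, power-iteration
# diagnostics, threshold counts, block detection, and multi-criterion
# ranking.

summary_or_table <- function(x, convention) {
  if (inherits(x, "correlation_summary")) x else correlation_summary(x, convention)
}

#' Relative charge-transfer magnitudes
#'
#' Reports each method's charge-transfer magnitude sigma (root-mean-squared
#' deviation of its NACs from their average), its average charge q_avg, and
#' sigma relative to a chosen reference method, sorted ascending by sigma.
#'
#' @param x A `correlation_summary`, or anything [correlation_summary()]
#'   accepts.
#' @param reference Name of the reference method (relative magnitude 1).
#' @param convention Divisor convention when `x` is raw data.
#' @return A tibble: `method`, `sigma`, `q_avg`, `relative`.
#' @export
charge_transfer_magnitudes <- function(x, reference,
                                       convention = c("population", "sample")) {
  s <- summary_or_table(x, convention)
  if (!reference %in% s$method_names) {
    abort(paste0("Unknown reference method: ", reference))
  }
  out <- tibble::tibble(method = s$method_names,
                        sigma = unname(s$sigma),
                        q_avg = unname(s$q_avg),
                        relative = unname(s$sigma / s$sigma[reference]))
  dplyr::arrange(out, .data$sigma)
}

#' Confluence scores: phi, summed correlations, and the superdelegate
#'
#' The average standardized variable phi_i is the mean over methods of the
#' standardized NACs at atom i; it is the linear combination of standardized
#' variables maximizing the summed correlation to all group members. For
#' each method, S_alpha sums its correlations to every group member
#' (including the self term Omega_aa = 1); the highest possible summed
#' correlation is S_phi = sqrt(sum(Omega)), achieved by phi itself, and
#' Omega(alpha, phi) = S_alpha / S_phi. The superdelegate is the group
#' member maximizing S_alpha. The phi-based quantities presume a mutually
#' positively correlated group (all Omega_ab > 0); when that premise fails
#' they are still computed but flagged.
#'
#' @param table A `nac_table` or numeric data frame / matrix of method
#'   columns.
#' @param convention Divisor convention, see [standardize()].
#' @return A `confluence_scores` object: tibble-like `scores`
#'   (`method`, `S_alpha`, `omega_phi`), plus `phi` (per-atom values),
#'   `phi_hat` (standardized phi), `sigma_phi`, `S_phi`, `superdelegate`,
#'   `mutually_positive`, and the `Omega` it was computed from.
#' @examples
#' tbl <- data.frame(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' confluence_scores(tbl)$S_phi
#' @export
confluence_scores <- function(table, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  s <- summary_or_table(table, convention)
  W <- standardized_matrix(table, convention)
  Omega <- s$Omega
  V <- length(s$method_names)
  S_alpha <- rowSums(Omega)
  S_phi <- sqrt(sum(Omega))
  phi <- rowMeans(W)
  sigma_phi <- sqrt(sum(phi^2) / s$M)
  mutually_positive <- all(Omega > 0)
  if (!mutually_positive) {
    warn("Correlation matrix is not mutually positive; phi-based quantities lie outside the confluence premise.")
  }
  scores <- tibble::tibble(method = s$method_names,
                           S_alpha = unname(S_alpha),
                           omega_phi = unname(S_alpha / S_phi))
  structure(list(scores = scores, phi = phi, phi_hat = phi / sigma_phi,
                 sigma_phi = sigma_phi, S_phi = S_phi,
                 superdelegate = s$method_names[which.max(S_alpha)],
                 mutually_positive = mutually_positive,
                 Omega = Omega, M = s$M, convention = convention),
            class = "confluence_scores")
}

#' @export
print.confluence_scores <- function(x, ...) {
  cat(sprintf("Confluence scores (V = %d): S_phi = %.5f, superdelegate = %s\n",
              nrow(x$scores), x$S_phi, x$superdelegate))
  print(dplyr::arrange(x$scores, dplyr::desc(.data$S_alpha)), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.confluence_scores <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.confluence_scores <- function(x, ...) {
  tibble::tibble(S_phi = x$S_phi, sigma_phi = x$sigma_phi,
                 superdelegate = x$superdelegate,
                 mutually_positive = x$mutually_positive)
}

#' PCA of a correlation (or covariance) matrix
#'
#' Full symmetric eigendecomposition, components sorted by descending
#' eigenvalue. For a correlation matrix the eigenvalues sum to the number of
#' variables V, so each eigenvalue is "how many variables' worth" of
#' correlation a component explains, and percent explained is
#' lambda / V * 100. Sign convention: the main principal component (MPC) is
#' flipped so its coefficient sum is positive; other components so their
#' largest-magnitude coefficient is positive. Components whose eigenvalue
#' gap is below `degeneracy_tol` are flagged as non-unique (any rotation of
#' a degenerate eigenspace is an equally valid set of eigenvectors).
#'
#' @param x A symmetric matrix, a `correlation_summary`, or a table from
#'   which one is computed.
#' @param kind `"correlation"` (default) or `"covariance"` — which matrix of
#'   a `correlation_summary` to decompose. Ignored when `x` is already a
#'   plain matrix.
#' @param convention Divisor convention when `x` is raw data.
#' @param degeneracy_tol Eigenvalue gap below which adjacent components are
#'   flagged degenerate.
#' @return An `nac_pca` object: `values` (eigenvalues), `vectors` (columns
#'   are components), `percent_explained`, `kind`, `V`, `degenerate`
#'   (logical per component).
#' @examples
#' p <- nac_pca(matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("a","b"), c("a","b"))))
#' p$values
#' @export
nac_pca <- function(x, kind = c("correlation", "covariance"),
                    convention = c("population", "sample"),
                    degeneracy_tol = 1e-9) {
  kind <- match.arg(kind)
  if (is.matrix(x) && nrow(x) == ncol(x) && !is_nac_table(x)) {
    mat <- x
  } else {
    s <- summary_or_table(x, convention)
    mat <- if (kind == "correlation") s$Omega else s$Lambda
  }
  if (max(abs(mat - t(mat))) > 1e-9) abort("Matrix is not symmetric.")
  mat <- (mat + t(mat)) / 2
  eig <- eigen(mat, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  V <- ncol(mat)
  # sign convention
  for (k in seq_len(V)) {
    if (k == 1) {
      if (sum(vecs[, k]) < 0) vecs[, k] <- -vecs[, k]
    } else if (vecs[which.max(abs(vecs[, k])), k] < 0) {
      vecs[, k] <- -vecs[, k]
    }
  }
  rownames(vecs) <- colnames(mat)
  colnames(vecs) <- paste0("PC", seq_len(V))
  gaps <- abs(diff(vals))
  degenerate <- logical(V)
  if (V > 1) {
    degenerate[-V] <- gaps < degeneracy_tol
    degenerate[-1] <- degenerate[-1] | gaps < degeneracy_tol
  }
  structure(list(values = vals, vectors = vecs,
                 percent_explained = vals / V * 100,
                 kind = kind, V = V, degenerate = degenerate),
            class = "nac_pca")
}

#' @export
print.nac_pca <- function(x, ...) {
  cat(sprintf("PCA of %s matrix (V = %d)\n", x$kind, x$V))
  cat("  eigenvalues:", paste(sprintf("%.4f", head(x$values, 6)),
                              collapse = ", "),
      if (x$V > 6) "..." else "", "\n")
  cat(sprintf("  MPC explains %.1f%% of correlation\n",
              x$percent_explained[1]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nac_pca <- function(x, ...) {
  tibble::tibble(component = rep(colnames(x$vectors), each = x$V),
                 method = rep(rownames(x$vectors), times = x$V),
                 coefficient = as.vector(x$vectors),
                 eigenvalue = rep(x$values, each = x$V))
}

#' @exportS3Method generics::glance
glance.nac_pca <- function(x, ...) {
  tibble::tibble(kind = x$kind, V = x$V, lambda_mpc = x$values[1],
                 percent_mpc = x$percent_explained[1],
                 eigenvalue_sum = sum(x$values),
                 any_degenerate = any(x$degenerate))
}

#' Correlation of a variable to a principal component
#'
#' For PCA of the correlation matrix, the correlation between standardized
#' variable alpha and the k-th component equals the variable's coefficient
#' in that component times the square root of the component's eigenvalue.
#'
#' @param coefficient Coefficient v of the variable in the component.
#' @param eigenvalue Eigenvalue lambda of the component (>= 0).
#' @return `coefficient * sqrt(eigenvalue)`.
#' @examples
#' pc_correlation(0.229, 17.158)  # 0.949
#' @export
pc_correlation <- function(coefficient, eigenvalue) {
  if (any(eigenvalue < 0)) abort("eigenvalue must be nonnegative.")
  coefficient * sqrt(eigenvalue)
}

#' Power iteration toward the main principal component
#'
#' Repeatedly applies the correlation matrix to a trial vector and
#' normalizes. For a mutually positively correlated group the all-ones trial
#' is safe, and a single refinement already gives the vector S / ||S||_2 of
#' normalized summed correlations, typically an excellent approximation to
#' the MPC.
#'
#' @param Omega Symmetric correlation matrix.
#' @param trial Starting vector (default all ones).
#' @param p Number of refinements (>= 1).
#' @param tol Vanishing-norm threshold used to detect a trial vector
#'   orthogonal to the dominant eigenvector.
#' @return List with `vector` (unit norm), `lambda` (Rayleigh-quotient
#'   estimate), and `iterations`.
#' @export
power_iteration_mpc <- function(Omega, trial = rep(1, ncol(Omega)), p = 1,
                                tol = 1e-12) {
  if (p < 1) abort("p must be >= 1.")
  v <- trial / sqrt(sum(trial^2))
  for (i in seq_len(p)) {
    v_new <- as.vector(Omega %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm < tol * ncol(Omega)) {
      abort("Trial vector is (numerically) orthogonal to the dominant eigenvector.")
    }
    v <- v_new / nrm
  }
  lam <- as.vector(t(v) %*% Omega %*% v)
  # a correlation matrix has lambda_max >= 1 (trace = V); an iterate stuck
  # below 1 can only happen when the trial had (numerically) no component
  # on the dominant eigenvector
  if (lam < 1 - 1e-9) {
    abort("Trial vector is orthogonal to the dominant eigenvector (iterate converged below the correlation-matrix floor lambda = 1).")
  }
  list(vector = setNames(v, colnames(Omega)), lambda = lam, iterations = p)
}

#' Summed correlation of the MPC and its correlation to phi
#'
#' The sum of correlations between the main principal component and the
#' group members is S_MPC = sqrt(lambda_MPC) * sum(v_MPC), and the
#' correlation between the average standardized variable phi and the MPC is
#' Omega(phi, MPC) = S_MPC / S_phi, necessarily <= 1 and typically extremely
#' close to 1 for a confluent group.
#'
#' @param scores A `confluence_scores` object.
#' @param pca An `nac_pca` of the matching correlation matrix.
#' @return A one-row tibble: `S_mpc`, `omega_phi_mpc`, `lambda_mpc`.
#' @export
mpc_summary <- function(scores, pca) {
  if (pca$kind != "correlation") abort("mpc_summary requires correlation-kind PCA.")
  if (pca$degenerate[1]) {
    abort("Top eigenvalue is degenerate; the MPC is not unique.")
  }
  S_mpc <- sqrt(pca$values[1]) * sum(pca$vectors[, 1])
  tibble::tibble(S_mpc = S_mpc, omega_phi_mpc = S_mpc / scores$S_phi,
                 lambda_mpc = pca$values[1])
}

#' Count of methods correlated above a threshold
#'
#' For each method, the number of group members beta (self included, since
#' Omega_aa = 1 exceeds any threshold below 1) whose correlation to it
#' exceeds `cut`.
#'
#' @param Omega Correlation matrix (or `correlation_summary`).
#' @param cut Threshold in (0, 1).
#' @param strict If `TRUE` (default) count `Omega > cut`, else `>= cut`.
#' @return Named integer vector of counts.
#' @export
threshold_counts <- function(Omega, cut, strict = TRUE) {
  if (inherits(Omega, "correlation_summary")) Omega <- Omega$Omega
  if (cut <= 0 || cut >= 1) abort("cut must lie strictly between 0 and 1.")
  counts <- if (strict) rowSums(Omega > cut) else rowSums(Omega >= cut)
  as.integer(counts) |> setNames(rownames(Omega))
}

#' Rank methods under the standard confluence criteria
#'
#' Produces one ordering per criterion: summed correlation `S_alpha`,
#' correlation to phi `omega_phi`, MPC coefficient `mpc_coefficient`,
#' correlation to the MPC `omega_mpc`, and one count criterion per
#' threshold (`count_gt_<cut>`). Because Omega(alpha, phi) = S_alpha /
#' S_phi and Omega(alpha, MPC) = v_alpha sqrt(lambda_MPC), the first two
#' criteria always order identically, as do the middle two. Ties are broken
#' alphabetically by method name.
#'
#' @param summary A `correlation_summary`.
#' @param scores A `confluence_scores` from the same data.
#' @param pca An `nac_pca` of the same correlation matrix.
#' @param thresholds Numeric thresholds for the count criteria.
#' @param strict Passed to [threshold_counts()].
#' @return A `ranking_table` tibble: `criterion`, `rank`, `method`, `score`.
#' @export
rank_methods <- function(summary, scores, pca, thresholds = c(0.8, 0.9),
                         strict = TRUE) {
  methods <- summary$method_names
  omega_mpc <- pc_correlation(pca$vectors[, 1], pca$values[1])
  crit <- list(
    S_alpha = setNames(scores$scores$S_alpha, scores$scores$method),
    omega_phi = setNames(scores$scores$omega_phi, scores$scores$method),
    mpc_coefficient = setNames(pca$vectors[, 1], methods),
    omega_mpc = setNames(omega_mpc, methods)
  )
  for (cut in thresholds) {
    crit[[sprintf("count_gt_%g", cut)]] <-
      setNames(as.numeric(threshold_counts(summary$Omega, cut, strict)),
               methods)
  }
  out <- purrr::imap_dfr(crit, function(score, name) {
    ord <- order(-score, names(score))
    tibble::tibble(criterion = name, rank = seq_along(score),
                   method = names(score)[ord], score = unname(score[ord]))
  })
  class(out) <- c("ranking_table", class(out))
  out
}

#' Detect blocks of mutually highly correlated methods
#'
#' Blocks are the connected components of the graph whose edges join method
#' pairs with Omega >= cut. A display ordering is returned that keeps each
#' component contiguous and sorts components by size (largest first) and
#' members by within-component connectivity, so a correlation heatmap shows
#' the block structure.
#'
#' @param Omega Correlation matrix (or `correlation_summary`).
#' @param cut Threshold in (0, 1); edges require `Omega >= cut`.
#' @return List with `membership` (tibble `method`, `block`), `adjacency`
#'   (named list of each method's high-correlation partners, self excluded),
#'   and `ordering` (character vector of methods for display).
#' @export
find_blocks <- function(Omega, cut = 0.9) {
  if (inherits(Omega, "correlation_summary")) Omega <- Omega$Omega
  if (cut <= 0 || cut >= 1) abort("cut must lie strictly between 0 and 1.")
  if (is.null(rownames(Omega))) {
    rownames(Omega) <- colnames(Omega) <- paste0("M", seq_len(ncol(Omega)))
  }
  methods <- rownames(Omega)
  adj_mat <- (Omega >= cut)
  diag(adj_mat) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj_mat, mode = "undirected")
  comp <- igraph::components(g)
  membership <- tibble::tibble(method = methods,
                               block = as.integer(comp$membership))
  adjacency <- purrr::map(setNames(methods, methods),
                          function(m) methods[adj_mat[m, ]])
  # order: big blocks first, most-connected members first within a block
  degree <- rowSums(adj_mat)
  ord <- order(-comp$csize[comp$membership], comp$membership, -degree, methods)
  list(membership = membership, adjacency = adjacency,
       ordering = methods[ord])
}

#' Run the full confluence analysis of a NAC table
#'
#' Convenience wrapper chaining [correlation_summary()],
#' [confluence_scores()], [nac_pca()], [mpc_summary()], and
#' [rank_methods()].
#'
#' @param table A `nac_table` or numeric data frame of method columns.
#' @param reference Reference method for relative charge-transfer
#'   magnitudes (default: the superdelegate).
#' @param thresholds Count-criterion thresholds.
#' @param convention Divisor convention.
#' @return A `confluence_analysis` list: `summary`, `scores`, `pca`, `mpc`,
#'   `magnitudes`, `ranking`, `blocks`.
#' @export
confluence_analysis <- function(table, reference = NULL,
                                thresholds = c(0.8, 0.9),
                                convention = c("population", "sample")) {
  convention <- match.arg(convention)
  s <- correlation_summary(table, convention)
  scores <- confluence_scores(table, convention)
  pca <- nac_pca(s, kind = "correlation")
  structure(list(
    summary = s,
    scores = scores,
    pca = pca,
    mpc = mpc_summary(scores, pca),
    magnitudes = charge_transfer_magnitudes(s, reference %||% scores$superdelegate),
    ranking = rank_methods(s, scores, pca, thresholds),
    blocks = find_blocks(s$Omega, max(thresholds))
  ), class = "confluence_analysis")
}

#' @export
print.confluence_analysis <- function(x, ...) {
  print(x$scores)
  cat(sprintf("MPC: lambda = %.4f (%.1f%%), Omega(phi, MPC) = %.5f\n",
              x$pca$values[1], x$pca$percent_explained[1],
              x$mpc$omega_phi_mpc))
  invisible(x)
}
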