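# Standardization, covariance/correlation with an explicit divisor
# convention, simple (irreversible) least squares, and instant least squares
# fitting (ILSF): the reversible regression of standardized variables whose
# optimum is the universal line w = z, simultaneously a total least squares
# fit, an orthogonal distance regression, and a PCA regression.

divisor <- function(n, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (convention == "population") n else n - 1
}

#' Standardize a numeric variable
#'
#' Shifts to zero mean and scales to unit standard deviation, with an
#' optional sign flip s: w_i = (x_i - mean(x)) * s / sigma. The divisor
#' convention (population M = N, or sample M = N - 1) must be chosen once
#' and used uniformly across all variables entering a joint analysis.
#'
#' @param values Numeric vector, length >= 2.
#' @param sign Either +1 or -1.
#' @param convention `"population"` (divide by N; the default) or
#'   `"sample"` (divide by N - 1).
#' @return A `standardized_variable`: list with `values` (the standardized
#'   w_i), `mean`, `sigma`, `sign`, `M`, and `convention`.
#' @examples
#' standardize(c(1, 2, 3))$values
#' @export
standardize <- function(values, sign = 1,
                        convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (length(values) < 2) abort("Need at least 2 values to standardize.")
  if (anyNA(values)) abort("Missing values are not allowed; drop rows explicitly.")
  if (!sign %in% c(-1, 1)) abort("sign must be +1 or -1.")
  m <- length(values)
  M <- divisor(m, convention)
  mu <- mean(values)
  sigma <- sqrt(sum((values - mu)^2) / M)
  if (sigma <= 0) abort("Degenerate variance: input is constant.")
  structure(list(values = (values - mu) * sign / sigma,
                 mean = mu, sigma = sigma, sign = sign, M = M,
                 convention = convention),
            class = "standardized_variable")
}

#' Inverse of [standardize()]
#'
#' @param sv A `standardized_variable`.
#' @return The original-unit values.
#' @export
unstandardize <- function(sv) {
  sv$values * sv$sigma / sv$sign + sv$mean
}

std_values <- function(x) {
  if (inherits(x, "standardized_variable")) x$values else x
}

#' Charge-transfer magnitudes, covariance, and correlation of a NAC table
#'
#' For each method the root-mean-squared deviation sigma from its average
#' NAC (the charge-transfer magnitude, in e), the average charge q_avg, the
#' covariance matrix Lambda (e^2), and the dimensionless correlation matrix
#' Omega = Lambda_ab / (sigma_a sigma_b) are computed with a single divisor
#' convention across all methods.
#'
#' @param table A `nac_table`, or a plain data frame / matrix of numeric
#'   columns (one column per method).
#' @param convention Divisor convention, see [standardize()].
#' @return A `correlation_summary`: list with `method_names`, `sigma`,
#'   `q_avg`, `Lambda`, `Omega`, `n`, and `convention`.
#' @examples
#' s <- correlation_summary(data.frame(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4)))
#' s$Omega
#' @export
correlation_summary <- function(table, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  vals <- if (is_nac_table(table)) nac_values(table) else as.matrix(table)
  if (anyNA(vals)) {
    abort("Missing NAC values present; drop the affected rows explicitly first.")
  }
  n <- nrow(vals)
  if (n < 2) abort("Need at least 2 rows.")
  M <- divisor(n, convention)
  q_avg <- colMeans(vals)
  centered <- sweep(vals, 2, q_avg)
  Lambda <- crossprod(centered) / M
  sigma <- sqrt(diag(Lambda))
  if (any(sigma <= 0)) {
    abort(paste0("Degenerate variance in column(s): ",
                 paste(colnames(vals)[sigma <= 0], collapse = ", ")))
  }
  Omega <- Lambda / tcrossprod(sigma)
  diag(Omega) <- 1
  structure(list(method_names = colnames(vals), sigma = sigma, q_avg = q_avg,
                 Lambda = Lambda, Omega = Omega, n = n, M = M,
                 convention = convention),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat("Correlation summary of", length(x$method_names), "methods over",
      x$n, "atoms (", x$convention, "convention )\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn correlation_summary One row per method: sigma, q_avg.
#' @param x A `correlation_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.correlation_summary <- function(x, ...) {
  tibble::tibble(method = x$method_names, sigma = unname(x$sigma),
                 q_avg = unname(x$q_avg))
}

#' Standardized value matrix of a NAC table
#'
#' @inheritParams correlation_summary
#' @return Numeric matrix of standardized columns (all signs +1).
#' @export
standardized_matrix <- function(table, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  vals <- if (is_nac_table(table)) nac_values(table) else as.matrix(table)
  apply(vals, 2, function(col) standardize(col, convention = convention)$values)
}

#' Simple (irreversible) least squares fit, both directions
#'
#' Ordinary least squares of y on x yields slope m = Lambda_xy / sigma_x^2;
#' fitting x on y yields a second line that is generally not the algebraic
#' inverse of the first. The reversibility defect |m m' - 1| is zero only
#' for perfectly correlated data (|Omega| = 1).
#'
#' @param x,y Numeric vectors of equal length.
#' @param convention Divisor convention (the fitted lines do not depend on
#'   it; reported moments do).
#' @return An `slsf` object with components `m`, `c` (y on x), `m_rev`,
#'   `c_rev` (x on y), `omega`, and `reversibility_defect`.
#' @export
slsf_fit <- function(x, y, convention = c("population", "sample")) {
  s <- correlation_summary(cbind(x = x, y = y), convention)
  m <- s$Lambda["x", "y"] / s$Lambda["x", "x"]
  c_ <- s$q_avg["y"] - m * s$q_avg["x"]
  m_rev <- s$Lambda["x", "y"] / s$Lambda["y", "y"]
  c_rev <- s$q_avg["x"] - m_rev * s$q_avg["y"]
  structure(list(m = unname(m), c = unname(c_), m_rev = unname(m_rev),
                 c_rev = unname(c_rev), omega = unname(s$Omega["x", "y"]),
                 reversibility_defect = unname(abs(m * m_rev - 1))),
            class = "slsf")
}

#' @export
print.slsf <- function(x, ...) {
  cat(sprintf("SLSF: y = %.6g x + %.6g ; x = %.6g y + %.6g\n",
              x$m, x$c, x$m_rev, x$c_rev))
  cat(sprintf("  Omega = %.6g ; reversibility defect |m m' - 1| = %.6g\n",
              x$omega, x$reversibility_defect))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slsf <- function(x, ...) {
  tibble::tibble(direction = c("y_on_x", "x_on_y"),
                 slope = c(x$m, x$m_rev), intercept = c(x$c, x$c_rev))
}

#' @exportS3Method generics::glance
glance.slsf <- function(x, ...) {
  tibble::tibble(omega = x$omega,
                 reversibility_defect = x$reversibility_defect)
}

#' Instant least squares fitting (ILSF)
#'
#' Standardizes both variables with s_x = 1 and s_y = sign(Lambda_xy), so
#' the standardized pair (w, z) is positively correlated, and returns the
#' universal reversible model z = w, i.e. (zeta, eta) = (1, 0). This single
#' line is simultaneously the total least squares fit, the orthogonal
#' distance regression, and the first-principal-component regression of the
#' standardized pair. At the optimum the TLS loss is L1 = 4 M (1 - Omega_wz)
#' and the ODR loss is L2 = M (1 - Omega_wz), so L1 = 4 L2, and the fit
#' quality equals Omega_wz = |Omega_xy|. If Lambda_xy = 0 the model
#' collapses to the single point (mean(x), mean(y)).
#'
#' @param x,y Numeric vectors of equal length.
#' @param convention Divisor convention, see [standardize()].
#' @return An `ilsf` object: `zeta`, `eta`, `omega_wz`, `L1`, `L2`,
#'   `quality`, `degenerate`, `slope`/`intercept` of the back-transformed
#'   original-unit line y = y_avg + s_y (sigma_y/sigma_x)(x - x_avg), plus
#'   the standardized variables `w` and `z`.
#' @examples
#' fit <- ilsf_fit(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' glance(fit)
#' @export
ilsf_fit <- function(x, y, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  s <- correlation_summary(cbind(x = x, y = y), convention)
  lam <- s$Lambda["x", "y"]
  if (abs(lam) < 1e-12 * s$sigma["x"] * s$sigma["y"]) {
    return(structure(list(zeta = NA_real_, eta = NA_real_,
                          omega_wz = 0, L1 = NA_real_, L2 = NA_real_,
                          quality = 0, degenerate = TRUE,
                          point = c(x = unname(s$q_avg["x"]),
                                    y = unname(s$q_avg["y"])),
                          slope = NA_real_, intercept = NA_real_,
                          M = s$M, w = NULL, z = NULL),
                     class = "ilsf"))
  }
  s_y <- sign(lam)
  w <- standardize(x, sign = 1, convention = convention)
  z <- standardize(y, sign = s_y, convention = convention)
  omega_wz <- abs(s$Omega["x", "y"])
  M <- s$M
  slope <- s_y * s$sigma["y"] / s$sigma["x"]
  structure(list(zeta = 1, eta = 0, omega_wz = unname(omega_wz),
                 L1 = unname(4 * M * (1 - omega_wz)),
                 L2 = unname(M * (1 - omega_wz)),
                 quality = unname(omega_wz), degenerate = FALSE,
                 point = NULL,
                 slope = unname(slope),
                 intercept = unname(s$q_avg["y"] - slope * s$q_avg["x"]),
                 M = M, w = w, z = z),
            class = "ilsf")
}

#' @export
print.ilsf <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("ILSF: degenerate (uncorrelated); model collapses to point (%.6g, %.6g)\n",
                x$point["x"], x$point["y"]))
  } else {
    cat(sprintf("ILSF: standardized model z = w ; original units y = %.6g x + %.6g\n",
                x$slope, x$intercept))
    cat(sprintf("  Omega_wz = %.6g ; L1 = %.6g ; L2 = %.6g ; quality = %.6g\n",
                x$omega_wz, x$L1, x$L2, x$quality))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ilsf <- function(x, ...) {
  tibble::tibble(term = c("zeta", "eta", "slope", "intercept"),
                 estimate = c(x$zeta, x$eta, x$slope, x$intercept))
}

#' @exportS3Method generics::glance
glance.ilsf <- function(x, ...) {
  tibble::tibble(omega_wz = x$omega_wz, L1 = x$L1, L2 = x$L2,
                 quality = x$quality, degenerate = x$degenerate)
}

#' Evaluate the TLS and ODR losses of a candidate standardized line
#'
#' For the line z = zeta w + eta and a standardized pair (w, z), the
#' vertical residual is dz_i = zeta w_i + eta - z_i and the horizontal
#' residual dw_i = -dz_i / zeta. The total least squares loss sums both
#' squared residuals, L1 = sum(dw_i^2 + dz_i^2); the orthogonal distance
#' regression loss sums the squared perpendicular distances,
#' L2 = sum(dz_i^2) / (1 + zeta^2).
#'
#' @param zeta,eta Line parameters; `zeta` must be nonzero (the TLS
#'   parameterization needs a finite horizontal residual).
#' @param w,z `standardized_variable`s or plain numeric vectors.
#' @return Named numeric vector `c(L1 = , L2 = )`.
#' @export
evaluate_losses <- function(zeta, eta, w, z) {
  if (zeta == 0) abort("zeta must be nonzero in the TLS parameterization.")
  wv <- std_values(w)
  zv <- std_values(z)
  dz <- zeta * wv + eta - zv
  dw <- -dz / zeta
  c(L1 = sum(dw^2 + dz^2), L2 = sum(dz^2) / (1 + zeta^2))
}
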