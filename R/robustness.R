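# Sensitivity of the confluence ranking to dataset manipulation: spamming
# with trivial variants of one method, +/-1 perturbations of threshold
# counts, and re-ranking on method subsets.

#' Closed-form summed-correlation update under spamming
#'
#' Adding k trivial variants of a target method (each correlating
#' `omega_to_target` with a given method) raises that method's summed
#' correlation to `S_old + k * omega_to_target`; for the target itself
#' `omega_to_target` is 1.
#'
#' @param S_old Summed correlation before spamming.
#' @param k Number of added variants.
#' @param omega_to_target Correlation of the method to the spammed target.
#' @return Updated summed correlation.
#' @examples
#' spam_updated_s(17.600, 1000, 1.0)
#' @export
spam_updated_s <- function(S_old, k, omega_to_target) {
  S_old + k * omega_to_target
}

#' Spam analysis: add k trivial variants of one method
#'
#' Models spamming the dataset with k copies of one method that correlate
#' 1.0 with it and inherit its correlation row to every other method. The
#' summed correlations then update in closed form: the spammed method gains
#' exactly k, and any other method alpha gains k * Omega(alpha, target);
#' its threshold count at cut c gains k iff Omega(alpha, target) > c (the
#' spammed method always gains k, since the variants correlate 1 with it).
#' For `k <= explicit_limit` the enlarged (V+k) x (V+k) correlation matrix
#' is also built explicitly and the closed forms verified against its row
#' sums. Spamming produces a ranking abnormality whenever the top method by
#' summed correlation differs from the top method by the count criterion.
#'
#' @param summary A `correlation_summary`.
#' @param scores Matching `confluence_scores`.
#' @param target Method to spam.
#' @param k Number of trivial variants to add (>= 0).
#' @param thresholds Count-criterion thresholds.
#' @param strict Passed to [threshold_counts()].
#' @param explicit_limit Largest k for which the enlarged matrix is built
#'   for verification.
#' @return A `spam_result`: tibble `methods` (per original method:
#'   `S_old`, `S_new`, and old/new counts per threshold), plus `target`,
#'   `k`, `ranking_abnormality`, `top_by_S`, `top_by_count`, and
#'   `explicit_max_error` (NA when the explicit check was skipped).
#' @export
spam_analysis <- function(summary, scores, target, k, thresholds = c(0.8, 0.9),
                          strict = TRUE, explicit_limit = 1000) {
  if (k < 0) abort("k must be >= 0.")
  methods <- summary$method_names
  if (!target %in% methods) abort(paste0("Unknown method: ", target))
  Omega <- summary$Omega
  omega_t <- Omega[, target]
  S_old <- setNames(scores$scores$S_alpha, scores$scores$method)[methods]
  S_new <- spam_updated_s(S_old, k, omega_t)

  out <- tibble::tibble(method = methods, omega_target = unname(omega_t),
                        S_old = unname(S_old), S_new = unname(S_new))
  for (cut in thresholds) {
    old_counts <- threshold_counts(Omega, cut, strict)
    gain <- ifelse(
      methods == target, k,
      k * as.integer(if (strict) omega_t > cut else omega_t >= cut))
    out[[sprintf("count_old_%g", cut)]] <- as.integer(old_counts[methods])
    out[[sprintf("count_new_%g", cut)]] <-
      as.integer(old_counts[methods] + gain)
  }

  explicit_max_error <- NA_real_
  if (k > 0 && k <= explicit_limit) {
    big <- enlarge_with_variants(Omega, target, k)
    S_big <- rowSums(big)[seq_along(methods)]
    explicit_max_error <- max(abs(S_big - S_new))
  }

  top_cut <- max(thresholds)
  top_by_S <- methods[which.max(S_new)]
  new_counts <- out[[sprintf("count_new_%g", top_cut)]]
  top_by_count <- methods[order(-new_counts, methods)][1]

  structure(list(methods = out, target = target, k = k,
                 thresholds = thresholds,
                 top_by_S = top_by_S, top_by_count = top_by_count,
                 ranking_abnormality = !identical(top_by_S, top_by_count),
                 explicit_max_error = explicit_max_error),
            class = "spam_result")
}

# (V+k) x (V+k) correlation matrix after appending k perfect copies of
# `target` that inherit its correlation row.
enlarge_with_variants <- function(Omega, target, k) {
  V <- ncol(Omega)
  methods <- rownames(Omega)
  big <- matrix(1, V + k, V + k)
  big[seq_len(V), seq_len(V)] <- Omega
  if (k > 0) {
    rows <- (V + 1):(V + k)
    big[rows, seq_len(V)] <- matrix(Omega[target, ], k, V, byrow = TRUE)
    big[seq_len(V), rows] <- t(big[rows, seq_len(V)])
    big[rows, rows] <- 1
  }
  rownames(big) <- colnames(big) <- c(methods, paste0(target, "_variant",
                                                      seq_len(k)))
  big
}

#' @export
print.spam_result <- function(x, ...) {
  cat(sprintf("Spam analysis: %d trivial variants of %s\n", x$k, x$target))
  cat(sprintf("  top by S: %s ; top by count(>%g): %s ; abnormality: %s\n",
              x$top_by_S, max(x$thresholds), x$top_by_count,
              x$ranking_abnormality))
  print(x$methods, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spam_result <- function(x, ...) x$methods

#' Rank stability under +/-1 count perturbations
#'
#' For each method, its best-case rank is computed after raising its own
#' threshold count by one while lowering every other method's by one, and
#' its worst-case rank after the reverse perturbation. Rank 1 is best; ties
#' share the better (smaller) rank.
#'
#' @param counts Named integer vector of per-method threshold counts.
#' @return A tibble: `method`, `count`, `best_rank`, `worst_rank`.
#' @export
swap_sensitivity <- function(counts) {
  if (is.null(names(counts))) names(counts) <- paste0("M", seq_along(counts))
  if (any(counts < 1)) abort("Counts include the self term and must be >= 1.")
  rank_of <- function(v, i) 1L + sum(v[-i] > v[i])
  n <- length(counts)
  best <- worst <- integer(n)
  for (i in seq_len(n)) {
    up <- counts; up[i] <- up[i] + 1L; up[-i] <- up[-i] - 1L
    dn <- counts; dn[i] <- dn[i] - 1L; dn[-i] <- dn[-i] + 1L
    best[i] <- rank_of(up, i)
    worst[i] <- rank_of(dn, i)
  }
  tibble::tibble(method = names(counts), count = as.integer(counts),
                 best_rank = best, worst_rank = worst)
}

#' Re-rank a subset of methods
#'
#' Recomputes the correlation matrix, confluence scores, PCA, and rankings
#' on a column subset of the NAC table.
#'
#' @param table A `nac_table` or numeric data frame of method columns.
#' @param keep Character vector of method names to retain (>= 2).
#' @param thresholds Count-criterion thresholds.
#' @param convention Divisor convention.
#' @return A `ranking_table` (see [rank_methods()]).
#' @export
subset_rerank <- function(table, keep, thresholds = c(0.8, 0.9),
                          convention = c("population", "sample")) {
  convention <- match.arg(convention)
  avail <- if (is_nac_table(table)) nac_methods(table) else colnames(table)
  unknown <- setdiff(keep, avail)
  if (length(unknown) > 0) {
    abort(paste0("Unknown method(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(keep) < 2) abort("Need at least 2 methods to re-rank.")
  sub <- if (is_nac_table(table)) {
    tibble::as_tibble(table)[c(.nac_meta_cols, keep)]
  } else {
    as.data.frame(table)[keep]
  }
  s <- correlation_summary(sub[keep], convention)
  scores <- confluence_scores(sub[keep], convention)
  pca <- nac_pca(s, kind = "correlation")
  rank_methods(s, scores, pca, thresholds)
}
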