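#' Fuse two class-probability vectors with the power posterior
#'
#' Combines a per-tree class-probability vector `p1` with the class-level
#' reliability vector `p2` (the row-normalized confusion-matrix diagonal)
#' while tempering for their non-independence. The exponent applied to the
#' second source is `alpha = 1 - |rho|`, where `rho` is the Pearson
#' correlation between the two vectors across classes: perfectly correlated
#' evidence is treated as a pure repeat (`alpha = 0`, `p2` ignored), while
#' uncorrelated evidence enters as a full Bayesian product (`alpha = 1`).
#' The fused vector is `p1 * p2^alpha`, renormalized to sum to one.
#'
#' When either vector is constant across classes the correlation is
#' undefined; `rho` is then taken as 0, i.e. full product fusion. (Note that
#' a constant `p2` rescales every class equally, so the result is `p1`
#' either way.)
#'
#' @param p1 numeric probability vector over `K >= 2` classes (e.g. one
#'   decision tree's class probabilities for a cell).
#' @param p2 numeric probability vector over the same classes (class-level
#'   accuracy from the confusion-matrix diagonal).
#' @return The fused posterior probability vector (sums to one).
#' @examples
#' fuse_power_posterior(c(0.7, 0.2, 0.1), rep(1, 3) / 3)  # uniform p2: p1 back
#' fuse_power_posterior(c(0.6, 0.3, 0.1), c(0.5, 0.2, 0.3))
#' @export
fuse_power_posterior <- function(p1, p2) {
  check_prob_vector(p1, "p1")
  check_prob_vector(p2, "p2")
  if (length(p1) != length(p2)) abort("`p1` and `p2` must have equal length.")
  if (length(p1) < 2L) abort("at least two classes are required.")
  rho <- if (sd(p1) == 0 || sd(p2) == 0) 0 else cor(p1, p2)
  a <- 1 - abs(rho)
  w <- p1 * p2^a
  w / sum(w)
}

check_prob_vector <- function(p, name) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must have entries in [0, 1].", name))
  }
  if (abs(sum(p) - 1) > 1e-6) {
    abort(sprintf("`%s` must sum to 1 (got %.8f).", name, sum(p)))
  }
  invisible(p)
}

#' Fuse a tree ensemble's probabilities into type-1/type-2 membership
#'
#' Applies [fuse_power_posterior()] to each ensemble member's probability
#' vector separately (trees are repeated estimates of the same quantity, so
#' their evidence is never chain-multiplied), then summarizes across trees:
#' the mean fused probability per class is the type-1 membership and the
#' across-tree variance is the type-2 uncertainty.
#'
#' @param tree_probs numeric matrix, one row per ensemble member, one column
#'   per class; each row a probability vector.
#' @param confusion_diag probability vector over classes from the
#'   row-normalized confusion-matrix diagonal.
#' @return A tibble with columns `class`, `membership` (type-1 mean) and
#'   `variance` (across-tree variance of the fused probabilities).
#' @examples
#' probs <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2), c(0.6, 0.25, 0.15))
#' fuse_tree_ensemble(probs, c(0.5, 0.3, 0.2))
#' @export
fuse_tree_ensemble <- function(tree_probs, confusion_diag) {
  if (!is.matrix(tree_probs)) tree_probs <- rbind(tree_probs)
  fused <- t(apply(tree_probs, 1L, fuse_power_posterior, p2 = confusion_diag))
  labels <- colnames(tree_probs)
  if (is.null(labels)) labels <- paste0("class_", seq_len(ncol(tree_probs)))
  v <- if (nrow(fused) > 1L) apply(fused, 2L, stats::var) else rep(0, ncol(fused))
  tibble::tibble(class = labels,
                 membership = colMeans(fused),
                 variance = v)
}

#' Read ensemble probabilities and a confusion matrix from CSV
#'
#' `read_tree_probs()` expects one row per ensemble member and one column
#' per class. `read_confusion_diag()` expects a K x K confusion matrix
#' (rows = reference classes); rows are normalized to sum to one, the
#' diagonal — the per-class probability of correct prediction — is
#' extracted, and that diagonal is itself normalized to a probability
#' vector over classes (the form [fuse_power_posterior()] expects).
#'
#' @param path path to a CSV file.
#' @return `read_tree_probs()`: a numeric matrix; `read_confusion_diag()`:
#'   a named probability vector summing to one.
#' @export
read_tree_probs <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) abort("tree-probability CSV must be all numeric.")
  m
}

#' @rdname read_tree_probs
#' @export
read_confusion_diag <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("confusion matrix must be square (got %d x %d).",
                  nrow(m), ncol(m)))
  }
  rs <- rowSums(m)
  if (any(rs <= 0)) abort("confusion matrix has a row summing to zero.")
  d <- diag(m / rs)
  if (sum(d) <= 0) abort("confusion matrix diagonal is all zero.")
  d <- d / sum(d)
  names(d) <- colnames(m)
  d
}
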