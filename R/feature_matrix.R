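#' Feature matrix over discrete sites
#'
#' Stores the bounded feature map \eqn{\Phi : \{1,\dots,n\} \to R^m} as an
#' \eqn{m \times n} matrix (rows = features, columns = sites), together with
#' the cached max-column Euclidean norm. Viewed as the linear operator
#' \eqn{A p = \sum_j p(j)\Phi(j)} from the probability simplex to \eqn{R^m},
#' the max-column norm is exactly the induced \eqn{(\ell_1 \to \ell_2)}
#' operator norm \eqn{\|A\|_{op}}, computable in a single \eqn{\Theta(mn)}
#' pass — the quantity that governs NPDHG stepsize feasibility.
#'
#' @param values numeric matrix, features by sites (m x n), all entries finite.
#' @param feature_names optional character vector of length m.
#' @param site_ids optional character vector of length n.
#' @return An object of class `feature_matrix` with elements `values`, `m`,
#'   `n`, `op_norm`, `feature_names`, `site_ids`.
#' @examples
#' fm <- feature_matrix(matrix(c(3, 4, 1, 0), nrow = 2))
#' operator_norm(fm) # 5
#' @export
feature_matrix <- function(values, feature_names = NULL, site_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("feature matrix entries must all be finite", call. = FALSE)
  }
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L || n < 2L) {
    stop("feature matrix needs at least 1 feature and 2 sites", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- rownames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(m))
  }
  if (is.null(site_ids)) {
    site_ids <- colnames(values)
    if (is.null(site_ids)) site_ids <- paste0("s", seq_len(n))
  }
  stopifnot(length(feature_names) == m, length(site_ids) == n)
  dimnames(values) <- NULL
  structure(
    list(
      values = values, m = m, n = n,
      op_norm = sqrt(max(colSums(values^2))),
      feature_names = as.character(feature_names),
      site_ids = as.character(site_ids)
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d features x %d sites, ||A||_op = %.6g\n",
    x$m, x$n, x$op_norm
  ))
  invisible(x)
}

is_feature_matrix <- function(x) inherits(x, "feature_matrix")

#' Induced (l1 -> l2) operator norm
#'
#' The maximum over sites of the Euclidean norm of the feature vector,
#' cached at construction time.
#'
#' @param features a [feature_matrix()].
#' @return scalar \eqn{\|A\|_{op}}.
#' @export
operator_norm <- function(features) {
  stopifnot(is_feature_matrix(features))
  features$op_norm
}

#' Largest singular value by power iteration
#'
#' Computes \eqn{\|A\|_2}, the largest singular value of the feature matrix,
#' by power iteration on the smaller of the two Gram matrices, starting from
#' the normalized all-ones vector so results are deterministic. This is the
#' (expensive) norm classical first-order methods need for their stepsizes;
#' here it is only used by the forward-backward splitting baseline and as a
#' diagnostic.
#'
#' @param features a [feature_matrix()].
#' @param tol relative accuracy on the singular value (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return scalar \eqn{\|A\|_2 \ge \|A\|_{op}}... equality only in degenerate
#'   cases; always at least `operator_norm(features)` up to roundoff.
#' @export
spectral_norm <- function(features, tol = 1e-10, max_iter = 10000L) {
  stopifnot(is_feature_matrix(features), tol > 0)
  A <- features$values
  # iterate on the smaller Gram matrix
  G <- if (features$m <= features$n) A %*% t(A) else crossprod(A)
  d <- nrow(G)
  v <- rep(1 / sqrt(d), d)
  lam <- 0
  for (k in seq_len(max_iter)) {
    gv <- G %*% v
    lam_new <- sqrt(sum(gv^2)) # ||Gv|| with ||v|| = 1
    if (lam_new == 0) return(0) # zero matrix
    v <- drop(gv) / lam_new
    if (abs(lam_new - lam) <= tol * max(lam_new, .Machine$double.xmin)) {
      return(sqrt(lam_new))
    }
    lam <- lam_new
  }
  stop(sprintf(
    "power iteration did not reach tol %g in %d iterations (last eigenvalue %g)",
    tol, max_iter, lam
  ), call. = FALSE)
}
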