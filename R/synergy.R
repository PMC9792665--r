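#' Muscle synergy set
#'
#' A rank-k non-negative factorization of a muscle-activation matrix
#' `A (nMusc x nPt) ~ W %*% H`: `H` holds k time-varying synergy activations
#' (rows) and `W` the time-invariant synergy vectors (one row of weights per
#' muscle).
#'
#' @param W nonnegative `nMusc x k` synergy-vector weight matrix.
#' @param H nonnegative `k x nPt` synergy-activation matrix.
#' @param muscle_labels names for the rows of `W`.
#' @param side `"left"`, `"right"`, or `NA` when sides are not meaningful.
#' @return An object of class `synergy_set`.
#' @export
synergy_set <- function(W, H, muscle_labels = rownames(W), side = NA_character_) {
  W <- as.matrix(W); H <- as.matrix(H)
  if (ncol(W) != nrow(H)) {
    stop_trunksyn("argument_error", "ncol(W) must equal nrow(H)")
  }
  if (min(W) < 0 || min(H) < 0) {
    stop_trunksyn("argument_error", "synergy factors must be nonnegative")
  }
  if (!is.null(muscle_labels)) rownames(W) <- muscle_labels
  structure(list(W = W, H = H, muscle_labels = rownames(W), side = side),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> k=%d synergies, %d muscles, %d samples%s\n",
              ncol(x$W), nrow(x$W), ncol(x$H),
              if (is.na(x$side)) "" else paste0(" (", x$side, " side)")))
  invisible(x)
}

# one multiplicative-update (Lee-Seung, Frobenius) NMF run from a given init
nmf_run <- function(A, W, H, tol, max_iter) {
  eps <- 1e-12
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A) / (crossprod(W) %*% H + eps))
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- norm(A - W %*% H, "F")
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(W = W, H = H, err = norm(A - W %*% H, "F"), iters = it)
}

#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes a nonnegative activation matrix `A (nMusc x nPt)` into k
#' synergies minimizing the Frobenius reconstruction error, using
#' multiplicative updates from `restarts` random nonnegative initializations;
#' the lowest-error factorization is kept. Deterministic for a fixed `seed`.
#'
#' @param A nonnegative `nMusc x nPt` activation matrix (rows = muscles).
#' @param k number of synergies, `1 <= k <= min(dim(A))`.
#' @param restarts random restarts (default 20).
#' @param seed integer RNG seed.
#' @param side passed through to the returned [synergy_set()].
#' @param tol relative change in reconstruction error declaring convergence
#'   (default 1e-6).
#' @param max_iter iteration cap per restart (default 2000).
#' @return a [synergy_set()]; attribute `vaf` holds the variance accounted
#'   for of the kept factorization.
#' @examples
#' H0 <- abs(matrix(rnorm(3 * 50), 3))
#' W0 <- abs(matrix(rnorm(8 * 3), 8))
#' s <- extract_synergies(W0 %*% H0, k = 3, restarts = 5, seed = 1)
#' attr(s, "vaf") # ~1
#' @export
extract_synergies <- function(A, k, restarts = 20L, seed = 1L,
                              side = NA_character_, tol = 1e-6,
                              max_iter = 2000L) {
  A <- as.matrix(A)
  if (min(A) < 0) {
    stop_trunksyn("argument_error", "A must be elementwise nonnegative")
  }
  if (k < 1 || k > min(dim(A))) {
    stop_trunksyn("argument_error", sprintf(
      "k=%d outside [1, %d]", k, min(dim(A))))
  }
  m <- nrow(A); n <- ncol(A)
  scale <- sqrt(mean(A) / k) + 1e-9
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    W0 <- matrix(stats::runif(m * k), m, k) * scale
    H0 <- matrix(stats::runif(k * n), k, n) * scale
    fit <- nmf_run(A, W0, H0, tol, max_iter)
    if (is.null(best) || fit$err < best$err) best <- fit
  }
  s <- synergy_set(best$W, best$H, rownames(A), side)
  attr(s, "vaf") <- variance_accounted_for(A, s)
  s
}

#' Max-normalize synergy activations
#'
#' Divides each synergy activation (row of `H`) by its maximum so every row
#' peaks at exactly 1, and multiplies the matching column of `W` by the same
#' factor, leaving the product `W %*% H` unchanged. Idempotent.
#'
#' @param s a [synergy_set()].
#' @return a [synergy_set()] with row-max-normalized `H`.
#' @export
normalize_activations <- function(s) {
  stopifnot(inherits(s, "synergy_set"))
  mx <- apply(s$H, 1, max)
  if (any(mx <= 0)) {
    stop_trunksyn("degenerate_synergy_error",
                  "a synergy activation is identically zero")
  }
  out <- synergy_set(sweep(s$W, 2, mx, "*"), sweep(s$H, 1, mx, "/"),
                     s$muscle_labels, s$side)
  attr(out, "vaf") <- attr(s, "vaf")
  out
}

#' Variance accounted for by a synergy factorization
#'
#' `VAF = 1 - ||A - W H||_F^2 / ||A||_F^2`, clipped to `[0, 1]`.
#'
#' @param A the matrix that was factorized.
#' @param s a [synergy_set()] of matching shape.
#' @return a fraction in `[0, 1]`.
#' @export
variance_accounted_for <- function(A, s) {
  A <- as.matrix(A)
  if (all(A == 0)) {
    stop_trunksyn("argument_error", "VAF undefined for an all-zero matrix")
  }
  if (nrow(A) != nrow(s$W) || ncol(A) != ncol(s$H)) {
    stop_trunksyn("argument_error", "shape mismatch between A and synergies")
  }
  v <- 1 - norm(A - s$W %*% s$H, "F")^2 / norm(A, "F")^2
  min(max(v, 0), 1)
}
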