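#' Static-optimization baseline for trunk muscle activations
#'
#' The conventional comparator: for each time frame independently, minimize
#' the sum of squared muscle activations subject to equality between the
#' muscle-generated and reference joint moments on every degree of freedom,
#' with `0 <= a <= 1`. Optional reserve actuators add a torque at each DoF,
#' penalized quadratically with weight `reserve_weight`, guaranteeing
#' feasibility.
#'
#' Each frame is an equality-constrained box-bounded quadratic program,
#' solved by an augmented-Lagrangian scheme with a bounded quasi-Newton
#' inner solver.
#'
#' @param model a [trunk_model()] with geometry.
#' @param moments `nPt x nDoF` reference moments, Nm.
#' @param passive include passive fiber forces (their moment is subtracted
#'   from the target before solving).
#' @param reserves enable reserve actuators (default FALSE).
#' @param reserve_weight quadratic penalty weight on reserve torques
#'   (default 1000).
#' @param tol infinity-norm tolerance on the moment equality (default 1e-9).
#' @return `nPt x nMusc` activation matrix; when `reserves = TRUE` the
#'   reserve torques are attached as attribute `"reserves"`
#'   (`nPt x nDoF`, Nm).
#' @export
static_optimization <- function(model, moments, passive = FALSE,
                                reserves = FALSE, reserve_weight = 1000,
                                tol = 1e-9) {
  if (inherits(moments, "ts_table")) moments <- moments$data
  M <- as.matrix(moments)
  g <- moment_gains(model, passive)
  n_pt <- dim(g$gains)[1]; n_musc <- dim(g$gains)[2]; n_dof <- dim(g$gains)[3]
  if (nrow(M) != n_pt || ncol(M) != n_dof) {
    stop_trunksyn("argument_error", "moment shape mismatch with geometry")
  }
  A <- matrix(0, n_pt, n_musc, dimnames = list(NULL, model$mtus$name))
  R <- matrix(0, n_pt, n_dof)
  lower <- c(rep(0, n_musc), if (reserves) rep(-Inf, n_dof))
  upper <- c(rep(1, n_musc), if (reserves) rep(Inf, n_dof))
  for (t in seq_len(n_pt)) {
    G <- matrix(g$gains[t, , ], n_musc, n_dof)     # dM/da at this frame
    m_t <- M[t, ] - g$passive_moment[t, ]
    cons <- function(x) {
      a <- x[seq_len(n_musc)]
      r <- if (reserves) x[n_musc + seq_len(n_dof)] else numeric(n_dof)
      as.numeric(crossprod(G, a)) + r - m_t
    }
    lambda <- numeric(n_dof); mu <- 10; prev <- Inf
    x <- c(rep(0, n_musc), if (reserves) rep(0, n_dof))
    for (outer in seq_len(50)) {
      fn <- function(x) {
        a <- x[seq_len(n_musc)]
        r <- if (reserves) x[n_musc + seq_len(n_dof)] else numeric(0)
        cv <- cons(x)
        sum(a^2) + reserve_weight * sum(r^2) +
          sum(lambda * cv) + mu / 2 * sum(cv^2)
      }
      gr <- function(x) {
        a <- x[seq_len(n_musc)]
        cv <- cons(x)
        lm <- lambda + mu * cv
        c(2 * a + as.numeric(G %*% lm),
          if (reserves) 2 * reserve_weight *
            x[n_musc + seq_len(n_dof)] + lm)
      }
      opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500, factr = 1e4))
      x <- opt$par
      cv <- cons(x)
      v <- max(abs(cv))
      if (v <= tol) break
      lambda <- lambda + mu * cv
      if (v > prev / 4) mu <- mu * 10
      prev <- v
    }
    if (max(abs(cons(x))) > 1e-5 && !reserves) {
      stop_trunksyn("data_error", sprintf(
        "static optimization infeasible at frame %d (moment residual %.3g Nm); enable reserves",
        t, max(abs(cons(x)))))
    }
    A[t, ] <- x[seq_len(n_musc)]
    if (reserves) R[t, ] <- x[n_musc + seq_len(n_dof)]
  }
  if (reserves) attr(A, "reserves") <- R
  A
}
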