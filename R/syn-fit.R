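#' Trunk activations from synergy-vector weights
#'
#' `a[t, i] = sum_s w[i, s] * H[s, t]` — the linear reconstruction of muscle
#' activations from nonnegative weights applied to time-varying synergy
#' activations. With `H` row-max-normalized and `w >= 0`, activations are
#' nonnegative by construction.
#'
#' @param w `nMusc x k` nonnegative weight matrix.
#' @param H `k x nPt` nonnegative synergy-activation matrix.
#' @return `nPt x nMusc` activation matrix.
#' @export
activations_from_weights <- function(w, H) {
  w <- as.matrix(w); H <- as.matrix(H)
  if (ncol(w) != nrow(H)) {
    stop_trunksyn("argument_error", "ncol(w) must equal nrow(H)")
  }
  if (min(w) < 0 || min(H) < 0) {
    stop_trunksyn("argument_error", "w and H must be nonnegative")
  }
  t(w %*% H)
}

#' Cost terms of the synergy-weight optimization
#'
#' The objective of the trunk estimator is `J = J_M + J_a + J_a_dev`
#' (optionally `+ J_w_dev`), each term a mean of squared deviations scaled
#' by an allowable value so it equals exactly 1 when every deviation equals
#' its allowance:
#' * `cost_moment_tracking`: mean over samples and DoFs of
#'   `((M_est - M_ref) / allow_dM)^2` — moment-tracking error.
#' * `cost_activation`: mean over samples and muscles of
#'   `(a / allow_a)^2` — activation-magnitude minimization.
#' * `cost_activation_deviation`: per muscle group, the mean over samples
#'   and member heads of `((a - group mean) / allow_da)^2`, summed over
#'   groups — keeps heads of one muscle acting together.
#' * `cost_weight_deviation`: the analogous quadratic on the weights.
#'
#' @param M_est,M_ref `nPt x nDoF` moment matrices, Nm.
#' @param allow_dM allowable moment error, Nm (default 5).
#' @return scalar cost.
#' @export
cost_moment_tracking <- function(M_est, M_ref, allow_dM = 5) {
  M_est <- as.matrix(M_est); M_ref <- as.matrix(M_ref)
  if (!all(dim(M_est) == dim(M_ref))) {
    stop_trunksyn("argument_error", "moment matrices differ in shape")
  }
  if (anyNA(M_est) || anyNA(M_ref)) {
    stop_trunksyn("data_error", "NaN in moment matrices")
  }
  mean(((M_est - M_ref) / allow_dM)^2)
}

#' @rdname cost_moment_tracking
#' @param a `nPt x nMusc` activation matrix.
#' @param allow_a allowable activation (default 0.5).
#' @export
cost_activation <- function(a, allow_a = 0.5) {
  a <- as.matrix(a)
  if (anyNA(a)) stop_trunksyn("data_error", "NaN in activations")
  mean((a / allow_a)^2)
}

#' @rdname cost_moment_tracking
#' @param groups list of member-column index vectors, one per muscle group.
#' @param allow_da allowable head-to-mean activation deviation (default 0.05).
#' @export
cost_activation_deviation <- function(a, groups, allow_da = 0.05) {
  a <- as.matrix(a)
  total <- 0
  for (g in groups) {
    if (length(g) == 0) stop_trunksyn("argument_error", "empty muscle group")
    sub <- a[, g, drop = FALSE]
    dev <- sub - rowMeans(sub)
    total <- total + mean((dev / allow_da)^2)
  }
  total
}

#' @rdname cost_moment_tracking
#' @param w `nMusc x k` weight matrix (groups index its rows).
#' @param allow_dw allowable head-to-mean weight deviation (default 0.05).
#' @export
cost_weight_deviation <- function(w, groups, allow_dw = 0.05) {
  w <- as.matrix(w)
  total <- 0
  for (g in groups) {
    if (length(g) == 0) stop_trunksyn("argument_error", "empty muscle group")
    sub <- w[g, , drop = FALSE]
    dev <- sweep(sub, 2, colMeans(sub))
    total <- total + mean((dev / allow_dw)^2)
  }
  total
}

#' Remove a muscle subset's contribution from inverse-dynamics moments
#'
#' Subtracts the joint moments generated by a specified muscle subset (e.g.
#' the psoas heads, whose activations come from the calibrated leg model)
#' from total inverse-dynamics moments, yielding the tracking reference for
#' the trunk estimator.
#'
#' @param M_total `nPt x nDoF` inverse-dynamics moments, Nm.
#' @param A_sub `nPt x nSub` subset activations.
#' @param model_sub a [trunk_model()] holding the subset's MTUs + geometry.
#' @param passive include passive fiber forces (default FALSE).
#' @return `nPt x nDoF` moments with the subset contribution removed.
#' @export
subtract_muscle_moments <- function(M_total, A_sub, model_sub,
                                    passive = FALSE) {
  M_total <- as.matrix(M_total)
  M_sub <- joint_moments(A_sub, model_sub, passive)
  if (!all(dim(M_total) == dim(M_sub))) {
    stop_trunksyn("argument_error", "moment shapes do not match")
  }
  M_total - M_sub
}

#' Control settings for the trunk synergy estimator
#'
#' The allowable-value ledger and solver settings. Allowances scale each
#' cost term so it reads 1 when deviations sit exactly at their allowed
#' size: `allow_dM = 5` Nm (comparable to leg-model moment errors),
#' `allow_a` in {1.00, 0.75, 0.50, 0.25} (default 0.50, the best-performing
#' case), `allow_da = allow_dw = 0.05`.
#'
#' @param allow_dM allowable moment-tracking error, Nm.
#' @param allow_a allowable activation magnitude.
#' @param allow_da allowable within-group activation deviation.
#' @param allow_dw allowable within-group weight deviation.
#' @param include_jw_dev include the weight-deviation term (default TRUE;
#'   set FALSE for the literal three-term objective).
#' @param passive include passive fiber forces in estimated moments.
#' @param bound_tol tolerance on the `a <= 1` constraints (default 1e-6).
#' @param max_iter iteration cap for the bounded quasi-Newton solver.
#' @param factr L-BFGS-B convergence factor.
#' @return list of class `syn_control`.
#' @export
syn_control <- function(allow_dM = 5, allow_a = 0.5, allow_da = 0.05,
                        allow_dw = 0.05, include_jw_dev = TRUE,
                        passive = FALSE, bound_tol = 1e-6,
                        max_iter = 3000L, factr = 1e5) {
  if (any(c(allow_dM, allow_a, allow_da, allow_dw) <= 0)) {
    stop_trunksyn("argument_error", "all allowable values must be > 0")
  }
  structure(list(allow_dM = allow_dM, allow_a = allow_a, allow_da = allow_da,
                 allow_dw = allow_dw, include_jw_dev = include_jw_dev,
                 passive = passive, bound_tol = bound_tol,
                 max_iter = as.integer(max_iter), factr = factr),
            class = "syn_control")
}

# resolve per-muscle synergy-activation matrices: `synergies` is either one
# synergy_set/matrix (shared by all MTUs) or list(left=, right=) matched to
# model$mtus$side; returns list(H_list per muscle, k)
resolve_H <- function(synergies, model) {
  as_H <- function(s) if (inherits(s, "synergy_set")) s$H else as.matrix(s)
  check_norm <- function(H) {
    if (min(H) < 0 || max(abs(apply(H, 1, max) - 1)) > 1e-6) {
      stop_trunksyn("argument_error",
                    "synergy activations must be nonnegative and max-normalized")
    }
    H
  }
  n <- nrow(model$mtus)
  if (is.list(synergies) && !inherits(synergies, "synergy_set")) {
    Hs <- lapply(synergies, function(s) check_norm(as_H(s)))
    if (!all(model$mtus$side %in% names(Hs))) {
      stop_trunksyn("argument_error",
                    "synergies list must be named by the sides in the model")
    }
    if (length(unique(vapply(Hs, nrow, 0L))) != 1) {
      stop_trunksyn("argument_error", "all sides must share the synergy count")
    }
    list(H = lapply(model$mtus$side, function(s) Hs[[s]]),
         k = nrow(Hs[[1]]), n_pt = ncol(Hs[[1]]))
  } else {
    H <- check_norm(as_H(synergies))
    list(H = rep(list(H), n), k = nrow(H), n_pt = ncol(H))
  }
}

#' Estimate trunk muscle activations from leg-muscle synergies
#'
#' The core estimator: finds nonnegative trunk synergy-vector weights `w`
#' such that trunk activations `a = w H` (built from the ipsilateral
#' max-normalized synergy activations `H`) generate lumbosacral joint
#' moments that track the inverse-dynamics reference, while keeping
#' activations small and the heads of each muscle acting coherently.
#' Minimizes `J_M + J_a + J_a_dev (+ J_w_dev)` over `w >= 0` subject to
#' `a <= 1` at every sample.
#'
#' Because `H` is fixed and row-max-normalized, the activations — and hence
#' the estimated moments — are linear in `w`, so the objective is a convex
#' quadratic and the constraints are linear: all time frames are solved
#' simultaneously as one quadratic program (bounded quasi-Newton with
#' analytic gradients; an augmented-Lagrangian outer loop enforces the
#' activation upper bound when it binds).
#'
#' @param model a [trunk_model()] with per-sample geometry for the trunk
#'   MTUs.
#' @param moments `nPt x nDoF` inverse-dynamics lumbosacral moments, Nm,
#'   with any psoas contribution already removed (see
#'   [subtract_muscle_moments()]); a [ts_table()] is also accepted.
#' @param synergies a [synergy_set()] (or bare `k x nPt` matrix) shared by
#'   all MTUs, or a list `list(left = , right = )` matched to the model's
#'   `side` column. Activations must be max-normalized
#'   (see [normalize_activations()]).
#' @param control a [syn_control()] object.
#' @return An object of class `syn_fit` with components `weights`
#'   (`nMusc x k`), `activations` (`nPt x nMusc`), `moments` (estimated,
#'   `nPt x nDoF`), `moments_target`, `costs` (list `j_m`, `j_a`,
#'   `j_a_dev`, `j_w_dev`, `total`), `converged`, `control`, and solver
#'   diagnostics. Supported methods: `print`, `summary`, `coef`, `fitted`,
#'   `predict`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' ds <- make_dataset(syn_spec(n_cycles = 1, n_pt = 51, seed = 7,
#'                             activation_noise_sd = 0, moment_noise_sd = 0))
#' cyc <- ds$cycles[[1]]
#' fit <- syn_estimate(ds$model, cyc$M_ID,
#'                     lapply(cyc$H_true, identity))
#' summary(fit)
#' }
#' @export
syn_estimate <- function(model, moments, synergies,
                         control = syn_control()) {
  stopifnot(inherits(model, "trunk_model"), inherits(control, "syn_control"))
  if (inherits(moments, "ts_table")) moments <- moments$data
  M_ref <- as.matrix(moments)
  if (anyNA(M_ref)) stop_trunksyn("data_error", "NaN in reference moments")
  hh <- resolve_H(synergies, model)
  n_musc <- nrow(model$mtus)
  n_pt <- hh$n_pt
  k <- hh$k
  g <- moment_gains(model, control$passive)
  n_dof <- dim(g$gains)[3]
  if (nrow(M_ref) != n_pt || ncol(M_ref) != n_dof ||
      dim(g$gains)[1] != n_pt) {
    stop_trunksyn("argument_error",
                  "moments, geometry and synergies disagree on shape")
  }
  groups <- grouping(model)
  Ht <- lapply(hh$H, t)                       # per muscle: nPt x k
  cols <- function(i) ((i - 1) * k + 1):(i * k)
  n_var <- n_musc * k

  ## --- stack the objective as ||C w - d||^2 and form normal equations ----
  s_m <- 1 / (control$allow_dM * sqrt(n_pt * n_dof))
  C_M <- matrix(0, n_pt * n_dof, n_var)
  for (j in seq_len(n_dof)) {
    rows <- (j - 1) * n_pt + seq_len(n_pt)
    for (i in seq_len(n_musc)) {
      C_M[rows, cols(i)] <- g$gains[, i, j] * Ht[[i]] * s_m
    }
  }
  d_M <- as.numeric(M_ref - g$passive_moment) * s_m

  s_a <- 1 / (control$allow_a * sqrt(n_pt * n_musc))
  C_a <- matrix(0, n_pt * n_musc, n_var)
  for (i in seq_len(n_musc)) {
    C_a[(i - 1) * n_pt + seq_len(n_pt), cols(i)] <- Ht[[i]] * s_a
  }

  C_ad <- matrix(0, n_pt * n_musc, n_var)
  for (g_idx in groups) {
    ng <- length(g_idx)
    s_g <- 1 / (control$allow_da * sqrt(n_pt * ng))
    for (i in g_idx) {
      rows <- (i - 1) * n_pt + seq_len(n_pt)
      for (i2 in g_idx) {
        C_ad[rows, cols(i2)] <- ((i == i2) - 1 / ng) * Ht[[i2]] * s_g
      }
    }
  }

  blocks_C <- list(C_M, C_a, C_ad)
  blocks_d <- list(d_M, numeric(n_pt * n_musc), numeric(n_pt * n_musc))
  if (control$include_jw_dev) {
    C_wd <- matrix(0, n_var, n_var)
    for (g_idx in groups) {
      ng <- length(g_idx)
      s_w <- 1 / (control$allow_dw * sqrt(k * ng))
      for (i in g_idx) for (i2 in g_idx) {
        ci <- cols(i); ci2 <- cols(i2)
        C_wd[cbind(ci, ci2)] <- ((i == i2) - 1 / ng) * s_w
      }
    }
    blocks_C <- c(blocks_C, list(C_wd))
    blocks_d <- c(blocks_d, list(numeric(n_var)))
  }
  C <- do.call(rbind, blocks_C)
  d <- unlist(blocks_d)
  Q <- crossprod(C)
  b <- as.numeric(crossprod(C, d))
  const <- sum(d^2)

  quad_f <- function(w) {
    v <- as.numeric(Q %*% w)
    sum(w * v) - 2 * sum(b * w) + const
  }
  quad_g <- function(w) 2 * (as.numeric(Q %*% w) - b)

  solve_lbfgsb <- function(fn, gr, start) {
    stats::optim(start, fn, gr, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = control$max_iter,
                                factr = control$factr, lmm = 20))
  }
  opt <- solve_lbfgsb(quad_f, quad_g, numeric(n_var))
  w_vec <- opt$par

  act_from <- function(w_vec) {
    w <- matrix(w_vec, n_musc, k, byrow = TRUE)
    a <- vapply(seq_len(n_musc),
                function(i) as.numeric(Ht[[i]] %*% w[i, ]), numeric(n_pt))
    list(w = w, a = matrix(a, n_pt, n_musc))
  }

  ## --- augmented Lagrangian on a <= 1, engaged only if the bound binds ---
  al_outer <- 0L
  viol <- max(act_from(w_vec)$a) - 1
  if (viol > control$bound_tol) {
    lambda <- matrix(0, n_pt, n_musc)
    mu <- 10
    prev_viol <- Inf
    for (outer in seq_len(30)) {
      al_outer <- outer
      fn <- function(wv) {
        a <- act_from(wv)$a
        s <- pmax(lambda + mu * (a - 1), 0)
        quad_f(wv) + sum(s^2 - lambda^2) / (2 * mu)
      }
      gr <- function(wv) {
        aw <- act_from(wv)
        s <- pmax(lambda + mu * (aw$a - 1), 0)
        extra <- vapply(seq_len(n_musc),
                        function(i) as.numeric(crossprod(Ht[[i]], s[, i])),
                        numeric(k))
        quad_g(wv) + as.numeric(extra)   # column i -> vars of muscle i
      }
      opt <- solve_lbfgsb(fn, gr, w_vec)
      w_vec <- opt$par
      a <- act_from(w_vec)$a
      viol <- max(a) - 1
      if (viol <= 1e-8) break
      lambda <- pmax(lambda + mu * (a - 1), 0)
      if (viol > prev_viol / 4) mu <- mu * 5
      prev_viol <- viol
    }
  }

  aw <- act_from(w_vec)
  w <- aw$w
  rownames(w) <- model$mtus$name
  a_est <- aw$a
  colnames(a_est) <- model$mtus$name
  M_est <- joint_moments(a_est, model, control$passive)
  costs <- list(
    j_m = cost_moment_tracking(M_est, M_ref, control$allow_dM),
    j_a = cost_activation(a_est, control$allow_a),
    j_a_dev = cost_activation_deviation(a_est, groups, control$allow_da),
    j_w_dev = if (control$include_jw_dev) {
      cost_weight_deviation(w, groups, control$allow_dw)
    } else NA_real_)
  costs$total <- costs$j_m + costs$j_a + costs$j_a_dev +
    if (control$include_jw_dev) costs$j_w_dev else 0
  structure(list(weights = w, activations = a_est, moments = M_est,
                 moments_target = M_ref, costs = costs,
                 converged = opt$convergence == 0 &&
                   max(a_est) <= 1 + control$bound_tol,
                 diagnostics = list(optim_convergence = opt$convergence,
                                    optim_message = opt$message,
                                    al_outer_iterations = al_outer,
                                    max_activation = max(a_est)),
                 control = control, groups = groups,
                 synergies = synergies, model = model),
            class = "syn_fit")
}

#' @export
print.syn_fit <- function(x, ...) {
  cat(sprintf(
    "Synergy-based trunk activation estimate: %d MTUs x %d synergies, %d samples\n",
    nrow(x$weights), ncol(x$weights), nrow(x$activations)))
  cat(sprintf("  total cost %.4g (J_M %.4g, J_a %.4g, J_a_dev %.4g%s)\n",
              x$costs$total, x$costs$j_m, x$costs$j_a, x$costs$j_a_dev,
              if (is.na(x$costs$j_w_dev)) "" else
                sprintf(", J_w_dev %.4g", x$costs$j_w_dev)))
  cat(sprintf("  moment RMSE per DoF (Nm): %s\n",
              paste(sprintf("%.3f", moment_rmse(x$moments, x$moments_target)),
                    collapse = ", ")))
  if (!x$converged) cat("  warning: solver did not fully converge\n")
  invisible(x)
}

#' @export
summary.syn_fit <- function(object, ...) {
  rmse <- moment_rmse(object$moments, object$moments_target)
  grp_mean <- vapply(object$groups, function(g) {
    mean(object$activations[, g, drop = FALSE])
  }, 0)
  out <- list(costs = object$costs, rmse = rmse,
              group_mean_activation = grp_mean,
              max_activation = max(object$activations),
              n_minimal_synergies = sum(apply(object$weights, 2,
                                              function(col) all(col < 0.01))),
              converged = object$converged)
  class(out) <- "summary.syn_fit"
  out
}

#' @export
print.summary.syn_fit <- function(x, ...) {
  cat("Trunk synergy-weight estimation summary\n")
  cat(sprintf("  moment tracking RMSE (Nm): %s\n",
              paste(sprintf("%.3f", x$rmse), collapse = ", ")))
  cat(sprintf("  cost total %.4g | J_M %.4g | J_a %.4g | J_a_dev %.4g\n",
              x$costs$total, x$costs$j_m, x$costs$j_a, x$costs$j_a_dev))
  cat("  mean activation by group:\n")
  print(round(x$group_mean_activation, 4))
  cat(sprintf("  max activation %.4f; minimally recruited synergies: %d\n",
              x$max_activation, x$n_minimal_synergies))
  invisible(x)
}

#' @export
coef.syn_fit <- function(object, ...) object$weights

#' @export
fitted.syn_fit <- function(object, ...) object$activations

#' @export
residuals.syn_fit <- function(object, ...) {
  object$moments_target - object$moments
}

#' Predict activations or moments from a fitted synergy-weight model
#'
#' Applies the fitted trunk weights to (possibly new) synergy activations —
#' e.g. those of another gait cycle — and optionally propagates them through
#' the musculotendon model to joint moments.
#'
#' @param object a `syn_fit`.
#' @param synergies new synergy activations in any form accepted by
#'   [syn_estimate()]; defaults to the ones used for fitting.
#' @param type `"activations"` or `"moments"`.
#' @param ... unused.
#' @return `nPt x nMusc` activations or `nPt x nDoF` moments.
#' @export
predict.syn_fit <- function(object, synergies = NULL,
                            type = c("activations", "moments"), ...) {
  type <- match.arg(type)
  if (is.null(synergies)) synergies <- object$synergies
  hh <- resolve_H(synergies, object$model)
  a <- vapply(seq_len(nrow(object$weights)),
              function(i) as.numeric(t(hh$H[[i]]) %*% object$weights[i, ]),
              numeric(hh$n_pt))
  a <- matrix(a, hh$n_pt, nrow(object$weights),
              dimnames = list(NULL, rownames(object$weights)))
  if (type == "activations") a else {
    joint_moments(a, object$model, object$control$passive)
  }
}

#' Plot moment tracking of a fitted trunk estimator
#'
#' One panel per lumbosacral degree of freedom: estimated (solid) vs
#' inverse-dynamics reference (dashed) moments over the gait cycle.
#'
#' @param x a `syn_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.syn_fit <- function(x, ...) {
  n_dof <- ncol(x$moments)
  labs <- colnames(x$moments)
  if (is.null(labs)) labs <- paste("DoF", seq_len(n_dof))
  old <- graphics::par(mfrow = c(1, n_dof), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pct <- seq(0, 100, length.out = nrow(x$moments))
  for (j in seq_len(n_dof)) {
    graphics::matplot(pct, cbind(x$moments[, j], x$moments_target[, j]),
                      type = "l", lty = c(1, 2), col = c("black", "grey40"),
                      xlab = "% gait cycle", ylab = "moment (Nm)",
                      main = labs[j], ...)
  }
  invisible(x)
}
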