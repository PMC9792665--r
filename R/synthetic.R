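#' Specification for a synthetic gait dataset
#'
#' Defines the study conditions a generated dataset emulates: a small set of
#' shared time-varying synergy activations driving both leg and trunk
#' muscles, smooth musculotendon geometry, lumbosacral moments produced by
#' the same rigid-tendon muscle model, optional additive noise, and a known
#' injected electromechanical delay on a surrogate "measured" excitation.
#' Defaults mirror the experimental layout: 15 leg channels and 29 trunk
#' MTUs per side, 7 synergies, 10 cycles of 101 time-normalized samples.
#'
#' @param k_true number of ground-truth synergies (default 7).
#' @param n_leg leg muscle channels per side (default 15).
#' @param n_trunk trunk MTUs per side (default 29; must stay 29 to use the
#'   bundled reduced-set parameter table).
#' @param n_pt samples per time-normalized cycle (default 101).
#' @param n_cycles gait cycles (default 10).
#' @param activation_noise_sd sd of truncated-Gaussian noise added to leg
#'   activations and the excitation surrogate (default 0.05).
#' @param moment_noise_sd sd of Gaussian noise added to the
#'   inverse-dynamics moments, Nm (default 1 — below the 5 Nm tracking
#'   allowance so the signal dominates).
#' @param minimal_fraction fraction of synergy columns given near-zero
#'   (< 0.01) trunk weights (default 1/7, one synergy minimally recruited).
#' @param injected_emd_ms electromechanical advance of the excitation
#'   surrogate relative to the true activation, ms (default 120).
#' @param weight_jitter_sd within-group relative jitter of trunk head
#'   weights (default 0: heads of a muscle share weights).
#' @param mean_cycle_duration_s mean cycle duration, seconds (default 1.1).
#' @param seed integer RNG seed.
#' @return list of class `syn_spec`.
#' @export
syn_spec <- function(k_true = 7L, n_leg = 15L, n_trunk = 29L, n_pt = 101L,
                     n_cycles = 10L, activation_noise_sd = 0.05,
                     moment_noise_sd = 1, minimal_fraction = 1 / 7,
                     injected_emd_ms = 120, weight_jitter_sd = 0,
                     mean_cycle_duration_s = 1.1, seed = 1L) {
  if (any(c(k_true, n_leg, n_trunk, n_pt, n_cycles) < 1)) {
    stop_trunksyn("argument_error", "all counts must be positive")
  }
  if (activation_noise_sd < 0 || moment_noise_sd < 0) {
    stop_trunksyn("argument_error", "noise sds must be >= 0")
  }
  structure(as.list(environment()), class = "syn_spec")
}

#' Generate synergy activation curves
#'
#' k nonnegative unimodal bumps (wrapped Gaussians, periodic over the
#' cycle) with peaks spread across the gait cycle — synergy activation
#' peaks distribute throughout the cycle as their number grows — each
#' max-normalized to 1.
#'
#' @param k number of synergies.
#' @param n_pt samples per cycle.
#' @param seed optional RNG seed (NULL: use the current RNG stream).
#' @param peak_jitter peak-position jitter as a fraction of the inter-peak
#'   spacing (default 0.25).
#' @param centers optional explicit peak positions as fractions of the
#'   cycle in `[0, 1)` (overrides the jittered even spacing); used to give
#'   the cycles of one synthetic subject stereotyped synergy timing.
#' @param widths optional explicit bump widths as fractions of the cycle.
#' @return `k x n_pt` matrix, each row with maximum exactly 1.
#' @export
make_synergy_activations <- function(k, n_pt, seed = NULL,
                                     peak_jitter = 0.25, centers = NULL,
                                     widths = NULL) {
  if (k < 1) stop_trunksyn("argument_error", "k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centers)) {
    centers <- ((seq_len(k) - 1 + 0.5 +
                   stats::runif(k, -peak_jitter, peak_jitter)) / k) %% 1
  }
  if (is.null(widths)) {
    widths <- stats::runif(k, 0.5, 0.9) / (2 * k)   # fraction of cycle
  }
  u <- (seq_len(n_pt) - 1) / n_pt
  H <- t(vapply(seq_len(k), function(i) {
    d <- abs(u - centers[i])
    d <- pmin(d, 1 - d)                           # circular distance
    exp(-d^2 / (2 * widths[i]^2))
  }, numeric(n_pt)))
  sweep(H, 1, apply(H, 1, max), "/")
}

#' Generate nonnegative synergy weights with bounded row sums
#'
#' Draws uniform nonnegative weights, zeroes a `sparsity` fraction, forces a
#' `minimal_fraction` share of the synergy columns below 0.01 (minimally
#' recruited synergies), and rescales rows so each row sum stays <= 1 —
#' which, combined with max-normalized synergy activations, keeps every
#' composed activation in `[0, 1]`.
#'
#' @param n_musc number of muscles (rows).
#' @param k number of synergies (columns).
#' @param sparsity fraction of entries set to zero (default 0.25).
#' @param minimal_fraction fraction of columns drawn below 0.01 (default 0).
#' @param seed optional RNG seed.
#' @param row_sum_range target row-sum range before capping at 1.
#' @return `n_musc x k` nonnegative matrix with row sums <= 1.
#' @export
make_weights <- function(n_musc, k, sparsity = 0.25, minimal_fraction = 0,
                         seed = NULL, row_sum_range = c(0.4, 0.8)) {
  if (minimal_fraction < 0 || minimal_fraction > 1 ||
      sparsity < 0 || sparsity > 1) {
    stop_trunksyn("argument_error", "fractions must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::runif(n_musc * k, 0.1, 1), n_musc, k)
  W[matrix(stats::runif(n_musc * k) < sparsity, n_musc, k)] <- 0
  n_min <- round(minimal_fraction * k)
  if (n_min > 0) {
    min_cols <- sample(k, n_min)
    W[, min_cols] <- matrix(stats::runif(n_musc * n_min, 0, 0.009),
                            n_musc, n_min)
  }
  target <- stats::runif(n_musc, row_sum_range[1], row_sum_range[2])
  rs <- rowSums(W)
  fac <- ifelse(rs > 0, pmin(1, target / rs), 1)
  W * fac
}

# smooth per-sample geometry for a given MTU parameter table: low-frequency
# moment arms with both agonist and antagonist arms per DoF, and lMT series
# keeping normalized fiber length inside [0.7, 1.0]
smooth_geometry <- function(mtus, n_dof, n_pt) {
  n_musc <- nrow(mtus)
  u <- 2 * pi * (seq_len(n_pt) - 1) / n_pt
  arms <- array(0, c(n_pt, n_musc, n_dof))
  for (j in seq_len(n_dof)) {
    sign_j <- rep_len(c(1, -1), n_musc)[sample.int(n_musc)]
    base <- stats::runif(n_musc, 0.02, 0.065) * sign_j
    amp <- 0.2 * abs(base)
    phase <- stats::runif(n_musc, 0, 2 * pi)
    for (i in seq_len(n_musc)) {
      arms[, i, j] <- pmin(pmax(
        base[i] + amp[i] * sin(u + phase[i]), -0.08), 0.08)
    }
  }
  lmt <- matrix(0, n_pt, n_musc)
  mid <- stats::runif(n_musc, 0.80, 0.90)
  amp <- stats::runif(n_musc, 0.02, 0.08)
  phase <- stats::runif(n_musc, 0, 2 * pi)
  for (i in seq_len(n_musc)) {
    lnorm <- pmin(pmax(mid[i] + amp[i] * sin(u + phase[i]), 0.7), 1.0)
    lmt[, i] <- mtus$lts[i] + lnorm * mtus$lmo[i]
  }
  list(lmt = lmt, arms = arms,
       dof_labels = c("extension", "bending", "rotation")[seq_len(n_dof)])
}

#' Generate smooth random musculotendon geometry and parameters
#'
#' Random MTUs with peak isometric forces in the reduced-set range
#' (57-892 N) and smooth per-sample geometry: low-frequency moment arms
#' within +/- 0.08 m including both agonist and antagonist arms for every
#' DoF, and musculotendon lengths keeping normalized fiber lengths within
#' `[0.7, 1.0]`.
#'
#' @param n_musc,n_dof,n_pt counts.
#' @param seed optional RNG seed.
#' @return a [trunk_model()] (single generic group per muscle).
#' @export
make_geometry <- function(n_musc, n_dof, n_pt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lmo <- stats::runif(n_musc, 0.04, 0.15)
  rho <- stats::runif(n_musc, 0.2, 0.7)
  mtus <- data.frame(
    name = sprintf("mtu%02d", seq_len(n_musc)),
    group = sprintf("g%02d", seq_len(n_musc)),
    side = "right",
    fmo = stats::runif(n_musc, 57, 892),
    lmo = lmo,
    lts = rho / (1 - rho) * lmo)
  trunk_model(mtus, smooth_geometry(mtus, n_dof, n_pt))
}

# Effort-consistent ground-truth trunk weights: the self-consistent
# allowance-weighted effort-optimal recruitment for the moment demand implied
# by a raw random draw. Starting from raw group-level weights, iterate
#   w <- argmin_{w >= 0} J_M(A w, A w_prev) + J_a(w)
# (a stacked nonnegative least-squares problem, solved with Lawson-Hanson
# NNLS) until the recruitment reproduces itself. Co-contraction components
# invisible to the three lumbosacral moments die out across iterations, so
# the surviving truth is identifiable from moment data — the property any
# moment-driven estimator needs ground truth to have. Heads of a muscle
# group share weights throughout (solved at group level).
effort_consistent_weights <- function(model, H_base, Wg_raw, group_index,
                                      allow_dM = 5, allow_a = 0.5,
                                      max_iter = 40, rel_tol = 0.01) {
  g <- moment_gains(model, FALSE)
  n_pt <- dim(g$gains)[1]
  n_dof <- dim(g$gains)[3]
  n_heads_total <- nrow(model$mtus)
  k <- ncol(Wg_raw[[1]])
  sides <- names(group_index)
  blocks <- list()   # one (side, group) entry per design-variable block
  for (s in sides) {
    for (gi in seq_along(group_index[[s]])) {
      blocks[[length(blocks) + 1]] <-
        list(side = s, members = group_index[[s]][[gi]])
    }
  }
  n_var <- length(blocks) * k
  A <- matrix(0, n_pt * n_dof, n_var)
  Ca <- matrix(0, length(blocks) * n_pt, n_var)
  s_a <- 1 / (allow_a * sqrt(n_pt * n_heads_total))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    cols <- (bi - 1) * k + seq_len(k)
    gain_sum <- vapply(seq_len(n_dof), function(j) {
      rowSums(g$gains[, b$members, j, drop = FALSE])
    }, numeric(n_pt))
    for (j in seq_len(n_dof)) {
      A[(j - 1) * n_pt + seq_len(n_pt), cols] <-
        gain_sum[, j] * t(H_base[[b$side]])
    }
    Ca[(bi - 1) * n_pt + seq_len(n_pt), cols] <-
      sqrt(length(b$members)) * s_a * t(H_base[[b$side]])
  }
  s_m <- 1 / (allow_dM * sqrt(n_pt * n_dof))
  C <- rbind(A * s_m, Ca)
  w <- as.numeric(t(do.call(rbind, Wg_raw)))    # block-major, k within block
  for (it in seq_len(max_iter)) {
    d <- c(as.numeric(A %*% w) * s_m, numeric(nrow(Ca)))
    w_new <- as.numeric(pracma::lsqnonneg(C, d)$x)
    rel <- sqrt(sum((w_new - w)^2) / max(sum(w^2), 1e-12))
    w <- w_new
    if (rel < rel_tol) break
  }
  # keep activations comfortably inside [0, 1]; positive rescaling
  # preserves the NNLS fixed point (KKT conditions are scale-covariant)
  a_max <- 0
  for (bi in seq_along(blocks)) {
    cols <- (bi - 1) * k + seq_len(k)
    a_max <- max(a_max, max(crossprod(H_base[[blocks[[bi]]$side]], w[cols])))
  }
  if (a_max > 0.95) w <- w * 0.9 / a_max
  out <- lapply(sides, function(s) {
    bis <- which(vapply(blocks, function(b) b$side == s, TRUE))
    Wg <- t(vapply(bis, function(bi) w[(bi - 1) * k + seq_len(k)],
                   numeric(k)))
    Wg
  })
  names(out) <- sides
  out
}

#' Generate a synthetic gait dataset with known ground truth
#'
#' Builds, deterministically for a fixed seed: a trunk model using the
#' bundled reduced-set MTU parameters (29 per side) with smooth synthetic
#' geometry; stereotyped per-cycle synergy activations per side (shared
#' peak layout, small cycle-to-cycle timing jitter); leg activations
#' `W_leg H` plus truncated noise; ground-truth trunk activations
#' `W_trunk H`; clean lumbosacral moments from the muscle model and a noisy
#' inverse-dynamics copy; and a surrogate "measured" erector spinae
#' excitation — the true ES group-mean activation circularly advanced by
#' the injected electromechanical delay, rescaled and noised.
#'
#' Ground-truth trunk weights are drawn at muscle-group level and then made
#' *effort-consistent*: with only 3 lumbosacral moment components
#' constraining 6 muscle groups per side, arbitrary co-contraction is
#' invisible to net joint moments and therefore unrecoverable by any
#' moment-driven method; the generator keeps the self-consistent
#' effort-optimal recruitment implied by the raw draw (see the methods
#' vignette), which is also the motor-control premise the estimator itself
#' encodes. Heads of one muscle group share their ground-truth weights.
#'
#' @param spec a [syn_spec()].
#' @return list of class `syn_dataset` with elements `spec`, `model`,
#'   `footstrike_times`, `trunk_weights` / `leg_weights`
#'   (`list(right, left)`), and `cycles` — one entry per cycle holding
#'   `H_true` (`list(right, left)`), `leg_activations`, `trunk_true`
#'   (`nPt x 58`), `M_ID_clean`, `M_ID`, `duration_s`, and `excitation`
#'   (`list(right, left)` surrogate curves).
#' @export
make_dataset <- function(spec = syn_spec()) {
  stopifnot(inherits(spec, "syn_spec"))
  set.seed(spec$seed)
  sides <- c("right", "left")

  mtus <- if (spec$n_trunk == 29) {
    trunk_mtu_table("both")
  } else {
    rbind_sides <- function(s) {
      g <- make_geometry(spec$n_trunk, 3, spec$n_pt)$mtus
      g$side <- s
      g$name <- paste0(g$name, "_", s)
      g
    }
    do.call(rbind, lapply(sides, rbind_sides))
  }
  model <- trunk_model(mtus, smooth_geometry(mtus, 3, spec$n_pt))

  group_levels <- lapply(sides, function(s) {
    unique(mtus$group[mtus$side == s])
  })
  names(group_levels) <- sides
  group_index <- lapply(sides, function(s) {
    lapply(group_levels[[s]], function(gl) {
      which(mtus$side == s & mtus$group == gl)
    })
  })
  names(group_index) <- sides

  # each synergy gets one anchor leg muscle it dominates, as observed for
  # gait synergies; anchors keep the factorization identifiable
  leg_W <- lapply(sides, function(s) {
    W <- make_weights(spec$n_leg, spec$k_true, sparsity = 0.3)
    anchors <- sample(spec$n_leg, min(spec$k_true, spec$n_leg))
    for (j in seq_along(anchors)) {
      W[anchors[j], ] <- 0.15 * W[anchors[j], ]
      W[anchors[j], j] <- stats::runif(1, 0.6, 0.85)
    }
    W
  })
  names(leg_W) <- sides

  # stereotyped synergy timing for this synthetic subject; peaks spread
  # across the cycle with spacing that keeps bumps distinguishable
  timing <- lapply(sides, function(s) {
    k <- spec$k_true
    list(centers = ((seq_len(k) - 1 + 0.5 +
                       stats::runif(k, -0.15, 0.15)) / k) %% 1,
         widths = stats::runif(k, 0.4, 0.65) / (2 * k))
  })
  names(timing) <- sides
  H_base <- lapply(sides, function(s) {
    make_synergy_activations(spec$k_true, spec$n_pt,
                             centers = timing[[s]]$centers,
                             widths = timing[[s]]$widths)
  })
  names(H_base) <- sides

  Wg_raw <- lapply(sides, function(s) {
    make_weights(length(group_levels[[s]]), spec$k_true, sparsity = 0.3,
                 minimal_fraction = spec$minimal_fraction)
  })
  names(Wg_raw) <- sides
  Wg <- effort_consistent_weights(model, H_base, Wg_raw, group_index)

  trunk_W <- lapply(sides, function(s) {
    gs <- lengths(group_index[[s]])
    W <- Wg[[s]][rep(seq_along(gs), gs), , drop = FALSE]
    if (spec$weight_jitter_sd > 0) {
      W <- W * matrix(pmax(stats::rnorm(length(W), 1,
                                        spec$weight_jitter_sd), 0),
                      nrow(W))
    }
    rownames(W) <- mtus$name[mtus$side == s]
    W
  })
  names(trunk_W) <- sides

  durations <- stats::rnorm(spec$n_cycles, spec$mean_cycle_duration_s, 0.03)
  footstrikes <- cumsum(c(0, durations))
  es_idx <- lapply(sides, function(s) {
    which(mtus$side == s & mtus$group == "ES")
  })
  names(es_idx) <- sides

  trunc_noise <- function(x, sd) {
    if (sd == 0) return(x)
    pmin(pmax(x + stats::rnorm(length(x), 0, sd), 0), 1)
  }

  cycles <- lapply(seq_len(spec$n_cycles), function(cy) {
    H <- lapply(sides, function(s) {
      make_synergy_activations(
        spec$k_true, spec$n_pt,
        centers = (timing[[s]]$centers +
                     stats::rnorm(spec$k_true, 0, 0.008)) %% 1,
        widths = timing[[s]]$widths)
    })
    names(H) <- sides
    leg <- lapply(sides, function(s) {
      A <- leg_W[[s]] %*% H[[s]]
      matrix(trunc_noise(A, spec$activation_noise_sd), nrow(A),
             dimnames = dimnames(A))
    })
    names(leg) <- sides
    a_true <- matrix(0, spec$n_pt, nrow(mtus),
                     dimnames = list(NULL, mtus$name))
    for (s in sides) {
      a_true[, mtus$side == s] <- t(trunk_W[[s]] %*% H[[s]])
    }
    M_clean <- joint_moments(a_true, model)
    M_id <- M_clean + if (spec$moment_noise_sd > 0) {
      matrix(stats::rnorm(length(M_clean), 0, spec$moment_noise_sd),
             nrow(M_clean))
    } else 0
    colnames(M_id) <- colnames(M_clean)
    exc <- lapply(sides, function(s) {
      es <- rowMeans(a_true[, es_idx[[s]], drop = FALSE])
      # excitation leads activation: advance by the injected delay
      adv <- circ_shift(es, -spec$injected_emd_ms / 1000 / durations[cy] *
                          length(es))
      pmax(trunc_noise(0.65 * adv, spec$activation_noise_sd), 0)
    })
    names(exc) <- sides
    list(H_true = H, leg_activations = leg, trunk_true = a_true,
         M_ID_clean = M_clean, M_ID = M_id, duration_s = durations[cy],
         excitation = exc)
  })
  structure(list(spec = spec, model = model, footstrike_times = footstrikes,
                 trunk_weights = trunk_W, leg_weights = leg_W,
                 cycles = cycles),
            class = "syn_dataset")
}

#' @export
print.syn_dataset <- function(x, ...) {
  cat(sprintf(
    "<syn_dataset> %d cycles x %d samples; k=%d synergies; %d trunk MTUs\n",
    x$spec$n_cycles, x$spec$n_pt, x$spec$k_true, nrow(x$model$mtus)))
  cat(sprintf("  noise: activation sd %.3g, moment sd %.3g Nm; injected EMD %g ms\n",
              x$spec$activation_noise_sd, x$spec$moment_noise_sd,
              x$spec$injected_emd_ms))
  invisible(x)
}

#' Export a synthetic dataset to storage/CSV files
#'
#' Writes one `.sto` per cycle for leg activations, trunk ground-truth
#' activations and moments, plus CSV bundles for the ground-truth weights
#' and foot-strike times, following the package's gait I/O conventions.
#'
#' @param dataset a `syn_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- dataset$footstrike_times
  utils::write.csv(data.frame(footstrike_s = fs),
                   file.path(dir, "footstrikes.csv"), row.names = FALSE)
  for (s in names(dataset$trunk_weights)) {
    utils::write.csv(dataset$trunk_weights[[s]],
                     file.path(dir, sprintf("trunk_weights_%s.csv", s)))
  }
  for (i in seq_along(dataset$cycles)) {
    cy <- dataset$cycles[[i]]
    tt <- seq(fs[i], fs[i + 1], length.out = dataset$spec$n_pt)
    write_storage(ts_table(tt, cy$trunk_true),
                  file.path(dir, sprintf("cycle%02d_trunk_true.sto", i)))
    write_storage(ts_table(tt, cy$M_ID),
                  file.path(dir, sprintf("cycle%02d_moments_id.sto", i)))
    for (s in names(cy$leg_activations)) {
      write_storage(ts_table(tt, t(cy$leg_activations[[s]])),
                    file.path(dir, sprintf("cycle%02d_leg_%s.sto", i, s)))
    }
  }
  invisible(dir)
}
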