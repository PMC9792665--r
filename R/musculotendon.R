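#' Trunk musculotendon model
#'
#' Bundles the musculotendon unit (MTU) parameter table with its per-sample
#' geometry. The full trunk set has 58 rigid-tendon Hill-type MTUs — 29 per
#' side — grouped into 6 anatomical muscles per side: rectus abdominis (RA),
#' erector spinae (ES), quadratus lumborum (QL), multifidus (MF), external
#' oblique (EO) and internal oblique (IO).
#'
#' @param mtus data.frame with columns `name`, `group`, `side`, `fmo` (peak
#'   isometric force, N), `lmo` (optimal fiber length, m), `lts` (tendon
#'   slack length, m) and optionally `acsa` (cm^2).
#' @param geometry list with `lmt` (`nPt x nMusc` musculotendon lengths, m),
#'   `arms` (`nPt x nMusc x nDoF` moment arms, m) and `dof_labels`.
#' @return An object of class `trunk_model`. `grouping(model)` returns the
#'   named list of MTU index vectors, one per side-specific muscle group.
#' @export
trunk_model <- function(mtus, geometry = NULL) {
  mtus <- as.data.frame(mtus)
  need <- c("name", "group", "side", "fmo", "lmo", "lts")
  if (!all(need %in% names(mtus))) {
    stop_trunksyn("argument_error", paste(
      "mtus must have columns", paste(need, collapse = ", ")))
  }
  if (any(mtus$fmo <= 0) || any(mtus$lmo <= 0) || any(mtus$lts < 0)) {
    stop_trunksyn("argument_error",
                  "require fmo > 0, lmo > 0, lts >= 0 for every MTU")
  }
  if (!is.null(geometry)) {
    if (ncol(geometry$lmt) != nrow(mtus) ||
        dim(geometry$arms)[2] != nrow(mtus) ||
        dim(geometry$arms)[1] != nrow(geometry$lmt)) {
      stop_trunksyn("argument_error", "geometry shapes inconsistent with MTUs")
    }
  }
  structure(list(mtus = mtus, geometry = geometry), class = "trunk_model")
}

#' @rdname trunk_model
#' @param model a `trunk_model`.
#' @export
grouping <- function(model) {
  key <- paste(model$mtus$group, model$mtus$side, sep = ".")
  split(seq_len(nrow(model$mtus)), key)
}

#' @export
print.trunk_model <- function(x, ...) {
  cat(sprintf("<trunk_model> %d MTUs in %d groups%s\n", nrow(x$mtus),
              length(grouping(x)),
              if (is.null(x$geometry)) " (no geometry)" else
                sprintf(", geometry %d samples x %d DoF",
                        nrow(x$geometry$lmt), dim(x$geometry$arms)[3])))
  invisible(x)
}

#' Reduced-set trunk MTU parameter table
#'
#' The 29 personalized reduced-set trunk MTUs (one side): anatomical
#' cross-sectional areas, peak isometric forces, optimal fiber lengths and
#' tendon slack lengths. Lengths are converted from the printed cm to m;
#' ACSA stays in cm^2.
#'
#' @param side `"right"`, `"left"`, or `"both"` (mirrored copy per side,
#'   58 rows).
#' @return data.frame with columns `name`, `group`, `side`, `acsa_generic`,
#'   `acsa`, `fmo`, `lmo_generic`, `lmo`, `lts_generic`, `lts`.
#' @export
trunk_mtu_table <- function(side = c("right", "left", "both")) {
  side <- match.arg(side)
  path <- system.file("extdata", "trunk_mtu_reduced_set.csv",
                      package = "trunksyn")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("lmo_generic", "lmo", "lts_generic", "lts")) {
    df[[col]] <- df[[col]] / 100  # cm -> m
  }
  one <- function(s, suffix = "") {
    df$side <- s
    df$name <- paste0(df$name, suffix)
    df[, c("name", "group", "side",
           setdiff(names(df), c("name", "group", "side")))]
  }
  if (side == "both") {
    rbind(one("right", "_r"), one("left", "_l"))
  } else {
    one(side)
  }
}

#' Normalized fiber length of a rigid-tendon MTU
#'
#' With a rigid tendon fixed at slack length, the fiber length is
#' `lMT - lTs` and the normalized fiber length is `(lMT - lTs)/lMo`. The
#' result is clamped to `[0.01, 1.8]` so degenerate geometry cannot produce
#' non-physical multipliers; clamping is reported via the `clamped`
#' attribute.
#'
#' @param lmt musculotendon length(s), m.
#' @param lmo optimal fiber length, m.
#' @param lts tendon slack length, m.
#' @return dimensionless normalized fiber length(s) in `[0.01, 1.8]`.
#' @export
normalized_fiber_length <- function(lmt, lmo, lts) {
  raw <- (lmt - lts) / lmo
  out <- pmin(pmax(raw, 0.01), 1.8)
  attr(out, "clamped") <- sum(raw < 0.01 | raw > 1.8)
  out
}

#' Hill active and passive force-length multipliers
#'
#' `active_fl` is the Gaussian active curve `exp(-(lnorm - 1)^2 / gamma)`
#' with width `gamma = 0.45` (a common Hill-model convention). `passive_fl`
#' is zero at or below optimal length and rises exponentially above it,
#' normalized to 1 at `lnorm = 1.7`.
#'
#' @param lnorm normalized fiber length(s), > 0.
#' @param gamma active curve width (default 0.45).
#' @return dimensionless force multiplier(s).
#' @export
active_fl <- function(lnorm, gamma = 0.45) exp(-(lnorm - 1)^2 / gamma)

#' @rdname active_fl
#' @param k passive exponential stiffness (default 4).
#' @export
passive_fl <- function(lnorm, k = 4) {
  pmax(expm1(k * (lnorm - 1)), 0) / expm1(k * 0.7)
}

#' Rigid-tendon Hill-type musculotendon force
#'
#' `F = FMo * (a * active_fl(lnorm) + passive_fl(lnorm))` with the
#' force-velocity multiplier fixed at 1, so force is affine in activation
#' for fixed geometry. The passive element is off by default (trunk fibers
#' are tuned to operate below optimal length where the passive curve is
#' zero anyway).
#'
#' @param a activation in `[0, 1]` (vector recycled against `lmt`).
#' @param fmo peak isometric force, N.
#' @param lmo optimal fiber length, m.
#' @param lts tendon slack length, m.
#' @param lmt musculotendon length(s), m.
#' @param passive include the passive force-length element (default FALSE).
#' @return force(s), N.
#' @export
mtu_force <- function(a, fmo, lmo, lts, lmt, passive = FALSE) {
  if (any(a < 0 | a > 1)) {
    stop_trunksyn("argument_error", "activation must lie in [0, 1]")
  }
  ln <- as.numeric(normalized_fiber_length(lmt, lmo, lts))
  fmo * (a * active_fl(ln) + if (passive) passive_fl(ln) else 0)
}

# nPt x nMusc matrix of moment gains dM/da (Nm per unit activation) for DoF j,
# plus the constant passive moment; shared by estimation and baselines
moment_gains <- function(model, passive = FALSE) {
  geo <- model$geometry
  if (is.null(geo)) stop_trunksyn("argument_error", "model has no geometry")
  if (anyNA(geo$lmt) || anyNA(geo$arms)) {
    stop_trunksyn("data_error", "NaN in musculotendon geometry")
  }
  ln <- sweep(sweep(geo$lmt, 2, model$mtus$lts, "-"), 2, model$mtus$lmo, "/")
  ln <- pmin(pmax(ln, 0.01), 1.8)
  act_gain <- sweep(active_fl(ln), 2, model$mtus$fmo, "*")   # nPt x nMusc
  n_dof <- dim(geo$arms)[3]
  gains <- array(0, dim(geo$arms))
  pass_m <- matrix(0, nrow(geo$lmt), n_dof)
  pf <- if (passive) sweep(passive_fl(ln), 2, model$mtus$fmo, "*") else NULL
  for (j in seq_len(n_dof)) {
    gains[, , j] <- geo$arms[, , j] * act_gain
    if (passive) pass_m[, j] <- rowSums(geo$arms[, , j] * pf)
  }
  list(gains = gains, passive_moment = pass_m)
}

#' Joint moments generated by a set of activations
#'
#' `M[t, j] = sum_i arms[t, i, j] * F_i(a[t, i], lMT[t, i])` for every
#' degree of freedom j of the model geometry.
#'
#' @param A `nPt x nMusc` activation matrix.
#' @param model a [trunk_model()] carrying geometry.
#' @param passive include passive fiber forces (default FALSE).
#' @return `nPt x nDoF` moment matrix, Nm, with DoF labels as column names.
#' @export
joint_moments <- function(A, model, passive = FALSE) {
  A <- as.matrix(A)
  g <- moment_gains(model, passive)
  if (nrow(A) != dim(g$gains)[1] || ncol(A) != dim(g$gains)[2]) {
    stop_trunksyn("argument_error", "activation shape mismatch with geometry")
  }
  n_dof <- dim(g$gains)[3]
  M <- vapply(seq_len(n_dof),
              function(j) rowSums(A * g$gains[, , j]) + g$passive_moment[, j],
              numeric(nrow(A)))
  M <- matrix(M, nrow = nrow(A))
  colnames(M) <- model$geometry$dof_labels
  M
}

#' Peak isometric force from anatomical cross-sectional area
#'
#' Multiplies ACSA by the maximum muscle stress of 100 N/cm^2.
#'
#' @param acsa anatomical cross-sectional area(s), cm^2, >= 0.
#' @return peak isometric force(s), N.
#' @examples
#' fmax_from_acsa(7.50) # 750
#' @export
fmax_from_acsa <- function(acsa) {
  if (any(acsa < 0)) stop_trunksyn("argument_error", "ACSA must be >= 0")
  100 * acsa
}

#' Distribute a muscle group's total ACSA over its member MTUs
#'
#' Splits the group total in proportion to the generic member ACSAs, so the
#' personalized members keep the generic fraction ratio and sum to the
#' group total.
#'
#' @param total_acsa group total ACSA, cm^2, >= 0.
#' @param generic_member_acsas positive generic ACSAs of the members.
#' @return member ACSAs summing to `total_acsa`.
#' @export
distribute_group_acsa <- function(total_acsa, generic_member_acsas) {
  if (total_acsa < 0) stop_trunksyn("argument_error", "total ACSA must be >= 0")
  s <- sum(generic_member_acsas)
  if (s <= 0) {
    stop_trunksyn("argument_error", "generic member ACSAs must sum > 0")
  }
  total_acsa * generic_member_acsas / s
}

#' Tune optimal fiber and tendon slack length to a target operating length
#'
#' Rescales `(lMo, lTs)` jointly — holding the ratio `lTs/(lTs + lMo)`
#' fixed — so that the maximum normalized fiber length over the supplied
#' musculotendon-length series equals `target` (default 0.95, i.e. "slightly
#' less than 1" for close-to-optimal force generation). Closed form: with
#' `rho = lTs/(lTs + lMo)`, the total `L = lTs + lMo` becomes
#' `max(lMT) / (rho + target * (1 - rho))`.
#'
#' @param lmo,lts current optimal fiber and tendon slack lengths, m.
#' @param lmt_series musculotendon lengths over the motion, m (> 0).
#' @param target desired maximum normalized fiber length in (0, 1).
#' @return list with tuned `lmo` and `lts`.
#' @export
tune_fiber_lengths <- function(lmo, lts, lmt_series, target = 0.95) {
  if (target <= 0 || target >= 1) {
    stop_trunksyn("argument_error", "target must lie in (0, 1)")
  }
  if (length(lmt_series) == 0 || any(lmt_series <= 0)) {
    stop_trunksyn("data_error", "lMT series must be nonempty and positive")
  }
  rho <- lts / (lts + lmo)
  L <- max(lmt_series) / (rho + target * (1 - rho))
  list(lmo = (1 - rho) * L, lts = rho * L)
}

#' Optimization-based muscle-set reduction
#'
#' Finds peak isometric forces for a reduced MTU set such that, over many
#' random poses at full activation, the reduced set generates joint moments
#' matching those of the original set: a nonnegative least-squares fit of
#' the pose-by-DoF moment matrix. Each reduced MTU inherits the geometry of
#' a representative original MTU.
#'
#' @param original a [trunk_model()] (full set; `fmo` known).
#' @param mapping integer vector over reduced MTUs giving, for each, the
#'   index of the original MTU whose geometry it shares.
#' @param pose_sampler `function(seed)` returning a list with `arms`
#'   (`nMusc x nDoF` moment arms) and `lmt` (`nMusc` lengths) for one random
#'   pose of the original set.
#' @param n_poses number of random poses (>= number of reduced MTUs).
#' @param seed integer RNG seed.
#' @return numeric vector of reduced-set peak isometric forces, N.
#' @export
reduce_mtu_set <- function(original, mapping, pose_sampler, n_poses,
                           seed = 1L) {
  n_red <- length(mapping)
  if (n_poses < n_red) {
    stop_trunksyn("argument_error", "need at least as many poses as MTUs")
  }
  mt <- original$mtus
  rows_y <- list(); rows_x <- list()
  for (p in seq_len(n_poses)) {
    pose <- pose_sampler(seed + p)
    ln <- normalized_fiber_length(pose$lmt, mt$lmo, mt$lts)
    f_unit <- active_fl(ln)                       # force per FMo at a = 1
    m_orig <- crossprod(pose$arms, mt$fmo * f_unit)  # nDoF
    x <- pose$arms[mapping, , drop = FALSE] * f_unit[mapping]  # nRed x nDoF
    rows_y[[p]] <- as.numeric(m_orig)
    rows_x[[p]] <- t(x)
  }
  X <- do.call(rbind, rows_x)
  y <- unlist(rows_y)
  if (qr(X)$rank < n_red) {
    warning("rank-deficient reduction system; minimum-norm NNLS solution")
  }
  as.numeric(pracma::lsqnonneg(X, y)$x)
}
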