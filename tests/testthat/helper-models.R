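# shared builders for small test models; geometry is constructed so the
# active force-length multiplier is exactly 1 (lnorm = 1) unless stated

# n_musc MTUs at lnorm = 1 with prescribed constant moment arms
# arms_mat: n_musc x n_dof
const_model <- function(arms_mat, fmo = 1000, n_pt = 3, group = "G",
                        side = "right", lmo = 0.1, lts = 0.1) {
  n_musc <- nrow(arms_mat)
  n_dof <- ncol(arms_mat)
  mtus <- data.frame(name = sprintf("m%d", seq_len(n_musc)),
                     group = rep_len(group, n_musc),
                     side = rep_len(side, n_musc),
                     fmo = rep_len(fmo, n_musc),
                     lmo = lmo, lts = lts)
  arms <- array(0, c(n_pt, n_musc, n_dof))
  for (j in seq_len(n_dof)) {
    arms[, , j] <- matrix(arms_mat[, j], n_pt, n_musc, byrow = TRUE)
  }
  trunk_model(mtus, list(lmt = matrix(lts + lmo, n_pt, n_musc),
                         arms = arms,
                         dof_labels = sprintf("dof%d", seq_len(n_dof))))
}

# random smooth model via the package generator, one group per muscle
random_model <- function(n_musc, n_dof, n_pt, seed) {
  make_geometry(n_musc, n_dof, n_pt, seed = seed)
}

# a well-behaved normalized synergy-activation matrix
test_H <- function(k, n_pt, seed = 1) {
  make_synergy_activations(k, n_pt, seed = seed)
}

# small ts_table with named channels
test_table <- function(n = 50, n_ch = 2, seed = 1, dt = 0.01) {
  set.seed(seed)
  ts_table(seq(0, by = dt, length.out = n),
           matrix(runif(n * n_ch), n, n_ch,
                  dimnames = list(NULL, sprintf("ch%d", seq_len(n_ch)))))
}
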