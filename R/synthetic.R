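# Synthetic spin systems and NOESY buildups with known ground truth,
# plus the experiment-design utilities (tau_c scaling, maximal mixing
# time).

# local proton offsets (A) of one idealized residue; geminal H5'/H5''
# pair 1.78 A apart, remaining protons spread so that inter-residue
# contacts span ~1.8-6 A on the assembled helix
.helix_protons <- data.frame(
  name = c("H8", "H1'", "H2'", "H5'", "H5''"),
  class = c("other", "other", "other", "methylene", "methylene"),
  dx = c(4.0, 6.2, 6.6, 7.4, 7.4),
  dy = c(0.0, 1.2, -1.4, 0.6, -0.6),
  dz = c(0.0, 0.2, 0.6, 2.1, 3.415),
  stringsAsFactors = FALSE)

#' Deterministic parametric helix spin system with known distances
#'
#' Places 5 protons per residue (a base proton, three ribose-like
#' protons and a geminal methylene pair at 1.78 A) on an A-form-like
#' helix (2.8 A rise, 32.7 degree twist).  Interproton distances span
#' roughly 1.8-6 A, the working range of eNOE extraction.  Optional
#' multi-conformer jitter (Gaussian, seeded) emulates an ensemble; the
#' recorded ground-truth distances are the r^-6 averages over
#' conformers, i.e. exactly what a NOE reports.
#'
#' @param n_residues number of residues (>= 2); 4 residues give the
#'   20-proton benchmark system.
#' @param conformers number of conformers (default 1).
#' @param displacement per-atom RMS jitter amplitude in Angstrom
#'   (default 0: all conformers identical).
#' @param seed RNG seed for the jitter.
#' @return list with \code{spin_system} and \code{truth} (data.frame
#'   \code{key_i}, \code{key_j}, \code{r_true}).
#' @export
make_helix_spin_system <- function(n_residues, conformers = 1L,
                                   displacement = 0, seed = 1L) {
  stopifnot(n_residues >= 2L, conformers >= 1L, displacement >= 0)
  rise <- 2.8; twist <- 32.7 * pi / 180
  per <- nrow(.helix_protons)
  atoms <- data.frame(
    resno = rep(seq_len(n_residues), each = per),
    resid = "G",
    name = rep(.helix_protons$name, n_residues),
    class = rep(.helix_protons$class, n_residues),
    exchangeable = FALSE,
    stringsAsFactors = FALSE)
  base <- matrix(0, n_residues * per, 3L)
  for (r in seq_len(n_residues)) {
    th <- (r - 1L) * twist
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L)
    loc <- as.matrix(.helix_protons[c("dx", "dy", "dz")])
    pts <- loc %*% t(rot)
    pts[, 3L] <- pts[, 3L] + (r - 1L) * rise
    base[(r - 1L) * per + seq_len(per), ] <- pts
  }
  xyz <- array(0, c(conformers, nrow(base), 3L))
  if (displacement > 0 && conformers > 1L) {
    jit <- withr::with_seed(seed, array(
      stats::rnorm(length(xyz), sd = displacement / sqrt(3)), dim(xyz)))
  } else jit <- array(0, dim(xyz))
  for (m in seq_len(conformers)) xyz[m, , ] <- base + jit[m, , ]
  s <- new_spin_system(atoms, xyz, source = sprintf(
    "synthetic-helix-%dres-%dconf", n_residues, conformers))
  keys <- s$atoms$key
  idx <- which(upper.tri(diag(length(keys))), arr.ind = TRUE)
  r_true <- vapply(seq_len(nrow(idx)), function(p) {
    ensemble_distance(s, keys[c(idx[p, 1L], idx[p, 2L])], mode = "r6")
  }, 0)
  truth <- data.frame(key_i = keys[idx[, 1L]], key_j = keys[idx[, 2L]],
                      r_true = r_true, stringsAsFactors = FALSE)
  list(spin_system = s, truth = truth)
}

#' Simulate a NOESY buildup series from a spin system
#'
#' Full relaxation-matrix simulation: intensities are the entries of
#' \eqn{A(\tau_m) = \exp(-R \tau_m)} scaled by the initial
#' magnetization deviations, averaged over conformers, with optional
#' additive Gaussian noise scaled to the largest diagonal intensity at
#' the first mixing time.  Emits every diagonal and both directions of
#' every cross peak in buildup-table form.
#'
#' @param s a \code{spin_system}.
#' @param cond \code{\link{noe_conditions}}.
#' @param mixing_times seconds; default the 8-point series
#'   \code{seq(0.04, 0.32, by = 0.04)}.
#' @param noise_sd_relative additive noise SD relative to the largest
#'   first-mixing-time diagonal (default 0).
#' @param seed RNG seed for the noise.
#' @param dM0 initial magnetization deviation: scalar or per-spin
#'   vector (heterogeneous values exercise gn-eNOE logic).
#' @param pairs optional two-column matrix of atom keys restricting the
#'   emitted cross peaks.
#' @return a \code{buildup_set} (uncorrected).
#' @export
simulate_noesy <- function(s, cond, mixing_times = seq(0.04, 0.32, by = 0.04),
                           noise_sd_relative = 0, seed = 1L, dM0 = 1,
                           pairs = NULL) {
  stopifnot(inherits(s, "spin_system"), all(mixing_times > 0))
  n <- nrow(s$atoms)
  dM0 <- rep_len(dM0, n)
  nt <- length(mixing_times)
  inten <- array(0, c(n, n, nt))
  for (m in seq_len(s$n_conf)) {
    R <- build_relaxation_matrix(s, m, cond)
    for (t in seq_len(nt)) {
      inten[, , t] <- inten[, , t] +
        propagate(R, mixing_times[t]) %*% diag(dM0, n)
    }
  }
  inten <- inten / s$n_conf
  keys <- s$atoms$key
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  } else {
    idx <- cbind(match(pairs[, 1L], keys), match(pairs[, 2L], keys))
    if (anyNA(idx)) stop("pair atom not in the spin system")
  }
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = paste0("D|", keys[i]), atom_i = keys[i], atom_j = keys[i],
      tau = mixing_times, intensity = inten[i, i, ],
      stringsAsFactors = FALSE)
  }
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1L]; j <- idx[p, 2L]
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = paste0("C|", keys[i], "|", keys[j]),
      atom_i = keys[i], atom_j = keys[j],
      tau = mixing_times, intensity = inten[i, j, ],
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = paste0("C|", keys[j], "|", keys[i]),
      atom_i = keys[j], atom_j = keys[i],
      tau = mixing_times, intensity = inten[j, i, ],
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  peaks$noise <- NA_real_
  if (noise_sd_relative > 0) {
    diag1 <- max(abs(inten[, , 1L][diag(n) == 1]))
    sd <- noise_sd_relative * diag1
    peaks$intensity <- peaks$intensity +
      withr::with_seed(seed, stats::rnorm(nrow(peaks), sd = sd))
    peaks$noise <- sd
  }
  peaks <- peaks[order(peaks$peak_id, peaks$tau), , drop = FALSE]
  rownames(peaks) <- NULL
  new_buildup_set(peaks, corrected = FALSE)
}

#' Stokes-Einstein scaling of the rotational correlation time
#'
#' The correlation time scales linearly with solvent viscosity, so a
#' reference tau_c can be carried to another solvent by multiplying
#' with the viscosity ratio (e.g. the 23% higher viscosity of D2O:
#' 2.23 ns x 1.23 = 2.74 ns).
#'
#' @param tau_ref reference correlation time (s).
#' @param viscosity_ratio target / reference solvent viscosity.
#' @return scaled correlation time (s).
#' @export
stokes_einstein_tau <- function(tau_ref, viscosity_ratio) {
  stopifnot(tau_ref > 0, viscosity_ratio > 0)
  tau_ref * viscosity_ratio
}

#' Maximal useful NOESY mixing time for buildup fitting
#'
#' Empirical inverse rule \eqn{\tau_{max} = c / \tau_c} with
#' \eqn{c = 4 \times 10^{-10}\,s^2} for RNA (proton density lower than
#' in proteins, where \eqn{c = 2.5 \times 10^{-10}\,s^2} applies).
#' For tau_c = 2.23 ns this gives ~0.179 s, i.e. the 40-160 ms window
#' of an 8 x 40 ms series.
#'
#' @param tau_c rotational correlation time (s).
#' @param constant rule constant in s^2 (default \code{4e-10}).
#' @param grid optional vector of acquired mixing times (s); when given,
#'   the result is floored to the largest grid point not exceeding the
#'   rule value.
#' @return maximal mixing time in seconds.
#' @export
max_mixing_time <- function(tau_c, constant = 4e-10, grid = NULL) {
  stopifnot(tau_c > 0, constant > 0)
  tmax <- constant / tau_c
  if (!is.null(grid)) {
    ok <- grid[grid <= tmax + 1e-12]
    if (length(ok) == 0L) stop("no acquired mixing time below the rule value")
    tmax <- max(ok)
  }
  tmax
}
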