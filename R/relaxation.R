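# Homonuclear dipolar relaxation: spectral density, Solomon pair rates,
# full relaxation matrix and NOESY magnetization propagation.
#
# Rate convention: K = (1/10) * ((mu0/4pi) * hbar * gammaH^2)^2 with the
# rigid isotropic Lorentzian J(w) = tau_c / (1 + (w tau_c)^2).  Distance
# extraction inverts the same expressions, so any self-consistent
# convention yields identical distances (verified by the sigma <-> r
# round-trip tests).

# gammaH in rad s^-1 T^-1, hbar in J s, mu0/4pi in T m A^-1
.gamma_h <- 2.6752218744e8
.hbar <- 1.054571817e-34
.mu0_4pi <- 1e-7

# dipolar constant in Angstrom^6 s^-2 (so that K * r[A]^-6 * J[s] is s^-1)
dipolar_constant <- function() {
  k_si <- 0.1 * (.mu0_4pi * .hbar * .gamma_h^2)^2  # m^6 s^-2
  k_si * 1e60
}

#' Spectral density function
#'
#' Rigid isotropic-tumbling Lorentzian \eqn{J(\omega) = \tau_c / (1 +
#' (\omega\tau_c)^2)}.
#'
#' @param omega angular frequency in rad/s (vectorized).
#' @param tau_c rotational correlation time in seconds.
#' @return spectral density value(s) in seconds.
#' @examples
#' spectral_density(0, 2.23e-9)        # == tau_c
#' spectral_density(1 / 2.23e-9, 2.23e-9)  # == tau_c / 2
#' @export
spectral_density <- function(omega, tau_c) {
  stopifnot(tau_c > 0)
  tau_c / (1 + (omega * tau_c)^2)
}

#' Dipolar cross- and auto-relaxation rates for a proton pair
#'
#' Solomon rates for an isolated, rigidly tumbling proton pair at
#' distance \code{r}:
#' \deqn{\sigma = K r^{-6} [6 J(2\omega_0) - J(0)]}
#' \deqn{\rho_{pair} = K r^{-6} [J(0) + 3 J(\omega_0) + 6 J(2\omega_0)]}
#' In the slow-tumbling regime (\eqn{\omega_0 \tau_c \gg 1.12}, always
#' the case for RNA at high field) \eqn{\sigma < 0}.
#'
#' @param r interproton distance in Angstrom (vectorized).
#' @param cond a \code{\link{noe_conditions}} object.
#' @return list with components \code{sigma} and \code{rho_pair}, both
#'   in s^-1.
#' @examples
#' cond <- noe_conditions()
#' pair_rates(3.0, cond)$sigma / pair_rates(6.0, cond)$sigma  # = 64
#' @export
pair_rates <- function(r, cond) {
  stopifnot(inherits(cond, "noe_conditions"))
  if (any(r <= 0.5)) stop("interproton distance must exceed 0.5 Angstrom")
  k6 <- dipolar_constant() * r^-6
  j0 <- spectral_density(0, cond$tau_c)
  j1 <- spectral_density(cond$omega0, cond$tau_c)
  j2 <- spectral_density(2 * cond$omega0, cond$tau_c)
  list(sigma = k6 * (6 * j2 - j0),
       rho_pair = k6 * (j0 + 3 * j1 + 6 * j2))
}

# sign-carrying cross-relaxation prefactor K * [6J(2w0) - J(0)], A^6 s^-1
cross_relaxation_prefactor <- function(cond) {
  j0 <- spectral_density(0, cond$tau_c)
  j2 <- spectral_density(2 * cond$omega0, cond$tau_c)
  dipolar_constant() * (6 * j2 - j0)
}

#' Full homonuclear relaxation matrix of a spin system conformer
#'
#' Assembles the relaxation-rate matrix R over all protons of one
#' conformer: off-diagonal entries are the pairwise cross-relaxation
#' rates \eqn{\sigma_{ij}}, diagonal entries the summed pairwise
#' auto-relaxation contributions \eqn{\sum_{j \ne i} \rho_{pair}(r_{ij})}
#' plus any external rate from \code{cond$rho_external}.  This matrix
#' realizes the simultaneous magnetization-transfer pathways among all
#' spins that the full-matrix spin-diffusion treatment requires.
#'
#' @param s a \code{\link{make_spin_system}} object.
#' @param conformer conformer index (default 1).
#' @param cond a \code{\link{noe_conditions}} object.
#' @param cutoff optional distance cutoff in Angstrom; pairs farther
#'   apart contribute nothing.  \code{NULL} (default) includes all
#'   pairs, appropriate for small systems.
#' @return object of class \code{"relaxation_matrix"}: list with
#'   \code{rates} (symmetric numeric matrix, s^-1, dimnames = atom
#'   keys), \code{conditions} and \code{atoms}.
#' @export
build_relaxation_matrix <- function(s, conformer = 1L, cond, cutoff = NULL) {
  stopifnot(inherits(s, "spin_system"), inherits(cond, "noe_conditions"))
  n <- nrow(s$atoms)
  if (n < 2L) stop("relaxation matrix needs at least 2 protons")
  if (conformer < 1L || conformer > s$n_conf) stop("no such conformer")
  xyz <- s$xyz[conformer, , , drop = TRUE]
  dim(xyz) <- c(n, 3L)
  d <- as.matrix(stats::dist(xyz))
  close <- d < 0.5 & upper.tri(d)
  if (any(close)) {
    idx <- which(close, arr.ind = TRUE)[1L, ]
    stop(sprintf("overlapping atoms (r < 0.5 A): %s and %s",
                 s$atoms$key[idx[1L]], s$atoms$key[idx[2L]]))
  }
  diag(d) <- Inf
  if (!is.null(cutoff)) d[d > cutoff] <- Inf
  pr <- pair_rates(ifelse(is.finite(d), d, 1), cond)
  sigma <- ifelse(is.finite(d), pr$sigma, 0)
  rho <- ifelse(is.finite(d), pr$rho_pair, 0)
  rates <- sigma
  diag(rates) <- rowSums(rho) + resolve_rho_external(cond, s$atoms$class)
  dimnames(rates) <- list(s$atoms$key, s$atoms$key)
  structure(list(rates = rates, conditions = cond, atoms = s$atoms),
            class = "relaxation_matrix")
}

#' Propagate NOESY magnetization through the full relaxation matrix
#'
#' Computes the transfer matrix \eqn{A(\tau_m) = \exp(-R \tau_m)} by a
#' dense matrix exponential.  Entry (i, j) is the normalized intensity
#' contribution of spin j's initial magnetization deviation to peak i
#' after a mixing period of \code{tau_m}.
#'
#' @param R a \code{\link{build_relaxation_matrix}} object.
#' @param tau_m mixing time(s) in seconds, each >= 0.
#' @return for a single mixing time a matrix; for several, a 3-d array
#'   with dim \code{c(n, n, length(tau_m))}.
#' @export
propagate <- function(R, tau_m) {
  stopifnot(inherits(R, "relaxation_matrix"), all(tau_m >= 0))
  n <- nrow(R$rates)
  one <- function(tm) {
    if (tm == 0) return(diag(n))
    as.matrix(Matrix::expm(-R$rates * tm))
  }
  if (length(tau_m) == 1L) {
    a <- one(tau_m)
    dimnames(a) <- dimnames(R$rates)
    return(a)
  }
  out <- vapply(tau_m, one, matrix(0, n, n))
  dimnames(out) <- c(dimnames(R$rates), list(NULL))
  out
}

#' Analytic two-spin Solomon solution
#'
#' Closed-form NOESY intensities of an isolated spin pair with auto
#' rates \code{rho_i}, \code{rho_j}, cross rate \code{sigma} and initial
#' magnetization deviations \code{dM_ii0}, \code{dM_jj0}.  With
#' \eqn{\bar\rho = (\rho_i+\rho_j)/2}, \eqn{\delta = (\rho_i-\rho_j)/2},
#' \eqn{\Delta = \sqrt{\delta^2 + \sigma^2}}:
#' \deqn{I_{ii}(\tau) = e^{-\bar\rho\tau}[\cosh\Delta\tau -
#'   \delta \sinh(\Delta\tau)/\Delta]\,\Delta M_{ii}(0)}
#' \deqn{I_{ij}(\tau) = -\sigma e^{-\bar\rho\tau}
#'   \sinh(\Delta\tau)/\Delta\,\Delta M_{jj}(0)}
#' Cross peak (i, j) carries the magnetization transferred from origin
#' spin j to destination spin i; this is the isolated-pair model used to
#' fit corrected buildups.
#'
#' @param rho_i,rho_j auto-relaxation rates, s^-1.
#' @param sigma cross-relaxation rate, s^-1 (negative for slow tumbling).
#' @param dM_ii0,dM_jj0 initial magnetization deviations (arbitrary units).
#' @param tau_m mixing time(s), s (vectorized).
#' @return list with numeric vectors \code{I_ii}, \code{I_jj},
#'   \code{I_ij}, \code{I_ji} along \code{tau_m}.
#' @export
two_spin_closed_form <- function(rho_i, rho_j, sigma, dM_ii0, dM_jj0, tau_m) {
  stopifnot(all(tau_m >= 0))
  rbar <- (rho_i + rho_j) / 2
  delta <- (rho_i - rho_j) / 2
  dd <- sqrt(delta^2 + sigma^2)
  e <- exp(-rbar * tau_m)
  if (dd < .Machine$double.eps^0.75) {
    ch <- rep(1, length(tau_m)); shd <- tau_m
  } else {
    ch <- cosh(dd * tau_m); shd <- sinh(dd * tau_m) / dd
  }
  list(I_ii = e * (ch - delta * shd) * dM_ii0,
       I_jj = e * (ch + delta * shd) * dM_jj0,
       I_ij = -sigma * e * shd * dM_jj0,
       I_ji = -sigma * e * shd * dM_ii0)
}
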