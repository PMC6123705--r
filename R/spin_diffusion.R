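# Spin-diffusion correction factors from a reference structure or
# ensemble, and their application to measured buildup intensities.

#' Spin-diffusion correction factors from a reference structure
#'
#' For every requested proton pair and mixing time, simulates (i) the
#' full-matrix NOESY intensity including all relayed transfer pathways
#' and (ii) the isolated two-spin intensity using the same auto rates
#' \eqn{\rho_i, \rho_j} (the full diagonal entries) and cross rate
#' \eqn{\sigma_{ij}}.  The correction factor is the ratio
#' two-spin / full-matrix; multiplying a measured cross-peak intensity
#' by it restores an effective isolated-pair buildup.  For
#' multi-conformer references, simulated intensities are averaged over
#' conformers before the ratio is taken (the ratio of averaged
#' observables, not the average of ratios).  Initial magnetization is
#' uniform; ratios cancel any uniform scaling.
#'
#' Factors whose full-matrix intensity is numerically zero are flagged
#' unusable and excluded from fitting downstream.
#'
#' @param s reference \code{spin_system} (single- or multi-conformer).
#' @param cond \code{\link{noe_conditions}}.
#' @param mixing_times mixing times in seconds.
#' @param pairs two-column matrix or data.frame of atom keys
#'   (destination, origin); default all unordered proton pairs.
#' @param cutoff optional relaxation-matrix distance cutoff (A).
#' @return object of class \code{"correction_set"}: data.frame
#'   \code{factors} with columns \code{atom_i}, \code{atom_j},
#'   \code{tau}, \code{factor}, \code{usable}, plus the reference label.
#' @export
correction_factors <- function(s, cond, mixing_times, pairs = NULL,
                               cutoff = NULL) {
  stopifnot(inherits(s, "spin_system"), all(mixing_times > 0))
  keys <- s$atoms$key
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(length(keys))), arr.ind = TRUE)
    pairs <- cbind(keys[idx[, 1L]], keys[idx[, 2L]])
  }
  pairs <- as.matrix(pairs)
  ii <- match(pairs[, 1L], keys); jj <- match(pairs[, 2L], keys)
  if (anyNA(ii) || anyNA(jj)) stop("pair atom not in the spin system")
  nt <- length(mixing_times); np <- nrow(pairs)
  full <- matrix(0, np, nt)   # conformer-averaged full-matrix intensity
  iso <- matrix(0, np, nt)    # conformer-averaged two-spin intensity
  for (m in seq_len(s$n_conf)) {
    R <- build_relaxation_matrix(s, m, cond, cutoff = cutoff)
    for (t in seq_len(nt)) {
      A <- propagate(R, mixing_times[t])
      full[, t] <- full[, t] + A[cbind(ii, jj)]
    }
    for (p in seq_len(np)) {
      ts <- two_spin_closed_form(R$rates[ii[p], ii[p]],
                                 R$rates[jj[p], jj[p]],
                                 R$rates[ii[p], jj[p]],
                                 1, 1, mixing_times)
      iso[p, ] <- iso[p, ] + ts$I_ij
    }
  }
  full <- full / s$n_conf; iso <- iso / s$n_conf
  usable <- abs(full) > .Machine$double.eps * 100
  factor <- ifelse(usable, iso / full, NA_real_)
  usable <- usable & is.finite(factor) & factor > 0
  out <- data.frame(atom_i = rep(pairs[, 1L], nt),
                    atom_j = rep(pairs[, 2L], nt),
                    tau = rep(mixing_times, each = np),
                    factor = as.vector(factor),
                    usable = as.vector(usable),
                    stringsAsFactors = FALSE)
  structure(list(factors = out, reference_label = s$source),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  f <- x$factors
  cat(sprintf("Spin-diffusion corrections from '%s': %d pairs x %d mixing times (%d unusable)\n",
              x$reference_label, length(unique(paste(f$atom_i, f$atom_j))),
              length(unique(f$tau)), sum(!f$usable)))
  invisible(x)
}

# look up factors for (i, j, tau) treating the pair as unordered
lookup_factors <- function(cs, atom_i, atom_j, tau) {
  f <- cs$factors
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sprintf("%.9g", tau))
  want <- paste(pmin(atom_i, atom_j), pmax(atom_i, atom_j),
                sprintf("%.9g", tau))
  have <- paste(pmin(f$atom_i, f$atom_j), pmax(f$atom_i, f$atom_j),
                sprintf("%.9g", f$tau))
  idx <- match(want, have)
  list(factor = f$factor[idx], usable = f$usable[idx] & !is.na(idx),
       found = !is.na(idx))
}

#' Reference-based bias correction for diagonal-decay parameters
#'
#' Diagonal decays in a dense spin system are multi-exponential: the
#' magnetization a proton loses to its neighbours (fastest for
#' geminal-coupled methylene and amino protons) makes a monoexponential
#' fit over a finite mixing-time window underestimate both \eqn{\rho}
#' and \eqn{\Delta M(0)}.  This function quantifies that bias from the
#' reference structure: it simulates the conformer-averaged full-matrix
#' diagonal decays, fits them with the same monoexponential protocol
#' used on measured data, and reports the apparent parameters next to
#' the true matrix rates.  Multiplying experimentally fitted parameters
#' by true/apparent removes the bias (see
#' \code{\link{correct_decay_fits}}).
#'
#' @param s reference \code{spin_system}.
#' @param cond \code{\link{noe_conditions}}.
#' @param mixing_times simulated mixing-time grid (s).
#' @param fit_range window used for the monoexponential fits (defaults
#'   to the full grid).
#' @param cutoff optional relaxation-matrix distance cutoff (A).
#' @return data.frame with \code{key}, \code{rho_matrix} (true diagonal
#'   rate, conformer-averaged), \code{rho_apparent},
#'   \code{dM0_apparent} (simulated with unit initial magnetization).
#' @export
diagonal_decay_reference <- function(s, cond, mixing_times,
                                     fit_range = range(mixing_times),
                                     cutoff = NULL) {
  stopifnot(inherits(s, "spin_system"), all(mixing_times > 0))
  n <- nrow(s$atoms); nt <- length(mixing_times)
  dec <- matrix(0, n, nt)
  rho_true <- numeric(n)
  for (m in seq_len(s$n_conf)) {
    R <- build_relaxation_matrix(s, m, cond, cutoff = cutoff)
    rho_true <- rho_true + diag(R$rates)
    for (t in seq_len(nt)) dec[, t] <- dec[, t] + diag(propagate(R, mixing_times[t]))
  }
  dec <- dec / s$n_conf; rho_true <- rho_true / s$n_conf
  fits <- lapply(seq_len(n), function(i) {
    fit_diagonal(data.frame(tau = mixing_times, intensity = dec[i, ]),
                 fit_range = fit_range, cond = cond,
                 atom = s$atoms$key[i], min_r2 = 0)
  })
  data.frame(key = s$atoms$key,
             rho_matrix = rho_true,
             rho_apparent = vapply(fits, `[[`, 0, "rho"),
             dM0_apparent = vapply(fits, `[[`, 0, "dM0"),
             stringsAsFactors = FALSE)
}

#' Remove the multi-exponential bias from fitted diagonal parameters
#'
#' Rescales each fitted diagonal decay by the apparent-to-true ratio
#' obtained from \code{\link{diagonal_decay_reference}}:
#' \eqn{\rho \leftarrow \rho\, (\rho_{matrix}/\rho_{apparent})},
#' \eqn{\Delta M(0) \leftarrow \Delta M(0) / \Delta M(0)_{apparent}}.
#' Fallback fits and atoms missing from the reference are returned
#' unchanged.
#'
#' @param decays named list of \code{\link{fit_diagonal}} results
#'   (names = atom keys).
#' @param ref a \code{\link{diagonal_decay_reference}} data.frame.
#' @return the corrected list of decay fits.
#' @export
correct_decay_fits <- function(decays, ref) {
  lapply(decays, function(d) {
    i <- match(d$atom, ref$key)
    if (is.na(i) || d$fallback_used) return(d)
    d$rho <- d$rho * ref$rho_matrix[i] / ref$rho_apparent[i]
    d$dM0 <- d$dM0 / ref$dM0_apparent[i]
    d
  })
}

#' Apply spin-diffusion corrections to a buildup set
#'
#' Cross-peak intensities are multiplied by their correction factors;
#' diagonal series are left untouched.  Points whose factor is flagged
#' unusable are dropped with a warning.  A buildup set can be corrected
#' only once (the factors are multiplicative, not idempotent).
#'
#' @param b a \code{buildup_set}.
#' @param cs a \code{\link{correction_factors}} result.
#' @return corrected \code{buildup_set} (with \code{corrected = TRUE}).
#' @export
apply_corrections <- function(b, cs) {
  stopifnot(inherits(b, "buildup_set"), inherits(cs, "correction_set"))
  if (b$corrected) stop("buildup set is already spin-diffusion corrected")
  p <- b$peaks
  cross <- p$atom_i != p$atom_j
  if (any(cross)) {
    lk <- lookup_factors(cs, p$atom_i[cross], p$atom_j[cross], p$tau[cross])
    if (any(!lk$found)) {
      stop(sprintf("no correction factor for %d cross-peak point(s), e.g. %s / %s at %.3f s",
                   sum(!lk$found), p$atom_i[cross][!lk$found][1L],
                   p$atom_j[cross][!lk$found][1L],
                   p$tau[cross][!lk$found][1L]))
    }
    drop <- !lk$usable
    p$intensity[cross] <- p$intensity[cross] * lk$factor
    if (any(drop)) {
      warning(sprintf("%d cross-peak point(s) with unusable correction were dropped",
                      sum(drop)))
      keep <- rep(TRUE, nrow(p)); keep[which(cross)[drop]] <- FALSE
      p <- p[keep, , drop = FALSE]
    }
  }
  new_buildup_set(p, corrected = TRUE)
}
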