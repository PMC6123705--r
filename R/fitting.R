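# Buildup fitting: monoexponential diagonal decays, two-spin cross-peak
# fits with frozen rho / dM0, normalization policy, quality control and
# generic-normalized (gn) upper-limit parameters.

default_thresholds <- function() {
  list(diag_r2 = 0.9, sigma_rel_se = 0.2, min_points = 3L)
}

in_range <- function(tau, fit_range) {
  tau >= fit_range[1L] - 1e-9 & tau <= fit_range[2L] + 1e-9
}

r_squared <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(1)
  1 - sum((obs - fitted)^2) / sst
}

#' Fit a diagonal-peak decay to a monoexponential
#'
#' Least-squares fit of \eqn{I(\tau) = \Delta M(0) e^{-\rho \tau}} over
#' the points inside \code{fit_range}.  The fit is parameterized on the
#' log scale to enforce positivity of both parameters.  When fewer than
#' 3 points are available, the optimizer fails, or the fit misses the
#' quality threshold, the fallback is returned instead: \eqn{\rho} =
#' \code{cond$rho_fallback} and \eqn{\Delta M(0)} back-extrapolated from
#' the earliest point with that rate.
#'
#' @param series data.frame with columns \code{tau} (s) and
#'   \code{intensity}; typically one diagonal series of a
#'   \code{buildup_set}.
#' @param fit_range numeric length-2, seconds; default
#'   \code{c(0.04, 0.16)}, the short-mixing-time window over which
#'   monoexponential decay is a good model even for geminal-coupled
#'   protons.
#' @param cond \code{\link{noe_conditions}} (supplies the fallback rate).
#' @param atom optional atom key stored on the result.
#' @param min_r2 quality threshold below which the fallback is used.
#' @return object of class \code{"decay_fit"}: list with \code{atom},
#'   \code{rho}, \code{dM0}, \code{fit_range}, \code{quality} (list:
#'   \code{r2}, \code{rel_se_rho}, \code{n}), \code{fallback_used}.
#' @export
fit_diagonal <- function(series, fit_range = c(0.04, 0.16), cond,
                         atom = NULL, min_r2 = 0.9) {
  stopifnot(inherits(cond, "noe_conditions"))
  if (is.null(series) || nrow(series) == 0L) stop("empty diagonal series")
  series <- series[order(series$tau), , drop = FALSE]
  sel <- series[in_range(series$tau, fit_range), , drop = FALSE]
  fallback <- function() {
    rho <- cond$rho_fallback
    first <- series[1L, ]
    structure(list(atom = atom, rho = rho,
                   dM0 = first$intensity * exp(rho * first$tau),
                   fit_range = fit_range,
                   quality = list(r2 = NA_real_, rel_se_rho = NA_real_,
                                  n = nrow(sel)),
                   fallback_used = TRUE),
              class = "decay_fit")
  }
  if (nrow(sel) < 3L || any(sel$intensity <= 0)) return(fallback())
  start <- stats::coef(stats::lm(log(sel$intensity) ~ sel$tau))
  st <- list(la = start[[1L]], lr = log(max(-start[[2L]], 1e-3)))
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ exp(la - exp(lr) * tau), data = sel,
                      start = st),
    error = function(e) NULL)
  if (is.null(fit)) {
    # zero-residual starts make the Levenberg-Marquardt gradient
    # singular; polish by direct minimization instead
    obj <- function(p) sum((sel$intensity - exp(p[1] - exp(p[2]) * sel$tau))^2)
    op <- stats::optim(unlist(st), obj, method = "Nelder-Mead")
    cf <- c(la = op$par[[1L]], lr = op$par[[2L]])
    fitted_vals <- exp(cf[["la"]] - exp(cf[["lr"]]) * sel$tau)
    se <- NA_real_
  } else {
    cf <- stats::coef(fit)
    fitted_vals <- stats::fitted(fit)
    se <- tryCatch(summary(fit)$coefficients["lr", "Std. Error"],
                   error = function(e) NA_real_)
  }
  rho <- exp(cf[["lr"]]); dM0 <- exp(cf[["la"]])
  r2 <- r_squared(sel$intensity, fitted_vals)
  if (!is.finite(r2) || r2 < min_r2) return(fallback())
  structure(list(atom = atom, rho = rho, dM0 = dM0, fit_range = fit_range,
                 quality = list(r2 = r2, rel_se_rho = se, n = nrow(sel)),
                 fallback_used = FALSE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Diagonal decay fit %s: rho = %.3f s^-1, dM0 = %.4g%s\n",
              if (is.null(x$atom)) "" else x$atom, x$rho, x$dM0,
              if (x$fallback_used) " [fallback]" else
                sprintf(" (r2 = %.3f, n = %d)", x$quality$r2, x$quality$n)))
  invisible(x)
}

# two-spin cross-peak model for one direction: origin magnetization dM0
cross_model <- function(sigma, rho_i, rho_j, dM0, tau) {
  two_spin_closed_form(rho_i, rho_j, sigma, dM0, dM0, tau)$I_ij
}

# 1-parameter least squares for sigma: coarse sign-aware grid, then
# local refinement; returns estimate, residual SS, and a Gauss-Newton
# standard error.
fit_sigma <- function(tau, intensity, rho_i, rho_j, dM0) {
  ss <- function(s) sum((intensity - cross_model(s, rho_i, rho_j, dM0, tau))^2)
  mags <- exp(seq(log(1e-4), log(60), length.out = 35L))
  grid <- c(-rev(mags), 0, mags)
  vals <- vapply(grid, ss, 0)
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(ss, lower = lo, upper = hi, tol = 1e-12)
  sigma <- opt$minimum
  n <- length(tau)
  h <- max(abs(sigma), 1e-3) * 1e-5
  jac <- (cross_model(sigma + h, rho_i, rho_j, dM0, tau) -
          cross_model(sigma - h, rho_i, rho_j, dM0, tau)) / (2 * h)
  s2 <- if (n > 1L) opt$objective / (n - 1L) else NA_real_
  se <- sqrt(s2 / max(sum(jac^2), .Machine$double.xmin))
  fitted <- cross_model(sigma, rho_i, rho_j, dM0, tau)
  list(sigma = sigma, se = se, rel_se = se / max(abs(sigma), 1e-12),
       r2 = r_squared(intensity, fitted), n = n)
}

#' Choose the normalization spin for a uni-directional buildup
#'
#' Cross peaks are preferentially normalized to the spin of origin; when
#' the origin's diagonal fit is unusable (fallback) but the destination
#' spin's diagonal fit is clean, normalization switches to the
#' destination spin.  When neither diagonal passes, the buildup is
#' rejected.
#'
#' @param decay_origin,decay_destination \code{\link{fit_diagonal}}
#'   results for the origin and destination spins (either may be
#'   \code{NULL} if no diagonal was observed).
#' @param min_r2 diagonal quality threshold.
#' @return \code{"origin"}, \code{"destination"} or \code{"reject"}.
#' @export
select_normalization <- function(decay_origin, decay_destination,
                                 min_r2 = 0.9) {
  ok <- function(d) {
    !is.null(d) && !d$fallback_used &&
      is.finite(d$quality$r2) && d$quality$r2 >= min_r2
  }
  if (ok(decay_origin)) "origin"
  else if (ok(decay_destination)) "destination"
  else "reject"
}

#' Fit cross-relaxation rates from corrected cross-peak buildups
#'
#' Fits the spin-diffusion-corrected buildup of cross peak (i, j) --
#' and, when present, of the symmetry-related peak (j, i) -- to the
#' analytic two-spin solution with \eqn{\rho_i, \rho_j, \Delta M(0)}
#' frozen at the diagonal-fit values and \eqn{\sigma} as the only free
#' variable.  Both directions are fitted independently; a pair with
#' both fits is \emph{bidirectional}, otherwise \emph{unidirectional}.
#'
#' @param series_ij data.frame (\code{tau}, \code{intensity}) of cross
#'   peak with destination i and origin j.
#' @param series_ji optional series of the reverse peak.
#' @param decay_i,decay_j \code{\link{fit_diagonal}} results for spins i
#'   and j (either may be \code{NULL}).
#' @param fit_range mixing-time window (s).
#' @param atom_i,atom_j atom keys stored on the result.
#' @param min_r2 diagonal quality threshold used by the normalization
#'   policy.
#' @return object of class \code{"cross_fit"}: list with \code{atom_i},
#'   \code{atom_j}, \code{sigma_ij}, \code{sigma_ji} (NA when absent),
#'   \code{direction_class}, \code{normalization} per direction,
#'   \code{quality} per direction, \code{flags}, \code{excluded}.
#' @export
fit_cross <- function(series_ij, series_ji = NULL, decay_i, decay_j,
                      fit_range = c(0.04, 0.16), atom_i = NULL,
                      atom_j = NULL, min_r2 = 0.9) {
  fit_dir <- function(series, decay_origin, decay_dest) {
    if (is.null(series)) return(NULL)
    sel <- series[in_range(series$tau, fit_range), , drop = FALSE]
    if (nrow(sel) == 0L) stop("no usable cross-peak points in fit range")
    norm <- select_normalization(decay_origin, decay_dest, min_r2)
    if (norm == "reject") {
      return(list(sigma = NA_real_, norm = "reject",
                  quality = list(r2 = NA_real_, rel_se = NA_real_,
                                 n = nrow(sel))))
    }
    dM0 <- if (norm == "origin") decay_origin$dM0 else decay_dest$dM0
    rho_o <- if (!is.null(decay_origin)) decay_origin$rho else decay_dest$rho
    rho_d <- if (!is.null(decay_dest)) decay_dest$rho else decay_origin$rho
    f <- fit_sigma(sel$tau, sel$intensity, rho_d, rho_o, dM0)
    list(sigma = f$sigma, norm = norm,
         quality = list(r2 = f$r2, rel_se = f$rel_se, n = f$n))
  }
  dij <- fit_dir(series_ij, decay_j, decay_i)  # origin j -> destination i
  dji <- fit_dir(series_ji, decay_i, decay_j)
  got_ij <- !is.null(dij) && dij$norm != "reject"
  got_ji <- !is.null(dji) && dji$norm != "reject"
  direction_class <- if (got_ij && got_ji) "bidirectional"
    else if (got_ij || got_ji) "unidirectional" else "rejected"
  structure(list(atom_i = atom_i, atom_j = atom_j,
                 sigma_ij = if (got_ij) dij$sigma else NA_real_,
                 sigma_ji = if (got_ji) dji$sigma else NA_real_,
                 direction_class = direction_class,
                 normalization = c(ij = if (is.null(dij)) NA_character_ else dij$norm,
                                   ji = if (is.null(dji)) NA_character_ else dji$norm),
                 quality = list(ij = if (is.null(dij)) NULL else dij$quality,
                                ji = if (is.null(dji)) NULL else dji$quality),
                 flags = character(0), excluded = direction_class == "rejected"),
            class = "cross_fit")
}

#' @export
print.cross_fit <- function(x, ...) {
  cat(sprintf("Cross fit %s / %s [%s]: sigma_ij = %.4g, sigma_ji = %.4g s^-1%s\n",
              x$atom_i, x$atom_j, x$direction_class, x$sigma_ij, x$sigma_ji,
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Automated quality filter for buildup fits
#'
#' Numeric surrogate for visual fit inspection: annotates (never
#' silently deletes) fits that miss the configured thresholds.  A
#' tightened threshold can only add flags, never remove one.
#'
#' @param fits list of \code{cross_fit} and/or \code{decay_fit} objects.
#' @param thresholds list with \code{diag_r2}, \code{sigma_rel_se},
#'   \code{min_points} (see \code{default_thresholds()}).
#' @return the same list, with \code{flags} and \code{excluded} filled.
#' @export
quality_filter <- function(fits, thresholds = default_thresholds()) {
  thr <- utils::modifyList(default_thresholds(), thresholds)
  lapply(fits, function(f) {
    flags <- character(0)
    if (inherits(f, "decay_fit")) {
      if (f$fallback_used) flags <- c(flags, "fallback")
      if (!is.na(f$quality$r2) && f$quality$r2 < thr$diag_r2)
        flags <- c(flags, "diagonal_r2")
      if (f$quality$n < thr$min_points) flags <- c(flags, "too_few_points")
    } else if (inherits(f, "cross_fit")) {
      for (d in c("ij", "ji")) {
        q <- f$quality[[d]]
        if (is.null(q)) next
        if (is.finite(q$rel_se) && q$rel_se > thr$sigma_rel_se)
          flags <- c(flags, paste0("sigma_precision_", d))
        if (q$n < thr$min_points) flags <- c(flags, paste0("too_few_points_", d))
      }
      if (f$direction_class == "rejected") flags <- c(flags, "rejected")
    }
    f$flags <- unique(c(f$flags, flags))
    f$excluded <- length(f$flags) > 0L
    f
  })
}

#' Group-wise upper-limit parameters for gn-eNOEs
#'
#' Overlapped diagonals cannot be fitted; their cross peaks are instead
#' normalized with upper-limit \eqn{\Delta M(0)} and \eqn{\rho} taken as
#' the maxima over the successfully fitted members of the proton's atom
#' group (amino, methylene or other), which guarantees that the derived
#' distance is an upper bound.
#'
#' @param decays list of \code{\link{fit_diagonal}} results belonging to
#'   one atom group.
#' @return list with \code{dM0_upper} and \code{rho_upper}.
#' @export
gn_parameters <- function(decays) {
  ok <- Filter(function(d) !d$fallback_used, decays)
  if (length(ok) == 0L) stop("no successful decay fit in the group")
  list(dM0_upper = max(vapply(ok, `[[`, 0, "dM0")),
       rho_upper = max(vapply(ok, `[[`, 0, "rho")))
}

#' Fit a gn-eNOE cross peak with group upper-limit normalization
#'
#' Like \code{\link{fit_cross}} for a single direction, but the
#' overlapped origin diagonal is replaced by the group's upper-limit
#' \eqn{\Delta M(0)} and \eqn{\rho}.
#'
#' @param series cross-peak series (\code{tau}, \code{intensity}).
#' @param gn \code{\link{gn_parameters}} of the origin's atom group.
#' @param decay_dest optional diagonal fit of the destination spin; when
#'   absent its rate is also taken from \code{gn}.
#' @param fit_range mixing-time window (s).
#' @param atom_i,atom_j atom keys.
#' @return a \code{cross_fit} with \code{direction_class = "gn"}.
#' @export
fit_cross_gn <- function(series, gn, decay_dest = NULL,
                         fit_range = c(0.04, 0.16),
                         atom_i = NULL, atom_j = NULL) {
  sel <- series[in_range(series$tau, fit_range), , drop = FALSE]
  if (nrow(sel) == 0L) stop("no usable cross-peak points in fit range")
  rho_d <- if (!is.null(decay_dest)) decay_dest$rho else gn$rho_upper
  f <- fit_sigma(sel$tau, sel$intensity, rho_d, gn$rho_upper, gn$dM0_upper)
  structure(list(atom_i = atom_i, atom_j = atom_j,
                 sigma_ij = f$sigma, sigma_ji = NA_real_,
                 direction_class = "gn",
                 normalization = c(ij = "group_upper", ji = NA_character_),
                 quality = list(ij = list(r2 = f$r2, rel_se = f$rel_se,
                                          n = f$n), ji = NULL),
                 flags = character(0), excluded = FALSE),
            class = "cross_fit")
}
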