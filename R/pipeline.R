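# One-shot eNOE extraction pipeline: correct -> fit diagonals -> fit
# cross peaks -> convert to distances and restraints.

#' Extract eNOE distances from a buildup set
#'
#' Runs the full extraction protocol: spin-diffusion correction factors
#' are computed from the reference structure and applied to the cross
#' peaks, diagonal decays are fitted to monoexponentials, corrected
#' cross-peak buildups are fitted to the two-spin model with the
#' diagonal parameters frozen, and the fitted cross-relaxation rates
#' are converted into distances and classed restraints (bidirectional
#' pairs average the two directions' sigma before conversion).
#'
#' @param b a \code{buildup_set} (raw or already corrected).
#' @param reference \code{spin_system} used for the spin-diffusion
#'   simulation (for experimental data: a previously solved structure;
#'   for synthetic data: the generating system).
#' @param cond \code{\link{noe_conditions}}.
#' @param fit_range mixing-time window in seconds (default 40-160 ms).
#' @param thresholds quality thresholds (see \code{quality_filter}).
#' @param correct apply spin-diffusion corrections (default TRUE;
#'   ignored if \code{b} is already corrected).
#' @param correct_diagonals remove the multi-exponential bias of the
#'   monoexponential diagonal fits using the reference structure
#'   (\code{\link{correct_decay_fits}}); default TRUE.
#' @return list with \code{decays} (named list of \code{decay_fit}),
#'   \code{fits} (list of \code{cross_fit}), \code{distances}
#'   (data.frame \code{key_i}, \code{key_j}, \code{sigma},
#'   \code{class}, \code{r}), \code{restraints}
#'   (\code{enoe_restraints}), \code{corrections}.
#' @export
extract_enoe_distances <- function(b, reference, cond,
                                   fit_range = c(0.04, 0.16),
                                   thresholds = default_thresholds(),
                                   correct = TRUE,
                                   correct_diagonals = TRUE) {
  stopifnot(inherits(b, "buildup_set"), inherits(reference, "spin_system"))
  p <- b$peaks
  cross <- p[p$atom_i != p$atom_j, , drop = FALSE]
  corrections <- NULL
  if (!b$corrected && correct && nrow(cross) > 0L) {
    pairs <- unique(data.frame(
      a = pmin(cross$atom_i, cross$atom_j),
      b = pmax(cross$atom_i, cross$atom_j), stringsAsFactors = FALSE))
    corrections <- correction_factors(reference, cond,
                                      sort(unique(cross$tau)),
                                      pairs = as.matrix(pairs))
    b <- apply_corrections(b, corrections)
    p <- b$peaks
  }
  diag_p <- p[p$atom_i == p$atom_j, , drop = FALSE]
  decays <- lapply(split(diag_p, diag_p$atom_i), function(d) {
    fit_diagonal(d[c("tau", "intensity")], fit_range, cond,
                 atom = d$atom_i[1L], min_r2 = thresholds$diag_r2)
  })
  if (correct_diagonals) {
    taus <- sort(unique(diag_p$tau))
    ref <- diagonal_decay_reference(reference, cond, taus,
                                    fit_range = fit_range)
    decays <- correct_decay_fits(decays, ref)
  }
  cross <- p[p$atom_i != p$atom_j, , drop = FALSE]
  pid <- unordered_pair_id(cross$atom_i, cross$atom_j)
  fits <- lapply(split(seq_len(nrow(cross)), pid), function(rows) {
    cp <- cross[rows, , drop = FALSE]
    a <- pmin(cp$atom_i[1L], cp$atom_j[1L])
    bkey <- pmax(cp$atom_i[1L], cp$atom_j[1L])
    s_ij <- cp[cp$atom_i == a & cp$atom_j == bkey,
               c("tau", "intensity"), drop = FALSE]
    s_ji <- cp[cp$atom_i == bkey & cp$atom_j == a,
               c("tau", "intensity"), drop = FALSE]
    fit_cross(if (nrow(s_ij)) s_ij else NULL,
              if (nrow(s_ji)) s_ji else NULL,
              decay_i = decays[[a]], decay_j = decays[[bkey]],
              fit_range = fit_range, atom_i = a, atom_j = bkey,
              min_r2 = thresholds$diag_r2)
  })
  fits <- quality_filter(fits, thresholds)
  # a noisy fit can land on the wrong side of zero; such sigmas carry no
  # distance information and are flagged out
  pref <- cross_relaxation_prefactor(cond)
  fits <- lapply(fits, function(f) {
    sig <- mean(c(f$sigma_ij, f$sigma_ji), na.rm = TRUE)
    if (f$direction_class != "rejected" &&
        (!is.finite(sig) || sig == 0 || sign(sig) != sign(pref))) {
      f$flags <- unique(c(f$flags, "wrong_sign"))
      f$excluded <- TRUE
      f$direction_class <- "rejected"
    }
    f
  })
  kept <- Filter(function(f) f$direction_class != "rejected", fits)
  dist_rows <- lapply(kept, function(f) {
    sig <- mean(c(f$sigma_ij, f$sigma_ji), na.rm = TRUE)
    data.frame(key_i = f$atom_i, key_j = f$atom_j, sigma = sig,
               class = f$direction_class,
               r = sigma_to_distance(sig, cond),
               flagged = isTRUE(f$excluded),
               stringsAsFactors = FALSE)
  })
  distances <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(key_i = character(0), key_j = character(0),
               sigma = numeric(0), class = character(0), r = numeric(0),
               flagged = logical(0))
  rownames(distances) <- NULL
  # restraints only from fits that survive the quality filter
  clean <- Filter(function(f) !isTRUE(f$excluded), kept)
  restr <- NULL
  if (length(clean)) {
    restr <- do.call(bind_restraints,
                     lapply(clean, make_restraint, cond = cond))
  }
  list(decays = decays, fits = fits, distances = distances,
       restraints = restr, corrections = corrections)
}
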