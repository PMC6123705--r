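# Ensemble validation metrics: bond-vector order parameters, heavy-atom
# bundle RMSD and nucleic-acid torsion angles.

#' Bond-vector order parameter S2 of an ensemble
#'
#' \deqn{S^2 = \tfrac12 (3 \sum_{\alpha\beta} \langle \mu_\alpha
#'   \mu_\beta \rangle^2 - 1)}
#' with \eqn{\mu} the unit bond vector and equal-weight averaging over
#' conformers.  S2 = 1 for a completely restricted bond orientation
#' (any single-conformer ensemble) and approaches 0 for complete
#' angular freedom.
#'
#' @param e an \code{ensemble} or \code{spin_system}.
#' @param pair length-2 character vector of atom keys defining the bond
#'   (e.g. C8 and H8 of one residue).
#' @return list with \code{bond} and \code{s2}.
#' @export
order_parameter <- function(e, pair) {
  idx <- match(pair, e$atoms$key)
  if (anyNA(idx)) stop("bond atom(s) not in the ensemble")
  v <- matrix(e$xyz[, idx[2L], ] - e$xyz[, idx[1L], ], ncol = 3L)
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-6)) stop("coincident bond atoms")
  mu <- v / len
  q <- crossprod(mu) / nrow(mu)   # <mu_a mu_b>
  s2 <- 0.5 * (3 * sum(q^2) - 1)
  list(bond = pair, s2 = s2)
}

# bio3d-ordered coordinate matrix (n_conf x 3*n_sel) for an atom subset
xyz_matrix <- function(e, sel) {
  n <- length(sel)
  out <- matrix(0, e$n_conf, 3L * n)
  for (m in seq_len(e$n_conf)) {
    out[m, ] <- as.vector(t(matrix(e$xyz[m, sel, ], ncol = 3L)))
  }
  out
}

#' Heavy-atom RMSD of a conformer bundle
#'
#' Mean RMSD to the mean structure: every conformer is optimally
#' superimposed (Kabsch, via \code{bio3d::fit.xyz}) onto the iteratively
#' refined mean coordinates of the selected atoms, and the reported
#' value is the average over conformers of the RMSD to that mean.  This
#' is the common bundle-precision statistic; other conventions
#' (pairwise-average RMSD, different superposition subsets) give
#' systematically different numbers.
#'
#' @param e an \code{ensemble} (>= 2 conformers).
#' @param resno optional residue numbers to restrict the subset (e.g.
#'   \code{1:14} overall, \code{c(1:5, 10:14)} stem, \code{6:9} loop).
#' @param atoms \code{"heavy"} (default, element != H) or \code{"all"}.
#' @param tol convergence tolerance on the mean structure (A).
#' @return mean RMSD-to-mean in Angstrom.
#' @export
heavy_atom_rmsd <- function(e, resno = NULL, atoms = c("heavy", "all"),
                            tol = 1e-7) {
  atoms <- match.arg(atoms)
  if (e$n_conf < 2L) stop("bundle RMSD needs at least 2 conformers")
  sel <- seq_len(nrow(e$atoms))
  if (!is.null(resno)) sel <- sel[e$atoms$resno[sel] %in% resno]
  if (atoms == "heavy") {
    is_h <- e$atoms$element == "H" | grepl("^H", e$atoms$name)
    sel <- sel[!is_h[sel]]
  }
  if (length(sel) == 0L) stop("atom subset is empty")
  x <- xyz_matrix(e, sel)
  inds <- seq_len(ncol(x))
  ref <- x[1L, ]
  for (it in seq_len(50L)) {
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = x,
                             fixed.inds = inds, mobile.inds = inds)
    m <- colMeans(fitted)
    if (sqrt(mean((m - ref)^2)) < tol) { ref <- m; break }
    ref <- m
  }
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = x,
                           fixed.inds = inds, mobile.inds = inds)
  dev2 <- sweep(fitted, 2L, ref)^2
  per_conf <- sqrt(rowSums(dev2) / length(sel))
  mean(per_conf)
}

# IUPAC backbone/sugar/glycosidic torsion definitions; offsets give the
# residue of each atom relative to the central residue.
.torsion_defs <- list(
  alpha = list(atoms = c("O3'", "P", "O5'", "C5'"), off = c(-1L, 0L, 0L, 0L)),
  beta = list(atoms = c("P", "O5'", "C5'", "C4'"), off = c(0L, 0L, 0L, 0L)),
  gamma = list(atoms = c("O5'", "C5'", "C4'", "C3'"), off = c(0L, 0L, 0L, 0L)),
  delta = list(atoms = c("C5'", "C4'", "C3'", "O3'"), off = c(0L, 0L, 0L, 0L)),
  epsilon = list(atoms = c("C4'", "C3'", "O3'", "P"), off = c(0L, 0L, 0L, 1L)),
  zeta = list(atoms = c("C3'", "O3'", "P", "O5'"), off = c(0L, 0L, 1L, 1L)),
  chi = NULL,  # residue-type dependent, handled below
  eta2 = list(atoms = c("C1'", "C2'", "O2'", "HO2'"), off = c(0L, 0L, 0L, 0L)),
  nu1 = list(atoms = c("O4'", "C1'", "C2'", "C3'"), off = c(0L, 0L, 0L, 0L)),
  nu2 = list(atoms = c("C1'", "C2'", "C3'", "C4'"), off = c(0L, 0L, 0L, 0L)))

chi_def <- function(resid) {
  if (canonical_residue(resid) %in% c("A", "G")) {
    list(atoms = c("O4'", "C1'", "N9", "C4"), off = c(0L, 0L, 0L, 0L))
  } else {
    list(atoms = c("O4'", "C1'", "N1", "C2"), off = c(0L, 0L, 0L, 0L))
  }
}

circular_mean <- function(deg) {
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

circular_sd <- function(deg) {
  rad <- deg * pi / 180
  rbar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  sqrt(pmax(-2 * log(rbar), 0)) * 180 / pi
}

#' Nucleic-acid torsion angles of an ensemble
#'
#' Computes the standard backbone (alpha...zeta), glycosidic (chi),
#' 2'-hydroxyl (eta2: C1'-C2'-O2'-HO2') and sugar (nu1, nu2; note that
#' delta, nu1 and nu2 are rigidly linked through the ring geometry)
#' torsions for each requested residue and conformer, with circular
#' mean and spread across conformers.  Angles whose atoms are missing
#' (chain termini, absent hydroxyl protons) are skipped with a warning.
#'
#' @param e an \code{ensemble}.
#' @param resno residue numbers (default: all).
#' @param angles subset of \code{c("alpha","beta","gamma","delta",
#'   "epsilon","zeta","chi","eta2","nu1","nu2")}.
#' @return data.frame with columns \code{resno}, \code{angle},
#'   \code{mean}, \code{sd} (degrees, in (-180, 180]) and a list column
#'   \code{values} of per-conformer angles.
#' @export
torsion_angles <- function(e, resno = NULL,
                           angles = names(.torsion_defs)) {
  angles <- match.arg(angles, names(.torsion_defs), several.ok = TRUE)
  if (is.null(resno)) resno <- sort(unique(e$atoms$resno))
  rows <- list(); skipped <- 0L
  for (rn in resno) {
    resid <- e$atoms$resid[match(rn, e$atoms$resno)]
    for (ang in angles) {
      def <- if (ang == "chi") chi_def(resid) else .torsion_defs[[ang]]
      keys <- atom_key(rn + def$off,
                       e$atoms$resid[match(rn + def$off, e$atoms$resno)],
                       def$atoms)
      idx <- match(keys, e$atoms$key)
      if (anyNA(idx)) { skipped <- skipped + 1L; next }
      vals <- vapply(seq_len(e$n_conf), function(m) {
        bio3d::torsion.xyz(as.vector(t(e$xyz[m, idx, ])))
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(resno = rn, angle = ang, mean = circular_mean(vals),
                   sd = circular_sd(vals), stringsAsFactors = FALSE)
      attr(rows[[length(rows)]], "values") <- vals
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d torsion(s) skipped for missing atoms", skipped))
  }
  if (length(rows) == 0L) {
    return(data.frame(resno = integer(0), angle = character(0),
                      mean = numeric(0), sd = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$values <- lapply(rows, attr, "values")
  rownames(out) <- NULL
  out
}
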