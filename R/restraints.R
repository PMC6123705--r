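# Conversion of fitted cross-relaxation rates into classed distance
# restraints, ensemble-averaged distances, comparison statistics,
# restraint-violation target functions, jack-knife cross-validation and
# peak-pruning experiments.

#' Convert a cross-relaxation rate into a distance
#'
#' Inverts the isolated-pair relationship \eqn{\sigma = K r^{-6}
#' [6J(2\omega_0) - J(0)]} used by \code{\link{pair_rates}}:
#' \deqn{r = (K [6J(2\omega_0) - J(0)] / \sigma)^{1/6}}
#' The sign of \eqn{\sigma} must match the tumbling regime implied by
#' \code{cond} (negative at slow tumbling); a mismatch usually indicates
#' a mis-set correlation time and raises an error.
#'
#' @param sigma cross-relaxation rate(s), s^-1.
#' @param cond \code{\link{noe_conditions}}.
#' @return distance(s) in Angstrom.
#' @examples
#' cond <- noe_conditions()
#' sigma_to_distance(pair_rates(3, cond)$sigma, cond)  # 3 A
#' @export
sigma_to_distance <- function(sigma, cond) {
  stopifnot(inherits(cond, "noe_conditions"))
  pref <- cross_relaxation_prefactor(cond)
  if (any(sigma == 0) || any(sign(sigma) != sign(pref))) {
    stop(sprintf("sigma has the wrong sign for this regime (expected %s at tau_c = %.3g ns); check tau_c",
                 if (pref < 0) "negative" else "positive", cond$tau_c * 1e9))
  }
  (pref / sigma)^(1 / 6)
}

restraint_row <- function(pair_i, pair_j, r_eff, class) {
  tol <- switch(class,
                bidirectional = c(1, 1),
                unidirectional = c(1.1, 0.9),
                gn = c(1.1, NA_real_))
  data.frame(resno_i = pair_i$resno, resid_i = pair_i$resid,
             name_i = pair_i$name,
             resno_j = pair_j$resno, resid_j = pair_j$resid,
             name_j = pair_j$name,
             r_eff = r_eff, class = class,
             upper = round(tol[1L] * r_eff, 10),
             lower = round(tol[2L] * r_eff, 10),
             stringsAsFactors = FALSE)
}

#' Convert a fitted cross-relaxation rate into a distance restraint
#'
#' Restraint class and tolerances follow the eNOE convention:
#' \emph{bidirectional} (both symmetry-related cross peaks fitted) uses
#' the arithmetic mean of \eqn{\sigma_{ij}, \sigma_{ji}} and carries no
#' tolerance (upper = lower = r); \emph{unidirectional} gets +/- 10%
#' bounds; \emph{gn} (generic normalized) yields only an upper limit at
#' 1.1 r.
#'
#' @param fit a \code{\link{fit_cross}} / \code{\link{fit_cross_gn}}
#'   result (must not be quality-excluded).
#' @param cond \code{\link{noe_conditions}}.
#' @return one-row data.frame of class \code{"enoe_restraints"}.
#' @export
make_restraint <- function(fit, cond) {
  stopifnot(inherits(fit, "cross_fit"))
  if (isTRUE(fit$excluded) || fit$direction_class == "rejected") {
    stop("cannot build a restraint from a rejected/excluded fit")
  }
  sig <- c(fit$sigma_ij, fit$sigma_ji)
  sig <- sig[is.finite(sig)]
  r <- sigma_to_distance(mean(sig), cond)
  out <- restraint_row(parse_atom_key(fit$atom_i),
                       parse_atom_key(fit$atom_j),
                       r, fit$direction_class)
  class(out) <- c("enoe_restraints", "data.frame")
  out
}

#' Combine restraint rows
#' @param ... \code{enoe_restraints} rows or data.frames.
#' @return a single \code{enoe_restraints} data.frame.
#' @export
bind_restraints <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("enoe_restraints", "data.frame")
  out
}

#' Effective ensemble-averaged interproton distance
#'
#' \code{"r6"} returns \eqn{\langle r^{-6} \rangle^{-1/6}}, the average
#' the NOE physically reports; \code{"linear"} returns
#' \eqn{\langle r \rangle}.  By Jensen's inequality the r^-6 average
#' never exceeds the linear one.
#'
#' @param e an \code{ensemble} or \code{spin_system}.
#' @param pair length-2 character vector of atom keys
#'   (\code{resno:resid:name}).
#' @param mode \code{"r6"} (default) or \code{"linear"}.
#' @return distance in Angstrom.
#' @export
ensemble_distance <- function(e, pair, mode = c("r6", "linear")) {
  mode <- match.arg(mode)
  idx <- match(pair, e$atoms$key)
  if (anyNA(idx)) {
    stop("atom(s) not in the ensemble: ",
         paste(pair[is.na(idx)], collapse = ", "))
  }
  d <- sqrt(rowSums((matrix(e$xyz[, idx[1L], ], ncol = 3L) -
                     matrix(e$xyz[, idx[2L], ], ncol = 3L))^2))
  if (mode == "r6") mean(d^-6)^(-1 / 6) else mean(d)
}

unordered_pair_id <- function(key_i, key_j) {
  paste(pmin(key_i, key_j), pmax(key_i, key_j), sep = "|")
}

#' Compare two distance sets
#'
#' Computes, over the pairs shared by both sets, the best-fit slope of a
#' line through the origin (\eqn{\hat b = \sum xy / \sum x^2}) and the
#' Pearson correlation coefficient, overall and -- when atom classes are
#' supplied -- for the three standard subgroups: pairs with no
#' amino/methylene proton, mixed pairs (one amino/methylene partner, or
#' amino/methylene partners on different residues), and within-residue
#' amino/methylene pairs.
#'
#' @param a,b data.frames with columns \code{key_i}, \code{key_j},
#'   \code{r} (Angstrom); \code{a} supplies x, \code{b} supplies y.
#' @param classes optional named character vector mapping atom keys to
#'   group classes (as in \code{spin_system$atoms}).
#' @return object of class \code{"comparison_stats"}: list with
#'   \code{slope}, \code{pearson_r}, \code{n_pairs} and a
#'   \code{subgroups} data.frame.
#' @export
compare_distances <- function(a, b, classes = NULL) {
  ida <- unordered_pair_id(a$key_i, a$key_j)
  idb <- unordered_pair_id(b$key_i, b$key_j)
  shared <- intersect(ida, idb)
  if (length(shared) < 3L) stop("need at least 3 shared pairs")
  x <- a$r[match(shared, ida)]
  y <- b$r[match(shared, idb)]
  stat <- function(x, y) {
    c(slope = sum(x * y) / sum(x^2),
      pearson_r = if (length(x) >= 3L) stats::cor(x, y) else NA_real_,
      n = length(x))
  }
  overall <- stat(x, y)
  subgroups <- NULL
  if (!is.null(classes)) {
    keys <- strsplit(shared, "|", fixed = TRUE)
    k1 <- vapply(keys, `[`, "", 1L); k2 <- vapply(keys, `[`, "", 2L)
    am <- function(k) classes[k] %in% c("amino", "methylene")
    res <- function(k) parse_atom_key(k)$resno
    grp <- ifelse(!am(k1) & !am(k2), "non_amino_methylene",
           ifelse(am(k1) & am(k2) & res(k1) == res(k2),
                  "within_amino_methylene", "mixed"))
    subgroups <- do.call(rbind, lapply(split(seq_along(x), grp), function(i) {
      if (length(i) < 3L) {
        data.frame(slope = NA_real_, pearson_r = NA_real_, n = length(i))
      } else as.data.frame(t(stat(x[i], y[i])))
    }))
  }
  structure(list(slope = unname(overall["slope"]),
                 pearson_r = unname(overall["pearson_r"]),
                 n_pairs = unname(overall["n"]),
                 subgroups = subgroups),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("Distance comparison over %d shared pairs: y = %.3f x, R = %.3f\n",
              x$n_pairs, x$slope, x$pearson_r))
  if (!is.null(x$subgroups)) print(round(x$subgroups, 3))
  invisible(x)
}

restraint_pair_keys <- function(r) {
  list(i = atom_key(r$resno_i, r$resid_i, r$name_i),
       j = atom_key(r$resno_j, r$resid_j, r$name_j))
}

#' Restraint-violation target function of an ensemble
#'
#' For every restraint, computes the effective distance d of the
#' ensemble -- either r^-6-averaged over the states (multi-state logic:
#' the bundle must satisfy restraints on average) or per conformer --
#' and the violation \eqn{v = \max(0, d - upper) + \max(0, lower - d)}.
#' The target function is the unweighted sum \eqn{\sum v^2} in A^2.
#' Restraints violated by at least \code{highlight} (default 0.2 A) are
#' listed separately.
#'
#' @param restraints an \code{enoe_restraints} data.frame.
#' @param e an \code{ensemble} or \code{spin_system}.
#' @param averaging \code{"r6_over_states"} (default) or
#'   \code{"per_conformer"}.
#' @param highlight violation threshold (A) for the highlighted list.
#' @return object of class \code{"validation_report"}: list with
#'   \code{tf} (scalar, or per-conformer vector), \code{violations}
#'   data.frame, \code{n_violated}, \code{highlighted}, \code{skipped}.
#' @export
violation_tf <- function(restraints, e,
                         averaging = c("r6_over_states", "per_conformer"),
                         highlight = 0.2) {
  averaging <- match.arg(averaging)
  r <- as.data.frame(restraints)
  keys <- restraint_pair_keys(r)
  ok_i <- keys$i %in% e$atoms$key; ok_j <- keys$j %in% e$atoms$key
  skipped <- which(!(ok_i & ok_j))
  if (length(skipped)) {
    warning(sprintf("%d restraint(s) reference atoms absent from the ensemble and were skipped",
                    length(skipped)))
  }
  use <- setdiff(seq_len(nrow(r)), skipped)
  viol_of <- function(d, upper, lower) {
    v <- pmax(0, d - upper) + pmax(0, ifelse(is.na(lower), -Inf, lower) - d)
    # zero-tolerance (bidirectional) restraints would otherwise count
    # floating-point dust as violations
    ifelse(v > 1e-6, v, 0)
  }
  if (averaging == "r6_over_states") {
    d <- vapply(use, function(k) {
      ensemble_distance(e, c(keys$i[k], keys$j[k]), mode = "r6")
    }, 0)
    v <- viol_of(d, r$upper[use], r$lower[use])
    tf <- sum(v^2)
    violations <- data.frame(r[use, c("resno_i", "name_i", "resno_j",
                                      "name_j", "class", "upper", "lower")],
                             d = d, violation = v)
  } else {
    idx_i <- match(keys$i[use], e$atoms$key)
    idx_j <- match(keys$j[use], e$atoms$key)
    dmat <- vapply(seq_along(use), function(p) {
      sqrt(rowSums((matrix(e$xyz[, idx_i[p], ], ncol = 3L) -
                    matrix(e$xyz[, idx_j[p], ], ncol = 3L))^2))
    }, numeric(e$n_conf))
    vmat <- t(apply(dmat, 1L, viol_of,
                    upper = r$upper[use], lower = r$lower[use]))
    if (length(use) == 1L) vmat <- matrix(vmat, ncol = 1L)
    tf <- rowSums(vmat^2)  # one TF per conformer
    v <- apply(vmat, 2L, max)
    violations <- data.frame(r[use, c("resno_i", "name_i", "resno_j",
                                      "name_j", "class", "upper", "lower")],
                             d = colMeans(dmat), violation = v)
  }
  structure(list(tf = tf, violations = violations,
                 n_violated = sum(violations$violation > 0),
                 highlighted = violations[violations$violation >= highlight, ,
                                          drop = FALSE],
                 skipped = skipped, averaging = averaging),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$tf) == 1L) {
    cat(sprintf("Target function (%s): %.4f A^2; %d violated, %d highlighted (>= 0.2 A)\n",
                x$averaging, x$tf, x$n_violated, nrow(x$highlighted)))
  } else {
    cat(sprintf("Per-conformer target function (A^2): %s\n",
                paste(sprintf("%.3f", x$tf), collapse = ", ")))
  }
  invisible(x)
}

#' Jack-knife cross-validation of a restraint set against an ensemble
#'
#' Randomly partitions the restraints into k folds (each restraint held
#' out exactly once), evaluates the partial target function of every
#' held-out fold against the supplied ensemble, and sums the partials
#' into a cross-validation target function.  This evaluates a given
#' bundle; it does not recalculate structures.
#'
#' @param restraints \code{enoe_restraints}.
#' @param e ensemble to validate against.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the partition.
#' @param averaging passed to \code{\link{violation_tf}}.
#' @return list with \code{cv_tf}, \code{partials} (length k),
#'   \code{folds} (fold index per restraint).
#' @export
jackknife <- function(restraints, e, k = 10L, seed = 1L,
                      averaging = "r6_over_states") {
  r <- as.data.frame(restraints)
  n <- nrow(r)
  if (k > n) stop("more folds than restraints")
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  partials <- vapply(seq_len(k), function(f) {
    sub <- r[folds == f, , drop = FALSE]
    class(sub) <- c("enoe_restraints", "data.frame")
    suppressWarnings(violation_tf(sub, e, averaging = averaging)$tf)
  }, 0)
  list(cv_tf = sum(partials), partials = partials, folds = folds)
}

#' Simulate peak loss for larger RNA: prune and reclassify
#'
#' Emulates the increasing spectral overlap of larger RNA by deleting a
#' fraction f of cross peaks and 2f of diagonal peaks uniformly at
#' random (diagonal overlap grows roughly twice as fast, since only one
#' resonance needs to coincide).  Restraint classes are demoted down the
#' chain bidirectional -> unidirectional -> gn: losing one diagonal (or
#' one of the two cross-peak directions) demotes to unidirectional,
#' losing both diagonals to gn; losing all cross peaks of a pair removes
#' the restraint.
#'
#' @param diagonal_ids character vector of diagonal atom keys.
#' @param cross_peaks data.frame with columns \code{atom_i},
#'   \code{atom_j}: one row per directed cross peak.
#' @param fraction_cross fraction of cross peaks to delete, in
#'   \code{[0, 0.5]} (diagonal fraction is twice that).
#' @param seed RNG seed.
#' @return data.frame with one row per surviving unordered pair:
#'   \code{atom_i}, \code{atom_j}, \code{n_directions},
#'   \code{n_diagonals}, \code{class}.
#' @export
prune_peaks <- function(diagonal_ids, cross_peaks, fraction_cross,
                        seed = 1L) {
  if (fraction_cross < 0 || fraction_cross > 0.5) {
    stop("fraction_cross must be in [0, 0.5]")
  }
  nd <- length(diagonal_ids); nc <- nrow(cross_peaks)
  del <- withr::with_seed(seed, list(
    diag = sample(nd, floor(2 * fraction_cross * nd)),
    cross = sample(nc, floor(fraction_cross * nc))))
  keep_diag <- diagonal_ids[setdiff(seq_len(nd), del$diag)]
  cp <- cross_peaks[setdiff(seq_len(nc), del$cross), , drop = FALSE]
  if (nrow(cp) == 0L) {
    return(data.frame(atom_i = character(0), atom_j = character(0),
                      n_directions = integer(0), n_diagonals = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  pid <- unordered_pair_id(cp$atom_i, cp$atom_j)
  agg <- lapply(split(seq_len(nrow(cp)), pid), function(i) {
    a <- pmin(cp$atom_i[i][1L], cp$atom_j[i][1L])
    b <- pmax(cp$atom_i[i][1L], cp$atom_j[i][1L])
    ndir <- length(unique(paste(cp$atom_i[i], cp$atom_j[i])))
    ndia <- sum(c(a, b) %in% keep_diag)
    lev <- min(if (ndir >= 2L) 3L else 2L,
               c(3L, 2L, 1L)[3L - ndia])
    data.frame(atom_i = a, atom_j = b, n_directions = ndir,
               n_diagonals = ndia,
               class = c("gn", "unidirectional", "bidirectional")[lev],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$atom_i, out$atom_j), , drop = FALSE]
}
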