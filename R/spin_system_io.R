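# Reading multi-conformer PDB files into ensembles and spin systems,
# canonical PDB-v3 proton naming for ribonucleotides, and the package's
# tabular formats (buildup tables, CYANA-style .upl/.lol restraints).

# canonical proton names per ribonucleotide (PDB v3)
.ribose_h <- c("H1'", "H2'", "H3'", "H4'", "H5'", "H5''",
               "HO2'", "HO3'", "HO5'")
.base_h <- list(
  A = c("H2", "H8", "H61", "H62"),
  G = c("H1", "H8", "H21", "H22"),
  C = c("H5", "H6", "H41", "H42"),
  U = c("H3", "H5", "H6"))
.amino_h <- c("H21", "H22", "H41", "H42", "H61", "H62")
.imino_h <- c("H1", "H3")  # G-H1, U-H3
.methylene_h <- c("H5'", "H5''")
.hydroxyl_h <- c("HO2'", "HO3'", "HO5'")

# strip chain/variant decorations of residue codes: "RA"/"ADE"/"A" -> "A"
canonical_residue <- function(resid) {
  r <- toupper(trimws(resid))
  map <- c(A = "A", G = "G", C = "C", U = "U",
           RA = "A", RG = "G", RC = "C", RU = "U",
           ADE = "A", GUA = "G", CYT = "C", URA = "U", URI = "U")
  out <- unname(map[r])
  ifelse(is.na(out), r, out)
}

canonical_protons <- function(residue_name) {
  base <- .base_h[[canonical_residue(residue_name)]]
  c(.ribose_h, base)
}

#' Normalize a PDB proton name to canonical PDB-v3 form
#'
#' Maps common PDB naming dialects (asterisks for primes, leading or
#' trailing position digits, terminal-hydroxyl shorthands) onto the
#' canonical PDB-v3 proton names used throughout the package, e.g.
#' \code{"H5*" -> "H5'"}, \code{"H5'1" -> "H5'"}, \code{"1H5'" -> "H5'"},
#' \code{"2H4" -> "H42"}, \code{"H5T" -> "HO5'"}.  Non-hydrogen names are
#' returned unchanged.  A hydrogen name that cannot be mapped onto a
#' canonical proton of the given residue raises an error: silent
#' mis-mapping would corrupt every downstream distance.
#'
#' @param raw atom name as found in the file.
#' @param residue_name residue code (\code{A}, \code{G}, \code{C},
#'   \code{U} or a recognized dialect such as \code{RA}, \code{ADE}).
#' @return canonical atom name (character scalar).
#' @examples
#' normalize_atom_name("H5*", "U")    # "H5'"
#' normalize_atom_name("1H4", "C")    # "H41"
#' normalize_atom_name("C1'", "G")    # unchanged, not a hydrogen
#' @export
normalize_atom_name <- function(raw, residue_name) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  nm <- gsub("\\*", "'", trimws(raw))
  nm <- gsub("′", "'", nm)
  if (!grepl("^[0-9]?H", nm)) return(nm)  # not a hydrogen
  # leading position digit (amino/methylene dialect): 1H4 -> H41, 1H5' -> H5'1
  nm <- sub("^([0-9])(H.*)$", "\\2\\1", nm)
  # trailing digit on primed methylene names: H5'1 -> H5', H5'2 -> H5''
  nm <- sub("^(H[0-9]')1$", "\\1", nm)
  nm <- sub("^(H[0-9]')2$", "\\1'", nm)
  # terminal hydroxyl shorthands
  nm <- switch(nm, "H5T" = "HO5'", "H3T" = "HO3'", "HO'2" = "HO2'",
               "H2T" = "HO2'", nm)
  canon <- canonical_protons(residue_name)
  if (is.null(canon) || !nm %in% canon) {
    stop(sprintf("cannot map hydrogen atom name '%s' (residue %s) onto a canonical PDB-v3 proton",
                 raw, residue_name))
  }
  nm
}

#' Atom keys
#'
#' Atoms are addressed throughout the package by the compact key
#' \code{"resno:resid:name"} (e.g. \code{"9:G:H2'"}).  \code{atom_key}
#' builds keys, \code{parse_atom_key} splits them back into a
#' data.frame with columns \code{resno}, \code{resid}, \code{name}.
#'
#' @param resno,resid,name residue number, residue code, atom name.
#' @param key character vector of keys.
#' @return \code{atom_key}: character vector; \code{parse_atom_key}:
#'   data.frame.
#' @export
atom_key <- function(resno, resid, name) paste(resno, resid, name, sep = ":")

#' @rdname atom_key
#' @export
parse_atom_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed atom key: ", key[bad][1L])
  data.frame(resno = as.integer(vapply(parts, `[`, "", 1L)),
             resid = vapply(parts, `[`, "", 2L),
             name = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

read_pdb_block <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  atom <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  data.frame(resno = atom$resno,
             resid = trimws(atom$resid),
             rawname = trimws(atom$elety),
             elesy = trimws(atom$elesy),
             x = atom$x, y = atom$y, z = atom$z,
             stringsAsFactors = FALSE)
}

#' Read a (multi-model) PDB file into a conformer ensemble
#'
#' MODEL/ENDMDL records delimit conformers; a file without MODEL records
#' is read as a single conformer.  Atom names are normalized with
#' \code{\link{normalize_atom_name}}.  Atoms present in only some models
#' are dropped with a warning, because all downstream computations
#' assume complete per-conformer coordinates.  Residue numbering is kept
#' verbatim as deposited.
#'
#' @param x path to a PDB file, or a character vector of PDB lines.
#' @param source_label free-text label stored on the ensemble (defaults
#'   to the file name).
#' @return object of class \code{"ensemble"}: list with \code{atoms}
#'   (data.frame: \code{resno}, \code{resid}, \code{name},
#'   \code{element}, \code{key}), \code{xyz} (array
#'   \code{c(n_conf, n_atom, 3)}, Angstrom), \code{n_conf},
#'   \code{source}.
#' @export
read_ensemble <- function(x, source_label = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    if (is.null(source_label)) source_label <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    if (is.null(source_label)) source_label <- "pdb-text"
  }
  rec <- substring(lines, 1, 6)
  starts <- which(trimws(rec) == "MODEL")
  if (length(starts) == 0L) {
    blocks <- list(lines)
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    if (length(ends) != length(starts)) {
      ends <- c(ends, length(lines))[seq_along(starts)]
    }
    blocks <- Map(function(s, e) lines[(s + 1):(e - 1)], starts, ends)
  }
  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    stop("no ATOM records found: not a PDB-format input")
  }
  tabs <- lapply(blocks, read_pdb_block)
  tabs <- lapply(tabs, function(tt) {
    tt$name <- mapply(normalize_atom_name, tt$rawname, tt$resid,
                      USE.NAMES = FALSE)
    tt$key <- atom_key(tt$resno, canonical_residue(tt$resid), tt$name)
    tt[!duplicated(tt$key), , drop = FALSE]  # first altloc wins
  })
  resnums <- lapply(tabs, function(tt) sort(unique(tt$resno)))
  if (length(tabs) > 1L &&
      !all(vapply(resnums[-1], identical, TRUE, resnums[[1L]]))) {
    stop("inconsistent residue numbering across models")
  }
  shared <- Reduce(intersect, lapply(tabs, `[[`, "key"))
  n_drop <- length(unique(unlist(lapply(tabs, `[[`, "key")))) - length(shared)
  if (n_drop > 0L) {
    warning(sprintf("%d atom(s) absent from some models were dropped", n_drop))
  }
  ref <- tabs[[1L]]
  ref <- ref[match(shared, ref$key), , drop = FALSE]
  n_atom <- nrow(ref)
  xyz <- array(NA_real_, c(length(tabs), n_atom, 3L))
  for (m in seq_along(tabs)) {
    tt <- tabs[[m]]
    idx <- match(shared, tt$key)
    xyz[m, , ] <- as.matrix(tt[idx, c("x", "y", "z")])
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in PDB input")
  element <- ifelse(nzchar(ref$elesy), ref$elesy,
                    sub("^[0-9]*([A-Za-z]).*$", "\\1", ref$rawname))
  atoms <- data.frame(resno = ref$resno,
                      resid = canonical_residue(ref$resid),
                      name = ref$name, element = element,
                      key = ref$key, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = xyz, n_conf = length(tabs),
                 source = source_label),
            class = "ensemble")
}

#' Write an ensemble to PDB text
#'
#' Inverse of \code{\link{read_ensemble}} (used mainly for fixtures and
#' round-trip tests); multi-conformer ensembles get MODEL/ENDMDL blocks.
#'
#' @param e an \code{ensemble} or \code{spin_system}.
#' @param file optional path; when \code{NULL} the lines are returned.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_ensemble <- function(e, file = NULL) {
  atoms <- e$atoms
  if (is.null(atoms$element)) atoms$element <- "H"
  fmt <- function(m) {
    xyz <- e$xyz[m, , , drop = TRUE]
    dim(xyz) <- c(nrow(atoms), 3L)
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(nrow(atoms)),
            ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
            atoms$resid, atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3],
            atoms$element)
  }
  if (e$n_conf == 1L) {
    lines <- c(fmt(1L), "END")
  } else {
    lines <- unlist(lapply(seq_len(e$n_conf), function(m) {
      c(sprintf("MODEL     %4d", m), fmt(m), "ENDMDL")
    }))
    lines <- c(lines, "END")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble '%s': %d conformer(s), %d atoms, residues %d-%d\n",
              x$source, x$n_conf, nrow(x$atoms),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

classify_proton <- function(name, resid) {
  if (name %in% .amino_h) "amino"
  else if (name %in% c("H5'", "H5''")) "methylene"
  else if (name %in% .hydroxyl_h) "hydroxyl"
  else "other"
}

is_exchangeable <- function(name, resid) {
  resid <- canonical_residue(resid)
  name %in% .amino_h || name %in% .hydroxyl_h ||
    (name == "H1" && resid == "G") || (name == "H3" && resid == "U")
}

# internal constructor shared with the synthetic generator
new_spin_system <- function(atoms, xyz, source = "spin-system") {
  stopifnot(is.array(xyz), length(dim(xyz)) == 3L, dim(xyz)[2L] == nrow(atoms))
  atoms$key <- atom_key(atoms$resno, atoms$resid, atoms$name)
  gem <- rep(NA_integer_, nrow(atoms))
  me <- which(atoms$class == "methylene")
  for (i in me) {
    partner_name <- if (atoms$name[i] == "H5'") "H5''" else "H5'"
    j <- which(atoms$resno == atoms$resno[i] & atoms$name == partner_name)
    if (length(j) == 1L) gem[i] <- j
  }
  if (any(is.na(gem[me]))) {
    warning("methylene proton(s) without geminal partner in the system")
  }
  atoms$geminal <- gem
  structure(list(atoms = atoms, xyz = xyz, n_conf = dim(xyz)[1L],
                 source = source),
            class = "spin_system")
}

#' Build a proton spin system from an ensemble
#'
#' Selects the hydrogens of an ensemble and classifies each proton as
#' \code{amino}, \code{methylene} (ribose H5'/H5'', geminal-paired),
#' \code{hydroxyl} or \code{other}.  Exchangeable protons (amino,
#' hydroxyl, and the G-H1 / U-H3 iminos) can be excluded to emulate a
#' D2O sample.
#'
#' @param e an \code{\link{read_ensemble}} object.
#' @param include_exchangeable keep exchangeable protons? Default
#'   \code{TRUE} (H2O condition).
#' @return object of class \code{"spin_system"}: list with \code{atoms}
#'   (data.frame: \code{resno}, \code{resid}, \code{name}, \code{class},
#'   \code{exchangeable}, \code{key}, \code{geminal} partner index),
#'   \code{xyz} (array \code{c(n_conf, n_proton, 3)}), \code{n_conf},
#'   \code{source}.
#' @export
make_spin_system <- function(e, include_exchangeable = TRUE) {
  stopifnot(inherits(e, "ensemble"))
  is_h <- e$atoms$element == "H" | grepl("^H", e$atoms$name)
  if (!any(is_h)) {
    stop("ensemble contains no hydrogens; protonated coordinates are required")
  }
  atoms <- e$atoms[is_h, c("resno", "resid", "name"), drop = FALSE]
  atoms$class <- mapply(classify_proton, atoms$name, atoms$resid,
                        USE.NAMES = FALSE)
  atoms$exchangeable <- mapply(is_exchangeable, atoms$name, atoms$resid,
                               USE.NAMES = FALSE)
  keep <- if (include_exchangeable) rep(TRUE, nrow(atoms)) else !atoms$exchangeable
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  xyz <- e$xyz[, is_h, , drop = FALSE][, keep, , drop = FALSE]
  new_spin_system(atoms, xyz, source = e$source)
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("Spin system '%s': %d protons, %d conformer(s)\n",
              x$source, nrow(x$atoms), x$n_conf))
  print(table(x$atoms$class))
  invisible(x)
}

#' Read a NOESY buildup intensity table
#'
#' Long-format, tab-separated, \code{#} comments allowed.  Required
#' columns: \code{peak_id}, \code{atom_i}, \code{atom_j},
#' \code{mixing_time_s} (or \code{mixing_time_ms} with
#' \code{time_unit = "ms"}), \code{intensity}; optional \code{noise}.
#' Atom columns hold \code{resno:resid:name} keys; cross peak
#' \code{(atom_i, atom_j)} carries magnetization transferred from origin
#' \code{atom_j} to destination \code{atom_i}; diagonal peaks have
#' \code{atom_i == atom_j}.
#'
#' @param x path or character vector of lines.
#' @param time_unit \code{"s"} (default) or \code{"ms"}.
#' @return object of class \code{"buildup_set"}: list with data.frame
#'   \code{peaks} (\code{peak_id}, \code{atom_i}, \code{atom_j},
#'   \code{tau}, \code{intensity}, \code{noise}), logical
#'   \code{corrected}.
#' @export
read_buildup_table <- function(x, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  if (length(x) > 1L || grepl("\n", x[1L]) || !file.exists(x[1L])) {
    x <- textConnection(paste(unlist(strsplit(x, "\n")), collapse = "\n"))
    on.exit(close(x))
  }
  df <- utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
  tcol <- paste0("mixing_time_", time_unit)
  need <- c("peak_id", "atom_i", "atom_j", tcol, "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) > 0L && (!is.numeric(df[[tcol]]) || !is.numeric(df$intensity))) {
    stop("non-numeric mixing time or intensity")
  }
  tau <- df[[tcol]] * if (time_unit == "ms") 1e-3 else 1
  peaks <- data.frame(peak_id = as.character(df$peak_id),
                      atom_i = df$atom_i, atom_j = df$atom_j,
                      tau = tau, intensity = df$intensity,
                      noise = if ("noise" %in% names(df)) df$noise else
                        rep(NA_real_, nrow(df)),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(peaks[c("peak_id", "tau")])) {
    stop("duplicate (peak, mixing time) measurement")
  }
  peaks <- peaks[order(peaks$peak_id, peaks$tau), , drop = FALSE]
  rownames(peaks) <- NULL
  if (nrow(peaks) == 0L) warning("empty buildup table")
  new_buildup_set(peaks, corrected = FALSE)
}

new_buildup_set <- function(peaks, corrected = FALSE) {
  structure(list(peaks = peaks, corrected = corrected), class = "buildup_set")
}

#' Write a buildup set back to the tabular format
#' @param b a \code{buildup_set}.
#' @param file optional output path.
#' @return invisibly, the character lines.
#' @export
write_buildup_table <- function(b, file = NULL) {
  stopifnot(inherits(b, "buildup_set"))
  p <- b$peaks
  hdr <- "peak_id\tatom_i\tatom_j\tmixing_time_s\tintensity\tnoise"
  lines <- c(if (b$corrected) "# spin-diffusion corrected intensities", hdr,
             sprintf("%s\t%s\t%s\t%.6g\t%.10g\t%s", p$peak_id, p$atom_i,
                     p$atom_j, p$tau, p$intensity,
                     ifelse(is.na(p$noise), "NA", sprintf("%.6g", p$noise))))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.buildup_set <- function(x, ...) {
  p <- x$peaks
  diag <- p$atom_i == p$atom_j
  cat(sprintf("NOESY buildup set: %d diagonal + %d cross series, %d mixing times%s\n",
              length(unique(p$peak_id[diag])),
              length(unique(p$peak_id[!diag])),
              length(unique(p$tau)),
              if (x$corrected) " [spin-diffusion corrected]" else ""))
  invisible(x)
}

#' Write CYANA-style distance restraint files
#'
#' One line per restraint: residue number, residue name and atom name of
#' both partners followed by the bound in Angstrom (2 decimals), ordered
#' by first then second atom.  Bi- and uni-directional restraints appear
#' in both the upper- and lower-limit dialects; gn restraints have no
#' lower bound and are skipped (with a warning) in \code{"lower"}.
#'
#' @param restraints an \code{enoe_restraints} data.frame from
#'   \code{\link{make_restraint}}.
#' @param dialect \code{"upper"} (.upl) or \code{"lower"} (.lol).
#' @param file optional output path.
#' @return invisibly, the character lines.
#' @export
write_restraints <- function(restraints, dialect = c("upper", "lower"),
                             file = NULL) {
  dialect <- match.arg(dialect)
  r <- as.data.frame(restraints)
  bound <- if (dialect == "upper") r$upper else r$lower
  if (any(is.na(bound))) {
    warning(sprintf("%d restraint(s) lack a %s bound and were skipped",
                    sum(is.na(bound)), dialect))
    r <- r[!is.na(bound), , drop = FALSE]
    bound <- bound[!is.na(bound)]
  }
  if (nrow(r) == 0L) stop("no restraints with a ", dialect, " bound")
  o <- order(r$resno_i, r$name_i, r$resno_j, r$name_j)
  r <- r[o, , drop = FALSE]; bound <- bound[o]
  lines <- sprintf("%4d %-4s %-5s %4d %-4s %-5s %8.2f",
                   r$resno_i, r$resid_i, r$name_i,
                   r$resno_j, r$resid_j, r$name_j, bound)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a CYANA-style restraint file
#'
#' @param x path or character vector of restraint lines.
#' @param dialect which bound the file holds.
#' @return data.frame with atom columns and a \code{bound} column (A).
#' @export
read_restraints <- function(x, dialect = c("upper", "lower")) {
  dialect <- match.arg(dialect)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else {
    x <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  x <- x[nzchar(trimws(x)) & !grepl("^\\s*#", x)]
  f <- strsplit(trimws(x), "\\s+")
  if (any(lengths(f) != 7L)) stop("malformed restraint line")
  m <- do.call(rbind, f)
  data.frame(resno_i = as.integer(m[, 1]), resid_i = m[, 2], name_i = m[, 3],
             resno_j = as.integer(m[, 4]), resid_j = m[, 5], name_j = m[, 6],
             bound = as.numeric(m[, 7]), dialect = dialect,
             stringsAsFactors = FALSE)
}
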