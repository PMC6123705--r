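# Fixtures are built in code: tiny PDB texts, random spin systems and
# forward-simulated buildups with known ground truth.

pdb_atom_lines <- function(df) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(nrow(df)),
          ifelse(nchar(df$name) < 4, paste0(" ", df$name), df$name),
          df$resid, df$resno, df$x, df$y, df$z,
          ifelse(grepl("^H", df$name), "H",
                 substr(sub("[0-9']+$", "", df$name), 1, 1)))
}

make_pdb_text <- function(models) {
  if (length(models) == 1L) return(c(pdb_atom_lines(models[[1L]]), "END"))
  c(unlist(lapply(seq_along(models), function(m) {
    c(sprintf("MODEL     %4d", m), pdb_atom_lines(models[[m]]), "ENDMDL")
  })), "END")
}

# a cytosine nucleotide with ribose: mixed proton classes
cytosine_model <- function(shift = 0) {
  df <- data.frame(
    resno = 1L, resid = "C",
    name = c("C1'", "H1'", "C2'", "H2'", "O2'", "HO2'", "H3'", "H4'",
             "H5'", "H5''", "N4", "H41", "H42", "H5", "H6"),
    stringsAsFactors = FALSE)
  n <- nrow(df)
  set.seed(7)
  base <- matrix(stats::runif(n * 3, 0, 8), n, 3)
  df$x <- base[, 1] + shift; df$y <- base[, 2]; df$z <- base[, 3]
  df
}

# random well-separated proton cloud as a spin_system (class "other")
random_spin_system <- function(n, seed, min_sep = 1.9, box = 9) {
  set.seed(seed)
  pts <- matrix(stats::runif(3, 0, box), 1, 3)
  while (nrow(pts) < n) {
    cand <- stats::runif(3, 0, box)
    if (min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep) {
      pts <- rbind(pts, cand)
    }
  }
  atoms <- data.frame(resno = seq_len(n), resid = "G", name = "H8",
                      class = "other", exchangeable = FALSE,
                      stringsAsFactors = FALSE)
  xyz <- array(0, c(1L, n, 3L))
  xyz[1L, , ] <- pts
  exactnoe:::new_spin_system(atoms, xyz, source = paste0("random-", seed))
}

test_conditions <- function(...) noe_conditions(tau_c = 2.23e-9,
                                                field_mhz = 900, ...)

unordered_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
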