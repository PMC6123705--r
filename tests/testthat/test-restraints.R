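test_that("sigma <-> distance conversion is an exact round trip with r^-6 scaling", {
  cond <- test_conditions()
  r <- seq(1.8, 6, by = 0.3)
  sig <- pair_rates(r, cond)$sigma
  expect_equal(sigma_to_distance(sig, cond), r, tolerance = 1e-12)
  # halving |sigma| stretches r by 2^(1/6)
  expect_equal(sigma_to_distance(sig / 2, cond),
               r * 2^(1 / 6), tolerance = 1e-12)
  # wrong-sign sigma (would mean fast tumbling) is rejected
  expect_error(sigma_to_distance(-sig[1], cond), "sign")
  expect_error(sigma_to_distance(0, cond), "sign")
})

test_that("restraint classes carry the right tolerances", {
  cond <- test_conditions()
  mk_fit <- function(class, r) {
    sig <- pair_rates(r, cond)$sigma
    structure(list(atom_i = "9:G:H2'", atom_j = "10:G:H8",
                   sigma_ij = sig,
                   sigma_ji = if (class == "bidirectional") sig else NA_real_,
                   direction_class = class, flags = character(0),
                   excluded = FALSE), class = "cross_fit")
  }
  bi <- make_restraint(mk_fit("bidirectional", 3.50), cond)
  expect_equal(bi$upper, 3.50, tolerance = 1e-9)
  expect_equal(bi$lower, 3.50, tolerance = 1e-9)
  uni <- make_restraint(mk_fit("unidirectional", 4.00), cond)
  expect_equal(uni$upper, 4.40, tolerance = 1e-9)
  expect_equal(uni$lower, 3.60, tolerance = 1e-9)
  gn <- make_restraint(mk_fit("gn", 4.00), cond)
  expect_equal(gn$upper, 4.40, tolerance = 1e-9)
  expect_true(is.na(gn$lower))
  # bidirectional combines the two directions by the sigma mean
  f <- mk_fit("bidirectional", 3.0)
  f$sigma_ji <- f$sigma_ij * 2
  rr <- make_restraint(f, cond)
  expect_equal(rr$r_eff,
               sigma_to_distance(1.5 * pair_rates(3, cond)$sigma, cond))
  bad <- mk_fit("bidirectional", 3); bad$excluded <- TRUE
  expect_error(make_restraint(bad, cond), "rejected")
})

test_that("ensemble distances: r^-6 averaging never exceeds linear averaging", {
  h <- make_helix_spin_system(2, conformers = 5, displacement = 0.7,
                              seed = 3)
  s <- h$spin_system
  keys <- s$atoms$key
  for (p in list(c(1, 4), c(2, 9), c(3, 7))) {
    r6 <- ensemble_distance(s, keys[p], mode = "r6")
    lin <- ensemble_distance(s, keys[p], mode = "linear")
    expect_lte(r6, lin + 1e-12)
  }
  # single conformer: both modes equal the geometric distance
  s1 <- make_helix_spin_system(2)$spin_system
  d_geo <- sqrt(sum((s1$xyz[1, 1, ] - s1$xyz[1, 4, ])^2))
  expect_equal(ensemble_distance(s1, s1$atoms$key[c(1, 4)], "r6"), d_geo)
  expect_equal(ensemble_distance(s1, s1$atoms$key[c(1, 4)], "linear"), d_geo)
  expect_error(ensemble_distance(s1, c("99:G:H8", s1$atoms$key[1])), "not in")
})

test_that("distance-set comparison computes through-origin slope and subgroups", {
  set.seed(8)
  keys_i <- sprintf("%d:G:H8", 1:12)
  keys_j <- sprintf("%d:G:H1'", 2:13)
  r <- runif(12, 2, 5)
  a <- data.frame(key_i = keys_i, key_j = keys_j, r = r)
  b <- a
  cs <- compare_distances(a, b)
  expect_equal(cs$slope, 1); expect_equal(cs$pearson_r, 1)
  b2 <- a; b2$r <- 2 * a$r
  cs2 <- compare_distances(a, b2)
  expect_equal(cs2$slope, 2); expect_equal(cs2$pearson_r, 1)
  expect_error(compare_distances(a[1:2, ], b[1:2, ]), "3 shared")

  # subgroup partition covers all shared pairs exactly once
  classes <- c(stats::setNames(rep("other", 12), keys_i),
               stats::setNames(rep("amino", 12), keys_j))
  classes[keys_j[1:4]] <- "other"
  cs3 <- compare_distances(a, b, classes = classes)
  expect_equal(sum(cs3$subgroups$n), cs3$n_pairs)
})

test_that("target function sums squared violations and honors r^-6 state averaging", {
  cond <- test_conditions()
  # two-state toy: one proton alternates between two positions so that
  # only the state-averaged distance satisfies the restraint
  atoms <- data.frame(resno = c(1, 2), resid = "G", name = c("H8", "H1'"),
                      element = "H",
                      key = c("1:G:H8", "2:G:H1'"), stringsAsFactors = FALSE)
  xyz <- array(0, c(2, 2, 3))
  xyz[1, 2, 1] <- 3.0   # state A: 3.0 A
  xyz[2, 2, 1] <- 4.4   # state B: 4.4 A
  e <- structure(list(atoms = atoms, xyz = xyz, n_conf = 2L,
                      source = "toy"), class = "ensemble")
  r6 <- mean(c(3, 4.4)^-6)^(-1 / 6)
  restr <- exactnoe:::restraint_row(
    data.frame(resno = 1, resid = "G", name = "H8"),
    data.frame(resno = 2, resid = "G", name = "H1'"), r6, "bidirectional")
  class(restr) <- c("enoe_restraints", "data.frame")

  rep_r6 <- violation_tf(restr, e, averaging = "r6_over_states")
  expect_equal(rep_r6$tf, 0)
  rep_pc <- violation_tf(restr, e, averaging = "per_conformer")
  expect_true(all(rep_pc$tf > 0))  # each single state violates

  # explicit arithmetic: 0.5 A violation -> TF 0.25 A^2
  tight <- restr; tight$upper <- 2.5; tight$lower <- 2.5; tight$r_eff <- 2.5
  e1 <- e; e1$xyz <- e$xyz[1, , , drop = FALSE]; e1$n_conf <- 1L
  rep1 <- violation_tf(tight, e1)
  expect_equal(rep1$tf, 0.25, tolerance = 1e-12)
  expect_equal(nrow(rep1$highlighted), 1L)  # 0.5 >= 0.2 A highlighting rule

  # reordering invariance and relaxation monotonicity
  two <- bind_restraints(restr, tight)
  expect_equal(violation_tf(two, e1)$tf,
               violation_tf(two[2:1, ], e1)$tf)
  relaxed <- tight; relaxed$upper <- 2.8
  expect_lt(violation_tf(relaxed, e1)$tf, rep1$tf)

  # unresolvable atoms are skipped with a warning
  ghost <- tight; ghost$resno_j <- 99
  expect_warning(rep_g <- violation_tf(bind_restraints(tight, ghost), e1),
                 "skipped")
  expect_equal(rep_g$tf, rep1$tf)
})

test_that("jack-knife partitions cover every restraint once and partial TFs add up", {
  cond <- test_conditions()
  h <- make_helix_spin_system(3, conformers = 2, displacement = 0.4,
                              seed = 5)
  s <- h$spin_system
  tr <- h$truth[h$truth$r_true <= 5.5, ]
  rows <- lapply(seq_len(nrow(tr)), function(k) {
    exactnoe:::restraint_row(parse_atom_key(tr$key_i[k]),
                             parse_atom_key(tr$key_j[k]),
                             tr$r_true[k] * 0.97, "unidirectional")
  })
  restr <- do.call(bind_restraints, rows)
  jk <- jackknife(restr, s, k = 10, seed = 42)
  expect_equal(sort(unique(jk$folds)), 1:10)
  expect_equal(length(jk$folds), nrow(restr))
  expect_equal(jk$cv_tf, sum(jk$partials))
  # fold-wise evaluation of the full set equals the sum of partials
  full_by_fold <- sum(vapply(1:10, function(f) {
    sub <- restr[jk$folds == f, ]
    class(sub) <- c("enoe_restraints", "data.frame")
    violation_tf(sub, s)$tf
  }, 0))
  expect_equal(jk$cv_tf, full_by_fold)
  # k = 1 degenerates to the plain target function
  jk1 <- jackknife(restr, s, k = 1, seed = 1)
  expect_equal(jk1$cv_tf, violation_tf(restr, s)$tf)
  expect_error(jackknife(restr, s, k = nrow(restr) + 1), "folds")
})

test_that("peak pruning deletes 2:1, demotes monotonically and is reproducible", {
  set.seed(10)
  n <- 30
  diag_ids <- sprintf("%d:G:H8", 1:n)
  pairs <- t(combn(n, 2))[sample(choose(n, 2), 60), ]
  cross <- data.frame(atom_i = diag_ids[pairs[, 1]],
                      atom_j = diag_ids[pairs[, 2]],
                      stringsAsFactors = FALSE)
  cross <- rbind(cross, data.frame(atom_i = cross$atom_j,
                                   atom_j = cross$atom_i))  # both directions

  # f = 0 is the identity: everything bidirectional
  r0 <- prune_peaks(diag_ids, cross, 0, seed = 1)
  expect_equal(nrow(r0), 60L)
  expect_true(all(r0$class == "bidirectional"))

  # f = 0.35 deletes 70% of diagonals and 35% of cross peaks
  r35 <- prune_peaks(diag_ids, cross, 0.35, seed = 1)
  expect_equal(length(unique(c(r35$atom_i, r35$atom_j))) >= 0, TRUE)
  n_del_diag <- floor(2 * 0.35 * n)
  n_del_cross <- floor(0.35 * nrow(cross))
  expect_equal(n_del_diag, 21L)   # 70% of 30
  expect_equal(n_del_cross, 42L)  # 35% of 120

  # reproducibility at fixed seed
  expect_identical(r35, prune_peaks(diag_ids, cross, 0.35, seed = 1))
  expect_error(prune_peaks(diag_ids, cross, 0.6), "0.5")

  # the demotion chain: losing peaks only ever weakens the class
  pair2 <- data.frame(atom_i = c("1:G:H8", "2:G:H8"),
                      atom_j = c("2:G:H8", "1:G:H8"),
                      stringsAsFactors = FALSE)
  cls <- function(diags, crosses) {
    prune_peaks(diags, crosses, 0, seed = 1)$class
  }
  expect_equal(cls(c("1:G:H8", "2:G:H8"), pair2), "bidirectional")
  expect_equal(cls("1:G:H8", pair2), "unidirectional")      # one diagonal lost
  expect_equal(cls(character(0), pair2), "gn")              # both lost
  expect_equal(cls(c("1:G:H8", "2:G:H8"), pair2[1, ]), "unidirectional")
  expect_equal(cls(character(0), pair2[1, ]), "gn")
  # deleted cross peaks remove the restraint entirely
  expect_equal(nrow(prune_peaks(diag_ids, cross[0, ], 0, seed = 1)), 0L)

  # across seeds: no restraint is ever stronger after pruning than before
  rank <- c(gn = 1, unidirectional = 2, bidirectional = 3)
  r_full <- prune_peaks(diag_ids, cross, 0, seed = 1)
  id_full <- paste(r_full$atom_i, r_full$atom_j)
  for (seed in 1:10) {
    pr <- prune_peaks(diag_ids, cross, 0.3, seed = seed)
    m <- match(paste(pr$atom_i, pr$atom_j), id_full)
    expect_true(all(rank[pr$class] <= rank[r_full$class[m]]))
  }
})
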