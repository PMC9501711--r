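test_that("measured torsions match hand geometry and an independent formula", {
  # planar anti and syn arrangements
  anti <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  syn  <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(measure_dihedral(anti, 1:4), 180)
  expect_equal(measure_dihedral(syn, 1:4), 0)
  # ideal staggered tetrahedral fragment: +/-60 against the oracle
  but <- make_toy_ligand("butane_like")
  sp <- but$dihedrals$gamma
  for (target in c(60, -60)) {
    conf <- rotate_about_bond(conformation(but), sp, target)
    expect_equal(measure_dihedral(conf, sp), target, tolerance = 1e-9)
    expect_equal(oracle_dihedral(conf[1, ], conf[2, ], conf[3, ], conf[4, ]),
                 target, tolerance = 1e-9)
  }
  # oracle agreement on random conformations
  withr::with_seed(7, {
    for (i in 1:50) {
      conf <- matrix(rnorm(12, sd = 2), 4, 3)
      expect_equal(measure_dihedral(conf, 1:4),
                   oracle_dihedral(conf[1, ], conf[2, ], conf[3, ], conf[4, ]),
                   tolerance = 1e-9)
    }
  })
  expect_error(measure_dihedral(rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)), 1:4),
               "collinear")
})

test_that("set-then-measure identity holds and rotation moves only the far side", {
  mol <- make_toy_ligand("catechol_amine_like")
  sp <- mol$dihedrals$gamma
  ref <- conformation(mol)
  near <- setdiff(seq_len(nrow(ref)), sp$rotating)
  withr::with_seed(3, {
    for (target in c(runif(25, -180, 180), 180, -179.999, 0)) {
      out <- rotate_about_bond(ref, sp, target)
      expect_equal(measure_dihedral(out, sp), wrap_angle(target), tolerance = 1e-9)
      expect_equal(out[near, ], ref[near, ])
    }
  })
  # identity and full-turn rotations leave coordinates unchanged
  cur <- measure_dihedral(ref, sp)
  expect_equal(rotate_about_bond(ref, sp, cur), ref, tolerance = 1e-12)
  turned <- rotate_about_bond(ref, sp, cur + 360)
  expect_equal(turned, ref, tolerance = 1e-9)
  # compose through 0/120/240 and return
  conf <- ref
  for (a in c(0, 120, 240, cur)) conf <- rotate_about_bond(conf, sp, a)
  expect_equal(conf, ref, tolerance = 1e-9)
  # internal geometry of the rotating half is rigid
  rot <- rotate_about_bond(ref, sp, cur + 77)
  d0 <- dist(ref[sp$rotating, ]); d1 <- dist(rot[sp$rotating, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-10)
  # a rotating set reaching across the bond onto the near side is rejected
  bad <- dihedral_spec("bad", sp$atoms, rotating = c(sp$atoms[2], sp$rotating))
  expect_error(rotate_about_bond(ref, bad, 10), "near-side")
  expect_error(dihedral_spec("bad", sp$atoms,
                             rotating = c(sp$atoms[1], sp$rotating)),
               "must not contain")
})

test_that("in-place RMSD matches hand arithmetic", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_in_place(a, a), 0)
  expect_equal(rmsd_in_place(a, sweep(a, 2, c(3, 0, 0), `+`)), 3)
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  moved <- rbind(c(1, 0, 0), c(5, 3, 0))
  expect_equal(rmsd_in_place(two, moved), sqrt(5))
  expect_error(rmsd_in_place(a, a, integer(0)), "nonempty")
})

test_that("superposition recovers rigid motions and never beats brute force", {
  withr::with_seed(11, {
    a <- matrix(rnorm(15, sd = 2), 5, 3)
    tr <- random_rigid()
    b <- sweep(a %*% t(tr$R), 2, tr$t, `+`)
    fit <- superpose(a, b)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(apply_transform(b, fit$rotation, fit$translation), a,
                 tolerance = 1e-8)
    ident <- superpose(a, a)
    expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
    expect_equal(ident$rmsd, 0, tolerance = 1e-12)

    # brute-force oracle: exhaustive search over a fine rotation grid can
    # never do better, and comes close with a fine enough grid
    b2 <- a + matrix(rnorm(15, sd = 0.7), 5, 3)
    fit2 <- superpose(a, b2)
    ca <- colMeans(a); cb <- colMeans(b2)
    A <- sweep(a, 2, ca); B <- sweep(b2, 2, cb)
    best <- Inf
    axes <- matrix(rnorm(3 * 800), ncol = 3)
    axes <- axes / sqrt(rowSums(axes^2))
    for (i in seq_len(nrow(axes))) {
      for (ang in seq(0, 2 * pi, length.out = 73)[-73]) {
        R <- dockfit:::rotation_about_axis(axes[i, ], ang)
        best <- min(best, sqrt(mean(rowSums((B %*% t(R) - A)^2))))
      }
    }
    expect_lte(fit2$rmsd, best + 1e-12)
    expect_lt(best - fit2$rmsd, 0.05)
  })
  expect_error(superpose(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3),
                         subset = 1:2), "3 subset atoms")
  line <- cbind(0:3, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("radius of gyration matches closed forms and supports mass weighting", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(radius_of_gyration(square), sqrt(2) / 2)
  # mass weighting shifts the centroid toward the heavy atom
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  weights = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
})

test_that("rg and superimposed RMSD are invariant under rigid transforms", {
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- matrix(rnorm(24, sd = 3), 8, 3)
      b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
      tr <- random_rigid()
      aT <- apply_transform(a, tr$R, tr$t)
      bT <- apply_transform(b, tr$R, tr$t)
      expect_equal(radius_of_gyration(aT), radius_of_gyration(a),
                   tolerance = 1e-9)
      expect_equal(superpose(a, bT)$rmsd, superpose(a, b)$rmsd,
                   tolerance = 1e-9)
      expect_lte(superpose(a, b)$rmsd, rmsd_in_place(a, b) + 1e-12)
    }
  })
})
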