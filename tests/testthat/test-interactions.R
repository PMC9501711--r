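test_that("distance rule classifies the boundary inclusively", {
  expect_identical(classify_hbond_distance(c(2.7, 3.5, 3.7)),
                   c(TRUE, TRUE, FALSE))
  expect_identical(classify_hbond_distance(3.6, threshold = 4), TRUE)
  expect_error(classify_hbond_distance(-1), "positive")
})

test_that("automatic donor-acceptor detection finds a toy hydrogen bond", {
  lig <- atom_table("N", "N", x = 0, donor = TRUE, acceptor = TRUE,
                    resname = "LIG", chain = "L")
  rec <- atom_table(c("OD1", "CB"), c("O", "C"), x = c(2.8, 3.0), y = c(0, 2),
                    acceptor = c(TRUE, FALSE), donor = c(TRUE, FALSE),
                    resname = "ASP", resno = 113L, chain = "R")
  hb <- detect_hbonds(lig, rec)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8)
  expect_true(hb$compatible)
  expect_match(hb$label, "OD1 \\(ASP113\\)-N")
  # swapping the molecule roles preserves the measured geometry
  hb_sw <- detect_hbonds(rec, lig)
  expect_equal(hb_sw$distance, hb$distance)
})

test_that("pair dictionaries realize reference columns and report absent groups", {
  plan <- reference_pair_plan("flexible", "DRO")
  site <- make_binding_site(plan)
  hb <- detect_hbonds(site$ligand, site$receptor, pairs = plan)
  expect_equal(hb$label, plan$label)
  expect_equal(hb$distance, plan$distance, tolerance = 1e-6)
  expect_identical(hb$compatible, plan$published_compatible)
  # the boundary cells: 3.5 compatible, 3.9 not
  expect_true(hb$compatible[which(abs(hb$distance - 3.5) < 1e-6)])
  expect_false(any(hb$compatible[hb$distance > 3.6]))
  # a ligand lacking the beta-OH: those pairs reported absent, not zero
  plan_dah <- reference_pair_plan("rigid", "DAH")
  site_dah <- make_binding_site(plan_dah)
  hb_dah <- detect_hbonds(site_dah$ligand, site_dah$receptor, pairs = plan_dah)
  absent <- hb_dah[!hb_dah$present, ]
  expect_equal(nrow(absent), 3)
  expect_true(all(is.na(absent$distance)))
  expect_true(all(absent$ligand_atom == "OB"))
  # a receptor atom missing from the structure is an error naming the pair
  plan_bad <- plan[1, ]
  plan_bad$receptor_atom <- "XX9"
  expect_error(detect_hbonds(site$ligand, site$receptor, pairs = plan_bad),
               "XX9")
})

test_that("rule-based classification reproduces the published pattern up to its one inconsistent cell", {
  # the published table marks rigid L-DOPA OG(S203)-para-O (2.8 A) as not
  # compatible even though 2.8 A satisfies the distance rule; every other
  # defined cell agrees with the <= 3.5 A classification
  mismatches <- list()
  for (m in c("rigid", "flexible")) for (lg in c("ALE", "DAH", "DRO")) {
    plan <- reference_pair_plan(m, lg)
    site <- make_binding_site(plan)
    hb <- detect_hbonds(site$ligand, site$receptor, pairs = plan)
    def <- hb$present
    bad <- which(hb$compatible[def] != plan$published_compatible[def])
    for (b in bad) {
      mismatches[[length(mismatches) + 1]] <-
        list(model = m, ligand = lg, label = hb$label[def][b])
    }
  }
  expect_equal(length(mismatches), 1)
  expect_equal(mismatches[[1]]$model, "rigid")
  expect_equal(mismatches[[1]]$ligand, "DAH")
  expect_match(mismatches[[1]]$label, "OG \\(S203\\)-OP")
})

test_that("hydrophobic contacts respect the cutoff and aggregate per residue", {
  lig <- atom_table("CB", "C", x = 0, hydrophobic = TRUE, chain = "L")
  near <- atom_table("CG1", "C", x = 3.9, hydrophobic = TRUE,
                     resname = "VAL", resno = 117L, chain = "R")
  far <- atom_table("CG1", "C", x = 4.1, hydrophobic = TRUE,
                    resname = "VAL", resno = 117L, chain = "R")
  expect_equal(nrow(detect_hydrophobic(lig, near)$contacts), 1)
  expect_equal(nrow(detect_hydrophobic(lig, far)$contacts), 0)
  # constructed pocket with per-residue counts (2, 1, 0)
  site <- make_binding_site(
    data.frame(label = "anchor", receptor_atom = "OD1",
               receptor_resname = "ASP", receptor_resno = 113L,
               ligand_atom = "N", distance = 2.8),
    hydrophobic_plan = data.frame(
      receptor_resname = c("VAL", "VAL", "PHE", "LEU"),
      receptor_resno = c(117L, 117L, 289L, 275L),
      atom = c("CG1", "CG2", "CZ", "CD1"),
      distance = c(3.5, 3.9, 3.2, 6.5)))
  hp <- detect_hydrophobic(site$ligand, site$receptor)
  counts <- setNames(hp$by_residue$n_contacts,
                     paste0(hp$by_residue$resname, hp$by_residue$resno))
  expect_equal(counts[["VAL117"]], 2)
  expect_equal(counts[["PHE289"]], 1)
  expect_false("LEU275" %in% names(counts))
  # counts are non-decreasing in the cutoff
  expect_gte(nrow(detect_hydrophobic(site$ligand, site$receptor, 7)$contacts),
             nrow(hp$contacts))
})

test_that("contact fractions follow the 5 A any-atom rule", {
  lig_at <- function(x) atom_table("C1", "C", x = x, chain = "L")
  rec <- atom_table(c("CA", "CA"), "C", x = c(0, 30),
                    resname = c("ASP", "SER"), resno = c(113L, 203L),
                    chain = "R")
  frames_in <- purrr::map(1:4, ~ list(ligand = lig_at(4.9), receptor = rec))
  cp <- contact_profile(frames_in)
  expect_equal(cp$fraction[cp$resno == 113], 1.0)
  expect_equal(cp$fraction[cp$resno == 203], 0.0)
  expect_equal(contact_profile(list(list(ligand = lig_at(5.1), receptor = rec)))$fraction,
               c(0, 0))
  # in contact for exactly 250 of 1000 frames
  frames <- purrr::map(1:1000, function(i) {
    list(ligand = lig_at(if (i <= 250) 4.0 else 9.0), receptor = rec)
  })
  expect_equal(contact_profile(frames)$fraction[1], 0.25)
  expect_error(contact_profile(list()), "frame")
})

test_that("interaction summaries are deterministic tabulations", {
  site <- make_binding_site(
    reference_pair_plan("flexible", "ALE"),
    hydrophobic_plan = data.frame(
      receptor_resname = c("VAL", "PHE"), receptor_resno = c(117L, 289L),
      atom = c("CG1", "CZ"), distance = c(3.8, 3.6)))
  s1 <- interaction_summary(site$ligand, site$receptor,
                            pairs = reference_pair_plan("flexible", "ALE"))
  s2 <- interaction_summary(site$ligand, site$receptor,
                            pairs = reference_pair_plan("flexible", "ALE"))
  expect_identical(s1, s2)
  expect_equal(s1$n_hydrophobic, 2)
  plan <- reference_pair_plan("flexible", "ALE")
  expect_equal(s1$n_hbonds, sum(plan$published_compatible, na.rm = TRUE))
  # empty receptor: all zeros
  empty_rec <- atom_table(character(), character())
  s0 <- interaction_summary(site$ligand, empty_rec)
  expect_equal(unlist(s0), c(n_hbonds = 0, n_hydrophobic = 0))
})
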