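test_that("built-in role table covers guanine donors/acceptors and backbone", {
  st <- tiny_scene()
  roles <- assign_roles(st)
  g_roles <- roles[roles$resno == 1, ]
  role_of <- stats::setNames(g_roles$role, g_roles$atom)
  expect_equal(unname(role_of["N2"]), "donor")
  expect_equal(unname(role_of[c("O6", "N3", "N7")]), rep("acceptor", 3))
  expect_equal(unname(role_of["OP2"]), "acceptor")
  # water oxygen: both roles, no antecedent
  stw <- tiny_scene(water_xyz = matrix(c(10, 10, 10), ncol = 3))
  wrow <- assign_roles(stw)
  wrow <- wrow[wrow$category == "water", ]
  expect_equal(wrow$role, "both")
  expect_length(wrow$antecedents[[1]], 0)
  # ligand atoms get roles only from overrides
  expect_false("NCH" %in% roles$atom)
  roles2 <- assign_roles(st, overrides = data.frame(atom = "NCH",
                                                    role = "donor"))
  expect_true("NCH" %in% roles2$atom)
  # override naming an absent atom warns, does not fail
  expect_warning(assign_roles(st, overrides = data.frame(atom = "QZ9",
                                                         role = "donor")),
                 "QZ9")
})

test_that("distance cutoff accepts at the boundary and rejects just above", {
  # waters at 2.9 and 3.30 A from the backbone OP2 at (8, 0, 0)
  st <- tiny_scene(water_xyz = rbind(c(8 + 2.9, 0, 0), c(8, 3.30, 0)))
  hb <- detect_hbonds(st)
  expect_equal(nrow(hb[hb$category == "water-DNA", ]), 1)
  expect_equal(hb$distance[hb$category == "water-DNA"], 2.9)
  # same geometry under a 3.30 cutoff picks up both
  hb2 <- detect_hbonds(st, criteria = hbond_criteria(max_distance = 3.30,
                                                     angle_mode = "distance_only"))
  expect_equal(sum(hb2$category == "water-DNA"), 2)
})

test_that("angle criterion rejects off-ideal donors except in distance_only", {
  # ligand donor NCH with antecedent C1; acceptor water placed so that
  # angle(C1, NCH, W) deviates 35 degrees from the sp3 ideal of 109.5
  ang <- (109.5 + 35) * pi / 180
  atoms <- data.frame(
    record = "HETATM",
    atom = c("C1", "NCH", "O"),
    resid = c("LIG", "LIG", "HOH"),
    chain = "A", resno = c(101, 101, 201),
    x = c(-1.5, 0, 2.8 * cos(pi - ang)),
    y = c(0, 0, 2.8 * sin(pi - ang)),
    z = 0, occupancy = 1, b = 10, altloc = "",
    element = c("C", "N", "O"))
  st <- gq_structure(atoms, ligand_codes = "LIG")
  ov <- data.frame(atom = "NCH", role = "donor", hybrid = "sp3")
  ov$antecedents <- list("C1")

  hb_proxy <- detect_hbonds(st, overrides = ov,
                            criteria = hbond_criteria())
  expect_equal(nrow(hb_proxy), 0)

  hb_dist <- detect_hbonds(st, overrides = ov,
                           criteria = hbond_criteria(angle_mode = "distance_only"))
  expect_equal(nrow(hb_dist), 1)

  # at the ideal angle the proxy mode accepts
  ang0 <- 109.5 * pi / 180
  atoms$x[3] <- 2.8 * cos(pi - ang0)
  atoms$y[3] <- 2.8 * sin(pi - ang0)
  st0 <- gq_structure(atoms, ligand_codes = "LIG")
  expect_equal(nrow(detect_hbonds(st0, overrides = ov)), 1)

  # ideal_hydrogen mode: collinear-ideal geometry accepted, far-off rejected
  hb_ideal0 <- detect_hbonds(st0, overrides = ov,
                             criteria = hbond_criteria(angle_mode = "ideal_hydrogen"))
  expect_equal(nrow(hb_ideal0), 1)
  hb_ideal35 <- detect_hbonds(st, overrides = ov,
                              criteria = hbond_criteria(angle_mode = "ideal_hydrogen"))
  expect_equal(nrow(hb_ideal35), 0)

  # waters are exempt from the angle test in every mode
  expect_equal(nrow(detect_hbonds(tiny_scene(
    water_xyz = matrix(c(8 + 2.9, 0, 0), ncol = 3)))), 1)
})

test_that("detection equals the brute-force all-pairs oracle on scenes", {
  for (seed in c(1, 7, 23)) {
    sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 3,
                                    n_decoy_waters = 6, jitter_sd = 0.1,
                                    seed = seed))
    roles <- assign_roles(sc$structure, overrides = scene_role_overrides(sc))
    for (crit in list(hbond_criteria(),
                      hbond_criteria(preset = "published"))) {
      hb <- detect_hbonds(sc$structure, roles = roles, criteria = crit)
      expect_equal(hbond_keys(hb),
                   oracle_hbond_keys(sc$structure, roles, crit),
                   info = paste("seed", seed, crit$angle_mode))
    }
  }
})

test_that("bond set is monotone in the distance cutoff", {
  sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 2,
                                  n_decoy_waters = 8, jitter_sd = 0.12,
                                  seed = 13))
  cuts <- c(2.6, 2.9, 3.25, 3.45)
  sets <- lapply(cuts, function(d) {
    hbond_keys(detect_hbonds(
      sc$structure, overrides = scene_role_overrides(sc),
      criteria = hbond_criteria(max_distance = d,
                                angle_mode = "distance_only")))
  })
  strip <- function(k) sub("\\|[0-9.]+$", "", k)
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(strip(sets[[i]]) %in% strip(sets[[i + 1]])))
  }
})

test_that("contact tables load with categories inferred from labels", {
  hb_b <- load_contact_table(braco19_contacts())
  expect_equal(nrow(hb_b), 14)
  expect_equal(as.integer(table(hb_b$category)[c(
    "ligand-water", "water-water", "water-DNA", "ligand-DNA")]),
    c(5L, 2L, 6L, 1L))

  g1 <- mm41_contacts()[mm41_contacts()$group_label == "groove 1", ]
  hb_g1 <- load_contact_table(g1)
  expect_equal(nrow(hb_g1), 8)
  lw <- hb_g1[hb_g1$category == "ligand-water", ]
  expect_setequal(paste(lw$atom_a, lw$atom_b),
                  c("NCH W204", "OAF W227"))

  expect_equal(nrow(load_contact_table(mm41_contacts()[0, ])), 0)

  bad <- data.frame(atom_a = "XQZ", atom_b = "W204", distance_A = 2.9)
  expect_error(load_contact_table(bad), "XQZ")
})

test_that("bonds are unordered and oriented canonically", {
  # same pair given in both orders collapses to one bond after detection
  st <- tiny_scene(water_xyz = rbind(c(8 + 2.9, 0, 0), c(8 + 2.9, 2.8, 0)))
  hb <- detect_hbonds(st)
  keys <- paste(pmin(hb$atom_a, hb$atom_b), pmax(hb$atom_a, hb$atom_b))
  expect_equal(anyDuplicated(keys), 0)
  # water-water pairs qualify in both donor->acceptor directions yet appear once
  expect_equal(sum(hb$category == "water-water"), 1)
  # table rows printed water-first still orient ligand-first
  row <- load_contact_table(data.frame(atom_a = "W56", atom_b = "N39",
                                       distance_A = 3.4))
  expect_equal(row$atom_a, "N39")
  expect_equal(row$category, "ligand-water")
})
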