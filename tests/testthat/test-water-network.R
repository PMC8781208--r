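hb_a <- load_contact_table(mm41_contacts())
hb_b <- load_contact_table(braco19_contacts())

test_that("contact graphs carry the expected water node sets", {
  ga <- build_contact_graph(hb_a)
  wa <- igraph::V(ga)$name[igraph::V(ga)$category == "water"]
  expect_setequal(wa, c("W204", "W203", "W227", "W251",
                        "W217", "W218", "W219", "W220"))
  gb <- build_contact_graph(hb_b)
  wb <- igraph::V(gb)$name[igraph::V(gb)$category == "water"]
  expect_setequal(wb, c("W52", "W53", "W56", "W55", "W41", "W44"))
  expect_equal(igraph::ecount(ga), nrow(hb_a))

  empty <- build_contact_graph(hb_a[0, ])
  expect_equal(igraph::vcount(empty), 0)
})

test_that("bridge enumeration finds the published mediation paths", {
  g1 <- load_contact_table(mm41_contacts()[mm41_contacts()$group_label == "groove 1", ])
  br <- find_bridges(g1, max_waters = 2)
  keys <- paste(br$ligand_atom, br$waters, br$dna_atom, sep = " / ")
  expect_true("NCH / W204 / N2 dG4" %in% keys)
  expect_true("NCH / W204 -> W203 / OP2 dG10" %in% keys)
  # waters distinct within a path; interior nodes all waters
  expect_true(all(vapply(br$water_list, anyDuplicated, 1L) == 0))
  expect_true(all(br$k >= 1 & br$k <= 2))
})

test_that("bridge enumeration equals exhaustive DFS on both tables", {
  for (hb in list(hb_a, hb_b)) {
    for (mw in c(1, 2, 4)) {
      expect_equal(bridge_keys(find_bridges(hb, max_waters = mw)),
                   oracle_bridges(hb, max_waters = mw))
    }
  }
  # and on planted synthetic graphs
  sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 4,
                                  n_decoy_waters = 6, seed = 17))
  hb <- detect_hbonds(sc$structure, overrides = scene_role_overrides(sc))
  expect_equal(bridge_keys(find_bridges(hb, max_waters = 4)),
               oracle_bridges(hb, max_waters = 4))
})

test_that("a graph without ligand nodes yields no bridges", {
  dna_only <- hb_a[hb_a$category %in% c("water-water", "water-DNA"), ]
  expect_equal(nrow(find_bridges(dna_only)), 0)
})

test_that("shell labels partition the waters and match the definitions", {
  sh <- classify_shells(hb_a)
  expect_setequal(sh$shell[sh$water == "W204"], "first")
  expect_equal(anyDuplicated(sh$water), 0)
  expect_true(all(sh$shell %in% c("first", "second", "bulk-like")))

  # constructed case: w2 only touches the first-shell w1; w3 isolated
  hb <- load_contact_table(data.frame(
    atom_a = c("NCH", "W1"), atom_b = c("W1", "W2"),
    distance_A = c(3.0, 2.8)))
  sh2 <- classify_shells(hb, waters = c("W1", "W2", "W3"))
  lab <- stats::setNames(sh2$shell, sh2$water)
  expect_equal(unname(lab[c("W1", "W2", "W3")]),
               c("first", "second", "bulk-like"))

  # third-shell chains fall through to bulk-like
  hb3 <- load_contact_table(data.frame(
    atom_a = c("NCH", "W1", "W2"), atom_b = c("W1", "W2", "W3"),
    distance_A = 2.8))
  sh3 <- classify_shells(hb3)
  expect_equal(sh3$shell[sh3$water == "W3"], "bulk-like")
})

test_that("every bridge interior water is first or second shell", {
  for (seed in c(3, 9)) {
    sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 4,
                                    n_decoy_waters = 5, seed = seed))
    hb <- detect_hbonds(sc$structure, overrides = scene_role_overrides(sc))
    sh <- classify_shells(hb)
    lab <- stats::setNames(sh$shell, sh$water)
    br <- find_bridges(hb)
    interior <- unique(unlist(br$water_list))
    expect_true(all(lab[interior] %in% c("first", "second")))
  }
})

test_that("water clusters reproduce the published groove chains", {
  cl <- water_clusters(hb_a)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$size, c(4L, 4L))
  m <- lapply(cl$members, identity)
  expect_true(any(vapply(m, function(x) {
    setequal(x, c("W204", "W203", "W227", "W251"))
  }, logical(1))))
  g23 <- which(vapply(m, function(x) {
    setequal(x, c("W217", "W218", "W219", "W220"))
  }, logical(1)))
  expect_length(g23, 1)
  expect_true(all(c("NCE", "NCG") %in% cl$anchors[[g23]]))

  # edgeless waters are singleton clusters
  cl0 <- water_clusters(hb_a[0, ], waters = c("W1", "W2", "W3"))
  expect_equal(cl0$size, c(1L, 1L, 1L))
})

test_that("cluster sizes sum to the number of water nodes", {
  for (hb in list(hb_a, hb_b)) {
    cl <- water_clusters(hb)
    sh <- classify_shells(hb)
    expect_equal(sum(cl$size), nrow(sh))
  }
})

test_that("mediation summary reproduces the published direct/mediated counts", {
  mb <- mediation_summary(hb_b)
  expect_equal(mb$summary$n_direct, 1L)
  expect_equal(mb$summary$n_water_adjacent, 5L)
  water_adj <- mb$detail$ligand_atom[mb$detail$water_adjacent]
  expect_setequal(water_adj, c("N7", "O52", "N39", "N17", "N47"))
  direct <- mb$detail$ligand_atom[mb$detail$direct > 0]
  expect_equal(direct, "N21")

  ma <- mediation_summary(hb_a)
  expect_equal(ma$summary$n_direct, 2L)
  expect_setequal(ma$detail$ligand_atom[ma$detail$direct > 0],
                  c("NCA", "NCF"))

  expect_error(mediation_summary(hb_a[hb_a$category == "water-water", ]),
               "ligand")
})

test_that("mediation counts are invariant under node relabeling", {
  relabel <- function(tab) {
    f <- function(x) {
      x <- sub("^W", "W9", x)
      sub("dG", "dA", x, fixed = TRUE)
    }
    tab$atom_a <- f(tab$atom_a)
    tab$atom_b <- f(tab$atom_b)
    tab
  }
  hb_rel <- load_contact_table(relabel(braco19_contacts()))
  expect_equal(glance(mediation_summary(hb_rel)),
               glance(mediation_summary(hb_b)))
})

test_that("waters per quadruplex normalization", {
  expect_equal(waters_per_quadruplex(158, 2)$per_gq, 79L)
  expect_equal(waters_per_quadruplex(51, 1)$per_gq, 51L)
  expect_equal(waters_per_quadruplex(0, 3)$per_gq, 0L)
  expect_equal(waters_per_quadruplex(158, 2)$ratio, 79)
  expect_error(waters_per_quadruplex(10, 0), "gq_count")
})
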