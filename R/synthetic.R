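#' Specification for a synthetic quadruplex scene
#'
#' Describes a generated test scene: stacked planar quartets of
#' pseudo-guanines (real guanine atom names, so the built-in role tables
#' apply), perimeter phosphate oxygens, a ligand layer stacked 3.6 angstroms
#' above the top quartet with named basic nitrogens (NCH, NCA, NCE, NCG),
#' planted ligand-to-phosphate water bridges with consecutive hydrogen-bond
#' distances of `hbond_length` plus truncated Gaussian jitter, and decoy
#' waters placed at least `decoy_margin` beyond the detection cutoff from
#' every polar atom (and from each other). Every random draw comes from one
#' stream seeded by `seed`.
#'
#' Jitter on planted bond lengths is truncated so no planted edge exceeds
#' 3.2 angstroms: recovery of planted bridges under the default 3.25-angstrom
#' criteria is then guaranteed by construction, not by luck.
#'
#' @param n_quartets Number of stacked quartets (>= 1).
#' @param waters_per_bridge Waters per planted bridge chain (1-4).
#' @param n_bridges Number of planted bridges (0-4; one per groove azimuth).
#' @param n_decoy_waters Number of decoy (bulk-like) waters.
#' @param hbond_length Target donor-acceptor distance in angstroms
#'   (2.4-3.2).
#' @param jitter_sd Gaussian jitter scale in angstroms (>= 0).
#' @param b_factor_model Named list of `c(mean, sd)` per category
#'   (`nucleotide`, `ligand`, `water`); defaults reflect typical refined
#'   values for a quadruplex-ligand complex at ~2-angstrom resolution
#'   (side-chain ligand atoms ~51, bound waters ~30).
#' @param decoy_margin Extra clearance beyond the 3.25-angstrom cutoff for
#'   decoy placement (default 0.5).
#' @param seed Integer seed for the scene's single random stream.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(n_quartets = 3, waters_per_bridge = 2, n_bridges = 2,
                       n_decoy_waters = 10, hbond_length = 2.8,
                       jitter_sd = 0, b_factor_model = NULL,
                       decoy_margin = 0.5, seed = 1) {
  stopifnot(n_quartets >= 1, waters_per_bridge >= 1, waters_per_bridge <= 4,
            n_bridges >= 0, n_bridges <= 4, n_decoy_waters >= 0,
            hbond_length >= 2.4, hbond_length <= 3.2, jitter_sd >= 0,
            decoy_margin >= 0)
  default_b <- list(nucleotide = c(25, 5), ligand = c(51, 8),
                    water = c(30, 3))
  if (!is.null(b_factor_model)) default_b[names(b_factor_model)] <-
    b_factor_model
  structure(list(n_quartets = n_quartets,
                 waters_per_bridge = waters_per_bridge,
                 n_bridges = n_bridges, n_decoy_waters = n_decoy_waters,
                 hbond_length = hbond_length, jitter_sd = jitter_sd,
                 b_factor_model = default_b, decoy_margin = decoy_margin,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Planar idealized guanine base: hexagon (N1 C2 N3 C4 C5 C6) fused with a
# pentagon (C4 N9 C8 N7 C5) plus exocyclic N2 and O6; bond length 1.39 A.
guanine_template <- function() {
  r6 <- 1.39
  ang6 <- c(N1 = 90, C2 = 150, N3 = 210, C4 = 270, C5 = 330, C6 = 30)
  hex <- t(vapply(ang6, function(a) {
    r6 * c(cos(a * pi / 180), sin(a * pi / 180), 0)
  }, numeric(3)))
  mid <- (hex["C4", ] + hex["C5", ]) / 2
  apo <- (r6 / 2) / tan(36 * pi / 180)
  pc <- mid + apo * mid / sqrt(sum(mid^2))
  r5 <- r6 / (2 * sin(36 * pi / 180))
  a4 <- atan2(hex["C4", 2] - pc[2], hex["C4", 1] - pc[1])
  a5 <- atan2(hex["C5", 2] - pc[2], hex["C5", 1] - pc[1])
  step <- 72 * pi / 180
  dirn <- if (sin(a5 - a4) > 0) -1 else 1  # continue past C4, away from C5
  penta <- t(vapply(1:3, function(i) {
    a <- a4 + dirn * i * step
    pc + r5 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  rownames(penta) <- c("N9", "C8", "N7")
  exo <- rbind(
    N2 = hex["C2", ] * (1 + 1.35 / r6),
    O6 = hex["C6", ] * (1 + 1.23 / r6))
  rbind(hex, penta, exo)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

trunc_norm1 <- function(sd, cap) {
  if (sd == 0) return(0)
  max(-cap, min(cap, rnorm(1, 0, sd)))
}

#' Generate a ground-truthed synthetic scene
#'
#' Deterministic given `spec$seed`. Quartets are stacked 3.4 angstroms apart;
#' each planted bridge runs from a ligand nitrogen up a steep chain of waters
#' to a phosphate oxygen anchor, with consecutive distances equal to
#' `hbond_length` plus truncated jitter and chain geometry chosen so the
#' ligand-donor angle criterion is satisfied. Decoy waters are rejected until
#' they clear `3.25 + decoy_margin` angstroms from every polar atom and
#' every other decoy; placement failure after bounded retries is an error
#' naming the constraint.
#'
#' @param spec A [scene_spec].
#' @return Object of class `gq_scene`: `structure` (a [gq_structure] with
#'   ligand code `LIG`), `truth` (list of tibbles: `bridges`, `clusters`,
#'   `shells`, `b_factors`), and `spec`.
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(n_bridges = 1, waters_per_bridge = 2,
#'                                 n_decoy_waters = 0, seed = 7))
#' sc$truth$bridges
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    tmpl <- guanine_template()
    z_top <- 3.4 * (spec$n_quartets - 1)
    radius <- 4.5

    atoms <- list()
    add <- function(atom, resid, resno, pos, record = "ATOM",
                    element = substr(atom, 1, 1)) {
      atoms[[length(atoms) + 1]] <<- tibble::tibble(
        record = record, atom = atom, resid = resid, resno = resno,
        chain = "A", x = pos[1], y = pos[2], z = pos[3],
        occupancy = 1, b = 0, altloc = "", element = element)
    }

    # quartet guanines with perimeter backbone oxygens
    for (q in seq_len(spec$n_quartets)) {
      zq <- 3.4 * (q - 1)
      for (j in 1:4) {
        resno <- (q - 1) * 4 + j
        theta <- (j - 1) * pi / 2
        base <- tmpl %*% t(rot_z(theta))
        base <- sweep(base, 2, radius * c(cos(theta), sin(theta), 0) +
                        c(0, 0, zq), `+`)
        for (nm in rownames(tmpl)) add(nm, "DG", resno, base[nm, ])
        perim <- function(name, dth, rr, dz) {
          add(name, "DG", resno,
              c(rr * cos(theta + dth), rr * sin(theta + dth), zq + dz))
        }
        perim("OP1", -10 * pi / 180, 9.0, 0.8)
        perim("OP2", 10 * pi / 180, 9.0, 0)
        perim("O4'", 25 * pi / 180, 8.0, 0.4)
        perim("O5'", -25 * pi / 180, 8.5, -0.5)
      }
    }

    # ligand layer: core carbon plus one basic nitrogen per planted bridge
    z_lig <- z_top + 3.6
    add("C1", "LIG", 101, c(0, 0, z_lig), record = "HETATM", element = "C")
    bridge_names <- c("NCH", "NCA", "NCE", "NCG")
    lig_pos <- list()
    for (b in seq_len(spec$n_bridges)) {
      theta <- (b - 1) * pi / 2
      pos <- c(3.5 * cos(theta), 3.5 * sin(theta), z_lig)
      add(bridge_names[b], "LIG", 101, pos, record = "HETATM",
          element = "N")
      lig_pos[[b]] <- pos
    }

    # planted bridges: steep chains so angle(C1, N, w1) = 109.5 degrees
    k <- spec$waters_per_bridge
    phi <- 70.5 * pi / 180
    len_cap <- min(2.5 * max(spec$jitter_sd, 1e-9),
                   3.2 - spec$hbond_length, spec$hbond_length - 2.4)
    wat_resno <- 200
    truth_bridges <- list()
    truth_shells <- list()
    truth_clusters <- list()
    anchor_pos <- list()
    for (b in seq_len(spec$n_bridges)) {
      theta <- (b - 1) * pi / 2
      radial <- c(cos(theta), sin(theta), 0)
      pos <- lig_pos[[b]]
      chain_labels <- character(k)
      for (i in seq_len(k)) {
        dir <- cos(phi) * radial + sin(phi) * c(0, 0, 1)
        if (spec$jitter_sd > 0) {
          tang <- c(-sin(theta), cos(theta), 0)
          bend <- trunc_norm1(spec$jitter_sd / spec$hbond_length, 0.12)
          dir <- dir + bend * tang
          dir <- dir / sqrt(sum(dir^2))
        }
        d <- spec$hbond_length + trunc_norm1(spec$jitter_sd, len_cap)
        pos <- pos + d * dir
        wat_resno <- wat_resno + 1
        add("O", "HOH", wat_resno, pos, record = "HETATM", element = "O")
        chain_labels[i] <- paste0("W", wat_resno)
      }
      # anchor: the OP2 of the top-quartet residue in this groove azimuth
      anchor_resno <- (spec$n_quartets - 1) * 4 + b
      d <- spec$hbond_length + trunc_norm1(spec$jitter_sd, len_cap)
      apos <- pos + d * (cos(phi) * radial + sin(phi) * c(0, 0, 1))
      anchor_pos[[b]] <- list(resno = anchor_resno, pos = apos)
      anchor_label <- paste0("OP2 dG", anchor_resno)
      lig_label <- bridge_names[b]
      truth_bridges[[b]] <- tibble::tibble(
        ligand_atom = lig_label,
        waters = paste(chain_labels, collapse = " -> "),
        water_list = list(chain_labels),
        dna_atom = anchor_label, k = k)
      shell <- rep("second", k)
      shell[1] <- "first"
      shell[k] <- "first"
      truth_shells[[b]] <- tibble::tibble(water = chain_labels,
                                          shell = shell)
      truth_clusters[[b]] <- tibble::tibble(
        members = list(sort(chain_labels)),
        anchors = list(sort(c(lig_label, anchor_label))),
        size = k)
    }

    atoms_tbl <- dplyr::bind_rows(atoms)
    # relocate anchor OP2 atoms to the chain ends
    for (a in anchor_pos) {
      sel <- atoms_tbl$resid == "DG" & atoms_tbl$resno == a$resno &
        atoms_tbl$atom == "OP2"
      atoms_tbl$x[sel] <- a$pos[1]
      atoms_tbl$y[sel] <- a$pos[2]
      atoms_tbl$z[sel] <- a$pos[3]
    }

    # decoy waters: clear of all polar atoms and of each other
    clearance <- 3.25 + spec$decoy_margin
    xyz <- as.matrix(atoms_tbl[, c("x", "y", "z")])
    decoy_labels <- character(spec$n_decoy_waters)
    for (i in seq_len(spec$n_decoy_waters)) {
      placed <- FALSE
      for (try in 1:500) {
        cand <- c(runif(1, -18, 18), runif(1, -18, 18),
                  runif(1, -6, z_top + 18))
        if (min(sqrt(rowSums(sweep(xyz, 2, cand)^2))) >= clearance) {
          wat_resno <- wat_resno + 1
          atoms_tbl <- dplyr::bind_rows(atoms_tbl, tibble::tibble(
            record = "HETATM", atom = "O", resid = "HOH",
            resno = wat_resno, chain = "A", x = cand[1], y = cand[2],
            z = cand[3], occupancy = 1, b = 0, altloc = "",
            element = "O"))
          decoy_labels[i] <- paste0("W", wat_resno)
          xyz <- rbind(xyz, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("could not place decoy water ", i, " at >= ",
                     clearance, " Å from all atoms after 500 tries"))
      }
    }

    # B factors from the per-category model
    st <- gq_structure(atoms_tbl, id = paste0("scene", spec$seed),
                       resolution = 1.95, source_format = "r",
                       ligand_codes = "LIG")
    bm <- spec$b_factor_model
    draw_b <- function(cat, n) {
      m <- bm[[cat]] %||% c(30, 5)
      pmax(1, rnorm(n, m[1], m[2]))
    }
    for (cat in unique(st$category)) {
      sel <- st$category == cat
      key <- if (cat %in% names(bm)) cat else "nucleotide"
      st$b[sel] <- round(draw_b(key, sum(sel)), 2)
    }

    truth <- list(
      bridges = if (length(truth_bridges) > 0) {
        dplyr::bind_rows(truth_bridges) |>
          dplyr::arrange(.data$ligand_atom)
      } else {
        empty_bridge_tbl()[, c("ligand_atom", "waters", "water_list",
                               "dna_atom", "k")]
      },
      clusters = dplyr::bind_rows(c(
        truth_clusters,
        lapply(decoy_labels, function(l) {
          tibble::tibble(members = list(l), anchors = list(character()),
                         size = 1L)
        }))),
      shells = dplyr::bind_rows(c(
        truth_shells,
        list(tibble::tibble(water = decoy_labels,
                            shell = rep("bulk-like",
                                        length(decoy_labels)))))) |>
        dplyr::arrange(.data$water),
      b_factors = tibble::tibble(label = st$label, b = st$b)
    )
    structure(list(structure = st, truth = truth, spec = spec),
              class = "gq_scene")
  })
}

#' @export
print.gq_scene <- function(x, ...) {
  cat(sprintf(paste0("<gq_scene> seed %d: %d quartets, %d bridge(s) of %d",
                     " water(s), %d decoy water(s)\n"),
              x$spec$seed, x$spec$n_quartets, x$spec$n_bridges,
              x$spec$waters_per_bridge, x$spec$n_decoy_waters))
  print(x$structure)
  invisible(x)
}

#' Residue correspondence between a scene and a derived copy
#'
#' Identity pairing of the quartet guanines, ready for [fit_quartets()].
#'
#' @param scene A `gq_scene`.
#' @return Correspondence tibble (`chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`).
#' @export
scene_correspondence <- function(scene) {
  resnos <- sort(unique(scene$structure$resno[
    scene$structure$resid == "DG"]))
  tibble::tibble(chain_a = "A", resno_a = resnos,
                 chain_b = "A", resno_b = resnos)
}

#' Derive a "native" copy of a scene
#'
#' Emulates the comparison of a ligand-bound structure with its native
#' (ligand-free) counterpart: the quadruplex atoms are moved by a rigid
#' transform, a fraction of the waters is carried over (with jitter whose
#' norm is capped at `max_displacement` so every conserved pair stays
#' inside the default 1.0-angstrom conservation threshold), the ligand is
#' dropped, and fresh decoy waters are added. Fresh decoys keep at least
#' 1.5 angstroms from the mapped position of every original water, so no
#' spurious conserved pair can arise and the truth pairing is exact.
#'
#' @param scene A `gq_scene` from [generate_scene()].
#' @param rotation 3x3 rotation matrix (default: 25 degrees about z).
#' @param translation Length-3 translation in angstroms.
#' @param conserved_fraction Fraction of waters carried into the copy
#'   (rounded to a count).
#' @param jitter_sd Per-coordinate Gaussian jitter of conserved waters.
#' @param n_fresh_decoys Fresh decoy waters in the copy.
#' @param max_displacement Cap on the conserved-water jitter norm.
#' @param seed Seed for the copy's random stream (default `spec$seed + 1`).
#' @return Object of class `gq_scene_pair`: `native` (a [gq_structure]),
#'   `conserved` (truth tibble `water_a`, `water_b`, `displacement`),
#'   `correspondence`, and the applied `rotation`/`translation`.
#' @export
derive_native_copy <- function(scene, rotation = NULL, translation = c(5, -3, 2),
                               conserved_fraction = 1, jitter_sd = 0,
                               n_fresh_decoys = 0, max_displacement = 0.9,
                               seed = scene$spec$seed + 1L) {
  stopifnot(conserved_fraction >= 0, conserved_fraction <= 1,
            jitter_sd >= 0)
  if (is.null(rotation)) rotation <- rot_z(25 * pi / 180)
  with_scene_seed(seed, {
    st <- scene$structure
    move <- function(m) sweep(m %*% rotation, 2, translation, `+`)

    dna <- st[st$category != "ligand" & st$category != "water", ]
    dxyz <- move(as.matrix(dna[, c("x", "y", "z")]))
    dna$x <- dxyz[, 1]; dna$y <- dxyz[, 2]; dna$z <- dxyz[, 3]

    wat <- st[st$category == "water", ]
    n_keep <- round(conserved_fraction * nrow(wat))
    keep <- if (n_keep > 0) sort(sample(seq_len(nrow(wat)), n_keep)) else
      integer()
    wxyz_all <- move(as.matrix(wat[, c("x", "y", "z")]))

    conserved_rows <- list()
    new_wat <- list()
    resno <- 500
    for (idx in keep) {
      jit <- rnorm(3, 0, jitter_sd)
      nj <- sqrt(sum(jit^2))
      if (nj > max_displacement) jit <- jit * max_displacement / nj
      resno <- resno + 1
      pos <- wxyz_all[idx, ] + jit
      new_wat[[length(new_wat) + 1]] <- tibble::tibble(
        record = "HETATM", atom = "O", resid = "HOH", resno = resno,
        chain = "A", x = pos[1], y = pos[2], z = pos[3],
        occupancy = 1, b = wat$b[idx], altloc = "", element = "O")
      conserved_rows[[length(conserved_rows) + 1]] <- tibble::tibble(
        water_a = wat$label[idx], water_b = paste0("W", resno),
        displacement = sqrt(sum(jit^2)))
    }

    occupied <- rbind(dxyz,
                      if (length(new_wat) > 0) {
                        as.matrix(dplyr::bind_rows(new_wat)[, c("x", "y",
                                                                "z")])
                      })
    for (i in seq_len(n_fresh_decoys)) {
      placed <- FALSE
      for (try in 1:500) {
        cand <- c(runif(1, -18, 18), runif(1, -18, 18), runif(1, -6, 25))
        cand <- as.numeric(cand %*% rotation + translation)
        ok <- min(sqrt(rowSums(sweep(occupied, 2, cand)^2))) >= 3.75 &&
          min(sqrt(rowSums(sweep(wxyz_all, 2, cand)^2))) >= 1.5
        if (ok) {
          resno <- resno + 1
          new_wat[[length(new_wat) + 1]] <- tibble::tibble(
            record = "HETATM", atom = "O", resid = "HOH", resno = resno,
            chain = "A", x = cand[1], y = cand[2], z = cand[3],
            occupancy = 1, b = round(pmax(1, rnorm(1, 30, 3)), 2),
            altloc = "", element = "O")
          occupied <- rbind(occupied, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("could not place fresh decoy ", i,
                     " clear of native atoms and mapped waters"))
      }
    }

    native <- gq_structure(
      dplyr::bind_rows(c(list(tibble::as_tibble(dna)[,
        c("record", "atom", "resid", "resno", "chain", "x", "y", "z",
          "occupancy", "b", "altloc", "element")]), new_wat)),
      id = paste0(structure_id(st), "_native"),
      resolution = structure_resolution(st), source_format = "r")

    structure(list(
      native = native,
      conserved = if (length(conserved_rows) > 0) {
        dplyr::bind_rows(conserved_rows)
      } else {
        tibble::tibble(water_a = character(), water_b = character(),
                       displacement = numeric())
      },
      correspondence = scene_correspondence(scene),
      rotation = rotation, translation = translation),
      class = "gq_scene_pair")
  })
}
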