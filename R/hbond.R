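#' Hydrogen-bond acceptance criteria
#'
#' Geometric rules for accepting a donor-acceptor contact: a distance cutoff
#' and an angular-deviation cutoff from ideality. Because the crystal
#' structures this package targets contain no hydrogens, three angle modes are
#' offered:
#'
#' * `"antecedent_proxy"` (default): accept when the angle
#'   antecedent-donor-acceptor lies within `max_angle_deviation` of the ideal
#'   angle for the donor's hybridization (sp2: 120 degrees, sp3: 109.5).
#' * `"ideal_hydrogen"`: place an idealized hydrogen 1.0 angstrom from the
#'   donor, coplanar with antecedent/donor/acceptor at the ideal
#'   antecedent-donor-hydrogen angle on the acceptor's side, and require the
#'   donor-hydrogen...acceptor angle to deviate no more than
#'   `max_angle_deviation` from linearity.
#' * `"distance_only"`: no angle test.
#'
#' Water donors (and any donor without a configured antecedent) are exempt
#' from the angle test: waters are free rotors.
#'
#' The `"published"` preset (`max_distance = 3.45`, `distance_only`) reproduces
#' the published contact tables packaged with this package, which list
#' contacts out to 3.4 angstroms; the default preset applies the stricter
#' 3.25-angstrom screening rule.
#'
#' @param max_distance Donor-acceptor distance cutoff in angstroms.
#' @param max_angle_deviation Maximum deviation from ideality, degrees.
#' @param angle_mode One of `"antecedent_proxy"`, `"ideal_hydrogen"`,
#'   `"distance_only"`.
#' @param preset `NULL`, `"default"`, or `"published"`; a preset overrides the
#'   other arguments.
#' @return An object of class `hbond_criteria`.
#' @export
#' @examples
#' hbond_criteria()
#' hbond_criteria(preset = "published")
hbond_criteria <- function(max_distance = 3.25, max_angle_deviation = 30,
                           angle_mode = c("antecedent_proxy", "ideal_hydrogen",
                                          "distance_only"),
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "published"))
    if (preset == "published") {
      return(hbond_criteria(max_distance = 3.45, angle_mode = "distance_only"))
    }
    return(hbond_criteria())
  }
  angle_mode <- match.arg(angle_mode)
  stopifnot(max_distance > 0,
            max_angle_deviation >= 0, max_angle_deviation <= 180)
  structure(list(max_distance = max_distance,
                 max_angle_deviation = max_angle_deviation,
                 angle_mode = angle_mode),
            class = "hbond_criteria")
}

#' @export
print.hbond_criteria <- function(x, ...) {
  cat(sprintf("<hbond_criteria> d <= %.2f Å, angle mode %s",
              x$max_distance, x$angle_mode))
  if (x$angle_mode != "distance_only") {
    cat(sprintf(" (<= %g° from ideality)", x$max_angle_deviation))
  }
  cat("\n")
  invisible(x)
}

# Built-in donor/acceptor chemistry for DNA bases, backbone and water.
# Antecedents are heavy atoms bonded to the donor, used for angle geometry.
.base_role_table <- local({
  row <- function(resid, atom, role, hybrid, ante) {
    tibble::tibble(resid = resid, atom = atom, role = role,
                   hybrid = hybrid, antecedents = list(ante))
  }
  dplyr::bind_rows(
    # guanine: N1 imino and N2 amino donors; O6, N3, N7 acceptors
    row("DG", "N1", "donor", "sp2", c("C2", "C6")),
    row("DG", "N2", "donor", "sp2", "C2"),
    row("DG", "O6", "acceptor", "sp2", "C6"),
    row("DG", "N3", "acceptor", "sp2", character()),
    row("DG", "N7", "acceptor", "sp2", character()),
    # adenine
    row("DA", "N6", "donor", "sp2", "C6"),
    row("DA", "N1", "acceptor", "sp2", character()),
    row("DA", "N3", "acceptor", "sp2", character()),
    row("DA", "N7", "acceptor", "sp2", character()),
    # thymine: N3 imino donor; O2, O4 acceptors
    row("DT", "N3", "donor", "sp2", c("C2", "C4")),
    row("DT", "O2", "acceptor", "sp2", "C2"),
    row("DT", "O4", "acceptor", "sp2", "C4"),
    # cytosine
    row("DC", "N4", "donor", "sp2", "C4"),
    row("DC", "O2", "acceptor", "sp2", "C2"),
    row("DC", "N3", "acceptor", "sp2", character())
  )
})
.backbone_acceptors <- c("OP1", "OP2", "O4'", "O5'", "O3'")

normalize_nuc <- function(resid) {
  out <- toupper(resid)
  map <- c(G = "DG", GUA = "DG", A = "DA", ADE = "DA", T = "DT",
           THY = "DT", U = "DT", DU = "DT", C = "DC", CYT = "DC")
  hit <- out %in% names(map)
  out[hit] <- unname(map[out[hit]])
  out
}

#' Assign donor/acceptor roles to the atoms of a structure
#'
#' Built-in tables cover the DNA bases (guanine N1/N2 donors and O6/N3/N7
#' acceptors, the thymine O2/O4 acceptors and N3 donor, and so on), the
#' backbone oxygens (OP1/OP2/O4'/O5'/O3' as acceptors), and water (oxygen is
#' both donor and acceptor, with no antecedent). Ligand atoms receive roles
#' only through `overrides`; atoms without an entry get no role and are
#' ignored by detection. An override naming an atom absent from the structure
#' raises a warning, not an error.
#'
#' @param structure A [gq_structure].
#' @param overrides Tibble with columns `atom`, `role` (`"donor"`,
#'   `"acceptor"`, or `"both"`), and optionally `hybrid` (`"sp2"`/`"sp3"`) and
#'   `antecedents` (list column of atom names in the same residue). Applied to
#'   ligand and `other` category atoms by atom name.
#' @return Role tibble with one row per polar atom: `label`, `chain`, `resno`,
#'   `atom`, `category`, `role`, `hybrid`, `antecedents`.
#' @export
assign_roles <- function(structure, overrides = NULL) {
  atoms <- tibble::as_tibble(structure)

  nuc <- atoms |>
    dplyr::filter(.data$category == "nucleotide") |>
    dplyr::mutate(nresid = normalize_nuc(.data$resid))
  base_part <- nuc |>
    dplyr::inner_join(.base_role_table,
                      by = c(nresid = "resid", atom = "atom"))
  bb_part <- nuc |>
    dplyr::filter(.data$atom %in% .backbone_acceptors) |>
    dplyr::mutate(role = "acceptor", hybrid = "sp3",
                  antecedents = list(character()))

  water_part <- atoms |>
    dplyr::filter(.data$category == "water") |>
    dplyr::mutate(role = "both", hybrid = "sp3",
                  antecedents = list(character()))

  lig_part <- NULL
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    if (!"hybrid" %in% names(overrides)) overrides$hybrid <- "sp3"
    if (!"antecedents" %in% names(overrides)) {
      overrides$antecedents <- rep(list(character()), nrow(overrides))
    }
    cand <- atoms |> dplyr::filter(.data$category %in% c("ligand", "other"))
    absent <- setdiff(overrides$atom, cand$atom)
    if (length(absent) > 0) {
      warn(paste0("role overrides name atoms absent from the structure: ",
                  paste(absent, collapse = ", ")))
    }
    lig_part <- cand |>
      dplyr::inner_join(overrides, by = "atom")
  }

  out <- dplyr::bind_rows(
    base_part[, c("label", "chain", "resno", "atom", "category",
                  "role", "hybrid", "antecedents")],
    bb_part[, c("label", "chain", "resno", "atom", "category",
                "role", "hybrid", "antecedents")],
    water_part[, c("label", "chain", "resno", "atom", "category",
                   "role", "hybrid", "antecedents")],
    if (!is.null(lig_part)) {
      lig_part[, c("label", "chain", "resno", "atom", "category",
                   "role", "hybrid", "antecedents")]
    }
  )
  dplyr::distinct(out, .data$chain, .data$resno, .data$atom,
                  .keep_all = TRUE)
}

ideal_angle <- function(hybrid) ifelse(hybrid == "sp3", 109.5, 120)

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Angular deviation from ideality for a donor -> acceptor contact.
# Returns NA when the donor is exempt (water, or no antecedent available).
donor_angle_deviation <- function(mode, d_pos, a_pos, ante_pos_list, hybrid) {
  if (length(ante_pos_list) == 0) return(NA_real_)
  theta <- ideal_angle(hybrid)
  devs <- vapply(ante_pos_list, function(p) {
    beta <- vec_angle(p - d_pos, a_pos - d_pos)
    if (mode == "antecedent_proxy") {
      abs(beta - theta)
    } else {
      # ideal_hydrogen: H at 1.0 A from donor, in the (ante, D, A) plane at
      # the ideal angle from the antecedent, on the acceptor's side; report
      # the deviation of angle(D-H...A) from 180 degrees.
      u <- (p - d_pos) / sqrt(sum((p - d_pos)^2))
      w <- (a_pos - d_pos)
      w_perp <- w - sum(w * u) * u
      nw <- sqrt(sum(w_perp * w_perp))
      if (nw < 1e-9) {
        # acceptor collinear with the antecedent axis: H direction undetermined
        # around the cone; the achievable D-H...A deviation is |beta - theta|
        return(abs(vec_angle(p - d_pos, a_pos - d_pos) - theta))
      }
      w_perp <- w_perp / nw
      h <- d_pos + 1.0 * (cos(theta * pi / 180) * u +
                          sin(theta * pi / 180) * w_perp)
      180 - vec_angle(d_pos - h, a_pos - h)
    }
  }, numeric(1))
  min(devs)
}

#' Detect hydrogen bonds in a structure
#'
#' All donor-acceptor pairs (from [assign_roles()]) in different residues with
#' distance at or below the criteria cutoff, subject to the criteria's angle
#' mode. Results are identical to an exhaustive all-pairs search by contract.
#' Each accepted contact appears once as an unordered pair, categorized from
#' the endpoint residue categories (`ligand-water`, `water-water`,
#' `water-DNA`, `ligand-DNA`, `DNA-DNA`, `other`) and sorted by category then
#' distance.
#'
#' @param structure A [gq_structure].
#' @param roles Role tibble from [assign_roles()]; computed on the fly when
#'   `NULL`.
#' @param criteria An [hbond_criteria] object.
#' @param overrides Passed to [assign_roles()] when `roles` is `NULL`.
#' @return Tibble with columns `atom_a`, `atom_b` (display labels),
#'   `distance` (angstroms, full precision), `angle_dev` (degrees or `NA`),
#'   `category`, `category_a`, `category_b`, `b_a`, `b_b`, `group_label`.
#' @export
detect_hbonds <- function(structure, roles = NULL,
                          criteria = hbond_criteria(), overrides = NULL) {
  if (is.null(roles)) roles <- assign_roles(structure, overrides)
  atoms <- tibble::as_tibble(structure)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  roles$idx <- match(paste(roles$chain, roles$resno, roles$atom, sep = "\r"),
                     key)
  roles <- dplyr::filter(roles, !is.na(.data$idx))
  if (nrow(roles) == 0) return(empty_hbond_tbl())

  don <- roles[roles$role %in% c("donor", "both"), ]
  acc <- roles[roles$role %in% c("acceptor", "both"), ]
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty_hbond_tbl())

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dd <- xyz[don$idx, , drop = FALSE]
  aa <- xyz[acc$idx, , drop = FALSE]
  d2 <- outer(rowSums(dd^2), rep(1, nrow(aa))) +
    outer(rep(1, nrow(dd)), rowSums(aa^2)) - 2 * dd %*% t(aa)
  d2[d2 < 0] <- 0
  hits <- which(d2 <= criteria$max_distance^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_hbond_tbl())

  res_of <- paste(atoms$chain, atoms$resno, atoms$resid, sep = "\r")
  rows <- vector("list", nrow(hits))
  n_out <- 0L
  for (h in seq_len(nrow(hits))) {
    i <- hits[h, 1]; j <- hits[h, 2]
    di <- don$idx[i]; aj <- acc$idx[j]
    if (di == aj) next
    if (res_of[di] == res_of[aj]) next
    dev <- NA_real_
    if (criteria$angle_mode != "distance_only" &&
        don$category[i] != "water") {
      ante_names <- don$antecedents[[i]]
      ante_idx <- which(res_of == res_of[di] & atoms$atom %in% ante_names)
      ante_pos <- lapply(ante_idx, function(k) xyz[k, ])
      dev <- donor_angle_deviation(criteria$angle_mode, xyz[di, ], xyz[aj, ],
                                   ante_pos, don$hybrid[i])
      if (!is.na(dev) && dev > criteria$max_angle_deviation) next
    }
    n_out <- n_out + 1L
    dist_ij <- sqrt(d2[i, j])
    rows[[n_out]] <- tibble::tibble(
      i = di, j = aj, distance = dist_ij, angle_dev = dev)
  }
  if (n_out == 0L) return(empty_hbond_tbl())
  out <- dplyr::bind_rows(rows[seq_len(n_out)])

  # collapse to unordered pairs (a water pair can qualify in both directions)
  out <- out |>
    dplyr::mutate(lo = pmin(.data$i, .data$j), hi = pmax(.data$i, .data$j)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(
      distance = .data$distance[1],
      angle_dev = if (all(is.na(.data$angle_dev))) NA_real_ else
        min(.data$angle_dev, na.rm = TRUE),
      .groups = "drop")

  tibble::tibble(
    atom_a = atoms$label[out$lo],
    atom_b = atoms$label[out$hi],
    distance = out$distance,
    angle_dev = out$angle_dev,
    category_a = atoms$category[out$lo],
    category_b = atoms$category[out$hi],
    b_a = atoms$b[out$lo],
    b_b = atoms$b[out$hi],
    group_label = NA_character_
  ) |>
    dplyr::mutate(category = pair_category(.data$category_a,
                                           .data$category_b)) |>
    orient_hbonds() |>
    sort_hbonds()
}

.hbond_category_levels <- c("ligand-water", "water-water", "water-DNA",
                            "ligand-DNA", "DNA-DNA", "other")

pair_category <- function(ca, cb) {
  f <- function(a, b) {
    s <- sort(c(a, b))
    if (identical(s, c("ligand", "water"))) "ligand-water"
    else if (identical(s, c("water", "water"))) "water-water"
    else if (identical(s, c("nucleotide", "water"))) "water-DNA"
    else if (identical(s, c("ligand", "nucleotide"))) "ligand-DNA"
    else if (identical(s, c("nucleotide", "nucleotide"))) "DNA-DNA"
    else "other"
  }
  mapply(f, ca, cb, USE.NAMES = FALSE)
}

# canonical endpoint order within a bond row: ligand, then water, then DNA;
# same-category pairs sort lexicographically by label
.category_rank <- c(ligand = 1, water = 2, nucleotide = 3, ion = 4, other = 5)

orient_hbonds <- function(bonds) {
  if (nrow(bonds) == 0) return(bonds)
  ra <- unname(.category_rank[bonds$category_a])
  rb <- unname(.category_rank[bonds$category_b])
  swap <- rb < ra | (rb == ra & bonds$atom_b < bonds$atom_a)
  sw <- function(a, b) {
    list(unname(ifelse(swap, b, a)), unname(ifelse(swap, a, b)))
  }
  s1 <- sw(bonds$atom_a, bonds$atom_b)
  s2 <- sw(bonds$category_a, bonds$category_b)
  s3 <- sw(bonds$b_a, bonds$b_b)
  bonds$atom_a <- s1[[1]]; bonds$atom_b <- s1[[2]]
  bonds$category_a <- s2[[1]]; bonds$category_b <- s2[[2]]
  bonds$b_a <- s3[[1]]; bonds$b_b <- s3[[2]]
  bonds
}

sort_hbonds <- function(bonds) {
  bonds |>
    dplyr::mutate(.cat = factor(.data$category, .hbond_category_levels)) |>
    dplyr::arrange(.data$.cat, .data$distance, .data$atom_a, .data$atom_b) |>
    dplyr::select(-".cat")
}

empty_hbond_tbl <- function() {
  tibble::tibble(atom_a = character(), atom_b = character(),
                 distance = numeric(), angle_dev = numeric(),
                 category_a = character(), category_b = character(),
                 b_a = numeric(), b_b = numeric(),
                 group_label = character(), category = character())
}

classify_contact_label <- function(label, ligand_atoms) {
  lab <- trimws(label)
  dplyr::case_when(
    grepl("^W[0-9]+$", lab) ~ "water",
    grepl("\\s", lab) ~ "nucleotide",
    lab %in% ligand_atoms ~ "ligand",
    TRUE ~ NA_character_
  )
}

#' Load a printed hydrogen-bond contact table
#'
#' Reads an edge list in the layout of published quadruplex contact tables:
#' columns `atom_a`, `atom_b`, `distance_A`, optional `b_a`, `b_b`,
#' `group_label` (groove annotation). Endpoint categories are inferred from
#' the label conventions: `W` + number is a water (e.g. `W204`), a label with
#' a residue suffix is a DNA atom (e.g. `OP2 dG10`), and a bare atom name must
#' appear in `ligand_atoms` to classify as ligand. An unclassifiable label is
#' a record-level error naming the label.
#'
#' @param x A file path (TSV) or a data frame.
#' @param ligand_atoms Vocabulary of ligand atom names; defaults to the union
#'   of [mm41_atoms()] and [braco19_atoms()].
#' @return Hydrogen-bond tibble in the same layout as [detect_hbonds()].
#' @export
#' @examples
#' load_contact_table(braco19_contacts())
load_contact_table <- function(x,
                               ligand_atoms = c(mm41_atoms(),
                                                braco19_atoms())) {
  tab <- if (is.character(x) && length(x) == 1) {
    readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  if (nrow(tab) == 0) return(empty_hbond_tbl())
  stopifnot(all(c("atom_a", "atom_b", "distance_A") %in% names(tab)))
  if (!"b_a" %in% names(tab)) tab$b_a <- NA_real_
  if (!"b_b" %in% names(tab)) tab$b_b <- NA_real_
  if (!"group_label" %in% names(tab)) tab$group_label <- NA_character_

  ca <- classify_contact_label(tab$atom_a, ligand_atoms)
  cb <- classify_contact_label(tab$atom_b, ligand_atoms)
  bad <- unique(c(tab$atom_a[is.na(ca)], tab$atom_b[is.na(cb)]))
  if (length(bad) > 0) {
    abort(paste0("unclassifiable contact-table label(s): ",
                 paste(bad, collapse = ", "),
                 " (not water, not 'ATOM residue', not in ligand_atoms)"))
  }
  tibble::tibble(
    atom_a = trimws(tab$atom_a), atom_b = trimws(tab$atom_b),
    distance = as.numeric(tab$distance_A), angle_dev = NA_real_,
    category_a = ca, category_b = cb,
    b_a = as.numeric(tab$b_a), b_b = as.numeric(tab$b_b),
    group_label = as.character(tab$group_label)
  ) |>
    dplyr::mutate(category = pair_category(.data$category_a,
                                           .data$category_b)) |>
    orient_hbonds() |>
    sort_hbonds()
}

#' Packaged contact-table fixtures
#'
#' The hydrogen-bond tables for the two quadruplex-ligand complexes packaged
#' with gqwater, as tidy edge lists: `mm41_contacts()` is the MM41 naphthalene
#' diimide complex with a human intramolecular telomeric quadruplex (17
#' contacts across grooves 1-4, with per-atom B factors), and `braco19_contacts()` is
#' the BRACO19 acridine complex with a bimolecular telomeric quadruplex (14
#' contacts). Feed them to [load_contact_table()].
#'
#' @return Tibble with columns `group_label`, `atom_a`, `atom_b`,
#'   `distance_A`, `b_a`, `b_b`.
#' @export
#' @examples
#' load_contact_table(mm41_contacts())
mm41_contacts <- function() {
  readr::read_tsv(system.file("extdata", "mm41_3uyh_contacts.tsv",
                              package = "gqwater"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname mm41_contacts
#' @export
braco19_contacts <- function() {
  readr::read_tsv(system.file("extdata", "braco19_3ce5_contacts.tsv",
                              package = "gqwater"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write the packaged contact tables to a directory
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_contact_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "mm41_3uyh_contacts.tsv"),
             file.path(dir, "braco19_3ce5_contacts.tsv"))
  readr::write_tsv(mm41_contacts(), paths[1])
  readr::write_tsv(braco19_contacts(), paths[2])
  invisible(paths)
}
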