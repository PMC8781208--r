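#' Role overrides for common ligands and synthetic scenes
#'
#' Donor/acceptor assignments for ligand atoms, which are never guessed from
#' chemistry: `mm41_role_overrides()` marks the basic side-chain ring
#' nitrogens of the naphthalene diimide MM41 as donors (they are presumed
#' protonated at physiological pH) and the chromophore carbonyl oxygens as
#' acceptors; `scene_role_overrides()` covers the named basic nitrogens of
#' generated scenes (donors anteceded by the ligand core atom `C1`).
#'
#' @return Override tibble for [assign_roles()].
#' @export
mm41_role_overrides <- function() {
  tibble::tibble(
    atom = c("NCH", "NCA", "NCE", "NCG", "NCF", "OAF", "OAG", "ODX"),
    role = c(rep("donor", 5), rep("acceptor", 3)),
    hybrid = c(rep("sp3", 5), rep("sp2", 3)),
    antecedents = rep(list(character()), 8))
}

#' @rdname mm41_role_overrides
#' @param scene Optional `gq_scene`; when given, the override table is
#'   trimmed to the ligand atoms the scene actually contains.
#' @export
scene_role_overrides <- function(scene = NULL) {
  ov <- tibble::tibble(
    atom = c("NCH", "NCA", "NCE", "NCG"),
    role = "donor", hybrid = "sp3",
    antecedents = rep(list("C1"), 4))
  if (!is.null(scene)) {
    ov <- ov[ov$atom %in% scene$structure$atom, ]
  }
  ov
}

#' Run the full contact analysis on one structure
#'
#' Detects hydrogen bonds, applies the structure acceptance filter, builds
#' the contact network, and reports bridges, water clusters, shell labels,
#' the direct-versus-mediated summary, and mobility statistics. This is the
#' end-to-end per-structure pipeline; [analyze_contacts()] runs the same
#' network stages on a pre-tabulated contact list.
#'
#' @param structure A [gq_structure] (ligand residues flagged via
#'   `ligand_codes` at read time).
#' @param criteria An [hbond_criteria]; `preset = "published"` relaxes to the
#'   published-table conventions.
#' @param overrides Role overrides for ligand atoms (see
#'   [mm41_role_overrides()]).
#' @param max_waters Bridge search depth.
#' @param max_resolution,require_ligand_contacting_water Acceptance filter
#'   settings.
#' @param mobility_groups Optional named list of atom-label vectors; each
#'   gets a [group_mobility()] row.
#' @return List of class `gq_report`: `structure_id`, `acceptance`,
#'   `hbonds`, `bridges`, `clusters`, `shells`, `mediation` (or `NULL` when
#'   the structure has no ligand atoms in the bond set), `mobility`.
#' @export
analyze_structure <- function(structure, criteria = hbond_criteria(),
                              overrides = NULL, max_waters = 4,
                              max_resolution = 2.5,
                              require_ligand_contacting_water = TRUE,
                              mobility_groups = NULL) {
  hb <- detect_hbonds(structure, criteria = criteria, overrides = overrides)
  acc <- accept_structure(structure, hb, max_resolution = max_resolution,
                          require_ligand_contacting_water =
                            require_ligand_contacting_water)
  waters <- structure$label[structure$category == "water"]
  med <- if (any(c(hb$category_a, hb$category_b) == "ligand")) {
    mediation_summary(hb, max_waters = max_waters)
  } else {
    NULL
  }
  mob <- list(
    by_category = group_mobility(structure, b = "b", group = "category"))
  if (!is.null(mobility_groups)) {
    mob$by_group <- purrr::imap_dfr(mobility_groups, function(labels, nm) {
      rows <- structure[structure$label %in% labels, ]
      dplyr::bind_cols(tibble::tibble(group = nm),
                       group_mobility(rows, b = "b"))
    })
  }
  structure(list(
    structure_id = structure_id(structure),
    acceptance = acc,
    hbonds = hb,
    bridges = find_bridges(hb, max_waters = max_waters),
    clusters = water_clusters(hb, waters = waters),
    shells = classify_shells(hb, waters = waters),
    mediation = med,
    mobility = mob), class = "gq_report")
}

#' Run the network stages on a printed contact table
#'
#' @param hbonds Hydrogen-bond tibble, e.g. from [load_contact_table()].
#' @param max_waters Bridge search depth.
#' @return A `gq_report` (without structure-level acceptance or mobility by
#'   category; mobility is computed over the table's per-atom B factors).
#' @export
#' @examples
#' rep <- analyze_contacts(load_contact_table(braco19_contacts()))
#' glance(rep$mediation)
analyze_contacts <- function(hbonds, max_waters = 4) {
  atoms <- tibble::tibble(
    label = c(hbonds$atom_a, hbonds$atom_b),
    category = c(hbonds$category_a, hbonds$category_b),
    b = c(hbonds$b_a, hbonds$b_b)) |>
    dplyr::distinct(.data$label, .keep_all = TRUE)
  mob <- if (all(!is.na(atoms$b))) {
    list(by_category = group_mobility(atoms, b = "b", group = "category"))
  } else {
    list()
  }
  med <- if (any(atoms$category == "ligand")) {
    mediation_summary(hbonds, max_waters = max_waters)
  } else {
    NULL
  }
  structure(list(
    structure_id = NA_character_,
    acceptance = NULL,
    hbonds = hbonds,
    bridges = find_bridges(hbonds, max_waters = max_waters),
    clusters = water_clusters(hbonds),
    shells = classify_shells(hbonds),
    mediation = med,
    mobility = mob), class = "gq_report")
}

#' @export
print.gq_report <- function(x, ...) {
  cat(sprintf("<gq_report> %s\n",
              if (is.na(x$structure_id %||% NA)) "(contact table)" else
                x$structure_id))
  if (!is.null(x$acceptance)) {
    cat(sprintf("  acceptance: %s (%s)\n",
                ifelse(x$acceptance$accepted, "accepted", "rejected"),
                x$acceptance$reason))
  }
  cat(sprintf("  %d hydrogen bond(s), %d bridge path(s), %d water cluster(s)\n",
              nrow(x$hbonds), nrow(x$bridges), nrow(x$clusters)))
  if (!is.null(x$mediation)) print(x$mediation$summary)
  invisible(x)
}

#' Format a hydrogen-bond tibble in the published table layout
#'
#' Distances to one decimal place and B factors to integers, the precision
#' conventions of printed contact tables.
#'
#' @param hbonds Hydrogen-bond tibble.
#' @return Tibble with `group_label`, `atom_1`, `atom_2`, `d_1_2`,
#'   `b_factor_1`, `b_factor_2`, `category`.
#' @export
format_contact_table <- function(hbonds) {
  tibble::tibble(
    group_label = hbonds$group_label,
    atom_1 = hbonds$atom_a,
    atom_2 = hbonds$atom_b,
    d_1_2 = round(hbonds$distance, 1),
    b_factor_1 = round(hbonds$b_a),
    b_factor_2 = round(hbonds$b_b),
    category = hbonds$category)
}

#' Write a report bundle to disk
#'
#' Emits the hydrogen-bond table (published layout), bridge table, cluster
#' table, shell labels and mobility summaries as TSV, and the mediation
#' summary plus acceptance decision as JSON. Output is byte-stable across
#' repeated runs on the same inputs.
#'
#' @param report A `gq_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(format_contact_table(report$hbonds),
                   file.path(dir, "hbonds.tsv"))
  readr::write_tsv(dplyr::select(report$bridges, -"water_list"),
                   file.path(dir, "bridges.tsv"))
  readr::write_tsv(dplyr::select(report$clusters, -"members", -"anchors"),
                   file.path(dir, "clusters.tsv"))
  readr::write_tsv(report$shells, file.path(dir, "shells.tsv"))
  if (!is.null(report$mobility$by_category)) {
    readr::write_tsv(format_mobility(report$mobility$by_category),
                     file.path(dir, "mobility.tsv"))
  }
  summary <- list(structure_id = report$structure_id)
  if (!is.null(report$acceptance)) {
    summary$acceptance <- as.list(report$acceptance)
  }
  if (!is.null(report$mediation)) {
    summary$mediation <- as.list(report$mediation$summary)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Compare two structures: quartet superposition and conserved waters
#'
#' Superposes `a` onto `b` on the quartet guanines of an explicit residue
#' correspondence, then pairs waters that occupy the same site within
#' `threshold` angstroms.
#'
#' @param a,b [gq_structure] objects.
#' @param correspondence Guanine residue correspondence (see
#'   [fit_quartets()]).
#' @param threshold Conservation distance threshold in angstroms.
#' @param method Matching method, see [match_conserved_waters()].
#' @param atoms Fitting atom names.
#' @return List of class `gq_comparison`: `superposition`, `conserved`
#'   (pair tibble), `counts` (one-row tibble with `rmsd`, `n_fit_atoms`,
#'   `n_waters_a`, `n_waters_b`, `n_conserved`).
#' @export
compare_structures <- function(a, b, correspondence, threshold = 1.0,
                               method = "mutual",
                               atoms = guanine_base_atoms()) {
  fit <- fit_quartets(a, b, correspondence, atoms = atoms)
  pairs <- match_conserved_waters(a, b, fit, threshold = threshold,
                                  method = method)
  counts <- tibble::tibble(
    rmsd = fit$rmsd, n_fit_atoms = fit$n_atoms,
    n_waters_a = sum(a$category == "water"),
    n_waters_b = sum(b$category == "water"),
    n_conserved = nrow(pairs))
  structure(list(superposition = fit, conserved = pairs, counts = counts),
            class = "gq_comparison")
}

#' @export
print.gq_comparison <- function(x, ...) {
  cat(sprintf(paste0("<gq_comparison> rmsd %.3f Å over %d atoms; ",
                     "%d conserved water pair(s)\n"),
              x$counts$rmsd, x$counts$n_fit_atoms, x$counts$n_conserved))
  invisible(x)
}

#' @export
#' @method glance gq_comparison
glance.gq_comparison <- function(x, ...) x$counts

#' @export
#' @method tidy gq_comparison
tidy.gq_comparison <- function(x, ...) x$conserved
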