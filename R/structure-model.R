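#' Crystal-structure atom tables
#'
#' A `gq_structure` is a tibble with one row per non-hydrogen atom (hydrogens
#' are parsed but excluded from analysis by default) and the columns
#' `record`, `atom`, `altloc`, `resid`, `chain`, `resno`, `x`, `y`, `z`,
#' `occupancy`, `b`, `element`, `category`, `label`. The structure-level
#' metadata (accession/label, resolution in angstroms, source format) travels
#' in attributes, readable with [structure_id()] and [structure_resolution()].
#'
#' `category` is assigned deterministically from the residue code: `water`
#' for the configured water codes (default HOH/WAT/DOD), `ligand` for codes in
#' `ligand_codes`, `nucleotide` for standard DNA/RNA codes, `ion` for common
#' monatomic ions, otherwise `other`. `label` follows the display conventions
#' of quadruplex crystallography papers: waters are `"W<seq>"` (e.g. `W204`),
#' nucleotide atoms are `"<atom> <residue><seq>"` (e.g. `"OP2 dG10"`), and
#' ligand atoms are the bare atom name (e.g. `"NCH"`).
#'
#' @param atoms Data frame with the atom columns listed above (minus
#'   `category`/`label`, which are derived).
#' @param id Structure identifier (accession or user label).
#' @param resolution Resolution in angstroms, or `NA` if unknown.
#' @param source_format `"pdb"`, `"cif"`, or `"r"` for in-memory structures.
#' @param ligand_codes Residue codes to categorize as ligand.
#' @param water_codes Residue codes to categorize as water.
#' @return A `gq_structure` tibble.
#' @export
gq_structure <- function(atoms, id = "structure", resolution = NA_real_,
                         source_format = "r",
                         ligand_codes = character(),
                         water_codes = .water_codes_default) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("atom", "resid", "chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[^A-Za-z].*$", "", atoms$atom), 1, 1)
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  if (any(atoms$b < 0, na.rm = TRUE)) abort("negative B factor in atom table")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    abort("occupancy outside [0, 1] in atom table")
  }
  atoms$category <- categorize_residue(atoms$resid, ligand_codes, water_codes)
  atoms$label <- atom_label(atoms$atom, atoms$resid, atoms$resno,
                            atoms$category)
  atoms <- atoms[, c("record", "atom", "altloc", "resid", "chain", "resno",
                     "x", "y", "z", "occupancy", "b", "element",
                     "category", "label")]
  bad_water <- atoms |>
    dplyr::filter(.data$category == "water",
                  !grepl("^H", .data$element)) |>
    dplyr::count(.data$chain, .data$resno) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_water) > 0) {
    abort("water residue with more than one heavy atom (check water codes)")
  }
  structure(atoms,
            class = c("gq_structure", class(tibble::tibble())),
            gq_id = id,
            gq_resolution = as.numeric(resolution),
            gq_source_format = source_format)
}

categorize_residue <- function(resid, ligand_codes, water_codes) {
  resid <- toupper(trimws(resid))
  dplyr::case_when(
    resid %in% toupper(water_codes) ~ "water",
    resid %in% toupper(ligand_codes) ~ "ligand",
    resid %in% .nucleotide_codes ~ "nucleotide",
    resid %in% .ion_codes ~ "ion",
    TRUE ~ "other"
  )
}

residue_display <- function(resid) {
  # "DG" -> "dG" per the W204 / dG10 display convention; others unchanged
  ifelse(nchar(resid) == 2 & substr(resid, 1, 1) == "D",
         paste0("d", substr(resid, 2, 2)), resid)
}

atom_label <- function(atom, resid, resno, category) {
  dplyr::case_when(
    category == "water" ~ paste0("W", resno),
    category == "ligand" ~ atom,
    TRUE ~ paste(atom, paste0(residue_display(resid), resno))
  )
}

#' @rdname gq_structure
#' @param structure A `gq_structure`.
#' @export
structure_id <- function(structure) attr(structure, "gq_id")

#' @rdname gq_structure
#' @export
structure_resolution <- function(structure) attr(structure, "gq_resolution")

#' @export
print.gq_structure <- function(x, ...) {
  res <- structure_resolution(x)
  cat(sprintf("<gq_structure> %s  (%s, resolution %s Å)\n",
              structure_id(x), attr(x, "gq_source_format"),
              if (is.na(res)) "unknown" else format(res)))
  cat(sprintf("  %d atoms; residues: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$category)),
                            as.integer(table(x$category))), collapse = " ")))
  NextMethod()
}

#' Read a crystal structure from a PDB or mmCIF file
#'
#' Parses coordinates with bio3d, resolves alternate locations (the
#' highest-occupancy conformer is kept; ties go to the alphabetically first
#' altloc code), uses model 1 only for multi-model files, and extracts the
#' resolution from `REMARK 2` (PDB) or `_refine.ls_d_res_high` /
#' `_reflns.d_resolution_high` (mmCIF). Hydrogens are dropped unless
#' `keep_hydrogens = TRUE`; crystal structures at the resolutions this package
#' targets do not resolve them.
#'
#' @param path File path.
#' @param ligand_codes Residue codes flagged as ligand (explicit list, never
#'   guessed from chemistry).
#' @param water_codes Residue codes flagged as water.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param keep_hydrogens Keep hydrogen atoms in the table.
#' @return A [gq_structure] tibble.
#' @export
read_structure <- function(path, ligand_codes = character(),
                           water_codes = .water_codes_default,
                           format = c("auto", "pdb", "cif"),
                           keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      abort(paste0("could not parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(paste0("empty structure: no ATOM/HETATM records in ", path))
  }
  atoms <- tibble::tibble(
    record = at$type,
    atom = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                            substr(gsub("[^A-Za-z].*$", "", trimws(at$elety)),
                                   1, 1),
                            at$elesy))
  )
  atoms <- resolve_altloc(atoms)
  if (!keep_hydrogens) {
    atoms <- dplyr::filter(atoms, toupper(.data$element) != "H",
                           toupper(.data$element) != "D")
  }
  if (nrow(atoms) == 0) abort(paste0("empty structure after filtering: ", path))
  gq_structure(atoms,
               id = sub("\\.(pdb|ent|cif)$", "", basename(path),
                        ignore.case = TRUE),
               resolution = parse_resolution(path, format),
               source_format = format,
               ligand_codes = ligand_codes, water_codes = water_codes)
}

# Keep the highest-occupancy conformer per (chain, resno, resid, atom);
# ties break to the alphabetically first altloc code.
resolve_altloc <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(altloc = "")
}

parse_resolution <- function(path, format) {
  lines <- tryCatch(readLines(path, n = 2000, warn = FALSE),
                    error = function(e) character())
  if (format == "pdb") {
    hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(hit) > 0) {
      m <- regmatches(hit[1],
                      regexpr("(?<=RESOLUTION\\.)\\s*[0-9]+\\.?[0-9]*",
                              hit[1], perl = TRUE))
      if (length(m) > 0 && nzchar(trimws(m))) {
        return(as.numeric(trimws(m)))
      }
    }
  } else {
    hit <- grep("_refine\\.ls_d_res_high|_reflns\\.d_resolution_high",
                lines, value = TRUE)
    if (length(hit) > 0) {
      m <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
      if (length(m) > 0) return(as.numeric(m))
    }
  }
  NA_real_
}

#' Write a structure to a PDB file
#'
#' Serializes via bio3d's PDB writer; coordinates survive a round trip to
#' 3 decimals and B factors to 2 decimals (the PDB fixed-column precision).
#' The resolution, when known, is recorded in a `REMARK 2` line so that
#' [read_structure()] recovers it.
#'
#' @param structure A [gq_structure].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (nrow(structure) == 0) abort("refusing to write an empty structure")
  if (any(nchar(structure$atom) > 4)) {
    abort("atom name longer than the 4-character PDB field")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
    type = structure$record,
    resno = structure$resno,
    resid = structure$resid,
    chain = ifelse(structure$chain == "", " ", structure$chain),
    eleno = seq_len(nrow(structure)),
    elety = structure$atom,
    o = structure$occupancy,
    b = structure$b,
    elesy = structure$element
  )
  res <- structure_resolution(structure)
  if (!is.na(res)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", res),
                 body), path)
  }
  invisible(path)
}

#' Structure acceptance filter
#'
#' The screening rule for considering a quadruplex-ligand structure further:
#' resolution at or below `max_resolution` (default 2.5 angstroms) and, when
#' `require_ligand_contacting_water` is on, at least one ligand-water hydrogen
#' bond in `hbonds`. A missing resolution is an explicit rejection reason, not
#' a silent pass.
#'
#' @param structure A [gq_structure].
#' @param hbonds Hydrogen-bond tibble (from [detect_hbonds()] or
#'   [load_contact_table()]); may be `NULL` when the water check is off.
#' @param max_resolution Resolution cutoff in angstroms.
#' @param require_ligand_contacting_water Require at least one ligand-water
#'   hydrogen bond.
#' @return One-row tibble with `accepted` (logical) and `reason`.
#' @export
accept_structure <- function(structure, hbonds = NULL, max_resolution = 2.5,
                             require_ligand_contacting_water = TRUE) {
  stopifnot(max_resolution > 0)
  res <- structure_resolution(structure)
  if (is.na(res)) {
    return(tibble::tibble(accepted = FALSE, reason = "unknown resolution"))
  }
  if (res > max_resolution) {
    return(tibble::tibble(
      accepted = FALSE,
      reason = sprintf("resolution %.2f Å exceeds %.2f Å",
                       res, max_resolution)))
  }
  if (require_ligand_contacting_water) {
    n_lw <- if (is.null(hbonds)) 0L else {
      sum(hbonds$category == "ligand-water")
    }
    if (n_lw == 0) {
      return(tibble::tibble(accepted = FALSE,
                            reason = "no ligand-contacting water"))
    }
  }
  tibble::tibble(accepted = TRUE, reason = "ok")
}
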