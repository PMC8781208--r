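#' Build the ligand-water-DNA contact graph
#'
#' Undirected graph over the polar atoms appearing in a hydrogen-bond tibble,
#' with one edge per bond and a `category` vertex attribute (`ligand`,
#' `water`, `nucleotide`, ...). Extra isolated waters can be supplied through
#' `waters` so that waters with no contacts still appear as nodes.
#'
#' @param hbonds Hydrogen-bond tibble from [detect_hbonds()] or
#'   [load_contact_table()].
#' @param waters Optional character vector of water labels to include as
#'   (possibly isolated) nodes.
#' @return An igraph object with vertex attributes `name` and `category` and
#'   edge attributes `distance` and `group_label`.
#' @export
build_contact_graph <- function(hbonds, waters = NULL) {
  nodes <- tibble::tibble(
    name = c(hbonds$atom_a, hbonds$atom_b),
    category = c(hbonds$category_a, hbonds$category_b)
  )
  if (!is.null(waters) && length(waters) > 0) {
    nodes <- dplyr::bind_rows(nodes,
                              tibble::tibble(name = waters,
                                             category = "water"))
  }
  nodes <- dplyr::distinct(nodes, .data$name, .keep_all = TRUE) |>
    dplyr::arrange(.data$name)
  conflicting <- tibble::tibble(
    name = c(hbonds$atom_a, hbonds$atom_b),
    category = c(hbonds$category_a, hbonds$category_b)) |>
    dplyr::distinct() |>
    dplyr::count(.data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicting) > 0) {
    abort(paste0("inconsistent node categories for: ",
                 paste(conflicting$name, collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(hbonds) > 0) {
      data.frame(from = hbonds$atom_a, to = hbonds$atom_b,
                 distance = hbonds$distance,
                 group_label = hbonds$group_label,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character(),
                 distance = numeric(), group_label = character())
    },
    directed = FALSE, vertices = as.data.frame(nodes))
  if (igraph::any_multiple(g)) {
    g <- igraph::simplify(g, edge.attr.comb = list(distance = "min",
                                                   group_label = "first"))
  }
  g
}

as_contact_graph <- function(x, waters = NULL) {
  if (igraph::is_igraph(x)) x else build_contact_graph(x, waters)
}

#' Enumerate water-bridged ligand-to-DNA paths
#'
#' All simple paths `ligand atom - water - ... - water - DNA atom` with
#' between 1 and `max_waters` intermediate waters (waters are distinct within
#' a path). The default depth of 4 matches the longest mediating chain the
#' packaged contact tables contain. Paths are sorted by ligand atom, number
#' of waters, total hydrogen-bond length, then water labels.
#'
#' @param hbonds Hydrogen-bond tibble (or a graph from
#'   [build_contact_graph()]).
#' @param max_waters Maximum number of intermediate waters (>= 1).
#' @return Tibble with `ligand_atom`, `waters` (labels joined by `" -> "`),
#'   `water_list` (list column), `dna_atom`, `k`, `total_length`.
#' @export
#' @examples
#' find_bridges(load_contact_table(mm41_contacts()), max_waters = 2)
find_bridges <- function(hbonds, max_waters = 4) {
  stopifnot(max_waters >= 1)
  g <- as_contact_graph(hbonds)
  cat_of <- setNames(igraph::V(g)$category, igraph::V(g)$name)
  lig <- names(cat_of)[cat_of == "ligand"]
  dna <- names(cat_of)[cat_of == "nucleotide"]
  if (length(lig) == 0 || length(dna) == 0) return(empty_bridge_tbl())

  dist_of <- function(path) {
    ids <- igraph::get_edge_ids(g, rbind(path[-length(path)], path[-1]))
    sum(igraph::E(g)$distance[ids])
  }
  rows <- list()
  for (l in lig) {
    paths <- igraph::all_simple_paths(g, from = l, to = dna,
                                      cutoff = max_waters + 1)
    for (p in paths) {
      labs <- igraph::V(g)$name[p]
      k <- length(labs) - 2
      if (k < 1 || k > max_waters) next
      interior <- labs[seq(2, length(labs) - 1)]
      if (!all(cat_of[interior] == "water")) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        ligand_atom = labs[1],
        waters = paste(interior, collapse = " -> "),
        water_list = list(interior),
        dna_atom = labs[length(labs)],
        k = as.integer(k),
        total_length = dist_of(labs))
    }
  }
  if (length(rows) == 0) return(empty_bridge_tbl())
  dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$ligand_atom, .data$waters, .data$dna_atom,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$ligand_atom, .data$k, .data$total_length,
                   .data$waters, .data$dna_atom)
}

empty_bridge_tbl <- function() {
  tibble::tibble(ligand_atom = character(), waters = character(),
                 water_list = list(), dna_atom = character(),
                 k = integer(), total_length = numeric())
}

#' Classify hydration shells
#'
#' Every water node is labeled `first` (hydrogen-bonded to at least one
#' non-water atom), `second` (not first, but bonded to a first-shell water),
#' or `bulk-like` (everything else, including isolated waters). The three
#' labels partition the water set.
#'
#' @inheritParams find_bridges
#' @param waters Optional labels of additional (isolated) waters.
#' @return Tibble with `water` and `shell`.
#' @export
classify_shells <- function(hbonds, waters = NULL) {
  g <- as_contact_graph(hbonds, waters)
  cat_of <- igraph::V(g)$category
  names(cat_of) <- igraph::V(g)$name
  wnames <- names(cat_of)[cat_of == "water"]
  if (length(wnames) == 0) {
    return(tibble::tibble(water = character(), shell = character()))
  }
  adj <- igraph::adjacent_vertices(g, wnames)
  first <- vapply(adj, function(v) any(cat_of[igraph::as_ids(v)] != "water"),
                  logical(1))
  first_set <- wnames[first]
  second <- vapply(seq_along(wnames), function(i) {
    !first[i] && any(igraph::as_ids(adj[[i]]) %in% first_set)
  }, logical(1))
  tibble::tibble(
    water = wnames,
    shell = unname(ifelse(first, "first",
                          ifelse(second, "second", "bulk-like")))
  ) |>
    dplyr::arrange(.data$water)
}

#' Water clusters and their anchors
#'
#' Connected components of the water-water subgraph; singleton clusters are
#' included. Each cluster reports its member waters and its anchors, the
#' non-water atoms hydrogen-bonded to any member.
#'
#' @inheritParams classify_shells
#' @return Tibble with `cluster` (integer id), `size`, `members` and
#'   `anchors` (list columns), `members_str`, `anchors_str`, and
#'   `group_label` (the groove annotations its edges carry, if any).
#' @export
water_clusters <- function(hbonds, waters = NULL) {
  g <- as_contact_graph(hbonds, waters)
  cat_of <- setNames(igraph::V(g)$category, igraph::V(g)$name)
  wnames <- names(cat_of)[cat_of == "water"]
  if (length(wnames) == 0) {
    return(tibble::tibble(cluster = integer(), size = integer(),
                          members = list(), anchors = list(),
                          members_str = character(),
                          anchors_str = character(),
                          group_label = character()))
  }
  wsub <- igraph::induced_subgraph(g, wnames)
  comp <- igraph::components(wsub)
  membership <- comp$membership[wnames]

  purrr::map_dfr(seq_len(comp$no), function(ci) {
    members <- sort(wnames[membership == ci])
    nb <- unique(unlist(lapply(
      igraph::adjacent_vertices(g, members), igraph::as_ids)))
    anchors <- sort(setdiff(nb[cat_of[nb] != "water"], members))
    eids <- unique(unlist(lapply(igraph::incident_edges(g, members),
                                 as.integer)))
    gl <- unique(stats::na.omit(igraph::E(g)$group_label[eids]))
    members_str <- paste(members, collapse = ", ")
    anchors_str <- paste(anchors, collapse = ", ")
    tibble::tibble(
      cluster = ci, size = length(members),
      members = list(members), anchors = list(anchors),
      members_str = members_str,
      anchors_str = anchors_str,
      group_label = if (length(gl) > 0) paste(gl, collapse = "; ")
                    else NA_character_)
  }) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$members_str) |>
    dplyr::mutate(cluster = dplyr::row_number())
}

#' Direct versus water-mediated ligand contact summary
#'
#' Counts, per the conventions of quadruplex hydration analyses: the number
#' of direct ligand-DNA hydrogen bonds, the number of distinct ligand atoms
#' hydrogen-bonded to at least one water, and the number of ligand atoms with
#' a complete water bridge to DNA within `max_waters` waters. A per-ligand-atom
#' detail table accompanies the totals. Water adjacency (not a complete
#' bridge) is the mediation count proper: a printed table can list a
#' ligand-bound water whose DNA partner is unresolved.
#'
#' @inheritParams find_bridges
#' @return List of class `gq_mediation` with elements `summary` (one-row
#'   tibble: `n_direct`, `n_water_adjacent`, `n_bridged`, `n_ligand_atoms`)
#'   and `detail` (per ligand atom: `ligand_atom`, `direct`,
#'   `water_adjacent`, `bridged`, `n_bridges`).
#' @export
#' @examples
#' mediation_summary(load_contact_table(braco19_contacts()))
mediation_summary <- function(hbonds, max_waters = 4) {
  g <- as_contact_graph(hbonds)
  cat_of <- setNames(igraph::V(g)$category, igraph::V(g)$name)
  lig <- sort(names(cat_of)[cat_of == "ligand"])
  if (length(lig) == 0) {
    abort("no ligand atoms in the contact set; cannot summarize mediation")
  }
  bridges <- find_bridges(g, max_waters = max_waters)
  detail <- purrr::map_dfr(lig, function(l) {
    nb <- igraph::as_ids(igraph::neighbors(g, l))
    tibble::tibble(
      ligand_atom = l,
      direct = sum(cat_of[nb] == "nucleotide"),
      water_adjacent = any(cat_of[nb] == "water"),
      n_bridges = sum(bridges$ligand_atom == l))
  }) |>
    dplyr::mutate(bridged = .data$n_bridges > 0)
  summary <- tibble::tibble(
    n_direct = sum(detail$direct),
    n_water_adjacent = sum(detail$water_adjacent),
    n_bridged = sum(detail$bridged),
    n_ligand_atoms = nrow(detail))
  structure(list(summary = summary, detail = detail, bridges = bridges),
            class = "gq_mediation")
}

#' @export
print.gq_mediation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<gq_mediation> %d ligand atom(s): %d direct ligand-DNA",
                     " bond(s), %d water-adjacent, %d bridged to DNA\n"),
              s$n_ligand_atoms, s$n_direct, s$n_water_adjacent, s$n_bridged))
  print(x$detail)
  invisible(x)
}

#' @export
#' @method tidy gq_mediation
tidy.gq_mediation <- function(x, ...) x$detail

#' @export
#' @method glance gq_mediation
glance.gq_mediation <- function(x, ...) x$summary

#' Waters per G-quadruplex
#'
#' Normalizes an asymmetric-unit water count by the number of quadruplexes it
#' contains, reporting both the exact ratio and the integer quotient quoted
#' in deposition tables.
#'
#' @param water_count Number of water molecules in the asymmetric unit.
#' @param gq_count Number of quadruplexes in the asymmetric unit (>= 1).
#' @return One-row tibble: `waters`, `quadruplexes`, `per_gq` (integer
#'   division), `ratio` (exact).
#' @export
#' @examples
#' waters_per_quadruplex(158, 2)
waters_per_quadruplex <- function(water_count, gq_count) {
  if (gq_count < 1) abort("gq_count must be at least 1")
  stopifnot(water_count >= 0)
  tibble::tibble(waters = as.integer(water_count),
                 quadruplexes = as.integer(gq_count),
                 per_gq = as.integer(water_count %/% gq_count),
                 ratio = water_count / gq_count)
}
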