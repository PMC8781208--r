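# Independent reference implementations used to cross-check the package.
# These are deliberately naive (nested loops, recursion) and share no code
# with the implementations they verify.

# Brute-force all-pairs hydrogen-bond detector. Returns a sorted key set
# "label|label|distance(3dp)" for comparison with detect_hbonds().
oracle_hbond_keys <- function(structure, roles, criteria) {
  at <- as.data.frame(structure)
  rl <- as.data.frame(roles[, c("chain", "resno", "atom", "role", "hybrid",
                                "category")])
  rl$ante <- roles$antecedents
  keys <- character()
  pos <- function(r) as.numeric(at[r, c("x", "y", "z")])
  find_atom <- function(chain, resno, atom) {
    which(at$chain == chain & at$resno == resno & at$atom == atom)
  }
  ang <- function(u, v) {
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  for (di in seq_len(nrow(rl))) {
    if (!rl$role[di] %in% c("donor", "both")) next
    d_row <- find_atom(rl$chain[di], rl$resno[di], rl$atom[di])
    if (length(d_row) != 1) next
    for (ai in seq_len(nrow(rl))) {
      if (!rl$role[ai] %in% c("acceptor", "both")) next
      a_row <- find_atom(rl$chain[ai], rl$resno[ai], rl$atom[ai])
      if (length(a_row) != 1 || a_row == d_row) next
      if (rl$chain[di] == rl$chain[ai] && rl$resno[di] == rl$resno[ai] &&
          at$resid[d_row] == at$resid[a_row]) next
      d <- sqrt(sum((pos(d_row) - pos(a_row))^2))
      if (d > criteria$max_distance) next
      if (criteria$angle_mode == "antecedent_proxy" &&
          rl$category[di] != "water") {
        antes <- rl$ante[[di]]
        arows <- unlist(lapply(antes, function(nm) {
          find_atom(rl$chain[di], rl$resno[di], nm)
        }))
        if (length(arows) > 0) {
          ideal <- if (rl$hybrid[di] == "sp3") 109.5 else 120
          devs <- sapply(arows, function(r) {
            abs(ang(pos(r) - pos(d_row), pos(a_row) - pos(d_row)) - ideal)
          })
          if (min(devs) > criteria$max_angle_deviation) next
        }
      }
      lo <- min(at$label[d_row], at$label[a_row])
      hi <- max(at$label[d_row], at$label[a_row])
      keys <- c(keys, paste(lo, hi, sprintf("%.3f", d), sep = "|"))
    }
  }
  sort(unique(keys))
}

hbond_keys <- function(hb) {
  sort(paste(pmin(hb$atom_a, hb$atom_b), pmax(hb$atom_a, hb$atom_b),
             sprintf("%.3f", hb$distance), sep = "|"))
}

# Exhaustive DFS enumeration of ligand -> water^k -> DNA simple paths.
oracle_bridges <- function(hbonds, max_waters) {
  adj <- list()
  adde <- function(a, b) {
    adj[[a]] <<- unique(c(adj[[a]], b))
    adj[[b]] <<- unique(c(adj[[b]], a))
  }
  cats <- c(stats::setNames(hbonds$category_a, hbonds$atom_a),
            stats::setNames(hbonds$category_b, hbonds$atom_b))
  cats <- cats[!duplicated(names(cats))]
  for (r in seq_len(nrow(hbonds))) adde(hbonds$atom_a[r], hbonds$atom_b[r])
  out <- character()
  walk <- function(node, path) {
    for (nb in adj[[node]]) {
      if (cats[nb] == "water" && !(nb %in% path) &&
          length(path) <= max_waters) {
        walk(nb, c(path, nb))
      } else if (cats[nb] == "nucleotide" && length(path) >= 2) {
        out <<- c(out, paste(c(path, nb), collapse = "|"))
      }
    }
  }
  for (l in names(cats)[cats == "ligand"]) walk(l, l)
  sort(unique(out))
}

bridge_keys <- function(bridges) {
  sort(paste(bridges$ligand_atom,
             gsub(" -> ", "|", bridges$waters),
             bridges$dna_atom, sep = "|"))
}

# O(n^2) mutual-nearest-neighbor water matching.
oracle_mutual_pairs <- function(pa, pb, la, lb, threshold) {
  if (nrow(pa) == 0 || nrow(pb) == 0) return(character())
  dm <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                              nrow(pa) + seq_len(nrow(pb)),
                                              drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(pa))) {
    j <- which.min(dm[i, ])
    if (dm[i, j] <= threshold && which.min(dm[, j]) == i) {
      keys <- c(keys, paste(la[i], lb[j], sep = "|"))
    }
  }
  sort(keys)
}

# A hand-built miniature structure: one guanine with an explicit backbone
# oxygen, one ligand nitrogen, and waters at chosen positions.
tiny_scene <- function(water_xyz = matrix(numeric(0), ncol = 3),
                       lig_xyz = c(0, 0, 6.8)) {
  g <- gqwater:::guanine_template()
  rows <- list()
  for (nm in rownames(g)) {
    rows[[length(rows) + 1]] <- data.frame(
      record = "ATOM", atom = nm, resid = "DG", chain = "A", resno = 1,
      x = g[nm, 1], y = g[nm, 2], z = g[nm, 3], occupancy = 1, b = 20,
      altloc = "", element = substr(nm, 1, 1))
  }
  rows[[length(rows) + 1]] <- data.frame(
    record = "ATOM", atom = "OP2", resid = "DG", chain = "A", resno = 1,
    x = 8, y = 0, z = 0, occupancy = 1, b = 25, altloc = "", element = "O")
  rows[[length(rows) + 1]] <- data.frame(
    record = "HETATM", atom = "NCH", resid = "LIG", chain = "A", resno = 101,
    x = lig_xyz[1], y = lig_xyz[2], z = lig_xyz[3], occupancy = 1, b = 50,
    altloc = "", element = "N")
  if (nrow(water_xyz) > 0) {
    for (i in seq_len(nrow(water_xyz))) {
      rows[[length(rows) + 1]] <- data.frame(
        record = "HETATM", atom = "O", resid = "HOH", chain = "A",
        resno = 200 + i, x = water_xyz[i, 1], y = water_xyz[i, 2],
        z = water_xyz[i, 3], occupancy = 1, b = 30, altloc = "",
        element = "O")
    }
  }
  gq_structure(do.call(rbind, rows), id = "tiny", resolution = 1.5,
               ligand_codes = "LIG")
}
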