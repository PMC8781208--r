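#' Guanine base heavy atoms used for quartet fitting
#'
#' The eleven base heavy atoms of guanine. Quartet superposition fits on
#' these (not the backbone), because the base planes define the quartet while
#' backbone and loops flex between structures.
#'
#' @return Character vector of atom names.
#' @export
guanine_base_atoms <- function() {
  c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6", "N7", "C8", "N9")
}

# Least-squares rigid superposition (Kabsch): returns the rotation R and
# translation t with P %*% R + t ~= Q for row-vector coordinates.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) abort("degenerate fit: fewer than 3 atom pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(t(Pc) %*% Qc)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    abort("degenerate fit: fitted atoms are (near-)collinear")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- as.numeric(cq - cp %*% R)
  resid <- Pc %*% R - Qc
  rmsd <- sqrt(mean(rowSums(resid^2)))
  list(rotation = R, translation = t, rmsd = rmsd, n_atoms = nrow(P))
}

#' Superpose two structures on their quartet guanines
#'
#' Least-squares rigid-body fit (Kabsch) of structure `a` onto structure `b`
#' using the guanine base heavy atoms of an explicit residue correspondence.
#' The correspondence is a scientific choice (which guanines overlay which)
#' and is never inferred automatically. Original coordinates are untouched;
#' apply the transform with [apply_superposition()].
#'
#' @param a,b [gq_structure] objects.
#' @param correspondence Tibble with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, one row per guanine pair.
#' @param atoms Atom names to fit on; the set actually used is the
#'   intersection present in every residue pair, so it is identical across
#'   pairs. Default [guanine_base_atoms()].
#' @return Object of class `gq_superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (angstroms over fitted atoms), `n_atoms`, and
#'   `fitted` (per-atom tibble with post-fit deviations).
#' @export
fit_quartets <- function(a, b, correspondence,
                         atoms = guanine_base_atoms()) {
  correspondence <- tibble::as_tibble(correspondence)
  stopifnot(all(c("chain_a", "resno_a", "chain_b", "resno_b") %in%
                names(correspondence)))
  if (nrow(correspondence) == 0) abort("empty residue correspondence")

  pick <- function(s, chain, resno) {
    s[s$chain == chain & s$resno == resno & s$atom %in% atoms, ]
  }
  pairs <- purrr::pmap(correspondence, function(chain_a, resno_a,
                                                chain_b, resno_b, ...) {
    ra <- pick(a, chain_a, resno_a)
    rb <- pick(b, chain_b, resno_b)
    common <- intersect(ra$atom, rb$atom)
    list(ra = ra, rb = rb, common = common,
         tag_a = paste0(chain_a, resno_a), tag_b = paste0(chain_b, resno_b))
  })
  common <- Reduce(intersect, lapply(pairs, `[[`, "common"))
  common <- intersect(atoms, common)   # stable, chemistry order
  if (length(common) == 0) {
    abort("no fitting atoms shared by every residue pair")
  }
  P <- do.call(rbind, lapply(pairs, function(p) {
    m <- p$ra[match(common, p$ra$atom), c("x", "y", "z")]
    as.matrix(m)
  }))
  Q <- do.call(rbind, lapply(pairs, function(p) {
    as.matrix(p$rb[match(common, p$rb$atom), c("x", "y", "z")])
  }))
  fit <- kabsch(P, Q)
  moved <- sweep(P %*% fit$rotation, 2, fit$translation, `+`)
  fitted <- tibble::tibble(
    residue_a = rep(vapply(pairs, `[[`, "", "tag_a"), each = length(common)),
    residue_b = rep(vapply(pairs, `[[`, "", "tag_b"), each = length(common)),
    atom = rep(common, times = length(pairs)),
    deviation = sqrt(rowSums((moved - Q)^2)))
  structure(c(fit, list(fitted = fitted)), class = "gq_superposition")
}

#' @export
print.gq_superposition <- function(x, ...) {
  cat(sprintf("<gq_superposition> rmsd %.4f Å over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' @export
#' @method glance gq_superposition
glance.gq_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms)
}

#' @export
#' @method tidy gq_superposition
tidy.gq_superposition <- function(x, ...) x$fitted

#' Apply a superposition transform to a structure
#'
#' @param structure A [gq_structure].
#' @param fit A `gq_superposition` from [fit_quartets()].
#' @return The structure with transformed coordinates.
#' @export
apply_superposition <- function(structure, fit) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  moved <- sweep(xyz %*% fit$rotation, 2, fit$translation, `+`)
  structure$x <- moved[, 1]
  structure$y <- moved[, 2]
  structure$z <- moved[, 3]
  structure
}

#' Match conserved water positions between two superposed structures
#'
#' After transforming the waters of `a` into the frame of `b`, waters closer
#' than `threshold` are paired. The default pairing is mutual nearest
#' neighbors (each member of a pair is the other's closest water), which is
#' deterministic and guarantees each water appears in at most one pair;
#' `method = "greedy"` instead sweeps candidate pairs by ascending distance.
#' The default threshold of 1.0 angstrom is the conventional criterion for
#' calling two crystallographic waters "the same site".
#'
#' @param a,b [gq_structure] objects.
#' @param fit `gq_superposition` mapping `a` onto `b` (use `NULL` for
#'   already-aligned structures).
#' @param threshold Pairing distance cutoff in angstroms (> 0).
#' @param method `"mutual"` or `"greedy"`.
#' @return Tibble sorted by distance: `water_a`, `water_b`, `distance`.
#' @export
match_conserved_waters <- function(a, b, fit = NULL, threshold = 1.0,
                                   method = c("mutual", "greedy")) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  wa <- a[a$category == "water", ]
  wb <- b[b$category == "water", ]
  if (nrow(wa) == 0 || nrow(wb) == 0) {
    return(tibble::tibble(water_a = character(), water_b = character(),
                          distance = numeric()))
  }
  pa <- as.matrix(wa[, c("x", "y", "z")])
  if (!is.null(fit)) {
    pa <- sweep(pa %*% fit$rotation, 2, fit$translation, `+`)
  }
  pb <- as.matrix(wb[, c("x", "y", "z")])
  dm <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  dm[dm < 0] <- 0
  dm <- sqrt(dm)
  cand <- which(dm <= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(water_a = character(), water_b = character(),
                          distance = numeric()))
  }
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used_a <- logical(nrow(wa)); used_b <- logical(nrow(wb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_a[i] || used_b[j]) next
    ok <- if (method == "mutual") {
      which.min(dm[i, ]) == j && which.min(dm[, j]) == i
    } else {
      TRUE
    }
    if (ok) {
      keep[r] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  tibble::tibble(water_a = wa$label[sel[, 1]],
                 water_b = wb$label[sel[, 2]],
                 distance = dm[sel]) |>
    dplyr::arrange(.data$distance, .data$water_a)
}
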