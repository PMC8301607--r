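# The 3D vectorization: a molecule becomes a weighted set of "views".
#
# A view is a local canonical coordinate frame centered on one atom; its
# rows are [period, group, x, y, z] for the center (row 0, at the origin)
# and the other atoms in order of distance. A k-way distance tie at the
# nearest-neighbor (axis-defining) position splits the center's view into k
# views with the center's unit weight divided equally; weights are then
# normalized to sum to 1 over the molecule.

#' View-construction configuration
#'
#' @param centers_mode `"all_atoms"` (a view per atom) or `"carbon_only"`
#'   (views only from carbons; falls back to all atoms when the molecule has
#'   no carbon).
#' @param max_atoms_per_view Maximum rows per view, center included.
#' @param tie_tol Distance tolerance in angstrom for treating two
#'   center-atom distances as tied.
#' @return A list of class `vt_view_config`.
#' @export
view_config <- function(centers_mode = c("all_atoms", "carbon_only"),
                        max_atoms_per_view = 10L, tie_tol = 1e-3) {
  centers_mode <- match.arg(centers_mode)
  stopifnot(max_atoms_per_view >= 1L, tie_tol >= 0)
  structure(list(centers_mode = centers_mode,
                 max_atoms_per_view = as.integer(max_atoms_per_view),
                 tie_tol = tie_tol),
            class = "vt_view_config")
}

#' Canonical local frame for one view
#'
#' Rigid transform taking the center to the origin and the designated
#' nearest atom onto the +x axis. The nearest non-collinear atom (in
#' distance order) fixes the half-plane y > 0; z completes a right-handed
#' frame, then the first off-plane atom in distance order is required to
#' have z > 0, applying a reflection if needed. Fully collinear molecules
#' get y = z = 0 for every atom. Because of the reflection rule, enantiomers
#' produce identical views (a documented representational limit).
#'
#' @param mol A `vt_molecule`.
#' @param center_index Index of the center atom.
#' @param nearest_index Index of the designated nearest atom (defines +x).
#' @return List with `coords` (all atoms transformed, n x 3), `rotation`
#'   (3 x 3, possibly improper), `origin`, and `reflected`.
#' @export
canonical_frame <- function(mol, center_index, nearest_index) {
  stopifnot(inherits(mol, "vt_molecule"), center_index != nearest_index)
  xyz <- atom_coords(mol)
  origin <- xyz[center_index, ]
  rel <- sweep(xyz, 2, origin)
  ax <- rel[nearest_index, ]
  if (sqrt(sum(ax^2)) < 1e-9) stop("zero-length axis vector for canonical frame")
  u <- unitv(ax)

  # candidate order: distance from center, then rotation-invariant keys
  others <- setdiff(seq_len(nrow(xyz)), center_index)
  d <- sqrt(rowSums(rel[others, , drop = FALSE]^2))
  d_near <- sqrt(rowSums(sweep(xyz[others, , drop = FALSE], 2,
                               xyz[nearest_index, ])^2))
  # keys quantized to 1e-6 angstrom so sub-tolerance numerical noise from a
  # rigid motion of the input cannot reorder candidates; the full sorted
  # distance profile breaks ties between atoms that are equidistant from
  # both the center and the designated nearest yet geometrically distinct
  # (atoms it cannot separate are exact symmetry mates, for which either
  # choice yields the same view)
  profile <- vapply(others, function(j) {
    dj <- sqrt(rowSums(sweep(xyz, 2, xyz[j, ])^2))
    paste(sprintf("%.5f", sort(dj)), collapse = ",")
  }, "")
  ord <- others[order(round(d, 6), mol$atoms$period[others],
                      mol$atoms$group[others], round(d_near, 6), profile)]

  ref <- NA_integer_
  for (j in ord) {
    perp <- rel[j, ] - sum(rel[j, ] * u) * u
    if (sqrt(sum(perp^2)) > 1e-6) { ref <- j; break }
  }
  if (is.na(ref)) {
    v <- perp_unit(u)          # collinear molecule: arbitrary perpendicular
  } else {
    perp <- rel[ref, ] - sum(rel[ref, ] * u) * u
    v <- unitv(perp)
  }
  w <- cross3(u, v)
  R <- cbind(u, v, w)
  out <- rel %*% R
  reflected <- FALSE
  for (j in ord) {
    if (abs(out[j, 3]) > 1e-6) {
      if (out[j, 3] < 0) { out[, 3] <- -out[, 3]; R[, 3] <- -R[, 3]
                           reflected <- TRUE }
      break
    }
  }
  list(coords = out, rotation = R, origin = origin, reflected = reflected)
}

#' Build the weighted set of views for a molecule
#'
#' One base view per center atom. When k atoms tie (within `tie_tol`) at a
#' center's nearest-neighbor position, that view splits into k views, one
#' per tied atom designated as nearest, and the center's base weight of 1 is
#' divided equally among them; all weights are finally normalized to sum to
#' 1. Non-center atoms enter each view in order of distance from the center
#' up to `max_atoms_per_view - 1`; residual distance ties beyond the nearest
#' position are broken canonically by (period, group, canonical-frame
#' coordinates) without further splitting.
#'
#' @param mol A `vt_molecule`.
#' @param cfg A `vt_view_config`.
#' @return An object of class `vt_viewset`: `molecule_id`, `views` (list),
#'   `weights` (numeric, sums to 1).
#' @examples
#' vs <- build_views(fixture_molecule("methyl_isothiocyanate"), view_config())
#' length(vs$views)   # 9
#' @export
build_views <- function(mol, cfg = view_config()) {
  stopifnot(inherits(mol, "vt_molecule"), inherits(cfg, "vt_view_config"))
  n <- n_atoms(mol)
  xyz <- atom_coords(mol)
  pg <- as.matrix(mol$atoms[, c("period", "group")])

  centers <- seq_len(n)
  if (cfg$centers_mode == "carbon_only") {
    cc <- which(mol$atoms$element == "C")
    if (length(cc) > 0L) centers <- cc
  }

  views <- list()
  weights <- numeric(0)
  for (ci in centers) {
    others <- setdiff(seq_len(n), ci)
    if (length(others) == 0L) {
      views[[length(views) + 1L]] <- list(
        center_index = ci, designated_nearest = NA_integer_,
        atom_order = ci,
        rows = matrix(c(pg[ci, ], 0, 0, 0), 1, 5,
                      dimnames = list(NULL, c("period", "group", "x", "y", "z"))))
      weights <- c(weights, 1)
      next
    }
    d <- sqrt(rowSums(sweep(xyz[others, , drop = FALSE], 2, xyz[ci, ])^2))
    tied <- others[d <= min(d) + cfg$tie_tol]
    for (ni in tied) {
      fr <- canonical_frame(mol, ci, ni)
      t_xyz <- fr$coords
      # order non-center atoms: distance groups, then canonical keys
      dd <- sqrt(rowSums(t_xyz[others, , drop = FALSE]^2))
      grp <- cumsum(c(0, diff(sort(dd)) > cfg$tie_tol))
      rank_of <- grp[match(dd, sort(dd))]
      key <- order(rank_of, pg[others, 1], pg[others, 2],
                   round(t_xyz[others, 1], 6), round(t_xyz[others, 2], 6),
                   round(t_xyz[others, 3], 6))
      ord <- others[key]
      keep <- ord[seq_len(min(length(ord), cfg$max_atoms_per_view - 1L))]
      idx <- c(ci, keep)
      rows <- cbind(pg[idx, 1], pg[idx, 2], t_xyz[idx, , drop = FALSE])
      rows[1, 3:5] <- 0
      colnames(rows) <- c("period", "group", "x", "y", "z")
      views[[length(views) + 1L]] <- list(
        center_index = ci, designated_nearest = ni, atom_order = idx,
        rows = rows)
      weights <- c(weights, 1 / length(tied))
    }
  }
  weights <- weights / sum(weights)
  structure(list(molecule_id = mol$id, views = views, weights = weights),
            class = "vt_viewset")
}

#' @export
print.vt_viewset <- function(x, ...) {
  cat("<vt_viewset>", x$molecule_id, "-", length(x$views),
      "views, weights sum", format(sum(x$weights)), "\n")
  invisible(x)
}

#' Pad a view set to fixed-shape arrays
#'
#' Emits every view as exactly `max_atoms` rows x 5 columns: short views are
#' zero-padded (period = group = 0 sentinel rows), long views truncated to
#' the `max_atoms` nearest atoms including the center. Weights are returned
#' unchanged.
#'
#' @param vs A `vt_viewset`.
#' @param max_atoms Number of rows per padded view.
#' @return List with `views` (array n_views x max_atoms x 5), `weights`, and
#'   `flat` (matrix n_views x 5*max_atoms, rows are slot-major flattened
#'   views, the layout the network feature layer consumes).
#' @export
pad_to_tensor <- function(vs, max_atoms) {
  stopifnot(inherits(vs, "vt_viewset"), max_atoms >= 1L)
  nv <- length(vs$views)
  arr <- array(0, dim = c(nv, max_atoms, 5))
  for (i in seq_len(nv)) {
    r <- vs$views[[i]]$rows
    m <- min(nrow(r), max_atoms)
    arr[i, seq_len(m), ] <- r[seq_len(m), , drop = FALSE]
  }
  flat <- matrix(aperm(arr, c(3, 2, 1)), nrow = nv, byrow = TRUE)
  list(views = arr, weights = vs$weights, flat = flat)
}

#' Write a view set as a long-format CSV
#'
#' One row per (view, atom slot): molecule_id, view_idx, weight, slot,
#' period, group, x, y, z.
#'
#' @param vs A `vt_viewset`.
#' @param path Output CSV path.
#' @param max_atoms Optional padding (defaults to the longest view).
#' @return `path`, invisibly.
#' @export
write_views_csv <- function(vs, path, max_atoms = NULL) {
  if (is.null(max_atoms)) {
    max_atoms <- max(vapply(vs$views, function(v) nrow(v$rows), 0L))
  }
  pt <- pad_to_tensor(vs, max_atoms)
  recs <- do.call(rbind, lapply(seq_along(vs$views), function(i) {
    data.frame(molecule_id = vs$molecule_id, view_idx = i,
               weight = vs$weights[i], slot = seq_len(max_atoms),
               period = pt$views[i, , 1], group = pt$views[i, , 2],
               x = pt$views[i, , 3], y = pt$views[i, , 4], z = pt$views[i, , 5])
  }))
  utils::write.csv(recs, path, row.names = FALSE)
  invisible(path)
}
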