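# The weighted-views vectorization: counts, tie-splitting, weights,
# canonical frames, padding.

test_that("methyl isothiocyanate yields nine all-atom views", {
  vs <- build_views(fixture_molecule("methyl_isothiocyanate"),
                    view_config(max_atoms_per_view = 10))
  expect_length(vs$views, 9L)
  expect_equal(sum(vs$weights), 1, tolerance = 1e-9)
  # the methyl carbon splits three ways on its tied hydrogens
  centers <- vapply(vs$views, `[[`, 0L, "center_index")
  expect_equal(sum(centers == 1L), 3L)
})

test_that("a single-atom molecule gives one center-only view of weight 1", {
  m <- molecule("lone", "C", matrix(0, 1, 3))
  vs <- build_views(m, view_config())
  expect_length(vs$views, 1L)
  expect_equal(vs$weights, 1)
  expect_equal(unname(vs$views[[1]]$rows),
               matrix(c(2, 14, 0, 0, 0), 1))
})

test_that("methane splits 4-way at carbon: 8 views with weights 1/20 and 1/5", {
  vs <- build_views(fixture_molecule("methane"), view_config())
  expect_length(vs$views, 8L)
  centers <- vapply(vs$views, `[[`, 0L, "center_index")
  expect_equal(unname(vs$weights[centers == 1L]), rep(1 / 20, 4))
  expect_equal(unname(vs$weights[centers != 1L]), rep(1 / 5, 4))
})

test_that("carbon-only mode restricts centers and falls back without carbon", {
  vc <- build_views(fixture_molecule("methyl_isothiocyanate"),
                    view_config("carbon_only"))
  expect_true(all(vapply(vc$views, `[[`, 0L, "center_index") %in% c(1L, 6L)))
  # a carbon-free molecule falls back to all-atom centers (asymmetric
  # O-H bond lengths so no nearest-neighbor tie splits the oxygen view)
  w <- molecule("water_like", c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.95, 0, 0),
                      0.98 * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0)))
  expect_length(build_views(w, view_config("carbon_only"))$views, 3L)
})

test_that("canonical frame puts the designated nearest on +x and handles collinearity", {
  co2 <- fixture_molecule("co2")
  vs <- build_views(co2, view_config())
  for (v in vs$views) {
    expect_lt(max(abs(v$rows[, c("y", "z")])), 1e-9)  # collinear molecule
  }
  mi <- fixture_molecule("methyl_isothiocyanate")
  for (v in build_views(mi, view_config())$views) {
    ni <- v$designated_nearest
    pos <- which(v$atom_order == ni)
    d <- sqrt(sum((atom_coords(mi)[ni, ] - atom_coords(mi)[v$center_index, ])^2))
    expect_equal(unname(v$rows[pos, c("x", "y", "z")]), c(d, 0, 0),
                 tolerance = 1e-9)
  }
  expect_error(canonical_frame(fixture_molecule("co2"), 1, 1))
})

test_that("row columns 1-2 are the atom's periodic position; row 0 the center", {
  mi <- fixture_molecule("methyl_isothiocyanate")
  vs <- build_views(mi, view_config())
  for (v in vs$views) {
    expect_equal(unname(v$rows[1, ]),
                 c(unname(periodic_position(mi$atoms$element[v$center_index])),
                   0, 0, 0))
    for (r in seq_along(v$atom_order)) {
      expect_equal(unname(v$rows[r, 1:2]),
                   unname(periodic_position(mi$atoms$element[v$atom_order[r]])))
    }
    # non-center rows in non-decreasing distance order
    dists <- sqrt(rowSums(v$rows[-1, 3:5, drop = FALSE]^2))
    expect_true(all(diff(dists) >= -1e-9))
  }
})

test_that("views are invariant to rigid motion and atom order", {
  set.seed(101)
  mols <- c(lapply(fixture_names, fixture_molecule),
            synth_molecules(synth_config(n_chemicals = 24, seed = 8)))
  for (m in mols) {
    v0 <- build_views(m, view_config())
    v1 <- build_views(rigid_motion(m), view_config())
    expect_length(v1$views, length(v0$views))
    expect_equal(v1$weights, v0$weights, tolerance = 1e-9)
    for (i in seq_along(v0$views)) {
      expect_lt(max(abs(v0$views[[i]]$rows - v1$views[[i]]$rows)), 1e-6)
    }
    v2 <- build_views(permute_atoms(m), view_config())
    expect_identical(view_signature(v2), view_signature(v0))
  }
})

test_that("weights always sum to one in both centers modes", {
  set.seed(11)
  mols <- synth_molecules(synth_config(n_chemicals = 20, seed = 12))
  for (m in mols) {
    for (mode in c("all_atoms", "carbon_only")) {
      vs <- build_views(m, view_config(mode))
      expect_equal(sum(vs$weights), 1, tolerance = 1e-9)
      expect_true(all(vs$weights >= 0))
    }
  }
})

test_that("raising tie_tol never decreases the number of views", {
  set.seed(13)
  mols <- c(lapply(fixture_names, fixture_molecule),
            synth_molecules(synth_config(n_chemicals = 10, seed = 14)))
  for (m in mols) {
    counts <- vapply(c(1e-6, 1e-3, 1e-1, 0.5),
                     function(tt) length(build_views(m,
                       view_config(tie_tol = tt))$views), 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("pad_to_tensor pads with zero rows and truncates to nearest atoms", {
  mi <- fixture_molecule("methyl_isothiocyanate")
  vs <- build_views(mi, view_config(max_atoms_per_view = 10))
  pt <- pad_to_tensor(vs, 10)
  expect_equal(dim(pt$views), c(9, 10, 5))
  expect_equal(pt$views[1, 8:10, ], matrix(0, 3, 5))  # 7 rows -> 3 zero rows
  expect_equal(pt$weights, vs$weights)                # padding touches rows only

  # truncation to 4 rows = center + 3 nearest, recomputed independently
  pt4 <- pad_to_tensor(vs, 4)
  expect_equal(dim(pt4$views), c(9, 4, 5))
  for (i in seq_along(vs$views)) {
    v <- vs$views[[i]]
    ctr <- v$center_index
    d <- sqrt(rowSums(sweep(atom_coords(mi), 2, atom_coords(mi)[ctr, ])^2))
    nearest3 <- sort(d[-ctr], partial = 3)[3]
    kept <- v$atom_order[-1][1:3]
    expect_true(all(d[kept] <= nearest3 + 1e-9))
    expect_equal(pt4$views[i, , ], v$rows[1:4, ], ignore_attr = TRUE)
  }

  # flat layout is the slot-major flattening the feature net consumes
  expect_equal(pt$flat[3, ], as.vector(t(pt$views[3, , ])))
})
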