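# Shared helpers: random rigid motions and molecule permutations.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion <- function(mol) {
  R <- random_rotation()
  tr <- stats::rnorm(3, sd = 5)
  molecule(mol$id, mol$atoms$element,
           sweep(atom_coords(mol) %*% R, 2, -tr))
}

permute_atoms <- function(mol, perm = sample(n_atoms(mol))) {
  molecule(mol$id, mol$atoms$element[perm],
           atom_coords(mol)[perm, , drop = FALSE])
}

# Canonical multiset signature of a view set's rows, for order-insensitive
# comparison.
view_signature <- function(vs, digits = 6) {
  sort(vapply(seq_along(vs$views), function(i) {
    paste(round(vs$views[[i]]$rows, digits), collapse = ",")
  }, ""))
}

fixture_names <- c("methane", "methanol", "co2", "methyl_isothiocyanate",
                   "glycine_betaine", "perfluorodecane")
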