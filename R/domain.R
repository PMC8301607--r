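# Domain-of-applicability filter. Predictions are refused for structures
# outside the space the generators were built for: perfluorinated chains
# longer than nine carbons, chloroperfluoro compounds, and betaine-motif
# compounds. Connectivity is inferred from interatomic distances.

#' Infer molecular connectivity from distances
#'
#' Two atoms are bonded when their distance is below 1.2 x the sum of their
#' covalent radii. Returns the bond list as an n x n logical adjacency
#' matrix. A multi-atom molecule whose inferred bond graph is disconnected
#' raises an error (inference failure), never a silent acceptance.
#'
#' @param mol A `vt_molecule`.
#' @return Logical adjacency matrix.
#' @export
infer_bonds <- function(mol) {
  stopifnot(inherits(mol, "vt_molecule"))
  n <- n_atoms(mol)
  radii <- vapply(mol$atoms$element, covalent_radius, 0)
  xyz <- atom_coords(mol)
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(radii, radii, "+") * 1.2
  adj <- d < cutoff
  diag(adj) <- FALSE
  if (n > 1L) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no > 1L) {
      stop("connectivity inference failed for '", mol$id,
           "': bond graph is disconnected")
    }
  }
  adj
}

# Longest path (in atoms) through the carbon skeleton. Exact for acyclic
# skeletons (tree diameter); a safe lower bound otherwise.
longest_carbon_chain <- function(mol, adj) {
  is_c <- mol$atoms$element == "C"
  if (!any(is_c)) return(0L)
  sub <- adj[is_c, is_c, drop = FALSE]
  if (sum(is_c) == 1L) return(1L)
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  dmat <- igraph::distances(g)
  max(dmat[is.finite(dmat)]) + 1L
}

#' Apply the domain-of-applicability filter
#'
#' Rejects (a) perfluorinated chains with more than nine carbons, (b)
#' chloroperfluoro compounds, and (c) compounds carrying a betaine motif
#' (quaternary N+ together with a carboxylate in the same molecule). The
#' returned reason names the triggered rule. Decisions depend only on
#' element identities and inferred connectivity, so they are invariant to
#' atom ordering and rigid motion.
#'
#' @param mol A `vt_molecule`.
#' @return A list with `accepted` (logical) and `reason` (character).
#' @examples
#' domain_filter(fixture_molecule("methanol"))$accepted          # TRUE
#' domain_filter(fixture_molecule("perfluorodecane"))$accepted   # FALSE
#' @export
domain_filter <- function(mol) {
  stopifnot(inherits(mol, "vt_molecule"))
  adj <- infer_bonds(mol)
  el <- mol$atoms$element
  is_c <- el == "C"

  # a carbon is "halogen-saturated" if it carries no hydrogen
  c_has_h <- vapply(which(is_c), function(i) any(el[adj[i, ]] == "H"), TRUE)
  no_h_on_c <- length(c_has_h) > 0L && !any(c_has_h)
  halogens_on_c <- unique(el[unlist(lapply(which(is_c), function(i) {
    which(adj[i, ] & !is_c)
  }))])

  if (no_h_on_c && length(halogens_on_c) > 0 && all(halogens_on_c == "F")) {
    chain <- longest_carbon_chain(mol, adj)
    if (chain > 9L) {
      return(list(accepted = FALSE, reason = "perfluorinated chain length > 9"))
    }
  }
  if (no_h_on_c && all(halogens_on_c %in% c("F", "Cl")) &&
      "F" %in% halogens_on_c && "Cl" %in% halogens_on_c) {
    return(list(accepted = FALSE, reason = "chloroperfluoro compound"))
  }

  deg <- rowSums(adj)
  quat_n <- any(el == "N" & deg == 4 &
                  vapply(seq_along(el), function(i) {
                    el[i] == "N" && all(el[adj[i, ]] == "C")
                  }, TRUE))
  carboxylate <- any(vapply(which(is_c), function(i) {
    o_nb <- which(adj[i, ] & el == "O")
    length(o_nb) == 2L && all(deg[o_nb] == 1L)
  }, TRUE))
  if (quat_n && carboxylate) {
    return(list(accepted = FALSE, reason = "betaine functional group"))
  }
  list(accepted = TRUE, reason = "within domain")
}
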