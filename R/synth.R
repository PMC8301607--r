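# Synthetic molecules and planted structure->toxicity mappings.
#
# The generator emulates the statistical shape of the empirical screen: 18
# binary endpoints, 32 replicate embryos per chemical, and ~16% of
# chemicals active at the 9.35-bit AggE threshold (the 159/1003 imbalance
# of the training screen). The planted signal passes only through
# descriptors derivable from 3D structure, so the views representation can
# in principle recover it.

#' Synthetic-data configuration
#'
#' @param n_chemicals Number of molecules to generate.
#' @param seed Integer seed controlling every random draw.
#' @param elements Named frequency vector for the heavy-atom alphabet.
#' @param chain_len Integer range (min, max) of heavy-atom chain lengths.
#' @param prevalence Target active-class fraction at threshold 9.35
#'   (default 0.16, mirroring the 159/1003 training imbalance).
#' @param beta Effect sizes on the five structural descriptors
#'   (size, heteroatom fraction, S presence, Cl presence, mean coordination).
#'   `beta = 0` (recycled) plants a pure null.
#' @param noise_scale SD of per-(chemical, endpoint) Gaussian noise on the
#'   logit scale.
#' @param n_replicates Replicates per endpoint for the binomial draws.
#' @param threshold AggE activity threshold used for calibration.
#' @return A list of class `vt_synth_config`.
#' @export
synth_config <- function(n_chemicals = 200L, seed = 1L,
                         elements = c(C = 0.60, N = 0.10, O = 0.15,
                                      S = 0.08, Cl = 0.07),
                         chain_len = c(3L, 9L),
                         prevalence = 0.16,
                         beta = c(size = 0.8, hetero = 1.0, S = 2.5,
                                  Cl = 1.5, coord = 0.5),
                         noise_scale = 0.25, n_replicates = 32L,
                         threshold = 9.35) {
  stopifnot(n_chemicals >= 1L, prevalence > 0, prevalence < 1,
            n_replicates >= 1L, all(elements > 0), length(chain_len) == 2L)
  for (el in names(elements)) covalent_radius(el)  # must have radius entries
  if (length(beta) == 1L) {
    beta <- stats::setNames(rep(beta, 5),
                            c("size", "hetero", "S", "Cl", "coord"))
  }
  structure(list(n_chemicals = as.integer(n_chemicals), seed = as.integer(seed),
                 elements = elements / sum(elements),
                 chain_len = as.integer(chain_len), prevalence = prevalence,
                 beta = beta, noise_scale = noise_scale,
                 n_replicates = as.integer(n_replicates),
                 threshold = threshold),
            class = "vt_synth_config")
}

#' Generate synthetic molecules
#'
#' Random acyclic heavy-atom chains over the configured element alphabet,
#' embedded as an idealized tetrahedral zigzag with bond lengths equal to
#' the sum of covalent radii (so a carbon chain has C-C = 1.54 angstrom).
#' Deterministic given the seed.
#'
#' @param cfg A `vt_synth_config`.
#' @return List of `vt_molecule`.
#' @export
synth_molecules <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "vt_synth_config"))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_chemicals), function(i) {
    len <- sample(seq(cfg$chain_len[1], cfg$chain_len[2]), 1)
    els <- sample(names(cfg$elements), len, replace = TRUE,
                  prob = cfg$elements)
    molecule(sprintf("syn%05d", i), els, chain_coords(els),
             provenance = list(source = "synthetic", seed = cfg$seed))
  })
}

# 3D-derivable structural descriptors the planted signal acts through.
synth_descriptors <- function(mol) {
  el <- mol$atoms$element
  adj <- infer_bonds(mol)
  c(size = (length(el) - 6) / 3,
    hetero = mean(el != "C"),
    S = as.numeric("S" %in% el),
    Cl = as.numeric("Cl" %in% el),
    coord = mean(rowSums(adj)) - 1.7)
}

# Endpoint-specific baseline offsets (deterministic heterogeneity).
.alpha_profile <- seq(-0.5, 0.5, length.out = 18)

# Expected (noise-free) incidence vector for a molecule given the global
# intercept shift.
synth_true_p <- function(mol, cfg, alpha_shift) {
  z <- sum(cfg$beta * synth_descriptors(mol))
  stats::plogis(.alpha_profile + alpha_shift + z)
}

#' Calibrate the intercept so the planted active rate matches prevalence
#'
#' Finds the global intercept shift for which the fraction of molecules
#' whose noise-free AggE meets the threshold equals the configured
#' prevalence (to the nearest achievable count). AggE is monotone in the
#' shift, so each molecule has a unique critical shift, located by
#' bisection; the population shift is the midpoint between the order
#' statistics bracketing the target count.
#'
#' @param molecules List of `vt_molecule`.
#' @param cfg A `vt_synth_config`.
#' @return The calibrated intercept shift (scalar).
#' @export
calibrate_alpha <- function(molecules, cfg) {
  crit <- vapply(molecules, function(m) {
    f <- function(a) agg_entropy(synth_true_p(m, cfg, a)) - cfg$threshold
    stats::uniroot(f, c(-30, 30), tol = 1e-8)$root
  }, 0)
  k <- max(1L, round(cfg$prevalence * length(molecules)))
  sc <- sort(crit)
  upper <- if (k < length(sc)) sc[k + 1] else sc[k] + 1
  (sc[k] + upper) / 2
}

#' Planted toxicity matrix for one molecule
#'
#' Per-endpoint incidence probability p_e = logistic(alpha_e + beta . d(mol)
#' + eps) with descriptor vector d(mol) and Gaussian logit noise eps;
#' binary incidences are then drawn Binomial(n_replicates, p_e).
#' Deterministic given the configured seed and the molecule id.
#'
#' @param mol A `vt_molecule`.
#' @param cfg A `vt_synth_config`.
#' @param alpha_shift Calibrated intercept shift (see [calibrate_alpha()]).
#' @return A `vt_toxmat` with attribute `"true_p"` (the noise-free
#'   probabilities).
#' @export
planted_toxicity <- function(mol, cfg, alpha_shift = 0) {
  idhash <- sum(utf8ToInt(mol$id) * seq_len(nchar(mol$id))) %% 1000003L
  set.seed((abs(cfg$seed) * 2011L + idhash * 7L) %% .Machine$integer.max)
  p0 <- synth_true_p(mol, cfg, alpha_shift)
  logit <- stats::qlogis(p0) + stats::rnorm(N_ENDPOINTS, 0, cfg$noise_scale)
  p <- stats::plogis(logit)
  x <- stats::rbinom(N_ENDPOINTS, cfg$n_replicates, p) / cfg$n_replicates
  tm <- toxicity_matrix(mol$id, x, n_replicates = cfg$n_replicates)
  attr(tm, "true_p") <- p0
  tm
}

#' Generate a full synthetic dataset
#'
#' Molecules, calibrated planted toxicity matrices, and a truth table with
#' both the noise-free ("true") and the sampled ("empirical") AggE and
#' activity call per chemical.
#'
#' @param cfg A `vt_synth_config`.
#' @return List with `molecules`, `tox` (list of `vt_toxmat`),
#'   `truth` (data.frame), `alpha_shift`, `config`.
#' @export
synth_dataset <- function(cfg = synth_config()) {
  mols <- synth_molecules(cfg)
  shift <- calibrate_alpha(mols, cfg)
  tox <- lapply(mols, planted_toxicity, cfg = cfg, alpha_shift = shift)
  true_agg <- vapply(tox, function(tm) agg_entropy(attr(tm, "true_p")), 0)
  emp_agg <- vapply(tox, agg_entropy, 0)
  truth <- data.frame(
    chemical_id = vapply(mols, function(m) m$id, ""),
    true_agg = true_agg, true_active = true_agg >= cfg$threshold,
    emp_agg = emp_agg, emp_active = emp_agg >= cfg$threshold,
    stringsAsFactors = FALSE)
  list(molecules = mols, tox = tox, truth = truth, alpha_shift = shift,
       config = cfg)
}

#' Write a synthetic dataset to disk
#'
#' PDB files (one per molecule), a wide-form toxicity CSV of the sampled
#' incidences, and a truth CSV with AggE values and activity calls.
#'
#' @param ds Result of [synth_dataset()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_synth_dataset <- function(ds, outdir) {
  dir.create(file.path(outdir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  for (m in ds$molecules) {
    write_pdb(m, file.path(outdir, "pdb", paste0(m$id, ".pdb")))
  }
  write_toxicity_csv(ds$tox, file.path(outdir, "toxicity.csv"))
  utils::write.csv(ds$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  invisible(outdir)
}
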