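# Bundled fixture molecules with idealized textbook geometry.
#
# Bond lengths/angles are exact by construction (tetrahedral cos = -1/3,
# methyl C-H 1.09, C-C 1.54), so symmetry-induced distance ties are exact
# and tie-splitting behaves deterministically.

.tetra_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

unitv <- function(v) v / sqrt(sum(v^2))

# Any unit vector perpendicular to a.
perp_unit <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(ref - sum(ref * a) * a)
}

# Three tetrahedral directions completing one given bond direction `a`
# (unit vector pointing from the atom toward its already-placed neighbor).
tetra_fan <- function(a, phase = 0) {
  p <- perp_unit(a)
  q <- cross3(a, p)
  th <- phase + c(0, 2 * pi / 3, 4 * pi / 3)
  t(vapply(th, function(t0) {
    -a / 3 + sqrt(8) / 3 * (cos(t0) * p + sin(t0) * q)
  }, numeric(3)))
}

# The two tetrahedral directions completing two given bond directions a, b.
tetra_pair <- function(a, b) {
  m <- unitv(-(a + b))
  n <- unitv(cross3(a, b))
  rbind(m / sqrt(3) + n * sqrt(2 / 3),
        m / sqrt(3) - n * sqrt(2 / 3))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Zigzag embedding of a heavy-atom chain; consecutive bond length is the sum
# of the two covalent radii (C-C comes out at 1.54).
chain_coords <- function(elements) {
  n <- length(elements)
  coords <- matrix(0, n, 3)
  half <- (109.47 / 2) * pi / 180
  for (i in seq_len(n)[-1]) {
    L <- covalent_radius(elements[i - 1]) + covalent_radius(elements[i])
    step <- c(sin(half), cos(half) * (-1)^i, 0) * L
    coords[i, ] <- coords[i - 1, ] + step
  }
  coords
}

.fixture_catalogue <- c(
  "methane", "methanol", "co2", "methyl_isothiocyanate",
  "perfluorodecane", "glycine_betaine",
  "chain_c3", "chain_c4", "chain_c5", "chain_c6", "chain_c8", "chain_c10"
)

#' Bundled idealized-geometry fixture molecules
#'
#' Deterministic molecules built from textbook bond lengths and exact
#' tetrahedral angles, so that e.g. the three methyl hydrogens of methyl
#' isothiocyanate are exactly equidistant from their carbon. Appending
#' `"_heavy"` to any name strips hydrogens (heavy-atom-only variant).
#'
#' @param name One of `"methane"`, `"methanol"`, `"co2"`,
#'   `"methyl_isothiocyanate"`, `"perfluorodecane"`, `"glycine_betaine"`,
#'   or `"chain_cN"` for N in 3,4,5,6,8,10.
#' @return A `vt_molecule`.
#' @examples
#' fixture_molecule("methane")
#' fixture_molecule("methyl_isothiocyanate")
#' @export
fixture_molecule <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  strip_h <- grepl("_heavy$", name)
  base <- sub("_heavy$", "", name)
  if (!(base %in% .fixture_catalogue)) {
    stop("unknown fixture '", name, "'; catalogue: ",
         paste(.fixture_catalogue, collapse = ", "),
         " (append _heavy for a hydrogen-free variant)")
  }
  mol <- switch(base,
    methane = {
      el <- c("C", rep("H", 4))
      xyz <- rbind(c(0, 0, 0), 1.09 * .tetra_dirs)
      molecule("methane", el, xyz, list(source = "fixture"))
    },
    co2 = {
      molecule("co2", c("C", "O", "O"),
               rbind(c(0, 0, 0), c(1.16, 0, 0), c(-1.16, 0, 0)),
               list(source = "fixture"))
    },
    methanol = {
      u <- .tetra_dirs[1, ]
      o <- 1.43 * u
      h_c <- 1.09 * .tetra_dirs[2:4, ]
      # O-H at 0.96 angstrom, H-O-C angle tetrahedral
      v <- u / 3 + perp_unit(u) * sqrt(8) / 3
      h_o <- o + 0.96 * v
      molecule("methanol", c("C", "O", "H", "H", "H", "H"),
               rbind(c(0, 0, 0), o, h_c, h_o), list(source = "fixture"))
    },
    methyl_isothiocyanate = {
      # CH3-N=C=S with a linear heavy-atom backbone along +x
      n <- c(1.47, 0, 0)
      c2 <- c(1.47 + 1.21, 0, 0)
      s <- c(1.47 + 1.21 + 1.56, 0, 0)
      fan <- tetra_fan(c(1, 0, 0))    # methyl H directions, away from N
      h <- 1.09 * fan
      molecule("methyl_isothiocyanate",
               c("C", "H", "H", "H", "N", "C", "S"),
               rbind(c(0, 0, 0), h, n, c2, s), list(source = "fixture"))
    },
    perfluorodecane = {
      nC <- 10
      cc <- chain_coords(rep("C", nC))
      el <- rep("C", nC)
      xyz <- cc
      for (i in seq_len(nC)) {
        if (i == 1 || i == nC) {
          a <- unitv(cc[if (i == 1) 2 else nC - 1, ] - cc[i, ])
          dirs <- tetra_fan(a)
        } else {
          a <- unitv(cc[i - 1, ] - cc[i, ])
          b <- unitv(cc[i + 1, ] - cc[i, ])
          dirs <- tetra_pair(a, b)
        }
        for (k in seq_len(nrow(dirs))) {
          el <- c(el, "F")
          xyz <- rbind(xyz, cc[i, ] + 1.35 * dirs[k, ])
        }
      }
      molecule("perfluorodecane", el, xyz, list(source = "fixture"))
    },
    glycine_betaine = {
      # (CH3)3 N+ -CH2-COO(-): quaternary nitrogen plus carboxylate
      el <- "N"; xyz <- matrix(0, 1, 3)
      cN <- 1.51
      cpos <- cN * .tetra_dirs
      for (k in 1:3) {           # three methyls
        el <- c(el, "C"); xyz <- rbind(xyz, cpos[k, ])
        fan <- tetra_fan(-.tetra_dirs[k, ], phase = 0.3)
        for (j in 1:3) {
          el <- c(el, "H"); xyz <- rbind(xyz, cpos[k, ] + 1.09 * fan[j, ])
        }
      }
      ch2 <- cpos[4, ]
      el <- c(el, "C"); xyz <- rbind(xyz, ch2)
      fan <- tetra_fan(-.tetra_dirs[4, ], phase = 0.1)
      ccx <- ch2 + 1.54 * fan[1, ]                  # carboxyl carbon
      el <- c(el, "H", "H")
      xyz <- rbind(xyz, ch2 + 1.09 * fan[2, ], ch2 + 1.09 * fan[3, ])
      el <- c(el, "C"); xyz <- rbind(xyz, ccx)
      b <- unitv(ch2 - ccx)
      p <- perp_unit(b)
      for (sgn in c(1, -1)) {   # two equivalent carboxylate oxygens
        d <- -b * 0.5 + p * sgn * sqrt(3) / 2
        el <- c(el, "O"); xyz <- rbind(xyz, ccx + 1.26 * d)
      }
      molecule("glycine_betaine", el, xyz, list(source = "fixture"))
    },
    {
      nC <- as.integer(sub("chain_c", "", base))
      molecule(base, rep("C", nC), chain_coords(rep("C", nC)),
               list(source = "fixture"))
    }
  )
  if (strip_h) {
    keep <- mol$atoms$element != "H"
    mol <- molecule(paste0(mol$id, "_heavy"), mol$atoms$element[keep],
                    as.matrix(mol$atoms[keep, c("x", "y", "z")]),
                    mol$provenance)
  }
  mol
}
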