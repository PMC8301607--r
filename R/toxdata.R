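# Toxicity matrices, aggregate entropy (AggE) and activity calls.
#
# A toxicity matrix is one chemical's vector of 18 developmental-endpoint
# incidence proportions (fraction of affected embryos among evaluable
# replicates at the highest tested concentration, 120 hpf). AggE condenses
# the 18 incidences into a single bits-scale toxicity summary; chemicals
# with AggE at or above the threshold (default 9.35) are called active.

N_ENDPOINTS <- 18L

#' Endpoint panel
#'
#' The 18 developmental endpoints with an optional grouping into correlation
#' groups. AggE pools incidences within a group (by max) before scoring, so
#' highly correlated endpoints are not double counted. Default: 18 singleton
#' groups.
#'
#' @param labels Character vector of 18 endpoint identifiers.
#' @param grouping List of integer/character vectors partitioning the 18
#'   endpoints.
#' @return A list of class `vt_panel`.
#' @export
endpoint_panel <- function(labels = sprintf("E%02d", 1:18),
                           grouping = as.list(seq_len(18))) {
  stopifnot(length(labels) == N_ENDPOINTS, !anyDuplicated(labels))
  idx <- lapply(grouping, function(g) {
    if (is.character(g)) g <- match(g, labels)
    g <- as.integer(g)
    if (anyNA(g) || any(g < 1L | g > N_ENDPOINTS)) stop("invalid grouping entry")
    g
  })
  all_idx <- sort(unname(unlist(idx)))
  if (!identical(all_idx, seq_len(N_ENDPOINTS))) {
    stop("grouping must partition all 18 endpoints exactly once")
  }
  structure(list(labels = labels, grouping = idx), class = "vt_panel")
}

#' Construct a toxicity matrix
#'
#' @param chemical_id Identifier string.
#' @param incidence Numeric vector of 18 incidence proportions in `[0, 1]`.
#' @param n_replicates Number of replicate embryos behind the proportions.
#' @param concentration_label Tested concentration (highest tested by
#'   convention).
#' @return A list of class `vt_toxmat`.
#' @export
toxicity_matrix <- function(chemical_id, incidence, n_replicates = 32L,
                            concentration_label = "64 uM") {
  incidence <- as.numeric(incidence)
  if (length(incidence) != N_ENDPOINTS) {
    stop("expected exactly ", N_ENDPOINTS, " endpoint incidences, got ",
         length(incidence))
  }
  if (anyNA(incidence) || any(incidence < 0 | incidence > 1)) {
    stop("incidence proportions must lie in [0, 1]")
  }
  structure(list(chemical_id = chemical_id, incidence = incidence,
                 n_replicates = as.integer(n_replicates),
                 concentration_label = concentration_label),
            class = "vt_toxmat")
}

#' Incidence proportions from a replicate-level binary table
#'
#' @param table Matrix or data.frame, replicates x 18 endpoints, entries
#'   0/1/NA (NA = not evaluable; excluded from numerator and denominator).
#' @param chemical_id Identifier for the resulting matrix.
#' @param concentration_label Passed through.
#' @return A `vt_toxmat` with `n_replicates = nrow(table)`.
#' @export
incidence_from_binary <- function(table, chemical_id = "chem",
                                  concentration_label = "64 uM") {
  m <- as.matrix(table)
  if (ncol(m) != N_ENDPOINTS) {
    stop("expected ", N_ENDPOINTS, " endpoint columns, got ", ncol(m))
  }
  if (!all(m %in% c(0, 1, NA))) stop("entries must be 0, 1 or NA")
  evaluable <- colSums(!is.na(m))
  if (any(evaluable == 0L)) {
    bad <- which(evaluable == 0L)[1]
    nm <- if (!is.null(colnames(m))) colnames(m)[bad] else paste0("column ", bad)
    stop("endpoint ", nm, " has zero evaluable replicates")
  }
  p <- colSums(m, na.rm = TRUE) / evaluable
  toxicity_matrix(chemical_id, p, n_replicates = nrow(m),
                  concentration_label = concentration_label)
}

# Binary Shannon entropy in bits, with 0 log 0 = 0.
binary_entropy <- function(q) {
  h <- numeric(length(q))
  inside <- q > 0 & q < 1
  qi <- q[inside]
  h[inside] <- -qi * log2(qi) - (1 - qi) * log2(1 - qi)
  h
}

#' Aggregate entropy (AggE) of a toxicity matrix
#'
#' Per correlation group g the member incidences are pooled by max into q_g,
#' scored by the monotone entropy ramp s(q) = H2(q) for q <= 1/2 and
#' 2 - H2(q) for q > 1/2 (H2 the binary Shannon entropy in bits), and the
#' group scores are summed. s is continuous and non-decreasing with s(0) = 0,
#' s(1/2) = 1, s(1) = 2, so AggE ranges over [0, 2 x number of groups]
#' ([0, 36] for singleton groups). The score lives in this one function so a
#' different aggregate-entropy definition can be swapped in.
#'
#' @param tm A `vt_toxmat`, or a bare numeric vector of 18 incidences.
#' @param panel A `vt_panel` (default: singleton groups).
#' @return AggE in bits.
#' @examples
#' agg_entropy(toxicity_matrix("x", rep(0.5, 18)))   # 18
#' @export
agg_entropy <- function(tm, panel = endpoint_panel()) {
  p <- if (inherits(tm, "vt_toxmat")) tm$incidence else as.numeric(tm)
  if (length(p) != N_ENDPOINTS) stop("expected 18 incidences")
  if (any(p < 0 | p > 1)) stop("incidence outside [0, 1]")
  q <- vapply(panel$grouping, function(g) max(p[g]), 0)
  s <- ifelse(q <= 0.5, binary_entropy(q), 2 - binary_entropy(q))
  sum(s)
}

#' Classify a chemical as active or inactive from its AggE
#'
#' Active if and only if AggE is at or above the threshold (the published
#' cut of 9.35 bits at the highest tested concentration; the threshold is
#' concentration dependent and therefore configurable).
#'
#' @param agg AggE value in bits (scalar or vector).
#' @param threshold Activity threshold in bits.
#' @param chemical_id Optional identifier(s) carried into the result.
#' @return Data frame with columns `chemical_id`, `agg_entropy`, `active`,
#'   `threshold`.
#' @export
classify <- function(agg, threshold = 9.35,
                     chemical_id = paste0("chem", seq_along(agg))) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (any(agg < 0)) stop("AggE must be non-negative")
  data.frame(chemical_id = chemical_id, agg_entropy = agg,
             active = agg >= threshold, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Read toxicity matrices from CSV (wide or long form)
#'
#' Wide form: `chemical_id`, 18 incidence columns, optional `n_replicates`
#' and `concentration_label`. Long form: `chemical_id`, `replicate`,
#' `endpoint`, `value` with binary values, converted per chemical via
#' [incidence_from_binary()].
#'
#' @param path CSV file path.
#' @return List of `vt_toxmat`.
#' @export
read_toxicity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("chemical_id", "replicate", "endpoint", "value") %in% names(df))) {
    eps <- sort(unique(df$endpoint))
    if (length(eps) != N_ENDPOINTS) {
      stop("long-form file has ", length(eps), " endpoints; expected 18")
    }
    return(lapply(split(df, df$chemical_id), function(d) {
      wide <- matrix(NA_real_, max(d$replicate), N_ENDPOINTS,
                     dimnames = list(NULL, eps))
      wide[cbind(d$replicate, match(d$endpoint, eps))] <- d$value
      incidence_from_binary(wide, chemical_id = d$chemical_id[1])
    }))
  }
  meta <- intersect(names(df), c("chemical_id", "n_replicates",
                                 "concentration_label"))
  ep_cols <- setdiff(names(df), meta)
  if (length(ep_cols) != N_ENDPOINTS) {
    stop("wide-form file has ", length(ep_cols),
         " endpoint columns; expected 18")
  }
  lapply(seq_len(nrow(df)), function(i) {
    toxicity_matrix(
      df$chemical_id[i], as.numeric(df[i, ep_cols]),
      n_replicates = if ("n_replicates" %in% meta) df$n_replicates[i] else 32L,
      concentration_label = if ("concentration_label" %in% meta)
        df$concentration_label[i] else "64 uM")
  })
}

#' Write toxicity matrices to wide-form CSV
#'
#' Lossless round-trip partner of [read_toxicity_csv()] (incidences survive
#' to better than 1e-9).
#'
#' @param tms List of `vt_toxmat`.
#' @param path Output path.
#' @param labels Endpoint column labels.
#' @return `path`, invisibly.
#' @export
write_toxicity_csv <- function(tms, path, labels = sprintf("E%02d", 1:18)) {
  df <- do.call(rbind, lapply(tms, function(tm) {
    row <- data.frame(chemical_id = tm$chemical_id, stringsAsFactors = FALSE)
    row[labels] <- as.list(tm$incidence)
    row$n_replicates <- tm$n_replicates
    row$concentration_label <- tm$concentration_label
    row
  }))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
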