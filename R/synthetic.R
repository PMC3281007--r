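#' Specification of a synthetic polypeptide
#'
#' Describes a toy single-chain structure built from ideal backbone
#' geometry: a list of secondary-structure blocks, optional Gaussian
#' coordinate noise, and the sequence source. Helix blocks use
#' (phi, psi) = (-57, -47), strand blocks (-120, +120); loop blocks draw
#' dihedrals uniformly from the polyproline/bridge region
#' (phi in (-170, -40), psi in (0, 50)), which the dihedral-window SSE
#' fallback classifies as coil.
#'
#' @param blocks list of `c(kind, length)` pairs or a data.frame with
#'   columns `kind` (`"helix"`, `"strand"`, `"loop"`) and `length`
#' @param noise_sd Gaussian coordinate noise (A), applied to every atom
#' @param sequence optional one-letter sequence; defaults to a random draw
#'   from the baseline background composition
#' @param seed RNG seed
#' @param protein_id identifier of the generated chain
#' @return object of class `cp_synthetic_spec`
#' @export
synthetic_spec <- function(blocks = list(c("helix", "12"), c("loop", "6"),
                                         c("strand", "8")),
                           noise_sd = 0, sequence = NULL, seed = 1L,
                           protein_id = "synth") {
  if (is.data.frame(blocks)) {
    kinds <- as.character(blocks$kind)
    lens <- as.integer(blocks$length)
  } else {
    kinds <- vapply(blocks, function(b) as.character(b[1]), character(1))
    lens <- vapply(blocks, function(b) as.integer(b[2]), integer(1))
  }
  stopifnot(all(kinds %in% c("helix", "strand", "loop")), all(lens >= 1L))
  structure(list(kinds = kinds, lengths = lens, noise_sd = noise_sd,
                 sequence = sequence, seed = as.integer(seed),
                 protein_id = protein_id),
            class = "cp_synthetic_spec")
}

# Ideal trans-peptide internal coordinates (A / degrees).
BACKBONE_GEOMETRY <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

block_dihedrals <- function(kinds, lengths) {
  phi <- psi <- numeric(0)
  for (b in seq_along(kinds)) {
    n <- lengths[b]
    ang <- switch(kinds[b],
                  helix = cbind(rep(-57, n), rep(-47, n)),
                  strand = cbind(rep(-120, n), rep(120, n)),
                  loop = cbind(stats::runif(n, -170, -40),
                               stats::runif(n, 0, 50)))
    phi <- c(phi, ang[, 1]); psi <- c(psi, ang[, 2])
  }
  list(phi = phi, psi = psi)
}

build_backbone <- function(phi, psi) {
  g <- BACKBONE_GEOMETRY
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                               g$b_c_n, g$a_ca_c_n, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                               g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

backbone_clashes <- function(bb, min_dist = 1.5) {
  xyz <- rbind(bb$N, bb$CA, bb$C, bb$O)
  n <- nrow(bb$N)
  owner <- rep(seq_len(n), 4)
  d <- cross_dist(xyz, xyz)
  apart <- abs(outer(owner, owner, "-")) >= 2
  any(d[apart] < min_dist)
}

#' Build a synthetic polypeptide structure
#'
#' Places an ideal backbone (N, CA, C, O per residue) by sequential
#' internal-coordinate construction from the block dihedrals, optionally
#' adds Gaussian coordinate noise, and returns a full [cp_structure] with
#' dihedrals and fallback SSE codes computed from the actual coordinates.
#' Self-clashing loop conformations are resampled (bounded retries).
#' Side chains are not built; descriptors run in backbone-only mode on
#' synthetic input. Per-residue B-factors are drawn at random and carry no
#' structural signal (a negative-control feature).
#'
#' @param spec a [synthetic_spec()]
#' @return a [cp_structure]
#' @export
build_polypeptide <- function(spec) {
  set.seed(spec$seed)
  n <- sum(spec$lengths)
  seq_aa <- spec$sequence
  if (is.null(seq_aa)) {
    seq_aa <- paste(sample(names(AA_BACKGROUND_COMPOSITION), n,
                           replace = TRUE,
                           prob = AA_BACKGROUND_COMPOSITION), collapse = "")
  }
  aa <- strsplit(seq_aa, "")[[1]]
  stopifnot(length(aa) == n)
  for (try in seq_len(50L)) {
    ang <- block_dihedrals(spec$kinds, spec$lengths)
    bb <- build_backbone(ang$phi, ang$psi)
    if (!backbone_clashes(bb)) break
    if (try == 50L) stop("could not build a clash-free backbone; simplify blocks")
  }
  if (spec$noise_sd > 0) {
    for (nm in names(bb)) {
      bb[[nm]] <- bb[[nm]] + matrix(stats::rnorm(3 * n, 0, spec$noise_sd),
                                    n, 3)
    }
  }
  bfac <- round(stats::rnorm(n, 10, 2), 2)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      seq_position = i,
      elety = c("N", "CA", "C", "O"),
      elesy = c("N", "C", "C", "O"),
      x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
      y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
      z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
      o = 1, b = bfac[i], stringsAsFactors = FALSE)
  }))
  residues <- data.frame(
    seq_position = seq_len(n), resno = seq_len(n), icode = "",
    aa = aa, x = bb$CA[, 1], y = bb$CA[, 2], z = bb$CA[, 3],
    b_factor_ca = bfac, sse8 = "-", phi = NA_real_, psi = NA_real_,
    stringsAsFactors = FALSE
  )
  st <- cp_structure(spec$protein_id, "A", residues, atoms,
                     source_path = "synthetic")
  st <- compute_dihedrals(st)
  st$residues$sse8 <- sse_fallback(st)
  st
}

#' Logistic viability label model
#'
#' @param intercept intercept beta0 on the log-odds scale
#' @param coef named coefficients over standardized features; the sign
#'   encodes the direction (e.g. a negative WCN coefficient makes unpacked
#'   residues viable)
#' @return object of class `cp_label_model`
#' @export
label_model <- function(intercept = 0,
                        coef = c(WCN = -2, RSA = 1, GNMF = 1)) {
  structure(list(intercept = intercept, coef = coef),
            class = "cp_label_model")
}

#' Plant viability labels from a logistic model
#'
#' P(viable at residue i) = logistic(beta0 + sum beta_f * z_f(i)) where z_f
#' are the per-protein standardized features named by the model
#' coefficients; labels are independent Bernoulli draws. Position 1 is
#' excluded (a CP there is the identity permutation).
#'
#' @param features per-residue feature table with `protein_id`,
#'   `seq_position` and the model's feature columns
#' @param model a [label_model()]
#' @param seed RNG seed
#' @return label data.frame (`protein_id`, `chain_id`, `site_position`,
#'   `viable`, `source`) as from [read_cp_labels()]
#' @export
plant_viability_labels <- function(features, model = label_model(),
                                   seed = 1L) {
  needed <- names(model$coef)
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks label-model column(s): ",
         paste(missing, collapse = ", "))
  }
  z <- standardize_features(as.matrix(features[, needed, drop = FALSE]),
                            features$protein_id)
  z[is.na(z)] <- 0
  eta <- model$intercept + as.numeric(z %*% model$coef)
  set.seed(seed)
  viable <- stats::runif(length(eta)) < stats::plogis(eta)
  keep <- features$seq_position > 1L
  data.frame(
    protein_id = features$protein_id[keep],
    chain_id = if ("chain_id" %in% names(features))
      features$chain_id[keep] else "A",
    site_position = features$seq_position[keep],
    viable = viable[keep],
    source = "synthetic-logistic",
    stringsAsFactors = FALSE
  )
}

#' Generate background and enriched site sequence groups
#'
#' The background group is drawn i.i.d. from the fixed baseline amino-acid
#' composition; the site group is drawn from the baseline reweighted by the
#' enrichment multipliers and renormalised. Background sequences default to
#' protein length (250 residues) while site sequences default to the
#' six-residue segment representation, mirroring the whole-protein versus
#' CP-site-segment contrast the propensity statistics are designed for.
#'
#' @param enrichment_map named positive multipliers per amino acid (missing
#'   names mean 1)
#' @param n_seqs sequences per group
#' @param site_length site segment length (default 6)
#' @param background_length background sequence length (default 250)
#' @param seed RNG seed
#' @return list with `background`, `site` (character vectors) and the
#'   normalised `site_composition`
#' @export
generate_sequence_groups <- function(enrichment_map = c(P = 1.32),
                                     n_seqs = 1000L, site_length = 6L,
                                     background_length = 250L, seed = 1L) {
  stopifnot(all(enrichment_map > 0))
  base <- AA_BACKGROUND_COMPOSITION / sum(AA_BACKGROUND_COMPOSITION)
  mult <- stats::setNames(rep(1, length(base)), names(base))
  mult[names(enrichment_map)] <- enrichment_map
  site_p <- base * mult
  site_p <- site_p / sum(site_p)
  set.seed(seed)
  draw <- function(m, len, p) {
    vapply(seq_len(m), function(i) {
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  }
  list(background = draw(n_seqs, background_length, base),
       site = draw(n_seqs, site_length, site_p),
       site_composition = site_p)
}

#' Generate a small labelled synthetic study set
#'
#' Convenience wrapper producing `n_proteins` helix-loop-strand chains,
#' their feature matrices and logistic-planted viability labels - the
#' self-contained testbed for the full training/evaluation pipeline.
#'
#' @param n_proteins number of chains
#' @param n_residues approximate residues per chain (split into blocks)
#' @param model a [label_model()]
#' @param seed RNG seed
#' @param config a [descriptor_config()]
#' @return list with `structures`, `features` (row-bound feature table) and
#'   `labels`
#' @export
synthetic_study <- function(n_proteins = 10L, n_residues = 60L,
                            model = label_model(), seed = 1L,
                            config = descriptor_config()) {
  structures <- vector("list", n_proteins)
  feats <- vector("list", n_proteins)
  third <- max(4L, round(n_residues / 5))
  for (i in seq_len(n_proteins)) {
    spec <- synthetic_spec(
      blocks = list(c("helix", third * 2), c("loop", third),
                    c("strand", third), c("loop", n_residues - third * 4)),
      noise_sd = 0.15, seed = seed + 1000L * i,
      protein_id = sprintf("synth%02d", i))
    structures[[i]] <- build_polypeptide(spec)
    feats[[i]] <- compute_feature_matrix(structures[[i]], config)
  }
  features <- do.call(rbind, feats)
  labels <- plant_viability_labels(features, model, seed = seed + 7L)
  list(structures = structures, features = features, labels = labels)
}
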