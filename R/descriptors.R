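#' Descriptor configuration
#'
#' Tunable parameters for the tertiary-structure residue descriptors. The
#' defaults are the working values of the underlying measures: a 6.4 A
#' contact-number radius (the radius with the best discriminating power for
#' CP viability), an 8 A closeness contact-graph cutoff, a 10 A Gaussian
#' network model cutoff, a 1.4 A solvent probe, a 3.5 A donor-acceptor
#' hydrogen-bond distance, RSA < 10% defining buried residues, and an
#' inverse-square farness weight (q = 2).
#'
#' @param cn_radius contact-number sphere radius (A)
#' @param closeness_edge_cutoff contact-graph edge cutoff (A)
#' @param gnm_cutoff Kirchhoff connectivity cutoff (A)
#' @param sasa_probe solvent probe radius (A)
#' @param sasa_points sphere sample points per atom
#' @param hbond_da_max maximum donor-acceptor distance (A)
#' @param buried_rsa_threshold RSA percentage below which a residue is buried
#' @param farness_weight_exponent exponent q of the farness weight d^(-q)
#' @return object of class `cp_descriptor_config`
#' @export
descriptor_config <- function(cn_radius = 6.4,
                              closeness_edge_cutoff = 8.0,
                              gnm_cutoff = 10.0,
                              sasa_probe = 1.4,
                              sasa_points = 960L,
                              hbond_da_max = 3.5,
                              buried_rsa_threshold = 10,
                              farness_weight_exponent = 2) {
  stopifnot(cn_radius > 0, closeness_edge_cutoff > 0, gnm_cutoff > 0,
            sasa_probe > 0, sasa_points >= 10,
            hbond_da_max > 0,
            buried_rsa_threshold > 0, buried_rsa_threshold < 100)
  structure(
    list(cn_radius = cn_radius,
         closeness_edge_cutoff = closeness_edge_cutoff,
         gnm_cutoff = gnm_cutoff,
         sasa_probe = sasa_probe,
         sasa_points = as.integer(sasa_points),
         hbond_da_max = hbond_da_max,
         buried_rsa_threshold = buried_rsa_threshold,
         farness_weight_exponent = farness_weight_exponent),
    class = "cp_descriptor_config"
  )
}

atom_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Per-atom and per-residue solvent accessible surface area
#'
#' Shrake-Rupley sphere sampling over heavy atoms: each atom is covered with
#' a deterministic quasi-uniform point shell at radius vdW + probe; a point
#' is accessible when it lies outside every neighbouring atom's probe-expanded
#' sphere. RSA is residue SASA normalised by a fixed published
#' maximum-accessible-area (Gly-X-Gly) table, in percent.
#'
#' @param structure a [cp_structure]
#' @param config a [descriptor_config()]
#' @param n_points override the number of sphere points (e.g. for
#'   high-resolution cross-checks)
#' @return list with `atom_sasa` (A^2 per heavy atom, in `structure$atoms`
#'   row order), `residue_sasa`, and `rsa` (percent, per residue)
#' @export
sasa_rsa <- function(structure, config = descriptor_config(),
                     n_points = NULL) {
  np <- if (is.null(n_points)) config$sasa_points else as.integer(n_points)
  xyz <- atom_matrix(structure)
  radii <- vdw_radius(structure$atoms$elesy) + config$sasa_probe
  m <- nrow(xyz)
  sphere <- fibonacci_sphere(np)
  d <- cross_dist(xyz, xyz)
  atom_sasa <- numeric(m)
  for (i in seq_len(m)) {
    nb <- which(d[i, ] < radii[i] + radii & seq_len(m) != i)
    if (length(nb) == 0L) {
      atom_sasa[i] <- 4 * pi * radii[i]^2
      next
    }
    pts <- sphere * radii[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    pd2 <- cross_dist(pts, xyz[nb, , drop = FALSE])
    buried <- rowSums(pd2 < rep(radii[nb], each = np)) > 0
    atom_sasa[i] <- 4 * pi * radii[i]^2 * mean(!buried)
  }
  res_sasa <- as.numeric(tapply(atom_sasa, structure$atoms$seq_position, sum))
  res_sasa <- res_sasa[match(seq_len(n_residues(structure)),
                             sort(unique(structure$atoms$seq_position)))]
  aa <- structure$residues$aa
  maxasa <- MAX_ASA[aa]
  if (anyNA(maxasa)) {
    warning("unknown residue type(s); using Gly reference area")
    maxasa[is.na(maxasa)] <- MAX_ASA["G"]
  }
  list(atom_sasa = atom_sasa,
       residue_sasa = res_sasa,
       rsa = 100 * res_sasa / unname(maxasa))
}

#' Residue depth from the solvent-accessible surface
#'
#' Depth of residue i is the distance from its C-alpha to the nearest
#' solvent-accessible heavy atom (atom SASA > 0). When that nearest
#' accessible atom belongs to residue i itself, the residue sits at the
#' surface and its depth is 0.
#'
#' @inheritParams sasa_rsa
#' @param sasa optional precomputed [sasa_rsa()] result
#' @return numeric vector of depths (A)
#' @export
residue_depth <- function(structure, config = descriptor_config(),
                          sasa = NULL) {
  if (is.null(sasa)) sasa <- sasa_rsa(structure, config)
  acc <- which(sasa$atom_sasa > 1e-9)
  if (length(acc) == 0L) {
    stop("no solvent-accessible atom in chain; cannot define depth")
  }
  ca <- ca_coords(structure)
  d <- cross_dist(ca, atom_matrix(structure)[acc, , drop = FALSE])
  owner <- structure$atoms$seq_position[acc]
  vapply(seq_len(nrow(ca)), function(i) {
    j <- which.min(d[i, ])
    if (owner[j] == i) 0 else d[i, j]
  }, numeric(1))
}

#' Distance from each C-alpha to the chain centroid
#'
#' The centroid is the unweighted mean of all C-alpha coordinates (the
#' package's residue-location convention); `mass_weighted = TRUE` uses the
#' all-heavy-atom centroid instead.
#'
#' @inheritParams sasa_rsa
#' @param mass_weighted use the mean of all heavy atoms as the centre
#' @return numeric vector of centroid distances CM (A)
#' @export
centroid_distance <- function(structure, mass_weighted = FALSE) {
  ca <- ca_coords(structure)
  centre <- if (mass_weighted) colMeans(atom_matrix(structure)) else colMeans(ca)
  sqrt(rowSums(sweep(ca, 2, centre)^2))
}

#' Contact number
#'
#' Number of heavy atoms belonging to *other* residues within `cn_radius`
#' of each residue's C-alpha.
#'
#' @inheritParams sasa_rsa
#' @return integer vector CN
#' @export
contact_number <- function(structure, config = descriptor_config()) {
  ca <- ca_coords(structure)
  d <- cross_dist(ca, atom_matrix(structure))
  other <- outer(structure$residues$seq_position,
                 structure$atoms$seq_position, "!=")
  as.integer(rowSums(d <= config$cn_radius & other))
}

#' Weighted contact number
#'
#' WCN(i) = sum over j != i of d(CA_i, CA_j)^(-2); no distance cutoff.
#'
#' @inheritParams sasa_rsa
#' @return numeric vector WCN
#' @export
weighted_contact_number <- function(structure) {
  ca <- ca_coords(structure)
  d <- cross_dist(ca, ca)
  diag(d) <- Inf
  if (any(d < 1e-9)) stop("coincident C-alpha pair; WCN undefined")
  rowSums(d^-2)
}

contact_graph <- function(structure, cutoff) {
  ca <- ca_coords(structure)
  d <- cross_dist(ca, ca)
  adj <- (d <= cutoff)
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Closeness centrality on the C-alpha contact graph
#'
#' Harmonic closeness on a unit-edge-length contact graph (edge when the
#' C-alpha distance is within the cutoff): closeness(i) =
#' (1/(n-1)) * sum over j != i of 1/sp(i, j), with unreachable residues
#' contributing 0. Well defined on disconnected graphs.
#'
#' @inheritParams sasa_rsa
#' @return numeric vector of closeness values
#' @export
closeness_centrality <- function(structure, config = descriptor_config()) {
  g <- contact_graph(structure, config$closeness_edge_cutoff)
  sp <- igraph::distances(g)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[is.infinite(sp)] <- 0
  rowSums(inv) / (nrow(sp) - 1)
}

#' Intra-molecular hydrogen bond count (heavy-atom criterion)
#'
#' Counts geometric hydrogen bonds without hydrogen placement: a bond exists
#' between an N/O atom of residue i and an N/O atom of a different residue j
#' when their distance is at most `hbond_da_max`, excluding pairs where both
#' atoms are backbone N/O of sequence neighbours (the trivial i, i+1 peptide
#' contact). Each bond increments the count of both residues.
#'
#' @inheritParams sasa_rsa
#' @return integer vector of hydrogen-bond counts
#' @export
hydrogen_bond_count <- function(structure, config = descriptor_config()) {
  at <- structure$atoms
  no <- which(at$elesy %in% c("N", "O"))
  counts <- integer(n_residues(structure))
  if (length(no) < 2L) return(counts)
  xyz <- atom_matrix(structure)[no, , drop = FALSE]
  d <- cross_dist(xyz, xyz)
  res <- at$seq_position[no]
  bb <- at$elety[no] %in% c("N", "O", "OXT")
  for (a in seq_along(no)) {
    for (b in seq_along(no)) {
      if (b <= a) next
      if (res[a] == res[b]) next
      if (d[a, b] > config$hbond_da_max) next
      if (abs(res[a] - res[b]) == 1L && bb[a] && bb[b]) next
      counts[res[a]] <- counts[res[a]] + 1L
      counts[res[b]] <- counts[res[b]] + 1L
    }
  }
  counts
}

#' Gaussian network model mean-square fluctuations
#'
#' Builds the Kirchhoff (connectivity) matrix on C-alpha nodes with the given
#' cutoff, takes its pseudo-inverse discarding the single zero mode, and
#' returns the unnormalised diagonal as the per-residue fluctuation GNM-F.
#'
#' @inheritParams sasa_rsa
#' @return numeric vector GNM-F
#' @export
gnm_fluctuation <- function(structure, config = descriptor_config()) {
  n <- n_residues(structure)
  if (n < 3L) stop("GNM needs at least 3 residues")
  ca <- ca_coords(structure)
  d <- cross_dist(ca, ca)
  gamma <- -(d <= config$gnm_cutoff) * 1
  diag(gamma) <- 0
  diag(gamma) <- -rowSums(gamma)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(gamma < 0, mode = "undirected"))
  if (comp$no > 1L) {
    stop("contact network disconnected at this cutoff; increase gnm_cutoff")
  }
  eig <- eigen(gamma, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-10
  v <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  rowSums(sweep(v^2, 2, lam, "/"))
}

#' Core residue sets
#'
#' The four working definitions of the buried/hydrophobic core: `B` (buried,
#' RSA below the threshold), `H` (hydrophobic amino acids of the three-class
#' table), and their union and intersection.
#'
#' @inheritParams sasa_rsa
#' @param kind one of `"B"`, `"H"`, `"BuH"` (union), `"BnH"` (intersection)
#' @param rsa per-residue RSA percentages (required for kinds involving B)
#' @return list with `kind` and `members` (seq_positions)
#' @export
core_set <- function(structure, kind = c("B", "H", "BuH", "BnH"),
                     rsa = NULL, config = descriptor_config()) {
  kind <- match.arg(kind)
  B <- H <- NULL
  if (kind %in% c("B", "BuH", "BnH")) {
    if (is.null(rsa)) stop("RSA values required for core set ", kind)
    B <- which(rsa < config$buried_rsa_threshold)
  }
  if (kind %in% c("H", "BuH", "BnH")) {
    H <- which(structure$residues$aa %in% hydrophobic_residues())
  }
  members <- switch(kind, B = B, H = H,
                    BuH = sort(union(B, H)), BnH = sort(intersect(B, H)))
  if (length(members) == 0L) {
    stop(sprintf("core set %s is empty; farness/DIS undefined", kind))
  }
  list(kind = kind, members = as.integer(members))
}

#' Mean distance to a core set
#'
#' DIS(i) = arithmetic mean over core members j != i of d(CA_i, CA_j).
#' For a residue whose core consists of itself alone the value is NA.
#'
#' @inheritParams sasa_rsa
#' @param core a [core_set()]
#' @return numeric vector DIS (A)
#' @export
mean_core_distance <- function(structure, core) {
  ca <- ca_coords(structure)
  d <- cross_dist(ca, ca[core$members, , drop = FALSE])
  vapply(seq_len(nrow(ca)), function(i) {
    keep <- core$members != i
    if (!any(keep)) return(NA_real_)
    mean(d[i, keep])
  }, numeric(1))
}

#' Farness from a core set
#'
#' Inverse weighted harmonic aggregation of distances from residue i to the
#' core G: F(i, G) = 1 / sum over j in G, j != i of W(j) / d_ij with weight
#' W(j) = d_ij^(-q). With the default q = 2 each core member contributes
#' d_ij^(-3); q = 0 recovers the plain unnormalised harmonic-mean form.
#' Large F means far from the core.
#'
#' @inheritParams sasa_rsa
#' @param core a [core_set()]
#' @param q weight exponent
#' @return numeric vector F
#' @export
farness <- function(structure, core, q = 2) {
  ca <- ca_coords(structure)
  d <- cross_dist(ca, ca[core$members, , drop = FALSE])
  vapply(seq_len(nrow(ca)), function(i) {
    keep <- core$members != i
    if (!any(keep)) return(NA_real_)
    dd <- d[i, keep]
    if (any(dd < 1e-9)) stop("zero distance to a core member; farness undefined")
    1 / sum(dd^-(q + 1))
  }, numeric(1))
}

#' Assemble the per-residue feature matrix
#'
#' Computes the full tertiary descriptor set (RSA, depth, CM, hydrogen
#' bonds, closeness, CN, WCN, C-alpha B-factor, GNM-F, mean core distances
#' DIS_b / DIS_hpho, and farness from the four core definitions), plus the
#' windowed sequence/SSE propensity features when score tables are supplied.
#' Descriptors whose core set is empty yield an all-NA column with a warning;
#' NA is the documented undefined-value sentinel and is excluded from
#' standardization downstream.
#'
#' @inheritParams sasa_rsa
#' @param dssp_text optional DSSP output for the 8-state SSE assignment
#' @param score_tables optional named list of propensity score tables
#'   (`aa`, `class3`, `class5`, `sse8`), see [build_score_table()]
#' @param k propensity window half-width
#' @return data.frame with `protein_id`, `chain_id`, `seq_position`, `resno`,
#'   `icode`, `aa`, `sse8` and one column per feature
#' @export
compute_feature_matrix <- function(structure, config = descriptor_config(),
                                   dssp_text = NULL, score_tables = NULL,
                                   k = 3L) {
  if (!is.null(dssp_text)) structure <- assign_sse(structure, dssp_text)
  sasa <- sasa_rsa(structure, config)
  rsa <- sasa$rsa
  q <- config$farness_weight_exponent
  core_col <- function(kind, fun) {
    tryCatch(fun(core_set(structure, kind, rsa = rsa, config = config)),
             error = function(e) {
               warning(sprintf("%s: %s", kind, conditionMessage(e)))
               rep(NA_real_, n_residues(structure))
             })
  }
  out <- data.frame(
    protein_id = structure$protein_id,
    chain_id = structure$chain_id,
    seq_position = structure$residues$seq_position,
    resno = structure$residues$resno,
    icode = structure$residues$icode,
    aa = structure$residues$aa,
    sse8 = structure$residues$sse8,
    RSA = rsa,
    depth = residue_depth(structure, config, sasa = sasa),
    CM = centroid_distance(structure),
    HB = hydrogen_bond_count(structure, config),
    closeness = closeness_centrality(structure, config),
    CN = contact_number(structure, config),
    WCN = weighted_contact_number(structure),
    Bfactor = structure$residues$b_factor_ca,
    GNMF = gnm_fluctuation(structure, config),
    DIS_b = core_col("B", function(cs) mean_core_distance(structure, cs)),
    DIS_hpho = core_col("H", function(cs) mean_core_distance(structure, cs)),
    F_b = core_col("B", function(cs) farness(structure, cs, q)),
    F_hpho = core_col("H", function(cs) farness(structure, cs, q)),
    F_bUh = core_col("BuH", function(cs) farness(structure, cs, q)),
    F_bIh = core_col("BnH", function(cs) farness(structure, cs, q)),
    stringsAsFactors = FALSE
  )
  if (!is.null(score_tables)) {
    prop <- residue_propensity_features(structure, score_tables, k = k)
    out <- cbind(out, prop)
  }
  out
}

#' Names of the tertiary descriptor columns
#' @return character vector
#' @export
tertiary_feature_names <- function() {
  c("RSA", "depth", "CM", "HB", "closeness", "CN", "WCN", "Bfactor",
    "GNMF", "DIS_b", "DIS_hpho", "F_b", "F_hpho", "F_bUh", "F_bIh")
}

#' Write a feature matrix as TSV
#' @param features data.frame from [compute_feature_matrix()]
#' @param path output file
#' @param header_lines optional provenance comment lines (prefixed `#`)
#' @export
write_feature_tsv <- function(features, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix TSV written by [write_feature_tsv()]
#' @param path input file
#' @export
read_feature_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
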