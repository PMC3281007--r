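# Fixtures built in code and independent brute-force oracles.

pdb_line <- function(serial, name, resname, chain, resno, xyz, occ = 1,
                     b = 10, element = substr(name, 1, 1), altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), altloc,
          resname, chain, resno, xyz[1], xyz[2], xyz[3], occ, b, element)
}

# Hand-built 3-residue chain A fixture with full backbone.
fixture_pdb_3res <- function() {
  lines <- character(0)
  coords <- list(
    ALA = list(N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.009, 1.42, 0),
               O = c(1.251, 2.39, 0)),
    GLY = list(N = c(3.332, 1.536, 0), CA = c(4.0, 2.78, 0.2),
               C = c(5.45, 2.62, 0.65), O = c(5.9, 1.5, 0.9)),
    SER = list(N = c(6.2, 3.7, 0.75), CA = c(7.62, 3.72, 1.1),
               C = c(8.3, 5.05, 0.85), O = c(7.7, 6.1, 1.05))
  )
  s <- 1L
  for (r in seq_along(coords)) {
    for (nm in names(coords[[r]])) {
      lines <- c(lines, pdb_line(s, nm, names(coords)[r], "A", r,
                                 coords[[r]][[nm]], b = 10 + r))
      s <- s + 1L
    }
  }
  c(lines, "END")
}

# n-residue random "bead" structure: one C-alpha atom per residue placed in
# a box, suitable for descriptor oracles.
random_bead_structure <- function(n, seed, box = 18, sequence = NULL) {
  set.seed(seed)
  repeat {
    xyz <- matrix(runif(3 * n, 0, box), n, 3)
    if (min(dist(xyz)) > 1.0) break
  }
  aa <- if (is.null(sequence)) {
    sample(cpsite::AA_ALPHABET, n, replace = TRUE)
  } else strsplit(sequence, "")[[1]]
  residues <- data.frame(
    seq_position = seq_len(n), resno = seq_len(n), icode = "",
    aa = aa, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b_factor_ca = round(runif(n, 5, 50), 2),
    sse8 = "-", phi = NA_real_, psi = NA_real_,
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    seq_position = seq_len(n), elety = "CA", elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
    b = residues$b_factor_ca, stringsAsFactors = FALSE
  )
  cpsite::cp_structure(sprintf("bead%d", seed), "A", residues, atoms)
}

rigid_transform <- function(structure, seed = 1) {
  set.seed(seed)
  rot <- {
    m <- matrix(rnorm(9), 3, 3); q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  shift <- runif(3, -20, 20)
  tx <- function(df) {
    new <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    new <- sweep(new, 2, shift, "+")
    df$x <- new[, 1]; df$y <- new[, 2]; df$z <- new[, 3]
    df
  }
  structure$residues <- tx(structure$residues)
  structure$atoms <- tx(structure$atoms)
  structure
}

# --- independent O(n^2)/graph-search oracles -------------------------------

bf_dist <- function(a, b) sqrt(sum((a - b)^2))

bf_contact_number <- function(structure, radius) {
  res <- structure$residues
  at <- structure$atoms
  vapply(seq_len(nrow(res)), function(i) {
    ca <- as.numeric(res[i, c("x", "y", "z")])
    cnt <- 0L
    for (j in seq_len(nrow(at))) {
      if (at$seq_position[j] == i) next
      if (bf_dist(ca, as.numeric(at[j, c("x", "y", "z")])) <= radius) {
        cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
}

bf_wcn <- function(structure) {
  ca <- as.matrix(structure$residues[, c("x", "y", "z")])
  n <- nrow(ca)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i) s <- s + bf_dist(ca[i, ], ca[j, ])^-2
    }
    s
  }, numeric(1))
}

bf_closeness <- function(structure, cutoff) {
  ca <- as.matrix(structure$residues[, c("x", "y", "z")])
  n <- nrow(ca)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && bf_dist(ca[i, ], ca[j, ]) <= cutoff) adj[i, j] <- TRUE
  }
  vapply(seq_len(n), function(i) {
    # breadth-first search from i
    depth <- rep(NA_integer_, n)
    depth[i] <- 0L
    frontier <- i
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ])) {
          if (is.na(depth[v])) { depth[v] <- depth[u] + 1L; nxt <- c(nxt, v) }
        }
      }
      frontier <- nxt
    }
    s <- 0
    for (j in seq_len(n)) if (j != i && !is.na(depth[j])) s <- s + 1 / depth[j]
    s / (n - 1)
  }, numeric(1))
}

bf_hbond <- function(structure, dmax) {
  at <- structure$atoms
  no <- which(at$elesy %in% c("N", "O"))
  counts <- integer(nrow(structure$residues))
  if (length(no) < 2) return(counts)
  for (ii in seq_along(no)) for (jj in seq_along(no)) {
    if (jj <= ii) next
    a <- no[ii]; b <- no[jj]
    ri <- at$seq_position[a]; rj <- at$seq_position[b]
    if (ri == rj) next
    d <- bf_dist(as.numeric(at[a, c("x", "y", "z")]),
                 as.numeric(at[b, c("x", "y", "z")]))
    if (d > dmax) next
    bb_a <- at$elety[a] %in% c("N", "O", "OXT")
    bb_b <- at$elety[b] %in% c("N", "O", "OXT")
    if (abs(ri - rj) == 1 && bb_a && bb_b) next
    counts[ri] <- counts[ri] + 1L
    counts[rj] <- counts[rj] + 1L
  }
  counts
}

bf_dis <- function(structure, members) {
  ca <- as.matrix(structure$residues[, c("x", "y", "z")])
  vapply(seq_len(nrow(ca)), function(i) {
    js <- setdiff(members, i)
    if (length(js) == 0) return(NA_real_)
    mean(vapply(js, function(j) bf_dist(ca[i, ], ca[j, ]), numeric(1)))
  }, numeric(1))
}

bf_farness <- function(structure, members, q) {
  ca <- as.matrix(structure$residues[, c("x", "y", "z")])
  vapply(seq_len(nrow(ca)), function(i) {
    js <- setdiff(members, i)
    if (length(js) == 0) return(NA_real_)
    s <- 0
    for (j in js) {
      d <- bf_dist(ca[i, ], ca[j, ])
      s <- s + d^(-q) / d
    }
    1 / s
  }, numeric(1))
}

# GNM oracle through an independent pseudo-inverse route (MASS::ginv).
bf_gnm <- function(structure, cutoff) {
  ca <- as.matrix(structure$residues[, c("x", "y", "z")])
  n <- nrow(ca)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && bf_dist(ca[i, ], ca[j, ]) <= cutoff) k[i, j] <- -1
  }
  diag(k) <- -rowSums(k)
  diag(MASS::ginv(k))
}

# SASA oracle: random (seeded) sphere points instead of the deterministic
# spiral, at high resolution; fresh directions per atom so Monte Carlo
# errors are independent across atoms.
bf_sasa <- function(structure, probe, n_points, seed = 99) {
  set.seed(seed)
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- ifelse(at$elesy == "N", 1.55,
                  ifelse(at$elesy == "O", 1.52,
                         ifelse(at$elesy == "S", 1.80, 1.70))) + probe
  m <- nrow(xyz)
  sapply(seq_len(m), function(i) {
    z <- matrix(rnorm(3 * n_points), n_points, 3)
    pts0 <- z / sqrt(rowSums(z^2))
    pts <- sweep(pts0 * radii[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(m)) {
      if (j == i) next
      dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
      free <- free & dj >= radii[j]
    }
    4 * pi * radii[i]^2 * mean(free)
  })
}

# Labelled feature table for classifier tests: two informative features.
separable_case <- function(n = 80, seed = 5, gap = 3) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  x <- cbind(f1 = rnorm(n) + gap * y, f2 = rnorm(n) + gap * y)
  list(x = x, y = y)
}
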