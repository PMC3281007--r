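#' Pattern catalogs
#'
#' A catalog defines the symbol alphabet over which pattern frequencies are
#' counted: single amino acids (`aa`), the three-class and five-class
#' physiochemical reductions (`class3`, `class5`), or 8-state secondary
#' structure codes (`sse8`). Setting `pair_gap` switches to pair patterns:
#' `pair_gap = 1` counts adjacent di-symbol patterns, `pair_gap = g` counts
#' coupled pairs (s_i, s_{i+g}).
#'
#' @param kind one of `"aa"`, `"class3"`, `"class5"`, `"sse8"`
#' @param pair_gap `NULL` for single-symbol patterns, or an integer gap
#' @return object of class `cp_catalog`
#' @export
pattern_catalog <- function(kind = c("aa", "class3", "class5", "sse8"),
                            pair_gap = NULL) {
  kind <- match.arg(kind)
  map <- switch(kind,
                aa = stats::setNames(AA_ALPHABET, AA_ALPHABET),
                class3 = AA_CLASS3,
                class5 = AA_CLASS5,
                sse8 = stats::setNames(SSE8_ALPHABET, SSE8_ALPHABET))
  alphabet <- sort(unique(unname(map)))
  if (!is.null(pair_gap)) {
    pair_gap <- as.integer(pair_gap)
    stopifnot(pair_gap >= 1L)
  }
  structure(list(kind = kind, map = map, alphabet = alphabet,
                 pair_gap = pair_gap,
                 arity = if (is.null(pair_gap)) 1L else 2L),
            class = "cp_catalog")
}

catalog_symbols <- function(catalog) {
  if (catalog$arity == 1L) return(catalog$alphabet)
  as.vector(outer(catalog$alphabet, catalog$alphabet, paste0))
}

# Map a residue-symbol string to catalog symbols; unknown symbols become NA.
map_symbols <- function(x, catalog) {
  s <- if (length(x) == 1L && nchar(x[1]) > 1L) strsplit(x, "")[[1]] else x
  out <- unname(catalog$map[s])
  out
}

#' Extract CP-site representative segments
#'
#' A site at position s (first residue of the permuted sequence; the cleavage
#' point lies between s-1 and s) is represented by the 2k-residue window
#' covering positions s-k .. s+k-1. Positions beyond either chain end are
#' omitted, giving a truncated segment.
#'
#' @param x a [cp_structure] or a character string/vector of residue symbols
#' @param sites integer site positions (each > 1 and <= chain length)
#' @param k half-width; `k = 3` is the standard six-residue representation,
#'   `k = 10` the wide exploratory window
#' @param what `"aa"` or `"sse8"` when `x` is a structure
#' @return list of segments; each has `site_position`, `positions`, `symbols`
#' @export
extract_segments <- function(x, sites, k = 3L, what = c("aa", "sse8")) {
  what <- match.arg(what)
  if (inherits(x, "cp_structure")) {
    symbols <- x$residues[[if (what == "aa") "aa" else "sse8"]]
  } else {
    symbols <- if (length(x) == 1L) strsplit(x, "")[[1]] else x
  }
  n <- length(symbols)
  stopifnot(k >= 1L)
  lapply(sites, function(s) {
    if (s <= 1L || s > n) {
      stop(sprintf("site position %d out of range (2..%d)", s, n))
    }
    pos <- max(1L, s - k):min(n, s + k - 1L)
    list(site_position = as.integer(s), positions = pos,
         symbols = symbols[pos])
  })
}

segment_strings <- function(segments) {
  vapply(segments, function(s) paste(s$symbols, collapse = ""), character(1))
}

#' Per-pattern occurrence frequencies in one polypeptide
#'
#' Single-symbol kinds: count/length. Pair kinds with gap g: count of
#' (s_i, s_{i+g}) pairs divided by (length - g). Sequences too short for the
#' pattern give all-zero frequencies.
#'
#' @param polypeptide character string or symbol vector (amino acids or SSE
#'   codes, matching the catalog kind)
#' @param catalog a [pattern_catalog()]
#' @return named numeric vector over the catalog's full symbol set
#' @export
pattern_frequencies <- function(polypeptide, catalog) {
  syms <- map_symbols(polypeptide, catalog)
  syms <- syms[!is.na(syms)]
  all_pat <- catalog_symbols(catalog)
  out <- stats::setNames(numeric(length(all_pat)), all_pat)
  n <- length(syms)
  if (catalog$arity == 1L) {
    if (n == 0L) return(out)
    tab <- table(syms) / n
    out[names(tab)] <- as.numeric(tab)
  } else {
    g <- catalog$pair_gap
    if (n <= g) return(out)
    pairs <- paste0(syms[seq_len(n - g)], syms[seq_len(n - g) + g])
    tab <- table(pairs) / (n - g)
    out[names(tab)] <- as.numeric(tab)
  }
  out
}

# n x K matrix of per-polypeptide pattern frequencies for a group.
group_frequency_matrix <- function(group, catalog) {
  pats <- catalog_symbols(catalog)
  out <- t(vapply(group, pattern_frequencies, numeric(length(pats)),
                  catalog = catalog, USE.NAMES = FALSE))
  colnames(out) <- pats
  out
}

#' Bootstrap resample indices
#'
#' One bootstrap sample of size n drawn uniformly with replacement from 1..n,
#' the resampling primitive shared by the bootstrap-aggregating analysis and
#' the random forest. About 63% of the indices are unique in expectation.
#'
#' @param n number of cases
#' @return integer vector of length n
#' @export
bootstrap_indices <- function(n) {
  sample.int(n, n, replace = TRUE)
}

#' Bootstrap aggregating of mean pattern occurrence
#'
#' Draws `m` bootstrap resamples of the group (n' = n, with replacement),
#' computes the group-mean pattern frequency in each resample, and returns
#' the mean and standard deviation of those resample means per pattern.
#'
#' @param group character vector of polypeptides
#' @param catalog a [pattern_catalog()]
#' @param m number of bootstrap resamples (default 5000)
#' @param seed RNG seed
#' @return list with `mean`, `sd` (named per pattern), `m`, `n`
#' @export
bootstrap_mean_occurrence <- function(group, catalog, m = 5000L, seed = 1L) {
  stopifnot(length(group) > 0L, m >= 1L)
  fmat <- group_frequency_matrix(group, catalog)
  n <- nrow(fmat)
  set.seed(seed)
  means <- matrix(0, m, ncol(fmat))
  for (b in seq_len(m)) {
    means[b, ] <- colMeans(fmat[bootstrap_indices(n), , drop = FALSE])
  }
  list(mean = stats::setNames(colMeans(means), colnames(fmat)),
       sd = stats::setNames(apply(means, 2, stats::sd), colnames(fmat)),
       m = m, n = n)
}

frequency_of_pattern <- function(group, pattern, catalog) {
  vapply(group, function(s) pattern_frequencies(s, catalog)[pattern],
         numeric(1), USE.NAMES = FALSE)
}

# Shared permutation machinery on precomputed per-polypeptide frequencies.
# Exact enumeration over all relabelings when feasible, else Monte Carlo
# sampling with the add-one p-value estimate.
perm_p_value <- function(v_e, v_c, T = 99999L, seed = 1L,
                         exact_limit = 10000) {
  n_e <- length(v_e); n_c <- length(v_c)
  stopifnot(n_e > 0L, n_c > 0L, T >= 1L)
  v <- c(v_e, v_c)
  N <- n_e + n_c
  theta <- mean(v_e) - mean(v_c)
  total <- sum(v)
  stat_from_sum <- function(s_e) s_e / n_e - (total - s_e) / n_c
  tol <- 1e-12
  n_comb <- suppressWarnings(choose(N, n_e))
  if (is.finite(n_comb) && n_comb <= exact_limit) {
    combs <- utils::combn(N, n_e)
    stats <- stat_from_sum(colSums(matrix(v[combs], nrow = n_e)))
    p <- mean(abs(stats) >= abs(theta) - tol)
    return(list(theta_hat = theta, p = p, method = "exact",
                n_resamples = length(stats)))
  }
  set.seed(seed)
  t_count <- 0L
  for (b in seq_len(T)) {
    s_e <- sum(v[sample.int(N, n_e)])
    if (abs(stat_from_sum(s_e)) >= abs(theta) - tol) t_count <- t_count + 1L
  }
  list(theta_hat = theta, p = (t_count + 1) / (T + 1), method = "sampled",
       n_resamples = T)
}

#' Two-sided permutation test of pattern enrichment
#'
#' Tests whether the mean per-polypeptide frequency of a pattern differs
#' between an experimental and a comparison group. The statistic is the
#' difference of group means; group labels are permuted without replacement
#' preserving group sizes. The two-sided p-value counts resampled statistics
#' at least as extreme in magnitude as the observed one, with the add-one
#' estimate p = (t+1)/(T+1) under Monte Carlo sampling. When the number of
#' distinct relabelings is at most `exact_limit`, exact full enumeration
#' replaces sampling.
#'
#' @param group_e,group_c character vectors of polypeptides
#' @param pattern the pattern symbol to test
#' @param catalog a [pattern_catalog()]
#' @param T number of random relabelings (default 99999)
#' @param seed RNG seed
#' @param exact_limit enumeration threshold on choose(N, n_e)
#' @return list with `theta_hat`, `p`, `method`, `n_resamples`
#' @export
permutation_test <- function(group_e, group_c, pattern, catalog,
                             T = 99999L, seed = 1L, exact_limit = 10000) {
  v_e <- frequency_of_pattern(group_e, pattern, catalog)
  v_c <- frequency_of_pattern(group_c, pattern, catalog)
  perm_p_value(v_e, v_c, T = T, seed = seed, exact_limit = exact_limit)
}

#' Pseudo-frequency epsilon for the propensity score
#'
#' Half the sum of the smallest nonzero per-polypeptide frequencies of the
#' pattern in the two groups; when a group never shows the pattern its
#' contribution falls back to 1 / (total residue count of the group).
#'
#' @inheritParams permutation_test
#' @return positive scalar epsilon
#' @export
propensity_epsilon <- function(group_e, group_c, pattern, catalog) {
  min_nonzero <- function(group) {
    v <- frequency_of_pattern(group, pattern, catalog)
    nz <- v[v > 0]
    if (length(nz) > 0L) return(min(nz))
    1 / sum(nchar(group))
  }
  (min_nonzero(group_e) + min_nonzero(group_c)) / 2
}

#' Significance-weighted propensity score
#'
#' S_p = W * log2((f_e + eps) / (f_c + eps)) with W = 1 - p. Positive when
#' the pattern is enriched at CP sites relative to background, zero when the
#' frequencies agree or the permutation p-value is 1.
#'
#' @param f_e,f_c mean pattern frequencies in the experimental and
#'   comparison groups
#' @param p permutation-test p-value in (0, 1]
#' @param epsilon pseudo-frequency guarding the ratio (> 0)
#' @return the propensity score S_p
#' @export
propensity_score <- function(f_e, f_c, p, epsilon) {
  stopifnot(f_e >= 0, f_c >= 0, p > 0, p <= 1)
  if (epsilon <= 0) stop("epsilon must be positive")
  (1 - p) * log2((f_e + epsilon) / (f_c + epsilon))
}

#' Propensity score table over a full catalog
#'
#' Runs the permutation test and propensity scoring for every symbol of the
#' catalog, sharing the per-polypeptide frequency matrices across symbols.
#'
#' @inheritParams permutation_test
#' @return data.frame of class `cp_propensity`: `pattern`, `f_e`, `f_c`,
#'   `n_e`, `n_c`, `p`, `W`, `epsilon`, `S_p`
#' @export
build_score_table <- function(group_e, group_c, catalog,
                              T = 9999L, seed = 1L, exact_limit = 10000) {
  fm_e <- group_frequency_matrix(group_e, catalog)
  fm_c <- group_frequency_matrix(group_c, catalog)
  len_e <- sum(nchar(group_e)); len_c <- sum(nchar(group_c))
  pats <- colnames(fm_e)
  rows <- lapply(seq_along(pats), function(j) {
    v_e <- fm_e[, j]; v_c <- fm_c[, j]
    pt <- perm_p_value(v_e, v_c, T = T, seed = seed + j,
                       exact_limit = exact_limit)
    nz_e <- v_e[v_e > 0]; nz_c <- v_c[v_c > 0]
    eps <- ((if (length(nz_e)) min(nz_e) else 1 / len_e) +
              (if (length(nz_c)) min(nz_c) else 1 / len_c)) / 2
    f_e <- mean(v_e); f_c <- mean(v_c)
    data.frame(pattern = pats[j], f_e = f_e, f_c = f_c,
               n_e = sum(v_e > 0), n_c = sum(v_c > 0),
               p = pt$p, W = 1 - pt$p, epsilon = eps,
               S_p = propensity_score(f_e, f_c, pt$p, eps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cp_propensity", "data.frame")
  out
}

#' Windowed per-residue propensity features
#'
#' For every residue s treated as a candidate CP site, each feature is the
#' mean propensity score of the symbols in its 2k segment window (truncated
#' at chain ends): `R_aa` over amino acids, `R_aat3` / `R_aat5` over the
#' three- and five-class reductions, `R_sse` over 8-state SSE codes.
#' Symbols missing from a score table contribute 0 with a warning.
#'
#' @param structure a [cp_structure]
#' @param score_tables named list of `cp_propensity` tables with elements
#'   `aa`, `class3`, `class5`, `sse8` (any subset)
#' @param k window half-width (default 3)
#' @return data.frame of per-residue propensity features
#' @export
residue_propensity_features <- function(structure, score_tables, k = 3L) {
  n <- n_residues(structure)
  feats <- list()
  spec <- list(aa = c("R_aa", "aa"), class3 = c("R_aat3", "aa"),
               class5 = c("R_aat5", "aa"), sse8 = c("R_sse", "sse8"))
  for (nm in names(spec)) {
    if (is.null(score_tables[[nm]])) next
    tab <- score_tables[[nm]]
    catalog <- pattern_catalog(nm)
    scores <- stats::setNames(tab$S_p, tab$pattern)
    src <- structure$residues[[spec[[nm]][2]]]
    syms <- unname(catalog$map[src])
    sp <- scores[syms]
    if (anyNA(sp)) {
      warning(sprintf("%s: symbol(s) missing from score table treated as 0",
                      nm))
      sp[is.na(sp)] <- 0
    }
    feats[[spec[[nm]][1]]] <- vapply(seq_len(n), function(s) {
      pos <- max(1L, s - k):min(n, s + k - 1L)
      mean(sp[pos])
    }, numeric(1))
  }
  as.data.frame(feats)
}

#' Pattern occurrence coverage
#'
#' Fraction of the theoretically possible symbol combinations of a catalog
#' that are observed at least once across a set of segments: distinct
#' observed combinations divided by |alphabet|^arity.
#'
#' @param segments list from [extract_segments()], or a character vector of
#'   segment strings
#' @param catalog a [pattern_catalog()]
#' @return coverage fraction in [0, 1]
#' @export
pattern_coverage <- function(segments, catalog) {
  if (is.list(segments) && length(segments) > 0 &&
      is.list(segments[[1]])) {
    segments <- segment_strings(segments)
  }
  if (length(segments) == 0L) return(0)
  observed <- character(0)
  for (s in segments) {
    syms <- map_symbols(s, catalog)
    syms <- syms[!is.na(syms)]
    n <- length(syms)
    if (catalog$arity == 1L) {
      observed <- c(observed, syms)
    } else {
      g <- catalog$pair_gap
      if (n > g) {
        observed <- c(observed,
                      paste0(syms[seq_len(n - g)], syms[seq_len(n - g) + g]))
      }
    }
  }
  length(unique(observed)) /
    length(catalog$alphabet)^catalog$arity
}

#' Write a propensity score table as TSV
#' @param table a `cp_propensity` data.frame
#' @param path output file
#' @param catalog_name catalog tag recorded in the first column
#' @export
write_score_table <- function(table, path, catalog_name = "aa") {
  df <- cbind(catalog = catalog_name, as.data.frame(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA sequences as a character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(vapply(seqs, as.character, character(1))),
                  names(seqs))
}

#' Write sequences to FASTA
#' @param sequences named character vector
#' @param path output file
#' @export
write_fasta_sequences <- function(sequences, path) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  seqinr::write.fasta(as.list(sequences), nm, file.out = path)
  invisible(path)
}
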