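#' Orient features so viable sites score higher
#'
#' Any feature whose mean among viable training sites is below its mean among
#' inviable sites is multiplied by -1, so that after orientation every
#' feature is positively associated with viability. (Negation is used
#' uniformly; the reciprocal transform is undefined for zero-crossing
#' standardized features.) Features with equal class means are left unchanged
#' with a warning.
#'
#' @param x numeric matrix or data.frame of features (rows = training cases)
#' @param labels logical viability labels, one per row
#' @param orientation optional previously fitted orientation to apply
#' @return list with `x` (oriented matrix) and `orientation` (+1/-1 per
#'   feature)
#' @export
orient_features <- function(x, labels = NULL, orientation = NULL) {
  x <- as.matrix(x)
  if (is.null(orientation)) {
    labels <- as.logical(labels)
    orientation <- vapply(seq_len(ncol(x)), function(j) {
      mv <- mean(x[labels, j], na.rm = TRUE)
      mi <- mean(x[!labels, j], na.rm = TRUE)
      if (is.na(mv) || is.na(mi) || mv == mi) {
        warning(sprintf("feature %s has equal class means; left unchanged",
                        colnames(x)[j]))
        return(1)
      }
      if (mv < mi) -1 else 1
    }, numeric(1))
    names(orientation) <- colnames(x)
  }
  list(x = sweep(x, 2, orientation[colnames(x)], "*"),
       orientation = orientation)
}

#' Per-protein standard-score transformation
#'
#' z = (x - mu) / sigma computed per feature within each protein (over all
#' of that protein's residues, never pooled across proteins). Zero-variance
#' columns become all zeros with a warning; NA sentinels stay NA and are
#' excluded from mu and sigma.
#'
#' @param x numeric matrix or data.frame of raw feature values
#' @param protein_id protein identifier per row
#' @return matrix of z-scores
#' @export
standardize_features <- function(x, protein_id) {
  x <- as.matrix(x)
  out <- x
  for (pid in unique(protein_id)) {
    rows <- which(protein_id == pid)
    if (length(rows) < 2L) stop("need >= 2 residues per protein to standardize")
    for (j in seq_len(ncol(x))) {
      v <- x[rows, j]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        if (!all(is.na(v))) {
          warning(sprintf("constant feature %s in protein %s; set to 0",
                          colnames(x)[j], pid))
        }
        out[rows, j] <- ifelse(is.na(v), NA_real_, 0)
      } else {
        out[rows, j] <- (v - mean(v, na.rm = TRUE)) / s
      }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Hierarchical integration
# ---------------------------------------------------------------------------

#' Default feature-integration tree
#'
#' Groups features by biological meaning: sequence propensities, SSE
#' propensity, exposure, packing, flexibility, and core distance, joined at
#' the root. Groups whose features are absent from `features` are dropped;
#' the topology is an ordinary nested list the user can edit.
#'
#' @param features feature names available in the training matrix
#' @return nested list topology for [hi_fit()]
#' @export
hi_default_topology <- function(features) {
  grp <- list(
    seq_propensity = c("R_aa", "R_aat3", "R_aat5"),
    sse_propensity = c("R_sse"),
    exposure = c("RSA", "depth", "CM"),
    packing = c("HB", "closeness", "CN", "WCN"),
    flexibility = c("Bfactor", "GNMF"),
    core_distance = c("DIS_b", "DIS_hpho", "F_b", "F_hpho", "F_bUh", "F_bIh")
  )
  children <- list()
  for (nm in names(grp)) {
    present <- intersect(grp[[nm]], features)
    if (length(present) == 0L) next
    if (length(present) == 1L) {
      children[[length(children) + 1L]] <- present
    } else {
      children[[length(children) + 1L]] <-
        list(name = nm, children = as.list(present))
    }
  }
  extra <- setdiff(features, unlist(grp))
  for (f in extra) children[[length(children) + 1L]] <- f
  list(name = "root", children = children)
}

# All nonnegative integer compositions of total into k parts (rows).
weight_compositions <- function(k, total) {
  if (k == 1L) return(matrix(total, 1, 1))
  out <- list()
  for (first in 0:total) {
    rest <- weight_compositions(k - 1L, total - first)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Lean internal metric kernels used in the exhaustive HI weight search.
# Semantics match roc_auc / optimal_threshold / mcc_at exactly, without the
# per-call data.frame overhead.
fast_auc <- function(s, y) {
  r <- rank(s)
  np <- sum(y)
  nn <- length(y) - np
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

fast_nearest_threshold <- function(s, y) {
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  ss <- s[ord]
  tp <- cumsum(ys)
  fp <- cumsum(!ys)
  np <- tp[length(tp)]
  nn <- fp[length(fp)]
  last <- which(!duplicated(ss, fromLast = TRUE))
  d2 <- (fp[last] / nn)^2 + (1 - tp[last] / np)^2
  cand <- ss[last]
  max(cand[d2 == min(d2)])
}

fast_mcc <- function(s, y, thr) {
  pred <- s >= thr
  tp <- as.numeric(sum(pred & y))
  fp <- as.numeric(sum(pred & !y))
  fn <- as.numeric(sum(!pred & y))
  tn <- as.numeric(sum(!pred & !y))
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Evaluate candidate weight vectors for one node: cross-validated MCC (fold
# threshold picked on the training part, nearest the (0,1) ROC corner),
# cross-validated AUC, and the Welch two-sample p-value of the integrated
# score. folds_id == NULL means evaluate on the training data itself.
hi_eval_candidates <- function(S, y, W, folds_id) {
  n_cand <- nrow(W)
  mcc <- auc <- pval <- numeric(n_cand)
  fold_list <- if (!is.null(folds_id)) {
    lapply(sort(unique(folds_id)), function(f) folds_id == f)
  }
  npos <- sum(y)
  nneg <- sum(!y)
  chunk <- 2000L
  for (start in seq(1L, n_cand, by = chunk)) {
    idx <- start:min(n_cand, start + chunk - 1L)
    IF <- S %*% t(W[idx, , drop = FALSE])
    # vectorised Welch t-test p-values across the chunk
    m1 <- colMeans(IF[y, , drop = FALSE])
    m0 <- colMeans(IF[!y, , drop = FALSE])
    v1 <- colSums(sweep(IF[y, , drop = FALSE], 2, m1)^2) / (npos - 1)
    v0 <- colSums(sweep(IF[!y, , drop = FALSE], 2, m0)^2) / (nneg - 1)
    se2 <- v1 / npos + v0 / nneg
    tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / npos)^2 / (npos - 1) +
                            (v0 / nneg)^2 / (nneg - 1)), 1)
    pval[idx] <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
    for (jj in seq_along(idx)) {
      s <- IF[, jj]
      if (is.null(fold_list)) {
        mcc[idx[jj]] <- fast_mcc(s, y, fast_nearest_threshold(s, y))
        auc[idx[jj]] <- fast_auc(s, y)
      } else {
        ms <- as <- 0
        nf <- 0L
        for (te in fold_list) {
          y_tr <- y[!te]
          y_te <- y[te]
          if (!any(y_tr) || all(y_tr) || !any(y_te) || all(y_te)) next
          thr <- fast_nearest_threshold(s[!te], y_tr)
          ms <- ms + fast_mcc(s[te], y_te, thr)
          as <- as + fast_auc(s[te], y_te)
          nf <- nf + 1L
        }
        mcc[idx[jj]] <- if (nf == 0L) -1 else ms / nf
        auc[idx[jj]] <- if (nf == 0L) 0 else as / nf
      }
    }
  }
  best <- order(-mcc, -auc, pval)[1]
  list(best = best, mcc = mcc[best], auc = auc[best], p = pval[best])
}

#' Fit the hierarchical feature-integration tree
#'
#' Bottom-up over the topology: at each node the children's (standardized,
#' oriented) scores are combined as IF = sum w_f * z_f with weights on a
#' two-decimal grid summing to exactly 1, chosen by exhaustive search.
#' Candidates are ranked by cross-validated mean MCC, ties broken by mean
#' AUC, then by the two-sample t-test p-value of the node score. `folds = 1`
#' evaluates on the training data directly (the search space then contains
#' every single-feature predictor, so the root cannot score below the best
#' leaf).
#'
#' @param x oriented, standardized feature matrix of the training cases
#' @param labels logical viability labels
#' @param topology nested-list tree, e.g. [hi_default_topology()]
#' @param weight_step weight grid resolution; 0.05 is the desk-scale
#'   default, 0.01 reproduces the full-resolution grid at higher cost
#' @param folds cross-validation folds for candidate ranking (1 = none)
#' @param seed RNG seed (fold assignment)
#' @return object of class `cp_hitree` carrying per-node weights, the root
#'   training IF values and the class-conditional training distributions
#' @export
hi_fit <- function(x, labels, topology = NULL, weight_step = 0.05,
                   folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.logical(labels)
  if (is.null(topology)) topology <- hi_default_topology(colnames(x))
  total <- round(1 / weight_step)
  if (abs(total * weight_step - 1) > 1e-9) {
    stop("weight_step must divide 1.00 exactly")
  }
  folds_id <- if (folds > 1L) stratified_folds(y, folds, seed) else NULL
  fit_node <- function(node) {
    if (is.character(node)) {
      if (!node %in% colnames(x)) stop("unknown feature in topology: ", node)
      return(list(leaf = node, values = x[, node]))
    }
    kids <- lapply(node$children, fit_node)
    S <- vapply(kids, `[[`, numeric(nrow(x)), "values")
    k <- ncol(S)
    if (k == 1L) {
      return(list(name = node$name, children = kids, weights = 1,
                  values = S[, 1]))
    }
    if (k > 6L && weight_step <= 0.01) {
      stop("node with more than 6 branches at step 0.01; use a coarser step")
    }
    W <- weight_compositions(k, total) / total
    sel <- hi_eval_candidates(S, y, W, folds_id)
    w <- W[sel$best, ]
    list(name = node$name, children = kids, weights = w,
         values = as.numeric(S %*% w),
         mcc = sel$mcc, auc = sel$auc, p = sel$p)
  }
  root <- fit_node(topology)
  structure(
    list(root = root, topology = topology, weight_step = weight_step,
         train_if_pos = root$values[y], train_if_neg = root$values[!y]),
    class = "cp_hitree"
  )
}

#' Integrated feature score of new cases
#' @param tree a fitted [hi_fit()] tree
#' @param x oriented, standardized feature matrix
#' @return numeric root IF per row
#' @export
hi_score <- function(tree, x) {
  x <- as.matrix(x)
  walk <- function(node) {
    if (!is.null(node$leaf)) return(x[, node$leaf])
    S <- vapply(node$children, walk, numeric(nrow(x)))
    as.numeric(S %*% node$weights)
  }
  walk(tree$root)
}

#' Probability score from training IF distributions
#'
#' For an IF value v, counts N_p = positives with training IF >= v and
#' N_n = negatives with training IF <= v; the score is N_n / (N_p + N_n)
#' (0.5 when both counts are zero). Monotone non-decreasing in v.
#'
#' @param if_value numeric IF value(s)
#' @param train_pos,train_neg training IF values of the positive and
#'   negative classes
#' @return scores in [0, 1]
#' @export
hi_probability <- function(if_value, train_pos, train_neg) {
  stopifnot(length(train_pos) > 0, length(train_neg) > 0)
  vapply(if_value, function(v) {
    np <- sum(train_pos >= v)
    nn <- sum(train_neg <= v)
    if (np + nn == 0L) 0.5 else nn / (np + nn)
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Artificial neural network
# ---------------------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the three-layer backpropagation network
#'
#' Fully connected input-hidden-output network with sigmoid activations and
#' one output neuron. Hidden layer size defaults to Round(sqrt(N_i * N_o)).
#' Training is per-iteration single-case stochastic backpropagation: at each
#' of the 5,000 iterations one training case is drawn at random (with
#' replacement), with learning rate 0.5 and momentum 0.1; initial weights
#' are uniform on (-2, 2). Fully deterministic given the seed.
#'
#' @param x oriented, standardized feature matrix
#' @param labels logical viability labels
#' @param seed RNG seed
#' @param iterations training iterations
#' @param learning_rate,momentum backpropagation parameters
#' @param n_hidden hidden layer size override
#' @return object of class `cp_ann`
#' @export
ann_fit <- function(x, labels, seed = 1L, iterations = 5000L,
                    learning_rate = 0.5, momentum = 0.1, n_hidden = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(as.logical(labels))
  ni <- ncol(x)
  nh <- if (is.null(n_hidden)) max(1L, round(sqrt(ni * 1))) else n_hidden
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    w1 <- matrix(stats::runif(nh * (ni + 1), -2, 2), nh, ni + 1)
    w2 <- matrix(stats::runif(nh + 1, -2, 2), 1, nh + 1)
    v1 <- w1 * 0; v2 <- w2 * 0
    ok <- TRUE
    for (it in seq_len(iterations)) {
      i <- sample.int(nrow(x), 1L)
      xi <- c(x[i, ], 1)
      h <- sigmoid(as.numeric(w1 %*% xi))
      hb <- c(h, 1)
      o <- sigmoid(as.numeric(w2 %*% hb))
      if (!is.finite(o)) { ok <- FALSE; break }
      d_o <- (y[i] - o) * o * (1 - o)
      d_h <- h * (1 - h) * as.numeric(w2[1, seq_len(nh)]) * d_o
      v2 <- learning_rate * d_o * rbind(hb) + momentum * v2
      v1 <- learning_rate * outer(d_h, xi) + momentum * v1
      w2 <- w2 + v2
      w1 <- w1 + v1
      if (!all(is.finite(w1)) || !all(is.finite(w2))) { ok <- FALSE; break }
    }
    if (ok) break
    message("non-finite ANN update; re-initialising with next seed")
  }
  structure(list(w1 = w1, w2 = w2, features = colnames(x),
                 n_hidden = nh), class = "cp_ann")
}

#' Network output scores
#' @param model a [ann_fit()] model
#' @param x oriented, standardized feature matrix
#' @return scores in (0, 1)
#' @export
ann_score <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  h <- sigmoid(cbind(x, 1) %*% t(model$w1))
  as.numeric(sigmoid(cbind(h, 1) %*% t(model$w2)))
}

# ---------------------------------------------------------------------------
# Random forest with out-of-bag tree selection
# ---------------------------------------------------------------------------

#' Grow the MCC-selected random forest
#'
#' Grows `n_trees` unpruned classification trees; each tree sees a random
#' feature subset of size max(1, floor(0.5 * n_f)) and a bootstrap sample of
#' n cases (n' = n, with replacement; ~63% unique). Each tree is scored by
#' the MCC of its predictions on its out-of-bag cases (MCC of a tree with an
#' empty out-of-bag set is taken as -1), and the `n_keep` highest-MCC trees
#' form the forest.
#'
#' @param x oriented, standardized feature matrix
#' @param labels logical viability labels
#' @param seed RNG seed
#' @param n_trees trees grown (default 1000)
#' @param n_keep trees retained (default 500)
#' @return object of class `cp_rf`
#' @export
rf_fit <- function(x, labels, seed = 1L, n_trees = 1000L, n_keep = 500L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("random forest needs at least 2 features")
  y <- factor(as.integer(as.logical(labels)), levels = c(0L, 1L))
  n <- nrow(x)
  nf <- ncol(x)
  nf_sub <- max(1L, floor(0.5 * nf))
  set.seed(seed)
  trees <- vector("list", n_trees)
  mccs <- numeric(n_trees)
  ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                               xval = 0L, maxsurrogate = 0L,
                               maxcompete = 0L)
  for (t in seq_len(n_trees)) {
    feats <- sample(names(x), nf_sub)
    boot <- bootstrap_indices(n)
    oob <- setdiff(seq_len(n), unique(boot))
    df <- cbind(.y = y[boot], x[boot, feats, drop = FALSE])
    fit <- rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
    if (length(oob) == 0L) {
      mccs[t] <- -1
    } else {
      pred <- predict(fit, x[oob, feats, drop = FALSE], type = "class")
      mccs[t] <- mcc_at(as.numeric(as.character(pred)),
                        y[oob] == "1", 0.5)$mcc
    }
    trees[[t]] <- list(fit = fit, feats = feats)
  }
  keep <- order(-mccs, seq_len(n_trees))[seq_len(min(n_keep, n_trees))]
  structure(list(trees = trees[keep], oob_mcc = mccs[keep],
                 features = names(x), n_keep = length(keep)),
            class = "cp_rf")
}

#' Forest vote fraction
#' @param model a [rf_fit()] forest
#' @param x oriented, standardized feature matrix
#' @return fraction of retained trees voting viable, in [0, 1]
#' @export
rf_score <- function(model, x) {
  x <- as.data.frame(x)
  votes <- vapply(model$trees, function(tr) {
    pred <- predict(tr$fit, x[, tr$feats, drop = FALSE], type = "class")
    as.numeric(as.character(pred))
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

# ---------------------------------------------------------------------------
# Kernel classifier (radial basis SVM with calibrated scores)
# ---------------------------------------------------------------------------

#' Fit the radial-basis kernel classifier
#'
#' Soft-margin support vector classification (LIBSVM via e1071) with an RBF
#' kernel; (cost, gamma) picked by seeded stratified cross-validated
#' accuracy over a grid. Decision values are mapped to [0, 1] by a
#' sigmoid (logistic) calibration fitted on held-out-fold decision values,
#' which keeps scoring deterministic for a fixed seed.
#'
#' @param x oriented, standardized feature matrix
#' @param labels logical viability labels
#' @param seed RNG seed (fold assignment)
#' @param cost_grid,gamma_grid search grids
#' @param folds cross-validation folds
#' @return object of class `cp_svm`
#' @export
svm_fit <- function(x, labels, seed = 1L,
                    cost_grid = 2^c(-1, 1, 3, 5),
                    gamma_grid = 2^c(-5, -3, -1),
                    folds = 5L) {
  x <- as.matrix(x)
  y <- factor(as.integer(as.logical(labels)), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("single-class training set")
  fid <- stratified_folds(y == "1", folds, seed)
  best <- NULL
  for (cost in cost_grid) {
    for (gamma in gamma_grid) {
      acc <- numeric(0)
      for (f in unique(fid)) {
        tr <- fid != f
        m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
        acc <- c(acc, mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr]))
      }
      cand <- list(cost = cost, gamma = gamma, cv_accuracy = mean(acc))
      if (is.null(best) || cand$cv_accuracy > best$cv_accuracy) best <- cand
    }
  }
  # out-of-fold decision values for the sigmoid calibration
  dv <- numeric(nrow(x))
  for (f in unique(fid)) {
    tr <- fid != f
    m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                    kernel = "radial", cost = best$cost, gamma = best$gamma,
                    scale = FALSE)
    p <- predict(m, x[!tr, , drop = FALSE], decision.values = TRUE)
    dv[!tr] <- as.numeric(attr(p, "decision.values"))
  }
  calib <- suppressWarnings(
    stats::glm((y == "1") ~ dv, family = stats::binomial()))
  model <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = best$cost, gamma = best$gamma, scale = FALSE)
  structure(list(model = model, calibration = stats::coef(calib),
                 cost = best$cost, gamma = best$gamma,
                 cv_accuracy = best$cv_accuracy, features = colnames(x)),
            class = "cp_svm")
}

#' Calibrated kernel-classifier scores
#' @param model a [svm_fit()] model
#' @param x oriented, standardized feature matrix
#' @return scores in [0, 1]
#' @export
svm_score <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  p <- predict(model$model, x, decision.values = TRUE)
  dv <- as.numeric(attr(p, "decision.values"))
  b <- model$calibration
  as.numeric(stats::plogis(b[1] + b[2] * dv))
}

# ---------------------------------------------------------------------------
# Combination and smoothing
# ---------------------------------------------------------------------------

#' Combine component probability scores
#'
#' Unweighted mean of the four component scores; errors if any input lies
#' outside [0, 1].
#'
#' @param hi,ann,rf,svm numeric score vectors in [0, 1]
#' @return combined raw score ps
#' @export
combine_scores <- function(hi, ann, rf, svm) {
  m <- cbind(hi, ann, rf, svm)
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE)) {
    stop("component scores must lie in [0, 1]")
  }
  rowMeans(pmin(pmax(m, 0), 1))
}

#' Three-residue weighted smoothing of a score profile
#'
#' ps'(i) = (0.25 ps(i-1) + 0.50 ps(i) + 0.25 ps(i+1)) with the weights
#' renormalised over the neighbours that exist at the chain termini. A
#' convex combination: the smoothed profile never leaves the raw range.
#'
#' @param raw_scores numeric profile in chain order
#' @param weights length-3 window weights (previous, self, next)
#' @return smoothed profile
#' @export
smooth_profile <- function(raw_scores, weights = c(0.25, 0.50, 0.25)) {
  n <- length(raw_scores)
  if (n == 1L) return(raw_scores)
  prev <- c(NA, raw_scores[-n])
  nxt <- c(raw_scores[-1], NA)
  num <- ifelse(is.na(prev), 0, weights[1] * prev) +
    weights[2] * raw_scores +
    ifelse(is.na(nxt), 0, weights[3] * nxt)
  den <- ifelse(is.na(prev), 0, weights[1]) + weights[2] +
    ifelse(is.na(nxt), 0, weights[3])
  num / den
}

# ---------------------------------------------------------------------------
# The ensemble model object
# ---------------------------------------------------------------------------

#' Train the CP viability prediction ensemble
#'
#' The central fitting function: takes a per-residue feature table (one row
#' per residue across one or more proteins) and a CP-site label table, then
#' (1) standardizes features per protein, (2) orients them so viable sites
#' score higher, and (3) fits the four probability scorers - the
#' hierarchical feature-integration tree, the backpropagation network, the
#' out-of-bag-selected random forest and the calibrated radial-basis kernel
#' classifier. Prediction averages the four scores and smooths the profile
#' along the chain; a residue is called a viable CP site when its smoothed
#' score is at least 0.5.
#'
#' @param features data.frame with `protein_id`, `seq_position` and numeric
#'   feature columns (see [compute_feature_matrix()])
#' @param labels data.frame with `protein_id`, `site_position`, `viable`
#'   (see [read_cp_labels()])
#' @param feature_cols feature columns to use; defaults to every numeric
#'   non-identifier column present
#' @param topology HI tree topology (default [hi_default_topology()])
#' @param weight_step HI weight grid step
#' @param folds cross-validation folds used inside HI weight selection
#' @param seed master RNG seed; all component seeds derive from it
#' @param n_trees,n_keep random forest size parameters
#' @param ann_iterations network training iterations
#' @return object of class `cp_ensemble`
#' @seealso [predict.cp_ensemble()], [evaluate_scores()]
#' @export
cp_train <- function(features, labels, feature_cols = NULL,
                     topology = NULL, weight_step = 0.05, folds = 10L,
                     seed = 1L, n_trees = 1000L, n_keep = 500L,
                     ann_iterations = 5000L) {
  meta <- c("protein_id", "chain_id", "seq_position", "resno", "icode",
            "aa", "sse8")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), meta)
    feature_cols <- feature_cols[vapply(features[feature_cols], is.numeric,
                                        logical(1))]
  }
  x_all <- as.matrix(features[, feature_cols, drop = FALSE])
  all_na <- colSums(!is.na(x_all)) == 0
  if (any(all_na)) {
    message("dropping undefined feature column(s): ",
            paste(feature_cols[all_na], collapse = ", "))
    feature_cols <- feature_cols[!all_na]
    x_all <- x_all[, feature_cols, drop = FALSE]
  }
  z_all <- standardize_features(x_all, features$protein_id)

  key_feat <- paste(features$protein_id, features$seq_position)
  key_lab <- paste(labels$protein_id, labels$site_position)
  row_idx <- match(key_lab, key_feat)
  if (anyNA(row_idx)) {
    stop("label positions missing from the feature table: ",
         paste(key_lab[is.na(row_idx)], collapse = ", "))
  }
  x_train <- z_all[row_idx, , drop = FALSE]
  y <- as.logical(labels$viable)
  ok_rows <- rowSums(is.na(x_train)) == 0
  if (!all(ok_rows)) {
    message(sprintf("dropping %d training case(s) with undefined features",
                    sum(!ok_rows)))
    x_train <- x_train[ok_rows, , drop = FALSE]
    y <- y[ok_rows]
  }
  if (length(unique(y)) < 2L) stop("training labels contain a single class")

  orient <- orient_features(x_train, y)
  x_or <- orient$x
  if (is.null(topology)) topology <- hi_default_topology(feature_cols)
  hi <- hi_fit(x_or, y, topology = topology, weight_step = weight_step,
               folds = folds, seed = seed)
  ann <- ann_fit(x_or, y, seed = seed + 1L, iterations = ann_iterations)
  rf <- rf_fit(x_or, y, seed = seed + 2L, n_trees = n_trees, n_keep = n_keep)
  svm <- svm_fit(x_or, y, seed = seed + 3L)

  structure(
    list(feature_cols = feature_cols, orientation = orient$orientation,
         hi = hi, ann = ann, rf = rf, svm = svm,
         n_train = length(y), n_pos = sum(y), seed = seed),
    class = "cp_ensemble"
  )
}

#' Predict per-residue CP viability probability scores
#'
#' Standardizes the new feature table per protein, applies the stored
#' orientation, scores every residue with the four component models,
#' averages into the raw probability score and applies the three-residue
#' smoothing along each chain. Residues score viable when the smoothed
#' score is at least 0.5.
#'
#' @param object a fitted [cp_train()] ensemble
#' @param features per-residue feature table as in [cp_train()]
#' @param smooth apply the 3-residue window (default TRUE)
#' @param ... unused
#' @return data.frame with per-residue component scores `ps_hi`, `ps_ann`,
#'   `ps_rf`, `ps_svm`, the combined `ps`, smoothed `ps_smooth` and the
#'   predicted `viable` label
#' @export
predict.cp_ensemble <- function(object, features, smooth = TRUE, ...) {
  missing <- setdiff(object$feature_cols, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(features[, object$feature_cols, drop = FALSE])
  z <- standardize_features(x, features$protein_id)
  if (anyNA(z)) {
    warning("undefined feature values imputed at the protein mean (z = 0)")
    z[is.na(z)] <- 0
  }
  z <- orient_features(z, orientation = object$orientation)$x
  ps_hi <- hi_probability(hi_score(object$hi, z),
                          object$hi$train_if_pos, object$hi$train_if_neg)
  ps_ann <- ann_score(object$ann, z)
  ps_rf <- rf_score(object$rf, z)
  ps_svm <- svm_score(object$svm, z)
  ps <- combine_scores(ps_hi, ps_ann, ps_rf, ps_svm)
  out <- data.frame(
    protein_id = features$protein_id,
    seq_position = features$seq_position,
    ps_hi = ps_hi, ps_ann = ps_ann, ps_rf = ps_rf, ps_svm = ps_svm,
    ps = ps, stringsAsFactors = FALSE
  )
  out$ps_smooth <- ps
  if (smooth) {
    for (pid in unique(out$protein_id)) {
      rows <- which(out$protein_id == pid)
      rows <- rows[order(out$seq_position[rows])]
      out$ps_smooth[rows] <- smooth_profile(out$ps[rows])
    }
  }
  out$viable <- out$ps_smooth >= 0.5
  out
}

#' @export
print.cp_ensemble <- function(x, ...) {
  cat(sprintf(
    paste0("CP viability ensemble (HI + ANN + RF + SVM)\n",
           "  trained on %d residues (%d viable / %d inviable)\n",
           "  features: %s\n",
           "  RF: %d retained trees; SVM: cost %.3g, gamma %.3g ",
           "(CV accuracy %.3f)\n"),
    x$n_train, x$n_pos, x$n_train - x$n_pos,
    paste(x$feature_cols, collapse = ", "),
    x$rf$n_keep, x$svm$cost, x$svm$gamma, x$svm$cv_accuracy))
  invisible(x)
}

#' @export
summary.cp_ensemble <- function(object, ...) {
  print(object)
  hi_root <- object$hi$root
  if (!is.null(hi_root$weights) && length(hi_root$weights) > 1) {
    kid_names <- vapply(hi_root$children, function(k) {
      if (!is.null(k$leaf)) k$leaf else k$name
    }, character(1))
    cat("  HI root weights:\n")
    for (i in seq_along(kid_names)) {
      cat(sprintf("    %-16s %.2f\n", kid_names[i], hi_root$weights[i]))
    }
  }
  cat(sprintf("  HI training IF separation: %.2f sd\n",
              (mean(object$hi$train_if_pos) - mean(object$hi$train_if_neg)) /
                stats::sd(c(object$hi$train_if_pos,
                            object$hi$train_if_neg))))
  invisible(object)
}
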