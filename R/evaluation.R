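# Positive-unlabeled ranking evaluation: k-fold splits of the known
# treatment pairs, the modified ROC (observed pairs above threshold are TP,
# unobserved pairs above threshold are FP), top-percentile retrieval and
# the guilt-by-association ratio diagnostic.

#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Partition the known positive pairs into cross-validation folds
#'
#' Uniform random partition of the positive entries of `Y`, reproducible
#' from `seed`; fold sizes differ by at most one.
#'
#' @param Y binary drugs x diseases treatment matrix.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed.
#' @return list with `positives` (two-column index matrix), `fold_of`
#'   (fold id in 1..k per positive), `k`, `seed`.
#' @export
make_folds <- function(Y, k = 10, seed = 1) {
  check_binary_matrix(Y, "treatment matrix")
  pos <- which(Y == 1, arr.ind = TRUE)
  if (nrow(pos) < k) stop("fewer positives (", nrow(pos), ") than folds (", k, ")")
  perm <- local_seed(seed, sample.int(nrow(pos)))
  fold_of <- integer(nrow(pos))
  fold_of[perm] <- rep(seq_len(k), length.out = nrow(pos))
  list(positives = pos[, c("row", "col"), drop = FALSE], fold_of = fold_of,
       k = k, seed = seed)
}

#' Modified ROC curve for positive-unlabeled scores
#'
#' Sweeps thresholds over the sorted unique score values (plus a +Inf
#' sentinel). At each threshold an observed pair (label 1) scoring at or
#' above it is a true positive, otherwise a false negative; an unobserved
#' pair (label 0) at or above it is a false positive, otherwise a true
#' negative. AUC is the trapezoidal integral of the (FPR, TPR) polyline.
#' Pairs where `mask` is FALSE (e.g. training positives) are excluded.
#'
#' @param scores numeric score field (matrix or vector).
#' @param labels binary field of the same shape: 1 = observed positive.
#' @param mask optional logical field; FALSE entries are dropped.
#' @return list of class `ssgc_roc`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   plus the confusion counts per threshold.
#' @export
modified_roc <- function(scores, labels, mask = NULL) {
  s <- as.vector(scores); y <- as.vector(labels)
  if (length(s) != length(y)) stop("scores and labels must have the same shape")
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  if (!is.null(mask)) { keep <- as.vector(mask); s <- s[keep]; y <- y[keep] }
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos < 1 || nneg < 1) stop("need at least one positive and one negative")
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  ord <- order(-s)
  ys <- y[ord]; ss <- s[ord]
  # cumulative positives/negatives at each distinct score, descending
  cumpos <- cumsum(ys); cumneg <- cumsum(1 - ys)
  last <- length(ss) - match(unique(ss), rev(ss)) + 1  # last index per distinct score
  tp <- c(0, cumpos[last]); fp <- c(0, cumneg[last])
  tpr <- tp / npos; fpr <- fp / nneg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 tp = tp, fp = fp, fn = npos - tp, tn = nneg - fp),
            class = "ssgc_roc")
}

#' @export
print.ssgc_roc <- function(x, ...) {
  cat(sprintf("modified ROC: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Confusion counts of the modified ROC at one threshold
#'
#' @inheritParams modified_roc
#' @param threshold score cut (pairs scoring >= threshold are called positive).
#' @return named vector (tp, fp, fn, tn, tpr, fpr).
#' @export
confusion_at <- function(scores, labels, threshold = 0.05, mask = NULL) {
  s <- as.vector(scores); y <- as.vector(labels)
  if (!is.null(mask)) { keep <- as.vector(mask); s <- s[keep]; y <- y[keep] }
  call <- s >= threshold
  tp <- sum(call & y == 1); fn <- sum(!call & y == 1)
  fp <- sum(call & y == 0); tn <- sum(!call & y == 0)
  c(tp = tp, fp = fp, fn = fn, tn = tn,
    tpr = tp / max(tp + fn, 1), fpr = fp / max(fp + tn, 1))
}

#' Held-out positives retrieved in the top percentile of the ranking
#'
#' Ranks all pairs except excluded ones (typically training positives) by
#' descending score, ties broken lexicographically by (drug id, disease id),
#' and counts how many held-out positives fall within the top
#' `ceiling(pct/100 * q)` ranks, where `q` is the full pair count.
#'
#' @param scores drugs x diseases score matrix with id dimnames.
#' @param held_out two-column (row, col) index matrix of held-out positives.
#' @param pct percentile in (0, 100].
#' @param exclude optional logical matrix; TRUE pairs leave the ranking.
#' @return integer count of retrieved held-out positives.
#' @export
top_percent_retrieval <- function(scores, held_out, pct = 1, exclude = NULL) {
  stopifnot(pct > 0, pct <= 100)
  q <- length(scores)
  mask <- if (is.null(exclude)) NULL else !exclude
  ranked <- rank_pairs(scores, mask = mask)
  top <- utils::head(ranked, ceiling(pct / 100 * q))
  key <- paste(top$drug, top$disease, sep = "\r")
  held_key <- paste(rownames(scores)[held_out[, 1]],
                    colnames(scores)[held_out[, 2]], sep = "\r")
  sum(held_key %in% key)
}

#' Guilt-by-association ratio of a similarity layer
#'
#' Compares the mean off-diagonal similarity of entity pairs that share at
#' least one association partner (`share = TRUE`) against pairs that share
#' none. A ratio above 1 supports the assumption that similar drugs treat
#' similar diseases (and vice versa).
#'
#' @param S similarity matrix.
#' @param share symmetric logical matrix over the same registry; the
#'   diagonal is ignored.
#' @return list with `avg_same`, `avg_diff`, `ratio` (NA when undefined).
#' @export
gba_ratio <- function(S, share) {
  stopifnot(identical(dim(S), dim(share)))
  off <- !diag(TRUE, nrow(S))
  same <- S[off & share]
  diff <- S[off & !share]
  avg_same <- if (length(same)) mean(same) else NA_real_
  avg_diff <- if (length(diff)) mean(diff) else NA_real_
  ratio <- if (is.na(avg_same) || is.na(avg_diff) || avg_diff == 0) NA_real_
           else avg_same / avg_diff
  list(avg_same = avg_same, avg_diff = avg_diff, ratio = ratio)
}

#' Do two entities share an association partner?
#'
#' For a drugs x diseases matrix `Y`, `shared_partner_matrix(Y)` marks drug
#' pairs treating at least one common disease; `shared_partner_matrix(t(Y))`
#' marks disease pairs sharing a drug.
#'
#' @param A binary entities x partners matrix.
#' @return symmetric logical entities x entities matrix (diagonal TRUE).
#' @export
shared_partner_matrix <- function(A) {
  check_binary_matrix(A)
  (A %*% t(A)) > 0
}

#' Cross-validate the full pipeline on one dataset
#'
#' For each fold the held-out positives are removed from the training label
#' matrix; the treatment-layer similarities, fusion weights and the prior
#' are recomputed from the training labels only (the base and gene layers do
#' not depend on the labels and are computed once); the solver is run and
#' the held-out positives are scored against all never-observed pairs, with
#' training positives excluded from evaluation.
#'
#' @param dataset an ssgc dataset list as produced by [generate_network()]
#'   or assembled from files (fields: `fingerprints`, `S_pheno`,
#'   `gene_adj`, `C`, `D`, `Y`).
#' @param k number of folds.
#' @param seed RNG seed for the fold split.
#' @param layers which layers to fuse: subset of
#'   `c("base", "gene", "treatment")` (base always included).
#' @param prior logical; use the gene-overlap prior.
#' @param opts pipeline options from [pipeline_options()].
#' @return list with `pooled` (modified ROC over all folds' pooled scores),
#'   `per_fold` data.frame (fold, auc, held_out, retrieved_top1),
#'   `mean_fold_auc`, `folds`.
#' @export
cross_validate <- function(dataset, k = 10, seed = 1,
                           layers = c("base", "gene", "treatment"),
                           prior = TRUE, opts = pipeline_options()) {
  folds <- make_folds(dataset$Y, k = k, seed = seed)
  static <- precompute_static_layers(dataset, opts)
  pooled_scores <- numeric(0); pooled_labels <- numeric(0)
  per <- vector("list", k)
  for (fold in seq_len(k)) {
    held <- folds$positives[folds$fold_of == fold, , drop = FALSE]
    Ytr <- dataset$Y
    Ytr[held] <- 0
    fit <- ssgc_pipeline(dataset, Ytr, static = static, layers = layers,
                         prior = prior, opts = opts)
    eval_mask <- Ytr == 0                       # drop training positives
    labels <- matrix(0, nrow(Ytr), ncol(Ytr)); labels[held] <- 1
    roc <- modified_roc(fit$result$scores, labels, mask = eval_mask)
    ret <- top_percent_retrieval(fit$result$scores, held, pct = 1,
                                 exclude = Ytr == 1)
    per[[fold]] <- data.frame(fold = fold, auc = roc$auc,
                              held_out = nrow(held), retrieved_top1 = ret)
    pooled_scores <- c(pooled_scores, fit$result$scores[eval_mask])
    pooled_labels <- c(pooled_labels, labels[eval_mask])
  }
  per_fold <- do.call(rbind, per)
  list(pooled = modified_roc(pooled_scores, pooled_labels),
       per_fold = per_fold, mean_fold_auc = mean(per_fold$auc), folds = folds)
}
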