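#' Discard-retain curve for spurious-contact removal
#'
#' Sweeps percentile thresholds over the nonzero off-diagonal contacts of a
#' matrix whose contigs carry ground-truth species labels. At each threshold
#' `t`, a contact is discarded when its value is <= `t`; the curve records the
#' fraction of truly spurious (inter-species) contacts discarded against the
#' fraction of intra-species contacts retained. The area under the curve
#' (AUDRC, trapezoidal over the retained-fraction axis) is 1 for a perfect
#' separator — some threshold discards every spurious contact while retaining
#' every intra-species one — and about 0.5 when the two classes are
#' indistinguishable.
#'
#' @param cm a `ContactMatrix` in any state (raw and normalized matrices are
#'   compared by their curves).
#' @param truth ground-truth labels: a named character vector
#'   (contig -> species) or a data frame with columns `contig_id`, `species`.
#' @param percentiles integer percentile grid (default `0:100`).
#' @return A list of class `DRCurve`: `curve` (data frame `percentile`,
#'   `threshold`, `discarded`, `retained`) and `audrc`.
#' @export
dr_curve <- function(cm, truth, percentiles = 0:100) {
  labels <- truth_labels(truth)
  trip <- Matrix::mat2triplet(cm$mat)
  upper <- trip$i < trip$j & trip$x > 0
  ids <- contact_ids(cm)
  la <- labels[ids[trip$i[upper]]]
  lb <- labels[ids[trip$j[upper]]]
  vals <- trip$x[upper]
  ok <- !is.na(la) & !is.na(lb)
  vals <- vals[ok]
  if (length(vals) == 0) stop("no labeled contacts to evaluate")
  spurious <- la[ok] != lb[ok]
  if (!any(spurious) || all(spurious)) {
    stop("both intra-species and spurious contacts are required for a DR curve")
  }
  thresholds <- stats::quantile(vals, percentiles / 100, type = 7,
                                names = FALSE)
  discarded <- vapply(thresholds, function(t) mean(vals[spurious] <= t),
                      numeric(1))
  retained <- vapply(thresholds, function(t) mean(vals[!spurious] > t),
                     numeric(1))
  curve <- data.frame(percentile = percentiles, threshold = thresholds,
                      discarded = discarded, retained = retained)
  # anchor at "nothing discarded" so the retained axis spans [0, 1]; ties in
  # the retained fraction collapse to the best achievable discard there
  x <- c(1, retained)
  y <- c(0, discarded)
  env <- tapply(y, x, max)
  x <- as.numeric(names(env))
  y <- as.numeric(env)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  audrc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(curve = curve, audrc = audrc), class = "DRCurve")
}

#' @export
print.DRCurve <- function(x, ...) {
  cat(sprintf("DRCurve over %d thresholds, AUDRC = %.4f\n",
              nrow(x$curve), x$audrc))
  invisible(x)
}

truth_labels <- function(truth) {
  if (is.data.frame(truth)) {
    if (!all(c("contig_id", "species") %in% names(truth))) {
      stop("truth table must have columns contig_id and species")
    }
    stats::setNames(as.character(truth$species), truth$contig_id)
  } else if (!is.null(names(truth))) {
    stats::setNames(as.character(truth), names(truth))
  } else {
    stop("truth must be a named vector or a (contig_id, species) data frame")
  }
}

#' Read a ground-truth species-label table
#'
#' @param path TSV with columns `contig_id`, `species`.
#' @return Named character vector contig -> species.
#' @export
read_truth <- function(path) {
  truth_labels(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Clustering agreement between predicted bins and species labels
#'
#' Compares a contig partition against ground-truth species labels over
#' contig pairs: the Fowlkes-Mallows score
#' \eqn{\mathrm{TP}/\sqrt{(\mathrm{TP+FP})(\mathrm{TP+FN})}}, the adjusted
#' Rand index (permutation-model chance correction), and normalized mutual
#' information with arithmetic-mean normalization
#' \eqn{I(U,V) / \tfrac{1}{2}(H(U)+H(V))}. Contigs lacking a truth label are
#' excluded. When both partitions are the trivial single cluster all three
#' scores are defined as 1.
#'
#' @param pred a `Partition` or named vector contig -> bin.
#' @param truth a named vector or `(contig_id, species)` data frame.
#' @return A list of class `ClusteringScore` with elements `fscore`, `ari`,
#'   `nmi`.
#' @export
clustering_scores <- function(pred, truth) {
  labels <- truth_labels(truth)
  if (inherits(pred, "Partition") || is.data.frame(pred)) {
    pred <- stats::setNames(pred$bin_id, pred$contig_id)
  }
  common <- intersect(names(pred), names(labels))
  common <- common[!is.na(labels[common]) & !is.na(pred[common])]
  if (length(common) == 0) {
    stop("no contigs are both clustered and labeled")
  }
  u <- factor(pred[common])
  v <- factor(labels[common])
  ct <- table(u, v)
  n <- length(common)
  nij2 <- sum(choose(ct, 2))
  a2 <- sum(choose(rowSums(ct), 2))
  b2 <- sum(choose(colSums(ct), 2))
  npairs <- choose(n, 2)

  fscore <- if (a2 == 0 && b2 == 0) 1 else if (a2 == 0 || b2 == 0) 0 else {
    nij2 / sqrt(a2 * b2)
  }
  exp_index <- if (npairs > 0) a2 * b2 / npairs else 0
  denom <- (a2 + b2) / 2 - exp_index
  ari <- if (abs(denom) < .Machine$double.eps) 1 else (nij2 - exp_index) / denom

  pu <- rowSums(ct) / n
  pv <- colSums(ct) / n
  hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
  p <- ct / n
  mi <- sum(ifelse(p > 0, p * log(p / (pu %o% pv)), 0))
  nmi <- if (hu + hv == 0) 1 else if (hu == 0 || hv == 0) 0 else {
    mi / ((hu + hv) / 2)
  }
  structure(list(fscore = fscore, ari = ari, nmi = nmi),
            class = "ClusteringScore")
}

#' @export
print.ClusteringScore <- function(x, ...) {
  cat(sprintf("F-score = %.4f  ARI = %.4f  NMI = %.4f\n",
              x$fscore, x$ari, x$nmi))
  invisible(x)
}
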