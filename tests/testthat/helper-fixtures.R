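# Shared fixtures: tiny catalogs/matrices built in code, a SAM writer for the
# alignment path, and independent brute-force oracles used against the
# implementation.

toy_catalog <- function(ids, length = 2000L, n_sites = 3L,
                        coverage = NA_real_, species = NA_character_) {
  contig_catalog(ids, rep_len(length, base::length(ids)),
                 rep_len(n_sites, base::length(ids)),
                 coverage = rep_len(coverage, base::length(ids)),
                 species = rep_len(species, base::length(ids)))
}

toy_cm <- function(mat, ids = LETTERS[seq_len(nrow(mat))], state = "raw") {
  dimnames(mat) <- list(ids, ids)
  contact_matrix(mat, state = state)
}

# minimal NormCCModel with prescribed per-contig means
toy_model <- function(mu_hat, c_hat = max(mu_hat), theta = 2) {
  structure(list(coefficients = c(beta0 = 0, beta_s = 0, beta_l = 0,
                                  beta_N = 0),
                 theta = theta, mu_hat = mu_hat, c_hat = c_hat),
            class = "NormCCModel")
}

# Write SAM text and convert to BAM. `records` is a data frame with columns
# qname, flag, rname, pos, mapq, cigar.
make_bam <- function(records, refs) {
  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar)
  writeLines(c(header, body), sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = FALSE)
}

# All set partitions of n items as membership vectors (restricted growth
# strings), for exhaustive modularity enumeration.
enum_set_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, maxc) {
    i <- length(memb) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (c in seq_len(maxc + 1)) {
      recurse(c(memb, c), max(maxc, c))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Naive ordered-pair evaluation of the resolution-tuned modularity from the
# dense adjacency matrix.
rb_oracle <- function(A, memb, r) {
  n_vert <- nrow(A)
  d <- rowSums(A)
  n <- sum(A) / 2
  total <- 0
  for (i in seq_len(n_vert)) {
    for (j in seq_len(n_vert)) {
      if (i != j && memb[i] == memb[j]) {
        total <- total + A[i, j] - d[i] * d[j] / (2 * n) * r
      }
    }
  }
  total
}

# Pair-counting confusion over all item pairs (independent of contingency
# tables).
pair_confusion <- function(pred, truth) {
  n <- length(pred)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_p <- pred[i] == pred[j]
      same_t <- truth[i] == truth[j]
      if (same_p && same_t) tp <- tp + 1
      else if (same_p && !same_t) fp <- fp + 1
      else if (!same_p && same_t) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# NMI oracle via the joint-entropy identity I(U,V) = H(U) + H(V) - H(U,V).
nmi_oracle <- function(pred, truth) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  hu <- ent(pred); hv <- ent(truth)
  mi <- hu + hv - ent(paste(pred, truth, sep = "\r"))
  if (hu + hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi / ((hu + hv) / 2)
}

# random weighted undirected adjacency matrix (about half the pairs joined)
random_adjacency <- function(n, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < 0.55) {
        w <- round(stats::runif(1, 0.1, 5), 3)
        A[i, j] <- w
        A[j, i] <- w
      }
    }
  }
  A
}

graph_from_adjacency <- function(A, ids = paste0("V", seq_len(nrow(A)))) {
  dimnames(A) <- list(ids, ids)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
}
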