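#' Build the weighted contact graph
#'
#' Transforms a denoised (or normalized) contact matrix into an undirected
#' weighted graph without self-loops: one vertex per contig, one edge per
#' nonzero off-diagonal upper-triangle entry, edge weight equal to the
#' normalized contact value. Contigs without remaining contacts are retained
#' as isolated vertices.
#'
#' @param cm a `ContactMatrix` (state `"denoised"` or `"normalized"`; a raw
#'   matrix is accepted for benchmarking clustering on raw contacts).
#' @return An `igraph` graph with vertex names set to contig ids and edge
#'   attribute `weight`.
#' @export
build_graph <- function(cm) {
  trip <- Matrix::mat2triplet(cm$mat)
  upper <- trip$i < trip$j & trip$x > 0
  if (!any(upper)) stop("contact matrix has no nonzero off-diagonal entries")
  ids <- contact_ids(cm)
  edges <- rbind(ids[trip$i[upper]], ids[trip$j[upper]])
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::E(g)$weight <- trip$x[upper]
  g
}

# Coerce a Partition / named vector / plain vector into an integer membership
# vector aligned with the graph's vertices.
membership_for_graph <- function(graph, partition) {
  ids <- igraph::V(graph)$name
  if (inherits(partition, "Partition") || is.data.frame(partition)) {
    memb <- stats::setNames(partition$bin_id, partition$contig_id)[ids]
  } else if (!is.null(names(partition))) {
    memb <- partition[ids]
  } else {
    if (length(partition) != length(ids)) {
      stop("membership length does not match the number of vertices")
    }
    memb <- partition
  }
  if (anyNA(memb)) stop("partition does not cover every graph vertex")
  as.integer(factor(memb))
}

#' Reichardt-Bornholdt Potts modularity of a partition
#'
#' Evaluates the resolution-tuned modularity objective
#' \deqn{\sum_{\{i,j \,|\, \Delta_{ij} = 1,\ i \neq j\}}
#'   \left(e_{ij} - \frac{d_i d_j}{2n} \, r\right),}
#' summed over ordered pairs of distinct vertices in the same community, with
#' \eqn{e_{ij}} the edge weight, \eqn{d_i} the weighted degree, and \eqn{n}
#' the total edge weight. Larger resolutions \eqn{r} penalise the null term
#' more strongly and favour more, smaller communities; \eqn{r = 1} recovers
#' (up to scale) the classical modularity. Self-pairs contribute nothing (the
#' graph has no self-loops).
#'
#' @param graph a weighted `igraph` graph (unweighted edges count as weight
#'   1).
#' @param partition a `Partition`, a named membership vector, or a membership
#'   vector in vertex order.
#' @param r resolution parameter (> 0; `r = 0` drops the null term).
#' @return The objective value (a real; not normalised by \eqn{2n}).
#' @export
rb_modularity <- function(graph, partition, r = 1) {
  memb <- membership_for_graph(graph, partition)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  d <- igraph::strength(graph, weights = w)
  n <- sum(w)
  within <- memb[ends[, 1]] == memb[ends[, 2]]
  w_in <- sum(w[within])
  D_c <- tapply(d, memb, sum)
  d2_c <- tapply(d^2, memb, sum)
  null_term <- if (n > 0) r / (2 * n) * sum(D_c^2 - d2_c) else 0
  2 * w_in - null_term
}

# Deterministic single-vertex local-move sweep: repeatedly move vertices to
# the neighbouring (or an empty) community with the largest strictly positive
# gain in the RB objective, in vertex order, until no move improves.
refine_local_moves <- function(graph, memb, r, max_sweeps = 100L) {
  nv <- igraph::vcount(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  nbr <- vector("list", nv)
  nbw <- vector("list", nv)
  for (e in seq_along(w)) {
    a <- ends[e, 1]; b <- ends[e, 2]
    nbr[[a]] <- c(nbr[[a]], b); nbw[[a]] <- c(nbw[[a]], w[e])
    nbr[[b]] <- c(nbr[[b]], a); nbw[[b]] <- c(nbw[[b]], w[e])
  }
  d <- igraph::strength(graph, weights = w)
  n2 <- 2 * sum(w)
  if (n2 == 0) return(memb)
  memb <- as.integer(factor(memb))
  # community degree sums in a plain vector indexed by community id
  ncomm <- max(memb)
  Dv <- numeric(ncomm + nv) # room for newly opened empty communities
  Dv[seq_len(ncomm)] <- vapply(seq_len(ncomm),
                               function(c) sum(d[memb == c]), numeric(1))
  next_comm <- ncomm + 1L
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (v in seq_len(nv)) {
      a <- memb[v]
      nb <- nbr[[v]]
      if (is.null(nb)) nb <- integer(0)
      S <- if (length(nb) > 0) {
        tapply(nbw[[v]], memb[nb], sum)
      } else numeric(0)
      S_a <- if (as.character(a) %in% names(S)) S[[as.character(a)]] else 0
      # gain of leaving community a (to an empty community), unordered scale
      leave_gain <- -S_a + r / n2 * d[v] * (Dv[a] - d[v])
      best_gain <- leave_gain
      best_comm <- next_comm
      for (bc in names(S)) {
        b <- as.integer(bc)
        if (b == a) next
        gain <- S[[bc]] - r / n2 * d[v] * Dv[b] + leave_gain
        if (gain > best_gain + 1e-12 ||
            (gain > best_gain - 1e-12 && b < best_comm)) {
          best_gain <- gain
          best_comm <- b
        }
      }
      if (best_gain > 1e-12) {
        if (best_comm > length(Dv)) Dv[best_comm] <- 0
        Dv[a] <- Dv[a] - d[v]
        Dv[best_comm] <- Dv[best_comm] + d[v]
        memb[v] <- best_comm
        if (best_comm == next_comm) next_comm <- next_comm + 1L
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  as.integer(factor(memb))
}

#' Cluster contigs by Leiden community detection
#'
#' Runs the Leiden algorithm on the weighted contact graph, greedily
#' maximising the Reichardt-Bornholdt modularity of [rb_modularity()] at
#' resolution `r`, then applies a deterministic single-vertex local-move
#' sweep so the returned partition is move-stable: no move of one contig to a
#' neighbouring or empty community increases the objective. The result is
#' deterministic given `(graph, r, seed)`.
#'
#' @param graph a weighted `igraph` contact graph from [build_graph()].
#' @param r resolution parameter (> 0).
#' @param seed integer seed for the stochastic Leiden refinement (default
#'   42).
#' @param n_iterations Leiden iterations before the stabilising sweep.
#' @return A `Partition`: a data frame with columns `contig_id`, `bin_id`
#'   (labels `B1`, `B2`, ... ordered by decreasing bin size in contigs) and
#'   attributes `resolution` and `seed`.
#' @export
leiden_cluster <- function(graph, r = 1, seed = 42L, n_iterations = 10L) {
  if (r <= 0) stop("resolution r must be > 0")
  w <- igraph::E(graph)$weight
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               weights = w, resolution = r,
                               n_iterations = n_iterations)
  memb <- refine_local_moves(graph, igraph::membership(cl), r)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  # relabel communities by decreasing size, ties by first appearance
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  partition <- data.frame(contig_id = igraph::V(graph)$name,
                          bin_id = paste0("B", relabel[as.character(memb)]),
                          stringsAsFactors = FALSE)
  rownames(partition) <- NULL
  structure(partition, class = c("Partition", "data.frame"),
            resolution = r, seed = seed)
}

#' Verify that a partition is a local optimum under single-vertex moves
#'
#' Explicitly scans every vertex and every candidate target community
#' (neighbouring or empty) and checks that no move increases
#' [rb_modularity()] by more than `tol`. Used to verify the clustering
#' contract independently of the clustering backend.
#'
#' @param graph a weighted `igraph` graph.
#' @param partition a `Partition` or membership vector.
#' @param r resolution parameter.
#' @param tol numeric slack on the objective.
#' @return `TRUE` if move-stable, otherwise `FALSE`.
#' @export
is_move_stable <- function(graph, partition, r = 1, tol = 1e-9) {
  memb <- membership_for_graph(graph, partition)
  base <- rb_modularity(graph, memb, r)
  comms <- unique(memb)
  empty <- max(comms) + 1L
  for (v in seq_len(igraph::vcount(graph))) {
    nb_comms <- unique(memb[igraph::neighbors(graph, v)])
    for (target in c(setdiff(nb_comms, memb[v]), empty)) {
      trial <- memb
      trial[v] <- target
      if (rb_modularity(graph, trial, r) > base + tol) return(FALSE)
    }
  }
  TRUE
}
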