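#' Estimate the number of genomes from single-copy marker counts
#'
#' Single-copy marker genes are detected in the assembly by external gene
#' prediction and HMM search; each marker's copy count approximates the number
#' of genomes carrying it. The genome count `k` is estimated as the ceiling of
#' the median per-marker copy count (markers can fail detection in some
#' species, so the estimate tends to run slightly low — which the resolution
#' search compensates for by requiring `k_r > k`). A user-supplied `k`
#' bypasses estimation.
#'
#' @param marker_counts a data frame with columns `marker_id` and `count`, or
#'   a numeric vector of per-marker copy counts. May be `NULL` when `k` is
#'   supplied.
#' @param k optional positive integer override.
#' @return A list of class `GenomeCountEstimate` with elements `k` and
#'   `counts`.
#' @export
estimate_genome_count <- function(marker_counts = NULL, k = NULL) {
  if (!is.null(k)) {
    k <- as.integer(k)
    if (is.na(k) || k < 1) stop("genome count override k must be >= 1")
    counts <- if (is.null(marker_counts)) numeric(0) else marker_counts
    return(structure(list(k = k, counts = counts, estimated = FALSE),
                     class = "GenomeCountEstimate"))
  }
  if (is.data.frame(marker_counts)) {
    if (!all(c("marker_id", "count") %in% names(marker_counts))) {
      stop("marker table must have columns marker_id and count")
    }
    counts <- stats::setNames(marker_counts$count, marker_counts$marker_id)
  } else {
    counts <- marker_counts
  }
  if (is.null(counts) || length(counts) == 0) {
    stop("empty marker-count table and no genome-count override")
  }
  k <- max(1L, as.integer(ceiling(stats::median(counts))))
  structure(list(k = k, counts = counts, estimated = TRUE),
            class = "GenomeCountEstimate")
}

#' Total length of each bin in bp
#'
#' @param partition a `Partition`.
#' @param catalog a `ContigCatalog` covering the partition's contigs.
#' @return Named numeric vector of per-bin sizes (sum of member contig
#'   lengths, bp).
#' @export
bin_sizes <- function(partition, catalog) {
  len <- stats::setNames(catalog$length, catalog$contig_id)[partition$contig_id]
  if (anyNA(len)) stop("catalog does not cover every contig in the partition")
  tapply(as.numeric(len), partition$bin_id, sum)
}

count_resolved <- function(partition, catalog, min_bin_size) {
  sum(bin_sizes(partition, catalog) >= min_bin_size)
}

#' Select the Leiden resolution by matching the genome-count estimate
#'
#' Clusters the contact graph at each resolution of an increasing grid
#' (default \eqn{\{1, 20, 40, 60, 80, \dots\}}) and counts the resolved bins
#' \eqn{k_r} — bins whose total contig length is at least `min_bin_size`. The
#' selected resolution is the smallest `r` with \eqn{k_r > k}; requiring
#' strict excess guards against underestimation of `k`. If the grid is
#' exhausted the `r` maximising \eqn{k_r} is returned with a warning.
#'
#' @param graph the weighted contact graph.
#' @param k estimated (or overridden) genome count.
#' @param catalog `ContigCatalog` providing contig lengths.
#' @param grid strictly increasing resolution grid; default `1` followed by
#'   steps of 20 up to `r_max`.
#' @param min_bin_size minimum resolved-bin size in bp (default 150000).
#' @param r_max upper bound of the default grid (default 2000).
#' @param seed passed to [leiden_cluster()].
#' @return A list with elements `r`, `partition`, and `trace` (a data frame
#'   of `(r, k_r)` pairs for every resolution tried).
#' @export
select_resolution <- function(graph, k, catalog,
                              grid = c(1, seq(20, r_max, by = 20)),
                              min_bin_size = 150000, r_max = 2000,
                              seed = 42L) {
  if (any(diff(grid) <= 0)) stop("resolution grid must be strictly increasing")
  trace <- data.frame(r = numeric(0), k_r = integer(0))
  best <- NULL
  for (r in grid) {
    partition <- leiden_cluster(graph, r = r, seed = seed)
    k_r <- count_resolved(partition, catalog, min_bin_size)
    trace <- rbind(trace, data.frame(r = r, k_r = k_r))
    if (is.null(best) || k_r > best$k_r) {
      best <- list(r = r, partition = partition, k_r = k_r)
    }
    if (k_r > k) {
      return(list(r = r, partition = partition, trace = trace))
    }
  }
  warning("resolution grid exhausted without k_r > k; returning r = ",
          best$r, " with the largest k_r = ", best$k_r)
  list(r = best$r, partition = best$partition, trace = trace)
}

#' Flag resolved bins in a partition
#'
#' Bins whose total contig length reaches `min_bin_size` (default 150 kbp,
#' slightly below the smallest known bacterial genomes) are flagged
#' `resolved` and counted as MAGs; smaller bins are retained in the output
#' but flagged below-threshold.
#'
#' @param partition a `Partition`.
#' @param catalog a `ContigCatalog`.
#' @param min_bin_size minimum resolved size in bp; the boundary is
#'   inclusive (a bin of exactly `min_bin_size` is resolved).
#' @return The partition with a logical `resolved` column and a `bins`
#'   attribute (data frame `bin_id`, `size_bp`, `resolved`).
#' @export
make_initial_bins <- function(partition, catalog, min_bin_size = 150000) {
  sizes <- bin_sizes(partition, catalog)
  bins <- data.frame(bin_id = names(sizes), size_bp = as.numeric(sizes),
                     resolved = as.numeric(sizes) >= min_bin_size,
                     stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  partition$resolved <- bins$resolved[match(partition$bin_id, bins$bin_id)]
  attr(partition, "bins") <- bins
  class(partition) <- c("Partition", "data.frame")
  partition
}

#' Clean partially contaminated bins by re-clustering
#'
#' A bin that is substantially complete but contaminated (completeness > 50
#' and contamination > 10, from an externally computed quality table) likely
#' merges several genomes. Each such bin is re-clustered on its induced
#' contact subgraph with the Leiden algorithm at resolution 1 (the number of
#' genomes inside one bin is expected to be small); sub-bins reaching
#' `min_bin_size` replace the parent in the final bin set, while smaller
#' sub-bins are kept in the output flagged below-threshold. All other bins
#' pass through unchanged.
#'
#' @param partition a `Partition` (from [make_initial_bins()]).
#' @param quality data frame with columns `bin_id`, `completeness`,
#'   `contamination` covering (at least) the contaminated bins.
#' @param graph the weighted contact graph the partition was derived from.
#' @param catalog a `ContigCatalog`.
#' @param min_bin_size minimum resolved-bin size in bp.
#' @param seed passed to the re-clustering.
#' @return The cleaned `Partition` with updated `resolved` flags and `bins`
#'   attribute.
#' @export
clean_bins <- function(partition, quality, graph, catalog,
                       min_bin_size = 150000, seed = 42L) {
  if (!all(c("bin_id", "completeness", "contamination") %in% names(quality))) {
    stop("quality table must have columns bin_id, completeness, contamination")
  }
  unknown <- setdiff(quality$bin_id, partition$bin_id)
  if (length(unknown) > 0) {
    stop("quality records reference unknown bins: ",
         paste(unknown, collapse = ", "))
  }
  contaminated <- quality$bin_id[quality$completeness > 50 &
                                   quality$contamination > 10]
  out <- as.data.frame(partition)[, c("contig_id", "bin_id")]
  for (bin in contaminated) {
    members <- out$contig_id[out$bin_id == bin]
    in_graph <- intersect(members, igraph::V(graph)$name)
    sub <- igraph::induced_subgraph(graph, in_graph)
    if (igraph::ecount(sub) == 0) {
      sub_memb <- stats::setNames(seq_along(in_graph), in_graph)
    } else {
      sub_part <- leiden_cluster(sub, r = 1, seed = seed)
      sub_memb <- stats::setNames(as.integer(factor(sub_part$bin_id)),
                                  sub_part$contig_id)
    }
    # contigs of the bin absent from the graph each form their own sub-bin
    orphans <- setdiff(members, in_graph)
    if (length(orphans) > 0) {
      sub_memb <- c(sub_memb,
                    stats::setNames(max(sub_memb) + seq_along(orphans),
                                    orphans))
    }
    out$bin_id[out$bin_id == bin] <-
      paste0(bin, "_", sub_memb[out$contig_id[out$bin_id == bin]])
  }
  cleaned <- structure(out, class = c("Partition", "data.frame"),
                       resolution = attr(partition, "resolution"),
                       seed = attr(partition, "seed"))
  make_initial_bins(cleaned, catalog, min_bin_size)
}

#' Write / read a bin assignment table
#'
#' TSV with columns `contig_id`, `bin_id`, `resolved`.
#'
#' @param partition a `Partition` (ideally after [make_initial_bins()]).
#' @param path output path.
#' @return `write_bins` returns `path` invisibly; `read_bins` a `Partition`.
#' @export
write_bins <- function(partition, path) {
  df <- as.data.frame(partition)
  if (!"resolved" %in% names(df)) df$resolved <- NA
  utils::write.table(df[, c("contig_id", "bin_id", "resolved")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("Partition", "data.frame"))
}

#' Write one FASTA per resolved bin
#'
#' @param partition a `Partition` with `resolved` flags.
#' @param fasta_path path to the contig FASTA the bins refer to.
#' @param out_dir directory receiving one `<bin_id>.fa` per resolved bin.
#' @return Character vector of written files, invisibly.
#' @export
write_bin_fastas <- function(partition, fasta_path, out_dir) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  resolved <- unique(partition$bin_id[partition$resolved %in% TRUE])
  for (bin in resolved) {
    members <- partition$contig_id[partition$bin_id == bin]
    members <- intersect(members, names(seqs))
    if (length(members) == 0) next
    f <- file.path(out_dir, paste0(bin, ".fa"))
    Biostrings::writeXStringSet(seqs[members], f)
    written <- c(written, f)
  }
  invisible(written)
}
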