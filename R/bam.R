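#' Alignment filtering policy for Hi-C read pairs
#'
#' Mirrors the standard metaHi-C alignment cleanup: unmapped reads, secondary
#' and supplementary alignments are removed, as are alignments with nucleotide
#' match length < 30 or mapping quality < 30.
#'
#' @param min_match_length minimum summed aligned (CIGAR M/=/X) bases.
#' @param min_mapq minimum mapping quality.
#' @param drop_unmapped,drop_secondary,drop_supplementary drop the
#'   corresponding flagged records.
#' @return A list of class `AlignmentFilterPolicy`.
#' @export
alignment_filter_policy <- function(min_match_length = 30L, min_mapq = 30L,
                                    drop_unmapped = TRUE,
                                    drop_secondary = TRUE,
                                    drop_supplementary = TRUE) {
  if (min_match_length < 0 || min_mapq < 0) stop("thresholds must be >= 0")
  structure(list(min_match_length = as.integer(min_match_length),
                 min_mapq = as.integer(min_mapq),
                 drop_unmapped = isTRUE(drop_unmapped),
                 drop_secondary = isTRUE(drop_secondary),
                 drop_supplementary = isTRUE(drop_supplementary)),
            class = "AlignmentFilterPolicy")
}

# Sum of CIGAR M/=/X run lengths: the aligned nucleotide match length.
cigar_match_length <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  runs <- regmatches(cigar[ok], gregexpr("\\d+[M=X]", cigar[ok]))
  out[ok] <- vapply(runs, function(r) {
    if (length(r) == 0) 0L else sum(as.integer(sub("[M=X]$", "", r)))
  }, integer(1))
  out
}

#' Build a raw contact matrix from Hi-C read alignments in BAM
#'
#' Applies the [alignment_filter_policy()] record by record, then pairs the
#' surviving alignments by query name (aligners are typically run with read
#' pairing disabled for Hi-C, so the paired flag cannot be relied on). Each
#' query name with exactly two surviving records contributes one contact:
#' both mates on the same contig increment that contig's diagonal
#' (within-contig contact), mates on different contigs increment the
#' off-diagonal entry symmetrically. Query names with more than two surviving
#' records are dropped with a warning.
#'
#' @param bam_path path to a BAM file whose reference names match
#'   `catalog$contig_id`.
#' @param catalog a `ContigCatalog`.
#' @param policy an `AlignmentFilterPolicy`.
#' @return A raw `ContactMatrix` aligned to `catalog`.
#' @export
read_contacts_from_bam <- function(bam_path, catalog,
                                   policy = alignment_filter_policy()) {
  validate_catalog(catalog)
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  header <- Rsamtools::scanBamHeader(bam_path)[[1]]
  refs <- names(header$targets)
  unknown <- setdiff(refs, catalog$contig_id)
  if (length(unknown) > 0) {
    stop("BAM references absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "mapq", "cigar"))
  aln <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  flag <- aln$flag
  keep <- rep(TRUE, length(flag))
  if (policy$drop_unmapped) keep <- keep & bitwAnd(flag, 4L) == 0L
  if (policy$drop_secondary) keep <- keep & bitwAnd(flag, 256L) == 0L
  if (policy$drop_supplementary) keep <- keep & bitwAnd(flag, 2048L) == 0L
  keep <- keep & !is.na(aln$mapq) & aln$mapq >= policy$min_mapq
  keep <- keep & cigar_match_length(aln$cigar) >= policy$min_match_length
  qname <- aln$qname[keep]
  rname <- as.character(aln$rname[keep])
  tab <- table(qname)
  extra <- names(tab)[tab > 2]
  if (length(extra) > 0) {
    warning(length(extra), " query name(s) with more than two usable ",
            "alignments were dropped")
  }
  paired <- names(tab)[tab == 2]
  ids <- catalog$contig_id
  n <- length(ids)
  if (length(paired) == 0) {
    return(contact_matrix(
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(n, n), dimnames = list(ids, ids)),
      state = "raw"))
  }
  sel <- qname %in% paired
  ord <- order(qname[sel])
  ref_idx <- match(rname[sel][ord], ids)
  if (anyNA(ref_idx)) stop("alignment references a contig absent from catalog")
  first <- seq(1, length(ref_idx), by = 2)
  i <- pmin(ref_idx[first], ref_idx[first + 1])
  j <- pmax(ref_idx[first], ref_idx[first + 1])
  agg <- rowsum(rep(1, length(i)), group = paste(i, j))
  key <- matrix(as.integer(unlist(strsplit(rownames(agg), " "))),
                ncol = 2, byrow = TRUE)
  contact_matrix(i = key[, 1], j = key[, 2], x = as.numeric(agg),
                 ids = ids, state = "raw")
}
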