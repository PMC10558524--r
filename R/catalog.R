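#' Construct a contig catalog
#'
#' A `ContigCatalog` holds the static per-contig features used throughout the
#' pipeline: length \eqn{l_i} (bp), restriction-site count \eqn{s_i}, and
#' optionally the mean read depth \eqn{c_i} ("coverage") and a ground-truth
#' species label. Coverage is never required by the normalization model, which
#' substitutes within-contig ligation counts for it; it is carried only so
#' synthetic data can expose the true biases to the evaluation module.
#'
#' @param contig_id character vector of unique contig identifiers.
#' @param length integer vector of contig lengths in bp (>= 1).
#' @param n_sites integer vector of restriction-site counts (>= 0).
#' @param coverage optional positive numeric vector of mean read depths.
#' @param species optional character vector of ground-truth species labels.
#'
#' @return A data frame of class `ContigCatalog` with columns
#'   `contig_id`, `length`, `n_sites`, `coverage`, `species`.
#' @export
contig_catalog <- function(contig_id, length, n_sites,
                           coverage = NA_real_, species = NA_character_) {
  catalog <- data.frame(
    contig_id = as.character(contig_id),
    length = as.integer(length),
    n_sites = as.integer(n_sites),
    coverage = as.numeric(coverage),
    species = as.character(species),
    stringsAsFactors = FALSE
  )
  class(catalog) <- c("ContigCatalog", "data.frame")
  validate_catalog(catalog)
  catalog
}

#' Validate a contig catalog
#'
#' Checks the `ContigCatalog` invariants: unique ids, lengths >= 1, site
#' counts >= 0, and strictly positive coverage where present.
#'
#' @param catalog a `ContigCatalog` (or any data frame with its columns).
#' @return The catalog, invisibly; errors on violation.
#' @export
validate_catalog <- function(catalog) {
  required <- c("contig_id", "length", "n_sites")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(catalog$contig_id)) {
    dup <- unique(catalog$contig_id[duplicated(catalog$contig_id)])
    stop("duplicate contig ids in catalog: ", paste(dup, collapse = ", "))
  }
  if (any(catalog$length < 1)) stop("contig lengths must be >= 1 bp")
  if (any(catalog$n_sites < 0)) stop("restriction-site counts must be >= 0")
  if ("coverage" %in% names(catalog)) {
    cov <- catalog$coverage
    if (any(!is.na(cov) & cov <= 0)) stop("coverage, when present, must be > 0")
  }
  invisible(catalog)
}

#' Count restriction recognition sites in a nucleotide sequence
#'
#' Counts exact, possibly overlapping occurrences of each enzyme's recognition
#' sequence on the forward strand; for a non-palindromic recognition sequence
#' the reverse-complement pattern is counted as well, so both strand
#' orientations of the cut site are seen. Matching is case-insensitive and
#' exact: positions carrying IUPAC ambiguity codes (e.g. `N`) never match.
#'
#' The Hi-C protocols this package targets use Sau3AI (`GATC`) and MluCI
#' (`AATT`), both palindromic, so the reverse-complement rule is inert for the
#' defaults.
#'
#' @param sequence a single nucleotide string, `DNAString`, or a
#'   `DNAStringSet` (vectorised).
#' @param enzymes character vector of recognition sequences,
#'   e.g. `c("GATC", "AATT")`.
#' @return Integer count per input sequence.
#' @examples
#' count_restriction_sites("GATCAATT", c("GATC", "AATT")) # 2
#' count_restriction_sites("GATCGATCGATC", "GATC") # 3
#' @export
count_restriction_sites <- function(sequence, enzymes) {
  if (length(enzymes) == 0) stop("at least one enzyme recognition sequence is required")
  enzymes <- toupper(as.character(enzymes))
  if (any(nchar(enzymes) == 0)) stop("empty enzyme recognition sequence")
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAStringSet(toupper(sequence))
  } else if (methods::is(sequence, "DNAString")) {
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  patterns <- character(0)
  for (enz in enzymes) {
    patterns <- c(patterns, enz)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(enz)))
    if (!identical(rc, enz)) patterns <- c(patterns, rc)
  }
  counts <- integer(length(sequence))
  wide_enough <- Biostrings::width(sequence) > 0
  for (pat in patterns) {
    ok <- wide_enough & Biostrings::width(sequence) >= nchar(pat)
    if (any(ok)) {
      counts[ok] <- counts[ok] +
        Biostrings::vcountPattern(pat, sequence[ok], fixed = TRUE)
    }
  }
  counts
}

#' Load assembled contigs from FASTA into a catalog
#'
#' Reads a FASTA of assembled contigs and builds a `ContigCatalog` with length
#' and restriction-site count populated. The contig id is the first
#' whitespace-delimited token of each header. Coverage and species are left
#' absent.
#'
#' @param fasta_path path to a FASTA file.
#' @param enzymes recognition sequences passed to
#'   [count_restriction_sites()].
#' @return A `ContigCatalog`.
#' @export
load_contigs <- function(fasta_path, enzymes = c("GATC", "AATT")) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA headers: ", paste(dup, collapse = ", "))
  }
  contig_catalog(
    contig_id = ids,
    length = Biostrings::width(seqs),
    n_sites = count_restriction_sites(seqs, enzymes)
  )
}

#' Write / read a contig catalog as TSV
#'
#' The catalog dialect is a 5-column tab-separated table with header
#' `contig_id  length  n_sites  coverage  species`; absent coverage/species
#' are written as `NA`.
#'
#' @param catalog a `ContigCatalog`.
#' @param path output path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns a
#'   `ContigCatalog`.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  cols <- c("contig_id", "length", "n_sites", "coverage", "species")
  out <- as.data.frame(catalog)[, intersect(cols, names(catalog)), drop = FALSE]
  for (absent in setdiff(cols, names(out))) out[[absent]] <- NA
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  contig_catalog(df$contig_id, df$length, df$n_sites,
                 coverage = if ("coverage" %in% names(df)) df$coverage else NA_real_,
                 species = if ("species" %in% names(df)) df$species else NA_character_)
}
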