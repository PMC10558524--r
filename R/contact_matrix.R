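#' Contig-by-contig Hi-C contact matrix
#'
#' A `ContactMatrix` is a symmetric sparse matrix aligned to a
#' [contig_catalog()]: diagonal entries are within-contig contact counts
#' \eqn{N_i} (both read mates on the same contig) and off-diagonal entries are
#' across-contig contact counts \eqn{H_{ij}}. The matrix exists in three
#' states: `"raw"` (nonnegative integer counts), `"normalized"`
#' (bias-corrected reals, zero diagonal) and `"denoised"` (after spurious
#' contact removal).
#'
#' @param mat a square matrix or `Matrix` sparse matrix with contig ids as
#'   dimnames, or `NULL` when building from triplets.
#' @param state one of `"raw"`, `"normalized"`, `"denoised"`.
#' @param i,j,x,ids triplet representation: integer indices into `ids` and
#'   values `x`; both orientations of each off-diagonal pair are filled in.
#' @param threshold optional removal threshold recorded by
#'   [remove_spurious()].
#' @return An object of class `ContactMatrix`: a list with elements `mat`
#'   (a `dgCMatrix` with dimnames), `state` and `threshold`.
#' @export
contact_matrix <- function(mat = NULL, state = "raw", i = NULL, j = NULL,
                           x = NULL, ids = NULL, threshold = NULL) {
  state <- match.arg(state, c("raw", "normalized", "denoised"))
  if (is.null(mat)) {
    if (is.null(ids)) stop("ids are required when building from triplets")
    n <- length(ids)
    off <- i != j
    ii <- c(i, j[off])
    jj <- c(j, i[off])
    xx <- c(x, x[off])
    mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                                dimnames = list(ids, ids))
  }
  mat <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"),
                     "CsparseMatrix")
  if (is.null(rownames(mat))) stop("contact matrix requires contig ids as dimnames")
  cm <- structure(list(mat = Matrix::drop0(mat), state = state,
                       threshold = threshold),
                  class = "ContactMatrix")
  validate_contact_matrix(cm)
  cm
}

#' Validate a contact matrix
#'
#' Checks symmetry, nonnegativity, integer entries in the raw state, and a
#' zero diagonal in the normalized/denoised states.
#'
#' @param cm a `ContactMatrix`.
#' @return `cm`, invisibly; errors on violation.
#' @export
validate_contact_matrix <- function(cm) {
  mat <- cm$mat
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (!identical(rownames(mat), colnames(mat))) stop("dimnames must agree")
  if (!Matrix::isSymmetric(mat, tol = 1e-10)) stop("contact matrix must be symmetric")
  if (any(mat@x < 0)) stop("contact values must be nonnegative")
  if (cm$state == "raw") {
    if (any(abs(mat@x - round(mat@x)) > 1e-9)) {
      stop("raw contact matrix must hold integer counts")
    }
  } else {
    if (any(Matrix::diag(mat) != 0)) {
      stop(cm$state, " contact matrix must have a zero diagonal")
    }
  }
  invisible(cm)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  nz <- Matrix::nnzero(x$mat)
  cat(sprintf("ContactMatrix [%s]: %d contigs, %d stored entries\n",
              x$state, nrow(x$mat), nz))
  if (!is.null(x$threshold)) {
    cat(sprintf("  removal threshold: %g\n", x$threshold))
  }
  invisible(x)
}

#' @export
dim.ContactMatrix <- function(x) dim(x$mat)

contact_ids <- function(cm) rownames(cm$mat)

#' Read a raw contact matrix from a 3-column TSV
#'
#' The contact-table dialect has a required header `contig_a  contig_b  count`
#' (lines starting with `#` are ignored). Rows with `contig_a == contig_b` set
#' the diagonal (within-contig contacts); duplicate unordered pairs are
#' summed.
#'
#' @param tsv_path path to the table.
#' @param catalog `ContigCatalog` giving the contig universe and order.
#' @param state state of the stored values (default `"raw"`, which enforces
#'   integer counts).
#' @return A `ContactMatrix` aligned to `catalog`.
#' @export
read_contacts_from_table <- function(tsv_path, catalog, state = "raw") {
  validate_catalog(catalog)
  state <- match.arg(state, c("raw", "normalized", "denoised"))
  df <- utils::read.delim(tsv_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  required <- c("contig_a", "contig_b", "count")
  if (!all(required %in% names(df))) {
    stop("contact table must have columns: ", paste(required, collapse = ", "))
  }
  ids <- catalog$contig_id
  ia <- match(df$contig_a, ids)
  ib <- match(df$contig_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    unknown <- unique(c(df$contig_a[is.na(ia)], df$contig_b[is.na(ib)]))
    stop("contact table references unknown contigs: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(df$count < 0)) stop("contact counts must be nonnegative")
  if (state == "raw" && any(abs(df$count - round(df$count)) > 1e-9)) {
    stop("contact counts must be nonnegative integers")
  }
  # collapse duplicate unordered pairs before building
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  agg <- rowsum(as.numeric(df$count), group = paste(lo, hi))
  key <- matrix(as.integer(unlist(strsplit(rownames(agg), " "))),
                ncol = 2, byrow = TRUE)
  contact_matrix(i = key[, 1], j = key[, 2], x = as.numeric(agg),
                 ids = ids, state = state)
}

#' Write a contact matrix as TSV
#'
#' Writes the upper triangle (including the diagonal for raw matrices) in the
#' 3-column contact dialect, preceded by `#`-comment header lines recording
#' the state and, when set, the spurious-removal threshold and model file.
#'
#' @param cm a `ContactMatrix`.
#' @param path output path.
#' @param model_file optional path of the normalization model, recorded in the
#'   header.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path, model_file = NULL) {
  tri <- Matrix::triu(cm$mat)
  trip <- Matrix::mat2triplet(tri)
  ids <- contact_ids(cm)
  keep <- trip$x != 0
  ord <- order(trip$i[keep], trip$j[keep])
  df <- data.frame(contig_a = ids[trip$i[keep]][ord],
                   contig_b = ids[trip$j[keep]][ord],
                   count = trip$x[keep][ord])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", cm$state), con)
  if (!is.null(cm$threshold)) {
    writeLines(sprintf("# threshold: %.10g", cm$threshold), con)
  }
  if (!is.null(model_file)) writeLines(sprintf("# model: %s", model_file), con)
  writeLines(paste("contig_a", "contig_b", "count", sep = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(paste(df$contig_a, df$contig_b,
                     format(df$count, digits = 15, trim = TRUE,
                            scientific = FALSE), sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a contact matrix written by [write_contacts()]
#'
#' Restores the state (and threshold) recorded in the `#` header comments.
#'
#' @param path path to the table.
#' @param catalog `ContigCatalog` giving the contig universe.
#' @return A `ContactMatrix`.
#' @export
read_contacts <- function(path, catalog) {
  header <- readLines(path, n = 20)
  header <- header[startsWith(header, "#")]
  state <- "raw"
  threshold <- NULL
  st <- grep("^# state:", header, value = TRUE)
  if (length(st) > 0) state <- trimws(sub("^# state:", "", st[1]))
  th <- grep("^# threshold:", header, value = TRUE)
  if (length(th) > 0) threshold <- as.numeric(trimws(sub("^# threshold:", "", th[1])))
  cm <- read_contacts_from_table(path, catalog, state = state)
  cm$threshold <- threshold
  validate_contact_matrix(cm)
  cm
}

#' Across-contig Hi-C signal per contig
#'
#' The Hi-C signal of contig \eqn{i} is its total number of across-contig
#' proximity-ligation events, \eqn{M_i = \sum_{k \neq i} H_{ik}} — the row sum
#' of the contact matrix excluding the diagonal. It is the response of the
#' normalization regression.
#'
#' @param cm a `ContactMatrix`.
#' @return Named numeric vector `M`, one entry per contig.
#' @export
hic_signal <- function(cm) {
  M <- Matrix::rowSums(cm$mat) - Matrix::diag(cm$mat)
  names(M) <- contact_ids(cm)
  M
}

#' Within-contig contact counts
#'
#' Extracts the diagonal \eqn{N_i = H_{ii}}: read pairs with both mates on the
#' same contig, used by the normalization model as a coverage surrogate.
#'
#' @param cm a `ContactMatrix`.
#' @return Named numeric vector `N`.
#' @export
within_contacts <- function(cm) {
  N <- Matrix::diag(cm$mat)
  names(N) <- contact_ids(cm)
  N
}

#' Contig filtering policy
#'
#' Problematic short contigs with few restriction sites or few Hi-C contacts
#' have high-variance signal and destabilise downstream analysis; they are
#' removed by thresholds on length, site count, across-contig contacts
#' \eqn{M_i} and within-contig contacts \eqn{N_i}.
#'
#' @param min_length minimum contig length in bp (default 1000).
#' @param min_sites minimum number of restriction sites (default 1).
#' @param min_across minimum across-contig Hi-C contacts \eqn{M_i} (default 2).
#' @param min_within minimum within-contig Hi-C contacts \eqn{N_i} (default 1).
#' @return A list of class `ContigFilterPolicy`.
#' @export
contig_filter_policy <- function(min_length = 1000L, min_sites = 1L,
                                 min_across = 2L, min_within = 1L) {
  policy <- list(min_length = as.integer(min_length),
                 min_sites = as.integer(min_sites),
                 min_across = as.integer(min_across),
                 min_within = as.integer(min_within))
  if (any(unlist(policy) < 0)) stop("filter thresholds must be >= 0")
  structure(policy, class = "ContigFilterPolicy")
}

#' Filter problematic contigs from catalog and contact matrix
#'
#' Removes, in a single pass computed on the input matrix, every contig
#' failing any clause of the [contig_filter_policy()]. Removal is not
#' iterated: a contig dropped for low contacts does not trigger recomputation
#' of its neighbours' signal.
#'
#' @param catalog a `ContigCatalog`.
#' @param cm a raw `ContactMatrix` aligned to `catalog`.
#' @param policy a `ContigFilterPolicy`.
#' @return A list with elements `catalog` and `matrix` restricted to the
#'   surviving contigs.
#' @export
apply_contig_filters <- function(catalog, cm, policy = contig_filter_policy()) {
  validate_catalog(catalog)
  if (!identical(catalog$contig_id, contact_ids(cm))) {
    stop("contact matrix is not aligned to the catalog")
  }
  M <- hic_signal(cm)
  N <- within_contacts(cm)
  keep <- catalog$length >= policy$min_length &
    catalog$n_sites >= policy$min_sites &
    M >= policy$min_across &
    N >= policy$min_within
  if (!any(keep)) stop("no contigs survive filtering")
  sub_cat <- catalog[keep, , drop = FALSE]
  rownames(sub_cat) <- NULL
  class(sub_cat) <- c("ContigCatalog", "data.frame")
  sub_mat <- cm$mat[keep, keep, drop = FALSE]
  list(catalog = sub_cat,
       matrix = contact_matrix(sub_mat, state = cm$state))
}
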