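test_that("restriction sites are counted exactly, overlapping, on both strands", {
  expect_identical(count_restriction_sites("GATCAATT", c("GATC", "AATT")), 2L)
  expect_identical(count_restriction_sites("CCCCCC", c("GATC", "AATT")), 0L)
  # sliding-window scan by hand: GATC at 1, 5, 9
  expect_identical(count_restriction_sites("GATCGATCGATC", "GATC"), 3L)
  # overlapping occurrences all counted: ATAT at 1 and 3
  expect_identical(count_restriction_sites("ATATAT", "ATAT"), 2L)
  # non-palindromic recognition sequence: reverse complement also counted
  expect_identical(count_restriction_sites("AAGACGCAAGCGTCAA", "GACGC"), 2L)
  # case-insensitive; ambiguity codes never match
  expect_identical(count_restriction_sites("gatc", "GATC"), 1L)
  expect_identical(count_restriction_sites("GATNCGANC", "GATC"), 0L)
  expect_identical(count_restriction_sites("", "GATC"), 0L)
  expect_error(count_restriction_sites("GATC", character(0)), "enzyme")
})

test_that("load_contigs builds a catalog from FASTA and rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "GATCAATTGG", ">c2", "CCCCC"), fa)
  catalog <- load_contigs(fa)
  expect_s3_class(catalog, "ContigCatalog")
  expect_identical(catalog$contig_id, c("c1", "c2"))
  expect_identical(catalog$length, c(10L, 5L))
  expect_identical(catalog$n_sites, c(2L, 0L))
  expect_true(all(is.na(catalog$coverage)))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), dup)
  expect_error(load_contigs(dup), "c1")
})

test_that("catalog invariants are enforced", {
  expect_error(contig_catalog(c("a", "a"), c(10, 10), c(1, 1)), "duplicate")
  expect_error(contig_catalog("a", 0, 1), "length")
  expect_error(contig_catalog("a", 10, -1), "site")
  expect_error(contig_catalog("a", 10, 1, coverage = 0), "coverage")
})

test_that("contact tables round-trip with summed duplicates and symmetry", {
  catalog <- toy_catalog(c("A", "B", "C"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("contig_a\tcontig_b\tcount",
               "A\tB\t2", "B\tA\t3", "A\tA\t5", "C\tB\t1"), tsv)
  cm <- read_contacts_from_table(tsv, catalog)
  expect_equal(as.numeric(cm$mat["A", "B"]), 5) # duplicate unordered pair summed
  expect_equal(as.numeric(cm$mat["B", "A"]), 5)
  expect_equal(as.numeric(cm$mat["A", "A"]), 5)
  expect_equal(as.numeric(cm$mat["B", "C"]), 1)
  expect_true(Matrix::isSymmetric(cm$mat))
  # total entries (diagonal once) equals the number of read pairs represented
  expect_equal(sum(Matrix::triu(cm$mat)), 2 + 3 + 5 + 1)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("contig_a\tcontig_b\tcount", "A\tZZ\t1"), bad)
  expect_error(read_contacts_from_table(bad, catalog), "ZZ")

  out <- tempfile(fileext = ".tsv")
  write_contacts(cm, out)
  back <- read_contacts(out, catalog)
  expect_equal(as.matrix(back$mat), as.matrix(cm$mat))
  expect_identical(back$state, "raw")
})

test_that("contig filters enforce every default clause in a single pass", {
  # defaults: length >= 1000, sites >= 1, M >= 2, N >= 1
  catalog <- contig_catalog(c("A", "B", "C", "D", "E"),
                            length = c(2000, 500, 2000, 2000, 2000),
                            n_sites = c(3, 5, 0, 2, 4))
  m <- matrix(0, 5, 5)
  # A: M=2, N=1 -> retained (meets every default exactly)
  # B: short (500) -> removed despite contacts
  # C: zero sites -> removed
  # D: M=1 (< 2) -> removed
  # E: N=0 -> removed
  m[1, 2] <- m[2, 1] <- 1
  m[1, 5] <- m[5, 1] <- 1
  m[3, 2] <- m[2, 3] <- 4
  m[4, 2] <- m[2, 4] <- 1
  diag(m) <- c(1, 2, 3, 4, 0)
  cm <- toy_cm(m, ids = catalog$contig_id)
  res <- apply_contig_filters(catalog, cm)
  expect_identical(res$catalog$contig_id, "A")
  # single pass: A retained although its surviving neighbourhood shrank
  expect_identical(dim(res$matrix$mat), c(1L, 1L))

  strict <- contig_filter_policy(min_length = 10000)
  expect_error(apply_contig_filters(catalog, cm, strict), "no contigs survive")
})

test_that("exactly one failing clause removes a contig (4-contig enumeration)", {
  catalog <- contig_catalog(c("w", "x", "y", "z"),
                            length = c(1000, 1200, 1500, 1100),
                            n_sites = c(1, 1, 2, 1))
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 2
  m[3, 4] <- m[4, 3] <- 2
  m[1, 3] <- m[3, 1] <- 1
  diag(m) <- c(1, 1, 1, 0) # z alone has N = 0
  cm <- toy_cm(m, ids = catalog$contig_id)
  res <- apply_contig_filters(catalog, cm)
  expect_identical(res$catalog$contig_id, c("w", "x", "y"))
  expect_true(Matrix::isSymmetric(res$matrix$mat))
})

test_that("raw matrices reject negatives, non-integers and asymmetry", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(toy_cm(m), "ContactMatrix")
  expect_error(toy_cm(matrix(c(0, 1.5, 1.5, 0), 2, 2)), "integer")
  expect_error(toy_cm(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  expect_error(contact_matrix(matrix(c(0, 2, 1, 0), 2, 2,
                                     dimnames = list(c("A", "B"),
                                                     c("A", "B")))),
               "symmetric")
})
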