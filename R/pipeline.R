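#' @title Pipeline entry points
#' @description Thin orchestration over the package's modules, in the order a
#'   metaHi-C analysis runs: simulate (optional) -> norm -> bin -> eval. Each
#'   stage reads/writes the package's plain-text TSV dialects and records a
#'   machine-readable provenance JSON with inputs, parameters, seed and
#'   package version, sufficient to reproduce its outputs bit-for-bit.
#' @name pipeline
NULL

write_provenance <- function(out_dir, stage, params) {
  record <- list(tool = "metahic",
                 version = as.character(utils::packageVersion("metahic")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 stage = stage, params = params)
  jsonlite::write_json(record, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

log_lines <- function(out_dir, stage, lines) {
  cat(lines, file = file.path(out_dir, paste0(stage, ".log")),
      sep = "\n", append = TRUE)
}

#' Generate a synthetic metaHi-C dataset on disk
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); receives
#'   `catalog.tsv`, `contacts_raw.tsv`, `truth.tsv`, `markers.tsv` and a
#'   provenance record.
#' @param fasta also emit random contig sequences as `contigs.fa` (off by
#'   default; sequence emission is slow for large catalogs).
#' @return Invisibly, the list from [simulate_metahic()].
#' @export
run_simulate <- function(config = sim_config(), out_dir, fasta = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_metahic(config)
  write_catalog(sim$catalog, file.path(out_dir, "catalog.tsv"))
  write_contacts(sim$contacts, file.path(out_dir, "contacts_raw.tsv"))
  utils::write.table(
    data.frame(contig_id = names(sim$truth), species = sim$truth),
    file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  markers <- simulate_marker_counts(config$n_genomes, seed = config$seed + 3L)
  utils::write.table(markers, file.path(out_dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (fasta) {
    simulate_fasta(sim$catalog, file.path(out_dir, "contigs.fa"),
                   seed = config$seed + 4L)
  }
  write_provenance(out_dir, "simulate", unclass(config))
  invisible(sim)
}

#' Run the normalization stage
#'
#' Builds the catalog (from FASTA or a catalog TSV) and the raw contact
#' matrix (from BAM or a contact TSV), applies the contig filters, fits the
#' normalization model, writes the bias-corrected matrix and removes spurious
#' contacts.
#'
#' @param out_dir output directory; receives `catalog.tsv`,
#'   `contacts_raw.tsv`, `normcc_model.tsv`, `contacts_normalized.tsv`,
#'   `contacts_denoised.tsv`, a log and a provenance record.
#' @param fasta,catalog path to contig FASTA or to a catalog TSV (one
#'   required).
#' @param bam,contacts path to a Hi-C BAM or to a raw contact TSV (one
#'   required).
#' @param enzymes restriction recognition sequences (FASTA path only).
#' @param filter_policy a [contig_filter_policy()].
#' @param alignment_policy an [alignment_filter_policy()] (BAM path only).
#' @param percentile spurious-removal percentile (default 5).
#' @return Invisibly, a list with the filtered `catalog`, `raw`,
#'   `normalized`, `denoised` matrices and the `model`.
#' @export
run_norm <- function(out_dir, fasta = NULL, catalog = NULL, bam = NULL,
                     contacts = NULL, enzymes = c("GATC", "AATT"),
                     filter_policy = contig_filter_policy(),
                     alignment_policy = alignment_filter_policy(),
                     percentile = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fasta) && is.null(catalog)) {
    stop("either a FASTA or a catalog TSV is required")
  }
  if (is.null(bam) && is.null(contacts)) {
    stop("either a BAM or a contact TSV is required")
  }
  cat_obj <- if (!is.null(fasta)) load_contigs(fasta, enzymes) else read_catalog(catalog)
  raw <- if (!is.null(bam)) {
    read_contacts_from_bam(bam, cat_obj, alignment_policy)
  } else {
    read_contacts_from_table(contacts, cat_obj)
  }
  filtered <- apply_contig_filters(cat_obj, raw, filter_policy)
  model <- fit_normcc(filtered$catalog, filtered$matrix)
  normalized <- normalize_contacts(filtered$matrix, model)
  denoised <- remove_spurious(normalized, spurious_removal_policy(percentile))
  write_catalog(filtered$catalog, file.path(out_dir, "catalog.tsv"))
  write_contacts(filtered$matrix, file.path(out_dir, "contacts_raw.tsv"))
  model_file <- file.path(out_dir, "normcc_model.tsv")
  write_normcc_model(model, model_file)
  write_contacts(normalized, file.path(out_dir, "contacts_normalized.tsv"),
                 model_file = "normcc_model.tsv")
  write_contacts(denoised, file.path(out_dir, "contacts_denoised.tsv"),
                 model_file = "normcc_model.tsv")
  log_lines(out_dir, "norm", c(
    sprintf("contigs in: %d, contigs retained: %d",
            nrow(cat_obj), nrow(filtered$catalog)),
    sprintf("model: %s, theta=%.4f",
            paste(sprintf("%s=%.4f", names(model$coefficients),
                          model$coefficients), collapse = " "), model$theta),
    sprintf("spurious removal: percentile=%g threshold=%.6g", percentile,
            denoised$threshold)))
  write_provenance(out_dir, "norm", list(
    fasta = fasta, catalog = catalog, bam = bam, contacts = contacts,
    enzymes = enzymes, filter_policy = unclass(filter_policy),
    alignment_policy = unclass(alignment_policy), percentile = percentile))
  invisible(list(catalog = filtered$catalog, raw = filtered$matrix,
                 normalized = normalized, denoised = denoised, model = model))
}

#' Run the binning stage
#'
#' Builds the contact graph from a denoised contact table, determines the
#' genome count (from a marker table or an override), selects the resolution,
#' flags resolved bins, optionally cleans contaminated bins, and writes the
#' assignment.
#'
#' @param out_dir output directory; receives `bins.tsv`, a log with the
#'   resolution-search trace, a provenance record and, when `fasta` is
#'   given, per-bin FASTAs under `bin_fasta/`.
#' @param contacts path to the denoised contact TSV.
#' @param catalog path to the matching catalog TSV.
#' @param markers path to a marker-count TSV (`marker_id`, `count`).
#' @param num_genomes optional integer override of the genome count.
#' @param quality optional path to a bin-quality TSV (`bin_id`,
#'   `completeness`, `contamination`); triggers bin cleaning.
#' @param min_bin_size minimum resolved-bin size in bp (default 150000).
#' @param seed clustering seed (default 42).
#' @param fasta optional contig FASTA for per-bin sequence output.
#' @return Invisibly, a list with `partition`, `r`, `k`, `trace`.
#' @export
run_bin <- function(out_dir, contacts, catalog, markers = NULL,
                    num_genomes = NULL, quality = NULL,
                    min_bin_size = 150000, seed = 42L, fasta = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cat_obj <- read_catalog(catalog)
  cm <- read_contacts(contacts, cat_obj)
  graph <- build_graph(cm)
  est <- if (!is.null(num_genomes)) {
    estimate_genome_count(k = num_genomes)
  } else {
    if (is.null(markers)) stop("either a marker table or --num-genomes is required")
    estimate_genome_count(utils::read.delim(markers, stringsAsFactors = FALSE))
  }
  sel <- select_resolution(graph, est$k, cat_obj, min_bin_size = min_bin_size,
                           seed = seed)
  partition <- make_initial_bins(sel$partition, cat_obj, min_bin_size)
  if (!is.null(quality)) {
    qual <- utils::read.delim(quality, stringsAsFactors = FALSE)
    partition <- clean_bins(partition, qual, graph, cat_obj, min_bin_size,
                            seed = seed)
  }
  write_bins(partition, file.path(out_dir, "bins.tsv"))
  if (!is.null(fasta)) {
    write_bin_fastas(partition, fasta, file.path(out_dir, "bin_fasta"))
  }
  log_lines(out_dir, "bin", c(
    if (est$estimated) sprintf("genome count estimated: k=%d", est$k)
    else sprintf("genome count override: k=%d (estimator skipped)", est$k),
    sprintf("resolution search trace: %s",
            paste(sprintf("(r=%g, k_r=%d)", sel$trace$r, sel$trace$k_r),
                  collapse = " ")),
    sprintf("selected resolution r=%g", sel$r),
    sprintf("resolved bins: %d",
            sum(attr(partition, "bins")$resolved))))
  write_provenance(out_dir, "bin", list(
    contacts = contacts, catalog = catalog, markers = markers,
    num_genomes = num_genomes, quality = quality,
    min_bin_size = min_bin_size, seed = seed))
  invisible(list(partition = partition, r = sel$r, k = est$k,
                 trace = sel$trace))
}

#' Run the evaluation stage
#'
#' Scores a bin assignment against ground-truth species labels and, when a
#' contact table is supplied, computes the discard-retain curve of its
#' values.
#'
#' @param out_dir output directory; receives `scores.tsv` (and
#'   `dr_curve.tsv`).
#' @param pred path to a bin TSV from [run_bin()].
#' @param truth path to a truth TSV (`contig_id`, `species`).
#' @param contacts optional contact TSV to evaluate with a DR curve.
#' @param catalog catalog TSV (required with `contacts`).
#' @return Invisibly, a list with `scores` and optionally `dr`.
#' @export
run_eval <- function(out_dir, pred, truth, contacts = NULL, catalog = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_vec <- read_truth(truth)
  partition <- read_bins(pred)
  scores <- clustering_scores(partition, truth_vec)
  utils::write.table(
    data.frame(metric = c("fscore", "ari", "nmi"),
               value = c(scores$fscore, scores$ari, scores$nmi)),
    file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  out <- list(scores = scores)
  if (!is.null(contacts)) {
    if (is.null(catalog)) stop("a catalog TSV is required with contacts")
    cm <- read_contacts(contacts, read_catalog(catalog))
    dr <- dr_curve(cm, truth_vec)
    utils::write.table(dr$curve, file.path(out_dir, "dr_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines(out_dir, "eval", sprintf("AUDRC = %.6f", dr$audrc))
    out$dr <- dr
  }
  write_provenance(out_dir, "eval", list(pred = pred, truth = truth,
                                         contacts = contacts,
                                         catalog = catalog))
  invisible(out)
}
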