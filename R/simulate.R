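#' Configuration for the synthetic metaHi-C generator
#'
#' The generator emulates, with known ground truth, the statistical structure
#' of a metaHi-C experiment on a small microbial community: contigs with
#' log-normal lengths, Poisson restriction-site counts at a fixed per-bp
#' density, genome abundances (hence contig coverages) that vary across
#' genomes, within-contig contact counts drawn from a negative binomial whose
#' log-mean is linear in log(sites), log(length), log(coverage), and
#' across-contig contacts drawn from a negative binomial whose mean is a
#' product of per-contig bias factors — two orders of magnitude larger within
#' a species than between species.
#'
#' @param n_genomes number of genomes in the community (default 10).
#' @param contigs_per_genome integer range `c(min, max)` of contigs drawn per
#'   genome (default `c(25, 50)`).
#' @param length_meanlog,length_sdlog log-normal contig-length parameters in
#'   bp (defaults `log(2e4)`, 0.7).
#' @param min_length lengths are floored here (default 1000 bp, matching the
#'   default assembly cutoff).
#' @param site_density expected restriction sites per bp (default 1/128, the
#'   expectation for the two 4-bp cutters GATC and AATT on uniform sequence).
#' @param site_density_sdlog log-normal spread of a per-genome multiplier on
#'   `site_density` (default 0.3): genome composition (notably GC content)
#'   shifts 4-bp cutter densities several-fold between taxa, so site count is
#'   not a deterministic function of length.
#' @param abundance_meanlog,abundance_sdlog log-normal genome-abundance
#'   parameters (defaults `log(5)`, 0.8).
#' @param coverage_noise_sdlog per-contig log-normal coverage noise around
#'   the genome abundance (default 0.3).
#' @param gamma0,gamma_s,gamma_l,gamma_c within-contig contact model
#'   coefficients: `log(nu_i) = gamma0 + gamma_s log(s_i) + gamma_l log(l_i)
#'   + gamma_c log(c_i)` (defaults -1, 0.6, 0.4, 0.9 — chosen so a typical
#'   20 kbp contig at 5x coverage yields roughly 1700 within-contig
#'   contacts, comparable to its total across-contig signal; in Hi-C
#'   libraries local ligations dominate, so within-contig counts are never
#'   rare relative to across-contig ones).
#' @param sigma within-contig NB dispersion (default 8, moderate residual
#'   overdispersion for a count aggregated over many restriction fragments).
#' @param intra_mean mean across-contig contact count for a same-species
#'   contig pair with median bias factors (default 100).
#' @param ratio intra/inter-species mean contact ratio (default 100).
#' @param exponents across-contig bias exponents `c(a, b, d)` on sites,
#'   length, coverage (default `c(0.75, 0.75, 0.9)`).
#' @param theta across-contig NB dispersion (default 2).
#' @param inter_sparsity fraction of inter-species contig pairs receiving a
#'   contact draw (default 0.05; ligation noise touches few pairs).
#' @param seed integer seed recorded in the config (default 42).
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genomes = 10L, contigs_per_genome = c(25L, 50L),
                       length_meanlog = log(2e4), length_sdlog = 0.7,
                       min_length = 1000L, site_density = 1 / 128,
                       site_density_sdlog = 0.3,
                       abundance_meanlog = log(5), abundance_sdlog = 0.8,
                       coverage_noise_sdlog = 0.3,
                       gamma0 = -1, gamma_s = 0.6, gamma_l = 0.4,
                       gamma_c = 0.9, sigma = 8,
                       intra_mean = 100, ratio = 100,
                       exponents = c(a = 0.75, b = 0.75, d = 0.9),
                       theta = 2, inter_sparsity = 0.05, seed = 42L) {
  config <- list(n_genomes = as.integer(n_genomes),
                 contigs_per_genome = as.integer(contigs_per_genome),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 site_density = site_density,
                 site_density_sdlog = site_density_sdlog,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 coverage_noise_sdlog = coverage_noise_sdlog,
                 gamma0 = gamma0, gamma_s = gamma_s, gamma_l = gamma_l,
                 gamma_c = gamma_c, sigma = sigma,
                 intra_mean = intra_mean, ratio = ratio,
                 exponents = exponents, theta = theta,
                 inter_sparsity = inter_sparsity, seed = as.integer(seed))
  if (config$sigma <= 0 || config$theta <= 0) stop("dispersions must be > 0")
  if (config$ratio <= 1) stop("intra/inter ratio must be > 1")
  if (config$inter_sparsity < 0 || config$inter_sparsity > 1) {
    stop("inter_sparsity must lie in [0, 1]")
  }
  structure(config, class = "SimulationConfig")
}

#' Simulate a contig catalog with ground-truth labels
#'
#' Draws, per genome, a number of contigs uniform in `contigs_per_genome`;
#' contig lengths are log-normal floored at `min_length`, restriction-site
#' counts Poisson with mean `length * site_density` floored at 1, and
#' coverages equal the genome abundance times log-normal noise. Species
#' labels `G1, G2, ...` are attached.
#'
#' @param config a [sim_config()].
#' @param seed seed applied before drawing (default `config$seed`); pass
#'   `NULL` to continue the current random stream.
#' @return A `ContigCatalog` with coverage and species populated.
#' @export
simulate_catalog <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cpg_range <- seq(config$contigs_per_genome[1], config$contigs_per_genome[2])
  n_per <- cpg_range[sample.int(length(cpg_range), config$n_genomes,
                                replace = TRUE)]
  genome <- rep(seq_len(config$n_genomes), n_per)
  n <- length(genome)
  len <- pmax(config$min_length,
              round(stats::rlnorm(n, config$length_meanlog,
                                  config$length_sdlog)))
  density <- config$site_density *
    stats::rlnorm(config$n_genomes, 0, config$site_density_sdlog)[genome]
  sites <- pmax(1L, stats::rpois(n, len * density))
  abundance <- stats::rlnorm(config$n_genomes, config$abundance_meanlog,
                             config$abundance_sdlog)
  coverage <- abundance[genome] *
    stats::rlnorm(n, 0, config$coverage_noise_sdlog)
  contig_catalog(contig_id = sprintf("C%05d", seq_len(n)),
                 length = len, n_sites = sites, coverage = coverage,
                 species = paste0("G", genome))
}

# Per-contig across-contig bias factor, scaled to median 1.
bias_factor <- function(catalog, config) {
  e <- config$exponents
  f <- catalog$n_sites^e[["a"]] * catalog$length^e[["b"]] *
    catalog$coverage^e[["d"]]
  f / stats::median(f)
}

#' Simulate a raw Hi-C contact matrix for a catalog
#'
#' Within-contig counts follow the within-contig model
#' \eqn{N_i \sim \mathrm{NB}(\nu_i, \sigma)} with
#' \eqn{\log \nu_i = \gamma_0 + \gamma_s \log s_i + \gamma_l \log l_i +
#' \gamma_c \log c_i}. Across-contig counts for a contig pair are negative
#' binomial with mean `intra_mean * f_i * f_j` for same-species pairs, where
#' `f_i` is the median-scaled bias factor \eqn{s_i^a l_i^b c_i^d}, and
#' `intra_mean * f_i * f_j / ratio` for the sampled fraction
#' (`inter_sparsity`) of different-species pairs.
#'
#' @param catalog a catalog from [simulate_catalog()] (coverage and species
#'   required).
#' @param config the same [sim_config()].
#' @param seed seed applied before drawing (default `config$seed + 1`);
#'   `NULL` continues the current stream.
#' @return A raw `ContactMatrix`.
#' @export
simulate_contacts <- function(catalog, config = sim_config(),
                              seed = config$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(catalog$coverage) || anyNA(catalog$species)) {
    stop("catalog must carry coverage and species (see simulate_catalog)")
  }
  n <- nrow(catalog)
  nu <- exp(config$gamma0) * catalog$n_sites^config$gamma_s *
    catalog$length^config$gamma_l * catalog$coverage^config$gamma_c
  N <- stats::rnbinom(n, size = config$sigma, mu = nu)
  f <- bias_factor(catalog, config)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- catalog$species[pair_idx[, 1]] == catalog$species[pair_idx[, 2]]
  intra <- pair_idx[same, , drop = FALSE]
  inter <- pair_idx[!same, , drop = FALSE]
  n_inter <- floor(config$inter_sparsity * nrow(inter))
  if (n_inter > 0) {
    inter <- inter[sample(nrow(inter), n_inter), , drop = FALSE]
  } else {
    inter <- inter[0, , drop = FALSE]
  }
  mu_intra <- config$intra_mean * f[intra[, 1]] * f[intra[, 2]]
  mu_inter <- config$intra_mean * f[inter[, 1]] * f[inter[, 2]] / config$ratio
  h_intra <- stats::rnbinom(nrow(intra), size = config$theta, mu = mu_intra)
  h_inter <- stats::rnbinom(nrow(inter), size = config$theta, mu = mu_inter)
  i <- c(intra[, 1], inter[, 1], seq_len(n))
  j <- c(intra[, 2], inter[, 2], seq_len(n))
  x <- c(h_intra, h_inter, N)
  keep <- x > 0
  contact_matrix(i = i[keep], j = j[keep], x = x[keep],
                 ids = catalog$contig_id, state = "raw")
}

#' Simulate catalog, contacts and truth in one deterministic call
#'
#' Wraps [simulate_catalog()] and [simulate_contacts()] with seeds derived
#' from `config$seed`, so two runs with equal configs are bit-identical.
#'
#' @param config a [sim_config()].
#' @return A list with elements `catalog`, `contacts` (raw `ContactMatrix`)
#'   and `truth` (named species vector).
#' @export
simulate_metahic <- function(config = sim_config()) {
  catalog <- simulate_catalog(config, seed = config$seed)
  contacts <- simulate_contacts(catalog, config, seed = config$seed + 1L)
  truth <- stats::setNames(catalog$species, catalog$contig_id)
  list(catalog = catalog, contacts = contacts, truth = truth,
       config = config)
}

#' Simulate the Hi-C signal directly under the regression model
#'
#' For studies of coefficient recovery: draws within-contig counts
#' \eqn{N_i} from the within-contig model (floored at 1 so the log predictor
#' exists), then the across-contig signal
#' \eqn{M_i \sim \mathrm{NB}(\exp(\beta_0 + \beta_s \log s_i +
#' \beta_l \log l_i + \beta_N \log N_i),\ \theta)} — exactly the model fitted
#' by [fit_normcc_glm()].
#'
#' @param catalog a catalog with coverage (from [simulate_catalog()]).
#' @param beta numeric `c(beta0, beta_s, beta_l, beta_N)`.
#' @param theta NB dispersion of the signal.
#' @param config a [sim_config()] supplying the within-contig model.
#' @param seed seed applied before drawing; `NULL` continues the stream.
#' @return A data frame `contig_id, s, l, N, M`.
#' @export
simulate_signal <- function(catalog, beta, theta, config = sim_config(),
                            seed = config$seed + 2L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(catalog)
  nu <- exp(config$gamma0) * catalog$n_sites^config$gamma_s *
    catalog$length^config$gamma_l * catalog$coverage^config$gamma_c
  N <- pmax(1L, stats::rnbinom(n, size = config$sigma, mu = nu))
  mu <- exp(beta[1] + beta[2] * log(catalog$n_sites) +
              beta[3] * log(catalog$length) + beta[4] * log(N))
  M <- stats::rnbinom(n, size = theta, mu = mu)
  data.frame(contig_id = catalog$contig_id, s = catalog$n_sites,
             l = catalog$length, N = N, M = M, stringsAsFactors = FALSE)
}

#' Simulate per-marker single-copy gene counts
#'
#' Emulates external marker-gene detection: each of `n_markers` single-copy
#' markers is detected independently in each genome with probability
#' `detection_rate`, so per-marker copy counts are binomial and the median
#' tends to sit slightly below the true genome number.
#'
#' @param n_genomes true number of genomes.
#' @param n_markers number of markers in the set (default 107, the size of
#'   the standard bacterial single-copy marker set).
#' @param detection_rate per-genome detection probability (default 0.9).
#' @param seed seed applied before drawing; `NULL` continues the stream.
#' @return A data frame `marker_id, count`.
#' @export
simulate_marker_counts <- function(n_genomes, n_markers = 107L,
                                   detection_rate = 0.9, seed = 42L) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(marker_id = sprintf("marker_%03d", seq_len(n_markers)),
             count = stats::rbinom(n_markers, n_genomes, detection_rate),
             stringsAsFactors = FALSE)
}

#' Emit random contig sequences matching a catalog
#'
#' Writes uniform-random ACGT sequences of the catalog's lengths to FASTA (at
#' uniform composition the two 4-bp recognition sites GATC and AATT occur at
#' the generator's default density of 1/128 per bp in expectation). Intended
#' to exercise the FASTA entry point on small catalogs; site counts realised
#' in the sequences are random, not the catalog's `n_sites`.
#'
#' @param catalog a `ContigCatalog`.
#' @param path output FASTA path.
#' @param seed seed applied before drawing; `NULL` continues the stream.
#' @return `path`, invisibly.
#' @export
simulate_fasta <- function(catalog, path, seed = 42L) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(catalog$length, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- catalog$contig_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
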