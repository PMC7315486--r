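#' Simulate nucleosome-phased cfDNA fragments
#'
#' Generates fragments from a dyad-jitter point process: nucleosome dyads
#' are placed at regular `dyad_spacing` intervals across the region (none
#' inside the optional nucleosome-free interval), each fragment picks a dyad
#' uniformly at random, its midpoint is the dyad plus Gaussian jitter
#' (`dyad_jitter_sd`, the phasing strength: 0 is perfect phasing, large
#' values approach an unphased library), and its length is drawn from a
#' normal truncated to `length_range`. Fragments are clipped to the region.
#' The defaults (190 bp spacing, 167 +/- 10 bp fragments) emulate the
#' mononucleosomal fragment peak of plasma cfDNA.
#'
#' @param region_start,region_end Region bounds (0-based half-open); must
#'   exceed twice the spacing.
#' @param n_fragments Number of fragments to generate.
#' @param chrom Chromosome name, default `"chr1"`.
#' @param dyad_spacing Nucleosome repeat length in bases, default 190.
#' @param dyad_jitter_sd Gaussian jitter SD of fragment midpoints around
#'   their dyad, in bases.
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution, default 167 +/- 10, truncated to `length_range`.
#' @param length_range Truncation bounds (inclusive), default `c(100, 500)`.
#' @param nfr Optional `c(start, end)` interval containing no dyads (a
#'   nucleosome-free region).
#' @param dyad_offset Offset of the first dyad from `region_start`;
#'   default half the spacing.
#' @param seed Integer seed; generation is a pure function of the
#'   parameters and the seed.
#' @return A `cf_fragments` tibble with `n_fragments` rows, plus attribute
#'   `dyads` (the dyad positions used).
#' @examples
#' fr <- simulate_phased_fragments(0, 2000, n_fragments = 500,
#'                                 dyad_jitter_sd = 5, seed = 1)
#' attr(fr, "dyads")
#' @export
simulate_phased_fragments <- function(region_start, region_end, n_fragments,
                                      chrom = "chr1", dyad_spacing = 190,
                                      dyad_jitter_sd = 20,
                                      fragment_length_mean = 167,
                                      fragment_length_sd = 10,
                                      length_range = c(100, 500), nfr = NULL,
                                      dyad_offset = NULL, seed) {
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (region_end - region_start <= 2 * dyad_spacing) {
    abort("region must be longer than twice the dyad spacing")
  }
  if (n_fragments <= 0) abort("n_fragments must be positive")
  dyad_offset <- dyad_offset %||% (dyad_spacing %/% 2)
  dyads <- seq.int(region_start + dyad_offset, region_end - 1L, by = dyad_spacing)
  if (!is.null(nfr)) dyads <- dyads[dyads < nfr[1] | dyads >= nfr[2]]
  if (length(dyads) == 0) abort("no dyads remain in the region")

  withr::with_seed(as.integer(seed), {
    mid <- dyads[sample.int(length(dyads), n_fragments, replace = TRUE)] +
      round(rnorm(n_fragments, 0, dyad_jitter_sd))
    len <- round(rnorm(n_fragments, fragment_length_mean, fragment_length_sd))
    bad <- which(len < length_range[1] | len > length_range[2])
    while (length(bad) > 0) { # redraw out-of-range lengths (truncated normal)
      len[bad] <- round(rnorm(length(bad), fragment_length_mean, fragment_length_sd))
      bad <- bad[len[bad] < length_range[1] | len[bad] > length_range[2]]
    }
    start <- pmax(region_start, as.integer(mid - len %/% 2L))
    end <- pmin(region_end, as.integer(start + len))
    start <- pmin(start, end - 1L) # clipping never empties a fragment
    out <- as_fragments(tibble(chrom = chrom, start = start, end = end))
    attr(out, "dyads") <- dyads
    out
  })
}

#' Simulate a methylation mixture over a synthetic reference atlas
#'
#' Draws a reference matrix of per-locus tissue methylation fractions from
#' `Beta(beta_shape[1], beta_shape[2])` (the default Beta(0.3, 0.3) is
#' bimodal, mimicking mostly-methylated/mostly-unmethylated informative
#' CpGs), mixes the tissue profiles with the supplied coefficients, and
#' samples the measured methylation of each locus binomially at the given
#' sequencing depth. The ground-truth coefficients are returned for
#' recovery testing.
#'
#' @param n_tissues,n_loci Reference dimensions.
#' @param depth Binomial sampling depth per locus (reads covering the
#'   locus).
#' @param true_coefficients Numeric vector of length `n_tissues`,
#'   non-negative with sum at most 1.
#' @param beta_shape Shape parameters of the Beta prior on reference
#'   entries, default `c(0.3, 0.3)`.
#' @param tissue_names,locus_ids Optional names; defaults `tissue1..k`,
#'   `locus1..n`.
#' @param seed Integer seed.
#' @return A list: `reference` (tibble `locus_id` + tissue columns),
#'   `sample` (tibble `locus_id`, `meth_fraction`, `coverage`),
#'   `true_coefficients` (named numeric).
#' @export
simulate_methylation_mixture <- function(n_tissues, n_loci, depth,
                                         true_coefficients,
                                         beta_shape = c(0.3, 0.3),
                                         tissue_names = NULL, locus_ids = NULL,
                                         seed) {
  if (length(true_coefficients) != n_tissues) {
    abort("true_coefficients must have one entry per tissue")
  }
  if (any(true_coefficients < 0) || sum(true_coefficients) > 1 + 1e-9) {
    abort("true coefficients must be non-negative with sum <= 1")
  }
  if (depth < 1) abort("depth must be >= 1")
  tissue_names <- tissue_names %||% paste0("tissue", seq_len(n_tissues))
  locus_ids <- locus_ids %||% paste0("locus", seq_len(n_loci))

  withr::with_seed(as.integer(seed), {
    A <- matrix(rbeta(n_loci * n_tissues, beta_shape[1], beta_shape[2]),
                nrow = n_loci, dimnames = list(NULL, tissue_names))
    expected <- drop(A %*% true_coefficients)
    measured <- rbinom(n_loci, size = depth, prob = pmin(1, expected)) / depth
    list(
      reference = dplyr::bind_cols(tibble(locus_id = locus_ids),
                                   as_tibble(A)),
      sample = tibble(locus_id = locus_ids, meth_fraction = measured,
                      coverage = as.integer(depth)),
      true_coefficients = stats::setNames(true_coefficients, tissue_names)
    )
  })
}

#' Simulate donor-allele pileups at informative SNP positions
#'
#' Each position's expected donor-allele fraction is the true graft-derived
#' cfDNA fraction for a homozygous-alternate donor, or half of it for a
#' heterozygous donor; alt counts are binomial at the given depth.
#'
#' @param true_fraction True graft-derived cfDNA fraction in `[0, 1]`.
#' @param donor_mode `"hom"` or `"het"`.
#' @param n_positions Number of informative positions.
#' @param depth Reads per position.
#' @param seed Integer seed.
#' @param chrom Chromosome name, default `"chr1"`.
#' @return A tibble `chrom`, `pos`, `alt_count`, `total_count` with
#'   attribute `donor_mode`.
#' @export
simulate_allele_pileups <- function(true_fraction, donor_mode = c("hom", "het"),
                                    n_positions, depth, seed, chrom = "chr1") {
  donor_mode <- match.arg(donor_mode)
  if (true_fraction < 0 || true_fraction > 1) abort("true_fraction must be in [0, 1]")
  expected <- if (donor_mode == "het") true_fraction / 2 else true_fraction
  withr::with_seed(as.integer(seed), {
    out <- tibble(
      chrom = chrom,
      pos = seq_len(n_positions) * 1000L,
      alt_count = rbinom(n_positions, size = depth, prob = expected),
      total_count = as.integer(depth)
    )
    attr(out, "donor_mode") <- donor_mode
    out
  })
}
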