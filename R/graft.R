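#' Select donor-informative SNP positions for graft-fraction estimation
#'
#' Keeps positions where the donor carries an A>T or T>A transversion
#' (homozygous alternate or heterozygous) and the recipient is called
#' reference. Only A/T transversions are usable because cytosine conversion
#' corrupts C/T and G/A evidence in converted libraries. Positions where a
#' heterozygous or homozygous variant call was made in the recipient are
#' excluded, as are positions the recipient table does not cover.
#'
#' @param donor A data frame `chrom`, `pos`, `ref`, `alt`, `genotype` with
#'   genotype in `hom_alt`, `het`, `hom_ref`/`ref`.
#' @param recipient A data frame `chrom`, `pos` with either a `genotype`
#'   column (as above) or raw call columns `alt_count`, `total_count`; in
#'   the latter case an alt fraction `>= recipient_alt_threshold` counts as
#'   a variant call.
#' @param recipient_alt_threshold Alt-fraction threshold treating a raw
#'   recipient call as variant, default 0.2.
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `donor_genotype`, `keep`,
#'   `reason` (empty for kept rows). Errors when no position survives.
#' @export
select_informative_positions <- function(donor, recipient,
                                         recipient_alt_threshold = 0.2) {
  d <- tibble(
    chrom = as.character(donor$chrom), pos = as.integer(donor$pos),
    ref = toupper(as.character(donor$ref)), alt = toupper(as.character(donor$alt)),
    donor_genotype = as.character(donor$genotype)
  )
  reason <- rep("", nrow(d))
  at <- (d$ref == "A" & d$alt == "T") | (d$ref == "T" & d$alt == "A")
  reason[!at] <- "not_AT_transversion"
  informative <- d$donor_genotype %in% c("hom_alt", "het")
  reason[at & !informative] <- "donor_not_variant"

  key <- paste(d$chrom, d$pos)
  if ("genotype" %in% names(recipient)) {
    rec_variant <- as.character(recipient$genotype) %in% c("het", "hom_alt")
  } else {
    if (!all(c("alt_count", "total_count") %in% names(recipient))) {
      abort("recipient needs a genotype column or alt_count/total_count columns")
    }
    frac <- ifelse(recipient$total_count > 0,
                   recipient$alt_count / recipient$total_count, 0)
    rec_variant <- frac >= recipient_alt_threshold
  }
  rec_key <- paste(as.character(recipient$chrom), as.integer(recipient$pos))
  idx <- match(key, rec_key)
  uncovered <- is.na(idx)
  variant_in_recipient <- !uncovered & rec_variant[idx]
  pending <- reason == ""
  reason[pending & uncovered] <- "recipient_uncalled"
  pending <- reason == ""
  reason[pending & variant_in_recipient] <- "variant_in_recipient"

  d$keep <- reason == ""
  d$reason <- reason
  if (!any(d$keep)) abort("no informative positions survive selection")
  d
}

#' Estimate the graft-derived cfDNA fraction from donor-allele pileups
#'
#' Averages the per-position donor-allele fractions over informative
#' positions with sufficient depth. When the donor is heterozygous for the
#' informative alleles, only half of the graft-derived molecules carry the
#' variant, so the averaged fraction is doubled; the result is capped at 1.
#' The 95% confidence halfwidth is `1.96 * sd(fractions) / sqrt(n)` computed
#' on the post-doubling per-position fractions.
#'
#' @param pileups A data frame `chrom`, `pos`, `alt_count`, `total_count`.
#' @param positions Optional output of [select_informative_positions()];
#'   pileups are restricted to its kept rows. When omitted, every pileup row
#'   is treated as informative and `donor_mode` is required.
#' @param donor_mode `"hom"` or `"het"`. Defaults to the (single) donor
#'   genotype of the kept positions; mixed genotypes are an error - estimate
#'   the homozygous and heterozygous sets separately.
#' @param min_depth Minimum pileup depth per position, default 10.
#' @return A `graft_fraction` object: list with `fraction`,
#'   `ci95_halfwidth`, `n_positions`, `doubled`, and `per_position` tibble.
#'   [glance()] returns the one-row summary; [tidy()] the per-position
#'   fractions.
#' @examples
#' pu <- simulate_allele_pileups(true_fraction = 0.1, donor_mode = "hom",
#'                               n_positions = 200, depth = 50, seed = 7)
#' glance(estimate_graft_fraction(pu, donor_mode = "hom"))
#' @export
estimate_graft_fraction <- function(pileups, positions = NULL, donor_mode = NULL,
                                    min_depth = 10) {
  pu <- tibble(
    chrom = as.character(pileups$chrom), pos = as.integer(pileups$pos),
    alt_count = as.integer(pileups$alt_count),
    total_count = as.integer(pileups$total_count)
  )
  if (any(pu$alt_count > pu$total_count)) abort("alt_count exceeds total_count")
  if (!is.null(positions)) {
    kept <- positions[positions$keep, ]
    modes <- unique(kept$donor_genotype)
    if (is.null(donor_mode)) {
      if (length(modes) > 1) {
        abort("positions mix hom_alt and het donors; estimate the sets separately")
      }
      donor_mode <- if (modes == "het") "het" else "hom"
    }
    pu <- dplyr::inner_join(pu, kept[, c("chrom", "pos")], by = c("chrom", "pos"))
  }
  if (is.null(donor_mode)) abort("donor_mode is required when positions are not given")
  donor_mode <- match.arg(donor_mode, c("hom", "het"))
  pu <- pu[pu$total_count >= min_depth, ]
  if (nrow(pu) == 0) abort("no positions with sufficient depth")

  frac <- pu$alt_count / pu$total_count
  if (donor_mode == "het") frac <- 2 * frac
  est <- min(1, mean(frac))
  ci <- if (nrow(pu) > 1) 1.96 * sd(frac) / sqrt(nrow(pu)) else NA_real_
  structure(
    list(fraction = est, ci95_halfwidth = ci, n_positions = nrow(pu),
         doubled = donor_mode == "het",
         per_position = tibble(chrom = pu$chrom, pos = pu$pos,
                               allele_fraction = pu$alt_count / pu$total_count,
                               depth = pu$total_count)),
    class = "graft_fraction"
  )
}

#' @export
print.graft_fraction <- function(x, ...) {
  cat("<graft_fraction> ", format(100 * x$fraction, digits = 3), "% +/- ",
      format(100 * x$ci95_halfwidth, digits = 2), "% (95% CI), n = ",
      x$n_positions, " positions",
      if (x$doubled) ", het donor (fractions doubled)" else "", "\n", sep = "")
  invisible(x)
}

#' @method tidy graft_fraction
#' @export
tidy.graft_fraction <- function(x, ...) x$per_position

#' @method glance graft_fraction
#' @export
glance.graft_fraction <- function(x, ...) {
  tibble(fraction = x$fraction, ci95_halfwidth = x$ci95_halfwidth,
         n_positions = x$n_positions, doubled = x$doubled)
}
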