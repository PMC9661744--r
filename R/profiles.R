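# Per-sample profiles and ctDNA level metrics.

#' Build a sample profile
#'
#' A sample profile bundles the filtered variant calls of one
#' (patient, compartment, timepoint) sample with its cell-free DNA
#' concentration and the derived ctDNA metrics:
#'
#' * `max_vaf` -- the largest VAF among VAF-bearing variants (0 if none),
#'   a proxy for the dominant clone's fraction;
#' * `mean_vaf` -- mean VAF over SNV/indel/fusion calls (CNVs carry no
#'   allele fraction and are excluded);
#' * `ctdna_hge_per_ml` -- mean VAF x cfDNA (pg/mL) / 3.3, the ctDNA
#'   concentration in haploid genome equivalents per mL, taking one
#'   haploid genome as 3.3 pg;
#' * `is_positive` -- whether at least one call passed filtering.
#'
#' Samples with zero passing variants are kept (`is_positive = FALSE`)
#' rather than dropped, since detection-rate statistics need them.
#'
#' @param sample_id,patient_id Identifiers.
#' @param compartment `"CSF"`, `"plasma"` or `"tissue"`.
#' @param timepoint `"baseline"`, `"week8"` or `"progression"`.
#' @param cfdna_pg_per_ml Total cell-free DNA concentration, pg/mL.
#' @param variants A variant-call data.frame for this sample.
#' @param cfg A [filter_config()] applied to `variants`; pass `NULL` if
#'   the calls are already filtered.
#'
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, patient_id, compartment, timepoint,
                           cfdna_pg_per_ml, variants = empty_variant_calls(),
                           cfg = filter_config()) {
  stopifnot(compartment %in% COMPARTMENTS, timepoint %in% TIMEPOINTS)
  if (cfdna_pg_per_ml < 0) stop("negative cfDNA concentration")
  variants <- validate_variant_calls(variants)
  if (!is.null(cfg)) variants <- apply_filters(variants, cfg)
  p <- structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         compartment = compartment, timepoint = timepoint,
         cfdna_pg_per_ml = cfdna_pg_per_ml, variants = variants),
    class = "sample_profile")
  p$max_vaf <- max_vaf(p)
  p$mean_vaf <- mean_vaf(p)
  p$ctdna_hge_per_ml <- ctdna_concentration(p)
  p$is_positive <- nrow(variants) > 0L
  p
}

vaf_bearing <- function(profile) {
  v <- profile$variants
  v[v$variant_class %in% VAF_CLASSES, , drop = FALSE]
}

#' Maximum variant allele frequency of a sample
#'
#' @param profile A [sample_profile()].
#' @return The largest VAF among VAF-bearing variants; 0 when none.
#' @export
max_vaf <- function(profile) {
  v <- vaf_bearing(profile)
  if (nrow(v) == 0L) return(0)
  max(v$vaf)
}

#' Mean variant allele frequency of a sample
#'
#' Mean over SNV/indel/fusion calls only; 0 when none.
#'
#' @param profile A [sample_profile()].
#' @return Mean VAF as a fraction.
#' @export
mean_vaf <- function(profile) {
  v <- vaf_bearing(profile)
  if (nrow(v) == 0L) return(0)
  mean(v$vaf)
}

#' ctDNA concentration in haploid genome equivalents per mL
#'
#' `mean VAF x cfDNA concentration (pg/mL) / 3.3`, assuming each haploid
#' genome equivalent (hGE) weighs 3.3 pg.  A sample with no VAF-bearing
#' variant has concentration 0.
#'
#' @param profile A [sample_profile()].
#' @return Non-negative concentration in hGE/mL.
#' @export
ctdna_concentration <- function(profile) {
  if (profile$cfdna_pg_per_ml < 0) stop("negative cfDNA concentration")
  mean_vaf(profile) * profile$cfdna_pg_per_ml / 3.3
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile> %s (%s %s %s): %d variants, maxVAF %.4f, %.3f hGE/mL\n",
    x$sample_id, x$patient_id, x$compartment, x$timepoint,
    nrow(x$variants), x$max_vaf, x$ctdna_hge_per_ml))
  invisible(x)
}

#' Build profiles for every sample in a manifest
#'
#' Reads each sample's VCF, applies the filters and derives the ctDNA
#' metrics.
#'
#' @param manifest A manifest data.frame from [read_manifest()].
#' @param cfg A [filter_config()].
#' @return A named list of `sample_profile` objects, keyed by sample id.
#' @export
build_profiles <- function(manifest, cfg = filter_config()) {
  profiles <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    calls <- read_variant_file(row$vcf_path, sample_id = row$sample_id,
                               patient_id = row$patient_id)
    sample_profile(sample_id = row$sample_id, patient_id = row$patient_id,
                   compartment = row$compartment, timepoint = row$timepoint,
                   cfdna_pg_per_ml = row$cfdna_pg_per_ml,
                   variants = calls, cfg = cfg)
  })
  names(profiles) <- manifest$sample_id
  profiles
}

#' Find one profile in a profile list
#'
#' @param profiles A list of [sample_profile()] objects.
#' @param patient_id,compartment,timepoint Selection keys.
#' @return The matching profile, or `NULL` when the sample is absent.
#' @export
find_profile <- function(profiles, patient_id, compartment, timepoint) {
  # fast path: simulated cohorts name samples "<patient>_<comp>_<tp>"
  guess <- paste(patient_id, compartment, timepoint, sep = "_")
  p <- profiles[[guess]]
  if (!is.null(p) && p$patient_id == patient_id &&
      p$compartment == compartment && p$timepoint == timepoint) {
    return(p)
  }
  for (p in profiles) {
    if (p$patient_id == patient_id && p$compartment == compartment &&
        p$timepoint == timepoint) {
      return(p)
    }
  }
  NULL
}

#' Sample-level detection rates
#'
#' Fraction of samples with at least one passing alteration, split by
#' compartment and timepoint.
#'
#' @param profiles A list of [sample_profile()] objects.
#' @return A data.frame with columns `compartment`, `timepoint`,
#'   `n_samples`, `n_positive`, `positivity`.
#' @export
detection_rates <- function(profiles) {
  df <- data.frame(
    compartment = vapply(profiles, `[[`, character(1), "compartment"),
    timepoint = vapply(profiles, `[[`, character(1), "timepoint"),
    positive = vapply(profiles, `[[`, logical(1), "is_positive")
  )
  agg <- aggregate(positive ~ compartment + timepoint, data = df,
                   FUN = function(x) c(n = length(x), pos = sum(x)))
  out <- data.frame(compartment = agg$compartment,
                    timepoint = agg$timepoint,
                    n_samples = agg$positive[, "n"],
                    n_positive = agg$positive[, "pos"])
  out$positivity <- out$n_positive / out$n_samples
  out[order(out$compartment, out$timepoint), , drop = FALSE]
}
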