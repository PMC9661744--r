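# Clonality assignment and longitudinal clonal-evolution bookkeeping.
#
# Clonality here is a relative-VAF definition, not a phylogenetic one: at
# baseline a mutation is clonal when its VAF reaches 25% of the sample's
# maxVAF, otherwise subclonal.  Mutations first seen after treatment are
# always subclonal ("acquired"), whatever their VAF.

#' Assign baseline clonal/subclonal status
#'
#' Labels every VAF-bearing variant of a baseline sample clonal when
#' `vaf >= 0.25 * maxVAF` (the variant attaining maxVAF is therefore
#' always clonal), else subclonal.  Equality at the threshold counts as
#' clonal by default; `strict = TRUE` demands strictly more than 25%.
#' CNV calls carry no allele fraction and are excluded.
#'
#' @param profile A filtered baseline [sample_profile()] with at least one
#'   VAF-bearing variant.
#' @param strict Use a strict `>` comparison at the 25% threshold.
#' @return A data.frame with `variant_key`, `gene`, `baseline_vaf`,
#'   `status` (clonal/subclonal) and `timepoint_observed`.
#' @export
assign_baseline_clonality <- function(profile, strict = FALSE) {
  v <- vaf_bearing(profile)
  if (nrow(v) == 0L) {
    stop("clonality is undefined for a sample with no VAF-bearing variant")
  }
  threshold <- 0.25 * max(v$vaf)
  clonal <- if (strict) v$vaf > threshold else v$vaf >= threshold
  clonal[which.max(v$vaf)] <- TRUE  # maxVAF variant is clonal by definition
  data.frame(variant_key = variant_key(v), gene = v$gene,
             baseline_vaf = v$vaf,
             status = ifelse(clonal, "clonal", "subclonal"),
             timepoint_observed = profile$timepoint,
             stringsAsFactors = FALSE)
}

#' Map clonal evolution between baseline and follow-up
#'
#' Matches variants across the two timepoints by identity key.  Every
#' baseline mutation is either retained or cleared; every follow-up-only
#' mutation is acquired and counted as subclonal regardless of its VAF.
#' The post-treatment clonal fraction is the share of retained clonal
#' mutations among all mutations detected at follow-up.  Complete
#' clearance (no mutation at follow-up) is reported as fraction 0 with
#' `complete_clearance = TRUE` so cohort summaries remain computable.
#'
#' @param baseline,followup [sample_profile()] objects for the same
#'   patient and compartment; `baseline` must have a VAF-bearing variant.
#' @param strict Passed to [assign_baseline_clonality()].
#' @return An object of class `evolution_summary`: counts of
#'   retained/cleared clonal and subclonal mutations, acquired mutations,
#'   `post_clonal_fraction` and the `high_retention` flag
#'   (fraction strictly above 0.80).
#' @export
map_evolution <- function(baseline, followup, strict = FALSE) {
  if (baseline$patient_id != followup$patient_id ||
      baseline$compartment != followup$compartment) {
    stop("baseline and follow-up must share patient and compartment")
  }
  base <- assign_baseline_clonality(baseline, strict = strict)
  fup_keys <- variant_key(vaf_bearing(followup))
  retained <- base$variant_key %in% fup_keys
  acquired_keys <- setdiff(fup_keys, base$variant_key)
  n_base_clonal <- sum(base$status == "clonal")
  n_base_subclonal <- sum(base$status == "subclonal")
  n_ret_clonal <- sum(retained & base$status == "clonal")
  n_ret_subclonal <- sum(retained & base$status == "subclonal")
  n_acquired <- length(acquired_keys)
  denom <- n_ret_clonal + n_ret_subclonal + n_acquired
  frac <- if (denom > 0L) n_ret_clonal / denom else 0
  s <- structure(
    list(patient_id = baseline$patient_id,
         compartment = baseline$compartment,
         n_baseline_clonal = n_base_clonal,
         n_baseline_subclonal = n_base_subclonal,
         n_retained_clonal = n_ret_clonal,
         n_cleared_clonal = n_base_clonal - n_ret_clonal,
         n_retained_subclonal = n_ret_subclonal,
         n_cleared_subclonal = n_base_subclonal - n_ret_subclonal,
         n_acquired = n_acquired,
         post_clonal_fraction = frac,
         complete_clearance = denom == 0L),
    class = "evolution_summary")
  s$high_retention <- classify_retention(s)
  s
}

#' Classify post-treatment clonal retention
#'
#' A patient retains a clonal profile when clonal mutations account for
#' more than 80% of mutations detected at follow-up (strict inequality).
#'
#' @param summary An `evolution_summary` from [map_evolution()].
#' @return `TRUE` when `post_clonal_fraction > 0.80`.
#' @export
classify_retention <- function(summary) {
  stopifnot(inherits(summary, "evolution_summary"))
  !summary$complete_clearance && summary$post_clonal_fraction > 0.80
}

#' @export
print.evolution_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<evolution_summary> %s (%s): baseline %d clonal / %d ",
           "subclonal; retained %d/%d; acquired %d; post-clonal %.2f%s\n"),
    x$patient_id, x$compartment, x$n_baseline_clonal,
    x$n_baseline_subclonal, x$n_retained_clonal + x$n_retained_subclonal,
    x$n_baseline_clonal + x$n_baseline_subclonal, x$n_acquired,
    x$post_clonal_fraction,
    if (x$complete_clearance) " (complete clearance)" else ""))
  invisible(x)
}

#' Cohort-level clonal composition
#'
#' Summarizes a set of evolution summaries two ways: pooling mutations
#' across patients, and averaging per-patient clonal fractions.  The two
#' differ when mutation counts vary across patients.
#'
#' @param summaries A list of `evolution_summary` objects.
#' @return A list with `pooled_post_clonal_fraction`,
#'   `mean_post_clonal_fraction`, `n_high_retention` and `n_patients`.
#' @export
clonal_composition <- function(summaries) {
  stopifnot(length(summaries) > 0L)
  ret_c <- vapply(summaries, `[[`, numeric(1), "n_retained_clonal")
  ret_s <- vapply(summaries, `[[`, numeric(1), "n_retained_subclonal")
  acq <- vapply(summaries, `[[`, numeric(1), "n_acquired")
  fracs <- vapply(summaries, `[[`, numeric(1), "post_clonal_fraction")
  denom <- sum(ret_c + ret_s + acq)
  list(
    pooled_post_clonal_fraction = if (denom > 0) sum(ret_c) / denom else 0,
    mean_post_clonal_fraction = mean(fracs),
    n_high_retention = sum(vapply(summaries, `[[`, logical(1),
                                  "high_retention")),
    n_patients = length(summaries)
  )
}
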