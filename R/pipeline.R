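# End-to-end pipeline: (simulate or load) -> filter -> per-sample metrics
# -> cross-compartment concordance -> clonal evolution -> molecular
# response -> survival contrasts -> machine-readable report.

#' Run the full paired CSF/plasma ctDNA analysis pipeline
#'
#' Accepts either a simulation request (a [cohort_config()] or overrides
#' for one) or paths to an existing manifest and clinical table, then
#' runs every analysis stage and assembles a self-contained report: the
#' configuration snapshot and seed, per-stage record counts, detection
#' rates by compartment and timepoint, per-patient and mean consistency
#' in both directions, per-gene 2x2 agreement with Cohen's kappa, clonal
#' evolution summaries, molecular response tables (including agreement
#' with radiographic response), and Kaplan-Meier / log-rank / hazard
#' ratio contrasts between response groups.  The report carries no
#' timestamp, so identical config + seed reproduce it byte for byte.
#'
#' @param config Either a list (or JSON file path) with elements
#'   `simulate` (overrides for [cohort_config()]) or `inputs`
#'   (`manifest`, `clinical` paths), plus optional `filters` (overrides
#'   for [filter_config()]), `genes` (symbols for per-gene kappa,
#'   default EGFR/TP53/KRAS) and `seed`.
#' @param out_dir Optional directory for `report.json` and per-stage
#'   TSVs.
#' @return The report (class `ctdna_run_report`), invisibly when
#'   `out_dir` is given.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  genes <- config$genes %||% c("EGFR", "TP53", "KRAS")
  fcfg <- do.call(filter_config, as.list(config$filters))

  # ---- data stage ----------------------------------------------------
  cohort <- NULL
  if (!is.null(config$inputs)) {
    manifest <- read_manifest(config$inputs$manifest)
    clinical <- if (!is.null(config$inputs$clinical))
      read_clinical_table(config$inputs$clinical) else NULL
    raw <- lapply(seq_len(nrow(manifest)), function(i) {
      read_variant_file(manifest$vcf_path[i],
                        sample_id = manifest$sample_id[i],
                        patient_id = manifest$patient_id[i])
    })
    names(raw) <- manifest$sample_id
  } else {
    sim <- as.list(config$simulate)
    if (!is.null(config$seed)) sim$seed <- config$seed
    ccfg <- do.call(cohort_config, sim)
    cohort <- simulate_cohort(ccfg)
    manifest <- cohort$manifest
    clinical <- cohort$clinical
    raw <- cohort$variants
  }

  # ---- filter stage --------------------------------------------------
  n_raw <- sum(vapply(raw, nrow, integer(1)))
  profiles <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    sample_profile(sample_id = row$sample_id, patient_id = row$patient_id,
                   compartment = row$compartment, timepoint = row$timepoint,
                   cfdna_pg_per_ml = row$cfdna_pg_per_ml,
                   variants = raw[[row$sample_id]], cfg = fcfg)
  })
  names(profiles) <- manifest$sample_id
  n_pass <- sum(vapply(profiles, function(p) nrow(p$variants), integer(1)))

  metrics <- data.frame(
    sample_id = manifest$sample_id,
    patient_id = manifest$patient_id,
    compartment = manifest$compartment,
    timepoint = manifest$timepoint,
    n_variants = vapply(profiles, function(p) nrow(p$variants), integer(1)),
    max_vaf = vapply(profiles, `[[`, numeric(1), "max_vaf"),
    mean_vaf = vapply(profiles, `[[`, numeric(1), "mean_vaf"),
    ctdna_hge_per_ml = vapply(profiles, `[[`, numeric(1),
                              "ctdna_hge_per_ml"),
    is_positive = vapply(profiles, `[[`, logical(1), "is_positive"),
    row.names = NULL)

  # ---- concordance stage ----------------------------------------------
  baseline_pairs <- Filter(function(pt) {
    a <- find_profile(profiles, pt, "CSF", "baseline")
    b <- find_profile(profiles, pt, "plasma", "baseline")
    !is.null(a) && !is.null(b) && a$is_positive && b$is_positive
  }, unique(manifest$patient_id))
  gene_kappa <- lapply(genes, function(g) {
    pa <- lapply(baseline_pairs, find_profile, profiles = profiles,
                 compartment = "CSF", timepoint = "baseline")
    pb <- lapply(baseline_pairs, find_profile, profiles = profiles,
                 compartment = "plasma", timepoint = "baseline")
    if (length(pa) == 0L) return(NULL)
    tab <- gene_level_2x2(pa, pb, g)
    list(gene = g, both_pos = tab$both_pos, a_only = tab$a_only,
         b_only = tab$b_only, both_neg = tab$both_neg,
         concordance_pct = tab$concordance_pct, kappa = tab$kappa)
  })
  names(gene_kappa) <- genes
  cons_p2c <- cohort_consistency(profiles, from = "plasma", to = "CSF")
  cons_c2p <- cohort_consistency(profiles, from = "CSF", to = "plasma")

  # ---- clonality stage ------------------------------------------------
  evolution <- list()
  for (comp in c("CSF", "plasma")) {
    for (pt in unique(manifest$patient_id)) {
      b <- find_profile(profiles, pt, comp, "baseline")
      f <- find_profile(profiles, pt, comp, "week8")
      if (is.null(b) || is.null(f) || nrow(vaf_bearing(b)) == 0L) next
      evolution[[paste(pt, comp, sep = "_")]] <- map_evolution(b, f)
    }
  }
  comp_of <- vapply(evolution, `[[`, character(1), "compartment")
  composition <- lapply(c(CSF = "CSF", plasma = "plasma"), function(cc) {
    subs <- evolution[comp_of == cc]
    if (length(subs)) clonal_composition(subs) else NULL
  })

  # ---- response stage -------------------------------------------------
  responses <- lapply(c(CSF = "CSF", plasma = "plasma"), function(cc)
    cohort_responses(profiles, compartment = cc))
  rad <- if (!is.null(clinical))
    unique(clinical[, c("patient_id", "radiographic_response")]) else NULL
  resp_vs_rad <- if (!is.null(rad)) {
    lapply(responses, function(calls) {
      if (sum(calls$evaluable) < 2) return(NULL)
      tab <- response_vs_radiology(calls, rad)
      list(both_pos = tab$both_pos, a_only = tab$a_only,
           b_only = tab$b_only, both_neg = tab$both_neg,
           concordance_pct = tab$concordance_pct, kappa = tab$kappa)
    })
  } else NULL

  # ---- survival stage -------------------------------------------------
  survival_results <- NULL
  if (!is.null(clinical)) {
    contrast_spec <- list(
      icPFS_by_csf_response = list(endpoint = "icPFS", calls = "CSF"),
      ecPFS_by_plasma_response = list(endpoint = "ecPFS", calls = "plasma"))
    survival_results <- lapply(contrast_spec, function(sp) {
      calls <- responses[[sp$calls]]
      calls <- calls[calls$evaluable, , drop = FALSE]
      if (nrow(calls) < 2 || length(unique(calls$responder)) < 2) {
        return(NULL)
      }
      groups <- data.frame(patient_id = calls$patient_id,
                           in_group_a = calls$responder)
      sc <- tryCatch(
        survival_contrast(clinical, groups, endpoint = sp$endpoint),
        error = function(e) stop("survival stage: ", conditionMessage(e)))
      list(endpoint = sp$endpoint, grouped_by = sp$calls,
           n_responder = sc$n_a, n_nonresponder = sc$n_b,
           median_responder = sc$km_a$median,
           median_nonresponder = sc$km_b$median,
           hr = sc$hr$hr, hr_ci95 = sc$hr$ci95,
           logrank_statistic = sc$logrank$statistic,
           logrank_p = sc$logrank$p_value)
    })
    retention_groups <- data.frame(
      patient_id = vapply(evolution[comp_of == "CSF"], `[[`, character(1),
                          "patient_id"),
      in_group_a = vapply(evolution[comp_of == "CSF"], `[[`, logical(1),
                          "high_retention"))
    if (nrow(retention_groups) >= 2 &&
        length(unique(retention_groups$in_group_a)) == 2) {
      sc <- survival_contrast(clinical, retention_groups,
                              endpoint = "icPFS")
      survival_results$icPFS_by_csf_retention <- list(
        endpoint = "icPFS", grouped_by = "CSF clonal retention",
        n_responder = sc$n_a, n_nonresponder = sc$n_b,
        median_responder = sc$km_a$median,
        median_nonresponder = sc$km_b$median,
        hr = sc$hr$hr, hr_ci95 = sc$hr$ci95,
        logrank_statistic = sc$logrank$statistic,
        logrank_p = sc$logrank$p_value)
    }
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("ctdyn")),
    seed = config$seed %||% (if (!is.null(cohort)) cohort$config$seed
                             else NA_integer_),
    config = config,
    counts = list(n_patients = length(unique(manifest$patient_id)),
                  n_samples = nrow(manifest),
                  n_calls_raw = n_raw, n_calls_pass = n_pass),
    detection_rates = detection_rates(profiles),
    sample_metrics = metrics,
    consistency = list(
      plasma_to_csf = cons_p2c$mean_consistency,
      csf_to_plasma = cons_c2p$mean_consistency,
      per_patient_plasma_to_csf = cons_p2c$per_patient,
      per_patient_csf_to_plasma = cons_c2p$per_patient),
    gene_kappa = gene_kappa,
    evolution = lapply(evolution, unclass),
    clonal_composition = composition,
    responses = responses,
    response_vs_radiographic = resp_vs_rad,
    survival = survival_results),
    class = "ctdna_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    utils::write.table(metrics, file.path(out_dir, "sample_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cons_p2c$per_patient,
                       file.path(out_dir, "consistency_plasma_to_csf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' @export
print.ctdna_run_report <- function(x, ...) {
  cat("<ctdna_run_report>", x$counts$n_patients, "patients,",
      x$counts$n_samples, "samples;",
      x$counts$n_calls_pass, "of", x$counts$n_calls_raw,
      "calls pass filters\n")
  det <- x$detection_rates
  det <- det[det$timepoint == "baseline", , drop = FALSE]
  for (i in seq_len(nrow(det))) {
    cat(sprintf("  baseline positivity %s: %.1f%% (%d/%d)\n",
                det$compartment[i], 100 * det$positivity[i],
                det$n_positive[i], det$n_samples[i]))
  }
  if (!is.null(x$consistency$plasma_to_csf)) {
    cat(sprintf("  mean consistency plasma->CSF: %.1f%%\n",
                x$consistency$plasma_to_csf))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
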