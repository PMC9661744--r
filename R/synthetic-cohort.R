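# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: per-patient
# somatic mutation sets with clonal/subclonal VAF tiers, a patient-level
# shedding gate plus per-variant binomial thinning that together produce
# compartment-asymmetric sample positivity (CSF well below plasma),
# CNV emission enriched in CSF, treatment-driven week-8 VAF scaling by
# responder group, acquired post-treatment subclonal mutations, and
# group-dependent exponential time-to-event outcomes with independent
# censoring.  Generation is at the variant-call level: no reads are
# simulated.

DRIVER_GENES <- c("EGFR", "KRAS", "ALK", "BRAF", "MET", "ERBB2", "ROS1",
                  "RET", "NTRK1")
PASSENGER_GENES <- c("TP53", "STK11", "KEAP1", "RB1", "PIK3CA", "SMAD4",
                     "CDKN2A", "NF1", "ARID1A", "CTNNB1", "PTEN", "BRCA2",
                     "ATM", "APC", "NOTCH1", "FBXW7", "MTOR", "TSC2",
                     "SETD2", "KMT2D")
GENE_CHROM <- c(
  EGFR = "chr7", KRAS = "chr12", ALK = "chr2", BRAF = "chr7",
  MET = "chr7", ERBB2 = "chr17", ROS1 = "chr6", RET = "chr10",
  NTRK1 = "chr1", TP53 = "chr17", STK11 = "chr19", KEAP1 = "chr19",
  RB1 = "chr13", PIK3CA = "chr3", SMAD4 = "chr18", CDKN2A = "chr9",
  NF1 = "chr17", ARID1A = "chr1", CTNNB1 = "chr3", PTEN = "chr10",
  BRCA2 = "chr13", ATM = "chr11", APC = "chr5", NOTCH1 = "chr9",
  FBXW7 = "chr4", MTOR = "chr1", TSC2 = "chr16", SETD2 = "chr3",
  KMT2D = "chr12", `NKX2-1` = "chr14", SMO = "chr7", CDK6 = "chr7")
GENE_POS <- c(
  EGFR = 55019017L, KRAS = 25205246L, ALK = 29192774L, BRAF = 140719327L,
  MET = 116672196L, ERBB2 = 39687914L, ROS1 = 117288300L, RET = 43077069L,
  NTRK1 = 156815750L, TP53 = 7668402L, STK11 = 1205778L,
  KEAP1 = 10486125L, RB1 = 48303748L, PIK3CA = 179148114L,
  SMAD4 = 50998396L, CDKN2A = 21967752L, NF1 = 31094927L,
  ARID1A = 26696015L, CTNNB1 = 41199505L, PTEN = 87863625L,
  BRCA2 = 32315086L, ATM = 108222832L, APC = 112707498L,
  NOTCH1 = 136494433L, FBXW7 = 152320544L, MTOR = 11106535L,
  TSC2 = 2047982L, SETD2 = 47016429L, KMT2D = 49018975L,
  `NKX2-1` = 36516392L, SMO = 129188633L, CDK6 = 92604921L)

# minimal-overhead data.frame constructor for hot paths
fast_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = c(NA_integer_, -length(cols[[1]])))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline is built for:
#' baseline sample-level positivity of about 64% in CSF and 91% in
#' plasma (a patient-level shedding gate times per-variant detection),
#' CNV emission enriched in CSF (39.3% vs 21.4%), roughly half the
#' cohort responding to first-line treatment, responder week-8 VAFs
#' scaled to 20% of baseline (non-responders 110%), and exponential
#' progression-free survival with medians near 13.3 vs 6.1 months for
#' intracranial progression.
#'
#' @param n_patients Number of patients.
#' @param seed Integer master seed; each patient draws from an
#'   independently derived substream, so enlarging the cohort leaves
#'   existing patients unchanged.
#' @param muts_per_patient Integer range (length 2) for the size of each
#'   patient's true somatic mutation set.
#' @param prob_clonal_tier Probability that a non-founder mutation is
#'   drawn from the clonal VAF tier.
#' @param clonal_vaf_range,subclonal_vaf_range True-VAF intervals for the
#'   two tiers (fractions); the founder mutation is always clonal-tier,
#'   so the baseline maxVAF comes from the clonal tier by construction.
#' @param p_shed Named (CSF, plasma) patient-level probabilities that the
#'   compartment receives tumor DNA at all; `NULL` (the default) derives
#'   them from `target_positivity` by inverting the detection model, so
#'   the configured positivity targets are met in expectation.
#' @param p_detect Named (CSF, plasma) per-variant detection
#'   probabilities given shedding; applied independently per timepoint.
#' @param target_positivity Named (CSF, plasma) intended baseline
#'   sample-level positivity; drives the derived `p_shed` and is the
#'   reference for calibration checks.
#' @param p_cnv Named (CSF, plasma) per-sample CNV emission
#'   probabilities given shedding.
#' @param cfdna_meanlog,cfdna_sdlog Named (CSF, plasma) log-normal
#'   parameters for total cfDNA (pg/mL).
#' @param responder_fraction Fraction of patients in the responder group.
#' @param responder_vaf_multiplier,nonresponder_vaf_multiplier Week-8
#'   true-VAF scale factors by group (defaults 0.2 and 1.1: responders
#'   fall well past the 50% concentration threshold, non-responders
#'   rise).
#' @param acquired_rate Poisson mean of newly acquired subclonal
#'   mutations per follow-up sample (per compartment).
#' @param vaf_noise_sdlog Log-normal measurement noise on observed VAFs
#'   (0 = exact).
#' @param seq_depth Nominal unique-read depth used to draw mutant read
#'   counts.
#' @param deterministic_reads Use `round(depth * vaf)` instead of a
#'   binomial draw for mutant reads.
#' @param hazard_by_group Per-endpoint named vectors of exponential event
#'   rates (per month) for responder/nonresponder groups.
#' @param censoring_rate Exponential rate of independent censoring.
#' @param max_followup_months Administrative censoring horizon.
#' @param radiology_flip_prob Probability that the radiographic label
#'   contradicts the true response group (controls the achievable
#'   molecular-vs-radiographic kappa).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 60L, seed = 1L,
    muts_per_patient = c(3L, 10L),
    prob_clonal_tier = 0.4,
    clonal_vaf_range = c(0.08, 0.40),
    subclonal_vaf_range = c(0.004, 0.02),
    p_shed = NULL,
    p_detect = c(CSF = 0.72, plasma = 0.82),
    target_positivity = c(CSF = 0.637, plasma = 0.911),
    p_cnv = c(CSF = 0.393, plasma = 0.214),
    cfdna_meanlog = c(CSF = log(800), plasma = log(8000)),
    cfdna_sdlog = c(CSF = 0.8, plasma = 0.6),
    responder_fraction = 0.48,
    responder_vaf_multiplier = 0.2,
    nonresponder_vaf_multiplier = 1.1,
    acquired_rate = 0.7,
    vaf_noise_sdlog = 0.15,
    seq_depth = 2000L,
    deterministic_reads = FALSE,
    hazard_by_group = list(
      icPFS = c(responder = log(2) / 13.27, nonresponder = log(2) / 6.13),
      ecPFS = c(responder = log(2) / 11.57, nonresponder = log(2) / 6.20),
      OS = c(responder = log(2) / 30, nonresponder = log(2) / 16)),
    censoring_rate = 0.03,
    max_followup_months = 36,
    radiology_flip_prob = 0.12) {
  if (is.null(p_shed)) {
    # invert the detection model so sample-level positivity targets are
    # hit in expectation: target = p_shed * P(positive | shedding), with
    # P(negative | shedding) = E[(1 - p_detect)^m] * (1 - p_cnv)
    m_range <- seq(muts_per_patient[1], muts_per_patient[2])
    p_pos_shed <- vapply(c("CSF", "plasma"), function(cc) {
      1 - mean((1 - p_detect[[cc]])^m_range) * (1 - p_cnv[[cc]])
    }, numeric(1))
    p_shed <- pmin(target_positivity[c("CSF", "plasma")] / p_pos_shed, 1)
    names(p_shed) <- c("CSF", "plasma")
  }
  probs <- c(p_shed, p_detect, p_cnv, responder_fraction,
             radiology_flip_prob, prob_clonal_tier)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(length(muts_per_patient) == 2L,
            muts_per_patient[1] >= 1L,
            muts_per_patient[1] <= muts_per_patient[2],
            responder_vaf_multiplier > 0,
            nonresponder_vaf_multiplier > 0,
            censoring_rate >= 0, seq_depth >= 1L)
  structure(as.list(environment()), class = "cohort_config")
}

#' Noise-free cohort configuration
#'
#' Degenerate limit used for exact truth-recovery checks: every patient
#' sheds into both compartments, every variant is detected, measured VAFs
#' equal true VAFs, read counts are deterministic, no mutations are
#' acquired after treatment, and radiographic labels match the true
#' group.  VAF tiers are raised so that every variant (including
#' responder week-8 VAFs scaled by 0.2) stays at or above the default
#' detection thresholds.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
noiseless_config <- function(...) {
  cohort_config(
    p_shed = c(CSF = 1, plasma = 1),
    p_detect = c(CSF = 1, plasma = 1),
    target_positivity = c(CSF = 1, plasma = 1),
    clonal_vaf_range = c(0.20, 0.50),
    subclonal_vaf_range = c(0.012, 0.05),
    vaf_noise_sdlog = 0,
    deterministic_reads = TRUE,
    acquired_rate = 0,
    radiology_flip_prob = 0,
    ...)
}

patient_substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1009) %% 2147483629)
}

BASES <- c("A", "C", "G", "T")

# vectorized locus/allele draw for a vector of gene symbols
draw_loci <- function(genes) {
  m <- length(genes)
  ref_i <- sample.int(4L, m, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, m, replace = TRUE)) %% 4L + 1L
  list(chrom = unname(GENE_CHROM[genes]),
       pos = unname(GENE_POS[genes]) +
         sample.int(3000L, m, replace = TRUE),
       ref = BASES[ref_i], alt = BASES[alt_i])
}

simulate_patient <- function(pid, cfg) {
  m <- sample(seq(cfg$muts_per_patient[1], cfg$muts_per_patient[2]), 1L)
  founder_weights <- ifelse(DRIVER_GENES == "EGFR", 0.45,
                     ifelse(DRIVER_GENES == "KRAS", 0.15, 0.05))
  founder_gene <- sample(DRIVER_GENES, 1L, prob = founder_weights)
  pass_weights <- ifelse(PASSENGER_GENES == "TP53", 0.30, 0.037)
  other_genes <- if (m > 1L) {
    sample(PASSENGER_GENES, m - 1L, replace = FALSE, prob = pass_weights)
  } else character(0)
  genes <- c(founder_gene, other_genes)
  clonal_tier <- c(TRUE, stats::runif(m - 1L) < cfg$prob_clonal_tier)
  lo <- ifelse(clonal_tier, cfg$clonal_vaf_range[1],
               cfg$subclonal_vaf_range[1])
  hi <- ifelse(clonal_tier, cfg$clonal_vaf_range[2],
               cfg$subclonal_vaf_range[2])
  true_vaf <- stats::runif(m, lo, hi)
  loci <- draw_loci(genes)
  is_driver <- genes %in% DRIVER_GENES
  # one latent CNV per patient; whether it surfaces is compartment-specific
  cnv_pick <- sample(c("EGFR_gain", "NTRK1_gain", "NKX2-1_gain", "SMO_gain",
                       "CDK6_gain", "STK11_loss"), 1L,
                     prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
  cnv_gene <- sub("_(gain|loss)$", "", cnv_pick)
  list(patient_id = pid,
       gene = genes, chrom = loci$chrom, pos = loci$pos,
       ref = loci$ref, alt = loci$alt,
       variant_class = sample(c("SNV", "indel", "fusion"), m,
                              replace = TRUE, prob = c(0.85, 0.12, 0.03)),
       true_vaf = true_vaf,
       is_driver = is_driver,
       is_oncogenic = is_driver | stats::runif(m) < 0.3,
       pop_freq = ifelse(stats::runif(m) < 0.3,
                         stats::runif(m, 0, 0.005), NA_real_),
       true_clonal = true_vaf >= 0.25 * max(true_vaf),
       cnv_gene = cnv_gene,
       cnv_class = if (grepl("gain$", cnv_pick)) "CNV_gain" else "CNV_loss",
       group = if (stats::runif(1) < cfg$responder_fraction) "responder"
               else "nonresponder",
       shed = c(CSF = stats::runif(1) < cfg$p_shed[["CSF"]],
                plasma = stats::runif(1) < cfg$p_shed[["plasma"]]),
       cfdna = c(CSF = stats::rlnorm(1, cfg$cfdna_meanlog[["CSF"]],
                                     cfg$cfdna_sdlog[["CSF"]]),
                 plasma = stats::rlnorm(1, cfg$cfdna_meanlog[["plasma"]],
                                        cfg$cfdna_sdlog[["plasma"]])))
}

measure_sample <- function(pat, compartment, timepoint, cfg) {
  sample_id <- paste(pat$patient_id, compartment, timepoint, sep = "_")
  if (!pat$shed[[compartment]]) return(empty_variant_calls())
  mult <- if (timepoint == "baseline") 1 else
    if (pat$group == "responder") cfg$responder_vaf_multiplier else
      cfg$nonresponder_vaf_multiplier
  keep <- stats::runif(length(pat$true_vaf)) < cfg$p_detect[[compartment]]
  gene <- pat$gene[keep]; chrom <- pat$chrom[keep]; pos <- pat$pos[keep]
  ref <- pat$ref[keep]; alt <- pat$alt[keep]
  vclass <- pat$variant_class[keep]
  tv <- pat$true_vaf[keep]
  is_driver <- pat$is_driver[keep]; is_onc <- pat$is_oncogenic[keep]
  pop_freq <- pat$pop_freq[keep]
  if (timepoint != "baseline" && cfg$acquired_rate > 0) {
    k <- stats::rpois(1, cfg$acquired_rate)
    if (k > 0) {
      agenes <- sample(PASSENGER_GENES, k, replace = TRUE)
      aloci <- draw_loci(agenes)
      gene <- c(gene, agenes)
      chrom <- c(chrom, aloci$chrom); pos <- c(pos, aloci$pos)
      ref <- c(ref, aloci$ref); alt <- c(alt, aloci$alt)
      vclass <- c(vclass, rep("SNV", k))
      # acquired true VAFs sit in the subclonal tier post-scaling
      tv <- c(tv, stats::runif(k, cfg$subclonal_vaf_range[1],
                               cfg$subclonal_vaf_range[2]) / mult)
      is_driver <- c(is_driver, rep(FALSE, k))
      is_onc <- c(is_onc, rep(FALSE, k))
      pop_freq <- c(pop_freq, rep(NA_real_, k))
    }
  }
  n <- length(tv)
  vaf <- numeric(0); reads <- integer(0)
  if (n > 0L) {
    noise <- if (cfg$vaf_noise_sdlog > 0)
      stats::rlnorm(n, 0, cfg$vaf_noise_sdlog) else 1
    vaf <- pmin(pmax(tv * mult * noise, 1e-5), 0.98)
    reads <- if (cfg$deterministic_reads) {
      as.integer(round(cfg$seq_depth * vaf))
    } else {
      stats::rbinom(n, cfg$seq_depth, vaf)
    }
  }
  if (stats::runif(1) < cfg$p_cnv[[compartment]]) {
    gene <- c(gene, pat$cnv_gene)
    chrom <- c(chrom, unname(GENE_CHROM[pat$cnv_gene]))
    pos <- c(pos, unname(GENE_POS[pat$cnv_gene]))
    ref <- c(ref, "N")
    alt <- c(alt, if (pat$cnv_class == "CNV_gain") "<DUP>" else "<DEL>")
    vclass <- c(vclass, pat$cnv_class)
    vaf <- c(vaf, NA_real_); reads <- c(reads, NA_integer_)
    pop_freq <- c(pop_freq, NA_real_)
    is_driver <- c(is_driver, pat$cnv_gene %in% DRIVER_GENES)
    is_onc <- c(is_onc, TRUE)
    n <- n + 1L
  }
  if (n == 0L) return(empty_variant_calls())
  fast_df(list(
    patient_id = rep(pat$patient_id, n), sample_id = rep(sample_id, n),
    gene = gene, chrom = chrom, pos = as.integer(pos), ref = ref,
    alt = alt, variant_class = vclass, vaf = as.numeric(vaf),
    alt_reads = as.integer(reads), pop_freq = as.numeric(pop_freq),
    is_driver = is_driver, is_oncogenic = is_onc))
}

#' Simulate a synthetic paired-compartment ctDNA cohort
#'
#' For each patient: draws a true somatic mutation set with clonal and
#' subclonal VAF tiers plus one latent CNV; emits CSF and plasma samples
#' at baseline and week 8 by patient-level shedding and per-variant
#' detection thinning; scales week-8 VAFs by the responder-group
#' multiplier and adds acquired subclonal mutations; draws
#' progression-free and overall survival from group-specific exponential
#' hazards with independent and administrative censoring; and generates
#' RECIST-style radiographic labels from the true group with a
#' configurable flip probability.  The truth tables record every latent
#' label so pipeline output can be scored against it.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Optional directory; when given, the cohort is also
#'   written to disk via [write_cohort()].
#' @return An object of class `ctdna_cohort`: a list with `manifest`,
#'   `variants` (named list of per-sample variant-call data.frames),
#'   `clinical`, `truth_patients`, `truth_variants` and the `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  endpoints <- names(cfg$hazard_by_group)
  n_ep <- length(endpoints)
  pids <- if (n > 0) sprintf("P%04d", seq_len(n)) else character(0)
  variants <- vector("list", 4L * n)
  man <- list(patient_id = character(4L * n), sample_id = character(4L * n),
              compartment = character(4L * n), timepoint = character(4L * n),
              cfdna_pg_per_ml = numeric(4L * n), vcf_path = character(4L * n))
  clinical_rows <- vector("list", n)
  truth_var_rows <- vector("list", n)
  truth_pat <- list(patient_id = pids,
                    responder_group = character(n),
                    shed_CSF = logical(n), shed_plasma = logical(n))
  k <- 0L
  for (i in seq_len(n)) {
    set.seed(patient_substream_seed(cfg$seed, i))
    pid <- pids[i]
    pat <- simulate_patient(pid, cfg)
    for (comp in c("CSF", "plasma")) {
      for (tp in c("baseline", "week8")) {
        k <- k + 1L
        sid <- paste(pid, comp, tp, sep = "_")
        variants[[k]] <- measure_sample(pat, comp, tp, cfg)
        man$patient_id[k] <- pid; man$sample_id[k] <- sid
        man$compartment[k] <- comp; man$timepoint[k] <- tp
        man$cfdna_pg_per_ml[k] <- pat$cfdna[[comp]]
        man$vcf_path[k] <- file.path("vcf", paste0(sid, ".vcf"))
      }
    }
    rad_group <- if (stats::runif(1) < cfg$radiology_flip_prob) {
      if (pat$group == "responder") "nonresponder" else "responder"
    } else pat$group
    recist <- if (rad_group == "responder") {
      sample(c("CR", "PR"), 1L, prob = c(0.2, 0.8))
    } else {
      sample(c("SD", "PD"), 1L, prob = c(0.6, 0.4))
    }
    rates <- vapply(endpoints, function(ep)
      cfg$hazard_by_group[[ep]][[pat$group]], numeric(1))
    t_event <- stats::rexp(n_ep, rates)
    t_cens <- if (cfg$censoring_rate > 0)
      stats::rexp(n_ep, cfg$censoring_rate) else rep(Inf, n_ep)
    horizon <- pmin(t_cens, cfg$max_followup_months)
    clinical_rows[[i]] <- fast_df(list(
      patient_id = rep(pid, n_ep), endpoint = endpoints,
      time_months = pmax(pmin(t_event, horizon), 1e-3),
      event = as.integer(t_event <= horizon),
      radiographic_response = rep(recist, n_ep)))
    truth_pat$responder_group[i] <- pat$group
    truth_pat$shed_CSF[i] <- unname(pat$shed[["CSF"]])
    truth_pat$shed_plasma[i] <- unname(pat$shed[["plasma"]])
    truth_var_rows[[i]] <- fast_df(list(
      patient_id = rep(pid, length(pat$true_vaf)),
      variant_key = paste(pat$chrom, pat$pos, pat$ref, pat$alt,
                          pat$variant_class, sep = ":"),
      gene = pat$gene, true_vaf = pat$true_vaf,
      true_clonal = pat$true_clonal))
  }
  names(variants) <- man$sample_id
  cohort <- structure(
    list(manifest = fast_df(man),
         variants = variants,
         clinical = if (n > 0) do.call(rbind, clinical_rows) else
           data.frame(patient_id = character(0), endpoint = character(0),
                      time_months = numeric(0), event = integer(0),
                      radiographic_response = character(0)),
         truth_patients = fast_df(truth_pat),
         truth_variants = if (n > 0) do.call(rbind, truth_var_rows) else
           data.frame(patient_id = character(0), variant_key = character(0),
                      gene = character(0), true_vaf = numeric(0),
                      true_clonal = logical(0)),
         config = cfg),
    class = "ctdna_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf(
    "<ctdna_cohort> %d patients, %d samples, seed %d\n",
    x$config$n_patients, nrow(x$manifest), x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `manifest.tsv`, `clinical.tsv`, `truth_patients.tsv`,
#' `truth_variants.tsv` and one VCF per sample under `vcf/`, in exactly
#' the formats the analysis side of the package consumes.  Output is a
#' pure function of the cohort object, so identical config + seed give
#' byte-identical files.
#'
#' @param cohort A `ctdna_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(cohort$manifest, "manifest.tsv")
  write_tsv(cohort$clinical, "clinical.tsv")
  write_tsv(cohort$truth_patients, "truth_patients.tsv")
  write_tsv(cohort$truth_variants, "truth_variants.tsv")
  for (sid in names(cohort$variants)) {
    write_variant_file(cohort$variants[[sid]],
                       file.path(dir, "vcf", paste0(sid, ".vcf")))
  }
  invisible(dir)
}

#' Build sample profiles directly from an in-memory cohort
#'
#' Equivalent to writing the cohort and calling [build_profiles()] on the
#' manifest, without the file round-trip.
#'
#' @param cohort A `ctdna_cohort`.
#' @param cfg A [filter_config()].
#' @return A named list of [sample_profile()] objects.
#' @export
profiles_from_cohort <- function(cohort, cfg = filter_config()) {
  m <- cohort$manifest
  profiles <- lapply(seq_len(nrow(m)), function(i) {
    sample_profile(sample_id = m$sample_id[i], patient_id = m$patient_id[i],
                   compartment = m$compartment[i], timepoint = m$timepoint[i],
                   cfdna_pg_per_ml = m$cfdna_pg_per_ml[i],
                   variants = cohort$variants[[m$sample_id[i]]], cfg = cfg)
  })
  names(profiles) <- m$sample_id
  profiles
}

#' Score pipeline output against simulation truth
#'
#' Runs the analysis pipeline on a simulated cohort and reports how well
#' it recovers the latent labels: agreement of baseline clonality calls
#' with true clonality (over variants detected at baseline), agreement of
#' the CSF molecular response call with the true responder group,
#' the estimated-vs-true hazard ratio for intracranial PFS using the true
#' group labels (with Wald 95% CI coverage), and Cohen's kappa between
#' the molecular response call and the simulated radiographic label.
#'
#' @param cohort A `ctdna_cohort`.
#' @param cfg A [filter_config()] used on the simulated calls.
#' @return A list of recovery metrics.
#' @export
truth_recovery_report <- function(cohort, cfg = filter_config()) {
  profiles <- profiles_from_cohort(cohort, cfg)
  truth_v <- cohort$truth_variants
  truth_p <- cohort$truth_patients

  # clonality agreement over variants detected in positive baseline samples
  n_match <- 0L; n_total <- 0L
  for (p in profiles) {
    if (p$timepoint != "baseline" || nrow(vaf_bearing(p)) == 0L) next
    asg <- assign_baseline_clonality(p)
    tv <- truth_v[truth_v$patient_id == p$patient_id, , drop = FALSE]
    idx <- match(asg$variant_key, tv$variant_key)
    hit <- !is.na(idx)
    n_total <- n_total + sum(hit)
    n_match <- n_match +
      sum((asg$status[hit] == "clonal") == tv$true_clonal[idx[hit]])
  }

  calls <- cohort_responses(profiles, compartment = "CSF")
  rc <- merge(calls[calls$evaluable, , drop = FALSE], truth_p,
              by = "patient_id")
  responder_agreement <- if (nrow(rc) > 0)
    mean(rc$responder == (rc$responder_group == "responder")) else NA_real_

  groups <- data.frame(patient_id = truth_p$patient_id,
                       in_group_a = truth_p$responder_group == "responder")
  hz <- cohort$config$hazard_by_group[["icPFS"]]
  true_hr <- unname(hz[["responder"]] / hz[["nonresponder"]])
  sc <- survival_contrast(cohort$clinical, groups, endpoint = "icPFS")

  rad <- unique(cohort$clinical[, c("patient_id", "radiographic_response")])
  kappa_mr <- if (sum(calls$evaluable) >= 2)
    tryCatch(cohens_kappa(response_vs_radiology(calls, rad)),
             error = function(e) NA_real_) else NA_real_

  list(
    clonality_agreement = if (n_total > 0) n_match / n_total else NA_real_,
    n_clonality_variants = n_total,
    responder_agreement = responder_agreement,
    n_response_evaluable = nrow(rc),
    hr_estimate = sc$hr$hr,
    hr_ci95 = sc$hr$ci95,
    true_hr = true_hr,
    hr_covered = true_hr >= sc$hr$ci95[1] && true_hr <= sc$hr$ci95[2],
    logrank_p = sc$logrank$p_value,
    kappa_molecular_vs_radiographic = kappa_mr
  )
}
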