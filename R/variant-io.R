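# Variant call input/output and hard filtering.
#
# Variant calls live in a plain data.frame with one row per somatic
# alteration in one sample.  SNVs, indels and fusions carry a VAF and a
# unique-mutant-read count; copy-number calls (CNV_gain / CNV_loss) carry
# neither.  Identity of a variant across samples is (chrom, pos, ref, alt,
# variant_class) -- the gene symbol is annotation, not identity, so
# cross-sample matching is immune to annotation drift.

VARIANT_CLASSES <- c("SNV", "indel", "fusion", "CNV_gain", "CNV_loss")
VAF_CLASSES     <- c("SNV", "indel", "fusion")
COMPARTMENTS    <- c("CSF", "plasma", "tissue")
TIMEPOINTS      <- c("baseline", "week8", "progression")

VARIANT_COLUMNS <- c("patient_id", "sample_id", "gene", "chrom", "pos",
                     "ref", "alt", "variant_class", "vaf", "alt_reads",
                     "pop_freq", "is_driver", "is_oncogenic")

#' Construct a variant-call table
#'
#' Builds (and validates) the canonical variant-call data.frame used by all
#' downstream analyses.  Each row is one somatic alteration observed in one
#' sample.
#'
#' @param patient_id,sample_id Character identifiers.
#' @param gene HGNC gene symbol (annotation only; not part of identity).
#' @param chrom Chromosome name.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt Allele strings; CNVs use symbolic alts (`<DUP>`/`<DEL>`).
#' @param variant_class One of `"SNV"`, `"indel"`, `"fusion"`,
#'   `"CNV_gain"`, `"CNV_loss"`.
#' @param vaf Variant allele frequency in `[0, 1]`; `NA` for CNV classes.
#' @param alt_reads Unique mutant read count; `NA` for CNV classes.
#' @param pop_freq Population allele frequency, or `NA` when the variant is
#'   absent from population databases.
#' @param is_driver,is_oncogenic Logical annotations.
#'
#' @return A data.frame with one row per call and the canonical column set.
#' @export
variant_calls <- function(patient_id, sample_id, gene, chrom, pos, ref, alt,
                          variant_class, vaf = NA_real_,
                          alt_reads = NA_integer_, pop_freq = NA_real_,
                          is_driver = FALSE, is_oncogenic = FALSE) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    sample_id = as.character(sample_id),
    gene = as.character(gene),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    variant_class = as.character(variant_class),
    vaf = as.numeric(vaf),
    alt_reads = as.integer(alt_reads),
    pop_freq = as.numeric(pop_freq),
    is_driver = as.logical(is_driver),
    is_oncogenic = as.logical(is_oncogenic),
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
}

#' @rdname variant_calls
#' @param calls A candidate variant-call data.frame.
#' @export
validate_variant_calls <- function(calls) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(calls))
  if (length(missing_cols) > 0L) {
    stop("variant-call table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad_class <- setdiff(unique(calls$variant_class), VARIANT_CLASSES)
  if (length(bad_class) > 0L) {
    stop("unknown variant_class: ", paste(bad_class, collapse = ", "))
  }
  is_cnv <- calls$variant_class %in% c("CNV_gain", "CNV_loss")
  if (any(is_cnv & (!is.na(calls$vaf) | !is.na(calls$alt_reads)))) {
    stop("CNV-class calls must not carry vaf or alt_reads")
  }
  if (any(!is_cnv & is.na(calls$vaf))) {
    bad <- which(!is_cnv & is.na(calls$vaf))[1L]
    stop("VAF-bearing record without a VAF: ",
         variant_key(calls[bad, , drop = FALSE]))
  }
  with_vaf <- !is.na(calls$vaf)
  if (any(calls$vaf[with_vaf] < 0 | calls$vaf[with_vaf] > 1)) {
    stop("vaf outside [0, 1]")
  }
  if (any(!is.na(calls$alt_reads) & calls$alt_reads < 0L)) {
    stop("negative alt_reads")
  }
  calls
}

#' Empty variant-call table
#'
#' @return A zero-row data.frame with the canonical variant columns.
#' @export
empty_variant_calls <- function() {
  variant_calls(patient_id = character(0), sample_id = character(0),
                gene = character(0), chrom = character(0),
                pos = integer(0), ref = character(0), alt = character(0),
                variant_class = character(0), vaf = numeric(0),
                alt_reads = integer(0), pop_freq = numeric(0),
                is_driver = logical(0), is_oncogenic = logical(0))
}

#' Variant identity keys
#'
#' The identity of a variant across samples and timepoints is the tuple
#' (chrom, pos, ref, alt, variant_class), rendered as a single
#' colon-separated string.
#'
#' @param calls A variant-call data.frame.
#' @return Character vector of identity keys, one per row.
#' @export
variant_key <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, calls$variant_class,
        sep = ":")
}

#' Filtering configuration
#'
#' Thresholds for retaining a somatic call: minimum VAF (default 0.2%),
#' minimum number of unique mutant reads (default 3), maximum population
#' allele frequency (default 1%), and an optional blacklist of recurrent
#' artifact identity keys.  All thresholds are inclusive on the passing
#' side, so a call sitting exactly at a printed cutoff passes.
#'
#' @param min_vaf Minimum variant allele frequency, fraction in `[0, 1)`.
#' @param min_alt_reads Minimum unique mutant reads, non-negative integer.
#' @param max_pop_freq Maximum population frequency, fraction in `[0, 1]`.
#' @param blacklist Character vector of variant identity keys (see
#'   [variant_key()]) to drop regardless of other criteria.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_vaf = 0.002, min_alt_reads = 3L,
                          max_pop_freq = 0.01, blacklist = character(0)) {
  stopifnot(min_vaf >= 0, min_vaf < 1, min_alt_reads >= 0,
            max_pop_freq >= 0, max_pop_freq <= 1)
  structure(list(min_vaf = min_vaf,
                 min_alt_reads = as.integer(min_alt_reads),
                 max_pop_freq = max_pop_freq,
                 blacklist = as.character(blacklist)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("ctDNA variant filter: vaf >=", x$min_vaf,
      "| alt reads >=", x$min_alt_reads,
      "| pop freq <=", x$max_pop_freq,
      "|", length(x$blacklist), "blacklisted keys\n")
  invisible(x)
}

#' Apply hard filters to variant calls
#'
#' Retains VAF-bearing calls (SNV/indel/fusion) with
#' `vaf >= min_vaf`, `alt_reads >= min_alt_reads` and population frequency
#' absent or `<= max_pop_freq`.  CNV calls carry no per-read support and
#' bypass the VAF/read criteria.  All calls are dropped when their identity
#' key is blacklisted.  Input order is preserved and the operation is
#' idempotent.
#'
#' @param calls A variant-call data.frame.
#' @param cfg A [filter_config()].
#' @return The retained subset of `calls` (possibly zero rows).
#' @export
apply_filters <- function(calls, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  calls <- validate_variant_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  keys <- variant_key(calls)
  is_cnv <- calls$variant_class %in% c("CNV_gain", "CNV_loss")
  pass_reads <- is_cnv |
    (calls$vaf >= cfg$min_vaf &
       !is.na(calls$alt_reads) & calls$alt_reads >= cfg$min_alt_reads)
  pass_pop <- is_cnv | is.na(calls$pop_freq) |
    calls$pop_freq <= cfg$max_pop_freq
  keep <- pass_reads & pass_pop & !(keys %in% cfg$blacklist)
  calls[keep, , drop = FALSE]
}

#' Read a variant file
#'
#' Parses a VCF (v4.2) whose INFO field carries the per-record annotations
#' `VAF` (fraction), `ALT_READS` (integer), `POP_FREQ` (fraction, optional),
#' `CLASS` (variant class), `GENE` (symbol) and optional `DRIVER`/`ONCOGENIC`
#' (0/1).  CNVs are encoded with symbolic alts (`<DUP>`/`<DEL>`) and
#' `CLASS=CNV_gain`/`CNV_loss`, with no `VAF`/`ALT_READS`.
#'
#' @param path Path to the VCF.
#' @param sample_id Sample identifier to stamp on every record.
#' @param patient_id Patient identifier; defaults to `sample_id`.
#' @return A variant-call data.frame (zero rows for a header-only file).
#' @export
read_variant_file <- function(path, sample_id, patient_id = sample_id) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e))
  )
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0L) return(empty_variant_calls())
  fix <- vcfR::getFIX(vcf)
  if (n == 1L) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  cls <- vcfR::extract.info(vcf, "CLASS")
  if (anyNA(cls)) {
    stop("record without CLASS annotation in '", path, "' at ",
         fix[which(is.na(cls))[1L], "CHROM"], ":",
         fix[which(is.na(cls))[1L], "POS"])
  }
  vaf <- suppressWarnings(vcfR::extract.info(vcf, "VAF", as.numeric = TRUE))
  alt_reads <- suppressWarnings(
    vcfR::extract.info(vcf, "ALT_READS", as.numeric = TRUE))
  pop_freq <- suppressWarnings(
    vcfR::extract.info(vcf, "POP_FREQ", as.numeric = TRUE))
  gene <- vcfR::extract.info(vcf, "GENE")
  drv <- suppressWarnings(vcfR::extract.info(vcf, "DRIVER", as.numeric = TRUE))
  onc <- suppressWarnings(
    vcfR::extract.info(vcf, "ONCOGENIC", as.numeric = TRUE))
  needs_vaf <- cls %in% VAF_CLASSES
  if (any(needs_vaf & (is.na(vaf) | is.na(alt_reads)))) {
    bad <- which(needs_vaf & (is.na(vaf) | is.na(alt_reads)))[1L]
    stop("VAF-bearing record lacking VAF/ALT_READS in '", path, "' at ",
         fix[bad, "CHROM"], ":", fix[bad, "POS"])
  }
  variant_calls(
    patient_id = patient_id, sample_id = sample_id,
    gene = ifelse(is.na(gene), ".", gene),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    variant_class = cls,
    vaf = ifelse(needs_vaf, vaf, NA_real_),
    alt_reads = ifelse(needs_vaf, alt_reads, NA_integer_),
    pop_freq = pop_freq,
    is_driver = !is.na(drv) & drv > 0,
    is_oncogenic = !is.na(onc) & onc > 0
  )
}

#' Write a variant file
#'
#' Emits the VCF dialect read by [read_variant_file()]; writing then
#' reading round-trips identity keys, VAFs and classes exactly.
#'
#' @param calls A variant-call data.frame (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_file <- function(calls, path) {
  calls <- validate_variant_calls(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=ALT_READS,Number=1,Type=Integer,Description=\"Unique mutant reads\">",
    "##INFO=<ID=POP_FREQ,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"HGNC gene symbol\">",
    "##INFO=<ID=DRIVER,Number=1,Type=Integer,Description=\"Driver gene variant (0/1)\">",
    "##INFO=<ID=ONCOGENIC,Number=1,Type=Integer,Description=\"Oncogenic variant (0/1)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  fmt_num <- function(x) formatC(x, format = "fg", digits = 15)
  body <- character(nrow(calls))
  if (nrow(calls) > 0L) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      r <- calls[i, ]
      parts <- character(0)
      if (!is.na(r$vaf)) parts <- c(parts, paste0("VAF=", fmt_num(r$vaf)))
      if (!is.na(r$alt_reads)) {
        parts <- c(parts, paste0("ALT_READS=", r$alt_reads))
      }
      if (!is.na(r$pop_freq)) {
        parts <- c(parts, paste0("POP_FREQ=", fmt_num(r$pop_freq)))
      }
      parts <- c(parts,
                 paste0("CLASS=", r$variant_class),
                 paste0("GENE=", r$gene),
                 paste0("DRIVER=", as.integer(r$is_driver)),
                 paste0("ONCOGENIC=", as.integer(r$is_oncogenic)))
      paste(parts, collapse = ";")
    }, character(1))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest is a TSV with columns `patient_id`, `sample_id`,
#' `compartment` (CSF/plasma/tissue), `timepoint`
#' (baseline/week8/progression), `cfdna_pg_per_ml` and `vcf_path`
#' (relative paths resolved against the manifest's directory).
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "sample_id", "compartment", "timepoint",
              "cfdna_pg_per_ml", "vcf_path")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols) > 0L) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(m$compartment %in% COMPARTMENTS)) {
    stop("manifest compartment must be one of: ",
         paste(COMPARTMENTS, collapse = ", "))
  }
  if (!all(m$timepoint %in% TIMEPOINTS)) {
    stop("manifest timepoint must be one of: ",
         paste(TIMEPOINTS, collapse = ", "))
  }
  if (any(m$cfdna_pg_per_ml < 0)) stop("negative cfDNA concentration")
  rel <- !grepl("^(/|[A-Za-z]:)", m$vcf_path)
  m$vcf_path[rel] <- file.path(dirname(path), m$vcf_path[rel])
  m
}
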