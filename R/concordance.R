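# Cross-compartment agreement: the asymmetric consistency statistic,
# three-way Venn partitions, per-gene 2x2 tables and Cohen's kappa.

#' Consistency of sample A to sample B
#'
#' The fraction of A's alterations that are also found in B:
#' `100 * |A intersect B| / |A|`.  The statistic is asymmetric by
#' construction -- consistency of a small set to a large one is not the
#' reverse.  It is defined only for mutation-positive A (non-empty set).
#'
#' @param a,b Character vectors of variant identity keys (see
#'   [variant_key()]); duplicates are ignored.
#' @param label_a,label_b Optional sample-type labels for reporting.
#' @param exclude_cnv If `TRUE`, CNV-class keys are removed from both sets
#'   before comparison (consistency over somatic mutations only).
#'
#' @return A one-row data.frame with `set_a_label`, `set_b_label`, `n_a`,
#'   `n_b`, `n_shared` and `consistency_a_to_b` (percent).
#' @export
consistency <- function(a, b, label_a = "A", label_b = "B",
                        exclude_cnv = FALSE) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (exclude_cnv) {
    a <- a[!grepl(":CNV_(gain|loss)$", a)]
    b <- b[!grepl(":CNV_(gain|loss)$", b)]
  }
  if (length(a) == 0L) {
    stop("consistency is undefined for an empty (mutation-negative) set A")
  }
  shared <- length(intersect(a, b))
  data.frame(set_a_label = label_a, set_b_label = label_b,
             n_a = length(a), n_b = length(b), n_shared = shared,
             consistency_a_to_b = 100 * shared / length(a),
             stringsAsFactors = FALSE)
}

#' 2x2 agreement table with Cohen's kappa
#'
#' Builds a 2x2 contingency table of paired binary calls and fills in the
#' observed agreement `po = (both_pos + both_neg) / n`, the chance
#' agreement expected from the marginals
#' `pe = (pA+ pB+ + pA- pB-)` and Cohen's kappa
#' `(po - pe) / (1 - pe)` (kappa = 1 at perfect agreement with degenerate
#' marginals).
#'
#' @param both_pos,a_only,b_only,both_neg Cell counts: both members
#'   positive, only A positive, only B positive, both negative.
#' @return An object of class `contingency_2x2` (a list with the four
#'   cells plus `n`, `po`, `pe`, `kappa`, `concordance_pct`).
#' @export
contingency_table <- function(both_pos, a_only, b_only, both_neg) {
  cells <- c(both_pos = both_pos, a_only = a_only, b_only = b_only,
             both_neg = both_neg)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0L) stop("empty contingency table")
  po <- (both_pos + both_neg) / n
  pa <- (both_pos + a_only) / n
  pb <- (both_pos + b_only) / n
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else if (po >= 1) 1 else NaN
  structure(list(both_pos = both_pos, a_only = a_only, b_only = b_only,
                 both_neg = both_neg, n = n, po = po, pe = pe,
                 kappa = kappa, concordance_pct = 100 * po),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$both_pos, x$b_only, x$a_only, x$both_neg), nrow = 2,
              dimnames = list(A = c("pos", "neg"), B = c("pos", "neg")))
  print(m)
  cat(sprintf("n = %d, agreement = %.1f%%, kappa = %.3f\n",
              x$n, x$concordance_pct, x$kappa))
  invisible(x)
}

#' Cohen's kappa of a 2x2 table
#'
#' @param table A `contingency_2x2` from [contingency_table()].
#' @return The chance-corrected agreement coefficient (at most 1).
#' @export
cohens_kappa <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  table$kappa
}

#' Reconstruct a 2x2 table from marginals and the agreement count
#'
#' Published concordance analyses often report only the two positive
#' marginals and the agreement (or concordance rate).  With the total `n`
#' these determine the table uniquely: the disagreement count
#' `n - n_agree` splits between the off-diagonal cells so that the
#' marginals are honored.
#'
#' @param n Number of pairs.
#' @param a_pos,b_pos Positive counts for each member.
#' @param n_agree Number of agreeing pairs (both positive or both
#'   negative).
#' @return A `contingency_2x2`.
#' @export
contingency_from_marginals <- function(n, a_pos, b_pos, n_agree) {
  # a_only + b_only = n - n_agree, a_only - b_only = a_pos - b_pos
  a_only <- ((n - n_agree) + (a_pos - b_pos)) / 2
  b_only <- ((n - n_agree) - (a_pos - b_pos)) / 2
  if (a_only < 0 || b_only < 0 || a_only != round(a_only)) {
    stop("marginals and agreement are inconsistent with an integer table")
  }
  both_pos <- a_pos - a_only
  both_neg <- n_agree - both_pos
  if (both_pos < 0 || both_neg < 0) {
    stop("marginals and agreement are inconsistent with an integer table")
  }
  contingency_table(both_pos, a_only, b_only, both_neg)
}

#' Per-gene presence/absence agreement across paired samples
#'
#' For each patient pair, records whether any passing alteration in the
#' named gene (mutations or CNVs) is present in each member, and
#' summarizes agreement as a 2x2 table with Cohen's kappa.
#'
#' @param profiles_a,profiles_b Parallel lists of [sample_profile()]
#'   objects; element i of each list must belong to the same patient.
#' @param gene HGNC symbol.
#' @return A `contingency_2x2`.
#' @export
gene_level_2x2 <- function(profiles_a, profiles_b, gene) {
  if (length(profiles_a) == 0L) stop("no sample pairs supplied")
  if (length(profiles_a) != length(profiles_b)) {
    stop("profile lists differ in length")
  }
  has_gene <- function(p) any(p$variants$gene == gene)
  cells <- c(0L, 0L, 0L, 0L)
  for (i in seq_along(profiles_a)) {
    pa <- profiles_a[[i]]; pb <- profiles_b[[i]]
    if (pa$patient_id != pb$patient_id) {
      stop("pair ", i, " mixes patients ", pa$patient_id, " and ",
           pb$patient_id)
    }
    ia <- has_gene(pa); ib <- has_gene(pb)
    idx <- if (ia && ib) 1L else if (ia) 2L else if (ib) 3L else 4L
    cells[idx] <- cells[idx] + 1L
  }
  contingency_table(cells[1], cells[2], cells[3], cells[4])
}

#' Three-way Venn partition of variant key sets
#'
#' Exact counts for the seven non-empty regions of a three-set Venn
#' diagram, plus per-set totals.
#'
#' @param set1,set2,set3 Character vectors of variant identity keys.
#' @param labels Character vector of three sample-type labels.
#' @return An object of class `venn_partition`: a list with `labels`,
#'   the seven `regions` counts (`only_1`, `only_2`, `only_3`,
#'   `only_12`, `only_13`, `only_23`, `all_123`) and `set_totals`.
#' @export
venn_partition <- function(set1, set2, set3,
                           labels = c("set1", "set2", "set3")) {
  s1 <- unique(as.character(set1))
  s2 <- unique(as.character(set2))
  s3 <- unique(as.character(set3))
  u <- union(union(s1, s2), s3)
  in1 <- u %in% s1; in2 <- u %in% s2; in3 <- u %in% s3
  regions <- c(
    only_1 = sum(in1 & !in2 & !in3),
    only_2 = sum(!in1 & in2 & !in3),
    only_3 = sum(!in1 & !in2 & in3),
    only_12 = sum(in1 & in2 & !in3),
    only_13 = sum(in1 & !in2 & in3),
    only_23 = sum(!in1 & in2 & in3),
    all_123 = sum(in1 & in2 & in3)
  )
  structure(list(labels = labels, regions = regions,
                 set_totals = stats::setNames(
                   c(length(s1), length(s2), length(s3)), labels)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>", paste(x$labels, collapse = " / "), "\n")
  print(x$regions)
  invisible(x)
}

#' Per-patient consistency between two compartments
#'
#' Computes, for every patient whose source-compartment sample is
#' mutation-positive, the consistency of compartment A to compartment B at
#' the chosen timepoint, and the unweighted cohort mean.
#'
#' @param profiles A list of [sample_profile()] objects.
#' @param from,to Source and target compartments.
#' @param timepoint Timepoint to compare at.
#' @param exclude_cnv Restrict to somatic mutations (drop CNV keys).
#' @return A list with `per_patient` (data.frame) and `mean_consistency`.
#' @export
cohort_consistency <- function(profiles, from = "plasma", to = "CSF",
                               timepoint = "baseline", exclude_cnv = FALSE) {
  pts <- unique(vapply(profiles, `[[`, character(1), "patient_id"))
  rows <- list()
  for (pt in pts) {
    pa <- find_profile(profiles, pt, from, timepoint)
    pb <- find_profile(profiles, pt, to, timepoint)
    if (is.null(pa) || is.null(pb)) next
    keys_a <- variant_key(pa$variants)
    keys_b <- variant_key(pb$variants)
    if (exclude_cnv) keys_a <- keys_a[!grepl(":CNV_(gain|loss)$", keys_a)]
    if (length(keys_a) == 0L) next  # mutation-negative source sample
    r <- consistency(keys_a, keys_b, label_a = from, label_b = to,
                     exclude_cnv = exclude_cnv)
    r$patient_id <- pt
    rows[[pt]] <- r
  }
  per_patient <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_a_label = character(0), set_b_label = character(0),
               n_a = integer(0), n_b = integer(0), n_shared = integer(0),
               consistency_a_to_b = numeric(0), patient_id = character(0))
  rownames(per_patient) <- NULL
  list(per_patient = per_patient,
       mean_consistency = if (nrow(per_patient))
         mean(per_patient$consistency_a_to_b) else NA_real_)
}
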