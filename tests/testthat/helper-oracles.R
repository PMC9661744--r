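# Independent brute-force reference implementations, deliberately written
# as plain loops over raw observations so they share no code path with
# the package (which wraps the survival package for these statistics).

# Cohen's kappa straight from two paired binary label vectors.
oracle_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe >= 1) return(if (po >= 1) 1 else NaN)
  (po - pe) / (1 - pe)
}

# Product-limit estimator by explicit risk-set bookkeeping.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Two-group log-rank chi-square with hypergeometric variance, looping
# over each distinct event time.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1], t2[e2])))
  o_minus_e <- 0
  v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt)
    d1 <- sum(t1 == tt & e1); d2 <- sum(t2 == tt & e2)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Random survival-record data.frame for property tests.
random_records <- function(n, rate = 0.2, cens_rate = 0.1) {
  te <- stats::rexp(n, rate)
  tc <- stats::rexp(n, cens_rate)
  data.frame(time_months = pmin(te, tc), event = te <= tc)
}

# Small variant-call table with given VAFs (passing default filters).
calls_with_vafs <- function(vafs, sample_id = "S1", patient_id = "P1",
                            genes = NULL) {
  n <- length(vafs)
  variant_calls(
    patient_id = rep(patient_id, n), sample_id = rep(sample_id, n),
    gene = genes %||% rep("TP53", n),
    chrom = rep("chr17", n), pos = seq_len(n) + 7660000L,
    ref = rep("C", n), alt = rep("T", n),
    variant_class = rep("SNV", n), vaf = vafs,
    alt_reads = rep(100L, n), pop_freq = rep(NA_real_, n))
}

profile_with_vafs <- function(vafs, cfdna = 1000,
                              compartment = "CSF",
                              timepoint = "baseline",
                              sample_id = "S1", patient_id = "P1",
                              genes = NULL) {
  sample_profile(sample_id = sample_id, patient_id = patient_id,
                 compartment = compartment, timepoint = timepoint,
                 cfdna_pg_per_ml = cfdna,
                 variants = if (length(vafs)) {
                   calls_with_vafs(vafs, sample_id, patient_id, genes)
                 } else empty_variant_calls(),
                 cfg = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
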