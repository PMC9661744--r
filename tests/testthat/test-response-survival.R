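resp_pair <- function(base_vafs, fup_vafs, cfdna = 330,
                      compartment = "CSF") {
  b <- profile_with_vafs(base_vafs, cfdna = cfdna,
                         compartment = compartment,
                         timepoint = "baseline")
  f <- profile_with_vafs(fup_vafs, cfdna = cfdna,
                         compartment = compartment, timepoint = "week8")
  list(b = b, f = f)
}

test_that("the 50% concentration drop is an inclusive responder rule", {
  # concentrations 10 -> 5 hGE/mL: exactly -50%, responder
  pr <- resp_pair(0.10, 0.05, cfdna = 330)
  rc <- call_response(pr$b, pr$f)
  expect_equal(rc$baseline_conc, 10)
  expect_equal(rc$followup_conc, 5)
  expect_equal(rc$pct_change, -50)
  expect_true(rc$responder)
  # 10 -> 6: not a responder
  expect_false(call_response(resp_pair(0.10, 0.06)$b,
                             resp_pair(0.10, 0.06)$f)$responder)
  # ctDNA-negative baseline: not evaluable
  pr0 <- resp_pair(numeric(0), 0.10)
  rc0 <- call_response(pr0$b, pr0$f)
  expect_false(rc0$evaluable)
  expect_false(rc0$responder)
  expect_true(is.na(rc0$pct_change))
  # follow-up clearance counts as a (100%) response
  prc <- resp_pair(0.10, numeric(0))
  expect_true(call_response(prc$b, prc$f)$responder)
})

test_that("response is scale-invariant and pairing is validated", {
  set.seed(5)
  for (rep in 1:20) {
    v <- runif(3, 0.01, 0.3)
    w <- runif(3, 0.01, 0.3)
    s <- runif(1, 0.1, 10)
    r1 <- call_response(resp_pair(v, w, cfdna = 100)$b,
                        resp_pair(v, w, cfdna = 100)$f)
    r2 <- call_response(resp_pair(v, w, cfdna = 100 * s)$b,
                        resp_pair(v, w, cfdna = 100 * s)$f)
    expect_equal(r1$responder, r2$responder)
  }
  pr <- resp_pair(0.1, 0.1)
  expect_error(call_response(pr$f, pr$b), "precede")
  other <- profile_with_vafs(0.1, compartment = "plasma",
                             timepoint = "week8")
  expect_error(call_response(pr$b, other), "compartment")
})

test_that("molecular vs radiographic agreement reproduces known tables", {
  # 25 pairs with 19 agreements (13 both-responder, 6 both-non)
  calls <- data.frame(
    patient_id = sprintf("P%02d", 1:25),
    responder = rep(c(TRUE, FALSE), c(16, 9)),
    evaluable = TRUE)
  labels <- data.frame(
    patient_id = sprintf("P%02d", 1:25),
    radiographic_response = c(rep("PR", 13), rep("SD", 3),
                              rep("CR", 3), rep("PD", 6)))
  tab <- response_vs_radiology(calls, labels)
  expect_equal(tab$n, 25L)
  expect_equal(tab$concordance_pct, 76.0)

  perfect <- response_vs_radiology(
    data.frame(patient_id = c("A", "B"), responder = c(TRUE, FALSE),
               evaluable = TRUE),
    data.frame(patient_id = c("A", "B"),
               radiographic_response = c("PR", "PD")))
  expect_equal(cohens_kappa(perfect), 1.0)

  expect_error(
    response_vs_radiology(calls,
                          data.frame(patient_id = "P01",
                                     radiographic_response = "MR")),
    "mapping")
})

test_that("kappa is near zero for independent labels", {
  set.seed(77)
  ks <- replicate(200, {
    n <- 200
    calls <- data.frame(patient_id = seq_len(n),
                        responder = runif(n) < 0.5, evaluable = TRUE)
    labels <- data.frame(patient_id = seq_len(n),
                         radiographic_response =
                           ifelse(runif(n) < 0.5, "PR", "PD"))
    cohens_kappa(response_vs_radiology(calls, labels))
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("KM estimates match closed-form and hand-worked cases", {
  fit <- km_fit(data.frame(time_months = 1:4, event = TRUE))
  expect_equal(fit$table$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(fit$median, 2)

  cens <- km_fit(data.frame(time_months = c(2, 5, 9), event = FALSE))
  expect_true(all(cens$table$surv == 1))
  expect_true(is.na(cens$median))

  # censored at 3, event at 5: risk set at 5 is one patient
  mixed <- km_fit(data.frame(time_months = c(3, 5),
                             event = c(FALSE, TRUE)))
  ev_row <- mixed$table[mixed$table$n_event > 0, ]
  expect_equal(ev_row$n_risk, 1)
  expect_equal(ev_row$surv, 0)
  expect_equal(mixed$median, 5)

  expect_error(km_fit(data.frame(time_months = c(1, -2),
                                 event = TRUE)), "non-positive")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(13)
  for (rep in 1:20) {
    t <- sort(sample(1:15, sample(3:10, 1), replace = TRUE))
    fit <- km_fit(data.frame(time_months = t, event = TRUE))
    o <- oracle_km(t, rep(TRUE, length(t)))
    expect_equal(fit$table$surv[fit$table$n_event > 0], o$surv,
                 tolerance = 1e-12)
    ecdf_surv <- vapply(o$time, function(x) mean(t > x), numeric(1))
    expect_equal(o$surv, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("log-rank matches the risk-set oracle and its edge cases", {
  g <- data.frame(time_months = c(1, 3, 5), event = TRUE)
  same <- logrank_test(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  nocens <- logrank_test(
    data.frame(time_months = c(8, 12, 20), event = FALSE),
    data.frame(time_months = c(6, 9), event = FALSE))
  expect_equal(nocens$statistic, 0)
  expect_equal(nocens$p_value, 1)

  # hand-worked 6-patient contrast, no censoring
  a <- data.frame(time_months = c(1, 2, 4), event = TRUE)
  b <- data.frame(time_months = c(3, 5, 6), event = TRUE)
  got <- logrank_test(a, b)
  expect_equal(got$statistic,
               oracle_logrank(a$time_months, rep(TRUE, 3),
                              b$time_months, rep(TRUE, 3)),
               tolerance = 1e-10)
  # swap invariance
  expect_equal(logrank_test(b, a)$statistic, got$statistic)
  # censoring before the first event only trims risk sets, per oracle
  a2 <- rbind(a, data.frame(time_months = 0.5, event = FALSE))
  got2 <- logrank_test(a2, b)
  expect_equal(got2$statistic,
               oracle_logrank(a2$time_months, a2$event,
                              b$time_months, rep(TRUE, 3)),
               tolerance = 1e-10)
})

test_that("hazard ratios behave under null, swap, and recovery", {
  set.seed(55)
  g1 <- random_records(150)
  null_hr <- univariate_hr(g1, g1)
  expect_lt(abs(null_hr$log_hr), 0.25)

  g2 <- random_records(80, rate = 0.5)
  swap <- univariate_hr(g2, g1)
  expect_equal(univariate_hr(g1, g2)$hr, 1 / swap$hr, tolerance = 1e-8)

  # parameter recovery at large n: true HR 0.3
  n <- 2000
  a <- data.frame(time_months = rexp(n, 0.3 * 0.1), event = TRUE)
  b <- data.frame(time_months = rexp(n, 0.1), event = TRUE)
  est <- univariate_hr(a, b)
  expect_gt(est$hr, 0.25)
  expect_lt(est$hr, 0.36)
  expect_true(est$ci95[1] < est$hr & est$hr < est$ci95[2])

  expect_error(univariate_hr(
    data.frame(time_months = 1, event = FALSE),
    data.frame(time_months = 2, event = FALSE)), "events")
})

test_that("survival contrasts split by response group", {
  set.seed(66)
  n <- 40
  clinical <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:n), each = 1),
    endpoint = "icPFS",
    time_months = c(rexp(n / 2, log(2) / 13), rexp(n / 2, log(2) / 6)),
    event = TRUE,
    radiographic_response = "PR")
  groups <- data.frame(patient_id = sprintf("P%02d", 1:n),
                       in_group_a = rep(c(TRUE, FALSE), each = n / 2))
  sc <- survival_contrast(clinical, groups, endpoint = "icPFS")
  expect_equal(sc$n_a, 20L)
  expect_lt(sc$hr$hr, 1)
  expect_error(survival_contrast(clinical, groups, endpoint = "OS"),
               "OS")
})
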