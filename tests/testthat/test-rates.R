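durations3 <- function(events) {
  expand.grid(event_id = events, treatment = c("before", "during", "after"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(exposure_min = 5)
}

test_that("tabulation pools classes, zero-fills, and conserves totals", {
  sels <- data.frame(
    event_id = "e1",
    treatment = c("before", "before", "before", "during", "after", "after"),
    class = c("HFBP_M", "HFBP_B", "CC", "WHISTLE", "BUZZ_EXCLUDED", "OTHER"))
  tab <- tabulate_rates(sels, durations3("e1"))
  expect_equal(nrow(tab), 9)
  expect_equal(sum(tab$count), 5)  # buzz dropped
  g <- function(tr, ty) tab$count[tab$treatment == tr & tab$call_type == ty]
  expect_equal(g("before", "HFBP"), 2)  # HFBP_M + HFBP_B pooled
  expect_equal(g("before", "CC"), 1)
  expect_equal(g("during", "OTHER"), 1)
  expect_equal(g("during", "HFBP"), 0)
  # empty input gives nine zero records
  none <- tabulate_rates(sels[0, ], durations3("e1"))
  expect_equal(nrow(none), 9)
  expect_true(all(none$count == 0))
  expect_error(tabulate_rates(sels, durations3("e1")[-1, ]), "missing")
})

test_that("tabulated truth counts match the generator's counts", {
  scene <- balanced_scene()
  truth <- scene$truth
  truth$event_id <- "scene1"
  tab <- tabulate_rates(truth, durations3("scene1") |> transform(exposure_min = 0.5))
  cnt <- scene$counts
  pool <- c(HFBP_M = "HFBP", HFBP_B = "HFBP", CC = "CC", WHISTLE = "OTHER")
  for (tr in c("before", "during", "after")) {
    for (ty in c("CC", "HFBP", "OTHER")) {
      want <- sum(cnt$count[cnt$treatment == tr &
                              pool[cnt$call_class] %in% ty], na.rm = TRUE)
      expect_equal(tab$count[tab$treatment == tr & tab$call_type == ty], want)
    }
  }
})

test_that("Pearson chi-square matches hand computation and stats::chisq.test", {
  # proportional rows are independent: statistic zero
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chisq_independence(prop)$statistic, 0, tolerance = 1e-12)
  # hand-computed 2x2
  res <- chisq_independence(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)
  # brute-force double loop and stats::chisq.test agreement
  set.seed(6)
  for (rep in 1:10) {
    tab <- matrix(rpois(6, 40) + 1, 2, 3)
    res <- chisq_independence(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    brute <- 0
    for (i in 1:2) for (j in 1:3) brute <- brute + (tab[i, j] - E[i, j])^2 / E[i, j]
    expect_equal(res$statistic, brute, tolerance = 1e-12)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-9)
    expect_equal(res$p, ct$p.value, tolerance = 1e-9)
  }
  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Holm adjustment equals the sort-multiply-cummax oracle", {
  holm_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- pmin(cummax(p[o] * (n - seq_len(n) + 1)), 1)
    out <- numeric(n)
    out[o] <- adj
    out
  }
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(6)
    expect_equal(p.adjust(p, "holm"), holm_oracle(p), tolerance = 1e-12)
  }
  # single-member family is unchanged
  expect_equal(p.adjust(0.03, "holm"), 0.03)
  # never decreases, nesting of rejection sets preserved
  p <- runif(6)
  expect_true(all(p.adjust(p, "holm") >= p))
})

test_that("the NB mixed model recovers simulated effects and offset algebra", {
  rates <- type_rates()
  rec <- sim_type_records(80, rates, seed0 = 300)
  fit <- fit_nb_glmm(rec)
  expect_true(fit$converged)
  # with the log-exposure offset the coefficients live on the per-minute scale
  truth <- beta_truth(rates)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  se <- setNames(fit$fixed$se, fit$fixed$term)
  covered <- abs(est[names(truth)] - truth) <= 2.5 * se[names(truth)]
  expect_true(all(covered))
  expect_equal(fit$theta, 2, tolerance = 0.8)
  # doubling every exposure with counts fixed shifts only the intercept by -log 2
  rec2 <- rec
  rec2$exposure_min <- rec2$exposure_min * 2
  fit2 <- fit_nb_glmm(rec2)
  est2 <- setNames(fit2$fixed$estimate, fit2$fixed$term)
  expect_equal(est2[["(Intercept)"]], est[["(Intercept)"]] - log(2),
               tolerance = 1e-3)
  others <- setdiff(names(est), "(Intercept)")
  expect_equal(est2[others], est[others], tolerance = 1e-3)
})

test_that("contrast estimates and SEs agree with emmeans", {
  skip_if_not_installed("emmeans")
  rec <- sim_type_records(40, type_rates(), seed0 = 500)
  fit <- fit_nb_glmm(rec)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 6)
  em <- emmeans::emmeans(fit$model, ~ treatment | call_type)
  ce <- as.data.frame(emmeans::contrast(em, "trt.vs.ctrl", ref = "during",
                                        adjust = "none"))
  for (i in seq_len(nrow(ct))) {
    j <- which(ce$call_type == ct$call_type[i] &
                 startsWith(as.character(ce$contrast),
                            sub(" -.*", "", ct$contrast[i])))
    expect_length(j, 1)
    expect_equal(ct$estimate[i], ce$estimate[j], tolerance = 1e-6)
    expect_equal(ct$se[i], ce$SE[j], tolerance = 1e-6)
  }
  expect_true(all(ct$p_holm >= ct$p_raw))
  expect_true(all(ct$p_holm <= 1 & ct$p_raw >= 0))
})

test_that("the pseudo-R2 decomposition sums to 100 and tracks the latent shares", {
  rates <- type_rates()
  rec <- sim_type_records(120, rates, theta = 50, event_sd = 0.6, seed0 = 700)
  fit <- fit_nb_glmm(rec)
  r2 <- pseudo_r2(fit)
  expect_equal(sum(r2), 100, tolerance = 1e-9)
  expect_true(all(r2 >= 0))
  # brute-force latent decomposition at the true parameters
  grid <- expand.grid(treatment = c("before", "during", "after"),
                      call_type = c("CC", "HFBP", "OTHER"),
                      stringsAsFactors = FALSE)
  eta <- log(rates[cbind(grid$treatment, grid$call_type)])
  var_f_true <- var(eta) * 8 / 9  # population variance over the 9 cells
  lambda <- exp(mean(eta) + log(5) + 0.6^2 / 2)
  shares <- c(var_f_true, 0.6^2, trigamma(1 / (1 / lambda + 1 / 50)))
  expect_equal(unname(r2["marginal_pct"]), 100 * shares[1] / sum(shares),
               tolerance = 8)
  expect_equal(unname(r2["random_pct"]), 100 * shares[2] / sum(shares),
               tolerance = 8)
  # no heterogeneity: the random share collapses
  rec0 <- sim_type_records(120, rates, theta = 50, event_sd = 0, seed0 = 900)
  r20 <- pseudo_r2(fit_nb_glmm(rec0))
  expect_lt(r20[["random_pct"]], 5)
})

test_that("degenerate count inputs are caught", {
  rec <- sim_type_records(2, type_rates(), seed0 = 1)
  expect_error(fit_nb_glmm(rec[rec$event_id == "e001", ]), "two events")
  rec0 <- rec
  rec0$count[rec0$call_type == "CC"] <- 0L
  w <- capture_warnings(fit_nb_glmm(rec0))
  expect_true(any(grepl("all-zero", w)))
})
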