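#' Tabulate call counts per event, treatment and call type
#'
#' Pools classified selections into the three analysis types: HFBP_M and
#' HFBP_B become HFBP (ultrasonic calls are modelled jointly since the
#' biphonal low-frequency element is unreliable in noise), WHISTLE and OTHER
#' become OTHER, and excluded echolocation buzzes (BUZZ, BUZZ_EXCLUDED) are
#' dropped. Every event contributes a complete 3 treatments x 3 types grid,
#' zero-filled where no calls occurred.
#'
#' @param selections data.frame with `event_id`, `treatment` and `class`
#'   columns (one row per classified selection).
#' @param durations data.frame with `event_id`, `treatment`, `exposure_min`
#'   giving the minutes of analysed audio per cell.
#' @return data.frame with `event_id`, `treatment`, `call_type`, `count`,
#'   `exposure_min`.
#' @export
tabulate_rates <- function(selections, durations) {
  .check(all(c("event_id", "treatment", "class") %in% names(selections)),
         "selections need event_id, treatment and class columns")
  .check(all(c("event_id", "treatment", "exposure_min") %in% names(durations)),
         "durations need event_id, treatment and exposure_min columns")
  .check(all(durations$exposure_min > 0), "exposures must be positive")
  pool <- c(HFBP_M = "HFBP", HFBP_B = "HFBP", CC = "CC",
            WHISTLE = "OTHER", OTHER = "OTHER")
  keep <- selections$class %in% names(pool)
  sel <- selections[keep, ]
  sel$call_type <- pool[sel$class]
  grid <- expand.grid(event_id = unique(durations$event_id),
                      treatment = c("before", "during", "after"),
                      call_type = c("CC", "HFBP", "OTHER"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$event_id, d$treatment, d$call_type)
  tab <- table(key(sel))
  grid$count <- as.integer(tab[key(grid)])
  grid$count[is.na(grid$count)] <- 0L
  dkey <- paste(durations$event_id, durations$treatment)
  grid$exposure_min <- durations$exposure_min[match(paste(grid$event_id, grid$treatment), dkey)]
  .check(!anyNA(grid$exposure_min), "missing treatment durations for some cells")
  grid[order(grid$event_id, grid$treatment, grid$call_type), ]
}

#' Fit the negative-binomial mixed model for call rates
#'
#' `count ~ treatment * call_type + offset(log(exposure_min)) + (1 | event_id)`
#' with a negative-binomial response (quadratic mean-variance, log link),
#' fitted by maximum likelihood with the Laplace approximation. The treatment
#' reference level is `during`, so the reported coefficients are
#' before-vs-during and after-vs-during effects; the call-type reference is
#' `CC`. Counts are modelled with a log-exposure offset rather than
#' pre-divided rates, which keeps the likelihood valid while retaining the
#' calls-per-minute interpretation. On non-convergence the optimiser is
#' restarted from up to five seeded jittered starting points before the fit
#' is flagged.
#'
#' @param records count records as from [tabulate_rates()] (columns
#'   `event_id`, `treatment`, `call_type`, `count`, `exposure_min`).
#' @return object of class `nb_glmm_fit`: list with `model` (the glmmTMB
#'   fit), `fixed` (data.frame of estimates, se, z), `theta` (NB dispersion),
#'   `sigma2_event` (random-intercept variance), `loglik`, `converged`.
#' @export
fit_nb_glmm <- function(records) {
  .check(all(c("event_id", "treatment", "call_type", "count", "exposure_min")
             %in% names(records)), "records are missing required columns")
  .check(length(unique(records$event_id)) >= 2, "need at least two events")
  .check(all(records$count >= 0), "counts must be non-negative")
  zero_strata <- tapply(records$count, records$call_type, sum) == 0
  if (any(zero_strata)) {
    warning(sprintf("all-zero call type(s): %s",
                    paste(names(zero_strata)[zero_strata], collapse = ", ")))
  }
  d <- records
  d$treatment <- stats::relevel(factor(d$treatment,
                                       levels = c("before", "during", "after")),
                                ref = "during")
  d$call_type <- stats::relevel(factor(d$call_type), ref = "CC")
  d$event_id <- factor(d$event_id)
  fit_once <- function(start = NULL) {
    suppressWarnings(glmmTMB::glmmTMB(
      count ~ treatment * call_type + offset(log(exposure_min)) + (1 | event_id),
      family = glmmTMB::nbinom2, data = d, REML = FALSE, start = start))
  }
  ok <- function(f) isTRUE(f$fit$convergence == 0) && !isFALSE(f$sdr$pdHess)
  fit <- fit_once()
  if (!ok(fit)) {
    # adaptive restarts from jittered starting values (seeded, up to 5)
    rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()), add = TRUE)
    n_beta <- ncol(stats::model.matrix(~ treatment * call_type, d))
    for (k in 1:5) {
      set.seed(1000 + k)
      cand <- try(fit_once(start = list(beta = stats::rnorm(n_beta, 0, 0.5),
                                        theta = stats::rnorm(1, 0, 0.5),
                                        betadisp = stats::rnorm(1, 0, 0.5))),
                  silent = TRUE)
      if (!inherits(cand, "try-error") && ok(cand)) { fit <- cand; break }
    }
  }
  converged <- ok(fit)
  if (!converged) {
    warning(sprintf("NB GLMM did not converge: %s",
                    fit$fit$message %||% "non-positive-definite Hessian"))
  }
  sm <- summary(fit)$coefficients$cond
  fixed <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], row.names = NULL)
  structure(list(model = fit, fixed = fixed,
                 theta = glmmTMB::sigma(fit),
                 sigma2_event = glmmTMB::VarCorr(fit)$cond$event_id[1, 1],
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged, data = d),
            class = "nb_glmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nb_glmm_fit <- function(x, ...) {
  cat(sprintf("<nb_glmm_fit> theta=%.3g, sigma2_event=%.3g, logLik=%.2f%s\n",
              x$theta, x$sigma2_event, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Treatment contrasts within call types, Holm-adjusted
#'
#' The six before-vs-during and after-vs-during rate-ratio contrasts, one
#' pair per call type, as linear combinations of the fixed effects. Standard
#' errors come from the fixed-effect covariance (delta method), p values are
#' two-sided normal, and the six are Holm-adjusted as one family.
#'
#' @param fit an `nb_glmm_fit`.
#' @return data.frame with `contrast`, `call_type`, `estimate`, `se`, `z`,
#'   `p_raw`, `p_holm`.
#' @export
pairwise_contrasts <- function(fit) {
  .check(inherits(fit, "nb_glmm_fit"), "fit must be an nb_glmm_fit")
  .check(fit$converged, "model did not converge")
  beta <- glmmTMB::fixef(fit$model)$cond
  V <- stats::vcov(fit$model)$cond
  types <- levels(fit$data$call_type)
  rows <- list()
  for (ty in types) {
    for (tr in c("before", "after")) {
      l <- stats::setNames(numeric(length(beta)), names(beta))
      l[paste0("treatment", tr)] <- 1
      inter <- paste0("treatment", tr, ":call_type", ty)
      if (inter %in% names(beta)) l[inter] <- 1
      est <- sum(l * beta)
      se <- sqrt(drop(t(l) %*% V %*% l))
      .check(is.finite(se) && se > 0, "singular fixed-effect covariance")
      rows[[length(rows) + 1]] <- data.frame(
        contrast = sprintf("%s - during | %s", tr, ty), call_type = ty,
        estimate = est, se = se, z = est / se)
    }
  }
  out <- do.call(rbind, rows)
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  rownames(out) <- NULL
  out
}

#' Latent-scale pseudo-R2 decomposition
#'
#' Partitions the latent (log-link) variance of the fitted model into the
#' share explained by the fixed effects (marginal), by the event random
#' intercept, and the residual, after Nakagawa's method: the fixed-effect
#' component is the variance of the fixed linear predictor, the random
#' component is the intercept variance, and the distribution-specific
#' residual variance of the negative binomial uses the trigamma form
#' `trigamma((1/lambda + 1/theta)^-1)` with `lambda` the typical marginal
#' mean count. The three shares sum to 100%.
#'
#' @param fit an `nb_glmm_fit`.
#' @return named numeric: `marginal_pct`, `random_pct`, `residual_pct`.
#' @export
pseudo_r2 <- function(fit) {
  .check(inherits(fit, "nb_glmm_fit"), "fit must be an nb_glmm_fit")
  X <- stats::model.matrix(~ treatment * call_type, fit$data)
  beta <- glmmTMB::fixef(fit$model)$cond
  eta_fix <- drop(X[, names(beta), drop = FALSE] %*% beta)
  var_f <- stats::var(eta_fix)
  var_a <- fit$sigma2_event
  offs <- log(fit$data$exposure_min)
  lambda <- exp(mean(eta_fix + offs) + var_a / 2)
  var_e <- trigamma(1 / (1 / lambda + 1 / fit$theta))
  total <- var_f + var_a + var_e
  .check(total > 0, "zero total latent variance")
  c(marginal_pct = 100 * var_f / total,
    random_pct = 100 * var_a / total,
    residual_pct = 100 * var_e / total)
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an r x c contingency table: expected counts
#' from the margin products, `sum((O-E)^2/E)`, df `(r-1)(c-1)`, upper-tail
#' chi-square p value. No continuity correction.
#'
#' @param table numeric matrix of non-negative counts.
#' @return list with `statistic`, `df`, `p`, and `expected`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  .check(all(table >= 0), "counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  .check(all(rs > 0) && all(cs > 0), "zero row or column margin")
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), expected = expected)
}
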