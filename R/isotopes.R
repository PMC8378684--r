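# Stable-isotope niche metrics and Bayesian trophic-position estimation.
# All delta values are carried in permil throughout.

#' Suess-effect correction for d13C
#'
#' Adjusts a d13C value from its sampling year to a target year at the
#' secular oceanic decline rate (default -0.022 permil per year).
#'
#' @param d13C value(s), permil.
#' @param from_year,to_year calendar years, `to_year >= from_year`.
#' @param rate decline, permil per year (negative).
#' @return corrected d13C, permil.
#' @examples
#' suess_correct(-18.7, 2009, 2017)  # -18.876
#' @export
suess_correct <- function(d13C, from_year, to_year, rate = -0.022) {
  if (any(to_year < from_year)) stop("to_year must be >= from_year")
  d13C + rate * (to_year - from_year)
}

#' Standard ellipse area of a bivariate isotope sample
#'
#' SEA is the area of the 1-SD standard ellipse,
#' `pi * sqrt(det(cov))`; SEA_C applies the small-sample correction
#' `(n - 1) / (n - 2)`.
#'
#' @param d13C,d15N numeric vectors (n >= 3).
#' @param label optional group label.
#' @return list of class `ellipse_fit`: `label`, `n`, `mean` (length-2),
#'   `cov` (2x2), `sea`, `sea_c` (permil^2).
#' @export
sea_from_samples <- function(d13C, d15N, label = NULL) {
  stopifnot(length(d13C) == length(d15N), length(d13C) >= 3,
            all(is.finite(d13C)), all(is.finite(d15N)))
  S <- stats::cov(cbind(d13C, d15N))
  dt <- det(S)
  if (dt <= 0) stop("singular covariance: degenerate isotope sample")
  n <- length(d13C)
  sea <- pi * sqrt(dt)
  structure(list(label = label, n = n,
                 mean = c(d13C = mean(d13C), d15N = mean(d15N)),
                 cov = S, sea = sea, sea_c = sea * (n - 1) / (n - 2)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse_fit%s: n = %d, SEA = %.3f, SEA_C = %.3f permil^2\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$n, x$sea, x$sea_c))
  invisible(x)
}

#' Bayesian standard ellipse area
#'
#' Posterior of the bivariate covariance under a conjugate
#' normal-inverse-Wishart model with a vague prior (`Psi0 = 1e-3 * I`,
#' `nu0 = 3`, location weight -> 0); each draw's ellipse area is
#' `pi * sqrt(det(Sigma_draw))`.
#'
#' @inheritParams sea_from_samples
#' @param n_draws posterior draws (default 4000).
#' @param seed integer seed.
#' @return list of class `sea_posterior`: `draws` (SEA_B values), `mean`,
#'   `ci` (2.5/97.5%), `n`, `label`.
#' @export
sea_bayesian <- function(d13C, d15N, n_draws = 4000, seed = 1L,
                         label = NULL) {
  stopifnot(length(d13C) >= 3)
  set.seed(seed)
  X <- cbind(d13C, d15N)
  n <- nrow(X)
  S <- crossprod(sweep(X, 2, colMeans(X)))
  Psi_n <- diag(2) * 1e-3 + S
  nu_n <- 3 + n
  W <- stats::rWishart(n_draws, df = nu_n, Sigma = solve(Psi_n))
  draws <- vapply(seq_len(n_draws),
                  function(i) pi / sqrt(det(W[, , i])), numeric(1))
  structure(list(draws = draws, mean = mean(draws),
                 ci = stats::quantile(draws, c(0.025, 0.975)),
                 n = n, label = label),
            class = "sea_posterior")
}

#' Posterior probability that one niche is smaller than another
#'
#' Fraction of index-paired draws with `SEA_B(A) < SEA_B(B)`.
#'
#' @param fit_a,fit_b `sea_posterior` objects.
#' @return probability in \[0, 1\].
#' @export
sea_b_smaller <- function(fit_a, fit_b) {
  k <- min(length(fit_a$draws), length(fit_b$draws))
  mean(fit_a$draws[seq_len(k)] < fit_b$draws[seq_len(k)])
}

# SEA_C ellipse boundary as a convex polygon (n_vertices CCW points)
.ellipse_polygon <- function(fit, n_vertices = 1024) {
  Sc <- fit$cov * (fit$n - 1) / (fit$n - 2)
  L <- t(chol(Sc))
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  P <- t(L %*% rbind(cos(th), sin(th))) +
    matrix(fit$mean, n_vertices, 2, byrow = TRUE)
  if (.shoelace(P) < 0) P <- P[rev(seq_len(nrow(P))), ]
  P
}

.shoelace <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  j <- c(seq_len(nrow(P))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Sutherland-Hodgman clipping of polygon `subj` by convex CCW polygon `clip`
.clip_convex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    # inside = left of edge a->b
    side <- function(p) (b[1] - a[1]) * (p[, 2] - a[2]) -
      (b[2] - a[2]) * (p[, 1] - a[1])
    s <- side(out)
    nxt <- matrix(numeric(0), 0, 2)
    n <- nrow(out)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      ci <- s[i] >= 0; cj <- s[j] >= 0
      if (ci) nxt <- rbind(nxt, out[i, ])
      if (xor(ci, cj)) {
        t <- s[i] / (s[i] - s[j])
        nxt <- rbind(nxt, out[i, ] + t * (out[j, ] - out[i, ]))
      }
    }
    out <- nxt
  }
  out
}

#' Overlap between two standard ellipses
#'
#' Intersection area of the two SEA_C ellipses, computed on 1024-vertex
#' polygon approximations with convex clipping. The joint percentage is
#' intersection over union; the per-group percentages are intersection
#' over each ellipse's own area.
#'
#' @param fit_a,fit_b `ellipse_fit` objects.
#' @param n_vertices polygon resolution (default 1024).
#' @return list: `intersection` (permil^2), `area_a`, `area_b`,
#'   `joint_pct`, `pct_of_a`, `pct_of_b`.
#' @export
ellipse_overlap <- function(fit_a, fit_b, n_vertices = 1024) {
  Pa <- .ellipse_polygon(fit_a, n_vertices)
  Pb <- .ellipse_polygon(fit_b, n_vertices)
  inter_poly <- .clip_convex(Pa, Pb)
  inter <- if (nrow(inter_poly) >= 3) abs(.shoelace(inter_poly)) else 0
  aa <- abs(.shoelace(Pa)); ab <- abs(.shoelace(Pb))
  list(intersection = inter, area_a = aa, area_b = ab,
       joint_pct = 100 * inter / (aa + ab - inter),
       pct_of_a = 100 * inter / aa,
       pct_of_b = 100 * inter / ab)
}

#' Analytic trophic-position point estimate (one baseline)
#'
#' Noise-free inversion of the enrichment equation:
#' `TP = lambda + (d15N_consumer - d15N_baseline) / dn`.
#'
#' @param d15N_consumer consumer d15N (vector averaged), permil.
#' @param d15N_baseline baseline mean d15N, permil.
#' @param dn trophic discrimination factor for nitrogen, permil.
#' @param lambda baseline trophic position (default 2).
#' @return trophic position estimate.
#' @export
tp_point_estimate <- function(d15N_consumer, d15N_baseline, dn = 2.8,
                              lambda = 2) {
  lambda + (mean(d15N_consumer) - d15N_baseline) / dn
}

#' MCMC settings
#'
#' @param n_iter post-burn-in iterations per chain.
#' @param n_burn burn-in iterations.
#' @param n_chains number of chains (>= 2 for convergence checks;
#'   default 3).
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 5000, n_burn = 1000, n_chains = 3) {
  stopifnot(n_iter >= 100, n_burn >= 0, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 n_chains = as.integer(n_chains)),
            class = "mcmc_settings")
}

# random-walk Metropolis-within-Gibbs over a named parameter vector.
# `ridge` (optional) adds a move tailored to the TP-vs-TDF ridge: it
# perturbs the discrimination factor while rescaling TP to keep the total
# enrichment dn * (TP - lambda) fixed (Jacobian dn/dn'), which decorrelates
# the two strongly trading-off parameters.
.mh_gibbs <- function(logpost, init, prop_sd, settings, ridge = NULL) {
  np <- length(init)
  total <- settings$n_burn + settings$n_iter
  draws <- array(NA_real_,
                 c(settings$n_iter, np, settings$n_chains),
                 dimnames = list(NULL, names(init), NULL))
  for (ch in seq_len(settings$n_chains)) {
    x <- init + stats::rnorm(np, 0, prop_sd) * 0.5
    lp <- logpost(x)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      x <- init + stats::rnorm(np, 0, prop_sd) * 0.5
      lp <- logpost(x); tries <- tries + 1
    }
    if (!is.finite(lp)) { x <- init; lp <- logpost(x) }
    sd_ch <- prop_sd
    acc <- att <- numeric(np)
    for (i in seq_len(total)) {
      for (k in seq_len(np)) {
        prop <- x
        prop[k] <- x[k] + stats::rnorm(1, 0, sd_ch[k])
        lpp <- logpost(prop)
        att[k] <- att[k] + 1
        if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
          x <- prop; lp <- lpp; acc[k] <- acc[k] + 1
        }
      }
      # burn-in-only proposal adaptation toward ~35% acceptance
      if (i <= settings$n_burn && i %% 100 == 0) {
        rate <- acc / pmax(att, 1)
        sd_ch <- sd_ch * ifelse(rate < 0.15, 0.5,
                                ifelse(rate > 0.5, 1.8, 1))
        acc[] <- 0; att[] <- 0
      }
      if (!is.null(ridge)) {
        dn <- x[ridge$dn]; tp <- x[ridge$tp]
        dn2 <- dn + stats::rnorm(1, 0, ridge$sd)
        if (dn2 > 0.01) {
          prop <- x
          prop[ridge$dn] <- dn2
          prop[ridge$tp] <- ridge$lambda + dn * (tp - ridge$lambda) / dn2
          lpp <- logpost(prop) + log(dn / dn2)
          if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
            x <- prop; lp <- logpost(x)
          }
        }
        # shear moves: shift a baseline-d15N parameter and compensate TP
        # so the fitted consumer mean is unchanged (unit Jacobian)
        # alpha shear: move the mixing proportion and compensate TP for
        # the induced change in the mixed baseline d15N (unit Jacobian)
        if (!is.null(ridge$alpha)) {
          eps <- stats::rnorm(1, 0, ridge$alpha$sd)
          prop <- x
          prop[ridge$alpha$idx] <- x[ridge$alpha$idx] + eps
          prop[ridge$tp] <- x[ridge$tp] -
            eps * (x[ridge$alpha$b1] - x[ridge$alpha$b2]) / x[ridge$dn]
          lpp <- logpost(prop)
          if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
            x <- prop; lp <- lpp
          }
        }
        for (sh in ridge$shifts) {
          eps <- stats::rnorm(1, 0, sh$sd)
          w <- if (is.null(sh$weight_of)) 1 else x[sh$weight_of]
          if (!is.null(sh$weight_complement) && sh$weight_complement)
            w <- 1 - w
          prop <- x
          prop[sh$param] <- x[sh$param] + eps
          prop[ridge$tp] <- x[ridge$tp] - w * eps / x[ridge$dn]
          lpp <- logpost(prop)
          if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
            x <- prop; lp <- lpp
          }
        }
      }
      if (i > settings$n_burn) draws[i - settings$n_burn, , ch] <- x
    }
  }
  draws
}

# split-Rhat per parameter over an [iter, param, chain] array
.rhat <- function(draws) {
  ni <- dim(draws)[1]; np <- dim(draws)[2]; nc <- dim(draws)[3]
  half <- floor(ni / 2)
  out <- numeric(np)
  for (k in seq_len(np)) {
    chains <- list()
    for (ch in seq_len(nc)) {
      chains[[length(chains) + 1]] <- draws[seq_len(half), k, ch]
      chains[[length(chains) + 1]] <- draws[(half + 1):(2 * half), k, ch]
    }
    m <- length(chains)
    means <- vapply(chains, mean, numeric(1))
    vars <- vapply(chains, stats::var, numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W <= 0) { out[k] <- 1; next }
    out[k] <- sqrt(((half - 1) / half * W + B / half) / W)
  }
  stats::setNames(out, dimnames(draws)[[2]])
}

.half_cauchy_lp <- function(s, scale = 1) {
  if (s <= 0) return(-Inf)
  stats::dcauchy(s, 0, scale, log = TRUE) + log(2)
}

.summarize_tp <- function(draws, settings, extra_flags = list()) {
  rh <- .rhat(draws)
  flat <- do.call(rbind, lapply(seq_len(dim(draws)[3]),
                                function(ch) draws[, , ch]))
  colnames(flat) <- dimnames(draws)[[2]]
  tp <- flat[, "tp"]
  out <- list(
    draws = as.data.frame(flat),
    tp_mean = mean(tp), tp_sd = stats::sd(tp),
    tp_ci = stats::quantile(tp, c(0.025, 0.975)),
    rhat = rh,
    converged = dim(draws)[3] < 2 || all(rh < 1.1, na.rm = TRUE),
    settings = settings)
  if ("alpha" %in% colnames(flat)) {
    al <- flat[, "alpha"]
    out$alpha_mean <- mean(al); out$alpha_sd <- stats::sd(al)
    out$alpha_ci <- stats::quantile(al, c(0.025, 0.975))
  }
  c(out, extra_flags)
}

#' One-baseline Bayesian trophic position
#'
#' Model: `d15N_consumer ~ Normal(bN + dn * (TP - lambda), sigma^2)` with
#' priors `bN ~ Normal(baseline mean, baseline SD)`, `dn ~ Normal(TDF
#' mean, TDF SD)`, `TP ~ Uniform(lambda, tp_max)`, `sigma ~
#' half-Cauchy(1)`. Sampled by random-walk Metropolis-within-Gibbs over
#' `n_chains` chains; convergence is checked with split-Rhat (< 1.1).
#'
#' @param d15N consumer d15N values, permil (baseline already
#'   Suess-consistent: d15N is assumed time-invariant).
#' @param baseline one row of a baseline table ([default_baselines()]
#'   format) or a list with `d15N_mean`, `d15N_sd`.
#' @param tdf [default_tdf()]-style list.
#' @param lambda baseline trophic position (default 2).
#' @param tp_max upper prior bound (default 10).
#' @param settings [mcmc_settings()].
#' @param seed integer seed.
#' @return list of class `tp_posterior` (draws, `tp_mean`, `tp_sd`,
#'   `tp_ci`, `rhat`, `converged`).
#' @export
tp_one_baseline <- function(d15N, baseline, tdf = default_tdf(),
                            lambda = 2, tp_max = 10,
                            settings = mcmc_settings(), seed = 1L) {
  set.seed(seed)
  y <- d15N
  b_mu <- baseline$d15N_mean; b_sd <- baseline$d15N_sd
  logpost <- function(th) {
    tp <- th[1]; bn <- th[2]; dn <- th[3]; sig <- exp(th[4])
    if (tp < lambda || tp > tp_max) return(-Inf)
    sum(stats::dnorm(y, bn + dn * (tp - lambda), sig, log = TRUE)) +
      stats::dnorm(bn, b_mu, b_sd, log = TRUE) +
      stats::dnorm(dn, tdf$dn_mean, tdf$dn_sd, log = TRUE) +
      .half_cauchy_lp(sig) + th[4]
  }
  tp0 <- min(max(tp_point_estimate(y, b_mu, tdf$dn_mean, lambda),
                 lambda + 0.05), tp_max - 0.05)
  init <- c(tp = tp0, bn = b_mu, dn = tdf$dn_mean,
            log_sigma = log(max(stats::sd(y), 0.05)))
  prop <- c(0.15, b_sd / 2 + 0.01, tdf$dn_sd / 2 + 0.01, 0.3)
  draws <- .mh_gibbs(logpost, init, prop, settings,
                     ridge = list(dn = 3L, tp = 1L, lambda = lambda,
                                  sd = tdf$dn_sd,
                                  shifts = list(list(param = 2L,
                                                     sd = b_sd))))
  out <- .summarize_tp(draws, settings)
  class(out) <- "tp_posterior"
  out
}

#' Two-baseline (full) Bayesian trophic position
#'
#' The mixing parameter `alpha` in \[0, 1\] weights baseline 1 against
#' baseline 2 in both elements:
#' `E[d15N] = alpha * bN1 + (1 - alpha) * bN2 + dn * (TP - lambda)` and
#' `E[d13C] = alpha * bC1 + (1 - alpha) * bC2 + dc * (TP - lambda)`.
#' Priors: baselines Normal at their reported means/SDs (d13C
#' Suess-corrected to `consumer_year` first), `dn`/`dc` Normal at the TDF,
#' `TP ~ Uniform(lambda, tp_max)`, `alpha ~ Beta(1, 1)`, both residual
#' SDs half-Cauchy(1). Baselines with (near-)identical d13C leave alpha
#' unidentifiable; this is flagged and the alpha posterior then simply
#' returns its prior.
#'
#' @param d15N,d13C consumer values, permil (same length).
#' @param baseline_1,baseline_2 rows/lists with `d15N_mean`, `d15N_sd`,
#'   `d13C_mean`, `d13C_sd`, `year`.
#' @param consumer_year year consumers were sampled (for the Suess
#'   correction of baseline d13C; default 2017).
#' @inheritParams tp_one_baseline
#' @return list of class `tp_posterior` with additional `alpha_*`
#'   summaries and an `alpha_unidentifiable` flag.
#' @export
tp_two_baseline <- function(d15N, d13C, baseline_1, baseline_2,
                            tdf = default_tdf(), lambda = 2, tp_max = 10,
                            consumer_year = 2017,
                            settings = mcmc_settings(), seed = 1L) {
  stopifnot(length(d15N) == length(d13C))
  set.seed(seed)
  b1c <- suess_correct(baseline_1$d13C_mean, baseline_1$year, consumer_year)
  b2c <- suess_correct(baseline_2$d13C_mean, baseline_2$year, consumer_year)
  alpha_flag <- abs(b1c - b2c) < 1e-6
  yN <- d15N; yC <- d13C
  logpost <- function(th) {
    tp <- th["tp"]; al <- th["alpha"]
    if (tp < lambda || tp > tp_max || al < 0 || al > 1) return(-Inf)
    bn1 <- th["bn1"]; bn2 <- th["bn2"]; bc1 <- th["bc1"]; bc2 <- th["bc2"]
    dn <- th["dn"]; dc <- th["dc"]
    sn <- exp(th["log_sn"]); sc <- exp(th["log_sc"])
    muN <- al * bn1 + (1 - al) * bn2 + dn * (tp - lambda)
    muC <- al * bc1 + (1 - al) * bc2 + dc * (tp - lambda)
    sum(stats::dnorm(yN, muN, sn, log = TRUE)) +
      sum(stats::dnorm(yC, muC, sc, log = TRUE)) +
      stats::dnorm(bn1, baseline_1$d15N_mean, baseline_1$d15N_sd, log = TRUE) +
      stats::dnorm(bn2, baseline_2$d15N_mean, baseline_2$d15N_sd, log = TRUE) +
      stats::dnorm(bc1, b1c, baseline_1$d13C_sd, log = TRUE) +
      stats::dnorm(bc2, b2c, baseline_2$d13C_sd, log = TRUE) +
      stats::dnorm(dn, tdf$dn_mean, tdf$dn_sd, log = TRUE) +
      stats::dnorm(dc, tdf$dc_mean, tdf$dc_sd, log = TRUE) +
      .half_cauchy_lp(sn) + th["log_sn"] +
      .half_cauchy_lp(sc) + th["log_sc"]
  }
  tp0 <- min(max(tp_point_estimate(yN, mean(c(baseline_1$d15N_mean,
                                              baseline_2$d15N_mean)),
                                   tdf$dn_mean, lambda),
                 lambda + 0.05), tp_max - 0.05)
  init <- c(tp = unname(tp0), alpha = 0.5,
            bn1 = baseline_1$d15N_mean, bn2 = baseline_2$d15N_mean,
            bc1 = b1c, bc2 = b2c,
            dn = tdf$dn_mean, dc = tdf$dc_mean,
            log_sn = log(max(stats::sd(yN), 0.05)),
            log_sc = log(max(stats::sd(yC), 0.05)))
  prop <- c(tp = 0.15, alpha = 0.1,
            bn1 = baseline_1$d15N_sd / 2 + 0.01,
            bn2 = baseline_2$d15N_sd / 2 + 0.01,
            bc1 = baseline_1$d13C_sd / 2 + 0.01,
            bc2 = baseline_2$d13C_sd / 2 + 0.01,
            dn = tdf$dn_sd / 2 + 0.01, dc = tdf$dc_sd / 2 + 0.01,
            log_sn = 0.3, log_sc = 0.3)
  draws <- .mh_gibbs(logpost, init, prop, settings,
                     ridge = list(dn = 7L, tp = 1L, lambda = lambda,
                                  sd = tdf$dn_sd,
                                  alpha = list(idx = 2L, b1 = 3L, b2 = 4L,
                                               sd = 0.15),
                                  shifts = list(
                                    list(param = 3L, sd = baseline_1$d15N_sd,
                                         weight_of = 2L),
                                    list(param = 4L, sd = baseline_2$d15N_sd,
                                         weight_of = 2L,
                                         weight_complement = TRUE))))
  out <- .summarize_tp(draws, settings,
                       extra_flags = list(alpha_unidentifiable = alpha_flag))
  class(out) <- "tp_posterior"
  out
}

#' @export
print.tp_posterior <- function(x, ...) {
  cat(sprintf("TP posterior: %.2f +/- %.2f [%.2f-%.2f]%s\n",
              x$tp_mean, x$tp_sd, x$tp_ci[1], x$tp_ci[2],
              if (x$converged) "" else "  (NOT converged, Rhat > 1.1)"))
  if (!is.null(x$alpha_mean))
    cat(sprintf("alpha: %.2f +/- %.2f [%.2f-%.2f]\n", x$alpha_mean,
                x$alpha_sd, x$alpha_ci[1], x$alpha_ci[2]))
  invisible(x)
}

#' Posterior probability that draws from a exceed draws from b
#'
#' Fraction of randomly index-paired draws with `a > b`; pairing is a
#' seeded shuffle of `b` against `a`.
#'
#' @param draws_a,draws_b numeric vectors of posterior draws (>= 1000
#'   each).
#' @param seed shuffle seed.
#' @return probability in \[0, 1\].
#' @export
compare_posteriors <- function(draws_a, draws_b, seed = 1L) {
  stopifnot(length(draws_a) >= 1000, length(draws_b) >= 1000)
  set.seed(seed)
  k <- min(length(draws_a), length(draws_b))
  a <- draws_a[sample.int(length(draws_a), k)]
  b <- draws_b[sample.int(length(draws_b), k)]
  mean(a > b)
}
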