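# All four estimators take the 2x2 cells of one drug-term pair:
#   a target reports with the term, b without; c background reports with
#   the term, d without; N = a+b+c+d.
# Tables with a zero cell have no finite estimate; by default they yield NA
# (an undefined-signal marker) rather than an error, and the
# Haldane-Anscombe +0.5 correction can be switched on instead.

.prep_cells <- function(a, b, c, d, haldane) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (haldane) {
    a <- ifelse(zero, a + 0.5, a); b <- ifelse(zero, b + 0.5, b)
    c <- ifelse(zero, c + 0.5, c); d <- ifelse(zero, d + 0.5, d)
    undef <- rep(FALSE, length(a))
  } else {
    undef <- zero
  }
  list(a = a, b = b, c = c, d = d, undef = undef)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a*d)/(b*c)`, with the log-scale Wald interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d 2x2 cell counts (vectorized).
#' @param conf confidence level (default 0.95).
#' @param haldane add 0.5 to every cell of tables containing a zero; when
#'   `FALSE` (default) such tables return `NA`.
#' @return data frame `ror`, `ror_low`, `ror_high`.
#' @export
compute_ror <- function(a, b, c, d, conf = 0.95, haldane = FALSE) {
  p <- .prep_cells(a, b, c, d, haldane)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ror <- (p$a * p$d) / (p$b * p$c)
  se <- sqrt(1 / p$a + 1 / p$b + 1 / p$c + 1 / p$d)
  out <- data.frame(ror = ror,
                    ror_low = exp(log(ror) - z * se),
                    ror_high = exp(log(ror) + z * se))
  out[p$undef, ] <- NA_real_
  out
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the Pearson
#' chi-squared of the 2x2 table, `N(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`,
#' without continuity correction.
#'
#' @inheritParams compute_ror
#' @return data frame `prr`, `chi2`.
#' @export
compute_prr <- function(a, b, c, d, haldane = FALSE) {
  p <- .prep_cells(a, b, c, d, haldane)
  a <- p$a; b <- p$b; c <- p$c; d <- p$d
  N <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  out <- data.frame(prr = prr, chi2 = chi2)
  out[p$undef, ] <- NA_real_
  out
}

#' Information component (BCPNN) with lower credibility bound
#'
#' `IC = log2[ a*N / ((a+b)(a+c)) ]`, the log2 ratio of the observed joint
#' reporting rate to its expectation under independence. Two variants of the
#' lower bound are provided:
#'
#' * `"delta"` (default): the delta-method standard deviation of IC on the
#'   log2 scale, `sd = sqrt(1/a - 1/(a+b) - 1/(a+c) + 1/N) / ln 2`, with
#'   `IC025 = IC - 1.96 sd`. For a rare term in a large corpus this
#'   approaches `1.96 sqrt(1/a)/ln 2`.
#' * `"gamma"`: a closed-form Bayesian bound — with expected count
#'   `E = (a+b)(a+c)/N`, the observed/expected ratio gets a
#'   Gamma(a + 1/2, E + 1/2) posterior and
#'   `IC025 = log2 q0.025[Gamma]`, with `IC = log2[(a+1/2)/(E+1/2)]`.
#'
#' @inheritParams compute_ror
#' @param variant `"delta"` or `"gamma"`.
#' @return data frame `ic`, `ic025` (bits).
#' @export
compute_ic <- function(a, b, c, d, variant = c("delta", "gamma"),
                       haldane = FALSE) {
  variant <- match.arg(variant)
  p <- .prep_cells(a, b, c, d, haldane)
  a <- p$a; b <- p$b; c <- p$c; d <- p$d
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  if (variant == "delta") {
    ic <- log2(a / E)
    v <- pmax(1 / a - 1 / (a + b) - 1 / (a + c) + 1 / N, 0)
    ic025 <- ic - 1.96 * sqrt(v) / log(2)
  } else {
    ic <- log2((a + 0.5) / (E + 0.5))
    ic025 <- log2(stats::qgamma(0.025, shape = a + 0.5, rate = E + 0.5))
  }
  out <- data.frame(ic = ic, ic025 = ic025)
  out[p$undef, ] <- NA_real_
  out
}

#' Fit the two-component gamma-Poisson (GPS) prior
#'
#' Maximum-likelihood fit of DuMouchel's mixture prior for observed counts
#' `a` with independence expectations `E`: the relative reporting rate
#' `lambda` is a priori `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2,
#' beta2)` (shape/rate), so marginally `a` is a mixture of negative
#' binomials. The five hyperparameters are estimated across the whole table
#' collection; fewer than `min_tables` pairs leave them unidentifiable and
#' the fit refuses.
#'
#' @param a integer vector of observed counts across tables.
#' @param E numeric vector of expected counts, same length.
#' @param min_tables minimum number of tables required (default 50).
#' @return list `alpha1`, `beta1`, `alpha2`, `beta2`, `w`, `loglik`,
#'   `convergence`.
#' @export
fit_gps_prior <- function(a, E, min_tables = 50L) {
  stopifnot(length(a) == length(E))
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < min_tables) {
    stop("gamma-Poisson shrinkage needs at least ", min_tables,
         " drug-term tables; got ", length(a),
         " (hyperparameters unidentifiable)")
  }
  nll <- function(par) {
    a1 <- exp(par[1L]); b1 <- exp(par[2L])
    a2 <- exp(par[3L]); b2 <- exp(par[4L])
    w <- stats::plogis(par[5L])
    f1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E))
    f2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E))
    -sum(log(pmax(w * f1 + (1 - w) * f2, 1e-300)))
  }
  init <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  list(alpha1 = exp(fit$par[1L]), beta1 = exp(fit$par[2L]),
       alpha2 = exp(fit$par[3L]), beta2 = exp(fit$par[4L]),
       w = stats::plogis(fit$par[5L]),
       loglik = -fit$value, convergence = fit$convergence)
}

# Posterior EBGM and 5th percentile for one (a, E) pair under a fitted GPS
# prior. The posterior is again a two-gamma mixture with updated weights.
.gps_posterior <- function(a, E, prior) {
  f1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E))
  f2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E))
  q <- prior$w * f1 / pmax(prior$w * f1 + (1 - prior$w) * f2, 1e-300)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  eblog <- q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2))
  ebgm <- exp(eblog)
  cdf <- function(x) q * stats::pgamma(x, s1, r1) +
    (1 - q) * stats::pgamma(x, s2, r2)
  lo <- min(stats::qgamma(0.01, s1, r1), stats::qgamma(0.01, s2, r2))
  hi <- max(stats::qgamma(0.99, s1, r1), stats::qgamma(0.99, s2, r2))
  ebgm05 <- stats::uniroot(function(x) cdf(x) - 0.05, lower = lo * 0.5,
                           upper = hi * 2, extendInt = "yes",
                           tol = 1e-9)$root
  c(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Empirical-Bayes geometric mean (MGPS family)
#'
#' Two modes:
#'
#' * `"simplified"`: the raw observed/expected relative reporting ratio,
#'   `EBGM = a*N / ((a+b)(a+c))` (identically `2^IC`), with a one-sided
#'   lower bound `EBGM05 = exp(ln EBGM - z * sqrt(1/a + 1/b + 1/c + 1/d))`,
#'   `z = 1.645` by default (1.96 is a common published alternative and can
#'   be passed instead).
#' * `"shrinkage"`: DuMouchel's gamma-Poisson shrinker. The mixture prior is
#'   fitted across the full table collection (see [fit_gps_prior()]), and
#'   for each table `EBGM = exp E[ln lambda | a]` with `EBGM05` the
#'   posterior 5th percentile. Shrinkage pulls small-count cells toward 1.
#'
#' @inheritParams compute_ror
#' @param mode `"simplified"` or `"shrinkage"`.
#' @param z lower-bound normal quantile for simplified mode.
#' @param prior optional pre-fitted GPS prior (list from [fit_gps_prior()]);
#'   fitted from `a`, `b`, `c`, `d` when absent in shrinkage mode.
#' @return data frame `ebgm`, `ebgm05`.
#' @export
compute_ebgm <- function(a, b, c, d, mode = c("simplified", "shrinkage"),
                         z = 1.645, haldane = FALSE, prior = NULL) {
  mode <- match.arg(mode)
  p <- .prep_cells(a, b, c, d, haldane)
  a2 <- p$a; b2 <- p$b; c2 <- p$c; d2 <- p$d
  N <- a2 + b2 + c2 + d2
  E <- (a2 + b2) * (a2 + c2) / N
  if (mode == "simplified") {
    ebgm <- a2 / E
    se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
    out <- data.frame(ebgm = ebgm, ebgm05 = exp(log(ebgm) - z * se))
  } else {
    if (is.null(prior)) prior <- fit_gps_prior(a, E)
    post <- t(vapply(seq_along(a), function(i) .gps_posterior(a[i], E[i], prior),
                     c(ebgm = 0, ebgm05 = 0)))
    out <- as.data.frame(post)
  }
  out[p$undef, ] <- NA_real_
  out
}

#' Default signal-detection thresholds
#'
#' The classical criteria: ROR requires at least `min_a` cases and a lower
#' CI bound above 1; PRR requires at least `min_a` cases, `PRR >= 2` and
#' `chi2 >= 4`; BCPNN requires `IC025 > 0`; MGPS requires `EBGM05 > 2`.
#'
#' @param min_a minimum case count for the ROR and PRR criteria (default 3).
#' @param ror_lower_gt,prr_ge,chi2_ge,ic025_gt,ebgm05_gt cutoffs.
#' @return list of thresholds.
#' @export
default_thresholds <- function(min_a = 3L, ror_lower_gt = 1, prr_ge = 2,
                               chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  list(min_a = min_a, ror_lower_gt = ror_lower_gt, prr_ge = prr_ge,
       chi2_ge = chi2_ge, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt)
}

#' Read thresholds from a YAML config file
#'
#' Keys mirror [default_thresholds()]; unknown keys are rejected, missing
#' keys keep their defaults.
#'
#' @param path YAML file path.
#' @return threshold list.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_thresholds()
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra)) stop("unknown threshold key(s): ", paste(extra, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' Apply the four significance criteria and the label classification
#'
#' @param est data frame with columns `term`, `a`, `ror_low`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (as produced by [signal_table()]).
#' @param thresholds list from [default_thresholds()].
#' @param label_terms character vector of terms on the product label;
#'   matching is case-insensitive exact-term matching after whitespace
#'   normalization.
#' @return `est` with added logical columns `ror_sig`, `prr_sig`, `ic_sig`,
#'   `ebgm_sig`, `all_four`, `expected`. `NA` estimates never flag.
#' @export
apply_criteria <- function(est, thresholds = default_thresholds(),
                           label_terms = character(0)) {
  th <- thresholds
  sig <- function(x) !is.na(x) & x
  est$ror_sig <- sig(est$a >= th$min_a & est$ror_low > th$ror_lower_gt)
  est$prr_sig <- sig(est$a >= th$min_a & est$prr >= th$prr_ge &
                       est$chi2 >= th$chi2_ge)
  est$ic_sig <- sig(est$ic025 > th$ic025_gt)
  est$ebgm_sig <- sig(est$ebgm05 > th$ebgm05_gt)
  est$all_four <- est$ror_sig & est$prr_sig & est$ic_sig & est$ebgm_sig
  est$expected <- normalize_term(est$term) %in% normalize_term(label_terms)
  est
}

#' Full signal table for a contingency-table collection
#'
#' Computes ROR (with CI), PRR (with chi-squared), IC (with IC025) and EBGM
#' (with EBGM05) for every term, then applies the significance criteria and
#' label classification.
#'
#' @param tables data frame from [build_tables()].
#' @param thresholds list from [default_thresholds()].
#' @param label_terms character vector of label (expected) terms.
#' @param ebgm_mode,ic_variant,haldane passed to the estimators.
#' @param ebgm_z lower-bound quantile for simplified EBGM05.
#' @return `tables` with every estimate, bound and flag appended, ordered by
#'   decreasing `a`.
#' @export
signal_table <- function(tables, thresholds = default_thresholds(),
                         label_terms = character(0),
                         ebgm_mode = c("simplified", "shrinkage"),
                         ic_variant = c("delta", "gamma"),
                         ebgm_z = 1.645, haldane = FALSE) {
  ebgm_mode <- match.arg(ebgm_mode)
  ic_variant <- match.arg(ic_variant)
  est <- cbind(
    tables,
    compute_ror(tables$a, tables$b, tables$c, tables$d, haldane = haldane),
    compute_prr(tables$a, tables$b, tables$c, tables$d, haldane = haldane),
    compute_ic(tables$a, tables$b, tables$c, tables$d, variant = ic_variant,
               haldane = haldane),
    compute_ebgm(tables$a, tables$b, tables$c, tables$d, mode = ebgm_mode,
                 z = ebgm_z, haldane = haldane)
  )
  est <- apply_criteria(est, thresholds, label_terms)
  est <- est[order(-est$a, est$term), , drop = FALSE]
  rownames(est) <- NULL
  est
}
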