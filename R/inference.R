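# Inference on the two mis-segregation rates from scored progeny counts.
#
# The observed data of one cross collapse to (n_x0, n_xxy, n_other) and are
# multinomial with class probabilities, conditional on survival (default
# sperm and viability):
#   Z      = 1 - d/2 - l/8
#   p_x0   = (d/4 + l/8) / Z
#   p_xxy  = (d/4) / Z
#   p_other = 1 - p_x0 - p_xxy
# Both rates are exactly identifiable from the two observed frequencies
# f0 = n_x0/N and f2 = n_xxy/N; the MLE is available in closed form because
# the fitted probabilities can match the empirical frequencies exactly
# whenever f0 >= f2.

# Multinomial log-likelihood kernel, vectorized over (d, l); 0*log(0) = 0,
# impossible observations give -Inf.
ll_kernel <- function(d, l, n0, n2, nr) {
  z  <- 1 - d / 2 - l / 8
  p0 <- (d / 4 + l / 8) / z
  p2 <- (d / 4) / z
  pr <- 1 - p0 - p2
  term <- function(n, p) {
    if (n == 0) return(rep(0, length(p)))
    ifelse(p > 0, n * log(p), -Inf)
  }
  term(n0, p0) + term(n2, p2) + term(nr, pr)
}

multinom_const <- function(n0, n2, nr) {
  lgamma(n0 + n2 + nr + 1) - lgamma(n0 + 1) - lgamma(n2 + 1) - lgamma(nr + 1)
}

#' Multinomial log-likelihood of progeny counts
#'
#' Log-probability of the observed `(n_x0, n_xxy, n_other)` counts under the
#' forward model at the given rates, with classes collapsed to X0 son / XXY
#' daughter / other. Returns `-Inf` when a class with zero model probability
#' has a nonzero count (e.g. any exceptional progeny at `d = l = 0`).
#'
#' @param params a [segregation_params()] object.
#' @param counts a [cross_counts()] object.
#' @param sperm,viability model components; fitting holds these at defaults.
#' @return The log-likelihood (finite or `-Inf`), including the multinomial
#'   coefficient.
#' @export
log_likelihood <- function(params, counts, sperm = sperm_model(),
                           viability = viability_model()) {
  stopifnot(inherits(params, "segregation_params"),
            inherits(counts, "cross_counts"))
  pr <- progeny_class_probabilities(params, sperm, viability)
  p <- c(pr$f_x0_son, pr$f_xxy_daughter,
         pr$f_normal_daughter + pr$f_normal_son)
  n <- c(counts$n_x0, counts$n_xxy, counts$n_other)
  ll <- sum(ifelse(n == 0, 0, ifelse(p > 0, n * log(p), -Inf)))
  ll + multinom_const(counts$n_x0, counts$n_xxy, counts$n_other)
}

# Softmax parametrization of the open simplex {d > 0, l > 0, d + l < 1},
# used only for the interior re-maximization check.
softmax_dl <- function(ab) {
  e <- exp(c(ab, 0))
  e <- e / sum(e)
  c(d = e[1], l = e[2])
}

#' Maximum-likelihood fit of the mis-segregation rates
#'
#' Closed-form inverse of the forward model: with `f0 = n_x0/N` and
#' `f2 = n_xxy/N`,
#' `d_hat = 4 f2 / (1 + f0 + f2)` and `l_hat = 8 (f0 - f2) / (1 + f0 + f2)`.
#' When `f0 < f2` (more XXY daughters than X0 sons) the loss rate is clamped
#' to zero with a boundary flag, and `d_hat` maximizes the constrained
#' likelihood in closed form. The closed form is re-checked by numeric
#' maximization; the two must agree within 1e-8 in the interior.
#'
#' @param counts a [cross_counts()] object.
#' @return An object of class `mle_fit` with fields `d_hat`, `l_hat`,
#'   `loglik`, `at_boundary` (named logical for `d` and `l`), `numeric_gap`
#'   (largest closed-form vs numeric discrepancy), `counts`, and `ci_d`,
#'   `ci_l` left `NULL` until [confidence_intervals()] is applied.
#' @examples
#' fit_mle(cross_counts("none", 99, 1283, 146, 106))  # d ~ 0.276, l ~ 0.209
#' @export
fit_mle <- function(counts) {
  stopifnot(inherits(counts, "cross_counts"))
  n0 <- counts$n_x0; n2 <- counts$n_xxy; nr <- counts$n_other
  N <- counts$total_progeny
  if (N == 0) abort_validation("cannot fit: cross '%s' has zero progeny", counts$label)
  f0 <- n0 / N; f2 <- n2 / N
  at_boundary <- c(d = FALSE, l = FALSE)
  if (f0 >= f2) {
    denom <- 1 + f0 + f2
    d_hat <- 4 * f2 / denom
    l_hat <- 8 * (f0 - f2) / denom
  } else {
    r <- (n0 + n2) / N
    d_hat <- 2 * r / (1 + r)
    l_hat <- 0
    at_boundary["l"] <- TRUE
  }
  if (d_hat + l_hat > 1 + 1e-12) {
    abort_validation("inconsistent counts: implied rates d + l = %.4f exceed 1",
                     d_hat + l_hat)
  }
  if (d_hat == 0) at_boundary["d"] <- TRUE
  if (l_hat == 0) at_boundary["l"] <- TRUE

  numeric_gap <- NA_real_
  if (!any(at_boundary) && d_hat + l_hat < 1 - 1e-9) {
    # interior: numeric re-maximization must land on the closed form
    s <- 1 - d_hat - l_hat
    start <- c(log(d_hat / s), log(l_hat / s))
    opt <- stats::optim(start,
                        function(ab) {
                          p <- softmax_dl(ab)
                          -ll_kernel(p["d"], p["l"], n0, n2, nr)
                        },
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    num <- softmax_dl(opt$par)
    numeric_gap <- max(abs(num - c(d_hat, l_hat)))
    if (numeric_gap > 1e-8) {
      warn_nullox("closed-form and numeric optimum differ by %.3g", numeric_gap)
    }
  } else if (at_boundary["l"] && !at_boundary["d"]) {
    # constrained re-maximization along the l = 0 edge
    opt <- stats::optimize(function(d) ll_kernel(d, 0, n0, n2, nr),
                           interval = c(1e-12, 1 - 1e-12),
                           maximum = TRUE, tol = 1e-12)
    numeric_gap <- abs(opt$maximum - d_hat)
  }

  structure(
    list(d_hat = d_hat, l_hat = l_hat,
         loglik = ll_kernel(d_hat, l_hat, n0, n2, nr) +
           multinom_const(n0, n2, nr),
         ci_d = NULL, ci_l = NULL, ci_level = NA_real_,
         ci_method = NA_character_,
         at_boundary = at_boundary, numeric_gap = numeric_gap,
         counts = counts),
    class = "mle_fit")
}

#' @export
print.mle_fit <- function(x, ...) {
  cat(sprintf("<mle_fit> %s: d_hat = %.4f%s, l_hat = %.4f%s, loglik = %.3f\n",
              x$counts$label,
              x$d_hat, if (x$at_boundary["d"]) " (boundary)" else "",
              x$l_hat, if (x$at_boundary["l"]) " (boundary)" else "",
              x$loglik))
  if (!is.null(x$ci_d)) {
    cat(sprintf("  %g%% %s CI: d in [%.4f, %.4f], l in [%.4f, %.4f]\n",
                100 * x$ci_level, x$ci_method,
                x$ci_d[1], x$ci_d[2], x$ci_l[1], x$ci_l[2]))
  }
  invisible(x)
}

# Profile log-likelihood of d (maximized over l) and of l (over d).
profile_ll_d <- function(d, n0, n2, nr) {
  hi <- 1 - d
  if (hi < 1e-10) return(ll_kernel(d, 0, n0, n2, nr))
  opt <- stats::optimize(function(l) ll_kernel(d, l, n0, n2, nr),
                         interval = c(0, hi), maximum = TRUE, tol = 1e-10)
  max(opt$objective, ll_kernel(d, 0, n0, n2, nr),
      ll_kernel(d, hi, n0, n2, nr))
}

profile_ll_l <- function(l, n0, n2, nr) {
  hi <- 1 - l
  if (hi < 1e-10) return(ll_kernel(0, l, n0, n2, nr))
  opt <- stats::optimize(function(d) ll_kernel(d, l, n0, n2, nr),
                         interval = c(0, hi), maximum = TRUE, tol = 1e-10)
  max(opt$objective, ll_kernel(0, l, n0, n2, nr),
      ll_kernel(hi, l, n0, n2, nr))
}

profile_root <- function(pll, hat, target, side) {
  h <- function(x) pll(x) - target
  eps <- 1e-9
  if (side == "lower") {
    if (hat <= eps || h(eps) >= 0) return(0)
    stats::uniroot(h, c(eps, hat), tol = 1e-9)$root
  } else {
    hi <- 1 - eps
    if (hat >= hi || h(hi) >= 0) return(1)
    stats::uniroot(h, c(hat, hi), tol = 1e-9)$root
  }
}

#' Confidence intervals for fitted mis-segregation rates
#'
#' Profile-likelihood intervals invert the chi-square(1) deviance cutoff on
#' each rate, profiling out the other; they are deterministic and the
#' default. Parametric-bootstrap percentile intervals resample progeny
#' counts from the fitted model and require an explicit seed.
#' Boundary-clamped rates yield one-sided intervals with lower bound 0.
#'
#' @param fit an [fit_mle()] result.
#' @param counts the [cross_counts()] the fit was computed from; defaults to
#'   the counts stored in the fit.
#' @param level confidence level in (0, 1).
#' @param method `"profile"` or `"bootstrap"`.
#' @param seed integer seed, mandatory for the bootstrap.
#' @param n_boot number of bootstrap resamples (>= 1000 recommended).
#' @return The fit with `ci_d`, `ci_l`, `ci_level`, `ci_method` filled in.
#' @export
confidence_intervals <- function(fit, counts = fit$counts, level = 0.95,
                                 method = c("profile", "bootstrap"),
                                 seed = NULL, n_boot = 1000) {
  stopifnot(inherits(fit, "mle_fit"), inherits(counts, "cross_counts"))
  method <- match.arg(method)
  if (!is_probability(level) || level <= 0 || level >= 1) {
    abort_domain("confidence level must be in (0, 1), got %s", format(level))
  }
  n0 <- counts$n_x0; n2 <- counts$n_xxy; nr <- counts$n_other

  if (method == "profile") {
    cutoff <- stats::qchisq(level, df = 1)
    llhat <- ll_kernel(fit$d_hat, fit$l_hat, n0, n2, nr)
    target <- llhat - cutoff / 2
    pd <- function(d) profile_ll_d(d, n0, n2, nr)
    pl <- function(l) profile_ll_l(l, n0, n2, nr)
    ci_d <- c(lower = if (fit$at_boundary["d"]) 0
                      else profile_root(pd, fit$d_hat, target, "lower"),
              upper = profile_root(pd, fit$d_hat, target, "upper"))
    ci_l <- c(lower = if (fit$at_boundary["l"]) 0
                      else profile_root(pl, fit$l_hat, target, "lower"),
              upper = profile_root(pl, fit$l_hat, target, "upper"))
  } else {
    if (is.null(seed)) abort_config("bootstrap confidence intervals require an explicit seed")
    if (n_boot < 2) abort_config("n_boot must be at least 2")
    set.seed(as.integer(seed))
    z <- 1 - fit$d_hat / 2 - fit$l_hat / 8
    p <- c((fit$d_hat / 4 + fit$l_hat / 8) / z, (fit$d_hat / 4) / z, NA)
    p[3] <- 1 - p[1] - p[2]
    N <- counts$total_progeny
    draws <- stats::rmultinom(n_boot, N, p)
    f0 <- draws[1, ] / N
    f2 <- draws[2, ] / N
    denom <- 1 + f0 + f2
    d_b <- 4 * f2 / denom
    l_b <- 8 * (f0 - f2) / denom
    clamp <- f0 < f2
    if (any(clamp)) {
      r <- (draws[1, clamp] + draws[2, clamp]) / N
      d_b[clamp] <- 2 * r / (1 + r)
      l_b[clamp] <- 0
    }
    a <- (1 - level) / 2
    ci_d <- if (fit$at_boundary["d"]) {
      c(lower = 0, upper = unname(stats::quantile(d_b, level)))
    } else {
      stats::setNames(unname(stats::quantile(d_b, c(a, 1 - a))),
                      c("lower", "upper"))
    }
    ci_l <- if (fit$at_boundary["l"]) {
      c(lower = 0, upper = unname(stats::quantile(l_b, level)))
    } else {
      stats::setNames(unname(stats::quantile(l_b, c(a, 1 - a))),
                      c("lower", "upper"))
    }
  }
  fit$ci_d <- ci_d
  fit$ci_l <- ci_l
  fit$ci_level <- level
  fit$ci_method <- method
  fit
}

# Maximize ll(test; d, l1) + ll(control; d, l2) over the shared-d model.
# Parametrized as (d, t1, t2) with l_i = t_i * (1 - d) so the box
# [eps, 1-eps] x [0, 1-eps]^2 covers the feasible region.
fit_shared_d <- function(test, control, d_start, t_start) {
  nt <- c(test$n_x0, test$n_xxy, test$n_other)
  nc <- c(control$n_x0, control$n_xxy, control$n_other)
  obj <- function(par) {
    d <- par[1]
    l1 <- par[2] * (1 - d)
    l2 <- par[3] * (1 - d)
    -(ll_kernel(d, l1, nt[1], nt[2], nt[3]) +
        ll_kernel(d, l2, nc[1], nc[2], nc[3]))
  }
  eps <- 1e-9
  start <- pmin(pmax(c(d_start, t_start), eps), 1 - 1e-6)
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(eps, 0, 0),
                      upper = rep(1 - eps, 3),
                      control = list(factr = 1e4, maxit = 500))
  list(loglik = -opt$value +
         multinom_const(nt[1], nt[2], nt[3]) +
         multinom_const(nc[1], nc[2], nc[3]),
       d = opt$par[1],
       l_test = opt$par[2] * (1 - opt$par[1]),
       l_control = opt$par[3] * (1 - opt$par[1]),
       convergence = opt$convergence)
}

#' Likelihood-ratio comparison of two crosses
#'
#' Tests whether a cross and a control share the same mis-segregation rates.
#' The primary test compares the shared-(d, l) model against separate rates
#' per cross (2 df). Because the scientific question is specifically whether
#' the chromosome-loss rate increased, an l-only test is also reported:
#' shared d with separate l against fully separate rates (1 df).
#'
#' @param test,control [cross_counts()] objects.
#' @return An object of class `lrt_comparison`: fits for both crosses and
#'   the pooled (shared) model, `lrt` (`stat`, `df = 2`, `p_value`),
#'   `lrt_l_only` (`stat`, `df = 1`, `p_value`), and `flagged` (`TRUE` with
#'   p values unset when a component fit is degenerate).
#' @examples
#' none <- cross_counts("none", 99, 1283, 146, 106)
#' at2  <- cross_counts("AtSPO11-2", 71, 1187, 178, 88)
#' compare_to_control(at2, none)$lrt_l_only$p_value
#' @export
compare_to_control <- function(test, control) {
  stopifnot(inherits(test, "cross_counts"), inherits(control, "cross_counts"))
  res <- tryCatch({
    ft <- fit_mle(test)
    fc <- fit_mle(control)
    pooled <- cross_counts("pooled",
                           test$mothers + control$mothers,
                           test$total_progeny + control$total_progeny,
                           test$n_x0 + control$n_x0,
                           test$n_xxy + control$n_xxy)
    fp <- fit_mle(pooled)  # shared-(d, l) MLE == pooled-counts MLE
    shared_params <- segregation_params(fp$d_hat, fp$l_hat)
    ll_sep <- ft$loglik + fc$loglik
    ll_shared <- log_likelihood(shared_params, test) +
      log_likelihood(shared_params, control)
    stat2 <- max(0, 2 * (ll_sep - ll_shared))

    # l-only test: null = fully shared rates, alternative = shared d with
    # separate loss rates (1 df)
    d0 <- fp$d_hat
    sd_fit <- fit_shared_d(test, control, d0,
                           c(ft$l_hat, fc$l_hat) / max(1 - d0, 1e-6))
    stat1 <- max(0, 2 * (sd_fit$loglik - ll_shared))

    list(fit_test = ft, fit_control = fc, fit_shared = fp,
         fit_shared_d = sd_fit,
         lrt = list(stat = stat2, df = 2L,
                    p_value = stats::pchisq(stat2, 2, lower.tail = FALSE)),
         lrt_l_only = list(stat = stat1, df = 1L,
                           p_value = stats::pchisq(stat1, 1, lower.tail = FALSE)),
         flagged = FALSE)
  }, nullox_error = function(e) {
    warn_nullox("degenerate fit in compare_to_control: %s", conditionMessage(e))
    list(fit_test = NULL, fit_control = NULL, fit_shared = NULL,
         fit_shared_d = NULL,
         lrt = list(stat = NA_real_, df = 2L, p_value = NA_real_),
         lrt_l_only = list(stat = NA_real_, df = 1L, p_value = NA_real_),
         flagged = TRUE)
  })
  structure(res, class = "lrt_comparison")
}

#' @export
print.lrt_comparison <- function(x, ...) {
  if (x$flagged) {
    cat("<lrt_comparison> degenerate fit; p values unset\n")
    return(invisible(x))
  }
  cat(sprintf("<lrt_comparison> %s vs %s\n",
              x$fit_test$counts$label, x$fit_control$counts$label))
  cat(sprintf("  shared (d,l) LRT: stat = %.4g, df = 2, P = %.3g\n",
              x$lrt$stat, x$lrt$p_value))
  cat(sprintf("  l-only LRT (shared d): stat = %.4g, df = 1, P = %.3g\n",
              x$lrt_l_only$stat, x$lrt_l_only$p_value))
  invisible(x)
}
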