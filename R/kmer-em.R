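# log(1 - exp(-x)) without underflow
.log1mexp <- function(x) {
  ifelse(x > 30, 0, log1p(-exp(-x)))
}

# Zero-truncated log pmfs over bins 1..M plus a pooled tail bin
# (multiplicity > M). Poisson block: means lambda, 2*lambda and
# 2*lambda*c for repeat copies c = 2..(1+R); NB block: the error class.
.poisLogPmf <- function(M, lambda, n_repeat) {
  m <- seq_len(M)
  means <- lambda * c(1, 2 * c(1, seq_len(n_repeat) + 1))
  logf <- matrix(-745, M + 1L, length(means))
  for (j in seq_along(means)) {
    mu <- means[j]
    tr <- .log1mexp(mu)
    logf[m, j] <- stats::dpois(m, mu, log = TRUE) - tr
    logf[M + 1L, j] <- stats::ppois(M, mu, lower.tail = FALSE,
                                    log.p = TRUE) - tr
  }
  logf[!is.finite(logf)] <- -745
  logf
}

.nbLogPmf <- function(M, mu_e, size_e) {
  lognb0 <- stats::dnbinom(0, mu = mu_e, size = size_e, log = TRUE)
  trunc_nb <- log1p(-exp(lognb0))
  v <- c(stats::dnbinom(seq_len(M), mu = mu_e, size = size_e, log = TRUE),
         stats::pnbinom(M, mu = mu_e, size = size_e,
                        lower.tail = FALSE, log.p = TRUE)) - trunc_nb
  v[!is.finite(v)] <- -745
  v
}

.componentLogPmf <- function(M, lambda, mu_e, size_e, n_repeat) {
  cbind(.nbLogPmf(M, mu_e, size_e), .poisLogPmf(M, lambda, n_repeat))
}

.emLogLik <- function(cnt, logf, logw) {
  lw <- sweep(logf, 2, logw, "+")
  mx <- apply(lw, 1, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  list(ll = sum(cnt * lse), resp = exp(lw - lse))
}

# One full EM run from a given lambda start. Generalized M-steps (1-D
# optimize for the shared coverage, Nelder-Mead for the NB) are accepted
# only when they improve their expected complete-data objective, so the
# log-likelihood trace is non-decreasing.
.emRun <- function(cnt, M, lambda, mu_e, size_e, w, n_repeat, tol,
                   max_iter) {
  trace <- numeric(0)
  logf <- .componentLogPmf(M, lambda, mu_e, size_e, n_repeat)
  for (it in seq_len(max_iter)) {
    e <- .emLogLik(cnt, logf, log(w))
    trace <- c(trace, e$ll)
    w <- colSums(cnt * e$resp) / sum(cnt)
    w <- pmax(w, 1e-12); w <- w / sum(w)
    # shared coverage parameter: Poisson components only
    wresp_pois <- cnt * e$resp[, -1, drop = FALSE]
    poisQ <- function(lam) sum(wresp_pois * .poisLogPmf(M, lam, n_repeat))
    cur <- poisQ(lambda)
    opt <- stats::optimize(poisQ, interval = c(lambda / 1.6, lambda * 1.6),
                           maximum = TRUE)
    if (opt$objective > cur) lambda <- opt$maximum
    # error NB parameters
    if (w[1] > 1e-10) {
      wresp_nb <- cnt * e$resp[, 1]
      nbQ <- function(par)
        -sum(wresp_nb * .nbLogPmf(M, exp(par[1]), exp(par[2])))
      cur_nb <- nbQ(log(c(mu_e, size_e)))
      on <- stats::optim(log(c(mu_e, size_e)), nbQ,
                         method = "Nelder-Mead",
                         control = list(maxit = 200))
      if (on$value < cur_nb) {
        mu_e <- exp(on$par[1]); size_e <- exp(on$par[2])
      }
    }
    logf <- .componentLogPmf(M, lambda, mu_e, size_e, n_repeat)
    e2 <- .emLogLik(cnt, logf, log(w))
    if (it > 1 && abs(e2$ll - e$ll) < tol * (abs(e$ll) + 1)) {
      return(list(lambda = lambda, mu_e = mu_e, size_e = size_e, w = w,
                  ll = e2$ll, resp = e2$resp, n_iter = it,
                  converged = TRUE, trace = c(trace, e2$ll)))
    }
  }
  list(lambda = lambda, mu_e = mu_e, size_e = size_e, w = w,
       ll = trace[length(trace)], resp = .emLogLik(cnt, logf, log(w))$resp,
       n_iter = max_iter, converged = FALSE, trace = trace)
}

#' Fit the k-mer spectrum mixture by expectation-maximization
#'
#' Fits a mixture of a zero-truncated negative binomial (sequencing-error
#' k-mers) and zero-truncated Poisson components for the haploid (mean
#' lambda), diploid (2*lambda) and repeat (2*lambda*c, c = 2..1+n_repeat_classes)
#' k-mer classes to a multiplicity histogram, on the categorical likelihood
#' of multiplicities weighted by counts. The diploid and repeat means are
#' hard-constrained to multiples of the single coverage parameter lambda.
#' Multiplicities above ten times the initial peak estimate are pooled into
#' one tail bin. Initialization is deterministic (error moments from the
#' sub-peak region, lambda from the highest local maximum above multiplicity
#' 4); because a unimodal spectrum is equally well explained by the haploid
#' or the diploid component, EM is started from both interpretations and the
#' higher-likelihood fit kept, preferring the diploid reading on ties.
#'
#' @param hist a [KmerHistogram-class] with at least 5 distinct
#'   multiplicities.
#' @param n_repeat_classes repeat copy classes (default 4).
#' @param tol relative log-likelihood convergence threshold (default 1e-8).
#' @param max_iter EM iteration cap (default 2000).
#' @param init optional list overriding the initialization: any of
#'   \code{lambda}, \code{error_mean}, \code{error_dispersion},
#'   \code{weights} (length 3 + n_repeat_classes). When \code{lambda} is
#'   given only that single start is run.
#' @return a [SpectrumFit-class].
#' @export
fitSpectrum <- function(hist, n_repeat_classes = 4, tol = 1e-8,
                        max_iter = 2000, init = NULL) {
  m <- hist@multiplicity
  cnt_in <- hist@count
  if (length(m) < 2) stop("degenerate histogram: need several multiplicities")
  if (length(m) < 5) stop("histogram has fewer than 5 distinct multiplicities")
  if (sum(cnt_in) <= 0) stop("histogram has zero total count")
  # peak finding on the dense series, above multiplicity 4
  dense <- numeric(max(m))
  dense[m] <- cnt_in
  peak <- NA_integer_
  if (max(m) > 5) {
    region <- 5:max(m)
    cand <- region[which(diff(sign(diff(c(0, dense[region], 0)))) == -2)]
    if (length(cand)) peak <- cand[which.max(dense[cand])]
  }
  if (is.na(peak)) peak <- max(5, round(sum(m * cnt_in) / sum(cnt_in)))
  M <- as.integer(min(max(m), max(10L * peak, 30L)))
  cnt <- numeric(M + 1L)
  cnt[seq_len(M)] <- dense[seq_len(M)]
  cnt[M + 1L] <- sum(cnt_in[m > M])
  tail_mass <- sum((m * cnt_in)[m > M])
  R <- as.integer(n_repeat_classes)
  J <- 3L + R

  initFor <- function(lam0) {
    err_reg <- m < pmax(2, lam0 / 2)
    if (any(err_reg) && sum(cnt_in[err_reg]) > 0) {
      mu_e <- sum((m * cnt_in)[err_reg]) / sum(cnt_in[err_reg])
      v <- sum(cnt_in[err_reg] * (m[err_reg] - mu_e)^2) /
        sum(cnt_in[err_reg])
      size_e <- if (v > mu_e) min(100, max(0.05, mu_e^2 / (v - mu_e))) else 1
    } else { mu_e <- 1; size_e <- 1 }
    tot <- sum(cnt_in)
    w <- c(sum(cnt_in[err_reg]),
           sum(cnt_in[m >= lam0 / 2 & m < 1.5 * lam0]),
           sum(cnt_in[m >= 1.5 * lam0 & m < 3 * lam0]),
           sum(cnt_in[m >= 3 * lam0]) * 0.5^seq_len(R) /
             sum(0.5^seq_len(R))) / tot
    w <- pmax(w, 1e-4); w <- w / sum(w)
    list(lambda = lam0, mu_e = mu_e, size_e = size_e, w = w)
  }
  override <- function(ini) {
    if (!is.null(init$error_mean)) ini$mu_e <- init$error_mean
    if (!is.null(init$error_dispersion)) ini$size_e <- init$error_dispersion
    if (!is.null(init$weights)) ini$w <- init$weights / sum(init$weights)
    ini
  }
  starts <- if (!is.null(init$lambda)) list(override(initFor(init$lambda)))
            else list(override(initFor(peak)), override(initFor(peak / 2)))
  runs <- lapply(starts, function(s)
    .emRun(cnt, M, s$lambda, s$mu_e, s$size_e, s$w, R, tol, max_iter))
  lls <- vapply(runs, `[[`, numeric(1), "ll")
  # A spectrum often admits near-equal-likelihood readings (e.g. a single
  # peak as haploid at lambda or diploid at lambda/2; a het-dominant double
  # peak as haploid+diploid or diploid+repeat). Among fits within likelihood
  # tolerance, prefer the most parsimonious genome reading: least total
  # repeat weight, then largest diploid weight.
  tied <- which(lls >= max(lls) - 1e-6 * (abs(max(lls)) + 1))
  if (length(tied) > 1) {
    w_rep <- vapply(tied, function(i) sum(runs[[i]]$w[-(1:3)]), numeric(1))
    tied <- tied[w_rep <= min(w_rep) + 1e-6]
    if (length(tied) > 1) {
      w_dip <- vapply(tied, function(i) runs[[i]]$w[3], numeric(1))
      tied <- tied[which.max(w_dip)]
    }
  }
  best <- runs[[tied[1]]]
  wn <- c("error", "haploid", "diploid", paste0("repeat", seq_len(R) + 1L))
  names(best$w) <- wn
  colnames(best$resp) <- wn
  new("SpectrumFit", lambda_hap = best$lambda, error_mean = best$mu_e,
      error_dispersion = best$size_e, weights = best$w,
      n_repeat_classes = R, loglik = best$ll, loglik_trace = best$trace,
      n_iter = best$n_iter, converged = best$converged,
      posterior = best$resp, multiplicity = c(seq_len(M), Inf),
      count = cnt, tail_mass = tail_mass, k = hist@k)
}

#' Genome size from a fitted k-mer spectrum
#'
#' G = (k-mer observations attributed to non-error components) / (2*lambda):
#' the total sequenced k-mer mass sum(m * count(m) * P(non-error | m)),
#' divided by the diploid coverage. The pooled tail bin contributes its exact
#' mass weighted by its posterior.
#'
#' @param fit a [SpectrumFit-class].
#' @return estimated haploid genome size in bp.
#' @export
estimateGenomeSize <- function(fit) {
  if (fit@lambda_hap <= 0) stop("non-positive coverage estimate")
  if (!fit@converged) warning("EM did not converge; estimate may be poor")
  M <- length(fit@count) - 1L
  mass <- c(seq_len(M) * fit@count[seq_len(M)], fit@tail_mass)
  p_nonerr <- 1 - fit@posterior[, "error"]
  sum(mass * p_nonerr) / (2 * fit@lambda_hap)
}

#' Heterozygous-site count from a fitted k-mer spectrum
#'
#' n_het = (distinct k-mers attributed to the haploid component) / divisor,
#' with divisor 2k by default: an isolated heterozygous site creates k novel
#' k-mers on each of the two haplotypes. The divisor is exposed because the
#' haploid-mass-to-site conversion is a modelling choice (clustered
#' heterozygosity yields fewer novel k-mers per site).
#'
#' @param fit a [SpectrumFit-class].
#' @param k k-mer length (default: the histogram's).
#' @param kmers_per_het divisor (default 2 * k).
#' @return estimated number of heterozygous sites.
#' @export
estimateHetSites <- function(fit, k = fit@k, kmers_per_het = 2 * k) {
  if (!fit@converged) warning("EM did not converge; estimate may be poor")
  sum(fit@count * fit@posterior[, "haploid"]) / kmers_per_het
}
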