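#' Bayesian circadian baseline for T_B or VO2 from day-1 recordings
#'
#' Fits, by MCMC, a two-harmonic circadian regression with Normal residuals
#' to the first 24 h of one physiological signal:
#' `y(t) = b0 + a1 cos(2 pi t / 24) + b1 sin(2 pi t / 24)
#'       + a2 cos(4 pi t / 24) + b2 sin(4 pi t / 24) + Normal(0, sigma)`.
#' Priors are weakly informative: mesor ~ Normal(signal mean, 10),
#' harmonic amplitudes ~ Normal(0, 5), sigma ~ HalfNormal(5).  The result
#' carries the per-time-of-day lower bound of the posterior predictive
#' distribution at the `(1 - ci) / 2` tail, which is the outlier bound
#' torpor calling uses: an individual time point is abnormal when its
#' observation falls below what the fitted baseline could plausibly
#' produce, hence the predictive distribution, not the narrower credible
#' band of the mean.
#'
#' @param trace data.frame with `time_h` and the signal column (`tb_c` or
#'   `vo2_ml_min`), e.g. from [genPhysio()].
#' @param signal `"tb"` or `"vo2"`.
#' @param ci credible level of the predictive band (default 0.999).
#' @param draws post-warmup draws per chain (default 1000).
#' @param warmup warmup iterations per chain (default equals `draws`).
#' @param chains number of chains (default 2).
#' @param seed integer seed.
#' @return a [BaselinePosterior-class].  A split R-hat above 1.05 on any
#'   parameter triggers a diagnostic warning but the fit is returned.
#' @export
fitBaseline <- function(trace, signal = c("tb", "vo2"), ci = 0.999,
                        draws = 1000L, warmup = draws, chains = 2L,
                        seed = 1L) {
    signal <- match.arg(signal)
    col <- if (signal == "tb") "tb_c" else "vo2_ml_min"
    day1 <- trace[trace$time_h < 24, , drop = FALSE]
    y <- day1[[col]]
    ok <- !is.na(y)
    if (!any(ok)) stop("signal ", signal, " has no day-1 data")
    t <- day1$time_h[ok]; y <- y[ok]
    if (diff(range(t)) < 12) stop("need >= 12 h of day-1 data")
    X <- .harmonicBasis(t)

    ybar <- mean(y)
    logpost <- function(th) {
        beta <- th[1:5]; sigma <- exp(th[6])
        mu <- X %*% beta
        sum(stats::dnorm(y, mu, sigma, log = TRUE)) +
            stats::dnorm(beta[1], ybar, 10, log = TRUE) +
            sum(stats::dnorm(beta[2:5], 0, 5, log = TRUE)) +
            stats::dnorm(sigma, 0, 5, log = TRUE) + th[6]  # HalfNormal + Jacobian
    }
    b0 <- stats::coef(stats::lm.fit(X, y))
    s0 <- stats::sd(y - X %*% b0)
    init <- c(b0, log(max(s0, 1e-3)))
    names(init) <- c("mesor", "a1", "b1", "a2", "b2", "log_sigma")
    post <- amSample(logpost, init, chains = chains, iter = draws,
                     warmup = warmup, seed = seed,
                     initScale = max(s0, 0.05) / 10)
    mx <- max(post@diagnostics$rhat, na.rm = TRUE)
    if (is.finite(mx) && mx > 1.05)
        warning("baseline fit for ", signal,
                ": split R-hat = ", round(mx, 3), " (> 1.05)")

    tod <- seq(0, 23.9, by = 0.1)
    Xg <- .harmonicBasis(tod)
    B <- apply(post@draws, 3, as.vector)          # draws x 6
    mu <- Xg %*% t(B[, 1:5])                      # tod x draws
    sig <- exp(B[, 6])
    alpha <- (1 - ci) / 2
    lower <- .mixtureQuantile(mu, sig, alpha)
    med <- apply(mu, 1, stats::median)
    new("BaselinePosterior", signal = signal, posterior = post,
        ci = ci, tod = tod, lower = lower, median = med)
}

.harmonicBasis <- function(t) {
    cbind(1, cos(2 * pi * t / 24), sin(2 * pi * t / 24),
          cos(4 * pi * t / 24), sin(4 * pi * t / 24))
}

#' Lower quantile of a Normal mixture, rowwise, by vectorised bisection
#' @param mu matrix (points x draws), sig vector over draws.
#' @keywords internal
.mixtureQuantile <- function(mu, sig, alpha) {
    lo <- apply(mu, 1, min) - 12 * max(sig)
    hi <- apply(mu, 1, max) + 12 * max(sig)
    for (k in 1:60) {
        mid <- (lo + hi) / 2
        Fm <- rowMeans(stats::pnorm((mid - mu) / rep(sig, each = nrow(mu))))
        below <- Fm < alpha
        lo[below] <- mid[below]
        hi[!below] <- mid[!below]
    }
    (lo + hi) / 2
}

#' Per-timepoint torpor calling against baseline predictive bounds
#'
#' A time point is labelled torpid iff every available signal lies below
#' its baseline lower predictive bound AND the point falls in the eligible
#' window of the day (default ZT 12-24, the dark phase: torpor onset in
#' fasted mice is around ZT 14).  When one signal is missing at a time
#' point, the recorded one alone decides.
#'
#' @param trace data.frame with `time_h` and signal columns.
#' @param posteriors named list of [BaselinePosterior-class]; names among
#'   `tb`, `vo2`.  Every signal present in the trace must have a fit.
#' @param window eligible time-of-day window in ZT hours (default
#'   `c(12, 24)`).
#' @return data.frame `time_h, eligible, below_tb, below_vo2, torpor`
#'   (below flags `NA` where the signal is missing).
#' @export
detectTorpor <- function(trace, posteriors, window = c(12, 24)) {
    cols <- c(tb = "tb_c", vo2 = "vo2_ml_min")
    have <- names(cols)[vapply(cols, function(cl)
        cl %in% names(trace) && any(!is.na(trace[[cl]])), logical(1))]
    if (!length(have)) stop("trace carries no usable signal")
    missingFit <- setdiff(have, names(posteriors))
    if (length(missingFit))
        stop("no fitted baseline for signal(s): ",
             paste(missingFit, collapse = ", "))
    tod <- trace$time_h %% 24
    eligible <- tod >= window[1] & tod < window[2]
    below <- matrix(NA, nrow(trace), 2,
                    dimnames = list(NULL, c("tb", "vo2")))
    for (s in have) {
        bp <- posteriors[[s]]
        bound <- stats::approx(bp@tod, bp@lower, xout = tod, rule = 2)$y
        below[, s] <- trace[[cols[[s]]]] < bound
    }
    avail <- !is.na(below)
    allBelow <- rowSums(below & avail, na.rm = TRUE) == rowSums(avail) &
        rowSums(avail) > 0
    data.frame(time_h = trace$time_h, eligible = eligible,
               below_tb = below[, "tb"], below_vo2 = below[, "vo2"],
               torpor = eligible & allBelow)
}

#' Minimal phenotype during torpor
#'
#' Minimum body temperature and oxygen consumption over torpor-labelled
#' time points; `NA` when nothing is labelled.
#'
#' @param trace the trace [detectTorpor()] was run on.
#' @param calls its result.
#' @return list `min_tb`, `min_vo2`.
#' @export
minPhenotype <- function(trace, calls) {
    stopifnot(nrow(trace) == nrow(calls))
    idx <- which(calls$torpor)
    safeMin <- function(v) if (length(v) && any(!is.na(v)))
        min(v, na.rm = TRUE) else NA_real_
    list(min_tb = safeMin(trace$tb_c[idx]),
         min_vo2 = safeMin(trace$vo2_ml_min[idx]))
}
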