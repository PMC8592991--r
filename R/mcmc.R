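#' Adaptive random-walk Metropolis sampler
#'
#' A self-contained multivariate Metropolis sampler with Haario-style
#' adaptation during warmup: the proposal covariance is the running
#' empirical covariance of the chain scaled by `2.38^2 / d`, with a global
#' scale tuned by Robbins-Monro towards a 0.234 acceptance rate.
#' Adaptation stops at the end of warmup, so the returned draws come from
#' a fixed-kernel Markov chain.
#'
#' @param logpost function(theta) returning the log posterior density
#'   (unnormalised).  Scale parameters should be passed on the log scale
#'   with the Jacobian folded into `logpost`.
#' @param init numeric vector of initial values (names become parameter
#'   names).
#' @param chains number of chains (>= 2).
#' @param iter post-warmup draws per chain.
#' @param warmup adaptation iterations discarded per chain.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param initScale initial proposal SD per coordinate.
#' @param jitter SD of the initial-value jitter applied per chain.
#' @return a [PosteriorDraws-class] with diagnostics attached.
#' @export
amSample <- function(logpost, init, chains = 4L, iter = 1000L,
                     warmup = 1000L, seed = 1L, initScale = 0.1,
                     jitter = 0.5) {
    d <- length(init)
    pn <- names(init)
    if (is.null(pn)) pn <- paste0("par", seq_len(d))
    draws <- array(NA_real_, c(iter, chains, d),
                   dimnames = list(NULL, NULL, pn))
    acc_rate <- numeric(chains)
    for (ch in seq_len(chains)) {
        set.seed(seed + ch)
        x <- init + stats::rnorm(d, 0, jitter * initScale)
        lp <- logpost(x)
        tries <- 0L
        while (!is.finite(lp) && tries < 50L) {
            x <- init + stats::rnorm(d, 0, jitter * initScale)
            lp <- logpost(x)
            tries <- tries + 1L
        }
        if (!is.finite(lp)) stop("could not find a finite starting point")
        scale <- 1
        cov_chol <- diag(initScale, d)
        hist <- matrix(NA_real_, warmup, d)
        n_acc <- 0L
        hist_acc <- 0L
        n_adapt <- 0L
        for (it in seq_len(warmup + iter)) {
            prop <- x + scale * as.vector(cov_chol %*% stats::rnorm(d))
            lp_p <- logpost(prop)
            if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
                x <- prop; lp <- lp_p
                if (it > warmup) n_acc <- n_acc + 1L
                hist_acc <- hist_acc + 1L
            }
            if (it <= warmup) {
                hist[it, ] <- x
                if (it %% 50L == 0L && it >= 200L) {
                    # covariance from the second half of the trajectory so
                    # the initial transient does not poison the proposal
                    S <- stats::cov(hist[ceiling(it / 2):it, , drop = FALSE])
                    S <- S + diag(max(diag(S), 1e-8) * 1e-6 + 1e-12, d)
                    cov_chol <- tryCatch(t(chol(S)) * (2.38 / sqrt(d)),
                                         error = function(e) cov_chol)
                    n_adapt <- n_adapt + 1L
                    rate <- hist_acc / 50L
                    scale <- scale * exp((rate - 0.234) / n_adapt^0.6)
                    hist_acc <- 0L
                }
            } else {
                draws[it - warmup, ch, ] <- x
            }
        }
        acc_rate[ch] <- n_acc / iter
    }
    pd <- new("PosteriorDraws", draws = draws,
              warmup = as.integer(warmup), seed = as.integer(seed),
              accept_rate = acc_rate,
              diagnostics = data.frame())
    pd@diagnostics <- mcmcDiagnostics(pd)
    pd
}

#' Univariate slice sampler step (stepping-out + shrinkage)
#'
#' One update of a scalar coordinate given its log target density.
#'
#' @param logf log density function of the coordinate.
#' @param x0 current value (must have finite `logf(x0)`).
#' @param w initial bracket width.
#' @param maxSteps stepping-out limit.
#' @return new value of the coordinate.
#' @keywords internal
.slice1 <- function(logf, x0, w = 1, maxSteps = 50L) {
    y <- logf(x0) + log(stats::runif(1))
    L <- x0 - stats::runif(1) * w
    R <- L + w
    k <- maxSteps
    while (k > 0 && logf(L) > y) { L <- L - w; k <- k - 1L }
    k <- maxSteps
    while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1L }
    repeat {
        x1 <- stats::runif(1, L, R)
        if (logf(x1) > y) return(x1)
        if (x1 < x0) L <- x1 else R <- x1
        if (R - L < 1e-12) return(x0)
    }
}

.rankNormalize <- function(v) {
    S <- length(v)
    stats::qnorm((rank(v, ties.method = "average") - 3 / 8) / (S + 1 / 4))
}

.splitChains <- function(m) {
    n <- nrow(m); h <- n %/% 2L
    cbind(m[seq_len(h), , drop = FALSE],
          m[(n - h + 1):n, , drop = FALSE])
}

.rhat <- function(m) {
    # m: iterations x chains (already split & rank-normalised)
    n <- nrow(m)
    W <- mean(apply(m, 2, stats::var))
    B <- n * stats::var(colMeans(m))
    sqrt(((n - 1) / n * W + B / n) / W)
}

.essOne <- function(m) {
    # Geyer initial-monotone estimator on split chains
    n <- nrow(m); nc <- ncol(m)
    if (stats::var(as.vector(m)) == 0) return(NA_real_)
    acov <- apply(m, 2, function(v) {
        a <- stats::acf(v, lag.max = n - 1, plot = FALSE,
                        type = "covariance", demean = TRUE)$acf[, 1, 1]
        a
    })
    chain_var <- acov[1, ] * n / (n - 1)
    mean_var <- mean(chain_var)
    var_plus <- mean_var * (n - 1) / n + stats::var(colMeans(m))
    rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
    rho[1] <- 1
    # pair sums, stop at first negative, enforce monotonicity
    maxt <- 1L; t <- 1L
    P <- c()
    while (t + 1 <= length(rho)) {
        p <- rho[t] + rho[t + 1]
        if (p < 0) break
        P <- c(P, p)
        t <- t + 2L
    }
    if (length(P) > 1) P <- cummin(P)
    tau <- -1 + 2 * sum(P)
    max(n * nc / max(tau, 1e-8), 1) |> min(n * nc)
}

#' Convergence diagnostics: split R-hat and effective sample size
#'
#' Rank-normalised split R-hat and bulk effective sample size per
#' parameter.  Values of R-hat above ~1.05 indicate non-convergence.
#'
#' @param x a [PosteriorDraws-class].
#' @return data.frame `parameter, rhat, ess`.
#' @export
mcmcDiagnostics <- function(x) {
    pn <- parNames(x)
    out <- lapply(pn, function(p) {
        m <- .splitChains(x@draws[, , p, drop = TRUE])
        if (stats::var(as.vector(m)) == 0)
            return(data.frame(parameter = p, rhat = NA_real_,
                              ess = NA_real_))
        z <- matrix(.rankNormalize(as.vector(m)), nrow(m), ncol(m))
        data.frame(parameter = p, rhat = .rhat(z), ess = .essOne(z))
    })
    do.call(rbind, out)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(prob * n)` of the
#' sorted samples; ties go to the lowest start.
#'
#' @param samples numeric vector of posterior draws (>= 2; 100+ advised).
#' @param prob interval mass, strictly between 0 and 1 (default 0.89).
#' @return numeric `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(4000), 0.89)
#' @export
hpdi <- function(samples, prob = 0.89) {
    if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1)
        stop("prob must lie strictly between 0 and 1")
    n <- length(samples)
    if (n < 2L) stop("need at least 2 samples")
    s <- sort(samples)
    k <- ceiling(prob * n)
    if (k >= n) return(c(s[1], s[n]))
    widths <- s[(k):n] - s[seq_len(n - k + 1L)]
    i <- which.min(widths)                     # which.min takes first tie
    c(s[i], s[i + k - 1L])
}

#' Posterior summary table
#'
#' Median, HPDI bounds and convergence diagnostics for every parameter.
#'
#' @param x a [PosteriorDraws-class].
#' @param prob HPDI mass (default 0.89).
#' @return data.frame `parameter, median, hpdi_low, hpdi_high, rhat, ess`.
#' @export
posteriorSummary <- function(x, prob = 0.89) {
    pn <- parNames(x)
    diag <- x@diagnostics
    out <- lapply(pn, function(p) {
        v <- extractPar(x, p)
        h <- hpdi(v, prob)
        data.frame(parameter = p, median = stats::median(v),
                   hpdi_low = h[1], hpdi_high = h[2])
    })
    out <- do.call(rbind, out)
    merge(out, diag, by = "parameter", sort = FALSE)
}
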