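#' Hierarchical Bayesian model of knockout torpor phenotypes
#'
#' Fits, by MCMC, the two-state hierarchical model of minimal phenotypes
#' (minimal T_B or minimal VO2) across knockout lines g and alleles a:
#' \preformatted{
#'   Y_NORMAL[i] ~ Normal(alpha + beta[g[i], a[i]],              sigma_NORMAL)
#'   Y_TORPOR[i] ~ Normal(alpha + beta[g[i], a[i]] + gamma[g[i], a[i]],
#'                        sigma_TORPOR)
#'   beta[g, a]  ~ Normal(0, sigma_beta)
#'   gamma[g, a] ~ Normal(0, sigma_gamma)
#' }
#' with Half-Cauchy(0, 2.5) priors on `sigma_beta` and `sigma_gamma`,
#' HalfNormal(10) on the residual scales, and a weakly informative
#' Normal(mean(Y_NORMAL), 10) prior on the shared global mean `alpha`.
#' `gamma` is the torpor effect; its between-allele contrasts
#' ([contrastGamma()]) quantify how a knockout shifts torpor depth.
#'
#' @param table data.frame `animal_id, line, allele, state, y` with
#'   `state` in NORMAL/TORPOR (e.g. from [genKOPhenotypes()]).
#' @param chains,draws,warmup,seed sampler settings.  The sampler is a
#'   Gibbs scheme: exact multivariate-normal draws of
#'   (alpha, beta, gamma) given the scales, and univariate slice updates
#'   of the four scale parameters on the log scale.
#' @return a [PosteriorDraws-class]; scale parameters are returned on the
#'   natural scale as `sigma_NORMAL, sigma_TORPOR, sigma_beta, sigma_gamma`;
#'   cell parameters are named `beta[line,allele]`, `gamma[line,allele]`.
#' @export
fitKOModel <- function(table, chains = 4L, draws = 2000L, warmup = 1000L,
                       seed = 1L) {
    stopifnot(all(c("line", "allele", "state", "y") %in% names(table)))
    tn <- table[table$state == "NORMAL", ]
    tt <- table[table$state == "TORPOR", ]
    if (!nrow(tt))
        stop("no TORPOR observations: gamma is unidentifiable")
    if (!nrow(tn)) stop("no NORMAL observations")
    cells <- unique(table[, c("line", "allele")])
    cells <- cells[order(cells$line, cells$allele), ]
    cellkey <- function(l, a) paste0(l, ",", a)
    ck <- cellkey(cells$line, cells$allele)
    if (any(!ck %in% cellkey(tn$line, tn$allele)))
        stop("every (line, allele) cell needs NORMAL-state data")
    nc <- nrow(cells)
    cn_idx <- match(cellkey(tn$line, tn$allele), ck)
    ct_idx <- match(cellkey(tt$line, tt$allele), ck)
    yn <- tn$y; yt <- tt$y
    ybar <- mean(yn)

    # Design: NORMAL rows load on (alpha, beta[cell]); TORPOR rows add
    # gamma[cell].  Given the four scales the coefficient block is
    # multivariate normal, so the sampler alternates an exact Gibbs draw of
    # (alpha, beta, gamma) with univariate slice updates of the scales on
    # the log scale -- the same posterior density, without random-walk
    # mixing problems in the hierarchical geometry.
    p <- 1L + 2L * nc
    Xn <- matrix(0, length(yn), p)
    Xn[, 1] <- 1; Xn[cbind(seq_along(yn), 1L + cn_idx)] <- 1
    Xt <- matrix(0, length(yt), p)
    Xt[, 1] <- 1; Xt[cbind(seq_along(yt), 1L + ct_idx)] <- 1
    Xt[cbind(seq_along(yt), 1L + nc + ct_idx)] <- 1
    XnTXn <- crossprod(Xn); XnTy <- crossprod(Xn, yn)
    XtTXt <- crossprod(Xt); XtTy <- crossprod(Xt, yt)

    pn <- c("alpha", paste0("beta[", ck, "]"), paste0("gamma[", ck, "]"),
            "sigma_NORMAL", "sigma_TORPOR", "sigma_beta", "sigma_gamma")
    out <- array(NA_real_, c(draws, chains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
    halfNormLog <- function(s, scale) stats::dnorm(s, 0, scale, log = TRUE)
    halfCauchyLog <- function(s, scale) stats::dcauchy(s, 0, scale, log = TRUE)
    for (ch in seq_len(chains)) {
        set.seed(seed + ch)
        sN <- max(stats::sd(yn), 0.5) * stats::runif(1, 0.5, 2)
        sT <- max(stats::sd(yt), 0.5) * stats::runif(1, 0.5, 2)
        sB <- stats::runif(1, 0.5, 3)
        sG <- stats::runif(1, 0.5, 3)
        theta <- numeric(p)
        for (it in seq_len(warmup + draws)) {
            # -- exact draw of (alpha, beta, gamma) | scales
            A <- XnTXn / sN^2 + XtTXt / sT^2 +
                diag(c(1 / 100, rep(1 / sB^2, nc), rep(1 / sG^2, nc)))
            b <- XnTy / sN^2 + XtTy / sT^2 +
                c(ybar / 100, rep(0, 2 * nc))
            U <- chol(A)
            theta <- backsolve(U, backsolve(U, b, transpose = TRUE)) +
                backsolve(U, stats::rnorm(p))
            beta <- theta[2:(1 + nc)]; gamma <- theta[(2 + nc):p]
            rn <- yn - Xn %*% theta; rt <- yt - Xt %*% theta
            # -- scales by slice sampling on log sigma
            ssn <- sum(rn^2); nnn <- length(yn)
            sN <- exp(.slice1(function(ls)
                -nnn * ls - ssn / (2 * exp(2 * ls)) +
                    halfNormLog(exp(ls), 10) + ls, log(sN)))
            sst <- sum(rt^2); nnt <- length(yt)
            sT <- exp(.slice1(function(ls)
                -nnt * ls - sst / (2 * exp(2 * ls)) +
                    halfNormLog(exp(ls), 10) + ls, log(sT)))
            ssb <- sum(beta^2)
            sB <- exp(.slice1(function(ls)
                -nc * ls - ssb / (2 * exp(2 * ls)) +
                    halfCauchyLog(exp(ls), 2.5) + ls, log(sB)))
            ssg <- sum(gamma^2)
            sG <- exp(.slice1(function(ls)
                -nc * ls - ssg / (2 * exp(2 * ls)) +
                    halfCauchyLog(exp(ls), 2.5) + ls, log(sG)))
            if (it > warmup)
                out[it - warmup, ch, ] <- c(theta, sN, sT, sB, sG)
        }
    }
    post <- new("PosteriorDraws", draws = out, warmup = as.integer(warmup),
                seed = as.integer(seed), accept_rate = rep(1, chains),
                diagnostics = data.frame())
    post@diagnostics <- mcmcDiagnostics(post)
    mx <- max(post@diagnostics$rhat, na.rm = TRUE)
    if (is.finite(mx) && mx > 1.05)
        warning("KO model fit: split R-hat = ", round(mx, 3), " (> 1.05)")
    post
}

#' Posterior contrast of torpor effects between alleles
#'
#' Drawwise difference `gamma[line, allele] - gamma[line, "wt"]`: the shift
#' in torpor phenotype a knockout allele causes relative to wildtype
#' within its line.
#'
#' @param x a [PosteriorDraws-class] from [fitKOModel()].
#' @param line knockout line (e.g. `"021a"`).
#' @param allele allele to contrast against wildtype (`"het"`, `"hom"`, or
#'   `"wt"` for the degenerate zero contrast).
#' @param prob HPDI mass (default 0.89).
#' @return list `draws` (posterior of the difference), `median`, `hpdi`.
#' @export
contrastGamma <- function(x, line, allele, prob = 0.89) {
    p1 <- paste0("gamma[", line, ",", allele, "]")
    p0 <- paste0("gamma[", line, ",wt]")
    if (!p1 %in% parNames(x) || !p0 %in% parNames(x))
        stop("unknown (line, allele) cell: ", line, ", ", allele)
    d <- extractPar(x, p1) - extractPar(x, p0)
    list(draws = d, median = stats::median(d),
         hpdi = if (all(d == 0)) c(0, 0) else hpdi(d, prob))
}

#' Bayesian delta-delta-CT estimate for one organ
#'
#' Models the per-animal reference-normalised qPCR cycle threshold
#' `dCT = CT_target - CT_reference` as `Normal(mu_condition, sigma)` with
#' weakly informative priors (mu ~ Normal(sample mean, 10),
#' sigma ~ HalfNormal(10)), and reports the posterior of
#' `ddCT = mu_TORPOR - mu_NORMAL`.  Negative ddCT means lower CT during
#' torpor, i.e. higher target mRNA.
#'
#' @param ct data.frame `organ, condition, animal, CT_target, CT_reference`
#'   with `condition` in NORMAL/TORPOR.
#' @param organ organ to analyse.
#' @param chains,draws,warmup,seed sampler settings.
#' @param prob HPDI mass (default 0.89).
#' @return list `draws` (ddCT posterior), `median`, `hpdi`, and
#'   `posterior` (the full [PosteriorDraws-class]).
#' @export
ddctEstimate <- function(ct, organ, chains = 4L, draws = 1000L,
                         warmup = 1000L, seed = 1L, prob = 0.89) {
    d <- ct[ct$organ == organ, ]
    if (!nrow(d)) stop("no rows for organ ", organ)
    dct <- d$CT_target - d$CT_reference
    isT <- d$condition == "TORPOR"
    if (!any(isT) || !any(!isT))
        stop("both NORMAL and TORPOR conditions are required for ", organ)
    m0 <- mean(dct)
    logpost <- function(th) {
        mu <- th[1:2]; sigma <- exp(th[3])
        sum(stats::dnorm(dct, mu[1 + isT], sigma, log = TRUE)) +
            sum(stats::dnorm(mu, m0, 10, log = TRUE)) +
            stats::dnorm(sigma, 0, 10, log = TRUE) + th[3]
    }
    init <- c(mean(dct[!isT]), mean(dct[isT]),
              log(max(stats::sd(dct), 0.1)))
    names(init) <- c("mu_NORMAL", "mu_TORPOR", "log_sigma")
    post <- amSample(logpost, init, chains = chains, iter = draws,
                     warmup = warmup, seed = seed, initScale = 0.1)
    dd <- extractPar(post, "mu_TORPOR") - extractPar(post, "mu_NORMAL")
    list(draws = dd, median = stats::median(dd), hpdi = hpdi(dd, prob),
         posterior = post)
}
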