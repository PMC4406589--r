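## Constant-gBGC likelihood machinery.
##
## Expected derived-allele-frequency spectra come from the stationary sojourn
## density of a new mutation under a directional transmission bias of scaled
## strength B:
##   phi(x; B) = (1 - exp(-B (1 - x))) / ((1 - exp(-B)) x (1 - x)),
## with the neutral limit phi(x; 0) = 1/x. Binomial sampling of i of n
## haplotypes gives G_i(B) = integral of C(n,i) x^i (1-x)^(n-i) phi(x;B) dx,
## evaluated by fixed-order Gauss-Legendre quadrature; the binomial kernel
## regularizes the endpoint singularities for 1 <= i <= n-1.

.quadCache <- new.env(parent = emptyenv())

.gaussLegendre01 <- function(nNodes = 256L) {
    key <- as.character(nNodes)
    if (is.null(.quadCache[[key]])) {
        gl <- pracma::gaussLegendre(nNodes, 0, 1)
        .quadCache[[key]] <- list(x = gl$x, w = gl$w)
    }
    .quadCache[[key]]
}

## Sojourn density, numerically stable on both signs of B (all exponents
## kept non-positive).
.sojourn <- function(x, B) {
    if (abs(B) < 1e-6) return(1 / x)
    if (B > 0) {
        (1 - exp(-B * (1 - x))) / ((1 - exp(-B)) * x * (1 - x))
    } else {
        exp(B * x) * (1 - exp(B * (1 - x))) / ((1 - exp(B)) * x * (1 - x))
    }
}

#' Expected class spectrum under a constant conversion coefficient
#'
#' Computes \eqn{G_i(B)} for i = 1..n-1: the expected (unnormalized) density
#' of derived-allele copy numbers among n sampled haplotypes for mutations
#' whose derived allele enjoys a scaled transmission advantage B (B < 0 for a
#' disadvantage, B = 0 neutral, where \eqn{G_i = 1/i}).
#'
#' @param B scaled conversion coefficient (finite; values within 1e-6 of 0
#'   are routed to the analytic neutral limit).
#' @param n haploid sample size (>= 2).
#' @param nNodes Gauss-Legendre quadrature order (default 256).
#' @return numeric vector of length n-1.
#' @examples
#' expectedClassSpectrum(0, 10)          # 1/i
#' expectedClassSpectrum(5.71, 60)[1:5]
#' @export
expectedClassSpectrum <- function(B, n, nNodes = 256L) {
    if (n < 2) stop("n must be >= 2")
    stopifnot(is.finite(B))
    i <- seq_len(n - 1L)
    if (abs(B) < 1e-6) return(1 / i)
    gl <- .gaussLegendre01(nNodes)
    phi <- .sojourn(gl$x, B)
    ## binomial kernel matrix (n-1) x nNodes: constant in B, cached per n
    kkey <- paste0("K", n, "_", nNodes)
    K <- .quadCache[[kkey]]
    if (is.null(K)) {
        lx <- log(gl$x); l1x <- log1p(-gl$x)
        K <- exp(lchoose(n, i) + outer(i, lx) + outer(n - i, l1x))
        .quadCache[[kkey]] <- K
    }
    as.numeric(K %*% (gl$w * phi))
}

#' Expected observed spectra with distortion and polarization error
#'
#' Maps model parameters to expected Poisson counts per observed class and
#' derived copy number i. Misorientation converts WS and SW into each other
#' with mirrored frequency (a derived-i WS SNP misread as ancestral appears
#' as a derived-(n-i) SW SNP), while the GC-conservative neutral class is
#' internally mirrored:
#' \deqn{E_i^{WS} = r_i [(1-e_{WS}) \theta_{WS} G_i(B) + e_{SW} \theta_{SW} G_{n-i}(-B)]}
#' \deqn{E_i^{SW} = r_i [(1-e_{SW}) \theta_{SW} G_i(-B) + e_{WS} \theta_{WS} G_{n-i}(B)]}
#' \deqn{E_i^{N}  = r_i \theta_N [(1-e_N) G_i(0) + e_N G_{n-i}(0)]}
#'
#' @param B scaled conversion coefficient.
#' @param theta named numeric (WS, SW, N): positive mutation-influx scales.
#' @param e named numeric (WS, SW, N): polarization-error probabilities in
#'   `[0, 0.5]`.
#' @param r distortion vector r_i of length n-1 with r_1 = 1 (shared across
#'   classes).
#' @param n haploid sample size.
#' @return 3 x (n-1) matrix with rows WS, SW, N.
#' @export
expectedObservedSpectra <- function(B, theta, e, r, n) {
    theta <- theta[c("WS", "SW", "N")]; e <- e[c("WS", "SW", "N")]
    if (any(is.na(theta)) || any(theta <= 0)) stop("theta must be positive (WS, SW, N)")
    if (any(is.na(e)) || any(e < 0 | e > 0.5)) stop("e must lie in [0, 0.5]")
    if (length(r) != n - 1L || any(r < 0)) stop("r must be nonnegative, length n-1")
    gP <- expectedClassSpectrum(B, n)
    gM <- expectedClassSpectrum(-B, n)
    g0 <- expectedClassSpectrum(0, n)
    rev_ <- function(v) rev(v)   # G_{n-i} for i = 1..n-1
    EWS <- r * ((1 - e["WS"]) * theta["WS"] * gP + e["SW"] * theta["SW"] * rev_(gM))
    ESW <- r * ((1 - e["SW"]) * theta["SW"] * gM + e["WS"] * theta["WS"] * rev_(gP))
    EN  <- r * theta["N"] * ((1 - e["N"]) * g0 + e["N"] * rev_(g0))
    rbind(WS = EWS, SW = ESW, N = EN)
}

#' Poisson log-likelihood of class spectra
#'
#' Independent Poisson cells over classes and copy numbers:
#' \eqn{\sum c \log E - E - \log c!}. An expected count of zero facing a
#' positive observed count yields `-Inf`.
#'
#' @param expected 3 x (n-1) matrix from [expectedObservedSpectra()].
#' @param sfs a [ClassSFS-class] (or a 3 x (n-1) count matrix).
#' @return log-likelihood (scalar).
#' @export
gbgcLoglik <- function(expected, sfs) {
    counts <- if (is(sfs, "ClassSFS")) sfsCounts(sfs) else sfs
    stopifnot(identical(dim(expected), dim(counts)))
    if (any(expected == 0 & counts > 0)) return(-Inf)
    pos <- counts > 0
    sum(counts[pos] * log(expected[pos])) - sum(expected) -
        sum(lgamma(counts[pos] + 1))
}

#' Build class-specific derived allele frequency spectra
#'
#' Tallies polarized SNPs into WS, SW and neutral (WW + SS pooled) spectra by
#' derived copy number, optionally stratified (e.g. by GC or recombination
#' bin, or by Ti/Tv).
#'
#' @param snps polarized SNP table from [polarizeSites()] (columns `k`, `n`,
#'   `mclass`).
#' @param stratum optional vector of stratum labels, one per SNP; `NULL` for
#'   a single spectrum.
#' @return a [ClassSFS-class], or a named list of them when stratified
#'   (strata with no SNPs are dropped).
#' @export
buildClassSFS <- function(snps, stratum = NULL) {
    n <- unique(snps$n)
    if (length(n) != 1L) stop("all SNPs must share the same haploid sample size n")
    build1 <- function(d, label = NA_character_) {
        tab <- function(cls) {
            k <- d$k[d$mclass %in% cls]
            tabulate(k, nbins = n - 1L)
        }
        ClassSFS(tab("WS"), tab("SW"), tab(c("WW", "SS")), n = n,
                 stratum = label)
    }
    if (is.null(stratum)) return(build1(snps))
    stratum <- as.character(stratum)
    stopifnot(length(stratum) == nrow(snps))
    idx <- split(seq_len(nrow(snps)), stratum)
    lapply(idx, function(ii) build1(snps[ii, , drop = FALSE],
                                    label = stratum[ii[1L]]))
}

## ---- fitting -------------------------------------------------------------

## Expected spectra without the distortion vector (r = 1).
.expectedNoR <- function(B, theta, e, n) {
    expectedObservedSpectra(B, theta, e, rep(1, n - 1L), n)
}

## Profile the distortion parameters analytically: with a Poisson likelihood
## the optimum at fixed (B, theta, e) is r_i = observed_i / expected0_i for
## i >= 2 (column totals over classes), with r_1 fixed at 1.
.profileR <- function(E0, counts) {
    obs <- colSums(counts)
    exp0 <- colSums(E0)
    r <- ifelse(exp0 > 0, obs / exp0, 1)
    r[1L] <- 1
    r
}

.negll <- function(par, counts, n) {
    B <- par[1L]
    theta <- stats::setNames(exp(par[2:4]), c("WS", "SW", "N"))
    e <- stats::setNames(0.5 * stats::plogis(par[5:7]), c("WS", "SW", "N"))
    if (!all(is.finite(theta)) || any(theta <= 0)) return(1e12)
    E0 <- .expectedNoR(B, theta, e, n)
    r <- .profileR(E0, counts)
    E <- sweep(E0, 2L, r, "*")
    ll <- gbgcLoglik(E, counts)
    if (!is.finite(ll)) return(1e12)
    -ll
}

#' Fit the constant-gBGC model to class spectra
#'
#' Maximizes the independent-Poisson likelihood of the WS/SW/neutral derived
#' allele frequency spectra over the conversion coefficient B, per-class
#' influx scales theta, polarization-error probabilities e in `[0, 0.5]`, and
#' a shared spectrum-distortion vector r_i (r_1 = 1) that absorbs demographic
#' departures from the stationary spectrum. The distortion parameters are
#' profiled out analytically at every objective evaluation; the remaining
#' seven parameters are optimized by bounded quasi-Newton from multiple
#' seeded random starts. Ties in log-likelihood are broken towards smaller
#' |B|.
#'
#' @param sfs a [ClassSFS-class].
#' @param Bbounds bounds for B (default `c(-50, 50)`).
#' @param nStarts random starts (default 8).
#' @param seed integer seed for the starts.
#' @param gc average GC content of the analyzed sequence context, used to
#'   convert the fitted influx ratio into the per-site AT mutational bias
#'   lambda via [estimateLambda()] (default 0.5: lambda is then the raw
#'   theta_SW / theta_WS ratio).
#' @param minTotal minimum total SNP count for a stable fit (default 200).
#' @param profileCI compute a 95 percent profile-likelihood CI for B.
#' @param distortion fit the distortion vector (default TRUE; FALSE fixes
#'   r = 1, appropriate for data generated at equilibrium).
#' @return a [GbgcFit-class].
#' @examples
#' E <- expectedObservedSpectra(2, c(WS = 500, SW = 3000, N = 400),
#'     c(WS = 0, SW = 0, N = 0), rep(1, 9), 10)
#' sfs <- ClassSFS(E["WS", ], E["SW", ], E["N", ], n = 10)
#' fitM1star(sfs, nStarts = 2)
#' @export
fitM1star <- function(sfs, Bbounds = c(-50, 50), nStarts = 8L, seed = 1L,
                      gc = 0.5, minTotal = 200L, profileCI = FALSE,
                      distortion = TRUE) {
    stopifnot(is(sfs, "ClassSFS"))
    counts <- sfsCounts(sfs)
    n <- sampleSizeN(sfs)
    if (sum(counts) < minTotal)
        stop("fewer than ", minTotal, " SNPs; fit would be unstable")

    negll <- if (distortion) .negll else function(par, counts, n) {
        B <- par[1L]
        theta <- stats::setNames(exp(par[2:4]), c("WS", "SW", "N"))
        e <- stats::setNames(0.5 * stats::plogis(par[5:7]), c("WS", "SW", "N"))
        E <- .expectedNoR(B, theta, e, n)
        ll <- gbgcLoglik(E, counts)
        if (!is.finite(ll)) return(1e12)
        -ll
    }

    a <- sum(1 / seq_len(n - 1L))
    tot <- pmax(rowSums(counts), 0.5)
    starts <- withSeed(seed, {
        lapply(seq_len(nStarts), function(s) {
            B0 <- if (s == 1L) 0 else stats::runif(1, -5, 15)
            c(B0, log(tot / a) + stats::rnorm(3, 0, if (s == 1L) 0 else 0.3),
              stats::qlogis(pmin(pmax(stats::runif(3, 0.01, 0.3) * 2, 1e-3),
                                 1 - 1e-3)))
        })
    })
    lower <- c(Bbounds[1L], rep(-Inf, 6)); upper <- c(Bbounds[2L], rep(Inf, 6))
    fits <- lapply(starts, function(p0) {
        tryCatch(stats::optim(p0, negll, counts = counts, n = n,
            method = "L-BFGS-B",
            lower = c(Bbounds[1L], rep(-30, 3), rep(-12, 3)),
            upper = c(Bbounds[2L], rep(30, 3), rep(12, 3)),
            control = list(maxit = 500L)),
            error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("all optimizer starts failed")
    vals <- vapply(fits, function(f) f$value, numeric(1))
    ## best log-likelihood; near-ties (< 1e-6) broken towards smaller |B|
    best <- which(vals <= min(vals) + 1e-6)
    best <- best[which.min(abs(vapply(fits[best], function(f) f$par[1L],
                                      numeric(1))))]
    fit <- fits[[best]]
    par <- fit$par
    B <- unname(par[1L])
    theta <- stats::setNames(exp(par[2:4]), c("WS", "SW", "N"))
    e <- stats::setNames(0.5 * stats::plogis(par[5:7]), c("WS", "SW", "N"))
    E0 <- .expectedNoR(B, theta, e, n)
    r <- if (distortion) pmax(.profileR(E0, counts), 1e-12) else rep(1, n - 1L)
    ll <- -fit$value
    lambda <- estimateLambda(theta["WS"], theta["SW"], gc)

    ciB <- c(NA_real_, NA_real_)
    obj <- new("GbgcFit", B = B, lambda = unname(lambda), theta = theta,
        distortion = unname(r), e = e, loglik = ll,
        converged = fit$convergence == 0L,
        nStarts = as.integer(length(fits)), n = n, ciB = ciB)
    if (profileCI) obj@ciB <- profileBCI(sfs, obj, distortion = distortion)
    obj
}

#' Profile-likelihood confidence interval for B
#'
#' Reoptimizes the remaining parameters over a search in B on either side of
#' the maximum-likelihood estimate and locates the points where the profile
#' log-likelihood drops by `qchisq(level, 1)/2` (1.92 for 95 percent).
#'
#' @param sfs a [ClassSFS-class].
#' @param fit a [GbgcFit-class] from [fitM1star()].
#' @param level confidence level (default 0.95).
#' @param Bbounds search bounds (default `c(-50, 50)`).
#' @param distortion as in [fitM1star()].
#' @return length-2 numeric: lower and upper CI bounds (clamped at
#'   `Bbounds` when the drop is not reached).
#' @export
profileBCI <- function(sfs, fit, level = 0.95, Bbounds = c(-50, 50),
                       distortion = TRUE) {
    counts <- sfsCounts(sfs)
    n <- sampleSizeN(sfs)
    drop <- stats::qchisq(level, 1) / 2
    par0 <- c(log(fit@theta),
              stats::qlogis(pmin(pmax(fit@e / 0.5, 1e-6), 1 - 1e-6)))
    ## warm-started profile: the optimum at the previous B seeds the next
    warm <- new.env(parent = emptyenv()); warm$par <- par0
    negllB <- function(B) {
        obj <- function(p) {
            if (distortion) .negll(c(B, p), counts, n) else {
                theta <- stats::setNames(exp(p[1:3]), c("WS", "SW", "N"))
                e <- stats::setNames(0.5 * stats::plogis(p[4:6]),
                                     c("WS", "SW", "N"))
                E <- .expectedNoR(B, theta, e, n)
                ll <- gbgcLoglik(E, counts)
                if (!is.finite(ll)) return(1e12)
                -ll
            }
        }
        ## two starts: the optimum of the neighbouring profile point and the
        ## global MLE; keeps the inner maximization off local branches
        runs <- lapply(unique(list(warm$par, par0)), function(p0)
            stats::optim(p0, obj, method = "L-BFGS-B",
                lower = c(rep(-30, 3), rep(-12, 3)),
                upper = c(rep(30, 3), rep(12, 3)),
                control = list(maxit = 300L)))
        o <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
        warm$par <- o$par
        o$value
    }
    target <- -fit@loglik + drop
    findEdge <- function(dir) {
        warm$par <- par0
        step <- max(0.25, abs(fit@B) * 0.1)
        Bcur <- fit@B
        for (j in seq_len(60L)) {
            Bnext <- Bcur + dir * step
            if (Bnext < Bbounds[1L]) return(Bbounds[1L])
            if (Bnext > Bbounds[2L]) return(Bbounds[2L])
            if (negllB(Bnext) >= target) {
                ## bisection (tolerant of tiny warm-start drift)
                lo <- Bcur; hi <- Bnext
                for (it in seq_len(25L)) {
                    mid <- (lo + hi) / 2
                    if (negllB(mid) >= target) hi <- mid else lo <- mid
                    if (abs(hi - lo) < 1e-3) break
                }
                return((lo + hi) / 2)
            }
            Bcur <- Bnext
            step <- step * 2
        }
        if (dir < 0) Bbounds[1L] else Bbounds[2L]
    }
    c(findEdge(-1), findEdge(1))
}

#' AT mutational bias from fitted influx scales
#'
#' \eqn{\lambda = (\theta_{SW}/gc) / (\theta_{WS}/(1-gc))}: the per-site
#' strong-to-weak mutation rate over the per-site weak-to-strong rate, given
#' the GC content of the analyzed context (which sets the per-class
#' mutational opportunity).
#'
#' @param thetaWS,thetaSW positive influx scales.
#' @param gc average GC content, strictly inside (0, 1).
#' @return lambda.
#' @examples
#' estimateLambda(1, 2, 0.34)
#' @export
estimateLambda <- function(thetaWS, thetaSW, gc) {
    if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
    if (thetaWS <= 0 || thetaSW <= 0) stop("theta must be positive")
    unname((thetaSW / gc) / (thetaWS / (1 - gc)))
}

#' Equilibrium GC content under mutation-conversion balance
#'
#' \eqn{GC^* = 1 / (1 + \lambda e^{-B})}.
#'
#' @param B scaled conversion coefficient.
#' @param lambda AT mutational bias (> 0).
#' @return equilibrium GC proportion.
#' @examples
#' equilibriumGC(5.71, 11.69)  # ~0.96
#' @export
equilibriumGC <- function(B, lambda) {
    if (any(lambda <= 0)) stop("lambda must be > 0")
    1 / (1 + lambda * exp(-B))
}

#' Per-meiosis conversion bias from the population-scaled coefficient
#'
#' `b = B / (4 Ne)` in diploids and `B / (3 Ne)` in haplodiploids (haploid
#' males contribute a 3/4 factor to the effective number of chromosome
#' copies).
#'
#' @param B scaled conversion coefficient.
#' @param Ne effective population size (> 0).
#' @param ploidy "haplodiploid" or "diploid".
#' @return per-meiosis transmission bias b.
#' @examples
#' bFromB(0.38, 1e4, "diploid")        # 9.5e-6
#' bFromB(5.71, 5e5, "haplodiploid")   # ~3.8e-6
#' @export
bFromB <- function(B, Ne, ploidy = c("haplodiploid", "diploid")) {
    ploidy <- match.arg(ploidy)
    if (Ne <= 0) stop("Ne must be > 0")
    B / (if (ploidy == "diploid") 4 else 3) / Ne
}

#' Crossover rate in cM/Mb from the population recombination rate
#'
#' Under haplodiploidy \eqn{\rho = 3 N_e r} (diploids: \eqn{4 N_e r}), where
#' r is the per-base, per-generation crossover rate; r per base times 1e8
#' expresses the map distance in cM/Mb.
#'
#' @param rhoPerKb population recombination rate per kb.
#' @param Ne effective population size (> 0).
#' @param ploidy "haplodiploid" or "diploid".
#' @return crossover rate in cM/Mb.
#' @examples
#' rFromRho(390, 5e5)  # 26 cM/Mb
#' @export
rFromRho <- function(rhoPerKb, Ne, ploidy = c("haplodiploid", "diploid")) {
    ploidy <- match.arg(ploidy)
    if (Ne <= 0) stop("Ne must be > 0")
    rhoPerBase <- rhoPerKb / 1000
    rPerBase <- rhoPerBase / (if (ploidy == "diploid") 4 else 3) / Ne
    rPerBase * 1e8
}

#' Local bin covariates for stratified fits
#'
#' `localGC` returns the GC content of the reference sequence in a window of
#' `flank` bp on each side of every SNP (the focal base excluded);
#' `localRho` the length-weighted recombination rate of the window of
#' `width` bp centred on it. These are the covariates the binned fits
#' stratify on.
#'
#' @param snps a site or polarized SNP table (columns `chrom`, `pos`).
#' @param genome a named [Biostrings::DNAStringSet].
#' @param flank flank width per side in bp (default 100).
#' @return numeric vector, one value per SNP.
#' @export
localGC <- function(snps, genome, flank = 100L) {
    vapply(seq_len(nrow(snps)), function(j) {
        ch <- snps$chrom[j]; p <- snps$pos[j]
        L <- length(genome[[ch]])
        lo <- max(1L, p - flank); hi <- min(L, p + flank)
        s <- Biostrings::extractAt(genome[[ch]],
            IRanges::IRanges(c(lo, min(p + 1L, hi)),
                             c(max(p - 1L, lo), hi)))
        comp <- .fragmentComposition(s[IRanges::width(s) > 0])
        if (comp["L"] > 0) unname(comp["GC"] / comp["L"]) else NA_real_
    }, numeric(1))
}

#' @rdname localGC
#' @param rateMap a `GRanges` with `rho_per_kb`.
#' @param width window width centred on the SNP (default 1 kb).
#' @export
localRho <- function(snps, rateMap, width = 1e3) {
    half <- as.integer(width %/% 2)
    aggregateRho(rateMap, GRanges(snps$chrom,
        IRanges(pmax(1L, snps$pos - half), snps$pos + half - 1L)))
}

#' Independent constant-gBGC fits in bins of a covariate
#'
#' Splits polarized SNPs by a local covariate (e.g. local GC from 100 bp of
#' flanking sequence each side, or the recombination rate of the enclosing
#' 1 kb window), builds a class spectrum per bin and runs [fitM1star()]
#' independently in each. Bins below the minimum SNP count are reported as
#' `NULL`. No pooling of parameters across bins.
#'
#' @param snps polarized SNP table.
#' @param binValues numeric covariate per SNP.
#' @param edges strictly ascending bin boundaries (outer values inclusive via
#'   [cut()] with `include.lowest = TRUE`).
#' @param gc per-bin average GC passed to the fit for lambda (single value or
#'   one per bin; default 0.5).
#' @param ... further arguments to [fitM1star()].
#' @param minTotal minimum SNPs per bin (default 200).
#' @return named list of [GbgcFit-class] (or `NULL`), one per bin.
#' @export
binnedFits <- function(snps, binValues, edges, gc = 0.5, minTotal = 200L, ...) {
    if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly ascending")
    bins <- cut(binValues, edges, include.lowest = TRUE)
    gc <- rep_len(gc, nlevels(bins))
    res <- lapply(seq_len(nlevels(bins)), function(j) {
        d <- snps[which(as.integer(bins) == j), , drop = FALSE]
        if (nrow(d) < minTotal) return(NULL)
        fitM1star(buildClassSFS(d), gc = gc[j], minTotal = minTotal, ...)
    })
    names(res) <- levels(bins)
    res
}

#' Folded weak/strong spectrum contingency test
#'
#' A polarization-free check of the GC fixation bias: sites where the minor
#' allele is unambiguously weak (A/T) with a strong major allele, or vice
#' versa, are folded on minor allele frequency, and the 2x2 contingency of
#' class by frequency stratum (MAF below vs at/above `mafCut`) is evaluated
#' with Fisher's exact test.
#'
#' @param sites a site table from [siteTable()] (no polarization needed).
#' @param mafCut frequency stratum boundary (default 0.25).
#' @return list with `spectra` (folded minor-allele-count spectra per class),
#'   `table` (2x2 counts), `odds_ratio` (sample cross-product ratio) and `p`
#'   (two-sided exact test).
#' @export
foldedSpectrumTest <- function(sites, mafCut = 0.25) {
    weakY <- sites$allele_y %in% WEAK
    weakX <- sites$allele_x %in% WEAK
    keep <- weakX != weakY          # one weak, one strong
    d <- sites[keep, , drop = FALSE]
    minorIsY <- d$count_y <= d$n - d$count_y
    m <- pmin(d$count_y, d$n - d$count_y)
    minorWeak <- ifelse(minorIsY, weakY[keep], weakX[keep])
    cls <- ifelse(minorWeak, "W", "S")
    maf <- m / d$n
    stratum <- ifelse(maf < mafCut, "low", "mid")
    if (length(unique(stratum)) < 2 || length(unique(cls)) < 2)
        stop("both frequency strata and both classes must be non-empty")
    tab <- table(factor(cls, c("W", "S")), factor(stratum, c("low", "mid")))
    or <- (tab["W", "low"] * tab["S", "mid"]) /
          (tab["W", "mid"] * tab["S", "low"])
    ft <- stats::fisher.test(tab)
    nfold <- floor(max(d$n) / 2)
    spectra <- sapply(c("W", "S"), function(cl)
        tabulate(m[cls == cl], nbins = nfold))
    list(spectra = spectra, table = tab, odds_ratio = unname(or),
         p = ft$p.value)
}

#' Mean derived allele frequencies by mutation class and context
#'
#' Summaries behind the class-comparison figures: mean derived allele
#' frequency per mutation class by Ti/Tv, per CpG/GpC-creating context within
#' WS and SS, each with percentile bootstrap CIs; WS/SW mean-frequency ratios
#' for transitions and transversions; and relative per-frequency-bin class
#' proportions.
#'
#' @param snps polarized SNP table from [polarizeSites()].
#' @param nBoot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @param nBins frequency bins for the relative spectra (default 10).
#' @return list with `class_means`, `context_means`, `ratios` and
#'   `relative_spectra`.
#' @export
classFrequencySummaries <- function(snps, nBoot = 200L, seed = 1L, nBins = 10L) {
    cellMean <- function(f) {
        if (!length(f)) return(c(mean = NA_real_, ci_lo = NA_real_,
                                 ci_hi = NA_real_, n = 0))
        b <- vapply(seq_len(nBoot), function(i) mean(sample(f, replace = TRUE)),
                    numeric(1))
        c(mean = mean(f), ci_lo = unname(stats::quantile(b, 0.025)),
          ci_hi = unname(stats::quantile(b, 0.975)), n = length(f))
    }
    withSeed(seed, {
        cells <- expand.grid(mclass = c("WS", "SW", "WW", "SS"),
                             titv = c("Ti", "Tv"), stringsAsFactors = FALSE)
        classMeans <- cbind(cells, t(apply(cells, 1L, function(row) {
            cellMean(snps$f_d[snps$mclass == row[["mclass"]] &
                              snps$titv == row[["titv"]]])
        })))
        ctxCells <- expand.grid(mclass = c("WS", "SS"),
                                context = c("cpg_creating", "gpc_creating"),
                                stringsAsFactors = FALSE)
        contextMeans <- cbind(ctxCells, t(apply(ctxCells, 1L, function(row) {
            sel <- snps$mclass == row[["mclass"]] & snps[[row[["context"]]]]
            cellMean(snps$f_d[sel])
        })))
        meanOf <- function(mc, tv) mean(snps$f_d[snps$mclass == mc &
                                                 snps$titv == tv])
        ratios <- c(ws_sw_ti = meanOf("WS", "Ti") / meanOf("SW", "Ti"),
                    ws_sw_tv = meanOf("WS", "Tv") / meanOf("SW", "Tv"))
        bins <- cut(snps$f_d, seq(0, 1, length.out = nBins + 1L),
                    include.lowest = TRUE)
        relTab <- table(bins, factor(snps$mclass, c("WS", "SW", "WW", "SS")))
        relative <- sweep(unclass(relTab), 1L, pmax(rowSums(relTab), 1L), "/")
        list(class_means = classMeans, context_means = contextMeans,
             ratios = ratios, relative_spectra = relative)
    })
}
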