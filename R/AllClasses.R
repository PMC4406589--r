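#' @import methods
#' @importFrom stats setNames
NULL

BASES <- c("A", "C", "G", "T")
WEAK <- c("A", "T")
STRONG <- c("C", "G")

#' SubstitutionModel: mutation and outgroup-substitution weights
#'
#' Holds the two 4x4 matrices used by substitution-aware weighted parsimony:
#' `mu`, the ingroup mutation weight \eqn{\mu(X \to Y)} per ancestral-base
#' opportunity, and `sigma`, the probability \eqn{\sigma(X \to Y)} that base X
#' was substituted by Y along the outgroup lineage. Diagonals are zero by
#' construction; both matrices are on a comparable per-site scale so their
#' products form scenario weights.
#'
#' @slot mu 4x4 nonnegative matrix, rows = ancestral base, columns = derived
#'   base, diagonal zero.
#' @slot sigma 4x4 nonnegative matrix of per-site outgroup substitution
#'   probabilities, diagonal zero, row sums at most 1.
#'
#' @seealso [estimateSubstitutionModel()], [polarizeSites()]
#' @export
setClass("SubstitutionModel",
    representation(mu = "matrix", sigma = "matrix"))

setValidity("SubstitutionModel", function(object) {
    msg <- NULL
    for (nm in c("mu", "sigma")) {
        m <- slot(object, nm)
        if (!identical(dim(m), c(4L, 4L)))
            msg <- c(msg, sprintf("%s must be 4x4", nm))
        else {
            if (!identical(rownames(m), BASES) || !identical(colnames(m), BASES))
                msg <- c(msg, sprintf("%s must have dimnames A,C,G,T", nm))
            if (any(m < 0)) msg <- c(msg, sprintf("%s has negative entries", nm))
            if (any(diag(m) != 0)) msg <- c(msg, sprintf("%s diagonal must be 0", nm))
        }
    }
    if (is.null(msg) && any(rowSums(object@sigma) > 1 + 1e-9))
        msg <- c(msg, "sigma row sums must be <= 1")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SubstitutionModel-class construct from mu and sigma matrices.
#' @param mu,sigma 4x4 matrices with dimnames A,C,G,T.
#' @export
SubstitutionModel <- function(mu, sigma) {
    mu <- as.matrix(mu); sigma <- as.matrix(sigma)
    dimnames(mu) <- dimnames(sigma) <- list(BASES, BASES)
    new("SubstitutionModel", mu = mu, sigma = sigma)
}

setMethod("show", "SubstitutionModel", function(object) {
    cat("SubstitutionModel\n  mu (ingroup mutation weights):\n")
    print(signif(object@mu, 4))
    cat("  sigma (outgroup substitution probabilities):\n")
    print(signif(object@sigma, 4))
})

#' ClassSFS: class-specific derived allele frequency spectra
#'
#' Counts of derived alleles at copy number i = 1..n-1 among n sampled
#' haplotypes, kept separately for weak-to-strong (WS), strong-to-weak (SW)
#' and GC-conservative neutral (WW + SS pooled) mutations. This is the input
#' to the constant-gBGC likelihood fit.
#'
#' @slot n haploid sample size.
#' @slot counts 3 x (n-1) integer matrix with rows WS, SW, N.
#' @slot stratum optional label (e.g. a GC or recombination-rate bin).
#'
#' @seealso [buildClassSFS()], [fitM1star()]
#' @export
setClass("ClassSFS",
    representation(n = "integer", counts = "matrix", stratum = "character"))

setValidity("ClassSFS", function(object) {
    msg <- NULL
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (!identical(rownames(object@counts), c("WS", "SW", "N")))
        msg <- c(msg, "counts rows must be WS, SW, N")
    if (ncol(object@counts) != object@n - 1L)
        msg <- c(msg, "counts must have n-1 columns")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ClassSFS-class construct from per-class count vectors.
#' @param countsWS,countsSW,countsN numeric vectors of length n-1
#'   (derived copy number 1..n-1).
#' @param n haploid sample size.
#' @param stratum optional stratum label.
#' @export
ClassSFS <- function(countsWS, countsSW, countsN, n = length(countsWS) + 1L,
                     stratum = NA_character_) {
    counts <- rbind(WS = countsWS, SW = countsSW, N = countsN)
    colnames(counts) <- as.character(seq_len(n - 1L))
    new("ClassSFS", n = as.integer(n), counts = counts,
        stratum = as.character(stratum))
}

setMethod("show", "ClassSFS", function(object) {
    tot <- rowSums(object@counts)
    cat(sprintf("ClassSFS (n = %d haplotypes%s)\n", object@n,
        if (is.na(object@stratum)) "" else paste0(", stratum ", object@stratum)))
    cat(sprintf("  WS: %d  SW: %d  neutral (WW+SS): %d SNPs\n",
        tot["WS"], tot["SW"], tot["N"]))
})

#' @rdname ClassSFS-class
#' @param x a `ClassSFS`.
#' @export
sfsCounts <- function(x) x@counts

#' @rdname ClassSFS-class
#' @export
sampleSizeN <- function(x) x@n

#' GbgcFit: maximum-likelihood fit of the constant-gBGC model
#'
#' Result of fitting the constant conversion-coefficient model to
#' class-specific derived allele frequency spectra: the population-scaled
#' conversion coefficient B, AT mutational bias lambda, per-class mutation
#' influx scales theta, nuisance spectrum-distortion parameters r_i (r_1 = 1)
#' shared across classes, and per-class polarization-error probabilities e.
#'
#' @slot B population-scaled conversion coefficient.
#' @slot lambda AT mutational bias (S->W over W->S per-site rate ratio).
#' @slot theta named numeric (WS, SW, N) mutation-influx scale parameters.
#' @slot distortion numeric vector r_i, i = 1..n-1, with r_1 = 1.
#' @slot e named numeric (WS, SW, N) polarization-error probabilities.
#' @slot loglik maximized log-likelihood.
#' @slot converged logical convergence flag.
#' @slot nStarts number of random starts used.
#' @slot n haploid sample size of the fitted spectra.
#' @slot ciB length-2 numeric, 95 percent profile-likelihood CI for B
#'   (NA when not requested).
#'
#' @seealso [fitM1star()], [estimateLambda()], [equilibriumGC()]
#' @export
setClass("GbgcFit",
    representation(B = "numeric", lambda = "numeric", theta = "numeric",
        distortion = "numeric", e = "numeric", loglik = "numeric",
        converged = "logical", nStarts = "integer", n = "integer",
        ciB = "numeric"))

setValidity("GbgcFit", function(object) {
    msg <- NULL
    if (!identical(names(object@theta), c("WS", "SW", "N")))
        msg <- c(msg, "theta must be named WS, SW, N")
    if (!identical(names(object@e), c("WS", "SW", "N")))
        msg <- c(msg, "e must be named WS, SW, N")
    if (any(object@theta <= 0)) msg <- c(msg, "theta must be > 0")
    if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
    if (any(object@e < 0 | object@e > 0.5))
        msg <- c(msg, "e must be in [0, 0.5]")
    if (any(object@distortion <= 0)) msg <- c(msg, "distortion must be > 0")
    if (abs(object@distortion[1L] - 1) > 1e-12)
        msg <- c(msg, "distortion r_1 must equal 1")
    if (object@converged && !is.finite(object@loglik))
        msg <- c(msg, "loglik must be finite when converged")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "GbgcFit", function(object) {
    cat("GbgcFit (constant-gBGC model, Poisson spectrum likelihood)\n")
    cat(sprintf("  B      = %.4f%s\n", object@B,
        if (all(is.finite(object@ciB)))
            sprintf("  [95%% profile CI %.3f, %.3f]", object@ciB[1], object@ciB[2])
        else ""))
    cat(sprintf("  lambda = %.4f\n", object@lambda))
    cat(sprintf("  theta  : WS %.4g  SW %.4g  N %.4g\n",
        object@theta["WS"], object@theta["SW"], object@theta["N"]))
    cat(sprintf("  e      : WS %.4f  SW %.4f  N %.4f\n",
        object@e["WS"], object@e["SW"], object@e["N"]))
    cat(sprintf("  loglik = %.3f  (converged: %s, %d starts)\n",
        object@loglik, object@converged, object@nStarts))
})

#' @rdname GbgcFit-class
#' @param x a `GbgcFit`.
#' @export
gbgcB <- function(x) x@B

#' @rdname GbgcFit-class
#' @export
gbgcLambda <- function(x) x@lambda

#' @rdname GbgcFit-class
#' @export
gbgcTheta <- function(x) x@theta

#' @rdname GbgcFit-class
#' @export
gbgcE <- function(x) x@e

#' @rdname GbgcFit-class
#' @export
gbgcCiB <- function(x) x@ciB

#' @rdname GbgcFit-class
#' @export
gbgcLoglikValue <- function(x) x@loglik
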