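## Classical diversity statistics and sequence composition measures.

#' Watterson's estimator of the population mutation rate per base
#'
#' \eqn{\theta_w = S / (a_{n-1} L)} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S number of segregating sites.
#' @param n haploid sample size (>= 2).
#' @param L covered bases; `L = 0` yields `NA` (absent), not zero.
#' @return per-base theta_w.
#' @examples
#' wattersonTheta(2, 4, 1000)
#' @export
wattersonTheta <- function(S, n, L) {
    stopifnot(n >= 2, S >= 0)
    if (length(L) == 1L && L <= 0) return(NA_real_)
    a <- sum(1 / seq_len(n - 1L))
    ifelse(L > 0, S / (a * L), NA_real_)
}

#' Nucleotide diversity (mean pairwise heterozygosity) per base
#'
#' \eqn{\pi = \sum_j 2 k_j (n - k_j) / (n (n - 1)) / L} over SNPs j with
#' derived (or either-allele) copy number `k_j`; symmetric in `k` and `n-k`.
#'
#' @param k vector of allele copy numbers at segregating sites.
#' @param n haploid sample size.
#' @param L covered bases; `L = 0` yields `NA`.
#' @return per-base pi.
#' @examples
#' nucleotideDiversity(2, 4, 100)
#' @export
nucleotideDiversity <- function(k, n, L) {
    stopifnot(n >= 2)
    if (L <= 0) return(NA_real_)
    sum(2 * k * (n - k)) / (n * (n - 1)) / L
}

#' Tajima's D
#'
#' The standard normalized difference between pairwise diversity and
#' Watterson's estimator, using the usual a1, a2, b1, b2, c1, c2, e1, e2
#' constants. `piTotal` is the summed pairwise diversity (pi per base times
#' L, i.e. not length-normalized).
#'
#' @param S segregating sites (must be > 0; otherwise `NA`).
#' @param piTotal total (non-per-base) pairwise diversity.
#' @param n haploid sample size.
#' @return Tajima's D.
#' @export
tajimasD <- function(S, piTotal, n) {
    if (is.na(S) || S <= 0) return(NA_real_)
    i <- seq_len(n - 1L)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' GC content of a sequence
#'
#' Proportion of G + C among unambiguous A/C/G/T bases; ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param seq a character string or [Biostrings::DNAString].
#' @return proportion in `[0, 1]`, `NA` when no unambiguous base exists.
#' @export
gcContent <- function(seq) {
    counts <- .baseCounts(seq)
    tot <- sum(counts)
    if (tot == 0) return(NA_real_)
    unname((counts["G"] + counts["C"]) / tot)
}

.baseCounts <- function(seq) {
    if (is(seq, "DNAString")) {
        Biostrings::letterFrequency(seq, BASES)[BASES]
    } else {
        s <- strsplit(toupper(as.character(seq)), "")[[1]]
        vapply(BASES, function(b) sum(s == b), numeric(1))
    }
}

#' CpG observed/expected ratio
#'
#' \eqn{CpG_{O/E} = (\#CG \cdot L) / (\#C \cdot \#G)} with overlapping
#' dinucleotides counted over contiguous runs of unambiguous bases and
#' `L` the number of valid bases.
#'
#' @param seq a character string or [Biostrings::DNAString].
#' @param dinucleotide which dinucleotide to score ("CG" for CpG, "GC" for
#'   GpC).
#' @return the O/E ratio; `NA` when the sequence contains no C or no G.
#' @examples
#' cpgOE("ACGT")   # 4
#' @export
cpgOE <- function(seq, dinucleotide = "CG") {
    s <- toupper(as.character(seq))
    ch <- strsplit(s, "")[[1]]
    valid <- ch %in% BASES
    nC <- as.numeric(sum(ch == substr(dinucleotide, 1, 1) & valid))
    nG <- as.numeric(sum(ch == substr(dinucleotide, 2, 2) & valid))
    L <- as.numeric(sum(valid))
    if (nC == 0 || nG == 0 || L < 2) return(NA_real_)
    ## count overlapping dinucleotides over contiguous valid bases
    first <- ch[-length(ch)]; second <- ch[-1]
    pair <- (first == substr(dinucleotide, 1, 1)) &
            (second == substr(dinucleotide, 2, 2)) &
            valid[-length(ch)] & valid[-1]
    sum(pair) * L / (nC * nG)
}

#' Per-base divergence between aligned ingroup and outgroup sequences
#'
#' Counts coordinate-wise differences between the ingroup reference and the
#' outgroup consensus over comparable (masked-in, unambiguous in both) sites.
#'
#' @param ingroup,outgroup equal-length character strings or `DNAString`s.
#' @param mask optional logical vector of comparable positions (default all).
#' @return list with `divergence` (differences / comparable sites; `NA` when
#'   no comparable site), `differences` and `comparable`.
#' @export
divergenceRate <- function(ingroup, outgroup, mask = NULL) {
    a <- strsplit(toupper(as.character(ingroup)), "")[[1]]
    b <- strsplit(toupper(as.character(outgroup)), "")[[1]]
    stopifnot(length(a) == length(b))
    ok <- a %in% BASES & b %in% BASES
    if (!is.null(mask)) ok <- ok & mask
    comp <- sum(ok)
    diffs <- sum(a[ok] != b[ok])
    list(divergence = if (comp > 0) diffs / comp else NA_real_,
         differences = diffs, comparable = comp)
}

#' Ordinary least-squares regression with R-squared and slope p-value
#'
#' Thin wrapper around [stats::lm()] reporting the quantities used for the
#' window-level correlation analyses: slope, intercept, R-squared and the
#' two-sided t-test p-value of the slope. No multiple-testing correction is
#' applied.
#'
#' @param x,y paired finite numeric vectors (>= 3 pairs after NA removal).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regressR2 <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 paired finite values")
    if (stats::var(x) == 0) stop("zero variance in x")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L],
         n = length(x))
}

#' Bootstrap comparison of class means
#'
#' Percentile 95 percent confidence intervals for per-class means from
#' resampling with replacement within each class (default 200 replicates),
#' plus two-sided bootstrap p-values for all pairwise differences in means.
#' Deterministic given `seed`.
#'
#' @param values numeric vector of observations.
#' @param class class label per observation.
#' @param nBoot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return list with `classes` (data.frame: class, n, mean, ci_lo, ci_hi,
#'   degenerate flag for singleton classes) and `pairs` (data.frame of
#'   pairwise mean differences with bootstrap CI and p).
#' @export
bootstrapCompare <- function(values, class, nBoot = 200L, seed = 1L) {
    class <- as.character(class)
    ok <- is.finite(values) & !is.na(class)
    values <- values[ok]; class <- class[ok]
    levs <- unique(class)
    if (any(tabulate(factor(class, levs)) == 0))
        stop("all classes must be non-empty")
    withSeed(seed, {
        boots <- sapply(levs, function(l) {
            v <- values[class == l]
            vapply(seq_len(nBoot), function(i) mean(sample(v, replace = TRUE)),
                   numeric(1))
        })
        boots <- matrix(boots, nrow = nBoot, dimnames = list(NULL, levs))
        classes <- data.frame(class = levs,
            n = vapply(levs, function(l) sum(class == l), numeric(1)),
            mean = vapply(levs, function(l) mean(values[class == l]), numeric(1)),
            ci_lo = apply(boots, 2L, stats::quantile, 0.025),
            ci_hi = apply(boots, 2L, stats::quantile, 0.975),
            degenerate = vapply(levs, function(l) sum(class == l) == 1, logical(1)),
            row.names = NULL, stringsAsFactors = FALSE)
        pairs <- NULL
        if (length(levs) > 1) {
            cmb <- utils::combn(levs, 2)
            pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
                d <- boots[, cmb[1, j]] - boots[, cmb[2, j]]
                ## two-sided bootstrap p for difference in means
                pLess <- mean(d < 0); pMore <- mean(d > 0)
                data.frame(class_a = cmb[1, j], class_b = cmb[2, j],
                    diff = mean(values[class == cmb[1, j]]) -
                           mean(values[class == cmb[2, j]]),
                    ci_lo = stats::quantile(d, 0.025),
                    ci_hi = stats::quantile(d, 0.975),
                    p = min(1, 2 * min(pLess + mean(d == 0), pMore + mean(d == 0))),
                    row.names = NULL, stringsAsFactors = FALSE)
            }))
        }
        list(classes = classes, pairs = pairs)
    })
}
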