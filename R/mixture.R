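#' @include AllGenerics.R
NULL

#' Construct a TissueMixture
#'
#' @param mean,var,weight numeric vectors, one entry per Gaussian component.
#' @param classes character vector of class labels (\code{GM}, \code{WM},
#'   \code{CSF}, \code{other}) per component.
#' @return a \linkS4class{TissueMixture}, components sorted by mean within
#'   class.
#' @export
tissueMixture <- function(mean, var, weight, classes) {
    ord <- order(match(classes, .tissueClasses), mean)
    new("TissueMixture", mean = as.numeric(mean[ord]),
        var = as.numeric(var[ord]),
        weight = as.numeric(weight[ord] / sum(weight)),
        classes = as.character(classes[ord]))
}

setMethod("show", "TissueMixture", function(object) {
    cat("TissueMixture (", length(object@mean), " components):\n", sep = "")
    for (i in seq_along(object@mean))
        cat(sprintf("  %-6s mean %.4g  sd %.3g  weight %.3f\n",
                    object@classes[i], object@mean[i],
                    sqrt(object@var[i]), object@weight[i]))
})

#' Deterministic quantile initialization of the tissue mixture
#'
#' Places component means at fixed quantiles of the masked apparent-R1
#' distribution — CSF low, GM middle, WM high, and the non-brain class
#' spread across the range — with equal weights and variances derived from
#' the inter-quantile spread.  Deterministic: identical input gives an
#' identical mixture, so the whole fit is reproducible without seeds.
#'
#' @param values numeric vector of masked apparent-R1 values (>= 1000).
#' @param nPerClass named integer vector, Gaussian components per class.
#' @return a \linkS4class{TissueMixture}.
#' @export
initMixture <- function(values,
                        nPerClass = c(GM = 2L, WM = 2L, CSF = 2L,
                                      other = 3L)) {
    values <- values[is.finite(values)]
    if (length(values) < 1000L)
        stop("need at least 1000 masked voxels to initialize the mixture",
             call. = FALSE)
    if (diff(range(values)) == 0)
        stop("degenerate input: all masked values are equal", call. = FALSE)
    stopifnot(all(.tissueClasses %in% names(nPerClass)),
              all(nPerClass >= 1L))
    # per-class quantile anchors; several components spread around each
    anchors <- list(CSF = c(0.05, 0.25), GM = c(0.40, 0.60),
                    WM = c(0.75, 0.92), other = c(0.15, 0.50, 0.85))
    q <- function(p) as.numeric(stats::quantile(values, p, names = FALSE))
    spread <- (q(0.95) - q(0.05)) / 8
    if (spread <= 0) spread <- diff(range(values)) / 8
    mean <- c(); var <- c(); weight <- c(); classes <- c()
    for (cl in .tissueClasses) {
        n <- nPerClass[[cl]]
        p <- anchors[[cl]]
        p <- if (n == length(p)) p else seq(min(p), max(p), length.out = n)
        mu <- q(p)
        # keep components within a class distinct even on pathological input
        mu <- mu + (seq_len(n) - (n + 1) / 2) * 1e-8 * spread
        mean <- c(mean, mu)
        var <- c(var, rep(spread^2, n))
        weight <- c(weight, rep(1, n))
        classes <- c(classes, rep(cl, n))
    }
    tissueMixture(mean, var, weight, classes)
}

## EM machinery (internal) --------------------------------------------------

# Log of weight_k * N(z; mu_k, var_k): matrix N x K.
.mixLogDens <- function(z, mix) {
    K <- length(mix@mean)
    out <- matrix(0, length(z), K)
    lc <- log(mix@weight + 1e-300) - 0.5 * log(2 * pi * mix@var)
    h <- 0.5 / mix@var
    for (k in seq_len(K))
        out[, k] <- lc[k] - (z - mix@mean[k])^2 * h[k]
    out
}

# Row-wise log-sum-exp (max.col is much cheaper than repeated pmax).
.logRowSums <- function(lp) {
    mx <- lp[cbind(seq_len(nrow(lp)), max.col(lp, ties.method = "first"))]
    mx + log(rowSums(exp(lp - mx)))
}

# E-step: responsibilities and total mixture log-likelihood at z.
.eStep <- function(z, mix) {
    lp <- .mixLogDens(z, mix)
    ls <- .logRowSums(lp)
    list(resp = exp(lp - ls), loglik = sum(ls))
}

# Mixture log-likelihood only (for line searches).
.mixLogLik <- function(z, mix) sum(.logRowSums(.mixLogDens(z, mix)))

# M-step with a variance floor relative to the data variance.
.mStep <- function(z, resp, mix, varFloor) {
    nk <- colSums(resp)
    sz <- as.vector(crossprod(resp, z))
    sz2 <- as.vector(crossprod(resp, z^2))
    ok <- nk > 0
    mean <- ifelse(ok, sz / pmax(nk, 1e-300), mix@mean)
    var <- ifelse(ok, sz2 / pmax(nk, 1e-300) - mean^2, mix@var)
    var <- pmax(var, varFloor)
    w <- pmax(nk / length(z), 1e-10)
    # EM can make means cross; restore the within-class ordering (a pure
    # relabelling of same-class components, invisible to the likelihood)
    ord <- order(match(mix@classes, .tissueClasses), mean)
    new("TissueMixture", mean = mean[ord], var = var[ord],
        weight = (w / sum(w))[ord], classes = mix@classes[ord])
}
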