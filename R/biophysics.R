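#' @include AllClasses.R
NULL

## Thermodynamic occupancy model. Spliceosome assembly around the ASE is
## collapsed into one binding reaction with dimensionless weight q0 = K.[S].
## Each splicing factor f contributes a weight x_f = K_f.[SF_f] and couples
## to the spliceosome through a cooperativity factor c_f (> 1 enhances, < 1
## represses); two SFs may couple to each other through cPair.

checkPositive <- function(...) {
    vals <- c(...)
    if (any(!is.finite(vals)) || any(vals <= 0))
        stop("all model parameters must be positive and finite")
    invisible(TRUE)
}

#' Probability of spliceosome assembly around an ASE
#'
#' Boltzmann-weighted probability that the pre-mRNA is bound by the
#' (fully assembled) spliceosome, for zero, one or two splicing factors.
#' With no SF the states are bound/unbound and
#' \eqn{P_b = q_0 / (1 + q_0)}; with one SF the four states give
#' \eqn{P_b = q_0(1 + c x) / (1 + x + q_0(1 + c x))}; with two SFs all
#' eight states are weighted, with \code{cPair} multiplying the
#' doubly-SF-bound states.
#'
#' @param q0 basal spliceosome weight (equilibrium constant times
#'   spliceosome concentration), positive.
#' @param x numeric vector of length 0, 1 or 2: SF occupancy weights.
#' @param cf numeric vector parallel to \code{x}: SF-spliceosome
#'   cooperativity factors; \code{cf = 1} means no interaction.
#' @param cPair SF-SF cooperativity factor (used only with two SFs).
#' @return the probability of spliceosome assembly, strictly in (0, 1).
#' @examples
#' spliceProbability(1)                      # 0.5
#' spliceProbability(1, x = 1, cf = 3)       # 2/3
#' @export
spliceProbability <- function(q0, x = numeric(0), cf = numeric(0),
                              cPair = 1) {
    if (length(x) != length(cf))
        stop("x and cf must have the same length")
    if (length(x) > 2L)
        stop("at most two splicing factors are supported")
    checkPositive(q0, x, cf, cPair)
    w <- boltzmannSums(q0, x, cf, cPair)
    w$bound / (w$bound + w$unbound)
}

## Sums of Boltzmann weights over spliceosome-bound and -unbound states.
boltzmannSums <- function(q0, x, cf, cPair) {
    if (length(x) == 0L) {
        list(bound = q0, unbound = 1)
    } else if (length(x) == 1L) {
        list(bound = q0 * (1 + cf * x), unbound = 1 + x)
    } else {
        bound <- q0 * (1 + cf[1L] * x[1L] + cf[2L] * x[2L] +
                       cf[1L] * cf[2L] * cPair * x[1L] * x[2L])
        unbound <- 1 + x[1L] + x[2L] + cPair * x[1L] * x[2L]
        list(bound = bound, unbound = unbound)
    }
}

#' Log ratio of including to excluding isoform expression
#'
#' At steady state the expression ratio of the inclusion isoform to the
#' skipping isoform is \eqn{N_1/N_2 = a \, P_b / (1 - P_b)}, where the
#' constant \eqn{a} absorbs synthesis and degradation rates. Its logarithm
#' is linear in the per-SF and pair contributions returned by
#' \code{\link{decomposeLogRatio}}.
#'
#' @inheritParams spliceProbability
#' @param exonConst the exon-specific constant \eqn{a} (positive).
#' @return \code{logIsoformRatio}: the scalar \eqn{\ln(N_1/N_2)}.
#' @examples
#' logIsoformRatio(1, x = 1, cf = 3)   # log(4/2)
#' @export
logIsoformRatio <- function(q0, exonConst = 1, x = numeric(0),
                            cf = numeric(0), cPair = 1) {
    checkPositive(exonConst)
    d <- decomposeLogRatio(q0, exonConst, x, cf, cPair)
    d$total
}

#' @describeIn logIsoformRatio decompose \eqn{\ln(N_1/N_2)} into the basal
#'   term \eqn{\ln(a q_0)}, one monotone contribution
#'   \eqn{\ln((1 + c_f x_f)/(1 + x_f))} per SF, and a pair term that
#'   vanishes exactly when \code{cPair = 1}. The terms sum to the direct
#'   log-ratio at machine precision.
#' @return \code{decomposeLogRatio}: list with elements \code{basal},
#'   \code{sfTerms}, \code{pairTerm} and \code{total}.
#' @export
decomposeLogRatio <- function(q0, exonConst = 1, x = numeric(0),
                              cf = numeric(0), cPair = 1) {
    if (length(x) != length(cf))
        stop("x and cf must have the same length")
    if (length(x) > 2L)
        stop("at most two splicing factors are supported")
    checkPositive(q0, exonConst, x, cf, cPair)
    basal <- log(exonConst * q0)
    sfTerms <- if (length(x)) log((1 + cf * x) / (1 + x)) else numeric(0)
    if (length(x) == 2L) {
        w <- boltzmannSums(q0, x, cf, cPair)
        ## closed form: what the joint ratio adds beyond the two
        ## independent single-SF ratios
        pairTerm <- log(w$bound / (q0 * w$unbound)) - sum(sfTerms)
    } else {
        pairTerm <- 0
    }
    total <- basal + sum(sfTerms) + pairTerm
    list(basal = basal, sfTerms = sfTerms, pairTerm = pairTerm,
         total = total)
}

#' Contribution of one splicing factor to the log isoform ratio
#'
#' \eqn{g(x) = \ln((1 + \theta x)/(1 + x))}, the amount an SF with
#' occupancy weight \eqn{x} and effective enhancement \eqn{\theta} adds to
#' the log isoform ratio. \eqn{g(0) = 0}; \eqn{g} is strictly increasing in
#' \eqn{x} iff \eqn{\theta > 1} and strictly decreasing iff
#' \eqn{\theta < 1}, which is what makes the effect-sign classification of
#' \code{\link{classifyEffect}} possible.
#'
#' @param x SF occupancy weight(s), non-negative; vectorized.
#' @param theta effective enhancement factor, positive.
#' @return numeric vector of contributions.
#' @examples
#' sfContribution(1, 3)    # log 2
#' @export
sfContribution <- function(x, theta) {
    if (any(!is.finite(x)) || any(x < 0))
        stop("x must be non-negative and finite")
    checkPositive(theta)
    log1p(theta * x) - log1p(x)
}

#' Classify an SRE as enhancer or silencer
#'
#' The sign of a fitted SRE coefficient alone does not determine the
#' regulatory effect, because the response is centered by the cross-tissue
#' average. When the binding SF's concentration in the target tissue lies
#' strictly above the concentrations in every reference tissue, a positive
#' coefficient implies an enhancer and a negative one a silencer; strictly
#' below every reference tissue, the calls flip. In between (or on ties)
#' the effect cannot be determined from the sign.
#'
#' @param gammaSign the sign of the fitted coefficient: \code{"+"},
#'   \code{"-"}, or a nonzero number whose sign is used.
#' @param sfConc named numeric vector of the SF's expression (concentration
#'   proxy, e.g. RPKM) per tissue, all positive.
#' @param targetTissue name of the tissue the coefficient was fitted in;
#'   must be present in \code{names(sfConc)}.
#' @return one of \code{"enhancer"}, \code{"silencer"},
#'   \code{"indeterminate"}.
#' @examples
#' conc <- c(brain = 1, heart = 9, liver = 2)
#' classifyEffect("+", conc, "heart")   # enhancer
#' @export
classifyEffect <- function(gammaSign, sfConc, targetTissue) {
    if (is.numeric(gammaSign)) {
        if (is.na(gammaSign) || gammaSign == 0) return("indeterminate")
        gammaSign <- if (gammaSign > 0) "+" else "-"
    }
    if (!gammaSign %in% c("+", "-"))
        stop("gammaSign must be '+', '-' or a nonzero number")
    if (is.null(names(sfConc)) || !targetTissue %in% names(sfConc))
        stop("target tissue '", targetTissue, "' not found in sfConc")
    checkPositive(sfConc)
    target <- sfConc[[targetTissue]]
    others <- sfConc[setdiff(names(sfConc), targetTissue)]
    if (!length(others)) stop("at least one reference tissue is required")
    if (target > max(others)) {
        if (gammaSign == "+") "enhancer" else "silencer"
    } else if (target < min(others)) {
        if (gammaSign == "+") "silencer" else "enhancer"
    } else {
        "indeterminate"
    }
}
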