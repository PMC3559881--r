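#' @include spliceSRE-package.R
NULL

## Region labels are fixed by the model: 5' and 3' ends of the upstream
## intron, the exon body, and 5' and 3' ends of the downstream intron.
REGION_LABELS <- c("UU", "UD", "EXON", "DU", "DD")

RNA_BASES <- c("A", "C", "G", "U")

#' TranscriptModels: transcript structures grouped by gene
#'
#' Container for transcript models parsed from genePred annotation. Exons are
#' stored per transcript as a \code{GRangesList} in genomic order (0-based
#' half-open coordinates are converted to the 1-based closed convention of
#' \code{GRanges} on input and back on output).
#'
#' @slot exons \code{GRangesList}, one element per transcript, exons sorted
#'   and disjoint.
#' @slot txGene \code{DataFrame} with columns \code{transcriptId},
#'   \code{geneId}, \code{strand}.
#' @exportClass TranscriptModels
setClass("TranscriptModels",
    slots = c(exons = "GRangesList", txGene = "DataFrame"))

setValidity("TranscriptModels", function(object) {
    msg <- NULL
    if (length(object@exons) != nrow(object@txGene))
        msg <- c(msg, "one txGene row per transcript required")
    if (!all(c("transcriptId", "geneId", "strand") %in%
             colnames(object@txGene)))
        msg <- c(msg, "txGene must have transcriptId, geneId, strand")
    if (!all(as.character(object@txGene$strand) %in% c("+", "-")))
        msg <- c(msg, "strand must be + or -")
    for (i in seq_along(object@exons)) {
        st <- start(object@exons[[i]])
        en <- end(object@exons[[i]])
        if (is.unsorted(st) || (length(st) > 1L &&
            any(st[-1L] <= en[-length(en)]))) {
            msg <- c(msg, "exons within a transcript must be disjoint and sorted")
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' CassetteExons: alternatively spliced (cassette) exons
#'
#' Each row is one ASE: an exon included by at least one isoform and skipped
#' by at least one isoform of the same gene, with flanking splice sites fixed
#' across the required isoform sets. Flanking introns are stored in
#' transcript orientation (the "upstream" intron precedes the ASE in the
#' direction of transcription).
#'
#' @slot ranges \code{GRanges} of the exons with metadata columns
#'   \code{aseId}, \code{geneId}, \code{upIntron} and \code{dnIntron}
#'   (\code{IRanges}, genomic coordinates of the flanking introns),
#'   \code{includingTx} and \code{excludingTx} (\code{CharacterList}).
#' @exportClass CassetteExons
setClass("CassetteExons", slots = c(ranges = "GRanges"))

setValidity("CassetteExons", function(object) {
    mc <- mcols(object@ranges)
    need <- c("aseId", "geneId", "upIntron", "dnIntron",
              "includingTx", "excludingTx")
    if (!all(need %in% colnames(mc)))
        return(paste("missing metadata columns:",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (length(object@ranges) > 0L) {
        if (any(lengths(mc$includingTx) == 0L) ||
            any(lengths(mc$excludingTx) == 0L))
            return("including and excluding isoform sets must be non-empty")
        if (anyDuplicated(mc$aseId))
            return("aseId must be unique")
    }
    TRUE
})

#' AseRegionSet: the five masked sequence regions around each ASE
#'
#' Sense-strand pre-mRNA sequences (alphabet A/C/G/U/N) for the regions UU,
#' UD, EXON, DU and DD. Masked positions (splice-site consensus windows, and
#' the joint between the two halves of a capped exon) are marked \code{N} so
#' that no hexamer window can cross them.
#'
#' @slot aseIds character vector of ASE identifiers.
#' @slot regions named list of five \code{RNAStringSet}s (UU, UD, EXON, DU,
#'   DD), each parallel to \code{aseIds}.
#' @exportClass AseRegionSet
setClass("AseRegionSet",
    slots = c(aseIds = "character", regions = "list"))

setValidity("AseRegionSet", function(object) {
    if (!identical(names(object@regions), REGION_LABELS))
        return("regions must be named UU, UD, EXON, DU, DD")
    for (r in REGION_LABELS) {
        if (!is(object@regions[[r]], "RNAStringSet"))
            return("each region must be an RNAStringSet")
        if (length(object@regions[[r]]) != length(object@aseIds))
            return("each region must be parallel to aseIds")
    }
    TRUE
})

#' SplicingResponse: inclusion ratios and centered logit responses
#'
#' Per-(ASE, tissue) inclusion ratio IR and the response
#' \eqn{y_{ij} = \mathrm{logit}(IR_{ij}) - T^{-1}\sum_t \mathrm{logit}(IR_{it})},
#' i.e. the logit inclusion ratio centered by the cross-tissue average used
#' as the reference. Entries are \code{NA} for (ASE, tissue) pairs dropped by
#' upstream filters.
#'
#' @slot ir numeric matrix (ASEs x tissues) of inclusion ratios in [0, 1].
#' @slot y numeric matrix (same shape) of centered logit responses.
#' @slot clipEpsilon the clipping constant applied to IR before the logit.
#' @exportClass SplicingResponse
setClass("SplicingResponse",
    slots = c(ir = "matrix", y = "matrix", clipEpsilon = "numeric"))

setValidity("SplicingResponse", function(object) {
    if (!identical(dim(object@ir), dim(object@y)))
        return("ir and y must have identical dimensions")
    v <- object@ir[!is.na(object@ir)]
    if (length(v) && (any(v < 0) || any(v > 1)))
        return("inclusion ratios must lie in [0, 1]")
    if (object@clipEpsilon <= 0 || object@clipEpsilon >= 0.5)
        return("clipEpsilon must lie in (0, 0.5)")
    TRUE
})

#' SpliceFeatureMatrix: binary hexamer-by-region design matrix
#'
#' Sparse binary matrix with one row per ASE and one column per retained
#' feature; a main-effect column indicates presence of a hexamer in one of
#' the five regions, a pair column is the elementwise product of two parent
#' columns (the cooperative interaction term of the model).
#'
#' @slot mat \code{dgCMatrix} of 0/1 indicators, rownames = ASE ids.
#' @slot info \code{DataFrame} of column metadata: \code{type} ("SRE" or
#'   "pair"), \code{hexamer1}, \code{region1}, \code{hexamer2},
#'   \code{region2}, \code{parent1}, \code{parent2} (column names of the
#'   parents for pair columns), \code{presence} (fraction of ASEs carrying
#'   the feature).
#' @exportClass SpliceFeatureMatrix
setClass("SpliceFeatureMatrix",
    slots = c(mat = "dgCMatrix", info = "DataFrame"))

setValidity("SpliceFeatureMatrix", function(object) {
    if (ncol(object@mat) != nrow(object@info))
        return("one info row per matrix column required")
    need <- c("type", "hexamer1", "region1", "hexamer2", "region2",
              "parent1", "parent2", "presence")
    if (!all(need %in% colnames(object@info)))
        return(paste("missing info columns:",
                     paste(setdiff(need, colnames(object@info)),
                           collapse = ", ")))
    if (length(object@mat@x) && any(object@mat@x != 1))
        return("matrix entries must be 0/1")
    TRUE
})

#' PenalizedPath: a Lasso (or adaptive Lasso) solution path
#'
#' Coefficients along a descending penalty grid for the objective
#' \eqn{(2n)^{-1} \|y - \beta_0 - X\beta\|^2 + \lambda \|\beta\|_1}
#' (weighted in the adaptive case). The intercept is unpenalized.
#'
#' @slot lambda numeric, descending penalty grid.
#' @slot a0 numeric, intercept per lambda.
#' @slot beta \code{dgCMatrix} (features x lambda) of coefficients on the
#'   original column scale.
#' @slot meta list of solver details (weights, convergence).
#' @exportClass PenalizedPath
setClass("PenalizedPath",
    slots = c(lambda = "numeric", a0 = "numeric", beta = "dgCMatrix",
              meta = "list"))

setValidity("PenalizedPath", function(object) {
    if (length(object@lambda) != ncol(object@beta) ||
        length(object@a0) != ncol(object@beta))
        return("lambda, a0 and beta columns must be parallel")
    if (is.unsorted(rev(object@lambda)))
        return("lambda must be descending")
    TRUE
})

#' RcvEstimate: refitted cross-validation variance estimate
#'
#' @slot sigma2 final residual-variance estimate (mean over repeats).
#' @slot perRepeat numeric matrix (repeats x 2) of half-sample estimates;
#'   \code{NA} where a half was skipped.
#' @slot seed integer seed that generated the splits.
#' @exportClass RcvEstimate
setClass("RcvEstimate",
    slots = c(sigma2 = "numeric", perRepeat = "matrix", seed = "integer"))

setValidity("RcvEstimate", function(object) {
    if (ncol(object@perRepeat) != 2L)
        return("exactly two half-sample estimates per repeat")
    if (!is.na(object@sigma2) && object@sigma2 < 0)
        return("sigma2 must be non-negative")
    TRUE
})

#' SreFit: final selected model for one tissue
#'
#' SREs and SRE pairs surviving the four-stage inference, with OLS refit
#' coefficients, p-values, BH-adjusted q-values, FDR flags, effect calls and
#' the percentage of variance explained.
#'
#' @slot tissue tissue label.
#' @slot results \code{DataFrame}, one row per selected feature.
#' @slot sigma2Rcv RCV residual-variance estimate used for model selection.
#' @slot residVariance OLS residual variance of the chosen model.
#' @slot lambda penalty at which the chosen model was read off the path.
#' @slot r2 percentage of variance explained by the FDR-passing model.
#' @slot n number of ASEs used in the fit.
#' @slot dropped character, columns dropped for collinearity during refit.
#' @slot notes character, warnings accumulated during selection.
#' @exportClass SreFit
setClass("SreFit",
    slots = c(tissue = "character", results = "DataFrame",
              sigma2Rcv = "numeric", residVariance = "numeric",
              lambda = "numeric", r2 = "numeric", n = "integer",
              dropped = "character", notes = "character"))

setValidity("SreFit", function(object) {
    if (nrow(object@results) > 0L) {
        need <- c("type", "hexamer1", "region1", "hexamer2", "region2",
                  "coefficient", "se", "pValue", "qValue", "passesFdr")
        if (!all(need %in% colnames(object@results)))
            return(paste("missing results columns:",
                         paste(setdiff(need, colnames(object@results)),
                               collapse = ", ")))
    }
    if (!is.na(object@r2) && object@r2 > 100)
        return("r2 cannot exceed 100 percent")
    TRUE
})
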