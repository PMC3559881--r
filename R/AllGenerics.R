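#' @include AllClasses.R
NULL

#' Accessors for spliceSRE classes
#'
#' \code{aseIds} returns ASE identifiers; \code{regionSeqs} the named list of
#' five \code{RNAStringSet}s; \code{designMatrix} the sparse 0/1 matrix;
#' \code{featureInfo} the per-column metadata; \code{inclusionRatios} and
#' \code{responses} the IR and centered-logit matrices; \code{modelResults}
#' the per-feature table of a fitted model; \code{explainedVariance} its
#' percentage of variance explained.
#'
#' @param x an object of the documented class.
#' @return the slot contents described above.
#' @name accessors
#' @aliases aseIds regionSeqs designMatrix featureInfo inclusionRatios
#'   responses modelResults explainedVariance
NULL

#' @rdname accessors
#' @export
setGeneric("aseIds", function(x) standardGeneric("aseIds"))

#' @rdname accessors
#' @export
setGeneric("regionSeqs", function(x) standardGeneric("regionSeqs"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname accessors
#' @export
setGeneric("inclusionRatios", function(x) standardGeneric("inclusionRatios"))

#' @rdname accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname accessors
#' @export
setGeneric("modelResults", function(x) standardGeneric("modelResults"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
setMethod("aseIds", "CassetteExons", function(x) mcols(x@ranges)$aseId)

#' @rdname accessors
setMethod("aseIds", "AseRegionSet", function(x) x@aseIds)

#' @rdname accessors
setMethod("aseIds", "SplicingResponse", function(x) rownames(x@ir))

#' @rdname accessors
setMethod("aseIds", "SpliceFeatureMatrix", function(x) rownames(x@mat))

#' @rdname accessors
setMethod("regionSeqs", "AseRegionSet", function(x) x@regions)

#' @rdname accessors
setMethod("designMatrix", "SpliceFeatureMatrix", function(x) x@mat)

#' @rdname accessors
setMethod("featureInfo", "SpliceFeatureMatrix", function(x) x@info)

#' @rdname accessors
setMethod("inclusionRatios", "SplicingResponse", function(x) x@ir)

#' @rdname accessors
setMethod("responses", "SplicingResponse", function(x) x@y)

#' @rdname accessors
setMethod("modelResults", "SreFit", function(x) x@results)

#' @rdname accessors
setMethod("explainedVariance", "SreFit", function(x) x@r2)

#' Coerce CassetteExons to GRanges
#'
#' @param x a \code{CassetteExons} object.
#' @return the underlying \code{GRanges} with all metadata columns.
#' @export
setGeneric("asGRanges", function(x) standardGeneric("asGRanges"))

#' @rdname asGRanges
setMethod("asGRanges", "CassetteExons", function(x) x@ranges)

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels:", length(object@exons), "transcripts,",
        length(unique(object@txGene$geneId)), "genes\n")
})

setMethod("show", "CassetteExons", function(object) {
    cat("CassetteExons:", length(object@ranges), "cassette exons\n")
    if (length(object@ranges)) {
        mc <- mcols(object@ranges)
        cat("  including isoforms per ASE:",
            paste(range(lengths(mc$includingTx)), collapse = "-"),
            " excluding:",
            paste(range(lengths(mc$excludingTx)), collapse = "-"), "\n")
    }
})

setMethod("show", "AseRegionSet", function(object) {
    cat("AseRegionSet:", length(object@aseIds), "ASEs x 5 regions (",
        paste(REGION_LABELS, collapse = ", "), ")\n")
})

setMethod("show", "SplicingResponse", function(object) {
    cat("SplicingResponse:", nrow(object@ir), "ASEs x", ncol(object@ir),
        "tissues; clipEpsilon =", object@clipEpsilon, "\n")
    cat("  valid (ASE, tissue) pairs:", sum(!is.na(object@y)), "\n")
})

setMethod("show", "SpliceFeatureMatrix", function(object) {
    n <- table(factor(object@info$type, levels = c("SRE", "pair")))
    cat("SpliceFeatureMatrix:", nrow(object@mat), "ASEs x",
        ncol(object@mat), "features (", n[["SRE"]], "SREs,", n[["pair"]],
        "pairs )\n")
})

setMethod("show", "PenalizedPath", function(object) {
    cat("PenalizedPath:", nrow(object@beta), "features,",
        length(object@lambda), "lambda values in [",
        signif(min(object@lambda), 3), ",", signif(max(object@lambda), 3),
        "]\n")
})

setMethod("show", "RcvEstimate", function(object) {
    cat("RcvEstimate: sigma2 =", signif(object@sigma2, 4), "over",
        nrow(object@perRepeat), "repeats\n")
})

setMethod("show", "SreFit", function(object) {
    res <- object@results
    cat("SreFit [", object@tissue, "]: n =", object@n, "ASEs\n")
    if (nrow(res)) {
        pass <- res$passesFdr
        cat("  selected:", sum(res$type == "SRE"), "SREs,",
            sum(res$type == "pair"), "pairs;", sum(pass), "pass FDR\n")
    } else {
        cat("  empty model\n")
    }
    cat("  R2 =", signif(object@r2, 4), "% ; sigma2(RCV) =",
        signif(object@sigma2Rcv, 4), "\n")
})
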