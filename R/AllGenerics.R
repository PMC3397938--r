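#' @describeIn TreeSample-class list of member trees
#' @param x,object a \code{TreeSample}
#' @export
setGeneric("trees", function(x) standardGeneric("trees"))

#' @describeIn TreeSample-class shared taxon set
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @describeIn TreeSample-class number of trees in the sample
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @describeIn CharacterColumn-class ordered state space
#' @export
setGeneric("stateSpace", function(x) standardGeneric("stateSpace"))

#' @describeIn CharacterColumn-class named taxon-to-code vector
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @describeIn AsrChain-class saved posterior samples as a data.frame
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @describeIn AsrChain-class posterior model frequencies
#' @export
setGeneric("modelPosterior", function(x) standardGeneric("modelPosterior"))

#' @describeIn AsrSummary-class marginal state probabilities per query node
#' @export
setGeneric("nodeProbs", function(x) standardGeneric("nodeProbs"))

setMethod("trees", "TreeSample", function(x) x@trees)
setMethod("taxa", "TreeSample", function(x) x@taxa)
setMethod("nTrees", "TreeSample", function(x) length(x@trees))
setMethod("stateSpace", "CharacterColumn", function(x) x@stateSpace)
setMethod("assignments", "CharacterColumn", function(x) x@assignments)
setMethod("samples", "AsrChain", function(x) x@samples)
setMethod("nodeProbs", "AsrSummary", function(x) x@nodeProbs)

setMethod("modelPosterior", "AsrChain", function(x) {
    tab <- table(factor(x@samples$model, levels = x@modelSpace@models))
    as.numeric(tab) / sum(tab) -> p
    names(p) <- x@modelSpace@models
    p
})
setMethod("modelPosterior", "AsrSummary", function(x) x@modelPosterior)

setMethod("show", "TreeSample", function(object) {
    cat(sprintf("TreeSample: %d trees over %d taxa\n",
                length(object@trees), length(object@taxa)))
    if (!is.na(object@provenance))
        cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "CharacterColumn", function(object) {
    a <- object@assignments
    cat(sprintf(
        "CharacterColumn '%s': %d states {%s}, %d taxa (%d missing)\n",
        object@name, length(object@stateSpace),
        paste(object@stateSpace, collapse = ","), length(a),
        sum(is.na(a))))
})

setMethod("show", "AsrChain", function(object) {
    cat(sprintf(
        "AsrChain: %d saved samples, %d-state character, %d models\n",
        nrow(object@samples), object@k, length(object@modelSpace@models)))
    cat(sprintf("  generations %g, burn-in %g, thin %g, seed %g\n",
                object@config@generations, object@config@burnin,
                object@config@thin, object@config@seed))
    acc <- object@acceptance
    cat("  acceptance:",
        paste(sprintf("%s %.2f", names(acc), acc), collapse = ", "), "\n")
})

setMethod("show", "AsrSummary", function(object) {
    cat(sprintf("AsrSummary for character '%s' (root prior: %s)\n",
                object@character, object@rootPrior))
    if (!is.na(object@qRatio))
        cat(sprintf("  q01/q10 (ratio of average rates): %.3f\n",
                    object@qRatio))
    cat(sprintf("  kappa: %.3f (95%% HPD %.3f-%.3f)\n", object@kappaMean,
                object@kappaHPD[1], object@kappaHPD[2]))
    if (nrow(object@nodeProbs)) {
        cat("  marginal P(state 0) at query nodes:\n")
        for (nm in rownames(object@nodeProbs))
            cat(sprintf("    %s: %.3f\n", nm, object@nodeProbs[nm, 1]))
    }
})
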