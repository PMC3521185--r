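## Generics, accessors and show methods.

#' @rdname ScoredPairTable-class
#' @param object,x an object.
#' @export
setGeneric("sourceName", function(object) standardGeneric("sourceName"))

#' @rdname ScoredPairTable-class
#' @export
setMethod("sourceName", "ScoredPairTable", function(object) object@sourceName)

#' @rdname ScoredPairTable-class
#' @export
setGeneric("scoredPairs", function(object) standardGeneric("scoredPairs"))

#' @rdname ScoredPairTable-class
#' @export
setMethod("scoredPairs", "ScoredPairTable", function(object) object@pairs)

#' Protein IDs of an object
#'
#' @param object a [ScoredPairTable-class], [CompositeNetwork-class],
#'   [ReferenceComplexSet-class] or [ClusterSet-class].
#' @return sorted character vector of distinct protein IDs.
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "ScoredPairTable", function(object)
    sort(unique(c(object@pairs$proteinA, object@pairs$proteinB))))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "CompositeNetwork", function(object)
    sort(unique(c(object@edges$proteinA, object@edges$proteinB))))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "ReferenceComplexSet", function(object)
    sort(unique(unlist(object@complexes, use.names = FALSE))))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "ClusterSet", function(object)
    sort(unique(unlist(object@members, use.names = FALSE))))

#' @rdname ReferenceComplexSet-class
#' @param object an object.
#' @export
setGeneric("complexes", function(object) standardGeneric("complexes"))

#' @rdname ReferenceComplexSet-class
#' @export
setMethod("complexes", "ReferenceComplexSet", function(object)
    object@complexes)

#' @rdname ReferenceComplexSet-class
#' @export
setGeneric("complexRole", function(object) standardGeneric("complexRole"))

#' @rdname ReferenceComplexSet-class
#' @export
setMethod("complexRole", "ReferenceComplexSet", function(object) object@role)

#' Edge table of a composite network
#'
#' @param object a [CompositeNetwork-class].
#' @return \code{edgeTable}: data.frame with the canonical pair columns,
#'   one feature column per source and, when present, \code{label} and
#'   \code{weight} columns.
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "CompositeNetwork", function(object) {
    out <- cbind(object@edges, as.data.frame(object@features))
    if (length(object@labels)) out$label <- object@labels
    if (length(object@weights)) out$weight <- object@weights
    out
})

#' @rdname edgeTable
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname edgeTable
#' @export
setMethod("edgeCount", "CompositeNetwork", function(object)
    nrow(object@edges))

#' @rdname edgeTable
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname edgeTable
#' @export
setMethod("featureNames", "CompositeNetwork", function(object)
    colnames(object@features))

#' @rdname edgeTable
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname edgeTable
#' @export
setMethod("featureMatrix", "CompositeNetwork", function(object)
    object@features)

#' @rdname edgeTable
#' @export
setGeneric("edgeLabels", function(object) standardGeneric("edgeLabels"))

#' @rdname edgeTable
#' @export
setMethod("edgeLabels", "CompositeNetwork", function(object) object@labels)

#' @rdname edgeTable
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @rdname edgeTable
#' @export
setMethod("edgeWeights", "CompositeNetwork", function(object) object@weights)

#' Accessors for ClusterSet
#'
#' @param object a [ClusterSet-class].
#' @name ClusterSet-accessors
NULL

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterMembers", function(object) standardGeneric("clusterMembers"))

#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterMembers", "ClusterSet", function(object) object@members)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterDensities", function(object)
    standardGeneric("clusterDensities"))

#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterDensities", "ClusterSet", function(object) object@density)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterScores", function(object) standardGeneric("clusterScores"))

#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterScores", "ClusterSet", function(object) object@score)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterProvenance", function(object)
    standardGeneric("clusterProvenance"))

#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterProvenance", "ClusterSet", function(object)
    object@provenance)

#' @rdname PRCurve-class
#' @param object an object.
#' @export
setGeneric("prPoints", function(object) standardGeneric("prPoints"))

#' @rdname PRCurve-class
#' @export
setMethod("prPoints", "PRCurve", function(object) object@points)

#' @rdname PRCurve-class
#' @export
setGeneric("prAuc", function(object) standardGeneric("prAuc"))

#' @rdname PRCurve-class
#' @export
setMethod("prAuc", "PRCurve", function(object) object@auc)

#' @rdname CalibrationTable-class
#' @param object an object.
#' @export
setGeneric("calibrationBins", function(object)
    standardGeneric("calibrationBins"))

#' @rdname CalibrationTable-class
#' @export
setMethod("calibrationBins", "CalibrationTable", function(object)
    object@bins)

## length methods --------------------------------------------------------------

#' @describeIn ScoredPairTable-class number of pairs.
#' @export
setMethod("length", "ScoredPairTable", function(x) nrow(x@pairs))

#' @describeIn ReferenceComplexSet-class number of complexes.
#' @export
setMethod("length", "ReferenceComplexSet", function(x) length(x@complexes))

#' @describeIn ClusterSet-class number of clusters.
#' @export
setMethod("length", "ClusterSet", function(x) length(x@members))

## show methods ----------------------------------------------------------------

setMethod("show", "ScoredPairTable", function(object) {
    cat("ScoredPairTable '", object@sourceName, "': ", nrow(object@pairs),
        " pairs, ", length(proteinIds(object)), " proteins\n", sep = "")
    if (nrow(object@pairs))
        cat("  score range: [", signif(min(object@pairs$score), 4), ", ",
            signif(max(object@pairs$score), 4), "]\n", sep = "")
})

setMethod("show", "ReferenceComplexSet", function(object) {
    sz <- lengths(object@complexes)
    cat("ReferenceComplexSet (", object@role, "): ", length(sz),
        " complexes, ", length(proteinIds(object)), " proteins\n", sep = "")
    if (length(sz))
        cat("  sizes: min ", min(sz), ", median ", stats::median(sz),
            ", max ", max(sz), "\n", sep = "")
})

setMethod("show", "CompositeNetwork", function(object) {
    cat("CompositeNetwork: ", nrow(object@edges), " edges, ",
        length(proteinIds(object)), " proteins, sources: ",
        paste(colnames(object@features), collapse = ", "), "\n", sep = "")
    if (length(object@labels))
        cat("  labelled: ", sum(object@labels == "co-complex"),
            " co-complex / ", sum(object@labels == "non-co-complex"),
            " non-co-complex\n", sep = "")
    if (length(object@weights))
        cat("  weighted: posterior in [",
            signif(min(object@weights), 4), ", ",
            signif(max(object@weights), 4), "]\n", sep = "")
})

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet: ", length(object@members), " clusters",
        sep = "")
    if (length(object@members)) {
        algos <- sort(unique(unlist(object@provenance)))
        cat(" (sizes ", min(lengths(object@members)), "-",
            max(lengths(object@members)), "), algorithms: ",
            paste(algos, collapse = ", "), sep = "")
    }
    cat("\n")
})

setMethod("show", "DiscretizationScheme", function(object) {
    cat("DiscretizationScheme: ", sum(!object@dropped), " retained, ",
        sum(object@dropped), " dropped feature(s)\n", sep = "")
    for (f in names(object@cuts)) {
        if (object@dropped[[f]]) {
            cat("  ", f, ": dropped\n", sep = "")
        } else {
            cat("  ", f, ": cuts at ",
                paste(signif(object@cuts[[f]], 4), collapse = ", "),
                "\n", sep = "")
        }
    }
})

setMethod("show", "NaiveBayesModel", function(object) {
    cat("NaiveBayesModel: priors P(co-complex) = ",
        signif(object@priors[["co-complex"]], 4),
        ", features: ", paste(names(object@condProb), collapse = ", "),
        ", alpha = ", object@alpha, "\n", sep = "")
})

setMethod("show", "PRCurve", function(object) {
    cat("PRCurve: ", nrow(object@points), " thresholds, AUC = ",
        signif(object@auc, 4), "\n", sep = "")
})

setMethod("show", "CalibrationTable", function(object) {
    cat("CalibrationTable: ", nrow(object@bins), " score bins, precision ",
        sep = "")
    if (nrow(object@bins))
        cat("[", signif(min(object@bins$precision), 3), ", ",
            signif(max(object@bins$precision), 3), "]", sep = "")
    cat("\n")
})

setMethod("show", "OntologyDag", function(object) {
    ns <- table(object@namespace)
    cat("OntologyDag: ", length(object@terms), " terms (",
        paste(sprintf("%s: %d", names(ns), as.integer(ns)), collapse = ", "),
        ")\n", sep = "")
})

setMethod("show", "AnnotationMap", function(object) {
    cat("AnnotationMap: ", length(unique(object@table$protein)),
        " proteins, ", nrow(object@table), " annotations\n", sep = "")
})
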