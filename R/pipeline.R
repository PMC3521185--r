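## End-to-end convenience wrappers: supervised weighting of a composite
## network and complex prediction on the weighted result.

#' Supervised weighting of a composite network
#'
#' Labels the network's edges from the training complexes, discretizes
#' every feature (entropy/MDL), fits the two-class naive-Bayes model and
#' weights every edge with its posterior co-complex probability.
#'
#' @param network an unlabelled [CompositeNetwork-class].
#' @param training a [ReferenceComplexSet-class].
#' @param alpha smoothing pseudocount for the conditionals.
#' @return list with the weighted \code{network}, the fitted
#'   \code{model} and the \code{scheme}.
#' @export
supervisedWeight <- function(network, training, alpha = 1) {
    labelled <- labelEdges(network, training)
    scheme <- discretizeFeatures(labelled)
    model <- fitNaiveBayes(labelled, scheme, alpha = alpha)
    list(network = weightEdges(labelled, model), model = model,
         scheme = scheme)
}

#' Predict complexes on a weighted network
#'
#' Keeps the top-k highest-weighted edges, runs every clusterer on the
#' reduced network and aggregates the clusterings with similarity voting
#' (see [combineClusters()]). Densities are scored against the full
#' weighted network.
#'
#' @param network a weighted [CompositeNetwork-class].
#' @param k number of top-weighted edges used for clustering (NULL keeps
#'   all edges).
#' @param clusterers named list of functions taking a weighted network
#'   and returning a [ClusterSet-class].
#' @param minClusterSize smallest cluster reported (default 4).
#' @param similarityThres Jaccard threshold for the vote grouping.
#' @return the aggregated [ClusterSet-class].
#' @export
predictComplexes <- function(network, k = 10000L,
                             clusterers = list(
                                 mcl = function(net) mclCluster(net),
                                 cmc = function(net) cmcCluster(net)),
                             minClusterSize = 4L,
                             similarityThres = 0.75) {
    stopifnot(is(network, "CompositeNetwork"))
    if (!length(network@weights)) stop("network must be weighted")
    input <- if (is.null(k)) network else topKEdges(network, k)
    sets <- list()
    for (nm in names(clusterers)) {
        cs <- tryCatch(clusterers[[nm]](input), error = function(e) {
            warning("clusterer '", nm, "' failed: ", conditionMessage(e))
            NULL
        })
        if (!is.null(cs) && length(cs@members)) sets[[nm]] <- cs
    }
    if (!length(sets)) stop("all clusterers failed")
    combineClusters(sets, network, similarityThres = similarityThres,
                    minSize = minClusterSize)
}
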