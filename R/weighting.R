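## Supervised edge labelling, naive-Bayes fitting, posterior weighting,
## likelihood-ratio export and top-k edge selection.

## Unordered co-member pair keys of a complex set.
.coMemberKeys <- function(complexSet) {
    keys <- lapply(complexSet@complexes, function(m) {
        if (length(m) < 2L) return(character())
        pr <- utils::combn(sort(m), 2L)
        .pairKeys(pr[1L, ], pr[2L, ])
    })
    unique(unlist(keys, use.names = FALSE))
}

#' Label composite-network edges from training complexes
#'
#' An edge (u, v) is labelled co-complex iff some single training complex
#' contains both u and v; every other edge is labelled non-co-complex.
#'
#' @param network a [CompositeNetwork-class].
#' @param training a [ReferenceComplexSet-class] used as training set.
#' @return the network with the \code{labels} slot filled.
#' @export
labelEdges <- function(network, training) {
    stopifnot(is(network, "CompositeNetwork"),
              is(training, "ReferenceComplexSet"))
    if (!length(training@complexes))
        stop("training complex set is empty; supervision impossible")
    co <- .coMemberKeys(training)
    keys <- .pairKeys(network@edges$proteinA, network@edges$proteinB)
    network@labels <- ifelse(keys %in% co, "co-complex", "non-co-complex")
    validObject(network)
    network
}

## Build a model from count tables (shared by fitNaiveBayes and the
## model reader).
.modelFromCounts <- function(scheme, classCounts, counts, alpha) {
    condProb <- lapply(counts, function(m) {
        nb <- ncol(m)
        p <- (m + alpha) / (rowSums(m) + alpha * nb)
        rownames(p) <- rownames(m)
        p
    })
    priors <- classCounts / sum(classCounts)
    new("NaiveBayesModel", scheme = scheme, classCounts = classCounts,
        counts = counts, condProb = condProb, priors = priors,
        alpha = alpha)
}

#' Fit the two-class naive-Bayes co-complex model
#'
#' Tallies labelled edges per (class, feature, bin) and estimates the
#' maximum-likelihood conditionals P(F = f | class) = n_{class,F=f} /
#' n_class, smoothed with pseudocount \code{alpha} on the conditionals
#' only: P = (count + alpha) / (class total + alpha * nbins). Class priors
#' are the unsmoothed label frequencies among the network's edges.
#'
#' @param network a labelled [CompositeNetwork-class].
#' @param scheme a [DiscretizationScheme-class] covering the features.
#' @param alpha smoothing pseudocount (default 1); guarantees positive
#'   probabilities and finite likelihood ratios for empty bins.
#' @return A [NaiveBayesModel-class].
#' @export
fitNaiveBayes <- function(network, scheme, alpha = 1) {
    stopifnot(is(network, "CompositeNetwork"),
              is(scheme, "DiscretizationScheme"), alpha >= 0)
    if (!length(network@labels)) stop("network must be labelled")
    retained <- names(scheme@dropped)[!scheme@dropped]
    retained <- intersect(retained, colnames(network@features))
    if (!length(retained)) stop("no informative features")
    isCo <- network@labels == "co-complex"
    classCounts <- c("co-complex" = sum(isCo),
                     "non-co-complex" = sum(!isCo))
    counts <- lapply(retained, function(f) {
        nb <- length(scheme@cuts[[f]]) + 1L
        b <- binValues(network@features[, f], scheme@cuts[[f]])
        rbind("co-complex" = tabulate(b[isCo], nbins = nb),
              "non-co-complex" = tabulate(b[!isCo], nbins = nb))
    })
    names(counts) <- retained
    .modelFromCounts(scheme, classCounts, counts, alpha)
}

## Log conditional probabilities looked up per edge; features is a numeric
## matrix with named columns covering the model's retained features.
.logLikelihoods <- function(model, features) {
    need <- names(model@condProb)
    missing <- setdiff(need, colnames(features))
    if (length(missing))
        stop("feature(s) unknown to input: ", paste(missing, collapse = ", "))
    n <- nrow(features)
    logCo <- rep(log(model@priors[["co-complex"]]), n)
    logNon <- rep(log(model@priors[["non-co-complex"]]), n)
    for (f in need) {
        b <- binValues(features[, f], model@scheme@cuts[[f]])
        logCo <- logCo + log(model@condProb[[f]]["co-complex", b])
        logNon <- logNon + log(model@condProb[[f]]["non-co-complex", b])
    }
    cbind(co = logCo, non = logNon)
}

#' Posterior co-complex probability of feature vectors
#'
#' Computes the normalized two-class naive-Bayes posterior
#' \deqn{w = \frac{\prod_i P(F_i = f_i | co) P(co)}{\prod_i P(F_i = f_i |
#'   co) P(co) + \prod_i P(F_i = f_i | non) P(non)}}
#' with log-space accumulation for numerical safety.
#'
#' @param model a fitted [NaiveBayesModel-class].
#' @param features named numeric vector (one edge) or numeric matrix with
#'   one named column per feature (one row per edge). Features the model
#'   does not know are ignored only if dropped by the scheme; a feature the
#'   model requires but the input lacks is an error.
#' @return numeric posterior weight(s) in (0, 1).
#' @export
posteriorWeight <- function(model, features) {
    stopifnot(is(model, "NaiveBayesModel"))
    if (is.null(dim(features)))
        features <- matrix(features, nrow = 1L,
                           dimnames = list(NULL, names(features)))
    ll <- .logLikelihoods(model, features)
    as.numeric(1 / (1 + exp(ll[, "non"] - ll[, "co"])))
}

#' Weight every edge of the composite network
#'
#' @param network a [CompositeNetwork-class].
#' @param model a fitted [NaiveBayesModel-class].
#' @return the network with the \code{weights} slot set to the posterior
#'   co-complex probability of each edge.
#' @export
weightEdges <- function(network, model) {
    stopifnot(is(network, "CompositeNetwork"))
    network@weights <- posteriorWeight(model, network@features)
    validObject(network)
    network
}

#' Assign uniform edge weights
#'
#' Gives every edge the same weight (default 1) — the unweighted baseline
#' in which clustering sees only the network topology.
#'
#' @param network a [CompositeNetwork-class].
#' @param value weight value.
#' @return the network with constant weights.
#' @export
uniformWeights <- function(network, value = 1) {
    network@weights <- rep(value, nrow(network@edges))
    validObject(network)
    network
}

#' Likelihood-ratio table of a fitted model
#'
#' Reports, per retained feature and bin, how many times likelier an edge
#' with that feature value is to be co-complex than non-co-complex:
#' P(F = f | co-complex) / P(F = f | non-co-complex), using the smoothed
#' conditionals (so all ratios are finite and positive). Bins are reported
#' with their cut-point ranges.
#'
#' @param model a fitted [NaiveBayesModel-class].
#' @return data.frame with columns \code{feature}, \code{bin}, \code{lo},
#'   \code{hi}, \code{pCo}, \code{pNon}, \code{ratio}, ordered by feature
#'   then bin.
#' @export
likelihoodRatioTable <- function(model) {
    stopifnot(is(model, "NaiveBayesModel"))
    out <- lapply(names(model@condProb), function(f) {
        rng <- binRanges(model@scheme, f)
        p <- model@condProb[[f]]
        data.frame(feature = f, bin = rng$bin, lo = rng$lo, hi = rng$hi,
                   pCo = p["co-complex", ], pNon = p["non-co-complex", ],
                   ratio = p["co-complex", ] / p["non-co-complex", ],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Keep the top-k highest-weighted edges
#'
#' Selects the k edges with the largest posterior weights; ties at the
#' boundary are broken by the canonical (lexicographic) edge key so the
#' output has exactly min(k, |E|) edges. Proteins left without edges are
#' dropped from the vertex set implicitly (the network is edge-defined).
#'
#' @param network a weighted [CompositeNetwork-class].
#' @param k positive integer.
#' @return the reduced network.
#' @export
topKEdges <- function(network, k) {
    stopifnot(is(network, "CompositeNetwork"))
    if (!is.numeric(k) || length(k) != 1L || k <= 0)
        stop("k must be a positive integer")
    if (!length(network@weights)) stop("network must be weighted")
    keep <- head(order(-network@weights, network@edges$proteinA,
                       network@edges$proteinB), k)
    keep <- sort(keep)
    network@edges <- network@edges[keep, , drop = FALSE]
    rownames(network@edges) <- NULL
    network@features <- network@features[keep, , drop = FALSE]
    if (length(network@labels)) network@labels <- network@labels[keep]
    network@weights <- network@weights[keep]
    validObject(network)
    network
}

#' Export the likelihood network of a predicted cluster
#'
#' Writes a multi-edge GraphML file visualizing the component evidence of
#' a cluster: one edge per (protein pair, data source with non-zero value)
#' among the cluster's members, attributed with the source name, the raw
#' score, the bin index, the likelihood ratio of that bin (the edge's
#' co-complexness strength, intended to scale edge thickness) and the
#' pair's posterior weight.
#'
#' @param network a [CompositeNetwork-class] containing the cluster's
#'   members.
#' @param model the fitted [NaiveBayesModel-class].
#' @param members character vector of cluster member proteins.
#' @param path output file path (GraphML).
#' @return invisibly, the data.frame of exported edges.
#' @export
exportLikelihoodNetwork <- function(network, model, members, path) {
    stopifnot(is(network, "CompositeNetwork"),
              is(model, "NaiveBayesModel"))
    members <- sort(unique(as.character(members)))
    if (!all(members %in% proteinIds(network)))
        stop("cluster members absent from network: ",
             paste(setdiff(members, proteinIds(network)), collapse = ", "))
    keys <- .pairKeys(network@edges$proteinA, network@edges$proteinB)
    pr <- utils::combn(members, 2L)
    idx <- match(.pairKeys(pr[1L, ], pr[2L, ]), keys)
    present <- which(!is.na(idx))
    idx <- idx[present]
    lrt <- likelihoodRatioTable(model)
    post <- posteriorWeight(model, network@features[idx, , drop = FALSE])
    rows <- list()
    for (f in names(model@condProb)) {
        val <- network@features[idx, f]
        nz <- which(val != 0)
        if (!length(nz)) next
        b <- binValues(val[nz], model@scheme@cuts[[f]])
        ratio <- lrt$ratio[match(paste(f, b), paste(lrt$feature, lrt$bin))]
        rows[[f]] <- data.frame(
            from = pr[1L, present][nz], to = pr[2L, present][nz],
            source = f, value = val[nz], bin = b, likelihoodRatio = ratio,
            posterior = post[nz], stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(edges))
        edges <- data.frame(from = character(), to = character(),
                            source = character(), value = numeric(),
                            bin = integer(), likelihoodRatio = numeric(),
                            posterior = numeric())
    g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = members, stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
    invisible(edges)
}
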