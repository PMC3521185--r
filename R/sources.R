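## Built-in data-source scoring: iterative shared-neighbour reliability
## weighting of physical interactions (with level-2 pair imputation),
## literature co-occurrence Jaccard scores, and composite-network assembly.

#' Read an interaction edge list
#'
#' Tab-separated file with two columns (proteinA, proteinB); an optional
#' third weight column is ignored with a warning (interaction inputs are
#' unweighted observations, initial weights are 1). Self-loops are dropped
#' with a warning and duplicate pairs collapsed.
#'
#' @param path file path.
#' @return data.frame with canonical columns \code{proteinA},
#'   \code{proteinB}.
#' @export
readInteractions <- function(path) {
    if (!file.exists(path)) stop("interaction file not found: ", path)
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    parts <- strsplit(raw, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
        stop("line ", which(lengths(parts) < 2L)[1L],
             ": expected >= 2 tab-separated columns")
    if (any(lengths(parts) > 2L))
        warning("third column present in ", path,
                "; interaction weights are ignored (initial weights are 1)")
    tab <- ScoredPairTable(vapply(parts, `[`, character(1), 1L),
                           vapply(parts, `[`, character(1), 2L),
                           rep(1, length(parts)), sourceName = "interactions")
    tab@pairs[c("proteinA", "proteinB")]
}

## Sparse symmetric adjacency over the interaction pattern.
.adjacency <- function(pairs, vertices, weights = NULL) {
    i <- match(pairs$proteinA, vertices)
    j <- match(pairs$proteinB, vertices)
    x <- if (is.null(weights)) rep(1, length(i)) else weights
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                         dims = c(length(vertices), length(vertices)))
}

#' Iterative shared-neighbour interaction scoring (AdjustCD)
#'
#' Scores every protein pair with at least one shared interaction partner
#' by the iterated, degree-penalized shared-neighbour measure: at iteration
#' k,
#' \deqn{w_k(u,v) = \frac{\sum_{x \in N_u \cap N_v} (w_{k-1}(u,x) +
#'   w_{k-1}(v,x))}{\max(\sum_{x \in N_u} w_{k-1}(u,x), \lambda) +
#'   \max(\sum_{x \in N_v} w_{k-1}(v,x), \lambda)}}
#' where \eqn{N_u} is the observed interaction neighbourhood of u (fixed
#' across iterations), all \eqn{w_0 = 1}, and \eqn{\lambda} is the mean
#' weighted degree at the previous iteration (a penalty for sparsely
#' connected proteins). Two tables are returned: the observed interactions
#' with their final score, excluding interactions whose proteins share no
#' neighbour (regarded as unreliable and discarded), and the level-2 pairs
#' (non-interacting pairs with shared neighbours) whose final score exceeds
#' \code{l2Threshold}, imputed as new relationships.
#'
#' @param interactions data.frame with columns \code{proteinA},
#'   \code{proteinB} (see [readInteractions()]).
#' @param iterations number of iterations (default 2).
#' @param l2Threshold strict score cutoff for imputed level-2 pairs
#'   (default 0.1).
#' @param sourceNames labels for the two returned tables.
#' @return list with elements \code{ppi} and \code{l2}, both
#'   [ScoredPairTable-class] objects.
#' @export
iterativeAdjustCD <- function(interactions, iterations = 2,
                              l2Threshold = 0.1,
                              sourceNames = c("ppi", "l2")) {
    stopifnot(iterations >= 1, l2Threshold >= 0, l2Threshold < 1)
    cp <- .canonicalPairs(interactions$proteinA, interactions$proteinB)
    pairs <- unique(data.frame(proteinA = cp$proteinA,
                               proteinB = cp$proteinB,
                               stringsAsFactors = FALSE))
    pairs <- pairs[pairs$proteinA != pairs$proteinB, , drop = FALSE]
    if (!nrow(pairs)) stop("interaction graph is empty")
    vertices <- sort(unique(c(pairs$proteinA, pairs$proteinB)))
    B <- .adjacency(pairs, vertices)           # fixed observed pattern
    A <- B                                     # iteration weights, w0 = 1
    W <- NULL
    for (k in seq_len(iterations)) {
        deg <- Matrix::rowSums(A)
        lambda <- mean(deg)
        denom <- pmax(deg, lambda)
        Num <- A %*% B + B %*% A
        T <- as(as(Num, "generalMatrix"), "TsparseMatrix")
        keep <- T@i < T@j                       # upper triangle, no diagonal
        ti <- T@i[keep] + 1L
        tj <- T@j[keep] + 1L
        tx <- T@x[keep] / (denom[ti] + denom[tj])
        W <- list(i = ti, j = tj, x = tx)
        ## next iteration reuses the observed pattern with updated weights
        if (k < iterations) {
            A <- Matrix::sparseMatrix(
                i = c(W$i, W$j), j = c(W$j, W$i), x = c(W$x, W$x),
                dims = dim(B))
            A <- A * B                          # restrict to observed edges
        }
    }
    observed <- as.logical(B[cbind(W$i, W$j)])
    mkTable <- function(sel, name) {
        ScoredPairTable(vertices[W$i[sel]], vertices[W$j[sel]], W$x[sel],
                        sourceName = name)
    }
    ppi <- mkTable(observed & W$x > 0, sourceNames[1L])
    l2 <- mkTable(!observed & W$x > l2Threshold, sourceNames[2L])
    list(ppi = ppi, l2 = l2)
}

#' Literature co-occurrence scores
#'
#' Scores every protein pair that co-occurs in at least
#' \code{max(1, minDocs)} documents by the Jaccard similarity of their
#' document sets: \eqn{s = |A_u \cap A_v| / |A_u \cup A_v|}, where
#' \eqn{A_x} is the set of documents mentioning protein x. Pairs with an
#' empty intersection are omitted.
#'
#' @param incidence named list mapping protein to a character vector of
#'   document IDs (see [readLiteratureIncidence()]).
#' @param minDocs minimum co-occurrence count (default 1; larger values
#'   bound memory on dense incidences).
#' @param sourceName label for the returned table.
#' @return A [ScoredPairTable-class].
#' @export
literatureJaccard <- function(incidence, minDocs = 1,
                              sourceName = "pubmed") {
    if (!length(incidence)) stop("literature incidence is empty")
    incidence <- lapply(incidence, unique)
    proteins <- names(incidence)
    docs <- sort(unique(unlist(incidence, use.names = FALSE)))
    i <- rep(seq_along(incidence), lengths(incidence))
    j <- match(unlist(incidence, use.names = FALSE), docs)
    M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(proteins), length(docs)))
    Int <- Matrix::tcrossprod(M)
    sizes <- Matrix::rowSums(M)
    T <- as(as(Int, "generalMatrix"), "TsparseMatrix")
    keep <- T@i < T@j & T@x >= max(1, minDocs)
    ti <- T@i[keep] + 1L
    tj <- T@j[keep] + 1L
    inter <- T@x[keep]
    s <- inter / (sizes[ti] + sizes[tj] - inter)
    ScoredPairTable(proteins[ti], proteins[tj], s, sourceName = sourceName)
}

#' Assemble the composite network
#'
#' Takes the union of the scored pairs of all data sources: the composite
#' network has an edge between u and v iff at least one source relates
#' them. Each edge's feature vector has one entry per source, with value 0
#' for sources that do not relate the pair.
#'
#' @param tables list of [ScoredPairTable-class] objects with distinct
#'   source names.
#' @return A [CompositeNetwork-class] (unlabelled, unweighted).
#' @export
assembleComposite <- function(tables) {
    stopifnot(is.list(tables))
    if (!length(tables)) {
        return(new("CompositeNetwork",
                   edges = data.frame(proteinA = character(),
                                      proteinB = character()),
                   features = matrix(numeric(), 0, 0),
                   labels = character(), weights = numeric()))
    }
    stopifnot(all(vapply(tables, is, logical(1), "ScoredPairTable")))
    srcs <- vapply(tables, sourceName, character(1))
    if (anyDuplicated(srcs))
        stop("duplicate source name: ", srcs[duplicated(srcs)][1L])
    keys <- lapply(tables, function(t)
        .pairKeys(t@pairs$proteinA, t@pairs$proteinB))
    allKeys <- sort(unique(unlist(keys, use.names = FALSE)))
    feat <- matrix(0, nrow = length(allKeys), ncol = length(tables),
                   dimnames = list(NULL, srcs))
    for (s in seq_along(tables))
        feat[match(keys[[s]], allKeys), s] <- tables[[s]]@pairs$score
    parts <- strsplit(allKeys, "\t", fixed = TRUE)
    edges <- data.frame(
        proteinA = vapply(parts, `[`, character(1), 1L),
        proteinB = vapply(parts, `[`, character(1), 2L),
        stringsAsFactors = FALSE)
    new("CompositeNetwork", edges = edges, features = feat,
        labels = character(), weights = numeric())
}
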