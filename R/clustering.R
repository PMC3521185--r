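## Native clusterers (Markov clustering, maximal-clique merging), weighted
## density scoring and the voting-based aggregation of multiple clusterings.

## Fast pair-key -> weight lookup closure over a weighted network.
.densityFun <- function(network) {
    if (!length(network@weights)) stop("network is not weighted")
    keys <- .pairKeys(network@edges$proteinA, network@edges$proteinB)
    env <- new.env(hash = TRUE, size = max(29L, length(keys)))
    w <- network@weights
    for (i in seq_along(keys)) assign(keys[i], w[i], envir = env)
    function(members) {
        n <- length(members)
        if (n < 2L) stop("weighted density needs >= 2 members")
        members <- sort(members)
        pr <- utils::combn(members, 2L)
        k <- .pairKeys(pr[1L, ], pr[2L, ])
        s <- sum(unlist(mget(k, envir = env, ifnotfound = 0),
                        use.names = FALSE))
        2 * s / (n * (n - 1))
    }
}

#' Weighted density of a protein set
#'
#' \deqn{dens_C = \frac{\sum_{u \in C, v \in C} w_{u,v}}{|C|(|C|-1)}}
#' (each unordered pair counted twice in the numerator); pairs with no
#' edge contribute 0. The base score of every predicted cluster.
#'
#' @param members character vector of >= 2 proteins.
#' @param network a weighted [CompositeNetwork-class].
#' @return the weighted density (in [0, 1] when weights are).
#' @export
weightedDensity <- function(members, network) {
    stopifnot(is(network, "CompositeNetwork"))
    .densityFun(network)(unique(as.character(members)))
}

#' Rescore a cluster set against a weighted network
#'
#' Recomputes every cluster's weighted density on the given network and
#' resets its score to the density (provenance kept). Clusters referencing
#' proteins absent from the network get 0 weight for the missing pairs
#' (with a warning).
#'
#' @param clusters a [ClusterSet-class].
#' @param network a weighted [CompositeNetwork-class].
#' @return the rescored [ClusterSet-class].
#' @export
rescoreClusters <- function(clusters, network) {
    stopifnot(is(clusters, "ClusterSet"))
    dens <- .densityFun(network)
    known <- proteinIds(network)
    out <- sort(unique(unlist(clusters@members, use.names = FALSE)))
    if (length(setdiff(out, known)))
        warning("clusters reference ", length(setdiff(out, known)),
                " protein(s) absent from the network; their pairs weigh 0")
    d <- vapply(clusters@members, dens, numeric(1))
    clusters@density <- d
    clusters@score <- d
    clusters
}

## igraph over the weighted edge structure.
.toIgraph <- function(network, weighted = TRUE) {
    df <- network@edges
    if (weighted && length(network@weights)) df$weight <- network@weights
    igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Markov clustering (MCL)
#'
#' Simulates stochastic flow on the weighted network to enhance the
#' contrast between regions of strong and weak flow: the column-stochastic
#' transition matrix (edge weights plus unit self-loops) is alternately
#' expanded (matrix squaring) and inflated (element-wise power followed by
#' column renormalization, with entries below \code{prune} zeroed for
#' tractability) until the matrix changes by less than \code{tol} or
#' \code{maxIter} is reached (non-convergence returns the current state
#' with a warning). Clusters are the connected components of the
#' attractor's non-zero structure — a partition of the vertices.
#'
#' @param network a weighted [CompositeNetwork-class].
#' @param inflation inflation exponent (> 1; typical grid 2, 3, 4).
#' @param expansion expansion power (default 2).
#' @param maxIter maximum iterations (default 100).
#' @param tol convergence tolerance on the max element-wise change.
#' @param prune entries below this are zeroed after inflation.
#' @param select keep at most this many largest entries per column after
#'   pruning (resource bound on dense intermediates).
#' @param minSize smallest cluster reported (default 2).
#' @return A [ClusterSet-class] with provenance \code{"mcl"}, scored by
#'   weighted density on \code{network}.
#' @export
mclCluster <- function(network, inflation = 2, expansion = 2,
                       maxIter = 100L, tol = 1e-6, prune = 1e-5,
                       select = 500L, minSize = 2L) {
    stopifnot(is(network, "CompositeNetwork"), inflation > 1, tol > 0,
              expansion >= 2)
    if (!nrow(network@edges)) stop("network is empty")
    if (!length(network@weights)) stop("network must be weighted")
    vertices <- proteinIds(network)
    n <- length(vertices)
    A <- .adjacency(network@edges, vertices, network@weights) +
        Matrix::Diagonal(n)                       # unit self-loops
    normalize <- function(M) {
        cs <- Matrix::colSums(M)
        cs[cs == 0] <- 1
        M %*% Matrix::Diagonal(x = 1 / cs)
    }
    selectTop <- function(M) {
        T <- as(as(M, "generalMatrix"), "TsparseMatrix")
        nnzCol <- tabulate(T@j + 1L, nbits <- ncol(M))
        if (all(nnzCol <= select)) return(M)
        o <- order(T@j, -T@x)
        pos <- sequence(nnzCol)                   # rank within column
        keep <- o[pos <= select]
        Matrix::sparseMatrix(i = T@i[keep] + 1L, j = T@j[keep] + 1L,
                             x = T@x[keep], dims = dim(M))
    }
    M <- normalize(A)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        M2 <- M
        for (e in seq_len(expansion - 1L)) M2 <- M2 %*% M
        M2 <- as(M2, "CsparseMatrix")
        M2@x <- M2@x^inflation                     # inflation
        M2@x[M2@x < prune] <- 0
        M2 <- Matrix::drop0(M2)
        M2 <- selectTop(M2)
        M2 <- normalize(M2)
        delta <- max(abs(M2 - M))
        M <- M2
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("MCL did not converge within ", maxIter,
                " iterations; using current state")
    P <- (M != 0) | Matrix::t(M != 0)
    g <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
    groups <- split(vertices, comp$membership)
    groups <- groups[lengths(groups) >= max(2L, minSize)]
    dens <- .densityFun(network)
    d <- vapply(groups, dens, numeric(1))
    ClusterSet(members = unname(groups), density = unname(d),
               score = unname(d), provenance = "mcl")
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of the network's (unweighted) edge structure, via
#' pivoting Bron-Kerbosch.
#'
#' @param network a [CompositeNetwork-class].
#' @param minSize smallest clique returned (default 2).
#' @return list of sorted character vectors.
#' @export
maximalCliques <- function(network, minSize = 2L) {
    stopifnot(is(network, "CompositeNetwork"))
    g <- .toIgraph(network, weighted = FALSE)
    cl <- igraph::max_cliques(g, min = minSize)
    out <- lapply(cl, function(x) sort(igraph::V(g)$name[as.integer(x)]))
    out[order(vapply(out, paste, character(1), collapse = "\t"))]
}

## Mean posterior weight over all pairs between the non-shared part of the
## smaller cluster and the larger cluster (absent edges weigh 0).
.interConnectivity <- function(a, b, weightEnv) {
    if (length(a) >= length(b)) { big <- a; small <- b }
    else { big <- b; small <- a }
    extra <- setdiff(small, big)
    if (!length(extra)) return(1)
    pairs <- expand.grid(x = extra, y = big, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    cp <- .canonicalPairs(pairs$x, pairs$y)
    k <- .pairKeys(cp$proteinA, cp$proteinB)
    mean(unlist(mget(k, envir = weightEnv, ifnotfound = 0),
                use.names = FALSE))
}

#' Clustering by maximal-clique merging (CMC)
#'
#' Enumerates all maximal cliques of size >= \code{minSize}, ranks them by
#' weighted density (descending), and resolves highly overlapping pairs:
#' when the overlap |A ∩ B| / min(|A|, |B|) strictly exceeds
#' \code{overlapThres}, the pair is merged if their inter-connectivity
#' (mean edge weight between the non-shared part of the smaller cluster
#' and the larger one, absent edges counting 0) reaches \code{mergeThres},
#' otherwise the lower-density cluster is removed. Passes repeat until
#' stable. \code{minDegRatio} is a connectivity floor on clique members
#' (the fraction of fellow members a member must be adjacent to); maximal
#' cliques satisfy it trivially at the default of 1, so it only excludes
#' candidate cliques when set above 1 (disabling) — it is kept as an
#' explicit knob for parity with the reference parameter grid.
#'
#' @param network a weighted [CompositeNetwork-class].
#' @param minDegRatio minimum in-clique connectivity ratio per member.
#' @param minSize smallest cluster (and clique) considered, default 4.
#' @param overlapThres strict overlap threshold, default 0.5.
#' @param mergeThres inter-connectivity threshold (grid 0.25/0.5/0.75).
#' @return A [ClusterSet-class] with provenance \code{"cmc"}.
#' @export
cmcCluster <- function(network, minDegRatio = 1, minSize = 4L,
                       overlapThres = 0.5, mergeThres = 0.25) {
    stopifnot(is(network, "CompositeNetwork"),
              overlapThres >= 0, overlapThres <= 1,
              mergeThres >= 0, mergeThres <= 1, minSize >= 2L)
    if (!length(network@weights)) stop("network must be weighted")
    cliques <- maximalCliques(network, minSize = minSize)
    dens <- .densityFun(network)
    keys <- .pairKeys(network@edges$proteinA, network@edges$proteinB)
    wEnv <- new.env(hash = TRUE, size = max(29L, length(keys)))
    for (i in seq_along(keys))
        assign(keys[i], network@weights[i], envir = wEnv)
    if (minDegRatio > 1) cliques <- list()   # cliques have ratio exactly 1
    if (!length(cliques))
        return(ClusterSet(provenance = list()))
    cl <- cliques
    d <- vapply(cl, dens, numeric(1))
    repeat {
        o <- order(-d, vapply(cl, paste, character(1), collapse = "\t"))
        cl <- cl[o]; d <- d[o]
        removed <- rep(FALSE, length(cl))
        changed <- FALSE
        for (i in seq_along(cl)) {
            if (removed[i]) next
            j <- i + 1L
            while (j <= length(cl)) {
                if (!removed[j]) {
                    ov <- length(intersect(cl[[i]], cl[[j]])) /
                        min(length(cl[[i]]), length(cl[[j]]))
                    if (ov > overlapThres) {
                        ic <- .interConnectivity(cl[[i]], cl[[j]], wEnv)
                        if (ic >= mergeThres) {
                            cl[[i]] <- sort(union(cl[[i]], cl[[j]]))
                            d[i] <- dens(cl[[i]])
                        }
                        removed[j] <- TRUE
                        changed <- TRUE
                    }
                }
                j <- j + 1L
            }
        }
        cl <- cl[!removed]; d <- d[!removed]
        if (!changed) break
    }
    keep <- lengths(cl) >= minSize
    cl <- cl[keep]
    if (!length(cl)) return(ClusterSet(provenance = list()))
    memberKey <- vapply(cl, paste, character(1), collapse = "\t")
    cl <- cl[!duplicated(memberKey)]
    d <- vapply(cl, dens, numeric(1))
    ClusterSet(members = cl, density = d, score = d, provenance = "cmc")
}

#' Aggregate clusterings by similarity voting (COMBINED)
#'
#' Pools the clusters of all input clusterings, links any two clusters
#' with Jaccard similarity >= \code{similarityThres} (default 0.75), and
#' collapses each connected group of similar clusters to its member with
#' the highest weighted density (ties broken by the lexicographically
#' smallest member set). The kept cluster's score is its density
#' multiplied by the number of distinct algorithms that produced clusters
#' in the group; unmatched clusters keep score = density. Provenance is
#' the union of contributing algorithms.
#'
#' @param clusterSets list of [ClusterSet-class] objects scored against
#'   the same network.
#' @param network the weighted [CompositeNetwork-class] used for density.
#' @param similarityThres Jaccard threshold defining similar clusters.
#' @param minSize smallest cluster entering the aggregation (default 4).
#' @return A [ClusterSet-class].
#' @export
combineClusters <- function(clusterSets, network, similarityThres = 0.75,
                            minSize = 4L) {
    stopifnot(is.list(clusterSets), length(clusterSets) >= 1L,
              all(vapply(clusterSets, is, logical(1), "ClusterSet")),
              similarityThres > 0, similarityThres <= 1)
    members <- unlist(lapply(clusterSets, clusterMembers),
                      recursive = FALSE, use.names = FALSE)
    prov <- unlist(lapply(clusterSets, clusterProvenance),
                   recursive = FALSE, use.names = FALSE)
    keep <- lengths(members) >= minSize
    members <- members[keep]
    prov <- prov[keep]
    if (!length(members)) return(ClusterSet(provenance = list()))
    pooled <- rescoreClusters(
        ClusterSet(members = members,
                   density = numeric(length(members)),
                   provenance = prov),
        network)
    members <- pooled@members
    d <- pooled@density
    ## sparse membership matrix -> pairwise Jaccard
    prots <- sort(unique(unlist(members, use.names = FALSE)))
    i <- rep(seq_along(members), lengths(members))
    j <- match(unlist(members, use.names = FALSE), prots)
    Mm <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                               dims = c(length(members), length(prots)))
    Int <- Matrix::tcrossprod(Mm)
    sz <- lengths(members)
    T <- as(as(Int, "generalMatrix"), "TsparseMatrix")
    sel <- T@i < T@j
    ti <- T@i[sel] + 1L; tj <- T@j[sel] + 1L
    jac <- T@x[sel] / (sz[ti] + sz[tj] - T@x[sel])
    link <- jac >= similarityThres
    g <- igraph::make_empty_graph(n = length(members), directed = FALSE)
    if (any(link))
        g <- igraph::add_edges(g, rbind(ti[link], tj[link]))
    grp <- igraph::components(g)$membership
    outM <- list(); outD <- numeric(); outS <- numeric(); outP <- list()
    for (gid in unique(grp)) {
        idx <- which(grp == gid)
        key <- vapply(members[idx], paste, character(1), collapse = "\t")
        best <- idx[order(-d[idx], key)][1L]
        algos <- unique(unlist(prov[idx], use.names = FALSE))
        outM[[length(outM) + 1L]] <- members[[best]]
        outD <- c(outD, d[best])
        outS <- c(outS, d[best] * length(algos))
        outP[[length(outP) + 1L]] <- sort(algos)
    }
    o <- order(-outS, vapply(outM, paste, character(1), collapse = "\t"))
    ClusterSet(members = outM[o], density = outD[o], score = outS[o],
               provenance = outP[o])
}
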