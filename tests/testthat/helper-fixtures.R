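## Shared fixtures and independent oracles used across the test files.

## Single-source network whose edge weights equal the source scores.
mkWeightedNetwork <- function(a, b, w, source = "s1") {
    tab <- ScoredPairTable(a, b, w, sourceName = source)
    net <- assembleComposite(list(tab))
    key <- paste(net@edges$proteinA, net@edges$proteinB)
    src <- paste(tab@pairs$proteinA, tab@pairs$proteinB)
    net@weights <- tab@pairs$score[match(key, src)]
    validObject(net)
    net
}

## Unweighted clique-union network helper.
mkCliqueNetwork <- function(..., weight = 1) {
    groups <- list(...)
    edges <- do.call(rbind, lapply(groups, function(g)
        t(utils::combn(g, 2L))))
    edges <- unique(edges)
    mkWeightedNetwork(edges[, 1L], edges[, 2L],
                      rep(weight, nrow(edges)))
}

## Brute-force maximal cliques by subset enumeration (<= 15 vertices).
bruteMaxCliques <- function(net, minSize = 2L) {
    verts <- proteinIds(net)
    stopifnot(length(verts) <= 15L)
    key <- paste(net@edges$proteinA, net@edges$proteinB)
    isEdge <- function(u, v) paste(min(u, v), max(u, v)) %in% key
    n <- length(verts)
    cliques <- list()
    for (mask in seq_len(2^n - 1L)) {
        sel <- verts[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
        if (length(sel) < minSize) next
        pr <- if (length(sel) >= 2L) t(utils::combn(sel, 2L)) else
            matrix(character(), 0, 2)
        ok <- all(apply(pr, 1L, function(p) isEdge(p[1L], p[2L])))
        if (ok) cliques[[length(cliques) + 1L]] <- sort(sel)
    }
    ## keep only maximal ones
    maximal <- vapply(cliques, function(c1)
        !any(vapply(cliques, function(c2)
            length(c2) > length(c1) && all(c1 %in% c2), logical(1))),
        logical(1))
    out <- cliques[maximal]
    out[order(vapply(out, paste, character(1), collapse = "\t"))]
}

## Exhaustive-search MDL discretization oracle: at every segment, evaluate
## the information gain of every midpoint between consecutive distinct
## values, take the best (smallest value on ties), and apply the MDL
## acceptance criterion; recurse on accepted splits.
bruteMdlCuts <- function(values, labels) {
    ent <- function(lab) {
        p <- table(lab) / length(lab)
        -sum(p * log2(p))
    }
    rec <- function(v, y) {
        o <- order(v)
        v <- v[o]; y <- y[o]
        N <- length(v)
        cand <- unique(v)
        if (length(cand) < 2L) return(numeric())
        mids <- (head(cand, -1L) + tail(cand, -1L)) / 2
        gains <- vapply(mids, function(m) {
            L <- y[v < m]; R <- y[v >= m]
            ent(y) - length(L) / N * ent(L) - length(R) / N * ent(R)
        }, numeric(1))
        best <- which.max(gains)
        m <- mids[best]
        L <- y[v < m]; R <- y[v >= m]
        k <- length(unique(y)); k1 <- length(unique(L))
        k2 <- length(unique(R))
        thr <- (log2(N - 1) + log2(3^k - 2) - k * ent(y) +
                    k1 * ent(L) + k2 * ent(R)) / N
        if (gains[best] <= thr) return(numeric())
        c(rec(v[v < m], L), m, rec(v[v >= m], R))
    }
    sort(rec(values, labels))
}

## Dense reference implementation of one AdjustCD iteration sweep.
refAdjustCD <- function(pairs, iterations = 1L) {
    verts <- sort(unique(c(pairs$proteinA, pairs$proteinB)))
    n <- length(verts)
    B <- matrix(0, n, n, dimnames = list(verts, verts))
    for (r in seq_len(nrow(pairs))) {
        B[pairs$proteinA[r], pairs$proteinB[r]] <- 1
        B[pairs$proteinB[r], pairs$proteinA[r]] <- 1
    }
    A <- B
    W <- matrix(0, n, n, dimnames = list(verts, verts))
    for (it in seq_len(iterations)) {
        deg <- rowSums(A)
        lambda <- mean(deg)
        W[] <- 0
        for (u in seq_len(n)) for (v in seq_len(n)) {
            if (u >= v) next
            shared <- which(B[u, ] > 0 & B[v, ] > 0)
            if (!length(shared)) next
            num <- sum(A[u, shared]) + sum(A[v, shared])
            W[u, v] <- num / (max(deg[u], lambda) + max(deg[v], lambda))
            W[v, u] <- W[u, v]
        }
        if (it < iterations) A <- W * B
    }
    list(W = W, B = B, verts = verts)
}

## Toy ontology: BP root with two branches, one two-deep.
##   root -> A -> A1, A -> A2 ; root -> B -> B1
toyDag <- function() {
    ontologyDag(
        terms = c("root", "A", "A1", "A2", "B", "B1"),
        namespace = c(root = "BP", A = "BP", A1 = "BP", A2 = "BP",
                      B = "BP", B1 = "BP"),
        parents = list(root = character(), A = "root", A1 = "A",
                       A2 = "A", B = "root", B1 = "B"))
}
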