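## Jaccard matching, cluster and edge precision-recall with
## training-complex exclusion, cross-validation, score calibration and
## novel-complex filtering.

#' Jaccard similarity of two protein sets
#'
#' |A ∩ B| / |A ∪ B|; symmetric, 1 iff equal, 0 iff disjoint. A cluster P
#' matches a complex C at threshold t iff Jaccard(P, C) >= t.
#'
#' @param a,b non-empty character vectors.
#' @return numeric in [0, 1].
#' @export
jaccardSimilarity <- function(a, b) {
    a <- unique(as.character(a))
    b <- unique(as.character(b))
    if (!length(a) || !length(b)) stop("empty set")
    length(intersect(a, b)) / length(union(a, b))
}

#' @rdname jaccardSimilarity
#' @param p,cx member sets of the cluster and the complex.
#' @param matchThres match threshold (typical values 0.5 and 0.75).
#' @export
matchesComplex <- function(p, cx, matchThres = 0.5) {
    jaccardSimilarity(p, cx) >= matchThres
}

## Cluster x complex match matrix (logical) at a Jaccard threshold,
## via sparse membership intersection counts.
.matchMatrix <- function(members, complexSets, matchThres) {
    if (!length(members) || !length(complexSets))
        return(matrix(FALSE, length(members), length(complexSets)))
    prots <- sort(unique(c(unlist(members, use.names = FALSE),
                           unlist(complexSets, use.names = FALSE))))
    mk <- function(sets) Matrix::sparseMatrix(
        i = rep(seq_along(sets), lengths(sets)),
        j = match(unlist(sets, use.names = FALSE), prots),
        x = 1, dims = c(length(sets), length(prots)))
    Int <- as.matrix(Matrix::tcrossprod(mk(members), mk(complexSets)))
    szP <- lengths(members)
    szC <- lengths(complexSets)
    jac <- Int / (outer(szP, szC, `+`) - Int)
    jac >= matchThres
}

## Trapezoidal area under the (recall, precision) polyline, extended from
## recall 0 at the first point's precision.
.prTrapezoid <- function(recall, precision) {
    if (!length(recall)) return(0)
    r <- c(0, recall)
    p <- c(precision[1L], precision)
    sum(diff(r) * (head(p, -1L) + tail(p, -1L)) / 2)
}

#' Cluster-level precision-recall curve
#'
#' Thresholds d run over the distinct cluster scores, descending. At each
#' d, with retained clusters those scoring >= d:
#' recall(d) is the fraction of test complexes matched by some retained
#' cluster; precision(d) is the number of retained clusters matching some
#' test complex divided by the number of retained clusters that either do
#' not match any training complex or match a test complex — predictions
#' that merely reproduce a training complex are excluded from the
#' denominator to remove the supervised methods' bias toward training
#' complexes. Where the denominator is empty precision is recorded as 1
#' (with zero area weight, since recall is then 0). The AUC is the
#' trapezoid over the (recall, precision) points.
#'
#' @param predicted a scored [ClusterSet-class].
#' @param test,train [ReferenceComplexSet-class] objects.
#' @param matchThres Jaccard match threshold (default 0.5).
#' @return A [PRCurve-class].
#' @export
clusterPRCurve <- function(predicted, test, train, matchThres = 0.5) {
    stopifnot(is(predicted, "ClusterSet"),
              is(test, "ReferenceComplexSet"),
              is(train, "ReferenceComplexSet"))
    if (!length(test@complexes)) stop("test complex set is empty")
    nTest <- length(test@complexes)
    if (!length(predicted@members)) {
        return(new("PRCurve",
                   points = data.frame(threshold = numeric(),
                                       recall = numeric(),
                                       precision = numeric(),
                                       nRetained = integer()),
                   auc = 0))
    }
    mTest <- .matchMatrix(predicted@members, test@complexes, matchThres)
    mTrain <- .matchMatrix(predicted@members, train@complexes, matchThres)
    hitsTest <- rowSums(mTest) > 0
    hitsTrain <- rowSums(mTrain) > 0
    o <- order(-predicted@score)
    scores <- predicted@score[o]
    thresholds <- unique(scores)
    covered <- rep(FALSE, nTest)
    cumNum <- cumsum(hitsTest[o])
    cumDen <- cumsum((!hitsTrain | hitsTest)[o])
    recall <- precision <- numeric(length(thresholds))
    nRet <- integer(length(thresholds))
    ti <- 1L
    for (i in seq_along(o)) {
        covered <- covered | mTest[o[i], ]
        last <- i == length(o) || scores[i + 1L] != scores[i]
        if (last && ti <= length(thresholds)) {
            recall[ti] <- sum(covered) / nTest
            precision[ti] <- if (cumDen[i] > 0) cumNum[i] / cumDen[i] else 1
            nRet[ti] <- i
            ti <- ti + 1L
        }
    }
    pts <- data.frame(threshold = thresholds, recall = recall,
                      precision = precision, nRetained = nRet)
    new("PRCurve", points = pts,
        auc = .prTrapezoid(pts$recall, pts$precision))
}

#' Edge-classification precision-recall curve with complex coverage
#'
#' Classifies composite-network edges as co-complex by thresholding their
#' posterior weights. Positives are edges whose endpoints are co-members
#' of some test complex; edges co-member in a training complex are
#' excluded from scoring altogether (mirroring the cluster-level training
#' exclusion). Each point also reports the complex coverage: the fraction
#' of test complexes with at least one retained edge between their
#' members.
#'
#' @param network a weighted [CompositeNetwork-class].
#' @param test,train [ReferenceComplexSet-class] objects.
#' @param excludeTraining logical; drop training co-member edges from the
#'   evaluation universe (default TRUE).
#' @return A [PRCurve-class] whose points carry a \code{coverage} column.
#' @export
edgeClassificationCurve <- function(network, test, train,
                                    excludeTraining = TRUE) {
    stopifnot(is(network, "CompositeNetwork"))
    if (!length(network@weights)) stop("network must be weighted")
    keys <- .pairKeys(network@edges$proteinA, network@edges$proteinB)
    testKeys <- lapply(test@complexes, function(m) {
        pr <- utils::combn(sort(m), 2L)
        .pairKeys(pr[1L, ], pr[2L, ])
    })
    trainKeys <- .coMemberKeys(train)
    keep <- if (excludeTraining) !(keys %in% trainKeys)
            else rep(TRUE, length(keys))
    keys <- keys[keep]
    w <- network@weights[keep]
    pos <- keys %in% unique(unlist(testKeys, use.names = FALSE))
    nPos <- sum(pos)
    nTest <- length(testKeys)
    ## edge -> test complexes incidence for coverage bookkeeping
    edgeComplex <- lapply(seq_len(nTest), function(ci)
        which(keys %in% testKeys[[ci]]))
    o <- order(-w)
    scores <- w[o]
    thresholds <- unique(scores)
    firstRank <- vapply(edgeComplex, function(idx)
        if (length(idx)) min(match(idx, o)) else NA_integer_, integer(1))
    cumTP <- cumsum(pos[o])
    recall <- precision <- coverage <- numeric(length(thresholds))
    nRet <- integer(length(thresholds))
    ti <- 1L
    for (i in seq_along(o)) {
        last <- i == length(o) || scores[i + 1L] != scores[i]
        if (last) {
            recall[ti] <- if (nPos > 0) cumTP[i] / nPos else 0
            precision[ti] <- cumTP[i] / i
            coverage[ti] <- sum(!is.na(firstRank) & firstRank <= i) / nTest
            nRet[ti] <- i
            ti <- ti + 1L
        }
    }
    pts <- data.frame(threshold = thresholds, recall = recall,
                      precision = precision, nRetained = nRet,
                      coverage = coverage)
    new("PRCurve", points = pts,
        auc = .prTrapezoid(pts$recall, pts$precision))
}

## round half away from zero (reproduces the printed test-set counts)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Random sub-sampling cross-validation split
#'
#' Test candidates are the complexes of size strictly greater than
#' \code{sizeFloor}; a uniform random sample of
#' round(\code{testFraction} x #candidates) of them (rounding half away
#' from zero) becomes the test set, and ALL remaining complexes —
#' including every complex of size <= sizeFloor — form the training set.
#' The split is a deterministic function of \code{seed} and
#' \code{roundIndex}.
#'
#' @param reference a [ReferenceComplexSet-class].
#' @param testFraction fraction t of candidates used for testing
#'   (default 0.9).
#' @param sizeFloor strict size floor for test candidates (default 3).
#' @param seed integer seed.
#' @param roundIndex cross-validation round (default 1).
#' @return list with [ReferenceComplexSet-class] elements \code{train}
#'   and \code{test}.
#' @export
cvSplit <- function(reference, testFraction = 0.9, sizeFloor = 3L,
                    seed = 1L, roundIndex = 1L) {
    stopifnot(is(reference, "ReferenceComplexSet"),
              testFraction > 0, testFraction < 1)
    sizes <- lengths(reference@complexes)
    cand <- which(sizes > sizeFloor)
    if (!length(cand)) stop("no complexes above the size floor")
    nTest <- .roundHalfAway(testFraction * length(cand))
    set.seed((as.integer(seed) + 7919L * as.integer(roundIndex)) %%
                 .Machine$integer.max)
    testIdx <- sort(sample(cand, nTest))
    list(train = new("ReferenceComplexSet",
                     complexes = reference@complexes[-testIdx],
                     role = "training"),
         test = new("ReferenceComplexSet",
                    complexes = reference@complexes[testIdx],
                    role = "test"))
}

## Weighted pool-adjacent-violators: smallest non-decreasing fit.
.pava <- function(y, w) {
    n <- length(y)
    if (n <= 1L) return(y)
    val <- y; wt <- w; idx <- rep(1L, n)
    m <- 0L
    for (i in seq_len(n)) {
        m <- m + 1L
        val[m] <- y[i]; wt[m] <- w[i]; idx[m] <- 1L
        while (m > 1L && val[m - 1L] > val[m]) {
            tot <- wt[m - 1L] + wt[m]
            val[m - 1L] <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tot
            wt[m - 1L] <- tot
            idx[m - 1L] <- idx[m - 1L] + idx[m]
            m <- m - 1L
        }
    }
    rep(val[seq_len(m)], idx[seq_len(m)])
}

#' Score-to-precision calibration
#'
#' Pools (cluster score, matched-a-test-complex) observations — typically
#' across cross-validation rounds — bins the scores into up to
#' \code{nBins} equal-frequency bins, computes the empirical precision
#' per bin and flattens it to be monotone non-decreasing in the score
#' (weighted pool-adjacent-violators), so that estimated precision never
#' increases as the score decreases.
#'
#' @param scores numeric cluster scores.
#' @param hits logical; did the cluster match a test complex?
#' @param nBins maximum number of score bins (default 20).
#' @return A [CalibrationTable-class].
#' @export
calibrationTable <- function(scores, hits, nBins = 20L) {
    stopifnot(length(scores) == length(hits), length(scores) >= 1L)
    breaks <- unique(stats::quantile(scores, probs = seq(0, 1,
                                                         length.out = nBins + 1L),
                                     names = FALSE, type = 1))
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1e-9)
    bin <- findInterval(scores, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    lv <- sort(unique(bin))
    prec <- vapply(lv, function(b) mean(hits[bin == b]), numeric(1))
    n <- vapply(lv, function(b) sum(bin == b), numeric(1))
    prec <- .pava(prec, n)
    bins <- data.frame(scoreLo = breaks[lv], scoreHi = breaks[lv + 1L],
                       precision = prec, n = n)
    new("CalibrationTable", bins = bins)
}

#' Estimated precision of cluster scores
#'
#' @param calibration a [CalibrationTable-class].
#' @param scores numeric scores.
#' @return numeric estimated precisions (scores above the top bin get the
#'   top bin's precision; below the bottom bin, the bottom bin's).
#' @export
calibratedPrecision <- function(calibration, scores) {
    stopifnot(is(calibration, "CalibrationTable"))
    b <- calibration@bins
    idx <- pmax(1L, findInterval(scores, b$scoreLo))
    b$precision[idx]
}

#' Cross-validation driver
#'
#' Runs the full supervised pipeline per round: split the reference
#' complexes, label the composite network's edges from the round's
#' training complexes, discretize and fit the naive-Bayes model, weight
#' all edges, keep the top-k, run every clusterer, aggregate with the
#' voting strategy, and evaluate cluster- and edge-level precision-recall
#' against the round's test complexes. A failing clusterer is skipped
#' with a warning and the aggregation proceeds with the survivors.
#' Observations (combined-cluster score, matched-test) are pooled across
#' rounds into the score-to-precision calibration table.
#'
#' @param network an unlabelled [CompositeNetwork-class].
#' @param reference the full [ReferenceComplexSet-class].
#' @param clusterers named list of functions taking a weighted network and
#'   returning a [ClusterSet-class]; defaults to the native Markov
#'   clustering and maximal-clique merging.
#' @param rounds number of rounds (default 10).
#' @param testFraction,sizeFloor see [cvSplit()].
#' @param k number of top-weighted edges used for clustering.
#' @param matchThres Jaccard match threshold for evaluation.
#' @param alpha naive-Bayes smoothing pseudocount.
#' @param minClusterSize smallest cluster entering aggregation.
#' @param seed integer seed driving every round's split.
#' @return list with per-round results (\code{rounds}: train/test sets,
#'   combined clusters, cluster and edge [PRCurve-class]s) and the pooled
#'   \code{calibration} [CalibrationTable-class].
#' @export
runCrossValidation <- function(network, reference,
                               clusterers = list(
                                   mcl = function(net) mclCluster(net),
                                   cmc = function(net) cmcCluster(net)),
                               rounds = 10L, testFraction = 0.9,
                               sizeFloor = 3L, k = 10000L,
                               matchThres = 0.5, alpha = 1,
                               minClusterSize = 4L, seed = 1L) {
    stopifnot(is(network, "CompositeNetwork"), rounds >= 1L)
    out <- vector("list", rounds)
    calScores <- numeric()
    calHits <- logical()
    for (r in seq_len(rounds)) {
        split <- cvSplit(reference, testFraction, sizeFloor, seed, r)
        labelled <- labelEdges(network, split$train)
        scheme <- discretizeFeatures(labelled)
        model <- fitNaiveBayes(labelled, scheme, alpha = alpha)
        weighted <- weightEdges(labelled, model)
        clusterInput <- topKEdges(weighted, k)
        sets <- list()
        for (nm in names(clusterers)) {
            cs <- tryCatch(clusterers[[nm]](clusterInput),
                           error = function(e) {
                               warning("clusterer '", nm, "' failed in round ",
                                       r, ": ", conditionMessage(e))
                               NULL
                           })
            if (!is.null(cs) && length(cs@members)) sets[[nm]] <- cs
        }
        if (!length(sets)) stop("all clusterers failed in round ", r)
        combined <- combineClusters(sets, weighted,
                                    minSize = minClusterSize)
        curve <- clusterPRCurve(combined, split$test, split$train,
                                matchThres)
        edgeCurve <- edgeClassificationCurve(weighted, split$test,
                                             split$train)
        if (length(combined@members)) {
            mTest <- .matchMatrix(combined@members, split$test@complexes,
                                  matchThres)
            mTrain <- .matchMatrix(combined@members, split$train@complexes,
                                   matchThres)
            eligible <- !(rowSums(mTrain) > 0) | (rowSums(mTest) > 0)
            calScores <- c(calScores, combined@score[eligible])
            calHits <- c(calHits, (rowSums(mTest) > 0)[eligible])
        }
        out[[r]] <- list(train = split$train, test = split$test,
                         clusters = combined, curve = curve,
                         edgeCurve = edgeCurve, model = model)
    }
    calibration <- if (length(calScores))
        calibrationTable(calScores, calHits) else
        new("CalibrationTable",
            bins = data.frame(scoreLo = 0, scoreHi = 1, precision = 0,
                              n = 0))
    list(rounds = out, calibration = calibration)
}

#' Filter predicted clusters down to unique, novel, high-confidence ones
#'
#' Three passes, in order: (1) deduplication — clusters are visited by
#' descending score (ties by lexicographic member set) and a cluster is
#' removed if it matches an already-kept cluster at Jaccard >=
#' \code{matchThres}; (2) novelty — clusters matching any reference
#' complex at the same threshold are removed; (3) confidence — clusters
#' whose calibrated precision is strictly below \code{confidenceThres}
#' are removed.
#'
#' @param predicted a scored [ClusterSet-class].
#' @param reference the [ReferenceComplexSet-class] of known complexes.
#' @param calibration a [CalibrationTable-class].
#' @param confidenceThres minimum estimated precision (presets 0.5, 0.4).
#' @param matchThres Jaccard threshold for both dedup and novelty
#'   (default 0.5).
#' @return the filtered [ClusterSet-class].
#' @export
filterNovel <- function(predicted, reference, calibration,
                        confidenceThres = 0.5, matchThres = 0.5) {
    stopifnot(is(predicted, "ClusterSet"),
              is(reference, "ReferenceComplexSet"),
              is(calibration, "CalibrationTable"))
    if (!length(predicted@members)) return(predicted)
    key <- vapply(predicted@members, paste, character(1), collapse = "\t")
    o <- order(-predicted@score, key)
    keptIdx <- integer()
    for (i in o) {
        dup <- any(vapply(keptIdx, function(j)
            jaccardSimilarity(predicted@members[[i]],
                              predicted@members[[j]]) >= matchThres,
            logical(1)))
        if (!dup) keptIdx <- c(keptIdx, i)
    }
    sel <- sort(keptIdx)
    if (length(reference@complexes)) {
        mRef <- .matchMatrix(predicted@members[sel], reference@complexes,
                             matchThres)
        sel <- sel[rowSums(mRef) == 0]
    }
    if (length(sel)) {
        est <- calibratedPrecision(calibration, predicted@score[sel])
        sel <- sel[est >= confidenceThres]
    }
    new("ClusterSet", members = predicted@members[sel],
        density = predicted@density[sel], score = predicted@score[sel],
        provenance = predicted@provenance[sel])
}
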