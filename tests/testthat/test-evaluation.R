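test_that("Jaccard similarity covers identity, disjointness and near-match", {
    ten <- sprintf("m%02d", 1:10)
    ## nine of ten members, no extras, vs the full complex
    expect_equal(jaccardSimilarity(ten[-1], ten), 0.9)
    expect_equal(jaccardSimilarity(ten, ten), 1)
    expect_equal(jaccardSimilarity(ten, paste0("x", 1:4)), 0)
    expect_true(matchesComplex(ten[-1], ten, 0.75))
    expect_false(matchesComplex(ten[1:5], ten, 0.75))
    expect_error(jaccardSimilarity(character(), ten), "empty")
})

test_that("cluster precision-recall follows the printed formulas", {
    test <- ReferenceComplexSet(list(C1 = c("a", "b", "c", "d"),
                                     C2 = c("e", "f", "g", "h"),
                                     C3 = c("i", "j", "k", "l"),
                                     C4 = c("m", "n", "o", "p")),
                                role = "test")
    train <- ReferenceComplexSet(list(T1 = c("q", "r", "s", "t")),
                                 role = "training")
    ## 2 clusters (scores 0.9, 0.4), only the first matches one of 4 test
    ## complexes -> points (0.25, 1) then (0.25, 0.5)
    pred <- ClusterSet(list(c("a", "b", "c", "d"), c("x", "y", "z", "w")),
                       density = c(0.9, 0.4), provenance = "mcl")
    pr <- prPoints(clusterPRCurve(pred, test, train, 0.5))
    expect_equal(pr$recall, c(0.25, 0.25))
    expect_equal(pr$precision, c(1, 0.5))
    expect_equal(pr$threshold, c(0.9, 0.4))
    ## every cluster equals a distinct test complex: recall = precision =
    ## auc = 1
    perfect <- ClusterSet(complexes(test), density = c(4, 3, 2, 1),
                          provenance = "mcl")
    curve <- clusterPRCurve(perfect, test, train, 0.5)
    expect_true(all(prPoints(curve)$precision == 1))
    expect_equal(max(prPoints(curve)$recall), 1)
    expect_equal(prAuc(curve), 1)
    ## a cluster matching only a training complex is excluded from the
    ## precision denominator (0/0 recorded as precision 1, zero weight)
    trainOnly <- ClusterSet(list(c("q", "r", "s", "t")), density = 1,
                            provenance = "mcl")
    pr2 <- prPoints(clusterPRCurve(trainOnly, test, train, 0.5))
    expect_equal(pr2$precision, 1)
    expect_equal(pr2$recall, 0)
    expect_equal(prAuc(clusterPRCurve(trainOnly, test, train, 0.5)), 0)
    expect_error(clusterPRCurve(pred, ReferenceComplexSet(role = "test"),
                                train, 0.5), "empty")
})

test_that("recall is monotone and the denominator never counts train-only clusters", {
    set.seed(41)
    prots <- sprintf("p%03d", 1:60)
    test <- ReferenceComplexSet(
        setNames(lapply(0:4, function(i) prots[(i * 6 + 1):(i * 6 + 6)]),
                 paste0("C", 1:5)), role = "test")
    train <- ReferenceComplexSet(list(T1 = prots[31:36],
                                      T2 = prots[37:42]),
                                 role = "training")
    pred <- ClusterSet(replicate(30, sample(prots, sample(4:8, 1)),
                                 simplify = FALSE),
                       density = runif(30), provenance = "x")
    curve <- clusterPRCurve(pred, test, train, 0.5)
    p <- prPoints(curve)
    expect_true(all(diff(p$recall) >= 0))
    expect_true(all(diff(p$nRetained) > 0))
    expect_true(prAuc(curve) >= 0 && prAuc(curve) <= 1)
})

test_that("edge classification scores only the non-training universe", {
    ## 2 test complexes; 4 positive edges, threshold retains 2 in one
    ## complex -> recall 0.5, coverage 0.5
    net <- mkWeightedNetwork(
        c("a", "a", "c", "d", "x", "y"),
        c("b", "c", "d", "e", "y", "z"),
        c(0.9, 0.8, 0.4, 0.3, 0.7, 0.2))
    test <- ReferenceComplexSet(list(C1 = c("a", "b", "c"),
                                     C2 = c("d", "e", "f")),
                                role = "test")
    train <- ReferenceComplexSet(list(T1 = c("x", "y")), role = "training")
    curve <- edgeClassificationCurve(net, test, train)
    p <- prPoints(curve)
    ## positives: a-b, a-c (C1), d-e (C2); c-d is not within a complex;
    ## x-y excluded as a training edge
    at05 <- p[p$threshold == 0.8, ]
    expect_equal(at05$recall, 2 / 3)
    expect_equal(at05$precision, 1)
    expect_equal(at05$coverage, 0.5)
    ## a threshold above the maximum weight retains nothing
    expect_equal(p$recall[1], 1 / 3)
    expect_true(all(p$coverage >= 0 & p$coverage <= 1))
    ## perfectly separating weights give precision 1 at every recall
    sep <- mkWeightedNetwork(c("a", "a", "p"), c("b", "c", "q"),
                             c(0.9, 0.8, 0.1))
    sepCurve <- edgeClassificationCurve(
        sep, ReferenceComplexSet(list(C = c("a", "b", "c")), role = "test"),
        ReferenceComplexSet(role = "training"))
    sp <- prPoints(sepCurve)
    expect_true(all(sp$precision[sp$recall < 1] == 1))
})

test_that("cross-validation splits reproduce the printed reference counts", {
    mkRef <- function(total, big) {
        sizes <- c(rep(5L, big), rep(2L, total - big))
        pool <- sprintf("y%04d", seq_len(6 * total))
        off <- cumsum(c(0L, sizes[-length(sizes)]))
        ReferenceComplexSet(setNames(lapply(seq_along(sizes), function(i)
            pool[(off[i] + 1):(off[i] + sizes[i])]),
            sprintf("cx%04d", seq_along(sizes))))
    }
    ## 408 complexes, 149 of size > 3 -> 134 test / 274 train
    ref <- mkRef(408, 149)
    sp <- cvSplit(ref, testFraction = 0.9, sizeFloor = 3, seed = 1)
    expect_equal(length(sp$test), 134L)
    expect_equal(length(sp$train), 274L)
    expect_true(all(lengths(complexes(sp$test)) > 3))
    ## 1829 complexes, 714 of size > 3 -> 643 test / 1186 train
    ref2 <- mkRef(1829, 714)
    sp2 <- cvSplit(ref2, testFraction = 0.9, sizeFloor = 3, seed = 1)
    expect_equal(length(sp2$test), 643L)
    expect_equal(length(sp2$train), 1186L)
    ## identical seed and round reproduce the split; rounds differ
    spA <- cvSplit(ref, seed = 7, roundIndex = 2)
    spB <- cvSplit(ref, seed = 7, roundIndex = 2)
    expect_identical(names(complexes(spA$test)),
                     names(complexes(spB$test)))
    spC <- cvSplit(ref, seed = 7, roundIndex = 3)
    expect_false(identical(names(complexes(spA$test)),
                           names(complexes(spC$test))))
    ## small complexes always train
    expect_true(all(lengths(complexes(sp$train)) > 0))
})

test_that("calibration is monotone and interpolates by score bin", {
    set.seed(13)
    scores <- runif(400)
    hits <- runif(400) < scores            # precision rises with score
    cal <- calibrationTable(scores, hits)
    b <- calibrationBins(cal)
    expect_true(all(diff(b$precision) >= -1e-9))
    est <- calibratedPrecision(cal, c(0.05, 0.5, 0.95))
    expect_true(est[1] <= est[2] && est[2] <= est[3])
    ## scores outside the observed range clamp to the boundary bins
    expect_equal(calibratedPrecision(cal, -1), b$precision[1L])
    expect_equal(calibratedPrecision(cal, 99), b$precision[nrow(b)])
})

test_that("novel-complex filtering applies dedup, novelty and confidence in order", {
    ref <- ReferenceComplexSet(list(K = c("a", "b", "c", "d")))
    cal <- new("CalibrationTable",
               bins = data.frame(scoreLo = c(0, 0.5), scoreHi = c(0.5, 1),
                                 precision = c(0.39, 0.9), n = c(5, 5)))
    pred <- ClusterSet(
        list(c("a", "b", "c", "d"),          # matches the reference
             c("p", "q", "r", "s"),          # novel, high score
             c("p", "q", "r", "s", "t"),     # Jaccard 0.8 dup, lower score
             c("u", "v", "w", "x")),         # novel, low score
        density = c(0.95, 0.9, 0.3, 0.2),
        score = c(0.95, 0.9, 0.3, 0.2), provenance = "mcl")
    out <- filterNovel(pred, ref, cal, confidenceThres = 0.4)
    expect_equal(clusterMembers(out), list(c("p", "q", "r", "s")))
    ## pass 3 is a strict less-than: estimated 0.39 < 0.4 removed, but
    ## kept at threshold 0.39
    out2 <- filterNovel(pred, ref, cal, confidenceThres = 0.39)
    expect_equal(length(out2), 2L)
    ## postconditions: no internal pair >= 0.5, nothing matching reference
    set.seed(19)
    prots <- sprintf("n%02d", 1:40)
    big <- ClusterSet(replicate(25, sample(prots, sample(4:8, 1)),
                                simplify = FALSE),
                      density = runif(25), provenance = "x")
    out3 <- filterNovel(big, ref, cal, confidenceThres = 0)
    mem <- clusterMembers(out3)
    if (length(mem) > 1L) {
        pr <- t(combn(seq_along(mem), 2))
        jac <- apply(pr, 1L, function(ij)
            jaccardSimilarity(mem[[ij[1]]], mem[[ij[2]]]))
        expect_true(all(jac < 0.5))
    }
    expect_true(all(vapply(mem, function(m)
        jaccardSimilarity(m, complexes(ref)[[1L]]) < 0.5, logical(1))))
})

test_that("the cross-validation driver is reproducible and well-formed", {
    p <- synthParams(nProteins = 250, nComplexes = 25,
                     sizeRange = c(4, 8),
                     sources = list(
                         s1 = list(coPresence = 0.7, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 1200),
                         s2 = list(coPresence = 0.7, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 1200)),
                     nTransientHubs = 4, hubDegreeMean = 10, seed = 33)
    bench <- generateBenchmark(p)
    net <- assembleComposite(bench$tables)
    run <- function() runCrossValidation(
        net, bench$complexes, rounds = 2L, testFraction = 0.5,
        k = 1500L, seed = 99L,
        clusterers = list(mcl = function(n) mclCluster(n),
                          cmc = function(n) cmcCluster(n)))
    r1 <- run()
    r2 <- run()
    expect_equal(length(r1$rounds), 2L)
    expect_equal(prAuc(r1$rounds[[1]]$curve), prAuc(r2$rounds[[1]]$curve))
    expect_equal(clusterMembers(r1$rounds[[2]]$clusters),
                 clusterMembers(r2$rounds[[2]]$clusters))
    expect_s4_class(r1$calibration, "CalibrationTable")
    ## a single clusterer flows through aggregation with vote 1
    r3 <- runCrossValidation(net, bench$complexes, rounds = 1L,
                             testFraction = 0.5, k = 1500L, seed = 99L,
                             clusterers = list(
                                 cmc = function(n) cmcCluster(n)))
    cs <- r3$rounds[[1]]$clusters
    expect_equal(clusterScores(cs), clusterDensities(cs))
})
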