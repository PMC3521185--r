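test_that("edge labelling follows the single-witnessing-complex rule", {
    net <- assembleComposite(list(ScoredPairTable(
        c("a", "a", "b", "c"), c("b", "c", "d", "d"),
        c(0.9, 0.8, 0.7, 0.6), "s")))
    train <- ReferenceComplexSet(list(X = c("a", "b", "z"),
                                      Y = c("a", "c", "d")),
                                 role = "training")
    lab <- edgeLabels(labelEdges(net, train))
    tab <- edgeTable(labelEdges(net, train))
    expect_equal(tab$label[tab$proteinA == "a" & tab$proteinB == "b"],
                 "co-complex")          # inside X
    expect_equal(tab$label[tab$proteinA == "a" & tab$proteinB == "c"],
                 "co-complex")          # a also in X, one witness suffices
    expect_equal(tab$label[tab$proteinA == "c" & tab$proteinB == "d"],
                 "co-complex")
    expect_equal(tab$label[tab$proteinA == "b" & tab$proteinB == "d"],
                 "non-co-complex")      # straddles X and Y
    expect_error(labelEdges(net, ReferenceComplexSet(role = "training")),
                 "empty")
})

test_that("maximum-likelihood estimates and smoothing follow the count rules", {
    ## 10 edges, 4 co-complex -> prior 0.4 (priors unsmoothed)
    set.seed(3)
    a <- rep("h", 10); b <- sprintf("t%02d", 1:10)
    net <- assembleComposite(list(
        ScoredPairTable(a, b, c(rep(0.2, 6), rep(0.8, 4)), "f")))
    net@labels <- c(rep("non-co-complex", 6), rep("co-complex", 4))
    scheme <- new("DiscretizationScheme", cuts = list(f = 0.5),
                  dropped = c(f = FALSE))
    m0 <- fitNaiveBayes(net, scheme, alpha = 0)
    expect_equal(m0@priors[["co-complex"]], 0.4)
    expect_equal(m0@condProb$f["co-complex", ], c(0, 1))
    ## counts (1,3) with alpha = 0 -> P(high | co) = 0.75
    net@labels <- c(rep("non-co-complex", 5), "co-complex",
                    "non-co-complex", rep("co-complex", 3))
    m1 <- fitNaiveBayes(net, scheme, alpha = 0)
    expect_equal(unname(m1@counts$f["co-complex", ]), c(1, 3))
    expect_equal(unname(m1@condProb$f["co-complex", 2L]), 0.75)
    ## Laplace: unseen bin with n_c = 4 and 2 bins -> 1/6
    net@labels <- c(rep("non-co-complex", 6), rep("co-complex", 4))
    m2 <- fitNaiveBayes(net, scheme, alpha = 1)
    expect_equal(unname(m2@condProb$f["co-complex", 1L]), 1 / 6)
    ## all-dropped schemes are fatal
    sAll <- new("DiscretizationScheme", cuts = list(f = numeric()),
                dropped = c(f = TRUE))
    expect_error(fitNaiveBayes(net, sAll), "no informative features")
})

mkModel <- function(priors, condProb, cuts) {
    ## hand-built model: condProb list of 2 x nbins matrices
    counts <- lapply(condProb, function(p) round(p * 1000))
    scheme <- new("DiscretizationScheme", cuts = cuts,
                  dropped = setNames(rep(FALSE, length(cuts)),
                                     names(cuts)))
    cls <- c("co-complex", "non-co-complex")
    condProb <- lapply(condProb, function(p) {
        rownames(p) <- cls; p
    })
    counts <- lapply(counts, function(m) {
        rownames(m) <- cls; m
    })
    new("NaiveBayesModel", scheme = scheme,
        classCounts = setNames(1000 * priors, cls),
        counts = counts, condProb = condProb,
        priors = setNames(priors, cls), alpha = 0)
}

test_that("posterior weights reproduce the closed-form worked examples", {
    ## all likelihood ratios 1 -> posterior equals the prior
    m <- mkModel(c(0.3, 0.7),
                 list(f = rbind(c(0.5, 0.5), c(0.5, 0.5))),
                 list(f = 0.5))
    expect_equal(posteriorWeight(m, c(f = 0.9)), 0.3)
    ## equal priors, single feature with LR 4 -> 0.8
    m <- mkModel(c(0.5, 0.5),
                 list(f = rbind(c(0.2, 0.8), c(0.8, 0.2))),
                 list(f = 0.5))
    expect_equal(posteriorWeight(m, c(f = 0.9)), 0.8)
    ## priors (0.25, 0.75), LRs 2 and 3 -> 6*0.25 / (6*0.25 + 0.75) = 2/3
    m <- mkModel(c(0.25, 0.75),
                 list(f1 = rbind(c(1 / 3, 2 / 3), c(2 / 3, 1 / 3)),
                      f2 = rbind(c(0.25, 0.75), c(0.75, 0.25))),
                 list(f1 = 0.5, f2 = 0.5))
    expect_equal(posteriorWeight(m, c(f1 = 0.9, f2 = 0.9)), 2 / 3)
    ## unknown feature is fatal
    expect_error(posteriorWeight(m, c(f1 = 0.9)), "unknown")
})

test_that("posteriors normalize and are monotone in the likelihood ratio", {
    set.seed(21)
    p <- synthParams(nProteins = 300, nComplexes = 20,
                     nTransientHubs = 0, seed = 77,
                     sources = list(
                         s1 = list(coPresence = 0.7, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 1500),
                         s2 = list(coPresence = 0.7, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 1500)))
    bench <- generateBenchmark(p)
    net <- assembleComposite(bench$tables)
    sw <- supervisedWeight(net, bench$complexes)
    m <- sw$model
    feats <- featureMatrix(net)
    ## two-class normalization: complement posterior sums to 1 exactly
    ll <- cocomplex:::.logLikelihoods(m, feats)
    wCo <- 1 / (1 + exp(ll[, "non"] - ll[, "co"]))
    wNon <- 1 / (1 + exp(ll[, "co"] - ll[, "non"]))
    expect_equal(wCo + wNon, rep(1, nrow(feats)))
    expect_true(all(edgeWeights(sw$network) > 0 &
                    edgeWeights(sw$network) < 1))
    ## monotonicity: moving one feature to a bin with larger LR never
    ## decreases the posterior
    lrt <- likelihoodRatioTable(m)
    for (f in names(m@condProb)) {
        sub <- lrt[lrt$feature == f, ]
        o <- order(sub$ratio)
        mids <- ifelse(is.finite(sub$lo) & is.finite(sub$hi),
                       (sub$lo + sub$hi) / 2,
                       ifelse(is.finite(sub$hi), sub$hi - 1, sub$lo + 1))
        base <- feats[1:50, , drop = FALSE]
        prev <- NULL
        for (b in o) {
            cur <- base
            cur[, f] <- mids[b]
            w <- posteriorWeight(m, cur)
            if (!is.null(prev)) expect_true(all(w >= prev - 1e-12))
            prev <- w
        }
    }
})

test_that("top-k selection is exact with lexicographic tie-breaking", {
    net <- mkWeightedNetwork(c("a", "a", "b", "c", "d"),
                             c("b", "c", "c", "d", "e"),
                             c(0.9, 0.5, 0.5, 0.5, 0.2))
    ## k >= |E| leaves the edge set unchanged
    expect_equal(edgeCount(topKEdges(net, 10)), 5L)
    ## distinct weights: the largest survive
    top2w <- edgeWeights(topKEdges(net, 1))
    expect_equal(top2w, 0.9)
    ## three edges tied at the cutoff, one slot: smallest edge key kept
    top2 <- topKEdges(net, 2)
    tab <- edgeTable(top2)
    expect_equal(paste(tab$proteinA, tab$proteinB),
                 c("a b", "a c"))
    expect_error(topKEdges(net, 0), "positive")
})

test_that("likelihood-ratio tables and the exported evidence agree", {
    set.seed(5)
    p <- synthParams(nProteins = 150, nComplexes = 10,
                     nTransientHubs = 0, seed = 9,
                     sources = list(
                         s1 = list(coPresence = 0.9, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 400),
                         s2 = list(coPresence = 0.9, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 400),
                         s3 = list(coPresence = 0.9, coShape = c(5, 2),
                                   bgShape = c(2, 5), nBackground = 400)))
    bench <- generateBenchmark(p)
    net <- assembleComposite(bench$tables)
    sw <- supervisedWeight(net, bench$complexes)
    lrt <- likelihoodRatioTable(sw$model)
    ## shape contract and elementwise ratio of the smoothed conditionals
    for (f in names(sw$model@condProb)) {
        sub <- lrt[lrt$feature == f, ]
        expect_equal(nrow(sub), ncol(sw$model@condProb[[f]]))
        expect_equal(sub$ratio, unname(
            sw$model@condProb[[f]]["co-complex", ] /
            sw$model@condProb[[f]]["non-co-complex", ]))
        expect_true(all(is.finite(sub$ratio) & sub$ratio > 0))
    }
    ## exported likelihood network: one edge per (pair, non-zero source),
    ## ratios equal to the table lookup
    members <- complexes(bench$complexes)[[1L]]
    f <- withr::local_tempfile(fileext = ".graphml")
    edges <- exportLikelihoodNetwork(sw$network, sw$model, members, f)
    expect_true(file.exists(f))
    feats <- featureMatrix(sw$network)
    keys <- paste(sw$network@edges$proteinA, sw$network@edges$proteinB)
    pr <- t(combn(sort(members), 2))
    inNet <- paste(pr[, 1], pr[, 2]) %in% keys
    nz <- sum(feats[match(paste(pr[inNet, 1], pr[inNet, 2]), keys), ] != 0)
    expect_equal(nrow(edges), nz)
    for (i in seq_len(nrow(edges))) {
        ref <- lrt[lrt$feature == edges$source[i] &
                   lrt$bin == edges$bin[i], "ratio"]
        expect_equal(edges$likelihoodRatio[i], ref)
    }
})
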