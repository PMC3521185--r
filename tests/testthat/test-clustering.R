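test_that("weighted density follows the ordered-pair normalization", {
    net <- mkWeightedNetwork(c("a", "a"), c("b", "c"), c(1, 0.5))
    ## {a,b,c}: w(a,b)=1, w(a,c)=0.5, (b,c) absent -> 2*1.5/6 = 0.5
    expect_equal(weightedDensity(c("a", "b", "c"), net), 0.5)
    ## clique with all weights 1 -> density 1, any size
    cl <- mkCliqueNetwork(letters[1:5])
    expect_equal(weightedDensity(letters[1:5], cl), 1)
    expect_equal(weightedDensity(letters[1:3], cl), 1)
    ## no internal edges -> 0
    expect_equal(weightedDensity(c("a", "b"), mkWeightedNetwork(
        c("a", "b"), c("x", "y"), c(1, 1))), 0)
    expect_error(weightedDensity("a", net), ">= 2")
})

test_that("Markov clustering separates flow regions deterministically", {
    ## disjoint triangles never merge
    tri <- mkCliqueNetwork(c("a", "b", "c"), c("x", "y", "z"))
    cs <- mclCluster(tri, inflation = 2)
    expect_equal(clusterMembers(cs),
                 list(c("a", "b", "c"), c("x", "y", "z")))
    expect_equal(clusterDensities(cs), c(1, 1))
    ## a single 4-clique is one cluster
    cs4 <- mclCluster(mkCliqueNetwork(letters[1:4]))
    expect_equal(clusterMembers(cs4), list(letters[1:4]))
    ## two 4-cliques joined by one weak bridge split at inflation 2
    cl1 <- t(combn(c("a", "b", "c", "d"), 2))
    cl2 <- t(combn(c("e", "f", "g", "h"), 2))
    bridged <- mkWeightedNetwork(
        c(cl1[, 1], cl2[, 1], "d"), c(cl1[, 2], cl2[, 2], "e"),
        c(rep(1, 12), 0.1))
    csb <- mclCluster(bridged, inflation = 2)
    expect_equal(clusterMembers(csb),
                 list(c("a", "b", "c", "d"), c("e", "f", "g", "h")))
    ## determinism
    expect_equal(clusterMembers(mclCluster(bridged)),
                 clusterMembers(mclCluster(bridged)))
    expect_true(all(vapply(clusterProvenance(csb), identical,
                           logical(1), "mcl")))
})

test_that("Markov clustering on a disconnected graph equals the union of components", {
    set.seed(17)
    nets <- lapply(1:2, function(i) {
        v <- paste0(c("l", "r")[i], 1:7)
        pr <- t(combn(v, 2))
        keep <- runif(nrow(pr)) < 0.6
        data.frame(a = pr[keep, 1], b = pr[keep, 2],
                   w = runif(sum(keep), 0.4, 1))
    })
    whole <- mkWeightedNetwork(c(nets[[1]]$a, nets[[2]]$a),
                               c(nets[[1]]$b, nets[[2]]$b),
                               c(nets[[1]]$w, nets[[2]]$w))
    parts <- lapply(nets, function(d) mkWeightedNetwork(d$a, d$b, d$w))
    got <- clusterMembers(mclCluster(whole))
    want <- c(clusterMembers(mclCluster(parts[[1]])),
              clusterMembers(mclCluster(parts[[2]])))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
})

test_that("maximal cliques match brute-force subset enumeration", {
    ## a 5-clique contains no separately-reported 4-clique
    net <- mkCliqueNetwork(letters[1:5])
    expect_equal(maximalCliques(net, minSize = 4), list(letters[1:5]))
    set.seed(23)
    for (rep in 1:5) {
        v <- letters[1:sample(6:9, 1)]
        pr <- t(combn(v, 2))
        keep <- runif(nrow(pr)) < 0.55
        if (sum(keep) < 3) next
        net <- mkWeightedNetwork(pr[keep, 1], pr[keep, 2],
                                 rep(1, sum(keep)))
        expect_equal(maximalCliques(net), bruteMaxCliques(net))
    }
})

test_that("clique merging honours the strict overlap threshold", {
    ## two disjoint 4-cliques pass through unmodified
    net <- mkCliqueNetwork(letters[1:4], letters[5:8])
    cs <- cmcCluster(net)
    expect_setequal(vapply(clusterMembers(cs), paste, character(1),
                           collapse = ","),
                    c("a,b,c,d", "e,f,g,h"))
    ## overlap 2/4 = 0.5 equals the threshold: not >, both kept
    net2 <- mkCliqueNetwork(c("a", "b", "c", "d"), c("c", "d", "e", "f"))
    cs2 <- cmcCluster(net2, overlapThres = 0.5)
    expect_equal(length(cs2), 2L)
    ## overlap 3/4 > 0.5 with full-weight interconnectivity: merged
    net3 <- mkCliqueNetwork(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
    cs3 <- cmcCluster(net3, overlapThres = 0.5, mergeThres = 0.25)
    expect_equal(clusterMembers(cs3), list(c("a", "b", "c", "d", "e")))
    ## same geometry with interconnectivity below mergeThres = 1:
    ## the lower-density clique is removed instead
    cs4 <- cmcCluster(net3, overlapThres = 0.5, mergeThres = 1)
    expect_equal(length(cs4), 1L)
    expect_equal(lengths(clusterMembers(cs4)), 4L)
    expect_true(all(vapply(clusterProvenance(cs3), identical,
                           logical(1), "cmc")))
})

test_that("aggregation votes, dedupes and keeps the densest representative", {
    net <- mkCliqueNetwork(letters[1:4], letters[5:8], weight = 0.5)
    cl <- list(letters[1:4])
    s1 <- ClusterSet(cl, density = 0.5, provenance = "mcl")
    s2 <- ClusterSet(cl, density = 0.5, provenance = "cmc")
    s3 <- ClusterSet(cl, density = 0.5, provenance = "ipca")
    ## identical cluster (density 0.5) from 3 algorithms:
    ## one cluster, score 1.5, provenance of size 3
    comb <- combineClusters(list(s1, s2, s3), net)
    expect_equal(length(comb), 1L)
    expect_equal(clusterDensities(comb), 0.5)
    expect_equal(clusterScores(comb), 1.5)
    expect_equal(clusterProvenance(comb)[[1L]], c("cmc", "ipca", "mcl"))
    ## a single input set passes through with scores = densities
    one <- combineClusters(list(s1), net)
    expect_equal(clusterScores(one), clusterDensities(one))
    ## two clusters with Jaccard 0.6 < 0.75 stay separate
    s4 <- ClusterSet(list(letters[1:4], letters[2:5]),
                     density = c(0.5, 0.4), provenance = "mcl")
    twoGroups <- combineClusters(list(s4), net)
    expect_equal(length(twoGroups), 2L)
})

test_that("no two aggregated clusters remain similar, and votes are monotone", {
    set.seed(31)
    prots <- sprintf("q%02d", 1:30)
    randomSet <- function(algo, n = 8) {
        ClusterSet(replicate(n, sample(prots, sample(4:7, 1)),
                             simplify = FALSE),
                   density = runif(n), provenance = algo)
    }
    net <- mkCliqueNetwork(prots[1:10], prots[11:20], prots[21:30],
                           weight = 0.8)
    sets <- list(randomSet("mcl"), randomSet("cmc"), randomSet("ipca"))
    comb <- combineClusters(sets, net)
    mem <- clusterMembers(comb)
    if (length(mem) > 1L) {
        pr <- t(combn(seq_along(mem), 2))
        jac <- apply(pr, 1L, function(ij)
            jaccardSimilarity(mem[[ij[1]]], mem[[ij[2]]]))
        expect_true(all(jac < 0.75))
    }
    ## adding a set that reproduces an existing cluster never lowers its score
    target <- mem[[1L]]
    extra <- ClusterSet(list(target), density = 0.1, provenance = "rnsc")
    comb2 <- combineClusters(c(sets, list(extra)), net)
    key <- vapply(clusterMembers(comb2), paste, character(1),
                  collapse = ",")
    hit <- which(vapply(clusterMembers(comb2), function(m)
        jaccardSimilarity(m, target) >= 0.75, logical(1)))
    expect_true(length(hit) >= 1L)
    expect_true(max(clusterScores(comb2)[hit]) >=
                clusterScores(comb)[1L])
})
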