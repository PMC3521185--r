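## Synthetic benchmark generator: planted complexes, class-conditional
## per-source score distributions, co-complex edge dropout and transient
## hub proteins, plus the closed-form likelihood-ratio oracle.

#' Parameters of the synthetic benchmark
#'
#' Describes the generative process the supervised weighting assumes:
#' complexes of bounded size planted on a protein universe; per data
#' source, co-complex pairs observed with a presence probability and
#' scores drawn from a co-complex Beta distribution, against a background
#' of uniformly sampled non-co-complex pairs with a lower-scoring Beta;
#' whole-pair dropout of co-complex relationships (missing interactions);
#' and transient-interaction hub proteins carrying many high-scoring
#' single-source (first source) edges that are nonetheless not co-complex
#' — the structured noise the supervised weighting must suppress.
#'
#' @param nProteins protein universe size.
#' @param nComplexes number of planted complexes.
#' @param sizeRange inclusive integer bounds of the uniform complex-size
#'   distribution.
#' @param overlapFraction expected fraction of each complex's members
#'   shared with previously planted complexes. The default 0 plants
#'   disjoint complexes, mirroring the lightly-overlapping structure of
#'   curated reference sets; positive values draw that fraction of
#'   members from already-used proteins.
#' @param sources named list; per source a list with \code{coPresence}
#'   (probability a non-dropped co-complex pair is observed),
#'   \code{coShape} / \code{bgShape} (Beta shape pairs for co-complex and
#'   background scores) and \code{nBackground} (target background edge
#'   count, which fixes the background presence probability).
#' @param dropout probability that a co-complex pair is missing from all
#'   sources.
#' @param nTransientHubs number of hub proteins.
#' @param hubDegreeMean Poisson mean of a hub's degree.
#' @param seed mandatory integer seed.
#' @return validated parameter list of class \code{synthParams}.
#' @export
synthParams <- function(nProteins = 2000L, nComplexes = 200L,
                        sizeRange = c(4L, 12L), overlapFraction = 0,
                        sources = list(
                            ppi = list(coPresence = 0.7,
                                       coShape = c(5, 2),
                                       bgShape = c(2, 5),
                                       nBackground = 15000L),
                            string = list(coPresence = 0.7,
                                          coShape = c(5, 2),
                                          bgShape = c(2, 5),
                                          nBackground = 15000L),
                            pubmed = list(coPresence = 0.7,
                                          coShape = c(5, 2),
                                          bgShape = c(2, 5),
                                          nBackground = 15000L)),
                        dropout = 0.2, nTransientHubs = 20L,
                        hubDegreeMean = 50, seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(nProteins >= 4L, nComplexes >= 1L,
              length(sizeRange) == 2L, sizeRange[1L] >= 2L,
              sizeRange[2L] >= sizeRange[1L],
              dropout >= 0, dropout < 1, nTransientHubs >= 0,
              overlapFraction >= 0, overlapFraction < 1,
              length(sources) >= 1L, !is.null(names(sources)))
    if (sizeRange[2L] > nProteins)
        stop("complexes cannot be larger than the protein universe")
    for (s in names(sources)) {
        p <- sources[[s]]
        stopifnot(p$coPresence > 0, p$coPresence <= 1,
                  length(p$coShape) == 2L, all(p$coShape > 0),
                  length(p$bgShape) == 2L, all(p$bgShape > 0),
                  p$nBackground >= 0)
    }
    structure(list(nProteins = as.integer(nProteins),
                   nComplexes = as.integer(nComplexes),
                   sizeRange = as.integer(sizeRange),
                   overlapFraction = overlapFraction,
                   sources = sources, dropout = dropout,
                   nTransientHubs = as.integer(nTransientHubs),
                   hubDegreeMean = hubDegreeMean,
                   seed = as.integer(seed)),
              class = "synthParams")
}

## m distinct canonical non-co-complex pairs sampled uniformly.
.sampleBackground <- function(m, proteins, coKeys) {
    n <- length(proteins)
    out <- character()
    while (length(out) < m) {
        draw <- max(1000L, ceiling((m - length(out)) * 1.4))
        i <- sample.int(n, draw, replace = TRUE)
        j <- sample.int(n, draw, replace = TRUE)
        ok <- i != j
        i <- i[ok]; j <- j[ok]
        cp <- .canonicalPairs(proteins[i], proteins[j])
        k <- .pairKeys(cp$proteinA, cp$proteinB)
        k <- k[!(k %in% coKeys)]
        out <- unique(c(out, k))
    }
    out[seq_len(m)]
}

#' Generate a synthetic benchmark
#'
#' Plants complexes (overlap across complexes allowed), samples per-source
#' presence and scores conditioned on the co-complex class, applies
#' whole-pair dropout to co-complex relationships, and adds transient hub
#' proteins whose edges are non-co-complex yet carry co-complex-like
#' scores in the first source only. Fully reproducible from the seed.
#'
#' @param params a [synthParams()] list.
#' @return list with \code{complexes} (a [ReferenceComplexSet-class]),
#'   \code{tables} (one [ScoredPairTable-class] per source) and
#'   \code{labels} (data.frame proteinA, proteinB, label giving the
#'   ground-truth class of every emitted pair).
#' @export
generateBenchmark <- function(params) {
    stopifnot(inherits(params, "synthParams"))
    set.seed(params$seed)
    width <- nchar(as.character(params$nProteins))
    proteins <- sprintf(paste0("P%0", width, "d"),
                        seq_len(params$nProteins))
    sizes <- sample(seq(params$sizeRange[1L], params$sizeRange[2L]),
                    params$nComplexes, replace = TRUE)
    unused <- sample(proteins)
    used <- character()
    members <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
        nShared <- if (length(used))
            min(.roundHalfAway(params$overlapFraction * sizes[i]),
                length(used)) else 0L
        nNew <- sizes[i] - nShared
        if (nNew > length(unused))
            stop("complexes need more proteins than exist in the universe")
        new <- unused[seq_len(nNew)]
        unused <- unused[-seq_len(nNew)]
        shared <- if (nShared > 0) sample(used, nShared) else character()
        members[[i]] <- c(new, shared)
        used <- c(used, new)
    }
    names(members) <- sprintf("synth_complex_%03d", seq_along(members))
    complexes <- ReferenceComplexSet(members, role = "reference")
    co <- .coMemberKeys(complexes)
    observedCo <- co[stats::runif(length(co)) >= params$dropout]
    tables <- vector("list", length(params$sources))
    names(tables) <- names(params$sources)
    hubSource <- names(params$sources)[1L]
    inComplex <- unique(unlist(members, use.names = FALSE))
    for (s in names(params$sources)) {
        p <- params$sources[[s]]
        present <- observedCo[stats::runif(length(observedCo)) <
                                  p$coPresence]
        coScores <- stats::rbeta(length(present), p$coShape[1L],
                                 p$coShape[2L])
        bgKeys <- if (p$nBackground > 0)
            .sampleBackground(p$nBackground, proteins, co) else character()
        bgScores <- stats::rbeta(length(bgKeys), p$bgShape[1L],
                                 p$bgShape[2L])
        keys <- c(present, bgKeys)
        scores <- c(coScores, bgScores)
        if (s == hubSource && params$nTransientHubs > 0) {
            pool <- setdiff(proteins, inComplex)
            if (length(pool) < params$nTransientHubs) {
                warning("fewer complex-free proteins than hubs requested")
                pool <- proteins
            }
            hubs <- sample(pool, params$nTransientHubs)
            hubKeys <- unlist(lapply(hubs, function(h) {
                deg <- stats::rpois(1L, params$hubDegreeMean)
                partners <- sample(setdiff(proteins, h), min(deg,
                    params$nProteins - 1L))
                cp <- .canonicalPairs(rep(h, length(partners)), partners)
                .pairKeys(cp$proteinA, cp$proteinB)
            }), use.names = FALSE)
            hubKeys <- setdiff(unique(hubKeys), co)
            hubScores <- stats::rbeta(length(hubKeys),
                                      params$sources[[s]]$coShape[1L],
                                      params$sources[[s]]$coShape[2L])
            keys <- c(keys, hubKeys)
            scores <- c(scores, hubScores)
        }
        parts <- strsplit(keys, "\t", fixed = TRUE)
        tables[[s]] <- ScoredPairTable(
            vapply(parts, `[`, character(1), 1L),
            vapply(parts, `[`, character(1), 2L),
            scores, sourceName = s)
    }
    allKeys <- sort(unique(unlist(lapply(tables, function(t)
        .pairKeys(t@pairs$proteinA, t@pairs$proteinB)),
        use.names = FALSE)))
    parts <- strsplit(allKeys, "\t", fixed = TRUE)
    labels <- data.frame(
        proteinA = vapply(parts, `[`, character(1), 1L),
        proteinB = vapply(parts, `[`, character(1), 2L),
        label = ifelse(allKeys %in% co, "co-complex", "non-co-complex"),
        stringsAsFactors = FALSE)
    list(complexes = complexes, tables = tables, labels = labels)
}

#' Closed-form likelihood ratios of the generative process
#'
#' Integrates the generator's class-conditional score distributions over
#' the bins of a discretization scheme to produce the exact likelihood
#' ratio the learner should recover. The computation conditions on
#' network membership (a pair is an edge iff at least one source relates
#' it), exactly as the learner does: the zero bin of a feature receives
#' the probability that the source is absent while some other source is
#' present. Expected transient-hub edges are folded into the
#' non-co-complex class of the hub source. Whole-pair dropout cancels
#' under the conditioning and does not enter.
#'
#' @param params a [synthParams()] list.
#' @param scheme a [DiscretizationScheme-class] over the sources.
#' @return data.frame with columns \code{feature}, \code{bin}, \code{lo},
#'   \code{hi}, \code{pCo}, \code{pNon}, \code{ratio} and
#'   \code{degenerate} (TRUE when one class has no mass in the bin, where
#'   the learner's smoothed estimate is bounded by the pseudocount).
#' @export
trueLikelihoodRatios <- function(params, scheme) {
    stopifnot(inherits(params, "synthParams"),
              is(scheme, "DiscretizationScheme"))
    srcs <- names(params$sources)
    retained <- names(scheme@dropped)[!scheme@dropped]
    stopifnot(all(retained %in% srcs))
    qc <- vapply(params$sources, function(p) p$coPresence, numeric(1))
    sz <- seq(params$sizeRange[1L], params$sizeRange[2L])
    expCoPairs <- params$nComplexes * mean(choose(sz, 2))
    M <- choose(params$nProteins, 2) - expCoPairs
    qn <- vapply(params$sources, function(p) p$nBackground / M,
                 numeric(1))
    H <- params$nTransientHubs * params$hubDegreeMean
    hubSource <- srcs[1L]
    pEdgeC <- 1 - prod(1 - qc)
    pEdgeN <- 1 - prod(1 - qn)
    out <- lapply(retained, function(f) {
        rng <- binRanges(scheme, f)
        zeroIn <- rng$lo <= 0 & rng$hi > 0
        dBeta <- function(shape) {
            stats::pbeta(pmin(pmax(rng$hi, 0), 1), shape[1L], shape[2L]) -
                stats::pbeta(pmin(pmax(rng$lo, 0), 1), shape[1L],
                             shape[2L])
        }
        othersC <- 1 - prod(1 - qc[setdiff(srcs, f)])
        othersN <- 1 - prod(1 - qn[setdiff(srcs, f)])
        pC <- zeroIn * (1 - qc[[f]]) * othersC +
            qc[[f]] * dBeta(params$sources[[f]]$coShape)
        pC <- pC / pEdgeC
        ## non-co-complex: plain background pairs plus expected hub edges
        pNplain <- zeroIn * (1 - qn[[f]]) * othersN +
            qn[[f]] * dBeta(params$sources[[f]]$bgShape)
        hubBin <- if (f == hubSource)
            dBeta(params$sources[[f]]$coShape) else as.numeric(zeroIn)
        pN <- (M * pNplain + H * hubBin) / (M * pEdgeN + H)
        data.frame(feature = f, bin = rng$bin, lo = rng$lo, hi = rng$hi,
                   pCo = pC, pNon = pN,
                   ratio = ifelse(pN > 0, pC / pN, Inf),
                   degenerate = pN == 0 | pC == 0,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
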