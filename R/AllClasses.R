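#' @import methods
#' @importFrom stats setNames
NULL

## Internal helpers shared by all modules -------------------------------------

## Canonical unordered-pair representation: proteinA is the lexicographically
## smaller ID. Every module stores and compares pairs in this form so that
## (u, v) and (v, u) always map to the same edge key.
.canonicalPairs <- function(a, b) {
    a <- as.character(a)
    b <- as.character(b)
    swap <- a > b
    if (any(swap)) {
        tmp <- a[swap]
        a[swap] <- b[swap]
        b[swap] <- tmp
    }
    list(proteinA = a, proteinB = b)
}

.pairKeys <- function(a, b) paste(a, b, sep = "\t")

.msg <- function(...) message("[cocomplex] ", ...)

#' Scored protein-pair table for one data source
#'
#' Holds the scored pairs contributed by a single data source: for each
#' unordered protein pair (u, v), the source relates u to v with a score
#' (in [0, 1] for the built-in sources). Pairs are stored canonically with
#' \code{proteinA < proteinB}; duplicates and self-pairs are invalid.
#'
#' @slot sourceName single character label naming the data source.
#' @slot pairs data.frame with columns \code{proteinA}, \code{proteinB},
#'   \code{score}.
#'
#' @seealso [readScoredPairs()], [assembleComposite()]
#' @export
setClass("ScoredPairTable",
    slots = c(sourceName = "character", pairs = "data.frame"))

setValidity("ScoredPairTable", function(object) {
    p <- object@pairs
    if (length(object@sourceName) != 1L || !nzchar(object@sourceName))
        return("sourceName must be a single non-empty string")
    if (!all(c("proteinA", "proteinB", "score") %in% names(p)))
        return("pairs must have columns proteinA, proteinB, score")
    if (nrow(p) == 0L) return(TRUE)
    if (any(p$proteinA == p$proteinB)) return("self-pairs are not allowed")
    if (any(p$proteinA > p$proteinB))
        return("pairs must be canonical (proteinA < proteinB)")
    if (anyDuplicated(.pairKeys(p$proteinA, p$proteinB)))
        return("duplicate unordered pairs")
    if (any(!is.finite(p$score))) return("scores must be finite")
    TRUE
})

#' Construct a ScoredPairTable
#'
#' Canonicalizes pairs, drops self-pairs (with a warning) and collapses
#' duplicate unordered pairs keeping the maximum score (union semantics of
#' repository merges).
#'
#' @param proteinA,proteinB character vectors of protein IDs (opaque,
#'   case-sensitive strings).
#' @param score numeric vector of per-pair scores.
#' @param sourceName label for the data source.
#' @return A [ScoredPairTable-class] object.
#' @export
ScoredPairTable <- function(proteinA = character(), proteinB = character(),
                            score = numeric(), sourceName = "source") {
    stopifnot(length(proteinA) == length(proteinB),
              length(proteinA) == length(score))
    cp <- .canonicalPairs(proteinA, proteinB)
    a <- cp$proteinA; b <- cp$proteinB; s <- as.numeric(score)
    self <- a == b
    if (any(self)) {
        warning(sum(self), " self-pair(s) dropped from source '",
                sourceName, "'")
        a <- a[!self]; b <- b[!self]; s <- s[!self]
    }
    if (length(a)) {
        key <- .pairKeys(a, b)
        if (anyDuplicated(key)) {
            agg <- tapply(s, key, max)
            uk <- names(agg)
            s <- as.numeric(agg)
            parts <- strsplit(uk, "\t", fixed = TRUE)
            a <- vapply(parts, `[`, character(1), 1L)
            b <- vapply(parts, `[`, character(1), 2L)
        }
        o <- order(a, b)
        a <- a[o]; b <- b[o]; s <- s[o]
    }
    new("ScoredPairTable", sourceName = sourceName,
        pairs = data.frame(proteinA = a, proteinB = b, score = s,
                           stringsAsFactors = FALSE))
}

#' Reference complex set
#'
#' A curated set of protein complexes (e.g. CYC2008- or CORUM-style lists)
#' used for training the edge-weighting model and/or for evaluation. Each
#' complex is a set of at least two protein IDs with a unique identifier.
#'
#' @slot complexes named list of character vectors (member sets).
#' @slot role one of \code{"reference"}, \code{"training"}, \code{"test"}.
#' @export
setClass("ReferenceComplexSet",
    slots = c(complexes = "list", role = "character"))

setValidity("ReferenceComplexSet", function(object) {
    cx <- object@complexes
    if (length(object@role) != 1L)
        return("role must be a single string")
    if (length(cx)) {
        if (is.null(names(cx)) || anyDuplicated(names(cx)) ||
            any(!nzchar(names(cx))))
            return("complexes must have unique non-empty identifiers")
        sizes <- lengths(cx)
        if (any(sizes < 2L)) return("every complex needs >= 2 members")
        if (any(vapply(cx, function(m) any(!nzchar(m)) || anyDuplicated(m) > 0,
                       logical(1))))
            return("members must be non-empty, unique IDs")
    }
    TRUE
})

#' Construct a ReferenceComplexSet
#'
#' @param complexes list of character vectors; names are used as complex
#'   identifiers (autogenerated when missing). Member vectors are
#'   deduplicated; complexes with fewer than two distinct members are
#'   dropped with a warning.
#' @param role the intended role of the set.
#' @return A [ReferenceComplexSet-class].
#' @export
ReferenceComplexSet <- function(complexes = list(), role = "reference") {
    complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
    if (is.null(names(complexes)) && length(complexes))
        names(complexes) <- sprintf("complex_%d", seq_along(complexes))
    empty <- !nzchar(names(complexes))
    if (any(empty))
        names(complexes)[empty] <- sprintf("complex_%d", which(empty))
    small <- lengths(complexes) < 2L
    if (any(small)) {
        warning(sum(small), " complex(es) with < 2 members dropped")
        complexes <- complexes[!small]
    }
    new("ReferenceComplexSet", complexes = complexes, role = role)
}

#' Composite protein network
#'
#' Undirected graph over proteins whose edges carry one feature value per
#' data source (0 when the source does not relate the pair). An edge exists
#' iff at least one source relates its endpoints. After supervision the
#' edges additionally carry a class label (co-complex / non-co-complex) and,
#' after weighting, a posterior co-complex probability in [0, 1].
#'
#' @slot edges data.frame with canonical columns \code{proteinA},
#'   \code{proteinB}.
#' @slot features numeric matrix, one row per edge, one column per source.
#' @slot labels character(0), or one of \code{"co-complex"} /
#'   \code{"non-co-complex"} per edge.
#' @slot weights numeric(0), or one posterior weight per edge.
#' @export
setClass("CompositeNetwork",
    slots = c(edges = "data.frame", features = "matrix",
              labels = "character", weights = "numeric"))

setValidity("CompositeNetwork", function(object) {
    e <- object@edges
    f <- object@features
    if (!all(c("proteinA", "proteinB") %in% names(e)))
        return("edges must have columns proteinA, proteinB")
    if (nrow(e) != nrow(f)) return("features must have one row per edge")
    if (nrow(e)) {
        if (any(e$proteinA >= e$proteinB))
            return("edges must be canonical (proteinA < proteinB) without self-loops")
        if (anyDuplicated(.pairKeys(e$proteinA, e$proteinB)))
            return("duplicate edges")
        if (is.null(colnames(f)) || anyDuplicated(colnames(f)))
            return("features need unique column names (source names)")
        if (any(!is.finite(f))) return("feature values must be finite")
        if (any(rowSums(f != 0) == 0))
            return("an edge must have at least one non-zero feature")
    }
    if (length(object@labels) &&
        (length(object@labels) != nrow(e) ||
         !all(object@labels %in% c("co-complex", "non-co-complex"))))
        return("labels must be empty or one co-complex/non-co-complex value per edge")
    if (length(object@weights)) {
        if (length(object@weights) != nrow(e))
            return("weights must be empty or one value per edge")
        if (any(!is.finite(object@weights) | object@weights < 0 |
                object@weights > 1))
            return("weights must lie in [0, 1]")
    }
    TRUE
})

#' Predicted cluster set
#'
#' Clusters predicted by one or several algorithms. Member sets may overlap.
#' Each cluster carries its weighted density, its score (density, or density
#' multiplied by the vote count after aggregation) and the set of algorithms
#' that produced it.
#'
#' @slot members list of character vectors (member protein sets).
#' @slot density numeric weighted densities.
#' @slot score numeric cluster scores (>= density).
#' @slot provenance list of character vectors (algorithm names).
#' @export
setClass("ClusterSet",
    slots = c(members = "list", density = "numeric", score = "numeric",
              provenance = "list"))

setValidity("ClusterSet", function(object) {
    n <- length(object@members)
    if (length(object@density) != n || length(object@score) != n ||
        length(object@provenance) != n)
        return("members, density, score, provenance must have equal length")
    if (n == 0L) return(TRUE)
    if (any(lengths(object@members) < 2L))
        return("clusters need >= 2 members")
    if (any(lengths(object@provenance) == 0L))
        return("provenance must be non-empty")
    if (any(object@score < object@density - 1e-12))
        return("score must be >= density")
    TRUE
})

#' Construct a ClusterSet
#'
#' @param members list of character vectors.
#' @param density,score numeric vectors (score defaults to density).
#' @param provenance list of character vectors, or a single algorithm name
#'   recycled to all clusters.
#' @return A [ClusterSet-class].
#' @export
ClusterSet <- function(members = list(), density = numeric(length(members)),
                       score = density, provenance = "unknown") {
    members <- lapply(members, function(m) sort(unique(as.character(m))))
    if (!is.list(provenance))
        provenance <- rep(list(as.character(provenance)), length(members))
    new("ClusterSet", members = members, density = as.numeric(density),
        score = as.numeric(score), provenance = provenance)
}

#' Supervised discretization scheme
#'
#' Per-feature cut points found by entropy-based recursive partitioning
#' with the minimum-description-length stopping rule. A feature for which
#' no top-level cut is accepted is flagged dropped and excluded from the
#' naive-Bayes model (implicit feature selection).
#'
#' @slot cuts named list; per feature a strictly increasing numeric vector
#'   of cut points (empty when dropped).
#' @slot dropped named logical vector, one flag per feature.
#' @export
setClass("DiscretizationScheme",
    slots = c(cuts = "list", dropped = "logical"))

setValidity("DiscretizationScheme", function(object) {
    if (!identical(names(object@cuts), names(object@dropped)))
        return("cuts and dropped must be parallel named entries")
    for (f in names(object@cuts)) {
        cc <- object@cuts[[f]]
        if (is.unsorted(cc, strictly = TRUE))
            return(sprintf("cut points for '%s' must be strictly increasing", f))
        if (!object@dropped[[f]] && length(cc) == 0L)
            return(sprintf("retained feature '%s' has no cuts", f))
    }
    TRUE
})

#' Two-class naive-Bayes co-complex model
#'
#' Maximum-likelihood naive-Bayes model over discretized source features,
#' with classes co-complex and non-co-complex. Conditional bin
#' probabilities are smoothed with a pseudocount \code{alpha}; class priors
#' are unsmoothed edge-label frequencies.
#'
#' @slot scheme the [DiscretizationScheme-class] used to bin features.
#' @slot classCounts named numeric: number of co-complex and
#'   non-co-complex training edges.
#' @slot counts named list; per retained feature a 2 x nbins count matrix
#'   (rows \code{co-complex}, \code{non-co-complex}).
#' @slot condProb named list; per retained feature the smoothed conditional
#'   probability matrix, rows summing to 1.
#' @slot priors named numeric class priors summing to 1.
#' @slot alpha smoothing pseudocount.
#' @export
setClass("NaiveBayesModel",
    slots = c(scheme = "DiscretizationScheme", classCounts = "numeric",
              counts = "list", condProb = "list", priors = "numeric",
              alpha = "numeric"))

setValidity("NaiveBayesModel", function(object) {
    cls <- c("co-complex", "non-co-complex")
    if (!identical(names(object@priors), cls))
        return("priors must be named co-complex, non-co-complex")
    if (abs(sum(object@priors) - 1) > 1e-9)
        return("priors must sum to 1")
    for (f in names(object@condProb)) {
        p <- object@condProb[[f]]
        if (!identical(rownames(p), cls))
            return("condProb rows must be co-complex, non-co-complex")
        if (any(p < 0)) return("probabilities must be non-negative")
        if (object@alpha > 0 && any(p <= 0))
            return("smoothed probabilities must be positive")
        if (any(abs(rowSums(p) - 1) > 1e-9))
            return("bin probabilities must sum to 1 per class")
    }
    TRUE
})

#' Precision-recall curve
#'
#' Score-thresholded precision/recall points (cluster-level or edge-level)
#' together with the trapezoidal area under the curve. For edge
#' classification each point also reports the fraction of test complexes
#' covered by at least one retained edge.
#'
#' @slot points data.frame with columns \code{threshold}, \code{recall},
#'   \code{precision}, \code{nRetained} and optionally \code{coverage};
#'   thresholds strictly decreasing.
#' @slot auc area under the precision-recall curve, trapezoidal over recall.
#' @export
setClass("PRCurve", slots = c(points = "data.frame", auc = "numeric"))

setValidity("PRCurve", function(object) {
    p <- object@points
    need <- c("threshold", "recall", "precision", "nRetained")
    if (!all(need %in% names(p)))
        return("points must have threshold, recall, precision, nRetained")
    if (nrow(p) > 1L && any(diff(p$threshold) >= 0))
        return("thresholds must be strictly decreasing")
    if (nrow(p) > 1L && any(diff(p$recall) < -1e-12))
        return("recall must be non-decreasing")
    if (any(p$recall < -1e-12 | p$recall > 1 + 1e-12) ||
        any(p$precision < -1e-12 | p$precision > 1 + 1e-12))
        return("recall and precision must lie in [0, 1]")
    TRUE
})

#' Score-to-precision calibration table
#'
#' Monotone mapping from cluster score to estimated precision, pooled over
#' cross-validation rounds: scores are binned, empirical precision computed
#' per bin, and flattened to be non-increasing as the score decreases.
#'
#' @slot bins data.frame with columns \code{scoreLo}, \code{scoreHi},
#'   \code{precision}, \code{n}, ordered by increasing score.
#' @export
setClass("CalibrationTable", slots = c(bins = "data.frame"))

setValidity("CalibrationTable", function(object) {
    b <- object@bins
    if (!all(c("scoreLo", "scoreHi", "precision", "n") %in% names(b)))
        return("bins must have scoreLo, scoreHi, precision, n")
    if (nrow(b) > 1L && any(diff(b$scoreLo) <= 0))
        return("bins must be ordered by increasing score")
    if (any(b$precision < -1e-12 | b$precision > 1 + 1e-12))
        return("precision must lie in [0, 1]")
    if (nrow(b) > 1L && any(diff(b$precision) < -1e-9))
        return("precision must be non-decreasing with score")
    TRUE
})

#' Ontology DAG (BP/CC/MF)
#'
#' Minimal Gene Ontology representation: terms with a namespace and
#' is_a/part_of parent links, plus the precomputed ancestor closure
#' (every term is its own ancestor).
#'
#' @slot terms character vector of term IDs.
#' @slot name named character, human-readable term names.
#' @slot namespace named character, one of BP/CC/MF per term.
#' @slot parents named list of parent term IDs.
#' @slot ancestors named list of ancestor closures (including self).
#' @export
setClass("OntologyDag",
    slots = c(terms = "character", name = "character",
              namespace = "character", parents = "list",
              ancestors = "list"))

#' Protein annotation map
#'
#' Direct protein-to-term annotations per namespace, validated against an
#' [OntologyDag-class].
#'
#' @slot table data.frame with columns \code{protein}, \code{term},
#'   \code{namespace}.
#' @export
setClass("AnnotationMap", slots = c(table = "data.frame"))
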