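## Entropy-based supervised discretization with the minimum-description-length
## stopping rule (recursive binary splitting of each feature's range).

## Binary class entropy (base 2) from two counts.
.ent2 <- function(n1, n2) {
    n <- n1 + n2
    p1 <- ifelse(n1 > 0, n1 / n, 0)
    p2 <- ifelse(n2 > 0, n2 / n, 0)
    -(ifelse(n1 > 0, p1 * log2(p1), 0) + ifelse(n2 > 0, p2 * log2(p2), 0))
}

## Find the best accepted cut for the sorted segment [lo, hi] (global
## indices), or NA. cum1/cum2 are global cumulative class counts, v the
## sorted values. Candidate cuts are midpoints between consecutive distinct
## values; the best information-gain cut is kept iff it clears the MDL
## acceptance threshold.
.mdlBestCut <- function(v, cum1, cum2, lo, hi) {
    N <- hi - lo + 1L
    if (N < 2L) return(NA_real_)
    cand <- which(v[lo:(hi - 1L)] < v[(lo + 1L):hi]) + lo - 1L
    if (!length(cand)) return(NA_real_)
    base1 <- if (lo > 1L) cum1[lo - 1L] else 0
    base2 <- if (lo > 1L) cum2[lo - 1L] else 0
    n1 <- cum1[hi] - base1
    n2 <- cum2[hi] - base2
    entS <- .ent2(n1, n2)
    l1 <- cum1[cand] - base1
    l2 <- cum2[cand] - base2
    r1 <- n1 - l1
    r2 <- n2 - l2
    nL <- l1 + l2
    nR <- r1 + r2
    entL <- .ent2(l1, l2)
    entR <- .ent2(r1, r2)
    gain <- entS - (nL / N) * entL - (nR / N) * entR
    best <- which.max(gain)            # ties: smallest cut value
    k <- (n1 > 0) + (n2 > 0)
    k1 <- (l1[best] > 0) + (l2[best] > 0)
    k2 <- (r1[best] > 0) + (r2[best] > 0)
    thresh <- (log2(N - 1) + log2(3^k - 2) - k * entS +
               k1 * entL[best] + k2 * entR[best]) / N
    if (gain[best] > thresh)
        (v[cand[best]] + v[cand[best] + 1L]) / 2
    else
        NA_real_
}

#' MDL supervised discretization of one feature
#'
#' Recursively splits the sorted feature range at the information-gain
#' maximizing midpoint between consecutive distinct values; a split of
#' segment S at cut T is accepted iff
#' \deqn{Gain(T;S) > \frac{\log_2(N-1) + \log_2(3^k-2) - k\,Ent(S) +
#'   k_1 Ent(S_1) + k_2 Ent(S_2)}{N}}
#' where N = |S|, k / k1 / k2 count the classes present in S / S1 / S2 and
#' Ent is the binary class entropy (base 2). A feature whose top-level
#' split is rejected carries no class information and is flagged dropped
#' (implicit feature selection).
#'
#' @param values numeric feature values.
#' @param labels parallel class labels (any two-valued vector).
#' @return list with components \code{cuts} (sorted accepted cut points)
#'   and \code{dropped} (TRUE when no top-level cut was accepted).
#' @export
mdlDiscretize <- function(values, labels) {
    stopifnot(length(values) == length(labels), length(values) >= 2L)
    if (any(!is.finite(values)))
        stop("non-finite feature value at index ",
             which(!is.finite(values))[1L])
    y <- as.integer(factor(labels))
    o <- order(values)
    v <- values[o]
    y <- y[o]
    cum1 <- cumsum(y == 1L)
    cum2 <- cumsum(y != 1L)
    cuts <- numeric()
    stack <- list(c(1L, length(v)))
    while (length(stack)) {
        seg <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        cut <- .mdlBestCut(v, cum1, cum2, seg[1L], seg[2L])
        if (!is.na(cut)) {
            cuts <- c(cuts, cut)
            ## split index: last position with value < cut
            mid <- seg[1L] - 1L +
                findInterval(cut, v[seg[1L]:seg[2L]])
            stack <- c(stack, list(c(seg[1L], mid), c(mid + 1L, seg[2L])))
        }
    }
    list(cuts = sort(cuts), dropped = length(cuts) == 0L)
}

#' Discretize all features of a labelled composite network
#'
#' Runs [mdlDiscretize()] on every feature column against the edge class
#' labels and collects the per-feature schemes. Features with no accepted
#' cut are flagged dropped.
#'
#' @param network a labelled [CompositeNetwork-class] (see [labelEdges()]).
#' @return A [DiscretizationScheme-class].
#' @export
discretizeFeatures <- function(network) {
    stopifnot(is(network, "CompositeNetwork"))
    if (!length(network@labels))
        stop("network must be labelled before discretization")
    feats <- colnames(network@features)
    cuts <- vector("list", length(feats))
    names(cuts) <- feats
    dropped <- logical(length(feats))
    names(dropped) <- feats
    for (f in feats) {
        d <- mdlDiscretize(network@features[, f], network@labels)
        cuts[[f]] <- d$cuts
        dropped[[f]] <- d$dropped
        if (d$dropped)
            .msg("feature '", f, "' carries no class information; dropped")
    }
    new("DiscretizationScheme", cuts = cuts, dropped = dropped)
}

#' Bin values under a discretization scheme
#'
#' Maps each value to its half-open bin index (1-based); with cut points
#' c1 < ... < ck the bins are (-Inf, c1), [c1, c2), ..., [ck, Inf).
#'
#' @param values numeric vector.
#' @param cuts strictly increasing cut points.
#' @return integer bin indices in 1..(length(cuts) + 1).
#' @export
binValues <- function(values, cuts) {
    findInterval(values, cuts) + 1L
}

#' Bin boundaries of a scheme feature
#'
#' @param scheme a [DiscretizationScheme-class].
#' @param feature feature name.
#' @return data.frame with columns \code{bin}, \code{lo}, \code{hi}.
#' @export
binRanges <- function(scheme, feature) {
    cuts <- scheme@cuts[[feature]]
    if (is.null(cuts)) stop("unknown feature: ", feature)
    lo <- c(-Inf, cuts)
    hi <- c(cuts, Inf)
    data.frame(bin = seq_along(lo), lo = lo, hi = hi)
}
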