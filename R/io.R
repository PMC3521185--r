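## Readers/writers for the on-disk formats: scored pair TSVs, complex lists,
## cluster files, literature incidence tables and the persisted model.

#' Read a scored protein-pair table
#'
#' Reads a tab-separated file with columns proteinA, proteinB, score (no
#' header). Duplicate unordered pairs are collapsed keeping the maximum
#' score; self-pairs are dropped with a warning. When \code{minScore} is
#' given, only pairs with score strictly greater than it are kept (the
#' cutoff used for functional-association scores is 0.5).
#'
#' @param path file path.
#' @param sourceName label for the data source.
#' @param minScore numeric or NULL; strict lower cutoff on the score.
#' @return A [ScoredPairTable-class].
#' @export
readScoredPairs <- function(path, sourceName, minScore = NULL) {
    if (!file.exists(path)) stop("scored-pair file not found: ", path)
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    if (!length(raw))
        return(ScoredPairTable(sourceName = sourceName))
    parts <- strsplit(raw, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("line ", bad[1L], ": expected >= 3 tab-separated columns")
    a <- vapply(parts, `[`, character(1), 1L)
    b <- vapply(parts, `[`, character(1), 2L)
    s <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
    if (anyNA(s))
        stop("line ", which(is.na(s))[1L], ": unparsable score")
    tab <- ScoredPairTable(a, b, s, sourceName = sourceName)
    if (!is.null(minScore)) {
        keep <- tab@pairs$score > minScore
        tab@pairs <- tab@pairs[keep, , drop = FALSE]
        rownames(tab@pairs) <- NULL
    }
    tab
}

#' Write a scored pair table as TSV
#'
#' @param table a [ScoredPairTable-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeScoredPairs <- function(table, path) {
    stopifnot(is(table, "ScoredPairTable"))
    utils::write.table(table@pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a reference complex set
#'
#' One complex per line, tab-separated member IDs, optionally preceded by
#' an identifier column. Complexes with fewer than two distinct members are
#' dropped with a warning; members on one line are deduplicated.
#'
#' @param path file path.
#' @param idColumn logical; does each line start with a complex identifier?
#' @param role role to assign the set.
#' @return A [ReferenceComplexSet-class] with stable (file) ordering.
#' @export
readComplexes <- function(path, idColumn = FALSE, role = "reference") {
    if (!file.exists(path)) stop("complex file not found: ", path)
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    parts <- strsplit(raw, "\t", fixed = TRUE)
    if (idColumn) {
        ids <- vapply(parts, `[`, character(1), 1L)
        members <- lapply(parts, `[`, -1L)
    } else {
        ids <- sprintf("complex_%d", seq_along(parts))
        members <- parts
    }
    names(members) <- make.unique(ids)
    ReferenceComplexSet(members, role = role)
}

#' Write / read cluster files
#'
#' Cluster files have one cluster per line: tab-separated member IDs,
#' optionally preceded by a numeric score column. \code{writeClusters}
#' always writes the score prefix; \code{readClusters} parses it when
#' \code{scorePrefix = TRUE} and otherwise recomputes nothing (clusters
#' without a score get density/score 0, to be rescored downstream with
#' [rescoreClusters()]). Empty lines are skipped with a warning. Reading
#' assigns provenance \code{algorithmName} to every cluster.
#'
#' @param clusters a [ClusterSet-class].
#' @param path file path.
#' @param scorePrefix logical; is/should the first column (be) the score?
#' @param algorithmName provenance label for clusters read from file.
#' @return \code{readClusters}: a [ClusterSet-class].
#' @export
writeClusters <- function(clusters, path, scorePrefix = TRUE) {
    stopifnot(is(clusters, "ClusterSet"))
    lines <- vapply(seq_along(clusters@members), function(i) {
        mem <- paste(clusters@members[[i]], collapse = "\t")
        if (scorePrefix)
            paste(format(clusters@score[i], digits = 17, scientific = FALSE,
                         trim = TRUE), mem, sep = "\t")
        else mem
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path, algorithmName, scorePrefix = TRUE) {
    if (!file.exists(path)) stop("cluster file not found: ", path)
    raw <- readLines(path)
    empty <- !nzchar(trimws(raw))
    if (any(empty)) {
        warning(sum(empty), " empty line(s) skipped in ", path)
        raw <- raw[!empty]
    }
    parts <- strsplit(raw, "\t", fixed = TRUE)
    if (scorePrefix) {
        score <- suppressWarnings(
            as.numeric(vapply(parts, `[`, character(1), 1L)))
        if (anyNA(score))
            stop("line ", which(is.na(score))[1L],
                 ": unparsable score prefix")
        members <- lapply(parts, `[`, -1L)
    } else {
        score <- rep(0, length(parts))
        members <- parts
    }
    ClusterSet(members = members, density = score, score = score,
               provenance = algorithmName)
}

#' Read a literature incidence table
#'
#' Tab-separated file with columns (protein, document-ID); one row per
#' mention. Returns the protein-to-document-set mapping used by
#' [literatureJaccard()].
#'
#' @param path file path.
#' @return named list: per protein, the character vector of document IDs.
#' @export
readLiteratureIncidence <- function(path) {
    if (!file.exists(path)) stop("incidence file not found: ", path)
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    if (!length(raw)) return(list())
    parts <- strsplit(raw, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
        stop("line ", which(lengths(parts) < 2L)[1L],
             ": expected 2 tab-separated columns (protein, document)")
    prot <- vapply(parts, `[`, character(1), 1L)
    doc <- vapply(parts, `[`, character(1), 2L)
    lapply(split(doc, prot), unique)
}

#' Persist / restore a fitted naive-Bayes model
#'
#' The model is written as a structured plain-text file: discretization cut
#' points, class counts and priors, per-feature per-bin counts and smoothed
#' conditional probabilities.
#'
#' @param model a [NaiveBayesModel-class].
#' @param path file path.
#' @return \code{readNaiveBayesModel}: the restored model.
#' @export
writeNaiveBayesModel <- function(model, path) {
    stopifnot(is(model, "NaiveBayesModel"))
    num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    wl <- function(...) writeLines(paste(..., sep = "\t"), con)
    wl("alpha", num(model@alpha))
    wl("classCounts", num(model@classCounts[["co-complex"]]),
       num(model@classCounts[["non-co-complex"]]))
    wl("priors", num(model@priors[["co-complex"]]),
       num(model@priors[["non-co-complex"]]))
    for (f in names(model@scheme@cuts)) {
        dropped <- model@scheme@dropped[[f]]
        wl("feature", f, if (dropped) "dropped" else "retained")
        if (!dropped) {
            wl("cuts", paste(num(model@scheme@cuts[[f]]), collapse = "\t"))
            wl("counts.co", paste(num(model@counts[[f]]["co-complex", ]),
                                  collapse = "\t"))
            wl("counts.non", paste(num(model@counts[[f]]["non-co-complex", ]),
                                   collapse = "\t"))
        }
    }
    invisible(path)
}

#' @rdname writeNaiveBayesModel
#' @export
readNaiveBayesModel <- function(path) {
    if (!file.exists(path)) stop("model file not found: ", path)
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    key <- vapply(lines, `[`, character(1), 1L)
    val <- function(i) as.numeric(lines[[i]][-1L])
    alpha <- val(which(key == "alpha"))
    cc <- val(which(key == "classCounts"))
    classCounts <- c("co-complex" = cc[1L], "non-co-complex" = cc[2L])
    cuts <- list(); dropped <- logical(); counts <- list()
    i <- which(key == "feature")
    for (j in i) {
        f <- lines[[j]][2L]
        isDropped <- identical(lines[[j]][3L], "dropped")
        dropped[f] <- isDropped
        if (isDropped) {
            cuts[[f]] <- numeric()
        } else {
            cuts[[f]] <- val(j + 1L)
            m <- rbind("co-complex" = val(j + 2L),
                       "non-co-complex" = val(j + 3L))
            counts[[f]] <- m
        }
    }
    scheme <- new("DiscretizationScheme", cuts = cuts, dropped = dropped)
    .modelFromCounts(scheme, classCounts, counts, alpha)
}
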