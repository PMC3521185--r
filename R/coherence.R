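## GO-based semantic coherence of predicted complexes: minimal OBO/DAG
## handling, information content, most-informative-common-ancestor
## similarity, per-complex coherence and high-level process annotation.

.namespaceMap <- c(biological_process = "BP", cellular_component = "CC",
                   molecular_function = "MF",
                   BP = "BP", CC = "CC", MF = "MF")

#' Read an ontology in OBO format
#'
#' Minimal OBO reader covering what coherence scoring needs: term IDs,
#' names, namespaces and the is_a / part_of parent links. Other
#' relationship types are ignored with a single warning; obsolete terms
#' are skipped. The ancestor closure (every term is its own ancestor) is
#' precomputed; cycles are a fatal error.
#'
#' @param path OBO file path.
#' @return An [OntologyDag-class].
#' @export
readObo <- function(path) {
    if (!file.exists(path)) stop("OBO file not found: ", path)
    lines <- readLines(path)
    starts <- which(lines == "[Term]")
    ids <- character(); nm <- character(); ns <- character()
    parents <- list()
    ignored <- character()
    bounds <- c(starts, length(lines) + 1L)
    for (s in seq_along(starts)) {
        block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
        block <- block[nzchar(block) & !startsWith(block, "[")]
        getv <- function(key) {
            hit <- block[startsWith(block, paste0(key, ": "))]
            sub("^[a-z_]+: ", "", hit)
        }
        if (length(getv("is_obsolete")) &&
            any(getv("is_obsolete") == "true")) next
        id <- getv("id")[1L]
        if (is.na(id) || !length(id)) next
        isa <- sub(" !.*$", "", getv("is_a"))
        rel <- getv("relationship")
        relType <- sub(" .*$", "", rel)
        partOf <- sub(" !.*$", "", sub("^part_of ", "", rel[relType == "part_of"]))
        ignored <- union(ignored, relType[relType != "part_of"])
        ids <- c(ids, id)
        nm <- c(nm, if (length(getv("name"))) getv("name")[1L] else id)
        nsRaw <- getv("namespace")
        ns <- c(ns, if (length(nsRaw)) unname(.namespaceMap[nsRaw[1L]])
                else NA_character_)
        parents[[id]] <- unique(c(isa, partOf))
    }
    if (length(ignored))
        warning("ignored relationship type(s): ",
                paste(ignored, collapse = ", "))
    names(nm) <- ids
    names(ns) <- ids
    parents <- lapply(parents, function(p) intersect(p, ids))
    ontologyDag(ids, nm, ns, parents)
}

#' Construct an ontology DAG directly
#'
#' @param terms character term IDs.
#' @param name named character of term names (defaults to the IDs).
#' @param namespace named character (BP/CC/MF) per term.
#' @param parents named list of parent term IDs (is_a/part_of).
#' @return An [OntologyDag-class] with precomputed ancestor closures.
#' @export
ontologyDag <- function(terms, name = NULL, namespace, parents) {
    terms <- as.character(terms)
    if (is.null(name)) name <- stats::setNames(terms, terms)
    parents <- parents[terms]
    names(parents) <- terms
    parents[vapply(parents, is.null, logical(1))] <-
        list(character())
    ## ancestor closure by memoized depth-first walk; cycle detection via
    ## an in-progress mark
    anc <- vector("list", length(terms))
    names(anc) <- terms
    state <- stats::setNames(integer(length(terms)), terms) # 0/1/2
    visit <- function(t) {
        if (state[[t]] == 2L) return(anc[[t]])
        if (state[[t]] == 1L) stop("ontology contains a cycle at ", t)
        state[[t]] <<- 1L
        up <- unique(unlist(lapply(parents[[t]], visit),
                            use.names = FALSE))
        anc[[t]] <<- unique(c(t, up))
        state[[t]] <<- 2L
        anc[[t]]
    }
    for (t in terms) visit(t)
    new("OntologyDag", terms = terms, name = name,
        namespace = namespace[terms], parents = parents,
        ancestors = anc)
}

#' @rdname OntologyDag-class
#' @param dag an [OntologyDag-class].
#' @param term a term ID.
#' @return \code{termAncestors}: the ancestor closure including the term
#'   itself.
#' @export
termAncestors <- function(dag, term) {
    a <- dag@ancestors[[term]]
    if (is.null(a)) stop("unknown term: ", term)
    a
}

#' Build an annotation map
#'
#' Direct protein-to-term annotations. Terms absent from the DAG are
#' dropped with a warning; each annotation inherits its term's namespace.
#'
#' @param protein,term parallel character vectors.
#' @param dag the [OntologyDag-class] the terms live in.
#' @return An [AnnotationMap-class].
#' @export
annotationMap <- function(protein, term, dag) {
    stopifnot(length(protein) == length(term), is(dag, "OntologyDag"))
    known <- term %in% dag@terms
    if (any(!known))
        warning(sum(!known), " annotation(s) to unknown terms dropped")
    tab <- unique(data.frame(protein = as.character(protein)[known],
                             term = as.character(term)[known],
                             stringsAsFactors = FALSE))
    tab$namespace <- unname(dag@namespace[tab$term])
    new("AnnotationMap", table = tab)
}

#' Read a GAF-like annotation table
#'
#' Tab-separated columns (protein, term); namespaces come from the DAG.
#'
#' @param path file path.
#' @param dag the [OntologyDag-class].
#' @return An [AnnotationMap-class].
#' @export
readAnnotations <- function(path, dag) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    parts <- strsplit(raw, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
        stop("line ", which(lengths(parts) < 2L)[1L],
             ": expected 2 tab-separated columns (protein, term)")
    annotationMap(vapply(parts, `[`, character(1), 1L),
                  vapply(parts, `[`, character(1), 2L), dag)
}

## Per-protein ancestor-closed term sets in one namespace, and the
## term -> #covered-proteins table derived from them.
.proteinClosures <- function(dag, annotations, namespace) {
    tab <- annotations@table
    tab <- tab[!is.na(tab$namespace) & tab$namespace == namespace, ,
               drop = FALSE]
    if (!nrow(tab)) return(list())
    byProt <- split(tab$term, tab$protein)
    lapply(byProt, function(tt)
        unique(unlist(dag@ancestors[tt], use.names = FALSE)))
}

.coverCounts <- function(closures) {
    if (!length(closures)) return(numeric())
    tab <- table(unlist(closures, use.names = FALSE))
    stats::setNames(as.numeric(tab), names(tab))
}

#' Information content of a term
#'
#' IC(t) = -log2 p(t), where p(t) is the fraction of the namespace's
#' annotated proteins that are annotated to t or any of its descendants.
#' The corpus is the supplied annotation map itself; the namespace root
#' (covering every annotated protein) has IC 0.
#'
#' @param dag an [OntologyDag-class].
#' @param annotations an [AnnotationMap-class].
#' @param term a term ID.
#' @return non-negative IC; a term covering no annotated protein is an
#'   error (its IC is undefined).
#' @export
termIC <- function(dag, annotations, term) {
    ns <- dag@namespace[[term]]
    if (is.null(ns) || is.na(ns)) stop("unknown term or namespace: ", term)
    closures <- .proteinClosures(dag, annotations, ns)
    if (!length(closures))
        stop("no annotated proteins in namespace ", ns)
    cover <- .coverCounts(closures)
    cnt <- cover[term]
    if (is.na(cnt) || cnt == 0)
        stop("term ", term, " covers no annotated protein; IC undefined")
    unname(-log2(cnt / length(closures)))
}

#' Semantic similarity of two proteins
#'
#' The most-informative-common-ancestor similarity: the maximum, over
#' pairs of the two proteins' annotated terms, of the IC of the pair's
#' most informative common ancestor — equivalently, the maximum IC over
#' the intersection of the proteins' ancestor-closed annotation sets.
#' Returns NA (an uncomputable pair, distinct from similarity 0) when
#' either protein has no annotation in the namespace.
#'
#' @param dag an [OntologyDag-class].
#' @param annotations an [AnnotationMap-class].
#' @param u,v protein IDs.
#' @param namespace one of "BP", "CC", "MF".
#' @return numeric similarity, or NA when uncomputable.
#' @export
pairSimilarity <- function(dag, annotations, u, v, namespace = "BP") {
    closures <- .proteinClosures(dag, annotations, namespace)
    .pairSimilarityFast(closures, .coverCounts(closures), length(closures),
                        u, v)
}

.pairSimilarityFast <- function(closures, cover, nAnnotated, u, v) {
    cu <- closures[[u]]
    cv <- closures[[v]]
    if (is.null(cu) || is.null(cv)) return(NA_real_)
    common <- intersect(cu, cv)
    if (!length(common)) return(NA_real_)
    max(-log2(cover[common] / nAnnotated))
}

#' Semantic coherence of a predicted complex
#'
#' The mean pairwise most-informative-common-ancestor similarity over all
#' computable unordered member pairs in one namespace, together with the
#' coverage (computable pairs / total pairs). Pairs involving unannotated
#' proteins are skipped, not scored 0, so missing annotation is not
#' conflated with dissimilarity.
#'
#' @param members character vector of complex members (or a
#'   [ClusterSet-class] cluster's member set).
#' @param dag an [OntologyDag-class].
#' @param annotations an [AnnotationMap-class].
#' @param namespace one of "BP", "CC", "MF".
#' @return list with \code{coherence} (NA when < 2 annotated members) and
#'   \code{coverage}.
#' @export
complexCoherence <- function(members, dag, annotations, namespace = "BP") {
    members <- unique(as.character(members))
    if (length(members) < 2L) stop("a complex needs >= 2 members")
    closures <- .proteinClosures(dag, annotations, namespace)
    cover <- .coverCounts(closures)
    nAnn <- length(closures)
    pr <- utils::combn(members, 2L)
    sims <- vapply(seq_len(ncol(pr)), function(i)
        .pairSimilarityFast(closures, cover, nAnn, pr[1L, i], pr[2L, i]),
        numeric(1))
    ok <- !is.na(sims)
    list(coherence = if (any(ok)) mean(sims[ok]) else NA_real_,
         coverage = mean(ok))
}

#' High-level process annotation of a novel complex
#'
#' Counts, per candidate term, the members annotated to the term or any
#' of its descendants, and annotates the complex with every candidate
#' achieving the maximum count, provided that count is a strict majority
#' of the members (> |members| / 2). Ties at the maximum all annotate, so
#' a complex may carry more than one high-level term.
#'
#' @param members character vector of complex members.
#' @param candidateTerms character vector of candidate high-level terms.
#' @param dag an [OntologyDag-class].
#' @param annotations an [AnnotationMap-class].
#' @return character vector of annotated terms (possibly empty).
#' @export
annotateHighLevel <- function(members, candidateTerms, dag, annotations) {
    stopifnot(all(candidateTerms %in% dag@terms))
    members <- unique(as.character(members))
    tab <- annotations@table
    byProt <- split(tab$term, tab$protein)
    closures <- lapply(byProt[intersect(members, names(byProt))],
                       function(tt)
                           unique(unlist(dag@ancestors[tt],
                                         use.names = FALSE)))
    counts <- vapply(candidateTerms, function(cand)
        sum(vapply(closures, function(cl) cand %in% cl, logical(1))),
        numeric(1))
    if (!length(counts) || max(counts) <= length(members) / 2)
        return(character())
    candidateTerms[counts == max(counts)]
}

#' Rank-sum comparison of coherence distributions
#'
#' Convenience wrapper around the Wilcoxon rank-sum test for comparing
#' semantic-coherence distributions between two sets of complexes
#' (NA coherences dropped).
#'
#' @param x,y numeric coherence vectors.
#' @param alternative passed to [stats::wilcox.test()].
#' @return the \code{htest} object.
#' @export
coherenceRankSum <- function(x, y, alternative = "two.sided") {
    stats::wilcox.test(x[!is.na(x)], y[!is.na(y)],
                       alternative = alternative, exact = FALSE)
}
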