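## Genome-scale analysis of torsionally isolated neighbour-gene pairs.
##
## A pair of adjacent genes is "torsionally isolated" when (i) the genes
## are close -- each transcription unit comes within the inclusion radius
## (default 5 kb) of the partner's promoter -- and (ii) both promoters are
## farther than the isolation radius (default 3 kb) from every other
## annotated transcription unit, so no third gene perturbs them
## torsionally.  All annotated genes (including non-coding ones and genes
## excluded from pairing because they overlap another gene) count as
## perturbers.

#' Read gene annotations from GFF3/GTF
#'
#' Imports an annotation with \link[rtracklayer]{import}, keeps features
#' of the requested type, and returns a named GRanges (1-based inclusive
#' coordinates, as in the file). Gene ids are taken from the \code{ID},
#' \code{gene_id} or \code{Name} attribute, in that order.
#'
#' @param path GFF3 or GTF file
#' @param featureType feature type to keep (default "gene")
#' @return a named GRanges
#' @export
readAnnotations <- function(path, featureType = "gene") {
    gr <- tryCatch(rtracklayer::import(path),
                   error = function(e)
                       .stopf("malformed annotation '%s': %s", path,
                              conditionMessage(e)))
    if (!is.null(gr$type) && featureType %in% as.character(gr$type))
        gr <- gr[as.character(gr$type) == featureType]
    ids <- NULL
    for (attr in c("ID", "gene_id", "Name"))
        if (is.null(ids) && !is.null(S4Vectors::mcols(gr)[[attr]]))
            ids <- as.character(S4Vectors::mcols(gr)[[attr]])
    if (is.null(ids))
        .stopf("no ID/gene_id/Name attribute found in '%s'", path)
    if (anyNA(ids)) .stopf("missing gene ids in '%s'", path)
    if (anyDuplicated(ids))
        .stopf("duplicate gene ids in '%s': %s", path,
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    bad <- !as.character(GenomicRanges::strand(gr)) %in% c("+", "-")
    if (any(bad))
        .stopf("%d feature(s) without a +/- strand in '%s'", sum(bad),
               path)
    names(gr) <- ids
    S4Vectors::mcols(gr) <- NULL
    gr
}

#' Classify the relative orientation of two adjacent genes
#'
#' For gene \code{a} left of gene \code{b} on the same chromosome and not
#' overlapping: divergent when they transcribe apart (a on "-", b on "+",
#' promoters in the shared intergenic region), convergent when they
#' transcribe toward each other (a on "+", b on "-"), tandem when they
#' share a strand.
#'
#' @param a,b single-element GRanges, \code{a} left of \code{b}
#' @return "divergent", "convergent" or "tandem"
#' @export
classifyOrientation <- function(a, b) {
    if (as.character(GenomeInfoDb::seqnames(a)) !=
        as.character(GenomeInfoDb::seqnames(b)))
        .stopf("genes are on different chromosomes")
    if (GenomicRanges::start(b) <= GenomicRanges::end(a) &&
        GenomicRanges::start(a) <= GenomicRanges::end(b))
        .stopf("genes overlap; pair cannot be classified")
    if (GenomicRanges::start(a) > GenomicRanges::start(b))
        .stopf("'a' must lie left of 'b'")
    sa <- as.character(GenomicRanges::strand(a))
    sb <- as.character(GenomicRanges::strand(b))
    if (sa == "-" && sb == "+") "divergent"
    else if (sa == "+" && sb == "-") "convergent"
    else "tandem"
}

#' Separation of two adjacent genes
#'
#' Default is the intergenic gap (number of bases strictly between the two
#' transcription units); \code{mode = "tss"} gives the TSS-to-TSS
#' distance.
#'
#' @param a,b single-element (or parallel) GRanges, \code{a} left of
#'   \code{b}
#' @param mode "gap" or "tss"
#' @return separation in bp (vectorized over parallel inputs)
#' @export
pairSeparation <- function(a, b, mode = c("gap", "tss")) {
    mode <- match.arg(mode)
    if (mode == "gap")
        pmax(0, GenomicRanges::start(b) - GenomicRanges::end(a) - 1)
    else
        abs(tssOf(b) - tssOf(a))
}

#' Select torsionally isolated neighbour-gene pairs
#'
#' Walks adjacent non-overlapping gene pairs along each chromosome and
#' keeps a pair when (i) each gene's transcription unit lies within
#' \code{inclusionRadius} of the partner's TSS (nearest-point distance,
#' strict) and (ii) both TSSs are more than \code{isolationRadius} away
#' from every other annotated transcription unit. Genes overlapping
#' another gene are excluded from pairing (with a message) but still count
#' as perturbers in criterion (ii), as do all other annotated genes.
#'
#' @param annotations named GRanges of genes (e.g. from
#'   \code{\link{readAnnotations}})
#' @param inclusionRadius closeness threshold in bp (default 5000)
#' @param isolationRadius isolation threshold in bp (default 3000)
#' @return a data.frame with one row per selected pair: geneA, geneB,
#'   orientation, separation (gap), tssDistance, upstream, downstream
#'   (NA for non-tandem pairs). The number of genes dropped for
#'   overlapping is attached as attribute \code{"droppedOverlapping"}.
#' @export
selectIsolatedPairs <- function(annotations, inclusionRadius = 5000,
                                isolationRadius = 3000) {
    genes <- annotations
    if (is.null(names(genes)))
        .stopf("annotations must carry gene ids as names")
    v <- c(isTRUE(all(GenomicRanges::width(genes) >= 1)))
    if (!v) .stopf("annotations contain zero-width genes")

    ## genes overlapping any other gene are unusable for pairing
    ov <- GenomicRanges::findOverlaps(genes, drop.self = TRUE,
                                      ignore.strand = TRUE)
    overlapping <- unique(S4Vectors::queryHits(ov))
    if (length(overlapping))
        message(length(overlapping),
                " gene(s) overlapping another gene excluded from pairing")
    pairable <- setdiff(seq_along(genes), overlapping)

    chrOf <- as.character(GenomeInfoDb::seqnames(genes))
    starts <- GenomicRanges::start(genes)
    ends <- GenomicRanges::end(genes)
    strands <- as.character(GenomicRanges::strand(genes))
    tssAll <- tssOf(genes)
    ord <- pairable[order(chrOf[pairable], starts[pairable])]

    ## nearest-point distance from the point t to interval [s, e]:
    ## number of bases strictly between (0 when adjacent or inside)
    pointDist <- function(t, s, e)
        ifelse(t < s, s - t - 1, ifelse(t > e, t - e - 1, 0))

    rows <- list()
    for (k in seq_len(max(0L, length(ord) - 1L))) {
        i <- ord[k]; j <- ord[k + 1L]
        if (chrOf[i] != chrOf[j]) next
        ## (i) closeness: each unit within inclusionRadius of the
        ## partner's promoter
        dA <- pointDist(tssAll[j], starts[i], ends[i])
        dB <- pointDist(tssAll[i], starts[j], ends[j])
        if (dA >= inclusionRadius || dB >= inclusionRadius) next
        ## (ii) isolation: both TSSs > isolationRadius from every other
        ## gene (nearest-point distance; all gene types perturb)
        keep <- seq_along(genes)[-c(i, j)]
        keep <- keep[chrOf[keep] == chrOf[i]]
        isolated <- TRUE
        for (t in c(i, j)) {
            if (length(keep) == 0L) break
            dd <- pointDist(tssAll[t], starts[keep], ends[keep])
            if (any(dd <= isolationRadius)) { isolated <- FALSE; break }
        }
        if (!isolated) next
        a <- genes[i]; b <- genes[j]
        orientation <- classifyOrientation(a, b)
        upstream <- downstream <- NA_character_
        if (orientation == "tandem") {
            if (strands[i] == "+") {
                upstream <- names(genes)[i]; downstream <- names(genes)[j]
            } else {
                upstream <- names(genes)[j]; downstream <- names(genes)[i]
            }
        }
        rows[[length(rows) + 1L]] <- data.frame(
            geneA = names(genes)[i], geneB = names(genes)[j],
            orientation = orientation,
            separation = pairSeparation(a, b, "gap"),
            tssDistance = pairSeparation(a, b, "tss"),
            upstream = upstream, downstream = downstream,
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(geneA = character(), geneB = character(),
                           orientation = character(),
                           separation = numeric(),
                           tssDistance = numeric(),
                           upstream = character(),
                           downstream = character(),
                           stringsAsFactors = FALSE)
    attr(out, "droppedOverlapping") <- length(overlapping)
    out
}

#' Read a genes x experiments expression matrix
#'
#' Tab-separated file, first column gene id, one column per experiment.
#'
#' @param path TSV file
#' @return numeric matrix with gene ids as rownames
#' @export
readExpression <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE))
        .stopf("expression matrix contains negative entries")
    m
}

## Correlation criterion for one pair of expression profiles: jointly
## expressed in >= minCoexpressed experiments AND Pearson r over all
## experiments > rThreshold (zero-variance profiles fail the criterion).
.pairCorrelated <- function(x, y, minCoexpressed, rThreshold) {
    if (sum(x > 0 & y > 0) < minCoexpressed) return(FALSE)
    if (sd(x) == 0 || sd(y) == 0) return(FALSE)
    cor(x, y) > rThreshold
}

#' Annotate pairs with co-expression statistics
#'
#' Adds, per pair, the correlated flag (simultaneously expressed in at
#' least \code{minCoexpressed} experiments and Pearson correlation over
#' all experiments above \code{rThreshold}) and per-gene mean expression.
#' Pairs whose genes are missing from the matrix are dropped with a
#' warning.
#'
#' @param pairs data.frame from \code{\link{selectIsolatedPairs}}
#' @param expr matrix from \code{\link{readExpression}}
#' @param minCoexpressed minimal number of jointly expressed experiments
#' @param rThreshold Pearson correlation threshold (strict)
#' @return the pair table with columns \code{correlated}, \code{meanA},
#'   \code{meanB} appended
#' @export
pairCorrelation <- function(pairs, expr, minCoexpressed = 6,
                            rThreshold = 0.5) {
    present <- pairs$geneA %in% rownames(expr) &
        pairs$geneB %in% rownames(expr)
    if (any(!present)) {
        missing <- unique(c(pairs$geneA, pairs$geneB))
        missing <- missing[!missing %in% rownames(expr)]
        warning(sum(!present), " pair(s) dropped; genes absent from ",
                "the expression matrix: ",
                paste(utils::head(missing, 5), collapse = ", "),
                call. = FALSE)
        pairs <- pairs[present, , drop = FALSE]
    }
    n <- nrow(pairs)
    pairs$correlated <- logical(n)
    pairs$meanA <- pairs$meanB <- numeric(n)
    for (k in seq_len(n)) {
        x <- expr[pairs$geneA[k], ]; y <- expr[pairs$geneB[k], ]
        pairs$correlated[k] <- .pairCorrelated(x, y, minCoexpressed,
                                               rThreshold)
        pairs$meanA[k] <- mean(x); pairs$meanB[k] <- mean(y)
    }
    pairs
}

#' Binned expression statistics of isolated pairs
#'
#' Bins pairs by separation into fixed windows (default 200 bp) and
#' computes, per orientation and window: pair count, correlated-pair
#' count, fraction of expressed (nonzero) gene x experiment entries,
#' total expression (sum over the window's genes of their mean expression
#' across experiments) and mean expression per gene. By construction
#' total = 2 x count x mean for the \code{member = "both"} rows. Tandem
#' pairs additionally get \code{upstream} and \code{downstream} rows
#' summarising each member separately.
#'
#' @param pairs data.frame from \code{\link{selectIsolatedPairs}}
#' @param expr expression matrix
#' @param window window width in bp (default 200)
#' @param minCoexpressed,rThreshold correlation criterion, see
#'   \code{\link{pairCorrelation}}
#' @param separation "gap" (default) or "tss": which separation to bin on
#' @return a data.frame with columns orientation, member, windowStart,
#'   windowEnd, nPairs, nCorrelated, expressedFraction, totalExpression,
#'   meanExpression
#' @export
binnedStatistics <- function(pairs, expr, window = 200,
                             minCoexpressed = 6, rThreshold = 0.5,
                             separation = c("gap", "tss")) {
    separation <- match.arg(separation)
    pairs <- pairCorrelation(pairs, expr, minCoexpressed, rThreshold)
    if (nrow(pairs) == 0L)
        return(data.frame(orientation = character(),
                          member = character(), windowStart = numeric(),
                          windowEnd = numeric(), nPairs = integer(),
                          nCorrelated = integer(),
                          expressedFraction = numeric(),
                          totalExpression = numeric(),
                          meanExpression = numeric()))
    sep <- if (separation == "gap") pairs$separation else
        pairs$tssDistance
    pairs$win <- floor(sep / window)

    summarise <- function(sub, genes, member) {
        entries <- expr[genes, , drop = FALSE]
        data.frame(
            orientation = sub$orientation[1], member = member,
            windowStart = sub$win[1] * window,
            windowEnd = (sub$win[1] + 1) * window,
            nPairs = nrow(sub), nCorrelated = sum(sub$correlated),
            expressedFraction = mean(entries > 0),
            totalExpression = sum(rowMeans(entries)),
            meanExpression = mean(rowMeans(entries)),
            stringsAsFactors = FALSE)
    }

    out <- list()
    for (or in unique(pairs$orientation)) {
        po <- pairs[pairs$orientation == or, , drop = FALSE]
        for (w in sort(unique(po$win))) {
            sub <- po[po$win == w, , drop = FALSE]
            out[[length(out) + 1L]] <-
                summarise(sub, c(sub$geneA, sub$geneB), "both")
            if (or == "tandem") {
                out[[length(out) + 1L]] <-
                    summarise(sub, sub$upstream, "upstream")
                out[[length(out) + 1L]] <-
                    summarise(sub, sub$downstream, "downstream")
            }
        }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
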