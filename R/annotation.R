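## Gene-window annotation of outlier loci against a GFF3 reference.
## Distances are edge distances in bp (0 inside a gene span) and the window
## is a strict upper bound: a gene 49,999 bp away is reported at window
## 50,000; one exactly 50,000 bp away is not.

#' Read gene intervals from a GFF3 file
#'
#' Imports the annotation with \pkg{rtracklayer} and keeps \code{gene}
#' features as a per-contig sorted \linkS4class{GRanges} (1-based inclusive
#' coordinates) with a \code{gene_id} metadata column (taken from the ID or
#' gene_id attribute, falling back to Name).
#'
#' @param path path to a GFF3 file
#' @return \linkS4class{GRanges} of genes
#' @export
readAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no gene features in ", path)
    id <- as.character(gr$ID)
    if (all(is.na(id)) && !is.null(gr$gene_id)) id <- gr$gene_id
    if (!is.null(gr$Name)) id <- ifelse(is.na(id), gr$Name, id)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = id)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Genes near a locus
#'
#' Reports genes on the locus contig whose span lies strictly less than
#' \code{window} bp from the locus position (edge distance; 0 when the
#' position falls inside the span).  Relation is computed from gene strand:
#' upstream = the 5' side of the gene.
#'
#' @param contig contig/chromosome name of the locus
#' @param position 1-based bp position of the SNP
#' @param genes \linkS4class{GRanges} from \code{\link{readAnnotation}}
#' @param window strict distance bound in bp (default 50000)
#' @return data.frame (gene_id, contig, distance, relation), sorted by
#'   distance then gene_id; zero rows when nothing is in range
#' @export
genesNear <- function(contig, position, genes, window = 50000L) {
    stopifnot(window > 0)
    empty <- data.frame(gene_id = character(), contig = character(),
                        distance = integer(), relation = character(),
                        stringsAsFactors = FALSE)
    if (!contig %in% as.character(unique(GenomicRanges::seqnames(genes)))) {
        warning("contig ", contig, " absent from annotation")
        return(empty)
    }
    pt <- GenomicRanges::GRanges(contig,
                                 IRanges::IRanges(position, position))
    hits <- GenomicRanges::findOverlaps(
        pt, suppressWarnings(GenomicRanges::resize(
            genes, GenomicRanges::width(genes) + 2L * (window - 1L),
            fix = "center")),
        ignore.strand = TRUE)
    g <- genes[S4Vectors::subjectHits(hits)]
    if (length(g) == 0L) return(empty)
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    dist <- pmax(0L, s - position, position - e)
    keep <- dist < window
    g <- g[keep]; s <- s[keep]; e <- e[keep]; dist <- dist[keep]
    if (length(g) == 0L) return(empty)
    minus <- as.character(GenomicRanges::strand(g)) == "-"
    relation <- ifelse(dist == 0L, "within",
                ifelse(xor(position < s, minus), "upstream", "downstream"))
    out <- data.frame(gene_id = g$gene_id,
                      contig = as.character(GenomicRanges::seqnames(g)),
                      distance = as.integer(dist), relation = relation,
                      stringsAsFactors = FALSE)
    out[order(out$distance, out$gene_id), , drop = FALSE]
}

#' Annotate an outlier report with nearby genes
#'
#' Joins each outlier locus (by its contig/position in the locus map) with
#' all genes strictly within \code{window} bp.  The karyotype pseudo-locus
#' has no genomic coordinate and receives no hits.
#'
#' @param report outlier report (see \code{\link{detectOutliers}})
#' @param map locus map data.frame (locus_id, contig, position), e.g.
#'   \code{locusMap(g)}
#' @param genes \linkS4class{GRanges} from \code{\link{readAnnotation}}
#' @param window strict distance bound in bp (default 50000)
#' @return data.frame with one row per (outlier, gene) hit; outliers with no
#'   hit are retained with NA gene fields
#' @export
annotateOutliers <- function(report, map, genes, window = 50000L) {
    rows <- lapply(seq_len(nrow(report)), function(i) {
        id <- report$locus_id[i]
        j <- match(id, map$locus_id)
        base <- report[i, , drop = FALSE]
        if (is.na(j) || is.na(map$contig[j]) || is.na(map$position[j]))
            hits <- NULL
        else
            hits <- genesNear(map$contig[j], map$position[j], genes,
                              window)
        if (is.null(hits) || nrow(hits) == 0L) {
            base$gene_id <- NA_character_
            base$gene_distance <- NA_integer_
            base$gene_relation <- NA_character_
            return(base)
        }
        cbind(base[rep(1L, nrow(hits)), , drop = FALSE],
              data.frame(gene_id = hits$gene_id,
                         gene_distance = hits$distance,
                         gene_relation = hits$relation,
                         stringsAsFactors = FALSE))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
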