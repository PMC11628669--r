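## Genotype import/export: VCF (v4.2) and tab-separated 012 matrix with a
## sidecar locus map.  All readers orient counts to the per-locus minor
## allele (ties broken toward the alternate allele) and are deterministic.

#' Read genotypes from VCF or a 012 matrix
#'
#' Dispatches on file extension: \code{.vcf} / \code{.vcf.gz} are parsed with
#' \pkg{vcfR}; anything else is treated as a tab-separated 012 matrix with a
#' sidecar locus map (see \code{\link{read012}}).  Multiallelic VCF sites are
#' dropped (a message reports the count); counts are oriented so that 2
#' copies of the \emph{minor} allele score 2, ties broken toward the
#' alternate allele.
#'
#' @param path path to the genotype file
#' @param samples optional data.frame of sample metadata (see
#'   \code{\link{GenoExperiment}}); placeholder metadata is synthesised when
#'   omitted.
#' @param locusMapPath for 012 input, path to the locus map (defaults to
#'   \code{<path>.loci.tsv})
#' @return a \linkS4class{GenoExperiment}
#' @export
readGenotypes <- function(path, samples = NULL, locusMapPath = NULL) {
    if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
        readVCF(path, samples = samples)
    else
        read012(path, samples = samples, locusMapPath = locusMapPath)
}

#' @rdname readGenotypes
#' @export
readVCF <- function(path, samples = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
        message(sum(multi), " multiallelic site(s) dropped")
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                       dimnames = list(rownames(gt),
                                                       colnames(gt)))
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    if (ncol(gt) == 0L) stop("empty input: zero samples")
    counts <- apply(gt, c(1, 2), .gtToCount)
    geno <- t(counts)                       # samples x loci
    lm <- data.frame(
        locus_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                          paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                          fix[, "ID"]),
        contig = fix[, "CHROM"],
        position = as.integer(fix[, "POS"]),
        stringsAsFactors = FALSE)
    colnames(geno) <- lm$locus_id
    .buildGeno(geno, lm, samples)
}

.gtToCount <- function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(sub(":.*", "", g), "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
}

#' @rdname readGenotypes
#' @export
read012 <- function(path, samples = NULL, locusMapPath = NULL) {
    if (is.null(locusMapPath)) locusMapPath <- paste0(path, ".loci.tsv")
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("empty input: zero samples")
    ids <- tab[[1L]]
    geno <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(geno) <- "integer"
    rownames(geno) <- ids
    bad <- !is.na(geno) & !(geno %in% 0:2)
    if (any(bad))
        stop("malformed 012 record at data row ",
             which(rowSums(bad) > 0)[1L])
    lm <- utils::read.delim(locusMapPath, stringsAsFactors = FALSE)
    stopifnot(all(c("locus_id", "contig", "position") %in% colnames(lm)))
    if (!identical(as.character(lm$locus_id), colnames(geno)))
        lm <- lm[match(colnames(geno), lm$locus_id), , drop = FALSE]
    .buildGeno(geno, lm, samples)
}

.buildGeno <- function(geno, lm, samples) {
    geno <- .orientMinor(geno)
    if (is.null(samples))
        samples <- data.frame(sample_id = rownames(geno),
                              population = NA_character_,
                              species = NA_character_,
                              latitude = NA_real_, longitude = NA_real_,
                              two_n = NA_integer_,
                              stringsAsFactors = FALSE)
    GenoExperiment(geno, lm, samples)
}

## Flip columns whose counted-allele frequency exceeds 0.5 so entries count
## the minor allele; a tie (freq exactly 0.5) keeps the alternate allele.
.orientMinor <- function(geno) {
    freq <- colMeans(geno, na.rm = TRUE) / 2
    flip <- !is.na(freq) & freq > 0.5
    geno[, flip] <- 2L - geno[, flip]
    geno
}

#' Write genotypes as a 012 matrix plus locus map
#'
#' Emits a tab-separated table (first column \code{sample_id}, then one
#' column per locus with 0/1/2/NA) and a sidecar \code{<path>.loci.tsv} with
#' columns locus_id, contig, position.  Column order is deterministic
#' (input locus order).
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param path output path for the matrix
#' @return \code{path}, invisibly
#' @export
write012 <- function(g, path) {
    m <- genoMatrix(g)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lm <- locusMap(g)
    utils::write.table(lm[, c("locus_id", "contig", "position")],
                       paste0(path, ".loci.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write genotypes as a minimal VCF v4.2
#'
#' SNP rows only (the karyotype pseudo-locus, having no genomic coordinate,
#' is skipped with a message).  Counts are written as unphased diploid
#' genotypes with REF/ALT placeholders A/T; allele identity is not tracked
#' by the 012 representation, so round-trips preserve counts, not alleles.
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param path output path
#' @param extraHeader optional character vector of extra \code{##} header
#'   lines (e.g. a seed record from the simulator)
#' @return \code{path}, invisibly
#' @export
writeVCF <- function(g, path, extraHeader = character()) {
    lm <- locusMap(g)
    if (any(lm$is_karyotype)) {
        message("karyotype pseudo-locus skipped in VCF output")
        g <- g[!lm$is_karyotype, ]
        lm <- locusMap(g)
    }
    m <- genoMatrix(g)
    gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##source=karyoRDA",
               extraHeader,
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(m)),
                     collapse = "\t"))
    body <- vapply(seq_len(ncol(m)), function(j) {
        gt <- ifelse(is.na(m[, j]), "./.", gtcode[as.character(m[, j])])
        paste(c(lm$contig[j], lm$position[j], lm$locus_id[j], "A", "T",
                ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
    invisible(path)
}

#' Write sample metadata as TSV
#'
#' @param g a \linkS4class{GenoExperiment}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeSampleTable <- function(g, path) {
    utils::write.table(sampleData(g), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
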