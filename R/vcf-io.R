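## VCF v4.2 dialect I/O. The writer pins an exact dialect (QUAL to one
## decimal, FORMAT GT:AD:DP, site DP plus gap/INDEL proximity flags in INFO,
## records sorted by chrom/pos/alt) so written files re-read to identical
## records; the reader additionally splits multi-allelic ALT lines so all
## downstream set logic is per-allele.

#' Write a CallSet as a VCF v4.2 file
#'
#' One record per variant, FORMAT `GT:AD:DP` (AD as `ref,alt`), site read
#' depth in INFO `DP`, and gap/INDEL proximity carried as the INFO flags
#' `NGAP`/`NIDL`. QUAL is written with one decimal; records are sorted by
#' (chrom, pos, alt). Contig header lines are emitted for every chromosome
#' present.
#'
#' @param calls a [CallSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readVcfCalls()]
#' @export
writeVcfCalls <- function(calls, path) {
  rd <- calls@rowdata
  ids <- genotypeNames(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sort(rd$chrom))),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste0("##INFO=<ID=NGAP,Number=0,Type=Flag,Description=",
           "\"Site within the gap proximity window\">"),
    paste0("##INFO=<ID=NIDL,Number=0,Type=Flag,Description=",
           "\"Site within the INDEL proximity window\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  lines <- header
  if (nrow(rd) > 0L) {
    ord <- order(rd$chrom, rd$pos, rd$alt)
    info <- paste0("DP=", siteDepth(calls),
                   ifelse(rd$nearGap, ";NGAP", ""),
                   ifelse(rd$nearIndel, ";NIDL", ""))
    geno <- matrix(paste0(calls@gt, ":", calls@adRef, ",", calls@adAlt,
                          ":", calls@dp),
                   nrow = nrow(rd))
    body <- apply(cbind(rd$chrom, rd$pos, ".", rd$ref, rd$alt,
                        sprintf("%.1f", rd$qual), ".", info, "GT:AD:DP",
                        geno)[ord, , drop = FALSE],
                  1L, paste, collapse = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF file into a CallSet
#'
#' Accepts the dialect written by [writeVcfCalls()] and plain VCF v4.2 files
#' with FORMAT `GT:AD:DP` (extra FORMAT fields are ignored). Multi-allelic
#' ALT lines are split into one record per alternative allele, with AD
#' decomposed to (ref, that alt) and genotype alleles for other alternatives
#' treated as reference. Genotype column labels are taken from the header
#' line. Genotype DP is reconstituted as AD ref + alt.
#'
#' @param path path to an (uncompressed) VCF file.
#' @param label label for the [CallSet] (default: file name without
#'   extension).
#' @return a [CallSet].
#' @export
readVcfCalls <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.vcf$", "", basename(path))
  lines <- readLines(path)
  hdrIdx <- which(startsWith(lines, "#CHROM"))
  if (length(hdrIdx) != 1L) {
    stop("missing #CHROM header line in ", path, call. = FALSE)
  }
  cols <- strsplit(lines[hdrIdx], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) {
    stop("VCF has no genotype columns: ", path, call. = FALSE)
  }
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdrIdx)]
  body <- body[nzchar(body)]

  rows <- vector("list", length(body))
  for (li in seq_along(body)) {
    f <- strsplit(body[li], "\t", fixed = TRUE)[[1L]]
    lineNo <- hdrIdx + li
    if (length(f) != length(cols)) {
      stop("parse error at line ", lineNo, ": expected ", length(cols),
           " fields, found ", length(f), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos)) {
      stop("parse error at line ", lineNo, ": non-numeric POS '", f[2L],
           "'", call. = FALSE)
    }
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    qual <- if (f[6L] == ".") 0 else as.numeric(f[6L])
    infoParts <- strsplit(f[8L], ";", fixed = TRUE)[[1L]]
    nearGap <- "NGAP" %in% infoParts
    nearIndel <- "NIDL" %in% infoParts
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gtPos <- match("GT", fmt)
    adPos <- match("AD", fmt)
    if (is.na(gtPos) || is.na(adPos)) {
      stop("parse error at line ", lineNo, ": FORMAT must contain GT and AD",
           call. = FALSE)
    }
    geno <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    gtRaw <- vapply(geno, `[`, character(1), gtPos)
    adRaw <- lapply(geno, function(g) {
      as.integer(strsplit(g[adPos], ",", fixed = TRUE)[[1L]])
    })
    badAd <- which(lengths(adRaw) != length(alts) + 1L)
    if (length(badAd)) {
      stop("parse error at line ", lineNo, ": AD arity != 1 + n_alt for ",
           "genotype ", ids[badAd[1L]], call. = FALSE)
    }
    alleles <- lapply(strsplit(gtRaw, "[/|]"), function(a) {
      suppressWarnings(as.integer(a))
    })
    badGt <- which(!(lengths(alleles) %in% 1:2))
    if (length(badGt)) {
      stop("parse error at line ", lineNo, ": malformed GT '",
           gtRaw[badGt[1L]], "'", call. = FALSE)
    }
    perAlt <- lapply(seq_along(alts), function(ai) {
      gt <- vapply(alleles, function(a) {
        if (anyNA(a)) return("./.")
        .GT_STRINGS[sum(a == ai) + 1L]
      }, character(1))
      adR <- vapply(adRaw, `[`, integer(1), 1L)
      adA <- vapply(adRaw, `[`, integer(1), ai + 1L)
      list(chrom = f[1L], pos = pos, ref = f[4L], alt = alts[ai],
           qual = qual, nearGap = nearGap, nearIndel = nearIndel,
           gt = gt, adRef = adR, adAlt = adA)
    })
    rows[[li]] <- perAlt
  }
  rows <- unlist(rows, recursive = FALSE)
  toMat <- function(field, mode) {
    m <- matrix(vector(mode, 0), nrow = length(rows), ncol = length(ids),
                dimnames = list(NULL, ids))
    for (i in seq_along(rows)) m[i, ] <- rows[[i]][[field]]
    m
  }
  gt <- toMat("gt", "character")
  adRef <- toMat("adRef", "integer")
  adAlt <- toMat("adAlt", "integer")
  pull <- function(field, mode) {
    vapply(rows, function(r) r[[field]], vector(mode, 1))
  }
  rowdata <- data.frame(
    chrom = pull("chrom", "character"),
    pos = pull("pos", "integer"),
    ref = pull("ref", "character"),
    alt = pull("alt", "character"),
    qual = pull("qual", "numeric"),
    nearGap = pull("nearGap", "logical"),
    nearIndel = pull("nearIndel", "logical"),
    stringsAsFactors = FALSE)
  CallSet(rowdata = rowdata, gt = gt, adRef = adRef, adAlt = adAlt,
          dp = adRef + adAlt, label = label)
}

#' Read gene intervals from GFF3 or BED
#'
#' GFF3 `gene` features are used as-is (1-based inclusive); BED intervals
#' (0-based half-open) are converted to 1-based inclusive coordinates.
#' Parsing and coordinate conversion are delegated to
#' `rtracklayer::import()`.
#'
#' @param path path to the annotation file.
#' @param format `"gff3"`, `"bed"`, or `"auto"` (by file extension).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t99\t200\tgeneA", bed)
#' readGeneIntervals(bed)   # 1-based interval [100, 200]
#' @export
readGeneIntervals <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ident <- if (!is.null(gr$ID)) as.character(gr$ID) else
      as.character(gr$Name)
  } else {
    ident <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("interval_", seq_along(gr))
  }
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("zero-length gene interval after coordinate conversion",
         call. = FALSE)
  }
  data.frame(gene_id = ident,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
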