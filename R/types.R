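#' Construct an aligned EST read
#'
#' A read placed on a contig with one Phred quality per base. Bases may
#' include `-` (alignment gap) and `N`; both are excluded from allele
#' depth downstream but kept here verbatim.
#'
#' @param read_id Unique read identifier.
#' @param start 0-based offset of the first base on the contig.
#' @param bases Aligned sequence as a single string over `A/C/G/T/N/-`.
#' @param quals Integer Phred scores, one per base, in `[0, 93]`.
#' @param taxon,individual Source labels (species and diploid individual).
#' @param technology One of `"sanger"`, `"pyro454"`, `"illumina"`,
#'   `"unknown"`.
#' @return An object of class `AlignedRead`.
#' @export
aligned_read <- function(read_id, start, bases, quals,
                         taxon = "unknown", individual = "unknown",
                         technology = c("sanger", "pyro454", "illumina",
                                        "unknown")) {
  technology <- match.arg(technology)
  bases <- toupper(as.character(bases))
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals)) {
    stop("read '", read_id, "': ", nchar(bases), " bases but ",
         length(quals), " quality values", call. = FALSE)
  }
  if (any(quals < 0L | quals > 93L)) {
    stop("read '", read_id, "': Phred qualities must lie in [0, 93]",
         call. = FALSE)
  }
  if (start < 0L) stop("read '", read_id, "': negative start", call. = FALSE)
  structure(
    list(read_id = as.character(read_id), taxon = as.character(taxon),
         individual = as.character(individual), technology = technology,
         start = as.integer(start), bases = bases, quals = quals),
    class = "AlignedRead")
}

#' Construct a contig alignment
#'
#' The substrate for SNP discovery: a set of reads placed on one contig,
#' plus optional repeat-mask and exon-map annotation. All intervals are
#' 0-based half-open; [gff_to_internal()] converts from the 1-based
#' inclusive convention used on disk.
#'
#' @param contig_id Contig identifier.
#' @param length Contig length in bases.
#' @param reads List of [aligned_read()] objects, each fitting within
#'   `[0, length)`.
#' @param repeat_mask Optional two-column integer matrix of half-open
#'   `[start, end)` intervals flagged as repetitive.
#' @param exon_map Optional `data.frame` with columns `start`, `end`
#'   (half-open) and `exon_id`; intervals must not overlap.
#' @return An object of class `ContigAlignment`.
#' @export
contig_alignment <- function(contig_id, length, reads = list(),
                             repeat_mask = NULL, exon_map = NULL) {
  length <- as.integer(length)
  if (length < 1L) stop("contig length must be >= 1", call. = FALSE)
  for (rd in reads) {
    stopifnot(inherits(rd, "AlignedRead"))
    if (rd$start + nchar(rd$bases) > length) {
      stop("read '", rd$read_id, "' extends past the end of contig '",
           contig_id, "'", call. = FALSE)
    }
  }
  repeat_mask <- .check_intervals(repeat_mask, length, "repeat_mask")
  if (!is.null(exon_map)) {
    stopifnot(is.data.frame(exon_map),
              all(c("start", "end", "exon_id") %in% names(exon_map)))
    iv <- .check_intervals(cbind(exon_map$start, exon_map$end), length,
                           "exon_map")
    if (nrow(iv) > 1L) {
      o <- order(iv[, 1L])
      if (any(iv[o[-nrow(iv)], 2L] > iv[o[-1L], 1L])) {
        stop("exon intervals overlap on contig '", contig_id, "'",
             call. = FALSE)
      }
    }
    exon_map <- data.frame(start = as.integer(iv[, 1L]),
                           end = as.integer(iv[, 2L]),
                           exon_id = as.character(exon_map$exon_id),
                           stringsAsFactors = FALSE)
  }
  structure(
    list(contig_id = as.character(contig_id), length = length,
         reads = unname(reads), repeat_mask = repeat_mask,
         exon_map = exon_map),
    class = "ContigAlignment")
}

.check_intervals <- function(x, len, what) {
  if (is.null(x) || NROW(x) == 0L) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  x <- matrix(as.integer(x), ncol = 2L)
  if (any(x[, 1L] < 0L) || any(x[, 2L] > len) || any(x[, 1L] >= x[, 2L])) {
    stop(what, ": intervals must be non-empty and lie within [0, ",
         len, ")", call. = FALSE)
  }
  colnames(x) <- c("start", "end")
  x[order(x[, 1L]), , drop = FALSE]
}

#' @export
print.ContigAlignment <- function(x, ...) {
  cat("ContigAlignment '", x$contig_id, "': ", x$length, " bp, ",
      length(x$reads), " reads, ", nrow(x$repeat_mask),
      " repeat interval(s), ",
      if (is.null(x$exon_map)) "no exon map" else
        paste0(nrow(x$exon_map), " exon(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Construct a genotype panel
#'
#' SNP-by-sample genotype calls on the Illumina A/B allele abstraction,
#' with the per-datapoint GenCall score and the per-SNP GenTrain and ADT
#' design scores carried as metadata. `NC` marks a no-call; its GenCall
#' score may be missing.
#'
#' @param snp_ids Character vector of SNP identifiers (rows).
#' @param samples `data.frame` with columns `sample_id`, `species`,
#'   `section`, `subgenus`; `sample_id` must be unique.
#' @param genotypes Character matrix over `{AA, AB, BB, NC}`,
#'   `length(snp_ids)` rows by `nrow(samples)` columns.
#' @param gencall Numeric matrix of the same shape with scores in
#'   `[0, 1]`; `NA` allowed only where the genotype is `NC`.
#' @param gentrain,adt Optional per-SNP scores in `[0, 1]` (`NA` allowed).
#' @return An object of class `GenotypePanel`.
#' @export
genotype_panel <- function(snp_ids, samples, genotypes, gencall,
                           gentrain = NULL, adt = NULL) {
  snp_ids <- as.character(snp_ids)
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "species", "section", "subgenus")
                %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  }
  genotypes <- as.matrix(genotypes)
  gencall <- as.matrix(gencall)
  if (!all(dim(genotypes) == c(length(snp_ids), nrow(samples))) ||
      !all(dim(gencall) == dim(genotypes))) {
    stop("genotype/gencall matrix shape does not match snp_ids x samples",
         call. = FALSE)
  }
  bad <- !(genotypes %in% c("AA", "AB", "BB", "NC"))
  if (any(bad)) stop("invalid genotype token(s): ",
                     paste(unique(genotypes[bad]), collapse = ", "),
                     call. = FALSE)
  if (any(gencall < 0 | gencall > 1, na.rm = TRUE)) {
    stop("gencall scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(is.na(gencall) & genotypes != "NC")) {
    stop("gencall score missing at a called datapoint", call. = FALSE)
  }
  dimnames(genotypes) <- dimnames(gencall) <-
    list(snp_ids, samples$sample_id)
  chk <- function(v, what) {
    if (is.null(v)) return(setNames(rep(NA_real_, length(snp_ids)), snp_ids))
    v <- as.numeric(v)
    stopifnot(length(v) == length(snp_ids))
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop(what, " scores must lie in [0, 1]", call. = FALSE)
    }
    setNames(v, snp_ids)
  }
  structure(
    list(snp_ids = snp_ids, samples = samples, genotypes = genotypes,
         gencall = gencall, gentrain = chk(gentrain, "gentrain"),
         adt = chk(adt, "adt")),
    class = "GenotypePanel")
}

#' @export
print.GenotypePanel <- function(x, ...) {
  cat("GenotypePanel: ", length(x$snp_ids), " SNPs x ",
      nrow(x$samples), " samples (",
      length(unique(x$samples$species)), " species)\n", sep = "")
  invisible(x)
}

#' Convert between GFF (1-based inclusive) and internal coordinates
#'
#' Internally every interval is 0-based half-open `[start, end)`; GFF3 and
#' all report files use 1-based inclusive `[start, end]`. The two
#' functions are exact inverses.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A two-column integer matrix in the target convention.
#' @export
gff_to_internal <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}
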