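# On-disk formats. FASTA via Biostrings; QUAL is the phrap-style sibling
# of FASTA (same headers, whitespace-separated integers) and is parsed
# here directly; read placements travel in a small documented JSON
# dialect; repeat masks and exon maps are a GFF3 subset read through
# rtracklayer. Everything on disk is 1-based inclusive.

DEFAULT_QUAL <- 15L

.read_qual <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no records in QUAL file '", path, "'",
                              call. = FALSE)
  ids <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    body <- lines[seq(starts[i], ends[i])]
    out[[i]] <- as.integer(unlist(strsplit(paste(body, collapse = " "),
                                           "[ \t]+"), use.names = FALSE))
    out[[i]] <- out[[i]][!is.na(out[[i]])]
  }
  setNames(out, ids)
}

.write_qual <- function(quals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(quals)) {
    writeLines(c(paste0(">", id),
                 paste(quals[[id]], collapse = " ")), con)
  }
  invisible(path)
}

.read_gff_intervals <- function(path) {
  # light pre-validation so malformed lines are reported with their number
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      stop("malformed GFF line ", i, " in '", path, "'", call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  iv <- gff_to_internal(GenomicRanges::start(gr), GenomicRanges::end(gr))
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  data.frame(contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = iv[, "start"], end = iv[, "end"],
             type = as.character(gr$type), feature_id = ids,
             stringsAsFactors = FALSE)
}

.write_gff_intervals <- function(df, path, source = "hetsnp") {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    type = df$type)
  gr$source <- source
  if (!is.null(df$feature_id)) gr$ID <- df$feature_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load a contig-alignment bundle
#'
#' Assembles [contig_alignment()] objects from a FASTA of read sequences,
#' its QUAL sibling, and a JSON file that places reads on contigs and
#' carries their taxon/individual/technology labels. Reads present in the
#' FASTA but lacking a QUAL record receive a flat default Phred quality
#' (15 unless overridden), the conventional stand-in for database ESTs
#' distributed without chromatogram qualities. Optional GFF3 files add a
#' repeat mask and an exon map per contig (1-based inclusive on disk,
#' converted to 0-based half-open).
#'
#' @param fasta_path,qual_path Read sequences and per-base Phred scores;
#'   records correspond by identifier. `qual_path = NULL` assigns the
#'   default quality everywhere.
#' @param alignment_path JSON with a top-level `contigs` array; each
#'   contig has `contig_id`, `length` and a `reads` array of
#'   `{read_id, taxon, individual, technology, start}` with 1-based
#'   `start`.
#' @param repeat_path,exon_path Optional GFF3 annotation; `seqid` must
#'   name a contig from the JSON.
#' @param default_qual Phred value assigned to quality-less reads.
#' @return Named list of `ContigAlignment` objects.
#' @export
load_contig_bundle <- function(fasta_path, qual_path, alignment_path,
                               repeat_path = NULL, exon_path = NULL,
                               default_qual = DEFAULT_QUAL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  seq_ids <- sub("[ \t].*$", "", names(seqs))
  names(seqs) <- seq_ids
  quals <- if (is.null(qual_path)) list() else .read_qual(qual_path)
  for (id in names(quals)) {
    if (!id %in% seq_ids) {
      stop("QUAL record '", id, "' has no FASTA record", call. = FALSE)
    }
    if (length(quals[[id]]) != Biostrings::width(seqs[id])) {
      stop("record '", id, "': FASTA length ",
           Biostrings::width(seqs[id]), " but ", length(quals[[id]]),
           " quality values", call. = FALSE)
    }
  }
  spec <- jsonlite::fromJSON(alignment_path, simplifyVector = FALSE)
  if (is.null(spec$contigs)) {
    stop("alignment JSON lacks a 'contigs' array", call. = FALSE)
  }
  rep_df <- if (!is.null(repeat_path)) .read_gff_intervals(repeat_path)
  exon_df <- if (!is.null(exon_path)) .read_gff_intervals(exon_path)
  contigs <- list()
  for (cg in spec$contigs) {
    reads <- lapply(cg$reads, function(r) {
      if (!r$read_id %in% seq_ids) {
        stop("alignment references unknown read '", r$read_id, "'",
             call. = FALSE)
      }
      bases <- as.character(seqs[[r$read_id]])
      q <- quals[[r$read_id]]
      if (is.null(q)) q <- rep(default_qual, nchar(bases))
      aligned_read(r$read_id, start = as.integer(r$start) - 1L,
                   bases = bases, quals = q,
                   taxon = r$taxon %||% "unknown",
                   individual = r$individual %||% "unknown",
                   technology = r$technology %||% "unknown")
    })
    rmask <- NULL
    if (!is.null(rep_df)) {
      sel <- rep_df$contig_id == cg$contig_id
      if (any(sel)) rmask <- cbind(rep_df$start[sel], rep_df$end[sel])
    }
    emap <- NULL
    if (!is.null(exon_df)) {
      sel <- exon_df$contig_id == cg$contig_id
      if (any(sel)) {
        emap <- data.frame(start = exon_df$start[sel],
                           end = exon_df$end[sel],
                           exon_id = ifelse(is.na(exon_df$feature_id[sel]),
                                            paste0(cg$contig_id, ".e",
                                                   seq_len(sum(sel))),
                                            exon_df$feature_id[sel]),
                           stringsAsFactors = FALSE)
      }
    }
    contigs[[cg$contig_id]] <- contig_alignment(
      cg$contig_id, cg$length, reads, repeat_mask = rmask, exon_map = emap)
  }
  unknown <- setdiff(c(if (!is.null(rep_df)) rep_df$contig_id,
                       if (!is.null(exon_df)) exon_df$contig_id),
                     names(contigs))
  if (length(unknown)) {
    stop("annotation references unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  contigs
}

#' Write a contig-alignment bundle
#'
#' Inverse of [load_contig_bundle()]: emits `reads.fasta`, `reads.qual`,
#' `alignment.json` and, when any contig carries them, `repeats.gff3` /
#' `exons.gff3` under `dir`.
#'
#' @param contigs Named list of [contig_alignment()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_contig_bundle <- function(contigs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- unlist(lapply(contigs, `[[`, "reads"), recursive = FALSE)
  seqs <- Biostrings::BStringSet(
    setNames(vapply(reads, `[[`, "", "bases"),
             vapply(reads, `[[`, "", "read_id")))
  Biostrings::writeXStringSet(seqs, file.path(dir, "reads.fasta"))
  .write_qual(setNames(lapply(reads, `[[`, "quals"),
                       vapply(reads, `[[`, "", "read_id")),
              file.path(dir, "reads.qual"))
  spec <- list(contigs = lapply(unname(contigs), function(cg) {
    list(contig_id = cg$contig_id, length = cg$length,
         reads = lapply(cg$reads, function(r) {
           list(read_id = r$read_id, taxon = r$taxon,
                individual = r$individual, technology = r$technology,
                start = r$start + 1L)
         }))
  }))
  jsonlite::write_json(spec, file.path(dir, "alignment.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rep_df <- do.call(rbind, lapply(contigs, function(cg) {
    if (nrow(cg$repeat_mask) == 0L) return(NULL)
    data.frame(contig_id = cg$contig_id, start = cg$repeat_mask[, 1L],
               end = cg$repeat_mask[, 2L], type = "repeat_region",
               stringsAsFactors = FALSE)
  }))
  if (!is.null(rep_df)) {
    .write_gff_intervals(rep_df, file.path(dir, "repeats.gff3"))
  }
  exon_df <- do.call(rbind, lapply(contigs, function(cg) {
    if (is.null(cg$exon_map)) return(NULL)
    data.frame(contig_id = cg$contig_id, start = cg$exon_map$start,
               end = cg$exon_map$end, type = "exon",
               feature_id = cg$exon_map$exon_id, stringsAsFactors = FALSE)
  }))
  if (!is.null(exon_df)) {
    .write_gff_intervals(exon_df, file.path(dir, "exons.gff3"))
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a genotype panel from CSV
#'
#' The matrix CSV has columns `snp_id`, `gentrain`, `adt`, then one
#' genotype column per sample followed by its `<sample>_gencall` score
#' column. Genotype tokens are folded to upper case (`ab` reads as `AB`,
#' `BA` as `AB`); anything outside `{AA, AB, BB, NC}` becomes `NC` and is
#' tallied in the `n_unknown_tokens` attribute with one warning.
#'
#' @param matrix_path Genotype matrix CSV.
#' @param samplesheet_path CSV with columns `sample_id`, `species`,
#'   `section`, `subgenus` covering every sample column.
#' @return A [genotype_panel()] with attribute `n_unknown_tokens`.
#' @export
load_genotype_panel <- function(matrix_path, samplesheet_path) {
  mat <- read.csv(matrix_path, stringsAsFactors = FALSE,
                  check.names = FALSE)
  sheet <- read.csv(samplesheet_path, stringsAsFactors = FALSE)
  gc_cols <- grep("_gencall$", names(mat), value = TRUE)
  gt_cols <- setdiff(names(mat), c("snp_id", "gentrain", "adt", gc_cols))
  missing <- setdiff(gt_cols, sheet$sample_id)
  if (length(missing)) {
    stop("sample(s) in matrix absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sheet <- sheet[match(gt_cols, sheet$sample_id), , drop = FALSE]
  norm <- function(x) {
    x <- toupper(trimws(x))
    x[x == "BA"] <- "AB"
    x
  }
  gts <- apply(as.matrix(mat[gt_cols]), 2L, norm)
  if (!is.matrix(gts)) gts <- matrix(gts, nrow = nrow(mat))
  unknown <- !(gts %in% c("AA", "AB", "BB", "NC"))
  if (any(unknown)) {
    warning(sum(unknown), " unknown genotype token(s) mapped to NC",
            call. = FALSE)
    gts[unknown] <- "NC"
  }
  gc <- as.matrix(mat[paste0(gt_cols, "_gencall")])
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
    stop("gencall score outside [0, 1] in '", matrix_path, "'",
         call. = FALSE)
  }
  gc[gts == "NC" & is.na(gc)] <- NA_real_
  panel <- genotype_panel(mat$snp_id, sheet, gts, gc,
                          gentrain = mat$gentrain, adt = mat$adt)
  attr(panel, "n_unknown_tokens") <- sum(unknown)
  panel
}

#' Write a genotype panel to CSV
#'
#' @param panel A [genotype_panel()].
#' @param matrix_path,samplesheet_path Output CSV paths
#'   (`samplesheet_path = NULL` skips the sheet).
#' @return Invisibly, `matrix_path`.
#' @export
write_genotype_panel <- function(panel, matrix_path,
                                 samplesheet_path = NULL) {
  out <- data.frame(snp_id = panel$snp_ids,
                    gentrain = unname(panel$gentrain),
                    adt = unname(panel$adt),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in panel$samples$sample_id) {
    out[[s]] <- panel$genotypes[, s]
    out[[paste0(s, "_gencall")]] <- panel$gencall[, s]
  }
  write.csv(out, matrix_path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(samplesheet_path)) {
    write.csv(panel$samples, samplesheet_path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(matrix_path)
}

#' Read / write trio genotype tables
#'
#' CSV with columns `snp_id`, `trio_id`, `father`, `mother`, `child`,
#' genotypes over `{AA, AB, BB, NC}`.
#'
#' @param path CSV path.
#' @return `read_trios()`: a data.frame of `TrioRecord` rows.
#' @export
read_trios <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "trio_id", "father", "mother", "child")
  if (!all(need %in% names(df))) {
    stop("trio CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' @rdname read_trios
#' @param trios Data frame as returned by [simulate_trios()].
#' @export
write_trios <- function(trios, path) {
  write.csv(trios[c("snp_id", "trio_id", "father", "mother", "child")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-SNP allele read counts
#'
#' TSV with columns `snp_id`, `ref_count`, `alt_count`, `other_count`;
#' the shotgun evidence consumed by [seq_genotype_call()].
#'
#' @param path TSV path.
#' @return `read_allele_counts()`: a data.frame.
#' @export
read_allele_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "ref_count", "alt_count", "other_count")
  if (!all(need %in% names(df))) {
    stop("counts TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' @rdname read_allele_counts
#' @param counts Data frame with the four count columns.
#' @export
write_allele_counts <- function(counts, path) {
  df <- counts[c("snp_id", "ref_count", "alt_count", "other_count")]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic record report
#'
#' Serialises a data.frame of records deterministically: column order as
#' given, doubles at 6 significant digits, and any column named
#' `position` (internal 0-based) shifted to 1-based for human
#' consumption. Two runs on the same records produce byte-identical
#' files.
#'
#' @param records Data frame; may have zero rows (TSV then holds only the
#'   header).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  df <- records
  if ("position" %in% names(df)) df$position <- df$position + 1L
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                na = "NA")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
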