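# Readers and writers for the allc per-cytosine methylation table and for
# feature annotations (BED / GFF3).
#
# Internal convention: all coordinates are 1-based and closed, the
# GRanges/IRanges convention. allc files store 1-based positions (methylpy
# convention) so no shift is applied at that boundary; BED (0-based,
# half-open) and GFF3 (1-based, closed) conversions are handled by
# rtracklayer at import/export.

ALLC_COLS <- c("chrom", "pos", "strand", "context3", "mc", "cov")

#' Read an allc per-cytosine methylation table
#'
#' Parses the 6-column (optionally 7-column, with a call flag) tab-delimited
#' allc dialect: chrom, 1-based position, strand, trinucleotide context,
#' methylated reads, total reads. Rows violating `mc <= cov` are an error;
#' under `lenient = TRUE` unparseable rows are dropped with a warning naming
#' their line numbers. Context classes (`major_class`, `subclass`) are derived
#' from the declared trinucleotide.
#'
#' @param path Path to the allc file.
#' @param lenient Drop malformed rows with a warning instead of failing.
#' @return A `data.table` keyed by (chrom, pos, strand) with columns
#'   `chrom`, `pos`, `strand`, `context3`, `mc`, `cov`, `major_class`,
#'   `subclass`.
#' @export
read_allc <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty allc file: ", path)
    return(empty_sites())
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 4)))
  if (nrow(dt) == 0L) {
    warning("empty allc file: ", path)
    return(empty_sites())
  }
  if (ncol(dt) < 6L) {
    stop(sprintf("allc file %s has %d columns; at least 6 required", path, ncol(dt)))
  }
  dt <- dt[, 1:6]
  data.table::setnames(dt, ALLC_COLS)
  suppressWarnings({
    dt[, pos := as.integer(pos)]
    dt[, mc := as.integer(mc)]
    dt[, cov := as.integer(cov)]
  })
  bad <- which(!complete.cases(dt) | dt$mc < 0L | dt$cov < 0L |
                 !dt$strand %in% c("+", "-"))
  if (length(bad)) {
    if (!lenient) {
      stop(sprintf("malformed allc row(s) at line %s in %s",
                   paste(head(bad, 5), collapse = ","), path))
    }
    warning(sprintf("dropped %d malformed allc row(s) (first at line %d)",
                    length(bad), bad[1]))
    dt <- dt[-bad]
  }
  over <- which(dt$mc > dt$cov)
  if (length(over)) {
    stop(sprintf("mc > cov at line %s in %s",
                 paste(head(over, 5), collapse = ","), path))
  }
  lab <- classify_context_string(dt$context3)
  dt[, `:=`(major_class = lab$major_class, subclass = lab$subclass)]
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  dt[]
}

empty_sites <- function() {
  dt <- data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    context3 = character(), mc = integer(), cov = integer(),
    major_class = character(), subclass = character())
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  dt
}

#' Write an allc table
#'
#' Emits the canonical 6 columns, tab-delimited, no header, sorted by
#' (chrom, pos, strand). `write_allc` then `read_allc` round-trips
#' byte-identically for well-formed tables.
#'
#' @param sites Site table as returned by [read_allc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allc <- function(sites, path) {
  dt <- data.table::as.data.table(sites)[, ALLC_COLS, with = FALSE]
  data.table::setorderv(dt, c("chrom", "pos", "strand"))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genomic features from BED or GFF3
#'
#' Imports a feature annotation through rtracklayer and returns a
#' [GenomicRanges::GRanges] with metadata columns `id` and `feature_class`.
#' For GFF3, gene/exon hierarchies are flattened: one range per gene carrying
#' `exon_count`; repeat-like types map to class `repeat`. For BED, the name
#' column is the id and `feature_class` is taken from the argument.
#'
#' @param path Annotation file.
#' @param dialect `"BED"` or `"GFF3"` (default: guessed from the extension).
#' @param feature_class Class assigned to BED features (default `"gene"`).
#' @return A `GRanges` with `id`, `feature_class` and (for GFF3 genes)
#'   `exon_count` metadata columns.
#' @export
read_features <- function(path, dialect = NULL, feature_class = "gene") {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "GFF3" else "BED"
  }
  dialect <- match.arg(toupper(dialect), c("BED", "GFF3"))
  if (dialect == "BED") {
    gr <- rtracklayer::import(path, format = "BED")
    mc <- S4Vectors::mcols(gr)
    id <- if (!is.null(mc$name)) as.character(mc$name) else
      rep(NA_character_, length(gr))
    blank <- is.na(id) | id == "." | id == ""
    id[blank] <- paste0("feat_", seq_along(gr))[blank]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      id = id, feature_class = rep(feature_class, length(gr)))
  } else {
    g <- rtracklayer::import(path, format = "GFF3")
    type <- as.character(g$type)
    repeat_types <- c("repeat_region", "transposable_element",
                      "transposable_element_gene", "repeat")
    genes <- g[type == "gene"]
    exons <- g[type == "exon"]
    reps <- g[type %in% repeat_types]
    others <- g[!type %in% c("gene", "exon", repeat_types)]
    parent_of <- function(x) {
      p <- x$Parent
      if (is.null(p)) rep(NA_character_, length(x)) else
        vapply(as.list(p), function(v) if (length(v)) as.character(v[1]) else NA_character_, "")
    }
    gid <- as.character(genes$ID)
    if (!length(gid) || anyNA(gid)) gid <- as.character(genes$Name)
    ex_parent <- sub("^(gene|transcript|mRNA):", "", parent_of(exons))
    exon_count <- as.integer(table(factor(ex_parent, levels = gid)))
    out <- c(
      granges_with(genes, gid, "gene", exon_count),
      granges_with(reps, feat_id(reps, "repeat"), "repeat", NA_integer_),
      granges_with(others, feat_id(others, "feat"), "other", NA_integer_)
    )
    gr <- sort(out)
  }
  if (any(GenomicRanges::width(gr) < 1L)) stop("feature with end < start after normalization")
  if (anyDuplicated(gr$id)) stop("duplicate feature ids in ", path)
  gr
}

feat_id <- function(g, prefix) {
  id <- as.character(g$ID)
  if (!length(g)) return(character())
  if (!length(id) || anyNA(id)) id <- paste0(prefix, "_", seq_along(g))
  id
}

granges_with <- function(g, id, cls, exon_count) {
  g2 <- GenomicRanges::granges(g)
  S4Vectors::mcols(g2) <- S4Vectors::DataFrame(
    id = id, feature_class = rep(cls, length(g2)),
    exon_count = rep_len(exon_count, length(g2)))
  g2
}

#' Write a result table with stable formatting
#'
#' TSV with a fixed column order and a provenance header line (tool version
#' and seed) so re-runs with the same inputs are byte-identical.
#'
#' @param dt A data.frame / data.table.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header (optional).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(dt, path, seed = NA) {
  writeLines(sprintf("# gbminit %s seed=%s",
                     as.character(utils::packageVersion("gbminit")),
                     as.character(seed)), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}
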