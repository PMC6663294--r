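# Strand-aware trinucleotide context classification.
#
# Every cytosine is labelled by the trinucleotide read 5'->3' on its own
# strand (first base C), then partitioned into the three canonical major
# classes and the chromomethylase-relevant subclasses:
#   CG;  CHG split into CWG (W = A/T) vs CCG;  CHH split into CWA vs other.
# CWG/CCG partition CHG exactly and CWA/other-CHH partition CHH exactly.

#' The 16 determined trinucleotide contexts
#'
#' Enumerates all `CNN` trinucleotides (N in A,C,G,T) together with their
#' major class (`CG`, `CHG`, `CHH`) and subclass (`CG`, `CWG`, `CCG`, `CWA`,
#' `CHH_other`).
#'
#' @return A `data.table` with columns `tri`, `major_class`, `subclass`,
#'   one row per determined trinucleotide (16 rows).
#' @export
context_table <- function() {
  bases <- c("A", "C", "G", "T")
  tri <- paste0("C", rep(bases, each = 4), rep(bases, 4))
  out <- classify_context_string(tri)
  data.table::setDT(out)
  out[]
}

#' Classify trinucleotide strings into methylation contexts
#'
#' Vectorised classification of 3-character trinucleotides (as read 5'->3' on
#' the cytosine's strand). Strings that are not length 3, do not start with C,
#' or contain non-ACGT characters are labelled `UNDETERMINED` and excluded
#' from all downstream statistics.
#'
#' @param tri Character vector of trinucleotides.
#' @return A `data.table` with columns `tri`, `major_class`, `subclass`.
#' @export
classify_context_string <- function(tri) {
  tri <- toupper(as.character(tri))
  b1 <- substr(tri, 1, 1)
  b2 <- substr(tri, 2, 2)
  b3 <- substr(tri, 3, 3)
  ok <- nchar(tri) == 3L & b1 == "C" &
    b2 %in% c("A", "C", "G", "T") & b3 %in% c("A", "C", "G", "T")
  major <- rep("UNDETERMINED", length(tri))
  sub <- rep("UNDETERMINED", length(tri))
  is_cg <- ok & b2 == "G"
  is_chg <- ok & b2 != "G" & b3 == "G"
  is_chh <- ok & b2 != "G" & b3 != "G"
  major[is_cg] <- "CG"
  major[is_chg] <- "CHG"
  major[is_chh] <- "CHH"
  sub[is_cg] <- "CG"
  sub[is_chg & b2 %in% c("A", "T")] <- "CWG"
  sub[is_chg & b2 == "C"] <- "CCG"
  sub[is_chh & b2 %in% c("A", "T") & b3 == "A"] <- "CWA"
  sub[is_chh & sub == "UNDETERMINED"] <- "CHH_other"
  data.table::data.table(tri = tri, major_class = major, subclass = sub)
}

#' Extract the genome-derived context of cytosines
#'
#' Reads the trinucleotide at each (chrom, pos, strand) from the genome,
#' reverse-complementing for minus-strand cytosines so the context is always
#' 5'->3' on the cytosine's own strand. Positions within two bases of the
#' contig end on the read direction, or whose window contains a non-ACGT
#' base, are `UNDETERMINED`. Positions are 1-based.
#'
#' @param genome A [Biostrings::DNAStringSet] named by contig.
#' @param chrom,pos,strand Parallel vectors locating each cytosine.
#' @return A `data.table` with columns `tri`, `major_class`, `subclass`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  if (!all(chrom %in% names(genome))) {
    stop("contig(s) absent from genome: ",
         paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  plus <- strand == "+"
  # window on the reference strand; minus-strand windows are the two bases
  # upstream on the reference, reverse-complemented
  win_start <- ifelse(plus, pos, pos - 2L)
  win_end <- ifelse(plus, pos + 2L, pos)
  in_range <- win_start >= 1L & win_end <= clen
  tri <- rep(NA_character_, n)
  if (any(in_range)) {
    seqs <- lapply(setNames(nm = unique(chrom)), function(ch) {
      as.character(genome[[ch]])
    })
    idx <- which(in_range)
    s_by_site <- character(length(idx))
    for (ch in unique(chrom[idx])) {
      ii <- chrom[idx] == ch
      s_by_site[ii] <- substring(seqs[[ch]], win_start[idx][ii], win_end[idx][ii])
    }
    mi <- !plus[in_range]
    if (any(mi)) {
      rc <- chartr("ACGTN", "TGCAN", s_by_site[mi])
      s_by_site[mi] <- paste0(substr(rc, 3, 3), substr(rc, 2, 2), substr(rc, 1, 1))
    }
    tri[in_range] <- s_by_site
  }
  first <- substr(tri, 1, 1)
  bad <- !is.na(tri) & first != "C" & first %in% c("A", "G", "T")
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("base at %s:%d(%s) is %s, not C on that strand",
                 chrom[i], pos[i], strand[i], first[i]))
  }
  tri[is.na(tri)] <- "NNN"
  classify_context_string(tri)
}

#' Reconcile file-declared contexts with genome-derived ones
#'
#' Recomputes every site's context from the genome and compares it with the
#' context declared in the methylation table. The genome-derived label always
#' wins; the mismatch count is reported, and a mismatch rate above
#' `max_mismatch_rate` aborts with a coordinate-convention hint, since an
#' off-by-one convention error is the most common silent cause.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param sites A site table from [read_allc()].
#' @param max_mismatch_rate Abort threshold on the declared-vs-derived
#'   mismatch fraction (default 0.01).
#' @return The site table with `context3`, `major_class`, `subclass` replaced
#'   by genome-derived values, and attributes `n_mismatch` / `mismatch_rate`.
#' @export
annotate_sites <- function(genome, sites, max_mismatch_rate = 0.01) {
  sites <- data.table::as.data.table(sites)
  lab <- classify_context(genome, sites$chrom, sites$pos, sites$strand)
  n_mismatch <- sum(lab$tri != sites$context3 & lab$major_class != "UNDETERMINED")
  rate <- if (nrow(sites)) n_mismatch / nrow(sites) else 0
  if (rate > max_mismatch_rate) {
    stop(sprintf(paste0(
      "declared/derived context mismatch rate %.1f%% exceeds %.1f%%; ",
      "check the position convention of the input (allc positions are 1-based)"),
      100 * rate, 100 * max_mismatch_rate))
  }
  out <- data.table::copy(sites)
  out[, `:=`(context3 = lab$tri,
             major_class = lab$major_class,
             subclass = lab$subclass)]
  data.table::setattr(out, "n_mismatch", n_mismatch)
  data.table::setattr(out, "mismatch_rate", rate)
  out[]
}
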