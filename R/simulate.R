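# Synthetic study generator.
#
# Emulates the study design end to end: a random genome with genes, repeats
# and intergenic space on a main contig plus a fully unmethylated control
# contig (the chloroplast stand-in); a wild-type methylome with methylated
# repeats and unmethylated genes; a transgenic generational series in which
# the probability that a gene gains CHG methylation rises with that
# generation's transgene expression, gained CHG methylation is CWG-enriched,
# co-gained CHH is CWA-enriched and co-gained CG is lower; and, after the
# silencing generation, per-site per-generation retention that is high for
# CG and low for CHG/CHH. Reads are emitted per cytosine as
# cov ~ Poisson(lambda), mc ~ Binomial(cov, f + (1 - f) r), where f is the
# site's true methylated fraction and r the bisulfite non-conversion rate.

#' Simulation configuration
#'
#' Returns the generator's parameter list. Defaults define the study
#' conditions: six generations with transgene expression rising to the
#' fourth and silenced afterwards, repeat methylation CG 0.80 / CHG 0.15 /
#' CHH 0.10, genes unmethylated in wild type, CWG:CCG gain odds 9:1, CWA
#' strongly preferred within co-gained CHH, post-silencing per-generation
#' retention CG 0.7 / CHG 0.2 / CHH 0.2, mean coverage 20 and non-conversion
#' 0.005.
#'
#' @param seed Integer seed controlling every draw.
#' @param ... Overrides for any listed parameter.
#' @return A named list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    main_chrom = "chr1",
    control_chrom = "chrC",
    control_len = 20000L,
    n_genes = 120L,
    gene_len = c(1000L, 3000L),
    exon_range = c(1L, 8L),
    n_repeats = 60L,
    repeat_len = c(500L, 1500L),
    intergenic_len = c(200L, 800L),
    gc = 0.36,
    # wild-type true methylated fractions over repeats (genes are 0)
    wt_repeat_meth = c(CG = 0.80, CHG = 0.15, CHH = 0.10),
    generations = paste0("T", 1:6),
    # transgene FPKM per generation; silenced after generation 4
    expression = c(T1 = 60, T2 = 120, T3 = 180, T4 = 240, T5 = 0, T6 = 0),
    silencing_after = 4L,
    # fraction of genes susceptible to gain at all (length-weighted)
    susceptible_frac = 0.6,
    # per-generation gene gain probability = expr / (expr + gain_half_fpkm)
    gain_half_fpkm = 60,
    # per-site methylation probabilities within a gained gene
    site_gain_prob = c(CWG = 0.60, CCG = 0.60 / 9, CWA = 0.30,
                       CHH_other = 0.02, CG = 0.25),
    # true methylated fraction of a gained site, by major class
    gain_meth = c(CG = 0.85, CHG = 0.80, CHH = 0.70),
    # per-generation post-silencing retention probability, by major class
    retention = c(CG = 0.7, CHG = 0.2, CHH = 0.2),
    coverage_lambda = 20,
    nonconversion = 0.005
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  probs <- c(cfg$wt_repeat_meth, cfg$site_gain_prob, cfg$gain_meth,
             cfg$retention, cfg$nonconversion)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  cfg
}

#' Generate a synthetic reference genome and annotation
#'
#' Lays genes and repeats in random order along the main contig separated by
#' intergenic spacers, draws random sequence at the configured GC content,
#' and appends the unmethylated control contig.
#'
#' @param config From [sim_config()].
#' @return A list with `genome` ([Biostrings::DNAStringSet]) and `features`
#'   (`GRanges` with `id`, `feature_class`, `exon_count`).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  n_feat <- config$n_genes + config$n_repeats
  is_gene <- sample(rep(c(TRUE, FALSE), c(config$n_genes, config$n_repeats)))
  lens <- integer(n_feat)
  lens[is_gene] <- sample(config$gene_len[1]:config$gene_len[2],
                          config$n_genes, replace = TRUE)
  lens[!is_gene] <- sample(config$repeat_len[1]:config$repeat_len[2],
                           config$n_repeats, replace = TRUE)
  gaps <- sample(config$intergenic_len[1]:config$intergenic_len[2],
                 n_feat + 1L, replace = TRUE)
  starts <- cumsum(gaps[seq_len(n_feat)]) + c(0L, cumsum(head(lens, -1L))) + 1L
  ends <- starts + lens - 1L
  main_len <- ends[n_feat] + gaps[n_feat + 1L]
  feat <- GenomicRanges::GRanges(
    config$main_chrom, IRanges::IRanges(starts, ends),
    strand = ifelse(is_gene, sample(c("+", "-"), n_feat, replace = TRUE), "*"))
  feat$id <- ifelse(is_gene,
                    sprintf("gene_%03d", cumsum(is_gene)),
                    sprintf("repeat_%03d", cumsum(!is_gene)))
  feat$feature_class <- ifelse(is_gene, "gene", "repeat")
  feat$exon_count <- ifelse(
    is_gene, sample(config$exon_range[1]:config$exon_range[2], n_feat,
                    replace = TRUE), NA_integer_)
  rand_seq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - config$gc) / 2, config$gc / 2,
                          config$gc / 2, (1 - config$gc) / 2)),
          collapse = "")
  }
  genome <- Biostrings::DNAStringSet(c(rand_seq(main_len),
                                       rand_seq(config$control_len)))
  names(genome) <- c(config$main_chrom, config$control_chrom)
  ctrl <- GenomicRanges::GRanges(config$control_chrom,
                                 IRanges::IRanges(1L, config$control_len))
  ctrl$id <- "control"
  ctrl$feature_class <- "control_contig"
  ctrl$exon_count <- NA_integer_
  list(genome = genome, features = suppressWarnings(c(feat, ctrl)))
}

#' All cytosine sites of a genome, both strands
#'
#' Scans every contig on both strands for cytosines with a determined
#' trinucleotide context (positions within two bases of a contig end are
#' dropped).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A `data.table`: chrom, pos (1-based), strand, context3,
#'   major_class, subclass, sorted by (chrom, pos, strand).
#' @export
all_cytosine_sites <- function(genome) {
  res <- lapply(names(genome), function(ch) {
    s <- as.character(genome[[ch]])
    n <- nchar(s)
    if (n < 3) return(NULL)
    b <- strsplit(s, "")[[1]]
    b1 <- b[1:(n - 2)]; b2 <- b[2:(n - 1)]; b3 <- b[3:n]
    # plus strand: C at p with window p..p+2
    pp <- which(b1 == "C")
    plus <- data.table::data.table(
      chrom = ch, pos = pp, strand = "+",
      context3 = paste0("C", b2[pp], b3[pp]))
    # minus strand: G on the reference at p+2 is a C on the minus strand,
    # its 5'->3' window is the reverse complement of p..p+2
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pm <- which(b3 == "G" & b1 %in% names(comp) & b2 %in% names(comp))
    minus <- data.table::data.table(
      chrom = ch, pos = pm + 2L, strand = "-",
      context3 = paste0("C", comp[b2[pm]], comp[b1[pm]]))
    rbind(plus, minus)
  })
  dt <- data.table::rbindlist(res)
  lab <- classify_context_string(dt$context3)
  dt[, `:=`(major_class = lab$major_class, subclass = lab$subclass)]
  dt <- dt[major_class != "UNDETERMINED"]
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  dt[]
}

#' Simulate the true methylome of a generational series
#'
#' Builds the per-site true methylated fraction for wild type and every
#' generation. Repeats carry the wild-type fractions in all samples; genes
#' are unmethylated in wild type; susceptible genes gain methylation with a
#' per-generation probability increasing in transgene expression, with
#' CWG-enriched CHG, CWA-enriched CHH and lower CG co-gain; after the
#' silencing generation each methylated genic site persists per generation
#' with the context-specific retention probability. The control contig is 0
#' everywhere.
#'
#' @param reference From [generate_reference()].
#' @param config From [sim_config()].
#' @return A list: `sites` (site table), `f` (sites x samples matrix of true
#'   fractions), `samples` (column names, "WT" first), `gene_truth`
#'   (per-gene gain generation and susceptibility), `config`, `reference`.
#' @export
simulate_methylome_series <- function(reference, config) {
  gens <- config$generations
  if (length(config$expression) < length(gens)) {
    stop("expression trajectory shorter than the generation count")
  }
  set.seed(config$seed + 1L)
  sites <- all_cytosine_sites(reference$genome)
  feats <- reference$features
  genes <- feats[feats$feature_class == "gene"]
  reps <- feats[feats$feature_class == "repeat"]
  sgr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  sites[, region_class := "intergenic"]
  sites[sites$chrom == config$control_chrom, region_class := "control"]
  ov_rep <- IRanges::overlapsAny(sgr, reps, ignore.strand = TRUE)
  sites[ov_rep, region_class := "repeat"]
  ovg <- GenomicRanges::findOverlaps(sgr, genes, ignore.strand = TRUE)
  sites[, gene_id := NA_character_]
  sites[S4Vectors::queryHits(ovg), `:=`(region_class = "gene",
                                        gene_id = genes$id[S4Vectors::subjectHits(ovg)])]
  samples <- c("WT", gens)
  nsite <- nrow(sites)
  f <- matrix(0, nrow = nsite, ncol = length(samples),
              dimnames = list(NULL, samples))
  # repeats: wild-type fractions, maintained in every sample
  in_rep <- sites$region_class == "repeat"
  f_rep <- config$wt_repeat_meth[sites$major_class[in_rep]]
  f[in_rep, ] <- f_rep
  # gene susceptibility weighted towards longer genes
  glen <- GenomicRanges::width(genes)
  sus_p <- config$susceptible_frac *
    (0.4 + 1.2 * (rank(glen) - 1) / max(1, length(glen) - 1))
  susceptible <- runif(length(genes)) < pmin(1, sus_p)
  gain_gen <- rep(NA_integer_, length(genes))
  expr <- config$expression[seq_along(gens)]
  p_gain <- expr / (expr + config$gain_half_fpkm)
  for (g in seq_along(gens)) {
    if (g > config$silencing_after) break
    can <- susceptible & is.na(gain_gen)
    hit <- can & runif(length(genes)) < p_gain[g]
    gain_gen[hit] <- g
  }
  # site-level gain within gained genes
  site_gene <- match(sites$gene_id, genes$id)
  site_gain_p <- config$site_gain_prob[sites$subclass]
  site_gain_p[sites$subclass == "CG"] <- config$site_gain_prob[["CG"]]
  site_gain_p[is.na(site_gain_p)] <- 0
  gained_site <- !is.na(site_gene) & !is.na(gain_gen[site_gene]) &
    runif(nsite) < site_gain_p
  g0 <- ifelse(gained_site, gain_gen[site_gene], NA_integer_)
  f_gain <- config$gain_meth[sites$major_class]
  ret_p <- config$retention[sites$major_class]
  alive <- gained_site  # methylated state carried generation to generation
  for (g in seq_along(gens)) {
    newly <- gained_site & !is.na(g0) & g0 == g
    if (g <= config$silencing_after) {
      on_now <- gained_site & !is.na(g0) & g0 <= g
    } else {
      # each surviving site persists with the per-context retention prob
      prev <- alive
      alive <- prev & runif(nsite) < ret_p
      on_now <- alive
    }
    if (g == config$silencing_after) alive <- gained_site & !is.na(g0) & g0 <= g
    f[on_now, gens[g]] <- pmax(f[on_now, gens[g]], f_gain[on_now])
  }
  gene_truth <- data.table::data.table(
    gene_id = genes$id, length = glen, exon_count = genes$exon_count,
    susceptible = susceptible, gain_generation = gain_gen)
  for (g in seq_along(gens)) {
    ggen <- gain_gen
    gained_in_g <- !is.na(ggen) & ggen <= g & g <= config$silencing_after
    gene_truth[, paste0("gained_", gens[g]) := gained_in_g]
  }
  list(sites = sites, f = f, samples = samples, gene_truth = gene_truth,
       config = config, reference = reference)
}

#' Emit an allc table for one simulated sample
#'
#' Draws coverage and methylated read counts under the read model
#' cov ~ Poisson(lambda), mc ~ Binomial(cov, f + (1 - f) r).
#'
#' @param sim From [simulate_methylome_series()].
#' @param sample Sample (column) name.
#' @param seed Integer seed for the read draws.
#' @return A site table in [read_allc()] layout.
#' @export
emit_allc <- function(sim, sample, seed) {
  stopifnot(sample %in% colnames(sim$f))
  cfg <- sim$config
  if (cfg$coverage_lambda <= 0) stop("coverage_lambda must be positive")
  if (cfg$nonconversion < 0 || cfg$nonconversion >= 1) {
    stop("nonconversion must be in [0, 1)")
  }
  set.seed(seed)
  n <- nrow(sim$sites)
  fv <- sim$f[, sample]
  cov <- rpois(n, cfg$coverage_lambda)
  mc <- rbinom(n, cov, fv + (1 - fv) * cfg$nonconversion)
  out <- sim$sites[, .(chrom, pos, strand, context3, major_class, subclass)]
  out[, `:=`(mc = mc, cov = cov)]
  data.table::setcolorder(out, c("chrom", "pos", "strand", "context3",
                                 "mc", "cov", "major_class", "subclass"))
  data.table::setkeyv(out, c("chrom", "pos", "strand"))
  out[]
}

#' Emit the whole simulated study
#'
#' Convenience wrapper: reference, methylome series, and one allc table per
#' sample (seeded deterministically from the config seed).
#'
#' @param config From [sim_config()].
#' @return The [simulate_methylome_series()] list with an added `allc`
#'   element (named list of site tables, "WT" first).
#' @export
simulate_study <- function(config) {
  ref <- generate_reference(config)
  sim <- simulate_methylome_series(ref, config)
  sim$allc <- lapply(seq_along(sim$samples), function(i) {
    emit_allc(sim, sim$samples[i], seed = config$seed + 100L + i)
  })
  names(sim$allc) <- sim$samples
  sim
}

#' Simulate ChIP and expression tables
#'
#' ChIP read counts are elevated over repeats and at background level over
#' genes (heterochromatin-restricted H3K9me2); the FPKM table carries the
#' transgene following the configured trajectory plus stable per-gene
#' baselines; Ct tables are back-computed from relative expression with
#' Gaussian technical noise.
#'
#' @param reference From [generate_reference()].
#' @param config From [sim_config()].
#' @param seed Integer seed.
#' @param bg_rate,peak_rate Per-bp read rates off/on repeats
#'   (defaults 0.01 and 0.2).
#' @return A list with `peaks` (`GRanges` + counts), `library_size`,
#'   `window_counts` (function of loci), `fpkm` (long table), `ct` (long
#'   table of technical replicates).
#' @export
simulate_chip_and_expression <- function(reference, config, seed = config$seed + 500L,
                                         bg_rate = 0.01, peak_rate = 0.2) {
  set.seed(seed)
  feats <- reference$features
  reps <- GenomicRanges::reduce(feats[feats$feature_class == "repeat"],
                                ignore.strand = TRUE)
  peak_counts <- rpois(length(reps), peak_rate * GenomicRanges::width(reps))
  genome_len <- sum(Biostrings::width(reference$genome))
  library_size <- sum(peak_counts) +
    rpois(1, bg_rate * (genome_len - sum(GenomicRanges::width(reps))))
  count_windows <- function(loci) {
    wins <- chip_windows(loci)
    m <- sapply(wins, function(w) {
      ov_bp <- rep(0L, length(w))
      hits <- GenomicRanges::findOverlaps(w, reps, ignore.strand = TRUE)
      if (length(hits)) {
        inter <- GenomicRanges::pintersect(w[S4Vectors::queryHits(hits)],
                                           reps[S4Vectors::subjectHits(hits)])
        bp <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
        ov_bp[as.integer(names(bp))] <- as.integer(bp)
      }
      lam <- bg_rate * GenomicRanges::width(w) + (peak_rate - bg_rate) * ov_bp
      rpois(length(w), lam)
    })
    matrix(m, ncol = 4L, dimnames = list(loci$id, names(wins)))
  }
  genes <- feats[feats$feature_class == "gene"]
  gens <- config$generations
  base <- exp(rnorm(length(genes), mean = 2.5, sd = 1))
  fpkm <- data.table::rbindlist(lapply(c("WT", gens), function(s) {
    e <- if (s == "WT") 0 else unname(config$expression[[s]])
    data.table::data.table(
      sample = s,
      gene_id = c(genes$id, "AtCMT3_transgene"),
      fpkm = c(base * exp(rnorm(length(genes), 0, 0.1)), e))
  }))
  ct <- data.table::rbindlist(lapply(c("WT", gens), function(s) {
    e <- if (s == "WT") 0 else unname(config$expression[[s]])
    rel <- max(e / 100, 2^-15)  # detection floor
    ct_ref <- 20 + rnorm(3, 0, 0.1)
    ct_tar <- mean(ct_ref) - log2(rel) + rnorm(3, 0, 0.1)
    data.table::data.table(sample = s,
                           replicate = 1:3, ct_target = ct_tar, ct_reference = ct_ref)
  }))
  list(peaks = reps, peak_counts = peak_counts, library_size = library_size,
       count_windows = count_windows, fpkm = fpkm, ct = ct)
}
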