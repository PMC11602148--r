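## Orchestration: a single explicit configuration object, validation, and
## stage runners that reproduce each figure-level analysis from declared
## inputs (here, the synthetic generators).  Every run writes its resolved
## configuration next to its outputs and logs record counts.

#' Default run configuration
#'
#' All numeric parameters of every stage, at the study's stated values:
#' ANOVA invariance threshold 1e-6, MAF threshold 0.05, accessibility
#' fraction 0.03, pseudobulk group sizes 175 and 50, bin counts 10 and 50,
#' centrality windows 50/250/750, PSS half-width 50 and NSS range 200-400,
#' and the clade scheme of [cladeScheme].
#'
#' @param seed Seed recorded in the config.
#' @return Named list of parameters.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    peak_width = 1500L,
    centrality_near = 50, centrality_distal = c(250, 750),
    per_peak_near = 100, per_peak_distal = 200,
    anova_threshold = 1e-6,
    pseudobulk_group_size = 175L,
    expr_group_size = 50L,
    accessible_min_fraction = 0.03,
    quantile_bins = 50L, score_bins = 10L,
    window_fraction = 0.4,
    max_gap = 30L,
    methylation_halfwidth = 5,
    methylation_bin = 10,
    maf_min = 0.05,
    pss_halfwidth = 50, nss_range = c(200, 400),
    clade_scheme = cladeScheme()
  )
}

#' Validate a run configuration
#'
#' Checks parameter ranges and ordering (e.g. NSS bounds increasing and
#' beyond the PSS half-width); errors name the offending key.
#'
#' @param config List from [defaultConfig] (possibly modified).
#' @return The config, invisibly, if valid.
#' @export
validateConfig <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(config$peak_width > 0, "peak_width must be positive")
  chk(config$centrality_distal[1] > config$centrality_near,
      "centrality distal window must start beyond the near half-width")
  chk(diff(config$centrality_distal) > 0,
      "centrality_distal must be increasing")
  chk(config$anova_threshold > 0 && config$anova_threshold < 1,
      "anova_threshold must be in (0,1)")
  chk(config$maf_min >= 0 && config$maf_min <= 0.5,
      "maf_min must be in [0, 0.5]")
  chk(config$nss_range[2] > config$nss_range[1],
      "nss_range must be increasing")
  chk(config$nss_range[1] > config$pss_halfwidth,
      "nss_range must lie beyond the PSS half-width")
  chk(config$pseudobulk_group_size >= 1, "pseudobulk_group_size must be >= 1")
  chk(config$quantile_bins >= 2, "quantile_bins must be >= 2")
  invisible(config)
}

.writeConfig <- function(config, out_dir) {
  path <- file.path(out_dir, "resolved_config.txt")
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.data.frame(v))
      v <- paste(apply(v, 1, paste, collapse = "/"), collapse = ";")
    paste0(k, " = ", paste(v, collapse = ","))
  }, "")
  writeLines(lines, path)
  path
}

#' Run a pipeline stage on synthetic inputs
#'
#' Stages: `"simulate"` writes synthetic inputs (genome + peaks,
#' pseudobulks, SELEX rounds, variants/alignments, methylation tracks) to
#' `out_dir`; the analysis stages (`"scan"`, `"grammar"`, `"trajectories"`,
#' `"methylation"`, `"selex"`, `"conservation"`) read those files, run the
#' corresponding operations and write delimited result tables.  Runs are
#' deterministic given (config, seed); each run writes its resolved config
#' and logs record counts.
#'
#' @param stage Stage name.
#' @param config From [defaultConfig]; validated before any computation.
#' @param out_dir Output (and, for analysis stages, input) directory.
#' @return Invisibly, a named list of output file paths.
#' @export
runStage <- function(stage = c("simulate", "scan", "grammar",
                               "trajectories", "methylation", "selex",
                               "conservation"),
                     config = defaultConfig(), out_dir = tempdir()) {
  stage <- match.arg(stage)
  validateConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .writeConfig(config, out_dir)
  seed <- config$seed
  paths <- list()
  need <- function(path) {
    if (!file.exists(path))
      stop("missing input for stage '", stage, "': ", path)
    path
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  if (stage == "simulate") {
    g <- simEBoxGenome(n_peaks = 200L, peak_width = config$peak_width,
                       density_near = c("CAT-CAT" = 0.03),
                       density_distal = c("CAT-CAT" = 0.01),
                       paired_gap = 6L, seed = seed)
    writeXStringSet(g$sequences, file.path(out_dir, "genome.fa"))
    writeNarrowPeak(g$peaks, file.path(out_dir, "peaks.narrowPeak"))
    tsv(g$truth, "genome_truth.tsv")
    pb <- simPseudobulk(seed = seed)
    tsv(data.frame(region = rownames(assay(pb$pseudobulk)),
                   assay(pb$pseudobulk), check.names = FALSE),
        "pseudobulk_counts.tsv")
    tsv(data.frame(sample = colnames(assay(pb$pseudobulk)),
                   cell_type = cellTypes(pb$pseudobulk)),
        "pseudobulk_samples.tsv")
    tsv(pb$truth, "pseudobulk_truth.tsv")
    sx <- simSelex(n_reads = 20000L, seed = seed)
    for (i in seq_len(nRounds(sx$rounds)))
      writeXStringSet(roundReads(sx$rounds, i),
                      file.path(out_dir, sprintf("selex_round%d.fa", i)))
    cons <- simConservation(n_sites = 4000L, seed = seed)
    tsv(data.frame(contig = as.character(seqnames(cons$sites)),
                   start = start(cons$sites),
                   ebox_class = cons$sites$ebox_class,
                   summit_distance = cons$sites$summit_distance,
                   ref = cons$sites$ref), "conservation_sites.tsv")
    tsv(cons$variants, "variants.tsv")
    tsv(cons$outgroup, "outgroup.tsv")
    tsv(cons$blocks, "alignment_blocks.tsv")
    sites_gr <- GRanges(seqnames(g$peaks), IRanges(g$peaks$summit, width = 1L))
    meth_sites <- scanEBoxSet(g$sequences)
    mt <- simMethylation(meth_sites, seed = seed)
    writeBedGraph(mt$track_a, file.path(out_dir, "meth_nsc.bedGraph"))
    writeBedGraph(mt$track_b, file.path(out_dir, "meth_pn.bedGraph"))
    message("simulate: ", length(g$peaks), " peaks, ",
            nrow(g$truth), " planted motifs, ",
            nrow(cons$variants), " variants")
  } else if (stage == "scan") {
    seqs <- readDNAStringSet(need(file.path(out_dir, "genome.fa")))
    peaks <- readNarrowPeak(need(file.path(out_dir, "peaks.narrowPeak")))
    sites <- annotateSummitDistance(scanEBoxSet(seqs), peaks)
    message("scan: ", length(sites), " E-box sites in ", length(seqs),
            " contigs")
    tsv(data.frame(contig = as.character(seqnames(sites)),
                   start = start(sites), hexamer = sites$hexamer,
                   ebox_class = sites$ebox_class, flank_a = sites$flank_a,
                   flank_b = sites$flank_b, peak_id = sites$peak_id,
                   summit_distance = sites$summit_distance), "sites.tsv")
  } else if (stage == "grammar") {
    s <- read.table(need(file.path(out_dir, "sites.tsv")), header = TRUE,
                    sep = "\t")
    sites <- GRanges(s$contig, IRanges(s$start, width = 6L),
                     hexamer = s$hexamer, ebox_class = s$ebox_class,
                     flank_a = s$flank_a, flank_b = s$flank_b,
                     peak_id = s$peak_id,
                     summit_distance = s$summit_distance)
    cen <- motifCentrality(sites, near_halfwidth = config$centrality_near,
                           distal_start = config$centrality_distal[1],
                           distal_end = config$centrality_distal[2])
    tsv(cen, "centrality.tsv")
    tsv(motifsPerPeak(sites, near_halfwidth = config$per_peak_near,
                      distal_threshold = config$per_peak_distal),
        "motifs_per_peak.tsv")
    tsv(flankBias(sites), "flank_bias.tsv")
    tsv(pairSpacing(sites, max_gap = config$max_gap), "spacing.tsv")
    message("grammar: ", sum(cen$near_count), " near-summit sites across ",
            nrow(cen), " classes")
  } else if (stage == "trajectories") {
    cm <- read.table(need(file.path(out_dir, "pseudobulk_counts.tsv")),
                     header = TRUE, sep = "\t", check.names = FALSE)
    meta <- read.table(need(file.path(out_dir, "pseudobulk_samples.tsv")),
                       header = TRUE, sep = "\t")
    counts <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts) <- cm$region
    pb <- PseudobulkMatrix(counts, cell_type = meta$cell_type,
                           kind = "counts")
    norm <- log2CPM(pb)
    calls <- assignTrajectories(norm, threshold = config$anova_threshold)
    tsv(data.frame(region = rownames(calls), calls, row.names = NULL),
        "trajectory_calls.tsv")
    message("trajectories: ", nrow(calls), " regions classified (",
            sum(calls$label == "invariant"), " invariant)")
  } else if (stage == "methylation") {
    trk_a <- readBedGraph(need(file.path(out_dir, "meth_nsc.bedGraph")))
    trk_b <- readBedGraph(need(file.path(out_dir, "meth_pn.bedGraph")))
    s <- read.table(need(file.path(out_dir, "sites.tsv")), header = TRUE,
                    sep = "\t")
    sites <- GRanges(s$contig, IRanges(s$start, width = 6L),
                     ebox_class = s$ebox_class)
    delta <- eboxMethylationDelta(trk_a, trk_b, sites,
                                  halfwidth = config$methylation_halfwidth)
    tsv(delta, "methylation_delta.tsv")
    message("methylation: deltas over ", length(sites), " sites")
  } else if (stage == "selex") {
    files <- Sys.glob(file.path(out_dir, "selex_round*.fa"))
    if (length(files) < 2L) stop("missing input for stage 'selex'")
    manifest <- data.frame(
      round = as.integer(sub(".*round(\\d+)\\.fa$", "\\1", files)),
      path = files)
    rounds <- readSelexRounds(manifest)
    fr <- roundClassFractions(rounds)
    tsv(data.frame(ebox_class = rownames(fr), fr, check.names = FALSE),
        "selex_fractions.tsv")
    tsv(enrichmentTrend(fr), "selex_trend.tsv")
    message("selex: ", nRounds(rounds), " rounds")
  } else if (stage == "conservation") {
    s <- read.table(need(file.path(out_dir, "conservation_sites.tsv")),
                    header = TRUE, sep = "\t")
    sites <- GRanges(s$contig, IRanges(s$start, width = 6L),
                     ebox_class = s$ebox_class,
                     summit_distance = s$summit_distance)
    variants <- read.table(need(file.path(out_dir, "variants.tsv")),
                           header = TRUE, sep = "\t")
    outg <- read.table(need(file.path(out_dir, "outgroup.tsv")),
                       header = TRUE, sep = "\t")
    poly <- countPolymorphisms(sites, variants, maf_min = config$maf_min)
    dv <- countSubstitutions(outg$ref_seq, outg$outgroup_seq)
    rat <- pssNssRatios(s$ebox_class, s$summit_distance, poly,
                        dv$substitutions,
                        pss_halfwidth = config$pss_halfwidth,
                        nss_range = config$nss_range)
    tsv(rat, "pss_nss_ratios.tsv")
    blocks <- read.table(need(file.path(out_dir, "alignment_blocks.tsv")),
                         header = TRUE, sep = "\t")
    tsv(phylostratumTable(blocks, config$clade_scheme), "phylostrata.tsv")
    message("conservation: ", length(sites), " sites, ",
            sum(dv$excluded != "no"), " excluded motifs, ",
            sum(poly), " qualifying polymorphisms")
  }
  invisible(paths)
}
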