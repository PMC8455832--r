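# Stage orchestration: each run_* function wires file inputs through one
# analysis module and writes machine-readable artifacts plus a JSON run
# manifest. The thin command-line wrapper in inst/scripts/sdrkit.R
# dispatches subcommands to these functions.

#' Pipeline configuration
#'
#' Reads a flat per-module YAML configuration and merges it over the
#' package defaults. Unknown keys raise an error.
#'
#' @param path optional YAML file; `NULL` gives the defaults.
#' @param overrides optional named list merged over the file values.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  defaults <- list(
    seed = 1,
    filter = list(min_aln_length = 300, min_identity = 75,
                  min_bitscore = 1000),
    vaf = list(min_depth = 5, k = 2),
    repeats = list(window = 100, fold_threshold = 10, merge_gap = 500,
                   min_locus_len = 1000, low_fold = 3),
    sdr = list(chain_gap = 20000, min_query_fraction = 0.5, flank = 50000,
               max_span = 10000, complete_fraction = 0.9),
    simulate = list(genome_size = 1e6, n_contigs = 20, dup_fraction = 0.45,
                    mismatch_rate = 130, indel_rate = 31,
                    n_y = 5, n_x = 5,
                    n_groups = 3, samples_per_group = 5, n_sites = 300,
                    group_divergence = 0.25, mean_depth = 30,
                    dropout_prob = 0.1,
                    track_length = 50000, background = 30, noise_sd = 3))
  cfg <- defaults
  merge_in <- function(cfg, user, where = "") {
    for (key in names(user)) {
      if (!key %in% names(cfg))
        stopf("unknown config key: %s%s", where, key)
      if (is.list(cfg[[key]]) && is.list(user[[key]])) {
        cfg[[key]] <- merge_in(cfg[[key]], user[[key]],
                               paste0(where, key, "."))
      } else cfg[[key]] <- user[[key]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- merge_in(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(out_dir, stage, params, inputs = character()) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("sdrkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

require_input <- function(path, what) {
  if (!file.exists(path))
    stopf("missing %s: %s", what, path)
  path
}

#' Write a complete synthetic fixture directory
#'
#' Generates a diploid assembly plus self-alignment table, an SDR contig
#' panel with marker hits, a group-structured VAF VCF, and a depth track
#' with one planted high-fold locus; truth tables are written alongside.
#'
#' @param out_dir output directory (created).
#' @param seed RNG seed used for every generator.
#' @param config a [pipeline_config()] (the `simulate` block is used).
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, seed = NULL, config = pipeline_config()) {
  sc <- config$simulate
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  asm <- gen_diploid_assembly(diploid_sim_params(
    genome_size = sc$genome_size, n_contigs = sc$n_contigs,
    dup_fraction = sc$dup_fraction, mismatch_rate = sc$mismatch_rate,
    indel_rate = sc$indel_rate, seed = seed))
  write_fasta(asm$records, file.path(out_dir, "assembly.fasta"))
  write_alignment_table(gen_self_alignment_table(asm$truth),
                        file.path(out_dir, "self_hits.tsv"))
  write.table(asm$truth$pairs, file.path(out_dir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- gen_sdr_panel(n_y = sc$n_y, n_x = sc$n_x, seed = seed + 1)
  write_fasta(panel$records, file.path(out_dir, "sdr_contigs.fasta"))
  write_fasta(panel$markers, file.path(out_dir, "markers.fasta"))
  write_alignment_table(panel$hits, file.path(out_dir, "marker_hits.tsv"))
  write.table(data.frame(contig_id = names(panel$labels),
                         haplotype = unname(panel$labels)),
              file.path(out_dir, "truth_haplotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  vaf <- gen_vaf_vcf(vaf_sim_params(
    n_groups = sc$n_groups, samples_per_group = sc$samples_per_group,
    n_sites = sc$n_sites, group_divergence = sc$group_divergence,
    mean_depth = sc$mean_depth, dropout_prob = sc$dropout_prob,
    seed = seed + 2), path = file.path(out_dir, "panel.vcf"))
  write.table(data.frame(sample = names(vaf$labels),
                         group = unname(vaf$labels)),
              file.path(out_dir, "truth_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  locus <- data.frame(start = round(sc$track_length * 0.4),
                      end = round(sc$track_length * 0.4) + 9269L,
                      fold = 100)
  dt <- gen_depth_track(sc$track_length, background = sc$background,
                        loci = locus, noise_sd = sc$noise_sd,
                        seed = seed + 3)
  write_depth_track(dt$track, file.path(out_dir, "depth.bedgraph"))
  write.table(dt$truth, file.path(out_dir, "truth_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "simulate", c(sc, list(seed = seed)))
  invisible(out_dir)
}

#' Run the self-coverage stage on file inputs
#'
#' @param alignments path to a self-alignment hit table.
#' @param fasta path to the assembly FASTA.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return The [genome_summary()], invisibly.
#' @export
run_selfcov <- function(alignments, fasta, out_dir,
                        config = pipeline_config()) {
  require_input(alignments, "alignment table")
  require_input(fasta, "assembly FASTA")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- do.call(filter_params, config$filter)
  records <- parse_alignment_table(alignments)
  asm <- read_fasta(fasta)
  kept <- filter_alignments(records, fp)
  prof <- multiplicity_profile(kept, stats::setNames(asm$length, asm$id))
  div <- allelic_divergence(kept)
  summ <- genome_summary(prof, div)
  write_genome_summary(summ, out_dir)
  write_manifest(out_dir, "selfcov", config$filter,
                 inputs = c(alignments, fasta))
  invisible(summ)
}

#' Run the SDR haplotyping stage on file inputs
#'
#' @param marker_hits path to a marker-hit alignment table.
#' @param markers path to the marker FASTA (provides query lengths).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return data.frame of SDR haplotype calls, invisibly.
#' @export
run_sdr <- function(marker_hits, markers, out_dir,
                    config = pipeline_config()) {
  require_input(marker_hits, "marker hit table")
  require_input(markers, "marker FASTA")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- config$sdr
  fp <- do.call(filter_params, config$filter)
  hits <- filter_alignments(parse_alignment_table(marker_hits), fp)
  mk <- read_fasta(markers)
  clusters <- cluster_marker_hits(hits, stats::setNames(mk$length, mk$id),
                                  chain_gap = sp$chain_gap)
  sdr_calls <- locate_sdr(clusters, min_query_fraction = sp$min_query_fraction)
  calls <- classify_haplotype(sdr_calls, clusters, flank = sp$flank,
                              contigs = unique(hits$sseqid))
  ir <- find_inverted_repeat(clusters, max_span = sp$max_span)
  msl <- call_msl(clusters, complete_fraction = sp$complete_fraction,
                  contigs = unique(sdr_calls$contig_id))
  write.table(calls, file.path(out_dir, "sdr_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(clusters, file.path(out_dir, "marker_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(msl, file.path(out_dir, "msl_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ok <- stats::complete.cases(calls[, c("start", "end")])
  if (any(ok))
    write_bed(data.frame(seq_id = calls$contig_id[ok],
                         start = calls$start[ok], end = calls$end[ok],
                         name = paste0("SDR_", calls$haplotype_class[ok])),
              file.path(out_dir, "sdr_intervals.bed"))
  jsonlite::write_json(
    list(n_y = sum(calls$haplotype_class == "Y"),
         n_x = sum(calls$haplotype_class == "X"),
         n_unclassified = sum(calls$haplotype_class == "unclassified"),
         inverted_repeats = nrow(ir)),
    file.path(out_dir, "sdr_summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "sdr", sp, inputs = c(marker_hits, markers))
  invisible(calls)
}

#' Run the VAF clustering stage on file inputs
#'
#' @param vcf path to a multi-sample VCF with DP/RO/AO fields.
#' @param out_dir output directory.
#' @param regions optional BED path restricting the analysed sites.
#' @param k number of clusters to cut the dendrogram into.
#' @param config a [pipeline_config()].
#' @return A list with the distance object, tree, embedding and labels,
#'   invisibly.
#' @export
run_vafclust <- function(vcf, out_dir, regions = NULL, k = NULL,
                         config = pipeline_config()) {
  require_input(vcf, "VCF")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vc <- config$vaf
  k <- k %||% vc$k
  reg <- if (!is.null(regions)) read_bed(require_input(regions, "regions BED"))
  parsed <- parse_sample_vcf(vcf, regions = reg)
  vm <- build_vaf_matrix(parsed, vaf_params(min_depth = vc$min_depth))
  d <- pairwise_distance(vm)
  tree <- ward_linkage(d)
  emb <- mds_embed(d, k = 2)
  labels <- cut_tree(tree, k)
  write.table(cbind(sample = rownames(d$D), as.data.frame(d$D)),
              file.path(out_dir, "distances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(tree, file.path(out_dir, "dendrogram.nwk"))
  write.table(data.frame(sample = rownames(emb$points),
                         mds1 = emb$points[, 1], mds2 = emb$points[, 2]),
              file.path(out_dir, "mds_coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(labels), cluster = unname(labels)),
              file.path(out_dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "vafclust", c(vc, list(k = k)), inputs = vcf)
  invisible(list(dist = d, tree = tree, embedding = emb, labels = labels))
}

#' Run the repeat-discovery stage on file inputs
#'
#' @param depth path to a depth track (bedgraph or depth TSV).
#' @param out_dir output directory.
#' @param fasta optional FASTA of the locus sequence for ORF scanning.
#' @param hits optional hit table of locus parts vs an assembly for copy
#'   counting.
#' @param features optional BED of ARR17 features (name column =
#'   `ARR17_gene`/`ARR17_repeat`) for proximity annotation.
#' @param config a [pipeline_config()].
#' @return data.frame of detected loci, invisibly.
#' @export
run_repeats <- function(depth, out_dir, fasta = NULL, hits = NULL,
                        features = NULL, config = pipeline_config()) {
  require_input(depth, "depth track")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rp <- do.call(repeat_scan_params, config$repeats)
  track <- read_depth_track(depth)
  loci <- detect_high_coverage_loci(track, rp)
  if (nrow(loci)) {
    segs <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      s <- segment_locus(track, loci[i, ], rp)
      s$locus <- i
      s
    }))
    write_bed(data.frame(seq_id = track$seq_id, start = segs$start,
                         end = segs$end, name = segs$label),
              file.path(out_dir, "segments.bed"))
  }
  loci_bed <- data.frame(seq_id = loci$seq_id, start = loci$start,
                         end = loci$end,
                         name = rep("repeat_locus", nrow(loci)),
                         score = round(loci$mean_fold, 1))
  write_bed(loci_bed, file.path(out_dir, "loci.bed"))
  if (!is.null(fasta)) {
    locus_fa <- read_fasta(require_input(fasta, "locus FASTA"))
    orfs <- do.call(rbind, lapply(seq_len(nrow(locus_fa)), function(i)
      find_orfs(locus_fa[i, ])))
    write.table(orfs, file.path(out_dir, "orfs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(hits)) {
    h <- parse_alignment_table(require_input(hits, "copy hit table"))
    counts <- do.call(rbind, lapply(split(h, h$qseqid), function(hh)
      data.frame(query = hh$qseqid[1],
                 copies = count_copies(hh, do.call(filter_params,
                                                   config$filter)))))
    write.table(counts, file.path(out_dir, "copy_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(features) && nrow(loci)) {
    fb <- read_bed(require_input(features, "features BED"))
    feats <- data.frame(seq_id = fb$seq_id, start = fb$start, end = fb$end,
                        strand = fb$strand %||% "+", type = fb$name)
    ann <- annotate_proximity(loci, feats)
    write.table(ann, file.path(out_dir, "loci_annotated.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "repeats", unclass(rp), inputs = depth)
  invisible(loci)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulates a fixture directory and runs every analysis stage on it.
#'
#' @param out_dir output directory; the fixture goes to `<out_dir>/fixture`
#'   and each stage to its own subdirectory.
#' @param seed RNG seed.
#' @param config a [pipeline_config()].
#' @return Named list of stage results, invisibly.
#' @export
run_all <- function(out_dir, seed = NULL, config = pipeline_config()) {
  seed <- seed %||% config$seed
  fx <- file.path(out_dir, "fixture")
  run_simulate(fx, seed = seed, config = config)
  res <- list(
    selfcov = run_selfcov(file.path(fx, "self_hits.tsv"),
                          file.path(fx, "assembly.fasta"),
                          file.path(out_dir, "selfcov"), config = config),
    sdr = run_sdr(file.path(fx, "marker_hits.tsv"),
                  file.path(fx, "markers.fasta"),
                  file.path(out_dir, "sdr"), config = config),
    vafclust = run_vafclust(file.path(fx, "panel.vcf"),
                            file.path(out_dir, "vafclust"),
                            k = config$simulate$n_groups, config = config),
    repeats = run_repeats(file.path(fx, "depth.bedgraph"),
                          file.path(out_dir, "repeats"), config = config))
  invisible(res)
}
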