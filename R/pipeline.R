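#' Pipeline configuration
#'
#' A validated list of every tunable the pipeline exposes, serializable
#' to YAML ([write_pipeline_config()] / [read_pipeline_config()] round-trip
#' to identity). Numeric defaults mirror the analysis conventions: 10-bp
#' bins, +/-1 kb composite flanks, 100 body bins for rescaled composites,
#' quintile percentile breaks, 20-bp peak/valley averaging window, 500-bp
#' extremum search and boundary-snapping radii.
#'
#' @param ... overrides of any default field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bin_width = 10L,
    normalize_first = TRUE,         # normalize replicates, then average
    division_pseudocount = 0,
    purified_mode = "ratio",        # sequence_normalize default
    flank_bp = 1000L,
    n_body_bins = 100L,
    percentile_breaks = c(20, 40, 60, 80),
    window_bp = 20,
    search_bp = 500,
    loop_max_dist_bp = 500,
    peak_min_separation_bp = 250,
    seed = 1L,
    ## input paths (optional; used by run_torsion_pipeline)
    with_torsion = character(), without_torsion = character(),
    purified = character(), genome = character(),
    blacklist = character(), genes = character(),
    mrna_plus = character(), mrna_minus = character(),
    classes = character(), loops = character(),
    cohesin = character(),
    out_dir = "torsionmap_out")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$bin_width > 0, "bin_width must be positive")
  chk(cfg$flank_bp %% cfg$bin_width == 0,
      "flank_bp must be a multiple of bin_width")
  chk(cfg$n_body_bins >= 1, "n_body_bins must be >= 1")
  chk(all(diff(cfg$percentile_breaks) > 0) &&
        all(cfg$percentile_breaks > 0 & cfg$percentile_breaks < 100),
      "percentile_breaks must be strictly increasing within (0,100)")
  chk(cfg$window_bp > 0, "window_bp must be positive")
  chk(cfg$purified_mode %in% c("ratio", "difference"),
      "purified_mode must be 'ratio' or 'difference'")
  chk(cfg$division_pseudocount >= 0, "division_pseudocount must be >= 0")
  if (length(problems))
    stop("invalid pipeline config:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] (or by
#'   hand).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ## YAML has no length-0 vector literal: [] comes back as list(); coerce
  ## every field to the type its default has
  defaults <- unclass(pipeline_config())
  for (nm in intersect(names(raw), names(defaults))) {
    raw[[nm]] <- if (is.integer(defaults[[nm]]))
      as.integer(unlist(raw[[nm]]))
    else if (is.numeric(defaults[[nm]])) as.numeric(unlist(raw[[nm]]))
    else if (is.character(defaults[[nm]]))
      as.character(unlist(raw[[nm]]))
    else if (is.logical(defaults[[nm]])) as.logical(unlist(raw[[nm]]))
    else raw[[nm]]
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the torsion pipeline end to end on simulated data
#'
#' Orchestrates the full analysis on an in-memory simulation: torsion
#' signal from the sampled replicates, expression from the mRNA fixtures,
#' expression/size quintile peak-valley statistics, gene-pair
#' configuration composites, promoter-class divergent-pair composites,
#' and loop-score-grouped boundary composites. Writes the tabular outputs
#' (TSV) and the torsion track (bedGraph) under `cfg$out_dir` together
#' with a JSON manifest of parameters and row counts.
#'
#' @param sim a `tmp_simulation` from [simulate_tmp_experiment()].
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the computed objects: `torsion`,
#'   `genes`, `pairs`, `peak_stats` (expression groups), `valley_stats`
#'   (size groups), `pair_profiles`, `class_profiles`, `loop_groups`,
#'   `loop_profiles`, `manifest_path`.
#' @export
run_torsion_pipeline <- function(sim, cfg = pipeline_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  torsion <- compute_torsion(sim$tracks$with, sim$tracks$without,
                             normalize_first = cfg$normalize_first)
  write_bedgraph(torsion, file.path(cfg$out_dir, "torsion.bedGraph"))
  genes <- expression_from_mrna(sim$fixtures$mrna_plus,
                                sim$fixtures$mrna_minus, sim$truth$genes)
  expr_groups <- percentile_groups(genes$expression, cfg$percentile_breaks)
  size_groups <- percentile_groups(genes$size, cfg$percentile_breaks)
  peak_stats <- peak_valley_stats(torsion, genes, expr_groups,
                                  anchor = "tss_peak",
                                  window_bp = cfg$window_bp,
                                  search_bp = cfg$search_bp,
                                  flank_bp = cfg$flank_bp)
  valley_stats <- peak_valley_stats(torsion, genes, size_groups,
                                    anchor = "tes_valley",
                                    window_bp = cfg$window_bp,
                                    search_bp = cfg$search_bp,
                                    flank_bp = cfg$flank_bp)
  write_peak_valley(rbind(peak_stats, valley_stats),
                    file.path(cfg$out_dir, "peak_valley.tsv"))
  ## gene-pair configuration composites over the purified intergenic gaps
  ann <- interval_set(genes$chrom, genes$start, genes$end,
                      name = genes$name, strand = genes$strand)
  pairs <- classify_gene_pairs(genes, ann)
  write_gene_pairs(pairs, file.path(cfg$out_dir, "gene_pairs.tsv"))
  pair_profiles <- list()
  for (config in c("divergent", "convergent", "codirectional")) {
    sel <- pairs[pairs$configuration == config & pairs$purified &
                   pairs$gap_end - pairs$gap_start >=
                     torsion$index$bin_width, , drop = FALSE]
    if (!nrow(sel)) next
    regions <- data.frame(chrom = sel$chrom, start = sel$gap_start,
                          end = sel$gap_end, strand = NA_character_,
                          name = paste(sel$left_name, sel$right_name,
                                       sep = "|"),
                          stringsAsFactors = FALSE)
    mat <- scaled_region_matrix(torsion, regions, cfg$flank_bp,
                                cfg$n_body_bins)
    prof <- composite_profile(mat)
    write_profile(prof, file.path(cfg$out_dir,
                                  sprintf("pairs_%s_profile.tsv", config)))
    pair_profiles[[config]] <- prof
  }
  ## promoter-class insulation composites (divergent pairs, class-pure)
  class_profiles <- list()
  div <- pairs[pairs$configuration == "divergent" & pairs$purified &
                 pairs$gap_end - pairs$gap_start >=
                   torsion$index$bin_width, , drop = FALSE]
  for (cl in c("UNB", "TFO", "STM")) {
    sel <- filter_pairs_by_class(div, genes, cl)
    if (!nrow(sel)) next
    regions <- data.frame(chrom = sel$chrom, start = sel$gap_start,
                          end = sel$gap_end, strand = NA_character_,
                          name = paste(sel$left_name, sel$right_name,
                                       sep = "|"),
                          stringsAsFactors = FALSE)
    mat <- scaled_region_matrix(torsion, regions, cfg$flank_bp,
                                cfg$n_body_bins)
    prof <- composite_profile(mat)
    write_profile(prof, file.path(cfg$out_dir,
                                  sprintf("divergent_%s_profile.tsv", cl)))
    class_profiles[[cl]] <- prof
  }
  ## loop-score-grouped boundary-to-boundary composites
  loops <- refine_nested_loops(sim$fixtures$loops)
  loop_groups <- if (nrow(loops))
    loop_score_percentile_groups(loops, cfg$percentile_breaks) else integer()
  loop_profiles <- list()
  for (g in sort(unique(loop_groups))) {
    sel <- loops[loop_groups == g, , drop = FALSE]
    mat <- loop_composites(torsion, sel, cfg$flank_bp, cfg$n_body_bins)
    prof <- composite_profile(mat)
    write_profile(prof, file.path(cfg$out_dir,
                                  sprintf("loops_group%d_profile.tsv", g)))
    loop_profiles[[as.character(g)]] <- prof
  }
  manifest <- list(
    config = unclass(cfg), seed = sim$seed,
    n_genes = nrow(genes), n_pairs = nrow(pairs),
    n_pairs_purified = sum(pairs$purified),
    n_loops = nrow(loops),
    provenance = attr(torsion, "provenance"))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(torsion = torsion, genes = genes, pairs = pairs,
                 peak_stats = peak_stats, valley_stats = valley_stats,
                 pair_profiles = pair_profiles,
                 class_profiles = class_profiles,
                 loop_groups = loop_groups, loop_profiles = loop_profiles,
                 manifest_path = manifest_path))
}

#' Count well-separated signal regions in a profile
#'
#' Counts contiguous runs of positions whose value exceeds
#' `frac * max(value)` -- a plain way to distinguish one merged signal
#' plateau (one run) from two separated peaks (two runs), as in the
#' comparison of insulated versus unbound divergent promoter pairs.
#'
#' @param values numeric profile (NAs ignored).
#' @param frac threshold as a fraction of the profile maximum.
#' @return Integer number of above-threshold runs.
#' @export
count_signal_regions <- function(values, frac = 0.5) {
  v <- values[!is.na(values)]
  if (!length(v) || max(v) <= 0) return(0L)
  above <- v > frac * max(v)
  sum(diff(c(FALSE, above)) == 1L)
}
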