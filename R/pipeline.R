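# End-to-end orchestration: declarative config, per-stage outputs and
# manifests, deterministic given one seed. Stages are idempotent and
# individually invocable; `inst/exec/panel-pipeline` is a thin command-line
# wrapper over these functions.

.pipeline_defaults <- function() list(
  out_dir = "pipeline_out",
  seed = 1,
  window_size = 1e4,          # het-count / F_ST / sharing windows
  pi_window_size = 5e5,       # nucleotide-diversity windows
  fst_min_snps = 50,
  fd_min_snps = 250,
  maf = 0.10,
  ld_max_dist = 1e4,
  ld_bin = 100,
  het_threshold = 5,
  hmm_K = 2, hmm_tol = 1e-6, hmm_max_iter = 500,
  sex_chrom = "chr1", sex_K = 4, sex_min_level = 0.8, sex_min_span = 3e5,
  identity_floor = 0.99,
  fd_window = 5e5, fd_step = 2.5e5,
  simulate = list(n_founder_pairs = 8, lines_per_family = 2, generations = 9,
                  target_pi = 0.0037, outcross_prob = 0.05,
                  genotype_error_rate = 0.001, n_chrom = 6,
                  chrom_length = 1e6, recomb_rate = 3,
                  sex_start = 450000, sex_end = 550000,
                  admixture_f = 0.3, admix_chrom_length = 2e6,
                  admix_n_chrom = 2, n_per_pop = 8)
)

#' Build (and validate) a pipeline configuration
#'
#' @param config `NULL` (all defaults), a named list overriding defaults, or
#'   the path of a YAML file with such a list. Nested `simulate` entries are
#'   merged element-wise.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  cfg <- .pipeline_defaults()
  for (nm in names(config)) {
    if (nm == "simulate" && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) cfg$simulate[[k]] <- config[[nm]][[k]]
    } else cfg[[nm]] <- config[[nm]]
  }
  with(cfg, stopifnot(window_size > 0, pi_window_size > 0, fst_min_snps >= 0,
                      fd_min_snps >= 0, maf >= 0, maf <= 0.5, ld_max_dist > 0,
                      ld_bin > 0, het_threshold >= 0, hmm_K >= 2,
                      hmm_tol > 0, sex_K >= 2, identity_floor > 0,
                      identity_floor <= 1, fd_window > 0, fd_step > 0))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

.write_manifest <- function(cfg, stage, params, inputs, outputs) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("inbredpanel")),
              seed = cfg$seed, parameters = params, inputs = inputs,
              outputs = lapply(outputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(man, file.path(.stage_dir(cfg, stage), "manifest.yaml"))
}

.panel_paths <- function(cfg) {
  d <- file.path(cfg$out_dir, "simulate")
  list(vcf = file.path(d, "panel.vcf"),
       sibling = file.path(d, "sibling_pairs.tsv"),
       groups = file.path(d, "groups.tsv"),
       phenotypes = file.path(d, "phenotypes.tsv"),
       admix_vcf = file.path(d, "admixed.vcf"),
       admix_pops = file.path(d, "admixed_pops.tsv"),
       admix_anc = file.path(d, "admixed_ancestral.tsv"))
}

.read_panel <- function(cfg) {
  p <- .panel_paths(cfg)
  if (!file.exists(p$vcf)) stop("panel VCF not found at ", p$vcf,
                                "; run the 'simulate' stage or point the ",
                                "config at an existing VCF")
  read_vcf(p$vcf)
}

.stage_simulate <- function(cfg) {
  d <- .stage_dir(cfg, "simulate")
  s <- cfg$simulate
  spec <- genome_spec(n_chrom = s$n_chrom, chrom_length = s$chrom_length,
                      recomb_rate = s$recomb_rate,
                      sex_region = list(chrom = cfg$sex_chrom,
                                        start = s$sex_start, end = s$sex_end))
  scfg <- sim_config(n_founder_pairs = s$n_founder_pairs,
                     lines_per_family = s$lines_per_family,
                     generations = s$generations, target_pi = s$target_pi,
                     outcross_prob = s$outcross_prob,
                     genotype_error_rate = s$genotype_error_rate,
                     seed = cfg$seed)
  panel <- simulate_panel(spec, scfg)
  write_sim_panel(panel, d)
  # alternating two-group split of a single panmictic panel (F_ST null)
  ids <- panel$gm$sample_ids
  write_tsv_table(data.frame(sample = ids,
                             group = rep(c("g1", "g2"), length.out = length(ids))),
                  file.path(d, "groups.tsv"))
  write_tsv_table(simulate_line_trait(ids, seed = cfg$seed + 1),
                  file.path(d, "phenotypes.tsv"))
  adm <- simulate_admixed_populations(
    stats::setNames(rep(s$admix_chrom_length, s$admix_n_chrom),
                    paste0("achr", seq_len(s$admix_n_chrom))),
    f = s$admixture_f, n_per_pop = s$n_per_pop, target_pi = s$target_pi,
    seed = cfg$seed + 2)
  write_vcf(adm$gm, file.path(d, "admixed.vcf"))
  write_tsv_table(data.frame(sample = unlist(adm$pops),
                             pop = rep(names(adm$pops), lengths(adm$pops))),
                  file.path(d, "admixed_pops.tsv"))
  write_tsv_table(adm$ancestral, file.path(d, "admixed_ancestral.tsv"))
  write_tsv_table(adm$truth_blocks, file.path(d, "admixed_truth_blocks.tsv"))
  outs <- list.files(d, full.names = TRUE)
  .write_manifest(cfg, "simulate", s, character(), as.list(outs))
  invisible(d)
}

.stage_hmm_call <- function(cfg) {
  d <- .stage_dir(cfg, "hmm-call")
  gm <- .read_panel(cfg)
  grid <- window_grid(chrom_lengths(gm, cfg$window_size), cfg$window_size)
  wc <- window_het_counts(gm, grid)
  fit <- fit_poisson_hmm(wc, K = cfg$hmm_K, tol = cfg$hmm_tol,
                         max_iter = cfg$hmm_max_iter, seed = cfg$seed)
  paths <- viterbi_decode(fit, wc)
  blocks <- states_to_blocks(paths)
  write_blocks_bed(blocks, file.path(d, "blocks.bed"))
  write_hmm_params(fit, file.path(d, "hmm_params.txt"))
  hf <- homozygous_fraction(blocks, exclude_chroms = cfg$sex_chrom)
  write_tsv_table(data.frame(line = names(hf), homozygous_fraction = hf),
                  file.path(d, "homozygous_fraction.tsv"))
  write_window_counts(wc, file.path(d, "window_het_counts.tsv"))
  .write_manifest(cfg, "hmm-call",
                  cfg[c("window_size", "hmm_K", "hmm_tol", "sex_chrom")],
                  list(.panel_paths(cfg)$vcf),
                  as.list(file.path(d, c("blocks.bed", "hmm_params.txt",
                                         "homozygous_fraction.tsv",
                                         "window_het_counts.tsv"))))
  invisible(d)
}

.stage_sex_region <- function(cfg) {
  d <- .stage_dir(cfg, "sex-region")
  gm <- .read_panel(cfg)
  grid <- window_grid(chrom_lengths(gm, cfg$window_size), cfg$window_size)
  wc <- window_het_counts(gm, grid)
  fit <- fit_poisson_hmm(wc, K = cfg$sex_K, tol = cfg$hmm_tol,
                         max_iter = cfg$hmm_max_iter, seed = cfg$seed)
  paths <- viterbi_decode(fit, wc)
  track <- het_proportion_track(wc, paths, fit, cfg$sex_chrom,
                                threshold = cfg$het_threshold)
  write_het_track(track, file.path(d, "het_track.tsv"))
  region <- refine_obligate_het_region(track, cfg$sex_min_level,
                                       cfg$sex_min_span)
  write_tsv_table(region, file.path(d, "obligate_het_region.tsv"))
  .write_manifest(cfg, "sex-region",
                  cfg[c("sex_K", "sex_chrom", "het_threshold",
                        "sex_min_level", "sex_min_span")],
                  list(.panel_paths(cfg)$vcf),
                  as.list(file.path(d, c("het_track.tsv",
                                         "obligate_het_region.tsv"))))
  invisible(d)
}

.stage_fst <- function(cfg) {
  d <- .stage_dir(cfg, "fst")
  gm <- .read_panel(cfg)
  gr <- read_tsv_table(.panel_paths(cfg)$groups)
  pops <- split(gr$sample, gr$group)
  if (length(pops) != 2) stop("F_ST stage needs exactly two groups")
  grid <- window_grid(chrom_lengths(gm, cfg$window_size), cfg$window_size)
  fst <- windowed_fst(gm, grid, pops[[1]], pops[[2]],
                      min_snps = cfg$fst_min_snps)
  write_window_stat(fst, file.path(d, "fst_windows.tsv"))
  .write_manifest(cfg, "fst", cfg[c("window_size", "fst_min_snps")],
                  list(.panel_paths(cfg)$vcf),
                  list(file.path(d, "fst_windows.tsv")))
  invisible(d)
}

.stage_pi <- function(cfg) {
  d <- .stage_dir(cfg, "pi")
  gm <- .read_panel(cfg)
  grid <- window_grid(chrom_lengths(gm, cfg$pi_window_size),
                      cfg$pi_window_size)
  pi_ <- nucleotide_diversity(gm, grid)
  write_window_stat(pi_, file.path(d, "pi_windows.tsv"))
  .write_manifest(cfg, "pi", cfg["pi_window_size"],
                  list(.panel_paths(cfg)$vcf),
                  list(file.path(d, "pi_windows.tsv")))
  invisible(d)
}

.stage_ld <- function(cfg) {
  d <- .stage_dir(cfg, "ld")
  gm <- .read_panel(cfg)
  gm <- filter_variants(gm, min_maf = cfg$maf)
  sex <- cfg$sex_chrom
  gm <- subset_geno(gm, variants = which(gm$variants$chrom != sex))
  pairs <- ld_pairs_r2(gm, max_dist = cfg$ld_max_dist)
  prof <- ld_decay_profile(pairs, bin_width = cfg$ld_bin,
                           max_dist = cfg$ld_max_dist)
  write_tsv_table(prof, file.path(d, "ld_decay.tsv"))
  .write_manifest(cfg, "ld", cfg[c("maf", "ld_max_dist", "ld_bin")],
                  list(.panel_paths(cfg)$vcf),
                  list(file.path(d, "ld_decay.tsv")))
  invisible(d)
}

.stage_introgression <- function(cfg) {
  d <- .stage_dir(cfg, "introgression")
  p <- .panel_paths(cfg)
  gm <- read_vcf(p$admix_vcf)
  pops_df <- read_tsv_table(p$admix_pops)
  pops <- split(pops_df$sample, pops_df$pop)
  anc <- read_tsv_table(p$admix_anc)
  freqs <- polarize(gm, pops, anc)
  scan <- sliding_fd_scan(freqs, chrom_lengths(gm), window = cfg$fd_window,
                          step = cfg$fd_step, min_snps = cfg$fd_min_snps)
  write_tsv_table(as.data.frame(scan), file.path(d, "fd_windows.tsv"))
  write_tsv_table(data.frame(mean_fd = genome_fd_mean(scan)),
                  file.path(d, "fd_genome_mean.tsv"))
  .write_manifest(cfg, "introgression",
                  cfg[c("fd_window", "fd_step", "fd_min_snps")],
                  list(p$admix_vcf, p$admix_pops, p$admix_anc),
                  as.list(file.path(d, c("fd_windows.tsv",
                                         "fd_genome_mean.tsv"))))
  invisible(d)
}

.stage_relatedness <- function(cfg) {
  d <- .stage_dir(cfg, "relatedness")
  gm <- .read_panel(cfg)
  ibs <- ibs_matrix(gm)
  write_ibs_matrix(ibs, file.path(d, "ibs_matrix.tsv"))
  cl <- cluster_and_order(ibs)
  write_newick(cl, file.path(d, "ibs_dendrogram.nwk"))
  outs <- c("ibs_matrix.tsv", "ibs_dendrogram.nwk")
  sibf <- .panel_paths(cfg)$sibling
  if (file.exists(sibf)) {
    sib <- read_tsv_table(sibf)
    adj <- sibling_adjacency_fraction(cl$order, sib)
    grid <- window_grid(chrom_lengths(gm, cfg$window_size), cfg$window_size)
    sharing <- vapply(seq_len(nrow(sib)), function(i)
      pairwise_sharing_fraction(gm, sib$line_a[i], sib$line_b[i], grid,
                                identity_floor = cfg$identity_floor),
      numeric(1))
    write_tsv_table(cbind(sib, sharing_fraction = sharing),
                    file.path(d, "sibling_sharing.tsv"))
    write_tsv_table(data.frame(adjacency_fraction = adj,
                               n_pairs = nrow(sib)),
                    file.path(d, "sibling_adjacency.tsv"))
    outs <- c(outs, "sibling_sharing.tsv", "sibling_adjacency.tsv")
  }
  .write_manifest(cfg, "relatedness", cfg[c("window_size", "identity_floor")],
                  list(.panel_paths(cfg)$vcf),
                  as.list(file.path(d, outs)))
  invisible(d)
}

.stage_heritability <- function(cfg) {
  d <- .stage_dir(cfg, "heritability")
  ph <- read_tsv_table(.panel_paths(cfg)$phenotypes)
  eta2 <- eta_squared_heritability(ph$value, ph$line)
  write_tsv_table(data.frame(trait = "value", eta_squared = eta2,
                             n_lines = length(unique(ph$line)),
                             n_individuals = nrow(ph)),
                  file.path(d, "heritability.tsv"))
  .write_manifest(cfg, "heritability", list(),
                  list(.panel_paths(cfg)$phenotypes),
                  list(file.path(d, "heritability.tsv")))
  invisible(d)
}

.stage_report <- function(cfg) {
  d <- .stage_dir(cfg, "report")
  grab <- function(stage, file) {
    f <- file.path(cfg$out_dir, stage, file)
    if (file.exists(f)) read_tsv_table(f) else NULL
  }
  rows <- list()
  hf <- grab("hmm-call", "homozygous_fraction.tsv")
  if (!is.null(hf)) rows$homozygous <- data.frame(
    metric = c("mean_homozygous_fraction", "frac_lines_above_0.70"),
    value = c(mean(hf$homozygous_fraction),
              mean(hf$homozygous_fraction > 0.70)))
  sx <- grab("sex-region", "obligate_het_region.tsv")
  if (!is.null(sx) && nrow(sx)) rows$sex <- data.frame(
    metric = c("sex_region_start", "sex_region_end"),
    value = c(sx$start[1], sx$end[1]))
  fst <- grab("fst", "fst_windows.tsv")
  if (!is.null(fst)) rows$fst <- data.frame(
    metric = "mean_window_fst", value = mean(fst$value, na.rm = TRUE))
  pi_ <- grab("pi", "pi_windows.tsv")
  if (!is.null(pi_)) rows$pi <- data.frame(
    metric = "mean_window_pi", value = mean(pi_$value, na.rm = TRUE))
  fd <- grab("introgression", "fd_genome_mean.tsv")
  if (!is.null(fd)) rows$fd <- data.frame(metric = "mean_fd",
                                          value = fd$mean_fd[1])
  adj <- grab("relatedness", "sibling_adjacency.tsv")
  if (!is.null(adj)) rows$adj <- data.frame(
    metric = "sibling_adjacency_fraction", value = adj$adjacency_fraction[1])
  sh <- grab("relatedness", "sibling_sharing.tsv")
  if (!is.null(sh)) rows$sh <- data.frame(
    metric = "mean_sibling_sharing", value = mean(sh$sharing_fraction,
                                                  na.rm = TRUE))
  h2 <- grab("heritability", "heritability.tsv")
  if (!is.null(h2)) rows$h2 <- data.frame(metric = "eta_squared",
                                          value = h2$eta_squared[1])
  summary_df <- do.call(rbind, rows)
  write_tsv_table(summary_df, file.path(d, "summary.tsv"))
  .write_manifest(cfg, "report", list(), list(cfg$out_dir),
                  list(file.path(d, "summary.tsv")))
  invisible(d)
}

.stage_registry <- function() list(
  "simulate" = .stage_simulate,
  "hmm-call" = .stage_hmm_call,
  "sex-region" = .stage_sex_region,
  "fst" = .stage_fst,
  "pi" = .stage_pi,
  "ld" = .stage_ld,
  "introgression" = .stage_introgression,
  "relatedness" = .stage_relatedness,
  "heritability" = .stage_heritability,
  "report" = .stage_report)

#' Run one pipeline stage
#'
#' @param stage stage name; one of simulate, hmm-call, sex-region, fst, pi,
#'   ld, introgression, relatedness, heritability, report.
#' @param config see [pipeline_config()].
#' @return the stage output directory, invisibly. Each stage writes a
#'   `manifest.yaml` recording parameters, inputs, seed, package version and
#'   output checksums.
#' @export
run_stage <- function(stage, config = NULL) {
  reg <- .stage_registry()
  if (!stage %in% names(reg))
    stop("unknown stage '", stage, "'; available stages: ",
         paste(names(reg), collapse = ", "))
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  reg[[stage]](cfg)
}

#' Run the full pipeline (or a subset of stages, in order)
#'
#' @param config see [pipeline_config()].
#' @param stages stage names; defaults to all, in dependency order.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config = NULL, stages = names(.stage_registry())) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  for (s in stages) run_stage(s, cfg)
  invisible(cfg$out_dir)
}
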