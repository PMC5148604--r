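# End-to-end orchestration: normalize -> traits -> screen -> top hits ->
# enrichment -> phylogram, from a single configuration list or YAML file.

#' Run the full screening pipeline
#'
#' Reads a features-by-samples matrix (TSV), a species trait table (CSV, as
#' for [read_trait_csv()]), a rooted newick tree and optional GMT
#' annotations; averages replicates, screens every feature against the
#' configured traits with the two-step procedure, calls multi-trait top
#' hits, runs hypergeometric enrichment when annotations are supplied, and
#' builds a bootstrap phylogram.  All outputs are written as plain text
#' under `out_dir` together with a JSON manifest recording the package
#' version, configuration hash, seed and per-stage row counts.
#'
#' @param config Path to a YAML file or a named list with entries:
#'   `matrix`, `traits`, `tree` (paths; required), `sample_map` (optional
#'   two-column TSV sample/species), `annotations` (optional GMT path),
#'   `trait_cols` (default `AW, ML, FTM, MLres, FTMres`), `p_robust_cut`
#'   (0.01), `p_max_cut` (0.05), `min_traits` (2), `n_boot` (100), `seed`
#'   (1), `out_dir` (required).
#' @return Invisibly, a list with `records`, `top_hits`, `enrichment`,
#'   `phylogram` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(trait_cols = c("AW", "ML", "FTM", "MLres", "FTMres"),
                   p_robust_cut = 0.01, p_max_cut = 0.05, min_traits = 2,
                   n_boot = 100L, seed = 1L)
  config <- modifyList(defaults, config)
  for (f in c("matrix", "traits", "tree")) {
    if (is.null(config[[f]])) stop("config entry missing: ", f, call. = FALSE)
    if (!file.exists(config[[f]])) {
      stop("config file not found: ", f, " = ", config[[f]], call. = FALSE)
    }
  }
  if (is.null(config$out_dir)) stop("config entry missing: out_dir", call. = FALSE)
  stopifnot(config$p_robust_cut > 0, config$p_robust_cut <= 1,
            config$p_max_cut > 0, config$p_max_cut <= 1)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  tree <- parse_newick(file = config$tree)
  traits <- read_trait_csv(config$traits, tree = tree)
  vals <- as.matrix(read.delim(config$matrix, row.names = 1, check.names = FALSE))
  species_map <- NULL
  if (!is.null(config$sample_map)) {
    sm <- read.delim(config$sample_map, header = TRUE,
                     stringsAsFactors = FALSE)
    species_map <- setNames(sm[[2]], sm[[1]])
  }
  mat <- omics_matrix(vals, species = species_map, provenance = "loaded")
  if (!is.null(mat$species) &&
      !identical(colnames(as.matrix(mat)), unname(mat$species))) {
    mat <- average_replicates(mat)
  }

  records <- screen_features(mat, traits, tree, trait_cols = config$trait_cols)
  write.table(records, file.path(config$out_dir, "records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  top <- call_top_hits(records, config$p_robust_cut, config$p_max_cut,
                       config$min_traits)
  write.table(top, file.path(config$out_dir, "top_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  enrich <- NULL
  if (!is.null(config$annotations)) {
    ann <- read_gmt(config$annotations)
    universe <- rownames(as.matrix(mat))
    hits <- intersect(top$feature, universe)
    enrich <- hypergeom_enrich(hits, ann, universe)
    write.table(enrich, file.path(config$out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  phylogram <- bootstrap_support(standardize_features(mat),
                                 n_boot = config$n_boot, seed = config$seed)
  ape::write.tree(phylogram, file.path(config$out_dir, "phylogram.nwk"))

  cfg_txt <- paste(deparse(config[order(names(config))]), collapse = "")
  tf <- tempfile(); writeLines(cfg_txt, tf)
  manifest <- list(
    package = "longscreen",
    version = as.character(utils::packageVersion("longscreen")),
    config = config,
    config_md5 = unname(tools::md5sum(tf)),
    seed = config$seed,
    rows = list(features = nrow(as.matrix(mat)),
                species = ncol(as.matrix(mat)),
                records = nrow(records),
                top_hits = nrow(top),
                enriched_sets = if (is.null(enrich)) 0L else nrow(enrich))
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(records = records, top_hits = top, enrichment = enrich,
                 phylogram = phylogram, manifest = manifest))
}

#' Write a bundled synthetic demo dataset and configuration
#'
#' Generates a tree, traits and an expression matrix with planted trait
#' associations, writes them as newick/CSV/TSV under `dir`, and returns a
#' configuration list ready for [run_pipeline()] along with the truth
#' table used to score recall.
#'
#' @param dir Output directory.
#' @param seed RNG seed driving every generator.
#' @param n_species,n_genes,frac_associated,slope_mean Passed to the
#'   generators; defaults give a small screen that runs in well under a
#'   minute.
#' @return List with `config` (a [run_pipeline()] configuration) and
#'   `truth` (data frame of true slopes).
#' @export
write_demo_inputs <- function(dir, seed = 1L, n_species = 15L, n_genes = 200L,
                              frac_associated = 0.1, slope_mean = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- gen_tree(n_species, seed = seed)
  traits <- gen_traits(tree, seed = seed + 1L)
  cfg <- sim_config(n_species = n_species, n_genes = n_genes,
                    frac_associated = frac_associated,
                    slope_mean = slope_mean, slope_sd = 0,
                    evo_model = "brownian", evo_params = list(sigma2 = 0.1),
                    replicate_noise_sd = 0.05, seed = seed + 2L)
  sim <- gen_expression(tree, setNames(traits$ML, traits$species), cfg,
                        n_replicates = 2L)
  write_newick(tree, file = file.path(dir, "tree.nwk"))
  write.csv(data.frame(species = traits$species, AW_g = traits$AW,
                       ML_yr = traits$ML, FTM_d = traits$FTM),
            file.path(dir, "traits.csv"), row.names = FALSE)
  m <- as.matrix(sim$matrix)
  write.table(data.frame(feature = rownames(m), m, check.names = FALSE),
              file.path(dir, "matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(sim$matrix$species),
                         species = unname(sim$matrix$species)),
              file.path(dir, "sample_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  config <- list(matrix = file.path(dir, "matrix.tsv"),
                 traits = file.path(dir, "traits.csv"),
                 tree = file.path(dir, "tree.nwk"),
                 sample_map = file.path(dir, "sample_map.tsv"),
                 out_dir = file.path(dir, "out"),
                 seed = seed)
  list(config = config, truth = sim$truth)
}
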