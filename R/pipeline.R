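# End-to-end synthetic demonstration run: simulate a wild-type and an
# SH3-deleted screen, score and classify the interactions, compare a
# coupled profile/sequence pair of dendrograms, and write every output
# with a manifest of parameters and content hashes.

#' Run the synthetic demonstration pipeline
#'
#' Executes simulate -> plate-score -> classify -> tree-comparison on
#' synthetic data and writes TSV/JSON outputs plus a \code{manifest.json}
#' recording the parameters, the seed and the MD5 hash of every output
#' file. Identical configuration and seed yield byte-identical outputs.
#' All parameters are validated before any file is written.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @param n_baits,n_preys Screen dimensions.
#' @param cfg Optional [sim_config()] (defaults to one seeded from
#'   \code{seed}).
#' @param top_quantile Interaction-call quantile (default 0.073).
#' @param ratio_quantile Dependency-ratio quantile (default 0.073).
#' @param n_domains,n_profile_preys,coupling Tree-comparison demo
#'   parameters.
#' @param n_perm Permutations for the cophenetic test.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_baits = 4L, n_preys = 60L,
                         cfg = NULL, top_quantile = 0.073,
                         ratio_quantile = 0.073, n_domains = 12L,
                         n_profile_preys = 20L, coupling = 0.8,
                         n_perm = 1000L) {
  # validate everything up front: fail before any output is written
  stopifnot(top_quantile > 0, top_quantile < 1,
            ratio_quantile > 0, ratio_quantile < 0.5,
            n_baits >= 1L, n_preys >= 2L, n_domains >= 3L,
            coupling >= 0, coupling <= 1, n_perm >= 1L)
  if (is.null(cfg)) cfg <- sim_config(seed = derive_seed(seed, "screen"))
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  baits <- sprintf("bait%02d", seq_len(n_baits))
  preys <- sprintf("prey%03d", seq_len(n_preys))

  # wild-type screen with planted interactions
  wt <- gen_plate_screen(cfg, baits, preys)
  # deletion screen: planted pairs lose their interaction effect
  cfg_mut <- cfg
  cfg_mut$seed <- derive_seed(seed, "mutant")
  mut <- gen_plate_screen(cfg_mut, baits, preys,
                          planted = data.frame(bait = character(),
                                               prey = character(),
                                               effect = numeric()))

  score_screen <- function(res) {
    plates <- split(res$screen, res$screen$plate_id)
    dips <- split(res$diploid, res$diploid$plate_id)
    normed <- lapply(plates, normalize_plate)
    collect_ppi_scores(normed, dips)
  }
  wt_scores <- score_screen(wt)
  mut_scores <- score_screen(mut)
  wt_calls <- detect_interactions(wt_scores, top_quantile)
  mut_calls <- detect_interactions(mut_scores, top_quantile)
  k <- function(d) paste(d$bait, d$prey, sep = "\r")
  common <- intersect(k(wt_scores), k(mut_scores))
  ratios <- data.frame(
    bait = wt_scores$bait[match(common, k(wt_scores))],
    prey = wt_scores$prey[match(common, k(wt_scores))],
    ratio = score_ratio(mut_scores$pca_score[match(common, k(mut_scores))],
                        wt_scores$pca_score[match(common, k(wt_scores))]),
    stringsAsFactors = FALSE)
  classes <- classify_ppis(wt_calls, mut_calls, ratios, ratio_quantile)

  # dendrogram comparison on a coupled profile/sequence set
  prof <- gen_coupled_profiles(n_domains, n_profile_preys, coupling,
                               seed = derive_seed(seed, "profiles"))
  tree_cmp <- cophenetic_permutation_test(prof$profiles, prof$alignment,
                                          n_perm = n_perm,
                                          seed = derive_seed(seed, "perm"))

  drop_list_cols <- function(d) d[, !vapply(d, is.list, logical(1L))]
  outputs <- list(
    "screen_plates.tsv" = wt$screen,
    "ppi_scores_wt.tsv" = drop_list_cols(wt_scores),
    "ppi_scores_mut.tsv" = drop_list_cols(mut_scores),
    "calls_wt.tsv" = wt_calls,
    "dependency_classes.tsv" = classes)
  for (nm in names(outputs)) {
    write_plate_tsv(outputs[[nm]], file.path(out_dir, nm))
  }
  jsonlite::write_json(
    list(r = tree_cmp$r, p = tree_cmp$p, n_perm = tree_cmp$n_perm,
         seed = tree_cmp$seed),
    file.path(out_dir, "tree_comparison.json"),
    auto_unbox = TRUE, digits = NA)

  files <- c(names(outputs), "tree_comparison.json")
  manifest <- list(
    seed = seed,
    parameters = list(n_baits = n_baits, n_preys = n_preys,
                      top_quantile = top_quantile,
                      ratio_quantile = ratio_quantile,
                      effect_log2 = cfg$effect_log2,
                      noise_sd = cfg$noise_sd,
                      frac_positive = cfg$frac_positive,
                      n_domains = n_domains, coupling = coupling,
                      n_perm = n_perm),
    outputs = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
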