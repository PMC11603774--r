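#' Pipeline configuration with field-standard defaults
#'
#' All stage parameters in one validated list. Defaults are the workflow's
#' stated operating points: 70% detection-frequency cutoff, 10,000 noise
#' floor, 1.00782 Da neutralization mass, 5 ppm / 0.5 min cross-polarity
#' merge tolerances, 0.1 min / 2 ppm annotation transfer tolerances,
#' 0.05 min / 5 ppm Level-1 confirmation, match score 90 for Level 2,
#' p < 0.05 and |log2 FC| > 1.2 volcano cutoffs, |R| > 0.5 network edges.
#'
#' @param freq_cutoff detection-frequency cutoff.
#' @param noise_floor minimum real-signal area; also used as the MDL for
#'   truncated imputation.
#' @param blank_ratio blank-to-sample mean ratio for blank filtering.
#' @param merge_ppm,merge_rt cross-polarity merge tolerances.
#' @param transfer_ppm,transfer_rt annotation-to-MS1 transfer tolerances.
#' @param level1_rt,level1_ppm Level-1 confirmation thresholds.
#' @param score_l2,score_l3 match-score thresholds for Levels 2 and 3.
#' @param p_cut,fc_cut volcano thresholds.
#' @param r_threshold network edge threshold on |Pearson R|.
#' @param creatinine_strategy `"median-ratio"` or `"divide"`.
#' @param seed top-level seed; every stage's randomness derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(freq_cutoff = 0.70, noise_floor = 1e4,
                            blank_ratio = 1 / 3,
                            merge_ppm = 5, merge_rt = 0.5,
                            transfer_ppm = 2, transfer_rt = 0.1,
                            level1_rt = 0.05, level1_ppm = 5,
                            score_l2 = 90, score_l3 = 50,
                            p_cut = 0.05, fc_cut = 1.2,
                            r_threshold = 0.5,
                            creatinine_strategy = "median-ratio",
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  stopifnot(cfg$freq_cutoff > 0, cfg$freq_cutoff <= 1,
            cfg$merge_ppm > 0, cfg$merge_rt > 0, cfg$r_threshold >= 0)
  cfg
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals[names(vals) %in%
                                  names(formals(pipeline_config))])
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full post-processing workflow on a simulated cohort
#'
#' Executes the end-to-end stage order — adduct removal, blank filtering,
#' detection-frequency cutoff (per ESI mode), cross-polarity merge,
#' creatinine normalization, below-MDL imputation, empirical-Bayes batch
#' correction, MS2 annotation and transfer, PCA / differential statistics /
#' volcano classification per matrix, and the endogenous-exogenous
#' correlation network on serum — writing every intermediate table, a JSON
#' run manifest with per-stage feature counts, and graph exports into
#' `out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param sim a [sim_config()]; defaults to the standard cohort with the
#'   pipeline seed.
#' @return invisibly, a list with all stage objects (tables, merge
#'   records, batch model, annotations, statistics, network, ground truth,
#'   stage counts).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         sim = sim_config(seed = config$seed)) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(out_dir, "input"), recursive = TRUE,
             showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # -- simulate inputs ------------------------------------------------
  cohort <- generate_cohort(sim)
  tabs <- generate_feature_tables(sim, cohort$manifest)
  sp <- generate_spectra(sim, tabs)
  write_manifest(cohort$manifest, file.path(out_dir, "input",
                                            "manifest.csv"))
  attr(tabs$pos, "blanks") <- tabs$blanks$pos
  attr(tabs$neg, "blanks") <- tabs$blanks$neg
  write_alignment(tabs$pos, file.path(out_dir, "input",
                                      "alignment_pos.csv"))
  write_alignment(tabs$neg, file.path(out_dir, "input",
                                      "alignment_neg.csv"))
  write_msp(sp$spectra, file.path(out_dir, "input", "pooled_spectra.msp"))
  write_msp(sp$library, file.path(out_dir, "input", "library.msp"))
  note("simulated ", nrow(tabs$pos$features), " ESI+ and ",
       nrow(tabs$neg$features), " ESI- features for ",
       nrow(cohort$manifest), " samples")

  # -- filtering cascade, per mode -----------------------------------
  counts <- list()
  cascade <- function(tab, mode) {
    counts[[paste0(mode, "_raw")]] <<- nrow(tab$features)
    t1 <- remove_linked_adducts(tab)
    counts[[paste0(mode, "_adducts_removed")]] <<- nrow(t1$features)
    t2 <- filter_blanks(t1, ratio_threshold = config$blank_ratio)
    counts[[paste0(mode, "_blank_filtered")]] <<- nrow(t2$features)
    t3 <- apply_frequency_cutoff(t2, config$freq_cutoff,
                                 config$noise_floor)
    counts[[paste0(mode, "_freq_filtered")]] <<- nrow(t3$features)
    t3
  }
  pos_f <- cascade(tabs$pos, "pos")
  neg_f <- cascade(tabs$neg, "neg")
  note("filtering: ESI+ ", counts$pos_raw, " -> ", counts$pos_freq_filtered,
       "; ESI- ", counts$neg_raw, " -> ", counts$neg_freq_filtered)

  mg <- merge_esi_modes(pos_f, neg_f, config$merge_ppm, config$merge_rt)
  counts$merged_pairs <- nrow(mg$merges)
  counts$merged_features <- nrow(mg$table$features)
  write.csv(mg$merges, file.path(out_dir, "merge_records.csv"),
            row.names = FALSE)
  write_alignment(mg$table, file.path(out_dir, "merged.csv"),
                  blanks = NULL)
  note("merged ", counts$merged_pairs, " cross-polarity pairs")

  # -- normalize, impute, correct ------------------------------------
  norm <- creatinine_normalize(mg$table, config$creatinine_strategy)
  imp <- impute_below_mdl(norm, mdl = config$noise_floor,
                          seed = config$seed + 3L)
  cc <- combat_correct(imp)
  corrected <- cc$table
  write_alignment(corrected, file.path(out_dir, "corrected.csv"),
                  blanks = NULL)
  jsonlite::write_json(
    list(n_batches = cc$model$n_batches,
         gamma_bar = cc$model$gamma_bar, t2 = cc$model$t2,
         a_prior = cc$model$a_prior, b_prior = cc$model$b_prior,
         mean_gamma_star = if (!is.null(cc$model$gamma_star))
           colMeans(cc$model$gamma_star)),
    file.path(out_dir, "batch_model.json"), auto_unbox = TRUE, digits = NA)

  # -- annotation -----------------------------------------------------
  ann <- annotate_spectra(sp$spectra, sp$library,
                          fragment_tol_ppm = 10,
                          rt_tol = config$level1_rt,
                          ion_tol_ppm = config$level1_ppm,
                          score_l2 = config$score_l2,
                          score_l3 = config$score_l3)
  tr <- transfer_annotations(corrected, ann, config$transfer_rt,
                             config$transfer_ppm)
  annotated <- tr$table
  counts$annotations <- sum(!is.na(ann$compound_name))
  counts$annotations_transferred <-
    sum(!is.na(annotated$features$annotation_name))
  write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  note("annotated ", counts$annotations, " spectra; ",
       counts$annotations_transferred, " transferred onto MS1 features")

  # -- statistics, per matrix ----------------------------------------
  results <- list()
  for (m in unique(annotated$samples$matrix)) {
    sub <- ft_subset(annotated, samples =
                       which(annotated$samples$matrix == m))
    res <- volcano_classify(differential_test(sub), config$p_cut,
                            config$fc_cut)
    write.csv(res, file.path(out_dir, paste0("differential_", m, ".csv")),
              row.names = FALSE)
    results[[m]] <- res
  }
  pca <- run_pca(annotated)
  write.csv(pca$correlations, file.path(out_dir, "pca_correlations.csv"),
            row.names = FALSE)
  freq_tab <- detection_frequency_by_group(
    annotated, noise_floor = config$noise_floor)
  write.csv(freq_tab, file.path(out_dir, "detection_frequency.csv"),
            row.names = FALSE)

  # -- network on serum ----------------------------------------------
  serum <- ft_subset(annotated,
                     samples = which(annotated$samples$matrix == "serum"))
  net <- build_network(serum, config$r_threshold)
  net <- group_proportions(net, serum, noise_floor = config$noise_floor)
  counts$network_nodes <- nrow(net$nodes)
  counts$network_edges <- nrow(net$edges)
  write_graph_file(net, file.path(out_dir, "network.json"), "json")
  write_graph_file(net, file.path(out_dir, "network.graphml"), "graphml")
  note("network: ", counts$network_nodes, " nodes, ",
       counts$network_edges, " edges")

  jsonlite::write_json(
    list(config = unclass(config), sim = unclass(sim),
         stage_counts = counts),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(dir = out_dir, config = config, manifest = cohort$manifest,
                 truth = tabs$truth, spectra_truth = sp$truth,
                 filtered = list(pos = pos_f, neg = neg_f), merge = mg,
                 imputed = imp, corrected = corrected, batch_model = cc$model,
                 annotations = ann, annotated = annotated,
                 differential = results, pca = pca,
                 detection_frequency = freq_tab, network = net,
                 stage_counts = counts))
}

#' Recovery rate of planted differential features
#'
#' Fraction of the simulator's planted differential features that a run
#' declares significant (BH q below `q_cut`) in the serum comparison.
#' Features lost in filtering count as not recovered.
#'
#' @param run result of [run_pipeline()].
#' @param q_cut adjusted-value threshold (default 0.05).
#' @return fraction in `[0, 1]`.
#' @export
differential_recovery <- function(run, q_cut = 0.05) {
  res <- run$differential$serum
  planted <- run$truth$differential_feature_ids
  hit <- res$feature_id %in% planted & res$q < q_cut
  sum(hit) / length(planted)
}
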