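#' Run the full population-analysis pipeline on a synthetic session
#'
#' Generates a session from `config`, screens it, computes response
#' probabilities and category-preference tests, performs the stimulus- and
#' trial-level representational analyses with permutation inference, decodes
#' category (generalisation to unseen exemplars) and stimulus identity, tests
#' the confusion structure, and runs the pixel-level image-similarity
#' controls.  Every stochastic step derives its seed from `config$rng_seed`,
#' so repeated runs are identical.
#'
#' @param config An [mtl_config()].
#' @param screening A [screening_config()].
#' @param n_perm Shuffles for the permutation tests.
#' @param n_splits Holdout divisions for the decoders.
#' @param image_noise_sd Within-category pixel noise of the control images.
#' @param out_dir Optional directory; when given, the machine-readable
#'   summary is written there as `summary.json` together with the session
#'   bundle.
#' @return Object of class `mtl_pipeline`: all stage results plus a flat
#'   numeric `summary` and a `log` of data-dependent branches taken.
#' @export
run_pipeline <- function(config = mtl_config(),
                         screening = screening_config(),
                         n_perm = 1e5, n_splits = 100L,
                         image_noise_sd = 10, out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  collect <- function(expr) withCallingHandlers(expr, message = function(m) {
    log <<- c(log, sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  }, warning = function(w) {
    log <<- c(log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  seed <- config$rng_seed

  session <- generate_population(config)
  scr <- screen_session(session, screening)
  sel <- selectivity_distribution(scr)
  rp <- collect(response_probability(scr))
  fisher <- category_preference_test(scr)

  pop_s <- collect(zscore_responses(session, "stimulus", screening))
  dis <- collect(dissimilarity(pop_s))
  tree <- cluster_dendrogram(dis)
  contig <- leaf_category_contiguity(tree, dis$labels$category_id)
  coords <- mds_embed(dis)
  perm_rsa <- within_between_permutation(dis, n_perm = n_perm,
                                         seed = seed + 101L)

  pop_t <- collect(zscore_responses(session, "trial", screening))
  dec_cat <- decode_category(pop_s, decoding_scheme("category",
                                                    n_splits = n_splits,
                                                    seed = seed + 201L))
  dec_id <- decode_identity(pop_t, decoding_scheme("identity",
                                                   n_splits = n_splits,
                                                   seed = seed + 202L))
  stim_cats <- session$stimuli$category_id[
    match(rownames(dec_id$confusion), session$stimuli$stimulus_id)]
  perm_conf <- confusion_within_between_test(dec_id$confusion, stim_cats,
                                             n_perm = n_perm,
                                             seed = seed + 301L)

  imgs <- generate_images(config, noise_sd = image_noise_sd)
  idist <- image_distances(imgs)
  img_dis <- image_rsa(idist, "euclidean", imgs$labels)
  perm_img <- within_between_permutation(img_dis, imgs$labels$category_id,
                                         n_perm = n_perm, seed = seed + 401L)

  summary <- list(
    n_units = nrow(session$units),
    n_trials = nrow(session$events),
    n_responsive_units = sum(sel$n_responses > 0),
    n_responses = sum(sel$n_responses),
    rp_max_percent = max(rp$rp),
    n_fisher_significant = sum(fisher$significant),
    rsa_within_between_p = perm_rsa$p.value,
    dendrogram_contiguous_categories = contig,
    category_accuracy_median = stats::median(dec_cat$per_split$accuracy),
    category_kappa_median = stats::median(dec_cat$per_split$kappa),
    identity_accuracy_median = stats::median(dec_id$per_split$accuracy),
    identity_kappa_median = stats::median(dec_id$per_split$kappa),
    confusion_within_between_p = perm_conf$p.value,
    image_within_between_p = perm_img$p.value,
    config_hash = config_hash(config))

  out <- structure(list(session = session, screening = scr,
                        selectivity = sel, response_probability = rp,
                        fisher = fisher, dissimilarity = dis, tree = tree,
                        mds = coords, perm_rsa = perm_rsa,
                        decoding_category = dec_cat,
                        decoding_identity = dec_id,
                        perm_confusion = perm_conf,
                        image_distances = idist, perm_image = perm_img,
                        summary = summary, log = log),
                   class = "mtl_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(session, file.path(out_dir, "session"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  out
}

#' @export
print.mtl_pipeline <- function(x, ...) {
  s <- x$summary
  cat("mtl_pipeline summary\n",
      "  units: ", s$n_units, " (", s$n_responsive_units, " responsive, ",
      s$n_responses, " responses)\n",
      "  RSA within<between p: ", format(s$rsa_within_between_p), "\n",
      "  contiguous categories in dendrogram: ",
      s$dendrogram_contiguous_categories, "\n",
      "  category decoding median accuracy: ",
      round(100 * s$category_accuracy_median, 1), "% (kappa ",
      round(s$category_kappa_median, 3), ")\n",
      "  identity decoding median accuracy: ",
      round(100 * s$identity_accuracy_median, 2), "% (kappa ",
      round(s$identity_kappa_median, 3), ")\n",
      "  confusion within>between p: ", format(s$confusion_within_between_p),
      "\n  image-control within<between p: ", format(s$image_within_between_p),
      "\n", sep = "")
  invisible(x)
}
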