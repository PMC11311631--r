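#' Run the full cohort-topology pipeline
#'
#' Executes, in order: read and validate the cohort, compute the Gower
#' distance matrix, extract persistent homology, score bar durations with
#' the empirical Bayes mixture, interpret the top-posterior loop (sectors,
#' sinusoid fits and kappa ranking, centroid separations, circos table) and
#' — when dimension 2 was computed and has a finite bar — the top void
#' (3-D embedding, binary axes, sphere projection, OFF skeleton), then the
#' binary-feature dependence table and silhouette widths. All artifacts are
#' written as plain TSV/CSV/JSON under `out_dir`, plus diagnostic plots and
#' a JSON manifest recording the configuration, seed and package version.
#'
#' @param config A named list or the path of a YAML/JSON config file.
#'   Recognised fields: `table`, `schema` (input paths; alternatively a
#'   `cohort` object in a list config), `na_tokens`, `max_dim` (default 2),
#'   `max_scale`, `embedding` (`method`, `k`), `sector_width` (default 20),
#'   `eb` (`pool_dimensions`, `bandwidth`), `clusters` (default 8),
#'   `dichotomize` (default `TRUE`: median-split continuous features before
#'   binary analyses), `seed`, `out_dir` (required), `plots` (default
#'   `TRUE`).
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `distance`, `homology`, `scored`, `loop`, `void`, `dependence`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(paste0("config error: file not found: ", config),
            class = "tda_config_error")
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- config
  if (is.null(cfg$out_dir))
    abort("config error: out_dir is required", class = "tda_config_error")
  # validate inputs before any computation
  if (is.null(cfg$cohort)) {
    for (f in c("table", "schema")) {
      if (is.null(cfg[[f]]))
        abort(paste0("config error: missing field '", f, "'"),
              class = "tda_config_error")
      if (!file.exists(cfg[[f]]))
        abort(paste0("config error: ", f, " path does not exist: ", cfg[[f]]),
              class = "tda_config_error")
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  max_dim <- cfg$max_dim %||% 2
  width <- cfg$sector_width %||% 20
  kclust <- cfg$clusters %||% 8
  emb_method <- cfg$embedding$method %||% "mds"
  seed <- cfg$seed %||% NA
  if (!is.na(seed)) set.seed(as.integer(seed))

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "tda_pipeline_error"))
    message(sprintf("[%s] %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  ch <- stage("read", {
    if (!is.null(cfg$cohort)) cfg$cohort
    else read_cohort(cfg$table, cfg$schema,
                     na_tokens = cfg$na_tokens %||% c("", "NA"))
  })
  d <- stage("distance", daisy_distance(ch))
  write_distance_csv(d, out("distance.csv"))

  ph <- stage("persist", vietoris_rips(d, max_dim = max_dim,
                                       max_scale = cfg$max_scale))
  write_barcodes(ph, out("barcodes.tsv"))

  scored <- stage("score", suppressWarnings(
    score_barcodes(ph, pool_dimensions = isTRUE(cfg$eb$pool_dimensions),
                   bandwidth = cfg$eb$bandwidth)))
  write_scored(scored, out("scored.tsv"), out("eb_models.json"))

  # binary view of the cohort for interpretation stages
  chb <- ch
  if (!identical(cfg$dichotomize, FALSE)) {
    sch <- schema_of(ch)
    for (f in sch$feature[sch$type == "continuous"])
      if (any(!is.na(ch[[f]]))) chb <- dichotomize_median(chb, f)
  }

  emb2 <- stage("embed", embed_distance(d, method = emb_method, k = 2))
  readr::write_tsv(as_tibble(emb2), out("embedding.tsv"))
  clusters <- cut_clusters(d, min(kclust, ph$n))

  loop_res <- NULL
  top_loop <- most_persistent(ph, 1)
  if (!is.na(top_loop)) loop_res <- stage("interpret_loop", {
    rep1 <- representative_cycle(ph, top_loop)
    lf <- loop_fit(ch, emb2, rep1, width = width)
    readr::write_tsv(tidy(lf), out("kappa.tsv"))
    write_circos(lf, out("circos.csv"))
    seps <- centroid_separation(chb, emb2)
    readr::write_tsv(seps, out("separations.tsv"))
    list(bar = top_loop, representative = rep1, fit = lf,
         separations = seps)
  })

  void_res <- NULL
  top_void <- if (max_dim >= 2) most_persistent(ph, 2) else NA
  if (!is.na(top_void)) void_res <- stage("interpret_void", {
    rep2 <- representative_cycle(ph, top_void)
    emb3 <- embed_distance(d, method = emb_method, k = 3)
    readr::write_tsv(as_tibble(emb3), out("embedding3d.tsv"))
    write_mesh_off(rep2, emb3, out("void_mesh.off"))
    seps3 <- centroid_separation(chb, emb3)
    axes <- NULL
    usable <- seps3[is.na(seps3$flag), ]
    if (nrow(usable) >= 3) {
      top3 <- usable$feature[order(-usable$separation)][1:3]
      axes <- void_axes(chb, emb3, top3)
      readr::write_tsv(tidy(axes), out("void_axes.tsv"))
    }
    cen <- loop_centroid(emb3, rep2)
    sph <- sphere_projection(emb3, cen)
    readr::write_tsv(sph, out("sphere_projection.tsv"))
    list(bar = top_void, representative = rep2, axes = axes,
         centroid = cen)
  })

  dep_res <- stage("depend", {
    if (length(binary_features(chb)) >= 2) {
      dep <- pairwise_chi2(chb)
      utils::write.csv(dep$neglog10p, out("chi2_heatmap.csv"))
      fc <- cluster_features(chb, k = min(3, length(binary_features(chb))))
      jsonlite::write_json(
        list(orderings = fc$orderings,
             agreement = fc$agreement),
        out("feature_clusters.json"), auto_unbox = TRUE, pretty = TRUE)
      sil <- silhouette_widths(d, clusters)
      readr::write_tsv(sil, out("silhouette.tsv"))
      list(chi2 = dep, clusters = fc, silhouette = sil)
    } else NULL
  })

  if (!identical(cfg$plots, FALSE)) stage("plots", {
    dir.create(out("plots"), showWarnings = FALSE)
    ggplot2::ggsave(out("plots", "barcode.png"), autoplot(ph),
                    width = 7, height = 5, dpi = 120)
    bars <- ph$pairs[is.finite(ph$pairs$death) & ph$pairs$duration > 0, ]
    p_bean <- ggplot2::ggplot(bars,
        ggplot2::aes(factor(.data$dimension), log10(.data$duration))) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_jitter(width = 0.08, alpha = 0.3, size = 0.5) +
      ggplot2::labs(x = "dimension", y = "log10 persistence") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(out("plots", "persistence_by_dim.png"), p_bean,
                    width = 5, height = 4, dpi = 120)
    loop_edges <- if (!is.null(loop_res)) loop_res$representative else NULL
    p_emb <- autoplot(emb2, colour = factor(clusters), loop = loop_edges)
    ggplot2::ggsave(out("plots", "embedding.png"), p_emb,
                    width = 6, height = 5, dpi = 120)
    for (mod_name in names(attr(scored, "models"))) {
      mod <- attr(scored, "models")[[mod_name]]
      ggplot2::ggsave(out("plots", paste0("posterior_dim", mod_name, ".png")),
                      autoplot(mod), width = 5, height = 4, dpi = 120)
    }
    invisible(NULL)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tdacohort")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg[setdiff(names(cfg), "cohort")],
    n_subjects = ph$n,
    n_bars = nrow(ph$pairs),
    top_loop = if (!is.na(top_loop)) as.list(
      ph$pairs[ph$pairs$id == top_loop,
               c("birth", "death", "duration")]) else NULL,
    top_void = if (!is.na(top_void)) as.list(
      ph$pairs[ph$pairs$id == top_void,
               c("birth", "death", "duration")]) else NULL)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(cohort = ch, distance = d, homology = ph, scored = scored,
                 loop = loop_res, void = void_res, dependence = dep_res,
                 embedding = emb2, clusters = clusters, manifest = manifest))
}
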