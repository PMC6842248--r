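# End-to-end orchestration: screen, morphology and titre analyses under one
# configuration with reproducible defaults.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the three analyses. The defaults are
#' the study-standard values: Spearman cutoff 0.5, enrichment FDR threshold
#' 0.05, dispersed/pellet area boundaries 95 and 500 square micrometres,
#' t-test alpha 0.05, doxycycline dose grid {0, 0.2, 2, 20} ug/ml.
#'
#' @param spearman_cutoff co-expression edge threshold in `[0, 1)`.
#' @param query_genes character vector of screen query genes.
#' @param q_threshold enrichment FDR threshold.
#' @param pixel_size_um image calibration, micrometres per pixel.
#' @param dispersed_min,pellet_min morphology class boundaries (um^2).
#' @param alpha significance level for titre comparisons.
#' @param control control strain label.
#' @param dox_levels dose grid (ug/ml), informational.
#' @param seed integer seed for any generator the pipeline invokes.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spearman_cutoff = 0.5, query_genes = character(),
                            q_threshold = 0.05, pixel_size_um = 1,
                            dispersed_min = 95, pellet_min = 500,
                            alpha = 0.05, control = "MA70.15",
                            dox_levels = c(0, 0.2, 2, 20), seed = 1L) {
  check_that(all(c(spearman_cutoff >= 0, spearman_cutoff < 1,
                   q_threshold > 0, q_threshold <= 1, pixel_size_um > 0,
                   dispersed_min > 0, pellet_min > dispersed_min,
                   alpha > 0, alpha <= 1)),
             "configuration thresholds out of range")
  structure(list(spearman_cutoff = spearman_cutoff, query_genes = query_genes,
                 q_threshold = q_threshold, pixel_size_um = pixel_size_um,
                 dispersed_min = dispersed_min, pellet_min = pellet_min,
                 alpha = alpha, control = control, dox_levels = dox_levels,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the co-expression screen with GO enrichment
#'
#' Builds a screen-mode network around the query genes, intersects the
#' query neighbourhoods, and characterises the intersection by GO
#' over-representation. With an `out_dir`, writes `intersection.txt`,
#' `screen_genes.csv`, `network_edges.tsv` and `enrichment.csv`.
#'
#' @param matrix expression matrix (or a TSV path readable by
#'   [read_expression_matrix()]).
#' @param annotations annotation table, [annotation_set()], or TSV path.
#' @param config a [pipeline_config()] with non-empty `query_genes`.
#' @param out_dir optional output directory (created if missing).
#' @return List with `network`, `screen` (a `screen_result`) and
#'   `enrichment` (data.frame, `NULL` if the intersection is empty).
#' @export
run_screen <- function(matrix, annotations, config, out_dir = NULL) {
  check_that(inherits(config, "pipeline_config"), "`config` required")
  check_that(length(config$query_genes) >= 1L,
             "config$query_genes must name at least one query")
  if (is.character(matrix)) matrix <- read_expression_matrix(matrix)
  missing <- setdiff(config$query_genes, rownames(matrix))
  check_that(length(missing) == 0L, "query genes absent from the matrix: %s",
             paste(missing, collapse = ", "))

  network <- build_network(matrix, cutoff = config$spearman_cutoff,
                           query_restriction = config$query_genes)
  screen <- intersect_subnetworks(network, config$query_genes)
  message(sprintf("screen: %d queries, %d edges, intersection of %d genes",
                  length(config$query_genes), nrow(network$edges),
                  screen$intersection_size))
  enrichment <- NULL
  if (screen$intersection_size > 0) {
    enrichment <- enrich(screen$intersection, annotations,
                         q_threshold = config$q_threshold)
  } else {
    warning("empty intersection: no genes co-expressed with all queries",
            call. = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(screen$intersection, file.path(out_dir, "intersection.txt"))
    utils::write.csv(screen_result_table(screen),
                     file.path(out_dir, "screen_genes.csv"), row.names = FALSE)
    write_network(network, tsv_path = file.path(out_dir, "network_edges.tsv"))
    if (!is.null(enrichment)) {
      utils::write.csv(enrichment, file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE)
    }
  }
  list(network = network, screen = screen, enrichment = enrichment)
}

#' Run the morphology analysis over a set of images
#'
#' Measures every image, classifies structures and summarises each culture.
#' With an `out_dir`, writes `structures.csv` (all images pooled, with an
#' `image` column) and `image_summaries.csv`.
#'
#' @param images named list of binary image matrices, or a directory of
#'   PNG files (names/filenames become image IDs).
#' @param config a [pipeline_config()] (supplies `pixel_size_um` and the
#'   class boundaries).
#' @param out_dir optional output directory.
#' @return List with `structures` (pooled data.frame) and `summaries`
#'   (data.frame, one row per image).
#' @export
run_morphology <- function(images, config, out_dir = NULL) {
  check_that(inherits(config, "pipeline_config"), "`config` required")
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    paths <- list.files(images, pattern = "\\.png$", full.names = TRUE)
    check_that(length(paths) > 0L, "no PNG images found in %s", images)
    images <- lapply(paths, read_culture_image)
    names(images) <- sub("\\.png$", "", basename(paths))
  }
  check_that(is.list(images) && length(images) >= 1L &&
               !is.null(names(images)),
             "`images` must be a non-empty named list or a directory")

  per_image <- lapply(names(images), function(id) {
    m <- measure_structures(images[[id]], config$pixel_size_um,
                            config$dispersed_min, config$pellet_min)
    if (nrow(m) == 0L) message("image ", id, ": no structures found")
    m$image <- if (nrow(m) > 0) id else character(0)
    m
  })
  structures <- do.call(rbind, per_image)
  summaries <- do.call(rbind, lapply(names(images), function(id) {
    s <- summarize_culture(structures[structures$image == id, , drop = FALSE])
    data.frame(image = id, n_pellets = s$n_pellets,
               n_dispersed = s$n_dispersed, n_excluded = s$n_excluded,
               pellet_area_fraction_pct = s$pellet_area_fraction_pct,
               mn_mean = s$mn_mean, mn_median = s$mn_median,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(structures, file.path(out_dir, "structures.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "image_summaries.csv"),
                     row.names = FALSE)
  }
  list(structures = structures, summaries = summaries)
}

#' Run the titre analysis
#'
#' Normalises the fermentation table, compares every mutant to the control
#' per dose, and fits the protein-versus-acid trend curves over strain x
#' dose means (degree 2 for citric acid, degree 1 for oxaloacetate). With
#' an `out_dir`, writes `normalized.csv`, `comparisons.csv` and
#' `trends.csv`.
#'
#' @param table fermentation data.frame or CSV path.
#' @param config a [pipeline_config()] (supplies `control` and `alpha`).
#' @param out_dir optional output directory.
#' @return List with `normalized`, `comparisons`, `means`
#'   (the [correlation_table()]) and `trends` (named list of [fit_trend()]
#'   results: `protein_vs_citric`, `protein_vs_oxaloacetate`).
#' @export
run_titres <- function(table, config, out_dir = NULL) {
  check_that(inherits(config, "pipeline_config"), "`config` required")
  if (is.character(table)) table <- read_fermentation_table(table)
  check_that(config$control %in% table$strain,
             "control strain `%s` absent from the table", config$control)
  normalized <- normalize_titres(table)
  comparisons <- compare_to_control(normalized, config$control, config$alpha)
  means <- correlation_table(normalized)
  trends <- list(
    protein_vs_citric = fit_trend(means$citric_g_per_g_glucose,
                                  means$protein_mg_per_g_biomass, degree = 2L),
    protein_vs_oxaloacetate = fit_trend(means$oxaloacetate_g_per_g_glucose,
                                        means$protein_mg_per_g_biomass,
                                        degree = 1L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(normalized, file.path(out_dir, "normalized.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    trend_df <- do.call(rbind, lapply(names(trends), function(nm) {
      tr <- trends[[nm]]
      data.frame(pair = nm, degree = tr$degree,
                 coefficients = paste(signif(tr$coefficients, 6),
                                      collapse = ";"),
                 r_squared = tr$r_squared, stringsAsFactors = FALSE)
    }))
    utils::write.csv(trend_df, file.path(out_dir, "trends.csv"),
                     row.names = FALSE)
  }
  list(normalized = normalized, comparisons = comparisons, means = means,
       trends = trends)
}
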