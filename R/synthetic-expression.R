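# Synthetic expression compendia and GO annotations with planted structure.
#
# The generators emulate the statistical shape of a public microarray
# compendium (hundreds of arrays over ~155 cultivation conditions) in which
# functionally coupled gene sets -- e.g. TCA-cycle enzymes, Golgi vesicle
# trafficking components and their regulators -- are strongly rank-correlated
# across conditions, while the genomic background is not.

#' Specify a planted co-expression module
#'
#' A module is a disjoint set of genes whose expression profiles are noisy
#' monotone copies of a shared latent condition profile, optionally tagged
#' with GO terms that [generate_go_annotations()] plants on its members.
#'
#' @param module_id single character label.
#' @param member_genes character vector of gene identifiers (no duplicates).
#' @param latent_correlation target within-module correlation in (0, 1].
#'   With the default 1 all members follow the same latent profile exactly
#'   (up to the matrix-level `noise_sd`); values below 1 mix in independent
#'   per-gene variation so the population Pearson correlation between two
#'   members equals `latent_correlation` before measurement noise.
#' @param enriched_terms character vector of GO term identifiers planted on
#'   every member (may be empty).
#' @return A `module_spec` list.
#' @seealso [generate_expression_matrix()], [generate_go_annotations()]
#' @export
#' @examples
#' module_spec("tca", paste0("tca_", 1:10), 0.9, "GO:0006099")
module_spec <- function(module_id, member_genes, latent_correlation = 1,
                        enriched_terms = character()) {
  check_that(is.character(module_id) && length(module_id) == 1L,
             "`module_id` must be a single string")
  check_that(is.character(member_genes) && length(member_genes) >= 1L &&
               !anyDuplicated(member_genes),
             "`member_genes` must be non-empty and duplicate-free")
  check_that(is_scalar_number(latent_correlation) &&
               latent_correlation > 0 && latent_correlation <= 1,
             "`latent_correlation` must lie in (0, 1]")
  structure(
    list(module_id = module_id,
         member_genes = member_genes,
         latent_correlation = latent_correlation,
         enriched_terms = as.character(enriched_terms)),
    class = "module_spec"
  )
}

check_modules_disjoint <- function(modules) {
  check_that(all(vapply(modules, inherits, logical(1), "module_spec")),
             "`modules` must be a list of module_spec objects")
  members <- unlist(lapply(modules, `[[`, "member_genes"))
  if (anyDuplicated(members)) {
    stop("module member gene lists overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(members)
}

#' Generate an expression matrix with planted co-expression modules
#'
#' Produces a genes x conditions matrix in which each module's members are
#' noisy monotone copies of a module-specific latent condition profile
#' (standard normal across conditions), and all remaining "background" genes
#' are independent standard-normal noise. Member profiles are
#' `sqrt(r) * latent + sqrt(1 - r) * gene_noise + noise_sd * measurement_noise`
#' with `r` the module's `latent_correlation`, plus a per-gene baseline
#' offset; offsets and positive scalings are rank-preserving, so the
#' within-module Spearman correlation concentrates near the population value
#' implied by `r` and `noise_sd`.
#'
#' @param n_genes total number of genes; module members must fit inside the
#'   universe `gene_0001 ... gene_<n_genes>` or be extra named genes counted
#'   within `n_genes`.
#' @param n_conditions number of conditions (columns); at least 5, below
#'   which rank correlations are too unstable to threshold.
#' @param modules list of [module_spec()] objects with disjoint members.
#' @param noise_sd standard deviation of additive measurement noise on every
#'   module member (background genes are pure noise already).
#' @param seed integer seed; identical arguments and seed give a
#'   bit-identical matrix.
#' @return Numeric matrix with gene IDs as rownames and condition IDs
#'   (`cond_001`, ...) as colnames. Module members occupy the first rows in
#'   module order; background genes fill the remainder.
#' @export
#' @examples
#' m <- generate_expression_matrix(50, 20,
#'        list(module_spec("m1", paste0("g", 1:5))), noise_sd = 0, seed = 1)
#' dim(m)
generate_expression_matrix <- function(n_genes, n_conditions, modules,
                                       noise_sd, seed) {
  check_that(is_count(n_genes, 1L), "`n_genes` must be a positive count")
  check_that(is_count(n_conditions, 5L),
             "`n_conditions` must be >= 5 (rank correlation unstable below)")
  check_that(is_scalar_number(noise_sd) && noise_sd >= 0,
             "`noise_sd` must be a nonnegative number")
  members <- check_modules_disjoint(modules)
  check_that(length(members) <= n_genes,
             "module members (%d) exceed `n_genes` (%d)",
             length(members), n_genes)

  n_bg <- n_genes - length(members)
  bg_ids <- setdiff(sprintf("gene_%04d", seq_len(n_genes)), members)[seq_len(n_bg)]
  gene_ids <- c(members, bg_ids)
  cond_ids <- sprintf("cond_%03d", seq_len(n_conditions))

  with_seed(seed, {
    values <- matrix(NA_real_, n_genes, n_conditions,
                     dimnames = list(gene_ids, cond_ids))
    for (mod in modules) {
      latent <- rnorm(n_conditions)
      r <- mod$latent_correlation
      for (g in mod$member_genes) {
        gene_noise <- if (r < 1) rnorm(n_conditions) else 0
        profile <- sqrt(r) * latent + sqrt(1 - r) * gene_noise
        if (noise_sd > 0) profile <- profile + rnorm(n_conditions, sd = noise_sd)
        # rank-preserving per-gene baseline shift, as on real arrays
        values[g, ] <- profile + rnorm(1, sd = 0.5)
      }
    }
    if (n_bg > 0) {
      values[bg_ids, ] <- matrix(rnorm(n_bg * n_conditions), n_bg, n_conditions)
    }
    values
  })
}

#' Generate a flat gene-to-GO annotation table
#'
#' Module members receive their module's `enriched_terms` plus up to
#' `terms_per_gene` terms drawn from a background pool `GO:BG0001 ...`;
#' background genes receive `terms_per_gene` background terms. When
#' `background_terms` is 0, genes outside any module carry no annotation and
#' therefore fall outside the enrichment universe.
#'
#' @param gene_universe character vector of gene IDs (non-empty).
#' @param modules list of [module_spec()] objects.
#' @param background_terms number of distinct background GO terms available.
#' @param terms_per_gene number of background terms drawn per gene (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `gene` and `term`, one pair per row.
#' @export
generate_go_annotations <- function(gene_universe, modules, background_terms,
                                    terms_per_gene, seed) {
  check_that(is.character(gene_universe) && length(gene_universe) >= 1L,
             "`gene_universe` must be a non-empty character vector")
  check_that(is_count(background_terms), "`background_terms` must be a count")
  check_that(is_count(terms_per_gene, 1L), "`terms_per_gene` must be >= 1")
  check_modules_disjoint(modules)

  planted <- list()
  for (mod in modules) {
    for (g in intersect(mod$member_genes, gene_universe)) {
      planted[[g]] <- mod$enriched_terms
    }
  }
  bg_pool <- if (background_terms > 0) {
    sprintf("GO:BG%04d", seq_len(background_terms))
  } else {
    character()
  }

  with_seed(seed, {
    rows <- lapply(gene_universe, function(g) {
      terms <- planted[[g]]
      if (length(bg_pool) > 0) {
        n_draw <- min(terms_per_gene, length(bg_pool))
        terms <- unique(c(terms, sample(bg_pool, n_draw)))
      }
      if (length(terms) == 0L) return(NULL)
      data.frame(gene = g, term = terms, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(gene = character(), term = character())
    rownames(out) <- NULL
    out
  })
}

#' Write/read an expression matrix as TSV
#'
#' First column `gene`, header row of condition IDs, tab-separated. Reading
#' rejects duplicate gene or condition IDs, missing values, and matrices
#' with fewer than 5 conditions -- the screen's preconditions are enforced
#' at load time rather than silently patched.
#'
#' @param matrix numeric matrix with gene rownames and condition colnames.
#' @param path file path.
#' @return `read_expression_matrix` returns the validated matrix;
#'   `write_expression_matrix` returns `path` invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_that(ncol(df) >= 2L && names(df)[1] == "gene",
             "expression TSV must have a leading `gene` column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  validate_expression_matrix(m)
  m
}

#' Validate an expression matrix against the screen's preconditions
#'
#' @param matrix numeric matrix, genes x conditions.
#' @return The matrix, invisibly; errors on violation.
#' @export
validate_expression_matrix <- function(matrix) {
  check_that(is.matrix(matrix) && is.numeric(matrix),
             "expression data must be a numeric matrix")
  check_that(!is.null(rownames(matrix)) && !anyDuplicated(rownames(matrix)),
             "gene IDs (rownames) must be present and unique")
  check_that(!is.null(colnames(matrix)) && !anyDuplicated(colnames(matrix)),
             "condition IDs (colnames) must be present and unique")
  check_that(ncol(matrix) >= 5L, "at least 5 conditions are required")
  check_that(!anyNA(matrix),
             "missing expression values are rejected; filter genes upstream")
  invisible(matrix)
}
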