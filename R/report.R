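# Comparative reporting: fold changes between isoforms, category-level
# summaries operationalizing ">x-fold" claims as minimum pairwise ratios,
# and the end-to-end simulate -> fit -> inhibit -> sequence-compare
# pipeline with a reproducibility manifest.

report_metrics <- c("kcat", "km_pep", "km_hco3", "efficiency_pep",
                    "efficiency_hco3")

metric_value <- function(params, metric) {
  switch(metric,
         kcat = params$kcat,
         km_pep = params$km_pep,
         km_hco3 = params$km_hco3,
         efficiency_pep = params$efficiency_pep,
         efficiency_hco3 = params$efficiency_hco3,
         stop("unknown metric: ", metric))
}

metric_se <- function(params, metric) {
  rel <- function(se, v) if (is.na(se) || is.na(v)) NA_real_ else se / v
  switch(metric,
         kcat = params$se_kcat,
         km_pep = params$se_km_pep,
         km_hco3 = params$se_km_hco3,
         efficiency_pep = {
           r <- sqrt(rel(params$se_kcat, params$kcat)^2 +
                       rel(params$se_km_pep, params$km_pep)^2)
           r * params$efficiency_pep
         },
         efficiency_hco3 = {
           r <- sqrt(rel(params$se_kcat, params$kcat)^2 +
                       rel(params$se_km_hco3, params$km_hco3)^2)
           r * params$efficiency_hco3
         })
}

#' Fold change of a kinetic metric between two parameter sets
#'
#' Ratio numerator/denominator of the chosen metric, with a standard
#' error from first-order (delta-method) propagation of the two SEs,
#' treating the estimates as independent.
#'
#' @param params_num,params_den \code{\link{kinetic_params}} objects.
#' @param metric One of \code{kcat, km_pep, km_hco3, efficiency_pep,
#'   efficiency_hco3}.
#' @return List with \code{metric}, \code{ratio} and \code{se} (NA when
#'   either SE is unavailable).
#' @export
fold_change <- function(params_num, params_den, metric = "kcat") {
  stopifnot(inherits(params_num, "kinetic_params"),
            inherits(params_den, "kinetic_params"))
  metric <- match.arg(metric, report_metrics)
  v1 <- metric_value(params_num, metric)
  v2 <- metric_value(params_den, metric)
  if (is.na(v2) || v2 == 0) stop("denominator metric is zero or missing")
  if (is.na(v1)) stop("numerator metric is missing")
  ratio <- v1 / v2
  s1 <- metric_se(params_num, metric)
  s2 <- metric_se(params_den, metric)
  se <- if (is.na(s1) || is.na(s2)) NA_real_
        else ratio * sqrt((s1 / v1)^2 + (s2 / v2)^2)
  list(metric = metric, ratio = ratio, se = se)
}

#' Category-level summary of fitted kinetic parameters
#'
#' Computes per-category means of each metric and, against a reference
#' category, the minimum and maximum pairwise ratios across category
#' members. The minimum pairwise ratio operationalizes ">x-fold"
#' statements as a lower bound over all member pairs.
#'
#' @param records data.frame with columns \code{isoform_id},
#'   \code{category} and the metrics in \code{metrics}.
#' @param reference_category Denominator category for the ratios.
#' @param metrics Metrics to summarize.
#' @return List with \code{means} (category x metric data.frame) and
#'   \code{fold_changes} (one row per non-reference category x metric:
#'   \code{min_ratio}, \code{max_ratio}).
#' @export
group_summary <- function(records, reference_category,
                          metrics = c("kcat", "km_pep", "km_hco3")) {
  stopifnot(is.data.frame(records), "category" %in% names(records))
  metrics <- intersect(metrics, names(records))
  if (!length(metrics)) stop("no requested metric column present")
  cats <- unique(records$category)
  if (!reference_category %in% cats) {
    stop("empty reference category: ", reference_category)
  }
  for (cat in cats) {
    if (!sum(records$category == cat)) stop("empty category: ", cat)
  }
  means <- do.call(rbind, lapply(cats, function(cat) {
    sub <- records[records$category == cat, , drop = FALSE]
    cbind(data.frame(category = cat, n = nrow(sub)),
          as.data.frame(lapply(sub[metrics], mean)))
  }))
  den <- records[records$category == reference_category, , drop = FALSE]
  fc <- list()
  for (cat in setdiff(cats, reference_category)) {
    num <- records[records$category == cat, , drop = FALSE]
    for (m in metrics) {
      ratios <- outer(num[[m]], den[[m]], "/")
      fc[[length(fc) + 1L]] <- data.frame(
        category = cat, reference = reference_category, metric = m,
        min_ratio = min(ratios), max_ratio = max(ratios))
    }
  }
  list(means = means,
       fold_changes = if (length(fc)) do.call(rbind, fc) else NULL)
}

#' Assemble a per-isoform kinetic table
#'
#' @param fits Named list of \code{fit_result} objects (names =
#'   isoform ids).
#' @param profiles Optional \code{\link{make_isoform_profiles}} output
#'   supplying lineage/category columns.
#' @param inhibition Optional named list (per isoform) of named lists of
#'   \code{inhibition_fit} objects, as returned by
#'   \code{\link{inhibition_analysis}}.
#' @return data.frame, one row per isoform, with estimates and SEs.
#' @export
kinetic_table <- function(fits, profiles = NULL, inhibition = NULL) {
  rows <- lapply(names(fits), function(id) {
    p <- fits[[id]]$params
    row <- data.frame(
      isoform_id = id,
      kcat = p$kcat, se_kcat = p$se_kcat,
      km_pep = p$km_pep, se_km_pep = p$se_km_pep,
      km_hco3 = p$km_hco3, se_km_hco3 = p$se_km_hco3,
      efficiency_pep = p$efficiency_pep,
      efficiency_hco3 = p$efficiency_hco3,
      residual_hco3 = fits[[id]]$residual_hco3,
      rss = fits[[id]]$rss, n_points = fits[[id]]$n_points,
      converged = fits[[id]]$converged,
      stringsAsFactors = FALSE)
    if (!is.null(inhibition) && id %in% names(inhibition)) {
      for (inh in names(inhibition[[id]])) {
        f <- inhibition[[id]][[inh]]
        row[[paste0("ki_", inh, "_mM")]] <- f$ki
        row[[paste0("se_ki_", inh, "_mM")]] <- f$se_ki
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(profiles)) {
    idx <- match(out$isoform_id, as.character(profiles$isoform_id))
    out$category <- profiles$category[idx]
    out$lineage <- profiles$lineage[idx]
    out$accession <- profiles$accession[idx]
  }
  rownames(out) <- NULL
  out
}

#' Run the full comparative pipeline
#'
#' Executes, per the configuration: synthetic assay simulation (or
#' loading of an assay table), bi-substrate fitting per isoform,
#' inhibition analysis, sequence comparisons, and report assembly. All
#' artifacts are written as delimited text plus a JSON manifest recording
#' the seed, configuration and package version; re-running with the same
#' configuration and seed reproduces identical outputs.
#'
#' @param config List (or path to a YAML file) with optional entries:
#'   \describe{
#'     \item{simulate}{list: \code{isoforms} (ids, default 1:14),
#'       \code{design} (arguments for \code{\link{assay_design}}),
#'       \code{jitter_cv}, \code{profile_overrides}.}
#'     \item{assay_table}{path to an existing assay table (alternative
#'       to simulation).}
#'     \item{kinetics}{logical, fit the rate law (default TRUE when assay
#'       data are available).}
#'     \item{inhibition}{logical, run the secondary-plot analysis.}
#'     \item{sequences}{list: \code{fasta}, \code{groups},
#'       \code{focal_nonC4}, \code{focal_C4}, \code{reference},
#'       optional \code{site_list}.}
#'     \item{reference_category}{denominator for group fold changes
#'       (default \code{"native co-opted"}).}
#'   }
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created if needed); NULL writes
#'   nothing.
#' @return Object of class \code{comparative_report}: list with
#'   \code{kinetics} (kinetic table), \code{group_summary},
#'   \code{pairwise} (substitution matrix), \code{sites} (site
#'   classification), \code{overlap}, \code{manifest}.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  # fail before any computation when named inputs are missing
  for (p in c(config$assay_table, config$sequences$fasta,
              config$sequences$groups)) {
    if (is.character(p) && !file.exists(p)) stop("missing input: ", p)
  }
  stages <- character(0)
  report <- list()

  profiles <- NULL
  points_by_isoform <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    profiles <- make_isoform_profiles(
      seed = seed,
      overrides = sim$profile_overrides,
      jitter_cv = if (is.null(sim$jitter_cv)) 0 else sim$jitter_cv)
    design <- do.call(assay_design,
                      if (is.null(sim$design)) list() else sim$design)
    isoforms <- if (is.null(sim$isoforms)) profiles$isoform_id
                else sim$isoforms
    for (i in seq_along(isoforms)) {
      id <- isoforms[i]
      prof <- profiles[profiles$isoform_id == id, , drop = FALSE]
      points_by_isoform[[as.character(id)]] <-
        simulate_rates(design, prof, seed = seed + 1000L * i)
    }
    stages <- c(stages, "simulate")
  } else if (!is.null(config$assay_table)) {
    pts <- read_assay_points(config$assay_table)
    points_by_isoform <- split(pts, pts$isoform_id)
    stages <- c(stages, "load_assay")
  }

  do_kinetics <- isTRUE(config$kinetics) ||
    (is.null(config$kinetics) && length(points_by_isoform) > 0)
  fits <- NULL; inhib <- NULL
  if (do_kinetics && length(points_by_isoform)) {
    fits <- lapply(points_by_isoform, function(pts) {
      fit_bisubstrate(pts[pts$inhibitor_mM == 0, , drop = FALSE])
    })
    stages <- c(stages, "fit")
    do_inhib <- isTRUE(config$inhibition) || is.null(config$inhibition)
    if (do_inhib) {
      inhib <- lapply(points_by_isoform, function(pts) {
        fixed_b <- unique(pts$hco3_uM[pts$inhibitor_mM > 0])
        if (!length(fixed_b)) return(NULL)
        sub <- pts[pts$hco3_uM %in% fixed_b & !pts$is_blank, , drop = FALSE]
        tryCatch(inhibition_analysis(sub), error = function(e) NULL)
      })
      inhib <- Filter(Negate(is.null), inhib)
      if (length(inhib)) stages <- c(stages, "inhibition")
    }
    report$kinetics <- kinetic_table(fits, profiles = profiles,
                                     inhibition = inhib)
    if (!is.null(profiles) && "category" %in% names(report$kinetics)) {
      ref_cat <- if (is.null(config$reference_category)) "native co-opted"
                 else config$reference_category
      if (ref_cat %in% report$kinetics$category) {
        report$group_summary <- group_summary(report$kinetics, ref_cat)
        stages <- c(stages, "group_summary")
      }
    }
  }

  if (!is.null(config$sequences)) {
    sq <- config$sequences
    panel <- if (inherits(sq$panel, "aligned_panel")) sq$panel
             else read_aligned_panel(sq$fasta, groups = sq$groups)
    report$pairwise <- pairwise_matrix(panel)
    stages <- c(stages, "pairwise")
    if (!is.null(sq$focal_nonC4) && !is.null(sq$focal_C4) &&
        !is.null(sq$reference)) {
      report$sites <- classify_sites(panel, sq$focal_nonC4, sq$focal_C4,
                                     sq$reference)
      stages <- c(stages, "classify_sites")
      if (!is.null(sq$site_list)) {
        report$overlap <- overlap_with_site_list(report$sites,
                                                 sq$site_list)
      }
    }
  }

  manifest <- list(
    package = "c4pepc",
    version = as.character(utils::packageVersion("c4pepc")),
    seed = seed,
    stages = stages,
    config = config[setdiff(names(config), "sequences")]
  )
  report$manifest <- manifest
  class(report) <- "comparative_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(x, name, rn = FALSE) {
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = rn,
                         col.names = if (rn) NA else TRUE)
    }
    if (!is.null(report$kinetics)) wtsv(report$kinetics, "kinetics.tsv")
    if (!is.null(report$group_summary)) {
      wtsv(report$group_summary$means, "category_means.tsv")
      if (!is.null(report$group_summary$fold_changes)) {
        wtsv(report$group_summary$fold_changes, "fold_changes.tsv")
      }
    }
    if (!is.null(report$pairwise)) {
      wtsv(report$pairwise, "pairwise_matrix.tsv", rn = TRUE)
    }
    if (!is.null(report$sites)) wtsv(report$sites, "site_classes.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("Comparative PEPC report; stages:",
      paste(x$manifest$stages, collapse = ", "), "\n")
  if (!is.null(x$kinetics)) {
    cat("\nKinetic parameters (", nrow(x$kinetics), " isoforms):\n",
        sep = "")
    cols <- intersect(c("isoform_id", "lineage", "kcat", "km_pep",
                        "km_hco3", "ki_malate_mM", "ki_aspartate_mM"),
                      names(x$kinetics))
    df <- x$kinetics[, cols]
    for (cc in setdiff(cols, c("isoform_id", "lineage"))) {
      df[[cc]] <- signif(df[[cc]], 3)
    }
    print(df, row.names = FALSE)
  }
  if (!is.null(x$group_summary$fold_changes)) {
    cat("\nCategory fold changes (min pairwise ratio):\n")
    fc <- x$group_summary$fold_changes
    fc$min_ratio <- signif(fc$min_ratio, 2)
    fc$max_ratio <- signif(fc$max_ratio, 2)
    print(fc, row.names = FALSE)
  }
  if (!is.null(x$sites)) {
    cat("\nClassified sites:", nrow(x$sites), "(",
        sum(x$sites$c4_state == "novel"), "novel,",
        sum(x$sites$c4_state == "ancestral"), "ancestral )\n")
  }
  invisible(x)
}
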