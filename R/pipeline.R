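## End-to-end pipeline: simulate -> profile -> score -> indicators ->
## promotions -> access -> correlate -> report, with a run manifest
## (config hash, file checksums, stage timings) written last.  Stages
## communicate through delimited files in `outdir`, so every schema
## contract is exercised on disk.

.product_required_cols <- c("product_id", "company_id", "who_category",
                            "is_beverage", "is_cheese", "is_added_fat",
                            "is_water", "energy_kj", "sugars_g",
                            "total_fat_g", "saturated_fat_g", "sodium_mg",
                            "fibre_g", "protein_g", "fruit_veg_pct",
                            "ingredient_markers")

#' Read and validate a products table
#'
#' @param path products.csv path.
#' @return validated data.frame.
#' @export
read_products <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.product_required_cols, names(df))
  if (length(missing) > 0L) {
    fb_stop("%s is missing required column '%s'", basename(path), missing[[1L]])
  }
  df$ingredient_markers[is.na(df$ingredient_markers)] <- ""
  df
}

#' Read a pipeline configuration from JSON
#'
#' Any field of [study_config()] may be set; omitted fields keep their
#' defaults.  `n_companies`, `category_mix` and `geo` are JSON objects.
#'
#' @param path JSON file.
#' @return a validated [study_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) fb_stop("config file '%s' does not exist", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (fld in c("portfolio_size_range", "coupling", "noise_sd", "seed",
                "n_flyer_weeks")) {
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  }
  if (!is.null(raw$n_companies)) args$n_companies <- unlist(raw$n_companies)
  if (!is.null(raw$category_mix)) args$category_mix <- unlist(raw$category_mix)
  if (!is.null(raw$geo)) {
    geo <- formals(study_config)$geo |> eval()
    geo[names(raw$geo)] <- raw$geo
    args$geo <- geo
  }
  do.call(study_config, args)
}

.stage_simulate <- function(config, outdir) {
  study <- generate_study(config)
  write_study(study, outdir)
}

.stage_profile <- function(config, outdir) {
  products <- read_products(file.path(outdir, "products.csv"))
  prof <- profile_products(products)
  utils::write.csv(prof, file.path(outdir, "profile_results.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
}

.stage_score <- function(config, outdir) {
  commitments <- utils::read.csv(file.path(outdir, "commitments.csv"),
                                 stringsAsFactors = FALSE)
  scores <- lapply(c("public_only", "verified"), function(st) {
    s <- score_commitments(commitments, stage = st)
    s$stage <- st
    s
  })
  utils::write.csv(do.call(rbind, scores),
                   file.path(outdir, "bia_scores.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
}

.stage_indicators <- function(config, outdir) {
  prof <- utils::read.csv(file.path(outdir, "profile_results.csv"),
                          stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(outdir, "truth.csv"),
                           stringsAsFactors = FALSE)
  summ <- summarize_portfolios(prof)
  summ$industry <- truth$industry[match(summ$company_id, truth$company_id)]
  utils::write.csv(summ, file.path(outdir, "portfolio_summaries.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  aggs <- do.call(rbind, lapply(c("all", intersect(industries, summ$industry)),
                                function(i) aggregate_industry(summ, i)))
  utils::write.csv(aggs, file.path(outdir, "industry_aggregates.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
}

.stage_promotions <- function(config, outdir) {
  flyers <- utils::read.csv(file.path(outdir, "flyers.csv"),
                            stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(sort(unique(flyers$supermarket_id)),
                               function(s) promotion_indicators(flyers, s)))
  utils::write.csv(out, file.path(outdir, "promotion_indicators.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
}

.stage_access <- function(config, outdir) {
  nodes <- utils::read.csv(file.path(outdir, "geo_nodes.csv"),
                           stringsAsFactors = FALSE)
  edges <- utils::read.csv(file.path(outdir, "geo_edges.csv"),
                           stringsAsFactors = FALSE)
  points <- utils::read.csv(file.path(outdir, "geo_points.csv"),
                            stringsAsFactors = FALSE)
  scene <- geo_scene(nodes, edges, points)
  acc <- accessibility_table(scene)
  utils::write.csv(acc, file.path(outdir, "accessibility.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
}

.stage_correlate <- function(config, outdir) {
  bia <- utils::read.csv(file.path(outdir, "bia_scores.csv"),
                         stringsAsFactors = FALSE)
  bia <- bia[bia$stage == "verified", , drop = FALSE]
  summ <- utils::read.csv(file.path(outdir, "portfolio_summaries.csv"),
                          stringsAsFactors = FALSE)
  res <- linkage_suite(bia, summ)
  utils::write.csv(res, file.path(outdir, "linkage_results.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
}

.stage_report <- function(config, outdir) {
  bia <- utils::read.csv(file.path(outdir, "bia_scores.csv"),
                         stringsAsFactors = FALSE)
  bia <- bia[bia$stage == "verified", , drop = FALSE]
  summ <- utils::read.csv(file.path(outdir, "portfolio_summaries.csv"),
                          stringsAsFactors = FALSE)
  rep <- render_report(bia, summ)
  utils::write.csv(rep$table, file.path(outdir, "benchmark_report.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  writeLines(rep$text, file.path(outdir, "benchmark_report.txt"))
}

.pipeline_stages <- c("simulate", "profile", "score", "indicators",
                      "promotions", "access", "correlate", "report")

#' Run the full benchmarking pipeline
#'
#' Executes all stages in dependency order against `outdir`, then writes
#' `manifest.json` (config hash, per-file md5 checksums, stage timings,
#' collected warnings).  A failing stage aborts with its name.
#'
#' @param config a [study_config()] or path to a JSON config (see
#'   [read_pipeline_config()]).
#' @param outdir output directory.
#' @param stages stages to run (default: all, in order).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir, stages = .pipeline_stages) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "study_config"))
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad) > 0L) fb_stop("unknown pipeline stage '%s'", bad[[1L]])
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  timings <- list()
  warn_log <- character(0)
  for (st in stages) {
    fn <- get(paste0(".stage_", st), mode = "function")
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(
      tryCatch(fn(config, outdir),
               error = function(e) {
                 fb_stop("pipeline stage '%s' failed: %s", st, conditionMessage(e))
               }),
      warning = function(w) {
        warn_log <<- c(warn_log, sprintf("[%s] %s", st, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[st]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(checksums) <- files
  cfg_plain <- unclass(config)
  manifest <- list(
    config = cfg_plain,
    config_hash = unname(tools::md5sum(
      {tmp <- tempfile(); writeLines(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                                                      digits = NA), tmp); tmp})),
    seed = config$seed,
    stages = stages,
    timings_s = timings,
    warnings = warn_log,
    files = checksums
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## rank-based tertile bands (ceil split, best first), identifier tie-break
.tertile_band <- function(value, id, higher_better = TRUE) {
  n <- length(value)
  if (n < 3L) return(rep(NA_character_, n))
  ord <- order(if (higher_better) -value else value, id)
  rank <- integer(n); rank[ord] <- seq_len(n)
  k <- ceiling(n / 3)
  ifelse(rank <= k, "top", ifelse(rank > n - k, "bottom", "middle"))
}

#' Render the benchmark report table
#'
#' Companies are sorted per industry by descending overall BIA-Obesity
#' score; the overall score and each performance indicator are annotated
#' with top/middle/bottom tertile bands within the industry (rank thirds,
#' ceiling split, ties broken by company identifier).  Industries with
#' fewer than three companies skip banding with a note.
#'
#' @param bia_scores verified-stage scores (from [score_commitments()]).
#' @param summaries portfolio summaries with an `industry` column.
#' @return list: `table` (data.frame) and `text` (character vector,
#'   plain-text summary).
#' @export
render_report <- function(bia_scores, summaries) {
  check_columns(bia_scores, c("company_id", "industry", "overall"),
                what = "bia_scores")
  merged <- merge(bia_scores, summaries[, setdiff(names(summaries), "industry")],
                  by = "company_id", all.x = TRUE)
  ind_dirs <- c(overall = TRUE, pct_AB = TRUE, pct_DE = FALSE,
                pct_upf = FALSE, pct_not_permitted = FALSE,
                pct_displaying_label = TRUE)
  notes <- character(0)
  parts <- lapply(split(merged, merged$industry), function(g) {
    g <- g[order(-g$overall, g$company_id), , drop = FALSE]
    for (col in names(ind_dirs)) {
      if (!col %in% names(g)) next
      band_col <- paste0(col, "_band")
      if (nrow(g) < 3L) {
        g[[band_col]] <- NA_character_
        notes <<- c(notes, sprintf(
          "industry '%s': fewer than 3 companies, tertile banding skipped",
          g$industry[[1L]]))
      } else {
        g[[band_col]] <- .tertile_band(g[[col]], g$company_id, ind_dirs[[col]])
      }
    }
    g
  })
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  txt <- c("Benchmark report: companies by descending overall BIA-Obesity score",
           "")
  for (ind in unique(tab$industry)) {
    g <- tab[tab$industry == ind, , drop = FALSE]
    txt <- c(txt, sprintf("== %s (n = %d) ==", ind, nrow(g)))
    txt <- c(txt, sprintf("  %-12s overall %5.1f%% [%s]",
                          g$company_id, g$overall,
                          ifelse(is.na(g$overall_band), "-", g$overall_band)))
    txt <- c(txt, "")
  }
  if (length(unique(notes)) > 0L) txt <- c(txt, paste("note:", unique(notes)))
  list(table = tab, text = txt)
}
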