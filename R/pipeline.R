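#' @include synthetic-world.R trade.R
NULL

#' Pipeline configuration
#'
#' Assembles the configuration for [runPipeline()]. `inputDir` must hold
#' a world fixture in the layout written by [writeWorld()] (per-crop
#' ASCII-grid pairs, `richness.asc`, `zones.csv`, `water.csv`,
#' `trade.csv`, `manifest.yml`).
#'
#' @param inputDir fixture directory.
#' @param outDir output directory.
#' @param weightBasis `"dry"` (default) or `"fresh"`: the production
#'   basis used in every downstream metric; trade tonnes are converted to
#'   the same basis.
#' @param tol zero-production tolerance in tonnes.
#' @param exclude country ids excluded from country statistics.
#' @param focal focal countries for the consumption stage (default: all).
#' @param targetGrid `"richness"` (align crop layers onto the richness
#'   grid, the default) or `"crops"` (align richness onto the crop grid).
#' @param groups optional named character vector mapping crop ids to food
#'   groups for the summary stage (default: one group `"all"`).
#' @return A named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(inputDir, outDir, weightBasis = c("dry", "fresh"),
                           tol = 1e-9, exclude = character(),
                           focal = NULL,
                           targetGrid = c("richness", "crops"),
                           groups = NULL) {
  stopifnot(tol >= 0)
  list(
    inputDir = inputDir, outDir = outDir,
    weightBasis = match.arg(weightBasis), tol = tol,
    exclude = exclude, focal = focal,
    targetGrid = match.arg(targetGrid), groups = groups
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()] in snake_case
#' (`input_dir`, `out_dir`, `weight_basis`, `tol`, `exclude`, `focal`,
#' `target_grid`, `groups`).
#'
#' @param path YAML file.
#' @return A configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pipelineConfig(
    inputDir = y$input_dir, outDir = y$out_dir,
    weightBasis = if (is.null(y$weight_basis)) "dry" else y$weight_basis,
    tol = if (is.null(y$tol)) 1e-9 else y$tol,
    exclude = as.character(y$exclude %||% character()),
    focal = y$focal,
    targetGrid = if (is.null(y$target_grid)) "richness" else y$target_grid,
    groups = if (is.null(y$groups)) NULL else unlist(y$groups)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full accounting pipeline
#'
#' Stages: `metrics` writes per-cell ASR and BP layers per crop;
#' `aggregate` writes the per-(country, crop) metrics table; `consume`
#' writes the consumption-pressure decomposition for each focal country;
#' `rank` writes global crop and country rankings by BP, production and
#' ASR; `summarize` writes the domestic-versus-imported summary. A run
#' log records the weight basis, grid, tolerances, masked-cell counts and
#' unattributed-import shares. Outputs are byte-stable across identical
#' runs (fixed column order, scientific notation with 9 significant
#' digits).
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @param stages subset of stages to write output for (all by default;
#'   earlier stages a later stage depends on are still computed).
#' @return Invisibly, a list with the in-memory results: `metrics`,
#'   `consumption`, `consumptionOrigins`, `rankings`, `summary`, `world`.
#' @export
runPipeline <- function(config,
                        stages = c("metrics", "aggregate", "consume",
                                   "rank", "summarize")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  world <- withStage("load", readWorld(config$inputDir))
  dry <- config$weightBasis == "dry"
  spec <- if (config$targetGrid == "richness") world$richness@spec
          else gridOf(world$crops[[1]])
  note("weight_basis: %s", config$weightBasis)
  note("grid: %d x %d cells of %.17g deg", spec@nRows, spec@nCols,
       spec@cellSize)
  note("zero_production_tolerance_t: %.9e", config$tol)
  note("excluded_countries: %s",
       if (length(config$exclude)) paste(config$exclude, collapse = ",")
       else "none")

  world$crops <- withStage("align", lapply(world$crops, function(cr) {
    if (sameGrid(gridOf(cr), spec)) return(cr)
    pre <- sum(cr@harvestedArea@values, na.rm = TRUE)
    ha <- alignToGrid(cr@harvestedArea, spec)
    note("align %s: harvested-area total %.9e -> %.9e", cr@cropId, pre,
         sum(ha@values, na.rm = TRUE))
    cropData(cr@cropId, ha, alignToGrid(cr@yield, spec), cr@waterPct)
  }))
  if (!sameGrid(world$richness@spec, spec))
    world$richness <- withStage("align",
                                alignToGrid(world$richness, spec))

  # per-cell layers
  layers <- withStage("metrics", lapply(world$crops, function(cr) {
    p <- computeProduction(cr, dry = dry)
    asr <- computeASR(cr, world$richness)
    bp <- computeBP(cr, world$richness, production = p, tol = config$tol)
    note("crop %s: masked BP cells %d of %d", cr@cropId,
         sum(is.na(bp@values)), length(bp@values))
    list(production = p, asr = asr, bp = bp)
  }))
  if ("metrics" %in% stages) {
    ldir <- file.path(out, "layers")
    dir.create(ldir, showWarnings = FALSE)
    for (id in names(layers)) {
      writeAsciiGrid(layers[[id]]$asr, file.path(ldir, paste0(id, "_asr.asc")))
      writeAsciiGrid(layers[[id]]$bp, file.path(ldir, paste0(id, "_bp.asc")))
    }
  }

  metrics <- withStage("aggregate", countryCropMetrics(
    world$crops, world$richness, world$zones, dry = dry,
    tol = config$tol, exclude = config$exclude
  ))
  meta <- list(
    weight_basis = config$weightBasis,
    grid = sprintf("%dx%d@%.17g", spec@nRows, spec@nCols, spec@cellSize),
    zero_production_tolerance_t = sprintf("%.9e", config$tol)
  )
  if ("aggregate" %in% stages)
    writeStableCSV(metrics, file.path(out, "country_crop_metrics.csv"),
                   meta = meta)

  # consumption stage
  trade <- if (dry) tradeToDry(world$trade, world$water) else world$trade
  focal <- config$focal %||% sort(unique(metrics$country))
  consRows <- list()
  origRows <- list()
  withStage("consume", for (fc in focal) {
    for (id in names(world$crops)) {
      prodTot <- metrics$production_total[metrics$country == fc &
                                            metrics$crop == id]
      prodTot <- if (length(prodTot)) prodTot else 0
      sp <- splitSupply(fc, id, prodTot, trade)
      cp <- bpCons(fc, id, sp$domestic, metrics, trade)
      consRows[[length(consRows) + 1L]] <- as.data.frame(cp)
      if (length(cp@importTerms)) {
        f <- trade@flows
        f <- f[f$crop == id & f$destination == fc &
                 f$origin %in% names(cp@importTerms), , drop = FALSE]
        origRows[[length(origRows) + 1L]] <- data.frame(
          focal = fc, crop = id, origin = names(cp@importTerms),
          tonnes = f$tonnes[match(names(cp@importTerms), f$origin)],
          term = as.numeric(cp@importTerms), stringsAsFactors = FALSE
        )
      }
      if (cp@unattributedImportTonnes > 0)
        note("consume %s/%s: unattributed imports %.9e t (share %.4f)",
             fc, id, cp@unattributedImportTonnes,
             cp@unattributedImportTonnes /
               (sp$imported + (sp$imported == 0)))
    }
  })
  consTab <- do.call(rbind, consRows)
  consTab <- consTab[order(consTab$focal, consTab$crop), , drop = FALSE]
  rownames(consTab) <- NULL
  origTab <- if (length(origRows)) {
    ot <- do.call(rbind, origRows)
    ot <- ot[order(ot$focal, ot$crop, ot$origin), , drop = FALSE]
    rownames(ot) <- NULL
    ot
  } else data.frame(focal = character(), crop = character(),
                    origin = character(), tonnes = numeric(),
                    term = numeric())
  if ("consume" %in% stages) {
    writeStableCSV(consTab, file.path(out, "consumption_pressure.csv"),
                   meta = meta)
    writeStableCSV(origTab, file.path(out, "consumption_origins.csv"))
  }

  rankings <- withStage("rank", buildRankings(metrics))
  if ("rank" %in% stages)
    for (nm in names(rankings))
      writeStableCSV(rankings[[nm]],
                     file.path(out, paste0("rank_", nm, ".csv")))

  summaryTab <- withStage("summarize",
    summarizeDomesticVsImported(consTab, origTab, metrics,
                                groups = config$groups))
  if ("summarize" %in% stages)
    writeStableCSV(summaryTab,
                   file.path(out, "domestic_vs_imported.csv"))

  writeLines(logLines, file.path(out, "run_log.txt"))
  invisible(list(metrics = metrics, consumption = consTab,
                 consumptionOrigins = origTab, rankings = rankings,
                 summary = summaryTab, world = world, log = logLines))
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# Global crop and country rankings by BP, production and ASR.
buildRankings <- function(metrics) {
  aggBy <- function(key) {
    p <- tapply(metrics$production_total, metrics[[key]], sum)
    a <- tapply(metrics$asr_total, metrics[[key]], sum)
    bp <- as.numeric(a) / ifelse(as.numeric(p) > 0, as.numeric(p), NA)
    data.frame(
      id = names(p), production_total = as.numeric(p),
      asr_total = as.numeric(a), bp = bp, stringsAsFactors = FALSE
    )
  }
  crops <- aggBy("crop")
  countries <- aggBy("country")
  list(
    crops_bp = rankEntities(crops, "bp", "id"),
    crops_production = rankEntities(crops, "production_total", "id"),
    crops_asr = rankEntities(crops, "asr_total", "id"),
    countries_bp = rankEntities(countries, "bp", "id"),
    countries_production = rankEntities(countries, "production_total", "id"),
    countries_asr = rankEntities(countries, "asr_total", "id")
  )
}

#' Domestic-versus-imported pressure summary
#'
#' For each focal country and food group: the median and mean, over crops
#' with value greater than zero, of the per-tonne BP and of the
#' consumption-pressure component, split into the domestic component
#' (domestic supply at the focal country's own BP) and the imported
#' component (import flows at the trade-weighted average of origin BPs).
#' Groups with no positive entries produce no row.
#'
#' @param consTab consumption table from [runPipeline()] (columns `focal`,
#'   `crop`, `domestic_term`, `import_term`, ...).
#' @param origTab per-origin breakdown table (columns `focal`, `crop`,
#'   `origin`, `tonnes`, `term`).
#' @param metrics per-(country, crop) metrics table (for the domestic
#'   per-tonne BP).
#' @param groups optional named character vector crop id -> group.
#' @return data.frame with one row per (focal, group, component).
#' @export
summarizeDomesticVsImported <- function(consTab, origTab, metrics,
                                        groups = NULL) {
  grp <- function(crop) {
    if (is.null(groups)) rep("all", length(crop))
    else unname(groups[crop])
  }
  rows <- list()
  for (fc in sort(unique(consTab$focal))) {
    ct <- consTab[consTab$focal == fc, , drop = FALSE]
    # per-crop per-tonne BPs
    bpDom <- metrics$bp_mean[match(paste(fc, ct$crop),
                                   paste(metrics$country, metrics$crop))]
    impBP <- vapply(ct$crop, function(id) {
      o <- origTab[origTab$focal == fc & origTab$crop == id, ,
                   drop = FALSE]
      if (!nrow(o) || sum(o$tonnes) <= 0) NA_real_
      else sum(o$term) / sum(o$tonnes)
    }, 0)
    tab <- data.frame(
      crop = ct$crop, group = grp(ct$crop),
      bp_domestic = bpDom, cons_domestic = ct$domestic_term,
      bp_imported = impBP, cons_imported = ct$import_term,
      stringsAsFactors = FALSE
    )
    for (g in sort(unique(tab$group))) {
      tg <- tab[tab$group == g, , drop = FALSE]
      for (comp in c("domestic", "imported")) {
        bp <- tg[[paste0("bp_", comp)]]
        cons <- tg[[paste0("cons_", comp)]]
        keep <- !is.na(cons) & cons > 0 & !is.na(bp)
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          focal = fc, group = g, component = comp, n = sum(keep),
          bp_median = stats::median(bp[keep]), bp_mean = mean(bp[keep]),
          bp_cons_median = stats::median(cons[keep]),
          bp_cons_mean = mean(cons[keep]), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows))
    return(data.frame(focal = character(), group = character(),
                      component = character(), n = integer(),
                      bp_median = numeric(), bp_mean = numeric(),
                      bp_cons_median = numeric(), bp_cons_mean = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
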