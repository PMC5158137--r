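## End-to-end orchestration: synthesize or load inputs, run the
## morphometry + orientation and elasticity arms, write per-item tables
## and group summaries with a provenance block.

pipelineDefaults <- function() list(
  seed = 1L,
  images = list(),
  morphometry = list(threshold = 0.5, tophatRadius = 5, smoothSigma = 10,
                     diagonalWeight = FALSE, useFullFrameMask = FALSE),
  orientation = list(elementLength = 11, angleStep = 10,
                     windowDiameter = 51),
  curves = list(),
  afm = list(depths = c(200, 400, 600), baselineFraction = 0.3,
             eBounds = c(1, 1e6))
)

mergeConfig <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    defaults[[nm]] <- if (is.list(cfg[[nm]]) && is.list(defaults[[nm]]))
      mergeConfig(defaults[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain filament images (synthetic, generated from the
#' config, or TIFF paths); (2) per image: cell-area detection, top-hat +
#' threshold binarisation, skeleton/branch-point morphometry and the
#' orientation/alignment analysis; (3) obtain force curves (synthetic or
#' CSV paths) and fit the Sneddon model at the configured depths;
#' (4) group summaries (t statistics for morphometry metrics, rank-sum
#' for elasticity). Identical config and seed give byte-identical
#' outputs. Per-item failures are recorded in status columns; only
#' configuration errors abort the run.
#'
#' Config layout (YAML file or nested list; missing entries take
#' defaults): \code{seed}; \code{images$synthetic} (\code{n}, optional
#' \code{groups}, plus [NetworkSpec()] arguments) or \code{images$paths}
#' (+ \code{images$groups}); \code{morphometry} (threshold,
#' tophatRadius, smoothSigma, diagonalWeight, useFullFrameMask);
#' \code{orientation} (elementLength, angleStep, windowDiameter);
#' \code{curves$synthetic} (\code{groupE} named vector of Young's
#' moduli, \code{nCellsPerGroup}, \code{curvesPerCell}, plus
#' [CurveSpec()] arguments) or \code{curves$paths} (+
#' \code{curves$groups}, \code{curves$cellIds}); \code{afm} (depths,
#' baselineFraction, eBounds).
#'
#' @param config nested list or path to a YAML file.
#' @param outDir output directory; created if missing. CSV tables and a
#'   provenance JSON are written there.
#' @return A [Report-class].
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- mergeConfig(pipelineDefaults(), config)
  if (!is.null(cfg$images$paths) && !all(file.exists(cfg$images$paths)))
    stop("missing input image(s): ",
         paste(cfg$images$paths[!file.exists(cfg$images$paths)],
               collapse = ", "))
  if (!is.null(cfg$curves$paths) && !all(file.exists(cfg$curves$paths)))
    stop("missing input curve(s): ",
         paste(cfg$curves$paths[!file.exists(cfg$curves$paths)],
               collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  ## ---- images ----
  images <- list(); imgGroups <- character()
  if (!is.null(cfg$images$synthetic)) {
    sy <- cfg$images$synthetic
    n <- as.integer(sy$n %||% 3L)
    grp <- rep_len(sy$groups %||% "groupA", n)
    specArgs <- sy[setdiff(names(sy), c("n", "groups", "seed"))]
    for (i in seq_len(n)) {
      spec <- do.call(NetworkSpec, c(specArgs, list(seed = seed + i)))
      images[[i]] <- generateFilamentImage(spec,
        id = sprintf("synthetic_%02d", i))$image
    }
    imgGroups <- grp
  } else if (!is.null(cfg$images$paths)) {
    images <- lapply(cfg$images$paths, readFilamentImage)
    imgGroups <- rep_len(cfg$images$groups %||% "groupA", length(images))
  }

  mrows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    row <- tryCatch({
      mcfg <- cfg$morphometry
      override <- if (isTRUE(mcfg$useFullFrameMask))
        CellMask(matrix(TRUE, nrow(pixels(img)), ncol(pixels(img))))
      morph <- analyzeMorphometry(img, threshold = mcfg$threshold,
        tophatRadius = mcfg$tophatRadius, smoothSigma = mcfg$smoothSigma,
        diagonalWeight = isTRUE(mcfg$diagonalWeight),
        cellMaskOverride = override)
      ocfg <- cfg$orientation
      ori <- analyzeOrientation(morph$binary,
        elementLength = ocfg$elementLength, angleStep = ocfg$angleStep,
        windowDiameter = ocfg$windowDiameter)
      res <- morph$result
      data.frame(id = imageId(img), group = imgGroups[i],
                 area_px2 = maskArea(morph$mask),
                 skeleton_length_px = skeletonLength(res),
                 branchpoints = branchpointCount(res),
                 mt_density = mtDensity(res),
                 crossing_density = crossingDensity(res),
                 angular_alignment = ori$alignment, status = "ok")
    }, error = function(e)
      data.frame(id = imageId(img), group = imgGroups[i],
                 area_px2 = NA_real_, skeleton_length_px = NA_real_,
                 branchpoints = NA_integer_, mt_density = NA_real_,
                 crossing_density = NA_real_, angular_alignment = NA_real_,
                 status = paste0("error: ", conditionMessage(e))))
    mrows[[length(mrows) + 1L]] <- row
  }
  morphTab <- if (length(mrows)) do.call(rbind, mrows) else
    data.frame(id = character(), group = character(),
               area_px2 = numeric(), skeleton_length_px = numeric(),
               branchpoints = integer(), mt_density = numeric(),
               crossing_density = numeric(),
               angular_alignment = numeric(), status = character())

  ## ---- curves ----
  curves <- list(); curveGroups <- character(); cellIds <- character()
  if (!is.null(cfg$curves$synthetic)) {
    sy <- cfg$curves$synthetic
    groupE <- unlist(sy$groupE %||% c(groupA = 500))
    nCells <- as.integer(sy$nCellsPerGroup %||% 3L)
    perCell <- as.integer(sy$curvesPerCell %||% 8L)
    specArgs <- sy[setdiff(names(sy),
      c("groupE", "nCellsPerGroup", "curvesPerCell", "seed"))]
    cseed <- seed * 1000L
    for (g in names(groupE)) for (ci in seq_len(nCells)) {
      cell <- sprintf("%s_cell%02d", g, ci)
      for (k in seq_len(perCell)) {
        cseed <- cseed + 1L
        spec <- do.call(CurveSpec, c(specArgs,
          list(youngsModulus = unname(groupE[[g]]), seed = cseed)))
        curves[[length(curves) + 1L]] <- generateForceCurve(spec,
          id = sprintf("%s_curve%02d", cell, k))
        curveGroups <- c(curveGroups, g)
        cellIds <- c(cellIds, cell)
      }
    }
  } else if (!is.null(cfg$curves$paths)) {
    curves <- lapply(cfg$curves$paths, readForceCurve)
    curveGroups <- rep_len(cfg$curves$groups %||% "groupA", length(curves))
    cellIds <- cfg$curves$cellIds %||%
      vapply(curves, function(x) x@id, "")
  }

  elastTab <- if (length(curves)) {
    fits <- batchFit(curves, depths = cfg$afm$depths, cellIds = cellIds,
                     eBounds = cfg$afm$eBounds,
                     baselineFraction = cfg$afm$baselineFraction)
    fits$group <- curveGroups[match(fits$cell_id, cellIds)]
    fits[c("curve_id", "cell_id", "group", "depth_nm", "E_Pa", "z0_nm",
           "rms_nN", "n_points", "status")]
  } else data.frame(curve_id = character(), cell_id = character(),
                    group = character(), depth_nm = numeric(),
                    E_Pa = numeric(), z0_nm = numeric(),
                    rms_nN = numeric(), n_points = integer(),
                    status = character())

  ## ---- summaries ----
  summaries <- list()
  if (nrow(morphTab) && length(unique(morphTab$group)) >= 2)
    summaries$morphometry <- summarizeGroups(morphTab,
      metrics = c("mt_density", "crossing_density", "angular_alignment"),
      group = "group", test = "t")
  if (nrow(elastTab) && length(unique(elastTab$group)) >= 2) {
    cells <- attr(batchFitCells(elastTab), "cells")
    summaries$elasticity <- summarizeGroups(
      merge(cells, unique(elastTab[c("cell_id", "group")])),
      metrics = "E_Pa", group = "group", test = "ranksum",
      by = "depth_nm")
  }

  prov <- list(config = cfg, package_version =
                 as.character(utils::packageVersion("cytomech")),
               seed = seed)
  provPath <- file.path(outDir, "provenance.json")
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov$config_hash <- unname(tools::md5sum(provPath))

  write.csv(morphTab, file.path(outDir, "morphometry.csv"),
            row.names = FALSE)
  write.csv(elastTab, file.path(outDir, "elasticity.csv"),
            row.names = FALSE)
  for (nm in names(summaries))
    write.csv(summaries[[nm]]$summary,
              file.path(outDir, paste0("summary_", nm, ".csv")),
              row.names = FALSE)
  new("Report", morphometry = morphTab, elasticity = elastTab,
      summaries = summaries, provenance = prov)
}

## per-cell median E table from an elasticity table
batchFitCells <- function(elastTab) {
  ok <- elastTab[elastTab$status == "ok", ]
  cells <- stats::aggregate(E_Pa ~ cell_id + depth_nm, data = ok,
                            FUN = median)
  structure(elastTab, cells = cells[order(cells$cell_id,
                                          cells$depth_nm), ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group summaries with pairwise comparisons
#'
#' Per group and metric: n, median, mean and SEM (NA, flagged, for
#' singleton groups). Pairwise comparisons between the first two groups:
#' Welch t statistic for \code{test = "t"} (used for the morphometry
#' metrics) or the rank-sum comparison of [compareGroups()] for
#' \code{test = "ranksum"} (used for the elasticity metric).
#'
#' @param table data.frame of per-item rows.
#' @param metrics character vector of metric column names.
#' @param group name of the grouping column.
#' @param test "t" or "ranksum".
#' @param by optional stratification column (e.g. depth_nm).
#' @return list with \code{summary} (data.frame) and \code{comparisons}
#'   (data.frame of statistic and two-sided p per metric and stratum).
#' @export
summarizeGroups <- function(table, metrics, group = "group",
                            test = c("t", "ranksum"), by = NULL) {
  test <- match.arg(test)
  groups <- sort(unique(table[[group]]))
  if (length(groups) < 2) stop("need at least two groups")
  strata <- if (is.null(by)) list(NULL) else sort(unique(table[[by]]))
  srows <- list(); crows <- list()
  for (st in strata) {
    sub <- if (is.null(by)) table else table[table[[by]] == st, ]
    for (m in metrics) for (g in groups) {
      v <- sub[[m]][sub[[group]] == g]
      v <- v[!is.na(v)]
      srows[[length(srows) + 1L]] <- data.frame(
        stratum = if (is.null(by)) NA else st, metric = m, group = g,
        n = length(v), median = median(v), mean = mean(v),
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        sem_defined = length(v) > 1)
    }
    for (m in metrics) {
      va <- sub[[m]][sub[[group]] == groups[1]]
      vb <- sub[[m]][sub[[group]] == groups[2]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      cmp <- if (test == "t") {
        if (identical(sort(va), sort(vb))) list(stat = 0, p = 1) else
          tryCatch({
            tt <- t.test(va, vb)
            list(stat = unname(tt$statistic), p = tt$p.value)
          }, error = function(e) list(stat = NA_real_, p = NA_real_))
      } else {
        mw <- compareGroups(va, vb)
        list(stat = mw$U, p = mw$p)
      }
      crows[[length(crows) + 1L]] <- data.frame(
        stratum = if (is.null(by)) NA else st, metric = m, test = test,
        statistic = cmp$stat, p = cmp$p)
    }
  }
  list(summary = do.call(rbind, srows),
       comparisons = do.call(rbind, crows))
}
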