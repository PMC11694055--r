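# End-to-end orchestration: classify -> localize -> blend -> defocus map
# -> depth volume -> red spot profile -> conic mesh, with artifacts and a
# machine-readable summary.

#' Construct a pipeline configuration
#'
#' All arguments default to the study configuration: CAM tapped at
#' "block5_conv4", blend alpha 0.4, Canny thresholds (50, 150), re-blur
#' sigma 1, blur clamp 5, depth scale 1000, thresholds 0-1000 by 100, no
#' exclusions, linear conic radii, absolute depth normalization, edges on
#' the original image ("blended" remains available; the blended heatmap's
#' own color ramps would otherwise read as spurious defocus).
#'
#' @param camLayer,blendAlpha,cannyLow,cannyHigh,sigma0,maxBlur,depthScale
#'   stage tunables; see \linkS4class{PipelineConfig}.
#' @param thresholds,exclusions,radiusMode,depthNormalization,edgeSource
#'   stage tunables; see \linkS4class{PipelineConfig}.
#' @param seed integer seed for stage-level randomness.
#' @param outputDir artifact directory (created if missing).
#' @return a validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(camLayer = "block5_conv4", blendAlpha = 0.4,
                           cannyLow = 50, cannyHigh = 150, sigma0 = 1,
                           maxBlur = 5, depthScale = 1000,
                           thresholds = seq(0, 1000, by = 100),
                           exclusions = list(), radiusMode = "linear",
                           depthNormalization = "absolute",
                           edgeSource = "original", seed = 1L,
                           outputDir = tempfile("lesiondepth_")) {
  new("PipelineConfig", camLayer = camLayer, blendAlpha = blendAlpha,
      cannyLow = cannyLow, cannyHigh = cannyHigh, sigma0 = sigma0,
      maxBlur = maxBlur, depthScale = depthScale, thresholds = thresholds,
      exclusions = exclusions, radiusMode = radiusMode,
      depthNormalization = depthNormalization, edgeSource = edgeSource,
      seed = as.integer(seed), outputDir = outputDir)
}

writeGridPNG <- function(grid, path, colormap = c("viridis", "gray")) {
  colormap <- match.arg(colormap)
  if (colormap == "gray") {
    png::writePNG(grid, path)
  } else {
    cols <- viridisColors(as.vector(grid))
    png::writePNG(array(cols, c(nrow(grid), ncol(grid), 3)), path)
  }
  invisible(path)
}

#' Run the full lesion-depth pipeline
#'
#' Executes every stage in order on one image: classification through the
#' adapter, gradient class activation mapping, heatmap blending, defocus
#' depth-map estimation, Gabor depth volume, red spot profiling (with
#' configured anomaly exclusions), and conic surface meshing. Each stage
#' failure aborts with the stage name and cause; artifacts written before
#' the failure are retained for debugging. Identical config, seed and
#' (stub) adapter reproduce identical summaries.
#'
#' Artifacts written to \code{config@outputDir}: \code{blended.png},
#' \code{defocus.png} (min-max stretched, viridis) and
#' \code{defocus.csv}, \code{cloud.ply}/\code{cloud.csv},
#' \code{profile.csv}, \code{conic.obj}/\code{conic.ply},
#' \code{summary.json}, \code{run.log}.
#'
#' @param image a \linkS4class{LesionImage} or a PNG file path.
#' @param adapter a \linkS4class{ModelAdapter}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{PipelineResult}.
#' @examples
#' img <- generateLesionImage(lesionSpec(seed = 3, edgeBlurSigma = 2))
#' res <- runPipeline(img, stubAdapter(0.98),
#'                    pipelineConfig(outputDir = tempfile()))
#' res
#' @export
runPipeline <- function(image, adapter, config = pipelineConfig()) {
  validObject(config)
  if (is.character(image)) image <- readLesionImage(image)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(config@outputDir, name)
  logLines <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    logLines <<- c(logLines, sprintf("%-12s %8.3f s", name, dt))
    out
  }
  withSeed(config@seed, {
    cls <- stage("classify", classifyLesion(image, adapter))
    cam <- stage("gradcam", {
      A <- adapter@featureFun(image)
      G <- adapter@gradFun(image, 1)
      gradCAM(A, G, sourceLayer = config@camLayer)
    })
    blended <- stage("blend", superimpose(image, cam, config@blendAlpha))
    writeLesionImage(blended, fp("blended.png"))
    depth <- stage("defocus", {
      src <- if (config@edgeSource == "blended") blended else image
      gray <- luminance(src@raster)
      edges <- detectEdges(gray, config@cannyLow, config@cannyHigh)
      reblur <- gaussianSmooth(gray, config@sigma0)
      sparse <- estimateEdgeBlur(gray, reblur, edges, config@sigma0,
                                 config@maxBlur)
      dense <- suppressWarnings(propagateDefocus(sparse))
      list(display = normalizeMinMax(dense),
           volume = if (config@depthNormalization == "absolute")
             normalizeAbsolute(dense, config@maxBlur)
           else normalizeMinMax(dense))
    })
    writeGridPNG(grid(depth$display), fp("defocus.png"))
    utils::write.table(grid(depth$display), fp("defocus.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    cloud <- stage("volume", depthVolume(depth$volume,
                                         depthScale = config@depthScale))
    writeCloudPLY(cloud, fp("cloud.ply"))
    writeCloudCSV(cloud, fp("cloud.csv"))
    profile <- stage("redspot", redSpotProfile(cloud,
        thresholds = config@thresholds, exclusions = config@exclusions))
    writeProfileCSV(profile, fp("profile.csv"))
    conic <- stage("conic", buildConic(profile, radiusMode = config@radiusMode))
    files <- c(blended = fp("blended.png"), defocus = fp("defocus.png"),
               defocus_csv = fp("defocus.csv"), cloud = fp("cloud.ply"),
               cloud_csv = fp("cloud.csv"), profile = fp("profile.csv"),
               summary = fp("summary.json"), log = fp("run.log"))
    if (nrow(conicSlices(conic))) {
      mesh <- stage("mesh", meshFromConic(conic))
      writeOBJ(mesh, fp("conic.obj"))
      writePLY(mesh, fp("conic.ply"))
      files <- c(files, mesh_obj = fp("conic.obj"), mesh_ply = fp("conic.ply"))
    }
    db <- as.numeric(depthBound(profile))
    de <- deepestExtent(profile)
    jsonlite::write_json(list(
      probability = cls$probability, label = cls$label,
      depth_bound = db, deepest_extent = de,
      counts = profile@counts, thresholds = profile@thresholds,
      seed = config@seed), fp("summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(logLines, fp("run.log"))
    new("PipelineResult", probability = cls$probability, label = cls$label,
        depthBound = db, deepestExtent = de, profile = profile,
        files = files)
  })
}
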