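#' Read a grayscale TIFF stack into a VoxelVolume
#'
#' Accepts a multi-page TIFF file or a directory of numbered 2D TIFF
#' slices (sorted by file name). 8- and 16-bit grayscale images are
#' accepted; RGB or mixed-shape stacks are refused. Slices are stored
#' \code{[x, y, z]} (TIFF rows become y).
#'
#' @param path TIFF file or directory of slice TIFFs.
#' @param voxelSize isotropic voxel size in mm.
#' @param provenance id string (defaults to the file/directory name).
#' @return a [VoxelVolume-class].
#' @export
readStack <- function(path, voxelSize, provenance = basename(path)) {
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    if (!file.exists(path)) stop("stack path does not exist: ", path)
    p <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(p)) list(p) else p
  }
  if (any(vapply(pages, function(m) length(dim(m)) != 2L, TRUE)))
    stop("non-grayscale TIFF: expected single-channel 2D pages")
  d1 <- dim(pages[[1]])
  if (any(vapply(pages, function(m) !identical(dim(m), d1), TRUE)))
    stop("mixed slice shapes in stack")
  vol <- array(0, c(d1[2], d1[1], length(pages)))  # [x, y, z]
  for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])
  new("VoxelVolume", intensities = vol, voxelSize = voxelSize,
      provenance = provenance)
}

#' Write a VoxelVolume as a multi-page 8-bit TIFF
#'
#' @param volume a [VoxelVolume-class] with intensities on 0..255.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  v <- volume@intensities
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a CrossSectionImage as an 8-bit TIFF
#'
#' @param section a [CrossSectionImage-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSection <- function(section, path) {
  stopifnot(is(section, "CrossSectionImage"))
  tiff::writeTIFF(t(section@intensities) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a single 2D grayscale TIFF as a CrossSectionImage
#'
#' @param path TIFF file.
#' @param pixelSize pixel size in mm.
#' @param provenance id string.
#' @return a [CrossSectionImage-class].
#' @export
readSection <- function(path, pixelSize, provenance = basename(path)) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L)
    stop("non-grayscale TIFF: expected a single-channel 2D image")
  new("CrossSectionImage", intensities = t(m), pixelSize = pixelSize,
      provenance = provenance)
}

#' Run the full specimen-to-results pipeline
#'
#' For each specimen listed in the metadata: read the stack, binarize,
#' align to principal axes, orient about the long axis, measure
#' intermetaphyseal length, extract sections at the requested fractions and
#' quantify each one. If at least 8 specimens succeed, cohort trend and
#' stage analyses are added. Writes a tidy results CSV, per-trend CSVs and
#' a JSON manifest (configuration, package version, seed, per-file
#' checksums, warnings) into \code{outputDir}.
#'
#' @param metadata data frame with columns \code{id}, \code{age_years},
#'   \code{side}, \code{voxel_size_mm} and \code{stack_path}.
#' @param outputDir output directory (created if needed).
#' @param fractions length fractions to section (default c(0.35, 0.5, 0.65)).
#' @param threshold \code{"auto"} or explicit intensity.
#' @param distal passed to [alignPrincipalAxes()].
#' @param cropRange optional z index range (after alignment) to retain, for
#'   partially fused ends.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list with \code{results}, \code{cohort} (or NULL), \code{manifest}.
#'   Errors (listing the specimens) if any specimen fails.
#' @export
runPipeline <- function(metadata, outputDir, fractions = c(0.35, 0.5, 0.65),
                        threshold = "auto", distal = "auto",
                        cropRange = NULL, seed = 1L) {
  need <- c("id", "age_years", "side", "voxel_size_mm", "stack_path")
  if (!all(need %in% names(metadata)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly inside (0, 1)")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  warningsLog <- character(0)
  failures <- character(0)
  rows <- list()
  for (i in seq_len(nrow(metadata))) {
    m <- metadata[i, ]
    res <- tryCatch(withCallingHandlers({
      vol <- readStack(m$stack_path, m$voxel_size_mm, provenance = m$id)
      bin <- binarizeVolume(vol, threshold)
      aligned <- alignPrincipalAxes(bin, vol@intensities, m$voxel_size_mm,
                                    distal = distal, provenance = m$id)
      aligned <- orientAboutLongAxis(aligned, side = tolower(
        ifelse(m$side %in% c("L", "left"), "left", "right")))
      if (!is.null(cropRange)) {
        keep <- seq(max(1L, cropRange[1]),
                    min(dim(aligned@binaryVolume)[3], cropRange[2]))
        aligned@binaryVolume <- aligned@binaryVolume[, , keep]
        aligned@grayVolume <- aligned@grayVolume[, , keep]
      }
      len <- intermetaphysealLength(aligned)
      do.call(rbind, lapply(fractions, function(f) {
        sec <- extractSection(aligned, f)
        g <- as.data.frame(sectionGeometry(sec, threshold))
        cbind(data.frame(id = m$id, fraction = f,
                         intermetaphyseal_length_mm = len), g)
      }))
    }, warning = function(w) {
      warningsLog <<- c(warningsLog,
                        sprintf("%s: %s", m$id, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", m$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[m$id]] <- res
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(results)) rownames(results) <- NULL
  cohort <- NULL
  if (!is.null(results) && length(unique(results$id)) >= 8L)
    cohort <- runCohortAnalysis(
      metadata[metadata$id %in% results$id,
               setdiff(names(metadata), "stack_path"), drop = FALSE],
      results)

  files <- character(0)
  if (!is.null(results)) {
    resPath <- file.path(outputDir, "section_geometry.csv")
    utils::write.csv(results, resPath, row.names = FALSE)
    files <- c(files, resPath)
  }
  if (!is.null(cohort)) {
    for (key in names(cohort$trends)) {
      tr <- cohort$trends[[key]]
      p <- file.path(outputDir, sprintf("trend_%s.csv", key))
      utils::write.csv(data.frame(age_years = tr@grid, fitted = tr@fitted,
                                  ci95_half_width = tr@halfWidth),
                       p, row.names = FALSE)
      files <- c(files, p)
    }
    p <- file.path(outputDir, "stage_summaries.csv")
    ss <- cohort$stageSummaries
    ss$outliers <- vapply(ss$outliers, function(v)
      paste(v, collapse = ";"), "")
    utils::write.csv(ss, p, row.names = FALSE)
    files <- c(files, p)
  }
  manifest <- list(
    package = "boneCSG",
    version = as.character(utils::packageVersion("boneCSG")),
    seed = seed,
    config = list(fractions = fractions, threshold = threshold,
                  distal = distal, cropRange = cropRange),
    specimens = metadata$id,
    failures = failures,
    warnings = warningsLog,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  manifestPath <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (length(failures))
    stop("pipeline failed for: ", paste(failures, collapse = " | "))
  invisible(list(results = results, cohort = cohort, manifest = manifest))
}
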